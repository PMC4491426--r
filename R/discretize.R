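#' Equal-width histogram bin of a value
#'
#' Maps a value to one of `B` equal-width bins spanning `[vmin, vmax]`,
#' the interval width being `(vmax - vmin) / B`.  Bins are half-open
#' except the last: `value == vmax` falls in bin `B - 1`.  A degenerate
#' range (`vmax == vmin`) puts everything in bin 0.
#'
#' @param value numeric vector of values to bin.
#' @param vmin,vmax range of the feature (its observed min/max).
#' @param B number of bins (>= 1).
#' @return Integer bin ids in `[0, B - 1]`.
#' @examples
#' bin_index(3.9, 0, 10, 5)  # 1
#' bin_index(10, 0, 10, 5)   # 4 (max clamps into the last bin)
#' @export
bin_index <- function(value, vmin, vmax, B) {
  if (length(B) != 1L || is.na(B) || B < 1) stop("'B' must be a positive integer")
  if (vmin > vmax) stop("'vmin' must not exceed 'vmax'")
  if (anyNA(value)) stop("missing values cannot be binned")
  if (any(value < vmin | value > vmax))
    stop("value outside [vmin, vmax]: data were not range-filtered")
  if (vmax == vmin) return(integer(length(value)))
  idx <- as.integer(floor((value - vmin) / ((vmax - vmin) / B)))
  pmin(idx, as.integer(B) - 1L)
}

#' Discretize a genomic profile into bin codes
#'
#' Continuous profiles (expression, methylation) are histogram-binned per
#' gene with [bin_index()] using that gene's own min/max; already-discrete
#' GISTIC copy-number calls (-2..2) are passed through, shifted
#' order-preservingly onto codes 0..4 so all profiles share one code
#' space.
#'
#' @param x numeric genes x patients matrix with rownames (gene ids) and
#'   colnames (patient ids); no missing values (preprocessing must have
#'   run).
#' @param B number of equal-width bins for continuous data (default 5,
#'   matching the five GISTIC levels).
#' @param kind `"continuous"` or `"gistic"`.
#' @return A `discretized_profile`: list with `gene_ids`, `patient_ids`,
#'   `codes` (integer matrix, values in `[0, B - 1]`), `B` and `ranges`
#'   (per-gene min/max used for binning).
#' @export
discretize_profile <- function(x, B = 5, kind = c("continuous", "gistic")) {
  kind <- match.arg(kind)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (anyNA(x)) stop("profile contains missing values; run preprocessing first")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("profile must carry gene rownames and patient colnames")
  if (kind == "gistic") {
    if (!all(x %in% -2:2)) stop("GISTIC profile has codes outside -2..2")
    codes <- matrix(as.integer(x) + 2L, nrow(x), ncol(x))
    B <- 5L
    ranges <- cbind(min = rep(-2, nrow(x)), max = rep(2, nrow(x)))
  } else {
    rmin <- apply(x, 1L, min)
    rmax <- apply(x, 1L, max)
    codes <- matrix(0L, nrow(x), ncol(x))
    for (g in seq_len(nrow(x)))
      codes[g, ] <- bin_index(x[g, ], rmin[g], rmax[g], B)
    ranges <- cbind(min = rmin, max = rmax)
  }
  dimnames(codes) <- dimnames(x)
  structure(list(gene_ids = rownames(x), patient_ids = colnames(x),
                 codes = codes, B = as.integer(B), ranges = ranges),
            class = "discretized_profile")
}

#' @export
print.discretized_profile <- function(x, ...) {
  cat(sprintf("<discretized_profile: %d genes x %d patients, B = %d>\n",
              length(x$gene_ids), length(x$patient_ids), x$B))
  invisible(x)
}

#' Binarize overall survival into short/long-term labels
#'
#' Patients are labelled `short` if they died within `cutoff` months and
#' `long` if they survived beyond it.  Patients whose label is ambiguous
#' are dropped: unknown status or missing follow-up time, and patients
#' alive with follow-up not exceeding the cutoff (alive at exactly the
#' cutoff is still ambiguous and excluded).
#'
#' @param clinical data.frame with columns `patient_id`, `months`
#'   (overall survival, months) and `status` (`"living"` / `"deceased"`;
#'   `NA` allowed).
#' @param cutoff survival cutoff C in months (default 36).
#' @return An `outcome_labels` object: `patient_ids` (retained patients),
#'   `labels` (factor `short`/`long`) and `cutoff_months`.
#' @export
binarize_survival <- function(clinical, cutoff = 36) {
  if (length(cutoff) != 1L || is.na(cutoff) || cutoff <= 0)
    stop("'cutoff' must be a positive number of months")
  req <- c("patient_id", "months", "status")
  if (!all(req %in% names(clinical)))
    stop("clinical table must have columns: ", paste(req, collapse = ", "))
  months <- as.numeric(clinical$months)
  if (any(months < 0, na.rm = TRUE)) stop("negative survival months")
  status <- as.character(clinical$status)
  dead <- !is.na(status) & status == "deceased" & !is.na(months)
  alive_long <- !is.na(status) & status == "living" & !is.na(months) &
    months > cutoff
  keep <- dead | alive_long
  labels <- ifelse(dead & months <= cutoff, "short", "long")[keep]
  structure(list(patient_ids = as.character(clinical$patient_id)[keep],
                 labels = factor(labels, levels = c("short", "long")),
                 cutoff_months = cutoff),
            class = "outcome_labels")
}

#' @export
print.outcome_labels <- function(x, ...) {
  cat(sprintf("<outcome_labels: %d patients (%d short, %d long), C = %g months>\n",
              length(x$patient_ids), sum(x$labels == "short"),
              sum(x$labels == "long"), x$cutoff_months))
  invisible(x)
}

# 0/1 outcome codes in the patient order given (short = 1)
.outcome_codes <- function(y, patient_ids = y$patient_ids) {
  m <- match(patient_ids, y$patient_ids)
  if (anyNA(m)) stop("outcome labels missing for some patients")
  as.integer(y$labels[m] == "short")
}
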