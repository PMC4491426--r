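#' Bundle co-registered genomic profiles
#'
#' @param profiles named list of genes x patients numeric matrices
#'   (rownames = gene ids, colnames = patient ids); values may be
#'   missing before filtering.
#' @param kinds character vector (`"continuous"`/`"gistic"`), one per
#'   profile, recycled if length 1.
#' @return A `profile_set` (named list of matrices with a `kinds`
#'   attribute).
#' @export
profile_set <- function(profiles, kinds = "continuous") {
  if (!is.list(profiles) || length(profiles) == 0L ||
      is.null(names(profiles)) || any(names(profiles) == ""))
    stop("'profiles' must be a non-empty named list of matrices")
  profiles <- lapply(profiles, function(m) {
    m <- as.matrix(m)
    if (is.null(rownames(m)) || is.null(colnames(m)))
      stop("every profile needs gene rownames and patient colnames")
    m
  })
  kinds <- rep_len(match.arg(kinds, c("continuous", "gistic"),
                             several.ok = TRUE), length(profiles))
  structure(profiles, kinds = stats::setNames(kinds, names(profiles)),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set: %d profile(s)>\n", length(x)))
  for (nm in names(x))
    cat(sprintf("  %s [%s]: %d genes x %d patients\n", nm,
                attr(x, "kinds")[[nm]], nrow(x[[nm]]), ncol(x[[nm]])))
  invisible(x)
}

#' Align profiles on a complete shared gene/patient universe
#'
#' Three sequential filters: (a) per profile, genes missing across the
#' whole patient group (entirely unmeasured) are removed; (b) patients
#' with all values missing for the remaining genes in any profile are
#' removed from all profiles; (c) genes with a missing value in at least
#' one profile on the remaining patients are removed, leaving the common
#' gene set.  Output matrices share identical, sorted gene and patient
#' lists and contain no missing values.  The pass is idempotent.
#'
#' @param profiles a [profile_set()].
#' @return A filtered `profile_set`.
#' @export
filter_step1 <- function(profiles) {
  stopifnot(inherits(profiles, "profile_set"))
  kinds <- attr(profiles, "kinds")
  # shared patient universe first: profiles are co-registered
  patients <- sort(Reduce(intersect, lapply(profiles, colnames)))
  if (length(patients) == 0L) stop("no patients shared across profiles")
  mats <- lapply(profiles, function(m) m[, patients, drop = FALSE])
  # (a) genes with no observed value at all, per profile
  mats <- lapply(mats, function(m) m[rowSums(!is.na(m)) > 0L, , drop = FALSE])
  # (b) patients entirely missing in any profile
  dead_pat <- Reduce(`|`, lapply(mats, function(m) colSums(!is.na(m)) == 0L))
  patients <- patients[!dead_pat]
  if (length(patients) == 0L) stop("all patients removed by filtering")
  mats <- lapply(mats, function(m) m[, patients, drop = FALSE])
  # (c) common genes, then drop any gene still missing somewhere
  genes <- sort(Reduce(intersect, lapply(mats, rownames)))
  mats <- lapply(mats, function(m) m[genes, , drop = FALSE])
  incomplete <- Reduce(`|`, lapply(mats, function(m) rowSums(is.na(m)) > 0L))
  genes <- genes[!incomplete]
  if (length(genes) == 0L) stop("all genes removed by filtering")
  mats <- lapply(mats, function(m) m[genes, , drop = FALSE])
  profile_set(mats, kinds)
}

#' Restrict profiles to patients with an unambiguous outcome label
#'
#' Applies [binarize_survival()] and keeps, in every profile, only the
#' patients that received a definite short/long label.
#'
#' @param profiles a [profile_set()] already passed through
#'   [filter_step1()].
#' @param clinical clinical table (see [binarize_survival()]).
#' @param cutoff survival cutoff C in months.
#' @return List with `profiles` (restricted `profile_set`) and `labels`
#'   (the aligned `outcome_labels`).
#' @export
filter_step2 <- function(profiles, clinical, cutoff = 36) {
  stopifnot(inherits(profiles, "profile_set"))
  y <- binarize_survival(clinical, cutoff)
  patients <- sort(intersect(colnames(profiles[[1L]]), y$patient_ids))
  if (length(patients) == 0L) stop("no labelled patients left")
  m <- match(patients, y$patient_ids)
  y <- structure(list(patient_ids = patients, labels = y$labels[m],
                      cutoff_months = y$cutoff_months),
                 class = "outcome_labels")
  if (!all(c("short", "long") %in% y$labels))
    stop("one outcome class is empty after filtering")
  mats <- lapply(profiles, function(mm) mm[, patients, drop = FALSE])
  list(profiles = profile_set(mats, attr(profiles, "kinds")), labels = y)
}
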