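# MDR-style stratification of patients by a gene pair's code grid,
# followed by log-rank validation and Kaplan-Meier curve extraction.

#' Cohort short-term fraction rho
#'
#' The MDR cell threshold: the proportion of short-term survivors in the
#' whole retained cohort.
#'
#' @param y an `outcome_labels` object.
#' @return `n_short / n_total`.
#' @export
compute_rho <- function(y) {
  stopifnot(inherits(y, "outcome_labels"))
  n <- length(y$labels)
  if (n == 0L) stop("no patients")
  sum(y$labels == "short") / n
}

#' MDR-style high/low-risk stratification by a gene pair
#'
#' Every occupied cell of the `codes1` x `codes2` grid is labelled
#' high-risk when the fraction of short-term survivors among its patients
#' strictly exceeds `rho`, and low-risk otherwise (a cell exactly at
#' `rho` is low-risk).  Patients inherit their cell's label.  Single-gene
#' mode: omit `codes2` (equivalently pass a constant vector).
#'
#' @param codes1,codes2 per-patient integer code vectors aligned with
#'   `y$patient_ids`; `codes2 = NULL` for single-gene stratification.
#' @param y an `outcome_labels` object.
#' @param rho cell threshold, typically [compute_rho()] of the cohort.
#' @return A `risk_stratification`: `cells` (data.frame `code1`, `code2`,
#'   `n`, `n_short`, `short_frac`, `risk`), `group` (per-patient factor
#'   `low`/`high` aligned with `y$patient_ids`) and `rho`.
#' @export
stratify_mdr <- function(codes1, codes2 = NULL, y, rho) {
  stopifnot(inherits(y, "outcome_labels"))
  n <- length(y$patient_ids)
  if (is.null(codes2)) codes2 <- integer(n)
  if (length(codes1) != n || length(codes2) != n)
    stop("code vectors must align with the outcome labels")
  if (anyNA(codes1) || anyNA(codes2)) stop("missing codes")
  short <- y$labels == "short"
  key <- paste(codes1, codes2, sep = "\r")
  n_cell <- tapply(rep(1L, n), key, sum)
  s_cell <- tapply(as.integer(short), key, sum)
  frac <- s_cell / n_cell
  risk <- ifelse(frac > rho, "high", "low")
  parts <- do.call(rbind, strsplit(names(n_cell), "\r", fixed = TRUE))
  cells <- data.frame(code1 = as.integer(parts[, 1L]),
                      code2 = as.integer(parts[, 2L]),
                      n = as.integer(n_cell), n_short = as.integer(s_cell),
                      short_frac = as.numeric(frac), risk = risk,
                      stringsAsFactors = FALSE)
  cells <- cells[order(cells$code1, cells$code2), , drop = FALSE]
  rownames(cells) <- NULL
  group <- factor(risk[match(key, names(n_cell))], levels = c("low", "high"))
  structure(list(cells = cells,
                 group = stats::setNames(group, y$patient_ids),
                 rho = rho),
            class = "risk_stratification")
}

#' @export
print.risk_stratification <- function(x, ...) {
  cat(sprintf("<risk_stratification: %d cells, %d high / %d low patients, rho = %.4f>\n",
              nrow(x$cells), sum(x$group == "high"), sum(x$group == "low"),
              x$rho))
  invisible(x)
}

#' Assemble per-patient survival records
#'
#' Joins follow-up times and event indicators from the clinical table to
#' a risk grouping.  Living patients are censored; deaths are events
#' regardless of whether they fall before or after the labelling cutoff.
#'
#' @param clinical clinical table with `patient_id`, `months`, `status`.
#' @param group named factor (patient id -> `low`/`high`), e.g. the
#'   `group` field of [stratify_mdr()].
#' @return data.frame with `patient_id`, `time`, `event` (1 = death
#'   observed), `group`.
#' @export
survival_records <- function(clinical, group) {
  ids <- names(group)
  m <- match(ids, as.character(clinical$patient_id))
  if (anyNA(m)) stop("clinical rows missing for some grouped patients")
  months <- as.numeric(clinical$months)[m]
  status <- as.character(clinical$status)[m]
  if (anyNA(months) || anyNA(status))
    stop("grouped patients must have known follow-up and status")
  if (any(months < 0)) stop("negative survival months")
  data.frame(patient_id = ids, time = months,
             event = as.integer(status == "deceased"),
             group = factor(as.character(group), levels = levels(group)),
             stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of the survival experience of two
#' groups: at each distinct event time, observed deaths per group are
#' compared with their hypergeometric expectation given the risk sets;
#' the statistic is referred to a chi-square distribution with 1 degree
#' of freedom.
#'
#' @param records data.frame with `time`, `event` (0/1) and a two-level
#'   `group`, e.g. from [survival_records()].
#' @return List with `statistic` (chi-square) and `p_value`.
#' @export
logrank_test <- function(records) {
  g <- factor(records$group)
  g <- droplevels(g)
  if (nlevels(g) != 2L) stop("log-rank test needs exactly two non-empty groups")
  if (sum(records$event) == 0L) stop("log-rank test needs at least one event")
  fit <- survival::survdiff(survival::Surv(time, event) ~ g,
                            data = data.frame(time = records$time,
                                              event = records$event, g = g))
  stat <- fit$chisq
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate for one group of patients: starts at
#' `(0, 1)`, drops only at event times; censored patients leave the risk
#' set without a drop.
#'
#' @param records survival records data.frame (`time`, `event`, and
#'   optionally `group`).
#' @param group if given, restrict to records with this group label.
#' @return data.frame of step points `time`, `surv` (and `n_risk`,
#'   `n_event` for the observed times).
#' @export
km_curve <- function(records, group = NULL) {
  if (!is.null(group)) records <- records[records$group == group, , drop = FALSE]
  if (nrow(records) == 0L) stop("no patients in the requested group")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = records[, c("time", "event")])
  data.frame(time = c(0, fit$time), surv = c(1, fit$surv),
             n_risk = c(nrow(records), fit$n.risk),
             n_event = c(0L, fit$n.event))
}

#' Log-rank validation of a gene pair and its singletons
#'
#' Runs the MDR stratification + log-rank test for the pair and, for
#' comparison, for each gene alone.
#'
#' @param codes1,codes2 per-patient discretized codes of the two genes.
#' @param y `outcome_labels` for the cohort.
#' @param clinical clinical table covering the cohort.
#' @param rho MDR cell threshold (defaults to [compute_rho()] of `y`).
#' @return List with elements `pair`, `gene1`, `gene2`, each a
#'   [logrank_test()] result (or `NULL` when the stratification is
#'   degenerate, i.e. produces a single group).
#' @export
validate_pair_survival <- function(codes1, codes2, y, clinical,
                                   rho = compute_rho(y)) {
  one <- function(c1, c2) {
    st <- stratify_mdr(c1, c2, y, rho)
    if (nlevels(droplevels(st$group)) != 2L) return(NULL)
    logrank_test(survival_records(clinical, st$group))
  }
  list(pair = one(codes1, codes2),
       gene1 = one(codes1, NULL),
       gene2 = one(codes2, NULL))
}
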