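# Synthetic multi-profile generator: co-registered profiles over a
# shared gene/patient universe with planted outcome-associated pairs,
# missing values and censored survival, so the whole pipeline can be
# exercised without any external download.

#' Specification of a synthetic multi-profile dataset
#'
#' The defaults describe the reference simulation conditions used
#' throughout this package: 60 genes x 200 patients, one continuous
#' profile, an XOR-type interaction pair of penetrance 0.9 with null
#' marginals by construction, exponential survival with a 3:1 hazard
#' ratio between short- and long-term groups, and 20% uniform censoring.
#'
#' @param n_genes,n_patients dimensions of each profile.
#' @param profiles named character vector of profile kinds, values in
#'   `"continuous"` / `"gistic"`.
#' @param planted data.frame with columns `gene_i`, `gene_j` (1-based
#'   gene indices), `model` (`"xor"`, `"and"` or `"marginal"`) and
#'   `penetrance` in `[0, 1]`; `NULL` for a null dataset whose outcome is
#'   independent of all genes.
#' @param missing_rate fraction of cells set missing (never on planted
#'   genes, which must survive the completeness filters).
#' @param hazard_high,hazard_low exponential death hazards (per month)
#'   of the short- and long-term groups.
#' @param censor_rate probability a patient's follow-up is cut by an
#'   independent uniform censoring time.
#' @param censor_max upper end (months) of the uniform censoring window.
#' @param cutoff survival cutoff C in months separating short from long.
#' @param short_frac short-term probability for null outcomes (default
#'   146/340, a typical cohort imbalance).
#' @param seed integer seed; every draw is reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 60, n_patients = 200,
                           profiles = c(expr = "continuous"),
                           planted = data.frame(gene_i = 1L, gene_j = 2L,
                                                model = "xor",
                                                penetrance = 0.9),
                           missing_rate = 0,
                           hazard_high = 1 / 12, hazard_low = 1 / 36,
                           censor_rate = 0.2, censor_max = 120,
                           cutoff = 36, short_frac = 146 / 340, seed = 1L) {
  if (n_genes < 2L || n_patients < 4L) stop("dataset too small")
  if (is.null(names(profiles)) || any(names(profiles) == ""))
    stop("'profiles' must be a named vector of kinds")
  stopifnot(all(profiles %in% c("continuous", "gistic")))
  if (!is.null(planted)) {
    stopifnot(all(c("gene_i", "gene_j", "model", "penetrance") %in%
                    names(planted)))
    if (any(planted$gene_i == planted$gene_j))
      stop("planted genes must be distinct")
    if (any(planted$penetrance < 0 | planted$penetrance > 1))
      stop("penetrance must lie in [0, 1]")
    if (max(planted$gene_i, planted$gene_j) > n_genes)
      stop("planted gene index beyond n_genes")
    stopifnot(all(planted$model %in% c("xor", "and", "marginal")))
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid missing rate")
  structure(list(n_genes = as.integer(n_genes),
                 n_patients = as.integer(n_patients), profiles = profiles,
                 planted = planted, missing_rate = missing_rate,
                 hazard_high = hazard_high, hazard_low = hazard_low,
                 censor_rate = censor_rate, censor_max = censor_max,
                 cutoff = cutoff, short_frac = short_frac,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.gene_ids <- function(n) sprintf("g%04d", seq_len(n))
.patient_ids <- function(n) sprintf("p%04d", seq_len(n))

# balanced quadrant bits for a planted pair: exactly n/4 (up to
# remainder) patients per (b1, b2) cell, randomly assigned, so each
# gene's marginal split carries no outcome information by symmetry
.planted_bits <- function(n) {
  cell <- sample(rep_len(0:3, n))
  cbind(b1 = cell %/% 2L, b2 = cell %% 2L)
}

# bimodal values whose median split recovers the planted bit
.bit_values <- function(bits) stats::rnorm(length(bits), ifelse(bits == 1L, 1, -1), 0.25)

#' Generate the genomic profiles of a synthetic dataset
#'
#' Continuous profiles draw each gene from its own location-scale normal
#' model; GISTIC profiles draw codes from `{-2..2}` with a peaked-at-0
#' distribution.  Planted genes (in the first profile) are given bimodal
#' values around their hidden binary state so a median split recovers it;
#' missing cells are injected at `missing_rate` everywhere except on
#' planted genes.
#'
#' @param spec a [synthetic_spec()].
#' @return A [profile_set()].
#' @export
generate_profiles <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  nG <- spec$n_genes; nP <- spec$n_patients
  genes <- .gene_ids(nG); patients <- .patient_ids(nP)
  planted_idx <- if (is.null(spec$planted)) integer() else
    unique(c(spec$planted$gene_i, spec$planted$gene_j))
  mats <- vector("list", length(spec$profiles))
  names(mats) <- names(spec$profiles)
  for (k in seq_along(spec$profiles)) {
    if (spec$profiles[[k]] == "gistic") {
      m <- matrix(sample(-2:2, nG * nP, replace = TRUE,
                         prob = c(.05, .2, .5, .2, .05)), nG, nP)
    } else {
      mu <- stats::rnorm(nG, 0, 2)
      sd <- stats::runif(nG, 0.5, 1.5)
      m <- matrix(stats::rnorm(nG * nP, rep(mu, nP), rep(sd, nP)), nG, nP)
      if (k == 1L && length(planted_idx)) {
        for (pr in seq_len(nrow(spec$planted))) {
          bits <- .planted_bits(nP)
          m[spec$planted$gene_i[pr], ] <- .bit_values(bits[, "b1"])
          m[spec$planted$gene_j[pr], ] <- .bit_values(bits[, "b2"])
        }
      }
    }
    dimnames(m) <- list(genes, patients)
    if (spec$missing_rate > 0) {
      mask <- matrix(stats::runif(nG * nP) < spec$missing_rate, nG, nP)
      mask[planted_idx, ] <- FALSE
      m[mask] <- NA
    }
    mats[[k]] <- m
  }
  profile_set(mats, unname(spec$profiles))
}

#' Plant a survival outcome tied to the hidden pair state
#'
#' The hidden risk label of each patient is derived from the planted
#' genes' median-split bits in the first profile: XOR parity, AND, or a
#' single-gene marginal effect, flipped with probability
#' `1 - penetrance`.  Short-term patients die at an
#' exponential(`hazard_high`) time truncated to `(0, C]`; long-term
#' patients survive to `C` plus an exponential(`hazard_low`) residual.
#' Independent uniform censoring then turns a fraction of records into
#' `living` at the censoring time.  With no planted pair the label is an
#' independent Bernoulli(`short_frac`) draw.
#'
#' @param spec a [synthetic_spec()].
#' @param profiles the [generate_profiles()] output for `spec`.
#' @return List with `clinical` (data.frame `patient_id`, `months`,
#'   `status`) and `truth` (the uncensored short/long risk factor).
#' @export
plant_outcome <- function(spec, profiles) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(profiles, "profile_set"))
  set.seed(spec$seed + 1L)
  nP <- spec$n_patients
  patients <- colnames(profiles[[1L]])
  if (is.null(spec$planted)) {
    risk <- stats::rbinom(nP, 1L, spec$short_frac)
  } else {
    p1 <- spec$planted[1L, ]
    v1 <- profiles[[1L]][p1$gene_i, ]
    v2 <- profiles[[1L]][p1$gene_j, ]
    b1 <- as.integer(v1 > stats::median(v1))
    b2 <- as.integer(v2 > stats::median(v2))
    risk <- switch(as.character(p1$model),
                   xor = bitwXor(b1, b2),
                   and = as.integer(b1 & b2),
                   marginal = b1)
    flip <- stats::rbinom(nP, 1L, 1 - p1$penetrance)
    risk <- bitwXor(risk, flip)
  }
  # death times consistent with the label relative to the cutoff
  t_death <- numeric(nP)
  ns <- sum(risk == 1L)
  t_death[risk == 1L] <- stats::qexp(
    stats::runif(ns) * stats::pexp(spec$cutoff, spec$hazard_high),
    spec$hazard_high)
  t_death[risk == 0L] <- spec$cutoff +
    stats::rexp(nP - ns, spec$hazard_low)
  censored <- stats::runif(nP) < spec$censor_rate
  t_cens <- stats::runif(nP, 0, spec$censor_max)
  is_cens <- censored & t_cens < t_death
  months <- ifelse(is_cens, t_cens, t_death)
  status <- ifelse(is_cens, "living", "deceased")
  list(clinical = data.frame(patient_id = patients, months = months,
                             status = status, stringsAsFactors = FALSE),
       truth = factor(ifelse(risk == 1L, "short", "long"),
                      levels = c("short", "long")))
}

#' Generate a complete synthetic dataset
#'
#' @param spec a [synthetic_spec()].
#' @return List with `profiles` (a `profile_set`), `clinical` and
#'   `truth` (see [plant_outcome()]).
#' @export
generate_dataset <- function(spec) {
  profiles <- generate_profiles(spec)
  out <- plant_outcome(spec, profiles)
  c(list(profiles = profiles), out)
}
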