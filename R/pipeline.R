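# End-to-end driver: preprocessing -> discretization -> permutation
# threshold -> pair selection -> networks + integration -> topology ->
# survival validation, with a deterministic report bundle on disk.

#' Pipeline configuration
#'
#' @param profiles named character vector of profile TSV paths, or a
#'   ready [profile_set()].
#' @param kinds profile kinds (`"continuous"`/`"gistic"`), recycled;
#'   ignored when `profiles` is already a `profile_set`.
#' @param clinical clinical TSV path or a clinical data.frame.
#' @param B histogram bin count (default 5).
#' @param cutoff survival cutoff C in months (default 36).
#' @param alphas significance multipliers (default 0, 0.1, 0.5, 0.8, 1).
#' @param n_permutations label permutations per profile (default 30).
#' @param seed master seed; per-profile permutation streams are derived
#'   from it.
#' @param out_dir report directory (created if needed); `NULL` to skip
#'   writing files.
#' @param strict use `>` instead of `>=` at the working threshold.
#' @param top_n number of top pairs per profile sent to survival
#'   validation.
#' @param max_genes optional cap: keep only the first `max_genes` genes
#'   (sorted order) after preprocessing, to bound the quadratic scan.
#' @return A `run_config` list.
#' @export
run_config <- function(profiles, kinds = "continuous", clinical,
                       B = 5, cutoff = 36,
                       alphas = c(0, 0.1, 0.5, 0.8, 1.0),
                       n_permutations = 30, seed = 1L, out_dir = NULL,
                       strict = FALSE, top_n = 10, max_genes = NULL) {
  if (B < 2) stop("'B' must be at least 2")
  if (cutoff <= 0) stop("'cutoff' must be positive")
  if (any(alphas < 0)) stop("'alphas' must be non-negative")
  structure(list(profiles = profiles, kinds = kinds, clinical = clinical,
                 B = B, cutoff = cutoff, alphas = sort(unique(alphas)),
                 n_permutations = n_permutations, seed = as.integer(seed),
                 out_dir = out_dir, strict = strict, top_n = top_n,
                 max_genes = max_genes),
            class = "run_config")
}

.load_profiles <- function(config) {
  if (inherits(config$profiles, "profile_set")) return(config$profiles)
  kinds <- rep_len(config$kinds, length(config$profiles))
  mats <- Map(read_profile_tsv, config$profiles, kinds)
  names(mats) <- names(config$profiles)
  profile_set(mats, kinds)
}

.load_clinical <- function(config) {
  if (is.character(config$clinical)) read_clinical_tsv(config$clinical)
  else config$clinical
}

#' Run the full outcome-guided network analysis
#'
#' Executes every stage on the configured inputs and, when `out_dir` is
#' set, writes a deterministic report bundle: per-profile ranked pair
#' lists, a threshold/pair-count table across the alpha grid, a network
#' topology table, SIF/GraphML network exports, and log-rank validation
#' of the top pairs (pair and singleton p-values).
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `labels`, `thetas`, `thresholds`
#'   (alpha-grid report), `pairs` (per-profile MI-ranked pairs at the
#'   base threshold), `networks` (per alpha: per-profile plus
#'   `I_all`/`I_any` integrations), `topology`, and `survival_top`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message("[oginet] ", msg)
  }
  say("run: B=%g C=%g permutations=%d seed=%d alphas=%s",
      config$B, config$cutoff, config$n_permutations, config$seed,
      paste(config$alphas, collapse = ","))

  ps <- .load_profiles(config)
  clinical <- .load_clinical(config)
  say("loaded %d profile(s), %d clinical record(s)", length(ps), nrow(clinical))

  ps <- filter_step1(ps)
  step2 <- filter_step2(ps, clinical, config$cutoff)
  ps <- step2$profiles
  y <- step2$labels
  say("after filtering: %d genes, %d patients (%d short / %d long)",
      nrow(ps[[1L]]), length(y$patient_ids), sum(y$labels == "short"),
      sum(y$labels == "long"))
  if (!is.null(config$max_genes) && nrow(ps[[1L]]) > config$max_genes) {
    keep <- rownames(ps[[1L]])[seq_len(config$max_genes)]
    ps <- profile_set(lapply(ps, function(m) m[keep, , drop = FALSE]),
                      attr(ps, "kinds"))
    say("gene cap applied: %d genes retained", config$max_genes)
  }

  kinds <- attr(ps, "kinds")
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(ps))

  thetas <- numeric(length(ps)); names(thetas) <- names(ps)
  scans <- vector("list", length(ps)); names(scans) <- names(ps)
  discs <- vector("list", length(ps)); names(discs) <- names(ps)
  for (k in seq_along(ps)) {
    nm <- names(ps)[k]
    discs[[k]] <- discretize_profile(ps[[k]], config$B, kinds[[k]])
    cfg <- permutation_config(config$n_permutations, sub_seeds[k])
    thetas[k] <- derive_threshold(average_permuted_mi(discs[[k]], y, cfg))$theta
    scans[[k]] <- mi_scan(discs[[k]], y)
    say("profile %s: theta = %.6f bits", nm, thetas[k])
  }

  total_pairs <- n_gene_pairs(nrow(ps[[1L]]))
  keep_fun <- function(mi, thr)
    if (config$strict) mi > thr else mi >= thr

  thr_rows <- list(); topo_rows <- list(); networks <- list(); pairs <- list()
  for (a in config$alphas) {
    nets_a <- list()
    for (k in seq_along(ps)) {
      nm <- names(ps)[k]
      thr <- scale_threshold(thetas[k], a)
      sel <- scans[[k]][keep_fun(scans[[k]]$mi, thr), , drop = FALSE]
      sel <- sel[order(-sel$mi, sel$gene_i, sel$gene_j), , drop = FALSE]
      rownames(sel) <- NULL
      if (a == 0) pairs[[nm]] <- sel
      thr_rows[[length(thr_rows) + 1L]] <- data.frame(
        profile = nm, alpha = a, threshold = round(thr, 4),
        n_pairs = nrow(sel), percentage = 100 * nrow(sel) / total_pairs)
      net <- build_network(sel, nm, a, thr)
      nets_a[[nm]] <- net
      topo_rows[[length(topo_rows) + 1L]] <-
        cbind(data.frame(alpha = a, network = nm), topology_summary(net))
    }
    if (length(nets_a) >= 2L) {
      nets_a$I_all <- intersect_networks(nets_a[names(ps)])
      nets_a$I_any <- union_networks(nets_a[names(ps)])
      for (nm in c("I_all", "I_any"))
        topo_rows[[length(topo_rows) + 1L]] <-
          cbind(data.frame(alpha = a, network = nm),
                topology_summary(nets_a[[nm]]))
    }
    networks[[sprintf("alpha_%g", a)]] <- nets_a
  }
  thresholds <- do.call(rbind, thr_rows)
  topology <- do.call(rbind, topo_rows)

  # survival validation of the top pairs per profile at the base threshold
  surv_rows <- list()
  for (nm in names(ps)) {
    sel <- utils::head(pairs[[nm]], config$top_n)
    d <- discs[[nm]]
    for (r in seq_len(nrow(sel))) {
      c1 <- d$codes[sel$gene_i[r], ]
      c2 <- d$codes[sel$gene_j[r], ]
      v <- validate_pair_survival(c1, c2, y, clinical)
      pv <- function(x) if (is.null(x)) NA_real_ else x$p_value
      surv_rows[[length(surv_rows) + 1L]] <- data.frame(
        profile = nm, gene_i = sel$gene_i[r], gene_j = sel$gene_j[r],
        mi = sel$mi[r], p_pair = pv(v$pair), p_gene_i = pv(v$gene1),
        p_gene_j = pv(v$gene2))
    }
  }
  survival_top <- if (length(surv_rows)) do.call(rbind, surv_rows) else NULL
  say("survival validation: %d pair(s) tested",
      if (is.null(survival_top)) 0L else nrow(survival_top))

  if (!is.null(out_dir)) {
    wt <- function(df, f) utils::write.table(
      df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(thresholds, "thresholds.tsv")
    wt(topology, "topology.tsv")
    for (nm in names(pairs)) wt(pairs[[nm]], sprintf("pairs_%s.tsv", nm))
    if (!is.null(survival_top)) wt(survival_top, "survival_top_pairs.tsv")
    for (an in names(networks)) for (nm in names(networks[[an]])) {
      net <- networks[[an]][[nm]]
      if (nrow(net$edges) == 0L) next
      base <- file.path(out_dir, sprintf("network_%s_%s", an, nm))
      write_network(net, paste0(base, ".sif"), "sif")
      write_network(net, paste0(base, ".graphml"), "graphml")
    }
    writeLines(log_lines, file.path(out_dir, "run.log"))
    say("report bundle written to %s", out_dir)
  }

  invisible(list(labels = y, thetas = thetas, thresholds = thresholds,
                 pairs = pairs, networks = networks, topology = topology,
                 survival_top = survival_top, discretized = discs))
}
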