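#' Per-scenario site log-likelihood matrix
#'
#' Fits branch lengths (and optionally the model) for every scenario
#' topology on a shared alignment and stacks the per-site log-likelihoods
#' into the S x L matrix the RELL bootstrap resamples.
#'
#' The substitution model is fitted once on the first scenario topology and
#' shared across scenarios (per-topology branch lengths, shared model), the
#' usual topology-testing setup.
#'
#' @param aln a [dna_alignment] containing every scenario tip.
#' @param scenarios a `scenario_set` from [enumerate_single_w] /
#'   [enumerate_multi_w], or a list of rooted topologies.
#' @param family substitution model family (see [subst_model]).
#' @param ncat discrete-gamma categories.
#' @param fit_shared_model estimate model parameters on the first topology
#'   (otherwise a default model of the family is used).
#' @return S x L numeric matrix, one row per scenario; attribute `loglik`
#'   holds the per-scenario total log-likelihoods.
#' @export
site_lnl_matrix <- function(aln, scenarios, family = "GTR", ncat = 4L,
                            fit_shared_model = TRUE) {
  trees <- if (inherits(scenarios, "scenario_set")) scenarios$trees
           else scenarios
  stopifnot(length(trees) >= 1L)
  model <- if (fit_shared_model)
    fit_model(aln, trees[[1L]], family = family, ncat = ncat)$model
  else subst_model(family, bf = empirical_bf(aln), ncat = ncat, alpha = 0.5)
  rows <- lapply(trees, function(tr) {
    fit <- optimize_branch_lengths(aln, tr, model)
    site_log_likelihoods(aln, fit$tree, model)
  })
  m <- do.call(rbind, rows)
  attr(m, "loglik") <- vapply(rows, function(r) attr(r, "total"), 0)
  m
}

#' Expected likelihood weights by RELL bootstrap
#'
#' Resamples site columns of a per-scenario site log-likelihood matrix
#' (resampling estimated log-likelihoods: no re-optimization per replicate).
#' Each replicate's scenario weights are the softmax of the resampled total
#' log-likelihoods; the expected likelihood weight of a scenario is the mean
#' of its replicate weights.
#'
#' @param m S x L matrix of per-site log-likelihoods (all finite, S >= 2).
#' @param n_boot bootstrap replicates (>= 1).
#' @param seed integer seed; results are deterministic given the seed.
#' @return object of class `elw_result`: `weights` (length S, sums to 1),
#'   `best` (argmax index), `range_95` (from [elw_range]), `n_boot`, `seed`.
#' @export
rell_elw <- function(m, n_boot = 1e5, seed = 1L) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 scenarios")
  if (n_boot < 1L) stop("n_boot must be >= 1")
  if (any(!is.finite(m))) stop("non-finite site log-likelihood row")
  L <- ncol(m)
  set.seed(seed)
  acc <- numeric(nrow(m))
  for (b in seq_len(n_boot)) {
    cnt <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
    tot <- as.numeric(m %*% cnt)
    w <- exp(tot - max(tot))
    acc <- acc + w / sum(w)
  }
  w <- acc / n_boot
  res <- structure(list(weights = w, best = which.max(w), n_boot = n_boot,
                        seed = seed),
                   class = "elw_result")
  res$range_95 <- elw_range(res, 0.95)
  res
}

#' @export
print.elw_result <- function(x, ...) {
  cat("ELW over", length(x$weights), "scenarios: best =", x$best,
      sprintf("(w = %.3f),", x$weights[x$best]),
      "95% range =", paste(x$range_95, collapse = "-"), "\n")
  invisible(x)
}

#' Accumulated-ELW index range
#'
#' Scenarios are added greedily in decreasing weight order (ties broken
#' toward the lower index) until the requested mass is accumulated; the
#' reported range is the contiguous index hull of the selected set.
#'
#' @param r an `elw_result` (or a bare weight vector).
#' @param mass accumulated-weight target in (0, 1].
#' @return integer `c(lo, hi)`.
#' @export
elw_range <- function(r, mass = 0.95) {
  w <- if (inherits(r, "elw_result")) r$weights else r
  if (mass <= 0 || mass > 1) stop("mass must be in (0, 1]")
  ord <- order(-w, seq_along(w))       # descending weight, ties: lower index
  cum <- cumsum(w[ord])
  sel <- ord[seq_len(which(cum >= mass - 1e-12)[1L])]
  c(lo = min(sel), hi = max(sel))
}

#' End-to-end ELW estimation of the cessation index for one gene
#'
#' Per-scenario branch-length optimization followed by the RELL bootstrap.
#'
#' @inheritParams site_lnl_matrix
#' @inheritParams rell_elw
#' @return an `elw_result`; `weights` has one entry per scenario.
#' @export
elw_pipeline <- function(aln, scenarios, family = "GTR", ncat = 4L,
                         n_boot = 1e5, seed = 1L) {
  m <- site_lnl_matrix(aln, scenarios, family = family, ncat = ncat)
  rell_elw(m, n_boot = n_boot, seed = seed)
}

# long-format ELW table over genes (gene x scenario x weight), the shape
# used for the heatmap figures
elw_long_table <- function(results) {
  do.call(rbind, lapply(names(results), function(g) {
    w <- results[[g]]$weights
    data.frame(gene_id = g, scenario = seq_along(w), weight = w)
  }))
}

#' Minimal ELW heatmap (genes x scenarios)
#'
#' Base-graphics helper for a quick look at per-gene weight distributions;
#' the TSV outputs are the canonical result surface.
#'
#' @param results named list of `elw_result` objects.
#' @param ... passed to [graphics::image].
#' @export
plot_elw_heatmap <- function(results, ...) {
  w <- t(vapply(results, function(r) r$weights,
                numeric(length(results[[1]]$weights))))
  graphics::image(x = seq_len(ncol(w)), y = seq_len(nrow(w)), z = t(w),
                  xlab = "scenario index (recent to ancient)", ylab = "gene",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(w)
}
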