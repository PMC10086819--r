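#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Coordinate-wise optimization: each branch in turn is optimized by
#' golden-section search on the log-length scale with the rest of the tree
#' held fixed, sweeping until the relative log-likelihood improvement falls
#' below `tol`. The returned log-likelihood is never below that of the
#' input lengths. Optionally the model's free parameters are re-fitted
#' between sweeps.
#'
#' @param aln a [dna_alignment].
#' @param topology rooted [ape::phylo]; existing branch lengths are used as
#'   the starting point, otherwise 0.1 throughout.
#' @param model a [subst_model].
#' @param optimize_model also optimize the model's rate parameters, gamma
#'   shape and invariant proportion (see [fit_model]).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_sweeps cap on branch sweeps.
#' @return list with `tree` (branch lengths replaced by their ML values),
#'   `loglik`, `model`, and `converged`.
#' @export
optimize_branch_lengths <- function(aln, topology, model,
                                    optimize_model = FALSE,
                                    tol = 1e-8, max_sweeps = 30L) {
  if (ape::Ntip(topology) < 2L) stop("need at least 2 taxa")
  if (is.null(topology$edge.length))
    topology$edge.length <- rep(0.1, nrow(topology$edge))
  if (optimize_model) {
    fit <- fit_model(aln, topology, family = model$family, ncat = model$ncat,
                     init = model)
    return(fit)
  }
  ctx <- likelihood_context(aln, topology, model)
  res <- optim_edges_cpp(ctx$edge, ctx$ntip, ctx$nnode, ctx$root, ctx$elen,
                         ctx$tip, ctx$npat, ctx$U, ctx$Uinv, ctx$lambda,
                         model$bf, model$rates, model$pinv, ctx$invprod,
                         ctx$weights, as.integer(max_sweeps), tol)
  tr <- ctx$tree
  tr$edge.length <- as.numeric(res$elen)
  list(tree = tr, loglik = res$loglik, model = model,
       converged = isTRUE(res$converged))
}

#' Fit a substitution model (and branch lengths) on a fixed topology
#'
#' Base frequencies are set empirically from the alignment; exchangeability
#' parameters, the gamma shape and the invariant proportion are optimized
#' jointly with the branch lengths by alternating one-dimensional searches
#' with branch sweeps.
#'
#' @inheritParams optimize_branch_lengths
#' @param family model family (see [subst_model]).
#' @param ncat gamma categories (1 = no rate variation).
#' @param use_pinv also estimate a proportion of invariant sites.
#' @param init optional [subst_model] providing starting parameter values.
#' @param rounds outer alternation rounds.
#' @return as [optimize_branch_lengths]; `model` carries fitted parameters.
#' @export
fit_model <- function(aln, topology, family = "GTR", ncat = 4L,
                      use_pinv = FALSE, init = NULL, rounds = 4L,
                      tol = 1e-7) {
  if (nrow(unique(unclass(aln)[topology$tip.label, , drop = FALSE])) == 1L) {
    warning("degenerate alignment (single distinct sequence); returning default parameters")
    m <- subst_model(family, bf = rep(.25, 4), ncat = ncat)
    fit <- optimize_branch_lengths(aln, topology, m, tol = tol)
    return(fit)
  }
  bf <- if (family %in% c("JC69", "K80")) rep(.25, 4) else empirical_bf(aln)
  use_pinv <- use_pinv || (!is.null(init) && init$pinv > 0)
  th <- model_theta(family, init, ncat, use_pinv)
  mk <- function(th) theta_model(family, th, bf, ncat, use_pinv)
  if (is.null(topology$edge.length))
    topology$edge.length <- rep(0.1, nrow(topology$edge))
  cur <- optimize_branch_lengths(aln, topology, mk(th), tol = tol)
  for (r in seq_len(rounds)) {
    prev <- cur$loglik
    ctx <- likelihood_context(aln, cur$tree, mk(th))
    for (i in seq_along(th)) {
      f <- function(v) { t2 <- th; t2[i] <- v; ctx_loglik(ctx, mk(t2)) }
      lim <- theta_bounds(names(th)[i])
      o <- stats::optimize(f, lower = lim[1], upper = lim[2], maximum = TRUE,
                           tol = 1e-4)
      if (o$objective > f(th[i])) th[i] <- o$maximum
    }
    cur <- optimize_branch_lengths(aln, cur$tree, mk(th), tol = tol)
    if (cur$loglik - prev < tol * (abs(prev) + 1)) break
  }
  cur$model <- mk(th)
  cur
}

# free parameters on transformed (log / raw) scales, with start values
model_theta <- function(family, init, ncat, use_pinv) {
  g <- function(nm, d) if (!is.null(init) && !is.null(init$params[[nm]]))
    init$params[[nm]] else d
  th <- switch(family,
    JC69  = c(),
    K80   = c(lkappa = log(g("kappa", 2))),
    HKY85 = c(lkappa = log(g("kappa", 2))),
    TN93  = c(lkappa1 = log(g("kappa1", 2)), lkappa2 = log(g("kappa2", 2))),
    GTR   = stats::setNames(log(if (!is.null(init) && !is.null(init$params$rates))
      init$params$rates[1:5] else rep(1, 5)),
      paste0("lr", 1:5)))
  if (ncat > 1)
    th <- c(th, lalpha = log(if (!is.null(init)) init$alpha else 1))
  if (use_pinv)
    th <- c(th, pinv = if (!is.null(init)) max(init$pinv, 1e-4) else 0.1)
  th
}

theta_bounds <- function(nm) {
  if (nm == "pinv") c(0, 0.95) else c(log(1e-3), log(1e3))
}

theta_model <- function(family, th, bf, ncat, use_pinv) {
  pinv <- if (use_pinv) unname(th["pinv"]) else 0
  alpha <- if (ncat > 1) exp(unname(th["lalpha"])) else 1
  switch(family,
    JC69  = subst_model("JC69", alpha = alpha, ncat = ncat, pinv = pinv),
    K80   = subst_model("K80", kappa = exp(unname(th["lkappa"])),
                        alpha = alpha, ncat = ncat, pinv = pinv),
    HKY85 = subst_model("HKY85", bf = bf, kappa = exp(unname(th["lkappa"])),
                        alpha = alpha, ncat = ncat, pinv = pinv),
    TN93  = subst_model("TN93", bf = bf, kappa1 = exp(unname(th["lkappa1"])),
                        kappa2 = exp(unname(th["lkappa2"])),
                        alpha = alpha, ncat = ncat, pinv = pinv),
    GTR   = subst_model("GTR", bf = bf,
                        rates = c(exp(unname(th[paste0("lr", 1:5)])), 1),
                        alpha = alpha, ncat = ncat, pinv = pinv))
}
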