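#' Per-site log-likelihoods on a fixed tree
#'
#' Felsenstein pruning under a reversible model with a discrete-gamma +
#' invariant-sites rate mixture. Gaps and ambiguity codes are treated as
#' missing data (partial likelihood 1 for every compatible state).
#'
#' @param aln a [dna_alignment] containing (at least) all tree tips.
#' @param tree rooted [ape::phylo] with non-negative branch lengths in
#'   expected substitutions/site.
#' @param model a [subst_model].
#' @return numeric vector of per-site log-likelihoods (length = alignment
#'   columns), with attribute `total` = their sum.
#' @export
site_log_likelihoods <- function(aln, tree, model) {
  ctx <- likelihood_context(aln, tree, model)
  ll <- prune_loglik_cpp(ctx$edge, ctx$ntip, ctx$nnode, ctx$root, ctx$elen,
                         ctx$tip, ctx$npat, ctx$U, ctx$Uinv, ctx$lambda,
                         model$bf, model$rates, model$pinv, ctx$invprod)
  if (any(!is.finite(ll))) {
    bad <- ctx$index[match(which(!is.finite(ll))[1], ctx$index)]
    stop("non-finite site log-likelihood at site ", bad)
  }
  out <- ll[ctx$index]
  attr(out, "total") <- sum(ctx$weights * ll)
  out
}

#' Total log-likelihood (convenience wrapper)
#' @inheritParams site_log_likelihoods
#' @export
tree_log_likelihood <- function(aln, tree, model) {
  attr(site_log_likelihoods(aln, tree, model), "total")
}

# everything the C++ kernels need, precomputed once per (aln, topology)
likelihood_context <- function(aln, tree, model) {
  stopifnot(inherits(aln, "dna_alignment"), inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tree <- ape::reorder.phylo(tree, "postorder")
  taxa <- tree$tip.label
  cp <- compress_alignment(aln, taxa)
  ntip <- ape::Ntip(tree)
  list(edge = tree$edge, ntip = ntip, nnode = ntip + tree$Nnode,
       root = ntip + 1L, elen = tree$edge.length,
       tip = cp$tip, npat = cp$npat, weights = as.numeric(cp$weights),
       index = cp$index,
       U = model$eig$U, Uinv = model$eig$Uinv, lambda = model$eig$lambda,
       invprod = invariant_weight(cp$tip, model$bf),
       tree = tree)
}

# total lnL from a prebuilt context at given edge lengths / model
ctx_loglik <- function(ctx, model, elen = ctx$elen) {
  ll <- prune_loglik_cpp(ctx$edge, ctx$ntip, ctx$nnode, ctx$root, elen,
                         ctx$tip, ctx$npat, model$eig$U, model$eig$Uinv,
                         model$eig$lambda, model$bf, model$rates, model$pinv,
                         invariant_weight_cached(ctx, model))
  sum(ctx$weights * ll)
}

# invprod depends only on tip partials and bf; recompute when bf changes
invariant_weight_cached <- function(ctx, model) {
  invariant_weight(ctx$tip, model$bf)
}
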