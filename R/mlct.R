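#' Neighbor-joining tree from a distance matrix
#'
#' Validation wrapper around [ape::nj]: requires a square symmetric
#' non-negative matrix with zero diagonal and at least 3 taxa. Recovers the
#' generating tree exactly on additive distances.
#'
#' @param d distance matrix (with dimnames) or `dist` object.
#' @return unrooted [ape::phylo].
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("need a square matrix")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("diagonal must be zero")
  ape::nj(d)
}

# dna_alignment -> phangorn phyDat
as_phydat <- function(aln) {
  phangorn::phyDat(unclass(aln), type = "DNA")
}

pml_model_name <- function(family) {
  switch(family, JC69 = "JC", K80 = "K80", HKY85 = "HKY", TN93 = "TrN",
         GTR = "GTR", stop("unknown family"))
}

#' Maximum-likelihood gene-tree search (NJ start + NNI hill climbing)
#'
#' A lightweight ML tree search: a neighbor-joining starting tree (ML
#' distances) improved by nearest-neighbor-interchange hill climbing with
#' simultaneous branch-length and model-parameter optimization. The search
#' never returns a tree with lower likelihood than the optimized starting
#' tree.
#'
#' @param aln a [dna_alignment].
#' @param family model family (see [subst_model]).
#' @param ncat discrete-gamma categories.
#' @param start optional starting [ape::phylo]; defaults to NJ.
#' @return list with `tree` (unrooted, ML branch lengths), `loglik`, `model`
#'   (fitted [subst_model] parameters as a list).
#' @export
ml_search <- function(aln, family = "GTR", ncat = 4L, start = NULL) {
  dat <- as_phydat(aln)
  if (is.null(start)) {
    dm <- phangorn::dist.ml(dat)
    start <- ape::nj(dm)
  }
  start <- ape::unroot(start)
  if (is.null(start$edge.length))
    start$edge.length <- rep(0.1, nrow(start$edge))
  start$edge.length[start$edge.length < 1e-8] <- 1e-8
  fit0 <- phangorn::pml(start, dat, k = ncat)
  fit <- phangorn::optim.pml(fit0, model = pml_model_name(family),
                             optNni = ape::Ntip(start) >= 4L,
                             optGamma = ncat > 1L, optEdge = TRUE,
                             control = phangorn::pml.control(trace = 0))
  list(tree = fit$tree, loglik = fit$logLik, fit = fit)
}

#' Bootstrap branch supports for a gene tree
#'
#' Resamples alignment columns with replacement `B` times, re-runs the tree
#' search on each replicate, and scores each internal branch of the full-data
#' tree by the fraction of replicate trees containing its bipartition.
#' Deterministic given `seed`.
#'
#' @inheritParams ml_search
#' @param B bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param tree optional full-data tree to annotate (defaults to a fresh
#'   [ml_search] fit).
#' @return rooted-at-nothing (unrooted) [ape::phylo] whose `node.label`
#'   carries supports in `[0, 1]` (`NA` for the root entry).
#' @export
bootstrap_supports <- function(aln, family = "GTR", ncat = 4L, B = 100L,
                               seed = 1L, tree = NULL) {
  if (B < 1L) stop("B must be >= 1")
  if (is.null(tree)) tree <- ml_search(aln, family, ncat)$tree
  set.seed(seed)
  L <- ncol(aln)
  boots <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- sample.int(L, L, replace = TRUE)
    alnb <- dna_alignment(unclass(aln)[, idx, drop = FALSE])
    boots[[b]] <- ml_search(alnb, family, ncat)$tree
  }
  class(boots) <- "multiPhylo"
  cnt <- ape::prop.clades(tree, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  tree$node.label <- cnt / B
  tree$node.label[1] <- NA  # root pseudo-node of an unrooted tree
  tree
}

#' Collapse weakly supported branches
#'
#' Contracts every internal branch whose support is below `threshold`
#' (strictly: support `< threshold` collapses, `= threshold` is kept),
#' producing a multifurcating cladogram. Supports on a `[0, 100]` scale are
#' auto-detected and divided by 100. Tips are never removed.
#'
#' @param tree [ape::phylo] with numeric `node.label` supports.
#' @param threshold collapse threshold on the `[0, 1]` scale.
#' @return multifurcating [ape::phylo] (cladogram; branch lengths dropped).
#' @export
collapse_low_support <- function(tree, threshold = 0.70) {
  sup <- suppressWarnings(as.numeric(tree$node.label))
  if (is.null(tree$node.label) || all(is.na(sup)))
    stop("tree carries no numeric support labels")
  if (max(sup, na.rm = TRUE) > 1) sup <- sup / 100
  n <- ape::Ntip(tree)
  tmp <- tree
  # internal edge = edge whose child is an internal node; weak ones get
  # length 0 and are contracted
  child <- tmp$edge[, 2]
  idx <- pmax(child - n, 1L)
  weak <- child > n & !is.na(sup[idx]) & sup[idx] < threshold
  tmp$edge.length <- ifelse(weak, 0, 1)
  out <- ape::di2multi(tmp, tol = 1e-9)
  out$edge.length <- NULL
  out$node.label <- NULL
  out
}

# non-trivial splits of a tree, each encoded as the sorted tip subset not
# containing the reference taxon, restricted to `taxa`
tree_splits <- function(tree, taxa) {
  tr <- ape::keep.tip(tree, intersect(tree$tip.label, taxa))
  ref <- sort(taxa)[1]
  tr <- ape::root(tr, outgroup = ref, resolve.root = TRUE)
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  out <- unique(vapply(pp, function(idx) {
    s <- sort(labs[idx])
    if (ref %in% s) s <- sort(setdiff(labs, s))
    paste(s, collapse = "|")
  }, ""))
  # drop trivial splits (single tip or all-but-reference)
  sizes <- lengths(strsplit(out, "\\|"))
  out[sizes >= 2 & sizes <= length(labs) - 2]
}

#' Scenario position range compatible with a collapsed gene tree
#'
#' A scenario is compatible when the collapsed gene tree can be refined into
#' the scenario topology: every bipartition of the gene tree (restricted to
#' shared taxa) must be a bipartition of the scenario tree. The reported
#' range is the span of compatible scenario indices, the automated
#' equivalent of reading the W-attachment position range off the reference
#' topology.
#'
#' @param g collapsed gene tree ([ape::phylo]), tips a subset of the
#'   scenario trees' tips.
#' @param scenarios a `scenario_set` (see [enumerate_single_w]).
#' @return object of class `position_range`: integer `c(lo, hi)`.
#' @export
w_position_range <- function(g, scenarios) {
  trees <- if (inherits(scenarios, "scenario_set")) scenarios$trees
           else scenarios
  taxa <- g$tip.label
  if (!all(taxa %in% trees[[1]]$tip.label))
    stop("gene-tree tips absent from scenario trees")
  gs <- tree_splits(g, taxa)
  comp <- logical(length(trees))
  first_conflict <- NULL
  for (k in seq_along(trees)) {
    ss <- tree_splits(trees[[k]], taxa)
    bad <- setdiff(gs, ss)
    comp[k] <- length(bad) == 0L
    if (!comp[k] && is.null(first_conflict)) first_conflict <- bad[1]
  }
  if (!any(comp))
    stop("no compatible scenario; conflicting bipartition: ", first_conflict)
  structure(c(lo = min(which(comp)), hi = max(which(comp))),
            class = "position_range")
}
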