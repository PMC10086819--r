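#' Dated reference species tree with a focal, W-bearing species
#'
#' Builds the coordinate system in which all recombination-cessation times
#' (t_RC) are expressed: a rooted, binary, time-calibrated species tree, a
#' focal species whose W gametolog is to be placed, and the set of species
#' for which W gametologs are available.
#'
#' Node ages (time before present; tips at 0) are taken from the tree's
#' branch lengths, which must therefore be ultrametric in time. Alternatively
#' a tree without branch lengths may be combined with an `ages` vector giving
#' one age per internal node in the order of the phylo node numbering
#' (`ntip+1 ... ntip+nnode`).
#'
#' @param tree an [ape::phylo] object or a Newick string.
#' @param focal tip label of the focal species (the one whose Z-W divergence
#'   is dated).
#' @param w_set tip labels of all W-bearing species; must contain `focal`.
#'   Defaults to just the focal species.
#' @param ages optional numeric vector of internal node ages (time before
#'   present) used when `tree` carries no branch lengths.
#' @return an object of class `species_tree`: a list with elements `phylo`
#'   (ultrametric, branch lengths in time), `focal`, `w_set`, `ages`
#'   (per-node ages, tips first), and `root_age`.
#' @examples
#' st <- species_tree("((A:1,B:1):1,C:2);", focal = "A")
#' focal_path(st)
#' @export
species_tree <- function(tree, focal, w_set = focal, ages = NULL) {
  if (is.character(tree)) tree <- parse_newick(tree)
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!ape::is.binary(tree) && ape::Ntip(tree) > 1L)
    stop("species tree must be fully binary")
  if (!focal %in% tree$tip.label)
    stop("focal species '", focal, "' is not a tip of the tree")
  if (!all(w_set %in% tree$tip.label))
    stop("w_set contains labels absent from the tree")
  if (!focal %in% w_set) stop("w_set must contain the focal species")

  if (is.null(tree$edge.length)) {
    if (is.null(ages))
      stop("tree has no branch lengths; supply internal node `ages`")
    if (length(ages) != tree$Nnode)
      stop("`ages` must have one entry per internal node (", tree$Nnode, ")")
    tree$edge.length <- ages[tree$edge[, 1] - ape::Ntip(tree)] -
      ifelse(tree$edge[, 2] <= ape::Ntip(tree), 0,
             ages[pmax(tree$edge[, 2] - ape::Ntip(tree), 1)])
    if (any(tree$edge.length < 0))
      stop("`ages` must decrease from root to tips")
  }
  age <- node_ages(tree)
  # ages must not decrease from tip to root on any path
  bad <- age[tree$edge[, 1]] < age[tree$edge[, 2]] - 1e-9
  if (any(bad)) stop("node ages decrease toward the root; tree is not time-ultrametric")
  ties <- abs(age[tree$edge[, 1]] - age[tree$edge[, 2]]) < 1e-12 &
    tree$edge[, 2] > ape::Ntip(tree)
  if (any(ties))
    warning("age ties between parent and child nodes: some conversion intervals will have zero width")
  structure(list(phylo = tree, focal = focal, w_set = w_set,
                 ages = age, root_age = max(age)),
            class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Dated species tree:", ape::Ntip(x$phylo), "tips, root age",
      format(x$root_age), "\n")
  cat("  focal species:", x$focal, "\n")
  cat("  W-bearing set:", paste(x$w_set, collapse = ", "), "\n")
  invisible(x)
}

#' Parse a Newick string or file
#'
#' Thin wrapper around [ape::read.tree] that validates tip-label uniqueness
#' and reports the character position of a syntax error. Numeric node labels
#' are interpreted downstream as bootstrap supports (auto-scaled from
#' \[0,100\] to \[0,1\] where needed).
#'
#' @param text a Newick string (possibly several, newline-separated).
#' @param file alternatively, path to a Newick file.
#' @return an [ape::phylo] object, or `multiPhylo` when several trees are read.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file)) stop("supply `text` or `file`")
  if (is.null(text)) text <- readLines(file, warn = FALSE)
  text <- trimws(text)
  text <- text[nzchar(text)]
  # basic syntax scan so failures name a position (ape's messages do not)
  for (s in text) {
    depth <- 0L
    for (i in seq_len(nchar(s))) {
      ch <- substr(s, i, i)
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") depth <- depth - 1L
      if (depth < 0L) stop("malformed Newick: unbalanced ')' at position ", i)
    }
    if (depth != 0L) stop("malformed Newick: ", depth, " unclosed '(' in '",
                          substr(s, 1, 30), "...'")
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick: no tree could be read")
  chk <- if (inherits(tr, "multiPhylo")) tr else list(tr)
  for (t1 in chk)
    if (anyDuplicated(t1$tip.label))
      stop("duplicate tip label: ",
           paste(unique(t1$tip.label[duplicated(t1$tip.label)]), collapse = ", "))
  tr
}

#' Write trees to Newick
#'
#' @param tree phylo or multiPhylo.
#' @param file output path, or `NULL` to return the string(s).
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

# tip labels descending from a node (iterative; avoids heavier dependencies)
descendant_tips <- function(phy, node) {
  n <- ape::Ntip(phy)
  if (node <= n) return(phy$tip.label[node])
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  acc <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[1L]
    stack <- stack[-1L]
    for (ch in kids[[as.character(v)]]) {
      if (ch <= n) acc <- c(acc, phy$tip.label[ch]) else stack <- c(stack, ch)
    }
  }
  acc
}

# node ages from root-to-node path lengths; tips forced to exactly 0
node_ages <- function(phy) {
  n <- ape::Ntip(phy)
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  d <- ape::node.depth.edgelength(phy)
  age <- max(d[seq_len(n)]) - d
  if (any(abs(age[seq_len(n)]) > 1e-6 * max(age)))
    stop("tree is not ultrametric: tips do not share a common age")
  age[seq_len(n)] <- 0
  age
}

# --- internal recursive representation -------------------------------------
# each node: list(id, label (tips only), age, children (list))
as_nodelist <- function(phy, age = NULL) {
  n <- ape::Ntip(phy)
  if (is.null(age)) age <- rep(NA_real_, n + phy$Nnode)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  build <- function(id) {
    if (id <= n)
      return(list(id = id, label = phy$tip.label[id], age = 0, children = NULL))
    ch <- lapply(kids[[as.character(id)]], build)
    list(id = id, label = NULL, age = age[id], children = ch)
  }
  build(n + 1L)
}

# newick for a nodelist, optionally wrapping designated nodes with a W graft.
# graft: named list id -> newick string to place as sister at that node.
nl_newick <- function(nl, graft = list()) {
  rec <- function(node) {
    s <- if (is.null(node$children)) node$label
         else paste0("(", paste(vapply(node$children, rec, ""), collapse = ","), ")")
    g <- graft[[as.character(node$id)]]
    if (!is.null(g)) s <- paste0("(", s, ",", g, ")")
    s
  }
  paste0(rec(nl), ";")
}

# newick of the subtree topology restricted to tips in `keep`,
# with labels passed through `rename`
nl_restrict_newick <- function(nl, keep, rename = identity) {
  rec <- function(node) {
    if (is.null(node$children)) {
      if (node$label %in% keep) return(rename(node$label))
      return(NULL)
    }
    parts <- Filter(Negate(is.null), lapply(node$children, rec))
    if (length(parts) == 0L) return(NULL)
    if (length(parts) == 1L) return(parts[[1L]])
    paste0("(", paste(unlist(parts), collapse = ","), ")")
  }
  rec(nl)
}

#' Internal nodes on the path from the focal tip to the root
#'
#' These nodes are the attachment positions available to the focal W lineage
#' and therefore define the discrete t_RC scale: node `k` of the path is the
#' upper boundary of scenario `k`.
#'
#' @param st a [species_tree].
#' @return object of class `focal_path`: list with `nodes` (phylo node ids,
#'   tip-to-root order), `ages` (strictly non-decreasing), and `P` (path length).
#' @export
focal_path <- function(st) {
  stopifnot(inherits(st, "species_tree"))
  phy <- st$phylo
  n <- ape::Ntip(phy)
  tip <- match(st$focal, phy$tip.label)
  parent <- integer(n + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  nodes <- integer(0)
  cur <- tip
  while (parent[cur] != 0L) {
    cur <- parent[cur]
    nodes <- c(nodes, cur)
  }
  structure(list(nodes = nodes, ages = st$ages[nodes], P = length(nodes)),
            class = "focal_path")
}

#' @export
print.focal_path <- function(x, ...) {
  cat("Focal path:", x$P, "internal nodes, ages",
      paste(format(x$ages, digits = 4), collapse = " < "), "\n")
  invisible(x)
}

new_scenario_set <- function(trees, st, type) {
  structure(list(trees = trees, S = length(trees), type = type,
                 focal = st$focal, w_set = st$w_set,
                 tree_labels = st$phylo$tip.label),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat("Scenario set (", x$type, "-W): ", x$S,
      " topologies, indexed 1 (recent) .. ", x$S, " (ancient)\n", sep = "")
  invisible(x)
}

#' Enumerate single-W recombination-cessation scenario topologies
#'
#' Constructs one hypothetical gametolog topology per attachment interval on
#' the focal path. Scenario 1 places the focal W gametolog sister to the
#' focal Z tip (cessation after all speciations on the path); scenario `k`
#' attaches W on the branch between path nodes `k-1` and `k`, i.e. sister to
#' the clade subtended by node `k-1`. Scenarios are indexed from recent (1)
#' to ancient (`S`) cessation. Attachments above the root (cessation
#' predating the root split, e.g. the bird-reptile split) are excluded by
#' default, so `S` equals the focal-path length.
#'
#' @param st a [species_tree] with `w_set == focal`.
#' @param exclude_above_root if `FALSE`, append one extra scenario with W
#'   sister to the entire ingroup (attachment above the root).
#' @param w_suffix suffix appended to the focal species label to name its W
#'   gametolog tip.
#' @return a `scenario_set`: list of rooted [ape::phylo] topologies plus
#'   bookkeeping (`S`, `type = "single"`, labels).
#' @examples
#' st <- species_tree("((A:1,B:1):1,C:2);", focal = "A")
#' ss <- enumerate_single_w(st)
#' sapply(ss$trees, function(t) ape::write.tree(t))
#' @export
enumerate_single_w <- function(st, exclude_above_root = TRUE, w_suffix = "_W") {
  stopifnot(inherits(st, "species_tree"))
  phy <- st$phylo
  if (ape::Ntip(phy) < 2L) stop("no scenarios definable on a single-tip tree")
  fp <- focal_path(st)
  nl <- as_nodelist(phy)
  wlab <- paste0(st$focal, w_suffix)
  tipid <- match(st$focal, phy$tip.label)
  targets <- c(tipid, fp$nodes[-fp$P])        # scenario k wraps this node
  if (!exclude_above_root) targets <- c(targets, fp$nodes[fp$P])
  trees <- lapply(targets, function(tg) {
    g <- stats::setNames(list(wlab), as.character(tg))
    parse_newick(nl_newick(nl, graft = g))
  })
  new_scenario_set(trees, st, "single")
}

#' Enumerate multi-W recombination-cessation scenario topologies
#'
#' Same index scale as [enumerate_single_w], but every W-bearing species
#' contributes a W tip. For scenario `k`, the W gametologs of species whose
#' lineages diverged from the focal path more recently than attachment point
#' `k` form a clade mirroring the species topology, attached at position `k`;
#' each W-bearing species that diverged earlier keeps its W tip sister to its
#' own Z tip (recombination continued independently in that lineage).
#' Scenario 1 places every W sister to its own Z.
#'
#' @inheritParams enumerate_single_w
#' @param st a [species_tree] with at least two W-bearing species, all inside
#'   one clade not spanning the root.
#' @return a `scenario_set` with `type = "multi"`; `S` equals the single-W
#'   scenario count.
#' @export
enumerate_multi_w <- function(st, exclude_above_root = TRUE, w_suffix = "_W") {
  stopifnot(inherits(st, "species_tree"))
  phy <- st$phylo
  if (length(st$w_set) < 2L)
    stop("multi-W enumeration needs at least two W-bearing species")
  fp <- focal_path(st)
  nl <- as_nodelist(phy)
  # w_set must sit inside one clade that does not span the root
  mrca <- if (length(st$w_set) > 1L) ape::getMRCA(phy, st$w_set) else 0L
  if (identical(mrca, ape::Ntip(phy) + 1L))
    stop("w_set spans the root; unsupported")
  wname <- function(z) paste0(z, w_suffix)
  clade_tips <- function(id) descendant_tips(phy, id)
  tipid <- match(st$focal, phy$tip.label)
  targets <- c(tipid, fp$nodes[-fp$P])
  if (!exclude_above_root) targets <- c(targets, fp$nodes[fp$P])
  trees <- lapply(targets, function(tg) {
    inside <- intersect(st$w_set, clade_tips(tg))
    outside <- setdiff(st$w_set, inside)
    graft <- list()
    graft[[as.character(tg)]] <- nl_restrict_newick(nl, inside, rename = wname)
    for (sp in outside)
      graft[[as.character(match(sp, phy$tip.label))]] <- wname(sp)
    parse_newick(nl_newick(nl, graft = graft))
  })
  new_scenario_set(trees, st, "multi")
}

#' Convert a scenario index to a normalized time interval
#'
#' Scenario `k` corresponds to cessation times in the half-open interval
#' `(h[k-1], h[k]] / h_root` where `h` are the focal-path node ages and
#' `h[0] = 0`. The intervals partition (0, 1]; over all scenarios the
#' boundary set has exactly `S + 1` distinct values (tip, root, and the
#' `S - 1` internal path ages).
#'
#' @param k scenario index, 1-based.
#' @param st a [species_tree] with node ages.
#' @return numeric `c(lo, hi)` on the normalized 0-1 time scale.
#' @export
scenario_to_time_interval <- function(k, st) {
  stopifnot(inherits(st, "species_tree"))
  fp <- focal_path(st)
  if (any(k < 1L) || any(k > fp$P)) stop("scenario index out of range 1..", fp$P)
  h <- c(0, fp$ages) / st$root_age
  if (length(k) == 1L) c(lo = h[k], hi = h[k + 1L])
  else cbind(lo = h[k], hi = h[k + 1L])
}

#' All scenario intervals and their boundary values
#'
#' @param st a [species_tree].
#' @return data frame with columns `scenario`, `t_lo`, `t_hi` (normalized);
#'   attribute `boundaries` holds the sorted distinct endpoint values.
#' @export
scenario_intervals <- function(st) {
  fp <- focal_path(st)
  iv <- t(vapply(seq_len(fp$P), function(k) scenario_to_time_interval(k, st),
                 numeric(2)))
  out <- data.frame(scenario = seq_len(fp$P), t_lo = iv[, 1], t_hi = iv[, 2])
  attr(out, "boundaries") <- sort(unique(c(out$t_lo, out$t_hi)))
  out
}

#' Scenario index containing a given cessation time
#'
#' Inverse of [scenario_to_time_interval] for a time on the absolute scale.
#' @param t_rc absolute cessation time (same unit as the tree's ages).
#' @param st a [species_tree].
#' @export
time_to_scenario <- function(t_rc, st) {
  fp <- focal_path(st)
  if (any(t_rc <= 0) || any(t_rc > st$root_age))
    stop("t_rc must lie in (0, root age]")
  h <- c(0, fp$ages)
  # half-open (h[k-1], h[k]]: scenario index is the first upper boundary >= t
  vapply(t_rc, function(t1) which(h[-1] >= t1 - 1e-12 * st$root_age)[1L], 0L)
}

#' Write a scenario set as a multi-tree Newick file plus index table
#'
#' One topology per line, ordered by scenario index. The companion table maps
#' each index to its normalized time interval.
#'
#' @param ss a `scenario_set`.
#' @param st the [species_tree] it was enumerated from (for the intervals).
#' @param file Newick output path; the index table goes to `<file>.tsv`.
#' @export
write_scenarios <- function(ss, st, file) {
  writeLines(vapply(ss$trees, ape::write.tree, ""), file)
  tab <- scenario_intervals(st)
  tab$description <- scenario_descriptions(ss, st)
  utils::write.table(tab, paste0(file, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

# human-readable attachment description per scenario
scenario_descriptions <- function(ss, st) {
  fp <- focal_path(st)
  phy <- st$phylo
  lab <- function(id) if (id <= ape::Ntip(phy)) phy$tip.label[id] else
    paste0("clade(", paste(descendant_tips(phy, id)[1:2], collapse = ","),
           ",...)")
  below <- c(st$focal, vapply(fp$nodes[-fp$P], lab, ""))
  vapply(seq_len(ss$S), function(k)
    paste0("W attaches between ", below[k], " and its parent node"), "")
}

#' The 13-species Sylvioidea reference topology fixture
#'
#' A pectinate, time-calibrated 13-species tree for the Sylvioidea songbird
#' system: six Sylvioidea species (great reed warbler focal), five further
#' Neognaths, one Paleognath and one reptile outgroup. Node ages are
#' literature-scale approximations in Myr (crown ages; root at the
#' bird-reptile split, 280 Myr). Intended for examples, simulation and
#' acceptance checks, not as a source of biological dates.
#'
#' @param multi_w if `TRUE`, mark all six Sylvioidea species as W-bearing;
#'   otherwise only the focal species.
#' @return a [species_tree].
#' @export
sylvioidea_reference_tree <- function(multi_w = FALSE) {
  sp <- c("A_arundinaceus", "A_stentoreus", "A_palustris", "I_opaca",
          "L_luscinioides", "P_biarmicus", "P_major", "T_guttata",
          "L_coronata", "M_undulatus", "G_gallus", "D_novaehollandiae",
          "A_carolinensis")
  ages <- c(3, 5, 7, 17, 21, 44, 47, 52, 55, 89, 110, 280)
  nwk <- paste0(sp[1], ":", ages[1])
  for (i in 2:13) {
    stem <- if (i < 13) ages[i] - ages[i - 1] else 0
    nwk <- paste0("(", nwk, ",", sp[i], ":", ages[i - 1], ")",
                  if (i < 13) paste0(":", stem) else "")
  }
  nwk <- paste0(nwk, ";")
  species_tree(nwk, focal = sp[1],
               w_set = if (multi_w) sp[1:6] else sp[1])
}
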