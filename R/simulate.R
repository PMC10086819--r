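#' Synthetic gametolog gene tree with a known recombination-cessation time
#'
#' Builds the dated gene tree implied by a cessation time `t_rc` on a dated
#' species tree: the Z genealogy equals the species tree; W lineages follow
#' the species tree until `t_rc` (recombination keeps Z and W of a lineage
#' identical), then split from their Z lineage exactly at `t_rc`. With a
#' single W-bearing species this attaches one W tip on the focal path; with
#' several, the W tips of species that speciated after `t_rc` form a clade
#' mirroring the species topology. Branch lengths are time x `rate`
#' substitutions/site, with every W-side branch additionally multiplied by
#' `w_rate` (faster W evolution).
#'
#' @param st a [species_tree]; its `w_set` decides which W tips exist.
#' @param t_rc cessation time, in the tree's time unit, `0 < t_rc <=` root age.
#' @param rate substitutions per site per time unit.
#' @param w_rate rate multiplier (>= 1 typically) for W-side branches.
#' @param w_suffix label suffix for W tips.
#' @return rooted [ape::phylo] with branch lengths in substitutions/site and
#'   attributes `t_rc` and `scenario` (the index whose interval contains
#'   `t_rc`).
#' @export
gametolog_tree <- function(st, t_rc, rate = 0.002, w_rate = 1.5,
                           w_suffix = "_W") {
  stopifnot(inherits(st, "species_tree"))
  if (t_rc <= 0 || t_rc > st$root_age)
    stop("t_rc must lie in (0, root age]")
  phy <- st$phylo
  nl <- as_nodelist(phy, age = st$ages)
  wname <- function(z) paste0(z, w_suffix)

  # W genealogy: species tree restricted to w_set, cut at t_rc into
  # components; each component joins its host Z lineage at exactly t_rc
  wnl <- restrict_nodelist(nl, st$w_set)
  comps <- cut_components(wnl, t_rc)
  grafts <- list()  # host node id -> W component nodelist
  for (cp in comps) {
    tips <- nodelist_tips(cp)
    v <- if (length(tips) == 1L) match(tips, phy$tip.label)
         else ape::getMRCA(phy, tips)
    # walk up to the highest ancestor still younger than t_rc
    parent <- integer(ape::Ntip(phy) + phy$Nnode)
    parent[phy$edge[, 2]] <- phy$edge[, 1]
    while (parent[v] != 0L && st$ages[parent[v]] < t_rc) v <- parent[v]
    key <- as.character(v)
    if (!is.null(grafts[[key]])) stop("internal error: two W components share a host lineage")
    grafts[[key]] <- cp
  }

  # newick writer: substitution branch lengths; a graft at a node inserts an
  # extra vertex at time t_rc on the branch above it
  wr2 <- function(node) {
    base <- if (is.null(node$children)) node$label
            else paste0("(", paste(vapply(node$children, function(ch) {
              sub <- wr2(ch)
              top_age <- attr(sub, "top_age")
              paste0(sub, ":", format((node$age - top_age) * rate, digits = 12))
            }, ""), collapse = ","), ")")
    g <- grafts[[as.character(node$id)]]
    out_age <- node$age
    if (!is.null(g)) {
      wn <- w_newick(g, t_rc, rate * w_rate, wname)
      base <- paste0("(", base, ":", format((t_rc - node$age) * rate, digits = 12),
                     ",", wn, ")")
      out_age <- t_rc
    }
    structure(base, top_age = out_age)
  }
  gt <- parse_newick(paste0(wr2(nl), ";"))
  attr(gt, "t_rc") <- t_rc
  attr(gt, "scenario") <- time_to_scenario(t_rc, st)
  gt
}

# subtree of a nodelist keeping only `keep` tips (ages preserved)
restrict_nodelist <- function(nl, keep) {
  rec <- function(node) {
    if (is.null(node$children))
      return(if (node$label %in% keep) node else NULL)
    ch <- Filter(Negate(is.null), lapply(node$children, rec))
    if (length(ch) == 0L) return(NULL)
    if (length(ch) == 1L) return(ch[[1L]])
    node$children <- ch
    node
  }
  rec(nl)
}

# maximal subtrees whose root is younger than t (components after cutting
# every edge spanning time t)
cut_components <- function(nl, t) {
  out <- list()
  rec <- function(node) {
    if (node$age < t) { out[[length(out) + 1L]] <<- node; return(invisible()) }
    for (ch in node$children) rec(ch)
  }
  rec(nl)
  out
}

nodelist_tips <- function(nl) {
  if (is.null(nl$children)) return(nl$label)
  unlist(lapply(nl$children, nodelist_tips))
}

# newick of a W component: internal ages from the species tree, stem up to
# t_rc, all branches at `wrate` substitutions per time
w_newick <- function(cp, t_rc, wrate, wname) {
  rec <- function(node, pa) {
    if (is.null(node$children))
      return(paste0(wname(node$label), ":", format(pa * wrate, digits = 12)))
    paste0("(", paste(vapply(node$children, rec, "", pa = node$age),
                      collapse = ","), ")",
           ":", format((pa - node$age) * wrate, digits = 12))
  }
  rec(cp, t_rc)
}

#' Simulate sequence evolution along a tree
#'
#' Root states are drawn from the model's stationary frequencies and evolved
#' along each branch with exact transition probabilities. Rate variation
#' follows the model: each site is invariant with probability `pinv`,
#' otherwise assigned one of the discrete-gamma category rates.
#'
#' @param tree rooted [ape::phylo], branch lengths in substitutions/site.
#' @param model a [subst_model].
#' @param L number of sites.
#' @param seed integer seed (deterministic output).
#' @param coding if `TRUE`, `L` must be divisible by 3; root codons avoid
#'   stops and codon columns where any tip carries a stop codon are re-drawn
#'   (the standard genetic code).
#' @return a [dna_alignment] over the tree's tips.
#' @export
simulate_alignment <- function(tree, model, L, seed = NULL, coding = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (coding && L %% 3 != 0) stop("coding simulation needs L divisible by 3")
  sim_once <- function(L) {
    phy <- ape::reorder.phylo(tree, "postorder")
    n <- ape::Ntip(phy)
    nn <- n + phy$Nnode
    bases <- c("A", "C", "G", "T")
    cat_of <- ifelse(stats::runif(L) < model$pinv, 0L,
                     sample.int(model$ncat, L, replace = TRUE))
    rate_of <- ifelse(cat_of == 0L, 0, model$rates[pmax(cat_of, 1L)])
    states <- matrix(0L, nn, L)
    root <- n + 1L
    states[root, ] <- sample.int(4L, L, replace = TRUE, prob = model$bf)
    if (coding) states[root, ] <- draw_root_codons(L, model$bf)
    eidx <- rev(seq_len(nrow(phy$edge)))  # preorder
    for (e in eidx) {
      p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      bl <- phy$edge.length[e]
      st <- states[p, ]
      out <- st
      for (cc in unique(cat_of[cat_of > 0L])) {
        P <- pmatrix(model, bl * model$rates[cc])
        for (i in 1:4) {
          idx <- which(st == i & cat_of == cc)
          if (length(idx))
            out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[i, ])
        }
      }
      states[ch, ] <- out
    }
    m <- matrix(bases[states[seq_len(n), ]], n, L,
                dimnames = list(phy$tip.label, NULL))
    m
  }
  m <- sim_once(L)
  if (coding) {
    stops <- c("TAA", "TAG", "TGA")
    for (round in 1:30) {
      cod <- codon_strings(m)
      bad <- which(colSums(matrix(cod %in% stops, nrow = nrow(m))) > 0)
      if (!length(bad)) break
      repl <- sim_once(3L * length(bad))
      for (j in seq_along(bad))
        m[, (3 * bad[j] - 2):(3 * bad[j])] <- repl[, (3 * j - 2):(3 * j)]
    }
    cod <- codon_strings(m)
    still <- which(colSums(matrix(cod %in% stops, nrow = nrow(m))) > 0)
    for (j in still)  # give up: copy the first row's codon everywhere
      m[, (3 * j - 2):(3 * j)] <- rep(m[1, (3 * j - 2):(3 * j)], each = nrow(m))
  }
  dna_alignment(m)
}

# ncod x ntaxa matrix of codon strings, returned as a plain vector matrix
codon_strings <- function(m) {
  ncod <- ncol(m) / 3L
  sapply(seq_len(ncod), function(j)
    apply(m[, (3 * j - 2):(3 * j), drop = FALSE], 1, paste, collapse = ""))
}

draw_root_codons <- function(L, bf) {
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  ncod <- L / 3L
  out <- integer(L)
  for (j in seq_len(ncod)) {
    repeat {
      cd <- sample.int(4L, 3L, replace = TRUE, prob = bf)
      if (!paste(bases[cd], collapse = "") %in% stops) break
    }
    out[(3 * j - 2):(3 * j)] <- cd
  }
  out
}

#' Simulation configuration for a two-strata gametolog gene set
#'
#' Describes the synthetic data set used throughout the package's tests:
#' genes from an "old" stratum (cessation before the crown of the
#' W-bearing clade, emulating the ancestral part of a neo-sex chromosome)
#' and a "young" stratum (cessation inside that clade, emulating the added
#' part), with the 22 + 29 gene-count structure of the Sylvioidea system.
#'
#' @param st a [species_tree] (defaults to the bundled 13-species reference
#'   with all six Sylvioidea species W-bearing).
#' @param n_old,n_young genes per stratum.
#' @param L alignment length (sites).
#' @param model a [subst_model] used for sequence evolution.
#' @param rate substitutions/site per time unit on Z branches.
#' @param w_rate W-branch rate multiplier.
#' @param old_range,young_range absolute-time ranges the per-gene cessation
#'   times are drawn from (uniformly).
#' @param coding simulate stop-free coding sequence.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(st = sylvioidea_reference_tree(multi_w = TRUE),
                       n_old = 22L, n_young = 29L, L = 1000L,
                       model = subst_model("HKY85", bf = c(.3, .2, .2, .3),
                                           kappa = 3, alpha = 0.8, ncat = 4L),
                       rate = 0.002, w_rate = 1.5,
                       old_range = c(55, 160), young_range = c(1.5, 21),
                       coding = FALSE, seed = 1L) {
  stopifnot(inherits(st, "species_tree"), n_old >= 0, n_young >= 0, L >= 3)
  structure(list(st = st, n_old = n_old, n_young = n_young, L = as.integer(L),
                 model = model, rate = rate, w_rate = w_rate,
                 old_range = old_range, young_range = young_range,
                 coding = coding, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-strata gametolog data set with ground truth
#'
#' Draws a cessation time per gene (old stratum: older than the W-clade
#' crown; young stratum: inside the W-bearing clade), builds each gene's
#' gametolog tree, and simulates an alignment per gene. Optionally writes
#' one FASTA per gene, the truth table and the reference tree to `out_dir`.
#'
#' @param config a [sim_config].
#' @param out_dir optional output directory.
#' @return list with `alignments` (named list of [dna_alignment]), `truth`
#'   (data frame: gene_id, t_rc, t_norm, scenario, stratum, seed) and
#'   `config`.
#' @export
simulate_two_strata <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_old + config$n_young
  stratum <- rep(c("old", "young"), c(config$n_old, config$n_young))
  t_rc <- ifelse(stratum == "old",
                 stats::runif(n, config$old_range[1], config$old_range[2]),
                 stats::runif(n, config$young_range[1], config$young_range[2]))
  gene_seeds <- sample.int(2^30, n)
  ids <- sprintf("g%03d", seq_len(n))
  alns <- vector("list", n)
  for (i in seq_len(n)) {
    gt <- gametolog_tree(config$st, t_rc[i], rate = config$rate,
                         w_rate = config$w_rate)
    alns[[i]] <- simulate_alignment(gt, config$model, config$L,
                                    seed = gene_seeds[i],
                                    coding = config$coding)
  }
  names(alns) <- ids
  truth <- data.frame(gene_id = ids, t_rc = t_rc,
                      t_norm = t_rc / config$st$root_age,
                      scenario = time_to_scenario(t_rc, config$st),
                      stratum = stratum, seed = gene_seeds)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n))
      write_fasta(alns[[i]], file.path(out_dir, paste0(ids[i], ".fasta")))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_newick(config$st$phylo, file.path(out_dir, "reference_tree.nwk"))
    writeLines(c(paste("# genes:", n), paste("# seed:", config$seed)),
               file.path(out_dir, "MANIFEST"))
  }
  list(alignments = alns, truth = truth, config = config)
}
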