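# shared fixtures and independent oracles used across test files

# random ultrametric species tree with strictly increasing node ages
random_species_tree <- function(ntip, seed) {
  set.seed(seed)
  phy <- ape::rcoal(ntip, tip.label = paste0("t", seq_len(ntip)))
  phy$edge.length <- phy$edge.length / max(ape::node.depth.edgelength(phy))
  species_tree(phy, focal = phy$tip.label[1])
}

# Robinson-Foulds distance by clade-set comparison (brute force, rooted or
# unrooted via a shared reference rooting)
rf_oracle <- function(t1, t2) {
  splits <- function(tr) {
    taxa <- sort(tr$tip.label)
    tr <- ape::root(ape::unroot(tr), outgroup = taxa[1], resolve.root = TRUE)
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    out <- vapply(pp, function(idx) {
      s <- sort(labs[idx])
      if (taxa[1] %in% s) s <- sort(setdiff(labs, s))
      paste(s, collapse = "|")
    }, "")
    sz <- lengths(strsplit(out, "\\|"))
    unique(out[sz >= 2 & sz <= length(labs) - 2])
  }
  s1 <- splits(t1); s2 <- splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# exhaustive-state pruning oracle: sums over all internal-node state
# assignments; trees <= 5 tips only
loglik_oracle <- function(aln, tree, model) {
  phy <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(phy)
  nn <- n + phy$Nnode
  lut <- trcest:::iupac_partial()
  m <- unclass(aln)[phy$tip.label, , drop = FALSE]
  ncat <- model$ncat
  P <- lapply(seq_len(ncat), function(cc)
    lapply(phy$edge.length, function(t1)
      trcest:::pmatrix(model, max(t1, 1e-9) * model$rates[cc])))
  sapply(seq_len(ncol(m)), function(s) {
    tipstates <- lapply(seq_len(n), function(i) which(lut[, m[i, s]] == 1))
    percat <- sapply(seq_len(ncat), function(cc) {
      tot <- 0
      grid <- expand.grid(rep(list(1:4), phy$Nnode))
      for (g in seq_len(nrow(grid))) {
        assign_int <- as.integer(grid[g, ])
        state_of <- function(v) if (v <= n) NA else assign_int[v - n]
        pr <- model$bf[assign_int[1]]  # root is node n+1
        ok <- TRUE
        contrib <- pr
        for (e in seq_len(nrow(phy$edge))) {
          p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
          sp <- assign_int[p - n]
          if (ch <= n) {
            contrib <- contrib * sum(P[[cc]][[e]][sp, tipstates[[ch]]])
          } else {
            contrib <- contrib * P[[cc]][[e]][sp, assign_int[ch - n]]
          }
        }
        tot <- tot + contrib
      }
      tot
    })
    lik <- (1 - model$pinv) * mean(percat)
    if (model$pinv > 0) {
      inv <- sum(sapply(1:4, function(b)
        model$bf[b] * prod(sapply(seq_len(n), function(i)
          lut[b, m[i, s]]))))
      lik <- lik + model$pinv * inv
    }
    log(lik)
  })
}

# random alignment helper
random_alignment <- function(taxa, L, seed) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), length(taxa) * L, replace = TRUE),
              length(taxa), L, dimnames = list(taxa, NULL))
  dna_alignment(m)
}

default_sim_model <- function() {
  subst_model("HKY85", bf = c(.3, .2, .2, .3), kappa = 3, alpha = 0.8,
              ncat = 4L)
}
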