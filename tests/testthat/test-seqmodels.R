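test_that("single-tip and two-tip JC likelihoods match closed forms", {
  # single tip: lnL = ln pi_b
  aln1 <- dna_alignment(c(a = "ACGT"))
  tr1 <- ape::read.tree(text = "(a:0);")
  m <- subst_model("HKY85", bf = c(.4, .3, .2, .1), kappa = 2)
  expect_equal(as.numeric(site_log_likelihoods(aln1, tr1, m)),
               log(m$bf), tolerance = 1e-12)

  # two tips under JC at branch lengths t each
  aln2 <- dna_alignment(c(a = "AG", b = "AC"))
  tr2 <- ape::read.tree(text = "(a:0.1,b:0.1);")
  jc <- subst_model("JC69")
  ll <- site_log_likelihoods(aln2, tr2, jc)
  t2 <- 0.2
  expect_equal(ll[1], log(1 / 4 * (1 / 4 + 3 / 4 * exp(-4 * t2 / 3))),
               tolerance = 1e-12)
  expect_equal(ll[2], log(1 / 4 * (1 / 4 - 1 / 4 * exp(-4 * t2 / 3))),
               tolerance = 1e-12)
})

test_that("pruning equals the exhaustive-state oracle on small trees", {
  set.seed(10)
  for (rep in 1:3) {
    ntip <- sample(3:5, 1)
    tr <- ape::rtree(ntip)
    aln <- random_alignment(tr$tip.label, 12, seed = rep)
    # add some ambiguity / gaps
    mm <- unclass(aln)
    mm[1, 1] <- "N"; mm[min(2, ntip), 2] <- "-"
    aln <- dna_alignment(mm)
    m <- subst_model("GTR", bf = c(.3, .2, .2, .3),
                     rates = c(1.5, 4, .8, 1.2, 5, 1),
                     alpha = 0.7, ncat = 4, pinv = 0.15)
    mine <- site_log_likelihoods(aln, tr, m)
    orac <- loglik_oracle(aln, tr, m)
    expect_equal(as.numeric(mine), orac, tolerance = 1e-9)
  }
})

test_that("likelihood is invariant to root placement for reversible models", {
  set.seed(3)
  tr <- ape::rtree(6)
  aln <- random_alignment(tr$tip.label, 40, seed = 4)
  m <- subst_model("TN93", bf = c(.3, .2, .2, .3), kappa1 = 4, kappa2 = 6,
                   alpha = 0.5, ncat = 4)
  l0 <- tree_log_likelihood(aln, tr, m)
  for (og in tr$tip.label[2:4]) {
    tr2 <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_equal(tree_log_likelihood(aln, tr2, m), l0, tolerance = 1e-8)
  }
})

test_that("one gamma category reduces to the rate-homogeneous model", {
  set.seed(5)
  tr <- ape::rtree(5)
  aln <- random_alignment(tr$tip.label, 30, seed = 6)
  m1 <- subst_model("HKY85", bf = c(.3, .2, .2, .3), kappa = 3, ncat = 1,
                    alpha = 7)  # alpha irrelevant at ncat = 1
  m2 <- subst_model("HKY85", bf = c(.3, .2, .2, .3), kappa = 3, ncat = 1,
                    alpha = 0.01)
  expect_equal(tree_log_likelihood(aln, tr, m1),
               tree_log_likelihood(aln, tr, m2), tolerance = 1e-12)
})

test_that("pruning matches phangorn on a mixed-rate model", {
  set.seed(8)
  tr <- ape::rtree(7)
  m <- subst_model("GTR", bf = c(.3, .2, .2, .3),
                   rates = c(1.5, 4, .8, 1.2, 5, 1), alpha = .7, ncat = 4,
                   pinv = .1)
  aln <- random_alignment(tr$tip.label, 100, seed = 9)
  dat <- phangorn::phyDat(unclass(aln), type = "DNA")
  ref <- phangorn::pml(tr, dat, bf = m$bf, Q = m$params$rates, k = 4,
                       shape = .7, inv = .1)$logLik
  expect_equal(tree_log_likelihood(aln, tr, m), ref, tolerance = 1e-8)
})

test_that("branch-length optimization reaches the JC ML distance", {
  set.seed(2)
  L <- 1000
  s1 <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  s2 <- s1
  flip <- sample(L, 120)
  s2[flip] <- sample(c("A", "C", "G", "T"), 120, replace = TRUE)
  p <- mean(s1 != s2)
  aln <- dna_alignment(rbind(a = s1, b = s2))
  o <- optimize_branch_lengths(aln, ape::read.tree(text = "(a:0.05,b:0.05);"),
                               subst_model("JC69"))
  expect_lt(abs(sum(o$tree$edge.length) - (-3 / 4 * log(1 - 4 * p / 3))),
            1e-6)
  expect_true(o$converged)
})

test_that("identical sequences optimize to (near) zero branch lengths", {
  s <- paste(rep("ACGT", 25), collapse = "")
  aln <- dna_alignment(c(a = s, b = s, c = s))
  o <- optimize_branch_lengths(aln, ape::read.tree(text = "((a:0.1,b:0.1):0.1,c:0.1);"),
                               subst_model("JC69"))
  expect_true(all(o$tree$edge.length < 1e-4))
})

test_that("optimized branch lengths are locally optimal", {
  set.seed(12)
  tr <- ape::rtree(5)
  m <- default_sim_model()
  aln <- simulate_alignment(tr, m, 500, seed = 13)
  o <- optimize_branch_lengths(aln, tr, m)
  l0 <- o$loglik
  expect_gte(l0, tree_log_likelihood(aln, tr, m))
  for (e in seq_len(nrow(o$tree$edge))) {
    for (f in c(0.9, 1.1)) {
      t2 <- o$tree
      t2$edge.length[e] <- t2$edge.length[e] * f
      expect_lte(tree_log_likelihood(aln, t2, m), l0 + 1e-6)
    }
  }
})

test_that("model fitting recovers a known transition/transversion ratio", {
  set.seed(21)
  tr <- ape::rcoal(6)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 0.4
  gen <- subst_model("HKY85", bf = c(.3, .2, .2, .3), kappa = 4, ncat = 1)
  aln <- simulate_alignment(tr, gen, 20000, seed = 22)
  fit <- fit_model(aln, tr, family = "HKY85", ncat = 1)
  expect_equal(fit$model$params$kappa, 4, tolerance = 0.15)
  expect_equal(fit$model$bf, c(.3, .2, .2, .3), tolerance = 0.05)
})

test_that("equal-frequency data yield near-uniform fitted frequencies", {
  aln <- random_alignment(c("a", "b", "c", "d"), 2000, seed = 30)
  expect_equal(trcest:::empirical_bf(aln), rep(0.25, 4), tolerance = 0.05)
})

test_that("fitted invariant proportion stays inside [0, 1)", {
  set.seed(31)
  tr <- ape::rtree(4)
  aln <- simulate_alignment(tr, subst_model("JC69"), 300, seed = 32)
  fit <- fit_model(aln, tr, family = "HKY85", ncat = 4, use_pinv = TRUE)
  expect_gte(fit$model$pinv, 0)
  expect_lt(fit$model$pinv, 1)
})

test_that("degenerate single-sequence alignments warn and fall back", {
  s <- paste(rep("ACGT", 10), collapse = "")
  aln <- dna_alignment(c(a = s, b = s, c = s))
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,c:0.1);")
  expect_warning(fit_model(aln, tr, family = "GTR"), "degenerate")
})

test_that("FASTA I/O round-trips including gaps and wrapping", {
  aln <- dna_alignment(c(seq_one = "ACGT-NACGTACGTACGT",
                         seq_two = "ACGTTTACG?ACGTACGA"))
  f <- tempfile(fileext = ".fasta")
  write_fasta(aln, f, width = 7)
  back <- read_fasta(f)
  expect_equal(rownames(back), rownames(aln))
  expect_equal(unclass(back)[, 1:18], unclass(aln)[, 1:18])
  unlink(f)
})
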