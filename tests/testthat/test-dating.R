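make_dating_fixture <- function(t_rc = 15, L = 600, seed = 3, rate = 0.01) {
  st <- species_tree("(((A:10,B:10):10,C:20):20,D:40);", focal = "A")
  gt <- gametolog_tree(st, t_rc, rate = rate, w_rate = 1)
  aln <- simulate_alignment(gt, subst_model("HKY85", bf = c(.3, .2, .2, .3),
                                            kappa = 3, ncat = 1),
                            L, seed = seed)
  topo <- gt
  topo$edge.length <- NULL
  list(st = st, gt = gt, aln = aln, topo = topo,
       cals = trcest:::auto_calibrations(st, frac = 0.05))
}

test_that("HPD intervals match a brute-force window scan", {
  expect_equal(unname(hpd_interval(rep(3.2, 10))), c(3.2, 3.2))

  x <- as.numeric(1:100)
  h <- hpd_interval(x, 0.95)
  expect_equal(h[["hi"]] - h[["lo"]], 94)

  # brute-force oracle on irregular samples
  set.seed(42)
  y <- rlnorm(200)
  m <- ceiling(0.95 * 200)
  ys <- sort(y)
  widths <- sapply(seq_len(200 - m + 1), function(i) ys[i + m - 1] - ys[i])
  i0 <- which.min(widths)
  expect_equal(unname(hpd_interval(y, 0.95)),
               c(ys[i0], ys[i0 + m - 1]), tolerance = 1e-12)

  set.seed(7)
  u <- runif(10000)
  h2 <- hpd_interval(u, 0.95)
  expect_equal(h2[["hi"]] - h2[["lo"]], 0.95, tolerance = 0.02)

  expect_error(hpd_interval(numeric(0)), "empty")
})

test_that("HPD is never wider than the equal-tailed interval", {
  set.seed(11)
  for (r in 1:5) {
    x <- rgamma(500, shape = 2)
    h <- hpd_interval(x, 0.95)
    q <- quantile(x, c(0.025, 0.975))
    expect_lte(h[["hi"]] - h[["lo"]], unname(q[2] - q[1]) + 1e-12)
  }
})

test_that("ESS behaves like an autocorrelation-time estimator", {
  set.seed(5)
  x <- rnorm(10000)
  expect_equal(ess(x), 10000, tolerance = 0.1)

  # AR(1): ESS ~ n (1 - phi) / (1 + phi)
  phi <- 0.6
  n <- 20000
  e <- rnorm(n)
  y <- as.numeric(stats::filter(e, phi, method = "recursive"))
  expect_equal(ess(y), n * (1 - phi) / (1 + phi), tolerance = 0.2)

  expect_warning(e10 <- ess(rep(1, 10)), "constant")
  expect_equal(e10, 10)
  expect_error(ess(1:5), "10 samples")
})

test_that("the dating trace has the configured length and layout", {
  fx <- make_dating_fixture()
  cfg <- dating_config(chain_length = 5000, sample_interval = 50,
                       pre_burnin = 500, seed = 8)
  tr <- run_dating_mcmc(fx$aln, fx$topo, fx$cals, cfg,
                        focal_z = "A", focal_w = "A_W",
                        model = subst_model("HKY85", bf = c(.3, .2, .2, .3),
                                            kappa = 3, ncat = 1))
  expect_equal(nrow(tr), floor((5000 - 500) / 50))
  expect_true(all(c("state", "posterior", "likelihood", "prior",
                    "focal_age", "root_age", "rate") %in% names(tr)))
  expect_true(all(tr$focal_age > 0))
  # ordering: focal age below its parent (root here is far above)
  expect_true(all(tr$focal_age <= tr$root_age))
  # determinism
  tr2 <- run_dating_mcmc(fx$aln, fx$topo, fx$cals, cfg,
                         focal_z = "A", focal_w = "A_W",
                         model = subst_model("HKY85", bf = c(.3, .2, .2, .3),
                                             kappa = 3, ncat = 1))
  expect_identical(tr$focal_age, tr2$focal_age)
})

test_that("prior-only sampling reproduces a calibration prior", {
  fx <- make_dating_fixture()
  cfg <- dating_config(chain_length = 42000, sample_interval = 4,
                       pre_burnin = 2000, seed = 6)
  tr <- run_dating_mcmc(fx$aln, fx$topo, fx$cals, cfg,
                        focal_z = "A", focal_w = "A_W", prior_only = TRUE)
  expect_gte(nrow(tr), 10000)
  # root calibration: normal(40, 2); ordering constraints bind negligibly
  ks <- suppressWarnings(stats::ks.test(tr$root_age, "pnorm", 40, 2))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("strict-clock dating concentrates around the true age", {
  fx <- make_dating_fixture(t_rc = 15, L = 800, seed = 31)
  cfg <- dating_config(chain_length = 20000, sample_interval = 20,
                       pre_burnin = 2000, seed = 32)
  tr <- run_dating_mcmc(fx$aln, fx$topo, fx$cals, cfg,
                        focal_z = "A", focal_w = "A_W",
                        model = subst_model("HKY85", bf = c(.3, .2, .2, .3),
                                            kappa = 3, ncat = 1))
  res <- dating_result(tr, normalize = FALSE)
  expect_lte(res$hpd_lo, 15)
  expect_gte(res$hpd_hi, 15)
  expect_lte(res$hpd_lo, res$median)
  expect_lte(res$median, res$hpd_hi)
  # normalized results live on (0, 1]
  resn <- dating_result(tr)
  expect_true(all(resn$samples > 0 & resn$samples <= 1))
})

test_that("the relaxed-clock sampler runs and keeps ordering", {
  fx <- make_dating_fixture()
  cfg <- dating_config(chain_length = 4000, sample_interval = 40,
                       pre_burnin = 400, clock = "ucln", seed = 9)
  tr <- run_dating_mcmc(fx$aln, fx$topo, fx$cals, cfg,
                        focal_z = "A", focal_w = "A_W",
                        model = subst_model("HKY85", bf = c(.3, .2, .2, .3),
                                            kappa = 3, ncat = 1))
  expect_true(all(tr$focal_age <= tr$root_age))
  expect_true("sigma" %in% names(tr))
})

test_that("calibrating the focal node is rejected", {
  fx <- make_dating_fixture()
  bad <- c(fx$cals, list(calibration_prior(c("A", "A_W"), "normal", 15, 1)))
  cfg <- dating_config(chain_length = 1000, sample_interval = 10,
                       pre_burnin = 100, seed = 1)
  expect_error(run_dating_mcmc(fx$aln, fx$topo, bad, cfg,
                               focal_z = "A", focal_w = "A_W"),
               "focal")
})

test_that("outgroup reduction prunes tree, alignment and calibrations", {
  st <- sylvioidea_reference_tree()
  gt <- gametolog_tree(st, 50, w_rate = 1)
  aln <- simulate_alignment(gt, default_sim_model(), 100, seed = 3)
  cals <- trcest:::auto_calibrations(st)

  full <- reduce_outgroups(st, aln, keep = 12, calibrations = cals)
  expect_equal(sort(full$st$phylo$tip.label), sort(st$phylo$tip.label))
  expect_length(full$calibrations, length(cals))

  one <- reduce_outgroups(st, aln, keep = 1, calibrations = cals)
  expect_equal(ape::Ntip(one$st$phylo), 2L)
  expect_setequal(rownames(one$aln),
                  c("A_arundinaceus", "A_stentoreus", "A_arundinaceus_W"))

  three <- reduce_outgroups(st, aln, keep = 3)
  expect_setequal(three$st$phylo$tip.label,
                  c("A_arundinaceus", "A_stentoreus", "A_palustris",
                    "I_opaca"))
  expect_error(reduce_outgroups(st, aln, keep = 13), "exceeds")
})
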