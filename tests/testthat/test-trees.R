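test_that("Newick parsing round-trips and validates", {
  tr <- parse_newick("((A,B),C);")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 2L)

  tr1 <- parse_newick("(A);")
  expect_equal(ape::Ntip(tr1), 1L)
  expect_equal(tr1$Nnode, 1L)

  expect_error(parse_newick("((A,B),C;"), "malformed")
  expect_error(parse_newick("((A,B),A);"), "duplicate")

  # parse-write identity on random 10-tip trees, by the RF clade-set oracle
  for (s in 1:5) {
    set.seed(s)
    t0 <- ape::rtree(10)
    t1 <- parse_newick(write_newick(t0))
    expect_equal(rf_oracle(t0, t1), 0)
  }
})

test_that("focal path extraction follows the tip-to-root path", {
  st <- species_tree("((A:1,B:1):1,C:2);", focal = "A")
  fp <- focal_path(st)
  expect_equal(fp$P, 2L)
  expect_equal(fp$ages, c(1, 2))

  st4 <- species_tree("((A:1,B:1):1,(C:1,D:1):1);", focal = "A")
  expect_equal(focal_path(st4)$P, 2L)

  # 13-species pectinate reference: 12 internal nodes on the focal path
  ref <- sylvioidea_reference_tree()
  expect_equal(focal_path(ref)$P, 12L)
  expect_equal(max(focal_path(ref)$ages), ref$root_age)

  expect_error(species_tree("((A:1,B:1):1,C:2);", focal = "Z"), "not a tip")
})

test_that("single-W enumeration emits one topology per focal-path interval", {
  st <- species_tree("((A:1,B:1):1,C:2);", focal = "A")
  ss <- enumerate_single_w(st)
  expect_equal(ss$S, 2L)
  got <- sort(vapply(ss$trees, write_newick, ""))
  expect_equal(got, sort(c("(((A,A_W),B),C);", "(((A,B),A_W),C);")))

  st2 <- species_tree("(A:1,B:1);", focal = "A")
  ss2 <- enumerate_single_w(st2)
  expect_equal(ss2$S, 1L)
  expect_equal(write_newick(ss2$trees[[1]]), "((A,A_W),B);")

  # above-root attachment appended only when requested
  expect_equal(enumerate_single_w(st, exclude_above_root = FALSE)$S, 3L)

  expect_error(enumerate_single_w(species_tree(ape::read.tree(text = "(A);"),
                                               focal = "A", ages = 1)),
               "single-tip")

  # S equals the focal-path length on random trees (4..20 tips)
  for (n in c(4, 7, 12, 20)) {
    st_r <- random_species_tree(n, seed = n)
    expect_equal(enumerate_single_w(st_r)$S, focal_path(st_r)$P)
  }

  # every emitted topology contains each required tip exactly once
  ref <- sylvioidea_reference_tree()
  for (tr in enumerate_single_w(ref)$trees)
    expect_setequal(tr$tip.label,
                    c(ref$phylo$tip.label, "A_arundinaceus_W"))
})

test_that("scenario 2 on the reference places W with the two reed warblers", {
  ref <- sylvioidea_reference_tree()
  ss <- enumerate_single_w(ref)
  expect_equal(ss$S, 12L)
  t2 <- ss$trees[[2]]
  w_parent_clade <- ape::extract.clade(
    t2, ape::getMRCA(t2, c("A_arundinaceus", "A_arundinaceus_W")))
  expect_setequal(w_parent_clade$tip.label,
                  c("A_arundinaceus", "A_stentoreus", "A_arundinaceus_W"))
})

test_that("multi-W enumeration mirrors the species topology for recent splits", {
  st <- species_tree("((A:1,B:1):1,C:2);", focal = "A", w_set = c("A", "B"))
  ss <- enumerate_multi_w(st)
  expect_equal(ss$S, 2L)
  expect_equal(write_newick(ss$trees[[1]]), "(((A,A_W),(B,B_W)),C);")
  expect_equal(write_newick(ss$trees[[2]]), "(((A,B),(A_W,B_W)),C);")

  ref <- sylvioidea_reference_tree(multi_w = TRUE)
  sm <- enumerate_multi_w(ref)
  expect_equal(sm$S, 12L)
  # scenario 1: every W sister to its own Z
  t1 <- sm$trees[[1]]
  for (sp in ref$w_set) {
    sib <- ape::extract.clade(t1, ape::getMRCA(t1, c(sp, paste0(sp, "_W"))))
    expect_setequal(sib$tip.label, c(sp, paste0(sp, "_W")))
  }
  # scenario 11: the six W tips form one clade placed between the
  # G. gallus and D. novaehollandiae attachment points
  t11 <- sm$trees[[11]]
  wtips <- paste0(ref$w_set, "_W")
  wclade <- ape::extract.clade(t11, ape::getMRCA(t11, wtips))
  expect_setequal(wclade$tip.label, wtips)
  up <- ape::extract.clade(
    t11, ape::getMRCA(t11, c("A_arundinaceus", "A_arundinaceus_W")))
  expect_true("G_gallus" %in% up$tip.label)
  expect_false("D_novaehollandiae" %in% up$tip.label)

  expect_error(enumerate_multi_w(species_tree("((A:1,B:1):1,C:2);",
                                              focal = "A",
                                              w_set = c("A", "C"))),
               "root")
})

test_that("multi-W scenarios restrict to the single-W scenarios", {
  ref1 <- sylvioidea_reference_tree()
  refm <- sylvioidea_reference_tree(multi_w = TRUE)
  ss <- enumerate_single_w(ref1)
  sm <- enumerate_multi_w(refm)
  keep <- c(ref1$phylo$tip.label, "A_arundinaceus_W")
  for (k in seq_len(ss$S)) {
    restr <- ape::keep.tip(sm$trees[[k]], keep)
    expect_equal(rf_oracle(restr, ss$trees[[k]]), 0)
  }
})

test_that("scenario intervals partition (0, 1] on the normalized scale", {
  ref <- sylvioidea_reference_tree()
  iv <- scenario_intervals(ref)
  expect_equal(iv$t_lo[1], 0)
  expect_equal(iv$t_hi[nrow(iv)], 1)
  expect_equal(iv$t_lo[-1], iv$t_hi[-nrow(iv)])   # contiguous, disjoint
  expect_length(attr(iv, "boundaries"), 13L)      # S + 1 distinct values

  expect_equal(scenario_to_time_interval(1, ref)[["lo"]], 0)
  expect_equal(scenario_to_time_interval(12, ref)[["hi"]], 1)
  expect_error(scenario_to_time_interval(13, ref), "range")

  # inverse lookup agrees with the intervals
  for (k in c(1, 4, 9, 12)) {
    mid <- mean(scenario_to_time_interval(k, ref)) * ref$root_age
    expect_equal(time_to_scenario(mid, ref), k)
  }
})

test_that("scenario sets serialize to multi-Newick plus an index table", {
  ref <- sylvioidea_reference_tree()
  ss <- enumerate_single_w(ref)
  f <- tempfile(fileext = ".nwk")
  write_scenarios(ss, ref, f)
  lines <- readLines(f)
  expect_length(lines, 12L)
  tab <- read.table(paste0(f, ".tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 12L)
  expect_true(all(c("scenario", "t_lo", "t_hi") %in% names(tab)))
  unlink(c(f, paste0(f, ".tsv")))
})
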