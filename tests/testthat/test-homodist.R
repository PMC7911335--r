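test_that("center selection minimizes mean distance with stable ties", {
  D <- matrix(c(0, .1, .1, .1, 0, .06, .1, .06, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  # row means: a .10, b .08, c .08 -> tie between b and c, b comes first
  expect_equal(find_center(D), "b")

  De <- matrix(0.2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(De) <- 0
  expect_equal(find_center(De), "a")

  # star-shaped matrix: hub at distance r from every spoke, spokes at 2r
  labs <- c("s1", "hub", "s2", "s3")
  Ds <- matrix(0.4, 4, 4, dimnames = list(labs, labs))
  Ds["hub", ] <- Ds[, "hub"] <- 0.2
  diag(Ds) <- 0
  means <- rowSums(Ds) / 3  # direct oracle
  expect_equal(find_center(Ds), labs[which.min(means)])
  expect_equal(find_center(Ds), "hub")
})

test_that("taxa are ordered by ascending distance from the center, ties stable", {
  labs <- c("a", "b", "c")
  D <- matrix(0, 3, 3, dimnames = list(labs, labs))
  D["c", "a"] <- D["a", "c"] <- 0.3
  D["c", "b"] <- D["b", "c"] <- 0.1
  D["a", "b"] <- D["b", "a"] <- 0.2
  expect_equal(order_by_center_distance(D, "c"), c("c", "b", "a"))

  # tie between two taxa keeps input order
  labs2 <- c("x", "p", "q", "r")
  D2 <- matrix(0.2, 4, 4, dimnames = list(labs2, labs2))
  diag(D2) <- 0
  D2["x", "r"] <- D2["r", "x"] <- 0.1
  expect_equal(order_by_center_distance(D2, "x"), c("x", "r", "p", "q"))

  # random matrix vs brute-force sort oracle
  set.seed(31)
  labs3 <- paste0("t", 1:5)
  M <- matrix(0, 5, 5, dimnames = list(labs3, labs3))
  M[upper.tri(M)] <- runif(10)
  M <- M + t(M)
  ctr <- "t3"
  oracle <- c(ctr, setdiff(labs3, ctr)[order(M[ctr, setdiff(labs3, ctr)])])
  expect_equal(order_by_center_distance(M, ctr), oracle)
})

test_that("the trace engine honors its step structure and invariants", {
  tr <- random_binary_tree(4, seed = 8)
  aln4 <- simulate_homoplasy_free_alignment(tr, 80, 25, seed = 9)
  trace4 <- run_homodist(aln4)
  expect_equal(nrow(tidy(trace4)), 1)
  expect_equal(tidy(trace4)$n_taxa, 4)

  expect_error(run_homodist(alignment(c("ACG", "ACT", "AGT"),
                                      c("a", "b", "c"))),
               "at least 4")

  tr10 <- random_binary_tree(10, seed = 21)
  aln <- simulate_homoplasy_free_alignment(tr10, 250, 80, seed = 22)
  trace <- run_homodist(aln)
  steps <- tidy(trace)
  expect_equal(nrow(steps), 10 - 3)
  expect_true(all(diff(steps$disCen) >= 0))
  expect_true(all(diff(steps$MaxD) >= 0))
  for (m in c("nj", "upgma")) {
    expect_equal(steps[[paste0(m, "_HI")]], 1 - steps[[paste0(m, "_CI")]])
    expect_equal(steps[[paste0(m, "_SHI")]] * steps$MaxD,
                 steps[[paste0(m, "_HI")]])
    expect_true(all(steps[[paste0(m, "_M")]] <= steps[[paste0(m, "_S")]]))
    expect_true(all(steps[[paste0(m, "_S")]] <= steps[[paste0(m, "_G")]]))
  }

  # homoplasy-free data whose NJ trees match the generating topology give a
  # flat HI = 0, SHI = 0 trace
  for (k in seq_len(nrow(steps))) {
    sub <- trace$series[seq_len(k + 3)]
    ref <- ape::keep.tip(tr10, sub)
    if (ape::dist.topo(ape::unroot(trace$trees[[k]]$nj),
                       ape::unroot(ref)) == 0) {
      expect_equal(steps$nj_HI[k], 0)
      expect_equal(steps$nj_SHI[k], 0)
    }
  }

  # glance summarizes the final step of the leading method
  g <- glance(trace)
  expect_equal(g$n_steps, 7)
  expect_equal(g$final_HI, steps$nj_HI[7])
})

test_that("manual center selection accepts labels and positions", {
  tr <- random_binary_tree(6, seed = 4)
  aln <- simulate_homoplasy_free_alignment(tr, 150, 50, seed = 5)
  lab <- taxa_labels(aln)[2]
  t_lab <- run_homodist(aln, auto_center = FALSE, center = lab)
  t_pos <- run_homodist(aln, auto_center = FALSE, center = 2)
  expect_equal(t_lab$center, lab)
  expect_equal(t_lab$series, t_pos$series)
  expect_error(run_homodist(aln, auto_center = FALSE), "center must be given")
  expect_error(run_homodist(aln, auto_center = FALSE, center = "nope"),
               "not found")
})

test_that("first_homoplasy_step finds the earliest HI > 0 step or none", {
  trc <- fake_trace(c(0, 0, 0.02, 0.05))
  hit <- first_homoplasy_step(trc)
  expect_equal(hit$step, 3)
  expect_equal(hit$HI, 0.02)
  expect_equal(hit$MaxD, trc$steps$MaxD[3])

  none <- first_homoplasy_step(fake_trace(c(0, 0, 0)))
  expect_equal(nrow(none), 0)
})

test_that("CI-distance correlation matches the Pearson oracle on qualifying steps", {
  # CI strictly linear in MaxD with negative slope -> r = -1
  maxd <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  ci <- 1 - maxd  # all < 1
  trc <- fake_trace(hi = 1 - ci, maxd = maxd, ci = ci)
  expect_equal(ci_distance_correlation(trc), -1)

  # arbitrary values vs direct formula, CI = 1 steps excluded
  ci2 <- c(1, 0.95, 0.9, 0.92, 0.85)
  maxd2 <- c(0.05, 0.1, 0.2, 0.3, 0.45)
  trc2 <- fake_trace(hi = 1 - ci2, maxd = maxd2, ci = ci2)
  expect_equal(ci_distance_correlation(trc2),
               pearson_oracle(maxd2[-1], ci2[-1]))

  # fewer than 3 qualifying steps -> NA
  ci3 <- c(1, 1, 1, 0.9, 0.8)
  trc3 <- fake_trace(hi = 1 - ci3, ci = ci3)
  expect_true(is.na(ci_distance_correlation(trc3)))

  # zero variance -> NA
  ci4 <- rep(0.9, 4)
  trc4 <- fake_trace(hi = 1 - ci4, ci = ci4)
  expect_true(is.na(ci_distance_correlation(trc4)))
})

test_that("HI plateaus partition the taxon series at HI change points", {
  # 9 taxa, 6 steps; step HI: 0 0 0 .1 .1 .2
  trc <- fake_trace(c(0, 0, 0, 0.1, 0.1, 0.2))
  part <- delimit_hi_groups(trc)
  expect_equal(max(part$group), 3)
  expect_equal(part$group, c(rep(1L, 6), 2L, 2L, 3L))
  expect_equal(attr(part, "boundaries"), c(4, 6))
  # groups partition the full series
  expect_setequal(part$taxon, trc$series)
  # consecutive groups differ in HI
  by_group <- tapply(part$HI, part$group, unique)
  expect_true(all(diff(unlist(by_group)) != 0))

  expect_equal(max(delimit_hi_groups(fake_trace(rep(0.1, 5)))$group), 1)

  inc <- delimit_hi_groups(fake_trace(c(0.01, 0.02, 0.03, 0.04)))
  expect_equal(inc$group, c(1L, 1L, 1L, 1L, 2L, 3L, 4L))

  # rounding control: a change below the rounding resolution merges
  trc5 <- fake_trace(c(0.1, 0.100004, 0.2))
  expect_equal(max(delimit_hi_groups(trc5, digits = 4)$group), 2)
  expect_equal(max(delimit_hi_groups(trc5, digits = Inf)$group), 3)
})

test_that("trace TSV and per-step Newick exports round-trip", {
  tr <- random_binary_tree(7, seed = 14)
  aln <- simulate_homoplasy_free_alignment(tr, 150, 60, seed = 15)
  aln <- inject_convergent_sites(aln, tr, 4, seed = 16)
  trace <- run_homodist(aln)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trace_tsv(trace, f)
  back <- read_trace_tsv(f)
  expect_equal(names(back), names(trace$steps))
  expect_equal(back$nj_CI, trace$steps$nj_CI, tolerance = 1e-9)

  d <- withr::local_tempdir()
  write_trace_trees(trace, d)
  files <- list.files(d)
  expect_length(files, 2 * nrow(trace$steps))
  expect_true("step_1_nj.nwk" %in% files)
  nwk <- readLines(file.path(d, "step_1_nj.nwk"))
  expect_setequal(ape::read.tree(text = nwk)$tip.label,
                  trace$series[1:4])
})

test_that("final-step HI is center-independent when the final NJ topology is", {
  tr <- random_binary_tree(8, seed = 51)
  aln <- simulate_homoplasy_free_alignment(tr, 200, 70, seed = 52)
  aln <- inject_convergent_sites(aln, tr, 3, seed = 53)
  traces <- lapply(taxa_labels(aln)[1:3], function(ctr) {
    run_homodist(aln, auto_center = FALSE, center = ctr,
                 tree_methods = "nj")
  })
  final_trees <- lapply(traces, function(t) {
    ape::unroot(t$trees[[length(t$trees)]]$nj)
  })
  same <- vapply(final_trees[-1], function(x) {
    ape::dist.topo(x, final_trees[[1]]) == 0
  }, logical(1))
  final_hi <- vapply(traces, function(t) tail(t$steps$nj_HI, 1), numeric(1))
  expect_equal(final_hi[c(TRUE, same)], rep(final_hi[1], 1 + sum(same)))
})
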