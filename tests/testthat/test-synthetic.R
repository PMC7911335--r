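test_that("random trees are deterministic per seed and valid", {
  t1 <- random_binary_tree(8, seed = 5)
  t2 <- random_binary_tree(8, seed = 5)
  expect_equal(to_newick(t1), to_newick(t2))
  expect_true(ape::is.binary(t1))
  expect_true(ape::is.rooted(t1))
  expect_equal(sort(t1$tip.label), sort(paste0("t", 1:8)))

  t3 <- random_binary_tree(3, seed = 1)
  expect_equal(length(t3$tip.label), 3)
  expect_error(random_binary_tree(2, seed = 1), "at least 3")
  # generators do not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(random_binary_tree(5, seed = 9)); after <- runif(1)
  expect_equal(before, after)
})

test_that("homoplasy-free construction scores CI = 1 on its generating topology", {
  for (seed in 1:25) {
    n <- 4 + seed %% 9
    tr <- random_binary_tree(n, seed = seed)
    aln <- simulate_homoplasy_free_alignment(tr, n_sites = 150,
                                             n_mutations = 50, seed = seed)
    sc <- consistency_indices(tr, aln)
    expect_equal(sc$CI, 1)
    expect_equal(sc$HI, 0)
  }

  # n_mutations = 0: invariant alignment, CI = 1 by the S = 0 convention
  tr <- random_binary_tree(6, seed = 3)
  inv <- simulate_homoplasy_free_alignment(tr, 50, 0, seed = 3)
  sc0 <- consistency_indices(tr, inv)
  expect_equal(sc0$S, 0)
  expect_equal(sc0$CI, 1)

  # the same data scored on an unrelated topology can only need more steps
  aln <- simulate_homoplasy_free_alignment(tr, 200, 60, seed = 10)
  other <- random_binary_tree(6, seed = 99)
  other$tip.label <- tr$tip.label[c(3, 1, 5, 2, 6, 4)]
  sc_other <- consistency_indices(other, aln)
  expect_gte(sc_other$S, sc_other$M)

  expect_error(simulate_homoplasy_free_alignment(tr, 10, 11, seed = 1),
               "n_mutations")
})

test_that("injected convergent sites add exactly 2 steps and 1 minimum step each", {
  tr <- random_binary_tree(10, seed = 6)
  base <- simulate_homoplasy_free_alignment(tr, 200, 70, seed = 7)
  sc_base <- consistency_indices(tr, base)
  k <- 5
  conv <- inject_convergent_sites(base, tr, k, seed = 8)
  expect_equal(n_sites(conv), n_sites(base) + k)
  sc <- consistency_indices(tr, conv)
  expect_equal(sc$S, sc_base$S + 2 * k)
  expect_equal(sc$M, sc_base$M + k)
  expect_equal(sc$HI, (sc$S - sc$M) / sc$S)
  expect_gt(sc$HI, 0)

  # deterministic per seed; k = 0 refused
  conv2 <- inject_convergent_sites(base, tr, k, seed = 8)
  expect_identical(unclass(conv2), unclass(conv))
  expect_error(inject_convergent_sites(base, tr, 0, seed = 1), "k must be")

  # explicit ineligible clade pair
  expect_error(
    inject_convergent_sites(base, tr, 1, seed = 1,
                            clades = list(tr$tip.label[1], tr$tip.label[1])),
    "not disjoint")
})

test_that("injection guarantees HI > 0 on the true topology across seeds", {
  for (seed in 1:15) {
    tr <- random_binary_tree(6 + seed %% 5, seed = seed)
    base <- simulate_homoplasy_free_alignment(tr, 120, 40, seed = seed + 100)
    conv <- inject_convergent_sites(base, tr, 3, seed = seed + 200)
    expect_gt(consistency_indices(tr, conv)$HI, 0)
  }
})

test_that("synthetic alignments round-trip through FASTA", {
  tr <- random_binary_tree(6, seed = 2)
  aln <- inject_convergent_sites(
    simulate_homoplasy_free_alignment(tr, 90, 30, seed = 2), tr, 2, seed = 3)
  f <- withr::local_tempfile(fileext = ".fas")
  write_fasta_alignment(aln, f)
  back <- read_fasta_alignment(f)
  expect_equal(unclass(back), unclass(aln), ignore_attr = TRUE)
})

test_that("F84 sequence simulation matches its stationary model", {
  # zero-length branches copy states
  two <- ape::read.tree(text = "(a:0,b:0);")
  aln0 <- simulate_f84_sequences(two, n_sites = 200, seed = 4)
  expect_equal(unclass(aln0)["a", ], unclass(aln0)["b", ])

  # deterministic per seed
  tr <- random_binary_tree(5, seed = 12)
  a1 <- simulate_f84_sequences(tr, kappa = 2, n_sites = 100, seed = 5)
  a2 <- simulate_f84_sequences(tr, kappa = 2, n_sites = 100, seed = 5)
  expect_identical(unclass(a1), unclass(a2))

  # skewed stationary frequencies are respected over long sequences
  freqs <- c(A = 0.4, C = 0.1, G = 0.3, T = 0.2)
  sim <- simulate_f84_sequences(ape::read.tree(text = "(a:0.05,b:0.05);"),
                                freqs = freqs, kappa = 1,
                                n_sites = 20000, seed = 6)
  obs <- estimate_base_frequencies(sim)
  expect_equal(unname(obs), unname(freqs), tolerance = 0.02)

  # uniform frequencies: transition excess raises P relative to Q in line
  # with K80-style expectations
  simk <- simulate_f84_sequences(ape::read.tree(text = "(a:0.1,b:0.1);"),
                                 kappa = 4, n_sites = 20000, seed = 7)
  pc <- count_pair_differences(unclass(simk)["a", ], unclass(simk)["b", ])
  expect_gt(pc$P, pc$Q)
})
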