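test_that("pruning equals brute-force internal-state enumeration", {
  set.seed(51)
  for (i in 1:15) {
    mod <- random_gtr()
    qa <- random_quartet_aln(sample(1:10, 1))
    bl <- runif(5, 0.01, 1)
    for (tp in c("T1", "T2", "T3")) {
      expect_equal(quartet_loglik(qa, tp, mod, bl),
                   brute_quartet_loglik(qa, tp, mod, bl),
                   tolerance = 1e-10)
    }
  }
  # amino acid / LG draws too
  mlg <- model_lg(gamma_shape = 0.8, n_categories = 4L)
  for (i in 1:5) {
    qa <- random_quartet_aln(6, "amino_acid")
    bl <- runif(5, 0.01, 1)
    expect_equal(quartet_loglik(qa, "T2", mlg, bl),
                 brute_quartet_loglik(qa, "T2", mlg, bl),
                 tolerance = 1e-10)
  }
})

test_that("label symmetry: identical sequences give equal topology likelihoods", {
  qa <- mk_aln(rep("ACGTACGTAC", 4))
  mod <- random_gtr()
  bl <- rep(0.2, 5)
  l <- vapply(c("T1", "T2", "T3"), function(tp) {
    quartet_loglik(qa, tp, mod, bl)
  }, numeric(1))
  expect_equal(l[["T1"]], l[["T2"]], tolerance = 1e-12)
  expect_equal(l[["T1"]], l[["T3"]], tolerance = 1e-12)
})

test_that("missing columns are excluded; zero-overlap quartets are undetermined", {
  qa <- mk_aln(c("AC--", "AC--", "--GT", "--GT"))
  mod <- model_jc()
  expect_true(is.na(quartet_loglik(qa, "T1", mod, rep(0.1, 5))))
  fit <- optimize_quartet(qa, "T1", mod)
  expect_true(is.na(fit$loglik))
  expect_identical(fit$n_sites_used, 0L)

  # partial missingness: only jointly observed columns count
  qb <- mk_aln(c("ACGT", "ACGT", "AC-T", "ACGT"))
  full <- mk_aln(c("ACT", "ACT", "ACT", "ACT"))
  expect_equal(quartet_loglik(qb, "T1", mod, rep(0.1, 5)),
               quartet_loglik(full, "T1", mod, rep(0.1, 5)))
})

test_that("site-likelihood additivity: doubling the alignment doubles lnL", {
  set.seed(52)
  qa <- random_quartet_aln(40)
  mod <- random_gtr()
  bl <- runif(5, 0.05, 0.5)
  doubled <- phylo_alignment(cbind(qa$matrix, qa$matrix), "nucleotide")
  expect_equal(quartet_loglik(doubled, "T1", mod, bl),
               2 * quartet_loglik(qa, "T1", mod, bl), tolerance = 1e-9)
})

test_that("topology weights are a normalized softmax of the log-likelihoods", {
  expect_equal(topology_weights(c(-5, -5, -5)), rep(1 / 3, 3))
  expect_equal(topology_weights(c(0, -1e9, -1e9)), c(1, 0, 0),
               tolerance = 1e-12)
  expect_equal(topology_weights(c(log(2), 0, 0)), c(0.5, 0.25, 0.25),
               tolerance = 1e-12)
  # shift invariance
  l <- c(-1043.2, -1041.7, -1044.9)
  expect_equal(topology_weights(l), topology_weights(l + 500),
               tolerance = 1e-12)
  expect_error(topology_weights(c(0, NA, 1)), "finite")
  expect_error(topology_weights(c(0, -Inf, 1)), "finite")
})

test_that("optimization recovers the generating topology and is deterministic", {
  fct <- four_cluster_tree(c(1, 1, 1, 1), internal_length = 0.5,
                           tip_length = 0.15)
  mod <- model_gtr(rates = c(1.5, 4, 1, 1.2, 4.5, 1),
                   frequencies = c(.3, .2, .2, .3),
                   gamma_shape = 1, n_categories = 4L)
  aln <- simulate_sequences(fct$tree, mod, 5000, seed = 53)
  fit1 <- optimize_quartet(aln, "T1", mod)
  fit2 <- optimize_quartet(aln, "T2", mod)
  fit3 <- optimize_quartet(aln, "T3", mod)
  expect_gt(fit1$loglik, fit2$loglik)
  expect_gt(fit1$loglik, fit3$loglik)
  expect_true(fit1$converged)
  # deterministic: same input, same result, bit for bit
  expect_identical(optimize_quartet(aln, "T1", mod), fit1)
  # the optimum is a real optimum of the reported likelihood
  expect_equal(fit1$loglik,
               quartet_loglik(aln, "T1", mod, fit1$branch_lengths),
               tolerance = 1e-9)
})

test_that("all-identical sequences drive branch lengths to the lower bound", {
  qa <- mk_aln(rep(paste(rep("ACGT", 25), collapse = ""), 4))
  fit <- optimize_quartet(qa, "T1", model_jc(), lower = 1e-8)
  expect_true(all(fit$branch_lengths < 1e-5))
})

test_that("consistent leaf relabeling permutes the weight vector", {
  fct <- four_cluster_tree(c(1, 1, 1, 1), internal_length = 0.4,
                           tip_length = 0.15)
  mod <- model_gtr(rates = c(2, 4, 1, 1, 4, 1), frequencies = c(.3, .2, .2, .3))
  aln <- simulate_sequences(fct$tree, mod, 2000, seed = 54)
  w0 <- as.numeric(evaluate_quartet(aln, mod)[, c("p1", "p2", "p3")])
  # swapping rows 2 and 3 exchanges T1 <-> T2
  swapped <- slice_alignment(aln, taxa_labels(aln)[c(1, 3, 2, 4)])
  w1 <- as.numeric(evaluate_quartet(swapped, mod)[, c("p1", "p2", "p3")])
  expect_equal(w1, w0[c(2, 1, 3)], tolerance = 1e-4)
})
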