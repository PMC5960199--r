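test_that("quartet enumeration is the group product, subsampled deterministically", {
  g1 <- taxon_groups(list(a = "a1", b = "b1", c = "c1", d = "d1"))
  expect_identical(nrow(enumerate_quartets(g1)), 1L)

  g <- taxon_groups(list(a = paste0("a", 1:2), b = paste0("b", 1:3),
                         c = paste0("c", 1:4), d = paste0("d", 1:5)))
  all_q <- enumerate_quartets(g)
  expect_identical(nrow(all_q), 120L)
  expect_identical(nrow(dplyr::distinct(all_q)), 120L)
  # subsample of the full size is the full enumeration
  expect_identical(enumerate_quartets(g, max_quartets = 120, seed = 1), all_q)
  # fixed seed reproduces the subsample; rows come from the product
  s1 <- enumerate_quartets(g, max_quartets = 10, seed = 9)
  expect_identical(s1, enumerate_quartets(g, max_quartets = 10, seed = 9))
  expect_identical(nrow(dplyr::inner_join(s1, all_q, by = names(all_q))), 10L)
})

test_that("region classification follows corner/edge/center boundaries", {
  expect_identical(classify_region(c(1, 0, 0)), "C1")
  expect_identical(classify_region(c(0, 0, 1)), "C3")
  expect_identical(classify_region(rep(1 / 3, 3)), "center")
  expect_identical(classify_region(c(0.5, 0.45, 0.05)), "E12")
  expect_identical(classify_region(c(0.05, 0.5, 0.45)), "E23")
  # just inside the corner vs just outside
  expect_identical(classify_region(c(0.67, 0.23, 0.10)), "C1")
  expect_identical(classify_region(c(0.66, 0.24, 0.10)), "E12")
  # tie between the two largest breaks toward the lower index pair
  expect_identical(classify_region(c(0.45, 0.45, 0.10)), "E12")
  # no weight below the edge threshold -> center
  expect_identical(classify_region(c(0.5, 0.3, 0.2)), "center")
  # matrix input vectorizes
  expect_identical(classify_region(rbind(c(1, 0, 0), rep(1 / 3, 3))),
                   c("C1", "center"))
})

test_that("simplex embedding maps weights to the fixed triangle", {
  expect_equal(simplex_xy(c(1, 0, 0)), cbind(0, 0))
  expect_equal(simplex_xy(c(0, 1, 0)), cbind(1, 0))
  expect_equal(simplex_xy(c(0, 0, 1)), cbind(0.5, sqrt(3) / 2))
  expect_equal(simplex_xy(rep(1 / 3, 3)), cbind(0.5, sqrt(3) / 6),
               tolerance = 1e-12)
})

test_that("run_fclm aggregates counts, is deterministic, and books undetermined quartets", {
  fct <- four_cluster_tree(c(2, 2, 2, 2), internal_length = 0.5)
  mod <- model_gtr(rates = c(1.5, 4, 1, 1.2, 4.5, 1),
                   frequencies = c(.3, .2, .2, .3))
  aln <- simulate_sequences(fct$tree, mod, 1500, seed = 61)
  rep1 <- run_fclm(aln, fct$groups, models = mod, seed = 62)
  expect_identical(rep1$n_quartets_total, 16L)
  expect_identical(sum(rep1$regions$count) + rep1$n_undetermined,
                   rep1$n_quartets_total)
  expect_equal(sum(rep1$regions$proportion), 1, tolerance = 1e-12)
  expect_gt(rep1$regions$proportion[rep1$regions$region == "C1"], 0.9)
  # byte-identical rerun under the same seed
  rep2 <- run_fclm(aln, fct$groups, models = mod, seed = 62)
  expect_identical(rep1, rep2)
  expect_s3_class(tidy(rep1), "tbl_df")
  expect_s3_class(autoplot(rep1), "ggplot")

  # a quartet member with no data anywhere -> undetermined bookkeeping
  m <- aln$matrix
  m["G1_t01", ] <- "-"
  aln2 <- phylo_alignment(m, "nucleotide")
  rep3 <- run_fclm(aln2, fct$groups, models = mod, seed = 62)
  expect_identical(rep3$n_undetermined, 8L)
  expect_equal(sum(rep3$regions$proportion), 1, tolerance = 1e-12)

  bad <- taxon_groups(list(a = "G1_t01", b = "G2_t01", c = "G3_t01",
                           d = "absent_taxon"))
  expect_error(run_fclm(aln, bad, models = mod), "absent_taxon")
})

test_that("region proportions are invariant to quartet enumeration order", {
  fct <- four_cluster_tree(c(2, 2, 2, 2), internal_length = 0.4)
  mod <- model_gtr(rates = c(2, 3, 1, 1, 3, 1), frequencies = rep(0.25, 4))
  aln <- simulate_sequences(fct$tree, mod, 800, seed = 63)
  rep1 <- run_fclm(aln, fct$groups, models = mod)
  rev_groups <- taxon_groups(lapply(fct$groups$groups, rev))
  rep2 <- run_fclm(aln, rev_groups, models = mod)
  expect_identical(rep1$regions, rep2$regions)
})

test_that("swapping groups permutes corners consistently with the topology map", {
  fct <- four_cluster_tree(c(2, 2, 2, 2), internal_length = 0.5)
  mod <- model_gtr(rates = c(1.5, 4, 1, 1.2, 4.5, 1),
                   frequencies = c(.3, .2, .2, .3))
  aln <- simulate_sequences(fct$tree, mod, 1500, seed = 64)
  rep1 <- run_fclm(aln, fct$groups, models = mod)
  # swapping groups 2 and 3 exchanges T1 and T2, hence C1 and C2
  g23 <- taxon_groups(fct$groups$groups[c(1, 3, 2, 4)])
  rep23 <- run_fclm(aln, g23, models = mod)
  p <- function(r, reg) r$regions$proportion[r$regions$region == reg]
  expect_equal(p(rep23, "C2"), p(rep1, "C1"))
  # swapping groups 3 and 4 preserves the T1 split, hence C1
  g34 <- taxon_groups(fct$groups$groups[c(1, 2, 4, 3)])
  rep34 <- run_fclm(aln, g34, models = mod)
  expect_equal(p(rep34, "C1"), p(rep1, "C1"))
})

test_that("corrected support floors at zero and validates inputs", {
  fct <- four_cluster_tree(c(2, 2, 2, 2), internal_length = 0.5)
  mod <- model_gtr(rates = c(1.5, 4, 1, 1.2, 4.5, 1),
                   frequencies = c(.3, .2, .2, .3))
  aln <- simulate_sequences(fct$tree, mod, 1200, seed = 65)
  orig <- run_fclm(aln, fct$groups, models = mod)
  # null correction: comparing a report against itself leaves nothing
  self_corr <- corrected_support(orig, orig)
  expect_true(all(self_corr$corrected == 0))
  # an all-zero permuted report leaves the original untouched
  null_rep <- orig
  null_rep$matrix_label <- "scheme_II"
  null_rep$regions$proportion <- rep(0, 7)
  corr <- corrected_support(orig, null_rep)
  expect_equal(corr$corrected, corr$original)
  expect_identical(attr(corr, "argmax_before"), "C1")
  # subtraction and flooring per region
  null_rep$regions$proportion <- c(0.2, 0.9, 0, 0, 0, 0, 0)
  corr2 <- corrected_support(orig, null_rep)
  expect_equal(corr2$corrected[1],
               max(0, corr2$original[1] - 0.2))
  expect_identical(corr2$corrected[2], 0)

  other <- orig
  other$hypothesis <- "different"
  expect_error(corrected_support(orig, other), "different hypotheses")
  short <- orig
  short$n_quartets_total <- 3L
  expect_error(corrected_support(orig, short), "quartet counts")
})
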