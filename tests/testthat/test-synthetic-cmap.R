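small_cfg <- function(...) {
  synthetic_config(n_genes = 300, n_compounds = 20,
                   instances_per_compound = 2, signature_sizes = c(20, 20),
                   n_background_sets = 20, background_set_size = 40, ...)
}

test_that("config invariants are enforced before generation", {
  expect_error(synthetic_config(n_genes = 50), "n_genes")
  expect_error(synthetic_config(n_compounds = 5), "n_compounds")
  expect_error(synthetic_config(mimic_fraction = 0.7,
                                antimimic_fraction = 0.5), "fraction")
  expect_error(synthetic_config(effect_size = -1), "effect_size")
  expect_error(synthetic_config(n_genes = 100,
                                signature_sizes = c(60, 60)), "exceeds")
  expect_error(synthetic_config(n_genes = 100, background_set_size = 200),
               "background_set_size")
})

test_that("generation is bit-identical for a repeated seed", {
  a <- simulate_compendium(small_cfg(seed = 77))
  b <- simulate_compendium(small_cfg(seed = 77))
  expect_identical(a$rank_matrix$ranks, b$rank_matrix$ranks)
  expect_identical(a$signature, b$signature)
  expect_identical(unclass(a$background), unclass(b$background))
  expect_identical(a$truth$labels, b$truth$labels)
  c <- simulate_compendium(small_cfg(seed = 78))
  expect_false(identical(a$rank_matrix$ranks, c$rank_matrix$ranks))
})

test_that("labels follow the configured fractions and planted tags the universe", {
  sim <- simulate_compendium(small_cfg(mimic_fraction = 0.2,
                                       antimimic_fraction = 0.1, seed = 8))
  expect_equal(sum(sim$truth$labels == "mimic"), 4)
  expect_equal(sum(sim$truth$labels == "antimimic"), 2)
  tags <- c(sim$signature$up_tags, sim$signature$down_tags)
  expect_equal(anyDuplicated(tags), 0L)
  expect_true(all(tags %in% sim$rank_matrix$universe))

  none <- simulate_compendium(small_cfg(mimic_fraction = 0, seed = 8))
  expect_false(any(none$truth$labels == "mimic"))
})

test_that("zero effect size makes planted compounds statistically null", {
  sim <- simulate_compendium(small_cfg(effect_size = 0, mimic_fraction = 0.5,
                                       seed = 13))
  sc <- score_instances(sim$signature, sim$rank_matrix)
  mimic_inst <- sc$compound %in%
    names(sim$truth$labels)[sim$truth$labels == "mimic"]
  m <- mean(sc$scaled_score[mimic_inst])
  se <- stats::sd(sc$scaled_score[mimic_inst]) / sqrt(sum(mimic_inst))
  expect_lt(abs(m), 3 * se + 0.05)
})

test_that("an extreme effect drives tag blocks to the ranking extremes", {
  cfg <- synthetic_config(n_genes = 1000, n_compounds = 10,
                          instances_per_compound = 2, effect_size = 10,
                          mimic_fraction = 0.3, antimimic_fraction = 0,
                          signature_sizes = c(50, 50),
                          n_background_sets = 20, seed = 1)
  sim <- simulate_compendium(cfg)
  sc <- score_instances(sim$signature, sim$rank_matrix)
  mimic_inst <- sc$compound %in%
    names(sim$truth$labels)[sim$truth$labels == "mimic"]
  expect_true(all(sc$ks_up[mimic_inst] >= 0.9))
  expect_true(all(sc$ks_down[mimic_inst] <= -0.9))
})

test_that("hard mode plants exact extreme blocks", {
  cfg <- small_cfg(mode = "hard", mimic_fraction = 0.2, seed = 2)
  sim <- simulate_compendium(cfg)
  sc <- score_instances(sim$signature, sim$rank_matrix)
  mimics <- names(sim$truth$labels)[sim$truth$labels == "mimic"]
  i <- which(sc$compound %in% mimics)[1]
  n <- nrow(sim$rank_matrix$ranks)
  up_ranks <- sim$rank_matrix$ranks[sim$signature$up_tags, i]
  dn_ranks <- sim$rank_matrix$ranks[sim$signature$down_tags, i]
  expect_setequal(sort(up_ranks), seq_len(20))
  expect_setequal(sort(dn_ranks), (n - 19):n)
})

test_that("mean planted connectivity is monotone in effect size", {
  lambdas <- c(0, 0.5, 1, 2, 4)
  mean_abs <- vapply(lambdas, function(l) {
    sim <- simulate_compendium(small_cfg(effect_size = l,
                                         mimic_fraction = 0.3, seed = 55))
    sc <- score_instances(sim$signature, sim$rank_matrix)
    mim <- sc$compound %in%
      names(sim$truth$labels)[sim$truth$labels == "mimic"]
    mean(abs(sc$raw_score[mim]))   # raw: scaling renormalises per run
  }, numeric(1))
  expect_true(all(diff(mean_abs) > -0.02))
  expect_gt(mean_abs[5], mean_abs[1] + 0.3)
})

test_that("null compounds' scores are symmetric about zero", {
  sim <- simulate_compendium(synthetic_config(
    n_genes = 500, n_compounds = 100, instances_per_compound = 2,
    mimic_fraction = 0, antimimic_fraction = 0,
    n_background_sets = 20, background_set_size = 50, seed = 29))
  sc <- score_instances(sim$signature, sim$rank_matrix)
  nz <- sc$scaled_score[sc$scaled_score != 0]
  bt <- stats::binom.test(sum(nz > 0), length(nz), p = 0.5)
  expect_gt(bt$p.value, 0.01)
})

test_that("recovery metrics behave on perfect and degenerate orderings", {
  labels <- c(a = "mimic", b = "mimic", c = "null", d = "null", e = "antimimic")
  truth <- structure(list(labels = labels, signature = NULL, config = NULL),
                     class = "synthetic_truth")
  report <- data.frame(compound = c("a", "b", "e", "c", "d"),
                       direction = c(1, 1, -1, 0, 0))
  m <- truth_recovery_report(report, truth, k = 2)
  expect_equal(m$recall_at_k, 1.0)
  expect_equal(m$precision_at_k, 1.0)
  expect_equal(m$direction_accuracy, 1.0)

  worst <- data.frame(compound = c("c", "d", "e", "a", "b"),
                      direction = c(0, 0, 1, -1, -1))
  w <- truth_recovery_report(worst, truth, k = 2)
  expect_equal(w$recall_at_k, 0.0)
  expect_equal(w$direction_accuracy, 0.0)

  expect_error(truth_recovery_report(report, truth, k = 6), "exceeds")
  expect_error(truth_recovery_report(report[1:3, ], truth, 2),
               "different compounds")
})

test_that("instance count ranges are honoured per compound", {
  cfg <- small_cfg(seed = 3)
  cfg$instances_per_compound <- c(1L, 4L)
  sim <- simulate_compendium(cfg)
  counts <- table(sim$rank_matrix$meta$compound)
  expect_true(all(counts >= 1 & counts <= 4))
  expect_gt(length(unique(as.integer(counts))), 1)
})
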