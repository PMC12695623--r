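test_that("summarize_compound computes mean, spread, count and direction", {
  s <- summarize_compound(c(0.9, 0.8, 0.7))
  expect_equal(s$mean_score, 0.8)
  expect_equal(s$instance_count, 3L)
  expect_equal(s$sd_score, stats::sd(c(0.9, 0.8, 0.7)))
  expect_equal(s$direction, 1)

  s1 <- summarize_compound(0.5)
  expect_equal(s1$mean_score, 0.5)
  expect_identical(s1$sd_score, 0)
  expect_equal(s1$instance_count, 1L)

  s0 <- summarize_compound(c(0.6, -0.6))
  expect_equal(s0$mean_score, 0)
  expect_equal(s0$direction, 0)

  expect_error(summarize_compound(numeric(0)), "no instances")
})

test_that("non_null_ratio counts majority-sign instances over all instances", {
  expect_equal(non_null_ratio(c(0.8, 0.6, -0.1, 0),
                              c(FALSE, FALSE, FALSE, TRUE)), 0.5)
  expect_equal(non_null_ratio(c(0.3, 0.4, 0.5), rep(FALSE, 3)), 1.0)
  expect_equal(non_null_ratio(c(0, 0), c(TRUE, TRUE)), 0.0)
  # negative majority
  expect_equal(non_null_ratio(c(-0.8, -0.6, 0.1), rep(FALSE, 3)), 2 / 3)
  # exactly tied non-null sum with zero mean: no majority
  expect_equal(non_null_ratio(c(0.5, -0.5), c(FALSE, FALSE)), 0)
})

test_that("permutation p-value has the pseudo-counted two-sided form", {
  pool <- c(stats::rnorm(100, sd = 0.1))
  # observed mean beyond every resample: floor 1/(B+1)
  p <- permutation_pvalue(5, 3, pool, B = 999, seed = 1)
  expect_equal(p, 1 / 1000)
  # observed mean 0: every resample qualifies
  p0 <- permutation_pvalue(0, 3, pool, B = 200, seed = 1)
  expect_equal(p0, 1.0)
  expect_error(permutation_pvalue(0.5, 200, pool[1:10], B = 100, seed = 1),
               "pool smaller")
  expect_error(permutation_pvalue(0.5, 3, pool, B = 10, seed = 1))
})

test_that("permutation p-value matches exhaustive enumeration on a tiny pool", {
  # pool {-1, 1}, n = 2: the only size-2 resample is the whole pool, mean 0
  pool <- c(-1, 1)
  for (obs in c(0, 0.4)) {
    p <- permutation_pvalue(obs, 2, pool, B = 500, seed = 3)
    enumerated <- mean(abs(0) >= abs(obs))   # single possible resample
    expect_equal(p, (1 + 500 * enumerated) / 501)
  }
  expect_identical(permutation_pvalue(0.2, 2, pool, B = 100, seed = 9),
                   permutation_pvalue(0.2, 2, pool, B = 100, seed = 9))
})

test_that("bh_fdr reproduces the step-up adjustment", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.05), 0.05)
  expect_error(bh_fdr(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\(0, 1\\]")
})

test_that("bh_fdr matches a brute-force oracle on random vectors", {
  set.seed(17)
  for (rep in 1:50) {
    p <- stats::runif(5)
    expect_equal(bh_fdr(p), bh_oracle(p))
    # order preserved against input: permuting input permutes output
    perm <- sample.int(5)
    expect_equal(bh_fdr(p[perm]), bh_oracle(p)[perm])
  }
  # sorted by input p, adjusted values are monotone non-decreasing
  p <- stats::runif(20)
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("specificity_score counts background exceedances", {
  expect_equal(specificity_score(0.9, c(0.1, -0.2, 0.3)), 1.0)
  expect_equal(specificity_score(0, c(0.1, -0.2, 0.3)), 0.0)
  bg <- c(0.9, -0.8, 0.7, 0.1, 0.2, 0.1, 0.05, -0.1, 0.15, 0.3)
  expect_equal(specificity_score(0.5, bg), 0.7)
  expect_error(specificity_score(0.5, numeric(0)), "no background")
})

test_that("surrogate signatures respect sizes, disjointness and thresholds", {
  universe <- paste0("g", 1:300)
  sets <- lapply(1:25, function(i) sample(universe, 40))
  names(sets) <- paste0("s", 1:25)
  col <- gene_set_collection(sets)
  surr <- make_surrogate_signatures(col, c(10, 15), universe, seed = 4)
  expect_length(surr, 25)
  for (s in surr) {
    expect_lte(length(s$up_tags), 10)
    expect_lte(length(s$down_tags), 15)
    expect_length(intersect(s$up_tags, s$down_tags), 0)
    expect_true(all(c(s$up_tags, s$down_tags) %in% universe))
  }
  # deterministic given seed
  surr2 <- make_surrogate_signatures(col, c(10, 15), universe, seed = 4)
  expect_identical(surr, surr2)

  # sets shrunken below 5 matched genes are dropped; < 20 usable is an error
  sets_small <- c(sets, list(tiny = c("zzz1", "zzz2")))
  expect_warning(
    make_surrogate_signatures(gene_set_collection(sets_small), c(10, 10),
                              universe, seed = 1),
    "dropped")
  expect_error(
    suppressWarnings(make_surrogate_signatures(
      gene_set_collection(sets[1:10]), c(10, 10), universe, seed = 1)),
    ">= 20 usable")
})

test_that("reliability_score is the stated convex combination", {
  expect_equal(reliability_score(1, 1e-12, 1e-12, 4, 1, 1), 1,
               tolerance = 1e-9)
  expect_equal(reliability_score(0.8, 1e-12, 1e-12, 4, 1, 1), 29 / 30,
               tolerance = 1e-9)
  expect_equal(reliability_score(0, 1, 1, 4, 0, 0), 1 / 6)
  expect_error(reliability_score(0.5, 0.5, 0.5, 2, 0.5, 0.5,
                                 weights = rep(0.2, 6)), "sum to 1")
  # instance count saturates at n_cap
  expect_equal(reliability_score(0, 1, 1, 40, 0, 0),
               reliability_score(0, 1, 1, 4, 0, 0))
})

test_that("reliability_score is monotone in every component", {
  base <- list(mean_score = 0.5, p_value = 0.4, fdr = 0.6,
               instance_count = 2, non_null = 0.5, specificity = 0.5)
  r0 <- do.call(reliability_score, base)
  bumps <- list(mean_score = 0.7, p_value = 0.2, fdr = 0.3,
                instance_count = 3, non_null = 0.8, specificity = 0.9)
  for (comp in names(bumps)) {
    args <- base
    args[[comp]] <- bumps[[comp]]
    expect_gt(do.call(reliability_score, args), r0)
  }
})

test_that("rank_compounds sorts with deterministic tie-breaks", {
  tab <- data.frame(compound = c("b", "a", "c"),
                    mean_score = c(0.5, -0.8, 0.2),
                    reliability = c(0.9, 0.9, 0.3),
                    stringsAsFactors = FALSE)
  out <- rank_compounds(tab)
  expect_equal(out$compound, c("a", "b", "c"))   # |mean| breaks the 0.9 tie
  expect_equal(out$rank, 1:3)
  tie <- data.frame(compound = c("z", "y"), mean_score = c(0.5, 0.5),
                    reliability = c(0.7, 0.7))
  expect_equal(rank_compounds(tie)$compound, c("y", "z"))
  expect_equal(rank_compounds(tab[1, ])$compound, "b")
  expect_error(rank_compounds(tab[0, ]), "no compounds")
})

test_that("anti-mimics mirror mimics: direction flips, magnitude is preserved", {
  cfg_m <- synthetic_config(n_genes = 500, n_compounds = 40,
                            mimic_fraction = 0.25, antimimic_fraction = 0.25,
                            n_background_sets = 20, background_set_size = 50,
                            seed = 31)
  sim <- simulate_compendium(cfg_m)
  sc <- score_instances(sim$signature, sim$rank_matrix)
  grp <- split(sc$scaled_score, sc$compound)
  means <- vapply(grp, mean, numeric(1))
  mimic_means <- means[names(sim$truth$labels)[sim$truth$labels == "mimic"]]
  anti_means <- means[names(sim$truth$labels)[sim$truth$labels == "antimimic"]]
  expect_true(all(mimic_means > 0))
  expect_true(all(anti_means < 0))
  expect_equal(mean(abs(mimic_means)), mean(abs(anti_means)), tolerance = 0.1)
})
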