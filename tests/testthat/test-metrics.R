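test_that("MER, MAR, AMDR and energy density match hand-computed values", {
  lim <- c(sodium = 100, sat_fat = 10)
  expect_equal(mer(c(sodium = 100, sat_fat = 10), lim), 1.0)
  expect_equal(mer(c(sodium = 50, sat_fat = 15), lim), 1.0)   # (0.5 + 1.5)/2
  expect_equal(mer(c(sodium = 0, sat_fat = 0), lim), 0.0)

  micros <- micro_nutrients()
  rdis <- stats::setNames(rep(10, 11), micros)
  expect_equal(mar(stats::setNames(rep(100, 11), micros), rdis), 1.0)  # capped
  expect_equal(mar(stats::setNames(rep(5, 11), micros), rdis), 0.5)
  I <- stats::setNames(rep(10, 11), micros); I[[micros[4]]] <- 0
  expect_equal(mar(I, rdis), 10 / 11)
  expect_error(mar(I[-1], rdis), micros[1])

  expect_equal(amdr_composite(c(protein = 20, fat = 30, carbohydrate = 50)), 1)
  expect_equal(amdr_composite(c(protein = 5, fat = 30, carbohydrate = 65)), 2 / 3)
  expect_equal(amdr_composite(c(protein = 10, fat = 20, carbohydrate = 45)), 1)

  expect_equal(energy_density(500, 400), 1.25)
  expect_equal(energy_density(0, 100), 0)
  expect_equal(energy_density(800, 640), 1.25)
  expect_error(energy_density(500, 0), "positive")
})

test_that("Hill diversity: closed forms, limits and validation", {
  expect_equal(hill_diversity(rep(0.25, 4), q = 1), 4)
  expect_equal(hill_diversity(1, q = 1), 1)
  expect_equal(hill_diversity(c(1, 0, 0), q = 2), 1)
  expect_equal(hill_diversity(c(0.5, 0.25, 0.25), q = 1), exp(1.5 * log(2)),
               tolerance = 1e-12)
  # continuity at q -> 1
  set.seed(5)
  for (i in 1:10) {
    p <- runif(4); p <- p / sum(p)
    expect_lt(abs(hill_diversity(p, 0.999) - hill_diversity(p, 1)), 1e-3)
  }
  expect_error(hill_diversity(c(0.5, 0.4)), "sum to 1")
  expect_error(hill_diversity(c(1.2, -0.2)), "negative")
})

test_that("bootstrap CI: degenerate and coverage behaviour", {
  ci <- bootstrap_ci(rep(3, 50), mean, seed = 1)
  expect_equal(unname(ci["lower"]), 3)
  expect_equal(unname(ci["upper"]), 3)                 # zero width
  set.seed(2)
  x <- rnorm(100)
  ci2 <- bootstrap_ci(x, mean, seed = 3)
  expect_true(ci2["lower"] <= ci2["estimate"] && ci2["estimate"] <= ci2["upper"])
  # coverage: CI for the mean of N(0,1), n = 200, covers 0 >= 90% of runs
  covered <- vapply(1:100, function(r) {
    y <- with_seed_test(r, rnorm(200))
    ci <- bootstrap_ci(y, mean, n_boot = 400, seed = r + 1000)
    ci["lower"] <= 0 && 0 <= ci["upper"]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("generated-vs-real comparison reports reductions and improvements", {
  real <- data.frame(rdi_deviation = rep(c(0.4, 0.8), each = 30),
                     cluster = rep(c("a", "b"), each = 30))
  # identical sets: 0% reduction, nothing improves
  same <- compare_generated_vs_real(real, real, n_boot = 200, seed = 1)
  expect_true(all(abs(same$by_cluster$pct_reduction) < 1e-9))
  expect_false(any(same$by_cluster$improved))
  # deviations exactly halved: 50% reduction everywhere, flagged improved
  gen <- real; gen$rdi_deviation <- real$rdi_deviation / 2
  half <- compare_generated_vs_real(gen, real, n_boot = 200, seed = 2)
  expect_equal(half$by_cluster$pct_reduction, c(50, 50))
  expect_true(all(half$by_cluster$improved))
  expect_equal(unname(half$overall["median_pct_reduction"]), 50)
  # clusters present on one side only are skipped with a warning
  gen2 <- rbind(gen, data.frame(rdi_deviation = 0.1, cluster = "c"))
  expect_warning(compare_generated_vs_real(gen2, real, n_boot = 200, seed = 3),
                 "one set only")
})

test_that("cross-validation folds partition, stratify and reproduce", {
  ids <- sprintf("m%03d", 1:100)
  cl <- rep(1:2, each = 50)
  mt <- rep(c("breakfast", "lunch"), 50)
  f1 <- crossval_folds(ids, cl, mt, k = 5, seed = 4)
  f2 <- crossval_folds(ids, cl, mt, k = 5, seed = 4)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:5)
  expect_equal(as.integer(table(f1)), rep(20L, 5))     # folds of 20, disjoint
  # stratification: per-fold cluster proportions within one meal of global
  for (k in 1:5) {
    tab <- table(cl[f1 == k])
    expect_true(all(abs(tab - 10) <= 1))
  }
  expect_warning(crossval_folds(ids[1:6], c(rep(1, 4), 2, 2),
                                rep("lunch", 6), k = 5, seed = 1),
                 "smaller than k")
})

test_that("the cross-validation harness trains per fold and reports held-out F1", {
  sc <- tiny_scene()
  idx <- mealforge:::meal_index(sc$corpus)
  cl <- stats::setNames(idx$true_archetype, idx$meal_id)
  cfg <- cvae_config(hidden = 32, latent_dim = 8, epochs = 8, seed = 2)
  cv <- crossval_harness(sc$corpus, sc$catalog, cl, k = 3, seed = 5,
                         config = cfg)
  expect_equal(nrow(cv), 3)
  expect_equal(sum(cv$n_test), length(cl))
  expect_true(all(cv$f1_holdout >= 0 & cv$f1_holdout <= 1))
  expect_true(all(cv$n_train + cv$n_test == length(cl)))
})

test_that("the per-meal metric report is internally consistent", {
  sc <- tiny_scene()
  sub <- sc$corpus[sc$corpus$meal_id %in% unique(sc$corpus$meal_id)[1:30], ]
  class(sub) <- c("meal_corpus", "data.frame")
  rep1 <- metric_report(sub, sc$catalog)
  expect_equal(nrow(rep1), 30)
  expect_true(all(rep1$mar >= 0 & rep1$mar <= 1))
  expect_true(all(rep1$amdr %in% c(0, 1 / 3, 2 / 3, 1)))
  expect_true(all(rep1$diversity >= 1))
  expect_true(all(rep1$energy_density > 0))
  # pure function: identical calls agree
  expect_identical(rep1, metric_report(sub, sc$catalog))
})
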