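test_that("per-meal targets scale the daily references by the meal share", {
  rdi <- default_rdi_table()
  tg <- per_meal_targets(rdi, "dinner")
  expect_equal(tg$energy_kcal, 800)                   # 40% of 2,000
  tb <- per_meal_targets(rdi, "breakfast")
  expect_equal(unname(tb$rdi[["vit_c"]]), 0.25 * 90)  # 22.5
  sh <- meal_shares()
  expect_equal(sum(sh) * 2000, 2000)
  expect_error(per_meal_targets(rdi, "brunch"), "unknown meal type")
})

test_that("portion initialization jitters around serving sizes", {
  sv <- structure(c(A = 30, B = 100), default = 100)
  g0 <- init_portions(c("A", "B"), sv, jitter_frac = 0, seed = 1)
  expect_equal(unname(g0), c(30, 100))
  g1 <- init_portions(rep("A", 50), sv, jitter_frac = 0.1, seed = 2)
  expect_true(all(g1 >= 27 & g1 <= 33))
  expect_identical(init_portions("B", sv, seed = 5), init_portions("B", sv, seed = 5))
  # unknown food falls back to the default serving
  expect_equal(unname(init_portions("C", sv, jitter_frac = 0, seed = 1)), 100)
})

test_that("the signed-log2 objective matches closed forms", {
  dens <- matrix(c(0.1, 0.2), 1, 2,
                 dimnames = list("X", c("protein", "sodium")))
  targets <- list(rdi = c(protein = 10), limit = c(sodium = 10),
                  energy_kcal = 500)
  cfg <- portion_config(under_weight = 2, over_weight = 2)
  # intakes exactly on target -> 0 (sodium at limit contributes 0, not over)
  expect_equal(portion_objective(c(X = 100), dens[, "protein", drop = FALSE],
                                 list(rdi = c(protein = 10), limit = numeric(0),
                                      energy_kcal = 1), cfg), 0)
  # one nutrient at double target, weight 1 -> contribution 1
  cfg1 <- portion_config(under_weight = 1, over_weight = 1, base_weight = 1)
  expect_equal(portion_objective(c(X = 200), dens[, "protein", drop = FALSE],
                                 list(rdi = c(protein = 10), limit = numeric(0),
                                      energy_kcal = 1), cfg1), 1)
  # protein at a quarter of target with under-weight 2 -> 2 * |log2(1/4)| = 4
  expect_equal(portion_objective(c(X = 25), dens[, "protein", drop = FALSE],
                                 list(rdi = c(protein = 10), limit = numeric(0),
                                      energy_kcal = 1), cfg), 4)
  # sodium below its limit contributes nothing
  expect_equal(portion_objective(c(X = 25), dens,
                                 list(rdi = c(protein = 10), limit = c(sodium = 100),
                                      energy_kcal = 1), cfg), 4)
})

test_that("energy retargeting: a single 2 kcal/g food lands at the share target", {
  cat1 <- hand_catalog("E2", "grains", energy = 2, protein = 0.05,
                       fat = 0.02, carbohydrate = 0.4)
  s <- optimize_portions("E2", cat1, "breakfast", seed = 1)
  expect_equal(unname(s$grams[["E2"]]), 250, tolerance = 1e-6)  # 500 kcal / 2
  expect_equal(unname(s$energy_kcal), 500, tolerance = 0.01)
})

test_that("constraint pipeline bounds hold on seeded synthetic meals", {
  sc <- tiny_scene()
  meals <- split(as.data.frame(sc$corpus), sc$corpus$meal_id)
  set.seed(14)
  pick <- meals[sample(length(meals), 25)]
  dens <- catalog_density_matrix(sc$catalog)
  for (i in seq_along(pick)) {
    m <- pick[[i]]
    s <- optimize_portions(m$food_code, sc$catalog, m$meal_type[1], seed = i)
    expect_gte(min(s$grams), 5)
    expect_lte(sum(s$grams), 900 + 1e-6)
    is_bev <- sc$catalog$is_beverage[match(m$food_code, sc$catalog$code)]
    bev_k <- sum(s$grams[is_bev] * dens[m$food_code[is_bev], "energy_kcal"])
    tot_k <- s$energy_kcal
    if (tot_k > 0 && !"beverage" %in% s$violated)
      expect_lte(bev_k, 0.25 * tot_k + 1e-6)
    if (s$feasible)
      expect_lte(abs(s$energy_kcal - s$targets$energy_kcal) /
                   s$targets$energy_kcal, 0.01 + 1e-9)
  }
})

test_that("the optimizer improves on its initialization", {
  sc <- tiny_scene()
  set.seed(15)
  for (i in 1:20) {
    foods <- sample(sc$catalog$code, sample(2:5, 1))
    mt <- sample(c("breakfast", "lunch", "dinner"), 1)
    s <- optimize_portions(foods, sc$catalog, mt, seed = i,
                           apply_constraints = FALSE)
    expect_lte(s$objective, s$init_objective + 1e-9)
  }
})

test_that("beverage-only meals are flagged infeasible, not silently wrong", {
  sc <- tiny_scene()
  bevs <- sc$catalog$code[sc$catalog$is_beverage][1]
  s <- optimize_portions(bevs, sc$catalog, "dinner", seed = 1)
  expect_false(s$feasible)
  expect_true(length(s$violated) >= 1)
})

test_that("RDI deviation uses upper-bound-only semantics for limit nutrients", {
  targets <- list(rdi = stats::setNames(rep(10, 9), paste0("n", 1:9)),
                  limit = c(sodium = 100), energy_kcal = 1)
  I <- c(stats::setNames(rep(10, 9), paste0("n", 1:9)), sodium = 50)
  expect_equal(as.numeric(rdi_deviation(I, targets)), 0)
  I2 <- I; I2[["n1"]] <- 15    # one adequacy nutrient at 150%, scope of 10
  expect_equal(as.numeric(rdi_deviation(I2, targets)), 0.05)
  I3 <- I; I3[["sodium"]] <- 150
  expect_equal(as.numeric(rdi_deviation(I3, targets)), 0.05)
})

test_that("1-2 item portions are near the 1 g grid-search optimum", {
  sc <- tiny_scene()
  targets_for <- function(mt) per_meal_targets(default_rdi_table(), mt)
  dens <- catalog_density_matrix(sc$catalog)
  cfg <- portion_config()
  set.seed(16)
  for (rep in 1:6) {
    k <- sample(1:2, 1)
    foods <- sample(sc$catalog$code, k)
    mt <- sample(c("breakfast", "lunch", "dinner"), 1)
    tg <- targets_for(mt)
    s <- optimize_portions(foods, sc$catalog, mt, seed = rep,
                           apply_constraints = FALSE)
    best <- grid_best_objective(foods, dens, tg, cfg, step = 1)
    expect_lte(s$objective, best * 1.02 + 1e-9)
  }
})
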