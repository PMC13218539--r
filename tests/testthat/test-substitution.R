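test_that("portion-based pricing follows the published rules", {
  cat <- hand_catalog(c("G1", "S1", "S2", "S3", "U1"),
                      c("grains", "soups", "soups", "soups", "unlisted_cat"),
                      energy = 1.5)
  pr <- pricing_model()
  # one generic (unlisted category) item at 150 g: 3 + 2 overhead
  expect_equal(meal_cost(data.frame(food_code = "U1", grams = 150), cat, pr), 5)
  # empty meal: overhead only
  expect_equal(meal_cost(data.frame(food_code = character(0),
                                    grams = numeric(0)), cat, pr), 2)
  # three full soup bowls, cross-item cap 1: exactly one bowl billed
  soup <- data.frame(food_code = c("S1", "S2", "S3"), grams = rep(300, 3))
  expect_equal(meal_cost(soup, cat, pr),
               1 * pr$categories$soups$price_per_portion + 2)
  # monotone nondecreasing in grams
  g1 <- meal_cost(data.frame(food_code = "G1", grams = 100), cat, pr)
  g2 <- meal_cost(data.frame(food_code = "G1", grams = 200), cat, pr)
  expect_gte(g2, g1)
  expect_error(meal_cost(data.frame(food_code = "G1", grams = -5), cat, pr),
               "negative grams")
})

test_that("hop counts are max set-difference sizes", {
  expect_equal(hop_count(c("A", "B"), c("A", "B")), 0)
  expect_equal(hop_count(c("A", "B", "C"), c("A", "B", "D")), 1)
  expect_equal(hop_count(c("A", "B"), c("A", "C", "D")), 2)
  expect_equal(hop_count("A", c("A", "B")), 1)  # unpaired add counts once
})

test_that("nutrition gain is the percent reduction in mean RDI deviation", {
  targets <- list(rdi = c(protein = 10, fiber = 5), limit = c(sodium = 100),
                  energy_kcal = 1)
  orig <- c(protein = 5, fiber = 5, sodium = 50)      # dev = (0.5 + 0)/3
  expect_equal(nutrition_gain(orig, orig, targets), 0)
  cand <- c(protein = 7.5, fiber = 5, sodium = 50)    # dev halves
  expect_equal(nutrition_gain(orig, cand, targets), 50)
  perfect <- c(protein = 10, fiber = 5, sodium = 100)
  expect_true(is.na(nutrition_gain(perfect, cand, targets)))
})

test_that("candidate search equals an exhaustive filter on a toy corpus", {
  sc <- tiny_scene()
  meals <- split(as.data.frame(sc$corpus), sc$corpus$meal_id)
  real <- do.call(rbind, meals[1:20])
  class(real) <- c("meal_corpus", "data.frame")
  m0 <- meals[[21]]
  sol <- optimize_portions(m0$food_code, sc$catalog, m0$meal_type[1], seed = 2)
  cands <- find_candidates(sol, real, sc$catalog, include_swaps = FALSE,
                           energy_tol = 0.5, count_tol = 2, max_hops = 5)
  # independent brute force over all real meals of the meal type
  dens <- catalog_density_matrix(sc$catalog)
  expected <- character(0)
  for (m in split(as.data.frame(real), real$meal_id)) {
    if (m$meal_type[1] != sol$meal_type) next
    k <- hop_count(sol$foods, m$food_code)
    if (k < 1 || k > 5) next
    tot <- as.numeric(m$grams %*% dens[m$food_code, , drop = FALSE])
    names(tot) <- colnames(dens)
    if (abs(tot[["energy_kcal"]] - sol$energy_kcal) / sol$energy_kcal > 0.5) next
    if (abs(nrow(m) - length(sol$foods)) > 2) next
    d0 <- as.numeric(rdi_deviation(sol$totals,
                                   per_meal_targets(default_rdi_table(), sol$meal_type)))
    if (d0 == 0) next
    expected <- c(expected, m$meal_id[1])
  }
  expect_setequal(cands$candidate_id[cands$source == "real"], expected)
  # the generated meal itself (k = 0) is never a candidate
  real2 <- rbind(real,
                 data.frame(meal_id = "SELF", meal_type = sol$meal_type,
                            food_code = sol$foods, grams = as.numeric(sol$grams),
                            true_archetype = NA_integer_))
  class(real2) <- c("meal_corpus", "data.frame")
  c2 <- find_candidates(sol, real2, sc$catalog, include_swaps = FALSE,
                        energy_tol = 0.5, count_tol = 2)
  expect_false("SELF" %in% c2$candidate_id)
})

test_that("selection maximizes the theta-scalarized score under filters", {
  cands <- data.frame(
    candidate_id = c("c1", "c2", "c3", "c4", "c5"),
    source = "real", k = c(1, 2, 1, 3, 2),
    gain_pct = c(10, 18, 6, 25, 18),
    cost = c(12, 9, 7, 15, 9),
    cost_delta = c(2, -1, -3, 5, -1),
    similarity = 0.5, stringsAsFactors = FALSE
  )
  orig_cost <- 10
  # theta = 0: pure nutrition argmax
  w0 <- select_substitution(cands, tradeoff_policy(theta = 0), orig_cost)
  expect_equal(w0$candidate_id, "c4")
  # no-cost-increase: winner must not cost more
  w1 <- select_substitution(cands, tradeoff_policy(theta = 0, no_cost_increase = TRUE),
                            orig_cost)
  expect_lte(w1$cost_delta, 0)
  expect_equal(w1$candidate_id, "c2")  # ties (c2/c5) break on lower k? equal k -> id
  # theta = 1 equals the brute-force argmax of gain + theta * savings%
  w2 <- select_substitution(cands, tradeoff_policy(theta = 1), orig_cost)
  sc <- cands$gain_pct + 1 * 100 * (orig_cost - cands$cost) / orig_cost
  expect_equal(w2$candidate_id, cands$candidate_id[which.max(sc)])
  # budget filter
  w3 <- select_substitution(cands, tradeoff_policy(theta = 0, budget = 8), orig_cost)
  expect_lte(w3$cost, 8)
  expect_null(select_substitution(cands[0, ], tradeoff_policy(), orig_cost))
})

test_that("the frontier reports medians with CIs and a geometric knee", {
  # construct candidate sets whose selected winners are known in closed form
  mk <- function(gain, cost) data.frame(
    candidate_id = sprintf("x%d", seq_along(gain)), source = rep("real", length(gain)),
    k = rep(1, length(gain)), gain_pct = gain, cost = cost, cost_delta = cost - 10,
    similarity = rep(0.5, length(gain)), stringsAsFactors = FALSE)
  sets <- list(
    A = mk(c(20, 10, 2), c(10, 8, 5)),
    B = mk(c(22, 12, 4), c(11, 8, 5)),
    C = mk(numeric(0), numeric(0))        # infeasible meal
  )
  costs <- c(A = 10, B = 10, C = 10)
  th <- c(0, 0.5, 2)
  fr <- frontier(sets, costs, th, n_boot = 100, seed = 3)
  expect_equal(nrow(fr$curve), 3)
  expect_equal(fr$feasibility, 2 / 3)
  # oracle: recompute winners per theta and compare medians
  for (i in seq_along(th)) {
    med <- sapply(c("A", "B"), function(id) {
      cs <- sets[[id]]
      sc <- cs$gain_pct + th[i] * 100 * (10 - cs$cost) / 10
      c(cs$gain_pct[which.max(sc)], 100 * (10 - cs$cost[which.max(sc)]) / 10)
    })
    expect_equal(fr$curve$median_gain[i], stats::median(med[1, ]))
    expect_equal(fr$curve$median_savings[i], stats::median(med[2, ]))
  }
  # knee: brute-force max perpendicular distance to the endpoint chord
  pts <- fr$curve[, c("median_savings", "median_gain")]
  a <- as.numeric(pts[1, ]); b <- as.numeric(pts[3, ])
  ch <- b - a
  d <- abs(ch[1] * (pts[, 2] - a[2]) - ch[2] * (pts[, 1] - a[1])) / sqrt(sum(ch^2))
  expect_equal(fr$knee, which.max(d))
  # single theta: degenerate one-point curve, knee = that point
  fr1 <- frontier(sets, costs, 0.5, n_boot = 100, seed = 4)
  expect_equal(fr1$knee, 1)
})

test_that("category transitions count and normalize as a row-stochastic matrix", {
  cat <- hand_catalog(c("GR1", "GR2", "VE1", "VE2", "DA1"),
                      c("grains", "grains", "vegetables", "vegetables", "dairy"),
                      energy = 1.5)
  # all swaps grain -> vegetable: single cell 1.0
  sw <- data.frame(removed = c("GR1", "GR2"), added = c("VE1", "VE2"),
                   stringsAsFactors = FALSE)
  tm <- transition_matrix(sw, cat)
  expect_equal(tm$matrix["grains", "vegetables"], 1)
  expect_true(all(abs(rowSums(tm$matrix)[rowSums(tm$counts) > 0] - 1) < 1e-12))
  # hand-counted mixed swaps
  sw2 <- data.frame(
    removed = c("GR1", "GR1", "GR2", "VE1", NA),
    added = c("VE1", "VE2", "DA1", "DA1", "GR2"),
    stringsAsFactors = FALSE)
  tm2 <- transition_matrix(sw2, cat)
  expect_equal(unname(tm2$counts["grains", "vegetables"]), 2)
  expect_equal(unname(tm2$counts["grains", "dairy"]), 1)
  expect_equal(unname(tm2$counts["vegetables", "dairy"]), 1)
  expect_equal(unname(tm2$net_adds[["grains"]]), 1)
  # swap pairing: same-category matches first
  pairs <- swap_pairs(c("GR1", "VE1"), c("GR2", "DA1"), cat)
  expect_equal(pairs$added[pairs$removed == "GR1"], "GR2")
})
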