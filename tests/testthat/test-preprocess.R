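test_that("code harmonization renumbers, merges by sum, keeps dropped codes", {
  corp <- hand_corpus(list(
    list(type = "lunch", items = c(A = 50)),
    list(type = "lunch", items = c(A = 50, B = 30)),
    list(type = "dinner", items = c(D = 70, C = 10))
  ))
  mapping <- data.frame(old_code = c("A", "D"),
                        action = c("consolidated", "dropped"),
                        new_code = c("B", NA), stringsAsFactors = FALSE)
  h <- harmonize_codes(corp, mapping)
  expect_equal(h$food_code[h$meal_id == "H001"], "B")
  expect_equal(h$grams[h$meal_id == "H001"], 50)
  m2 <- h[h$meal_id == "H002", ]
  expect_equal(nrow(m2), 1)            # A+B merged
  expect_equal(m2$grams, 80)           # grams summed
  expect_true("D" %in% h$food_code)    # dropped codes kept
  # idempotent after closure
  expect_equal(as.data.frame(harmonize_codes(h, mapping)), as.data.frame(h))
  # chains resolve transitively; cycles are reported
  chain <- data.frame(old_code = c("A", "B"), action = "renumbered",
                      new_code = c("B", "C"), stringsAsFactors = FALSE)
  expect_true(all(harmonize_codes(corp, chain)$food_code != "A"))
  cyc <- data.frame(old_code = c("A", "B"), action = "renumbered",
                    new_code = c("B", "A"), stringsAsFactors = FALSE)
  expect_error(harmonize_codes(corp, cyc), "cycle")
})

test_that("binarization produces presence matrices with counting identities", {
  corp <- hand_corpus(list(
    list(type = "lunch", items = c(A = 50)),
    list(type = "lunch", items = c(A = 20, B = 10)),
    list(type = "dinner", items = c(B = 5))
  ))
  pb <- binarize(corp)
  expect_equal(unname(pb$lunch[, "A"]), c(1L, 1L))
  expect_equal(unname(pb$lunch[, "B"]), c(0L, 1L))
  expect_equal(nrow(pb$lunch), 2)
  # column sums equal per-food meal counts
  for (mt in names(pb)) {
    d <- corp[corp$meal_type == mt, ]
    cnt <- table(factor(d$food_code, colnames(pb[[mt]])))
    expect_equal(unname(colSums(pb[[mt]])), as.integer(cnt))
  }
  expect_true(all(rowSums(do.call(rbind, pb[])) >= 1))
})

test_that("LOF filter removes the planted outlier and exactly round(c*n) meals", {
  set.seed(42)
  x <- matrix(rnorm(99 * 3, sd = 1), 99, 3)
  x <- rbind(x, matrix(100, 1, 3))   # planted point at 100 sigma
  rownames(x) <- sprintf("m%03d", 1:100)
  res <- lof_filter(x, contamination = 0.01)
  expect_equal(res$removed, "m100")
  expect_equal(sort(c(res$retained, res$removed)), sort(rownames(x)))
  # removal count is exact
  set.seed(7)
  y <- matrix(rnorm(1000 * 4), 1000, 4)
  expect_equal(length(lof_filter(y, contamination = 0.003)$removed), 3)
  # tiny contamination with small n removes nothing
  z <- matrix(rnorm(30 * 2), 30, 2)
  expect_equal(length(lof_filter(z, contamination = 0.001)$removed), 0)
  expect_error(lof_filter(y, contamination = 0.7), "invalid argument")
  expect_error(lof_filter(y, contamination = 0), "invalid argument")
})

test_that("prototype aggregation meets thresholds and self-reports honestly", {
  sc <- tiny_scene()
  pm <- aggregate_prototypes(sc$catalog, sc$corpus)
  # independent recomputation of coverage and fidelity from the returned map
  dens <- catalog_density_matrix(sc$catalog)
  w_all <- tapply(sc$corpus$grams, sc$corpus$food_code, sum)
  for (scat in pm$summary$subcategory) {
    a <- pm$assignment[pm$assignment$subcategory == scat, ]
    w <- stats::setNames(rep(0, nrow(a)), a$food)
    w[intersect(names(w_all), a$food)] <- w_all[intersect(names(w_all), a$food)]
    if (sum(w) == 0) w[] <- 1
    w <- w / sum(w)
    sim <- vapply(seq_len(nrow(a)), function(i) {
      x <- dens[a$food[i], ]; y <- dens[a$prototype[i], ]
      sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    }, numeric(1))
    cover <- sum(w[ifelse(a$food == a$prototype, TRUE, sim >= 0.70)])
    tot <- colSums(dens[a$food, , drop = FALSE] * w)
    rec <- colSums(dens[a$prototype, , drop = FALSE] * w)
    keep <- tot > 0
    fid <- mean(abs(tot[keep] - rec[keep]) / tot[keep])
    srow <- pm$summary[pm$summary$subcategory == scat, ]
    expect_equal(srow$fidelity, fid, tolerance = 1e-9)
    expect_gte(cover + 1e-12, 0.90)
    expect_lte(fid, 0.07)
    # assignment similarity floor for reassigned foods
    moved <- a$food != a$prototype
    if (any(moved)) expect_gte(min(sim[moved]), 0.70)
    # prototypes map to themselves
    expect_true(all(a$prototype[a$food %in% a$prototype] ==
                      a$food[a$food %in% a$prototype]))
  }
})

test_that("prototype aggregation degenerate cases", {
  # two identical foods collapse to one prototype with perfect fidelity
  cat2 <- hand_catalog(c("X1", "X2"), c("grains", "grains"), energy = 1.5)
  corp2 <- hand_corpus(list(list(type = "lunch", items = c(X1 = 100, X2 = 50))))
  pm2 <- aggregate_prototypes(cat2, corp2)
  expect_equal(length(unique(pm2$assignment$prototype)), 1)
  expect_equal(pm2$summary$coverage, 1.0)
  expect_equal(pm2$summary$fidelity, 0.0)
  # mutually orthogonal foods: the similarity floor is unreachable, so every
  # food becomes its own prototype
  cat3 <- hand_catalog(c("Y1", "Y2", "Y3"), rep("dairy", 3), energy = 0,
                       protein = 0, fat = 0, carbohydrate = 0, fiber = 0)
  for (nm in c(micro_nutrients(), limit_nutrients())) cat3[[nm]] <- 0
  cat3$calcium <- c(1, 0, 0); cat3$iron <- c(0, 1, 0); cat3$zinc <- c(0, 0, 1)
  corp3 <- hand_corpus(list(list(type = "lunch", items = c(Y1 = 10, Y2 = 10, Y3 = 10))))
  pm3 <- aggregate_prototypes(cat3, corp3)
  expect_true(all(pm3$assignment$prototype == pm3$assignment$food))
})

test_that("bootstrap ingredient filter keeps ubiquitous foods, drops absent and singleton foods", {
  set.seed(1)
  n <- 1000
  m <- cbind(
    always = rep(1L, n),
    never = rep(0L, n),
    once = c(1L, rep(0L, n - 1)),
    common = rbinom(n, 1, 0.3)
  )
  res <- bootstrap_ingredient_filter(m, n_boot = 1000, seed = 11)
  expect_true("always" %in% res$retained)   # lower bound = 1
  expect_true("never" %in% res$removed)
  expect_true("once" %in% res$removed)      # lower bound 0 w.h.p.
  expect_true("common" %in% res$retained)
  expect_equal(res$lower_bounds[["always"]], 1)
})
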