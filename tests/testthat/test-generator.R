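test_that("FiLM is an elementwise affine modulation", {
  h <- c(1, 2)
  expect_equal(film(h, c(1, 1), c(0, 0)), h)            # identity
  expect_equal(film(h, c(0, 0), c(5, -5)), c(5, -5))    # gamma 0 -> beta
  expect_equal(film(c(1, 2), c(2, 0.5), c(1, -1)), c(3, 0))
  expect_error(film(c(1, 2), c(1, 1, 1), c(0, 0)), "length mismatch")
})

test_that("beta schedule: warmup ramp then triangular cycling", {
  cfg <- cvae_config(warmup_epochs = 10, cycle_epochs = 8,
                     beta_max = 1, beta_min = 0.1)
  expect_equal(beta_schedule(0, cfg), 0)
  expect_equal(beta_schedule(5, cfg), 0.5)
  expect_equal(beta_schedule(10, cfg), 1)           # ramp endpoint
  expect_equal(beta_schedule(14, cfg), (1 + 0.1) / 2)  # mid-leg: midpoint
  expect_equal(beta_schedule(18, cfg), 0.1)         # leg end: beta_min
  expect_equal(beta_schedule(22, cfg), (1 + 0.1) / 2)  # ascending mid-leg
  expect_equal(beta_schedule(26, cfg), 1)
})

test_that("gate and pair prior honour their construction rules", {
  X <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 0, 1, 0),
             c(0, 0, 1, 1), c(0, 0, 1, 1))
  colnames(X) <- c("A", "B", "C", "D")
  pairs <- c("1:lunch", "1:lunch", "1:lunch", "2:lunch", "2:lunch")
  gate <- build_gate(X, pairs)
  expect_equal(gate$`1:lunch`$k, 2)                 # median item count
  expect_equal(gate$`1:lunch`$allowed, c("A", "B")) # top-k by prevalence
  expect_equal(sort(gate$`2:lunch`$allowed), c("C", "D"))
  prior <- build_pair_prior(X, pairs)
  expect_true(all(is.finite(unlist(prior))))        # clipped log-odds
  n <- 3
  expect_equal(prior$`1:lunch`[["A"]],
               log((1 - 1 / (n + 2)) / (1 / (n + 2))))  # p = 1 clipped
})

test_that("loss components match closed forms on crafted passes", {
  cfg <- cvae_config(latent_dim = 4, hidden = 8, n_blocks = 1, emb_dim = 2,
                     epochs = 1, count_weight = 1, free_bits = 0.05)
  X <- rbind(c(1, 1, 1, 1, 1, 0, 0, 0))
  colnames(X) <- paste0("f", 1:8)
  # fabricate a forward state: probabilities sum to 3, posterior = prior
  fw <- list(probs = matrix(c(rep(0.6, 5), rep(0, 3)), 1),
             mu = matrix(0, 1, 4), lv = matrix(0, 1, 4))
  loss <- mealforge:::.cvae_loss(fw, X, beta = 1, cfg)
  expect_equal(loss$count, (5 - 3)^2)                     # count mismatch
  expect_equal(loss$kl_raw, 0)                            # posterior = prior
  expect_equal(loss$kl, 0.05 * 4)                         # free-bits floor
  # near-perfect reconstruction drives BCE toward 0
  fw2 <- list(probs = matrix(c(rep(1 - 1e-9, 5), rep(1e-9, 3)), 1),
              mu = matrix(0, 1, 4), lv = matrix(0, 1, 4))
  expect_lt(mealforge:::.cvae_loss(fw2, X, 1, cfg)$bce, 1e-6)
  # all-zero targets: pos-weight clipped, no division error
  X0 <- matrix(0L, 1, 8); colnames(X0) <- paste0("f", 1:8)
  l0 <- mealforge:::.cvae_loss(fw, X0, 1, cfg)
  expect_true(is.finite(l0$total))
  expect_lte(l0$pos_weight, 50)
  expect_gte(l0$pos_weight, 1)
})

test_that("training memorizes a tiny dataset and is seed-deterministic", {
  set.seed(3)
  F <- 20; n <- 20
  X <- t(vapply(1:n, function(i) {
    v <- integer(F); v[sample(F, 4)] <- 1L; v
  }, integer(F)))
  colnames(X) <- sprintf("f%02d", 1:F)
  cl <- rep(c(1, 2), each = 10)
  mt <- rep("lunch", n)
  cfg <- cvae_config(latent_dim = 16, hidden = 64, epochs = 500,
                     batch_size = 10, warmup_epochs = 50, cycle_epochs = 100,
                     seed = 4)
  m1 <- cvae(X, cl, mt, cfg)
  expect_gte(m1$f1_train, 0.95)
  m2 <- cvae(X, cl, mt, cfg)
  expect_equal(utils::tail(m1$history$total, 1),
               utils::tail(m2$history$total, 1), tolerance = 1e-12)
  expect_equal(m1$params$out.W, m2$params$out.W, tolerance = 1e-12)

  # sampling respects the gate for every draw
  sets <- simulate(m1, nsim = 50, seed = 5, cluster = 1, meal_type = "lunch")
  allowed <- m1$gate[["1:lunch"]]$allowed
  expect_true(all(unlist(sets) %in% allowed))
  expect_equal(simulate(m1, nsim = 0, seed = 1, cluster = 1, meal_type = "lunch"),
               list())
  expect_error(simulate(m1, nsim = 1, seed = 1, cluster = 9, meal_type = "lunch"),
               "known")
})

test_that("a degenerate pair is reproduced after memorization", {
  F <- 10
  X <- matrix(0L, 16, F)
  colnames(X) <- sprintf("f%02d", 1:F)
  X[1:8, c(1, 2)] <- 1L                       # pair 1: always exactly {f01, f02}
  set.seed(6)
  for (i in 9:16) X[i, sample(3:F, 3)] <- 1L  # pair 2: varied filler
  cl <- rep(c(1, 2), each = 8)
  mt <- rep("dinner", 16)
  cfg <- cvae_config(latent_dim = 6, hidden = 24, epochs = 250, batch_size = 8,
                     warmup_epochs = 25, cycle_epochs = 50, seed = 7)
  m <- cvae(X, cl, mt, cfg)
  sets <- simulate(m, nsim = 40, seed = 8, cluster = 1, meal_type = "dinner")
  frac <- mean(vapply(sets, function(s) setequal(s, c("f01", "f02")), logical(1)))
  expect_gte(frac, 0.9)
})

test_that("count realism: sampled item counts track the pair median", {
  sc <- tiny_scene()
  pb <- binarize(sc$corpus)
  idx <- mealforge:::meal_index(sc$corpus)
  X <- do.call(rbind, pb[])
  cl <- idx$true_archetype[match(rownames(X), idx$meal_id)]
  mt <- idx$meal_type[match(rownames(X), idx$meal_id)]
  cfg <- cvae_config(latent_dim = 16, hidden = 48, epochs = 40, seed = 9)
  m <- cvae(X, cl, mt, cfg)
  pp <- names(m$gate)[1]
  parts <- strsplit(pp, ":", fixed = TRUE)[[1]]
  sets <- simulate(m, nsim = 40, seed = 10, cluster = parts[1],
                   meal_type = parts[2])
  expect_lte(abs(mean(lengths(sets)) - m$gate[[pp]]$k), 1)
})
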