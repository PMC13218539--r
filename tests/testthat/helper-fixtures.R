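# Shared fixtures, built in code. The small scene is cached per test run.

tiny_scene_cache <- new.env()

# small but structured synthetic scene for fast module tests
tiny_scene <- function() {
  if (is.null(tiny_scene_cache$scene))
    tiny_scene_cache$scene <- synthetic_benchmark(
      n_meals = 400, n_foods = 60, n_categories = 6,
      archetypes_per_type = 2, seed = 3)
  tiny_scene_cache$scene
}

# hand-built catalog: energy and macros set directly, micros default small
hand_catalog <- function(codes, categories, energy, protein = 0.05,
                         fat = 0.03, carbohydrate = 0.15, fiber = 0.01,
                         is_beverage = categories == "beverages", ...) {
  n <- length(codes)
  rec <- function(x) rep_len(x, n)
  out <- data.frame(
    code = codes, main_category = categories,
    subcategory = paste0(categories, "_1"),
    is_beverage = rec(is_beverage), energy_kcal = rec(energy),
    protein = rec(protein), fat = rec(fat),
    carbohydrate = rec(carbohydrate), fiber = rec(fiber),
    stringsAsFactors = FALSE
  )
  for (nm in c(micro_nutrients(), limit_nutrients())) out[[nm]] <- 0.01
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- rec(extra[[nm]])
  class(out) <- c("food_catalog", "data.frame")
  out
}

# long-format corpus from a list of meals: list(list(type=, items=c(code=grams)))
hand_corpus <- function(meals) {
  rows <- lapply(seq_along(meals), function(i) {
    m <- meals[[i]]
    data.frame(meal_id = sprintf("H%03d", i), meal_type = m$type,
               food_code = names(m$items), grams = as.numeric(m$items),
               true_archetype = NA_integer_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("meal_corpus", "data.frame")
  out
}

# run expr under a seed without disturbing the ambient RNG stream
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# vectorized exhaustive 1 g grid search over portions of 1-2 foods;
# independent oracle for the portion optimizer
grid_best_objective <- function(foods, dens, targets, cfg, step = 1,
                                lo = 5, hi = 400) {
  grid <- seq(lo, hi, by = step)
  G <- if (length(foods) == 1) matrix(grid, ncol = 1)
  else as.matrix(expand.grid(grid, grid))
  D <- dens[foods, c(names(targets$rdi), names(targets$limit)), drop = FALSE]
  I <- pmax(G %*% D, 1e-9)
  tg <- c(targets$rdi, targets$limit)
  adq <- seq_along(targets$rdi)
  lim <- length(targets$rdi) + seq_along(targets$limit)
  L <- abs(log2(sweep(I, 2, tg, "/")))
  W <- matrix(cfg$base_weight, nrow(I), ncol(I))
  under <- sweep(I, 2, tg, "<")
  W[, adq][under[, adq]] <- cfg$under_weight
  W[, lim][!under[, lim]] <- cfg$over_weight
  W[, lim][under[, lim]] <- cfg$limit_under_weight
  min(rowSums(W * L))
}

# brute-force Benjamini-Hochberg step-up (independent oracle)
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}
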