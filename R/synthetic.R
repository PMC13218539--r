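# Synthetic corpus machinery: seeded generators for a food catalog, meal
# archetype specs and an archetype-structured meal corpus, emulating the
# structure of dietary-survey data (sparse meals, heavy-tailed food
# popularity, category-typed gram amounts, a low-energy beverage category).

# run expr under a fixed RNG seed, restoring caller RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# pool of category names; "beverages" is always included exactly once
.category_pool <- c(
  "grains", "vegetables", "fruits", "dairy", "protein_foods",
  "mixed_dishes", "snacks_sweets", "soups", "condiments", "seafood",
  "legumes", "eggs", "nuts_seeds", "breads"
)

#' Generate a synthetic food catalog
#'
#' Creates `n_foods` foods spread round-robin over `n_categories` main
#' categories (always including exactly one `beverages` category), each with
#' per-gram densities for the 20-nutrient panel plus energy. Energy density
#' is Atwater-consistent: within 5% of `4*protein + 4*carbohydrate + 9*fat`
#' per gram. Beverages are dilute (mean energy density below 1 kcal/g,
#' around 0.4).
#'
#' @param n_foods Number of foods (>= n_categories).
#' @param n_categories Number of main categories (>= 2).
#' @param seed Integer RNG seed.
#' @param subcats_per_category Subcategories per main category (default 2).
#' @return A `food_catalog`: a data.frame with columns `code`,
#'   `main_category`, `subcategory`, `is_beverage`, `energy_kcal` and one
#'   column per panel nutrient (per-gram densities).
#' @examples
#' cat <- generate_catalog(50, 5, seed = 1)
#' table(cat$main_category)
#' @export
generate_catalog <- function(n_foods, n_categories, seed,
                             subcats_per_category = 2) {
  if (n_categories < 2) stop("need at least 2 categories")
  if (n_foods < n_categories)
    stop("invalid argument: n_foods must be >= n_categories")
  with_seed(seed, {
    cats <- c("beverages", .category_pool[seq_len(n_categories - 1)])
    if (n_categories > length(.category_pool) + 1)
      cats <- c(cats, paste0("category_", seq_len(n_categories - 1 - length(.category_pool))))
    cats <- sort(cats)
    main_category <- rep(cats, length.out = n_foods)
    code <- sprintf("F%04d", seq_len(n_foods))
    sub_idx <- stats::ave(seq_len(n_foods), main_category,
                          FUN = function(i) (seq_along(i) - 1L) %% subcats_per_category + 1L)
    subcategory <- paste0(main_category, "_", sub_idx)
    is_beverage <- main_category == "beverages"

    n <- n_foods
    # macro mass per gram of food (rest is water/ash); beverages are dilute
    macro_mass <- ifelse(is_beverage, stats::runif(n, 0.005, 0.18),
                         stats::runif(n, 0.15, 0.45))
    # category-level macro profile, food-level jitter
    prof <- t(vapply(cats, function(ct) {
      a <- stats::rgamma(3, shape = c(1.5, 1.2, 2.5))
      a / sum(a)
    }, numeric(3)))
    rownames(prof) <- cats
    jitter <- matrix(stats::rgamma(3 * n, shape = 8), ncol = 3)
    p3 <- prof[main_category, , drop = FALSE] * jitter
    p3 <- p3 / rowSums(p3)
    protein <- macro_mass * p3[, 1]
    fat <- macro_mass * p3[, 2]
    carbohydrate <- macro_mass * p3[, 3]
    fiber <- carbohydrate * stats::runif(n, 0.02, 0.25)
    energy_kcal <- (4 * protein + 4 * carbohydrate + 9 * fat) *
      stats::runif(n, 0.96, 1.04)

    rdi <- default_rdi_table()
    micro <- sapply(micro_nutrients(), function(nm) {
      # ~100 g of food supplies a lognormal share of daily RDI, median ~15%
      rdi$rdi[[nm]] / 100 * 0.15 * stats::rlnorm(n, 0, 0.9)
    })
    # quality-nutrient densities calibrated so a typical 2,000-kcal day of
    # synthetic foods sits near (not far above) the daily limits
    sodium <- rdi$limit[["sodium"]] / 100 * 0.045 * stats::rlnorm(n, 0, 0.7)
    sat_fat <- fat * stats::runif(n, 0.1, 0.35)
    total_sugars <- carbohydrate * stats::runif(n, 0.05, 0.3)
    added_sugars <- total_sugars * stats::runif(n, 0, 0.8)
    cholesterol <- p3[, 1] * stats::rlnorm(n, log(0.3), 1)  # mg/g, protein-linked

    out <- data.frame(
      code = code, main_category = main_category, subcategory = subcategory,
      is_beverage = is_beverage, energy_kcal = energy_kcal,
      protein = protein, fat = fat, carbohydrate = carbohydrate, fiber = fiber,
      stringsAsFactors = FALSE
    )
    out <- cbind(out, micro)
    out$sodium <- sodium
    out$sat_fat <- sat_fat
    out$total_sugars <- total_sugars
    out$cholesterol <- cholesterol
    out$added_sugars <- added_sugars
    class(out) <- c("food_catalog", "data.frame")
    out
  })
}

#' Nutrient density matrix of a catalog
#'
#' @param catalog A `food_catalog`.
#' @param nutrients Which columns to extract (default energy + full panel).
#' @return Numeric matrix (foods x nutrients) with food codes as rownames.
#' @export
catalog_density_matrix <- function(catalog,
                                   nutrients = c("energy_kcal", nutrient_panel()$nutrient)) {
  m <- as.matrix(catalog[, nutrients, drop = FALSE])
  rownames(m) <- catalog$code
  m
}

#' Generate archetype specifications
#'
#' Each archetype is a distribution over meal composition: a category-weight
#' simplex concentrated on a dominant category, a mean item count, per-
#' category lognormal gram parameters and a Zipf popularity exponent. With
#' the default `dominance` the archetypes have disjoint dominant categories
#' (cycled over the catalog's categories), giving well-separated planted
#' structure.
#'
#' @param catalog A `food_catalog`.
#' @param n_archetypes Archetypes per meal type.
#' @param seed Integer RNG seed.
#' @param meal_types Meal types to cover.
#' @param lambda Mean of the Poisson part of the item count (count is
#'   `1 + Poisson(lambda)`).
#' @param dominance Weight placed on the dominant category (simplex mass).
#' @param beverage_weight Fixed simplex share for the beverage category;
#'   beverages accompany meals rather than dominating archetypes (default
#'   0.08).
#' @param gram_log_sd Lognormal sigma for item gram draws (default 0.4).
#' @param zipf_s Zipf popularity exponent (default 1.2).
#' @return List of archetype specs (class `archetype_spec`), each with
#'   fields `meal_type`, `weights`, `lambda`, `gram_meanlog`, `gram_sdlog`,
#'   `zipf_s`, `id`.
#' @export
archetype_specs <- function(catalog, n_archetypes, seed,
                            meal_types = c("breakfast", "lunch", "dinner"),
                            lambda = 3, dominance = 0.75,
                            beverage_weight = 0.08,
                            gram_log_sd = 0.4, zipf_s = 1.2) {
  cats <- sort(unique(catalog$main_category))
  solid <- setdiff(cats, "beverages")
  has_bev <- "beverages" %in% cats
  if (n_archetypes < 1) stop("need at least one archetype per meal type")
  with_seed(seed, {
    specs <- list()
    id <- 0L
    for (mt in meal_types) {
      for (a in seq_len(n_archetypes)) {
        id <- id + 1L
        dom <- solid[(id - 1L) %% length(solid) + 1L]
        w <- stats::rgamma(length(cats), shape = 0.8)
        names(w) <- cats
        bw <- if (has_bev) min(beverage_weight, (1 - dominance) / 2) else 0
        w["beverages"] <- 0
        w <- w / sum(w) * (1 - dominance - bw)
        w[dom] <- w[dom] + dominance
        if (has_bev) w["beverages"] <- bw
        # typical item ~40-150 g; the dominant (main-dish) category carries
        # entree-scale portions; beverages ~240 g
        mu <- stats::runif(length(cats), log(40), log(150))
        names(mu) <- cats
        mu[dom] <- stats::runif(1, log(90), log(160))
        if (has_bev) mu["beverages"] <- log(240)
        specs[[id]] <- structure(list(
          id = id, meal_type = mt, weights = w, lambda = lambda,
          gram_meanlog = mu, gram_sdlog = gram_log_sd, zipf_s = zipf_s
        ), class = "archetype_spec")
      }
    }
    specs
  })
}

#' Generate a synthetic meal corpus
#'
#' For each meal: a meal type is drawn from `meal_type_mix`, an archetype is
#' drawn uniformly among that type's specs, the item count is
#' `1 + Poisson(lambda)`, foods are drawn by Zipf popularity within
#' weight-sampled categories without replacement, and grams are lognormal
#' with the archetype's per-category parameters. The generating archetype id
#' is recorded as `true_archetype`.
#'
#' @param catalog A `food_catalog`.
#' @param archetypes List of specs from [archetype_specs()] (>= 2).
#' @param n_meals Number of meals (>= 1).
#' @param seed Integer RNG seed.
#' @param meal_type_mix Named simplex over meal types (default uniform over
#'   types present in `archetypes`).
#' @return A `meal_corpus`: long data.frame with columns `meal_id`,
#'   `meal_type`, `food_code`, `grams`, `true_archetype`.
#' @export
generate_corpus <- function(catalog, archetypes, n_meals, seed,
                            meal_type_mix = NULL) {
  if (nrow(catalog) == 0) stop("invalid argument: empty catalog")
  if (length(archetypes) < 2) stop("need at least 2 archetypes")
  if (n_meals < 1) stop("n_meals must be >= 1")
  types <- unique(vapply(archetypes, `[[`, "", "meal_type"))
  if (is.null(meal_type_mix)) {
    meal_type_mix <- stats::setNames(rep(1 / length(types), length(types)), types)
  }
  if (abs(sum(meal_type_mix) - 1) > 1e-9) stop("meal_type_mix must sum to 1")
  by_type <- split(seq_along(archetypes),
                   vapply(archetypes, `[[`, "", "meal_type"))
  foods_by_cat <- split(seq_len(nrow(catalog)), catalog$main_category)

  with_seed(seed, {
    rows <- vector("list", n_meals)
    mts <- sample(names(meal_type_mix), n_meals, replace = TRUE,
                  prob = meal_type_mix)
    for (i in seq_len(n_meals)) {
      mt <- mts[i]
      ai <- by_type[[mt]][sample.int(length(by_type[[mt]]), 1L)]
      sp <- archetypes[[ai]]
      k <- 1L + stats::rpois(1L, sp$lambda)
      chosen <- integer(0)
      guard <- 0L
      while (length(chosen) < k && guard < 50L * k) {
        guard <- guard + 1L
        ct <- sample(names(sp$weights), 1L, prob = sp$weights)
        pool <- setdiff(foods_by_cat[[ct]], chosen)
        if (!length(pool)) next
        # Zipf over within-category rank (catalog order = popularity order)
        r <- rank(pool)
        pr <- r^(-sp$zipf_s)
        chosen <- c(chosen, pool[sample.int(length(pool), 1L, prob = pr)])
      }
      cts <- catalog$main_category[chosen]
      grams <- stats::rlnorm(length(chosen), sp$gram_meanlog[cts], sp$gram_sdlog)
      rows[[i]] <- data.frame(
        meal_id = sprintf("M%06d", i), meal_type = mt,
        food_code = catalog$code[chosen], grams = grams,
        true_archetype = sp$id, stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("meal_corpus", "data.frame")
    out
  })
}

#' Generate the standard synthetic benchmark
#'
#' Convenience wrapper producing the catalog + corpus pair used throughout
#' the package's evaluation: by default 200 foods in 10 categories, 4
#' archetypes per meal type, and a corpus of `n_meals` meals.
#'
#' @param n_meals Corpus size (default 2000).
#' @param n_foods,n_categories,archetypes_per_type Benchmark dimensions.
#' @param seed Integer RNG seed.
#' @param dominance Archetype category dominance; the benchmark uses 0.95 so
#'   the planted archetypes are well-separated (disjoint dominant categories
#'   with most meal mass on them), the regime in which recovery is expected.
#' @return List with `catalog`, `archetypes`, `corpus`.
#' @export
synthetic_benchmark <- function(n_meals = 2000, n_foods = 200,
                                n_categories = 10, archetypes_per_type = 4,
                                seed = 5, dominance = 0.95) {
  catalog <- generate_catalog(n_foods, n_categories, seed = seed)
  specs <- archetype_specs(catalog, archetypes_per_type, seed = seed + 1L,
                           dominance = dominance)
  corpus <- generate_corpus(catalog, specs, n_meals, seed = seed + 2L)
  list(catalog = catalog, archetypes = specs, corpus = corpus)
}

#' @export
print.meal_corpus <- function(x, ...) {
  cat("Meal corpus:", length(unique(x$meal_id)), "meals,",
      length(unique(x$food_code)), "distinct foods\n")
  print(table(x$meal_type[!duplicated(x$meal_id)]))
  invisible(x)
}

#' @export
print.food_catalog <- function(x, ...) {
  cat("Food catalog:", nrow(x), "foods,",
      length(unique(x$main_category)), "categories\n")
  invisible(x)
}
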