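# Hybrid meal features: nutrient composition block + per-category gram
# block, z-scored within meal type. These features drive outlier filtering
# and archetype clustering.

# Gini coefficient of a nonnegative share vector
.gini <- function(p) {
  n <- length(p)
  if (sum(p) == 0) return(0)
  sum(abs(outer(p, p, "-"))) / (2 * n * sum(p))
}

# Hill diversity of order 1 (Shannon exponential) of a share vector
.hill1 <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  p <- p / sum(p)
  exp(-sum(p * log(p)))
}

#' Per-meal nutrient totals
#'
#' Sums grams x per-gram density over a meal's items for energy and the full
#' nutrient panel.
#'
#' @param corpus A `meal_corpus`.
#' @param catalog A `food_catalog` covering all corpus foods.
#' @return Matrix (meals x nutrients), meal ids as rownames, in corpus meal
#'   order.
#' @export
meal_nutrient_totals <- function(corpus, catalog) {
  unknown <- setdiff(corpus$food_code, catalog$code)
  if (length(unknown))
    stop("catalog does not cover food code(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  dens <- catalog_density_matrix(catalog)
  meals <- unique(corpus$meal_id)
  ridx <- match(corpus$meal_id, meals)
  fidx <- match(corpus$food_code, catalog$code)
  out <- matrix(0, length(meals), ncol(dens),
                dimnames = list(meals, colnames(dens)))
  contrib <- dens[fidx, , drop = FALSE] * corpus$grams
  for (j in seq_len(ncol(out)))
    out[, j] <- as.numeric(tapply(contrib[, j], ridx, sum)[as.character(seq_along(meals))])
  out
}

#' Extract hybrid clustering features
#'
#' Builds, per meal: (i) a nutrient block — macronutrient and fiber totals,
#' energy, macro energy shares, energy density, fiber per 1,000 kcal, macro
#' diversity (Hill number of order 1 over macro energy shares) and a meal
#' balance score (1 - Gini of macro energy shares); and (ii) a category
#' block — grams per main category and per subcategory, plus each main
#' category's share of total meal grams (composition fractions factor out
#' meal-size variation, which otherwise swamps the category signal in
#' density-based clustering). Features are z-score standardized within meal
#' type (zero-variance columns map to 0). Zero-energy meals get ratio
#' features of 0, with a warning.
#'
#' @param corpus A `meal_corpus`.
#' @param catalog A `food_catalog` covering all corpus foods.
#' @param standardize Z-score within meal type (default TRUE).
#' @return A `hybrid_features` object: named list (by meal type) of numeric
#'   matrices (meals x features) with meal ids as rownames, plus attribute
#'   `feature_names`.
#' @export
extract_features <- function(corpus, catalog, standardize = TRUE) {
  tot <- meal_nutrient_totals(corpus, catalog)
  energy <- tot[, "energy_kcal"]
  if (any(energy <= 0)) warning("zero-energy meal(s): ratio features set to 0")
  macroE <- cbind(protein = 4 * tot[, "protein"], fat = 9 * tot[, "fat"],
                  carbohydrate = 4 * tot[, "carbohydrate"])
  shares <- macroE / ifelse(rowSums(macroE) > 0, rowSums(macroE), 1)
  shares[rowSums(macroE) <= 0, ] <- 0
  grams_tot <- as.numeric(tapply(corpus$grams, match(corpus$meal_id, rownames(tot)), sum))

  ratio <- cbind(
    share_protein = shares[, 1], share_fat = shares[, 2],
    share_carb = shares[, 3],
    energy_density = ifelse(grams_tot > 0, energy / grams_tot, 0),
    fiber_per_1000kcal = ifelse(energy > 0, tot[, "fiber"] / energy * 1000, 0),
    macro_diversity = apply(shares, 1, .hill1),
    meal_balance = 1 - apply(shares, 1, .gini)
  )
  ratio[energy <= 0, c("share_protein", "share_fat", "share_carb",
                       "fiber_per_1000kcal", "macro_diversity",
                       "meal_balance")] <- 0

  # category gram blocks
  cat_of <- catalog$main_category[match(corpus$food_code, catalog$code)]
  sub_of <- catalog$subcategory[match(corpus$food_code, catalog$code)]
  meals <- rownames(tot)
  gram_block <- function(groups) {
    lv <- sort(unique(groups))
    m <- matrix(0, length(meals), length(lv), dimnames = list(meals, lv))
    agg <- tapply(corpus$grams, list(corpus$meal_id, groups), sum)
    m[rownames(agg), colnames(agg)] <- ifelse(is.na(agg), 0, agg)
    m
  }
  mainb <- gram_block(cat_of)
  tot_g <- rowSums(mainb)
  fracb <- mainb / ifelse(tot_g > 0, tot_g, 1)
  colnames(fracb) <- paste0("frac_main_", colnames(mainb))
  colnames(mainb) <- paste0("g_main_", colnames(mainb))
  subb <- gram_block(sub_of)
  colnames(subb) <- paste0("g_sub_", colnames(subb))

  nutr <- tot[, c("energy_kcal", "protein", "fat", "carbohydrate", "fiber")]
  feat <- cbind(nutr, ratio, mainb, fracb, subb)

  idx <- meal_index(corpus)
  out <- lapply(split(idx$meal_id, idx$meal_type), function(ids) {
    m <- feat[ids, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(m)
      sdv <- apply(m, 2, stats::sd)
      m <- sweep(m, 2, mu, "-")
      m <- sweep(m, 2, ifelse(sdv > 0, sdv, 1), "/")
      m[, sdv == 0] <- 0
    }
    m
  })
  structure(out, feature_names = colnames(feat), class = "hybrid_features")
}
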