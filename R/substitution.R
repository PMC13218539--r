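# Few-item meal substitution: portion-based pricing, candidate search over
# real meals (plus same-category single-item swaps), nutrition-gain vs
# cost-delta scoring, theta-parameterized selection, cost-benefit frontier
# with knee point, and category transition summaries.

#' Portion-based pricing model
#'
#' Restaurant-style pricing: each item is billed as
#' `portions = grams / grams_per_portion` (capped per item), at a per-portion
#' price for its category; cross-item caps limit the billed portions of a
#' class per meal (e.g., at most one soup bowl); unknown categories fall back
#' to a generic side default (150 g, $3 per portion); a fixed $2 overhead is
#' added once per meal.
#'
#' @param categories Named list: category -> list(grams_per_portion,
#'   price_per_portion, item_cap). Defaults cover the synthetic categories.
#' @param cross_item_caps Named numeric: category -> max billed portions per
#'   meal.
#' @param generic list(grams_per_portion = 150, price_per_portion = 3).
#' @param overhead Per-meal overhead in USD (default 2).
#' @param per_100g Optional named numeric of per-100g prices; when supplied
#'   the model is the grocery dialect: cost = price/100g * grams (+overhead).
#' @return List of class `pricing_model`.
#' @export
pricing_model <- function(categories = NULL, cross_item_caps = c(soups = 1),
                          generic = list(grams_per_portion = 150,
                                         price_per_portion = 3),
                          overhead = 2, per_100g = NULL) {
  if (is.null(categories)) {
    categories <- list(
      grains = list(grams_per_portion = 120, price_per_portion = 3, item_cap = 3),
      vegetables = list(grams_per_portion = 85, price_per_portion = 3.5, item_cap = 3),
      fruits = list(grams_per_portion = 120, price_per_portion = 3, item_cap = 3),
      dairy = list(grams_per_portion = 120, price_per_portion = 3, item_cap = 3),
      protein_foods = list(grams_per_portion = 140, price_per_portion = 6, item_cap = 3),
      seafood = list(grams_per_portion = 140, price_per_portion = 8, item_cap = 3),
      mixed_dishes = list(grams_per_portion = 250, price_per_portion = 9, item_cap = 2),
      snacks_sweets = list(grams_per_portion = 60, price_per_portion = 2.5, item_cap = 3),
      soups = list(grams_per_portion = 300, price_per_portion = 5, item_cap = 2),
      condiments = list(grams_per_portion = 30, price_per_portion = 0.75, item_cap = 3),
      beverages = list(grams_per_portion = 360, price_per_portion = 2.5, item_cap = 3)
    )
  }
  structure(list(categories = categories, cross_item_caps = cross_item_caps,
                 generic = generic, overhead = overhead, per_100g = per_100g),
            class = "pricing_model")
}

#' Read a pricing model from YAML
#'
#' @param path YAML file with keys `categories`, `cross_item_caps`,
#'   `generic`, `overhead`.
#' @return A `pricing_model`.
#' @export
read_pricing <- function(path) {
  y <- yaml::read_yaml(path)
  pricing_model(
    categories = y$categories,
    cross_item_caps = unlist(y$cross_item_caps),
    generic = if (!is.null(y$generic)) y$generic else
      list(grams_per_portion = 150, price_per_portion = 3),
    overhead = if (!is.null(y$overhead)) y$overhead else 2
  )
}

#' Price a meal
#'
#' @param items Data.frame with `food_code` and `grams` (or a
#'   `portion_solution`).
#' @param catalog A `food_catalog` (category lookup).
#' @param pricing A [pricing_model()].
#' @return Meal cost in USD (includes the per-meal overhead exactly once).
#' @export
meal_cost <- function(items, catalog, pricing = pricing_model()) {
  if (inherits(items, "portion_solution"))
    items <- data.frame(food_code = items$foods, grams = as.numeric(items$grams))
  if (nrow(items) == 0) return(pricing$overhead)
  if (any(items$grams < 0)) stop("invalid argument: negative grams")
  cats <- catalog$main_category[match(items$food_code, catalog$code)]
  if (!is.null(pricing$per_100g)) {
    pp <- pricing$per_100g[cats]
    pp[is.na(pp)] <- pricing$generic$price_per_portion /
      pricing$generic$grams_per_portion * 100
    return(sum(pp / 100 * items$grams) + pricing$overhead)
  }
  portions <- numeric(nrow(items))
  price <- numeric(nrow(items))
  for (i in seq_len(nrow(items))) {
    spec <- pricing$categories[[cats[i]]]
    if (is.null(spec))
      spec <- c(pricing$generic, list(item_cap = Inf))
    cap <- if (is.null(spec$item_cap)) Inf else spec$item_cap
    portions[i] <- min(items$grams[i] / spec$grams_per_portion, cap)
    price[i] <- spec$price_per_portion
  }
  # cross-item caps: excess portions of a capped class are not billed
  for (cc in names(pricing$cross_item_caps)) {
    j <- which(cats == cc)
    tot <- sum(portions[j])
    cap <- pricing$cross_item_caps[[cc]]
    if (length(j) && tot > cap) portions[j] <- portions[j] * cap / tot
  }
  sum(portions * price) + pricing$overhead
}

#' Hop count between two meals
#'
#' The number of items replaced: `max(|A \ B|, |B \ A|)`, so an unpaired
#' addition or removal counts as one change.
#'
#' @param a,b Character food-code sets.
#' @return Integer k.
#' @export
hop_count <- function(a, b) {
  max(length(setdiff(a, b)), length(setdiff(b, a)))
}

#' Nutrition gain of a candidate over an original meal
#'
#' Percent reduction in the mean absolute RDI deviation:
#' `100 * (dev_orig - dev_cand) / dev_orig`.
#'
#' @param orig_totals,cand_totals Named nutrient totals of the two meals.
#' @param targets Per-meal targets ([per_meal_targets()]).
#' @return Percent gain (negative when the candidate is worse); `NA` when
#'   the original deviation is zero.
#' @export
nutrition_gain <- function(orig_totals, cand_totals, targets) {
  d0 <- as.numeric(rdi_deviation(orig_totals, targets))
  d1 <- as.numeric(rdi_deviation(cand_totals, targets))
  if (d0 == 0) return(NA_real_)
  100 * (d0 - d1) / d0
}

#' Find substitution candidates for a meal
#'
#' Ranks real meals of the same meal type by a combined similarity
#' `alpha * Jaccard(item sets) + (1 - alpha) * cosine(nutrient totals)`,
#' keeps those with comparable energy (relative difference <=
#' `energy_tol`) and item count (difference <= `count_tol`), and adds
#' same-category single-item swaps (the removed item's grams transfer to
#' the added food). The identity (k = 0) is excluded; `max_hops` bounds k.
#'
#' @param solution A `portion_solution` for the generated meal.
#' @param real_corpus A `meal_corpus` of real meals.
#' @param catalog A `food_catalog`.
#' @param rdi RDI table (targets for the gain computation).
#' @param pricing A [pricing_model()].
#' @param alpha Similarity mixing weight (default 0.5).
#' @param energy_tol Relative energy tolerance (default 0.15).
#' @param count_tol Item-count tolerance (default 1).
#' @param max_hops Maximum k (default 3).
#' @param include_swaps Add single-item same-category swaps (default TRUE).
#' @return Data.frame of candidates: `candidate_id`, `source`
#'   (real/swap), `k`, `gain_pct`, `cost` , `cost_delta`, `similarity`,
#'   plus a list-column `items` of (food_code, grams) data.frames.
#' @export
find_candidates <- function(solution, real_corpus, catalog,
                            rdi = default_rdi_table(),
                            pricing = pricing_model(),
                            alpha = 0.5, energy_tol = 0.15, count_tol = 1,
                            max_hops = 3, include_swaps = TRUE) {
  targets <- per_meal_targets(rdi, solution$meal_type)
  dens <- catalog_density_matrix(catalog)
  orig_items <- data.frame(food_code = solution$foods,
                           grams = as.numeric(solution$grams),
                           stringsAsFactors = FALSE)
  orig_set <- solution$foods
  orig_tot <- solution$totals
  orig_cost <- meal_cost(orig_items, catalog, pricing)
  orig_e <- solution$energy_kcal
  orig_n <- length(orig_set)

  cands <- list()
  add_candidate <- function(id, source, items) {
    set <- items$food_code
    k <- hop_count(orig_set, set)
    if (k < 1 || k > max_hops) return()
    tot <- as.numeric(items$grams %*% dens[set, , drop = FALSE])
    names(tot) <- colnames(dens)
    e <- tot[["energy_kcal"]]
    if (abs(e - orig_e) / max(orig_e, 1e-9) > energy_tol) return()
    if (abs(length(set) - orig_n) > count_tol) return()
    nz <- sqrt(sum(orig_tot^2)) * sqrt(sum(tot^2))
    cosim <- if (nz > 0) sum(orig_tot * tot) / nz else 0
    jac <- length(intersect(orig_set, set)) / length(union(orig_set, set))
    cost <- meal_cost(items, catalog, pricing)
    gain <- nutrition_gain(orig_tot, tot, targets)
    if (is.na(gain)) return()
    cands[[length(cands) + 1L]] <<- data.frame(
      candidate_id = id, source = source, k = k, gain_pct = gain,
      cost = cost, cost_delta = cost - orig_cost,
      similarity = alpha * jac + (1 - alpha) * cosim,
      items = I(list(items)), stringsAsFactors = FALSE
    )
  }

  real <- real_corpus[real_corpus$meal_type == solution$meal_type, , drop = FALSE]
  for (m in split(as.data.frame(real), real$meal_id)) {
    add_candidate(m$meal_id[1], "real",
                  data.frame(food_code = m$food_code, grams = m$grams,
                             stringsAsFactors = FALSE))
  }
  if (include_swaps) {
    for (i in seq_along(orig_set)) {
      ct <- catalog$main_category[match(orig_set[i], catalog$code)]
      alternatives <- setdiff(catalog$code[catalog$main_category == ct], orig_set)
      for (alt in alternatives) {
        items <- orig_items
        items$food_code[i] <- alt
        add_candidate(paste0("swap:", orig_set[i], ">", alt), "swap", items)
      }
    }
  }
  if (!length(cands))
    return(data.frame(candidate_id = character(0), source = character(0),
                      k = integer(0), gain_pct = numeric(0), cost = numeric(0),
                      cost_delta = numeric(0), similarity = numeric(0)))
  out <- do.call(rbind, cands)
  out[order(-out$similarity, out$candidate_id), ]
}

#' Trade-off policy
#'
#' @param theta Cost-savings emphasis (>= 0, finite).
#' @param budget Optional absolute budget cap (USD) on the candidate cost.
#' @param no_cost_increase Require cost_delta <= 0 (default FALSE).
#' @return List of class `tradeoff_policy`.
#' @export
tradeoff_policy <- function(theta = 0, budget = NULL, no_cost_increase = FALSE) {
  stopifnot(is.finite(theta), theta >= 0)
  structure(list(theta = theta, budget = budget,
                 no_cost_increase = no_cost_increase),
            class = "tradeoff_policy")
}

#' Select the winning substitution
#'
#' Applies the budget / no-cost-increase filters, then maximizes
#' `gain_pct + theta * savings_pct` where `savings_pct` is the percent cost
#' saving relative to the original cost. Ties prefer lower k, then lower
#' cost.
#'
#' @param candidates Candidate data.frame from [find_candidates()].
#' @param policy A [tradeoff_policy()].
#' @param orig_cost Original meal cost (for the savings percentage).
#' @return The winning candidate row (one-row data.frame with
#'   `savings_pct` and `score` appended), or NULL if none is feasible.
#' @export
select_substitution <- function(candidates, policy, orig_cost) {
  if (!nrow(candidates)) return(NULL)
  x <- candidates
  if (!is.null(policy$budget)) x <- x[x$cost <= policy$budget, , drop = FALSE]
  if (isTRUE(policy$no_cost_increase)) x <- x[x$cost_delta <= 0, , drop = FALSE]
  if (!nrow(x)) return(NULL)
  x$savings_pct <- 100 * (orig_cost - x$cost) / orig_cost
  x$score <- x$gain_pct + policy$theta * x$savings_pct
  x[order(-x$score, x$k, x$cost, x$candidate_id), ][1, , drop = FALSE]
}

#' Cost-benefit frontier over a theta grid
#'
#' For each theta: selects winners for every meal, then reports the median
#' nutrition gain and median cost savings over meals with a winner, with
#' percentile bootstrap CIs. The knee is the point of maximum perpendicular
#' distance from the chord joining the curve endpoints (in the
#' savings-gain plane).
#'
#' @param candidate_sets Named list (by meal id) of candidate data.frames.
#' @param orig_costs Named numeric of original meal costs.
#' @param theta_grid Numeric vector of theta values (nonempty).
#' @param policy_args Extra arguments passed to [tradeoff_policy()] (budget,
#'   no_cost_increase).
#' @param n_boot Bootstrap resamples for the CIs (default 1000).
#' @param seed Integer RNG seed.
#' @return List with `curve` (data.frame per theta), `knee` (row index into
#'   the curve), `feasibility` (fraction of meals with >= 1 candidate).
#' @export
frontier <- function(candidate_sets, orig_costs, theta_grid,
                     policy_args = list(), n_boot = 1000, seed = 1) {
  if (!length(theta_grid)) stop("theta grid must be nonempty")
  feas <- vapply(candidate_sets, function(cs) nrow(cs) > 0, logical(1))
  rows <- lapply(seq_along(theta_grid), function(gi) {
    th <- theta_grid[gi]
    pol <- do.call(tradeoff_policy, c(list(theta = th), policy_args))
    gains <- sav <- numeric(0)
    for (id in names(candidate_sets)) {
      w <- select_substitution(candidate_sets[[id]], pol, orig_costs[[id]])
      if (!is.null(w)) { gains <- c(gains, w$gain_pct); sav <- c(sav, w$savings_pct) }
    }
    if (!length(gains))
      return(data.frame(theta = th, n = 0, median_gain = NA, gain_lo = NA,
                        gain_hi = NA, median_savings = NA, sav_lo = NA,
                        sav_hi = NA))
    gci <- if (length(gains) > 1)
      bootstrap_ci(gains, stats::median, n_boot, seed = seed + gi)
    else c(estimate = gains, lower = gains, upper = gains)
    sci <- if (length(sav) > 1)
      bootstrap_ci(sav, stats::median, n_boot, seed = seed + 1000 + gi)
    else c(estimate = sav, lower = sav, upper = sav)
    data.frame(theta = th, n = length(gains),
               median_gain = gci[["estimate"]], gain_lo = gci[["lower"]],
               gain_hi = gci[["upper"]],
               median_savings = sci[["estimate"]], sav_lo = sci[["lower"]],
               sav_hi = sci[["upper"]])
  })
  curve <- do.call(rbind, rows)
  ok <- !is.na(curve$median_gain)
  knee <- if (sum(ok) == 1) which(ok) else if (sum(ok) >= 2) {
    pts <- curve[ok, c("median_savings", "median_gain")]
    a <- as.numeric(pts[1, ]); b <- as.numeric(pts[nrow(pts), ])
    chord <- b - a
    nc <- sqrt(sum(chord^2))
    d <- if (nc == 0) rep(0, nrow(pts)) else
      abs(chord[1] * (pts[, 2] - a[2]) - chord[2] * (pts[, 1] - a[1])) / nc
    which(ok)[which.max(d)]
  } else NA_integer_
  list(curve = curve, knee = knee, feasibility = mean(feas))
}

#' Category transition matrix of winning substitutions
#'
#' Rows are the removed item's category, columns the added item's category,
#' normalized so each row sums to 1. Swapped pairs are matched
#' same-category first, then in sorted order; unmatched adds/removes appear
#' in the `net_adds` / `net_removes` marginals.
#'
#' @param swaps Data.frame with columns `removed` and `added` food codes
#'   (one row per replaced item; NA marks unpaired adds/removes).
#' @param catalog A `food_catalog`.
#' @return List with `matrix` (row-normalized), `counts`, `net_adds`,
#'   `net_removes` (named category counts).
#' @export
transition_matrix <- function(swaps, catalog) {
  cat_of <- function(code) catalog$main_category[match(code, catalog$code)]
  paired <- swaps[!is.na(swaps$removed) & !is.na(swaps$added), , drop = FALSE]
  if (!nrow(paired)) stop("need at least one paired swap")
  rc <- cat_of(paired$removed); ac <- cat_of(paired$added)
  cats <- sort(unique(c(rc, ac)))
  counts <- table(factor(rc, cats), factor(ac, cats))
  m <- sweep(unclass(counts), 1, pmax(rowSums(counts), 1), "/")
  adds <- table(cat_of(swaps$added[is.na(swaps$removed)]))
  rems <- table(cat_of(swaps$removed[is.na(swaps$added)]))
  list(matrix = m, counts = unclass(counts),
       net_adds = adds, net_removes = rems)
}

#' Itemized swap list between two meals
#'
#' Pairs removed and added foods (same-category matches first, then sorted
#' order); leftovers become unpaired adds/removes.
#'
#' @param orig,cand Character food-code sets.
#' @param catalog A `food_catalog`.
#' @return Data.frame with columns `removed`, `added` (NA where unpaired).
#' @export
swap_pairs <- function(orig, cand, catalog) {
  removed <- sort(setdiff(orig, cand))
  added <- sort(setdiff(cand, orig))
  cat_of <- function(code) catalog$main_category[match(code, catalog$code)]
  out <- list()
  # same-category matches first
  left_r <- character(0)
  for (r in removed) {
    j <- which(cat_of(added) == cat_of(r))[1]
    if (!is.na(j)) {
      out[[length(out) + 1L]] <- data.frame(removed = r, added = added[j],
                                            stringsAsFactors = FALSE)
      added <- added[-j]
    } else left_r <- c(left_r, r)
  }
  n <- min(length(left_r), length(added))
  if (n) for (i in seq_len(n))
    out[[length(out) + 1L]] <- data.frame(removed = left_r[i], added = added[i],
                                          stringsAsFactors = FALSE)
  if (length(left_r) > n) for (r in left_r[(n + 1):length(left_r)])
    out[[length(out) + 1L]] <- data.frame(removed = r, added = NA_character_,
                                          stringsAsFactors = FALSE)
  if (length(added) > n) for (a in added[(n + 1):length(added)])
    out[[length(out) + 1L]] <- data.frame(removed = NA_character_, added = a,
                                          stringsAsFactors = FALSE)
  if (!length(out)) data.frame(removed = character(0), added = character(0))
  else do.call(rbind, out)
}
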