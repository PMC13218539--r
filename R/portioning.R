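# Portion assignment: converts a food set into gram portions meeting
# per-meal RDI targets. Serving-size initialization with jitter, projected
# gradient descent on a signed-log2 objective with asymmetric penalties,
# coordinate polish, then an ordered constraint pipeline.

#' Per-meal nutrient targets
#'
#' Scales the daily RDI/limit/energy values by the meal-type share
#' (breakfast 25%, lunch 35%, dinner 40% by default).
#'
#' @param rdi An RDI table ([default_rdi_table()]).
#' @param meal_type One of breakfast/lunch/dinner.
#' @param shares Meal shares ([meal_shares()]).
#' @return List with `rdi` (adequacy targets), `limit` (limit caps), and
#'   `energy_kcal`, all at the per-meal scale.
#' @export
per_meal_targets <- function(rdi = default_rdi_table(), meal_type,
                             shares = meal_shares()) {
  if (!meal_type %in% names(shares)) stop("unknown meal type: ", meal_type)
  s <- shares[[meal_type]]
  list(rdi = s * rdi$rdi, limit = s * rdi$limit,
       energy_kcal = s * rdi$energy_kcal)
}

#' Default serving-size table
#'
#' Deterministic canonical serving sizes per food, by main category
#' (beverages 240 g; otherwise typical plate-component servings), with a
#' 100 g fallback for unknown foods.
#'
#' @param catalog A `food_catalog`.
#' @return Named numeric vector of grams per food code, with attribute
#'   `default` = 100.
#' @export
default_serving_table <- function(catalog) {
  by_cat <- c(beverages = 240, grains = 80, vegetables = 85, fruits = 120,
              dairy = 100, protein_foods = 85, mixed_dishes = 200,
              snacks_sweets = 40, soups = 240, condiments = 15,
              seafood = 85, legumes = 90, eggs = 50, nuts_seeds = 30,
              breads = 50)
  sv <- by_cat[catalog$main_category]
  sv[is.na(sv)] <- 100
  structure(stats::setNames(as.numeric(sv), catalog$code), default = 100)
}

#' Initialize portions from serving sizes
#'
#' Grams = serving size times `1 + U(-jitter, +jitter)`, floored at 5 g.
#'
#' @param foods Character food codes.
#' @param serving_table Named numeric from [default_serving_table()].
#' @param jitter_frac Jitter half-width as a fraction (default 0.1).
#' @param seed Integer RNG seed.
#' @return Named numeric grams vector.
#' @export
init_portions <- function(foods, serving_table, jitter_frac = 0.1, seed = 1) {
  sv <- serving_table[foods]
  dflt <- attr(serving_table, "default")
  sv[is.na(sv)] <- if (is.null(dflt)) 100 else dflt
  with_seed(seed, {
    g <- sv * (1 + stats::runif(length(foods), -jitter_frac, jitter_frac))
    stats::setNames(pmax(5, g), foods)
  })
}

#' Portioning configuration
#'
#' @param under_weight Penalty weight for under-consuming adequacy nutrients
#'   (protein, fiber, micronutrients); default 2.
#' @param over_weight Penalty weight for over-consuming limit nutrients
#'   (sodium, saturated fat, sugars); default 2.
#' @param base_weight Weight otherwise (over-consuming adequacy nutrients);
#'   default 1.
#' @param limit_under_weight Weight for limit nutrients below their cap;
#'   default 0 (upper-bound-only semantics).
#' @param min_grams Per-item minimum (default 5 g).
#' @param item_cap Per-item maximum (default 400 g).
#' @param category_cap Per-main-category gram cap (default 500 g).
#' @param beverage_cap Beverage gram cap (default 500 g).
#' @param total_cap Total meal gram cap (default 900 g).
#' @param bev_kcal_frac Maximum fraction of meal energy from beverages
#'   (default 0.25).
#' @param energy_tol Relative tolerance for the meal energy target (default
#'   0.01).
#' @param iters,step,tol Projected-gradient budget, step size (gram units)
#'   and relative-change early-stop tolerance.
#' @param polish_sweeps Coordinate-descent polish sweeps after the gradient
#'   loop (default 2).
#' @param jitter_frac Initialization jitter (default 0.1).
#' @return A list of class `portion_config`.
#' @export
portion_config <- function(under_weight = 2, over_weight = 2, base_weight = 1,
                           limit_under_weight = 0,
                           min_grams = 5, item_cap = 400, category_cap = 500,
                           beverage_cap = 500, total_cap = 900,
                           bev_kcal_frac = 0.25, energy_tol = 0.01,
                           iters = 300, step = 2, tol = 1e-5,
                           polish_sweeps = 2, jitter_frac = 0.1) {
  structure(as.list(environment()), class = "portion_config")
}

# per-nutrient weights given intakes vs targets
.portion_weights <- function(I, targets, cfg) {
  adq <- names(targets$rdi); lim <- names(targets$limit)
  w <- numeric(length(adq) + length(lim))
  names(w) <- c(adq, lim)
  w[adq] <- ifelse(I[adq] < targets$rdi, cfg$under_weight, cfg$base_weight)
  w[lim] <- ifelse(I[lim] > targets$limit, cfg$over_weight, cfg$limit_under_weight)
  w
}

#' Signed-log2 portion objective
#'
#' `sum_n w_n |log2(intake_n / target_n)|` over the adequacy and limit
#' nutrients, with asymmetric weights: under-consumption of adequacy
#' nutrients and over-consumption of limit nutrients carry the higher
#' penalty; limit nutrients below their cap contribute
#' `limit_under_weight` (0 by default). Intakes are clipped below at a small
#' epsilon.
#'
#' @param grams Named numeric grams per food.
#' @param densities Matrix (foods x nutrients) of per-gram densities.
#' @param targets Per-meal targets from [per_meal_targets()].
#' @param config A [portion_config()].
#' @return Scalar objective (0 when every intake equals its target).
#' @export
portion_objective <- function(grams, densities, targets,
                              config = portion_config()) {
  I <- as.numeric(grams %*% densities[names(grams), , drop = FALSE])
  names(I) <- colnames(densities)
  nuts <- c(names(targets$rdi), names(targets$limit))
  tg <- c(targets$rdi, targets$limit)
  I <- pmax(I[nuts], 1e-9)
  w <- .portion_weights(I, targets, config)
  sum(w * abs(log2(I / tg)))
}

# analytic gradient of the objective wrt grams (piecewise; weights frozen
# at current intake side)
.portion_gradient <- function(grams, densities, targets, cfg) {
  D <- densities[names(grams), , drop = FALSE]
  nuts <- c(names(targets$rdi), names(targets$limit))
  tg <- c(targets$rdi, targets$limit)
  I <- pmax(as.numeric(grams %*% D)[match(nuts, colnames(D))], 1e-9)
  names(I) <- nuts
  w <- .portion_weights(I, targets, cfg)
  sgn <- sign(log2(I / tg))
  coefn <- w * sgn / (I * log(2))
  as.numeric(D[, nuts, drop = FALSE] %*% coefn)
}

#' Optimize portions for a food set
#'
#' Runs the full portioning procedure: serving-size initialization with
#' jitter, projected gradient descent on [portion_objective()] with a
#' coordinate-descent polish, then the ordered constraint pipeline:
#' (1) per-item minimum 5 g; (2) per-item and per-category caps;
#' (3) uniform energy retargeting of non-capped items to the meal energy
#' target; (4) upper-bound-only scaling of the largest contributors to
#' sodium / sugars / saturated fat; (5) beverage gram cap and beverage
#' energy fraction (<= 25% of meal kcal); (6) total-grams cap (900 g) with
#' rebalancing and a single energy re-target. If a stage cannot be
#' satisfied, the best-effort solution is returned flagged infeasible with
#' the violated stages listed.
#'
#' @param foods Character food codes.
#' @param catalog A `food_catalog`.
#' @param meal_type Meal type, sets the target share.
#' @param rdi RDI table.
#' @param serving_table Serving sizes (default [default_serving_table()]).
#' @param config A [portion_config()].
#' @param seed Integer RNG seed (initialization jitter).
#' @param apply_constraints Run the constraint pipeline (default TRUE);
#'   FALSE returns the unconstrained optimum (projected to item bounds).
#' @return A `portion_solution`: list with `grams`, `objective`, `totals`,
#'   `energy_kcal`, `report` (per-stage), `feasible`, `violated`.
#' @export
optimize_portions <- function(foods, catalog, meal_type,
                              rdi = default_rdi_table(),
                              serving_table = default_serving_table(catalog),
                              config = portion_config(), seed = 1,
                              apply_constraints = TRUE) {
  if (!length(foods)) stop("need at least one food")
  if (anyDuplicated(foods)) stop("duplicate food codes")
  targets <- per_meal_targets(rdi, meal_type)
  dens <- catalog_density_matrix(catalog)[foods, , drop = FALSE]
  is_bev <- catalog$is_beverage[match(foods, catalog$code)]
  cats <- catalog$main_category[match(foods, catalog$code)]
  cfg <- config

  g <- init_portions(foods, serving_table, cfg$jitter_frac, seed)
  g <- pmin(pmax(g, cfg$min_grams), cfg$item_cap)
  obj <- function(gg) portion_objective(stats::setNames(gg, foods), dens, targets, cfg)
  cur <- obj(g)
  init_obj <- cur
  for (it in seq_len(cfg$iters)) {
    gr <- .portion_gradient(stats::setNames(g, foods), dens, targets, cfg)
    step <- cfg$step
    cand <- pmin(pmax(g - step * gr * 1000, cfg$min_grams), cfg$item_cap)
    newv <- obj(cand)
    # halve the step until improvement (backtracking)
    tries <- 0
    while (newv > cur && tries < 8) {
      step <- step / 2; tries <- tries + 1
      cand <- pmin(pmax(g - step * gr * 1000, cfg$min_grams), cfg$item_cap)
      newv <- obj(cand)
    }
    if (newv <= cur) {
      if ((cur - newv) / max(cur, 1e-12) < cfg$tol) { g <- cand; cur <- newv; break }
      g <- cand; cur <- newv
    } else break
  }
  # coordinate polish
  for (sw in seq_len(cfg$polish_sweeps)) {
    for (j in seq_along(g)) {
      f <- function(v) { gg <- g; gg[j] <- v; obj(gg) }
      opt <- stats::optimize(f, c(cfg$min_grams, cfg$item_cap))
      if (opt$objective < cur) { g[j] <- opt$minimum; cur <- opt$objective }
    }
  }
  names(g) <- foods

  report <- list()
  violated <- character(0)
  if (apply_constraints) {
    e_dens <- dens[, "energy_kcal"]
    # stage 1: per-item minimum
    before <- g
    g <- pmax(g, cfg$min_grams)
    report$min_grams <- list(satisfied = TRUE, adjusted = any(g != before))
    # stage 2: per-item and per-category caps
    before <- g
    g <- pmin(g, cfg$item_cap)
    for (ct in unique(cats)) {
      i <- which(cats == ct)
      cap <- if (ct == "beverages") min(cfg$category_cap, cfg$beverage_cap) else cfg$category_cap
      if (sum(g[i]) > cap) g[i] <- pmax(cfg$min_grams, g[i] * cap / sum(g[i]))
    }
    report$caps <- list(satisfied = all(g <= cfg$item_cap + 1e-9),
                        adjusted = any(g != before))
    # stage 3: energy retargeting (uniform rescale of non-capped items)
    g <- .retarget_energy(g, e_dens, targets$energy_kcal, cfg)
    e_now <- sum(g * e_dens)
    ok_e <- abs(e_now - targets$energy_kcal) / targets$energy_kcal <= cfg$energy_tol
    report$energy <- list(satisfied = ok_e, energy_kcal = e_now)
    if (!ok_e) violated <- c(violated, "energy")
    # stage 4: upper-bound-only limit caps (sodium, sugars, SFA)
    lim_n <- intersect(c("sodium", "total_sugars", "sat_fat"), names(targets$limit))
    adjusted4 <- FALSE
    for (rep_i in 1:20) {
      I <- as.numeric(g %*% dens); names(I) <- colnames(dens)
      exc <- I[lim_n] / targets$limit[lim_n]
      if (all(exc <= 1 + 1e-9)) break
      worst <- lim_n[which.max(exc)]
      contrib <- g * dens[, worst]
      j <- which.max(contrib)
      need <- I[worst] - targets$limit[worst]
      newg <- max(cfg$min_grams, g[j] - need / dens[j, worst])
      if (abs(newg - g[j]) < 1e-12) break  # floored: cannot reduce further
      g[j] <- newg; adjusted4 <- TRUE
    }
    I <- as.numeric(g %*% dens); names(I) <- colnames(dens)
    ok4 <- all(I[lim_n] <= targets$limit[lim_n] * (1 + 1e-6))
    report$limits <- list(satisfied = ok4, adjusted = adjusted4)
    if (!ok4) violated <- c(violated, "limits")
    # stage 5: beverage grams and beverage energy fraction
    adjusted5 <- FALSE
    if (any(is_bev)) {
      bg <- sum(g[is_bev])
      if (bg > cfg$beverage_cap) {
        g[is_bev] <- pmax(cfg$min_grams, g[is_bev] * cfg$beverage_cap / bg)
        adjusted5 <- TRUE
      }
      bev_k <- sum(g[is_bev] * e_dens[is_bev])
      non_k <- sum(g[!is_bev] * e_dens[!is_bev])
      # bev kcal <= frac * meal kcal  <=>  bev kcal <= frac/(1-frac) * non-bev kcal
      max_bev_k <- cfg$bev_kcal_frac / (1 - cfg$bev_kcal_frac) * non_k
      if (bev_k > max_bev_k && bev_k > 0) {
        g[is_bev] <- pmax(cfg$min_grams, g[is_bev] * max_bev_k / bev_k)
        adjusted5 <- TRUE
      }
    }
    bev_k <- sum(g[is_bev] * e_dens[is_bev])
    tot_k <- sum(g * e_dens)
    ok5 <- !any(is_bev) || tot_k == 0 || bev_k <= cfg$bev_kcal_frac * tot_k + 1e-9
    report$beverage <- list(satisfied = ok5, adjusted = adjusted5)
    if (!ok5) violated <- c(violated, "beverage")
    # stage 6: total-grams cap with rebalancing, then one energy re-target
    adjusted6 <- FALSE
    if (sum(g) > cfg$total_cap) {
      adjusted6 <- TRUE
      free <- g > cfg$min_grams
      excess <- sum(g) - cfg$total_cap
      g[free] <- pmax(cfg$min_grams,
                      g[free] - excess * g[free] / sum(g[free]))
      g <- .retarget_energy(g, e_dens, targets$energy_kcal, cfg,
                            gram_budget = cfg$total_cap)
      if (sum(g) > cfg$total_cap + 1e-9)
        g <- g * cfg$total_cap / sum(g)  # hard cap wins
    }
    e_now <- sum(g * e_dens)
    ok6 <- sum(g) <= cfg$total_cap + 1e-6
    ok_e2 <- abs(e_now - targets$energy_kcal) / targets$energy_kcal <= cfg$energy_tol
    report$total_grams <- list(satisfied = ok6, adjusted = adjusted6)
    if (!ok_e2 && !("energy" %in% violated)) violated <- c(violated, "energy")
    if (!ok6) violated <- c(violated, "total_grams")
  }

  totals <- as.numeric(g %*% dens); names(totals) <- colnames(dens)
  out <- list(
    foods = foods, grams = g, meal_type = meal_type,
    objective = portion_objective(g, dens, targets, cfg),
    init_objective = init_obj,
    totals = totals, energy_kcal = totals[["energy_kcal"]],
    targets = targets, report = report,
    feasible = length(violated) == 0, violated = violated
  )
  class(out) <- "portion_solution"
  out
}

# uniform rescale of non-capped items to hit the energy target; items at
# their bounds are frozen and the factor recomputed (few passes)
.retarget_energy <- function(g, e_dens, e_target, cfg, gram_budget = Inf) {
  for (pass in 1:5) {
    e_now <- sum(g * e_dens)
    if (e_now <= 0) break
    if (abs(e_now - e_target) / e_target <= cfg$energy_tol * 0.5) break
    fac <- e_target / e_now
    free <- if (fac > 1) g < cfg$item_cap - 1e-9 else g > cfg$min_grams + 1e-9
    if (!any(free)) break
    e_free <- sum(g[free] * e_dens[free])
    if (e_free <= 0) break
    fac_free <- (e_target - (e_now - e_free)) / e_free
    if (fac_free <= 0) break
    g[free] <- pmin(pmax(g[free] * fac_free, cfg$min_grams), cfg$item_cap)
    if (is.finite(gram_budget) && sum(g) > gram_budget) {
      g <- g * gram_budget / sum(g)
      g <- pmax(g, cfg$min_grams)
      break
    }
  }
  g
}

#' @export
print.portion_solution <- function(x, ...) {
  cat("Portion solution (", x$meal_type, "): ", length(x$foods), " items, ",
      sprintf("%.0f g total, %.0f kcal", sum(x$grams), x$energy_kcal),
      if (x$feasible) ", feasible" else
        paste0(", INFEASIBLE (", paste(x$violated, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Mean absolute RDI deviation
#'
#' Mean over the scoped nutrients of the fractional deviation from the
#' per-meal target: adequacy nutrients contribute `|I - t| / t`; limit
#' nutrients contribute `max(0, I - L) / L` (no credit for being under a
#' limit).
#'
#' @param intakes Named numeric nutrient totals.
#' @param targets Per-meal targets from [per_meal_targets()].
#' @param scope Optional character subset of nutrients to score (default:
#'   all adequacy + limit nutrients in `targets`).
#' @return Scalar mean deviation; attribute `per_nutrient` carries the
#'   percent-form per-nutrient deviations.
#' @export
rdi_deviation <- function(intakes, targets, scope = NULL) {
  adq <- names(targets$rdi); lim <- names(targets$limit)
  if (is.null(scope)) scope <- c(adq, lim)
  dev <- numeric(0)
  for (n in scope) {
    if (n %in% adq) dev[n] <- abs(intakes[[n]] - targets$rdi[[n]]) / targets$rdi[[n]]
    else if (n %in% lim) dev[n] <- max(0, intakes[[n]] - targets$limit[[n]]) / targets$limit[[n]]
    else stop("nutrient not in targets: ", n)
  }
  structure(mean(dev), per_nutrient = 100 * dev)
}
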