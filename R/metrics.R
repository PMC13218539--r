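# Nutritional quality metric suite: MER, MAR, AMDR composite, Hill
# diversity, energy density; bootstrap CIs; generated-vs-real comparison
# harness with FDR control; stratified cross-validation folds.

#' Mean Excess Ratio (MER)
#'
#' Average intake-to-upper-limit ratio over the limit nutrients: a
#' moderation score where lower is better and 1 means intakes sit at their
#' limits on average.
#'
#' @param intakes Named numeric intakes.
#' @param limits Named numeric upper limits (positive); the nutrients scored
#'   are `names(limits)`.
#' @return Mean of `intake / limit`.
#' @export
mer <- function(intakes, limits) {
  if (!length(limits)) stop("need at least one limit nutrient")
  if (any(limits <= 0)) stop("limits must be positive")
  miss <- setdiff(names(limits), names(intakes))
  if (length(miss)) stop("missing intake for: ", paste(miss, collapse = ", "))
  mean(intakes[names(limits)] / limits)
}

#' Mean Adequacy Ratio (MAR)
#'
#' Average over the 11 micronutrients of the capped Nutrient Adequacy Ratio
#' `min(1, intake / RDI)`.
#'
#' @param intakes Named numeric intakes covering all 11 MAR micronutrients.
#' @param rdis Named numeric RDIs for the micronutrients (defaults to the
#'   package RDI table).
#' @return MAR in [0, 1].
#' @export
mar <- function(intakes, rdis = default_rdi_table()$rdi[micro_nutrients()]) {
  micros <- micro_nutrients()
  miss <- setdiff(micros, names(intakes))
  if (length(miss)) stop("missing micronutrient intake: ", paste(miss, collapse = ", "))
  miss_r <- setdiff(micros, names(rdis))
  if (length(miss_r)) stop("missing micronutrient RDI: ", paste(miss_r, collapse = ", "))
  mean(pmin(1, intakes[micros] / rdis[micros]))
}

#' AMDR composite
#'
#' Fraction of the three macronutrients whose percent of total energy lies
#' within its Acceptable Macronutrient Distribution Range (inclusive
#' bounds).
#'
#' @param shares Named numeric percent-of-energy shares for `protein`,
#'   `fat`, `carbohydrate`.
#' @param bounds AMDR bounds table (default [amdr_bounds()]).
#' @return One of 0, 1/3, 2/3, 1.
#' @export
amdr_composite <- function(shares, bounds = amdr_bounds()) {
  e <- shares[bounds$macro]
  mean(e >= bounds$lower & e <= bounds$upper)
}

#' Hill diversity
#'
#' Effective number of groups `(sum p_i^q)^(1/(1-q))`, with the Shannon
#' exponential `exp(-sum p_i log p_i)` at q = 1. Zero-proportion groups are
#' excluded.
#'
#' @param p Nonnegative proportions summing to 1 (tolerance 1e-9).
#' @param q Diversity order (default 1).
#' @return Hill number (>= 1 when at least one group is present).
#' @export
hill_diversity <- function(p, q = 1) {
  if (any(p < 0)) stop("invalid argument: negative proportions")
  if (abs(sum(p) - 1) > 1e-9) stop("invalid argument: proportions must sum to 1")
  p <- p[p > 0]
  if (abs(q - 1) < 1e-12) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Energy density
#'
#' @param kcal Total meal energy (kcal).
#' @param grams Total meal mass (g), positive.
#' @return kcal per gram.
#' @export
energy_density <- function(kcal, grams) {
  if (grams <= 0) stop("invalid argument: grams must be positive")
  kcal / grams
}

#' Percentile bootstrap confidence interval
#'
#' @param values Numeric data (n >= 2).
#' @param statistic Function of a numeric vector (default mean).
#' @param n_boot Resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer RNG seed.
#' @return Named numeric: `estimate`, `lower`, `upper`.
#' @export
bootstrap_ci <- function(values, statistic = mean, n_boot = 1000,
                         level = 0.95, seed = 1) {
  if (length(values) < 2) stop("need at least 2 values")
  with_seed(seed, {
    est <- statistic(values)
    bs <- vapply(seq_len(n_boot), function(b)
      statistic(sample(values, replace = TRUE)), numeric(1))
    qs <- stats::quantile(bs, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    c(estimate = est, lower = qs[1], upper = qs[2])
  })
}

#' Per-meal metric report
#'
#' Computes the five evaluation metrics plus the RDI deviation for every
#' meal in a corpus, against per-meal targets scaled by the meal-type share.
#'
#' @param corpus A `meal_corpus`.
#' @param catalog A `food_catalog`.
#' @param rdi An RDI table ([default_rdi_table()]).
#' @param shares Meal shares ([meal_shares()]).
#' @return Data.frame, one row per meal: `meal_id`, `meal_type`, `mer`,
#'   `mar`, `amdr`, `diversity`, `energy_density`, `rdi_deviation`.
#' @export
metric_report <- function(corpus, catalog, rdi = default_rdi_table(),
                          shares = meal_shares()) {
  validate_rdi_table(rdi)
  tot <- meal_nutrient_totals(corpus, catalog)
  idx <- meal_index(corpus)
  grams_tot <- tapply(corpus$grams, corpus$meal_id, sum)[idx$meal_id]
  cat_of <- catalog$main_category[match(corpus$food_code, catalog$code)]
  lim_n <- intersect(c("sodium", "sat_fat", "added_sugars"), names(rdi$limit))
  out <- lapply(seq_len(nrow(idx)), function(i) {
    id <- idx$meal_id[i]; mt <- idx$meal_type[i]
    s <- shares[[mt]]
    I <- tot[id, ]
    macroE <- c(protein = 4 * I[["protein"]], fat = 9 * I[["fat"]],
                carbohydrate = 4 * I[["carbohydrate"]])
    sh <- if (sum(macroE) > 0) 100 * macroE / sum(macroE) else macroE * 0
    rowsi <- corpus$meal_id == id
    gr <- tapply(corpus$grams[rowsi], cat_of[rowsi], sum)
    tg <- per_meal_targets(rdi, mt, shares)
    data.frame(
      meal_id = id, meal_type = mt,
      mer = mer(I, s * rdi$limit[lim_n]),
      mar = mar(I, s * rdi$rdi[micro_nutrients()]),
      amdr = amdr_composite(sh),
      diversity = hill_diversity(as.numeric(gr) / sum(gr)),
      energy_density = energy_density(I[["energy_kcal"]], grams_tot[[id]]),
      rdi_deviation = rdi_deviation(I, tg),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Compare generated vs real meals by cluster
#'
#' For each cluster: a bootstrap CI of the mean difference in per-meal RDI
#' deviation (generated minus real; an improvement is flagged when the 95%
#' interval lies below zero), and the percent reduction of the cluster-level
#' median deviation. Also reports the overall median percent reduction
#' across clusters with a bootstrap CI, and BH-adjusted q-values across the
#' per-cluster tests. Clusters present in only one set are skipped with a
#' warning. Percent reduction is `NA` ("not applicable") when the real
#' median deviation is 0.
#'
#' @param gen,real Data.frames with columns `rdi_deviation` and `cluster`
#'   (e.g., [metric_report()] output plus a `cluster` column).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer RNG seed.
#' @return List with `by_cluster` (data.frame) and `overall` (named
#'   numeric: median percent reduction + CI + fraction improved).
#' @export
compare_generated_vs_real <- function(gen, real, n_boot = 1000, seed = 1) {
  common <- intersect(unique(gen$cluster), unique(real$cluster))
  only <- c(setdiff(unique(gen$cluster), common), setdiff(unique(real$cluster), common))
  if (length(only)) warning("skipping cluster(s) present in one set only: ",
                            paste(only, collapse = ", "))
  rows <- lapply(common, function(c1) {
    g <- gen$rdi_deviation[gen$cluster == c1]
    r <- real$rdi_deviation[real$cluster == c1]
    ci <- with_seed(seed + as.integer(factor(c1, levels = common)), {
      bs <- vapply(seq_len(n_boot), function(b)
        mean(sample(g, replace = TRUE)) - mean(sample(r, replace = TRUE)),
        numeric(1))
      stats::quantile(bs, c(0.025, 0.975), names = FALSE)
    })
    med_r <- stats::median(r); med_g <- stats::median(g)
    pct <- if (med_r == 0) NA_real_ else 100 * (med_r - med_g) / med_r
    p <- tryCatch(suppressWarnings(stats::wilcox.test(g, r)$p.value),
                  error = function(e) NA_real_)
    data.frame(cluster = c1, n_gen = length(g), n_real = length(r),
               diff_lower = ci[1], diff_upper = ci[2],
               improved = ci[2] < 0, pct_reduction = pct, p_value = p,
               stringsAsFactors = FALSE)
  })
  by_cluster <- do.call(rbind, rows)
  by_cluster$q_value <- stats::p.adjust(by_cluster$p_value, method = "BH")
  pr <- by_cluster$pct_reduction[!is.na(by_cluster$pct_reduction)]
  overall <- if (length(pr) >= 2) {
    ci <- bootstrap_ci(pr, stats::median, n_boot = n_boot, seed = seed)
    c(median_pct_reduction = unname(ci["estimate"]),
      lower = unname(ci["lower"]), upper = unname(ci["upper"]),
      frac_improved = mean(by_cluster$improved))
  } else c(median_pct_reduction = if (length(pr)) pr else NA_real_,
           lower = NA_real_, upper = NA_real_,
           frac_improved = mean(by_cluster$improved))
  list(by_cluster = by_cluster, overall = overall)
}

#' Cross-validated generator evaluation
#'
#' Trains the meal generator on k-1 folds and evaluates held-out
#' reconstruction micro-F1 on the remaining fold, for each fold of a
#' stratified (cluster, meal type) split. With `leakage_safe = TRUE` the
#' feature standardization and clustering are re-fit on each training fold
#' and the held-out fold's label agreement (ARI) with the baseline
#' clustering is reported alongside.
#'
#' @param corpus A `meal_corpus` (labeled meals only).
#' @param catalog A `food_catalog`.
#' @param clusters Named cluster labels (by meal id; no noise meals).
#' @param k Number of folds (default 5).
#' @param seed Integer RNG seed.
#' @param config A [cvae_config()]; use a scaled-down one for desk runs.
#' @param leakage_safe Re-fit standardization + clustering per fold
#'   (default FALSE).
#' @param ... Passed to [cluster_meals()] when `leakage_safe`.
#' @return Data.frame, one row per fold: `fold`, `n_train`, `n_test`,
#'   `f1_holdout`, and `label_ari` when `leakage_safe`.
#' @export
crossval_harness <- function(corpus, catalog, clusters, k = 5, seed = 1,
                             config = cvae_config(hidden = 64, latent_dim = 16,
                                                  epochs = 30),
                             leakage_safe = FALSE, ...) {
  idx <- meal_index(corpus)
  idx <- idx[idx$meal_id %in% names(clusters), ]
  cl <- clusters[idx$meal_id]
  folds <- crossval_folds(idx$meal_id, cl, idx$meal_type, k = k, seed = seed)
  pb <- binarize(corpus)
  X <- do.call(rbind, lapply(pb, function(m)
    m[intersect(rownames(m), idx$meal_id), , drop = FALSE]))
  X <- X[idx$meal_id, , drop = FALSE]
  rows <- lapply(seq_len(k), function(f) {
    test <- which(folds[idx$meal_id] == f)
    cfg <- config
    cfg$seed <- config$seed + f
    model <- cvae(X, cl, idx$meal_type, config = cfg, holdout = test)
    out <- data.frame(fold = f, n_train = nrow(X) - length(test),
                      n_test = length(test), f1_holdout = model$f1_holdout)
    if (leakage_safe) {
      tr_ids <- idx$meal_id[-test]
      sub <- corpus[corpus$meal_id %in% tr_ids, ]
      class(sub) <- c("meal_corpus", "data.frame")
      feats <- extract_features(sub, catalog)
      agree <- vapply(names(feats), function(mt) {
        lab <- tryCatch(cluster_meals(feats[[mt]], ...),
                        error = function(e) NULL)
        if (is.null(lab)) return(NA_real_)
        common <- intersect(names(lab), names(clusters))
        if (length(common) < 2) return(NA_real_)
        ari(lab[common], clusters[common])
      }, numeric(1))
      out$label_ari <- mean(agree, na.rm = TRUE)
    }
    out
  })
  do.call(rbind, rows)
}

#' Stratified cross-validation folds
#'
#' Assigns meals to k folds stratified by (cluster, meal type): within each
#' stratum, meals are shuffled and dealt round-robin, so per-fold cluster
#' proportions match the global ones to within one meal. Clusters smaller
#' than k are merged into the largest cluster of the same meal type for
#' folding, with a warning.
#'
#' @param meal_ids Character meal ids.
#' @param clusters,meal_types Labels aligned to `meal_ids`.
#' @param k Number of folds (default 5).
#' @param seed Integer RNG seed.
#' @return Integer fold assignment (1..k) named by meal id.
#' @export
crossval_folds <- function(meal_ids, clusters, meal_types, k = 5, seed = 1) {
  strat <- paste(meal_types, clusters, sep = ":")
  tab <- table(strat)
  small <- names(tab)[tab < k]
  if (length(small)) {
    warning("merging stratum(s) smaller than k into largest same-type stratum: ",
            paste(small, collapse = ", "))
    for (s in small) {
      mt <- sub(":.*", "", s)
      cand <- names(tab)[startsWith(names(tab), paste0(mt, ":")) & !(names(tab) %in% small)]
      tgt <- if (length(cand)) cand[which.max(tab[cand])] else names(tab)[which.max(tab)]
      strat[strat == s] <- tgt
    }
  }
  with_seed(seed, {
    fold <- integer(length(meal_ids))
    for (s in unique(strat)) {
      i <- which(strat == s)
      i <- i[sample.int(length(i))]
      fold[i] <- rep_len(seq_len(k), length(i))
    }
    stats::setNames(fold, meal_ids)
  })
}
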