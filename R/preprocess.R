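# Corpus cleaning and compression: food-code harmonization, presence
# binarization, Local Outlier Factor meal filtering, nutrient-aware
# prototype aggregation (greedy facility location), and bootstrap-based
# ingredient filtering.

#' Harmonize food codes
#'
#' Applies a code mapping to a corpus. Codes with action `expanded`,
#' `consolidated` or `renumbered` are replaced by their most recent code
#' (following chains transitively); `dropped` and `revised` codes are kept
#' unchanged. Duplicate foods created by consolidation are merged by summing
#' grams. Idempotent after closure.
#'
#' @param corpus A `meal_corpus`.
#' @param mapping A data.frame with columns `old_code`, `action` (one of
#'   expanded/consolidated/renumbered/dropped/revised), `new_code`
#'   (NA for dropped/revised).
#' @return The harmonized `meal_corpus`.
#' @export
harmonize_codes <- function(corpus, mapping) {
  acts <- c("expanded", "consolidated", "renumbered", "dropped", "revised")
  if (!all(mapping$action %in% acts))
    stop("unknown mapping action(s): ",
         paste(setdiff(mapping$action, acts), collapse = ", "))
  active <- mapping[mapping$action %in% c("expanded", "consolidated", "renumbered"), ]
  if (any(is.na(active$new_code) | active$new_code == ""))
    stop("expanded/consolidated/renumbered rows must carry a new code")
  map <- stats::setNames(active$new_code, active$old_code)
  # transitive closure with cycle detection
  closed <- map
  for (o in names(map)) {
    seen <- o
    cur <- map[[o]]
    while (cur %in% names(map)) {
      if (cur %in% seen)
        stop("mapping cycle: ", paste(c(seen, cur), collapse = " -> "))
      seen <- c(seen, cur)
      cur <- map[[cur]]
    }
    closed[[o]] <- cur
  }
  x <- as.data.frame(corpus)
  hit <- x$food_code %in% names(closed)
  x$food_code[hit] <- unname(closed[x$food_code[hit]])
  # merge duplicates created by consolidation, summing grams
  key <- paste(x$meal_id, x$food_code, sep = "\r")
  if (anyDuplicated(key)) {
    grams <- tapply(x$grams, key, sum)
    first <- x[!duplicated(key), ]
    first$grams <- as.numeric(grams[paste(first$meal_id, first$food_code, sep = "\r")])
    x <- first[order(match(first$meal_id, unique(corpus$meal_id))), ]
  }
  rownames(x) <- NULL
  class(x) <- c("meal_corpus", "data.frame")
  x
}

#' Binarize a corpus to presence matrices
#'
#' One binary meals-by-foods matrix per meal type; an entry is 1 iff the
#' meal contains positive grams of the food.
#'
#' @param corpus A `meal_corpus`.
#' @param foods Optional food-code universe (default: codes seen in corpus,
#'   sorted).
#' @return Named list (by meal type) of binary matrices with meal ids as
#'   rownames and food codes as colnames; class `presence_matrix`.
#' @export
binarize <- function(corpus, foods = NULL) {
  if (nrow(corpus) == 0) stop("empty corpus")
  if (is.null(foods)) foods <- sort(unique(corpus$food_code))
  out <- lapply(split(as.data.frame(corpus), corpus$meal_type), function(d) {
    meals <- unique(d$meal_id)
    m <- matrix(0L, length(meals), length(foods),
                dimnames = list(meals, foods))
    m[cbind(match(d$meal_id, meals), match(d$food_code, foods))] <- 1L
    m
  })
  structure(out, class = "presence_matrix")
}

#' Local Outlier Factor scores
#'
#' Classic LOF: for each point, the mean ratio of its neighbours' local
#' reachability density to its own. Scores well above 1 indicate outliers.
#'
#' @param x Numeric matrix (observations x features).
#' @param k Neighbourhood size (default 20).
#' @return Numeric vector of LOF scores.
#' @export
lof_scores <- function(x, k = 20) {
  n <- nrow(x)
  if (n < k + 1) stop("need more than k observations")
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  # k-distance and k-neighbourhood (ties included)
  kdist <- apply(d, 1, function(r) sort(r, partial = k)[k])
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= kdist[i] + 1e-12))
  lrd <- vapply(seq_len(n), function(i) {
    rd <- pmax(kdist[nbrs[[i]]], d[i, nbrs[[i]]])
    1 / pmax(mean(rd), .Machine$double.eps)
  }, numeric(1))
  vapply(seq_len(n), function(i) mean(lrd[nbrs[[i]]]) / lrd[i], numeric(1))
}

#' Filter outlier meals by LOF
#'
#' Removes the `round(contamination * n)` meals with the most extreme
#' (largest) LOF scores.
#'
#' @param features Numeric matrix (meals x features) with meal ids as
#'   rownames.
#' @param contamination Fraction to remove, in (0, 0.5); default 0.003.
#' @param k LOF neighbourhood size (default 20).
#' @return List with `retained` and `removed` meal id vectors and `scores`.
#' @export
lof_filter <- function(features, contamination = 0.003, k = 20) {
  n <- nrow(features)
  if (n < 20) stop("need at least 20 meals")
  if (contamination <= 0 || contamination >= 0.5)
    stop("invalid argument: contamination must be in (0, 0.5)")
  n_remove <- round(contamination * n)
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n_remove == 0)
    return(list(retained = ids, removed = character(0),
                scores = stats::setNames(rep(NA_real_, n), ids)))
  sc <- lof_scores(features, k = min(k, n - 1))
  ord <- order(-sc, ids)  # most extreme first, ties by id
  removed <- ids[ord[seq_len(n_remove)]]
  list(retained = setdiff(ids, removed), removed = removed,
       scores = stats::setNames(sc, ids))
}

# cosine similarity of columns of a against vector b (or matrix rows)
.cosine_mat <- function(m, v) {
  num <- as.numeric(m %*% v)
  den <- sqrt(rowSums(m^2)) * sqrt(sum(v^2))
  ifelse(den > 0, num / den, 0)
}

# fidelity of a prototype assignment within one subcategory
# totals reconstructed with each food's grams at its prototype's density
.fidelity <- function(dens, w, proto_idx, metric = "mare") {
  tot <- colSums(dens * w)
  rec <- colSums(dens[proto_idx, , drop = FALSE] * w)
  if (metric == "mare") {
    keep <- tot > 0
    if (!any(keep)) return(0)
    mean(abs(tot[keep] - rec[keep]) / tot[keep])
  } else { # weighted cosine error
    den <- sqrt(sum(tot^2)) * sqrt(sum(rec^2))
    if (den == 0) return(0)
    1 - sum(tot * rec) / den
  }
}

#' Nutrient-aware prototype aggregation
#'
#' Compresses the food space per subcategory by greedy facility location:
#' prototypes are added until the consumed-gram-weighted mass coverage
#' reaches `coverage_min` and the nutrient fidelity error falls to
#' `fidelity_max`. Each food is then assigned to its nearest prototype by
#' nutrient-density cosine similarity, provided the similarity is at least
#' `sim_floor`; otherwise the food becomes its own prototype. Ties are broken
#' lexicographically by food code.
#'
#' @param catalog A `food_catalog`.
#' @param corpus A `meal_corpus` supplying food weights (total grams
#'   consumed).
#' @param coverage_min Minimum weighted mass coverage (default 0.90).
#' @param fidelity_max Maximum fidelity error (default 0.07).
#' @param sim_floor Assignment similarity floor (default 0.70).
#' @param fidelity_metric `"mare"` (mean absolute relative error of
#'   reconstructed nutrient totals, default) or `"wcos"` (weighted cosine
#'   error).
#' @return A `prototype_map`: list with `assignment` (data.frame: `food`,
#'   `subcategory`, `prototype`, `similarity`) and `summary` (per
#'   subcategory: `coverage`, `fidelity`, `n_foods`, `n_prototypes`).
#' @export
aggregate_prototypes <- function(catalog, corpus,
                                 coverage_min = 0.90, fidelity_max = 0.07,
                                 sim_floor = 0.70,
                                 fidelity_metric = c("mare", "wcos")) {
  fidelity_metric <- match.arg(fidelity_metric)
  dens_all <- catalog_density_matrix(catalog)
  w_all <- tapply(corpus$grams, corpus$food_code, sum)
  weights <- stats::setNames(rep(0, nrow(catalog)), catalog$code)
  weights[names(w_all)] <- as.numeric(w_all)

  assign_rows <- list()
  summ_rows <- list()
  for (sc in sort(unique(catalog$subcategory))) {
    idx <- which(catalog$subcategory == sc)
    idx <- idx[order(catalog$code[idx])]
    codes <- catalog$code[idx]
    dens <- dens_all[codes, , drop = FALSE]
    w <- weights[codes]
    if (sum(w) == 0) w[] <- 1  # unconsumed subcategory: uniform weights
    w <- w / sum(w)
    nf <- length(codes)
    sim <- if (nf > 1) {
      nrm <- dens / pmax(sqrt(rowSums(dens^2)), .Machine$double.eps)
      tcrossprod(nrm)
    } else matrix(1, 1, 1)
    dimnames(sim) <- list(codes, codes)

    sel <- integer(0)
    repeat {
      if (length(sel)) {
        best_sim <- apply(sim[, sel, drop = FALSE], 1, max)
        nearest <- sel[max.col(sim[, sel, drop = FALSE], ties.method = "first")]
        covered <- best_sim >= sim_floor
        coverage <- sum(w[covered])
        proto_idx <- ifelse(covered, nearest, seq_len(nf))  # fallback: self
        fid <- .fidelity(dens, w, proto_idx, fidelity_metric)
      } else {
        coverage <- 0; fid <- Inf
      }
      if ((coverage >= coverage_min && fid <= fidelity_max) || length(sel) == nf)
        break
      cand <- setdiff(seq_len(nf), sel)
      if (coverage < coverage_min) {
        # marginal covered weight; ties broken by (already sorted) code order
        gain <- vapply(cand, function(j) {
          bs <- if (length(sel)) pmax(apply(sim[, sel, drop = FALSE], 1, max), sim[, j]) else sim[, j]
          sum(w[bs >= sim_floor])
        }, numeric(1))
        sel <- c(sel, cand[which.max(gain)])
      } else {
        # coverage met but fidelity too high: add the food that most reduces it
        fids <- vapply(cand, function(j) {
          s2 <- c(sel, j)
          bs <- apply(sim[, s2, drop = FALSE], 1, max)
          nr <- s2[max.col(sim[, s2, drop = FALSE], ties.method = "first")]
          pi2 <- ifelse(bs >= sim_floor, nr, seq_len(nf))
          .fidelity(dens, w, pi2, fidelity_metric)
        }, numeric(1))
        sel <- c(sel, cand[which.min(fids)])
      }
    }
    # final assignment with self-prototype fallback
    best_sim <- apply(sim[, sel, drop = FALSE], 1, max)
    nearest <- sel[max.col(sim[, sel, drop = FALSE], ties.method = "first")]
    self <- best_sim < sim_floor
    proto <- ifelse(self, codes, codes[nearest])
    similarity <- ifelse(self, 1, best_sim)
    proto[sel] <- codes[sel]  # prototypes map to themselves
    similarity[sel] <- 1
    proto_idx <- match(proto, codes)
    fid <- .fidelity(dens, w, proto_idx, fidelity_metric)
    coverage <- sum(w[similarity >= sim_floor])
    assign_rows[[sc]] <- data.frame(
      food = codes, subcategory = sc, prototype = proto,
      similarity = similarity, stringsAsFactors = FALSE
    )
    summ_rows[[sc]] <- data.frame(
      subcategory = sc, coverage = coverage, fidelity = fid,
      n_foods = nf, n_prototypes = length(unique(proto)),
      stringsAsFactors = FALSE
    )
  }
  out <- list(
    assignment = do.call(rbind, c(assign_rows, make.row.names = FALSE)),
    summary = do.call(rbind, c(summ_rows, make.row.names = FALSE)),
    params = list(coverage_min = coverage_min, fidelity_max = fidelity_max,
                  sim_floor = sim_floor, fidelity_metric = fidelity_metric)
  )
  class(out) <- "prototype_map"
  out
}

#' @export
print.prototype_map <- function(x, ...) {
  cat("Prototype map:", nrow(x$assignment), "foods ->",
      length(unique(x$assignment$prototype)), "prototypes in",
      nrow(x$summary), "subcategories\n")
  cat(sprintf("min coverage %.3f, max fidelity %.4f\n",
              min(x$summary$coverage), max(x$summary$fidelity)))
  invisible(x)
}

#' Apply a prototype map to a corpus
#'
#' Replaces each food by its prototype; duplicate prototypes within a meal
#' are merged by summing grams.
#'
#' @param corpus A `meal_corpus`.
#' @param pmap A `prototype_map`.
#' @return The compressed `meal_corpus`.
#' @export
apply_prototypes <- function(corpus, pmap) {
  map <- stats::setNames(pmap$assignment$prototype, pmap$assignment$food)
  mapping <- data.frame(old_code = names(map), action = "consolidated",
                        new_code = unname(map), stringsAsFactors = FALSE)
  mapping <- mapping[mapping$old_code != mapping$new_code, ]
  harmonize_codes(corpus, mapping)
}

#' Bootstrap ingredient filter
#'
#' For each food, a percentile bootstrap confidence interval of its mean
#' presence across meals; the food is removed when the CI lower bound does
#' not exceed `threshold` (default 0), i.e., when the bootstrap cannot bound
#' its prevalence away from zero.
#'
#' @param m Binary presence matrix (meals x foods).
#' @param n_boot Bootstrap resamples (>= 100; default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer RNG seed.
#' @param threshold Removal comparison value for the lower bound (default 0).
#' @return List with `retained`, `removed` food-code vectors and
#'   `lower_bounds` (named numeric).
#' @export
bootstrap_ingredient_filter <- function(m, n_boot = 1000, level = 0.95, seed = 1,
                                        threshold = 0) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  n <- nrow(m)
  with_seed(seed, {
    # resample rows; bootstrap means via counts %*% matrix
    W <- matrix(0L, n_boot, n)
    for (b in seq_len(n_boot))
      W[b, ] <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
    means <- (W %*% m) / n
    lower <- apply(means, 2, stats::quantile, probs = (1 - level) / 2,
                   names = FALSE)
    names(lower) <- colnames(m)
    removed <- colnames(m)[lower <= threshold]
    list(retained = setdiff(colnames(m), removed), removed = removed,
         lower_bounds = lower)
  })
}
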