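# Density-based meal archetype discovery: an HDBSCAN*-style clusterer
# (core distances -> mutual reachability -> single-linkage hierarchy ->
# condensed tree -> excess-of-mass selection) with centroid-cosine cluster
# merging as post-processing, plus cluster profiling and subsample
# stability.

# HDBSCAN* labels for a feature matrix. Returns integer labels, -1 = noise.
hdbscan_labels <- function(x, min_cluster_size = 15, min_samples = 5) {
  n <- nrow(x)
  if (min_cluster_size < 2) stop("min_cluster_size must be >= 2")
  d <- as.matrix(stats::dist(x))
  diag(d) <- 0
  core <- apply(d, 1, function(r) sort(r)[min_samples + 1L])  # dist to k-th NN
  mrd <- pmax(d, outer(core, core, pmax))
  diag(mrd) <- 0
  hc <- stats::hclust(stats::as.dist(mrd), method = "single")

  # leaves under each internal dendrogram node
  leaves <- vector("list", n - 1L)
  node_size <- integer(n - 1L)
  for (k in seq_len(n - 1L)) {
    ch <- hc$merge[k, ]
    lv <- c(if (ch[1] < 0) -ch[1] else NULL, if (ch[1] > 0) leaves[[ch[1]]],
            if (ch[2] < 0) -ch[2] else NULL, if (ch[2] > 0) leaves[[ch[2]]])
    leaves[[k]] <- lv
    node_size[k] <- length(lv)
  }

  # condensed tree
  cl_birth <- 0          # per condensed cluster: birth lambda
  cl_parent <- NA_integer_
  cl_children <- list(integer(0))
  cl_stab <- 0
  n_clusters <- 1L
  fallout_cluster <- integer(n)   # condensed cluster each point exits from
  fallout_lambda <- numeric(n)
  stack <- list(list(node = n - 1L, cluster = 1L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    k <- fr$node; cl <- fr$cluster
    h <- hc$height[k]
    lam <- 1 / max(h, 1e-12)
    ch <- hc$merge[k, ]
    sz <- ifelse(ch < 0, 1L, node_size[pmax(ch, 1L)])
    get_leaves <- function(c1) if (c1 < 0) -c1 else leaves[[c1]]
    if (all(sz >= min_cluster_size)) {
      # true split: two child clusters born at lam
      for (side in 1:2) {
        n_clusters <- n_clusters + 1L
        cl_birth[n_clusters] <- lam
        cl_parent[n_clusters] <- cl
        cl_children[[n_clusters]] <- integer(0)
        cl_stab[n_clusters] <- 0
        cl_children[[cl]] <- c(cl_children[[cl]], n_clusters)
        stack[[length(stack) + 1L]] <- list(node = ch[side], cluster = n_clusters)
      }
      cl_stab[cl] <- cl_stab[cl] + (lam - cl_birth[cl]) * sum(sz)
    } else {
      big <- which(sz >= min_cluster_size)
      small <- setdiff(1:2, big)
      for (side in small) {
        pts <- get_leaves(ch[side])
        fallout_cluster[pts] <- cl
        fallout_lambda[pts] <- lam
        cl_stab[cl] <- cl_stab[cl] + (lam - cl_birth[cl]) * length(pts)
      }
      for (side in big) {
        if (ch[side] < 0) { # singleton can't be >= mcs when mcs >= 2
          pts <- get_leaves(ch[side])
          fallout_cluster[pts] <- cl
          fallout_lambda[pts] <- lam
          cl_stab[cl] <- cl_stab[cl] + (lam - cl_birth[cl]) * length(pts)
        } else {
          stack[[length(stack) + 1L]] <- list(node = ch[side], cluster = cl)
        }
      }
    }
  }

  # excess-of-mass selection; root eligible only if it never split
  selected <- logical(n_clusters)
  s_hat <- cl_stab
  ord <- order(cl_birth, decreasing = TRUE)  # deepest first
  for (c1 in ord) {
    kids <- cl_children[[c1]]
    if (!length(kids)) { selected[c1] <- TRUE; next }
    kid_sum <- sum(s_hat[kids])
    if (c1 == 1L) { selected[c1] <- FALSE; s_hat[c1] <- kid_sum; next }
    if (cl_stab[c1] > kid_sum) {
      selected[c1] <- TRUE
      # deselect entire subtree
      sub <- kids
      while (length(sub)) {
        selected[sub] <- FALSE
        sub <- unlist(cl_children[sub])
      }
      s_hat[c1] <- cl_stab[c1]
    } else s_hat[c1] <- kid_sum
  }

  # map each point to the selected ancestor of its fallout cluster
  labels <- rep(-1L, n)
  anc_cache <- new.env()
  for (i in seq_len(n)) {
    c1 <- fallout_cluster[i]
    while (!is.na(c1)) {
      if (selected[c1]) { labels[i] <- c1; break }
      c1 <- cl_parent[c1]
    }
  }
  # renumber by decreasing size, 1..K
  tab <- sort(table(labels[labels > 0]), decreasing = TRUE)
  remap <- stats::setNames(seq_along(tab), names(tab))
  labels[labels > 0] <- as.integer(remap[as.character(labels[labels > 0])])
  labels
}

#' Cluster meals into archetypes
#'
#' HDBSCAN*-style density clustering on the hybrid feature matrix, followed
#' by post-processing merging: cluster pairs whose centroids have cosine
#' similarity at least `merge_threshold` are merged iteratively (most
#' similar pair first) until none qualify.
#'
#' @param features Numeric matrix (meals x features), z-scored; meal ids as
#'   rownames.
#' @param min_cluster_size Minimum cluster size; default
#'   `max(15, nrow(features) / 200)`.
#' @param min_samples Core-distance neighbourhood size (default 5).
#' @param merge_threshold Centroid cosine merge threshold (default 0.95);
#'   1.0 disables merging of non-identical centroids.
#' @return Integer vector of labels named by meal id; -1 marks noise meals.
#' @export
cluster_meals <- function(features, min_cluster_size = NULL, min_samples = 5,
                          merge_threshold = 0.95) {
  n <- nrow(features)
  if (is.null(min_cluster_size))
    min_cluster_size <- max(15, round(n / 200))
  if (n < 10 * min_cluster_size)
    stop("too few meals for min_cluster_size ", min_cluster_size,
         "; need at least ", 10 * min_cluster_size)
  labels <- hdbscan_labels(features, min_cluster_size, min_samples)
  if (all(labels == -1L))
    stop("all meals labelled noise; decrease min_cluster_size or min_samples")
  labels <- merge_clusters(features, labels, merge_threshold)
  stats::setNames(labels, rownames(features))
}

# iterative centroid-cosine merging
merge_clusters <- function(features, labels, threshold) {
  repeat {
    ids <- sort(unique(labels[labels > 0]))
    if (length(ids) < 2) break
    cent <- t(vapply(ids, function(c1) colMeans(features[labels == c1, , drop = FALSE]),
                     numeric(ncol(features))))
    nrm <- cent / pmax(sqrt(rowSums(cent^2)), .Machine$double.eps)
    sim <- tcrossprod(nrm)
    diag(sim) <- -Inf
    if (max(sim) < threshold) break
    best <- which(sim == max(sim), arr.ind = TRUE)[1, ]
    keep <- ids[min(best)]; drop <- ids[max(best)]
    labels[labels == drop] <- keep
  }
  ids <- sort(unique(labels[labels > 0]))
  remap <- stats::setNames(seq_along(ids), ids)
  labels[labels > 0] <- as.integer(remap[as.character(labels[labels > 0])])
  labels
}

#' Statistically profile clusters
#'
#' For each cluster (noise excluded) and feature: within-cluster mean,
#' complement mean, their difference on the z scale, a Welch t-test p-value,
#' a Benjamini-Hochberg q-value across all cluster-feature tests, Cohen's d
#' (pooled SD), and flags: `significant` (q <= 0.01 and |delta| >= 0.15) and
#' `distinctive` (|delta| >= 0.20). Clusters smaller than 3 are marked
#' unstable and their tests skipped.
#'
#' @param features Numeric matrix (meals x features).
#' @param labels Integer labels aligned to rows; -1 = noise.
#' @param q_max Significance q-value threshold (default 0.01).
#' @param delta_sig,delta_dist Mean-difference thresholds (0.15 / 0.20).
#' @return A `cluster_profiles` data.frame, one row per cluster-feature.
#' @export
profile_clusters <- function(features, labels, q_max = 0.01,
                             delta_sig = 0.15, delta_dist = 0.20) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) < 2) stop("need at least 2 clusters (excluding noise)")
  keep <- labels > 0
  rows <- list()
  for (c1 in ids) {
    inc <- keep & labels == c1
    outc <- keep & labels != c1
    unstable <- sum(inc) < 3
    for (j in seq_len(ncol(features))) {
      a <- features[inc, j]; b <- features[outc, j]
      delta <- mean(a) - mean(b)
      if (unstable) { p <- NA_real_; d <- NA_real_ }
      else {
        p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) {
          if (abs(delta) < 1e-12) 1 else 0
        })
        sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
                     (length(a) + length(b) - 2))
        d <- if (sp > 0) delta / sp else ifelse(abs(delta) < 1e-12, 0, sign(delta) * Inf)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = c1, n_meals = sum(inc), feature = colnames(features)[j],
        mean_in = mean(a), mean_out = mean(b), delta = delta,
        p_value = p, cohens_d = d, unstable = unstable,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  tested <- !is.na(out$p_value)
  out$q_value[tested] <- stats::p.adjust(out$p_value[tested], method = "BH")
  out$significant <- !is.na(out$q_value) & out$q_value <= q_max &
    abs(out$delta) >= delta_sig
  out$distinctive <- abs(out$delta) >= delta_dist & !out$unstable
  class(out) <- c("cluster_profiles", "data.frame")
  out
}

#' Adjusted Rand Index
#'
#' Chance-corrected agreement between two labelings.
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in [-1, 1].
#' @export
ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' Subsample-and-recluster stability
#'
#' Repeatedly subsamples a fraction of meals, reclusters, and computes the
#' ARI against the baseline labels restricted to the subsample — both over
#' all subsampled meals and restricted to meals that are non-noise in both
#' labelings.
#'
#' @param features Feature matrix with meal ids as rownames.
#' @param baseline Baseline labels (named, aligned to rows).
#' @param n_subsamples Number of subsamples (default 20).
#' @param frac Subsample fraction (default 0.8).
#' @param seed Integer RNG seed.
#' @param ... Passed to [cluster_meals()].
#' @return List with `ari` and `ari_non_noise` vectors plus `median` and
#'   95% percentile `ci` of the all-meals ARI.
#' @export
stability_ari <- function(features, baseline, n_subsamples = 20, frac = 0.8,
                          seed = 1, ...) {
  n <- nrow(features)
  with_seed(seed, {
    all_ari <- nn_ari <- numeric(n_subsamples)
    for (s in seq_len(n_subsamples)) {
      idx <- sort(sample.int(n, round(frac * n)))
      lab <- tryCatch(cluster_meals(features[idx, , drop = FALSE], ...),
                      error = function(e) rep(-1L, length(idx)))
      base <- baseline[idx]
      all_ari[s] <- ari(lab, base)
      nn <- lab != -1L & base != -1L
      nn_ari[s] <- if (sum(nn) > 1) ari(lab[nn], base[nn]) else NA_real_
    }
    list(ari = all_ari, ari_non_noise = nn_ari,
         median = stats::median(all_ari),
         ci = stats::quantile(all_ari, c(0.025, 0.975), names = FALSE))
  })
}
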