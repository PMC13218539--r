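# End-to-end orchestration: synth -> preprocess -> cluster -> train ->
# sample -> portion -> evaluate -> substitute, from a single config, with
# derived per-stage seeds and a structured run report.

#' Default pipeline configuration
#'
#' @param seed Global seed; per-stage seeds are derived deterministically
#'   from it and the stage name, so stage results do not depend on
#'   execution order.
#' @param out_dir Output directory for intermediate artifacts (NULL keeps
#'   everything in memory).
#' @param n_foods,n_categories,archetypes_per_type,n_meals Synthetic corpus
#'   dimensions.
#' @param contamination LOF removal fraction.
#' @param n_boot_filter Bootstrap resamples for the ingredient filter.
#' @param cvae CVAE config ([cvae_config()]); a scaled-down default is used
#'   here.
#' @param n_sample Generated meals per (cluster, meal type) pair.
#' @param theta_grid Frontier theta grid.
#' @param max_hops Substitution hop limit.
#' @param stages Character subset of stages to run.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = NULL,
                       n_foods = 120, n_categories = 8,
                       archetypes_per_type = 3, n_meals = 1200,
                       contamination = 0.003, n_boot_filter = 200,
                       cvae = cvae_config(hidden = 64, latent_dim = 16,
                                          epochs = 30, warmup_epochs = 3,
                                          cycle_epochs = 5),
                       n_sample = 20, theta_grid = seq(0, 2, by = 0.5),
                       max_hops = 3,
                       stages = c("synth", "preprocess", "cluster", "train",
                                  "sample", "portion", "evaluate",
                                  "substitute")) {
  structure(as.list(environment()), class = "run_config")
}

# deterministic per-stage seed below 2^31
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(global_seed) * 7919 + h * 104729) %% 2147483647)
}

#' Run the full pipeline
#'
#' Executes the configured stages in order, carrying artifacts forward and
#' (optionally) writing them to disk. A stage failure marks the stage
#' failed in the report and skips downstream stages.
#'
#' @param config A [run_config()].
#' @param verbose Log stage progress (default TRUE).
#' @return A `run_report`: list with one entry per executed stage
#'   (summaries and key counts), plus `config_hash` and `artifacts`.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  cfg <- config
  report <- list()
  art <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  t_all <- proc.time()[3]
  hash_src <- paste(deparse(cfg[setdiff(names(cfg), "out_dir")]), collapse = "")
  config_hash <- sprintf("%08x", sum(utf8ToInt(hash_src) *
                                       (seq_along(utf8ToInt(hash_src)) %% 97 + 1)) %% .Machine$integer.max)
  save_csv <- function(x, name) {
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      p <- file.path(cfg$out_dir, name)
      utils::write.csv(cbind(as.data.frame(x), .config_hash = config_hash),
                       p, row.names = FALSE)
    }
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    t0 <- proc.time()[3]
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      report[[stage]] <<- list(status = "failed", error = conditionMessage(res))
      say("stage %s FAILED: %s", stage, conditionMessage(res))
      FALSE
    } else {
      res$status <- "ok"
      res$elapsed_s <- round(proc.time()[3] - t0, 2)
      report[[stage]] <<- res
      say("stage %-10s ok (%.1fs)", stage, res$elapsed_s)
      TRUE
    }
  }

  ok <- run_stage("synth", function() {
    art$catalog <<- generate_catalog(cfg$n_foods, cfg$n_categories,
                                     seed = stage_seed(cfg$seed, "synth"))
    art$specs <<- archetype_specs(art$catalog, cfg$archetypes_per_type,
                                  seed = stage_seed(cfg$seed, "synth_arch"))
    art$corpus <<- generate_corpus(art$catalog, art$specs, cfg$n_meals,
                                   seed = stage_seed(cfg$seed, "synth_corpus"))
    save_csv(art$catalog, "catalog.csv")
    save_csv(art$corpus, "meals.csv")
    list(n_foods = nrow(art$catalog), n_meals = length(unique(art$corpus$meal_id)))
  })
  if (!isFALSE(ok) && "preprocess" %in% cfg$stages) ok <- run_stage("preprocess", function() {
    feats <- extract_features(art$corpus, art$catalog)
    removed <- character(0)
    for (mt in names(feats)) {
      lf <- lof_filter(feats[[mt]], contamination = cfg$contamination)
      removed <- c(removed, lf$removed)
    }
    art$corpus <<- {
      x <- art$corpus[!art$corpus$meal_id %in% removed, ]
      class(x) <- c("meal_corpus", "data.frame"); x
    }
    pmap <- aggregate_prototypes(art$catalog, art$corpus)
    art$pmap <<- pmap
    art$corpus <<- apply_prototypes(art$corpus, pmap)
    pb <- binarize(art$corpus)
    kept <- lapply(names(pb), function(mt)
      bootstrap_ingredient_filter(pb[[mt]], n_boot = cfg$n_boot_filter,
                                  seed = stage_seed(cfg$seed, paste0("filter_", mt))))
    names(kept) <- names(pb)
    keep_codes <- unique(unlist(lapply(kept, `[[`, "retained")))
    art$corpus <<- {
      x <- art$corpus[art$corpus$food_code %in% keep_codes, ]
      x <- x[x$meal_id %in% names(which(table(x$meal_id) > 0)), ]
      class(x) <- c("meal_corpus", "data.frame"); x
    }
    save_csv(art$corpus, "meals.clean.csv")
    save_csv(art$pmap$assignment, "prototype_map.csv")
    list(n_removed_lof = length(removed),
         n_prototypes = length(unique(pmap$assignment$prototype)),
         n_foods_retained = length(keep_codes),
         n_meals = length(unique(art$corpus$meal_id)))
  })
  if (!isFALSE(ok) && "cluster" %in% cfg$stages) ok <- run_stage("cluster", function() {
    feats <- extract_features(art$corpus, art$catalog)
    labels <- lapply(feats, cluster_meals)
    art$labels <<- labels
    lab_df <- do.call(rbind, lapply(names(labels), function(mt)
      data.frame(meal_id = names(labels[[mt]]), meal_type = mt,
                 cluster = as.integer(labels[[mt]]), stringsAsFactors = FALSE)))
    art$label_df <<- lab_df
    save_csv(lab_df, "labels.csv")
    list(n_clusters = sum(vapply(labels, function(l) length(unique(l[l > 0])), 1L)),
         noise_frac = round(mean(lab_df$cluster == -1L), 4))
  })
  if (!isFALSE(ok) && "train" %in% cfg$stages) ok <- run_stage("train", function() {
    lab <- art$label_df[art$label_df$cluster != -1L, ]
    pb <- binarize(art$corpus)
    X <- do.call(rbind, lapply(names(pb), function(mt) {
      m <- pb[[mt]][intersect(rownames(pb[[mt]]), lab$meal_id), , drop = FALSE]
      m
    }))
    lab <- lab[match(rownames(X), lab$meal_id), ]
    ccfg <- cfg$cvae
    ccfg$seed <- stage_seed(cfg$seed, "train")
    cl <- paste0(lab$meal_type, "#", lab$cluster)
    art$model <<- cvae(X, cl, lab$meal_type, config = ccfg)
    list(f1_train = round(art$model$f1_train, 4),
         n_pairs = length(art$model$gate))
  })
  if (!isFALSE(ok) && "sample" %in% cfg$stages) ok <- run_stage("sample", function() {
    gens <- list()
    for (pp in names(art$model$gate)) {
      parts <- strsplit(pp, ":", fixed = TRUE)[[1]]
      sets <- simulate.cvae(art$model, nsim = cfg$n_sample,
                            seed = stage_seed(cfg$seed, paste0("sample_", pp)),
                            cluster = parts[1], meal_type = parts[2])
      gens[[pp]] <- sets
    }
    art$generated <<- gens
    list(n_generated = sum(lengths(gens)))
  })
  if (!isFALSE(ok) && "portion" %in% cfg$stages) ok <- run_stage("portion", function() {
    sols <- list()
    i <- 0
    sv <- default_serving_table(art$catalog)
    for (pp in names(art$generated)) {
      mt <- strsplit(pp, ":", fixed = TRUE)[[1]][2]
      for (s in art$generated[[pp]]) {
        i <- i + 1
        sols[[i]] <- optimize_portions(s, art$catalog, mt, serving_table = sv,
                                       seed = stage_seed(cfg$seed, paste0("portion", i)))
        sols[[i]]$pair <- pp
      }
    }
    art$solutions <<- sols
    feas <- vapply(sols, `[[`, logical(1), "feasible")
    save_csv(do.call(rbind, lapply(seq_along(sols), function(j)
      data.frame(meal_id = paste0("G", j), food_code = sols[[j]]$foods,
                 grams = as.numeric(sols[[j]]$grams)))), "portions.csv")
    list(n_meals = length(sols), frac_feasible = round(mean(feas), 4))
  })
  if (!isFALSE(ok) && "evaluate" %in% cfg$stages) ok <- run_stage("evaluate", function() {
    gen_corpus <- do.call(rbind, lapply(seq_along(art$solutions), function(j) {
      s <- art$solutions[[j]]
      data.frame(meal_id = paste0("G", j), meal_type = s$meal_type,
                 food_code = s$foods, grams = as.numeric(s$grams),
                 true_archetype = NA_integer_, stringsAsFactors = FALSE)
    }))
    class(gen_corpus) <- c("meal_corpus", "data.frame")
    gr <- metric_report(gen_corpus, art$catalog)
    gr$cluster <- vapply(art$solutions, `[[`, "", "pair")
    rr <- metric_report(art$corpus, art$catalog)
    lab <- art$label_df
    cl <- lab$cluster[match(rr$meal_id, lab$meal_id)]
    mt <- lab$meal_type[match(rr$meal_id, lab$meal_id)]
    rr$cluster <- paste(paste0(mt, "#", cl), mt, sep = ":")
    rr <- rr[!is.na(cl) & cl != -1L, ]
    cmp <- compare_generated_vs_real(gr, rr, n_boot = 200,
                                     seed = stage_seed(cfg$seed, "evaluate"))
    art$gen_report <<- gr
    art$real_report <<- rr
    list(median_pct_reduction = round(unname(cmp$overall["median_pct_reduction"]), 2),
         frac_improved = round(unname(cmp$overall["frac_improved"]), 3))
  })
  if (!isFALSE(ok) && "substitute" %in% cfg$stages) ok <- run_stage("substitute", function() {
    pricing <- pricing_model()
    n_sub <- min(length(art$solutions), 30L)
    csets <- list(); costs <- numeric(0)
    for (j in seq_len(n_sub)) {
      s <- art$solutions[[j]]
      csets[[paste0("G", j)]] <- find_candidates(s, art$corpus, art$catalog,
                                                 pricing = pricing,
                                                 max_hops = cfg$max_hops,
                                                 include_swaps = FALSE)
      costs[paste0("G", j)] <- meal_cost(s, art$catalog, pricing)
    }
    fr <- frontier(csets, costs, cfg$theta_grid, n_boot = 200,
                   seed = stage_seed(cfg$seed, "substitute"))
    art$frontier <<- fr
    list(feasibility = round(fr$feasibility, 4),
         knee_theta = if (!is.na(fr$knee)) fr$curve$theta[fr$knee] else NA)
  })

  report$config_hash <- config_hash
  report$elapsed_s <- round(proc.time()[3] - t_all, 2)
  structure(list(report = report, artifacts = art), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run", x$report$config_hash, "-",
      x$report$elapsed_s, "s\n")
  for (st in setdiff(names(x$report), c("config_hash", "elapsed_s"))) {
    r <- x$report[[st]]
    cat(sprintf("  %-10s %s\n", st,
                paste(names(r)[names(r) != "status"],
                      vapply(r[names(r) != "status"], function(v)
                        paste(format(v), collapse = ","), ""),
                      sep = "=", collapse = "  ")))
  }
  invisible(x)
}
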