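# On-disk formats. Catalog and corpus are plain CSV (corpus in long format,
# one row per meal item) so artifacts diff cleanly and round-trip exactly.

#' Read and write food catalogs and meal corpora
#'
#' CSV round-trip IO with validation. `read_corpus()` rejects rows with
#' non-positive grams (reporting the offending row) and, when a catalog is
#' supplied, enforces referential integrity of food codes.
#'
#' @param catalog,corpus Objects to write.
#' @param path File path.
#' @return The read object, or (for writers) the path invisibly.
#' @name corpus_io
NULL

#' @rdname corpus_io
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog), path, row.names = FALSE)
  invisible(path)
}

#' @rdname corpus_io
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "main_category", "subcategory", "is_beverage", "energy_kcal",
            nutrient_panel()$nutrient)
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("malformed catalog, missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(x$code)) stop("malformed catalog: duplicate food codes")
  dens <- as.matrix(x[, c("energy_kcal", nutrient_panel()$nutrient)])
  if (any(dens < 0)) {
    bad <- which(rowSums(dens < 0) > 0)[1]
    stop("malformed catalog: negative density at row ", bad)
  }
  x$is_beverage <- as.logical(x$is_beverage)
  class(x) <- c("food_catalog", "data.frame")
  x
}

#' @rdname corpus_io
#' @export
write_corpus <- function(corpus, path) {
  utils::write.csv(as.data.frame(corpus), path, row.names = FALSE)
  invisible(path)
}

#' @rdname corpus_io
#' @param catalog Optional `food_catalog` for referential-integrity checks.
#' @export
read_corpus <- function(path, catalog = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("meal_id", "meal_type", "food_code", "grams")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("malformed corpus, missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"true_archetype" %in% names(x)) x$true_archetype <- NA_integer_
  bad <- which(!is.finite(x$grams) | x$grams <= 0)
  if (length(bad)) stop("corpus row ", bad[1], ": grams must be > 0")
  bad_type <- which(!x$meal_type %in% c("breakfast", "lunch", "dinner"))
  if (length(bad_type)) stop("corpus row ", bad_type[1], ": unknown meal type '",
                             x$meal_type[bad_type[1]], "'")
  dup <- duplicated(x[, c("meal_id", "food_code")])
  if (any(dup)) stop("corpus row ", which(dup)[1],
                     ": duplicate food code within meal ", x$meal_id[which(dup)[1]])
  if (!is.null(catalog)) {
    unknown <- setdiff(x$food_code, catalog$code)
    if (length(unknown)) stop("referential-integrity error: unknown food code(s): ",
                              paste(utils::head(unknown, 5), collapse = ", "))
  }
  class(x) <- c("meal_corpus", "data.frame")
  x
}

# split a long corpus into a list of per-meal data.frames, preserving order
split_meals <- function(corpus) {
  split(as.data.frame(corpus), factor(corpus$meal_id, levels = unique(corpus$meal_id)))
}

# one-row-per-meal summary (meal_id, meal_type, true_archetype)
meal_index <- function(corpus) {
  first <- !duplicated(corpus$meal_id)
  data.frame(meal_id = corpus$meal_id[first],
             meal_type = corpus$meal_type[first],
             true_archetype = corpus$true_archetype[first],
             stringsAsFactors = FALSE)
}
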