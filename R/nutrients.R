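#' The 20-nutrient panel
#'
#' Returns the fixed nutrient panel used throughout the package: 4
#' macronutrients, 11 micronutrients (the MAR set) and 5 limit ("diet
#' quality") nutrients. Energy (kcal) is tracked separately from the panel.
#'
#' @return A data.frame with columns `nutrient`, `unit`, and `class`
#'   (one of `"macro"`, `"micro"`, `"limit"`).
#' @examples
#' np <- nutrient_panel()
#' sum(np$class == "micro")  # 11
#' @export
nutrient_panel <- function() {
  data.frame(
    nutrient = c(
      "protein", "fat", "carbohydrate", "fiber",
      "calcium", "iron", "zinc", "vit_a", "vit_c", "vit_b6", "vit_b12",
      "thiamin", "riboflavin", "niacin", "folate",
      "sodium", "sat_fat", "total_sugars", "cholesterol", "added_sugars"
    ),
    unit = c(
      "g", "g", "g", "g",
      "mg", "mg", "mg", "ug_rae", "mg", "mg", "ug",
      "mg", "mg", "mg", "ug_dfe",
      "mg", "g", "g", "mg", "g"
    ),
    class = c(
      rep("macro", 4), rep("micro", 11), rep("limit", 5)
    ),
    stringsAsFactors = FALSE
  )
}

#' Nutrient name helpers
#'
#' @return Character vectors of panel nutrient names by class.
#' @rdname nutrient_names
#' @export
macro_nutrients <- function() nutrient_panel()$nutrient[nutrient_panel()$class == "macro"]

#' @rdname nutrient_names
#' @export
micro_nutrients <- function() nutrient_panel()$nutrient[nutrient_panel()$class == "micro"]

#' @rdname nutrient_names
#' @export
limit_nutrients <- function() nutrient_panel()$nutrient[nutrient_panel()$class == "limit"]

#' Default daily RDI / upper-limit table
#'
#' Daily reference values for an adult reference diet: an RDI for each
#' adequacy nutrient (macros except fat, plus the 11 MAR micronutrients), an
#' upper limit for each limit nutrient, and a 2,000-kcal daily energy target.
#' Values follow standard US adult reference intakes and can be replaced
#' wholesale by the user.
#'
#' @param energy_kcal Daily energy target in kcal (default 2000).
#' @return A list with elements `rdi` (named numeric, adequacy nutrients),
#'   `limit` (named numeric, limit nutrients), and `energy_kcal`.
#' @export
default_rdi_table <- function(energy_kcal = 2000) {
  rdi <- c(
    protein = 50, carbohydrate = 275, fiber = 28,
    calcium = 1000, iron = 18, zinc = 11, vit_a = 900, vit_c = 90,
    vit_b6 = 1.7, vit_b12 = 2.4, thiamin = 1.2, riboflavin = 1.3,
    niacin = 16, folate = 400
  )
  lim <- c(
    sodium = 2300, sat_fat = 20, total_sugars = 50,
    cholesterol = 300, added_sugars = 50
  )
  structure(list(rdi = rdi, limit = lim, energy_kcal = energy_kcal),
            class = "rdi_table")
}

#' Validate an RDI table
#'
#' @param rdi An object as returned by [default_rdi_table()].
#' @return The table, invisibly, or an error.
#' @keywords internal
validate_rdi_table <- function(rdi) {
  stopifnot(is.list(rdi), all(c("rdi", "limit", "energy_kcal") %in% names(rdi)))
  if (any(rdi$rdi <= 0) || any(rdi$limit <= 0) || rdi$energy_kcal <= 0)
    stop("RDI table values must be positive")
  missing_micro <- setdiff(micro_nutrients(), names(rdi$rdi))
  if (length(missing_micro))
    stop("RDI table missing micronutrient(s): ", paste(missing_micro, collapse = ", "))
  missing_lim <- setdiff(c("sodium", "sat_fat", "total_sugars"), names(rdi$limit))
  if (length(missing_lim))
    stop("RDI table missing limit(s): ", paste(missing_lim, collapse = ", "))
  invisible(rdi)
}

#' AMDR bounds
#'
#' Acceptable Macronutrient Distribution Ranges as percent of total energy:
#' protein 10-35%, fat 20-35%, carbohydrate 45-65%.
#'
#' @return A data.frame with columns `macro`, `lower`, `upper`.
#' @export
amdr_bounds <- function() {
  data.frame(
    macro = c("protein", "fat", "carbohydrate"),
    lower = c(10, 20, 45),
    upper = c(35, 35, 65),
    stringsAsFactors = FALSE
  )
}

#' Per-meal share of the daily targets
#'
#' Breakfast, lunch and dinner are allocated 25%, 35% and 40% of the daily
#' targets, respectively.
#'
#' @param shares Optional named numeric replacing the default split; must sum
#'   to 1.
#' @return Named numeric vector of shares.
#' @export
meal_shares <- function(shares = NULL) {
  if (is.null(shares))
    shares <- c(breakfast = 0.25, lunch = 0.35, dinner = 0.40)
  if (abs(sum(shares) - 1) > 1e-9) stop("meal shares must sum to 1")
  shares
}

#' Atwater energy density of a food
#'
#' 4 kcal/g protein + 4 kcal/g carbohydrate + 9 kcal/g fat, applied to
#' per-gram densities.
#'
#' @param density Named numeric per-gram nutrient density vector containing
#'   `protein`, `carbohydrate`, `fat`.
#' @return Energy density in kcal/g.
#' @export
atwater_energy <- function(density) {
  4 * density[["protein"]] + 4 * density[["carbohydrate"]] + 9 * density[["fat"]]
}
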