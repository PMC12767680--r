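#' Hyper-palatability thresholds
#'
#' Threshold set for the three hyper-palatability criteria. Energy-share
#' thresholds are strict (`>`), sodium thresholds non-strict (`>=`).
#' `fat_sodium_fat_epct` defaults to 5 E% from fat for the fat + sodium
#' criterion; the original operational definition by Fazzino and colleagues
#' uses 25 E%, so the value is configurable (see the methods vignette).
#'
#' @param fat_sodium_fat_epct Fat energy-share threshold (E%) of the
#'   fat + sodium criterion.
#' @param fat_sodium_sodium_pct Sodium threshold (g/100 g, i.e. % by weight)
#'   of the fat + sodium criterion.
#' @param fat_sugar_fat_epct,fat_sugar_sugar_epct Fat and sugar energy-share
#'   thresholds (E%) of the fat + sugar criterion.
#' @param carb_sodium_carb_epct Non-sugar carbohydrate energy-share
#'   threshold (E%) of the carbohydrate + sodium criterion.
#' @param carb_sodium_sodium_pct Sodium threshold (% by weight) of the
#'   carbohydrate + sodium criterion.
#' @return A named list of thresholds.
#' @export
hp_thresholds <- function(fat_sodium_fat_epct = 5,
                          fat_sodium_sodium_pct = 0.30,
                          fat_sugar_fat_epct = 20,
                          fat_sugar_sugar_epct = 20,
                          carb_sodium_carb_epct = 40,
                          carb_sodium_sodium_pct = 0.20) {
  list(
    fat_sodium_fat_epct = fat_sodium_fat_epct,
    fat_sodium_sodium_pct = fat_sodium_sodium_pct,
    fat_sugar_fat_epct = fat_sugar_fat_epct,
    fat_sugar_sugar_epct = fat_sugar_sugar_epct,
    carb_sodium_carb_epct = carb_sodium_carb_epct,
    carb_sodium_sodium_pct = carb_sodium_sodium_pct
  )
}

hp_labels <- c("NotHP", "FatSodium", "FatSugar", "CarbSodium",
               "FitsMoreThanOne", "ExcludedBeverage")

#' Energy shares and sodium from declared nutrition
#'
#' Converts declared macronutrients to shares of declared total energy:
#' fat contributes 37 kJ/g, carbohydrate and sugar 17 kJ/g (EU food
#' information regulation factors); each is divided by the declared total
#' energy (kJ/100 g) and multiplied by 100. Sodium is estimated as 40% of
#' declared salt. Declared energy is authoritative; energy is never
#' recomputed from macronutrients. Since eligible products have
#' sugar <= carbohydrate, the non-sugar carbohydrate share is clamped at 0
#' defensively.
#'
#' @param products Data frame with columns `energy_kj`, `fat_g`, `carb_g`,
#'   `sugar_g`, `salt_g` (per 100 g).
#' @return The input tibble with columns `e_pct_fat`, `e_pct_carb`,
#'   `e_pct_sugar`, `e_pct_carb_nosugar` (E%) and `sodium_g` (g/100 g)
#'   appended.
#' @examples
#' energy_shares(tibble::tibble(
#'   energy_kj = 1000, fat_g = 10, carb_g = 20, sugar_g = 5, salt_g = 1
#' ))
#' @export
energy_shares <- function(products) {
  products <- tibble::as_tibble(products)
  if (any(is.na(products$energy_kj) | products$energy_kj <= 0)) {
    stop("energy_kj must be positive for all products ",
         "(such records cannot survive eligibility screening)")
  }
  dplyr::mutate(
    products,
    e_pct_fat = .data$fat_g * 37 / .data$energy_kj * 100,
    e_pct_carb = .data$carb_g * 17 / .data$energy_kj * 100,
    e_pct_sugar = .data$sugar_g * 17 / .data$energy_kj * 100,
    e_pct_carb_nosugar = pmax(.data$carb_g - .data$sugar_g, 0) * 17 /
      .data$energy_kj * 100,
    sodium_g = 0.40 * .data$salt_g
  )
}

#' Classify products as hyper-palatable
#'
#' Applies the three-criterion operational definition of hyper-palatable
#' food: (1) fat + sodium (fat energy share above `fat_sodium_fat_epct` E%
#' and sodium at or above 0.30% by weight); (2) fat + sugar (both above
#' 20 E%); (3) non-sugar carbohydrate + sodium (carbohydrate above 40 E% and
#' sodium at or above 0.20% by weight). Products meeting two or more
#' criteria are labelled `FitsMoreThanOne`; beverages are excluded from the
#' classification regardless of nutrition.
#'
#' @param shares Data frame with the [energy_shares()] columns.
#' @param is_beverage Logical vector (recycled) marking beverages; defaults
#'   to `shares$group == "Beverages"` when a `group` column is present.
#' @param thresholds A [hp_thresholds()] list.
#' @return The input tibble with an `hp_class` factor column appended
#'   (levels `NotHP`, `FatSodium`, `FatSugar`, `CarbSodium`,
#'   `FitsMoreThanOne`, `ExcludedBeverage`).
#' @export
classify_hp <- function(shares, is_beverage = NULL,
                        thresholds = hp_thresholds()) {
  shares <- tibble::as_tibble(shares)
  if (is.null(is_beverage)) {
    is_beverage <- if ("group" %in% names(shares)) {
      !is.na(shares$group) & shares$group == "Beverages"
    } else {
      FALSE
    }
  }
  is_beverage <- rep_len(is_beverage, nrow(shares))
  t <- thresholds
  c1 <- shares$e_pct_fat > t$fat_sodium_fat_epct &
    shares$sodium_g >= t$fat_sodium_sodium_pct
  c2 <- shares$e_pct_fat > t$fat_sugar_fat_epct &
    shares$e_pct_sugar > t$fat_sugar_sugar_epct
  c3 <- shares$e_pct_carb_nosugar > t$carb_sodium_carb_epct &
    shares$sodium_g >= t$carb_sodium_sodium_pct
  n_crit <- c1 + c2 + c3
  label <- dplyr::case_when(
    is_beverage ~ "ExcludedBeverage",
    n_crit >= 2 ~ "FitsMoreThanOne",
    c1 ~ "FatSodium",
    c2 ~ "FatSugar",
    c3 ~ "CarbSodium",
    TRUE ~ "NotHP"
  )
  shares$hp_class <- factor(label, levels = hp_labels)
  shares
}

#' Append energy shares and hyper-palatability class to a product table
#'
#' Convenience wrapper chaining [energy_shares()] and [classify_hp()].
#'
#' @inheritParams energy_shares
#' @inheritParams classify_hp
#' @return The product tibble with nutrition-derived columns appended.
#' @export
add_nutrition <- function(products, thresholds = hp_thresholds()) {
  classify_hp(energy_shares(products), thresholds = thresholds)
}
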