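#' The sixteen harmonized food groups
#'
#' Product records arrive with source-specific raw food groups; analysis uses
#' a fixed sixteen-group taxonomy. Unmappable non-empty raw groups fall into
#' `"Others"`.
#'
#' @return Character vector of the sixteen group names.
#' @export
food_groups <- function() {
  c(
    "Desserts & Ice Creams",
    "Beverages",
    "Fish & Shellfish",
    "Meat & Poultry",
    "Fats, Margarine & Spreads",
    "Premade Food & Dinner Kits",
    "Snacks, Chocolate & Sweets",
    "Bakery, Cakes & Pastries",
    "Eggs & Dairy Products",
    "Grains, Baking Mixes & Cereals",
    "Baking Condiments",
    "Sauces, Dressings & Other Dinner Condiments",
    "Processed Fruits & Vegetables",
    "Fruit, Vegetables & Legumes",
    "Infant Food",
    "Others"
  )
}

#' Default raw-group harmonization map
#'
#' Maps the two source vocabularies (Norwegian labels in database A,
#' English-style labels in database B) onto the sixteen analysis groups.
#' Extend or replace it to cover additional source vocabularies.
#'
#' @return A tibble with columns `raw` and `group`.
#' @export
default_group_map <- function() {
  tibble::tribble(
    ~raw,                    ~group,
    "iskrem",                "Desserts & Ice Creams",
    "dessert",               "Desserts & Ice Creams",
    "drikke",                "Beverages",
    "drikkevarer",           "Beverages",
    "soft drinks",           "Beverages",
    "fisk og skalldyr",      "Fish & Shellfish",
    "seafood",               "Fish & Shellfish",
    "kjott og fjaerkre",     "Meat & Poultry",
    "meat",                  "Meat & Poultry",
    "margarin og smor",      "Fats, Margarine & Spreads",
    "spreads",               "Fats, Margarine & Spreads",
    "ferdigmat",             "Premade Food & Dinner Kits",
    "ready meals",           "Premade Food & Dinner Kits",
    "snacks og sjokolade",   "Snacks, Chocolate & Sweets",
    "confectionery",         "Snacks, Chocolate & Sweets",
    "bakervarer",            "Bakery, Cakes & Pastries",
    "bakery",                "Bakery, Cakes & Pastries",
    "egg og meieri",         "Eggs & Dairy Products",
    "dairy",                 "Eggs & Dairy Products",
    "korn og gryn",          "Grains, Baking Mixes & Cereals",
    "cereals",               "Grains, Baking Mixes & Cereals",
    "bakeingredienser",      "Baking Condiments",
    "baking",                "Baking Condiments",
    "sauser og dressinger",  "Sauces, Dressings & Other Dinner Condiments",
    "sauces",                "Sauces, Dressings & Other Dinner Condiments",
    "hermetikk",             "Processed Fruits & Vegetables",
    "preserved produce",     "Processed Fruits & Vegetables",
    "frukt og gront",        "Fruit, Vegetables & Legumes",
    "fresh produce",         "Fruit, Vegetables & Legumes",
    "barnemat",              "Infant Food",
    "baby food",             "Infant Food"
  )
}

#' Harmonize raw food-group labels
#'
#' Already-harmonized group names pass through unchanged; mapped raw labels
#' (case-insensitive) are translated; unmapped non-empty labels become
#' `"Others"`; missing labels stay `NA` and are flagged for manual
#' assignment.
#'
#' @param raw_group Character vector of raw labels.
#' @param mapping A data frame with columns `raw`, `group`
#'   (default [default_group_map()]).
#' @return Character vector of harmonized group names (or `NA`).
#' @export
harmonize_food_group <- function(raw_group, mapping = default_group_map()) {
  raw <- tolower(trimws(as.character(raw_group)))
  out <- rep(NA_character_, length(raw))
  groups <- food_groups()
  direct <- match(raw, tolower(groups))
  mapped <- mapping$group[match(raw, tolower(mapping$raw))]
  out[!is.na(direct)] <- groups[direct[!is.na(direct)]]
  fill <- is.na(out) & !is.na(mapped)
  out[fill] <- mapped[fill]
  unknown <- is.na(out) & !is.na(raw_group) & nzchar(raw)
  out[unknown] <- "Others"
  if (anyNA(out)) {
    warning(sum(is.na(out)), " record(s) lack a raw food group; ",
            "flagged NA for manual assignment")
  }
  out
}

nutrient_cols <- c("fat_g", "satfat_g", "carb_g", "sugar_g", "protein_g", "salt_g")

exclusion_reasons <- c(
  "non_food", "no_ingredients", "nutrient_gt_100", "sugar_gt_carb",
  "satfat_gt_fat", "no_energy", "energy_gt_4200", "bad_kj_kcal_ratio",
  "duplicate"
)

#' Read a raw product table
#'
#' Reads product records from CSV or JSON-lines and renames source columns to
#' the canonical schema (`gtin`, `name`, `source`, `raw_group`, `is_food`,
#' `ingredient_text`, `energy_kj`, `energy_kcal`, `fat_g`, `satfat_g`,
#' `carb_g`, `sugar_g`, `protein_g`, `salt_g`).
#'
#' @param path CSV (`.csv`) or JSON-lines (`.json`/`.jsonl`) file.
#' @param schema Optional named character vector or YAML file path mapping
#'   canonical field names to source column names.
#' @return A tibble of raw product records.
#' @export
read_product_table <- function(path, schema = NULL) {
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    records <- tibble::as_tibble(jsonlite::stream_in(file(path), verbose = FALSE))
  } else {
    records <- readr::read_csv(path, show_col_types = FALSE)
  }
  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    schema <- unlist(yaml::read_yaml(schema))
  }
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (src %in% names(records)) {
        names(records)[names(records) == src] <- canonical
      }
    }
  }
  records
}

#' Flag unrealistic declared nutrition
#'
#' Applies the nutrition plausibility checks to records that have already
#' passed the non-food and ingredient-list screens: any single nutrient above
#' 100 g/100 g, more sugar than total carbohydrate, more saturated than total
#' fat, no declared energy, more than 4,200 kJ/100 g, or a kJ/kcal ratio
#' outside \[3.984, 4.384\] (4.184 kJ per kcal, plus/minus 0.2). The ratio
#' check is skipped for low-energy products (kJ < 10 and kcal < 2). Absent
#' fields trigger only the checks they make evaluable, so a record with no
#' energy fields fails only `no_energy`.
#'
#' @param record A one-row data frame (or list) with the canonical nutrition
#'   fields.
#' @return Character vector of triggered reason codes, in the fixed check
#'   order (empty when the record is plausible).
#' @export
is_unrealistic <- function(record) {
  val <- function(field) {
    v <- record[[field]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v[[1]])
  }
  reasons <- character(0)
  nutr <- vapply(nutrient_cols, val, numeric(1))
  if (any(!is.na(nutr) & nutr > 100)) reasons <- c(reasons, "nutrient_gt_100")
  sugar <- val("sugar_g"); carb <- val("carb_g")
  if (!is.na(sugar) && !is.na(carb) && sugar > carb) {
    reasons <- c(reasons, "sugar_gt_carb")
  }
  satfat <- val("satfat_g"); fat <- val("fat_g")
  if (!is.na(satfat) && !is.na(fat) && satfat > fat) {
    reasons <- c(reasons, "satfat_gt_fat")
  }
  kj <- val("energy_kj"); kcal <- val("energy_kcal")
  if (is.na(kj) || kj <= 0) {
    reasons <- c(reasons, "no_energy")
  } else {
    if (kj > 4200) reasons <- c(reasons, "energy_gt_4200")
    low_energy <- kj < 10 && !is.na(kcal) && kcal < 2
    if (!is.na(kcal) && !low_energy) {
      ratio <- kj / kcal
      if (!(ratio >= 3.984 && ratio <= 4.384)) {
        reasons <- c(reasons, "bad_kj_kcal_ratio")
      }
    }
  }
  reasons
}

normalize_name <- function(x) {
  gsub("\\s+", " ", trimws(tolower(as.character(x))))
}

#' Apply eligibility screening, deduplication and additive detection
#'
#' Runs the inclusion flowchart over raw product records: non-food products,
#' then products without ingredient lists, then unrealistic declared
#' nutrition (see [is_unrealistic()]), then duplicates (shared GTIN, or
#' case-folded whitespace-collapsed name). Each excluded record is tallied
#' under the first reason that triggers. Duplicates are resolved after a
#' deterministic sort by (source, gtin), keeping the first occurrence.
#' Surviving records get a harmonized food group and their detected additive
#' codes.
#'
#' @param records Tibble of raw product records (canonical schema).
#' @param lexicon An [ets_lexicon()] used for detection.
#' @param group_map Raw-group harmonization table, see
#'   [harmonize_food_group()].
#' @return A list with `products` (tibble of eligible products, plus columns
#'   `group`, `ets_codes` (list-column) and `n_ets`) and `report` (an
#'   `eligibility_report`: `n_input`, per-reason `tallies`, `n_eligible`;
#'   `n_input = n_eligible + sum(tallies)`).
#' @export
apply_eligibility <- function(records, lexicon = ets_lexicon(),
                              group_map = default_group_map()) {
  records <- tibble::as_tibble(records)
  tallies <- stats::setNames(integer(length(exclusion_reasons)), exclusion_reasons)
  n_input <- nrow(records)
  if (n_input == 0) {
    report <- structure(list(n_input = 0L, tallies = tallies, n_eligible = 0L),
                        class = "eligibility_report")
    return(list(products = records, report = report))
  }

  is_food <- if ("is_food" %in% names(records)) {
    !(records$is_food %in% c(FALSE, "FALSE", "false", 0))
  } else {
    rep(TRUE, n_input)
  }
  has_ingredients <- !is.na(records$ingredient_text) &
    nzchar(trimws(records$ingredient_text))

  reason <- rep(NA_character_, n_input)
  reason[!is_food] <- "non_food"
  reason[is.na(reason) & !has_ingredients] <- "no_ingredients"

  todo <- which(is.na(reason))
  for (i in todo) {
    r <- is_unrealistic(records[i, ])
    if (length(r) > 0) reason[i] <- r[[1]]
  }

  # deterministic dedup: sort survivors by (source, gtin), keep the first
  # record per GTIN and per normalized name
  alive <- which(is.na(reason))
  ord <- alive[order(records$source[alive], records$gtin[alive])]
  key_unique <- function(k) {
    k <- as.character(k)
    blank <- is.na(k) | !nzchar(k)
    k[blank] <- paste0(".__missing__", seq_len(sum(blank)))
    k
  }
  dup <- duplicated(key_unique(records$gtin[ord])) |
    duplicated(key_unique(normalize_name(records$name[ord])))
  reason[ord[dup]] <- "duplicate"

  tab <- table(factor(reason, levels = exclusion_reasons))
  tallies[names(tab)] <- as.integer(tab)

  keep <- is.na(reason)
  products <- records[keep, , drop = FALSE]
  products$group <- harmonize_food_group(products$raw_group, group_map)
  products$ets_codes <- detect_ets(products$ingredient_text, lexicon)
  products$n_ets <- lengths(products$ets_codes)

  report <- structure(
    list(n_input = n_input, tallies = tallies, n_eligible = sum(keep)),
    class = "eligibility_report"
  )
  stopifnot(report$n_input == report$n_eligible + sum(report$tallies))
  list(products = products, report = report)
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat("<eligibility_report> ", x$n_input, " records in, ",
      x$n_eligible, " eligible\n", sep = "")
  shown <- x$tallies[x$tallies > 0]
  if (length(shown) > 0) {
    for (r in names(shown)) cat("  excluded ", r, ": ", shown[[r]], "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.eligibility_report <- function(x, ...) {
  tibble::tibble(
    reason = c(names(x$tallies), "eligible"),
    n = c(as.integer(x$tallies), x$n_eligible)
  )
}

#' @export
glance.eligibility_report <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input,
    n_excluded = sum(x$tallies),
    n_eligible = x$n_eligible
  )
}
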