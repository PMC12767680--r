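#' Build the product-by-additive presence matrix
#'
#' @param products Tibble with an `ets_codes` list-column (and optionally
#'   `group`), as returned by [apply_eligibility()].
#' @param lump If `TRUE`, codes are projected through [lump_ets()] before
#'   tabulation.
#' @param codes Optional fixed column order; defaults to the sorted union of
#'   observed codes.
#' @return An `ets_presence` object: binary matrix (products x codes) with
#'   attributes `group` (per-row food group, or `NA`) and `lumped`.
#' @export
presence_matrix <- function(products, lump = FALSE, codes = NULL) {
  sets <- products$ets_codes
  if (lump) sets <- lapply(sets, function(s) unique(lump_ets(s)))
  if (is.null(codes)) codes <- sort(unique(unlist(sets)))
  m <- matrix(0L, nrow = length(sets), ncol = length(codes),
              dimnames = list(NULL, codes))
  idx <- lapply(sets, function(s) match(intersect(s, codes), codes))
  for (i in seq_along(idx)) {
    m[i, idx[[i]]] <- 1L
  }
  structure(
    m,
    group = if ("group" %in% names(products)) products$group else
      rep(NA_character_, length(sets)),
    lumped = lump,
    class = c("ets_presence", class(m))
  )
}

cap_counts <- function(n_ets, cap = 10) {
  lev <- c(as.character(0:(cap - 1)), paste0(cap, "+"))
  factor(ifelse(n_ets >= cap, paste0(cap, "+"), as.character(n_ets)),
         levels = lev)
}

#' Distribution of per-product additive counts
#'
#' Tallies how many products carry 0, 1, ..., `cap`+ distinct additives,
#' overall or stratified (typically by food group or hyper-palatability
#' class).
#'
#' @param products Tibble with an `n_ets` column.
#' @param cap Counts at or above `cap` are pooled into a `"cap+"` bin.
#' @param by Optional column name to stratify by (e.g. `"group"`,
#'   `"hp_class"`).
#' @return A tibble with columns `n_ets` (factor `0` ... `cap+`), `n` and
#'   `share` (within stratum), plus the stratum column when `by` is given.
#' @export
ets_count_distribution <- function(products, cap = 10, by = NULL) {
  products <- tibble::as_tibble(products)
  products$.capped <- cap_counts(products$n_ets, cap)
  grouped <- if (is.null(by)) products else
    dplyr::group_by(products, dplyr::across(dplyr::all_of(by)))
  out <- grouped |>
    dplyr::count(.data$.capped, .drop = FALSE, name = "n") |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::rename(n_ets = ".capped")
  class(out) <- c("ets_count_dist", class(out))
  out
}

#' Per-group additive prevalence
#'
#' Percentage of products in each food group containing each additive
#' (heatmap-style summary).
#'
#' @param matrix An [presence_matrix()] object with per-row groups.
#' @param by_group If `FALSE`, a single overall stratum is used.
#' @return A tibble with columns `group`, `code`, `n_products`, `n_with`
#'   and `prevalence_pct`. Empty groups are dropped with a warning.
#' @export
prevalence_table <- function(matrix, by_group = TRUE) {
  stopifnot(inherits(matrix, "ets_presence"))
  grp <- if (by_group) attr(matrix, "group") else rep("All", nrow(matrix))
  empty <- is.na(grp)
  if (any(empty)) {
    warning(sum(empty), " product(s) without food group omitted")
    matrix <- matrix[!empty, , drop = FALSE]
    grp <- grp[!empty]
  }
  if (nrow(matrix) == 0) {
    warning("no products; empty prevalence table")
    return(tibble::tibble(group = character(), code = character(),
                          n_products = integer(), n_with = integer(),
                          prevalence_pct = double()))
  }
  purrr::map_dfr(split(seq_along(grp), grp), function(rows) {
    n_with <- as.integer(colSums(matrix[rows, , drop = FALSE]))
    tibble::tibble(
      group = grp[rows[1]],
      code = colnames(matrix),
      n_products = length(rows),
      n_with = n_with,
      prevalence_pct = n_with / length(rows) * 100
    )
  })
}

#' Count exact additive combinations
#'
#' Counts products whose additive set *equals* each combination (the
#' intersection-plot semantics, as opposed to the at-least semantics used in
#' enrichment testing), with a per-food-group breakdown.
#'
#' @param matrix An [presence_matrix()] object.
#' @param min_products Combinations found in fewer products are dropped
#'   (default 50).
#' @return A tibble with columns `combo` (codes joined by `"&"`), `size`,
#'   `n` and a nested `groups` list-column of per-group counts, sorted by
#'   decreasing `n`. Products with no additives are not combinations and are
#'   never counted.
#' @export
exact_combination_counts <- function(matrix, min_products = 50) {
  stopifnot(inherits(matrix, "ets_presence"))
  grp <- attr(matrix, "group")
  codes <- colnames(matrix)
  key <- apply(matrix, 1, function(r) paste(codes[r == 1], collapse = "&"))
  keep <- nzchar(key)
  key <- key[keep]
  grp <- grp[keep]
  if (length(key) == 0) {
    return(tibble::tibble(combo = character(), size = integer(),
                          n = integer(), groups = list()))
  }
  tab <- table(key)
  tab <- tab[tab >= min_products]
  out <- tibble::tibble(
    combo = names(tab),
    size = lengths(strsplit(names(tab), "&", fixed = TRUE)),
    n = as.integer(tab),
    groups = lapply(names(tab), function(k) {
      g <- table(grp[key == k], useNA = "no")
      tibble::tibble(group = names(g), n = as.integer(g))
    })
  )
  dplyr::arrange(out, dplyr::desc(.data$n))
}

#' Rank correlation between additive count and nutrient content
#'
#' Spearman rank correlation (average ranks for ties) between the capped
#' additive count (0 to `cap`+) and each declared nutrient, across products.
#'
#' @param products Tibble with `n_ets` and nutrient columns.
#' @param nutrients Named character vector mapping output labels to column
#'   names; defaults to energy, fat, saturated fat, carbohydrate, sugar,
#'   protein and sodium (40% of salt when `sodium_g` is absent).
#' @param cap Cap applied to the additive count before ranking.
#' @return A tibble with columns `nutrient`, `rho`, `p_value`, `n` and
#'   `flag` (`"constant"` when the correlation is undefined).
#' @export
spearman_ets_nutrients <- function(products, nutrients = NULL, cap = 10) {
  products <- tibble::as_tibble(products)
  if (!"sodium_g" %in% names(products) && "salt_g" %in% names(products)) {
    products$sodium_g <- 0.40 * products$salt_g
  }
  if (is.null(nutrients)) {
    nutrients <- c(
      energy_kj = "energy_kj", fat_g = "fat_g", satfat_g = "satfat_g",
      carb_g = "carb_g", sugar_g = "sugar_g", protein_g = "protein_g",
      sodium_g = "sodium_g"
    )
    nutrients <- nutrients[nutrients %in% names(products)]
  }
  capped <- pmin(products$n_ets, cap)
  purrr::imap_dfr(nutrients, function(col, label) {
    y <- products[[col]]
    ok <- !is.na(y) & !is.na(capped)
    if (sum(ok) < 3 || length(unique(y[ok])) < 2 ||
        length(unique(capped[ok])) < 2) {
      return(tibble::tibble(nutrient = label, rho = NA_real_,
                            p_value = NA_real_, n = sum(ok),
                            flag = "constant"))
    }
    ct <- suppressWarnings(
      stats::cor.test(capped[ok], y[ok], method = "spearman", exact = FALSE)
    )
    tibble::tibble(nutrient = label, rho = unname(ct$estimate),
                   p_value = ct$p.value, n = sum(ok), flag = "")
  })
}
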