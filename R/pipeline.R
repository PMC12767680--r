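#' Round a share of a count to a printed percentage
#'
#' Percentages are reported as `numerator / denominator * 100`, rounded
#' half-up at the requested precision (the convention used for printed
#' summary tables, where e.g. 27.502% of a food group prints as 28%).
#'
#' @param numerator,denominator Non-negative counts,
#'   `numerator <= denominator`.
#' @param digits Decimal places of the printed percentage.
#' @return The rounded percentage; zero denominators give `NA` with a
#'   warning.
#' @examples
#' summarize_shares(14464, 45851, digits = 1)
#' @export
summarize_shares <- function(numerator, denominator, digits = 0) {
  if (any(numerator > denominator, na.rm = TRUE)) {
    stop("numerator exceeds denominator")
  }
  pct <- numerator / denominator * 100
  bad <- denominator == 0
  if (any(bad)) {
    warning("zero denominator; undefined share")
    pct[bad] <- NA_real_
  }
  # round half-up (round() rounds half to even)
  scale <- 10^digits
  sign(pct) * floor(abs(pct) * scale + 0.5) / scale
}

#' Run the full surveillance pipeline
#'
#' Sequences the whole analysis over a raw product table: eligibility
#' screening and deduplication with additive detection
#' ([apply_eligibility()]), energy shares and hyper-palatability
#' ([add_nutrition()]), additive count distributions, per-group prevalence,
#' exact combination counts, the fold-enrichment scan and additive-count /
#' nutrient rank correlations. When `out_dir` is given, every table is
#' written as tidy CSV, the eligibility report and the resolved
#' configuration as JSON (for provenance), so a re-run with the same inputs
#' and configuration reproduces the artifacts byte-identically.
#'
#' @param records Raw product tibble (canonical schema) or a file path
#'   accepted by [read_product_table()].
#' @param out_dir Optional output directory (created if needed).
#' @param lexicon An [ets_lexicon()].
#' @param thresholds Hyper-palatability thresholds, see [hp_thresholds()].
#' @param prevalence_min,expected_min,combo_sizes,B,seed Enrichment-scan
#'   parameters, see [enrichment_scan()].
#' @param min_products Exact-combination reporting threshold, see
#'   [exact_combination_counts()].
#' @return A list (invisibly when writing): `report`, `products`,
#'   `count_distribution`, `count_distribution_by_group`, `prevalence`,
#'   `exact_combos`, `enrichment`, `spearman` and `stage_counts` (records
#'   surviving each stage).
#' @export
run_pipeline <- function(records, out_dir = NULL,
                         lexicon = ets_lexicon(),
                         thresholds = hp_thresholds(),
                         prevalence_min = 0.01, expected_min = 10,
                         combo_sizes = 2:4, B = 1000, seed = 1L,
                         min_products = 50) {
  if (is.character(records) && length(records) == 1) {
    records <- read_product_table(records)
  }
  elig <- apply_eligibility(records, lexicon = lexicon)
  products <- add_nutrition(elig$products, thresholds = thresholds)

  m <- presence_matrix(products)
  results <- list(
    report = elig$report,
    products = products,
    count_distribution = ets_count_distribution(products),
    count_distribution_by_group = ets_count_distribution(products, by = "group"),
    prevalence = prevalence_table(m),
    exact_combos = exact_combination_counts(m, min_products = min_products),
    enrichment = enrichment_scan(products, prevalence_min = prevalence_min,
                                 expected_min = expected_min,
                                 combo_sizes = combo_sizes, B = B, seed = seed),
    spearman = spearman_ets_nutrients(products),
    stage_counts = c(
      input = elig$report$n_input,
      eligible = elig$report$n_eligible,
      with_ets = sum(products$n_ets > 0)
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(results$count_distribution,
                     file.path(out_dir, "count_distribution.csv"))
    readr::write_csv(results$count_distribution_by_group,
                     file.path(out_dir, "count_distribution_by_group.csv"))
    readr::write_csv(results$prevalence,
                     file.path(out_dir, "prevalence_by_group.csv"))
    readr::write_csv(dplyr::select(results$exact_combos, -"groups"),
                     file.path(out_dir, "exact_combos.csv"))
    readr::write_csv(tibble::as_tibble(unclass(results$enrichment)),
                     file.path(out_dir, "enrichment.csv"))
    readr::write_csv(results$spearman, file.path(out_dir, "spearman.csv"))
    products_out <- dplyr::mutate(
      products, ets_codes = purrr::map_chr(.data$ets_codes, paste, collapse = "|")
    )
    readr::write_csv(products_out, file.path(out_dir, "eligible_products.csv"))
    jsonlite::write_json(
      list(n_input = results$report$n_input,
           tallies = as.list(results$report$tallies),
           n_eligible = results$report$n_eligible),
      file.path(out_dir, "eligibility_report.json"), auto_unbox = TRUE
    )
    jsonlite::write_json(
      list(prevalence_min = prevalence_min, expected_min = expected_min,
           combo_sizes = combo_sizes, B = B, seed = seed,
           min_products = min_products, thresholds = thresholds),
      file.path(out_dir, "run_config.json"), auto_unbox = TRUE
    )
    return(invisible(results))
  }
  results
}
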