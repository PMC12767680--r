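#' Synthetic market configuration
#'
#' Builds and validates the generative parameters of a synthetic food
#' market. Each food group gets a product count, a truncated log-normal
#' nutrition profile (with sugar <= carbohydrate and saturated <= total fat
#' enforced by construction), and a Bernoulli *archetype mixture* governing
#' additive inclusion: a product first draws an archetype `a` with
#' probability `w_a`, then includes each additive `c` independently with
#' probability `p_{a,c}`. The mixture yields closed-form marginals
#' `P(c) = sum_a w_a p_{a,c}`, closed-form at-least combination
#' probabilities `P(S) = sum_a w_a prod_{c in S} p_{a,c}`, and therefore an
#' analytic fold enrichment `FE(S) = P(S) / prod_c P(c)` usable as ground
#' truth in recovery tests. A single-archetype group is exactly independent
#' (`FE = 1` for every combination).
#'
#' @param groups A list of group specifications, each a list with `name`,
#'   `n` (product count), `archetypes` (list of `list(weight, probs)` with
#'   `probs` a named vector of per-code inclusion probabilities) and
#'   `nutrition` (list of `fat`, `carb`, `protein`, `salt` = c(meanlog,
#'   sdlog) and `sugar_frac`, `satfat_frac` = c(shape1, shape2) beta
#'   parameters).
#' @param style_probs Probabilities of the four ingredient-text rendering
#'   styles (`enumber`, `name`, `misspelled`, `subclass`); normalized.
#' @param defect_rates Named rates in `[0, 1)` of injected ineligible
#'   records per exclusion reason (fractions of the clean record count).
#' @param seed Default seed for [generate_market()].
#' @param lexicon Lexicon the configured codes must belong to.
#' @return A `market_config` object.
#' @export
market_config <- function(groups,
                          style_probs = c(enumber = 0.45, name = 0.30,
                                          misspelled = 0.15, subclass = 0.10),
                          defect_rates = NULL,
                          seed = 1L,
                          lexicon = ets_lexicon()) {
  rates <- stats::setNames(numeric(length(exclusion_reasons)), exclusion_reasons)
  if (!is.null(defect_rates)) {
    unknown <- setdiff(names(defect_rates), exclusion_reasons)
    if (length(unknown) > 0) stop("unknown defect rate(s): ",
                                  paste(unknown, collapse = ", "))
    rates[names(defect_rates)] <- unlist(defect_rates)
  }
  if (any(rates < 0 | rates >= 1)) stop("defect rates must lie in [0, 1)")
  style_probs <- unlist(style_probs)[c("enumber", "name", "misspelled", "subclass")]
  if (anyNA(style_probs) || any(style_probs < 0) || sum(style_probs) <= 0) {
    stop("style_probs must be non-negative over enumber/name/misspelled/subclass")
  }
  style_probs <- style_probs / sum(style_probs)

  known_codes <- lexicon$entries$code
  nutrition_fields <- c("fat", "carb", "protein", "salt", "sugar_frac", "satfat_frac")
  for (g in groups) {
    stopifnot(is.character(g$name), length(g$n) == 1, g$n > 0)
    w <- vapply(g$archetypes, function(a) a$weight, numeric(1))
    if (abs(sum(w) - 1) > 1e-8) {
      stop("archetype weights of '", g$name, "' must sum to 1")
    }
    for (a in g$archetypes) {
      p <- unlist(a$probs)
      if (length(p) > 0) {
        if (any(p < 0 | p > 1)) {
          stop("inclusion probabilities of '", g$name, "' must lie in [0, 1]")
        }
        bad <- setdiff(names(p), known_codes)
        if (length(bad) > 0) {
          stop("codes not in lexicon for '", g$name, "': ",
               paste(bad, collapse = ", "))
        }
      }
    }
    miss <- setdiff(nutrition_fields, names(g$nutrition))
    if (length(miss) > 0) {
      stop("nutrition profile of '", g$name, "' lacks: ",
           paste(miss, collapse = ", "))
    }
    if (any(unlist(g$nutrition[c("sugar_frac", "satfat_frac")]) <= 0)) {
      stop("fraction parameters of '", g$name, "' must be positive ",
           "(sugar cannot exceed carbohydrate by construction)")
    }
  }
  structure(
    list(groups = groups, style_probs = style_probs, defect_rates = rates,
         seed = as.integer(seed)),
    class = "market_config"
  )
}

#' Load the bundled "norway-like" market configuration
#'
#' Reads the versioned YAML shipped with the package: sixteen food groups
#' with sizes and additive prevalences loosely shaped on a national
#' packaged-food market, a two-to-three archetype mixture per group, and
#' small defect-injection rates. The eight additives absent from that
#' market (E426, E427, E479, E483, E493, E494, E495, E499) have inclusion
#' probability zero everywhere.
#'
#' @param n_total Total clean product count; group counts are
#'   `round(share * n_total)` from the YAML shares (normalized).
#' @param path YAML file; defaults to the bundled configuration.
#' @param defect_rates Override the YAML defect rates (e.g. `NULL` keeps
#'   them; a named vector replaces them; `0` named rates disable).
#' @param seed Default generation seed.
#' @return A `market_config`.
#' @export
default_market_config <- function(n_total = 20000, path = NULL,
                                  defect_rates = NULL, seed = 1L) {
  if (is.null(path)) {
    path <- system.file("extdata", "market_norway_like.yml", package = "etscan")
  }
  y <- yaml::read_yaml(path)
  shares <- vapply(y$groups, function(g) g$share, numeric(1))
  shares <- shares / sum(shares)
  profiles <- y$nutrition_profiles
  groups <- purrr::map2(y$groups, shares, function(g, share) {
    list(
      name = g$name,
      n = max(1L, as.integer(round(share * n_total))),
      archetypes = lapply(g$archetypes, function(a) {
        list(weight = a$weight, probs = unlist(a$probs) %||% numeric(0))
      }),
      nutrition = profiles[[g$nutrition]]
    )
  })
  market_config(
    groups,
    style_probs = unlist(y$style_probs),
    defect_rates = if (is.null(defect_rates)) unlist(y$defect_rates) else defect_rates,
    seed = seed
  )
}

#' Analytic ground truth of an archetype-mixture group
#'
#' Closed-form marginal inclusion probability, at-least combination
#' probability and fold enrichment implied by a group's archetype mixture.
#'
#' @param config A `market_config`.
#' @param group Group name.
#' @param codes Character vector of codes (for `analytic_combo_prob()` and
#'   `analytic_fold_enrichment()`).
#' @return `analytic_marginals()`: named numeric vector of `P(c)` over all
#'   codes with positive probability; the other two: a single number.
#' @export
analytic_marginals <- function(config, group) {
  g <- market_group(config, group)
  codes <- sort(unique(unlist(lapply(g$archetypes, function(a) names(a$probs)))))
  vapply(stats::setNames(codes, codes), function(code) {
    sum(vapply(g$archetypes, function(a) {
      a$weight * (a$probs[code] %||% 0)
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
}

#' @rdname analytic_marginals
#' @export
analytic_combo_prob <- function(config, group, codes) {
  g <- market_group(config, group)
  sum(vapply(g$archetypes, function(a) {
    p <- vapply(codes, function(code) {
      v <- a$probs[code]
      if (is.na(v) || is.null(v)) 0 else unname(v)
    }, numeric(1))
    a$weight * prod(p)
  }, numeric(1)))
}

#' @rdname analytic_marginals
#' @export
analytic_fold_enrichment <- function(config, group, codes) {
  marg <- analytic_marginals(config, group)
  analytic_combo_prob(config, group, codes) / prod(marg[codes])
}

market_group <- function(config, group) {
  for (g in config$groups) {
    if (g$name == group) return(g)
  }
  stop("no such group in config: ", group)
}

filler_ingredients <- c(
  "vann", "sukker", "salt", "hvetemel", "rapsolje", "melk", "egg",
  "ris", "tomat", "lok", "pepper", "gjaer", "kakao", "vanilje",
  "havre", "smor", "flote", "potetstivelse", "maisstivelse", "sitronsyre"
)

#' Render an additive set as ingredient-list text
#'
#' Produces a comma-separated ingredient list containing benign filler
#' ingredients plus one token per additive, each rendered in one of four
#' styles: the E-number form (`E407`, `E 407`, `E-407`, possibly lower
#' case), a plaintext name or synonym, a stored misspelling, or a subclass
#' token (`E472a`). Every rendered token is guaranteed to be matched back to
#' its main-class code by [detect_ets()].
#'
#' @param ets_set Character vector of main-class codes.
#' @param lexicon An [ets_lexicon()].
#' @param style Either a single style for all tokens (`"enumber"`, `"name"`,
#'   `"misspelled"`, `"subclass"`) or a named probability vector to draw a
#'   style per token.
#' @param n_filler Number of filler ingredients (drawn 3 to 6 when `NULL`).
#' @return A single ingredient-list string.
#' @export
render_ingredient_text <- function(ets_set, lexicon = ets_lexicon(),
                                   style = c(enumber = 0.45, name = 0.3,
                                             misspelled = 0.15, subclass = 0.1),
                                   n_filler = NULL) {
  entries <- lexicon$entries
  idx <- match(ets_set, entries$code)
  if (anyNA(idx)) {
    stop("codes not in lexicon: ", paste(ets_set[is.na(idx)], collapse = ", "))
  }
  if (is.null(n_filler)) n_filler <- sample(3:6, 1)
  styles <- c("enumber", "name", "misspelled", "subclass")
  tokens <- vapply(idx, function(i) {
    s <- if (length(style) == 1 && is.character(style)) {
      match.arg(style, styles)
    } else {
      sample(styles, 1, prob = style[styles])
    }
    code <- entries$code[i]
    digits <- sub("^E", "", code)
    sub_letters <- strsplit(entries$subclasses[i], "")[[1]]
    if (s == "subclass" && length(sub_letters) == 0) s <- "enumber"
    if (s == "misspelled" && length(entries$misspellings[[i]]) == 0) s <- "name"
    switch(s,
      enumber = sprintf(sample(c("E%s", "E %s", "E-%s", "e%s"), 1), digits),
      name = sample(c(entries$name[i], entries$synonyms[[i]]), 1),
      misspelled = sample(entries$misspellings[[i]], 1),
      subclass = sprintf("E%s%s", digits, sample(sub_letters, 1))
    )
  }, character(1))
  paste(sample(c(sample(filler_ingredients, min(n_filler, length(filler_ingredients))),
                 tokens)), collapse = ", ")
}

draw_nutrition <- function(n, prof) {
  fat <- pmin(stats::rlnorm(n, prof$fat[1], prof$fat[2]), 100)
  carb <- pmin(stats::rlnorm(n, prof$carb[1], prof$carb[2]), 100)
  protein <- pmin(stats::rlnorm(n, prof$protein[1], prof$protein[2]), 100)
  total <- fat + carb + protein
  over <- total > 95
  scale <- ifelse(over, 95 / total, 1)
  fat <- fat * scale; carb <- carb * scale; protein <- protein * scale
  sugar <- carb * stats::rbeta(n, prof$sugar_frac[1], prof$sugar_frac[2])
  satfat <- fat * stats::rbeta(n, prof$satfat_frac[1], prof$satfat_frac[2])
  salt <- pmin(stats::rlnorm(n, prof$salt[1], prof$salt[2]), 25)
  # declared energy: integer kcal label, kJ consistent with 4.184 kJ/kcal,
  # so clean records always pass the kJ/kcal ratio screen
  kcal <- pmax(1, round((37 * fat + 17 * carb + 17 * protein) / 4.184))
  kj <- round(4.184 * kcal)
  tibble::tibble(
    energy_kj = kj, energy_kcal = kcal,
    fat_g = round(fat, 1), satfat_g = round(satfat, 1),
    carb_g = round(carb, 1), sugar_g = round(sugar, 1),
    protein_g = round(protein, 1), salt_g = round(salt, 2)
  )
}

#' Generate a synthetic product market with ground truth
#'
#' Draws a seed-reproducible raw product table from a [market_config()]:
#' per-group archetype-mixture additive sets, rendered ingredient texts
#' (round-trippable through [detect_ets()]), plausible declared nutrition,
#' and injected ineligible and duplicate records in exact correspondence
#' with the returned ground truth. With all defect rates zero,
#' [apply_eligibility()] excludes nothing.
#'
#' @param config A `market_config`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @param lexicon Lexicon used for rendering.
#' @return A list with `records` (raw product tibble, canonical schema),
#'   and `truth`: `products` (tibble of `gtin`, `group`, `true_codes`
#'   list-column, `defect` label, `NA` for clean records), `defect_counts`
#'   (named integer vector), `marginals` (tibble of per-group analytic
#'   `P(c)`) and the `config`.
#' @export
generate_market <- function(config, seed = config$seed,
                            lexicon = ets_lexicon()) {
  stopifnot(inherits(config, "market_config"))
  set.seed(seed)
  gtin_counter <- 0L
  next_gtin <- function(n) {
    out <- sprintf("70%010d", gtin_counter + seq_len(n))
    gtin_counter <<- gtin_counter + n
    out
  }
  raw_labels <- group_raw_labels()

  clean <- purrr::map_dfr(config$groups, function(g) {
    n <- g$n
    w <- vapply(g$archetypes, function(a) a$weight, numeric(1))
    arch <- sample.int(length(w), n, replace = TRUE, prob = w)
    codes_all <- sort(unique(unlist(lapply(g$archetypes, function(a) names(a$probs)))))
    sets <- lapply(arch, function(a) {
      p <- vapply(codes_all, function(code) {
        v <- g$archetypes[[a]]$probs[code]
        if (length(v) == 0 || is.na(v)) 0 else unname(v)
      }, numeric(1))
      if (length(codes_all) == 0) character(0) else
        codes_all[stats::runif(length(codes_all)) < p]
    })
    source <- sample(c("db_A", "db_B"), n, replace = TRUE, prob = c(0.6, 0.4))
    texts <- vapply(sets, function(s) {
      render_ingredient_text(s, lexicon, style = config$style_probs)
    }, character(1))
    nut <- draw_nutrition(n, g$nutrition)
    slug <- gsub("[^A-Za-z]+", " ", g$name)
    tibble::tibble(
      gtin = next_gtin(n),
      name = sprintf("%s product %04d", trimws(slug), seq_len(n)),
      source = source,
      raw_group = ifelse(source == "db_A",
                         raw_labels$db_A[raw_labels$group == g$name],
                         raw_labels$db_B[raw_labels$group == g$name]),
      is_food = TRUE,
      ingredient_text = texts,
      !!!nut,
      group_true = g$name,
      true_codes = sets
    )
  })

  n_clean <- nrow(clean)
  defects <- purrr::imap_dfr(config$defect_rates, function(rate, reason) {
    n_def <- as.integer(round(rate * n_clean))
    if (n_def == 0) return(NULL)
    base <- clean[sample.int(n_clean, n_def, replace = FALSE), ]
    base$gtin <- next_gtin(n_def)
    base$name <- sprintf("%s defect %s %04d", base$name, reason, seq_len(n_def))
    base <- switch(reason,
      non_food = dplyr::mutate(base, is_food = FALSE),
      no_ingredients = dplyr::mutate(base, ingredient_text = NA_character_),
      nutrient_gt_100 = dplyr::mutate(base, fat_g = 120, satfat_g = 10),
      sugar_gt_carb = dplyr::mutate(base, carb_g = 10, sugar_g = 15),
      satfat_gt_fat = dplyr::mutate(base, fat_g = 5, satfat_g = 8),
      no_energy = dplyr::mutate(base, energy_kj = NA_real_, energy_kcal = NA_real_),
      energy_gt_4200 = dplyr::mutate(base, energy_kj = 5000,
                                     energy_kcal = round(5000 / 4.184)),
      bad_kj_kcal_ratio = dplyr::mutate(base, energy_kj = 400, energy_kcal = 133),
      duplicate = {
        # exact copies of existing clean records (same GTIN and name)
        orig <- clean[sample.int(n_clean, n_def, replace = FALSE), ]
        orig
      }
    )
    base$defect <- reason
    base
  })

  records <- dplyr::bind_rows(
    dplyr::mutate(clean, defect = NA_character_),
    defects
  )
  # shuffle so defects are interleaved, then keep originals before copies
  records <- records[order(sample.int(nrow(records))), ]
  dup_rows <- which(!is.na(records$defect) & records$defect == "duplicate")
  if (length(dup_rows) > 0) {
    records <- dplyr::bind_rows(records[-dup_rows, ], records[dup_rows, ])
  }

  truth <- list(
    products = tibble::tibble(
      gtin = records$gtin, group = records$group_true,
      true_codes = records$true_codes, defect = records$defect
    ),
    defect_counts = vapply(
      stats::setNames(exclusion_reasons, exclusion_reasons),
      function(r) sum(records$defect == r, na.rm = TRUE), integer(1)
    ),
    marginals = purrr::map_dfr(config$groups, function(g) {
      m <- analytic_marginals(config, g$name)
      if (length(m) == 0) return(NULL)
      tibble::tibble(group = g$name, code = names(m), p = unname(m))
    }),
    config = config,
    seed = seed
  )
  records <- dplyr::select(records, -"group_true", -"true_codes", -"defect")
  list(records = records, truth = truth)
}

group_raw_labels <- function() {
  map <- default_group_map()
  groups <- food_groups()
  tibble::tibble(
    group = groups,
    db_A = vapply(groups, function(g) {
      raw <- map$raw[map$group == g]
      if (length(raw) >= 1) raw[1] else g
    }, character(1)),
    db_B = vapply(groups, function(g) {
      raw <- map$raw[map$group == g]
      if (length(raw) >= 2) raw[2] else g
    }, character(1))
  )
}
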