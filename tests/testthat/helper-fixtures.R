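# shared fixtures and independent oracles, built in code at test time

valid_record <- function(gtin, name, ...) {
  rec <- tibble::tibble(
    gtin = gtin, name = name, source = "db_A", raw_group = "iskrem",
    is_food = TRUE, ingredient_text = "vann, sukker, E 407",
    energy_kj = 1000, energy_kcal = 239, fat_g = 10, satfat_g = 3,
    carb_g = 20, sugar_g = 5, protein_g = 5, salt_g = 1
  )
  dots <- list(...)
  for (nm in names(dots)) rec[[nm]] <- dots[[nm]]
  rec
}

# 12 records: one violation per exclusion rule + 3 valid (hand-enumerated:
# n_eligible = 3, every tally = 1)
eligibility_fixture <- function() {
  dplyr::bind_rows(
    valid_record("G01", "nonfood item", is_food = FALSE),
    valid_record("G02", "no ingredients", ingredient_text = NA_character_),
    valid_record("G03", "too much fat", fat_g = 101),
    valid_record("G04", "sugar over carb", carb_g = 20, sugar_g = 25),
    valid_record("G05", "satfat over fat", fat_g = 10, satfat_g = 12),
    valid_record("G06", "no energy", energy_kj = NA_real_,
                 energy_kcal = NA_real_),
    valid_record("G07", "too energetic", energy_kj = 4300,
                 energy_kcal = 1028),
    valid_record("G08", "bad ratio", energy_kj = 1000, energy_kcal = 300),
    valid_record("G09", "duplicate a"),
    valid_record("G09", "duplicate b"),
    valid_record("G10", "valid one"),
    valid_record("G11", "valid two")
  )
}

# products tibble straight from additive sets (skips text rendering)
products_from_sets <- function(sets, group = "G") {
  tibble::tibble(
    gtin = sprintf("P%04d", seq_along(sets)),
    group = rep_len(group, length(sets)),
    ets_codes = lapply(sets, sort),
    n_ets = lengths(sets)
  )
}

# Monte-Carlo oracle: empirical pmf of the intersection size of independent
# uniformly random fixed-size subsets, simulated directly
mc_intersection_pmf <- function(N, sizes, draws, seed) {
  set.seed(seed)
  kmax <- min(sizes)
  counts <- integer(kmax + 1)
  for (i in seq_len(draws)) {
    inter <- sample.int(N, sizes[1])
    for (s in sizes[-1]) inter <- intersect(inter, sample.int(N, s))
    counts[length(inter) + 1] <- counts[length(inter) + 1] + 1L
  }
  counts / draws
}

# exhaustive oracle for two sets of size 5 in N = 20: enumerate every
# possible second subset against a fixed first subset and apply the
# two-sided acceptability definition directly
blaker_enumeration_oracle <- function() {
  subsets <- utils::combn(20, 5)
  overlap <- colSums(subsets <= 5)  # first subset fixed at {1..5}
  pmf <- tabulate(overlap + 1, nbins = 6) / ncol(subsets)
  support <- 0:5
  p_for <- function(obs) {
    gamma <- vapply(support, function(x) {
      min(sum(pmf[support <= x]), sum(pmf[support >= x]))
    }, numeric(1))
    g_obs <- gamma[support == obs]
    sum(pmf[gamma <= g_obs * (1 + 1e-7)])
  }
  list(pmf = pmf, support = support, p = p_for)
}

# minimal single-group market configuration
one_group_config <- function(archetypes, n, name = "Premade Food & Dinner Kits",
                             seed = 1L) {
  market_config(
    list(list(
      name = name, n = n, archetypes = archetypes,
      nutrition = list(fat = c(1.5, 0.5), carb = c(2.5, 0.5),
                       protein = c(1.5, 0.5), salt = c(0, 0.5),
                       sugar_frac = c(2, 3), satfat_frac = c(2, 3))
    )),
    seed = seed
  )
}
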