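test_that("market generation is reproducible for a fixed seed", {
  cfg <- default_market_config(n_total = 400, seed = 21)
  a <- generate_market(cfg)
  b <- generate_market(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$products, b$truth$products)
  c <- generate_market(cfg, seed = 22)
  expect_false(identical(a$records, c$records))
})

test_that("configuration validation rejects infeasible parameters", {
  arch_bad_w <- list(list(weight = 0.6, probs = c(E412 = 0.5)),
                     list(weight = 0.6, probs = c(E415 = 0.5)))
  expect_error(one_group_config(arch_bad_w, n = 10), "sum to 1")
  expect_error(one_group_config(
    list(list(weight = 1, probs = c(E412 = 1.2))), n = 10), "\\[0, 1\\]")
  expect_error(one_group_config(
    list(list(weight = 1, probs = c(E999 = 0.5))), n = 10), "lexicon")
  cfg_ok <- one_group_config(list(list(weight = 1, probs = c(E412 = 0.5))),
                             n = 10)
  expect_error(
    market_config(cfg_ok$groups, defect_rates = c(duplicate = 1)),
    "defect rates"
  )
  g <- cfg_ok$groups
  g[[1]]$nutrition$sugar_frac <- c(-1, 2)
  expect_error(market_config(g), "sugar cannot exceed carbohydrate")
})

test_that("rendered ingredient texts round-trip for every style", {
  lex <- ets_lexicon()
  set.seed(99)
  expect_match(render_ingredient_text("E407", lex, style = "enumber"),
               "(?i)e[ -]?407", perl = TRUE)
  sub <- render_ingredient_text("E472", lex, style = "subclass")
  expect_match(sub, "E472[a-f]")
  expect_equal(detect_ets(sub, lex)[[1]], "E472")
  filler_only <- render_ingredient_text(character(0), lex)
  expect_equal(detect_ets(filler_only, lex)[[1]], character(0))
  for (st in c("enumber", "name", "misspelled", "subclass")) {
    for (i in 1:50) {
      s <- sort(sample(lex$entries$code, sample(1:4, 1)))
      txt <- render_ingredient_text(s, lex, style = st)
      expect_identical(detect_ets(txt, lex)[[1]], s, label = paste(st, txt))
    }
  }
})

test_that("injected defects match the ground-truth tallies exactly", {
  cfg <- default_market_config(n_total = 1500, seed = 13)
  mk <- generate_market(cfg)
  out <- apply_eligibility(mk$records)
  expect_equal(out$report$tallies, mk$truth$defect_counts)
  expect_equal(out$report$n_eligible,
               sum(is.na(mk$truth$products$defect)))

  clean_cfg <- default_market_config(n_total = 300, defect_rates = c(non_food = 0),
                                     seed = 13)
  mk0 <- generate_market(clean_cfg)
  out0 <- apply_eligibility(mk0$records)
  expect_true(all(out0$report$tallies == 0))
  expect_equal(out0$report$n_eligible, nrow(mk0$records))
})

test_that("detected additive sets equal the generator's truth per product", {
  cfg <- default_market_config(n_total = 600, defect_rates = c(non_food = 0),
                               seed = 31)
  mk <- generate_market(cfg)
  out <- apply_eligibility(mk$records)
  truth <- mk$truth$products
  m <- match(out$products$gtin, truth$gtin)
  expect_false(anyNA(m))
  expect_identical(
    lapply(out$products$ets_codes, identity),
    lapply(truth$true_codes[m], sort)
  )
  # harmonization recovers the generating group
  expect_identical(out$products$group, truth$group[m])
})

test_that("empirical prevalence converges to the analytic marginals", {
  cfg <- one_group_config(list(
    list(weight = 0.5, probs = c(E412 = 0.8, E415 = 0.8)),
    list(weight = 0.5, probs = c(E412 = 0.1, E415 = 0.1))
  ), n = 5000, seed = 8)
  mk <- generate_market(cfg, seed = 8)
  prods <- apply_eligibility(mk$records)$products
  m <- presence_matrix(prods)
  p_hat <- colSums(m) / nrow(m)
  marg <- analytic_marginals(cfg, cfg$groups[[1]]$name)  # 0.45 each
  for (code in names(marg)) {
    half_width <- 3 * sqrt(marg[code] * (1 - marg[code]) / nrow(m))
    expect_lt(abs(p_hat[code] - marg[code]), half_width)
  }
})

test_that("mixture ground truth matches the hand-derived fold enrichment", {
  cfg <- one_group_config(list(
    list(weight = 0.5, probs = c(E412 = 0.8, E415 = 0.8)),
    list(weight = 0.5, probs = c(E412 = 0.1, E415 = 0.1))
  ), n = 10)
  g <- cfg$groups[[1]]$name
  expect_equal(analytic_combo_prob(cfg, g, c("E412", "E415")),
               0.5 * 0.64 + 0.5 * 0.01)
  expect_equal(analytic_fold_enrichment(cfg, g, c("E412", "E415")),
               (0.5 * 0.64 + 0.5 * 0.01) / 0.45^2)  # ~1.605
  single <- one_group_config(list(list(weight = 1,
                                       probs = c(E412 = 0.3, E415 = 0.6))),
                             n = 10)
  expect_equal(analytic_fold_enrichment(single, g, c("E412", "E415")), 1)
})
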