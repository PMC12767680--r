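test_that("nutrition plausibility checks trigger the documented reasons", {
  expect_equal(is_unrealistic(valid_record("X", "x", fat_g = 101)),
               "nutrient_gt_100")
  expect_equal(is_unrealistic(valid_record("X", "x")), character(0))
  # ratio exactly at the centre of the window passes
  expect_equal(
    is_unrealistic(valid_record("X", "x", energy_kj = 418.4, energy_kcal = 100)),
    character(0)
  )
  # low-energy exemption: ratio 8.0 would fail, but kJ < 10 and kcal < 2
  expect_equal(
    is_unrealistic(valid_record("X", "x", energy_kj = 8, energy_kcal = 1)),
    character(0)
  )
  # the same ratio without the exemption fails
  expect_equal(
    is_unrealistic(valid_record("X", "x", energy_kj = 80, energy_kcal = 10)),
    "bad_kj_kcal_ratio"
  )
  # inclusive window bounds
  expect_equal(
    is_unrealistic(valid_record("X", "x", energy_kj = 398.4, energy_kcal = 100)),
    character(0)
  )
  # absent fields trigger only evaluable checks
  expect_equal(
    is_unrealistic(valid_record("X", "x", energy_kj = NA_real_,
                                energy_kcal = NA_real_)),
    "no_energy"
  )
  expect_equal(
    is_unrealistic(valid_record("X", "x", sugar_g = NA_real_)),
    character(0)
  )
  # multiple violations are all reported, in the fixed check order
  expect_equal(
    is_unrealistic(valid_record("X", "x", fat_g = 110, satfat_g = 120,
                                energy_kj = 5000, energy_kcal = 1195)),
    c("nutrient_gt_100", "satfat_gt_fat", "energy_gt_4200")
  )
})

test_that("GTIN and name duplicates are resolved keeping one record", {
  recs <- dplyr::bind_rows(
    valid_record("A1", "first name"),
    valid_record("A1", "second name"),
    valid_record("A2", "Shared  Name"),
    valid_record("A3", "shared name")
  )
  out <- apply_eligibility(recs)
  expect_equal(out$report$n_eligible, 2)
  expect_equal(unname(out$report$tallies[["duplicate"]]), 2)
})

test_that("an all-valid table passes untouched and empty input is clean", {
  recs <- dplyr::bind_rows(lapply(1:5, function(i) {
    valid_record(sprintf("V%02d", i), sprintf("valid %d", i))
  }))
  out <- apply_eligibility(recs)
  expect_equal(out$report$n_eligible, 5)
  expect_true(all(out$report$tallies == 0))
  expect_equal(out$products$n_ets, rep(1L, 5))  # fixture text carries E 407

  empty <- apply_eligibility(valid_record("x", "y")[0, ])
  expect_equal(empty$report$n_input, 0)
  expect_equal(empty$report$n_eligible, 0)
})

test_that("every input record lands in exactly one bin (conservation)", {
  recs <- eligibility_fixture()
  out <- apply_eligibility(recs)
  expect_equal(out$report$n_input,
               out$report$n_eligible + sum(out$report$tallies))
  # adding a record never evicts a previously eligible one
  more <- dplyr::bind_rows(recs, valid_record("G99", "late arrival"))
  out2 <- apply_eligibility(more)
  expect_true(all(out$products$gtin %in% out2$products$gtin))
})

test_that("raw food groups harmonize onto the sixteen-group taxonomy", {
  expect_equal(harmonize_food_group("iskrem"), "Desserts & Ice Creams")
  expect_equal(harmonize_food_group("Meat & Poultry"), "Meat & Poultry")
  expect_equal(harmonize_food_group("novelty"), "Others")
  expect_warning(out <- harmonize_food_group(NA), "manual")
  expect_true(is.na(out))
  expect_length(food_groups(), 16)
  expect_true(all(default_group_map()$group %in% food_groups()))
})

test_that("tables round-trip through CSV and schema renaming", {
  recs <- eligibility_fixture()
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::rename(recs, ean = gtin, ingredients = ingredient_text),
                   tmp)
  back <- read_product_table(tmp, schema = c(gtin = "ean",
                                             ingredient_text = "ingredients"))
  expect_equal(nrow(back), 12)
  expect_true(all(c("gtin", "ingredient_text") %in% names(back)))
  expect_equal(apply_eligibility(back)$report$n_eligible, 3)
})
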