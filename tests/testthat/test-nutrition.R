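shares_row <- function(e_pct_fat = 0, e_pct_sugar = 0,
                       e_pct_carb_nosugar = 0, sodium_g = 0) {
  tibble::tibble(
    e_pct_fat = e_pct_fat, e_pct_carb = e_pct_sugar + e_pct_carb_nosugar,
    e_pct_sugar = e_pct_sugar, e_pct_carb_nosugar = e_pct_carb_nosugar,
    sodium_g = sodium_g
  )
}

test_that("energy shares use the 37/17 kJ per g factors and 40% sodium", {
  out <- energy_shares(tibble::tibble(
    energy_kj = 1000, fat_g = 10, carb_g = 20, sugar_g = 5, salt_g = 1
  ))
  expect_equal(out$e_pct_fat, 37.0)        # 10 * 37 / 1000 * 100
  expect_equal(out$e_pct_carb, 34.0)
  expect_equal(out$e_pct_sugar, 8.5)
  expect_equal(out$e_pct_carb_nosugar, 25.5)
  expect_equal(out$sodium_g, 0.40)

  zero <- energy_shares(tibble::tibble(
    energy_kj = 500, fat_g = 0, carb_g = 0, sugar_g = 0, salt_g = 0
  ))
  expect_true(all(unlist(zero[c("e_pct_fat", "e_pct_carb", "e_pct_sugar",
                                "e_pct_carb_nosugar", "sodium_g")]) == 0))
  expect_error(energy_shares(tibble::tibble(
    energy_kj = 0, fat_g = 1, carb_g = 1, sugar_g = 0, salt_g = 0
  )), "energy")
})

test_that("energy-share criteria are scale-free in declared energy", {
  base <- tibble::tibble(energy_kj = 800, fat_g = 9, carb_g = 30,
                         sugar_g = 12, salt_g = 1.2)
  scaled <- dplyr::mutate(base, energy_kj = energy_kj * 3, fat_g = fat_g * 3,
                          carb_g = carb_g * 3, sugar_g = sugar_g * 3)
  cls <- function(x) classify_hp(energy_shares(x))$hp_class
  expect_identical(cls(base), cls(scaled))
})

test_that("each hyper-palatability region classifies to its own label", {
  expect_equal(as.character(classify_hp(
    shares_row(e_pct_fat = 10, sodium_g = 0.5))$hp_class), "FatSodium")
  expect_equal(as.character(classify_hp(
    shares_row(e_pct_fat = 25, e_pct_sugar = 25))$hp_class), "FatSugar")
  expect_equal(as.character(classify_hp(
    shares_row(e_pct_carb_nosugar = 50, sodium_g = 0.25))$hp_class),
    "CarbSodium")
  expect_equal(as.character(classify_hp(shares_row())$hp_class), "NotHP")
  expect_equal(as.character(classify_hp(
    shares_row(e_pct_fat = 30, e_pct_sugar = 25, sodium_g = 0.35))$hp_class),
    "FitsMoreThanOne")
  expect_equal(as.character(classify_hp(
    shares_row(e_pct_fat = 30, e_pct_sugar = 25, sodium_g = 0.35),
    is_beverage = TRUE)$hp_class), "ExcludedBeverage")
})

test_that("share thresholds are strict and sodium thresholds non-strict", {
  # exactly at the sodium threshold counts; exactly at the share does not
  expect_equal(as.character(classify_hp(
    shares_row(e_pct_fat = 5.0001, sodium_g = 0.30))$hp_class), "FatSodium")
  expect_equal(as.character(classify_hp(
    shares_row(e_pct_fat = 5, sodium_g = 0.30))$hp_class), "NotHP")
  expect_equal(as.character(classify_hp(
    shares_row(e_pct_fat = 20, e_pct_sugar = 20.5))$hp_class), "NotHP")
  expect_equal(as.character(classify_hp(
    shares_row(e_pct_carb_nosugar = 40, sodium_g = 0.2))$hp_class), "NotHP")
  # the fat threshold of the fat+sodium criterion is configurable
  t25 <- hp_thresholds(fat_sodium_fat_epct = 25)
  expect_equal(as.character(classify_hp(
    shares_row(e_pct_fat = 10, sodium_g = 0.5),
    thresholds = t25)$hp_class), "NotHP")
})

test_that("defensive clamp keeps the non-sugar carbohydrate share at >= 0", {
  out <- energy_shares(tibble::tibble(
    energy_kj = 1000, fat_g = 0, carb_g = 5, sugar_g = 7, salt_g = 0
  ))
  expect_equal(out$e_pct_carb_nosugar, 0)
})
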