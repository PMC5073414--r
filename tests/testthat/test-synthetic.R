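test_that("invalid configuration fields are rejected by name", {
  expect_error(synthetic_config(n_registry = 0), "n_registry")
  expect_error(synthetic_config(typo_rate = 1.5), "typo_rate")
  expect_error(synthetic_config(unlinkable_frac = -0.1), "unlinkable_frac")
  expect_error(synthetic_config(era_quality = data.frame(
    year_from = 1985, year_to = 2000, multiplier = -1)), "multiplier")
})

test_that("seeded generation is bit-reproducible", {
  cfg <- synthetic_config(n_registry = 1000, n_source = 200, seed = 7)
  a <- simulate_registries(cfg)
  b <- simulate_registries(cfg)
  expect_identical(a$registry, b$registry)
  expect_identical(a$source, b$source)
  expect_identical(a$truth, b$truth)
})

test_that("degenerate surname pool yields identical surnames", {
  cfg <- synthetic_config(n_registry = 200, common_surname_frac = 1,
                          common_surname_pool = "LEE", seed = 3)
  reg <- generate_registry(cfg)
  expect_true(all(reg$surname == "LEE"))
})

test_that("common-surname share matches its binomial expectation", {
  cfg <- synthetic_config(n_registry = 10000, common_surname_frac = 0.5,
                          seed = 21)
  reg <- generate_registry(cfg)
  share <- mean(reg$surname %in% cfg$common_surname_pool)
  se <- sqrt(0.5 * 0.5 / 10000)
  # pool and main list overlap on nothing, so the share is a clean binomial
  expect_lt(abs(share - 0.5), 3 * se)
})

test_that("registry is well formed", {
  cfg <- synthetic_config(n_registry = 500, seed = 13)
  reg <- generate_registry(cfg)
  expect_equal(nrow(reg), 500)
  expect_false(anyDuplicated(reg$key) > 0)
  expect_true(all(reg$sex %in% c("F", "M")))
  expect_true(all(grepl("^\\d{4}-\\d{2}-\\d{2}$", reg$birth_date)))
  expect_false(any(is.na(as.Date(reg$birth_date))))
  # identifying tuple unique -> unambiguous ground truth
  tup <- paste(reg$surname, reg$given_names, reg$sex, reg$birth_date)
  expect_false(anyDuplicated(tup) > 0)
})

test_that("noise-free derivation copies identifiers exactly", {
  sim <- simulate_registries(noise_free_config(seed = 5))
  expect_true(all(sim$truth$registry_key != ""))
  idx <- match(sim$truth$registry_key, sim$registry$key)
  for (f in c("surname", "given_names", "sex", "birth_date", "postal_code")) {
    expect_identical(sim$source[[f]], sim$registry[[f]][idx])
  }
})

test_that("unlinkable_frac = 1 gives a truth map of all NONE", {
  cfg <- synthetic_config(n_registry = 100, n_source = 80,
                          unlinkable_frac = 1, seed = 2)
  sim <- simulate_registries(cfg)
  expect_true(all(sim$truth$registry_key == ""))
})

test_that("every source record has exactly one truth entry", {
  cfg <- synthetic_config(n_registry = 300, n_source = 400, dup_frac = 0.2,
                          unlinkable_frac = 0.1, seed = 17)
  sim <- simulate_registries(cfg)
  expect_identical(sort(sim$truth$source_id), sort(sim$source$source_id))
  expect_equal(anyDuplicated(sim$truth$source_id), 0L)
})

test_that("realized unlinkable fraction sits inside binomial 99% bounds", {
  cfg <- synthetic_config(n_registry = 2000, n_source = 5000,
                          unlinkable_frac = 0.05, seed = 29)
  sim <- simulate_registries(cfg)
  k <- sum(sim$truth$registry_key == "")
  expect_gte(k, qbinom(0.005, 5000, 0.05))
  expect_lte(k, qbinom(0.995, 5000, 0.05))
})

test_that("per-field corruption counts match their binomial expectation", {
  flat_era <- data.frame(year_from = 1900, year_to = 2100, multiplier = 1)
  cfg <- synthetic_config(n_registry = 5000, n_source = 10000,
                          unlinkable_frac = 0, dup_frac = 0,
                          typo_rate = 0.1, phonetic_swap_rate = 0,
                          date_transpose_rate = 0, missing_rate = 0,
                          era_quality = flat_era, seed = 31)
  sim <- simulate_registries(cfg)
  n_typo <- sim$corruption_log$surname_typo
  se <- sqrt(10000 * 0.1 * 0.9)
  expect_lt(abs(n_typo - 1000), 3 * se)
})

test_that("duplicates of one truth person differ in event date", {
  cfg <- synthetic_config(n_registry = 200, n_source = 400, dup_frac = 0.5,
                          unlinkable_frac = 0, typo_rate = 0,
                          phonetic_swap_rate = 0, date_transpose_rate = 0,
                          missing_rate = 0, seed = 19)
  sim <- simulate_registries(cfg)
  per <- split(sim$source$event_date, sim$truth$registry_key)
  dups <- per[vapply(per, length, integer(1)) > 1]
  expect_gt(length(dups), 0)
  for (d in dups) expect_equal(anyDuplicated(d), 0L)
})

test_that("corrupt_field applies each operator's documented rule", {
  expect_identical(corrupt_field("1987-04-09", "date_transpose"), "1987-09-04")
  expect_identical(corrupt_field("SMITH", "drop"), "")
  set.seed(1)
  y <- corrupt_field("JOHNSON", "typo")
  expect_false(identical(y, "JOHNSON"))
  expect_true(abs(nchar(y) - 7L) <= 1L)
  # inapplicable operators are warning no-ops
  expect_warning(out <- corrupt_field("1987-04-13", "date_transpose"),
                 "not transposable")
  expect_identical(out, "1987-04-13")
  expect_warning(out2 <- corrupt_field("", "typo"), "missing")
  expect_identical(out2, "")
})

test_that("phonetic swap preserves the NYSIIS code", {
  set.seed(4)
  for (nm in c("MACDONALD", "BROWN", "NIELSEN", "JOHNSON", "PETERSEN",
               "ANDERSON", "KOWALSKI", "FERNANDES")) {
    sw <- corrupt_field(nm, "phonetic_swap")
    expect_identical(nysiis(sw), nysiis(nm))
  }
})

test_that("era multipliers scale realized corruption monotonically", {
  era <- data.frame(year_from = c(1985, 1995, 2005),
                    year_to = c(1994, 2004, 2030),
                    multiplier = c(3, 1.5, 0.5))
  cfg <- synthetic_config(n_registry = 4000, n_source = 10000,
                          unlinkable_frac = 0, dup_frac = 0,
                          typo_rate = 0.1, phonetic_swap_rate = 0,
                          date_transpose_rate = 0, missing_rate = 0,
                          era_quality = era, seed = 37)
  sim <- simulate_registries(cfg)
  idx <- match(sim$truth$registry_key, sim$registry$key)
  corrupted <- sim$source$surname != sim$registry$surname[idx]
  yr <- as.integer(substr(sim$source$event_date, 1, 4))
  band <- cut(yr, c(1984, 1994, 2004, 2030), labels = c("a", "b", "c"))
  rate <- tapply(corrupted, band, mean)
  expect_true(rate[["a"]] > rate[["b"]])
  expect_true(rate[["b"]] > rate[["c"]])
})

test_that("CSV round trip preserves the files byte-for-byte semantics", {
  dir <- withr::local_tempdir()
  sim <- simulate_registries(synthetic_config(n_registry = 50, n_source = 30,
                                              seed = 8))
  paths <- write_synthetic_csv(sim, dir)
  reg <- utils::read.csv(paths[["registry"]], colClasses = "character")
  expect_equal(nrow(reg), 50)
  truth <- utils::read.csv(paths[["truth"]], colClasses = "character")
  expect_identical(truth$registry_key, sim$truth$registry_key)
})
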