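test_that("compute_bmi uses metres and rejects nonpositive inputs", {
  expect_equal(compute_bmi(80, 200), 20.0)
  expect_equal(compute_bmi(75, 170), 75 / 1.7^2, tolerance = 1e-10)
  expect_error(compute_bmi(0, 170), "positive")
  expect_error(compute_bmi(80, -1), "positive")
})

test_that("hf_duration_months completes dates and applies the >= 18 rule", {
  r <- hf_duration_months(hf_date(2017, 1, 15), as.Date("2018-07-15"))
  expect_equal(r$months, 18L); expect_true(r$ge_18)
  r <- hf_duration_months(hf_date(2017), as.Date("2018-07-01"))
  expect_equal(r$months, 12L); expect_false(r$ge_18)
  r <- hf_duration_months(hf_date(2018, 7, 1), as.Date("2018-07-01"))
  expect_equal(r$months, 0L); expect_false(r$ge_18)
  # onset completing after recruitment: missing, not fatal
  r <- hf_duration_months(hf_date(2018), as.Date("2018-03-01"))
  expect_true(is.na(r$months))
})

test_that("select_closest matches a brute-force argmin with earlier-tie rule", {
  rec <- as.Date("2019-06-15")
  expect_equal(select_closest(as.Date("2019-01-01"), rec), 1L)
  expect_equal(select_closest(rec + c(-10, 3), rec), 2L)
  expect_equal(select_closest(rec + c(5, -5), rec), 2L)  # tie -> earlier

  oracle <- function(dates, rec) {
    best <- 1L
    for (i in seq_along(dates)) {
      di <- abs(as.numeric(dates[i] - rec)); db <- abs(as.numeric(dates[best] - rec))
      if (di < db || (di == db && dates[i] < dates[best])) best <- i
    }
    best
  }
  set.seed(7)
  for (trial in 1:300) {
    dates <- rec + sample(-400:400, sample(1:8, 1), replace = TRUE)
    expect_identical(select_closest(dates, rec), oracle(dates, rec))
  }
})

test_that("medication mapping applies absence, default-dose and conversion rules", {
  empty <- data.frame(drug_group = character(0), substance = character(0),
                      dose_mg_day = numeric(0), stringsAsFactors = FALSE)
  m <- map_medication(empty)
  expect_false(m$loop_diuretic); expect_equal(m$furosemide_equiv_dose, 0)

  e1 <- data.frame(drug_group = "loop_diuretic", substance = "furosemide",
                   dose_mg_day = NA_real_, stringsAsFactors = FALSE)
  m <- map_medication(e1)
  expect_true(m$loop_diuretic)
  expect_equal(m$furosemide_equiv_dose, 40)
  expect_true("loop_diuretic_default_dose" %in% m$defaults_applied)

  e2 <- data.frame(drug_group = "loop_diuretic", substance = "torasemide",
                   dose_mg_day = 10, stringsAsFactors = FALSE)
  expect_equal(map_medication(e2)$furosemide_equiv_dose, 40)
  expect_equal(map_medication(e2, torasemide_factor = 2)$furosemide_equiv_dose, 20)

  e3 <- data.frame(drug_group = c("beta_blocker", "statin"),
                   substance = NA_character_, dose_mg_day = NA_real_,
                   stringsAsFactors = FALSE)
  m <- map_medication(e3)
  expect_true(m$beta_blocker); expect_true(m$statin)
  expect_false(m$acei_arb); expect_false(m$loop_diuretic)

  e4 <- data.frame(drug_group = "loop_diuretic", substance = "furosemide",
                   dose_mg_day = -5, stringsAsFactors = FALSE)
  expect_error(map_medication(e4), "negative")
})

test_that("build_harmonized conserves patients and fills the tiny fixture", {
  co <- tiny_cohort()
  h <- build_harmonized(co)
  expect_equal(nrow(h$table), nrow(co$enrollment))
  p07 <- h$table[h$table$local_id == "p07", ]
  expect_equal(p07$age, 68)               # 1950 -> 1950-07-01, rec 2019-06-15
  expect_equal(p07$bmi, 20)               # 80 kg / 2.00 m^2
  expect_equal(p07$hf_duration, 29)       # 2017-01-15 .. 2019-06-15
  expect_true(p07$hf_duration_ge_18)
  expect_true(p07$beta_blocker); expect_false(p07$acei_arb)
  expect_equal(p07$furosemide_equiv_dose, 40)  # torasemide 10 x 4
  expect_equal(p07$lvef, 28)
  expect_equal(p07$creatinine, 95)
  expect_identical(p07$prov_lvef, "2019-06-01")
  # completion events logged
  expect_true(any(h$log$event == "date_completed" & h$log$local_id == "p07"))
})

test_that("missing templates yield missing fields plus log entries", {
  co <- tiny_cohort()
  co$echo <- co$echo[0, ]
  h <- build_harmonized(co)
  expect_true(all(is.na(h$table$lvef)))
  expect_equal(sum(h$log$event == "empty_template" & h$log$detail == "echo"), 2)
  # medication absence is "not taken", not missing
  co$medication <- co$medication[0, ]
  h2 <- build_harmonized(co)
  expect_true(all(h2$table$beta_blocker == FALSE))
  expect_true(all(h2$table$furosemide_equiv_dose == 0))
})

test_that("harmonization is deterministic", {
  co <- generate_site(site_profile("HD", n_patients = 40,
                                   inpatient_fraction = 0), seed = 3)
  expect_identical(build_harmonized(co)$table, build_harmonized(co)$table)
})
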