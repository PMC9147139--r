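test_that("template tables round-trip through the CSV dialect", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  for (tpl in c("enrollment", "personal", "history", "medication", "echo", "labs"))
    expect_identical(back[[tpl]], co[[tpl]], label = tpl)
  # write(read(file)) is byte-identical for canonical files
  f <- file.path(dir, "history.csv")
  bytes1 <- readBin(f, "raw", file.size(f))
  write_template_table(read_template_table(f, "history"), f, "history")
  expect_identical(readBin(f, "raw", file.size(f)), bytes1)
})

test_that("larger generated cohorts also round-trip exactly", {
  co <- generate_site(site_profile("H", n_patients = 25), seed = 5)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  for (tpl in names(hf_cohort(co$enrollment, co$personal, co$history,
                              co$medication, co$echo, co$labs)))
    expect_identical(back[[tpl]], co[[tpl]], label = tpl)
})

test_that("partial birth dates keep their precision through I/O", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  pers <- read_template_table(file.path(dir, "personal.csv"), "personal")
  expect_identical(pers$birth_date, c("1950", "1948-03-20"))
  expect_identical(parse_hf_date("1950")$precision, "year")
})

test_that("the reader enforces header, units and LOINC/analyte consistency", {
  dir <- withr::local_tempdir()
  write_cohort(tiny_cohort(), dir)

  # missing mandatory column is named
  f <- file.path(dir, "echo.csv")
  lines <- readLines(f)
  writeLines(sub(",lvef_percent", "", lines), f)
  expect_error(read_template_table(f, "echo"), "lvef_percent")

  # unknown columns are rejected
  writeLines(c("site,local_id,record_date,lvef_percent,extra",
               "G,p07,2019-06-01,28,1"), f)
  expect_error(read_template_table(f, "echo"), "unknown column")

  # unparseable number carries the row index
  writeLines(c("site,local_id,record_date,lvef_percent",
               "G,p07,2019-06-01,28", "G,p02,2019-03-05,abc"), f)
  expect_error(read_template_table(f, "echo"), "row 2")

  # LOINC 2951-2 belongs to sodium and only sodium
  fl <- file.path(dir, "labs.csv")
  writeLines(c("site,local_id,record_date,loinc,analyte,value,unit",
               "G,p07,2019-06-12,2951-2,creatinine,95,umol/L"), fl)
  expect_error(read_template_table(fl, "labs"), "inconsistent")
  writeLines(c("site,local_id,record_date,loinc,analyte,value,unit",
               "G,p07,2019-06-12,2951-2,sodium,139,mmol/L"), fl)
  expect_identical(read_template_table(fl, "labs")$analyte, "sodium")

  # fixed units are enforced, not converted
  writeLines(c("site,local_id,record_date,loinc,analyte,value,unit",
               "G,p07,2019-06-12,14682-9,creatinine,1.1,mg/dL"), fl)
  expect_error(read_template_table(fl, "labs"), "unit")
})

test_that("validate_cohort reports orphans and duplicate enrollments only", {
  co <- tiny_cohort()
  expect_equal(nrow(validate_cohort(co)), 0)

  co2 <- co
  co2$labs <- rbind(co2$labs, data.frame(
    site = "G", local_id = "ghost", record_date = "2019-01-01",
    loinc = "2951-2", analyte = "sodium", value = 140, unit = "mmol/L",
    stringsAsFactors = FALSE))
  rep2 <- validate_cohort(co2)
  expect_equal(sum(rep2$issue == "orphan_record"), 1)
  expect_equal(rep2$local_id[rep2$issue == "orphan_record"], "ghost")

  co3 <- co
  co3$enrollment <- rbind(co3$enrollment, co3$enrollment[1, ])
  rep3 <- validate_cohort(co3)
  expect_equal(sum(rep3$issue == "duplicate_enrollment"), 1)
})

test_that("pseudonymization is sorted, injective, idempotent, key kept apart", {
  co <- tiny_cohort()  # local ids p07, p02 at site G
  ps <- pseudonymize(co)
  key <- ps$key
  expect_identical(key$pseudonym[key$local_id == "p02"], "G1")
  expect_identical(key$pseudonym[key$local_id == "p07"], "G2")
  expect_false(any(c("p02", "p07") %in% unlist(lapply(ps$cohort, `[[`, "local_id"))))
  expect_equal(anyDuplicated(key$pseudonym), 0)

  # idempotence: second application leaves pseudonyms unchanged
  ps2 <- pseudonymize(ps$cohort)
  expect_identical(ps2$cohort$enrollment$local_id, ps$cohort$enrollment$local_id)

  # idempotence also with >= 10 patients (lexicographic trap: G10 < G2)
  big <- generate_site(site_profile("G", n_patients = 12), seed = 3)
  pb <- pseudonymize(big)
  pb2 <- pseudonymize(pb$cohort)
  expect_identical(pb2$cohort$enrollment$local_id, pb$cohort$enrollment$local_id)

  # empty cohort -> empty key table
  em <- hf_cohort(co$enrollment[0, ], co$personal[0, ], co$history[0, ],
                  co$medication[0, ], co$echo[0, ], co$labs[0, ])
  expect_equal(nrow(pseudonymize(em)$key), 0)
})
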