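test_that("shipped definitions load with their declared policies", {
  defs <- shipped_defs()
  m <- defs$maggic
  expect_equal(m$method, "points_table")
  expect_equal(m$completeness, "require_complete")
  expect_equal(m$horizons, c(1, 3))
  b <- defs$bcn_biohf_v1_synthetic
  expect_equal(b$method, "cox_lp")
  expect_equal(b$completeness, "allow_imputation")
  expect_equal(b$horizons, c(1, 2, 3))
  # the stand-in nature of the Cox coefficients is declared in the file
  expect_match(b$description, "SYNTHETIC")
})

test_that("schema violations are rejected at load time", {
  bad <- toy_points_def()
  bad$points[[1]]$bands[[2]]$min <- 5  # overlap with first band
  expect_error(load_score_definition(write_def_json(bad)), "gap or overlap")

  bad2 <- toy_points_def()
  bad2$risk_lookup$risk$`1`[3] <- 0.9  # breaks monotonicity later on
  expect_error(load_score_definition(write_def_json(bad2)), "monotone")

  bad3 <- toy_points_def()
  bad3$points[[1]]$variable <- "nope"
  expect_error(load_score_definition(write_def_json(bad3)), "undeclared")

  bad4 <- toy_cox_def()
  bad4$baseline_survival <- list(`1` = 0.8, `3` = 0.9)  # increasing S0
  expect_error(load_score_definition(write_def_json(bad4)), "non-increasing")
})

test_that("clipping replaces out-of-boundary values by the nearer bound", {
  def <- load_score_definition(write_def_json(toy_cox_def()))
  r <- clip_inputs(def, list(x = -3, y = 1))
  expect_equal(r$row$x, 0)
  expect_equal(nrow(r$log), 1)
  r2 <- clip_inputs(def, list(x = 5, y = 1))
  expect_equal(r2$row$x, 5)
  expect_equal(nrow(r2$log), 0)
  # idempotence
  r3 <- clip_inputs(def, r$row)
  expect_identical(r3$row, r$row)
})

test_that("the points engine sums matched bands, with stratified lookup", {
  def <- load_score_definition(write_def_json(toy_points_def()))
  expect_equal(points_score(def, list(a = 0, b = -1, c = FALSE))$points, 0L)
  expect_equal(points_score(def, list(a = 12, b = 3, c = FALSE))$points, 5L)
  expect_equal(points_score(def, list(a = 25, b = 3, c = TRUE))$points, 9L)

  miss <- points_score(def, list(a = 12, b = NA, c = TRUE))
  expect_true(is.na(miss$points))
  expect_equal(miss$missing, "b")

  # stratified: same band, different stratum, different points
  sdef <- toy_points_def()
  sdef$variables[[length(sdef$variables) + 1]] <- list(name = "ef", kind = "continuous")
  sdef$points[[length(sdef$points) + 1]] <- list(
    variable = "a2", type = "stratified_bands", stratifier = "ef",
    strata = list(
      list(min = NULL, max = 30, bands = list(
        list(min = NULL, max = 60, points = 0),
        list(min = 60, max = NULL, points = 4))),
      list(min = 30, max = NULL, bands = list(
        list(min = NULL, max = 60, points = 0),
        list(min = 60, max = NULL, points = 2)))))
  sdef$variables[[length(sdef$variables) + 1]] <- list(name = "a2", kind = "continuous")
  sdef$risk_lookup <- list(points = 0:13, risk = list(`1` = seq(0.01, 0.14, by = 0.01)))
  sd <- load_score_definition(write_def_json(sdef))
  lo <- points_score(sd, list(a = 0, b = -1, c = FALSE, ef = 25, a2 = 65))$points
  hi <- points_score(sd, list(a = 0, b = -1, c = FALSE, ef = 35, a2 = 65))$points
  expect_equal(lo, 4L)
  expect_equal(hi, 2L)
})

test_that("points-to-risk is an exact monotone lookup with declared clamping", {
  def <- load_score_definition(write_def_json(toy_points_def()))
  expect_equal(points_to_risk(def, 0, 1), 0.02)
  expect_equal(points_to_risk(def, 1, 1), 0.04)
  expect_equal(points_to_risk(def, 9, 1), 0.20)
  expect_error(points_to_risk(def, 10, 1), "outside lookup domain")

  m <- shipped_defs()$maggic
  risks1 <- vapply(m$risk_lookup$points, function(p) points_to_risk(m, p, 1), numeric(1))
  risks3 <- vapply(m$risk_lookup$points, function(p) points_to_risk(m, p, 3), numeric(1))
  expect_true(all(diff(risks1) >= 0))
  expect_true(all(risks3 >= risks1))
  # clamp declared: scores beyond the table use the plateau row
  expect_equal(points_to_risk(m, 57, 1), max(risks1))
})

test_that("cox risks follow 1 - S0^exp(LP - center)", {
  def <- load_score_definition(write_def_json(toy_cox_def()))
  # LP == center -> risk = 1 - S0
  expect_equal(cox_risk(def, list(x = 3, y = 2.5), 1), 1 - 0.9, tolerance = 1e-12)
  expect_equal(cox_risk(def, list(x = 3, y = 2.5), 3), 1 - 0.7, tolerance = 1e-12)
  # closed form: S0 = 0.9, LP - center = 0.5
  expect_equal(cox_risk(def, list(x = 4, y = 2.5), 1),
               1 - 0.9^exp(0.5), tolerance = 5e-4)
  # S0 = 1 -> risk 0 regardless of LP
  one <- toy_cox_def(); one$baseline_survival <- list(`1` = 1, `3` = 1)
  d1 <- load_score_definition(write_def_json(one))
  expect_equal(cox_risk(d1, list(x = 10, y = -50), 1), 0)
  # missing input -> NA
  expect_true(is.na(cox_risk(def, list(x = 1, y = NA), 1)))
})

test_that("imputation substitutes references and names every substitution", {
  def <- load_score_definition(write_def_json(toy_cox_def()))
  r <- impute(def, list(x = 1, y = NA))
  expect_equal(r$row$y, 2)
  expect_equal(r$imputed, "y")
  r2 <- impute(def, list(x = 1, y = 5))
  expect_equal(r2$row$y, 5)
  expect_length(r2$imputed, 0)
  # variable without a reference stays missing
  r3 <- impute(def, list(x = NA, y = NA))
  expect_true(is.na(r3$row$x))
})

test_that("cohort scoring applies the imputation asymmetry between scores", {
  defs <- shipped_defs()
  tab <- rbind(complete_patient_row(local_id = "G1"),
               complete_patient_row(local_id = "G2", hf_duration = NA_integer_,
                                    hf_duration_ge_18 = NA),
               complete_patient_row(local_id = "G3", lvef = NA_real_))
  sc <- compute_cohort_scores(defs, tab)

  g2m <- sc[sc$local_id == "G2" & sc$score_id == "maggic", ]
  expect_equal(g2m$status, "not_computable")
  expect_match(g2m$reason, "hf_duration_ge_18")
  g2b <- sc[sc$local_id == "G2" & sc$score_id == "bcn_biohf_v1_synthetic", ]
  expect_true(all(g2b$status == "complete"))  # BCN does not use HF duration

  # complete patient: all variants complete, risks in [0,1], 3y >= 1y
  g1 <- sc[sc$local_id == "G1", ]
  expect_true(all(g1$status == "complete"))
  expect_true(all(g1$risk_1y >= 0 & g1$risk_1y <= 1))
  expect_true(all(g1$risk_3y >= g1$risk_1y))

  # missing LVEF: MAGGIC fails; BCN fails complete-case, succeeds imputed
  g3 <- sc[sc$local_id == "G3", ]
  expect_equal(g3$status[g3$score_id == "maggic"], "not_computable")
  expect_equal(g3$status[g3$score_id == "bcn_biohf_v1_synthetic" &
                           g3$variant == "complete"], "not_computable")
  g3i <- g3[g3$score_id == "bcn_biohf_v1_synthetic" & g3$variant == "imputed", ]
  expect_equal(g3i$status, "imputed")
  expect_equal(g3i$imputed_variables, "lvef")
})

test_that("complete-case BCN agrees with and without imputation enabled", {
  defs <- shipped_defs()
  set.seed(12)
  co <- generate_site(site_profile("G", n_patients = 60), seed = 12)
  h <- apply_plausibility(build_harmonized(co)$table)$table
  sc <- compute_cohort_scores(defs["bcn_biohf_v1_synthetic"], h)
  cc <- sc[sc$variant == "complete" & sc$status == "complete", ]
  im <- sc[sc$variant == "imputed", ]
  im <- im[match(cc$local_id, im$local_id), ]
  expect_true(all(im$status == "complete"))
  expect_identical(cc$risk_1y, im$risk_1y)
  expect_identical(cc$risk_3y, im$risk_3y)
})

test_that("worsening one risk factor never lowers the predicted risk", {
  defs <- shipped_defs()
  base <- complete_patient_row()
  worsen <- list(list(nyha = 4L), list(age = 85), list(lvef = 18),
                 list(systolic_bp = 95), list(creatinine = 300),
                 list(beta_blocker = FALSE), list(diabetes = TRUE))
  for (def in defs) {
    sc0 <- compute_cohort_scores(list(def), base)
    r0 <- sc0$risk_1y[sc0$variant == "complete"]
    for (w in worsen) {
      if (def$method == "cox_lp" &&
          !w_name_in_def(names(w)[1], def)) next
      tab <- do.call(complete_patient_row, w)
      sc1 <- compute_cohort_scores(list(def), tab)
      r1 <- sc1$risk_1y[sc1$variant == "complete"]
      expect_gte(r1, r0)
    }
  }
})
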