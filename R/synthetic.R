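#' Site profile for the synthetic cohort generator
#'
#' Describes one synthetic hospital site: cohort size, inpatient/outpatient
#' mix, per-variable generating distributions, per-item missingness, the
#' fraction of birth / HF-onset dates recorded at year precision only, and
#' the rate of deliberately implausible values. Defaults emulate a
#' middle-aged-to-elderly chronic heart-failure cohort recruited at a
#' German university hospital; see the methods vignette for the rationale
#' behind each default.
#'
#' @param site site code, one of `"B"`, `"G"`, `"H"`, `"HD"`, `"WU"`.
#' @param n_patients number of patients to generate (>= 1).
#' @param inpatient_fraction probability that a patient is enrolled as an
#'   inpatient.
#' @param recruitment_window character vector of two ISO dates bounding
#'   recruitment.
#' @param continuous named list of truncated-normal specs
#'   `list(mean, sd, min, max)` (creatinine uses `meanlog`/`sdlog`,
#'   i.e. a truncated log-normal). Variables: `age`, `height`, `bmi`,
#'   `systolic_bp`, `lvef`, `creatinine`, `sodium`, `hemoglobin`, `egfr`.
#' @param nyha_probs probability vector over NYHA classes I-IV (sums to 1).
#' @param smoker_p,diabetes_p,lung_disease_p Bernoulli rates for the
#'   corresponding history flags.
#' @param med_p named Bernoulli rates for drug-group presence
#'   (`beta_blocker`, `acei_arb`, `statin`, `loop_diuretic`).
#' @param dose_missing_p probability that a loop-diuretic entry lacks its
#'   dose (exercises the default-dose rule downstream).
#' @param torasemide_frac fraction of loop-diuretic entries that are
#'   torasemide rather than furosemide.
#' @param hf_onset_mean_months mean of the (exponential) HF-duration
#'   distribution, in months before recruitment.
#' @param missing named per-item missingness probabilities; items:
#'   `weight`, `height`, `systolic_bp`, `nyha`, `current_smoker`,
#'   `hf_first_diagnosis`, `diabetes`, `chronic_lung_disease`, `lvef`,
#'   `creatinine`, `sodium`, `hemoglobin`, `egfr`. A rate of 1 yields no
#'   records carrying that item at all.
#' @param year_only_birth_fraction,year_only_hf_onset_fraction fractions of
#'   dates degraded to year precision.
#' @param implausible_rate probability that a recorded continuous value
#'   (systolic BP, LVEF, creatinine, sodium, hemoglobin, eGFR) is drawn
#'   just outside its plausibility range instead.
#' @param records_per_template integer range `c(lo, hi)` of dated records
#'   generated per template per patient.
#' @return a validated `hf_site_profile` object.
#' @export
site_profile <- function(site,
                         n_patients = 200L,
                         inpatient_fraction = 0.5,
                         recruitment_window = c("2018-06-01", "2021-12-31"),
                         continuous = NULL,
                         nyha_probs = c(0.15, 0.45, 0.32, 0.08),
                         smoker_p = 0.15,
                         diabetes_p = 0.35,
                         lung_disease_p = 0.15,
                         med_p = c(beta_blocker = 0.85, acei_arb = 0.80,
                                   statin = 0.55, loop_diuretic = 0.70),
                         dose_missing_p = 0.30,
                         torasemide_frac = 0.40,
                         hf_onset_mean_months = 36,
                         missing = NULL,
                         year_only_birth_fraction = 0.5,
                         year_only_hf_onset_fraction = 0.3,
                         implausible_rate = 0,
                         records_per_template = c(1L, 3L)) {
  defaults_cont <- list(
    age         = list(mean = 68,   sd = 12,  min = 19,  max = 95),
    height      = list(mean = 170,  sd = 9,   min = 150, max = 195),
    bmi         = list(mean = 27.5, sd = 4.5, min = 16,  max = 45),
    systolic_bp = list(mean = 130,  sd = 20,  min = 75,  max = 245),
    lvef        = list(mean = 35,   sd = 12,  min = 5,   max = 84),
    creatinine  = list(meanlog = log(95), sdlog = 0.35, min = 30, max = 1300),
    sodium      = list(mean = 139,  sd = 3,   min = 121, max = 149),
    hemoglobin  = list(mean = 13.4, sd = 1.8, min = 6,   max = 19.5),
    egfr        = list(mean = 62,   sd = 20,  min = 6,   max = 119)
  )
  if (!is.null(continuous)) defaults_cont[names(continuous)] <- continuous
  defaults_missing <- c(weight = 0.05, height = 0.05, systolic_bp = 0.05,
                        nyha = 0.1, current_smoker = 0.1,
                        hf_first_diagnosis = 0.2, diabetes = 0.05,
                        chronic_lung_disease = 0.1, lvef = 0.1,
                        creatinine = 0.05, sodium = 0.05, hemoglobin = 0.05,
                        egfr = 0.1)
  if (!is.null(missing)) defaults_missing[names(missing)] <- missing
  p <- structure(list(
    site = site, n_patients = as.integer(n_patients),
    inpatient_fraction = inpatient_fraction,
    recruitment_window = as.Date(recruitment_window),
    continuous = defaults_cont, nyha_probs = nyha_probs,
    smoker_p = smoker_p, diabetes_p = diabetes_p,
    lung_disease_p = lung_disease_p, med_p = med_p,
    dose_missing_p = dose_missing_p, torasemide_frac = torasemide_frac,
    hf_onset_mean_months = hf_onset_mean_months,
    missing = defaults_missing,
    year_only_birth_fraction = year_only_birth_fraction,
    year_only_hf_onset_fraction = year_only_hf_onset_fraction,
    implausible_rate = implausible_rate,
    records_per_template = as.integer(records_per_template)
  ), class = "hf_site_profile")
  validate_site_profile(p)
  p
}

validate_site_profile <- function(p) {
  fail <- function(msg) stop(sprintf("invalid site profile: %s", msg), call. = FALSE)
  if (!p$site %in% HF_SITES) fail(sprintf("unknown site '%s'", p$site))
  if (is.na(p$n_patients) || p$n_patients < 1L) fail("n_patients must be >= 1")
  probs <- c(p$inpatient_fraction, p$smoker_p, p$diabetes_p, p$lung_disease_p,
             p$med_p, p$dose_missing_p, p$torasemide_frac, p$missing,
             p$year_only_birth_fraction, p$year_only_hf_onset_fraction,
             p$implausible_rate, p$nyha_probs)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    fail("all probabilities must lie in [0, 1]")
  if (abs(sum(p$nyha_probs) - 1) > 1e-9) fail("nyha_probs must sum to 1")
  if (any(is.na(p$recruitment_window)) || p$recruitment_window[1] > p$recruitment_window[2])
    fail("recruitment_window must be an ordered date pair")
  if (length(p$records_per_template) != 2L ||
      p$records_per_template[1] < 1L ||
      p$records_per_template[1] > p$records_per_template[2])
    fail("records_per_template must be an ordered positive integer pair")
  invisible(p)
}

# rejection-sampled truncated normal (deterministic under the active RNG)
rtnorm <- function(n, mean, sd, min, max) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= min & draw <= max
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

rtlnorm <- function(n, meanlog, sdlog, min, max) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rlnorm(length(todo), meanlog, sdlog)
    ok <- draw >= min & draw <= max
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

# draw a value just outside [lower, upper]: uniform in the 50% band beyond
# the violated bound (never exactly on the inclusive boundary)
draw_implausible <- function(lower, upper) {
  if (stats::runif(1) < 0.5 && lower > 0) {
    v <- stats::runif(1, lower * 0.5, lower)
    min(v, lower - 1e-3)
  } else {
    v <- stats::runif(1, upper, upper * 1.5)
    max(v, upper + 1e-3)
  }
}

#' Generate a synthetic cohort for one site
#'
#' Fully deterministic given `(profile, seed)`. All generated patients are
#' at least 18 years old at recruitment (the study inclusion bound holds
#' even after mid-year completion of year-precision birth dates), and with
#' `implausible_rate = 0` every generated value lies inside the packaged
#' plausibility limits.
#'
#' @param profile an [site_profile()] object.
#' @param seed integer seed.
#' @return an `hf_cohort`.
#' @export
generate_site <- function(profile, seed) {
  validate_site_profile(profile)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))

  n <- profile$n_patients
  site <- profile$site
  cont <- profile$continuous
  miss <- profile$missing
  lim <- default_limits()
  krange <- profile$records_per_template
  nrec <- function() sample(seq(krange[1], krange[2]), 1L)

  maybe_implausible <- function(value, var) {
    if (profile$implausible_rate > 0 &&
        stats::runif(1) < profile$implausible_rate) {
      b <- lim$static[lim$static$variable == var, ]
      round(draw_implausible(b$lower, b$upper), 3)
    } else value
  }

  row_store <- function() {
    env <- new.env(parent = emptyenv())
    env$rows <- vector("list", 64L); env$k <- 0L
    env
  }
  push <- function(store, row) {
    store$k <- store$k + 1L
    if (store$k > length(store$rows)) length(store$rows) <- 2L * length(store$rows)
    store$rows[[store$k]] <- row
  }
  collect <- function(store, template) {
    if (!store$k) return(empty_template(template))
    rows <- store$rows[seq_len(store$k)]
    cols <- names(hf_template_schema(template))
    out <- lapply(cols, function(cn) unlist(lapply(rows, `[[`, cn), use.names = FALSE))
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }

  local_ids <- sprintf("p%04d", seq_len(n))
  status <- ifelse(stats::runif(n) < profile$inpatient_fraction,
                   "inpatient", "outpatient")
  window_days <- as.integer(profile$recruitment_window[2] - profile$recruitment_window[1])
  recruit <- profile$recruitment_window[1] +
    sample.int(window_days + 1L, n, replace = TRUE) - 1L

  age <- rtnorm(n, cont$age$mean, cont$age$sd, cont$age$min, cont$age$max)
  # full birth date: age plus a sub-year offset; the margin keeps completed
  # ages >= 18 even when the date is degraded to year precision
  birth_full <- recruit - round((age + stats::runif(n, 0.05, 0.9)) * 365.2425)
  birth_year_only <- stats::runif(n) < profile$year_only_birth_fraction
  sex <- ifelse(stats::runif(n) < 0.65, "male", "female")

  height <- round(rtnorm(n, cont$height$mean, cont$height$sd,
                         cont$height$min, cont$height$max), 1)
  bmi <- rtnorm(n, cont$bmi$mean, cont$bmi$sd, cont$bmi$min, cont$bmi$max)
  weight <- round(bmi * (height / 100)^2, 1)
  sbp <- round(rtnorm(n, cont$systolic_bp$mean, cont$systolic_bp$sd,
                      cont$systolic_bp$min, cont$systolic_bp$max), 0)
  lvef <- round(rtnorm(n, cont$lvef$mean, cont$lvef$sd,
                       cont$lvef$min, cont$lvef$max), 0)
  creat <- round(rtlnorm(n, cont$creatinine$meanlog, cont$creatinine$sdlog,
                         cont$creatinine$min, cont$creatinine$max), 1)
  sodium <- round(rtnorm(n, cont$sodium$mean, cont$sodium$sd,
                         cont$sodium$min, cont$sodium$max), 1)
  hgb <- round(rtnorm(n, cont$hemoglobin$mean, cont$hemoglobin$sd,
                      cont$hemoglobin$min, cont$hemoglobin$max), 1)
  egfr <- round(rtnorm(n, cont$egfr$mean, cont$egfr$sd,
                       cont$egfr$min, cont$egfr$max), 1)
  nyha <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                 prob = profile$nyha_probs)
  smoker <- stats::runif(n) < profile$smoker_p
  diabetes <- stats::runif(n) < profile$diabetes_p
  lung <- stats::runif(n) < profile$lung_disease_p
  # HF duration in months before recruitment; >= 12 keeps the completed
  # onset date safely before recruitment and the dynamic age*12 bound holds
  onset_cap <- pmin(240, (floor(age) - 19) * 12)
  onset_months <- pmin(12 + stats::rexp(n, 1 / profile$hf_onset_mean_months),
                       onset_cap)
  onset_full <- recruit - round(onset_months * 30.44)
  onset_year_only <- stats::runif(n) < profile$year_only_hf_onset_fraction

  med_present <- sapply(names(profile$med_p), function(g)
    stats::runif(n) < profile$med_p[[g]])

  enr <- row_store(); pers <- row_store(); hist_rows <- row_store()
  med_rows <- row_store(); echo_rows <- row_store(); lab_rows <- row_store()

  for (i in seq_len(n)) {
    pid <- local_ids[i]
    rdate <- recruit[i]
    push(enr, list(site = site, local_id = pid,
                   recruitment_date = format(rdate), status = status[i]))
    bd <- if (birth_year_only[i]) format(birth_full[i], "%Y") else format(birth_full[i])
    push(pers, list(site = site, local_id = pid, birth_date = bd, sex = sex[i]))

    # patient history: k dated records around recruitment
    k <- nrec()
    hdates <- sort(rdate + sample.int(241L, k, replace = FALSE) - 121L)
    onset_tok <- if (onset_year_only[i]) format(onset_full[i], "%Y") else format(onset_full[i])
    for (d in seq_len(k)) {
      push(hist_rows, list(
        site = site, local_id = pid, record_date = format(hdates[d]),
        weight_kg = if (stats::runif(1) < miss[["weight"]]) NA_real_ else weight[i],
        height_cm = if (stats::runif(1) < miss[["height"]]) NA_real_ else height[i],
        systolic_bp_mmhg = if (stats::runif(1) < miss[["systolic_bp"]]) NA_real_ else
          maybe_implausible(sbp[i], "systolic_bp"),
        nyha = if (stats::runif(1) < miss[["nyha"]]) NA_character_ else nyha[i],
        current_smoker = if (stats::runif(1) < miss[["current_smoker"]]) NA else smoker[i],
        hf_first_diagnosis = if (stats::runif(1) < miss[["hf_first_diagnosis"]]) NA_character_ else onset_tok,
        diabetes = if (stats::runif(1) < miss[["diabetes"]]) NA else diabetes[i],
        chronic_lung_disease = if (stats::runif(1) < miss[["chronic_lung_disease"]]) NA else lung[i]))
    }

    # medication lists: shared record_date per list, presence constant
    kl <- nrec()
    mdates <- sort(rdate + sample.int(121L, kl, replace = FALSE) - 61L)
    for (d in seq_len(kl)) {
      for (g in names(profile$med_p)) {
        if (!med_present[i, g]) next
        if (g == "loop_diuretic") {
          tora <- stats::runif(1) < profile$torasemide_frac
          substance <- if (tora) "torasemide" else "furosemide"
          dose <- if (stats::runif(1) < profile$dose_missing_p) NA_real_ else
            if (tora) sample(c(5, 10, 20), 1) else sample(c(20, 40, 80, 125), 1)
        } else {
          substance <- NA_character_; dose <- NA_real_
        }
        push(med_rows, list(
          site = site, local_id = pid, record_date = format(mdates[d]),
          drug_group = g, substance = substance, dose_mg_day = dose))
      }
    }

    # echocardiography: item-level missingness removes the record entirely
    if (stats::runif(1) >= miss[["lvef"]]) {
      ke <- nrec()
      edates <- sort(rdate + sample.int(241L, ke, replace = FALSE) - 121L)
      for (d in seq_len(ke)) {
        push(echo_rows, list(
          site = site, local_id = pid, record_date = format(edates[d]),
          lvef_percent = maybe_implausible(lvef[i], "lvef")))
      }
    }

    lab_vals <- c(creatinine = creat[i], sodium = sodium[i],
                  hemoglobin = hgb[i], egfr = egfr[i])
    for (an in names(lab_vals)) {
      if (stats::runif(1) < miss[[an]]) next
      kl2 <- nrec()
      ldates <- sort(rdate + sample.int(121L, kl2, replace = FALSE) - 61L)
      for (d in seq_len(kl2)) {
        push(lab_rows, list(
          site = site, local_id = pid, record_date = format(ldates[d]),
          loinc = HF_LOINC[[an]][1], analyte = an,
          value = maybe_implausible(lab_vals[[an]], an),
          unit = HF_LAB_UNITS[[an]]))
      }
    }
  }

  hf_cohort(enrollment = collect(enr, "enrollment"),
            personal = collect(pers, "personal"),
            history = collect(hist_rows, "history"),
            medication = collect(med_rows, "medication"),
            echo = collect(echo_rows, "echo"),
            labs = collect(lab_rows, "labs"))
}

#' Derive a per-site sub-seed from a master seed
#'
#' Stable hash of `(seed, site code)`, so that a site's cohort does not
#' depend on the order of profiles in the configuration.
#'
#' @param seed master integer seed.
#' @param site site code.
#' @return integer in `[1, 2^31 - 2]`.
#' @export
site_subseed <- function(seed, site) {
  h <- digest::digest(paste(seed, site, sep = ":"), algo = "xxhash32",
                      serialize = FALSE)
  # parse as double: 32-bit hex can exceed .Machine$integer.max
  as.integer(as.numeric(paste0("0x", h)) %% 2147483646) + 1L
}

#' Generate synthetic cohorts for several sites
#'
#' @param profiles list of [site_profile()] objects with distinct site codes.
#' @param seed master integer seed; each site uses [site_subseed()].
#' @return named list of `hf_cohort` objects (one per site code).
#' @export
generate_multisite <- function(profiles, seed) {
  if (!length(profiles)) return(list())
  codes <- vapply(profiles, function(p) p$site, character(1))
  if (anyDuplicated(codes))
    stop("generate_multisite: duplicate site codes", call. = FALSE)
  out <- lapply(profiles, function(p) generate_site(p, site_subseed(seed, p$site)))
  names(out) <- codes
  out
}

#' Default five-site study profiles
#'
#' A ready-made multi-site configuration echoing the recruitment structure
#' of a five-center German heart-failure cohort: one site recruiting only
#' outpatients, one mainly inpatients, and heterogeneous per-item
#' missingness (e.g. poor HF-onset and LVEF availability at site B).
#' Numeric choices are documented in the methods vignette.
#'
#' @param n_scale multiplier applied to every site's default `n_patients`.
#' @return list of [site_profile()] objects.
#' @export
default_study_profiles <- function(n_scale = 1) {
  sz <- function(n) max(1L, as.integer(round(n * n_scale)))
  list(
    site_profile("B",  n_patients = sz(300), inpatient_fraction = 0.85,
                 missing = c(hf_first_diagnosis = 0.8, current_smoker = 0.6,
                             lvef = 0.5)),
    site_profile("G",  n_patients = sz(350), inpatient_fraction = 0.35,
                 missing = c(hf_first_diagnosis = 0.35)),
    site_profile("H",  n_patients = sz(950), inpatient_fraction = 0.92,
                 missing = c(hf_first_diagnosis = 0.45)),
    site_profile("HD", n_patients = sz(300), inpatient_fraction = 0,
                 missing = c(hf_first_diagnosis = 0.4, nyha = 0.3,
                             creatinine = 0.25)),
    site_profile("WU", n_patients = sz(550), inpatient_fraction = 0.06,
                 missing = c(hf_first_diagnosis = 0.5, weight = 0.35,
                             height = 0.35))
  )
}
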