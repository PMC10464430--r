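#' Default synthetic cause catalogue
#'
#' One row per level-4 cause of the demo map that the generator can assign
#' as a true cause: a representative specific ICD-10 code used as the
#' underlying cause when the death is not garbled, relative prevalence
#' weights per redistribution age group, and the sex the cause is limited
#' to (`"both"` otherwise). Weights are loosely modelled on the mortality
#' profile of an ageing Western European population: cardiovascular
#' disease, dementia and pneumonia dominate at old ages, injuries at young
#' ages.
#'
#' @return data.table with columns `cause_l4`, `code`, `sex`, and one
#'   weight column per age group (`w1`..`w6`).
#' @export
synthetic_catalogue <- function() {
  dt <- data.table::fread(text = '
cause_l4,code,sex,w1,w2,w3,w4,w5,w6
ischemic_heart_disease,I219,both,0.1,0.1,1,6,14,15
ischemic_stroke,I639,both,0.1,0.1,0.5,3,9,11
hemorrhagic_stroke,I619,both,0.1,0.1,0.5,2,4,4
alzheimers_dementias,G309,both,0,0,0.05,1,8,16
lung_cancer,C349,both,0,0,0.5,8,10,3
breast_cancer,C509,female,0,0,1,5,5,2
prostate_cancer,C619,male,0,0,0.05,2,6,6
cervical_cancer,C539,female,0,0,0.6,1.2,0.8,0.3
uterine_cancer,C549,female,0,0,0.3,1.5,1.6,0.6
colorectal_cancer,C189,both,0,0,0.4,4,6,3
diabetes_mellitus,E119,both,0.05,0.05,0.3,2,4,3
chronic_kidney_disease,N189,both,0.05,0.05,0.2,1,3,4
copd,J449,both,0,0,0.1,3,8,5
lower_respiratory_infections,J159,both,0.3,0.1,0.3,1.5,6,10
atrial_fibrillation,I489,both,0,0,0.05,0.5,2,4
hypertensive_heart_disease,I119,both,0,0,0.1,0.8,2,3
other_cardiovascular,I719,both,0.05,0.05,0.3,1.5,3,3
cirrhosis,K709,both,0,0,0.5,3,2,0.5
self_harm,X709,both,0,0.2,4,3,1,0.5
falls,W199,both,0.1,0.1,0.5,1,2,4
road_injuries,V892,both,0.2,0.5,3,1.5,0.8,0.3
accidental_poisoning,X449,both,0.05,0.05,1.5,1,0.3,0.1
drug_use_disorders,F119,both,0,0,1,0.5,0.1,0
diarrheal_diseases,A099,both,0.3,0.1,0.1,0.3,1,2
parkinsons_disease,G209,both,0,0,0,0.3,2,2
')
  dt[]
}

#' Default garble map
#'
#' For each true cause, the ill-defined codes it may be garbled into and
#' their probabilities, emulating the classic garbage-code regime: heart
#' disease certified as unspecified heart failure (I50.9), strokes as
#' unspecified stroke (I64), pneumonias as unspecified pneumonia (J18.9),
#' uterine cancers as uterus-part-unspecified (C55), kidney disease as
#' unspecified kidney failure (N19/N17.9), dementia as unspecified
#' dementia (F03), and a residual of wholly uninformative codes (R99, R96,
#' R54, I46). The `.default` element applies to causes not listed.
#'
#' @return Named list of data.frames with columns `code`, `p`.
#' @export
synthetic_garble_map <- function() {
  g <- function(...) {
    x <- c(...)
    data.frame(code = names(x), p = unname(x))
  }
  cardio <- g(I509 = 0.7, R99 = 0.2, R54 = 0.1)
  stroke <- g(I64 = 0.7, R99 = 0.2, R54 = 0.1)
  cancer <- g(C80 = 0.7, R99 = 0.2, R54 = 0.1)
  injury <- g(Y34 = 0.7, R99 = 0.2, R54 = 0.1)
  resp <- g(J989 = 0.7, R99 = 0.2, R54 = 0.1)
  list(
    ischemic_heart_disease = cardio,
    hypertensive_heart_disease = cardio,
    atrial_fibrillation = cardio,
    other_cardiovascular = cardio,
    ischemic_stroke = stroke,
    hemorrhagic_stroke = stroke,
    lower_respiratory_infections = g(J189 = 0.7, R99 = 0.2, R54 = 0.1),
    lung_cancer = cancer,
    breast_cancer = cancer,
    prostate_cancer = cancer,
    colorectal_cancer = cancer,
    cervical_cancer = g(C55 = 0.7, R99 = 0.2, R54 = 0.1),
    uterine_cancer = g(C55 = 0.7, R99 = 0.2, R54 = 0.1),
    chronic_kidney_disease = g(N19 = 0.5, N179 = 0.2, R99 = 0.2,
                               R54 = 0.1),
    diabetes_mellitus = g(N19 = 0.7, R99 = 0.2, R54 = 0.1),
    alzheimers_dementias = g(F03 = 0.7, R54 = 0.2, R99 = 0.1),
    copd = resp,
    asthma = resp,
    cirrhosis = g(K729 = 0.7, R99 = 0.2, R54 = 0.1),
    self_harm = injury,
    accidental_poisoning = injury,
    road_injuries = injury,
    falls = injury,
    .default = g(R99 = 0.5, R96 = 0.2, R54 = 0.2, I46 = 0.1)
  )
}

#' Synthetic-data generator configuration
#'
#' @param years Calendar years to generate (default 2010--2019; the first
#'   `window_years - 1` serve as redistribution lead-in).
#' @param n_per_year Deaths per year (default 2000).
#' @param idd_fraction Probability that a death's UC is garbled into an
#'   ill-defined code (default 0.33, the magnitude seen in high-IDD
#'   registries).
#' @param p_mcod_truth Probability that the true cause remains on the
#'   certificate as a contributory (MCOD) code after garbling (default
#'   0.8).
#' @param mcod_noise_mean Mean number of additional contributory codes per
#'   death (Poisson; default 1.2).
#' @param idd_noise_share Share of noise codes drawn from ill-defined
#'   codes rather than specific ones (default 0.3); this is what makes
#'   package codes appear in MCOD chains of specific deaths.
#' @param idd_logit_age Logit-scale increase of the garbling probability
#'   per year of age above the mean age (default 0: age-independent).
#' @param idd_logit_female Logit-scale shift of the garbling probability
#'   for females (default 0).
#' @param female_share Probability a death is female (default 0.51).
#' @param age_mean,age_sd,young_frac Age model: a Normal(`age_mean`,
#'   `age_sd`) bulk (mode near 80) mixed with a `young_frac` uniform
#'   0--54 component; clamped to 0--110 completed years.
#' @param region_weights Named sampling weights for the region labels.
#' @param catalogue Cause catalogue (see [synthetic_catalogue()]).
#' @param garble_map Garble map (see [synthetic_garble_map()]).
#' @param seed RNG seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(years = 2010:2019, n_per_year = 2000,
                             idd_fraction = 0.33, p_mcod_truth = 0.8,
                             mcod_noise_mean = 1.2, idd_noise_share = 0.3,
                             idd_logit_age = 0, idd_logit_female = 0,
                             female_share = 0.51, age_mean = 79,
                             age_sd = 12, young_frac = 0.04,
                             region_weights = c(north = 0.55,
                                                capital = 0.12,
                                                south = 0.33),
                             catalogue = synthetic_catalogue(),
                             garble_map = synthetic_garble_map(),
                             seed = 1L) {
  stopifnot(idd_fraction >= 0, idd_fraction < 1,
            p_mcod_truth >= 0, p_mcod_truth <= 1,
            n_per_year >= 1, length(years) >= 1)
  for (gm in garble_map)
    if (abs(sum(gm$p) - 1) > 1e-9)
      stop("garble map probabilities must sum to 1", call. = FALSE)
  structure(list(years = as.integer(years),
                 n_per_year = as.integer(n_per_year),
                 idd_fraction = idd_fraction, p_mcod_truth = p_mcod_truth,
                 mcod_noise_mean = mcod_noise_mean,
                 idd_noise_share = idd_noise_share,
                 idd_logit_age = idd_logit_age,
                 idd_logit_female = idd_logit_female,
                 female_share = female_share, age_mean = age_mean,
                 age_sd = age_sd, young_frac = young_frac,
                 region_weights = region_weights,
                 catalogue = data.table::as.data.table(catalogue),
                 garble_map = garble_map, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate synthetic death-certificate microdata with known truth
#'
#' Draws age, sex, region and a true level-4 cause per death from the
#' catalogue's age/sex-specific prevalence weights; garbles the underlying
#' cause into an ill-defined code with probability `idd_fraction`
#' (optionally age/sex-dependent); retains the true cause's ICD code in
#' the MCOD chain with probability `p_mcod_truth`; and adds Poisson noise
#' codes. Reproducible under `seed`.
#'
#' @param config A [generator_config()].
#' @return List of class `synthetic_cod` with `data` (a [cod_data]),
#'   `truth` (data.table `record_id`, `cause_l4`, `garbled`, `uc`) and the
#'   `config`.
#' @export
generate_synthetic_deaths <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cat <- config$catalogue
  # every garble target must exist (garbled codes are checked against the
  # demo map at test time; here we only check structure)
  set.seed(config$seed)
  n <- length(config$years) * config$n_per_year
  year <- rep(config$years, each = config$n_per_year)
  young <- stats::runif(n) < config$young_frac
  age <- ifelse(young,
                floor(stats::runif(n, 0, 55)),
                round(stats::rnorm(n, config$age_mean, config$age_sd)))
  age <- as.integer(pmin(pmax(age, 0), 110))
  sex <- ifelse(stats::runif(n) < config$female_share, "female", "male")
  region <- sample(names(config$region_weights), n, replace = TRUE,
                   prob = config$region_weights)
  agi <- age_group6_int(age)
  sxi <- ifelse(sex == "male", 1L, 2L)

  # true cause per (age group, sex) stratum
  wcols <- paste0("w", 1:6)
  cause <- character(n)
  for (g in 1:6) for (s in 1:2) {
    idx <- which(agi == g & sxi == s)
    if (!length(idx)) next
    w <- cat[[wcols[g]]]
    w[cat$sex == "male" & s == 2L] <- 0
    w[cat$sex == "female" & s == 1L] <- 0
    cause[idx] <- cat$cause_l4[sample.int(nrow(cat), length(idx),
                                          replace = TRUE, prob = w)]
  }

  # garbling
  pg <- stats::plogis(stats::qlogis(config$idd_fraction) +
                        config$idd_logit_age * (age - config$age_mean) +
                        config$idd_logit_female * (sex == "female"))
  if (config$idd_fraction == 0) pg[] <- 0
  garbled <- stats::runif(n) < pg
  uc <- cat$code[match(cause, cat$cause_l4)]
  gm <- config$garble_map
  for (cz in unique(cause[garbled])) {
    idx <- which(garbled & cause == cz)
    spec <- if (!is.null(gm[[cz]])) gm[[cz]] else gm$.default
    uc[idx] <- spec$code[sample.int(nrow(spec), length(idx),
                                    replace = TRUE, prob = spec$p)]
  }

  record_id <- sprintf("r%07d", seq_len(n))
  deaths <- data.table::data.table(record_id = record_id, year = year,
                                   age = age, sex = sex, region = region,
                                   uc = normalize_icd(uc))

  # MCOD: retained truth for garbled deaths + noise codes for everyone
  roles <- c("immediate", "intermediate", "associated")
  keep_truth <- garbled & stats::runif(n) < config$p_mcod_truth
  mc_truth <- data.table::data.table(
    record_id = record_id[keep_truth],
    code = cat$code[match(cause[keep_truth], cat$cause_l4)],
    role = sample(roles, sum(keep_truth), replace = TRUE))
  k <- stats::rpois(n, config$mcod_noise_mean)
  nz <- which(k > 0)
  rid_noise <- rep(nz, k[nz])
  m <- length(rid_noise)
  from_idd <- stats::runif(m) < config$idd_noise_share
  noise_code <- character(m)
  if (any(from_idd)) {
    # disease-linked ill-defined mentions: the same garbage codes a death
    # of this cause would be garbled into also appear as contributory
    # codes (heart failure on cardiac deaths, N19 on kidney deaths, ...)
    idx <- rid_noise[from_idd]
    codes <- character(length(idx))
    for (cz in unique(cause[idx])) {
      sel <- cause[idx] == cz
      spec <- if (!is.null(gm[[cz]])) gm[[cz]] else gm$.default
      codes[sel] <- spec$code[sample.int(nrow(spec), sum(sel),
                                         replace = TRUE, prob = spec$p)]
    }
    noise_code[from_idd] <- codes
  }
  if (any(!from_idd)) {
    # specific comorbidity mentions drawn from the death's own
    # age-group/sex cause mix
    idx <- rid_noise[!from_idd]
    codes <- character(length(idx))
    for (g in 1:6) for (s in 1:2) {
      sel <- agi[idx] == g & sxi[idx] == s
      if (!any(sel)) next
      w <- cat[[wcols[g]]]
      w[cat$sex == "male" & s == 2L] <- 0
      w[cat$sex == "female" & s == 1L] <- 0
      noise_cause <- cat$cause_l4[sample.int(nrow(cat), sum(sel),
                                             replace = TRUE, prob = w)]
      codes[sel] <- cat$code[match(noise_cause, cat$cause_l4)]
    }
    noise_code[!from_idd] <- codes
  }
  mc_noise <- data.table::data.table(
    record_id = record_id[rid_noise],
    code = noise_code,
    role = sample(roles, m, replace = TRUE))
  mcod <- rbind(mc_truth, mc_noise)
  mcod$code <- normalize_icd(mcod$code)
  data.table::setorder(mcod, record_id)

  truth <- data.table::data.table(record_id = record_id, cause_l4 = cause,
                                  garbled = garbled, uc = deaths$uc)
  structure(list(data = cod_data(deaths, mcod), truth = truth,
                 config = config),
            class = "synthetic_cod")
}

#' @export
print.synthetic_cod <- function(x, ...) {
  cat("<synthetic_cod> ", nrow(x$truth), " deaths, ",
      round(100 * mean(x$truth$garbled), 1), "% garbled\n", sep = "")
  invisible(x)
}

#' Deterministic population counts matching the generator demographics
#'
#' Builds a mid-year population table (year, sex, region, five-year age
#' group) consistent with the synthetic microdata: a fixed age pyramid,
#' the configured sex and region shares, and a total of
#' `n_per_year * scale` persons per year.
#'
#' @param config A [generator_config()].
#' @param scale Persons per annual death (default 100, i.e. a crude
#'   mortality around 1000 per 100,000).
#' @return data.table with `year`, `sex`, `region`, `age_lo`,
#'   `population`.
#' @export
synthetic_population <- function(config = generator_config(),
                                 scale = 100) {
  pyramid <- c(5, 5, 5.5, 5.5, 6, 6, 6.5, 6.5, 6.5, 7, 7, 7, 6.5, 5.5,
               4.5, 3.5, 2.5, 1.5, 0.8)
  age_lo <- c(seq(0, 85, by = 5), 90)
  pyr <- pyramid / sum(pyramid)
  grid <- data.table::CJ(year = config$years,
                         sex = c("female", "male"),
                         region = names(config$region_weights),
                         age_lo = age_lo, sorted = TRUE)
  sexw <- c(female = config$female_share, male = 1 - config$female_share)
  grid$population <- config$n_per_year * scale *
    pyr[match(grid$age_lo, age_lo)] *
    sexw[grid$sex] * config$region_weights[grid$region]
  grid[]
}

#' Compare redistributed estimates against known truth
#'
#' Joins per-cause true counts (from the generator's truth table,
#' restricted to the summarized report years) with the ensemble summary:
#' relative errors of the mean estimates and coverage of the 95%
#' uncertainty intervals.
#'
#' @param synth A `synthetic_cod` (or a truth table with `record_id`,
#'   `cause_l4`).
#' @param summary A `redistribution_summary` (counts keyed by the same
#'   stratifiers).
#' @param map The [cause_map] used.
#' @return data.table per cause (and summary stratifiers): `true_n`,
#'   `mean`, `lower`, `upper`, `rel_error`, `covered`.
#' @export
recovery_report <- function(synth, summary, map) {
  stopifnot(inherits(summary, "redistribution_summary"))
  truth <- if (inherits(synth, "synthetic_cod")) synth$truth else
    data.table::as.data.table(synth)
  d <- if (inherits(synth, "synthetic_cod"))
    synth$data$deaths else NULL
  if (!is.null(d))
    truth <- merge(truth, d[, c("record_id", "year", "sex", "region")],
                   by = "record_id")
  truth <- truth[truth$year %in% summary$years]
  truth$cause <- cause_at_level(truth$cause_l4, map, summary$level)
  tc <- truth[, list(true_n = .N), by = c(summary$by, "cause")]
  out <- merge(summary$counts, tc, by = c(summary$by, "cause"),
               all = TRUE)
  # a cause can vanish from the estimates when every one of its deaths was
  # garbled and redistributed elsewhere (e.g. a rare-filtered cause): that
  # is an estimate of zero, not an inconsistency
  zero <- is.na(out$mean)
  out$mean[zero] <- 0
  out$lower[zero] <- 0
  out$upper[zero] <- 0
  out$true_n[is.na(out$true_n)] <- 0
  out$rel_error <- ifelse(out$true_n > 0,
                          (out$mean - out$true_n) / out$true_n, NA_real_)
  out$covered <- out$true_n >= out$lower & out$true_n <= out$upper
  data.table::setorderv(out, c(summary$by, "cause"))
  out[]
}
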