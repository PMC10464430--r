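run1 <- function(deaths, mcod = NULL, config = fast_config(), ...) {
  run_redistribution(cod_data(deaths, mcod), .demo_map, config, ...)
}

test_that("ICD-based redistribution splits pro rata to the window targets", {
  deaths <- rbind(window_deaths("C539", 30, age = 50, sex = "female"),
                  window_deaths("C549", 70, age = 50, sex = "female"),
                  make_deaths(list(uc = "C55", year = 2019, age = 50,
                                   sex = "female")))
  deaths$record_id <- sprintf("x%05d", seq_len(nrow(deaths)))
  ens <- run1(deaths, config = fast_config(mode = "fractional"))
  a <- ens$assignments[ens$assignments$record_id == "x00101"]
  expect_equal(a$step, rep("step1", 2))
  expect_equal(a$weight[a$cause_l4 == "cervical_cancer"], 0.30)
  expect_equal(a$weight[a$cause_l4 == "uterine_cancer"], 0.70)
})

test_that("sampled step-1 assignments follow the target distribution", {
  deaths <- rbind(window_deaths("C539", 30, age = 50, sex = "female"),
                  window_deaths("C549", 70, age = 50, sex = "female"),
                  make_deaths(list(uc = "C55", n = 10000, year = 2019,
                                   age = 50, sex = "female")))
  deaths$record_id <- sprintf("x%05d", seq_len(nrow(deaths)))
  ens <- run1(deaths, config = fast_config(master_seed = 11))
  a <- ens$assignments[ens$assignments$step == "step1"]
  expect_equal(nrow(a), 10000L)
  p_hat <- mean(a$cause_l4 == "cervical_cancer")
  expect_lt(abs(p_hat - 0.30), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("step-1 deaths with no observed targets defer to all-cause", {
  deaths <- rbind(window_deaths("I219", 50, age = 50, sex = "female"),
                  make_deaths(list(uc = "C55", year = 2019, age = 50,
                                   sex = "female")))
  deaths$record_id <- sprintf("x%05d", seq_len(nrow(deaths)))
  ens <- run1(deaths)
  a <- ens$assignments[ens$assignments$record_id == "x00051"]
  expect_equal(a$step, "step4")
  expect_equal(a$cause_l4, "ischemic_heart_disease")
})

test_that("package redistribution uses the UCs of MCOD-mentioning deaths", {
  deaths <- rbind(
    window_deaths("E119", 6, age = 80, sex = "male"),   # mention N19
    window_deaths("I119", 2, age = 80, sex = "male"),   # mention N19
    window_deaths("I119", 5, age = 50, sex = "male"),   # rare-filter ballast
    make_deaths(list(uc = "N19", year = 2019, age = 80, sex = "male")))
  deaths$record_id <- sprintf("x%05d", seq_len(nrow(deaths)))
  mcod <- data.table(record_id = deaths$record_id[1:8],
                     code = "N19", role = "associated")
  ens <- run1(deaths, mcod, config = fast_config(mode = "fractional"))
  a <- ens$assignments[ens$assignments$record_id == "x00014"]
  expect_equal(unique(a$step), "step2")
  expect_equal(a$weight[a$cause_l4 == "diabetes_mellitus"], 0.75)
  expect_equal(a$weight[a$cause_l4 == "hypertensive_heart_disease"], 0.25)
})

test_that("packages without MCOD-mentioning deaths defer to all-cause", {
  deaths <- rbind(window_deaths("I219", 50, age = 80, sex = "male"),
                  make_deaths(list(uc = "N19", year = 2019, age = 80,
                                   sex = "male")))
  deaths$record_id <- sprintf("x%05d", seq_len(nrow(deaths)))
  ens <- run1(deaths)
  a <- ens$assignments[ens$assignments$record_id == "x00051"]
  expect_equal(a$step, "step4")
})

test_that("internal redistribution draws uniformly from certificate causes", {
  deaths <- rbind(window_deaths("C349", 6, age = 70, sex = "male"),
                  window_deaths("I119", 6, age = 70, sex = "male"),
                  make_deaths(list(uc = "R99", year = 2019, age = 70,
                                   sex = "male")))
  deaths$record_id <- sprintf("x%05d", seq_len(nrow(deaths)))
  mcod <- data.table(record_id = "x00013", code = c("C349", "I10"),
                     role = "associated")
  ens <- run1(deaths, mcod, config = fast_config(mode = "fractional"))
  a <- ens$assignments[ens$assignments$record_id == "x00013"]
  expect_equal(unique(a$step), "step3")
  expect_setequal(a$cause_l4,
                  c("lung_cancer", "hypertensive_heart_disease"))
  expect_equal(a$weight, c(0.5, 0.5))
})

test_that("deaths without specific certificate mentions pass to step 4", {
  deaths <- rbind(window_deaths("I219", 30, age = 70, sex = "male"),
                  make_deaths(list(uc = "R99", year = 2019, age = 70,
                                   sex = "male"),
                              list(uc = "R99", year = 2019, age = 70,
                                   sex = "male")))
  deaths$record_id <- sprintf("x%05d", seq_len(nrow(deaths)))
  # one empty MCOD chain, one whose only mention is itself ill-defined
  mcod <- data.table(record_id = "x00032", code = "R54",
                     role = "associated")
  ens <- run1(deaths, mcod)
  a <- ens$assignments[ens$assignments$record_id %in%
                         c("x00031", "x00032")]
  expect_equal(a$step, c("step4", "step4"))
})

test_that("all-cause redistribution falls back to sex-only support", {
  deaths <- rbind(window_deaths("I219", 40, age = 80, sex = "male"),
                  make_deaths(list(uc = "R99", year = 2019, age = 30,
                                   sex = "male")))
  deaths$record_id <- sprintf("x%05d", seq_len(nrow(deaths)))
  ens <- run1(deaths)
  a <- ens$assignments[ens$assignments$record_id == "x00041"]
  expect_equal(a$cause_l4, "ischemic_heart_disease")
  expect_equal(a$step, "step4")
})

test_that("a pool without any specific deaths is a hard error", {
  deaths <- make_deaths(list(uc = "R99", n = 5, year = 2019, age = 70,
                             sex = "male"))
  expect_error(run1(deaths, config = fast_config(window_years = 1L)),
               "no specific deaths")
})

test_that("rare causes never receive redistributed deaths", {
  deaths <- rbind(window_deaths("A82", 4, age = 70, sex = "male"),
                  window_deaths("I219", 50, age = 70, sex = "male"),
                  make_deaths(list(uc = "R99", n = 30, year = 2019,
                                   age = 70, sex = "male")))
  deaths$record_id <- sprintf("x%05d", seq_len(nrow(deaths)))
  ens <- run1(deaths, config = fast_config(n_iterations = 5L))
  redist <- ens$assignments[ens$assignments$step != "mapped"]
  expect_false("rabies" %in% redist$cause_l4)
})

test_that("conservation and specificity hold per iteration and cell", {
  s <- generate_synthetic_deaths(generator_config(
    n_per_year = 400, years = 2013:2019, seed = 12))
  ens <- run_redistribution(s$data, .demo_map,
                            redistribution_config(n_iterations = 3L,
                                                  master_seed = 5L))
  a <- merge(ens$assignments, s$data$deaths, by = "record_id")
  expect_false(any(is.na(a$cause_l4)))
  a$ag <- as.character(age_group6(a$age))
  post <- a[, .(n = sum(weight)), by = .(iteration, year, sex, ag, region)]
  d <- s$data$deaths[s$data$deaths$year %in% ens$report_years]
  d$ag <- as.character(age_group6(d$age))
  pre <- d[, .(n_pre = as.numeric(.N)), by = .(year, sex, ag, region)]
  cmp <- merge(post, pre, by = c("year", "sex", "ag", "region"),
               all = TRUE)
  expect_false(any(is.na(cmp$n) | is.na(cmp$n_pre)))
  expect_equal(cmp$n, cmp$n_pre)
})

test_that("identical master seeds reproduce the ensemble exactly", {
  s <- generate_synthetic_deaths(generator_config(
    n_per_year = 200, years = 2015:2019, seed = 2))
  e1 <- run_redistribution(s$data, .demo_map,
                           redistribution_config(n_iterations = 2L,
                                                 master_seed = 99L))
  e2 <- run_redistribution(s$data, .demo_map,
                           redistribution_config(n_iterations = 2L,
                                                 master_seed = 99L))
  expect_identical(e1$assignments, e2$assignments)
  e3 <- run_redistribution(s$data, .demo_map,
                           redistribution_config(n_iterations = 2L,
                                                 master_seed = 100L))
  expect_false(identical(e1$assignments, e3$assignments))
})

test_that("report years start after a full lead-in window", {
  s <- generate_synthetic_deaths(generator_config(
    n_per_year = 60, years = 2000:2019, seed = 4))
  ens <- run_redistribution(s$data, .demo_map,
                            fast_config(mode = "fractional"))
  expect_equal(ens$report_years, 2004:2019)
  s2 <- generate_synthetic_deaths(generator_config(
    n_per_year = 60, years = 2018:2019, seed = 4))
  expect_error(run_redistribution(s2$data, .demo_map, fast_config()),
               "2022")
})

test_that("fractional mode yields one deterministic completed dataset", {
  s <- generate_synthetic_deaths(generator_config(
    n_per_year = 250, years = 2015:2019, seed = 6))
  e1 <- run_redistribution(s$data, .demo_map,
                           fast_config(mode = "fractional"))
  e2 <- run_redistribution(s$data, .demo_map,
                           fast_config(mode = "fractional",
                                       master_seed = 77L))
  expect_identical(e1$assignments, e2$assignments)  # no RNG involved
  per_record <- e1$assignments[, .(w = sum(weight)), by = record_id]
  expect_equal(per_record$w, rep(1, nrow(per_record)))
})

test_that("per-step target updating can be relaxed to per-step-end", {
  s <- generate_synthetic_deaths(generator_config(
    n_per_year = 250, years = 2015:2019, seed = 6))
  ens <- run_redistribution(s$data, .demo_map,
                            fast_config(update = "step"))
  a <- ens$assignments
  expect_false(any(is.na(a$cause_l4)))
  expect_equal(nrow(a), sum(s$data$deaths$year == 2019))
})

test_that("summaries report means, percentile intervals and step shares", {
  s <- generate_synthetic_deaths(generator_config(
    n_per_year = 300, years = 2015:2019, seed = 8))
  ens <- run_redistribution(s$data, .demo_map,
                            redistribution_config(n_iterations = 4L,
                                                  master_seed = 3L))
  sm <- summarize_ensemble(ens, s$data, .demo_map, level = 3, by = "year")
  expect_true(all(sm$counts$lower <= sm$counts$mean + 1e-9))
  expect_true(all(sm$counts$mean <= sm$counts$upper + 1e-9))
  shares <- sm$step_shares[, .(tot = sum(share)), by = year]
  expect_equal(shares$tot, rep(1, nrow(shares)))
  expect_true(all(sm$idd_share$idd_share >= 0 &
                    sm$idd_share$idd_share <= 1))
  expect_error(summarize_ensemble(ens, s$data, .demo_map, by = "planet"),
               "unknown stratifier")
  # constant counts across iterations give a zero-width interval
  const <- sm$counts[sm$counts$lower == sm$counts$upper]
  if (nrow(const)) expect_equal(const$mean, const$lower)
})
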