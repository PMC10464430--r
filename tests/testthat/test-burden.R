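test_that("life-table completion anchors residual expectancy at (122, 0)", {
  raw <- data.frame(age = c(0, 50, 95), residual_expectancy = c(88, 40, 10))
  lt <- complete_life_table(raw)
  expect_equal(lt$age[nrow(lt)], 122)
  expect_equal(lt$residual_expectancy[nrow(lt)], 0)
  expect_identical(as.data.frame(complete_life_table(lt)),
                   as.data.frame(lt))  # idempotent
})

test_that("non-monotone life tables are rejected", {
  expect_error(complete_life_table(
    data.frame(age = c(0, 50, 95), residual_expectancy = c(88, 40, 45))),
    "non-increasing")
  expect_error(complete_life_table(
    data.frame(age = c(0, 50, 50), residual_expectancy = c(88, 40, 39))),
    "strictly increasing")
})

test_that("SEYLL interpolates linearly between knots", {
  lt <- complete_life_table(
    data.frame(age = c(0, 95), residual_expectancy = c(88, 10)))
  expect_equal(seyll_at_age(lt, 122), 0)
  expect_equal(seyll_at_age(lt, 95), 10)     # knot identity
  expect_equal(seyll_at_age(lt, 108.5), 5)   # midpoint of (95,10)-(122,0)
  expect_error(seyll_at_age(lt, 123), "outside")
  expect_error(seyll_at_age(lt, -1), "outside")
  # interpolation stays between bracketing knot values
  ages <- seq(0, 122, by = 0.5)
  v <- seyll_at_age(lt, ages)
  expect_true(all(v <= 88 & v >= 0))
  expect_true(all(diff(v) <= 1e-12))
})

test_that("ensemble SEYLL is additive over member deaths", {
  lt <- synthetic_life_table()
  deaths <- make_deaths(
    list(uc = "I219", n = 2, year = 2019, age = 70, sex = "male"),
    list(uc = "I219", n = 48, year = 2015, age = 70, sex = "male"))
  deaths$record_id <- sprintf("x%05d", seq_len(nrow(deaths)))
  ens <- run_redistribution(cod_data(deaths), .demo_map, fast_config())
  s <- compute_seyll(ens, cod_data(deaths), lt, .demo_map, by = "year")
  w70 <- seyll_at_age(lt, 70)
  expect_equal(s$mean[s$cause == "ischemic_heart_disease"], 2 * w70)
  expect_equal(s$lower, s$upper)  # constant across iterations
})

test_that("a death at the terminal age contributes zero SEYLL", {
  lt <- synthetic_life_table()
  deaths <- rbind(window_deaths("I219", 20, age = 80, sex = "male"),
                  make_deaths(list(uc = "I219", year = 2019, age = 122,
                                   sex = "male")))
  deaths$record_id <- sprintf("x%05d", seq_len(nrow(deaths)))
  ens <- run_redistribution(cod_data(deaths), .demo_map, fast_config())
  s20 <- compute_seyll(ens, cod_data(deaths), lt, .demo_map, by = "year")
  expect_equal(s20$mean, 4 * seyll_at_age(lt, 80))  # the age-122 row adds 0
})

test_that("crude rates are per 100,000", {
  expect_equal(crude_rate(972, 1e5), 972)
  expect_equal(crude_rate(0, 1e5), 0)
  expect_equal(round(crude_rate(101250, 10416666), 1), 972.0)
  expect_error(crude_rate(10, 0), "population")
})

test_that("age standardization reproduces hand-computed examples", {
  # two groups, rates 10 and 30 per 100k, standard weights 0.25/0.75
  asr <- age_standardized_rate(
    data.frame(age_lo = c(0, 5), count = c(10, 30)),
    data.frame(age_lo = c(0, 5), population = c(1e5, 1e5)),
    data.frame(age_lo = c(0, 5), weight = c(0.25, 0.75)))
  expect_equal(asr, 25)
})

test_that("ASR equals the crude rate when age structures coincide", {
  std <- esp2013()
  pop <- data.frame(age_lo = std$age_lo, population = std$weight * 50)
  counts <- data.frame(age_lo = std$age_lo,
                       count = std$weight * 50 * 0.012 *
                         seq(0.2, 3.8, length.out = nrow(std)))
  asr <- age_standardized_rate(counts, pop, std)
  crude <- crude_rate(sum(counts$count), sum(pop$population))
  expect_equal(asr, crude, tolerance = 1e-9)
})

test_that("constant age-specific rates standardize to themselves", {
  std <- esp2013()
  pop <- data.frame(age_lo = std$age_lo, population = rep(2e5, nrow(std)))
  counts <- data.frame(age_lo = std$age_lo, count = rep(50, nrow(std)))
  expect_equal(age_standardized_rate(counts, pop, std),
               crude_rate(50, 2e5))
})

test_that("ASR is invariant to jointly scaling counts and population", {
  std <- esp2013()
  pop <- data.frame(age_lo = std$age_lo,
                    population = std$weight * seq(20, 70,
                                                  length.out = nrow(std)))
  counts <- data.frame(age_lo = std$age_lo, count = seq_len(nrow(std)) * 3)
  a1 <- age_standardized_rate(counts, pop, std)
  counts2 <- counts
  pop2 <- pop
  counts2$count <- counts$count * 7
  pop2$population <- pop$population * 7
  expect_equal(age_standardized_rate(counts2, pop2, std), a1)
})

test_that("missing population under observed deaths is an error", {
  expect_error(age_standardized_rate(
    data.frame(age_lo = 0, count = 5),
    data.frame(age_lo = 5, population = 100),
    data.frame(age_lo = c(0, 5), weight = c(1, 1))),
    "missing population")
})

test_that("burden tables carry counts, crude rates and ASRs per cause", {
  cfg <- generator_config(n_per_year = 400, years = 2015:2019, seed = 10)
  s <- generate_synthetic_deaths(cfg)
  ens <- run_redistribution(s$data, .demo_map,
                            redistribution_config(n_iterations = 3L,
                                                  master_seed = 2L))
  bt <- burden_table(ens, s$data, synthetic_life_table(),
                     synthetic_population(cfg), map = .demo_map,
                     by = "year")
  expect_setequal(unique(bt$measure), c("deaths", "seyll"))
  expect_setequal(unique(as.character(bt$statistic)),
                  c("count", "crude_rate", "asr"))
  expect_true(all(bt$lower <= bt$mean + 1e-9 &
                    bt$mean <= bt$upper + 1e-9))
  # total death count equals the microdata count in the report years
  tot <- bt[bt$measure == "deaths" & bt$statistic == "count" &
              bt$year == 2019]
  expect_equal(sum(tot$mean), sum(s$data$deaths$year == 2019))
})

test_that("leading causes rank by mean and report percent change", {
  tb <- data.table(
    year = rep(c(2004L, 2019L), each = 5),
    cause = rep(letters[1:5], 2),
    level = 3L, measure = "deaths", statistic = "asr",
    mean = c(100, 80, 60, 40, 20, 44, 90, 50, 45, 10),
    lower = 0, upper = 200)
  top <- leading_causes(tb, year = 2019, k = 3)
  expect_equal(top$cause, c("b", "c", "d"))
  same <- leading_causes(tb, year = 2019, k = 5, baseline_year = 2019)
  expect_equal(same$pct_change, rep(0, 5))
  chg <- leading_causes(tb, year = 2019, k = 5, baseline_year = 2004)
  expect_equal(chg$pct_change[chg$cause == "a"], -56)
  expect_error(leading_causes(tb, year = 1990), "empty slice")
})
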