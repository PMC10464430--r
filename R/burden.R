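#' Complete a reference life table
#'
#' Aspirational reference life tables typically end around age 95; for
#' SEYLL the table is completed by anchoring residual life expectancy to 0
#' at age 122 (the highest observed human lifespan), so that a death at
#' 122 contributes no years of life lost. Idempotent if the anchor is
#' already present. Validates that ages increase strictly and residual
#' expectancy is non-negative and non-increasing.
#'
#' @param life_table data.frame with columns `age`, `residual_expectancy`.
#' @return data.table ending in the row `(122, 0)`.
#' @export
complete_life_table <- function(life_table) {
  lt <- data.table::as.data.table(life_table)[, c("age",
                                                  "residual_expectancy")]
  data.table::setorder(lt, age)
  if (max(lt$age) > 122)
    stop("life table extends beyond age 122", call. = FALSE)
  if (!(max(lt$age) == 122 && lt$residual_expectancy[nrow(lt)] == 0))
    lt <- rbind(lt, data.table::data.table(age = 122,
                                           residual_expectancy = 0))
  if (any(diff(lt$age) <= 0))
    stop("life table ages must be strictly increasing", call. = FALSE)
  if (any(lt$residual_expectancy < 0) ||
        any(diff(lt$residual_expectancy) > 0))
    stop("residual expectancy must be non-negative and non-increasing",
         call. = FALSE)
  lt[]
}

#' Standard expected years of life lost at an age
#'
#' Linear interpolation of the completed reference life table between its
#' knots; exact table values at the knots, and exactly 0 at age 122.
#'
#' @param life_table A completed life table (see [complete_life_table()]).
#' @param age Numeric vector of ages at death, in `[0, 122]`.
#' @return Numeric vector of expected years of life lost.
#' @export
seyll_at_age <- function(life_table, age) {
  if (any(age < life_table$age[1] | age > 122, na.rm = TRUE))
    stop("age outside [", life_table$age[1], ", 122]", call. = FALSE)
  stats::approx(life_table$age, life_table$residual_expectancy,
                xout = age, method = "linear")$y
}

#' SEYLL by group with uncertainty
#'
#' Per iteration, sums the residual-life-expectancy weight at each death's
#' age over the deaths assigned to each cause, then reports the mean and
#' 2.5th/97.5th percentile across iterations.
#'
#' @param ensemble A `redistribution_ensemble`.
#' @param data The [cod_data] used.
#' @param life_table A completed life table.
#' @param map A [cause_map].
#' @param level Cause hierarchy level (default 3).
#' @param by Stratifiers among `"year"`, `"sex"`, `"region"`.
#' @param age_offset Added to the integer age before evaluating the life
#'   table (e.g. 0.5 for a mid-year correction); default 0.
#' @return data.table with `by`, `cause`, `mean`, `lower`, `upper`.
#' @export
compute_seyll <- function(ensemble, data, life_table, map, level = 3L,
                          by = "year", age_offset = 0) {
  stopifnot(inherits(ensemble, "redistribution_ensemble"))
  d <- data$deaths[, c("record_id", "year", "sex", "region", "age")]
  missing_ids <- setdiff(unique(ensemble$assignments$record_id),
                         d$record_id)
  if (length(missing_ids))
    stop("ensemble references record(s) absent from the data: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  a <- merge(ensemble$assignments, d, by = "record_id")
  a$cause <- cause_at_level(a$cause_l4, map, level)
  a$yll <- seyll_at_age(life_table, pmin(a$age + age_offset, 122)) * a$weight
  n_iter <- ensemble$config$n_iterations
  s <- a[, list(n = sum(yll)), by = c("iteration", by, "cause")]
  cells <- unique(s[, c(by, "cause"), with = FALSE])
  grid <- cells[rep(seq_len(nrow(cells)), each = n_iter)]
  grid$iteration <- rep(seq_len(n_iter), nrow(cells))
  s <- merge(grid, s, by = c("iteration", by, "cause"), all.x = TRUE)
  s$n[is.na(s$n)] <- 0
  out <- s[, list(mean = mean(n),
                  lower = stats::quantile(n, 0.025, names = FALSE),
                  upper = stats::quantile(n, 0.975, names = FALSE)),
           by = c(by, "cause")]
  data.table::setorderv(out, c(by, "cause"))
  out[]
}

#' Crude rate per 100,000
#'
#' @param count Deaths or SEYLL.
#' @param population Person-count denominator (> 0).
#' @return `count / population * 100000`.
#' @export
crude_rate <- function(count, population) {
  if (any(population <= 0)) stop("population must be > 0", call. = FALSE)
  count / population * 1e5
}

#' Five-year age groups for standardization
#'
#' @param age Ages in completed years.
#' @param open_from Lower bound of the open terminal group (default 90,
#'   matching the 2013 European Standard Population).
#' @return Integer lower bound of each age's five-year group.
#' @export
age_group5_lo <- function(age, open_from = 90) {
  pmin((age %/% 5) * 5, open_from)
}

#' Age-standardized rate per 100,000
#'
#' Weighted average of the age-group-specific rates using a standard
#' population's age structure: `sum(w_g * c_g / p_g) / sum(w_g) * 100000`
#' over five-year age groups `g`.
#'
#' @param counts_by_age data.frame with columns `age_lo`, `count`.
#' @param population_by_age data.frame with columns `age_lo`, `population`.
#' @param standard A standard population (columns `age_lo`, `weight`), e.g.
#'   [esp2013()].
#' @return The age-standardized rate per 100,000.
#' @export
age_standardized_rate <- function(counts_by_age, population_by_age,
                                  standard) {
  cb <- data.table::as.data.table(counts_by_age)[, list(
    count = sum(count)), by = "age_lo"]
  pb <- data.table::as.data.table(population_by_age)[, list(
    population = sum(population)), by = "age_lo"]
  st <- data.table::as.data.table(standard)
  x <- merge(st[, c("age_lo", "weight")], cb, by = "age_lo", all.x = TRUE)
  x <- merge(x, pb, by = "age_lo", all.x = TRUE)
  x$count[is.na(x$count)] <- 0
  if (any(x$count > 0 & (is.na(x$population) | x$population <= 0)))
    stop("missing population for age group(s) with deaths: ",
         paste(x$age_lo[x$count > 0 &
                          (is.na(x$population) | x$population <= 0)],
               collapse = ", "), call. = FALSE)
  rate <- ifelse(x$count > 0, x$count / x$population, 0)
  sum(x$weight * rate) / sum(x$weight) * 1e5
}

#' Bundled 2013 European Standard Population
#'
#' Five-year age-group weights of the 2013 European Standard Population
#' (19 groups, 90+ open, total weight 100,000).
#'
#' @return data.table with `age_lo`, `age_hi`, `weight`.
#' @export
esp2013 <- function() {
  read_standard_population(system.file("extdata", "esp2013.csv",
                                       package = "gcredist"))
}

#' Bundled synthetic reference life table
#'
#' A synthetic residual-life-expectancy table with the structure of an
#' aspirational reference life table (5-year knots from age 0 to 95,
#' life expectancy at birth 88.9 years). It is a stand-in for a real
#' reference life table, which users should supply via [read_life_table()].
#'
#' @param complete If `TRUE` (default), anchor the table at `(122, 0)`.
#' @return data.table with `age`, `residual_expectancy`.
#' @export
synthetic_life_table <- function(complete = TRUE) {
  lt <- read_life_table(system.file("extdata", "life_table_synthetic.csv",
                                    package = "gcredist"))
  if (complete) complete_life_table(lt) else lt
}

#' Full burden table with uncertainty
#'
#' Computes, per iteration, deaths and SEYLL by cause and grouping, as
#' absolute counts, crude rates per 100,000 and age-standardized rates per
#' 100,000 (five-year age groups), then summarizes each as mean and
#' 2.5th/97.5th percentiles across iterations.
#'
#' @param ensemble A `redistribution_ensemble`.
#' @param data The [cod_data] used.
#' @param life_table Completed life table.
#' @param population Population table (`year`, `sex`, `region`, `age_lo`,
#'   `population`).
#' @param standard Standard population for ASRs (default [esp2013()]).
#' @param map A [cause_map].
#' @param level Cause hierarchy level (default 3).
#' @param by Stratifiers among `"year"`, `"sex"`, `"region"` (default
#'   `"year"`; rates aggregate the population over the omitted ones).
#' @param age_offset Passed to the SEYLL weight evaluation.
#' @return data.table with one row per (`by`, `cause`, `measure`,
#'   `statistic`): `measure` in `deaths`/`seyll`, `statistic` in
#'   `count`/`crude_rate`/`asr`, and `mean`, `lower`, `upper`.
#' @export
burden_table <- function(ensemble, data, life_table, population,
                         standard = esp2013(), map, level = 3L,
                         by = "year", age_offset = 0) {
  pop <- data.table::as.data.table(population)
  d <- data$deaths[, c("record_id", "year", "sex", "region", "age")]
  a <- merge(ensemble$assignments, d, by = "record_id")
  a$cause <- cause_at_level(a$cause_l4, map, level)
  a$age_lo <- age_group5_lo(a$age)
  a$yll <- seyll_at_age(life_table, pmin(a$age + age_offset, 122)) *
    a$weight

  popg <- pop[, list(population = sum(population)), by = c(by, "age_lo")]
  cnt <- a[, list(deaths = sum(weight), seyll = sum(yll)),
           by = c("iteration", by, "cause", "age_lo")]
  cnt <- merge(cnt, popg, by = c(by, "age_lo"), all.x = TRUE)
  st <- data.table::as.data.table(standard)
  wmap <- stats::setNames(st$weight, st$age_lo)
  totw <- sum(st$weight)
  cnt$w <- wmap[as.character(cnt$age_lo)]
  totpop <- popg[, list(population = sum(population)), by = by]

  per_iter <- function(measure) {
    cnt$x <- cnt[[measure]]
    g <- cnt[, list(count = sum(x),
                    asr = sum(w * x / population) / totw * 1e5),
             by = c("iteration", by, "cause")]
    g <- merge(g, totpop, by = by)
    g$crude_rate <- g$count / g$population * 1e5
    g
  }

  n_iter <- ensemble$config$n_iterations
  out <- list()
  for (measure in c("deaths", "seyll")) {
    g <- per_iter(measure)
    long <- data.table::melt(
      g, id.vars = c("iteration", by, "cause"),
      measure.vars = c("count", "crude_rate", "asr"),
      variable.name = "statistic", value.name = "v")
    cells <- unique(long[, c(by, "cause", "statistic"), with = FALSE])
    grid <- cells[rep(seq_len(nrow(cells)), each = n_iter)]
    grid$iteration <- rep(seq_len(n_iter), nrow(cells))
    long <- merge(grid, long, by = c("iteration", by, "cause", "statistic"),
                  all.x = TRUE)
    long$v[is.na(long$v)] <- 0
    s <- long[, list(mean = mean(v),
                     lower = stats::quantile(v, 0.025, names = FALSE),
                     upper = stats::quantile(v, 0.975, names = FALSE)),
              by = c(by, "cause", "statistic")]
    s$measure <- measure
    out[[measure]] <- s
  }
  res <- data.table::rbindlist(out)
  res$level <- level
  data.table::setcolorder(res, c(by, "cause", "level", "measure",
                                 "statistic", "mean", "lower", "upper"))
  data.table::setorderv(res, c(by, "measure", "statistic", "cause"))
  res[]
}

#' Leading causes by a burden statistic
#'
#' Ranks causes by the mean of the requested measure/statistic in a given
#' slice of a burden table, optionally with the percent change relative to
#' a baseline year (`(new - old) / old * 100`, computed on the mean
#' estimates of both years).
#'
#' @param table A [burden_table()] result.
#' @param year Year of interest.
#' @param k Number of leading causes (default 10).
#' @param measure `"deaths"` or `"seyll"`.
#' @param statistic `"count"`, `"crude_rate"` or `"asr"`.
#' @param baseline_year Optional comparison year.
#' @param ... Further slice filters matched against table columns (e.g.
#'   `sex = "female"`).
#' @return data.table ranked by descending mean, with `pct_change` when a
#'   baseline year is given.
#' @export
leading_causes <- function(table, year, k = 10L, measure = "deaths",
                           statistic = "asr", baseline_year = NULL, ...) {
  tb <- data.table::as.data.table(table)
  sel <- tb$measure == measure & tb$statistic == statistic
  extra <- list(...)
  for (nm in names(extra)) sel <- sel & tb[[nm]] == extra[[nm]]
  idx_cur <- which(sel & tb$year == year)
  cur <- tb[idx_cur]
  if (nrow(cur) == 0L) stop("empty slice", call. = FALSE)
  data.table::setorder(cur, -mean)
  cur <- cur[seq_len(min(k, nrow(cur)))]
  cur$rank <- seq_len(nrow(cur))
  if (!is.null(baseline_year)) {
    idx_base <- which(sel & tb$year == baseline_year)
    base <- tb[idx_base]
    cur$pct_change <- (cur$mean / base$mean[match(cur$cause, base$cause)] -
                         1) * 100
  }
  cur[]
}
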