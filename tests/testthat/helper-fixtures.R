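library(data.table)

# demo map is read from disk once per test run
.demo_map <- gcredist::demo_cause_map()

# build a deaths table from per-group specs: list(uc=, n=, year=, age=, sex=)
make_deaths <- function(..., region = "r1") {
  specs <- list(...)
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    n <- if (is.null(s$n)) 1L else s$n
    data.table(year = rep(s$year, n), age = rep(s$age, n),
               sex = rep(s$sex, n), region = region,
               uc = rep(gcredist::normalize_icd(s$uc), n))
  })
  d <- rbindlist(rows)
  d[, record_id := sprintf("x%05d", .I)]
  setcolorder(d, c("record_id", "year", "age", "sex", "region", "uc"))
  d
}

# spread n deaths with a given uc evenly over a 5-year window
window_deaths <- function(uc, n, age, sex, years = 2015:2019) {
  make_deaths(list(uc = uc, n = n, year = years[1], age = age, sex = sex))[
    , year := rep(years, length.out = n)][]
}

fast_config <- function(...) {
  args <- utils::modifyList(list(n_iterations = 1L, master_seed = 1L),
                            list(...))
  do.call(gcredist::redistribution_config, args)
}
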