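#' Redistribution age groups
#'
#' The six age groups used to stratify target distributions:
#' 0-4, 5-14, 15-44, 45-64, 65-84, 85+ (closed-open bounds, 85+ open).
#'
#' @param age Integer vector of ages in completed years.
#' @return Factor with the six group labels.
#' @export
age_group6 <- function(age) {
  cut(age, breaks = c(0, 5, 15, 45, 65, 85, Inf), right = FALSE,
      labels = c("0-4", "5-14", "15-44", "45-64", "65-84", "85+"))
}

age_group6_int <- function(age) {
  findInterval(age, c(0, 5, 15, 45, 65, 85))
}

#' Redistribution configuration
#'
#' @param window_years Length of the rolling reference window: targets for
#'   ill-defined deaths in year `y` are the specific deaths of years
#'   `y - window_years + 1` to `y`. Default 5.
#' @param n_iterations Number of probabilistic iterations; each is a
#'   complete run of the four-step process producing a fully imputed
#'   dataset. Default 100.
#' @param rare_cause_min Level-3 causes with fewer occurrences than this in
#'   the reference window are excluded as targets (default 5, i.e. less
#'   than one per year on average).
#' @param sparse_stratum_min If the age-group-by-sex target support in a
#'   stratum is below this count, the distribution is rebuilt on sex only.
#'   Default 20.
#' @param master_seed Master RNG seed; per-iteration child seeds are
#'   `master_seed + (i - 1) * 1000003` (kept below 2^31).
#' @param mode `"sample"` draws one cause per death per iteration;
#'   `"fractional"` spreads each death fractionally over the target
#'   distribution (deterministic; typically used with `n_iterations = 1`).
#' @param update `"group"` (default) refreshes target distributions after
#'   every redistribution group within a step; `"step"` only between steps.
#' @return Object of class `redistribution_config`.
#' @export
redistribution_config <- function(window_years = 5L, n_iterations = 100L,
                                  rare_cause_min = 5, sparse_stratum_min = 20,
                                  master_seed = 1L,
                                  mode = c("sample", "fractional"),
                                  update = c("group", "step")) {
  mode <- match.arg(mode)
  update <- match.arg(update)
  stopifnot(window_years >= 1, n_iterations >= 1, rare_cause_min >= 0,
            sparse_stratum_min >= 0)
  structure(list(window_years = as.integer(window_years),
                 n_iterations = as.integer(n_iterations),
                 rare_cause_min = rare_cause_min,
                 sparse_stratum_min = sparse_stratum_min,
                 master_seed = as.integer(master_seed),
                 mode = mode, update = update),
            class = "redistribution_config")
}

child_seeds <- function(master_seed, n) {
  as.integer((as.numeric(master_seed) + (seq_len(n) - 1) * 1000003) %%
               .Machine$integer.max)
}

# ---- shared internal machinery -------------------------------------------

# Precompute everything that is constant across iterations.
redist_setup <- function(data, map, asg) {
  deaths <- data$deaths
  n <- nrow(deaths)
  e <- map$entries
  spec <- e[e$idd_class == "specific"]
  causes <- sort(unique(spec$cause_l4))
  K <- length(causes)
  l3_by_cause <- spec$cause_l3[match(causes, spec$cause_l4)]
  l3s <- sort(unique(l3_by_cause))
  l3_of <- match(l3_by_cause, l3s)
  restr <- rep(0L, K)
  if (nrow(map$restricted_l4)) {
    m <- match(map$restricted_l4$cause_l4, causes)
    restr[m[!is.na(m)]] <-
      ifelse(map$restricted_l4$sex[!is.na(m)] == "male", 1L, 2L)
  }

  sexi <- ifelse(deaths$sex == "male", 1L, 2L)
  agv <- age_group6_int(deaths$age)
  cause0 <- match(asg$cause_l4, causes)

  # step-1 groups present among the records, lexicographic by entry prefix
  t1_prefixes <- sort(unique(asg$map_prefix[asg$idd_class == "icd_targeted"]))
  t1_targets <- lapply(t1_prefixes, function(p) {
    tc <- split_codes(e$target_codes[e$icd_prefix == p])[[1]]
    sort(match(target_causes(map, tc), causes))
  })
  names(t1_targets) <- t1_prefixes

  pkg_of <- ifelse(asg$idd_class == "packaged",
                   e$package_id[match(asg$map_prefix, e$icd_prefix)],
                   NA_character_)
  pkg_ids <- sort(unique(stats::na.omit(pkg_of)))
  # records whose MCOD chain mentions a package member code, per package
  mc <- data$mcod
  rid_of <- match(mc$record_id, deaths$record_id)
  pkg_rids <- lapply(pkg_ids, function(p) {
    members <- map$packages$member_prefix[map$packages$package_id == p]
    sort(unique(rid_of[icd_in_set(mc$code, members)]))
  })
  names(pkg_rids) <- pkg_ids

  # step-3 candidates: distinct specific level-4 causes mapped from MCOD
  midx <- match_icd_prefix(mc$code, e$icd_prefix)
  keep <- !is.na(midx) & e$idd_class[midx] == "specific"
  mc3 <- unique(data.table::data.table(
    rid = rid_of[keep], cidx = match(e$cause_l4[midx[keep]], causes)))
  data.table::setkey(mc3, rid)

  list(n = n, deaths = deaths, causes = causes, K = K, l3s = l3s,
       l3_of = l3_of, restr = restr, sexi = sexi, agv = agv,
       year_v = deaths$year, cause0 = cause0, idd_class = asg$idd_class,
       t1_prefixes = t1_prefixes, t1_targets = t1_targets,
       grp1_of = asg$map_prefix, pkg_of = pkg_of, pkg_ids = pkg_ids,
       pkg_rids = pkg_rids, mc3 = mc3)
}

# Filter + normalize a count slice into a target distribution.
# arr: K x 6 x 2 weight array; targets: candidate cause indices.
# Fallback chain: stratum -> sex only -> (optionally) both sexes pooled.
dist_from_array <- function(arr, targets, ag, sx, l3cnt, su, cfg,
                            allow_bothsex = FALSE) {
  ok <- (su$restr[targets] == 0L | su$restr[targets] == sx) &
    l3cnt[su$l3_of[targets]] >= cfg$rare_cause_min
  targets <- targets[ok]
  if (!length(targets)) return(NULL)
  v <- arr[targets, ag, sx]
  if (sum(v) < cfg$sparse_stratum_min)
    v <- rowSums(arr[targets, , sx, drop = FALSE], dims = 1)
  if (allow_bothsex && sum(v) == 0)
    v <- rowSums(array(arr[targets, , ], c(length(targets), 6L, 2L)),
                 dims = 1)
  tot <- sum(v)
  if (tot == 0) return(NULL)
  pos <- v > 0
  list(cidx = targets[pos], p = v[pos] / tot)
}

#' Draw causes from a target distribution
#'
#' @param masses Named numeric vector of probabilities (summing to 1).
#' @param n Number of independent draws.
#' @return Character vector of sampled cause ids.
#' @export
sample_causes <- function(masses, n) {
  stopifnot(abs(sum(masses) - 1) < 1e-9)
  names(masses)[sample.int(length(masses), n, replace = TRUE, prob = masses)]
}

#' Build a stratum-specific target distribution
#'
#' Counts deaths of the five-year reference window ending in `year` whose
#' current cause is specific (original or already redistributed), within
#' the requested age-group/sex stratum and optionally restricted to the
#' level-4 causes reachable from a set of ICD target prefixes. Causes whose
#' level-3 parent has fewer than `rare_cause_min` window occurrences and
#' causes sex-restricted away from the stratum are dropped; if the stratum
#' support falls below `sparse_stratum_min` the distribution is rebuilt on
#' sex only; if support is still empty an empty distribution is returned
#' (the caller falls through to all-cause redistribution).
#'
#' @param pool data.frame of pool deaths with columns `year`, `age`, `sex`,
#'   `cause_l4` (specific causes) and optionally `weight`.
#' @param year Reference year (window is `year - window_years + 1 .. year`).
#' @param sex `"male"` or `"female"`.
#' @param age_group One of the [age_group6()] labels, or `NULL` for
#'   sex-only.
#' @param restrict_to Optional character vector of ICD target prefixes.
#' @param map A [cause_map].
#' @param config A [redistribution_config].
#' @return List with `masses` (named probabilities, empty when no support)
#'   and `support` (named window counts backing them).
#' @export
build_target_distribution <- function(pool, year, sex, age_group = NULL,
                                      restrict_to = NULL, map,
                                      config = redistribution_config()) {
  pool <- data.table::as.data.table(pool)
  if (!"weight" %in% names(pool)) pool$weight <- 1
  spec <- map$entries[map$entries$idd_class == "specific"]
  causes <- sort(unique(spec$cause_l4))
  l3v <- spec$cause_l3[match(causes, spec$cause_l4)]
  in_window <- which(pool$year >= year - config$window_years + 1 &
                       pool$year <= year)
  w <- pool[in_window]
  w <- w[which(w$cause_l4 %in% causes)]
  l3cnt_dt <- w[, list(n = sum(weight)),
                by = list(l3 = l3v[match(cause_l4, causes)])]
  l3cnt <- stats::setNames(l3cnt_dt$n, l3cnt_dt$l3)
  targets <- if (is.null(restrict_to)) causes else
    intersect(causes, target_causes(map, normalize_icd(restrict_to)))
  # sex restrictions for this stratum
  if (nrow(map$restricted_l4)) {
    bad <- map$restricted_l4$cause_l4[map$restricted_l4$sex != sex]
    targets <- setdiff(targets, bad)
  }
  targets <- targets[!is.na(l3cnt[l3v[match(targets, causes)]]) &
                       l3cnt[l3v[match(targets, causes)]] >=
                       config$rare_cause_min]
  count_in <- function(sub) {
    cc <- sub[which(sub$cause_l4 %in% targets),
              list(n = sum(weight)), by = "cause_l4"]
    stats::setNames(cc$n, cc$cause_l4)
  }
  same_sex <- which(w$sex == sex)
  support <- numeric(0)
  if (!is.null(age_group)) {
    in_stratum <- intersect(
      same_sex, which(as.character(age_group6(w$age)) == age_group))
    support <- count_in(w[in_stratum])
  }
  if (is.null(age_group) || sum(support) < config$sparse_stratum_min)
    support <- count_in(w[same_sex])
  if (sum(support) == 0)
    return(list(masses = numeric(0), support = numeric(0)))
  list(masses = support / sum(support), support = support)
}

# ---- the per-iteration engine --------------------------------------------

run_one_iteration <- function(su, cfg, report_years, seed) {
  sample_mode <- cfg$mode == "sample"
  if (sample_mode) set.seed(seed)
  K <- su$K
  n <- su$n
  stepv <- ifelse(su$idd_class == "specific", "mapped", NA_character_)

  # running assignment, long format (rid, cidx, w); specific deaths first
  spec_rid <- which(!is.na(su$cause0))
  chunks <- list(data.table::data.table(rid = spec_rid,
                                        cidx = su$cause0[spec_rid],
                                        w = 1))
  env <- new.env(parent = emptyenv())

  upd_counts <- function(asg) {
    # asg: data.table(rid, cidx, w) of newly assigned year-y deaths
    agg <- asg[, list(w = sum(w)),
               by = list(cidx, ag = su$agv[rid], sx = su$sexi[rid])]
    i <- cbind(agg$cidx, agg$ag, agg$sx)
    env$arr[i] <- env$arr[i] + agg$w
    l3a <- asg[, list(w = sum(w)), by = list(l3 = su$l3_of[cidx])]
    env$l3cnt[l3a$l3] <- env$l3cnt[l3a$l3] + l3a$w
    for (p in su$pkg_ids) {
      sub <- asg[asg$rid %in% su$pkg_rids[[p]]]
      if (nrow(sub)) {
        a2 <- sub[, list(w = sum(w)),
                  by = list(cidx, ag = su$agv[rid], sx = su$sexi[rid])]
        i2 <- cbind(a2$cidx, a2$ag, a2$sx)
        env$parr[[p]][i2] <- env$parr[[p]][i2] + a2$w
      }
    }
  }

  assign_stratum <- function(rids, dist, step_label) {
    # rids all share one stratum; dist from dist_from_array
    if (sample_mode) {
      pick <- dist$cidx[sample.int(length(dist$p), length(rids),
                                   replace = TRUE, prob = dist$p)]
      out <- data.table::data.table(rid = rids, cidx = pick, w = 1)
    } else {
      out <- data.table::data.table(
        rid = rep(rids, each = length(dist$cidx)),
        cidx = rep(dist$cidx, length(rids)),
        w = rep(dist$p, length(rids)))
    }
    stepv[rids] <<- step_label
    out
  }

  for (y in report_years) {
    lo <- y - cfg$window_years + 1L
    cur <- data.table::rbindlist(chunks)
    win <- su$year_v >= lo & su$year_v <= y
    wcur <- cur[win[cur$rid]]
    env$arr <- array(0, c(K, 6L, 2L))
    agg <- wcur[, list(w = sum(w)),
                by = list(cidx, ag = su$agv[rid], sx = su$sexi[rid])]
    env$arr[cbind(agg$cidx, agg$ag, agg$sx)] <- agg$w
    env$l3cnt <- numeric(length(su$l3s))
    l3a <- wcur[, list(w = sum(w)), by = list(l3 = su$l3_of[cidx])]
    env$l3cnt[l3a$l3] <- l3a$w
    env$parr <- lapply(su$pkg_ids, function(p) {
      a <- array(0, c(K, 6L, 2L))
      sub <- wcur[wcur$rid %in% su$pkg_rids[[p]]]
      if (nrow(sub)) {
        a2 <- sub[, list(w = sum(w)),
                  by = list(cidx, ag = su$agv[rid], sx = su$sexi[rid])]
        a[cbind(a2$cidx, a2$ag, a2$sx)] <- a2$w
      }
      a
    })
    names(env$parr) <- su$pkg_ids

    is_y <- su$year_v == y
    deferred <- integer(0)
    year_chunks <- list()
    flush_group <- function(asgs) {
      # one redistribution group finished: pool sees its deaths
      if (length(asgs)) {
        grp <- data.table::rbindlist(asgs)
        year_chunks[[length(year_chunks) + 1L]] <<- grp
        if (cfg$update == "group") upd_counts(grp)
      }
    }
    pending_step <- list()
    flush_step <- function() {
      if (cfg$update == "step" && length(pending_step)) {
        upd_counts(data.table::rbindlist(pending_step))
        pending_step <<- list()
      }
    }
    note_step <- function(asgs) {
      if (cfg$update == "step" && length(asgs))
        pending_step[[length(pending_step) + 1L]] <<-
          data.table::rbindlist(asgs)
    }

    # ---- step 1: ICD-based redistribution --------------------------------
    for (g in su$t1_prefixes) {
      rids <- which(is_y & !is.na(su$grp1_of) & su$grp1_of == g &
                      su$idd_class == "icd_targeted")
      if (!length(rids)) next
      targets <- su$t1_targets[[g]]
      asgs <- list()
      strata <- unique(data.table::data.table(ag = su$agv[rids],
                                              sx = su$sexi[rids]))
      data.table::setorder(strata, ag, sx)
      for (k in seq_len(nrow(strata))) {
        srids <- rids[su$agv[rids] == strata$ag[k] &
                        su$sexi[rids] == strata$sx[k]]
        dist <- dist_from_array(env$arr, targets, strata$ag[k],
                                strata$sx[k], env$l3cnt, su, cfg)
        if (is.null(dist)) deferred <- c(deferred, srids)
        else asgs[[length(asgs) + 1L]] <-
          assign_stratum(sort(srids), dist, "step1")
      }
      flush_group(asgs); note_step(asgs)
    }
    flush_step()

    # ---- step 2: package redistribution ----------------------------------
    for (p in su$pkg_ids) {
      rids <- which(is_y & !is.na(su$pkg_of) & su$pkg_of == p)
      if (!length(rids)) next
      asgs <- list()
      strata <- unique(data.table::data.table(ag = su$agv[rids],
                                              sx = su$sexi[rids]))
      data.table::setorder(strata, ag, sx)
      for (k in seq_len(nrow(strata))) {
        srids <- rids[su$agv[rids] == strata$ag[k] &
                        su$sexi[rids] == strata$sx[k]]
        dist <- dist_from_array(env$parr[[p]], seq_len(K), strata$ag[k],
                                strata$sx[k], env$l3cnt, su, cfg)
        if (is.null(dist)) deferred <- c(deferred, srids)
        else asgs[[length(asgs) + 1L]] <-
          assign_stratum(sort(srids), dist, "step2")
      }
      flush_group(asgs); note_step(asgs)
    }
    flush_step()

    # ---- step 3: internal redistribution ---------------------------------
    rids3 <- which(is_y & su$idd_class == "unassigned")
    if (length(rids3)) {
      cand <- su$mc3[su$mc3$rid %in% rids3]
      if (nrow(cand)) {
        ok <- (su$restr[cand$cidx] == 0L |
                 su$restr[cand$cidx] == su$sexi[cand$rid]) &
          env$l3cnt[su$l3_of[cand$cidx]] >= cfg$rare_cause_min
        cand <- cand[ok]
      }
      if (nrow(cand)) {
        data.table::setorder(cand, rid, cidx)
        if (sample_mode) {
          asg3 <- cand[, list(cidx = cidx[sample.int(.N, 1L)], w = 1),
                       by = "rid"]
        } else {
          asg3 <- cand[, list(cidx = cidx, w = 1 / .N), by = "rid"]
        }
        stepv[unique(asg3$rid)] <- "step3"
        asgs <- list(asg3[, list(rid, cidx, w)])
        flush_group(asgs); note_step(asgs)
      }
      deferred <- c(deferred, setdiff(rids3, cand$rid))
    }
    flush_step()

    # ---- step 4: all-cause redistribution --------------------------------
    rids4 <- sort(unique(deferred))
    if (length(rids4)) {
      asgs <- list()
      strata <- unique(data.table::data.table(ag = su$agv[rids4],
                                              sx = su$sexi[rids4]))
      data.table::setorder(strata, ag, sx)
      for (k in seq_len(nrow(strata))) {
        srids <- rids4[su$agv[rids4] == strata$ag[k] &
                         su$sexi[rids4] == strata$sx[k]]
        dist <- dist_from_array(env$arr, seq_len(K), strata$ag[k],
                                strata$sx[k], env$l3cnt, su, cfg,
                                allow_bothsex = TRUE)
        if (is.null(dist))
          stop("all-cause redistribution impossible in year ", y,
               ": no specific deaths in the reference window", call. = FALSE)
        asgs[[length(asgs) + 1L]] <-
          assign_stratum(sort(srids), dist, "step4")
      }
      flush_group(asgs); note_step(asgs)
    }
    flush_step()

    chunks <- c(chunks, year_chunks)
  }

  final <- data.table::rbindlist(chunks)
  keep <- su$year_v[final$rid] %in% report_years
  final <- final[keep]
  data.table::data.table(record_id = su$deaths$record_id[final$rid],
                         cause_l4 = su$causes[final$cidx],
                         step = stepv[final$rid],
                         weight = final$w)
}

#' Run the four-step probabilistic redistribution
#'
#' For every iteration and every report year (ascending), applies the four
#' redistribution steps in sequence: (1) predefined ICD target codes,
#' (2) MCOD packages, (3) internal redistribution within the certificate,
#' (4) all-cause redistribution. Target distributions are rebuilt from the
#' rolling five-year window and updated after every redistribution group,
#' so that evidence accumulates along the process; deaths whose nominal
#' step has no support fall through to step 4, which always resolves them.
#' Report years start at `min(year) + window_years - 1`, the first year
#' with a complete reference window.
#'
#' @param data A validated [cod_data] (combination rules applied, see
#'   [apply_combination_rules()]).
#' @param map A [cause_map].
#' @param config A [redistribution_config].
#' @param report_years Years to redistribute; default all years with a full
#'   lead-in window.
#' @return Object of class `redistribution_ensemble`: the per-iteration
#'   assignment table (`iteration`, `record_id`, `cause_l4`, `step`,
#'   `weight`), the configuration, per-iteration seeds, and the report
#'   years.
#' @export
run_redistribution <- function(data, map, config = redistribution_config(),
                               report_years = NULL) {
  stopifnot(inherits(data, "cod_data"), inherits(map, "cause_map"),
            inherits(config, "redistribution_config"))
  years <- sort(unique(data$deaths$year))
  first_ok <- min(years) + config$window_years - 1L
  if (is.null(report_years)) {
    report_years <- years[years >= first_ok]
    if (!length(report_years))
      stop("insufficient lead-in years: first reportable year would be ",
           first_ok, " but data end in ", max(years), call. = FALSE)
  } else {
    if (any(report_years < first_ok))
      stop("report year(s) before ", first_ok,
           " lack a complete reference window", call. = FALSE)
    report_years <- sort(as.integer(report_years))
  }
  asg <- map_underlying_cause(data, map)
  su <- redist_setup(data, map, asg)
  seeds <- child_seeds(config$master_seed, config$n_iterations)
  out <- vector("list", config$n_iterations)
  for (i in seq_len(config$n_iterations)) {
    res <- run_one_iteration(su, config, report_years, seeds[i])
    res[, "iteration" := i]
    out[[i]] <- res
  }
  assignments <- data.table::rbindlist(out)
  data.table::setcolorder(assignments,
                          c("iteration", "record_id", "cause_l4", "step",
                            "weight"))
  structure(list(assignments = assignments[], config = config,
                 seeds = seeds, report_years = report_years),
            class = "redistribution_ensemble")
}

#' @export
print.redistribution_ensemble <- function(x, ...) {
  cat("<redistribution_ensemble> ", x$config$n_iterations, " iteration(s), ",
      length(unique(x$assignments$record_id)), " deaths, years ",
      paste(range(x$report_years), collapse = "-"),
      ", mode ", x$config$mode, "\n", sep = "")
  invisible(x)
}

#' Summarize a redistribution ensemble
#'
#' Aggregates per-iteration cause-of-death counts at a chosen hierarchy
#' level and reports the mean and the 2.5th/97.5th percentiles across
#' iterations (the 95% uncertainty interval), together with the
#' step-attribution shares per year (fraction of deaths resolved at
#' mapping and at each redistribution step) and the ill-defined share by
#' cause (proportion of each cause's final deaths that started as
#' ill-defined).
#'
#' @param ensemble A `redistribution_ensemble`.
#' @param data The [cod_data] the ensemble was computed from.
#' @param map The [cause_map] used.
#' @param level Cause hierarchy level for reporting (1-4; default 3).
#' @param by Character vector of record stratifiers (`"year"`, `"sex"`,
#'   `"region"`); default `"year"`.
#' @return List of class `redistribution_summary` with elements `counts`
#'   (`by`, `cause`, `mean`, `lower`, `upper`), `step_shares` (`year`,
#'   `step`, `share`), `idd_share` (`cause`, `idd_share`) and metadata.
#' @export
summarize_ensemble <- function(ensemble, data, map, level = 3L,
                               by = "year") {
  stopifnot(inherits(ensemble, "redistribution_ensemble"),
            inherits(data, "cod_data"))
  bad <- setdiff(by, c("year", "sex", "region"))
  if (length(bad))
    stop("unknown stratifier(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  a <- merge(ensemble$assignments,
             data$deaths[, c("record_id", "year", "sex", "region", "age")],
             by = "record_id")
  a$cause <- cause_at_level(a$cause_l4, map, level)
  n_iter <- ensemble$config$n_iterations

  cnt <- a[, list(n = sum(weight)), by = c("iteration", by, "cause")]
  # complete with zero cells so percentiles see absent causes
  cells <- unique(cnt[, c(by, "cause"), with = FALSE])
  grid <- cells[rep(seq_len(nrow(cells)), each = n_iter)]
  grid$iteration <- rep(seq_len(n_iter), nrow(cells))
  cnt <- merge(grid, cnt, by = c("iteration", by, "cause"), all.x = TRUE)
  cnt$n[is.na(cnt$n)] <- 0
  counts <- cnt[, list(mean = mean(n),
                       lower = stats::quantile(n, 0.025, names = FALSE),
                       upper = stats::quantile(n, 0.975, names = FALSE)),
                by = c(by, "cause")]
  data.table::setorderv(counts, c(by, "cause"))

  ss <- a[, list(n = sum(weight)), by = c("iteration", "year", "step")]
  ss[, "share" := n / sum(n), by = c("iteration", "year")]
  step_shares <- ss[, list(share = mean(share)), by = c("year", "step")]
  data.table::setorderv(step_shares, c("year", "step"))

  a$redist <- a$step != "mapped"
  ishr <- a[, list(s = sum(weight * redist) / sum(weight)),
            by = c("iteration", "cause")]
  idd_share <- ishr[, list(idd_share = mean(s)), by = "cause"]
  data.table::setorderv(idd_share, "cause")

  structure(list(counts = counts[], step_shares = step_shares[],
                 idd_share = idd_share[], level = level, by = by,
                 n_iterations = n_iter,
                 years = sort(unique(a$year))),
            class = "redistribution_summary")
}

#' @export
print.redistribution_summary <- function(x, ...) {
  cat("<redistribution_summary> level-", x$level, " causes by ",
      paste(x$by, collapse = "+"), ", ", x$n_iterations,
      " iteration(s)\n", sep = "")
  print(utils::head(x$counts, 10))
  invisible(x)
}

#' Translate level-4 cause ids to a higher hierarchy level
#'
#' @param cause_l4 Character vector of level-4 cause ids.
#' @param map A [cause_map].
#' @param level Target level (1-4).
#' @return Character vector of cause ids at the requested level.
#' @export
cause_at_level <- function(cause_l4, map, level) {
  if (level == 4L) return(cause_l4)
  col <- paste0("cause_l", level)
  map$hierarchy[[col]][match(cause_l4, map$hierarchy$cause_l4)]
}
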