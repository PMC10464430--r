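#' Cause-of-death microdata container
#'
#' Bundles the one-row-per-death table and the long multiple-causes-of-death
#' (MCOD) table into a single object. `deaths` has columns `record_id`,
#' `year`, `age`, `sex` (`"male"`/`"female"`), `region` and `uc` (normalized
#' underlying-cause ICD-10 code); `mcod` has `record_id`, `code` and `role`
#' (`"immediate"`, `"intermediate"` or `"associated"`).
#'
#' @param deaths data.frame of deaths.
#' @param mcod data.frame of contributory causes (may be empty).
#' @return An object of class `cod_data`.
#' @export
cod_data <- function(deaths, mcod = NULL) {
  deaths <- data.table::as.data.table(deaths)
  need <- c("record_id", "year", "age", "sex", "region", "uc")
  miss <- setdiff(need, names(deaths))
  if (length(miss))
    stop("deaths table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(deaths$record_id))
    stop("duplicate record_id in deaths table", call. = FALSE)
  if (is.null(mcod)) {
    mcod <- data.table::data.table(record_id = deaths$record_id[0],
                                   code = character(0), role = character(0))
  } else {
    mcod <- data.table::as.data.table(mcod)
    missm <- setdiff(c("record_id", "code", "role"), names(mcod))
    if (length(missm))
      stop("mcod table lacks column(s): ", paste(missm, collapse = ", "),
           call. = FALSE)
    badrole <- setdiff(unique(mcod$role),
                       c("immediate", "intermediate", "associated"))
    if (length(badrole))
      stop("unknown MCOD role(s): ", paste(badrole, collapse = ", "),
           call. = FALSE)
  }
  out <- list(deaths = deaths[], mcod = mcod[])
  class(out) <- "cod_data"
  out
}

#' @export
print.cod_data <- function(x, ...) {
  cat("<cod_data> ", nrow(x$deaths), " deaths, ",
      nrow(x$mcod), " MCOD entries, years ",
      if (nrow(x$deaths)) paste(range(x$deaths$year), collapse = "-") else "-",
      "\n", sep = "")
  invisible(x)
}

normalize_sex <- function(x) {
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("m", "male", "1")] <- "male"
  out[s %in% c("f", "female", "2")] <- "female"
  out
}

#' Read death-certificate microdata
#'
#' Reads a delimited file of deaths (one row per death) and, optionally, the
#' multiple causes of death either from wide columns (`cause_1..cause_k` /
#' `role_1..role_k`) in the same file or from a long companion file with
#' columns `record_id`, `code`, `role`. ICD codes are normalized on read;
#' row order is preserved.
#'
#' @param path Path to the deaths file (CSV/TSV; delimiter sniffed by
#'   [data.table::fread()]).
#' @param mcod_path Optional path to a long-format MCOD companion file.
#' @param col_map Named list mapping the canonical roles `record_id`, `year`,
#'   `age`, `sex`, `region`, `uc` to the column names actually present.
#' @return A [cod_data] object.
#' @export
read_death_records <- function(path, mcod_path = NULL,
                               col_map = list()) {
  dt <- data.table::fread(path, colClasses = list(character = "record_id"),
                          showProgress = FALSE)
  defaults <- list(record_id = "record_id", year = "year", age = "age",
                   sex = "sex", region = "region", uc = "uc")
  cm <- utils::modifyList(defaults, col_map)
  unknown <- setdiff(unlist(cm), names(dt))
  if (length(unknown))
    stop("unknown column(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  deaths <- data.table::data.table(
    record_id = as.character(dt[[cm$record_id]]),
    year = suppressWarnings(as.integer(dt[[cm$year]])),
    age = suppressWarnings(as.integer(dt[[cm$age]])),
    sex = normalize_sex(dt[[cm$sex]]),
    region = as.character(dt[[cm$region]]),
    uc = normalize_icd(as.character(dt[[cm$uc]]))
  )
  badyear <- which(is.na(deaths$year) & !is.na(dt[[cm$year]]) &
                     trimws(as.character(dt[[cm$year]])) != "")
  if (length(badyear))
    stop("unparseable year at row(s): ",
         paste(utils::head(badyear, 10L), collapse = ", "), call. = FALSE)
  badage <- which(is.na(deaths$age) & !is.na(dt[[cm$age]]) &
                    trimws(as.character(dt[[cm$age]])) != "")
  if (length(badage))
    stop("unparseable age at row(s): ",
         paste(utils::head(badage, 10L), collapse = ", "), call. = FALSE)

  mcod <- NULL
  wide_cause <- grep("^cause_[0-9]+$", names(dt), value = TRUE)
  if (!is.null(mcod_path)) {
    ml <- data.table::fread(mcod_path, showProgress = FALSE)
    missm <- setdiff(c("record_id", "code", "role"), names(ml))
    if (length(missm))
      stop("MCOD file lacks column(s): ", paste(missm, collapse = ", "),
           call. = FALSE)
    mcod <- data.table::data.table(record_id = as.character(ml$record_id),
                                   code = normalize_icd(as.character(ml$code)),
                                   role = as.character(ml$role))
  } else if (length(wide_cause)) {
    k <- sort(as.integer(sub("^cause_", "", wide_cause)))
    parts <- lapply(k, function(i) {
      code <- as.character(dt[[paste0("cause_", i)]])
      rolecol <- paste0("role_", i)
      role <- if (rolecol %in% names(dt)) as.character(dt[[rolecol]]) else
        rep("associated", nrow(dt))
      keep <- !is.na(code) & trimws(code) != ""
      data.table::data.table(record_id = deaths$record_id[keep],
                             code = normalize_icd(code[keep]),
                             role = role[keep])
    })
    mcod <- data.table::rbindlist(parts)
    data.table::setorder(mcod, record_id)
  }
  cod_data(deaths, mcod)
}

#' Validate death records
#'
#' Excludes (without erroring) records that cannot enter the analysis:
#' missing age or sex, age outside 0--122 after clamping, and stillbirths
#' (underlying cause in `stillbirth_codes`, default ICD-10 P95). Ages above
#' 122 are clamped to 122 with a warning, matching the terminal age of the
#' reference life table.
#'
#' @param data A [cod_data] object.
#' @param stillbirth_codes ICD-10 prefixes identifying stillbirths.
#' @return List with `kept` (a [cod_data]) and `exclusions` (named integer
#'   vector with counts per reason). Counts conserve:
#'   `nrow(kept) + sum(exclusions) == nrow(input)`.
#' @export
validate_records <- function(data, stillbirth_codes = "P95") {
  stopifnot(inherits(data, "cod_data"))
  d <- data.table::copy(data$deaths)
  n <- nrow(d)
  reason <- rep(NA_character_, n)
  reason[is.na(d$age)] <- "missing_age"
  reason[is.na(reason) & is.na(d$sex)] <- "missing_sex"
  reason[is.na(reason) & d$age < 0] <- "negative_age"
  if (length(stillbirth_codes)) {
    sb <- icd_in_set(d$uc, normalize_icd(stillbirth_codes))
    reason[is.na(reason) & sb] <- "stillbirth"
  }
  over <- !is.na(d$age) & d$age > 122L & is.na(reason)
  if (any(over)) {
    warning(sum(over), " record(s) with age > 122 clamped to 122",
            call. = FALSE)
    d[over, "age"] <- 122L
  }
  keep <- is.na(reason)
  excl <- table(reason[!keep])
  exclusions <- stats::setNames(as.integer(excl), names(excl))
  kept_ids <- d$record_id[keep]
  kept <- cod_data(d[keep], data$mcod[data$mcod$record_id %in% kept_ids])
  list(kept = kept, exclusions = exclusions)
}

#' Read a reference life table
#'
#' Expects two columns: `age` and `residual_expectancy` (remaining life
#' expectancy in years at the exact age of death).
#'
#' @param path CSV file path.
#' @return data.table ordered by age.
#' @export
read_life_table <- function(path) {
  lt <- data.table::fread(path, showProgress = FALSE)
  miss <- setdiff(c("age", "residual_expectancy"), names(lt))
  if (length(miss))
    stop("life table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  data.table::setorder(lt, age)
  lt[]
}

#' Read a standard population
#'
#' Expects columns `age_lo`, `age_hi` (upper bound exclusive; `NA` for the
#' open terminal group) and `weight` (person-count). Groups must be
#' contiguous five-year groups apart from the first (which may be split at
#' age 1) and the open terminal group.
#'
#' @param path CSV file path.
#' @return data.table ordered by `age_lo`.
#' @export
read_standard_population <- function(path) {
  sp <- data.table::fread(path, showProgress = FALSE)
  miss <- setdiff(c("age_lo", "age_hi", "weight"), names(sp))
  if (length(miss))
    stop("standard population lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  data.table::setorder(sp, age_lo)
  if (any(sp$weight <= 0)) stop("standard weights must be > 0", call. = FALSE)
  sp[]
}

#' Read mid-year population counts
#'
#' Expects columns `year`, `sex`, `region`, `age_lo` (lower bound of the
#' five-year age group) and `population`.
#'
#' @param path CSV file path.
#' @return data.table.
#' @export
read_population <- function(path) {
  p <- data.table::fread(path, showProgress = FALSE)
  miss <- setdiff(c("year", "sex", "region", "age_lo", "population"),
                  names(p))
  if (length(miss))
    stop("population table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(p$population < 0)) stop("negative population count", call. = FALSE)
  p$sex <- normalize_sex(p$sex)
  p[]
}

#' Write result tables
#'
#' Writes each summarized result table to `<dir>/<name>.csv`. Re-reading a
#' written file with [data.table::fread()] reproduces the table.
#'
#' @param tables Named list of data.frames.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_estimates <- function(tables, dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    data.table::fwrite(data.table::as.data.table(tables[[nm]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write microdata to disk
#'
#' Writes the deaths table and the long MCOD companion table as CSV, in the
#' dialect accepted by [read_death_records()].
#'
#' @param data A [cod_data] object.
#' @param path Path for the deaths CSV; the MCOD table goes to
#'   `<path minus .csv>_mcod.csv`.
#' @return Invisibly, the two paths.
#' @export
write_death_records <- function(data, path) {
  stopifnot(inherits(data, "cod_data"))
  data.table::fwrite(data$deaths, path)
  mpath <- sub("\\.csv$", "", path)
  mpath <- paste0(mpath, "_mcod.csv")
  data.table::fwrite(data$mcod, mpath)
  invisible(c(path, mpath))
}
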