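#' Construct a cause map
#'
#' A cause map relates ICD-10 prefixes (3 or 4 characters; a 4-character
#' entry shadows its 3-character parent) to a four-level GBD-style cause
#' hierarchy and classifies ill-defined codes for routing through the
#' redistribution steps:
#' \describe{
#'   \item{specific}{maps directly to a level-4 cause;}
#'   \item{icd_targeted}{ill-defined, redistributed in step 1 against a
#'     predefined list of ICD target codes;}
#'   \item{packaged}{ill-defined and intrinsically uninformative,
#'     redistributed in step 2 via an MCOD-defined package;}
#'   \item{unassigned}{ill-defined with no a-priori targets, redistributed
#'     internally (step 3) or over all causes (step 4).}
#' }
#'
#' @param entries data.frame with columns `icd_prefix`, `cause_l4`,
#'   `cause_l3`, `cause_l2`, `cause_l1`, `idd_class`, `target_codes`
#'   (semicolon-separated ICD prefixes, icd_targeted entries only) and
#'   `package_id` (packaged entries only). For non-specific entries the
#'   hierarchy columns are empty.
#' @param packages data.frame with columns `package_id`, `name`,
#'   `member_prefix` (one row per member ICD prefix). Optional.
#' @param combination_rules data.frame with columns `uc_codes`,
#'   `mcod_codes` (semicolon-separated prefix sets) and `override`
#'   (replacement UC ICD code). Optional.
#' @param sex_restrictions data.frame with columns `cause` (a level-4 or
#'   level-3 cause id) and `sex` (the only sex the cause may receive).
#'   Optional.
#' @return Object of class `cause_map`.
#' @export
cause_map <- function(entries, packages = NULL, combination_rules = NULL,
                      sex_restrictions = NULL) {
  e <- data.table::as.data.table(entries)
  need <- c("icd_prefix", "cause_l4", "cause_l3", "cause_l2", "cause_l1",
            "idd_class")
  miss <- setdiff(need, names(e))
  if (length(miss))
    stop("entries lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"target_codes" %in% names(e)) e$target_codes <- ""
  if (!"package_id" %in% names(e)) e$package_id <- ""
  for (col in names(e)) if (is.character(e[[col]]))
    data.table::set(e, j = col, value = trimws(e[[col]]))
  e$icd_prefix <- normalize_icd(e$icd_prefix)
  if (anyDuplicated(e$icd_prefix))
    stop("duplicate ICD prefixes in cause map: ",
         paste(unique(e$icd_prefix[duplicated(e$icd_prefix)]),
               collapse = ", "), call. = FALSE)
  badclass <- setdiff(unique(e$idd_class),
                      c("specific", "icd_targeted", "packaged", "unassigned"))
  if (length(badclass))
    stop("unknown idd_class: ", paste(badclass, collapse = ", "),
         call. = FALSE)

  spec <- e[e$idd_class == "specific"]
  if (any(spec$cause_l4 == "" | spec$cause_l3 == "" |
            spec$cause_l2 == "" | spec$cause_l1 == ""))
    stop("specific entries must carry a full level-4..1 hierarchy",
         call. = FALSE)
  # hierarchy must be a tree: each child has exactly one parent
  hier <- unique(spec[, c("cause_l4", "cause_l3", "cause_l2", "cause_l1")])
  for (pair in list(c("cause_l4", "cause_l3"), c("cause_l3", "cause_l2"),
                    c("cause_l2", "cause_l1"))) {
    parents <- unique(hier[, pair, with = FALSE])
    dup <- parents[[1]][duplicated(parents[[1]])]
    if (length(dup))
      stop("cause hierarchy is not a tree: ", pair[1], " ",
           paste(unique(dup), collapse = ", "),
           " has multiple ", pair[2], " parents", call. = FALSE)
  }

  tgt <- e[e$idd_class == "icd_targeted"]
  if (any(tgt$target_codes == ""))
    stop("icd_targeted entries need a non-empty target_codes list: ",
         paste(tgt$icd_prefix[tgt$target_codes == ""], collapse = ", "),
         call. = FALSE)

  pk <- e[e$idd_class == "packaged"]
  if (any(pk$package_id == ""))
    stop("packaged entries need a package_id", call. = FALSE)
  if (is.null(packages)) {
    packages <- data.table::data.table(package_id = character(0),
                                       name = character(0),
                                       member_prefix = character(0))
  } else {
    packages <- data.table::as.data.table(packages)
    packages$member_prefix <- normalize_icd(packages$member_prefix)
  }
  orphan <- setdiff(pk$package_id, packages$package_id)
  if (length(orphan))
    stop("packaged entries reference unknown package(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)

  if (is.null(combination_rules)) {
    combination_rules <- data.table::data.table(uc_codes = character(0),
                                                mcod_codes = character(0),
                                                override = character(0))
  } else {
    combination_rules <- data.table::as.data.table(combination_rules)
  }
  if (is.null(sex_restrictions)) {
    sex_restrictions <- data.table::data.table(cause = character(0),
                                               sex = character(0))
  } else {
    sex_restrictions <- data.table::as.data.table(sex_restrictions)
    bad <- setdiff(unique(sex_restrictions$sex), c("male", "female"))
    if (length(bad))
      stop("sex restriction sex must be male/female", call. = FALSE)
  }
  # resolve restrictions (given at level 3 or 4) to level-4 cause ids
  restr_l4 <- rbind(
    hier[hier$cause_l4 %in% sex_restrictions$cause,
         .(cause_l4, sex = sex_restrictions$sex[
           match(cause_l4, sex_restrictions$cause)])],
    hier[hier$cause_l3 %in% sex_restrictions$cause,
         .(cause_l4, sex = sex_restrictions$sex[
           match(cause_l3, sex_restrictions$cause)])])
  restr_l4 <- unique(restr_l4)

  out <- list(entries = e[], hierarchy = hier[], packages = packages[],
              combination_rules = combination_rules[],
              sex_restrictions = sex_restrictions[],
              restricted_l4 = restr_l4[])
  class(out) <- "cause_map"
  out
}

#' @export
print.cause_map <- function(x, ...) {
  cat("<cause_map> ", nrow(x$entries), " ICD prefixes (",
      sum(x$entries$idd_class == "specific"), " specific, ",
      sum(x$entries$idd_class != "specific"), " ill-defined); ",
      length(unique(x$hierarchy$cause_l3)), " level-3 causes, ",
      length(unique(x$hierarchy$cause_l2)), " level-2 groups, ",
      length(unique(x$hierarchy$cause_l1)), " level-1 clusters; ",
      nrow(x$packages), " package member rows; ",
      nrow(x$combination_rules), " combination rules\n", sep = "")
  invisible(x)
}

split_codes <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE),
         function(v) normalize_icd(trimws(v[trimws(v) != ""])))
}

#' Load a cause map from disk
#'
#' Reads the four CSV components of a cause map from a directory:
#' `entries.csv` (required), `packages.csv`, `combination_rules.csv` and
#' `sex_restrictions.csv` (each optional). The bundled demo map
#' (`demo_cause_map()`) is the canonical example of the format.
#'
#' @param path Directory containing the map files.
#' @return A [cause_map].
#' @export
load_cause_map <- function(path) {
  ef <- file.path(path, "entries.csv")
  if (!file.exists(ef)) stop("no entries.csv under ", path, call. = FALSE)
  rd <- function(f) if (file.exists(file.path(path, f)))
    data.table::fread(file.path(path, f), showProgress = FALSE,
                      colClasses = "character") else NULL
  cause_map(data.table::fread(ef, showProgress = FALSE,
                              colClasses = "character"),
            packages = rd("packages.csv"),
            combination_rules = rd("combination_rules.csv"),
            sex_restrictions = rd("sex_restrictions.csv"))
}

#' Bundled demonstration cause map
#'
#' A compact GBD-style map covering 27 specific level-3 causes across the
#' three level-1 clusters (non-communicable; communicable, maternal,
#' neonatal and nutritional; injuries), the classic ill-defined codes
#' (I50.9, J18.9, I64, R99, C55, N19, ...), two MCOD packages
#' (heart failure, acute kidney failure) and the drug-death combination
#' rules. Intended for examples, tests and synthetic data; real analyses
#' should supply a full national map via [load_cause_map()].
#'
#' @return A [cause_map].
#' @export
demo_cause_map <- function() {
  load_cause_map(system.file("extdata", "demo_map", package = "gcredist"))
}

#' Apply UC/MCOD combination rules
#'
#' Replaces the underlying cause of a record when its UC matches a rule's
#' UC code set and any of its MCOD codes matches the rule's MCOD code set
#' (e.g. accidental poisoning codes combined with T40 opioid codes are
#' recoded to drug-use disorder F19). Rules are applied in file order,
#' before ill-defined classification.
#'
#' @param data A [cod_data] object.
#' @param map A [cause_map].
#' @return A modified [cod_data].
#' @export
apply_combination_rules <- function(data, map) {
  stopifnot(inherits(data, "cod_data"), inherits(map, "cause_map"))
  rules <- map$combination_rules
  if (nrow(rules) == 0L) return(data)
  d <- data.table::copy(data$deaths)
  mc <- data$mcod
  for (i in seq_len(nrow(rules))) {
    uc_set <- split_codes(rules$uc_codes[i])[[1]]
    mcod_set <- split_codes(rules$mcod_codes[i])[[1]]
    override <- normalize_icd(rules$override[i])
    hit_ids <- unique(mc$record_id[icd_in_set(mc$code, mcod_set)])
    sel <- icd_in_set(d$uc, uc_set) & d$record_id %in% hit_ids
    if (any(sel)) d[sel, "uc"] <- override
  }
  cod_data(d, mc)
}

#' Map underlying causes to the cause hierarchy
#'
#' Longest-prefix lookup of each record's (combination-rule-adjusted)
#' underlying cause against the map. Specific causes are resolved
#' immediately (`resolution_step = "mapped"`); ill-defined codes carry their
#' class for routing through redistribution steps 1--4. Codes with no map
#' entry at all are treated as unassigned ill-defined, with a warning.
#'
#' @param data A [cod_data] object.
#' @param map A [cause_map].
#' @return data.table with one row per record: `record_id`, `cause_l4`
#'   (`NA` for ill-defined), `idd_class`, `resolution_step` (`"mapped"` or
#'   `NA`), `map_prefix` (the matched entry) .
#' @export
map_underlying_cause <- function(data, map) {
  stopifnot(inherits(data, "cod_data"), inherits(map, "cause_map"))
  e <- map$entries
  idx <- match_icd_prefix(data$deaths$uc, e$icd_prefix)
  unmatched <- is.na(idx)
  if (any(unmatched))
    warning(sum(unmatched), " UC code(s) without a map entry treated as ",
            "unassigned ill-defined (e.g. ",
            paste(utils::head(unique(data$deaths$uc[unmatched]), 5L),
                  collapse = ", "), ")", call. = FALSE)
  idd_class <- ifelse(unmatched, "unassigned", e$idd_class[idx])
  cause_l4 <- ifelse(idd_class == "specific", e$cause_l4[idx], NA_character_)
  data.table::data.table(
    record_id = data$deaths$record_id,
    cause_l4 = cause_l4,
    idd_class = idd_class,
    resolution_step = ifelse(idd_class == "specific", "mapped",
                             NA_character_),
    map_prefix = ifelse(unmatched, NA_character_, e$icd_prefix[idx]))
}

# level-4 causes reachable (via prefix matching on specific map entries)
# from a set of ICD target prefixes
target_causes <- function(map, prefixes) {
  spec <- map$entries[map$entries$idd_class == "specific"]
  hit <- icd_in_set(spec$icd_prefix, prefixes)
  unique(spec$cause_l4[hit])
}
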