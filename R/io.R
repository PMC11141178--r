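## Cohort and configuration I/O: CSV read/write with schema validation,
## JSON generator configuration.

subject_columns <- c("subject_id", "tract_id", "race", "sex", "age", "bmi",
                     "family_history_fdr", "smoking_years", "diabetes",
                     "calcium_use", "red_meat_per_week", "alcohol_per_week",
                     "acn")

#' Write a generated tract table and cohort to CSV
#'
#' @param sim list with `tracts` and `cohort` as returned by
#'   [generate_cohort()].
#' @param subject_csv,tract_csv output paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(sim, subject_csv, tract_csv) {
  utils::write.csv(sim$cohort, subject_csv, row.names = FALSE)
  utils::write.csv(sim$tracts, tract_csv, row.names = FALSE)
  invisible(c(subject_csv, tract_csv))
}

#' Read, validate and join a cohort from CSV
#'
#' Reads the subject-level and tract-level tables, optionally renaming
#' columns through a dictionary, validates the schema (all canonical
#' subject columns present, ages within the screening eligibility window
#' 50-80, binary outcome), resolves every subject's `tract_id` against the
#' tract table, and joins the tract deprivation score onto subjects.  When
#' the tract table has no `adi` column the index is computed from the 17
#' indicator columns with [compute_adi()].
#'
#' @param subject_csv path to the subject table.
#' @param tract_csv path to the tract table.
#' @param dictionary optional named character vector mapping file column
#'   names to the canonical schema (`c(file_name = "canonical_name")`).
#' @return list with `tracts` and `cohort` data frames (cohort carries a
#'   joined `adi` column).
#' @export
read_cohort <- function(subject_csv, tract_csv, dictionary = NULL) {
  for (p in c(subject_csv, tract_csv))
    if (!file.exists(p)) stop("file not found: ", p)
  subj <- utils::read.csv(subject_csv, stringsAsFactors = FALSE)
  tracts <- utils::read.csv(tract_csv, stringsAsFactors = FALSE)
  rename <- function(d) {
    if (is.null(dictionary)) return(d)
    hit <- names(d) %in% names(dictionary)
    names(d)[hit] <- unname(dictionary[names(d)[hit]])
    d
  }
  subj <- rename(subj); tracts <- rename(tracts)
  need <- setdiff(subject_columns, c(names(subj), "adi"))
  if (length(need))
    stop("schema error: missing required subject column(s): ",
         paste(need, collapse = ", "))
  if (!"tract_id" %in% names(tracts))
    stop("schema error: tract table lacks tract_id")
  if (anyDuplicated(tracts$tract_id))
    stop("tract_id values must be unique in the tract table")
  bad_age <- which(subj$age < 50 | subj$age > 80)
  if (length(bad_age))
    stop("validation error: age outside the 50-80 eligibility window ",
         "in row(s): ", paste(utils::head(bad_age, 20), collapse = ", "))
  if (!all(subj$acn %in% c(0, 1)))
    stop("validation error: acn must be binary 0/1")
  unresolved <- which(!(subj$tract_id %in% tracts$tract_id))
  if (length(unresolved))
    stop("referential integrity error: unresolvable tract_id in row(s): ",
         paste(utils::head(unresolved, 20), collapse = ", "))
  if (!"adi" %in% names(tracts)) {
    adi <- compute_adi(tracts)
    tracts$adi <- unname(adi$adi_by_tract[as.character(tracts$tract_id)])
  }
  subj$adi <- tracts$adi[match(subj$tract_id, tracts$tract_id)]
  list(tracts = tracts, cohort = subj)
}

#' Read a generator configuration from JSON
#'
#' The JSON mirrors the arguments of [generator_config()]: scalar fields
#' at the top level, `race_blocks` an object keyed by race label whose
#' entries hold [race_block()] arguments, and `coefficients` objects of
#' named log odds ratios.  Absent fields fall back to the defaults.
#'
#' @param path JSON file path.
#' @return an `acn_generator_config`.
#' @export
read_generator_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (nm in c("n_tracts", "factor_loading", "adi_log_or_per_10",
               "tract_sigma", "seed"))
    if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
  if (!is.null(cfg$coefficients))
    args$coefficients <- as.list(cfg$coefficients)
  if (!is.null(cfg$race_blocks)) {
    args$race_blocks <- lapply(cfg$race_blocks, function(b) {
      b <- as.list(b)
      if (!is.null(b$coefficients)) b$coefficients <- as.list(b$coefficients)
      do.call(race_block, b)
    })
  }
  do.call(generator_config, args)
}

## FNV-1a hash of a serialized object; provenance fingerprint for reports.
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    ## xor touches only the low byte (b < 256); h kept as a double
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    ## 32-bit modular multiply kept inside double precision
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}
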