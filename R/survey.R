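#' Survey dataset container
#'
#' An `ethno_survey` joins the three tables of a quantitative
#' ethnobotanical survey: the informant roster, the taxon register and the
#' use-reports. A use-report is the atomic unit of the analysis: one
#' citation of one taxon by one informant for one ailment, optionally
#' binned into a disease category and localized to a village.
#'
#' Two levels are supported. At `informant_level` every report row carries
#' an informant id and a count of 1. At `aggregate` level reports are
#' (taxon, category, village) counts and the number of informants `n` must
#' be supplied explicitly, because published surveys typically print only
#' the aggregated tallies.
#'
#' @param informants data.frame with columns `informant_id`, `age`,
#'   `gender`, `education`, `community`, `village`; may have zero rows for
#'   aggregate-only data.
#' @param taxa data.frame with columns `taxon_id`, `botanical_name`,
#'   `family`, `life_form`, `parts_used` (semicolon-joined), `preparation`,
#'   `route`, `nativity`, `voucher` and optionally `taxonomic_group`.
#' @param reports data.frame with columns `informant_id`, `taxon_id`,
#'   `ailment`, `category`, `village`, `count`.
#' @param level `"informant_level"` or `"aggregate"`.
#' @param n_informants informant count; required at aggregate level,
#'   derived from the roster otherwise.
#' @return validated object of class `ethno_survey`.
#' @seealso [read_survey()], [aggregate_survey()], [generate_survey()]
#' @export
ethno_survey <- function(informants = empty_informants(), taxa, reports,
                         level = c("informant_level", "aggregate"),
                         n_informants = NULL) {
  level <- match.arg(level)
  if (level == "informant_level") {
    n_informants <- nrow(informants)
  } else if (is.null(n_informants)) {
    ei_error("ei_validation_error",
             "aggregate-level datasets require an explicit n_informants")
  }
  ds <- structure(
    list(informants = informants, taxa = taxa, reports = reports,
         level = level, n_informants = as.integer(n_informants)),
    class = "ethno_survey")
  validate_survey(ds)
}

#' @rdname ethno_survey
#' @export
empty_informants <- function() {
  data.frame(informant_id = character(), age = integer(),
             gender = character(), education = character(),
             community = character(), village = character(),
             stringsAsFactors = FALSE)
}

empty_reports <- function() {
  data.frame(informant_id = character(), taxon_id = character(),
             ailment = character(), category = character(),
             village = character(), count = integer(),
             stringsAsFactors = FALSE)
}

#' Validate an ethno_survey
#'
#' Checks identifier uniqueness, referential integrity of reports against
#' the registers, vocabulary membership and the level contract. Errors are
#' classed (`ei_uniqueness_error`, `ei_reference_error`,
#' `ei_validation_error`) and name the offending rows.
#'
#' @param ds object as returned by [ethno_survey()].
#' @return `ds`, invisibly usable, after validation.
#' @export
validate_survey <- function(ds) {
  inf <- ds$informants; tax <- ds$taxa; rep <- ds$reports

  if (anyDuplicated(inf$informant_id)) {
    ei_error("ei_uniqueness_error", "duplicate informant_id: %s",
             paste(unique(inf$informant_id[duplicated(inf$informant_id)]),
                   collapse = ", "))
  }
  if (anyDuplicated(tax$taxon_id)) {
    ei_error("ei_uniqueness_error", "duplicate taxon_id: %s",
             paste(unique(tax$taxon_id[duplicated(tax$taxon_id)]),
                   collapse = ", "))
  }
  if (nrow(inf)) {
    bad_age <- which(is.na(inf$age) | inf$age < 15 | inf$age > 110)
    if (length(bad_age)) {
      ei_error("ei_validation_error",
               "informant age outside [15, 110] on row(s): %s",
               paste(bad_age, collapse = ", "))
    }
    stopifnot(all(inf$gender %in% .genders),
              all(inf$education %in% .educations),
              all(inf$community %in% .communities))
  }
  if (!nrow(tax)) {
    ei_error("ei_validation_error", "taxon register is empty")
  }
  if (any(!nzchar(tax$family) | is.na(tax$family))) {
    ei_error("ei_validation_error", "taxon rows with empty family: %s",
             paste(which(!nzchar(tax$family) | is.na(tax$family)),
                   collapse = ", "))
  }
  parts <- strsplit(tax$parts_used, ";", fixed = TRUE)
  if (any(lengths(parts) == 0L)) {
    ei_error("ei_validation_error", "taxon rows without parts_used: %s",
             paste(which(lengths(parts) == 0L), collapse = ", "))
  }
  stopifnot(all(unlist(parts) %in% .plant_parts),
            all(tax$life_form %in% .life_forms),
            all(tax$preparation %in% .preparations),
            all(tax$route %in% .routes),
            all(tax$nativity %in% .nativities))

  if (nrow(rep)) {
    dangling <- which(!(rep$taxon_id %in% tax$taxon_id))
    if (length(dangling)) {
      ei_error("ei_reference_error",
               "use-report row(s) cite unknown taxa: rows %s (taxon %s)",
               paste(dangling, collapse = ", "),
               paste(unique(rep$taxon_id[dangling]), collapse = ", "))
    }
    if (any(is.na(rep$count) | rep$count < 1L)) {
      ei_error("ei_validation_error", "use-report counts must be >= 1")
    }
    cat_set <- !is.na(rep$category) & nzchar(rep$category)
    if (any(!(rep$category[cat_set] %in% .cats))) {
      ei_error("ei_validation_error", "unknown disease category: %s",
               paste(setdiff(rep$category[cat_set], .cats), collapse = ", "))
    }
  }

  if (ds$level == "informant_level") {
    if (nrow(rep)) {
      no_inf <- which(is.na(rep$informant_id) | !nzchar(rep$informant_id))
      if (length(no_inf)) {
        ei_error("ei_validation_error",
                 "informant-level reports lack informant_id on rows: %s",
                 paste(no_inf, collapse = ", "))
      }
      if (any(rep$count != 1L)) {
        ei_error("ei_validation_error",
                 "informant-level reports must have count = 1")
      }
      dangling <- which(!(rep$informant_id %in% inf$informant_id))
      if (length(dangling)) {
        ei_error("ei_reference_error",
                 "use-report row(s) cite unknown informants: rows %s",
                 paste(dangling, collapse = ", "))
      }
    }
  } else if (is.na(ds$n_informants) || ds$n_informants < 1L) {
    ei_error("ei_validation_error", "aggregate level requires n_informants > 0")
  }
  ds
}

#' Total number of use-reports
#'
#' @param ds an `ethno_survey`.
#' @return integer sum of report counts (the study-wide citation total).
#' @export
total_use_reports <- function(ds) {
  as.integer(sum(ds$reports$count))
}

#' @export
print.ethno_survey <- function(x, ...) {
  cat(sprintf(
    "ethno_survey (%s): %d taxa, %d families, %d informants, %d use-reports\n",
    x$level, nrow(x$taxa), length(unique(x$taxa$family)),
    x$n_informants, total_use_reports(x)))
  invisible(x)
}

#' Read a survey from delimited text files
#'
#' Files are comma- or tab-delimited (auto-detected from the header line)
#' with a header row. Vocabulary columns accept full words or the common
#' field abbreviations (`H`, `Wp`, `N`/`E`, ...) in any case; tokens are
#' trimmed and normalized. Missing columns raise a schema error naming the
#' column; dangling references raise a referential-integrity error listing
#' the offending row numbers.
#'
#' @param informants_path path to the roster CSV, or `NULL` for
#'   aggregate-only data.
#' @param taxa_path path to the taxon register CSV.
#' @param reports_path path to the use-reports CSV.
#' @param level dataset level, see [ethno_survey()].
#' @param n_informants required when `level = "aggregate"`.
#' @return an `ethno_survey`.
#' @export
read_survey <- function(taxa_path, reports_path, informants_path = NULL,
                        level = c("informant_level", "aggregate"),
                        n_informants = NULL) {
  level <- match.arg(level)

  tax <- read_delim_file(
    taxa_path,
    required = c("taxon_id", "botanical_name", "family", "life_form",
                 "parts_used", "preparation", "route", "nativity", "voucher"),
    optional = c("taxonomic_group", "common_name"), what = "taxa file")
  tax$life_form <- normalize_token(tax$life_form, .life_forms,
                                   .aliases$life_form, "life_form")
  tax$parts_used <- vapply(strsplit(tax$parts_used, ";", fixed = TRUE),
                           function(p) paste(normalize_token(
                             p, .plant_parts, .aliases$plant_part,
                             "plant_part"), collapse = ";"), character(1))
  tax$preparation <- normalize_token(tax$preparation, .preparations,
                                     .aliases$preparation, "preparation")
  tax$route <- normalize_token(tax$route, .routes, field = "route")
  tax$nativity <- normalize_token(tax$nativity, .nativities,
                                  .aliases$nativity, "nativity")

  rep <- read_delim_file(
    reports_path,
    required = c("informant_id", "taxon_id", "ailment", "category",
                 "village", "count"), what = "use-reports file")
  rep$count <- as.integer(rep$count)
  rep$category <- toupper(trimws(rep$category))
  rep$category[!nzchar(rep$category)] <- NA_character_
  rep$informant_id[!nzchar(trimws(rep$informant_id))] <- NA_character_
  rep$village[!nzchar(trimws(rep$village))] <- NA_character_

  inf <- empty_informants()
  if (!is.null(informants_path)) {
    inf <- read_delim_file(
      informants_path,
      required = c("informant_id", "age", "gender", "education",
                   "community", "village"), what = "informants file")
    inf$age <- as.integer(inf$age)
    inf$gender <- normalize_token(inf$gender, .genders, .aliases$gender,
                                  "gender")
    inf$education <- normalize_token(inf$education, .educations,
                                     .aliases$education, "education")
    inf$community <- normalize_token(inf$community, .communities,
                                     field = "community")
  }
  ethno_survey(inf, tax, rep, level, n_informants)
}

#' Write a survey to the three-CSV layout
#'
#' Emits `informants.csv`, `taxa.csv` and `use_reports.csv` under `dir`
#' with RFC-4180 quoting; [read_survey()] on the result round-trips all
#' fields.
#'
#' @param ds an `ethno_survey`.
#' @param dir output directory, created if needed.
#' @return the directory path, invisibly.
#' @export
write_survey <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_delim_file(ds$informants, file.path(dir, "informants.csv"))
  write_delim_file(ds$taxa, file.path(dir, "taxa.csv"))
  write_delim_file(ds$reports, file.path(dir, "use_reports.csv"))
  invisible(dir)
}

#' Collapse an informant-level survey to aggregate counts
#'
#' Groups reports by (taxon, category, village) and sums counts; this is
#' the bridge between interview records and the count tables a published
#' survey prints. The total number of use-reports is conserved, and the
#' operation is idempotent on aggregate-level input.
#'
#' @param ds an `ethno_survey`.
#' @return an aggregate-level `ethno_survey` with `n_informants` equal to
#'   the number of distinct informants (or the stored value when already
#'   aggregated).
#' @export
aggregate_survey <- function(ds) {
  rep <- ds$reports
  n <- if (ds$level == "informant_level") {
    length(unique(rep$informant_id[!is.na(rep$informant_id)])) %||% 0L
  } else ds$n_informants
  if (ds$level == "informant_level" && n == 0L) n <- nrow(ds$informants)
  if (nrow(rep)) {
    key <- paste(rep$taxon_id,
                 ifelse(is.na(rep$category), "", rep$category),
                 ifelse(is.na(rep$village), "", rep$village), sep = "\r")
    groups <- split(seq_len(nrow(rep)), key)
    counts <- vapply(groups, function(i) sum(rep$count[i]), numeric(1))
    first <- vapply(groups, function(i) i[[1L]], integer(1))
    agg <- data.frame(informant_id = NA_character_,
                      taxon_id = rep$taxon_id[first],
                      ailment = NA_character_,
                      category = rep$category[first],
                      village = rep$village[first],
                      count = as.integer(counts),
                      stringsAsFactors = FALSE)
    o <- order(agg$taxon_id, agg$category, agg$village, na.last = TRUE)
    agg <- agg[o, ]
    rownames(agg) <- NULL
  } else {
    agg <- empty_reports()
  }
  ethno_survey(empty_informants(), ds$taxa, agg, "aggregate",
               n_informants = max(n, 1L))
}

#' Cross-check recomputed use frequencies against printed values
#'
#' Published tables occasionally print an Fq that is inconsistent with the
#' use-report count it should derive from. This recomputes
#' `Fq = 100 * URs / n` for every row of a printed index table and returns
#' one record per taxon whose recomputed value differs from the printed one
#' by more than 0.01 after 2-decimal rounding. It never raises: the point
#' is to surface discrepancies in the source, not to repair them.
#'
#' @param ds an `ethno_survey` supplying the informant denominator `n`.
#' @param printed data.frame with columns `taxon_id`, `ur_printed`,
#'   `fq_printed`.
#' @return data.frame of discrepancies with the recomputed value and delta.
#' @export
validate_consistency <- function(ds, printed) {
  if (!nrow(printed)) {
    return(data.frame(taxon_id = character(), ur_printed = integer(),
                      fq_printed = numeric(), fq_recomputed = numeric(),
                      delta = numeric(), stringsAsFactors = FALSE))
  }
  fq_re <- round_half_up(100 * as.numeric(printed$ur_printed) /
                           ds$n_informants, 2)
  delta <- fq_re - as.numeric(printed$fq_printed)
  bad <- abs(delta) > 0.01 + 1e-9
  out <- data.frame(taxon_id = printed$taxon_id,
                    ur_printed = as.integer(printed$ur_printed),
                    fq_printed = as.numeric(printed$fq_printed),
                    fq_recomputed = fq_re, delta = delta,
                    stringsAsFactors = FALSE)[bad, ]
  rownames(out) <- NULL
  out
}
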