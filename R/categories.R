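#' Ailment-to-category map
#'
#' A category map translates free-text interview ailments into the fifteen
#' disease-category codes. Lookup is performed on lowercased, trimmed
#' strings; every ailment belongs to exactly one category.
#'
#' @param entries data.frame with columns `ailment`, `category`.
#' @param fallback what to do with an unmapped ailment:
#'   `"unassigned"` leaves the report's category `NA` (with a warning),
#'   `"reject"` raises a categorization error listing the strings.
#' @return object of class `category_map`.
#' @export
category_map <- function(entries, fallback = c("unassigned", "reject")) {
  fallback <- match.arg(fallback)
  entries$ailment <- tolower(trimws(entries$ailment))
  entries$category <- toupper(trimws(entries$category))
  if (any(!(entries$category %in% .cats))) {
    ei_error("ei_validation_error", "unknown category code(s): %s",
             paste(setdiff(entries$category, .cats), collapse = ", "))
  }
  dup <- duplicated(entries$ailment)
  if (any(dup)) {
    ei_error("ei_validation_error",
             "ailment(s) mapped to more than one category: %s",
             paste(unique(entries$ailment[dup]), collapse = ", "))
  }
  structure(list(entries = entries, fallback = fallback),
            class = "category_map")
}

#' @rdname category_map
#' @param path CSV with columns `ailment`, `category`.
#' @export
read_category_map <- function(path, fallback = c("unassigned", "reject")) {
  df <- read_delim_file(path, required = c("ailment", "category"),
                        what = "category map")
  category_map(df, fallback)
}

#' Default ailment-to-category map
#'
#' The map shipped with the package: the ailments recorded in the Kupwara
#' survey (85 normalized entries across the 15 categories). Compound
#' strings such as "constipation/indigestion" are stored as separate
#' entries, and ethnoveterinary uses are namespaced ("veterinary wounds")
#' so that no ailment string is claimed by two categories.
#'
#' @inheritParams category_map
#' @return a `category_map`.
#' @export
default_category_map <- function(fallback = c("unassigned", "reject")) {
  read_category_map(system.file("extdata", "kupwara", "category_map.csv",
                                package = "ethnoindex", mustWork = TRUE),
                    fallback)
}

#' Assign disease categories to use-reports
#'
#' Fills the `category` column of a report table from each report's
#' free-text ailment. Reports whose category is already set are left
#' untouched; counts are never changed.
#'
#' @param reports use-report data.frame (see [ethno_survey()]).
#' @param cmap a [category_map()].
#' @return the report table with categories assigned.
#' @export
assign_categories <- function(reports, cmap) {
  todo <- is.na(reports$category) | !nzchar(reports$category)
  if (!any(todo)) return(reports)
  key <- tolower(trimws(reports$ailment[todo]))
  hit <- cmap$entries$category[match(key, cmap$entries$ailment)]
  if (anyNA(hit)) {
    missing <- unique(reports$ailment[todo][is.na(hit)])
    if (cmap$fallback == "reject") {
      ei_error("ei_categorization_error",
               "unmapped ailment string(s): %s",
               paste(sprintf("'%s'", missing), collapse = ", "))
    }
    warning(sprintf("%d report(s) with unmapped ailment left unassigned: %s",
                    sum(is.na(hit)),
                    paste(sprintf("'%s'", missing), collapse = ", ")),
            call. = FALSE)
  }
  reports$category[todo] <- hit
  reports
}

#' Descriptive profile of the taxon register
#'
#' Tallies the 107-taxon-style descriptive distributions: each taxon is
#' counted exactly once by its annotation on the requested dimension (for
#' `plant_part`, by its first-listed, primary part). Percentages are
#' count / number-of-taxa x 100, rounded half-up to 2 decimals.
#'
#' @param ds an `ethno_survey`.
#' @param dimension one of `life_form`, `plant_part`, `preparation`,
#'   `route`, `nativity`, `taxonomic_group`.
#' @return data.frame of class `ethno_profile` with columns `label`,
#'   `count`, `percent`.
#' @export
profile <- function(ds, dimension = c("life_form", "plant_part",
                                      "preparation", "route", "nativity",
                                      "taxonomic_group")) {
  dimension <- match.arg(dimension)
  tax <- ds$taxa
  labels <- switch(dimension,
    life_form = tax$life_form,
    plant_part = vapply(strsplit(tax$parts_used, ";", fixed = TRUE),
                        `[[`, character(1), 1L),
    preparation = tax$preparation,
    route = tax$route,
    nativity = tax$nativity,
    taxonomic_group = {
      if (is.null(tax$taxonomic_group)) {
        ei_error("ei_validation_error",
                 "taxon register has no taxonomic_group column")
      }
      tax$taxonomic_group
    })
  counts <- sort(table(labels), decreasing = TRUE)
  out <- data.frame(label = names(counts), count = as.integer(counts),
                    percent = round_half_up(100 * as.integer(counts) /
                                              nrow(tax), 2),
                    stringsAsFactors = FALSE)
  attr(out, "dimension") <- dimension
  class(out) <- c("ethno_profile", "data.frame")
  out
}

#' Native versus exotic composition of the register
#'
#' @param ds an `ethno_survey` whose taxa all carry a nativity annotation.
#' @return an `ethno_profile` (counts and percentages of Native/Exotic).
#' @export
nativity_summary <- function(ds) {
  missing <- which(is.na(ds$taxa$nativity))
  if (length(missing)) {
    ei_error("ei_validation_error",
             "taxa without nativity annotation: %s",
             paste(ds$taxa$taxon_id[missing], collapse = ", "))
  }
  profile(ds, "nativity")
}
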