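#' Load the packaged Kupwara survey transcription
#'
#' Returns the published aggregates of the 2017-2020 Kupwara (Kashmir
#' Himalaya) medicinal-plant survey as machine-readable data: the
#' 107-taxon register with its per-category use-report splits as an
#' aggregate [ethno_survey()] (n = 102 informants), plus the printed
#' per-taxon Fq/RI values, the family use-value table, the 15-category
#' consensus table, the per-village site table and the five knowledge
#' contingency tables with their printed test statistics.
#'
#' The transcription is stored as printed, inconsistencies included: a few
#' taxa print an Fq that disagrees with their use-report count (surface
#' them with [validate_consistency()]), the register's per-category splits
#' do not everywhere match the category table's totals, and the register's
#' own column sums to 1632 use-reports while the category table sums to
#' the published total of 1631. The per-taxon administration route is not
#' published and is carried as a uniform `Oral` placeholder.
#'
#' @return list of class `kupwara_fixture` with elements `survey`,
#'   `printed_indices`, `families`, `categories`, `villages`,
#'   `contingency` (named list of `ethno_contingency`),
#'   `contingency_stats` and `constants`.
#' @examples
#' fx <- load_kupwara()
#' fx$survey
#' @export
load_kupwara <- function() {
  dir <- system.file("extdata", "kupwara", package = "ethnoindex",
                     mustWork = TRUE)
  p <- function(f) file.path(dir, f)

  survey <- read_survey(taxa_path = p("taxa.csv"),
                        reports_path = p("use_reports.csv"),
                        level = "aggregate", n_informants = 102L)
  printed <- read_delim_file(p("printed_indices.csv"),
                             required = c("taxon_id", "botanical_name",
                                          "ur_printed", "fq_printed",
                                          "ri_printed"))
  printed$ur_printed <- as.integer(printed$ur_printed)
  printed$fq_printed <- as.numeric(printed$fq_printed)
  printed$ri_printed <- as.numeric(printed$ri_printed)

  families <- read_delim_file(p("table4_families.csv"),
                              required = c("family", "ur_printed",
                                           "uv_printed", "fuv_printed"))
  families[-1] <- lapply(families[-1], as.numeric)

  categories <- read_delim_file(p("table5_categories.csv"),
                                required = c("category", "label", "n_t",
                                             "pct_nt_printed", "n_ur",
                                             "pct_nur_printed",
                                             "icf_printed"))
  categories$n_t <- as.integer(categories$n_t)
  categories$n_ur <- as.integer(categories$n_ur)
  categories$icf_printed <- as.numeric(categories$icf_printed)

  villages <- read_delim_file(p("table1_villages.csv"),
                              required = c("village", "informants",
                                           "use_reports", "taxa_identified",
                                           "rf_printed"))
  villages[-1] <- lapply(villages[-1], as.numeric)

  cont_raw <- read_delim_file(p("table2_contingency.csv"),
                              required = c("factor", "row_label",
                                           "le_count", "gt_count"))
  cont_raw$le_count <- as.integer(cont_raw$le_count)
  cont_raw$gt_count <- as.integer(cont_raw$gt_count)
  contingency <- lapply(split(cont_raw, cont_raw$factor), function(d)
    contingency_table(d, factor = d$factor[1]))

  stats_tab <- read_delim_file(p("table2_stats.csv"),
                               required = c("factor", "chisq_printed",
                                            "p_printed"))
  stats_tab[-1] <- lapply(stats_tab[-1], as.numeric)

  fx <- structure(list(
    survey = survey, printed_indices = printed, families = families,
    categories = categories, villages = villages,
    contingency = contingency, contingency_stats = stats_tab,
    constants = list(n_informants = 102L, n_taxa = 107L,
                     total_use_reports = 1631L)),
    class = "kupwara_fixture")

  # integrity guard on the packaged files
  ok <- nrow(survey$taxa) == 107L &&
    nrow(categories) == 15L &&
    sum(categories$n_ur) == 1631L &&
    sum(contingency$education$counts) == 102L &&
    sum(contingency$age_category$counts) == 102L &&
    nrow(villages) == 8L
  if (!ok) {
    ei_error("ei_integrity_error",
             "packaged fixture failed its integrity checksums")
  }
  fx
}

#' @export
print.kupwara_fixture <- function(x, ...) {
  cat("Kupwara survey transcription\n")
  print(x$survey)
  cat(sprintf("category table: %d categories, %d use-reports\n",
              nrow(x$categories), sum(x$categories$n_ur)))
  invisible(x)
}
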