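#' Run the full survey analysis pipeline
#'
#' Categorization, indices and (when the data are informant-level) the
#' demographic association tests, written out as CSVs plus a plain-text
#' summary. Warnings raised along the way (undefined ICF, low expected
#' counts, printed-value discrepancies) are collected into a structured
#' log rather than changing the outcome; only structural errors abort.
#' The pipeline is deterministic: identical inputs give byte-identical
#' outputs.
#'
#' @param ds an `ethno_survey`.
#' @param out_dir output directory, created if needed; `NULL` computes
#'   without writing.
#' @param cmap [category_map()] used to fill missing report categories.
#' @param threshold knowledge dichotomization threshold.
#' @param printed optional printed index table for the consistency check
#'   (see [validate_consistency()]).
#' @param ri_annotations optional PH/BS table for [relative_importance()].
#' @param top size of the "top taxa" listing in the summary.
#' @return list with the computed tables, the summary lines and the
#'   warning log, invisibly when writing.
#' @export
run_full_analysis <- function(ds, out_dir = NULL, cmap = default_category_map(),
                              threshold = 5L, printed = NULL,
                              ri_annotations = NULL, top = 5L) {
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  catch <- function(expr) withCallingHandlers(expr, warning = function(w) {
    note("warning: %s", conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  ds$reports <- catch(assign_categories(ds$reports, cmap))
  uv <- use_value(ds)
  fuv <- family_use_value(ds)
  consensus <- catch(icf(ds))
  if (any(!consensus$defined)) {
    note("ICF undefined for category(ies): %s",
         paste(consensus$category[!consensus$defined], collapse = ", "))
  }
  rf <- catch(relative_frequency(ds))
  profiles <- lapply(c(life_form = "life_form", plant_part = "plant_part",
                       preparation = "preparation", nativity = "nativity"),
                     function(d) profile(ds, d))
  ri <- if (!is.null(ri_annotations)) relative_importance(ri_annotations)

  assoc <- NULL
  if (ds$level == "informant_level" && nrow(ds$informants)) {
    assoc <- lapply(c("gender", "community", "education", "age_category"),
                    function(f) {
      tab <- dichotomize_knowledge(ds, f, threshold = threshold,
                                   drop_empty = TRUE)
      res <- catch(chi_square(tab))
      data.frame(factor = f, statistic = res$statistic, df = res$df,
                 p_value = res$p_value, stringsAsFactors = FALSE)
    })
    assoc <- do.call(rbind, assoc)
  }
  discrepancies <- NULL
  if (!is.null(printed)) {
    discrepancies <- validate_consistency(ds, printed)
    if (nrow(discrepancies)) {
      note("printed Fq disagrees with use-reports for %d taxa: %s",
           nrow(discrepancies),
           paste(discrepancies$taxon_id, collapse = ", "))
    }
  }

  defined <- consensus$icf[consensus$defined]
  top_uv <- rank_report(uv, "ur_total", top)
  summary_lines <- c(
    sprintf("taxa: %d  families: %d  informants: %d  use-reports: %d",
            nrow(ds$taxa), length(unique(ds$taxa$family)),
            ds$n_informants, total_use_reports(ds)),
    if (length(defined))
      sprintf("ICF range: %.2f-%.2f", round_half_up(min(defined), 2),
              round_half_up(max(defined), 2)),
    sprintf("top taxa by use-reports: %s",
            paste(sprintf("%s (%d)", top_uv$botanical_name,
                          top_uv$ur_total), collapse = ", ")),
    sprintf("top families by FUV: %s",
            paste(sprintf("%s (%.2f)",
                          utils::head(fuv$family, top),
                          round_half_up(utils::head(fuv$fuv, top), 2)),
                  collapse = ", ")))

  result <- list(use_value = uv, family_use_value = fuv, icf = consensus,
                 relative_frequency = rf, profiles = profiles,
                 relative_importance = ri, association = assoc,
                 discrepancies = discrepancies, summary = summary_lines,
                 log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_delim_file(uv, file.path(out_dir, "taxon_indices.csv"))
    write_delim_file(fuv, file.path(out_dir, "family_fuv.csv"))
    write_delim_file(consensus, file.path(out_dir, "category_icf.csv"))
    if (nrow(rf)) write_delim_file(rf, file.path(out_dir, "village_rf.csv"))
    if (!is.null(assoc))
      write_delim_file(assoc, file.path(out_dir, "association.csv"))
    if (!is.null(ri))
      write_delim_file(ri, file.path(out_dir, "taxon_ri.csv"))
    writeLines(c(summary_lines, "", "log:", log),
               file.path(out_dir, "summary.txt"))
    return(invisible(result))
  }
  result
}

#' Command-line entry point
#'
#' Subcommands: `indices` (aggregate or informant surveys in the
#' three-CSV layout), `simulate` (write a generated survey), `validate`
#' (consistency check against a printed index table). Used by the
#' `inst/cli/ethnoindex.R` launcher; callable directly for testing.
#'
#' @param args character vector, as from `commandArgs(trailingOnly=TRUE)`.
#' @return exit status, 0 on success.
#' @export
ethnoindex_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ethnoindex <indices|simulate|validate> [options]",
    "  indices  --taxa F --reports F [--informants F] [--level L]",
    "           [--n-informants N] [--category-map F] --out DIR",
    "  simulate --seed N --n-informants N --out DIR",
    "  validate --taxa F --reports F --n-informants N --printed F",
    sep = "\n")
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  if (!length(args)) { message(usage); return(1L) }
  cmd <- args[1L]
  status <- tryCatch({
    if (cmd == "indices") {
      level <- opt("level", "aggregate")
      ds <- read_survey(taxa_path = opt("taxa"),
                        reports_path = opt("reports"),
                        informants_path = opt("informants"),
                        level = level,
                        n_informants = as.integer(opt("n-informants", "0")))
      cm <- if (!is.null(opt("category-map")))
        read_category_map(opt("category-map")) else default_category_map()
      res <- run_full_analysis(ds, out_dir = opt("out"), cmap = cm)
      writeLines(res$summary)
      0L
    } else if (cmd == "simulate") {
      cfg <- generator_config(
        seed = as.integer(opt("seed", "1")),
        n_informants = as.integer(opt("n-informants", "102")))
      write_survey(generate_survey(cfg), opt("out"))
      0L
    } else if (cmd == "validate") {
      ds <- read_survey(taxa_path = opt("taxa"),
                        reports_path = opt("reports"),
                        level = "aggregate",
                        n_informants = as.integer(opt("n-informants")))
      printed <- utils::read.csv(opt("printed"), stringsAsFactors = FALSE)
      d <- validate_consistency(ds, printed)
      if (nrow(d)) {
        message(sprintf("%d discrepancy(ies):", nrow(d)))
        message(paste(utils::capture.output(print(d)), collapse = "\n"))
      } else message("no discrepancies")
      0L
    } else {
      message(usage)
      1L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
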