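#' Use value (UV) and use frequency (Fq) per taxon
#'
#' `UV = sum(U) / n`: the total number of use-reports a taxon received,
#' divided by the number of informants `n`. U counts use-reports, not
#' distinct informants, so a taxon cited by one informant for two disease
#' categories contributes 2. `Fq` is the same quantity as a percentage
#' (`100 * UV`), rounded half-up to 2 decimals for display; the unrounded
#' `uv` is retained. Taxa that were never cited get `uv = 0`.
#'
#' @param ds an `ethno_survey` with `n_informants >= 1`.
#' @return data.frame with one row per register taxon: `taxon_id`,
#'   `botanical_name`, `ur_total`, `uv`, `fq_percent`.
#' @export
use_value <- function(ds) {
  if (is.na(ds$n_informants) || ds$n_informants < 1L) {
    ei_error("ei_domain_error",
             "use value is undefined for n_informants = 0")
  }
  ur <- tapply(ds$reports$count, ds$reports$taxon_id, sum)
  tot <- as.integer(ur[match(ds$taxa$taxon_id, names(ur))])
  tot[is.na(tot)] <- 0L
  uv <- tot / ds$n_informants
  data.frame(taxon_id = ds$taxa$taxon_id,
             botanical_name = ds$taxa$botanical_name,
             ur_total = tot, uv = uv,
             fq_percent = round_half_up(100 * uv, 2),
             stringsAsFactors = FALSE)
}

#' Per-village relative frequency (Rf)
#'
#' The share of the study's taxa that were cited at least once in each
#' village: `Rf = 100 * taxa_cited / total_taxa`. Reports without a
#' village label are excluded. Alternatively a pre-tabulated count of
#' distinct taxa per village (as printed in a survey's site table) can be
#' supplied directly.
#'
#' @param ds an `ethno_survey`; ignored when `village_counts` is given.
#' @param village_counts optional named integer vector, village ->
#'   distinct taxa cited there.
#' @param n_taxa total taxa in the study; defaults to the register size.
#' @return data.frame with `village`, `taxa_cited`, `rf_percent`.
#' @export
relative_frequency <- function(ds = NULL, village_counts = NULL,
                               n_taxa = NULL) {
  if (is.null(village_counts)) {
    rep <- ds$reports
    keep <- !is.na(rep$village) & nzchar(rep$village)
    if (!any(keep)) {
      warning("no village-annotated reports; empty relative frequency",
              call. = FALSE)
      return(data.frame(village = character(), taxa_cited = integer(),
                        rf_percent = numeric(), stringsAsFactors = FALSE))
    }
    rep <- rep[keep, ]
    village_counts <- vapply(split(rep$taxon_id, rep$village),
                             function(x) length(unique(x)), integer(1))
    n_taxa <- n_taxa %||% nrow(ds$taxa)
  } else if (is.null(n_taxa)) {
    ei_error("ei_domain_error",
             "n_taxa is required with pre-tabulated village counts")
  }
  data.frame(village = names(village_counts),
             taxa_cited = as.integer(village_counts),
             rf_percent = round_half_up(
               100 * as.integer(village_counts) / n_taxa, 2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Family use value (FUV)
#'
#' `FUV = sum(UV_s) / ns`: the mean use value over the `ns` taxa of a
#' botanical family. Families whose members are uniformly popular score as
#' high as their members; a single blockbuster taxon is diluted by quiet
#' congeners.
#'
#' @param ds an `ethno_survey`.
#' @return data.frame with `family`, `ns`, `ur_total`, `uv_sum`, `fuv`,
#'   sorted by decreasing `fuv`.
#' @export
family_use_value <- function(ds) {
  uvt <- use_value(ds)
  fam <- ds$taxa$family[match(uvt$taxon_id, ds$taxa$taxon_id)]
  sp <- split(seq_len(nrow(uvt)), fam)
  out <- data.frame(
    family = names(sp),
    ns = lengths(sp),
    ur_total = vapply(sp, function(i) sum(uvt$ur_total[i]), numeric(1)),
    uv_sum = vapply(sp, function(i) sum(uvt$uv[i]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out$fuv <- out$uv_sum / out$ns
  out[order(-out$fuv, out$family), , drop = FALSE]
}

#' Informant consensus factor (ICF)
#'
#' `ICF = (N_ur - N_t) / (N_ur - 1)` per disease category, where `N_ur` is
#' the number of use-reports in the category and `N_t` the number of
#' distinct taxa cited for it. ICF approaches 1 when many citations
#' concentrate on few taxa (high informant agreement) and is 0 when every
#' citation names a different taxon. With fewer than two use-reports the
#' formula divides by zero; such categories are returned with `icf = NA`
#' and flagged `defined = FALSE`.
#'
#' @param ds an `ethno_survey` with categorized reports. Uncategorized
#'   reports are ignored with a warning.
#' @return data.frame with `category`, `n_t`, `n_ur`, `icf`, `defined`.
#' @export
icf <- function(ds) {
  rep <- ds$reports
  drop <- is.na(rep$category) | !nzchar(rep$category)
  if (any(drop)) {
    warning(sprintf("%d uncategorized report(s) ignored in ICF", sum(drop)),
            call. = FALSE)
    rep <- rep[!drop, ]
  }
  cats <- intersect(.cats, unique(rep$category))
  n_ur <- vapply(cats, function(cc) sum(rep$count[rep$category == cc]),
                 numeric(1))
  n_t <- vapply(cats, function(cc)
    length(unique(rep$taxon_id[rep$category == cc])), integer(1))
  icf_from_counts(n_t, as.integer(n_ur), cats)
}

#' @rdname icf
#' @param n_t integer vector of distinct taxa per category.
#' @param n_ur integer vector of use-report counts per category.
#' @param category optional category codes for the rows.
#' @export
icf_from_counts <- function(n_t, n_ur, category = NULL) {
  n_t <- as.integer(n_t); n_ur <- as.integer(n_ur)
  if (any(n_ur >= 1L & n_t > n_ur)) {
    ei_error("ei_domain_error", "N_t cannot exceed N_ur")
  }
  defined <- n_ur >= 2L
  val <- ifelse(defined, (n_ur - n_t) / pmax(n_ur - 1L, 1L), NA_real_)
  data.frame(category = category %||% paste0("C", seq_along(n_t)),
             n_t = n_t, n_ur = n_ur, icf = val, defined = defined,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Relative importance (RI)
#'
#' Versatility score combining how many pharmacological functions (PH) a
#' taxon is credited with and how many body systems (BS) it treats, each
#' normalized by the study-wide maximum:
#' `RI = 100 * (PH/max(PH) + BS/max(BS)) / 2`. The taxon holding both
#' maxima scores exactly 100; scores live in (0, 100]. PH/BS counts are an
#' explicit annotation table because they are rarely published per taxon.
#'
#' @param annotations data.frame with columns `taxon_id`, `ph`, `bs`
#'   (positive integers).
#' @return data.frame with `taxon_id`, `ph`, `bs`, `rel_ph`, `rel_bs`,
#'   `ri`.
#' @export
relative_importance <- function(annotations) {
  if (!nrow(annotations)) {
    ei_error("ei_domain_error", "empty RI annotation table")
  }
  ph <- as.numeric(annotations$ph); bs <- as.numeric(annotations$bs)
  if (any(is.na(ph) | is.na(bs) | ph < 1 | bs < 1)) {
    ei_error("ei_domain_error", "RI requires ph >= 1 and bs >= 1")
  }
  data.frame(taxon_id = annotations$taxon_id, ph = ph, bs = bs,
             rel_ph = ph / max(ph), rel_bs = bs / max(bs),
             ri = 100 * (ph / max(ph) + bs / max(bs)) / 2,
             stringsAsFactors = FALSE)
}

#' Rank an index table
#'
#' Stable descending sort on a numeric index column, ties broken by
#' botanical name (or the first character column) ascending; reproduces
#' the "top-most taxa" listings of survey reports.
#'
#' @param rows an index-row data.frame.
#' @param key name of the numeric column to rank by.
#' @param top number of rows to keep (default all).
#' @return the reordered (and truncated) data.frame.
#' @export
rank_report <- function(rows, key, top = nrow(rows)) {
  if (!key %in% names(rows)) {
    ei_error("ei_usage_error", "unknown ranking key '%s'", key)
  }
  tie_col <- intersect(c("botanical_name", "family", "category", "village",
                         "taxon_id"), names(rows))[1]
  tie <- if (is.na(tie_col)) seq_len(nrow(rows)) else rows[[tie_col]]
  out <- rows[order(-rows[[key]], tie), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, max(top, 0L))
}
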