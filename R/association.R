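#' Dichotomize informant knowledge into an r x 2 contingency table
#'
#' Per informant, knowledge is the number of *distinct* taxa cited.
#' Informants are split at the threshold (column classes `<=5` / `>5` by
#' default) and cross-tabulated against a demographic factor. The
#' education factor folds Postgraduate into Graduate (the convention of
#' six-row survey tables); `age_category` uses the bins `<=30`, `31-40`,
#' ..., `71-80`.
#'
#' @param ds an informant-level `ethno_survey`. Aggregate datasets cannot
#'   be dichotomized (per-informant distinct-taxon counts are lost) and
#'   raise a capability error; use [contingency_table()] on a
#'   pre-tabulated table instead.
#' @param factor one of `gender`, `place`, `community`, `education`,
#'   `age_category`.
#' @param threshold knowledge split point (default 5 distinct taxa).
#' @param drop_empty drop factor levels with no informants (default keeps
#'   all canonical levels).
#' @return an `ethno_contingency` object.
#' @export
dichotomize_knowledge <- function(ds, factor = c("gender", "place",
                                                 "community", "education",
                                                 "age_category"),
                                  threshold = 5L, drop_empty = FALSE) {
  factor <- match.arg(factor)
  if (ds$level != "informant_level" || !nrow(ds$informants)) {
    ei_error("ei_capability_error", paste(
      "dichotomization needs informant-level data;",
      "supply a pre-tabulated table via contingency_table()"))
  }
  inf <- ds$informants
  rep <- ds$reports
  k <- vapply(split(rep$taxon_id, rep$informant_id),
              function(x) length(unique(x)), integer(1))
  knowledge <- as.integer(k[match(inf$informant_id, names(k))])
  knowledge[is.na(knowledge)] <- 0L

  lev_val <- switch(factor,
    gender = factor(inf$gender, levels = .genders),
    place = factor(inf$village, levels = sort(unique(inf$village))),
    community = factor(inf$community, levels = .communities),
    education = {
      e <- ifelse(inf$education == "Postgraduate", "Graduate",
                  inf$education)
      factor(e, levels = setdiff(.educations, "Postgraduate"))
    },
    age_category = cut(inf$age, breaks = .age_breaks, labels = .age_labels))

  le <- tapply(knowledge <= threshold, lev_val, sum, default = 0L)
  gt <- tapply(knowledge > threshold, lev_val, sum, default = 0L)
  counts <- cbind(le, gt)
  if (drop_empty) counts <- counts[rowSums(counts) > 0L, , drop = FALSE]
  contingency_table(counts, factor = factor, threshold = threshold)
}

#' Construct a contingency table of knowledge classes
#'
#' @param counts r x 2 integer matrix (rows = factor levels, columns =
#'   informants reporting at most / more than `threshold` taxa), with row
#'   names, or a data.frame `row_label, le_count, gt_count`.
#' @param factor label of the demographic factor.
#' @param threshold the dichotomization threshold the columns encode.
#' @return an `ethno_contingency` object.
#' @export
contingency_table <- function(counts, factor = "custom", threshold = 5L) {
  if (is.data.frame(counts)) {
    m <- as.matrix(counts[, c("le_count", "gt_count")])
    rownames(m) <- counts$row_label
    counts <- m
  }
  storage.mode(counts) <- "integer"
  if (ncol(counts) != 2L || nrow(counts) < 2L) {
    ei_error("ei_validation_error",
             "contingency table must be r x 2 with r >= 2")
  }
  if (any(counts < 0L)) {
    ei_error("ei_validation_error", "negative cell counts")
  }
  colnames(counts) <- paste0(c("<=", ">"), threshold)
  structure(list(factor = factor, counts = counts,
                 threshold = as.integer(threshold)),
            class = "ethno_contingency")
}

#' @export
print.ethno_contingency <- function(x, ...) {
  cat(sprintf("knowledge contingency table (factor: %s)\n", x$factor))
  print(x$counts)
  invisible(x)
}

#' Pearson chi-square test on a knowledge contingency table
#'
#' The plain Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the row/column marginals and no continuity correction; the
#' p-value is the upper tail of the chi-square distribution with
#' `(r - 1)(c - 1)` degrees of freedom. A warning (not an error) is
#' emitted when any expected count falls below 5.
#'
#' @param table an `ethno_contingency` (or bare r x 2 matrix).
#' @return list of class `ethno_chisq`: `statistic`, `df`, `p_value`,
#'   `expected`.
#' @export
chi_square <- function(table) {
  m <- if (inherits(table, "ethno_contingency")) table$counts else table
  m <- as.matrix(m)
  if (sum(m) < 1L) {
    ei_error("ei_validation_error", "all-zero contingency table")
  }
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0L) || any(cs == 0L)) {
    ei_error("ei_degenerate_table_error",
             "zero row or column marginal; drop the empty level(s) first")
  }
  expected <- outer(rs, cs) / sum(m)
  if (any(expected < 5)) {
    warning("expected count below 5 in at least one cell; ",
            "chi-square approximation may be inaccurate", call. = FALSE)
  }
  stat <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 expected = expected),
            class = "ethno_chisq")
}

#' @export
print.ethno_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X^2 = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Age-knowledge linear regression
#'
#' Ordinary least squares of relative knowledge (total use-reports per
#' informant) on age, with the Pearson correlation and its two-sided
#' p-value, optionally per gender stratum. Strata with fewer than three
#' informants are returned flagged undefined.
#'
#' @param ds an informant-level `ethno_survey`.
#' @param stratify_by_gender also fit within the F and M strata.
#' @return data.frame with one row per stratum: `stratum`, `n`,
#'   `pearson_r`, `slope`, `intercept`, `p_value`, `defined`.
#' @export
knowledge_age_regression <- function(ds, stratify_by_gender = TRUE) {
  if (ds$level != "informant_level" || !nrow(ds$informants)) {
    ei_error("ei_capability_error",
             "age-knowledge regression needs informant-level data")
  }
  inf <- ds$informants
  tot <- vapply(split(ds$reports$count, ds$reports$informant_id), sum,
                numeric(1))
  y_all <- as.numeric(tot[match(inf$informant_id, names(tot))])
  y_all[is.na(y_all)] <- 0

  fit_one <- function(stratum, idx) {
    x <- inf$age[idx]; y <- y_all[idx]
    n <- length(idx)
    if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(stratum = stratum, n = n, pearson_r = NA_real_,
                        slope = NA_real_, intercept = NA_real_,
                        p_value = NA_real_, defined = FALSE,
                        stringsAsFactors = FALSE))
    }
    b <- stats::cov(x, y) / stats::var(x)
    a <- mean(y) - b * mean(x)
    r <- stats::cor(x, y)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
    data.frame(stratum = stratum, n = n, pearson_r = r, slope = b,
               intercept = a, p_value = p, defined = TRUE,
               stringsAsFactors = FALSE)
  }
  out <- fit_one("all", seq_len(nrow(inf)))
  if (stratify_by_gender) {
    out <- rbind(fit_one("F", which(inf$gender == "F")),
                 fit_one("M", which(inf$gender == "M")), out)
  }
  rownames(out) <- NULL
  out
}
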