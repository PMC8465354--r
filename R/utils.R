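#' Round half away from zero
#'
#' Presentation rounding used for printed percentages and index values.
#' Base `round()` rounds half to even; published survey tables round half
#' up, so 0.845 must print as 0.85.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# classed conditions so callers can distinguish failure modes
ei_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "ethnoindex_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = NULL)))
}

# auto-detect comma vs tab delimiter from the header line
detect_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) return(",")
  if (lengths(regmatches(header, gregexpr("\t", header))) >
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

read_delim_file <- function(path, required, optional = character(),
                            what = basename(path)) {
  if (!file.exists(path)) {
    ei_error("ei_io_error", "file not found: %s", path)
  }
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          quote = "\"", stringsAsFactors = FALSE,
                          comment.char = "", colClasses = "character",
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    ei_error("ei_schema_error", "%s: missing required column(s): %s",
             what, paste(missing, collapse = ", "))
  }
  df[intersect(c(required, optional), names(df))]
}

write_delim_file <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
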