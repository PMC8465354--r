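# Small in-code fixtures and independent oracles used across the suite.

toy_taxa <- function(n = 3, families = NULL) {
  data.frame(
    taxon_id = sprintf("t%02d", seq_len(n)),
    botanical_name = sprintf("Species %02d", seq_len(n)),
    family = families %||% rep("Famae", n),
    life_form = rep_len(c("Herb", "Shrub"), n),
    parts_used = rep_len(c("Leaf", "Root;Leaf"), n),
    preparation = rep_len(c("Powder", "Decoction"), n),
    route = "Oral",
    nativity = rep_len(c("Native", "Exotic"), n),
    voucher = sprintf("V%02d", seq_len(n)),
    stringsAsFactors = FALSE)
}

toy_informants <- function(n = 4) {
  data.frame(
    informant_id = sprintf("i%02d", seq_len(n)),
    age = seq(25, by = 10, length.out = n),
    gender = rep_len(c("F", "M"), n),
    education = rep_len(c("Illiterate", "Middle"), n),
    community = rep_len(c("Dard", "Gujjar", "Kashmiri"), n),
    village = rep_len(c("VillageA", "VillageB"), n),
    stringsAsFactors = FALSE)
}

# informant-level survey: each row of `cites` is informant, taxon, category
toy_survey <- function(cites, n_taxa = 3, n_inf = 4, village = NULL) {
  inf <- toy_informants(n_inf)
  reports <- data.frame(
    informant_id = cites$informant_id,
    taxon_id = cites$taxon_id,
    ailment = cites$ailment %||% NA_character_,
    category = cites$category %||% NA_character_,
    village = village %||% inf$village[match(cites$informant_id,
                                             inf$informant_id)],
    count = 1L, stringsAsFactors = FALSE)
  ethno_survey(inf, toy_taxa(n_taxa), reports, "informant_level")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles (explicit loops, no shared code path) ----------

oracle_icf <- function(n_ur, n_t) {
  out <- numeric(length(n_ur))
  for (i in seq_along(n_ur)) {
    out[i] <- if (n_ur[i] >= 2) (n_ur[i] - n_t[i]) / (n_ur[i] - 1) else NA
  }
  out
}

oracle_ri <- function(ph, bs) {
  mph <- max(ph); mbs <- max(bs)
  out <- numeric(length(ph))
  for (i in seq_along(ph)) {
    out[i] <- (ph[i] / mph + bs[i] / mbs) / 2 * 100
  }
  out
}

oracle_chisq_stat <- function(m) {
  total <- sum(m); stat <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- sum(m[i, ]) * sum(m[, j]) / total
      stat <- stat + (m[i, j] - e)^2 / e
    }
  }
  stat
}

# permutation oracle: expand the table to one unit per informant, shuffle
# the knowledge-class labels, re-tabulate
oracle_perm_pvalue <- function(m, n_perm = 10000) {
  rows <- rep(seq_len(nrow(m)), rowSums(m))
  cls <- unlist(lapply(seq_len(nrow(m)),
                       function(i) rep(seq_len(ncol(m)), m[i, ])))
  obs <- oracle_chisq_stat(m)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- table(factor(rows, seq_len(nrow(m))),
                  factor(sample(cls), seq_len(ncol(m))))
    if (oracle_chisq_stat(perm) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}
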