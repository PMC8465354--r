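#' Configuration for the interview simulator
#'
#' Describes the world the generator draws from. The defaults restate the
#' Kupwara survey's design: 102 informants aged 21-80 across eight
#' villages, a 25/77 female/male split, the printed education and
#' community margins, 107 taxa in 52 families, and a log-linear
#' distinct-taxa knowledge model in which knowledge grows with age,
#' shrinks with schooling, and is highest among the nomadic Gujjar
#' community. Taxon popularity and per-taxon ailment profiles are
#' Dirichlet draws; small concentrations give the Zipf-like skew real
#' citation tables show.
#'
#' @param seed integer RNG seed; the generator is deterministic given it.
#' @param n_informants,n_taxa,n_families survey dimensions
#'   (`n_taxa >= n_families`).
#' @param villages named numeric vector of sampling weights.
#' @param gender_split probability an informant is female.
#' @param age_range inclusive integer age bounds.
#' @param education_probs probabilities over the seven education levels.
#' @param community_probs probabilities over Dard, Gujjar, Kashmiri.
#' @param knowledge_model list with `base_rate` (mean distinct taxa for
#'   the reference informant: age 50, Middle education, Dard), `age_coef`
#'   (log-scale effect per decade), `education_coef` (per level) and
#'   `community_offsets` (length 3).
#' @param taxon_popularity Dirichlet concentration for taxon popularity;
#'   small values give few blockbuster taxa.
#' @param category_profile_sharpness Dirichlet concentration of each
#'   taxon's distribution over the 15 disease categories; small values
#'   make taxa near-monothematic.
#' @param reports_per_taxon_mean mean use-reports an informant contributes
#'   for each taxon they know (>= 1).
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(
    seed = 1L,
    n_informants = 102L,
    n_taxa = 107L,
    n_families = 52L,
    villages = c("Chota Bungus" = 7, "Ringbala" = 8, "Indradhook" = 21,
                 "Dudi" = 12, "Machil" = 8, "Lalpora" = 16, "Warnow" = 18,
                 "Chuntiwari" = 12) / 102,
    gender_split = 25 / 102,
    age_range = c(21L, 80L),
    education_probs = c(25, 18, 24, 9, 17, 6, 3) / 102,
    community_probs = c(35, 21, 46) / 102,
    knowledge_model = list(base_rate = 5, age_coef = 0.3,
                           education_coef = -0.2,
                           community_offsets = c(Dard = 0, Gujjar = 0.25,
                                                 Kashmiri = -0.05)),
    taxon_popularity = 0.3,
    category_profile_sharpness = 0.3,
    reports_per_taxon_mean = 3) {
  cfg <- list(seed = as.integer(seed),
              n_informants = as.integer(n_informants),
              n_taxa = as.integer(n_taxa),
              n_families = as.integer(n_families),
              villages = villages, gender_split = gender_split,
              age_range = as.integer(age_range),
              education_probs = education_probs,
              community_probs = community_probs,
              knowledge_model = knowledge_model,
              taxon_popularity = taxon_popularity,
              category_profile_sharpness = category_profile_sharpness,
              reports_per_taxon_mean = reports_per_taxon_mean)
  ok <- function(p) abs(sum(p) - 1) < 1e-9 && all(p >= 0)
  if (!ok(cfg$villages) || !ok(cfg$education_probs) ||
      !ok(cfg$community_probs)) {
    ei_error("ei_config_error", "probability vectors must sum to 1")
  }
  if (length(cfg$education_probs) != 7L ||
      length(cfg$community_probs) != 3L ||
      length(cfg$knowledge_model$community_offsets) != 3L) {
    ei_error("ei_config_error", "probability/offset vectors of wrong length")
  }
  if (cfg$n_taxa < cfg$n_families || cfg$n_informants < 1L ||
      cfg$taxon_popularity <= 0 || cfg$category_profile_sharpness <= 0 ||
      cfg$reports_per_taxon_mean < 1) {
    ei_error("ei_config_error", "infeasible generator dimensions or rates")
  }
  km <- cfg$knowledge_model
  ages <- cfg$age_range[1]:cfg$age_range[2]
  mu_mean <- km$base_rate *
    mean(exp(km$age_coef * (ages - 50) / 10)) *
    sum(cfg$education_probs * exp(km$education_coef * (1:7 - 3))) *
    sum(cfg$community_probs * exp(km$community_offsets))
  if (mu_mean > cfg$n_taxa) {
    ei_error("ei_config_error",
             "expected knowledge mean (%.1f) exceeds the taxon pool (%d)",
             mu_mean, cfg$n_taxa)
  }
  structure(cfg, class = "generator_config")
}

# one representative free-text ailment per category, matching the default
# category map so that assign_categories() round-trips generated data
.rep_ailments <- c(GAS = "diarrhea", CAR = "heart disorders",
                   DER = "eczema", GYN = "menstrual problem",
                   NER = "anxiety", PAR = "antihelminthic",
                   CAN = "cancer", RES = "asthma", SKE = "arthritis",
                   MET = "diabetes", ETH = "veterinary wounds",
                   EY = "tonic", ENT = "toothache", FVR = "malaria",
                   IB = "insect bite")

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(k, 1L)] <- 1
  g / sum(g)
}

# Poisson truncated at >= 1 (every interviewed informant cited something),
# capped at the number of taxa
rtrunc_pois <- function(mu, cap) {
  k <- stats::rpois(length(mu), mu)
  for (it in 1:100) {
    z <- k == 0L
    if (!any(z)) break
    k[z] <- stats::rpois(sum(z), mu[z])
  }
  pmin(pmax(k, 1L), cap)
}

#' Simulate an informant-level survey
#'
#' Draws a complete interview dataset with the statistical structure the
#' downstream analysis assumes. The pseudo-random draw order is fixed and
#' documented -- demographics, then knowledge counts, then the taxon
#' register, popularity weights and category profiles, then the
#' per-informant reports -- so adding draws at a later stage never
#' reshuffles earlier ones under the same seed.
#'
#' Each informant's distinct-taxa count is Poisson with log-linear mean in
#' age (per decade, centred at 50), education level (centred at Middle)
#' and community, truncated at 1; the taxa they cite are drawn without
#' replacement by popularity weight; every known taxon then yields
#' `1 + Poisson(reports_per_taxon_mean - 1)` use-reports whose categories
#' follow that taxon's Dirichlet profile. Families partition the register
#' with a skewed size distribution (a few large families, many monotypic).
#'
#' @param cfg a [generator_config()].
#' @return an informant-level `ethno_survey` that passes
#'   [validate_survey()].
#' @export
generate_survey <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n_informants

  # 1. demographics
  inf <- data.frame(
    informant_id = sprintf("i%04d", seq_len(n)),
    age = sample(cfg$age_range[1]:cfg$age_range[2], n, replace = TRUE),
    gender = ifelse(stats::runif(n) < cfg$gender_split, "F", "M"),
    education = sample(.educations, n, replace = TRUE,
                       prob = cfg$education_probs),
    community = sample(.communities, n, replace = TRUE,
                       prob = cfg$community_probs),
    village = sample(names(cfg$villages), n, replace = TRUE,
                     prob = cfg$villages),
    stringsAsFactors = FALSE)

  # 2. knowledge counts (distinct taxa per informant)
  km <- cfg$knowledge_model
  edu_idx <- match(inf$education, .educations)
  log_mu <- log(km$base_rate) +
    km$age_coef * (inf$age - 50) / 10 +
    km$education_coef * (edu_idx - 3) +
    km$community_offsets[match(inf$community, .communities)]
  k <- rtrunc_pois(exp(log_mu), cfg$n_taxa)

  # 3. taxon register: one taxon per family, remainder by skewed weights
  fam_names <- sprintf("Family%02d", seq_len(cfg$n_families))
  fam_w <- stats::rgamma(cfg$n_families, shape = 0.4, rate = 1) + 1e-6
  fam <- c(fam_names,
           sample(fam_names, cfg$n_taxa - cfg$n_families, replace = TRUE,
                  prob = fam_w))
  tax <- data.frame(
    taxon_id = sprintf("t%03d", seq_len(cfg$n_taxa)),
    botanical_name = sprintf("Genus species%03d", seq_len(cfg$n_taxa)),
    family = fam,
    life_form = sample(.life_forms, cfg$n_taxa, replace = TRUE,
                       prob = c(77, 13, 13, 3, 1) / 107),
    parts_used = sample(.plant_parts, cfg$n_taxa, replace = TRUE),
    preparation = sample(.preparations, cfg$n_taxa, replace = TRUE,
                         prob = c(43, 24, 14, 16, 10) / 107),
    route = sample(.routes, cfg$n_taxa, replace = TRUE,
                   prob = c(0.85, 0.10, 0.03, 0.02)),
    nativity = sample(.nativities, cfg$n_taxa, replace = TRUE,
                      prob = c(69, 38) / 107),
    voucher = sprintf("SYN%04d", seq_len(cfg$n_taxa)),
    stringsAsFactors = FALSE)

  # 4. popularity weights and per-taxon category profiles
  pop <- rdirichlet1(cfg$n_taxa, cfg$taxon_popularity)
  prof <- t(vapply(seq_len(cfg$n_taxa), function(i)
    rdirichlet1(length(.cats), cfg$category_profile_sharpness),
    numeric(length(.cats))))

  # 5. reports
  out <- vector("list", n)
  for (i in seq_len(n)) {
    chosen <- sample.int(cfg$n_taxa, k[i], prob = pop)
    nrep <- 1L + stats::rpois(k[i], cfg$reports_per_taxon_mean - 1)
    tid <- base::rep(tax$taxon_id[chosen], nrep)
    cat_i <- unlist(lapply(seq_along(chosen), function(j)
      sample(.cats, nrep[j], replace = TRUE, prob = prof[chosen[j], ])),
      use.names = FALSE)
    out[[i]] <- data.frame(informant_id = inf$informant_id[i],
                           taxon_id = tid,
                           ailment = unname(.rep_ailments[cat_i]),
                           category = cat_i,
                           village = inf$village[i],
                           count = 1L, stringsAsFactors = FALSE)
  }
  reports <- do.call(rbind, out)
  rownames(reports) <- NULL
  ethno_survey(inf, tax, reports, "informant_level")
}

#' Re-estimate generator parameters from a simulated survey
#'
#' Closes the loop on the simulator: fits the age and education effects
#' back out of a generated dataset (Poisson regression of the distinct-
#' taxa count, age-knowledge Pearson correlation, education chi-square)
#' and measures the popularity skew, reporting each estimate next to the
#' configured truth and whether the truth lies inside the 95% Wald
#' interval. The Poisson fit ignores the >= 1 truncation, which is
#' negligible at the default mean of five taxa per informant.
#'
#' @param ds an informant-level `ethno_survey` from [generate_survey()].
#' @param truth the [generator_config()] that produced it.
#' @return list of class `recovery_report`.
#' @export
recover_parameters <- function(ds, truth) {
  inf <- ds$informants
  k <- vapply(split(ds$reports$taxon_id, ds$reports$informant_id),
              function(x) length(unique(x)), integer(1))
  knowledge <- as.integer(k[match(inf$informant_id, names(k))])
  knowledge[is.na(knowledge)] <- 0L

  dec <- (inf$age - 50) / 10
  edu <- match(inf$education, .educations) - 3
  fit <- stats::glm(knowledge ~ dec + edu, family = stats::poisson())
  est <- stats::coef(summary(fit))
  ci <- function(row) est[row, 1] + c(-1.96, 1.96) * est[row, 2]

  r <- stats::cor(inf$age, knowledge)
  nn <- nrow(inf)
  tt <- r * sqrt((nn - 2) / max(1 - r^2, 1e-12))
  r_p <- 2 * stats::pt(abs(tt), nn - 2, lower.tail = FALSE)

  edu_chisq <- tryCatch({
    tab <- dichotomize_knowledge(ds, "education", drop_empty = TRUE)
    suppressWarnings(chi_square(tab))
  }, error = function(e) NULL)

  uv <- use_value(ds)
  top_share <- max(uv$ur_total) / sum(uv$ur_total)

  structure(list(
    age = list(estimate = est["dec", 1], se = est["dec", 2],
               ci = ci("dec"), truth = truth$knowledge_model$age_coef,
               covered = truth$knowledge_model$age_coef >= ci("dec")[1] &&
                 truth$knowledge_model$age_coef <= ci("dec")[2],
               correlation = r, correlation_p = r_p),
    education = list(
      estimate = est["edu", 1], se = est["edu", 2], ci = ci("edu"),
      truth = truth$knowledge_model$education_coef,
      covered = truth$knowledge_model$education_coef >= ci("edu")[1] &&
        truth$knowledge_model$education_coef <= ci("edu")[2],
      chisq = if (is.null(edu_chisq)) NA_real_ else edu_chisq$statistic,
      chisq_p = if (is.null(edu_chisq)) NA_real_ else edu_chisq$p_value),
    popularity = list(top_taxon_share = top_share,
                      uniform_share = 1 / nrow(ds$taxa),
                      alpha = truth$taxon_popularity)),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("age effect/decade:  est %.3f (truth %.3f, covered: %s)\n",
              x$age$estimate, x$age$truth, x$age$covered))
  cat(sprintf("education effect:   est %.3f (truth %.3f, covered: %s)\n",
              x$education$estimate, x$education$truth, x$education$covered))
  cat(sprintf("education chi-square p: %.3g\n", x$education$chisq_p))
  cat(sprintf("top taxon UR share: %.3f (uniform would be %.3f)\n",
              x$popularity$top_taxon_share, x$popularity$uniform_share))
  invisible(x)
}
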