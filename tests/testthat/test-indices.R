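test_that("use value and use frequency follow UV = sum(U)/n, Fq = 100*UV", {
  fx <- load_kupwara()
  uv <- use_value(fx$survey)
  val <- uv[grepl("Valeriana", uv$botanical_name), ]
  expect_identical(val$ur_total, 47L)
  expect_equal(val$uv, 47 / 102, tolerance = 1e-12)
  expect_equal(val$fq_percent, 46.08)

  # definitional identity over all taxa
  expect_equal(uv$fq_percent, round_half_up(100 * uv$uv, 2))

  # unreported taxon and the all-informants taxon
  cites <- data.frame(informant_id = sprintf("i%02d", 1:4),
                      taxon_id = "t01", stringsAsFactors = FALSE)
  ds <- toy_survey(cites)
  u <- use_value(ds)
  expect_equal(u$uv[u$taxon_id == "t01"], 1)      # cited by all n
  expect_equal(u$uv[u$taxon_id == "t02"], 0)
  expect_equal(u$fq_percent[u$taxon_id == "t02"], 0)

  zero <- ds; zero$n_informants <- 0L
  expect_error(use_value(zero), class = "ei_domain_error")
})

test_that("family use value is the member-UV mean, bounded by the members", {
  fx <- load_kupwara()
  fuv <- family_use_value(fx$survey)
  capri <- fuv[fuv$family == "Caprifoliaceae", ]
  expect_identical(capri$ns, 2L)
  expect_equal(capri$fuv, (2 + 47) / 102 / 2, tolerance = 1e-12)
  expect_equal(round_half_up(capri$fuv, 2), 0.24)
  berb <- fuv[fuv$family == "Berberidaceae", ]
  expect_equal(berb$fuv, (20 + 24) / 102 / 2, tolerance = 1e-12)
  expect_equal(round_half_up(berb$fuv, 2), 0.22)

  # FUV bounded by min/max member UV; single-member families equal their UV
  uv <- use_value(fx$survey)
  fam <- fx$survey$taxa$family[match(uv$taxon_id, fx$survey$taxa$taxon_id)]
  for (f in unique(fam)) {
    members <- uv$uv[fam == f]
    expect_gte(fuv$fuv[fuv$family == f], min(members) - 1e-12)
    expect_lte(fuv$fuv[fuv$family == f], max(members) + 1e-12)
  }
  mono <- fuv[fuv$ns == 1L, ]
  expect_equal(mono$fuv, mono$uv_sum)
})

test_that("ICF matches its oracle, stays in [0,1], decreases in n_t", {
  # oracle agreement over random counts
  set.seed(42)
  n_ur <- sample(0:60, 40, replace = TRUE)
  n_t <- pmin(sample(1:20, 40, replace = TRUE), pmax(n_ur, 1L))
  got <- icf_from_counts(n_t, n_ur)
  expect_equal(got$icf, oracle_icf(n_ur, n_t))
  expect_identical(got$defined, n_ur >= 2L)
  ok <- got$defined
  expect_true(all(got$icf[ok] >= 0 & got$icf[ok] <= 1))
  # ICF = 1 iff a single taxon carries all reports
  expect_identical(got$icf[ok] == 1, got$n_t[ok] == 1L)

  # strictly decreasing in n_t at fixed n_ur
  path <- icf_from_counts(1:10, rep(10L, 10))
  expect_true(all(diff(path$icf) < 0))
  # every citation a different taxon -> 0
  expect_equal(icf_from_counts(7L, 7L)$icf, 0)
  expect_error(icf_from_counts(8L, 7L), class = "ei_domain_error")

  # dataset path agrees with the counts path on generated data
  ds <- generate_survey(generator_config(seed = 7L, n_informants = 40L,
                                         n_taxa = 20L, n_families = 5L))
  agg <- aggregate_survey(ds)
  res <- icf(agg)
  for (k in seq_len(nrow(res))) {
    sub <- agg$reports[agg$reports$category == res$category[k], ]
    expect_identical(res$n_ur[k], as.integer(sum(sub$count)))
    expect_identical(res$n_t[k], length(unique(sub$taxon_id)))
  }
  expect_identical(sum(res$n_ur), total_use_reports(agg))  # conservation
})

test_that("relative importance matches a brute-force oracle and its invariants", {
  set.seed(99)
  for (rep in 1:5) {
    ann <- data.frame(taxon_id = sprintf("t%02d", 1:20),
                      ph = sample(1:12, 20, replace = TRUE),
                      bs = sample(1:8, 20, replace = TRUE))
    ri <- relative_importance(ann)
    expect_equal(ri$ri, oracle_ri(ann$ph, ann$bs))
    expect_true(all(ri$ri > 0 & ri$ri <= 100))
    # scale-free: multiplying all ph and bs by constants changes nothing
    scaled <- ann; scaled$ph <- ann$ph * 3L; scaled$bs <- ann$bs * 7L
    expect_equal(relative_importance(scaled)$ri, ri$ri)
    # joint maxima score exactly 100
    expect_equal(ri$ri[ann$ph == max(ann$ph) & ann$bs == max(ann$bs)],
                 rep(100, sum(ann$ph == max(ann$ph) & ann$bs == max(ann$bs))))
  }
  # half of both (even) maxima -> 50
  ann <- data.frame(taxon_id = c("a", "b"), ph = c(4L, 2L), bs = c(6L, 3L))
  expect_equal(relative_importance(ann)$ri[2], 50)
  expect_error(relative_importance(ann[0, ]), class = "ei_domain_error")
  expect_error(relative_importance(data.frame(taxon_id = "a", ph = 0, bs = 1)),
               class = "ei_domain_error")
})

test_that("relative frequency counts distinct taxa per village", {
  fx <- load_kupwara()
  rf <- relative_frequency(
    village_counts = stats::setNames(fx$villages$taxa_identified,
                                     fx$villages$village),
    n_taxa = fx$constants$n_taxa)
  expect_equal(rf$rf_percent[rf$village == "Machil"], 71.96)
  expect_equal(relative_frequency(village_counts = c(V = 107), n_taxa = 107)$rf_percent,
               100.00)

  # report-based path equals a brute-force distinct count
  ds <- generate_survey(generator_config(seed = 13L, n_informants = 30L,
                                         n_taxa = 25L, n_families = 6L))
  rf2 <- relative_frequency(ds)
  for (v in rf2$village) {
    brute <- length(unique(ds$reports$taxon_id[ds$reports$village == v]))
    expect_identical(rf2$taxa_cited[rf2$village == v], brute)
  }
  # villageless reports -> warning and empty table
  bare <- ds; bare$reports$village <- NA_character_
  expect_warning(empty <- relative_frequency(bare), "village")
  expect_identical(nrow(empty), 0L)
})

test_that("rank_report sorts stably with alphabetical tie-breaks", {
  fx <- load_kupwara()
  top <- rank_report(use_value(fx$survey), "ur_total", 5)
  expect_identical(top$ur_total, c(47L, 45L, 37L, 36L, 35L))
  expect_match(top$botanical_name[1], "Valeriana jatamansi")
  expect_match(top$botanical_name[2], "Fritillaria cirrhosa")
  expect_match(top$botanical_name[3], "Arisaema jacquemontii")
  expect_match(top$botanical_name[4], "Asparagus racemosus")
  expect_match(top$botanical_name[5], "Rumex acetosa")

  expect_identical(nrow(rank_report(top, "ur_total", 0)), 0L)
  tied <- data.frame(botanical_name = c("Zed", "Abel"), x = c(1, 1))
  expect_identical(rank_report(tied, "x")$botanical_name, c("Abel", "Zed"))
  expect_error(rank_report(tied, "nope"), class = "ei_usage_error")
})
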