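test_that("constructor enforces the level contract and invariants", {
  cites <- data.frame(informant_id = c("i01", "i02"),
                      taxon_id = c("t01", "t02"),
                      stringsAsFactors = FALSE)
  ds <- toy_survey(cites)
  expect_s3_class(ds, "ethno_survey")
  expect_identical(ds$n_informants, 4L)

  # informant-level reports must carry ids and unit counts
  bad <- ds
  bad$reports$count[1] <- 2L
  expect_error(validate_survey(bad), class = "ei_validation_error")

  # aggregate needs explicit n
  expect_error(
    ethno_survey(taxa = toy_taxa(), reports = ds$reports[0, ],
                 level = "aggregate"),
    class = "ei_validation_error")

  # duplicate ids and dangling references are classed errors
  dup <- ds; dup$taxa <- rbind(dup$taxa, dup$taxa[1, ])
  expect_error(validate_survey(dup), class = "ei_uniqueness_error")
  dangling <- ds; dangling$reports$taxon_id[1] <- "tXX"
  expect_error(validate_survey(dangling), class = "ei_reference_error",
               regexp = "rows 1")
})

test_that("read_survey parses dialect tokens and flags schema problems", {
  dir <- withr::local_tempdir()
  writeLines(c("taxon_id,botanical_name,family,life_form,parts_used,preparation,route,nativity,voucher",
               "t01,Alpha one,Famae,h,Wp;Lv,juice/extract,ORAL,n,V01",
               "t02,Beta two,Fambe,T,rt,Chew/Roasted,Oral,E,V02"),
             file.path(dir, "taxa.csv"))
  writeLines(c("informant_id,taxon_id,ailment,category,village,count",
               "i01,t01,diarrhea,gas,VillageA,1"),
             file.path(dir, "reps.csv"))
  writeLines(c("informant_id,age,gender,education,community,village",
               "i01,44,female,matriculation,Dard,VillageA"),
             file.path(dir, "inf.csv"))
  ds <- read_survey(file.path(dir, "taxa.csv"), file.path(dir, "reps.csv"),
                    file.path(dir, "inf.csv"))
  expect_identical(ds$taxa$life_form, c("Herb", "Tree"))
  expect_identical(ds$taxa$parts_used, c("WholePlant;Leaf", "Root"))
  expect_identical(ds$taxa$preparation, c("JuiceExtract", "Chew"))
  expect_identical(ds$informants$education, "Matric")
  expect_identical(ds$reports$category, "GAS")

  # unknown token is named in the error
  writeLines(c("taxon_id,botanical_name,family,life_form,parts_used,preparation,route,nativity,voucher",
               "t01,Alpha one,Famae,X,Wp,Powder,Oral,N,V01"),
             file.path(dir, "bad.csv"))
  expect_error(read_survey(file.path(dir, "bad.csv"),
                           file.path(dir, "reps.csv"),
                           file.path(dir, "inf.csv")),
               "life_form.*X")

  # missing column -> schema error naming it
  writeLines("taxon_id,botanical_name", file.path(dir, "short.csv"))
  expect_error(read_survey(file.path(dir, "short.csv"),
                           file.path(dir, "reps.csv")),
               class = "ei_schema_error", regexp = "family")

  # empty reports file with a valid header is a 0-report dataset
  writeLines("informant_id,taxon_id,ailment,category,village,count",
             file.path(dir, "empty.csv"))
  ds0 <- read_survey(file.path(dir, "taxa.csv"), file.path(dir, "empty.csv"),
                     level = "aggregate", n_informants = 10)
  expect_identical(total_use_reports(ds0), 0L)
})

test_that("write/read round-trips generated surveys and conserves totals", {
  for (seed in c(11L, 12L)) {
    ds <- generate_survey(generator_config(seed = seed, n_informants = 40L,
                                           n_taxa = 25L, n_families = 10L))
    dir <- withr::local_tempdir()
    write_survey(ds, dir)
    back <- read_survey(file.path(dir, "taxa.csv"),
                        file.path(dir, "use_reports.csv"),
                        file.path(dir, "informants.csv"))
    expect_identical(back$taxa, ds$taxa)
    expect_identical(back$informants$age, ds$informants$age)
    expect_identical(back$reports$taxon_id, ds$reports$taxon_id)
    expect_identical(total_use_reports(back), total_use_reports(ds))
  }
})

test_that("aggregation conserves counts, matches recounts, is idempotent", {
  ds <- generate_survey(generator_config(seed = 5L, n_informants = 50L,
                                         n_taxa = 30L, n_families = 12L))
  agg <- aggregate_survey(ds)
  expect_identical(agg$level, "aggregate")
  expect_identical(total_use_reports(agg), total_use_reports(ds))
  expect_identical(agg$n_informants, length(unique(ds$reports$informant_id)))

  # brute-force recount per (taxon, category, village)
  key <- paste(ds$reports$taxon_id, ds$reports$category, ds$reports$village)
  recount <- c(table(key))
  akey <- paste(agg$reports$taxon_id, agg$reports$category,
                agg$reports$village)
  expect_identical(as.integer(recount[akey]), agg$reports$count)

  # per-village sums survive
  v1 <- sum(ds$reports$count[ds$reports$village == ds$reports$village[1]])
  expect_identical(
    sum(agg$reports$count[agg$reports$village == ds$reports$village[1]]),
    as.integer(v1))

  expect_identical(aggregate_survey(agg)$reports$count, agg$reports$count)

  # trivial case: 3 informants, same taxon, same category
  cites <- data.frame(informant_id = c("i01", "i02", "i03"),
                      taxon_id = "t01", category = "GAS",
                      stringsAsFactors = FALSE)
  a <- aggregate_survey(toy_survey(cites, village = "V"))
  expect_identical(nrow(a$reports), 1L)
  expect_identical(a$reports$count, 3L)
})

test_that("validate_consistency surfaces printed-Fq disagreements only", {
  reports <- data.frame(informant_id = NA_character_,
                        taxon_id = c("t01", "t02"),
                        ailment = NA_character_, category = "GAS",
                        village = NA_character_, count = c(47L, 24L),
                        stringsAsFactors = FALSE)
  ds <- ethno_survey(taxa = toy_taxa(2), reports = reports,
                     level = "aggregate", n_informants = 102L)
  printed <- data.frame(taxon_id = c("t01", "t02"),
                        ur_printed = c(47L, 24L),
                        fq_printed = c(46.08, 20.59))
  d <- validate_consistency(ds, printed)
  expect_identical(d$taxon_id, "t02")          # 24/102 = 23.53, not 20.59
  expect_equal(d$fq_recomputed, 23.53)
  expect_identical(nrow(validate_consistency(ds, printed[0, ])), 0L)
})
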