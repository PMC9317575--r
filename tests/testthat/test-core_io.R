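test_that("species normalization is deterministic and genus-capitalized", {
  expect_equal(normalize_species("  calopteryx   VIRGO "),
               "Calopteryx virgo")
  expect_equal(normalize_species("SYMPETRUM fonscolombii"),
               "Sympetrum fonscolombii")
  # subspecies tokens survive (lower-cased)
  expect_equal(normalize_species("cordulegaster boltonii Boltonii"),
               "Cordulegaster boltonii boltonii")
  expect_equal(normalize_species(character(0)), character(0))
})

test_that("survey read/write round-trips and validates", {
  sv <- fixture_survey()
  f <- tempfile(fileext = ".csv")
  write_survey(sv, f)
  expect_equal(read_survey(f), sv)

  # missing column
  bad <- as.data.frame(sv)[, -5]
  expect_error(read_survey(tmp_csv(bad)), "missing required column")

  # duplicate key names the offending tuple
  dup <- rbind(as.data.frame(sv), as.data.frame(sv)[1, ])
  expect_error(read_survey(tmp_csv(dup)),
               "duplicate survey key.*Calopteryx virgo")

  # non-integer count names the row
  bad2 <- as.data.frame(sv)
  bad2$count[3] <- "2.5"
  expect_error(read_survey(tmp_csv(bad2)), "row 3")

  # zero counts rejected unless record_absences
  z <- as.data.frame(sv)
  z$count[1] <- 0L
  expect_error(read_survey(tmp_csv(z)), "record_absences")
  expect_silent(read_survey(tmp_csv(z),
                            odocon_config(record_absences = TRUE)))
})

test_that("trait table read validates categories, bounds and round-trips", {
  tr <- fixture_traits()
  f <- tempfile(fileext = ".csv")
  write_traits(tr, f)
  expect_equal(read_traits(f), tr)

  # DBI totals later evaluate to the subscore sum (3,3,3) -> 9
  t9 <- as_traits(trait_row("Anax imperator", "Aeshnidae", "Anax",
                            d = 3L, r = 3L, s = 3L))
  expect_equal(dbi_species(t9)$dbi, 9L)

  bad <- trait_row("Anax imperator", "Aeshnidae", "Anax", d = 4L)
  expect_error(as_traits(bad), "out of range")

  bad2 <- trait_row("Anax imperator", "Aeshnidae", "Anax",
                    redlist = "XX")
  expect_error(as_traits(bad2), "permitted: LC, NT, VU, EN, CR, NA")

  # "NA" is a literal not-assessed category, not a missing value
  na_cat <- as_traits(trait_row("Anax imperator", "Aeshnidae", "Anax",
                                redlist = "NA"))
  expect_identical(na_cat$redlist, "NA")

  # header-only file: empty table with a warning
  hdr <- tempfile(fileext = ".csv")
  writeLines(paste("species,family,genus,endemic,semivoltine,redlist,",
                   "dbi_distribution,dbi_redlist,dbi_sensitivity",
                   sep = ""), hdr)
  expect_warning(empty <- read_traits(hdr), "empty")
  expect_equal(nrow(empty), 0L)

  # genus not a prefix of the binomial warns but loads
  expect_warning(as_traits(trait_row("Anax imperator", "Aeshnidae",
                                     "Aeshna")), "not a prefix")
})

test_that("landcover read validates kinds and sums, and round-trips", {
  lc <- as_landcover(data.frame(
    river = c("A", "A", "B"), class_code = c("311", "211", "311"),
    value = c(30, 70, 871), value_kind = c("percentage", "percentage",
                                           "area")))
  f <- tempfile(fileext = ".csv")
  write_landcover(lc, f)
  expect_equal(read_landcover(f), lc)

  expect_error(as_landcover(data.frame(
    river = "A", class_code = c("1", "2"), value = c(40, 70),
    value_kind = "percentage")), "sum to")
  expect_error(as_landcover(data.frame(
    river = "A", class_code = c("1", "2"), value = c(40, 60),
    value_kind = c("percentage", "area"))), "mixes")
})

test_that("registry round-trips and rejects duplicates", {
  rg <- fixture_registry()
  f <- tempfile(fileext = ".csv")
  write_registry(rg, f)
  expect_equal(read_registry(f), rg)
  expect_error(as_registry(rbind(as.data.frame(rg),
                                 as.data.frame(rg)[1, ])), "duplicate")
})

test_that("consistency report is order-independent and one-sided fatal", {
  sv <- fixture_survey()
  tr <- fixture_traits()
  rep <- validate_consistency(sv, tr)
  expect_length(rep$missing_traits, 0L)
  expect_length(rep$unused_traits, 0L)

  # survey species missing from traits is reported by name
  rep2 <- validate_consistency(sv, as_traits(as.data.frame(tr)[-1, ]))
  expect_equal(rep2$missing_traits, "Calopteryx virgo")

  # traits superset of survey: warning only, never an error
  extra <- as_traits(rbind(as.data.frame(tr),
                           trait_row("Anax imperator", "Aeshnidae",
                                     "Anax")))
  expect_warning(rep3 <- validate_consistency(sv, extra),
                 "never observed")
  expect_equal(rep3$unused_traits, "Anax imperator")

  # permuting rows never changes the outcome
  perm <- as_survey(as.data.frame(sv)[sample(nrow(sv)), ])
  rep4 <- validate_consistency(perm, tr)
  expect_equal(rep4, rep)
})

test_that("config validates enumerations and rejects unknown keys", {
  cfg <- odocon_config(seed = 9, alpha_level = 0.01)
  expect_s3_class(cfg, "odocon_config")
  expect_error(odocon_config(replicate_unit = "plot"), "arg")
  expect_error(odocon_config(alpha_level = 1.5), "alpha_level")
  expect_error(odocon_config(rlc_score_map = c(XX = 1)), "unknown")

  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(seed = 4, replicate_unit = "river_event"), f,
                       auto_unbox = TRUE)
  cfg2 <- read_config(f)
  expect_equal(cfg2$seed, 4L)
  expect_equal(cfg2$replicate_unit, "river_event")

  jsonlite::write_json(list(seeed = 4), f, auto_unbox = TRUE)
  expect_error(read_config(f), "unknown configuration keys: seeed")
})
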