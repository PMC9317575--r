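test_that("DBI totals are the subscore sums with printed anchors", {
  tr <- rbind(trait_row("A a", "Fa", "A", d = 0L, r = 0L, s = 0L),
              trait_row("B b", "Fb", "B", d = 3L, r = 3L, s = 3L),
              trait_row("C c", "Fc", "C", d = 1L, r = 2L, s = 0L))
  d <- dbi_species(tr)
  expect_equal(d$dbi, c(0L, 9L, 3L))
  expect_error(dbi_species(trait_row("A a", "Fa", "A", d = 5L)),
               "\\{0,1,2,3\\}")
})

test_that("standardized DBI is the mean over species present", {
  tr <- as_traits(rbind(
    trait_row("A a", "Fa", "A", d = 0L, r = 0L, s = 0L),
    trait_row("B b", "Fb", "B", d = 3L, r = 3L, s = 3L),
    trait_row("C c", "Fc", "C", d = 2L, r = 2L, s = 2L)))
  expect_equal(standardized_dbi("C c", tr), 6)
  expect_equal(standardized_dbi(c("A a", "B b"), tr), 4.5)
  expect_true(is.na(standardized_dbi(character(0), tr)))
  # bounded in [0, 9]; equals the species DBI when N = 1
  expect_gte(standardized_dbi(tr$species, tr), 0)
  expect_lte(standardized_dbi(tr$species, tr), 9)
})

test_that("RLC scoring uses the configured map and guards threatened", {
  expect_equal(rlc_score(c("NT", "LC", "NA")), c(0.5, 0, 0))
  expect_equal(rlc_score("VU", c(VU = 1.0)), 1.0)
  expect_error(rlc_score("VU"), "extend rlc_score_map")
  expect_error(rlc_score("ZZ"), "unknown red-list")
})

test_that("CCOI reproduces hand-evaluated single-assemblage cases", {
  lc1 <- as_traits(trait_row("Genus01 spa", "FamilyA", "Genus01"))
  # 1 sp, 1 fam, 1 gen, remaining, LC, rtd 1: ((1+1)/2 * (1 + 1)) / 1 = 2
  expect_equal(ccoi("Genus01 spa", lc1)$ccoi, 2.0, tolerance = 1e-12)

  en1 <- as_traits(trait_row("Genus01 spa", "FamilyA", "Genus01",
                             endemic = TRUE))
  # endemic: E=1, R=0: (1 * (3 + 1)) / 1 = 4
  expect_equal(ccoi("Genus01 spa", en1)$ccoi, 4.0, tolerance = 1e-12)

  cong <- as_traits(rbind(
    trait_row("Genus01 spa", "FamilyA", "Genus01"),
    trait_row("Genus01 spb", "FamilyA", "Genus01")))
  # 2 congeneric remaining species, rtd 1/sqrt(2):
  # ((1+1)/2 * (2 + 1/sqrt(2))) / 2
  out <- ccoi(cong$species, cong)
  expect_equal(out$ccoi, (2 + 1 / sqrt(2)) / 2, tolerance = 1e-12)
  expect_equal(out$ccoi, 1.35355, tolerance = 1e-5)
})

test_that("CCOI components are self-consistent and label-invariant", {
  set.seed(33)
  sp <- synthesis_spec(seed = 33)
  tr <- generate_traits(generate_taxonomy(sp)$species, sp)
  for (i in 1:20) {
    s <- sample(tr$species, sample(2:10, 1))
    out <- ccoi(s, tr)
    # recompute from returned components
    again <- ((out$F + out$G) / 2 *
                (3 * out$E + 3 * out$S + out$R + out$sum_rtd +
                   out$sum_rlc)) / out$N
    expect_equal(again, out$ccoi, tolerance = 1e-12)
    # ordering invariance
    expect_equal(ccoi(rev(s), tr)$ccoi, out$ccoi)
    # set-based R identity: E + S + R = N + |E n S|
    both <- sum(tr$endemic[match(s, tr$species)] &
                  tr$semivoltine[match(s, tr$species)])
    expect_equal(out$E + out$S + out$R, out$N + both)
  }
})

test_that("swapping a remaining species to endemic adds exactly 2 to the bracket", {
  # exhaustive over assemblages of <= 4 species drawn from a 4-species
  # pool, toggling each non-semivoltine remaining species
  pool <- as_traits(rbind(
    trait_row("A a", "Fa", "A"), trait_row("A b", "Fa", "A"),
    trait_row("B c", "Fb", "B", semivoltine = TRUE),
    trait_row("C d", "Fc", "C", redlist = "NT")))
  bracket <- function(x) 3 * x$E + 3 * x$S + x$R + x$sum_rtd + x$sum_rlc
  for (n in 1:4) for (s in utils::combn(pool$species, n,
                                        simplify = FALSE)) {
    base <- ccoi(s, pool)
    for (target in s) {
      row <- match(target, pool$species)
      if (pool$endemic[row] || pool$semivoltine[row]) next
      mod <- as.data.frame(pool)
      mod$endemic[row] <- TRUE
      expect_equal(bracket(ccoi(s, as_traits(mod))),
                   bracket(base) + 2, tolerance = 1e-12)
    }
  }
})

test_that("overlap rules and empty assemblages behave as documented", {
  both <- as_traits(rbind(
    trait_row("A a", "Fa", "A", endemic = TRUE, semivoltine = TRUE),
    trait_row("B b", "Fb", "B")))
  out <- ccoi(both$species, both)
  expect_equal(out$E, 1L)
  expect_equal(out$S, 1L)
  expect_equal(out$R, 1L)  # N - |E u S| = 2 - 1, never negative
  expect_error(ccoi(both$species, both,
                    config = odocon_config(ccoi_overlap = "exclusive")),
               "exclusive")
  expect_warning(e <- ccoi(character(0), both), "empty")
  expect_true(is.na(e$ccoi))
})

test_that("conservation replicate table carries indices and NA for empties", {
  sv <- fixture_survey()
  rg <- fixture_registry()
  tr <- fixture_traits()
  rep <- conservation_replicates(sv, rg, tr)
  empty <- rep[rep$richness == 0L, ]
  expect_true(all(is.na(empty$ccoi)))
  expect_true(all(is.na(empty$dbi_standardized)))
  filled <- rep[rep$richness > 0L, ]
  expect_true(all(!is.na(filled$ccoi)))
  # single-species replicate: ccoi components N=1, F=G=1
  one <- rep[rep$unit == "B|S2|E1", ]
  expect_equal(one$N, 1L)
  expect_equal(one$F, 1L)

  # river scope accumulates the river's replicate RTDs
  cfg <- odocon_config(ccoi_scope = "river")
  rep2 <- conservation_replicates(sv, rg, tr, cfg)
  a_units <- rep$river == "A" & rep$richness > 0L
  expect_equal(unique(rep2$sum_rtd[a_units]),
               sum(rep$rtd[rep$river == "A"], na.rm = TRUE))
})
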