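# In-code fixtures shared across test files. Everything is built at test
# time; no data files are read.

# minimal trait row builder
trait_row <- function(species, family, genus,
                      endemic = FALSE, semivoltine = FALSE,
                      redlist = "LC", d = 0L, r = 0L, s = 0L) {
  data.frame(species = species, family = family, genus = genus,
             endemic = endemic, semivoltine = semivoltine,
             redlist = redlist, dbi_distribution = d, dbi_redlist = r,
             dbi_sensitivity = s, stringsAsFactors = FALSE)
}

# a 4-species, 2-family trait table used throughout
fixture_traits <- function() {
  as_traits(rbind(
    trait_row("Calopteryx virgo", "Calopterygidae", "Calopteryx",
              semivoltine = TRUE, d = 1L, r = 0L, s = 2L),
    trait_row("Calopteryx splendens", "Calopterygidae", "Calopteryx",
              d = 0L, r = 0L, s = 1L),
    trait_row("Sympetrum meridionale", "Libellulidae", "Sympetrum",
              redlist = "NT", d = 2L, r = 1L, s = 1L),
    trait_row("Cordulegaster heros", "Cordulegastridae", "Cordulegaster",
              endemic = TRUE, semivoltine = TRUE, redlist = "NT",
              d = 3L, r = 1L, s = 3L)))
}

# small two-river survey over 2 sites x 2 events with one empty sample
fixture_survey <- function() {
  as_survey(data.frame(
    river = c("A", "A", "A", "A", "B", "B", "B"),
    site = c("S1", "S1", "S1", "S2", "S1", "S1", "S2"),
    event = c("E1", "E1", "E2", "E1", "E1", "E2", "E1"),
    species = c("Calopteryx virgo", "Sympetrum meridionale",
                "Calopteryx virgo", "Calopteryx splendens",
                "Cordulegaster heros", "Cordulegaster heros",
                "Sympetrum meridionale"),
    count = c(3L, 1L, 2L, 5L, 1L, 2L, 4L),
    stringsAsFactors = FALSE))
}

fixture_registry <- function() {
  as_registry(expand.grid(river = c("A", "B"), site = c("S1", "S2"),
                          event = c("E1", "E2"),
                          stringsAsFactors = FALSE)[, c("river", "site",
                                                        "event")])
}

# write a data.frame as a temp CSV, returning the path
tmp_csv <- function(df, dir = tempdir()) {
  f <- tempfile(fileext = ".csv", tmpdir = dir)
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  f
}

# all permutations of 1:k (k small), for exhaustive invariance checks
.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) for (rest in .permutations(k - 1L))
    out <- c(out, list(c(i, setdiff(seq_len(k), i)[rest])))
  out
}

# random assemblage generator for property tests
random_assemblage <- function(max_s = 12L, max_count = 50L) {
  s <- sample.int(max_s, 1L)
  stats::setNames(sample.int(max_count, s, replace = TRUE),
                  paste0("sp", seq_len(s)))
}
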