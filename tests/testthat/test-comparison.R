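# independent brute-force oracle: mid-ranks by pairwise counting, H from
# the definitional between-group rank dispersion, tie divisor from value
# counts
kw_oracle <- function(values, groups) {
  N <- length(values)
  r <- vapply(values, function(v)
    sum(values < v) + (sum(values == v) + 1) / 2, numeric(1))
  groups <- factor(groups)
  H <- 0
  for (g in levels(groups)) {
    idx <- groups == g
    H <- H + sum(idx) * (mean(r[idx]) - (N + 1) / 2)^2
  }
  H <- 12 / (N * (N + 1)) * H
  tie <- table(values)
  div <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (div <= 0) 0 else H / div
}

test_that("Kruskal-Wallis H matches hand computation and stats oracle", {
  # no ties: groups (1,2,3) vs (4,5,6)
  out <- kruskal_wallis(1:6, rep(c("a", "b"), each = 3))
  expect_equal(out$statistic, 12 / 42 * 13.5, tolerance = 1e-12)
  expect_equal(out$df, 1L)

  # two identical groups: H = 0
  sym <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(sym$statistic, 0, tolerance = 1e-12)

  # all observations identical: guarded degenerate case
  deg <- kruskal_wallis(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)

  # random tied data against stats::kruskal.test
  set.seed(14)
  for (i in 1:30) {
    g <- rep(letters[1:3], times = sample(3:8, 3, replace = TRUE))
    v <- sample(1:5, length(g), replace = TRUE)
    ours <- kruskal_wallis(v, g, posthoc = FALSE)
    ref <- stats::kruskal.test(v, factor(g))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(15)
  g <- rep(letters[1:4], each = 6)
  v <- rnorm(24)
  h0 <- kruskal_wallis(v, g, posthoc = FALSE)$statistic
  for (f in list(function(x) 2 * x + 7, exp,
                 function(x) x^3)) {
    expect_equal(kruskal_wallis(f(v), g, posthoc = FALSE)$statistic, h0,
                 tolerance = 1e-10)
  }
})

test_that("H equals the brute-force oracle on sampled small instances", {
  # full exhaustive coverage lives in the acceptance suite; here a
  # randomized spot check keeps the unit run fast
  set.seed(16)
  for (i in 1:200) {
    n <- sample(4:8, 1)
    sizes <- c(1, 1, sample(0:2, 1))
    sizes <- sizes[sizes > 0]
    while (sum(sizes) < n) {
      i_grow <- sample(length(sizes), 1)
      sizes[i_grow] <- sizes[i_grow] + 1
    }
    g <- rep(seq_along(sizes), sizes)
    v <- sample(1:3, n, replace = TRUE)
    expect_equal(kruskal_wallis(v, g, posthoc = FALSE)$statistic,
                 kw_oracle(v, g), tolerance = 1e-10)
  }
})

test_that("Dunn pairwise comparisons separate a shifted group", {
  set.seed(17)
  v <- c(rnorm(15), rnorm(15), rnorm(15, mean = 6))
  g <- rep(c("a", "b", "c"), each = 15)
  out <- kruskal_wallis(v, g)
  pw <- out$pairwise
  expect_true(pw$significant[pw$group_a == "a" & pw$group_b == "c"])
  expect_true(pw$significant[pw$group_a == "b" & pw$group_b == "c"])
  expect_false(pw$significant[pw$group_a == "a" & pw$group_b == "b"])
  expect_equal(unname(out$letters), c("a", "a", "b"))
  # bonferroni: adjusted = pmin(1, 3 * raw) for 3 pairs
  expect_equal(pw$p_adjusted, pmin(1, 3 * pw$p), tolerance = 1e-12)
})

test_that("ANOVA fixture gives F = 3 on (2, 6) df and matches Tukey oracle", {
  v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  out <- anova_tukey(v, g)
  expect_equal(out$statistic, 3, tolerance = 1e-12)
  expect_equal(out$df, c(2L, 6L))

  # oracle: studentized-range p for each pair from first principles
  msw <- 1  # within-group mean square of the fixture
  means <- tapply(v, g, mean)
  for (i in seq_len(nrow(out$pairwise))) {
    a <- out$pairwise$group_a[i]; b <- out$pairwise$group_b[i]
    q <- abs(means[[b]] - means[[a]]) / sqrt(msw / 3)
    p_ref <- stats::ptukey(q, nmeans = 3, df = 6, lower.tail = FALSE)
    expect_equal(out$pairwise$p_adjusted[i], p_ref, tolerance = 1e-6)
  }

  # flat means: F ~ 0
  flat <- anova_tukey(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(flat$statistic, 0, tolerance = 1e-12)

  # all-constant groups: F undefined
  expect_error(anova_tukey(rep(c(1, 2), each = 3),
                           rep(c("a", "b"), each = 3)), "undefined")
})

test_that("normality gate routes by distribution shape", {
  set.seed(18)
  # well-behaved Gaussian samples go parametric in most seeded draws
  pass <- vapply(1:200, function(s) {
    set.seed(s)
    v <- rnorm(60)
    g <- rep(c("a", "b"), each = 30)
    shapiro_gate(v, g)$route == "anova"
  }, logical(1))
  expect_gte(mean(pass), 0.85)  # two groups, gate size ~ 2 * alpha

  # heavy-tailed data go nonparametric (ladder cannot rescue a symmetric
  # heavy tail)
  set.seed(19)
  v <- abs(rcauchy(60))^2
  g <- rep(c("a", "b"), each = 30)
  expect_equal(shapiro_gate(v, g)$route, "kruskal_wallis")

  # constant group: fail-safe nonparametric
  expect_equal(shapiro_gate(c(rep(1, 5), rnorm(5)),
                            rep(c("a", "b"), each = 5))$route,
               "kruskal_wallis")
  expect_error(shapiro_gate(rnorm(5), rep("a", 5)), "2 groups")
})

test_that("compact letters encode pairwise decisions", {
  # no significant pairs: all share 'a'
  pw0 <- data.frame(group_a = c("x", "x", "y"),
                    group_b = c("y", "z", "z"), significant = FALSE)
  expect_equal(unname(compact_letters(c("x", "y", "z"), pw0)),
               c("a", "a", "a"))

  # one group apart from all others
  pw1 <- data.frame(group_a = c("x", "x", "y"),
                    group_b = c("y", "z", "z"),
                    significant = c(FALSE, TRUE, TRUE))
  expect_equal(compact_letters(c("x", "y", "z"), pw1),
               c(x = "a", y = "a", z = "b"))

  # non-transitive chain a!=c, a=b, b=c
  pw2 <- data.frame(group_a = c("a", "a", "b"),
                    group_b = c("b", "c", "c"),
                    significant = c(FALSE, TRUE, FALSE))
  expect_equal(compact_letters(c("a", "b", "c"), pw2),
               c(a = "a", b = "ab", c = "b"))

  # groups share a letter iff not significantly different
  set.seed(20)
  for (i in 1:50) {
    k <- sample(3:5, 1)
    gs <- letters[1:k]
    pairs <- t(utils::combn(gs, 2))
    pw <- data.frame(group_a = pairs[, 1], group_b = pairs[, 2],
                     significant = sample(c(TRUE, FALSE), nrow(pairs),
                                          replace = TRUE))
    lt <- compact_letters(gs, pw)
    for (r in seq_len(nrow(pw))) {
      shared <- length(intersect(strsplit(lt[[pw$group_a[r]]], "")[[1]],
                                 strsplit(lt[[pw$group_b[r]]], "")[[1]]))
      if (pw$significant[r]) expect_equal(shared, 0L)
      else expect_gt(shared, 0L)
    }
  }
})

test_that("compare_rivers runs the gate and labels results", {
  sp <- synthesis_spec(seed = 21)
  dat <- synthesize_dataset(sp)
  rep <- conservation_replicates(dat$survey, dat$registry, dat$traits)
  res <- compare_rivers(rep, c("richness", "ccoi"))
  expect_named(res, c("richness", "ccoi"))
  for (m in names(res)) {
    expect_s3_class(res[[m]], "odocon_test")
    expect_true(res[[m]]$p_value >= 0 && res[[m]]$p_value <= 1)
    expect_equal(sort(names(res[[m]]$letters)),
                 sort(unique(rep$river)))
  }
  expect_error(compare_rivers(rep, "nope"), "not found")
})
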