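#' Normality gate for among-group tests
#'
#' Applies the Shapiro-Wilk test per group, walking a transformation
#' ladder (identity, square root, fourth root, log(x+1)) in that order.
#' The first step at which every group passes at `alpha` routes the metric
#' to one-way ANOVA on the transformed data; if none passes - or any group
#' is too small (n < 3) or constant, where the test is undefined - the
#' fail-safe route is the nonparametric Kruskal-Wallis test.
#'
#' @param values numeric vector (NA dropped).
#' @param groups grouping vector, same length.
#' @param alpha gate significance level.
#' @return list with `route` (`"anova"` or `"kruskal_wallis"`),
#'   `transform` (name of the passing ladder step or `NA`), and `details`
#'   (per-group W and p for each step tried).
#' @export
shapiro_gate <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values)
  values <- values[ok]
  groups <- factor(groups[ok])
  if (nlevels(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  ladder <- list(identity = function(x) x,
                 sqrt = sqrt,
                 fourth_root = function(x) x^0.25,
                 log1p = log1p)
  details <- list()
  for (step in names(ladder)) {
    f <- ladder[[step]]
    tx <- suppressWarnings(f(values))
    if (any(!is.finite(tx))) next  # transform inapplicable (negatives)
    res <- lapply(levels(groups), function(g) {
      x <- f(values[groups == g])
      if (length(x) < 3L || length(unique(x)) == 1L)
        return(data.frame(group = g, n = length(x), W = NA_real_,
                          p = NA_real_, pass = FALSE))
      sw <- stats::shapiro.test(x)
      data.frame(group = g, n = length(x), W = unname(sw$statistic),
                 p = sw$p.value, pass = sw$p.value >= alpha)
    })
    res <- do.call(rbind, res)
    details[[step]] <- res
    if (all(res$pass))
      return(list(route = "anova", transform = step, details = details))
  }
  list(route = "kruskal_wallis", transform = NA_character_,
       details = details)
}

#' Kruskal-Wallis H test with average-rank post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference on k-1
#' degrees of freedom, followed by Dunn-type pairwise comparisons of
#' average ranks (z statistics on the shared rank variance, with the tie
#' term) adjusted for multiplicity, and a compact letter display at
#' `alpha`. If every observation is identical the tie correction is
#' degenerate and the documented guard returns H = 0, p = 1.
#'
#' @param values numeric vector (NA dropped).
#' @param groups grouping vector, same length.
#' @param adjust multiplicity adjustment for pairwise p-values
#'   (see [stats::p.adjust()]); default `"bonferroni"`.
#' @param alpha significance level for the letter display.
#' @param metric label carried into the result.
#' @param posthoc compute the pairwise comparisons and letter display;
#'   set `FALSE` for the omnibus statistic and p-value only (cheaper in
#'   simulations).
#' @return an `odocon_test` list: `metric`, `method`, `statistic` (H),
#'   `df`, `p_value`, `pairwise` (data.frame `group_a,group_b,z,
#'   p,p_adjusted,significant`), `letters` (named character vector).
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))$statistic
#' @export
kruskal_wallis <- function(values, groups, adjust = "bonferroni",
                           alpha = 0.05, metric = "value",
                           posthoc = TRUE) {
  ok <- !is.na(values)
  values <- values[ok]
  groups <- factor(groups[ok])
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 non-empty groups", call. = FALSE)
  n <- tabulate(groups)
  if (any(n == 0L)) stop("empty group", call. = FALSE)
  N <- length(values)
  r <- rank(values)  # mid-ranks
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  H_raw <- 12 / (N * (N + 1)) * sum(n * rbar^2) - 3 * (N + 1)
  C <- 1 - tie_term / (N^3 - N)
  if (C <= 0) {  # every observation identical
    H <- 0
    p <- 1
  } else {
    H <- H_raw / C
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  if (!posthoc)
    return(structure(list(metric = metric, method = "kruskal_wallis",
                          statistic = H, df = k - 1L, p_value = p,
                          pairwise = NULL, letters = NULL),
                     class = "odocon_test"))
  # Dunn-type pairwise z on average ranks, shared tie-corrected variance
  sigma2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  pairs <- utils::combn(levels(groups), 2L)
  pw <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                   z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    se <- sqrt(sigma2 * (1 / n[levels(groups) == a] +
                           1 / n[levels(groups) == b]))
    z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    pw$z[i] <- z
    pw$p[i] <- 2 * stats::pnorm(-abs(z))
  }
  pw$p_adjusted <- stats::p.adjust(pw$p, method = adjust)
  pw$significant <- pw$p_adjusted < alpha
  structure(list(metric = metric, method = "kruskal_wallis",
                 statistic = H, df = k - 1L, p_value = p, pairwise = pw,
                 letters = compact_letters(levels(groups), pw)),
            class = "odocon_test")
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Standard one-way analysis of variance (F on k-1 and N-k degrees of
#' freedom) with Tukey honest-significant-difference pairwise comparisons
#' and a compact letter display. Errors when the within-group variance is
#' zero everywhere (F undefined).
#'
#' @inheritParams kruskal_wallis
#' @return an `odocon_test` list as in [kruskal_wallis()] but with
#'   `method = "anova"`, `statistic` the F value and `df = c(k-1, N-k)`;
#'   pairwise column `diff` instead of `z`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05, metric = "value") {
  ok <- !is.na(values)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 non-empty groups", call. = FALSE)
  if (any(tabulate(groups) < 2L))
    stop("each group needs n >= 2 for ANOVA", call. = FALSE)
  if (all(tapply(values, groups, stats::var) == 0))
    stop("zero within-group variance in every group: F undefined",
         call. = FALSE)
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  pw <- data.frame(group_a = vapply(nm, `[`, "", 2L),
                   group_b = vapply(nm, `[`, "", 1L),
                   diff = tk[, "diff"], p_adjusted = tk[, "p adj"],
                   stringsAsFactors = FALSE)
  pw$significant <- pw$p_adjusted < alpha
  rownames(pw) <- NULL
  structure(list(metric = metric, method = "anova",
                 statistic = an[["F value"]][1L],
                 df = c(an[["Df"]][1L], an[["Df"]][2L]),
                 p_value = an[["Pr(>F)"]][1L], pairwise = pw,
                 letters = compact_letters(levels(groups), pw)),
            class = "odocon_test")
}

#' Compact letter display
#'
#' Minimal letter assignment such that two groups share a letter if and
#' only if they are not significantly different (insertion-absorption
#' algorithm). Non-transitive decision sets are representable: a group may
#' carry several letters.
#'
#' @param groups character vector of group names.
#' @param pairwise data.frame with columns `group_a,group_b,significant`.
#' @return named character vector of letter codes per group.
#' @examples
#' pw <- data.frame(group_a = c("a", "a", "b"), group_b = c("b", "c", "c"),
#'                  significant = c(FALSE, TRUE, FALSE))
#' compact_letters(c("a", "b", "c"), pw)
#' @export
compact_letters <- function(groups, pairwise) {
  sets <- list(groups)
  sig <- pairwise[pairwise$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$group_a[i]; b <- sig$group_b[i]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    new_sets <- new_sets[lengths(new_sets) > 0L]
    # absorption: drop sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (p in seq_along(new_sets)) for (q in seq_along(new_sets))
      if (p != q && keep[p] && keep[q] &&
          all(new_sets[[p]] %in% new_sets[[q]]) &&
          !(all(new_sets[[q]] %in% new_sets[[p]]) && p < q))
        keep[p] <- FALSE
    sets <- new_sets[keep]
  }
  # order letter sets by first member so letters read left-to-right
  ord <- order(vapply(sets, function(s) min(match(s, groups)), numeric(1)))
  sets <- sets[ord]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets))
    out[sets[[i]]] <- paste0(out[sets[[i]]], letters[i])
  out
}

#' @export
print.odocon_test <- function(x, ...) {
  lab <- if (x$method == "kruskal_wallis")
    sprintf("Kruskal-Wallis H = %.3f, d.f. = %d, p = %.4g",
            x$statistic, x$df, x$p_value)
  else
    sprintf("one-way ANOVA F = %.3f, d.f. = (%d, %d), p = %.4g",
            x$statistic, x$df[1L], x$df[2L], x$p_value)
  cat(x$metric, ": ", lab, "\n", sep = "")
  cat("letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}

#' Among-river comparison of replicate metrics
#'
#' Runs, for each requested metric column of a replicate table, the
#' Shapiro-Wilk gate and then either one-way ANOVA with Tukey HSD (on the
#' transform that passed the gate) or the Kruskal-Wallis test with
#' average-rank post hoc comparisons. Missing replicate values (e.g. RTD
#' of empty samples) are excluded per metric.
#'
#' @param replicates data.frame with a `river` column and metric columns
#'   (e.g. from [per_replicate_metrics()] or [conservation_replicates()]).
#' @param metrics character vector of metric column names to test.
#' @param config an [odocon_config()].
#' @return named list of `odocon_test` objects, one per metric; each also
#'   carries `$route` (the gate decision).
#' @export
compare_rivers <- function(replicates,
                           metrics = c("richness", "abundance"),
                           config = odocon_config()) {
  miss <- setdiff(metrics, names(replicates))
  if (length(miss))
    stop("metric column(s) not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (m in metrics) {
    v <- replicates[[m]]
    g <- replicates$river
    gate <- shapiro_gate(v, g, alpha = config$alpha_level)
    res <- if (gate$route == "anova") {
      ladder <- list(identity = function(x) x, sqrt = sqrt,
                     fourth_root = function(x) x^0.25, log1p = log1p)
      anova_tukey(ladder[[gate$transform]](v), g,
                  alpha = config$alpha_level, metric = m)
    } else {
      kruskal_wallis(v, g, adjust = config$posthoc_adjustment,
                     alpha = config$alpha_level, metric = m)
    }
    res$route <- gate
    out[[m]] <- res
  }
  out
}
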