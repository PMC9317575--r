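#' Per-river mean and standard error summary
#'
#' Mean and SE (= sd / sqrt(n)) of each metric per river, excluding
#' missing values per metric. A river with a single non-missing replicate
#' gets a defined mean and a missing SE.
#'
#' @param replicates data.frame with a `river` column and numeric metric
#'   columns.
#' @param metrics character vector of metric columns; default all numeric
#'   columns except identifiers.
#' @return data.frame with columns `river`, then `<metric>_mean`,
#'   `<metric>_se`, `<metric>_n` per metric.
#' @examples
#' summarize_replicates(data.frame(river = "r", richness = c(2, 4)),
#'                      "richness")
#' @export
summarize_replicates <- function(replicates, metrics = NULL) {
  if (is.null(metrics)) {
    num <- vapply(replicates, is.numeric, logical(1))
    metrics <- setdiff(names(replicates)[num],
                       c("river", "site", "event", "unit"))
  }
  rivers <- sort(unique(replicates$river))
  out <- data.frame(river = rivers, stringsAsFactors = FALSE)
  for (m in metrics) {
    mu <- se <- rep(NA_real_, length(rivers))
    nn <- integer(length(rivers))
    for (i in seq_along(rivers)) {
      v <- replicates[[m]][replicates$river == rivers[i]]
      v <- v[!is.na(v)]
      nn[i] <- length(v)
      if (length(v)) mu[i] <- mean(v)
      if (length(v) > 1L) se[i] <- stats::sd(v) / sqrt(length(v))
    }
    out[[paste0(m, "_mean")]] <- mu
    out[[paste0(m, "_se")]] <- se
    out[[paste0(m, "_n")]] <- nn
  }
  out
}

#' Run the full assessment pipeline
#'
#' Orchestrates every stage: data load (or synthesis), land-cover
#' heterogeneity, per-replicate diversity and conservation indices,
#' Bray-Curtis/NMDS/UPGMA ordination, and among-river comparisons. All
#' stochastic stages are driven by `config$seed`, so output is a pure
#' function of (inputs, config, seed). When `out_dir` is given, a fixed
#' set of CSV files plus `run.json` metadata is written there.
#'
#' @param config an [odocon_config()].
#' @param survey,registry,traits,landcover loaded input objects; or
#' @param synthesis a [synthesis_spec()] used to generate them (inputs win
#'   if both given).
#' @param out_dir optional output directory (created if needed); files:
#'   `summary.csv`, `replicates.csv`, `tests.csv`, `pairwise.csv`,
#'   `letters.csv`, `ordination.csv`, `hhi.csv`, `run.json`.
#' @param cluster_thresholds similarity thresholds for the cluster
#'   overlay.
#' @param test_metrics metric columns compared among rivers.
#' @return list of class `odocon_report`: `summary`, `replicates`,
#'   `pooled`, `hhi`, `ordination` (`odocon_nmds`), `clusters`, `tests`
#'   (list of `odocon_test`), `config`, `meta`.
#' @export
run_assessment <- function(config = odocon_config(),
                           survey = NULL, registry = NULL, traits = NULL,
                           landcover = NULL, synthesis = NULL,
                           out_dir = NULL,
                           cluster_thresholds = c(20, 40),
                           test_metrics = c("richness", "abundance",
                                            "rtd", "dbi_standardized",
                                            "ccoi")) {
  if (is.null(survey)) {
    if (is.null(synthesis))
      stop("provide either input tables or a synthesis spec",
           call. = FALSE)
    message("stage synthesis: generating dataset (seed ",
            synthesis$seed, ")")
    dat <- synthesize_dataset(synthesis)
    survey <- dat$survey; registry <- dat$registry
    traits <- dat$traits; landcover <- dat$landcover
  }
  if (is.null(registry))
    stop("a sample registry is required (empty samples must be explicit)",
         call. = FALSE)
  consistency <- validate_consistency(survey, traits)
  if (length(consistency$missing_traits))
    stop("stage validation: species without trait rows: ",
         paste(consistency$missing_traits, collapse = ", "),
         call. = FALSE)

  message("stage landcover: ", length(unique(landcover$river)), " rivers")
  hhi <- compute_hhi(landcover)

  message("stage indices: replicate unit ", config$replicate_unit)
  replicates <- conservation_replicates(survey, registry, traits, config)
  pooled <- pooled_river_metrics(survey)

  message("stage ordination")
  sim <- bray_curtis_matrix(survey, registry, config)
  ord <- nmds_ordination(sim, restarts = config$nmds_restarts,
                         seed = config$seed)
  clusters <- cluster_overlay(sim, cluster_thresholds)

  message("stage comparison")
  tests <- compare_rivers(replicates,
                          intersect(test_metrics, names(replicates)),
                          config)

  smry <- merge(merge(pooled, summarize_replicates(replicates),
                      by = "river"), as.data.frame(hhi),
                by = "river", all.x = TRUE)

  report <- structure(
    list(summary = smry, replicates = replicates, pooled = pooled,
         hhi = hhi, similarity = sim, ordination = ord,
         clusters = clusters, tests = tests, config = config,
         meta = list(seed = config$seed,
                     package_version =
                       as.character(utils::packageVersion("odocon")),
                     r_version = as.character(getRversion()),
                     n_records = nrow(survey),
                     n_units = nrow(registry),
                     timestamp = format(Sys.time(), tz = "UTC"))),
    class = "odocon_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a report bundle to disk
#'
#' @param report an `odocon_report` from [run_assessment()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                        row.names = FALSE)
  w(report$summary, "summary.csv")
  w(report$replicates, "replicates.csv")
  w(as.data.frame(report$hhi), "hhi.csv")
  tests <- do.call(rbind, lapply(report$tests, function(t) data.frame(
    metric = t$metric, method = t$method, statistic = t$statistic,
    df = paste(t$df, collapse = ";"), p_value = t$p_value,
    stringsAsFactors = FALSE)))
  w(tests, "tests.csv")
  pw <- do.call(rbind, lapply(report$tests, function(t) data.frame(
    metric = t$metric,
    group_a = t$pairwise$group_a, group_b = t$pairwise$group_b,
    statistic = if (!is.null(t$pairwise$z)) t$pairwise$z else
      t$pairwise$diff,
    p_adjusted = t$pairwise$p_adjusted,
    significant = t$pairwise$significant, stringsAsFactors = FALSE)))
  w(pw, "pairwise.csv")
  lt <- do.call(rbind, lapply(report$tests, function(t) data.frame(
    metric = t$metric, river = names(t$letters), letter = t$letters,
    stringsAsFactors = FALSE)))
  w(lt, "letters.csv")
  coords <- as.data.frame(report$ordination$coordinates)
  names(coords) <- paste0("nmds", seq_len(ncol(coords)))
  ord <- cbind(unit = rownames(report$ordination$coordinates), coords,
               stress = report$ordination$stress)
  ord <- merge(ord, report$clusters, by = "unit")
  w(ord, "ordination.csv")
  jsonlite::write_json(
    c(report$meta,
      list(config = unclass(report$config))),
    file.path(out_dir, "run.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA, always_decimal = FALSE)
  invisible(out_dir)
}

#' @export
print.odocon_report <- function(x, ...) {
  cat("odocon assessment report\n")
  cat("  rivers:", paste(x$summary$river, collapse = ", "), "\n")
  cat("  replicates:", nrow(x$replicates), "(unit",
      x$config$replicate_unit, ")\n")
  cat("  NMDS stress:", format(x$ordination$stress, digits = 4), "\n")
  for (t in x$tests) print(t)
  invisible(x)
}

#' Plot a report (optional artifact)
#'
#' Base-graphics two-panel figure: NMDS configuration with cluster
#' symbols, and per-river Renyi profiles of the pooled assemblages.
#' Purely cosmetic; no analysis depends on it.
#'
#' @param x an `odocon_report`.
#' @param survey the survey used (for the pooled profiles); if `NULL`
#'   only the NMDS panel is drawn.
#' @param ... unused.
#' @export
plot.odocon_report <- function(x, survey = NULL, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(survey)) 1 else 2))
  on.exit(graphics::par(op))
  co <- x$ordination$coordinates
  grp <- x$clusters[[ncol(x$clusters)]]
  graphics::plot(co, pch = grp, col = grp,
                 xlab = "NMDS1", ylab = "NMDS2",
                 main = sprintf("NMDS (stress %.3f)", x$ordination$stress))
  if (!is.null(survey)) {
    rivers <- sort(unique(survey$river))
    alphas <- x$config$renyi_alphas
    fin <- is.finite(alphas)
    graphics::plot(NULL, xlim = range(alphas[fin]), ylim = c(0, 3.5),
                   xlab = "scale parameter", ylab = "Renyi diversity",
                   main = "Renyi profiles")
    for (i in seq_along(rivers)) {
      counts <- tapply(survey$count[survey$river == rivers[i]],
                       survey$species[survey$river == rivers[i]], sum)
      pr <- renyi_profile(counts, alphas[fin])
      graphics::lines(pr$alpha, pr$value, col = i, type = "b", pch = i)
    }
    graphics::legend("topright", legend = rivers, col = seq_along(rivers),
                     pch = seq_along(rivers), bty = "n")
  }
  invisible(x)
}
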