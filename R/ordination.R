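#' Log abundance transform
#'
#' Elementwise `log(x + 1)` (natural log by default, base 10 optional),
#' the usual compression applied to absolute abundance data before
#' computing Bray-Curtis similarities so that a few very abundant species
#' do not dominate the ordination.
#'
#' @param x numeric vector or matrix of counts (>= 0).
#' @param base `"natural"` or `"10"`.
#' @return transformed object of the same shape.
#' @export
log_transform <- function(x, base = c("natural", "10")) {
  base <- match.arg(base)
  if (any(x < 0, na.rm = TRUE))
    stop("abundances must be non-negative", call. = FALSE)
  if (base == "natural") log1p(x) else log10(x + 1)
}

#' Bray-Curtis similarity between two abundance vectors
#'
#' \eqn{100 (1 - \sum_i |x_i - y_i| / \sum_i (x_i + y_i))}, on a 0-100
#' percent scale. Undefined (NA) when both vectors are all zero, matching
#' the convention of excluding empty samples from ordination.
#'
#' @param x,y equal-length non-negative numeric vectors.
#' @return similarity in [0, 100], or `NA` for two empty samples.
#' @examples
#' bray_curtis(c(2, 2, 0), c(2, 0, 0))  # 100 * (1 - 2/6)
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors must have equal length", call. = FALSE)
  if (any(x < 0) || any(y < 0))
    stop("abundances must be non-negative", call. = FALSE)
  tot <- sum(x + y)
  if (tot == 0) return(NA_real_)
  100 * (1 - sum(abs(x - y)) / tot)
}

#' Bray-Curtis similarity matrix of replicate units
#'
#' Builds the unit x species abundance matrix over the registry, drops
#' units with no species (they have no defined similarity to anything;
#' a message lists them), applies the log transform, and returns the
#' symmetric percent-similarity matrix.
#'
#' @param survey an `odocon_survey`.
#' @param registry an `odocon_registry`.
#' @param config an [odocon_config()] (`replicate_unit`, `log_base`).
#' @param transform apply the log transform first (`TRUE`, default).
#' @return symmetric numeric matrix (diagonal 100) with unit ids as
#'   dimnames; attribute `units` carries the unit metadata.
#' @export
bray_curtis_matrix <- function(survey, registry, config = odocon_config(),
                               transform = TRUE) {
  um <- .unit_matrix(survey, registry, config$replicate_unit)
  m <- um$matrix
  keep <- rowSums(m) > 0
  if (any(!keep))
    message("dropping empty unit(s) from ordination: ",
            paste(rownames(m)[!keep], collapse = ", "))
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) stop("no non-empty units", call. = FALSE)
  if (transform) m <- log_transform(m, config$log_base)
  n <- nrow(m)
  sim <- matrix(100, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      sim[i, j] <- sim[j, i] <- bray_curtis(m[i, ], m[j, ])
  structure(sim, units = um$units[keep, , drop = FALSE])
}

#' Non-metric multidimensional scaling of a similarity matrix
#'
#' Two-dimensional NMDS on dissimilarity `100 - similarity`, minimizing
#' Kruskal stress-1 by monotone regression over multiple seeded random
#' starts (delegated to \pkg{vegan}'s `metaMDS`/`monoMDS` engine). The
#' reported stress is the best over restarts; results are reproducible
#' from the seed.
#'
#' @param sim symmetric similarity matrix in [0, 100] (e.g. from
#'   [bray_curtis_matrix()]).
#' @param k embedding dimension (default 2).
#' @param restarts number of random starts.
#' @param seed integer seed.
#' @return list of class `odocon_nmds` with `coordinates` (units x k
#'   matrix), `stress` (Kruskal stress-1, 0-1 scale), `n_restarts`,
#'   `seed`.
#' @export
nmds_ordination <- function(sim, k = 2L, restarts = 50L, seed = 1L) {
  if (nrow(sim) < 3L)
    stop("NMDS needs at least 3 units", call. = FALSE)
  d <- stats::as.dist(100 - sim)
  fit <- .with_seed(seed,
    vegan::metaMDS(d, k = k, try = restarts, trymax = restarts,
                   trace = 0, autotransform = FALSE, wascores = FALSE))
  structure(list(coordinates = fit$points, stress = fit$stress,
                 n_restarts = as.integer(restarts),
                 seed = as.integer(seed)),
            class = "odocon_nmds")
}

#' @export
print.odocon_nmds <- function(x, ...) {
  cat("NMDS ordination:", nrow(x$coordinates), "units,",
      ncol(x$coordinates), "dimensions\n")
  cat(sprintf("stress (Kruskal-1): %.4f over %d restarts (seed %d)\n",
              x$stress, x$n_restarts, x$seed))
  invisible(x)
}

#' UPGMA cluster overlay at similarity thresholds
#'
#' Group-average (UPGMA) agglomeration on dissimilarity `100 - sim`; for
#' each threshold `t` the units are partitioned into the connected groups
#' of the dendrogram cut at similarity `t` (i.e. groups whose members are
#' linked at similarity >= t). Superimposing these groups on the NMDS
#' plane is the standard way of reading cluster structure into an
#' ordination.
#'
#' @param sim symmetric similarity matrix in [0, 100].
#' @param thresholds numeric vector of similarity thresholds in [0, 100].
#' @return data.frame with one row per unit and one `cut_<t>` integer
#'   group column per threshold; attribute `hclust` carries the tree.
#' @export
cluster_overlay <- function(sim, thresholds = c(20, 40)) {
  if (any(thresholds < 0 | thresholds > 100))
    stop("thresholds must lie in [0, 100]", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(100 - sim), method = "average")
  out <- data.frame(unit = rownames(sim), stringsAsFactors = FALSE)
  for (t in thresholds)
    out[[sprintf("cut_%g", t)]] <- stats::cutree(hc, h = 100 - t)
  structure(out, hclust = hc)
}
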