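#' Per-species Dragonfly Biotic Index
#'
#' The DBI scores each species as the sum of three 0-3 subscores:
#' regional distribution, national red-list classification, and
#' sensitivity to habitat change. A widespread, non-threatened, tolerant
#' species scores 0 (0 + 0 + 0); a range-restricted, highly threatened,
#' extremely sensitive species scores the maximum 9 (3 + 3 + 3). The
#' subscores are expert-assigned inputs carried in the trait table, not
#' computed.
#'
#' @param traits an `odocon_traits` (or any data.frame with the three
#'   `dbi_*` columns and `species`).
#' @return data.frame of class `dbi_score` with columns
#'   `species,dbi_distribution,dbi_redlist,dbi_sensitivity,dbi`.
#' @examples
#' tr <- data.frame(species = "X y", dbi_distribution = 3,
#'                  dbi_redlist = 3, dbi_sensitivity = 3)
#' dbi_species(tr)$dbi  # 9
#' @export
dbi_species <- function(traits) {
  cols <- c("dbi_distribution", "dbi_redlist", "dbi_sensitivity")
  .require_columns(traits, c("species", cols), "DBI", "<traits>")
  for (k in cols) {
    v <- traits[[k]]
    if (any(is.na(v) | v != round(v) | v < 0 | v > 3))
      stop(k, " must be an integer in {0,1,2,3}", call. = FALSE)
  }
  out <- data.frame(species = traits$species,
                    dbi_distribution = as.integer(traits$dbi_distribution),
                    dbi_redlist = as.integer(traits$dbi_redlist),
                    dbi_sensitivity = as.integer(traits$dbi_sensitivity),
                    stringsAsFactors = FALSE)
  out$dbi <- out$dbi_distribution + out$dbi_redlist + out$dbi_sensitivity
  class(out) <- c("dbi_score", "data.frame")
  out
}

#' Standardized DBI of an assemblage
#'
#' Mean per-species DBI over the species present in a unit: the sum of
#' the DBI values of all species occurring there divided by the number of
#' species. Bounded in [0, 9]; equals the single species' DBI when only
#' one is present; `NA` for an empty assemblage.
#'
#' @param species character vector of species present.
#' @param traits an `odocon_traits` covering them.
#' @return a single numeric value.
#' @export
standardized_dbi <- function(species, traits) {
  species <- unique(normalize_species(species))
  species <- species[nzchar(species)]
  if (!length(species)) return(NA_real_)
  .assert_traits_cover(species, traits)
  d <- dbi_species(traits)
  mean(d$dbi[match(species, d$species)])
}

#' Red-list conservation score
#'
#' Maps red-list categories to the additive scores used in the CCOI.
#' By default only near-threatened species contribute (0.5 points each);
#' LC and not-assessed species score 0. Threatened categories (VU, EN, CR)
#' have no canonical weight here and must be supplied explicitly via the
#' score map, otherwise an error instructs configuration.
#'
#' @param categories character vector of red-list categories.
#' @param score_map named numeric vector, e.g.
#'   `c(LC = 0, "NA" = 0, NT = 0.5)`.
#' @return numeric vector of scores, same length as `categories`.
#' @examples
#' rlc_score(c("LC", "NT"))  # 0.0 0.5
#' @export
rlc_score <- function(categories,
                      score_map = c(LC = 0, "NA" = 0, NT = 0.5)) {
  categories <- toupper(trimws(as.character(categories)))
  bad <- setdiff(unique(categories), REDLIST_LEVELS)
  if (length(bad))
    stop("unknown red-list categories: ", paste(bad, collapse = ", "),
         " (permitted: ", paste(REDLIST_LEVELS, collapse = ", "), ")",
         call. = FALSE)
  unmapped <- setdiff(unique(categories), names(score_map))
  if (length(unmapped))
    stop("no RLC score configured for categories: ",
         paste(unmapped, collapse = ", "),
         "; extend rlc_score_map in odocon_config()", call. = FALSE)
  unname(score_map[categories])
}

#' Croatian Conservation Odonatological Index
#'
#' Composite presence/absence conservation index of an assemblage:
#' \deqn{CCOI = \frac{(F+G)/2 \times (3E + 3S + R + \Sigma RTD +
#'   \Sigma RLC)}{N}}
#' where F and G are the numbers of families and genera, E the number of
#' endemic species, S the number of semivoltine species, R the remaining
#' species, \eqn{\Sigma RTD} the accumulated relative taxonomic
#' distinctness, \eqn{\Sigma RLC} the summed red-list scores and N the
#' total number of species. Endemic and semivoltine species are weighted
#' three-fold, so taxonomically broad assemblages rich in endemic,
#' slow-developing or threatened species score highest.
#'
#' With `config$ccoi_overlap = "set"` (default) a species carrying both
#' flags is credited once in E and once in S while
#' \eqn{R = N - |E \cup S|}, so R never goes negative;
#' `"exclusive"` instead errors if any species carries both flags.
#' `rtd_values` defaults to the assemblage's own RTD (the single-replicate
#' scope); pass the river's per-replicate RTD values for the river-scope
#' accumulation.
#'
#' @param species character vector of species present.
#' @param traits an `odocon_traits` covering them.
#' @param rtd_values numeric vector whose sum is the \eqn{\Sigma RTD} term;
#'   default `NULL` uses `rtd(species, traits)$rtd`. `NA` entries dropped.
#' @param config an [odocon_config()] (RLC map, overlap rule).
#' @return one-row data.frame of class `ccoi_result` with columns
#'   `F,G,E,S,R,sum_rtd,sum_rlc,N,ccoi`. Empty input returns `ccoi = NA`
#'   with a warning.
#' @examples
#' tr <- as_traits(data.frame(
#'   species = "Genus01 spa", family = "FamilyA", genus = "Genus01",
#'   endemic = FALSE, semivoltine = FALSE, redlist = "LC",
#'   dbi_distribution = 0, dbi_redlist = 0, dbi_sensitivity = 0))
#' ccoi("Genus01 spa", tr)$ccoi  # (1 * (1 + 1)) / 1 = 2
#' @export
ccoi <- function(species, traits, rtd_values = NULL,
                 config = odocon_config()) {
  species <- unique(normalize_species(species))
  species <- species[nzchar(species)]
  if (!length(species)) {
    warning("empty assemblage: CCOI undefined", call. = FALSE)
    return(structure(data.frame(F = 0L, G = 0L, E = 0L, S = 0L, R = 0L,
                                sum_rtd = NA_real_, sum_rlc = NA_real_,
                                N = 0L, ccoi = NA_real_),
                     class = c("ccoi_result", "data.frame")))
  }
  .assert_traits_cover(species, traits)
  idx <- match(species, traits$species)
  tr <- traits[idx, ]
  n <- length(species)
  e <- sum(tr$endemic)
  s <- sum(tr$semivoltine)
  both <- tr$endemic & tr$semivoltine
  if (config$ccoi_overlap == "exclusive" && any(both))
    stop("species both endemic and semivoltine under exclusive overlap ",
         "rule: ", paste(species[both], collapse = ", "), call. = FALSE)
  r <- n - sum(tr$endemic | tr$semivoltine)  # N - |E u S|
  tx <- rtd(species, traits)
  if (is.null(rtd_values)) rtd_values <- tx$rtd
  sum_rtd <- sum(rtd_values, na.rm = TRUE)
  sum_rlc <- sum(rlc_score(tr$redlist, config$rlc_score_map))
  value <- ((tx$n_family + tx$n_genus) / 2 *
              (3 * e + 3 * s + r + sum_rtd + sum_rlc)) / n
  structure(data.frame(F = tx$n_family, G = tx$n_genus, E = e, S = s,
                       R = r, sum_rtd = sum_rtd, sum_rlc = sum_rlc,
                       N = n, ccoi = value),
            class = c("ccoi_result", "data.frame"))
}

#' Per-replicate conservation indices
#'
#' Standardized DBI and CCOI (with all CCOI components) for every
#' replicate unit in the registry. Empty replicates carry `NA` for both
#' indices. With `config$ccoi_scope = "river"`, the \eqn{\Sigma RTD} term
#' of each replicate's CCOI is the sum of the per-replicate RTD values of
#' its river (accumulated scope); the default `"replicate"` scope uses the
#' replicate's own RTD.
#'
#' @param survey an `odocon_survey`.
#' @param registry an `odocon_registry`.
#' @param traits an `odocon_traits` covering every surveyed species.
#' @param config an [odocon_config()].
#' @return data.frame: the [per_replicate_metrics()] columns plus
#'   `dbi_standardized`, the CCOI components and `ccoi`.
#' @export
conservation_replicates <- function(survey, registry, traits,
                                    config = odocon_config()) {
  .assert_traits_cover(survey$species, traits)
  base <- per_replicate_metrics(survey, registry, traits, config)
  um <- .unit_matrix(survey, registry, config$replicate_unit)
  m <- um$matrix
  comp <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    sp <- colnames(m)[m[i, ] > 0]
    rv <- if (config$ccoi_scope == "river")
      base$rtd[base$river == base$river[i]] else NULL
    comp[[i]] <- if (length(sp))
      suppressWarnings(ccoi(sp, traits, rtd_values = rv, config = config))
    else
      data.frame(F = 0L, G = 0L, E = 0L, S = 0L, R = 0L,
                 sum_rtd = NA_real_, sum_rlc = NA_real_, N = 0L,
                 ccoi = NA_real_)
    comp[[i]]$dbi_standardized <- if (length(sp))
      standardized_dbi(sp, traits) else NA_real_
  }
  comp <- do.call(rbind, comp)
  cbind(base, comp[c("dbi_standardized", "F", "G", "E", "S", "R",
                     "sum_rtd", "sum_rlc", "N", "ccoi")])
}
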