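#' Renyi diversity profile
#'
#' Computes the Renyi entropy of order \eqn{\alpha} for an assemblage with
#' relative abundances \eqn{p_i}:
#' \deqn{H_\alpha = \frac{\ln \sum_i p_i^\alpha}{1-\alpha}}
#' with the analytic limits \eqn{H_1 = -\sum_i p_i \ln p_i} (Shannon) and
#' \eqn{H_\infty = -\ln \max_i p_i} (Berger-Parker); \eqn{H_0 = \ln S}
#' (log richness) and \eqn{H_2} is the log of the inverse Simpson
#' concentration. Natural logarithm throughout. The profile is
#' non-increasing in \eqn{\alpha}, so plotting it against \eqn{\alpha}
#' ranks assemblages by diversity across the whole rare-to-dominant
#' sensitivity spectrum.
#'
#' @param x numeric vector of abundances (zeros are dropped; names are
#'   species and optional).
#' @param alphas non-negative scale parameters; `Inf` allowed.
#' @return data.frame of class `renyi_profile` with columns `alpha,value`
#'   and attributes `richness` and `abundance`. An empty assemblage gives
#'   an all-`NA` profile (not zeros).
#' @examples
#' renyi_profile(c(2, 1, 1), alphas = c(0, 1, 2, Inf))
#' @export
renyi_profile <- function(x, alphas = c(0, 0.25, 0.5, 1, 2, 4, 8, Inf)) {
  if (any(is.na(alphas)) || any(alphas < 0))
    stop("alphas must be non-negative", call. = FALSE)
  x <- x[!is.na(x)]
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  x <- x[x > 0]
  out <- data.frame(alpha = alphas, value = NA_real_)
  if (length(x)) {
    p <- x / sum(x)
    out$value <- vapply(alphas, function(a) {
      if (a == 0) log(length(p))
      else if (a == 1) -sum(p * log(p))
      else if (is.infinite(a)) -log(max(p))
      else log(sum(p^a)) / (1 - a)
    }, numeric(1))
  }
  structure(out, richness = length(x), abundance = sum(x),
            class = c("renyi_profile", "data.frame"))
}

#' Relative taxonomic distinctness
#'
#' Presence-based measure of how taxonomically concentrated an assemblage
#' is:
#' \deqn{RTD = 1 / \sqrt{N_{family} \times N_{genus} \times N_{species}}}
#' where each \eqn{N} counts distinct units of that rank present. RTD is 1
#' for a single species and decreases as taxonomic breadth grows; an
#' assemblage of closely related species (few families/genera) scores
#' higher than an equally rich but taxonomically scattered one.
#'
#' @param species character vector of species present (duplicates ignored).
#' @param traits an `odocon_traits` supplying family and genus per species.
#' @return one-row data.frame of class `rtd_result` with columns
#'   `n_family,n_genus,n_species,rtd`. Empty input gives `rtd = NA`.
#' @examples
#' tr <- as_traits(data.frame(
#'   species = c("Genus01 spa", "Genus01 spb"), family = "FamilyA",
#'   genus = "Genus01", endemic = FALSE, semivoltine = FALSE,
#'   redlist = "LC", dbi_distribution = 0, dbi_redlist = 0,
#'   dbi_sensitivity = 0))
#' rtd(tr$species, tr)$rtd  # 1/sqrt(1 * 1 * 2)
#' @export
rtd <- function(species, traits) {
  species <- unique(normalize_species(species))
  species <- species[nzchar(species)]
  if (!length(species))
    return(structure(data.frame(n_family = 0L, n_genus = 0L,
                                n_species = 0L, rtd = NA_real_),
                     class = c("rtd_result", "data.frame")))
  idx <- match(species, traits$species)
  if (anyNA(idx))
    stop("missing taxonomy for: ",
         paste(species[is.na(idx)], collapse = ", "), call. = FALSE)
  nf <- length(unique(traits$family[idx]))
  ng <- length(unique(traits$genus[idx]))
  ns <- length(species)
  structure(data.frame(n_family = nf, n_genus = ng, n_species = ns,
                       rtd = 1 / sqrt(nf * ng * ns)),
            class = c("rtd_result", "data.frame"))
}

# Abundance matrix (units x species) over the replicate units implied by
# the registry; empty units are all-zero rows. Errors if the survey holds
# samples outside the registry.
.unit_matrix <- function(survey, registry, replicate_unit = "site_event") {
  skey <- if (replicate_unit == "site_event")
    paste(survey$river, survey$site, survey$event, sep = "|") else
      paste(survey$river, survey$event, sep = "|")
  reg <- as.data.frame(registry)
  units <- if (replicate_unit == "site_event")
    unique(reg[c("river", "site", "event")]) else
      unique(reg[c("river", "event")])
  ukey <- do.call(paste, c(units, sep = "|"))
  miss <- setdiff(unique(skey), ukey)
  if (length(miss))
    stop("survey contains replicate unit(s) absent from registry: ",
         paste(miss, collapse = "; "), call. = FALSE)
  species <- sort(unique(survey$species))
  m <- matrix(0, nrow = nrow(units), ncol = length(species),
              dimnames = list(ukey, species))
  if (nrow(survey)) {
    i <- match(skey, ukey)
    j <- match(survey$species, species)
    for (r in seq_len(nrow(survey)))
      m[i[r], j[r]] <- m[i[r], j[r]] + survey$count[r]
  }
  list(units = units, matrix = m)
}

#' Per-replicate diversity metrics
#'
#' One row per replicate unit (site x event by default) per river, with
#' species richness, total abundance, and - when a trait table is given -
#' relative taxonomic distinctness. Units registered but never yielding a
#' record appear with richness 0 and abundance 0; their RTD is `NA`
#' (undefined, excluded pairwise downstream) rather than 0.
#'
#' @param survey an `odocon_survey`.
#' @param registry an `odocon_registry` covering every surveyed unit.
#' @param traits optional `odocon_traits` for the RTD column.
#' @param config an [odocon_config()]; `replicate_unit` selects the
#'   aggregation level.
#' @return data.frame with columns `river` (plus `site`/`event` as
#'   applicable), `unit`, `richness`, `abundance` and optionally `rtd`.
#' @export
per_replicate_metrics <- function(survey, registry, traits = NULL,
                                  config = odocon_config()) {
  um <- .unit_matrix(survey, registry, config$replicate_unit)
  m <- um$matrix
  out <- um$units
  out$unit <- rownames(m)
  out$richness <- as.integer(rowSums(m > 0))
  out$abundance <- as.integer(rowSums(m))
  if (!is.null(traits)) {
    .assert_traits_cover(colnames(m), traits)
    out$rtd <- vapply(seq_len(nrow(m)), function(i) {
      sp <- colnames(m)[m[i, ] > 0]
      if (!length(sp)) NA_real_ else rtd(sp, traits)$rtd
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Pooled per-river richness and abundance
#'
#' Species richness pooled over all sites and events of each river (the
#' reporting default for "species per river") together with total
#' abundance.
#'
#' @param survey an `odocon_survey`.
#' @return data.frame with columns `river,richness_pooled,abundance`.
#' @export
pooled_river_metrics <- function(survey) {
  rivers <- sort(unique(survey$river))
  data.frame(
    river = rivers,
    richness_pooled = vapply(rivers, function(r)
      length(unique(survey$species[survey$river == r])), integer(1)),
    abundance = vapply(rivers, function(r)
      sum(survey$count[survey$river == r]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
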