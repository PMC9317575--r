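#' Specification for synthetic survey data
#'
#' Parameter object for the seeded generators. The defaults emulate a
#' replicated Mediterranean intermittent-river survey: 4 rivers x 3 sites x
#' 3 sampling events, a 25-species regional pool with a per-river richness
#' gradient (4, 9, 14, 18), one site with no records at all, a small
#' fraction of near-threatened species, and land-cover compositions over
#' 4-8 classes whose concentration index spans roughly 3000-5500.
#'
#' @param n_rivers number of rivers.
#' @param sites_per_river study sites per river.
#' @param events sampling events (each site is visited at every event).
#' @param pool_size size of the regional species pool.
#' @param per_river_richness integer vector (length `n_rivers`) of realized
#'   per-river species pools, imposed by construction so parameter-recovery
#'   tests have known ground truth.
#' @param abundance_dispersion negative-binomial size parameter of the
#'   count distribution (smaller = more clumped).
#' @param mean_abundance mean count of a species present in a sample;
#'   counts are truncated at >= 1.
#' @param occupancy probability that a river-pool species occurs in a given
#'   site x event sample of its river.
#' @param taxonomy_shape list with `n_families` and `n_genera` controlling
#'   how the pool is partitioned taxonomically.
#' @param trait_probs list with elements `endemic`, `semivoltine`
#'   (Bernoulli probabilities) and `redlist` (named probability vector over
#'   red-list categories).
#' @param landcover_classes integer vector of class counts per river
#'   (recycled to `n_rivers`).
#' @param landcover_concentration symmetric Dirichlet concentration of the
#'   land-cover composition; smaller values give more uneven compositions
#'   and hence higher heterogeneity-index values.
#' @param empty_site_quota number of (river, site) pairs forced to have no
#'   records in any event.
#' @param seed master seed; generator substreams use fixed offsets
#'   (taxonomy +1000, traits +2000, survey +3000, land cover +4000).
#'
#' @return an object of class `synthesis_spec`.
#' @examples
#' sp <- synthesis_spec(seed = 7)
#' dat <- synthesize_dataset(sp)
#' nrow(dat$registry)  # 4 rivers x 3 sites x 3 events = 36
#' @export
synthesis_spec <- function(n_rivers = 4L,
                           sites_per_river = 3L,
                           events = 3L,
                           pool_size = 25L,
                           per_river_richness = c(4L, 9L, 14L, 18L),
                           abundance_dispersion = 1,
                           mean_abundance = 5,
                           occupancy = 0.6,
                           taxonomy_shape = list(n_families = 7L,
                                                 n_genera = 16L),
                           trait_probs = list(endemic = 0.08,
                                              semivoltine = 0.12,
                                              redlist = c(LC = 0.88,
                                                          NT = 0.12)),
                           landcover_classes = c(4L, 5L, 8L, 7L),
                           landcover_concentration = 0.5,
                           empty_site_quota = 1L,
                           seed = 1L) {
  n_rivers <- as.integer(n_rivers)
  per_river_richness <- as.integer(per_river_richness)
  if (length(per_river_richness) != n_rivers)
    stop("per_river_richness must have one entry per river", call. = FALSE)
  if (any(per_river_richness > pool_size))
    stop("per-river richness cannot exceed pool_size", call. = FALSE)
  if (any(per_river_richness < 0L))
    stop("per-river richness must be non-negative", call. = FALSE)
  stopifnot(sites_per_river >= 1L, events >= 1L, pool_size >= 1L,
            abundance_dispersion > 0, mean_abundance >= 1,
            landcover_concentration > 0)
  if (occupancy < 0 || occupancy > 1)
    stop("occupancy must be in [0, 1]", call. = FALSE)
  for (p in c(trait_probs$endemic, trait_probs$semivoltine,
              trait_probs$redlist))
    if (p < 0 || p > 1) stop("trait probabilities must be in [0, 1]",
                             call. = FALSE)
  if (abs(sum(trait_probs$redlist) - 1) > 1e-8)
    stop("trait_probs$redlist must sum to 1", call. = FALSE)
  bad <- setdiff(names(trait_probs$redlist), REDLIST_LEVELS)
  if (length(bad))
    stop("unknown red-list categories in trait_probs: ",
         paste(bad, collapse = ", "), call. = FALSE)
  landcover_classes <- rep_len(as.integer(landcover_classes), n_rivers)
  if (any(landcover_classes < 1L))
    stop("landcover_classes must be >= 1", call. = FALSE)
  if (empty_site_quota < 0L ||
      empty_site_quota > n_rivers * sites_per_river)
    stop("empty_site_quota out of range", call. = FALSE)
  structure(
    list(n_rivers = n_rivers, sites_per_river = as.integer(sites_per_river),
         events = as.integer(events), pool_size = as.integer(pool_size),
         per_river_richness = per_river_richness,
         abundance_dispersion = abundance_dispersion,
         mean_abundance = mean_abundance, occupancy = occupancy,
         taxonomy_shape = taxonomy_shape, trait_probs = trait_probs,
         landcover_classes = landcover_classes,
         landcover_concentration = landcover_concentration,
         empty_site_quota = as.integer(empty_site_quota),
         seed = as.integer(seed)),
    class = "synthesis_spec")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Deterministic pool taxonomy
#'
#' Partitions the regional species pool into genera and genera into
#' families; every family and (pool permitting) every genus is used at
#' least once. Names are synthetic placeholders (`Genus01 sp01`).
#'
#' @param spec a [synthesis_spec()].
#' @return data.frame with columns `species,genus,family`, `pool_size` rows.
#' @export
generate_taxonomy <- function(spec) {
  ng <- min(spec$taxonomy_shape$n_genera, spec$pool_size)
  nf <- min(spec$taxonomy_shape$n_families, ng)
  .with_seed(spec$seed + 1000L, {
    genera <- sprintf("Genus%02d", seq_len(ng))
    fam_of_genus <- c(seq_len(nf),
                      if (ng > nf) sample.int(nf, ng - nf, replace = TRUE))
    genus_of_sp <- c(seq_len(ng),
                     if (spec$pool_size > ng)
                       sample.int(ng, spec$pool_size - ng, replace = TRUE))
    genus_of_sp <- sort(genus_of_sp)
    idx <- stats::ave(genus_of_sp, genus_of_sp, FUN = seq_along)
    data.frame(
      species = sprintf("%s sp%02d", genera[genus_of_sp], idx),
      genus = genera[genus_of_sp],
      family = sprintf("Family%02d", fam_of_genus[genus_of_sp]),
      stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic survey and its sample registry
#'
#' Draws per-river species pools of the requested sizes from the global
#' pool, samples presence at each site x event by independent occupancy
#' draws (with a guarantee that every river-pool species is observed at
#' least once, so realized per-river richness equals the requested value),
#' and draws counts for present species from a zero-truncated negative
#' binomial. `empty_site_quota` (river, site) pairs, chosen by a seeded
#' draw, have all their records suppressed and all river-pool species
#' re-routed to the remaining sites.
#'
#' @param spec a [synthesis_spec()].
#' @return list with `survey` (an `odocon_survey`) and `registry` (an
#'   `odocon_registry` covering every surveyed sample, including empty
#'   ones).
#' @export
generate_survey <- function(spec) {
  taxo <- generate_taxonomy(spec)
  rivers <- sprintf("river%d", seq_len(spec$n_rivers))
  sites <- sprintf("S%d", seq_len(spec$sites_per_river))
  evts <- sprintf("E%d", seq_len(spec$events))
  registry <- expand.grid(event = evts, site = sites, river = rivers,
                          stringsAsFactors = FALSE)[, c("river", "site",
                                                        "event")]
  .with_seed(spec$seed + 3000L, {
    # choose the forced-empty (river, site) pairs up front
    all_pairs <- expand.grid(site = sites, river = rivers,
                             stringsAsFactors = FALSE)
    empty_idx <- if (spec$empty_site_quota > 0L)
      sample.int(nrow(all_pairs), spec$empty_site_quota) else integer(0)
    empty_key <- paste(all_pairs$river[empty_idx],
                       all_pairs$site[empty_idx])
    rec <- vector("list", spec$n_rivers)
    for (i in seq_len(spec$n_rivers)) {
      rich <- spec$per_river_richness[i]
      if (rich == 0L) next
      pool_i <- sort(sample(taxo$species, rich))
      open_sites <- sites[!(paste(rivers[i], sites) %in% empty_key)]
      if (!length(open_sites))
        stop("river ", rivers[i], " has positive richness but every site ",
             "is forced empty", call. = FALSE)
      combos <- expand.grid(event = evts, site = open_sites,
                            stringsAsFactors = FALSE)
      nc <- nrow(combos)
      rows <- list()
      for (sp in pool_i) {
        pres <- stats::rbinom(nc, 1L, spec$occupancy) == 1L
        if (!any(pres)) pres[sample.int(nc, 1L)] <- TRUE
        n <- sum(pres)
        counts <- 1L + stats::rnbinom(n, size = spec$abundance_dispersion,
                                      mu = spec$mean_abundance - 1)
        rows[[sp]] <- data.frame(river = rivers[i],
                                 site = combos$site[pres],
                                 event = combos$event[pres],
                                 species = sp, count = as.integer(counts),
                                 stringsAsFactors = FALSE)
      }
      rec[[i]] <- do.call(rbind, rows)
    }
    rec <- do.call(rbind, rec)
    rec <- rec[order(rec$river, rec$site, rec$event, rec$species), ]
    list(survey = as_survey(rec), registry = as_registry(registry))
  })
}

#' Generate a synthetic species trait table
#'
#' Taxonomy comes from the deterministic pool partition
#' ([generate_taxonomy()]); endemism and voltinism flags and red-list
#' categories are sampled from `spec$trait_probs`. The DBI red-list
#' subscore is made consistent with the category (LC/NA -> 0, NT -> 1,
#' VU -> 2, EN/CR -> 3); distribution and sensitivity subscores are drawn
#' skewed towards low values (most species are widespread and tolerant),
#' with the distribution subscore of endemic species floored at 2.
#'
#' @param species character vector of species to score.
#' @param spec a [synthesis_spec()].
#' @return an `odocon_traits` table, one row per species.
#' @export
generate_traits <- function(species, spec) {
  if (!length(species)) stop("empty species list", call. = FALSE)
  species <- normalize_species(unique(species))
  taxo <- generate_taxonomy(spec)
  idx <- match(species, taxo$species)
  genus <- ifelse(is.na(idx), vapply(strsplit(species, " "), `[`, "", 1L),
                  taxo$genus[idx])
  family <- ifelse(is.na(idx), paste0(genus, "idae"), taxo$family[idx])
  .with_seed(spec$seed + 2000L, {
    n <- length(species)
    endemic <- stats::rbinom(n, 1L, spec$trait_probs$endemic) == 1L
    semiv <- stats::rbinom(n, 1L, spec$trait_probs$semivoltine) == 1L
    rl <- sample(names(spec$trait_probs$redlist), n, replace = TRUE,
                 prob = spec$trait_probs$redlist)
    rl_sub <- c(LC = 0L, "NA" = 0L, NT = 1L, VU = 2L, EN = 3L, CR = 3L)[rl]
    distr <- sample(0:3, n, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    distr[endemic] <- pmax(distr[endemic], 2L)
    sens <- sample(0:3, n, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    as_traits(data.frame(
      species = species, family = family, genus = genus,
      endemic = endemic, semivoltine = semiv, redlist = rl,
      dbi_distribution = as.integer(distr),
      dbi_redlist = as.integer(rl_sub),
      dbi_sensitivity = as.integer(sens), stringsAsFactors = FALSE))
  })
}

#' Generate synthetic land-cover compositions
#'
#' Per-river compositions are drawn from a symmetric Dirichlet with the
#' requested concentration (via normalized gamma draws; concentrations are
#' capped at 1e8, at which point the composition is numerically uniform)
#' and expressed as percentages summing to 100. Class codes are drawn from
#' the level-3 CORINE stock seen around Mediterranean rivers; synthetic
#' codes are appended when more classes are requested than the stock holds.
#'
#' @param spec a [synthesis_spec()].
#' @return an `odocon_landcover` (percentage kind).
#' @export
generate_landcover <- function(spec) {
  stock <- c("112", "211", "221", "231", "242", "243", "311", "321", "324")
  conc <- min(spec$landcover_concentration, 1e8)
  rivers <- sprintf("river%d", seq_len(spec$n_rivers))
  .with_seed(spec$seed + 4000L, {
    out <- vector("list", spec$n_rivers)
    for (i in seq_len(spec$n_rivers)) {
      k <- spec$landcover_classes[i]
      codes <- if (k <= length(stock)) sort(sample(stock, k)) else
        c(stock, sprintf("syn%02d", seq_len(k - length(stock))))
      g <- stats::rgamma(k, shape = conc)
      if (sum(g) == 0) g <- rep(1, k)  # degenerate underflow guard
      pct <- 100 * g / sum(g)
      out[[i]] <- data.frame(river = rivers[i], class_code = codes,
                             value = pct, value_kind = "percentage",
                             stringsAsFactors = FALSE)
    }
    as_landcover(do.call(rbind, out))
  })
}

#' Generate the full synthetic bundle
#'
#' @param spec a [synthesis_spec()].
#' @return list with `survey`, `registry`, `traits` (for the whole pool)
#'   and `landcover`.
#' @export
synthesize_dataset <- function(spec = synthesis_spec()) {
  sv <- generate_survey(spec)
  taxo <- generate_taxonomy(spec)
  list(survey = sv$survey, registry = sv$registry,
       traits = generate_traits(taxo$species, spec),
       landcover = generate_landcover(spec))
}
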