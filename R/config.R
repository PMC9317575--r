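#' Pipeline configuration
#'
#' Builds the validated configuration object shared by all pipeline stages.
#' Unknown arguments are rejected so that typos in configuration files fail
#' loudly rather than silently falling back to defaults.
#'
#' @param replicate_unit unit treated as an independent replicate in
#'   among-river tests: `"site_event"` (default; one replicate per study site
#'   per sampling event) or `"river_event"`.
#' @param log_base base of the `log(x + 1)` abundance transform applied
#'   before Bray-Curtis similarity: `"natural"` (default) or `"10"`.
#' @param rlc_score_map named numeric vector mapping red-list categories to
#'   red-list conservation (RLC) scores. Defaults to `c(LC = 0, NA = 0,
#'   NT = 0.5)`; threatened categories (VU/EN/CR) must be supplied
#'   explicitly by the user when present in the data.
#' @param renyi_alphas non-negative scale parameters of the Renyi profile;
#'   `Inf` allowed. Default `c(0, 0.25, 0.5, 1, 2, 4, 8, Inf)` spans
#'   richness, Shannon, Simpson and Berger-Parker behaviour.
#' @param posthoc_adjustment multiplicity adjustment for Dunn-type pairwise
#'   comparisons; any method of [stats::p.adjust()]. Default `"bonferroni"`.
#' @param seed integer master seed for stochastic stages (NMDS restarts,
#'   synthesis).
#' @param alpha_level significance level in (0, 1) used by the normality
#'   gate, post hoc decisions and letter displays.
#' @param record_absences logical; if `TRUE`, survey rows with count 0 are
#'   accepted (explicit absences), otherwise rejected.
#' @param ccoi_overlap how species that are both endemic and semivoltine
#'   enter the CCOI bracket: `"set"` (default; credited in both E and S,
#'   with R = N - |E union S| so R never goes negative) or `"exclusive"`
#'   (an error if any species carries both flags).
#' @param ccoi_scope accumulation scope of the RTD and RLC sums inside the
#'   CCOI: `"replicate"` (default; the computing unit's own values) or
#'   `"river"` (summed across the river's replicates).
#' @param nmds_restarts number of random starts for the NMDS search.
#'
#' @return an object of class `odocon_config` (a named list).
#' @examples
#' cfg <- odocon_config(seed = 42)
#' cfg$renyi_alphas
#' @export
odocon_config <- function(replicate_unit = c("site_event", "river_event"),
                          log_base = c("natural", "10"),
                          rlc_score_map = c(LC = 0, "NA" = 0, NT = 0.5),
                          renyi_alphas = c(0, 0.25, 0.5, 1, 2, 4, 8, Inf),
                          posthoc_adjustment = "bonferroni",
                          seed = 1L,
                          alpha_level = 0.05,
                          record_absences = FALSE,
                          ccoi_overlap = c("set", "exclusive"),
                          ccoi_scope = c("replicate", "river"),
                          nmds_restarts = 50L) {
  replicate_unit <- match.arg(replicate_unit)
  log_base <- match.arg(log_base)
  ccoi_overlap <- match.arg(ccoi_overlap)
  ccoi_scope <- match.arg(ccoi_scope)
  if (!is.numeric(rlc_score_map) || is.null(names(rlc_score_map)))
    stop("`rlc_score_map` must be a named numeric vector", call. = FALSE)
  bad <- setdiff(names(rlc_score_map), REDLIST_LEVELS)
  if (length(bad))
    stop("unknown red-list categories in `rlc_score_map`: ",
         paste(bad, collapse = ", "),
         " (permitted: ", paste(REDLIST_LEVELS, collapse = ", "), ")",
         call. = FALSE)
  if (!is.numeric(renyi_alphas) || any(renyi_alphas < 0) ||
      any(is.na(renyi_alphas)))
    stop("`renyi_alphas` must be non-negative (Inf allowed)", call. = FALSE)
  posthoc_adjustment <- match.arg(posthoc_adjustment, stats::p.adjust.methods)
  if (!is.numeric(alpha_level) || length(alpha_level) != 1L ||
      alpha_level <= 0 || alpha_level >= 1)
    stop("`alpha_level` must be a single value in (0, 1)", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)
  nmds_restarts <- as.integer(nmds_restarts)
  if (is.na(nmds_restarts) || nmds_restarts < 1L)
    stop("`nmds_restarts` must be a positive integer", call. = FALSE)
  structure(
    list(replicate_unit = replicate_unit,
         log_base = log_base,
         rlc_score_map = rlc_score_map,
         renyi_alphas = sort(renyi_alphas),
         posthoc_adjustment = posthoc_adjustment,
         seed = seed,
         alpha_level = alpha_level,
         record_absences = isTRUE(record_absences),
         ccoi_overlap = ccoi_overlap,
         ccoi_scope = ccoi_scope,
         nmds_restarts = nmds_restarts),
    class = "odocon_config")
}

#' Read a configuration file
#'
#' Loads an `odocon_config` from a flat JSON file. Keys mirror the arguments
#' of [odocon_config()]; unknown keys are rejected.
#'
#' @param path path to a JSON configuration file.
#' @return an `odocon_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(odocon_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         " (permitted: ", paste(known, collapse = ", "), ")", call. = FALSE)
  if (!is.null(raw$rlc_score_map)) raw$rlc_score_map <- unlist(raw$rlc_score_map)
  if (!is.null(raw$renyi_alphas)) {
    a <- raw$renyi_alphas
    a[a == "Inf"] <- Inf
    raw$renyi_alphas <- as.numeric(a)
  }
  do.call(odocon_config, raw)
}

#' @export
print.odocon_config <- function(x, ...) {
  cat("odocon configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.null(names(v)))
      v <- paste(names(v), v, sep = "=", collapse = ", ")
    else
      v <- paste(format(v), collapse = ", ")
    cat(sprintf("  %-20s %s\n", nm, v))
  }
  invisible(x)
}

# permitted red-list categories ("NA" = not assessed, a literal category,
# never the R missing value)
REDLIST_LEVELS <- c("LC", "NT", "VU", "EN", "CR", "NA")
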