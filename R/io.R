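#' Normalize species binomials
#'
#' Trims outer whitespace, collapses internal runs of whitespace to single
#' spaces, case-folds the name and re-capitalizes the genus (first token).
#' Epithet and any subspecies tokens are kept in lower case; this makes
#' joins against the trait table deterministic regardless of transcription
#' casing.
#'
#' @param x character vector of species names.
#' @return normalized character vector of the same length.
#' @examples
#' normalize_species("  calopteryx   VIRGO ")
#' @export
normalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  x <- tolower(x)
  # capitalize the genus (first character) only
  out <- x
  nz <- nchar(x) > 0L
  out[nz] <- paste0(toupper(substr(x[nz], 1L, 1L)), substring(x[nz], 2L))
  out
}

.require_columns <- function(df, cols, what, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
}

.read_csv <- function(path, what) {
  if (!file.exists(path))
    stop(what, " file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = character(0), check.names = TRUE)
}

#' Read a long-format survey table
#'
#' Reads abundance records keyed by (river, site, event, species). Species
#' names are normalized on ingest ([normalize_species()]); duplicate keys
#' and non-integer counts are errors naming the offending row. Rows with
#' count 0 are rejected unless `config$record_absences` is `TRUE`.
#'
#' @param path CSV file with columns `river,site,event,species,count`.
#' @param config an [odocon_config()].
#' @return a data.frame of class `odocon_survey` with character keys and an
#'   integer `count` column; input row order preserved.
#' @seealso [write_survey()], [read_registry()]
#' @export
read_survey <- function(path, config = odocon_config()) {
  df <- .read_csv(path, "survey")
  .require_columns(df, c("river", "site", "event", "species", "count"),
                   "survey", path)
  df <- df[c("river", "site", "event", "species", "count")]
  as_survey(df, record_absences = config$record_absences)
}

#' Construct and validate a survey table
#'
#' @param df data.frame with columns `river,site,event,species,count`.
#' @param record_absences allow explicit zero-count rows.
#' @return a validated `odocon_survey` data.frame.
#' @export
as_survey <- function(df, record_absences = FALSE) {
  .require_columns(df, c("river", "site", "event", "species", "count"),
                   "survey", "<data.frame>")
  df <- as.data.frame(df)[c("river", "site", "event", "species", "count")]
  for (k in c("river", "site", "event")) df[[k]] <- as.character(df[[k]])
  df$species <- normalize_species(df$species)
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(cnt) | cnt != round(cnt) | cnt < 0)
  if (length(bad))
    stop("non-integer or negative count at row ", bad[1L],
         " (species ", df$species[bad[1L]], ")", call. = FALSE)
  df$count <- as.integer(cnt)
  if (!record_absences && any(df$count == 0L)) {
    i <- which(df$count == 0L)[1L]
    stop("count 0 at row ", i, " (", df$river[i], "/", df$site[i], "/",
         df$event[i], "/", df$species[i],
         "); set record_absences = TRUE to allow explicit absences",
         call. = FALSE)
  }
  key <- paste(df$river, df$site, df$event, df$species, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate survey key at row ", dup[1L], ": (",
         df$river[dup[1L]], ", ", df$site[dup[1L]], ", ",
         df$event[dup[1L]], ", ", df$species[dup[1L]], ")", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("odocon_survey", "data.frame")
  df
}

#' @rdname read_survey
#' @param survey an `odocon_survey`.
#' @export
write_survey <- function(survey, path) {
  utils::write.csv(as.data.frame(survey), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a species trait table
#'
#' One row per species with taxonomy, endemism and voltinism flags, the
#' national red-list category and the three Dragonfly Biotic Index
#' subscores (each 0-3). The red-list category `"NA"` means "not assessed"
#' and is a literal category, not a missing value.
#'
#' @param path CSV with columns
#'   `species,family,genus,endemic,semivoltine,redlist,dbi_distribution,dbi_redlist,dbi_sensitivity`.
#' @return a data.frame of class `odocon_traits`, one row per species.
#' @export
read_traits <- function(path) {
  df <- .read_csv(path, "traits")
  cols <- c("species", "family", "genus", "endemic", "semivoltine",
            "redlist", "dbi_distribution", "dbi_redlist", "dbi_sensitivity")
  .require_columns(df, cols, "traits", path)
  as_traits(df[cols])
}

#' @rdname read_traits
#' @param df data.frame with the trait columns.
#' @export
as_traits <- function(df) {
  cols <- c("species", "family", "genus", "endemic", "semivoltine",
            "redlist", "dbi_distribution", "dbi_redlist", "dbi_sensitivity")
  .require_columns(df, cols, "traits", "<data.frame>")
  df <- as.data.frame(df)[cols]
  if (nrow(df) == 0L) {
    warning("trait table is empty (header only)", call. = FALSE)
    df$species <- character(0)
  }
  df$species <- normalize_species(df$species)
  df$family <- trimws(as.character(df$family))
  df$genus <- normalize_species(df$genus)
  for (k in c("endemic", "semivoltine")) {
    v <- df[[k]]
    if (!is.logical(v)) v <- toupper(trimws(as.character(v))) %in%
        c("TRUE", "T", "1", "YES")
    df[[k]] <- v
  }
  df$redlist <- toupper(trimws(as.character(df$redlist)))
  bad <- setdiff(unique(df$redlist), REDLIST_LEVELS)
  if (length(bad))
    stop("unknown red-list code(s): ", paste(bad, collapse = ", "),
         " (permitted: ", paste(REDLIST_LEVELS, collapse = ", "), ")",
         call. = FALSE)
  for (k in c("dbi_distribution", "dbi_redlist", "dbi_sensitivity")) {
    v <- suppressWarnings(as.numeric(df[[k]]))
    bad <- which(is.na(v) | v != round(v) | v < 0 | v > 3)
    if (length(bad))
      stop(k, " out of range {0,1,2,3} at row ", bad[1L],
           " (species ", df$species[bad[1L]], ")", call. = FALSE)
    df[[k]] <- as.integer(v)
  }
  dup <- which(duplicated(df$species))
  if (length(dup))
    stop("duplicate species in trait table: ", df$species[dup[1L]],
         call. = FALSE)
  # genus should be a prefix of the binomial; tolerated with a warning
  # (hybrids, placeholder codes) since only distinct-genus counts use it
  pref <- startsWith(df$species, paste0(df$genus, " ")) |
    df$species == df$genus
  if (nrow(df) && any(!pref))
    warning("genus is not a prefix of the species binomial for: ",
            paste(df$species[!pref], collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("odocon_traits", "data.frame")
  df
}

#' @rdname read_traits
#' @param traits an `odocon_traits`.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a land-cover composition table
#'
#' Per-river class composition, either as raw areas or as percentages. All
#' entries of one river must share `value_kind`; percentage compositions
#' must sum to 100 within 1e-6 after normalization.
#'
#' @param path CSV with columns `river,class_code,value,value_kind`.
#' @return data.frame of class `odocon_landcover`.
#' @export
read_landcover <- function(path) {
  df <- .read_csv(path, "landcover")
  .require_columns(df, c("river", "class_code", "value", "value_kind"),
                   "landcover", path)
  as_landcover(df[c("river", "class_code", "value", "value_kind")])
}

#' @rdname read_landcover
#' @param df data.frame with the land-cover columns.
#' @export
as_landcover <- function(df) {
  .require_columns(df, c("river", "class_code", "value", "value_kind"),
                   "landcover", "<data.frame>")
  df <- as.data.frame(df)[c("river", "class_code", "value", "value_kind")]
  df$river <- as.character(df$river)
  df$class_code <- as.character(df$class_code)
  v <- suppressWarnings(as.numeric(df$value))
  if (any(is.na(v) | v < 0))
    stop("land-cover values must be non-negative numbers", call. = FALSE)
  df$value <- v
  df$value_kind <- tolower(as.character(df$value_kind))
  if (!all(df$value_kind %in% c("area", "percentage")))
    stop("value_kind must be 'area' or 'percentage'", call. = FALSE)
  for (r in unique(df$river)) {
    sub <- df[df$river == r, ]
    if (length(unique(sub$value_kind)) != 1L)
      stop("river ", r, " mixes area and percentage entries", call. = FALSE)
    if (sub$value_kind[1L] == "percentage" &&
        abs(sum(sub$value) - 100) > 1e-6)
      stop("percentages for river ", r, " sum to ", sum(sub$value),
           ", not 100", call. = FALSE)
    if (any(duplicated(sub$class_code)))
      stop("duplicate class code for river ", r, call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("odocon_landcover", "data.frame")
  df
}

#' @rdname read_landcover
#' @param landcover an `odocon_landcover`.
#' @export
write_landcover <- function(landcover, path) {
  utils::write.csv(as.data.frame(landcover), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read the sample registry
#'
#' The registry lists every (river, site, event) combination that was
#' actually surveyed, so that samples yielding no records at all exist as
#' richness-0 replicates instead of silently vanishing from the analysis.
#'
#' @param path CSV with columns `river,site,event`.
#' @return data.frame of class `odocon_registry`.
#' @export
read_registry <- function(path) {
  df <- .read_csv(path, "registry")
  .require_columns(df, c("river", "site", "event"), "registry", path)
  as_registry(df[c("river", "site", "event")])
}

#' @rdname read_registry
#' @param df data.frame with columns `river,site,event`.
#' @export
as_registry <- function(df) {
  .require_columns(df, c("river", "site", "event"), "registry",
                   "<data.frame>")
  df <- as.data.frame(df)[c("river", "site", "event")]
  for (k in names(df)) df[[k]] <- as.character(df[[k]])
  key <- paste(df$river, df$site, df$event, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate registry entries", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("odocon_registry", "data.frame")
  df
}

#' @rdname read_registry
#' @param registry an `odocon_registry`.
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Cross-check survey against trait table
#'
#' Reports species present in the survey but missing from the trait table
#' (fatal for conservation indices, enforced downstream) and trait species
#' never observed (a warning only). The outcome does not depend on input
#' row order.
#'
#' @param survey an `odocon_survey`.
#' @param traits an `odocon_traits`.
#' @return list with components `missing_traits` and `unused_traits`
#'   (sorted character vectors) and class `odocon_consistency`.
#' @export
validate_consistency <- function(survey, traits) {
  s <- sort(unique(survey$species))
  t <- sort(unique(traits$species))
  rep <- structure(list(missing_traits = setdiff(s, t),
                        unused_traits = setdiff(t, s)),
                   class = "odocon_consistency")
  if (length(rep$unused_traits))
    warning("trait table contains species never observed: ",
            paste(rep$unused_traits, collapse = ", "), call. = FALSE)
  rep
}

#' @export
print.odocon_consistency <- function(x, ...) {
  if (!length(x$missing_traits) && !length(x$unused_traits)) {
    cat("survey and trait table are consistent\n")
  } else {
    if (length(x$missing_traits))
      cat("surveyed species missing from traits:\n  ",
          paste(x$missing_traits, collapse = "\n  "), "\n", sep = "")
    if (length(x$unused_traits))
      cat("trait species never observed:\n  ",
          paste(x$unused_traits, collapse = "\n  "), "\n", sep = "")
  }
  invisible(x)
}

.assert_traits_cover <- function(survey_species, traits) {
  miss <- setdiff(unique(survey_species), traits$species)
  if (length(miss))
    stop("species without trait rows: ", paste(miss, collapse = ", "),
         "; conservation indices cannot be computed", call. = FALSE)
  invisible(TRUE)
}
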