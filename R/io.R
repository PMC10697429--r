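#' @title Data model: multi-study diet datasets
#' @description A `prey_dataset` bundles the four input tables of a
#'   prey-selection meta-analysis:
#'   \describe{
#'     \item{diet}{`study_id`, `species_id`, `occurrences` (non-negative
#'       integer count of dietary records containing the species).}
#'     \item{availability}{`study_id`, `species_id`, `rel_abundance`
#'       (proportion of the local prey community; normalized per study).}
#'     \item{traits}{`species_id`, `scientific_name`,
#'       `adult_female_mass_kg`, `mass_is_scaled` (logical: `TRUE` when the
#'       stored mass already includes the 3/4 juvenile correction),
#'       `group_size_class` (1 solitary ... 5 very large groups),
#'       `threat_level` (0 none, 1 injury, 2 death).}
#'     \item{studies}{`study_id`, `site_name`, `period`, `latitude`,
#'       `habitat`, `bioregion`, `mean_temp`, `mean_rainfall`,
#'       `wolf_present`, `puma_present`, `coywolf_range`, `deer_present`,
#'       `coyote_density`, `home_range`, `diet_method`, `n_samples`.}
#'   }
#' @name prey_dataset
NULL

PERIOD_LEVELS  <- c("annual", "spring", "summer", "fall", "winter")
HABITAT_LEVELS <- c("rural", "suburban", "urban", "wilderness", "mixed/unknown")
METHOD_LEVELS  <- c("scat", "stomach", "both", "dna")

DIET_COLS   <- c("study_id", "species_id", "occurrences")
AVAIL_COLS  <- c("study_id", "species_id", "rel_abundance")
TRAIT_COLS  <- c("species_id", "scientific_name", "adult_female_mass_kg",
                 "group_size_class", "threat_level")
STUDY_COLS  <- c("study_id", "site_name", "period", "latitude", "habitat",
                 "bioregion", "mean_temp", "mean_rainfall", "wolf_present",
                 "puma_present", "coywolf_range", "deer_present",
                 "coyote_density", "home_range", "diet_method", "n_samples")

check_columns <- function(df, required, table) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    psel_schema_error(sprintf("table '%s' is missing required column(s): %s",
                              table, paste(missing, collapse = ", ")))
  invisible(df)
}

check_unique_key <- function(df, keys, table) {
  dup <- duplicated(df[keys])
  if (any(dup))
    psel_integrity_error(sprintf(
      "table '%s' has duplicate (%s) key(s), e.g. %s",
      table, paste(keys, collapse = ", "),
      paste(unlist(df[which(dup)[1L], keys]), collapse = "/")))
  invisible(df)
}

#' Scale adult female body mass to the consumed-prey mass
#'
#' Predators take juveniles and subadults as well as adults, so analyses use
#' 3/4 of mean adult female body mass as the effective prey mass.
#'
#' @param adult_female_mass_kg positive body mass in kg.
#' @return `0.75 * adult_female_mass_kg`.
#' @examples
#' scale_body_mass(476) # 357
#' @export
scale_body_mass <- function(adult_female_mass_kg) {
  check_positive(adult_female_mass_kg, "adult_female_mass_kg")
  0.75 * adult_female_mass_kg
}

# Effective (scaled) mass per trait row, honouring the mass_is_scaled flag
# used for summary-table fixtures whose masses are already 3/4-scaled.
scaled_mass <- function(traits) {
  flag <- if ("mass_is_scaled" %in% names(traits)) {
    isTRUE_vec(traits$mass_is_scaled)
  } else {
    rep(FALSE, nrow(traits))
  }
  ifelse(flag, traits$adult_female_mass_kg,
         0.75 * traits$adult_female_mass_kg)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

normalize_availability <- function(availability) {
  if (any(availability$rel_abundance < 0, na.rm = TRUE))
    psel_domain_error("rel_abundance must be non-negative")
  tot <- tapply(availability$rel_abundance, availability$study_id, sum)
  if (any(tot <= 0))
    psel_integrity_error("a study has zero total availability")
  availability$rel_abundance <- availability$rel_abundance /
    as.numeric(tot[as.character(availability$study_id)])
  availability
}

#' Assemble and validate a multi-study prey-selection dataset
#'
#' Validates schemas and keys, normalizes availability to a per-study
#' simplex, applies the inclusion rules (a study needs availability for at
#' least `min_avail_species` species and at least `min_samples` dietary
#' samples), and cross-references species against the trait table.
#'
#' Diet species with no availability record for their study are kept with
#' availability 0 (they yield Jacobs' index +1) and flagged with a warning;
#' set `drop_zero_availability = TRUE` to exclude them instead. Species
#' present in availability but never eaten get diet proportion 0 (index -1):
#' an observed absence is data, not missingness.
#'
#' @param diet,availability,traits,studies data frames (see
#'   [prey_dataset]); [load_dataset()] reads them from CSV.
#' @param drop_zero_availability drop diet records lacking availability?
#' @param min_avail_species minimum availability species per study (default 3).
#' @param min_samples minimum dietary sample size per study (default 20).
#' @return A `prey_dataset` object (list of the four validated tables).
#' @export
prey_dataset <- function(diet, availability, traits, studies,
                         drop_zero_availability = FALSE,
                         min_avail_species = 3, min_samples = 20) {
  check_columns(diet, DIET_COLS, "diet")
  check_columns(availability, AVAIL_COLS, "availability")
  check_columns(traits, TRAIT_COLS, "traits")
  check_columns(studies, STUDY_COLS, "studies")
  check_unique_key(diet, c("study_id", "species_id"), "diet")
  check_unique_key(availability, c("study_id", "species_id"), "availability")
  check_unique_key(traits, "species_id", "traits")
  check_unique_key(studies, "study_id", "studies")

  if (any(diet$occurrences < 0, na.rm = TRUE))
    psel_domain_error("diet occurrences must be non-negative")
  bad_period <- setdiff(unique(studies$period), PERIOD_LEVELS)
  if (length(bad_period))
    psel_integrity_error(sprintf("unknown period value(s): %s",
                                 paste(bad_period, collapse = ", ")))
  bad_method <- setdiff(unique(studies$diet_method), METHOD_LEVELS)
  if (length(bad_method))
    psel_integrity_error(sprintf("unknown diet_method value(s): %s",
                                 paste(bad_method, collapse = ", ")))
  bad_habitat <- setdiff(unique(studies$habitat), HABITAT_LEVELS)
  if (length(bad_habitat))
    psel_integrity_error(sprintf("unknown habitat value(s): %s",
                                 paste(bad_habitat, collapse = ", ")))
  if (any(traits$adult_female_mass_kg <= 0, na.rm = TRUE))
    psel_domain_error("adult_female_mass_kg must be positive")

  # Inclusion rules: availability recorded for >= min_avail_species species,
  # dietary sample size >= min_samples.
  n_avail <- table(availability$study_id)
  thin <- names(n_avail)[n_avail < min_avail_species]
  small <- studies$study_id[!is.na(studies$n_samples) &
                              studies$n_samples < min_samples]
  drop <- union(thin, as.character(small))
  if (length(drop)) {
    message(sprintf(
      "excluding %d study(ies): %s (availability for <%d species or <%d samples)",
      length(drop), paste(drop, collapse = ", "),
      min_avail_species, min_samples))
    studies <- studies[!studies$study_id %in% drop, , drop = FALSE]
    diet <- diet[!diet$study_id %in% drop, , drop = FALSE]
    availability <- availability[!availability$study_id %in% drop, , drop = FALSE]
  }
  if (nrow(studies) == 0L)
    psel_integrity_error("no studies left after applying inclusion rules")

  availability <- normalize_availability(availability)

  key <- function(d) paste(d$study_id, d$species_id, sep = "\r")
  orphan <- !(key(diet) %in% key(availability))
  if (any(orphan)) {
    if (drop_zero_availability) {
      warning(sprintf("dropping %d diet record(s) with no availability",
                      sum(orphan)), call. = FALSE)
      diet <- diet[!orphan, , drop = FALSE]
    } else {
      warning(sprintf(
        "%d diet record(s) have no availability for their study; kept with p = 0",
        sum(orphan)), call. = FALSE)
    }
  }
  no_traits <- setdiff(unique(diet$species_id), traits$species_id)
  if (length(no_traits))
    warning(sprintf("species in diet but absent from traits: %s",
                    paste(no_traits, collapse = ", ")), call. = FALSE)

  if (!"mass_is_scaled" %in% names(traits)) traits$mass_is_scaled <- FALSE

  structure(list(diet = diet, availability = availability,
                 traits = traits, studies = studies,
                 species_without_traits = no_traits),
            class = "prey_dataset")
}

#' @rdname prey_dataset
#' @param x a `prey_dataset`.
#' @param ... ignored.
#' @export
print.prey_dataset <- function(x, ...) {
  cat(sprintf(
    "prey_dataset: %d studies, %d species, %d diet records, %d availability records\n",
    nrow(x$studies), length(unique(c(x$diet$species_id,
                                     x$availability$species_id))),
    nrow(x$diet), nrow(x$availability)))
  invisible(x)
}

#' Read a dataset from four CSV files
#'
#' Files are comma-separated UTF-8 with a mandatory header row and `.` as
#' the decimal mark (one dialect, no sniffing).
#'
#' @param diet_path,availability_path,traits_path,studies_path CSV paths.
#' @param ... passed to [prey_dataset()].
#' @return A validated `prey_dataset`.
#' @export
load_dataset <- function(diet_path, availability_path, traits_path,
                         studies_path, ...) {
  paths <- c(diet_path, availability_path, traits_path, studies_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    psel_schema_error(sprintf("input file(s) not found: %s",
                              paste(missing, collapse = ", ")))
  rd <- function(p) read.csv(p, stringsAsFactors = FALSE, encoding = "UTF-8")
  prey_dataset(rd(diet_path), rd(availability_path), rd(traits_path),
               rd(studies_path), ...)
}

#' Write a dataset back to four CSV files
#'
#' Numeric columns are written at full IEEE precision (`%.17g`) so that
#' `load_dataset(write_dataset(x))` round-trips bit-identically.
#'
#' @param dataset a `prey_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named character vector of file paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "prey_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(diet = file.path(dir, "diet.csv"),
             availability = file.path(dir, "availability.csv"),
             traits = file.path(dir, "traits.csv"),
             studies = file.path(dir, "studies.csv"))
  for (nm in names(paths)) {
    df <- dataset[[nm]]
    out <- as.data.frame(lapply(df, format_full), stringsAsFactors = FALSE,
                         check.names = FALSE)
    write.csv(out, paths[[nm]], row.names = FALSE, quote = TRUE,
              fileEncoding = "UTF-8")
  }
  invisible(paths)
}

#' Standardize study and trait covariates for linear modelling
#'
#' Adds `temperature_z` (z-score of mean temperature) and `log_rainfall_z`
#' (z-score of log10 rainfall) to the study table, and `log_mass` (log10 of
#' the 3/4-scaled body mass) to the trait table. Z-scores use the sample
#' standard deviation over non-missing entries.
#'
#' @param studies study-attribute data frame.
#' @param traits optional species-trait data frame.
#' @return `studies` (or `list(studies=, traits=)` when `traits` is given)
#'   with the derived columns appended.
#' @export
standardize_covariates <- function(studies, traits = NULL) {
  zscore <- function(x, name) {
    ok <- !is.na(x)
    if (sum(ok) < 2)
      psel_domain_error(sprintf("need >=2 non-missing values in '%s'", name))
    s <- sd(x[ok])
    if (s == 0)
      psel_domain_error(sprintf("column '%s' has zero variance", name))
    (x - mean(x[ok])) / s
  }
  studies$temperature_z  <- zscore(studies$mean_temp, "mean_temp")
  if (any(studies$mean_rainfall <= 0, na.rm = TRUE))
    psel_domain_error("mean_rainfall must be positive")
  studies$log_rainfall_z <- zscore(log10(studies$mean_rainfall),
                                   "mean_rainfall")
  if (is.null(traits)) return(studies)
  traits$log_mass <- log10(scaled_mass(traits))
  list(studies = studies, traits = traits)
}

#' Packaged cross-study species summary fixture
#'
#' A transcription of a published cross-study summary of coyote prey
#' selection: per-taxon mean Jacobs' index, its standard error, number of
#' contributing study datasets, 3/4-scaled body mass (kg), the undefined
#' "kills" column kept verbatim, and the printed t / d.f. / P values. The
#' `mass_is_scaled` flag is `TRUE`: these masses already carry the juvenile
#' correction (e.g. moose 357 = 0.75 x 476).
#'
#' @return A data frame with 60 taxon rows.
#' @export
species_summary_fixture <- function() {
  path <- system.file("extdata", "species_summary_table.csv",
                      package = "preysel", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}
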