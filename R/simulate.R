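# Synthetic multi-study diet data with known ground truth.
#
# Data-generating model: each species carries a positive preference weight
# w; a study's expected diet proportions are r*_i = w_i p_i / sum_j w_j p_j
# where p is the study's availability simplex (Dirichlet around a community
# base measure). Preference acts multiplicatively on availability: this is
# the minimal model in which Jacobs' index has a closed form
# D*_i = jacobs_index(r*_i, p_i) and equal weights give D* = 0 for every
# species. Occurrence counts are multinomial draws of n_scats items from
# r*; censoring removes a species from both the diet and the availability
# table, emulating studies that recorded only part of the community.

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a prey community
#'
#' Draws species traits and the availability base measure for a synthetic
#' community: body masses log-uniform over `mass_range_kg` (stored as raw
#' adult-female masses, scaled downstream), group-size classes 1-5 with
#' probabilities (0.45, 0.20, 0.20, 0.10, 0.05) (small mammals dominate
#' real prey lists), threat levels 0-2 with probabilities (0.70, 0.25,
#' 0.05), and Dirichlet concentration parameters
#' `alpha = concentration * base_proportions` with base proportions drawn
#' once from a symmetric Dirichlet(5).
#'
#' @param n_species number of species (>= 2).
#' @param mass_range_kg length-2 positive range (equal endpoints allowed).
#' @param seed optional RNG seed (bit-identical reruns).
#' @param concentration Dirichlet concentration (default 30: availability
#'   varies moderately between studies).
#' @return List: `traits` (data frame in the [prey_dataset()] schema),
#'   `availability_alpha` (named), `base_proportions` (named).
#' @export
simulate_community <- function(n_species, mass_range_kg = c(0.01, 357),
                               seed = NULL, concentration = 30) {
  if (n_species < 2) psel_domain_error("need n_species >= 2")
  if (length(mass_range_kg) != 2 || any(mass_range_kg <= 0) ||
      mass_range_kg[1] > mass_range_kg[2])
    psel_domain_error("`mass_range_kg` must be an ascending positive range")
  with_seed(seed)
  ids <- sprintf("sp%02d", seq_len(n_species))
  mass <- 10^runif(n_species, log10(mass_range_kg[1]),
                   log10(mass_range_kg[2]))
  traits <- data.frame(
    species_id = ids,
    scientific_name = paste("Synthetica", ids),
    adult_female_mass_kg = mass,
    mass_is_scaled = FALSE,
    group_size_class = sample(1:5, n_species, replace = TRUE,
                              prob = c(0.45, 0.20, 0.20, 0.10, 0.05)),
    threat_level = sample(0:2, n_species, replace = TRUE,
                          prob = c(0.70, 0.25, 0.05)),
    stringsAsFactors = FALSE)
  base <- rdirichlet1(rep(5, n_species))
  list(traits = traits,
       availability_alpha = setNames(concentration * base, ids),
       base_proportions = setNames(base, ids))
}

#' Closed-form expected Jacobs' index (the oracle)
#'
#' Expected diet proportions under the multiplicative preference model are
#' `r* = w p / sum(w p)`; the oracle selection value is
#' `D* = jacobs_index(r*, p)`, exact. Equal weights give zeros.
#'
#' @param w positive preference weights.
#' @param p availability simplex (same length/names).
#' @return List: `r_star`, `D_star` (named as `w`).
#' @export
closed_form_D <- function(w, p) {
  check_positive(w, "w")
  check_prob(p, "p")
  r_star <- w * p / sum(w * p)
  list(r_star = r_star, D_star = jacobs_index(r_star, p))
}

#' Simulate one study
#'
#' Draws an availability simplex from the Dirichlet base measure, forms the
#' expected diet proportions from the preference weights, draws multinomial
#' occurrence counts, and censors each species independently with
#' probability `censor_prob` (removed from both tables; the reported
#' availability is renormalized over retained species, as a real study
#' would report it). If censoring would retain fewer than
#' `min(3, n_species)` species the censoring mask is redrawn (up to 100
#' times, then an error).
#'
#' @param truth list with `w` (named positive weights) and
#'   `availability_alpha` (named Dirichlet parameters), e.g. from
#'   [simulate_community()].
#' @param n_scats number of dietary records to draw (>= 1).
#' @param censor_prob per-species censoring probability in `[0, 1)`.
#' @param seed optional RNG seed.
#' @param study_id id string for the output tables.
#' @return List: `diet`, `availability` (schema tables over retained
#'   species), `p` (full realized simplex), `r_star`, `D_star` (oracle,
#'   full suite), `retained`, `censored`.
#' @export
simulate_study <- function(truth, n_scats = 200, censor_prob = 0,
                           seed = NULL, study_id = "s1") {
  if (n_scats < 1) psel_domain_error("`n_scats` must be >= 1")
  if (censor_prob < 0 || censor_prob >= 1)
    psel_domain_error("`censor_prob` must lie in [0, 1)")
  with_seed(seed)
  w <- truth$w
  alpha <- truth$availability_alpha
  species <- names(w)
  stopifnot(!is.null(species), identical(sort(species), sort(names(alpha))))
  n_sp <- length(species)
  floor_keep <- min(3L, n_sp)
  if (censor_prob > 0 && (1 - censor_prob) * n_sp < 1)
    psel_domain_error("censoring parameters leave too few retainable species")

  p <- setNames(rdirichlet1(alpha[species]), species)
  cf <- closed_form_D(w, p)
  counts <- drop(rmultinom(1, n_scats, cf$r_star))
  for (try in seq_len(100)) {
    keep <- runif(n_sp) >= censor_prob
    if (sum(keep) >= floor_keep) break
    if (try == 100)
      psel_domain_error("could not retain enough species under censoring")
  }
  retained <- species[keep]
  diet <- data.frame(study_id = study_id, species_id = retained,
                     occurrences = unname(counts[keep]),
                     stringsAsFactors = FALSE)
  avail <- data.frame(study_id = study_id, species_id = retained,
                      rel_abundance = unname(p[keep] / sum(p[keep])),
                      stringsAsFactors = FALSE)
  list(diet = diet, availability = avail, p = p,
       r_star = cf$r_star, D_star = cf$D_star,
       retained = retained, censored = species[!keep])
}

#' Simulate a full multi-study dataset with known truth
#'
#' Builds a community, draws per-study attributes, applies any stated
#' covariate effects on the log preference weights, simulates every study,
#' and returns a validated [prey_dataset()] together with the ground truth.
#'
#' Study attributes: latitude Uniform(19, 55) decimal degrees (the
#' predator's continental range); period sampled from (annual, spring,
#' summer, fall, winter) with weights (0.4, 0.15, 0.15, 0.15, 0.15);
#' habitat mostly rural; mean temperature decreasing in latitude
#' (`28 - 0.5 lat + N(0, 2)` deg C); rainfall log-normal around 700 mm/yr;
#' wolf/puma presence Bernoulli(0.3)/Bernoulli(0.4); coywolf-range flag
#' Bernoulli(0.2); deer presence Bernoulli(0.8); predator density
#' log-normal around 0.3 per km2 (10% missing); home range log-normal
#' around 15 km2 (10% missing); diet method sampled with weights (0.70
#' scat, 0.20 stomach, 0.07 both, 0.03 dna); `n_samples = n_scats`.
#'
#' Base preference weights are log-normal (`sdlog = 0.7`, median 1), a
#' moderate spread giving typical `|D*|` up to about 0.5. A covariate
#' effect `list(sp03 = list(latitude = 0.05))` adds
#' `0.05 * (latitude - 37)` to that species' log weight in each study
#' (latitude centred at 37; `coyote_density` effects use the density minus
#' 0.3).
#'
#' @param n_studies number of studies (>= 1).
#' @param n_species community size.
#' @param n_scats dietary records per study.
#' @param censor_prob per-species per-study censoring probability.
#' @param covariate_effects named list (species -> named slopes on
#'   `latitude` and/or `coyote_density`); unknown species is an error.
#' @param seed optional RNG seed.
#' @param mass_range_kg,concentration passed to [simulate_community()].
#' @return List: `dataset` (a `prey_dataset`), `truth` (list with `w`
#'   matrix of per-study weights, `p`, `r_star`, `D_star` matrices
#'   (species x study), `effects`, `community`, `seed`).
#' @export
simulate_dataset <- function(n_studies, n_species = 12, n_scats = 200,
                             censor_prob = 0, covariate_effects = NULL,
                             seed = NULL, mass_range_kg = c(0.01, 357),
                             concentration = 30) {
  if (n_studies < 1) psel_domain_error("need n_studies >= 1")
  with_seed(seed)
  community <- simulate_community(n_species, mass_range_kg,
                                  concentration = concentration)
  ids <- community$traits$species_id
  if (!is.null(covariate_effects)) {
    unknown <- setdiff(names(covariate_effects), ids)
    if (length(unknown))
      psel_domain_error(sprintf("covariate effect for unknown species: %s",
                                paste(unknown, collapse = ", ")))
  }
  w_base <- setNames(exp(rnorm(n_species, 0, 0.7)), ids)

  sids <- sprintf("study%03d", seq_len(n_studies))
  studies <- data.frame(
    study_id = sids,
    site_name = paste("site", seq_len(n_studies)),
    period = sample(PERIOD_LEVELS, n_studies, replace = TRUE,
                    prob = c(0.4, 0.15, 0.15, 0.15, 0.15)),
    latitude = runif(n_studies, 19, 55),
    habitat = sample(c("rural", "suburban", "urban", "wilderness"),
                     n_studies, replace = TRUE,
                     prob = c(0.75, 0.08, 0.05, 0.12)),
    bioregion = sample(c("temperate_forest", "grassland", "desert",
                         "boreal"), n_studies, replace = TRUE),
    wolf_present = runif(n_studies) < 0.3,
    puma_present = runif(n_studies) < 0.4,
    coywolf_range = runif(n_studies) < 0.2,
    deer_present = runif(n_studies) < 0.8,
    coyote_density = exp(rnorm(n_studies, log(0.3), 0.6)),
    home_range = exp(rnorm(n_studies, log(15), 0.7)),
    diet_method = sample(METHOD_LEVELS, n_studies, replace = TRUE,
                         prob = c(0.70, 0.20, 0.07, 0.03)),
    n_samples = as.integer(n_scats),
    stringsAsFactors = FALSE)
  studies$mean_temp <- 28 - 0.5 * studies$latitude + rnorm(n_studies, 0, 2)
  studies$mean_rainfall <- exp(rnorm(n_studies, log(700), 0.5))
  studies$coyote_density[runif(n_studies) < 0.1] <- NA
  studies$home_range[runif(n_studies) < 0.1] <- NA
  studies <- studies[, STUDY_COLS]

  w_mat <- matrix(rep(w_base, n_studies), nrow = n_species,
                  dimnames = list(ids, sids))
  if (!is.null(covariate_effects)) {
    for (sp in names(covariate_effects)) {
      eff <- covariate_effects[[sp]]
      shift <- rep(0, n_studies)
      if (!is.null(eff$latitude))
        shift <- shift + eff$latitude * (studies$latitude - 37)
      if (!is.null(eff$coyote_density)) {
        dens <- ifelse(is.na(studies$coyote_density), 0.3,
                       studies$coyote_density)
        shift <- shift + eff$coyote_density * (dens - 0.3)
      }
      w_mat[sp, ] <- w_mat[sp, ] * exp(shift)
    }
  }

  p_mat <- matrix(NA_real_, n_species, n_studies, dimnames = list(ids, sids))
  r_mat <- p_mat; D_mat <- p_mat
  diet <- list(); avail <- list()
  for (j in seq_len(n_studies)) {
    st <- simulate_study(list(w = w_mat[, j],
                              availability_alpha = community$availability_alpha),
                         n_scats = n_scats, censor_prob = censor_prob,
                         study_id = sids[j])
    p_mat[, j] <- st$p; r_mat[, j] <- st$r_star; D_mat[, j] <- st$D_star
    diet[[j]] <- st$diet; avail[[j]] <- st$availability
  }
  dataset <- prey_dataset(do.call(rbind, diet), do.call(rbind, avail),
                          community$traits, studies,
                          min_samples = min(20, n_scats))
  list(dataset = dataset,
       truth = list(w = w_mat, p = p_mat, r_star = r_mat, D_star = D_mat,
                    effects = covariate_effects, community = community,
                    seed = seed))
}
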