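# In-code fixtures shared across test files.

# Minimal valid study-attribute rows.
make_studies <- function(study_id, period = "annual", latitude = 45,
                         habitat = "rural", mean_temp = NULL,
                         diet_method = "scat", n_samples = 40) {
  n <- length(study_id)
  if (is.null(mean_temp)) mean_temp <- seq(5, 15, length.out = max(n, 2))[seq_len(n)]
  data.frame(
    study_id = study_id,
    site_name = paste("site", study_id),
    period = rep_len(period, n),
    latitude = rep_len(latitude, n),
    habitat = rep_len(habitat, n),
    bioregion = "temperate_forest",
    mean_temp = mean_temp,
    mean_rainfall = seq(400, 900, length.out = max(n, 2))[seq_len(n)],
    wolf_present = FALSE, puma_present = TRUE,
    coywolf_range = FALSE, deer_present = TRUE,
    coyote_density = 0.3, home_range = 12,
    diet_method = rep_len(diet_method, n),
    n_samples = rep_len(n_samples, n),
    stringsAsFactors = FALSE)
}

make_traits <- function(species_id, mass = NULL) {
  n <- length(species_id)
  if (is.null(mass)) mass <- seq(0.5, 4, length.out = n)
  data.frame(species_id = species_id,
             scientific_name = paste("Testus", species_id),
             adult_female_mass_kg = mass,
             mass_is_scaled = FALSE,
             group_size_class = rep_len(c(1, 3, 2), n),
             threat_level = rep_len(c(0, 1, 0), n),
             stringsAsFactors = FALSE)
}

# Two studies x three species with hand-computable selection values:
# study A: r = (0.75, 0.25, 0),  p = (0.4, 0.4, 0.2)
#          D = (0.35/0.55, -0.15/0.45, -1) = (7/11, -1/3, -1)
# study B: r = (0.25, 0.25, 0.5), p = (1/3, 1/3, 1/3)
#          D = (-0.2, -0.2, 1/3)
make_toy_dataset <- function(...) {
  diet <- data.frame(
    study_id = rep(c("A", "B"), each = 3),
    species_id = rep(c("x", "y", "z"), 2),
    occurrences = c(30, 10, 0, 10, 10, 20),
    stringsAsFactors = FALSE)
  avail <- data.frame(
    study_id = rep(c("A", "B"), each = 3),
    species_id = rep(c("x", "y", "z"), 2),
    rel_abundance = c(0.2, 0.2, 0.1, 1, 1, 1),
    stringsAsFactors = FALSE)
  prey_dataset(diet, avail, make_traits(c("x", "y", "z")),
               make_studies(c("A", "B")), ...)
}

TOY_D <- list(A = c(x = 7 / 11, y = -1 / 3, z = -1),
              B = c(x = -0.2, y = -0.2, z = 1 / 3))

# Independent symbolic oracle for Jacobs' index: the odds-difference form
# D = (o_r - o_p) / (o_r + o_p) with o = q / (1 - q).
jacobs_odds_oracle <- function(r, p) {
  or <- r / (1 - r); op <- p / (1 - p)
  (or - op) / (or + op)
}

# Independent oracle for the generator's expected Jacobs value:
# with r* = w p / S, S = sum(w p), algebra gives
# D* = (w - S) / (w + S - 2 w p).
closed_form_D_oracle <- function(w, p) {
  S <- sum(w * p)
  (w - S) / (w + S - 2 * w * p)
}
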