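#' Jacobs' selectivity index
#'
#' `D = (r - p) / (r + p - 2 r p)`, where `r` is the proportion of a food
#' item in the diet and `p` its proportion of the available prey community.
#' `D` ranges from -1 (maximum avoidance) through 0 (use in proportion to
#' availability) to +1 (maximum selection), and is antisymmetric under
#' swapping `r` and `p`.
#'
#' @param r diet proportion(s) in `[0, 1]`.
#' @param p availability proportion(s) in `[0, 1]`.
#' @return Jacobs' index value(s) in `[-1, 1]`.
#' @examples
#' jacobs_index(0.5, 0.2) # 0.6
#' @export
jacobs_index <- function(r, p) {
  check_prob(r, "r")
  check_prob(p, "p")
  if (any(r == 0 & p == 0))
    psel_domain_error("Jacobs' index is undefined for r = p = 0")
  (r - p) / (r + p - 2 * r * p)
}

#' Invert Jacobs' index for a known availability
#'
#' Solves `D = (r - p)/(r + p - 2 r p)` for the diet proportion `r`. Used by
#' the iterative preference averaging estimator to impute the expected diet
#' share of a species missing from a study.
#'
#' @param D Jacobs' index value(s) in `(-1, 1)`.
#' @param p availability proportion(s) in `(0, 1)`.
#' @return Diet proportion(s) `r = p (1 + D) / (1 + 2 D p - D)`.
#' @export
inverse_jacobs <- function(D, p) {
  check_prob(p, "p")
  if (any(abs(D) > 1)) psel_domain_error("`D` must lie in [-1, 1]")
  p * (1 + D) / (1 + 2 * D * p - D)
}

#' Fisher's z-transformation of a bounded index
#'
#' Maps `D` in `[-1, 1]` to the real line via `atanh`, clamping to
#' `[-1 + eps, 1 - eps]` so the boundary values stay finite. Strictly
#' increasing and odd in `D`.
#'
#' @param D index value(s) in `[-1, 1]`.
#' @param eps boundary clamp, in `(0, 0.01)`; default `1e-6`.
#' @return Transformed value(s) `atanh(clamp(D))`.
#' @export
fisher_z <- function(D, eps = 1e-6) {
  if (length(eps) != 1L || !is.finite(eps) || eps <= 0 || eps >= 0.01)
    psel_domain_error("`eps` must lie in (0, 0.01)")
  if (any(!is.finite(D)) || any(abs(D) > 1))
    psel_domain_error("`D` must lie in [-1, 1]")
  atanh(pmin(pmax(D, -1 + eps), 1 - eps))
}

#' @rdname fisher_z
#' @param z Fisher-z value(s).
#' @export
inv_fisher_z <- function(z) tanh(z)

#' Relative frequency of occurrence
#'
#' A species' share of all dietary item occurrences within one study:
#' `r_i = occurrences_i / sum_j occurrences_j`.
#'
#' @param occurrences named non-negative counts (one study).
#' @return Named proportions summing to 1.
#' @export
relative_frequency_of_occurrence <- function(occurrences) {
  if (any(occurrences < 0, na.rm = TRUE))
    psel_domain_error("occurrences must be non-negative")
  tot <- sum(occurrences)
  if (!is.finite(tot) || tot <= 0)
    psel_domain_error("all occurrence counts are zero")
  occurrences / tot
}

#' Study-level selection values
#'
#' Computes, for every study, the diet proportion `r` (relative frequency of
#' occurrence, or the estimated-individuals proportion when
#' `basis = "individuals"`), availability `p`, Jacobs' index `D`, and its
#' Fisher-z transform. Species present in availability but never eaten enter
#' with `r = 0`; diet species lacking availability enter with `p = 0`.
#' Species with `r = p = 0` (zero-count diet rows without availability) are
#' dropped.
#'
#' @param dataset a [prey_dataset()].
#' @param basis `"occurrences"` (relative frequency of occurrence) or
#'   `"individuals"` (occurrences converted to estimated individuals
#'   consumed via [scats_per_individual()]).
#' @param model allometric scat-production model for the individuals basis.
#' @param eps Fisher-z boundary clamp.
#' @param method label stored in the `method` column; defaults to
#'   `"traditional"` for the occurrence basis and `"biomass"` otherwise.
#' @param zero_correction add half a record to zero occurrence counts of
#'   species present in availability (continuity correction). A sampling
#'   zero otherwise maps to `D = -1` exactly, whose Fisher-z value is the
#'   clamp boundary (about -7.25 at the default `eps`) regardless of effort;
#'   the half-record correction makes the boundary value reflect the
#'   study's sample size. Off by default for the traditional estimator
#'   (observed absence is an informative extreme); on inside
#'   [ipa_estimate()], which averages on the z scale.
#' @return Data frame: `study_id`, `species_id`, `method`, `r`, `p`, `D`, `z`.
#' @export
selection_values <- function(dataset, basis = c("occurrences", "individuals"),
                             model = allometric_model(), eps = 1e-6,
                             method = NULL, zero_correction = FALSE) {
  stopifnot(inherits(dataset, "prey_dataset"))
  basis <- match.arg(basis)
  if (is.null(method))
    method <- if (basis == "occurrences") "traditional" else "biomass"
  out <- lapply(split(seq_len(nrow(dataset$studies)),
                      seq_len(nrow(dataset$studies))), function(i) {
    sid <- dataset$studies$study_id[i]
    diet <- dataset$diet[dataset$diet$study_id == sid, , drop = FALSE]
    avail <- dataset$availability[dataset$availability$study_id == sid, ,
                                  drop = FALSE]
    species <- union(avail$species_id, diet$species_id)
    occ <- setNames(rep(0, length(species)), species)
    occ[diet$species_id] <- diet$occurrences
    p <- setNames(rep(0, length(species)), species)
    p[avail$species_id] <- avail$rel_abundance
    if (sum(occ) <= 0) return(NULL)
    if (zero_correction) occ[occ == 0 & p > 0] <- 0.5
    r <- if (basis == "occurrences") {
      relative_frequency_of_occurrence(occ)
    } else {
      conv <- individuals_from_occurrences(occ, species_mass(dataset$traits,
                                                             species), model)
      pr <- setNames(rep(NA_real_, length(species)), species)
      pr[conv$species_id] <- conv$proportion
      keep <- !is.na(pr)
      occ <- occ[keep]; p <- p[keep]; species <- species[keep]
      pr[keep]
    }
    keep <- !(r == 0 & p == 0)
    if (!all(keep)) {
      r <- r[keep]; p <- p[keep]; species <- species[keep]
    }
    if (!length(species)) return(NULL)
    D <- jacobs_index(r, p)
    data.frame(study_id = sid, species_id = species, method = method,
               r = unname(r), p = unname(p), D = unname(D),
               z = fisher_z(unname(D), eps), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Named vector of scaled masses for a species set (NA when absent).
species_mass <- function(traits, species) {
  m <- setNames(rep(NA_real_, length(species)), species)
  hit <- match(species, traits$species_id)
  ok <- !is.na(hit)
  m[ok] <- scaled_mass(traits[hit[ok], , drop = FALSE])
  m
}

#' Reconstruct a one-sample t-test from summary statistics
#'
#' Given a cross-study mean selection value, its standard error, and the
#' number of contributing studies, returns the t statistic against 0, its
#' degrees of freedom, and the two-sided p-value.
#'
#' @param mean_D cross-study mean Jacobs' index.
#' @param se_D its standard error (`sd / sqrt(n)`).
#' @param n number of study-level values.
#' @return List with `t`, `df`, `p_value`.
#' @export
t_from_summary <- function(mean_D, se_D, n) {
  if (n < 2) psel_domain_error("need n >= 2 for a one-sample t-test")
  if (se_D < 0) psel_domain_error("`se_D` must be non-negative")
  t <- if (se_D > 0) mean_D / se_D else sign(mean_D) * Inf
  df <- n - 1
  p <- if (is.finite(t)) 2 * pt(-abs(t), df) else if (mean_D == 0) 1 else 0
  list(t = t, df = df, p_value = p)
}

#' Pool study-level selection values into per-species summaries
#'
#' For each species (within each estimator method), computes the mean
#' Jacobs' index across studies, its standard error, a two-sided one-sample
#' t-test against 0 on the raw `D` values, and a preference class:
#' `preferred` if `p < alpha` and the mean is positive, `avoided` if
#' `p < alpha` and the mean is negative, otherwise `none`. Values with
#' `0.05 <= p < 0.10` are additionally flagged `near_significant`. With a
#' single study the test is marked missing; zero cross-study variance gives
#' a signed-infinity t sentinel with `p = 0`. No multiple-testing correction
#' is applied by default (`adjust = "holm"` enables one).
#'
#' @param values data frame from [selection_values()] (columns `species_id`,
#'   `method`, `D`).
#' @param alpha two-sided significance level (default 0.05).
#' @param adjust p-value adjustment: `"none"` (default) or `"holm"`.
#' @return Data frame: `species_id`, `method`, `n`, `mean_D`, `se_D`,
#'   `t_stat`, `df`, `p_value`, `preference_class`, `near_significant`.
#' @export
summarize_species <- function(values, alpha = 0.05,
                              adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    psel_domain_error("`alpha` must lie in (0, 1)")
  grp <- interaction(values$species_id, values$method, drop = TRUE)
  rows <- lapply(split(values, grp), function(v) {
    n <- nrow(v)
    m <- mean(v$D)
    if (n == 1L) {
      return(data.frame(species_id = v$species_id[1], method = v$method[1],
                        n = 1L, mean_D = m, se_D = NA_real_,
                        t_stat = NA_real_, df = 0L, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    se <- sd(v$D) / sqrt(n)
    ts <- t_from_summary(m, se, n)
    data.frame(species_id = v$species_id[1], method = v$method[1],
               n = n, mean_D = m, se_D = se, t_stat = ts$t,
               df = ts$df, p_value = ts$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  p <- out$p_value
  if (adjust == "holm") p <- stats::p.adjust(p, method = "holm")
  cls <- rep("none", nrow(out))
  sig <- !is.na(p) & p < alpha
  cls[sig & out$mean_D > 0] <- "preferred"
  cls[sig & out$mean_D < 0] <- "avoided"
  out$preference_class <- cls
  out$near_significant <- !is.na(p) & p >= 0.05 & p < 0.10
  out <- out[order(out$method, out$species_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ideal prey mass
#'
#' The unweighted mean of the (3/4-scaled) body masses of the species
#' classified as significantly preferred.
#'
#' @param summaries output of [summarize_species()].
#' @param traits trait table giving masses (honours `mass_is_scaled`).
#' @return Mean mass in kg, or `numeric(0)` when no species is preferred.
#' @export
ideal_prey_mass <- function(summaries, traits) {
  pref <- summaries$species_id[summaries$preference_class == "preferred"]
  if (!length(pref)) return(numeric(0))
  m <- species_mass(traits, pref)
  if (anyNA(m)) {
    warning(sprintf("preferred species without mass dropped: %s",
                    paste(names(m)[is.na(m)], collapse = ", ")), call. = FALSE)
    m <- m[!is.na(m)]
  }
  if (!length(m)) return(numeric(0))
  mean(m)
}

#' Predator-to-preferred-prey mass ratio
#'
#' @param ideal_mass_kg mean mass of significantly preferred prey (kg).
#' @param predator_mass_kg mean predator body mass (kg).
#' @return List with `ratio` (= ideal / predator) and `label`, the
#'   conventional `"1:x"` string with x to 2 decimals.
#' @export
predator_prey_ratio <- function(ideal_mass_kg, predator_mass_kg) {
  check_positive(ideal_mass_kg, "ideal_mass_kg")
  check_positive(predator_mass_kg, "predator_mass_kg")
  ratio <- ideal_mass_kg / predator_mass_kg
  list(ratio = ratio, label = sprintf("1:%.2f", ratio))
}
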