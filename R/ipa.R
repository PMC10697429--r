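#' Iterative preference averaging (IPA)
#'
#' Cross-study selectivity estimation that accounts for species missing
#' from individual studies. A study that never recorded a species (in
#' either its diet or its availability table) still constrains nothing
#' about it directly, but the species' absence distorts the *other*
#' species' proportions, which are conditioned on the reduced community.
#' IPA alternates two steps until the pooled estimates stabilise:
#'
#' 1. *Pooling*: per-species mean of the study-level Fisher-z values over
#'    the full (observed + imputed) suite of studies.
#' 2. *Re-imputation*: for each study, species missing from both tables are
#'    given an availability share equal to their cross-study mean
#'    availability, and a diet share obtained by inverting Jacobs' index at
#'    the current pooled estimate ([inverse_jacobs()]). Observed shares are
#'    rescaled to make room, and Jacobs' indices for *all* species in that
#'    study are recomputed on the completed simplexes.
#'
#' Species observed in a study's availability but absent from its diet are
#' data (`r = 0`), not missingness, and are never imputed. The imputation
#' community is the union of species over all studies. With complete data
#' the loop is a no-op and the estimates equal the traditional per-species
#' mean (on the averaging scale) after one iteration.
#'
#' @param dataset a [prey_dataset()].
#' @param basis `"scat_counts"` (occurrence-based diet proportions) or
#'   `"individuals"` (biomass-corrected, via [individuals_from_occurrences()]).
#' @param scale scale of the reported `estimate`: `"z"` (mean Fisher-z,
#'   default: averaging happens on this unbounded scale) or `"D"`
#'   (back-transformed `tanh` of the mean z).
#' @param tolerance convergence tolerance on the maximum absolute change of
#'   the pooled estimates (default 1e-8).
#' @param max_iterations iteration cap (default 500); non-convergence
#'   returns `converged = FALSE` with a warning.
#' @param model allometric model for the individuals basis.
#' @param eps Fisher-z clamp.
#' @param zero_correction continuity-correct sampling zeros before the
#'   z transform (default `TRUE`; see [selection_values()]). Averaging on
#'   the z scale is otherwise dominated by the clamp boundary whenever an
#'   available species drew zero dietary records.
#' @return An `ipa_result` list:
#'   \describe{
#'     \item{species}{per-species data frame with `estimate` (chosen
#'       scale), `estimate_D` (always the D scale), `n_effective` (studies
#'       where the species was observed), `iterations`, `converged`,
#'       `delta_final`.}
#'     \item{values}{study-level data frame of post-imputation `D` and `z`
#'       for the full suite, usable by [compare_methods()].}
#'     \item{deltas}{the per-iteration maximum-change trace.}
#'   }
#' @export
ipa_estimate <- function(dataset, basis = c("scat_counts", "individuals"),
                         scale = c("z", "D"), tolerance = 1e-8,
                         max_iterations = 500L, model = allometric_model(),
                         eps = 1e-6, zero_correction = TRUE) {
  stopifnot(inherits(dataset, "prey_dataset"))
  basis <- match.arg(basis)
  scale <- match.arg(scale)
  if (tolerance <= 0) psel_domain_error("`tolerance` must be positive")

  vals <- selection_values(dataset,
                           basis = if (basis == "scat_counts") "occurrences"
                                   else "individuals",
                           model = model, eps = eps,
                           zero_correction = zero_correction)
  if (is.null(vals) || !nrow(vals))
    psel_domain_error("no usable selection values in dataset")
  studies <- split(vals, vals$study_id)
  community <- sort(unique(vals$species_id))

  # Cross-study mean availability, the imputation base measure. Species that
  # never appear in any availability table cannot be imputed. Reported
  # availabilities are renormalized over each study's recorded subset, which
  # inflates every observed share when records are incomplete; renormalizing
  # the means over the full community removes that common inflation factor
  # (without it the imputed shares are systematically too large and the
  # pooled estimates shrink toward zero).
  p_bar <- vapply(community, function(sp) {
    p <- vals$p[vals$species_id == sp & vals$p > 0]
    if (length(p)) mean(p) else 0
  }, numeric(1))
  p_bar <- p_bar / sum(p_bar)

  pooled <- vapply(community, function(sp)
    mean(vals$z[vals$species_id == sp]), numeric(1))
  n_eff <- vapply(community, function(sp)
    sum(vals$species_id == sp), numeric(1))

  method_label <- if (basis == "scat_counts") "ipa_scat" else "ipa_biomass"
  deltas <- numeric(0)
  converged <- FALSE
  iter <- 0L
  study_z <- NULL

  repeat {
    iter <- iter + 1L
    study_z <- lapply(studies, function(sv) {
      obs <- sv$species_id
      miss <- setdiff(community, obs)
      miss <- miss[p_bar[miss] > 0]
      if (!length(miss)) {
        return(setNames(sv$z, obs))
      }
      p_m <- p_bar[miss]
      if (sum(p_m) >= 0.9) p_m <- p_m * (0.5 / sum(p_m))
      p_full <- c(setNames(sv$p * (1 - sum(p_m)), obs), p_m)
      D_cur <- inv_fisher_z(pooled[miss])
      r_m <- pmin(pmax(inverse_jacobs(D_cur, p_full[miss]), 0), 0.95)
      if (sum(r_m) >= 0.9) r_m <- r_m * (0.5 / sum(r_m))
      r_full <- c(setNames(sv$r * (1 - sum(r_m)), obs), r_m)
      keep <- !(r_full == 0 & p_full == 0)
      fisher_z(jacobs_index(r_full[keep], p_full[keep]), eps)
    })
    pooled_new <- vapply(community, function(sp) {
      zs <- unlist(lapply(study_z, function(z) z[sp]), use.names = FALSE)
      mean(zs, na.rm = TRUE)
    }, numeric(1))
    delta <- max(abs(pooled_new - pooled))
    deltas <- c(deltas, delta)
    pooled <- pooled_new
    if (delta <= tolerance) { converged <- TRUE; break }
    if (iter >= max_iterations) break
  }
  if (!converged)
    warning(sprintf("IPA did not converge in %d iterations (delta = %.3g)",
                    iter, deltas[length(deltas)]), call. = FALSE)

  values <- do.call(rbind, lapply(names(study_z), function(sid) {
    z <- study_z[[sid]]
    data.frame(study_id = sid, species_id = names(z), method = method_label,
               D = unname(inv_fisher_z(z)), z = unname(z),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  species <- data.frame(
    species_id = community,
    estimate = if (scale == "z") unname(pooled) else unname(tanh(pooled)),
    estimate_D = unname(tanh(pooled)),
    n_effective = unname(n_eff),
    iterations = iter,
    converged = converged,
    delta_final = deltas[length(deltas)],
    stringsAsFactors = FALSE)
  structure(list(species = species, values = values, deltas = deltas,
                 basis = basis, scale = scale),
            class = "ipa_result")
}

#' @rdname ipa_estimate
#' @param x an `ipa_result`.
#' @param ... ignored.
#' @export
print.ipa_result <- function(x, ...) {
  cat(sprintf("IPA (%s basis): %d species, %d iteration(s), %s\n",
              x$basis, nrow(x$species), x$species$iterations[1],
              if (x$species$converged[1]) "converged" else "NOT converged"))
  invisible(x)
}

#' Run IPA on both the scat-count and the individuals basis
#'
#' Convenience wrapper producing paired per-species estimates from
#' occurrence counts and from estimated individuals consumed (biomass
#' correction). Species lacking body mass are excluded from the individuals
#' basis with a warning; if the individuals basis fails outright (e.g. an
#' empty trait table) the scat-basis results are still returned and the
#' error is recorded.
#'
#' @inheritParams ipa_estimate
#' @return List with `species` (data frame: `species_id`, `estimate_scat`,
#'   `estimate_biomass`), the two full `ipa_result`s (`scat`, `biomass`),
#'   and `biomass_error` (message or `NULL`).
#' @export
ipa_compare_bases <- function(dataset, scale = c("z", "D"),
                              tolerance = 1e-8, max_iterations = 500L,
                              model = allometric_model()) {
  scale <- match.arg(scale)
  scat <- ipa_estimate(dataset, basis = "scat_counts", scale = scale,
                       tolerance = tolerance,
                       max_iterations = max_iterations)
  biomass <- NULL; biomass_error <- NULL
  biomass <- tryCatch(
    ipa_estimate(dataset, basis = "individuals", scale = scale,
                 tolerance = tolerance, max_iterations = max_iterations,
                 model = model),
    error = function(e) { biomass_error <<- conditionMessage(e); NULL })
  if (!is.null(biomass_error))
    warning(sprintf("individuals basis failed: %s", biomass_error),
            call. = FALSE)
  species <- scat$species[, c("species_id", "estimate")]
  names(species)[2] <- "estimate_scat"
  species$estimate_biomass <- if (is.null(biomass)) NA_real_ else
    biomass$species$estimate[match(species$species_id,
                                   biomass$species$species_id)]
  list(species = species, scat = scat, biomass = biomass,
       biomass_error = biomass_error)
}
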