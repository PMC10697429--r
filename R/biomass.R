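#' Scat-production allometry
#'
#' Large canids produce more scats from a large carcass than from a small
#' one. Feeding trials on canids with similar digestive systems give the
#' log-log relationship
#' `log10(scats) = slope * log10(carcass mass kg) + intercept`, with default
#' coefficients slope 1.32 and intercept -0.89 (r^2 = 0.932, n = 58 trials).
#' [refit_allometry()] re-estimates the coefficients from user-supplied
#' feeding-trial data.
#'
#' @param slope log-log slope (> 0).
#' @param intercept log10 intercept.
#' @param r2,n fit metadata carried along for reporting.
#' @return An `allometric_model` object.
#' @export
allometric_model <- function(slope = 1.32, intercept = -0.89,
                             r2 = 0.932, n = 58L) {
  if (!is.finite(slope) || slope <= 0)
    psel_domain_error("allometric slope must be positive")
  structure(list(slope = slope, intercept = intercept, r2 = r2, n = n),
            class = "allometric_model")
}

#' @rdname allometric_model
#' @param x an `allometric_model`.
#' @param ... ignored.
#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf(
    "log10(scats) = %.4g * log10(mass kg) + %.4g  (r2 = %.3f, n = %d)\n",
    x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Expected scats produced from one consumed individual
#'
#' Evaluates the allometry `10^(slope * log10(mass) + intercept)`; strictly
#' increasing in mass.
#'
#' @param mass_kg positive carcass mass(es), kg.
#' @param model an [allometric_model()].
#' @return Expected scat count(s).
#' @examples
#' scats_per_individual(357) # about 302: a moose-sized carcass, > 200 scats
#' @export
scats_per_individual <- function(mass_kg, model = allometric_model()) {
  check_positive(mass_kg, "mass_kg")
  10^(model$slope * log10(mass_kg) + model$intercept)
}

#' Convert scat occurrences to estimated individuals consumed
#'
#' `N_i = occurrences_i / scats_per_individual(mass_i)`; the resulting
#' proportions `N_i / sum(N)` replace the diet proportion for the
#' biomass-corrected selection basis. Species with occurrences but no mass
#' are excluded with a warning.
#'
#' @param occurrences named non-negative occurrence counts.
#' @param mass_kg named (or positionally aligned) scaled masses, kg; may
#'   contain `NA`.
#' @param model an [allometric_model()].
#' @return Data frame: `species_id`, `occurrences`, `n_individuals`,
#'   `proportion`.
#' @export
individuals_from_occurrences <- function(occurrences, mass_kg,
                                         model = allometric_model()) {
  if (any(occurrences < 0, na.rm = TRUE))
    psel_domain_error("occurrences must be non-negative")
  species <- names(occurrences)
  if (is.null(species)) species <- as.character(seq_along(occurrences))
  if (!is.null(names(mass_kg))) mass_kg <- mass_kg[species]
  no_mass <- occurrences > 0 & (is.na(mass_kg) | mass_kg <= 0)
  if (any(no_mass)) {
    warning(sprintf("excluding species without body mass: %s",
                    paste(species[no_mass], collapse = ", ")), call. = FALSE)
  }
  keep <- !no_mass
  occ <- occurrences[keep]; m <- mass_kg[keep]; sp <- species[keep]
  n_ind <- ifelse(occ == 0, 0, occ / scats_per_individual(pmax(m, .Machine$double.xmin),
                                                          model))
  tot <- sum(n_ind)
  if (tot <= 0) psel_domain_error("no estimable individuals (all counts zero)")
  data.frame(species_id = sp, occurrences = unname(occ),
             n_individuals = unname(n_ind),
             proportion = unname(n_ind / tot),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Refit the scat-production allometry from feeding trials
#'
#' Ordinary least squares of `log10(scats)` on `log10(mass)`.
#'
#' @param trials data frame with columns `mass_kg` and `scats` (one feeding
#'   trial per row; both positive).
#' @return An [allometric_model()] with fitted slope/intercept and the
#'   trial r^2 and n.
#' @export
refit_allometry <- function(trials) {
  check_columns(trials, c("mass_kg", "scats"), "trials")
  check_positive(trials$mass_kg, "mass_kg")
  check_positive(trials$scats, "scats")
  if (nrow(trials) < 3)
    psel_domain_error("need >= 3 feeding trials to refit the allometry")
  fit <- lm(log10(scats) ~ log10(mass_kg), data = trials)
  allometric_model(slope = unname(coef(fit)[2]),
                   intercept = unname(coef(fit)[1]),
                   r2 = summary(fit)$r.squared, n = nrow(trials))
}

#' Compare selection estimates across estimator methods
#'
#' Stacks study-level Jacobs' index values from several estimators (e.g.
#' traditional, IPA on scats, IPA on biomass) and reports (i) a two-factor
#' fixed-effects ANOVA (species, method, interaction; type-II sums of
#' squares on the unbalanced table) and (ii) pairwise Pearson correlations
#' between methods over aligned study-by-species values.
#'
#' @param values data frame with columns `study_id`, `species_id`,
#'   `method`, `D` covering two or more methods.
#' @return A `method_comparison` list: `anova` (data frame with term, df1,
#'   df2, F, p), `correlations` (data frame with the method pair, R, df, p;
#'   `NULL` when fewer than 3 aligned pairs exist).
#' @export
compare_methods <- function(values) {
  methods <- unique(values$method)
  if (length(methods) < 2)
    psel_domain_error("need >= 2 methods to compare")
  df <- data.frame(D = values$D,
                   species = factor(values$species_id),
                   method = factor(values$method))
  an <- two_way_anova_type2(df, "D", "species", "method")
  pairs <- combn(methods, 2, simplify = FALSE)
  key <- paste(values$study_id, values$species_id, sep = "\r")
  cors <- lapply(pairs, function(pr) {
    a <- values[values$method == pr[1], ]; b <- values[values$method == pr[2], ]
    ka <- paste(a$study_id, a$species_id, sep = "\r")
    kb <- paste(b$study_id, b$species_id, sep = "\r")
    common <- intersect(ka, kb)
    if (length(common) < 3) return(NULL)
    x <- a$D[match(common, ka)]; y <- b$D[match(common, kb)]
    n <- length(common)
    R <- cor(x, y)
    tt <- R * sqrt((n - 2) / (1 - R^2))
    data.frame(method_a = pr[1], method_b = pr[2], R = R, df = n - 2L,
               p_value = 2 * pt(-abs(tt), n - 2), stringsAsFactors = FALSE)
  })
  cors <- do.call(rbind, cors)
  structure(list(anova = an, correlations = cors),
            class = "method_comparison")
}

# Two-factor fixed-effects ANOVA with type-II sums of squares, computed by
# comparing residual sums of squares of nested least-squares fits. Used for
# the estimator-method comparison and the seasonal analysis.
two_way_anova_type2 <- function(df, y, a, b, interaction = TRUE) {
  f <- function(rhs) lm(as.formula(paste(y, "~", rhs)), data = df)
  rss <- function(fit) sum(resid(fit)^2)
  dfres <- function(fit) fit$df.residual
  m_a  <- f(a); m_b <- f(b); m_ab <- f(paste(a, "+", b))
  full <- if (interaction) f(paste(a, "*", b)) else m_ab
  int_ok <- interaction && dfres(m_ab) > dfres(full) && dfres(full) > 0
  if (interaction && !int_ok) {
    warning("interaction inestimable (empty cells); omitted", call. = FALSE)
    full <- m_ab
  }
  err_rss <- rss(full); err_df <- dfres(full)
  if (err_df <= 0) psel_domain_error("no residual degrees of freedom")
  row <- function(term, reduced) {
    ss <- rss(reduced) - rss(m_ab)
    d1 <- dfres(reduced) - dfres(m_ab)
    Fv <- (ss / d1) / (err_rss / err_df)
    data.frame(term = term, df1 = d1, df2 = err_df, F = Fv,
               p_value = pf(Fv, d1, err_df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  out <- rbind(row(a, m_b), row(b, m_a))
  if (int_ok) {
    ss <- rss(m_ab) - rss(full)
    d1 <- dfres(m_ab) - dfres(full)
    Fv <- (ss / d1) / (err_rss / err_df)
    out <- rbind(out, data.frame(term = paste0(a, ":", b), df1 = d1,
                                 df2 = err_df, F = Fv,
                                 p_value = pf(Fv, d1, err_df,
                                              lower.tail = FALSE),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
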