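SUPPORTED_COVARIATES <- c(
  "log_mass", "group_size", "threat", "ecoregion", "habitat",
  "temperature_z", "log_rainfall_z", "wolf_present", "puma_present",
  "coywolf_range", "deer_present", "coyote_density", "home_range",
  "period", "diet_method")

#' Build the driver-model design table
#'
#' One row per study-level selection value; the response is the Fisher-z
#' transform of Jacobs' index. Species-level covariates (`log_mass`,
#' `group_size`, `threat`) come from the trait table; study-level ones from
#' the study table, with `temperature_z` / `log_rainfall_z` derived via
#' [standardize_covariates()] and `ecoregion` mapped from `bioregion`.
#' Categorical covariates are returned as factors (reference level first
#' alphabetically); rows missing any selected covariate are dropped with a
#' message. A factor reduced to a single level is an error.
#'
#' @param dataset a [prey_dataset()].
#' @param covariates character vector drawn from the supported set
#'   `r paste(SUPPORTED_COVARIATES, collapse = ", ")`; empty for an
#'   intercept-only design.
#' @param values optional precomputed [selection_values()] output.
#' @return A `psel_design` list: `data` (response `z` plus covariate
#'   columns), `covariates`, and `model_matrix` (full design matrix with
#'   reference-level factor coding).
#' @export
build_design <- function(dataset, covariates = character(0), values = NULL) {
  stopifnot(inherits(dataset, "prey_dataset"))
  bad <- setdiff(covariates, SUPPORTED_COVARIATES)
  if (length(bad))
    psel_schema_error(sprintf("unsupported covariate(s): %s",
                              paste(bad, collapse = ", ")))
  if (is.null(values)) values <- selection_values(dataset)
  std <- standardize_covariates(dataset$studies, dataset$traits)
  studies <- std$studies; traits <- std$traits
  studies$ecoregion <- studies$bioregion

  si <- match(values$study_id, studies$study_id)
  ti <- match(values$species_id, traits$species_id)
  src <- list(
    log_mass = traits$log_mass[ti], group_size = traits$group_size_class[ti],
    threat = traits$threat_level[ti], ecoregion = studies$ecoregion[si],
    habitat = studies$habitat[si], temperature_z = studies$temperature_z[si],
    log_rainfall_z = studies$log_rainfall_z[si],
    wolf_present = studies$wolf_present[si],
    puma_present = studies$puma_present[si],
    coywolf_range = studies$coywolf_range[si],
    deer_present = studies$deer_present[si],
    coyote_density = studies$coyote_density[si],
    home_range = studies$home_range[si], period = studies$period[si],
    diet_method = studies$diet_method[si])

  df <- data.frame(z = values$z, study_id = values$study_id,
                   species_id = values$species_id,
                   stringsAsFactors = FALSE)
  categorical <- c("ecoregion", "habitat", "period", "diet_method")
  logical_cov <- c("wolf_present", "puma_present", "coywolf_range",
                   "deer_present")
  for (cv in covariates) {
    x <- src[[cv]]
    if (cv %in% categorical) {
      x <- factor(x, levels = sort(unique(x[!is.na(x)])))
    } else if (cv %in% logical_cov) {
      x <- factor(as.logical(x), levels = c(FALSE, TRUE))
    }
    df[[cv]] <- x
  }
  keep <- complete.cases(df[, c("z", covariates), drop = FALSE])
  if (!all(keep))
    message(sprintf("dropping %d row(s) with missing covariate values",
                    sum(!keep)))
  df <- df[keep, , drop = FALSE]
  for (cv in covariates) {
    if (is.factor(df[[cv]])) {
      df[[cv]] <- droplevels(df[[cv]])
      if (nlevels(df[[cv]]) < 2)
        psel_domain_error(sprintf("covariate '%s' has a single level", cv))
    }
  }
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  mm <- model.matrix(as.formula(paste("z ~", rhs)), data = df)
  structure(list(data = df, covariates = covariates, model_matrix = mm),
            class = "psel_design")
}

#' Build a design from an arbitrary observation table
#'
#' Escape hatch for simulation studies and external data: wraps a plain
#' data frame (response column plus covariates) as a `psel_design` usable
#' by [fit_all_subsets()] and [partial_correlation_screen()].
#'
#' @param df data frame containing `response_col` and the covariates.
#' @param covariates covariate column names.
#' @param response_col response column name (default `"z"`).
#' @return A `psel_design`.
#' @export
design_from_frame <- function(df, covariates, response_col = "z") {
  missing <- setdiff(c(response_col, covariates), names(df))
  if (length(missing))
    psel_schema_error(sprintf("missing column(s): %s",
                              paste(missing, collapse = ", ")))
  df <- df[complete.cases(df[, c(response_col, covariates), drop = FALSE]), ,
           drop = FALSE]
  if (response_col != "z") df$z <- df[[response_col]]
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  mm <- model.matrix(as.formula(paste("z ~", rhs)), data = df)
  structure(list(data = df, covariates = covariates, model_matrix = mm),
            class = "psel_design")
}

log_lik_gaussian <- function(fit) {
  # ML (not REML) Gaussian log-likelihood of a least-squares fit.
  n <- length(resid(fit))
  rss <- sum(resid(fit)^2)
  -n / 2 * (log(2 * pi) + log(rss / n) + 1)
}

#' All-subsets model selection with information-criterion weights
#'
#' Fits a Gaussian linear model for every subset of the design's covariates
#' (null model included), ranks them by AICc (default) or AIC, converts
#' criterion differences into Akaike weights `w_i = exp(-delta_i/2)`
#' (normalized to sum to 1), and reports: the full model table; per-covariate
#' relative importance (the sum of weights of models containing the
#' covariate); and full-model-averaged coefficients (zero substitution for
#' models not containing a term) with unconditional standard errors.
#'
#' @param design a [build_design()] result.
#' @param criterion `"AICc"` (small-sample, default) or `"AIC"`. The
#'   parameter count includes the residual variance.
#' @param max_covariates safety cap on the subset enumeration (default 16,
#'   i.e. up to 65536 models).
#' @return A `model_selection_table` list: `models` (data frame with
#'   `terms`, `k`, `logLik`, criterion, `delta`, `weight`), `importance`
#'   (named numeric), `averaged` (data frame `term`, `estimate`, `se`),
#'   `criterion`.
#' @export
fit_all_subsets <- function(design, criterion = c("AICc", "AIC"),
                            max_covariates = 16L) {
  stopifnot(inherits(design, "psel_design"))
  criterion <- match.arg(criterion)
  covs <- design$covariates
  if (length(covs) > max_covariates)
    psel_domain_error(sprintf("more than %d covariates (%d subsets)",
                              max_covariates, 2^length(covs)))
  df <- design$data
  n <- nrow(df)
  subsets <- lapply(0:length(covs), function(m)
    if (m == 0) list(character(0)) else combn(covs, m, simplify = FALSE))
  subsets <- unlist(subsets, recursive = FALSE)

  all_terms <- colnames(design$model_matrix)
  est <- matrix(0, nrow = length(subsets), ncol = length(all_terms),
                dimnames = list(NULL, all_terms))
  se2 <- est
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    rhs <- if (length(s)) paste(s, collapse = " + ") else "1"
    fit <- lm(as.formula(paste("z ~", rhs)), data = df)
    cf <- coef(fit)
    if (anyNA(cf)) {
      message(sprintf("skipping singular subset: %s", rhs))
      rows[[i]] <- NULL
      next
    }
    k <- length(cf) + 1L  # + residual variance
    if (n <= k + 1L)
      psel_domain_error("too few rows for the largest candidate model")
    ll <- log_lik_gaussian(fit)
    aic <- -2 * ll + 2 * k
    crit <- if (criterion == "AICc") aic + 2 * k * (k + 1) / (n - k - 1) else aic
    vc <- diag(stats::vcov(fit))
    est[i, names(cf)] <- cf
    se2[i, names(cf)] <- vc
    rows[[i]] <- data.frame(terms = rhs, k = k, logLik = ll, crit = crit,
                            stringsAsFactors = FALSE)
  }
  ok <- !vapply(rows, is.null, logical(1))
  models <- do.call(rbind, rows[ok])
  est <- est[ok, , drop = FALSE]; se2 <- se2[ok, , drop = FALSE]
  subsets <- subsets[ok]
  models$delta <- models$crit - min(models$crit)
  w <- exp(-models$delta / 2)
  models$weight <- w / sum(w)
  names(models)[names(models) == "crit"] <- criterion
  ord <- order(models$delta)
  importance <- vapply(covs, function(cv)
    sum(models$weight[vapply(subsets, function(s) cv %in% s, logical(1))]),
    numeric(1))
  avg <- colSums(models$weight * est)
  # Burnham & Anderson unconditional SE with zero substitution.
  use <- sqrt(se2 + sweep(est, 2, avg)^2)
  se_u <- colSums(models$weight * use)
  averaged <- data.frame(term = all_terms, estimate = unname(avg),
                         se = unname(se_u), stringsAsFactors = FALSE)
  structure(list(models = models[ord, , drop = FALSE],
                 importance = importance, averaged = averaged,
                 criterion = criterion),
            class = "model_selection_table")
}

#' @rdname fit_all_subsets
#' @param x a `model_selection_table`.
#' @param ... ignored.
#' @export
print.model_selection_table <- function(x, ...) {
  cat(sprintf("%d candidate models (%s); covariate importance:\n",
              nrow(x$models), x$criterion))
  print(round(sort(x$importance, decreasing = TRUE), 3))
  invisible(x)
}

#' Pairwise partial correlations among numeric covariates
#'
#' Partial correlation of each covariate pair controlling for all the
#' others, obtained from the inverse correlation matrix
#' (`rho_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`). With exactly two
#' covariates this reduces to the plain Pearson correlation.
#'
#' @param design a [build_design()] result, or a numeric matrix/data frame.
#' @param threshold absolute partial correlation above which a pair is
#'   flagged as collinear (default 0.7).
#' @return List: `partial` (symmetric matrix), `flagged` (data frame of
#'   pairs with `|rho| >= threshold`).
#' @export
partial_correlation_screen <- function(design, threshold = 0.7) {
  x <- if (inherits(design, "psel_design")) {
    num <- vapply(design$data[design$covariates], is.numeric, logical(1))
    as.matrix(design$data[design$covariates[num]])
  } else {
    as.matrix(design)
  }
  if (ncol(x) < 2)
    psel_domain_error("need >= 2 numeric covariates")
  x <- x[complete.cases(x), , drop = FALSE]
  R <- cor(x)
  Om <- tryCatch(solve(R), error = function(e)
    psel_domain_error("covariance matrix is singular (collinear covariates)"))
  P <- -Om / sqrt(diag(Om) %o% diag(Om))
  diag(P) <- 1
  idx <- which(upper.tri(P) & abs(P) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(var_a = colnames(P)[idx[, 1]],
                        var_b = colnames(P)[idx[, 2]],
                        partial_r = P[idx], stringsAsFactors = FALSE)
  list(partial = P, flagged = flagged)
}

#' Per-species trend regression
#'
#' Simple linear regression of a species' study-level Fisher-z selection
#' values on a study attribute (latitude or predator density), reported
#' with slope, intercept, r^2, n, and the two-sided p-value of the slope.
#'
#' @param values [selection_values()] output (or IPA study-level values).
#' @param studies study-attribute table supplying the predictor.
#' @param species_id species to analyse.
#' @param predictor `"latitude"` or `"coyote_density"`.
#' @return One-row data frame (`species_id`, `predictor`, `slope`,
#'   `intercept`, `r2`, `n`, `df`, `p_value`).
#' @export
trend_regression <- function(values, studies, species_id,
                             predictor = c("latitude", "coyote_density")) {
  predictor <- match.arg(predictor)
  v <- values[values$species_id == species_id, , drop = FALSE]
  x <- studies[[predictor]][match(v$study_id, studies$study_id)]
  ok <- !is.na(x) & !is.na(v$z)
  x <- x[ok]; y <- v$z[ok]
  n <- length(y)
  if (n < 3)
    psel_domain_error(sprintf("need >= 3 studies with '%s' for %s",
                              predictor, species_id))
  if (sd(x) == 0)
    psel_domain_error(sprintf("'%s' has zero variance", predictor))
  fit <- lm(y ~ x)
  sm <- summary(fit)
  p <- if (sm$sigma == 0) 0 else sm$coefficients["x", "Pr(>|t|)"]
  data.frame(species_id = species_id, predictor = predictor,
             slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
             r2 = sm$r.squared, n = n, df = n - 2L, p_value = p,
             stringsAsFactors = FALSE)
}

#' Seasonal two-factor ANOVA of selection values
#'
#' Fixed-effects ANOVA of Jacobs' index values on study period and species
#' (type-II sums of squares), restricted to the `top_k` most frequently
#' recorded species. The period-by-species interaction tests whether
#' seasonal shifts are species-specific; when empty cells make it
#' inestimable it is omitted with a warning.
#'
#' @param values [selection_values()] output.
#' @param studies study-attribute table supplying `period`.
#' @param top_k number of most-recorded species to keep (default 12).
#' @param response `"D"` (default, matching the t-test convention) or `"z"`.
#' @return ANOVA table (data frame: term, df1, df2, F, p_value).
#' @export
seasonal_anova <- function(values, studies, top_k = 12, response = c("D", "z")) {
  response <- match.arg(response)
  period <- studies$period[match(values$study_id, studies$study_id)]
  counts <- sort(table(values$species_id), decreasing = TRUE)
  keep_sp <- names(counts)[seq_len(min(top_k, length(counts)))]
  sel <- values$species_id %in% keep_sp & !is.na(period)
  df <- data.frame(y = values[[response]][sel],
                   period = factor(period[sel]),
                   species = factor(values$species_id[sel]))
  if (nlevels(droplevels(df$period)) < 2)
    psel_domain_error("need >= 2 periods for the seasonal ANOVA")
  if (nlevels(droplevels(df$species)) < 2)
    psel_domain_error("need >= 2 species for the seasonal ANOVA")
  df$period <- droplevels(df$period); df$species <- droplevels(df$species)
  two_way_anova_type2(df, "y", "period", "species")
}
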