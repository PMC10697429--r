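# Continuous piecewise-linear (segmented) regression with estimated
# breakpoints, used to delimit the prey weight ranges over which selection
# changes. Fitting is on log10 prey mass; breakpoints are reported both in
# log10 units and back-transformed to kg.

# Least-squares fit of the hinge basis {1, x, (x - b_j)_+} at fixed
# breakpoints b.
fit_hinge <- function(x, y, b) {
  X <- cbind(1, x)
  for (bj in b) X <- cbind(X, pmax(x - bj, 0))
  fit <- lm.fit(X, y)
  if (any(is.na(fit$coefficients))) return(NULL)
  list(coef = fit$coefficients, rss = sum(fit$residuals^2), breakpoints = b)
}

# One-step linearization update of the breakpoints (iterative relocation):
# regress on U_j = (x - b_j)_+ and V_j = -I(x > b_j); the working update is
# b_j <- b_j + gamma_j / beta_j, damped to keep breakpoints ordered and
# interior. Returns the relocated breakpoints or NULL on failure.
relocate_breakpoints <- function(x, y, b, max_iter = 100, tol = 1e-9) {
  lo <- min(x); hi <- max(x)
  span <- hi - lo
  for (it in seq_len(max_iter)) {
    U <- vapply(b, function(bj) pmax(x - bj, 0), numeric(length(x)))
    V <- vapply(b, function(bj) -as.numeric(x > bj), numeric(length(x)))
    X <- cbind(1, x, U, V)
    fit <- tryCatch(lm.fit(X, y), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) return(NULL)
    k <- length(b)
    beta <- fit$coefficients[2 + seq_len(k)]
    gamma <- fit$coefficients[2 + k + seq_len(k)]
    if (any(abs(beta) < 1e-12)) return(NULL)
    step <- gamma / beta
    h <- 1
    repeat {
      b_new <- sort(b + h * step)
      if (all(b_new > lo + 1e-8 * span) && all(b_new < hi - 1e-8 * span) &&
          (k < 2 || min(diff(b_new)) > 1e-8 * span)) break
      h <- h / 2
      if (h < 1e-4) return(NULL)
    }
    if (max(abs(b_new - b)) < tol * max(span, 1)) return(b_new)
    b <- b_new
  }
  NULL  # did not converge
}

# Coordinate-descent grid refinement: optimize one breakpoint at a time
# over candidate locations (midpoints of adjacent unique x) within a local
# window around the initialization, accepting only RSS improvements.
# Deterministic and monotone. The window keeps the estimator local, like
# the iterative relocation it backs up: a global knot search would inflate
# the spurious fit improvement on null data and bias breakpoint-count
# selection upwards.
grid_refine <- function(x, y, b, max_pass = 10, window = NULL) {
  ux <- sort(unique(x))
  cand <- (ux[-1] + ux[-length(ux)]) / 2
  if (length(cand) > 120)
    cand <- unique(quantile(cand, probs = seq(0, 1, length.out = 120),
                            names = FALSE, type = 1))
  best <- fit_hinge(x, y, b)
  if (is.null(best)) return(NULL)
  k <- length(b)
  if (is.null(window)) window <- diff(range(x)) / (2 * (k + 1))
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (j in seq_len(k)) {
      lo <- max(if (j > 1) best$breakpoints[j - 1] else -Inf, b[j] - window)
      hi <- min(if (j < k) best$breakpoints[j + 1] else Inf, b[j] + window)
      for (cj in cand[cand > lo & cand < hi]) {
        bb <- best$breakpoints; bb[j] <- cj
        f <- fit_hinge(x, y, bb)
        if (!is.null(f) && f$rss < best$rss - 1e-12) {
          best <- f; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  best$breakpoints
}

#' Fit a segmented (breakpoint) regression
#'
#' Continuous piecewise-linear least squares of a selection value on
#' (log10) prey mass with `k` estimated breakpoints. Breakpoints start at
#' the interior quantiles of `x` and are relocated iteratively
#' (linearization of the hinge basis); if relocation fails to converge a
#' deterministic coordinate-descent grid search over midpoints of adjacent
#' unique `x` values is used instead. `k = 0` reduces to ordinary simple
#' regression.
#'
#' @param x numeric predictor (log10 prey mass in kg in the intended use).
#' @param y numeric response (study-level Jacobs' index values, or species
#'   means).
#' @param k number of breakpoints (>= 0); requires
#'   `length(x) >= 2 (k + 1) + k`.
#' @param init optional starting breakpoints (ascending).
#' @return A `segmented_fit`: `k`, `breakpoints` (ascending, in `x` units),
#'   `breakpoints_kg` (`10^breakpoints`), `coefficients` (hinge basis),
#'   `segments` (per-segment slope and intercept), `rss`, `logLik`, `AIC`
#'   (parameter count `2 + 2k + 1`: coefficients, breakpoints, residual
#'   variance), `fitted`, and the data.
#' @export
fit_segmented <- function(x, y, k, init = NULL) {
  if (length(x) != length(y)) psel_domain_error("x and y lengths differ")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    psel_domain_error("non-finite values in x or y")
  if (k < 0 || k != round(k)) psel_domain_error("`k` must be a non-negative integer")
  n <- length(x)
  if (n < 2 * (k + 1) + k)
    psel_domain_error(sprintf("need >= %d points for k = %d breakpoints",
                              2 * (k + 1) + k, k))
  if (length(unique(x)) < k + 2)
    psel_domain_error("too few distinct x values (collinear predictor)")

  if (k == 0) {
    f <- fit_hinge(x, y, numeric(0))
    return(new_segmented_fit(x, y, f))
  }
  b0 <- if (!is.null(init)) sort(init) else
    quantile(x, probs = seq_len(k) / (k + 1), names = FALSE, type = 7)
  span <- diff(range(x))
  b0 <- pmin(pmax(b0, min(x) + 1e-6 * span), max(x) - 1e-6 * span)
  if (k >= 2 && min(diff(b0)) <= 0)
    b0 <- seq(min(x) + span / (k + 1), max(x) - span / (k + 1),
              length.out = k)
  b <- relocate_breakpoints(x, y, b0)
  if (is.null(b)) b <- grid_refine(x, y, b0)
  if (is.null(b)) psel_domain_error("segmented fit failed (singular basis)")
  f <- fit_hinge(x, y, b)
  if (is.null(f)) psel_domain_error("segmented fit failed (singular basis)")
  new_segmented_fit(x, y, f)
}

new_segmented_fit <- function(x, y, f) {
  b <- f$breakpoints
  k <- length(b)
  n <- length(y)
  cf <- unname(f$coef)
  # Per-segment slope/intercept implied by the hinge coefficients; the mean
  # function is continuous at each breakpoint by construction.
  slopes <- cumsum(c(cf[2], if (k) cf[3:(2 + k)] else NULL))
  intercepts <- numeric(k + 1)
  intercepts[1] <- cf[1]
  if (k) for (j in seq_len(k))
    intercepts[j + 1] <- intercepts[j] + (slopes[j] - slopes[j + 1]) * b[j]
  X <- cbind(1, x)
  for (bj in b) X <- cbind(X, pmax(x - bj, 0))
  fitted <- drop(X %*% f$coef)
  ll <- -n / 2 * (log(2 * pi) + log(f$rss / n) + 1)
  # Effective parameter count: intercept + base slope, one slope change per
  # segment boundary, TWO effective df per estimated breakpoint location
  # (the non-regular free-knot cost; a nominal 1-df count makes AIC
  # anticonservative for breakpoint-count selection), plus the residual
  # variance.
  n_par <- 2 + k + 2 * k + 1
  structure(list(k = k, breakpoints = b, breakpoints_kg = 10^b,
                 coefficients = f$coef,
                 segments = data.frame(segment = seq_len(k + 1),
                                       slope = slopes,
                                       intercept = intercepts),
                 rss = f$rss, logLik = ll, n_par = n_par,
                 AIC = -2 * ll + 2 * n_par,
                 fitted = fitted, x = x, y = y),
            class = "segmented_fit")
}

#' @rdname fit_segmented
#' @param object a `segmented_fit`.
#' @param ... ignored.
#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("segmented fit: k = %d, RSS = %.4g, AIC = %.2f\n",
              x$k, x$rss, x$AIC))
  if (x$k)
    cat("breakpoints (kg):", paste(signif(x$breakpoints_kg, 3),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Choose the number of breakpoints by AIC
#'
#' Fits `k = 0 .. k_max` segmented models (each initialized from the
#' previous fit's breakpoints plus one grid-optimized addition, so residual
#' sums of squares are non-increasing in `k`) and returns the
#' AIC-minimizing `k` with the full comparison table. Individual fit
#' failures are recorded and excluded.
#'
#' @inheritParams fit_segmented
#' @param k_max largest breakpoint count to consider.
#' @return List: `best_k`, `best_fit`, `table` (data frame `k`, `n_par`,
#'   `rss`, `AIC`, `delta`), `fits` (list indexed `k0 ... k<k_max>`),
#'   `failures` (character).
#' @export
select_breakpoint_count <- function(x, y, k_max) {
  if (k_max < 0) psel_domain_error("`k_max` must be >= 0")
  fits <- list(); failures <- character(0)
  prev <- NULL
  for (k in 0:k_max) {
    fit <- tryCatch({
      f1 <- fit_segmented(x, y, k)
      if (!is.null(prev) && k > 0) {
        # Nested candidate: previous breakpoints plus one extra knot in the
        # middle of the widest gap. Adding a hinge regressor cannot raise
        # the residual sum of squares, so RSS is non-increasing in k.
        edges <- c(min(x), prev$breakpoints, max(x))
        gap <- which.max(diff(edges))
        extra <- (edges[gap] + edges[gap + 1]) / 2
        f2 <- fit_hinge(x, y, sort(c(prev$breakpoints, extra)))
        if (!is.null(f2) && f2$rss < f1$rss)
          f1 <- new_segmented_fit(x, y, f2)
      }
      f1
    }, error = function(e) { failures <<- c(failures,
        sprintf("k = %d: %s", k, conditionMessage(e))); NULL })
    fits[[paste0("k", k)]] <- fit
    if (!is.null(fit)) prev <- fit
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) psel_domain_error("all segmented fits failed")
  tab <- do.call(rbind, lapply(fits[ok], function(f)
    data.frame(k = f$k, n_par = f$n_par, rss = f$rss, AIC = f$AIC)))
  rownames(tab) <- NULL
  tab$delta <- tab$AIC - min(tab$AIC)
  best_k <- tab$k[which.min(tab$AIC)]
  list(best_k = best_k, best_fit = fits[[paste0("k", best_k)]],
       table = tab, fits = fits, failures = failures)
}

#' Between-group tests of selection across prey mass bins
#'
#' Bins study-level selection values by the breakpoints of a segmented
#' model (in kg), merges bins with fewer than 2 values into their nearest
#' neighbour (with a warning), and reports a one-way fixed-effects ANOVA
#' with Tukey-adjusted all-pairs comparisons plus a Kruskal-Wallis
#' rank-based test.
#'
#' @param D selection values (Jacobs' index).
#' @param mass_kg prey mass (kg) aligned with `D`.
#' @param breakpoints_kg ascending breakpoint masses (kg).
#' @return A `mass_group_tests` list: `groups` (factor), `summary` (per-bin
#'   n, mean, interval in kg), `anova` (F, df1, df2, p), `tukey` (data
#'   frame of pairwise adjusted p-values), `kruskal` (statistic, df, p).
#' @export
mass_group_tests <- function(D, mass_kg, breakpoints_kg) {
  check_positive(mass_kg, "mass_kg")
  if (length(D) != length(mass_kg)) psel_domain_error("length mismatch")
  b <- sort(breakpoints_kg)
  edges <- c(min(mass_kg), b, max(mass_kg))
  if (any(duplicated(edges))) edges <- unique(edges)
  cuts <- c(-Inf, b, Inf)
  g <- cut(mass_kg, breaks = cuts, labels = FALSE)
  lower <- c(min(mass_kg), b)
  upper <- c(b, max(mass_kg))
  # Merge under-filled bins into the adjacent bin (downwards when possible).
  repeat {
    tabs <- table(factor(g, levels = seq_along(lower)))
    small <- which(tabs > 0 & tabs < 2)
    empty <- which(tabs == 0)
    drop_bin <- c(small, empty)
    if (!length(drop_bin)) break
    j <- drop_bin[1]
    target <- if (j > 1) j - 1 else j + 1
    if (target > length(lower)) psel_domain_error("cannot form >= 2 groups")
    if (j %in% small)
      warning(sprintf("mass bin %d has < 2 values; merged into neighbour", j),
              call. = FALSE)
    keep <- setdiff(seq_along(lower), j)
    lo <- min(lower[c(j, target)]); hi <- max(upper[c(j, target)])
    lower[target] <- lo; upper[target] <- hi
    g[g == j] <- target
    # reindex
    remap <- match(seq_along(lower), keep)
    g <- match(g, keep)
    lower <- lower[keep]; upper <- upper[keep]
  }
  if (length(lower) < 2)
    psel_domain_error("need >= 2 mass groups with >= 2 values each")
  groups <- factor(g, levels = seq_along(lower),
                   labels = sprintf("G%d", seq_along(lower)))
  fit <- aov(D ~ groups)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$groups
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  kw <- kruskal.test(D ~ groups)
  summary_df <- data.frame(
    group = levels(groups),
    n = as.integer(table(groups)),
    mean_D = as.numeric(tapply(D, groups, mean)),
    lower_kg = lower, upper_kg = upper, stringsAsFactors = FALSE)
  structure(list(groups = groups, summary = summary_df,
                 anova = data.frame(F = an$`F value`[1],
                                    df1 = an$Df[1], df2 = an$Df[2],
                                    p_value = an$`Pr(>F)`[1]),
                 tukey = tukey,
                 kruskal = data.frame(statistic = unname(kw$statistic),
                                      df = unname(kw$parameter),
                                      p_value = kw$p.value)),
            class = "mass_group_tests")
}

#' Accessible and preferred prey weight ranges
#'
#' Operationalizes the weight-range summary of a segmented analysis: a mass
#' bin belongs to the *preferred* range when its mean selection exceeds the
#' across-bin mean of bin means *and* its Tukey-adjusted contrast with the
#' lowest-mass bin is significant at `alpha`; the preferred range is the
#' union of contiguous such bins (reported per contiguous run). The
#' *accessible* range is all masses above the lower edge of that union.
#' Open outer edges are reported at the observed mass extremes.
#'
#' @param group_tests a [mass_group_tests()] result.
#' @param alpha significance level for the contrast with the lowest bin.
#' @return List: `preferred` (data frame `lower_kg`, `upper_kg`; zero rows
#'   when no bin qualifies), `accessible_above_kg` (scalar or `NA`), and
#'   `rule` (the criterion text).
#' @export
accessible_and_preferred_range <- function(group_tests, alpha = 0.05) {
  stopifnot(inherits(group_tests, "mass_group_tests"))
  s <- group_tests$summary
  elevated <- s$mean_D > mean(s$mean_D)
  ref <- s$group[1]
  sig <- vapply(s$group, function(gp) {
    if (gp == ref) return(FALSE)
    pair <- group_tests$tukey$pair %in% c(paste(gp, ref, sep = "-"),
                                          paste(ref, gp, sep = "-"))
    any(group_tests$tukey$p_adj[pair] < alpha)
  }, logical(1))
  selected <- elevated & sig
  runs <- rle(selected)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  idx <- which(runs$values)
  preferred <- data.frame(lower_kg = s$lower_kg[starts[idx]],
                          upper_kg = s$upper_kg[ends[idx]])
  list(preferred = preferred,
       accessible_above_kg = if (nrow(preferred)) min(preferred$lower_kg)
                             else NA_real_,
       rule = paste("bin mean above across-bin mean and Tukey contrast with",
                    sprintf("the lowest-mass bin significant at alpha = %g",
                            alpha)))
}
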