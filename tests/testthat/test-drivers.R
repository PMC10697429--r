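sim_design_frame <- function(n, seed = NULL, beta1 = 0, sigma = 1) {
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  df$z <- beta1 * df$x1 + rnorm(n, 0, sigma)
  df
}

test_that("design construction: column counting and degenerate factors", {
  sim <- simulate_dataset(12, n_species = 6, n_scats = 200, seed = 44)
  covs <- c("log_mass", "group_size", "habitat", "period", "puma_present")
  des <- build_design(sim$dataset, covs)
  nlev <- vapply(des$data[covs], function(x)
    if (is.factor(x)) nlevels(x) else NA_integer_, integer(1))
  expected <- 1 + sum(nlev - 1, na.rm = TRUE) + sum(is.na(nlev))
  expect_equal(ncol(des$model_matrix), expected)

  expect_s3_class(build_design(sim$dataset, character(0)), "psel_design")
  expect_equal(ncol(build_design(sim$dataset, character(0))$model_matrix), 1L)

  expect_error(build_design(sim$dataset, "shoe_size"),
               class = "preysel_schema_error")

  allann <- sim$dataset
  allann$studies$period <- "annual"
  expect_error(build_design(allann, "period"), "single level",
               class = "preysel_domain_error")
})

test_that("missing covariate rows are dropped with a message", {
  sim <- simulate_dataset(12, n_species = 5, n_scats = 200, seed = 45)
  sim$dataset$studies$coyote_density[1:3] <- NA
  expect_message(des <- build_design(sim$dataset, "coyote_density"),
                 "dropping")
  expect_false(anyNA(des$data$coyote_density))
})

test_that("all-subsets table: weights, counts, and planted-effect recovery", {
  df <- sim_design_frame(200, seed = 1, beta1 = 2, sigma = 0.1)
  des <- design_from_frame(df, c("x1", "x2", "x3"))
  tab <- fit_all_subsets(des)
  expect_equal(nrow(tab$models), 8L)
  expect_equal(sum(tab$models$weight), 1, tolerance = 1e-9)
  expect_equal(min(tab$models$delta), 0)
  expect_true(all(tab$importance >= 0 & tab$importance <= 1))
  expect_gt(tab$importance[["x1"]], 0.99)
  expect_equal(tab$averaged$estimate[tab$averaged$term == "x1"], 2,
               tolerance = 0.05)

  # single covariate: exactly the null and the full model
  tab1 <- fit_all_subsets(design_from_frame(df, "x1"))
  expect_equal(nrow(tab1$models), 2L)
  expect_equal(sum(tab1$models$weight), 1, tolerance = 1e-9)

  # weights are invariant to a constant shift of all criterion values
  w <- exp(-(tab$models$delta + 7) / 2)
  expect_equal(w / sum(w), tab$models$weight, tolerance = 1e-12)
})

test_that("null covariates carry low importance; planted zeros average to ~0", {
  set.seed(6)
  imp <- replicate(25, {
    df <- sim_design_frame(200, beta1 = 2, sigma = 0.1)
    tab <- fit_all_subsets(design_from_frame(df, c("x1", "x2", "x3")))
    c(tab$importance[["x2"]], tab$importance[["x3"]],
      tab$averaged$estimate[tab$averaged$term == "x2"])
  })
  expect_lt(mean(imp[1:2, ]), 0.5)
  expect_lt(mean(abs(imp[3, ])), 0.02)
})

test_that("AICc and AIC differ by the small-sample correction", {
  df <- sim_design_frame(30, seed = 9, beta1 = 1)
  des <- design_from_frame(df, c("x1", "x2"))
  aicc <- fit_all_subsets(des, criterion = "AICc")
  aic <- fit_all_subsets(des, criterion = "AIC")
  m <- aic$models[match(aicc$models$terms, aic$models$terms), ]
  expect_equal(aicc$models$AICc,
               m$AIC + 2 * m$k * (m$k + 1) / (30 - m$k - 1),
               tolerance = 1e-9)
})

test_that("partial correlations: definition, singularity, orthogonality", {
  set.seed(10)
  x <- matrix(rnorm(3000), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  scr <- partial_correlation_screen(x, threshold = 0.5)
  expect_true(all(abs(scr$partial[upper.tri(scr$partial)]) < 0.1))
  expect_equal(nrow(scr$flagged), 0L)

  # two covariates: partial equals plain correlation
  scr2 <- partial_correlation_screen(x[, 1:2])
  expect_equal(scr2$partial["a", "b"], cor(x[, 1], x[, 2]),
               tolerance = 1e-12)

  dup <- cbind(x, d = x[, "a"])
  expect_error(partial_correlation_screen(dup),
               class = "preysel_domain_error")
})

test_that("trend regression matches the closed-form least-squares oracle", {
  xs <- c(31, 35, 40, 44, 52)
  ys <- c(-0.42, -0.10, 0.08, 0.35, 0.61)
  vals <- data.frame(study_id = paste0("s", 1:5), species_id = "md",
                     z = ys)
  st <- make_studies(paste0("s", 1:5)); st$latitude <- xs
  fit <- trend_regression(vals, st, "md", "latitude")
  # independent oracle: explicit normal equations
  sxx <- sum((xs - mean(xs))^2); sxy <- sum((xs - mean(xs)) * (ys - mean(ys)))
  slope <- sxy / sxx; intercept <- mean(ys) - slope * mean(xs)
  r2 <- sxy^2 / (sxx * sum((ys - mean(ys))^2))
  expect_equal(fit$slope, slope, tolerance = 1e-10)
  expect_equal(fit$intercept, intercept, tolerance = 1e-10)
  expect_equal(fit$r2, r2, tolerance = 1e-10)
  expect_equal(fit$df, 3L)

  # perfectly linear: r2 = 1; constant response: slope 0, r2 0
  vals$z <- 0.02 * xs - 1
  expect_equal(suppressWarnings(
    trend_regression(vals, st, "md", "latitude")$r2), 1, tolerance = 1e-9)
  vals$z <- rep(0.3, 5)
  flat <- suppressWarnings(trend_regression(vals, st, "md", "latitude"))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r2, 0, tolerance = 1e-12)

  st$latitude <- rep(40, 5)
  expect_error(trend_regression(vals, st, "md", "latitude"),
               class = "preysel_domain_error")
  expect_error(trend_regression(vals[1:2, ], st, "md", "latitude"),
               class = "preysel_domain_error")
})

test_that("latitude-dependent preference is recovered by trend regression", {
  hits <- 0
  for (rep in 1:20) {
    sim <- simulate_dataset(18, n_species = 6, n_scats = 800,
                            covariate_effects = list(sp03 = list(latitude = 0.08)),
                            seed = 100 + rep)
    v <- selection_values(sim$dataset)
    fit <- trend_regression(v, sim$dataset$studies, "sp03", "latitude")
    hits <- hits + (fit$slope > 0 && fit$p_value < 0.05)
  }
  expect_gte(hits / 20, 0.8)
})

test_that("seasonal ANOVA: null calibration, planted species effect, errors", {
  make_seasonal <- function(species_shift = 0, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    periods <- c("spring", "summer", "fall", "winter")
    df <- expand.grid(study_id = paste0("s", 1:16),
                      species_id = paste0("sp", 1:4),
                      stringsAsFactors = FALSE)
    df$D <- rnorm(nrow(df), 0, 0.2) +
      species_shift * as.integer(factor(df$species_id))
    st <- make_studies(paste0("s", 1:16),
                       period = rep(periods, each = 4))
    list(values = df, studies = st)
  }
  # under the null the period F is a central F(3, 48): mean 48/46 ~ 1.04
  set.seed(12)
  fs <- replicate(200, {
    d <- make_seasonal()
    seasonal_anova(d$values, d$studies)$F[1]
  })
  expect_gt(mean(fs), 0.8)
  expect_lt(mean(fs), 1.25)

  d <- make_seasonal(species_shift = 0.5, seed = 2)
  an <- seasonal_anova(d$values, d$studies)
  expect_gt(an$F[an$term == "species"], 10)
  expect_lt(an$F[an$term == "period"], 3)
  expect_equal(an$term, c("period", "species", "period:species"))

  d$studies$period <- "annual"
  expect_error(seasonal_anova(d$values, d$studies),
               class = "preysel_domain_error")
})
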