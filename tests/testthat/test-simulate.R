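test_that("community simulation: ranges, determinism, degenerate input", {
  com <- simulate_community(2, mass_range_kg = c(1, 1), seed = 1)
  expect_equal(com$traits$adult_female_mass_kg, c(1, 1))

  a <- simulate_community(10, seed = 7)
  b <- simulate_community(10, seed = 7)
  expect_identical(a, b)

  expect_error(simulate_community(1), class = "preysel_domain_error")
  expect_error(simulate_community(5, mass_range_kg = c(2, 1)),
               class = "preysel_domain_error")
  expect_error(simulate_community(5, mass_range_kg = c(-1, 1)),
               class = "preysel_domain_error")

  # masses stay inside the requested range (property over many seeds)
  ok <- vapply(1:1000, function(s) {
    m <- simulate_community(60, mass_range_kg = c(0.01, 357),
                            seed = s)$traits$adult_female_mass_kg
    all(m >= 0.01 & m <= 357)
  }, logical(1))
  expect_true(all(ok))
})

test_that("closed-form D matches the independent algebraic oracle", {
  expect_equal(closed_form_D(c(3, 1), c(0.5, 0.5))$r_star, c(0.75, 0.25))
  expect_equal(closed_form_D(c(3, 1), c(0.5, 0.5))$D_star, c(0.5, -0.5))
  expect_equal(closed_form_D(c(2, 2, 2), c(0.2, 0.3, 0.5))$D_star,
               c(0, 0, 0))
  set.seed(40)
  for (i in 1:50) {
    w <- exp(rnorm(6)); p <- rgamma(6, 2); p <- p / sum(p)
    cf <- closed_form_D(w, p)
    expect_equal(cf$D_star, closed_form_D_oracle(w, p), tolerance = 1e-12)
    expect_equal(sum(cf$r_star), 1, tolerance = 1e-12)
    expect_equal(cf$D_star, jacobs_index(cf$r_star, p), tolerance = 1e-15)
  }
  # a species eaten near-exclusively (r* -> 1) with p < 1 approaches D* = 1
  expect_equal(closed_form_D(c(1e12, 1), c(0.5, 0.5))$D_star[1], 1,
               tolerance = 1e-6)
})

test_that("study simulation: censoring semantics and retention floor", {
  truth <- list(w = setNames(rep(1, 6), paste0("sp", 1:6)),
                availability_alpha = setNames(rep(10, 6), paste0("sp", 1:6)))
  st <- simulate_study(truth, n_scats = 100, censor_prob = 0.5, seed = 5)
  expect_identical(st$diet$species_id, st$availability$species_id)
  expect_gte(length(st$retained), 3L)
  expect_setequal(c(st$retained, st$censored), paste0("sp", 1:6))
  expect_equal(sum(st$availability$rel_abundance), 1, tolerance = 1e-12)
  # counts are drawn for the full community, then censored rows removed
  expect_lte(sum(st$diet$occurrences), 100)
  expect_error(simulate_study(truth, n_scats = 0),
               class = "preysel_domain_error")
  expect_error(simulate_study(truth, censor_prob = 1),
               class = "preysel_domain_error")
})

test_that("empirical D concentrates on the closed form as scats grow", {
  truth <- list(w = setNames(c(3, 1), c("a", "b")),
                availability_alpha = setNames(c(25, 25), c("a", "b")))
  set.seed(50)
  close <- vapply(1:100, function(i) {
    st <- simulate_study(truth, n_scats = 2000)
    r <- st$diet$occurrences / sum(st$diet$occurrences)
    p <- st$availability$rel_abundance
    all(abs(jacobs_index(r, p) - st$D_star) <= 0.05)
  }, logical(1))
  expect_gte(mean(close), 0.95)
})

test_that("full dataset simulation is valid, deterministic, and effect-aware", {
  sim <- simulate_dataset(5, n_species = 6, n_scats = 120, seed = 61)
  expect_s3_class(sim$dataset, "prey_dataset")  # generator passes validation
  expect_equal(nrow(sim$dataset$studies), 5L)

  sim2 <- simulate_dataset(5, n_species = 6, n_scats = 120, seed = 61)
  expect_identical(sim$dataset$diet, sim2$dataset$diet)
  expect_identical(sim$truth$D_star, sim2$truth$D_star)
  # byte-identical CSV output under a fixed seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(sim$dataset, d1); write_dataset(sim2$dataset, d2)
  for (f in c("diet.csv", "availability.csv", "traits.csv", "studies.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  expect_error(simulate_dataset(3, covariate_effects = list(ghost = list(
    latitude = 0.1)), seed = 1), class = "preysel_domain_error")

  # a single-study dataset flows through every stage
  one <- simulate_dataset(1, n_species = 5, n_scats = 100, seed = 62)
  v <- selection_values(one$dataset)
  expect_gt(nrow(v), 0)
  s <- summarize_species(v)
  expect_true(all(s$preference_class == "none"))  # n = 1: no test
  expect_s3_class(ipa_estimate(one$dataset), "ipa_result")

  # a stated latitude effect raises the species' weight at high latitude
  eff <- simulate_dataset(12, n_species = 6, n_scats = 100,
                          covariate_effects = list(sp01 = list(latitude = 0.1)),
                          seed = 63)
  w <- eff$truth$w["sp01", ]
  lat <- eff$dataset$studies$latitude
  expect_gt(cor(log(w), lat), 0.999)
})

test_that("selection pipeline on exact expected proportions reproduces D*", {
  # oracle coherence: feed r* directly as occurrence weights (the
  # infinite-scat limit); the traditional estimator must return D* exactly
  set.seed(70)
  w <- setNames(exp(rnorm(5, 0, 0.7)), paste0("sp", 1:5))
  p <- rgamma(5, 3); p <- setNames(p / sum(p), names(w))
  cf <- closed_form_D(w, p)
  big <- 1e7  # counts proportional to r*; scale is irrelevant to RFO
  diet <- data.frame(study_id = "s", species_id = names(w),
                     occurrences = cf$r_star * big)
  avail <- data.frame(study_id = "s", species_id = names(w),
                      rel_abundance = p)
  ds <- suppressWarnings(prey_dataset(diet, avail, make_traits(names(w)),
                                      make_studies("s")))
  v <- selection_values(ds)
  expect_equal(setNames(v$D, v$species_id), cf$D_star, tolerance = 1e-12)
})
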