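test_that("relative frequency of occurrence", {
  expect_equal(relative_frequency_of_occurrence(c(A = 5, B = 5)),
               c(A = 0.5, B = 0.5))
  expect_equal(relative_frequency_of_occurrence(c(A = 30, B = 10, C = 0)),
               c(A = 0.75, B = 0.25, C = 0))
  expect_equal(relative_frequency_of_occurrence(c(A = 7)), c(A = 1))
  expect_error(relative_frequency_of_occurrence(c(A = 0, B = 0)),
               class = "preysel_domain_error")
  expect_error(relative_frequency_of_occurrence(c(A = -1, B = 2)),
               class = "preysel_domain_error")
})

test_that("Jacobs' index point examples and degenerate pair", {
  expect_equal(jacobs_index(0.3, 0.3), 0)
  expect_equal(jacobs_index(0.5, 0.2), 0.6)     # 0.3 / (0.7 - 0.2)
  expect_equal(jacobs_index(1, 0.4), 1)
  expect_error(jacobs_index(0, 0), class = "preysel_domain_error")
  expect_error(jacobs_index(1.2, 0.5), class = "preysel_domain_error")
})

test_that("Jacobs' index agrees with the odds-form oracle on a dense grid", {
  g <- seq(0.005, 0.995, by = 0.015)
  grid <- expand.grid(r = g, p = g)
  expect_equal(jacobs_index(grid$r, grid$p),
               jacobs_odds_oracle(grid$r, grid$p), tolerance = 1e-12)
  # antisymmetry under swapping use and availability
  expect_identical(jacobs_index(grid$p, grid$r), -jacobs_index(grid$r, grid$p))
  # bounded and zero iff r = p in the interior
  D <- jacobs_index(grid$r, grid$p)
  expect_true(all(D >= -1 & D <= 1))
  expect_identical(D == 0, grid$r == grid$p)
  expect_identical(sign(D), sign(grid$r - grid$p))
})

test_that("Fisher z transform: closed forms, clamp, oddness", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.6), 0.5 * log(1.6 / 0.4), tolerance = 1e-12)
  expect_equal(fisher_z(0.6), 0.6931, tolerance = 1e-4)
  # boundary clamp: atanh(1 - eps), here via the independent log form
  expect_equal(fisher_z(1, eps = 1e-6), 0.5 * log((2 - 1e-6) / 1e-6),
               tolerance = 1e-10)
  expect_equal(fisher_z(1, eps = 1e-6), 7.2543, tolerance = 1e-4)
  D <- seq(-1, 1, by = 0.05)
  expect_equal(fisher_z(-D), -fisher_z(D))
  expect_true(all(diff(fisher_z(D)) > 0))
  expect_equal(inv_fisher_z(fisher_z(0.37)), 0.37, tolerance = 1e-12)
  expect_error(fisher_z(0.5, eps = 0.5), class = "preysel_domain_error")
})

test_that("inverse_jacobs inverts the index at fixed availability", {
  g <- expand.grid(D = seq(-0.9, 0.9, by = 0.1), p = seq(0.05, 0.95, 0.1))
  r <- inverse_jacobs(g$D, g$p)
  expect_equal(jacobs_index(r, g$p), g$D, tolerance = 1e-12)
  expect_equal(inverse_jacobs(0, 0.3), 0.3)  # no selection: r = p
  expect_equal(inverse_jacobs(0.5, 0.5), 0.75)
})

test_that("study-level selection values match the hand-computed toy", {
  v <- selection_values(make_toy_dataset())
  for (s in c("A", "B")) {
    got <- v[v$study_id == s, ]
    expect_equal(setNames(got$D, got$species_id), TOY_D[[s]],
                 tolerance = 1e-12)
    expect_equal(got$z, fisher_z(got$D))
  }
  expect_true(all(v$method == "traditional"))
})

test_that("species summaries pool, test, and classify", {
  v <- selection_values(make_toy_dataset())
  s <- summarize_species(v)
  expect_equal(nrow(s), 3L)
  x <- s[s$species_id == "x", ]
  expect_equal(x$mean_D, (7 / 11 - 0.2) / 2, tolerance = 1e-12)
  expect_equal(x$df, 1L)
  expect_equal(x$t_stat, x$mean_D / x$se_D)

  # printed-summary reconstruction: mean 0.47, SE 0.10, n 38 -> t ~ 4.71
  ts <- t_from_summary(0.47, 0.10, 38)
  expect_equal(ts$t, 4.7, tolerance = 1e-12)
  expect_equal(ts$df, 37)
  expect_lt(ts$p_value, 0.001)

  # symmetric pair: mean 0, t 0, p 1, no class
  sym <- data.frame(species_id = "a", method = "traditional",
                    D = c(0.2, -0.2))
  out <- summarize_species(sym)
  expect_equal(out$t_stat, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$preference_class, "none")

  # degenerate variance: signed infinity sentinel, p = 0, classified
  con <- data.frame(species_id = "a", method = "traditional",
                    D = c(0.5, 0.5, 0.5))
  out <- summarize_species(con)
  expect_identical(out$t_stat, Inf)
  expect_identical(out$p_value, 0)
  expect_equal(out$preference_class, "preferred")

  # single study: test marked missing, class none
  one <- data.frame(species_id = "a", method = "traditional", D = 0.9)
  out <- summarize_species(one)
  expect_true(is.na(out$t_stat) && is.na(out$p_value))
  expect_equal(out$preference_class, "none")

  # near-significance annotation band [0.05, 0.10)
  tab <- species_summary_fixture()
  jbt <- tab[tab$common_name == "Jackrabbit, black-tailed", ]
  ts <- t_from_summary(jbt$mean_D, jbt$se_D, jbt$n)
  expect_true(ts$p_value >= 0.05 && ts$p_value < 0.10)
})

test_that("mean-D pooling is order-invariant; duplication halves variance", {
  v <- selection_values(make_toy_dataset())
  s1 <- summarize_species(v)
  s2 <- summarize_species(v[rev(seq_len(nrow(v))), ])
  expect_equal(s1, s2)
  dup <- rbind(v, transform(v, study_id = paste0(study_id, "2")))
  s3 <- summarize_species(dup)
  expect_equal(s3$mean_D, s1$mean_D)
  # sd unchanged, n doubled (2 -> 4): se scales by sd-ratio sqrt((n-1)/... )
  # for an exact duplicate, sd_4 = sd_2 * sqrt(2/3) and se = sd/sqrt(n):
  expect_equal(s3$se_D, s1$se_D * sqrt(2 / 3) / sqrt(2), tolerance = 1e-12)
})

test_that("ideal prey mass and predator:prey ratio", {
  tr <- data.frame(species_id = c("dall", "wtd", "cottontail", "vole"),
                   scientific_name = NA, adult_female_mass_kg =
                     c(55.65, 55.51, 1.17, 0.06),
                   mass_is_scaled = TRUE, group_size_class = 3,
                   threat_level = 1)
  summ <- data.frame(species_id = tr$species_id,
                     preference_class = "preferred")
  im <- ideal_prey_mass(summ, tr)
  expect_equal(im, 28.0975, tolerance = 1e-12)
  rat <- predator_prey_ratio(im, 13.2)
  expect_equal(round(rat$ratio, 2), 2.13)
  expect_identical(rat$label, "1:2.13")

  expect_equal(ideal_prey_mass(summ[1, , drop = FALSE], tr), 55.65)
  none <- data.frame(species_id = "dall", preference_class = "none")
  expect_identical(ideal_prey_mass(none, tr), numeric(0))

  expect_equal(predator_prey_ratio(13.2, 13.2)$label, "1:1.00")
  expect_equal(predator_prey_ratio(6.6, 13.2)$label, "1:0.50")
  expect_error(predator_prey_ratio(0, 13.2), class = "preysel_domain_error")
})
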