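test_that("density estimate is a proper density peaked where the data are", {
  prof <- new_fraction_profile(rep(0.5, 500))
  d <- estimate_density(prof)
  expect_equal(trapz(d$x, d$y), 1, tolerance = 1e-6)
  expect_true(all(d$y >= 0))
  expect_equal(d$x[which.max(d$y)], 0.5, tolerance = 2 / length(d$x))
})

test_that("a uniform sample yields a near-flat interior density", {
  set.seed(1)
  prof <- new_fraction_profile(stats::runif(20000, 0.05, 0.95))
  d <- estimate_density(prof)
  interior <- d$x >= 0.15 & d$x <= 0.85
  expect_lt(max(d$y[interior]) / min(d$y[interior]), 1.5)
})

test_that("too few sites raise an error carrying the counts", {
  prof <- new_fraction_profile(stats::runif(50, 0.2, 0.8))
  err <- tryCatch(estimate_density(prof, min_sites = 200),
                  radploidy_too_few_sites = identity)
  expect_s3_class(err, "radploidy_too_few_sites")
  expect_equal(err$n_sites, 50)
  expect_equal(err$min_sites, 200)
})

test_that("mode detection finds analytic Gaussian peaks and respects symmetry", {
  x <- seq(0, 1, length.out = 512)
  two <- stats::dnorm(x, 1/3, 0.05) + stats::dnorm(x, 2/3, 0.05)
  dens <- structure(list(x = x, y = two / trapz(x, two), bw = NA, n = NA),
                    class = "fraction_density")
  modes <- detect_modes(dens)
  expect_length(modes, 2)
  expect_equal(modes[1], 1/3, tolerance = 0.01)
  expect_equal(modes[2], 2/3, tolerance = 0.01)
  # mirror symmetry within grid resolution
  expect_equal(modes[1] + modes[2], 1, tolerance = 2 / 512)

  one <- stats::dnorm(x, 0.5, 0.05)
  dens1 <- structure(list(x = x, y = one / trapz(x, one), bw = NA, n = NA),
                     class = "fraction_density")
  expect_equal(detect_modes(dens1), 0.5, tolerance = 0.01)

  flat <- structure(list(x = x, y = rep(1, 512), bw = NA, n = NA),
                    class = "fraction_density")
  expect_lte(length(detect_modes(flat)), 1)
})

test_that("simulated hexaploid-class samples show modes near 1/3 and 2/3", {
  sites <- simulate_sample(sim_config(3, n_sites = 5000, seed = 21))
  prof <- fraction_profile(sites)
  modes <- detect_modes(estimate_density(prof))
  expect_length(modes, 2)
  expect_lt(abs(modes[1] - 1/3), 0.05)
  expect_lt(abs(modes[2] - 2/3), 0.05)
})

test_that("candidate scoring ranks the generating copy number first", {
  for (m in 2:3) {
    sites <- simulate_sample(sim_config(m, n_sites = 3000, seed = 30 + m))
    prof <- fraction_profile(sites)
    sc <- score_candidates(prof)
    expect_equal(sc$m[which.max(sc$peak_score)], m)
    expect_equal(sc$m[which.min(sc$bic)], m)
  }
  # m = 4 over replicates: majority recovery on both scores
  wins_peak <- wins_bic <- 0L
  for (r in 1:10) {
    sites <- simulate_sample(sim_config(4, n_sites = 3000, seed = 400 + r))
    sc <- score_candidates(fraction_profile(sites))
    wins_peak <- wins_peak + (sc$m[which.max(sc$peak_score)] == 4L)
    wins_bic <- wins_bic + (sc$m[which.min(sc$bic)] == 4L)
  }
  expect_gte(wins_peak, 8L)
  expect_gte(wins_bic, 8L)
})

test_that("calls map effective copy number to cytotype ploidy", {
  sites2 <- simulate_sample(sim_config(2, n_sites = 5000,
                                       depth_law = depth_uniform(30, 30),
                                       seed = 51))
  expect_equal(call_ploidy(fraction_profile(sites2))$reported_ploidy, "4x")

  sites3 <- simulate_sample(sim_config(3, n_sites = 3000, seed = 52))
  call3 <- call_ploidy(fraction_profile(sites3))
  expect_equal(call3$reported_ploidy, "6x")
  expect_equal(call3$effective_m, 3L)

  # autopolyploid reporting: cytotype factor 1
  expect_equal(call_ploidy(fraction_profile(sites3),
                           cytotype_factor = 1)$reported_ploidy, "3x")

  expect_error(call_ploidy(fraction_profile(sites3), candidates = list()),
               "empty candidate")
})

test_that("calls are deterministic, bit for bit in the serialized report", {
  sites <- simulate_sample(sim_config(3, n_sites = 2000, seed = 99))
  prof <- fraction_profile(sites)
  a <- call_ploidy(prof)
  b <- call_ploidy(prof)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_identical(as_report_row(a), as_report_row(b))
})

test_that("mirroring fractions f -> 1 - f leaves the reported ploidy unchanged", {
  for (m in 2:4) {
    sites <- simulate_sample(sim_config(m, n_sites = 2500, seed = 60 + m))
    prof <- fraction_profile(sites)
    mirrored <- new_fraction_profile(1 - prof$fractions,
                                     sample_id = prof$sample_id)
    a <- call_ploidy(prof)
    b <- call_ploidy(mirrored)
    expect_identical(a$reported_ploidy, b$reported_ploidy)
    expect_identical(a$effective_m, b$effective_m)
  }
})

test_that("thin profiles are called but flagged low_sites", {
  sites <- simulate_sample(sim_config(2, n_sites = 120, seed = 8))
  prof <- fraction_profile(sites)
  expect_warning(call <- call_ploidy(prof), "low-confidence")
  expect_equal(call$confidence_flag, "low_sites")
  expect_equal(call$reported_ploidy, "4x")
})

test_that("recovery does not degrade as sites accumulate", {
  recover_rate <- function(n_sites) {
    hits <- 0L
    for (r in 1:8) {
      # common random seeds across the n_sites grid
      sites <- simulate_sample(sim_config(3, n_sites = n_sites,
                                          seed = 7000 + r))
      suppressWarnings(
        hits <- hits + (call_ploidy(fraction_profile(sites))$effective_m == 3L)
      )
    }
    hits
  }
  rates <- vapply(c(300, 1000, 3000), recover_rate, integer(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[3], 8L)
})

test_that("the mixture criterion separates hexaploid from octoploid laws", {
  sites3 <- simulate_sample(sim_config(3, n_sites = 3000, seed = 71))
  f3 <- fraction_profile(sites3)$fractions
  spec3 <- ploidy_model_spec(3)
  spec4 <- ploidy_model_spec(4)
  fit33 <- fit_dosage_mixture(f3, spec3$component_means)
  fit34 <- fit_dosage_mixture(f3, spec4$component_means)
  expect_lt(fit33$bic, fit34$bic)

  sites4 <- simulate_sample(sim_config(4, n_sites = 3000, seed = 72))
  f4 <- fraction_profile(sites4)$fractions
  fit43 <- fit_dosage_mixture(f4, spec3$component_means)
  fit44 <- fit_dosage_mixture(f4, spec4$component_means)
  expect_lt(fit44$bic, fit43$bic)
  # weights are a probability vector
  expect_equal(sum(fit44$weights), 1, tolerance = 1e-8)
})
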