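test_that("initial_peak_estimate finds the peak beyond the error valley", {
  sp <- make_spectrum(c(1L, 2L, 3L, 54L, 55L, 56L),
                      c(1e6, 1e5, 1e3, 1e3, 5e3, 1e3))
  expect_identical(initial_peak_estimate(sp), 55L)

  # tie in the transformed series resolves toward smaller abundance
  tie <- make_spectrum(c(1L, 2L, 10L, 50L, 60L), c(1e6, 1e4, 5, 60, 50))
  expect_identical(initial_peak_estimate(tie), 50L)

  expect_error(initial_peak_estimate(make_spectrum(integer(0), numeric(0))),
               "empty")
  mono <- make_spectrum(1:6, c(1e6, 2e5, 4e4, 9e3, 2e3, 400))
  expect_error(initial_peak_estimate(mono), class = "kspectra_low_coverage")

  # no error spike at all: global argmax of x * z
  clean <- make_spectrum(c(30L, 31L, 32L), c(10, 500, 12))
  expect_identical(initial_peak_estimate(clean), 31L)
})

test_that("peak estimate tracks simulated k-mer depth", {
  spec <- genome_spec(data.frame(copy_number = 1, length = 50000), seed = 61)
  g <- generate_genome(spec)
  params <- sim_params(read_length = 76, depth = 40, error_rate = 0, seed = 62)
  sp <- kmer_spectrum(simulate_reads(g, params))
  expected <- 40 * (76 - 21 + 1) / 76        # read depth scaled to k-mer depth
  c0 <- initial_peak_estimate(sp)
  expect_lt(abs(c0 - expected) / expected, 0.10)
})

noiseless_fixture <- function(c = 50, s = 0.3, a = c(1e5, 1e3, rep(0, 4), 500),
                              x_max = 600) {
  m <- mixture_model(c = c, s = s, a = a)
  x <- 1:x_max
  list(model = m, spectrum = make_spectrum(x, round(model_expectation(x, m))))
}

test_that("noiseless spectra are re-fit to within 1%", {
  fx <- noiseless_fixture()
  fit <- fit_spectrum(fx$spectrum, fit_config(max_copy_number = 10))
  expect_lt(abs(fit$model$c - fx$model$c) / fx$model$c, 0.01)
  truth <- genome_size_estimate(fx$model)
  expect_lt(abs(genome_size_estimate(fit) - truth) / truth, 0.01)
  expect_true(fit$reliable)
})

test_that("scaling all bin counts scales the coefficients, not c or s", {
  fx <- noiseless_fixture()
  fit1 <- fit_spectrum(fx$spectrum, fit_config(max_copy_number = 8))
  sp3 <- make_spectrum(fx$spectrum$abundance, 3 * fx$spectrum$count)
  fit3 <- fit_spectrum(sp3, fit_config(max_copy_number = 8))
  expect_equal(fit3$model$c, fit1$model$c, tolerance = 0.01)
  expect_equal(fit3$model$s, fit1$model$s, tolerance = 0.05)
  expect_equal(genome_size_estimate(fit3), 3 * genome_size_estimate(fit1),
               tolerance = 0.01)
})

test_that("bins below the low-abundance cutoff cannot move the estimate", {
  fx <- noiseless_fixture()
  fit <- fit_spectrum(fx$spectrum, fit_config(max_copy_number = 8))
  x_min <- fit$model$x_min
  # inject arbitrarily large error bins strictly below the cutoff
  low <- seq_len(x_min - 1L)
  keep <- fx$spectrum$abundance >= x_min
  sp_err <- make_spectrum(c(low, fx$spectrum$abundance[keep]),
                          c(10^7 / low^3, fx$spectrum$count[keep]))
  fit_err <- fit_spectrum(sp_err, fit_config(max_copy_number = 8))
  expect_identical(fit_err$model$x_min, x_min)
  expect_identical(genome_size_estimate(fit_err), genome_size_estimate(fit))
  expect_identical(fit_err$model$a, fit$model$a)
})

test_that("component count can be constrained to one (phiX-style fit)", {
  m <- mixture_model(c = 500, s = 0.05, a = 2000)
  x <- 1:1500
  sp <- make_spectrum(x, round(model_expectation(x, m)))
  fit <- fit_spectrum(sp, fit_config(max_components = 1, min_abundance = 100))
  expect_identical(sum(fit$model$a > 0), 1L)
  expect_gte(fit$model$x_min, 100L)
  expect_equal(fit$model$a[1], 2000, tolerance = 0.02)
  expect_equal(fit$model$c, 500, tolerance = 0.01)
})

test_that("adding components never worsens the fit on a fixed range", {
  # identical masked range for every fit, so the optima are over nested
  # coefficient spaces and the log-likelihood must be non-decreasing in N
  fx <- noiseless_fixture()
  fits <- lapply(c(1, 2, 5, 8), function(N)
    fit_spectrum(fx$spectrum, fit_config(max_copy_number = N,
                                         max_abundance = 600)))
  r <- fits[[1]]$x_range[1]:fits[[1]]$x_range[2]
  lls <- vapply(fits, function(f)
    spectrum_log_likelihood(fx$spectrum, f$model, r), numeric(1))
  expect_true(all(diff(lls) > -1e-4 * abs(lls[-length(lls)])))
})

test_that("fit result serialises to JSON with the derived profile", {
  fx <- noiseless_fixture()
  fit <- fit_spectrum(fx$spectrum, fit_config(max_copy_number = 8))
  js <- withr_local_file("fit.json")
  tsv <- withr_local_file("fit_profile.tsv")
  write_fit_result(fit, js, tsv)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$model$c, fit$model$c)
  expect_equal(back$genome_size_estimate, genome_size_estimate(fit))
  expect_true(file.exists(tsv))
})

test_that("genome size recovers across seeds at 60x coverage", {
  # scaled-down recovery sweep: 100-kb genome with a 7-copy repeat
  errs <- vapply(1:10, function(seed) {
    spec <- genome_spec(data.frame(copy_number = c(1, 7),
                                   length = c(80000, 2000)), seed = 600 + seed)
    params <- sim_params(depth = 60, error_rate = 0.01, seed = 700 + seed)
    rep <- recovery_experiment(spec, params, fit_config(max_copy_number = 10))
    expect_identical(rep$status, "ok")
    abs(rep$size_relative_error)
  }, numeric(1))
  expect_lt(median(errs), 0.03)
})
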