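#' Negative binomial pmf in the mu-alpha parameterization
#'
#' Probability mass at `x` of a negative binomial with mean `mean` and
#' dispersion `alpha`, i.e. variance = mean + alpha * mean^2 (size
#' r = 1/alpha, success probability r / (r + mean)). The parameterization
#' is continuous in alpha, and alpha = 0 is the Poisson limit; means need
#' not be integers. Evaluation is delegated to `stats::dnbinom`, which
#' works in log space internally, so large x do not underflow.
#'
#' @param x non-negative integer (vectorised).
#' @param mean positive real mean.
#' @param alpha non-negative dispersion; 0 gives Poisson(`mean`).
#' @param log return log probability.
#' @return probability mass (or its log).
#' @examples
#' nb_pmf(0, mean = 1, alpha = 0)       # exp(-1)
#' nb_pmf(5, mean = 10, alpha = 0.5)
#' @export
nb_pmf <- function(x, mean, alpha, log = FALSE) {
  if (any(x < 0) || any(x != floor(x))) stop("x must be a non-negative integer",
                                             call. = FALSE)
  if (any(mean <= 0)) stop("mean must be positive", call. = FALSE)
  if (any(alpha < 0)) stop("alpha must be non-negative", call. = FALSE)
  # below ~1e-14 the NB size parameter overflows usefully; the pmf is
  # numerically Poisson there anyway
  if (all(alpha < 1e-14)) return(dpois(x, lambda = mean, log = log))
  dnbinom(x, size = 1 / alpha, mu = mean, log = log)
}

#' Mixture model of a k-mer abundance spectrum
#'
#' Container for the fitted mixed over-dispersed Poisson model. Component
#' n (copy number n) is a negative binomial with mean `c * n` and
#' dispersion `s / n`, weighted by the coefficient `a[n]` — the amount of
#' unique sequence (distinct k-mers) at copy number n. `c` is the abundance
#' of the principal (single-copy) peak, i.e. the per-k-mer sequencing
#' depth; `s` absorbs coverage unevenness beyond Poisson.
#'
#' @param c principal-peak abundance (> 0).
#' @param s overdispersion shape (>= 0); 0 gives a pure mixed Poisson.
#' @param a numeric vector of non-negative coefficients a_1..a_N.
#' @param x_min low-abundance cutoff below which bins are excluded from the
#'   likelihood (default 1 = nothing excluded).
#' @return a `mixture_model` object.
#' @export
mixture_model <- function(c, s, a, x_min = 1L) {
  stopifnot(length(c) == 1L, c > 0, length(s) == 1L, s >= 0,
            length(a) >= 1L, all(a >= 0), x_min >= 1)
  structure(list(c = as.numeric(c), s = as.numeric(s), a = as.numeric(a),
                 N = length(a), x_min = as.integer(x_min)),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  nz <- which(x$a > 0.5)
  cat("mixture_model: c = ", signif(x$c, 5), ", s = ", signif(x$s, 4),
      ", N = ", x$N, ", x_min = ", x$x_min, "\n", sep = "")
  cat("  genome size ", format(round(genome_size_estimate(x)), big.mark = ","),
      " bp; non-negligible components at n = {",
      paste(nz, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Expected spectrum counts under a mixture model
#'
#' Evaluates P_NO(x) = sum_n a_n * NB(x; mean = c n, alpha = s / n): the
#' expected number of distinct k-mers at abundance x. With s = 0 this is
#' the mixed Poisson P_N; with a single component it reduces to
#' a_1 * Poisson(x; c). Linear in the coefficients; sums over x to
#' sum(a).
#'
#' @param x vector of non-negative integer abundances.
#' @param model a `mixture_model`.
#' @return expected counts, same length as `x`.
#' @export
model_expectation <- function(x, model) {
  stopifnot(inherits(model, "mixture_model"))
  out <- numeric(length(x))
  for (n in seq_len(model$N)) {
    if (model$a[n] == 0) next
    out <- out + model$a[n] * nb_pmf(x, mean = model$c * n,
                                     alpha = model$s / n)
  }
  out
}

spectrum_counts_on_grid <- function(spectrum, x_range) {
  z <- numeric(length(x_range))
  hit <- match(spectrum$abundance, x_range)
  ok <- !is.na(hit)
  z[hit[ok]] <- spectrum$count[ok]
  z
}

#' Log-likelihood of a spectrum under a mixture model
#'
#' Each observed bin count z_i is treated as a Poisson draw with mean
#' P_NO(i); the log-likelihood is summed over every integer abundance in
#' `x_range`, including abundances absent from the spectrum (z_i = 0).
#' A bin with z_i > 0 where the model puts zero mass yields -Inf.
#'
#' @param spectrum a `kmer_spectrum`.
#' @param model a `mixture_model`.
#' @param x_range integer vector (typically `x_min:x_max`) of abundances to
#'   include.
#' @return the log-likelihood (may be -Inf).
#' @export
spectrum_log_likelihood <- function(spectrum, model, x_range) {
  stopifnot(inherits(spectrum, "kmer_spectrum"), inherits(model, "mixture_model"))
  x_range <- as.integer(x_range)
  z <- spectrum_counts_on_grid(spectrum, x_range)
  lambda <- model_expectation(x_range, model)
  sum(dpois(round(z), lambda, log = TRUE))
}

#' Genome size implied by a model or profile
#'
#' The genome size in bp(-equivalents) is the copy-number-weighted sum of
#' unique sequence: sum over n of n * a_n for a fitted model, or the sum of
#' the `total_bp` column of a repeat profile.
#'
#' @param x a `mixture_model`, `repeat_profile` or `fit_result`.
#' @return genome size (numeric).
#' @export
genome_size_estimate <- function(x) UseMethod("genome_size_estimate")

#' @export
genome_size_estimate.mixture_model <- function(x) sum(seq_len(x$N) * x$a)

#' @export
genome_size_estimate.repeat_profile <- function(x) sum(x$total_bp)

#' @export
genome_size_estimate.fit_result <- function(x) genome_size_estimate(x$model)

#' Number of unique k-mers implied by a model or profile
#'
#' The number of distinct k-mers is the plain sum of the coefficients
#' (or of the `unique_bp` column of a profile).
#'
#' @inheritParams genome_size_estimate
#' @return unique k-mer count (numeric).
#' @export
unique_kmer_estimate <- function(x) UseMethod("unique_kmer_estimate")

#' @export
unique_kmer_estimate.mixture_model <- function(x) sum(x$a)

#' @export
unique_kmer_estimate.repeat_profile <- function(x) sum(x$unique_bp)

#' @export
unique_kmer_estimate.fit_result <- function(x) unique_kmer_estimate(x$model)

#' Repeat profile implied by a fitted mixture model
#'
#' Row n of the profile is (n, a_n, n * a_n); totals agree exactly with
#' [genome_size_estimate()] and [unique_kmer_estimate()]. Rows with
#' a_n = 0 are dropped.
#'
#' @param model a `mixture_model` (or `fit_result`).
#' @return a `repeat_profile` data frame.
#' @export
repeat_profile_from_model <- function(model) {
  if (inherits(model, "fit_result")) model <- model$model
  stopifnot(inherits(model, "mixture_model"))
  new_repeat_profile(seq_len(model$N), model$a)
}
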