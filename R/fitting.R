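#' Fitting configuration
#'
#' @param max_copy_number maximum modeled copy number N (default 30, i.e.
#'   the principal peak plus 29 repeat components at 2x..30x).
#' @param min_abundance optional manual low-abundance cutoff; the cutoff
#'   actually used is `max(min_abundance, c0 / 2)` where c0 is the
#'   principal-peak estimate. Required for spectra with no resolvable peak
#'   (e.g. ultra-high-coverage tiny genomes).
#' @param max_components optional cap on the number of mixture components
#'   fitted (e.g. 1 for a phiX-style single-peak control spectrum).
#' @param max_abundance optional upper bound of the fitted abundance range;
#'   default `min(max observed abundance, (N + 0.5) * c)`.
#' @param reltol relative log-likelihood improvement declared converged.
#' @param maxit maximum optimizer iterations per stage.
#' @return a `fit_config` list.
#' @export
fit_config <- function(max_copy_number = 30L, min_abundance = NULL,
                       max_components = NULL, max_abundance = NULL,
                       reltol = 1e-8, maxit = 500L) {
  stopifnot(max_copy_number >= 1,
            is.null(min_abundance) || min_abundance >= 1,
            is.null(max_components) || max_components >= 1,
            is.null(max_abundance) || max_abundance >= 1)
  structure(list(max_copy_number = as.integer(max_copy_number),
                 min_abundance = min_abundance,
                 max_components = max_components,
                 max_abundance = max_abundance,
                 reltol = reltol, maxit = as.integer(maxit)),
            class = "fit_config")
}

#' Locate the principal peak of a spectrum
#'
#' Scans the transformed series x * z_x in ascending abundance: the series
#' starts in the error-driven descending region (sequencing errors create
#' huge numbers of rare k-mers), passes a local minimum, and rises to the
#' principal peak. Returns the abundance maximizing x * z_x beyond the
#' first local minimum (ties broken toward smaller x); if the series never
#' descends there is no error spike and the global argmax is returned; if
#' it never rises again the coverage is too low to resolve a peak and an
#' error of class `kspectra_low_coverage` is signalled.
#'
#' @param spectrum a `kmer_spectrum`.
#' @return the principal-peak abundance c0 (positive integer).
#' @export
initial_peak_estimate <- function(spectrum) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (nrow(spectrum) == 0L) stop("empty spectrum", call. = FALSE)
  x <- spectrum$abundance
  y <- as.numeric(x) * spectrum$count
  if (length(y) == 1L) return(x[1L])
  rises <- which(diff(y) > 0)          # first index i with y[i+1] > y[i]
  if (!length(rises)) {
    cond <- structure(class = c("kspectra_low_coverage", "error", "condition"),
                      list(message = paste0(
                        "no resolvable principal peak: transformed spectrum is ",
                        "monotone decreasing (coverage likely below ~10x)"),
                        call = sys.call(-1)))
    stop(cond)
  }
  m <- rises[1L]
  if (m == 1L) {
    idx <- seq_along(y)                # no descending error region at all
  } else {
    idx <- (m + 1L):length(y)          # beyond the first local minimum
  }
  x[idx][which.max(y[idx])]            # which.max takes the first (smallest x)
}

# Component pmf matrix f[n, x] for par = (c, s, a_1..a_n).
component_pmfs <- function(par, x_range) {
  cc <- par[1L]; s <- par[2L]; n_comp <- length(par) - 2L
  f <- matrix(0, nrow = n_comp, ncol = length(x_range))
  for (n in seq_len(n_comp))
    f[n, ] <- nb_pmf(x_range, mean = cc * n, alpha = s / n)
  f
}

# Negative Poisson log-likelihood of the masked spectrum for a parameter
# vector par = (c, s, a_1..a_n). z is pre-gridded on x_range.
neg_loglik <- function(par, x_range, z) {
  cc <- par[1L]; s <- par[2L]; a <- par[-(1:2)]
  if (cc <= 0 || s < 0 || any(a < 0)) return(1e300)
  lambda <- pmax(drop(crossprod(component_pmfs(par, x_range), a)), 1e-300)
  ll <- sum(dpois(z, lambda, log = TRUE))
  if (!is.finite(ll)) return(1e300)
  -ll
}

# Analytic gradient of neg_loglik. d(loglik)/d(theta) = sum_x (z/lambda - 1)
# dlambda/dtheta; exact in c and the coefficients (dlogNB/dmu =
# (x - mu) r / (mu (r + mu)), r = 1/alpha, with Poisson limit (x - mu)/mu),
# and in s via the digamma form of dlogNB/dr; near the s = 0 boundary the
# digamma form loses precision, so a forward difference is used there.
neg_loglik_grad <- function(par, x_range, z) {
  cc <- par[1L]; s <- par[2L]; a <- par[-(1:2)]
  if (cc <= 0 || s < 0 || any(a < 0)) return(numeric(length(par)))
  n_comp <- length(a)
  f <- component_pmfs(par, x_range)
  lambda <- pmax(drop(crossprod(f, a)), 1e-300)
  w <- z / lambda - 1                 # d(loglik)/d(lambda)
  g_a <- drop(f %*% w)
  g_c <- 0
  g_s <- 0
  use_digamma <- s > 1e-6
  for (n in seq_len(n_comp)) {
    if (a[n] == 0 && n > 1 && all(a[n:n_comp] == 0)) break
    mu <- cc * n
    dmu <- (x_range - mu) / mu        # Poisson limit of dlogNB/dmu
    if (s > 1e-14) {
      r <- n / s
      dmu <- (x_range - mu) * r / (mu * (r + mu))
    }
    g_c <- g_c + a[n] * sum(w * f[n, ] * dmu) * n
    if (use_digamma && a[n] > 0) {
      r <- n / s
      dlogf_dr <- digamma(x_range + r) - digamma(r) + log(r / (r + mu)) +
        1 - (r + x_range) / (r + mu)
      g_s <- g_s + a[n] * sum(w * f[n, ] * dlogf_dr) * (-n / s^2)
    }
  }
  if (!use_digamma) {                 # forward difference at the boundary
    h <- 1e-6
    g_s <- (neg_loglik(`[<-`(par, 2L, s + h), x_range, z) -
              neg_loglik(par, x_range, z)) / h
    return(c(-g_c, g_s, -g_a))
  }
  out <- c(-g_c, -g_s, -g_a)
  pmin(pmax(out, -1e12), 1e12)
}

run_stage <- function(par, x_range, z, reltol, maxit, restarts = 1L) {
  lower <- c(1e-6, 0, rep(0, length(par) - 2L))
  a_scale <- max(sum(par[-(1:2)]) / 1e3, 1)
  parscale <- pmax(abs(par), c(1, 0.1, rep(a_scale, length(par) - 2L)))
  fit <- optim(par, neg_loglik, gr = neg_loglik_grad,
               x_range = x_range, z = z,
               method = "L-BFGS-B", lower = lower,
               control = list(parscale = parscale, maxit = maxit,
                              factr = max(reltol / .Machine$double.eps, 10)))
  # restarting refreshes the Hessian approximation and escapes premature
  # convergence on nearly-flat coefficient exchanges
  for (i in seq_len(restarts)) {
    again <- optim(fit$par, neg_loglik, gr = neg_loglik_grad,
                   x_range = x_range, z = z,
                   method = "L-BFGS-B", lower = lower,
                   control = list(parscale = pmax(abs(fit$par), parscale),
                                  maxit = maxit,
                                  factr = max(reltol / .Machine$double.eps, 10)))
    improved <- fit$value - again$value
    if (again$value <= fit$value) {
      again$counts <- again$counts + fit$counts
      fit <- again
    }
    if (improved < abs(fit$value) * 1e-6) break
  }
  fit
}

# WLS initial value for a new coefficient a_n: regress residual bin counts
# on the component shape over a one-peak-wide window, weights 1/max(z, 1).
wls_init <- function(n, cc, s, a, x_range, z) {
  win <- x_range >= (n - 0.5) * cc & x_range <= (n + 0.5) * cc
  if (!any(win)) return(0)
  g <- nb_pmf(x_range[win], mean = cc * n, alpha = s / n)
  model <- numeric(sum(win))
  for (j in seq_along(a)) {
    if (a[j] == 0) next
    model <- model + a[j] * nb_pmf(x_range[win], mean = cc * j, alpha = s / j)
  }
  r <- z[win] - model
  w <- 1 / pmax(z[win], 1)
  denom <- sum(w * g * g)
  if (denom <= 0) return(0)
  max(0, sum(w * r * g) / denom)
}

#' Fit the mixture model to an abundance spectrum
#'
#' Staged maximum-likelihood fitting of the mixed over-dispersed Poisson
#' model. The procedure: (1) estimate the principal-peak abundance c0 with
#' [initial_peak_estimate()]; (2) set the low-abundance cutoff
#' x_min = max(manual cutoff, c0 / 2), excluding the error-dominated region;
#' (3) fit (a_1, c, s) on bins with x in \[x_min, 1.5 c\] — the cutoff is
#' recomputed once from the fitted c if it moved by more than 10%;
#' (4) for n = 2..N add coefficient a_n, initialised by weighted least
#' squares on residual counts near x = n c, widen the mask to
#' x <= (n + 0.5) c, and re-optimise all parameters jointly under a_n >= 0,
#' c > 0, s >= 0 (a stage whose initial a_n is < 1 retains the near-zero
#' coefficient without re-optimisation, so negligible components stay at
#' zero); (5) a final joint optimisation over the full masked range. The
#' mixture terminates at the highest observed abundance: components whose
#' centre n c would lie beyond the data are excluded rather than
#' extrapolated.
#'
#' Bins above the fitted range (e.g. very-high-copy plasmid mass beyond
#' N x) are not modeled; their k-mer instances are reported in
#' `unmodeled_instances`.
#'
#' @param spectrum a `kmer_spectrum` (from reads or [read_histogram()]).
#' @param config a [fit_config()].
#' @return a `fit_result`: list with elements `model` (the fitted
#'   [mixture_model()]), `log_likelihood`, `c0`, `x_range` (fitted
#'   abundance range), `diagnostics` (per-stage data frame),
#'   `unmodeled_instances`, and `reliable` (FALSE when the fitted coverage
#'   peak is below ~10x, where the error and signal regions of the spectrum
#'   merge and inferences are unsupported).
#' @export
fit_spectrum <- function(spectrum, config = fit_config()) {
  stopifnot(inherits(spectrum, "kmer_spectrum"), inherits(config, "fit_config"))
  if (nrow(spectrum) == 0L) stop("empty spectrum", call. = FALSE)
  N <- config$max_copy_number
  n_comp <- min(N, config$max_components %||% N)

  manual <- config$min_abundance
  spec_vis <- spectrum
  if (!is.null(manual)) spec_vis <- spectrum[spectrum$abundance >= manual, ,
                                             drop = FALSE]
  class(spec_vis) <- class(spectrum)
  c0 <- initial_peak_estimate(spec_vis)
  x_min <- as.integer(max(ceiling(c0 / 2), manual %||% 1))
  max_obs <- max(spectrum$abundance)
  # the mixture terminates at the highest observed abundance: a component
  # whose centre n*c lies beyond the data cannot be estimated (WLS and ML
  # would extrapolate from its unobserved peak) and is excluded
  n_comp <- max(1L, min(n_comp, as.integer(floor(max_obs / c0))))

  diagnostics <- list()
  note_stage <- function(stage, n, value, iters, conv, ok) {
    diagnostics[[length(diagnostics) + 1L]] <<- data.frame(
      stage = stage, n = n, neg_loglik = value, iterations = iters,
      convergence = conv, success = ok)
  }

  grid <- function(lo, hi) {
    hi <- as.integer(min(hi, max_obs, config$max_abundance %||% Inf))
    lo <- as.integer(lo)
    if (hi < lo) hi <- lo
    xr <- lo:hi
    list(x = xr, z = round(spectrum_counts_on_grid(spectrum, xr)))
  }

  # stage 1: principal peak (a1, c, s)
  stage1 <- function(x_min) {
    g <- grid(x_min, ceiling(1.5 * c0))
    a1_0 <- max(sum(g$z), 1)
    par <- c(c0, 0.01, a1_0)
    fit <- run_stage(par, g$x, g$z, config$reltol, config$maxit)
    list(fit = fit, g = g)
  }
  s1 <- stage1(x_min)
  cc <- s1$fit$par[1L]
  # bootstrap the half-peak cutoff: recompute once if c moved materially
  if (abs(cc - c0) / c0 > 0.10 && is.null(manual)) {
    x_min <- as.integer(max(ceiling(cc / 2), 1))
    s1 <- stage1(x_min)
    cc <- s1$fit$par[1L]
  }
  par <- c(s1$fit$par[1:2], s1$fit$par[3L])
  note_stage("principal", 1L, s1$fit$value, s1$fit$counts[1L],
             s1$fit$convergence, s1$fit$convergence == 0)

  # stages 2..n_comp: sequential extension by one copy-number component
  for (n in seq_len(n_comp)[-1L]) {
    cc <- par[1L]; s <- par[2L]; a <- par[-(1:2)]
    g <- grid(x_min, ceiling((n + 0.5) * cc))
    a_n0 <- wls_init(n, cc, s, a, g$x, g$z)
    if (a_n0 < 1) {                     # negligible component: retain, skip
      par <- c(cc, s, a, a_n0)
      note_stage("extend", n, NA_real_, 0L, NA_integer_, TRUE)
      next
    }
    cand <- c(cc, s, a, a_n0)
    fit <- tryCatch(run_stage(cand, g$x, g$z, config$reltol, config$maxit),
                    error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$par))) {
      par <- c(cc, s, a, 0)             # keep last successful lower-order model
      note_stage("extend", n, NA_real_, NA_integer_, NA_integer_, FALSE)
    } else {
      par <- fit$par
      note_stage("extend", n, fit$value, fit$counts[1L], fit$convergence,
                 fit$convergence == 0)
    }
  }

  # final joint optimisation over the full masked range
  cc <- par[1L]
  g <- grid(x_min, config$max_abundance %||% ceiling((N + 0.5) * cc))
  fit <- tryCatch(run_stage(par, g$x, g$z, config$reltol, config$maxit,
                            restarts = 4L),
                  error = function(e) NULL)
  if (!is.null(fit) && all(is.finite(fit$par))) {
    par <- fit$par
    note_stage("final", length(par) - 2L, fit$value, fit$counts[1L],
               fit$convergence, fit$convergence == 0)
  } else {
    note_stage("final", length(par) - 2L, NA_real_, NA_integer_, NA_integer_,
               FALSE)
  }

  a_full <- c(par[-(1:2)], rep(0, N - (length(par) - 2L)))
  model <- mixture_model(c = par[1L], s = par[2L], a = a_full, x_min = x_min)
  ll <- spectrum_log_likelihood(spectrum, model, g$x)
  above <- spectrum$abundance > max(g$x)
  structure(list(model = model,
                 log_likelihood = ll,
                 c0 = c0,
                 x_range = range(g$x),
                 diagnostics = do.call(rbind, diagnostics),
                 unmodeled_instances = sum(as.numeric(spectrum$abundance[above]) *
                                             spectrum$count[above]),
                 # below ~10x per-k-mer coverage the error and signal regions
                 # of the spectrum merge and inferences are unsupported
                 reliable = par[1L] >= 10),
            class = "fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result\n")
  cat("  principal peak: c0 = ", x$c0, " -> fitted c = ",
      signif(x$model$c, 5), ", s = ", signif(x$model$s, 4), "\n", sep = "")
  cat("  fitted range: [", x$x_range[1L], ", ", x$x_range[2L],
      "], log-likelihood ", signif(x$log_likelihood, 8), "\n", sep = "")
  cat("  genome size ", format(round(genome_size_estimate(x)), big.mark = ","),
      " bp, ", format(round(unique_kmer_estimate(x)), big.mark = ","),
      " unique k-mers\n", sep = "")
  if (!x$reliable)
    cat("  WARNING: fitted coverage peak below 10x; estimates unreliable\n")
  if (x$unmodeled_instances > 0)
    cat("  unmodeled high-abundance mass: ",
        format(x$unmodeled_instances, big.mark = ","),
        " k-mer instances above the fitted range\n", sep = "")
  invisible(x)
}

#' Serialise a fit result to JSON
#'
#' Writes the fitted parameters, diagnostics and derived summary statistics
#' as JSON (and, optionally, the derived repeat profile as TSV alongside).
#'
#' @param result a `fit_result`.
#' @param path output JSON path.
#' @param profile_path optional TSV path for the derived repeat profile.
#' @export
write_fit_result <- function(result, path, profile_path = NULL) {
  stopifnot(inherits(result, "fit_result"))
  obj <- list(
    model = list(c = result$model$c, s = result$model$s, a = result$model$a,
                 N = result$model$N, x_min = result$model$x_min),
    log_likelihood = result$log_likelihood,
    c0 = result$c0,
    x_range = result$x_range,
    genome_size_estimate = genome_size_estimate(result),
    unique_kmer_estimate = unique_kmer_estimate(result),
    unmodeled_instances = result$unmodeled_instances,
    reliable = result$reliable,
    diagnostics = result$diagnostics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(profile_path))
    write_repeat_profile(repeat_profile_from_model(result), profile_path)
  invisible(path)
}
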