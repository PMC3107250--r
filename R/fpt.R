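# First-passage-time statistics. Transport through the pore behaves as
# drifted Brownian motion toward an absorbing wall, whose first-passage law
# is the inverse Gaussian with mean mu and scale parameter lambda:
#   f(t) = sqrt(lambda / (2 pi t^3)) exp(-lambda (t - mu)^2 / (2 mu^2 t)).

#' First-passage-time sample
#'
#' @param times_ms positive first-passage times in ms.
#' @return an `fpt_sample` tibble (column `fpt_ms`) with `n`, `mean` and
#'   `sem` attributes; the SEM is `NA` for a single observation.
#' @export
fpt_sample <- function(times_ms) {
  times_ms <- as.numeric(times_ms)
  if (any(is.na(times_ms)) || any(times_ms <= 0)) {
    abort("first-passage times must be positive and non-missing",
          class = "npcbd_domain_error")
  }
  out <- tibble(fpt_ms = times_ms)
  attr(out, "n") <- length(times_ms)
  attr(out, "mean") <- if (length(times_ms)) mean(times_ms) else NA_real_
  attr(out, "sem") <- if (length(times_ms) > 1) {
    sd(times_ms) / sqrt(length(times_ms))
  } else NA_real_
  class(out) <- c("fpt_sample", class(out))
  out
}

#' Inverse-Gaussian density
#'
#' @param t time (ms), positive.
#' @param mu mean parameter (ms), positive.
#' @param lam scale parameter lambda (ms), positive.
#' @return the density at `t`.
#' @export
invgauss_pdf <- function(t, mu, lam) {
  if (any(t <= 0) || any(mu <= 0) || any(lam <= 0)) {
    abort("t, mu and lambda must be positive", class = "npcbd_domain_error")
  }
  sqrt(lam / (2 * pi * t^3)) * exp(-lam * (t - mu)^2 / (2 * mu^2 * t))
}

#' Inverse-Gaussian cumulative distribution
#'
#' @inheritParams invgauss_pdf
#' @return P(T <= t).
#' @export
invgauss_cdf <- function(t, mu, lam) {
  if (any(t <= 0) || any(mu <= 0) || any(lam <= 0)) {
    abort("t, mu and lambda must be positive", class = "npcbd_domain_error")
  }
  q <- sqrt(lam / t)
  pnorm(q * (t / mu - 1)) + exp(2 * lam / mu) * pnorm(-q * (t / mu + 1))
}

#' Inverse-Gaussian random deviates
#'
#' Michael-Schucany-Haas transformation method; uses R's RNG.
#'
#' @param n sample size.
#' @inheritParams invgauss_pdf
#' @return `n` draws.
#' @export
rinvgauss <- function(n, mu, lam) {
  if (mu <= 0 || lam <= 0) {
    abort("mu and lambda must be positive", class = "npcbd_domain_error")
  }
  nu <- rnorm(n)
  y <- nu^2
  x <- mu + mu^2 * y / (2 * lam) -
    mu / (2 * lam) * sqrt(4 * mu * lam * y + mu^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

#' Maximum-likelihood inverse-Gaussian fit
#'
#' Closed-form MLE: mu-hat is the sample mean and
#' lambda-hat = n / sum(1/t_i - 1/mu-hat). Also reports the maximum
#' discrepancy between the empirical and fitted CDFs as a descriptive
#' goodness-of-fit measure.
#'
#' @param sample an [fpt_sample()] or a numeric vector of times (ms).
#' @return an `igfit` object; see [tidy.igfit()] and [glance.igfit()].
#' @export
fit_invgauss <- function(sample) {
  t <- if (inherits(sample, "fpt_sample")) sample$fpt_ms else as.numeric(sample)
  n <- length(t)
  if (n < 3) {
    abort("need at least 3 observations to fit", class = "npcbd_domain_error")
  }
  if (any(t <= 0)) {
    abort("times must be positive", class = "npcbd_domain_error")
  }
  mu <- mean(t)
  denom <- sum(1 / t - 1 / mu)
  if (denom <= .Machine$double.eps * n) {
    abort("degenerate sample (no dispersion): lambda-hat diverges",
          class = "npcbd_degenerate_error")
  }
  lam <- n / denom
  loglik <- sum(log(invgauss_pdf(t, mu, lam)))
  ts <- sort(t)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1) / n
  fit_cdf <- invgauss_cdf(ts, mu, lam)
  ks <- max(abs(emp_hi - fit_cdf), abs(emp_lo - fit_cdf))
  structure(list(mu = mu, lam = lam, n = n, loglik = loglik,
                 cdf_discrepancy = ks, times = t),
            class = "igfit")
}

#' @export
print.igfit <- function(x, ...) {
  cat(sprintf(
    "<igfit> inverse Gaussian: mu = %.4g ms, lambda = %.4g ms (n = %d)\n",
    x$mu, x$lam, x$n))
  cat(sprintf("  log-likelihood %.4g, max CDF discrepancy %.3f\n",
              x$loglik, x$cdf_discrepancy))
  invisible(x)
}

#' Tidy an inverse-Gaussian fit
#'
#' @param x an `igfit`.
#' @param ... unused.
#' @return a tibble with one row per parameter (`mu`, `lambda`).
#' @export
tidy.igfit <- function(x, ...) {
  # asymptotic standard errors of the IG MLEs
  tibble(term = c("mu", "lambda"),
         estimate = c(x$mu, x$lam),
         std.error = c(sqrt(x$mu^3 / (x$lam * x$n)),
                       x$lam * sqrt(2 / x$n)))
}

#' One-row summary of an inverse-Gaussian fit
#'
#' @inheritParams tidy.igfit
#' @return a one-row tibble: parameters, log-likelihood, CDF discrepancy,
#'   and the implied drift statistics are left to [drift_estimate()].
#' @export
glance.igfit <- function(x, ...) {
  tibble(mu = x$mu, lambda = x$lam, n = x$n, logLik = x$loglik,
         cdf_discrepancy = x$cdf_discrepancy)
}

#' Effective drift velocity implied by a mean first-passage time
#'
#' v = L / mu for a particle drifting to an absorbing wall a distance L
#' away.
#'
#' @param L distance to the absorbing wall (nm); 160 nm for the default
#'   pore.
#' @param mu mean first-passage time (ms).
#' @return drift velocity in um/s.
#' @export
drift_estimate <- function(L, mu) {
  if (any(L <= 0) || any(mu <= 0)) {
    abort("L and mu must be positive", class = "npcbd_domain_error")
  }
  L / mu # nm/ms == um/s
}

#' Free-diffusion first-passage baseline
#'
#' t = L^2 / (2 D), the 1D mean first-passage time of a freely diffusing
#' particle over a distance L - the model's reference for how close
#' facilitated transport sits to free diffusion.
#'
#' @param L distance (nm).
#' @param D diffusion coefficient (um^2/s).
#' @return time in ms.
#' @examples
#' free_diffusion_fpt(160, stokes_diffusion(1.5)) # ~0.42 ms (3 nm cargo)
#' @export
free_diffusion_fpt <- function(L, D) {
  if (any(L <= 0) || any(D <= 0)) {
    abort("L and D must be positive", class = "npcbd_domain_error")
  }
  (L^2 / (2 * D * 1e6)) * 1e3 # nm^2 / (nm^2/s) -> s -> ms
}
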