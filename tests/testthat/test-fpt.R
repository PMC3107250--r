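# Inverse-Gaussian first-passage statistics: density properties, closed-form
# MLE recovery, drift and free-diffusion baselines.

test_that("inverse-Gaussian density normalizes and has mean mu", {
  mu <- 2.6; lam <- 5
  norm <- integrate(function(t) invgauss_pdf(t, mu, lam), 0, Inf,
                    rel.tol = 1e-9)
  expect_equal(norm$value, 1, tolerance = 1e-6)
  m1 <- integrate(function(t) t * invgauss_pdf(t, mu, lam), 0, Inf,
                  rel.tol = 1e-9)
  expect_equal(m1$value, mu, tolerance = 1e-6)
  # exact value at t = mu (exponent vanishes)
  expect_equal(invgauss_pdf(mu, mu, lam), sqrt(lam / (2 * pi * mu^3)))
  expect_error(invgauss_pdf(-1, mu, lam), class = "npcbd_domain_error")
})

test_that("inverse-Gaussian cdf matches quadrature of the pdf", {
  mu <- 1.8; lam <- 3.2
  for (t in c(0.3, 1, 1.8, 4, 9)) {
    q <- integrate(function(u) invgauss_pdf(u, mu, lam), 0, t,
                   rel.tol = 1e-10)$value
    expect_equal(invgauss_cdf(t, mu, lam), q, tolerance = 1e-7)
  }
})

test_that("random deviates reproduce the IG mean and variance", {
  set.seed(10)
  x <- rinvgauss(2e5, 2.6, 5)
  expect_equal(mean(x), 2.6, tolerance = 0.02)
  expect_equal(var(x), 2.6^3 / 5, tolerance = 0.05)
})

test_that("closed-form MLE recovers (mu, lambda) within 5% at n = 1e4", {
  set.seed(11)
  fit <- fit_invgauss(rinvgauss(1e4, 2.6, 5))
  expect_equal(fit$mu, 2.6, tolerance = 0.05)
  expect_equal(fit$lam, 5, tolerance = 0.05)
  expect_lt(fit$cdf_discrepancy, 0.02)
  td <- tidy(fit)
  expect_equal(td$term, c("mu", "lambda"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$n, 1e4)
  # degenerate sample: lambda-hat diverges and is signalled
  expect_error(fit_invgauss(rep(2.5, 10)), class = "npcbd_degenerate_error")
  expect_error(fit_invgauss(c(1, 2)), class = "npcbd_domain_error")
})

test_that("drift estimate v = L / mu in um/s", {
  expect_equal(drift_estimate(160, 2.6), 61.5, tolerance = 0.001)
  expect_equal(drift_estimate(160, 5.2), drift_estimate(160, 2.6) / 2)
  expect_equal(drift_estimate(160, 2.6) * 2.6, 160)
  expect_error(drift_estimate(-1, 2), class = "npcbd_domain_error")
})

test_that("free-diffusion baseline t = L^2 / 2D", {
  # 3 nm particle over the 160 nm span: the printed 0.4 ms
  t3 <- free_diffusion_fpt(160, stokes_diffusion(1.5))
  expect_equal(round(t3, 1), 0.4)
  # 15 nm cargo: ~2.1 ms, about 20% under the simulated 2.6 ms
  t15 <- free_diffusion_fpt(160, 6.1)
  expect_equal(t15, 2.1, tolerance = 0.01)
  expect_equal(2.6 / t15, 1.24, tolerance = 0.02)
  expect_lt(free_diffusion_fpt(160, 1e6), 1e-4) # D -> inf limit
})

test_that("zero-drift 1D simulation reproduces L^2/2D within 3 SE", {
  # reflecting start, absorbing end
  set.seed(12)
  L <- 50; D <- 610 # nm, nm^2/ms
  dt <- 0.002
  n <- 400
  x <- numeric(n); t <- numeric(n); alive <- rep(TRUE, n)
  while (any(alive)) {
    k <- which(alive)
    x[k] <- abs(x[k] + rnorm(length(k), 0, sqrt(2 * D * dt)))
    t[k] <- t[k] + dt
    alive[k] <- x[k] < L
  }
  expected <- free_diffusion_fpt(L, D * 1e-3) # D back to um^2/s
  expect_lt(abs(mean(t) - expected), 3 * sd(t) / sqrt(n) + 2 * dt)
})
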