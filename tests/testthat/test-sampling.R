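test_that("guided estimate interpolates/extrapolates the two branches", {
  eu <- matrix(0.2, 2, 2); ec <- matrix(0.5, 2, 2)
  expect_equal(guided_noise_estimate(ec, eu, 0), eu)
  expect_equal(guided_noise_estimate(ec, eu, 1), ec)
  expect_equal(guided_noise_estimate(ec, eu, 3), matrix(1.1, 2, 2))
  expect_error(guided_noise_estimate(matrix(0, 2, 3), eu, 1), "shape")
})

test_that("clean-sample estimate inverts the forward map and clips", {
  sch <- build_schedule(100, 1e-3, 0.05)
  set.seed(5)
  x0 <- matrix(stats::runif(12, -1, 1), 4, 3)
  eps <- matrix(stats::rnorm(12), 4, 3)
  for (t in c(1L, 37L, 100L)) {
    xt <- forward_noise(x0, t, eps, sch)
    expect_equal(estimate_clean(xt, eps, t, sch), x0, tolerance = 1e-9)
  }
  # clipping contract: a raw estimate of 1.5 clips to 1.0
  big <- estimate_clean(matrix(1.5 * sqrt(sch$alpha_bar[1])), matrix(0),
                        1L, sch)
  expect_equal(big[1, 1], 1)
  low <- estimate_clean(matrix(-9), matrix(0), 50L, sch)
  expect_equal(low[1, 1], -1)
  # scalar oracle on random inputs, no clipping
  for (i in 1:200) {
    t <- sample(100L, 1); xt <- stats::rnorm(1); eh <- stats::rnorm(1)
    ab <- sch$alpha_bar[t]
    expect_equal(estimate_clean(xt, eh, t, sch, clip_range = NULL),
                 (xt - sqrt(1 - ab) * eh) / sqrt(ab), tolerance = 1e-12)
  }
  expect_error(estimate_clean(matrix(0), 0L, matrix(0), sch))
})

test_that("reverse posterior collapses at t = 1 and obeys the coefficient identity", {
  sch <- build_schedule(50, 1e-3, 0.2)
  x0h <- matrix(c(0.3, -0.2), 1)
  xt <- matrix(c(0.9, 0.1), 1)
  p1 <- posterior_params(x0h, xt, 1L, sch)
  expect_equal(p1$mu, x0h)
  expect_equal(p1$sigma2, 0)
  # beta_t -> 0 limit (with accumulated noise fixed): the step is a no-op
  beta <- c(0.3, 0.2, 1e-12)
  tiny <- structure(list(T = 3L, beta = beta, alpha = 1 - beta,
                         alpha_bar = cumprod(1 - beta), alpha_bar0 = 1),
                    class = "diffusion_schedule")
  p <- posterior_params(x0h, xt, 3L, tiny)
  expect_equal(p$mu, xt, tolerance = 1e-6)
  # exact coefficient identity, for all t:
  # sqrt(abp)*beta + sqrt(alpha)*(1 - abp) = (sqrt(alpha) + sqrt(abp)) * (1 - sqrt(ab))
  # (with a = sqrt(alpha), b = sqrt(abp): b(1-a^2) + a(1-b^2) = (a+b)(1-ab));
  # hence the coefficients sum to (a+b)/(1+ab) <= 1, with equality exactly
  # at t = 1 where abp = 1.
  for (t in 1:50) {
    ab <- sch$alpha_bar[t]
    abp <- if (t == 1) 1 else sch$alpha_bar[t - 1]
    a <- sqrt(sch$alpha[t]); b <- sqrt(abp)
    lhs <- b * sch$beta[t] + a * (1 - abp)
    expect_equal(lhs, (a + b) * (1 - sqrt(ab)), tolerance = 1e-12)
    pp <- posterior_params(xt, xt, t, sch)
    expect_equal(pp$mu, ((a + b) / (1 + a * b)) * xt, tolerance = 1e-9)
    expect_gte(pp$sigma2, 0)
  }
  pp1 <- posterior_params(xt, xt, 1L, sch)
  expect_equal(pp1$mu, xt, tolerance = 1e-12)   # sum is exactly 1 at t = 1
  expect_error(posterior_params(x0h, xt, 51L, sch))
})

test_that("sampler output is bitwise independent of s when branches coincide", {
  sch <- reduced_schedule(30)
  same <- denoiser_fn(function(X, t, labels, B) 0.3 * X)
  outs <- lapply(c(0, 1, 3, 7), function(s)
    reverse_sample(same, sch, 1L, guidance_settings(s = s), c(8L, 2L),
                   n = 3L, seed = 17L))
  for (k in 2:4) expect_identical(outs[[1]], outs[[k]])
  # determinism: same seed -> identical; different seed -> different
  again <- reverse_sample(same, sch, 1L, guidance_settings(s = 1), c(8L, 2L),
                          n = 3L, seed = 17L)
  expect_identical(outs[[2]], again)
  other <- reverse_sample(same, sch, 1L, guidance_settings(s = 1), c(8L, 2L),
                          n = 3L, seed = 18L)
  expect_false(identical(outs[[2]], other))
})

test_that("with the Bayes-optimal denoiser the sampler recovers the data law", {
  sch <- build_schedule(1000)
  orc <- oracle_gaussian_denoiser(0.3, 0.05, sch)
  out <- reverse_sample(orc, sch, 1L, guidance_settings(s = 1, seed = 5L),
                        c(1L, 1L), n = 2000L)
  x <- vapply(out, function(s) s$values[1, 1], numeric(1))
  expect_lt(abs(mean(x) - 0.3), 3 * 0.05 / sqrt(2000))
  expect_lt(abs(stats::sd(x) - 0.05) / 0.05, 0.15)
  # every sample stays in [-1, 1] (clip + t = 1 collapse)
  expect_true(all(abs(x) <= 1))
  for (s in out[1:5]) expect_equal(s$provenance, "synthetic")
})

test_that("guidance moves the conditional mean monotonically on a 2-class oracle", {
  sch <- build_schedule(400, 1e-4, 0.05)
  mu <- c(0.5, -0.5)
  orc <- oracle_gaussian_denoiser(mu, c(0.1, 0.1), sch)
  mu_uncond <- 0
  means <- vapply(c(0, 1, 2, 3), function(s) {
    out <- reverse_sample(orc, sch, 1L, guidance_settings(s = s), c(1L, 1L),
                          n = 400L, seed = 31L)
    mean(vapply(out, function(x) x$values[1, 1], numeric(1)))
  }, numeric(1))
  # class-1 mean moves away from the unconditional mean along mu_c - mu_u
  expect_true(all(diff(means) > 0))
  expect_lt(abs(means[1] - mu_uncond), 0.08)   # s = 0: unconditional law
  expect_lt(abs(means[2] - mu[1]), 0.08)       # s = 1: conditional law
})
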