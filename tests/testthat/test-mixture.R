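test_that("mixture_pdf matches closed-form component densities", {
  g <- mixture_params(1, NA, 100, 10, "background")
  expect_equal(mixture_pdf(100, g), 1 / (10 * sqrt(2 * pi)), tolerance = 1e-12)

  r <- mixture_params(1, 25, class_of_component = "background")
  expect_equal(mixture_pdf(0, r), 0)
  expect_equal(mixture_pdf(25, r), (25 / 625) * exp(-0.5), tolerance = 1e-12)

  two <- mixture_params(c(0.5, 0.5), NA, c(90, 110), c(10, 10),
                        c("background", "target"))
  # both components sit one sd away from t = 100
  expect_equal(mixture_pdf(100, two), exp(-0.5) / (10 * sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_equal(mixture_pdf(100, two), 0.0241971, tolerance = 1e-5)
})

test_that("invalid mixture parameters are rejected", {
  expect_error(mixture_params(c(0.6, 0.6), NA, c(1, 2), c(1, 1),
                              c("background", "target")), "sum to 1")
  expect_error(mixture_params(c(0.5, 0.5), -3, 100, 10,
                              c("background", "target")), "positive")
  expect_error(mixture_params(c(0.5, 0.5), NA, c(1, 2), c(1, 1),
                              c("target", "target")), "at most one")
})

test_that("discrete mixture mass over the gray range is close to 1", {
  cases <- list(
    recovery_truth(),
    mixture_params(c(0.5, 0.5), 30, 180, 12, c("background", "target")),
    mixture_params(1, NA, 128, 20, "background"))
  for (p in cases) {
    mass <- sum(mixture_pdf(0:255, p))
    expect_gte(mass, 0.98)
    expect_lte(mass, 1.005)
  }
})

test_that("single-Gaussian EM reproduces the histogram moments in one step", {
  x <- sample_mixture(5000, recovery_truth(), seed = 11)
  h <- hist_from_sample(x)
  fit <- fit_em(h, mixture_spec(0, 1, 0), tol = 0, max_iter = 1)
  mu <- sum((0:255) * h$counts) / h$n_pixels
  s2 <- sum(((0:255) - mu)^2 * h$counts) / h$n_pixels
  expect_equal(fit$gauss_means, mu, tolerance = 1e-10)
  expect_equal(fit$gauss_sds, sqrt(s2), tolerance = 1e-10)
})

test_that("histogram-weighted EM equals the per-pixel EM oracle", {
  for (seed in c(3, 4, 5)) {
    px <- matrix(sample_mixture(256, recovery_truth(), seed = seed), 16, 16)
    img <- gray_image(px)
    h <- compute_histogram(img)
    spec <- mixture_spec(1, 1, 1)
    fit <- fit_em(h, spec, tol = 0, max_iter = 10)
    oracle <- perpixel_em(as.numeric(px), curvseg:::em_init(h, spec), 10)
    expect_equal(fit$weights, oracle$weights, tolerance = 1e-9)
    expect_equal(fit$rayleigh_sigma, oracle$rayleigh_sigma, tolerance = 1e-9)
    expect_equal(fit$gauss_means, oracle$gauss_means, tolerance = 1e-9)
    expect_equal(fit$gauss_sds, oracle$gauss_sds, tolerance = 1e-9)
  }
})

test_that("EM log-likelihood trace is non-decreasing and runs are reproducible", {
  x <- sample_mixture(2e4, recovery_truth(), seed = 8)
  h <- hist_from_sample(x)
  f1 <- fit_em(h, mixture_spec(1, 2, 1), seed = 2)
  f2 <- fit_em(h, mixture_spec(1, 2, 1), seed = 2)
  tr <- attr(f1, "loglik_trace")
  expect_true(all(diff(tr) >= -1e-9 * abs(tr[-length(tr)])))
  expect_equal(attr(f1, "loglik_trace"), attr(f2, "loglik_trace"))
  expect_equal(f1$gauss_means, f2$gauss_means)
})

test_that("EM recovers a two-component Rayleigh+Gaussian mixture", {
  truth <- mixture_params(c(0.5, 0.5), 30, 180, 12,
                          c("background", "target"))
  x <- sample_mixture(1e6, truth, seed = 1)
  fit <- fit_em(hist_from_sample(x), mixture_spec(1, 0, 1), seed = 1)
  expect_lt(max(abs(fit$weights - truth$weights)), 0.03)
  expect_lt(abs(fit$gauss_means - 180), 2)
  expect_lt(abs(fit$rayleigh_sigma - 30), 2)
})

test_that("EM rejects a one-level histogram", {
  img <- gray_image(matrix(7L, 5, 5))
  expect_error(fit_em(compute_histogram(img)), "degenerate")
})

test_that("likelihood energies apply the negative-log rule with clamping", {
  params <- recovery_truth()
  img <- gray_image(matrix(c(90L, 200L, 0L, rep(128L, 6)), 3, 3))
  ep <- likelihood_energy(img, params)
  # direct recomputation of the background class-conditional at level 90
  w_bg <- params$weights[1:3] / sum(params$weights[1:3])
  p90 <- w_bg[1] * (90 / 400) * exp(-90^2 / 800) +
    w_bg[2] * dnorm(90, 90, 10) + w_bg[3] * dnorm(90, 140, 12)
  expect_equal(ep$e_bg[1, 1], -log(p90), tolerance = 1e-12)
  expect_equal(ep$e_fg[2, 1], -log(dnorm(200, 200, 10)), tolerance = 1e-12)
  # gray level 0 has zero target density -> clamped to E_max
  expect_equal(ep$e_fg[3, 1], -log(1e-12), tolerance = 1e-9)
  expect_true(all(ep$e_bg >= 0 & ep$e_bg <= -log(1e-12) + 1e-9))
})

test_that("mixture parameters survive a JSON round trip", {
  p <- recovery_truth()
  f <- withr::local_tempfile(fileext = ".json")
  params_to_json(p, f)
  q <- params_from_json(f)
  expect_equal(q$weights, p$weights)
  expect_equal(q$rayleigh_sigma, p$rayleigh_sigma)
  expect_equal(q$gauss_means, p$gauss_means)
  expect_equal(q$gauss_sds, p$gauss_sds)
  expect_equal(q$class_of_component, p$class_of_component)
})
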