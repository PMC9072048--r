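test_that("Potts prior counts disagreeing 4-neighbor pairs once", {
  expect_equal(prior_energy(matrix(1L, 5, 5), 3), 0)
  checker <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  expect_equal(prior_energy(checker, 1), 4)
  y <- matrix(0L, 3, 3); y[2, 2] <- 1L
  expect_equal(prior_energy(y, 1.5), 6.0)
})

test_that("feature energy is the alpha-weighted mismatch", {
  y1 <- matrix(1L, 4, 4)
  expect_equal(feature_energy(y1, matrix(1, 4, 4), 5), 0)
  expect_equal(feature_energy(matrix(1L, 1, 1), matrix(0, 1, 1), 2), 2)
  set.seed(3)
  v <- matrix(runif(16), 4, 4)
  y <- matrix(rbinom(16, 1, 0.5), 4, 4)
  expect_equal(feature_energy(y, v, 0), 0)
  expect_equal(feature_energy(y, v, 2),
               2 * sum(ifelse(y == 1, 1 - v, v)), tolerance = 1e-12)
})

test_that("total energy decomposes and matches an exhaustive oracle", {
  set.seed(9)
  px <- matrix(sample_mixture(9, recovery_truth(), seed = 9), 3, 3)
  img <- gray_image(px)
  params <- recovery_truth()
  ep <- likelihood_energy(img, params)
  v <- matrix(runif(9), 3, 3)
  for (rep in 1:5) {
    y <- matrix(sample(0:1, 9, replace = TRUE), 3, 3)
    eb <- total_energy(img, params, y, fmap = v, beta = 0.7, alpha = 1.3)
    expect_equal(eb$total,
                 eb$likelihood_term + eb$prior_term + eb$feature_term,
                 tolerance = 1e-9)
    expect_equal(eb$total,
                 oracle_total_energy(y, ep$e_bg, ep$e_fg, v, 0.7, 1.3),
                 tolerance = 1e-9)
  }
  eb0 <- total_energy(img, params, matrix(0L, 3, 3), beta = 0, alpha = 0)
  expect_equal(eb0$total, eb0$likelihood_term)
})

test_that("with beta = alpha = 0 ICM returns the per-pixel ML labeling", {
  inst <- random_energy_instance(21)
  res <- icm_label(inst$e_bg, inst$e_fg, v = NULL, beta = 0, alpha = 0)
  ml <- matrix(as.integer(inst$e_fg < inst$e_bg), 8, 8)
  expect_identical(res$labels, ml)
  expect_equal(res$iterations, 1L)
  expect_true(res$converged)
  # the separable minimum over all 2^64 labelings is the unary sum
  expect_equal(res$energy_trace[1],
               sum(pmin(inst$e_bg, inst$e_fg)), tolerance = 1e-9)
})

test_that("ICM energy traces never increase and results are 1-flip optimal", {
  for (seed in c(1, 2, 3, 4, 5)) {
    inst <- random_energy_instance(seed)
    res <- icm_label(inst$e_bg, inst$e_fg, inst$v, beta = 0.8, alpha = 1.2,
                     max_iter = 100)
    expect_true(all(diff(res$energy_trace) <= 1e-12))
    base <- oracle_total_energy(res$labels, inst$e_bg, inst$e_fg, inst$v,
                                0.8, 1.2)
    expect_equal(base, res$energy_trace[length(res$energy_trace)],
                 tolerance = 1e-9)
    for (p in seq_len(64)) {
      y2 <- res$labels
      y2[p] <- 1L - y2[p]
      expect_gte(oracle_total_energy(y2, inst$e_bg, inst$e_fg, inst$v,
                                     0.8, 1.2), base - 1e-12)
    }
    # ICM can only improve on its ML initialization
    ml <- matrix(as.integer(inst$e_fg < inst$e_bg), 8, 8)
    expect_lte(base, oracle_total_energy(ml, inst$e_bg, inst$e_fg, inst$v,
                                         0.8, 1.2) + 1e-12)
  }
})

test_that("a strong prior smooths an isolated salt pixel; beta = 0 keeps it", {
  # center pixel prefers feature by 1 unit of likelihood; neighbors are
  # strongly background
  e_bg <- matrix(0, 3, 3); e_fg <- matrix(10, 3, 3)
  e_bg[2, 2] <- 1; e_fg[2, 2] <- 0
  keep <- icm_label(e_bg, e_fg, beta = 0)
  expect_equal(keep$labels[2, 2], 1L)
  # with beta = 2: flipping center to background costs 1 (likelihood)
  # but saves 4 * 2 (prior) -> smoothed
  smooth <- icm_label(e_bg, e_fg, beta = 2)
  expect_equal(sum(smooth$labels), 0L)
})

test_that("a dominating beta flattens a scattered minority to uniform", {
  # ICM is a coordinate-descent optimizer: from a mixed initialization
  # a huge beta freezes whole domains, so the attainable limit claim
  # is for scattered minority pixels, which must all be absorbed
  set.seed(77)
  e_bg <- matrix(0, 8, 8); e_fg <- matrix(4, 8, 8)
  minority <- sample(64, 6)
  e_bg[minority] <- 4; e_fg[minority] <- 0
  res <- icm_label(e_bg, e_fg, beta = 1e4)
  expect_true(all(res$labels == 0L))
  # and a uniform initialization stays uniform for any beta
  res_u <- icm_label(matrix(0, 6, 6), matrix(5, 6, 6), beta = 1e4)
  expect_true(all(res_u$labels == 0L))
})

test_that("ICM converges on seeded phantoms with monotone energy", {
  for (seed in c(101, 102, 103)) {
    ph <- generate_phantom(test_phantom_config(seed))
    params <- suppressWarnings(
      fit_em(compute_histogram(ph$image), seed = seed))
    fmap <- multiscale_response(ph$image, c(1, 2, 3, 4))
    res <- icm_segment(ph$image, params, fmap, beta = 1.5, alpha = 1,
                       max_iter = 100)
    expect_true(res$converged)
    expect_lt(res$iterations, 100L)
    expect_true(all(diff(res$energy_trace) <= 1e-9))
  }
})
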