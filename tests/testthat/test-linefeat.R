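test_that("Hessian of a constant image vanishes", {
  hf <- hessian_at_scale(matrix(0.4, 20, 20), 2)
  expect_equal(max(abs(hf$lxx)), 0, tolerance = 1e-12)
  expect_equal(max(abs(hf$lxy)), 0, tolerance = 1e-12)
  expect_equal(max(abs(hf$lyy)), 0, tolerance = 1e-12)
})

test_that("gamma-normalized derivatives match quadratic closed forms", {
  n <- 64L
  quad <- outer(rep(1, n), as.numeric(seq_len(n))^2)   # I(r,c) = c^2
  mixed <- outer(as.numeric(seq_len(n)), as.numeric(seq_len(n)))  # I = r*c
  interior <- 28:36
  for (s in c(1, 2, 4)) {
    hq <- hessian_at_scale(quad, s)
    expect_lt(max(abs(hq$lxx[interior, interior] - 2 * s^2)), 1e-3)
    expect_lt(max(abs(hq$lyy[interior, interior])), 1e-3)
    hm <- hessian_at_scale(mixed, s)
    expect_lt(max(abs(hm$lxy[interior, interior] - s^2)), 1e-3)
  }
  expect_error(hessian_at_scale(quad, 0), "positive")
})

test_that("2x2 eigenvalues are exact and magnitude-ordered", {
  expect_equal(eigvals2x2(-2, 0, -0.1), c(-0.1, -2))
  expect_equal(eigvals2x2(0, 0, 0), c(0, 0))
  expect_equal(eigvals2x2(1, 2, 1), c(-1, 3))   # roots of l^2 - 2l - 3
  # magnitude tie broken by signed ascending
  expect_equal(eigvals2x2(1, 0, -1), c(-1, 1))
  # agreement with the generic eigensolver on random symmetric matrices
  set.seed(42)
  for (k in 1:25) {
    a <- rnorm(1); b <- rnorm(1); c <- rnorm(1)
    ours <- sort(eigvals2x2(a, b, c))
    ref <- sort(eigen(matrix(c(a, b, b, c), 2, 2), symmetric = TRUE)$values)
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("line response follows the eigenvalue similarity measure", {
  expect_equal(line_response(0, 5, 0.5, 1), 0)         # wrong sign
  expect_equal(line_response(0, -10, 0.5, 1), 1 - exp(-50), tolerance = 1e-12)
  expect_equal(line_response(-1, -1, 0.5, 1),
               exp(-2) * (1 - exp(-1)), tolerance = 1e-7)
  # dark polarity flips the sign test
  expect_equal(line_response(0, -10, 0.5, 1, polarity = "dark"), 0)
  expect_gt(line_response(0, 10, 0.5, 1, polarity = "dark"), 0.99)
  expect_error(line_response(0, -1, beta_r = 0), "positive")
})

test_that("multiscale response is a pointwise max over the scale grid", {
  expect_equal(max(multiscale_response(matrix(0.3, 16, 16), c(1, 2))$v), 0)
  set.seed(5)
  img <- matrix(runif(24 * 24), 24, 24)
  f1 <- multiscale_response(img, 1, c_r = 0.1)
  f12 <- multiscale_response(img, c(1, 2), c_r = 0.1)
  expect_true(all(f12$v >= f1$v - 1e-12))
  expect_true(all(f12$v >= 0 & f12$v <= 1))
  # v at each pixel equals the response at its recorded best scale
  per_scale <- lapply(c(1, 2), function(s) {
    hf <- hessian_at_scale(img, s)
    eg <- curvseg:::eigvals2x2_vec(hf$lxx, hf$lxy, hf$lyy)
    line_response(eg$l1, eg$l2, 0.5, 0.1)
  })
  picked <- ifelse(f12$best_scale_idx == 1L, per_scale[[1]], per_scale[[2]])
  expect_equal(f12$v, picked, tolerance = 1e-12)
  expect_error(multiscale_response(img, numeric(0)), "non-empty")
})

test_that("ridge best scale agrees with a dense brute-force argmax", {
  grid <- c(1, 1.5, 2, 3, 4)
  dense <- seq(0.5, 6, length.out = 50)
  img <- gaussian_ridge(2)
  dvals <- vapply(dense, function(s) centerline_response(img, s), numeric(1))
  s_dense <- dense[which.max(dvals)]
  fm <- multiscale_response(img, grid, c_r = 0.05)
  mid <- (nrow(img) + 1L) %/% 2L
  s_grid <- grid[fm$best_scale_idx[mid, mid]]
  i_grid <- which(grid == s_grid)
  lo <- if (i_grid == 1L) -Inf else grid[i_grid - 1L]
  hi <- if (i_grid == length(grid)) Inf else grid[i_grid + 1L]
  expect_gte(s_dense, lo)
  expect_lte(s_dense, hi)
})

test_that("response map commutes with 90-degree rotation", {
  set.seed(12)
  img <- matrix(runif(30 * 30), 30, 30)
  f <- multiscale_response(img, c(1, 2, 3), c_r = 0.1)
  fr <- multiscale_response(rot90(img), c(1, 2, 3), c_r = 0.1)
  expect_equal(fr$v, rot90(f$v), tolerance = 1e-12)
})

test_that("a 45-degree ridge responds like an axis-aligned one", {
  n <- 41L
  horiz <- gaussian_ridge(1.5, n)
  idx <- matrix(seq_len(n), n, n)
  diag45 <- exp(-((idx - t(idx)) / sqrt(2))^2 / (2 * 1.5^2))
  fh <- multiscale_response(horiz, c(1, 2, 3), c_r = 0.05)
  fd <- multiscale_response(diag45, c(1, 2, 3), c_r = 0.05)
  mid <- (n + 1L) %/% 2L
  on_line <- 12:30
  vh <- fh$v[mid, on_line]
  vd <- fd$v[cbind(on_line, on_line)]
  expect_lt(mean(abs(vh - vd)), 0.05)
})

test_that("wider ridges select larger scales", {
  img <- matrix(0, 40, 60)
  img[10, ] <- 1          # 1 px wide
  img[25:30, ] <- 1       # 6 px wide
  fm <- multiscale_response(img, c(1, 2, 3, 4, 6, 8), c_r = 0.05)
  narrow <- median(fm$best_scale_idx[10, 10:50])
  wide <- median(fm$best_scale_idx[27, 10:50])
  expect_gt(wide, narrow)
})
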