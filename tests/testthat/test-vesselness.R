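test_that("constant volumes produce zero Hessian eigenvalues and zero response", {
  v <- volume3d(array(0.5, c(20, 20, 20)), 1)
  e <- hessian_eigenvalues(v, 2)
  expect_lt(max(abs(e$e3)), 1e-12)
  resp <- frangi_response(v, frangi_params(0.2, 0.5, 40, 2))
  expect_equal(max(resp$data), 0)
})

test_that("Hessian eigenvalues match the analytic Gaussian blob and ridge fields", {
  # isotropic Gaussian blob, sd t: smoothing at scale s gives amplitude
  # (t^2/(t^2+s^2))^(3/2) and centre eigenvalues -A' s^2/(t^2+s^2)
  n <- 33; t0 <- 3; s <- 3; c0 <- 17
  co <- (1:n) - c0
  r2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  v <- volume3d(array(exp(-r2 / (2 * t0^2)), c(n, n, n)), 1)
  e <- hessian_eigenvalues(v, s)
  lam_true <- -(t0^2 / (t0^2 + s^2))^1.5 / (t0^2 + s^2) * s^2
  for (comp in list(e$e1, e$e2, e$e3))
    expect_equal(comp[c0, c0, c0], lam_true, tolerance = 1e-3)
  # blob signature: R_a ~ 1, R_b ~ 1
  expect_equal(abs(e$e2[c0, c0, c0] / e$e3[c0, c0, c0]), 1, tolerance = 1e-3)

  # bright Gaussian ridge along z, sd t in (y, x): lambda1 ~ 0 (axis),
  # lambda2 = lambda3 < 0 with 2D amplitude t^2/(t^2+s^2);
  # cross-check against a finite-difference Hessian of the analytically
  # convolved field
  ridge <- array(0, c(n, n, n))
  for (z in 1:n) ridge[z, , ] <- exp(-outer(co^2, co^2, "+") / (2 * t0^2))
  vr <- volume3d(ridge, 1)
  er <- hessian_eigenvalues(vr, s)
  sig2 <- t0^2 + s^2
  f <- function(y, x) t0^2 / sig2 * exp(-(y^2 + x^2) / (2 * sig2))
  h <- 1e-3
  fd_yy <- (f(h, 0) - 2 * f(0, 0) + f(-h, 0)) / h^2 * s^2
  expect_equal(er$e2[c0, c0, c0], fd_yy, tolerance = 1e-3)
  expect_equal(er$e3[c0, c0, c0], fd_yy, tolerance = 1e-3)
  expect_lt(abs(er$e1[c0, c0, c0]), 1e-3 * abs(fd_yy))
  # tube signature at the axis: R_a ~ 1, R_b ~ 0
  expect_equal(abs(er$e2[c0, c0, c0] / er$e3[c0, c0, c0]), 1,
               tolerance = 1e-3)
})

test_that("the vesselness formula matches scalar hand evaluation and sign gates", {
  p <- frangi_params(0.2, 0.5, 40, 3)
  # ideal tube voxel: lambda = (0, -20, -20)
  expect_equal(frangi_measure(0, -20, -20, p),
               (1 - exp(-12.5)) * 1 * (1 - exp(-0.25)), tolerance = 1e-12)
  # ideal blob voxel: lambda = (-20, -20, -20), S^2 = 1200
  expect_equal(frangi_measure(-20, -20, -20, p),
               (1 - exp(-12.5)) * exp(-1 / (2 * 0.25)) *
                 (1 - exp(-1200 / 3200)),
               tolerance = 1e-12)
  # bright-polarity gate: positive lambda2/lambda3 kill the response
  expect_equal(frangi_measure(0, 20, -20, p), 0)
  expect_equal(frangi_measure(0, -20, 20, p), 0)
  # dark polarity mirrors the gate
  pd <- frangi_params(0.2, 0.5, 40, 3, polarity = "dark")
  expect_equal(frangi_measure(0, -20, -20, pd), 0)
  expect_gt(frangi_measure(0, 20, 20, pd), 0)
  # degenerate structure: zero eigenvalues give zero response
  expect_equal(frangi_measure(0, 0, 0, p), 0)
})

test_that("a bright blob yields no response under dark polarity", {
  n <- 25; co <- (1:n) - 13
  r2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  v <- volume3d(array(0.2 + 0.6 * exp(-r2 / 18), c(n, n, n)), 1)
  dark <- frangi_response(v, frangi_params(0.2, 0.5, 40, 3,
                                           polarity = "dark",
                                           intensity_scale = 240))
  expect_equal(dark$data[13, 13, 13], 0)
  bright <- frangi_response(v, frangi_params(0.2, 0.5, 40, 3,
                                             intensity_scale = 240))
  expect_gt(bright$data[13, 13, 13], 0)
})

test_that("the response lies in [0,1] and is invariant under axis permutations and flips", {
  v <- rand_volume(c(32, 32, 32), seed = 21)
  p <- cell_mode_params(scales_vox = 3:4)
  r0 <- frangi_response(v, p)$data
  expect_gte(min(r0), 0)
  expect_lte(max(r0), 1)
  perms <- list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))
  for (pm in perms) {
    vp <- volume3d(aperm(v$data, pm), 1)
    rp <- frangi_response(vp, p)$data
    expect_lt(max(abs(rp - aperm(r0, pm))), 1e-6)
  }
  vf <- volume3d(v$data[32:1, , ], 1)
  rf <- frangi_response(vf, p)$data
  expect_lt(max(abs(rf - r0[32:1, , ])), 1e-6)
})

test_that("adding a scale can only increase the multi-scale maximum", {
  v <- rand_volume(c(28, 28, 28), seed = 22)
  r34 <- frangi_response(v, cell_mode_params(scales_vox = 3:4))$data
  r35 <- frangi_response(v, cell_mode_params(scales_vox = 3:5))$data
  expect_true(all(r35 >= r34 - 1e-12))
})

test_that("scale selection: the per-scale response at a tube axis peaks at the tube scale", {
  n <- 41; t0 <- 3; c0 <- 21
  co <- (1:n) - c0
  ridge <- array(0, c(n, n, n))
  for (z in 1:n) ridge[z, , ] <- exp(-outer(co^2, co^2, "+") / (2 * t0^2))
  v <- volume3d(0.3 * ridge, 1)
  at_axis <- vapply(1:6, function(s) {
    frangi_response(v, cell_mode_params(scales_vox = s,
                                        intensity_scale = 240))$data[c0, c0, c0]
  }, numeric(1))
  expect_equal(which.max(at_axis), t0)
})
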