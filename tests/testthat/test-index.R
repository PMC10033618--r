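# Selection response: B matrix, unrestricted/restricted gain, ellipse geometry.

test_that("unrestricted gain matches the Lagrange closed form", {
  # B = I2, equal weights -> response and coefficients (0.707, 0.707)
  g <- gain(diag(2), merit_weights = c(1, 1))
  expect_equal(unname(g$response), rep(sqrt(0.5), 2), tolerance = 1e-8)
  expect_equal(unname(g$coefficients), rep(sqrt(0.5), 2), tolerance = 1e-8)
  # general B: x* = i * B c / sqrt(c' B c)
  set.seed(41)
  for (i in 1:10) {
    B <- random_psd(4)
    w <- runif(4, 0.2, 2)
    cvec <- w / sqrt(sum(w^2))
    g <- gain(B, merit_weights = w, intensity = 1.7)
    xstar <- 1.7 * drop(B %*% cvec) / sqrt(drop(t(cvec) %*% B %*% cvec))
    expect_equal(unname(g$response), xstar, tolerance = 1e-6)
    # boundary attainment: x' B^-1 x = i^2
    expect_equal(drop(t(g$response) %*% solve(B, g$response)), 1.7^2,
                 tolerance = 1e-6)
  }
})

test_that("one equality restriction matches the Lagrange-multiplier solution", {
  set.seed(42)
  for (i in 1:10) {
    B <- random_psd(3)
    w <- c(runif(2, 0.5, 2), 0)
    g <- gain(B, merit_weights = w, restrictions = c(trait3 = "=0"))
    # independent oracle: stationarity of c'x - lambda x'B^-1x - mu x_3
    cvec <- w / sqrt(sum(w^2))
    E <- matrix(c(0, 0, 1), 3, 1)
    mu <- drop(solve(crossprod(E, B %*% E), crossprod(E, B %*% cvec)))
    d <- drop(B %*% (cvec - E %*% mu))
    xo <- d / sqrt(drop(t(d) %*% solve(B, d)))
    expect_equal(unname(g$response), xo, tolerance = 1e-6)
    expect_equal(unname(g$response["trait3"]), 0, tolerance = 1e-8)
  }
})

test_that("a restriction already satisfied by the optimum is inactive", {
  g <- gain(diag(2), merit_weights = c(1, 0),
            restrictions = c(trait2 = "=0"))
  expect_equal(unname(g$response), c(1, 0), tolerance = 1e-8)
})

test_that("inequality constraints never do worse than equalities", {
  set.seed(43)
  for (i in 1:12) {
    B <- random_psd(4)
    w <- c(runif(2, 0.5, 2), 0, 0)
    geq <- gain(B, merit_weights = w,
                restrictions = c(trait3 = "=0", trait4 = "=0"))
    gin <- gain(B, merit_weights = w,
                restrictions = c(trait3 = "<=0", trait4 = "<=0"))
    expect_gte(gin$merit_gain, geq$merit_gain - 1e-8)
    expect_true(all(gin$response[3:4] <= 1e-8))
  }
  # with a single constraint the inequality optimum sits at zero response
  B <- random_psd(3, 431)
  # make the unrestricted response for trait3 positive so <=0 binds
  w <- c(1, 1, 0)
  if (gain(B, merit_weights = w)$response[3] > 0) {
    g1 <- gain(B, merit_weights = w, restrictions = c(trait3 = "<=0"))
    g2 <- gain(B, merit_weights = w, restrictions = c(trait3 = "=0"))
    expect_equal(g1$merit_gain, g2$merit_gain, tolerance = 1e-8)
  }
})

test_that("gain is invariant to the scale of the merit weights", {
  B <- random_psd(3, 44)
  g1 <- gain(B, merit_weights = c(1, 2, 0.5))
  g2 <- gain(B, merit_weights = 10 * c(1, 2, 0.5))
  expect_equal(g1$response, g2$response, tolerance = 1e-10)
  expect_equal(g1$coefficients, g2$coefficients, tolerance = 1e-10)
})

test_that("infeasible restrictions are reported", {
  expect_error(gain(diag(2), merit_weights = c(1, 0),
                    restrictions = c(trait2 = "=5")), "infeasible")
})

test_that("response matrix has selection-theory structure on simulated data", {
  p2 <- small_pipeline2()
  B <- response_matrix(p2$state, what = "BV")
  expect_equal(B, t(B))
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
  # B is the population covariance of the predicted genetic-value vectors:
  # recompute it through the per-trait prediction route
  m1 <- predict_merit(p2$state, index_weights = c(1, 0), what = "BV")
  m2 <- predict_merit(p2$state, index_weights = c(0, 1), what = "BV")
  w <- p2$state$w_env
  wcor <- function(a, b) {
    Tn <- sum(w)
    ca <- a - sum(w * a) / Tn; cb <- b - sum(w * b) / Tn
    sum(w * ca * cb) / sqrt(sum(w * ca^2) * sum(w * cb^2))
  }
  # B is the EXPECTED population covariance (quadratic-form identity), so it
  # agrees with the realized covariance of the predictions up to sampling
  expect_equal(cov2cor(B)[1, 2], wcor(m1$value, m2$value), tolerance = 0.05)
  # prediction correlations are shrinkage-inflated relative to the generating
  # additive correlation; require broad agreement only
  expect_lt(abs(cov2cor(B)[1, 2] - cor(p2$truth$genetic)[1, 2]), 0.45)
  # single-trait case collapses to a 1 x 1 variance
  p <- small_pipeline()
  B1 <- response_matrix(p$state, what = "BV")
  expect_equal(dim(B1), c(1, 1))
  expect_gt(B1[1, 1], 0)
  # identical predictions for everyone would give zero response:
  # achieved trivially when var_uhat and fixed effects are zeroed
  st0 <- p$state
  st0$uhat[] <- 0; st0$var_uhat[] <- 0
  st0$delta[] <- 0
  expect_equal(unname(response_matrix(st0, what = "BV")[1, 1]), 0)
})

test_that("ellipse slices have the analytic axes and live on the ellipsoid", {
  # diagonal B: axis-aligned ellipse with semi-axes (sigma1, sigma2)
  es <- ellipse_slice(diag(c(4, 9)), traits = c(1, 2))
  expect_equal(sort(es$semi_axes), c(2, 3), tolerance = 1e-10)
  # B = I with unit SDs: unit circle
  B <- diag(2); attr(B, "sigma_b") <- c(1, 1)
  es2 <- ellipse_slice(B, traits = c(1, 2))
  expect_equal(es2$semi_axes, c(1, 1), tolerance = 1e-10)
  # any PSD B: every boundary point satisfies x' B^-1 x = i^2
  B3 <- random_psd(3, 45)
  g <- gain(B3, merit_weights = c(1, 1, 1), intensity = 1.3)
  es3 <- ellipse_slice(B3, traits = c(1, 2), intensity = 1.3, at = g$response)
  x3 <- g$response[3]
  qf <- apply(es3$boundary, 1, function(xy)
    drop(t(c(xy, x3)) %*% solve(B3, c(xy, x3))))
  expect_lt(max(abs(qf - 1.3^2)), 1e-8)
})

test_that("degenerate response matrices are flagged and handled", {
  B <- matrix(1, 2, 2)  # rank 1
  suppressMessages(g <- gain(B, merit_weights = c(1, 1)))
  expect_true(g$degenerate)
  expect_equal(unname(g$response), c(1, 1), tolerance = 1e-6)
  es <- ellipse_slice(B, traits = c(1, 2))
  expect_true(es$degenerate)
})
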