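# REML engine: closed-form equivalences, invariances, structures, AIC.

test_that("balanced one-way REML equals the ANOVA closed form", {
  set.seed(101)
  g <- 25; r <- 4
  id <- factor(rep(seq_len(g), each = r))
  y <- rnorm(g, 0, 1.3)[id] + rnorm(g * r, 0, 0.9)
  fit <- reml_fit(y, matrix(1, g * r, 1), random = list(
    geno = list(map = as.integer(id), struct = vs_iid(g)),
    resid = list(map = seq_along(y), struct = vs_iid(g * r))))
  a <- anova(lm(y ~ id))
  MSB <- a[1, 3]; MSE <- a[2, 3]
  expect_equal(fit$estimates$geno$sigma2, (MSB - MSE) / r, tolerance = 1e-5)
  expect_equal(fit$estimates$resid$sigma2, MSE, tolerance = 1e-5)
  expect_equal(fit$AIC, -2 * fit$loglik + 2 * fit$k)
  expect_equal(fit$k, 2L)
})

test_that("restricted likelihood is invariant to translation by fixed effects", {
  set.seed(102)
  n <- 60
  X <- cbind(1, rnorm(n))
  id <- rep(1:20, 3)
  y <- rnorm(20)[id] + rnorm(n)
  terms <- list(g = list(map = id, struct = vs_iid(20)),
                e = list(map = 1:n, struct = vs_iid(n)))
  f1 <- reml_fit(y, X, terms)
  f2 <- reml_fit(y + X %*% c(5, -3), X, terms)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$estimates$g$sigma2, f2$estimates$g$sigma2, tolerance = 1e-5)
})

test_that("scaling y rescales variance components quadratically", {
  set.seed(103)
  n <- 80
  id <- rep(1:20, 4)
  y <- rnorm(20, 0, 1.5)[id] + rnorm(n)
  terms <- list(g = list(map = id, struct = vs_iid(20)),
                e = list(map = 1:n, struct = vs_iid(n)))
  X <- matrix(1, n, 1)
  f1 <- reml_fit(y, X, terms)
  f2 <- reml_fit(3 * y, X, terms)
  expect_equal(f2$estimates$g$sigma2, 9 * f1$estimates$g$sigma2,
               tolerance = 1e-4)
  expect_equal(f2$estimates$e$sigma2, 9 * f1$estimates$e$sigma2,
               tolerance = 1e-4)
  # logLik shifts by -(n - p) * log(c)
  expect_equal(f2$loglik, f1$loglik - (n - 1) * log(3), tolerance = 1e-4)
})

test_that("AI optimum matches a derivative-free optimum of an independent
           likelihood implementation on a kernel + residual problem", {
  set.seed(104)
  n <- 50
  K <- random_psd(n, 104)
  y <- drop(crossprod(chol(K), rnorm(n))) + rnorm(n, 0, 0.8)
  X <- matrix(1, n, 1)
  fit <- reml_fit(y, X, list(g = list(map = 1:n, struct = vs_kernel(K)),
                             e = list(map = 1:n, struct = vs_iid(n))))
  # brute-force oracle: dense REML likelihood written from the definition
  nll <- function(th) {
    V <- exp(th[1]) * K + exp(th[2]) * diag(n)
    Vi <- solve(V)
    XtViX <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
    0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
             drop(crossprod(y, P %*% y)) + (n - 1) * log(2 * pi))
  }
  opt <- optim(c(0, 0), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-5)
  expect_equal(log(fit$estimates$g$sigma2), opt$par[1], tolerance = 1e-3)
  expect_equal(log(fit$estimates$e$sigma2), opt$par[2], tolerance = 1e-3)
  # monotonicity: the optimum is at least as good as the deterministic start
  vshare <- 0.5 * var(y) / 2
  expect_gte(fit$loglik, -nll(log(c(vshare / mean(diag(K)), vshare))) - 1e-6)
})

test_that("a fixed known covariance term enters V with coefficient one", {
  set.seed(105)
  n <- 120; id <- rep(1:40, 3)
  svar <- runif(n, 0.5, 2)
  y <- rnorm(40)[id] + rnorm(n, 0, sqrt(0.5)) + rnorm(n, 0, sqrt(svar))
  X <- matrix(1, n, 1)
  terms <- list(g = list(map = id, struct = vs_iid(40)),
                e = list(map = 1:n, struct = vs_iid(n)))
  f1 <- reml_fit(y, X, terms, fixed_V = diag(svar))
  expect_equal(f1$k, 2L)                      # the fixed term adds no parameter
  # all-zero fixed covariance reproduces the plain fit exactly
  f0 <- reml_fit(y, X, terms)
  fz <- reml_fit(y, X, terms, fixed_V = matrix(0, n, n))
  expect_equal(fz$loglik, f0$loglik, tolerance = 1e-9)
  expect_error(reml_fit(y, X, terms, fixed_V = -diag(n)), "positive semi")
})

test_that("boundary variance components are clamped and flagged", {
  set.seed(106)
  n <- 90; id <- rep(1:30, 3)
  y <- rnorm(n)     # no group variance at all
  fit <- reml_fit(y, matrix(1, n, 1),
                  list(g = list(map = id, struct = vs_iid(30)),
                       e = list(map = 1:n, struct = vs_iid(n))))
  expect_true(fit$boundary[1])
  expect_lt(fit$estimates$g$sigma2, 1e-6 * var(y))
})

test_that("FA2 reconstructs a factor-analytic covariance and bounds the radii", {
  set.seed(107)
  s <- 6; n <- 250
  Lam <- cbind(runif(s, 0.6, 1.2), c(0, runif(s - 1, -0.5, 0.5)))
  Psi <- runif(s, 0.05, 0.3)
  Gam <- tcrossprod(Lam) + diag(Psi)
  U <- matrix(rnorm(n * s), n) %*% chol(Gam)
  obs_id <- rep(seq_len(n), each = s); obs_loc <- rep(seq_len(s), n)
  y <- U[cbind(obs_id, obs_loc)] + rnorm(n * s, 0, 0.4)
  fit <- reml_fit(y, model.matrix(~ 0 + factor(obs_loc)), list(
    gl = list(map = (obs_id - 1L) * s + obs_loc,
              struct = vs_kron_fa2(diag(n), s)),
    e = list(map = seq_along(y), struct = vs_iid(n * s))))
  Ghat <- fit$estimates$gl$Gamma
  expect_lt(max(abs(Ghat - Gam)), 0.35)   # sampling + FA2 approximation error
  rot <- fa2_rotate(fit$estimates$gl$Lambda, fit$estimates$gl$Psi)
  expect_true(all(rot$radius2 <= 1 + 1e-8))
  expect_true(all(rot$radius2 >= 0))
})

test_that("fa2_rotate handles the no-specific-variance and no-loading cases", {
  Lam <- cbind(c(1, 0.8, 0.6), c(0, 0.3, -0.2))
  r1 <- fa2_rotate(Lam, Psi = rep(0, 3))
  expect_equal(unname(r1$radius2), rep(1, 3))          # points on the unit circle
  r0 <- fa2_rotate(matrix(0, 3, 2), Psi = rep(1, 3))   # Gamma = I, Lambda = 0
  expect_equal(unname(r0$radius2), rep(0, 3))
  expect_error(fa2_rotate(Lam[1:2, ], rep(0, 2)), ">= 3")
  # rotation preserves Lambda Lambda'
  expect_equal(tcrossprod(r1$loadings), tcrossprod(Lam), tolerance = 1e-10)
})

test_that("heterogeneous group variances are recovered", {
  set.seed(108)
  grp <- rep(1:3, each = 100)
  y <- rnorm(300, 0, sqrt(c(0.5, 1, 2))[grp])
  fit <- reml_fit(y, matrix(1, 300, 1), list(
    e = list(map = 1:300, struct = vs_diag_groups(factor(grp)))))
  expect_equal(unname(fit$estimates$e$sigma2), c(0.5, 1, 2), tolerance = 0.35)
})

test_that("compare_aic requires the same response and differences are AIC", {
  set.seed(109)
  n <- 60; id <- rep(1:20, 3)
  y <- rnorm(20)[id] + rnorm(n)
  X <- matrix(1, n, 1)
  f1 <- reml_fit(y, X, list(g = list(map = id, struct = vs_iid(20)),
                            e = list(map = 1:n, struct = vs_iid(n))))
  expect_equal(compare_aic(f1, f1), 0)
  f2 <- reml_fit(y + 1, X, list(g = list(map = id, struct = vs_iid(20)),
                                e = list(map = 1:n, struct = vs_iid(n))))
  expect_error(compare_aic(f1, f2), "same response")
})
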