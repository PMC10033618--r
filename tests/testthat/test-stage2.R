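# Stage 2: model assembly, the Stage-1 error term, PVE accounting, H blending.

test_that("expected-variance components follow the quadratic-form identity", {
  pvc <- polystage:::pve_component
  s2 <- 1.7
  # K = sigma2 * I over t = 4 records of one effect -> sigma2 * (1 - 1/4)
  expect_equal(pvc(K = s2 * diag(4), w = rep(1, 4)), 0.75 * s2)
  # constant mean, no covariance -> zero contribution
  expect_equal(pvc(mu = rep(3, 5), w = rep(1, 5)), 0)
  # two genotypes, G = I, balanced 2-loc main effect (off-diagonal of Gamma)
  g12 <- 0.6
  expect_equal(pvc(K = diag(2), w = c(1, 1)) * g12, 0.5 * g12)
  # weighted average: unbalanced weights enter both terms
  K <- matrix(c(1, 0.3, 0.3, 1), 2)
  w <- c(3, 1)
  Tn <- 4
  expect_equal(pvc(K = K, w = w),
               sum(w * diag(K)) / Tn - drop(t(w) %*% K %*% w) / Tn^2)
})

test_that("PVE rows are non-negative, sum to one, and are scale invariant", {
  p <- small_pipeline()
  pve <- p$fit$PVE
  expect_true(all(pve >= -1e-10))
  expect_equal(colSums(pve), c(trait1 = 1))
  expect_setequal(rownames(pve), c("additive", "dominance", "heterosis",
                                   "g x env", "Stage 1 error"))
  # rescaling all BLUEs (and their covariances) leaves the PVE unchanged
  s1 <- p$sim$stage1
  s1$blues$value <- 2 * s1$blues$value
  s1$vcov <- lapply(s1$vcov, function(V) 4 * V)
  fit2 <- fit_stage2(s1, stage2_spec(geno = p$gd, model = "dominance"))
  expect_equal(fit2$PVE, p$fit$PVE, tolerance = 0.02)
})

test_that("the s-term with all-zero Stage-1 covariance reproduces the plain fit", {
  p <- small_pipeline()
  s1 <- p$sim$stage1
  s1$vcov <- lapply(s1$vcov, function(V) V * 0)
  f_with <- fit_stage2(s1, stage2_spec(geno = p$gd, model = "dominance"),
                       include_s_term = TRUE)
  f_without <- fit_stage2(s1, stage2_spec(geno = p$gd, model = "dominance"),
                          include_s_term = FALSE)
  expect_equal(f_with$loglik, f_without$loglik, tolerance = 1e-7)
  expect_equal(f_with$AIC, f_without$AIC, tolerance = 1e-6)
})

test_that("AIC favors the model that carries heterogeneous Stage-1 errors", {
  p <- small_pipeline()
  f_with <- p$fit
  f_without <- fit_stage2(p$sim$stage1,
                          stage2_spec(geno = p$gd, model = "dominance"),
                          include_s_term = FALSE)
  expect_lt(compare_aic(f_with, f_without), 0)
})

test_that("a multi-trait fit with a single trait reduces to the single-trait fit", {
  p <- small_pipeline()
  f1 <- fit_stage2(p$sim$stage1,
                   stage2_spec(geno = p$gd, model = "genetic_residual"))
  fm <- fit_stage2(p$sim$stage1,
                   stage2_spec(geno = p$gd, model = "genetic_residual",
                               multi = "trait"))
  expect_equal(fm$loglik, f1$loglik, tolerance = 1e-5)
  expect_equal(fm$reml$estimates$additive$Sigma[1, 1],
               f1$reml$estimates$additive$sigma2, tolerance = 1e-3)
})

test_that("dominance PVE collapses to the boundary under a null simulation", {
  ms <- sim_population(100, 400, ploidy = 4, pedigree = TRUE,
                       n.founders = 25, seed = 501)
  truth <- sim_truth(ms, sigma2A = 1, sigma2D = 1e-12, b = 0, seed = 502)
  sim <- sim_phenotypes(ms, truth, n_env = 3, seed = 503)
  gd <- geno_data(ms)
  fit <- fit_stage2(sim$stage1, stage2_spec(geno = gd, model = "dominance"))
  expect_lt(fit$PVE["dominance", 1], 0.05)
})

test_that("heterosis and fixed-marker covariates are estimated per trait", {
  p2 <- small_pipeline2()
  expect_length(p2$fit$b, 2)
  expect_true(all(dim(p2$fit$add_corr) == c(2, 2)))
  expect_equal(diag(p2$fit$add_corr), c(trait1 = 1, trait2 = 1))
  # the additive/dominance covariance split is weakly identified at this
  # population size, but the total genetic covariance is not: its implied
  # correlation should track the realized correlation of the simulated
  # genetic values
  SG <- p2$fit$reml$estimates$additive$Sigma +
    p2$fit$reml$estimates$dominance$Sigma
  expect_lt(abs(cov2cor(SG)[1, 2] - cor(p2$truth$genetic)[1, 2]), 0.2)
  # with i.i.d. non-additive values the additive correlation itself is clean
  fit_gr <- fit_stage2(p2$sim$stage1,
                       stage2_spec(geno = p2$gd, model = "genetic_residual",
                                   multi = "trait"))
  expect_lt(abs(fit_gr$add_corr[1, 2] - cor(p2$truth$additive)[1, 2]), 0.25)
  # fixed marker covariate: one coefficient per trait
  sp <- stage2_spec(geno = p2$gd, model = "dominance", multi = "trait",
                    fixed_markers = p2$ms$marker_ids[1])
  fitm <- fit_stage2(p2$sim$stage1, sp)
  expect_length(fitm$fixed_marker_effects[[1]]$estimate, 2)
  expect_true("markers" %in% rownames(fitm$PVE))
})

test_that("blending with A identical to G gives a flat AIC curve", {
  p <- small_pipeline()
  gd2 <- p$gd
  gd2$A <- rel_matrix(gd2$G$values, kind = "A")   # A := G
  sp <- stage2_spec(geno = gd2, model = "genetic_residual", omega = 0)
  ob <- optimize_blend(p$sim$stage1, sp, omega_grid = c(0, 0.4, 0.8))
  expect_lt(diff(range(ob$table$AIC)), 1e-4)
})

test_that("the AIC-optimal blend weight tracks the generating kernel", {
  # data generated under K = 0.7 G + 0.3 A; omega* should be near 0.3
  omega_hat <- sapply(1:3, function(s) {
    ms <- sim_population(150, 500, ploidy = 2, pedigree = TRUE,
                         n.founders = 30, seed = 600 + s)
    gd <- geno_data(ms, pedigree = attr(ms, "pedigree"))
    K <- 0.7 * gd$G$values + 0.3 * gd$A$values[gd$G$ids, gd$G$ids]
    set.seed(700 + s)
    g <- drop(crossprod(chol(K + diag(1e-6, nrow(K))), rnorm(nrow(K))))
    n <- length(g); envs <- paste0("env", 1:3)
    blues <- do.call(rbind, lapply(envs, function(e)
      data.frame(id = ms$ids, env = e, trait = "y",
                 value = g + rnorm(n, 0, sqrt(0.4)) + rnorm(n, 0, sqrt(0.2)))))
    vc <- lapply(envs, function(e) {
      V <- diag(0.2, n); dimnames(V) <- list(ms$ids, ms$ids); V })
    names(vc) <- envs
    s1 <- as_stage1(blues, vc)
    ob <- optimize_blend(s1, stage2_spec(geno = gd, model = "genetic_residual"),
                         omega_grid = seq(0, 1, 0.1))
    ob$omega_opt
  })
  expect_lt(abs(mean(omega_hat) - 0.3), 0.25)
})

test_that("model preconditions are enforced", {
  p <- small_pipeline()
  s1 <- p$sim$stage1
  one_env <- s1
  one_env$blues <- one_env$blues[one_env$blues$env == one_env$blues$env[1], ]
  expect_error(fit_stage2(one_env, stage2_spec(geno = p$gd, model = "dominance")),
               ">= 2 environments")
  expect_error(stage2_spec(model = "dominance"), "geno_data")
  expect_error(stage2_spec(geno = p$gd, model = "dominance",
                           fixed_markers = "nope"), "not in the marker set")
})
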