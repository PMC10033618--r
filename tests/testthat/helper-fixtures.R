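# Shared fixtures, built in code and cached for the test run.

.fixtures <- new.env(parent = emptyenv())

# small family-structured tetraploid population with a fitted dominance model
small_pipeline <- function() {
  if (is.null(.fixtures$pipe)) {
    ms <- sim_population(100, 400, ploidy = 4, pedigree = TRUE,
                         n.founders = 25, seed = 401)
    truth <- sim_truth(ms, sigma2A = 1, sigma2D = 0.3, b = 5, seed = 402)
    sim <- sim_phenotypes(ms, truth, n_env = 3, seed = 403)
    gd <- geno_data(ms, pedigree = attr(ms, "pedigree"))
    fit <- fit_stage2(sim$stage1, stage2_spec(geno = gd, model = "dominance"))
    .fixtures$pipe <- list(ms = ms, truth = truth, sim = sim, gd = gd,
                           fit = fit, state = blup_prep(fit))
  }
  .fixtures$pipe
}

# two-trait variant with known additive genetic correlation 0.6
small_pipeline2 <- function() {
  if (is.null(.fixtures$pipe2)) {
    p <- small_pipeline()
    SA <- matrix(c(1, 0.6, 0.6, 1), 2)
    truth <- sim_truth(p$ms, sigma2A = SA, sigma2D = diag(0.3, 2),
                       b = c(3, 0), seed = 412)
    sim <- sim_phenotypes(p$ms, truth, n_env = 3, seed = 413)
    fit <- fit_stage2(sim$stage1,
                      stage2_spec(geno = p$gd, model = "dominance",
                                  multi = "trait"))
    .fixtures$pipe2 <- list(ms = p$ms, truth = truth, sim = sim, gd = p$gd,
                            fit = fit, state = blup_prep(fit))
  }
  .fixtures$pipe2
}

# marker set built from explicit dosages
ms_from <- function(X, ploidy, ids = NULL, markers = NULL) {
  if (!is.null(ids)) rownames(X) <- ids
  if (!is.null(markers)) colnames(X) <- markers
  marker_set(X, ploidy = ploidy)
}

# exact dominance coefficient, straight from its defining polynomial
Q_of <- function(X, phi, p) -2 * choose(phi, 2) * p^2 + 2 * p * (phi - 1) * X -
  X * (X - 1)

# random PSD matrix
random_psd <- function(t, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(rnorm(t * t), t)
  crossprod(M) / t + diag(0.1, t)
}
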