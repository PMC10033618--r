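# Synthetic-data generator reproducing the distributional assumptions of the
# two-stage pipeline: bi-allelic dosages at given frequencies (optionally with
# family structure or excess homozygosity), additive + directional-dominance
# genetic values built from random substitution effects, environment effects,
# i.i.d. GxE, plot errors, and heterogeneous Stage-1 error covariances.

#' Simulate a panmictic (or structured) marker population
#'
#' Dosages are drawn independently per locus as `Binomial(ploidy, p_k)`
#' (panmictic baseline, Hardy-Weinberg within locus).  With
#' `inbreeding` a two-element range, each individual gets its own autozygosity
#' level `f_i ~ Unif(range)` and each locus is fully homozygous (dosage 0 or
#' `ploidy`) with probability `f_i` — a simple way to create real variation in
#' the genomic inbreeding coefficient.  With `pedigree = TRUE`, founders are
#' panmictic and the remaining individuals are offspring of random founder
#' pairs, gametes sampled without replacement from the parental dosage
#' (random bivalent pairing).
#'
#' @param n individuals
#' @param m markers
#' @param ploidy even integer >= 2 (default 4, the tetraploid case)
#' @param p allele frequencies: vector of length m, or a range to draw from
#'   (default `c(0.1, 0.9)`)
#' @param inbreeding NULL (panmictic) or range of per-individual autozygosity
#' @param pedigree if TRUE, generate founders plus F1 families and attach the
#'   pedigree as attribute `"pedigree"`
#' @param n.founders number of founders when `pedigree = TRUE`
#' @param n.chrom chromosomes for the simulated map
#' @param seed integer seed (all randomness in the generator flows from it)
#'
#' @return A [marker_set]; with `pedigree = TRUE` the pedigree data frame is
#'   attached as `attr(ms, "pedigree")`.
#' @export
sim_population <- function(n, m, ploidy = 4, p = c(0.1, 0.9),
                           inbreeding = NULL, pedigree = FALSE,
                           n.founders = max(10, round(n / 5)),
                           n.chrom = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 1 || m < 1) stop("n and m must be >= 1")
  if (ploidy < 2 || ploidy %% 2 != 0) stop("ploidy must be an even integer >= 2")
  pk <- if (length(p) == m) p else stats::runif(m, min(p), max(p))
  ids <- sprintf("G%03d", seq_len(n))
  ped <- NULL
  if (pedigree) {
    nf <- min(n.founders, n)
    X <- matrix(stats::rbinom(nf * m, ploidy, rep(pk, each = nf)), nf, m)
    gamete <- function(x) stats::rhyper(length(x), x, ploidy - x, ploidy / 2)
    par1 <- par2 <- rep(NA_character_, n)
    if (n > nf) {
      for (i in (nf + 1):n) {
        pr <- sample.int(nf, 2, replace = FALSE)
        par1[i] <- ids[pr[1]]; par2[i] <- ids[pr[2]]
        X <- rbind(X, gamete(X[pr[1], ]) + gamete(X[pr[2], ]))
      }
    }
    ped <- as_pedigree(data.frame(id = ids, parent1 = par1, parent2 = par2))
  } else {
    X <- matrix(stats::rbinom(n * m, ploidy, rep(pk, each = n)), n, m)
    if (!is.null(inbreeding)) {
      f <- stats::runif(n, min(inbreeding), max(inbreeding))
      auto <- matrix(stats::runif(n * m) < f, n, m)   # autozygous calls
      hom <- matrix(ploidy * (stats::runif(n * m) <
                                matrix(pk, n, m, byrow = TRUE)), n, m)
      X[auto] <- hom[auto]
    }
  }
  dimnames(X) <- list(ids, sprintf("M%04d", seq_len(m)))
  map <- data.frame(marker = colnames(X),
                    chrom = paste0("chr", rep_len(seq_len(n.chrom), m)),
                    position = as.integer(seq(1e5, 9e7, length.out = m)))
  ms <- marker_set(X, ploidy = ploidy, map = map)
  if (!is.null(ped)) attr(ms, "pedigree") <- ped
  ms
}

#' True genetic values from random substitution effects
#'
#' Draws per-marker additive substitution effects
#' `alpha_k ~ N(0, sigma2A / (ploidy * sum(p q)))` and digenic substitution
#' effects `beta_k ~ N(mu_beta, sigma2D / denomD)` with
#' `mu_beta = b / denomF`, so that the additive values `W alpha` have
#' population variance close to `sigma2A`, the no-heterosis dominance values
#' have variance close to `sigma2D`, and the regression of genetic value on
#' the genomic inbreeding coefficient F is `-b` (b > 0 = heterosis =
#' inbreeding depression).  For `t` traits, `sigma2A` and `sigma2D` are t x t
#' covariance matrices and `b` a length-t vector.
#'
#' @param ms a [marker_set]
#' @param sigma2A additive variance (scalar) or trait covariance matrix
#' @param sigma2D dominance variance (scalar) or trait covariance matrix
#' @param b heterosis regression coefficient(s), per trait
#' @param sigma2gE i.i.d. genotype-by-environment variance, per trait
#' @param sigma2e plot error variance, per trait
#' @param seed integer seed
#'
#' @return An object of class `sim_truth`: marker effects `alpha`, `beta`
#'   (m x t), true `additive`, `dominance`, `genetic` values (n x t), the
#'   inbreeding covariate `F`, and the variance settings.
#' @export
sim_truth <- function(ms, sigma2A = 1, sigma2D = 0.3, b = 5,
                      sigma2gE = 0.5, sigma2e = 1, seed = NULL) {
  stopifnot(inherits(ms, "marker_set"))
  if (!is.null(seed)) set.seed(seed)
  SA <- as.matrix(sigma2A); SD <- as.matrix(sigma2D)
  t <- nrow(SA)
  stopifnot(nrow(SD) == t, length(b) == t)
  m <- length(ms$marker_ids)
  p <- ms$p; q <- 1 - p
  phi <- ms$ploidy
  denomA <- phi * sum(p * q)
  dom <- compute_dominance(ms)
  denomD <- dom$coeff$denomD
  denomF <- dom$coeff$denomF
  rmvn_rows <- function(m, S) {
    if (nrow(S) == 1) matrix(stats::rnorm(m, 0, sqrt(S[1, 1])), m, 1)
    else matrix(stats::rnorm(m * nrow(S)), m) %*% chol(S)
  }
  alpha <- rmvn_rows(m, SA / denomA)
  beta0 <- rmvn_rows(m, SD / denomD)
  mu_beta <- b / denomF
  beta <- beta0 + matrix(mu_beta, m, t, byrow = TRUE)
  W <- dosage_W(ms)
  additive <- W %*% alpha
  dominance <- dom$coeff$Q %*% beta
  tn <- paste0("trait", seq_len(t))
  dimnames(additive) <- dimnames(dominance) <- list(ms$ids, tn)
  structure(list(alpha = alpha, beta = beta, additive = additive,
                 dominance = dominance, genetic = additive + dominance,
                 F = dom$coeff$F, b = b, sigma2A = SA, sigma2D = SD,
                 sigma2gE = rep_len(sigma2gE, t), sigma2e = rep_len(sigma2e, t),
                 traits = tn, seed = seed),
            class = "sim_truth")
}

#' Simulate plot phenotypes and exact Stage-1 results
#'
#' Plot-level phenotypes are
#' `y = E_j + g_i + gE_ij + e_plot` for environment effects `E_j`, total
#' genetic values `g_i` from [sim_truth], i.i.d. GxE draws, and plot error.
#' In parallel, exact Stage-1-style BLUEs `E_j + g_i + gE_ij + s_ij` are
#' emitted with heterogeneous KNOWN error variances: each environment gets a
#' scale drawn from `s1_error` and each genotype a lognormal-ish multiplier,
#' giving diagonal per-environment covariance blocks in `[min, max]` of the
#' range (roughly), which is what the Stage-2 fixed-covariance term consumes.
#'
#' @param ms a [marker_set]
#' @param truth a [sim_truth]
#' @param n_env number of environments
#' @param reps plots per genotype per environment
#' @param s1_error range of per-environment Stage-1 error variance scales
#' @param seed integer seed
#'
#' @return list with `pheno` (plot data frame: id, env, block, traits),
#'   `stage1` (a `stage1_fit` holding the simulated BLUEs and their known
#'   diagonal covariance blocks), `env_effects`, and `s1_var` (the error
#'   variances used, env x id per trait).
#' @export
sim_phenotypes <- function(ms, truth, n_env = 4, reps = 2,
                           s1_error = c(0.5, 2), seed = NULL) {
  stopifnot(inherits(ms, "marker_set"), inherits(truth, "sim_truth"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(ms$ids)
  t <- length(truth$traits)
  envs <- sprintf("env%02d", seq_len(n_env))
  E <- stats::rnorm(n_env, 0, 2)
  names(E) <- envs
  g <- truth$genetic

  pheno <- list()
  blues <- list()
  vcovs <- list()
  for (j in seq_len(n_env)) {
    gE <- matrix(stats::rnorm(n * t, 0,
                              rep(sqrt(truth$sigma2gE), each = n)), n, t)
    mu_ij <- E[j] + g + gE          # n x t genotype-in-env values
    # plots
    for (r in seq_len(reps)) {
      err <- matrix(stats::rnorm(n * t, 0,
                                 rep(sqrt(truth$sigma2e), each = n)), n, t)
      yy <- mu_ij + err
      colnames(yy) <- truth$traits
      pheno[[paste(j, r)]] <- data.frame(id = ms$ids, env = envs[j],
                                         block = paste0("B", r), yy,
                                         check.names = FALSE)
    }
    # exact Stage-1 BLUEs with heterogeneous known error
    scale_j <- stats::runif(1, min(s1_error), max(s1_error))
    v_ij <- scale_j * stats::runif(n, 0.8, 1.2)   # per-genotype variances
    verr <- outer(v_ij, rep(1, t))
    s_ij <- matrix(stats::rnorm(n * t), n, t) * sqrt(verr)
    bl <- mu_ij + s_ij
    blues[[j]] <- data.frame(id = rep(ms$ids, each = t), env = envs[j],
                             trait = rep(truth$traits, n),
                             value = as.vector(t(bl)))
    rn <- if (t == 1) ms$ids else
      as.vector(t(outer(ms$ids, truth$traits, paste, sep = ":")))
    V <- diag(as.vector(t(verr)), n * t)
    dimnames(V) <- list(rn, rn)
    vcovs[[envs[j]]] <- V
  }
  s1 <- as_stage1(do.call(rbind, c(blues, make.row.names = FALSE)), vcovs)
  list(pheno = do.call(rbind, c(pheno, make.row.names = FALSE)),
       stage1 = s1, env_effects = E,
       s1_var = vapply(vcovs, function(V) mean(diag(V)), numeric(1)))
}
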