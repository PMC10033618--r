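# Empirical BLUP conditional on the Stage-2 variance estimates.  blup_prep
# does the heavy inversion once (mixed-model equations when there are more
# records than random effects, otherwise direct inversion of V), so that
# merit predictions, reliabilities, and GWAS scores can be queried repeatedly
# under arbitrary index vectors without refitting.

# inverse with a small ridge when the matrix is (near-)singular, which the
# centered-dosage G is by construction (G1 = 0); the MME route needs var(u)
# invertible, and the ridge-regularized solution agrees with the exact
# V-inversion route to the order of the ridge
safe_inv <- function(M, label = "matrix") {
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(R) && min(diag(R))^2 > 1e-10 * mean(diag(M)))
    return(chol2inv(R))
  ridge <- 1e-8 * mean(diag(M))
  out <- tryCatch(chol2inv(chol(M + diag(ridge, nrow(M)))),
                  error = function(e) NULL)
  if (is.null(out))
    stop(sprintf("%s is singular (condition too poor even with ridge)", label))
  out
}

# description of the random-effect layout for a fitted Stage-2 model:
# a list of blocks, each with a kernel K (n x n over ids), an inner dimension
# (traits/locations) and its inner covariance, plus the obs -> effect map.
blup_blocks <- function(fit) {
  md <- fit$model
  est <- fit$reml$estimates
  spec <- fit$spec
  n <- length(md$ids)
  t <- length(md$traits)
  blocks <- list()
  if (spec$model == "none") {
    if (spec$multi == "loc") {
      s <- length(md$locs)
      Gam <- if (!is.null(est$genotype$Gamma)) est$genotype$Gamma else est$genotype$Sigma
      blocks$genotype <- list(K = diag(n), inner = Gam, dim = n * s,
                              emap = function(id_idx, tr_idx, loc_idx)
                                (id_idx - 1L) * s + loc_idx)
    } else if (spec$multi == "trait") {
      blocks$genotype <- list(K = diag(n), inner = est$genotype$Sigma, dim = n * t,
                              emap = function(id_idx, tr_idx, loc_idx)
                                (id_idx - 1L) * t + tr_idx)
    } else {
      blocks$genotype <- list(K = diag(n), inner = matrix(est$genotype$sigma2, 1, 1),
                              dim = n, emap = function(id_idx, tr_idx, loc_idx) id_idx)
    }
  } else {
    if (spec$multi == "loc") {
      s <- length(md$locs)
      Gam <- if (!is.null(est$additive$Gamma)) est$additive$Gamma else est$additive$Sigma
      blocks$additive <- list(K = md$K_add, inner = Gam, dim = n * s,
                              emap = function(id_idx, tr_idx, loc_idx)
                                (id_idx - 1L) * s + loc_idx)
    } else if (spec$multi == "trait") {
      blocks$additive <- list(K = md$K_add, inner = est$additive$Sigma, dim = n * t,
                              emap = function(id_idx, tr_idx, loc_idx)
                                (id_idx - 1L) * t + tr_idx)
    } else {
      blocks$additive <- list(K = md$K_add,
                              inner = matrix(est$additive$sigma2, 1, 1), dim = n,
                              emap = function(id_idx, tr_idx, loc_idx) id_idx)
    }
    if (spec$model == "dominance") {
      if (spec$multi == "trait") {
        blocks$nonadd <- list(K = md$K_dom, inner = est$dominance$Sigma, dim = n * t,
                              emap = function(id_idx, tr_idx, loc_idx)
                                (id_idx - 1L) * t + tr_idx)
      } else {
        blocks$nonadd <- list(K = md$K_dom,
                              inner = matrix(est$dominance$sigma2, 1, 1), dim = n,
                              emap = function(id_idx, tr_idx, loc_idx) id_idx)
      }
    } else {
      if (spec$multi == "trait") {
        blocks$nonadd <- list(K = diag(n), inner = est$gresid$Sigma, dim = n * t,
                              emap = function(id_idx, tr_idx, loc_idx)
                                (id_idx - 1L) * t + tr_idx)
      } else {
        blocks$nonadd <- list(K = diag(n),
                              inner = matrix(est$gresid$sigma2, 1, 1), dim = n,
                              emap = function(id_idx, tr_idx, loc_idx) id_idx)
      }
    }
  }
  blocks
}

#' Prepare BLUP solutions from a Stage-2 fit
#'
#' Computes the predicted random genetic effects `u_hat` and their
#' variance-covariance matrix `var(u_hat)` conditional on the Stage-2
#' variance estimates, by one of two numerically equivalent routes: inversion
#' of the mixed-model-equation coefficient matrix (when there are more
#' records than random effects; `var(u_hat) = var(u) - C22`) or direct
#' inversion of `V = var(y)` (`u_hat = var(u) Z' P y`,
#' `var(u_hat) = var(u) Z' P Z var(u)`).  Records can be masked to emulate
#' prediction of unphenotyped individuals (marker-based selection) or of new
#' environments; masked individuals remain in the random-effect vector and
#' are predicted through their genomic relationships.
#'
#' @param fit a `stage2_fit`
#' @param mask optional data frame with column `id` and optionally `env`
#'   and/or `trait`; all matching Stage-2 records are removed before solving
#' @param method `"auto"` (size-based choice), `"MME"`, or `"Vinv"`
#'
#' @return An object of class `blup_state` holding `uhat`, `var_uhat`,
#'   fixed-effect estimates, the random-effect layout, and the metadata
#'   needed by [predict_merit], [response_matrix], and [marker_effects].
#' @export
blup_prep <- function(fit, mask = NULL, method = c("auto", "MME", "Vinv")) {
  stopifnot(inherits(fit, "stage2_fit"))
  method <- match.arg(method)
  md <- fit$model
  est <- fit$reml$estimates
  spec <- fit$spec
  obs <- md$obs
  n_obs <- nrow(obs)

  keep <- rep(TRUE, n_obs)
  if (!is.null(mask)) {
    mask <- as.data.frame(mask)
    stopifnot("id" %in% names(mask))
    for (r in seq_len(nrow(mask))) {
      sel <- obs$id == as.character(mask$id[r])
      if ("env" %in% names(mask) && !is.na(mask$env[r]))
        sel <- sel & obs$env == as.character(mask$env[r])
      if ("trait" %in% names(mask) && !is.na(mask$trait[r]))
        sel <- sel & obs$trait == as.character(mask$trait[r])
      keep[sel] <- FALSE
    }
  }
  if (!any(keep)) stop("mask removes every Stage-2 record")
  X <- md$X[keep, , drop = FALSE]
  dropcol <- colSums(abs(X)) == 0
  if (any(dropcol[md$xmeta$env]))
    stop("masking removed all records of environment(s): ",
         paste(md$xmeta$env[dropcol[md$xmeta$env]], collapse = ", "))
  y <- md$y[keep]
  id_idx <- md$id_idx[keep]
  tr_idx <- md$tr_idx[keep]
  loc_idx <- if (!is.null(md$locs)) match(obs$loc[keep], md$locs) else
    rep(1L, sum(keep))

  blocks <- blup_blocks(fit)
  qs <- vapply(blocks, function(b) b$dim, numeric(1))
  q_u <- sum(qs)
  off <- cumsum(c(0, qs[-length(qs)]))
  names(off) <- names(blocks)

  nk <- length(y)
  Z <- matrix(0, nk, q_u)
  for (bn in names(blocks)) {
    e <- blocks[[bn]]$emap(id_idx, tr_idx, loc_idx)
    Z[cbind(seq_len(nk), off[bn] + e)] <- 1
  }
  Gu <- matrix(0, q_u, q_u)
  for (bn in names(blocks)) {
    b <- blocks[[bn]]
    ix <- off[bn] + seq_len(b$dim)
    Gu[ix, ix] <- if (nrow(b$inner) == 1) b$inner[1, 1] * b$K else
      b$K %x% b$inner
  }

  # residual covariance R = gE (+ Stage-1 error when it was in the model)
  R <- matrix(0, nk, nk)
  if (spec$multi == "loc") {
    diag(R) <- est$gxe$sigma2[loc_idx]
  } else if (spec$multi == "trait") {
    cell <- as.integer(factor(paste(obs$id, obs$env)))[keep]
    R <- est$gxe$Sigma[tr_idx, tr_idx] * outer(cell, cell, `==`)
  } else {
    diag(R) <- est$gxe$sigma2
  }
  if (!is.null(md$S)) R <- R + md$S[keep, keep, drop = FALSE]

  use_mme <- switch(method, auto = nk > q_u, MME = TRUE, Vinv = FALSE)
  p <- ncol(X)
  mme_failed <- FALSE
  if (use_mme) {
    Rinv <- safe_inv(R, "residual covariance R")
    Guinv <- matrix(0, q_u, q_u)
    for (bn in names(blocks)) {
      b <- blocks[[bn]]
      ix <- off[bn] + seq_len(b$dim)
      Kinv <- safe_inv(b$K, sprintf("kernel of '%s'", bn))
      Guinv[ix, ix] <- if (nrow(b$inner) == 1) Kinv / b$inner[1, 1] else
        Kinv %x% safe_inv(b$inner, sprintf("inner covariance of '%s'", bn))
    }
    XtR <- crossprod(X, Rinv)
    ZtR <- crossprod(Z, Rinv)
    C <- rbind(cbind(XtR %*% X, XtR %*% Z),
               cbind(ZtR %*% X, ZtR %*% Z + Guinv))
    rhs <- c(XtR %*% y, ZtR %*% y)
    Ci <- tryCatch(solve(C), error = function(e) NULL)
    if (is.null(Ci) || rcond(C) < 1e-15) {
      if (method == "MME")
        stop("singular MME coefficient matrix; reciprocal condition estimate ",
             signif(rcond(C), 3))
      message("MME coefficient matrix is numerically singular; switching to the V-inversion route")
      use_mme <- FALSE
      mme_failed <- TRUE
    } else {
      sol <- drop(Ci %*% rhs)
      delta <- sol[seq_len(p)]
      uhat <- sol[-seq_len(p)]
      var_uhat <- Gu - Ci[-seq_len(p), -seq_len(p)]
      var_delta <- Ci[seq_len(p), seq_len(p)]
      cov_delta_uhat <- -Ci[seq_len(p), -seq_len(p)]
    }
  }
  if (!use_mme) {
    V <- Z %*% Gu %*% t(Z) + R
    Vi <- tryCatch(chol2inv(chol(V)), error = function(e)
      stop("singular V; reciprocal condition estimate ", signif(rcond(V), 3)))
    W1 <- Vi %*% X
    XtViX <- crossprod(X, W1)
    var_delta <- solve(XtViX)
    P <- Vi - W1 %*% var_delta %*% t(W1)
    Py <- drop(P %*% y)
    GuZt <- tcrossprod(Gu, Z)
    uhat <- drop(GuZt %*% Py)
    var_uhat <- GuZt %*% P %*% t(GuZt)
    delta <- drop(var_delta %*% crossprod(X, Vi %*% y))
    cov_delta_uhat <- -var_delta %*% crossprod(W1, t(GuZt))
  }
  names(delta) <- colnames(X)

  w_env <- tabulate(id_idx, nbins = length(md$ids))  # records per genotype
  structure(list(uhat = uhat, var_uhat = var_uhat, delta = delta,
                 var_delta = var_delta, cov_delta_uhat = cov_delta_uhat,
                 blocks = blocks, offsets = off, Gu = Gu,
                 method = if (use_mme) "MME" else "Vinv", mask = mask,
                 ids = md$ids, traits = md$traits, locs = md$locs,
                 xmeta = md$xmeta, Fc = md$Fc, W_fix = md$W_fix,
                 geno = md$geno, spec = spec, estimates = est,
                 n_records = nk, w_env = w_env, fit = fit),
            class = "blup_state")
}

#' @export
print.blup_state <- function(x, ...) {
  cat(sprintf("blup_state (%s route): %d records, %d random effects (%s)%s\n",
              x$method, x$n_records, length(x$uhat),
              paste(names(x$blocks), collapse = " + "),
              if (!is.null(x$mask)) sprintf(", %d mask rows", nrow(x$mask)) else ""))
  invisible(x)
}

# gamma weight on non-additive values for a given merit type and ploidy
merit_gamma <- function(what, ploidy) {
  switch(what, AV = 0, GV = 1, BV = (ploidy / 2 - 1) / (ploidy - 1))
}

# index dimension of a state: traits, locations, or 1
index_levels <- function(state) {
  if (!is.null(state$locs)) state$locs
  else if (length(state$traits) > 1) state$traits
  else state$traits
}

# standardized, unit-norm index vector c from user weights
index_coef <- function(state, weights, gamma) {
  lv <- index_levels(state)
  if (is.null(weights)) weights <- rep(1, length(lv))
  if (!is.null(names(weights))) weights <- weights[lv]
  if (length(weights) != length(lv))
    stop("index weights must have length ", length(lv))
  if (all(weights == 0)) stop("index weights are all zero")
  sds <- breeding_sd(state, gamma)
  cvec <- weights / sds
  cvec / sqrt(sum(cvec^2))
}

# per-trait (or per-location) SD of the genetic values entering the index:
# sqrt(sigma2_A + gamma^2 sigma2_D) at the requested gamma
breeding_sd <- function(state, gamma) {
  est <- state$estimates
  spec <- state$spec
  if (spec$model == "none") {
    e <- est$genotype
    if (!is.null(e$sigma2)) return(sqrt(e$sigma2))
    M <- if (!is.null(e$Gamma)) e$Gamma else e$Sigma
    return(sqrt(diag(M)))
  }
  if (!is.null(state$locs)) {
    Gam <- if (!is.null(est$additive$Gamma)) est$additive$Gamma else est$additive$Sigma
    s2d <- if (spec$model == "dominance") est$dominance$sigma2 else est$gresid$sigma2
    sqrt(diag(Gam) + gamma^2 * s2d)
  } else if (length(state$traits) > 1) {
    SA <- est$additive$Sigma
    SD <- if (spec$model == "dominance") est$dominance$Sigma else est$gresid$Sigma
    sqrt(diag(SA) + gamma^2 * diag(SD))
  } else {
    s2a <- est$additive$sigma2
    s2d <- if (spec$model == "dominance") est$dominance$sigma2 else est$gresid$sigma2
    sqrt(s2a + gamma^2 * s2d)
  }
}

# per-individual selector: lambda entries over the stacked u for individual i,
# i.e. indices and coefficients such that theta_i(random) = sum(coef * u[idx])
merit_selector <- function(state, cvec, gamma) {
  blocks <- state$blocks
  off <- state$offsets
  n <- length(state$ids)
  t_add <- nrow(blocks[[1]]$inner)
  sel <- list()
  for (bn in names(blocks)) {
    b <- blocks[[bn]]
    inner_dim <- b$dim / n
    coef <- if (bn == "genotype") cvec
      else if (bn == "additive") cvec
      else if (inner_dim == length(cvec)) gamma * cvec   # nonadd, per trait
      else gamma * sum(cvec)                             # nonadd common across locs
    sel[[bn]] <- list(offset = off[bn], inner = inner_dim, coef = coef)
  }
  sel
}

#' Predict genetic merit with reliability
#'
#' Returns the BLUP of genetic merit for every individual:
#' `theta = ([I gamma*I] (x) c') u + ([W gamma*F] (x) c') delta`, where `c` is
#' the unit-norm index vector formed by dividing the user weights by the
#' breeding-value standard deviations, `u` stacks additive and non-additive
#' values, and `delta` holds the fixed marker and heterosis (inbreeding
#' regression) effects — environment effects are excluded.  The weight
#' `gamma` on non-additive values is 0 for additive value (`"AV"`), 1 for
#' total genotypic value (`"GV"`), and `(ploidy/2 - 1)/(ploidy - 1)` for
#' breeding value (`"BV"`).  The reliability of each prediction is
#' `r2_i = lambda' var(u_hat_i) lambda / lambda' var(u_i) lambda`
#' (squared correlation with the true merit, using the BLUP identity
#' `cov(u, u_hat) = var(u_hat)`).
#'
#' @param state a [blup_prep] result
#' @param index_weights relative (pre-standardization) weights, one per trait
#'   or location; default equal weights
#' @param what `"AV"`, `"BV"`, or `"GV"`
#' @return data frame with columns `id`, `merit`, `value`, `r2`.
#' @export
predict_merit <- function(state, index_weights = NULL,
                          what = c("BV", "AV", "GV")) {
  stopifnot(inherits(state, "blup_state"))
  what <- match.arg(what)
  ploidy <- if (!is.null(state$geno)) state$geno$ploidy else 2
  gamma <- merit_gamma(what, ploidy)
  cvec <- index_coef(state, index_weights, gamma)
  sel <- merit_selector(state, cvec, gamma)
  n <- length(state$ids)

  value <- numeric(n)
  r2 <- numeric(n)
  lv <- index_levels(state)
  # fixed-effect contribution per id and per index level
  fixed_lv <- matrix(0, n, length(lv))
  if (!is.null(state$W_fix) && length(state$xmeta$markers) > 0) {
    for (mk in names(state$xmeta$markers)) {
      cls <- state$xmeta$markers[[mk]]
      d <- state$delta[cls]
      fixed_lv <- fixed_lv + outer(state$W_fix[, mk], rep(1, length(lv))) *
        matrix(d, n, length(lv), byrow = TRUE)
    }
  }
  if (!is.null(state$Fc) && length(state$xmeta$F) > 0) {
    dF <- state$delta[state$xmeta$F]
    fixed_lv <- fixed_lv + gamma * outer(state$Fc, rep(1, length(lv))) *
      matrix(dF, n, length(lv), byrow = TRUE)
  }

  for (i in seq_len(n)) {
    idx <- integer(0); coefs <- numeric(0)
    for (bn in names(sel)) {
      s <- sel[[bn]]
      ix <- s$offset + (i - 1L) * s$inner + seq_len(s$inner)
      idx <- c(idx, ix)
      coefs <- c(coefs, s$coef)
    }
    value[i] <- sum(coefs * state$uhat[idx]) + sum(cvec * fixed_lv[i, ])
    # true-merit variance for individual i
    Vu_i <- matrix(0, length(idx), length(idx))
    pos <- 0
    for (bn in names(sel)) {
      b <- state$blocks[[bn]]
      s <- sel[[bn]]
      ii <- pos + seq_len(s$inner)
      Vu_i[ii, ii] <- b$K[i, i] * b$inner
      pos <- pos + s$inner
    }
    num <- drop(crossprod(coefs, state$var_uhat[idx, idx] %*% coefs))
    den <- drop(crossprod(coefs, Vu_i %*% coefs))
    r2[i] <- if (den <= 0) 0 else min(max(num / den, 0), 1)
  }
  data.frame(id = state$ids, merit = what, value = value, r2 = r2)
}

#' Reliability of marker-assisted vs marker-based selection
#'
#' Selection-index relation between the reliability of marker-based selection
#' (`rB2`, candidates not phenotyped) and marker-assisted selection (`rA2`,
#' candidates phenotyped with heritability `h2`):
#' `rA2 = rB2 + h2 * (1 - rB2)^2 / (1 - h2 * rB2)`.
#'
#' @param h2 heritability of the candidates' own phenotypic information
#' @param rB2 marker-based (training-only) reliability
#' @return `rA2`, the marker-assisted reliability.
#' @export
mas_reliability <- function(h2, rB2) {
  stopifnot(all(h2 >= 0 & h2 <= 1), all(rB2 >= 0 & rB2 <= 1))
  out <- ifelse(1 - h2 * rB2 <= 0, 1,
                rB2 + h2 * (1 - rB2)^2 / (1 - h2 * rB2))
  pmin(out, 1)
}
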