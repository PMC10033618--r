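# Restricted maximum likelihood engine for Gaussian mixed models whose random
# terms are (i) variance components attached to known covariance matrices,
# (ii) Kronecker structures K x Sigma with Sigma unstructured or second-order
# factor-analytic (FA2), and (iii) one term with FIXED, known, unscaled
# covariance (the Stage-1 estimation errors).  All free parameters are
# optimized on an unconstrained scale (log variances; Cholesky factors for
# unstructured; loadings + log specific variances for FA2) by average
# information (AI) iterations with step halving, falling back to a
# derivative-free search when AI steps fail.

#' Variance structures for [reml_fit]
#'
#' Constructors for the covariance structure of one random term.  Each term of
#' the model is a list `list(map, struct)`: `map` is an integer vector of
#' length `n` (observations) giving the effect level of each observation, and
#' `struct` describes the covariance among the `q` effect levels:
#'
#' * `vs_iid(q)` — `sigma2 * I_q` (one free variance)
#' * `vs_diag_groups(groups)` — heterogeneous variances, one per group level
#' * `vs_kernel(K)` — `sigma2 * K` for a known symmetric PSD matrix `K`
#' * `vs_kron_unstr(K, t)` — `K %x% Sigma` with `Sigma` (t x t) unstructured,
#'   parameterized by its Cholesky factor (log-diagonal); effect levels are
#'   ordered inner-dimension-within-kernel-level
#' * `vs_kron_fa2(K, s)` — `K %x% Gamma` with `Gamma = Lambda Lambda' + Psi`,
#'   `Lambda` an s x 2 loading matrix (`Lambda[1,2] = 0` for identifiability)
#'   and `Psi` diagonal; requires `s >= 3` (for `s <= 2` use
#'   `vs_kron_unstr`, which is what the model-building code substitutes)
#'
#' A term with completely known covariance (no free parameter) is passed to
#' [reml_fit] through its `fixed_V` argument and enters V with coefficient
#' exactly 1.
#'
#' @param q,t,s dimensions
#' @param groups factor of length q assigning effect levels to variance groups
#' @param K known covariance matrix
#' @name var_struct
NULL

#' @rdname var_struct
#' @export
vs_iid <- function(q) {
  structure(list(kind = "iid", q = as.integer(q), npar = 1L,
                 is_logvar = TRUE), class = "var_struct")
}

#' @rdname var_struct
#' @export
vs_diag_groups <- function(groups) {
  groups <- as.factor(groups)
  structure(list(kind = "diag_groups", q = length(groups), groups = groups,
                 npar = nlevels(groups),
                 is_logvar = rep(TRUE, nlevels(groups))), class = "var_struct")
}

#' @rdname var_struct
#' @export
vs_kernel <- function(K) {
  K <- as.matrix(K)
  structure(list(kind = "kernel", q = nrow(K), K = K, npar = 1L,
                 is_logvar = TRUE), class = "var_struct")
}

#' @rdname var_struct
#' @export
vs_kron_unstr <- function(K, t) {
  K <- as.matrix(K)
  t <- as.integer(t)
  np <- as.integer(t * (t + 1L) / 2L)
  # parameter order: column-major lower triangle of L; diagonal entries on log scale
  ij <- which(lower.tri(diag(t), diag = TRUE), arr.ind = TRUE)
  structure(list(kind = "kron_unstr", q = nrow(K) * t, K = K, t = t, ij = ij,
                 npar = np, is_logvar = ij[, 1] == ij[, 2]),
            class = "var_struct")
}

#' @rdname var_struct
#' @export
vs_kron_fa2 <- function(K, s) {
  K <- as.matrix(K)
  s <- as.integer(s)
  if (s < 3) stop("FA2 requires >= 3 levels; use vs_kron_unstr for s <= 2")
  np <- (2L * s - 1L) + s
  structure(list(kind = "kron_fa2", q = nrow(K) * s, K = K, t = s, npar = np,
                 is_logvar = c(rep(FALSE, 2L * s - 1L), rep(TRUE, s))),
            class = "var_struct")
}

#' @rdname var_struct
#' @param cells integer cell index per observation (effects are i.i.d. across
#'   cells); `traits` is the trait index per observation.  Used for the
#'   multi-trait model residual: `cov(y_a, y_b) = Sigma[trait_a, trait_b]`
#'   when `a` and `b` share a cell, else 0, with `Sigma` (t x t) unstructured.
#'   The term's `map` must be the identity `1:n`.
#' @param traits integer trait index per observation
#' @export
vs_obs_unstr <- function(cells, traits, t) {
  n <- length(cells)
  stopifnot(length(traits) == n)
  t <- as.integer(t)
  ij <- which(lower.tri(diag(t), diag = TRUE), arr.ind = TRUE)
  structure(list(kind = "obs_unstr", q = n, t = t, ij = ij,
                 traits = as.integer(traits),
                 SC = outer(cells, cells, `==`) * 1.0,
                 npar = as.integer(t * (t + 1L) / 2L),
                 is_logvar = ij[, 1] == ij[, 2]), class = "var_struct")
}

# ---- structure internals ----------------------------------------------------

vs_init <- function(st, vshare) {
  switch(st$kind,
    iid = log(vshare),
    obs_unstr = {
      par <- numeric(st$npar)
      par[st$ij[, 1] == st$ij[, 2]] <- log(sqrt(vshare))
      par
    },
    diag_groups = rep(log(vshare), st$npar),
    kernel = log(vshare / mean(diag(st$K))),
    kron_unstr = {
      t <- st$t
      L <- diag(sqrt(vshare / mean(diag(st$K))), t)
      par <- numeric(st$npar)
      for (r in seq_len(st$npar))
        par[r] <- if (st$ij[r, 1] == st$ij[r, 2]) log(L[st$ij[r, 1], st$ij[r, 1]]) else 0
      par
    },
    kron_fa2 = {
      s <- st$t
      v <- vshare / mean(diag(st$K))
      c(rep(sqrt(v / 2), s),            # Lambda[,1]
        rep(0.01 * sqrt(v), s - 1),     # Lambda[2:s,2]
        rep(log(v / 2), s))             # log Psi
    })
}

# inner t x t covariance (Sigma or Gamma) for kron structures
vs_inner <- function(st, par) {
  switch(st$kind,
    obs_unstr = ,
    kron_unstr = {
      t <- st$t
      L <- matrix(0, t, t)
      for (r in seq_len(st$npar)) {
        i <- st$ij[r, 1]; j <- st$ij[r, 2]
        L[i, j] <- if (i == j) exp(par[r]) else par[r]
      }
      tcrossprod(L)
    },
    kron_fa2 = {
      s <- st$t
      Lam <- matrix(0, s, 2)
      Lam[, 1] <- par[1:s]
      Lam[2:s, 2] <- par[(s + 1):(2 * s - 1)]
      tcrossprod(Lam) + diag(exp(par[(2 * s):(3 * s - 1)]), s)
    },
    stop("not a kron structure"))
}

# full q x q covariance of the effect vector
vs_cov <- function(st, par) {
  switch(st$kind,
    iid = diag(exp(par), st$q),
    diag_groups = diag(exp(par)[as.integer(st$groups)], st$q),
    kernel = exp(par) * st$K,
    obs_unstr = vs_inner(st, par)[st$traits, st$traits] * st$SC,
    kron_unstr = ,
    kron_fa2 = st$K %x% vs_inner(st, par))
}

# list of q x q derivatives of vs_cov wrt each unconstrained parameter
vs_dcov <- function(st, par) {
  switch(st$kind,
    iid = list(diag(exp(par), st$q)),
    diag_groups = lapply(seq_len(st$npar), function(g)
      diag(exp(par[g]) * (as.integer(st$groups) == g), st$q)),
    kernel = list(exp(par) * st$K),
    obs_unstr = {
      t <- st$t
      L <- matrix(0, t, t)
      for (r in seq_len(st$npar)) {
        i <- st$ij[r, 1]; j <- st$ij[r, 2]
        L[i, j] <- if (i == j) exp(par[r]) else par[r]
      }
      lapply(seq_len(st$npar), function(r) {
        i <- st$ij[r, 1]; j <- st$ij[r, 2]
        dL <- matrix(0, t, t)
        dL[i, j] <- if (i == j) exp(par[r]) else 1
        dS <- tcrossprod(dL, L); dS <- dS + t(dS)
        dS[st$traits, st$traits] * st$SC
      })
    },
    kron_unstr = {
      t <- st$t
      L <- matrix(0, t, t)
      for (r in seq_len(st$npar)) {
        i <- st$ij[r, 1]; j <- st$ij[r, 2]
        L[i, j] <- if (i == j) exp(par[r]) else par[r]
      }
      lapply(seq_len(st$npar), function(r) {
        i <- st$ij[r, 1]; j <- st$ij[r, 2]
        dL <- matrix(0, t, t)
        dL[i, j] <- if (i == j) exp(par[r]) else 1
        dS <- tcrossprod(dL, L); dS <- dS + t(dS)
        st$K %x% dS
      })
    },
    kron_fa2 = {
      s <- st$t
      Lam <- matrix(0, s, 2)
      Lam[, 1] <- par[1:s]
      Lam[2:s, 2] <- par[(s + 1):(2 * s - 1)]
      out <- vector("list", st$npar)
      k <- 1L
      for (r in 1:2) {
        rows <- if (r == 1) 1:s else 2:s
        for (i in rows) {
          dG <- matrix(0, s, s)
          dG[i, ] <- dG[i, ] + Lam[, r]
          dG[, i] <- dG[, i] + Lam[, r]
          out[[k]] <- st$K %x% dG
          k <- k + 1L
        }
      }
      for (i in 1:s) {
        dG <- matrix(0, s, s)
        dG[i, i] <- exp(par[2 * s - 1 + i])
        out[[k]] <- st$K %x% dG
        k <- k + 1L
      }
      out
    })
}

# natural-scale report of the estimates
vs_report <- function(st, par) {
  switch(st$kind,
    iid = list(sigma2 = unname(exp(par))),
    diag_groups = list(sigma2 = stats::setNames(exp(par), levels(st$groups))),
    kernel = list(sigma2 = unname(exp(par))),
    obs_unstr = ,
    kron_unstr = list(Sigma = vs_inner(st, par)),
    kron_fa2 = {
      s <- st$t
      Lam <- matrix(0, s, 2)
      Lam[, 1] <- par[1:s]
      Lam[2:s, 2] <- par[(s + 1):(2 * s - 1)]
      list(Gamma = vs_inner(st, par), Lambda = Lam,
           Psi = exp(par[(2 * s):(3 * s - 1)]))
    })
}

#' Control parameters for [reml_fit]
#'
#' @param max.iter maximum AI iterations
#' @param tol relative log-likelihood convergence tolerance
#' @param grad.tol gradient-norm convergence tolerance
#' @param bound.factor variance lower bound as a fraction of var(y)
#' @param fallback.maxit iteration cap for the derivative-free fallback
#' @param verbose print the iteration trace
#' @export
reml_control <- function(max.iter = 100, tol = 1e-7, grad.tol = 1e-3,
                         bound.factor = 1e-8, fallback.maxit = 2000,
                         verbose = FALSE) {
  list(max.iter = max.iter, tol = tol, grad.tol = grad.tol,
       bound.factor = bound.factor, fallback.maxit = fallback.maxit,
       verbose = verbose)
}

#' Restricted maximum likelihood for mixed models with known covariance terms
#'
#' Maximizes the restricted log-likelihood of `y = X delta + sum_r Z_r u_r + e`
#' over the free (co)variance parameters of the random terms.  Each random
#' term is given as `list(map, struct)` where `map[i]` is the effect level of
#' observation `i` and `struct` is a [var_struct].  The residual must be
#' included as one of the terms (e.g. `vs_iid` with `map = 1:n`).  A known,
#' unscaled covariance matrix (`fixed_V`) — the Stage-1 error term of a
#' fully efficient two-stage analysis — enters V with coefficient exactly 1
#' and contributes no free parameters.
#'
#' The restricted log-likelihood includes the `-log|X'V^-1 X|/2` term and the
#' Gaussian constant, so values are comparable across implementations that use
#' the same convention.  `AIC = -2*logLik + 2*k`, where `k` counts only free
#' (co)variance parameters, so the fixed-covariance term adds nothing.
#'
#' @param y numeric response vector
#' @param X fixed-effect design matrix (full column rank)
#' @param random named list of terms `list(map, struct)`
#' @param fixed_V optional known n x n PSD covariance matrix, coefficient 1
#' @param control see [reml_control]
#'
#' @return An object of class `reml_fit` with elements `loglik`, `AIC`, `k`,
#'   `estimates` (natural-scale estimates per term), `par`, `boundary`,
#'   `beta`, `beta.vcov` (GLS fixed effects at the optimum), `converged`,
#'   `iterations`, `method` (`"AI"` or `"fallback"`), and the model inputs.
#' @export
reml_fit <- function(y, X, random, fixed_V = NULL, control = reml_control()) {
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("dimensions of y and X disagree")
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design X is rank deficient")
  p <- ncol(X)
  if (is.null(names(random)) || any(names(random) == ""))
    names(random) <- paste0("term", seq_along(random))
  for (term in random) {
    if (length(term$map) != n) stop("term map length must equal length(y)")
    if (max(term$map) > term$struct$q) stop("map index exceeds structure dimension")
  }
  if (!is.null(fixed_V)) {
    fixed_V <- as.matrix(fixed_V)
    if (!isTRUE(all.equal(dim(fixed_V), c(n, n))))
      stop("fixed_V must be n x n")
    ev <- min(eigen(fixed_V, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-6 * max(1, max(abs(fixed_V))))
      stop("fixed_V (known covariance) is not positive semi-definite")
  }

  vary <- stats::var(y)
  lbound <- log(control$bound.factor * vary)
  nterm <- length(random)
  npar_t <- vapply(random, function(tm) tm$struct$npar, integer(1))
  k <- sum(npar_t)
  pidx <- split(seq_len(k), rep(seq_len(nterm), npar_t))
  is_logvar <- unlist(lapply(random, function(tm) rep_len(tm$struct$is_logvar,
                                                          tm$struct$npar)))

  # kernel/iid/diag terms have obs-level covariance linear in exp(par):
  # precompute the obs-level base matrices once
  base <- vector("list", nterm)
  for (r in seq_len(nterm)) {
    st <- random[[r]]$struct
    map <- random[[r]]$map
    if (st$kind %in% c("iid", "kernel")) {
      M <- if (st$kind == "iid") {
        outer(map, map, `==`) * 1.0
      } else st$K[map, map, drop = FALSE]
      base[[r]] <- M
    }
  }

  build_V <- function(par) {
    V <- if (is.null(fixed_V)) matrix(0, n, n) else fixed_V
    for (r in seq_len(nterm)) {
      st <- random[[r]]$struct
      th <- par[pidx[[r]]]
      if (!is.null(base[[r]])) {
        V <- V + exp(th) * base[[r]]
      } else if (st$kind == "diag_groups") {
        g <- as.integer(st$groups)[random[[r]]$map]
        diag(V) <- diag(V) + exp(th)[g]
      } else {
        C <- vs_cov(st, th)
        V <- V + C[random[[r]]$map, random[[r]]$map, drop = FALSE]
      }
    }
    V
  }

  dV_list <- function(par) {
    out <- vector("list", k)
    for (r in seq_len(nterm)) {
      st <- random[[r]]$struct
      th <- par[pidx[[r]]]
      if (!is.null(base[[r]])) {
        out[[pidx[[r]]]] <- exp(th) * base[[r]]
      } else if (st$kind == "diag_groups") {
        g <- as.integer(st$groups)[random[[r]]$map]
        for (jj in seq_along(pidx[[r]])) {
          d <- numeric(n)
          d[g == jj] <- exp(th[jj])
          out[[pidx[[r]][jj]]] <- diag(d, n)
        }
      } else {
        dC <- vs_dcov(st, th)
        for (jj in seq_along(pidx[[r]]))
          out[[pidx[[r]][jj]]] <-
            dC[[jj]][random[[r]]$map, random[[r]]$map, drop = FALSE]
      }
    }
    out
  }

  # restricted log-likelihood and (optionally) gradient/AI pieces
  eval_ll <- function(par, deriv = FALSE) {
    V <- build_V(par)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(list(ll = -Inf))
    Vi <- chol2inv(R)
    W1 <- Vi %*% X
    XtViX <- crossprod(X, W1)
    cX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cX)) return(list(ll = -Inf))
    P <- Vi - W1 %*% chol2inv(cX) %*% t(W1)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(R))) + 2 * sum(log(diag(cX))) +
                    sum(y * Py) + (n - p) * log(2 * pi))
    if (!deriv) return(list(ll = ll, P = P, Py = Py))
    dV <- dV_list(par)
    grad <- numeric(k)
    Q <- matrix(0, n, k)
    for (i in seq_len(k)) {
      Qi <- dV[[i]] %*% Py
      grad[i] <- -0.5 * (sum(P * dV[[i]]) - sum(Py * Qi))
      Q[, i] <- Qi
    }
    AI <- 0.5 * crossprod(Q, P %*% Q)
    list(ll = ll, grad = grad, AI = AI, P = P, Py = Py)
  }

  # deterministic start: half the phenotypic variance split across terms
  vshare <- 0.5 * vary / nterm
  par <- unlist(lapply(random, function(tm) vs_init(tm$struct, vshare)))
  clamp <- function(par) {
    at <- is_logvar & par < lbound
    par[at] <- lbound
    par
  }
  par <- clamp(par)

  cur <- eval_ll(par, deriv = TRUE)
  if (!is.finite(cur$ll)) stop("restricted likelihood undefined at the starting values")
  ll0 <- cur$ll
  method <- "AI"
  converged <- FALSE
  iter <- 0L
  while (iter < control$max.iter) {
    iter <- iter + 1L
    g <- cur$grad
    atbound <- is_logvar & par <= lbound + 1e-10 & g < 0
    g[atbound] <- 0
    if (max(abs(g)) < control$grad.tol) { converged <- TRUE; break }
    AI <- cur$AI
    # Levenberg-style damping: inflate the AI diagonal until a step that
    # increases the restricted likelihood is found (flat directions, e.g. an
    # FA2 second factor near zero, make the raw AI matrix near-singular)
    ok <- FALSE
    lambda <- 1e-8 * max(diag(AI), 1)
    for (damp in 1:10) {
      delta <- tryCatch(solve(AI + diag(lambda, nrow(AI)), g),
                        error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta))) {
        delta[atbound & delta < 0] <- 0
        step <- 1
        for (h in 1:10) {
          cand <- clamp(par + step * delta)
          new <- eval_ll(cand, deriv = TRUE)
          if (is.finite(new$ll) && new$ll > cur$ll - 1e-10) { ok <- TRUE; break }
          step <- step / 2
        }
      }
      if (ok) break
      lambda <- lambda * 100
    }
    if (!ok) {
      if (max(abs(g)) < 100 * control$grad.tol) { converged <- TRUE; break }
      method <- "fallback"; break
    }
    if (control$verbose)
      message(sprintf("AI iter %d: logLik %.6f (step %.3g)", iter, new$ll, step))
    done <- abs(new$ll - cur$ll) < control$tol * (1 + abs(cur$ll))
    par <- cand
    cur <- new
    if (done && max(abs(cur$grad[!atbound])) < 10 * control$grad.tol) {
      converged <- TRUE; break
    }
  }

  if (method == "fallback" || !converged) {
    negll <- function(pp) {
      v <- eval_ll(clamp(pp))$ll
      if (!is.finite(v)) 1e10 else -v
    }
    opt <- if (k == 1) {
      o <- stats::optimize(negll, interval = c(lbound, log(10 * vary)))
      list(par = o$minimum, value = o$objective)
    } else {
      stats::optim(par, negll, method = "Nelder-Mead",
                   control = list(maxit = control$fallback.maxit,
                                  reltol = 1e-12))
    }
    if (-opt$value > cur$ll + 1e-9) {
      par <- clamp(opt$par)
      cur <- eval_ll(par, deriv = TRUE)
      method <- "fallback"
    }
    converged <- TRUE
  }
  if (cur$ll < ll0 - 1e-8)
    stop("REML failed to improve on the starting values; iteration trace: ",
         sprintf("start %.4f end %.4f", ll0, cur$ll))

  # GLS fixed effects at the optimum
  V <- build_V(par)
  Vi <- chol2inv(chol(V))
  XtViX <- crossprod(X, Vi %*% X)
  bv <- solve(XtViX)
  beta <- drop(bv %*% crossprod(X, Vi %*% y))
  names(beta) <- colnames(X)

  estimates <- lapply(seq_len(nterm), function(r)
    vs_report(random[[r]]$struct, par[pidx[[r]]]))
  names(estimates) <- names(random)
  boundary <- is_logvar & par <= lbound + 1e-10

  structure(list(loglik = cur$ll, AIC = -2 * cur$ll + 2 * k, k = k,
                 estimates = estimates, par = par, pidx = pidx,
                 boundary = boundary, beta = beta, beta.vcov = bv,
                 converged = converged, iterations = iter, method = method,
                 gradient = cur$grad, y = y, X = X, random = random,
                 fixed_V = fixed_V, n = n),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("reml_fit: logLik %.4f, AIC %.2f (k = %d), %s, %d iterations\n",
              x$loglik, x$AIC, x$k, x$method, x$iterations))
  for (nm in names(x$estimates)) {
    est <- x$estimates[[nm]]
    if (!is.null(est$sigma2))
      cat(sprintf("  %s: sigma2 = %s\n", nm,
                  paste(signif(est$sigma2, 4), collapse = ", ")))
    else cat(sprintf("  %s: %s\n", nm,
                     if (!is.null(est$Gamma)) "FA2 covariance" else "unstructured covariance"))
  }
  if (any(x$boundary)) cat("  [B] some variance parameters at the lower bound\n")
  invisible(x)
}

#' AIC difference between two REML fits of the same response
#'
#' @param fit_a,fit_b objects from [reml_fit] on identical `y`
#' @return `AIC(fit_a) - AIC(fit_b)`; negative favors `fit_a`.
#' @export
compare_aic <- function(fit_a, fit_b) {
  if (inherits(fit_a, "stage2_fit")) fit_a <- fit_a$reml
  if (inherits(fit_b, "stage2_fit")) fit_b <- fit_b$reml
  stopifnot(inherits(fit_a, "reml_fit"), inherits(fit_b, "reml_fit"))
  if (!isTRUE(all.equal(fit_a$y, fit_b$y)))
    stop("fits are not on the same response vector")
  fit_a$AIC - fit_b$AIC
}

#' Rotate FA2 loadings and compute uniplot coordinates
#'
#' Applies a varimax-type rotation to the s x 2 loading matrix with the sign
#' convention that each rotated column has non-negative mean, then scales by
#' the genetic standard deviations: location i is plotted at
#' `Lambda[i,]/sqrt(Gamma[i,i])`, so its squared distance from the origin is
#' the proportion of genetic variance explained by the two latent factors
#' (between 0 and 1; 1 when the specific variance `Psi[i]` is zero).
#'
#' @param Lambda s x 2 loading matrix (s >= 3)
#' @param Psi length-s vector of specific variances (>= 0)
#' @return list with `loadings` (rotated), `coord` (s x 2 scaled coordinates),
#'   `radius2` (squared radius per location), and `excluded` (locations with
#'   zero genetic variance, flagged and given NA coordinates).
#' @export
fa2_rotate <- function(Lambda, Psi) {
  Lambda <- as.matrix(Lambda)
  s <- nrow(Lambda)
  if (s < 3) stop("FA2 rotation requires >= 3 locations")
  stopifnot(ncol(Lambda) == 2, length(Psi) == s, all(Psi >= 0))
  rot <- stats::varimax(Lambda, normalize = FALSE)
  L <- Lambda %*% rot$rotmat
  for (j in 1:2) if (mean(L[, j]) < 0) L[, j] <- -L[, j]
  gdiag <- rowSums(L^2) + Psi
  excluded <- gdiag <= 0
  coord <- L / sqrt(ifelse(excluded, NA, gdiag))
  radius2 <- rowSums(L^2) / ifelse(excluded, NA, gdiag)
  rn <- rownames(Lambda)
  if (!is.null(rn)) { rownames(coord) <- rn; names(radius2) <- rn }
  list(loadings = L, coord = coord, radius2 = radius2, excluded = excluded)
}
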