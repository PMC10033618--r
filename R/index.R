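# Multi-trait selection-response machinery: the response covariance matrix B
# (population covariance of the predicted merit components), the response
# ellipsoid x' B^-1 x = i^2, and unrestricted/restricted index optimization.
# The restricted index maximizes c'x over the ellipsoid subject to per-trait
# equality or inequality constraints; because the feasible set is convex and
# the objective linear, enumerating active sets of the (few) trait
# constraints and solving each equality-constrained subproblem in closed form
# yields the exact optimum.

pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Response covariance matrix B
#'
#' The expected multi-trait response to truncation selection on a merit index
#' is `x = i * B c / sd(theta_hat)`, where `B = var_n(b_hat)` is the
#' covariance, over the n individuals of the population, of the predicted
#' genetic-value vectors.  Entry (j,k) is computed as
#' `wmean(diag L) - wmean(L) + wmean(mu_j mu_k) - wmean(mu_j) wmean(mu_k)`
#' with `L = cov([a_hat_j + gamma d_hat_j], [a_hat_k + gamma d_hat_k])` from
#' the BLUP solution, `mu_j` the fixed marker + gamma-scaled heterosis
#' contributions, and weights equal to the number of records per genotype.
#'
#' @param state a [blup_prep] result
#' @param what merit type, as in [predict_merit]; determines `gamma`
#' @return t x t matrix `B` (1 x 1 for a single trait) with attribute
#'   `"sigma_b"` (per-trait genetic standard deviations
#'   `sqrt(sigma2_A + gamma^2 sigma2_D)`).
#' @export
response_matrix <- function(state, what = c("BV", "AV", "GV")) {
  stopifnot(inherits(state, "blup_state"))
  what <- match.arg(what)
  ploidy <- if (!is.null(state$geno)) state$geno$ploidy else 2
  gamma <- merit_gamma(what, ploidy)
  lv <- index_levels(state)
  t <- length(lv)
  n <- length(state$ids)
  w <- state$w_env
  Tn <- sum(w)

  # selector matrix S_j (q_u x n): column i picks a_hat_{i,j} + gamma d_hat_{i,j}
  Smat <- function(j) {
    S <- matrix(0, length(state$uhat), n)
    for (bn in names(state$blocks)) {
      b <- state$blocks[[bn]]
      inner <- b$dim / n
      coef <- if (bn %in% c("genotype", "additive")) 1 else gamma
      inner_ix <- if (inner == t) j else 1L
      S[cbind(state$offsets[bn] + (seq_len(n) - 1L) * inner + inner_ix,
              seq_len(n))] <- coef
    }
    S
  }
  mu_j <- function(j) {
    mu <- numeric(n)
    if (!is.null(state$W_fix) && length(state$xmeta$markers) > 0) {
      for (mk in names(state$xmeta$markers)) {
        cls <- state$xmeta$markers[[mk]]
        cl <- if (length(cls) == 1) cls else cls[j]
        mu <- mu + state$W_fix[, mk] * state$delta[cl]
      }
    }
    if (!is.null(state$Fc) && length(state$xmeta$F) > 0) {
      clF <- if (length(state$xmeta$F) == 1) state$xmeta$F else state$xmeta$F[j]
      mu <- mu + gamma * state$Fc * state$delta[clF]
    }
    mu
  }

  Slist <- lapply(seq_len(t), Smat)
  mulist <- lapply(seq_len(t), mu_j)
  B <- matrix(0, t, t, dimnames = list(lv, lv))
  for (j in seq_len(t)) for (k in j:t) {
    L <- crossprod(Slist[[j]], state$var_uhat %*% Slist[[k]])
    muj <- mulist[[j]]; muk <- mulist[[k]]
    B[j, k] <- B[k, j] <-
      sum(w * diag(L)) / Tn - drop(crossprod(w, L %*% w)) / Tn^2 +
      sum(w * muj * muk) / Tn - (sum(w * muj) / Tn) * (sum(w * muk) / Tn)
  }
  attr(B, "sigma_b") <- stats::setNames(breeding_sd(state, gamma), lv)
  attr(B, "gamma") <- gamma
  B
}

# parse restrictions given as named character vector/list like
# c(maturity = "=0", earliness = "<=0.5")
parse_restrictions <- function(restrictions, traits) {
  if (is.null(restrictions) || length(restrictions) == 0) return(NULL)
  out <- list()
  for (nm in names(restrictions)) {
    if (!nm %in% traits) stop("restricted trait not in the index: ", nm)
    spec <- gsub(" ", "", as.character(restrictions[[nm]]))
    m <- regmatches(spec, regexec("^(<=|>=|=)(-?[0-9.]+)$", spec))[[1]]
    if (length(m) == 0) stop("cannot parse restriction '", spec, "' for ", nm)
    out[[nm]] <- list(trait = match(nm, traits), type = m[2],
                      value = as.numeric(m[3]))
  }
  out
}

# maximize c'x subject to E'x = v and x' Binv x <= i2 (closed form).
# x0 is the minimum-quadratic-norm point satisfying the equalities; the
# remainder is a linear objective over an ellipsoid in the null space of E'.
solve_eq_qcqp <- function(B, Binv, cvec, E, v, i2) {
  t <- length(cvec)
  if (is.null(E) || ncol(E) == 0) {
    Bc <- B %*% cvec
    den <- drop(crossprod(cvec, Bc))
    if (den <= 0) return(list(x = rep(0, t), feasible = TRUE))
    return(list(x = drop(sqrt(i2) * Bc / sqrt(den)), feasible = TRUE))
  }
  EBE <- crossprod(E, B %*% E)
  sol_v <- tryCatch(solve(EBE, v), error = function(e) NULL)
  if (is.null(sol_v)) return(list(feasible = FALSE))
  x0 <- drop(B %*% E %*% sol_v)
  r2 <- i2 - drop(crossprod(v, sol_v))
  if (r2 < -1e-10) return(list(feasible = FALSE))
  r2 <- max(r2, 0)
  qq <- qr(E)
  Qfull <- qr.Q(qq, complete = TRUE)
  if (ncol(E) >= t) return(list(x = x0, feasible = TRUE))
  N <- Qfull[, (qq$rank + 1):t, drop = FALSE]
  M <- crossprod(N, Binv %*% N)
  a <- drop(crossprod(N, cvec))
  if (sqrt(sum(a^2)) < 1e-14 || r2 == 0) return(list(x = x0, feasible = TRUE))
  Ma <- solve(M, a)
  z <- sqrt(r2) * Ma / sqrt(drop(crossprod(a, Ma)))
  list(x = x0 + drop(N %*% z), feasible = TRUE)
}

#' Optimal (possibly restricted) selection response and index coefficients
#'
#' Maximizes the merit gain `c'x` over the response ellipsoid
#' `x' B^-1 x <= i^2`, optionally subject to equality or inequality
#' constraints on the response of designated traits (restricted selection
#' index); restricted traits are excluded from the objective.  The exact
#' optimum is found by enumerating active sets of the trait constraints and
#' solving each equality-constrained subproblem in closed form (the optimum
#' of a linear objective over this convex set lies on the ellipsoid
#' boundary).  Index coefficients are recovered from the intensity-1 solution
#' as `c = B^-1 x`, rescaled to unit norm.
#'
#' @param B response matrix from [response_matrix] (or any symmetric PSD
#'   matrix); if it carries a `"sigma_b"` attribute the responses and the
#'   coefficients are also reported in units of genetic standard deviation
#' @param merit_weights relative weights of the traits in the merit
#'   (standardized internally when `sigma_b` is available); weights of
#'   restricted traits are ignored
#' @param restrictions named character vector, e.g.
#'   `c(maturity = "=0", height = "<=0.5")`; values are in genetic-SD units
#'   when `sigma_b` is available, otherwise on the trait scale
#' @param intensity selection intensity i
#' @param sigma_b optional per-trait genetic SDs (overrides the attribute)
#'
#' @return An object of class `gain_result`: `response` (trait scale),
#'   `response_std` (genetic-SD units, when SDs are known), `coefficients`
#'   (unit-norm index coefficients for standardized traits), `merit_gain`,
#'   and `restrictions`.
#' @export
gain <- function(B, merit_weights = NULL, restrictions = NULL, intensity = 1,
                 sigma_b = NULL) {
  B <- as.matrix(B)
  t <- nrow(B)
  traits <- rownames(B)
  if (is.null(traits)) traits <- rownames(B) <- colnames(B) <- paste0("trait", 1:t)
  if (is.null(sigma_b)) sigma_b <- attr(B, "sigma_b")
  if (is.null(merit_weights)) merit_weights <- rep(1, t)
  if (!is.null(names(merit_weights))) merit_weights <- merit_weights[traits]
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  degenerate <- min(ev) < 1e-10 * max(abs(ev))
  Binv <- if (degenerate) pinv(B) else chol2inv(chol(B))
  if (degenerate)
    message(sprintf("B is singular (rank %d of %d); using the pseudo-inverse",
                    sum(ev > 1e-10 * max(abs(ev))), t))

  res <- parse_restrictions(restrictions, traits)
  # merit vector: standardized weights, restricted traits excluded
  wts <- merit_weights
  if (!is.null(res)) wts[vapply(res, `[[`, 1, "trait")] <- 0
  if (all(wts == 0)) stop("no unrestricted trait with nonzero weight")
  cvec <- if (!is.null(sigma_b)) wts / sigma_b else wts
  cvec <- cvec / sqrt(sum(cvec^2))

  to_raw <- function(j, v) if (!is.null(sigma_b)) v * sigma_b[j] else v
  solve_at <- function(i2) {
    eqs <- Filter(function(r) r$type == "=", res)
    ineqs <- Filter(function(r) r$type != "=", res)
    best <- NULL
    n_in <- length(ineqs)
    for (code in seq_len(2^n_in) - 1L) {
      active <- if (n_in > 0) as.logical(bitwAnd(code, 2^(seq_len(n_in) - 1))) else logical(0)
      act <- c(eqs, ineqs[active])
      E <- NULL; v <- numeric(0)
      if (length(act) > 0) {
        E <- matrix(0, t, length(act))
        for (k in seq_along(act)) {
          E[act[[k]]$trait, k] <- 1
          v[k] <- to_raw(act[[k]]$trait, act[[k]]$value)
        }
      }
      cand <- solve_eq_qcqp(B, Binv, cvec, E, v, i2)
      if (!cand$feasible) next
      ok <- TRUE
      for (r in ineqs) {
        xr <- cand$x[r$trait]; vr <- to_raw(r$trait, r$value)
        if (r$type == "<=" && xr > vr + 1e-8) ok <- FALSE
        if (r$type == ">=" && xr < vr - 1e-8) ok <- FALSE
      }
      if (!ok) next
      obj <- sum(cvec * cand$x)
      if (is.null(best) || obj > best$obj) best <- list(x = cand$x, obj = obj)
    }
    if (is.null(best))
      stop("restricted index is infeasible; binding constraints: ",
           paste(names(res), collapse = ", "))
    best
  }

  opt <- solve_at(intensity^2)
  opt1 <- if (intensity == 1) opt else solve_at(1)
  craw <- drop(Binv %*% opt1$x)
  cidx <- if (!is.null(sigma_b)) craw * sigma_b else craw  # standardized traits
  cidx <- cidx / sqrt(sum(cidx^2))
  x <- stats::setNames(opt$x, traits)
  structure(list(response = x,
                 response_std = if (!is.null(sigma_b)) x / sigma_b else NULL,
                 coefficients = stats::setNames(cidx, traits),
                 merit_gain = opt$obj, restrictions = res,
                 intensity = intensity, degenerate = degenerate,
                 B = B, sigma_b = sigma_b),
            class = "gain_result")
}

#' @export
print.gain_result <- function(x, ...) {
  cat(sprintf("gain_result (intensity %g%s):\n", x$intensity,
              if (length(x$restrictions)) ", restricted" else ""))
  tab <- data.frame(coefficients = round(x$coefficients, 3),
                    response = round(x$response, 3))
  if (!is.null(x$response_std)) tab$response_std <- round(x$response_std, 3)
  print(tab)
  cat(sprintf("merit gain: %.4f\n", x$merit_gain))
  invisible(x)
}

#' 2D slice of the selection-response ellipsoid
#'
#' The set of attainable responses at intensity i is the ellipsoid
#' `x' B^-1 x = i^2`.  This returns the 2D slice through the plane of two
#' selected traits, with the non-displayed responses held at the values in
#' `at` (e.g. the optimal response from [gain]; 0 by default).  With
#' `sigma_b`, the slice is computed in genetic-SD units, i.e. for the matrix
#' `Delta B^-1 Delta`; the principal axes are the eigenvectors of the
#' quadratic-form matrix and the semi-axis lengths are the inverse
#' square-roots of its eigenvalues (scaled by the slice radius).
#'
#' @param B response matrix
#' @param traits length-2 vector (names or indices) of the traits to display
#' @param intensity selection intensity i
#' @param sigma_b optional per-trait genetic SDs (standardized-response mode)
#' @param at optional full response vector fixing the non-displayed traits
#' @return list with `center`, `axes` (columns = principal directions),
#'   `semi_axes`, `boundary` (200 x 2 points on the slice), and `degenerate`.
#' @export
ellipse_slice <- function(B, traits = c(1, 2), intensity = 1, sigma_b = NULL,
                          at = NULL) {
  B <- as.matrix(B)
  t <- nrow(B)
  if (t < 2) stop("ellipse_slice requires >= 2 traits")
  if (is.null(sigma_b)) sigma_b <- attr(B, "sigma_b")
  tn <- rownames(B)
  if (is.null(tn)) tn <- paste0("trait", 1:t)
  pr <- if (is.character(traits)) match(traits, tn) else as.integer(traits)
  stopifnot(length(pr) == 2, !anyNA(pr))
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  degenerate <- min(ev) < 1e-10 * max(abs(ev))
  A <- if (degenerate) pinv(B) else chol2inv(chol(B))
  if (!is.null(sigma_b)) A <- diag(sigma_b) %*% A %*% diag(sigma_b)
  oth <- setdiff(seq_len(t), pr)
  xo <- if (is.null(at)) rep(0, length(oth)) else at[oth]
  App <- A[pr, pr, drop = FALSE]
  r2 <- intensity^2
  center <- c(0, 0)
  if (length(oth) > 0) {
    Apo <- A[pr, oth, drop = FALSE]
    Aoo <- A[oth, oth, drop = FALSE]
    center <- drop(-solve(App, Apo %*% xo))
    r2 <- intensity^2 - drop(crossprod(xo, (Aoo - crossprod(Apo, solve(App, Apo))) %*% xo))
  }
  if (r2 < 0) stop("the requested slice does not intersect the ellipsoid")
  eg <- eigen(App, symmetric = TRUE)
  semi <- sqrt(r2 / eg$values)
  th <- seq(0, 2 * pi, length.out = 200)
  boundary <- t(center + eg$vectors %*% rbind(semi[1] * cos(th), semi[2] * sin(th)))
  colnames(boundary) <- tn[pr]
  list(center = stats::setNames(center, tn[pr]), axes = eg$vectors,
       semi_axes = semi, boundary = boundary, r2 = r2,
       degenerate = degenerate)
}
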