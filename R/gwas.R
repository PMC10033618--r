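# Two-stage GWAS by backsolving marker effects from the genomic predictions:
# additive substitution effects from a_hat through W'G^-1, digenic dominance
# effects from d_hat (including the fixed heterosis part) through Q'D^-1,
# with standard errors from var(a_hat) and a multiple-testing threshold based
# on the effective number of markers.

#' Backsolve marker effects from genomic predictions
#'
#' Additive (substitution) effects on the index scale are
#' `alpha_hat = (W' G^-1 (x) c') a_hat / (ploidy * sum(p q))`, and digenic
#' dominance effects are
#' `beta_hat = (Q' D^-1 (x) c') d_hat / (choose(ploidy,2) * sum(4 p^2 q^2))`,
#' where `d_hat` includes the fitted heterosis term `-b*F` so directional
#' dominance is represented in the marker effects.  For a single trait
#' `c = 1` and `W alpha_hat` reconstructs `a_hat` exactly (the GBLUP /
#' ridge-regression-BLUP identity).  If `G` (or `D`) is ill-conditioned a
#' ridge of `1e-6 * mean(diag)` is added before inversion (backsolve only).
#'
#' @param state a [blup_prep] result from a marker-based Stage-2 model
#' @param index_weights per-trait index weights as in [predict_merit];
#'   effects are standardized with the additive SDs (`gamma = 0`)
#' @return data frame of class `gwas_table`: `marker`, `chrom`, `position`,
#'   `add_effect`, and (dominance model) `dom_effect`; markers with zero
#'   dosage variance are excluded.
#' @export
marker_effects <- function(state, index_weights = NULL) {
  stopifnot(inherits(state, "blup_state"))
  if (is.null(state$geno) || state$spec$model == "none")
    stop("marker effects require a marker-based Stage-2 model")
  geno <- state$geno
  ms <- geno$ms
  ids <- state$ids
  n <- length(ids)
  t <- length(index_levels(state))
  cvec <- index_coef(state, index_weights, gamma = 0)

  poly <- apply(ms$dosage[ids, , drop = FALSE], 2, stats::var) > 0
  W <- dosage_W(ms)[ids, poly, drop = FALSE]
  p <- ms$p[poly]
  denomA <- ms$ploidy * sum(ms$p * (1 - ms$p))

  # index-combined additive predictions (n x 1)
  off <- state$offsets["additive"]
  inner <- state$blocks$additive$dim / n
  Ahat <- matrix(state$uhat[off + seq_len(state$blocks$additive$dim)],
                 nrow = n, byrow = TRUE)
  ac <- if (inner == t) drop(Ahat %*% cvec) else drop(Ahat) * sum(cvec)
  Ginv <- ridge_inv(state$blocks$additive$K, "G")
  add_effect <- drop(crossprod(W, Ginv %*% ac)) / denomA

  out <- data.frame(marker = colnames(W), add_effect = add_effect,
                    row.names = NULL)
  if (state$spec$model == "dominance") {
    Q <- geno$Q[ids, poly, drop = FALSE]
    off_d <- state$offsets["nonadd"]
    inner_d <- state$blocks$nonadd$dim / n
    Dhat <- matrix(state$uhat[off_d + seq_len(state$blocks$nonadd$dim)],
                   nrow = n, byrow = TRUE)
    dc <- if (inner_d == t) drop(Dhat %*% cvec) else drop(Dhat) * sum(cvec)
    # the fixed heterosis term -b*F is part of the dominance value (index scale)
    dF <- if (length(state$xmeta$F) > 0) unname(state$delta[state$xmeta$F]) else
      numeric(0)
    if (length(dF) == t) dc <- dc + state$Fc * sum(cvec * dF)
    else if (length(dF) == 1) dc <- dc + state$Fc * dF[1] * sum(cvec)
    Dinv <- ridge_inv(state$blocks$nonadd$K, "D")
    out$dom_effect <- drop(crossprod(Q, Dinv %*% dc)) / geno$denomD
  }
  if (!is.null(ms$map)) {
    mi <- match(out$marker, ms$map$marker)
    out$chrom <- ms$map$chrom[mi]
    out$position <- ms$map$position[mi]
    out <- out[, c("marker", "chrom", "position",
                   setdiff(names(out), c("marker", "chrom", "position")))]
  }
  attr(out, "cvec") <- cvec
  attr(out, "poly") <- poly
  class(out) <- c("gwas_table", "data.frame")
  out
}

# Centered-dosage G satisfies G1 = 0, so it is singular by construction; the
# backsolve uses the Moore-Penrose inverse, under which W alpha_hat
# reconstructs a_hat exactly (a_hat lies in the range of G).
ridge_inv <- function(K, label) {
  kap <- tryCatch(kappa(K, exact = FALSE), error = function(e) Inf)
  if (is.finite(kap) && kap < 1e10)
    return(chol2inv(chol(K)))
  pinv(K)
}

#' GWAS scores and discovery threshold
#'
#' Standard errors of the backsolved additive effects are
#' `SE_k = sqrt((w_k' G^-1 (x) c') var(a_hat) (G^-1 w_k (x) c)) / (ploidy * sum(p q))`
#' (dominance analog via Q and D).  The standardized effects are treated as
#' asymptotically standard normal, giving two-sided p-values and the score
#' `-log10(p)`.  The discovery threshold divides the genome-wide significance
#' level by the effective number of markers (see [effective_nmarkers]).
#'
#' @param effects a `gwas_table` from [marker_effects]
#' @param state the same [blup_prep] result
#' @param level genome-wide significance level (default 0.05)
#' @param meff_method method for the effective number of markers
#' @return the `gwas_table` with columns `add_se`, `score` (additive
#'   `-log10 p`; NA with a flag where SE = 0), `significant`, and (dominance)
#'   `dom_se`, `dom_score`; attributes `threshold` and `m_eff`.
#' @export
gwas_scores <- function(effects, state, level = 0.05,
                        meff_method = c("ms", "liji")) {
  stopifnot(inherits(effects, "gwas_table"), inherits(state, "blup_state"))
  meff_method <- match.arg(meff_method)
  geno <- state$geno
  ms <- geno$ms
  ids <- state$ids
  n <- length(ids)
  t <- length(index_levels(state))
  cvec <- attr(effects, "cvec")
  poly <- attr(effects, "poly")
  W <- dosage_W(ms)[ids, poly, drop = FALSE]
  denomA <- ms$ploidy * sum(ms$p * (1 - ms$p))

  # contract var(a_hat) with the index: M[i1,i2] = c' var(a_hat)_{i1,i2} c
  off <- state$offsets["additive"]
  ia <- off + seq_len(state$blocks$additive$dim)
  inner <- state$blocks$additive$dim / n
  M <- contract_index(state$var_uhat[ia, ia], n, inner, cvec)
  Ginv <- ridge_inv(state$blocks$additive$K, "G")
  Tm <- Ginv %*% W                        # n x m of G^-1 w_k
  se_add <- sqrt(pmax(colSums((M %*% Tm) * Tm), 0)) / denomA
  effects$add_se <- se_add
  z <- ifelse(se_add > 0, effects$add_effect / se_add, NA)
  effects$score <- -log10(2 * stats::pnorm(-abs(z)))
  effects$se_zero <- se_add <= 0

  if (!is.null(effects$dom_effect)) {
    Q <- geno$Q[ids, poly, drop = FALSE]
    io <- state$offsets["nonadd"] + seq_len(state$blocks$nonadd$dim)
    inner_d <- state$blocks$nonadd$dim / n
    Md <- contract_index(state$var_uhat[io, io], n, inner_d, cvec)
    Dinv <- ridge_inv(state$blocks$nonadd$K, "D")
    Td <- Dinv %*% Q
    se_dom <- sqrt(pmax(colSums((Md %*% Td) * Td), 0)) / geno$denomD
    effects$dom_se <- se_dom
    zd <- ifelse(se_dom > 0, effects$dom_effect / se_dom, NA)
    effects$dom_score <- -log10(2 * stats::pnorm(-abs(zd)))
  }

  meff <- effective_nmarkers(ms, ids = ids, method = meff_method)
  thr <- -log10(level / meff)
  effects$significant <- !is.na(effects$score) & effects$score >= thr
  attr(effects, "threshold") <- thr
  attr(effects, "m_eff") <- meff
  attr(effects, "level") <- level
  effects
}

# c' var_block c contraction: var over (id x inner) effects -> n x n
contract_index <- function(Vblk, n, inner, cvec) {
  if (inner == 1) return(Vblk * sum(cvec)^2)
  Cm <- matrix(0, n * inner, n)
  Cm[cbind(seq_len(n * inner), rep(seq_len(n), each = inner))] <-
    rep(cvec, n)
  crossprod(Cm, Vblk %*% Cm)
}

#' Effective number of independent markers
#'
#' Computed per chromosome and summed.  The default (`"ms"`) is the
#' sequential correlation-based count: markers are taken in map order and
#' marker j contributes `sqrt(1 - max_{k<j} r^2_jk)`, so a marker perfectly
#' correlated with an earlier one adds 0 and an independent marker adds 1.
#' The `"liji"` alternative uses the eigenvalues `lambda` of the marker
#' correlation matrix: each eigenvalue contributes
#' `I(lambda >= 1) + (lambda - floor(lambda))`.
#'
#' @param ms a [marker_set]
#' @param ids optional subset of individuals on which to compute correlations
#' @param method `"ms"` (sequential max-correlation) or `"liji"` (eigenvalue)
#' @return effective number of markers (scalar).
#' @export
effective_nmarkers <- function(ms, ids = NULL, method = c("ms", "liji")) {
  method <- match.arg(method)
  stopifnot(inherits(ms, "marker_set"))
  X <- ms$dosage
  if (!is.null(ids)) X <- X[ids, , drop = FALSE]
  keep <- apply(X, 2, stats::var) > 0
  X <- X[, keep, drop = FALSE]
  chrom <- if (!is.null(ms$map)) as.character(ms$map$chrom[keep]) else
    rep("chr1", ncol(X))
  pos <- if (!is.null(ms$map)) ms$map$position[keep] else seq_len(ncol(X))
  total <- 0
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    sel <- sel[order(pos[sel])]
    mc <- length(sel)
    if (mc == 1) { total <- total + 1; next }
    R2 <- stats::cor(X[, sel, drop = FALSE])^2
    if (method == "ms") {
      kap <- 1
      for (j in 2:mc)
        kap <- kap + sqrt(max(0, 1 - max(R2[j, 1:(j - 1)])))
      total <- total + kap
    } else {
      lam <- eigen(stats::cov2cor(stats::cov(X[, sel, drop = FALSE])),
                   symmetric = TRUE, only.values = TRUE)$values
      lam <- pmax(lam, 0)
      total <- total + sum((lam >= 1) + (lam - floor(lam)))
    }
  }
  total
}
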