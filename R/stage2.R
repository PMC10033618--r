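# Stage 2 of the two-stage analysis: the genomic mixed model on the Stage-1
# BLUEs, with the Stage-1 error covariance carried as a random effect with
# known covariance ("fully efficient" weighting), additive/non-additive
# decomposition with optional directional dominance, fixed-effect marker
# covariates, multi-location (FA2) and multi-trait (unstructured) variants,
# and Legarra-style proportion-of-variance accounting.

#' Prepare marker-derived inputs for Stage 2
#'
#' Bundles the marker panel with its additive (G) and dominance (D)
#' relationship matrices, dominance coefficients Q, genomic inbreeding F, and
#' (optionally) the pedigree relationship matrix A for H-blending.
#'
#' @param ms a [marker_set]
#' @param pedigree optional `pedigree` (see [read_pedigree]); individuals of
#'   `ms` must appear in it
#' @return An object of class `geno_data`.
#' @export
geno_data <- function(ms, pedigree = NULL) {
  stopifnot(inherits(ms, "marker_set"))
  G <- compute_G(ms)
  dom <- compute_dominance(ms)
  A <- NULL
  if (!is.null(pedigree)) {
    A <- pedigree_A(pedigree, ploidy = if (ms$ploidy %in% c(2, 4)) ms$ploidy else 2)
    if (!all(ms$ids %in% A$ids))
      stop("some genotyped individuals are missing from the pedigree")
  }
  structure(list(ms = ms, G = G, D = dom$D, Q = dom$coeff$Q, F = dom$coeff$F,
                 denomD = dom$coeff$denomD, denomF = dom$coeff$denomF,
                 A = A, ploidy = ms$ploidy),
            class = "geno_data")
}

#' Stage-2 model specification
#'
#' @param geno optional [geno_data]; required for the marker-based models
#' @param model `"none"` (i.i.d. genotype effects), `"genetic_residual"`
#'   (additive + i.i.d. non-additive), or `"dominance"` (additive +
#'   directional digenic dominance with the genomic inbreeding covariate)
#' @param fixed_markers marker ids to include as fixed-effect covariates
#'   (one regression coefficient per location/trait)
#' @param multi `"none"`, `"loc"` (FA2 additive covariance between locations,
#'   non-additive correlation fixed at 1, heterogeneous GxE variance per
#'   location), or `"trait"` (unstructured covariances)
#' @param omega H-matrix blend weight on the pedigree A (0 = pure G)
#' @param drop_fixed_markers if TRUE, remove the fixed-effect markers from the
#'   G/D/F construction (default keeps them in)
#' @return An object of class `stage2_spec`.
#' @export
stage2_spec <- function(geno = NULL,
                        model = c("none", "genetic_residual", "dominance"),
                        fixed_markers = character(0),
                        multi = c("none", "loc", "trait"),
                        omega = 0, drop_fixed_markers = FALSE) {
  model <- match.arg(model)
  multi <- match.arg(multi)
  if (model != "none" && is.null(geno))
    stop("marker-based models require geno_data")
  if (!is.null(geno)) stopifnot(inherits(geno, "geno_data"))
  if (length(fixed_markers) > 0) {
    if (is.null(geno)) stop("fixed_markers require geno_data")
    missing_m <- setdiff(fixed_markers, geno$ms$marker_ids)
    if (length(missing_m) > 0)
      stop("fixed markers not in the marker set: ",
           paste(missing_m, collapse = ", "))
  }
  if (omega < 0 || omega > 1) stop("omega must be in [0, 1]")
  if (omega > 0 && (is.null(geno) || is.null(geno$A)))
    stop("omega > 0 requires geno_data with a pedigree A matrix")
  structure(list(geno = geno, model = model, fixed_markers = fixed_markers,
                 multi = multi, omega = omega,
                 drop_fixed_markers = drop_fixed_markers),
            class = "stage2_spec")
}

# build the observation table, fixed design, random terms and S matrix
stage2_build <- function(s1, spec, include_s_term) {
  stopifnot(inherits(s1, "stage1_fit"), inherits(spec, "stage2_spec"))
  blues <- s1$blues
  blues$id <- as.character(blues$id)
  envs <- unique(as.character(blues$env))
  if (length(envs) < 2) stop("Stage 2 requires >= 2 environments")
  traits <- s1$traits
  t <- length(traits)
  if (spec$multi != "trait" && t > 1)
    stop("multiple Stage-1 traits require multi = 'trait'")
  if (spec$multi == "loc" && is.null(s1$env_loc))
    stop("multi = 'loc' requires a loc column in Stage 1")

  geno <- spec$geno
  if (!is.null(geno) && spec$drop_fixed_markers &&
      length(spec$fixed_markers) > 0) {
    keep <- setdiff(geno$ms$marker_ids, spec$fixed_markers)
    ms2 <- marker_set(geno$ms$dosage[, keep, drop = FALSE], geno$ms$ploidy,
                      map = if (!is.null(geno$ms$map))
                        geno$ms$map[geno$ms$map$marker %in% keep, ])
    geno <- geno_data(ms2, pedigree = NULL)
    geno$A <- spec$geno$A
    geno$ms <- spec$geno$ms   # keep full panel for the fixed covariates
  }

  ids <- unique(blues$id)
  if (!is.null(geno)) {
    dropped <- setdiff(ids, geno$ms$ids)
    if (length(dropped) > 0) {
      warning(sprintf("%d phenotyped ids without marker data dropped from Stage 2",
                      length(dropped)))
      ids <- intersect(ids, geno$ms$ids)
    }
  }
  obs <- blues[blues$id %in% ids, , drop = FALSE]
  obs$loc <- if (!is.null(s1$env_loc)) unname(s1$env_loc[as.character(obs$env)])
             else NA_character_
  n_obs <- nrow(obs)
  id_idx <- match(obs$id, ids)
  tr_idx <- match(obs$trait, traits)
  n <- length(ids)

  locs <- NULL
  if (spec$multi == "loc") {
    locs <- unique(obs$loc)
    if (length(locs) < 2) stop("multi = 'loc' requires >= 2 locations")
  }
  s <- length(locs)

  # additive kernel (G, or H-blend) and dominance kernel, aligned to ids
  K_add <- K_dom <- Fvec <- NULL
  if (!is.null(geno) && spec$model != "none") {
    K <- if (spec$omega > 0) blend_H(geno$G, geno$A, spec$omega) else geno$G
    K_add <- K$values[ids, ids]
    if (spec$model == "dominance") {
      K_dom <- geno$D$values[ids, ids]
      Fvec <- geno$F[ids]
    }
  }

  # fixed-effect design
  env_f <- factor(obs$env, levels = envs)
  if (spec$multi == "trait" && t > 1) {
    tr_f <- factor(obs$trait, levels = traits)
    X <- stats::model.matrix(~ 0 + env_f:tr_f)
    colnames(X) <- sub("env_f", "env", sub("tr_f", "trait", colnames(X)))
  } else {
    X <- stats::model.matrix(~ 0 + env_f)
    colnames(X) <- sub("env_f", "env", colnames(X))
  }
  xmeta <- list(env = colnames(X), F = character(0), markers = list())

  rep_dim <- switch(spec$multi, none = "1", loc = "loc", trait = "trait")
  rep_levels <- switch(spec$multi, none = "1", loc = locs, trait = traits)
  rep_idx <- switch(spec$multi, none = rep(1L, n_obs),
                    loc = match(obs$loc, locs), trait = tr_idx)

  Fc <- NULL
  if (spec$model == "dominance") {
    Fc <- Fvec - mean(Fvec)          # centered covariate; intercepts absorb the mean
    Xf <- matrix(0, n_obs, length(rep_levels))
    for (l in seq_along(rep_levels)) {
      sel <- rep_idx == l
      Xf[sel, l] <- Fc[id_idx[sel]]
    }
    colnames(Xf) <- if (length(rep_levels) == 1) "F" else
      paste0("F:", rep_levels)
    xmeta$F <- colnames(Xf)
    X <- cbind(X, Xf)
  }
  W_fix <- NULL
  if (length(spec$fixed_markers) > 0) {
    Wall <- dosage_W(spec$geno$ms)
    W_fix <- Wall[ids, spec$fixed_markers, drop = FALSE]
    for (mk in spec$fixed_markers) {
      Xm <- matrix(0, n_obs, length(rep_levels))
      for (l in seq_along(rep_levels)) {
        sel <- rep_idx == l
        Xm[sel, l] <- W_fix[id_idx[sel], mk]
      }
      colnames(Xm) <- if (length(rep_levels) == 1) mk else
        paste0(mk, ":", rep_levels)
      xmeta$markers[[mk]] <- colnames(Xm)
      X <- cbind(X, Xm)
    }
  }

  # random terms
  terms <- list()
  if (spec$model == "none") {
    if (spec$multi == "loc") {
      loc_idx <- match(obs$loc, locs)
      gmap <- (id_idx - 1L) * s + loc_idx
      terms$genotype <- list(map = gmap,
                             struct = if (s >= 3) vs_kron_fa2(diag(n), s)
                                      else vs_kron_unstr(diag(n), s))
    } else if (spec$multi == "trait") {
      gmap <- (id_idx - 1L) * t + tr_idx
      terms$genotype <- list(map = gmap, struct = vs_kron_unstr(diag(n), t))
    } else {
      terms$genotype <- list(map = id_idx, struct = vs_iid(n))
    }
  } else {
    if (spec$multi == "loc") {
      loc_idx <- match(obs$loc, locs)
      amap <- (id_idx - 1L) * s + loc_idx
      terms$additive <- list(map = amap,
                             struct = if (s >= 3) vs_kron_fa2(K_add, s)
                                      else vs_kron_unstr(K_add, s))
    } else if (spec$multi == "trait") {
      amap <- (id_idx - 1L) * t + tr_idx
      terms$additive <- list(map = amap, struct = vs_kron_unstr(K_add, t))
    } else {
      terms$additive <- list(map = id_idx, struct = vs_kernel(K_add))
    }
    if (spec$model == "dominance") {
      if (spec$multi == "trait") {
        dmap <- (id_idx - 1L) * t + tr_idx
        terms$dominance <- list(map = dmap, struct = vs_kron_unstr(K_dom, t))
      } else {
        # correlation fixed at 1 across locations: one value per genotype
        terms$dominance <- list(map = id_idx, struct = vs_kernel(K_dom))
      }
    } else {
      if (spec$multi == "trait") {
        dmap <- (id_idx - 1L) * t + tr_idx
        terms$gresid <- list(map = dmap, struct = vs_kron_unstr(diag(n), t))
      } else {
        terms$gresid <- list(map = id_idx, struct = vs_iid(n))
      }
    }
  }
  if (spec$multi == "loc") {
    terms$gxe <- list(map = seq_len(n_obs),
                      struct = vs_diag_groups(factor(obs$loc, levels = locs)))
  } else if (spec$multi == "trait") {
    cell <- as.integer(factor(paste(obs$id, obs$env)))
    terms$gxe <- list(map = seq_len(n_obs),
                      struct = vs_obs_unstr(cell, tr_idx, t))
  } else {
    terms$gxe <- list(map = seq_len(n_obs), struct = vs_iid(n_obs))
  }

  # Stage-1 error covariance: direct sum of the per-env blocks
  S <- NULL
  if (include_s_term) {
    S <- matrix(0, n_obs, n_obs)
    key <- if (t == 1) obs$id else paste(obs$id, obs$trait, sep = ":")
    for (e in envs) {
      sel <- which(obs$env == e)
      V <- s1$vcov[[e]]
      S[sel, sel] <- V[key[sel], key[sel]]
    }
  }

  list(obs = obs, y = obs$value, X = X, xmeta = xmeta, terms = terms, S = S,
       ids = ids, traits = traits, locs = locs, id_idx = id_idx,
       tr_idx = tr_idx, K_add = K_add, K_dom = K_dom, F_raw = Fvec, Fc = Fc,
       W_fix = W_fix, geno = geno, spec = spec)
}

#' Stage 2: genomic mixed model on the Stage-1 BLUEs
#'
#' Fits `BLUE[g_ij] = E_j + (genetic) + gE_ij + s_ij` by REML, where the
#' genetic part is an i.i.d. genotype effect, additive + i.i.d. non-additive
#' values, or additive + directional dominance (with the genomic inbreeding
#' coefficient F as a fixed covariate whose negated coefficient is the
#' heterosis/inbreeding-depression parameter b), `gE` is the i.i.d. model
#' residual, and `s` carries the Stage-1 estimation errors as a random effect
#' with KNOWN covariance (the direct sum of the per-environment BLUE
#' covariance blocks) and no free parameter.  With `multi = "loc"`, the
#' additive effect is genotype-within-location with an FA2 covariance between
#' locations; with `multi = "trait"`, all trait covariance matrices are
#' unstructured and environment fixed effects are trait-specific.
#'
#' @param s1 a `stage1_fit`
#' @param spec a [stage2_spec]
#' @param include_s_term include the Stage-1 error covariance term (the
#'   "fully efficient" analysis); set FALSE to ignore Stage-1 errors, e.g.
#'   to measure the information loss via [compare_aic]
#' @param control see [reml_control]
#'
#' @return An object of class `stage2_fit`: the underlying [reml_fit]
#'   (`$reml`), `AIC`, `loglik`, a variance-component table (`$vartable`),
#'   heterosis coefficients `$b` with standard errors, fixed marker effects,
#'   the PVE table (`$PVE`, see [pve_summary]), the additive trait
#'   correlation matrix (`$add_corr`, multi-trait), rotated FA2 loadings
#'   (`$loadings`, multi-location), and the assembled model (`$model`).
#' @export
fit_stage2 <- function(s1, spec, include_s_term = TRUE,
                       control = reml_control()) {
  md <- stage2_build(s1, spec, include_s_term)
  rf <- reml_fit(md$y, md$X, random = md$terms, fixed_V = md$S,
                 control = control)

  # heterosis coefficients b = -coef(F), one per trait/location
  b <- b.se <- NULL
  if (length(md$xmeta$F) > 0) {
    ii <- match(md$xmeta$F, names(rf$beta))
    b <- -rf$beta[ii]
    b.se <- sqrt(diag(rf$beta.vcov)[ii])
    names(b) <- names(b.se) <- sub("^F:?", "", md$xmeta$F)
    if (length(b) == 1) names(b) <- names(b.se) <- "b"
  }
  marker_effects <- NULL
  if (length(md$xmeta$markers) > 0) {
    marker_effects <- lapply(md$xmeta$markers, function(cls) {
      ii <- match(cls, names(rf$beta))
      data.frame(coef = cls, estimate = rf$beta[ii],
                 se = sqrt(diag(rf$beta.vcov)[ii]), row.names = NULL)
    })
  }

  est <- rf$estimates
  vartable <- data.frame(component = character(0), estimate = numeric(0))
  addv <- function(vt, comp, val) rbind(vt, data.frame(component = comp,
                                                       estimate = val))
  for (nm in names(est)) {
    e <- est[[nm]]
    if (!is.null(e$sigma2)) {
      lab <- if (length(e$sigma2) > 1) paste0(nm, ":", names(e$sigma2)) else nm
      vartable <- addv(vartable, lab, unname(e$sigma2))
    } else {
      M <- if (!is.null(e$Sigma)) e$Sigma else e$Gamma
      labs <- outer(seq_len(nrow(M)), seq_len(ncol(M)),
                    function(i, j) paste0(nm, "[", i, ",", j, "]"))
      keep <- lower.tri(M, diag = TRUE)
      vartable <- addv(vartable, labs[keep], M[keep])
    }
  }

  add_corr <- NULL
  if (spec$multi == "trait" && spec$model != "none") {
    SigA <- est$additive$Sigma
    dimnames(SigA) <- list(md$traits, md$traits)
    add_corr <- stats::cov2cor(SigA)
  }
  loadings <- NULL
  if (spec$multi == "loc" && !is.null(est$additive$Lambda)) {
    loadings <- fa2_rotate(est$additive$Lambda, est$additive$Psi)
    rownames(loadings$loadings) <- rownames(loadings$coord) <- md$locs
    names(loadings$radius2) <- md$locs
  }

  out <- structure(list(reml = rf, AIC = rf$AIC, loglik = rf$loglik,
                        vartable = vartable, b = b, b.se = b.se,
                        fixed_marker_effects = marker_effects,
                        add_corr = add_corr, loadings = loadings,
                        model = md, spec = spec,
                        include_s_term = include_s_term),
                   class = "stage2_fit")
  out$PVE <- pve_summary(out)
  out
}

#' @export
print.stage2_fit <- function(x, ...) {
  cat(sprintf("stage2_fit (%s, multi = %s): logLik %.3f, AIC %.2f\n",
              x$spec$model, x$spec$multi, x$loglik, x$AIC))
  if (!is.null(x$b)) {
    cat("heterosis b (SE):",
        paste(sprintf("%s = %.3g (%.3g)", names(x$b), x$b, x$b.se),
              collapse = ", "), "\n")
  }
  cat("PVE:\n")
  print(round(x$PVE, 3))
  invisible(x)
}

# expected variance of one model effect (Legarra-style):
#   E[V_y] = [wmean(diag K) - wmean(K)] + [wmean(mu^2) - wmean(mu)^2]
# with weights = number of Stage-2 records per effect level.
pve_component <- function(K = NULL, mu = NULL, w) {
  Tn <- sum(w)
  out <- 0
  if (!is.null(K)) out <- out + sum(w * diag(K)) / Tn -
      drop(crossprod(w, K %*% w)) / Tn^2
  if (!is.null(mu)) out <- out + sum(w * mu^2) / Tn - (sum(w * mu) / Tn)^2
  out
}

#' Proportion of variance explained by each Stage-2 effect
#'
#' Expected variance of every model effect, computed from the fitted
#' (co)variances by the quadratic-form identity
#' `E[V_y] = [mean(diag K) - mean(K)] + [mean(mu^2) - mean(mu)^2]` with
#' weighted averages (weights = number of environments per genotype) for
#' genotype-indexed effects, then normalized to sum to 1.  The environment
#' main effect is excluded (mirroring how heritability is computed).  The
#' heterosis row is the variance of the fitted `-b*F` fixed term; the
#' dominance row is the kernel part.  For the multi-location model the
#' genotype-within-location variance is split into an additive main effect
#' (based on the mean off-diagonal of the FA2 covariance) plus a
#' genotype-by-location interaction.  For multi-trait fits one PVE column is
#' returned per trait.
#'
#' @param fit a `stage2_fit`
#' @return numeric matrix, one row per variance source, one column per trait.
#' @export
pve_summary <- function(fit) {
  stopifnot(inherits(fit, "stage2_fit"))
  md <- fit$model
  est <- fit$reml$estimates
  spec <- fit$spec
  obs <- md$obs
  n <- length(md$ids)
  traits <- md$traits
  t <- length(traits)
  rows <- list()
  for (r in seq_len(t)) {
    sel <- md$tr_idx == r
    w <- tabulate(md$id_idx[sel], nbins = n)   # envs per genotype
    comp <- c()
    if (spec$model == "none") {
      comp["genotype"] <- pve_component(K = est$genotype$sigma2 * diag(n), w = w)
    } else if (spec$multi == "none") {
      comp["additive"] <- pve_component(K = est$additive$sigma2 * md$K_add, w = w)
      if (spec$model == "dominance") {
        comp["dominance"] <- pve_component(K = est$dominance$sigma2 * md$K_dom,
                                           w = w)
        comp["heterosis"] <- pve_component(mu = -fit$b[1] * md$Fc, w = w)
      } else {
        comp["genetic residual"] <- pve_component(K = est$gresid$sigma2 * diag(n),
                                                  w = w)
      }
    } else if (spec$multi == "trait") {
      SigA <- est$additive$Sigma
      comp["additive"] <- pve_component(K = SigA[r, r] * md$K_add, w = w)
      if (spec$model == "dominance") {
        comp["dominance"] <- pve_component(K = est$dominance$Sigma[r, r] * md$K_dom,
                                           w = w)
        comp["heterosis"] <- pve_component(mu = -fit$b[r] * md$Fc, w = w)
      } else {
        comp["genetic residual"] <- pve_component(
          K = est$gresid$Sigma[r, r] * diag(n), w = w)
      }
    } else { # multi = "loc": Rogers-style split of the g(L) variance
      Gam <- if (!is.null(est$additive$Gamma)) est$additive$Gamma
             else est$additive$Sigma
      s <- length(md$locs)
      wcell <- tabulate((md$id_idx[sel] - 1L) * s + match(obs$loc[sel], md$locs),
                        nbins = n * s)
      Kfull <- md$K_add %x% Gam
      total <- pve_component(K = Kfull, w = wcell)
      offbar <- if (s > 1) mean(Gam[upper.tri(Gam)]) else 0
      main <- pve_component(K = md$K_add, w = w) * offbar
      comp["additive"] <- main
      comp["g x loc"] <- max(total - main, 0)
      if (spec$model == "dominance") {
        comp["dominance"] <- pve_component(K = est$dominance$sigma2 * md$K_dom,
                                           w = w)
        bl <- fit$b[md$locs]
        muF <- md$Fc[md$id_idx[sel]] * -bl[match(obs$loc[sel], md$locs)]
        comp["heterosis"] <- pve_component(mu = muF, w = rep(1, sum(sel)))
      } else if (spec$model == "genetic_residual") {
        comp["genetic residual"] <- pve_component(K = est$gresid$sigma2 * diag(n),
                                                  w = w)
      }
    }
    if (length(md$xmeta$markers) > 0) {
      delta <- fit$reml$beta
      mu_m <- numeric(n)
      for (mk in names(md$xmeta$markers)) {
        cls <- md$xmeta$markers[[mk]]
        cl <- if (length(cls) == 1) cls else cls[r]
        mu_m <- mu_m + md$W_fix[, mk] * delta[cl]
      }
      comp["markers"] <- pve_component(mu = mu_m, w = w)
    }
    # gE (model residual) and the Stage-1 error, on the record basis
    Tn <- sum(sel)
    gxe_var <- if (spec$multi == "none") est$gxe$sigma2
      else if (spec$multi == "loc") {
        lv <- est$gxe$sigma2[match(obs$loc[sel], names(est$gxe$sigma2))]
        mean(lv)
      } else est$gxe$Sigma[r, r]
    comp[if (spec$multi == "loc") "g x env" else "g x env"] <-
      gxe_var * (1 - 1 / Tn)
    if (!is.null(md$S)) {
      Ssub <- md$S[sel, sel, drop = FALSE]
      comp["Stage 1 error"] <- mean(diag(Ssub)) - mean(Ssub)
    }
    rows[[r]] <- comp
  }
  all_names <- unique(unlist(lapply(rows, names)))
  out <- sapply(rows, function(x) {
    v <- x[all_names]
    names(v) <- all_names
    v[is.na(v)] <- 0
    v / sum(v)
  })
  out <- matrix(out, nrow = length(all_names),
                dimnames = list(all_names, traits))
  out
}

#' Optimize the G/A blending weight of the H matrix by AIC
#'
#' Refits Stage 2 over a grid of blend weights `omega`
#' (`H = (1-omega) G + omega A`) and returns the AIC-minimizing weight
#' together with the AIC and PVE traces.
#'
#' @param s1 a `stage1_fit`
#' @param spec a [stage2_spec] whose `geno` contains a pedigree A matrix
#' @param omega_grid grid of blend weights in `[0, 1]`
#' @param include_s_term as in [fit_stage2]
#' @param control see [reml_control]
#' @return list with `omega_opt`, `table` (omega, AIC, PVE rows), and
#'   `fits` (the refits, named by omega).
#' @export
optimize_blend <- function(s1, spec, omega_grid = seq(0, 1, by = 0.1),
                           include_s_term = TRUE, control = reml_control()) {
  if (any(omega_grid < 0 | omega_grid > 1))
    stop("omega grid must lie within [0, 1]")
  if (is.null(spec$geno$A)) stop("optimize_blend requires a pedigree A matrix")
  fits <- list()
  tab <- list()
  for (om in omega_grid) {
    sp <- spec
    sp$omega <- om
    f <- fit_stage2(s1, sp, include_s_term = include_s_term, control = control)
    fits[[as.character(om)]] <- f
    pve <- f$PVE
    tab[[as.character(om)]] <- data.frame(
      omega = om, AIC = f$AIC,
      PVE_additive = if ("additive" %in% rownames(pve)) mean(pve["additive", ]) else NA,
      PVE_dominance = if ("dominance" %in% rownames(pve)) mean(pve["dominance", ]) else NA)
  }
  tab <- do.call(rbind, c(tab, make.row.names = FALSE))
  list(omega_opt = tab$omega[which.min(tab$AIC)], table = tab, fits = fits)
}
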