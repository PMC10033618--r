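# Stage 1 of the two-stage analysis: per-environment fixed-effect models for
# genotype means (BLUEs) with their full variance-covariance matrices, which
# become the response and the known error covariance of Stage 2.

#' Stage 1: genotype BLUEs per environment
#'
#' Fits, for each environment, a fixed-effect model
#' `trait ~ 0 + id + fixed covariates` (optionally with i.i.d. random
#' covariates, estimated by REML) and returns the genotype BLUEs on the
#' observation scale together with their full variance-covariance matrix.
#' A companion model with genotype random gives the broad-sense heritability
#' on a plot basis, `H2 = sigma2_g / (sigma2_g + sigma2_e)`.
#'
#' For multiple traits a separable residual model is used: the traits share
#' the design matrix, the residual covariance `Sigma_t` is estimated from the
#' OLS residual cross-products, and the BLUE covariance in each environment is
#' the Kronecker product of the genotype block of `(X'X)^-1` with `Sigma_t`
#' (BLUEs stacked trait-within-genotype).  Random covariates are supported for
#' single-trait analysis only.
#'
#' @param data data frame of plots with columns `id`, `env`, optional `loc`,
#'   the trait column(s), and any design covariates
#' @param traits character vector of trait column names
#' @param fixed character vector of fixed covariate column names
#' @param random character vector of i.i.d. random covariate column names
#'   (single trait only)
#'
#' @return An object of class `stage1_fit`: list with `blues` (data frame
#'   `id, env, trait, value`), `vcov` (named list of per-environment BLUE
#'   covariance matrices, row order trait-within-genotype), `resid`
#'   (per-environment residual (co)variance), `h2` (per-env, per-trait
#'   plot-basis heritability), `traits`, and `env_loc` (environment-to-
#'   location map if a `loc` column is present).
#' @export
fit_stage1 <- function(data, traits, fixed = character(0),
                       random = character(0)) {
  data <- as.data.frame(data)
  stopifnot(all(c("id", "env") %in% names(data)),
            all(traits %in% names(data)),
            all(fixed %in% names(data)), all(random %in% names(data)))
  nt <- length(traits)
  if (nt > 1 && length(random) > 0)
    stop("random covariates are supported for single-trait Stage 1 only")
  data$id <- factor(data$id)
  data$env <- factor(data$env)
  envs <- levels(data$env)

  env_loc <- NULL
  if ("loc" %in% names(data)) {
    el <- unique(data[, c("env", "loc")])
    if (anyDuplicated(el$env) > 0)
      stop("each env must nest within a single loc")
    env_loc <- stats::setNames(as.character(el$loc), as.character(el$env))
  }

  blues <- list()
  vcovs <- list()
  h2 <- list()
  resid_tab <- list()
  for (e in envs) {
    d <- droplevels(data[data$env == e, , drop = FALSE])
    d <- d[stats::complete.cases(d[, c("id", traits, fixed, random)]), , drop = FALSE]
    if (nlevels(d$id) < 2) {
      warning(sprintf("environment %s has < 2 genotypes and was skipped", e))
      next
    }
    ff <- stats::as.formula(paste("~ 0 + id",
                                  if (length(fixed)) paste("+", paste(fixed, collapse = "+")) else ""))
    X <- stats::model.matrix(ff, d)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      stop(sprintf("singular Stage 1 design in env %s; aliased columns: %s",
                   e, paste(aliased, collapse = ", ")))
    }
    gcols <- seq_len(nlevels(d$id))
    gids <- levels(d$id)

    if (length(random) == 0) {
      XtXi <- chol2inv(chol(crossprod(X)))
      Bmat <- XtXi %*% crossprod(X, as.matrix(d[, traits, drop = FALSE]))
      E <- as.matrix(d[, traits, drop = FALSE]) - X %*% Bmat
      df <- nrow(X) - ncol(X)
      Sigma_t <- crossprod(E) / df
      blue_e <- Bmat[gcols, , drop = FALSE]
      V_e <- XtXi[gcols, gcols, drop = FALSE] %x% Sigma_t
    } else {
      stopifnot(nt == 1)
      rterms <- list()
      for (rv in random) {
        fr <- factor(d[[rv]])
        rterms[[rv]] <- list(map = as.integer(fr), struct = vs_iid(nlevels(fr)))
      }
      rterms$resid <- list(map = seq_len(nrow(d)), struct = vs_iid(nrow(d)))
      rf <- reml_fit(d[[traits]], X, random = rterms)
      blue_e <- matrix(rf$beta[gcols], ncol = 1)
      V_e <- rf$beta.vcov[gcols, gcols, drop = FALSE]
      Sigma_t <- matrix(rf$estimates$resid$sigma2, 1, 1)
    }
    rn <- if (nt == 1) gids else
      as.vector(t(outer(gids, traits, paste, sep = ":")))
    dimnames(V_e) <- list(rn, rn)
    vcovs[[e]] <- V_e
    blues[[e]] <- data.frame(id = rep(gids, each = nt), env = e,
                             trait = rep(traits, length(gids)),
                             value = as.vector(t(blue_e)))
    dimnames(Sigma_t) <- list(traits, traits)
    resid_tab[[e]] <- Sigma_t

    # companion random-genotype fit for plot-basis H2, one trait at a time
    fH <- stats::as.formula(paste("~ 1",
                                  if (length(fixed)) paste("+", paste(fixed, collapse = "+")) else ""))
    XH <- stats::model.matrix(fH, d)
    XH <- XH[, qr(XH)$pivot[seq_len(qr(XH)$rank)], drop = FALSE]
    for (tr in traits) {
      rterms <- list(geno = list(map = as.integer(d$id),
                                 struct = vs_iid(nlevels(d$id))))
      for (rv in random) {
        fr <- factor(d[[rv]])
        rterms[[rv]] <- list(map = as.integer(fr), struct = vs_iid(nlevels(fr)))
      }
      rterms$resid <- list(map = seq_len(nrow(d)), struct = vs_iid(nrow(d)))
      rfH <- reml_fit(d[[tr]], XH, random = rterms)
      s2g <- rfH$estimates$geno$sigma2
      s2e <- rfH$estimates$resid$sigma2
      bflag <- rfH$boundary[1]
      h2[[paste(e, tr)]] <- data.frame(env = e, trait = tr,
                                       H2 = if (bflag) 0 else s2g / (s2g + s2e),
                                       boundary = bflag)
    }
  }
  if (length(blues) == 0) stop("no environment could be analyzed")
  structure(list(blues = do.call(rbind, c(blues, make.row.names = FALSE)),
                 vcov = vcovs, resid = resid_tab,
                 h2 = do.call(rbind, c(h2, make.row.names = FALSE)),
                 traits = traits, env_loc = env_loc),
            class = "stage1_fit")
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat(sprintf("stage1_fit: %d environments, %d traits, %d BLUEs\n",
              length(x$vcov), length(x$traits), nrow(x$blues)))
  invisible(x)
}

#' Plot-basis broad-sense heritability per environment
#'
#' @param fit a [fit_stage1] result
#' @return data frame with columns `env`, `trait`, `H2`, `boundary`
#'   (TRUE when the genotypic variance hit the zero boundary).
#' @export
h2_table <- function(fit) {
  stopifnot(inherits(fit, "stage1_fit"))
  fit$h2
}

#' Assemble a Stage-1 fit from externally computed BLUEs and covariances
#'
#' Allows spatially adjusted (or otherwise externally produced) Stage-1
#' results to enter the pipeline.  `blues` must have columns
#' `id, env, trait, value`; `vcov` is a named list of per-environment
#' covariance matrices with row/column names `id` (single trait) or
#' `id:trait` with trait nested within genotype.
#'
#' @param blues data frame of BLUEs
#' @param vcov named list of per-env covariance matrices
#' @param env_loc optional named character vector mapping env to loc
#' @return A `stage1_fit`.
#' @export
as_stage1 <- function(blues, vcov, env_loc = NULL) {
  blues <- as.data.frame(blues)
  stopifnot(all(c("id", "env", "trait", "value") %in% names(blues)))
  traits <- unique(as.character(blues$trait))
  envs <- unique(as.character(blues$env))
  if (!all(envs %in% names(vcov)))
    stop("vcov must contain one matrix per environment")
  nt <- length(traits)
  for (e in envs) {
    V <- as.matrix(vcov[[e]])
    b <- blues[blues$env == e, ]
    ids <- unique(as.character(b$id))
    rn <- if (nt == 1) ids else as.vector(t(outer(ids, traits, paste, sep = ":")))
    if (nrow(V) != length(rn))
      stop(sprintf("vcov block for env %s has wrong dimension", e))
    if (is.null(rownames(V))) dimnames(V) <- list(rn, rn)
    if (max(abs(V - t(V))) > 1e-8 * (1 + max(abs(V))))
      stop(sprintf("vcov block for env %s is not symmetric", e))
    vcov[[e]] <- (V + t(V)) / 2
  }
  structure(list(blues = blues[, c("id", "env", "trait", "value")],
                 vcov = vcov[envs], resid = NULL, h2 = NULL,
                 traits = traits, env_loc = env_loc),
            class = "stage1_fit")
}

#' Write / read Stage-1 results as CSV
#'
#' Two files: the BLUEs (`id, env, trait, value`) and the covariance entries
#' in long format (`env, id1, trait1, id2, trait2, value`; upper triangle).
#'
#' @param fit a `stage1_fit`
#' @param blues_file,vcov_file output/input paths
#' @export
write_stage1 <- function(fit, blues_file, vcov_file) {
  stopifnot(inherits(fit, "stage1_fit"))
  utils::write.csv(fit$blues, blues_file, row.names = FALSE)
  nt <- length(fit$traits)
  rows <- list()
  for (e in names(fit$vcov)) {
    V <- fit$vcov[[e]]
    rn <- rownames(V)
    split_rn <- if (nt == 1) cbind(rn, fit$traits) else
      do.call(rbind, strsplit(rn, ":", fixed = TRUE))
    ut <- which(upper.tri(V, diag = TRUE), arr.ind = TRUE)
    rows[[e]] <- data.frame(env = e,
                            id1 = split_rn[ut[, 1], 1], trait1 = split_rn[ut[, 1], 2],
                            id2 = split_rn[ut[, 2], 1], trait2 = split_rn[ut[, 2], 2],
                            value = V[ut])
  }
  utils::write.csv(do.call(rbind, rows), vcov_file, row.names = FALSE)
  invisible(fit)
}

#' @rdname write_stage1
#' @export
read_stage1 <- function(blues_file, vcov_file) {
  blues <- utils::read.csv(blues_file, colClasses = c(id = "character",
                                                      env = "character",
                                                      trait = "character"))
  vl <- utils::read.csv(vcov_file, colClasses = "character")
  vl$value <- as.numeric(vl$value)
  traits <- unique(blues$trait)
  nt <- length(traits)
  vcov <- list()
  for (e in unique(blues$env)) {
    b <- blues[blues$env == e, ]
    ids <- unique(b$id)
    rn <- if (nt == 1) ids else as.vector(t(outer(ids, traits, paste, sep = ":")))
    V <- matrix(0, length(rn), length(rn), dimnames = list(rn, rn))
    ve <- vl[vl$env == e, ]
    k1 <- if (nt == 1) ve$id1 else paste(ve$id1, ve$trait1, sep = ":")
    k2 <- if (nt == 1) ve$id2 else paste(ve$id2, ve$trait2, sep = ":")
    V[cbind(k1, k2)] <- ve$value
    V[cbind(k2, k1)] <- ve$value
    vcov[[e]] <- V
  }
  as_stage1(blues, vcov)
}
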