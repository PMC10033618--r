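#' Marker panel for a genotyped population
#'
#' Container for bi-allelic allele dosages of an even-ploidy population,
#' together with the genetic map.  Dosages are stored individuals x markers,
#' with entries in `[0, ploidy]` (fractional dosages from array intensities
#' are allowed).  Allele frequencies are the observed frequencies of the
#' population, `p = colMeans(dosage)/ploidy`.
#'
#' @param dosage numeric matrix, individuals x markers, with row names
#'   (individual ids) and column names (marker ids); entries in `[0, ploidy]`
#' @param ploidy even integer >= 2
#' @param map optional data frame with columns `marker`, `chrom`, `position`
#'   (one row per marker, same order as `colnames(dosage)`)
#'
#' @return An object of class `marker_set`: a list with elements `dosage`,
#'   `ploidy`, `map`, `ids`, `marker_ids`, and `p` (allele frequencies).
#' @export
marker_set <- function(dosage, ploidy, map = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("id", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("m", seq_len(ncol(dosage)))
  if (ploidy < 2 || ploidy %% 2 != 0)
    stop("ploidy must be an even integer >= 2")
  if (anyDuplicated(rownames(dosage)))
    stop("duplicate individual ids in dosage matrix")
  if (anyDuplicated(colnames(dosage)))
    stop("duplicate marker ids in dosage matrix")
  bad <- which(!is.na(dosage) & (dosage < 0 | dosage > ploidy), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("dosage outside [0, %d]: marker %s, individual %s (value %g)",
                 ploidy, colnames(dosage)[bad[1, 2]], rownames(dosage)[bad[1, 1]],
                 dosage[bad[1, , drop = FALSE]]))
  }
  if (!is.null(map)) {
    map <- as.data.frame(map)
    stopifnot(all(c("marker", "chrom", "position") %in% names(map)))
    if (!identical(as.character(map$marker), colnames(dosage)))
      map <- map[match(colnames(dosage), map$marker), ]
  }
  structure(list(dosage = dosage, ploidy = as.integer(ploidy), map = map,
                 ids = rownames(dosage), marker_ids = colnames(dosage),
                 p = colMeans(dosage, na.rm = TRUE) / ploidy),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d individuals x %d markers, ploidy %d\n",
              length(x$ids), length(x$marker_ids), x$ploidy))
  invisible(x)
}

#' Read and filter a marker dosage file
#'
#' Reads a CSV with header `marker,chrom,position,<id1>,<id2>,...` and one row
#' per marker.  Markers failing the minor-allele-frequency or missingness
#' filters are dropped (monomorphic markers are always dropped, since they
#' contribute nothing to any relationship matrix), and remaining missing
#' dosages are imputed with the marker (column) mean.
#'
#' @param filename path to the dosage CSV
#' @param ploidy even integer >= 2
#' @param min.MAF minimum minor allele frequency (markers with
#'   `min(p, 1-p) < min.MAF` are dropped)
#' @param max.missing maximum fraction of missing dosages per marker
#'
#' @return A [marker_set] of the retained markers, missing values imputed.
#' @export
read_geno <- function(filename, ploidy, min.MAF = 0, max.missing = 1) {
  raw <- utils::read.csv(filename, check.names = FALSE)
  if (ncol(raw) < 4 || !all(c("marker", "chrom", "position") %in% names(raw)[1:3]))
    stop("expected CSV header 'marker,chrom,position,<id1>,...'")
  map <- raw[, c("marker", "chrom", "position")]
  X <- t(as.matrix(raw[, -(1:3), drop = FALSE]))  # individuals x markers
  colnames(X) <- as.character(map$marker)
  storage.mode(X) <- "double"

  bad <- which(!is.na(X) & (X < 0 | X > ploidy), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("dosage outside [0, %d]: marker %s, individual %s",
                 ploidy, colnames(X)[bad[1, 2]], rownames(X)[bad[1, 1]]))

  m0 <- ncol(X)
  miss <- colMeans(is.na(X))
  keep.miss <- miss <= max.missing
  p <- colMeans(X, na.rm = TRUE) / ploidy
  maf <- pmin(p, 1 - p)
  keep.maf <- maf >= min.MAF & maf > 0
  keep <- keep.miss & keep.maf
  message(sprintf("read_geno: %d markers read; %d dropped for missingness > %g, %d for MAF < %g or monomorphic; %d retained",
                  m0, sum(!keep.miss), max.missing,
                  sum(keep.miss & !keep.maf), min.MAF, sum(keep)))
  if (sum(keep) == 0L)
    stop("no markers survive the MAF/missingness filters")
  X <- X[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]
  # mean imputation keeps the centered matrix W well-defined
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    cm <- colMeans(X, na.rm = TRUE)
    X[nas] <- cm[nas[, 2]]
  }
  marker_set(X, ploidy = ploidy, map = map)
}

#' Relationship matrix
#'
#' A named symmetric kinship-like matrix over individual ids, of kind
#' `"G"` (genomic additive), `"D"` (genomic dominance), `"A"` (pedigree
#' additive), or `"H"` (blend of G and A).
#'
#' @param values symmetric numeric matrix with identical row/column ids
#' @param kind one of `"G"`, `"D"`, `"A"`, `"H"`
#' @return An object of class `rel_matrix`.
#' @export
rel_matrix <- function(values, kind = c("G", "D", "A", "H")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (is.null(rownames(values)))
    rownames(values) <- colnames(values) <- paste0("id", seq_len(nrow(values)))
  if (!identical(rownames(values), colnames(values)))
    stop("row and column ids of a relationship matrix must be identical")
  if (max(abs(values - t(values))) > 1e-8 * (1 + max(abs(values))))
    stop("relationship matrix is not symmetric")
  values <- (values + t(values)) / 2
  structure(list(ids = rownames(values), values = values, kind = kind),
            class = "rel_matrix")
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("rel_matrix (%s): %d individuals, mean diag %.3f\n",
              x$kind, length(x$ids), mean(diag(x$values))))
  invisible(x)
}

#' @export
as.matrix.rel_matrix <- function(x, ...) x$values

#' Genomic additive relationship matrix
#'
#' VanRaden method-1 G matrix extended to arbitrary even ploidy:
#' `G = W W' / (ploidy * sum(p*q))` with `W` the column-centered dosage
#' matrix.  The grand mean of G is exactly zero by construction.
#'
#' @param ms a [marker_set]
#' @return A [rel_matrix] of kind `"G"`.
#' @export
compute_G <- function(ms) {
  stopifnot(inherits(ms, "marker_set"))
  p <- ms$p
  denom <- ms$ploidy * sum(p * (1 - p))
  if (denom <= 0) stop("all markers are monomorphic; G denominator is zero")
  W <- sweep(ms$dosage, 2, ms$ploidy * p)
  rel_matrix(tcrossprod(W) / denom, kind = "G")
}

#' Centered dosage matrix
#'
#' @param ms a [marker_set]
#' @return individuals x markers matrix `W`, columns centered at `ploidy * p`.
#' @export
dosage_W <- function(ms) {
  stopifnot(inherits(ms, "marker_set"))
  sweep(ms$dosage, 2, ms$ploidy * ms$p)
}

#' Dominance coefficients, genomic dominance matrix, and inbreeding
#'
#' For ploidy `phi` and allele dosage `X`, the per-locus dominance coefficient
#' is `Q = -2*choose(phi,2)*p^2 + 2*p*(phi-1)*X - X*(X-1)`; the dominance
#' value of an individual is `Q %*% beta` for digenic substitution effects
#' `beta`.  The genomic dominance matrix is `D = Q Q' / denomD` with
#' `denomD = choose(phi,2) * sum(4 p^2 q^2)`, and the genomic inbreeding
#' coefficient is `F = -rowSums(Q) / denomF` with
#' `denomF = choose(phi,2) * sum(2 p q)`, scaled so that a fully homozygous
#' population has mean F = 1 and a panmictic (Hardy-Weinberg) population has
#' mean F = 0.
#'
#' @param ms a [marker_set]
#' @return A list with elements `coeff` (class `dom_coeffs`: `Q`, `F`,
#'   `denomD`, `denomF`) and `D` (a [rel_matrix] of kind `"D"`).
#' @export
compute_dominance <- function(ms) {
  stopifnot(inherits(ms, "marker_set"))
  phi <- ms$ploidy
  p <- ms$p
  q <- 1 - p
  if (sum(p * q) <= 0) stop("all markers are monomorphic")
  X <- ms$dosage
  n <- nrow(X)
  Q <- matrix(-2 * choose(phi, 2) * p^2, n, ncol(X), byrow = TRUE) +
    sweep(X, 2, 2 * p * (phi - 1), `*`) - X * (X - 1)
  dimnames(Q) <- dimnames(X)
  denomD <- choose(phi, 2) * sum(4 * p^2 * q^2)
  denomF <- choose(phi, 2) * sum(2 * p * q)
  Fvec <- -rowSums(Q) / denomF
  names(Fvec) <- rownames(X)
  coeff <- structure(list(Q = Q, F = Fvec, denomD = denomD, denomF = denomF),
                     class = "dom_coeffs")
  list(coeff = coeff, D = rel_matrix(tcrossprod(Q) / denomD, kind = "D"))
}

#' Inbreeding coefficients from the diagonal of an additive relationship matrix
#'
#' `F_i = (K_ii - 1) / (ploidy - 1)` for K of kind G, A, or H.
#'
#' @param K a [rel_matrix] of kind `"G"`, `"A"`, or `"H"`
#' @param ploidy even integer >= 2
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding_from_diag <- function(K, ploidy) {
  stopifnot(inherits(K, "rel_matrix"))
  if (!K$kind %in% c("G", "A", "H"))
    stop("inbreeding from the diagonal requires an additive-type matrix (G, A, or H)")
  if (ploidy <= 1) stop("ploidy must be > 1")
  (diag(K$values) - 1) / (ploidy - 1)
}

#' Read a three-column pedigree
#'
#' CSV with columns `id, parent1, parent2`; blank or NA parent = unknown
#' founder.  The pedigree must be acyclic.
#'
#' @param filename path to pedigree CSV
#' @return data frame of class `pedigree` with character columns
#'   `id`, `parent1`, `parent2`.
#' @export
read_pedigree <- function(filename) {
  ped <- utils::read.csv(filename, colClasses = "character")
  names(ped)[1:3] <- c("id", "parent1", "parent2")
  as_pedigree(ped)
}

#' @rdname read_pedigree
#' @param ped data frame with columns id, parent1, parent2
#' @export
as_pedigree <- function(ped) {
  ped <- as.data.frame(ped)[, 1:3]
  names(ped) <- c("id", "parent1", "parent2")
  for (j in 1:3) {
    ped[[j]] <- as.character(ped[[j]])
    ped[[j]][ped[[j]] %in% c("", "NA", "0")] <- NA
  }
  if (anyDuplicated(ped$id)) stop("duplicate ids in pedigree")
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# topological order of a pedigree; errors on cycles
ped_order <- function(ped) {
  ids <- ped$id
  placed <- logical(length(ids))
  names(placed) <- ids
  ord <- integer(0)
  repeat {
    ready <- which(!placed & vapply(seq_along(ids), function(i) {
      pa <- c(ped$parent1[i], ped$parent2[i])
      all(is.na(pa) | !(pa %in% ids) | placed[pa])
    }, logical(1)))
    if (length(ready) == 0) break
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  if (!all(placed))
    stop("pedigree contains a cycle involving: ",
         paste(ids[!placed], collapse = ", "))
  ord
}

#' Pedigree additive relationship matrix
#'
#' Tabular (recursive coancestry) method for diploids, and its extension to
#' autotetraploids under random bivalent pairing without double reduction.
#' For an individual with parents s and d, the tetraploid inbreeding
#' coefficient is `F = F_s/6 + F_d/6 + 2/3 * f(s,d)` where `f` is coancestry;
#' the additive relationship is `A = ploidy * f`, so non-inbred individuals
#' have diagonal 1 and inbred ones `1 + (ploidy-1)*F`.
#'
#' @param ped a `pedigree` (see [read_pedigree])
#' @param ploidy 2 or 4
#' @return A [rel_matrix] of kind `"A"`.
#' @export
pedigree_A <- function(ped, ploidy = 2) {
  stopifnot(inherits(ped, "pedigree"))
  if (!ploidy %in% c(2, 4))
    stop("pedigree_A supports ploidy 2 and 4 only")
  ord <- ped_order(ped)
  ped <- ped[ord, ]
  ids <- ped$id
  N <- length(ids)
  f <- matrix(0, N, N, dimnames = list(ids, ids))
  Fcoef <- numeric(N)
  names(Fcoef) <- ids
  idx <- function(x) if (is.na(x) || !(x %in% ids)) NA_integer_ else match(x, ids)
  for (i in seq_len(N)) {
    s <- idx(ped$parent1[i]); d <- idx(ped$parent2[i])
    fs <- function(j) {
      a <- if (is.na(s)) 0 else f[s, j]
      b <- if (is.na(d)) 0 else f[d, j]
      (a + b) / 2
    }
    if (i > 1) for (j in seq_len(i - 1)) f[i, j] <- f[j, i] <- fs(j)
    fsd <- if (is.na(s) || is.na(d)) 0 else f[s, d]
    Fi <- if (ploidy == 2) fsd else {
      (ifelse(is.na(s), 0, Fcoef[s]) + ifelse(is.na(d), 0, Fcoef[d])) / 6 +
        2 / 3 * fsd
    }
    Fcoef[i] <- Fi
    f[i, i] <- 1 / ploidy + (1 - 1 / ploidy) * Fi
  }
  rel_matrix(ploidy * f, kind = "A")
}

#' Blend genomic and pedigree relationship matrices
#'
#' `H = (1 - omega) * G + omega * A`.  A is subset/reordered to G's ids; all
#' of G's ids must be present in A.
#'
#' @param G a [rel_matrix] of kind `"G"`
#' @param A a [rel_matrix] of kind `"A"`
#' @param omega blend weight on A, in `[0, 1]`
#' @return A [rel_matrix] of kind `"H"` (kind `"G"`/`"A"` at the endpoints
#'   omega = 0 / 1 is still labelled `"H"` for traceability of the blend).
#' @export
blend_H <- function(G, A, omega) {
  stopifnot(inherits(G, "rel_matrix"), inherits(A, "rel_matrix"))
  if (omega < 0 || omega > 1) stop("omega must be in [0, 1]")
  missing_ids <- setdiff(G$ids, A$ids)
  if (length(missing_ids) > 0)
    stop("ids missing from A: ", paste(utils::head(missing_ids, 5), collapse = ", "))
  Av <- A$values[G$ids, G$ids]
  rel_matrix((1 - omega) * G$values + omega * Av, kind = "H")
}

#' Write / read a relationship matrix as square CSV
#'
#' Square CSV with the ids as header row and first column.
#'
#' @param K a [rel_matrix]
#' @param filename output path
#' @export
write_rel_matrix <- function(K, filename) {
  stopifnot(inherits(K, "rel_matrix"))
  utils::write.csv(as.data.frame(K$values), filename, row.names = TRUE)
  invisible(filename)
}

#' @rdname write_rel_matrix
#' @param kind kind of the matrix being read
#' @export
read_rel_matrix <- function(filename, kind = "G") {
  d <- utils::read.csv(filename, row.names = 1, check.names = FALSE)
  rel_matrix(as.matrix(d), kind = kind)
}
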