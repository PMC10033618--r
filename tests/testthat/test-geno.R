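# Marker ingestion, relationship matrices, dominance coefficients, inbreeding.

test_that("read_geno parses, filters, and imputes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("marker,chrom,position,A,B",
               "m1,chr1,100,0,2",
               "m2,chr1,200,2,0",
               "m3,chr2,300,0,0",        # monomorphic -> dropped
               "m4,chr2,400,1,NA"), f)   # missing -> imputed with column mean
  ms <- suppressMessages(read_geno(f, ploidy = 2, min.MAF = 0.01))
  expect_setequal(ms$marker_ids, c("m1", "m2", "m4"))
  expect_equal(unname(ms$p[c("m1", "m2")]), c(0.5, 0.5))
  expect_equal(unname(ms$dosage["B", "m4"]), 1)  # imputed = observed mean

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("marker,chrom,position,A,B", "m1,chr1,100,0,3"), f2)
  expect_error(suppressMessages(read_geno(f2, ploidy = 2)), "outside")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("marker,chrom,position,A,B", "m1,chr1,100,0,0"), f3)
  expect_error(suppressMessages(read_geno(f3, ploidy = 2, min.MAF = 0.01)),
               "no markers")
})

test_that("read_geno imputes a partially missing column with its mean", {
  f <- withr::local_tempfile(fileext = ".csv")
  # column mean of m1 over observed = 1.4
  writeLines(c("marker,chrom,position,A,B,C,D,E,F",
               "m1,chr1,100,2,1,1,2,1,NA",
               "m2,chr1,200,0,1,2,0,1,2"), f)
  ms <- suppressMessages(read_geno(f, ploidy = 2))
  expect_equal(unname(ms$dosage["F", "m1"]), 1.4)
})

test_that("G matches the hand-computed VanRaden example and is centered", {
  ms <- ms_from(matrix(c(0, 2, 2, 0), 2, 2), 2, c("a", "b"), c("m1", "m2"))
  G <- compute_G(ms)
  expect_equal(unname(G$values), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  # grand mean is 0 for any marker set (centered W)
  set.seed(5)
  ms2 <- sim_population(40, 60, ploidy = 4, seed = 5)
  expect_equal(mean(compute_G(ms2)$values), 0, tolerance = 1e-10)
  # all monomorphic -> error
  ms3 <- ms_from(matrix(2, 3, 2), 2)
  expect_error(compute_G(ms3), "monomorphic")
})

test_that("diagonal of G recovers inbreeding near 0 under tetraploid HWE", {
  ms <- sim_population(500, 2000, ploidy = 4, seed = 77)
  G <- compute_G(ms)
  expect_lt(abs(mean((diag(G$values) - 1) / (4 - 1))), 0.02)
})

test_that("dominance coefficients match the defining polynomial", {
  # diploid, p = 0.5: Q(0,1,2) = (-0.5, +0.5, -0.5)
  X <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2)  # both markers p = 0.5
  ms <- ms_from(X, 2)
  dom <- compute_dominance(ms)
  expect_equal(unname(dom$coeff$Q[, 1]), c(-0.5, 0.5, -0.5))
  # simplex = duplex contribution exactly at the tetraploid crossover p = 1/3
  expect_equal(Q_of(1, 4, 1 / 3), Q_of(2, 4, 1 / 3))
  # inbreeding contribution is -Q: simplex exceeds duplex only for p > 1/3
  expect_gt(-Q_of(1, 4, 0.5), -Q_of(2, 4, 0.5))
  expect_lt(-Q_of(1, 4, 0.25), -Q_of(2, 4, 0.25))
})

test_that("digenic effects are consistent with the substitution effect", {
  set.seed(8)
  for (i in 1:20) {
    p <- runif(1, 0.05, 0.95); q <- 1 - p; beta <- rnorm(1)
    b00 <- -2 * p^2 * beta; b01 <- 2 * p * q * beta; b11 <- -2 * q^2 * beta
    expect_equal(b01 - (b00 + b11) / 2, beta, tolerance = 1e-12)
    # classical diploid dominance genic variance (2 p q d)^2 at one locus
    expect_equal(choose(2, 2) * 4 * p^2 * q^2 * beta^2, (2 * p * q * beta)^2)
  }
})

test_that("homozygote inbreeding contributions differ by phi(phi-1)(q-p)", {
  set.seed(9)
  for (phi in c(2, 4, 6)) {
    p <- runif(1, 0.1, 0.9)
    # contribution to inbreeding is -Q; difference between the two homozygotes
    expect_equal((-Q_of(phi, phi, p)) - (-Q_of(0, phi, p)),
                 phi * (phi - 1) * ((1 - p) - p), tolerance = 1e-12)
  }
})

test_that("genomic inbreeding F is 0 at exact HWE and 1 when fully homozygous", {
  # diploid exact HWE counts at p = 0.5: genotypes 0,1,1,2
  Xh <- cbind(c(0, 1, 1, 2), c(2, 1, 1, 0))
  expect_equal(mean(compute_dominance(ms_from(Xh, 2))$coeff$F), 0,
               tolerance = 1e-12)
  # tetraploid exact HWE at p = 0.5: binomial(4, .5) counts 1:4:6:4:1
  Xt <- cbind(rep(0:4, c(1, 4, 6, 4, 1)), rep(4:0, c(1, 4, 6, 4, 1)))
  expect_equal(mean(compute_dominance(ms_from(Xt, 4))$coeff$F), 0,
               tolerance = 1e-12)
  # fully homozygous: dosage 0 or phi only
  for (phi in c(2, 4)) {
    Xf <- cbind(rep(c(0, phi), c(3, 7)), rep(c(phi, 0), c(6, 4)))
    expect_equal(mean(compute_dominance(ms_from(Xf, phi))$coeff$F), 1,
                 tolerance = 1e-12)
  }
})

test_that("dominance-based F and diagonal-based F agree on structured data", {
  ms <- sim_population(150, 3000, ploidy = 4, inbreeding = c(0, 0.3),
                       seed = 31)
  FD <- compute_dominance(ms)$coeff$F
  FG <- inbreeding_from_diag(compute_G(ms), 4)
  expect_gt(cor(FD, FG), 0.95)
  # F = -rowSums(Q)/denomF exactly, and Q columns have the stated mean
  dom <- compute_dominance(ms)
  expect_equal(unname(-rowSums(dom$coeff$Q) / dom$coeff$denomF),
               unname(dom$coeff$F))
})

test_that("inbreeding_from_diag applies (K_ii - 1)/(phi - 1)", {
  K <- rel_matrix(diag(c(1, 1.5, 1.3)), kind = "A")
  expect_equal(unname(inbreeding_from_diag(K, 2)), c(0, 0.5, 0.3))
  K4 <- rel_matrix(diag(c(1, 1.3)), kind = "G")
  expect_equal(unname(inbreeding_from_diag(K4, 4)), c(0, 0.1))
  expect_error(inbreeding_from_diag(K, 1), "ploidy")
  D <- rel_matrix(diag(2), kind = "D")
  expect_error(inbreeding_from_diag(D, 2), "additive")
})

test_that("pedigree A reproduces tabular-method values", {
  ped <- as_pedigree(data.frame(
    id = c("p1", "p2", "s1", "s2", "sf"),
    parent1 = c(NA, NA, "p1", "p1", "p1"),
    parent2 = c(NA, NA, "p2", "p2", "p1")))
  A <- pedigree_A(ped, 2)
  expect_equal(A$values["p1", "p2"], 0)           # unrelated founders
  expect_equal(A$values["s1", "s2"], 0.5)         # full sibs
  expect_equal(A$values["s1", "s1"], 1)           # non-inbred diagonal
  expect_equal(A$values["sf", "sf"], 1.5)         # selfed diploid: F = 1/2
  # founders only -> identity
  pf <- as_pedigree(data.frame(id = letters[1:3], parent1 = NA, parent2 = NA))
  expect_equal(unname(pedigree_A(pf, 2)$values), diag(3))
  # tetraploid self progeny: F = 2/3 * f(p,p) = 2/3 * 1/4 -> diag 1 + 3F = 1.5
  A4 <- pedigree_A(ped, 4)
  expect_equal(A4$values["sf", "sf"], 1.5)
  expect_equal(A4$values["s1", "s1"], 1)
  # tetraploid full sibs: f = (1/16 + 1/16)*2 = 1/8 -> A = 4f = 0.5
  expect_equal(A4$values["s1", "s2"], 0.5)
  # cycle detection
  pc <- as_pedigree(data.frame(id = c("x", "y"), parent1 = c("y", "x"),
                               parent2 = c(NA, NA)))
  expect_error(pedigree_A(pc, 2), "cycle")
})

test_that("H blending is an elementwise convex combination", {
  G <- rel_matrix(matrix(c(1, 0.2, 0.2, 1), 2,
                         dimnames = list(c("a", "b"), c("a", "b"))), "G")
  A <- rel_matrix(matrix(c(1, 0.4, 0.4, 1), 2,
                         dimnames = list(c("a", "b"), c("a", "b"))), "A")
  expect_equal(blend_H(G, A, 0)$values, G$values)
  expect_equal(blend_H(G, A, 1)$values, A$values)
  expect_equal(blend_H(G, A, 0.5)$values["a", "b"], 0.3)
  expect_error(blend_H(G, A, 1.2), "omega")
  A2 <- rel_matrix(matrix(1, 1, 1, dimnames = list("a", "a")), "A")
  expect_error(blend_H(G, A2, 0.5), "missing")
})

test_that("relationship matrices round-trip through square CSV", {
  set.seed(4)
  ms <- sim_population(10, 30, ploidy = 2, seed = 4)
  G <- compute_G(ms)
  f <- withr::local_tempfile(fileext = ".csv")
  write_rel_matrix(G, f)
  G2 <- read_rel_matrix(f, kind = "G")
  expect_equal(G2$values, G$values, tolerance = 1e-8)
  expect_equal(G2$ids, G$ids)
})
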