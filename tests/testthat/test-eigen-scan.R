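test_that("SNP-count windows are exact runs with remainders discarded", {
  set.seed(1)
  f <- makeFreqTable(cbind(SRC = runif(650, 0.1, 0.5),
                           P1 = runif(650)), "SRC",
                     pos = sort(sample.int(1e6, 650)))
  w <- buildWindows(f, 200L)
  expect_identical(nrow(w), 3L)
  expect_identical(w$startIdx, c(1L, 201L, 401L))
  expect_identical(w$endIdx, c(200L, 400L, 600L))

  f200 <- makeFreqTable(cbind(SRC = runif(200, 0.1, 0.5),
                              P1 = runif(200)), "SRC")
  expect_identical(nrow(buildWindows(f200, 200L)), 1L)

  f199 <- makeFreqTable(cbind(SRC = runif(199, 0.1, 0.5),
                              P1 = runif(199)), "SRC")
  expect_message(w0 <- buildWindows(f199, 200L), "fewer than")
  expect_identical(nrow(w0), 0L)
})

test_that("the change matrix is element-wise derived minus source", {
  f <- makeFreqTable(cbind(SRC = 0.2, P1 = 0.5, P2 = 0.2), "SRC",
                     pos = 10L)
  X <- deltaMatrix(f, 1L)@X
  expect_equal(unname(X["P1", 1]), 0.3)
  expect_equal(unname(X["P2", 1]), 0)

  set.seed(2)
  freq <- cbind(SRC = runif(30, 0.05, 0.5), P1 = runif(30), P2 = runif(30),
                P3 = runif(30))
  f2 <- makeFreqTable(freq, "SRC")
  X2 <- deltaMatrix(f2, 1:30, c("P1", "P2", "P3"))@X
  for (pop in c("P1", "P2", "P3"))
    expect_equal(unname(X2[pop, ]), unname(freq[, pop] - freq[, "SRC"]))
  # row order follows the supplied population order
  expect_identical(rownames(deltaMatrix(f2, 1:30, c("P3", "P1", "P2"))@X),
                   c("P3", "P1", "P2"))
})

test_that("row normalization yields unit vectors and flags zero rows", {
  # 3-4-5 triangle, scaled into the admissible change range
  w <- normalizeRows(makeWindow(rbind(c(0.3, 0.4))))
  expect_equal(unname(w@X[1, ]), c(0.6, 0.8))

  u <- makeWindow(rbind(c(0.6, 0.8)))
  expect_equal(normalizeRows(u)@X, normalizeRows(normalizeRows(u))@X)

  set.seed(3)
  r <- normalizeRows(makeWindow(matrix(runif(200, -1, 1) / 2, 1)))
  expect_equal(sqrt(sum(r@X^2)), 1, tolerance = 1e-12)

  z <- makeWindow(rbind(c(0.1, 0.2), c(0, 0)))
  expect_message(z <- normalizeRows(z), "all-zero")
  expect_false(z@usable)
  expect_error(eigenDecompose(z), "unusable")
})

test_that("constructed windows give their known spectra", {
  v <- rep(1 / sqrt(200), 200)

  ident <- eigenDecompose(makeWindow(rbind(v, v, v, v), normalized = TRUE))
  expect_equal(eigenValues(ident), c(4, 0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(eigenVectors(ident)[, 1]), rep(0.5, 4),
               tolerance = 1e-12)

  ortho <- eigenDecompose(makeWindow(diag(4L), normalized = TRUE))
  expect_equal(eigenValues(ortho), rep(1, 4), tolerance = 1e-12)

  w <- c(1, -1, rep(0, 198)) / sqrt(2)
  vv <- c(1, 1, rep(0, 198)) / sqrt(2)
  pairs <- eigenDecompose(makeWindow(rbind(vv, vv, w, w),
                                     normalized = TRUE))
  expect_equal(eigenValues(pairs), c(2, 2, 0, 0), tolerance = 1e-12)

  alt <- eigenDecompose(makeWindow(rbind(v, -v, v, -v), normalized = TRUE))
  expect_equal(eigenValues(alt)[1], 4, tolerance = 1e-12)
  expect_equal(unname(eigenVectors(alt)[, 1]), c(0.5, -0.5, 0.5, -0.5),
               tolerance = 1e-12)
})

test_that("spectra satisfy trace, bounds, orthonormality and an SVD oracle", {
  set.seed(4)
  for (i in 1:100) {
    w <- randomUnitWindow(4L, 200L)
    e <- eigenDecompose(w)
    lam <- eigenValues(e)
    expect_lt(abs(sum(lam) - 4), 1e-8)
    expect_gt(min(lam), -1e-10)
    expect_lt(lam[1], 4 + 1e-8)
    expect_gt(lam[1], 1 - 1e-8)
    G <- crossprod(eigenVectors(e))
    expect_lt(max(abs(G - diag(4))), 1e-8)
    # independent route: squared singular values of X itself
    expect_lt(max(abs(lam - svd(w@X)$d^2)), 1e-9)
  }
})

test_that("eigenvalues are invariant to SNP order, scaling, and row order", {
  set.seed(5)
  X <- matrix(runif(4 * 50, -0.4, 0.4), 4, 50,
              dimnames = list(paste0("P", 1:4), NULL))
  base <- eigenDecompose(normalizeRows(makeWindow(X)))

  perm <- eigenDecompose(normalizeRows(makeWindow(X[, sample.int(50)])))
  expect_equal(eigenValues(perm), eigenValues(base), tolerance = 1e-12)

  scaled <- X
  scaled[2, ] <- scaled[2, ] * 1.7  # positive rescale dies in normalization
  expect_equal(eigenValues(eigenDecompose(normalizeRows(
    makeWindow(scaled)))), eigenValues(base), tolerance = 1e-12)

  rows <- c(3, 1, 4, 2)
  rperm <- eigenDecompose(normalizeRows(makeWindow(X[rows, ])))
  expect_equal(eigenValues(rperm), eigenValues(base), tolerance = 1e-12)
  V1 <- eigenVectors(base)[, 1]
  V1p <- eigenVectors(rperm)[, 1]
  # loadings follow the populations up to the overall sign convention
  agree <- max(abs(V1p - V1[rows]), abs(V1p + V1[rows]))
  expect_lt(min(max(abs(V1p - V1[rows])), max(abs(V1p + V1[rows]))), 1e-10)
})

test_that("direction labels follow loading signs with a zero threshold", {
  mk <- function(load1) {
    V <- diag(4)
    V[, 1] <- load1
    # orthonormalize remaining columns against load1 via QR for validity
    V <- qr.Q(qr(cbind(load1, diag(4)[, 1:3])))
    if (V[1, 1] < 0) V <- -V
    new("EigenResult", chrom = "chr1", startBp = 1L, endBp = 2L,
        snpIdx = 1:2, values = c(4, 0, 0, 0),
        vectors = matrix(V, 4, 4, dimnames = list(paste0("P", 1:4), NULL)))
  }
  par <- classifyDirection(mk(c(0.5, 0.5, 0.5, 0.5)))
  expect_identical(par$label, "parallel")
  anti <- classifyDirection(mk(c(0.5, -0.5, 0.5, -0.5)))
  expect_identical(anti$label, "antiparallel")
  expect_setequal(anti$partition$positive, c("P1", "P3"))
  expect_setequal(anti$partition$negative, c("P2", "P4"))
  ind <- classifyDirection(mk(c(0.7, 0.7, 0.1414, 0)))
  expect_identical(ind$label, "indeterminate")
  expect_identical(unname(ind$signs[4]), "indeterminate")
})

test_that("the genome scan reproduces per-window eigendecompositions", {
  set.seed(6)
  freq <- cbind(SRC = runif(450, 0.05, 0.5), P1 = runif(450),
                P2 = runif(450), P3 = runif(450), P4 = runif(450))
  f <- makeFreqTable(freq, "SRC", pos = sort(sample.int(1e6, 450)))
  scan <- scanEigen(f, 100L)
  tab <- windowTable(scan)
  expect_identical(nrow(tab), 4L)
  w2 <- eigenDecompose(normalizeRows(deltaMatrix(f, 101:200)))
  expect_equal(unlist(as.data.frame(tab)[2L, paste0("lambda", 1:4)],
                      use.names = FALSE),
               eigenValues(w2), tolerance = 1e-12)
  expect_equal(unlist(as.data.frame(tab)[2L, paste0("loading_P", 1:4)],
                      use.names = FALSE),
               unname(eigenVectors(w2)[, 1]), tolerance = 1e-12)
  expect_equal(scanStatistics(scan, 2L),
               tab$lambda1 + tab$lambda2)
})
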