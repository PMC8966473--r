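#' Partition SNPs into windows of a fixed SNP count
#'
#' Splits each chromosome's SNPs (in coordinate order) into consecutive,
#' non-overlapping runs of exactly `snpsPerWindow` SNPs. A terminal remainder
#' shorter than the window is discarded, so every analysed window carries the
#' same number of SNPs and is exchangeable with the permutation null.
#'
#' @param freqs an [AlleleFreqTable].
#' @param snpsPerWindow SNPs per window (default 200).
#' @return a `DataFrame` with chrom, startIdx, endIdx (row indices into
#'   `freqs`), startBp, endBp.
#' @export
buildWindows <- function(freqs, snpsPerWindow = 200L) {
  stopifnot(snpsPerWindow >= 2)
  chrom <- as.character(seqnames(freqs))
  pos <- start(rowRanges(freqs))
  out <- lapply(unique(chrom), function(ch) {
    idx <- which(chrom == ch)
    nWin <- length(idx) %/% snpsPerWindow
    if (nWin == 0L) {
      message("chromosome ", ch, " has fewer than ", snpsPerWindow,
              " SNPs; no windows")
      return(NULL)
    }
    s <- idx[(seq_len(nWin) - 1L) * snpsPerWindow + 1L]
    e <- idx[seq_len(nWin) * snpsPerWindow]
    DataFrame(chrom = ch, startIdx = s, endIdx = e,
              startBp = pos[s], endBp = pos[e])
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(DataFrame(chrom = character(), startIdx = integer(),
                     endIdx = integer(), startBp = integer(),
                     endBp = integer()))
  do.call(rbind, out)
}

#' Allele-frequency-change matrix for one window
#'
#' Builds the m x n matrix X whose entry (j, i) is the polarized-allele
#' frequency change of derived population j at SNP i, relative to the source.
#'
#' @param freqs an [AlleleFreqTable].
#' @param window integer vector of row indices into `freqs` (one window).
#' @param derived ordered derived population labels (default: all non-source
#'   populations in `freqs` column order).
#' @return a [DeltaAFWindow] with raw (un-normalized) rows.
#' @export
deltaMatrix <- function(freqs, window, derived = NULL) {
  f <- freqMatrix(freqs)
  if (is.null(derived))
    derived <- setdiff(colnames(f), metadata(freqs)$sourcePop)
  if (!all(derived %in% colnames(f)))
    stop("unknown population: ", setdiff(derived, colnames(f))[1L])
  window <- as.integer(window)
  X <- t(f[window, derived, drop = FALSE] - sourceFreqs(freqs)[window])
  rownames(X) <- derived
  chrom <- unique(as.character(seqnames(freqs))[window])
  if (length(chrom) != 1L) stop("window spans more than one chromosome")
  pos <- start(rowRanges(freqs))[window]
  new("DeltaAFWindow", chrom = chrom, startBp = min(pos), endBp = max(pos),
      snpIdx = window, X = X, normalized = FALSE, usable = TRUE)
}

#' Scale each change vector to unit length
#'
#' Divides every row of the window's X matrix by its Euclidean norm so the
#' eigenanalysis compares directions of change, not magnitudes. A window with
#' an all-zero row has no defined direction for that population and is marked
#' unusable.
#'
#' @param window a [DeltaAFWindow].
#' @return the window with unit-length rows (or flagged unusable).
#' @export
normalizeRows <- function(window) {
  norms <- sqrt(rowSums(window@X^2))
  if (any(norms == 0)) {
    message("window ", window@chrom, ":", window@startBp, "-", window@endBp,
            " has an all-zero change vector; excluded from eigenanalysis")
    window@usable <- FALSE
    window@normalized <- TRUE
    return(window)
  }
  window@X <- window@X / norms
  window@normalized <- TRUE
  window
}

#' Eigendecomposition of a window's correlation matrix
#'
#' Forms C = XX' from the row-normalized change matrix (m x m, symmetric,
#' unit diagonal) and returns its eigenvalues in descending order with
#' orthonormal loadings. Each eigenvector's sign is fixed so the first
#' population's loading is non-negative (the sign of an eigenvector is
#' mathematically arbitrary; a convention makes output reproducible).
#'
#' @param window a normalized, usable [DeltaAFWindow].
#' @return an [EigenResult].
#' @export
eigenDecompose <- function(window) {
  if (!window@normalized) stop("rows must be normalized first")
  if (!window@usable) stop("window is unusable (all-zero change vector)")
  C <- tcrossprod(window@X)
  e <- tryCatch(eigen(C, symmetric = TRUE),
                error = function(err)
                  stop("eigendecomposition failed for window ",
                       window@chrom, ":", window@startBp, "-", window@endBp))
  V <- e$vectors
  for (k in seq_len(ncol(V))) {
    piv <- which(abs(V[, k]) > 1e-10)[1L]
    if (!is.na(piv) && V[piv, k] < 0) V[, k] <- -V[, k]
  }
  dimnames(V) <- list(rownames(window@X), paste0("EV", seq_len(ncol(V))))
  new("EigenResult", chrom = window@chrom, startBp = window@startBp,
      endBp = window@endBp, snpIdx = window@snpIdx,
      values = e$values, vectors = V)
}

#' @rdname EigenResult
#' @export
setMethod("eigenValues", "EigenResult", function(x) x@values)

#' @rdname EigenResult
#' @export
setMethod("eigenVectors", "EigenResult", function(x) x@vectors)

setMethod("show", "EigenResult", function(object) {
  cat("EigenResult ", object@chrom, ":", object@startBp, "-", object@endBp,
      " (", length(object@snpIdx), " SNPs)\n", sep = "")
  cat("  lambda:", paste(signif(object@values, 4), collapse = ", "), "\n")
})

#' Classify the direction of shared allele-frequency change
#'
#' Reads the per-population loading signs on one eigenvector: all-equal signs
#' mean the populations move along the shared axis in the same direction
#' (parallel); mixed signs mean antiparallel change, reported with the
#' partition. A loading within 1e-10 of zero is labelled indeterminate and
#' blocks a parallel/antiparallel call.
#'
#' @param result an [EigenResult].
#' @param eigenvector eigenvector index (default 1).
#' @return a list with `signs` (per-population "+", "-" or "indeterminate"),
#'   `label` ("parallel", "antiparallel" or "indeterminate") and, for
#'   antiparallel calls, `partition` (the two sign groups).
#' @export
classifyDirection <- function(result, eigenvector = 1L) {
  m <- length(eigenValues(result))
  stopifnot(eigenvector >= 1, eigenvector <= m)
  v <- eigenVectors(result)[, eigenvector]
  signs <- ifelse(abs(v) <= 1e-10, "indeterminate", ifelse(v > 0, "+", "-"))
  names(signs) <- rownames(eigenVectors(result))
  if (any(signs == "indeterminate"))
    return(list(signs = signs, label = "indeterminate", partition = NULL))
  if (length(unique(signs)) == 1L)
    return(list(signs = signs, label = "parallel", partition = NULL))
  list(signs = signs, label = "antiparallel",
       partition = list(positive = names(signs)[signs == "+"],
                        negative = names(signs)[signs == "-"]))
}

#' Genome-wide eigenanalysis of allele-frequency-change windows
#'
#' Runs the full window pipeline: SNP-count windows, ΔAF matrices, row
#' normalization, eigendecomposition and direction classification.
#'
#' @inheritParams buildWindows
#' @param derived ordered derived population labels (default: all non-source).
#' @return an [EigenScan].
#' @export
scanEigen <- function(freqs, snpsPerWindow = 200L, derived = NULL) {
  win <- buildWindows(freqs, snpsPerWindow)
  if (is.null(derived))
    derived <- setdiff(colnames(freqs), metadata(freqs)$sourcePop)
  m <- length(derived)
  # one extraction up front; the per-window math below is identical to
  # deltaMatrix() + normalizeRows() + eigenDecompose() on pure matrices
  f <- freqMatrix(freqs)
  fsrc <- sourceFreqs(freqs)
  nWin <- nrow(win)
  lam <- matrix(NA_real_, nWin, m,
                dimnames = list(NULL, paste0("lambda", seq_len(m))))
  ld1 <- matrix(NA_real_, nWin, m,
                dimnames = list(NULL, paste0("loading_", derived)))
  direction <- character(nWin)
  vecs <- vector("list", nWin)
  ok <- logical(nWin)
  for (i in seq_len(nWin)) {
    idx <- win$startIdx[i]:win$endIdx[i]
    X <- t(f[idx, derived, drop = FALSE] - fsrc[idx])
    norms <- sqrt(rowSums(X^2))
    if (any(norms == 0)) {
      message("window ", win$chrom[i], ":", win$startBp[i], "-",
              win$endBp[i], " has an all-zero change vector; excluded")
      next
    }
    e <- eigen(tcrossprod(X / norms), symmetric = TRUE)
    V <- e$vectors
    for (k in seq_len(m)) {
      piv <- which(abs(V[, k]) > 1e-10)[1L]
      if (!is.na(piv) && V[piv, k] < 0) V[, k] <- -V[, k]
    }
    dimnames(V) <- list(derived, paste0("EV", seq_len(m)))
    lam[i, ] <- e$values
    ld1[i, ] <- V[, 1L]
    res <- new("EigenResult", chrom = win$chrom[i],
               startBp = win$startBp[i], endBp = win$endBp[i],
               snpIdx = as.integer(idx), values = e$values, vectors = V)
    direction[i] <- classifyDirection(res)$label
    vecs[[i]] <- V
    ok[i] <- TRUE
  }
  windows <- if (any(ok))
    DataFrame(win[ok, c("chrom", "startBp", "endBp"), drop = FALSE],
              nSnps = win$endIdx[ok] - win$startIdx[ok] + 1L,
              DataFrame(lam[ok, , drop = FALSE]),
              DataFrame(ld1[ok, , drop = FALSE]),
              direction = direction[ok])
  else DataFrame()
  new("EigenScan", windows = windows, vectors = vecs[ok], m = as.integer(m),
      snpsPerWindow = as.integer(snpsPerWindow),
      dropped = as.integer(sum(!ok)))
}

setMethod("show", "EigenScan", function(object) {
  cat("EigenScan:", nrow(object@windows), "windows of", object@snpsPerWindow,
      "SNPs,", object@m, "derived populations")
  if (object@dropped) cat(" (", object@dropped, " dropped)", sep = "")
  cat("\n")
  if (nrow(object@windows))
    print(utils::head(as.data.frame(object@windows), 3L))
})

#' @rdname EigenScan-class
#' @param x an [EigenScan].
#' @export
windowTable <- function(x) x@windows

#' Observed test statistic per window
#'
#' lambda_1 for `eigenvector = 1`; the cumulative sum
#' lambda_1 + ... + lambda_k for k > 1 (a single lambda_k is not monotone in
#' excess parallelism).
#'
#' @param scan an [EigenScan].
#' @param eigenvector eigenvector index k.
#' @return numeric vector, one statistic per window.
#' @export
scanStatistics <- function(scan, eigenvector = 1L) {
  stopifnot(eigenvector >= 1, eigenvector <= scan@m)
  lam <- as.matrix(as.data.frame(
    scan@windows[, paste0("lambda", seq_len(eigenvector)), drop = FALSE]))
  rowSums(lam)
}
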