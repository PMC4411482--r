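# Fixed-length sequence comparison utilities.
#
# Every comparison in the package is ungapped Hamming distance between
# equal-length nucleotide strings; these helpers do it at scale via
# one-hot encoding and BLAS crossprod, in column blocks to bound memory.

DNA_CODES <- utf8ToInt("ACGT")

#' Convert equal-length sequences to an integer byte matrix
#'
#' @param seqs character vector of equal-length sequences.
#' @return integer matrix with one column per sequence (L rows).
#' @keywords internal
seq_matrix <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(integer(0), nrow = 0L, ncol = 0L))
  L <- nchar(seqs[1L])
  if (any(nchar(seqs) != L)) stop("sequences must all have the same length")
  vapply(seqs, utf8ToInt, integer(L), USE.NAMES = FALSE)
}

#' Hamming distance between two equal-length strings
#'
#' @param a,b character scalars of equal length.
#' @return integer count of mismatching positions.
#' @export
#' @examples
#' hamming("ACGT", "ACGA")
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have the same length")
  sum(charToRaw(a) != charToRaw(b))
}

# One-hot encode a block of the byte matrix: 4L x n, rows grouped by base.
one_hot_block <- function(X) {
  L <- nrow(X)
  out <- matrix(0, nrow = 4L * L, ncol = ncol(X))
  for (k in seq_along(DNA_CODES)) {
    out[(k - 1L) * L + seq_len(L), ] <- (X == DNA_CODES[k])
  }
  out
}

#' All sequence pairs within a mismatch budget
#'
#' Computes, blockwise, the Hamming distance between columns of `X` (and of
#' `Y` if given) and returns the pairs at distance `<= budget`. With a
#' single input the comparison is over unordered pairs (i < j).
#'
#' @param X integer byte matrix from [seq_matrix()].
#' @param budget maximum Hamming distance retained.
#' @param Y optional second byte matrix (cross comparison).
#' @param block column block size for the crossprod.
#' @return data.frame with columns `i`, `j`, `d`.
#' @keywords internal
hamming_pairs <- function(X, budget, Y = NULL, block = 2048L) {
  L <- nrow(X)
  self <- is.null(Y)
  if (self) Y <- X
  if (nrow(Y) != L) stop("sequence lengths differ between sets")
  nx <- ncol(X); ny <- ncol(Y)
  if (nx == 0L || ny == 0L) {
    return(data.frame(i = integer(0), j = integer(0), d = integer(0)))
  }
  xb <- split(seq_len(nx), (seq_len(nx) - 1L) %/% block)
  yb <- split(seq_len(ny), (seq_len(ny) - 1L) %/% block)
  res_i <- list(); res_j <- list(); res_d <- list(); r <- 0L
  for (ai in seq_along(xb)) {
    A <- one_hot_block(X[, xb[[ai]], drop = FALSE])
    for (bi in seq_along(yb)) {
      if (self && bi < ai) next
      B <- if (self && bi == ai) A else one_hot_block(Y[, yb[[bi]], drop = FALSE])
      D <- L - crossprod(A, B)
      hit <- which(D <= budget, arr.ind = TRUE)
      if (nrow(hit)) {
        gi <- xb[[ai]][hit[, 1L]]
        gj <- yb[[bi]][hit[, 2L]]
        keep <- if (self) gi < gj else rep(TRUE, length(gi))
        if (any(keep)) {
          r <- r + 1L
          res_i[[r]] <- gi[keep]
          res_j[[r]] <- gj[keep]
          res_d[[r]] <- as.integer(D[hit[keep, , drop = FALSE]])
        }
      }
    }
  }
  if (r == 0L) {
    return(data.frame(i = integer(0), j = integer(0), d = integer(0)))
  }
  data.frame(i = unlist(res_i), j = unlist(res_j), d = unlist(res_d))
}

# Union-find over n items; edges given as parallel integer vectors.
# Returns component membership labelled 1..k in first-appearance order.
uf_components <- function(n, ei, ej) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(ei)) {
    a <- find(ei[k]); b <- find(ej[k])
    if (a != b) parent[if (a < b) b else a] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
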