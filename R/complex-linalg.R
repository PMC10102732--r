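# Dense complex linear algebra helpers. Base R's det() and the Matrix
# package's expm() are real-only, so the 4x4 complex systems here get their
# own determinant (LU with partial pivoting) and matrix exponential
# (scaling-and-squaring with a [13/13] Pade approximant).

#' Determinant of a complex square matrix
#'
#' LU factorisation with partial pivoting; works for any square complex
#' matrix (base `det()` rejects complex input).
#'
#' @param A complex square matrix.
#' @return Complex scalar determinant.
#' @export
complex_det <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  stopifnot(n == ncol(A))
  storage.mode(A) <- "complex"
  d <- 1 + 0i
  for (k in seq_len(n - 1L)) {
    p <- which.max(Mod(A[k:n, k])) + k - 1L
    if (Mod(A[p, k]) == 0) return(0 + 0i)
    if (p != k) {
      A[c(k, p), ] <- A[c(p, k), ]
      d <- -d
    }
    piv <- A[k, k]
    rows <- (k + 1L):n
    A[rows, ] <- A[rows, ] - (A[rows, k] / piv) %o% A[k, ]
  }
  d * prod(diag(A))
}

#' Matrix exponential for complex matrices
#'
#' Scaling-and-squaring with a diagonal Pade approximant, following the
#' standard Higham recipe; accepts real or complex square matrices.
#'
#' @param A square matrix.
#' @return `exp(A)` as a complex matrix.
#' @export
complex_expm <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  stopifnot(n == ncol(A))
  storage.mode(A) <- "complex"
  nrmA <- max(rowSums(Mod(A)))   # infinity norm
  s <- max(0L, ceiling(log2(max(nrmA, .Machine$double.xmin) / 5.4)))
  A <- A / 2^s
  # [13/13] Pade coefficients
  b <- c(64764752532480000, 32382376266240000, 7771770303897600,
         1187353796428800, 129060195264000, 10559470521600, 670442572800,
         33522128640, 1323241920, 40840800, 960960, 16380, 182, 1)
  I <- diag(1 + 0i, n)
  A2 <- A %*% A
  A4 <- A2 %*% A2
  A6 <- A2 %*% A4
  U <- A %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
                b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * I)
  V <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
    b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * I
  E <- solve(V - U, V + U)
  for (k in seq_len(s)) E <- E %*% E
  E
}

# phi functions for one exact step of the driven linear system:
#   phi0 = expm(A h); phi1 = \int_0^h expm(A u) du; phi2 = \int_0^h u expm(A u) du
# Computed by the Van Loan augmented-matrix trick so singular A needs no
# special case: for M = [[A, I, 0], [0, 0, I], [0, 0, 0]], expm(M h) carries
# phi1 in block (1,2) and \int_0^h expm(A(h-s)) s ds = h phi1 - phi2 in (1,3).
phi_step <- function(A, h) {
  n <- nrow(A)
  Z <- matrix(0 + 0i, n, n)
  I <- diag(1 + 0i, n)
  M <- rbind(cbind(A, I, Z),
             cbind(Z, Z, I),
             cbind(Z, Z, Z))
  E <- complex_expm(M * h)
  ix <- seq_len(n)
  phi1 <- E[ix, n + ix, drop = FALSE]
  list(phi0 = E[ix, ix, drop = FALSE],
       phi1 = phi1,
       phi2 = h * phi1 - E[ix, 2 * n + ix, drop = FALSE])
}
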