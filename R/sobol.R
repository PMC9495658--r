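# Sobol' low-discrepancy sequence, Gray-code construction.
# Direction numbers from the Joe & Kuo "new-joe-kuo-6" table (first 13
# dimensions), enough for Saltelli sampling of models with up to 6
# inputs.
.JOE_KUO <- list(
  list(s = 1, a = 0,  m = c(1)),
  list(s = 2, a = 1,  m = c(1, 3)),
  list(s = 3, a = 1,  m = c(1, 3, 1)),
  list(s = 3, a = 2,  m = c(1, 1, 1)),
  list(s = 4, a = 1,  m = c(1, 1, 3, 3)),
  list(s = 4, a = 4,  m = c(1, 3, 5, 13)),
  list(s = 5, a = 2,  m = c(1, 1, 5, 5, 17)),
  list(s = 5, a = 4,  m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7,  m = c(1, 1, 7, 11, 19)),
  list(s = 5, a = 11, m = c(1, 1, 5, 1, 1)),
  list(s = 5, a = 13, m = c(1, 1, 1, 3, 11)),
  list(s = 5, a = 14, m = c(1, 3, 5, 5, 31))
)

#' Sobol' quasi-random sequence
#'
#' First `n` points (after the origin) of the unscrambled Sobol'
#' sequence in `dim` dimensions, by the Gray-code recursion with
#' Joe-Kuo direction numbers.
#'
#' @param n Number of points.
#' @param dim Dimension (1 to 13).
#' @return An `n x dim` matrix in the open unit hypercube.
#' @export
sobol_sequence <- function(n, dim) {
  if (dim < 1 || dim > length(.JOE_KUO) + 1)
    stop("dim must be between 1 and ", length(.JOE_KUO) + 1)
  if (n < 1) stop("n must be >= 1")
  L <- ceiling(log2(n + 1))
  Vi <- matrix(0L, nrow = L, ncol = dim)
  Vi[, 1] <- bitwShiftL(1L, L - seq_len(L))      # van der Corput
  if (dim > 1) for (d in 2:dim) {
    p <- .JOE_KUO[[d - 1]]
    s <- p$s; a <- p$a
    mm <- integer(max(L, s))
    mm[seq_len(s)] <- p$m
    if (L > s) for (j in (s + 1):L) {
      mm[j] <- bitwXor(mm[j - s], bitwShiftL(mm[j - s], s))
      if (s > 1) for (t in 1:(s - 1)) {
        if (bitwAnd(bitwShiftR(a, s - 1 - t), 1L) == 1L)
          mm[j] <- bitwXor(mm[j], bitwShiftL(mm[j - t], t))
      }
    }
    Vi[, d] <- bitwShiftL(mm[seq_len(L)], L - seq_len(L))
  }
  X <- matrix(0, nrow = n, ncol = dim)
  state <- integer(dim)
  for (i in seq_len(n)) {
    v <- i - 1L; c <- 1L
    while (bitwAnd(v, 1L) == 1L) { v <- bitwShiftR(v, 1L); c <- c + 1L }
    state <- bitwXor(state, Vi[c, ])
    X[i, ] <- state / 2^L
  }
  X
}
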