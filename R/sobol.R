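# Sobol low-discrepancy sequence, Gray-code order, up to 10 dimensions.
# Direction numbers come from the standard primitive-polynomial tables
# (degree s, coefficient a, initial odd integers m_1..m_s per dimension).
# 30-bit resolution keeps all integer work inside R's 32-bit signed range.

SOBOL_BITS <- 30L

# dimension 1 is the van der Corput sequence (all m = 1, handled separately)
SOBOL_TABLE <- list(
  list(s = 1L, a = 0L, m = c(1L)),              # dim 2
  list(s = 2L, a = 1L, m = c(1L, 3L)),          # dim 3
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),      # dim 4
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),      # dim 5
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),  # dim 6
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)), # dim 7
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L)), # dim 8
  list(s = 5L, a = 4L, m = c(1L, 1L, 5L, 5L, 5L)),  # dim 9
  list(s = 5L, a = 7L, m = c(1L, 1L, 7L, 11L, 19L)) # dim 10
)

# direction numbers v_k (as integers scaled by 2^SOBOL_BITS) for one dimension
sobol_directions <- function(dim, bits = SOBOL_BITS) {
  if (dim == 1L) {
    m <- rep(1L, bits)
  } else {
    par <- SOBOL_TABLE[[dim - 1L]]
    s <- par$s
    m <- integer(bits)
    m[seq_len(min(s, bits))] <- par$m[seq_len(min(s, bits))]
    if (bits > s) {
      abits <- as.integer(intToBits(par$a))[seq_len(max(s - 1L, 1L))]
      for (k in (s + 1L):bits) {
        mk <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
        if (s > 1L) for (i in seq_len(s - 1L)) {
          if (abits[s - i] == 1L)  # coefficient of x^(s-i) term
            mk <- bitwXor(mk, bitwShiftL(m[k - i], i))
        }
        m[k] <- mk
      }
    }
  }
  vapply(seq_len(bits), function(k) bitwShiftL(m[k], bits - k), integer(1))
}

#' Raw Sobol points on the unit hypercube
#'
#' Gray-code generation: point `i` is point `i-1` XORed with the direction
#' number indexed by the lowest zero bit of `i-1`. Index 0 is the origin.
#'
#' @param n number of points (starting at index 0).
#' @param d dimension, at most 10.
#' @return `n x d` matrix in `[0, 1)`.
#' @export
sobol_points <- function(n, d) {
  n <- stop_if_not_scalar_count(n, "n")
  d <- stop_if_not_scalar_count(d, "d")
  if (d > length(SOBOL_TABLE) + 1L)
    stop(sprintf("Sobol direction-number table covers at most %d dimensions",
                 length(SOBOL_TABLE) + 1L))
  v <- vapply(seq_len(d), sobol_directions, integer(SOBOL_BITS))
  x <- matrix(0, nrow = n, ncol = d)
  acc <- integer(d)
  if (n > 1L) for (i in 2:n) {
    im1 <- i - 2L  # previous index in 0-based counting
    c <- 1L
    while (bitwAnd(bitwShiftR(im1, c - 1L), 1L) == 1L) c <- c + 1L
    acc <- bitwXor(acc, v[c, ])
    x[i, ] <- acc / 2^SOBOL_BITS
  }
  x
}
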