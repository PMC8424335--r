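# Internal polynomial arithmetic on coefficient vectors in descending powers.
# The zero polynomial is c(0); constants are length-1 vectors.

poly_trim <- function(p, tol = 0) {
  p <- as.numeric(p)
  if (length(p) == 0L) return(0)
  scale <- max(abs(p))
  if (scale == 0) return(0)
  keep <- abs(p) > tol * scale
  first <- which(keep)[1L]
  if (is.na(first)) return(0)
  p[first:length(p)]
}

poly_deg <- function(p) length(poly_trim(p)) - 1L

poly_is_zero <- function(p) length(p) == 1L && p[1L] == 0

poly_add <- function(p, q) {
  np <- length(p); nq <- length(q); n <- max(np, nq)
  poly_trim(c(rep(0, n - np), p) + c(rep(0, n - nq), q))
}

poly_scale <- function(p, k) {
  if (k == 0) return(0)
  p * k
}

poly_mul <- function(p, q) {
  if (poly_is_zero(p) || poly_is_zero(q)) return(0)
  # outer-product convolution; exact for modest degrees
  n <- length(p); m <- length(q)
  r <- numeric(n + m - 1L)
  for (i in seq_len(n)) r[i:(i + m - 1L)] <- r[i:(i + m - 1L)] + p[i] * q
  poly_trim(r)
}

# Horner evaluation; works for complex s
poly_eval <- function(p, s) {
  r <- if (is.complex(s)) 0 + 0i else 0
  for (coef in p) r <- r * s + coef
  r
}

# polynomial long division: returns list(quotient, remainder)
poly_divmod <- function(p, q) {
  p <- poly_trim(p); q <- poly_trim(q)
  if (poly_is_zero(q)) stop("division by the zero polynomial")
  dp <- length(p) - 1L; dq <- length(q) - 1L
  if (dp < dq) return(list(quotient = 0, remainder = p))
  quot <- numeric(dp - dq + 1L)
  rem <- p
  for (i in seq_len(dp - dq + 1L)) {
    c0 <- rem[1L] / q[1L]
    quot[i] <- c0
    sub <- c(c0 * q, rep(0, length(rem) - dq - 1L))
    rem <- (rem - sub)[-1L]
    if (length(rem) == 0L) { rem <- 0; break }
  }
  list(quotient = poly_trim(quot), remainder = poly_trim(rem, tol = 1e-14))
}

# monic polynomial from a set of (possibly complex) roots, coerced real
poly_from_roots <- function(roots) {
  p <- 1
  for (r in roots) p <- poly_mul_complex(p, c(1, -r))
  re <- Re(p)
  im <- if (is.complex(p)) max(abs(Im(p))) else 0
  if (im > 1e-8 * max(1, max(abs(re))))
    warning("poly_from_roots: imaginary residue ", format(im))
  poly_trim(re)
}

poly_mul_complex <- function(p, q) {
  n <- length(p); m <- length(q)
  r <- complex(real = numeric(n + m - 1L))
  for (i in seq_len(n)) r[i:(i + m - 1L)] <- r[i:(i + m - 1L)] + p[i] * q
  r
}

poly_roots <- function(p) {
  p <- poly_trim(p)
  if (length(p) <= 1L) return(complex(0))
  polyroot(rev(p))
}

# Taylor coefficients of p about s0: p(s0 + e) = sum_k a_k e^k, returns a_0..a_k
poly_shift <- function(p, s0, k) {
  # repeated synthetic division by (s - s0)
  out <- complex(real = numeric(k + 1L))
  rem <- as.complex(p)
  for (j in 0:k) {
    if (length(rem) == 0L) break
    # evaluate/deflate: divide rem by (s - s0)
    n <- length(rem)
    q <- complex(real = numeric(max(n - 1L, 0L)))
    acc <- 0 + 0i
    for (i in seq_len(n)) {
      acc <- if (i == 1L) rem[1L] else acc * s0 + rem[i]
      if (i < n) q[i] <- acc
    }
    out[j + 1L] <- acc
    rem <- q
  }
  out
}
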