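#' Rational transfer functions
#'
#' `rf()` builds a scalar rational function `num(s)/den(s)` (or in `z` for
#' discrete-time entries) from coefficient vectors in descending powers. The
#' denominator is normalized to be monic; the zero function is canonically
#' `num = 0, den = 1`. These are the entries of the matrix transfer functions
#' `W(s)`, `V(s)`, `Q(s)`, `P(s)` and `G(s)` used throughout the package.
#'
#' @param num numeric vector of numerator coefficients, descending powers.
#' @param den numeric vector of denominator coefficients, descending powers;
#'   the leading coefficient must be nonzero.
#' @param var transform variable, `"s"` (Laplace) or `"z"` (z-transform).
#' @return an object of class `rf`.
#' @examples
#' r <- rf(1, c(1, 2))       # 1/(s+2)
#' tf_eval_rf(r, 0)          # 0.5
#' @export
rf <- function(num, den = 1, var = c("s", "z")) {
  var <- match.arg(var)
  num <- poly_trim(num)
  den <- poly_trim(den)
  if (poly_is_zero(den)) stop("rf: denominator is identically zero")
  k <- den[1L]
  num <- num / k
  den <- den / k
  if (poly_is_zero(num)) { num <- 0; den <- 1 }
  structure(list(num = num, den = den, var = var), class = "rf")
}

#' @export
print.rf <- function(x, ...) {
  fmt <- function(p) paste(signif(p, 6), collapse = " ")
  cat(sprintf("rf[%s]: (%s) / (%s)\n", x$var, fmt(x$num), fmt(x$den)))
  invisible(x)
}

#' @rdname rf
#' @export
rf_zero <- function(var = "s") rf(0, 1, var)

as_rf <- function(x, var = "s") {
  if (inherits(x, "rf")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(rf(x, 1, var))
  stop("cannot coerce to rf")
}

#' @rdname rf
#' @export
rf_is_zero <- function(x) poly_is_zero(x$num)

rf_degree <- function(x) c(num = poly_deg(x$num), den = poly_deg(x$den))

#' @rdname rf
#' @export
rf_proper <- function(x) rf_is_zero(x) || poly_deg(x$num) <= poly_deg(x$den)

#' @rdname rf
#' @export
rf_strictly_proper <- function(x) rf_is_zero(x) || poly_deg(x$num) < poly_deg(x$den)

#' @rdname rf
#' @export
rf_poles <- function(x) poly_roots(x$den)

#' @rdname rf
#' @export
rf_stable <- function(x) {
  p <- rf_poles(x)
  if (length(p) == 0L) return(TRUE)
  if (x$var == "s") all(Re(p) < 0) else all(Mod(p) < 1)
}

check_var <- function(a, b) {
  if (a$var != b$var) stop("rf: mixed transform variables (s vs z)")
  a$var
}

rf_add <- function(a, b) {
  v <- check_var(a, b)
  if (rf_is_zero(a)) return(b)
  if (rf_is_zero(b)) return(a)
  rf(poly_add(poly_mul(a$num, b$den), poly_mul(b$num, a$den)),
     poly_mul(a$den, b$den), v)
}

rf_neg <- function(a) rf(-a$num, a$den, a$var)

rf_sub <- function(a, b) rf_add(a, rf_neg(b))

rf_mul <- function(a, b) {
  v <- check_var(a, b)
  if (rf_is_zero(a) || rf_is_zero(b)) return(rf_zero(v))
  rf(poly_mul(a$num, b$num), poly_mul(a$den, b$den), v)
}

rf_reciprocal <- function(a) {
  if (rf_is_zero(a)) stop("rf: reciprocal of the zero function")
  rf(a$den, a$num, a$var)
}

rf_div <- function(a, b) rf_mul(a, rf_reciprocal(b))

#' @export
Ops.rf <- function(e1, e2) {
  if (.Generic %in% c("+", "-", "*", "/")) {
    if (missing(e2)) {
      if (.Generic == "-") return(rf_neg(e1))
      return(e1)
    }
    v <- if (inherits(e1, "rf")) e1$var else e2$var
    a <- as_rf(e1, v); b <- as_rf(e2, v)
    return(switch(.Generic,
      "+" = rf_add(a, b), "-" = rf_sub(a, b),
      "*" = rf_mul(a, b), "/" = rf_div(a, b)))
  }
  stop("operation '", .Generic, "' not defined for rf objects")
}

# ---- state-space bridge ------------------------------------------------------

# controllable canonical realization of a proper rf: list(A, b, c, d)
rf_ss <- function(x) {
  if (!rf_proper(x)) stop("rf_ss: transfer function is not proper")
  if (rf_is_zero(x)) return(list(A = matrix(0, 0, 0), b = numeric(0),
                                 c = numeric(0), d = 0))
  dv <- poly_divmod(x$num, x$den)
  d <- if (poly_is_zero(dv$quotient)) 0 else dv$quotient[1L]
  num <- dv$remainder
  n <- poly_deg(x$den)
  if (n == 0L) return(list(A = matrix(0, 0, 0), b = numeric(0),
                           c = numeric(0), d = d))
  a <- x$den[-1L]                       # den is monic
  A <- rbind(-a, cbind(diag(1, n - 1L, n - 1L), rep(0, n - 1L)))
  if (n == 1L) A <- matrix(-a, 1L, 1L)
  b <- c(1, rep(0, n - 1L))
  cc <- numeric(n)
  if (!poly_is_zero(num)) cc[(n - length(num) + 1L):n] <- num
  list(A = unname(A), b = b, c = cc, d = d)
}

# transfer function of (A,b,c,d) by Faddeev-LeVerrier (exact adjugate/charpoly)
ss_to_rf <- function(A, b, c, d = 0, var = "s") {
  n <- nrow(A)
  if (is.null(n) || n == 0L) return(rf(d, 1, var))
  den <- numeric(n + 1L); den[1L] <- 1
  numc <- numeric(n)
  M <- diag(1, n)
  for (k in seq_len(n)) {
    numc[k] <- as.numeric(c %*% M %*% b)
    AM <- A %*% M
    den[k + 1L] <- -sum(diag(AM)) / k
    M <- AM + den[k + 1L] * diag(1, n)
  }
  num <- poly_add(numc, poly_scale(den, d))
  # drop leading coefficients at cancellation-noise level
  rf(poly_trim(num, tol = 1e-9), den, var)
}

#' Minimal realization / common-factor cancellation
#'
#' Cancels common numerator/denominator factors of a rational function by
#' projecting a controllable canonical realization onto its observable
#' subspace (SVD rank decision on the row-normalized observability matrix),
#' then reconstructing the transfer function. Robust to repeated and
#' clustered poles, where root-pairing cancellation breaks down.
#'
#' @param x an [rf()] object.
#' @param tol relative singular-value threshold for the observable-subspace
#'   rank decision.
#' @return simplified `rf` of minimal order.
#' @export
rf_simplify <- function(x, tol = 1e-8) {
  if (rf_is_zero(x) || poly_deg(x$den) == 0L) return(x)
  if (!rf_proper(x)) {
    dv <- poly_divmod(x$num, x$den)
    strict <- rf_simplify(rf(dv$remainder, x$den, x$var), tol)
    return(rf(poly_add(poly_mul(dv$quotient, strict$den), strict$num),
              strict$den, x$var))
  }
  # rescale the transform variable so poles are O(1): conditions the
  # companion-form observability computation and centers the verification
  # annulus on the pole cluster
  poles0 <- poly_roots(x$den)
  mags <- Mod(poles0)
  mags <- mags[mags > 1e-12 * max(mags, 1)]
  rho <- if (length(mags)) exp(mean(log(mags))) else var_scale(x$den)
  if (!is.finite(rho) || rho <= 0) rho <- 1
  xs <- rf_scale_var(x, rho)
  ss <- rf_ss(xs)
  n <- length(ss$b)
  if (n == 0L) return(x)
  O <- matrix(0, n, n)
  v <- ss$c
  for (i in seq_len(n)) {
    nv <- sqrt(sum(v^2))
    O[i, ] <- if (nv > 0) v / nv else v
    v <- as.numeric(v %*% ss$A)
  }
  sv <- svd(O)
  ranks <- unique(pmin(n, c(sum(sv$d > 1e-7 * sv$d[1L]),
                            sum(sv$d > 1e-10 * sv$d[1L]),
                            sum(sv$d > 1e-13 * sv$d[1L]))))
  ranks <- sort(ranks[ranks < n])
  # verification points on several radii, kept away from the scaled poles
  poles <- poles0 / rho
  s_test <- as.vector(outer(exp(2i * pi * (1:5) / 5 + 0.19i),
                            c(0.032, 0.1, 0.32, 1, 3.2, 10)))
  if (length(poles))
    s_test <- s_test[apply(abs(outer(s_test, poles, "-")), 1L,
                           min) > 0.05 * abs(s_test)]
  if (length(s_test) < 6L)
    s_test <- 5.3 * exp(2i * pi * (1:11) / 11 + 0.41i)
  ref <- tf_eval_rf_raw(xs, s_test)
  sc <- max(abs(ref), 1e-300)
  ok_fit <- function(val) all(abs(val - ref) <= tol * pmax(abs(ref), 1e-6 * sc))
  for (r in ranks) {
    if (r == 0L) {
      red <- rf(ss$d, 1, x$var)   # constant feedthrough only
      if (ok_fit(rep(complex(real = ss$d), length(s_test)))) return(red)
      next
    }
    Vr <- sv$v[, seq_len(r), drop = FALSE]
    red <- ss_to_rf(t(Vr) %*% ss$A %*% Vr, as.numeric(t(Vr) %*% ss$b),
                    as.numeric(ss$c %*% Vr), ss$d, x$var)
    if (ok_fit(tf_eval_rf_raw(red, s_test)))
      return(rf_scale_var(red, 1 / rho))
  }
  x
}

# upper root-magnitude bound (Cauchy-style) used as a variable scale
var_scale <- function(den) {
  n <- length(den) - 1L
  if (n < 1L) return(1)
  mags <- abs(den[-1L] / den[1L])
  k <- seq_len(n)
  rho <- max(mags^(1 / k), na.rm = TRUE)
  if (!is.finite(rho) || rho <= 0) 1 else rho
}

# substitute s -> rho * s (poles divided by rho)
rf_scale_var <- function(x, rho) {
  if (rho == 1) return(x)
  dn <- poly_deg(x$num); dd <- poly_deg(x$den)
  num <- x$num * rho^(dn:0)
  den <- x$den * rho^(dd:0)
  rf(num, den, x$var)
}

# ---- transfer matrices -------------------------------------------------------

#' Matrix transfer functions
#'
#' A `tfm` is a rows x cols grid of [rf()] entries sharing one transform
#' variable, with row and column identifiers. Used for the network structure
#' Q(s), control structure P(s), the precursors W(s), V(s) and the closed-loop
#' map G(s).
#'
#' @param entries a list of `rf` objects (row-major) or a `rows x cols` matrix
#'   of lists; numeric scalars are promoted to constant entries.
#' @param rows,cols dimensions.
#' @param row_names,col_names identifier character vectors.
#' @param var transform variable used for promoted numeric entries.
#' @return an object of class `tfm`.
#' @export
tfm <- function(entries, rows, cols, row_names = NULL, col_names = NULL,
                var = "s") {
  if (is.matrix(entries)) {
    rows <- nrow(entries); cols <- ncol(entries)
    entries <- t(entries)  # row-major flatten
    entries <- entries[seq_along(entries)]
  }
  if (length(entries) != rows * cols)
    stop("tfm: expected ", rows * cols, " entries, got ", length(entries))
  entries <- lapply(entries, as_rf, var = var)
  vars <- unique(vapply(entries, function(e) e$var, ""))
  if (length(vars) > 1L) stop("tfm: entries mix transform variables")
  if (is.null(row_names)) row_names <- paste0("y", seq_len(rows))
  if (is.null(col_names)) col_names <- paste0("c", seq_len(cols))
  if (length(row_names) != rows || length(col_names) != cols)
    stop("tfm: name lists inconsistent with shape")
  structure(list(entries = entries, rows = rows, cols = cols,
                 row_names = row_names, col_names = col_names,
                 var = if (length(vars)) vars else var),
            class = "tfm")
}

#' @rdname tfm
#' @export
tm_entry <- function(tm, i, j) tm$entries[[(i - 1L) * tm$cols + j]]

tm_set_entry <- function(tm, i, j, value) {
  tm$entries[[(i - 1L) * tm$cols + j]] <- value
  tm
}

tm_map <- function(tm, f) {
  tm$entries <- lapply(tm$entries, f)
  tm
}

#' @rdname tfm
#' @export
tm_identity <- function(p, var = "s", names = NULL) {
  ent <- vector("list", p * p)
  for (i in seq_len(p)) for (j in seq_len(p))
    ent[[(i - 1L) * p + j]] <- rf(as.numeric(i == j), 1, var)
  tfm(ent, p, p, row_names = names, col_names = names, var = var)
}

#' @export
print.tfm <- function(x, ...) {
  cat(sprintf("tfm[%s] %d x %d (%s | %s)\n", x$var, x$rows, x$cols,
              paste(x$row_names, collapse = ","),
              paste(x$col_names, collapse = ",")))
  for (i in seq_len(x$rows)) for (j in seq_len(x$cols)) {
    e <- tm_entry(x, i, j)
    if (!rf_is_zero(e)) {
      cat(sprintf("  [%d,%d] ", i, j)); print(e)
    }
  }
  invisible(x)
}

#' Evaluate a transfer function or transfer matrix at a point
#'
#' Entrywise Horner evaluation of `num(s0)/den(s0)`. Evaluation close to a
#' pole (denominator magnitude below `tol * max|den coeff|`) is an error
#' naming the offending entry.
#'
#' @param tm a [tfm()] object (or an [rf()] for `tf_eval_rf`).
#' @param s0 complex (or real) evaluation point.
#' @param tol pole-proximity tolerance.
#' @return complex matrix of entry values.
#' @export
tf_eval <- function(tm, s0, tol = 1e-12) {
  out <- matrix(0 + 0i, tm$rows, tm$cols,
                dimnames = list(tm$row_names, tm$col_names))
  for (i in seq_len(tm$rows)) for (j in seq_len(tm$cols)) {
    e <- tm_entry(tm, i, j)
    d <- poly_eval(e$den, as.complex(s0))
    if (abs(d) < tol * max(abs(e$den)))
      stop(sprintf("tf_eval: s0 within tolerance of a pole of entry (%d,%d)",
                   i, j))
    out[i, j] <- poly_eval(e$num, as.complex(s0)) / d
  }
  out
}

#' @rdname tf_eval
#' @export
tf_eval_rf <- function(tm, s0, tol = 1e-12) {
  e <- as_rf(tm)
  d <- poly_eval(e$den, as.complex(s0))
  if (any(abs(d) < tol * max(abs(e$den))))
    stop("tf_eval_rf: s0 within tolerance of a pole")
  v <- poly_eval(e$num, as.complex(s0)) / d
  if (all(Im(v) == 0)) Re(v) else v
}

tm_mul <- function(a, b, simplify = TRUE) {
  if (a$cols != b$rows) stop("tm_mul: shape mismatch")
  v <- a$var
  ent <- vector("list", a$rows * b$cols)
  for (i in seq_len(a$rows)) for (j in seq_len(b$cols)) {
    acc <- rf_zero(v)
    for (k in seq_len(a$cols))
      acc <- rf_add(acc, rf_mul(tm_entry(a, i, k), tm_entry(b, k, j)))
    if (simplify) acc <- rf_simplify(acc)
    ent[[(i - 1L) * b$cols + j]] <- acc
  }
  tfm(ent, a$rows, b$cols, a$row_names, b$col_names, var = v)
}

tm_sub <- function(a, b) {
  stopifnot(a$rows == b$rows, a$cols == b$cols)
  ent <- mapply(rf_sub, a$entries, b$entries, SIMPLIFY = FALSE)
  tfm(ent, a$rows, a$cols, a$row_names, a$col_names, var = a$var)
}

# determinant of a square tfm by cofactor expansion with simplification
tm_det <- function(tm) {
  n <- tm$rows
  if (n != tm$cols) stop("tm_det: matrix not square")
  if (n == 1L) return(tm_entry(tm, 1, 1))
  if (n == 2L)
    return(rf_simplify(rf_sub(rf_mul(tm_entry(tm, 1, 1), tm_entry(tm, 2, 2)),
                              rf_mul(tm_entry(tm, 1, 2), tm_entry(tm, 2, 1)))))
  acc <- rf_zero(tm$var)
  for (j in seq_len(n)) {
    e <- tm_entry(tm, 1, j)
    if (rf_is_zero(e)) next
    minor <- tm_minor(tm, 1L, j)
    term <- rf_mul(e, tm_det(minor))
    if (j %% 2L == 0L) term <- rf_neg(term)
    acc <- rf_add(acc, term)
  }
  rf_simplify(acc)
}

tm_minor <- function(tm, i, j) {
  keep_r <- setdiff(seq_len(tm$rows), i)
  keep_c <- setdiff(seq_len(tm$cols), j)
  ent <- vector("list", length(keep_r) * length(keep_c))
  k <- 1L
  for (r in keep_r) for (cc in keep_c) {
    ent[[k]] <- tm_entry(tm, r, cc); k <- k + 1L
  }
  tfm(ent, length(keep_r), length(keep_c),
      tm$row_names[keep_r], tm$col_names[keep_c], var = tm$var)
}

#' Invert a square transfer matrix
#'
#' Adjugate-over-determinant inversion with entrywise minimal-realization
#' simplification, as needed for the hidden-state resolvent and the
#' closed-loop map `(I - Q)^-1 P`.
#'
#' @param tm square [tfm()].
#' @param tol zero-detection tolerance on the determinant numerator.
#' @return the inverse `tfm`.
#' @export
tm_inverse <- function(tm, tol = 1e-12) {
  n <- tm$rows
  if (n != tm$cols) stop("tm_inverse: matrix not square")
  det <- tm_det(tm)
  if (rf_is_zero(det) || max(abs(det$num)) < tol)
    stop("tm_inverse: matrix is singular (determinant identically zero)")
  ent <- vector("list", n * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cof <- if (n == 1L) rf(1, 1, tm$var) else tm_det(tm_minor(tm, j, i))
    if ((i + j) %% 2L == 1L) cof <- rf_neg(cof)
    ent[[(i - 1L) * n + j]] <- rf_simplify(rf_div(cof, det))
  }
  tfm(ent, n, n, tm$col_names, tm$row_names, var = tm$var)
}

# ---- impulse kernels ---------------------------------------------------------

#' Impulse-response kernel of a strictly proper transfer function
#'
#' Inverse Laplace transform on a time grid by partial-fraction expansion.
#' Poles closer than `cluster_tol` (relative) are treated as one repeated
#' pole, yielding polynomial-times-exponential terms; complex-conjugate pairs
#' combine to damped sinusoids, so the returned kernel is real.
#'
#' @param x strictly proper [rf()] with `var = "s"`.
#' @param t_grid increasing vector of time points.
#' @param cluster_tol relative pole-clustering tolerance.
#' @return numeric vector of kernel values on `t_grid`.
#' @export
impulse_kernel <- function(x, t_grid, cluster_tol = 1e-7) {
  if (x$var != "s") stop("impulse_kernel: continuous-time (var = 's') only")
  if (!rf_strictly_proper(x))
    stop("impulse_kernel: transfer function must be strictly proper")
  t_grid <- as.numeric(t_grid)
  if (rf_is_zero(x)) return(numeric(length(t_grid)))
  cl <- cluster_poles(rf_poles(x), cluster_tol)
  vals <- complex(real = numeric(length(t_grid)))
  for (ci in seq_along(cl$centers)) {
    r <- cl$centers[ci]; m <- cl$mult[ci]
    # q(s) = den(s) / (s - r)^m from the other clusters (den is monic)
    q <- 1 + 0i
    for (cj in seq_along(cl$centers)) {
      if (cj == ci) next
      for (k in seq_len(cl$mult[cj]))
        q <- poly_mul_complex(q, c(1, -cl$centers[cj]))
    }
    ns <- poly_shift(x$num, r, m - 1L)
    qs <- poly_shift(q, r, m - 1L)
    g <- complex(real = numeric(m))           # series division num/q about r
    for (k in seq_len(m)) {
      acc <- ns[k]
      if (k > 1L) for (l in seq_len(k - 1L)) acc <- acc - g[l] * qs[k - l + 1L]
      g[k] <- acc / qs[1L]
    }
    # residue A_k at order k is the (m-k)-th Taylor coefficient of g
    for (k in seq_len(m)) {
      A <- g[m - k + 1L]
      vals <- vals + A * t_grid^(k - 1L) * exp(r * t_grid) / factorial(k - 1L)
    }
  }
  im <- max(abs(Im(vals)))
  sc <- max(abs(Re(vals)), 1e-300)
  if (im > 1e-6 * max(sc, 1))
    warning("impulse_kernel: imaginary residue ", format(im))
  out <- Re(vals)
  if (any(!is.finite(out))) stop("impulse_kernel: non-finite kernel values")
  out
}

cluster_poles <- function(roots, tol) {
  centers <- complex(0); mult <- integer(0)
  remaining <- roots
  while (length(remaining)) {
    r0 <- remaining[1L]
    sel <- abs(remaining - r0) <= tol * max(1, abs(r0))
    # one re-centering pass catches stragglers of a scattered multiple root
    ctr <- mean(remaining[sel])
    sel <- abs(remaining - ctr) <= tol * max(1, abs(ctr))
    centers <- c(centers, mean(remaining[sel]))
    mult <- c(mult, sum(sel))
    remaining <- remaining[!sel]
  }
  # force conjugate symmetry: a center with tiny imaginary part is made real
  reals <- abs(Im(centers)) <= tol * max(1, abs(centers))
  centers[reals] <- complex(real = Re(centers[reals]), imaginary = 0)
  list(centers = centers, mult = mult)
}

# ---- norms -------------------------------------------------------------------

#' Worst-case frequency-response gain (H-infinity norm)
#'
#' `sup_w |H(jw)|` for a stable proper transfer function, via a dense
#' log-spaced frequency sweep refined by local maximization. Discrete-time
#' entries are swept on the unit circle. Used to rank edge strengths of an
#' estimated network structure.
#'
#' @param x proper, stable [rf()].
#' @param n_grid number of sweep points.
#' @return nonnegative scalar gain.
#' @export
hinf_norm <- function(x, n_grid = 24000L) {
  if (rf_is_zero(x)) return(0)
  if (!rf_proper(x)) stop("hinf_norm: transfer function is not proper")
  p <- rf_poles(x)
  if (x$var == "s") {
    if (any(Re(p) >= 0))
      stop("hinf_norm: unstable entry (pole at ",
           format(p[which.max(Re(p))], digits = 6), ")")
    gain <- function(w) abs(tf_eval_rf_raw(x, 1i * w))
    grid <- c(0, 10^seq(-6, 6, length.out = n_grid))
    g <- gain(grid)
    i0 <- which.max(g)
    lo <- grid[max(i0 - 1L, 1L)]; hi <- grid[min(i0 + 1L, length(grid))]
    if (hi > lo) {
      opt <- stats::optimize(gain, c(lo, hi), maximum = TRUE,
                             tol = .Machine$double.eps^0.5)
      return(max(g[i0], opt$objective))
    }
    return(g[i0])
  }
  if (any(Mod(p) >= 1))
    stop("hinf_norm: unstable entry (pole at ",
         format(p[which.max(Mod(p))], digits = 6), ")")
  gain <- function(th) abs(tf_eval_rf_raw(x, exp(1i * th)))
  grid <- seq(0, pi, length.out = min(n_grid, 20001L))
  g <- gain(grid)
  i0 <- which.max(g)
  lo <- grid[max(i0 - 1L, 1L)]; hi <- grid[min(i0 + 1L, length(grid))]
  opt <- stats::optimize(gain, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  max(g[i0], opt$objective)
}

# evaluation without the pole-proximity guard (vectorized over s)
tf_eval_rf_raw <- function(x, s) {
  poly_eval(x$num, s) / poly_eval(x$den, s)
}

#' Energy gain (H2 norm)
#'
#' `sqrt((1/2pi) integral |H(jw)|^2 dw)` for a strictly proper stable
#' transfer function, computed exactly through the Lyapunov equation of a
#' state-space realization (discrete-time entries use the discrete Lyapunov
#' equation).
#'
#' @param x strictly proper, stable [rf()].
#' @return nonnegative scalar gain.
#' @export
h2_norm <- function(x) {
  if (rf_is_zero(x)) return(0)
  if (!rf_strictly_proper(x))
    stop("h2_norm: transfer function must be strictly proper")
  if (!rf_stable(x)) stop("h2_norm: unstable entry")
  ss <- rf_ss(x)
  n <- length(ss$b)
  bb <- ss$b %o% ss$b
  if (x$var == "s") {
    Pv <- solve(kronecker(diag(1, n), ss$A) + kronecker(ss$A, diag(1, n)),
                -as.numeric(bb))
  } else {
    Pv <- solve(diag(1, n * n) - kronecker(ss$A, ss$A), as.numeric(bb))
  }
  P <- matrix(Pv, n, n)
  v <- as.numeric(ss$c %*% P %*% ss$c)
  sqrt(max(v, 0))
}

# ---- sampling-domain conversion (continuous <-> discrete) --------------------

mat_expm <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

# principal matrix logarithm; eigendecomposition route with a fallback for
# defective/ill-conditioned eigenvector matrices
mat_logm <- function(M) {
  e <- tryCatch(eigen(M), error = function(err) NULL)
  if (!is.null(e)) {
    kappa <- tryCatch(kappa(e$vectors, exact = TRUE), error = function(err) Inf)
    if (is.finite(kappa) && kappa < 1e8) {
      L <- e$vectors %*% diag(log(as.complex(e$values)), nrow(M)) %*%
        solve(e$vectors)
      return(L)
    }
  }
  pracma::logm(M)
}

#' Discretize a continuous-time transfer function
#'
#' Zero-order-hold or bilinear (Tustin) sampling of an `s`-domain entry,
#' through a state-space realization. Companion to [to_continuous()].
#'
#' @param x proper [rf()] with `var = "s"`.
#' @param dt sampling interval, > 0.
#' @param method `"zoh"` or `"tustin"`.
#' @return an `rf` with `var = "z"`.
#' @export
rf_discretize <- function(x, dt, method = c("zoh", "tustin")) {
  method <- match.arg(method)
  if (x$var != "s") stop("rf_discretize: input must be continuous-time")
  if (dt <= 0) stop("rf_discretize: dt must be positive")
  if (rf_is_zero(x)) return(rf_zero("z"))
  if (method == "tustin") return(rf_bilinear(x, dt, to = "z"))
  ss <- rf_ss(x)
  n <- length(ss$b)
  if (n == 0L) return(rf(ss$d, 1, "z"))
  M <- mat_expm(rbind(cbind(ss$A * dt, ss$b * dt),
                      matrix(0, 1, n + 1L)))
  Ad <- M[seq_len(n), seq_len(n), drop = FALSE]
  bd <- M[seq_len(n), n + 1L]
  ss_to_rf(Ad, bd, ss$c, ss$d, var = "z")
}

#' Continuous-time reconstruction of a discrete transfer function
#'
#' Inverse of [rf_discretize()]: bilinear (Tustin), zero-order-hold (via the
#' matrix logarithm of a realization) or matched-pole-zero mapping from the
#' `z` to the `s` domain.
#'
#' @param x proper [rf()] with `var = "z"`.
#' @param dt sampling interval of the discrete entry.
#' @param method `"tustin"`, `"zoh"` or `"matched"`.
#' @return an `rf` with `var = "s"`.
#' @export
rf_undiscretize <- function(x, dt, method = c("tustin", "zoh", "matched")) {
  method <- match.arg(method)
  if (x$var != "z") stop("rf_undiscretize: input must be discrete-time")
  if (dt <= 0) stop("rf_undiscretize: dt must be positive")
  if (rf_is_zero(x)) return(rf_zero("s"))
  if (method == "tustin") {
    dz <- abs(poly_eval(x$den, -1 + 0i))
    if (dz < 1e-10 * max(abs(x$den)))
      stop("rf_undiscretize: denominator root at z = -1; the bilinear map ",
           "is singular there - use method = 'zoh' or 'matched'")
    return(rf_bilinear(x, dt, to = "s"))
  }
  if (method == "zoh") {
    ss <- rf_ss(x)
    n <- length(ss$b)
    if (n == 0L) return(rf(ss$d, 1, "s"))
    Ac <- mat_logm(ss$A) / dt
    if (max(abs(Im(Ac))) > 1e-6 * max(1, max(abs(Re(Ac)))))
      stop("rf_undiscretize: matrix logarithm is not real (negative real ",
           "pole); use method = 'tustin' or 'matched'")
    Ac <- Re(Ac)
    bc <- as.numeric(Ac %*% solve(ss$A - diag(1, n), ss$b))
    return(ss_to_rf(Ac, bc, ss$c, ss$d, var = "s"))
  }
  # matched poles and zeros: z0 -> log(z0)/dt, gain matched at DC
  zs <- poly_roots(x$num); ps <- poly_roots(x$den)
  num <- poly_from_roots(log(as.complex(zs)) / dt)
  den <- poly_from_roots(log(as.complex(ps)) / dt)
  lead <- x$num[1L]
  cand <- rf(poly_scale(num, lead), den, "s")
  g_z <- tryCatch(abs(tf_eval_rf_raw(x, 1 + 0i)), error = function(e) NA)
  g_s <- tryCatch(abs(tf_eval_rf_raw(cand, 0 + 0i)), error = function(e) NA)
  if (is.finite(g_z) && is.finite(g_s) && g_s > 0) {
    sgn <- sign(Re(tf_eval_rf_raw(x, 1 + 0i)) / Re(tf_eval_rf_raw(cand, 0 + 0i)))
    cand <- rf(poly_scale(cand$num, sgn * g_z / g_s), cand$den, "s")
  }
  cand
}

# bilinear substitution z = (1 + s dt/2)/(1 - s dt/2) (and its inverse)
rf_bilinear <- function(x, dt, to) {
  N <- max(poly_deg(x$num), poly_deg(x$den))
  h <- dt / 2
  if (to == "s") { up <- c(h, 1); dn <- c(-h, 1) }   # z -> (1+hs)/(1-hs)
  else { up <- c(2, -2); dn <- c(dt, dt) }           # s -> (2/dt)(z-1)/(z+1)
  subst <- function(p) {
    d <- length(p) - 1L
    acc <- 0
    for (k in 0:d) {
      term <- p[d - k + 1L]                          # coefficient of x^k
      f <- 1
      for (i in seq_len(k)) f <- poly_mul(f, up)
      for (i in seq_len(N - k)) f <- poly_mul(f, dn)
      acc <- poly_add(acc, poly_scale(f, term))
    }
    acc
  }
  num <- poly_trim(subst(x$num), tol = 1e-12)
  den <- poly_trim(subst(x$den), tol = 1e-12)
  rf(num, den, if (to == "s") "s" else "z")
}
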