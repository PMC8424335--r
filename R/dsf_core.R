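#' Partitioned linear time-invariant system
#'
#' Holds the blocks of a linearized circuit model with the measured states
#' ordered first, so that the measurement map is fixed at `C = [I 0]`:
#' \deqn{d/dt [y; x_h] = [A11 A12; A21 A22] [y; x_h] + [B1; B2] u.}
#' Measured states `y` are typically reporter proteins; hidden states `x_h`
#' are unmeasured species such as mRNA.
#'
#' @param A11 p x p matrix (measured-to-measured).
#' @param A12 p x (n-p) matrix (hidden-to-measured).
#' @param A21 (n-p) x p matrix (measured-to-hidden).
#' @param A22 (n-p) x (n-p) matrix (hidden block).
#' @param B1 p x m input map into measured states.
#' @param B2 (n-p) x m input map into hidden states.
#' @param output_names,input_names,hidden_names identifier vectors.
#' @return an object of class `partitioned_lti`.
#' @export
partitioned_lti <- function(A11, A12, A21, A22, B1, B2,
                            output_names = NULL, input_names = NULL,
                            hidden_names = NULL) {
  A11 <- as.matrix(A11); A22 <- as.matrix(A22)
  p <- nrow(A11); nh <- nrow(A22)
  A12 <- matrix(as.numeric(A12), p, nh)
  A21 <- matrix(as.numeric(A21), nh, p)
  B1 <- as.matrix(B1); m <- ncol(B1)
  B2 <- matrix(as.numeric(B2), nh, m)
  if (ncol(A11) != p || ncol(A22) != nh || nrow(B1) != p)
    stop("partitioned_lti: inconsistent block dimensions")
  if (is.null(output_names)) output_names <- paste0("y", seq_len(p))
  if (is.null(input_names)) input_names <- paste0("u", seq_len(m))
  if (is.null(hidden_names)) hidden_names <- if (nh) paste0("h", seq_len(nh)) else character(0)
  structure(list(A11 = A11, A12 = A12, A21 = A21, A22 = A22, B1 = B1, B2 = B2,
                 p = p, nh = nh, m = m, output_names = output_names,
                 input_names = input_names, hidden_names = hidden_names),
            class = "partitioned_lti")
}

lti_full <- function(sys) {
  A <- rbind(cbind(sys$A11, sys$A12), cbind(sys$A21, sys$A22))
  B <- rbind(sys$B1, sys$B2)
  list(A = A, B = B)
}

# adjugate and characteristic polynomial of (sI - A), Faddeev-LeVerrier.
# returns list(den = charpoly coeffs, M = list of n matrices, adj = sum_k M_k s^(n-k))
resolvent_adjugate <- function(A) {
  n <- nrow(A)
  den <- numeric(n + 1L); den[1L] <- 1
  M <- vector("list", n)
  Mk <- diag(1, n)
  for (k in seq_len(n)) {
    M[[k]] <- Mk
    AM <- A %*% Mk
    den[k + 1L] <- -sum(diag(AM)) / k
    Mk <- AM + den[k + 1L] * diag(1, n)
  }
  list(den = den, M = M)
}

#' Eliminate hidden states: the (W, V) precursor pair
#'
#' Computes `W(s) = A11 + A12 (sI - A22)^-1 A21` and
#' `V(s) = B1 + A12 (sI - A22)^-1 B2`, the hidden-state-eliminated dynamics of
#' the measured block. Entries are returned over the common denominator
#' `det(sI - A22)` without cancellation; [compute_QP()] simplifies.
#'
#' @param sys a [partitioned_lti()].
#' @return list with `tfm` components `W` (p x p) and `V` (p x m).
#' @export
compute_WV <- function(sys) {
  p <- sys$p; m <- sys$m; nh <- sys$nh
  vnames <- sys$output_names
  if (nh == 0L || all(sys$A12 == 0)) {
    # no hidden block, or one that cannot reach the measured states
    W <- tfm(as.list(t(sys$A11)), p, p, vnames, vnames)
    V <- tfm(as.list(t(sys$B1)), p, m, vnames, sys$input_names)
    return(list(W = W, V = V))
  }
  fl <- resolvent_adjugate(sys$A22)
  den <- fl$den
  # numerator polynomial matrices: N_W(s) = sum_k (A12 M_k A21) s^(nh-k)
  NW <- lapply(fl$M, function(Mk) sys$A12 %*% Mk %*% sys$A21)
  NV <- lapply(fl$M, function(Mk) sys$A12 %*% Mk %*% sys$B2)
  mk_entries <- function(base, Nlist, cols) {
    ent <- vector("list", p * cols)
    for (i in seq_len(p)) for (j in seq_len(cols)) {
      num <- poly_scale(den, base[i, j])
      tail_coefs <- vapply(Nlist, function(Nk) Nk[i, j], 0)
      num <- poly_add(num, tail_coefs)
      ent[[(i - 1L) * cols + j]] <- rf(num, den, "s")
    }
    ent
  }
  W <- tfm(mk_entries(sys$A11, NW, p), p, p, vnames, vnames)
  V <- tfm(mk_entries(sys$B1, NV, m), p, m, vnames, sys$input_names)
  list(W = W, V = V)
}

#' Dynamical structure function (Q, P)
#'
#' Forms the DSF from the precursor pair: with `D(s) = diag(W(s))`,
#' `Q(s) = (sI - D)^-1 (W - D)` and `P(s) = (sI - D)^-1 V`. Because `D` is
#' diagonal this is a row-wise rescaling: `Q_ij = W_ij / (s - W_ii)` off the
#' diagonal and zero on it. The construction guarantees a zero diagonal and
#' strictly proper entries, which is what makes (Q, P) unique and
#' identifiable. Entries are simplified to minimal order.
#'
#' @param W,V the precursor pair from [compute_WV()].
#' @return an object of class `dsf` with components `Q` (p x p `tfm`) and `P`
#'   (p x m `tfm`).
#' @export
compute_QP <- function(W, V) {
  p <- W$rows
  if (W$cols != p) stop("compute_QP: W must be square")
  if (V$rows != p) stop("compute_QP: V not row-conformal with W")
  s_rf <- rf(c(1, 0), 1, "s")
  Q <- tm_identity(p, names = W$row_names)
  Pm <- V
  for (i in seq_len(p)) {
    Wii <- tm_entry(W, i, i)
    # when an entry shares W_ii's denominator d(s) (the compute_WV common
    # denominator), X/(s - W_ii) collapses analytically to x_num/(s d - w_ii),
    # avoiding degree blow-up; otherwise fall back to rational division
    row_den <- poly_add(poly_mul(c(1, 0), Wii$den), -Wii$num)  # s*d - w_ii
    denom_i <- rf_sub(s_rf, Wii)
    scale_row <- function(X) {
      if (identical(X$den, Wii$den)) rf_simplify(rf(X$num, row_den, "s"))
      else rf_simplify(rf_div(X, denom_i))
    }
    for (j in seq_len(p)) {
      val <- if (i == j) rf_zero("s") else scale_row(tm_entry(W, i, j))
      Q <- tm_set_entry(Q, i, j, val)
    }
    for (j in seq_len(V$cols)) {
      Pm <- tm_set_entry(Pm, i, j, scale_row(tm_entry(V, i, j)))
    }
  }
  new_dsf(Q, Pm)
}

new_dsf <- function(Q, P, dt = NULL, check = TRUE) {
  if (check) {
    for (i in seq_len(Q$rows)) {
      if (!rf_is_zero(tm_entry(Q, i, i)))
        stop("dsf: diagonal of Q must be identically zero")
    }
    ok <- all(vapply(c(Q$entries, P$entries), rf_strictly_proper, TRUE))
    if (!ok) warning("dsf: non-strictly-proper entry (direct feedthrough); ",
                     "exact constructions are strictly proper, converted ",
                     "estimates may not be")
  }
  structure(list(Q = Q, P = P, dt = dt), class = "dsf")
}

#' @export
print.dsf <- function(x, ...) {
  cat(sprintf("Dynamical structure function: p = %d outputs, m = %d inputs (%s)\n",
              x$Q$rows, x$P$cols, if (is.null(x$dt)) "continuous"
              else paste0("discrete, dt = ", x$dt)))
  cat("Q:\n"); print(x$Q)
  cat("P:\n"); print(x$P)
  invisible(x)
}

#' Derive the DSF of a partitioned linear system
#'
#' Convenience composition of [compute_WV()] and [compute_QP()].
#'
#' @param sys a [partitioned_lti()].
#' @return a `dsf` object.
#' @export
dsf_from_lti <- function(sys) {
  wv <- compute_WV(sys)
  compute_QP(wv$W, wv$V)
}

#' Closed-loop transfer matrix of a DSF
#'
#' The system transfer function implied by `Y = Q Y + P U`, i.e.
#' `G(s) = (I - Q)^-1 P`. For a DSF derived from a partitioned system this
#' equals the direct input-output map `C (sI - A)^-1 B`.
#'
#' @param dsf a `dsf` object.
#' @return a p x m `tfm`.
#' @export
dsf_closed_loop <- function(dsf) {
  p <- dsf$Q$rows
  ImQ <- tm_sub(tm_identity(p, var = dsf$Q$var, names = dsf$Q$row_names), dsf$Q)
  tm_mul(tm_inverse(ImQ), dsf$P)
}

#' Kernel responses of a DSF
#'
#' Entrywise inverse Laplace transform `Q(t) = L^-1(Q(s))` (and `P(t)`) on a
#' time grid: the convolution kernels whose sign and magnitude over time
#' express the activating/repressing nature and time scale of each edge.
#'
#' @param dsf a continuous-time `dsf`.
#' @param t_grid increasing time grid.
#' @param which `"Q"` or `"P"`.
#' @return object of class `kernel_response`: list with `t_grid`, a
#'   `rows x cols x T` array `values`, and the entry names.
#' @export
kernel_matrix <- function(dsf, t_grid, which = c("Q", "P")) {
  which <- match.arg(which)
  M <- if (which == "Q") dsf$Q else dsf$P
  vals <- array(0, dim = c(M$rows, M$cols, length(t_grid)))
  for (i in seq_len(M$rows)) for (j in seq_len(M$cols)) {
    e <- tm_entry(M, i, j)
    if (!rf_is_zero(e)) vals[i, j, ] <- impulse_kernel(e, t_grid)
  }
  structure(list(t_grid = as.numeric(t_grid), values = vals,
                 row_names = M$row_names, col_names = M$col_names),
            class = "kernel_response")
}

#' Support and sign structure of a network structure Q(s)
#'
#' Evaluates each off-diagonal entry of `Q` on a positive real grid and labels
#' it `absent` (relative magnitude below `tol`), `activating` (positive on the
#' whole grid), `repressing` (negative on the whole grid) or `mixed`. For a
#' transcriptional circuit the sign on `s > 0` matches the regulatory role of
#' the corresponding edge.
#'
#' @param dsf a `dsf` object (or a square `tfm` taken as Q).
#' @param s_grid positive real evaluation points avoiding poles.
#' @param tol relative magnitude threshold for `absent`, against the largest
#'   entry magnitude seen on the grid.
#' @return list with logical `support` matrix and character `signs` matrix.
#' @export
structure_report <- function(dsf, s_grid = 10^seq(-4, 1, length.out = 25),
                             tol = 1e-2) {
  Q <- if (inherits(dsf, "dsf")) dsf$Q else dsf
  if (length(s_grid) == 0L) stop("structure_report: empty evaluation grid")
  p <- Q$rows
  maxmag <- matrix(0, p, p, dimnames = list(Q$row_names, Q$col_names))
  allpos <- matrix(TRUE, p, p); allneg <- matrix(TRUE, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    e <- tm_entry(Q, i, j)
    if (rf_is_zero(e)) { allpos[i, j] <- allneg[i, j] <- FALSE; next }
    v <- Re(vapply(s_grid, function(s) tf_eval_rf(e, s), 0))
    maxmag[i, j] <- max(abs(v))
    allpos[i, j] <- all(v > 0); allneg[i, j] <- all(v < 0)
  }
  ref <- max(maxmag)
  support <- maxmag >= tol * max(ref, .Machine$double.xmin)
  signs <- matrix("absent", p, p, dimnames = dimnames(maxmag))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) { signs[i, j] <- ""; next }
    if (!support[i, j]) next
    signs[i, j] <- if (allpos[i, j]) "activating"
                   else if (allneg[i, j]) "repressing" else "mixed"
  }
  diag(support) <- FALSE
  list(support = support, signs = signs, max_magnitude = maxmag)
}
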