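#' Difference between two network structures
#'
#' Entrywise `Q_ref - Q_est`, the first-order predictor of the deviation
#' between an idealized circuit trajectory and one subject to crosstalk: for
#' edges absent from the reference, the difference reduces to minus the
#' estimated crosstalk entry.
#'
#' @param Q_ref,Q_est same-shape [tfm()] objects in the same variable.
#' @return simplified `tfm` of differences.
#' @export
dsf_delta <- function(Q_ref, Q_est) {
  if (Q_ref$rows != Q_est$rows || Q_ref$cols != Q_est$cols)
    stop("dsf_delta: shape mismatch")
  if (Q_ref$var != Q_est$var) stop("dsf_delta: transform variables differ")
  ent <- mapply(function(a, b) rf_simplify(rf_sub(a, b)),
                Q_ref$entries, Q_est$entries, SIMPLIFY = FALSE)
  tfm(ent, Q_ref$rows, Q_ref$cols, Q_ref$row_names, Q_ref$col_names,
      var = Q_ref$var)
}

#' Entrywise gain matrix scaled by its maximum
#'
#' Computes the H-infinity (or H2) gain of every entry and divides by the
#' largest, following the normalized-gain display used to rank designed
#' versus crosstalk edges. The diagonal is zero; an all-zero matrix maps to
#' all zeros. Unstable entries are excluded from the ranking with a warning
#' (reported as `NA`).
#'
#' @param Q square [tfm()] (a network structure).
#' @param norm `"hinf"` or `"h2"`.
#' @return numeric matrix with maximum entry 1 (when any entry is nonzero).
#' @export
normalized_gain_matrix <- function(Q, norm = c("hinf", "h2")) {
  norm <- match.arg(norm)
  p <- Q$rows
  G <- matrix(0, p, Q$cols, dimnames = list(Q$row_names, Q$col_names))
  for (i in seq_len(p)) for (j in seq_len(Q$cols)) {
    e <- tm_entry(Q, i, j)
    if (rf_is_zero(e) || i == j) next
    G[i, j] <- tryCatch(
      if (norm == "hinf") hinf_norm(e) else h2_norm(e),
      error = function(err) {
        warning("entry (", i, ",", j, ") excluded from gain ranking: ",
                conditionMessage(err))
        NA_real_
      })
  }
  mx <- suppressWarnings(max(G, na.rm = TRUE))
  if (is.finite(mx) && mx > 0) G <- G / mx
  G
}

#' Classify estimated edges against a reference support
#'
#' Thresholds the max-normalized entry gains of an estimated network
#' structure: entries below `tol` are `absent`; entries at or above `tol`
#' are `crosstalk` where the reference support is empty and
#' `designed-active` where it is not. When a full reference `tfm` is
#' supplied, designed edges whose estimated-to-reference gain ratio falls
#' outside `mismatch_band` are flagged `gain-mismatch` - the deliberate
#' single-edge attenuation debugging scenario.
#'
#' @param Q_ref_support logical matrix of designed edges, or a reference
#'   `tfm` (support and gains taken from it).
#' @param Q_est estimated network structure (`tfm`, `s` or `z` domain).
#' @param tol normalized-gain threshold in (0, 1).
#' @param norm gain type passed to [normalized_gain_matrix()].
#' @param mismatch_band acceptable estimated/reference gain ratio range.
#' @return object of class `crosstalk_report`: label matrix, raw and
#'   normalized gain matrices, and the threshold used.
#' @export
classify_edges <- function(Q_ref_support, Q_est, tol = 0.05,
                           norm = c("hinf", "h2"),
                           mismatch_band = c(0.5, 2)) {
  norm <- match.arg(norm)
  if (tol <= 0 || tol >= 1) stop("classify_edges: tol must be in (0, 1)")
  p <- Q_est$rows
  Q_ref <- NULL
  if (inherits(Q_ref_support, "tfm")) {
    Q_ref <- Q_ref_support
    Q_ref_support <- matrix(!vapply(Q_ref$entries, rf_is_zero, TRUE),
                            p, p, byrow = TRUE)
  }
  Q_ref_support <- as.matrix(Q_ref_support)
  diag(Q_ref_support) <- FALSE
  gains <- matrix(0, p, p, dimnames = list(Q_est$row_names, Q_est$col_names))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    e <- tm_entry(Q_est, i, j)
    if (i == j || rf_is_zero(e)) next
    gains[i, j] <- tryCatch(
      if (norm == "hinf") hinf_norm(e) else h2_norm(e),
      error = function(err) {
        warning("unstable entry (", i, ",", j, ") excluded from ranking")
        NA_real_
      })
  }
  mx <- suppressWarnings(max(gains, na.rm = TRUE))
  ngains <- if (is.finite(mx) && mx > 0) gains / mx else gains
  labels <- matrix("absent", p, p,
                   dimnames = list(Q_est$row_names, Q_est$col_names))
  diag(labels) <- ""
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    g <- ngains[i, j]
    if (is.na(g)) { labels[i, j] <- "unstable"; next }
    if (g < tol) next
    if (!Q_ref_support[i, j]) { labels[i, j] <- "crosstalk"; next }
    labels[i, j] <- "designed-active"
    if (!is.null(Q_ref)) {
      gr <- tryCatch(hinf_norm(tm_entry(Q_ref, i, j)), error = function(e) NA)
      if (is.finite(gr) && gr > 0) {
        ratio <- gains[i, j] / gr
        if (ratio < mismatch_band[1L] || ratio > mismatch_band[2L])
          labels[i, j] <- "gain-mismatch"
      }
    }
  }
  structure(list(labels = labels, gains = gains, normalized_gains = ngains,
                 tol = tol, norm = norm, reference_support = Q_ref_support),
            class = "crosstalk_report")
}

#' @export
print.crosstalk_report <- function(x, ...) {
  cat("crosstalk_report (tol =", x$tol, ", norm =", x$norm, ")\n")
  print(x$labels)
  invisible(x)
}

#' Finite-horizon Laplace transform of sampled signals
#'
#' Trapezoid-rule evaluation of `integral_0^T exp(-s t) f(t) dt` on real
#' `s > 0`, used to compare time-domain deviations against frequency-domain
#' predictions.
#'
#' @param t uniform time grid.
#' @param f vector or `T x k` matrix of samples.
#' @param s_vals positive real transform points.
#' @return `length(s_vals) x k` matrix of transforms.
#' @export
finite_laplace <- function(t, f, s_vals) {
  f <- as.matrix(f)
  dt <- check_uniform(t)
  out <- matrix(0, length(s_vals), ncol(f))
  w <- rep(dt, length(t)); w[c(1L, length(t))] <- dt / 2
  for (k in seq_along(s_vals)) {
    kern <- exp(-s_vals[k] * t) * w
    out[k, ] <- as.numeric(crossprod(kern, f))
  }
  out
}

#' First-order crosstalk prediction residual
#'
#' Numerical check of the crosstalk-deviation expansion: simulates the
#' idealized and crosstalk models from matched operating points under a
#' common step perturbation of amplitude `eps`, and measures how well the
#' DSF difference `(Q_a - Q_c)` predicts the transform of the trajectory
#' deviation `zeta = y_a - y_c` (deviation coordinates) on a real `s > 0`
#' grid:
#' \deqn{res(eps) = || L(zeta) - (Q_a - Q_c) L(y_c) ||_F.}
#' The remainder is second order in the perturbation, so the residual decays
#' quadratically with `eps`.
#'
#' @param model_a,model_c idealized and crosstalk `circuit_model`s with
#'   identical measured sets.
#' @param u_baseline shared baseline inputs (each model sits at its own
#'   equilibrium there).
#' @param eps step amplitude applied to every input at `t = 0`.
#' @param t_end,dt simulation horizon and sampling interval.
#' @param s_grid real positive transform points.
#' @return list with `residual`, the per-point prediction error matrix, and
#'   the DSF difference used.
#' @export
crosstalk_scaling_residual <- function(model_a, model_c, u_baseline, eps,
                                       t_end = 4000, dt = 4,
                                       s_grid = c(0.002, 0.005, 0.01, 0.02, 0.05)) {
  t_grid <- seq(0, t_end, by = dt)
  run <- function(model) {
    op <- find_equilibrium(model, u_baseline)
    sched <- step_schedule(u_baseline, rep(eps, model$m), rep(0, model$m))
    tr <- simulate_circuit(model, sched, op$x_e, t_grid)
    dev <- sweep(tr$Y, 2L, op$x_e[model$measured_indices])
    list(op = op, dev = dev, dsf = dsf_from_lti(linearize(model, op)))
  }
  ra <- run(model_a); rc <- run(model_c)
  zeta <- ra$dev - rc$dev
  Lz <- finite_laplace(t_grid, zeta, s_grid)
  Ly <- finite_laplace(t_grid, rc$dev, s_grid)
  p <- ncol(zeta)
  pred <- matrix(0, length(s_grid), p)
  for (k in seq_along(s_grid)) {
    dQ <- Re(tf_eval(ra$dsf$Q, s_grid[k]) - tf_eval(rc$dsf$Q, s_grid[k]))
    pred[k, ] <- as.numeric(dQ %*% Ly[k, ])
  }
  err <- Lz - pred
  list(residual = sqrt(sum(err^2)), error = err, s_grid = s_grid)
}
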