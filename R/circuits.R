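#' Benchmark genetic-circuit models
#'
#' Nonlinear ODE models of small synthetic gene circuits with hidden mRNA
#' states, stored as R expressions so that vector fields and Jacobians are
#' evaluated exactly. Available models:
#'
#' * `iffl_ideal`: three-gene incoherent feedforward loop (activator drives a
#'   reporter directly and through a repressor), Michaelis-Menten protein
#'   degradation per gene, no loading. States `x1..x3` (proteins, measured),
#'   `m1..m3` (mRNA, hidden); inputs `u1..u3`.
#' * `iffl_crosstalk`: the same circuit with a shared, saturating protease
#'   pool: all three degradation terms compete through a common denominator,
#'   coupling every protein to every other.
#' * `event_detector`: two constitutive relay genes plus a two-gene mutual
#'   repression memory module with NIMPLY-logic promoters. Measured outputs
#'   are the memory-module proteins `x2, x3`; inputs `u1, u2` are the two
#'   inducers. The `hill` parameter sets repression cooperativity; the
#'   default 2 (with `kM2 = kM3 = 1`) gives a bistable latch, while `hill = 1`
#'   reproduces the first-order kinetic form.
#' * `repressilator3`: generic three-node cyclic repressor with hidden mRNA,
#'   influence pattern y1<-y3, y2<-y1, y3<-y2, per-node gain attenuation
#'   factors `atten1..3` and an optional shared-degradation loading term
#'   (`C0load > 0`).
#'
#' @param name model identifier.
#' @param overrides named list of parameter overrides; values must be
#'   positive (attenuation and loading parameters may be zero).
#' @return an object of class `circuit_model`.
#' @examples
#' m <- builtin_model("iffl_ideal")
#' m$parameters$rho1
#' @export
builtin_model <- function(name = c("iffl_ideal", "iffl_crosstalk",
                                   "event_detector", "repressilator3"),
                          overrides = list()) {
  name <- match.arg(name)
  def <- switch(name,
    iffl_ideal = iffl_def(crosstalk = FALSE),
    iffl_crosstalk = iffl_def(crosstalk = TRUE),
    event_detector = event_detector_def(),
    repressilator3 = repressilator3_def())
  pars <- def$parameters
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(pars))
    if (length(bad)) stop("unknown parameter override: ", paste(bad, collapse = ", "))
    for (nm in names(overrides)) {
      v <- overrides[[nm]]
      if (!is.numeric(v) || length(v) != 1L || v < 0 ||
          (v == 0 && !(nm %in% def$zero_ok)))
        stop("non-positive override for parameter '", nm, "'")
      pars[[nm]] <- v
    }
  }
  circuit_model(name = name, state_names = def$state_names,
                measured_indices = def$measured_indices,
                input_names = def$input_names, parameters = pars,
                field_exprs = def$field_exprs, zero_ok = def$zero_ok)
}

circuit_model <- function(name, state_names, measured_indices, input_names,
                          parameters, field_exprs, zero_ok = character(0)) {
  n <- length(state_names)
  if (length(field_exprs) != n) stop("circuit_model: one expression per state")
  if (anyDuplicated(measured_indices) || any(measured_indices < 1L) ||
      any(measured_indices > n))
    stop("circuit_model: measured_indices must be distinct and in range")
  for (nm in names(parameters)) {
    v <- parameters[[nm]]
    if (v < 0 || (v == 0 && !(nm %in% zero_ok)))
      stop("circuit_model: parameter '", nm, "' must be strictly positive")
  }
  # exact Jacobian expressions d f_i / d x_j and d f_i / d u_j
  jac_x <- lapply(field_exprs, function(e)
    lapply(state_names, function(v) stats::D(e, v)))
  jac_u <- lapply(field_exprs, function(e)
    lapply(input_names, function(v) stats::D(e, v)))
  structure(list(name = name, state_names = state_names,
                 measured_indices = as.integer(measured_indices),
                 input_names = input_names, parameters = parameters,
                 field_exprs = field_exprs, jac_x = jac_x, jac_u = jac_u,
                 n = n, p = length(measured_indices),
                 m = length(input_names), zero_ok = zero_ok),
            class = "circuit_model")
}

#' @export
print.circuit_model <- function(x, ...) {
  cat(sprintf("circuit_model '%s': %d states (%d measured), %d inputs\n",
              x$name, x$n, x$p, x$m))
  invisible(x)
}

model_env <- function(model, x, u) {
  e <- as.list(model$parameters)
  e[model$state_names] <- as.numeric(x)
  e[model$input_names] <- as.numeric(u)
  list2env(e, parent = baseenv())
}

#' Evaluate a circuit model's vector field
#'
#' @param model a [builtin_model()] (or any `circuit_model`).
#' @param x state vector (model state ordering).
#' @param u input vector.
#' @return numeric derivative vector.
#' @export
eval_field <- function(model, x, u) {
  env <- model_env(model, x, u)
  vapply(model$field_exprs, function(e) eval(e, env), 0)
}

# exact Jacobians (A wrt states, B wrt inputs) at a point, model ordering
model_jacobian <- function(model, x, u, method = c("exact", "fd")) {
  method <- match.arg(method)
  n <- model$n; m <- model$m
  if (method == "exact") {
    env <- model_env(model, x, u)
    A <- matrix(0, n, n); B <- matrix(0, n, m)
    for (i in seq_len(n)) {
      A[i, ] <- vapply(model$jac_x[[i]], function(e) eval(e, env), 0)
      B[i, ] <- vapply(model$jac_u[[i]], function(e) eval(e, env), 0)
    }
    return(list(A = A, B = B))
  }
  fd <- function(k, wrt) {
    h <- 1e-6 * max(1, abs(if (wrt == "x") x[k] else u[k]))
    pert <- function(sgn) {
      if (wrt == "x") { xp <- x; xp[k] <- xp[k] + sgn * h; eval_field(model, xp, u) }
      else { up <- u; up[k] <- up[k] + sgn * h; eval_field(model, x, up) }
    }
    (pert(1) - pert(-1)) / (2 * h)
  }
  A <- vapply(seq_len(n), fd, numeric(n), wrt = "x")
  B <- vapply(seq_len(m), fd, numeric(n), wrt = "u")
  list(A = matrix(A, n, n), B = matrix(B, n, m))
}

# ---- model definitions -------------------------------------------------------

iffl_def <- function(crosstalk) {
  # shared protease pool couples all degradation terms in the crosstalk variant
  deg_den <- if (crosstalk) "(1 + x1/k1d + x2/k2d + x3/k3d)" else NULL
  dd <- function(i) if (crosstalk) deg_den else sprintf("(1 + x%d/k%dd)", i, i)
  ex <- c(
    sprintf("rho1*m1 - C0*(x1/k1d)/%s", dd(1)),
    sprintf("rho2*m2 - C0*(x2/k2d)/%s", dd(2)),
    sprintf("rho3*m3 - C0*(x3/k3d)/%s", dd(3)),
    "alpha1*u1/(kMu1 + u1) - dm*m1",
    "alpha2*(x1*u2/kMu2)/(1 + x1*u2/kMu2) - dm*m2",
    "alpha3*(x1*u2/kMu2)/(1 + x1*u2/kMu2 + x2/(kM2 + u3/kMu3)) - dm*m3")
  list(state_names = c("x1", "x2", "x3", "m1", "m2", "m3"),
       measured_indices = 1:3,
       input_names = c("u1", "u2", "u3"),
       parameters = list(rho1 = 641.4, rho2 = 585.1, rho3 = 652.8,
                         alpha1 = 7.8, alpha2 = 7.1, alpha3 = 7.92,
                         k1d = 200, k2d = 200, k3d = 200,
                         kMu1 = 4000, kMu2 = 4000, kMu3 = 4000,
                         kM2 = 200, C0 = 1, dm = 10),
       field_exprs = lapply(ex, function(s) str2lang(s)),
       zero_ok = character(0))
}

event_detector_def <- function() {
  ex <- c(
    "rho1*m1 - dp*x1",
    "rho2*m2 - dp*x2",
    "rho3*m3 - dp*x3",
    "rho4*m4 - dp*x4",
    "k1*(kl + u1/kMu1)/(1 + u1/kMu1) - dm*m1",
    "k2*(kl + u1/kMu1)/(1 + (x3/kM3)^hill + u1/kMu1) - dm*m2",
    "k3*(kl + u2/kMu2)/(1 + (x2/kM2)^hill + u2/kMu2) - dm*m3",
    "k4*(kl + u2/kMu2)/(1 + u2/kMu2) - dm*m4")
  list(state_names = c("x1", "x2", "x3", "x4", "m1", "m2", "m3", "m4"),
       measured_indices = c(2L, 3L),
       input_names = c("u1", "u2"),
       parameters = list(rho1 = 5, rho2 = 5, rho3 = 5, rho4 = 5,
                         k1 = 10, k2 = 10, k3 = 10, k4 = 10,
                         kl = 0.01, dp = 0.1, dm = 1,
                         kMu1 = 1000, kMu2 = 1000, kM2 = 1, kM3 = 1,
                         hill = 2),
       field_exprs = lapply(ex, function(s) str2lang(s)),
       zero_ok = character(0))
}

repressilator3_def <- function() {
  ex <- c(
    "rho*m1 - dp*x1 - C0load*(x1/kd)/(1 + (x1 + x2 + x3)/kd)",
    "rho*m2 - dp*x2 - C0load*(x2/kd)/(1 + (x1 + x2 + x3)/kd)",
    "rho*m3 - dp*x3 - C0load*(x3/kd)/(1 + (x1 + x2 + x3)/kd)",
    "atten1*alpha/(1 + (x3/kM)^hill) - dm*m1 + u1",
    "atten2*alpha/(1 + (x1/kM)^hill) - dm*m2 + u2",
    "atten3*alpha/(1 + (x2/kM)^hill) - dm*m3 + u3")
  list(state_names = c("x1", "x2", "x3", "m1", "m2", "m3"),
       measured_indices = 1:3,
       input_names = c("u1", "u2", "u3"),
       parameters = list(rho = 2, alpha = 4, kM = 1, hill = 2,
                         dp = 0.5, dm = 1,
                         atten1 = 1, atten2 = 1, atten3 = 1,
                         C0load = 0, kd = 1),
       field_exprs = lapply(ex, function(s) str2lang(s)),
       zero_ok = c("C0load"))
}

# ---- operating points --------------------------------------------------------

#' Find an operating point of a circuit model
#'
#' Damped-Newton root finding of the vector field at fixed inputs, with
#' multi-start from the supplied guess, log-spaced rescalings of it, and an
#' ODE-relaxed point. Succeeds when the sup-norm residual is below
#' `tol * max(1, |x_e|_inf)`.
#'
#' @param model a `circuit_model`.
#' @param u_fixed nonnegative input vector held constant.
#' @param x_guess initial state guess (default: small positive vector).
#' @param tol relative residual tolerance.
#' @param max_iter Newton iteration budget per start.
#' @return object of class `operating_point`: `x_e`, `u_e`, `residual_norm`.
#' @export
find_equilibrium <- function(model, u_fixed, x_guess = NULL, tol = 1e-9,
                             max_iter = 80L) {
  if (any(u_fixed < 0)) stop("find_equilibrium: u_fixed must be nonnegative")
  n <- model$n
  if (is.null(x_guess)) x_guess <- rep(0.1, n)
  newton <- function(x0) {
    x <- x0
    f <- eval_field(model, x, u_fixed)
    for (it in seq_len(max_iter)) {
      sc <- max(1, max(abs(x)))
      if (max(abs(f)) < tol * sc) return(list(x = x, ok = TRUE))
      J <- model_jacobian(model, x, u_fixed)$A
      dx <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(dx)) return(list(x = x, ok = FALSE))
      lam <- 1
      repeat {
        xn <- x + lam * dx
        fn <- tryCatch(eval_field(model, xn, u_fixed),
                       error = function(e) rep(Inf, n))
        if (all(is.finite(fn)) && max(abs(fn)) < max(abs(f))) break
        lam <- lam / 2
        if (lam < 1e-10) return(list(x = x, ok = FALSE))
      }
      x <- xn; f <- fn
    }
    list(x = x, ok = max(abs(f)) < tol * max(1, max(abs(x))))
  }
  starts <- c(list(x_guess),
              lapply(c(-2, -1, 1, 2), function(k) x_guess * 10^k))
  for (x0 in starts) {
    r <- newton(x0)
    if (r$ok) return(make_op(model, r$x, u_fixed))
  }
  # relax along the flow, then polish
  relax <- tryCatch({
    tr <- simulate_circuit(model, constant_schedule(u_fixed), x_guess,
                           seq(0, 5000, length.out = 51))
    tr$X[nrow(tr$X), ]
  }, error = function(e) NULL)
  if (!is.null(relax)) {
    r <- newton(relax)
    if (r$ok) return(make_op(model, r$x, u_fixed))
  }
  stop("find_equilibrium: no convergence after restart budget")
}

make_op <- function(model, x, u) {
  res <- max(abs(eval_field(model, x, u)))
  structure(list(x_e = x, u_e = as.numeric(u), residual_norm = res),
            class = "operating_point")
}

#' Linearize a circuit model about an operating point
#'
#' Exact (expression-derivative) Jacobians, with states reordered so the
#' measured states come first, yielding the partitioned blocks consumed by
#' [compute_WV()]. A non-equilibrium operating point only warns: transients
#' about nominal (even unstable) initial conditions are legitimate
#' linearization targets.
#'
#' @param model a `circuit_model`.
#' @param op an `operating_point` (or a list with `x_e`, `u_e`).
#' @param method `"exact"` expression derivatives or `"fd"` central finite
#'   differences.
#' @return a [partitioned_lti()].
#' @export
linearize <- function(model, op, method = c("exact", "fd")) {
  method <- match.arg(method)
  res <- max(abs(eval_field(model, op$x_e, op$u_e)))
  if (res > 1e-6 * max(1, max(abs(op$x_e))))
    warning("linearize: operating point is not an equilibrium (residual ",
            format(res, digits = 3), "); proceeding")
  J <- model_jacobian(model, op$x_e, op$u_e, method)
  meas <- model$measured_indices
  hid <- setdiff(seq_len(model$n), meas)
  perm <- c(meas, hid)
  A <- J$A[perm, perm, drop = FALSE]
  B <- J$B[perm, , drop = FALSE]
  p <- length(meas)
  partitioned_lti(A11 = A[seq_len(p), seq_len(p), drop = FALSE],
                  A12 = A[seq_len(p), -seq_len(p), drop = FALSE],
                  A21 = A[-seq_len(p), seq_len(p), drop = FALSE],
                  A22 = A[-seq_len(p), -seq_len(p), drop = FALSE],
                  B1 = B[seq_len(p), , drop = FALSE],
                  B2 = B[-seq_len(p), , drop = FALSE],
                  output_names = model$state_names[meas],
                  input_names = model$input_names,
                  hidden_names = model$state_names[hid])
}

# ---- input schedules and simulation ------------------------------------------

#' Piecewise-constant input schedules
#'
#' `step_schedule()` builds a serial-perturbation schedule: channel `j` steps
#' from `u_baseline[j]` by `amplitudes[j]` at `onsets[j]`, holding for
#' `duration` (default: indefinitely, a non-degrading perturbant).
#' `constant_schedule()` holds `u` fixed.
#'
#' @param u_baseline baseline input vector.
#' @param amplitudes,onsets per-channel step sizes and onset times.
#' @param duration hold time of each step (`Inf` = hold forever).
#' @return an `input_schedule`: switch times and a `u(t)` lookup.
#' @export
step_schedule <- function(u_baseline, amplitudes, onsets, duration = Inf) {
  m <- length(u_baseline)
  stopifnot(length(amplitudes) == m, length(onsets) == m)
  ufun <- function(t) {
    u <- u_baseline
    on <- t >= onsets & t < onsets + duration
    u[on] <- u[on] + amplitudes[on]
    u
  }
  sw <- sort(unique(c(onsets, if (is.finite(duration)) onsets + duration)))
  structure(list(u = ufun, switch_times = sw[is.finite(sw)], m = m),
            class = "input_schedule")
}

#' @rdname step_schedule
#' @param u fixed input vector.
#' @export
constant_schedule <- function(u) {
  structure(list(u = function(t) u, switch_times = numeric(0), m = length(u)),
            class = "input_schedule")
}

#' Simulate a circuit model
#'
#' Stiff-capable integration (`deSolve::lsoda`) of the nonlinear vector field
#' under a piecewise-constant input schedule, integrated segment-wise between
#' input switch times and sampled on a uniform grid.
#'
#' @param model a `circuit_model`.
#' @param schedule an `input_schedule`.
#' @param x0 initial state (model ordering).
#' @param t_grid uniform, increasing time grid.
#' @param rtol,atol integrator tolerances.
#' @return a `trajectory`: `t`, measured outputs `Y`, inputs `U`, full states
#'   `X`.
#' @export
simulate_circuit <- function(model, schedule, x0, t_grid,
                             rtol = 1e-8, atol = 1e-10) {
  t_grid <- as.numeric(t_grid)
  check_uniform(t_grid)
  deriv <- function(t, x, parms) list(eval_field(model, x, parms))
  sw <- schedule$switch_times
  sw <- sw[sw > t_grid[1L] & sw < t_grid[length(t_grid)]]
  bounds <- c(t_grid[1L], sw, t_grid[length(t_grid)])
  X <- matrix(NA_real_, length(t_grid), model$n)
  X[1L, ] <- x0
  x_cur <- x0
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    u_seg <- schedule$u((a + b) / 2)
    idx <- which(t_grid > a & t_grid <= b)
    times <- unique(c(a, t_grid[idx], b))
    sol <- deSolve::ode(y = x_cur, times = times, func = deriv, parms = u_seg,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      stop("simulate_circuit: integrator failure on segment [",
           format(a), ", ", format(b), "]")
    sm <- as.matrix(sol)
    if (length(idx))
      X[idx, ] <- sm[match(t_grid[idx], sm[, 1L]), -1L, drop = FALSE]
    x_cur <- as.numeric(sm[nrow(sm), -1L])
  }
  U <- do.call(rbind, lapply(t_grid, schedule$u))
  Y <- X[, model$measured_indices, drop = FALSE]
  colnames(Y) <- model$state_names[model$measured_indices]
  colnames(U) <- model$input_names
  new_trajectory(t_grid, Y, U, X = X)
}

#' @rdname experiment_suite
#' @param t,Y,U,X,meta trajectory fields.
#' @export
new_trajectory <- function(t, Y, U, X = NULL, meta = list()) {
  structure(list(t = t, Y = as.matrix(Y), U = as.matrix(U), X = X,
                 meta = meta), class = "trajectory")
}

check_uniform <- function(t, tol = 1e-6) {
  if (length(t) < 2L) stop("time grid needs at least two points")
  d <- diff(t)
  if (any(d <= 0)) stop("time grid must be strictly increasing")
  if ((max(d) - min(d)) > tol * mean(d))
    stop("time grid is not uniform (max relative spacing deviation ",
         format((max(d) - min(d)) / mean(d), digits = 3), ")")
  mean(d)
}

# exact simulation of the linearized deviation system under a schedule whose
# switches align with the grid
sim_lti_schedule <- function(A, B, schedule, u_ref, t_grid, x0 = NULL) {
  dt <- check_uniform(t_grid)
  n <- nrow(A); m <- ncol(B)
  M <- mat_expm(rbind(cbind(A * dt, B * dt), matrix(0, m, n + m)))
  Ad <- M[seq_len(n), seq_len(n), drop = FALSE]
  Bd <- M[seq_len(n), n + seq_len(m), drop = FALSE]
  X <- matrix(0, length(t_grid), n)
  x <- if (is.null(x0)) rep(0, n) else x0
  X[1L, ] <- x
  for (k in seq_len(length(t_grid) - 1L)) {
    du <- schedule$u(t_grid[k]) - u_ref
    x <- as.numeric(Ad %*% x + Bd %*% du)
    X[k + 1L, ] <- x
  }
  X
}

# nonlinear simulation with additive perturbation rates on measured nodes
# (the injected-inhibitor design); model inputs held at u_baseline
simulate_perturbed <- function(model, sched, x0, t_grid, u_baseline) {
  meas <- model$measured_indices
  deriv <- function(t, x, parms) {
    f <- eval_field(model, x, u_baseline)
    f[meas] <- f[meas] + parms
    list(f)
  }
  sw <- sched$switch_times
  sw <- sw[sw > t_grid[1L] & sw < t_grid[length(t_grid)]]
  bounds <- c(t_grid[1L], sw, t_grid[length(t_grid)])
  X <- matrix(NA_real_, length(t_grid), model$n)
  X[1L, ] <- x0
  x_cur <- x0
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    v_seg <- sched$u((a + b) / 2)
    idx <- which(t_grid > a & t_grid <= b)
    times <- unique(c(a, t_grid[idx], b))
    sol <- deSolve::ode(y = x_cur, times = times, func = deriv, parms = v_seg,
                        method = "lsoda", rtol = 1e-8, atol = 1e-10)
    if (attr(sol, "istate")[1L] < 0)
      stop("simulate_perturbed: integrator failure")
    sm <- as.matrix(sol)
    if (length(idx))
      X[idx, ] <- sm[match(t_grid[idx], sm[, 1L]), -1L, drop = FALSE]
    x_cur <- as.numeric(sm[nrow(sm), -1L])
  }
  U <- do.call(rbind, lapply(t_grid, sched$u))
  Y <- X[, meas, drop = FALSE]
  colnames(Y) <- model$state_names[meas]
  colnames(U) <- paste0("v", seq_along(meas))
  new_trajectory(t_grid, Y, U, X = X)
}

# ---- perturbation experiment suites ------------------------------------------

#' Generate perturbation experiments for network reconstruction
#'
#' Emulates the serial step-input perturbation design: each measured node is
#' independently perturbed through its own input channel, either staggered
#' within one trajectory (`serial = TRUE`) or as one trajectory per node.
#' Measured outputs receive additive i.i.d. Gaussian noise; the
#' pre-perturbation baseline window is recorded for detrending. Optionally
#' attaches the ground-truth DSF of the linearization at the baseline
#' operating point.
#'
#' @param model a `circuit_model`.
#' @param design list with `u_baseline`, `amplitudes` (length p), `onsets`
#'   (length p), `dt`, `t_end`, and optionally `duration` (default `Inf`),
#'   `serial` (default `TRUE`), `plant` (`"nonlinear"` or `"linearized"`),
#'   `input_mode` (`"direct"`, the default: perturbants act as additive rates
#'   on each measured node's own equation, the injected-inhibitor design that
#'   makes the true P diagonal; or `"channels"`: steps on the model's own
#'   input channels, whose P need not be diagonal), `noise_mode`
#'   (`"absolute"` or `"relative"` to each channel's maximum deviation),
#'   `attach_truth` (default `TRUE`), `x0` (default: equilibrium at
#'   `u_baseline`).
#' @param noise_sd measurement noise standard deviation (see `noise_mode`).
#' @param seed RNG seed (required: suites must be reproducible).
#' @return an `experiment_suite`.
#' @export
generate_experiments <- function(model, design, noise_sd = 0, seed) {
  if (missing(seed)) stop("generate_experiments: a seed is required")
  p <- model$p
  d <- design
  d$duration <- d$duration %||% Inf
  d$serial <- d$serial %||% TRUE
  d$plant <- d$plant %||% "nonlinear"
  d$input_mode <- d$input_mode %||% "direct"
  d$noise_mode <- d$noise_mode %||% "absolute"
  d$attach_truth <- d$attach_truth %||% TRUE
  if (length(d$amplitudes) < p)
    warning("design perturbs fewer than p nodes: the suite will not satisfy ",
            "the identifiability conditions (p - 1 known entries per column)")
  direct <- d$input_mode == "direct"
  n_ch <- if (direct) p else model$m
  if (!direct && model$m < p)
    stop("generate_experiments: need one input channel per measured node")
  t_grid <- seq(0, d$t_end, by = d$dt)
  op <- find_equilibrium(model, d$u_baseline,
                         x_guess = d$x0 %||% rep(0.1, model$n))
  x0 <- d$x0 %||% op$x_e
  sys <- linearize(model, op)
  if (direct) {
    # perturbation channels: additive rate on each measured node's equation
    sys$B1 <- diag(1, p); sys$B2 <- matrix(0, sys$nh, p)
    sys$m <- p
    sys$input_names <- paste0("v", seq_len(p))
  }
  input_names <- sys$input_names
  truth <- if (isTRUE(d$attach_truth)) dsf_from_lti(sys) else NULL

  run_one <- function(onsets, amplitudes) {
    pert_base <- if (direct) rep(0, p) else d$u_baseline
    sched <- step_schedule(pert_base, amplitudes, onsets, d$duration)
    if (d$plant == "linearized") {
      fl <- lti_full(sys)
      Xdev <- sim_lti_schedule(fl$A, fl$B, sched, pert_base, t_grid)
      y_e <- op$x_e[model$measured_indices]
      Y <- sweep(Xdev[, seq_len(p), drop = FALSE], 2L, -y_e)
      U <- do.call(rbind, lapply(t_grid, sched$u))
      colnames(Y) <- sys$output_names; colnames(U) <- input_names
      new_trajectory(t_grid, Y, U)
    } else if (direct) {
      simulate_perturbed(model, sched, x0, t_grid, d$u_baseline)
    } else {
      simulate_circuit(model, sched, x0, t_grid)
    }
  }

  set.seed(as.integer(seed %% .Machine$integer.max))
  trajs <- list()
  if (isTRUE(d$serial)) {
    ons <- rep(Inf, n_ch)
    ons[seq_along(d$onsets)] <- d$onsets
    trajs[[1L]] <- run_one(ons, pad_to(d$amplitudes, n_ch))
  } else {
    for (j in seq_len(p)) {
      amps <- rep(0, n_ch); amps[j] <- d$amplitudes[j]
      ons <- rep(Inf, n_ch); ons[j] <- d$onsets[j]
      trajs[[j]] <- run_one(ons, amps)
    }
  }
  first_onset <- min(d$onsets[seq_len(min(p, length(d$onsets)))])
  for (k in seq_along(trajs)) {
    tr <- trajs[[k]]
    sd_ch <- rep(noise_sd, p)
    if (d$noise_mode == "relative") {
      base <- vapply(seq_len(p), function(j) {
        dev <- tr$Y[, j] - mean(tr$Y[tr$t < first_onset, j])
        max(abs(dev))
      }, 0)
      sd_ch <- noise_sd * base
    }
    noise <- vapply(seq_len(p), function(j) stats::rnorm(nrow(tr$Y), 0, sd_ch[j]),
                    numeric(nrow(tr$Y)))
    tr$meta <- list(seed = seed, noise_sd = sd_ch,
                    baseline_window = which(tr$t < first_onset))
    tr$Y_clean <- tr$Y
    tr$Y <- tr$Y + noise
    trajs[[k]] <- tr
  }
  experiment_suite(trajs,
                   output_names = sys$output_names,
                   input_names = input_names,
                   truth = truth,
                   meta = list(seed = seed, design = d, noise_sd = noise_sd,
                               operating_point = op))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pad_to <- function(v, m) { out <- rep(0, m); out[seq_along(v)] <- v; out }

#' Experiment suites
#'
#' A list of [new_trajectory] objects sharing channel names and a sampling
#' interval, with optional attached ground-truth DSF.
#'
#' @param trajectories list of `trajectory` objects.
#' @param output_names,input_names channel identifiers.
#' @param truth optional ground-truth `dsf`.
#' @param meta metadata list.
#' @return an object of class `experiment_suite`.
#' @export
experiment_suite <- function(trajectories, output_names, input_names,
                             truth = NULL, meta = list()) {
  for (tr in trajectories) {
    check_uniform(tr$t)
    if (!all(is.finite(tr$Y)) || !all(is.finite(tr$U)))
      stop("experiment_suite: non-finite trajectory values")
  }
  dts <- vapply(trajectories, function(tr) mean(diff(tr$t)), 0)
  structure(list(trajectories = trajectories, output_names = output_names,
                 input_names = input_names, dt = dts[1L], truth = truth,
                 meta = meta),
            class = "experiment_suite")
}

#' @export
print.experiment_suite <- function(x, ...) {
  cat(sprintf("experiment_suite: %d trajectories, outputs (%s), inputs (%s), dt = %g\n",
              length(x$trajectories), paste(x$output_names, collapse = ","),
              paste(x$input_names, collapse = ","), x$dt))
  invisible(x)
}
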