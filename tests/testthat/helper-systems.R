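# shared generators and oracles

# random stable partitioned LTI (eigenvalues shifted into the left half-plane)
random_partitioned <- function(n_max = 8, p_max = 4, m_max = 4) {
  n <- sample(2:n_max, 1)
  p <- sample(1:min(p_max, n), 1)
  m <- sample(1:m_max, 1)
  A <- matrix(rnorm(n * n), n, n)
  A <- A - (max(Re(eigen(A)$values)) + 0.5) * diag(n)
  B <- matrix(rnorm(n * m), n, m)
  ip <- seq_len(p)
  partitioned_lti(A[ip, ip, drop = FALSE],
                  matrix(A[ip, -ip], p, n - p),
                  matrix(A[-ip, ip], n - p, p),
                  matrix(A[-ip, -ip], n - p, n - p),
                  B[ip, , drop = FALSE],
                  matrix(B[-ip, ], n - p, m))
}

# evaluate (I - Q)^-1 P and C(sI - A)^-1 B at one point
closed_loop_pair <- function(sys, d, s0) {
  fl <- dsfnet:::lti_full(sys)
  n <- nrow(fl$A); p <- sys$p
  C <- cbind(diag(p), matrix(0, p, n - p))
  G1 <- solve(diag(p) - tf_eval(d$Q, s0), tf_eval(d$P, s0))
  G2 <- C %*% solve(s0 * diag(n) - fl$A) %*% fl$B
  list(G1 = G1, G2 = G2,
       rtol = max(Mod(G1 - G2)) / max(Mod(G2), 1e-12))
}

# random coupled-stable discrete DSF ground truth (shared dt = 1)
random_ddsf <- function(p = 3, nd = 2, cross_sd = 0.08) {
  repeat {
    rows <- list()
    for (i in seq_len(p)) {
      r1 <- runif(1, -0.5, 0.85); r2 <- runif(1, -0.5, 0.85)
      a <- if (nd == 2) c(-(r1 + r2), r1 * r2) else -r1
      TQ <- list()
      for (j in setdiff(seq_len(p), i))
        TQ[[as.character(j)]] <- rnorm(nd, 0, cross_sd)
      rows[[i]] <- list(a = a, Theta_Q = TQ, Theta_P = rnorm(nd, 0, 0.5),
                        nd = nd, dt = 1, hmax = Inf, row = i)
    }
    Fs <- lapply(seq_len(nd), function(k) {
      Fk <- matrix(0, p, p)
      for (i in seq_len(p)) {
        Fk[i, i] <- -rows[[i]]$a[k]
        for (j in names(rows[[i]]$Theta_Q))
          Fk[i, as.integer(j)] <- rows[[i]]$Theta_Q[[j]][k]
      }
      Fk
    })
    comp <- rbind(do.call(cbind, Fs),
                  cbind(diag(p * (nd - 1)), matrix(0, p * (nd - 1), p)))
    if (nd == 1) comp <- Fs[[1]]
    if (max(Mod(eigen(comp)$values)) < 0.95)
      return(discrete_dsf(rows, paste0("y", seq_len(p)),
                          paste0("u", seq_len(p)), 1))
  }
}

# serial-step suite simulated from a discrete ground truth
ddsf_suite <- function(dd, T = 240, onsets = NULL, noise_sd = 0, seed = NULL) {
  p <- length(dd$rows)
  if (is.null(onsets)) onsets <- floor(seq(T / 12, 2 * T / 3, length.out = p))
  U <- matrix(0, T, p)
  for (j in seq_len(p)) U[(onsets[j] + 1):T, j] <- 1
  Y <- ddsf_simulate(dd, U)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    Y <- Y + matrix(rnorm(length(Y), 0, noise_sd), nrow(Y))
  }
  tr <- new_trajectory(0:(T - 1), Y, U,
                       meta = list(baseline_window = seq_len(min(onsets))))
  colnames(tr$Y) <- dd$output_names
  colnames(tr$U) <- dd$input_names
  experiment_suite(list(tr), dd$output_names, dd$input_names)
}

# replicate suite: three experiments with staggered onsets and varied
# amplitudes (richer excitation than a single serial trace)
rich_ddsf_suite <- function(dd, noise_sd = 0, seed = NULL, T = 240) {
  p <- length(dd$rows)
  if (!is.null(seed)) set.seed(seed)
  trs <- lapply(1:3, function(k) {
    onsets <- floor(T * c(0.1, 0.35, 0.6))[seq_len(p)] + (k - 1) * 7
    U <- matrix(0, T, p)
    for (j in seq_len(p)) U[(onsets[j] + 1):T, j] <- c(1, -0.8, 1.3)[k]
    Y <- ddsf_simulate(dd, U)
    if (noise_sd > 0) Y <- Y + matrix(rnorm(length(Y), 0, noise_sd), nrow(Y))
    tr <- new_trajectory(0:(T - 1), Y, U, meta = list(baseline_window = 1:10))
    colnames(tr$Y) <- dd$output_names; colnames(tr$U) <- dd$input_names
    tr
  })
  experiment_suite(trs, dd$output_names, dd$input_names)
}

# max absolute coefficient discrepancy between two fitted rows
row_coef_error <- function(r0, r1) {
  max(c(abs(r0$a - r1$a), abs(r0$Theta_P - r1$Theta_P),
        unlist(Map(function(a, b) max(abs(a - b)),
                   r0$Theta_Q, r1$Theta_Q[names(r0$Theta_Q)]))))
}

# numerical Laplace transform of a sampled kernel (trapezoid)
laplace_of_kernel <- function(t, k, s) {
  w <- rep(diff(t)[1], length(t)); w[c(1, length(t))] <- w[1] / 2
  sum(exp(-s * t) * k * w)
}

# study conditions shared by the end-to-end reconstruction tests:
# per-node direct step perturbations of the IFFL at a stable positive
# operating point, sampled every 5 time units
iffl_study_design <- function() {
  list(u_baseline = c(1, 0.02, 1), amplitudes = c(0.02, 0.05, 0.05),
       onsets = rep(100, 3), dt = 5, t_end = 2000,
       plant = "linearized", noise_mode = "relative", serial = FALSE)
}

iffl_study_config <- function() {
  estimation_config(nd_grid = 1:4, hmax_grid = c(32, 64, 128, Inf))
}

ideal_iffl_support <- function() {
  s <- matrix(FALSE, 3, 3)
  s[2, 1] <- s[3, 1] <- s[3, 2] <- TRUE
  s
}

crosstalk_label_set <- function(report) {
  unname(apply(which(report$labels == "crosstalk", arr.ind = TRUE), 1,
               paste, collapse = ","))
}
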