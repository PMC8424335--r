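---
title: "Dynamical structure functions for genetic circuits: models, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical structure functions for genetic circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsfnet)
```

## The problem

Synthetic gene circuits are designed as graphs — activator X drives reporter
Y, repressor Z shuts it off — but what is actually realized in a cell or a
test tube is a web of biochemical interactions in which many species (most
often mRNA) are never measured. A model of the network among the *measured*
species that is honest about the hidden ones cannot be a static adjacency
matrix: eliminating hidden states turns each edge into a dynamic, frequency-
dependent object.

The **dynamical structure function (DSF)** is that object. For a linear
(or linearized) system with measured states $y \in \mathbb{R}^p$ first and
hidden states $x_h \in \mathbb{R}^{n-p}$,

$$\frac{d}{dt}\begin{bmatrix}y \\ x_h\end{bmatrix} =
\begin{bmatrix}A_{11} & A_{12}\\ A_{21} & A_{22}\end{bmatrix}
\begin{bmatrix}y \\ x_h\end{bmatrix} +
\begin{bmatrix}B_1\\ B_2\end{bmatrix}u, \qquad y = [\,I\ 0\,]x,$$

Laplace transformation and elimination of $X_h(s)$ give
$sY = W(s)Y + V(s)U$ with
$W = A_{11} + A_{12}(sI-A_{22})^{-1}A_{21}$ and
$V = B_1 + A_{12}(sI-A_{22})^{-1}B_2$. Subtracting the diagonal
$D(s) = \mathrm{diag}(W)$ and solving for $Y$ yields

$$Y(s) = Q(s)Y(s) + P(s)U(s), \qquad
Q = (sI-D)^{-1}(W-D), \quad P = (sI-D)^{-1}V.$$

$Q$ is the network structure (entry $Q_{ij}$: the open-loop causal effect of
measured node $j$ on node $i$), $P$ the control structure. The construction
forces a zero diagonal and strictly proper entries, which is exactly what
makes $(Q,P)$ unique and identifiable from data; the closed-loop transfer
function is recovered as $G = (I-Q)^{-1}P$. The inverse transform
$Q(t) = \mathcal{L}^{-1}(Q(s))$ gives impulse-response *kernels*: each edge
is a signed function of time whose sign (on $s>0$, equivalently of the
kernel) encodes activation versus repression, and whose shape encodes the
time scale of the interaction.

The package does three things:

1. **derive** $(Q,P)$ from nonlinear circuit models by equilibrium finding,
   linearization, and hidden-state elimination (`builtin_model()`,
   `find_equilibrium()`, `linearize()`, `compute_WV()`, `compute_QP()`);
2. **estimate** $(Q,P)$ directly from time-series perturbation data by a
   structured ARX regression in the $z$-domain followed by a
   discrete-to-continuous map (`fit_dsf()`, `to_continuous()`);
3. **compare** an estimated structure with a designed one, ranking edges by
   normalized $H_\infty$ (or $H_2$) gain and labelling entries that the
   design says must vanish as *crosstalk* (`classify_edges()`,
   `dsf_delta()`, `normalized_gain_matrix()`).

## Benchmark circuits and their parameters

`builtin_model()` ships four nonlinear ODE models, stored as R expressions
so that vector fields and Jacobians are exact (no finite differencing in
the default path; `linearize(..., method = "fd")` exists as a cross-check).

**`iffl_ideal`** — a three-gene incoherent feedforward loop with hidden
mRNA: an activator ($x_1$) drives both a reporter ($x_3$) and its repressor
($x_2$). Protein production rates $\rho_{1..3} = 641.4,\ 585.1,\ 652.8$,
mRNA production $\alpha_{1..3} = 7.8,\ 7.1,\ 7.92$, degradation Michaelis
constants $k_{i,d} = 200$, inducer Michaelis constants $k_{M,u_i} = 4000$,
saturating protease capacity $C_0 = 1$ and mRNA turnover $\delta_m = 10$
(concentrations in nM; the rate constants are treated as dimensionless
numbers with an abstract time unit). The repression Michaelis constant $k_{M,2} = 200$ is an
implementation default on the same scale as the degradation constants.

An important and easily missed property of this parameterization: the
protein degradation term saturates at $C_0$, so a *finite* equilibrium
exists only where each $\rho_i m_{i,e} < C_0$. With $x_{1,e}$ of order 30,
that bounds the second inducer at $u_2 \sim 10^{-2}$. The stable positive
operating points used throughout the package (e.g. $u = (1, 0.02, 1)$) were
chosen once from that feasibility analysis.

**`iffl_crosstalk`** — the same circuit with one change: all three
degradation terms compete for a shared protease pool,
$C_0 (x_i/k_{i,d})/(1 + \sum_j x_j/k_{j,d})$. At any strictly positive
operating point this couples every protein to every other, so $Q$ acquires
all six off-diagonal entries; at the origin the coupling vanishes to first
order (the loading terms are quadratic in the state), a fact the deviation
analysis below exploits.

**`event_detector`** — two constitutive relay genes plus a two-gene mutual
repression memory module with NIMPLY promoter logic; measured outputs are
the two memory proteins, hidden states are two relay proteins and four
mRNAs. Under parameter symmetry ($k_i = k$, $\rho_i = \rho$,
$k_{M,i} = k_M$, first-order repression) the derived entries collapse to
closed forms,

$$Q_{12}(s) = \frac{-k\rho\,(k_l + u_1/k_M)}
{k_M(\delta_m+s)(\delta_p+s)\,(u_1/k_M + x_3/k_M + 1)^2},$$

symmetrically for $Q_{21}$, with $P_{ii}$ sharing the denominator
$(\delta_m+s)(\delta_p+s)$; the test suite checks the package derivation
against these expressions at random parameter draws, which (since both
sides are rational in every parameter) establishes the identity itself.
The kinetic defaults are $k_i = 10$, $k_l = 0.01$, $\rho_i = 5$,
$\delta_p = 0.1$, $\delta_m = 1$, $k_{M,u} = 1000$. Two points are
implementation decisions worth flagging. First, a two-gene toggle with
*first-order* repression is globally monostable — no parameter values can
latch it — so the model exposes a cooperativity parameter `hill`. The
default is `hill = 2` with repression constants $k_{M,2} = k_{M,3} = 1$,
chosen so the maximum protein level $\rho k k_l/(\delta_p\delta_m) = 5$
sits well above the repression threshold; this gives two mirror-image
stable latched states (verified by the test suite). Second, the closed-form
checks use `hill = 1`, the first-order form in which those expressions
hold.

**`repressilator3`** — a generic three-node cyclic repressor
($y_1 \leftarrow y_3 \leftarrow y_2 \leftarrow y_1$) with hidden mRNA,
Hill repression with exposed cooperativity, per-node gain attenuation
factors `atten1..3` (the deliberate single-edge attenuation debugging
scenario), and an optional shared-degradation loading term (`C0load`,
default off) that induces crosstalk edges. It stands in for in vitro
transcriptional oscillators whose full mechanism (enzyme-mediated RNA
degradation, activator sequestration) is out of scope.

## The synthetic-data generator

`generate_experiments()` emulates serial step-input perturbation
experiments: each measured node receives its own step perturbation, either
staggered within one trajectory (`serial = TRUE`) or as one trajectory per
node, with a pre-onset baseline window recorded for detrending and
additive i.i.d. Gaussian noise on the measured outputs only (a bulk-culture,
high-copy-number assumption; single-cell stochasticity is out of scope).
Two choices deserve explanation:

* **`input_mode = "direct"` (default).** Identifiability requires each
  measured node to be *independently* perturbed — the true $P$ must be
  diagonal. The circuits' native inducer channels do not satisfy this (the
  feedforward loop's second inducer drives two nodes at once), which is a
  property of the chemistry, not a modelling artifact. Experimentally one
  perturbs each node directly — e.g. injecting a non-degradable DNA
  analogue of a node's inhibitor, which acts as a held step on that node
  alone. `input_mode = "direct"` emulates exactly that: the perturbation
  enters as an additive rate on the perturbed node's own equation, making
  the ground-truth $P$ diagonal ($V = I$). `input_mode = "channels"` is
  available when steps on the native inputs are wanted.
* **`plant = "linearized"`** simulates the linearization exactly (matrix
  exponential stepping per sampling interval), which is the right plant for
  validating the estimator in isolation; `plant = "nonlinear"` integrates
  the full ODEs (`deSolve::lsoda`, stiff-capable, rtol $10^{-8}$ /
  atol $10^{-10}$) and is what the deviation analysis uses.

What the generator does *not* emulate: growth-phase drift and dilution
dynamics, autofluorescence backgrounds, stochastic (low-copy) kinetics, and
input chemistry such as inducer depletion. Passing the package's seeded
studies therefore demonstrates correctness of the algorithms under the
stated noise model, not robustness to every artifact of plate-reader data.

## Direct estimation

With $P$ diagonal, each output row $i$ is a single-output identification
problem. Writing $\hat Q(z), \hat P(z)$ over a shared monic characteristic
polynomial $z^{n_d} + a_1 z^{n_d-1} + \cdots + a_{n_d}$ per row (the
denominators are per-row, not global: each row is its own $p \times 1$
fit), multiplying through and inverse-transforming gives a linear
regression of $y_i[t]$ on $n_d$ lags of itself, $n_d$ lags of every other
output, and $n_d$ lags of its own input — the stacked normal form
$B = X\Theta$. Structural zeros (the $Q$ diagonal, off-diagonal $P$) are
simply never given regressors, so they are *exactly* zero in the estimate.
Numerator degree is capped at $n_d - 1$, enforcing strict properness. The
least-squares solve is rank-revealing (SVD, `rcond` $10^{-10}$), with an
optional ridge term (default 0).

Two hyperparameters are searched exhaustively over a small grid:

* $n_d$, the row order (default grid 1–6);
* $h_\mathrm{max}$, the number of retained points per trace. Oversampled
  slow transients make adjacent regression rows near-duplicates and the
  regression ill-conditioned; candidates whose condition number exceeds
  $10^8$ are rejected outright. $h_\mathrm{max}$ is realized as
  **block-average decimation** rather than plain thinning: averaging
  within blocks conditions the regression the same way but also attenuates
  measurement noise by $\sqrt{\text{stride}}$, which materially reduces
  spurious edge gains at realistic noise levels.

Selection minimizes the free-run L1 prediction error: candidate
coefficients are fit on the leading 75% of every trace, then scored by
recursive prediction across the *whole* of every trace (own output fed
back, other outputs and inputs from data), normalized by the target's L1
mass so scores are comparable across decimation levels. The whole-trace
score matters: the transient part exposes under-ordered models, while the
part unseen during fitting exposes noise-fitting. Ties break toward smaller
$n_d$, then smaller $h_\mathrm{max}$. The winner is refit on all samples.
Fitted models are deliberately *not* constrained to be stable — capturing
divergent transients is part of the method's point — but unstable entries
are excluded (with a warning) from gain rankings downstream.

Conversion back to continuous time (`to_continuous()`) is entrywise:
bilinear (Tustin) by default, with matched-pole-zero and zero-order-hold
alternatives; structural zeros are preserved exactly. A Tustin-converted
strictly proper entry can carry a small direct feedthrough; exact
derivations are always strictly proper.

## Crosstalk quantification

Given a designed support (or full reference DSF) and an estimate,
`classify_edges()` computes each entry's $H_\infty$ gain, scales by the
maximum, and labels entries: below `tol` → *absent*; at or above `tol`
where the design has no edge → *crosstalk*; on a designed edge →
*designed-active*, flagged *gain-mismatch* when the estimated-to-reference
gain ratio leaves $[0.5, 2]$ (headroom around a deliberate 20%
single-component attenuation). The default `tol = 0.05` sits between the normalized gain scale of minor
in vitro crosstalk interactions and the numerical floor of absent
entries;
classification is invariant to global rescaling of the estimate by
construction.

The deviation theory says more: if $\zeta = y^a - y^c$ is the gap between
an idealized and a crosstalk-affected trajectory under the same input (in
deviation coordinates, both started at the matched operating point), then
to first order $\mathcal{L}(\zeta_i) = \sum_j (Q^a_{ij} - Q^c_{ij})
\mathcal{L}(Y_j)$, with a remainder that is second order in the state.
`crosstalk_scaling_residual()` verifies this numerically with
finite-horizon Laplace transforms on a real $s>0$ grid, using the
*crosstalk* trajectory's transform for $Y$ (the statement leaves this
choice open; it is documented here, not asserted as intent). A subtlety
dictates the study conditions: at a strictly positive pair of matched
equilibria, the two systems' equilibria (hence their $P$ matrices and
closed loops) differ at zeroth order, which injects terms *linear* in the
perturbation amplitude into the residual — halving the amplitude then
halves the residual, and the quadratic law is unobservable. The theorem's
own premise linearizes both systems about the origin with zero initial
condition, and at the origin the two feedforward vector fields agree to
first order (the protease-loading terms are quadratic in state). The
scaling study therefore uses the origin as the matched operating point
(zero baseline input, both models exactly at rest) with step amplitudes
$\varepsilon \cdot 100$ nM, $\varepsilon \in \{10^{-2}, 5\times 10^{-3},
2.5\times10^{-3}\}$; there the residual contracts by well under 0.35 per
halving, as the acceptance study recomputes.

## Numerical design choices

* **Common-factor cancellation** is done by exact state-space reduction,
  not root matching: a controllable-canonical realization of the entry is
  projected onto its observable subspace (SVD rank decision on the
  row-normalized observability matrix, after rescaling the transform
  variable so poles are O(1)), and every candidate reduction is *verified*
  against the original at ~20 points spread over several radii around the
  pole cluster before being accepted. Root-pairing cancellation was
  rejected because an $m$-fold root is located by `polyroot` only to
  $O(\epsilon^{1/m})$ — about $10^{-4}$ relative for the event detector's
  fourth-order mRNA factor — which no fixed pairing tolerance survives.
* **Hidden-block elimination** uses the Faddeev–LeVerrier recursion for
  the adjugate and characteristic polynomial of $(sI - A_{22})$, giving
  all $W, V$ entries over the common denominator in one pass; the row
  scaling $X/(s - W_{ii})$ is collapsed analytically to
  $x_\mathrm{num}/(s\,d - w_{ii})$ when numerator and denominator share
  $d(s)$, avoiding needless degree growth.
* **Impulse kernels** are computed by partial fractions with pole
  clustering at $10^{-7}$ relative tolerance (so float-jittered repeated
  poles are treated as one pole with polynomial-times-exponential terms);
  complex pairs recombine to damped sinusoids and the result is checked to
  be real. An independent matrix-exponential simulation serves as the test
  oracle.
* **Gains**: $H_\infty$ by dense log-spaced sweep ($10^{-6}$–$10^6$ rad
  per unit time, 24000 points) refined by local maximization — accurate to
  the sweep resolution without a Hamiltonian eigensolve, which is adequate
  for ranking edges; $H_2$ exactly via the Lyapunov equation of a
  realization (discrete entries use the discrete analogues on the unit
  circle/disk).
* **Pole-proximity guard**: evaluation errors out when
  $|\mathrm{den}(s_0)| < 10^{-12}\max_k|\mathrm{den}_k|$, naming the
  entry.
* **Degenerate inputs**: constant (unexcited) regressor columns are
  flagged; an all-zero suite estimates all-zero numerators through the
  rank-revealing pseudo-inverse; duplicated timepoints drive the condition
  number over the rejection threshold rather than silently fitting.
* **Matrix functions**: `Matrix::expm` (machine-precision scaling and
  squaring) for discretization and linear simulation; the matrix logarithm
  for zero-order-hold reconstruction uses an eigendecomposition with a
  conditioning check and a dense-algorithm fallback.
* The alternative diagonal-free normalization $Q_\mathrm{alt} = W/s$ is
  not implemented: it sacrifices the zero diagonal, hence uniqueness and
  identifiability.
* **Identifiability counting** (`check_identifiability()`): at least
  $p-1$ entries of each column of $[Q\ P]^*$ must be known beyond the
  structural $Q$ diagonal; the diagonal-$P$ design contributes $m-1$
  known zeros per column and passes when $m \ge p$.

## Study sizes

The seeded validation studies run at desk scale: 200 random partitioned
systems ($n \le 8$, $p \le 4$, $m \le 4$) for the closed-loop consistency
check, 50 random hidden-basis changes, 25 random discrete ground truths
for noiseless recovery, ten seeds × two circuit variants for the
end-to-end crosstalk detection study (three per-node step experiments of
401 samples each at 1% relative noise), and three perturbation amplitudes
for the deviation-scaling study (3000 time units at $\Delta t = 10$).
These sizes were chosen to exercise every code path with comfortable
statistical margins.

## Known limitations

* Only `builtin:` models are exposed through the CLI config format;
  arbitrary user models are constructed in R.
* Order selection is grid search; Hankel-rank order estimation is not
  implemented.
* Crosstalk that rides on an *existing* designed edge cannot be separated
  from the designed dynamics by support comparison alone — only flagged
  via gain mismatch.
* No statistical significance testing or bootstrap confidence bands on
  edge presence: the threshold classification is deterministic given the
  estimate.
* The bilinear conversion of estimated entries can introduce a small
  direct feedthrough; use `method = "zoh"` when strict properness of the
  converted estimate matters and the row poles are well inside the unit
  circle.
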