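---
title: "Imaginary-time-averaged density matrices and stochastic CASPT2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaginary-time-averaged density matrices and stochastic CASPT2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcpt2)
```

## The problem

Multireference perturbation theory on large complete active space (CAS)
references needs the active-space reduced density matrices (RDMs) up to rank
three, plus the rank-four tensor contracted with the generalized Fock matrix
(the F.4RDM). When the CAS eigenvector is itself obtained stochastically —
by full configuration interaction quantum Monte Carlo (FCIQMC), where signed
walker populations on determinants integrate the imaginary-time Schrödinger
equation — the RDMs must be estimated from noisy snapshots. The standard
remedy is replica sampling: two statistically independent walker populations
are propagated and products $C^{(1)}_i C^{(2)}_j$ are averaged, which makes
the estimator unbiased because the two factors have zero covariance. But a
*finite* replica average is not the RDM of any pure state: its 3RDM
matrixization develops negative eigenvalues, and internally contracted
CASPT2 — which must invert overlap (metric) matrices built from those RDMs —
amplifies such fermionic-positivity violations into numerical instability.

The protocol implemented here cures this at the source. Because the
determinants of the semistochastic (deterministically projected) subspace
are held in memory anyway, their instantaneous coefficients can be averaged
over imaginary time at no extra cost, and the same greedy rule can extend
the *histogrammable set* beyond the subspace: any determinant whose
population stays above a selection threshold for one full reporting period
is added, and from then on its instantaneous weight — including zeros — is
accumulated every iteration. After the run, determinants whose average
occupation falls below a discard threshold $t$ (in walkers) are dropped and
the rest is renormalized. The result is a single pure-state vector, so
*every* positivity condition of its RDMs holds by construction; the price is
a truncation error that is systematically controlled by $t$ and by the
averaging duration.

## Package anatomy

* `integrals_io`: FCIDUMP reading/writing (1-based indices, chemist-notation
  $(pq|rs)$ with 8-fold symmetry), synthetic Hamiltonians (Hubbard chains,
  random two-body sets, minimal-basis H2 computed from closed-form s-type
  Gaussian integrals), the generalized Fock matrix
  $f_{pq} = h_{pq} + \sum_{rs} D_{rs}\,[(pq|rs) - \tfrac12 (pr|sq)]$ with
  $D = 2$ on inactive and $\Gamma^{(1)}$ on active orbitals, and
  pseudocanonical rotations (separate diagonalization of the
  inactive/active/virtual Fock blocks).
* `detspace`: determinants as per-spin bitmasks, Slater–Condon matrix
  elements, connection enumeration, and sparse matrices of the spin-free
  excitation operators $E_{pq}$.
* `exact_ci`: Davidson diagonalization and exact normal-ordered spin-free
  RDMs. The convention is
  $\Gamma^{(2)}_{pq,rs} = \langle E_{pq}E_{rs}\rangle - \delta_{qr}\langle E_{ps}\rangle$
  and its rank-3 analogue, i.e. the expectations of the two- and three-body
  operators $e_{pq,rs}$, $e_{pq,rs,tu}$; a literal spin-orbital oracle in
  the test suite pins this convention numerically rather than by prose.
  The F.4RDM $\bar A_{pq,rs,tu} = \sum_{vw} f_{vw}\Gamma^{(4)}_{pq,rs,tu,vw}$
  is never formed from a stored 4RDM: the CAS is closed under active
  excitations, so $|F\rangle = \sum_{vw} f_{vw}E_{vw}|\psi\rangle$ lives in
  the same determinant space and $\bar A$ equals the transition 3RDM
  $\langle\psi|e_{pq,rs,tu}|F\rangle$ minus three $f$-contracted
  $\Gamma^{(3)}$ re-normal-ordering terms.
* `fciqmc`: vectorized walker dynamics (spawning, diagonal death/cloning,
  annihilation, shift control, optional semistochastic projection, optional
  initiator rule), the histogram accumulators, projected-energy and shift
  estimators with Flyvbjerg–Petersen blocking errors.
* `rdm_estimators`: the three RDM routes (pure histogram, replica, hybrid),
  the excitation-driven sparse RDM builder, positivity reports and the
  nearest-PSD projection.
* `caspt2`: internally contracted CASPT2 with IPEA and imaginary shifts,
  Löwdin orthogonalization with linear-dependence truncation, and an
  explicit-vector oracle.

## The CASPT2 working equations as operator algebra

The first-order interacting space is spanned by the doubly excited
perturbers $E_{pq}E_{rs}|\psi\rangle$, grouped into eight classes by their
(inactive-hole, virtual-electron) pattern. Rather than transcribing the
closed-form per-class matrix elements from the literature, the package
evaluates every overlap ($S$), zeroth-order ($B$) and right-hand-side ($V$)
element with a generic contraction engine: inactive and virtual indices are
eliminated exactly through the commutator
$E_{ab}E_{cd} = E_{cd}E_{ab} + \delta_{bc}E_{ad} - \delta_{da}E_{cb}$
(virtual annihilators move right until they contract or hit the ket;
inactive creators likewise, using $E_{iq}|\psi\rangle = 2\delta_{iq}|\psi\rangle$),
and the surviving pure-active string is reduced to normal-ordered
$e$-operators whose expectations are the stored $\Gamma^{(1\ldots3)}$. One
operator pair may represent $\sum_{vw}f_{vw}E_{vw}$ symbolically; a
surviving intact symbolic pair at active rank four is precisely an element
of the F.4RDM. The engine therefore consumes exactly the tensors the theory
requires — at most $\Gamma^{(3)}$ for $S$ and $V$, the F.4RDM for $B$ — and
is validated element-by-element against literal operator products in the
full determinant space, and end-to-end against the explicit-vector CASPT2
oracle, which builds every perturber as an explicit vector and computes the
same matrices as plain inner products.

Design choices in this module, made where the formulation is genuinely
open:

* **Zeroth-order operator.** $H_0$ is the generalized Fock operator
  projected onto the space-diagonal blocks; couplings between excitation
  classes through the inactive–active–virtual off-diagonal Fock blocks are
  dropped. This is the standard projected formulation; it is exact in the
  pseudocanonical basis, which is the default (`basis_mode =
  "pseudocanonical"` rotates integrals and co-rotates all RDM tensors,
  including the F.4RDM, whose contracted pair transforms jointly with the
  Fock matrix).
* **Linear dependence.** Each class metric is diagonalized and eigenvectors
  below `lindep_threshold` (default $10^{-8}$, relative to the largest
  eigenvalue of the class) are discarded; $X = U s^{-1/2}$ orthonormalizes
  the rest. A metric eigenvalue below $-10^{-6}$ aborts with an error
  naming the class — that is exactly the instability mode that
  positivity-violating RDMs trigger, and it must not be silently absorbed.
* **IPEA shift.** The shift is applied as
  $B \mathrel{+}= \tfrac{\varepsilon_\mathrm{IPEA}}{4}(\Theta S + S\Theta)$
  with $\theta_\mu$ summing, over the *active* indices of perturber $\mu$
  only, $2-\Gamma^{(1)}_{tt}$ for creations and $\Gamma^{(1)}_{tt}$ for
  annihilations. Inactive/virtual indices contribute nothing, so the MP2
  limit is IPEA-independent. This occupation-weighted convention is pinned
  here and exercised by the oracle with nonzero IPEA; parity with any
  specific production code's micro-convention is not claimed. The default
  0.25 Hartree is the conventional value; the imaginary shift defaults to
  0.1 Hartree.
* **Imaginary shift.** Amplitudes are damped as
  $t_k = -V_k \Delta_k/(\Delta_k^2+\varepsilon^2)$ in the eigenbasis of the
  orthonormalized $B$, and the energy is reported through the corrected
  Hylleraas form $E_2 = \sum_k t_k^2\Delta_k + 2t_kV_k$, not the raw
  complex-shifted value. $|E_2|$ is monotone non-increasing in
  $\varepsilon$. With $\varepsilon = 0$ a vanishing denominator raises an
  intruder-state error advising a nonzero shift.
* **Reference weight** is reported for the (possibly truncated) reference
  actually used: $\omega = 1/(1+\|t\|^2)$ in the orthonormal basis.

## Walker dynamics and its parameters

`qmc_params` collects the knobs that matter (all energies in Hartree,
"walkers" are unsigned weight units):

* `tau` (default 0.02 / Hartree): first-order projector step; must stay
  below the inverse spectral range, and the run warns when the diagonal
  death factor exceeds one.
* `n_target`: the walker population at which the shift becomes variable.
  The update $S \leftarrow S - \tfrac{\zeta}{A\tau}\ln(N_w/N_w')$ uses
  `shift_damping` $\zeta = 0.5$ every `shift_update_period` $A = 5$
  iterations, and the shift is initialized from the instantaneous projected
  energy when control engages. The per-update correction is roughly
  $\zeta$ times the energy offset; desk-scale Hamiltonians have large
  correlation energies per determinant, so weaker control (small $\zeta$)
  lets the population overshoot by orders of magnitude before the shift
  catches up.
* Real-valued walker weights with a minimum spawn magnitude (`min_spawn`,
  default $10^{-3}$) and stochastic rounding below it; excitations are
  drawn uniformly among the nonzero Hamiltonian connections of the source
  determinant, and the spawn amplitude carries the inverse generation
  probability. An initiator rule is available but off by default.
* `semistoch_size`: the most-populated determinants (ties broken by the
  canonical determinant order) are selected when the shift becomes
  variable; inside this set projection is applied exactly each iteration
  and stochastic spawns between subspace members are discarded.
* Stationarity: histogram and sampling windows open `equilibration`
  (default 500) iterations after the shift turns variable.
* Reproducibility: the generator is re-keyed per (seed, replica,
  iteration), so a trajectory is bit-reproducible from its seed and the two
  replicas are independent by construction.

## The three RDM estimators

All sampled estimators scale each stored snapshot to unit L2 norm before
multiplying. The final tensors are trace-normalized to the exact
$N, N(N-1), N(N-1)(N-2)$ traces, so this choice cannot change the
estimator's target; what it removes is the slow population-norm drift
between the two replicas, which at desk-scale walker numbers ($10^3$–$10^5$)
is a few percent and would otherwise contaminate the consistency between
differently estimated blocks of the pair density. At the walker numbers of
production calculations ($10^7$–$10^8$) this drift is negligible and the
distinction immaterial. The hermiticity error is recorded *before*
symmetrization, then tensors are symmetrized, then trace-normalized — in
that fixed order, so diagnostics are comparable across modes.

* **Replica**: the mean over snapshots of the transition-RDM contraction of
  $u^{(1)} (u^{(2)})^{\mathsf T}$. Unbiased, but each finite average
  violates positivity; violations grow with rank and shrink with sampling.
* **Pure histogram**: RDMs of the truncated, renormalized
  imaginary-time-averaged vector. Positivity of every matrixization is
  automatic because the vector is a pure state. The averages include
  unoccupied cycles (zeros); the occupied-cycle counts are recorded and
  reported but are *not* used as denominators here.
* **Hybrid**: the replica estimator with the deterministic-subspace pair
  block replaced by the product of the two replicas' independently averaged
  subspace coefficients — "first average, then multiply". The averages are
  again zero-inclusive: dividing by occupied cycles only would estimate a
  conditional mean and systematically inflate marginally occupied subspace
  determinants relative to the zero-inclusive remainder, which in
  experiments on the Hubbard fixtures *worsened* positivity instead of
  improving it. With zero-inclusive averages the hybrid's negative
  eigenvalue mass sits between pure histogramming (exactly zero) and the
  replica estimator on the package's fixtures, reproducing the qualitative
  ordering of the three schemes.

The excitation-driven sparse RDM builder (`rdms_from_vector(method =
"excitation")`) realizes the selected-CI-style algorithm: for each stored
determinant all excitations up to the target rank are generated and a
contribution is accumulated only when the excited determinant is found in
the stored set. It shares no code path with the dense operator route beyond
the determinant layer, and the two agree to machine precision — that
equality *is* the exactness contract of the sparse algorithm. At desk scale
the dense route is used automatically above 64 determinants; the sparse
route is the one that generalizes to large stochastic selections.

`f4rdm_from_histogram` adds the $|F\rangle$ compression knob: coefficients
of $|F\rangle$ below a relative threshold (default $10^{-8}$) are dropped
without renormalization ($|F\rangle$ is an operator image, not a state);
zero compression reproduces the exact pathway on the same vector, and the
error grows monotonically with the threshold on the fixtures.

## What the synthetic fixtures do and do not emulate

The generators stand in for the transition-metal active spaces of
production calculations:

* `make_hubbard(L, t, U)` — strong, tunable static correlation with sparse
  connectivity; the main dynamics fixture is the periodic $L=6$, $U/t=4$
  chain at half filling (CAS(6,6), 400 determinants), run with $5\times10^4$
  walkers for 20k iterations and a ~15k-iteration histogram window in the
  acceptance tests. Positivity comparisons use deliberately *short* (2k
  iteration) and sparse (2k walkers, i.e. ~5 walkers per determinant)
  two-replica runs with a 40-determinant semistochastic space — the noisy
  regime where estimator differences are visible.
* `make_random_twobody(n, seed, scale)` — dense, symmetry-free two-electron
  structure for oracle work (CAS(4,4), 36 determinants) and for CASPT2
  fixtures with genuine inactive/active/virtual partitions.
* `make_h2_sto3g()` — a real molecular integral set computed from
  closed-form Gaussian integrals, with the generator's own independent 2x2
  full-CI secular solution as a cross-check.

What passing these tests shows: the estimators, contractions and
perturbation equations are mutually consistent and exact where exactness is
claimed, and the stochastic machinery reproduces deterministic answers
within its own error bars. What they do not show: behaviour under
point-group symmetry blocking, initiator bias at production walker numbers,
the interplay with orbital optimization, or wall-clock viability beyond
enumerable spaces — the fixtures are enumerable by design so that every
stochastic result has a deterministic oracle.

## Numerical choices and degenerate inputs

* Degenerate Fock eigenvalues are tie-broken by lexicographic comparison of
  absolute eigenvector components, and signs are fixed by making the
  largest-magnitude component positive, so pseudocanonicalization is
  deterministic.
* Determinant order is total: $(\alpha,\beta)$ bitmasks compared as
  unsigned integers. All enumerations, tie-breaks and semistochastic
  selections inherit reproducibility from it.
* Bitmasks are R integers (31 orbitals per spin); desk scale needs far
  fewer.
* FCIDUMP writing emits one canonical symmetry representative per value,
  drops magnitudes below $10^{-12}$, and prints 16 significant digits so a
  read/write round trip is value-exact to ~$10^{-14}$.
* Blocking errors use Flyvbjerg–Petersen halving with a plateau rule:
  the first level whose successor grows by less than 3%, falling back to
  the largest estimate with at least 16 blocks. The projected-energy error
  propagates numerator/denominator covariance at each blocking level.
* The Davidson solver falls back to dense diagonalization below ~60
  determinants; iterative residual norms bottom out around $10^{-9}$ on the
  degenerate-diagonal Hubbard fixtures, which bounds energy errors near
  machine precision (quadratic in the residual).

## Known limitations

* Single-state theory only: no multi-state or extended multi-state mixing,
  no analytic gradients, no cumulant approximation of the F.4RDM.
* The replica estimator samples full snapshot outer products rather than
  compressing the off-diagonal accumulation into spawning events; at desk
  scale the snapshot contraction is exact and cheap, but the
  spawning-event compression is what scales to non-enumerable spaces.
* Point-group labels restrict determinant enumeration only; integrals are
  not stored symmetry-blocked.
* The engine-based CASPT2 is dense per class and intended for desk-scale
  orbital counts (say, up to ten orbitals); its value is transparency and
  oracle-verifiability, not throughput.
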