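# qcpt2

Stochastic CAS-CI (FCIQMC) with imaginary-time-averaged density matrices
and internally contracted CASPT2, at desk scale and fully oracle-checked.

## What this is for

Second-order perturbation theory on a complete-active-space (CAS) reference
— CASPT2 — needs the active-space reduced density matrices Γ⁽¹⁾…Γ⁽³⁾ and
the Fock-contracted 4RDM,

    Ā_pq,rs,tu = Σ_vw f_vw Γ⁽⁴⁾_pq,rs,tu,vw ,

where f is the generalized Fock matrix. When the CAS eigenvector is
obtained with full configuration interaction quantum Monte Carlo (FCIQMC),
the RDMs must be estimated from stochastic walker populations. The standard
replica estimator (averaging products of two independent populations) is
unbiased but its finite averages violate fermionic positivity: the 3RDM
matrixization develops negative eigenvalues, and the Löwdin
orthogonalization at the heart of internally contracted CASPT2 turns those
violations into numerical instability.

This package implements the cure: **histogramming**. Determinants selected
by a greedy occupancy rule have their instantaneous walker weights averaged
over imaginary time (zeros included); after discarding averages below a
threshold *t* (in walkers) and renormalizing, the result is a *pure state*,
so every positivity condition of its RDMs holds by construction. The
Fock-contracted 4RDM is evaluated without ever forming a 4RDM, as a
transition 3RDM with the singly excited state |F⟩ = Σ f_vw E_vw |ψ⟩. The
package provides, as first-class tested code:

* FCIDUMP I/O and synthetic Hamiltonian fixtures (Hubbard chains, random
  two-body sets, minimal-basis H₂ from closed-form Gaussian integrals);
* determinant algebra, Slater–Condon rules, spin-free excitation operators;
* Davidson CI, exact/transition RDMs, the |F⟩ pathway, and literal
  spin-orbital brute-force oracles;
* vectorized FCIQMC (spawning, death, annihilation, shift control,
  semistochastic subspace, replicas, blocking analysis);
* the three RDM estimators — replica, hybrid, pure histogram — with
  positivity diagnostics;
* internally contracted CASPT2 (eight perturber classes, IPEA and imaginary
  shifts, Löwdin truncation) whose S/B/V matrices are assembled by a
  generic spin-free contraction engine consuming at most Γ⁽³⁾ and the
  F.4RDM, verified against an explicit-vector oracle to 1e-8.

Everything runs on enumerable determinant spaces so that each stochastic
result has a deterministic oracle; see the methods vignette
(`vignettes/histogrammed-rdm-caspt2.Rmd`) for the model, conventions and
design decisions.

## Worked example

```r
library(qcpt2)

## CASPT2 on a correlated toy system: 6 orbitals, 6 electrons, CAS(2,2)
ints  <- make_random_twobody(6, seed = 31, scale = 0.05)
space <- orbital_space(inactive = 1:2, active = 3:4, virtual = 5:6, n_elec = 6)
caspt2_energy(ints, space, caspt2_params(ipea = 0.25, imaginary_shift = 0.1))
#> CASPT2 second-order energy
#>   reference energy :      -2.6579845343 Eh
#>   E2 total         :      -0.1572855593 Eh
#>   total energy     :      -2.8152700936 Eh
#>   reference weight :  89.25 %
#>   per class: A=-0.07351822 B=-0.00102621 C=-0.00856748 D=-0.06220569
#>              E=-0.00384389 F=-0.00033153 G=-0.00498860 H=-0.00280395

## stochastic CAS-CI on a Hubbard chain, then the histogrammed wave function
hub  <- make_hubbard(6, t = 1, U = 4, boundary = "periodic")
dets <- enumerate_cas(6, 3, 3)
p    <- qmc_params(tau = 0.02, n_target = 20000, n_iters = 6000, seed = 1,
                   semistoch_size = 50, histogram_threshold = 1)
run  <- run_fciqmc(hub, dets, p)
projected_energy(run)     # -3.668770 +- 0.000328 Eh
davidson(run$H)$values[1] # -3.668706 Eh (exact, for comparison)

hist <- truncate_and_normalize(histogram_vector(run), t = 0)
positivity_report(rdms_from_vector(hist$ci, dets, max_rank = 3))
#> 3RDM positivity report (histogram, spin-free)
#>   eigenvalues < -1e-10 : 0 (total negative mass 0.000e+00)
#>   hermiticity error : 0.000e+00
#>   trace deviations  : trace1=1.78e-15 trace2=2.66e-15 trace3=5.88e-15
```

The projected energy agrees with the exact Davidson energy within its
blocking error bar; the histogrammed vector overlaps the exact ground state
to better than 0.9999, and its 3RDM is positive semidefinite *exactly* —
the property that makes the subsequent CASPT2 metric inversions stable. The
replica estimator on the same dynamics (`replica_rdms(run)`) reports
negative eigenvalues and a nonzero hermiticity error.

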