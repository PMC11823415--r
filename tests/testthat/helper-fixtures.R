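# Shared fixtures, built once per test session and cached.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Hubbard dimer: ground state at half filling is 2 - 2 sqrt(2) for t=1, U=4
hub2 <- function() fx_get("hub2", function() {
  ints <- make_hubbard(2, 1, 4)
  ds <- enumerate_cas(2, 1, 1)
  list(ints = ints, ds = ds, H = build_hamiltonian(ds, ints),
       e0 = 2 - 2 * sqrt(2))
})

hub6 <- function() fx_get("hub6", function() {
  ints <- make_hubbard(6, 1, 4, "periodic")
  ds <- enumerate_cas(6, 3, 3)
  H <- build_hamiltonian(ds, ints)
  dv <- davidson(H, tol = 1e-9)
  list(ints = ints, ds = ds, H = H, e0 = dv$values[1], vec = dv$vectors[, 1])
})

# random CAS(4,4) problem with exact ground state and RDMs
rand44 <- function(seed = 7) fx_get(paste0("rand44_", seed), function() {
  ints <- make_random_twobody(4, seed = seed)
  gs <- casci_ground_state(ints, 2, 2, tol = 1e-11)
  C <- gs$vectors[, 1]
  list(ints = ints, ds = gs$dspace, H = gs$H, e0 = gs$energies[1], C = C,
       rdms = exact_rdms(C, gs$dspace, 3))
})

# (2 inactive, 2 active, 2 virtual) toy with 6 electrons, pre-rotated to the
# pseudocanonical basis so production and oracle share orbitals exactly
toy222 <- function() fx_get("toy222", function() {
  ints <- make_random_twobody(6, seed = 31, scale = 0.05)
  space <- orbital_space(inactive = 1:2, active = 3:4, virtual = 5:6,
                         n_elec = 6)
  ha <- active_hamiltonian(ints, space)
  gs <- casci_ground_state(ha, 1, 1, tol = 1e-11)
  rd1 <- exact_rdms(gs$vectors[, 1], gs$dspace, 1)
  fock <- build_generalized_fock(ints, rd1$gamma1, space)
  pc <- pseudocanonicalize(ints, fock, space)
  list(ints = ints, ints_pc = pc$ints, space = space, fock = fock, pc = pc)
})

# mixed-space engine test system: (1 inactive, 3 active, 1 virtual),
# 6 electrons, with everything needed to evaluate operator strings both
# through the contraction engine and explicitly in the full space
mixed5 <- function() fx_get("mixed5", function() {
  space <- orbital_space(inactive = 1L, active = 2:4, virtual = 5L,
                         n_elec = 6)
  ints <- make_random_twobody(5, seed = 9)
  ha <- active_hamiltonian(ints, space)
  gs <- casci_ground_state(ha, 2, 2, tol = 1e-11)
  Cact <- gs$vectors[, 1]
  rd <- exact_rdms(Cact, gs$dspace, 3)
  set.seed(402)
  f_act <- matrix(stats::rnorm(9), 3, 3)
  f_act <- (f_act + t(f_act)) / 2
  A4 <- f_contracted_4rdm(Cact, gs$dspace, f_act, gamma3 = rd$gamma3)
  ctx <- qcpt2:::wick_context(space, rd$gamma1, rd$gamma2, rd$gamma3,
                              f_act, A4)
  dfull <- enumerate_cas(5, 3, 3)
  psi <- expand_cas_vector(Cact, gs$dspace, space, dfull)
  opsF <- qcpt2:::spinfree_ops(dfull)
  list(space = space, ints = ints, dact = gs$dspace, C = Cact, rd = rd,
       f_act = f_act, ctx = ctx, dfull = dfull, psi = psi, opsF = opsF)
})

# apply a product of full-space E operators and take the expectation value
full_expectation <- function(mx, ops) {
  v <- mx$psi
  for (k in rev(seq_len(nrow(ops))))
    v <- as.numeric(qcpt2:::get_Eop(mx$opsF, 5, ops[k, 1], ops[k, 2]) %*% v)
  sum(mx$psi * v)
}

random_orthogonal <- function(n) qr.Q(qr(matrix(stats::rnorm(n * n), n)))
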