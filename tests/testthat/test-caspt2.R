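test_that("perturber class dimensions match hand-counted index tuples", {
  sp <- orbital_space(inactive = 1:2, active = 3:4, virtual = 5:6, n_elec = 6)
  cls <- qcpt2:::enumerate_perturbers(sp)
  dims <- vapply(cls, function(x) length(x$ops), 0L)
  # A: t,i,u,v = 2*2*2*2; B: unordered pairs of 4 (t,i) combos incl equal;
  # C: a,t,u,v; D: (ai,tu) + (ti,au); E: t,i,a,j; F/H like B; G: a,i,b,t
  expect_equal(unname(dims[c("A", "B", "C", "D", "E", "F", "G", "H")]),
               c(16L, 10L, 16L, 32L, 16L, 10L, 16L, 10L))
  # empty active space: only the doubly-external/doubly-internal class
  sp0 <- orbital_space(inactive = 1:2, active = integer(0), virtual = 3:4,
                       n_elec = 4)
  dims0 <- vapply(qcpt2:::enumerate_perturbers(sp0),
                  function(x) length(x$ops), 0L)
  expect_true(all(dims0[c("A", "B", "C", "D", "E", "F", "G")] == 0L))
  expect_gt(dims0["H"], 0L)
})

test_that("Lowdin truncation orthonormalizes and discards null directions", {
  lw <- lowdin_truncate(diag(3))
  # for S = I the transformation is orthogonal (identity up to basis freedom)
  expect_equal(crossprod(lw$X), diag(3), tolerance = 1e-12)
  expect_equal(lw$n_kept, 3L)
  lw2 <- lowdin_truncate(diag(c(1, 1e-12)), 1e-8)
  expect_equal(lw2$n_kept, 1L)
  set.seed(77)
  A <- matrix(stats::rnorm(64), 8)
  S <- crossprod(A)
  lw3 <- lowdin_truncate(S, 1e-10)
  expect_lt(max(abs(t(lw3$X) %*% S %*% lw3$X - diag(lw3$n_kept))), 1e-10)
  expect_error(lowdin_truncate(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("MP2 limit: empty active space equals the closed-form expression", {
  pt0 <- caspt2_params(ipea = 0, imaginary_shift = 0)
  fixtures <- list(
    list(ints = make_random_twobody(5, seed = 21, scale = 0.1),
         space = orbital_space(inactive = 1:2, active = integer(0),
                               virtual = 3:5, n_elec = 4)),
    list(ints = make_random_twobody(6, seed = 35, scale = 0.08),
         space = orbital_space(inactive = 1:3, active = integer(0),
                               virtual = 4:6, n_elec = 6)),
    list(ints = make_h2_sto3g()$ints,
         space = orbital_space(inactive = 1L, active = integer(0),
                               virtual = 2L, n_elec = 2)))
  for (fx in fixtures) {
    e_mp2 <- mp2_energy(fx$ints, fx$space)
    res <- caspt2_energy(fx$ints, fx$space, pt0)
    expect_equal(res$e2_total, e_mp2, tolerance = 1e-9)
  }
  # minimal two-electron model: single pair energy -(ov|ov)^2/(2(ev-eo))
  h2 <- fixtures[[3]]
  fock <- build_generalized_fock(h2$ints, matrix(0, 0, 0), h2$space)
  pc <- pseudocanonicalize(h2$ints, fock, h2$space)
  g <- pc$ints$g
  analytic <- -g[1, 2, 1, 2]^2 / (2 * (pc$eps[2] - pc$eps[1]))
  expect_equal(caspt2_energy(h2$ints, h2$space, pt0)$e2_total, analytic,
               tolerance = 1e-10)
})

test_that("RDM-based CASPT2 equals the explicit-vector oracle", {
  toy <- toy222()
  for (ps in list(c(0, 0), c(0.25, 0.1))) {
    pt <- caspt2_params(ipea = ps[1], imaginary_shift = ps[2],
                        basis_mode = "general")
    prod <- caspt2_energy(toy$ints_pc, toy$space, pt)
    orac <- explicit_vector_oracle(toy$ints_pc, toy$space, pt)
    expect_equal(prod$e2_total, orac$e2_total, tolerance = 1e-8)
    expect_equal(prod$e_ref, orac$e_ref, tolerance = 1e-9)
    expect_equal(prod$reference_weight, orac$reference_weight,
                 tolerance = 1e-8)
    expect_equal(prod$e2_by_class[names(orac$e2_by_class)],
                 orac$e2_by_class, tolerance = 1e-8)
  }
})

test_that("E2 is invariant under subspace rotations and pseudocanonicalization", {
  toy <- toy222()
  pt <- caspt2_params(0.25, 0.1)
  r0 <- caspt2_energy(toy$ints, toy$space, pt)
  set.seed(99)
  U <- diag(6)
  U[1:2, 1:2] <- random_orthogonal(2)
  U[3:4, 3:4] <- random_orthogonal(2)
  U[5:6, 5:6] <- random_orthogonal(2)
  r1 <- caspt2_energy(rotate_integrals(toy$ints, U), toy$space, pt)
  expect_equal(r1$e2_total, r0$e2_total, tolerance = 1e-8)
  # pre-rotated integrals in general mode give the same answer
  r2 <- caspt2_energy(toy$ints_pc, toy$space,
                      caspt2_params(0.25, 0.1, basis_mode = "general"))
  expect_equal(r2$e2_total, r0$e2_total, tolerance = 1e-8)
})

test_that("imaginary shift damps |E2| monotonically", {
  toy <- toy222()
  e2s <- vapply(c(0, 0.1, 0.2, 0.3), function(eps)
    caspt2_energy(toy$ints_pc, toy$space,
                  caspt2_params(ipea = 0, imaginary_shift = eps,
                                basis_mode = "general"))$e2_total, 0)
  expect_true(all(diff(abs(e2s)) <= 1e-12))
})

test_that("a positivity-violating Gamma3 fails loudly in the block build", {
  toy <- toy222()
  res <- caspt2_energy(toy$ints_pc, toy$space,
                       caspt2_params(basis_mode = "general"))
  det <- attr(res, "detail")
  rd <- det$rdms
  # inject a negative eigenvalue into the 3RDM matrixization
  n <- rd$n_act
  M <- gamma3_matrixization(rd$gamma3)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  eps <- 0.05
  M2 <- M - (eg$values[1] * 0 + eps) *
    tcrossprod(eg$vectors[, ncol(eg$vectors)])
  G2 <- array(aperm(array(M2, rep(n, 6)), c(1, 4, 2, 5, 3, 6)), rep(n, 6))
  rd_bad <- rdm_set(rd$gamma1, rd$gamma2, G2, f4 = rd$f4,
                    provenance = "replica", n_act_elec = rd$n_act_elec)
  expect_error(build_class_blocks(det$ints, toy$space, rd_bad, det$fock),
               "positiv")
})

test_that("CASPT2 from an exact ci_active vector equals the exact pipeline", {
  toy <- toy222()
  pt <- caspt2_params()
  r0 <- caspt2_energy(toy$ints, toy$space, pt)
  ha <- active_hamiltonian(toy$ints, toy$space)
  gs <- casci_ground_state(ha, 1, 1, tol = 1e-11)
  r1 <- caspt2_energy(toy$ints, toy$space, pt, ci_active = gs$vectors[, 1])
  expect_equal(r1$e2_total, r0$e2_total, tolerance = 1e-8)
})
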