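test_that("CAS enumeration counts and ordering are deterministic", {
  expect_equal(enumerate_cas(2, 1, 1)$n_det, 4L)
  expect_equal(enumerate_cas(6, 3, 3)$n_det, choose(6, 3)^2)
  d <- enumerate_cas(4, 2, 1)
  expect_true(all(diff(d$key) > 0))
  # symmetry restriction can only shrink the space
  osym <- c(1L, 2L, 1L, 2L)
  dsym <- enumerate_cas(4, 2, 2, orb_sym = osym, isym = 1L)
  expect_lte(dsym$n_det, enumerate_cas(4, 2, 2)$n_det)
  expect_gt(dsym$n_det, 0L)
  expect_error(enumerate_cas(4, 5, 0))
})

test_that("Slater-Condon rules: rank cutoff, hermiticity, analytic dimer", {
  h2 <- hub2()
  # rank-3 difference vanishes identically
  d6 <- enumerate_cas(6, 3, 3)
  i6 <- make_hubbard(6, 1, 4)
  a1 <- bit_mask(1:3); b1 <- bit_mask(1:3)
  a2 <- bit_mask(4:6); b2 <- bit_mask(1:3)   # alpha triple excitation
  expect_identical(slater_condon(a2, b2, a1, b1, i6), 0)
  # analytic 4x4 Hubbard dimer block: order |20>,|ud>,|du>,|02>
  H <- as.matrix(h2$H)
  ds <- h2$ds
  lbl <- paste(ds$alpha, ds$beta)
  # diagonal: doubly occupied sites have U = 4, singly occupied 0
  docc <- ds$alpha == ds$beta
  expect_equal(sort(diag(H)), sort(ifelse(docc, 4, 0)))
  # all off-diagonal couplings between single/double occupancy are +-t
  off <- H[upper.tri(H)]
  expect_setequal(round(abs(off[off != 0]), 12), 1)
  # hermiticity on a random system
  r4 <- rand44()
  Hm <- as.matrix(r4$H)
  expect_lt(max(abs(Hm - t(Hm))), 1e-12)
})

test_that("connections enumerate exactly the nonzero Hamiltonian row", {
  # Hubbard: off-diagonals are nearest-neighbour hops; count by hand for the
  # alternating half-filled determinant of an open L=4 chain
  i4 <- make_hubbard(4, 1, 4, "open")
  d4 <- enumerate_cas(4, 2, 2)
  k <- det_index(d4, bit_mask(c(1, 3)), bit_mask(c(2, 4)))
  cn <- connections(d4, k, i4)
  # each of the 4 electrons can hop left/right onto an empty neighbour:
  # alpha on 1 -> 2; alpha on 3 -> 2,4; beta on 2 -> 1,3; beta on 4 -> 3
  expect_equal(length(cn$idx), 6L)
  expect_true(all(abs(abs(cn$h) - 1) < 1e-12))
  # screen = Inf yields nothing
  expect_length(connections(d4, k, i4, screen = Inf)$idx, 0L)
  # consistency with the dense row for a correlated Hamiltonian
  r4 <- rand44()
  row <- as.numeric(r4$H[, 5])
  cn2 <- connections(r4$ds, 5L, r4$ints, screen = 0)
  dense_off <- sum(row[-5]^2)
  expect_equal(sum(cn2$h^2), dense_off, tolerance = 1e-12)
})

test_that("spin-free excitation operators obey number and RDM identities", {
  r4 <- rand44()
  C <- r4$C
  # E_pp on a doubly occupied orbital multiplies by 2
  d2 <- enumerate_cas(2, 1, 1)
  vec <- numeric(4)
  k <- det_index(d2, 1L, 1L)         # both electrons on orbital 1
  vec[k] <- 1
  expect_equal(apply_spinfree_excitation(vec, d2, 1, 1), 2 * vec)
  # <psi|E_pq|psi> equals Gamma1
  for (p in 1:4) for (q in 1:4) {
    expect_equal(sum(C * apply_spinfree_excitation(C, r4$ds, p, q)),
                 r4$rdms$gamma1[p, q], tolerance = 1e-12)
  }
  # parity: the operator matrix equals the adjoint of its reverse
  E12 <- qcpt2:::spinfree_op(r4$ds, 1, 2)
  E21 <- qcpt2:::spinfree_op(r4$ds, 2, 1)
  expect_lt(max(abs(E12 - Matrix::t(E21))), 1e-14)
  # commutator [E_pq, E_rs] = d_qr E_ps - d_sp E_rq on the dense space
  E13 <- as.matrix(qcpt2:::spinfree_op(r4$ds, 1, 3))
  E32 <- as.matrix(qcpt2:::spinfree_op(r4$ds, 3, 2))
  Ecm <- E13 %*% E32 - E32 %*% E13
  expect_equal(Ecm, as.matrix(qcpt2:::spinfree_op(r4$ds, 1, 2)),
               tolerance = 1e-12)
  expect_error(apply_spinfree_excitation(C, r4$ds, 0, 5), "outside")
})
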