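test_that("Davidson recovers closed-form and dense spectra", {
  h2 <- hub2()
  expect_equal(davidson(h2$H)$values[1], h2$e0, tolerance = 1e-10)
  h6 <- hub6()
  e_dense <- sort(eigen(as.matrix(h6$H), symmetric = TRUE,
                        only.values = TRUE)$values)
  dv <- davidson(h6$H, n_roots = 2, tol = 1e-8)
  expect_equal(dv$values, e_dense[1:2], tolerance = 1e-8)
  expect_true(all(diff(dv$values) >= 0))
})

test_that("exact RDMs satisfy all trace identities and pin the convention", {
  r4 <- rand44()
  rd <- r4$rdms
  expect_lt(max(rdm_trace_deviations(rd)), 1e-10)
  # single closed-shell determinant: Gamma1 = diag(2 on occupied)
  d2 <- enumerate_cas(2, 1, 1)
  vec <- numeric(4)
  vec[det_index(d2, 1L, 1L)] <- 1
  g1 <- exact_rdms(vec, d2, 1)$gamma1
  expect_equal(g1, diag(c(2, 0)), tolerance = 1e-14)
  # the dense-operator route equals the literal spin-orbital contraction
  o2 <- qcpt2:::spinorb_erdm(r4$C, r4$C, r4$ds, 2)
  o3 <- qcpt2:::spinorb_erdm(r4$C, r4$C, r4$ds, 3)
  expect_lt(max(abs(rd$gamma2 - o2)), 1e-12)
  expect_lt(max(abs(rd$gamma3 - o3)), 1e-12)
  # rank > 3 refused
  expect_error(exact_rdms(r4$C, r4$ds, 4), "refused")
})

test_that("the 3RDM matrixization of a pure state is PSD", {
  r4 <- rand44()
  M <- gamma3_matrixization(r4$rdms$gamma3)
  expect_lt(max(abs(M - t(M))), 1e-12)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("|F> construction obeys the number-operator and contraction identities", {
  r4 <- rand44()
  C <- r4$C
  # f = identity: |F> = N_act |psi>
  expect_equal(build_f_state(C, r4$ds, diag(4)), 4 * C, tolerance = 1e-12)
  # f = 0: zero vector
  expect_equal(build_f_state(C, r4$ds, matrix(0, 4, 4)), numeric(r4$ds$n_det))
  # <psi|F> = sum f Gamma1
  set.seed(19)
  f <- matrix(stats::rnorm(16), 4); f <- (f + t(f)) / 2
  Fv <- build_f_state(C, r4$ds, f)
  expect_equal(sum(C * Fv), sum(f * r4$rdms$gamma1), tolerance = 1e-12)
})

test_that("transition 3RDM is bilinear and reduces to the diagonal case", {
  r4 <- rand44()
  set.seed(23)
  u <- stats::rnorm(r4$ds$n_det); u <- u / sqrt(sum(u^2))
  expect_equal(transition_3rdm(r4$C, r4$C, r4$ds), r4$rdms$gamma3,
               tolerance = 1e-12)
  t1 <- transition_3rdm(r4$C, u, r4$ds)
  t2 <- transition_3rdm(r4$C, 2 * u + 0.3 * r4$C, r4$ds)
  expect_equal(t2, 2 * t1 + 0.3 * r4$rdms$gamma3, tolerance = 1e-11)
  # and against the literal spin-orbital oracle for distinct bra/ket
  o3 <- qcpt2:::spinorb_erdm(r4$C, u, r4$ds, 3)
  expect_lt(max(abs(t1 - o3)), 1e-12)
})

test_that("Fock-contracted 4RDM: operator identities and brute-force equality", {
  r4 <- rand44()
  C <- r4$C
  # f = 0 gives the zero tensor
  expect_equal(max(abs(f_contracted_4rdm(C, r4$ds, matrix(0, 4, 4)))), 0)
  # f = identity: sum_v Gamma4[..., v, v] = (N - 3) Gamma3
  Aid <- f_contracted_4rdm(C, r4$ds, diag(4))
  expect_equal(Aid, (4 - 3) * r4$rdms$gamma3, tolerance = 1e-11)
  # transition-3RDM pathway equals the literal contraction
  set.seed(29)
  f <- matrix(stats::rnorm(16), 4); f <- (f + t(f)) / 2
  A <- f_contracted_4rdm(C, r4$ds, f, gamma3 = r4$rdms$gamma3)
  B <- brute_force_f4rdm(C, r4$ds, f)
  expect_lt(max(abs(A - B)), 1e-10)
  # too few electrons: the rank-4 normal-ordered part of a 3-electron state
  d3 <- enumerate_cas(4, 2, 1)
  gs3 <- davidson(build_hamiltonian(d3, r4$ints))
  C3 <- gs3$vectors[, 1]
  expect_lt(max(abs(brute_force_f4rdm(C3, d3, f))), 1e-10)
  expect_error(brute_force_f4rdm(C, enumerate_cas(6, 1, 1), f), "limited")
})
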