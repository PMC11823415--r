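test_that("FCIDUMP parsing maps fields and resolves symmetry permutations", {
  path <- withr::local_tempfile(fileext = ".fcidump")
  writeLines(c("&FCI NORB=2,NELEC=2,MS2=0,", "  ORBSYM=1,1,", "  ISYM=1,",
               " &END",
               " 0.5 1 1 1 1", " -1.0 1 1 0 0", " 0.1 0 0 0 0"), path)
  fd <- read_fcidump(path)
  expect_equal(fd$ints$g[1, 1, 1, 1], 0.5)
  expect_equal(fd$ints$h[1, 1], -1.0)
  expect_equal(fd$ints$e_core, 0.1)
  expect_equal(fd$n_elec, 2L)
  # stored value appears under every 8-fold permutation
  ints <- make_random_twobody(3, seed = 4)
  expect_equal(max(abs(ints$g - aperm(ints$g, c(3, 4, 1, 2)))), 0)
})

test_that("FCIDUMP write/read round trip is value-exact", {
  ints <- make_random_twobody(4, seed = 3)
  sp <- orbital_space(active = 1:4, n_elec = 4)
  path <- withr::local_tempfile(fileext = ".fcidump")
  write_fcidump(ints, sp, path)
  rr <- read_fcidump(path)
  expect_lt(max(abs(rr$ints$h - ints$h)), 1e-14)
  expect_lt(max(abs(rr$ints$g - ints$g)), 1e-14)
  expect_lt(abs(rr$ints$e_core - ints$e_core), 1e-14)
  # malformed inputs fail loudly
  bad <- withr::local_tempfile()
  writeLines(c("&FCI NORB=2,NELEC=2,", " &END", " 0.5 1 1 3 1"), bad)
  expect_error(read_fcidump(bad), "exceeds NORB")
  writeLines("no header here", bad)
  expect_error(read_fcidump(bad), "header")
})

test_that("Hubbard fixtures reproduce closed-form and dense energies", {
  h2 <- hub2()
  expect_equal(min(eigen(as.matrix(h2$H), symmetric = TRUE)$values),
               h2$e0, tolerance = 1e-12)
  # non-interacting limit: sum of lowest occupied one-electron eigenvalues
  i0 <- make_hubbard(4, 1, 0)
  d0 <- enumerate_cas(4, 2, 2)
  e_orb <- sort(eigen(i0$h, symmetric = TRUE)$values)
  expect_equal(davidson(build_hamiltonian(d0, i0))$values[1],
               2 * sum(e_orb[1:2]), tolerance = 1e-10)
  # periodic L=6 half filling: Davidson equals dense diagonalization
  h6 <- hub6()
  e_dense <- min(eigen(as.matrix(h6$H), symmetric = TRUE,
                       only.values = TRUE)$values)
  expect_equal(h6$e0, e_dense, tolerance = 1e-10)
  expect_equal(h6$ds$n_det, 400L)
})

test_that("random two-body fixture is reproducible, symmetric, hermitian", {
  a <- make_random_twobody(4, seed = 11)
  b <- make_random_twobody(4, seed = 11)
  expect_identical(a$g, b$g)
  expect_equal(max(abs(a$g - aperm(a$g, c(2, 1, 3, 4)))), 0)
  ds <- enumerate_cas(4, 2, 2)
  H <- as.matrix(build_hamiltonian(ds, a))
  expect_lt(max(abs(H - t(H))), 1e-12)
})

test_that("H2/STO-3G fixture: Davidson matches the generator's own FCI", {
  h2 <- make_h2_sto3g()
  gs <- casci_ground_state(h2$ints, 1, 1, tol = 1e-11)
  expect_equal(gs$energies[1], h2$e_fci, tolerance = 1e-9)
  expect_lt(h2$e_fci, h2$e_hf)   # correlation lowers the energy
})

test_that("generalized Fock reduces to h for g = 0 and is symmetric", {
  i0 <- make_hubbard(4, 1, 0)
  sp <- orbital_space(inactive = 1:2, active = integer(0), virtual = 3:4,
                      n_elec = 4)
  f <- build_generalized_fock(i0, matrix(0, 0, 0), sp)
  expect_equal(f$f, i0$h, tolerance = 1e-13)
  # closed-shell case equals an independently coded restricted Fock matrix
  ints <- make_random_twobody(4, seed = 5)
  fr <- build_generalized_fock(ints, matrix(0, 0, 0), sp)$f
  frhf <- ints$h
  for (p in 1:4) for (q in 1:4) for (i in 1:2)
    frhf[p, q] <- frhf[p, q] + 2 * ints$g[p, q, i, i] - ints$g[p, i, i, q]
  expect_equal(fr, frhf, tolerance = 1e-12)
  # gamma1 trace violation is rejected
  spa <- orbital_space(inactive = 1L, active = 2:3, virtual = 4L, n_elec = 4)
  expect_error(build_generalized_fock(ints, diag(c(2, 2)), spa), "trace")
})

test_that("pseudocanonicalization block-diagonalizes and preserves physics", {
  ints <- make_random_twobody(6, seed = 13, scale = 0.1)
  sp <- orbital_space(inactive = 1:2, active = 3:4, virtual = 5:6, n_elec = 6)
  ha <- active_hamiltonian(ints, sp)
  gs <- casci_ground_state(ha, 1, 1, tol = 1e-11)
  g1 <- exact_rdms(gs$vectors[, 1], gs$dspace, 1)$gamma1
  fock <- build_generalized_fock(ints, g1, sp)
  pc <- pseudocanonicalize(ints, fock, sp)
  expect_lt(max(abs(crossprod(pc$rotation) - diag(6))), 1e-12)
  for (blk in list(1:2, 3:4, 5:6)) {
    fb <- pc$fock$f[blk, blk]
    expect_lt(max(abs(fb - diag(diag(fb)))), 1e-10)
    expect_true(all(diff(diag(fb)) >= -1e-12))   # ascending within block
  }
  # total CASCI energy invariant under the rotation
  ha2 <- active_hamiltonian(pc$ints, sp)
  gs2 <- casci_ground_state(ha2, 1, 1, tol = 1e-11)
  expect_equal(gs2$energies[1], gs$energies[1], tolerance = 1e-10)
  # already-pseudocanonical input: rotation is the identity up to signs
  pc2 <- pseudocanonicalize(pc$ints, pc$fock, sp)
  expect_lt(max(abs(abs(pc2$rotation) - diag(6))), 1e-8)
})

test_that("active_hamiltonian folds the inactive shell consistently", {
  ints <- make_random_twobody(5, seed = 21)
  sp <- orbital_space(inactive = 1L, active = 2:4, virtual = 5L, n_elec = 6)
  ha <- active_hamiltonian(ints, sp)
  gs <- casci_ground_state(ha, 2, 2, tol = 1e-11)
  # the same state expanded into the full space has the same energy
  dfull <- enumerate_cas(5, 3, 3)
  psi <- expand_cas_vector(gs$vectors[, 1], gs$dspace, sp, dfull)
  Hf <- build_hamiltonian(dfull, ints)
  expect_equal(sum(psi * as.numeric(Hf %*% psi)), gs$energies[1],
               tolerance = 1e-10)
})
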