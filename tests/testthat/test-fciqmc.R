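test_that("blocking analysis: constant, iid and autocorrelated series", {
  expect_equal(blocking_error(rep(3.2, 64))$sigma, 0)
  set.seed(5)
  n <- 2^14
  x <- stats::rnorm(n)
  bl <- blocking_error(x)
  expect_lt(abs(bl$sigma - 1 / sqrt(n)) / (1 / sqrt(n)), 0.2)
  # AR(1) with coefficient phi: sigma_mean = sd/sqrt(n) * sqrt((1+phi)/(1-phi))
  phi <- 0.8
  y <- numeric(n)
  innov <- stats::rnorm(n)
  for (k in 2:n) y[k] <- phi * y[k - 1] + innov[k]
  bl2 <- blocking_error(y)
  target <- stats::sd(y) / sqrt(n) * sqrt((1 + phi) / (1 - phi))
  expect_lt(abs(bl2$sigma - target) / target, 0.25)
  expect_error(blocking_error(1:8), "short")
})

test_that("diagonal Hamiltonian: population stays put, projection exact", {
  # t = 0 Hubbard has no off-diagonal elements at all
  i0 <- make_hubbard(4, 0, 4)
  d0 <- enumerate_cas(4, 2, 2)
  p <- qmc_params(tau = 0.05, n_target = 500, n_iters = 600, seed = 2,
                  equilibration = 50)
  run <- run_fciqmc(i0, d0, p)
  occ <- which(run$C[[1]] != 0)
  expect_equal(occ, run$ref)
  pe <- projected_energy(run, burn_in = 200)
  expect_equal(pe$energy, run$e_ref_det, tolerance = 1e-12)
  expect_equal(pe$sigma, 0, tolerance = 1e-12)
})

test_that("trajectories are bit-reproducible from the seed and differ across seeds", {
  h2 <- hub2()
  p <- qmc_params(tau = 0.02, n_target = 300, n_iters = 400, seed = 7)
  r1 <- run_fciqmc(h2$ints, h2$ds, p)
  r2 <- run_fciqmc(h2$ints, h2$ds, p)
  expect_identical(r1$trajectory[[1]], r2$trajectory[[1]])
  p$seed <- 8
  r3 <- run_fciqmc(h2$ints, h2$ds, p)
  expect_false(isTRUE(all.equal(r1$trajectory[[1]]$n_w, r3$trajectory[[1]]$n_w)))
  # two replicas have different instantaneous populations
  p2 <- qmc_params(tau = 0.02, n_target = 300, n_iters = 400, seed = 7,
                   n_replicas = 2)
  r4 <- run_fciqmc(h2$ints, h2$ds, p2)
  expect_false(isTRUE(all.equal(r4$trajectory[[1]]$n_w, r4$trajectory[[2]]$n_w)))
})

test_that("Hubbard dimer energies agree with the closed form within 3 sigma", {
  h2 <- hub2()
  p <- qmc_params(tau = 0.02, n_target = 3000, n_iters = 6000, seed = 3)
  run <- run_fciqmc(h2$ints, h2$ds, p)
  pe <- projected_energy(run)
  se <- shift_energy(run)
  expect_lt(abs(pe$energy - h2$e0), 3 * max(pe$sigma, 1e-6))
  expect_lt(abs(se$energy - h2$e0), 3 * max(se$sigma, 1e-6))
})

test_that("full semistochastic space reduces to deterministic projection", {
  h2 <- hub2()
  p <- qmc_params(tau = 0.05, n_target = 2000, n_iters = 4000, seed = 9,
                  semistoch_size = 4, min_spawn = 0)
  run <- run_fciqmc(h2$ints, h2$ds, p)
  # all determinants deterministic: the late-time normalized population is
  # the exact ground state to solver accuracy
  v <- run$C[[1]] / sqrt(sum(run$C[[1]]^2))
  dv <- davidson(run$H)$vectors[, 1]
  expect_gt(abs(sum(v * dv)), 1 - 1e-6)
  expect_equal(length(run$D_idx), 4L)
  # the selected set always contains the reference determinant
  expect_true(run$ref %in% run$D_idx)
})

test_that("semistochastic selection is by population with deterministic ties", {
  d4 <- enumerate_cas(4, 2, 2)
  C <- numeric(d4$n_det)
  C[c(3, 10, 17)] <- c(5, -7, 5)
  sel <- semistochastic_select(C, d4, 2)
  expect_equal(sel, sort(c(10, 3)))  # tie 3 vs 17 broken by det order
  expect_equal(semistochastic_select(C, d4, 10), sort(c(3, 10, 17)))
})

test_that("estimator guards catch degenerate windows", {
  h2 <- hub2()
  p <- qmc_params(tau = 0.02, n_target = 300, n_iters = 300, seed = 7)
  run <- run_fciqmc(h2$ints, h2$ds, p)
  expect_error(projected_energy(run, burn_in = 300), "no iterations")
})
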