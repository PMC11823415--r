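# A short two-replica Hubbard L=4 dynamic shared by the estimator tests.
est_run <- function() fx_get("est_run", function() {
  i4 <- make_hubbard(4, 1, 4)
  d4 <- enumerate_cas(4, 2, 2)
  p <- qmc_params(tau = 0.05, n_target = 4000, n_iters = 2500, seed = 11,
                  n_replicas = 2, semistoch_size = 8, histogram_threshold = 1,
                  sample_period = 20)
  list(ints = i4, ds = d4, run = run_fciqmc(i4, d4, p),
       exact = exact_rdms(davidson(build_hamiltonian(d4, i4))$vectors[, 1],
                          d4, 3))
})

test_that("histogram selection, accumulation and truncation behave as specified", {
  er <- est_run()
  hv <- histogram_vector(er$run)
  # inclusion iteration never precedes the window, cycles bounded by length
  wlen <- hv$window[2] - hv$window[1] + 1
  expect_true(all(is.na(hv$incl_iter) | hv$incl_iter >= hv$window[1]))
  expect_true(all(hv$cycles <= wlen))
  tn0 <- truncate_and_normalize(hv, 0)
  expect_equal(sum(tn0$ci^2), 1, tolerance = 1e-12)
  expect_equal(tn0$l2 * tn0$ci[which.max(abs(tn0$ci))],
               hv$mean[which.max(abs(tn0$ci))], tolerance = 1e-10)
  # n_retained is monotone non-increasing in t
  ts <- c(0, 0.5, 1, 2, 4, 8)
  nret <- vapply(ts, function(t) truncate_and_normalize(hv, t)$n_retained, 0L)
  expect_true(all(diff(nret) <= 0))
  expect_error(truncate_and_normalize(hv, Inf), "every determinant")
})

test_that("deterministic diagonal dynamics: averaged coefficient is the fixed point", {
  i0 <- make_hubbard(4, 0, 4)
  d0 <- enumerate_cas(4, 2, 2)
  p <- qmc_params(tau = 0.05, n_target = 50, n_iters = 800, seed = 2,
                  equilibration = 50, histogram_threshold = 1)
  run <- run_fciqmc(i0, d0, p)
  hv <- histogram_vector(run)
  tn <- truncate_and_normalize(hv, 0)
  expect_equal(tn$n_retained, 1L)
  expect_equal(abs(tn$ci[run$ref]), 1)
})

test_that("excitation-driven sparse builder equals the dense operator route", {
  er <- est_run()
  hv <- histogram_vector(er$run)
  tn <- truncate_and_normalize(hv, 2)   # genuinely truncated vector
  a <- rdms_from_vector(tn$ci, er$ds, 3, method = "excitation")
  b <- rdms_from_vector(tn$ci, er$ds, 3, method = "operator")
  expect_lt(max(abs(a$gamma1 - b$gamma1)), 1e-12)
  expect_lt(max(abs(a$gamma2 - b$gamma2)), 1e-12)
  expect_lt(max(abs(a$gamma3 - b$gamma3)), 1e-12)
  # partial-trace identities hold exactly for any truncated pure state
  expect_lt(max(rdm_trace_deviations(a)), 1e-10)
  # and the full untruncated exact vector reproduces exact_rdms
  dvec <- davidson(build_hamiltonian(er$ds, er$ints))$vectors[, 1]
  c_ <- rdms_from_vector(dvec, er$ds, 3, method = "excitation")
  expect_lt(max(abs(c_$gamma3 - er$exact$gamma3)), 1e-12)
})

test_that("|F> compression: exact at zero, monotone error growth", {
  er <- est_run()
  hv <- histogram_vector(er$run)
  tn <- truncate_and_normalize(hv, 0)
  set.seed(31)
  f <- matrix(stats::rnorm(16), 4); f <- (f + t(f)) / 2
  a0 <- f4rdm_from_histogram(tn$ci, er$ds, f, compression = 0)
  ref <- f_contracted_4rdm(tn$ci, er$ds, f)
  expect_lt(max(abs(a0 - ref)), 1e-10)
  errs <- vapply(c(0, 1e-4, 1e-2, 1e-1), function(cmp)
    max(abs(f4rdm_from_histogram(tn$ci, er$ds, f, compression = cmp) - ref)),
    0)
  expect_true(all(diff(errs) >= -1e-12))
})

test_that("replica estimator: trace normalization, refusal rules, accuracy", {
  er <- est_run()
  rd <- replica_rdms(er$run, 3)
  expect_equal(sum(diag(rd$gamma1)), 4, tolerance = 1e-12)
  expect_lt(max(abs(rd$gamma1 - er$exact$gamma1)), 0.05)
  expect_gt(rd$hermiticity_error, 0)
  # single-replica runs are refused by the replica estimator
  i4 <- er$ints
  p1 <- qmc_params(tau = 0.05, n_target = 1000, n_iters = 800, seed = 3,
                   sample_period = 20)
  r1 <- run_fciqmc(i4, er$ds, p1)
  expect_error(replica_rdms(r1), "two replicas")
})

test_that("single-population estimator shows the positive diagonal bias", {
  er <- est_run()
  rb <- biased_single_replica_rdms(er$run, 1, normalize = FALSE)
  rr <- replica_rdms(er$run, 1, normalize = FALSE)
  expect_gt(sum(diag(rb$gamma1)) - sum(diag(rr$gamma1)), 0)
})

test_that("hybrid estimator limits: full subspace and no subspace", {
  i4 <- make_hubbard(4, 1, 4)
  d4 <- enumerate_cas(4, 2, 2)
  # no deterministic space: hybrid coincides with the replica estimator
  p0 <- qmc_params(tau = 0.05, n_target = 2000, n_iters = 1500, seed = 5,
                   n_replicas = 2, histogram_threshold = 1, sample_period = 25)
  r0 <- run_fciqmc(i4, d4, p0)
  expect_equal(hybrid_rdms(r0, 2)$gamma2, replica_rdms(r0, 2)$gamma2,
               tolerance = 1e-12)
  # full-space subspace: hybrid equals the product of the two snapshot means
  pf <- qmc_params(tau = 0.05, n_target = 2000, n_iters = 1500, seed = 5,
                   n_replicas = 2, semistoch_size = d4$n_det,
                   histogram_threshold = 1, sample_period = 25)
  rf <- run_fciqmc(i4, d4, pf)
  u1 <- qcpt2:::unitize(rf$samples$C[[1]])
  u2 <- qcpt2:::unitize(rf$samples$C[[2]])
  m1 <- Reduce(`+`, u1) / length(u1)
  m2 <- Reduce(`+`, u2) / length(u2)
  ref <- qcpt2:::finalize_sampled_rdms(
    list(g1 = transition_rdms(m1, m2, d4, 2)$gamma1,
         g2 = transition_rdms(m1, m2, d4, 2)$gamma2, g3 = NULL),
    d4, "hybrid", TRUE)
  expect_equal(hybrid_rdms(rf, 2)$gamma2, ref$gamma2, tolerance = 1e-10)
})

test_that("positivity report: exact states clean, constructed violations counted", {
  er <- est_run()
  pr <- positivity_report(er$exact)
  expect_equal(pr$n_negative, 0L)
  expect_equal(pr$negative_mass, 0)
  # perturb one eigenvalue by -eps: exactly one negative of that size
  eps <- 1e-4
  M <- gamma3_matrixization(er$exact$gamma3)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  M2 <- M - (eg$values[length(eg$values)] + eps) *
    tcrossprod(eg$vectors[, ncol(eg$vectors)])
  n <- 4
  G2 <- aperm(array(M2, rep(n, 6)), c(1, 4, 2, 5, 3, 6))
  rd2 <- rdm_set(er$exact$gamma1, er$exact$gamma2, G2,
                 provenance = "replica", n_act_elec = 4)
  pr2 <- positivity_report(rd2)
  expect_equal(pr2$n_negative, 1L)
  expect_equal(pr2$negative_mass, eps, tolerance = 1e-6)
})

test_that("PSD projection is optimal in Frobenius norm", {
  M <- diag(c(0.5, -0.1))
  P <- project_to_psd(M)
  expect_equal(P, diag(c(0.5, 0)))
  expect_equal(project_to_psd(P), P)       # idempotent
  set.seed(12)
  A <- matrix(stats::rnorm(16), 4); S <- (A + t(A)) / 2
  P2 <- project_to_psd(S)
  expect_gt(min(eigen(P2, symmetric = TRUE)$values), -1e-12)
  d0 <- sqrt(sum((P2 - S)^2))
  neg <- eigen(S, symmetric = TRUE)$values
  expect_equal(d0, sqrt(sum(pmin(neg, 0)^2)), tolerance = 1e-10)
  # no random PSD candidate comes closer
  for (k in 1:200) {
    B <- matrix(stats::rnorm(16), 4)
    cand <- crossprod(B) / 4
    expect_gte(sqrt(sum((cand - S)^2)), d0 - 1e-10)
  }
  expect_error(project_to_psd(matrix(c(1, 2, 0, 1), 2)), "symmetr")
})
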