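# FCIQMC: stochastic integration of the imaginary-time Schroedinger equation
# in a CAS determinant space. Walker populations are real-valued dense
# vectors over the enumerated space (desk scale); spawning is vectorized
# over all walkers, with uniform excitation generation among the nonzero
# Hamiltonian connections of each determinant, a minimum spawn magnitude
# with stochastic rounding, exact diagonal death/cloning, annihilation by
# signed aggregation, population control through the standard shift update,
# and an optional semistochastic space in which projection is deterministic.

#' FCIQMC run parameters
#'
#' @param tau imaginary time step (1/Hartree).
#' @param n_target target walker number for population control.
#' @param n_iters total iterations.
#' @param shift_damping damping zeta of the shift update (default 0.5; the
#'   per-update correction is roughly zeta times the energy offset, and the
#'   strongly projecting desk-scale Hamiltonians here need tight control).
#' @param shift_update_period iterations between shift updates (default 5).
#' @param n_replicas 1 or 2 statistically independent walker populations.
#' @param semistoch_size deterministic-subspace size (0 = pure stochastic).
#' @param reporting_period iterations between reports/hooks (default 10).
#' @param seed PRNG seed; each (replica, iteration) re-keys the generator so
#'   trajectories are bit-reproducible and replicas independent.
#' @param initiator_threshold walker threshold of the initiator rule, or
#'   `NA` (default) for initiator-free dynamics.
#' @param init_walkers walkers placed on the reference at iteration 0.
#' @param min_spawn minimum spawn magnitude; smaller spawns are
#'   stochastically rounded to 0 or `min_spawn`.
#' @param equilibration extra iterations after the shift turns variable
#'   before histogram/sampling windows open (default 500).
#' @param histogram_threshold selection threshold (walkers) of the greedy
#'   histogrammable-set rule, or `NA` to disable histogramming.
#' @param sample_period iterations between stored replica snapshots
#'   (0 disables snapshot storage).
#' @return list of class `qmc_params`.
#' @export
qmc_params <- function(tau = 0.02, n_target = 10000, n_iters = 10000,
                       shift_damping = 0.5, shift_update_period = 5,
                       n_replicas = 1, semistoch_size = 0,
                       reporting_period = 10, seed = 1,
                       initiator_threshold = NA, init_walkers = 100,
                       min_spawn = 1e-3, equilibration = 500,
                       histogram_threshold = NA, sample_period = 0) {
  stopifnot(tau > 0, n_replicas %in% c(1, 2), reporting_period >= 1)
  structure(as.list(environment()), class = "qmc_params")
}

qmc_seed <- function(seed, replica, iter) {
  as.integer((as.numeric(seed) * 1000003 + replica * 7919 +
                as.numeric(iter) * 104729) %% 2147483629)
}

#' Run FCIQMC on a CAS Hamiltonian
#'
#' Propagates one or two replica walker populations with the first-order
#' projector `1 - tau (H - E_ref - S)`. Per iteration: (i) each determinant
#' makes `max(1, round(|C_i|))` spawn attempts onto uniformly drawn nonzero
#' connections with amplitude `-tau H_ij C_i / p_gen` per unit attempt;
#' (ii) exact diagonal death/cloning; (iii) annihilation by signed merging;
#' (iv) shift update `S <- S - zeta/(A tau) log(N_w/N_w')` every `A`
#' iterations once the population first reaches `n_target`. The
#' deterministic subspace (most populated determinants, selected when the
#' shift turns variable) is projected exactly; stochastic spawns inside it
#' are discarded. Optional accumulators: imaginary-time histogramming of
#' coefficients (the greedy selection rule plus per-iteration accumulation)
#' and periodic replica snapshots for RDM sampling.
#'
#' @param ints an [integral_set] over the active orbitals.
#' @param dspace a `det_space` (e.g. from [enumerate_cas]).
#' @param params a [qmc_params].
#' @param hooks optional list of functions `f(run_state)` called every
#'   reporting period.
#' @return object of class `qmc_run`: trajectory data frame(s), final
#'   populations, histogram accumulators, snapshots, and problem handles.
#' @export
run_fciqmc <- function(ints, dspace, params, hooks = list()) {
  nd <- dspace$n_det
  H <- build_hamiltonian(dspace, ints)
  hd <- Matrix::diag(H)
  ref <- which.min(hd)
  e_ref <- hd[ref]
  # CSR-like connection table (off-diagonal nonzeros, column-wise)
  Ht <- as(Matrix::drop0(H - Matrix::Diagonal(nd, hd)), "CsparseMatrix")
  conn_ptr <- Ht@p               # 0-based starts per column
  conn_j <- Ht@i + 1L
  conn_h <- Ht@x
  conn_n <- diff(conn_ptr)
  if (max(abs(params$tau * (hd - e_ref))) > 1)
    warning("tau too large: diagonal death factor exceeds 1")
  Hrow_ref <- as.numeric(H[ref, ])

  nrep <- params$n_replicas
  C <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    C[[r]] <- numeric(nd)
    C[[r]][ref] <- params$init_walkers
  }
  S <- rep(0, nrep)
  vary <- rep(FALSE, nrep)
  nw_prev <- rep(NA_real_, nrep)
  vary_iter <- rep(NA_integer_, nrep)

  n_it <- params$n_iters
  # flat matrices (in-place writes; nested lists would copy on assignment)
  tr_shift <- matrix(0, n_it, nrep); tr_nw <- matrix(0, n_it, nrep)
  tr_l2 <- matrix(0, n_it, nrep); tr_num <- matrix(0, n_it, nrep)
  tr_den <- matrix(0, n_it, nrep)

  # semistochastic bookkeeping
  ss_size <- params$semistoch_size
  in_D <- rep(FALSE, nd)
  D_idx <- integer(0)
  H_DD <- NULL
  ss_armed <- ss_size > 0

  # histogram accumulators: inclusion driven by replica 1, coefficient sums
  # kept per replica (the hybrid estimator multiplies the two independent
  # subspace averages, so both replicas must be histogrammed)
  hist_on <- !is.na(params$histogram_threshold)
  h_sum <- matrix(0, nd, nrep)
  h_incl <- rep(NA_integer_, nd)
  h_cycles <- matrix(0, nd, nrep)
  h_start <- NA_integer_
  period_min <- rep(Inf, nd)

  # snapshots
  samp_on <- params$sample_period > 0 && nrep >= 1
  samp_iters <- integer(0)
  samp <- lapply(seq_len(nrep), function(r) list())

  window_open <- function(it, r = 1L) {
    !is.na(vary_iter[r]) && it > vary_iter[r] + params$equilibration
  }

  for (it in seq_len(n_it)) {
    for (r in seq_len(nrep)) {
      set.seed(qmc_seed(params$seed, r, it))
      Cr <- C[[r]]
      occ <- which(Cr != 0)
      w <- Cr[occ]
      natt <- pmax(1L, as.integer(round(abs(w))))
      src <- rep.int(occ, natt)
      amp <- rep.int(w / natt, natt)
      nc <- conn_n[src]
      ok <- nc > 0L
      spawned <- numeric(nd)
      if (any(ok)) {
        src <- src[ok]; amp <- amp[ok]; nc <- nc[ok]
        pick <- conn_ptr[src] + as.integer(floor(stats::runif(length(src)) * nc)) + 1L
        dst <- conn_j[pick]
        sw <- -params$tau * conn_h[pick] * amp * nc
        if (ss_size > 0 && length(D_idx)) {
          drop_ <- in_D[src] & in_D[dst]
          if (any(drop_)) sw[drop_] <- 0
        }
        if (!is.na(params$initiator_threshold)) {
          kill <- Cr[dst] == 0 & abs(Cr[src]) < params$initiator_threshold &
            !in_D[src]
          sw[kill] <- 0
        }
        small <- abs(sw) < params$min_spawn & sw != 0
        if (any(small)) {
          u <- stats::runif(sum(small))
          sv <- sw[small]
          sw[small] <- ifelse(u < abs(sv) / params$min_spawn,
                              sign(sv) * params$min_spawn, 0)
        }
        nzs <- sw != 0
        if (any(nzs)) {
          agg <- rowsum(sw[nzs], dst[nzs])
          spawned[as.integer(rownames(agg))] <- agg
        }
      }
      if (ss_size > 0 && length(D_idx)) {
        spawned[D_idx] <- spawned[D_idx] -
          params$tau * as.numeric(H_DD %*% Cr[D_idx])
      }
      Cr <- Cr * (1 - params$tau * (hd - e_ref - S[r])) + spawned
      nw <- sum(abs(Cr))
      if (!is.finite(nw) || nw > 100 * params$n_target)
        stop("population explosion at iteration ", it,
             " (N_w = ", format(nw), "); reduce tau or raise n_target")
      if (!vary[r] && nw >= params$n_target) {
        vary[r] <- TRUE
        vary_iter[r] <- it
        nw_prev[r] <- nw
        # growth-matched initialization: without it the damped update lags
        # the exponential growth and the population overshoots uncontrollably
        S[r] <- sum(Hrow_ref * Cr) / Cr[ref] - e_ref
        # select the semistochastic space from the equilibrated population
        if (ss_armed && r == 1L) {
          sz <- min(ss_size, sum(Cr != 0))
          ord <- order(-abs(Cr), dspace$key)
          D_idx <- sort(ord[seq_len(sz)])
          in_D[] <- FALSE; in_D[D_idx] <- TRUE
          H_DD <- H[D_idx, D_idx, drop = FALSE]
          Matrix::diag(H_DD) <- 0
          ss_armed <- FALSE
        }
      }
      if (vary[r] && it %% params$shift_update_period == 0) {
        S[r] <- S[r] - params$shift_damping /
          (params$shift_update_period * params$tau) * log(nw / nw_prev[r])
        nw_prev[r] <- nw
      }
      tr_shift[it, r] <- S[r]
      tr_nw[it, r] <- nw
      tr_l2[it, r] <- sqrt(sum(Cr^2))
      tr_num[it, r] <- sum(Hrow_ref * Cr)
      tr_den[it, r] <- Cr[ref]
      C[[r]] <- Cr
    }
    # histogram accumulation (replica 1, per iteration, zeros included)
    if (hist_on && window_open(it)) {
      if (is.na(h_start)) {
        h_start <- it
        if (length(D_idx)) h_incl[D_idx] <- it   # subspace from window start
      }
      inc <- !is.na(h_incl)
      if (any(inc)) for (r in seq_len(nrep)) {
        h_sum[inc, r] <- h_sum[inc, r] + C[[r]][inc]
        h_cycles[inc, r] <- h_cycles[inc, r] + (C[[r]][inc] != 0)
      }
      period_min <- pmin(period_min, abs(C[[1L]]))
      if (it %% params$reporting_period == 0) {
        newly <- is.na(h_incl) & period_min >= params$histogram_threshold
        h_incl[newly] <- it + 1L
        period_min[] <- Inf
      }
    }
    if (samp_on && it %% params$sample_period == 0 && window_open(it)) {
      samp_iters <- c(samp_iters, it)
      for (r in seq_len(nrep))
        samp[[r]][[length(samp_iters)]] <- C[[r]]
    }
    if (length(hooks) && it %% params$reporting_period == 0) {
      st <- list(iter = it, C = C, shift = S, vary_iter = vary_iter)
      for (h in hooks) h(st)
    }
  }
  traj_df <- lapply(seq_len(nrep), function(r) {
    data.frame(iteration = seq_len(n_it), shift = tr_shift[, r],
               n_w = tr_nw[, r], l2 = tr_l2[, r],
               num = tr_num[, r], denom = tr_den[, r])
  })
  structure(list(
    trajectory = traj_df, C = C, params = params, dspace = dspace,
    ints = ints, H = H, ref = ref, e_ref_det = e_ref,
    shift_start = vary_iter,
    histogram = if (hist_on) list(sum = h_sum, incl_iter = h_incl,
                                  cycles = h_cycles,
                                  window = c(h_start, n_it),
                                  threshold = params$histogram_threshold)
    else NULL,
    samples = if (samp_on) list(iters = samp_iters, C = samp) else NULL,
    D_idx = D_idx), class = "qmc_run")
}

#' Select the semistochastic determinant set
#'
#' The `size` most populated determinants of a population vector, ties
#' broken by the canonical determinant order; always contains the most
#' populated (reference) determinant. If fewer determinants are occupied,
#' all occupied ones are returned.
#' @param C population vector.
#' @param dspace the `det_space`.
#' @param size requested set size.
#' @return sorted integer indices.
#' @export
semistochastic_select <- function(C, dspace, size) {
  sz <- min(size, sum(C != 0))
  ord <- order(-abs(C), dspace$key)
  sort(ord[seq_len(sz)])
}

#' Blocking error analysis
#'
#' Flyvbjerg-Petersen reblocking: the series is repeatedly pairwise
#' averaged; the standard error of the blocked mean rises until blocks
#' exceed the correlation time. The reported sigma is taken at the first
#' plateau (successive estimates within 3%), falling back to the largest
#' estimate among blockings with at least 16 blocks.
#'
#' @param x numeric series (length >= 16).
#' @return list `sigma`, `sigmas` (per level), `block_sizes`.
#' @export
blocking_error <- function(x) {
  n <- length(x)
  if (n < 16) stop("series too short for blocking analysis")
  sigmas <- c(); sizes <- c()
  b <- 1
  while (length(x) >= 16) {
    m <- length(x)
    sigmas <- c(sigmas, stats::sd(x) / sqrt(m))
    sizes <- c(sizes, b)
    m2 <- floor(m / 2)
    x <- (x[2 * seq_len(m2) - 1] + x[2 * seq_len(m2)]) / 2
    b <- 2 * b
  }
  sigma <- sigmas[length(sigmas)]
  for (k in seq_len(length(sigmas) - 1)) {
    if (sigmas[k + 1] <= 1.03 * sigmas[k]) { sigma <- sigmas[k]; break }
  }
  list(sigma = max(sigma, 0), sigmas = sigmas, block_sizes = sizes)
}

# blocking for a ratio of means <num>/<den> with covariance propagation
blocking_error_ratio <- function(num, den) {
  n <- length(num)
  if (n < 16) stop("series too short for blocking analysis")
  est <- mean(num) / mean(den)
  sig_of <- function(x, y) {
    m <- length(x)
    vx <- stats::var(x) / m; vy <- stats::var(y) / m
    cxy <- stats::cov(x, y) / m
    sqrt(max((vx - 2 * est * cxy + est^2 * vy) / mean(y)^2, 0))
  }
  sigmas <- c()
  while (length(num) >= 16) {
    sigmas <- c(sigmas, sig_of(num, den))
    m2 <- floor(length(num) / 2)
    num <- (num[2 * seq_len(m2) - 1] + num[2 * seq_len(m2)]) / 2
    den <- (den[2 * seq_len(m2) - 1] + den[2 * seq_len(m2)]) / 2
  }
  sigma <- sigmas[length(sigmas)]
  for (k in seq_len(length(sigmas) - 1)) {
    if (sigmas[k + 1] <= 1.03 * sigmas[k]) { sigma <- sigmas[k]; break }
  }
  list(estimate = est, sigma = sigma, sigmas = sigmas)
}

#' Projected-energy estimator
#'
#' `E = <sum_j H_ref,j C_j> / <C_ref>` over the post-burn-in window (an
#' absolute energy, including the diagonal reference term), with the
#' blocking error of the ratio.
#' @param run a `qmc_run`.
#' @param burn_in iterations to discard (default: shift-variable onset plus
#'   the equilibration window).
#' @param replica which replica.
#' @return list `energy`, `sigma`.
#' @export
projected_energy <- function(run, burn_in = NULL, replica = 1) {
  tr <- run$trajectory[[replica]]
  if (is.null(burn_in)) {
    st <- run$shift_start[replica]
    if (is.na(st)) stop("population never reached the target; no stationary window")
    burn_in <- st + run$params$equilibration
  }
  if (burn_in >= nrow(tr)) stop("burn_in leaves no iterations")
  sel <- (burn_in + 1):nrow(tr)
  if (mean(abs(tr$denom[sel])) < 1e-12)
    stop("reference coefficient averages to zero; projected estimator invalid")
  bl <- blocking_error_ratio(tr$num[sel], tr$denom[sel])
  list(energy = bl$estimate, sigma = bl$sigma)
}

#' Shift-energy estimator
#'
#' Mean shift over the post-burn-in window plus the reference determinant
#' energy, with blocking error.
#' @inheritParams projected_energy
#' @return list `energy`, `sigma`.
#' @export
shift_energy <- function(run, burn_in = NULL, replica = 1) {
  tr <- run$trajectory[[replica]]
  if (is.null(burn_in)) {
    st <- run$shift_start[replica]
    if (is.na(st)) stop("population never reached the target")
    burn_in <- st + run$params$equilibration
  }
  sel <- (burn_in + 1):nrow(tr)
  bl <- blocking_error(tr$shift[sel])
  list(energy = run$e_ref_det + mean(tr$shift[sel]), sigma = bl$sigma)
}
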