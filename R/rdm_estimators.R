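# Three routes from FCIQMC dynamics to active-space RDMs:
#
#  * pure histogramming — average the instantaneous walker weight of every
#    selected determinant over imaginary time (zeros included), truncate at
#    a discard threshold t (walkers), renormalize; the result is a pure
#    state, so all its RDMs satisfy every fermionic positivity condition by
#    construction;
#  * replica sampling — average products C^(1)_i C^(2)_j of two independent
#    walker populations (zero covariance, unbiased, but each finite average
#    is not the RDM of any pure state and can violate positivity);
#  * hybrid — deterministic-subspace contributions from occupancy-cycle-
#    normalized histogram averages, the remainder from replica products.
#
# Plus the excitation-driven sparse RDM builder and positivity diagnostics.

#' Imaginary-time-averaged (histogrammed) wave function
#'
#' Collects the per-determinant accumulation of a [run_fciqmc] run with
#' histogramming enabled: each selected determinant's instantaneous weight
#' is averaged over all iterations since its inclusion (zeros included);
#' deterministic-subspace determinants are averaged from the window start.
#'
#' @param run a `qmc_run` with `histogram_threshold` set.
#' @return object of class `histogram_vector`: `mean` (walker units),
#'   `incl_iter`, `cycles` (occupied-cycle counts), `window`, `threshold`.
#' @export
histogram_vector <- function(run) {
  hs <- run$histogram
  if (is.null(hs)) stop("run was performed without histogramming")
  if (is.na(hs$window[1])) stop("histogram window never opened (population ",
                                "did not equilibrate)")
  denom <- hs$window[2] - hs$incl_iter + 1
  mean_w <- ifelse(is.na(hs$incl_iter), 0, hs$sum[, 1] / denom)
  structure(list(mean = mean_w, incl_iter = hs$incl_iter,
                 cycles = hs$cycles[, 1], window = hs$window,
                 threshold = hs$threshold, sum = hs$sum[, 1],
                 sum_all = hs$sum, cycles_all = hs$cycles,
                 dspace = run$dspace, D_idx = run$D_idx),
            class = "histogram_vector")
}

#' Truncate and normalize a histogrammed vector
#'
#' Discards determinants with average occupation below the threshold `t`
#' (in walkers), reports the L1/L2 norms of the retained pre-normalization
#' vector, and returns the L2-normalized CI vector — the renormalized
#' projection of the sampled state onto the retained determinants.
#'
#' @param hv a [histogram_vector].
#' @param t discard threshold in walker units (`t = 0` keeps everything).
#' @return list: `ci` (normalized, dense over the space), `n_retained`,
#'   `l1`, `l2`, `kept` (indices).
#' @export
truncate_and_normalize <- function(hv, t = 0) {
  keep <- abs(hv$mean) >= t & hv$mean != 0
  if (!any(keep)) stop("discard threshold removed every determinant")
  v <- ifelse(keep, hv$mean, 0)
  l1 <- sum(abs(v)); l2 <- sqrt(sum(v^2))
  list(ci = v / l2, n_retained = sum(keep), l1 = l1, l2 = l2,
       kept = which(keep))
}

#' RDMs of a sparse CI vector by excitation-driven accumulation
#'
#' The sparse-selection RDM algorithm: for every determinant in the stored
#' set, all excitations up to `max_rank` are generated and a contribution is
#' accumulated only when the excited determinant is found in the stored set
#' (hash lookup). Exactly equals [exact_rdms] on the same vector — the two
#' implementations share no code path beyond the determinant layer. The
#' `"operator"` method computes the same tensors by dense operator algebra
#' and is preferred automatically on larger enumerable spaces.
#'
#' @param ci normalized coefficient vector over `dspace`.
#' @param dspace a `det_space`.
#' @param max_rank 1-3.
#' @param method `"auto"`, `"excitation"` or `"operator"`.
#' @param provenance provenance label for the returned [rdm_set].
#' @return an [rdm_set].
#' @export
rdms_from_vector <- function(ci, dspace, max_rank = 3,
                             method = c("auto", "excitation", "operator"),
                             provenance = "histogram") {
  method <- match.arg(method)
  if (abs(sum(ci^2) - 1) > 1e-8) stop("vector not normalized")
  if (method == "auto")
    method <- if (dspace$n_det <= 64) "excitation" else "operator"
  if (method == "operator") {
    tr <- transition_rdms(ci, ci, dspace, max_rank)
    return(rdm_set(tr$gamma1, tr$gamma2, tr$gamma3, provenance = provenance,
                   n_act_elec = dspace$n_alpha + dspace$n_beta))
  }
  g1 <- spinorb_erdm(ci, ci, dspace, 1)
  g2 <- if (max_rank >= 2) spinorb_erdm(ci, ci, dspace, 2) else NULL
  g3 <- if (max_rank >= 3) spinorb_erdm(ci, ci, dspace, 3) else NULL
  rdm_set(g1, g2, g3, provenance = provenance,
          n_act_elec = dspace$n_alpha + dspace$n_beta)
}

#' Fock-contracted 4RDM from a histogrammed vector with |F> compression
#'
#' Builds `|F> = sum f_vw E_vw |psi>`, discards |F> coefficients below
#' `compression` times the largest coefficient (no renormalization — |F> is
#' an operator image, not a state), and evaluates the transition-3RDM
#' pathway. `compression = 0` equals the exact pathway on the same vector.
#'
#' @param ci normalized truncated histogram vector over `dspace`.
#' @param dspace a `det_space`.
#' @param f_active symmetric active Fock block.
#' @param compression relative coefficient threshold (default 1e-8).
#' @return rank-6 array (same convention as [f_contracted_4rdm]).
#' @export
f4rdm_from_histogram <- function(ci, dspace, f_active, compression = 1e-8) {
  Fv <- build_f_state(ci, dspace, f_active)
  if (compression > 0 && any(Fv != 0)) {
    Fv[abs(Fv) < compression * max(abs(Fv))] <- 0
  }
  g3 <- transition_rdms(ci, ci, dspace, 3)$gamma3
  Tt <- transition_3rdm(ci, Fv, dspace)
  n <- dspace$n_orb
  contract_slot <- function(g3, slot) {
    perm <- switch(slot, `1` = c(1, 3, 4, 5, 6, 2), `2` = c(1, 2, 3, 5, 6, 4),
                   `3` = c(1, 2, 3, 4, 5, 6))
    gp <- aperm(g3, perm)
    dim(gp) <- c(n^5, n)
    res <- gp %*% t(f_active)
    dim(res) <- rep(n, 6)
    aperm(res, order(perm))
  }
  Tt - contract_slot(g3, 1) - contract_slot(g3, 2) - contract_slot(g3, 3)
}

# symmetrize a pair tensor: average with the bra/ket-swapped transpose
pair_transpose <- function(G) {
  r <- length(dim(G)) / 2
  aperm(G, as.vector(rbind(2 * seq_len(r), 2 * seq_len(r) - 1)))
}

hermiticity_error_of <- function(G) {
  if (is.null(G)) return(0)
  sqrt(sum((G - pair_transpose(G))^2))
}

# trace-normalize rank-k tensors of an rdm_set to the exact electron-count
# traces N, N(N-1), N(N-1)(N-2)
trace_normalize_rdms <- function(g1, g2, g3, n_elec) {
  n <- nrow(g1)
  tr1 <- sum(diag(g1))
  if (abs(tr1) > 1e-300) g1 <- g1 * (n_elec / tr1)
  if (!is.null(g2)) {
    tr2 <- 0
    for (p in seq_len(n)) for (q in seq_len(n)) tr2 <- tr2 + g2[p, p, q, q]
    tgt <- n_elec * (n_elec - 1)
    if (abs(tr2) > 1e-300) g2 <- g2 * (tgt / tr2)
  }
  if (!is.null(g3)) {
    tr3 <- 0
    for (p in seq_len(n)) for (q in seq_len(n)) for (r in seq_len(n))
      tr3 <- tr3 + g3[p, p, q, q, r, r]
    tgt <- n_elec * (n_elec - 1) * (n_elec - 2)
    if (abs(tr3) > 1e-300) g3 <- g3 * (tgt / tr3)
  }
  list(g1 = g1, g2 = g2, g3 = g3)
}

# normalize each snapshot to unit L2: the estimators are defined up to an
# overall scale (tensors are trace-normalized on readout), and removing the
# slow population-norm drift keeps the subspace and remainder blocks of the
# sampled pair density mutually consistent at desk-scale walker numbers.
unitize <- function(lst) lapply(lst, function(v) {
  nv <- sqrt(sum(v^2))
  if (nv > 0) v / nv else v
})

# core of the replica estimators: average transition tensors over stored
# snapshot pairs (b_list[s], k_list[s]); returns raw per-sample means.
accumulate_pair_rdms <- function(b_list, k_list, dspace, max_rank) {
  ns <- length(b_list)
  g1 <- NULL; g2 <- NULL; g3 <- NULL
  for (s in seq_len(ns)) {
    tr <- transition_rdms(b_list[[s]], k_list[[s]], dspace, max_rank)
    if (s == 1) {
      g1 <- tr$gamma1; g2 <- tr$gamma2; g3 <- tr$gamma3
    } else {
      g1 <- g1 + tr$gamma1
      if (max_rank >= 2) g2 <- g2 + tr$gamma2
      if (max_rank >= 3) g3 <- g3 + tr$gamma3
    }
  }
  list(g1 = g1 / ns, g2 = if (max_rank >= 2) g2 / ns,
       g3 = if (max_rank >= 3) g3 / ns, n_samples = ns)
}

finalize_sampled_rdms <- function(raw, dspace, provenance, normalize) {
  herm <- hermiticity_error_of(raw$g3)
  g1 <- (raw$g1 + t(raw$g1)) / 2
  g2 <- if (!is.null(raw$g2)) (raw$g2 + pair_transpose(raw$g2)) / 2
  g3 <- if (!is.null(raw$g3)) (raw$g3 + pair_transpose(raw$g3)) / 2
  n_elec <- dspace$n_alpha + dspace$n_beta
  if (normalize) {
    tn <- trace_normalize_rdms(g1, g2, g3, n_elec)
    g1 <- tn$g1; g2 <- tn$g2; g3 <- tn$g3
  }
  rdm_set(g1, g2, g3, provenance = provenance, hermiticity_error = herm,
          n_act_elec = n_elec)
}

# replace the deterministic-subspace block of raw pair-product tensors:
# subtract the snapshot-sampled D x D part and add `block` (a D x D matrix
# of pair-density estimates), contracted through its SVD factorization.
swap_subspace_block <- function(raw, run, block, max_rank, b_list, k_list) {
  D <- run$D_idx
  restr <- function(v) { w <- numeric(length(v)); w[D] <- v[D]; w }
  raw_DD <- accumulate_pair_rdms(lapply(b_list, restr),
                                 lapply(k_list, restr),
                                 run$dspace, max_rank)
  sv <- svd(block)
  th <- NULL
  nd <- run$dspace$n_det
  for (k in seq_along(sv$d)) {
    if (sv$d[k] < 1e-12 * sv$d[1]) break
    u <- numeric(nd); v <- numeric(nd)
    u[D] <- sv$u[, k]; v[D] <- sv$v[, k]
    tk <- transition_rdms(u, v, run$dspace, max_rank)
    if (is.null(th)) {
      th <- list(gamma1 = sv$d[k] * tk$gamma1,
                 gamma2 = if (max_rank >= 2) sv$d[k] * tk$gamma2,
                 gamma3 = if (max_rank >= 3) sv$d[k] * tk$gamma3)
    } else {
      th$gamma1 <- th$gamma1 + sv$d[k] * tk$gamma1
      if (max_rank >= 2) th$gamma2 <- th$gamma2 + sv$d[k] * tk$gamma2
      if (max_rank >= 3) th$gamma3 <- th$gamma3 + sv$d[k] * tk$gamma3
    }
  }
  raw$g1 <- raw$g1 - raw_DD$g1 + th$gamma1
  if (max_rank >= 2) raw$g2 <- raw$g2 - raw_DD$g2 + th$gamma2
  if (max_rank >= 3) raw$g3 <- raw$g3 - raw_DD$g3 + th$gamma3
  raw
}

#' Replica-sampled RDMs
#'
#' Unbiased on-the-fly estimator: products of coefficients from two
#' statistically independent walker populations are averaged over the
#' stored sampling snapshots (`C^(1)_i C^(2)_j` has zero covariance between
#' the factors). Snapshots are scaled to unit norm before multiplying; the
#' hermiticity error is recorded before symmetrization, then the tensors
#' are symmetrized and (by default) trace-normalized.
#'
#' @param run a two-replica `qmc_run` with `sample_period > 0`.
#' @param max_rank 1-3.
#' @param normalize trace-normalize (default TRUE); `FALSE` returns the raw
#'   per-sample averages of unit-snapshot products (used by the bias
#'   demonstration).
#' @return an [rdm_set] with provenance `"replica"`.
#' @export
replica_rdms <- function(run, max_rank = 3, normalize = TRUE) {
  if (run$params$n_replicas != 2)
    stop("replica_rdms requires two replicas; the single-population ",
         "estimator is exposed separately as biased_single_replica_rdms")
  if (is.null(run$samples) || length(run$samples$iters) == 0)
    stop("no sampling snapshots stored (set sample_period)")
  raw <- accumulate_pair_rdms(unitize(run$samples$C[[1]]),
                              unitize(run$samples$C[[2]]),
                              run$dspace, max_rank)
  finalize_sampled_rdms(raw, run$dspace, "replica", normalize)
}

#' Single-population (biased) RDM estimator
#'
#' The same accumulation as [replica_rdms] but with both factors drawn from
#' one population: `E[C_i C_i] = E[C_i]^2 + Var(C_i)`, so diagonal
#' accumulations acquire a positive bias that trace normalization then
#' redistributes into the whole tensor. Exposed for bias demonstrations.
#'
#' @inheritParams replica_rdms
#' @param replica which population to square.
#' @return an [rdm_set] with provenance `"replica"` (biased single).
#' @export
biased_single_replica_rdms <- function(run, max_rank = 3, normalize = TRUE,
                                       replica = 1) {
  if (is.null(run$samples) || length(run$samples$iters) == 0)
    stop("no sampling snapshots stored (set sample_period)")
  u <- unitize(run$samples$C[[replica]])
  raw <- accumulate_pair_rdms(u, u, run$dspace, max_rank)
  finalize_sampled_rdms(raw, run$dspace, "replica", normalize)
}

#' Hybrid semistochastic-histogramming + replica RDMs
#'
#' Like [replica_rdms], but the deterministic-subspace pair block of the
#' sampled density is built by averaging each replica's (unit-normalized)
#' subspace coefficients over imaginary time first and multiplying the two
#' independent averages second — the "first average, then multiply"
#' principle. This removes the product-noise term of the instantaneous
#' estimator for the dominant determinants while the remainder keeps the
#' replica snapshot products; the resulting positivity violations are
#' intermediate between the replica estimator and pure histogramming.
#'
#' Coefficient averages here include the cycles where a determinant is
#' unoccupied (zero weight); normalizing by occupied cycles only would
#' estimate a conditional mean and systematically inflate marginally
#' occupied subspace determinants relative to the zero-inclusive product
#' accumulation of the remainder.
#'
#' @param run a two-replica `qmc_run` with histogramming and sampling.
#' @param max_rank 1-3.
#' @param normalize trace-normalize the final tensors (default TRUE).
#' @return an [rdm_set] with provenance `"hybrid"`.
#' @export
hybrid_rdms <- function(run, max_rank = 3, normalize = TRUE) {
  if (run$params$n_replicas != 2) stop("hybrid_rdms requires two replicas")
  D <- run$D_idx
  u1 <- unitize(run$samples$C[[1]])
  u2 <- unitize(run$samples$C[[2]])
  raw <- accumulate_pair_rdms(u1, u2, run$dspace, max_rank)
  if (length(D)) {
    m1 <- Reduce(`+`, u1) / length(u1)
    m2 <- Reduce(`+`, u2) / length(u2)
    raw <- swap_subspace_block(raw, run, outer(m1[D], m2[D]), max_rank, u1, u2)
  }
  finalize_sampled_rdms(raw, run$dspace, "hybrid", normalize)
}

#' Fermionic positivity report of a 3RDM
#'
#' Eigen-decomposition of the spin-free 3RDM matrixization
#' ([gamma3_matrixization]); for the RDMs of any pure state the spectrum is
#' nonnegative, while finite-sampling replica estimates develop negative
#' tails.
#'
#' @param rdms an [rdm_set] with `gamma3`.
#' @param tol eigenvalues below `-tol` count as violations (default 1e-10).
#' @param matrixization only `"spin-free"` is stored at desk scale; the
#'   label is recorded in the report.
#' @return object of class `positivity_report`: sorted `eigenvalues`,
#'   `n_negative`, `negative_mass` (sum of |negative eigenvalues|),
#'   `hermiticity_error`, `trace_deviations`, `mode`.
#' @export
positivity_report <- function(rdms, tol = 1e-10,
                              matrixization = "spin-free") {
  if (!identical(matrixization, "spin-free"))
    stop("only the spin-free matrixization is available: the estimators ",
         "store spin-summed tensors")
  if (is.null(rdms$gamma3)) stop("rdm_set lacks gamma3")
  M <- gamma3_matrixization(rdms$gamma3)
  M <- (M + t(M)) / 2
  ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  neg <- ev[ev < -tol]
  structure(list(eigenvalues = ev, n_negative = length(neg),
                 negative_mass = sum(abs(neg)), tol = tol,
                 hermiticity_error = rdms$hermiticity_error,
                 trace_deviations = rdm_trace_deviations(rdms),
                 mode = rdms$provenance,
                 matrixization = matrixization),
            class = "positivity_report")
}

#' @export
print.positivity_report <- function(x, ...) {
  cat("3RDM positivity report (", x$mode, ", ", x$matrixization, ")\n",
      sep = "")
  cat(sprintf("  eigenvalues < -%g : %d (total negative mass %.3e)\n",
              x$tol, x$n_negative, x$negative_mass))
  cat(sprintf("  hermiticity error : %.3e\n", x$hermiticity_error))
  cat("  trace deviations  :",
      paste(sprintf("%s=%.2e", names(x$trace_deviations),
                    x$trace_deviations), collapse = " "), "\n")
  invisible(x)
}

#' Nearest positive-semidefinite matrix
#'
#' Frobenius-norm projection by eigenvalue clipping at zero; idempotent,
#' with `||out - in||_F = sqrt(sum(negatives^2))`.
#' @param M symmetric matrix.
#' @return PSD matrix of the same dimension.
#' @export
project_to_psd <- function(M) {
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M))))
    stop("input not symmetric; symmetrize first")
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  eg$vectors %*% (ev * t(eg$vectors))
}
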