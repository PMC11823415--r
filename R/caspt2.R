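# Internally contracted CASPT2: the first-order interacting space is spanned
# by the doubly excited perturbers E_pq E_rs |psi> grouped into eight classes
# by their inactive-hole / virtual-electron pattern. Overlap (S) and
# zeroth-order (B) matrices are assembled with the generic contraction
# engine (wick.R), consuming at most Gamma3 for S/V and the Fock-contracted
# 4RDM for B. Each class is Lowdin-orthogonalized with linear-dependence
# truncation and solved by direct dense linear algebra; the zeroth-order
# operator is the generalized Fock projected block-diagonally (inter-class
# couplings through inactive-active-virtual off-diagonal Fock blocks are
# dropped, which is exact in the pseudocanonical basis used by default).

#' CASPT2 parameters
#'
#' @param ipea IPEA shift in Hartree (default 0.25, the conventional value).
#' @param imaginary_shift imaginary level shift in Hartree (default 0.1);
#'   suppresses intruder-state denominators, energy reported through the
#'   standard shift-corrected Hylleraas expression.
#' @param lindep_threshold relative overlap-eigenvalue cutoff for the
#'   Lowdin truncation (default 1e-8 of the largest eigenvalue per class).
#' @param basis_mode `"pseudocanonical"` (rotate internally, default) or
#'   `"general"` (use the orbitals as given).
#' @param frozen inactive orbitals to exclude from correlation (default none).
#' @return list of class `caspt2_params`.
#' @export
caspt2_params <- function(ipea = 0.25, imaginary_shift = 0.1,
                          lindep_threshold = 1e-8,
                          basis_mode = c("pseudocanonical", "general"),
                          frozen = integer(0)) {
  stopifnot(ipea >= 0, imaginary_shift >= 0, lindep_threshold > 0)
  structure(list(ipea = ipea, imaginary_shift = imaginary_shift,
                 lindep_threshold = lindep_threshold,
                 basis_mode = match.arg(basis_mode),
                 frozen = as.integer(frozen)),
            class = "caspt2_params")
}

# ---- perturber classes ----

# Each perturber |mu> = E_{p1 q1} E_{p2 q2} |psi>, stored as a 2x2 integer
# matrix of global orbital indices. Classes keyed by (virtual electrons,
# inactive holes):
#   A (0,1) E_ti E_uv   B (0,2) E_ti E_uj   C (1,0) E_at E_uv
#   D (1,1) E_ai E_tu and E_ti E_au         E (1,2) E_ti E_aj
#   F (2,0) E_at E_bu   G (2,1) E_ai E_bt   H (2,2) E_ai E_bj
enumerate_perturbers <- function(space) {
  I <- space$inactive; A <- space$active; V <- space$virtual
  cls <- list()
  add <- function(label, ops) cls[[label]] <<- list(label = label, ops = ops)
  pair_le <- function(x, y) (x[1] < y[1]) || (x[1] == y[1] && x[2] <= y[2])
  ops <- list()
  for (t in A) for (i in I) for (u in A) for (v in A)
    ops[[length(ops) + 1L]] <- rbind(c(t, i), c(u, v))
  add("A", ops)
  ops <- list()
  for (t in A) for (i in I) for (u in A) for (j in I)
    if (pair_le(c(t, i), c(u, j)))
      ops[[length(ops) + 1L]] <- rbind(c(t, i), c(u, j))
  add("B", ops)
  ops <- list()
  for (a in V) for (t in A) for (u in A) for (v in A)
    ops[[length(ops) + 1L]] <- rbind(c(a, t), c(u, v))
  add("C", ops)
  ops <- list()
  for (a in V) for (i in I) for (t in A) for (u in A)
    ops[[length(ops) + 1L]] <- rbind(c(a, i), c(t, u))
  for (t in A) for (i in I) for (a in V) for (u in A)
    ops[[length(ops) + 1L]] <- rbind(c(t, i), c(a, u))
  add("D", ops)
  ops <- list()
  for (t in A) for (i in I) for (a in V) for (j in I)
    ops[[length(ops) + 1L]] <- rbind(c(t, i), c(a, j))
  add("E", ops)
  ops <- list()
  for (a in V) for (t in A) for (b in V) for (u in A)
    if (pair_le(c(a, t), c(b, u)))
      ops[[length(ops) + 1L]] <- rbind(c(a, t), c(b, u))
  add("F", ops)
  ops <- list()
  for (a in V) for (i in I) for (b in V) for (t in A)
    ops[[length(ops) + 1L]] <- rbind(c(a, i), c(b, t))
  add("G", ops)
  ops <- list()
  for (a in V) for (i in I) for (b in V) for (j in I)
    if (pair_le(c(a, i), c(b, j)))
      ops[[length(ops) + 1L]] <- rbind(c(a, i), c(b, j))
  add("H", ops)
  cls
}

bra_ops <- function(op2) rbind(rev(op2[2, ]), rev(op2[1, ]))

# IPEA occupation weight of one perturber: active creations count 2 - n_t,
# active annihilations count n_t (n_t = Gamma1 diagonal).
ipea_theta <- function(op2, space, g1diag) {
  act <- space$active
  th <- 0
  for (r in 1:2) {
    p <- op2[r, 1]; q <- op2[r, 2]
    ip <- match(p, act); iq <- match(q, act)
    if (!is.na(ip)) th <- th + (2 - g1diag[ip])
    if (!is.na(iq)) th <- th + g1diag[iq]
  }
  th
}

# ---- S, B, V assembly ----

#' Build the perturber-class matrices of internally contracted CASPT2
#'
#' For every excitation class, assembles the overlap matrix `S`, the
#' zeroth-order matrix `B = <mu| f |nu>` (generalized Fock projected on
#' space-diagonal blocks), and the right-hand side `V = <mu|H|psi>`, from
#' the integrals and the RDM set (Gamma1-3 plus Fock-contracted 4RDM).
#'
#' @param ints an [integral_set] over all orbitals.
#' @param space an [orbital_space].
#' @param rdms an [rdm_set] including `f4` built against `fock`'s active block.
#' @param fock a `fock_matrix` over all orbitals.
#' @return list of class blocks: `label`, `ops`, `S`, `B`, `V`, `theta`,
#'   plus attributes `e0` (Fock expectation) and `e_ref`.
#' @export
build_class_blocks <- function(ints, space, rdms, fock) {
  n <- ints$n_orb
  act <- space$active; ia <- space$inactive; vi <- space$virtual
  n_act <- length(act)
  if (n_act > 0 && is.null(rdms$f4))
    stop("rdm_set lacks the Fock-contracted 4RDM needed for the B matrices")
  f <- fock$f
  f_act <- f[act, act, drop = FALSE]
  ctx <- wick_context(space, rdms$gamma1, rdms$gamma2, rdms$gamma3,
                      f_active = f_act, f4 = rdms$f4)
  e0 <- 2 * sum(diag(f)[ia]) +
    (if (n_act) sum(f_act * rdms$gamma1) else 0)
  e_ref <- cas_energy_from_rdms(ints, space, rdms$gamma1, rdms$gamma2)

  # Hamiltonian candidate terms for V (E-product form):
  # H = e_core + sum h1_pq E_pq + 1/2 sum g_pqrs E_pq E_rs
  h1 <- ints$h
  for (p in seq_len(n)) for (q in seq_len(n))
    h1[p, q] <- h1[p, q] - 0.5 * sum(ints$g[p, , , q][cbind(seq_len(n), seq_len(n))])
  ob <- which(abs(h1) > 1e-13, arr.ind = TRUE)
  tb <- which(abs(ints$g) > 1e-13, arr.ind = TRUE)
  spc <- ctx$spc
  # Exact per-orbital net-balance screen: <...> vanishes unless every
  # inactive/virtual orbital has equal creation and annihilation counts in
  # the whole operator string (number-operator eigenstate argument). Each
  # candidate H term is keyed by its net non-active balance; a perturber
  # only pairs with candidates whose key cancels its own.
  net_key <- function(cre, ann) {
    cnt <- integer(n)
    for (o in cre) if (spc[o] != 2L) cnt[o] <- cnt[o] + 1L
    for (o in ann) if (spc[o] != 2L) cnt[o] <- cnt[o] - 1L
    nz <- which(cnt != 0L)
    if (!length(nz)) return("0")
    paste(nz, cnt[nz], sep = ":", collapse = ",")
  }
  ob_keys <- vapply(seq_len(nrow(ob)), function(r)
    net_key(ob[r, 1], ob[r, 2]), "")
  tb_keys <- vapply(seq_len(nrow(tb)), function(r)
    net_key(tb[r, c(1, 3)], tb[r, c(2, 4)]), "")
  ob_groups <- split(seq_len(nrow(ob)), ob_keys)
  tb_groups <- split(seq_len(nrow(tb)), tb_keys)
  hvals <- h1[ob]; gvals <- ints$g[tb]

  cls <- enumerate_perturbers(space)
  g1diag <- if (n_act) diag(rdms$gamma1) else numeric(0)
  fII <- which(abs(f[ia, ia, drop = FALSE]) > 1e-13, arr.ind = TRUE)
  fVV <- which(abs(f[vi, vi, drop = FALSE]) > 1e-13, arr.ind = TRUE)
  blocks <- list()
  for (cl in cls) {
    d <- length(cl$ops)
    if (d == 0) {
      blocks[[cl$label]] <- list(label = cl$label, ops = cl$ops,
                                 S = matrix(0, 0, 0), B = matrix(0, 0, 0),
                                 V = numeric(0), theta = numeric(0))
      next
    }
    S <- matrix(0, d, d); B <- matrix(0, d, d); V <- numeric(d)
    bras <- lapply(cl$ops, bra_ops)
    for (mu in seq_len(d)) {
      bo <- bras[[mu]]
      for (nu in mu:d) {
        ko <- cl$ops[[nu]]
        S[mu, nu] <- S[nu, mu] <- mixed_expectation(rbind(bo, ko), ctx)
        bv <- 0
        if (n_act)
          bv <- bv + mixed_expectation(rbind(bo, c(-1L, -2L), ko), ctx,
                                       f_pair_at = 3L)
        if (nrow(fII)) for (r in seq_len(nrow(fII))) {
          i_ <- ia[fII[r, 1]]; j_ <- ia[fII[r, 2]]
          bv <- bv + f[i_, j_] *
            mixed_expectation(rbind(bo, c(i_, j_), ko), ctx)
        }
        if (nrow(fVV)) for (r in seq_len(nrow(fVV))) {
          a_ <- vi[fVV[r, 1]]; b_ <- vi[fVV[r, 2]]
          bv <- bv + f[a_, b_] *
            mixed_expectation(rbind(bo, c(a_, b_), ko), ctx)
        }
        B[mu, nu] <- B[nu, mu] <- bv
      }
      # ---- V: candidates whose net balance cancels the bra's ----
      cnt <- integer(n)
      for (o in bo[, 1]) if (spc[o] != 2L) cnt[o] <- cnt[o] - 1L
      for (o in bo[, 2]) if (spc[o] != 2L) cnt[o] <- cnt[o] + 1L
      nz <- which(cnt != 0L)
      need_key <- if (!length(nz)) "0" else
        paste(nz, cnt[nz], sep = ":", collapse = ",")
      vmu <- 0
      for (r in ob_groups[[need_key]]) {
        vmu <- vmu + hvals[r] *
          mixed_expectation(rbind(bo, ob[r, , drop = FALSE]), ctx)
      }
      for (r in tb_groups[[need_key]]) {
        q4 <- tb[r, ]
        vmu <- vmu + 0.5 * gvals[r] *
          mixed_expectation(rbind(bo, q4[1:2], q4[3:4]), ctx)
      }
      V[mu] <- vmu
    }
    theta <- vapply(cl$ops, ipea_theta, 0, space = space, g1diag = g1diag)
    smin <- if (d) min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) else 0
    if (smin < -1e-6)
      stop("overlap matrix of class ", cl$label, " is not positive ",
           "semidefinite (min eigenvalue ", format(smin), "): ",
           "the supplied RDMs violate fermionic positivity")
    blocks[[cl$label]] <- list(label = cl$label, ops = cl$ops, S = S, B = B,
                               V = V, theta = theta)
  }
  attr(blocks, "e0") <- e0
  attr(blocks, "e_ref") <- e_ref
  blocks
}

#' Lowdin orthogonalization with linear-dependence truncation
#'
#' Diagonalizes the overlap, discards eigenvectors below
#' `lindep_threshold * max(eigenvalue)`, and returns
#' `X = U_kept s_kept^{-1/2}` so that `t(X) S X = I` on the retained space.
#'
#' @param S symmetric PSD overlap matrix.
#' @param lindep_threshold relative eigenvalue cutoff.
#' @return list `X`, `n_kept`, `n_discarded`, `eigenvalues`.
#' @export
lowdin_truncate <- function(S, lindep_threshold = 1e-8) {
  if (nrow(S) == 0)
    return(list(X = matrix(0, 0, 0), n_kept = 0L, n_discarded = 0L,
                eigenvalues = numeric(0)))
  if (max(abs(S - t(S))) > 1e-8) stop("overlap matrix not symmetric")
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  thr <- lindep_threshold * max(eg$values, 0)
  keep <- eg$values > thr
  X <- eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[keep]), sum(keep))
  list(X = X, n_kept = sum(keep), n_discarded = sum(!keep),
       eigenvalues = eg$values)
}

#' Solve the CASPT2 equations class by class
#'
#' In each Lowdin-orthonormalized class solves
#' `(B - E0 + shifts) t = -V`; the IPEA shift enters as the symmetric
#' occupation-weighted diagonal modification
#' `B += ipea/4 (Theta S + S Theta)` in the nonorthogonal basis, and the
#' imaginary shift through the standard corrected (Hylleraas-type) energy
#' `E2 = sum_k t_k^2 D_k + 2 t_k V_k` with `t_k = -V_k D_k / (D_k^2 + eps^2)`.
#'
#' @param blocks output of [build_class_blocks].
#' @param params a [caspt2_params].
#' @return object of class `caspt2_result`: `e2_total`, `e2_by_class`,
#'   `e_ref`, `reference_weight`, `diagnostics`.
#' @export
solve_and_energy <- function(blocks, params) {
  e0 <- attr(blocks, "e0")
  e2 <- c(); tnorm2 <- 0
  diag_list <- list()
  eps <- params$imaginary_shift
  for (bl in blocks) {
    d <- length(bl$V)
    if (d == 0) { e2[bl$label] <- 0; next }
    Bm <- bl$B
    if (params$ipea != 0) {
      Th <- diag(bl$theta, d)
      Bm <- Bm + params$ipea / 4 * (Th %*% bl$S + bl$S %*% Th)
    }
    lw <- lowdin_truncate(bl$S, params$lindep_threshold)
    if (lw$n_kept == 0) {
      e2[bl$label] <- 0
      diag_list[[bl$label]] <- list(kept = 0L, discarded = lw$n_discarded,
                                    min_denom = NA_real_)
      next
    }
    Bt <- t(lw$X) %*% Bm %*% lw$X
    Bt <- (Bt + t(Bt)) / 2
    Vt <- as.numeric(t(lw$X) %*% bl$V)
    eg <- eigen(Bt, symmetric = TRUE)
    Dk <- eg$values - e0
    Vk <- as.numeric(t(eg$vectors) %*% Vt)
    if (eps == 0 && any(abs(Dk) < 1e-8 & abs(Vk) > 1e-10))
      stop("vanishing zeroth-order denominator in class ", bl$label,
           " (intruder state); set imaginary_shift > 0")
    tk <- -Vk * Dk / (Dk^2 + eps^2)
    e2[bl$label] <- sum(tk^2 * Dk + 2 * tk * Vk)
    tnorm2 <- tnorm2 + sum(tk^2)
    diag_list[[bl$label]] <- list(kept = lw$n_kept,
                                  discarded = lw$n_discarded,
                                  min_denom = min(abs(Dk)))
  }
  structure(list(e2_total = sum(e2), e2_by_class = e2,
                 e_ref = attr(blocks, "e_ref"), e0 = e0,
                 reference_weight = 1 / (1 + tnorm2),
                 diagnostics = diag_list),
            class = "caspt2_result")
}

#' @export
print.caspt2_result <- function(x, ...) {
  cat("CASPT2 second-order energy\n")
  cat(sprintf("  reference energy : %18.10f Eh\n", x$e_ref))
  cat(sprintf("  E2 total         : %18.10f Eh\n", x$e2_total))
  cat(sprintf("  total energy     : %18.10f Eh\n", x$e_ref + x$e2_total))
  cat(sprintf("  reference weight : %6.2f %%\n", 100 * x$reference_weight))
  cat("  per class:", paste(sprintf("%s=%.8f", names(x$e2_by_class),
                                    x$e2_by_class), collapse = " "), "\n")
  invisible(x)
}

# rotate the pair indices of a 2k-index tensor by orbital rotation U
rotate_pair_tensor <- function(G, U, npairs) {
  n <- nrow(U)
  if (n == 0) return(G)
  K <- kronecker(U, U)
  for (k in seq_len(npairs)) {
    dim(G) <- c(n^2, n^(2 * (npairs - 1)))
    G <- crossprod(K, G)                     # transform leading pair
    dim(G) <- rep(n, 2 * npairs)
    if (npairs > 1)
      G <- aperm(G, c(3:(2 * npairs), 1, 2)) # cycle pairs
  }
  G
}

#' Rotate an rdm_set into a new active orbital basis
#'
#' Applies `Gamma'_{p'q'...} = sum Gamma_{pq...} U_{pp'} U_{qq'}...` to all
#' stored tensors. The Fock-contracted 4RDM co-rotates on its six explicit
#' indices (valid because its contracted pair transforms jointly with the
#' Fock matrix).
#' @param rdms an [rdm_set].
#' @param U_act active-block rotation (columns = new orbitals).
#' @return rotated [rdm_set].
#' @export
rotate_rdms <- function(rdms, U_act) {
  rdm_set(gamma1 = t(U_act) %*% rdms$gamma1 %*% U_act,
          gamma2 = if (!is.null(rdms$gamma2))
            rotate_pair_tensor(rdms$gamma2, U_act, 2),
          gamma3 = if (!is.null(rdms$gamma3))
            rotate_pair_tensor(rdms$gamma3, U_act, 3),
          f4 = if (!is.null(rdms$f4)) rotate_pair_tensor(rdms$f4, U_act, 3),
          provenance = rdms$provenance,
          hermiticity_error = rdms$hermiticity_error,
          n_act_elec = rdms$n_act_elec)
}

#' End-to-end CASPT2 energy
#'
#' Pipeline: (optionally) solve the CAS-CI problem for the reference vector,
#' build the generalized Fock matrix, rotate to pseudocanonical orbitals,
#' form Gamma1-3 and the Fock-contracted 4RDM, assemble the class blocks and
#' solve for the second-order energy.
#'
#' @param ints an [integral_set] over all orbitals.
#' @param space an [orbital_space].
#' @param params a [caspt2_params].
#' @param ci_active optional reference CI vector over the active-space
#'   determinant enumeration (e.g. a truncated histogrammed vector); default
#'   NULL solves CAS-CI exactly.
#' @return a `caspt2_result`; attribute `"detail"` carries the rotated
#'   integrals, Fock, RDMs and reference vector.
#' @export
caspt2_energy <- function(ints, space, params = caspt2_params(),
                          ci_active = NULL) {
  n_act <- length(space$active)
  na <- (space$n_act_elec + space$ms2) / 2
  nb <- (space$n_act_elec - space$ms2) / 2
  if (n_act > 0) {
    ha <- active_hamiltonian(ints, space)
    dact <- enumerate_cas(n_act, na, nb)
    if (is.null(ci_active)) {
      H <- build_hamiltonian(dact, ha)
      C <- davidson(H)$vectors[, 1]
    } else {
      if (length(ci_active) != dact$n_det)
        stop("ci_active has wrong length for the active space")
      C <- ci_active / sqrt(sum(ci_active^2))
    }
    rd <- exact_rdms(C, dact, 3)
  } else {
    C <- 1
    rd <- rdm_set(gamma1 = matrix(0, 0, 0),
                  gamma2 = array(0, rep(0, 4)),
                  gamma3 = array(0, rep(0, 6)),
                  f4 = array(0, rep(0, 6)), n_act_elec = 0)
  }
  fock <- build_generalized_fock(ints, rd$gamma1, space)
  U_act <- diag(n_act)
  if (params$basis_mode == "pseudocanonical") {
    pc <- pseudocanonicalize(ints, fock, space)
    ints2 <- pc$ints; fock2 <- pc$fock
    U_act <- pc$rotation[space$active, space$active, drop = FALSE]
  } else {
    ints2 <- ints; fock2 <- fock
  }
  if (n_act > 0) {
    # F.4RDM computed in the original basis with the original Fock active
    # block, then co-rotated (see rotate_rdms)
    f4_old <- f_contracted_4rdm(C, dact, fock$f[space$active, space$active,
                                                drop = FALSE],
                                gamma3 = rd$gamma3)
    rd$f4 <- f4_old
    rd2 <- if (params$basis_mode == "pseudocanonical")
      rotate_rdms(rd, U_act) else rd
  } else rd2 <- rd
  blocks <- build_class_blocks(ints2, space, rd2, fock2)
  res <- solve_and_energy(blocks, params)
  attr(res, "detail") <- list(ints = ints2, fock = fock2, rdms = rd2,
                              ci = C, rotation_act = U_act)
  res
}

#' Explicit-vector CASPT2 oracle
#'
#' Independent correctness check: every contracted perturber is built as an
#' explicit vector in the full-orbital determinant space, and S, B, V are
#' computed as literal inner products with the full Hamiltonian and the
#' (block-diagonally projected) generalized Fock operator, then passed
#' through the same Lowdin/shift solver. Feasible only for small systems
#' (full space guarded at ~20k determinants).
#'
#' @param ints an [integral_set] (orbitals as given; no internal rotation —
#'   pre-rotate for pseudocanonical comparisons).
#' @param space an [orbital_space].
#' @param params a [caspt2_params] (basis_mode is ignored; orbitals used
#'   as given).
#' @param ci_active optional active-space reference vector.
#' @return a `caspt2_result`.
#' @export
explicit_vector_oracle <- function(ints, space, params = caspt2_params(),
                                   ci_active = NULL) {
  n <- ints$n_orb
  n_act <- length(space$active)
  na_f <- (space$n_elec + space$ms2) / 2
  nb_f <- (space$n_elec - space$ms2) / 2
  dfull <- enumerate_cas(n, na_f, nb_f)
  if (dfull$n_det > 20000) stop("full space too large for the oracle")
  na <- (space$n_act_elec + space$ms2) / 2
  nb <- (space$n_act_elec - space$ms2) / 2
  if (n_act > 0) {
    ha <- active_hamiltonian(ints, space)
    dact <- enumerate_cas(n_act, na, nb)
    C <- if (is.null(ci_active)) {
      davidson(build_hamiltonian(dact, ha))$vectors[, 1]
    } else ci_active / sqrt(sum(ci_active^2))
    rd1 <- exact_rdms(C, dact, 1)
    g1 <- rd1$gamma1
  } else {
    dact <- NULL; C <- 1
    g1 <- matrix(0, 0, 0)
  }
  fock <- build_generalized_fock(ints, g1, space)
  psi <- expand_cas_vector(C, dact, space, dfull)
  Hf <- build_hamiltonian(dfull, ints)
  e_ref <- sum(psi * as.numeric(Hf %*% psi))
  # block-diagonally projected Fock as a full-space one-body operator
  f <- fock$f
  fbd <- matrix(0, n, n)
  for (blk in list(space$inactive, space$active, space$virtual))
    if (length(blk)) fbd[blk, blk] <- f[blk, blk]
  opsF <- spinfree_ops(dfull)
  Fop <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(dfull$n_det, dfull$n_det))
  for (p in seq_len(n)) for (q in seq_len(n))
    if (abs(fbd[p, q]) > 1e-14)
      Fop <- Fop + fbd[p, q] * get_Eop(opsF, n, p, q)
  e0 <- sum(psi * as.numeric(Fop %*% psi))
  Hpsi <- as.numeric(Hf %*% psi)
  cls <- enumerate_perturbers(space)
  g1diag <- if (n_act) diag(g1) else numeric(0)
  blocks <- list()
  for (cl in cls) {
    d <- length(cl$ops)
    if (d == 0) {
      blocks[[cl$label]] <- list(label = cl$label, ops = cl$ops,
                                 S = matrix(0, 0, 0), B = matrix(0, 0, 0),
                                 V = numeric(0), theta = numeric(0))
      next
    }
    P <- matrix(0, dfull$n_det, d)
    for (mu in seq_len(d)) {
      o2 <- cl$ops[[mu]]
      v <- as.numeric(get_Eop(opsF, n, o2[2, 1], o2[2, 2]) %*% psi)
      P[, mu] <- as.numeric(get_Eop(opsF, n, o2[1, 1], o2[1, 2]) %*% v)
    }
    S <- crossprod(P)
    B <- crossprod(P, as.matrix(Fop %*% P))
    B <- (B + t(B)) / 2
    V <- as.numeric(crossprod(P, Hpsi))
    theta <- vapply(cl$ops, ipea_theta, 0, space = space, g1diag = g1diag)
    blocks[[cl$label]] <- list(label = cl$label, ops = cl$ops, S = S, B = B,
                               V = V, theta = theta)
  }
  attr(blocks, "e0") <- e0
  attr(blocks, "e_ref") <- e_ref
  solve_and_energy(blocks, params)
}

#' Embed an active-space CI vector in the full orbital space
#'
#' Maps each active determinant onto the full determinant with the inactive
#' orbitals doubly occupied, including the fermionic reordering sign when
#' inactive and active orbitals interleave.
#' @param C active-space coefficients (or scalar 1 when no active orbitals).
#' @param dact active `det_space` (NULL when no active orbitals).
#' @param space an [orbital_space].
#' @param dfull full `det_space`.
#' @return coefficient vector over `dfull`.
#' @export
expand_cas_vector <- function(C, dact, space, dfull) {
  psi <- numeric(dfull$n_det)
  core <- bit_mask(space$inactive)
  if (is.null(dact)) {
    j <- det_index(dfull, core, core)
    psi[j] <- 1
    return(psi)
  }
  act <- space$active
  map_mask <- function(m) {
    v <- bits_of(m, length(act))
    bit_mask(act[v])
  }
  resign <- function(m_act_full) {
    # inversions between core creations and active creations below them
    s <- 0L
    for (i in space$inactive)
      s <- s + popcount(bitwAnd(m_act_full, bitwShiftL(1L, i - 1L) - 1L))
    s
  }
  for (k in seq_len(dact$n_det)) {
    am <- map_mask(dact$alpha[k]); bm <- map_mask(dact$beta[k])
    j <- det_index(dfull, bitwOr(core, am), bitwOr(core, bm))
    if (is.na(j)) stop("internal: full-space determinant not found")
    sg <- if ((resign(am) + resign(bm)) %% 2L) -1 else 1
    psi[j] <- sg * C[k]
  }
  psi
}

#' Closed-form spin-adapted MP2 energy
#'
#' Independent textbook formula for a closed-shell reference in canonical
#' orbitals: `E2 = sum_{ijab} (ia|jb)[2(ia|jb)-(ib|ja)] / (ei+ej-ea-eb)`.
#' Orbitals are canonicalized internally from the closed-shell Fock matrix.
#'
#' @param ints an [integral_set].
#' @param space an [orbital_space] with an empty active list.
#' @return scalar MP2 correlation energy (Hartree).
#' @export
mp2_energy <- function(ints, space) {
  if (length(space$active) != 0) stop("mp2_energy requires an empty active space")
  fock <- build_generalized_fock(ints, matrix(0, 0, 0), space)
  pc <- pseudocanonicalize(ints, fock, space)
  eps <- pc$eps
  g <- pc$ints$g
  occ <- space$inactive; vir <- space$virtual
  e2 <- 0
  for (i in occ) for (j in occ) for (a in vir) for (b in vir) {
    e2 <- e2 + g[i, a, j, b] * (2 * g[i, a, j, b] - g[i, b, j, a]) /
      (eps[i] + eps[j] - eps[a] - eps[b])
  }
  e2
}
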