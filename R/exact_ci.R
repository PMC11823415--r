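# Deterministic CI machinery: Davidson eigensolver, exact spin-free RDMs up
# to rank 3 (normal-ordered), transition 3RDMs, |F> construction, and the
# Fock-contracted 4RDM via the transition-3RDM pathway plus a literal
# spin-orbital oracle.
#
# Normal-ordering convention (pinned by the spin-orbital oracle in tests):
#   Gamma1_pq       = <E_pq>
#   Gamma2_pq,rs    = <e_pq,rs>    with e_pq,rs = E_pq E_rs - d_qr E_ps
#   Gamma3_pq,rs,tu = <e_pq,rs,tu>, the expectation of
#                     sum_spins a+_p a+_r a+_t a_u a_s a_q (spatial indices).

#' Davidson diagonalization
#'
#' Davidson-Liu iteration with diagonal preconditioning for the lowest
#' `n_roots` eigenpairs of a (sparse) symmetric CI matrix. Small matrices
#' fall through to dense `eigen`.
#'
#' @param H symmetric matrix (dense or `Matrix` sparse).
#' @param n_roots number of lowest roots.
#' @param tol residual norm convergence threshold.
#' @param max_iter maximum iterations.
#' @param max_subspace subspace size before collapse.
#' @return list with `values` (ascending) and `vectors` (columns, normalized).
#' @export
davidson <- function(H, n_roots = 1, tol = 1e-9, max_iter = 400,
                     max_subspace = NULL) {
  nd <- nrow(H)
  if (is.null(max_subspace)) max_subspace <- min(nd, max(24, 10 * n_roots))
  if (nd <= max(60, 5 * n_roots)) {
    eg <- eigen(as.matrix(H), symmetric = TRUE)
    ord <- order(eg$values)[seq_len(n_roots)]   # eigen() sorts decreasing
    return(list(values = eg$values[ord],
                vectors = eg$vectors[, ord, drop = FALSE]))
  }
  hd <- Matrix::diag(H)
  guess_idx <- order(hd)[seq_len(n_roots)]
  V <- matrix(0, nd, n_roots)
  for (k in seq_len(n_roots)) V[guess_idx[k], k] <- 1
  W <- as.matrix(H %*% V)
  for (it in seq_len(max_iter)) {
    G <- crossprod(V, W)
    G <- (G + t(G)) / 2
    eg <- eigen(G, symmetric = TRUE)
    sel <- order(eg$values)[seq_len(n_roots)]   # eigen() sorts decreasing
    theta <- eg$values[sel]
    S <- eg$vectors[, sel, drop = FALSE]
    X <- V %*% S
    R <- W %*% S - X %*% diag(theta, n_roots)
    rn <- sqrt(colSums(R^2))
    if (all(rn < tol)) return(list(values = theta, vectors = X))
    for (k in which(rn >= tol)) {
      denom <- hd - theta[k]
      denom[abs(denom) < 1e-8] <- 1e-8
      d <- R[, k] / denom
      for (pass in 1:2) d <- d - V %*% crossprod(V, d)
      dn <- sqrt(sum(d^2))
      if (dn > 1e-10) {
        V <- cbind(V, d / dn)
        W <- cbind(W, as.matrix(H %*% (d / dn)))
      }
    }
    if (ncol(V) > max_subspace) {
      V <- qr.Q(qr(X))
      W <- as.matrix(H %*% V)
    }
  }
  stop("davidson: no convergence after ", max_iter, " iterations")
}

#' Ground state(s) of a CAS Hamiltonian
#'
#' Enumerates the space, builds the sparse Hamiltonian, Davidson-diagonalizes.
#' @param ints an [integral_set] over the active orbitals.
#' @param n_alpha,n_beta electron counts.
#' @param n_roots,tol passed to [davidson].
#' @return list: `energies`, `vectors`, `dspace`, `H`.
#' @export
casci_ground_state <- function(ints, n_alpha, n_beta, n_roots = 1, tol = 1e-9) {
  ds <- enumerate_cas(ints$n_orb, n_alpha, n_beta)
  H <- build_hamiltonian(ds, ints)
  dv <- davidson(H, n_roots = n_roots, tol = tol)
  list(energies = dv$values, vectors = dv$vectors, dspace = ds, H = H)
}

# ---- E-operator product tensors ----

# columns: Y[, (q-1)*n + p] = E_pq |ket>
eop_image <- function(ket, dspace) {
  ops <- spinfree_ops(dspace)
  n <- dspace$n_orb
  Y <- matrix(0, dspace$n_det, n * n)
  for (c_ in seq_len(n * n)) Y[, c_] <- as.numeric(ops[[c_]] %*% ket)
  Y
}

#' Transition reduced density matrices between two CI vectors
#'
#' Normal-ordered spin-free transition RDMs `T^(k) = <bra| e_... |ket>` up to
#' `max_rank` (<= 3) by dense operator algebra on the enumerated space.
#' `bra = ket` yields the ordinary RDMs; the rank-3 tensor is not symmetric
#' for distinct bra/ket.
#'
#' @param bra,ket coefficient vectors over `dspace`.
#' @param dspace a `det_space`.
#' @param max_rank highest rank (1-3).
#' @return list `gamma1` (+ `gamma2`, `gamma3` up to `max_rank`).
#' @export
transition_rdms <- function(bra, ket, dspace, max_rank = 3) {
  stopifnot(max_rank >= 1, max_rank <= 3)
  n <- dspace$n_orb
  ops <- spinfree_ops(dspace)
  Yk <- eop_image(ket, dspace)
  g1 <- matrix(crossprod(bra, Yk), n, n)     # [p,q] = <bra|E_pq|ket>
  out <- list(gamma1 = g1)
  if (max_rank == 1) return(out)
  Yb <- eop_image(bra, dspace)
  # <E_ab E_cd>: crossprod index c1=(q1-1)n+p1 encodes E_{q1p1} on the bra
  EE <- aperm(array(crossprod(Yb, Yk), c(n, n, n, n)), c(2, 1, 3, 4))
  g2 <- EE
  for (v in seq_len(n)) g2[, v, v, ] <- g2[, v, v, ] - g1
  out$gamma2 <- g2
  if (max_rank == 2) return(out)
  # Z[, (rs) + (tu)-block] = E_rs E_tu |ket>
  Z <- matrix(0, dspace$n_det, n^4)
  for (c2 in seq_len(n * n)) {
    base <- (c2 - 1L) * n * n
    for (c1 in seq_len(n * n))
      Z[, base + c1] <- as.numeric(ops[[c1]] %*% Yk[, c2])
  }
  EEE <- aperm(array(crossprod(Yb, Z), rep(n, 6)), c(2, 1, 3, 4, 5, 6))
  g3 <- EEE
  # Gamma3 = <EEE> - d_qr G2[p,s,t,u] - d_qt G2[p,u,r,s] - d_st G2[p,q,r,u]
  #          - d_st d_qr G1[p,u]
  g2purs <- aperm(g2, c(1, 3, 4, 2))         # [p,r,s,u] = G2[p,u,r,s]
  for (v in seq_len(n)) {
    g3[, v, v, , , ] <- g3[, v, v, , , ] - g2
    g3[, v, , , v, ] <- g3[, v, , , v, ] - g2purs
    g3[, , , v, v, ] <- g3[, , , v, v, ] - g2
  }
  for (v1 in seq_len(n)) for (v2 in seq_len(n))
    g3[, v1, v1, v2, v2, ] <- g3[, v1, v1, v2, v2, ] - g1
  out$gamma3 <- g3
  out
}

#' RDM container
#'
#' Bundles the normal-ordered spin-free RDM tensors of ranks 1-3, the
#' Fock-contracted 4RDM, and provenance metadata.
#'
#' @param gamma1,gamma2,gamma3 RDM arrays (rank 2/4/6).
#' @param f4 Fock-contracted 4RDM (rank 6) or NULL.
#' @param provenance one of `"exact"`, `"replica"`, `"histogram"`, `"hybrid"`.
#' @param hermiticity_error Frobenius asymmetry recorded before any
#'   symmetrization (0 for exact provenance).
#' @param n_act_elec active electron count the tensors refer to.
#' @return object of class `rdm_set`.
#' @export
rdm_set <- function(gamma1, gamma2 = NULL, gamma3 = NULL, f4 = NULL,
                    provenance = "exact", hermiticity_error = 0,
                    n_act_elec = NA_real_) {
  structure(list(gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3, f4 = f4,
                 provenance = provenance,
                 hermiticity_error = hermiticity_error,
                 n_act_elec = n_act_elec,
                 n_act = nrow(gamma1)),
            class = "rdm_set")
}

#' Exact RDMs of a normalized CI vector
#'
#' Ranks 1-3 by dense operator algebra. Rank 4 is refused; the 4RDM enters
#' only through its Fock contraction ([f_contracted_4rdm]).
#'
#' @param C normalized coefficient vector.
#' @param dspace a `det_space`.
#' @param max_rank 1-3.
#' @return an [rdm_set] with provenance `"exact"`.
#' @export
exact_rdms <- function(C, dspace, max_rank = 3) {
  if (max_rank > 3) stop("rank > 3 refused; use f_contracted_4rdm")
  if (abs(sum(C^2) - 1) > 1e-10) stop("CI vector not normalized")
  tr <- transition_rdms(C, C, dspace, max_rank)
  rdm_set(tr$gamma1, tr$gamma2, tr$gamma3,
          provenance = "exact",
          n_act_elec = dspace$n_alpha + dspace$n_beta)
}

#' Partial-trace and trace identities of an rdm_set
#'
#' Returns the maximum deviations of `tr Gamma1 = N`,
#' `sum_s Gamma2[p,q,s,s] = (N-1) Gamma1[p,q]` and
#' `sum_t Gamma3[p,q,r,s,t,t] = (N-2) Gamma2[p,q,r,s]`.
#' @param rdms an [rdm_set].
#' @param n_elec active electron count (defaults to stored value).
#' @return named numeric vector of absolute deviations.
#' @export
rdm_trace_deviations <- function(rdms, n_elec = rdms$n_act_elec) {
  n <- rdms$n_act
  out <- c(trace1 = abs(sum(diag(rdms$gamma1)) - n_elec))
  if (!is.null(rdms$gamma2)) {
    pt2 <- apply(rdms$gamma2, c(1, 2), function(x) 0)  # init
    pt2 <- matrix(0, n, n)
    for (v in seq_len(n)) pt2 <- pt2 + rdms$gamma2[, , v, v]
    out["trace2"] <- max(abs(pt2 - (n_elec - 1) * rdms$gamma1))
  }
  if (!is.null(rdms$gamma3)) {
    pt3 <- array(0, c(n, n, n, n))
    for (v in seq_len(n)) pt3 <- pt3 + rdms$gamma3[, , , , v, v]
    out["trace3"] <- max(abs(pt3 - (n_elec - 2) * rdms$gamma2))
  }
  out
}

#' PSD matrixization of the 3RDM
#'
#' Reshapes `Gamma3[p1,q1,p2,q2,p3,q3]` into the `n^3 x n^3` matrix with row
#' index `(p1,p2,p3)` and column index `(q1,q2,q3)`. For RDMs of a pure state
#' this matrix is a Gram matrix (spin-traced), hence symmetric positive
#' semidefinite — the fermionic positivity property at rank 3.
#' @param gamma3 rank-6 array.
#' @return dense symmetric matrix.
#' @export
gamma3_matrixization <- function(gamma3) {
  n <- dim(gamma3)[1]
  m <- aperm(gamma3, c(1, 3, 5, 2, 4, 6))
  dim(m) <- c(n^3, n^3)
  m
}

# ---- |F> pathway for the Fock-contracted 4RDM ----

#' Build the singly excited state |F>
#'
#' `|F> = sum_vw f_vw E_vw |psi>` with `f` the active block of the
#' generalized Fock matrix. The CAS is closed under active excitations, so
#' |F> lives in the same determinant space; it is intentionally NOT
#' normalized (it is an operator image, not a state).
#'
#' @param C coefficient vector of |psi>.
#' @param dspace a `det_space`.
#' @param f_active symmetric active Fock block.
#' @return unnormalized coefficient vector.
#' @export
build_f_state <- function(C, dspace, f_active) {
  n <- dspace$n_orb
  stopifnot(nrow(f_active) == n)
  Y <- eop_image(C, dspace)
  as.numeric(Y %*% as.vector(f_active))  # as.vector(f)[(w-1)n+v] = f[v,w]
}

#' Transition 3RDM
#'
#' `T_pq,rs,tu = <bra| e_pq,rs,tu |ket>` with the same normal-ordering
#' convention as [exact_rdms]; bilinear in both arguments and not symmetric
#' in general.
#' @param bra,ket coefficient vectors over `dspace` (same space).
#' @param dspace a `det_space`.
#' @return rank-6 array.
#' @export
transition_3rdm <- function(bra, ket, dspace) {
  if (length(bra) != dspace$n_det || length(ket) != dspace$n_det)
    stop("vector/space dimension mismatch")
  transition_rdms(bra, ket, dspace, max_rank = 3)$gamma3
}

#' Fock-contracted 4RDM via the transition-3RDM pathway
#'
#' Computes `A_pq,rs,tu = sum_vw f_vw Gamma4_pq,rs,tu,vw` (normal-ordered)
#' without ever forming the 4RDM, using
#' `e_pq,rs,tu E_vw = e_pq,rs,tu,vw + sum_j d_{v,q_j} e_(...q_j -> w...)`:
#' the transition 3RDM with `|F>` minus three f-contracted Gamma3 terms.
#'
#' @param C normalized coefficient vector.
#' @param dspace a `det_space`.
#' @param f_active symmetric active Fock block.
#' @param gamma3 optional precomputed Gamma3 of `C` (else computed).
#' @return rank-6 array `A[p,q,r,s,t,u]`.
#' @export
f_contracted_4rdm <- function(C, dspace, f_active, gamma3 = NULL) {
  n <- dspace$n_orb
  Fv <- build_f_state(C, dspace, f_active)
  Tt <- transition_3rdm(C, Fv, dspace)
  if (is.null(gamma3)) gamma3 <- transition_rdms(C, C, dspace, 3)$gamma3
  contract_slot <- function(g3, slot) {
    # sum_w f[q_slot, w] g3 with annihilation index of pair `slot` -> w
    perm <- switch(slot,
                   `1` = c(1, 3, 4, 5, 6, 2),
                   `2` = c(1, 2, 3, 5, 6, 4),
                   `3` = c(1, 2, 3, 4, 5, 6))
    gp <- aperm(g3, perm)              # annihilation slot moved last
    dim(gp) <- c(n^5, n)
    res <- gp %*% t(f_active)          # res[..., q_slot] = sum_w g3[..,w] f[q,w]
    dim(res) <- rep(n, 6)
    aperm(res, order(perm))            # restore original index order
  }
  Tt - contract_slot(gamma3, 1) - contract_slot(gamma3, 2) -
    contract_slot(gamma3, 3)
}

# ---- literal spin-orbital oracle ----

# sequential application of annihilation/creation to (amask, bmask) with
# fermionic ordering alpha_1..alpha_n beta_1..beta_n.
so_annihilate <- function(st, orb, spin) {
  if (!st$alive) return(st)
  m <- bitwShiftL(1L, orb - 1L)
  if (spin == 1L) {
    if (bitwAnd(st$a, m) == 0L) { st$alive <- FALSE; return(st) }
    below <- if (orb > 1) popcount(bitwAnd(st$a, m - 1L)) else 0L
    st$sign <- st$sign * (if (below %% 2L) -1 else 1)
    st$a <- bitwXor(st$a, m)
  } else {
    if (bitwAnd(st$b, m) == 0L) { st$alive <- FALSE; return(st) }
    below <- popcount(st$a) + (if (orb > 1) popcount(bitwAnd(st$b, m - 1L)) else 0L)
    st$sign <- st$sign * (if (below %% 2L) -1 else 1)
    st$b <- bitwXor(st$b, m)
  }
  st
}

so_create <- function(st, orb, spin) {
  if (!st$alive) return(st)
  m <- bitwShiftL(1L, orb - 1L)
  if (spin == 1L) {
    if (bitwAnd(st$a, m) != 0L) { st$alive <- FALSE; return(st) }
    below <- if (orb > 1) popcount(bitwAnd(st$a, m - 1L)) else 0L
    st$sign <- st$sign * (if (below %% 2L) -1 else 1)
    st$a <- bitwOr(st$a, m)
  } else {
    if (bitwAnd(st$b, m) != 0L) { st$alive <- FALSE; return(st) }
    below <- popcount(st$a) + (if (orb > 1) popcount(bitwAnd(st$b, m - 1L)) else 0L)
    st$sign <- st$sign * (if (below %% 2L) -1 else 1)
    st$b <- bitwOr(st$b, m)
  }
  st
}

# literal <bra| e_{P1..Pr} |ket> tensor by explicit second quantization:
# for each ket determinant, every ordered choice of r annihilated spin
# orbitals (chains fix the spins) and r creations of matching spin. Slow and
# simple on purpose: this is the convention-pinning oracle.
spinorb_erdm <- function(bra, ket, dspace, rank, f_active = NULL) {
  n <- dspace$n_orb
  if (rank == 4 && is.null(f_active))
    stop("rank-4 oracle only in Fock-contracted form")
  if (rank == 4 && n > 5) stop("spin-orbital rank-4 oracle limited to 5 orbitals")
  out_rank <- if (rank == 4) 3 else rank
  G <- array(0, rep(n, 2 * out_rank))
  spins_occ <- function(k) {
    rbind(cbind(dspace$occ_a[[k]], 1L),
          cbind(dspace$occ_b[[k]], 2L))
  }
  perms_of <- function(m) {
    if (m == 1) return(list(1L))
    out <- list()
    for (p in seq_len(m)) {
      v <- seq_len(m)[-p]
      for (rest in perms_of(m - 1)) out[[length(out) + 1L]] <- c(p, v[rest])
    }
    out
  }
  all_perms <- perms_of(rank)
  cre_grid <- as.matrix(expand.grid(rep(list(seq_len(n)), rank)))
  for (k in which(abs(ket) > 0)) {
    so <- spins_occ(k)
    nocc <- nrow(so)
    if (nocc < rank) next
    ann_sets <- utils::combn(nocc, rank, simplify = FALSE)
    for (aset in ann_sets) for (pm in all_perms) {
      ann <- so[aset[pm], , drop = FALSE]   # rows: chain 1..rank (q_i, spin_i)
      st0 <- list(a = dspace$alpha[k], b = dspace$beta[k], sign = 1, alive = TRUE)
      for (i in seq_len(rank)) st0 <- so_annihilate(st0, ann[i, 1], ann[i, 2])
      if (!st0$alive) next
      for (g_ in seq_len(nrow(cre_grid))) {
        st <- st0
        for (i in rev(seq_len(rank))) st <- so_create(st, cre_grid[g_, i], ann[i, 2])
        if (!st$alive) next
        j <- det_index(dspace, st$a, st$b)
        if (is.na(j) || bra[j] == 0) next
        contrib <- st$sign * bra[j] * ket[k]
        idx <- as.vector(rbind(cre_grid[g_, ], ann[, 1]))  # p1,q1,p2,q2,...
        if (rank == 4) {
          w <- f_active[idx[7], idx[8]]
          if (w != 0) {
            pos <- 1 + sum((idx[1:6] - 1) * n^(0:5))
            G[pos] <- G[pos] + w * contrib
          }
        } else {
          pos <- 1 + sum((idx - 1) * n^(seq_along(idx) - 1))
          G[pos] <- G[pos] + contrib
        }
      }
    }
  }
  G
}

#' Brute-force Fock-contracted 4RDM
#'
#' Independent oracle: assembles the normal-ordered rank-4 contribution by
#' literal spin-orbital operator application (every ordered annihilation
#' quadruple times every matching creation quadruple), contracting the last
#' chain with `f`. Refuses more than 5 active orbitals.
#'
#' @param C normalized coefficient vector.
#' @param dspace a `det_space`.
#' @param f_active symmetric active Fock block.
#' @return rank-6 array comparable to [f_contracted_4rdm].
#' @export
brute_force_f4rdm <- function(C, dspace, f_active) {
  if (dspace$n_orb > 5) stop("brute-force 4RDM limited to 5 active orbitals")
  spinorb_erdm(C, C, dspace, rank = 4, f_active = f_active)
}
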