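# Determinant representation and Slater-Condon algebra.
#
# A determinant is a pair of bitmasks (alpha, beta) over spatial orbitals,
# stored as R integers (31-bit limit; desk scale uses <= ~12 orbitals).
# Orbital p occupies bit p-1. The total order used everywhere is
# (alpha, beta) compared as unsigned integers, which makes every enumeration
# and tie-break reproducible.

.qcpt2_env <- new.env(parent = emptyenv())

.popcnt_tab <- function() {
  tab <- .qcpt2_env$popcnt
  if (is.null(tab)) {
    x <- 0:65535
    tab <- integer(65536)
    v <- x
    while (any(v > 0)) {
      tab <- tab + (v %% 2L)
      v <- v %/% 2L
    }
    .qcpt2_env$popcnt <- tab
  }
  tab
}

popcount <- function(x) {
  tab <- .popcnt_tab()
  tab[bitwAnd(x, 65535L) + 1L] + tab[bitwShiftR(x, 16L) + 1L]
}

bit_mask <- function(orbs) {
  if (!length(orbs)) return(0L)
  sum(bitwShiftL(1L, orbs - 1L))
}

bits_of <- function(mask, n_orb) which(bitwAnd(mask, bitwShiftL(1L, 0:(n_orb - 1L))) != 0L)

# number of set bits strictly between positions i and a (1-based orbitals)
bits_between <- function(mask, i, a) {
  lo <- min(i, a); hi <- max(i, a)
  if (hi - lo < 2) return(0L)
  seg <- bitwAnd(bitwShiftL(1L, hi - 1L) - 1L, bitwNot(bitwShiftL(1L, lo) - 1L))
  popcount(bitwAnd(mask, seg))
}

#' Enumerate a complete active space of determinants
#'
#' All determinants with `n_alpha` spin-up and `n_beta` spin-down electrons in
#' `n_orb` orbitals, optionally restricted to a target irrep (abelian XOR
#' product of occupied orbital labels). Determinants are sorted by
#' `(alpha, beta)` bitmasks ascending; the order is deterministic.
#'
#' @param n_orb number of (active) spatial orbitals (<= 31).
#' @param n_alpha,n_beta electron counts per spin.
#' @param orb_sym optional per-orbital irrep labels (1..8, Molpro convention).
#' @param isym optional target irrep; determinants of other irreps dropped.
#' @return object of class `det_space`: masks, sorted keys for O(log n)
#'   lookup, and cached occupation lists.
#' @export
enumerate_cas <- function(n_orb, n_alpha, n_beta, orb_sym = NULL, isym = NULL) {
  stopifnot(n_orb >= 1, n_orb <= 31, n_alpha >= 0, n_beta >= 0,
            n_alpha <= n_orb, n_beta <= n_orb)
  masks_of <- function(k) {
    if (k == 0) return(0L)
    combs <- utils::combn(n_orb, k)
    as.integer(colSums(matrix(bitwShiftL(1L, combs - 1L), nrow = k)))
  }
  am <- masks_of(n_alpha); bm <- masks_of(n_beta)
  alpha <- rep(am, each = length(bm))
  beta <- rep(bm, times = length(am))
  if (!is.null(isym) && !is.null(orb_sym)) {
    dsym <- vapply(seq_along(alpha), function(k) {
      occ <- c(bits_of(alpha[k], n_orb), bits_of(beta[k], n_orb))
      s <- 0L
      for (o in occ) s <- bitwXor(s, orb_sym[o] - 1L)
      s + 1L
    }, integer(1))
    keep <- dsym == isym
    alpha <- alpha[keep]; beta <- beta[keep]
  }
  key <- as.numeric(alpha) * 2^n_orb + as.numeric(beta)
  ord <- order(key)
  alpha <- alpha[ord]; beta <- beta[ord]; key <- key[ord]
  n_det <- length(alpha)
  occ_a <- lapply(seq_len(n_det), function(k) bits_of(alpha[k], n_orb))
  occ_b <- lapply(seq_len(n_det), function(k) bits_of(beta[k], n_orb))
  structure(list(n_orb = n_orb, n_alpha = as.integer(n_alpha),
                 n_beta = as.integer(n_beta), n_det = n_det,
                 alpha = alpha, beta = beta, key = key,
                 occ_a = occ_a, occ_b = occ_b),
            class = "det_space")
}

#' Locate determinants in a det_space
#'
#' Binary-search lookup of `(alpha, beta)` mask pairs; vectorized.
#' @param dspace a `det_space`.
#' @param alpha,beta integer bitmask vectors.
#' @return integer indices (NA where absent).
#' @export
det_index <- function(dspace, alpha, beta) {
  key <- as.numeric(alpha) * 2^dspace$n_orb + as.numeric(beta)
  pos <- findInterval(key, dspace$key)
  ok <- pos >= 1L & pos <= dspace$n_det
  out <- rep(NA_integer_, length(key))
  hit <- ok & dspace$key[pmax(pos, 1L)] == key
  out[hit] <- pos[hit]
  out
}

# ---- Slater-Condon matrix elements ----

sc_diagonal <- function(occa, occb, ints) {
  h <- ints$h; g <- ints$g
  e <- ints$e_core + sum(diag(h)[occa]) + sum(diag(h)[occb])
  same_spin <- function(occ) {
    if (length(occ) < 2) return(0)
    s <- 0
    for (i in occ) for (j in occ) s <- s + g[i, i, j, j] - g[i, j, j, i]
    s / 2
  }
  e <- e + same_spin(occa) + same_spin(occb)
  if (length(occa) && length(occb)) {
    for (i in occa) for (j in occb) e <- e + g[i, i, j, j]
  }
  e
}

# single excitation i -> a within spin sigma; occ_s = occupied (spatial) of
# that spin in the KET, occ_o = other spin occupation.
sc_single <- function(i, a, occ_s, occ_o, mask_s, ints) {
  v <- ints$h[a, i]
  for (j in occ_s) v <- v + ints$g[a, i, j, j] - ints$g[a, j, j, i]
  for (j in occ_o) v <- v + ints$g[a, i, j, j]
  sign <- if (bits_between(mask_s, i, a) %% 2L) -1 else 1
  sign * v
}

#' Slater-Condon matrix element between two determinants
#'
#' Full Hamiltonian matrix element `<D_i|H|D_j>` including the core energy on
#' the diagonal and fermionic parity in the sign; exactly zero beyond double
#' excitations.
#'
#' @param ai,bi alpha/beta masks of the bra determinant.
#' @param aj,bj alpha/beta masks of the ket determinant.
#' @param ints an [integral_set] over the same orbitals.
#' @param n_orb number of orbitals.
#' @return matrix element (Hartree).
#' @export
slater_condon <- function(ai, bi, aj, bj, ints, n_orb = ints$n_orb) {
  xa <- bitwXor(ai, aj); xb <- bitwXor(bi, bj)
  ra <- popcount(xa) %/% 2L; rb <- popcount(xb) %/% 2L
  rank <- ra + rb
  if (rank > 2L) return(0)
  occa <- bits_of(aj, n_orb); occb <- bits_of(bj, n_orb)
  if (rank == 0L) return(sc_diagonal(occa, occb, ints))
  g <- ints$g
  if (rank == 1L) {
    if (ra == 1L) {
      i <- bits_of(bitwAnd(xa, aj), n_orb); a <- bits_of(bitwAnd(xa, ai), n_orb)
      return(sc_single(i, a, occa, occb, aj, ints))
    } else {
      i <- bits_of(bitwAnd(xb, bj), n_orb); a <- bits_of(bitwAnd(xb, bi), n_orb)
      return(sc_single(i, a, occb, occa, bj, ints))
    }
  }
  # doubles
  if (ra == 1L && rb == 1L) {
    i <- bits_of(bitwAnd(xa, aj), n_orb); a <- bits_of(bitwAnd(xa, ai), n_orb)
    j <- bits_of(bitwAnd(xb, bj), n_orb); b <- bits_of(bitwAnd(xb, bi), n_orb)
    s <- (bits_between(aj, i, a) + bits_between(bj, j, b)) %% 2L
    return((if (s) -1 else 1) * g[a, i, b, j])
  }
  same_spin_double <- function(mask_j, x, mask_i) {
    holes <- bits_of(bitwAnd(x, mask_j), ints$n_orb)   # i < j
    parts <- bits_of(bitwAnd(x, mask_i), ints$n_orb)   # a < b
    i <- holes[1]; j <- holes[2]; a <- parts[1]; b <- parts[2]
    # apply i->a then j->b with intermediate mask
    s1 <- bits_between(mask_j, i, a)
    m1 <- bitwXor(mask_j, bitwOr(bitwShiftL(1L, i - 1L), bitwShiftL(1L, a - 1L)))
    s2 <- bits_between(m1, j, b)
    sgn <- if ((s1 + s2) %% 2L) -1 else 1
    sgn * (g[a, i, b, j] - g[b, i, a, j])
  }
  if (ra == 2L) return(same_spin_double(aj, xa, ai))
  same_spin_double(bj, xb, bi)
}

# ---- connection enumeration ----

# all single/double excitations of determinant k within the space, with H
# values; returns list(idx=..., h=...) over determinants PRESENT in dspace.
det_connections <- function(dspace, k, ints, screen = 0) {
  n <- dspace$n_orb
  aj <- dspace$alpha[k]; bj <- dspace$beta[k]
  occa <- dspace$occ_a[[k]]; occb <- dspace$occ_b[[k]]
  vira <- setdiff(seq_len(n), occa); virb <- setdiff(seq_len(n), occb)
  am <- integer(0); bm <- integer(0)
  # singles alpha / beta
  for (i in occa) for (a in vira) {
    am <- c(am, bitwXor(aj, bitwOr(bitwShiftL(1L, i - 1L), bitwShiftL(1L, a - 1L))))
    bm <- c(bm, bj)
  }
  for (i in occb) for (a in virb) {
    am <- c(am, aj)
    bm <- c(bm, bitwXor(bj, bitwOr(bitwShiftL(1L, i - 1L), bitwShiftL(1L, a - 1L))))
  }
  # doubles aa
  if (length(occa) >= 2 && length(vira) >= 2) {
    for (i1 in seq_along(occa)) for (i2 in seq_len(i1 - 1L))
      for (a1 in seq_along(vira)) for (a2 in seq_len(a1 - 1L)) {
        m <- bitwXor(aj, bit_mask(c(occa[i1], occa[i2], vira[a1], vira[a2])))
        am <- c(am, m); bm <- c(bm, bj)
      }
  }
  if (length(occb) >= 2 && length(virb) >= 2) {
    for (i1 in seq_along(occb)) for (i2 in seq_len(i1 - 1L))
      for (a1 in seq_along(virb)) for (a2 in seq_len(a1 - 1L)) {
        m <- bitwXor(bj, bit_mask(c(occb[i1], occb[i2], virb[a1], virb[a2])))
        am <- c(am, aj); bm <- c(bm, m)
      }
  }
  # doubles ab
  for (i in occa) for (a in vira) for (j in occb) for (b in virb) {
    am <- c(am, bitwXor(aj, bit_mask(c(i, a))))
    bm <- c(bm, bitwXor(bj, bit_mask(c(j, b))))
  }
  idx <- det_index(dspace, am, bm)
  keep <- !is.na(idx)
  idx <- idx[keep]; am <- am[keep]; bm <- bm[keep]
  h <- vapply(seq_along(idx), function(q)
    slater_condon(am[q], bm[q], aj, bj, ints), 0)
  keep2 <- abs(h) > screen
  list(idx = idx[keep2], h = h[keep2])
}

#' Hamiltonian connections of a determinant
#'
#' Enumerates all single and double excitations of determinant `k` that lie
#' in `dspace`, returning those with `|H| >` `screen` (no duplicates,
#' consistent with [slater_condon]). `screen = Inf` yields nothing.
#'
#' @param dspace a `det_space`.
#' @param k determinant index.
#' @param ints an [integral_set].
#' @param screen magnitude threshold.
#' @return list with `idx` (indices into `dspace`) and `h` (matrix elements).
#' @export
connections <- function(dspace, k, ints, screen = 0) {
  if (is.infinite(screen)) return(list(idx = integer(0), h = numeric(0)))
  det_connections(dspace, k, ints, screen)
}

#' Sparse Hamiltonian over an enumerated determinant space
#'
#' Builds the full symmetric CI matrix (as a `dgCMatrix`) via excitation
#' enumeration; intended for desk-scale spaces (guarded at 20k determinants).
#'
#' @param dspace a `det_space`.
#' @param ints an [integral_set].
#' @param screen drop off-diagonal elements with `|H| <= screen`.
#' @return sparse symmetric matrix of dimension `n_det`.
#' @export
build_hamiltonian <- function(dspace, ints, screen = 0) {
  nd <- dspace$n_det
  if (nd > 20000) stop("determinant space too large for dense enumeration")
  ii <- vector("list", nd); jj <- vector("list", nd); vv <- vector("list", nd)
  diagv <- vapply(seq_len(nd), function(k)
    sc_diagonal(dspace$occ_a[[k]], dspace$occ_b[[k]], ints), 0)
  for (k in seq_len(nd)) {
    cn <- det_connections(dspace, k, ints, screen)
    ii[[k]] <- cn$idx; jj[[k]] <- rep.int(k, length(cn$idx)); vv[[k]] <- cn$h
  }
  Matrix::sparseMatrix(i = c(unlist(ii), seq_len(nd)),
                       j = c(unlist(jj), seq_len(nd)),
                       x = c(unlist(vv), diagv),
                       dims = c(nd, nd))
}

# ---- spin-free excitation operators ----

#' Matrix of a spin-free singlet excitation operator
#'
#' Sparse representation of `E_pq = sum_sigma a+_p,sigma a_q,sigma` on the
#' determinant space, with fermionic parity. `E_pp` is the (spin-summed)
#' number operator of orbital `p`.
#'
#' @param dspace a `det_space`.
#' @param p,q orbital indices (1-based, within the space's orbitals).
#' @return sparse `n_det x n_det` matrix with `[i, j] = <D_i|E_pq|D_j>`.
#' @export
spinfree_op <- function(dspace, p, q) {
  nd <- dspace$n_det
  if (p == q) {
    occ <- vapply(seq_len(nd), function(k)
      (p %in% dspace$occ_a[[k]]) + (p %in% dspace$occ_b[[k]]), 0)
    return(Matrix::sparseMatrix(i = which(occ != 0), j = which(occ != 0),
                                x = occ[occ != 0], dims = c(nd, nd)))
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  pm <- bitwShiftL(1L, p - 1L); qm <- bitwShiftL(1L, q - 1L)
  for (k in seq_len(nd)) {
    a <- dspace$alpha[k]; b <- dspace$beta[k]
    # alpha branch
    if (bitwAnd(a, qm) != 0L && bitwAnd(a, pm) == 0L) {
      a2 <- bitwXor(a, bitwOr(pm, qm))
      t_ <- det_index(dspace, a2, b)
      if (!is.na(t_)) {
        s <- if (bits_between(a, q, p) %% 2L) -1 else 1
        ii <- c(ii, t_); jj <- c(jj, k); xx <- c(xx, s)
      }
    }
    # beta branch
    if (bitwAnd(b, qm) != 0L && bitwAnd(b, pm) == 0L) {
      b2 <- bitwXor(b, bitwOr(pm, qm))
      t_ <- det_index(dspace, a, b2)
      if (!is.na(t_)) {
        s <- if (bits_between(b, q, p) %% 2L) -1 else 1
        ii <- c(ii, t_); jj <- c(jj, k); xx <- c(xx, s)
      }
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nd, nd))
}

# all E_pq matrices, cached on the dspace via an attribute-free memo keyed by
# the space's identity in the package environment.
spinfree_ops <- function(dspace) {
  key <- paste0("Eops_", dspace$n_orb, "_", dspace$n_alpha, "_",
                dspace$n_beta, "_", dspace$n_det, "_",
                format(sum(dspace$key), digits = 17))
  memo <- .qcpt2_env[[key]]
  if (!is.null(memo)) return(memo)
  n <- dspace$n_orb
  ops <- vector("list", n * n)
  for (p in seq_len(n)) for (q in seq_len(n))
    ops[[(q - 1L) * n + p]] <- spinfree_op(dspace, p, q)
  .qcpt2_env[[key]] <- ops
  ops
}

get_Eop <- function(ops, n, p, q) ops[[(q - 1L) * n + p]]

#' Apply a spin-free excitation to a CI vector
#'
#' Returns `E_pq |psi>` as a coefficient vector over the same space.
#' @param vec numeric coefficient vector over `dspace`.
#' @param dspace a `det_space`.
#' @param p,q orbital indices.
#' @return numeric vector.
#' @export
apply_spinfree_excitation <- function(vec, dspace, p, q) {
  n <- dspace$n_orb
  if (p < 1 || q < 1 || p > n || q > n) stop("orbital index outside space")
  as.numeric(spinfree_op(dspace, p, q) %*% vec)
}
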