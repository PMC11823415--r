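#' Electronic Hamiltonian container
#'
#' Bundles the core energy, one-electron integrals `h[p,q]` and two-electron
#' integrals `g[p,q,r,s] = (pq|rs)` (chemist notation, real orbitals, full
#' 8-fold permutational symmetry) that define a second-quantized Hamiltonian
#'
#' \deqn{H = E_core + \sum_{pq} h_{pq} E_{pq} + \tfrac12 \sum_{pqrs} (pq|rs)\, e_{pq,rs}}
#'
#' with \eqn{E_{pq}} the spin-free singlet excitation operator and
#' \eqn{e_{pq,rs} = E_{pq}E_{rs} - \delta_{qr}E_{ps}}.
#'
#' Externally (FCIDUMP) indices are 1-based, matching the internal R
#' convention, so no off-by-one mapping exists anywhere in the package.
#'
#' @param n_orb number of spatial orbitals.
#' @param e_core scalar core (frozen/nuclear) energy in Hartree.
#' @param h `n_orb x n_orb` symmetric matrix of one-electron integrals.
#' @param g 4-dimensional array `(pq|rs)`; may be given with only one symmetry
#'   representative filled, full symmetrization is applied.
#' @param orb_sym integer irrep label per orbital (1 = totally symmetric).
#' @return an object of class `integral_set`.
#' @export
integral_set <- function(n_orb, e_core = 0, h = NULL, g = NULL, orb_sym = NULL) {
  n_orb <- as.integer(n_orb)
  if (is.null(h)) h <- matrix(0, n_orb, n_orb)
  if (is.null(g)) g <- array(0, c(n_orb, n_orb, n_orb, n_orb))
  if (is.null(orb_sym)) orb_sym <- rep(1L, n_orb)
  stopifnot(nrow(h) == n_orb, ncol(h) == n_orb, all(dim(g) == n_orb),
            length(orb_sym) == n_orb)
  if (!all(is.finite(h)) || !all(is.finite(g)) || !is.finite(e_core))
    stop("integral_set: non-finite values")
  h <- (h + t(h)) / 2
  g <- symmetrize_g(g)
  structure(list(n_orb = n_orb, e_core = as.numeric(e_core), h = h, g = g,
                 orb_sym = as.integer(orb_sym)),
            class = "integral_set")
}

# average over the 8 permutations (pq|rs)=(qp|rs)=(pq|sr)=(rs|pq)...
symmetrize_g <- function(g) {
  g <- (g + aperm(g, c(2, 1, 3, 4))) / 2
  g <- (g + aperm(g, c(1, 2, 4, 3))) / 2
  g <- (g + aperm(g, c(3, 4, 1, 2))) / 2
  g
}

#' Validate integral_set invariants
#'
#' Checks symmetry of `h`, 8-fold symmetry of `g`, and finiteness.
#' @param ints an `integral_set`.
#' @param tol tolerance for symmetry deviations.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_integral_set <- function(ints, tol = 1e-10) {
  stopifnot(inherits(ints, "integral_set"))
  if (max(abs(ints$h - t(ints$h))) > tol) stop("h not symmetric")
  g <- ints$g
  dev <- max(abs(g - aperm(g, c(2, 1, 3, 4))),
             abs(g - aperm(g, c(1, 2, 4, 3))),
             abs(g - aperm(g, c(3, 4, 1, 2))))
  if (dev > tol) stop("g lacks 8-fold symmetry")
  invisible(TRUE)
}

#' Partition of the orbital space
#'
#' Defines the inactive (doubly occupied), active and virtual (empty) orbital
#' index lists of a CAS calculation, together with electron count and spin
#' projection.
#'
#' @param inactive,active,virtual 1-based orbital index vectors; together they
#'   must partition `1..n_orb` disjointly.
#' @param n_elec total electron count.
#' @param ms2 two times the spin projection Sz (default 0).
#' @return an object of class `orbital_space` with derived field `n_act_elec`.
#' @export
orbital_space <- function(inactive = integer(0), active = integer(0),
                          virtual = integer(0), n_elec, ms2 = 0L) {
  inactive <- as.integer(inactive); active <- as.integer(active)
  virtual <- as.integer(virtual)
  all_idx <- sort(c(inactive, active, virtual))
  n_orb <- length(all_idx)
  if (!identical(all_idx, seq_len(n_orb)))
    stop("inactive/active/virtual must partition 1..n_orb disjointly")
  n_act_elec <- as.integer(n_elec - 2L * length(inactive))
  if (n_act_elec < 0 || n_act_elec > 2L * length(active))
    stop("infeasible active electron count: ", n_act_elec)
  if (abs(ms2) > n_act_elec || (n_act_elec - ms2) %% 2 != 0)
    stop("infeasible ms2 for active electron count")
  structure(list(inactive = inactive, active = active, virtual = virtual,
                 n_elec = as.integer(n_elec), ms2 = as.integer(ms2),
                 n_act_elec = n_act_elec, n_orb = n_orb),
            class = "orbital_space")
}

#' Read an FCIDUMP file
#'
#' Parses the plain-text integral interchange format: a `&FCI` namelist header
#' with `NORB`, `NELEC`, `MS2`, `ORBSYM`, `ISYM`, followed by lines
#' `value i j k l` (1-based). Lines with `i=j=k=l=0` carry the core energy,
#' `k=l=0` one-electron integrals, the rest `(ij|kl)` in chemist notation.
#' All 8 symmetry-equivalent index permutations are resolved to one value;
#' duplicated entries must agree to `1e-10`.
#'
#' @param path file path.
#' @return list with elements `ints` (an [integral_set]) and header metadata
#'   `n_elec`, `ms2`, `isym`, `orb_sym`.
#' @export
read_fcidump <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr_end <- grep("^\\s*(&END|/)\\s*$", lines)[1]
  if (is.na(hdr_end)) stop("malformed FCIDUMP header: no &END or / terminator")
  hdr <- paste(lines[seq_len(hdr_end)], collapse = " ")
  if (!grepl("&FCI", hdr)) stop("malformed FCIDUMP header: missing &FCI")
  get_int <- function(key, default = NA_integer_) {
    m <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*(-?[0-9]+)"), hdr))[[1]]
    if (length(m) < 2) default else as.integer(m[2])
  }
  n_orb <- get_int("NORB")
  if (is.na(n_orb)) stop("malformed FCIDUMP header: NORB missing")
  n_elec <- get_int("NELEC")
  ms2 <- get_int("MS2", 0L)
  isym <- get_int("ISYM", 1L)
  m <- regmatches(hdr, regexec("ORBSYM\\s*=\\s*([0-9, ]+)", hdr))[[1]]
  orb_sym <- if (length(m) >= 2) {
    as.integer(strsplit(gsub("\\s", "", m[2]), ",")[[1]])[seq_len(n_orb)]
  } else rep(1L, n_orb)
  orb_sym[is.na(orb_sym)] <- 1L

  body <- lines[-seq_len(hdr_end)]
  body <- body[nzchar(trimws(body))]
  h <- matrix(NA_real_, n_orb, n_orb)
  g <- array(NA_real_, c(n_orb, n_orb, n_orb, n_orb))
  e_core <- 0
  if (length(body)) {
    toks <- strsplit(trimws(body), "\\s+")
    val <- vapply(toks, function(x) as.numeric(x[1]), 0)
    idx <- t(vapply(toks, function(x) as.integer(x[2:5]), integer(4)))
    if (any(is.na(val)) || any(is.na(idx))) stop("malformed FCIDUMP body line")
    if (any(idx > n_orb)) stop("orbital index exceeds NORB")
    for (k in seq_along(val)) {
      i <- idx[k, 1]; j <- idx[k, 2]; l <- idx[k, 3]; m4 <- idx[k, 4]
      if (i == 0 && j == 0 && l == 0 && m4 == 0) {
        e_core <- val[k]
      } else if (l == 0 && m4 == 0) {
        if (i == 0 || j == 0) stop("malformed one-electron index line")
        set_h <- function(a, b) {
          if (!is.na(h[a, b]) && abs(h[a, b] - val[k]) > 1e-10)
            stop("inconsistent duplicate h(", a, ",", b, ")")
          h[a, b] <<- val[k]
        }
        set_h(i, j); set_h(j, i)
      } else {
        if (i == 0 || j == 0 || l == 0 || m4 == 0)
          stop("malformed two-electron index line")
        perms <- unique(list(c(i, j, l, m4), c(j, i, l, m4), c(i, j, m4, l),
                             c(j, i, m4, l), c(l, m4, i, j), c(m4, l, i, j),
                             c(l, m4, j, i), c(m4, l, j, i)))
        for (p in perms) {
          old <- g[p[1], p[2], p[3], p[4]]
          if (!is.na(old) && abs(old - val[k]) > 1e-10)
            stop("inconsistent duplicate g(", paste(p, collapse = ","), ")")
          g[p[1], p[2], p[3], p[4]] <- val[k]
        }
      }
    }
  }
  h[is.na(h)] <- 0
  g[is.na(g)] <- 0
  list(ints = integral_set(n_orb, e_core, h, g, orb_sym),
       n_elec = n_elec, ms2 = ms2, isym = isym, orb_sym = orb_sym)
}

#' Write an FCIDUMP file
#'
#' Emits one canonical symmetry representative per unique integral value
#' (indices `i>=j`, `k>=l`, `(i,j) >= (k,l)`), dropping entries below
#' `1e-12` in magnitude. Values are printed with 16 significant digits so a
#' read/write round trip is value-exact to ~1e-14 relative.
#'
#' @param ints an [integral_set].
#' @param space an [orbital_space] (supplies NELEC/MS2 header fields) or NULL.
#' @param path output path.
#' @param n_elec,ms2 overrides used when `space` is NULL.
#' @return the path, invisibly.
#' @export
write_fcidump <- function(ints, space = NULL, path, n_elec = NULL, ms2 = NULL) {
  validate_integral_set(ints, tol = 1e-8)
  n <- ints$n_orb
  if (!is.null(space)) { n_elec <- space$n_elec; ms2 <- space$ms2 }
  if (is.null(n_elec)) n_elec <- 0L
  if (is.null(ms2)) ms2 <- 0L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("&FCI NORB=%d,NELEC=%d,MS2=%d,", n, n_elec, ms2),
    sprintf("  ORBSYM=%s,", paste0(ints$orb_sym, collapse = ",")),
    "  ISYM=1,",
    " &END"), con)
  fmt <- function(v, i, j, k, l) sprintf("%23.16E %4d %4d %4d %4d", v, i, j, k, l)
  out <- character(0)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    ij <- i * (i - 1) / 2 + j
    for (k in seq_len(i)) for (l in seq_len(k)) {
      kl <- k * (k - 1) / 2 + l
      if (kl > ij) next
      v <- ints$g[i, j, k, l]
      if (abs(v) >= 1e-12) out <- c(out, fmt(v, i, j, k, l))
    }
  }
  for (i in seq_len(n)) for (j in seq_len(i)) {
    v <- ints$h[i, j]
    if (abs(v) >= 1e-12) out <- c(out, fmt(v, i, j, 0, 0))
  }
  out <- c(out, fmt(ints$e_core, 0, 0, 0, 0))
  writeLines(out, con)
  invisible(path)
}

#' Hubbard chain Hamiltonian
#'
#' Nearest-neighbour hopping `-t` and on-site repulsion `U` in the site basis:
#' `h[p,p+1] = -t`, `(pp|pp) = U`, everything else zero. A standard strongly
#' correlated stand-in for transition-metal active spaces at desk scale.
#'
#' @param L number of sites (>= 2).
#' @param t hopping amplitude.
#' @param U on-site repulsion.
#' @param boundary `"open"` or `"periodic"`.
#' @return an [integral_set] over `L` orbitals.
#' @export
make_hubbard <- function(L, t = 1, U = 4, boundary = c("open", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(L >= 2)
  h <- matrix(0, L, L)
  for (p in seq_len(L - 1)) h[p, p + 1] <- h[p + 1, p] <- -t
  if (boundary == "periodic" && L > 2) h[1, L] <- h[L, 1] <- -t
  g <- array(0, c(L, L, L, L))
  for (p in seq_len(L)) g[p, p, p, p] <- U
  integral_set(L, 0, h, g)
}

#' Random symmetric two-body Hamiltonian fixture
#'
#' Draws reproducible random one- and two-electron integrals, imposes exact
#' 8-fold symmetry, and adds a diagonally dominant one-electron part so that
#' spectra stay bounded and ground states are non-degenerate in practice.
#'
#' @param n_orb number of orbitals (intended <= 10, oracle scale).
#' @param seed RNG seed.
#' @param scale magnitude of the random two-body part.
#' @return an [integral_set].
#' @export
make_random_twobody <- function(n_orb, seed = 1, scale = 0.2) {
  stopifnot(n_orb <= 12)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  h <- matrix(stats::rnorm(n_orb^2, sd = scale), n_orb, n_orb)
  h <- (h + t(h)) / 2
  diag(h) <- diag(h) + seq(-1, 1, length.out = n_orb)  # spread, diagonal dominance
  g <- array(stats::rnorm(n_orb^4, sd = scale), rep(n_orb, 4))
  g <- symmetrize_g(g)
  # make the Coulomb-like diagonal repulsive so spectra are bounded below
  for (p in seq_len(n_orb)) g[p, p, p, p] <- abs(g[p, p, p, p]) + scale
  integral_set(n_orb, e_core = 0.1, h, g)
}

# ---- minimal-basis H2 (STO-3G, s functions only), closed-form Gaussians ----

.sto3g_h_exp <- c(3.42525091, 0.62391373, 0.16885540)
.sto3g_coef <- c(0.15432897, 0.53532814, 0.44463454)

boys_f0 <- function(x) ifelse(x < 1e-12, 1 - x / 3,
                              0.5 * sqrt(pi / x) * erf_local(sqrt(x)))
erf_local <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Minimal-basis H2 integrals
#'
#' Computes the STO-3G integrals of H2 at internuclear distance `r_bohr`
#' using the closed-form s-type Gaussian formulas (overlap, kinetic,
#' nuclear attraction, repulsion via the Boys function), forms the two
#' symmetry-determined molecular orbitals (g/u combinations, no SCF needed),
#' and returns MO-basis integrals plus the generator's own independent
#' full-CI ground-state energy from the analytic 2x2 singlet secular problem.
#'
#' @param r_bohr bond length in Bohr (0.74 Angstrom = 1.3984 Bohr).
#' @return list: `ints` (an [integral_set], 2 orbitals), `e_fci` (generator's
#'   own FCI ground-state energy), `e_hf` (restricted HF energy).
#' @export
make_h2_sto3g <- function(r_bohr = 1.39839733) {
  a <- .sto3g_h_exp; d <- .sto3g_coef
  # normalized primitive coefficients
  dn <- d * (2 * a / pi)^0.75
  centers <- c(0, r_bohr)
  sij <- tij <- vij <- matrix(0, 2, 2)
  for (A in 1:2) for (B in 1:2) {
    RA <- centers[A]; RB <- centers[B]; R2 <- (RA - RB)^2
    for (i in 1:3) for (j in 1:3) {
      p <- a[i] + a[j]; mu <- a[i] * a[j] / p
      pre <- dn[i] * dn[j] * (pi / p)^1.5 * exp(-mu * R2)
      sij[A, B] <- sij[A, B] + pre
      tij[A, B] <- tij[A, B] + pre * mu * (3 - 2 * mu * R2)
      Pc <- (a[i] * RA + a[j] * RB) / p
      for (C in 1:2) {
        x <- p * (Pc - centers[C])^2
        vij[A, B] <- vij[A, B] - dn[i] * dn[j] * (2 * pi / p) *
          exp(-mu * R2) * boys_f0(x)
      }
    }
  }
  eri <- array(0, c(2, 2, 2, 2))
  for (A in 1:2) for (B in 1:2) for (C in 1:2) for (D in 1:2) {
    RA <- centers[A]; RB <- centers[B]; RC <- centers[C]; RD <- centers[D]
    v <- 0
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
      p <- a[i] + a[j]; q <- a[k] + a[l]
      Pp <- (a[i] * RA + a[j] * RB) / p; Qq <- (a[k] * RC + a[l] * RD) / q
      pre <- dn[i] * dn[j] * dn[k] * dn[l] *
        2 * pi^2.5 / (p * q * sqrt(p + q)) *
        exp(-a[i] * a[j] / p * (RA - RB)^2 - a[k] * a[l] / q * (RC - RD)^2)
      v <- v + pre * boys_f0(p * q / (p + q) * (Pp - Qq)^2)
    }
    eri[A, B, C, D] <- v
  }
  hcore <- tij + vij
  s12 <- sij[1, 2]
  # symmetry MOs: sigma_g, sigma_u
  cg <- 1 / sqrt(2 * (1 + s12)); cu <- 1 / sqrt(2 * (1 - s12))
  U <- cbind(c(cg, cg), c(cu, -cu))
  h_mo <- t(U) %*% hcore %*% U
  K <- kronecker(U, U)
  gm <- eri; dim(gm) <- c(4, 4)
  g_mo <- t(K) %*% gm %*% K
  dim(g_mo) <- c(2, 2, 2, 2)
  e_nuc <- 1 / r_bohr
  ints <- integral_set(2, e_nuc, h_mo, g_mo)
  # independent FCI: 2x2 secular problem in {|1a 1b>, |2a 2b>}
  h11 <- 2 * h_mo[1, 1] + g_mo[1, 1, 1, 1]
  h22 <- 2 * h_mo[2, 2] + g_mo[2, 2, 2, 2]
  h12 <- g_mo[1, 2, 1, 2]
  e_fci <- (h11 + h22) / 2 - sqrt(((h11 - h22) / 2)^2 + h12^2) + e_nuc
  list(ints = ints, e_fci = e_fci, e_hf = h11 + e_nuc)
}

# ---- generalized Fock / pseudocanonical orbitals ----

#' Generalized Fock matrix
#'
#' Builds \eqn{f_{pq} = h_{pq} + \sum_{rs} D_{rs}[(pq|rs) - (pr|sq)/2]}
#' where the effective one-particle density `D` is `2 I` on the inactive
#' orbitals and the active 1RDM on the active orbitals. This is the
#' zeroth-order (unperturbed) one-body operator of CASPT2; for an empty
#' active space it reduces to the restricted closed-shell Fock matrix.
#'
#' @param ints an [integral_set].
#' @param gamma1 active-space 1RDM (`n_act x n_act`, over `space$active`).
#' @param space an [orbital_space].
#' @return object of class `fock_matrix`: list(`f`, `basis_tag`).
#' @export
build_generalized_fock <- function(ints, gamma1, space) {
  n <- ints$n_orb
  act <- space$active
  if (length(act)) {
    if (abs(sum(diag(as.matrix(gamma1))) - space$n_act_elec) > 1e-8)
      stop("gamma1 trace != active electron count")
    if (max(abs(gamma1 - t(gamma1))) > 1e-8) stop("gamma1 not symmetric")
  }
  D <- matrix(0, n, n)
  if (length(space$inactive)) diag(D)[space$inactive] <- 2
  if (length(act)) D[act, act] <- gamma1
  gmat <- ints$g; dim(gmat) <- c(n * n, n * n)       # [(p,q),(r,s)] chemist
  J <- matrix(gmat %*% as.vector(D), n, n)           # sum_rs (pq|rs) D_rs
  Kx <- matrix(0, n, n)                              # sum_rs (pr|sq) D_rs
  for (p in seq_len(n)) {
    Kx[p, ] <- vapply(seq_len(n), function(q) sum(ints$g[p, , , q] * D), 0)
  }
  f <- ints$h + J - 0.5 * Kx
  f <- (f + t(f)) / 2
  structure(list(f = f, basis_tag = "general"), class = "fock_matrix")
}

#' Rotate to pseudocanonical orbitals
#'
#' Diagonalizes the inactive-inactive, active-active and virtual-virtual
#' blocks of the generalized Fock matrix separately, applies the resulting
#' block-orthogonal rotation to the integrals, and returns orbital energies.
#' Within each block eigenvalues are sorted ascending; eigenvector signs are
#' fixed (largest-magnitude component positive) and exact degeneracies are
#' tie-broken by lexicographic comparison of absolute eigenvector components,
#' making the rotation deterministic.
#'
#' @param ints an [integral_set].
#' @param fock a `fock_matrix` from [build_generalized_fock].
#' @param space an [orbital_space].
#' @return list: `ints` (rotated), `rotation` (orthogonal `n x n`), `eps`
#'   (orbital energies, full length), `fock` (rotated Fock, tagged
#'   `pseudocanonical`).
#' @export
pseudocanonicalize <- function(ints, fock, space) {
  n <- ints$n_orb
  U <- diag(n)
  eps <- rep(NA_real_, n)
  for (blk in list(space$inactive, space$active, space$virtual)) {
    if (!length(blk)) next
    eg <- eigen(fock$f[blk, blk, drop = FALSE], symmetric = TRUE)
    ord <- order(eg$values)
    vals <- eg$values[ord]; vecs <- eg$vectors[, ord, drop = FALSE]
    # deterministic signs and degenerate tie-break
    for (k in seq_along(vals)) {
      v <- vecs[, k]
      if (v[which.max(abs(v))] < 0) vecs[, k] <- -v
    }
    k <- 1
    while (k < length(vals)) {
      if (abs(vals[k + 1] - vals[k]) < 1e-12) {
        j <- k + 1
        while (j < length(vals) && abs(vals[j + 1] - vals[k]) < 1e-12) j <- j + 1
        sub <- vecs[, k:j, drop = FALSE]
        keyord <- do.call(order, as.data.frame(t(-abs(sub))))
        vecs[, k:j] <- sub[, keyord]
        k <- j + 1
      } else k <- k + 1
    }
    U[blk, blk] <- vecs
    eps[blk] <- vals
  }
  ri <- rotate_integrals(ints, U)
  fr <- t(U) %*% fock$f %*% U
  fr <- (fr + t(fr)) / 2
  list(ints = ri, rotation = U,
       eps = diag(fr),
       fock = structure(list(f = fr, basis_tag = "pseudocanonical"),
                        class = "fock_matrix"))
}

#' Apply an orbital rotation to an integral set
#'
#' Four-index transforms `g` and two-index transforms `h` by the (orthogonal)
#' matrix `U` whose columns are the new orbitals.
#' @param ints an [integral_set].
#' @param U rotation matrix.
#' @return rotated [integral_set].
#' @export
rotate_integrals <- function(ints, U) {
  n <- ints$n_orb
  if (max(abs(t(U) %*% U - diag(n))) > 1e-12) stop("rotation not orthogonal")
  h2 <- t(U) %*% ints$h %*% U
  K <- kronecker(U, U)   # row (q-1)*n+p maps pair (p,q), matches R flattening
  gm <- ints$g; dim(gm) <- c(n * n, n * n)
  g2 <- t(K) %*% gm %*% K
  dim(g2) <- c(n, n, n, n)
  integral_set(n, ints$e_core, h2, g2, ints$orb_sym)
}

#' Fold the inactive orbitals into an active-space Hamiltonian
#'
#' Returns the effective Hamiltonian over the active orbitals only:
#' `e_core` absorbs the closed-shell inactive energy, `h` gains the inactive
#' Coulomb/exchange field, `g` is the active-block slice. CAS-CI /
#' FCIQMC dynamics run on this object.
#'
#' @param ints an [integral_set] over all orbitals.
#' @param space an [orbital_space].
#' @return an [integral_set] over `length(space$active)` orbitals.
#' @export
active_hamiltonian <- function(ints, space) {
  ia <- space$inactive; act <- space$active
  e <- ints$e_core
  if (length(ia)) {
    e <- e + 2 * sum(diag(ints$h)[ia])
    for (i in ia) for (j in ia)
      e <- e + 2 * ints$g[i, i, j, j] - ints$g[i, j, j, i]
  }
  na <- length(act)
  h <- ints$h[act, act, drop = FALSE]
  if (length(ia) && na) {
    for (ti in seq_len(na)) for (ui in seq_len(na)) {
      t_ <- act[ti]; u_ <- act[ui]
      h[ti, ui] <- h[ti, ui] +
        sum(vapply(ia, function(i) 2 * ints$g[t_, u_, i, i] - ints$g[t_, i, i, u_], 0))
    }
  }
  g <- ints$g[act, act, act, act, drop = FALSE]
  dim(g) <- c(na, na, na, na)
  integral_set(na, e, h, g, ints$orb_sym[act])
}

#' CAS reference energy from RDMs
#'
#' \eqn{E = E_{core}^{eff} + \sum_{tu} h^{eff}_{tu}\Gamma^{(1)}_{tu}
#'   + \tfrac12 \sum_{tuvx}(tu|vx)\Gamma^{(2)}_{tu,vx}}
#' evaluated with the inactive-folded active Hamiltonian.
#'
#' @param ints full-space [integral_set].
#' @param space an [orbital_space].
#' @param gamma1,gamma2 active-space spin-free RDMs (normal-ordered).
#' @return scalar energy (Hartree).
#' @export
cas_energy_from_rdms <- function(ints, space, gamma1, gamma2) {
  ha <- active_hamiltonian(ints, space)
  na <- ha$n_orb
  e <- ha$e_core
  if (na) {
    e <- e + sum(ha$h * gamma1)
    e <- e + 0.5 * sum(ha$g * gamma2)
  }
  e
}
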