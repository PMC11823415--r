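# Generic evaluation of <psi| E_{p1 q1} E_{p2 q2} ... |psi> for a
# closed-shell-inactive x CAS x empty-virtual reference, consuming only the
# active-space RDMs (Gamma1-3) and, where a Fock-contracted pair appears,
# the F.4RDM. This is the workhorse behind the internally contracted CASPT2
# matrices: no per-class formulas are transcribed; inactive and virtual
# indices are eliminated by exact commutator algebra,
#
#   E_ab E_cd = E_cd E_ab + d_bc E_ad - d_da E_cb ,
#
# and the surviving pure-active operator string is reduced to normal-ordered
# e-operators via E_ab e_{...} = e_{ab,...} + sum_j d_{b,c_j} e_{...(a,d_j)...},
# whose expectations are the stored RDM tensors.
#
# One operator pair may be "symbolic" (sentinels -1, -2 in its two slots),
# representing sum_{vw in active} f_vw E_vw. Deltas that touch a symbolic
# slot fix the corresponding f index; a surviving intact symbolic pair at
# rank 4 is exactly an element of the F.4RDM. This is how the B matrices
# consume at most the Fock-contracted 4RDM while S and V consume at most
# Gamma3.

# context constructor: spc[o] in {1 inactive, 2 active, 3 virtual};
# act_pos[o] = position of global orbital o within the active list.
wick_context <- function(space, gamma1, gamma2, gamma3, f_active = NULL,
                         f4 = NULL) {
  n <- space$n_orb
  spc <- integer(n)
  spc[space$inactive] <- 1L; spc[space$active] <- 2L; spc[space$virtual] <- 3L
  act_pos <- integer(n)
  act_pos[space$active] <- seq_along(space$active)
  list(spc = spc, act_pos = act_pos, n_act = length(space$active),
       g1 = gamma1, g2 = gamma2, g3 = gamma3, f = f_active, f4 = f4,
       fg1 = if (!is.null(f_active)) sum(f_active * gamma1) else NULL,
       fg2 = if (!is.null(f_active)) contract_last_pair(gamma2, f_active) else NULL,
       fg3 = if (!is.null(f_active)) contract_last_pair(gamma3, f_active) else NULL)
}

# sum_vw G[..., v, w] f[v, w] over the last index pair
contract_last_pair <- function(G, f) {
  n <- nrow(f)
  d <- length(dim(G))
  m <- matrix(G, ncol = n * n)
  res <- m %*% as.vector(f)
  if (d == 4) matrix(res, n, n) else array(res, rep(n, d - 2))
}

# look up a normal-ordered e-expectation for concrete active-relative pairs
# (matrix r x 2); rank limited to 3.
gamma_lookup <- function(ctx, pairs) {
  r <- nrow(pairs)
  n <- ctx$n_act
  idx <- as.vector(t(pairs))                  # p1,q1,p2,q2,...
  pos <- 1 + sum((idx - 1) * n^(seq_along(idx) - 1))
  switch(r, ctx$g1[pos], ctx$g2[pos], ctx$g3[pos],
         stop("rank-4 without Fock contraction: needs uncontracted 4RDM"))
}

# evaluate one fully reduced e-term (active-relative pairs, possibly with
# symbolic slots -1/-2), with f bookkeeping frow/fcol (active-relative).
eval_eterm <- function(ctx, pairs, frow, fcol, has_f) {
  n <- ctx$n_act
  if (!has_f) return(if (nrow(pairs) == 0) 1 else gamma_lookup(ctx, pairs))
  i1 <- which(pairs[, 1] == -1L)
  i2 <- which(pairs[, 2] == -2L)
  if (length(i1) == 0 && length(i2) == 0) {
    # both f indices fixed by deltas (or pair fully consumed)
    fac <- ctx$f[frow, fcol]
    return(fac * (if (nrow(pairs) == 0) 1 else gamma_lookup(ctx, pairs)))
  }
  if (length(i1) == 1 && length(i2) == 1 && i1 == i2) {
    # intact symbolic pair: full contraction sum_vw f_vw <e_{..., (v,w)}>
    rest <- pairs[-i1, , drop = FALSE]
    r <- nrow(rest) + 1L
    if (r == 1) return(ctx$fg1)
    if (r == 4) {
      idx <- as.vector(t(rest))
      pos <- 1 + sum((idx - 1) * n^(seq_along(idx) - 1))
      return(ctx$f4[pos])
    }
    G <- if (r == 2) ctx$fg2 else ctx$fg3
    idx <- as.vector(t(rest))
    pos <- 1 + sum((idx - 1) * n^(seq_along(idx) - 1))
    return(G[pos])
  }
  if (length(i1) == 1) {
    # row (w, d), f column fixed: sum_v f[v, fcol] <e_{..., (v, d)}>
    d_ <- pairs[i1, 2]
    rest <- pairs[-i1, , drop = FALSE]
    r <- nrow(rest) + 1L
    if (r > 3) stop("internal: rank-4 with partially fixed f index")
    acc <- 0
    for (v in seq_len(n))
      acc <- acc + ctx$f[v, fcol] *
        gamma_lookup(ctx, rbind(rest, c(v, d_)))
    return(acc)
  }
  # length(i2) == 1: row (a, w'), f row fixed: sum_w f[frow, w] <e_{...,(a,w)}>
  a_ <- pairs[i2, 1]
  rest <- pairs[-i2, , drop = FALSE]
  r <- nrow(rest) + 1L
  if (r > 3) stop("internal: rank-4 with partially fixed f index")
  acc <- 0
  for (w in seq_len(n))
    acc <- acc + ctx$f[frow, w] * gamma_lookup(ctx, rbind(rest, c(a_, w)))
  acc
}

# reduce a pure-active product of E operators (global indices already mapped
# to active-relative; symbols -1/-2 allowed) to e-terms and evaluate.
active_reduce <- function(ctx, ops, frow, fcol, has_f) {
  m <- nrow(ops)
  if (m == 0) {
    return(eval_eterm(ctx, matrix(0L, 0, 2), frow, fcol, has_f))
  }
  # terms: list(coef, pairs, frow, fcol)
  terms <- list(list(coef = 1, pairs = ops[m, , drop = FALSE],
                     frow = frow, fcol = fcol))
  if (m >= 2) for (k in seq(m - 1L, 1L)) {
    a <- ops[k, 1]; b <- ops[k, 2]
    new_terms <- vector("list", 0)
    for (tm in terms) {
      P <- tm$pairs
      # prepend
      new_terms[[length(new_terms) + 1L]] <-
        list(coef = tm$coef, pairs = rbind(c(a, b), P),
             frow = tm$frow, fcol = tm$fcol)
      for (j in seq_len(nrow(P))) {
        cj <- P[j, 1]
        if (b > 0L && cj > 0L && b == cj) {
          P2 <- P; P2[j, ] <- c(a, P[j, 2])
          new_terms[[length(new_terms) + 1L]] <-
            list(coef = tm$coef, pairs = P2, frow = tm$frow, fcol = tm$fcol)
        } else if (b > 0L && cj == -1L) {
          # delta fixes the f row index to b; pair keeps its slot2
          P2 <- P; P2[j, ] <- c(a, P[j, 2])
          new_terms[[length(new_terms) + 1L]] <-
            list(coef = tm$coef, pairs = P2, frow = b, fcol = tm$fcol)
        } else if (b == -2L && cj > 0L) {
          # prepended op is the symbolic pair; delta fixes f column to cj
          P2 <- P; P2[j, ] <- c(a, P[j, 2])   # a == -1L here
          new_terms[[length(new_terms) + 1L]] <-
            list(coef = tm$coef, pairs = P2, frow = tm$frow, fcol = cj)
        }
      }
    }
    terms <- new_terms
  }
  acc <- 0
  for (tm in terms)
    acc <- acc + tm$coef * eval_eterm(ctx, tm$pairs, tm$frow, tm$fcol, has_f)
  acc
}

# main recursive eliminator over mixed-space operator strings.
# ops: integer matrix (k x 2), global orbital indices; -1/-2 symbolic active.
wick_eval <- function(ctx, ops, coef = 1, frow = NA_integer_,
                      fcol = NA_integer_, has_f = FALSE) {
  spc <- ctx$spc
  m <- nrow(ops)
  if (m == 0) {
    return(coef * eval_eterm(ctx, matrix(0L, 0, 2), frow, fcol, has_f))
  }
  s1 <- ifelse(ops[, 1] > 0L, spc[pmax(ops[, 1], 1L)], 2L)
  s2 <- ifelse(ops[, 2] > 0L, spc[pmax(ops[, 2], 1L)], 2L)

  commute_step <- function(k, kind) {
    # move op k past op k+1: E_ab E_cd = E_cd E_ab + d_bc E_ad - d_da E_cb
    a <- ops[k, 1]; b <- ops[k, 2]; cc <- ops[k + 1, 1]; d_ <- ops[k + 1, 2]
    acc <- 0
    swapped <- ops
    swapped[k, ] <- c(cc, d_); swapped[k + 1, ] <- c(a, b)
    acc <- acc + wick_eval(ctx, swapped, coef, frow, fcol, has_f)
    if (b > 0L && cc > 0L && b == cc) {
      merged <- ops[-(k + 1), , drop = FALSE]
      merged[k, ] <- c(a, d_)
      acc <- acc + wick_eval(ctx, merged, coef, frow, fcol, has_f)
    } else if (b > 0L && cc == -1L && spc[b] == 2L) {
      merged <- ops[-(k + 1), , drop = FALSE]
      merged[k, ] <- c(a, d_)                  # d_ is -2 or already fixed
      acc <- acc + wick_eval(ctx, merged, coef, ctx$act_pos[b], fcol, has_f)
    } else if (b == -2L && cc > 0L && spc[cc] == 2L) {
      # moving op carries the unfixed f column symbol: delta fixes it
      merged <- ops[-(k + 1), , drop = FALSE]
      merged[k, ] <- c(a, d_)
      acc <- acc + wick_eval(ctx, merged, coef, frow, ctx$act_pos[cc], has_f)
    }
    if (d_ > 0L && a > 0L && a == d_) {
      merged <- ops[-(k + 1), , drop = FALSE]
      merged[k, ] <- c(cc, b)
      acc <- acc - wick_eval(ctx, merged, coef, frow, fcol, has_f)
    } else if (d_ == -2L && a > 0L && spc[a] == 2L) {
      merged <- ops[-(k + 1), , drop = FALSE]
      merged[k, ] <- c(cc, b)                  # cc is -1 or fixed
      acc <- acc - wick_eval(ctx, merged, coef, frow, ctx$act_pos[a], has_f)
    } else if (a == -1L && d_ > 0L && spc[d_] == 2L) {
      # moving op carries the unfixed f row symbol: delta fixes it
      merged <- ops[-(k + 1), , drop = FALSE]
      merged[k, ] <- c(cc, b)
      acc <- acc - wick_eval(ctx, merged, coef, ctx$act_pos[d_], fcol, has_f)
    }
    acc
  }

  # 1) eliminate virtual annihilators (slot2 virtual), rightmost first
  vk <- which(s2 == 3L)
  if (length(vk)) {
    k <- max(vk)
    if (k == m) return(0)                      # a_virtual |psi> = 0
    return(commute_step(k))
  }
  # 2) unmatched virtual creators vanish
  if (any(s1 == 3L)) return(0)
  # 3) eliminate inactive creators (slot1 inactive), rightmost first
  ik <- which(s1 == 1L)
  if (length(ik)) {
    k <- max(ik)
    if (k == m) {
      # E_{iq}|psi> = 2 d_{iq} |psi>
      if (ops[k, 2] == ops[k, 1]) {
        return(wick_eval(ctx, ops[-k, , drop = FALSE], 2 * coef,
                         frow, fcol, has_f))
      }
      return(0)
    }
    return(commute_step(k))
  }
  # 4) leftover inactive annihilators cannot be balanced
  if (any(s2 == 1L)) return(0)
  # 5) pure active string
  act_ops <- ops
  act_ops[, 1] <- ifelse(ops[, 1] > 0L, ctx$act_pos[pmax(ops[, 1], 1L)], ops[, 1])
  act_ops[, 2] <- ifelse(ops[, 2] > 0L, ctx$act_pos[pmax(ops[, 2], 1L)], ops[, 2])
  coef * active_reduce(ctx, act_ops, frow, fcol, has_f)
}

#' Mixed-space expectation value of a product of spin-free excitations
#'
#' Evaluates `<psi| E_{p1q1} E_{p2q2} ... |psi>` for a reference that is a
#' closed shell on the inactive orbitals, an arbitrary correlated state on
#' the active orbitals (entering only through its RDMs), and empty virtuals.
#' If `f_pair_at` is given, the operator at that position is replaced by
#' `sum_vw f_vw E_vw` over the active orbitals; rank-4 active residues are
#' then read from the Fock-contracted 4RDM.
#'
#' @param ops integer matrix (k x 2) of global orbital index pairs (p, q).
#' @param ctx context from `wick_context` (internal constructor holding the
#'   orbital partition, RDM tensors, Fock active block and F.4RDM).
#' @param f_pair_at optional row index of the symbolic Fock pair.
#' @return scalar expectation value.
#' @export
mixed_expectation <- function(ops, ctx, f_pair_at = NULL) {
  ops <- matrix(as.integer(ops), ncol = 2)
  has_f <- !is.null(f_pair_at)
  if (has_f) ops[f_pair_at, ] <- c(-1L, -2L)
  wick_eval(ctx, ops, has_f = has_f)
}
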