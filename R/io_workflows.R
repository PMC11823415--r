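# Serialization of RDM sets and reports (plain-text JSON containers), run
# configuration handling, and the orchestration workflows that mirror the
# package's standard numerical experiments: the positivity comparison of
# the three RDM estimators across PRNG seeds, the discard-threshold sweep,
# and the histogram-duration stability study.

#' Write an rdm_set to a JSON container
#'
#' Plain-text serialization: tensors stored flattened with dimensions,
#' provenance and diagnostics as attributes.
#' @param rdms an [rdm_set].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_rdm_set <- function(rdms, path) {
  pack <- function(a) if (is.null(a)) NULL else
    list(dim = dim(a), data = as.vector(a))
  obj <- list(gamma1 = pack(rdms$gamma1), gamma2 = pack(rdms$gamma2),
              gamma3 = pack(rdms$gamma3), f4 = pack(rdms$f4),
              provenance = rdms$provenance,
              hermiticity_error = rdms$hermiticity_error,
              n_act_elec = rdms$n_act_elec)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an rdm_set from a JSON container
#' @param path file written by [write_rdm_set].
#' @return an [rdm_set].
#' @export
read_rdm_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(x) if (is.null(x) || length(x$data) == 0) NULL else
    array(x$data, dim = x$dim)
  rdm_set(gamma1 = unpack(obj$gamma1), gamma2 = unpack(obj$gamma2),
          gamma3 = unpack(obj$gamma3), f4 = unpack(obj$f4),
          provenance = obj$provenance,
          hermiticity_error = obj$hermiticity_error,
          n_act_elec = obj$n_act_elec)
}

#' Write a trajectory as TSV
#' @param run a `qmc_run`.
#' @param path output path (replica index appended for two replicas).
#' @return paths written, invisibly.
#' @export
write_trajectory <- function(run, path) {
  paths <- character(0)
  for (r in seq_along(run$trajectory)) {
    p <- if (length(run$trajectory) == 1) path else
      sub("(\\.[^.]*)?$", paste0("_r", r, "\\1"), path)
    utils::write.table(run$trajectory[[r]], p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a run configuration file
#'
#' YAML with keys `fcidump`, `inactive`, `active`, `virtual`, `n_elec`,
#' `ms2`, `qmc` (fields of [qmc_params]), `caspt2` (fields of
#' [caspt2_params]), `t_list`, `seeds`, `output_dir`.
#' @param path YAML file.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

config_space <- function(cfg) {
  orbital_space(inactive = cfg$inactive %||% integer(0),
                active = cfg$active %||% integer(0),
                virtual = cfg$virtual %||% integer(0),
                n_elec = cfg$n_elec, ms2 = cfg$ms2 %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

qmc_params_from <- function(cfg, seed, overrides = list()) {
  args <- cfg$qmc %||% list()
  args$seed <- seed
  args <- utils::modifyList(args, overrides)
  do.call(qmc_params, args)
}

#' Positivity comparison of the three RDM estimation modes
#'
#' For each seed, runs a two-replica FCIQMC dynamic with histogramming and
#' computes the 3RDM with the replica, hybrid and pure-histogram estimators,
#' returning a [positivity_report] per (seed, mode) and a comparison table
#' of negative-eigenvalue counts and masses. The pure-histogram mode is
#' nonnegative by construction; the replica estimators develop negative
#' tails whose magnitude depends on the PRNG seed.
#'
#' @param ints active-space [integral_set].
#' @param dspace a `det_space`.
#' @param params a [qmc_params] template (seed field overridden per run).
#' @param seeds integer vector (>= 2 seeds).
#' @param t discard threshold for the histogram vector (walkers).
#' @return list: `reports` (nested by seed/mode), `table` (data frame).
#' @export
workflow_positivity <- function(ints, dspace, params, seeds, t = 0) {
  stopifnot(length(seeds) >= 2)
  if (params$n_replicas != 2) stop("two replicas required")
  reports <- list()
  rows <- list()
  for (sd in seeds) {
    p <- params
    p$seed <- sd
    run <- run_fciqmc(ints, dspace, p)
    hv <- histogram_vector(run)
    tn <- truncate_and_normalize(hv, t)
    modes <- list(
      histogram = rdms_from_vector(tn$ci, dspace, 3, method = "operator"),
      hybrid = hybrid_rdms(run, 3),
      replica = replica_rdms(run, 3))
    reports[[as.character(sd)]] <- lapply(modes, positivity_report)
    for (m in names(modes)) {
      pr <- reports[[as.character(sd)]][[m]]
      rows[[length(rows) + 1L]] <-
        data.frame(seed = sd, mode = m, n_negative = pr$n_negative,
                   negative_mass = pr$negative_mass,
                   hermiticity_error = pr$hermiticity_error)
    }
  }
  list(reports = reports, table = do.call(rbind, rows))
}

#' Discard-threshold sweep
#'
#' One histogrammed run; for each threshold `t` (strictly decreasing, in
#' walkers) the truncated wave function is formed, its variational energy
#' and CASPT2 second-order energy computed, and the retained-determinant
#' count recorded — the convergence-with-t pattern of the histogramming
#' protocol.
#'
#' @param ints full-orbital [integral_set].
#' @param space an [orbital_space].
#' @param params a [qmc_params] (histogramming enabled).
#' @param t_list strictly decreasing discard thresholds (walkers).
#' @param pt2 a [caspt2_params].
#' @return data frame: `t`, `n_retained`, `l1`, `e_var`, `e2`, `e_total`.
#' @export
workflow_threshold_sweep <- function(ints, space, params, t_list,
                                     pt2 = caspt2_params()) {
  if (any(diff(t_list) >= 0)) stop("t_list must be strictly decreasing")
  n_act <- length(space$active)
  na <- (space$n_act_elec + space$ms2) / 2
  nb <- (space$n_act_elec - space$ms2) / 2
  dact <- enumerate_cas(n_act, na, nb)
  ha <- active_hamiltonian(ints, space)
  run <- run_fciqmc(ha, dact, params)
  hv <- histogram_vector(run)
  Ha <- run$H
  rows <- lapply(t_list, function(t) {
    tn <- truncate_and_normalize(hv, t)
    e_var <- sum(tn$ci * as.numeric(Ha %*% tn$ci))
    res <- caspt2_energy(ints, space, pt2, ci_active = tn$ci)
    data.frame(t = t, n_retained = tn$n_retained, l1 = tn$l1,
               e_var = e_var, e2 = res$e2_total,
               e_total = res$e_ref + res$e2_total)
  })
  out <- do.call(rbind, rows)
  attr(out, "run") <- run
  out
}

#' Histogram-duration stability study
#'
#' Runs dynamics once with the longest duration, then evaluates the
#' truncated histogram vector and its CASPT2 energy over nested windows of
#' increasing length, demonstrating stabilization of the second-order
#' energy with averaging duration.
#'
#' @param ints full-orbital [integral_set].
#' @param space an [orbital_space].
#' @param params a [qmc_params] template.
#' @param durations increasing window lengths (iterations).
#' @param t discard threshold (walkers).
#' @param pt2 a [caspt2_params].
#' @return data frame: `duration`, `n_retained`, `e_var`, `e2`.
#' @export
workflow_duration <- function(ints, space, params, durations, t = 0.5,
                              pt2 = caspt2_params()) {
  if (any(diff(durations) <= 0)) stop("durations must be increasing")
  if (any(durations < 2)) stop("window of one iteration is unreliable")
  n_act <- length(space$active)
  na <- (space$n_act_elec + space$ms2) / 2
  nb <- (space$n_act_elec - space$ms2) / 2
  dact <- enumerate_cas(n_act, na, nb)
  ha <- active_hamiltonian(ints, space)
  rows <- list()
  for (dur in durations) {
    p <- params
    p$n_iters <- NULL
    p <- do.call(qmc_params, utils::modifyList(
      params[setdiff(names(params), "n_iters")],
      list(n_iters = as.integer(dur))))
    run <- run_fciqmc(ha, dact, p)
    hv <- histogram_vector(run)
    tn <- truncate_and_normalize(hv, t)
    e_var <- sum(tn$ci * as.numeric(run$H %*% tn$ci))
    res <- caspt2_energy(ints, space, pt2, ci_active = tn$ci)
    rows[[length(rows) + 1L]] <-
      data.frame(duration = dur, n_retained = tn$n_retained, e_var = e_var,
                 e2 = res$e2_total)
  }
  do.call(rbind, rows)
}
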