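#' Integration settings
#'
#' Fixed-step RK4 settings. The default step dt = 1e-14 s resolves the
#' fastest linearized pair mode (about 1e12 s^-1, set by
#' max(k12 R (R1+R2) / I) and K / I) with two orders of magnitude of
#' margin; [check_dt()] verifies this on a given system by step halving.
#' The recording stride defaults to the smallest value that keeps at most
#' `max_records` snapshots.
#'
#' @param t_end Final time (s).
#' @param dt Time step (s), default 1e-14.
#' @param record_stride Record every `record_stride`-th step; `NULL` (the
#'   default) chooses automatically from `max_records`.
#' @param record_full Record full per-site states (matrices) in addition to
#'   the always-recorded chain-mean series. Memory scales with
#'   n x records; off by default.
#' @param max_records Cap on the number of recorded snapshots used when
#'   `record_stride` is `NULL`.
#' @return An object of class `integration_settings`.
#' @export
integration_settings <- function(t_end, dt = 1e-14, record_stride = NULL,
                                 record_full = FALSE, max_records = 1e5) {
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0")
  if (!is.numeric(t_end) || t_end < dt) stop("`t_end` must be >= dt")
  nsteps <- as.integer(round(t_end / dt))
  if (is.null(record_stride))
    record_stride <- max(1L, as.integer(ceiling(nsteps / max_records)))
  record_stride <- as.integer(record_stride)
  if (record_stride < 1L) stop("`record_stride` must be >= 1")
  structure(list(dt = dt, t_end = t_end, nsteps = nsteps,
                 record_stride = record_stride,
                 record_full = isTRUE(record_full)),
            class = "integration_settings")
}

sequence_digest <- function(symbols) {
  # order-sensitive polynomial hash; enough to fingerprint a run's sequence
  v <- match(symbols, c("A", "C", "G", "T"))
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483647
  sprintf("n%d-%08x", length(v), as.integer(h))
}

variant_code <- function(variant) if (variant == "as_printed") 0L else 1L

#' One classical RK4 step
#'
#' Advances the full 4n-component first-order system by one step of the
#' classical fourth-order Runge-Kutta scheme (stage weights 1/6, 1/3, 1/3,
#' 1/6).
#'
#' @param state A `duplex_state`.
#' @param dt Step size (s), > 0.
#' @param system A `duplex_system` with matching `n`.
#' @return The `duplex_state` at `state$t + dt`.
#' @export
rk4_step <- function(state, dt, system) {
  check_state_system(state, system)
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0")
  out <- rk4_step_cpp(state$phi1, state$phi2, state$v1, state$v2,
                      state$t, dt,
                      system$I1, system$I2, system$K1, system$K2,
                      system$R1, system$R2, system$B1, system$B2, system$k12,
                      system$force$F0, system$force$omega,
                      variant_code(system$variant))
  duplex_state(out$phi1, out$phi2, out$v1, out$v2, t = out$t)
}

#' Integrate the Cauchy problem
#'
#' Repeated fixed-step RK4 from `initial` to `t_end`, recording every
#' `record_stride`-th step (the initial state is always the first record).
#' Deterministic: identical inputs give bit-identical trajectories. A
#' non-finite state aborts with the step index and the largest angle seen.
#'
#' @param system A `duplex_system`.
#' @param settings An `integration_settings`.
#' @param initial Initial `duplex_state`; defaults to
#'   [equilibrium_state()] of the system's n.
#' @return An object of class `duplex_trajectory`: `times`, chain-mean
#'   series `mean_phi1` / `mean_phi2`, optional per-site matrices `phi1`,
#'   `phi2`, `v1`, `v2` (records x n), the `final_state`, and `metadata`.
#' @examples
#' sys <- build_system(random_sequence(10, seed = 1),
#'                     force = force_spec(0.5e-22, 1e10))
#' traj <- integrate_duplex(sys, integration_settings(t_end = 1e-12))
#' range(traj$mean_phi1)
#' @export
integrate_duplex <- function(system, settings,
                             initial = equilibrium_state(system$n)) {
  stopifnot(inherits(system, "duplex_system"),
            inherits(settings, "integration_settings"))
  check_state_system(initial, system)
  raw <- integrate_cpp(initial$phi1, initial$phi2, initial$v1, initial$v2,
                       initial$t,
                       system$I1, system$I2, system$K1, system$K2,
                       system$R1, system$R2, system$B1, system$B2,
                       system$k12,
                       system$force$F0, system$force$omega,
                       variant_code(system$variant),
                       settings$dt, settings$nsteps, settings$record_stride,
                       settings$record_full)
  fin <- raw$final
  structure(list(
    times = raw$times,
    mean_phi1 = raw$mean_phi1, mean_phi2 = raw$mean_phi2,
    phi1 = raw$phi1, phi2 = raw$phi2, v1 = raw$v1, v2 = raw$v2,
    final_state = duplex_state(fin$phi1, fin$phi2, fin$v1, fin$v2, t = fin$t),
    metadata = list(
      n = system$n, dt = settings$dt, t_end = settings$t_end,
      record_stride = settings$record_stride,
      variant = system$variant,
      F0 = system$force$F0, omega = system$force$omega,
      sequence_id = system$id,
      sequence_digest = sequence_digest(system$seq1))),
    class = "duplex_trajectory")
}

#' @export
print.duplex_trajectory <- function(x, ...) {
  m <- x$metadata
  cat(sprintf(
    "<duplex_trajectory> %s: n = %d, %d records over %g s (dt = %g s, stride %d)\n  variant = %s, F0 = %g J, omega = %g s^-1\n",
    m$sequence_id, m$n, length(x$times), m$t_end, m$dt, m$record_stride,
    m$variant, m$F0, m$omega))
  invisible(x)
}

#' Pick a stable, accurate step size for a system
#'
#' Halves dt starting from `dt0` until the post-transient amplitude of the
#' chain-1 mean deviation changes by less than `rel_tol` between
#' successive halvings, over a short probe run.
#'
#' @param system A `duplex_system`.
#' @param t_probe Probe run length (s).
#' @param dt0 Starting step (s).
#' @param rel_tol Relative amplitude-change tolerance between halvings.
#' @param transient_cutoff Cutoff passed to the amplitude estimator (s).
#' @param max_halvings Safety bound.
#' @return The accepted dt (s).
#' @export
check_dt <- function(system, t_probe = 1e-10, dt0 = 1e-14, rel_tol = 1e-3,
                     transient_cutoff = t_probe / 5, max_halvings = 6L) {
  amp_at <- function(dt) {
    traj <- integrate_duplex(system, integration_settings(t_end = t_probe, dt = dt))
    amplitude(mean_angular_deviation(traj, 1, transient_cutoff = transient_cutoff))
  }
  dt <- dt0
  a_prev <- amp_at(dt)
  for (h in seq_len(max_halvings)) {
    a_half <- amp_at(dt / 2)
    denom <- max(abs(a_half), .Machine$double.eps)
    if (abs(a_half - a_prev) / denom < rel_tol) return(dt)
    dt <- dt / 2
    a_prev <- a_half
  }
  warning("amplitude did not stabilize within max_halvings; returning smallest dt tried")
  dt
}

#' Export a trajectory as TSV with a YAML sidecar
#'
#' Writes `t`, `mean_phi1`, `mean_phi2` columns (plus per-site `phi1_i`,
#' `phi2_i` columns when the trajectory holds full states) and a
#' `<path>.meta.yaml` sidecar with all run metadata.
#'
#' @param traj A `duplex_trajectory`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "duplex_trajectory"))
  df <- data.frame(t = traj$times, mean_phi1 = traj$mean_phi1,
                   mean_phi2 = traj$mean_phi2)
  if (!is.null(traj$phi1)) {
    p1 <- as.data.frame(traj$phi1); names(p1) <- sprintf("phi1_%d", seq_len(ncol(p1)))
    p2 <- as.data.frame(traj$phi2); names(p2) <- sprintf("phi2_%d", seq_len(ncol(p2)))
    df <- cbind(df, p1, p2)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(traj$metadata, paste0(path, ".meta.yaml"))
  invisible(path)
}
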