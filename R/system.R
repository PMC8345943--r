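#' Build the mechanical duplex system from a sequence
#'
#' Maps each chain-1 base (and its Watson-Crick partner on chain 2) to its
#' row of the parameter table, producing the per-site coefficient arrays of
#' the equations of motion. Site i couples the two chains through the pair
#' stiffness `k12` of its pair type (A-T or G-C).
#'
#' Two right-hand-side variants are provided. `"as_printed"` keeps the
#' model's original sign structure of the chain-2 pair torque
#' (+k12 R1 (R1+R2) sin(phi2) - k12 R1 R2 sin(phi1 - phi2), with the
#' boundary rows taken as the one-neighbour specialization of the interior
#' rows). `"potential_consistent"` replaces the chain-2 pair torque by the
#' negative gradient of the pair potential used by [total_energy()]
#' (-k12 R2 (R1+R2) sin(phi2) + k12 R1 R2 sin(phi1 - phi2)), which makes
#' the undriven undamped system conservative and enables energy-based
#' validation. Chain-1 torques are identical in both variants.
#'
#' @param seq A `dna_sequence` (chain 1; chain 2 is its complement).
#' @param params A `param_table` (default [default_param_table()]).
#' @param force A `force_spec` (default: constant torque 0.5e-22 J).
#' @param variant `"as_printed"` (default) or `"potential_consistent"`.
#' @return An object of class `duplex_system` with fields `n`, `seq1`,
#'   `seq2`, per-site arrays `I1, I2, R1, R2, K1, K2, B1, B2, k12`,
#'   `force`, and `variant`.
#' @examples
#' sys <- build_system(dna_sequence("AG"), force = force_spec(0, 0))
#' sys$I1   # 7.61e-44 8.22e-44
#' sys$seq2 # "T" "C"
#' @export
build_system <- function(seq, params = default_param_table(),
                         force = force_spec(),
                         variant = c("as_printed", "potential_consistent")) {
  stopifnot(inherits(seq, "dna_sequence"), inherits(params, "param_table"),
            inherits(force, "force_spec"))
  variant <- match.arg(variant)
  s1 <- seq$symbols
  s2 <- complement_base(s1)
  pick <- function(chain, field)
    vapply(chain, function(b) params$bases[[b]][[field]], numeric(1),
           USE.NAMES = FALSE)
  pair_type <- ifelse(s1 %in% c("A", "T"), "AT", "GC")
  structure(list(
    n = length(s1), seq1 = s1, seq2 = s2, id = seq$id,
    I1 = pick(s1, "I"), I2 = pick(s2, "I"),
    R1 = pick(s1, "R"), R2 = pick(s2, "R"),
    K1 = pick(s1, "K"), K2 = pick(s2, "K"),
    B1 = pick(s1, "beta"), B2 = pick(s2, "beta"),
    k12 = unname(params$k12[pair_type]),
    force = force, variant = variant), class = "duplex_system")
}

#' @export
print.duplex_system <- function(x, ...) {
  cat(sprintf(
    "<duplex_system> %s: n = %d pairs, variant = %s, F0 = %g J, omega = %g s^-1\n",
    x$id, x$n, x$variant, x$force$F0, x$force$omega))
  invisible(x)
}

#' External torque on one pendulum
#'
#' `-beta * v + F0 * cos(omega * t)`: linear viscous drag from the
#' surrounding liquid plus the uniform periodic drive. With `omega = 0`
#' the drive is the constant `F0`.
#'
#' @param t Time (s).
#' @param v Angular velocity (rad/s); vectorized.
#' @param beta Dissipation coefficient (J s).
#' @param force A `force_spec`.
#' @return Torque (J).
#' @export
external_torque <- function(t, v, beta, force) {
  stopifnot(inherits(force, "force_spec"))
  -beta * v + force$F0 * cos(force$omega * t)
}

#' Construct a dynamical state
#'
#' @param phi1,phi2 Angles of the n chain-1 / chain-2 pendulums (rad).
#' @param v1,v2 Angular velocities (rad/s).
#' @param t Time (s).
#' @return An object of class `duplex_state`.
#' @export
duplex_state <- function(phi1, phi2, v1, v2, t = 0) {
  n <- length(phi1)
  if (n < 1L || length(phi2) != n || length(v1) != n || length(v2) != n)
    stop("phi1, phi2, v1, v2 must all have the same positive length")
  vals <- c(phi1, phi2, v1, v2, t)
  if (any(!is.finite(vals))) stop("state contains non-finite entries")
  structure(list(t = t, phi1 = as.numeric(phi1), phi2 = as.numeric(phi2),
                 v1 = as.numeric(v1), v2 = as.numeric(v2), n = n),
            class = "duplex_state")
}

#' The equilibrium initial state
#'
#' The rest configuration used as initial data for the Cauchy problem:
#' phi1 = 0, phi2 = pi, all angular velocities 0, t = 0. With no drive the
#' right-hand side vanishes identically there (exactly, in floating point)
#' for both variants.
#'
#' @param n Number of base pairs (>= 1).
#' @return A `duplex_state`.
#' @export
equilibrium_state <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  duplex_state(phi1 = rep(0, n), phi2 = rep(pi, n),
               v1 = rep(0, n), v2 = rep(0, n), t = 0)
}

check_state_system <- function(state, system) {
  stopifnot(inherits(state, "duplex_state"), inherits(system, "duplex_system"))
  if (state$n != system$n)
    stop(sprintf("state has n = %d but system has n = %d", state$n, system$n))
}

#' Evaluate the equations of motion
#'
#' Time derivative of the full 4n-component first-order system at `state`:
#' d(phi)/dt = v and d(v)/dt = (backbone torsion + pair torque + external
#' torque) / I, per chain and site.
#'
#' @param state A `duplex_state`.
#' @param system A `duplex_system` with matching `n`.
#' @return A list with `dphi1`, `dphi2`, `dv1`, `dv2`.
#' @export
duplex_rhs <- function(state, system) {
  check_state_system(state, system)
  rhs_cpp(state$phi1, state$phi2, state$v1, state$v2, state$t,
          system$I1, system$I2, system$K1, system$K2,
          system$R1, system$R2, system$B1, system$B2, system$k12,
          system$force$F0, system$force$omega,
          if (system$variant == "as_printed") 0L else 1L)
}

#' Total mechanical energy (conservative variant, homopolymer only)
#'
#' Kinetic energy plus torsional spring energy plus the pair potential
#' whose negative gradient is the `potential_consistent` pair torque:
#' \deqn{E = \sum_i \tfrac12 I_{1} v_{1i}^2 + \tfrac12 I_{2} v_{2i}^2
#'  + \sum_{i<n} \tfrac12 K_1 (\phi_{1,i+1}-\phi_{1i})^2
#'             + \tfrac12 K_2 (\phi_{2,i+1}-\phi_{2i})^2
#'  + \sum_i k_{12} [R_1(R_1{+}R_2)(1-\cos\phi_{1i})
#'             + R_2(R_1{+}R_2)(1-\cos\phi_{2i})
#'             + R_1 R_2 (1-\cos(\phi_{1i}-\phi_{2i}))]}
#'
#' Restricted to homopolymer chain-1 sequences: with site-varying K the
#' printed torsional force K_i(phi_{i-1} - 2 phi_i + phi_{i+1}) is not the
#' gradient of any symmetric spring energy, so an exact invariant only
#' exists when K is constant along each chain.
#'
#' @param state A `duplex_state`.
#' @param system A `duplex_system` built with `variant =
#'   "potential_consistent"` from a homopolymer sequence.
#' @return Energy (J).
#' @export
total_energy <- function(state, system) {
  check_state_system(state, system)
  if (system$variant != "potential_consistent")
    stop("total_energy is defined only for the potential_consistent variant")
  if (length(unique(system$seq1)) != 1L)
    stop("total_energy is defined only for homopolymer sequences (constant K per chain)")
  kin <- 0.5 * sum(system$I1 * state$v1^2 + system$I2 * state$v2^2)
  n <- system$n
  tors <- if (n > 1L) {
    d1 <- diff(state$phi1); d2 <- diff(state$phi2)
    0.5 * system$K1[1L] * sum(d1^2) + 0.5 * system$K2[1L] * sum(d2^2)
  } else 0
  r1 <- system$R1; r2 <- system$R2; k <- system$k12
  pair <- sum(k * (r1 * (r1 + r2) * (1 - cos(state$phi1)) +
                   r2 * (r1 + r2) * (1 - cos(state$phi2)) +
                   r1 * r2 * (1 - cos(state$phi1 - state$phi2))))
  kin + tors + pair
}
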