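# Independent reference implementations used as test oracles.
# Deliberately written in plain R, straight from the equations of motion
# (direct sin() calls, no reformulation), so they share no code path with
# the package's compiled core.

# state vector layout used by the oracles: y = c(phi1, phi2, v1, v2)
state_to_vec <- function(st) c(st$phi1, st$phi2, st$v1, st$v2)
vec_to_state <- function(y, n, t = 0)
  duplex_state(y[1:n], y[n + 1:n], y[2 * n + 1:n], y[3 * n + 1:n], t = t)

ref_deriv <- function(t, y, sys) {
  n <- sys$n
  phi1 <- y[1:n]; phi2 <- y[n + 1:n]
  v1 <- y[2 * n + 1:n]; v2 <- y[3 * n + 1:n]
  lap <- function(phi, K) {
    if (n == 1) return(0)
    c(K[1] * (phi[2] - phi[1]),
      if (n > 2) K[2:(n - 1)] * (phi[1:(n - 2)] - 2 * phi[2:(n - 1)] + phi[3:n]),
      K[n] * (phi[n - 1] - phi[n]))
  }
  drive <- sys$force$F0 * cos(sys$force$omega * t)
  k <- sys$k12; r1 <- sys$R1; r2 <- sys$R2
  pair1 <- -k * r1 * (r1 + r2) * sin(phi1) - k * r1 * r2 * sin(phi1 - phi2)
  pair2 <- if (sys$variant == "as_printed")
    k * r1 * (r1 + r2) * sin(phi2) - k * r1 * r2 * sin(phi1 - phi2)
  else
    -k * r2 * (r1 + r2) * sin(phi2) + k * r1 * r2 * sin(phi1 - phi2)
  a1 <- (lap(phi1, sys$K1) + pair1 - sys$B1 * v1 + drive) / sys$I1
  a2 <- (lap(phi2, sys$K2) + pair2 - sys$B2 * v2 + drive) / sys$I2
  c(v1, v2, a1, a2)
}

# classical RK4 step, independent of the compiled implementation
ref_rk4_step <- function(y, t, dt, sys) {
  k1 <- ref_deriv(t, y, sys)
  k2 <- ref_deriv(t + dt / 2, y + dt / 2 * k1, sys)
  k3 <- ref_deriv(t + dt / 2, y + dt / 2 * k2, sys)
  k4 <- ref_deriv(t + dt, y + dt * k3, sys)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# adaptive high-accuracy reference trajectory at the requested times
oracle_traj <- function(sys, y0, times, rtol = 1e-12, atol = 1e-12) {
  f <- function(t, y, parms) list(ref_deriv(t, y, sys))
  out <- deSolve::ode(y = y0, times = times, func = f, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 1e8)
  unname(as.matrix(out)[, -1, drop = FALSE])
}

# parameter table with damping switched off (conservation checks)
undamped_table <- function() {
  tab <- default_param_table()
  for (b in names(tab$bases)) tab$bases[[b]]$beta <- 0
  tab
}

poly_seq <- function(base, n, id = sprintf("poly%s%d", base, n))
  dna_sequence(strrep(base, n), id = id)

# linearization of the equations of motion about the equilibrium state,
# from typed-in constants (not via the package RHS): returns the
# first-order system matrix for small deviations (d1, d2) = (phi1, phi2 - pi)
# of a single base pair.
pair_linearization <- function(I1, I2, R1, R2, k,
                               variant = c("as_printed", "potential_consistent")) {
  variant <- match.arg(variant)
  a <- k * R1 * (R1 + R2)   # on-site prefactor, chain-1 convention
  b <- k * R1 * R2          # cross prefactor
  # chain 1: d(v1)/dt = (-(a - b) d1 - b d2) / I1 (cos(phi1-phi2) = -1 at rest)
  # chain 2, as_printed: d(v2)/dt = (b d1 - (a + b) d2) / I2
  # chain 2, potential : d(v2)/dt = (-b d1 + (k R2 (R1+R2) + b) d2) / I2
  if (variant == "as_printed") {
    K <- matrix(c(-(a - b) / I1, -b / I1,
                  b / I2, -(a + b) / I2), 2, 2, byrow = TRUE)
  } else {
    a2 <- k * R2 * (R1 + R2)
    K <- matrix(c(-(a - b) / I1, -b / I1,
                  -b / I2, (a2 + b) / I2), 2, 2, byrow = TRUE)
  }
  K
}
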