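# Table 1 constants for the A-T pair, typed independently for oracle use
AT <- list(I1 = 7.61e-44, I2 = 4.86e-44, R1 = 5.80e-10, R2 = 4.80e-10,
           k = 6.20e-2, B1 = 4.25e-34, B2 = 2.91e-34)

test_that("build_system maps bases to their tabulated coefficients", {
  sys <- build_system(dna_sequence("AG"), force = force_spec(0, 0))
  expect_equal(sys$seq2, c("T", "C"))
  expect_equal(sys$I1, c(7.61e-44, 8.22e-44))
  expect_equal(sys$I2, c(4.86e-44, 4.11e-44))
  expect_equal(sys$R1, c(5.80e-10, 5.70e-10))
  expect_equal(sys$R2, c(4.80e-10, 4.70e-10))
  expect_equal(sys$K1, c(2.35e-18, 2.27e-18))
  expect_equal(sys$K2, c(1.61e-18, 1.54e-18))
  expect_equal(sys$B1, c(4.25e-34, 4.10e-34))
  expect_equal(sys$B2, c(2.91e-34, 2.79e-34))
  expect_equal(sys$k12, c(6.20e-2, 9.60e-2))

  big <- build_system(random_sequence(980, seed = 1), force = force_spec(0, 0))
  for (f in c("I1", "I2", "R1", "R2", "K1", "K2", "B1", "B2", "k12"))
    expect_length(big[[f]], 980)

  hom <- build_system(poly_seq("A", 7), force = force_spec(0, 0))
  for (f in c("I1", "I2", "R1", "R2", "K1", "K2", "B1", "B2", "k12"))
    expect_length(unique(hom[[f]]), 1L)
  expect_equal(unique(hom$k12), 6.20e-2)
  expect_equal(unique(build_system(poly_seq("C", 4),
                                   force = force_spec(0, 0))$k12), 9.60e-2)
})

test_that("external torque combines drag and the periodic drive", {
  fs <- force_spec(F0 = 0.5e-22, omega = 1e10)
  expect_equal(external_torque(0, 0, 4.25e-34, fs), 0.5e-22)
  expect_equal(external_torque(pi / 1e10, 0, 4.25e-34, fs), -0.5e-22)
  expect_equal(external_torque(0.3, 1, 4.25e-34, force_spec(0, 0)), -4.25e-34)
  # omega = 0: constant drive
  fs0 <- force_spec(F0 = 2e-23, omega = 0)
  expect_equal(external_torque(17, 0, 1e-34, fs0), 2e-23)
})

test_that("equilibrium state is phi1 = 0, phi2 = pi at rest", {
  st <- equilibrium_state(3)
  expect_equal(st$phi1, c(0, 0, 0))
  expect_equal(st$phi2, c(pi, pi, pi))
  expect_equal(st$v1, c(0, 0, 0))
  expect_equal(st$v2, c(0, 0, 0))
  expect_equal(st$t, 0)
  expect_error(equilibrium_state(0), ">= 1")
})

test_that("the RHS vanishes exactly at equilibrium without drive, both variants", {
  s <- random_sequence(25, seed = 8)
  for (v in c("as_printed", "potential_consistent")) {
    sys <- build_system(s, force = force_spec(0, 0), variant = v)
    d <- duplex_rhs(equilibrium_state(25), sys)
    expect_identical(max(abs(c(d$dphi1, d$dphi2, d$dv1, d$dv2))), 0)
  }
})

test_that("at equilibrium a drive produces accelerations F0 / I", {
  sys <- build_system(dna_sequence("AGTC"), force = force_spec(0.5e-22, 1e10))
  d <- duplex_rhs(equilibrium_state(4), sys)
  expect_equal(d$dv1, 0.5e-22 / sys$I1)
  expect_equal(d$dv2, 0.5e-22 / sys$I2)
})

test_that("single-pair RHS matches an independent scalar evaluation", {
  sys <- build_system(dna_sequence("A"), force = force_spec(0, 0))
  st <- duplex_state(phi1 = 0.1, phi2 = pi, v1 = 0, v2 = 0)
  d <- duplex_rhs(st, sys)
  # scalar transcription of the chain-1 equation (no torsion at n = 1)
  a1_expect <- (-AT$k * AT$R1 * (AT$R1 + AT$R2) * sin(0.1)
                - AT$k * AT$R1 * AT$R2 * sin(0.1 - pi)) / AT$I1
  a2_expect <- (AT$k * AT$R1 * (AT$R1 + AT$R2) * sin(pi)
                - AT$k * AT$R1 * AT$R2 * sin(0.1 - pi)) / AT$I2
  expect_equal(d$dv1, a1_expect, tolerance = 1e-12)
  expect_equal(d$dv2, a2_expect, tolerance = 1e-9)
  expect_equal(d$dphi1, 0)
})

test_that("RHS agrees with the plain-R reference on random states, both variants", {
  set.seed(21)
  for (v in c("as_printed", "potential_consistent")) {
    for (seq in list(dna_sequence("ACGTTGCA"), poly_seq("G", 5))) {
      sys <- build_system(seq, force = force_spec(0.5e-22, 5e9), variant = v)
      n <- sys$n
      st <- duplex_state(rnorm(n, 0, 0.3), pi + rnorm(n, 0, 0.3),
                         rnorm(n, 0, 1e10), rnorm(n, 0, 1e10), t = 3e-11)
      d <- duplex_rhs(st, sys)
      ref <- ref_deriv(st$t, state_to_vec(st), sys)
      expect_equal(c(d$dphi1, d$dphi2, d$dv1, d$dv2), ref, tolerance = 1e-10)
    }
  }
})

test_that("potential_consistent accelerations are the negative energy gradient", {
  sys <- build_system(poly_seq("A", 3), params = undamped_table(),
                      force = force_spec(0, 0), variant = "potential_consistent")
  set.seed(5)
  st <- duplex_state(rnorm(3, 0, 0.2), pi + rnorm(3, 0, 0.2),
                     rep(0, 3), rep(0, 3))
  d <- duplex_rhs(st, sys)
  h <- 1e-7
  num_grad <- function(idx, chain) {
    bump <- function(s) {
      st2 <- st
      st2[[chain]][idx] <- st2[[chain]][idx] + s
      total_energy(st2, sys)
    }
    (bump(h) - bump(-h)) / (2 * h)
  }
  for (i in 1:3) {
    expect_equal(d$dv1[i], -num_grad(i, "phi1") / sys$I1[i], tolerance = 1e-6)
    expect_equal(d$dv2[i], -num_grad(i, "phi2") / sys$I2[i], tolerance = 1e-6)
  }
})

test_that("total_energy at equilibrium equals its closed form and is guarded", {
  n <- 5
  sys <- build_system(poly_seq("A", n), force = force_spec(0, 0),
                      variant = "potential_consistent")
  # only the phi2 = pi on-site and cross pair terms contribute: 2 each
  E_expect <- n * AT$k * (AT$R2 * (AT$R1 + AT$R2) * 2 + AT$R1 * AT$R2 * 2)
  expect_equal(total_energy(equilibrium_state(n), sys), E_expect,
               tolerance = 1e-12)

  ap <- build_system(poly_seq("A", n), force = force_spec(0, 0))
  expect_error(total_energy(equilibrium_state(n), ap), "potential_consistent")
  het <- build_system(dna_sequence("ACGTA"), force = force_spec(0, 0),
                      variant = "potential_consistent")
  expect_error(total_energy(equilibrium_state(5), het), "homopolymer")
})

test_that("a state at the potential minimum has (near-)minimal energy", {
  # all angles 0, at rest: every pair term and spring term vanishes
  n <- 4
  sys <- build_system(poly_seq("T", n), params = undamped_table(),
                      force = force_spec(0, 0), variant = "potential_consistent")
  bottom <- duplex_state(rep(0, n), rep(0, n), rep(0, n), rep(0, n))
  E0 <- total_energy(bottom, sys)
  expect_equal(E0, 0)
  set.seed(13)
  for (i in 1:20) {
    st <- duplex_state(rnorm(n, 0, 0.5), rnorm(n, 0, 0.5),
                       rep(0, n), rep(0, n))
    expect_gt(total_energy(st, sys), E0)
  }
})

test_that("with damping and no drive the energy is non-increasing", {
  sys <- build_system(poly_seq("A", 5), force = force_spec(0, 0),
                      variant = "potential_consistent")
  set.seed(17)
  st <- duplex_state(rnorm(5, 0, 0.1), pi + rnorm(5, 0, 0.1),
                     rep(0, 5), rep(0, 5))
  tr <- integrate_duplex(sys, integration_settings(t_end = 2e-10,
                                                   record_full = TRUE),
                         initial = st)
  E <- vapply(seq_along(tr$times), function(i)
    total_energy(duplex_state(tr$phi1[i, ], tr$phi2[i, ],
                              tr$v1[i, ], tr$v2[i, ]), sys), numeric(1))
  expect_true(all(diff(E) <= abs(E[1]) * 1e-9))
  expect_lt(E[length(E)], E[1])
})

test_that("chain swap symmetry holds in the conservative variant", {
  # a poly-A duplex and the poly-T duplex are the same physical system with
  # chain labels exchanged; exchanging the state blocks must commute with
  # time evolution
  n <- 6
  set.seed(23)
  p <- rnorm(n, 0, 0.3); q <- rnorm(n, 0, 0.3)
  u <- rnorm(n, 0, 1e10); w <- rnorm(n, 0, 1e10)
  sysA <- build_system(poly_seq("A", n), force = force_spec(0.5e-22, 1e9),
                       variant = "potential_consistent")
  sysT <- build_system(poly_seq("T", n), force = force_spec(0.5e-22, 1e9),
                       variant = "potential_consistent")
  set <- integration_settings(t_end = 1e-11, record_full = TRUE)
  trA <- integrate_duplex(sysA, set, initial = duplex_state(p, q, u, w))
  trT <- integrate_duplex(sysT, set, initial = duplex_state(q, p, w, u))
  expect_equal(trT$phi1, trA$phi2, tolerance = 1e-10)
  expect_equal(trT$phi2, trA$phi1, tolerance = 1e-10)
})

test_that("parameter tables validate and round-trip through YAML", {
  expect_error(base_params(1, 1, 1, -1), "non-negative")
  expect_error(base_params(0, 1, 1, 1), "strictly positive")
  expect_error(param_table(list(A = base_params(1, 1, 1, 1)), c(AT = 1, GC = 1)),
               "all of A, C, G, T")
  f <- withr::local_tempfile(fileext = ".yaml")
  tab <- default_param_table()
  yaml::write_yaml(list(
    bases = lapply(tab$bases, function(b) b[c("I", "R", "K", "beta")]),
    k12 = as.list(tab$k12)), f)
  tab2 <- read_param_table(f)
  expect_equal(tab2, tab)
})
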