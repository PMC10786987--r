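# Four-state gating model: generator construction, propagation,
# simulated current, and the protocol/trace containers.

test_that("rate_matrix builds a conservative generator with the scheme's rates", {
  p <- kinetic_params(0.47, 0.59, 47.22, 200, k_b = 25)
  Q <- rate_matrix(p, mk801 = 1)
  expect_equal(colSums(Q), c(D = 0, C = 0, O = 0, B = 0), tolerance = 1e-12)
  expect_equal(Q["B", "O"], 25)           # k_b x [MK-801] at 1 uM
  expect_equal(Q["D", "C"], 0.47)
  expect_equal(Q["C", "D"], 0.59)
  expect_equal(Q["O", "C"], 47.22)
  expect_equal(Q["C", "O"], 200)
  # no transitions at all
  p0 <- kinetic_params(0, 0, 0, 0, k_b = 0)
  expect_equal(rate_matrix(p0, 0), matrix(0, 4, 4,
    dimnames = list(c("D", "C", "O", "B"), c("D", "C", "O", "B"))))
  expect_error(rate_matrix(p, mk801 = -1), "mk801")
  expect_error(kinetic_params(-0.1, 0.59, 47, 200), ">= 0")
})

test_that("relaxation spectrum matches an independent eigendecomposition", {
  # oracle: build the 3-state (D, C, O) generator directly and
  # eigendecompose it with base eigen()
  k_d <- 0.47; k_r <- 0.59; k_o <- 47.22; k_c <- 200
  A <- matrix(c(-k_r, k_d, 0,
                k_r, -(k_d + k_o), k_c,
                0, k_o, -k_c), 3, 3, byrow = TRUE)
  ev <- sort(abs(Re(eigen(A)$values)))
  slowest_oracle <- ev[2]                     # slowest nonzero relaxation
  expect_equal(slowest_oracle, 0.97, tolerance = 0.005)

  Q <- rate_matrix(kinetic_params(k_d, k_r, k_o, k_c), mk801 = 0)
  ev_pkg <- sort(abs(Re(eigen(Q[1:3, 1:3])$values)))
  expect_equal(ev_pkg[2], slowest_oracle, tolerance = 1e-10)
})

test_that("propagation conserves probability and hits known steady states", {
  proto <- control_protocol(t_app = 30)
  # channel that never opens
  occ0 <- propagate_states(kinetic_params(0.47, 0.59, 0, 200), proto,
                           dt = 1e-3)
  expect_true(all(occ0$O == 0))
  # no desensitization: two-state C<->O equilibrium
  p2 <- kinetic_params(0, 0, 47.22, 200)
  occ2 <- propagate_states(p2, proto, dt = 1e-3)
  o_end <- occ2$O[nrow(occ2)]
  expect_equal(o_end / (o_end + occ2$C[nrow(occ2)]), 47.22 / 247.22,
               tolerance = 1e-9)
  # wild-type-like steady state against a nullspace oracle
  p <- params_for(wt_2a_rates)
  Q <- rate_matrix(p, 0)
  ns <- MASS::Null(t(Q[1:3, 1:3] - 0))       # nullspace of 3-state generator
  ns <- abs(ns[, 1]) / sum(abs(ns[, 1]))
  occ <- propagate_states(p, proto, dt = 1e-3)
  expect_equal(occ$O[nrow(occ)], ns[3], tolerance = 1e-6)
  expect_equal(ns[3], 0.1162, tolerance = 1e-3)
  # conservation at every step
  err <- abs(rowSums(occ[, c("D", "C", "O", "B")]) - 1)
  expect_lt(max(err), 1e-9)
})

test_that("MK-801 block is monotone and complete when unblocking is zero", {
  p <- params_for(wt_2a_rates)
  occ <- propagate_states(p, mk_protocol(t_app = 60), dt = 1e-3)
  expect_true(all(diff(occ$B) >= -1e-12))
  expect_equal(occ$B[nrow(occ)], 1, tolerance = 1e-3)
  expect_lt(occ$O[nrow(occ)], 1e-3)
})

test_that("matrix-exponential propagation agrees with a stiff ODE solver", {
  skip_if_not_installed("deSolve")
  p <- params_for(wt_2a_rates)
  proto <- mk_protocol(t_app = 4.9)
  occ <- propagate_states(p, proto, dt = 1e-3)
  seg_mk <- function(t) ifelse(t >= 0.1, 1, 0)
  rhs <- function(t, y, parms) {
    Q <- rate_matrix(p, mk801 = seg_mk(t))
    list(as.numeric(Q %*% y))
  }
  onset <- 0.1
  times <- occ$time[occ$time >= onset]
  sol <- deSolve::lsoda(c(0, 1, 0, 0), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  pkg <- as.matrix(occ[occ$time >= onset, c("D", "C", "O", "B")])
  expect_lt(max(abs(pkg - sol[, 2:5])), 1e-6)
})

test_that("propagation rejects degenerate inputs", {
  p <- params_for(wt_2a_rates)
  expect_error(application_protocol(data.frame()), "non-empty")
  expect_error(propagate_states(p, control_protocol(5), dt = 0.2),
               "shortest")
  expect_error(propagate_states(p, control_protocol(5), dt = -1),
               "positive")
})

test_that("simulated current is inward-negative and scales with occupancy", {
  p <- params_for(wt_2a_rates)
  # no agonist anywhere -> zero current
  quiet <- application_protocol(data.frame(t_start = 0, t_end = 1,
                                           glutamate = 0, glycine = 30))
  tr0 <- simulate_current(p, quiet)
  expect_true(all(tr0$current == 0))
  # inward sign convention at -60 mV
  tr <- simulate_current(p, control_protocol(20), gain = 500)
  expect_true(all(tr$current <= 0))
  # steady-state : peak ratio against a fine-grid ODE oracle
  skip_if_not_installed("deSolve")
  rhs <- function(t, y, parms) list(as.numeric(rate_matrix(p, 0) %*% y))
  sol <- deSolve::lsoda(c(0, 1, 0, 0), seq(0, 20, by = 1e-4), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  ratio_oracle <- unname(sol[nrow(sol), 4] / max(sol[, 4]))
  pk <- max(abs(tr$current))
  ss <- abs(tr$current[length(tr$current)])
  expect_equal(ss / pk, ratio_oracle, tolerance = 1e-3)
  expect_equal(ratio_oracle, 0.61, tolerance = 0.01)
})

test_that("the recording-chain emulation preserves amplitudes approximately", {
  p <- params_for(wt_2a_rates)
  tr_raw <- simulate_current(p, control_protocol(3), filter_on = FALSE)
  tr_flt <- simulate_current(p, control_protocol(3), filter_on = TRUE)
  expect_equal(tr_flt$sampling_rate, 5000)
  # 2 kHz filtering and 10 ms exchange round the peak but leave the
  # steady state intact
  expect_equal(abs(tr_flt$current[length(tr_flt$current)]),
               abs(tr_raw$current[length(tr_raw$current)]),
               tolerance = 0.02)
  expect_lt(max(abs(tr_flt$current)), max(abs(tr_raw$current)) + 1e-9)
})

test_that("protocol and trace serialization round-trips", {
  proto <- application_protocol(data.frame(
    t_start = c(0, 1 / 3), t_end = c(1 / 3, 2 / 3 + 1e-9),
    glutamate = c(0, 1000 * pi / 3), glycine = 30,
    mk801 = c(0, sqrt(2)), steroid_id = c(NA, "PE-S"),
    steroid_conc = c(0, 100)), exchange_tau = 0.01)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_protocol(proto, f)
  rt <- read_protocol(f)
  expect_identical(rt$segments$t_end, proto$segments$t_end)
  expect_identical(rt$segments$mk801, proto$segments$mk801)
  expect_identical(rt$exchange_tau, proto$exchange_tau)
  expect_identical(rt$segments$steroid_id, proto$segments$steroid_id)

  tr <- simulate_current(params_for(wt_2a_rates), control_protocol(0.5))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, tf)
  tr2 <- read_trace(tf)
  expect_identical(tr2$current, tr$current)
  expect_identical(tr2$time, tr$time)
  expect_s3_class(tr2$protocol, "application_protocol")

  expect_error(new_trace(c(0, 1e-3, 2.5e-3), c(0, 0, 0), 1000),
               "uniform")
  expect_error(new_trace(c(0, 1e-3), c(0, NA), 1000), "non-finite")
})
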