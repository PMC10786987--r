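# Deterministic propagation of the four-state gating scheme.
#
# Within a protocol segment the generator is constant, so the occupancy
# vector evolves as P(t) = expm(Q t) P0. For speed the propagator uses the
# eigendecomposition of Q (one 4x4 eigenproblem per segment, then a single
# matrix product for all requested times); when Q is defective or badly
# conditioned it falls back to stepwise Matrix::expm().

# occupancies at times tvec (>= 0, relative to P0) under constant Q
propagate_constant_Q <- function(Q, P0, tvec) {
  if (length(tvec) == 0L) return(matrix(numeric(0), nrow = 4))
  e <- eigen(Q)
  ok <- is.finite(rcond(e$vectors)) && rcond(e$vectors) > 1e-10
  if (ok) {
    coef <- solve(e$vectors, P0)
    out <- e$vectors %*% (exp(outer(e$values, tvec)) * coef)
    out <- Re(out)
    # eigendecomposition can leak round-off at the 1e-16 level into
    # states that are exactly unreachable (e.g. O when k_o = 0); zap it
    out[abs(out) < 1e-14] <- 0
    if (max(abs(colSums(out) - 1)) < 1e-8) return(out)
  }
  # fallback: scaling-and-squaring matrix exponential, stepwise
  out <- matrix(0, 4, length(tvec))
  ord <- order(tvec)
  P <- P0
  tprev <- 0
  for (j in ord) {
    dt <- tvec[j] - tprev
    if (dt > 0) P <- as.matrix(Matrix::expm(Q * dt)) %*% P
    out[, j] <- P
    tprev <- tvec[j]
  }
  out
}

#' State occupancies under an application protocol
#'
#' Propagates the four-state scheme (D, C, O, B) across the protocol's
#' segments on a uniform time grid. The model omits agonist binding, so
#' before glutamate onset the receptor is held at the resting assignment
#' C = 1, D = O = B = 0; propagation starts at onset and is continuous at
#' segment boundaries. Probability is conserved exactly up to numerical
#' round-off.
#'
#' @param params a [kinetic_params()] object.
#' @param protocol an [application_protocol()].
#' @param dt time step of the output grid, s. Must not exceed the
#'   shortest protocol segment.
#' @return A data frame of class `state_occupancy` with columns `time`,
#'   `D`, `C`, `O`, `B`.
#' @examples
#' p <- kinetic_params(0.47, 0.59, 47.22, 200)
#' occ <- propagate_states(p, glu_step_protocol(t_app = 5), dt = 1e-3)
#' max(abs(rowSums(occ[, c("D", "C", "O", "B")]) - 1)) # conservation
#' @export
propagate_states <- function(params, protocol, dt) {
  if (!inherits(protocol, "application_protocol"))
    stop("protocol must be an application_protocol", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  seg <- protocol$segments
  if (dt > min(seg$t_end - seg$t_start))
    stop("dt is larger than the shortest protocol segment", call. = FALSE)
  tr <- protocol_t_range(protocol)
  time <- seq(tr[1], tr[2], by = dt)
  occ <- matrix(0, nrow = length(time), ncol = 4,
                dimnames = list(NULL, state_names))
  occ[, "C"] <- 1
  onset <- glutamate_onset(protocol)
  if (!is.na(onset)) {
    P <- c(D = 0, C = 1, O = 0, B = 0)
    active <- which(time >= onset - 1e-12)
    # walk segments from the one containing onset; propagate the grid
    # points inside each, then carry the exact boundary state over
    i0 <- protocol_segment_at(protocol, onset)
    t_cursor <- onset
    for (si in i0:nrow(seg)) {
      Q <- rate_matrix(params, mk801 = seg$mk801[si])
      t_stop <- seg$t_end[si]
      idx <- active[time[active] > t_cursor - 1e-12 &
                    time[active] <= t_stop + 1e-12]
      if (length(idx)) {
        occ[idx, ] <- t(propagate_constant_Q(Q, P, time[idx] - t_cursor))
      }
      if (si < nrow(seg)) {
        P <- drop(propagate_constant_Q(Q, P, t_stop - t_cursor))
        t_cursor <- t_stop
      }
    }
  }
  out <- data.frame(time = time, occ)
  class(out) <- c("state_occupancy", "data.frame")
  out
}

# -- 4-pole Bessel low-pass ---------------------------------------------------

# Digital 4-pole Bessel low-pass (forward only), the standard patch-clamp
# anti-alias filter shape. The analog prototype poles are the roots of the
# reversed Bessel polynomial s^4 + 10 s^3 + 45 s^2 + 105 s + 105, scaled by
# the 4th-order -3 dB normalization factor 2.113918, then discretized with
# the bilinear transform.
bessel4_coefficients <- function(fc, fs) {
  poles <- polyroot(c(105, 105, 45, 10, 1))
  w3 <- 2.113917675
  Sp <- poles * (2 * pi * fc) / w3
  Sg <- Re(prod(-Sp))
  zp <- signal::bilinear(Sz = numeric(0), Sp = Sp, Sg = Sg, T = 1 / fs)
  signal::as.Arma(zp)
}

bessel4_lowpass <- function(x, fc, fs) {
  ar <- bessel4_coefficients(fc, fs)
  as.numeric(signal::filter(Re(ar$b), Re(ar$a), x))
}

# exponential relaxation of a piecewise-constant target (solution exchange):
# y[n] = (1 - a) x[n] + a y[n-1], a = exp(-dt/tau), on a uniform grid
exchange_relax <- function(x, dt, tau, y0 = x[1]) {
  if (tau <= 0) return(x)
  a <- exp(-dt / tau)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive", init = y0))
}

#' Simulate a macroscopic whole-cell current trace
#'
#' Maps open-state occupancy to an inward current at -60 mV:
#' `I(t) = -gain * O(t)`. With `filter_on = TRUE` the simulation emulates
#' the recording chain: MK-801 concentration relaxes toward each
#' segment's nominal value with the solution-exchange time constant
#' (which shapes the generator), the current envelope is smoothed at
#' glutamate transitions with the same constant, a 4-pole Bessel low-pass
#' at `filter_hz` is applied forward, and the result is resampled at
#' `sampling_rate`. With `filter_on = FALSE` the trace is the noiseless,
#' unfiltered model current on the `1/sampling_rate` grid.
#'
#' @param params a [kinetic_params()] object.
#' @param protocol an [application_protocol()].
#' @param gain current per unit open probability, pA (> 0).
#' @param filter_on apply solution-exchange and low-pass shaping?
#' @param sampling_rate output sampling rate, Hz.
#' @param filter_hz low-pass corner frequency, Hz.
#' @param cell_id,genotype labels carried on the trace.
#' @return A [new_trace()] object.
#' @export
simulate_current <- function(params, protocol, gain = 500,
                             filter_on = FALSE, sampling_rate = 5000,
                             filter_hz = 2000, cell_id = NA_character_,
                             genotype = NA_character_) {
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) || gain <= 0)
    stop("gain must be a single positive number", call. = FALSE)
  if (!filter_on) {
    occ <- propagate_states(params, protocol, dt = 1 / sampling_rate)
    glu <- protocol$segments$glutamate[protocol_segment_at(protocol, occ$time)]
    cur <- -gain * occ$O * as.numeric(glu > 0)
    return(new_trace(occ$time, cur, sampling_rate, protocol = protocol,
                     cell_id = cell_id, genotype = genotype))
  }
  fs_int <- max(10 * filter_hz, 4 * sampling_rate)  # internal rate, Hz
  dt <- 1 / fs_int
  tau <- protocol$exchange_tau
  tr <- protocol_t_range(protocol)
  time <- seq(tr[1], tr[2], by = dt)
  segi <- protocol_segment_at(protocol, time)
  mk_nom <- protocol$segments$mk801[segi]
  glu_nom <- as.numeric(protocol$segments$glutamate[segi] > 0)
  mk_eff <- exchange_relax(mk_nom, dt, tau, y0 = mk_nom[1])
  env <- exchange_relax(glu_nom, dt, tau, y0 = glu_nom[1])

  onset <- glutamate_onset(protocol)
  occ_O <- numeric(length(time))
  if (!is.na(onset)) {
    P <- c(0, 1, 0, 0)
    start <- which(time >= onset - 1e-12)[1]
    # during the exchange transient the generator is time-varying: step
    # with per-sample expm-free first-order splitting at dt <= 0.1 ms;
    # once mk_eff has settled (within 1e-6 uM) use the constant-Q fast path
    i <- start
    n <- length(time)
    while (i <= n) {
      settle <- abs(mk_eff[i:n] - mk_nom[i:n]) < 1e-6
      run_end <- if (all(settle)) n else i + which(!settle)[1] - 2L
      if (run_end >= i && all(mk_nom[i:run_end] == mk_nom[i]) &&
          run_end > i + 1L) {
        # constant concentration run (also requires staying in one segment)
        seg_end <- max(which(segi == segi[i]))
        run_end <- min(run_end, seg_end)
        Q <- rate_matrix(params, mk801 = mk_nom[i])
        block <- propagate_constant_Q(Q, P, (seq(i, run_end) - i) * dt)
        occ_O[i:run_end] <- block[3, ]
        P <- block[, ncol(block)]
        i <- run_end + 1L
      } else {
        Q <- rate_matrix(params, mk801 = mk_eff[i])
        P <- drop(as.matrix(Matrix::expm(Q * dt)) %*% P)
        occ_O[i] <- P[3]
        i <- i + 1L
      }
    }
  }
  cur <- -gain * occ_O * env
  cur <- bessel4_lowpass(cur, filter_hz, fs_int)
  keep <- seq(1, length(time), by = round(fs_int / sampling_rate))
  new_trace(time[keep], cur[keep], sampling_rate, protocol = protocol,
            cell_id = cell_id, genotype = genotype)
}
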