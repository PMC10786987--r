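# Amplitude and desensitization analysis of agonist-evoked currents.

# default analysis window: glutamate onset to the end of the last
# contiguous glutamate-containing segment
default_window <- function(trace) {
  if (is.null(trace$protocol))
    return(range(trace$time))
  s <- trace$protocol$segments
  on <- which(s$glutamate > 0)
  if (length(on) == 0L) return(range(trace$time))
  i0 <- min(on)
  i1 <- i0
  while (i1 + 1L <= nrow(s) && (i1 + 1L) %in% on &&
         abs(s$t_start[i1 + 1L] - s$t_end[i1]) < 1e-12) i1 <- i1 + 1L
  c(s$t_start[i0], s$t_end[i1])
}

window_index <- function(trace, window) {
  idx <- which(trace$time >= window[1] - 1e-12 & trace$time <= window[2] + 1e-12)
  if (length(idx) < 10L)
    stop("analysis window holds fewer than 10 samples", call. = FALSE)
  idx
}

#' Peak and steady-state amplitude of an agonist-evoked response
#'
#' Measures the peak amplitude `I_P` (maximum of `|current|` after a
#' 3-sample median filter) and the steady-state amplitude `I_SS` inside
#' the application window. `I_SS` is by default the plateau of the
#' single-exponential desensitization fit; `method = "tail"` instead uses
#' the mean of `|current|` over the final 10 % of the window.
#'
#' @param trace a [new_trace()] object.
#' @param window `c(t0, t1)` in s; defaults to the glutamate application.
#' @param method `"fit"` (exponential plateau) or `"tail"`.
#' @return Named numeric vector `c(I_P =, I_SS =)`, pA magnitudes. For an
#'   all-zero trace, `c(0, 0)` with a warning and attribute
#'   `flag = "zero_trace"`.
#' @export
measure_peak_ss <- function(trace, window = NULL,
                            method = c("fit", "tail")) {
  method <- match.arg(method)
  if (is.null(window)) window <- default_window(trace)
  idx <- window_index(trace, window)
  y <- abs(trace$current[idx])
  if (all(y == 0)) {
    warning("trace is identically zero inside the window")
    return(structure(c(I_P = 0, I_SS = 0), flag = "zero_trace"))
  }
  ys <- stats::runmed(y, 3)
  I_P <- max(ys)
  if (method == "tail") {
    tail_idx <- idx[seq.int(ceiling(0.9 * length(idx)), length(idx))]
    I_SS <- mean(abs(trace$current[tail_idx]))
  } else {
    fit <- fit_desensitization(trace, window = window)
    I_SS <- fit$I_SS
    I_P <- fit$I_P
  }
  c(I_P = I_P, I_SS = I_SS)
}

#' Desensitization metrics from amplitudes and the decay time constant
#'
#' Desensitization is the percent decline from peak to plateau,
#' `D = 100 (1 - I_SS / I_P)`. When the single-exponential decay time
#' constant `tau_d` is supplied, the lumped desensitization and
#' resensitization rate constants follow as `k_d = D_fraction / tau_d`
#' and `k_r = (1 - D_fraction) / tau_d` (with `D` as a fraction — the
#' only dimensionally consistent reading).
#'
#' @param I_P peak amplitude magnitude (> 0).
#' @param I_SS steady-state amplitude magnitude (0 <= I_SS <= I_P).
#' @param tau_d desensitization time constant, s (optional).
#' @return List with `D_percent`, `D_fraction`, `k_d`, `k_r`.
#' @examples
#' desensitization_metrics(1.00, 0.58)$D_percent # 42
#' @export
desensitization_metrics <- function(I_P, I_SS, tau_d = NA_real_) {
  if (!is.finite(I_P) || I_P <= 0)
    stop("I_P must be a positive finite amplitude", call. = FALSE)
  if (!is.finite(I_SS) || I_SS < 0)
    stop("I_SS must be a non-negative finite amplitude", call. = FALSE)
  D_fraction <- 1 - I_SS / I_P
  D_fraction <- min(max(D_fraction, 0), 1)
  list(D_percent = 100 * D_fraction,
       D_fraction = D_fraction,
       k_d = if (is.na(tau_d)) NA_real_ else D_fraction / tau_d,
       k_r = if (is.na(tau_d)) NA_real_ else (1 - D_fraction) / tau_d)
}

#' Single-exponential fit of desensitization onset
#'
#' Fits `|I(t)| = I_SS + (I_P - I_SS) exp(-(t - t_peak)/tau_d)` from the
#' detected peak to the end of the window by unweighted least squares,
#' then derives the desensitization metrics (percent desensitization and
#' the rate constants `k_d`, `k_r`).
#'
#' @param trace a [new_trace()] object.
#' @param window `c(t0, t1)` in s; defaults to the glutamate application.
#' @return An object of class `desens_fit`: list with `I_P`, `I_SS`,
#'   `tau_d` (s), `D_percent`, `D_fraction`, `k_d`, `k_r` (1/s),
#'   `fit_residual` (RMS, pA) and `flag` (`NA` or `"non_decaying"`).
#' @export
fit_desensitization <- function(trace, window = NULL) {
  if (is.null(window)) window <- default_window(trace)
  idx <- window_index(trace, window)
  t <- trace$time[idx]
  y <- abs(trace$current[idx])
  ys <- stats::runmed(y, 3)
  ipk <- which.max(ys)
  t_peak <- t[ipk]
  td <- t[ipk:length(t)] - t_peak
  yd <- y[ipk:length(y)]
  I_P0 <- ys[ipk]
  I_SS0 <- mean(yd[seq.int(ceiling(0.9 * length(yd)), length(yd))])
  flag <- NA_character_
  if (I_SS0 >= I_P0 || I_P0 <= 0 || length(td) < 10L) {
    return(structure(list(I_P = I_P0, I_SS = I_P0, tau_d = NA_real_,
                          D_percent = 0, D_fraction = 0,
                          k_d = NA_real_, k_r = NA_real_,
                          fit_residual = NA_real_, flag = "non_decaying"),
                     class = "desens_fit"))
  }
  span <- max(td)
  fit <- try(minpack.lm::nlsLM(
    yd ~ iss + (ip - iss) * exp(-td / tau),
    start = list(ip = I_P0, iss = I_SS0, tau = span / 5),
    lower = c(ip = 0, iss = 0, tau = 1e-3),
    upper = c(ip = Inf, iss = Inf, tau = 100),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    cf <- c(ip = I_P0, iss = I_SS0, tau = span / 5)
    resid_rms <- NA_real_
    flag <- "fit_failed"
  } else {
    cf <- stats::coef(fit)
    resid_rms <- sqrt(mean(stats::resid(fit)^2))
  }
  if (cf[["iss"]] >= cf[["ip"]]) {
    flag <- "non_decaying"
    m <- list(D_percent = 0, D_fraction = 0, k_d = NA_real_, k_r = NA_real_)
    cf[["iss"]] <- cf[["ip"]]
    tau_out <- NA_real_
  } else {
    m <- desensitization_metrics(cf[["ip"]], cf[["iss"]], cf[["tau"]])
    tau_out <- cf[["tau"]]
  }
  structure(list(I_P = cf[["ip"]], I_SS = cf[["iss"]], tau_d = tau_out,
                 D_percent = m$D_percent, D_fraction = m$D_fraction,
                 k_d = m$k_d, k_r = m$k_r, fit_residual = resid_rms,
                 flag = flag),
            class = "desens_fit")
}

#' @export
print.desens_fit <- function(x, ...) {
  cat(sprintf("Desensitization fit: I_P = %.3g, I_SS = %.3g, tau_d = %.3g s\n",
              x$I_P, x$I_SS, x$tau_d))
  cat(sprintf("  D = %.1f%%  k_d = %.3g 1/s  k_r = %.3g 1/s\n",
              x$D_percent, x$k_d, x$k_r))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Degree of steroid modulation
#'
#' `E = 100 (I_S - I_A) / I_A`, where `I_A` is the amplitude of the
#' agonist-alone response and `I_S` the amplitude in the presence of
#' agonist plus steroid. Positive `E` is potentiation, negative `E`
#' inhibition. `E` is invariant to a common scaling of both amplitudes.
#'
#' @param I_A agonist-alone amplitude (magnitude, > 0).
#' @param I_S agonist-plus-steroid amplitude (magnitude, >= 0).
#' @return List with `I_A`, `I_S` and `E` (percent, signed).
#' @examples
#' steroid_modulation(1.00, 2.04)$E # 104 (potentiation)
#' steroid_modulation(1.0, 0.5)$E  # -50 (inhibition)
#' @export
steroid_modulation <- function(I_A, I_S) {
  if (!is.finite(I_A) || I_A <= 0)
    stop("I_A must be a positive finite amplitude", call. = FALSE)
  if (!is.finite(I_S) || I_S < 0)
    stop("I_S must be a non-negative finite amplitude", call. = FALSE)
  list(I_A = I_A, I_S = I_S, E = 100 * (I_S - I_A) / I_A)
}
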