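# Macroscopic open-probability estimation from the onset of MK-801 block.
#
# MK-801 only enters open channels, so the decay of the glutamate response
# during MK-801 co-application reports how often the channel opens. With
# the desensitization rates fixed from a control response, the closing
# rate fixed by convention at 200 1/s and the blocking rate at
# 25 1/(uM s), the opening rate k_o is the single free parameter of the
# four-state model, and P_o = 100 k_o / (k_o + k_c).

#' Open probability from opening and closing rates
#'
#' @param k_o opening rate, 1/s (>= 0).
#' @param k_c closing rate, 1/s (> 0).
#' @return Open probability in percent, `100 k_o / (k_o + k_c)`.
#' @examples
#' po_from_rates(47.22, 200) # 19.1
#' @export
po_from_rates <- function(k_o, k_c) {
  if (any(!is.finite(k_o)) || any(k_o < 0))
    stop("k_o must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(k_c)) || any(k_c <= 0))
    stop("k_c must be finite and > 0", call. = FALSE)
  100 * k_o / (k_o + k_c)
}

#' Opening rate implied by a stated open probability
#'
#' Inverts [po_from_rates()]: `k_o = k_c P_o / (100 - P_o)`. Useful for
#' constructing simulations whose fitted open probability is known.
#'
#' @param P_o open probability, percent (0 <= P_o < 100).
#' @param k_c closing rate, 1/s.
#' @return Opening rate, 1/s.
#' @export
ko_from_po <- function(P_o, k_c = 200) {
  if (any(!is.finite(P_o)) || any(P_o < 0) || any(P_o >= 100))
    stop("P_o must be in [0, 100)", call. = FALSE)
  k_c * P_o / (100 - P_o)
}

# locate the first segment with glutamate and MK-801 co-applied
mk_segment <- function(trace) {
  if (is.null(trace$protocol))
    stop("trace carries no protocol; cannot locate the MK-801 segment",
         call. = FALSE)
  s <- trace$protocol$segments
  i <- which(s$glutamate > 0 & s$mk801 > 0)
  if (length(i) == 0L)
    stop("trace has no glutamate + MK-801 co-application segment",
         call. = FALSE)
  min(i)
}

#' Fit the opening rate to the onset of MK-801 block
#'
#' Normalizes the measured response to its own peak inside the MK-801
#' co-application, simulates the four-state model under the same protocol
#' with `k_d`, `k_r`, `k_c` and `k_b` fixed, normalizes the model current
#' to its own peak over the same window, and minimizes the RMS difference
#' with `k_o` as the single free parameter in (0, 1e4) 1/s. The window
#' runs from the peak of the MK-801-condition response to the end of the
#' co-application. The bounded scalar search is restarted from three
#' log-spaced intervals; a solution at the bound is flagged.
#'
#' @param mk_trace trace recorded with glutamate + MK-801 co-applied
#'   (must carry its protocol).
#' @param k_d,k_r desensitization/resensitization rates held fixed, 1/s.
#' @param k_c closing rate held fixed, 1/s.
#' @param k_b MK-801 blocking rate held fixed, 1/(uM s).
#' @param k_u unblocking rate, 1/s (default 0: irreversible block).
#' @return An object of class `po_fit`: list with `k_o`, `P_o` (percent,
#'   via [po_from_rates()]), the fixed constants, `fit_residual` (RMS of
#'   normalized current) and `flag` (`NA` or `"at_bound"`).
#' @export
fit_ko <- function(mk_trace, k_d, k_r, k_c = 200, k_b = 25, k_u = 0) {
  si <- mk_segment(mk_trace)
  seg <- mk_trace$protocol$segments[si, ]
  idx <- which(mk_trace$time >= seg$t_start - 1e-12 &
               mk_trace$time <= seg$t_end + 1e-12)
  if (length(idx) < 10L)
    stop("MK-801 segment holds fewer than 10 samples", call. = FALSE)
  yobs <- abs(mk_trace$current[idx])
  if (max(yobs) <= 0)
    stop("MK-801-condition response is identically zero", call. = FALSE)
  ipk <- which.max(stats::runmed(yobs, 3))
  fit_idx <- ipk:length(idx)
  yobs_n <- yobs / max(yobs)

  sim_norm <- function(k_o) {
    p <- kinetic_params(k_d = k_d, k_r = k_r, k_o = k_o, k_c = k_c,
                        k_b = k_b, k_u = k_u)
    sim <- simulate_current(p, mk_trace$protocol, gain = 1,
                            filter_on = FALSE,
                            sampling_rate = mk_trace$sampling_rate)
    ysim <- abs(sim$current[idx])
    pk <- max(ysim)
    if (pk <= 0) return(NULL)
    ysim / pk
  }
  objective <- function(log10_ko) {
    ysim_n <- sim_norm(10^log10_ko)
    if (is.null(ysim_n)) return(1e6)
    sqrt(mean((ysim_n[fit_idx] - yobs_n[fit_idx])^2))
  }
  lo <- -3; hi <- 4
  starts <- list(c(lo, 1), c(0, 3), c(1, hi))
  best <- NULL
  for (iv in starts) {
    o <- stats::optimize(objective, interval = iv, tol = 1e-10)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  # polish over the full interval around the best point
  o <- stats::optimize(objective,
                       interval = c(max(lo, best$minimum - 0.5),
                                    min(hi, best$minimum + 0.5)),
                       tol = 1e-12)
  if (o$objective < best$objective) best <- o
  k_o <- 10^best$minimum
  flag <- if (best$minimum <= lo + 1e-6 || best$minimum >= hi - 1e-6)
    "at_bound" else NA_character_
  structure(list(k_o = k_o, P_o = po_from_rates(k_o, k_c),
                 k_c_fixed = k_c, k_d_fixed = k_d, k_r_fixed = k_r,
                 k_b_fixed = k_b, k_u_fixed = k_u, mk801 = seg$mk801,
                 fit_residual = best$objective, flag = flag),
            class = "po_fit")
}

#' @export
print.po_fit <- function(x, ...) {
  cat(sprintf("Open-probability fit: k_o = %.4g 1/s -> P_o = %.2f%%\n",
              x$k_o, x$P_o))
  cat(sprintf("  fixed: k_d = %.3g, k_r = %.3g, k_c = %g 1/s, k_b = %g 1/(uM s), [MK-801] = %g uM\n",
              x$k_d_fixed, x$k_r_fixed, x$k_c_fixed, x$k_b_fixed, x$mk801))
  cat(sprintf("  RMS residual (normalized current) = %.3g\n", x$fit_residual))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Two-step open-probability estimation
#'
#' Step 1 fits the single-exponential desensitization of the control
#' response (1 mM glutamate, no MK-801) and converts it to the lumped
#' rates `k_d = D/tau_d`, `k_r = (1 - D)/tau_d` (`D` as a fraction).
#' Step 2 fixes those rates (plus `k_c` and `k_b`) and fits the opening
#' rate `k_o` to the onset of MK-801 block ([fit_ko()]). A flat control
#' response gives `k_d = 0` and step 2 proceeds.
#'
#' @param control_trace glutamate response without MK-801.
#' @param mk_trace glutamate + MK-801 response (with protocol).
#' @param k_c,k_b,k_u fixed rate constants, as in [fit_ko()].
#' @return A `po_fit` (see [fit_ko()]) with the step-1 `desens_fit`
#'   attached as `$step1`.
#' @export
estimate_po_two_step <- function(control_trace, mk_trace, k_c = 200,
                                 k_b = 25, k_u = 0) {
  d <- fit_desensitization(control_trace)
  k_d <- if (is.na(d$k_d)) 0 else d$k_d
  k_r <- if (is.na(d$k_r)) {
    # flat response: no desensitization observed; make D<->C exchange inert
    0
  } else d$k_r
  fit <- fit_ko(mk_trace, k_d = k_d, k_r = k_r, k_c = k_c, k_b = k_b,
                k_u = k_u)
  fit$step1 <- d
  fit
}
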