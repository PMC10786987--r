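#' Rate constants of the four-state NMDAR gating scheme
#'
#' Bundles the six rate constants of the lumped gating scheme
#' `D <-> C <-> O <-> B`, where `D` is the desensitized, `C` the closed
#' (doubly liganded), `O` the open and `B` the MK-801-blocked state.
#' Agonist binding steps are not modeled: at a saturating glutamate
#' concentration the receptor is assumed fully liganded, so the scheme
#' starts at `C` on agonist onset.
#'
#' @param k_d desensitization rate C -> D, 1/s.
#' @param k_r resensitization rate D -> C, 1/s.
#' @param k_o opening rate C -> O, 1/s.
#' @param k_c closing rate O -> C, 1/s. Conventionally fixed at 200 1/s in
#'   open-probability estimation.
#' @param k_b MK-801 blocking rate O -> B, 1/(uM s). Conventionally 25.
#' @param k_u MK-801 unblocking rate B -> O, 1/s. Defaults to 0: on the
#'   timescale of a whole-cell recording MK-801 block is effectively
#'   irreversible.
#'
#' @return An object of class `kinetic_params`: a named list of the six
#'   rates.
#' @examples
#' kinetic_params(k_d = 0.47, k_r = 0.59, k_o = 47.22, k_c = 200)
#' @export
kinetic_params <- function(k_d, k_r, k_o, k_c, k_b = 25, k_u = 0) {
  p <- list(k_d = k_d, k_r = k_r, k_o = k_o, k_c = k_c, k_b = k_b, k_u = k_u)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("rate '", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("rate '", nm, "' must be >= 0, got ", v, call. = FALSE)
  }
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Four-state NMDAR gating rates (D <-> C <-> O <-> B)\n")
  cat(sprintf("  k_d = %g 1/s   k_r = %g 1/s\n", x$k_d, x$k_r))
  cat(sprintf("  k_o = %g 1/s   k_c = %g 1/s\n", x$k_o, x$k_c))
  cat(sprintf("  k_b = %g 1/(uM s)   k_u = %g 1/s\n", x$k_b, x$k_u))
  invisible(x)
}

state_names <- c("D", "C", "O", "B")

#' Generator matrix of the four-state scheme
#'
#' Builds the infinitesimal generator `Q` over the states (D, C, O, B)
#' such that the occupancy column vector `P` evolves as `dP/dt = Q P`.
#' The O -> B rate is the product of the blocking rate constant `k_b` and
#' the MK-801 concentration; every column sums to zero so total occupancy
#' is conserved.
#'
#' @param params a [kinetic_params()] object.
#' @param mk801 MK-801 concentration, uM (>= 0).
#' @return A 4 x 4 numeric matrix with dimnames `c("D","C","O","B")`.
#' @examples
#' p <- kinetic_params(0.47, 0.59, 47.22, 200)
#' rate_matrix(p, mk801 = 1)["B", "O"] # k_b * [MK-801] = 25
#' @export
rate_matrix <- function(params, mk801 = 0) {
  if (!inherits(params, "kinetic_params"))
    params <- do.call(kinetic_params, as.list(params))
  if (!is.numeric(mk801) || length(mk801) != 1L || !is.finite(mk801) || mk801 < 0)
    stop("mk801 concentration must be a single finite number >= 0", call. = FALSE)
  kon_b <- params$k_b * mk801
  Q <- matrix(0, 4, 4, dimnames = list(state_names, state_names))
  Q["C", "D"] <- params$k_r
  Q["D", "C"] <- params$k_d
  Q["O", "C"] <- params$k_o
  Q["C", "O"] <- params$k_c
  Q["B", "O"] <- kon_b
  Q["O", "B"] <- params$k_u
  diag(Q) <- -colSums(Q)
  Q
}
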