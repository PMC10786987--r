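# Hill-equation concentration-response fitting, per cell, with pooling
# on log10 EC50.

#' Normalize per-concentration response amplitudes
#'
#' Divides amplitudes by the maximal response — by default the amplitude
#' observed at the highest concentration. When the top concentration is
#' well above the EC50 (>= ~20x) this approximates the true fractional
#' occupancy closely.
#'
#' @param concentrations agonist concentrations, uM.
#' @param amplitudes response amplitudes (magnitudes), same length.
#' @return Numeric vector of normalized amplitudes.
#' @export
normalize_responses <- function(concentrations, amplitudes) {
  if (length(concentrations) != length(amplitudes))
    stop("concentrations and amplitudes must have the same length",
         call. = FALSE)
  if (length(unique(concentrations)) < 3L)
    stop("need responses at >= 3 distinct concentrations", call. = FALSE)
  ref <- amplitudes[which.max(concentrations)]
  if (!is.finite(ref) || ref <= 0)
    stop("maximal response amplitude must be positive", call. = FALSE)
  amplitudes / ref
}

#' Fit the Hill (logistic) concentration-response equation
#'
#' Fits `I = 1 / (1 + (EC50 / [agonist])^h)` to normalized responses by
#' nonlinear least squares, starting from the geometric mean of the
#' concentrations (EC50) and `h = 1`, with bounds
#' `EC50 in [1e-3, 1e4]` uM and `h in [0.3, 5]`. When `free_max = TRUE` a
#' third parameter scales the maximum.
#'
#' @param concentrations agonist concentrations, uM (>= 3 distinct).
#' @param response normalized response amplitudes in `[0, ~1]`.
#' @param agonist `"glutamate"` or `"glycine"` (metadata).
#' @param co_agonist_conc concentration of the co-agonist present, uM
#'   (metadata; glutamate curves are determined in the presence of 30 uM
#'   glycine and glycine curves in the presence of 1000 uM glutamate).
#' @param cell_id label (metadata).
#' @param free_max also fit the maximal response?
#' @return Object of class `hill_fit`: list with `EC50` (uM), `h`,
#'   `log10_EC50`, `I_max`, metadata, and `flag`
#'   (`"extrapolated"` when the fitted EC50 lies outside the tested
#'   concentration range).
#' @examples
#' cc <- c(0.3, 1, 3, 10, 30, 100)
#' fit_hill(cc, 1 / (1 + (5.0 / cc)^1.09))$EC50
#' @export
fit_hill <- function(concentrations, response,
                     agonist = c("glutamate", "glycine"),
                     co_agonist_conc = NA_real_, cell_id = NA_character_,
                     free_max = FALSE) {
  agonist <- match.arg(agonist)
  if (length(unique(concentrations)) < 3L)
    stop("need >= 3 distinct concentrations", call. = FALSE)
  if (any(concentrations <= 0))
    stop("concentrations must be positive", call. = FALSE)
  if (!is.na(co_agonist_conc)) {
    if (agonist == "glutamate" && co_agonist_conc != 30)
      stop("glutamate curves are determined in the presence of 30 uM glycine",
           call. = FALSE)
    if (agonist == "glycine" && co_agonist_conc != 1000)
      stop("glycine curves are determined in the presence of 1 mM glutamate",
           call. = FALSE)
  }
  df <- data.frame(conc = concentrations, y = response)
  ec0 <- exp(mean(log(concentrations)))
  if (free_max) {
    fit <- minpack.lm::nlsLM(
      y ~ imax / (1 + (ec50 / conc)^h), data = df,
      start = list(ec50 = ec0, h = 1, imax = 1),
      lower = c(ec50 = 1e-3, h = 0.3, imax = 0.1),
      upper = c(ec50 = 1e4, h = 5, imax = 10))
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ 1 / (1 + (ec50 / conc)^h), data = df,
      start = list(ec50 = ec0, h = 1),
      lower = c(ec50 = 1e-3, h = 0.3),
      upper = c(ec50 = 1e4, h = 5))
  }
  cf <- stats::coef(fit)
  flag <- if (cf[["ec50"]] < min(concentrations) ||
              cf[["ec50"]] > max(concentrations)) "extrapolated"
          else NA_character_
  structure(list(EC50 = cf[["ec50"]], h = cf[["h"]],
                 log10_EC50 = log10(cf[["ec50"]]),
                 I_max = if (free_max) cf[["imax"]] else 1,
                 agonist = agonist, co_agonist_conc = co_agonist_conc,
                 cell_id = cell_id,
                 fit_residual = sqrt(mean(stats::resid(fit)^2)),
                 flag = flag),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (%s): EC50 = %.3g uM, h = %.3g\n",
              x$agonist, x$EC50, x$h))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Pool per-cell Hill fits
#'
#' Summarizes per-cell fits per genotype. EC50 statistics are computed on
#' `log10(EC50)` (so the reported central EC50 is the geometric mean);
#' Hill slopes are averaged arithmetically.
#'
#' @param fits a list of `hill_fit` objects or a data frame with columns
#'   `genotype`, `EC50`, `h`.
#' @return Data frame with one row per genotype: `n`, `log10_EC50_mean`,
#'   `log10_EC50_sem`, `EC50` (geometric mean, uM), `h_mean`, `h_sem`.
#' @export
pool_fits <- function(fits) {
  if (is.list(fits) && !is.data.frame(fits)) {
    fits <- do.call(rbind, lapply(fits, function(f) data.frame(
      genotype = if (is.null(f$genotype)) NA_character_ else f$genotype,
      cell_id = f$cell_id, EC50 = f$EC50, h = f$h)))
  }
  if (nrow(fits) < 1L) stop("need at least one fit", call. = FALSE)
  if (is.null(fits$genotype)) fits$genotype <- NA_character_
  fits$genotype[is.na(fits$genotype)] <- "(unspecified)"
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  out <- do.call(rbind, lapply(split(fits, fits$genotype, drop = TRUE),
    function(g) data.frame(
      genotype = g$genotype[1], n = nrow(g),
      log10_EC50_mean = mean(log10(g$EC50)),
      log10_EC50_sem = sem(log10(g$EC50)),
      EC50 = 10^mean(log10(g$EC50)),
      h_mean = mean(g$h), h_sem = sem(g$h))))
  rownames(out) <- NULL
  out
}

#' Fit the Hill equation per cell from a long-format table
#'
#' @param table data frame with columns `cell_id`, `concentration_uM`,
#'   `amplitude_pA` and optionally `genotype`.
#' @param agonist,co_agonist_conc,free_max passed to [fit_hill()]. The
#'   default max-normalization pins the top-concentration point at 1,
#'   which biases EC50 slightly low when the top concentration does not
#'   fully saturate; `free_max = TRUE` removes that bias.
#' @return A list of `hill_fit` objects (one per cell) with `genotype`
#'   attached.
#' @export
fit_hill_per_cell <- function(table, agonist = "glutamate",
                              co_agonist_conc = NA_real_,
                              free_max = FALSE) {
  stopifnot(all(c("cell_id", "concentration_uM", "amplitude_pA") %in%
                  names(table)))
  lapply(split(table, table$cell_id), function(d) {
    y <- normalize_responses(d$concentration_uM, abs(d$amplitude_pA))
    f <- fit_hill(d$concentration_uM, y, agonist = agonist,
                  co_agonist_conc = co_agonist_conc,
                  cell_id = as.character(d$cell_id[1]),
                  free_max = free_max)
    f$genotype <- if (is.null(d$genotype)) NA_character_ else
      as.character(d$genotype[1])
    f
  })
}
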