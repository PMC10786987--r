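# Seeded synthetic-data generators with ground truth for every analysis
# substrate: current traces from the four-state model, per-cell Hill
# dose-response datasets, HEK-cell surface/intracellular images, and
# dendrite images with two punctate channels of controlled overlap.
# Every generator records its parameters and seed in a ground-truth
# object that can be written as a YAML sidecar; regeneration with the
# same seed is bit-identical.

new_ground_truth <- function(kind, params, seed) {
  structure(list(kind = kind, params = params, seed = seed),
            class = "ground_truth")
}

#' Write / read a ground-truth sidecar
#'
#' @param gt a ground-truth object (returned in `$ground_truth` by the
#'   generators).
#' @param path YAML file path.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` the ground-truth list.
#' @export
write_ground_truth <- function(gt, path) {
  yaml::write_yaml(list(kind = gt$kind, seed = gt$seed,
                        params = rapply(gt$params, function(v)
                          if (is.numeric(v)) sprintf("%.17g", v) else v,
                          how = "replace")), path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  y <- yaml::read_yaml(path)
  y$params <- rapply(y$params, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!anyNA(n)) n else v
  }, how = "replace")
  new_ground_truth(y$kind, y$params, y$seed)
}

#' Synthetic whole-cell current trace
#'
#' Simulates the four-state model under `protocol` (with the recording
#' chain emulated when `filter_on`: ~10 ms solution exchange, 2 kHz
#' 4-pole Bessel low-pass, 5 kHz sampling) and adds Gaussian noise with
#' SD equal to `noise_sd` times the peak amplitude.
#'
#' @param params a [kinetic_params()] object.
#' @param protocol an [application_protocol()].
#' @param noise_sd noise SD as a fraction of the peak amplitude (>= 0).
#' @param seed RNG seed.
#' @param gain peak scaling, pA per unit open probability; the default
#'   puts typical peaks near -500 pA.
#' @param filter_on emulate exchange and low-pass filtering?
#' @param sampling_rate output sampling rate, Hz.
#' @param genotype,cell_id labels.
#' @return List with `trace` and `ground_truth`.
#' @export
gen_trace <- function(params, protocol, noise_sd = 0.02, seed = 1,
                      gain = 2500, filter_on = TRUE, sampling_rate = 5000,
                      genotype = NA_character_, cell_id = NA_character_) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  tr <- simulate_current(params, protocol, gain = gain,
                         filter_on = filter_on,
                         sampling_rate = sampling_rate,
                         genotype = genotype, cell_id = cell_id)
  if (noise_sd > 0) {
    set.seed(seed)
    peak <- max(abs(tr$current))
    tr$current <- tr$current + stats::rnorm(length(tr$current),
                                            sd = noise_sd * peak)
  }
  gt <- new_ground_truth("trace",
    list(rates = unclass(params), noise_sd = noise_sd, gain = gain,
         filter_on = filter_on, sampling_rate = sampling_rate,
         P_o = po_from_rates(params$k_o, params$k_c)), seed)
  list(trace = tr, ground_truth = gt)
}

#' Synthetic per-cell dose-response dataset
#'
#' Per-cell amplitudes follow the Hill equation at the given EC50 and
#' slope, scaled by `max_amplitude_pA` and perturbed by multiplicative
#' Gaussian noise with coefficient of variation `noise_cv`.
#'
#' @param EC50 generating EC50, uM.
#' @param h generating Hill slope.
#' @param concentrations tested concentrations, uM. The default grid is
#'   half-log steps bracketing the EC50 by >= 1.5 decades on each side.
#' @param n_cells number of cells.
#' @param noise_cv multiplicative noise CV (>= 0).
#' @param seed RNG seed.
#' @param max_amplitude_pA saturating amplitude, pA.
#' @param genotype label.
#' @return List with `table` (cell_id, genotype, concentration_uM,
#'   amplitude_pA) and `ground_truth`.
#' @export
gen_dr_dataset <- function(EC50, h, concentrations = NULL, n_cells = 6,
                           noise_cv = 0.05, seed = 1,
                           max_amplitude_pA = 1000,
                           genotype = NA_character_) {
  if (n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  if (is.null(concentrations)) {
    lo <- floor((log10(EC50) - 1.5) * 2) / 2
    hi <- ceiling((log10(EC50) + 1.5) * 2) / 2
    concentrations <- 10^seq(lo, hi, by = 0.5)
  }
  set.seed(seed)
  frac <- 1 / (1 + (EC50 / concentrations)^h)
  tab <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    amp <- max_amplitude_pA * frac *
      (1 + stats::rnorm(length(frac), sd = noise_cv))
    data.frame(cell_id = sprintf("cell%02d", i), genotype = genotype,
               concentration_uM = concentrations, amplitude_pA = amp)
  }))
  gt <- new_ground_truth("dose_response",
    list(EC50 = EC50, h = h, concentrations = concentrations,
         n_cells = n_cells, noise_cv = noise_cv,
         max_amplitude_pA = max_amplitude_pA), seed)
  list(table = tab, ground_truth = gt)
}

# disk/annulus masks on a pixel grid
disk_mask <- function(nr, nc, cx, cy, r_in, r_out) {
  d2 <- outer(seq_len(nr) - cx, seq_len(nc) - cy,
              function(a, b) a^2 + b^2)
  d2 >= r_in^2 & d2 <= r_out^2
}

#' Synthetic HEK-cell surface/intracellular image
#'
#' Disk-shaped cells with an annular surface ring and an interior
#' intracellular fill on a uniform background. Ring and fill intensities
#' are set so that the ROI-mean surface-to-intracellular ratio after
#' exact background subtraction equals `true_ratio`. Optional Gaussian
#' noise and a linear illumination gradient.
#'
#' @param true_ratio planted surface/intracellular ratio (> 0).
#' @param cell_count number of cells.
#' @param background_level uniform background intensity.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @param size image side, pixels.
#' @param pixel_size um per pixel.
#' @param illumination_gradient peak-to-peak relative gradient (0 = flat).
#' @return List with `stack` (an [image_stack()] with channels
#'   `surface`, `intracellular`, ROIs `cell01`..., `background`) and
#'   `ground_truth`.
#' @export
gen_hek_image <- function(true_ratio, cell_count = 3, background_level = 20,
                          noise_sd = 0, seed = 1, size = 192,
                          pixel_size = 0.2, illumination_gradient = 0) {
  if (true_ratio <= 0) stop("true_ratio must be > 0", call. = FALSE)
  set.seed(seed)
  surf <- matrix(background_level, size, size)
  ic <- matrix(background_level, size, size)
  rois <- list()
  fill_intensity <- 100
  r_cell <- size / (3.2 * ceiling(sqrt(cell_count)))
  grid_n <- ceiling(sqrt(cell_count))
  centers <- expand.grid(
    x = seq(size / (grid_n + 1), size * grid_n / (grid_n + 1),
            length.out = grid_n),
    y = seq(size / (grid_n + 1), size * grid_n / (grid_n + 1),
            length.out = grid_n))[seq_len(cell_count), ]
  centers <- centers + matrix(stats::runif(2 * cell_count, -2, 2),
                              ncol = 2)
  for (i in seq_len(cell_count)) {
    full <- disk_mask(size, size, centers$x[i], centers$y[i], 0, r_cell)
    ring <- disk_mask(size, size, centers$x[i], centers$y[i],
                      0.8 * r_cell, r_cell)
    # ROI mean of surface channel must be true_ratio * fill_intensity
    ring_value <- true_ratio * fill_intensity * sum(full) / sum(ring)
    ic[full] <- background_level + fill_intensity
    surf[ring] <- background_level + ring_value
    rois[[sprintf("cell%02d", i)]] <- full
  }
  occupied <- Reduce(`|`, rois)
  rois$background <- !occupied &
    disk_mask(size, size, 1, 1, 0, size / 6)
  if (illumination_gradient > 0) {
    g <- 1 + illumination_gradient *
      (matrix(seq_len(size), size, size) / size - 0.5)
    surf <- surf * g
    ic <- ic * g
  }
  if (noise_sd > 0) {
    surf <- pmax(surf + matrix(stats::rnorm(size^2, sd = noise_sd),
                               size, size), 0)
    ic <- pmax(ic + matrix(stats::rnorm(size^2, sd = noise_sd),
                           size, size), 0)
  }
  stack <- image_stack(list(surface = surf, intracellular = ic),
                       pixel_size = pixel_size, rois = rois)
  gt <- new_ground_truth("hek_image",
    list(true_ratio = true_ratio, cell_count = cell_count,
         background_level = background_level, noise_sd = noise_sd,
         size = size, illumination_gradient = illumination_gradient),
    seed)
  list(stack = stack, ground_truth = gt)
}

# add a 2D Gaussian spot to an image
add_spot <- function(img, cx, cy, sigma_px, amplitude) {
  r <- ceiling(4 * sigma_px)
  xs <- max(1, round(cx) - r):min(nrow(img), round(cx) + r)
  ys <- max(1, round(cy) - r):min(ncol(img), round(cy) + r)
  g <- outer(xs - cx, ys - cy,
             function(a, b) exp(-(a^2 + b^2) / (2 * sigma_px^2)))
  img[xs, ys] <- img[xs, ys] + amplitude * g
  img
}

#' Synthetic dendrite image with two punctate channels
#'
#' Places Gaussian puncta for PSD-95 and surface receptors along a
#' simulated straight dendrite of stated length. A fraction
#' `planted_overlap_fraction` of the surface puncta is centered exactly
#' on PSD-95 puncta; the remainder is kept at least 4 punctum sigmas
#' away from every PSD-95 punctum.
#'
#' @param n_puncta_surface,n_puncta_psd95 planted punctum counts.
#' @param planted_overlap_fraction fraction of surface puncta on PSD-95
#'   puncta, in `[0, 1]`.
#' @param segment_length_um dendrite segment length, um.
#' @param pixel_size_um um per pixel.
#' @param seed RNG seed.
#' @param punctum_sigma_um Gaussian sigma of a punctum, um.
#' @param amplitude punctum peak intensity.
#' @param background_level,noise_sd background and additive noise.
#' @return List with `stack` (channels `surface`, `psd95`; ROI
#'   `dendrite`) and `ground_truth` (including punctum coordinates).
#' @export
gen_dendrite_image <- function(n_puncta_surface = 15, n_puncta_psd95 = 15,
                               planted_overlap_fraction = 0.5,
                               segment_length_um = 20,
                               pixel_size_um = 0.1, seed = 1,
                               punctum_sigma_um = 0.15, amplitude = 120,
                               background_level = 10, noise_sd = 2) {
  if (planted_overlap_fraction < 0 || planted_overlap_fraction > 1)
    stop("planted_overlap_fraction must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  len_px <- round(segment_length_um / pixel_size_um)
  wid_px <- round(2 / pixel_size_um)           # 2 um wide dendrite band
  nr <- wid_px + 20L
  nc <- len_px + 20L
  sig_px <- punctum_sigma_um / pixel_size_um
  band_r <- 11:(10 + wid_px)
  band_c <- 11:(10 + nc - 20L)

  rand_center <- function() c(stats::runif(1, min(band_r) + 2, max(band_r) - 2),
                              stats::runif(1, min(band_c) + 2, max(band_c) - 2))
  min_dist <- function(centers, cand) {
    if (is.null(centers) || nrow(centers) == 0L) return(Inf)
    sqrt(min((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2))
  }
  # rejection-sample centers so that puncta within a channel stay
  # resolvable (>= 6 sigma apart) and "off" surface puncta stay clear of
  # every PSD-95 punctum (>= 4 sigma)
  sep_px <- 6 * sig_px
  place <- function(n, avoid = NULL, avoid_d = 0, own = NULL) {
    centers <- own
    guard <- 0L
    while ((if (is.null(centers)) 0L else nrow(centers)) <
           n + (if (is.null(own)) 0L else nrow(own)) && guard < 20000L) {
      cand <- rand_center()
      if (min_dist(centers, cand) > sep_px &&
          min_dist(avoid, cand) > avoid_d)
        centers <- rbind(centers, cand)
      guard <- guard + 1L
    }
    got <- (if (is.null(centers)) 0L else nrow(centers)) -
      (if (is.null(own)) 0L else nrow(own))
    if (got < n)
      stop("could not place non-overlapping puncta; reduce counts or ",
           "overlap constraints", call. = FALSE)
    centers[seq.int((if (is.null(own)) 0L else nrow(own)) + 1L,
                    length.out = n), , drop = FALSE]
  }
  psd_centers <- place(n_puncta_psd95)
  n_on <- round(planted_overlap_fraction * n_puncta_surface)
  if (n_on > n_puncta_psd95)
    stop("planted overlap needs more PSD-95 puncta than available",
         call. = FALSE)
  on_centers <- if (n_on > 0)
    psd_centers[sample.int(n_puncta_psd95, n_on), , drop = FALSE]
  else NULL
  off_centers <- if (n_on < n_puncta_surface)
    place(n_puncta_surface - n_on, avoid = psd_centers,
          avoid_d = 4 * sig_px, own = on_centers)
  else NULL
  surf_centers <- rbind(on_centers, off_centers)
  rownames(surf_centers) <- NULL

  surf <- matrix(background_level, nr, nc)
  psd <- matrix(background_level, nr, nc)
  for (j in seq_len(n_puncta_psd95))
    psd <- add_spot(psd, psd_centers[j, 1], psd_centers[j, 2], sig_px,
                    amplitude)
  for (j in seq_len(n_puncta_surface))
    surf <- add_spot(surf, surf_centers[j, 1], surf_centers[j, 2], sig_px,
                     amplitude)
  if (noise_sd > 0) {
    surf <- pmax(surf + matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc), 0)
    psd <- pmax(psd + matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc), 0)
  }
  dendrite <- matrix(FALSE, nr, nc)
  dendrite[band_r, band_c] <- TRUE
  stack <- image_stack(list(surface = surf, psd95 = psd),
                       pixel_size = pixel_size_um,
                       rois = list(dendrite = dendrite))
  gt <- new_ground_truth("dendrite_image",
    list(n_puncta_surface = n_puncta_surface,
         n_puncta_psd95 = n_puncta_psd95,
         planted_overlap_fraction = planted_overlap_fraction,
         segment_length_um = segment_length_um,
         pixel_size_um = pixel_size_um,
         punctum_sigma_um = punctum_sigma_um,
         surface_centers = as.numeric(surf_centers),
         psd95_centers = as.numeric(psd_centers)), seed)
  list(stack = stack, ground_truth = gt)
}
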