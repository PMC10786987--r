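# Quantification of surface expression and synaptic localization from
# fluorescence images: maximum projection, background-subtracted
# surface-to-intracellular intensity ratios, adaptive thresholding,
# pixel-overlap colocalization and puncta counting.

#' Labeled multi-channel image stack
#'
#' @param channels named list of 2D matrices or 3D arrays (x, y, z), all
#'   the same x/y shape; names give the channel roles (e.g. `surface`,
#'   `intracellular`, `psd95`, `dapi`).
#' @param pixel_size pixel size, um.
#' @param z_step z-step of the stack, um (NA for single planes).
#' @param rois named list of logical 2D masks (e.g. cell somata, 20-um
#'   dendrite segments, a background region).
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size, z_step = NA_real_,
                        rois = list()) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("channels must be a named list", call. = FALSE)
  shapes <- lapply(channels, function(ch) dim(ch)[1:2])
  if (length(unique(lapply(shapes, paste, collapse = "x"))) != 1L)
    stop("all channels must share the same x/y shape", call. = FALSE)
  for (nm in names(channels))
    if (any(channels[[nm]] < 0))
      stop("channel '", nm, "' has negative intensities", call. = FALSE)
  structure(list(channels = channels, pixel_size = pixel_size,
                 z_step = z_step, rois = rois),
            class = "image_stack")
}

#' Maximum projection over z
#'
#' Pixel-wise maximum across the z planes of each channel. Single-plane
#' (2D) channels are returned unchanged.
#'
#' @param x an [image_stack()] or a single 2D/3D array.
#' @return Same type as the input, with all channels 2D.
#' @export
max_project <- function(x) {
  proj <- function(a) {
    if (length(dim(a)) == 2L || is.null(dim(a))) return(a)
    apply(a, c(1, 2), max)
  }
  if (inherits(x, "image_stack")) {
    x$channels <- lapply(x$channels, proj)
    return(x)
  }
  proj(x)
}

#' Background estimate for one channel
#'
#' Median intensity of a user-supplied background region; when no region
#' is given, falls back to the mode of the intensity histogram (the most
#' common intensity, which in a sparse fluorescence image is background).
#'
#' @param image 2D intensity matrix.
#' @param roi optional logical mask of background pixels.
#' @return Scalar background intensity.
#' @export
estimate_background <- function(image, roi = NULL) {
  if (!is.null(roi)) {
    if (!any(roi)) stop("background ROI is empty", call. = FALSE)
    return(stats::median(image[roi]))
  }
  h <- graphics::hist(image, breaks = 256, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Surface-to-intracellular expression ratio
#'
#' `(mean surface intensity in ROI - surface background) /`
#' `(mean intracellular intensity in ROI - intracellular background)`.
#' The ratio is invariant to a common gain on both channels. A
#' non-positive denominator marks an unusable cell: the ratio is `NA`
#' with attribute `flag = "nonpositive_denominator"`.
#'
#' @param surface,intracellular 2D intensity matrices.
#' @param roi logical mask of the measured region (non-empty).
#' @param background_surface,background_intracellular scalar backgrounds;
#'   when `NULL` they are estimated with [estimate_background()] using
#'   `background_roi`.
#' @param background_roi optional logical mask of a background region.
#' @return Scalar ratio (or flagged `NA`).
#' @export
surface_ratio <- function(surface, intracellular, roi,
                          background_surface = NULL,
                          background_intracellular = NULL,
                          background_roi = NULL) {
  if (!identical(dim(surface), dim(intracellular)))
    stop("channel shapes differ", call. = FALSE)
  if (!any(roi)) stop("measurement ROI is empty", call. = FALSE)
  if (is.null(background_surface))
    background_surface <- estimate_background(surface, background_roi)
  if (is.null(background_intracellular))
    background_intracellular <- estimate_background(intracellular,
                                                    background_roi)
  num <- mean(surface[roi]) - background_surface
  den <- mean(intracellular[roi]) - background_intracellular
  if (den <= 0) {
    warning("intracellular signal does not exceed background; cell excluded")
    return(structure(NA_real_, flag = "nonpositive_denominator"))
  }
  num / den
}

#' Surface-to-intracellular ratio from a colorimetric assay
#'
#' Absorbance arithmetic of the plate assay: replicate absorbances are
#' averaged first, the background (cells without the tagged subunit) is
#' subtracted from surface and total, the intracellular component is
#' `total - surface`, and the reported value is `surface/intracellular`.
#'
#' @param surface_abs,total_abs,background_abs absorbances (vectors of
#'   replicates allowed; averaged before the ratio).
#' @return Scalar ratio; flagged `NA` when the intracellular component is
#'   not positive.
#' @examples
#' colorimetric_ratio(0.4, 0.8, 0.2) # 0.5
#' @export
colorimetric_ratio <- function(surface_abs, total_abs, background_abs) {
  if (any(c(surface_abs, total_abs, background_abs) < 0))
    stop("absorbances must be >= 0", call. = FALSE)
  s <- mean(surface_abs) - mean(background_abs)
  t <- mean(total_abs) - mean(background_abs)
  ic <- t - s
  if (ic <= 0) {
    warning("intracellular absorbance component is not positive")
    return(structure(NA_real_, flag = "nonpositive_intracellular"))
  }
  max(s, 0) / ic
}

#' Adaptive (local-mean) thresholding
#'
#' A pixel is foreground iff its intensity exceeds the local mean over a
#' `window_px` x `window_px` neighbourhood by more than `offset`. Local
#' means use replicated-boundary box filtering. Unlike a global
#' threshold, this tracks uneven illumination along dendrites.
#'
#' @param image 2D intensity matrix.
#' @param window_px odd window size, >= 3, not larger than the image.
#' @param offset threshold offset above the local mean; default is twice
#'   the robust noise SD (1.4826 x MAD of the pixel intensities).
#' @return Logical mask, same shape as `image`.
#' @export
adaptive_threshold <- function(image, window_px = 51, offset = NULL) {
  if (window_px %% 2 != 1 || window_px < 3)
    stop("window_px must be odd and >= 3", call. = FALSE)
  if (window_px > min(dim(image)))
    stop("window_px exceeds the image size", call. = FALSE)
  if (is.null(offset)) offset <- 2 * stats::mad(image)
  kern <- matrix(1 / window_px^2, window_px, window_px)
  local_mean <- EBImage::filter2(image, kern, boundary = "replicate")
  mask <- image > local_mean + offset
  mask
}

#' Percent of mask-a pixels overlapping mask b
#'
#' `100 |a & b| / |a|`. Not symmetric in its arguments: it answers "what
#' fraction of the surface-receptor mask lies on PSD-95", not the
#' converse. An empty `a` returns 0 flagged `"empty_reference_mask"`.
#'
#' @param mask_a,mask_b logical masks of identical shape.
#' @return Percent overlap in `[0, 100]`.
#' @export
percent_overlap <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("mask shapes differ", call. = FALSE)
  na <- sum(mask_a)
  if (na == 0L) {
    warning("reference mask is empty")
    return(structure(0, flag = "empty_reference_mask"))
  }
  100 * sum(mask_a & mask_b) / na
}

# 8-connectivity connected-component labeling. (EBImage::bwlabel uses
# 4-connectivity, which splits diagonally touching puncta.)
label_components8 <- function(mask) {
  mask <- mask != 0
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask)
  pos <- data.frame(r = ((idx - 1L) %% nr) + 1L, c = ((idx - 1L) %/% nr) + 1L)
  id_of <- integer(length(mask)); id_of[idx] <- seq_along(idx)
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- pos$r + off[1]; c2 <- pos$c + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[nb]
    if (any(hit))
      edges <- c(edges, rbind(id_of[idx[ok]][hit], id_of[nb][hit]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

#' Count puncta in a binary mask
#'
#' Connected components under 8-connectivity (diagonally touching pixels
#' belong to the same punctum) with area of at least `min_area_px`.
#'
#' @param mask logical mask.
#' @param min_area_px minimum punctum area, pixels.
#' @return Integer count.
#' @export
count_puncta <- function(mask, min_area_px = 4) {
  lab <- label_components8(mask)
  if (max(lab) == 0L) return(0L)
  sum(tabulate(lab[lab > 0L]) >= min_area_px)
}

#' Colocalization and puncta summary for a dendrite segment
#'
#' Thresholds the surface-receptor and PSD-95 channels adaptively within
#' a dendrite-segment ROI, computes the percentage of surface pixels
#' overlapping PSD-95 and counts puncta in both masks.
#'
#' @param stack an [image_stack()] with `surface` and `psd95` channels
#'   (projected with [max_project()] if 3D).
#' @param roi logical mask of the dendrite segment; defaults to
#'   `stack$rois$dendrite` when present, else the whole image.
#' @param window_px,offset see [adaptive_threshold()]; the default
#'   window is 51 px, clamped to the image size.
#' @param min_area_px see [count_puncta()].
#' @param segment_length_um stated segment length, um (metadata).
#' @return List with `percent_overlap`, `n_puncta_surface`,
#'   `n_puncta_psd95`, `segment_length_um`.
#' @export
colocalize_dendrite <- function(stack, roi = NULL, window_px = NULL,
                                offset = NULL, min_area_px = 4,
                                segment_length_um = 20) {
  stack <- max_project(stack)
  if (is.null(window_px)) {
    window_px <- min(51L, min(dim(stack$channels[[1]])[1:2]))
    if (window_px %% 2L == 0L) window_px <- window_px - 1L
  }
  need <- c("surface", "psd95")
  if (!all(need %in% names(stack$channels)))
    stop("stack must have 'surface' and 'psd95' channels", call. = FALSE)
  surf <- stack$channels$surface
  psd <- stack$channels$psd95
  if (is.null(roi))
    roi <- if (!is.null(stack$rois$dendrite)) stack$rois$dendrite else
      matrix(TRUE, nrow(surf), ncol(surf))
  m_surf <- adaptive_threshold(surf, window_px, offset) & roi
  m_psd <- adaptive_threshold(psd, window_px, offset) & roi
  list(percent_overlap = as.numeric(percent_overlap(m_surf, m_psd)),
       n_puncta_surface = count_puncta(m_surf, min_area_px),
       n_puncta_psd95 = count_puncta(m_psd, min_area_px),
       segment_length_um = segment_length_um)
}

#' Read / write an image stack as TIFF
#'
#' `read_image_stack` reads one multi-page TIFF per channel (pages become
#' z-planes); `write_image_stack` writes each channel to
#' `<dir>/<name>.tif`. Intensities are stored as 32-bit floats.
#'
#' @param paths named character vector of TIFF paths (names = channel
#'   roles).
#' @param pixel_size,z_step see [image_stack()].
#' @param stack an [image_stack()].
#' @param dir output directory.
#' @return `read_image_stack`: an [image_stack()]; `write_image_stack`:
#'   the written paths, invisibly.
#' @export
read_image_stack <- function(paths, pixel_size, z_step = NA_real_) {
  channels <- lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    if (length(pages) == 1L) pages[[1]]
    else array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  })
  names(channels) <- names(paths)
  image_stack(channels, pixel_size = pixel_size, z_step = z_step)
}

#' @rdname read_image_stack
#' @export
write_image_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(stack$channels), function(nm) {
    ch <- stack$channels[[nm]]
    p <- file.path(dir, paste0(nm, ".tif"))
    mx <- max(ch)
    if (mx > 0) ch <- ch / mx  # tiff stores [0,1]; scale is metadata-free
    if (length(dim(ch)) == 3L)
      tiff::writeTIFF(lapply(seq_len(dim(ch)[3]), function(z) ch[, , z]),
                      p, bits.per.sample = 32L)
    else tiff::writeTIFF(ch, p, bits.per.sample = 32L)
    p
  }, character(1))
  invisible(paths)
}
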