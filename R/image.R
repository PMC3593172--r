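#' Region-of-interest layout for the synthetic transverse imaging plane
#'
#' Circular ROIs mimicking the phantom's transverse imaging plane, which
#' shows the aorta, both myocardial compartments, the vena cava and the
#' pulmonary vessel in one slice.
#'
#' @param shape Image dimensions (rows, cols) in pixels.
#' @param pixel_size_mm Isotropic pixel size in mm.
#' @return A `roi_layout`: list of ROIs (`name`, `center`, `radius`) plus
#'   image geometry.
#' @export
default_roi_layout <- function(shape = c(64L, 64L), pixel_size_mm = 1.2) {
  structure(
    list(shape = as.integer(shape), pixel_size_mm = pixel_size_mm,
         rois = list(
           list(name = "aorta", center = c(32, 20), radius = 6),
           list(name = "myo_right", center = c(16, 44), radius = 8),
           list(name = "myo_left", center = c(46, 44), radius = 8),
           list(name = "vena_cava", center = c(12, 14), radius = 4),
           list(name = "pulmonary", center = c(52, 16), radius = 4)
         )),
    class = "roi_layout"
  )
}

roi_mask <- function(layout, roi) {
  spec <- NULL
  for (r in layout$rois) if (r$name == roi) spec <- r
  if (is.null(spec)) stop(sprintf("unknown roi '%s'", roi), call. = FALSE)
  nr <- layout$shape[1L]
  nc <- layout$shape[2L]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rows - spec$center[1L])^2 + (cols - spec$center[2L])^2 <= spec$radius^2
}

#' Render a dynamic image series from per-ROI signal curves
#'
#' Builds one frame per sample: every ROI's pixels carry that ROI's signal
#' intensity at the frame time (plus optional per-pixel noise) over a
#' constant background. ROIs must be disjoint and every supplied curve
#' must share the same time grid.
#'
#' @param curves Named list of [signal_curve()]s; names must match ROI
#'   names in `layout`. ROIs without a curve stay at background.
#' @param layout A [default_roi_layout()]-style layout.
#' @param background Background intensity in au.
#' @param sigma Per-pixel Gaussian noise SD in au.
#' @param seed Seed for the pixel noise.
#' @return A `phantom_image_stack`: list of frame matrices plus timing and
#'   geometry.
#' @export
render_image_series <- function(curves, layout = default_roi_layout(),
                                background = 0, sigma = 0, seed = NULL) {
  stopifnot(is.list(curves), length(curves) >= 1L, !is.null(names(curves)))
  t0 <- curves[[1L]]$times
  for (cv in curves) {
    if (length(cv$times) != length(t0) || any(abs(cv$times - t0) > 1e-9)) {
      stop("all curves must share the same time grid", call. = FALSE)
    }
  }
  masks <- lapply(names(curves), function(nm) roi_mask(layout, nm))
  names(masks) <- names(curves)
  overlap <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(overlap > 1L)) stop("ROIs overlap", call. = FALSE)

  nframes <- length(t0)
  noise <- NULL
  if (sigma > 0) {
    npix <- prod(layout$shape)
    noise <- with_seed(seed, stats::rnorm(npix * nframes, 0, sigma))
  }
  frames <- lapply(seq_len(nframes), function(i) {
    fr <- matrix(background, layout$shape[1L], layout$shape[2L])
    for (nm in names(curves)) fr[masks[[nm]]] <- curves[[nm]]$values[i]
    if (!is.null(noise)) {
      npix <- prod(layout$shape)
      fr <- fr + matrix(noise[((i - 1L) * npix + 1L):(i * npix)],
                        layout$shape[1L], layout$shape[2L])
    }
    fr
  })
  structure(list(frames = frames, times = t0, layout = layout,
                 background = background, sigma = sigma),
            class = "phantom_image_stack")
}

#' Extract the mean ROI time-intensity curve from an image stack
#'
#' @param stack A `phantom_image_stack` from [render_image_series()].
#' @param roi ROI name present in the stack's layout.
#' @return A [signal_curve()] of per-frame mean intensity over the mask.
#' @export
extract_roi <- function(stack, roi) {
  stopifnot(inherits(stack, "phantom_image_stack"))
  mask <- roi_mask(stack$layout, roi)
  if (!any(mask)) stop(sprintf("roi '%s' has an empty mask", roi),
                       call. = FALSE)
  vals <- vapply(stack$frames, function(fr) mean(fr[mask]), 0)
  signal_curve(stack$times, pmax(vals, 0), roi = roi)
}

#' @export
print.phantom_image_stack <- function(x, ...) {
  cat(sprintf("<phantom_image_stack> %d frames of %dx%d px (%.1f mm), t = [%g, %g] s\n",
              length(x$frames), x$layout$shape[1L], x$layout$shape[2L],
              x$layout$pixel_size_mm, x$times[1L],
              x$times[length(x$times)]))
  invisible(x)
}
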