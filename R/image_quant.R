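#' Render a synthetic two-channel microscopy field
#'
#' Renders cells as 2-D Gaussian spots in a nuclear (Hoechst) channel and a
#' wider spot in the YP channel whose integral equals the cell's ground-truth
#' YP amount, over a constant background with additive Gaussian noise.
#' Overlapping cells are allowed (a warning is raised for centers closer than
#' one nuclear sigma, since such nuclei may merge at segmentation).
#'
#' @param cells data.frame with columns \code{x, y} (centers, pixels, inside
#'   the raster), \code{nuclear_amp} (peak nuclear amplitude, >= 0) and
#'   \code{yp} (integrated YP amount, >= 0).
#' @param shape raster dimensions \code{c(nrow, ncol)} in pixels.
#' @param nuclear_sigma,yp_sigma Gaussian spot SDs in pixels.
#' @param background constant background level (both channels).
#' @param noise_sd SD of additive Gaussian noise.
#' @param seed integer seed for the noise.
#' @return list of class \code{"field_image"} with matrices \code{nuclear}
#'   and \code{yp}, the \code{truth} table, and the render parameters.
#' @export
render_field <- function(cells, shape = c(256, 256), nuclear_sigma = 3,
                         yp_sigma = 6, background = 10, noise_sd = 0,
                         seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 8))
  if (nrow(cells) > 0) {
    stopifnot(all(c("x", "y", "nuclear_amp", "yp") %in% names(cells)))
    if (any(cells$x < 1 | cells$x > shape[2] |
            cells$y < 1 | cells$y > shape[1]))
      stop("cell centers must lie inside the raster")
    if (any(cells$nuclear_amp < 0 | cells$yp < 0))
      stop("amplitudes must be >= 0")
    if (nrow(cells) > 1) {
      dmin <- min(stats::dist(cells[, c("x", "y")]))
      if (dmin < nuclear_sigma)
        warning("cell centers closer than one nuclear sigma may merge")
    }
  }
  nuc <- matrix(background, shape[1], shape[2])
  ypc <- matrix(background, shape[1], shape[2])
  xs <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1])
  ys <- matrix(rep(seq_len(shape[1]), shape[2]), shape[1])
  for (i in seq_len(nrow(cells))) {
    r2 <- (xs - cells$x[i])^2 + (ys - cells$y[i])^2
    nuc <- nuc + cells$nuclear_amp[i] * exp(-r2 / (2 * nuclear_sigma^2))
    # YP spot scaled so its continuous integral equals the yp amount
    ypc <- ypc + cells$yp[i] / (2 * pi * yp_sigma^2) *
      exp(-r2 / (2 * yp_sigma^2))
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    nuc <- nuc + stats::rnorm(length(nuc), 0, noise_sd)
    ypc <- ypc + stats::rnorm(length(ypc), 0, noise_sd)
    nuc[nuc < 0] <- 0
    ypc[ypc < 0] <- 0
  }
  structure(list(nuclear = nuc, yp = ypc, truth = cells,
                 nuclear_sigma = nuclear_sigma, yp_sigma = yp_sigma,
                 background = background),
            class = "field_image")
}

#' Identify cells as nuclear-channel objects
#'
#' Segments Hoechst-positive nuclei by a global Otsu threshold on the nuclear
#' channel followed by connected-component labeling; components smaller than
#' \code{min_area} pixels are discarded. Deterministic given the inputs.
#' Nuclei closer than about one spot sigma can merge into one object (a
#' documented limitation of global thresholding). A field without real
#' objects (Otsu splitting the background noise itself, leaving more than
#' \code{max_fg} of the pixels "foreground") returns zero regions.
#'
#' @param field a \code{"field_image"}.
#' @param min_area minimum object area in pixels.
#' @param max_fg maximum plausible foreground pixel fraction; nuclei are
#'   sparse, so a larger fraction indicates a blank (pure-noise) field.
#' @return integer label matrix (0 = background); possibly all zero.
#' @export
identify_cells <- function(field, min_area = 9, max_fg = 0.3) {
  stopifnot(inherits(field, "field_image"))
  x <- field$nuclear
  rng <- range(x)
  if (rng[1] == rng[2]) stop("nuclear channel is constant")
  xn <- (x - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
  fg <- xn > th
  if (mean(fg) > max_fg) return(matrix(0L, nrow(x), ncol(x)))
  lab <- EBImage::bwlabel(fg)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  out <- matrix(match(lab, keep, nomatch = 0L), nrow(x), ncol(x))
  out
}

#' Integrate background-subtracted YP fluorescence per cell
#'
#' Expands each nuclear region by \code{dilation_radius} pixels into a "cell
#' region"; pixels claimed by several dilated regions are assigned to the
#' nearest region by geodesic propagation. The background is the median YP
#' intensity outside all cell regions; the per-cell readout is the sum of
#' background-subtracted YP over the cell region.
#'
#' @param field a \code{"field_image"}.
#' @param labels label matrix from \code{\link{identify_cells}} on the same
#'   field.
#' @param dilation_radius cell-region expansion in pixels.
#' @return data.frame of cell records: \code{cell_id, x, y, area, hoechst,
#'   yp}.
#' @export
measure_yp <- function(field, labels, dilation_radius = 5) {
  stopifnot(inherits(field, "field_image"),
            all(dim(labels) == dim(field$yp)))
  n <- max(labels)
  if (n == 0)
    return(data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0), hoechst = numeric(0),
                      yp = numeric(0)))
  brush <- EBImage::makeBrush(2 * dilation_radius + 1, shape = "disc")
  mask <- EBImage::dilate(labels > 0, brush)
  # constant intensity image -> propagation metric is purely spatial, so
  # contested pixels go to the nearest seed region
  zones <- EBImage::propagate(EBImage::Image(matrix(0, nrow(labels),
                                                    ncol(labels))),
                              seeds = labels, mask = mask)
  zones <- matrix(as.integer(EBImage::imageData(zones)), nrow(labels))
  outside <- zones == 0
  bg <- stats::median(field$yp[outside])
  rows <- lapply(seq_len(n), function(i) {
    inz <- zones == i
    innuc <- labels == i
    ys <- row(labels)[innuc]; xs <- col(labels)[innuc]
    data.frame(cell_id = i, x = mean(xs), y = mean(ys),
               area = sum(innuc),
               hoechst = sum(field$nuclear[innuc]),
               yp = sum(field$yp[inz] - bg))
  })
  do.call(rbind, rows)
}

#' Quantify a rendered field end to end
#'
#' Convenience wrapper: \code{\link{identify_cells}} then
#' \code{\link{measure_yp}}.
#'
#' @inheritParams identify_cells
#' @inheritParams measure_yp
#' @return per-cell data.frame, see \code{\link{measure_yp}}.
#' @export
quantify_field <- function(field, min_area = 9, dilation_radius = 5) {
  measure_yp(field, identify_cells(field, min_area), dilation_radius)
}

#' Write / read a two-channel field as 16-bit TIFF
#'
#' Stores the nuclear and YP channels as two pages of a 16-bit TIFF after
#' scaling by \code{scale} (intensity a.u. per grey level); reading inverts
#' the scaling.
#'
#' @param field a \code{"field_image"}.
#' @param path output file path.
#' @param scale grey levels per intensity unit.
#' @return \code{write_field_tiff}: the path, invisibly;
#'   \code{read_field_tiff}: a \code{"field_image"} (without ground truth).
#' @export
write_field_tiff <- function(field, path, scale = 16) {
  stopifnot(inherits(field, "field_image"))
  to16 <- function(x) pmin(pmax(x * scale / 65535, 0), 1)
  tiff::writeTIFF(list(to16(field$nuclear), to16(field$yp)), path,
                  bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path, scale = 16) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2) stop("expected a 2-page (2-channel) TIFF")
  structure(list(nuclear = pages[[1]] * 65535 / scale,
                 yp = pages[[2]] * 65535 / scale,
                 truth = NULL, background = NA_real_),
            class = "field_image")
}

#' Render a whole sample's field from simulated cells
#'
#' Places a simulated sample's cells on a randomly jittered grid (settled
#' cells spread across the well bottom, so heavy clumping is not modeled) and
#' renders both channels, as a visualization front end for the screen
#' generator.
#'
#' @param sample_cells per-cell table from
#'   \code{\link{simulate_cell_sample}} (columns \code{hoechst, yp}).
#' @param shape raster size; must offer at least one grid site per cell.
#' @param seed integer seed for cell placement.
#' @param ... passed to \code{\link{render_field}}.
#' @return a \code{"field_image"} whose truth table carries the input cells.
#' @export
render_sample_field <- function(sample_cells, shape = c(512, 512), seed = 1L,
                                ...) {
  n <- nrow(sample_cells)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  margin <- 12
  step <- floor(sqrt((shape[1] - 2 * margin) * (shape[2] - 2 * margin) / n))
  gx <- seq(margin, shape[2] - margin, by = step)
  gy <- seq(margin, shape[1] - margin, by = step)
  sites <- expand.grid(x = gx, y = gy)
  if (nrow(sites) < n) stop("raster too small for ", n, " cells")
  sites <- sites[sample.int(nrow(sites), n), ]
  cells <- data.frame(
    x = sites$x + stats::runif(n, -step / 6, step / 6),
    y = sites$y + stats::runif(n, -step / 6, step / 6),
    nuclear_amp = sample_cells$hoechst,
    yp = sample_cells$yp
  )
  render_field(cells, shape = shape, seed = seed + 1L, ...)
}
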