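## Synthetic microscopy: spherocylindrical cells on an agarose pad, rendered
## as brightfield + fluorescence image pairs with a camera noise model.

#' Field specification for synthetic microscopy
#'
#' Geometry of a rendered field. Dimensions are pre-binning sensor pixels;
#' sizes are typical rod-shaped B. subtilis dimensions at 100x
#' magnification. Pixel indices are 0-based, row-major `(row, col)`, with
#' geometry in floating-point pixel units at pixel centers.
#'
#' @param width_px,height_px field size in pre-binning pixels.
#' @param pixel_size_um physical pixel size (micrometers per pre-binning
#'   pixel).
#' @param cell_length_um,cell_width_um `(min, max)` ranges for cell length
#'   (pole to pole) and width.
#' @param n_cells_target number of cells to attempt to place.
#' @param allow_touching if `FALSE` (default) placed cells keep a minimum
#'   boundary gap.
#' @param min_gap_px minimum boundary-to-boundary gap (pre-binning px).
#' @param psf_sigma_px Gaussian point-spread-function sigma (pre-binning px);
#'   0 disables blur.
#' @param brightfield_bg_level brightfield background (photon-equivalent AU).
#' @param brightfield_cell_contrast cells are darker than background by this
#'   factor, in (0, 1].
#' @param fluor_bg_level fluorescence background level (AU).
#' @return object of class `"field_spec"`.
#' @export
field_spec <- function(width_px = 512, height_px = 512,
                       pixel_size_um = 0.065,
                       cell_length_um = c(2, 4),
                       cell_width_um = c(0.8, 1),
                       n_cells_target = 150,
                       allow_touching = FALSE,
                       min_gap_px = 2,
                       psf_sigma_px = 0.8,
                       brightfield_bg_level = 400,
                       brightfield_cell_contrast = 0.35,
                       fluor_bg_level = 20) {
  check_pos(width_px, "width_px"); check_pos(height_px, "height_px")
  check_pos(pixel_size_um, "pixel_size_um")
  stopifnot(length(cell_length_um) == 2, cell_length_um[1] <= cell_length_um[2],
            length(cell_width_um) == 2, cell_width_um[1] <= cell_width_um[2],
            all(cell_length_um > 0), all(cell_width_um > 0))
  check_nonneg(n_cells_target, "n_cells_target")
  check_nonneg(min_gap_px, "min_gap_px")
  check_nonneg(psf_sigma_px, "psf_sigma_px")
  check_nonneg(brightfield_bg_level, "brightfield_bg_level")
  if (!is_number(brightfield_cell_contrast) ||
      brightfield_cell_contrast <= 0 || brightfield_cell_contrast > 1) {
    stop("`brightfield_cell_contrast` must be in (0, 1]", call. = FALSE)
  }
  check_nonneg(fluor_bg_level, "fluor_bg_level")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um,
                 cell_length_um = cell_length_um,
                 cell_width_um = cell_width_um,
                 n_cells_target = as.integer(n_cells_target),
                 allow_touching = isTRUE(allow_touching),
                 min_gap_px = min_gap_px,
                 psf_sigma_px = psf_sigma_px,
                 brightfield_bg_level = brightfield_bg_level,
                 brightfield_cell_contrast = brightfield_cell_contrast,
                 fluor_bg_level = fluor_bg_level),
            class = "field_spec")
}

#' Camera model for synthetic acquisition
#'
#' Counts are formed as
#' `offset + gain * Poisson(photon-equivalent AU) + Gaussian read noise`,
#' optionally binned. Binning averages blocks (2x2 mean), so AU scales are
#' binning-invariant.
#'
#' @param offset constant camera offset (counts).
#' @param read_noise_sd Gaussian read noise SD (counts, pre-binning pixel).
#' @param gain counts per photon-equivalent AU.
#' @param shot_noise logical; Poisson shot noise on the AU signal.
#' @param bit_depth ADC bit depth; pixel values clip to `[0, 2^bit_depth-1]`.
#' @param binning 1 (none) or 2 (2x2 mean).
#' @return object of class `"camera_model"`.
#' @export
camera_model <- function(offset = 100, read_noise_sd = 3, gain = 2,
                         shot_noise = TRUE, bit_depth = 16, binning = 2) {
  check_nonneg(offset, "offset")
  check_nonneg(read_noise_sd, "read_noise_sd")
  check_nonneg(gain, "gain")
  stopifnot(binning %in% c(1L, 2L), bit_depth >= 8)
  structure(list(offset = offset, read_noise_sd = read_noise_sd, gain = gain,
                 shot_noise = isTRUE(shot_noise),
                 bit_depth = as.integer(bit_depth),
                 binning = as.integer(binning)),
            class = "camera_model")
}

#' Noise-free camera for ground-truth checks
#' @return a [camera_model()] with shot and read noise disabled.
#' @export
ideal_camera <- function() {
  camera_model(offset = 100, read_noise_sd = 0, gain = 2,
               shot_noise = FALSE, binning = 2)
}

## geometry ------------------------------------------------------------------

# Distance between two segments (p1-p2) and (q1-q2), each a length-2 vector.
# Standard clamped closest-point computation.
segment_distance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-12 && e <= 1e-12) return(sqrt(sum(r * r)))
  if (a <= 1e-12) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    c_ <- sum(d1 * r)
    if (e <= 1e-12) {
      t <- 0; s <- min(max(-c_ / a, 0), 1)
    } else {
      b <- sum(d1 * d2); denom <- a * e - b * b
      s <- if (denom > 1e-12) min(max((b * f - c_ * e) / denom, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c_ / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c_) / a, 0), 1) }
    }
  }
  cp <- p1 + s * d1; cq <- q1 + t * d2
  sqrt(sum((cp - cq)^2))
}

#' Place spherocylindrical cells in a field
#'
#' Samples cell lengths, widths and orientations uniformly from the spec
#' ranges and places cells by rejection sampling. Cells are kept fully inside
#' the field (a margin of half the cell length plus width is enforced) so no
#' ground-truth cell touches the border. When `allow_touching` is `FALSE`
#' the boundary-to-boundary distance between any two cells is at least
#' `min_gap_px`.
#'
#' @param spec a [field_spec()].
#' @param n number of cells to place (defaults to `spec$n_cells_target`).
#' @param seed integer seed.
#' @param max_attempts rejection-sampling bound per field; when the field
#'   saturates fewer than `n` cells are returned with a warning.
#' @return data.frame of cell geometries with columns `id`, `cx`, `cy`
#'   (center, pre-binning px), `theta` (orientation, rad), `length_px`,
#'   `width_px`.
#' @export
place_cells <- function(spec, n = spec$n_cells_target, seed = 1L,
                        max_attempts = 200L * max(n, 1L)) {
  stopifnot(inherits(spec, "field_spec"))
  if (!is_number(n) || n < 0) stop("`n` must be >= 0", call. = FALSE)
  n <- as.integer(n)
  empty <- data.frame(id = integer(0), cx = numeric(0), cy = numeric(0),
                      theta = numeric(0), length_px = numeric(0),
                      width_px = numeric(0))
  if (n == 0) return(empty)

  px <- spec$pixel_size_um
  with_seed(seed, {
    placed <- matrix(NA_real_, nrow = n, ncol = 5)  # cx, cy, theta, len, wid
    k <- 0; attempts <- 0
    while (k < n && attempts < max_attempts) {
      attempts <- attempts + 1
      len <- stats::runif(1, spec$cell_length_um[1], spec$cell_length_um[2]) / px
      wid <- stats::runif(1, spec$cell_width_um[1], spec$cell_width_um[2]) / px
      theta <- stats::runif(1, 0, pi)
      margin <- len / 2 + wid
      if (2 * margin >= min(spec$width_px, spec$height_px)) next
      cx <- stats::runif(1, margin, spec$width_px - margin)
      cy <- stats::runif(1, margin, spec$height_px - margin)
      ok <- TRUE
      if (!spec$allow_touching && k > 0) {
        half <- (len - wid) / 2
        p1 <- c(cx - half * cos(theta), cy - half * sin(theta))
        p2 <- c(cx + half * cos(theta), cy + half * sin(theta))
        # cheap center-distance prefilter before exact segment distances
        d2 <- (placed[seq_len(k), 1] - cx)^2 + (placed[seq_len(k), 2] - cy)^2
        reach <- (len + placed[seq_len(k), 4]) / 2 +
          (wid + placed[seq_len(k), 5]) / 2 + spec$min_gap_px
        for (j in which(d2 < reach^2)) {
          oj <- placed[j, ]
          halfj <- (oj[4] - oj[5]) / 2
          q1 <- c(oj[1] - halfj * cos(oj[3]), oj[2] - halfj * sin(oj[3]))
          q2 <- c(oj[1] + halfj * cos(oj[3]), oj[2] + halfj * sin(oj[3]))
          gap <- segment_distance(p1, p2, q1, q2) - (wid + oj[5]) / 2
          if (gap < spec$min_gap_px) { ok <- FALSE; break }
        }
      }
      if (ok) {
        k <- k + 1
        placed[k, ] <- c(cx, cy, theta, len, wid)
      }
    }
    if (k < n) {
      warning(sprintf("field saturated: placed %d of %d requested cells",
                      k, n), call. = FALSE)
    }
    if (k == 0) return(empty)
    placed <- placed[seq_len(k), , drop = FALSE]
    data.frame(id = seq_len(k), cx = placed[, 1], cy = placed[, 2],
               theta = placed[, 3], length_px = placed[, 4],
               width_px = placed[, 5])
  })
}

# Rasterize one spherocylinder: returns integer matrix indices (row, col,
# 1-based) of pixels whose centers lie inside the outline. Pixel center of
# image[r, c] is at (x, y) = (c - 1, r - 1).
rasterize_cell <- function(geom, width_px, height_px) {
  half <- (geom$length_px - geom$width_px) / 2
  rad <- geom$width_px / 2
  dx <- cos(geom$theta); dy <- sin(geom$theta)
  ex <- geom$cx + c(-1, 1) * half * dx
  ey <- geom$cy + c(-1, 1) * half * dy
  x0 <- max(1L, floor(min(ex) - rad)); x1 <- min(width_px,  ceiling(max(ex) + rad) + 1L)
  y0 <- max(1L, floor(min(ey) - rad)); y1 <- min(height_px, ceiling(max(ey) + rad) + 1L)
  xs <- seq.int(x0, x1) - 1; ys <- seq.int(y0, y1) - 1
  gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
  # distance from pixel center to the axis segment
  px <- gx - ex[1]; py <- gy - ey[1]
  ax <- ex[2] - ex[1]; ay <- ey[2] - ey[1]
  len2 <- ax^2 + ay^2
  t <- if (len2 > 1e-12) pmin(pmax((px * ax + py * ay) / len2, 0), 1) else 0
  ddx <- px - t * ax; ddy <- py - t * ay
  inside <- (ddx^2 + ddy^2) <= rad^2
  cbind(row = gy[inside] + 1L, col = gx[inside] + 1L)
}

bin2_mean <- function(m) {
  nr <- nrow(m) %/% 2L * 2L; nc <- ncol(m) %/% 2L * 2L
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  (m[seq(1, nr, 2), seq(1, nc, 2)] + m[seq(2, nr, 2), seq(1, nc, 2)] +
   m[seq(1, nr, 2), seq(2, nc, 2)] + m[seq(2, nr, 2), seq(2, nc, 2)]) / 4
}

# Majority-rule 2x2 binning for label masks: a binned pixel takes the label
# occupying >= 2 of its 4 sensor pixels (ties broken by smaller label; with
# non-overlapping cells a tie between two labels cannot reach majority).
bin2_labels <- function(m) {
  nr <- nrow(m) %/% 2L * 2L; nc <- ncol(m) %/% 2L * 2L
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  a <- m[seq(1, nr, 2), seq(1, nc, 2)]; b <- m[seq(2, nr, 2), seq(1, nc, 2)]
  c_ <- m[seq(1, nr, 2), seq(2, nc, 2)]; d <- m[seq(2, nr, 2), seq(2, nc, 2)]
  out <- matrix(0L, nrow(a), ncol(a))
  for (lab in list(a, b, c_, d)) {
    cnt <- (a == lab) + (b == lab) + (c_ == lab) + (d == lab)
    take <- lab > 0L & cnt >= 2L & (out == 0L | lab < out)
    out[take] <- lab[take]
  }
  out
}

apply_camera <- function(au, camera) {
  # au: photon-equivalent AU per pre-binning pixel
  signal <- if (camera$shot_noise) {
    matrix(stats::rpois(length(au), pmax(au, 0)), nrow(au))
  } else au
  counts <- camera$offset + camera$gain * signal
  if (camera$read_noise_sd > 0) {
    counts <- counts + matrix(stats::rnorm(length(counts), 0,
                                           camera$read_noise_sd), nrow(counts))
  }
  if (camera$binning == 2L) counts <- bin2_mean(counts)
  counts
}

#' Render a synthetic brightfield/fluorescence field
#'
#' Builds the ideal photon-equivalent images (fluorescence: background plus
#' each cell's AU value over its footprint; brightfield: background with
#' cells darker by the contrast factor), applies Gaussian PSF blur, converts
#' to camera counts with shot and read noise, bins, and clips to the ADC
#' range. The ground-truth label mask is the unblurred footprint, binned by
#' majority rule.
#'
#' @param values numeric vector of per-cell fluorescence values (AU), one per
#'   geometry row.
#' @param geometries data.frame from [place_cells()].
#' @param spec a [field_spec()].
#' @param camera a [camera_model()].
#' @param seed integer seed for the camera noise.
#' @return object of class `"field_image"`: list with matrices `brightfield`,
#'   `fluorescence` (counts, post-binning), `truth_mask` (integer labels),
#'   data.frame `cell_truths` (id, centroid, orientation, size, true AU,
#'   expected in-mask optical mean AU), `saturated_fraction`, plus the spec,
#'   camera and seed.
#' @export
render_field <- function(values, geometries, spec, camera, seed = 1L) {
  stopifnot(inherits(spec, "field_spec"), inherits(camera, "camera_model"))
  if (length(values) != nrow(geometries)) {
    stop("`values` must have one AU value per geometry", call. = FALSE)
  }
  W <- spec$width_px; H <- spec$height_px
  fl_au <- matrix(spec$fluor_bg_level, H, W)
  bf_au <- matrix(spec$brightfield_bg_level, H, W)
  mask <- matrix(0L, H, W)
  for (i in seq_len(nrow(geometries))) {
    idx <- rasterize_cell(geometries[i, ], W, H)
    if (nrow(idx) == 0) next
    fl_au[idx] <- fl_au[idx] + values[i]
    bf_au[idx] <- spec$brightfield_bg_level *
      (1 - spec$brightfield_cell_contrast)
    mask[idx] <- i
  }
  fl_ideal <- fl_au
  if (spec$psf_sigma_px > 0) {
    fl_au <- ebi_blur(fl_au, spec$psf_sigma_px)
    bf_au <- ebi_blur(bf_au, spec$psf_sigma_px)
    fl_ideal <- fl_au
  }
  imgs <- with_seed(seed, {
    list(fl = apply_camera(fl_au, camera), bf = apply_camera(bf_au, camera))
  })
  maxval <- 2^camera$bit_depth - 1
  sat <- mean(imgs$fl > maxval | imgs$fl < 0 | imgs$bf > maxval | imgs$bf < 0)
  fl <- pmin(pmax(imgs$fl, 0), maxval)
  bf <- pmin(pmax(imgs$bf, 0), maxval)
  mask_b <- if (camera$binning == 2L) bin2_labels(mask) else mask

  # per-cell truths: au_true is the simulated value; optical_mean_au is the
  # expected background-subtracted in-mask mean after PSF blur (the value an
  # unbiased quantification of the blurred optics should recover)
  ct <- geometries
  ct$au_true <- values
  ideal_b <- if (camera$binning == 2L) bin2_mean(fl_ideal) else fl_ideal
  ct$optical_mean_au <- vapply(seq_len(nrow(geometries)), function(i) {
    sel <- mask_b == i
    if (!any(sel)) return(NA_real_)
    mean(ideal_b[sel]) - spec$fluor_bg_level
  }, numeric(1))

  structure(list(brightfield = bf, fluorescence = fl, truth_mask = mask_b,
                 cell_truths = ct, saturated_fraction = sat,
                 field_spec = spec, camera = camera, seed = as.integer(seed)),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> %d x %d px (post-binning), %d cells, seed %d\n",
              nrow(x$fluorescence), ncol(x$fluorescence),
              max(x$truth_mask), x$seed))
  if (x$saturated_fraction > 0) {
    cat(sprintf("  WARNING: %.2f%% saturated pixels\n",
                100 * x$saturated_fraction))
  }
  invisible(x)
}

# EBImage Gaussian blur on a plain matrix; brush radius capped to image size.
ebi_blur <- function(m, sigma) {
  as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma,
                           boundary = "replicate"))
}

## TIFF I/O ------------------------------------------------------------------

#' Write a 16-bit grayscale TIFF
#'
#' Counts are stored as 16-bit unsigned integers (values clipped and rounded
#' to `[0, 65535]`).
#'
#' @param image numeric matrix of counts (or integer labels).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tiff16 <- function(image, path) {
  m <- pmin(pmax(round(image), 0), 65535) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a 16-bit grayscale TIFF written by [write_tiff16()]
#'
#' @param path TIFF path.
#' @return numeric matrix of counts.
#' @export
read_tiff16 <- function(path) {
  round(tiff::readTIFF(path) * 65535)
}

#' Write a rendered field to disk
#'
#' Writes `<prefix>_bf.tif`, `<prefix>_fl.tif`, `<prefix>_mask.tif` (16-bit
#' grayscale / label TIFF) and `<prefix>_truth.csv`.
#'
#' @param field a [render_field()] result.
#' @param prefix path prefix (directories are created).
#' @return character vector of the four paths, invisibly.
#' @export
write_field_image <- function(field, prefix) {
  stopifnot(inherits(field, "field_image"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- paste0(prefix, c("_bf.tif", "_fl.tif", "_mask.tif", "_truth.csv"))
  write_tiff16(field$brightfield, paths[1])
  write_tiff16(field$fluorescence, paths[2])
  write_tiff16(field$truth_mask, paths[3])
  utils::write.csv(field$cell_truths, paths[4], row.names = FALSE)
  invisible(paths)
}
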