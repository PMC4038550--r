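## Brightfield segmentation of rod-shaped cells, and scoring against the
## generator's ground-truth masks.
##
## The published analysis this emulates used an unpublished in-house
## segmentation program; the pipeline here is a standard, fully parameterized
## brightfield chain: shift-invariant background flattening by a morphological
## black top-hat, global Otsu threshold, hole filling, size/shape/border
## filters, and distance-transform watershed to split touching cells.

#' Construct a label mask
#'
#' @param labels integer matrix, 0 = background, k = cell k; labels must be
#'   consecutive 1..n.
#' @param provenance list of parameters that produced the mask.
#' @return object of class `"label_mask"` with fields `labels`, `n_cells`,
#'   `provenance`.
#' @export
label_mask <- function(labels, provenance = list()) {
  stopifnot(is.matrix(labels))
  labels <- matrix(as.integer(labels), nrow(labels))
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) && !identical(u, seq_along(u))) {
    stop("labels must be consecutive integers 1..n_cells", call. = FALSE)
  }
  structure(list(labels = labels, n_cells = length(u),
                 provenance = provenance),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d cells\n",
              nrow(x$labels), ncol(x$labels), x$n_cells))
  invisible(x)
}

# Relabel a labelled matrix to consecutive 1..n (order of original label id).
relabel <- function(m) {
  u <- sort(unique(m[m > 0]))
  if (!length(u)) return(matrix(0L, nrow(m), ncol(m)))
  lut <- integer(max(u)); lut[u] <- seq_along(u)
  out <- matrix(0L, nrow(m), ncol(m))
  out[m > 0] <- lut[m[m > 0]]
  out
}

# Solidity (area / convex-hull area) of a set of pixel coordinates.
pixel_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n <= 3) return(1)
  pts <- cbind(cols, rows)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  # shoelace; pad by 0.5 px on each side via +n/ correction is ignored:
  # pixel-center hull slightly underestimates area, bounded by clamping at 1
  x <- hp[, 1]; y <- hp[, 2]
  a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (a <= 0) return(1)
  # hull through pixel centers slightly underestimates the pixel-square
  # region of a convex object, so the ratio is clamped at 1
  min(n / a, 1)
}

#' Segment single cells from a brightfield image
#'
#' Cells are assumed darker than the background. The chain is: black top-hat
#' (grayscale closing minus image) with a disc larger than the cell width,
#' which flattens the background and is invariant to adding a constant to the
#' image; global Otsu threshold on the top-hat; hole filling; removal of
#' objects below `min_area_px` or touching the border; watershed on the
#' distance transform (tolerance `watershed_tolerance`) to split touching
#' cells; and a solidity filter. Deterministic: no random step.
#'
#' @param image numeric matrix (post-binning brightfield counts).
#' @param closing_radius_px disc radius for the top-hat (px); should exceed
#'   half the cell width.
#' @param min_area_px minimum object area (px).
#' @param solidity_min minimum solidity (area / convex hull area) kept.
#' @param watershed_tolerance minimum depth between distance-transform maxima
#'   for them to seed separate cells (px).
#' @param discard_border drop objects touching the field border (their means
#'   would be biased); default `TRUE`.
#' @return a [label_mask()].
#' @export
segment_brightfield <- function(image,
                                closing_radius_px = 9,
                                min_area_px = 40,
                                solidity_min = 0.8,
                                watershed_tolerance = 1.5,
                                discard_border = TRUE) {
  stopifnot(is.matrix(image), nrow(image) > 0, ncol(image) > 0)
  prov <- list(closing_radius_px = closing_radius_px,
               min_area_px = min_area_px, solidity_min = solidity_min,
               watershed_tolerance = watershed_tolerance,
               discard_border = discard_border)
  if (diff(range(image)) == 0) {
    return(label_mask(matrix(0L, nrow(image), ncol(image)), prov))
  }
  img <- EBImage::Image(image)
  brush <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L, "disc")
  tophat <- EBImage::closing(img, brush) - img   # dark objects -> positive
  th <- as.matrix(tophat)
  rng <- range(th)
  thr <- EBImage::otsu(EBImage::Image((th - rng[1]) / diff(rng)), levels = 256)
  binary <- (th - rng[1]) / diff(rng) > thr
  binary <- EBImage::fillHull(EBImage::Image(binary))
  lab <- EBImage::bwlabel(binary)

  m <- as.matrix(lab)
  m <- filter_labels(m, min_area_px, discard_border)
  if (!any(m > 0)) return(label_mask(relabel(m), prov))

  # split touching cells: watershed on the distance transform
  dm <- EBImage::distmap(EBImage::Image(m > 0))
  ws <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  m <- as.matrix(ws)
  m <- filter_labels(m, min_area_px, discard_border)

  # shape filter
  keep <- integer(0)
  u <- sort(unique(m[m > 0]))
  for (lb in u) {
    idx <- which(m == lb, arr.ind = TRUE)
    if (pixel_solidity(idx[, 1], idx[, 2]) >= solidity_min) {
      keep <- c(keep, lb)
    }
  }
  m[!(m %in% keep)] <- 0L
  label_mask(relabel(m), prov)
}

# Remove objects smaller than min_area_px or (optionally) touching the border.
filter_labels <- function(m, min_area_px, discard_border) {
  if (!any(m > 0)) return(m)
  areas <- tabulate(m[m > 0])
  drop <- which(areas > 0 & areas < min_area_px)
  if (discard_border) {
    border <- unique(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
    drop <- union(drop, border[border > 0])
  }
  m[m %in% drop] <- 0L
  m
}

#' Score a segmentation against a ground-truth label mask
#'
#' Objects are matched one-to-one by greedy assignment in order of descending
#' intersection-over-union (IoU); a pair is a match when IoU >= `iou_match`.
#' A truth object substantially overlapped (>= 25% of the detected object's
#' area) by two or more detected objects counts as a false split; a detected
#' object substantially overlapping two or more truth objects counts as a
#' false merge.
#'
#' @param mask a [label_mask()] (or integer label matrix).
#' @param truth integer label matrix of the same dimensions.
#' @param iou_match IoU threshold for a match (default 0.5).
#' @return object of class `"segmentation_score"`: list with `n_truth`,
#'   `n_detected`, `n_matched`, `iou` (per matched truth object),
#'   `matches` (data.frame truth/detected/iou), `false_splits`,
#'   `false_merges`.
#' @export
score_against_truth <- function(mask, truth, iou_match = 0.5) {
  m <- if (inherits(mask, "label_mask")) mask$labels else mask
  stopifnot(is.matrix(m), is.matrix(truth))
  if (!all(dim(m) == dim(truth))) {
    stop("mask and truth dimensions differ", call. = FALSE)
  }
  n_truth <- length(unique(truth[truth > 0]))
  n_det <- length(unique(m[m > 0]))
  sel <- truth > 0 | m > 0
  if (!any(sel) || n_truth == 0 || n_det == 0) {
    return(structure(list(n_truth = n_truth, n_detected = n_det,
                          n_matched = 0L, iou = numeric(0),
                          matches = data.frame(truth = integer(0),
                                               detected = integer(0),
                                               iou = numeric(0)),
                          false_splits = 0L, false_merges = 0L),
                     class = "segmentation_score"))
  }
  tab <- table(truth = truth[sel], detected = m[sel])
  tl <- as.integer(rownames(tab)); dl <- as.integer(colnames(tab))
  area_t <- tapply(truth[truth > 0], truth[truth > 0], length)
  area_d <- tapply(m[m > 0], m[m > 0], length)
  pairs <- which(tab > 0, arr.ind = TRUE)
  pairs <- pairs[tl[pairs[, 1]] > 0 & dl[pairs[, 2]] > 0, , drop = FALSE]
  if (nrow(pairs) == 0) inter <- numeric(0) else inter <- tab[pairs]
  pt <- tl[pairs[, 1]]; pd <- dl[pairs[, 2]]
  iou <- unname(as.numeric(inter) /
    (area_t[as.character(pt)] + area_d[as.character(pd)] - as.numeric(inter)))

  ord <- order(iou, pt, pd, decreasing = c(TRUE, FALSE, FALSE), method = "radix")
  used_t <- used_d <- integer(0)
  mt <- md <- integer(0); mi <- numeric(0)
  for (k in ord) {
    if (iou[k] < iou_match) break
    if (pt[k] %in% used_t || pd[k] %in% used_d) next
    used_t <- c(used_t, pt[k]); used_d <- c(used_d, pd[k])
    mt <- c(mt, pt[k]); md <- c(md, pd[k]); mi <- c(mi, iou[k])
  }

  # split/merge structure from substantial overlaps
  substantial <- as.numeric(inter) >= 0.25 * area_d[as.character(pd)]
  splits <- sum(pmax(tapply(substantial, pt, sum) - 1, 0), na.rm = TRUE)
  substantial_m <- as.numeric(inter) >= 0.25 * area_t[as.character(pt)]
  merges <- sum(pmax(tapply(substantial_m, pd, sum) - 1, 0), na.rm = TRUE)

  structure(list(n_truth = n_truth, n_detected = n_det,
                 n_matched = length(mt), iou = mi,
                 matches = data.frame(truth = mt, detected = md, iou = mi),
                 false_splits = as.integer(splits),
                 false_merges = as.integer(merges)),
            class = "segmentation_score")
}

#' @export
print.segmentation_score <- function(x, ...) {
  cat(sprintf(paste0("<segmentation_score> %d/%d truth cells matched ",
                     "(%d detected); median IoU %.3f; ",
                     "%d splits, %d merges\n"),
              x$n_matched, x$n_truth, x$n_detected,
              if (length(x$iou)) stats::median(x$iou) else NA_real_,
              x$false_splits, x$false_merges))
  invisible(x)
}
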