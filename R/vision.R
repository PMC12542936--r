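# Vision pipeline: tip localization by background subtraction, classical
# cell detection behind a pluggable interface, and motion-history-image
# (MHI) contact detection with the pixel-mean-value (PMV) criterion.

#' Grayscale image stack
#'
#' @param frames 3-D numeric array `[y, x, t]` with intensities in `[0, 1]`,
#'   or a list of equal-size matrices.
#' @param frame_rate frames per second.
#' @param pixel_size um per pixel.
#' @return an object of class `nt_stack`.
#' @export
nt_stack <- function(frames, frame_rate = 25, pixel_size = 1) {
  if (is.list(frames))
    frames <- array(unlist(frames),
                    dim = c(nrow(frames[[1]]), ncol(frames[[1]]),
                            length(frames)))
  stopifnot(length(dim(frames)) == 3)
  stopifnot_scalar(frame_rate, "frame_rate", positive = TRUE)
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_size = pixel_size),
            class = "nt_stack")
}

n_frames <- function(stack) dim(stack$frames)[3]

#' Locate the nanoprobe tip by background subtraction
#'
#' Subtracts a background model (supplied, or the temporal median over the
#' stack), thresholds the absolute residual with Otsu's method, takes the
#' largest connected component as the probe, and returns the component's
#' extreme point along its principal axis on the side farther from the
#' image border (the needle enters from an edge; its tip is interior).
#'
#' @param stack an [nt_stack()].
#' @param background optional background frame (matrix); when absent the
#'   stack must have at least 11 frames for a temporal-median background.
#' @param frame index of the frame to analyse (default: last).
#' @return an object of class `nt_tipestimate`: list with `position`
#'   (c(x, y) px), `axis_angle` (degrees), `confidence` (0-1).
#' @export
locate_tip <- function(stack, background = NULL, frame = NULL) {
  stopifnot(inherits(stack, "nt_stack"))
  nf <- n_frames(stack)
  if (is.null(background)) {
    if (nf < 11)
      stop("need >= 11 frames for a temporal-median background", call. = FALSE)
    background <- apply(stack$frames, c(1, 2), stats::median)
  }
  if (is.null(frame)) frame <- nf
  img <- stack$frames[, , frame]
  res <- abs(img - background)
  if (max(res) < 1e-6)
    stop("no tip found: zero residual after background subtraction",
         call. = FALSE)
  th <- otsu_threshold(res / max(res)) * max(res)
  mask <- res > th
  if (!any(mask))
    stop("no tip found: no component above threshold", call. = FALSE)
  lab <- label_components(mask)
  comp <- lab == 1
  pix <- which(comp, arr.ind = TRUE)   # [ , 1] = y, [ , 2] = x
  xy <- cbind(x = pix[, 2], y = pix[, 1])
  ctr <- colMeans(xy)
  cc <- sweep(xy, 2, ctr)
  ev <- eigen(stats::cov(cc), symmetric = TRUE)
  ax <- ev$vectors[, 1]
  proj <- cc %*% ax
  lo <- xy[which.min(proj), ]; hi <- xy[which.max(proj), ]
  h <- nrow(img); w <- ncol(img)
  border_dist <- function(p) min(p[1] - 1, w - p[1], p[2] - 1, h - p[2])
  tip <- if (border_dist(hi) >= border_dist(lo)) hi else lo
  structure(list(position = c(x = unname(tip[1]), y = unname(tip[2])),
                 axis_angle = as.numeric(atan2(ax[2], ax[1]) * 180 / pi),
                 confidence = sum(res[comp]) / sum(res)),
            class = "nt_tipestimate")
}

#' Detect cells in a frame
#'
#' Pluggable detector interface: a `detector` function
#' `function(frame) -> list of detections` replaces the classical
#' fallback, which smooths the frame, thresholds bright cytoplasm with
#' Otsu's method, fills nucleus holes, splits touching cells at
#' distance-transform peaks, and segments the darker nucleus inside each
#' cell.
#'
#' @param frame numeric matrix `[y, x]` in `[0, 1]`.
#' @param detector optional replacement detector function.
#' @param min_area minimum cell area in px.
#' @param nucleus_quantile intensity quantile (within the cell) below
#'   which pixels are called nucleus.
#' @return list of detections, each with `contour`, `nucleus_contour`
#'   (two-column matrices, px), `centroid` (c(x, y)), `area` (px).
#' @export
detect_cells <- function(frame, detector = NULL, min_area = 60,
                         nucleus_quantile = 0.25) {
  if (!is.null(detector)) return(detector(frame))
  if (max(frame) - min(frame) < 1e-3) return(list())
  sm <- box_blur(frame, 5)
  th <- otsu_threshold(sm)
  # second Otsu level below the first separates dark nuclei from the
  # mid-gray background, so cells = bright cytoplasm + dark nucleus
  # (no hole-filling pass needed)
  lowvals <- sm[sm <= th]
  th_dark <- if (length(lowvals) > 100) otsu_threshold(lowvals) else -Inf
  mask <- sm > th | sm < th_dark
  # closing bridges the blur-transition ring between nucleus and cytoplasm
  mask <- erode8(dilate8(mask, 3), 3)
  lab <- split_mask_at_peaks(mask, min_sep = 16, min_peak = 5)
  out <- list()
  for (k in seq_len(max(lab))) {
    cm <- lab == k
    area <- sum(cm)
    if (area < min_area) next
    poly <- mask_to_polygon(cm)
    if (is.null(poly) || nrow(poly) < 8) next
    vals <- frame[cm]
    nth <- stats::quantile(vals, nucleus_quantile)
    nmask <- cm & frame < nth
    nlab <- label_components(nmask)
    npoly <- if (max(nlab) > 0) mask_to_polygon(nlab == 1) else NULL
    pix <- which(cm, arr.ind = TRUE)
    out[[length(out) + 1]] <-
      list(contour = poly, nucleus_contour = npoly,
           centroid = c(x = mean(pix[, 2]), y = mean(pix[, 1])),
           area = area)
  }
  out
}

#' Motion history image sequence
#'
#' Per pixel: refresh to `mhi_max` where the inter-frame absolute
#' difference exceeds `diff_threshold`, else decay by `decay` (floored at
#' 0).  Returns one MHI map per frame transition.
#'
#' @param stack an [nt_stack()] with >= 2 frames.
#' @param diff_threshold inter-frame difference threshold (intensity
#'   units; default 10/255).
#' @param decay per-frame decay (default 25.5 on the 0-255 MHI scale).
#' @param mhi_max saturation value (default 255).
#' @return list of `n_frames - 1` matrices in `[0, mhi_max]`.
#' @export
motion_history <- function(stack, diff_threshold = 10 / 255, decay = 25.5,
                           mhi_max = 255) {
  stopifnot(inherits(stack, "nt_stack"))
  nf <- n_frames(stack)
  if (nf < 2) stop("need at least 2 frames", call. = FALSE)
  mhi <- matrix(0, dim(stack$frames)[1], dim(stack$frames)[2])
  out <- vector("list", nf - 1)
  for (t in 2:nf) {
    dmask <- abs(stack$frames[, , t] - stack$frames[, , t - 1]) > diff_threshold
    mhi <- pmax(mhi - decay, 0)
    mhi[dmask] <- mhi_max
    out[[t - 1]] <- mhi
  }
  out
}

#' Contact detection by pixel mean value over a tip ROI
#'
#' PMV = mean MHI value inside a circular region of interest around the
#' tip estimate; PMV above `threshold` sustained for `sustain` consecutive
#' frames is a contact.
#'
#' @param mhi_sequence list of MHI maps from [motion_history()].
#' @param roi list with `x`, `y`, `radius` in px (e.g. around a
#'   [locate_tip()] position).
#' @param threshold PMV contact threshold (default 1).
#' @param frame_rate frames per second for `t_contact`.
#' @param sustain consecutive frames required (default 3).
#' @return an object of class `nt_contact`: list with `pmv` (per-frame
#'   vector), `contact` (logical), `t_contact` (s or NA), `mhi` (last map).
#' @export
contact_pmv <- function(mhi_sequence, roi, threshold = 1, frame_rate = 25,
                        sustain = 3) {
  stopifnot(is.list(mhi_sequence), length(mhi_sequence) >= 1)
  m1 <- mhi_sequence[[1]]
  h <- nrow(m1); w <- ncol(m1)
  if (roi$x < 1 || roi$x > w || roi$y < 1 || roi$y > h)
    stop("ROI centre outside frame", call. = FALSE)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  sel <- (xs - roi$x)^2 + (ys - roi$y)^2 <= roi$radius^2
  pmv <- vapply(mhi_sequence, function(m) mean(m[sel]), numeric(1))
  above <- pmv > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= sustain)
  contact <- length(hit) > 0
  t_contact <- if (contact) (starts[hit[1]] - 1 + 1) / frame_rate else NA_real_
  structure(list(pmv = pmv, contact = contact, t_contact = t_contact,
                 mhi = mhi_sequence[[length(mhi_sequence)]]),
            class = "nt_contact")
}
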