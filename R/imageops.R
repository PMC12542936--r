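# Minimal raster toolbox used by the vision pipeline.  Images are numeric
# matrices indexed [y, x] (row = y, top-left origin, intensities in [0, 1]).

#' Otsu threshold of a grayscale image
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param n_bins histogram bins (default 256).
#' @return threshold value maximizing between-class variance.
#' @export
otsu_threshold <- function(img, n_bins = 256) {
  v <- as.numeric(img)
  v <- v[is.finite(v)]
  h <- tabulate(pmin(pmax(floor(v * n_bins) + 1, 1), n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(n_bins) - 0.5) / n_bins)
  mu_t <- mu[n_bins]
  s2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  s2[!is.finite(s2)] <- 0
  (which.max(s2) - 0.5) / n_bins
}

shift_mat <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Connected-component labelling (8-connectivity)
#'
#' Iterated neighbourhood-minimum label propagation; exact for any mask.
#'
#' @param mask logical matrix.
#' @return integer matrix; 0 = background, components numbered 1..k in
#'   decreasing size order.
#' @export
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(seq_len(h * w), h, w)
  lab[!mask] <- Inf
  repeat {
    nb <- pmin(lab,
               shift_mat(lab, 1, 0, Inf), shift_mat(lab, -1, 0, Inf),
               shift_mat(lab, 0, 1, Inf), shift_mat(lab, 0, -1, Inf),
               shift_mat(lab, 1, 1, Inf), shift_mat(lab, 1, -1, Inf),
               shift_mat(lab, -1, 1, Inf), shift_mat(lab, -1, -1, Inf))
    nb[!mask] <- Inf
    if (all(nb[mask] == lab[mask])) break
    lab <- nb
  }
  out <- matrix(0L, h, w)
  if (any(mask)) {
    ids <- sort(unique(lab[mask]))
    sizes <- vapply(ids, function(i) sum(lab[mask] == i), numeric(1))
    ord <- order(sizes, decreasing = TRUE)
    for (k in seq_along(ord)) out[mask & lab == ids[ord[k]]] <- k
  }
  out
}

#' Chessboard distance to the mask complement by iterated erosion
#'
#' @param mask logical matrix; distances are counted inside the mask
#'   (0 outside, 1 at boundary pixels, ...).
#' @return numeric matrix of distances in px.
#' @export
erosion_distance <- function(mask) {
  d <- matrix(0, nrow(mask), ncol(mask))
  cur <- mask
  while (any(cur)) {
    d[cur] <- d[cur] + 1
    cur <- cur &
      shift_mat(cur, 1, 0, FALSE) & shift_mat(cur, -1, 0, FALSE) &
      shift_mat(cur, 0, 1, FALSE) & shift_mat(cur, 0, -1, FALSE) &
      shift_mat(cur, 1, 1, FALSE) & shift_mat(cur, 1, -1, FALSE) &
      shift_mat(cur, -1, 1, FALSE) & shift_mat(cur, -1, -1, FALSE)
  }
  d
}

dilate8 <- function(mask, n = 1) {
  for (i in seq_len(n))
    mask <- mask |
      shift_mat(mask, 1, 0, FALSE) | shift_mat(mask, -1, 0, FALSE) |
      shift_mat(mask, 0, 1, FALSE) | shift_mat(mask, 0, -1, FALSE) |
      shift_mat(mask, 1, 1, FALSE) | shift_mat(mask, 1, -1, FALSE) |
      shift_mat(mask, -1, 1, FALSE) | shift_mat(mask, -1, -1, FALSE)
  mask
}

erode8 <- function(mask, n = 1) {
  for (i in seq_len(n))
    mask <- mask &
      shift_mat(mask, 1, 0, FALSE) & shift_mat(mask, -1, 0, FALSE) &
      shift_mat(mask, 0, 1, FALSE) & shift_mat(mask, 0, -1, FALSE) &
      shift_mat(mask, 1, 1, FALSE) & shift_mat(mask, 1, -1, FALSE) &
      shift_mat(mask, -1, 1, FALSE) & shift_mat(mask, -1, -1, FALSE)
  mask
}

# box blur with an odd kernel width (separable, edge-replicated)
box_blur <- function(img, width = 5) {
  k <- rep(1 / width, width)
  half <- (width - 1) / 2
  pad <- function(v) c(rep(v[1], half), v, rep(v[length(v)], half))
  smooth1 <- function(v) stats::filter(pad(v), k, sides = 2)[(half + 1):(half + length(v))]
  tmp <- apply(img, 2, smooth1)
  t(apply(t(tmp), 2, smooth1))
}

#' Split a foreground mask at distance-transform peaks
#'
#' Poor-man's watershed: seeds are local maxima of the in-mask distance
#' transform (non-max suppressed within `min_sep`), and foreground pixels
#' are assigned to the nearest seed by breadth-first label propagation.
#'
#' @param mask logical matrix.
#' @param min_sep minimum seed separation in px.
#' @param min_peak minimum distance value for a seed.
#' @return integer label matrix.
#' @export
split_mask_at_peaks <- function(mask, min_sep = 8, min_peak = 3) {
  d <- erosion_distance(mask)
  db <- box_blur(d, 5)
  # local maxima of the blurred distance map
  mx <- db
  for (dy in -2:2) for (dx in -2:2)
    if (dy != 0 || dx != 0) mx <- pmax(mx, shift_mat(db, dy, dx, 0))
  peaks <- which(mask & db >= mx - 1e-9 & d >= min_peak, arr.ind = TRUE)
  if (nrow(peaks) == 0) return(label_components(mask))
  # non-max suppression by separation
  ordp <- order(db[peaks], decreasing = TRUE)
  peaks <- peaks[ordp, , drop = FALSE]
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i < nrow(peaks)) {
      j <- (i + 1):nrow(peaks)
      dd <- sqrt((peaks[j, 1] - peaks[i, 1])^2 + (peaks[j, 2] - peaks[i, 2])^2)
      keep[j][dd < min_sep] <- FALSE
    }
  }
  peaks <- peaks[keep, , drop = FALSE]
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[peaks] <- seq_len(nrow(peaks))
  # geodesic propagation of seed labels through the mask
  repeat {
    grown <- lab
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      sh <- shift_mat(lab, dy, dx, 0L)
      upd <- grown == 0L & sh > 0L & mask
      grown[upd] <- sh[upd]
    }
    if (all(grown == lab)) break
    lab <- grown
  }
  lab
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param px,py point coordinates (vectors).
#' @param poly two-column matrix/data.frame of polygon vertices (closed
#'   implicitly).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  nv <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    cross <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Extract the boundary polygon of a binary mask
#'
#' Uses marching-squares contours at level 0.5; returns the longest
#' contour in (x, y) pixel coordinates.
#'
#' @param mask logical or 0/1 matrix `[y, x]`.
#' @return two-column matrix (x, y), counter-clockwise, or NULL if empty.
#' @export
mask_to_polygon <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(NULL)
  # pad so contours close around border-touching masks
  mp <- matrix(0, nrow(m) + 2, ncol(m) + 2)
  mp[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  cl <- grDevices::contourLines(x = seq_len(nrow(mp)), y = seq_len(ncol(mp)),
                                z = mp, levels = 0.5)
  if (length(cl) == 0) return(NULL)
  len <- vapply(cl, function(c) length(c$x), numeric(1))
  c1 <- cl[[which.max(len)]]
  # contourLines' x follows rows (= image y); convert back and unpad
  poly <- cbind(x = c1$y - 1, y = c1$x - 1)
  # enforce counter-clockwise orientation (image coords, y down)
  area2 <- sum(poly[, 1] * c(poly[-1, 2], poly[1, 2]) -
               c(poly[-1, 1], poly[1, 1]) * poly[, 2])
  if (area2 < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  poly
}

rasterize_polygon <- function(poly, h, w) {
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  matrix(point_in_polygon(as.numeric(xs), as.numeric(ys), poly), h, w)
}
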