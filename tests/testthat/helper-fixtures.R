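# Shared fixture builders and small geometric oracles for the test suite.

default_setup <- function() {
  list(medium = medium_water(),
       body = body_mitochondrion(),
       tip = calibrate_tip(nt_tip()),
       drive = nt_drive(7, 1e6))
}

# water at 298 K: tabulated viscosity 0.8937 mPa s
water_298 <- function() nt_medium(80, 1e-4, 0.8937e-3, 298)

# all bead centres at contact with the apex (r = a), random directions
contact_cluster <- function(n, body, seed) {
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  nt_ensemble(u * body$radius, body, trapped = rep(TRUE, n))
}

# IoU of two polygons on a unit raster of their joint bounding box
polygon_iou <- function(p1, p2) {
  x0 <- floor(min(p1[, 1], p2[, 1])); x1 <- ceiling(max(p1[, 1], p2[, 1]))
  y0 <- floor(min(p1[, 2], p2[, 2])); y1 <- ceiling(max(p1[, 2], p2[, 2]))
  gx <- rep(x0:x1, each = y1 - y0 + 1)
  gy <- rep(y0:y1, x1 - x0 + 1)
  in1 <- point_in_polygon(gx, gy, p1)
  in2 <- point_in_polygon(gx, gy, p2)
  sum(in1 & in2) / sum(in1 | in2)
}

# greedy IoU matching of detections against dish ground truth
match_detections <- function(dets, dish, iou_min = 0.5) {
  used <- integer(0)
  tp <- 0L
  for (d in dets) {
    best <- 0; best_id <- 0L
    for (cl in dish$cells) {
      if (cl$id %in% used) next
      iou <- polygon_iou(d$contour, cl$contour)
      if (iou > best) { best <- iou; best_id <- cl$id }
    }
    if (best >= iou_min) { tp <- tp + 1L; used <- c(used, best_id) }
  }
  list(tp = tp, n_det = length(dets), n_true = length(dish$cells))
}

# render a small static-probe stack; contact fixtures add the membrane
# flicker, no-contact fixtures are a static scene with sensor noise
contact_fixture <- function(contact, seed, n_frames = 10, size = 48) {
  dish <- make_dish(1, fov = c(size, size), seed = seed,
                    params = list(cell_radius_range = c(14, 16)))
  ctr <- dish$cells[[1]]$center
  traj <- matrix(rep(ctr, each = n_frames), ncol = 2)
  render_frames(dish, traj, contact = rep(contact, n_frames),
                region = c(0, 0, size, size), seed = seed,
                noise_sd = 0.005)
}
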