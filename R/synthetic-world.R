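# Seeded generators for every input the pipeline consumes: virtual dishes
# of adherent cells, paired current/fluorescence measurements, rendered
# bright-field-like frames with ground truth, and amperometric traces with
# programmed insertion/withdrawal events.
#
# Fixture regime defaults follow the experimental setting they emulate:
# ~50 cells in a 620 x 500 um field, per-cell depletion time constants
# log-normal with median 12 s, initial ROS/RNS concentrations high enough
# for an 8-pA detection at the default calibration, escape probability
# 15/47, per-attempt death probability 0.04 (96% single-attempt survival).

dish_defaults <- function() {
  list(cell_radius_range = c(12, 20),     # semi-major axis, um
       aspect_range = c(0.7, 1.0),
       nucleus_frac_range = c(0.35, 0.5),
       tau_meanlog = log(12), tau_sdlog = 0.35,
       c0_meanlog = log(0.8), c0_sdlog = 0.4,   # mM
       escape_probability = 15 / 47,
       death_probability = 0.04,
       compliance_range = c(1.5, 3),      # um of deformation before entry
       mito_density_range = c(0.4, 1),
       nucleus_ros_factor = 0.08,
       overlap_tolerance = 2)             # um of allowed contour overlap
}

ellipse_poly <- function(center, rx, ry, angle = 0, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- rx * cos(th); y <- ry * sin(th)
  ca <- cos(angle); sa <- sin(angle)
  cbind(x = center[1] + x * ca - y * sa,
        y = center[2] + x * sa + y * ca)
}

#' Generate a virtual dish of adherent cells
#'
#' Rejection-samples non-overlapping elliptical cells with nuclei in a
#' rectangular field of view and draws all per-cell physiology (depletion
#' time constant, initial ROS/RNS concentration, adhesion, compliance,
#' mitochondrial density) from the fixture-regime distributions.  Fully
#' reproducible from `seed`.
#'
#' @param n_cells number of cells (>= 0).
#' @param fov field of view `c(width, height)` in um (default 620 x 500).
#' @param seed integer seed.
#' @param params named list overriding entries of the default parameter
#'   set (see source of `dish_defaults`).
#' @return an object of class `nt_dish`: list with `cells`, `fov`, `seed`.
#' @export
make_dish <- function(n_cells = 50, fov = c(620, 500), seed = 1,
                      params = list()) {
  if (n_cells < 0) stop("n_cells must be >= 0", call. = FALSE)
  p <- utils::modifyList(dish_defaults(), params)
  cells <- list()
  with_seed(seed, {
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    tries <- 0L
    while (length(cells) < n_cells) {
      tries <- tries + 1L
      if (tries > 300L * max(n_cells, 1))
        stop("packing error: cannot place ", n_cells, " cells in the field",
             call. = FALSE)
      rx <- stats::runif(1, p$cell_radius_range[1], p$cell_radius_range[2])
      ry <- rx * stats::runif(1, p$aspect_range[1], p$aspect_range[2])
      r <- max(rx, ry)
      ctr <- c(stats::runif(1, r, fov[1] - r), stats::runif(1, r, fov[2] - r))
      if (nrow(centers) > 0) {
        dd <- sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2)
        if (any(dd < radii + r - p$overlap_tolerance)) next
      }
      ang <- stats::runif(1, 0, pi)
      nf <- stats::runif(1, p$nucleus_frac_range[1], p$nucleus_frac_range[2])
      noff <- stats::runif(2, -0.2, 0.2) * c(rx, ry) * (1 - nf)
      id <- length(cells) + 1L
      cells[[id]] <- list(
        id = id, center = ctr, rx = rx, ry = ry, angle = ang,
        contour = ellipse_poly(ctr, rx, ry, ang),
        nucleus_center = ctr + noff,
        nucleus_contour = ellipse_poly(ctr + noff, rx * nf, ry * nf, ang),
        adherent = p$escape_probability < 0.5,
        escape_probability = p$escape_probability,
        death_probability_per_attempt = p$death_probability,
        ros_c0 = stats::rlnorm(1, p$c0_meanlog, p$c0_sdlog),
        tau = stats::rlnorm(1, p$tau_meanlog, p$tau_sdlog),
        mito_density = stats::runif(1, p$mito_density_range[1],
                                    p$mito_density_range[2]),
        nucleus_ros_factor = p$nucleus_ros_factor,
        membrane_compliance = stats::runif(1, p$compliance_range[1],
                                           p$compliance_range[2]))
      centers <- rbind(centers, ctr)
      radii <- c(radii, r)
    }
  })
  structure(list(cells = cells, fov = fov, seed = seed, params = p),
            class = "nt_dish")
}

#' Local ROS/RNS concentration inside a cell
#'
#' High in the cytoplasm, suppressed to `nucleus_ros_factor` of the
#' cytoplasmic value inside the nucleus (the nuclear region carries both
#' low ROS/RNS and low mitochondrial fluorescence), 0 outside the cell.
#'
#' @param cell a cell from [make_dish()].
#' @param point c(x, y) in um.
#' @return concentration in mM.
#' @export
cell_ros_at <- function(cell, point) {
  if (!point_in_polygon(point[1], point[2], cell$contour)) return(0)
  if (point_in_polygon(point[1], point[2], cell$nucleus_contour))
    return(cell$ros_c0 * cell$nucleus_ros_factor)
  cell$ros_c0
}

#' Generate paired current/fluorescence measurements
#'
#' Both channels read a latent per-measurement mitochondrial density with
#' independent Gaussian noises sized so the population Pearson correlation
#' is exactly `coupling_rho`.
#'
#' @param n_points number of measurements.
#' @param coupling_rho target population correlation in `[-1, 1]`.
#' @param seed integer seed.
#' @param current_scale c(mean, sd) of the current channel in pA.
#' @param fluor_scale c(mean, sd) of the fluorescence channel (a.u.).
#' @return data.frame with columns `current`, `fluorescence`.
#' @export
make_paired_measurements <- function(n_points = 89, coupling_rho = 0.65,
                                     seed = 1,
                                     current_scale = c(15, 5),
                                     fluor_scale = c(100, 30)) {
  if (abs(coupling_rho) > 1) stop("|coupling_rho| must be <= 1", call. = FALSE)
  with_seed(seed, {
    z <- stats::rnorm(n_points)
    if (coupling_rho == 0) {
      cur <- stats::rnorm(n_points)
      flu <- stats::rnorm(n_points)
    } else {
      s <- sqrt(1 / abs(coupling_rho) - 1)
      cur <- z + s * stats::rnorm(n_points)
      flu <- sign(coupling_rho) * z + s * stats::rnorm(n_points)
    }
    data.frame(
      current = current_scale[1] + current_scale[2] * scale01(cur),
      fluorescence = fluor_scale[1] + fluor_scale[2] * scale01(flu))
  })
}

scale01 <- function(x) if (stats::sd(x) == 0) x - mean(x) else
  (x - mean(x)) / stats::sd(x)

# -- frame rendering ---------------------------------------------------------

render_base <- function(dish, region, pixel_size, seed) {
  w <- ceiling((region[3] - region[1]) / pixel_size)
  h <- ceiling((region[4] - region[2]) / pixel_size)
  xs <- region[1] + (matrix(rep(seq_len(w), each = h), h, w) - 0.5) * pixel_size
  ys <- region[2] + (matrix(rep(seq_len(h), w), h, w) - 0.5) * pixel_size
  img <- matrix(0.45, h, w)
  labels <- matrix(0L, h, w)
  nuclei <- matrix(FALSE, h, w)
  tex <- with_seed(seed, box_blur(matrix(stats::rnorm(h * w), h, w), 7))
  for (cell in dish$cells) {
    inc <- matrix(point_in_polygon(as.numeric(xs), as.numeric(ys),
                                   cell$contour), h, w)
    if (!any(inc)) next
    img[inc] <- 0.62 + 0.05 * tex[inc]
    labels[inc] <- cell$id
    inn <- matrix(point_in_polygon(as.numeric(xs), as.numeric(ys),
                                   cell$nucleus_contour), h, w)
    img[inn] <- 0.25 + 0.02 * tex[inn]
    nuclei <- nuclei | inn
  }
  list(img = img, labels = labels, nuclei = nuclei, w = w, h = h)
}

draw_needle <- function(img, tip_px, angle = 45, width = 2, intensity = 0.92,
                        length_px = 1e4) {
  h <- nrow(img); w <- ncol(img)
  dirv <- c(cos(angle * pi / 180), sin(angle * pi / 180))
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  relx <- xs - tip_px[1]; rely <- ys - tip_px[2]
  # needle occupies the half-line behind the tip along -dir
  s <- -(relx * dirv[1] + rely * dirv[2])       # distance behind tip
  d <- abs(-relx * dirv[2] + rely * dirv[1])    # perpendicular offset
  shaft <- s >= 0 & s <= length_px & d <= width
  img[shaft] <- intensity
  img
}

#' Render a bright-field-like image stack with ground truth
#'
#' Cells are textured bright ellipses with darker nuclei on a gray
#' background; the needle is an oriented bright ridge ending at the tip;
#' contact frames animate a local membrane-deformation flicker at the tip
#' so the motion-history pipeline sees it; Gaussian sensor noise is added
#' per frame.
#'
#' @param dish an [nt_dish()].
#' @param trajectory data.frame/matrix with columns x, y (tip position per
#'   frame, um), or NULL for a probe-free stack.
#' @param n_frames frames to render when `trajectory` is NULL.
#' @param contact logical per-frame vector marking membrane contact.
#' @param region crop `c(x0, y0, x1, y1)` in um (default: whole dish fov).
#' @param pixel_size um per px.
#' @param frame_rate frames per second.
#' @param noise_sd Gaussian noise SD (intensity units).
#' @param seed integer seed.
#' @return list with `stack` ([nt_stack()]), `tip_px` (n x 2 matrix or
#'   NULL), `labels` (cell-id mask), `nuclei` (logical mask), `contact`
#'   (logical vector).
#' @export
render_frames <- function(dish, trajectory = NULL, n_frames = 12,
                          contact = NULL,
                          region = NULL, pixel_size = 1, frame_rate = 25,
                          noise_sd = 0.01, seed = 1) {
  if (is.null(region)) region <- c(0, 0, dish$fov[1], dish$fov[2])
  if (!is.null(trajectory)) {
    trajectory <- as.matrix(trajectory)
    n_frames <- nrow(trajectory)
  }
  if (is.null(contact)) contact <- rep(FALSE, n_frames)
  base <- render_base(dish, region, pixel_size, seed)
  h <- base$h; w <- base$w
  frames <- array(0, dim = c(h, w, n_frames))
  tip_px <- NULL
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  with_seed(seed + 1L, {
    for (f in seq_len(n_frames)) {
      img <- base$img
      if (!is.null(trajectory)) {
        tp <- c((trajectory[f, 1] - region[1]) / pixel_size,
                (trajectory[f, 2] - region[2]) / pixel_size)
        img <- draw_needle(img, tp)
        if (is.null(tip_px)) tip_px <- matrix(NA_real_, n_frames, 2)
        tip_px[f, ] <- tp
        if (contact[f]) {
          rr2 <- (xs - tp[1])^2 + (ys - tp[2])^2
          zone <- rr2 <= 36
          img[zone] <- img[zone] +
            0.12 * sin(2 * pi * f / 3 + rr2[zone] / 8)
        }
      }
      img <- img + stats::rnorm(h * w, sd = noise_sd)
      frames[, , f] <- pmin(pmax(img, 0), 1)
    }
  })
  list(stack = nt_stack(frames, frame_rate, pixel_size),
       tip_px = tip_px, labels = base$labels, nuclei = base$nuclei,
       contact = contact)
}

#' Synthesize an amperometric trace for one penetration of a cell
#'
#' Baseline outside the cell; a current step at membrane penetration
#' scaled by the sensor calibration at the local ROS/RNS concentration;
#' exponential sealed-chamber depletion with the cell's time constant
#' while inside; return to baseline at the withdrawal separation point.
#' The synchronized position channel follows the insertion speed and the
#' cell's membrane compliance.
#'
#' @param cell a cell from [make_dish()] (or a list with the same fields).
#' @param cal an [sensor_calibration()].
#' @param t_contact contact time in s.
#' @param inside_window time spent sensing inside the cell in s.
#' @param insertion_speed probe speed in um/s (default 200).
#' @param insertion_point c(x, y) um inside the cell (default: cell
#'   centroid offset away from the nucleus); sets the local concentration.
#' @param noise_sd current noise SD in pA.
#' @param tail extra recording after separation in s.
#' @param sample_rate Hz.
#' @param seed integer seed.
#' @param depletion_elapsed cumulative prior sensing time in s (repeated
#'   penetrations keep depleting the same sealed volume).
#' @return an [nt_trace()] with position channel, `contact`/`withdraw`
#'   annotations, and a `truth` field recording the generative values.
#' @export
make_trace <- function(cell, cal = sensor_calibration(),
                       t_contact = 0.5, inside_window = 2,
                       insertion_speed = 200, insertion_point = NULL,
                       noise_sd = 0.5, tail = 0.5, sample_rate = 1000,
                       seed = NULL, depletion_elapsed = 0) {
  compliance <- cell$membrane_compliance
  t_insert <- t_contact + compliance / insertion_speed
  t_wstart <- t_insert + inside_window
  wdef <- 0.7 * compliance
  t_sep <- t_wstart + wdef / insertion_speed
  total <- t_sep + tail
  n <- round(total * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  if (is.null(insertion_point)) {
    # medial cytoplasm point (inside the cell, clear of the nucleus)
    insertion_point <- tryCatch(plan_insertion_point(cell, margin = 1),
                                error = function(e) cell$center)
  }
  c_local <- cell_ros_at(cell, insertion_point)
  amp <- calibration_current(cal, c_local) - cal$intercept
  inside <- t >= t_insert & t < t_sep
  cur <- rep(0, n)
  cur[inside] <- amp *
    exp(-(depletion_elapsed + (t[inside] - t_insert)) / cell$tau)
  if (noise_sd > 0)
    cur <- cur + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  # probe d-axis position: approach, deform, dwell, retract
  pos <- numeric(n)
  seg1 <- t < t_insert                       # approaching + deforming
  pos[seg1] <- insertion_speed * t[seg1]
  d_in <- insertion_speed * t_insert
  seg2 <- t >= t_insert & t < t_wstart       # stationary inside
  pos[seg2] <- d_in
  seg3 <- t >= t_wstart                      # retracting
  pos[seg3] <- pmax(d_in - insertion_speed * (t[seg3] - t_wstart), 0)
  tr <- nt_trace(cur, sample_rate, position = pos,
                 annotations = data.frame(
                   time = c(t_contact, t_wstart),
                   label = c("contact", "withdraw")))
  tr$truth <- list(t_insert = t_insert, t_withdraw_sep = t_sep,
                   tau = cell$tau, amplitude = amp, c_local = c_local,
                   insertion_deformation = compliance,
                   withdrawal_deformation = wdef)
  tr
}
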