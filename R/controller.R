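# The automation state machine: plan insertion points avoiding nuclei,
# order targets, then per cell contact -> penetrate -> sense -> decide ->
# biopsy -> retract against the virtual dish, with complete event logging.

#' Protocol configuration
#'
#' Defaults follow the automated run the twin emulates: 200 um/s
#' insertion, 1-s sense window at 1 kHz, 8-pA decision threshold, 7 Vpp /
#' 1 MHz trapping drive held for 60 s, at most 7 attempts per cell.
#'
#' @param insertion_speed um/s.
#' @param sense_window s.
#' @param current_threshold pA.
#' @param dep_voltage_pp V.
#' @param dep_frequency Hz.
#' @param dep_dwell s.
#' @param max_attempts_per_cell integer >= 1.
#' @param seed integer seed for the whole run.
#' @param sample_rate sensor rate in Hz.
#' @param noise_sd current noise SD in pA.
#' @param retraction_speed um/s during DEP-on retraction.
#' @param stage_speed um/s for dish travel between cells.
#' @param margin planning margin in um (cell erosion / nucleus dilation).
#' @param reposition_min_dist um between successive attempts on a cell.
#' @return an object of class `nt_protocol`.
#' @export
nt_protocol <- function(insertion_speed = 200, sense_window = 1,
                        current_threshold = 8, dep_voltage_pp = 7,
                        dep_frequency = 1e6, dep_dwell = 60,
                        max_attempts_per_cell = 7L, seed = 1L,
                        sample_rate = 1000, noise_sd = 0.5,
                        retraction_speed = 200, stage_speed = 500,
                        margin = 2, reposition_min_dist = 2) {
  vals <- c(insertion_speed, sense_window, current_threshold,
            dep_voltage_pp, dep_frequency, dep_dwell, sample_rate,
            retraction_speed, stage_speed, margin)
  if (any(vals <= 0)) stop("all protocol parameters must be positive",
                           call. = FALSE)
  if (max_attempts_per_cell < 1) stop("max_attempts_per_cell must be >= 1",
                                      call. = FALSE)
  structure(list(insertion_speed = insertion_speed,
                 sense_window = sense_window,
                 current_threshold = current_threshold,
                 dep_voltage_pp = dep_voltage_pp,
                 dep_frequency = dep_frequency, dep_dwell = dep_dwell,
                 max_attempts_per_cell = as.integer(max_attempts_per_cell),
                 seed = as.integer(seed), sample_rate = sample_rate,
                 noise_sd = noise_sd, retraction_speed = retraction_speed,
                 stage_speed = stage_speed, margin = margin,
                 reposition_min_dist = reposition_min_dist),
            class = "nt_protocol")
}

#' Plan a nucleus-avoiding insertion point
#'
#' Returns the medial point of the cytoplasmic band: the point inside the
#' cell contour eroded by `margin` and outside the nucleus contour dilated
#' by `margin` that maximizes the smaller of the two boundary distances.
#' Works on a unit-spaced raster of the cell's bounding box.
#'
#' @param cell list with `contour` and `nucleus_contour` (two-column
#'   matrices, any planar unit; the answer is in the same unit).
#' @param margin erosion/dilation margin (same unit as the contours).
#' @return `c(x, y)`; errors if the feasible band is empty.
#' @export
plan_insertion_point <- function(cell, margin = 2) {
  poly <- cell$contour
  npoly <- cell$nucleus_contour
  if (is.null(npoly)) stop("cell has no nucleus contour", call. = FALSE)
  x0 <- floor(min(poly[, 1])) - 1; x1 <- ceiling(max(poly[, 1])) + 1
  y0 <- floor(min(poly[, 2])) - 1; y1 <- ceiling(max(poly[, 2])) + 1
  w <- x1 - x0 + 1; h <- y1 - y0 + 1
  gx <- matrix(rep(x0:x1, each = h), h, w)
  gy <- matrix(rep(y0:y1, w), h, w)
  inc <- matrix(point_in_polygon(as.numeric(gx), as.numeric(gy), poly), h, w)
  inn <- matrix(point_in_polygon(as.numeric(gx), as.numeric(gy), npoly), h, w)
  dcell <- erosion_distance(inc)            # distance to cell outside
  dnuc <- erosion_distance(!inn)            # distance to nucleus
  feas <- inc & !inn & dcell > margin & dnuc > margin
  if (!any(feas))
    stop("no feasible insertion point: cytoplasmic band is empty",
         call. = FALSE)
  score <- pmin(dcell, dnuc)
  score[!feas] <- -Inf
  best <- which.max(score)
  c(x = gx[best], y = gy[best])
}

#' Nearest-neighbour target ordering
#'
#' Greedy tour from the current probe position; never longer on average
#' than a random visiting order.
#'
#' @param points n x 2 matrix of target positions.
#' @param start `c(x, y)` starting position (default origin).
#' @return integer visiting order (row indices of `points`).
#' @export
order_targets <- function(points, start = c(0, 0)) {
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(points)
  if (n == 0) return(integer(0))
  left <- seq_len(n)
  cur <- start
  ord <- integer(n)
  for (i in seq_len(n)) {
    dd <- sqrt((points[left, 1] - cur[1])^2 + (points[left, 2] - cur[2])^2)
    j <- left[which.min(dd)]
    ord[i] <- j
    cur <- points[j, ]
    left <- setdiff(left, j)
  }
  ord
}

tour_length <- function(points, ord, start = c(0, 0)) {
  pts <- rbind(start, points[ord, , drop = FALSE])
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Diffusive capture rate of organelles into the trap sphere (1/s):
# Smoluchowski flux 4 pi D R times an effective number density scaled by
# the cell's mitochondrial density.
capture_rate <- function(body, medium, tip, drive, mito_density,
                         density_scale = 2e17) {
  R <- trapping_radius(body, medium, tip, drive)
  if (R <= 0) return(0)
  gamma <- 6 * pi * medium$viscosity * body$radius
  D <- KB * medium$temperature / gamma
  4 * pi * D * R * density_scale * mito_density
}

#' Run the automated sense-then-extract protocol on a virtual dish
#'
#' For each cell (nearest-neighbour order over planned nucleus-avoiding
#' insertion points): contact detection, one penetration attempt (the
#' cell escapes with its escape probability; an escaped cell is a failed
#' operation), intracellular sensing for `sense_window` at the sensor
#' rate, threshold decision, and on detection a DEP biopsy (drive on for
#' `dep_dwell`, retraction with the drive held on).  A cell sensed without
#' detection is re-probed at a repositioned point up to
#' `max_attempts_per_cell` times.  Every sensing interval is logged at the
#' full sensor rate; every attempt gets a terminal outcome.
#'
#' @param dish an [nt_dish()].
#' @param config an [nt_protocol()].
#' @param medium,tip,body DEP model components for the biopsy stage
#'   (defaults: working medium, calibrated default tip, default
#'   mitochondrion).
#' @param cal an [sensor_calibration()].
#' @return an object of class `nt_runlog`: list with `events`
#'   (data.frame: cell, attempt, t_start, phase durations, outcome),
#'   `samples` (data.frame: time, current, probe_d, cell, attempt),
#'   `records` (data.frame of biopsy records: cell, attempts, penetrated,
#'   detected, trapped_count, retraction_retained, extracted), `config`.
#' @export
run_protocol <- function(dish, config = nt_protocol(),
                         medium = medium_water(),
                         tip = calibrate_tip(nt_tip()),
                         body = body_mitochondrion(),
                         cal = sensor_calibration()) {
  stopifnot(inherits(dish, "nt_dish"), inherits(config, "nt_protocol"))
  cells <- dish$cells
  empty_log <- list(events = data.frame(), samples = data.frame(),
                    records = data.frame(), config = config)
  class(empty_log) <- "nt_runlog"
  if (length(cells) == 0) return(empty_log)
  drive <- nt_drive(config$dep_voltage_pp, config$dep_frequency)
  pts <- t(vapply(cells, function(cl)
    tryCatch(plan_insertion_point(cl, config$margin),
             error = function(e) cl$center), numeric(2)))
  ord <- order_targets(pts, start = c(0, 0))
  events <- list(); samples <- list(); records <- list()
  with_seed(config$seed, {
    clock <- 0; probe_xy <- c(0, 0)
    for (ci in ord) {
      cell <- cells[[ci]]
      pt <- pts[ci, ]
      clock <- clock + sqrt(sum((pt - probe_xy)^2)) / config$stage_speed
      probe_xy <- pt
      depleted <- 0
      detected <- FALSE; extracted <- FALSE; penetrated <- FALSE
      trapped_count <- 0L; retained <- FALSE
      attempt <- 0L
      repeat {
        attempt <- attempt + 1L
        escaped <- stats::runif(1) < cell$escape_probability
        if (escaped) {
          events[[length(events) + 1]] <- data.frame(
            cell = cell$id, attempt = attempt, t_start = clock,
            outcome = "escape")
          clock <- clock + 2 * cell$membrane_compliance /
            config$insertion_speed
          break
        }
        penetrated <- TRUE
        tr <- make_trace(cell, cal, t_contact = 0.2,
                         inside_window = config$sense_window,
                         insertion_speed = config$insertion_speed,
                         insertion_point = pt,
                         noise_sd = config$noise_sd,
                         sample_rate = config$sample_rate,
                         seed = NULL, depletion_elapsed = depleted)
        depleted <- depleted + config$sense_window
        det <- detect_mitochondrion(tr, config$current_threshold)
        nt <- length(tr$current)
        samples[[length(samples) + 1]] <- data.frame(
          time = clock + trace_time(tr), current = tr$current,
          probe_d = tr$position, cell = cell$id, attempt = attempt)
        t_end <- clock + nt / config$sample_rate
        if (det$detected) {
          detected <- TRUE
          lam <- capture_rate(body, medium, tip, drive, cell$mito_density)
          trapped_count <- min(stats::rpois(1, lam * config$dep_dwell), 25L)
          fhold <- abs(dep_force(body, medium, tip, drive, body$radius))
          drag <- 6 * pi * medium$viscosity * body$radius *
            (config$retraction_speed * 1e-6)
          retained <- fhold >= drag
          extracted <- trapped_count >= 1 && retained
          clock <- t_end + config$dep_dwell
          events[[length(events) + 1]] <- data.frame(
            cell = cell$id, attempt = attempt, t_start = t_end,
            outcome = if (extracted) "extracted" else "biopsy_failed")
          break
        }
        events[[length(events) + 1]] <- data.frame(
          cell = cell$id, attempt = attempt, t_start = t_end,
          outcome = "no_detection")
        clock <- t_end
        if (attempt >= config$max_attempts_per_cell) break
        # reposition: next feasible point >= reposition_min_dist away
        ang <- stats::runif(1, 0, 2 * pi)
        cand <- pt + config$reposition_min_dist * 1.2 * c(cos(ang), sin(ang))
        if (point_in_polygon(cand[1], cand[2], cell$contour) &&
            !point_in_polygon(cand[1], cand[2], cell$nucleus_contour))
          pt <- cand
      }
      records[[length(records) + 1]] <- data.frame(
        cell = cell$id, attempts = attempt, penetrated = penetrated,
        detected = detected, trapped_count = trapped_count,
        retraction_retained = retained, extracted = extracted)
    }
  })
  structure(list(events = do.call(rbind, events),
                 samples = do.call(rbind, samples),
                 records = do.call(rbind, records),
                 config = config),
            class = "nt_runlog")
}

#' Survival versus penetration count
#'
#' Draws per-attempt viability from each cell's per-penetration death
#' probability and aggregates a Kaplan-Meier-style survival curve over
#' attempt number (monotone nonincreasing by construction).
#'
#' @param log an `nt_runlog` from [run_protocol()].
#' @param dish the dish the log was produced from.
#' @param seed integer seed for the viability draws.
#' @return data.frame with `attempt`, `at_risk`, `deaths`, `survival`.
#' @export
survival_report <- function(log, dish, seed = 1) {
  stopifnot(inherits(log, "nt_runlog"))
  rec <- log$records
  if (is.null(rec) || nrow(rec) == 0)
    return(data.frame(attempt = integer(), at_risk = integer(),
                      deaths = integer(), survival = numeric()))
  pdeath <- vapply(rec$cell, function(id)
    dish$cells[[id]]$death_probability_per_attempt, numeric(1))
  kmax <- max(rec$attempts)
  at_risk <- deaths <- integer(kmax)
  with_seed(seed, {
    alive <- rep(TRUE, nrow(rec))
    for (k in seq_len(kmax)) {
      risk <- alive & rec$attempts >= k
      at_risk[k] <- sum(risk)
      die <- risk & stats::runif(nrow(rec)) < pdeath
      deaths[k] <- sum(die)
      alive[die] <- FALSE
    }
  })
  surv <- cumprod(ifelse(at_risk > 0, 1 - deaths / at_risk, 1))
  data.frame(attempt = seq_len(kmax), at_risk = at_risk,
             deaths = deaths, survival = surv)
}
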