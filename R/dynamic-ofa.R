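#' Power-stroke trajectory
#'
#' Ordered waypoints (mm, in the occlusal frame of the upper mesh) that the
#' lower tooth's reference origin follows during the power stroke. Waypoints
#' up to and including the maximum-intercuspation waypoint are phase I (the
#' upward, anteriorly and medially directed closing movement); later
#' waypoints are phase II (the anterior, medial and slightly downward
#' movement after intercuspation).
#'
#' @param waypoints numeric matrix (rows = 3D waypoints, >= 2, consecutive
#'   waypoints distinct).
#' @param intercuspation_index 1-based index of the maximum-intercuspation
#'   waypoint.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(waypoints, intercuspation_index) {
  w <- as.matrix(waypoints)
  stopifnot(ncol(w) == 3L, nrow(w) >= 2L)
  steps <- diff(w)
  if (any(sqrt(rowSums(steps^2)) < 1e-12))
    stop("consecutive waypoints must be distinct", call. = FALSE)
  k <- as.integer(intercuspation_index)
  if (k < 1L || k > nrow(w))
    stop("intercuspation_index out of range", call. = FALSE)
  structure(list(waypoints = w, intercuspation_index = k),
            class = "trajectory")
}

#' Read / write a trajectory as JSON
#'
#' JSON layout: `{"waypoints": [[x,y,z], ...], "intercuspation_index": k}`
#' with a 0-based index on disk (1-based in R).
#'
#' @param path JSON path.
#' @return a [trajectory()].
#' @export
read_trajectory_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trajectory(matrix(as.numeric(t(obj$waypoints)), ncol = 3L, byrow = TRUE),
             as.integer(obj$intercuspation_index) + 1L)
}

#' @rdname read_trajectory_json
#' @param traj a [trajectory()].
#' @export
write_trajectory_json <- function(traj, path) {
  jsonlite::write_json(
    list(waypoints = apply(traj$waypoints, 1L, as.numeric, simplify = FALSE),
         intercuspation_index = traj$intercuspation_index - 1L),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Collision-simulation configuration
#'
#' @param step_mm attempted advance per timestep (mm); the canonical
#'   power-stroke simulation step is 0.05 mm.
#' @param contact_eps faces whose centroid lies closer than this to the
#'   antagonist surface count as in contact (mm).
#' @param penetration_tol maximum tolerated interpenetration after collision
#'   resolution (mm).
#' @param max_iter maximum bisection/slide resolution iterations per step.
#' @param seed reproducibility placeholder recorded in outputs (the
#'   simulation itself is deterministic).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(step_mm = 0.05, contact_eps = 0.02,
                              penetration_tol = 0.005, max_iter = 20L,
                              seed = NULL) {
  stopifnot(step_mm > 0, contact_eps > 0, penetration_tol > 0,
            step_mm >= penetration_tol, max_iter >= 1L)
  structure(list(step_mm = step_mm, contact_eps = contact_eps,
                 penetration_tol = penetration_tol,
                 max_iter = as.integer(max_iter), seed = seed),
            class = "simulation_config")
}

#' Contact detection between antagonist meshes
#'
#' A lower-mesh face is in contact when its centroid's signed distance to the
#' upper surface is below `eps`; negative distances are interpenetration.
#' Signed distance uses the closest-point query against the upper mesh with
#' the closest face's normal fixing the sign, so the upper mesh's occluding
#' surface must face the lower tooth.
#'
#' @param lower,upper [triangle_mesh()] objects in a common frame.
#' @param eps contact distance threshold (mm).
#' @return list with `faces` (1-based lower-face indices in contact), `area`
#'   (mm^2), `penetration` (mm, >= 0), `distances` (per lower face).
#' @export
detect_contact <- function(lower, upper, eps = 0.02) {
  stopifnot(inherits(lower, "triangle_mesh"), inherits(upper, "triangle_mesh"))
  res <- .point_mesh_signed_distance(face_centroids(lower), upper$vertices,
                                     upper$faces)
  d <- res$distance
  faces <- which(d < eps)
  a <- triangle_areas(lower$vertices, lower$faces)
  list(faces = faces, area = sum(a[faces]),
       penetration = max(0, -min(d)), distances = d)
}

#' One timestep of the power-stroke simulation
#'
#' Translates the lower mesh toward the target waypoint by at most one step
#' length. If the move interpenetrates the upper mesh beyond tolerance, the
#' advance is bisected back along the step direction until the penetration is
#' tolerable, then one tangential slide is attempted: the remaining motion is
#' projected onto the mean contact plane (mean normal of the lower contact
#' faces) and applied as far as tolerance allows. If no advance at all
#' satisfies the tolerance the step is flagged `"jammed"`.
#'
#' @param lower the lower [triangle_mesh()] at its reference pose.
#' @param offset current translation of the lower mesh (3-vector).
#' @param target target waypoint (3-vector) for the reference origin, which
#'   sits at `offset` relative to the start of the trajectory.
#' @param upper the upper [triangle_mesh()].
#' @param config a [simulation_config()].
#' @return list with `offset` (new translation), `contact` (from
#'   [detect_contact()] at the final pose), `advanced` (mm actually moved),
#'   `status` (`"free"`, `"contact"` or `"jammed"`).
#' @export
advance_step <- function(lower, offset, target, upper, config) {
  stopifnot(inherits(config, "simulation_config"))
  dir <- target - offset
  remaining <- sqrt(sum(dir^2))
  if (remaining < 1e-12)
    return(list(offset = offset, contact = contact_at(lower, offset, upper, config),
                advanced = 0, status = "at_waypoint"))
  u <- dir / remaining
  step <- min(config$step_mm, remaining)

  pen_at <- function(t) contact_at(lower, offset + t * u, upper, config)
  trial <- pen_at(step)
  iter <- 0L
  t_ok <- step
  if (trial$penetration > config$penetration_tol) {
    # back off to 80% of the tolerance so the subsequent tangential slide
    # has headroom and a pose resting at the tolerance cannot deadlock
    tol_resolve <- 0.8 * config$penetration_tol
    lo <- 0; hi <- step
    c_lo <- pen_at(0)
    if (c_lo$penetration > config$penetration_tol) {
      # cannot satisfy tolerance even without advancing
      return(list(offset = offset, contact = c_lo, advanced = 0,
                  status = "jammed"))
    }
    while (iter < config$max_iter && (hi - lo) > 1e-6) {
      mid <- (lo + hi) / 2
      cm <- pen_at(mid)
      if (cm$penetration > tol_resolve) hi <- mid else { lo <- mid; c_lo <- cm }
      iter <- iter + 1L
    }
    # the faces that actually block the full step (penetrating at the trial
    # pose) define the contact plane; faces merely within the contact
    # threshold must not steer the slide
    blocking <- trial$faces[trial$distances[trial$faces] < 0]
    if (length(blocking) == 0L) blocking <- trial$faces
    t_ok <- lo
    trial <- c_lo
    # tangential slide of the leftover motion along the mean contact plane
    leftover <- step - t_ok
    if (leftover > 1e-9 && length(blocking) > 0L) {
      nrm <- face_normals(lower)[blocking, , drop = FALSE]
      nbar <- colMeans(nrm)
      nn <- sqrt(sum(nbar^2))
      if (nn > 1e-9) {
        nbar <- nbar / nn
        tang <- (u - sum(u * nbar) * nbar) * leftover
        tl <- sqrt(sum(tang^2))
        if (tl > 1e-9) {
          base <- offset + t_ok * u
          slide_at <- function(s) {
            detect_contact(translate_mesh(lower, base + s * tang), upper,
                           config$contact_eps)
          }
          cs <- slide_at(1)
          if (cs$penetration <= config$penetration_tol) {
            return(list(offset = base + tang, contact = cs,
                        advanced = t_ok + tl, status = "contact"))
          }
          lo2 <- 0; hi2 <- 1; c2 <- trial
          while (iter < config$max_iter && (hi2 - lo2) > 1e-3) {
            mid <- (lo2 + hi2) / 2
            cm <- slide_at(mid)
            if (cm$penetration > config$penetration_tol) hi2 <- mid
            else { lo2 <- mid; c2 <- cm }
            iter <- iter + 1L
          }
          return(list(offset = base + lo2 * tang, contact = c2,
                      advanced = t_ok + lo2 * tl, status = "contact"))
        }
      }
    }
  }
  status <- if (length(trial$faces) > 0L) "contact" else "free"
  list(offset = offset + t_ok * u, contact = trial, advanced = t_ok,
       status = status)
}

contact_at <- function(lower, offset, upper, config) {
  detect_contact(translate_mesh(lower, offset), upper, config$contact_eps)
}

#' Simulate the masticatory power stroke
#'
#' Advances the lower mesh along the trajectory in timesteps of at most the
#' configured step length (0.05 mm by default), detecting contacts with the
#' upper mesh at every step and classifying contact areas by the lower
#' mesh's wear-facet annotation. Deterministic for fixed inputs; per-step
#' failures are recorded in the `status` column, never aborting the run.
#'
#' The lower mesh is supplied at the pose corresponding to the first
#' waypoint; waypoints are absolute positions of its reference origin.
#'
#' @param lower annotated lower [triangle_mesh()] positioned at the first
#'   waypoint.
#' @param upper upper [triangle_mesh()] in the same frame.
#' @param annotation a [facet_annotation()] for `lower`.
#' @param catalog a [facet_catalog()].
#' @param traj a [trajectory()].
#' @param config a [simulation_config()].
#' @return data.frame of class `contact_timeline` with columns `step`,
#'   `phase` (`"I"`/`"II"`), `x`, `y`, `z` (lower origin position),
#'   `area_bpi`, `area_lpi`, `area_pii`, `area_unlabeled` (mm^2),
#'   `penetration` (mm), `status`.
#' @export
simulate_power_stroke <- function(lower, upper, annotation, catalog, traj,
                                  config = simulation_config()) {
  stopifnot(inherits(traj, "trajectory"))
  check_annotation(lower, annotation, catalog)
  areas <- triangle_areas(lower$vertices, lower$faces)
  face_class <- rep(NA_character_, nrow(lower$faces))
  face_class[annotation$face_index] <-
    as.character(catalog[annotation$facet_label])

  w <- traj$waypoints
  start <- w[1L, ]
  # lower is given at the first waypoint; track absolute origin position
  lower0 <- translate_mesh(lower, -start)
  pos <- start
  path_len <- sum(sqrt(rowSums(diff(w)^2)))
  max_steps <- 10L * ceiling(path_len / config$step_mm) + 10L
  rows <- list()
  step_i <- 0L
  for (wi in 2L:nrow(w)) {
    phase <- if (wi <= traj$intercuspation_index) "I" else "II"
    repeat {
      if (sqrt(sum((w[wi, ] - pos)^2)) < 1e-9) break
      if (step_i >= max_steps) break
      st <- advance_step(lower0, pos, w[wi, ], upper, config)
      step_i <- step_i + 1L
      if (st$advanced < 1e-6 && st$status == "contact") st$status <- "stalled"
      cls <- face_class[st$contact$faces]
      ar <- areas[st$contact$faces]
      rows[[step_i]] <- data.frame(
        step = step_i, phase = phase,
        x = st$offset[1], y = st$offset[2], z = st$offset[3],
        area_bpi = sum(ar[!is.na(cls) & cls == "BPI"]),
        area_lpi = sum(ar[!is.na(cls) & cls == "LPI"]),
        area_pii = sum(ar[!is.na(cls) & cls == "PII"]),
        area_unlabeled = sum(ar[is.na(cls) | cls == "TIP_CRUSH"]),
        penetration = st$contact$penetration,
        status = st$status, stringsAsFactors = FALSE)
      pos <- st$offset
      if (st$status %in% c("jammed", "stalled")) break
    }
  }
  tl <- do.call(rbind, rows)
  rownames(tl) <- NULL
  class(tl) <- c("contact_timeline", "data.frame")
  attr(tl, "config") <- config
  attr(tl, "trajectory") <- traj
  tl
}

#' Summaries of a contact timeline
#'
#' @param timeline a `contact_timeline` from [simulate_power_stroke()].
#' @return list with `n_steps`, `phase1_steps`, `phase2_steps`,
#'   `contact_steps` (steps with any contact area), `exclusive_pii_steps`
#'   (steps with phase II contact only), `total_area_trace` (per-step total
#'   labeled contact area) and `table` (the plot-ready stacked-area
#'   data.frame).
#' @export
timeline_summary <- function(timeline) {
  stopifnot(nrow(timeline) >= 1L)
  tot <- timeline$area_bpi + timeline$area_lpi + timeline$area_pii
  any_contact <- tot + timeline$area_unlabeled > 0
  excl_pii <- timeline$area_pii > 0 & timeline$area_bpi == 0 &
    timeline$area_lpi == 0
  list(n_steps = nrow(timeline),
       phase1_steps = sum(timeline$phase == "I"),
       phase2_steps = sum(timeline$phase == "II"),
       contact_steps = sum(any_contact),
       exclusive_pii_steps = sum(excl_pii),
       total_area_trace = tot,
       table = as.data.frame(timeline))
}

#' Write a contact timeline as CSV
#' @param timeline a `contact_timeline`.
#' @param path output CSV path.
#' @export
write_timeline_csv <- function(timeline, path) {
  utils::write.csv(as.data.frame(timeline), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
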