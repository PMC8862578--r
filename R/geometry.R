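# Trajectories, the vertebral measurement frame, corridor HU sampling and
# the axial/sagittal position measurements.
#
# Measurement conventions (axial and sagittal 2D views):
#   d      unsigned distance (mm) from the entry point to the midline plane
#   theta  axial-view angle (deg) between the screw axis and the
#          perpendicular from the entry point toward the midline
#   d'     unsigned distance (mm) from the entry point to the lower
#          endplate guideline
#   theta' sagittal-view angle (deg) between the screw axis and the
#          perpendicular of d', measured from the side of the entry point
#   abduction     = 90 - theta   (positive: screw converges medially)
#   craniocaudal  = theta' - 90  (positive: caudal, negative: cephalic)

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

#' Construct a screw trajectory (cylindrical corridor)
#'
#' @param entry Entry point (world mm, posterior end).
#' @param direction Direction from entry toward the tip; normalized.
#' @param length Screw length (mm), > 0.
#' @param diameter Screw diameter (mm), > 0.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(entry, direction, length = 30, diameter = 6) {
  if (length <= 0 || diameter <= 0)
    stop("length and diameter must be > 0")
  structure(list(entry = as.numeric(entry),
                 direction = .unit(as.numeric(direction)),
                 length = length, diameter = diameter),
            class = "trajectory")
}

#' Tip of a trajectory
#' @param t A `trajectory`.
#' @return World point `entry + length * direction`.
#' @export
trajectory_tip <- function(t) t$entry + t$length * t$direction

#' Anatomical reference frame for trajectory measurements
#'
#' @param midline_point,midline_normal Point and unit normal of the
#'   midline (sagittal symmetry) plane; the normal follows the left-right
#'   axis.
#' @param endplate_point,endplate_normal Point and unit normal of the
#'   lower endplate plane; the normal follows the craniocaudal axis.
#' @param axial_normal Craniocaudal axis (normal of the axial view).
#' @param side `"left"` or `"right"` laterality context.
#' @return An object of class `vertebral_frame`.
#' @export
vertebral_frame <- function(midline_point, midline_normal,
                            endplate_point, endplate_normal,
                            axial_normal = endplate_normal,
                            side = c("left", "right")) {
  side <- match.arg(side)
  structure(list(midline_point = as.numeric(midline_point),
                 midline_normal = .unit(as.numeric(midline_normal)),
                 endplate_point = as.numeric(endplate_point),
                 endplate_normal = .unit(as.numeric(endplate_normal)),
                 axial_normal = .unit(as.numeric(axial_normal)),
                 side = side),
            class = "vertebral_frame")
}

# Deterministic orthonormal basis perpendicular to a unit vector.
.orthobasis <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- .unit(c(ref[2] * u[3] - ref[3] * u[2],
                ref[3] * u[1] - ref[1] * u[3],
                ref[1] * u[2] - ref[2] * u[1]))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Deterministic quadrature lattice over a screw corridor cylinder
#'
#' Axial stations every `step_axial` (midpoint rule), each carrying the
#' centerline point plus concentric equal-area rings out to the corridor
#' radius; all samples have equal weight, so weights sum to 1.
#'
#' @param t A `trajectory`.
#' @param step_axial Axial station spacing (mm), > 0.
#' @param rings Number of radial zones (>= 1); `rings = 1` samples the
#'   centerline only.
#' @return List with `points` (n x 3 world mm) and `weights` (sum 1).
#' @export
cylinder_samples <- function(t, step_axial, rings = 3L) {
  if (step_axial <= 0) stop("step_axial must be > 0")
  rings <- as.integer(rings)
  if (rings < 1L) stop("rings must be >= 1")
  K <- max(1L, as.integer(round(t$length / step_axial)))
  s <- (seq_len(K) - 0.5) * t$length / K
  R <- t$diameter / 2

  # ring j has 6*(j-1) points (1 at the center); zone boundaries follow
  # cumulative point counts so every sample represents equal volume
  counts <- c(1L, if (rings > 1L) 6L * seq_len(rings - 1L))
  M <- sum(counts)
  cum <- cumsum(counts)
  radii <- numeric(0); angles <- numeric(0)
  for (j in seq_len(rings)) {
    if (j == 1L) { radii <- 0; angles <- 0; next }
    frac_mid <- (cum[j - 1L] + cum[j]) / (2 * M)
    rj <- R * sqrt(frac_mid)
    nj <- counts[j]
    ang <- 2 * pi * (seq_len(nj) - 1L) / nj + pi * ((j %% 2L) / nj)
    radii <- c(radii, rep(rj, nj))
    angles <- c(angles, ang)
  }

  basis <- .orthobasis(t$direction)
  disk <- cbind(radii * cos(angles), radii * sin(angles))
  offs <- disk[, 1] %o% basis$e1 + disk[, 2] %o% basis$e2   # M x 3
  axial <- s %o% t$direction                                # K x 3
  pts <- axial[rep(seq_len(K), each = M), , drop = FALSE] +
    offs[rep(seq_len(M), times = K), , drop = FALSE]
  pts <- pts + matrix(t$entry, nrow(pts), 3, byrow = TRUE)
  list(points = pts, weights = rep(1 / (K * M), K * M))
}

#' Mean CT value of a screw corridor
#'
#' Quadrature-weighted mean of trilinearly interpolated HU over the
#' corridor cylinder; with `centerline = TRUE` only the axis is sampled.
#'
#' @param t A `trajectory`.
#' @param v A `ct_volume`.
#' @param step_axial Axial station spacing (mm); default half the minimum
#'   voxel spacing.
#' @param rings Radial zones (default 3).
#' @param centerline If `TRUE`, use the centerline mean instead of the
#'   volume-weighted mean.
#' @return Mean HU of the corridor.
#' @export
mean_ct_value <- function(t, v, step_axial = NULL, rings = 3L,
                          centerline = FALSE) {
  if (is.null(step_axial)) step_axial <- min(v$spacing) / 2
  if (centerline) rings <- 1L
  cs <- cylinder_samples(t, step_axial, rings)
  hu <- tryCatch(sample_hu(v, cs$points),
                 error = function(e) stop("corridor exits the scanned grid"))
  sum(cs$weights * hu)
}

.angle_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(pmax(ca, -1), 1)) * 180 / pi
}

#' Measure the axial/sagittal position of a trajectory
#'
#' @param t A `trajectory`.
#' @param f A `vertebral_frame`.
#' @return An object of class `trajectory_measurement` with fields `d`,
#'   `theta`, `d_prime`, `theta_prime`, `abduction` (= 90 - theta) and
#'   `craniocaudal` (= theta_prime - 90), plus the frame's `side`.
#' @export
measure_trajectory <- function(t, f) {
  nm <- f$midline_normal; ne <- f$endplate_normal; na <- f$axial_normal
  sm <- sum((f$midline_point - t$entry) * nm)
  d <- abs(sm)
  de <- sum((t$entry - f$endplate_point) * ne)
  d_prime <- abs(de)

  # axial view: angle to the perpendicular from entry toward the midline
  w_ax <- sign(sm) * nm
  if (d < 1e-9) w_ax <- nm  # entry on the midline: side degenerate
  proj_ax <- t$direction - sum(t$direction * na) * na
  if (sqrt(sum(proj_ax^2)) < 1e-9)
    stop("degenerate axial projection: screw axis parallel to the craniocaudal axis")
  theta <- .angle_deg(proj_ax, w_ax - sum(w_ax * na) * na)

  # sagittal view: angle to the endplate perpendicular on the entry side
  w_sag <- sign(de) * ne
  if (d_prime < 1e-9) w_sag <- ne
  proj_sag <- t$direction - sum(t$direction * nm) * nm
  if (sqrt(sum(proj_sag^2)) < 1e-9)
    stop("degenerate sagittal projection: screw axis parallel to the midline normal")
  theta_prime <- .angle_deg(proj_sag, w_sag - sum(w_sag * nm) * nm)

  structure(list(d = d, theta = theta, d_prime = d_prime,
                 theta_prime = theta_prime,
                 abduction = 90 - theta,
                 craniocaudal = theta_prime - 90,
                 side = f$side),
            class = "trajectory_measurement")
}

#' Reconstruct a trajectory from its angular measurements
#'
#' Inverts [measure_trajectory()] for a given entry point: the direction
#' is rebuilt from `theta` (axial) and `theta_prime` (sagittal), pointing
#' anteriorly; `d` and `d_prime` follow from the entry point.
#'
#' @param m A `trajectory_measurement` (or list with `theta`,
#'   `theta_prime`).
#' @param entry Entry point (world mm), off the midline plane.
#' @param f A `vertebral_frame`.
#' @param length,diameter Screw dimensions (mm).
#' @return A `trajectory` whose measurement reproduces `m` (angles, and
#'   the distances implied by `entry`) within 1e-6.
#' @export
reconstruct_trajectory <- function(m, entry, f, length = 30, diameter = 6) {
  abd <- 90 - m$theta
  cc <- m$theta_prime - 90
  if (abs(abd) >= 90 || abs(cc) >= 90)
    stop("inconsistent angles: |90 - theta| and |theta' - 90| must be < 90")
  xhat <- f$midline_normal
  zhat <- f$endplate_normal
  yhat <- .unit(c(zhat[2] * xhat[3] - zhat[3] * xhat[2],
                  zhat[3] * xhat[1] - zhat[1] * xhat[3],
                  zhat[1] * xhat[2] - zhat[2] * xhat[1]))
  sm <- sum((f$midline_point - entry) * xhat)
  s_m <- if (abs(sm) < 1e-12) 1 else sign(sm)
  dir <- s_m * tan(abd * pi / 180) * xhat + yhat -
    tan(cc * pi / 180) * zhat
  trajectory(entry, .unit(dir), length, diameter)
}

#' Screw placement error between planned and actual trajectories
#'
#' @param planned,actual `trajectory_measurement`s taken in the same
#'   frame.
#' @return An object of class `placement_error` with
#'   `displacement_error` (mm, actual d minus planned d) and
#'   `angle_error` (degrees, actual theta minus planned theta).
#' @export
placement_error <- function(planned, actual) {
  structure(list(displacement_error = actual$d - planned$d,
                 angle_error = actual$theta - planned$theta),
            class = "placement_error")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %.1f x %.1f mm screw\n", x$diameter, x$length))
  cat(sprintf("  entry (%.2f, %.2f, %.2f) mm -> tip (%.2f, %.2f, %.2f) mm\n",
              x$entry[1], x$entry[2], x$entry[3],
              trajectory_tip(x)[1], trajectory_tip(x)[2],
              trajectory_tip(x)[3]))
  invisible(x)
}

#' @export
print.trajectory_measurement <- function(x, ...) {
  cat(sprintf("axial:    d = %.2f mm, theta = %.2f deg (abduction %.2f deg)\n",
              x$d, x$theta, x$abduction))
  cat(sprintf("sagittal: d' = %.2f mm, theta' = %.2f deg (craniocaudal %.2f deg)\n",
              x$d_prime, x$theta_prime, x$craniocaudal))
  invisible(x)
}

#' Write a trajectory to JSON
#'
#' @param t A `trajectory`.
#' @param path Output path.
#' @param side Optional laterality tag.
#' @param meta Optional named list stored under `meta`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(t, path, side = NULL, meta = NULL) {
  obj <- list(entry_mm = t$entry, direction = t$direction,
              length_mm = t$length, diameter_mm = t$diameter)
  if (!is.null(side)) obj$side <- side
  if (!is.null(meta)) obj$meta <- meta
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trajectory from JSON
#'
#' @param path Path written by [write_trajectory()].
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trajectory(obj$entry_mm, obj$direction, obj$length_mm, obj$diameter_mm)
}

#' Export guide-plate design coordinates
#'
#' Writes the entry and stop (tip) world coordinates of a trajectory, the
#' inputs a patient-specific drill guide is designed from.
#'
#' @param t A `trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_guide <- function(t, path) {
  tip <- trajectory_tip(t)
  df <- data.frame(point = c("entry", "tip"),
                   x_mm = c(t$entry[1], tip[1]),
                   y_mm = c(t$entry[2], tip[2]),
                   z_mm = c(t$entry[3], tip[3]))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
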