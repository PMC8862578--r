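# Trajectory feasibility: containment in bone, passage through the
# narrowest-pedicle-section ROI, and anterior cortex clearance.
#
# Containment is decided from the bone-mask distance map along the
# centerline. The entry point of a real trajectory sits ON the posterior
# bone surface, where the distance to the bone exterior is ~0; the
# corridor is therefore required to be fully inside bone from the first
# centerline station at which that holds ("entry transition") through the
# tip. For trajectories that start fully interior this reduces to the
# plain min-over-centerline rule.

.roi_label_for <- function(side) {
  switch(side, left = 6L, right = 7L,
         stop("side must be 'left' or 'right'"))
}

.centerline_points <- function(t, step) {
  s <- seq(0, t$length, by = step)
  if (s[length(s)] < t$length) s <- c(s, t$length)
  outer(s, t$direction) + matrix(t$entry, length(s), 3, byrow = TRUE)
}

#' Check corridor containment in bone
#'
#' Samples the centerline at half-voxel steps against the Euclidean
#' distance map of the bone mask. Contained iff, from the first station
#' where the corridor is fully inside bone through the tip, the distance
#' to the bone exterior never drops below `diameter/2 + safety_margin`
#' (boundary equality counts as contained).
#'
#' @param t A `trajectory`.
#' @param l A `label_volume`.
#' @param safety_margin Extra clearance (mm), default 0.
#' @param dmap Optional precomputed [distance_map()] of [bone_labels()].
#' @return List with `contained` (logical) and `margin` (mm, min distance
#'   over the checked stations minus `diameter/2 + safety_margin`).
#' @export
check_containment <- function(t, l, safety_margin = 0, dmap = NULL) {
  if (is.null(dmap)) dmap <- distance_map(l, bone_labels())
  step <- min(l$spacing) / 2
  pts <- .centerline_points(t, step)
  dist <- tryCatch(sample_distance(dmap, pts),
                   error = function(e) stop("centerline exits the scanned grid"))
  r_eff <- t$diameter / 2 + safety_margin
  i0 <- which(dist >= r_eff)[1]
  if (is.na(i0)) {
    list(contained = FALSE, margin = max(dist) - r_eff)
  } else {
    margin <- min(dist[i0:length(dist)]) - r_eff
    list(contained = margin >= 0, margin = margin)
  }
}

#' Check passage through the narrowest-pedicle-section ROI
#'
#' True iff the corridor cylinder, sampled at the default cylinder
#' lattice resolution, intersects at least one voxel carrying the side's
#' ROI label.
#'
#' @param t A `trajectory`.
#' @param l A `label_volume`.
#' @param side `"left"` or `"right"`.
#' @return Logical.
#' @export
check_pedicle_passage <- function(t, l, side) {
  roi <- .roi_label_for(side)
  if (!any(l$data == roi))
    stop("missing narrowest-section ROI label for side ", side)
  cs <- cylinder_samples(t, min(l$spacing) / 2, 3L)
  labs <- sample_label(l, cs$points)
  any(labs == roi, na.rm = TRUE)
}

#' Check anterior vertebral margin clearance
#'
#' Safe iff the screw tip lies inside the vertebral body (cortical shell
#' or cancellous label) and its distance to the bone exterior is at least
#' the corridor radius.
#'
#' @inheritParams check_containment
#' @return List with `safe` (logical) and `clearance` (mm, tip distance
#'   to bone exterior minus `diameter/2`).
#' @export
check_anterior_margin <- function(t, l, dmap = NULL) {
  if (is.null(dmap)) dmap <- distance_map(l, bone_labels())
  tip <- trajectory_tip(t)
  lab <- sample_label(l, tip)
  tipdist <- tryCatch(sample_distance(dmap, tip),
                      error = function(e) stop("tip outside the scanned grid"))
  inside_body <- !is.na(lab) && lab %in% c(1L, 2L)
  clearance <- tipdist - t$diameter / 2
  list(safe = inside_body && clearance >= 0, clearance = clearance)
}

#' Full feasibility report for a trajectory
#'
#' Aggregates containment, narrowest-section passage and anterior margin
#' checks; an infeasible trajectory yields a report, not an error.
#'
#' @inheritParams check_containment
#' @param side `"left"` or `"right"`.
#' @return An object of class `feasibility_report` with fields
#'   `contained`, `containment_margin`, `passes_pedicle_roi`,
#'   `anterior_safe`, `anterior_clearance`, `feasible`.
#' @export
feasibility <- function(t, l, side, safety_margin = 0, dmap = NULL) {
  if (is.null(dmap)) dmap <- distance_map(l, bone_labels())
  cont <- check_containment(t, l, safety_margin, dmap)
  roi <- check_pedicle_passage(t, l, side)
  ant <- check_anterior_margin(t, l, dmap)
  structure(list(contained = cont$contained,
                 containment_margin = cont$margin,
                 passes_pedicle_roi = roi,
                 anterior_safe = ant$safe,
                 anterior_clearance = ant$clearance,
                 feasible = cont$contained && roi && ant$safe),
            class = "feasibility_report")
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat(sprintf("feasible: %s\n", x$feasible))
  cat(sprintf("  contained: %s (margin %.2f mm)\n", x$contained,
              x$containment_margin))
  cat(sprintf("  passes narrowest pedicle section: %s\n",
              x$passes_pedicle_roi))
  cat(sprintf("  anterior margin safe: %s (clearance %.2f mm)\n",
              x$anterior_safe, x$anterior_clearance))
  invisible(x)
}
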