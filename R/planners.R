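# Trajectory planners: the conventional manual baseline anchored at the
# midpoint of the narrowest pedicle section, and the automatic planner
# that searches for the feasible corridor maximizing mean HU.
#
# The automatic search is fully deterministic: a grid over entry offsets
# on the posterior bone surface (within the pedicle's posterior shadow)
# crossed with a cone of directions about the pedicle axis, optionally
# followed by a derivative-free pattern search with step halving. Exact
# ties are broken lexicographically by enumeration order (entry index,
# then direction index), so flat objectives still give reproducible
# plans.

`%||%` <- function(a, b) if (is.null(a)) b else a

.side_labels <- function(side) {
  switch(side, left = c(3L, 6L), right = c(4L, 7L),
         stop("side must be 'left' or 'right'"))
}

# 6-connectivity flood fill on a cropped logical array.
.is_connected <- function(mask) {
  d <- dim(mask)
  cur <- array(FALSE, d)
  cur[which(mask)[1]] <- TRUE
  repeat {
    grown <- cur
    grown[-1, , ] <- grown[-1, , ] | cur[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | cur[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | cur[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | cur[, -1, ]
    grown[, , -1] <- grown[, , -1] | cur[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | cur[, , -1]
    grown <- grown & mask
    if (identical(grown, cur)) break
    cur <- grown
  }
  !any(mask & !cur)
}

# World coordinates (n x 3) of voxels carrying the given labels.
.label_coords <- function(l, labels) {
  idx <- which(array(l$data %in% labels, dim(l$data)))
  if (length(idx) == 0L) return(NULL)
  ijk <- arrayInd(idx, dim(l$data)) - 1L
  voxel_to_world(l, ijk)
}

#' Locate the narrowest cross-section of a pedicle
#'
#' The pedicle axis is taken as the principal direction of the pedicle
#' voxel coordinates (oriented toward the vertebral body); cutting slabs
#' one voxel thick are swept along it at half-voxel steps, and the
#' station of minimal cross-sectional area is returned. Exact area ties
#' are broken to the station closest to the pedicle mid-length.
#'
#' @param l A `label_volume`.
#' @param side `"left"` or `"right"`.
#' @return List with `plane` (point + normal), `centroid` (world mm),
#'   `area` (mm^2), `width` (minimal caliper width, mm) and `axis` (unit
#'   vector along the pedicle, pointing anteriorly).
#' @export
find_min_pedicle_section <- function(l, side = c("left", "right")) {
  side <- match.arg(side)
  labs <- .side_labels(side)
  coords <- .label_coords(l, labs)
  if (is.null(coords)) stop("pedicle label is empty for side ", side)

  mask <- array(l$data %in% labs, dim(l$data))
  rng <- apply(arrayInd(which(mask), dim(mask)), 2, range)
  sub <- mask[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
              rng[1, 3]:rng[2, 3], drop = FALSE]
  if (!.is_connected(sub)) stop("disconnected pedicle label for side ", side)

  ctr <- colMeans(coords)
  u <- eigen(stats::cov(coords), symmetric = TRUE)$vectors[, 1]
  body <- .label_coords(l, 2L)
  ref <- if (is.null(body)) c(0, 1, 0) else colMeans(body) - ctr
  if (sum(u * ref) < 0) u <- -u

  s <- drop((coords - matrix(ctr, nrow(coords), 3, byrow = TRUE)) %*% u)
  smin <- min(s); smax <- max(s)
  delta <- max(l$spacing)
  stations <- seq(smin + delta, smax - delta, by = min(l$spacing) / 2)
  if (length(stations) == 0L) stations <- (smin + smax) / 2
  voxvol <- prod(l$spacing)
  counts <- vapply(stations, function(st) sum(abs(s - st) <= delta / 2), 0L)
  areas <- counts * voxvol / delta
  smid <- (smin + smax) / 2
  cand <- which(areas == min(areas))
  best <- cand[order(abs(stations[cand] - smid), stations[cand])][1]
  st <- stations[best]
  sel <- abs(s - st) <= delta / 2
  centroid <- colMeans(coords[sel, , drop = FALSE])

  basis <- .orthobasis(u)
  rel <- coords[sel, , drop = FALSE] -
    matrix(centroid, sum(sel), 3, byrow = TRUE)
  p1 <- drop(rel %*% basis$e1); p2 <- drop(rel %*% basis$e2)
  angles <- seq(0, pi, length.out = 37)[-37]
  extents <- vapply(angles, function(a) {
    pr <- p1 * cos(a) + p2 * sin(a)
    max(pr) - min(pr)
  }, 0)
  width <- min(extents) + min(l$spacing)  # voxel centers + one voxel extent

  list(plane = list(point = centroid, normal = u),
       centroid = centroid, area = areas[best], width = width, axis = u)
}

# March from an interior point against `u` to the posterior bone surface.
.surface_entry <- function(l, start, u, max_depth = 80) {
  step <- min(l$spacing) / 4
  s <- seq(0, max_depth, by = step)
  pts <- outer(s, -u) + matrix(start, length(s), 3, byrow = TRUE)
  labs <- sample_label(l, pts)
  bone <- !is.na(labs) & labs %in% bone_labels()
  if (!bone[1]) return(NULL)
  j <- which(!bone)[1]
  if (is.na(j)) return(NULL)
  lo <- s[j - 1]; hi <- s[j]
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    p <- start - mid * u
    lb <- sample_label(l, p)
    if (!is.na(lb) && lb %in% bone_labels()) lo <- mid else hi <- mid
  }
  start - ((lo + hi) / 2) * u
}

.plan_result <- function(traj, mean_hu, feas, evaluations, settings,
                         method) {
  structure(list(trajectory = traj, mean_hu = mean_hu,
                 feasibility = feas, evaluations = evaluations,
                 search_settings = settings, method = method),
            class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  cat(sprintf("%s plan: mean corridor CT value %.1f HU (%d candidate evaluations)\n",
              x$method, x$mean_hu, x$evaluations))
  print(x$trajectory)
  print(x$feasibility)
  invisible(x)
}

#' Conventional manual trajectory plan
#'
#' The trajectory runs along the pedicle principal axis projected to be
#' parallel to the lower endplate plane, anchored at the midpoint of the
#' narrowest pedicle section, with the entry point on the posterior bone
#' surface.
#'
#' @param v A `ct_volume`.
#' @param l The aligned `label_volume`.
#' @param f A `vertebral_frame`.
#' @param side `"left"` or `"right"`.
#' @param length,diameter Screw dimensions (mm); 6 x 30 mm default.
#' @param safety_margin Containment margin (mm).
#' @param dmap Optional precomputed bone [distance_map()].
#' @return An object of class `plan_result`.
#' @export
plan_manual <- function(v, l, f, side, length = 30, diameter = 6,
                        safety_margin = 0, dmap = NULL) {
  ms <- find_min_pedicle_section(l, side)
  ne <- f$endplate_normal
  up <- ms$axis - sum(ms$axis * ne) * ne
  if (sqrt(sum(up^2)) < 1e-6)
    stop("degenerate projection: pedicle axis perpendicular to the endplate")
  up <- .unit(up)
  entry <- .surface_entry(l, ms$centroid, up)
  if (is.null(entry)) stop("could not locate the posterior bone surface")
  traj <- trajectory(entry, up, length, diameter)
  dmap <- dmap %||% distance_map(l, bone_labels())
  feas <- feasibility(traj, l, side, safety_margin, dmap)
  .plan_result(traj, mean_ct_value(traj, v), feas, 1L, NULL, "manual")
}

#' Search settings for the automatic planner
#'
#' @param entry_grid_step Entry-offset grid step (mm) on the posterior
#'   surface.
#' @param cone_half_angle Half-angle (degrees, in (0, 45]) of the search
#'   cone about the pedicle axis.
#' @param angular_step Direction grid step (degrees).
#' @param refine Run the pattern-search refinement stage.
#' @param refine_min_step Smallest refinement step (mm for entry offsets,
#'   degrees for direction angles).
#' @return An object of class `search_settings`.
#' @export
search_settings <- function(entry_grid_step = 1, cone_half_angle = 20,
                            angular_step = 2, refine = TRUE,
                            refine_min_step = 0.25) {
  if (entry_grid_step <= 0 || angular_step <= 0 || refine_min_step <= 0)
    stop("steps must be > 0")
  if (cone_half_angle <= 0 || cone_half_angle > 45)
    stop("cone_half_angle must lie in (0, 45]")
  structure(list(entry_grid_step = entry_grid_step,
                 cone_half_angle = cone_half_angle,
                 angular_step = angular_step,
                 refine = refine, refine_min_step = refine_min_step),
            class = "search_settings")
}

# Deterministic candidate set shared by plan_auto and brute_force_plan.
.candidate_set <- function(l, side, settings, ms) {
  u <- ms$axis
  basis <- .orthobasis(u)
  A <- ms$width / 2
  m <- floor(A / settings$entry_grid_step)
  offs <- (-m:m) * settings$entry_grid_step
  entries <- list()
  for (a in offs) for (b in offs) {
    if (a^2 + b^2 > A^2 + 1e-12) next
    start <- ms$centroid + a * basis$e1 + b * basis$e2
    lb <- sample_label(l, start)
    if (is.na(lb) || !(lb %in% bone_labels())) next
    entry <- .surface_entry(l, start, u)
    if (is.null(entry)) next
    entries[[length(entries) + 1L]] <- list(point = entry, a = a, b = b)
  }
  h <- settings$cone_half_angle
  m2 <- floor(h / settings$angular_step)
  angs <- (-m2:m2) * settings$angular_step
  dirs <- list()
  for (al in angs) for (be in angs) {
    if (al^2 + be^2 > h^2 + 1e-12) next
    dir <- .unit(u + tan(al * pi / 180) * basis$e1 +
                   tan(be * pi / 180) * basis$e2)
    dirs[[length(dirs) + 1L]] <- list(dir = dir, alpha = al, beta = be)
  }
  list(entries = entries, dirs = dirs, basis = basis, axis = u,
       centroid = ms$centroid)
}

.try_feasibility <- function(t, l, side, safety_margin, dmap) {
  tryCatch(feasibility(t, l, side, safety_margin, dmap),
           error = function(e) NULL)
}

#' Automatic trajectory plan maximizing the mean corridor CT value
#'
#' Stage 1 enumerates entry points on the posterior bone surface within
#' the pedicle's posterior shadow crossed with a cone of directions about
#' the pedicle axis, keeping the best-scoring feasible corridor. Stage 2
#' (if `settings$refine`) runs a deterministic pattern search over the
#' two entry-offset and two direction degrees of freedom, halving steps
#' down to `refine_min_step` and rejecting infeasible moves.
#'
#' @inheritParams plan_manual
#' @param settings A [search_settings()].
#' @return An object of class `plan_result`; errors if no candidate is
#'   feasible at the grid resolution.
#' @export
plan_auto <- function(v, l, f, side, length = 30, diameter = 6,
                      settings = search_settings(), safety_margin = 0,
                      dmap = NULL) {
  ms <- find_min_pedicle_section(l, side)
  dmap <- dmap %||% distance_map(l, bone_labels())
  cs <- .candidate_set(l, side, settings, ms)
  nev <- 0L
  best <- NULL
  for (e in cs$entries) {
    for (dd in cs$dirs) {
      nev <- nev + 1L
      t <- trajectory(e$point, dd$dir, length, diameter)
      rep <- .try_feasibility(t, l, side, safety_margin, dmap)
      if (is.null(rep) || !rep$feasible) next
      hu <- tryCatch(mean_ct_value(t, v), error = function(e) NA_real_)
      if (is.na(hu)) next
      if (is.null(best) || hu > best$hu)
        best <- list(traj = t, hu = hu, feas = rep,
                     a = e$a, b = e$b, alpha = dd$alpha, beta = dd$beta)
    }
  }
  if (is.null(best))
    stop("no feasible candidate trajectory; try a finer search grid or a smaller screw")

  if (isTRUE(settings$refine)) {
    sa <- settings$entry_grid_step
    sg <- settings$angular_step
    entry_cache <- new.env(parent = emptyenv())
    entry_for <- function(a, b) {
      key <- paste(a, b)
      if (!is.null(entry_cache[[key]])) return(entry_cache[[key]])
      start <- cs$centroid + a * cs$basis$e1 + b * cs$basis$e2
      lb <- sample_label(l, start)
      res <- if (is.na(lb) || !(lb %in% bone_labels())) list(NULL)
             else list(.surface_entry(l, start, cs$axis))
      entry_cache[[key]] <- res
      res
    }
    evaluate <- function(a, b, al, be) {
      ent <- entry_for(a, b)[[1]]
      if (is.null(ent)) return(NULL)
      dir <- .unit(cs$axis + tan(al * pi / 180) * cs$basis$e1 +
                     tan(be * pi / 180) * cs$basis$e2)
      t <- trajectory(ent, dir, length, diameter)
      rep <- .try_feasibility(t, l, side, safety_margin, dmap)
      if (is.null(rep) || !rep$feasible) return(NULL)
      hu <- tryCatch(mean_ct_value(t, v), error = function(e) NA_real_)
      if (is.na(hu)) return(NULL)
      list(traj = t, hu = hu, feas = rep, a = a, b = b,
           alpha = al, beta = be)
    }
    while ((sa >= settings$refine_min_step ||
            sg >= settings$refine_min_step) && nev < 5000L) {
      moves <- list(c(sa, 0, 0, 0), c(-sa, 0, 0, 0),
                    c(0, sa, 0, 0), c(0, -sa, 0, 0),
                    c(0, 0, sg, 0), c(0, 0, -sg, 0),
                    c(0, 0, 0, sg), c(0, 0, 0, -sg))
      improved <- NULL
      for (mv in moves) {
        nev <- nev + 1L
        cand <- evaluate(best$a + mv[1], best$b + mv[2],
                         best$alpha + mv[3], best$beta + mv[4])
        if (!is.null(cand) && cand$hu > best$hu &&
            (is.null(improved) || cand$hu > improved$hu))
          improved <- cand
      }
      if (!is.null(improved)) best <- improved
      else { sa <- sa / 2; sg <- sg / 2 }
    }
  }

  .plan_result(best$traj, best$hu, best$feas, nev, settings, "auto")
}

#' Exhaustive enumeration oracle for the automatic planner
#'
#' Enumerates the identical candidate set as [plan_auto()] (same entry
#' and direction grids, same lexicographic tie rule) with a plain nested
#' loop, checking and scoring every candidate. Intended as a test oracle
#' on coarse grids.
#'
#' @inheritParams plan_auto
#' @return An object of class `plan_result`.
#' @export
brute_force_plan <- function(v, l, f, side, length = 30, diameter = 6,
                             settings = search_settings(refine = FALSE),
                             safety_margin = 0, dmap = NULL) {
  ms <- find_min_pedicle_section(l, side)
  dmap <- dmap %||% distance_map(l, bone_labels())
  cs <- .candidate_set(l, side, settings, ms)
  nev <- 0L
  best <- NULL
  for (e in cs$entries) {
    for (dd in cs$dirs) {
      nev <- nev + 1L
      t <- trajectory(e$point, dd$dir, length, diameter)
      rep <- .try_feasibility(t, l, side, safety_margin, dmap)
      hu <- tryCatch(mean_ct_value(t, v), error = function(e) NA_real_)
      if (is.null(rep) || !rep$feasible || is.na(hu)) next
      if (is.null(best) || hu > best$hu)
        best <- list(traj = t, hu = hu, feas = rep)
    }
  }
  if (is.null(best))
    stop("no feasible candidate trajectory; try a finer search grid or a smaller screw")
  .plan_result(best$traj, best$hu, best$feas, nev, settings,
               "brute-force")
}

#' Standard screw size for measured pedicle dimensions
#'
#' Sizing rule: the largest standard diameter not exceeding 80% of the
#' narrowest-section caliper width, and the largest standard length not
#' exceeding 80% of the bony chord available along the pedicle axis.
#'
#' @param width Narrowest-section caliper width (mm).
#' @param chord Chord (mm) from the posterior surface through the
#'   narrowest-section midpoint to the anterior inner cortex.
#' @param diameters,lengths Standard size sets (mm).
#' @return List with `diameter` and `length` (mm).
#' @export
screw_size <- function(width, chord,
                       diameters = c(4.5, 5, 5.5, 6, 6.5, 7),
                       lengths = c(25, 30, 35, 40, 45)) {
  dok <- diameters[diameters <= 0.8 * width]
  if (length(dok) == 0L) stop("no admissible diameter for width ", width, " mm")
  lok <- lengths[lengths <= 0.8 * chord]
  if (length(lok) == 0L) stop("no admissible length for chord ", chord, " mm")
  list(diameter = max(dok), length = max(lok))
}

#' Recommend a screw size for a pedicle
#'
#' Measures the narrowest-section caliper width and the bony chord along
#' the pedicle axis (posterior surface to anterior inner cortex) and
#' applies [screw_size()].
#'
#' @param l A `label_volume`.
#' @param side `"left"` or `"right"`.
#' @return List with `diameter`, `length`, `width`, `chord` (mm).
#' @export
recommend_screw <- function(l, side) {
  ms <- find_min_pedicle_section(l, side)
  u <- ms$axis
  step <- min(l$spacing) / 4
  s <- seq(0, 100, by = step)
  fwd <- outer(s, u) + matrix(ms$centroid, length(s), 3, byrow = TRUE)
  labs <- sample_label(l, fwd)
  bone <- !is.na(labs) & labs %in% bone_labels()
  j <- which(!bone)[1]
  if (is.na(j) || j < 2L) stop("could not trace the anterior cortex")
  k <- j - 1L
  while (k > 1L && labs[k] == 1L) k <- k - 1L  # strip the anterior cortex
  s_ant <- s[k]
  entry <- .surface_entry(l, ms$centroid, u)
  if (is.null(entry)) stop("could not locate the posterior bone surface")
  s_post <- sqrt(sum((entry - ms$centroid)^2))
  chord <- s_ant + s_post
  sz <- screw_size(ms$width, chord)
  c(sz, list(width = ms$width, chord = chord))
}
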