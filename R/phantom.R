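# Parametric synthetic vertebra phantom.
#
# An idealized geometric vertebra voxelized on a regular grid: an
# elliptic-cylinder body with a cortical shell, two oblique cylindrical
# pedicles with cortical sleeves and an hourglass waist, a posterior bone
# block (lamina/spinous mass) that the pedicles merge into, a spinal canal
# between them, and one-voxel-thick narrowest-section ROI disks at the
# pedicle waists. Decalcification is modeled as uniform multiplicative HU
# attenuation of bone toward water (0 HU), mirroring the linear CT-BMD
# relation the osteoporosis score relies on.

#' Specification of a synthetic vertebra phantom
#'
#' Defaults describe a lumbar-sized vertebra into which a 6 mm x 30 mm
#' screw fits comfortably through either pedicle.
#'
#' @param body_half_axes Half-axes (mm) of the elliptical body
#'   cross-section, `c(x, y)`.
#' @param body_height Body height (mm, craniocaudal).
#' @param cortical_thickness Cortical shell / pedicle sleeve thickness (mm).
#' @param pedicle_radius Pedicle waist radius (mm); the pedicle flares to
#'   1.2x this radius at its ends.
#' @param pedicle_length Nominal pedicle span (mm) from the posterior body
#'   surface; the waist sits at half this span.
#' @param pedicle_convergence_angle Axial angle (degrees) of the pedicle
#'   axis toward the midline.
#' @param canal_radius Spinal canal radius (mm).
#' @param hu_cortical,hu_cancellous_mean,hu_cancellous_sd,hu_soft_tissue
#'   HU of the cortical compartment, mean and per-voxel Gaussian sd of the
#'   cancellous compartment, and HU of soft tissue / canal.
#' @param corridor Optional planted dense corridor: list with `point`
#'   (world mm, on the axis), `direction`, `radius` (mm) and `hu_boost`
#'   (HU added to bone voxels inside the cylinder).
#' @param decalcification_factor In `[0, 1]`; 1 = untreated. Applied to
#'   bone HU at generation time.
#' @param spacing Isotropic voxel size (mm).
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_half_axes = c(18, 14),
                         body_height = 30,
                         cortical_thickness = 1.5,
                         pedicle_radius = 4.5,
                         pedicle_length = 15,
                         pedicle_convergence_angle = 12,
                         canal_radius = 5.5,
                         hu_cortical = 3200,
                         hu_cancellous_mean = 2650,
                         hu_cancellous_sd = 50,
                         hu_soft_tissue = 50,
                         corridor = NULL,
                         decalcification_factor = 1,
                         spacing = 0.5,
                         seed = 1L) {
  spec <- list(body_half_axes = as.numeric(body_half_axes),
               body_height = body_height,
               cortical_thickness = cortical_thickness,
               pedicle_radius = pedicle_radius,
               pedicle_length = pedicle_length,
               pedicle_convergence_angle = pedicle_convergence_angle,
               canal_radius = canal_radius,
               hu_cortical = hu_cortical,
               hu_cancellous_mean = hu_cancellous_mean,
               hu_cancellous_sd = hu_cancellous_sd,
               hu_soft_tissue = hu_soft_tissue,
               corridor = corridor,
               decalcification_factor = decalcification_factor,
               spacing = spacing,
               seed = as.integer(seed))
  lengths <- c(spec$body_half_axes, spec$body_height,
               spec$cortical_thickness, spec$pedicle_radius,
               spec$pedicle_length, spec$canal_radius, spec$spacing)
  if (any(lengths <= 0)) stop("all lengths must be > 0")
  if (spec$cortical_thickness >= min(spec$body_half_axes))
    stop("cortical_thickness must be smaller than the body half-axes")
  if (spec$pedicle_radius >= min(spec$body_half_axes))
    stop("degenerate anatomy: pedicle_radius >= body_half_axes")
  if (spec$decalcification_factor < 0 || spec$decalcification_factor > 1)
    stop("decalcification_factor must lie in [0, 1]")
  if (!is.null(corridor)) {
    stopifnot(is.list(corridor),
              all(c("point", "direction", "radius", "hu_boost") %in%
                    names(corridor)))
    if (corridor$radius <= 0) stop("corridor radius must be > 0")
  }
  structure(spec, class = "phantom_spec")
}

# Derived layout of the phantom in world mm (midline plane x = 0, body
# centered at the origin).
.phantom_layout <- function(spec) {
  a <- spec$body_half_axes[1]; b <- spec$body_half_axes[2]
  phi <- spec$pedicle_convergence_angle * pi / 180
  canal_center_y <- -(b + spec$canal_radius + 1.5)
  block_y1 <- canal_center_y - spec$canal_radius - 0.5  # anterior face
  block_y0 <- block_y1 - 9                              # posterior face
  anchor_x <- 0.55 * a
  anchor_y <- -b * sqrt(1 - (anchor_x / a)^2)
  u_left <- c(sin(phi), cos(phi), 0)    # anterior-medial, left pedicle
  u_right <- c(-sin(phi), cos(phi), 0)
  list(a = a, b = b, phi = phi,
       canal_center_y = canal_center_y,
       block_y0 = block_y0, block_y1 = block_y1,
       block_half_width = a + 2,
       block_half_height = max(spec$body_height / 2 - 2, spec$pedicle_radius * 1.3),
       anchor_left = c(-anchor_x, anchor_y, 0),
       anchor_right = c(anchor_x, anchor_y, 0),
       u_left = u_left, u_right = u_right,
       waist_s = -spec$pedicle_length / 2)
}

# Pedicle radius profile along the axial coordinate s (s = 0 at the body
# anchor, negative posteriorly; waist at -pedicle_length/2).
.pedicle_radius_at <- function(spec, s) {
  rel <- (s - (-spec$pedicle_length / 2)) / (spec$pedicle_length / 2)
  rel <- pmin(pmax(rel, -1), 1)
  spec$pedicle_radius * (1 + 0.2 * rel^2)
}

#' Generate a synthetic vertebra phantom
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `ct` (a `ct_volume`), `labels`
#'   (a `label_volume`) and `truth` (ground-truth geometry: midline and
#'   lower-endplate planes, per-side pedicle axes and minimum-section
#'   centroids, and the planted corridor axis when present).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lay <- .phantom_layout(spec)
  sp <- spec$spacing
  t <- spec$cortical_thickness
  h2 <- spec$body_height / 2

  # grid: x centers symmetric about the midline so mirroring is exact
  x_ext <- max(lay$a, lay$block_half_width) + 4 * sp
  nx <- 2L * ceiling(x_ext / sp) + 1L
  xs <- (seq_len(nx) - (nx + 1) / 2) * sp
  y_lo <- lay$block_y0 - 4 * sp; y_hi <- lay$b + 4 * sp
  ny <- ceiling((y_hi - y_lo) / sp) + 1L
  ys <- y_lo + (seq_len(ny) - 1L) * sp
  z_ext <- h2 + 4 * sp
  nz <- 2L * ceiling(z_ext / sp) + 1L
  zs <- (seq_len(nz) - (nz + 1) / 2) * sp

  lab <- array(0L, c(nx, ny, nz))
  hu <- array(spec$hu_soft_tissue, c(nx, ny, nz))

  # mirror-symmetric cancellous noise (left half generated, right mirrored)
  set.seed(spec$seed)
  noise <- array(0, c(nx, ny, nz))
  half <- ceiling(nx / 2)
  noise[seq_len(half), , ] <- rnorm(half * ny * nz, 0, spec$hu_cancellous_sd)
  if (nx > half)
    noise[(half + 1L):nx, , ] <- noise[rev(seq_len(nx - half)), , ]

  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  E_out <- (X / lay$a)^2 + (Y / lay$b)^2
  E_in <- (X / (lay$a - t))^2 + (Y / (lay$b - t))^2
  canal2 <- X^2 + (Y - lay$canal_center_y)^2
  in_block_xy <- abs(X) <= lay$block_half_width &
    Y >= lay$block_y0 & Y <= lay$block_y1

  ped <- function(side) {
    anchor <- if (side == "left") lay$anchor_left else lay$anchor_right
    u <- if (side == "left") lay$u_left else lay$u_right
    dx <- X - anchor[1]; dy <- Y - anchor[2]
    S <- dx * u[1] + dy * u[2]
    inplane2 <- dx^2 + dy^2 - S^2
    # axial extent: from 2 mm inside the block to a merge collar carried
    # into the body, so the pedicle-body junction has no thin neck
    s_blk <- (lay$block_y1 - 2 - anchor[2]) / u[2]
    s_fwd <- 0.4 * spec$pedicle_length
    list(S = S, inplane2 = inplane2, r = .pedicle_radius_at(spec, S),
         s_blk = s_blk, s_fwd = s_fwd, anchor = anchor, u = u)
  }
  pl <- ped("left"); pr <- ped("right")

  corr <- spec$corridor
  if (!is.null(corr)) {
    w <- corr$direction / sqrt(sum(corr$direction^2))
    cp <- corr$point
  }

  for (k in seq_len(nz)) {
    z <- zs[k]
    sl <- lab[, , k]
    sh <- hu[, , k]

    # posterior block (fully cortical bone)
    if (abs(z) <= lay$block_half_height) {
      m <- in_block_xy
      sl[m] <- 1L
      sh[m] <- spec$hu_cortical
    }

    # pedicles: cortical sleeve around a uniform cancellous-like core
    for (side in c("left", "right")) {
      pp <- if (side == "left") pl else pr
      core_lab <- if (side == "left") 3L else 4L
      roi_lab <- if (side == "left") 6L else 7L
      rad2 <- pp$inplane2 + z^2
      collar <- pp$S > 0 & pp$S <= pp$s_fwd & rad2 <= pp$r^2
      if (any(collar)) {
        # junction collar carried into the body: cortical bone, so the
        # pedicle-body junction has no thin neck (mostly overridden by
        # the body paint inside the ellipse)
        sl[collar] <- 1L
        sh[collar] <- spec$hu_cortical
      }
      inside <- pp$S >= pp$s_blk & pp$S <= 0 & rad2 <= pp$r^2
      if (any(inside)) {
        # full cross-section carries the pedicle label; the cortical
        # sleeve is expressed in HU only
        core <- inside & rad2 <= pmax(pp$r - t, 0)^2
        sl[inside] <- core_lab
        sh[inside] <- spec$hu_cortical
        sh[core] <- spec$hu_cancellous_mean
        roi <- inside & abs(pp$S - lay$waist_s) <= sp / 2
        sl[roi] <- roi_lab
      }
    }

    # vertebral body (overrides pedicle at the junction)
    if (abs(z) <= h2) {
      body <- E_out <= 1
      shell <- body & (E_in > 1 | abs(z) > h2 - t)
      canc <- body & !shell
      sl[shell] <- 1L
      sh[shell] <- spec$hu_cortical
      sl[canc] <- 2L
      sh[canc] <- spec$hu_cancellous_mean + noise[, , k][canc]
    }

    # spinal canal (geometry keeps it clear of bone)
    m <- canal2 <= spec$canal_radius^2
    sl[m] <- 5L
    sh[m] <- spec$hu_soft_tissue

    # planted dense corridor: boost bone voxels inside the cylinder
    if (!is.null(corr)) {
      dx <- X - cp[1]; dy <- Y - cp[2]; dz <- z - cp[3]
      tt <- dx * w[1] + dy * w[2] + dz * w[3]
      r2 <- dx^2 + dy^2 + dz^2 - tt^2
      m <- r2 <= corr$radius^2 & sl %in% bone_labels()
      sh[m] <- sh[m] + corr$hu_boost
    }

    lab[, , k] <- sl
    hu[, , k] <- sh
  }

  f <- spec$decalcification_factor
  if (f < 1) {
    bone <- lab %in% bone_labels()
    hu[bone] <- f * hu[bone]
  }

  affine <- diag(c(sp, sp, sp, 1))
  affine[1:3, 4] <- c(xs[1], ys[1], zs[1])
  ct <- ct_volume(hu, affine)
  labels <- label_volume(lab, affine)

  waist_left <- lay$anchor_left + lay$waist_s * lay$u_left
  waist_right <- lay$anchor_right + lay$waist_s * lay$u_right
  truth <- list(
    midline_plane = list(point = c(0, 0, 0), normal = c(1, 0, 0)),
    lower_endplate_plane = list(point = c(0, 0, -h2), normal = c(0, 0, 1)),
    axial_plane_normal = c(0, 0, 1),
    pedicle_axes = list(
      left = list(point = waist_left, direction = lay$u_left),
      right = list(point = waist_right, direction = lay$u_right)),
    min_section_centroids = list(left = waist_left, right = waist_right),
    waist_radius = spec$pedicle_radius,
    corridor_axis = if (!is.null(corr))
      list(point = corr$point,
           direction = corr$direction / sqrt(sum(corr$direction^2))))

  list(ct = ct, labels = labels, truth = truth)
}

#' Vertebral frame of a phantom from its ground truth
#'
#' @param truth The `truth` element returned by [generate_phantom()].
#' @param side `"left"` or `"right"`.
#' @return A [vertebral_frame()].
#' @export
frame_from_truth <- function(truth, side = c("left", "right")) {
  side <- match.arg(side)
  vertebral_frame(midline_point = truth$midline_plane$point,
                  midline_normal = truth$midline_plane$normal,
                  endplate_point = truth$lower_endplate_plane$point,
                  endplate_normal = truth$lower_endplate_plane$normal,
                  axial_normal = truth$axial_plane_normal,
                  side = side)
}

#' Apply the linear decalcification model
#'
#' Bone voxels are attenuated toward water:
#' `HU_new = hu_water + factor * (HU - hu_water)` with `hu_water = 0`.
#' Non-bone voxels are unchanged. Applying factors f1 then f2 equals
#' applying f1 * f2.
#'
#' @param v A `ct_volume`.
#' @param l The aligned `label_volume`.
#' @param factor Attenuation factor in `[0, 1]`; 1 = untreated.
#' @return A decalcified `ct_volume`.
#' @export
apply_decalcification <- function(v, l, factor) {
  if (factor < 0 || factor > 1) stop("factor must lie in [0, 1]")
  if (!all(dim(v$data) == dim(l$data)))
    stop("CT and label volumes are not aligned")
  hu <- v$data
  bone <- l$data %in% bone_labels()
  hu[bone] <- factor * hu[bone]
  ct_volume(hu, v$affine, v$world_frame_tag)
}

#' Mean Hounsfield value over the bone compartments
#'
#' @param v A `ct_volume`.
#' @param l The aligned `label_volume`.
#' @return Mean HU over voxels labeled as bone.
#' @export
vertebral_mean_hu <- function(v, l) {
  bone <- l$data %in% bone_labels()
  if (!any(bone)) stop("empty bone mask")
  mean(v$data[bone])
}

#' Solve for the decalcification factor hitting a target T-prime score
#'
#' By linearity of the decalcification model the vertebral mean scales
#' with the factor, giving the closed form
#' `factor = (ref_mean + target * ref_sd) / mean_bone_hu`.
#'
#' @param target_t_prime Target T-prime score.
#' @param ref_mean,ref_sd Reference (untreated) mean and SD in HU;
#'   `ref_sd > 0`.
#' @param v,l CT and label volumes of the untreated vertebra.
#' @return The factor in `[0, 1]`; errors (reporting the feasible T-prime
#'   range) if the target would require a factor outside `[0, 1]`.
#' @export
calibrate_decalcification <- function(target_t_prime, ref_mean, ref_sd,
                                      v, l) {
  if (ref_sd <= 0) stop("ref_sd must be > 0")
  m0 <- vertebral_mean_hu(v, l)
  factor <- (ref_mean + target_t_prime * ref_sd) / m0
  if (factor < 0 || factor > 1) {
    lo <- (0 - ref_mean) / ref_sd
    hi <- (m0 - ref_mean) / ref_sd
    stop(sprintf(
      "target T' %.3f infeasible: factor would be %.4f; feasible T' range is [%.3f, %.3f]",
      target_t_prime, factor, min(lo, hi), max(lo, hi)))
  }
  factor
}
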