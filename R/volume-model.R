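# Volume containers and sampling primitives.
#
# Conventions: world frame is right-handed and RAS-like (x: left -> right
# across the midline, y: posterior -> anterior, z: caudal -> cranial).
# Voxel indices are 0-based; the affine maps homogeneous 0-based voxel
# indices to world millimetres. All geometry downstream is in world mm.

#' Compartment label scheme for vertebral label volumes
#'
#' Integer codes used by [label_volume()]: 0 background, 1 cortical shell,
#' 2 cancellous body, 3 left pedicle, 4 right pedicle, 5 spinal canal,
#' 6 narrowest-pedicle-section ROI (left), 7 narrowest-pedicle-section ROI
#' (right).
#'
#' @return Named integer vector mapping compartment names to label codes.
#' @export
label_scheme <- function() {
  c(background = 0L, cortical_shell = 1L, cancellous_body = 2L,
    pedicle_left = 3L, pedicle_right = 4L, spinal_canal = 5L,
    pedicle_roi_left = 6L, pedicle_roi_right = 7L)
}

#' Labels counted as bone
#'
#' The bone mask comprises the cortical shell, cancellous body, both
#' pedicles and the narrowest-pedicle-section ROI disks (which are pedicle
#' bone carrying a distinct code).
#'
#' @return Integer vector of bone label codes.
#' @export
bone_labels <- function() c(1L, 2L, 3L, 4L, 6L, 7L)

.spacing_from_affine <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

.check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (!all(is.finite(affine))) stop("affine must be finite")
  inv <- tryCatch(solve(affine), error = function(e) NULL)
  if (is.null(inv)) stop("affine is not invertible")
  if (max(abs(affine %*% inv - diag(4))) > 1e-9)
    stop("affine is numerically singular")
  inv
}

#' Construct a CT volume
#'
#' @param data 3D numeric array of Hounsfield values (finite).
#' @param affine 4x4 matrix mapping homogeneous 0-based voxel indices to
#'   world millimetres; must be invertible.
#' @param world_frame_tag Orientation tag of the world frame; fixed
#'   RAS-like convention.
#' @return An object of class `ct_volume` with fields `data`, `spacing`
#'   (mm per axis, derived from the affine), `affine`, `world_frame_tag`.
#' @export
ct_volume <- function(data, affine, world_frame_tag = "RAS") {
  if (length(dim(data)) != 3L) stop("expected 3D volume")
  if (!all(is.finite(data))) stop("HU values must be finite")
  .check_affine(affine)
  spacing <- .spacing_from_affine(affine)
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
  structure(list(data = data, spacing = spacing, affine = affine,
                 world_frame_tag = world_frame_tag),
            class = "ct_volume")
}

#' Construct a label volume
#'
#' @param data 3D integer array of compartment labels.
#' @param affine 4x4 voxel-to-world affine (same as the companion CT).
#' @param scheme Named integer label scheme; defaults to [label_scheme()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, affine, scheme = label_scheme()) {
  if (length(dim(data)) != 3L) stop("expected 3D volume")
  storage.mode(data) <- "integer"
  if (!all(data %in% scheme))
    stop("labels outside the label scheme: ",
         paste(setdiff(unique(c(data)), scheme), collapse = ", "))
  .check_affine(affine)
  structure(list(data = data, spacing = .spacing_from_affine(affine),
                 affine = affine, label_scheme = scheme),
            class = "label_volume")
}

.as_point_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L, byrow = TRUE)
  if (ncol(p) != 3L) stop("points must have 3 columns")
  p
}

#' Map world coordinates (mm) to continuous 0-based voxel indices
#'
#' @param v A `ct_volume`, `label_volume` or `distance_map`.
#' @param p World point(s): length-3 vector or n x 3 matrix.
#' @return n x 3 matrix of continuous voxel indices.
#' @export
world_to_voxel <- function(v, p) {
  p <- .as_point_matrix(p)
  inv <- solve(v$affine)
  t(inv %*% rbind(t(p), 1))[, 1:3, drop = FALSE]
}

#' Map 0-based voxel indices to world coordinates (mm)
#'
#' @inheritParams world_to_voxel
#' @param idx Voxel index/indices (0-based, possibly fractional).
#' @return n x 3 matrix of world coordinates.
#' @export
voxel_to_world <- function(v, idx) {
  idx <- .as_point_matrix(idx)
  t(v$affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

#' Load a CT or label volume from a NIfTI file
#'
#' Affine and spacing are taken from the file header (sform preferred);
#' voxel values are not modified. For label volumes a `.labels.json`
#' sidecar written by [save_volume()] is read when present.
#'
#' @param path Path to a `.nii` / `.nii.gz` file holding a 3D image.
#' @param type `"ct"` or `"label"`.
#' @return A `ct_volume` or `label_volume`.
#' @export
load_volume <- function(path, type = c("ct", "label")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("cannot read file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim = dim(arr))  # strip image attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1L, drop = TRUE]
  if (length(dim(arr)) != 3L) stop("expected 3D volume")
  affine <- structure(RNifti::xform(img), class = NULL)
  affine <- matrix(as.numeric(affine), 4L, 4L)
  if (type == "ct") {
    if (!all(is.finite(arr))) stop("non-finite voxels in ", path)
    ct_volume(arr, affine)
  } else {
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")
    scheme <- label_scheme()
    if (file.exists(sidecar)) {
      sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      scheme <- structure(as.integer(sc), names = names(sc))
    }
    label_volume(round(arr), affine, scheme = scheme)
  }
}

#' Save a CT or label volume to NIfTI
#'
#' Label volumes additionally get a `.labels.json` sidecar with the
#' integer-to-name map.
#'
#' @param v A `ct_volume` or `label_volume`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
save_volume <- function(v, path) {
  img <- RNifti::asNifti(v$data)
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path)
  if (inherits(v, "label_volume")) {
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")
    jsonlite::write_json(as.list(v$label_scheme), sidecar,
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Sample Hounsfield values by trilinear interpolation
#'
#' @param v A `ct_volume`.
#' @param p World point(s) (mm); every point must lie inside the grid
#'   (between the first and last voxel centers on each axis).
#' @return Numeric vector of interpolated HU values.
#' @export
sample_hu <- function(v, p) {
  vox <- world_to_voxel(v, p)
  out <- .trilinear(v$data, dim(v$data), vox)
  if (anyNA(out)) stop("sample point outside the scanned grid")
  out
}

#' Euclidean distance map of a label mask
#'
#' Per-voxel distance (mm, anisotropy-aware) from the voxel center to the
#' nearest voxel center outside the mask; zero outside the mask. The
#' exterior beyond the array edge counts as outside.
#'
#' @param l A `label_volume`.
#' @param labels Nonempty subset of label codes defining the mask;
#'   defaults to [bone_labels()].
#' @return An object of class `distance_map` with fields `data`,
#'   `spacing`, `affine`, `mask_labels`.
#' @export
distance_map <- function(l, labels = bone_labels()) {
  if (length(labels) == 0L) stop("labels must be a nonempty subset")
  mask <- array(l$data %in% labels, dim = dim(l$data))
  if (!any(mask)) stop("empty mask: no voxels carry the requested labels")
  d <- .edt3d(mask, dim(mask), l$spacing)
  structure(list(data = d, spacing = l$spacing, affine = l$affine,
                 mask_labels = as.integer(labels)),
            class = "distance_map")
}

#' Interpolate a distance map at world points
#'
#' @param dm A `distance_map`.
#' @param p World point(s) (mm) inside the grid.
#' @return Numeric vector of distances (mm).
#' @export
sample_distance <- function(dm, p) {
  vox <- world_to_voxel(dm, p)
  out <- .trilinear(dm$data, dim(dm$data), vox)
  if (anyNA(out)) stop("sample point outside the scanned grid")
  out
}

#' Nearest-voxel label lookup at world points
#'
#' @param l A `label_volume`.
#' @param p World point(s) (mm).
#' @return Integer labels; `NA` for points outside the grid.
#' @export
sample_label <- function(l, p) {
  vox <- world_to_voxel(l, p)
  .nn_lookup(l$data, dim(l$data), vox)
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("ct_volume:", paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = "/"),
      "mm,", x$world_frame_tag, "frame\n")
  cat("  HU range:", paste(signif(range(x$data), 6), collapse = " .. "),
      "\n")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = "/"),
      "mm\n")
  tb <- table(factor(x$data, levels = x$label_scheme,
                     labels = names(x$label_scheme)))
  print(tb[tb > 0])
  invisible(x)
}
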