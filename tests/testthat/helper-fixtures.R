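# Shared fixtures, built in code. Phantoms are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

default_phantom <- function() {
  cached("phantom_default", function() generate_phantom(phantom_spec()))
}

default_dmap <- function() {
  cached("dmap_default",
         function() distance_map(default_phantom()$labels, bone_labels()))
}

# coarse (1 mm) phantom for brute-force voxel oracles
coarse_phantom <- function() {
  cached("phantom_coarse",
         function() generate_phantom(phantom_spec(spacing = 1, seed = 3)))
}

coarse_dmap <- function() {
  cached("dmap_coarse",
         function() distance_map(coarse_phantom()$labels, bone_labels()))
}

# simple bone cylinder (cancellous label) along z, centered at the origin
bone_cylinder <- function(radius = 10, height = 40, spacing = 1) {
  pad <- 4 * spacing
  n_xy <- 2L * ceiling((radius + pad) / spacing) + 1L
  n_z <- 2L * ceiling((height / 2 + pad) / spacing) + 1L
  xs <- (seq_len(n_xy) - (n_xy + 1) / 2) * spacing
  zs <- (seq_len(n_z) - (n_z + 1) / 2) * spacing
  lab <- array(0L, c(n_xy, n_xy, n_z))
  r2 <- outer(xs^2, xs^2, "+")
  disk <- r2 <= radius^2
  for (k in seq_len(n_z)) if (abs(zs[k]) <= height / 2) lab[, , k][disk] <- 2L
  affine <- diag(c(spacing, spacing, spacing, 1))
  affine[1:3, 4] <- c(xs[1], xs[1], zs[1])
  label_volume(lab, affine)
}

# uniform HU volume on the same grid as a label volume
uniform_ct <- function(l, hu = 1000) {
  ct_volume(array(hu, dim(l$data)), l$affine)
}

standard_frame <- function(side = "left") {
  vertebral_frame(midline_point = c(0, 0, 0), midline_normal = c(1, 0, 0),
                  endplate_point = c(0, 0, -15),
                  endplate_normal = c(0, 0, 1), side = side)
}

# random anterior-pointing trajectory in a standard frame
random_trajectory <- function() {
  entry <- c(runif(1, -25, -5), runif(1, -40, -20), runif(1, -8, 8))
  dir <- c(runif(1, -0.6, 0.6), 1, runif(1, -0.6, 0.6))
  trajectory(entry, dir / sqrt(sum(dir^2)), runif(1, 20, 40),
             runif(1, 4, 7))
}

# independent vector-algebra oracle for trajectory measurements
oracle_measure <- function(t, f) {
  nm <- f$midline_normal; ne <- f$endplate_normal; na <- f$axial_normal
  ang <- function(a, b) {
    acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
  }
  drop_comp <- function(v, n) v - sum(v * n) * n
  sm <- sum((f$midline_point - t$entry) * nm)
  de <- sum((t$entry - f$endplate_point) * ne)
  w_ax <- sign(sm) * nm
  w_sag <- sign(de) * ne
  theta <- ang(drop_comp(t$direction, na), drop_comp(w_ax, na))
  theta_p <- ang(drop_comp(t$direction, nm), drop_comp(w_sag, nm))
  list(d = abs(sm), theta = theta, d_prime = abs(de),
       theta_prime = theta_p)
}
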