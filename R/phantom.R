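#' @keywords internal
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic lung phantom
#'
#' Describes a lung-like sample: a soft-tissue cylinder (optionally wrapped
#' in an agarose shell) containing a large central airway, randomly placed
#' spherical air vesicles (the parenchyma), an optional bone rod, and a
#' fine-scale multiplicative density texture that preserves the
#' delta/beta ratio voxelwise. All in-plane geometry is expressed as
#' fractions of the smaller in-plane dimension so phantoms scale with
#' `shape`.
#'
#' @param shape integer length-3 voxel counts (slice, row, column)
#' @param voxel_size voxel edge in um (default 9, the detector pixel)
#' @param vesicle_count number of air vesicles (default 350 at 128^3)
#' @param vesicle_radius_range length-2 numeric, vesicle radii in um
#' @param bone_rod logical, include a bone rod parallel to the slice axis
#' @param bone_radius_frac bone rod radius as fraction of min in-plane size
#' @param gamma_lung delta/beta for soft tissue and agarose (default 1950)
#' @param gamma_bone delta/beta for bone (default 250)
#' @param delta_tissue reference refractive decrement of soft tissue
#'   (default 4.06e-7, a plausible soft-tissue scale at 22 keV; only the
#'   ratio gamma matters for retrieval correctness, delta sets contrast)
#' @param delta_bone refractive decrement of bone (default 2.5x tissue)
#' @param sample_radius_frac tissue cylinder radius fraction; `NA` fills the
#'   whole volume with tissue (no cylinder boundary)
#' @param airway_radius_frac radius fraction of the central airway
#'   (0 disables)
#' @param airway_offset_frac length-2 (row, col) offset fraction of the
#'   airway axis from the volume center
#' @param airway_collar_frac width fraction of a vesicle-free tissue
#'   collar outside the airway wall, keeping the measurement interface
#'   clean for edge-profile extraction
#' @param agarose_frac agarose shell thickness fraction (0 disables)
#' @param roi_patch_frac half-width fraction of a vesicle-free solid-tissue
#'   patch reserved for ROI measurements (0 disables exclusion)
#' @param roi_patch_offset_frac length-2 (row, col) offset fraction of that
#'   patch from the volume center
#' @param texture_sd relative RMS amplitude of the gamma-preserving density
#'   texture in tissue/agarose (default 0.03; 0 disables)
#' @param seed integer; fully determines the phantom
#' @return an object of class `phantom_spec` (a validated list)
#' @export
phantom_spec <- function(shape = c(128L, 128L, 128L),
                         voxel_size = 9,
                         vesicle_count = 350L,
                         vesicle_radius_range = c(27, 54),
                         bone_rod = TRUE,
                         bone_radius_frac = 0.08,
                         gamma_lung = 1950,
                         gamma_bone = 250,
                         delta_tissue = 4.06e-7,
                         delta_bone = 2.5 * 4.06e-7,
                         sample_radius_frac = 0.44,
                         airway_radius_frac = 0.18,
                         airway_offset_frac = c(0.10, -0.12),
                         airway_collar_frac = 0.10,
                         agarose_frac = 0.04,
                         roi_patch_frac = 0.11,
                         roi_patch_offset_frac = c(-0.19, 0.19),
                         texture_sd = 0.03,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 8))
  if (gamma_lung <= 0 || gamma_bone <= 0)
    stop("gamma values must be positive")
  stopifnot(voxel_size > 0, delta_tissue > 0, delta_bone > 0)
  stopifnot(length(vesicle_radius_range) == 2,
            all(vesicle_radius_range > 0),
            vesicle_radius_range[1] <= vesicle_radius_range[2])
  if (vesicle_radius_range[1] < 2 * voxel_size)
    stop("vesicle radii must be >= 2 voxels so interfaces are resolvable")
  half_extent_um <- min(shape[2:3]) * voxel_size / 2
  if (vesicle_radius_range[2] > half_extent_um)
    stop("vesicle radii must not exceed half the volume extent")
  stopifnot(vesicle_count >= 0, texture_sd >= 0)
  spec <- list(shape = shape, voxel_size = voxel_size,
               vesicle_count = as.integer(vesicle_count),
               vesicle_radius_range = vesicle_radius_range,
               bone_rod = isTRUE(bone_rod),
               bone_radius_frac = bone_radius_frac,
               gamma_lung = gamma_lung, gamma_bone = gamma_bone,
               delta_tissue = delta_tissue, delta_bone = delta_bone,
               sample_radius_frac = sample_radius_frac,
               airway_radius_frac = airway_radius_frac,
               airway_offset_frac = airway_offset_frac,
               airway_collar_frac = airway_collar_frac,
               agarose_frac = agarose_frac,
               roi_patch_frac = roi_patch_frac,
               roi_patch_offset_frac = roi_patch_offset_frac,
               texture_sd = texture_sd,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

## Distance of every in-plane voxel center from a point, in voxels.
## Returns an (nrow x ncol) matrix; rows/cols are 1-based grid indices.
inplane_dist2 <- function(nr, nc, center_r, center_c) {
  dr <- (seq_len(nr) - center_r)
  dc <- (seq_len(nc) - center_c)
  outer(dr^2, dc^2, "+")
}

## fractional in-circle occupancy of every voxel, by ss x ss supersampling
circle_occupancy <- function(nr, nc, center_r, center_c, radius, ss = 4L) {
  if (!is.finite(radius)) return(matrix(1, nr, nc))
  if (radius <= 0) return(matrix(0, nr, nc))
  occ <- matrix(0, nr, nc)
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss
  for (or in offs) for (oc in offs)
    occ <- occ + (inplane_dist2(nr, nc, center_r - or, center_c - oc) <=
                    radius^2)
  occ / ss^2
}

## 3x3x3 box smoothing with reflected boundaries, separable; used only to
## correlate the texture field at ~1 voxel.
box_smooth_3d <- function(a) {
  sm_axis <- function(x, axis) {
    n <- dim(x)[axis]
    idx_m <- c(1L, seq_len(n - 1L))
    idx_p <- c(seq_len(n - 1L) + 1L, n)
    pick <- function(i) switch(axis, x[i, , , drop = FALSE],
                               x[, i, , drop = FALSE], x[, , i, drop = FALSE])
    (pick(idx_m) + x + pick(idx_p)) / 3
  }
  sm_axis(sm_axis(sm_axis(a, 1L), 2L), 3L)
}

## Seeded vesicle geometry in scale-free units: radius as a fraction of
## the min in-plane extent n, in-plane center offsets from the volume
## center as fractions of n, z as a fraction of the slice range. The
## accept/reject sequence uses only fraction-unit quantities, so any
## rasterization of the same spec (e.g. a supersampled one) gets the
## identical physical vesicle set.
vesicle_list <- function(spec) {
  shp <- spec$shape
  n <- min(shp[2:3])
  aspect_z <- shp[1] / n                # z placement span relative to n
  rv_frac <- spec$vesicle_radius_range / (spec$voxel_size * n)
  r_sample_f <- if (is.na(spec$sample_radius_frac)) Inf else
    spec$sample_radius_frac
  margin <- 2 / 128                     # ~2 px at the reference 128 grid
  out <- local_seed(spec$seed, {
    acc <- matrix(0, 0, 4)
    placed <- 0L; guard <- 0L
    while (placed < spec$vesicle_count && guard < 50L * spec$vesicle_count) {
      guard <- guard + 1L
      u <- stats::runif(4)
      rad <- rv_frac[1] + u[1] * (rv_frac[2] - rv_frac[1])
      zf <- if (aspect_z > 2 * rad) {
        (rad + u[2] * (aspect_z - 2 * rad)) / aspect_z
      } else u[2]
      rf <- (u[3] - 0.5) * min(shp[2] / n, 2)
      cf <- (u[4] - 0.5) * min(shp[3] / n, 2)
      d_cen <- sqrt(rf^2 + cf^2)
      if (is.finite(r_sample_f) && d_cen > r_sample_f - rad - margin / 2) next
      if (spec$airway_radius_frac > 0 &&
          sqrt((rf - spec$airway_offset_frac[1])^2 +
                 (cf - spec$airway_offset_frac[2])^2) <
            spec$airway_radius_frac + rad +
              max(margin, spec$airway_collar_frac)) next
      if (spec$bone_rod &&
          sqrt((rf + 0.22)^2 + (cf + 0.22)^2) <
            spec$bone_radius_frac + rad + margin) next
      if (spec$roi_patch_frac > 0 &&
          max(abs(rf - spec$roi_patch_offset_frac[1]),
              abs(cf - spec$roi_patch_offset_frac[2])) <
            spec$roi_patch_frac + rad + margin) next
      acc <- rbind(acc, c(rad, zf, rf, cf))
      placed <- placed + 1L
    }
    acc
  })
  data.frame(rad_frac = out[, 1], z_frac = out[, 2],
             r_frac = out[, 3], c_frac = out[, 4])
}

#' Generate a lung-like complex-refractive-index phantom
#'
#' Builds the sample described by a [phantom_spec()]: soft tissue with
#' delta/beta = `gamma_lung`, air vesicles (delta = beta = 0), an optional
#' bone rod with delta/beta = `gamma_bone`, a central airway and an agarose
#' shell, plus a gamma-preserving fine density texture. Deterministic under
#' `spec$seed`.
#'
#' Vesicle centers are drawn uniformly in the parenchyma (inside the tissue
#' cylinder, outside the airway, bone rod and the reserved ROI patch);
#' overlapping vesicles union, air wins over tissue.
#'
#' @param spec a `phantom_spec`
#' @return a `complex_index_volume`
#' @export
make_lung_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$shape
  nz <- shp[1]; nr <- shp[2]; nc <- shp[3]
  n <- min(nr, nc)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2

  r_sample <- if (is.na(spec$sample_radius_frac)) Inf else
    spec$sample_radius_frac * n
  r_airway <- spec$airway_radius_frac * n
  r_bone <- if (spec$bone_rod) spec$bone_radius_frac * n else 0
  t_agar <- spec$agarose_frac * n
  airway_c <- c(cr + spec$airway_offset_frac[1] * n,
                cc + spec$airway_offset_frac[2] * n)
  bone_c <- c(cr - 0.22 * n, cc - 0.22 * n)
  patch_c <- c(cr + spec$roi_patch_offset_frac[1] * n,
               cc + spec$roi_patch_offset_frac[2] * n)
  patch_hw <- spec$roi_patch_frac * n

  ## Partial-volume (antialiased) rasterization: structure boundaries get
  ## fractional occupancy from 4x4 in-plane supersampling, so material
  ## surfaces do not carry artificial stair-step content above the voxel
  ## Nyquist frequency. Labels stay binary: a voxel is labeled air only
  ## when it contains no material at all, so air voxels have
  ## delta = beta = 0 exactly.
  occ_sample <- circle_occupancy(nr, nc, cr, cc, r_sample)
  occ_shell_out <- if (is.finite(r_sample) && t_agar > 0)
    circle_occupancy(nr, nc, cr, cc, r_sample + t_agar) else occ_sample
  occ_airway <- if (r_airway > 0)
    circle_occupancy(nr, nc, airway_c[1], airway_c[2], r_airway) else
    matrix(0, nr, nc)
  occ_bone <- if (r_bone > 0)
    circle_occupancy(nr, nc, bone_c[1], bone_c[2], r_bone) else
    matrix(0, nr, nc)

  ## bone rim voxels hold bone material only (scaled by occupancy) so
  ## every voxel's delta/beta is exactly one material's gamma
  f_bone2d <- occ_sample * occ_bone
  f_tissue2d <- occ_sample * (1 - occ_airway) * (occ_bone == 0)
  f_agar2d <- pmax(occ_shell_out - occ_sample, 0)

  ## 2D templates -> replicate over slices; vesicles then carve the
  ## tissue fraction slice by slice
  rep3 <- function(m) array(rep(m, each = nz), dim = c(nz, nr, nc))
  f_tissue <- rep3(f_tissue2d)
  f_bone <- rep3(f_bone2d)
  f_agar <- rep3(f_agar2d)

  ## vesicles: seeded placement in the parenchyma, drawn in scale-free
  ## (fraction-of-extent) units so that rasterizations of the same spec at
  ## different voxel sizes carve the identical physical sample
  if (spec$vesicle_count > 0) {
    ves <- vesicle_list(spec)
    for (v in seq_len(nrow(ves))) {
      rad <- ves$rad_frac[v] * n
      vz <- 1 + ves$z_frac[v] * (nz - 1)
      vr <- cr + ves$r_frac[v] * n
      vc <- cc + ves$c_frac[v] * n
      ## carve the sphere (bounding box loop over slices; in-plane
      ## cross-section antialiased, z handled by the shrinking radius)
      z0 <- max(1L, floor(vz - rad)); z1 <- min(nz, ceiling(vz + rad))
      r0 <- max(1L, floor(vr - rad)); r1 <- min(nr, ceiling(vr + rad))
      c0 <- max(1L, floor(vc - rad)); c1 <- min(nc, ceiling(vc + rad))
      for (z in z0:z1) {
        rem2 <- rad^2 - (z - vz)^2
        if (rem2 <= 0) next
        occ_v <- circle_occupancy(r1 - r0 + 1L, c1 - c0 + 1L,
                                  vr - r0 + 1, vc - c0 + 1, sqrt(rem2))
        f_tissue[z, r0:r1, c0:c1] <-
          f_tissue[z, r0:r1, c0:c1] * (1 - occ_v)
      }
    }
  }

  delta <- spec$delta_tissue * f_tissue +
    0.9 * spec$delta_tissue * f_agar + spec$delta_bone * f_bone
  beta <- (spec$delta_tissue * f_tissue + 0.9 * spec$delta_tissue * f_agar) /
    spec$gamma_lung + spec$delta_bone * f_bone / spec$gamma_bone

  ## labels: dominant material; air only where no material at all
  labels <- array(LABEL_AIR, dim = c(nz, nr, nc))
  any_mat <- f_tissue + f_agar + f_bone > 0
  labels[any_mat] <- LABEL_TISSUE
  labels[any_mat & f_agar >= f_tissue & f_bone == 0] <- LABEL_AGAROSE
  labels[f_bone > 0] <- LABEL_BONE
  is_t <- labels == LABEL_TISSUE
  is_a <- labels == LABEL_AGAROSE

  ## gamma-preserving fine density texture on tissue/agarose: delta and
  ## beta are scaled by the SAME multiplicative field, so delta/beta is
  ## untouched voxelwise. This emulates the intrinsic small density
  ## variation of biological tissue that converts into phase "noise"
  ## growing with propagation distance.
  if (spec$texture_sd > 0) {
    mfield <- local_seed(spec$seed + 7654321L, {
      z <- array(stats::rnorm(prod(dim(labels))), dim = dim(labels))
      z <- box_smooth_3d(z)
      z <- z / stats::sd(z)
      pmax(1 + spec$texture_sd * z, 0.5)
    })
    sel <- is_t | is_a
    delta[sel] <- delta[sel] * mfield[sel]
    beta[sel] <- beta[sel] * mfield[sel]
  }

  complex_index_volume(delta, beta, labels, spec$voxel_size,
                       meta = list(spec = unclass(spec),
                                   airway_center_px = airway_c,
                                   airway_radius_px = r_airway,
                                   bone_center_px = bone_c,
                                   bone_radius_px = r_bone,
                                   roi_patch_center_px = patch_c,
                                   roi_patch_halfwidth_px = patch_hw))
}

#' Half-space air / half-space tissue edge phantom
#'
#' A planar air-tissue interface aligned to the row axis of the volume, so
#' that a projection at angle 0 (beam along the column axis) shows a step
#' edge at detector column `floor(n_row/2)` (0-based). Air occupies the
#' low-index side.
#'
#' @param shape length-3 voxel counts, each >= 32
#' @param voxel_size voxel edge in um
#' @param gamma delta/beta of the tissue half
#' @param delta_tissue refractive decrement of the tissue half
#' @return a `complex_index_volume`; `meta$interface_col` records the
#'   0-based index of the first tissue column in the projection
#' @export
make_edge_phantom <- function(shape = c(64L, 128L, 64L), voxel_size = 9,
                              gamma = 1950, delta_tissue = 4.06e-7) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 32))
  if (gamma <= 0) stop("gamma must be positive")
  nz <- shape[1]; nr <- shape[2]; nc <- shape[3]
  iface0 <- nr %/% 2L                 # 0-based first tissue row
  labels <- array(LABEL_AIR, dim = shape)
  labels[, (iface0 + 1L):nr, ] <- LABEL_TISSUE
  delta <- array(0, dim = shape)
  beta <- array(0, dim = shape)
  delta[labels == LABEL_TISSUE] <- delta_tissue
  beta[labels == LABEL_TISSUE] <- delta_tissue / gamma
  complex_index_volume(delta, beta, labels, voxel_size,
                       meta = list(interface_col = iface0, gamma = gamma))
}

#' Uniform absorbing disk (cylinder) phantom
#'
#' A pure-absorption cylinder: beta derived from a stated linear
#' attenuation coefficient via beta = mu * lambda / (4 pi), delta = 0.
#' Used as the analytic oracle fixture for filtered back-projection.
#'
#' @param shape length-3 voxel counts (slice, row, column)
#' @param voxel_size voxel edge in um
#' @param mu_disk linear attenuation of the disk, 1/cm
#' @param energy_kev photon energy fixing lambda (default 22)
#' @param radius_frac disk radius as a fraction of the in-plane size
#'   (must be <= 0.4)
#' @return a `complex_index_volume`; `meta$mu_per_um` records the target mu
#' @export
make_disk_phantom <- function(shape = c(8L, 128L, 128L), voxel_size = 9,
                              mu_disk = 5, energy_kev = 22,
                              radius_frac = 0.3) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, radius_frac > 0)
  if (radius_frac > 0.4)
    stop("disk radius must be <= 0.4 x field of view")
  nz <- shape[1]; nr <- shape[2]; nc <- shape[3]
  lam_A <- energy_to_wavelength(energy_kev)
  mu_per_um <- mu_disk / 1e4
  beta_disk <- mu_to_beta(mu_per_um, lam_A)
  rad <- radius_frac * min(nr, nc)
  d2 <- inplane_dist2(nr, nc, (nr + 1) / 2, (nc + 1) / 2)
  occ <- circle_occupancy(nr, nc, (nr + 1) / 2, (nc + 1) / 2, rad)
  in_disk <- occ > 0                      # any material present
  labels <- array(LABEL_AIR, dim = shape)
  beta <- array(0, dim = shape)
  for (z in seq_len(nz)) {
    labels[z, , ][in_disk] <- LABEL_TISSUE
    beta[z, , ] <- beta_disk * occ        # antialiased rim
  }
  complex_index_volume(array(0, dim = shape), beta, labels, voxel_size,
                       meta = list(mu_per_um = mu_per_um,
                                   radius_px = rad,
                                   energy_kev = energy_kev))
}
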