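## Synthetic brain phantom.
##
## Nested ellipsoids stand in for the ventricles, white matter, cortex and
## skull; angular wedges in the coronal/axial angle define the eight lobar
## sectors, and two para-ventricular ellipsoids (merged into one bilateral
## region) stand in for the basal ganglia. The geometry is deliberately
## simple: its only job is to populate all 36 bullseye parcels with known
## ground truth.

#' Default phantom geometry
#'
#' All radii are fractions of the half field of view (half of the smallest
#' physical grid extent), so the same geometry scales to any grid of at least
#' 32 voxels per axis.
#'
#' @param ventricle_axes semi-axes of the central ventricle ellipsoid.
#' @param wm_frac outer radius of the white-matter shell.
#' @param cortex_frac outer radius of the cortical shell.
#' @param skull_frac radius of the intracranial sphere.
#' @param bg_center_frac distance of each basal-ganglia ellipsoid center from
#'   the midline along x.
#' @param bg_axes semi-axes of each basal-ganglia ellipsoid.
#' @return a named list of geometry parameters.
#' @export
phantom_geometry <- function(ventricle_axes = c(0.20, 0.30, 0.22),
                             wm_frac = 0.71,
                             cortex_frac = 0.83,
                             skull_frac = 0.94,
                             bg_center_frac = 0.45,
                             bg_axes = c(0.24, 0.14, 0.14)) {
  list(ventricle_axes = ventricle_axes, wm_frac = wm_frac,
       cortex_frac = cortex_frac, skull_frac = skull_frac,
       bg_center_frac = bg_center_frac, bg_axes = bg_axes)
}

#' Generate a synthetic brain phantom
#'
#' Builds binary ventricle, white-matter, cortex and intracranial masks plus
#' a lobar label volume (codes 1..8 for frontal/parietal/temporal/occipital x
#' left/right, 9 for the bilateral basal ganglia) on a common grid. Masks are
#' pairwise disjoint, every white-matter and basal-ganglia voxel carries
#' exactly one lobar code, and with the default geometry every one of the 9
#' regions intersects all 4 concentric layers, so the downstream bullseye map
#' has all 36 parcels populated.
#'
#' @param shape integer length-3, at least 32 per axis.
#' @param spacing numeric length-3 in mm.
#' @param geometry a list from [phantom_geometry()].
#' @param seed integer, recorded in the object (the geometry itself is
#'   deterministic).
#' @return an object of class `phantom_brain`: list with `ventricle_mask`,
#'   `cortex_mask`, `wm_mask`, `lobar_labels`, `intracranial_mask` (3D
#'   arrays), `spacing`, `etiv_mm3`, `geometry`, `seed`.
#' @export
#' @examples
#' pb <- make_phantom_brain(shape = c(48, 48, 48))
#' pb$etiv_mm3
make_phantom_brain <- function(shape = c(96, 96, 96), spacing = c(1, 1, 1),
                               geometry = phantom_geometry(), seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, length(spacing) == 3L)
  if (any(shape < 32L)) stop("make_phantom_brain: shape must be >= 32 per axis")
  if (any(spacing <= 0)) stop("make_phantom_brain: spacing must be positive")
  g <- geometry
  if (any(g$ventricle_axes <= 0))
    stop("invalid geometry: ventricle radius must be positive ",
         "(normalized distance undefined for an empty ventricle)")
  if (!(max(g$ventricle_axes) < g$wm_frac && g$wm_frac < g$cortex_frac &&
        g$cortex_frac < g$skull_frac && g$skull_frac <= 1))
    stop("invalid geometry: radii must nest as ventricle < white matter < ",
         "cortex < skull <= 1")

  half <- min((shape - 1) / 2 * spacing)  # half field of view, mm
  ax <- (seq_len(shape[1]) - (shape[1] + 1) / 2) * spacing[1]
  ay <- (seq_len(shape[2]) - (shape[2] + 1) / 2) * spacing[2]
  az <- (seq_len(shape[3]) - (shape[3] + 1) / 2) * spacing[3]
  X <- array(ax, dim = shape)
  Y <- array(rep(ay, each = shape[1]), dim = shape)
  Z <- array(rep(az, each = shape[1] * shape[2]), dim = shape)
  R <- sqrt(X^2 + Y^2 + Z^2)

  ev <- sqrt((X / (g$ventricle_axes[1] * half))^2 +
             (Y / (g$ventricle_axes[2] * half))^2 +
             (Z / (g$ventricle_axes[3] * half))^2)
  ventricle <- ev <= 1
  intracranial <- R <= g$skull_frac * half
  cortex <- R <= g$cortex_frac * half & R > g$wm_frac * half
  wm_all <- R <= g$wm_frac * half & !ventricle

  bgc <- g$bg_center_frac * half
  bg_e <- function(cx) sqrt(((X - cx) / (g$bg_axes[1] * half))^2 +
                            (Y / (g$bg_axes[2] * half))^2 +
                            (Z / (g$bg_axes[3] * half))^2)
  bg <- wm_all & (bg_e(-bgc) <= 1 | bg_e(bgc) <= 1)
  wm <- wm_all & !bg

  # lobar wedges: angle in the anterior(y)/superior(z) plane
  phi <- atan2(Z, Y) * 180 / pi
  lobe <- ifelse(phi >= -45 & phi < 45, 1L,          # frontal
          ifelse(phi >= 45 & phi < 135, 2L,          # parietal
          ifelse(phi >= -135 & phi < -45, 3L, 4L)))  # temporal / occipital
  hemi <- ifelse(X < 0, 1L, 2L)                      # left / right
  lobar <- array(0L, dim = shape)
  lobar[wm] <- (2L * (lobe[wm] - 1L) + hemi[wm])
  lobar[bg] <- 9L

  structure(
    list(ventricle_mask = ventricle, cortex_mask = cortex, wm_mask = wm,
         lobar_labels = lobar, intracranial_mask = intracranial,
         spacing = spacing,
         etiv_mm3 = sum(intracranial) * voxel_volume(spacing),
         geometry = g, seed = as.integer(seed)),
    class = "phantom_brain"
  )
}

#' @export
print.phantom_brain <- function(x, ...) {
  cat("phantom_brain: ", paste(dim(x$wm_mask), collapse = "x"), " grid, ",
      "eTIV ", format(x$etiv_mm3, big.mark = ","), " mm^3\n",
      "  ventricle ", sum(x$ventricle_mask), " vox, wm ", sum(x$wm_mask),
      " vox, cortex ", sum(x$cortex_mask), " vox, BG ",
      sum(x$lobar_labels == 9L), " vox\n", sep = "")
  invisible(x)
}

#' Parcellate a phantom brain
#'
#' @param phantom a `phantom_brain`.
#' @return a `bullseye_map` (see [bullseye_parcellation()]).
#' @export
parcellate_phantom <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_brain"))
  bullseye_parcellation(phantom$ventricle_mask, phantom$cortex_mask,
                        phantom$wm_mask, phantom$lobar_labels, phantom$spacing)
}

#' Seed WMH lesions with exact per-parcel volumes
#'
#' Grows lesions voxel-by-voxel from random intra-parcel seed voxels
#' (6-connected growth with a randomly ordered frontier, new seeds when a
#' component is exhausted) so that the per-parcel lesion voxel counts match
#' the requested volumes exactly. This provides a round-trip oracle for
#' parcel volumetry: quantification must recover `targets` to the voxel.
#'
#' @param parcels a `bullseye_map`.
#' @param targets named numeric vector, mm^3 per parcel code (names are codes,
#'   e.g. `"11"`); each value must be a non-negative integer multiple of the
#'   voxel volume and at most the parcel's available volume.
#' @param spacing numeric length-3 in mm; defaults to the map's spacing.
#' @param seed integer RNG seed.
#' @return an object of class `lesion_ground_truth`: list with `lesion_mask`
#'   (3D logical), `per_parcel_mm3` (named, all 36 codes), `spacing`, `seed`.
#' @export
seed_wmh_lesions <- function(parcels, targets, spacing = parcels$spacing, seed = 1L) {
  stopifnot(inherits(parcels, "bullseye_map"))
  vv <- voxel_volume(spacing)
  codes <- parcel_codes()
  full <- setNames(numeric(36L), as.character(codes))
  if (length(targets)) {
    if (is.null(names(targets))) stop("targets must be named by parcel code")
    unknown <- setdiff(names(targets), names(full))
    if (length(unknown)) stop("unknown parcel code(s): ", paste(unknown, collapse = ", "))
    full[names(targets)] <- targets
  }
  if (any(full < 0)) stop("targets must be non-negative")
  nvox <- full / vv
  if (any(abs(nvox - round(nvox)) > 1e-6))
    stop("each target must be an integer multiple of the voxel volume (",
         format(vv), " mm^3)")
  nvox <- as.integer(round(nvox))

  vals <- parcels$values
  mask <- array(FALSE, dim = dim(vals))
  with_stream(seed, "lesions", {
    for (ci in seq_along(codes)) {
      n_target <- nvox[ci]
      if (n_target == 0L) next
      idx <- which(vals == codes[ci])
      if (length(idx) < n_target)
        stop("target for parcel ", codes[ci], " (", full[ci], " mm^3) exceeds ",
             "its capacity (", length(idx) * vv, " mm^3)")
      mask[grow_lesion(dim(vals), vals, codes[ci], idx, n_target)] <- TRUE
    }
  })
  got <- tabulate_parcels(vals, mask, vv)
  structure(
    list(lesion_mask = mask, per_parcel_mm3 = got, spacing = spacing,
         seed = as.integer(seed)),
    class = "lesion_ground_truth"
  )
}

## random 6-connected growth inside one parcel; returns selected linear indices
grow_lesion <- function(dims, vals, code, idx, n_target) {
  selected <- integer(0)
  in_lesion <- new.env(hash = TRUE, size = 2L * n_target)
  frontier <- integer(0)
  pool <- sample(idx)   # randomized fallback seeds
  pool_pos <- 1L
  strides <- c(1L, dims[1], dims[1] * dims[2])
  while (length(selected) < n_target) {
    if (length(frontier) == 0L) {
      while (pool_pos <= length(pool) &&
             !is.null(in_lesion[[as.character(pool[pool_pos])]]))
        pool_pos <- pool_pos + 1L
      frontier <- pool[pool_pos]
    }
    pick <- if (length(frontier) == 1L) 1L else sample.int(length(frontier), 1L)
    v <- frontier[pick]
    frontier <- frontier[-pick]
    key <- as.character(v)
    if (!is.null(in_lesion[[key]])) next
    in_lesion[[key]] <- TRUE
    selected <- c(selected, v)
    ijk <- arrayInd(v, dims)
    for (ax in 1:3) for (dlt in c(-1L, 1L)) {
      pos <- ijk[ax] + dlt
      if (pos < 1L || pos > dims[ax]) next
      nb <- v + dlt * strides[ax]
      if (vals[nb] == code && is.null(in_lesion[[as.character(nb)]]))
        frontier <- c(frontier, nb)
    }
  }
  selected
}

## internal: per-parcel lesion volumes (mm^3) over all 36 codes
tabulate_parcels <- function(vals, lesion, vox_vol) {
  codes <- parcel_codes()
  cnt <- table(factor(vals[as.logical(lesion)], levels = codes))
  setNames(as.numeric(cnt) * vox_vol, as.character(codes))
}
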