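## Bullseye parcellation of cerebral white matter.
##
## The coordinate system crosses two maps: (i) four concentric equidistant
## layers of normalized ventricle-to-cortex distance and (ii) nine lobar
## regions (four lobes x two hemispheres plus one bilateral basal-ganglia
## region). Their intersection yields 36 parcels covering exactly the white
## matter and basal ganglia.

REGION_NAMES <- c("frontal_L", "frontal_R", "parietal_L", "parietal_R",
                  "temporal_L", "temporal_R", "occipital_L", "occipital_R",
                  "basal_ganglia")

#' Encode a (region, layer) pair as a bullseye parcel code
#'
#' Codes are `region * 10 + layer`, a bijection onto
#' \{11..14, 21..24, ..., 91..94\}. Region order is fixed: frontal L/R,
#' parietal L/R, temporal L/R, occipital L/R, basal ganglia (bilateral).
#'
#' @param region integer in 1..9.
#' @param layer integer in 1..4 (1 periventricular .. 4 juxtacortical).
#' @return integer parcel code.
#' @seealso [parcel_decode()], [parcel_code_table()]
#' @export
#' @examples
#' parcel_code(1, 1)   # 11
#' parcel_decode(94)   # region 9, layer 4
parcel_code <- function(region, layer) {
  region <- as.integer(region); layer <- as.integer(layer)
  if (any(is.na(region)) || any(region < 1L | region > 9L))
    stop("region must be in 1..9")
  if (any(is.na(layer)) || any(layer < 1L | layer > 4L))
    stop("layer must be in 1..4")
  region * 10L + layer
}

#' @rdname parcel_code
#' @param code integer parcel code in the 11..94 scheme.
#' @export
parcel_decode <- function(code) {
  code <- as.integer(code)
  region <- code %/% 10L
  layer <- code %% 10L
  if (any(is.na(code)) || any(region < 1L | region > 9L | layer < 1L | layer > 4L))
    stop("invalid parcel code(s): ", paste(code, collapse = ", "))
  list(region = region, layer = layer)
}

#' Table of all 36 bullseye parcel codes
#'
#' @return a data.frame with columns `code`, `region`, `region_name`,
#'   `hemisphere` (`"L"`, `"R"` or `"both"`), `layer`, in fixed column order
#'   (region-major), matching the `p11..p94` CSV convention.
#' @export
parcel_code_table <- function() {
  region <- rep(1:9, each = 4L)
  layer <- rep(1:4, times = 9L)
  hemi <- c(rep(c("L", "R"), each = 4L, times = 4L), rep("both", 4L))
  data.frame(
    code = parcel_code(region, layer),
    region = region,
    region_name = REGION_NAMES[region],
    hemisphere = hemi,
    layer = layer,
    stringsAsFactors = FALSE
  )
}

#' All 36 parcel codes in canonical order
#' @return integer vector `c(11:14, 21:24, ..., 91:94)`.
#' @export
parcel_codes <- function() parcel_code_table()$code

#' Spacing-aware Euclidean distance transform of a binary mask
#'
#' Per-voxel exact Euclidean distance, in mm, to the nearest mask voxel
#' (voxel centers; anisotropic spacing honored). Zero on the mask itself.
#'
#' @param mask 3D logical/0-1 array; must contain at least one TRUE voxel.
#' @param spacing numeric length-3, mm per voxel along each axis.
#' @return 3D numeric array of distances in mm.
#' @export
distance_map <- function(mask, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(mask)) == 3L, length(spacing) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) stop("spacing must be positive")
  m <- as.logical(mask)
  if (!any(m)) stop("distance_map: mask is empty, distance undefined")
  d2 <- .edt_sq(m, dim(mask), as.double(spacing))
  array(sqrt(d2), dim = dim(mask))
}

#' Normalized ventricle-to-cortex distance map
#'
#' On each domain voxel i the value is
#' `dist_vent[i] / (dist_vent[i] + dist_cortex[i])`: 0 at the ventricular
#' surface, 1 at the cortical surface. Outside the domain the map is `NA`.
#'
#' @param dist_vent 3D array, distance to the ventricle mask (mm).
#' @param dist_cortex 3D array, distance to the cortex mask (mm).
#' @param domain 3D logical/0-1 array marking where the map is defined
#'   (white matter plus basal ganglia).
#' @return 3D numeric array in `[0, 1]` on the domain, `NA` elsewhere.
#' @export
normalized_distance <- function(dist_vent, dist_cortex, domain) {
  check_same_shape(dist_vent, dist_cortex, domain)
  dom <- as.logical(domain)
  tot <- dist_vent + dist_cortex
  bad <- dom & (tot <= 0)
  if (any(bad))
    stop("normalized_distance: ", sum(bad),
         " domain voxel(s) have zero distance to both ventricles and cortex; ",
         "masks overlap the domain inconsistently")
  out <- array(NA_real_, dim = dim(dist_vent))
  out[dom] <- dist_vent[dom] / tot[dom]
  out
}

#' Assign concentric equidistant layers from a normalized distance map
#'
#' Layers follow the fixed intervals `[0, 0.25)`, `[0.25, 0.5)`,
#' `[0.5, 0.75)`, `[0.75, 1]` (last interval closed), named 1 to 4 from the
#' ventricles out to the juxtacortical location.
#'
#' @param norm 3D numeric array in `[0, 1]` on its domain, `NA` elsewhere.
#' @return 3D integer array: layer 1..4 on the domain, 0 elsewhere.
#' @export
assign_layers <- function(norm) {
  dom <- !is.na(norm)
  v <- norm[dom]
  if (any(v < 0 | v > 1))
    stop("assign_layers: normalized distances outside [0, 1]")
  layer <- pmin(floor(v / 0.25) + 1, 4)  # value 1.0 folds into layer 4
  out <- array(0L, dim = dim(norm))
  out[dom] <- as.integer(layer)
  out
}

#' Intersect concentric layers with lobar regions into the bullseye map
#'
#' Every domain voxel gets code `region * 10 + layer`. Domain voxels without
#' a lobar label (real data: e.g. deep white matter the cortical projection
#' missed) are gap-filled with the nearest labeled region in mm, ties broken
#' by the lowest region code, so that the parcel voxels are conserved: the
#' nonzero-code count equals the domain count.
#'
#' @param layers 3D integer array, 1..4 on the domain (from [assign_layers()]).
#' @param lobar 3D integer array of lobar region codes 1..9 (0 = unlabeled).
#' @param domain 3D logical/0-1 array (white matter plus basal ganglia).
#' @param spacing numeric length-3 (mm), used by the nearest-region gap fill.
#' @return an object of class `bullseye_map`: list with `values` (3D integer
#'   array of parcel codes, 0 off-domain), `spacing`, `code_table`, and
#'   `n_gap_filled`.
#' @export
build_bullseye <- function(layers, lobar, domain, spacing = c(1, 1, 1)) {
  check_same_shape(layers, lobar, domain)
  dom <- as.logical(domain)
  vals <- array(0L, dim = dim(layers))
  if (any(dom)) {
    if (any(layers[dom] < 1L | layers[dom] > 4L))
      stop("build_bullseye: ", sum(layers[dom] < 1L | layers[dom] > 4L),
           " domain voxel(s) carry no layer assignment")
    lob <- fill_lobar_gaps(lobar, dom, spacing)
    n_gap <- sum(lobar[dom] == 0L)
    if (any(lob[dom] < 1L | lob[dom] > 9L))
      stop("build_bullseye: ", sum(lob[dom] < 1L | lob[dom] > 9L),
           " domain voxel(s) carry no lobar label after gap fill")
    vals[dom] <- lob[dom] * 10L + as.integer(layers[dom])
  } else n_gap <- 0L
  structure(
    list(values = vals, spacing = spacing, code_table = parcel_code_table(),
         n_gap_filled = as.integer(n_gap)),
    class = "bullseye_map"
  )
}

## Nearest-region gap fill: unlabeled domain voxels take the region of the
## nearest labeled voxel (mm distance, spacing-aware); distance ties go to
## the lowest region code. Implemented as one EDT per present region.
fill_lobar_gaps <- function(lobar, dom, spacing) {
  lob <- array(as.integer(lobar), dim = dim(lobar))
  gaps <- dom & (lob == 0L)
  if (!any(gaps)) return(lob)
  present <- sort(unique(lob[lob > 0L]))
  if (length(present) == 0L)
    stop("build_bullseye: domain has no lobar labels at all")
  gap_idx <- which(gaps)
  best_d <- rep(Inf, length(gap_idx))
  best_r <- rep(0L, length(gap_idx))
  for (r in present) {  # ascending => strict '<' keeps the lowest code on ties
    d <- .edt_sq(lob == r, dim(lob), as.double(spacing))[gap_idx]
    better <- d < best_d - 1e-9
    best_d[better] <- d[better]
    best_r[better] <- r
  }
  lob[gap_idx] <- best_r
  lob
}

#' Full bullseye parcellation from subject masks
#'
#' Convenience wrapper running the whole chain: distance transforms of the
#' ventricle and cortex masks, normalized distance, layer assignment, and
#' intersection with the lobar labels. The parcellation domain is
#' `(wm | lobar == 9) & !ventricle & !cortex`; white-matter voxels erroneously
#' overlapping the ventricle or cortex masks are excluded, and an overlap
#' beyond 0.1\% of the domain aborts.
#'
#' @param ventricle,cortex,wm 3D binary arrays.
#' @param lobar 3D integer array of lobar codes 1..9 (9 = basal ganglia).
#' @param spacing numeric length-3 in mm.
#' @return a `bullseye_map` (see [build_bullseye()]) with an extra element
#'   `normalized_distance`.
#' @export
bullseye_parcellation <- function(ventricle, cortex, wm, lobar, spacing = c(1, 1, 1)) {
  check_same_shape(ventricle, cortex, wm, lobar)
  vent <- as_mask(ventricle); ctx <- as_mask(cortex)
  domain_raw <- as_mask(wm) | (lobar == 9L)
  overlap <- domain_raw & (vent | ctx)
  dom <- domain_raw & !vent & !ctx
  if (sum(overlap) > 0.001 * max(sum(dom), 1L))
    stop("bullseye_parcellation: ", sum(overlap), " domain voxels overlap the ",
         "ventricle/cortex masks (> 0.1% of domain); inputs are inconsistent")
  dv <- distance_map(vent, spacing)
  dc <- distance_map(ctx, spacing)
  nd <- normalized_distance(dv, dc, dom)
  layers <- assign_layers(nd)
  bm <- build_bullseye(layers, lobar, dom, spacing)
  bm$normalized_distance <- nd
  bm
}

#' @export
print.bullseye_map <- function(x, ...) {
  n <- sum(x$values > 0L)
  codes <- sort(unique(x$values[x$values > 0L]))
  cat("bullseye_map: ", paste(dim(x$values), collapse = "x"),
      " grid, spacing ", paste(signif(x$spacing, 3), collapse = "x"), " mm\n",
      "  ", n, " parcellated voxels, ", length(codes), " distinct parcels",
      if (x$n_gap_filled > 0L) paste0(", ", x$n_gap_filled, " gap-filled"),
      "\n", sep = "")
  invisible(x)
}
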