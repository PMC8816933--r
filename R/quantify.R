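## Per-parcel WMH volumetry and table-level transforms.

#' Per-parcel WMH volumes from a bullseye map and a lesion mask
#'
#' @param parcels a `bullseye_map` or a 3D integer array of parcel codes.
#' @param wmh 3D binary lesion mask of the same shape.
#' @param spacing numeric length-3 in mm (defaults to the map's spacing).
#' @return list with `per_parcel_mm3` (named numeric over all 36 codes) and
#'   `unassigned_mm3` (lesion volume outside the parcellated domain, reported
#'   rather than silently dropped; a warning fires above 5\% of the lesion
#'   load).
#' @export
parcel_volumes <- function(parcels, wmh, spacing = NULL) {
  if (inherits(parcels, "bullseye_map")) {
    if (is.null(spacing)) spacing <- parcels$spacing
    vals <- parcels$values
  } else {
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    vals <- parcels
  }
  check_same_shape(vals, wmh)
  vv <- voxel_volume(spacing)
  lesion <- as.logical(wmh)
  per <- tabulate_parcels(vals, lesion, vv)
  unassigned <- sum(lesion & vals == 0L) * vv
  total <- sum(per) + unassigned
  if (total > 0 && unassigned > 0.05 * total)
    warning(sprintf("%.1f%% of WMH volume falls outside the parcellated domain",
                    100 * unassigned / total))
  list(per_parcel_mm3 = per, unassigned_mm3 = unassigned)
}

#' Build a parcel-volume table from a cohort data.frame
#'
#' @param cohort data.frame with `subject_id`, `etiv_mm3` and `p11..p94`
#'   columns (e.g. from [simulate_cohort()] or a quantification CSV).
#' @return a `parcel_volume_table`: the subset data.frame with bookkeeping
#'   attributes (`adjusted`, `logged`, `log_offset`, `etiv_mean`).
#' @export
parcel_table <- function(cohort) {
  pcols <- paste0("p", parcel_codes())
  missing_cols <- setdiff(c("subject_id", "etiv_mm3", pcols), names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  out <- cohort[, c("subject_id", "etiv_mm3", pcols)]
  if (any(out$etiv_mm3 <= 0)) stop("eTIV must be positive")
  if (any(as.matrix(out[, pcols]) < 0)) stop("parcel volumes must be non-negative")
  structure(out, adjusted = FALSE, logged = FALSE, log_offset = NA_real_,
            etiv_mean = NA_real_, class = c("parcel_volume_table", "data.frame"))
}

#' Head-size adjustment of parcel volumes
#'
#' Scales every subject's parcel volumes by `eTIV_mean / eTIV_i`, where
#' `eTIV_mean` is the arithmetic mean over the full loaded sample (computed
#' once, not per model subset). Zeros and within-subject parcel ratios are
#' preserved.
#'
#' @param table a `parcel_volume_table` (raw scale, not yet adjusted).
#' @return the adjusted table, with `adjusted = TRUE` and `etiv_mean` recorded.
#' @export
adjust_etiv <- function(table) {
  stopifnot(inherits(table, "parcel_volume_table"))
  if (isTRUE(attr(table, "adjusted"))) stop("table is already eTIV-adjusted")
  if (isTRUE(attr(table, "logged"))) stop("adjust before log transforming")
  if (any(table$etiv_mm3 <= 0)) stop("eTIV must be positive")
  etiv_mean <- mean(table$etiv_mm3)
  pcols <- paste0("p", parcel_codes())
  table[, pcols] <- table[, pcols] * (etiv_mean / table$etiv_mm3)
  attr(table, "adjusted") <- TRUE
  attr(table, "etiv_mean") <- etiv_mean
  table
}

#' Brain parenchymal fraction
#'
#' `BPF = supratentorial brain volume / eTIV * 100` (percent).
#'
#' @param supratentorial_mm3 supratentorial brain volume (gray + white), mm^3.
#' @param etiv_mm3 estimated total intracranial volume, mm^3.
#' @return BPF in percent.
#' @export
#' @examples
#' compute_bpf(1140000, 1500000)  # 76
compute_bpf <- function(supratentorial_mm3, etiv_mm3) {
  if (any(etiv_mm3 <= 0)) stop("eTIV must be positive")
  if (any(supratentorial_mm3 < 0)) stop("supratentorial volume must be non-negative")
  supratentorial_mm3 / etiv_mm3 * 100
}

#' Log-transform parcel volumes
#'
#' Applies `ln(volume + offset)` to every parcel column. The offset (default
#' 1 mm^3) makes the transform defined for the exact zeros that occur in
#' sparse parcels, and is recorded so the transform is invertible.
#'
#' @param table a `parcel_volume_table`.
#' @param offset additive offset in mm^3 (default 1).
#' @return the transformed table (`logged = TRUE`, `log_offset` recorded).
#' @export
log_transform <- function(table, offset = 1) {
  stopifnot(inherits(table, "parcel_volume_table"))
  if (isTRUE(attr(table, "logged"))) stop("table is already log-transformed")
  pcols <- paste0("p", parcel_codes())
  m <- as.matrix(table[, pcols])
  if (any(m < 0)) stop("negative volumes cannot be log-transformed")
  table[, pcols] <- log(m + offset)
  attr(table, "logged") <- TRUE
  attr(table, "log_offset") <- offset
  table
}

## sample skewness (method-of-moments)
skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

#' Descriptive summaries of the WMH distribution
#'
#' Computes, from raw (non-log) volumes: the proportion of each lobar
#' region's total WMH load falling in each of the 4 layers (rows sum to 1, or
#' are all 0 for an empty region), the per-parcel median volume, and the
#' per-parcel skewness across subjects.
#'
#' @param table a `parcel_volume_table` on the raw volume scale.
#' @return list with `layer_proportions` (9 x 4 matrix, regions x layers),
#'   `parcel_medians` and `parcel_skewness` (named 36-vectors, mm^3).
#' @export
summarize_distribution <- function(table) {
  stopifnot(inherits(table, "parcel_volume_table"))
  if (isTRUE(attr(table, "logged")))
    stop("summarize_distribution expects raw (non-log) volumes")
  ct <- parcel_code_table()
  pcols <- paste0("p", ct$code)
  m <- as.matrix(table[, pcols])
  totals <- colSums(m)
  prop <- matrix(0, 9L, 4L, dimnames = list(REGION_NAMES, paste0("layer", 1:4)))
  for (r in 1:9) {
    sel <- ct$region == r
    reg_tot <- sum(totals[sel])
    if (reg_tot > 0) prop[r, ct$layer[sel]] <- totals[sel] / reg_tot
  }
  list(
    layer_proportions = prop,
    parcel_medians = setNames(apply(m, 2L, median), pcols),
    parcel_skewness = setNames(apply(m, 2L, skewness), pcols)
  )
}
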