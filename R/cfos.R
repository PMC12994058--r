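#' Spot detection parameters
#'
#' @param smoothing_sigma Gaussian smoothing sigma in pixels (0 = off).
#' @param maxima_min_distance minimum distance between local maxima used
#'   as watershed seeds, in pixels.
#' @param intensity_threshold either a single absolute intensity, or a
#'   list `list(quantile = q)` for a per-image quantile threshold. In
#'   quantile mode a robust background guard (`median + 6 * mad` of the
#'   smoothed image) is also applied, so a signal-free image yields no
#'   objects.
#' @param min_object_area smallest object kept, in pixels.
#' @return an object of class `spot_params`; the threshold mode is
#'   recorded for the audit trail.
#' @export
spot_params <- function(smoothing_sigma = 2, maxima_min_distance = 5,
                        intensity_threshold = list(quantile = 0.99),
                        min_object_area = 9) {
  if (smoothing_sigma < 0 || maxima_min_distance < 0 || min_object_area < 0)
    stop("spot_params(): parameters must be >= 0")
  mode <- if (is.list(intensity_threshold)) "quantile" else "absolute"
  structure(list(smoothing_sigma = smoothing_sigma,
                 maxima_min_distance = maxima_min_distance,
                 intensity_threshold = intensity_threshold,
                 threshold_mode = mode,
                 min_object_area = min_object_area),
            class = "spot_params")
}

#' Detect nuclei in a single channel
#'
#' Gaussian smoothing, intensity thresholding, local-maxima seed detection
#' (minimum-distance constrained) and seeded watershed of the binary mask,
#' followed by a minimum-area filter. Fused nuclei with distinct intensity
#' maxima are split into separate labels.
#'
#' @param channel 2-D numeric matrix (x by y).
#' @param params a [spot_params()].
#' @return integer label matrix of the same shape (0 = background), with
#'   the labels renumbered consecutively.
#' @export
detect_nuclei <- function(channel, params = spot_params()) {
  stopifnot(is.matrix(channel))
  empty <- matrix(0L, nrow(channel), ncol(channel))
  if (length(channel) == 0L || all(channel == channel[1L])) return(empty)
  img <- EBImage::Image(channel)
  sm <- if (params$smoothing_sigma > 0)
    EBImage::gblur(img, sigma = params$smoothing_sigma) else img
  smd <- EBImage::imageData(sm)
  if (params$threshold_mode == "quantile") {
    q <- stats::quantile(smd, params$intensity_threshold$quantile)
    guard <- stats::median(smd) + 6 * stats::mad(smd)
    thr <- max(q, guard)
  } else thr <- params$intensity_threshold
  mask <- smd > thr
  if (!any(mask)) return(empty)
  ## local maxima under a minimum-distance constraint: a pixel is a seed if
  ## it attains the maximum of its (2d+1)-square neighbourhood; plateaus
  ## collapse to one seed through labelling of connected maxima
  d <- max(1L, round(params$maxima_min_distance))
  brush <- matrix(1, 2L * d + 1L, 2L * d + 1L)
  dil <- EBImage::imageData(EBImage::dilate(sm, brush))
  seeds <- (smd >= dil - 1e-12) & mask
  seed_lab <- EBImage::bwlabel(EBImage::Image(seeds + 0))
  if (max(seed_lab) == 0) return(empty)
  lab <- EBImage::propagate(sm, seed_lab, mask = EBImage::Image(mask + 0))
  lab <- EBImage::imageData(lab)
  areas <- tabulate(lab[lab > 0])
  drop <- which(areas > 0 & areas < params$min_object_area)
  if (length(drop)) lab[lab %in% drop] <- 0
  relabel(lab)
}

## renumber labels to 1..k
relabel <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (length(u)) out[lab > 0] <- match(lab[lab > 0], u)
  out
}

#' Count labelled objects
#'
#' @param mask integer label matrix.
#' @return number of distinct non-zero labels.
#' @export
n_objects <- function(mask) length(unique(mask[mask > 0]))

#' Per-pixel AND of two binary masks
#'
#' @param a,b matrices of the same shape; non-zero pixels count as
#'   foreground.
#' @return logical matrix.
#' @export
mask_and <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask_and(): shape mismatch")
  (a > 0) & (b > 0)
}

#' Combine nuclear and c-Fos masks
#'
#' Keeps a nuclear object iff the fraction of its footprint overlapping
#' the c-Fos mask (their per-pixel AND) exceeds `overlap_fraction`
#' (default: any overlap). Never increases the object count.
#'
#' @param nuclear_mask integer label matrix of detected nuclei.
#' @param cfos_mask binary or label matrix of c-Fos signal.
#' @param overlap_fraction minimum overlapping footprint fraction.
#' @return integer label matrix of c-Fos-positive nuclei (renumbered).
#' @export
combine_masks <- function(nuclear_mask, cfos_mask, overlap_fraction = 0) {
  both <- mask_and(nuclear_mask, cfos_mask)
  labs <- unique(nuclear_mask[nuclear_mask > 0])
  if (length(labs) == 0L) return(matrix(0L, nrow(nuclear_mask),
                                        ncol(nuclear_mask)))
  area <- tabulate(nuclear_mask[nuclear_mask > 0], nbins = max(labs))
  over <- tabulate(nuclear_mask[both], nbins = max(labs))
  keep <- labs[over[labs] / area[labs] > overlap_fraction |
                 (overlap_fraction == 0 & over[labs] > 0)]
  out <- nuclear_mask
  out[!(out %in% keep)] <- 0L
  relabel(out)
}

#' Count objects per region of interest
#'
#' Assigns each labelled object to the ROI containing its centroid and
#' reports counts and densities per square millimetre.
#'
#' @param mask integer label matrix of objects.
#' @param roi integer label matrix of regions (same shape; 0 = outside).
#' @param pixel_size_um pixel edge length in microns (> 0).
#' @param roi_names optional named character vector mapping ROI labels to
#'   region names.
#' @return data.frame with `roi`, `region`, `count`, `area_mm2`, `density`
#'   (one row per ROI label present in `roi`).
#' @export
count_in_roi <- function(mask, roi, pixel_size_um, roi_names = NULL) {
  if (!identical(dim(mask), dim(roi))) stop("count_in_roi(): shape mismatch")
  if (pixel_size_um <= 0) stop("count_in_roi(): pixel size must be > 0")
  roi_labels <- sort(unique(roi[roi > 0]))
  areas_px <- vapply(roi_labels, function(l) sum(roi == l), numeric(1))
  if (any(areas_px == 0)) stop("count_in_roi(): zero-area ROI")
  counts <- stats::setNames(rep(0L, length(roi_labels)), roi_labels)
  labs <- unique(mask[mask > 0])
  if (length(labs)) {
    idx <- which(mask > 0, arr.ind = TRUE)
    cx <- round(tapply(idx[, 1L], mask[mask > 0], mean))
    cy <- round(tapply(idx[, 2L], mask[mask > 0], mean))
    hit <- roi[cbind(cx, cy)]
    for (h in hit[hit > 0]) {
      k <- as.character(h)
      counts[k] <- counts[k] + 1L
    }
  }
  area_mm2 <- areas_px * (pixel_size_um / 1000)^2
  region <- if (is.null(roi_names)) as.character(roi_labels) else
    unname(roi_names[as.character(roi_labels)])
  data.frame(roi = roi_labels, region = region,
             count = as.integer(counts), area_mm2 = area_mm2,
             density = as.integer(counts) / area_mm2)
}

#' Median density over slices
#'
#' Per-animal regional densities are summarised as the median over the
#' (up to three) analysed slices; fewer than three slices is flagged.
#'
#' @param densities numeric vector of per-slice densities (>= 1).
#' @return list with `median`, `n_slices`, `flagged`.
#' @export
region_median <- function(densities) {
  densities <- densities[is.finite(densities)]
  if (length(densities) == 0L) stop("region_median(): no slice densities")
  list(median = stats::median(densities), n_slices = length(densities),
       flagged = length(densities) < 3L)
}

#' Regional activation scores
#'
#' Scores each animal's median c-Fos+ density per region 0-3 against the
#' control reference with one-sided higher-is-more-activated cuts at the
#' control median, 75th percentile and maximum, then sums paired regions
#' into 0-6 combined scores: BLA = BA + LA, CeA = CeL + CeM, and the
#' anterior + posterior dorsal and ventral PAG columns.
#'
#' @param densities data.frame with `animal_id`, `region`, `density`
#'   (median over slices), regions named `BA`, `LA`, `CeL`, `CeM`,
#'   `dPAG_ant`, `dPAG_post`, `vPAG_ant`, `vPAG_post`.
#' @param control_ids animal ids of the control reference (>= 4 per
#'   region).
#' @return list with `scores` (per animal x region) and `combined`
#'   (per animal: `BLA`, `CeA`, `dPAG`, `vPAG`).
#' @export
activation_scores <- function(densities, control_ids) {
  regions <- unique(densities$region)
  per <- lapply(regions, function(rg) {
    d <- densities[densities$region == rg, , drop = FALSE]
    ctrl <- d$density[d$animal_id %in% control_ids & is.finite(d$density)]
    if (length(ctrl) < 4L)
      stop("activation_scores(): undersampled controls for region ", rg)
    ts <- build_thresholds(list(variable = rg, rule = "CONTROL_PERCENTILE",
                                direction = "higher_is_worse"), ctrl)
    data.frame(animal_id = d$animal_id, region = rg,
               score = assign_score(d$density, ts))
  })
  scores <- do.call(rbind, per)
  wide <- stats::reshape(scores, idvar = "animal_id", timevar = "region",
                         direction = "wide")
  names(wide) <- sub("^score\\.", "", names(wide))
  comb <- function(a, b)
    if (all(c(a, b) %in% names(wide))) wide[[a]] + wide[[b]] else NA_integer_
  combined <- data.frame(animal_id = wide$animal_id,
                         BLA = comb("BA", "LA"),
                         CeA = comb("CeL", "CeM"),
                         dPAG = comb("dPAG_ant", "dPAG_post"),
                         vPAG = comb("vPAG_ant", "vPAG_post"))
  list(scores = scores, combined = combined)
}
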