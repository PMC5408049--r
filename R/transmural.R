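#' Myocardial wall band for transmural sampling
#'
#' An angular sector of the wall together with its endocardial and
#' epicardial border curves.  For the circular annulus geometry the borders
#' are radii about the annulus centre; when either radius is `NULL`,
#' [sample_profile()] detects the border along each sampling ray from the
#' map mask (first and last masked position), which also accommodates
#' mildly non-circular masks.
#'
#' @param center_mm annulus centre (x, y) in mm.
#' @param angle_start_deg,angle_end_deg angular span sampled (degrees,
#'   counter-clockwise from +x).
#' @param endo_radius_mm,epi_radius_mm border radii (mm), or `NULL` to
#'   detect from the mask.
#' @return an object of class `wall_band`.
#' @export
wall_band <- function(center_mm, angle_start_deg, angle_end_deg,
                      endo_radius_mm = NULL, epi_radius_mm = NULL) {
  stop_if_not(angle_end_deg > angle_start_deg,
              "`angle_end_deg` must exceed `angle_start_deg`")
  if (!is.null(endo_radius_mm) && !is.null(epi_radius_mm)) {
    stop_if_not(epi_radius_mm > endo_radius_mm && endo_radius_mm > 0,
                "need epi_radius_mm > endo_radius_mm > 0")
  }
  structure(
    list(center_mm = center_mm, angle_start_deg = angle_start_deg,
         angle_end_deg = angle_end_deg, endo_radius_mm = endo_radius_mm,
         epi_radius_mm = epi_radius_mm),
    class = "wall_band"
  )
}

# Detect endo/epi border radii along one ray from the mask, by marching at
# quarter-pixel resolution.
detect_borders <- function(mask2d, center_mm, theta_rad, pixel_mm) {
  r_max <- sqrt(sum((dim(mask2d) * pixel_mm)^2))
  rr <- seq(0, r_max, by = pixel_mm / 4)
  xs <- center_mm[1] + rr * cos(theta_rad)
  ys <- center_mm[2] + rr * sin(theta_rad)
  nx <- nrow(mask2d); ny <- ncol(mask2d)
  ix <- round(xs / pixel_mm + 0.5); iy <- round(ys / pixel_mm + 0.5)
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  inside <- rep(FALSE, length(rr))
  inside[ok] <- mask2d[cbind(ix[ok], iy[ok])]
  if (!any(inside)) return(NULL)
  c(endo = rr[which(inside)[1]], epi = rr[rev(which(inside))[1]])
}

#' Transmural MBF profile by perpendicular line sampling
#'
#' Takes linear samples perpendicular to the myocardial surface (along the
#' local radial direction of the annulus) at equal depth intervals across
#' the wall, one line per `line_step_deg` degrees of the band, and projects
#' the mean MBF of the sampled points at each depth into the transmural
#' profile curve.  Sampling is sub-pixel by bilinear interpolation.
#'
#' @param map an `mbf_map`.
#' @param band a [wall_band()].
#' @param slice slice index.
#' @param step_mm depth sampling interval (mm), default 0.4.
#' @param line_step_deg angular spacing of the sample lines (degrees).
#' @return an object of class `transmural_profile` with `depths_mm`
#'   (0 at the endocardial border, increasing toward the epicardium),
#'   `mean_mbf`, `step_mm`, `n_lines`, `slice_index`, `wall_thickness_mm`.
#' @export
sample_profile <- function(map, band, slice = 1, step_mm = 0.4,
                           line_step_deg = 1) {
  stopifnot(inherits(map, "mbf_map"), inherits(band, "wall_band"))
  img <- map$mbf[, , slice]
  mask2d <- map$mask[, , slice]
  angles <- seq(band$angle_start_deg, band$angle_end_deg - line_step_deg / 2,
                by = line_step_deg) * pi / 180
  stop_if_not(length(angles) >= 1, "the band spans no sample lines")

  if (is.null(band$endo_radius_mm) || is.null(band$epi_radius_mm)) {
    borders <- lapply(angles, function(th) {
      detect_borders(mask2d, band$center_mm, th, map$pixel_mm)
    })
    keep <- !vapply(borders, is.null, TRUE)
    stop_if_not(any(keep), "the band lies outside the map mask")
    angles <- angles[keep]; borders <- borders[keep]
    endo_r <- vapply(borders, `[[`, 0, "endo")
    epi_r <- vapply(borders, `[[`, 0, "epi")
  } else {
    endo_r <- rep(band$endo_radius_mm, length(angles))
    epi_r <- rep(band$epi_radius_mm, length(angles))
  }
  thickness <- min(epi_r - endo_r)
  stop_if_not(thickness >= 2 * step_mm,
              "wall thinner than two depth steps; cannot profile")
  depths <- seq(0, thickness, by = step_mm)

  prof <- vapply(depths, function(d) {
    xs <- band$center_mm[1] + (endo_r + d) * cos(angles)
    ys <- band$center_mm[2] + (endo_r + d) * sin(angles)
    mean(bilinear_interp(img, xs, ys, map$pixel_mm), na.rm = TRUE)
  }, 0)
  stop_if_not(all(is.finite(prof)),
              "profile contains non-finite depths; band outside the mask")

  structure(
    list(depths_mm = depths, mean_mbf = prof, step_mm = step_mm,
         n_lines = length(angles), slice_index = slice,
         wall_thickness_mm = thickness),
    class = "transmural_profile"
  )
}

#' @export
print.transmural_profile <- function(x, ...) {
  cat(sprintf(
    "Transmural MBF profile: %d depths @ %.1f mm over a %.1f mm wall (%d lines)\n",
    length(x$depths_mm), x$step_mm, x$wall_thickness_mm, x$n_lines))
  cat(sprintf("  endocardial end %.1f, epicardial end %.1f ml/100 ml/min\n",
              x$mean_mbf[1], x$mean_mbf[length(x$mean_mbf)]))
  invisible(x)
}

#' @export
plot.transmural_profile <- function(x, ...) {
  plot(x$depths_mm, x$mean_mbf, type = "b", pch = 19,
       xlab = "depth from endocardial border (mm)",
       ylab = "mean MBF (ml/100 ml/min)", main = "Transmural MBF profile",
       ...)
  invisible(x)
}

#' Select subendocardial and subepicardial MBF from a profile
#'
#' Manual mode returns the profile values (linearly interpolated) at two
#' user-supplied depths, mirroring reader selection of the endocardial and
#' epicardial positions on the profile curve.  Auto mode averages the
#' profile over an inner band at 10--35 % and an outer band at 65--90 % of
#' wall depth; the excluded 10 % margins keep the samples away from the LV
#' lumen and the epicardial border, where displacement artefacts make
#' absolute values unreliable.
#'
#' @param profile a `transmural_profile`.
#' @param mode `"auto"` or `"manual"`.
#' @param manual_depths length-2 depths (mm) for manual mode,
#'   endocardial first.
#' @param bands list with `endo` and `epi` depth-fraction intervals for
#'   auto mode.
#' @return an object of class `tpr_measurement` with `endo_mbf`, `epi_mbf`,
#'   `tpr`, `endo_depth_mm`, `epi_depth_mm`, `selection_mode`.
#' @export
select_endo_epi <- function(profile, mode = c("auto", "manual"),
                            manual_depths = NULL,
                            bands = list(endo = c(0.10, 0.35),
                                         epi = c(0.65, 0.90))) {
  stopifnot(inherits(profile, "transmural_profile"))
  mode <- match.arg(mode)
  d <- profile$depths_mm; v <- profile$mean_mbf
  if (mode == "manual") {
    stop_if_not(length(manual_depths) == 2,
                "`manual_depths` must give two depths (endo, epi)")
    stop_if_not(all(manual_depths >= min(d) & manual_depths <= max(d)),
                "manual depths outside the profile range")
    stop_if_not(manual_depths[1] < manual_depths[2],
                "the endocardial depth must be shallower than the epicardial")
    vv <- stats::approx(d, v, xout = manual_depths)$y
    endo_mbf <- vv[1]; epi_mbf <- vv[2]
    endo_depth <- manual_depths[1]; epi_depth <- manual_depths[2]
  } else {
    frac <- d / profile$wall_thickness_mm
    in_endo <- frac >= bands$endo[1] & frac <= bands$endo[2]
    in_epi <- frac >= bands$epi[1] & frac <= bands$epi[2]
    stop_if_not(any(in_endo) && any(in_epi),
                "profile too short to place the auto selection bands")
    endo_mbf <- mean(v[in_endo]); epi_mbf <- mean(v[in_epi])
    endo_depth <- mean(d[in_endo]); epi_depth <- mean(d[in_epi])
  }
  structure(
    list(endo_mbf = endo_mbf, epi_mbf = epi_mbf,
         tpr = compute_tpr(endo_mbf, epi_mbf),
         endo_depth_mm = endo_depth, epi_depth_mm = epi_depth,
         selection_mode = mode),
    class = "tpr_measurement"
  )
}

#' @export
print.tpr_measurement <- function(x, ...) {
  cat(sprintf(
    "TPR %.2f (subendocardial %.1f / subepicardial %.1f ml/100 ml/min, %s selection)\n",
    x$tpr, x$endo_mbf, x$epi_mbf, x$selection_mode))
  invisible(x)
}

#' Transmural perfusion ratio
#'
#' The ratio of the subendocardial to the subepicardial myocardial blood
#' flow.  A TPR well below 1 indicates relative subendocardial
#' hypoperfusion.
#'
#' @param endo_mbf subendocardial MBF (ml/100 ml/min).
#' @param epi_mbf subepicardial MBF (ml/100 ml/min), must be > 0.
#' @return dimensionless ratio `endo_mbf / epi_mbf`.
#' @export
#' @examples
#' compute_tpr(58, 91)  # 0.64 to two decimals
compute_tpr <- function(endo_mbf, epi_mbf) {
  stop_if_not(all(is.finite(endo_mbf)) && all(is.finite(epi_mbf)),
              "MBF values must be finite")
  stop_if_not(all(epi_mbf > 0), "`epi_mbf` must be positive")
  endo_mbf / epi_mbf
}

#' Classify territories against the diagnostic thresholds
#'
#' Applies the inclusive diagnostic thresholds to a territory table:
#' a territory is MBF-positive when `mbf <= mbf_threshold`, TPR-positive
#' when `tpr <= tpr_threshold`, and the reference is positive when
#' `ffr <= ffr_threshold`.  Rows with a missing measurement are excluded
#' with a message.
#'
#' @param records data.frame with columns `patient_id`, `territory`, `mbf`,
#'   `tpr`, `ffr`.
#' @param mbf_threshold MBF cut-off (ml/100 ml/min), default 76.
#' @param tpr_threshold TPR cut-off, default 0.82.
#' @param ffr_threshold FFR cut-off for haemodynamic significance,
#'   default 0.80.
#' @return the records with logical columns `ischaemic`, `mbf_positive`,
#'   `tpr_positive` and `concordant` (MBF and TPR classifications agree)
#'   appended; excluded rows dropped.
#' @export
classify_territory <- function(records, mbf_threshold = 76,
                               tpr_threshold = 0.82, ffr_threshold = 0.80) {
  stop_if_not(all(c("patient_id", "mbf", "tpr", "ffr") %in% names(records)),
              "`records` needs columns patient_id, mbf, tpr, ffr")
  stop_if_not(mbf_threshold > 0 && tpr_threshold > 0,
              "thresholds must be positive")
  miss <- !stats::complete.cases(records[, c("mbf", "tpr", "ffr")])
  if (any(miss)) {
    message(sum(miss), " territory(ies) excluded for missing measurements")
    records <- records[!miss, , drop = FALSE]
  }
  records$ischaemic <- records$ffr <= ffr_threshold
  records$mbf_positive <- records$mbf <= mbf_threshold
  records$tpr_positive <- records$tpr <= tpr_threshold
  records$concordant <- records$mbf_positive == records$tpr_positive
  records
}
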