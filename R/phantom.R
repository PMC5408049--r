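#' Myocardial sector specification
#'
#' One angular sector of the short-axis left-ventricular annulus, mapped to a
#' coronary territory with its reference fractional flow reserve (FFR).
#' Angles are in degrees, measured counter-clockwise from the positive
#' x-axis; a voxel belongs to the sector when its angle lies in
#' `[angle_start_deg, angle_end_deg)`.
#'
#' @param angle_start_deg,angle_end_deg angular span (degrees in [0, 360]).
#' @param mbf_epi true subepicardial blood flow (ml/100 ml/min), > 0.
#' @param transmural_ratio true subendocardial / subepicardial flow ratio,
#'   > 0; 1 means transmurally uniform flow.
#' @param territory_label coronary territory: `"LAD"`, `"LCX"` or `"RCA"`.
#' @param reference_ffr invasive FFR reference in (0, 1].
#' @return an object of class `sector_spec`.
#' @export
sector_spec <- function(angle_start_deg, angle_end_deg, mbf_epi,
                        transmural_ratio = 1,
                        territory_label = c("LAD", "LCX", "RCA"),
                        reference_ffr = 0.9) {
  territory_label <- match.arg(territory_label)
  stop_if_not(mbf_epi > 0, "`mbf_epi` must be positive")
  stop_if_not(transmural_ratio > 0, "`transmural_ratio` must be positive")
  stop_if_not(reference_ffr > 0 && reference_ffr <= 1,
              "`reference_ffr` must lie in (0, 1]")
  stop_if_not(angle_end_deg > angle_start_deg,
              "`angle_end_deg` must exceed `angle_start_deg`")
  structure(
    list(angle_start_deg = angle_start_deg, angle_end_deg = angle_end_deg,
         mbf_epi = mbf_epi, transmural_ratio = transmural_ratio,
         territory_label = territory_label, reference_ffr = reference_ffr),
    class = "sector_spec"
  )
}

#' Default three-territory sector layout
#'
#' A schematic LAD / LCX / RCA partition of the annulus with one ischaemic
#' territory: the LAD carries a subendocardial defect with epicardial flow
#' 91 ml/100 ml/min and transmural ratio 0.64 (so a 58 ml/100 ml/min
#' subendocardium) behind an FFR of 0.69, while LCX and RCA are normal
#' territories with near-uniform flow around 92 ml/100 ml/min.
#'
#' @return list of three [sector_spec()] objects spanning [0, 360).
#' @export
default_sectors <- function() {
  list(
    sector_spec(0, 120, mbf_epi = 91, transmural_ratio = 0.64,
                territory_label = "LAD", reference_ffr = 0.69),
    sector_spec(120, 240, mbf_epi = 92, transmural_ratio = 0.95,
                territory_label = "LCX", reference_ffr = 0.85),
    sector_spec(240, 360, mbf_epi = 92, transmural_ratio = 0.95,
                territory_label = "RCA", reference_ffr = 0.91)
  )
}

#' Digital perfusion phantom specification
#'
#' Describes a short-axis left-ventricular annulus imaged in shuttle mode:
#' two overlapping slice stacks (cranial / caudal) acquired at alternating
#' table positions, each sampled once every second heartbeat.  Tissue
#' enhancement follows the flow-scaled convolution of the gamma-variate AIF
#' with a plug-flow (box) impulse-residue function; the aorta region follows
#' the AIF itself; i.i.d. Gaussian attenuation noise is added everywhere.
#'
#' The transmural flow pattern within each sector interpolates from
#' `transmural_ratio * mbf_epi` at the endocardial border to `mbf_epi` at the
#' epicardial border.  With `transmural_shape = "step"` (default) the two
#' plateaus are joined by a linear ramp over the central 40--60 % of wall
#' depth, so the generated transmural ratio is exactly the ratio of the
#' subendocardial to subepicardial plateau; `"linear"` gives a straight
#' transmural gradient.
#'
#' @param grid_nx,grid_ny in-plane grid size in pixels.
#' @param pixel_mm pixel size (mm), default 0.35.
#' @param n_slices number of slices (split between the two stacks).
#' @param slice_thickness_mm slice thickness (mm), default 3.
#' @param lv_center LV centre (mm, mm); default grid centre.
#' @param endo_radius_mm,epi_radius_mm endocardial / epicardial radii (mm).
#' @param sectors list of [sector_spec()] partitioning [0, 360).
#' @param baseline_hu pre-contrast tissue attenuation (HU).
#' @param noise_sd_hu Gaussian attenuation noise SD (HU).
#' @param heart_rate_bpm heart rate; each stack is sampled every second beat.
#' @param n_timepoints acquisitions per stack, in [9, 14].
#' @param aif_params true arterial input, an [aif_params()] object.
#' @param aorta_center descending-aorta centre (mm, mm); default placed
#'   10 mm outside the epicardial border along +x.
#' @param aorta_radius_mm aorta disk radius (mm).
#' @param transit_time_s tissue transit time of the box residue (s).
#' @param transmural_shape `"step"` or `"linear"` (see Details).
#' @param seed integer seed governing all noise draws.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_nx = 256, grid_ny = 256, pixel_mm = 0.35,
                         n_slices = 2, slice_thickness_mm = 3,
                         lv_center = NULL, endo_radius_mm = 20,
                         epi_radius_mm = 30, sectors = default_sectors(),
                         baseline_hu = 75, noise_sd_hu = 10,
                         heart_rate_bpm = 83, n_timepoints = 12,
                         aif_params = ctmpi::aif_params(),
                         aorta_center = NULL, aorta_radius_mm = 3,
                         transit_time_s = 8,
                         transmural_shape = c("step", "linear"), seed = 1L) {
  transmural_shape <- match.arg(transmural_shape)
  stop_if_not(epi_radius_mm > endo_radius_mm && endo_radius_mm > 0,
              "need epi_radius_mm > endo_radius_mm > 0")
  stop_if_not(n_timepoints >= 9 && n_timepoints <= 14,
              "`n_timepoints` must lie in [9, 14]")
  stop_if_not(length(sectors) > 0, "`sectors` must not be empty")
  stop_if_not(all(vapply(sectors, inherits, TRUE, "sector_spec")),
              "`sectors` must be a list of sector_spec objects")
  starts <- vapply(sectors, `[[`, 0, "angle_start_deg")
  ends <- vapply(sectors, `[[`, 0, "angle_end_deg")
  ord <- order(starts)
  ok <- isTRUE(all.equal(starts[ord][1], 0)) &&
    isTRUE(all.equal(ends[ord][length(ord)], 360)) &&
    (length(ord) == 1 ||
       isTRUE(all.equal(ends[ord][-length(ord)], starts[ord][-1])))
  stop_if_not(ok, "sector angular spans must partition [0, 360) exactly")
  if (is.null(lv_center)) {
    lv_center <- c(grid_nx, grid_ny) * pixel_mm / 2
  }
  if (is.null(aorta_center)) {
    aorta_center <- lv_center + c(epi_radius_mm + 10, 0)
  }
  ext <- c(grid_nx, grid_ny) * pixel_mm
  stop_if_not(all(lv_center - epi_radius_mm >= 0) &&
                all(lv_center + epi_radius_mm <= ext),
              "the annulus exceeds the grid bounds")
  stop_if_not(all(aorta_center - aorta_radius_mm >= 0) &&
                all(aorta_center + aorta_radius_mm <= ext),
              "the aorta disk exceeds the grid bounds")
  stop_if_not(sqrt(sum((aorta_center - lv_center)^2)) >
                epi_radius_mm + aorta_radius_mm,
              "the aorta disk overlaps the annulus")
  stopifnot(inherits(aif_params, "aif_params"))
  structure(
    list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
         pixel_mm = pixel_mm, n_slices = as.integer(n_slices),
         slice_thickness_mm = slice_thickness_mm, lv_center = lv_center,
         endo_radius_mm = endo_radius_mm, epi_radius_mm = epi_radius_mm,
         sectors = sectors, baseline_hu = baseline_hu,
         noise_sd_hu = noise_sd_hu, heart_rate_bpm = heart_rate_bpm,
         n_timepoints = as.integer(n_timepoints), aif_params = aif_params,
         aorta_center = aorta_center, aorta_radius_mm = aorta_radius_mm,
         transit_time_s = transit_time_s, transmural_shape = transmural_shape,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Dynamic perfusion phantom specification\n")
  cat(sprintf("  grid      : %d x %d px @ %.2f mm, %d slice(s)\n",
              x$grid_nx, x$grid_ny, x$pixel_mm, x$n_slices))
  cat(sprintf("  annulus   : endo %.1f mm, epi %.1f mm (wall %.1f mm)\n",
              x$endo_radius_mm, x$epi_radius_mm,
              x$epi_radius_mm - x$endo_radius_mm))
  cat(sprintf("  shuttle   : %d time points per stack @ %.0f bpm\n",
              x$n_timepoints, x$heart_rate_bpm))
  cat(sprintf("  noise     : %.1f HU; seed %d\n", x$noise_sd_hu, x$seed))
  for (s in x$sectors) {
    cat(sprintf("  sector %s: [%3.0f, %3.0f) deg, epi %.0f, ratio %.2f, FFR %.2f\n",
                s$territory_label, s$angle_start_deg, s$angle_end_deg,
                s$mbf_epi, s$transmural_ratio, s$reference_ffr))
  }
  invisible(x)
}

#' Shuttle-mode acquisition time grid
#'
#' Each table position (stack) is revisited every second heartbeat, so the
#' per-stack sampling period is `2 * 60 / heart_rate_bpm` seconds; the caudal
#' stack is offset by one beat.  Acquisition starts 5 s after the start of
#' contrast injection.
#'
#' @param spec a [phantom_spec()].
#' @return a 2 x n_timepoints matrix of times (s), rows `cranial`, `caudal`.
#' @export
shuttle_times <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  period <- 2 * 60 / spec$heart_rate_bpm
  k <- seq_len(spec$n_timepoints) - 1
  rbind(cranial = 5 + k * period,
        caudal = 5 + period / 2 + k * period)
}

# Transmural flow shape s(depth_frac) in [ratio, 1]; depth_frac = 0 at the
# endocardial border, 1 at the epicardial border.
transmural_shape_fn <- function(depth_frac, ratio, shape) {
  if (shape == "linear") {
    ratio + (1 - ratio) * depth_frac
  } else {
    ramp <- pmin(pmax((depth_frac - 0.4) / 0.2, 0), 1)
    ratio + (1 - ratio) * ramp
  }
}

#' Noiseless tissue enhancement curve
#'
#' Forward model of myocardial enhancement: the AIF enhancement above
#' baseline convolved with a flow-scaled plug-flow (box) impulse-residue
#' function of duration `transit_time_s`, delayed by `delay_s`, on top of the
#' tissue baseline.  Flow in ml/100 ml/min converts to the per-second rate
#' constant by division by 6000 (100 ml basis times 60 s/min), so
#' \deqn{C(t) = b_{tis} + \frac{\mathrm{MBF}}{6000}
#'       \left[G(t - d) - G(t - d - T)\right]}
#' with `G` from [aif_integral()].
#'
#' @param true_mbf flow (ml/100 ml/min), >= 0.
#' @param aif an [aif_params()] object (the true arterial input).
#' @param t time(s) in seconds.
#' @param transit_time_s box residue duration (s), > 0.
#' @param delay_s arterial-to-tissue delay (s), >= 0.
#' @param baseline_hu tissue pre-contrast attenuation (HU).
#' @return attenuation (HU), same length as `t`.
#' @export
tissue_curve <- function(true_mbf, aif, t, transit_time_s = 8, delay_s = 0,
                         baseline_hu = 75) {
  stop_if_not(is.finite(true_mbf) && true_mbf >= 0,
              "`true_mbf` must be non-negative")
  stop_if_not(transit_time_s > 0, "`transit_time_s` must be positive")
  stop_if_not(delay_s >= 0, "`delay_s` must be non-negative")
  f <- true_mbf / 6000
  baseline_hu +
    f * (aif_integral(aif, t - delay_s) -
           aif_integral(aif, t - delay_s - transit_time_s))
}

#' Generate a synthetic dynamic perfusion series with ground truth
#'
#' Builds the annulus and aorta geometry from a [phantom_spec()], assigns
#' every annulus voxel its true flow from the sector layout and transmural
#' shape, renders noiseless voxel time-attenuation curves at the shuttle time
#' grid of the voxel's stack, adds seeded Gaussian noise, and returns the
#' series together with the exact ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `ctmpi_phantom` with elements:
#' \describe{
#'   \item{series}{`perfusion_series`: `volumes` (nx, ny, nz, nt) in HU,
#'     `times_s` (2 x nt matrix), `stack_of_slice`, `pixel_mm`,
#'     `slice_thickness_mm`, `aif_mask`.}
#'   \item{truth}{`phantom_truth`: `true_mbf` (nx, ny, nz), `sector_of_voxel`
#'     (integer codes, 0 outside the annulus), `sector_table` (per-sector
#'     truth incl. the by-construction transmural perfusion ratio of
#'     endocardial-half over epicardial-half mean flow), `true_aif`,
#'     `depth_frac`, and the spec echo.}
#' }
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$grid_nx; ny <- spec$grid_ny; nz <- spec$n_slices
  nt <- spec$n_timepoints
  cc <- pixel_centres(nx, ny, spec$pixel_mm)
  xg <- matrix(cc$x, nx, ny)
  yg <- matrix(cc$y, nx, ny, byrow = TRUE)
  dx <- xg - spec$lv_center[1]
  dy <- yg - spec$lv_center[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  annulus <- r >= spec$endo_radius_mm & r < spec$epi_radius_mm
  depth_frac <- matrix(NA_real_, nx, ny)
  depth_frac[annulus] <- (r[annulus] - spec$endo_radius_mm) /
    (spec$epi_radius_mm - spec$endo_radius_mm)

  sector_id <- matrix(0L, nx, ny)
  true_mbf2d <- matrix(NA_real_, nx, ny)
  for (i in seq_along(spec$sectors)) {
    s <- spec$sectors[[i]]
    inside <- annulus & ang >= s$angle_start_deg & ang < s$angle_end_deg
    sector_id[inside] <- i
    true_mbf2d[inside] <- s$mbf_epi *
      transmural_shape_fn(depth_frac[inside], s$transmural_ratio,
                          spec$transmural_shape)
  }

  da <- sqrt((xg - spec$aorta_center[1])^2 + (yg - spec$aorta_center[2])^2)
  aorta2d <- da < spec$aorta_radius_mm
  stop_if_not(any(aorta2d), "the aorta disk contains no voxels")

  times <- shuttle_times(spec)
  stack_of_slice <- rep(c("cranial", "caudal"), length.out = nz)
  if (nz == 1) stack_of_slice <- "cranial"

  kernel <- function(t) {
    aif_integral(spec$aif_params, t) -
      aif_integral(spec$aif_params, t - spec$transit_time_s)
  }

  set.seed(spec$seed)
  volumes <- array(NA_real_, dim = c(nx, ny, nz, nt))
  for (z in seq_len(nz)) {
    tz <- times[stack_of_slice[z], ]
    K <- kernel(tz)
    plane <- matrix(spec$baseline_hu, nx, ny)
    for (k in seq_len(nt)) {
      frame <- plane
      frame[annulus] <- spec$baseline_hu + true_mbf2d[annulus] / 6000 * K[k]
      frame[aorta2d] <- aif_curve(spec$aif_params, tz[k])
      volumes[, , z, k] <- frame
    }
  }
  if (spec$noise_sd_hu > 0) {
    volumes <- volumes + array(stats::rnorm(length(volumes), 0,
                                            spec$noise_sd_hu), dim(volumes))
  }

  true_mbf <- array(rep(true_mbf2d, nz), dim = c(nx, ny, nz))
  sector_of_voxel <- array(rep(sector_id, nz), dim = c(nx, ny, nz))
  aif_mask <- array(rep(aorta2d, nz), dim = c(nx, ny, nz))

  sector_table <- do.call(rbind, lapply(seq_along(spec$sectors), function(i) {
    s <- spec$sectors[[i]]
    sel <- sector_id == i
    endo_half <- sel & depth_frac < 0.5
    epi_half <- sel & depth_frac >= 0.5
    data.frame(
      sector = i, territory = s$territory_label,
      mbf_epi = s$mbf_epi, transmural_ratio = s$transmural_ratio,
      reference_ffr = s$reference_ffr,
      true_mean_mbf = mean(true_mbf2d[sel]),
      true_tpr = mean(true_mbf2d[endo_half]) / mean(true_mbf2d[epi_half]),
      stringsAsFactors = FALSE
    )
  }))

  series <- structure(
    list(volumes = volumes, times_s = times, stack_of_slice = stack_of_slice,
         pixel_mm = spec$pixel_mm,
         slice_thickness_mm = spec$slice_thickness_mm, aif_mask = aif_mask),
    class = "perfusion_series"
  )
  truth <- structure(
    list(true_mbf = true_mbf, sector_of_voxel = sector_of_voxel,
         sector_table = sector_table, true_aif = spec$aif_params,
         depth_frac = array(rep(depth_frac, nz), dim = c(nx, ny, nz)),
         spec = spec),
    class = "phantom_truth"
  )
  structure(list(series = series, truth = truth), class = "ctmpi_phantom")
}

#' Simulate dynamic series from a phantom specification
#'
#' `simulate()` method: draws `nsim` independent phantom realisations,
#' re-seeding the generator for each draw.
#'
#' @param object a [phantom_spec()].
#' @param nsim number of realisations.
#' @param seed base seed; realisation `i` uses `seed + i - 1`. Defaults to
#'   the spec's own seed.
#' @param ... unused.
#' @return a list of `ctmpi_phantom` objects (length `nsim`).
#' @export
simulate.phantom_spec <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$seed
  lapply(seq_len(nsim), function(i) {
    sp <- object
    sp$seed <- as.integer(seed + i - 1)
    generate_phantom(sp)
  })
}

#' @export
print.perfusion_series <- function(x, ...) {
  dm <- dim(x$volumes)
  cat(sprintf("Dynamic perfusion series: %d x %d x %d voxels, %d time points/stack\n",
              dm[1], dm[2], dm[3], dm[4]))
  cat(sprintf("  pixel %.2f mm, slices %.1f mm (%s)\n", x$pixel_mm,
              x$slice_thickness_mm, paste(x$stack_of_slice, collapse = ", ")))
  cat(sprintf("  acquisition window %.1f - %.1f s\n", min(x$times_s),
              max(x$times_s)))
  invisible(x)
}

#' @export
print.ctmpi_phantom <- function(x, ...) {
  print(x$series)
  cat("Ground truth sectors:\n")
  print(x$truth$sector_table, row.names = FALSE)
  invisible(x)
}
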