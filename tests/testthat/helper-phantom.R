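# Desk-scale phantom geometry used throughout the suite: a 22.4 mm field
# (64 px at 0.35 mm) with a 5-9 mm annulus and a small aorta disk in the
# corner.  Everything else keeps the package defaults.
small_spec <- function(...) {
  args <- list(...)
  base <- list(grid_nx = 64, grid_ny = 64, endo_radius_mm = 5,
               epi_radius_mm = 9, aorta_center = c(19.5, 3.5),
               aorta_radius_mm = 2, n_slices = 1, noise_sd_hu = 0, seed = 1L)
  base[names(args)] <- args
  do.call(phantom_spec, base)
}

# Uniform-flow sector layout (three territories, same flow and ratio).
uniform_sectors <- function(mbf_epi, ratio = 1) {
  list(
    sector_spec(0, 120, mbf_epi, ratio, "LAD", 0.69),
    sector_spec(120, 240, mbf_epi, ratio, "LCX", 0.85),
    sector_spec(240, 360, mbf_epi, ratio, "RCA", 0.91)
  )
}

# Wrap a 2-D value matrix as an mbf_map, for tests that probe the profile
# and ROI machinery without running the estimator.
synthetic_map <- function(values, pixel_mm = 0.35, mask = NULL) {
  dm <- dim(values)
  if (is.null(mask)) mask <- !is.na(values)
  structure(
    list(mbf = array(values, c(dm, 1)), mask = array(mask, c(dm, 1)),
         converged = array(TRUE, c(dm, 1)), transit_s = NULL, delay_s = NULL,
         pixel_mm = pixel_mm, slice_thickness_mm = 3,
         slice_increment_mm = 1.5),
    class = "mbf_map"
  )
}

# Radial step-profile annulus image on an (n x n) grid: value r * peak on
# the endocardial plateau, peak on the epicardial plateau, NA outside.
annulus_image <- function(n = 128, pixel_mm = 0.35, endo = 10, epi = 20,
                          peak = 91, ratio = 0.64) {
  cx <- n * pixel_mm / 2
  x <- matrix((seq_len(n) - 0.5) * pixel_mm, n, n)
  y <- t(x)
  r <- sqrt((x - cx)^2 + (y - cx)^2)
  df <- (r - endo) / (epi - endo)
  ramp <- pmin(pmax((df - 0.4) / 0.2, 0), 1)
  vals <- peak * (ratio + (1 - ratio) * ramp)
  vals[r < endo | r >= epi] <- NA
  vals
}
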