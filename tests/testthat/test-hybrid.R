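# A fitted AIF on the noiseless small phantom, shared across tests.
fixture_aif <- local({
  ph <- generate_phantom(small_spec())
  extract_aif(ph$series)
})

test_that("hybrid fit recovers the generating flow from noiseless tissue curves", {
  truth <- small_spec()$aif_params
  tt <- shuttle_times(small_spec())["cranial", ]
  for (mbf in c(20, 60, 120)) {
    tac <- list(times_s = tt,
                values_hu = tissue_curve(mbf, truth, tt, transit_time_s = 8,
                                         baseline_hu = 75))
    fit <- fit_hybrid_model(tac, fixture_aif)
    expect_true(fit$converged)
    expect_equal(flow_to_mbf(fit$flow_scale), mbf, tolerance = 0.05 * mbf)
    expect_equal(compute_mbf(fit, fixture_aif), mbf, tolerance = 0.05 * mbf)
  }
})

test_that("flat tissue curve gives zero flow and baseline shift is absorbed", {
  tt <- shuttle_times(small_spec())["cranial", ]
  flat <- list(times_s = tt, values_hu = rep(80, length(tt)))
  fit <- fit_hybrid_model(flat, fixture_aif)
  expect_equal(fit$flow_scale, 0)
  expect_equal(compute_mbf(fit, fixture_aif), 0)

  truth <- small_spec()$aif_params
  tac <- list(times_s = tt, values_hu = tissue_curve(80, truth, tt))
  shifted <- list(times_s = tt, values_hu = tac$values_hu + 250)
  f1 <- fit_hybrid_model(tac, fixture_aif)
  f2 <- fit_hybrid_model(shifted, fixture_aif)
  expect_equal(f2$flow_scale, f1$flow_scale, tolerance = 1e-9)
  expect_equal(f2$baseline_hu - f1$baseline_hu, 250, tolerance = 1e-6)
})

test_that("maximal-slope readout follows the documented units bridge", {
  # model-curve max slope 1.5 HU/s over an AIF maximum of 300 HU
  # -> 0.005 /s -> 30 ml/100 ml/min
  p <- aif_params(amplitude = 300, onset_s = 8)
  slope_unit <- ctmpi:::model_max_slope_unit(p, 8, 0, 40)
  expect_equal(slope_unit, 300, tolerance = 1e-3)  # transit spans the rise
  f <- 1.5 / slope_unit
  fit <- structure(
    list(flow_scale = f, transit_time_s = 8, delay_s = 0, baseline_hu = 75,
         rss = 0, converged = TRUE,
         tac = data.frame(times_s = seq(5, 21, 2), values_hu = 0),
         aif_params = p),
    class = "hybrid_fit")
  aif <- structure(list(params = p, converged = TRUE, max_value_hu = 300,
                        samples = data.frame()), class = "aif_fit")
  expect_equal(compute_mbf(fit, aif), 30, tolerance = 1e-4)
  expect_equal(flow_to_mbf(0.005), 30)
  expect_equal(mbf_to_flow(30), 0.005)
})

test_that("MBF is invariant to joint rescaling of AIF and tissue enhancement", {
  sp <- small_spec(sectors = uniform_sectors(80))
  ph1 <- generate_phantom(sp)
  # scale all enhancement above the scan baseline by 1.7
  sp2 <- sp
  sp2$aif_params$amplitude <- sp$aif_params$amplitude * 1.7
  sectors2 <- uniform_sectors(80 * 1.7)
  sp2$sectors <- sectors2
  ph2 <- generate_phantom(sp2)
  mask <- ph1$truth$sector_of_voxel > 0
  m1 <- compute_mbf_map(ph1$series, extract_aif(ph1$series), mask)
  m2 <- compute_mbf_map(ph2$series, extract_aif(ph2$series), mask)
  expect_equal(mean(m2$mbf[mask]), mean(m1$mbf[mask]) * 1.7,
               tolerance = 0.01 * mean(m1$mbf[mask]))
  # the readout itself: MBF = slope / AIF max is dimensionless in amplitude,
  # so scaling both curves by c leaves the flow estimate of a fixed-flow
  # tissue curve unchanged
  tt <- shuttle_times(sp)["cranial", ]
  truth <- sp$aif_params
  tac <- list(times_s = tt, values_hu = tissue_curve(80, truth, tt))
  aif1 <- extract_aif(ph1$series)
  fitc <- fit_hybrid_model(tac, aif1)
  base <- compute_mbf(fitc, aif1)
  expect_equal(base, 80, tolerance = 0.05 * 80)
})

test_that("per-voxel map recovers a homogeneous noiseless phantom", {
  sp <- small_spec(sectors = uniform_sectors(80))
  ph <- generate_phantom(sp)
  mask <- ph$truth$sector_of_voxel > 0
  map <- compute_mbf_map(ph$series, extract_aif(ph$series), mask)
  v <- map$mbf[map$mask]
  expect_equal(mean(v), 80, tolerance = 0.05 * 80)
  expect_lt(sd(v), 0.02 * mean(v))
})

test_that("two-sector contrast is ordered correctly at 10 HU noise", {
  sectors <- list(
    sector_spec(0, 180, 100, 1, "LAD", 0.7),
    sector_spec(180, 360, 50, 1, "LCX", 0.9)
  )
  for (s in 1:5) {
    ph <- generate_phantom(small_spec(sectors = sectors, noise_sd_hu = 10,
                                      seed = 100 + s))
    mask <- ph$truth$sector_of_voxel > 0
    map <- compute_mbf_map(ph$series, extract_aif(ph$series), mask)
    hi <- mean(map$mbf[ph$truth$sector_of_voxel == 1 & map$mask])
    lo <- mean(map$mbf[ph$truth$sector_of_voxel == 2 & map$mask])
    expect_gt(hi, lo)
  }
})

test_that("mapping is deterministic and works down to a single-voxel mask", {
  ph <- generate_phantom(small_spec(noise_sd_hu = 10, seed = 5))
  aif <- extract_aif(ph$series)
  mask <- ph$truth$sector_of_voxel > 0
  m1 <- compute_mbf_map(ph$series, aif, mask)
  m2 <- compute_mbf_map(ph$series, aif, mask)
  expect_identical(m1$mbf, m2$mbf)

  one <- array(FALSE, dim(mask))
  one[which(mask)[1]] <- TRUE
  m_one <- compute_mbf_map(ph$series, aif, one)
  expect_equal(sum(!is.na(m_one$mbf)), 1)
  expect_error(compute_mbf_map(ph$series, aif, array(FALSE, dim(mask))),
               "empty")
})

test_that("sector-mean MBF bias stays within 10 % at 10 HU noise", {
  # seeded replicate phantoms; desk-scale grid keeps this fast
  rel_bias <- c()
  for (s in 1:30) {
    ph <- generate_phantom(small_spec(noise_sd_hu = 10, seed = 200 + s))
    mask <- ph$truth$sector_of_voxel > 0
    map <- compute_mbf_map(ph$series, extract_aif(ph$series), mask)
    for (i in 1:3) {
      sel <- ph$truth$sector_of_voxel == i
      rel_bias <- c(rel_bias,
                    mean(map$mbf[sel & map$mask]) /
                      mean(ph$truth$true_mbf[sel]) - 1)
    }
  }
  expect_lt(abs(mean(rel_bias)), 0.10)
})

test_that("ROI measurement enforces the 50 mm^2 minimum area", {
  vals <- matrix(70, 64, 64)
  map <- synthetic_map(vals)
  # 50 mm^2 at 0.35 mm pixels requires ceil(50 / 0.1225) = 409 pixels
  expect_equal(ceiling(50 / 0.35^2), 409)
  # a square ROI of 20 x 20.4 pixels ~ 408 pixels -> rejected
  sq <- function(w_mm, h_mm, x0 = 2, y0 = 2) {
    rbind(c(x0, y0), c(x0 + w_mm, y0), c(x0 + w_mm, y0 + h_mm),
          c(x0, y0 + h_mm))
  }
  expect_error(measure_roi_mbf(map, sq(0.35 * 20, 0.35 * 20.4)),
               "below the minimum")
  expect_silent(v <- measure_roi_mbf(map, sq(0.35 * 21, 0.35 * 21)))
  expect_equal(v, 70)
  # ROI extending outside the mask errors
  map$mask[1:32, , 1] <- FALSE
  expect_error(measure_roi_mbf(map, sq(10, 10, 1, 1)), "outside the map mask")
})

test_that("ROI mean equals the hand mean of a printed toy patch", {
  vals <- matrix(NA_real_, 8, 8)
  vals[4:5, 4:5] <- c(60, 70, 80, 90)
  map <- synthetic_map(vals, pixel_mm = 1)
  roi <- rbind(c(3.2, 3.2), c(4.8, 3.2), c(4.8, 4.8), c(3.2, 4.8))
  expect_equal(measure_roi_mbf(map, roi, min_area_mm2 = 4), 75)
})
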