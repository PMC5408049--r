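test_that("a constant map yields a flat profile and TPR 1 in both modes", {
  vals <- annulus_image(peak = 75, ratio = 1)
  map <- synthetic_map(vals)
  band <- wall_band(c(128 * 0.35 / 2, 128 * 0.35 / 2), 0, 90, 10, 20)
  prof <- sample_profile(map, band)
  expect_true(all(abs(prof$mean_mbf - 75) < 1e-9))
  expect_equal(diff(prof$depths_mm), rep(0.4, length(prof$depths_mm) - 1))
  auto <- select_endo_epi(prof)
  expect_equal(auto$tpr, 1)
  man <- select_endo_epi(prof, "manual", manual_depths = c(1, 8))
  expect_equal(c(man$endo_mbf, man$epi_mbf), c(75, 75))
})

test_that("profile endpoints recover a generated linear gradient (58 -> 91)", {
  sp <- small_spec(sectors = uniform_sectors(91, ratio = 0.64),
                   transmural_shape = "linear")
  ph <- generate_phantom(sp)
  mask <- ph$truth$sector_of_voxel > 0
  map <- compute_mbf_map(ph$series, extract_aif(ph$series), mask)
  band <- wall_band(sp$lv_center, 0, 360, sp$endo_radius_mm,
                    sp$epi_radius_mm)
  prof <- sample_profile(map, band)
  inner <- prof$mean_mbf[2]                      # one edge step excluded
  outer <- prof$mean_mbf[length(prof$mean_mbf) - 1]
  wall <- sp$epi_radius_mm - sp$endo_radius_mm
  expect_lin <- function(depth) 58.24 + (91 - 58.24) * depth / wall
  expect_equal(inner, expect_lin(prof$depths_mm[2]), tolerance = 0.03 * 58)
  expect_equal(outer,
               expect_lin(prof$depths_mm[length(prof$mean_mbf) - 1]),
               tolerance = 0.03 * 91)
})

test_that("profiles are equivariant under a 90-degree map rotation", {
  vals <- annulus_image(ratio = 0.7)
  # break the circular symmetry: gradient only in the first quadrant band
  map <- synthetic_map(vals)
  ctr <- 128 * 0.35 / 2
  band <- wall_band(c(ctr, ctr), 10, 80, 10, 20)
  prof <- sample_profile(map, band)
  # rotate image 90 deg CCW about the centre: (x, y) -> (-y, x)
  vals_rot <- t(apply(vals, 2, rev))
  map_rot <- synthetic_map(vals_rot)
  band_rot <- wall_band(c(ctr, ctr), 10 + 90, 80 + 90, 10, 20)
  prof_rot <- sample_profile(map_rot, band_rot)
  expect_equal(prof_rot$mean_mbf, prof$mean_mbf, tolerance = 1e-6)
})

test_that("border detection from the mask matches the known radii", {
  vals <- annulus_image(ratio = 0.64)
  map <- synthetic_map(vals)
  ctr <- 128 * 0.35 / 2
  explicit <- sample_profile(map, wall_band(c(ctr, ctr), 0, 360, 10, 20))
  detected <- sample_profile(map, wall_band(c(ctr, ctr), 0, 360))
  expect_equal(detected$wall_thickness_mm, explicit$wall_thickness_mm,
               tolerance = 0.15)
  a <- select_endo_epi(explicit)$tpr
  b <- select_endo_epi(detected)$tpr
  expect_equal(b, a, tolerance = 0.03)
})

test_that("manual selection returns the profile values at the chosen depths", {
  prof <- structure(
    list(depths_mm = seq(0, 8, by = 0.4),
         mean_mbf = seq(58, 91, length.out = 21), step_mm = 0.4,
         n_lines = 90, slice_index = 1, wall_thickness_mm = 8),
    class = "transmural_profile")
  sel <- select_endo_epi(prof, "manual", manual_depths = c(0, 8))
  expect_equal(c(sel$endo_mbf, sel$epi_mbf), c(58, 91))
  expect_equal(round(sel$tpr, 2), 0.64)
  expect_error(select_endo_epi(prof, "manual", manual_depths = c(0, 9)),
               "outside")
  expect_error(select_endo_epi(prof, "manual", manual_depths = c(8, 1)),
               "shallower")
  # auto mode on a strictly increasing profile: endo < epi
  auto <- select_endo_epi(prof)
  expect_lt(auto$endo_mbf, auto$epi_mbf)
})

test_that("compute_tpr matches the worked 58/91 example and guards its domain", {
  expect_equal(round(compute_tpr(58, 91), 2), 0.64)
  expect_equal(compute_tpr(70, 70), 1.0)
  expect_equal(compute_tpr(0, 80), 0.0)
  expect_error(compute_tpr(58, 0), "positive")
  expect_error(compute_tpr(58, -3), "positive")
})

test_that("TPR is invariant under global flow scaling of the map", {
  vals <- annulus_image(ratio = 0.64)
  ctr <- 128 * 0.35 / 2
  band <- wall_band(c(ctr, ctr), 0, 360, 10, 20)
  t1 <- select_endo_epi(sample_profile(synthetic_map(vals), band))$tpr
  for (c_scale in c(0.5, 0.7, 2)) {
    t2 <- select_endo_epi(sample_profile(synthetic_map(vals * c_scale),
                                         band))$tpr
    expect_equal(t2, t1, tolerance = 1e-9)
  }
})

test_that("auto bands exclude a bright endocardial rim artefact", {
  # displacement artefacts put spuriously high MBF next to the LV lumen
  vals <- annulus_image(ratio = 0.64)
  ctr <- 128 * 0.35 / 2
  band <- wall_band(c(ctr, ctr), 0, 360, 10, 20)
  tpr_clean <- select_endo_epi(sample_profile(synthetic_map(vals), band))$tpr
  x <- matrix((seq_len(128) - 0.5) * 0.35, 128, 128)
  y <- t(x)
  r <- sqrt((x - ctr)^2 + (y - ctr)^2)
  rim <- r >= 10 & r < 10 + 2 * 0.35      # 2-pixel rim at the lumen border
  vals_rim <- vals
  vals_rim[rim] <- 250
  tpr_rim <- select_endo_epi(sample_profile(synthetic_map(vals_rim),
                                            band))$tpr
  expect_lt(abs(tpr_rim - tpr_clean), 0.05)
})

test_that("auto-band TPR recovers the generated transmural ratio end to end", {
  for (r in c(0.5, 0.8)) {
    sp <- small_spec(sectors = uniform_sectors(91, ratio = r))
    ph <- generate_phantom(sp)
    mask <- ph$truth$sector_of_voxel > 0
    map <- compute_mbf_map(ph$series, extract_aif(ph$series), mask)
    band <- wall_band(sp$lv_center, 0, 360, sp$endo_radius_mm,
                      sp$epi_radius_mm)
    tpr <- select_endo_epi(sample_profile(map, band))$tpr
    expect_equal(tpr, r, tolerance = 0.05)
  }
})

test_that("territory classification applies inclusive thresholds", {
  rec <- data.frame(
    patient_id = c("P1", "P1", "P2", "P2"),
    territory = c("LAD", "LCX", "RCA", "LAD"),
    mbf = c(76, 100, 60, NA),
    tpr = c(0.9, 1.0, 0.64, 0.7),
    ffr = c(0.75, 0.92, 0.60, 0.80))
  expect_message(out <- classify_territory(rec), "excluded")
  expect_equal(nrow(out), 3)
  expect_equal(out$mbf_positive, c(TRUE, FALSE, TRUE))   # 76 inclusive
  expect_equal(out$tpr_positive, c(FALSE, FALSE, TRUE))  # 0.64 positive
  expect_equal(out$ischaemic, c(TRUE, FALSE, TRUE))      # FFR <= 0.80
  expect_equal(out$concordant, c(FALSE, TRUE, TRUE))
})
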