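test_that("perfusion density follows its defining arithmetic and is linear in intensity", {
  img <- matrix(0.5, 20, 20)
  region <- matrix(FALSE, 20, 20); region[1:10, 1:10] <- TRUE  # 100 px
  comp <- matrix(FALSE, 20, 20); comp[1:5, 1:5] <- TRUE        # 25 px
  img[comp] <- 0.8
  dvm <- dvm_image(img)
  expect_equal(perfusion_density(dvm, comp, region), 25 * 0.8 / 100)
  # full coverage at intensity 1 -> 1; empty compartment -> 0
  one <- dvm_image(matrix(1, 20, 20))
  expect_equal(perfusion_density(one, region, region), 1)
  expect_equal(perfusion_density(dvm, matrix(FALSE, 20, 20), region), 0)
  # linearity: scaling intensities by c scales PD by exactly c
  pd1 <- perfusion_density(dvm, comp, region)
  half <- dvm_image(img * 0.4)
  expect_equal(perfusion_density(half, comp, region), 0.4 * pd1)
  # binary mode is the area fraction
  expect_equal(perfusion_density(dvm, comp, region, binary_mode = TRUE), 0.25)
  expect_error(perfusion_density(dvm, comp, matrix(FALSE, 20, 20)),
               class = "octacrmb_undefined_region")
})

test_that("box-counting dimension hits the analytic limits and is orientation-invariant", {
  expect_gte(box_counting_fd(matrix(TRUE, 512, 512)), 1.95)
  expect_lte(box_counting_fd(matrix(TRUE, 512, 512)), 2.0)
  ln <- matrix(FALSE, 512, 512); ln[256, ] <- TRUE
  expect_equal(box_counting_fd(ln), 1, tolerance = 0.05)
  # Sierpinski carpet, depth 5: log 8 / log 3
  expect_equal(box_counting_fd(sierpinski_carpet(5)), log(8) / log(3),
               tolerance = 0.05 / (log(8) / log(3)))
  # flips and 90-degree rotations move FD by < 0.02
  smp <- generate_sample(synthetic_params(seed = 4, size_px = 192))
  b <- binarize(smp$scp)$pixels
  fds <- c(box_counting_fd(b), box_counting_fd(b[nrow(b):1, ]),
           box_counting_fd(t(b)), box_counting_fd(b[, ncol(b):1]))
  expect_lt(max(fds) - min(fds), 0.02)
  # degenerate inputs
  expect_error(box_counting_fd(matrix(FALSE, 64, 64)))
  one_px <- matrix(FALSE, 64, 64); one_px[1, 1] <- TRUE
  expect_error(box_counting_fd(one_px), class = "octacrmb_degenerate_fit")
})

test_that("tortuosity matches arc/chord oracles", {
  # straight bar -> exactly 1
  bar <- matrix(FALSE, 40, 160); bar[20, 20:140] <- TRUE
  expect_equal(vessel_tortuosity(skeletonize_map(bar)), 1, tolerance = 1e-9)
  # half circle -> pi/2 within 2%
  sk <- skeletonize_map(half_circle_mask())
  expect_equal(vessel_tortuosity(sk), pi / 2, tolerance = 0.02)
  # sine vessel -> quadrature oracle within 2%
  fx <- sine_vessel_fixture()
  expect_equal(vessel_tortuosity(skeletonize_map(fx$mask)), fx$ratio,
               tolerance = 0.02)
  # no qualifying segment -> missing, not zero
  dot <- matrix(FALSE, 30, 30); dot[15, 14:16] <- TRUE
  expect_true(is.na(vessel_tortuosity(skeletonize_map(dot))))
})

test_that("mean vessel diameter averages local calibers and respects the region", {
  psz <- 3 / 304
  m <- matrix(FALSE, 80, 160)
  m[18:20, 10:150] <- TRUE    # 3 px wide
  m[58:63, 10:150] <- TRUE    # 6 px wide
  sk <- skeletonize_map(binary_vessel_map(m, psz))
  mid <- col(m) %in% 30:130
  got <- mean(sk$diameter_um[sk$pixels & mid], na.rm = TRUE)
  expect_equal(got, mean(c(3, 6)) * psz * 1000, tolerance = 0.25)
  # region excluding all vessels -> missing
  empty_region <- matrix(FALSE, 80, 160)
  expect_true(is.na(mean_vessel_diameter(sk, empty_region)))
})

test_that("vessel dispersion spans its orientation limits", {
  ctr <- c(152.5, 152.5)
  ann <- annulus_mask(304, 50, 152)
  # radial spokes: near 0
  expect_lt(vessel_dispersion(skeletonize_map(synth_spokes_mask()), ctr, ann),
            0.05)
  # concentric rings: near 1
  expect_gt(vessel_dispersion(skeletonize_map(synth_rings_mask()), ctr, ann),
            0.9)
  # isotropic strokes: 1 - 2/pi
  iso <- skeletonize_map(synth_isotropic_mask(304, 0.12, seed = 3))
  expect_equal(vessel_dispersion(iso, ctr, ann), 1 - 2 / pi, tolerance = 0.03 / (1 - 2 / pi))
  # too few pixels -> missing
  few <- matrix(FALSE, 304, 304); few[100, 100:105] <- TRUE
  expect_true(is.na(vessel_dispersion(skeletonize_map(few), ctr, ann)))
})

test_that("FAZ demarcation recovers disc and ellipse geometry", {
  # avascular disc r = 0.3 mm in a dense mesh
  smp <- generate_sample(synthetic_params(faz_radius_mm = 0.3,
                                          faz_eccentricity = 0,
                                          n_large_vessels = 0,
                                          capillary_density = 0.35, seed = 11))
  fz <- demarcate_faz(binarize(smp$scp))
  expect_equal(fz$area_mm2, pi * 0.09, tolerance = 0.03)
  expect_gte(fz$acircularity, 1 - 1e-6)
  expect_lte(fz$acircularity, 1.05)
  # convergence: doubling the rays changes the area by < 1%
  fz720 <- demarcate_faz(binarize(smp$scp), n_rays = 720)
  expect_equal(fz720$area_mm2, fz$area_mm2, tolerance = 0.01)
  # ellipse, semi-axes 0.2 / 0.1 mm (area preserved by the generator)
  smp2 <- generate_sample(synthetic_params(faz_radius_mm = sqrt(0.02),
                                           faz_eccentricity = 0.5,
                                           n_large_vessels = 0,
                                           capillary_density = 0.35, seed = 12))
  fz2 <- demarcate_faz(binarize(smp2$scp))
  expect_equal(fz2$area_mm2, pi * 0.02, tolerance = 0.03)
  # acircularity against the quadrature perimeter oracle of the ellipse
  a <- 0.2; b <- 0.1
  perim <- stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                            0, 2 * pi, subdivisions = 2000L)$value
  expect_equal(fz2$acircularity, perim / (2 * sqrt(pi * (pi * a * b))),
               tolerance = 0.02)
  # every produced polygon satisfies the isoperimetric bound
  for (f in list(fz, fz720, fz2)) expect_gte(f$acircularity, 1 - 1e-6)
})

test_that("compute_crmbs populates all 12 metrics with the expected structure", {
  smp <- generate_sample(synthetic_params(seed = 7, size_px = 192))
  rec <- suppressWarnings(compute_crmbs(smp$scp, smp$dcp))
  v <- unlist(rec[crmb_names()])
  expect_length(v, 12)
  expect_true(all(is.finite(v)))
  expect_true(all(v[c("PDL", "PDCS", "PDCD")] >= 0 & v[c("PDL", "PDCS", "PDCD")] <= 1))
  expect_gte(v["MVT"], 1)
  expect_true(v["MVDisp"] >= 0 && v["MVDisp"] <= 1)
  expect_true(all(v[c("FDS", "FDD")] > 0 & v[c("FDS", "FDD")] <= 2))
  expect_true(all(v[c("FACS", "FACD")] >= 1 - 1e-6))
  # provenance records the thresholds actually used
  expect_true(is.list(rec$provenance))
  expect_equal(rec$provenance$lv_diameter_threshold_um, 25)
  # SCP fed as both layers: layer-paired metrics coincide
  rec2 <- suppressWarnings(compute_crmbs(smp$scp, smp$scp))
  expect_equal(rec2$FDS, rec2$FDD)
  expect_equal(rec2$FAS, rec2$FAD)
  expect_equal(rec2$FACS, rec2$FACD)
  # blank images fail at the binarization stage with a stage label
  blank <- dvm_image(matrix(0.5, 192, 192))
  expect_error(compute_crmbs(blank, blank), "binarize")
})
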