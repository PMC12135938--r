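test_that("degenerate mixture puts every spot in the configured cluster", {
  g <- std_geometry()
  m <- cluster_only_model(total = 50)
  sp <- sample_presynapses(m, g, n_total = 50, seed = 5)
  expect_equal(nrow(sp), 50)
  expect_true(all(sp$true_region == "i1"))
  ctr <- hemisegment_centroid(g) + m$cluster_centers["i1", ]
  # clustered near the i1 center (cluster sd 0.5 in ml/dv, jitter 0.6)
  expect_lt(max(abs(sp$x_um - ctr[1])), 4)
  expect_lt(max(abs(sp$y_um - ctr[2])), 4)
})

test_that("empirical region fractions converge to the mixture weights", {
  g <- std_geometry()
  w <- c(i1 = 0.04, i2 = 0.04, i3 = 0.08, late = 0.84)
  m <- genotype_model(region_weights = w)
  sp <- sample_presynapses(m, g, n_total = 10000, seed = 11)
  obs <- table(factor(sp$true_region, names(w)))
  # chi-square goodness of fit not rejected at alpha = 0.01
  gof <- chisq.test(obs, p = w)
  expect_gt(gof$p.value, 0.01)
  # and each fraction within 3 binomial SE of its weight
  se <- sqrt(w * (1 - w) / 10000)
  expect_true(all(abs(as.numeric(obs) / 10000 - w) < 3 * se))
})

test_that("mixture weights must sum to one", {
  expect_error(genotype_model(region_weights = c(i1 = 0.5, i2 = 0.5,
                                                 i3 = 0.5, late = 0.5)),
               "sum to 1")
  expect_error(genotype_model(total_count_mean = -1), "positive")
})

test_that("every sampled spot lies inside the neuropil outline", {
  g <- std_geometry()
  for (mdl in list(wt_model(), hboe_model(), hb_filtered_model())) {
    sp <- sample_presynapses(mdl, g, seed = 3)
    expect_true(all(point_in_neuropil(cbind(sp$x_um, sp$y_um, sp$z_um), g)))
  }
  # right-side hemisegments too
  gr <- make_geometry(20, 20, 20, side = "right")
  spr <- sample_presynapses(wt_model(), gr, seed = 4)
  expect_true(all(point_in_neuropil(cbind(spr$x_um, spr$y_um, spr$z_um), gr)))
})

test_that("sampling is reproducible given a seed and varies across seeds", {
  g <- std_geometry()
  a <- sample_presynapses(wt_model(), g, n_total = 100, seed = 42)
  b <- sample_presynapses(wt_model(), g, n_total = 100, seed = 42)
  c <- sample_presynapses(wt_model(), g, n_total = 100, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$x_um, c$x_um))
})

test_that("rendering zero spots gives a constant background volume", {
  g <- make_geometry(6, 6, 6)
  sp <- sample_presynapses(cluster_only_model(), g, n_total = 0, seed = 1)
  v <- render_volume(sp, g, voxel_size = c(0.2, 0.2, 0.3), background = 2)
  expect_true(all(v$data == 2))
})

test_that("a single rendered spot peaks within one voxel of its center", {
  g <- make_geometry(6, 6, 6)
  sp <- data.frame(x_um = 3.07, y_um = 2.71, z_um = 3.33, intensity = 5)
  v <- render_volume(sp, g, voxel_size = c(0.2, 0.2, 0.3))
  peak <- arrayInd(which.max(v$data), dim(v$data))
  ctr <- index_to_world(peak, v)
  expect_true(all(abs(ctr - c(3.07, 2.71, 3.33)) <= v$voxel_size))
})

test_that("rendered integrated intensity matches the spot intensities", {
  g <- make_geometry(10, 10, 10)
  set.seed(8)
  # spots placed well inside so no PSF mass is clipped
  sp <- data.frame(
    x_um = runif(20, 3, 7), y_um = runif(20, 3, 7), z_um = runif(20, 3, 7),
    intensity = runif(20, 1, 10)
  )
  v <- render_volume(sp, g, voxel_size = c(0.2, 0.2, 0.22))
  integral <- sum(v$data) * prod(v$voxel_size)
  expect_equal(integral, sum(sp$intensity), tolerance = 0.01)
})

test_that("spots outside the grid are clipped with a warning, not an error", {
  g <- make_geometry(5, 5, 5)
  sp <- data.frame(x_um = 4.99, y_um = 2.5, z_um = 2.5, intensity = 5)
  expect_warning(render_volume(sp, g, voxel_size = c(0.2, 0.2, 0.2)),
                 "clipped")
})

test_that("noiseless render plus detection recovers nearly all spots", {
  g <- std_geometry()
  m <- genotype_model(region_weights = c(i1 = 0, i2 = 0, i3 = 0, late = 1),
                      intensity_sdlog = 0)
  sp <- sample_presynapses(m, g, n_total = 100, seed = 17)
  v <- suppressWarnings(render_volume(sp, g, voxel_size = c(0.2, 0.2, 0.3)))
  det <- detect_spots(v, spot_params(0.41, 1.46, min_intensity = 1))
  m <- match_spots(det, sp, radius_um = 0.5)
  expect_gte(m$recall, 0.99)
})

test_that("cohorts are deterministic and extensible under one seed", {
  g <- std_geometry()
  models <- list(WT = wt_model(), HbOE = hboe_model())
  c1 <- simulate_cohort(models, n_hemisegments = 4, geometry = g, seed = 9)
  c2 <- simulate_cohort(models, n_hemisegments = 4, geometry = g, seed = 9)
  expect_identical(c1$spots, c2$spots)
  # byte-identical CSV output
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_spot_table(c1$spots, f1)
  write_spot_table(c2$spots, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # growing the cohort leaves earlier hemisegments untouched
  c3 <- simulate_cohort(models, n_hemisegments = 6, geometry = g, seed = 9)
  h_first <- unique(c1$spots$hemisegment_id)
  sub <- c3$spots[c3$spots$hemisegment_id %in% h_first, ]
  rownames(sub) <- NULL
  expect_identical(c1$spots, sub)
})

test_that("an empty cohort yields valid empty tables", {
  g <- std_geometry()
  m <- genotype_model(total_count_mean = 1e-9)
  co <- simulate_cohort(list(WT = m), n_hemisegments = 1, geometry = g,
                        seed = 1)
  expect_s3_class(co$spots, "data.frame")
  expect_true(all(c("spot_id", "x_um", "true_region") %in% names(co$spots)))
})

test_that("cohort files round-trip through the on-disk dataset", {
  g <- std_geometry()
  dir <- tempfile("cohort")
  co <- simulate_cohort(list(WT = wt_model()), n_hemisegments = 2,
                        geometry = g, seed = 31, out_dir = dir)
  expect_true(file.exists(file.path(dir, "spots.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_spot_table(file.path(dir, "spots.csv"))
  expect_equal(nrow(back), nrow(co$spots))
  expect_equal(back$x_um, co$spots$x_um, tolerance = 1e-12)
})

test_that("volumes survive a TIFF round trip", {
  g <- make_geometry(4, 4, 4)
  sp <- data.frame(x_um = 2, y_um = 2, z_um = 2, intensity = 7)
  v <- render_volume(sp, g, voxel_size = c(0.2, 0.2, 0.4))
  path <- tempfile(fileext = ".tif")
  write_volume_tiff(v, path)
  v2 <- read_volume_tiff(path)
  expect_equal(dim(v2$data), dim(v$data))
  expect_equal(v2$voxel_size, v$voxel_size)
  expect_equal(v2$data, v$data, tolerance = 1e-6)
})
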