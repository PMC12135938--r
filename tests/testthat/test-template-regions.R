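test_that("affine transforms store a working inverse", {
  A <- rbind(c(1.1, 0.1, 0), c(-0.05, 0.95, 0), c(0, 0, 1.02))
  tr <- affine3d(A, c(1, -2, 0.5))
  p <- matrix(rnorm(30), ncol = 3)
  expect_equal(apply_affine(tr, apply_affine(tr, p), inverse = TRUE), p,
               tolerance = 1e-10)
  expect_error(affine3d(matrix(0, 3, 3)), "singular")
})

test_that("registering a mask to itself returns the identity", {
  mk <- coarse_mask()
  tr <- register_to_template(mk, mk)
  expect_equal(attr(tr, "dice"), 1)
  expect_lt(max(abs(tr$A - diag(3))), 1e-3)
  expect_lt(max(abs(tr$t)), 1e-2)
})

test_that("a known translation is recovered within one voxel", {
  mk <- coarse_mask()
  moved <- mk
  moved$origin <- mk$origin + c(3, 2, 1)
  tr <- register_to_template(moved, mk)
  expect_gte(attr(tr, "dice"), 0.99)
  expect_true(all(abs(tr$t - c(-3, -2, -1)) <= mk$voxel_size))
})

test_that("incompatible shapes fail to align with an explicit error", {
  mk <- coarse_mask()
  # a thin bar cannot reach Dice 0.5 against the neuropil outline
  bar <- mk
  bar$data[] <- FALSE
  bar$data[12, 12, ] <- TRUE
  expect_error(register_to_template(bar, mk, maxit = 50), "lignment")
})

test_that("template built from identical inputs is a fixed point", {
  mk <- coarse_mask()
  bt <- build_template(list(mk, mk, mk), n_iterations = 2)
  expect_identical(bt$template$data, mk$data)
  for (tr in bt$transforms) {
    expect_lt(max(abs(tr$A - diag(3))), 1e-3)
  }
  expect_error(build_template(list(mk)), "at least 2")
})

test_that("template construction absorbs a translated input", {
  mk <- coarse_mask()
  moved <- mk
  moved$origin <- mk$origin + c(3, 2, 1)
  bt <- build_template(list(mk, moved, mk), n_iterations = 2)
  expect_gte(bt$mean_dice, 0.98)
  expect_true(all(abs(bt$transforms[[2]]$t - c(-3, -2, -1)) <=
                    mk$voxel_size))
})

test_that("mirroring is an exact involution for spots and masks", {
  g <- std_geometry()
  sp <- sample_presynapses(wt_model(), g, n_total = 80, seed = 61)
  plane <- g$midline
  sp2 <- mirror_hemisegment(mirror_hemisegment(sp, plane), plane)
  expect_equal(sp2$x_um, sp$x_um, tolerance = 1e-9)
  # a point on the midline is fixed
  onp <- data.frame(x_um = plane$offset, y_um = 3, z_um = 4,
                    hemisegment_id = "h")
  expect_equal(mirror_hemisegment(onp, plane)$x_um, plane$offset)
  mk <- coarse_mask(g)
  mk2 <- mirror_hemisegment(mirror_hemisegment(mk, plane), plane)
  expect_identical(mk2$data, mk$data)
  expect_equal(mk2$origin, mk$origin)
})

test_that("mirrored right-side data reproduce the left-side density", {
  g <- std_geometry()
  gr <- make_geometry(20, 20, 20, side = "right")
  tmpl <- coarse_mask(g)
  spl <- do.call(rbind, lapply(1:6, function(i) {
    sample_presynapses(wt_model(), g, seed = 100 + i,
                       hemisegment_id = paste0("L", i))
  }))
  spr <- do.call(rbind, lapply(1:6, function(i) {
    sample_presynapses(wt_model(), gr, seed = 200 + i,
                       hemisegment_id = paste0("R", i))
  }))
  spr_m <- mirror_hemisegment(spr, gr$midline)
  dl <- density_map(spl, tmpl, sigma_um = 1.5)
  dr <- density_map(spr_m, tmpl, sigma_um = 1.5)
  # overlap of the suprathreshold sets of two independent cohorts
  tl <- quantile(dl$data[dl$data > 0], 0.5)
  a <- dl$data >= tl
  b <- dr$data >= quantile(dr$data[dr$data > 0], 0.5)
  dice <- 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gte(dice, 0.9)
})

test_that("density maps integrate to scale times spot count", {
  g <- std_geometry()
  tmpl <- coarse_mask(g)
  one <- data.frame(x_um = 10, y_um = 10, z_um = 10, hemisegment_id = "h")
  dm <- density_map(one, tmpl, sigma_um = 1)
  expect_equal(sum(dm$data) * prod(dm$voxel_size), 1, tolerance = 0.01)
  peak <- arrayInd(which.max(dm$data), dim(dm$data))
  expect_true(all(abs(index_to_world(peak, dm) - c(10, 10, 10)) <=
                    dm$voxel_size))
  # scaling is exactly linear
  dm10 <- density_map(one, tmpl, sigma_um = 1, scale_factor = 10)
  expect_equal(dm10$data, 10 * dm$data, tolerance = 1e-12)
  # 10:1 spot counts with 1:10 scales give equal integrals
  sp10 <- sample_presynapses(wt_model(), g, n_total = 300, seed = 71)
  sp1 <- sample_presynapses(hb_filtered_model(), g, n_total = 30, seed = 72)
  int_a <- sum(density_map(sp10, tmpl, 1, scale_factor = 1)$data)
  int_b <- sum(density_map(sp1, tmpl, 1, scale_factor = 10)$data)
  expect_equal(int_a, int_b, tolerance = 0.02)
})

test_that("zero spots give an all-zero density and thresholding errors", {
  g <- std_geometry()
  tmpl <- coarse_mask(g)
  none <- data.frame(x_um = numeric(0), y_um = numeric(0),
                     z_um = numeric(0), hemisegment_id = character(0))
  dm <- density_map(none, tmpl)
  expect_true(all(dm$data == 0))
  expect_error(threshold_inclusive(dm, none), "zero spots")
})

test_that("inclusive thresholding includes the required spot fraction", {
  g <- std_geometry()
  tmpl <- coarse_mask(g)
  sp <- sample_presynapses(hb_filtered_model(), g, n_total = 20, seed = 81)
  dm <- density_map(sp, tmpl, sigma_um = 1, scale_factor = 10)
  rm95 <- threshold_inclusive(dm, sp, 0.95)
  expect_gte(rm95$n_inside, 19)
  # fraction 1 keeps every spot voxel suprathreshold
  rm100 <- threshold_inclusive(dm, sp, 1.0)
  expect_equal(rm100$n_inside, 20L)
  # nesting: the 90% region is contained in the 95% region
  rm90 <- threshold_inclusive(dm, sp, 0.90)
  expect_true(all(!(rm90$data & !rm95$data)))
  expect_true(all(!(rm95$data & !rm100$data)))
})

test_that("late region matches the target volume and avoids Hb territory", {
  g <- std_geometry()
  tmpl <- coarse_mask(g)
  # disjoint supports: Hb density on the medial side, WT on the lateral
  hb_sp <- data.frame(x_um = runif(30, 2, 7), y_um = runif(30, 6, 14),
                      z_um = runif(30, 4, 16), hemisegment_id = "a")
  wt_sp <- data.frame(x_um = runif(60, 12, 18), y_um = runif(60, 6, 14),
                      z_um = runif(60, 4, 16), hemisegment_id = "b")
  hb <- density_map(hb_sp, tmpl, 1, scale_factor = 10)
  wt <- density_map(wt_sp, tmpl, 1, scale_factor = 1)
  target <- 120
  late <- define_late_region(hb, wt, target)
  oracle <- brute_force_late(hb, wt, target)
  expect_equal(late$threshold, oracle$threshold)
  expect_equal(late$volume_um3, oracle$volume)
  # the late region sits where the WT density dominates
  expect_true(all(wt$data[late$data] > hb$data[late$data]))
  # identical densities leave nothing to subtract
  expect_error(define_late_region(wt, wt, target), "unreachable")
})

test_that("medial-lateral partition conserves the Hb region", {
  g <- std_geometry()
  tmpl <- coarse_mask(g)
  ref <- simulate_cohort(list(HBF = hb_filtered_model()), 10, g, seed = 83)
  sp <- pool_left_frame(ref)
  dm <- density_map(sp, tmpl, 1, 10)
  hb_all <- threshold_inclusive(dm, sp, 0.95)
  subs <- partition_subregions(hb_all, c(7, 13), labels = c("i1", "i3", "i2"))
  n_union <- sum(subs$i1$data) + sum(subs$i2$data) + sum(subs$i3$data)
  expect_equal(n_union, sum(hb_all$data))
  expect_equal(sum(subs$i1$data & subs$i2$data), 0)
  # each slab contains exactly one cluster peak (clusters at ml 4, 10, 16)
  for (lab in c("i1", "i2", "i3")) {
    dslab <- dm$data
    dslab[!subs[[lab]]$data] <- 0
    peak <- index_to_world(arrayInd(which.max(dslab), dim(dslab)), dm)
    ctr <- hemisegment_centroid(g)
    truth <- ctr[1] + wt_model()$cluster_centers[lab, "ml"]
    expect_lt(abs(peak[1] - truth), 2.5)
  }
  expect_error(partition_subregions(hb_all, c(13, 7)), "increasing")
  expect_error(partition_subregions(hb_all, c(-5, 13)), "extent")
})

test_that("template quantification conserves counts and flags bad input", {
  g <- std_geometry()
  tmpl <- coarse_mask(g)
  ref <- simulate_cohort(list(HBF = hb_filtered_model()), 10, g, seed = 85)
  rsp <- pool_left_frame(ref)
  dm <- density_map(rsp, tmpl, 1, 10)
  hb_all <- threshold_inclusive(dm, rsp, 0.95)
  subs <- partition_subregions(hb_all, c(7, 13), labels = c("i1", "i3", "i2"))
  wtc <- simulate_cohort(list(WT = wt_model()), 4, g, seed = 86)
  wsp <- pool_left_frame(wtc)
  wdm <- density_map(wsp, tmpl, 1, 1)
  late <- define_late_region(dm, wdm, hb_all$volume_um3)
  qc <- quantify_template(wsp, c(subs, list(late = late)))
  expect_equal(qc$i1_n + qc$i2_n + qc$i3_n + qc$late_n + qc$outside_n,
               qc$total_n)
  expect_true(all(qc$i1_pct + qc$i2_pct + qc$i3_pct + qc$late_pct <= 100 + 1e-9))
  # all spots inside the late mask -> late = 100%
  fg <- which(late$data, arr.ind = TRUE)
  pts <- index_to_world(fg[seq_len(min(25, nrow(fg))), , drop = FALSE], late)
  allin <- data.frame(x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
                      hemisegment_id = "x")
  qa <- quantify_template(allin, c(subs, list(late = late)))
  expect_equal(qa$late_pct, 100)
  expect_equal(qa$i1_pct + qa$i2_pct + qa$i3_pct, 0)
  # grossly untransformed spots raise the unregistered error
  off <- wsp
  off$x_um <- off$x_um + 500
  expect_error(quantify_template(off, c(subs, list(late = late))),
               "unregistered")
})

test_that("genotype shifts survive the template pipeline with correct sign", {
  g <- std_geometry()
  tmpl <- coarse_mask(g)
  ref <- simulate_cohort(list(HBF = hb_filtered_model()), 12, g, seed = 87)
  rsp <- pool_left_frame(ref)
  dm <- density_map(rsp, tmpl, 1, 10)
  hb_all <- threshold_inclusive(dm, rsp, 0.95)
  subs <- partition_subregions(hb_all, c(7, 13), labels = c("i1", "i3", "i2"))
  wt_ref <- simulate_cohort(list(WT = wt_model()), 4, g, seed = 88)
  wdm <- density_map(pool_left_frame(wt_ref), tmpl, 1, 1)
  late <- define_late_region(dm, wdm, hb_all$volume_um3)
  regions <- c(subs, list(late = late))
  ok <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    wc <- simulate_cohort(list(WT = wt_model()), 6, g, seed = 1000 + r)
    hc <- simulate_cohort(list(HbOE = hboe_model()), 6, g, seed = 2000 + r)
    qw <- quantify_template(pool_left_frame(wc), regions)
    qh <- quantify_template(pool_left_frame(hc), regions)
    d <- colMeans(qh[, c("i1_pct", "i2_pct", "late_pct")]) -
      colMeans(qw[, c("i1_pct", "i2_pct", "late_pct")])
    if (d[1] > 0 && d[2] > 0 && d[3] < 0) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.9)
})
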