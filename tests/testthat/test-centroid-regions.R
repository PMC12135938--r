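test_that("per-hemisegment region centers are offsets from the centroid", {
  g <- std_geometry()
  ctr <- hemisegment_centroid(g)
  one <- data.frame(x_um = ctr[1], y_um = ctr[2], z_um = 3,
                    hemisegment_id = "h", true_region = "i1")
  expect_equal(region_center_per_hemisegment(one, "i1", g),
               c(ml = 0, dv = 0))
  two <- data.frame(x_um = ctr[1] + c(2, 4), y_um = ctr[2], z_um = 1,
                    hemisegment_id = "h", true_region = "i2")
  expect_equal(region_center_per_hemisegment(two, "i2", g),
               c(ml = 3, dv = 0))
  expect_error(region_center_per_hemisegment(two, "i3", g), "i3")
})

test_that("mirror-then-measure equals measure-then-mirror for right data", {
  gl <- std_geometry()
  gr <- make_geometry(20, 20, 20, side = "right")
  sp <- sample_presynapses(hb_filtered_model(), gr, seed = 12,
                           hemisegment_id = "hr")
  # route 1: mirror spots into the left frame, then measure
  off1 <- region_center_per_hemisegment(mirror_spots(sp, gr$midline),
                                        "i2", gl)
  # route 2: measure in the right frame, then mirror the ml offset
  off2 <- region_center_per_hemisegment(sp, "i2", gr)
  expect_equal(off1[["ml"]], -off2[["ml"]], tolerance = 1e-9)
  expect_equal(off1[["dv"]], off2[["dv"]], tolerance = 1e-9)
})

test_that("region boxes use mean offset plus/minus 2 sample SD", {
  g <- std_geometry()
  offs <- rbind(c(1, 0), c(2, 0), c(3, 0))
  rd <- build_region_definition(offs, "i1", g)
  expect_equal(rd$mean_offset[["ml"]], 2)
  expect_equal(rd$sd[["ml"]], 1) # sample SD, n-1 denominator
  # ml interval is mean +/- 2 SD = [0, 4] in offset coordinates
  ctr <- hemisegment_centroid(g)
  expect_equal(unname(rd$box["lower", "ml"] - ctr[1]), 0)
  expect_equal(unname(rd$box["upper", "ml"] - ctr[1]), 4)
  # anterior-posterior spans the full depth
  expect_equal(unname(rd$box[, "ap"]), unname(g$box[, "ap"]))
  expect_error(build_region_definition(offs[1, , drop = FALSE], "i1", g),
               "2 reference")
})

test_that("degenerate references clamp to the half-width floor", {
  g <- std_geometry()
  offs <- rbind(c(1, 1), c(1, 1), c(1, 1))
  rd <- build_region_definition(offs, "i1", g, min_halfwidth = 0.1)
  expect_equal(unname(rd$halfwidth), c(0.1, 0.1))
  expect_gt(rd$box["upper", "ml"], rd$box["lower", "ml"])
})

test_that("counts are conserved and percentages normalized per hemisegment", {
  g <- std_geometry()
  ctr <- hemisegment_centroid(g)
  rd <- build_region_definition(rbind(c(-1, 0), c(1, 0)), "i1", g)
  # 100 spots, 4 inside the box
  inside <- data.frame(x_um = ctr[1], y_um = ctr[2], z_um = 10)
  sp <- data.frame(
    x_um = c(rep(ctr[1], 4), rep(18, 96)),
    y_um = c(rep(ctr[2], 4), rep(18, 96)),
    z_um = 10, hemisegment_id = "h1", genotype = "WT"
  )
  rc <- assign_and_percent(sp, list(i1 = rd), g)
  expect_equal(rc$i1_n, 4L)
  expect_equal(rc$total_n, 100L)
  expect_equal(rc$i1_pct, 4.0)
  expect_equal(rc$i1_n + rc$outside_n, rc$total_n)
})

test_that("a spot exactly on a box face counts as inside (closed box)", {
  g <- std_geometry()
  rd <- build_region_definition(rbind(c(-1, 0), c(1, 0)), "i1", g)
  on_face <- data.frame(x_um = rd$box["upper", "ml"],
                        y_um = hemisegment_centroid(g)[2],
                        z_um = 10, hemisegment_id = "h1")
  rc <- assign_and_percent(on_face, list(i1 = rd), g)
  expect_equal(rc$i1_n, 1L)
})

test_that("overlapping regions warn and tie-break to the first label", {
  g <- std_geometry()
  rd1 <- build_region_definition(rbind(c(-1, 0), c(1, 0)), "i1", g)
  rd2 <- build_region_definition(rbind(c(-1, 0), c(1, 0)), "i2", g)
  sp <- data.frame(x_um = hemisegment_centroid(g)[1],
                   y_um = hemisegment_centroid(g)[2],
                   z_um = 10, hemisegment_id = "h1")
  expect_warning(rc <- assign_and_percent(sp, list(i1 = rd1, i2 = rd2), g),
                 "overlap")
  expect_equal(rc$i1_n, 1L)
  expect_equal(rc$i2_n, 0L)
})

test_that("zero-spot hemisegments are flagged missing, not zero", {
  g <- std_geometry()
  rd <- build_region_definition(rbind(c(-1, 0), c(1, 0)), "i1", g)
  sp <- data.frame(x_um = 1, y_um = 1, z_um = 1, hemisegment_id = "h1")
  rc <- assign_and_percent(sp, list(i1 = rd), g,
                           hemisegment_ids = c("h1", "h2"))
  expect_equal(rc$total_n, c(1L, 0L))
  expect_true(is.na(rc$i1_pct[2]))
})

test_that("counts are translation-equivariant and monotone in box size", {
  g <- std_geometry()
  sp <- sample_presynapses(wt_model(), g, n_total = 200, seed = 55)
  rd <- build_region_definition(rbind(c(-6.5, -3.2), c(-5.5, -2.8)), "i1", g)
  rc <- assign_and_percent(sp, list(i1 = rd), g)
  # translate geometry and spots together
  t <- c(4, -3, 2)
  g2 <- make_geometry(20, 20, 20, origin = t)
  sp2 <- sp
  sp2$x_um <- sp$x_um + t[1]
  sp2$y_um <- sp$y_um + t[2]
  sp2$z_um <- sp$z_um + t[3]
  rd2 <- build_region_definition(rbind(c(-6.5, -3.2), c(-5.5, -2.8)), "i1", g2)
  rc2 <- assign_and_percent(sp2, list(i1 = rd2), g2)
  expect_equal(rc2$i1_n, rc$i1_n)
  expect_equal(rc2$i1_pct, rc$i1_pct)
  # widening the references never loses spots
  rd_wide <- build_region_definition(rbind(c(-8, -5), c(-4, -1)), "i1", g)
  rc_wide <- assign_and_percent(sp, list(i1 = rd_wide), g)
  expect_gte(rc_wide$i1_n, rc$i1_n)
})

test_that("capture rate matches its definition on constructed fixtures", {
  g <- std_geometry()
  # a region covering the whole neuropil captures everything
  rd_all <- build_region_definition(rbind(c(-10, -10), c(10, 10)), "i2", g)
  ctr <- hemisegment_centroid(g)
  mk_hemi <- function(hid, offset) {
    data.frame(
      x_um = ctr[1] + offset[1] + c(-0.2, 0, 0.2),
      y_um = ctr[2] + offset[2] + c(0.1, -0.1, 0),
      z_um = 10, hemisegment_id = hid, true_region = "i2"
    )
  }
  held <- do.call(rbind, lapply(1:6, function(i) mk_hemi(paste0("h", i), c(0, 0))))
  expect_equal(capture_rate(rd_all, held)$rate, 1.0)
  # a region disjoint from every spot captures nothing
  rd_off <- build_region_definition(rbind(c(7, 7), c(8, 8)), "i2", g)
  expect_equal(capture_rate(rd_off, held)$rate, 0.0)
  expect_error(capture_rate(rd_all, held[held$true_region == "zz", ]),
               "no spots")
  # five tight hemisegments and one displaced by 4 SD -> 5/6 captured
  rd <- build_region_definition(
    rbind(c(-0.5, 0), c(0.5, 0), c(0, -0.5), c(0, 0.5)), "i2", g
  )
  sdm <- rd$sd[["ml"]]
  held2 <- rbind(
    do.call(rbind, lapply(1:5, function(i) mk_hemi(paste0("k", i), c(0, 0)))),
    mk_hemi("k6", c(4 * 2 * sdm, 0)) # well beyond the 2 SD half-width
  )
  cr <- capture_rate(rd, held2)
  expect_equal(cr$captured, 5)
  expect_equal(cr$n_hemisegments, 6)
})
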