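# small shared fixtures: coarse grids keep the scans fast
topo_model <- build_ideal_helix(SAAP148, -65, -45)
topo_tensor <- csa_tensor()
topo_motion <- motion_model(10, 18, 11)

test_that("an all-covering restraint yields an all-true mask", {
  tn <- topo_tensor
  r <- shift_restraint(11, tn$iso, tn$sigma33 - tn$sigma11)
  map <- scan_restraint(topo_model, tn, topo_motion, r, grid_step = 10)
  expect_true(all(map$mask))
})

test_that("forward/invert consistency: the generating orientation is compatible", {
  r_obs <- averaged_shift(amide_frame(topo_model, 11), topo_tensor,
                          orientation(90, 130), topo_motion)
  map <- scan_restraint(topo_model, topo_tensor, topo_motion,
                        shift_restraint(11, r_obs, 2), grid_step = 5)
  i <- which(map$tilt_grid == 90); j <- which(map$pitch_grid == 130)
  expect_true(map$mask[i, j])
})

test_that("scan validates residue and grid step", {
  expect_error(scan_restraint(topo_model, topo_tensor, topo_motion,
                              shift_restraint(99, 80, 2.5)), "not in model")
  expect_error(scan_restraint(topo_model, topo_tensor, topo_motion,
                              shift_restraint(11, 80, 2.5), grid_step = 7),
               "divide")
})

test_that("map intersection is idempotent, annihilating, and grid-checked", {
  map <- scan_restraint(topo_model, topo_tensor, topo_motion,
                        shift_restraint(11, 80, 2.5), grid_step = 10)
  self <- intersect_maps(list(map, map))
  expect_identical(self$mask, map$mask)
  comp <- map; comp$mask <- !map$mask
  expect_false(any(intersect_maps(list(map, comp))$mask))
  other <- scan_restraint(topo_model, topo_tensor, topo_motion,
                          shift_restraint(11, 80, 2.5), grid_step = 5)
  expect_error(intersect_maps(list(map, other)), "different grids")
})

test_that("region finding matches the doubled-axis flood-fill oracle", {
  # hand-built mask: one blob split by the pitch seam plus one interior
  # blob and one single-cell speck
  mask <- matrix(FALSE, 19, 36)  # 10-degree grid
  mask[5:7, c(35, 36, 1, 2)] <- TRUE   # wraps around the seam
  mask[12:14, 10:12] <- TRUE
  mask[2, 20] <- TRUE
  map <- memtopo:::new_compatibility_map(seq(0, 180, 10), seq(0, 350, 10),
                                         mask, NULL, "hand")
  regs <- find_regions(map, min_area = 3)
  expect_length(regs, 2)
  oracle <- oracle_region_sizes(mask)
  expect_equal(sort(sapply(regs, `[[`, "n_cells"), decreasing = TRUE),
               oracle[oracle >= 3])
  # the seam-split blob is one region whose centroid pitch is near 0/360
  cen_p <- sapply(regs, function(r) r$centroid$pitch)
  expect_true(any(pmin(cen_p, 360 - cen_p) < 20))
  # empty map
  map$mask[] <- FALSE
  expect_length(find_regions(map), 0)
})

test_that("topology classification bands behave as configured", {
  mk <- function(tilt) structure(list(
    label = "I", cells = data.frame(tilt = tilt, pitch = 0),
    centroid = orientation(tilt, 0), n_cells = 1, area_deg2 = 1),
    class = "solution_region")
  expect_equal(classify_topology(mk(90)), "in-plane")
  expect_equal(classify_topology(mk(10)), "transmembrane")
  expect_equal(classify_topology(mk(171)), "transmembrane")
  expect_equal(classify_topology(mk(50)), "tilted")
})

test_that("shrinking restraint errors monotonically shrinks the compatible set", {
  errs <- c(8, 4, 2, 1)
  masks <- lapply(errs, function(e)
    scan_restraint(topo_model, topo_tensor, topo_motion,
                   shift_restraint(11, 80, e), grid_step = 5)$mask)
  for (k in 2:length(errs)) {
    expect_true(all(masks[[k]] <= masks[[k - 1]]))
    expect_lt(sum(masks[[k]]), sum(masks[[k - 1]]))
  }
})

test_that("forward/invert round trip recovers random ground truths", {
  set.seed(202)
  motion <- topo_motion
  for (k in 1:20) {
    tilt <- runif(1, 10, 170); pitch <- runif(1, 0, 360)
    truth <- orientation(tilt, pitch)
    obs <- vapply(c(11, 12), function(r)
      averaged_shift(amide_frame(topo_model, r), topo_tensor, truth, motion),
      0)
    res <- run_topology_analysis(
      list(shift_restraint(11, obs[1], 2.5), shift_restraint(12, obs[2], 4)),
      topo_model, topo_tensor, motion, grid_step = 1, min_area = 1)
    inside <- any(vapply(res$regions, function(r)
      any(abs(r$cells$tilt - tilt) <= 1 &
          (pmin(abs(r$cells$pitch - pitch),
                360 - abs(r$cells$pitch - pitch)) <= 1)), TRUE))
    expect_true(inside, info = sprintf("truth (%.1f, %.1f)", tilt, pitch))
  }
})

test_that("region count and centroids are stable to grid refinement", {
  # synthetic two-restraint problem away from tangency
  truth <- orientation(90, 130)
  obs <- vapply(c(11, 12), function(r)
    averaged_shift(amide_frame(topo_model, r), topo_tensor, truth,
                   topo_motion), 0)
  rs <- list(shift_restraint(11, obs[1], 2.5), shift_restraint(12, obs[2], 4))
  r2 <- run_topology_analysis(rs, topo_model, topo_tensor, topo_motion,
                              grid_step = 2)
  r1 <- run_topology_analysis(rs, topo_model, topo_tensor, topo_motion,
                              grid_step = 1)
  expect_equal(nrow(r1$table), nrow(r2$table))
  ord1 <- r1$table[order(r1$table$tilt, r1$table$pitch), ]
  ord2 <- r2$table[order(r2$table$tilt, r2$table$pitch), ]
  expect_lt(max(abs(ord1$tilt - ord2$tilt)), 2)
  dp <- abs(ord1$pitch - ord2$pitch) %% 360
  expect_lt(max(pmin(dp, 360 - dp)), 2)
})
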