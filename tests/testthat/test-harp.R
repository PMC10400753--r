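# Tagged-phantom generation and HARP strain extraction.

small_cfg <- function(...) {
  # 10 tag periods on a 96-px matrix keeps unit tests quick
  tag_sim_config(fov_mm = 30, matrix = 96, tag_span_mm = 3, tag_line_mm = 1,
                 n_frames = 2, ...)
}

test_that("the tagged phantom is deterministic and identity frames repeat
           frame 0", {
  sim <- sim_tagged_stack(small_cfg(noise_sd = 0))
  expect_equal(sim$stack$frames[, , 1], sim$stack$frames[, , 2])
  a <- sim_tagged_stack(small_cfg(noise_sd = 0.03, seed = 5))
  b <- sim_tagged_stack(small_cfg(noise_sd = 0.03, seed = 5))
  expect_identical(a$stack$frames, b$stack$frames)
  expect_false(identical(
    a$stack$frames,
    sim_tagged_stack(small_cfg(noise_sd = 0.03, seed = 6))$stack$frames))
})

test_that("mean intensity is invariant under rigid translation (periodic
           pattern)", {
  sim <- sim_tagged_stack(small_cfg(deformation = deform_translation(1.2, -0.7)))
  m0 <- mean(sim$stack$frames[, , 1])
  m1 <- mean(sim$stack$frames[, , 2])
  expect_equal(m1, m0, tolerance = 1e-6)
})

test_that("folding deformations are rejected and config invariants hold", {
  expect_error(deform_stretch(-0.5), "folding")
  bad <- deform_radial(function(r, amp) r * (1 - 1.5 * amp)) # collapses
  expect_error(sim_tagged_stack(small_cfg(deformation = bad)), "fold")
  expect_error(tag_sim_config(tag_span_mm = 0.7), "integer")
  expect_error(tag_sim_config(matrix = 191), "even")
})

test_that("the tag harmonic sits at fov/span cycles per FOV and phases are
           planar ramps on the undeformed phantom", {
  sim <- sim_tagged_stack(tag_sim_config(n_frames = 1))
  ph <- harp_phase_maps(sim$stack)
  expect_equal(ph$directions[[1]]$peak_cycles_fov, c(50, 0))
  expect_equal(ph$directions[[2]]$peak_cycles_fov, c(0, 50))
  g <- cardioage:::phase_gradient(ph$directions[[1]]$phi_plus[, , 1],
                                  sim$stack$pixel_spacing)
  expect_equal(mean(g$gx), 2 * pi * 50 / 30, tolerance = 0.01)
  expect_lt(max(abs(g$gx - 2 * pi * 50 / 30)) / (2 * pi * 50 / 30), 0.01)
  # untagged image: no harmonic
  flat <- sim$stack
  flat$frames[] <- 1
  expect_error(harp_phase_maps(flat), class = "cardioage_tag_detection")
})

test_that("translation shifts the harmonic phase uniformly by 2 pi k . t", {
  t_mm <- c(0.45, -0.25)
  sim <- sim_tagged_stack(tag_sim_config(
    n_frames = 2, deformation = deform_translation(t_mm[1], t_mm[2])))
  ph <- harp_phase_maps(sim$stack)
  for (d in 1:2) {
    k <- sim$stack$tag_wavevectors[d, ]
    dphi <- ph$directions[[d]]$phi_plus[, , 2] - ph$directions[[d]]$phi_plus[, , 1]
    # compare as angles: wrap(dphi - expected) must vanish
    resid <- (dphi - (-2 * pi * sum(k * t_mm)) + pi) %% (2 * pi) - pi
    expect_lt(max(abs(resid)), 1e-6)
  }
})

test_that("identity and rigid translation give zero strain, uniform stretch
           gives the engineering strain", {
  sim <- sim_tagged_stack(tag_sim_config(n_frames = 2))
  sf <- strain_field(harp_phase_maps(sim$stack))
  expect_lt(max(abs(sf$err[, , 2][sf$mask])), 0.1)
  expect_lt(max(abs(sf$ecc[, , 2][sf$mask])), 0.1)

  simt <- sim_tagged_stack(tag_sim_config(
    n_frames = 2, deformation = deform_translation(0.45, -0.3)))
  sft <- strain_field(harp_phase_maps(simt$stack))
  expect_lt(max(abs(sft$err[, , 2][sft$mask])), 0.1)
  expect_lt(max(abs(sft$ecc[, , 2][sft$mask])), 0.1)

  sims <- sim_tagged_stack(tag_sim_config(
    n_frames = 2, deformation = deform_stretch(1.10)))
  sfs <- strain_field(harp_phase_maps(sims$stack))
  g <- global_strain_curves(sfs)
  expect_equal(g$err[2], 10, tolerance = 0.5)
  expect_equal(g$ecc[2], 10, tolerance = 0.5)
})

test_that("uniform stretches across the physiological range are recovered at
           zero noise and at moderate noise", {
  for (lam in c(0.85, 1.25)) {
    sim <- sim_tagged_stack(tag_sim_config(
      n_frames = 2, deformation = deform_stretch(lam)))
    g <- global_strain_curves(strain_field(harp_phase_maps(sim$stack)))
    expect_equal(g$err[2], (lam - 1) * 100, tolerance = 0.5)
    expect_equal(g$ecc[2], (lam - 1) * 100, tolerance = 0.5)
  }
  # SNR ~ 20 (signal baseline 1, noise sd 0.05)
  simn <- sim_tagged_stack(tag_sim_config(
    n_frames = 2, deformation = deform_stretch(1.10), noise_sd = 0.05,
    seed = 3))
  gn <- global_strain_curves(strain_field(harp_phase_maps(simn$stack)))
  expect_equal(gn$err[2], 10, tolerance = 1.5)
  expect_equal(gn$ecc[2], 10, tolerance = 1.5)
})

test_that("strain maps are invariant under global intensity scaling/offset
           and under swapping the tag directions", {
  sim <- sim_tagged_stack(tag_sim_config(
    n_frames = 2, deformation = deform_stretch(1.10)))
  sf1 <- strain_field(harp_phase_maps(sim$stack))
  scaled <- sim$stack
  scaled$frames <- 3.2 * scaled$frames + 0.7
  sf2 <- strain_field(harp_phase_maps(scaled))
  expect_lt(max(abs(sf1$err[, , 2][sf1$mask] - sf2$err[, , 2][sf2$mask])), 0.1)

  swapped <- sim$stack
  swapped$tag_wavevectors <- swapped$tag_wavevectors[2:1, ]
  sf3 <- strain_field(harp_phase_maps(swapped))
  expect_lt(max(abs(sf1$err[, , 2][sf1$mask] - sf3$err[, , 2][sf1$mask])), 1e-6)
  expect_lt(max(abs(sf1$ecc[, , 2][sf1$mask] - sf3$ecc[, , 2][sf1$mask])), 1e-6)
})

test_that("collinear wavevectors are rejected", {
  sim <- sim_tagged_stack(small_cfg())
  ph <- harp_phase_maps(sim$stack)
  ph$tag_wavevectors <- rbind(c(1 / 3, 0), c(2 / 3, 0))
  expect_error(strain_field(ph), "collinear")
})

test_that("sector averaging reproduces uniform fields, analytic cos(theta)
           integrals, and flags empty sectors", {
  sim <- sim_tagged_stack(tag_sim_config(
    n_frames = 2, deformation = deform_stretch(1.10)))
  sf <- strain_field(harp_phase_maps(sim$stack))
  sc <- segment_strain_curves(sf)
  expect_equal(nrow(sc), 16)
  # spatially uniform deformation: all 8 sector curves agree
  f2 <- dplyr::filter(sc, frame == 1)
  expect_lt(diff(range(f2$err)), 0.2)
  # per-frame sector mean average equals the mask mean (equal-weight check)
  g <- global_strain_curves(sf)
  w <- sapply(1:8, function(s) {
    m <- dim(sf$err)[1]
    rows <- matrix(seq_len(m), m, m); cols <- matrix(seq_len(m), m, m, byrow = TRUE)
    theta <- atan2(rows - sf$center[1], cols - sf$center[2])
    rel <- (theta - pi / 2) %% (2 * pi)
    sum(sf$mask & floor(rel / (pi / 4)) == s - 1)
  })
  expect_equal(sum(f2$err * w) / sum(w), g$err[2], tolerance = 1e-6)

  # analytic sector integrals of a cos(theta) field
  m <- dim(sf$err)[1]
  rows <- matrix(seq_len(m), m, m); cols <- matrix(seq_len(m), m, m, byrow = TRUE)
  theta <- atan2(rows - sf$center[1], cols - sf$center[2])
  synth <- sf
  synth$err[, , 1] <- cos(theta); synth$err[, , 2] <- cos(theta)
  synth$ecc <- synth$err
  sc2 <- segment_strain_curves(synth)
  b0 <- pi / 2 + (0:7) * pi / 4
  analytic <- (sin(b0 + pi / 4) - sin(b0)) / (pi / 4)
  got <- dplyr::filter(sc2, frame == 0) |> dplyr::arrange(segment)
  expect_equal(got$err, analytic, tolerance = 0.01)

  # void sector: flagged NA with warning
  void <- sf
  rel <- (theta - pi / 2) %% (2 * pi)
  void$mask[rel < pi / 4] <- FALSE
  expect_warning(sc3 <- segment_strain_curves(void), "empty sector")
  expect_true(all(is.na(dplyr::filter(sc3, segment == 1)$err)))
  expect_equal(sum(!is.na(dplyr::filter(sc3, frame == 1)$err)), 7)
})

test_that("radial deformation profiles carry analytic stretch truth", {
  # material radius R = rho_m(r): mild radial compression profile
  rho <- function(r, amp) r * (1 + 0.05 * amp * exp(-((r - 7) / 4)^2))
  sim <- sim_tagged_stack(tag_sim_config(n_frames = 2,
                                         deformation = deform_radial(rho)))
  sf <- strain_field(harp_phase_maps(sim$stack))
  # check Ecc against lambda_c - 1 = r/R - 1 at a mid-mask radius band
  m <- dim(sf$err)[1]
  delta <- sim$stack$pixel_spacing
  rows <- matrix(seq_len(m), m, m); cols <- matrix(seq_len(m), m, m, byrow = TRUE)
  rpix <- sqrt((rows - sf$center[1])^2 + (cols - sf$center[2])^2)
  rmm <- rpix * delta
  band <- sf$mask & rmm > 6.5 & rmm < 7.5
  expected <- mean(rmm[band] / rho(rmm[band], 1) - 1) * 100
  expect_equal(mean(sf$ecc[, , 2][band]), expected, tolerance = 0.3)
})
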