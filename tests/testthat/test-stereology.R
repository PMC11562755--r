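test_that("top-frame exclusion and bottom-frame inclusion are honored", {
  # sections: [-60,-30), [-30,0), [0,30), [30,60); dz = 3
  # nucleus visible ONLY at the bottom frame of section 1 (z = 0 plane,
  # shared with the top frame of section 2)
  g <- manual_ganglion(z = -1, nucleus_radius = 2)
  ser <- cut_sections(g, thickness = 30, dz = 3, axial_shrinkage = 1,
                      thickness_noise = 0, phase = 0, seed = 1)
  expect_equal(count_section(build_stack(ser, 1, g)), 1)  # bottom frame counts
  expect_equal(count_section(build_stack(ser, 2, g)), 0)  # top frame excluded

  # nucleus visible only in the top frame of its own section contributes 0
  # there but is caught by the section above through the shared plane
  g2 <- manual_ganglion(z = 1, nucleus_radius = 2)
  expect_equal(count_section(build_stack(ser, 2, g2)), 0)
  expect_equal(count_section(build_stack(ser, 1, g2)), 1)

  # interior nucleus counted once in its own section
  g3 <- manual_ganglion(z = 15, nucleus_radius = 4)
  expect_equal(count_section(build_stack(ser, 2, g3)), 1)
  expect_equal(sum(sapply(0:3, function(i)
    count_section(build_stack(ser, i, g3)))), 1)

  st <- build_stack(ser, 2, g3)
  st$plane_zs <- st$plane_zs[1]
  expect_error(count_section(st), "fewer than 2 planes")
})

test_that("dissector counts over all slides equal the brute-force oracle", {
  for (seed in c(7, 8)) {
    g <- generate_ganglion(100, semi_axes = c(100, 100, 120),
                           subpops = one_pop(), seed = seed)
    ser <- cut_sections(g, thickness = 30, dz = 3, axial_shrinkage = 1,
                        thickness_noise = 0, seed = seed + 100)
    total <- dissector_count(g, ser, slide = NULL, collected_only = FALSE)
    expect_identical(total, brute_dissector_total(g, ser))
    # every nucleus (diameter > dz, inside the tissue) is counted exactly once
    expect_gte(total, 99)
    expect_lte(total, 100)
  }
})

test_that("section volume and Cavalieri arithmetic are exact", {
  expect_equal(section_volume(30, 100000), 3.0e6)
  expect_equal(section_volume(26, 0), 0)
  expect_equal(section_volume(25.5, 214000), 5.457e6)
  expect_error(section_volume(0, 10), "> 0")

  expect_equal(cavalieri_volume(200000, 30, 40), 2.4e8)
  expect_equal(cavalieri_volume(0, 30, 40), 0)
  expect_error(cavalieri_volume(200000, 30, 0), "positive integer")
  expect_error(cavalieri_volume(200000, 30, 2.5), "positive integer")
})

test_that("Cavalieri volume from random-phase sectioning is within 10%", {
  g <- manual_ganglion(z = 0, nucleus_radius = 4,
                       semi_axes = c(300, 250, 400))
  v_true <- 4 / 3 * pi * 300 * 250 * 400
  for (seed in 1:5) {
    ser <- cut_sections(g, thickness = 30, dz = 3, axial_shrinkage = 1,
                        thickness_noise = 0, seed = seed)
    coll <- ser$sections[ser$sections$mid_plane_area > 0, ]
    v_hat <- cavalieri_volume(mean(coll$mid_plane_area), 30, nrow(coll))
    expect_lt(abs(v_hat / v_true - 1), 0.10)
  }
})

test_that("estimate_total combines density and volume as specified", {
  # homogeneous case, exact
  est <- estimate_total(counts = rep(50, 4), thicknesses = rep(30, 4),
                        areas = rep(1e5, 4), l = 20)
  expect_equal(est$N_v_bar, 50 / 3e6, tolerance = 1e-12)
  expect_equal(est$V_DRG, 6.0e7)
  expect_equal(est$N_DRG, 1000, tolerance = 1e-9)

  # N_DRG = N_v_bar * V_DRG arithmetic
  est2 <- estimate_total(counts = 99, thicknesses = 30, areas = 1e5, l = 80)
  expect_equal(est2$N_v_bar, 3.3e-5, tolerance = 1e-12)
  expect_equal(est2$V_DRG, 2.4e8)
  expect_equal(est2$N_DRG, 7920, tolerance = 1e-9)

  # empty sections -> zero estimate
  est3 <- estimate_total(counts = rep(0, 4), thicknesses = rep(30, 4),
                         areas = rep(1e5, 4), l = 20)
  expect_equal(est3$N_DRG, 0)

  expect_error(estimate_total(counts = 5, thicknesses = 30, areas = 0, l = 4),
               "zero section volume")
  expect_error(estimate_total(counts = c(1, 2), thicknesses = 30,
                              areas = c(1, 1), l = 4), "aligned")

  # pooled alternative: sum(N)/sum(V)
  estp <- estimate_total(counts = c(10, 30), thicknesses = c(30, 30),
                         areas = c(1e5, 3e5), l = 10, pooled = TRUE)
  expect_equal(estp$N_v_bar, 40 / (3e6 + 9e6))
})

test_that("scale equivariance: x2 linear scale gives x8 volume, same count", {
  g <- generate_ganglion(2000, semi_axes = c(150, 120, 180),
                         subpops = one_pop(), seed = 31)
  g2 <- g
  g2$semi_axes <- 2 * g$semi_axes
  g2$neurons[c("x", "y", "z")] <- 2 * g$neurons[c("x", "y", "z")]
  g2$neurons$soma_radius <- 2 * g$neurons$soma_radius
  g2$neurons$nucleus_radius <- 2 * g$neurons$nucleus_radius

  ser <- cut_sections(g, thickness = 30, dz = 3, axial_shrinkage = 1,
                      thickness_noise = 0, phase = 10, seed = 1)
  ser2 <- cut_sections(g2, thickness = 60, dz = 6, axial_shrinkage = 1,
                       thickness_noise = 0, phase = 20, seed = 1)
  est <- estimate_ganglion(g, ser)
  est2 <- estimate_ganglion(g2, ser2)
  expect_equal(est2$V_DRG, 8 * est$V_DRG, tolerance = 1e-9)
  expect_equal(est2$N_DRG, est$N_DRG, tolerance = 1e-9)
  expect_equal(est2$per_section$N_sec, est$per_section$N_sec)
})

test_that("counts are invariant to axial shrinkage", {
  for (shrink in c(1.0, 0.8, 0.6)) {
    g <- generate_ganglion(500, semi_axes = c(120, 100, 150),
                           subpops = one_pop(), seed = 41)
    ser <- cut_sections(g, thickness = 30, dz = 3, axial_shrinkage = shrink,
                        thickness_noise = 0, seed = 42)
    total <- dissector_count(g, ser, slide = NULL, collected_only = FALSE)
    expect_identical(total, brute_dissector_total(g, ser))
    expect_gte(total, 495)  # ~all nuclei seen regardless of shrinkage
  }
})
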