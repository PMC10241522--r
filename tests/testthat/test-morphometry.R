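test_that("Sholl profiles match simple geometry and the dense oracle", {
  cab <- generate_cable(100, 1, 11)
  sh <- sholl(cab, seq(20, 200, by = 20))
  expect_equal(sh$crossings, c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))

  # bifurcation at 50 um into two 50 um daughters: two crossings at 60-100
  nodes <- data.frame(
    id = 1:5, type = 3L,
    x = c(0, 50, 50 + 50 * cos(0.4), 50, 50 + 50 * cos(-0.4)),
    y = c(0, 0, 50 * sin(0.4), 0, 50 * sin(-0.4)),
    z = 0, radius = 1, parent = c(-1L, 1L, 2L, -0L, 2L))
  nodes <- nodes[-4, ]; nodes$id <- 1:4; nodes$parent <- c(-1L, 1L, 2L, 2L)
  m <- swc_morphology(nodes)
  sh2 <- sholl(m, c(40, 60, 80, 95))
  expect_equal(sh2$crossings, c(1, 2, 2, 2))

  # random trees agree with the brute-force resampling counter
  for (seed in c(2, 8)) {
    gen <- generate_swc(morph_spec(seed = seed, n_bifurcations = 3))
    radii <- seq(20, 200, by = 20)
    expect_equal(sholl(gen$morphology, radii)$crossings,
                 oracle_sholl(gen$morphology, radii, step = 0.05)$crossings)
  }
})

test_that("spine densities match planted values and window recounts", {
  sc <- generate_spiny_cable(100, 1, 50)
  rolled <- spine_density(sc$morphology, "rolling")
  expect_equal(unique(round(rolled$profile[[1]], 12)), 0.5)
  expect_equal(rolled$density, 0.5)

  # 12 spines on a 30 um tertiary stretch -> 0.4 spines/um
  gen <- generate_swc(morph_spec(spine_density = 0.4, seed = 4))
  seg <- spine_density(gen$morphology, "segment")
  expect_equal(seg$density, 0.4, tolerance = 1e-9)
  expect_true(all(seg$per_segment$order >= 2))
  expect_lte(nrow(seg$per_segment), 4)

  # windowed counts match a brute-force recount on every segment
  gen2 <- generate_swc(morph_spec(spine_density = 0.9, seed = 6))
  segs <- arcoephys:::build_segments(gen2$morphology)
  roll <- spine_density(gen2$morphology, "rolling")
  for (si in seq_along(segs)) {
    counts <- oracle_rolling_counts(gen2$morphology, segs[[si]], 20)
    own <- arcoephys:::node_ownership(segs[[si]])
    w <- min(20, length(segs[[si]]$nodes))
    expected <- counts / vapply(seq_along(counts), function(i)
      sum(own[i:(i + w - 1)]), numeric(1))
    expect_equal(roll$profile[[si]], expected)
  }

  # exclusions: a bare cable with 4 spines (soma-adjacent, < 10) drops out
  sc2 <- generate_spiny_cable(100, 1, 4)
  r2 <- spine_density(sc2$morphology, "rolling")
  expect_true(all(r2$per_segment$excluded ==
                    (r2$per_segment$order == 0 &
                       r2$per_segment$n_spines < 10) |
                    r2$per_segment$length < 20))
  expect_error(spine_density(generate_cable(50, 1), "rolling"),
               "no spine")
})

test_that("spine geometry matches closed forms and the naive loop", {
  # sphere r 0.5 with neck length 1: 4 pi 0.25 + 2 pi 0.066 * 1
  nodes <- data.frame(id = 1:3, type = c(3L, 3L, 5L),
                      x = c(0, 10, 5), y = c(0, 0, 1.5), z = 0,
                      radius = c(1, 1, 0.5), parent = c(-1L, 1L, 1L))
  # attachment node 1 at origin; spine at (5, 1.5): distance sqrt(27.25)
  # adjust to give exactly neck length 1: place spine at distance 1.5
  nodes$x[3] <- 0; nodes$y[3] <- 1.5
  m <- swc_morphology(nodes, spines = list(list(nodes = 3L,
                                                multi = FALSE)))
  g <- spine_geometry(m)
  expect_equal(g$area, 4 * pi * 0.25 + 2 * pi * 0.066 * 1,
               tolerance = 1e-12)
  expect_equal(g$volume, 4 / 3 * pi * 0.5^3, tolerance = 1e-12)

  # two-point spine, both r 0.3, 1 um apart: 2 pi 0.3 * 1 + 2 pi 0.09
  nodes2 <- rbind(nodes[1:2, ],
                  data.frame(id = 3:4, type = 5L, x = c(0, 0),
                             y = c(1, 2), z = 0, radius = 0.3,
                             parent = c(1L, 3L)))
  m2 <- swc_morphology(nodes2, spines = list(list(nodes = c(3L, 4L),
                                                  multi = TRUE)))
  g2 <- spine_geometry(m2)
  expect_equal(g2$area, 2 * pi * 0.3 * 1 + 2 * pi * 0.09,
               tolerance = 1e-12)
  expect_equal(g2$volume, 2 * 4 / 3 * pi * 0.3^3, tolerance = 1e-12)

  # generated population totals match the independent recomputation
  gen <- generate_swc(morph_spec(seed = 12))
  tot <- spine_geometry(gen$morphology)
  orc <- oracle_spine_totals(gen$morphology)
  expect_equal(sum(tot$area), orc$area, tolerance = 1e-12)
  expect_equal(sum(tot$volume), orc$volume, tolerance = 1e-12)
  expect_equal(sum(tot$area), gen$ground_truth$spine_area_total,
               tolerance = 1e-9)
})

test_that("dendrite geometry: cylinder, subdivision and union bounds", {
  cab <- generate_cable(50, 1, 11)
  g <- dendrite_geometry(cab, voxel_size = 0.1)
  expect_equal(g$length, 50)
  expect_equal(g$area, 2 * pi * 1 * 50, tolerance = 1e-12)
  expect_equal(g$volume, pi * 50, tolerance = 0.02)

  # same cable split into many collinear nodes: identical length and area
  g2 <- dendrite_geometry(generate_cable(50, 1, 101), voxel_size = 0.2)
  expect_equal(g2$length, 50, tolerance = 1e-9)
  expect_equal(g2$area, 2 * pi * 50, tolerance = 1e-9)

  # voxel volume error shrinks with resolution
  e1 <- abs(dendrite_geometry(cab, voxel_size = 0.4)$volume - pi * 50)
  e2 <- abs(dendrite_geometry(cab, voxel_size = 0.1)$volume - pi * 50)
  expect_lt(e2, e1)

  # Y junction: union volume does not double-count the shared wedge
  nodes <- data.frame(id = 1:3, type = 3L, x = c(0, 10, 10),
                      y = c(0, 8, -8), z = 0, radius = 1,
                      parent = c(-1L, 1L, 1L))
  gy <- dendrite_geometry(swc_morphology(nodes), voxel_size = 0.1)
  branch <- pi * 1^2 * sqrt(10^2 + 8^2)
  expect_lt(gy$volume, 2 * branch)
  expect_gt(gy$volume, 1.8 * branch)
})

test_that("soma triangulation converges to the analytic sphere", {
  st <- generate_soma_stack(10, slice_thickness = 0.25)
  sg <- soma_geometry(st)
  expect_equal(sg$area, 4 * pi * 100, tolerance = 0.03)
  expect_equal(sg$volume, 4 / 3 * pi * 1000, tolerance = 0.03)

  # errors decrease monotonically with slice thickness
  errs <- vapply(c(2, 1, 0.5, 0.25), function(th) {
    s <- soma_geometry(generate_soma_stack(10, slice_thickness = th))
    abs(s$volume - 4 / 3 * pi * 1000)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))

  # dendrite attachment correction is exactly pi r^2 per dendrite
  sg1 <- soma_geometry(st, first_dendrite_radius = 1)
  expect_equal(sg$area - sg1$area, pi)

  expect_error(soma_geometry(structure(list(slices = st$slices[1],
                                            slice_thickness = 0.25),
                                       class = "contour_stack")),
               "two")
})

test_that("geometry is invariant under rigid motion", {
  gen <- generate_swc(morph_spec(seed = 13))
  m <- gen$morphology
  m2 <- rotate_morph(m)
  g1 <- dendrite_geometry(m, voxel_size = 0.25)
  g2 <- dendrite_geometry(m2, voxel_size = 0.25)
  expect_equal(g2$length, g1$length, tolerance = 1e-9)
  expect_equal(g2$area, g1$area, tolerance = 1e-9)
  expect_equal(g2$volume, g1$volume, tolerance = 0.02)
  s1 <- spine_geometry(m); s2 <- spine_geometry(m2)
  expect_equal(s2$area, s1$area, tolerance = 1e-9)
  # 3D Sholl is rotation-invariant about the root (radii chosen off the
  # node lattice so boundary ties cannot flip under rounding)
  radii <- seq(20, 160, by = 20) + 0.37
  m3 <- rotate_morph(m, shift = c(0, 0, 0))
  expect_equal(sholl(m3, radii, mode = "3D")$crossings,
               sholl(m, radii, mode = "3D")$crossings)
})

test_that("morphometry summaries combine compartments correctly", {
  rep_ <- summarize_morphometry(
    soma = list(area = 879.7, volume = 500),
    dendrite = list(length = 3000, area = 5047.7, volume = 2000),
    spines = list(area = 638.7, volume = 100),
    shrinkage = 0.2, shrinkage_mode = "areal")
  expect_equal(rep_$total_area_adjusted, 8207.625, tolerance = 1e-6)
  expect_equal(rep_$surface_to_volume, 6566.1 / 2600, tolerance = 1e-9)

  # sphere r = 3: surface to volume = 1
  rep2 <- summarize_morphometry(
    soma = list(area = 4 * pi * 9, volume = 4 / 3 * pi * 27),
    shrinkage_mode = "none")
  expect_equal(rep2$surface_to_volume, 1, tolerance = 1e-12)

  # missing compartments yield explicit NAs
  expect_true(is.na(rep2$dendrite_area))
  expect_true(is.na(rep2$spine_count))

  # round trip against the generator ground truth
  gen <- generate_swc(morph_spec(seed = 14))
  dg <- dendrite_geometry(gen$morphology, voxel_size = 0.2)
  expect_equal(dg$length, gen$ground_truth$dendrite_length,
               tolerance = 1e-9)
  expect_equal(dg$area, gen$ground_truth$dendrite_area, tolerance = 1e-9)
  expect_equal(dg$volume, gen$ground_truth$dendrite_volume,
               tolerance = 0.02)
})
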