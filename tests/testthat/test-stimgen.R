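geom <- display_geometry()

test_that("pixels per degree follows the screen geometry", {
  expect_equal(px_per_degree(geom), 25.92, tolerance = 0.001)
  # 1 px/cm at the distance where 1 deg spans 1 cm
  g1 <- display_geometry(screen_width_cm = 10, screen_px_w = 10,
                         screen_px_h = 10, viewing_distance_cm = 57.29)
  expect_equal(px_per_degree(g1), 1.0, tolerance = 1e-4)
  g2 <- display_geometry(viewing_distance_cm = 116)
  expect_equal(px_per_degree(g2) / px_per_degree(geom), 2, tolerance = 1e-4)
  expect_error(display_geometry(screen_width_cm = 0), "positive")
  expect_error(display_geometry(viewing_distance_cm = -1), "positive")
})

test_that("hexagram vertices form two equilateral triangles of edge r*sqrt(3)", {
  r <- 3.2
  v <- hexagram_vertices(r)
  expect_equal(dim(v), c(6, 2))
  expect_equal(sqrt(rowSums(v^2)), rep(r, 6))
  edge <- function(i, j) sqrt(sum((v[i, ] - v[j, ])^2))
  for (tri in list(c(1, 3, 5), c(2, 4, 6)))  # upright / inverted triangles
    expect_equal(c(edge(tri[1], tri[2]), edge(tri[2], tri[3]),
                   edge(tri[3], tri[1])), rep(r * sqrt(3), 3))
  expect_equal(unname(hexagram_vertices(6 / sqrt(3))[1, 2]) * sqrt(3), 6,
               tolerance = 1e-12)  # default radius implies a 6-deg triangle
  expect_equal(unname(hexagram_vertices(1)[1, ]), c(0, 1), tolerance = 1e-12)
  expect_error(hexagram_vertices(0), "positive")
})

test_that("mixed displays put black at the inverted and white at the upright vertices", {
  sp <- make_stimulus_spec("mixed", 0.5, "up")
  pol <- vapply(sp$kanizsa$inducers, `[[`, character(1), "polarity")
  ys <- vapply(sp$kanizsa$inducers, function(i) i$center_deg[2], numeric(1))
  # vertex order follows polar angle 90 + 60k: even k upright (white)
  expect_equal(pol, rep(c("white", "black"), 3))
  # top vertex is white and its jaw bisector points straight down
  expect_equal(pol[which.max(ys)], "white")
  expect_equal(sp$kanizsa$inducers[[which.max(ys)]]$jaw_heading_deg, 270)
  # every jaw faces the figure center
  for (ind in sp$kanizsa$inducers) {
    to_center <- atan2(-ind$center_deg[2], -ind$center_deg[1]) * 180 / pi
    ang_diff <- abs(((ind$jaw_heading_deg - to_center + 180) %% 360) - 180)
    expect_lt(ang_diff, 1e-9)
  }
  hb <- make_stimulus_spec("homog_black", 0.1, "down")
  expect_true(all(vapply(hb$kanizsa$inducers, `[[`, character(1),
                         "polarity") == "black"))
  expect_equal(hb$match$orientation, "down")
  expect_error(make_stimulus_spec("mixed", 0.3, "up"), "blur_sigma_deg")
  expect_error(make_stimulus_spec("speckled", 0.5, "up"))
})

test_that("unblurred Kanizsa renders are exact where no surface exists", {
  img <- render_kanizsa(kanizsa_spec("homog_black", 0.1), geom, blur = FALSE)
  v <- img$values
  expect_true(all(v >= 0 & v <= 20))  # black pacmen on gray, nothing brighter
  n <- nrow(v)
  expect_equal(v[(n + 1) %/% 2, (n + 1) %/% 2], 20)  # illusory center is background
  # pixel mass at exactly 0 matches the pacman area (5/6 disc each)
  pred <- 6 * (300 / 360) * pi * 1.5^2 * img$px_per_deg^2
  expect_equal(sum(v == 0) / pred, 1, tolerance = 0.05)
  # polarity swap maps L -> 40 - L exactly (anti-aliasing included)
  imgw <- render_kanizsa(kanizsa_spec("homog_white", 0.1), geom, blur = FALSE)
  expect_equal(imgw$values, 40 - v, tolerance = 1e-12)
})

test_that("the Kanizsa image ignores the cue and respects hexagram symmetry", {
  up <- make_stimulus_spec("mixed", 0.2, "up")$kanizsa
  dn <- make_stimulus_spec("mixed", 0.2, "down")$kanizsa
  expect_identical(up, dn)  # cue changes only the matching display
  # rotating by 60 deg and swapping polarity reproduces the original spec
  rot <- render_kanizsa(up, geom, blur = FALSE)
  swapped <- up
  swapped$inducers <- lapply(up$inducers, function(ind) {
    ang <- atan2(ind$center_deg[2], ind$center_deg[1]) + pi / 3
    r <- sqrt(sum(ind$center_deg^2))
    inducer_spec(c(r * cos(ang), r * sin(ang)),
                 if (ind$polarity == "black") "white" else "black",
                 jaw_heading_deg = ind$jaw_heading_deg + 60)
  })
  swapped_img <- render_kanizsa(swapped, geom, blur = FALSE)
  expect_equal(swapped_img$values, rot$values, tolerance = 1e-9)
})

test_that("Gaussian blur preserves bounds, mass, and the sigma = 0 identity", {
  img <- render_kanizsa(kanizsa_spec("mixed", 0.5), geom, blur = FALSE)
  expect_identical(apply_blur(img, 0), img)
  b <- apply_blur(img, 0.5)
  expect_true(all(b$values >= 0 & b$values <= 40))
  expect_equal(mean(b$values) / mean(img$values), 1, tolerance = 1e-3)
  expect_error(apply_blur(img, -0.1), ">= 0")
})

test_that("edge-profile fitting recovers rendered blur", {
  s <- 0.5
  step <- make_step_edge(geom, extent_deg = 16 * s + 4)
  est <- estimate_edge_sigma(apply_blur(step, s), fit_halfwidth_deg = 4 * s + 2)
  expect_equal(est, s, tolerance = 0.05)
  # a hard edge is sharp at the sub-pixel scale
  expect_lt(estimate_edge_sigma(make_step_edge(geom)), 0.05)
  flat <- luminance_image(matrix(20, 64, 64), px_per_degree(geom))
  expect_error(estimate_edge_sigma(flat), "gradient")
})

test_that("matching display composites a calibrated triangle on filtered noise", {
  sp <- match_spec("up", 30, 0.2, noise_seed = 42)
  img <- render_matching(sp, geom)
  expect_true(all(img$values >= 0 & img$values <= 40))
  expect_equal(max(img$values), 30)  # sharp triangle keeps its luminance
  # a zero-contrast triangle leaves the field mean at the background level
  m0 <- render_matching(match_spec("down", 20, 0.2, noise_seed = 9), geom)
  expect_equal(mean(m0$values), 20, tolerance = 0.5)
  expect_equal(pse_to_weber(20, 20), 0)
  # same seed reproduces the identical image; new seed does not
  img2 <- render_matching(sp, geom)
  expect_identical(img$values, img2$values)
  img3 <- render_matching(match_spec("up", 30, 0.2, noise_seed = 43), geom)
  expect_false(identical(img$values, img3$values))
  # the triangle mask itself mirrors between orientations
  xs <- seq(-4, 4, length.out = 161)
  up <- kanizsaPSE:::.triangle_coverage(6, "up", xs, xs)
  dn <- kanizsaPSE:::.triangle_coverage(6, "down", xs, xs)
  # agree everywhere except ties exactly on the mirrored boundary samples
  expect_lt(mean(up[nrow(up):1, ] != dn), 0.002)
  expect_error(match_spec("up", 45, 0.2), "\\[0, 40\\]")
  # truncated-Gaussian noise stays in range with the right mean
  mg <- render_matching(match_spec("up", 20, 0.1, noise_dist = "gaussian",
                                   noise_seed = 5), geom)
  expect_true(all(mg$values >= 0 & mg$values <= 40))
  expect_equal(mean(mg$values), 20, tolerance = 0.5)
})

test_that("stimulus export round-trips through PNG and YAML", {
  img <- render_kanizsa(kanizsa_spec("mixed", 0.1), geom, extent_deg = 6)
  f <- withr::local_tempfile(fileext = ".png")
  write_stimulus_png(img, f)
  back <- png::readPNG(f) * 40
  expect_equal(back, img$values, tolerance = 40 / 255)
  sp <- make_stimulus_spec("mixed", 0.5, "up", triangle_lum = 24)
  y <- withr::local_tempfile(fileext = ".yaml")
  write_stimulus_yaml(sp, y)
  raw <- yaml::read_yaml(y)
  expect_equal(raw$units$luminance, "cd/m^2")
  expect_equal(raw$match$triangle_lum, 24)
  expect_equal(length(raw$kanizsa$inducers), 6)
})
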