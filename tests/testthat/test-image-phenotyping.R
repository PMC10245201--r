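tab1 <- generate_phenotypes(two_pop_study(seed = 4))
rec1 <- tab1[1, ]

test_that("colour correction recovers identity and inverts a known cast", {
  img <- render_frog(rec1)
  corrected <- color_correct(img)
  cal <- attr(corrected, "calibration")
  expect_equal(cal$matrix, diag(3), tolerance = 1e-8)
  expect_true(all(cal$residuals < 1e-6))

  img8 <- render_frog(rec1, render_spec(colour_cast = scaled_cast(0.8)))
  corr8 <- color_correct(img8)
  for (p in corr8$patches) {
    rc <- p$rect
    obs <- apply(corr8$raster[(rc[1]:rc[2]) + 1, (rc[3]:rc[4]) + 1, ,
                              drop = FALSE], 3, mean)
    expect_true(all(abs(obs - p$true_rgb) < 2 / 255))
  }
  # a non-diagonal in-gamut cast is also inverted at the patches
  M <- matrix(c(0.8, 0.08, 0.02, 0.05, 0.75, 0.1, 0.02, 0.05, 0.7), 3, 3)
  imgM <- render_frog(rec1, render_spec(colour_cast = colour_cast(M, c(0.02, 0.01, 0.03))))
  corrM <- color_correct(imgM)
  for (p in corrM$patches) {
    rc <- p$rect
    obs <- apply(corrM$raster[(rc[1]:rc[2]) + 1, (rc[3]:rc[4]) + 1, ,
                              drop = FALSE], 3, mean)
    expect_true(all(abs(obs - p$true_rgb) < 2 / 255))
  }
})

test_that("fewer than 4 patches is an insufficient-calibration error", {
  img <- render_frog(rec1)
  img$patches <- img$patches[1:3]
  expect_error(color_correct(img), class = "insufficient_calibration")
})

test_that("degenerate (collinear in RGB) patches are rejected", {
  img <- render_frog(rec1)
  # grey-axis-only patches: observed colours span a 1-D affine subspace
  greys <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  for (i in seq_along(greys)) {
    rc <- img$patches[[i]]$rect
    for (ch in 1:3)
      img$raster[(rc[1]:rc[2]) + 1, (rc[3]:rc[4]) + 1, ch] <- greys[i]
    img$patches[[i]]$true_rgb <- rep(greys[i], 3)
  }
  img$patches <- img$patches[1:5]
  expect_error(color_correct(img), class = "degenerate_patch")
})

test_that("region colour: definitional cases and hue wrap-around", {
  img <- flat_image(matrix(c(1, 0, 0), 1, 3, byrow = TRUE))
  rc <- extract_region_color(img, "head")
  expect_equal(rc$hue, 0)
  expect_equal(rc$saturation, 1)

  # half hue 350, half hue 10: circular mean 0, not 180
  cols <- rbind(hsb_rgb(350, 0.8), hsb_rgb(350, 0.8),
                hsb_rgb(10, 0.8), hsb_rgb(10, 0.8))
  img2 <- flat_image(cols)
  cc <- extract_region_color(img2, "head")
  # 8-bit quantization of the rendered colours shifts hue by < 0.5 degree
  expect_lt(min(cc$hue, 360 - cc$hue), 0.5)
  am <- extract_region_color(img2, "head", hue_mode = "arithmetic")
  expect_equal(am$hue, 180, tolerance = 0.5)

  # all-black region
  img3 <- flat_image(matrix(0, 2, 3))
  expect_error(extract_region_color(img3, "head"),
               class = "no_pattern_pixels")
})

test_that("extracted colour matches generator ground truth (round trip)", {
  tab <- generate_phenotypes(two_pop_study(n = 5, seed = 9))
  for (i in seq_len(nrow(tab))) {
    img <- render_frog(tab[i, ])
    rec <- phenotype_image(img, tab$pattern_class[i])
    expect_lt(hue_difference(rec$colour_head$hue, tab$hue_head[i]), 2)
    expect_lt(abs(rec$colour_head$saturation - tab$sat_head[i]), 0.02)
    expect_lt(hue_difference(rec$colour_back$hue, tab$hue_dorsum[i]), 2)
    expect_lt(abs(rec$colour_back$saturation - tab$sat_dorsum[i]), 0.02)
    expect_lt(hue_difference(rec$colour_limb$hue, tab$hue_limb[i]), 2)
    expect_identical(rec$dorsal_transitions_left,
                     as.integer(tab$dorsal_transitions_left[i]))
    expect_identical(rec$dorsal_transitions_right,
                     as.integer(tab$dorsal_transitions_right[i]))
    expect_identical(rec$limb_transitions, as.integer(tab$limb_transitions[i]))
  }
})

test_that("transition counting: label-change semantics and reversal invariance", {
  # a 1 x 5 strip: black, yellow, black, yellow, black -> 4 transitions
  cols <- rbind(c(0, 0, 0), c(1, 1, 0), c(0, 0, 0), c(1, 1, 0), c(0, 0, 0))
  img <- flat_image(cols, region = 2L)
  tr <- transect(data.frame(x = c(0, 4), y = c(1, 1)), "dorsal_left")
  expect_identical(count_transitions(img, tr), 4L)
  rev_tr <- transect(data.frame(x = c(4, 0), y = c(1, 1)), "dorsal_left")
  expect_identical(count_transitions(img, rev_tr), 4L)

  # uniform (diffuse) transect -> 0
  img0 <- flat_image(matrix(rep(c(1, 0.5, 0), 5), 5, 3, byrow = TRUE),
                     region = 2L)
  expect_identical(count_transitions(img0, tr), 0L)

  # leaving the mask is a geometry error
  bad <- transect(data.frame(x = c(0, 4), y = c(0, 0)), "dorsal_left")
  expect_error(count_transitions(img, bad), class = "geometry_error")
})

test_that("reversal invariance holds on rendered transects", {
  img <- render_frog(rec1)
  trs <- warnsig:::layout_transects(img$landmarks)
  for (t1 in trs) {
    rev_t <- transect(t1$points[rev(seq_len(nrow(t1$points))), ], t1$role)
    expect_identical(count_transitions(img, t1),
                     count_transitions(img, rev_t))
  }
})

test_that("head-pattern alignment is invariant to translation and rotation", {
  img <- render_frog(rec1)
  template <- default_template()
  base <- align_head_pattern(img, template, grid_size = 64)
  expect_true(all(base %in% c(0L, 1L)))

  shifted <- translate_image(img, 10, 5)
  expect_identical(align_head_pattern(shifted, template, grid_size = 64),
                   base)

  rotated <- rotate_image(img, 10)
  rot <- align_head_pattern(rotated, template, grid_size = 64)
  expect_lt(mean(rot != base), 0.05)
})

test_that("collinear landmarks are an alignment error", {
  img <- render_frog(rec1)
  img$landmarks$x <- 70
  expect_error(align_head_pattern(img, default_template()),
               class = "alignment_error")
})

test_that("an empty hindlimb mask propagates a no-pattern-pixels error", {
  img <- render_frog(rec1)
  img$mask[img$mask == 3L] <- 0L
  expect_error(phenotype_image(img, rec1$pattern_class),
               class = "no_pattern_pixels")
})

test_that("colour extraction tolerates any invertible in-gamut cast after correction", {
  casts <- list(scaled_cast(0.85),
                colour_cast(matrix(c(0.9, 0.05, 0, 0.05, 0.85, 0.05,
                                     0, 0.05, 0.9), 3, 3), c(0.02, 0, 0.01)))
  for (cast in casts) {
    img <- color_correct(render_frog(rec1, render_spec(colour_cast = cast)))
    rec <- phenotype_image(img, rec1$pattern_class)
    expect_lt(hue_difference(rec$colour_head$hue, rec1$hue_head), 2)
    expect_lt(abs(rec$colour_head$saturation - rec1$sat_head), 0.02)
  }
})
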