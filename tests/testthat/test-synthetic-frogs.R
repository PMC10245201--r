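test_that("zero-variance populations yield identical colour records", {
  spec <- two_pop_study(n = 4, hue_sd = 0, sat_sd = 0, band_sd = 0)
  tab <- generate_phenotypes(spec)
  one <- tab[tab$species == "imitator", ]
  for (col in c("hue_head", "sat_head", "hue_dorsum", "sat_dorsum",
                "hue_limb", "sat_limb", "dorsal_bands", "limb_bands"))
    expect_equal(length(unique(one[[col]])), 1L, info = col)
})

test_that("full convergence pull equalizes generative means", {
  spec <- two_pop_study(convergence = 1)
  tab <- generate_phenotypes(spec)
  m <- attr(tab, "generative_means")
  expect_equal(m[["variabilis@sauce"]]$hue$head, m[["imitator@sauce"]]$hue$head)
  expect_equal(m[["variabilis@sauce"]]$sat$dorsum,
               m[["imitator@sauce"]]$sat$dorsum)
  expect_equal(m[["variabilis@sauce"]]$dorsal_bands,
               m[["imitator@sauce"]]$dorsal_bands)
  # no pull: means stay at the spec values
  spec0 <- two_pop_study(convergence = 0)
  m0 <- attr(generate_phenotypes(spec0), "generative_means")
  expect_equal(m0[["variabilis@sauce"]]$hue$head, 120)
})

test_that("sample circular means track generative means (hue 30 vs 120)", {
  spec <- two_pop_study(n = 20, hue1 = 30, hue2 = 120, hue_sd = 5, seed = 1)
  tab <- generate_phenotypes(spec)
  for (pop in list(c("imitator", 30), c("variabilis", 120))) {
    h <- tab$hue_head[tab$species == pop[1]]
    # independent oracle: circular mean by direct formula on the sample
    cm <- (atan2(mean(sin(h * pi / 180)), mean(cos(h * pi / 180))) *
             180 / pi) %% 360
    expect_lt(hue_difference(cm, as.numeric(pop[2])), 3)
    expect_equal(circular_mean(h), cm, tolerance = 1e-12)
  }
})

test_that("generation is deterministic and duplicate keys are rejected", {
  t1 <- generate_phenotypes(two_pop_study(seed = 7))
  t2 <- generate_phenotypes(two_pop_study(seed = 7))
  expect_identical(t1, t2)
  t3 <- generate_phenotypes(two_pop_study(seed = 8))
  expect_false(identical(t1$hue_head, t3$hue_head))
  p <- two_pop_study()$populations[[1]]
  expect_error(study_spec(list(p, p)), class = "configuration_error")
})

test_that("rendering is deterministic and controls transitions exactly", {
  tab <- generate_phenotypes(two_pop_study(seed = 3))
  rec <- tab[1, ]
  i1 <- render_frog(rec); i2 <- render_frog(rec)
  expect_identical(i1$raster, i2$raster)
  # jitter seed changes pixels but never the transition counts
  i3 <- render_frog(rec, seed = 999)
  p1 <- phenotype_image(i1, rec$pattern_class)
  p3 <- phenotype_image(i3, rec$pattern_class)
  expect_identical(p1$dorsal_transitions_left, p3$dorsal_transitions_left)
  expect_identical(p1$dorsal_transitions_right, p3$dorsal_transitions_right)
  expect_identical(p1$limb_transitions, p3$limb_transitions)
})

test_that("reference patches render true RGB under the identity cast", {
  tab <- generate_phenotypes(two_pop_study())
  rs <- render_spec()
  img <- render_frog(tab[1, ], rs)
  for (p in rs$patches) {
    rc <- p$rect
    obs <- apply(img$raster[(rc[1]:rc[2]) + 1, (rc[3]:rc[4]) + 1, ,
                            drop = FALSE], 3, mean)
    expect_equal(obs, p$true_rgb, tolerance = 1e-12)
  }
  # 0.8-scaled cast: rendered patch = 0.8 x true RGB (all within gamut)
  img8 <- render_frog(tab[1, ], render_spec(colour_cast = scaled_cast(0.8)))
  for (p in rs$patches) {
    rc <- p$rect
    obs <- apply(img8$raster[(rc[1]:rc[2]) + 1, (rc[3]:rc[4]) + 1, ,
                             drop = FALSE], 3, mean)
    expect_equal(obs, 0.8 * p$true_rgb, tolerance = 1e-12)
  }
})

test_that("over-large band counts are a render error", {
  tab <- generate_phenotypes(two_pop_study())
  rec <- tab[1, ]; rec$dorsal_bands <- 60L
  expect_error(render_frog(rec), class = "render_error")
})

test_that("Var grows with sds; partner centroid distance shrinks with convergence", {
  # the focal population's sds scale with identical seeds while a second,
  # widely spread population pins each characteristic's normalization
  # maximum, so the focal Var must not decrease; band counts are
  # integer-rounded (non-monotone pairwise), so their sd is held at 0
  var_of <- function(sd_scale) {
    p1 <- population_spec("imitator", "sauce", 8,
      hue_mean = 45, hue_sd = 5 * sd_scale, sat_mean = 0.85,
      sat_sd = 0.02 * sd_scale,
      dorsal_band_mean = 3, dorsal_band_sd = 0,
      limb_band_mean = 2, limb_band_sd = 0, pattern_class = "spotted",
      head_coverage_sd = 0.03 * sd_scale)
    p2 <- population_spec("variabilis", "sauce", 8,
      hue_mean = 210, hue_sd = 35, sat_mean = 0.6, sat_sd = 0.1,
      dorsal_band_mean = 4, dorsal_band_sd = 0,
      limb_band_mean = 2, limb_band_sd = 0, pattern_class = "striped",
      head_coverage_sd = 0.15)
    tab <- generate_phenotypes(study_spec(list(p1, p2), seed = 11))
    D <- global_distance(tab)$global
    within_population_var(D, tab$individual_id[tab$species == "imitator"])$var
  }
  vars <- vapply(c(0, 0.5, 1, 1.5, 2), var_of, numeric(1))
  expect_true(all(diff(vars) >= 0))

  cd_of <- function(conv) {
    spec <- two_pop_study(n = 10, convergence = conv, seed = 5)
    tab <- generate_phenotypes(spec)
    m <- attr(tab, "generative_means")
    # centroid separation at the generative level, fused across traits
    hue_d <- hue_difference(m[["imitator@sauce"]]$hue$head,
                            m[["variabilis@sauce"]]$hue$head)
    band_d <- abs(m[["imitator@sauce"]]$dorsal_bands -
                  m[["variabilis@sauce"]]$dorsal_bands)
    c(hue_d, band_d)
  }
  seps <- vapply(c(0, 0.25, 0.5, 0.75, 1), cd_of, numeric(2))
  expect_true(all(diff(seps[1, ]) <= 1e-9))
  expect_true(all(diff(seps[2, ]) <= 1e-9))
  # and the measured centroid distance follows at the ends of the dial
  cd_meas <- function(conv) {
    tab <- generate_phenotypes(two_pop_study(n = 12, convergence = conv,
                                             seed = 5, hue_sd = 3))
    D <- global_distance(tab)$global
    centroid_distance(D, tab$individual_id[tab$species == "imitator"],
                      tab$individual_id[tab$species == "variabilis"])
  }
  expect_lt(cd_meas(1), cd_meas(0))
})

test_that("phenotype CSV round-trips through disk", {
  tab <- generate_phenotypes(two_pop_study(seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(tab, path)
  back <- read_phenotypes(path)
  expect_equal(back$individual_id, tab$individual_id)
  expect_equal(back$hue_head, tab$hue_head, tolerance = 1e-12)
  expect_equal(back$pattern_class, tab$pattern_class)
})
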