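nm_from <- function(vals, labels) {
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  k <- 1
  for (i in seq_along(labels)[-length(labels)])
    for (j in (i + 1):length(labels)) {
      m[i, j] <- m[j, i] <- vals[k]; k <- k + 1
    }
  warnsig:::new_char_matrix(m, labels, "colour.head")
}

test_that("characteristic_var: definitional cases", {
  expect_equal(characteristic_var(nm_from(0.4, c("a", "b")), c("a", "b"))$var, 0.4)
  expect_equal(characteristic_var(nm_from(c(0.1, 0.2, 0.3), letters[1:3]),
                                  letters[1:3])$var, 0.2)
  clones <- nm_from(c(0, 0, 0), letters[1:3])
  expect_equal(characteristic_var(clones, letters[1:3])$var, 0)
  expect_error(characteristic_var(clones, "a"), class = "insufficient_members")
})

test_that("variance_sum adds per-population contributions, both senses", {
  tab <- generate_phenotypes(two_pop_study(n = 5, seed = 13))
  gd <- global_distance(tab)
  mem <- tab[, c("individual_id", "species", "locality")]
  vs <- variance_sum(gd$normalized, mem)
  expect_setequal(vs$characteristic, setdiff(characteristic_names(),
                                             "classif.pattern"))
  # oracle: recompute one characteristic by hand over the two populations
  ch <- "colour.back"
  total_mean <- 0; total_var <- 0
  for (sp in unique(mem$species)) {
    ids <- mem$individual_id[mem$species == sp]
    sub <- unclass(gd$normalized[[ch]])[ids, ids]
    pd <- sub[upper.tri(sub)]
    total_mean <- total_mean + mean(pd)
    total_var <- total_var + var(pd)
  }
  expect_equal(vs$sum_mean_pairwise[vs$characteristic == ch], total_mean)
  expect_equal(vs$sum_variance[vs$characteristic == ch], total_var)

  # single population: the total equals that population's value
  one <- tab[tab$species == "imitator", ]
  gd1 <- global_distance(one)
  vs1 <- variance_sum(gd1$normalized, one[, c("individual_id", "species",
                                              "locality")])
  cv <- characteristic_var(gd1$normalized[[ch]], one$individual_id)$var
  expect_equal(vs1$sum_mean_pairwise[vs1$characteristic == ch], cv)
})

test_that("doubling one characteristic's generative sd raises its total most", {
  mk <- function(hue_sd_head) {
    p <- population_spec("imitator", "sauce", 12,
      hue_mean = c(head = 40, dorsum = 40, limb = 40),
      hue_sd = c(head = hue_sd_head, dorsum = 4, limb = 4),
      sat_mean = 0.85, sat_sd = 0.01,
      dorsal_band_mean = 3, dorsal_band_sd = 0.3,
      limb_band_mean = 2, limb_band_sd = 0.3, pattern_class = "spotted")
    generate_phenotypes(study_spec(list(p), seed = 21))
  }
  # raw (un-normalized) colour matrices expose the sd ordering
  lo <- characteristic_matrices(mk(4))
  hi <- characteristic_matrices(mk(16))
  mean_d <- function(m) mean(unclass(m)[upper.tri(m)])
  expect_gt(mean_d(hi$colour.head), mean_d(lo$colour.head))
  expect_gt(mean_d(hi$colour.head), mean_d(hi$colour.back))
})

test_that("compare_characteristics: df, degenerate and power cases", {
  set.seed(31)
  groups6 <- lapply(1:6, function(i) rnorm(30))
  names(groups6) <- characteristic_names()[1:6]
  kw <- compare_characteristics(groups6)
  expect_identical(unname(kw$df), 5L)        # 6 groups -> df = 5
  expect_equal(dim(kw$pairwise), c(6L, 6L))
  expect_equal(kw$pairwise, t(kw$pairwise))
  expect_true(all(kw$pairwise >= 0 & kw$pairwise <= 1))

  same <- list(a = rep(1, 5), b = rep(1, 5))
  expect_warning(kw0 <- compare_characteristics(same), "tied")
  expect_equal(kw0$h, 0)
  expect_equal(kw0$p, 1)

  shifted <- list(a = rnorm(50, 0, 1), b = rnorm(50, 5, 1))
  kws <- compare_characteristics(shifted)
  expect_lt(kws$pairwise["a", "b"], 0.001)

  expect_error(compare_characteristics(list(a = 1:3)),
               class = "validation_error")
})

test_that("paired mode uses matched signed ranks", {
  set.seed(41)
  x <- rnorm(30)
  y <- x + 0.5 + rnorm(30, 0, 0.1)   # constant shift on matched pairs
  kp <- compare_characteristics(list(a = x, b = y), paired = TRUE)
  expect_lt(kp$pairwise["a", "b"], 0.001)
})

test_that("rank_characteristics flags least/most variable, ties stable", {
  vt <- data.frame(
    species = rep("imitator", 6), locality = rep("sauce", 6),
    characteristic = characteristic_names()[1:6],
    var = c(0, 0.2, 0.2, 0.5, 0.3, 0.1),
    n_pairs = 10)
  rk <- rank_characteristics(vt)
  expect_identical(rk$least_variable, "colour.head")
  expect_identical(rk$most_variable, "pattern.head")
  tied <- rk$overall[rk$overall$characteristic %in%
                       c("colour.back", "colour.limb"), ]
  expect_equal(tied$rank[1], tied$rank[2])
  expect_identical(tied$characteristic, sort(tied$characteristic))
})

test_that("ranking recovers the generative variability order", {
  # head pattern made most variable, colours least
  p <- population_spec("imitator", "sauce", 15,
    hue_mean = 40, hue_sd = 2, sat_mean = 0.85, sat_sd = 0.005,
    dorsal_band_mean = 3, dorsal_band_sd = 1.2,
    limb_band_mean = 2, limb_band_sd = 0.8,
    pattern_class = "spotted", head_coverage_sd = 0.2)
  q <- population_spec("variabilis", "jeberos", 15,
    hue_mean = 150, hue_sd = 2, sat_mean = 0.8, sat_sd = 0.005,
    dorsal_band_mean = 4, dorsal_band_sd = 1.2,
    limb_band_mean = 1, limb_band_sd = 0.8,
    pattern_class = "striped", head_coverage_sd = 0.2)
  tab <- generate_phenotypes(study_spec(list(p, q), seed = 17))
  gd <- global_distance(tab)
  vt <- variability_table(gd$normalized,
                          tab[, c("individual_id", "species", "locality")])
  rk <- rank_characteristics(vt)
  ov <- rk$overall
  expect_gt(ov$var[ov$characteristic == "pattern.head"],
            ov$var[ov$characteristic == "colour.head"])
  expect_true(all(rk$overall$var >= 0 & rk$overall$var <= 1))
})

test_that("characteristic variability is monotone in its generative sd", {
  cv_head <- function(scale) {
    p <- population_spec("imitator", "sauce", 10,
      hue_mean = 40, hue_sd = 3 * scale, sat_mean = 0.85, sat_sd = 0.01,
      dorsal_band_mean = 3, dorsal_band_sd = 0.3,
      limb_band_mean = 2, limb_band_sd = 0.3, pattern_class = "spotted")
    tab <- generate_phenotypes(study_spec(list(p), seed = 19))
    m <- characteristic_matrices(tab)$colour.head
    mean(unclass(m)[upper.tri(m)])
  }
  vals <- vapply(c(0, 1, 2, 4), cv_head, numeric(1))
  expect_true(all(diff(vals) >= 0))
})
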