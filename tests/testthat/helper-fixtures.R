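# Fixtures are built in code; no binary test data.

# a minimal two-population study (one locality, optional convergence)
two_pop_study <- function(n = 5, hue1 = 45, hue2 = 120, hue_sd = 4,
                          convergence = 0, seed = 1L, sat_sd = 0.02,
                          band_sd = 0.3, cov_sd = 0.03) {
  p1 <- population_spec("imitator", "sauce", n,
    hue_mean = hue1, hue_sd = hue_sd, sat_mean = 0.85, sat_sd = sat_sd,
    dorsal_band_mean = 3, dorsal_band_sd = band_sd,
    limb_band_mean = 2, limb_band_sd = band_sd,
    pattern_class = "spotted", head_coverage_sd = cov_sd)
  p2 <- population_spec("variabilis", "sauce", n,
    hue_mean = hue2, hue_sd = hue_sd, sat_mean = 0.80, sat_sd = sat_sd,
    dorsal_band_mean = 4, dorsal_band_sd = band_sd,
    limb_band_mean = 2, limb_band_sd = band_sd,
    pattern_class = "striped", convergence = convergence,
    head_coverage_sd = cov_sd)
  study_spec(list(p1, p2), seed = seed)
}

# an exactly Euclidean labelled distance matrix from planted coordinates
coords_to_D <- function(X, ids = NULL) {
  D <- as.matrix(dist(X))
  if (is.null(ids)) ids <- sprintf("i%03d", seq_len(nrow(X)))
  dimnames(D) <- list(ids, ids)
  D
}

# a tiny hand-built frog_image: uniform colour block as region `head`
flat_image <- function(colours, region = 1L) {
  # colours: matrix n x 3, one row per pixel laid on one raster row
  n <- nrow(colours)
  raster <- array(0, dim = c(4, n, 3))
  for (i in seq_len(n)) raster[2, i, ] <- colours[i, ]
  mask <- matrix(0L, 4, n)
  mask[2, ] <- region
  list_img <- list(raster = raster, mask = mask,
                   landmarks = data.frame(name = character(0),
                                          x = numeric(0), y = numeric(0)),
                   patches = list())
  structure(list_img, class = "frog_image")
}

hsb_rgb <- function(h, s, b = 0.9) {
  as.numeric(grDevices::col2rgb(grDevices::hsv((h %% 360) / 360, s, b))) / 255
}

# rigidly rotate a frog_image about the image centre (nearest-neighbour),
# rotating raster, mask and landmarks together
rotate_image <- function(img, degrees) {
  th <- degrees * pi / 180
  H <- dim(img$raster)[1]; W <- dim(img$raster)[2]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out_r <- array(0, dim = dim(img$raster))
  out_m <- matrix(0L, H, W)
  # inverse map: for each destination pixel, sample the source
  xs <- rep(0:(W - 1), each = H); ys <- rep(0:(H - 1), times = W)
  src <- cbind(xs - cx, ys - cy) %*% R           # R^-1 = R(-th) = t(R)? use inverse rotation
  sx <- round(src[, 1] + cx); sy <- round(src[, 2] + cy)
  ok <- sx >= 0 & sx < W & sy >= 0 & sy < H
  di <- cbind(ys + 1L, xs + 1L)[ok, , drop = FALSE]
  si <- cbind(sy + 1L, sx + 1L)[ok, , drop = FALSE]
  for (ch in 1:3) out_r[cbind(di, ch)] <- img$raster[cbind(si, ch)]
  out_m[di] <- img$mask[si]
  # forward-rotate the landmarks with the true (non-inverse) rotation
  Rf <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  lm <- img$landmarks
  p <- cbind(lm$x - cx, lm$y - cy) %*% t(Rf)
  lm$x <- p[, 1] + cx; lm$y <- p[, 2] + cy
  structure(list(raster = out_r, mask = out_m, landmarks = lm,
                 patches = img$patches), class = "frog_image")
}

# translate a frog_image by whole pixels
translate_image <- function(img, dx, dy) {
  H <- dim(img$raster)[1]; W <- dim(img$raster)[2]
  out_r <- array(0, dim = dim(img$raster))
  out_m <- matrix(0L, H, W)
  src_r <- 1:H - dy; src_c <- 1:W - dx
  ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
  out_r[which(ok_r), which(ok_c), ] <-
    img$raster[src_r[ok_r], src_c[ok_c], , drop = FALSE]
  out_m[which(ok_r), which(ok_c)] <- img$mask[src_r[ok_r], src_c[ok_c]]
  lm <- img$landmarks; lm$x <- lm$x + dx; lm$y <- lm$y + dy
  structure(list(raster = out_r, mask = out_m, landmarks = lm,
                 patches = img$patches), class = "frog_image")
}
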