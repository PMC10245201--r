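# Extraction of the six quantitative warning-signal characteristics from a
# standardized, landmarked, masked frog image.

REGION_IDS <- c(head = 1L, dorsum = 2L, limb = 3L)

# brightness channel (hexcone V = max of RGB) for every pixel
brightness_matrix <- function(raster) {
  pmax(raster[, , 1], raster[, , 2], raster[, , 3])
}

#' Colour-correct a frog image against its reference patches
#'
#' Fits a 3x4 affine RGB transform (3x3 matrix plus offset) by least squares
#' mapping the observed mean RGB of each reference patch to its true RGB,
#' then applies it to the whole raster (clipped to `[0, 1]`).  This is the
#' in-package stand-in for vendor colour-checker calibration software.
#'
#' @param image a `frog_image` with at least 4 reference patches.
#' @return The corrected `frog_image`, with attribute `"calibration"`: a
#'   list with the fitted `matrix`, `offset`, and per-patch RGB `residuals`
#'   (root-mean-square, after correction).
#' @export
color_correct <- function(image) {
  stopifnot(inherits(image, "frog_image"))
  patches <- image$patches
  if (length(patches) < 4)
    ws_stop("insufficient_calibration",
            sprintf("need >= 4 reference patches, got %d", length(patches)))
  obs <- t(vapply(patches, function(p) {
    rc <- p$rect
    sub <- image$raster[(rc[1]:rc[2]) + 1L, (rc[3]:rc[4]) + 1L, , drop = FALSE]
    apply(sub, 3, mean)
  }, numeric(3)))
  tru <- t(vapply(patches, function(p) p$true_rgb, numeric(3)))
  X <- cbind(obs, 1)
  if (qr(X)$rank < 4L)
    ws_stop("degenerate_patch",
            "reference patch colours are affinely degenerate")
  beta <- qr.solve(X, tru)                      # 4 x 3
  M <- t(beta[1:3, , drop = FALSE])             # 3 x 3
  off <- as.numeric(beta[4, ])
  image$raster <- apply_cast(image$raster, list(matrix = M, offset = off))
  fitted <- X %*% beta
  resid <- sqrt(rowMeans((fitted - tru)^2))
  names(resid) <- vapply(patches, function(p)
    if (!is.null(p$name)) p$name else "", character(1))
  attr(image, "calibration") <- list(matrix = M, offset = off,
                                     residuals = resid)
  image
}

#' Mean colour of a body region, brightness discarded
#'
#' Converts the region's non-black pixels to hue/saturation/brightness
#' (standard hexcone) and returns the circular mean hue and arithmetic mean
#' saturation.  Brightness reflects illumination, not the frog, and is
#' dropped.
#'
#' @param image a `frog_image`.
#' @param region `"head"`, `"dorsum"` or `"limb"`.
#' @param blackness brightness threshold above which a pixel counts as
#'   non-black pattern (default 0.2).
#' @param hue_mode `"circular"` (default) averages hue on the circle;
#'   `"arithmetic"` averages raw degree values (literal-replication mode,
#'   wrong across the 0/360 boundary).
#' @return list with `hue` (degrees in `[0, 360)`) and `saturation`
#'   (fraction), class `region_colour`.
#' @export
extract_region_color <- function(image, region, blackness = 0.2,
                                 hue_mode = c("circular", "arithmetic")) {
  stopifnot(inherits(image, "frog_image"))
  hue_mode <- match.arg(hue_mode)
  region <- match.arg(region, names(REGION_IDS))
  sel <- image$mask == REGION_IDS[[region]]
  bri <- brightness_matrix(image$raster)
  sel <- sel & bri > blackness
  if (!any(sel))
    ws_stop("no_pattern_pixels",
            sprintf("region '%s' has no non-black pixels", region))
  rgb <- cbind(image$raster[, , 1][sel], image$raster[, , 2][sel],
               image$raster[, , 3][sel])
  hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 1)
  hue <- hsv[1, ] * 360
  hue <- switch(hue_mode,
    circular = circular_mean(hue),
    arithmetic = mean(hue))
  structure(list(hue = hue %% 360, saturation = mean(hsv[2, ])),
            class = "region_colour")
}

# integer Bresenham line between two 0-based pixel coordinates, inclusive
bresenham <- function(x0, y0, x1, y1) {
  x0 <- round(x0); y0 <- round(y0); x1 <- round(x1); y1 <- round(y1)
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  pts <- matrix(0L, nrow = dx - dy + 1L, ncol = 2L)
  i <- 0L
  repeat {
    i <- i + 1L
    pts[i, ] <- c(x0, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  pts[seq_len(i), , drop = FALSE]
}

#' Build a transect polyline
#'
#' @param points numeric matrix (or data.frame) with columns `x`, `y`
#'   (0-based pixel coordinates), at least 2 rows.
#' @param role one of `"dorsal_left"`, `"dorsal_right"`, `"limb"`.
#' @return An object of class `transect`.
#' @export
transect <- function(points, role = c("dorsal_left", "dorsal_right", "limb")) {
  role <- match.arg(role)
  points <- as.matrix(points[, c("x", "y")])
  if (nrow(points) < 2)
    ws_stop("geometry_error", "a transect needs at least 2 points")
  structure(list(points = points, role = role), class = "transect")
}

#' Count colour transitions along a transect (the "adjacent method")
#'
#' Samples pixels along the polyline with Bresenham's algorithm, labels each
#' as black or non-black by the brightness threshold, and returns the number
#' of label changes — the reticulation score: 0 for a uniform (diffuse)
#' transect, `2b` for `b` clean bands (one entry and one exit each).
#'
#' @param image a `frog_image`.
#' @param tr a [transect()].
#' @param blackness brightness threshold (default 0.2).
#' @param check_mask if `TRUE` (default) error when any sampled pixel falls
#'   outside the region mask implied by the transect role.
#' @return Integer transition count.
#' @export
count_transitions <- function(image, tr, blackness = 0.2, check_mask = TRUE) {
  stopifnot(inherits(image, "frog_image"), inherits(tr, "transect"))
  pts <- tr$points
  samp <- NULL
  for (i in seq_len(nrow(pts) - 1L)) {
    seg <- bresenham(pts[i, 1], pts[i, 2], pts[i + 1, 1], pts[i + 1, 2])
    if (i > 1L) seg <- seg[-1L, , drop = FALSE]   # avoid duplicated joints
    samp <- rbind(samp, seg)
  }
  H <- dim(image$raster)[1]; W <- dim(image$raster)[2]
  if (any(samp[, 1] < 0 | samp[, 1] >= W | samp[, 2] < 0 | samp[, 2] >= H))
    ws_stop("geometry_error", "transect leaves the image")
  idx <- cbind(samp[, 2] + 1L, samp[, 1] + 1L)
  if (check_mask) {
    region_id <- switch(tr$role, dorsal_left = , dorsal_right = 2L, limb = 3L)
    if (any(image$mask[idx] != region_id))
      ws_stop("geometry_error",
              sprintf("transect '%s' leaves its region mask", tr$role))
  }
  bri <- brightness_matrix(image$raster)
  labels <- bri[idx] > blackness
  sum(labels[-1L] != labels[-length(labels)])
}

#' Align the head pattern onto a common landmark frame
#'
#' Fits a least-squares affine transform between the image's 10 landmarks
#' and the template landmarks, then samples the head region onto a G x G
#' grid over the template head box.  A grid cell is 1 when it lands on a
#' head pixel whose brightness exceeds the blackness threshold (a non-black
#' pattern element), enabling pixel-by-pixel homology comparison of stacked
#' images.
#'
#' @param image a `frog_image`.
#' @param template list with `landmarks` (data.frame `name, x, y`) and
#'   `head_bbox` (`c(row0, row1, col0, col1)`, 0-based, in template
#'   coordinates); see [default_template()].
#' @param grid_size G, the common raster resolution (default 64).
#' @param blackness brightness threshold (default 0.2).
#' @return A G x G binary matrix (class `pattern_raster`); rows follow the
#'   template y axis.
#' @export
align_head_pattern <- function(image, template, grid_size = 64L,
                               blackness = 0.2) {
  stopifnot(inherits(image, "frog_image"))
  G <- as.integer(grid_size)
  tlm <- template$landmarks; ilm <- image$landmarks
  common <- intersect(tlm$name, ilm$name)
  if (length(common) < 3)
    ws_stop("alignment_error", "need >= 3 shared landmarks")
  tlm <- tlm[match(common, tlm$name), ]; ilm <- ilm[match(common, ilm$name), ]
  X <- cbind(tlm$x, tlm$y, 1)
  if (qr(X)$rank < 3L || qr(cbind(ilm$x, ilm$y, 1))$rank < 3L)
    ws_stop("alignment_error", "landmark configuration is collinear")
  beta <- qr.solve(X, cbind(ilm$x, ilm$y))      # template -> image
  bb <- template$head_bbox
  gx <- seq(bb[3], bb[4], length.out = G)
  gy <- seq(bb[1], bb[2], length.out = G)
  pts <- cbind(rep(gx, each = G), rep(gy, times = G), 1)  # (x, y, 1)
  img_xy <- pts %*% beta
  px <- round(img_xy[, 1]) + 1L; py <- round(img_xy[, 2]) + 1L
  H <- dim(image$raster)[1]; W <- dim(image$raster)[2]
  ok <- px >= 1L & px <= W & py >= 1L & py <= H
  val <- logical(nrow(pts))
  bri <- brightness_matrix(image$raster)
  idx <- cbind(py[ok], px[ok])
  val[ok] <- image$mask[idx] == REGION_IDS[["head"]] & bri[idx] > blackness
  out <- matrix(as.integer(val), nrow = G, ncol = G)   # rows = y, cols = x
  class(out) <- c("pattern_raster", class(out))
  out
}

#' Default alignment template from a render spec
#'
#' @param rspec a [render_spec()].
#' @return list with `landmarks` and `head_bbox` in template coordinates.
#' @export
default_template <- function(rspec = render_spec()) {
  list(landmarks = rspec$landmarks, head_bbox = rspec$regions$head)
}

# dorsal and limb transects from named landmarks: two lines parallel to the
# neck->groin axis offset +/- `offset` of the shoulder width, and the
# hip->knee line
layout_transects <- function(landmarks, offset = 0.15) {
  lm <- function(n) {
    i <- match(n, landmarks$name)
    if (is.na(i)) ws_stop("geometry_error", sprintf("missing landmark '%s'", n))
    c(landmarks$x[i], landmarks$y[i])
  }
  neck <- lm("neck"); groin <- lm("groin")
  sl <- lm("shoulder_left"); sr <- lm("shoulder_right")
  width <- sqrt(sum((sl - sr)^2))
  axis <- groin - neck
  perp <- c(-axis[2], axis[1]) / sqrt(sum(axis^2))
  off <- offset * width * perp
  mk <- function(p0, p1, role)
    transect(data.frame(x = c(p0[1], p1[1]), y = c(p0[2], p1[2])), role)
  list(
    dorsal_left = mk(neck - off, groin - off, "dorsal_left"),
    dorsal_right = mk(neck + off, groin + off, "dorsal_right"),
    limb = mk(lm("hip"), lm("knee"), "limb")
  )
}

#' Phenotype a frog image: all six quantitative characteristics
#'
#' Runs region-colour extraction for head/dorsum/limb, head-pattern
#' alignment, and transition counting along the two dorsal transects
#' (neck to groin, offset either side of the spine axis) and the hindlimb
#' transect (hip to knee; forelimbs are never measured).  The qualitative
#' pattern class is an annotation input, not computed from pixels.
#'
#' @param image a `frog_image`, already colour-corrected (or rendered with
#'   an identity cast).
#' @param pattern_class annotation: one of [pattern_classes()], or `NA`.
#' @param template alignment template (default from [render_spec()]).
#' @param grid_size head-raster resolution G.
#' @param blackness brightness threshold.
#' @param hue_mode passed to [extract_region_color()].
#' @param transect_offset dorsal transect offset as a fraction of shoulder
#'   width.
#' @return list (class `phenotype_record`) with `colour_head`,
#'   `colour_back`, `colour_limb` (each a `region_colour`), `head_raster`,
#'   `dorsal_transitions_left`, `dorsal_transitions_right`,
#'   `limb_transitions`, `pattern_class`.
#' @export
phenotype_image <- function(image, pattern_class = NA_character_,
                            template = default_template(),
                            grid_size = 64L, blackness = 0.2,
                            hue_mode = "circular", transect_offset = 0.15) {
  trs <- layout_transects(image$landmarks, transect_offset)
  structure(list(
    colour_head = extract_region_color(image, "head", blackness, hue_mode),
    colour_back = extract_region_color(image, "dorsum", blackness, hue_mode),
    colour_limb = extract_region_color(image, "limb", blackness, hue_mode),
    head_raster = align_head_pattern(image, template, grid_size, blackness),
    dorsal_transitions_left =
      count_transitions(image, trs$dorsal_left, blackness),
    dorsal_transitions_right =
      count_transitions(image, trs$dorsal_right, blackness),
    limb_transitions = count_transitions(image, trs$limb, blackness),
    pattern_class = pattern_class
  ), class = "phenotype_record")
}
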