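# Synthetic frog renderer: turns a phenotype record into a raster image with
# landmarks, region masks and colour-reference patches, emulating the
# standardized dorsal photographs the pipeline was designed for.

# body pixels are rendered at fixed brightness; only hue and saturation
# carry signal (brightness is discarded downstream anyway)
BODY_BRIGHTNESS <- 0.9

hsb_to_rgb <- function(hue_deg, sat, bri = BODY_BRIGHTNESS) {
  as.numeric(grDevices::col2rgb(grDevices::hsv((hue_deg %% 360) / 360,
                                               sat, bri))) / 255
}

#' Render a synthetic frog image from a phenotype record
#'
#' Produces a `frog_image`: black body background with coloured pattern
#' elements in the record's per-region hue/saturation, the dorsal region
#' crossed by exactly `dorsal_bands` transverse bands (so each dorsal
#' transect sees `2 * dorsal_bands` colour transitions), the hindlimb strip
#' crossed by `limb_bands` bars, and a head pattern whose style follows
#' `pattern_class` and whose pixel coverage equals `head_coverage`.
#' Reference patches are painted with their true RGB, then the spec's
#' global colour cast is applied to the whole image.
#'
#' @param record a single-row data.frame (or list) with the columns produced
#'   by [generate_phenotypes()].
#' @param rspec a [render_spec()].
#' @param seed integer controlling pattern jitter only; by default derived
#'   from `individual_id` so re-rendering a record is deterministic.
#'   Transition counts do not depend on it.
#' @return An object of class `frog_image`: list with `raster`
#'   (height x width x 3 array in `[0, 1]`), `mask` (integer matrix, 0
#'   background / 1 head / 2 dorsum / 3 limb), `landmarks` (data.frame
#'   `name, x, y`), and `patches` (list of `list(name, rect, true_rgb)`).
#' @export
render_frog <- function(record, rspec = render_spec(), seed = NULL) {
  record <- as.list(record)
  stopifnot(inherits(rspec, "render_spec"))
  if (is.null(seed)) {
    id <- if (!is.null(record$individual_id)) record$individual_id else "frog"
    seed <- abs(digest::digest2int(as.character(id))) %% 2147483647L
  }
  H <- rspec$height; W <- rspec$width
  raster <- array(0, dim = c(H, W, 3))
  mask <- matrix(0L, H, W)
  ids <- c(head = 1L, dorsum = 2L, limb = 3L)
  for (r in names(rspec$regions)) {
    rc <- rspec$regions[[r]]
    mask[(rc[1]:rc[2]) + 1L, (rc[3]:rc[4]) + 1L] <- ids[[r]]
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  col_head <- hsb_to_rgb(record$hue_head, record$sat_head)
  col_dors <- hsb_to_rgb(record$hue_dorsum, record$sat_dorsum)
  col_limb <- hsb_to_rgb(record$hue_limb, record$sat_limb)

  raster <- paint_bands(raster, rspec$regions$dorsum,
                        n_bands = record$dorsal_bands, colour = col_dors,
                        along = "rows", margin = 4L, inset = 4L,
                        jitter = rspec$jitter)
  raster <- paint_bands(raster, rspec$regions$limb,
                        n_bands = record$limb_bands, colour = col_limb,
                        along = "cols", margin = 4L, inset = 3L,
                        jitter = rspec$jitter)
  raster <- paint_head(raster, rspec$regions$head,
                       class = record$pattern_class,
                       coverage = record$head_coverage, colour = col_head)

  for (p in rspec$patches) {
    rc <- p$rect
    for (ch in 1:3)
      raster[(rc[1]:rc[2]) + 1L, (rc[3]:rc[4]) + 1L, ch] <- p$true_rgb[ch]
  }

  raster <- apply_cast(raster, rspec$colour_cast)

  structure(list(raster = raster, mask = mask,
                 landmarks = rspec$landmarks, patches = rspec$patches),
            class = "frog_image")
}

# preserve the caller's RNG stream across the jitter draws
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# paint n_bands coloured bands across a rectangular region, leaving black
# margins at both ends of the crossing axis so a transect entering and
# leaving each band counts exactly 2 transitions per band
paint_bands <- function(raster, rect, n_bands, colour, along, margin, inset,
                        jitter) {
  n_bands <- as.integer(n_bands)
  if (n_bands == 0L) return(raster)
  lo <- if (along == "rows") rect[1] else rect[3]
  hi <- if (along == "rows") rect[2] else rect[4]
  inner0 <- lo + margin; inner1 <- hi - margin
  span <- inner1 - inner0 + 1L
  if (n_bands > span %/% 2L)
    ws_stop("render_error",
            sprintf("band count %d too large for region span %d",
                    n_bands, span))
  seg <- span / n_bands
  jmax <- max(0, floor(0.15 * seg))
  for (k in seq_len(n_bands) - 1L) {
    a <- inner0 + round((k + 0.2) * seg)
    b <- inner0 + round((k + 0.8) * seg) - 1L
    if (b < a) b <- a
    if (jmax > 0) {
      j <- round(runif(1, -jmax, jmax))
      a <- a + j; b <- b + j
    }
    a <- max(a, inner0); b <- min(b, inner1)
    if (along == "rows") {
      cols <- (rect[3] + inset):(rect[4] - inset)
      for (ch in 1:3) raster[(a:b) + 1L, cols + 1L, ch] <- colour[ch]
    } else {
      rows <- (rect[1] + inset):(rect[2] - inset)
      for (ch in 1:3) raster[rows + 1L, (a:b) + 1L, ch] <- colour[ch]
    }
  }
  raster
}

# paint the head pattern: rank head pixels by a class-specific score field
# and colour exactly round(coverage * n) of them, so pixel coverage is the
# controllable quantitative head-pattern trait.  The field is deterministic
# given the pattern class: the rendered head is a faithful depiction of the
# record (coverage + class), so the raster distance between two frogs of
# one class reduces to their coverage difference
paint_head <- function(raster, rect, class, coverage, colour) {
  rows <- (rect[1]:rect[2]) + 1L; cols <- (rect[3]:rect[4]) + 1L
  ny <- length(rows); nx <- length(cols)
  yy <- matrix(rep(seq_len(ny), nx), ny, nx)
  xx <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  score <- switch(class,
    striped = {
      centers <- nx * c(0.25, 0.5, 0.75)
      -apply(abs(outer(as.vector(xx), centers, "-")), 1, min)
    },
    lined = {
      centers <- ny * c(0.25, 0.5, 0.75)
      -apply(abs(outer(as.vector(yy), centers, "-")), 1, min)
    },
    spotted = {
      cy <- rep(ny * c(0.25, 0.5, 0.75), each = 3)
      cx <- rep(nx * c(0.25, 0.5, 0.75), times = 3)
      d2 <- outer(as.vector(yy), cy, "-")^2 + outer(as.vector(xx), cx, "-")^2
      -sqrt(apply(d2, 1, min))
    },
    diffuse = {
      -sqrt((as.vector(yy) - (ny + 1) / 2)^2 + (as.vector(xx) - (nx + 1) / 2)^2)
    },
    ws_stop("validation_error", sprintf("unknown pattern class '%s'", class))
  )
  n_on <- round(coverage * ny * nx)
  if (n_on > 0) {
    sel <- order(score, decreasing = TRUE)[seq_len(n_on)]
    on_y <- rows[(sel - 1L) %% ny + 1L]
    on_x <- cols[(sel - 1L) %/% ny + 1L]
    for (ch in 1:3) raster[cbind(on_y, on_x, ch)] <- colour[ch]
  }
  raster
}

# new_rgb = M rgb + offset, clipped to [0, 1]
apply_cast <- function(raster, cast) {
  d <- dim(raster)
  flat <- matrix(raster, ncol = 3)
  out <- flat %*% t(cast$matrix) + rep(cast$offset, each = nrow(flat))
  out[out < 0] <- 0; out[out > 1] <- 1
  array(out, dim = d)
}

#' @export
print.frog_image <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf("frog_image: %d x %d px, %d landmarks, %d patches\n",
              d[2], d[1], nrow(x$landmarks), length(x$patches)))
  invisible(x)
}

#' Write a frog image (raster, mask, landmarks) to disk
#'
#' The raster goes to `<stem>.png`, the region mask to an indexed
#' `<stem>_mask.png` (grey levels 0/1/2/3 scaled to 0..3/255) and the
#' landmarks to `<stem>_landmarks.csv` with columns `name,x,y`.
#' @param image a `frog_image`.
#' @param stem path stem without extension.
#' @return Invisibly, the paths written.
#' @export
write_frog_image <- function(image, stem) {
  png_path <- paste0(stem, ".png")
  png::writePNG(image$raster, png_path)
  mask_path <- paste0(stem, "_mask.png")
  png::writePNG(image$mask / 255, mask_path)
  lm_path <- paste0(stem, "_landmarks.csv")
  utils::write.csv(image$landmarks, lm_path, row.names = FALSE, quote = FALSE)
  invisible(c(png_path, mask_path, lm_path))
}
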