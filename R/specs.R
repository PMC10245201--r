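#' Describe one population (species x locality) for the synthetic generator
#'
#' A population is one ecotype: a species at a locality, with generative
#' means and standard deviations for its warning-signal characteristics and
#' a mimicry-convergence fraction pulling its means towards a designated
#' sympatric partner.
#'
#' @param species,locality non-empty labels; the pair must be unique within
#'   a study.
#' @param n_individuals integer >= 2 (pairwise distances must exist).
#' @param hue_mean,hue_sd per-region hue mean (degrees, `[0, 360)`) and sd
#'   (degrees >= 0).  Named numeric vectors with entries `head`, `dorsum`,
#'   `limb`; a single unnamed value is recycled to all three regions.
#' @param sat_mean,sat_sd per-region saturation mean (fraction in `[0, 1]`)
#'   and sd (>= 0), same recycling rule.
#' @param dorsal_band_mean,dorsal_band_sd dorsal coloured-band count mean and
#'   sd (non-negative reals; counts are drawn as `max(0, round(Normal))`).
#' @param limb_band_mean,limb_band_sd hindlimb band count mean and sd.
#' @param pattern_class one of [pattern_classes()].
#' @param convergence fraction in `[0, 1]`: how far this population's
#'   generative means are pulled towards its sympatric partner's means.
#' @param head_coverage_mean,head_coverage_sd mean and sd of the fraction of
#'   the head occupied by pattern elements (the quantitative head-pattern
#'   trait in table-only analyses; also controls rendering).  Default mean
#'   depends on `pattern_class`.
#'
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(species, locality, n_individuals,
                            hue_mean, hue_sd, sat_mean, sat_sd,
                            dorsal_band_mean, dorsal_band_sd,
                            limb_band_mean, limb_band_sd,
                            pattern_class,
                            convergence = 0,
                            head_coverage_mean = NULL,
                            head_coverage_sd = 0.03) {
  stopifnot(is.character(species), nzchar(species),
            is.character(locality), nzchar(locality))
  if (n_individuals < 2)
    ws_stop("configuration_error", "n_individuals must be >= 2")
  pattern_class <- match.arg(pattern_class, pattern_classes())
  per_region <- function(x, nm) {
    if (length(x) == 1L && is.null(names(x)))
      x <- c(head = unname(x), dorsum = unname(x), limb = unname(x))
    if (!all(c("head", "dorsum", "limb") %in% names(x)))
      ws_stop("configuration_error",
              sprintf("%s must name regions head, dorsum, limb", nm))
    x[c("head", "dorsum", "limb")]
  }
  hue_mean <- per_region(hue_mean, "hue_mean") %% 360
  hue_sd   <- per_region(hue_sd, "hue_sd")
  sat_mean <- per_region(sat_mean, "sat_mean")
  sat_sd   <- per_region(sat_sd, "sat_sd")
  if (any(c(hue_sd, sat_sd, dorsal_band_sd, limb_band_sd,
            head_coverage_sd) < 0))
    ws_stop("configuration_error", "standard deviations must be >= 0")
  if (any(sat_mean < 0 | sat_mean > 1))
    ws_stop("configuration_error", "sat_mean must lie in [0, 1]")
  if (convergence < 0 || convergence > 1)
    ws_stop("configuration_error", "convergence must lie in [0, 1]")
  if (any(c(dorsal_band_mean, limb_band_mean) < 0))
    ws_stop("configuration_error", "band count means must be >= 0")
  if (is.null(head_coverage_mean))
    head_coverage_mean <- switch(pattern_class,
      striped = 0.35, spotted = 0.30, lined = 0.40, diffuse = 0.85)
  structure(list(
    species = species, locality = locality,
    n_individuals = as.integer(n_individuals),
    hue_mean = hue_mean, hue_sd = hue_sd,
    sat_mean = sat_mean, sat_sd = sat_sd,
    dorsal_band_mean = dorsal_band_mean, dorsal_band_sd = dorsal_band_sd,
    limb_band_mean = limb_band_mean, limb_band_sd = limb_band_sd,
    pattern_class = pattern_class, convergence = convergence,
    head_coverage_mean = head_coverage_mean,
    head_coverage_sd = head_coverage_sd
  ), class = "population_spec")
}

#' Describe a whole synthetic study
#'
#' @param populations list of [population_spec()] objects; every
#'   (species, locality) pair must be unique.
#' @param sympatry named list mapping locality to the character vector of
#'   species present there.  Defaults to the species actually listed per
#'   locality in `populations`.
#' @param seed integer seed; every random draw in the generator flows from
#'   it, so identical specs give identical tables and images.
#' @return An object of class `study_spec`.
#' @export
study_spec <- function(populations, sympatry = NULL, seed = 1L) {
  stopifnot(is.list(populations), length(populations) >= 1)
  ok <- vapply(populations, inherits, logical(1), "population_spec")
  if (!all(ok))
    ws_stop("configuration_error", "populations must be population_spec objects")
  keys <- vapply(populations, function(p) paste(p$species, p$locality, sep = "@"),
                 character(1))
  if (anyDuplicated(keys))
    ws_stop("configuration_error",
            sprintf("duplicate population keys: %s",
                    paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  if (is.null(sympatry)) {
    locs <- unique(vapply(populations, `[[`, character(1), "locality"))
    sympatry <- lapply(stats::setNames(locs, locs), function(l)
      vapply(Filter(function(p) p$locality == l, populations),
             `[[`, character(1), "species"))
  } else {
    for (p in populations)
      if (!p$species %in% sympatry[[p$locality]])
        ws_stop("configuration_error", sprintf(
          "sympatry map omits %s at %s", p$species, p$locality))
  }
  structure(list(populations = populations, sympatry = sympatry,
                 seed = as.integer(seed)),
            class = "study_spec")
}

#' @export
print.study_spec <- function(x, ...) {
  cat(sprintf("study_spec: %d populations, %d localities, seed %d\n",
              length(x$populations), length(x$sympatry), x$seed))
  for (p in x$populations)
    cat(sprintf("  %s @ %s  n=%d  class=%s  convergence=%.2f\n",
                p$species, p$locality, p$n_individuals, p$pattern_class,
                p$convergence))
  invisible(x)
}

#' Rendering geometry and imaging conditions for synthetic frogs
#'
#' Fixed geometry shared by all renders of a study: image size, the three
#' body-region rectangles, the 10-landmark template, the colour-reference
#' patches, a global linear colour cast (3x3 matrix plus offset, emulating
#' unstandardized camera response), and pattern jitter amplitudes.
#'
#' @param width,height image size in pixels.
#' @param colour_cast list with `matrix` (3x3) and `offset` (length-3),
#'   applied to every rendered pixel; the default is the identity.
#' @param jitter amplitude (pixels) of random displacement of pattern
#'   elements between renders.
#' @return An object of class `render_spec` with fields `width`, `height`,
#'   `regions` (named list of `c(row0, row1, col0, col1)`), `landmarks`
#'   (data.frame `name, x, y`, 0-based pixel coordinates, x right, y down),
#'   `patches` (list of `list(rect, true_rgb)`) and `transect_offset`
#'   (fraction of body width).
#' @export
render_spec <- function(width = 140L, height = 200L,
                        colour_cast = identity_cast(),
                        jitter = 1.5) {
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width >= 120L, height >= 180L)
  # region rectangles, 0-based inclusive (row0, row1, col0, col1)
  regions <- list(
    head   = c(20, 59, 40, 99),
    dorsum = c(70, 149, 40, 99),
    limb   = c(160, 179, 30, 109)
  )
  landmarks <- data.frame(
    name = c("snout", "eye_left", "eye_right", "neck",
             "shoulder_left", "shoulder_right", "spine_mid",
             "groin", "hip", "knee"),
    x = c(70, 50, 90, 70, 40, 99, 70, 70, 30, 109),
    y = c(12, 30, 30, 70, 75, 75, 110, 149, 170, 170)
  )
  # reference patches: a 6-swatch chart below the body, disjoint from it
  truths <- list(white = c(1, 1, 1), grey = c(0.5, 0.5, 0.5),
                 red = c(1, 0, 0), green = c(0, 1, 0),
                 blue = c(0, 0, 1), yellow = c(1, 1, 0))
  patches <- vector("list", 6L)
  x0 <- 8L
  for (i in seq_along(truths)) {
    patches[[i]] <- list(
      name = names(truths)[i],
      rect = c(186, 196, x0, x0 + 14L),
      true_rgb = truths[[i]]
    )
    x0 <- x0 + 22L
  }
  stopifnot(x0 - 22L + 14L < width)
  structure(list(width = width, height = height, regions = regions,
                 landmarks = landmarks, patches = patches,
                 colour_cast = colour_cast, jitter = jitter,
                 transect_offset = 0.15),
            class = "render_spec")
}

#' Identity and scaled colour casts
#'
#' Convenience constructors for the global linear colour cast applied by
#' [render_frog()]: `new_rgb = matrix %*% rgb + offset`, clipped to `[0, 1]`.
#' @param scale scalar multiplier for [scaled_cast()].
#' @param matrix 3x3 numeric matrix.
#' @param offset length-3 numeric offset.
#' @return list with elements `matrix` and `offset`.
#' @export
identity_cast <- function() list(matrix = diag(3), offset = rep(0, 3))

#' @rdname identity_cast
#' @export
scaled_cast <- function(scale) list(matrix = scale * diag(3), offset = rep(0, 3))

#' @rdname identity_cast
#' @export
colour_cast <- function(matrix, offset = rep(0, 3)) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == 3), length(offset) == 3)
  list(matrix = matrix, offset = offset)
}
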