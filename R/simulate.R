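#' Generate a synthetic phenotype table with known ground truth
#'
#' Draws one phenotype record per individual from the generative model of a
#' [study_spec()].  Hues are drawn from wrapped normals on the colour circle,
#' saturations and head-pattern coverage from clamped normals, and band
#' counts as `max(0, round(Normal))` — integers, matching the transect-count
#' semantics of the adjacent method.  Before drawing, each population's
#' means are pulled a fraction `convergence` along the shortest path towards
#' the base means of its sympatric attractor partner (the first other
#' species listed at its locality), emulating mimetic advergence of a mimic
#' onto its model.
#'
#' Both dorsal transects report the same underlying band count (left and
#' right transitions are equal by construction; the rendered bands span the
#' full dorsum width).
#'
#' @param spec a [study_spec()].
#' @return A data.frame with one row per individual and columns
#'   `individual_id`, `species`, `locality`, `hue_head`, `sat_head`,
#'   `hue_dorsum`, `sat_dorsum`, `hue_limb`, `sat_limb`, `dorsal_bands`,
#'   `dorsal_transitions_left`, `dorsal_transitions_right`, `limb_bands`,
#'   `limb_transitions`, `head_coverage`, `pattern_class`.  The effective
#'   (post-convergence) generative means are attached as attribute
#'   `"generative_means"`.
#' @seealso [render_frog()] to turn records into images,
#'   [characteristic_matrices()] to go from table to distance matrices.
#' @export
generate_phenotypes <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  set.seed(spec$seed)
  pops <- spec$populations
  keys <- vapply(pops, function(p) paste(p$species, p$locality, sep = "@"),
                 character(1))
  base <- lapply(pops, effective_means, partner = NULL)
  names(base) <- keys
  eff <- vector("list", length(pops))
  for (i in seq_along(pops)) {
    p <- pops[[i]]
    partner <- NULL
    if (p$convergence > 0) {
      others <- setdiff(spec$sympatry[[p$locality]], p$species)
      if (length(others)) {
        pk <- paste(others[[1]], p$locality, sep = "@")
        if (pk %in% names(base)) partner <- base[[pk]]
      }
    }
    eff[[i]] <- effective_means(p, partner)
  }
  names(eff) <- keys

  rows <- vector("list", length(pops))
  for (i in seq_along(pops)) {
    p <- pops[[i]]; m <- eff[[i]]; n <- p$n_individuals
    draw_region <- function(region) {
      h <- rwrapped_hue(n, m$hue[[region]], p$hue_sd[[region]])
      s <- pmin(1, pmax(0, rnorm(n, m$sat[[region]], p$sat_sd[[region]])))
      list(h = h, s = s)
    }
    head <- draw_region("head"); dors <- draw_region("dorsum")
    limb <- draw_region("limb")
    db <- pmax(0, round(rnorm(n, m$dorsal_bands, p$dorsal_band_sd)))
    lb <- pmax(0, round(rnorm(n, m$limb_bands, p$limb_band_sd)))
    cov <- pmin(0.95, pmax(0.05, rnorm(n, m$head_coverage, p$head_coverage_sd)))
    rows[[i]] <- data.frame(
      individual_id = sprintf("%s_%s_%03d", p$species, p$locality, seq_len(n)),
      species = p$species, locality = p$locality,
      hue_head = head$h, sat_head = head$s,
      hue_dorsum = dors$h, sat_dorsum = dors$s,
      hue_limb = limb$h, sat_limb = limb$s,
      dorsal_bands = as.integer(db),
      dorsal_transitions_left = as.integer(2 * db),
      dorsal_transitions_right = as.integer(2 * db),
      limb_bands = as.integer(lb),
      limb_transitions = as.integer(2 * lb),
      head_coverage = cov,
      pattern_class = p$pattern_class,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "generative_means") <- eff
  out
}

# effective generative means for a population, after the convergence pull
# towards `partner` (a list as returned by this function, or NULL)
effective_means <- function(p, partner = NULL) {
  m <- list(hue = as.list(p$hue_mean), sat = as.list(p$sat_mean),
            dorsal_bands = p$dorsal_band_mean,
            limb_bands = p$limb_band_mean,
            head_coverage = p$head_coverage_mean)
  if (!is.null(partner) && p$convergence > 0) {
    c_ <- p$convergence
    for (r in c("head", "dorsum", "limb")) {
      m$hue[[r]] <- hue_lerp(m$hue[[r]], partner$hue[[r]], c_)
      m$sat[[r]] <- (1 - c_) * m$sat[[r]] + c_ * partner$sat[[r]]
    }
    m$dorsal_bands <- (1 - c_) * m$dorsal_bands + c_ * partner$dorsal_bands
    m$limb_bands <- (1 - c_) * m$limb_bands + c_ * partner$limb_bands
    m$head_coverage <- (1 - c_) * m$head_coverage + c_ * partner$head_coverage
  }
  m
}

#' Write / read a phenotype table as CSV
#'
#' UTF-8, comma-separated, header row, "." decimal.
#' @param table a phenotype data.frame as from [generate_phenotypes()].
#' @param path file path.
#' @return `read_phenotypes()` returns the data.frame.
#' @export
write_phenotypes <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
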