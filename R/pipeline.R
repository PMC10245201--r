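# End-to-end study pipeline: configuration, stage sequencing, file I/O and
# the run manifest.

PIPELINE_STAGES <- c("simulate", "phenotype", "distances", "mimicry",
                     "morphospace", "anatomy")

#' Read a study configuration from YAML
#'
#' The configuration carries the synthetic study (or a path to a phenotype
#' CSV), mode flags and the seed.  In YAML study configs the `sympatry` map
#' is required explicitly — a config without one is rejected before any
#' computation.
#'
#' @param path YAML file path.
#' @return A validated config list (class `study_config`).
#' @export
read_study_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_study_config
#' @param config a raw config list.
#' @export
validate_config <- function(config) {
  if (is.null(config$study) && is.null(config$phenotypes_csv))
    ws_stop("configuration_error",
            "config needs either a 'study' block or 'phenotypes_csv'")
  if (!is.null(config$study)) {
    if (is.null(config$study$populations))
      ws_stop("configuration_error", "study block lacks populations")
    if (is.null(config$study$sympatry))
      ws_stop("configuration_error", "study block lacks a sympatry map")
  }
  if (is.null(config$seed)) config$seed <- 1L
  defaults <- list(hue_mode = "circular", back_mode = "pair",
                   aggregate = "sum", mds_method = "classical",
                   use_images = FALSE, grid_size = 64L, blackness = 0.2,
                   transect_offset = 0.15)
  config$options <- utils::modifyList(defaults,
                                      if (is.null(config$options)) list()
                                      else config$options)
  class(config) <- c("study_config", "list")
  config
}

# build a study_spec from the config's study block
config_to_study <- function(config) {
  pops <- lapply(config$study$populations, function(p) {
    as_region <- function(x) if (is.list(x)) unlist(x) else x
    population_spec(
      species = p$species, locality = p$locality,
      n_individuals = p$n_individuals,
      hue_mean = as_region(p$hue_mean), hue_sd = as_region(p$hue_sd),
      sat_mean = as_region(p$sat_mean), sat_sd = as_region(p$sat_sd),
      dorsal_band_mean = p$dorsal_band_mean,
      dorsal_band_sd = p$dorsal_band_sd,
      limb_band_mean = p$limb_band_mean, limb_band_sd = p$limb_band_sd,
      pattern_class = p$pattern_class,
      convergence = if (is.null(p$convergence)) 0 else p$convergence)
  })
  study_spec(pops, sympatry = config$study$sympatry, seed = config$seed)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full study pipeline
#'
#' Sequences the stages: simulate (or load) the phenotype table, optionally
#' render and re-phenotype images, build the 7 characteristic matrices and
#' the global distance, compute Var/Im/ms and the Var-ms correlation, the
#' morphospace embedding, and the characteristic-level variability report.
#' All outputs are written under `out_dir` together with a run manifest
#' (config hash, seed, package version); identical config + seed give
#' byte-identical CSV outputs.
#'
#' @param config a config list (see [validate_config()]) or YAML path.
#' @param out_dir output directory (created if missing).
#' @param from_stage resume from this stage, reading earlier stages'
#'   intermediate CSVs from `out_dir`.
#' @return Invisibly, a list (class `study_result`) with `phenotypes`,
#'   `matrices`, `summary` (Var/Im/ms table), `correlation`, `embedding`,
#'   `anatomy` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir, from_stage = "simulate") {
  if (is.character(config)) config <- read_study_config(config)
  config <- validate_config(unclass(config))
  from_stage <- match.arg(from_stage, PIPELINE_STAGES)
  start <- match(from_stage, PIPELINE_STAGES)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "matrices"), showWarnings = FALSE)
  opt <- config$options
  seed <- config$seed
  manifest <- list(
    config_hash = digest::digest(config),
    seed = seed,
    package = "warnsig",
    version = as.character(utils::packageVersion("warnsig")),
    options = opt)
  write_json(manifest, file.path(out_dir, "manifest.json"))

  stage_err <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }

  pheno_path <- file.path(out_dir, "phenotypes.csv")
  if (start <= 1L) {
    table <- stage_err("simulate", {
      if (!is.null(config$study)) {
        generate_phenotypes(config_to_study(config))
      } else {
        read_phenotypes(config$phenotypes_csv)
      }
    })
    write_phenotypes(table, pheno_path)
  } else {
    table <- read_phenotypes(pheno_path)
  }

  head_rasters <- NULL
  if (isTRUE(opt$use_images) && start <= 2L) {
    # image route: render every record, colour-correct, re-extract the
    # phenotype from pixels; the table's measured columns are replaced
    stage_err("phenotype", {
      rspec <- render_spec()
      template <- default_template(rspec)
      recs <- vector("list", nrow(table))
      for (i in seq_len(nrow(table))) {
        img <- render_frog(table[i, ], rspec)
        img <- color_correct(img)
        recs[[i]] <- phenotype_image(
          img, pattern_class = table$pattern_class[i], template = template,
          grid_size = opt$grid_size, blackness = opt$blackness,
          hue_mode = opt$hue_mode, transect_offset = opt$transect_offset)
      }
      head_rasters <- lapply(recs, `[[`, "head_raster")
      table$hue_head <- vapply(recs, function(r) r$colour_head$hue, 1)
      table$sat_head <- vapply(recs, function(r) r$colour_head$saturation, 1)
      table$hue_dorsum <- vapply(recs, function(r) r$colour_back$hue, 1)
      table$sat_dorsum <- vapply(recs, function(r) r$colour_back$saturation, 1)
      table$hue_limb <- vapply(recs, function(r) r$colour_limb$hue, 1)
      table$sat_limb <- vapply(recs, function(r) r$colour_limb$saturation, 1)
      table$dorsal_transitions_left <-
        vapply(recs, function(r) r$dorsal_transitions_left, 1)
      table$dorsal_transitions_right <-
        vapply(recs, function(r) r$dorsal_transitions_right, 1)
      table$limb_transitions <- vapply(recs, function(r) r$limb_transitions, 1)
      write_phenotypes(table, pheno_path)
    })
  }

  gd <- stage_err("distances", global_distance(
    table, head_rasters = head_rasters,
    hue_mode = opt$hue_mode, back_mode = opt$back_mode))
  for (ch in names(gd$normalized))
    write_matrix_csv(gd$normalized[[ch]],
                     file.path(out_dir, "matrices", paste0(ch, ".csv")))
  write_matrix_csv(gd$global, file.path(out_dir, "matglob.csv"))

  membership <- table[, c("individual_id", "species", "locality")]
  summary <- stage_err("mimicry",
    population_summary(gd$global, membership, aggregate = opt$aggregate))
  utils::write.csv(summary, file.path(out_dir, "mimicry.csv"),
                   row.names = FALSE, quote = FALSE)
  pts <- summary[!duplicated(paste(summary$species, summary$locality)) &
                 !is.na(summary$ms), ]
  correlation <- if (nrow(pts) >= 3 && sd(pts$var) > 0 && sd(pts$ms) > 0) {
    stage_err("mimicry",
              suppressWarnings(var_ms_correlation(pts$var, pts$ms)))
  } else NULL
  if (!is.null(correlation))
    write_json(unclass(correlation), file.path(out_dir, "correlation.json"))

  embedding <- stage_err("morphospace",
    classical_mds(gd$global, k = 2, method = opt$mds_method))
  emb_df <- data.frame(individual_id = rownames(embedding$points),
                       dim1 = embedding$points[, 1],
                       dim2 = embedding$points[, min(2, ncol(embedding$points))])
  utils::write.csv(emb_df, file.path(out_dir, "embedding.csv"),
                   row.names = FALSE, quote = FALSE)

  anatomy <- stage_err("anatomy", {
    vt <- variability_table(gd$normalized, membership)
    totals <- variance_sum(gd$normalized, membership)
    groups <- characteristic_groups(gd$normalized, membership)
    kw <- suppressWarnings(compare_characteristics(groups))
    list(variability = vt, totals = totals, tests = kw,
         ranking = rank_characteristics(vt))
  })
  utils::write.csv(anatomy$variability, file.path(out_dir, "anatomy_var.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(anatomy$totals, file.path(out_dir, "anatomy_totals.csv"),
                   row.names = FALSE, quote = FALSE)
  write_json(list(h = anatomy$tests$h, df = anatomy$tests$df,
                  p = anatomy$tests$p,
                  pairwise = as.data.frame(anatomy$tests$pairwise),
                  dependence_note = anatomy$tests$dependence_note),
             file.path(out_dir, "anatomy_tests.json"))

  invisible(structure(list(
    phenotypes = table, matrices = gd, summary = summary,
    correlation = correlation, embedding = embedding, anatomy = anatomy,
    manifest = manifest), class = "study_result"))
}
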