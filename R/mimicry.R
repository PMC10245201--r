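# Within-population variability (Var), centroid-based mimetic distance (Im),
# mimicry similarity (ms), and the Var-ms correlation.

# classical (Torgerson) MDS embedding retaining every component with a
# positive eigenvalue; the fused matrix is not guaranteed Euclidean-
# embeddable, so the dropped negative-eigenvalue mass is reported
mds_embed <- function(D, tol = 1e-9) {
  D <- unclass(as.matrix(D))
  n <- nrow(D)
  A <- -0.5 * D^2
  B <- A - outer(rowMeans(A), rep(1, n)) - outer(rep(1, n), colMeans(A)) +
    mean(A)                      # double centering: B = -1/2 J D^2 J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  thr <- tol * max(abs(e$values), 1e-300)
  keep <- which(e$values > thr)
  X <- if (length(keep)) {
    e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                             length(keep))
  } else {
    matrix(0, n, 1)
  }
  rownames(X) <- rownames(D)
  neg_mass <- sum(abs(pmin(e$values, 0))) / max(sum(abs(e$values)), 1e-300)
  list(points = X, eigenvalues = e$values, negative_mass = neg_mass)
}

resolve_members <- function(D, members) {
  if (is.character(members)) {
    idx <- match(members, rownames(D))
    if (anyNA(idx))
      ws_stop("lookup_error", sprintf(
        "individuals not in matrix: %s",
        paste(members[is.na(idx)], collapse = ", ")))
    idx
  } else as.integer(members)
}

#' Within-population warning-signal variability (Var)
#'
#' Mean pairwise phenotypic distance between all unordered pairs of
#' individuals of one population, computed on the global distance matrix.
#'
#' @param D global distance matrix (`char_matrix` or plain labelled matrix).
#' @param members individual IDs (or indices) of the population, length >= 2.
#' @return list (class `var_result`) with `var`, `n` and `n_pairs`.
#' @export
within_population_var <- function(D, members) {
  idx <- resolve_members(D, members)
  if (length(idx) < 2)
    ws_stop("insufficient_members", "Var needs at least 2 individuals")
  sub <- unclass(D)[idx, idx, drop = FALSE]
  structure(list(var = mean(sub[upper.tri(sub)]),
                 n = length(idx),
                 n_pairs = choose(length(idx), 2)),
            class = "var_result")
}

#' Centroid distance between two groups in MDS space
#'
#' Individuals are embedded by classical MDS on `D`, retaining all
#' positive-eigenvalue components; the distance between the two group mean
#' vectors in that embedding is returned.  On an exactly
#' Euclidean-embeddable matrix this equals the coordinate-space centroid
#' distance.
#'
#' @param D global distance matrix.
#' @param groupA,groupB individual IDs (or indices); non-empty.
#' @param embedding optional precomputed result of the internal embedding
#'   (used by [mimetic_distance()] to avoid re-embedding).
#' @return Non-negative scalar.
#' @export
centroid_distance <- function(D, groupA, groupB, embedding = NULL) {
  ia <- resolve_members(D, groupA); ib <- resolve_members(D, groupB)
  if (!length(ia) || !length(ib))
    ws_stop("lookup_error", "both groups must be non-empty")
  if (is.null(embedding)) embedding <- mds_embed(D)
  X <- embedding$points
  ca <- colMeans(X[ia, , drop = FALSE])
  cb <- colMeans(X[ib, , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

#' Mimetic distance (Im) and mimicry similarity (ms) for one population
#'
#' For each sympatric heterospecific partner,
#' `Im = centroid distance(focal, partner) / mean centroid distance(focal,
#' allopatric conspecific populations)`.  The mimicry similarity is
#' `ms = 1 / aggregate(Im)` with `aggregate = sum` by default (mean as an
#' option); with a single partner both give `ms = 1 / Im`.  `ms` grows with
#' mimetic perfection; values below 1 mean no detected convergence.
#'
#' @param D global distance matrix.
#' @param membership data.frame with columns `individual_id`, `species`,
#'   `locality` covering the labels of `D`.
#' @param focal list or one-row data.frame with `species` and `locality`.
#' @param partners character vector of sympatric partner species; defaults
#'   to all other species present at the focal locality.
#' @param aggregate `"sum"` (default) or `"mean"`.
#' @param embedding optional precomputed embedding (see
#'   [centroid_distance()]).
#' @return list (class `mimicry_result`) with `Im` (named per partner),
#'   `ms`, `classification`, `allopatric_mean` and the focal key.
#' @export
mimetic_distance <- function(D, membership, focal, partners = NULL,
                             aggregate = c("sum", "mean"),
                             embedding = NULL) {
  aggregate <- match.arg(aggregate)
  pop_ids <- function(sp, loc)
    membership$individual_id[membership$species == sp &
                             membership$locality == loc]
  focal_ids <- pop_ids(focal$species, focal$locality)
  if (!length(focal_ids))
    ws_stop("lookup_error", "focal population has no members")
  if (is.null(partners))
    partners <- setdiff(unique(
      membership$species[membership$locality == focal$locality]),
      focal$species)
  if (!length(partners))
    ws_stop("lookup_error", "focal population has no sympatric partner")
  allo_locs <- setdiff(unique(
    membership$locality[membership$species == focal$species]),
    focal$locality)
  if (!length(allo_locs))
    ws_stop("lookup_error", "no allopatric conspecific populations")
  if (is.null(embedding)) embedding <- mds_embed(D)
  allo <- vapply(allo_locs, function(l)
    centroid_distance(D, focal_ids, pop_ids(focal$species, l), embedding),
    numeric(1))
  denom <- mean(allo)
  if (denom <= 0)
    ws_stop("degenerate_denominator",
            "mean allopatric conspecific centroid distance is zero")
  Im <- vapply(partners, function(sp)
    centroid_distance(D, focal_ids, pop_ids(sp, focal$locality), embedding),
    numeric(1)) / denom
  ms <- 1 / switch(aggregate, sum = sum(Im), mean = mean(Im))
  structure(list(species = focal$species, locality = focal$locality,
                 Im = Im, ms = ms,
                 classification = classify_mimicry(ms),
                 allopatric_mean = denom,
                 negative_eigenvalue_mass = embedding$negative_mass),
            class = "mimicry_result")
}

#' Classify a mimicry-similarity value
#'
#' `ms < 1`: no mimetic convergence detected; `ms >= 1`: mimetic.
#' @param ms non-negative mimicry similarity.
#' @return `"non_mimetic"` or `"mimetic"`.
#' @export
classify_mimicry <- function(ms) {
  if (is.na(ms) || ms < 0)
    ws_stop("validation_error", "ms must be a non-negative number")
  if (ms < 1) "non_mimetic" else "mimetic"
}

#' Pearson correlation between Var and ms across population points
#'
#' Tests the predicted negative relationship between within-population
#' variability and mimicry similarity.  Each margin is first checked with a
#' Shapiro-Wilk normality test; non-normality produces a warning, not an
#' error.  The two-sided p-value from the t distribution with `n - 2`
#' degrees of freedom is reported alongside the one-sided
#' (negative-direction) p.
#'
#' @param var_values,ms_values paired numeric vectors (one point per
#'   population with at least one sympatric partner).
#' @return list (class `correlation_result`) with `r`, `df`, `p_two_sided`,
#'   `p_one_sided`, `shapiro_w`, `shapiro_p` (length-2, Var then ms margin)
#'   and `n`.
#' @export
var_ms_correlation <- function(var_values, ms_values) {
  stopifnot(length(var_values) == length(ms_values))
  n <- length(var_values)
  if (n < 3)
    ws_stop("insufficient_points", "need at least 3 population points")
  if (sd(var_values) == 0 || sd(ms_values) == 0)
    ws_stop("degenerate_error", "zero variance in a margin")
  sw <- lapply(list(var_values, ms_values), shapiro.test)
  if (any(vapply(sw, function(s) s$p.value, numeric(1)) < 0.05))
    warning("a margin deviates from normality (Shapiro-Wilk p < 0.05); ",
            "Pearson correlation reported anyway", call. = FALSE)
  ct <- cor.test(var_values, ms_values, method = "pearson",
                 alternative = "two.sided")
  r <- unname(ct$estimate)
  tstat <- unname(ct$statistic)
  structure(list(
    r = r, df = n - 2L,
    p_two_sided = ct$p.value,
    p_one_sided = stats::pt(tstat, df = n - 2),
    shapiro_w = vapply(sw, function(s) unname(s$statistic), numeric(1)),
    shapiro_p = vapply(sw, function(s) s$p.value, numeric(1)),
    n = n
  ), class = "correlation_result")
}

#' Var / Im / ms summary for every eligible population
#'
#' Computes Var for every population and Im/ms for every population with at
#' least one sympatric partner and at least one allopatric conspecific
#' population, sharing a single MDS embedding.
#'
#' @param D global distance matrix.
#' @param membership data.frame with `individual_id`, `species`, `locality`.
#' @param aggregate passed to [mimetic_distance()].
#' @return data.frame with one row per (population, partner) pair: columns
#'   `species`, `locality`, `n`, `var`, `partner`, `Im`, `ms`,
#'   `classification` (`NA` partner columns for populations without one).
#' @export
population_summary <- function(D, membership, aggregate = "sum") {
  embedding <- mds_embed(D)
  pops <- unique(membership[, c("species", "locality")])
  out <- NULL
  for (i in seq_len(nrow(pops))) {
    sp <- pops$species[i]; loc <- pops$locality[i]
    ids <- membership$individual_id[membership$species == sp &
                                    membership$locality == loc]
    v <- if (length(ids) >= 2) within_population_var(D, ids)$var else NA_real_
    partners <- setdiff(unique(
      membership$species[membership$locality == loc]), sp)
    allo <- setdiff(unique(
      membership$locality[membership$species == sp]), loc)
    if (length(partners) && length(allo)) {
      mr <- mimetic_distance(D, membership,
                             list(species = sp, locality = loc),
                             aggregate = aggregate, embedding = embedding)
      out <- rbind(out, data.frame(
        species = sp, locality = loc, n = length(ids), var = v,
        partner = names(mr$Im), Im = unname(mr$Im), ms = mr$ms,
        classification = mr$classification, stringsAsFactors = FALSE))
    } else {
      out <- rbind(out, data.frame(
        species = sp, locality = loc, n = length(ids), var = v,
        partner = NA_character_, Im = NA_real_, ms = NA_real_,
        classification = NA_character_, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
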