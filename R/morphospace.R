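# Warning-signal morphospace: MDS embedding, per-population density
# surfaces, and overlap/outlier quantification.

#' Classical multidimensional scaling of the global distance matrix
#'
#' Torgerson double centering and eigendecomposition; the top `k`
#' positive-eigenvalue coordinates are returned with a deterministic sign
#' convention (first nonzero loading of each axis positive).  If fewer than
#' `k` positive eigenvalues exist, the available dimensions are returned
#' with a warning.  A stress-minimizing non-metric variant
#' (`MASS::isoMDS`, tolerance 1e-6, at most 500 iterations) is available
#' behind `method = "nonmetric"`.
#'
#' @param D global distance matrix (`char_matrix` or labelled matrix).
#' @param k number of dimensions (default 2); `n >= k + 1` required.
#' @param method `"classical"` (default) or `"nonmetric"`.
#' @return list (class `morphospace_embedding`) with `points` (n x k,
#'   rownames = individual IDs), `eigenvalues` (all n, non-increasing),
#'   `retained_variance` (fraction of positive eigenvalue mass in the
#'   returned axes), `negative_mass`, and for the non-metric variant
#'   `stress`.
#' @export
classical_mds <- function(D, k = 2L, method = c("classical", "nonmetric")) {
  method <- match.arg(method)
  n <- nrow(as.matrix(D))
  k <- as.integer(k)
  if (n < k + 1)
    ws_stop("validation_error", "need at least k + 1 individuals")
  emb <- mds_embed(D)
  pos <- sum(emb$eigenvalues > 1e-9 * max(abs(emb$eigenvalues), 1e-300))
  k_eff <- min(k, pos)
  if (k_eff < k)
    warning(sprintf("only %d positive eigenvalue(s); returning %d dimension(s)",
                    pos, k_eff), call. = FALSE)
  X <- emb$points[, seq_len(max(k_eff, 1L)), drop = FALSE]
  if (method == "nonmetric") {
    d <- stats::as.dist(unclass(as.matrix(D)))
    fit <- MASS::isoMDS(d + 1e-12, y = X[, seq_len(max(k_eff, 2L)), drop = FALSE],
                        k = max(k_eff, 2L), maxit = 500, tol = 1e-6,
                        trace = FALSE)
    X <- fit$points
  }
  # sign convention: first nonzero loading of each axis positive
  for (j in seq_len(ncol(X))) {
    nz <- which(abs(X[, j]) > 1e-12)
    if (length(nz) && X[nz[1], j] < 0) X[, j] <- -X[, j]
  }
  pos_mass <- sum(pmax(emb$eigenvalues, 0))
  retained <- if (pos_mass > 0)
    sum(pmax(emb$eigenvalues[seq_len(k_eff)], 0)) / pos_mass else 0
  structure(list(points = X,
                 eigenvalues = emb$eigenvalues,
                 retained_variance = retained,
                 negative_mass = emb$negative_mass,
                 stress = if (method == "nonmetric") fit$stress else NULL,
                 method = method),
            class = "morphospace_embedding")
}

#' @export
print.morphospace_embedding <- function(x, ...) {
  cat(sprintf("morphospace: %d individuals, %d axes, %.1f%% variance retained\n",
              nrow(x$points), ncol(x$points), 100 * x$retained_variance))
  invisible(x)
}

#' Per-population frequency surfaces in the 2-D morphospace
#'
#' Bins the first two embedding axes on a common grid over the bounding box
#' (padded 5%) and returns per-population count matrices plus 10 equally
#' spaced frequency contour levels for plotting.
#'
#' @param embedding a `morphospace_embedding` with >= 2 axes (or an n x 2
#'   coordinate matrix).
#' @param assignments factor/character vector of population labels, one per
#'   individual.
#' @param bins grid resolution per axis (default 50).
#' @return list (class `density_map`) with `surfaces` (named list of
#'   bins x bins count matrices), `x_breaks`, `y_breaks` and `levels`
#'   (10 frequency levels per population).
#' @export
density_map <- function(embedding, assignments, bins = 50L) {
  X <- if (inherits(embedding, "morphospace_embedding"))
    embedding$points else as.matrix(embedding)
  if (ncol(X) < 2) ws_stop("validation_error", "need a 2-D embedding")
  X <- X[, 1:2, drop = FALSE]
  stopifnot(length(assignments) == nrow(X))
  pad <- function(r) r + c(-1, 1) * 0.05 * max(diff(r), 1e-12)
  rx <- pad(range(X[, 1])); ry <- pad(range(X[, 2]))
  xb <- seq(rx[1], rx[2], length.out = bins + 1L)
  yb <- seq(ry[1], ry[2], length.out = bins + 1L)
  pops <- unique(as.character(assignments))
  surfaces <- list(); levels <- list()
  for (p in pops) {
    sel <- assignments == p
    if (!any(sel)) { warning(sprintf("empty population '%s'", p)); next }
    ix <- pmin(pmax(findInterval(X[sel, 1], xb, all.inside = TRUE), 1L), bins)
    iy <- pmin(pmax(findInterval(X[sel, 2], yb, all.inside = TRUE), 1L), bins)
    m <- matrix(0L, bins, bins)
    for (i in seq_along(ix)) m[iy[i], ix[i]] <- m[iy[i], ix[i]] + 1L
    surfaces[[p]] <- m
    levels[[p]] <- seq(0, max(m), length.out = 11L)[-1]
  }
  structure(list(surfaces = surfaces, x_breaks = xb, y_breaks = yb,
                 levels = levels, bins = bins),
            class = "density_map")
}

#' Fraction of individuals closer to another conspecific population
#'
#' For the focal population, the fraction of individuals strictly closer to
#' some other conspecific population's centroid than to their own
#' population's centroid, where the own centroid excludes the individual
#' itself (leave-self-out) and ties are not outliers.  This operationalizes
#' "individuals harbouring warning signals more similar to those of other
#' localities".
#'
#' @param embedding a `morphospace_embedding` or coordinate matrix with
#'   rownames = individual IDs.
#' @param membership data.frame with `individual_id`, `species`, `locality`.
#' @param focal list with `species` and `locality`.
#' @return list (class `outlier_result`) with `fraction`, `n`, `outliers`
#'   (IDs).
#' @export
outlier_fraction <- function(embedding, membership, focal) {
  X <- if (inherits(embedding, "morphospace_embedding"))
    embedding$points else as.matrix(embedding)
  ids_of <- function(loc)
    membership$individual_id[membership$species == focal$species &
                             membership$locality == loc]
  focal_ids <- ids_of(focal$locality)
  if (!length(focal_ids)) ws_stop("lookup_error", "focal population empty")
  other_locs <- setdiff(unique(
    membership$locality[membership$species == focal$species]),
    focal$locality)
  if (!length(other_locs))
    ws_stop("undefined_fraction", "no conspecific alternative population")
  fi <- match(focal_ids, rownames(X))
  if (anyNA(fi)) ws_stop("lookup_error", "focal IDs missing from embedding")
  other_centroids <- lapply(other_locs, function(l) {
    oi <- match(ids_of(l), rownames(X))
    colMeans(X[oi, , drop = FALSE])
  })
  out <- character(0)
  for (j in seq_along(fi)) {
    i <- fi[j]
    own <- colMeans(X[setdiff(fi, i), , drop = FALSE])
    d_own <- sqrt(sum((X[i, ] - own)^2))
    d_other <- min(vapply(other_centroids, function(cc)
      sqrt(sum((X[i, ] - cc)^2)), numeric(1)))
    if (d_other < d_own) out <- c(out, focal_ids[j])
  }
  structure(list(fraction = length(out) / length(fi),
                 n = length(fi), outliers = out),
            class = "outlier_result")
}
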