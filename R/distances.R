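# Per-characteristic pairwise distance matrices, min-max normalization, and
# fusion into the global phenotypic distance.

new_char_matrix <- function(values, labels, characteristic) {
  dimnames(values) <- list(labels, labels)
  structure(values, characteristic = characteristic,
            class = c("char_matrix", "matrix", "array"))
}

check_char_matrix <- function(m, tol = 1e-10) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > tol) ws_stop("validation_error", "matrix not symmetric")
  if (max(abs(diag(m))) > tol) ws_stop("validation_error", "nonzero diagonal")
  if (min(m) < -tol) ws_stop("validation_error", "negative distances")
  invisible(m)
}

#' Euclidean distance matrix for one quantitative characteristic
#'
#' For colour characteristics (`colour.*`) each individual's value is a
#' `(hue, saturation)` pair; in `"circular"` hue mode the hue difference is
#' the shortest arc scaled to `[0, 1]` (`min(|dh|, 360 - |dh|) / 180`) and
#' the distance is `sqrt(dh'^2 + ds^2)`.  In `"linear"` mode hue degrees are
#' treated as plain numbers (literal-replication mode).  For pattern
#' characteristics the vectors are used as-is: the back-pattern
#' (left, right) transition pair, the scalar limb count, or the flattened
#' binary head raster (Euclidean distance = sqrt of the Hamming distance).
#'
#' @param values numeric matrix, one row per individual (a vector is taken
#'   as a one-column matrix); rownames are the individual IDs.
#' @param characteristic one of [characteristic_names()] (not
#'   `classif.pattern`, which uses [dice_matrix()]).
#' @param hue_mode `"circular"` (default) or `"linear"`; only consulted for
#'   colour characteristics.
#' @return A symmetric `char_matrix` with zero diagonal.
#' @export
euclidean_matrix <- function(values, characteristic,
                             hue_mode = c("circular", "linear")) {
  hue_mode <- match.arg(hue_mode)
  if (is.null(dim(values))) {
    values <- matrix(values, ncol = 1,
                     dimnames = list(names(values), NULL))
  }
  values <- as.matrix(values)
  if (anyNA(values))
    ws_stop("missing_data", sprintf(
      "missing values in characteristic '%s'; no imputation is performed",
      characteristic))
  labels <- rownames(values)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(values)))
  is_colour <- grepl("^colour\\.", characteristic)
  if (is_colour && hue_mode == "circular") {
    stopifnot(ncol(values) == 2)
    h <- values[, 1]; s <- values[, 2]
    dh <- hue_difference(outer(h, h, "-"), 0) / 180
    ds <- abs(outer(s, s, "-"))
    d <- sqrt(dh^2 + ds^2)
  } else {
    d <- as.matrix(stats::dist(values, method = "euclidean"))
  }
  diag(d) <- 0
  new_char_matrix(d, labels, characteristic)
}

#' Dice distance matrix for the qualitative pattern class
#'
#' Dice distance between single-label class sets: 0 when two individuals
#' share the class, 1 otherwise.
#'
#' @param classes character vector of classes from [pattern_classes()],
#'   optionally named by individual ID.
#' @return A symmetric binary `char_matrix`.
#' @export
dice_matrix <- function(classes) {
  bad <- setdiff(unique(classes), pattern_classes())
  if (length(bad))
    ws_stop("validation_error",
            sprintf("unknown pattern class(es): %s", paste(bad, collapse = ", ")))
  labels <- names(classes)
  if (is.null(labels)) labels <- as.character(seq_along(classes))
  d <- 1 - outer(classes, classes, "==")
  storage.mode(d) <- "double"
  new_char_matrix(d, labels, "classif.pattern")
}

#' Min-max normalize a distance matrix
#'
#' `NM = (mat - min) / (max - min)`, with min and max taken over the full
#' matrix including the zero diagonal — so for any matrix with positive
#' off-diagonal entries this reduces to division by the maximum.  A
#' constant matrix maps to all zeros.
#'
#' @param mat a `char_matrix`.
#' @return The normalized `char_matrix`, values in `[0, 1]`.
#' @export
minmax_normalize <- function(mat) {
  lo <- min(mat); hi <- max(mat)
  out <- if (hi > lo) (mat - lo) / (hi - lo) else mat * 0
  attributes(out) <- attributes(mat)
  attr(out, "normalized") <- TRUE
  out
}

#' Fuse the seven normalized matrices into the global phenotypic distance
#'
#' Entrywise `sqrt(sum_c NM_c^2)` over the seven normalized characteristic
#' matrices, giving all characteristics identical weight.  Entries lie in
#' `[0, sqrt(7)]`.
#'
#' @param matrices list of exactly 7 normalized `char_matrix` objects with
#'   identical labels in identical order (names are informative only; the
#'   fusion is symmetric in its inputs).
#' @return The global distance `char_matrix` (characteristic `"global"`).
#' @export
combine_characteristics <- function(matrices) {
  if (length(matrices) != 7)
    ws_stop("arity_error",
            sprintf("need exactly 7 matrices, got %d", length(matrices)))
  labels <- rownames(matrices[[1]])
  for (m in matrices) {
    if (!identical(rownames(m), labels))
      ws_stop("alignment_error", "matrices have mismatching labels")
    if (min(m) < 0 || max(m) > 1 + 1e-12)
      ws_stop("validation_error", "matrices must be normalized to [0, 1]")
  }
  acc <- matrix(0, length(labels), length(labels))
  for (m in matrices) acc <- acc + unclass(m)^2
  new_char_matrix(sqrt(acc), labels, "global")
}

#' Build all seven characteristic matrices from a phenotype table
#'
#' @param table phenotype data.frame as from [generate_phenotypes()] (or
#'   assembled from [phenotype_image()] records).
#' @param head_rasters optional list of `pattern_raster` objects, one per
#'   individual in table order; when supplied, the head-pattern distance is
#'   Euclidean on flattened binary rasters (the square root of the Hamming
#'   distance).  Without rasters the scalar analogue
#'   `sqrt(|coverage_i - coverage_j|)` is used: for frogs sharing a pattern
#'   class the rendered patterns are nested superlevel sets of one score
#'   field, so the raster Hamming distance is the head area times the
#'   coverage difference and the two modes agree after min-max
#'   normalization.
#' @param hue_mode `"circular"` or `"linear"`.
#' @param back_mode `"pair"` (default: the (left, right) transition pair) or
#'   `"sum"` (their sum).
#' @return Named list of 7 `char_matrix` objects, in
#'   [characteristic_names()] order.
#' @export
characteristic_matrices <- function(table, head_rasters = NULL,
                                    hue_mode = "circular",
                                    back_mode = c("pair", "sum")) {
  back_mode <- match.arg(back_mode)
  ids <- table$individual_id
  v <- function(m) { rownames(m) <- ids; m }
  head_mat <- if (is.null(head_rasters)) {
    cov <- table$head_coverage
    new_char_matrix(sqrt(abs(outer(cov, cov, "-"))), ids, "pattern.head")
  } else {
    stopifnot(length(head_rasters) == nrow(table))
    euclidean_matrix(v(do.call(rbind, lapply(head_rasters, as.numeric))),
                     "pattern.head")
  }
  back_vals <- if (back_mode == "pair") {
    v(cbind(table$dorsal_transitions_left, table$dorsal_transitions_right))
  } else {
    v(matrix(table$dorsal_transitions_left +
             table$dorsal_transitions_right, ncol = 1))
  }
  classes <- stats::setNames(table$pattern_class, ids)
  list(
    colour.head = euclidean_matrix(v(cbind(table$hue_head, table$sat_head)),
                                   "colour.head", hue_mode),
    colour.back = euclidean_matrix(v(cbind(table$hue_dorsum, table$sat_dorsum)),
                                   "colour.back", hue_mode),
    colour.limb = euclidean_matrix(v(cbind(table$hue_limb, table$sat_limb)),
                                   "colour.limb", hue_mode),
    pattern.head = head_mat,
    pattern.back = euclidean_matrix(back_vals, "pattern.back"),
    pattern.limb = euclidean_matrix(v(matrix(table$limb_transitions, ncol = 1)),
                                    "pattern.limb"),
    classif.pattern = dice_matrix(classes)
  )
}

#' Full fusion: table to global distance matrix
#'
#' Convenience wrapper: build the 7 characteristic matrices, min-max
#' normalize each, fuse.
#' @inheritParams characteristic_matrices
#' @return list with `characteristic` (raw matrices), `normalized`, and
#'   `global` (the fused `char_matrix`).
#' @export
global_distance <- function(table, head_rasters = NULL,
                            hue_mode = "circular", back_mode = "pair") {
  mats <- characteristic_matrices(table, head_rasters, hue_mode, back_mode)
  nms <- lapply(mats, minmax_normalize)
  list(characteristic = mats, normalized = nms,
       global = combine_characteristics(nms))
}

#' Write / read a labelled distance matrix as CSV
#'
#' Individual IDs form the header row and first column.
#' @param mat a `char_matrix`.
#' @param path file path.
#' @return `read_matrix_csv()` returns a `char_matrix`.
#' @export
write_matrix_csv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), unclass(mat), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @param characteristic characteristic label to attach on read.
#' @export
read_matrix_csv <- function(path, characteristic = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  new_char_matrix(m, df[[1]], characteristic)
}
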