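# Characteristic-level anatomy of warning-signal variability: which of the
# six quantitative characteristics vary most, within and across populations.

within_pairs <- function(NM, members) {
  idx <- resolve_members(NM, members)
  sub <- unclass(NM)[idx, idx, drop = FALSE]
  sub[upper.tri(sub)]
}

#' Within-population variability of one characteristic
#'
#' Mean normalized pairwise distance over all unordered pairs of the
#' population's individuals, for one characteristic's normalized matrix.
#'
#' @param NM normalized `char_matrix` for one characteristic.
#' @param members individual IDs (or indices), length >= 2.
#' @return list (class `characteristic_var`) with `var`, `n_pairs`, and the
#'   matrix's `characteristic` label.
#' @export
characteristic_var <- function(NM, members) {
  idx <- resolve_members(NM, members)
  if (length(idx) < 2)
    ws_stop("insufficient_members", "need at least 2 individuals")
  pd <- within_pairs(NM, members)
  structure(list(var = mean(pd), n_pairs = length(pd),
                 characteristic = attr(NM, "characteristic")),
            class = "characteristic_var")
}

#' Per-population, per-characteristic variability table
#'
#' @param normalized named list of normalized `char_matrix` objects (the 6
#'   quantitative characteristics; `classif.pattern` is skipped if present).
#' @param membership data.frame with `individual_id`, `species`, `locality`.
#' @return data.frame with columns `species`, `locality`, `characteristic`,
#'   `var`, `n_pairs`.
#' @export
variability_table <- function(normalized, membership) {
  normalized <- normalized[setdiff(names(normalized), "classif.pattern")]
  pops <- unique(membership[, c("species", "locality")])
  out <- NULL
  for (i in seq_len(nrow(pops))) {
    ids <- membership$individual_id[
      membership$species == pops$species[i] &
      membership$locality == pops$locality[i]]
    if (length(ids) < 2) next
    for (ch in names(normalized)) {
      cv <- characteristic_var(normalized[[ch]], ids)
      out <- rbind(out, data.frame(
        species = pops$species[i], locality = pops$locality[i],
        characteristic = ch, var = cv$var, n_pairs = cv$n_pairs,
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-characteristic totals across populations
#'
#' Two readings of "sum of the variance among all populations" are computed
#' and labelled distinctly: `sum_mean_pairwise`, the sum over populations of
#' the mean within-population pairwise distance (the Var sense), and
#' `sum_variance`, the sum over populations of the statistical variance of
#' the within-population pairwise distances.
#'
#' @param normalized named list of normalized `char_matrix` objects.
#' @param membership data.frame with `individual_id`, `species`, `locality`.
#' @return data.frame with one row per characteristic: `characteristic`,
#'   `sum_mean_pairwise`, `sum_variance`, `n_populations`.
#' @export
variance_sum <- function(normalized, membership) {
  normalized <- normalized[setdiff(names(normalized), "classif.pattern")]
  pops <- unique(membership[, c("species", "locality")])
  out <- NULL
  for (ch in names(normalized)) {
    s_mean <- 0; s_var <- 0; np <- 0L
    for (i in seq_len(nrow(pops))) {
      ids <- membership$individual_id[
        membership$species == pops$species[i] &
        membership$locality == pops$locality[i]]
      if (length(ids) < 2) next
      pd <- within_pairs(normalized[[ch]], ids)
      s_mean <- s_mean + mean(pd)
      s_var <- s_var + if (length(pd) > 1) stats::var(pd) else 0
      np <- np + 1L
    }
    out <- rbind(out, data.frame(
      characteristic = ch, sum_mean_pairwise = s_mean,
      sum_variance = s_var, n_populations = np, stringsAsFactors = FALSE))
  }
  out
}

#' Compare variability across characteristics (Kruskal-Wallis + Wilcoxon)
#'
#' Tests whether some characteristics are more variable than others: a
#' Kruskal-Wallis test over the groups of within-population pairwise
#' distances (df = groups - 1, chi-square p), followed by all pairwise
#' two-sided Wilcoxon rank-sum tests with Bonferroni multiplication
#' (capped at 1).  The groups share underlying individuals, so the
#' distances are not independent; the default unpaired rank-sum replicates
#' the field procedure, and a paired signed-rank mode over matched pairs is
#' available.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values), e.g. one vector of within-population pair distances per
#'   characteristic.
#' @param paired if `TRUE`, pairwise comparisons use the Wilcoxon
#'   signed-rank test on matched (equal-length) vectors.
#' @return list (class `kw_result`) with `h`, `df`, `p`, `pairwise`
#'   (symmetric matrix of Bonferroni-adjusted p-values), `paired` and a
#'   `dependence_note`.
#' @export
compare_characteristics <- function(groups, paired = FALSE) {
  if (length(groups) < 2)
    ws_stop("validation_error", "need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    ws_stop("validation_error", "each group needs at least 2 values")
  all_vals <- unlist(groups, use.names = FALSE)
  if (length(unique(all_vals)) == 1L) {
    warning("all values tied across all groups; H = 0, p = 1", call. = FALSE)
    kw <- list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
               parameter = c(df = length(groups) - 1L), p.value = 1)
  } else {
    kw <- kruskal.test(groups)
  }
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  pw <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  n_comp <- choose(k, 2)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    p <- tryCatch({
      if (paired) {
        stopifnot(length(groups[[i]]) == length(groups[[j]]))
        suppressWarnings(wilcox.test(groups[[i]], groups[[j]],
                                     paired = TRUE, exact = FALSE)$p.value)
      } else {
        suppressWarnings(wilcox.test(groups[[i]], groups[[j]],
                                     exact = FALSE)$p.value)
      }
    }, error = function(e) NA_real_)
    if (is.na(p)) p <- 1          # fully tied pair: no evidence against H0
    pw[i, j] <- pw[j, i] <- min(1, p * n_comp)
  }
  diag(pw) <- 1
  structure(list(
    h = unname(kw$statistic), df = unname(kw$parameter), p = kw$p.value,
    pairwise = pw, paired = paired,
    dependence_note = paste(
      "groups are within-population pairwise distances sharing individuals;",
      "observations are not independent")),
    class = "kw_result")
}

#' Rank characteristics by their within-population variability
#'
#' @param vtable output of [variability_table()].
#' @return list (class `characteristic_ranking`) with `overall` (data.frame
#'   of characteristic, mean var across populations, rank; ties share the
#'   min rank, stable order by characteristic name), `least_variable`,
#'   `most_variable`, and `by_population` (named list of ranked
#'   data.frames).
#' @export
rank_characteristics <- function(vtable) {
  stopifnot(all(c("species", "locality", "characteristic", "var") %in%
                names(vtable)))
  agg <- stats::aggregate(var ~ characteristic, data = vtable, FUN = mean)
  agg <- agg[order(agg$var, agg$characteristic), ]
  agg$rank <- rank(agg$var, ties.method = "min")
  rownames(agg) <- NULL
  key <- paste(vtable$species, vtable$locality, sep = "@")
  by_pop <- lapply(split(vtable, key), function(df) {
    df <- df[order(df$var, df$characteristic), ]
    df$rank <- rank(df$var, ties.method = "min")
    rownames(df) <- NULL
    df
  })
  structure(list(
    overall = agg,
    least_variable = agg$characteristic[agg$rank == min(agg$rank)],
    most_variable = agg$characteristic[agg$rank == max(agg$rank)],
    by_population = by_pop), class = "characteristic_ranking")
}

#' Within-population pair-distance groups per characteristic
#'
#' Collects, for each quantitative characteristic, the pooled vector of
#' within-population pairwise normalized distances — the groups compared by
#' [compare_characteristics()].
#'
#' @param normalized named list of normalized `char_matrix` objects.
#' @param membership data.frame with `individual_id`, `species`, `locality`.
#' @return Named list of numeric vectors.
#' @export
characteristic_groups <- function(normalized, membership) {
  normalized <- normalized[setdiff(names(normalized), "classif.pattern")]
  pops <- unique(membership[, c("species", "locality")])
  lapply(normalized, function(NM) {
    unlist(lapply(seq_len(nrow(pops)), function(i) {
      ids <- membership$individual_id[
        membership$species == pops$species[i] &
        membership$locality == pops$locality[i]]
      if (length(ids) < 2) return(numeric(0))
      within_pairs(NM, ids)
    }), use.names = FALSE)
  })
}
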