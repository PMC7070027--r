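# polyA tail summaries per transcript class and nonparametric tests for
# shifts between time points. Paired comparisons (each mRNA class providing
# one data point per time point) use the Wilcoxon signed-rank test; unpaired
# comparisons use the Mann-Whitney U test. Two-sided p values throughout,
# no multiple-testing correction.

#' Per-class, per-sample polyA summaries
#'
#' Means are computed over polyA-usable reads only (QC PASS and tail >= the
#' usability threshold applied in [attach_polya()]). Classes with zero
#' usable reads in every sample are omitted with a message.
#'
#' @param keyed_reads read table after [assign_groups()] and
#'   [attach_polya()].
#' @param class_by "group" (transcript group key) or "feature" (canonical
#'   feature via `annotations`).
#' @param annotations required for `class_by = "feature"`: annotation table
#'   whose matched_feature labels the class of each group; unmatched groups
#'   are pooled under "no known ORF".
#' @param groups group table, required for `class_by = "feature"`.
#' @return tibble (class_id, sample_id, polya_mean, polya_sd, polya_n); sd is
#'   the sample standard deviation (n-1 denominator), NA when n < 2.
#' @export
class_series <- function(keyed_reads, class_by = c("group", "feature"),
                         annotations = NULL, groups = NULL) {
  class_by <- match.arg(class_by)
  r <- keyed_reads
  if (class_by == "group") {
    r$class_id <- r$group_key
  } else {
    stopifnot(!is.null(annotations), !is.null(groups))
    feat <- annotations$matched_feature
    feat[is.na(feat)] <- "no known ORF"
    map <- stats::setNames(feat, groups$group_key[
      match(annotations$group_id, groups$group_id)])
    r$class_id <- unname(map[r$group_key])
  }
  usable <- r[r$polya_usable, ]
  dropped <- setdiff(unique(r$class_id), unique(usable$class_id))
  if (length(dropped)) {
    message(length(dropped), " class(es) without polyA-usable reads omitted")
  }
  usable |>
    dplyr::group_by(.data$class_id, .data$sample_id) |>
    dplyr::summarise(polya_mean = mean(.data$polya_length),
                     polya_sd = ifelse(dplyr::n() > 1,
                                       stats::sd(.data$polya_length), NA_real_),
                     polya_n = dplyr::n(), .groups = "drop")
}

#' Wilcoxon signed-rank test on paired class means
#'
#' Zero differences are dropped (their count is reported). The exact null
#' distribution is used for up to 25 informative pairs when the absolute
#' differences are tie-free; otherwise the normal approximation with tie
#' correction is used. The statistic W is the sum of ranks of the positive
#' differences (`y - x` convention is *not* used: differences are `x - y`).
#'
#' @param means_t1,means_t2 equal-length paired vectors (length >= 5 after
#'   zero removal).
#' @return list(statistic = W, p.value, n, n_zero, method).
#' @export
paired_test <- function(means_t1, means_t2) {
  stopifnot(length(means_t1) == length(means_t2))
  d <- means_t1 - means_t2
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0L) stop("degenerate pairing: all differences zero")
  if (length(d) < 5L) stop("paired_test needs >= 5 informative pairs")
  exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = !exact))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       n = length(d), n_zero = n_zero,
       method = if (exact) "exact" else "normal approximation, tie-corrected")
}

#' Mann-Whitney U test on two unpaired vectors
#'
#' The exact null distribution is used when n + m <= 12 and the pooled data
#' are tie-free; otherwise the normal approximation with tie correction.
#' The statistic U counts (x_i > y_j) pairs, so U(x,y) + U(y,x) = n*m.
#'
#' @param x,y numeric vectors, each length >= 3.
#' @return list(statistic = U, p.value, n, m, method).
#' @export
unpaired_test <- function(x, y) {
  stopifnot(length(x) >= 3L, length(y) >= 3L)
  exact <- (length(x) + length(y)) <= 12L && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       n = length(x), m = length(y),
       method = if (exact) "exact" else "normal approximation, tie-corrected")
}

#' Per-class polyA trend across ordered samples
#'
#' Reports each class's mean-length delta between consecutive samples and,
#' for every consecutive sample pair, the paired signed-rank test over class
#' means plus the unpaired Mann-Whitney U test on the same means. A
#' consistent negative delta with small paired p indicates progressive tail
#' shortening. With fewer than 5 classes the tests are refused (NA, with the
#' reason recorded) while deltas are still reported.
#'
#' @param series tibble from [class_series()].
#' @param sample_order character vector giving the temporal order.
#' @return list(deltas = tibble(class_id, from, to, delta),
#'   tests = tibble(from, to, n_classes, W, p_paired, U, p_unpaired, note)).
#' @export
trend_report <- function(series, sample_order) {
  stopifnot(length(sample_order) >= 2)
  wide <- lapply(sample_order, function(sid) {
    sub <- series[series$sample_id == sid, ]
    stats::setNames(sub$polya_mean, sub$class_id)
  })
  deltas <- list(); tests <- list()
  for (k in seq_len(length(sample_order) - 1L)) {
    a <- wide[[k]]; b <- wide[[k + 1L]]
    shared <- intersect(names(a), names(b))
    deltas[[k]] <- tibble::tibble(class_id = shared,
                                  from = sample_order[k],
                                  to = sample_order[k + 1L],
                                  delta = unname(b[shared] - a[shared]))
    if (length(shared) >= 5L) {
      pt <- paired_test(a[shared], b[shared])
      ut <- unpaired_test(a[shared], b[shared])
      tests[[k]] <- tibble::tibble(
        from = sample_order[k], to = sample_order[k + 1L],
        n_classes = length(shared), W = pt$statistic,
        p_paired = pt$p.value, U = ut$statistic, p_unpaired = ut$p.value,
        note = NA_character_)
    } else {
      tests[[k]] <- tibble::tibble(
        from = sample_order[k], to = sample_order[k + 1L],
        n_classes = length(shared), W = NA_real_, p_paired = NA_real_,
        U = NA_real_, p_unpaired = NA_real_,
        note = "tests refused: fewer than 5 shared classes")
    }
  }
  list(deltas = dplyr::bind_rows(deltas), tests = dplyr::bind_rows(tests))
}

#' Write the polyA trend TSV
#' @param series class series tibble.
#' @param trend result of [trend_report()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_trend_table <- function(series, trend, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tpath <- sub("\\.tsv$", "_tests.tsv", path)
  utils::write.table(as.data.frame(trend$tests), tpath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
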