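# Stated data filters and per-group aggregation.

#' Remove outliers outside mean +/- 2 SD
#'
#' Single-pass rule: the mean and sample SD are computed once on the full
#' input and values outside mean +/- 2 SD are removed. The rule is
#' deliberately not iterated — applying it twice to the kept values may
#' remove more, which is a documented behavioural contract, not a bug.
#'
#' @param values numeric vector, length >= 3.
#' @return list with `kept`, `removed`, `removed_idx`, `mean`, `sd`,
#'   `bounds`.
#' @export
remove_outliers_2sd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("outlier removal needs at least 3 values")
  m <- mean(values)
  s <- stats::sd(values)
  lo <- m - 2 * s
  hi <- m + 2 * s
  out <- values < lo | values > hi
  list(kept = values[!out], removed = values[out],
       removed_idx = which(out), mean = m, sd = s, bounds = c(lo, hi))
}

#' Per-group mean and SEM after outlier removal
#'
#' Applies [remove_outliers_2sd()] within each group (groups with fewer
#' than 3 values are kept untrimmed), then reports mean and SEM
#' (SD / sqrt(n)). Empty groups are skipped with a warning.
#'
#' @param df data frame.
#' @param value_col name of the numeric column to summarize.
#' @param group_col name of the grouping column.
#' @param id_col optional id column; removed ids are reported.
#' @return data frame with group, n_before, n_after, mean, sem,
#'   removed_ids (comma-separated).
#' @export
summarize_groups <- function(df, value_col, group_col, id_col = NULL) {
  stopifnot(value_col %in% names(df), group_col %in% names(df))
  groups <- unique(df[[group_col]])
  rows <- list()
  for (g in groups) {
    sel <- df[[group_col]] == g
    v <- df[[value_col]][sel]
    ids <- if (!is.null(id_col)) as.character(df[[id_col]][sel]) else
      as.character(which(sel))
    v_ok <- !is.na(v)
    v <- v[v_ok]; ids <- ids[v_ok]
    if (!length(v)) {
      warning("group '", g, "' is empty; skipped")
      next
    }
    if (length(v) >= 3) {
      trim <- remove_outliers_2sd(v)
      kept <- trim$kept
      removed_ids <- ids[trim$removed_idx]
    } else {
      kept <- v
      removed_ids <- character()
    }
    rows[[length(rows) + 1]] <- data.frame(
      group = as.character(g), n_before = length(v),
      n_after = length(kept), mean = mean(kept),
      sem = stats::sd(kept) / sqrt(length(kept)),
      removed_ids = paste(removed_ids, collapse = ","),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Welch two-sample summary
#'
#' Plain difference-of-means summary (Welch t interval) for comparing two
#' synthetic conditions; used in parameter-recovery checks, not a
#' replacement for a full inference workflow.
#'
#' @param x,y numeric vectors.
#' @param conf confidence level (default 0.95).
#' @return list with `diff`, `ci`, `t`, `df`, `p`.
#' @export
welch_summary <- function(x, y, conf = 0.95) {
  ht <- stats::t.test(x, y, conf.level = conf)
  list(diff = unname(ht$estimate[1] - ht$estimate[2]),
       ci = unname(ht$conf.int), t = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value)
}
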