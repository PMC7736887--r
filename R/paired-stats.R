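# Paired nonparametric inference: exact Wilcoxon signed-rank,
# Hodges-Lehmann estimates and intervals, stratified summaries.

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped; |d| are ranked with midranks for ties.
#' The two-sided p-value is exact — W+ enumerated over all 2^n sign
#' assignments — when n <= 20 and the |d| are tie-free; otherwise a
#' normal approximation with continuity correction and tie-corrected
#' variance is used. With every difference zero the test is degenerate
#' and p = 1.
#'
#' @param diffs Numeric vector of paired differences.
#' @return List: statistic (W+), p.value, n (nonzero differences),
#'   exact (logical), degenerate (logical).
#' @examples
#' wilcoxonSignedRank(c(1, 2, 3, 4, 5))$p.value  # 0.0625
#' @export
wilcoxonSignedRank <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p.value = 1, n = 0L, exact = FALSE,
                degenerate = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= 20 && !ties) {
    # exact: enumerate all 2^n sign assignments of the ranks
    dist <- signrank_distribution(n)
    tot <- 2^n
    p_le <- sum(dist$count[dist$w <= W + 1e-9]) / tot
    p_ge <- sum(dist$count[dist$w >= W - 1e-9]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    if (W == mu) z <- 0
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = W, p.value = p, n = n, exact = exact,
       degenerate = FALSE)
}

# null distribution of W+ for tie-free ranks 1..n (exact convolution)
signrank_distribution <- function(n) {
  counts <- 1
  for (k in seq_len(n)) counts <- c(counts, numeric(k)) +
      c(numeric(k), counts)
  list(w = 0:(n * (n + 1) / 2), count = counts)
}

#' Hodges-Lehmann estimate and confidence interval
#'
#' The estimate is the median of the n(n+1)/2 Walsh averages
#' (d_i + d_j)/2, i <= j. The CI endpoints are the k-th smallest and
#' k-th largest Walsh averages with k taken from the exact signed-rank
#' null distribution at the requested level, giving conservative
#' coverage >= level. When n is too small for the requested level the
#' widest attainable interval (the extreme Walsh averages) is returned
#' with \code{attained = FALSE}.
#'
#' @param diffs Numeric vector of paired differences (>= 1 value).
#' @param level Confidence level (default 0.95).
#' @return List: estimate, lo, hi, level, attained.
#' @export
hodgesLehmannCI <- function(diffs, level = 0.95) {
  n <- length(diffs)
  if (n < 1) stop("need at least one difference", call. = FALSE)
  w <- sort(walsh_averages(diffs))
  M <- length(w)
  est <- median(w)
  alpha <- 1 - level
  # largest k with P(W+ <= k - 1) <= alpha/2 under the exact null
  cdf <- psignrank(0:(n * (n + 1) %/% 2), n)
  ok <- which(cdf <= alpha / 2 + 1e-12)   # index i corresponds to W = i - 1
  if (length(ok)) {
    k <- max(ok)
    attained <- TRUE
  } else {
    k <- 1
    attained <- FALSE
  }
  list(estimate = est, lo = w[k], hi = w[M - k + 1], level = level,
       attained = attained)
}

walsh_averages <- function(d) {
  n <- length(d)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  (d[idx[, 1]] + d[idx[, 2]]) / 2
}

quartiles <- function(x) {
  # linear interpolation between order statistics (type 7)
  stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
}

#' Paired db-vs-wb comparison table
#'
#' One row per feature: median (IQR) under each modality, the
#' Hodges-Lehmann median difference (db - wb) with its confidence
#' interval, and the Wilcoxon signed-rank p-value. No multiplicity
#' adjustment is applied by default; \code{adjust = "holm"} enables
#' Holm correction for reuse.
#'
#' @param db,wb data.frames with a \code{case} column and one column
#'   per feature; case IDs must match.
#' @param features Character vector of feature columns (default: all
#'   shared numeric columns except \code{case}).
#' @param level Confidence level (default 0.95).
#' @param adjust "none" (default) or "holm".
#' @return data.frame with columns feature, db_median, db_q1, db_q3,
#'   wb_median, wb_q1, wb_q3, hl_difference, ci_lo, ci_hi, p_value,
#'   significant, degenerate.
#' @export
compareModalities <- function(db, wb, features = NULL, level = 0.95,
                              adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (!"case" %in% names(db) || !"case" %in% names(wb))
    stop("both tables need a 'case' column", call. = FALSE)
  miss <- c(setdiff(db$case, wb$case), setdiff(wb$case, db$case))
  if (length(miss))
    stop("unmatched case IDs: ", paste(unique(miss), collapse = ", "),
         call. = FALSE)
  wb <- wb[match(db$case, wb$case), , drop = FALSE]
  if (is.null(features))
    features <- setdiff(intersect(names(db), names(wb)), "case")
  rows <- lapply(features, function(f) {
    x <- db[[f]]; y <- wb[[f]]
    diffs <- x - y
    qs_db <- quartiles(x); qs_wb <- quartiles(y)
    wt <- wilcoxonSignedRank(diffs)
    hl <- hodgesLehmannCI(diffs, level = level)
    data.frame(
      feature = f,
      db_median = qs_db[2], db_q1 = qs_db[1], db_q3 = qs_db[3],
      wb_median = qs_wb[2], wb_q1 = qs_wb[1], wb_q3 = qs_wb[3],
      hl_difference = hl$estimate, ci_lo = hl$lo, ci_hi = hl$hi,
      p_value = wt$p.value, degenerate = wt$degenerate)
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p_value <- stats::p.adjust(out$p_value, "holm")
  out$significant <- out$p_value < 0.05
  rownames(out) <- NULL
  out
}

#' Size-stratified summary and db/wb fold changes
#'
#' Splits the cohort at the MRI longest-diameter cutoff (default
#' 2.5 cm) and reports, per stratum, modality and metric, the median
#' and IQR (linear-interpolation quartiles) plus the fold change of
#' stratum medians, fold = median_db / median_wb.
#'
#' @param metrics data.frame with columns \code{case}, \code{modality}
#'   ("db"/"wb"), \code{d_MRI_cm} and one column per metric.
#' @param cutoff d_MRI cutoff in cm (default 2.5).
#' @param metrics_cols Metric columns (default: all numeric columns
#'   except \code{d_MRI_cm}).
#' @return List: \code{summary} (long data.frame: stratum, modality,
#'   metric, median, q1, q3, n) and \code{fold_change} (data.frame:
#'   stratum, metric, fold). Empty strata are omitted with a warning.
#' @export
stratifiedSummary <- function(metrics, cutoff = 2.5,
                              metrics_cols = NULL) {
  need <- c("case", "modality", "d_MRI_cm")
  if (!all(need %in% names(metrics)))
    stop("metrics must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(metrics_cols))
    metrics_cols <- setdiff(
      names(metrics)[vapply(metrics, is.numeric, logical(1))], "d_MRI_cm")
  strata <- list(
    small = metrics$d_MRI_cm <= cutoff,
    large = metrics$d_MRI_cm > cutoff)
  names(strata) <- c(sprintf("d_MRI <= %.1f cm", cutoff),
                     sprintf("d_MRI > %.1f cm", cutoff))
  sum_rows <- list(); fold_rows <- list()
  for (s in names(strata)) {
    sub <- metrics[strata[[s]], , drop = FALSE]
    if (!nrow(sub)) {
      warning("empty stratum: ", s)
      next
    }
    med <- list()
    for (mod in c("db", "wb")) {
      smod <- sub[sub$modality == mod, , drop = FALSE]
      if (!nrow(smod)) next
      for (f in metrics_cols) {
        v <- smod[[f]][is.finite(smod[[f]])]
        if (!length(v)) next
        qs <- quartiles(v)
        med[[paste(mod, f)]] <- qs[2]
        sum_rows[[length(sum_rows) + 1L]] <- data.frame(
          stratum = s, modality = mod, metric = f, median = qs[2],
          q1 = qs[1], q3 = qs[3], n = length(v))
      }
    }
    for (f in metrics_cols) {
      m_db <- med[[paste("db", f)]]
      m_wb <- med[[paste("wb", f)]]
      if (is.null(m_db) || is.null(m_wb) || !is.finite(m_wb) || m_wb == 0)
        next
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        stratum = s, metric = f, fold = m_db / m_wb)
    }
  }
  list(summary = do.call(rbind, sum_rows),
       fold_change = do.call(rbind, fold_rows))
}
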