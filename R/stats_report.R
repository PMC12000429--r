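# Paired nonparametric comparison of two experimental conditions and the
# twelve-measure summary report.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples. For `n <= exact_max`
#' effective (non-zero) differences the p-value is computed by exact
#' enumeration over all `2^n` sign assignments of the observed absolute
#' ranks (ties handled through midranks); for larger samples a normal
#' approximation with continuity and tie correction is used. Zero
#' differences are handled per `zero_policy`: `"discard"` (classic) drops
#' them; `"split"` keeps them in the ranking with zero contribution to the
#' statistic (Pratt).
#'
#' @param values_A,values_B equal-length numeric vectors, paired by index.
#' @param zero_policy `"discard"` or `"split"`.
#' @param exact_max largest `n` for exact enumeration.
#' @return list with `p_value`, `statistic` (W+, computed on B - A),
#'   `n_effective`, `method`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(values_A, values_B,
                                 zero_policy = c("discard", "split"),
                                 exact_max = 12) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(length(values_A) == length(values_B))
  d <- values_B - values_A
  d <- d[is.finite(d)]
  if (!length(d) || all(d == 0)) {
    return(list(p_value = 1, statistic = NA_real_, n_effective = 0L,
                method = "degenerate", degenerate = TRUE))
  }
  if (zero_policy == "discard") {
    d <- d[d != 0]
    r <- rank(abs(d))
    contrib <- r
    signs_pos <- d > 0
  } else {
    r <- rank(abs(d))
    contrib <- ifelse(d == 0, 0, r)
    signs_pos <- d > 0
    keep <- d != 0
    contrib <- contrib[keep]
    signs_pos <- signs_pos[keep]
    r <- r[keep]
  }
  n <- length(contrib)
  if (n < 5) {
    stop("need at least 5 non-zero paired differences", call. = FALSE)
  }
  W <- sum(contrib[signs_pos])
  if (n <= exact_max) {
    # exact: distribution of W+ over all sign assignments of these ranks
    tot <- 2^n
    w_all <- numeric(tot)
    # enumerate via bit recursion to avoid building a 2^n x n matrix
    w_all <- 0
    for (i in seq_len(n)) {
      w_all <- c(w_all, w_all + contrib[i])
    }
    p_le <- sum(w_all <= W + 1e-9) / tot
    p_ge <- sum(w_all >= W - 1e-9) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(p_value = p, statistic = W, n_effective = n, method = method,
       degenerate = FALSE)
}

#' Percent difference between condition means
#'
#' `(mean_B - mean_A) / mean_A * 100`. Undefined when `mean_A` is zero; in
#' that case `NA` is returned with a warning.
#'
#' @param mean_A,mean_B condition means (A is the reference).
#' @return percent difference.
#' @export
diff_percent <- function(mean_A, mean_B) {
  if (mean_A == 0) {
    warning("diff_percent undefined for a zero reference mean")
    return(NA_real_)
  }
  (mean_B - mean_A) / mean_A * 100
}

.report_measures <- data.frame(
  measure = c("t_SKF", "t_SAPF", "delta_SAPF_LLTD",
              "dmag_TL", "dp_TL_x", "dp_TL_y",
              "dmag_RB", "dp_RB_x", "dp_RB_y",
              "dmag_CoM", "dp_CoM_x", "dp_CoM_y"),
  unit = c(rep("%GC", 3), rep("kg m/s", 9)),
  source = c(rep("events", 3), rep("impulses", 9)),
  stringsAsFactors = FALSE
)

#' Compare two experimental conditions measure by measure
#'
#' Runs the paired Wilcoxon signed-rank test on the twelve standard
#' measures — the event timings `t_SKF`, `t_SAPF` and
#' `delta_SAPF_LLTD = t_SAPF - t_LLTD`, and the magnitude, horizontal and
#' vertical momentum changes of the trailing leg, remaining body and CoM
#' over the step-to-step transition — pairing cycles by index. Cycles
#' missing in either condition for a measure are dropped pairwise. No
#' multiple-testing correction is applied; each measure is reported at the
#' `alpha` significance convention.
#'
#' @param events_A,events_B `gait_events` objects of the two conditions.
#' @param impulses_A,impulses_B `impulse_table` objects.
#' @param alpha significance level for the flag column.
#' @param zero_policy passed to [wilcoxon_signed_rank()].
#' @return data.frame of class `comparison_report`: per measure `mean_A`,
#'   `sd_A`, `mean_B`, `sd_B`, `diff_percent`, `p_value`, `significant`,
#'   `n`.
#' @export
compare_experiments <- function(events_A, events_B, impulses_A, impulses_B,
                                alpha = 0.001, zero_policy = "discard") {
  stopifnot(inherits(events_A, "gait_events"),
            inherits(events_B, "gait_events"),
            inherits(impulses_A, "impulse_table"),
            inherits(impulses_B, "impulse_table"))
  nA <- nrow(events_A$per_cycle); nB <- nrow(events_B$per_cycle)
  if (nA != nB || nrow(impulses_A$per_cycle) != nrow(impulses_B$per_cycle)) {
    stop("conditions have mismatched cycle counts; cannot pair by index",
         call. = FALSE)
  }
  pull <- function(events, impulses, measure, source) {
    if (source == "events") events$per_cycle[[measure]]
    else impulses$per_cycle[[measure]]
  }
  rows <- lapply(seq_len(nrow(.report_measures)), function(i) {
    ms <- .report_measures$measure[i]
    src <- .report_measures$source[i]
    a <- pull(events_A, impulses_A, ms, src)
    b <- pull(events_B, impulses_B, ms, src)
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    wt <- wilcoxon_signed_rank(a, b, zero_policy = zero_policy)
    data.frame(
      measure = ms, unit = .report_measures$unit[i],
      mean_A = mean(a), sd_A = sd(a),
      mean_B = mean(b), sd_B = sd(b),
      diff_percent = suppressWarnings(diff_percent(mean(a), mean(b))),
      p_value = wt$p_value,
      significant = !wt$degenerate && wt$p_value < alpha,
      n = length(a),
      stringsAsFactors = FALSE
    )
  })
  rep <- do.call(rbind, rows)
  attr(rep, "alpha") <- alpha
  attr(rep, "provenance") <- list(
    condition_A = events_A$provenance$condition,
    condition_B = events_B$provenance$condition,
    filtering = events_A$provenance$filtering,
    threshold = events_A$provenance$threshold,
    zero_policy = zero_policy,
    note = "no multiple-testing correction; per-measure reporting"
  )
  class(rep) <- c("comparison_report", "data.frame")
  rep
}

#' Serialize a comparison report
#'
#' Writes the report as CSV (with `#`-prefixed provenance header lines) or
#' JSON (with an explicit provenance block). A round-trip through either
#' format preserves all numeric fields.
#'
#' @param report a [compare_experiments()] report.
#' @param format `"csv"` or `"json"`.
#' @param path output file; if `NULL` the serialized text is returned.
#' @return the output path, or the text invisibly.
#' @export
render_report <- function(report, format = c("csv", "json"), path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(report, "comparison_report"))
  prov <- attr(report, "provenance")
  if (format == "csv") {
    hdr <- c(
      sprintf("# comparison report: %s vs %s",
              prov$condition_A, prov$condition_B),
      sprintf("# significance convention: p < %g, no correction (%s zeros)",
              attr(report, "alpha"), prov$zero_policy)
    )
    lines <- c(hdr, capture_csv(as.data.frame(report)))
    if (is.null(path)) return(invisible(paste(lines, collapse = "\n")))
    writeLines(lines, path)
    return(path)
  }
  obj <- list(report = as.data.frame(report), alpha = attr(report, "alpha"),
              provenance = prov)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(txt)))
  writeLines(as.character(txt), path)
  path
}

#' Parse a serialized comparison report back into a data.frame
#' @param path file written by [render_report()].
#' @param format `"csv"` or `"json"`.
#' @return data.frame of the report rows.
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path)$report)
  }
}

# data.frame -> CSV lines without writing a temp file
capture_csv <- function(df) {
  tc <- textConnection("out", "w", local = TRUE)
  write.csv(df, tc, row.names = FALSE)
  close(tc)
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s vs %s (alpha = %g)\n",
              attr(x, "provenance")$condition_A,
              attr(x, "provenance")$condition_B, attr(x, "alpha")))
  df <- as.data.frame(x)
  df$mean_A <- signif(df$mean_A, 4); df$mean_B <- signif(df$mean_B, 4)
  df$sd_A <- signif(df$sd_A, 2); df$sd_B <- signif(df$sd_B, 2)
  df$diff_percent <- round(df$diff_percent, 2)
  df$p_value <- signif(df$p_value, 3)
  print(df)
  invisible(x)
}
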