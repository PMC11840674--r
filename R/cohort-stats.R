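## Group-level nonparametric comparisons. All reporting follows the
## convention of medians with ranges. The computational engines are R's
## vetted stats routines; this module standardises their interface, the
## exact-vs-approximate switch and degenerate-input handling into one
## record shape.

.groupComparison <- function(metric, test, groups, n, statistic, p_value,
                             medians, ranges, flag = NA_character_) {
  structure(list(metric = metric, test = test, groups = groups, n = n,
                 statistic = statistic, p_value = p_value,
                 medians = medians, ranges = ranges, flag = flag),
            class = "groupComparison")
}

#' @export
print.groupComparison <- function(x, ...) {
  cat(sprintf("%s: %s (%s)\n", x$test, x$metric,
              paste(sprintf("%s n=%d", x$groups, x$n), collapse = " vs ")))
  cat(sprintf("  statistic = %s, p = %.5g\n",
              format(x$statistic, digits = 6), x$p_value))
  for (i in seq_along(x$groups))
    cat(sprintf("  %s: median %.5g (range %.5g to %.5g)\n", x$groups[i],
                x$medians[i], x$ranges[i, 1L], x$ranges[i, 2L]))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

.rangeRow <- function(x) if (length(x)) range(x) else c(NA_real_, NA_real_)

#' Mann-Whitney U test for two independent groups
#'
#' Two-sided. The exact null distribution is used when the combined sample
#' size is at most \code{exactLimit} and there are no ties; otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param x,y non-empty numeric vectors.
#' @param metric,groups labels carried into the result record.
#' @param exactLimit combined-size ceiling for the exact distribution
#'   (default 20).
#' @return a \code{groupComparison} record (statistic is the U of the first
#'   group).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$p_value   # exact 0.1
#' @export
mannWhitneyU <- function(x, y, metric = "metric", groups = c("x", "y"),
                         exactLimit = 20L) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= exactLimit && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  .groupComparison(metric, "mann_whitney", groups,
                   n = c(length(x), length(y)),
                   statistic = unname(wt$statistic), p_value = wt$p.value,
                   medians = c(stats::median(x), stats::median(y)),
                   ranges = rbind(.rangeRow(x), .rangeRow(y)))
}

#' Wilcoxon signed rank test for paired measurements
#'
#' Two-sided, on the pairwise differences \code{post - pre}. Zero
#' differences are dropped (Wilcoxon's original rule). The exact null
#' distribution is used when at most \code{exactLimit} non-zero differences
#' remain and their absolute values are untied. When every difference is
#' zero the test is degenerate: p is reported as 1 with a flag.
#'
#' @param pre,post equal-length paired numeric vectors.
#' @param metric label carried into the record.
#' @param exactLimit ceiling for the exact distribution (default 15).
#' @return a \code{groupComparison} record (statistic is the signed-rank V
#'   of positive differences).
#' @examples
#' wilcoxonSignedRank(1:5, 2:6)$p_value   # exact 2/32 = 0.0625
#' @export
wilcoxonSignedRank <- function(pre, post, metric = "metric",
                               exactLimit = 15L) {
  if (length(pre) != length(post))
    stop("paired vectors must have equal length")
  if (!length(pre)) stop("empty paired vectors")
  d <- post - pre
  nz <- d[d != 0]
  if (!length(nz))
    return(.groupComparison(metric, "wilcoxon_signed_rank",
                            c("pre", "post"),
                            n = c(length(pre), length(post)),
                            statistic = 0, p_value = 1,
                            medians = c(stats::median(pre),
                                        stats::median(post)),
                            ranges = rbind(.rangeRow(pre), .rangeRow(post)),
                            flag = "degenerate: all differences zero"))
  exact <- length(nz) <= exactLimit && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(
    stats::wilcox.test(nz, exact = exact, correct = TRUE))
  .groupComparison(metric, "wilcoxon_signed_rank", c("pre", "post"),
                   n = c(length(pre), length(post)),
                   statistic = unname(wt$statistic), p_value = wt$p.value,
                   medians = c(stats::median(pre), stats::median(post)),
                   ranges = rbind(.rangeRow(pre), .rangeRow(post)),
                   flag = if (length(nz) < length(d))
                     sprintf("%d zero difference(s) dropped",
                             length(d) - length(nz)) else NA_character_)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided by hypergeometric minimum-likelihood summation. A zero row or
#' column margin makes the test degenerate; p is reported as 1 with a
#' flag.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param metric label carried into the record.
#' @return a \code{groupComparison} record (statistic is the sample odds
#'   ratio estimate, NA when degenerate).
#' @examples
#' fisherExact2x2(matrix(c(5, 0, 0, 5), 2))$p_value   # 2/252
#' @export
fisherExact2x2 <- function(tab, metric = "metric") {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L) || any(tab < 0) || any(tab != floor(tab)))
    stop("expected a 2x2 table of non-negative integer counts")
  rowMed <- apply(tab, 1L, stats::median)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(.groupComparison(metric, "fisher_exact",
                            c("row1", "row2"), n = rowSums(tab),
                            statistic = NA_real_, p_value = 1,
                            medians = rowMed,
                            ranges = rbind(.rangeRow(tab[1, ]),
                                           .rangeRow(tab[2, ])),
                            flag = "degenerate: zero margin"))
  ft <- stats::fisher.test(tab)
  .groupComparison(metric, "fisher_exact", c("row1", "row2"),
                   n = rowSums(tab),
                   statistic = unname(ft$estimate), p_value = ft$p.value,
                   medians = rowMed,
                   ranges = rbind(.rangeRow(tab[1, ]), .rangeRow(tab[2, ])))
}

#' Kruskal-Wallis rank-sum test across several groups
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' k - 1 degrees of freedom.
#'
#' @param groups named (or unnamed) list of at least two non-empty numeric
#'   vectors.
#' @param metric label carried into the record.
#' @return a \code{groupComparison} record (statistic is H).
#' @export
kruskalWallis <- function(groups, metric = "metric") {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(lengths(groups) == 0L)) stop("empty group")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  if (length(unique(unlist(groups))) == 1L) {
    ## every observation tied: the tie correction annihilates H
    return(.groupComparison(metric, "kruskal_wallis", nm,
                            n = lengths(groups), statistic = 0,
                            p_value = 1,
                            medians = vapply(groups, stats::median,
                                             numeric(1)),
                            ranges = do.call(rbind,
                                             lapply(groups, .rangeRow)),
                            flag = "degenerate: all observations equal"))
  }
  kt <- stats::kruskal.test(groups)
  .groupComparison(metric, "kruskal_wallis", nm,
                   n = lengths(groups),
                   statistic = unname(kt$statistic), p_value = kt$p.value,
                   medians = vapply(groups, stats::median, numeric(1)),
                   ranges = do.call(rbind, lapply(groups, .rangeRow)))
}

## one tidy row per comparison for the cohort roll-up file
.comparisonRow <- function(gc) {
  data.frame(metric = gc$metric, test = gc$test,
             groups = paste(gc$groups, collapse = " vs "),
             n = paste(gc$n, collapse = "/"),
             statistic = unname(gc$statistic), p_value = gc$p_value,
             medians = paste(signif(gc$medians, 6), collapse = "/"),
             flag = ifelse(is.na(gc$flag), "", gc$flag),
             stringsAsFactors = FALSE)
}
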