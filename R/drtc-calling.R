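#' Exact two-sided binomial p-value for a clone split across two samples
#'
#' A clone observed \code{countA} times in sample A (productive total
#' \code{totalA}) and \code{countB} times in sample B (total \code{totalB})
#' is tested against the null hypothesis that its templates are evenly
#' distributed between the two samples relative to their repertoire sizes:
#' the combined count \code{n = countA + countB} is treated as a fixed
#' number of Bernoulli trials with null success probability
#' \code{p0 = totalA / (totalA + totalB)}.
#'
#' The default two-sided p-value uses the minimum-likelihood rule: the sum
#' of \code{P(k | n, p0)} over every outcome \code{k} whose probability does
#' not exceed that of the observed count (up to a relative tie tolerance).
#' This rule is symmetric under swapping the two samples. Tail-doubling
#' (\code{2 * min(lower tail, upper tail)}, capped at 1) is available as an
#' alternative.
#'
#' @param countA,countB non-negative clone template counts, with
#'   \code{countA + countB > 0}.
#' @param totalA,totalB positive productive template totals.
#' @param method \code{"minlike"} (default) or \code{"doubling"}.
#' @param tieTolerance relative tolerance for probability ties in the
#'   minimum-likelihood comparison.
#' @return a single p-value in (0, 1].
#' @examples
#' binomTwoSidedP(5, 0, 1000, 1000)      # 2/32 = 0.0625
#' binomTwoSidedP(3, 1, 1000, 3000)      # 0.05078125
#' binomTwoSidedP(2, 2, 1000, 1000)      # 1 (observed count is the mode)
#' @export
binomTwoSidedP <- function(countA, countB, totalA, totalB,
                           method = c("minlike", "doubling"),
                           tieTolerance = 1e-7) {
  method <- match.arg(method)
  stopifnot(length(countA) == 1L, length(countB) == 1L,
            countA >= 0, countB >= 0, countA == floor(countA),
            countB == floor(countB), totalA > 0, totalB > 0,
            countA <= totalA, countB <= totalB)
  n <- countA + countB
  if (n == 0)
    stop("undefined test: combined count is zero ",
         "(gate on the count floor before testing)")
  p0 <- totalA / (totalA + totalB)
  if (method == "minlike") {
    d <- stats::dbinom(0:n, n, p0)
    p <- sum(d[d <= d[countA + 1L] * (1 + tieTolerance)])
  } else {
    lower <- stats::pbinom(countA, n, p0)
    upper <- stats::pbinom(countA - 1L, n, p0, lower.tail = FALSE)
    p <- 2 * min(lower, upper)
  }
  min(max(p, .Machine$double.xmin), 1)
}

## vectorised driver used by callDRTC
.binomTwoSidedPVec <- function(countA, countB, totalA, totalB,
                               method = "minlike", tieTolerance = 1e-7) {
  vapply(seq_along(countA), function(i) {
    binomTwoSidedP(countA[i], countB[i], totalA, totalB,
                   method = method, tieTolerance = tieTolerance)
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment: for p-values sorted ascending,
#' \code{q_i = min_{j >= i} (p_j * m / j)} capped at 1, returned in the
#' original order. Adjustment never lowers a p-value.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as the input.
#' @examples
#' bhAdjust(c(0.005, 0.01, 0.03))   # 0.015 0.015 0.030
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Call donor-reactive T-cell clones from a paired MLR / unstimulated
#' comparison
#'
#' Implements the differential-abundance definition of donor reactivity.
#' The clone universe is the union of productive rearrangements across the
#' MLR-sorted and the unstimulated pre-transplant sample (count 0 where
#' absent). Clones with a combined count below \code{countFloor} are not
#' tested (call \code{below_count_floor}, no p-value). The remaining clones
#' receive the exact two-sided binomial p-value of [binomTwoSidedP()] under
#' the repertoire-size-weighted null, adjusted by Benjamini-Hochberg across
#' the tested clones of this single pairwise comparison. A clone is called
#' \code{drtc} when its adjusted p-value is below \code{alpha} and its MLR
#' frequency is at least \code{foldMin} times its unstimulated frequency; a
#' clone absent from the unstimulated sample satisfies the fold criterion by
#' convention (no pseudocount). Clones significant in the opposite direction
#' (at least \code{foldMin}-fold more frequent unstimulated) are
#' \code{enriched_unstim}; everything else is \code{not_significant}.
#'
#' @param mlrSample \linkS4class{RepertoireSample}, the MLR-sorted
#'   population (CD4+ or CD8+).
#' @param unstimSample \linkS4class{RepertoireSample}, the unstimulated
#'   pre-transplant sample.
#' @param alpha FDR threshold on the adjusted p-value (default 0.01).
#' @param foldMin minimum MLR/unstimulated frequency ratio (default 2).
#' @param countFloor minimum combined template count for a clone to be
#'   tested (default 5).
#' @param method two-sided p-value rule, see [binomTwoSidedP()].
#' @param tieTolerance see [binomTwoSidedP()].
#' @return a \linkS4class{DRTCSet} carrying the full per-clone result table
#'   and the parameters used.
#' @export
callDRTC <- function(mlrSample, unstimSample, alpha = 0.01, foldMin = 2,
                     countFloor = 5L, method = c("minlike", "doubling"),
                     tieTolerance = 1e-7) {
  stopifnot(is(mlrSample, "RepertoireSample"),
            is(unstimSample, "RepertoireSample"))
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value in (0, 1)")
  if (foldMin < 1) stop("foldMin must be >= 1")
  countFloor <- as.integer(countFloor)
  if (countFloor < 1L) stop("countFloor must be >= 1")

  clA <- mlrSample@clones[mlrSample@clones$productive, , drop = FALSE]
  clB <- unstimSample@clones[unstimSample@clones$productive, , drop = FALSE]
  totalA <- sum(clA$templates)
  totalB <- sum(clB$templates)
  if (totalA == 0L || totalB == 0L)
    stop("both samples must contain productive templates")

  universe <- sort(union(clA$rearrangement, clB$rearrangement))
  countA <- clA$templates[match(universe, clA$rearrangement)]
  countB <- clB$templates[match(universe, clB$rearrangement)]
  countA[is.na(countA)] <- 0L
  countB[is.na(countB)] <- 0L
  freqA <- countA / totalA
  freqB <- countB / totalB

  tested <- (countA + countB) >= countFloor
  p <- rep(NA_real_, length(universe))
  q <- rep(NA_real_, length(universe))
  if (any(tested)) {
    p[tested] <- .binomTwoSidedPVec(countA[tested], countB[tested],
                                    totalA, totalB, method = method,
                                    tieTolerance = tieTolerance)
    q[tested] <- bhAdjust(p[tested])
  }
  fold <- ifelse(freqB > 0, freqA / freqB, ifelse(freqA > 0, Inf, NaN))

  call <- rep("not_significant", length(universe))
  call[!tested] <- "below_count_floor"
  sig <- tested & !is.na(q) & q < alpha
  call[sig & freqA >= foldMin * freqB & freqA > 0] <- "drtc"
  call[sig & freqB >= foldMin * freqA & freqB > 0 &
         call != "drtc"] <- "enriched_unstim"

  results <- data.frame(
    rearrangement = universe,
    count_mlr = countA, count_unstim = countB,
    total_mlr = totalA, total_unstim = totalB,
    freq_mlr = freqA, freq_unstim = freqB,
    fold = fold, p_value = p, q_value = q, call = call,
    stringsAsFactors = FALSE)

  new("DRTCSet",
      subjectId = mlrSample@subjectId,
      subset = mlrSample@subset,
      results = results,
      parameters = list(alpha = alpha, foldMin = foldMin,
                        countFloor = countFloor, method = method,
                        tieTolerance = tieTolerance))
}

#' Tally call classes of a differential-abundance result
#'
#' @param x a \linkS4class{DRTCSet} or its result data.frame.
#' @return named integer vector over the four call classes (\code{drtc},
#'   \code{enriched_unstim}, \code{not_significant},
#'   \code{below_count_floor}); the values sum to the universe size.
#' @export
classifyScatter <- function(x) {
  res <- if (is(x, "DRTCSet")) x@results else x
  if (!is.data.frame(res) || (nrow(res) && is.null(res$call)))
    stop("expected a DRTCSet or a result table with a 'call' column")
  counts <- stats::setNames(integer(length(.CALL_CLASSES)), .CALL_CLASSES)
  if (nrow(res)) {
    tab <- table(factor(res$call, levels = .CALL_CLASSES))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Write a DRTC result table as tab-separated text
#'
#' Infinite fold changes are written as the literal \code{inf}. Parameter
#' provenance is recorded in '#'-prefixed header lines.
#'
#' @param drtc a \linkS4class{DRTCSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDRTCTable <- function(drtc, path) {
  stopifnot(is(drtc, "DRTCSet"))
  res <- drtc@results
  res$fold <- ifelse(is.infinite(res$fold), "inf",
                     ifelse(is.nan(res$fold), "NA",
                            format(res$fold, digits = 8, trim = TRUE)))
  p <- drtc@parameters
  header <- c(
    sprintf("# DRTC differential abundance: subject %s, subset %s",
            drtc@subjectId, drtc@subset),
    sprintf("# alpha=%g foldMin=%g countFloor=%d method=%s",
            p$alpha, p$foldMin, p$countFloor, p$method))
  .writeTsvWithHeader(res, path, header)
  invisible(path)
}
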