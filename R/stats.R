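## Statistical pipeline on maximum occupancy time distributions.
## All tests are evaluated at alpha = 0.01 by default.

#' Distribution descriptors and Tukey outlier fence
#'
#' Summarizes a t_max sample (contacting residues only, t_max > 0) by
#' its median, quartiles and the box-plot upper fence
#' `T = Q3 + 1.5 (Q3 - Q1)` used as the outlier threshold.  Quartiles
#' use linear interpolation between order statistics (R quantile type 7
#' by default; the convention is configurable because printed thresholds
#' are only reproducible to printed precision).
#'
#' @param values Numeric vector of t_max values in ns.
#' @param label Sample label.
#' @param quantileType Passed to [stats::quantile()].
#' @return One-row data.frame: `label`, `n_contacting`, `median_ns`,
#'   `q1_ns`, `q3_ns`, `outlier_threshold_ns`.
#' @examples
#' ## quartiles 4.5 and 113.6 ns give a fence of 277.25 ns
#' tukeyFence(4.5, 113.6)
#' @export
summarizeTmax <- function(values, label = "sample", quantileType = 7) {
    values <- values[is.finite(values)]
    if (length(values) < 4L)
        stop("quartiles undefined: need at least 4 values")
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = quantileType,
                         names = FALSE)
    data.frame(label = label,
               n_contacting = length(values),
               median_ns = q[2], q1_ns = q[1], q3_ns = q[3],
               outlier_threshold_ns = tukeyFence(q[1], q[3]),
               stringsAsFactors = FALSE)
}

#' Tukey box-plot upper fence
#'
#' @param q1,q3 First and third quartiles.
#' @return `q3 + 1.5 * (q3 - q1)`.
#' @export
tukeyFence <- function(q1, q3) q3 + 1.5 * (q3 - q1)

#' Chi-square critical value
#'
#' Upper critical value referenced by the rank tests: the `1 - alpha`
#' quantile of the chi-square distribution.
#'
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @return Numeric critical value (e.g. 9.21 for alpha 0.01, df 2).
#' @export
chi2Critical <- function(alpha = 0.01, df) {
    if (alpha <= 0 || alpha >= 1)
        stop("alpha must be in (0, 1)")
    if (df < 1)
        stop("df must be >= 1")
    stats::qchisq(1 - alpha, df)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness z-score and the Anscombe-Glynn
#' kurtosis z-score into the omnibus statistic K^2 = z_s^2 + z_k^2,
#' referred to a chi-square distribution with 2 degrees of freedom.
#'
#' @param values Numeric sample (n >= 20 recommended; smaller samples
#'   set a warning flag since the z approximations degrade).
#' @param alpha Significance level.
#' @return A data.frame with `test`, `statistic`, `df`, `alpha`,
#'   `critical`, `p_value`, `reject`, `small_n_warning`.
#' @export
dagostinoPearson <- function(values, alpha = 0.01) {
    x <- values[is.finite(values)]
    n <- length(x)
    if (n < 8L)
        stop("need at least 8 observations")
    if (stats::sd(x) == 0)
        stop("undefined moments: constant input")
    zs <- .skewnessZ(x)
    zk <- .kurtosisZ(x)
    k2 <- zs^2 + zk^2
    crit <- chi2Critical(alpha, 2)
    data.frame(test = "dagostino_pearson", statistic = k2, df = 2L,
               alpha = alpha, critical = crit,
               p_value = stats::pchisq(k2, 2, lower.tail = FALSE),
               reject = k2 > crit,
               small_n_warning = n < 20L,
               stringsAsFactors = FALSE)
}

## D'Agostino (1970) transformed skewness z-score
.skewnessZ <- function(x) {
    n <- length(x)
    m2 <- mean((x - mean(x))^2)
    m3 <- mean((x - mean(x))^3)
    g1 <- m3 / m2^1.5
    y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
    b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
        ((n - 2) * (n + 5) * (n + 7) * (n + 9))
    w2 <- -1 + sqrt(2 * (b2 - 1))
    delta <- 1 / sqrt(log(sqrt(w2)))
    a <- sqrt(2 / (w2 - 1))
    delta * log(y / a + sqrt((y / a)^2 + 1))
}

## Anscombe-Glynn (1983) transformed kurtosis z-score
.kurtosisZ <- function(x) {
    n <- length(x)
    m2 <- mean((x - mean(x))^2)
    m4 <- mean((x - mean(x))^4)
    b2 <- m4 / m2^2
    eb2 <- 3 * (n - 1) / (n + 1)
    vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
    xx <- (b2 - eb2) / sqrt(vb2)
    beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
        sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
    a <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
    (1 - 2 / (9 * a) -
        ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
        sqrt(2 / (9 * a))
}

#' Kruskal-Wallis comparison of data-set t_max distributions
#'
#' Tie-corrected Kruskal-Wallis H over k samples, with the decision
#' taken against the chi-square critical value at `alpha` with k - 1
#' degrees of freedom.
#'
#' @param samples A list of (>= 2) non-empty numeric vectors.
#' @param alpha Significance level.
#' @return A data.frame with `test`, `statistic` (H), `df`, `alpha`,
#'   `critical`, `p_value`, `reject`.
#' @export
kruskalWallis <- function(samples, alpha = 0.01) {
    if (length(samples) < 2L)
        stop("need at least 2 samples")
    if (any(vapply(samples, length, 0L) == 0L))
        stop("empty sample")
    kt <- stats::kruskal.test(samples)
    df <- unname(kt$parameter)
    crit <- chi2Critical(alpha, df)
    h <- unname(kt$statistic)
    data.frame(test = "kruskal_wallis", statistic = h, df = df,
               alpha = alpha, critical = crit,
               p_value = unname(kt$p.value), reject = h > crit,
               stringsAsFactors = FALSE)
}

#' Two-sided Wilcoxon rank-sum test (normal approximation)
#'
#' @param a,b Non-empty numeric samples.
#' @param alpha Significance level.
#' @return A data.frame like [kruskalWallis()] (statistic is the
#'   standardized z; `critical` the normal quantile).
#' @export
wilcoxonRankSum <- function(a, b, alpha = 0.01) {
    if (!length(a) || !length(b))
        stop("both samples must be non-empty")
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    z <- stats::qnorm(wt$p.value / 2, lower.tail = FALSE)
    crit <- stats::qnorm(1 - alpha / 2)
    data.frame(test = "wilcoxon_rank_sum", statistic = unname(z), df = NA_integer_,
               alpha = alpha, critical = crit,
               p_value = unname(wt$p.value),
               reject = wt$p.value < alpha,
               stringsAsFactors = FALSE)
}

#' Merge replicate data-sets by Kruskal-Wallis with iterative leave-one-out
#'
#' If the full set of data-sets passes the Kruskal-Wallis test at
#' `alpha`, all are pooled into one macro-sample.  Otherwise every
#' leave-one-out subset is tested; among passing subsets the one with
#' the smallest H is merged and the excluded label recorded.  If no
#' subset of size k-1 passes, subsets of size k-2 (and so on, never
#' below 2) are examined; with two data-sets the merge happens iff the
#' k = 2 rank test passes.  If nothing passes, an empty macro-sample is
#' returned with reason `"irreconcilable data-sets"`.
#'
#' @param datasets Named list of numeric t_max vectors.
#' @param alpha Significance level.
#' @return A list with `members` (labels merged), `excluded` (labels
#'   left out), `values` (pooled vector), `H` (test result data.frame
#'   for the merged subset, NULL if empty), `reason`.
#' @export
leaveOneOutMerge <- function(datasets, alpha = 0.01) {
    stopifnot(!is.null(names(datasets)), all(nzchar(names(datasets))))
    labs <- names(datasets)
    k <- length(datasets)
    if (k < 2L)
        stop("need at least 2 data-sets")
    test <- function(sub) kruskalWallis(datasets[sub], alpha)
    full <- test(labs)
    if (!full$reject) {
        return(list(members = labs, excluded = character(),
                    values = unlist(datasets, use.names = FALSE),
                    H = full, reason = "all data-sets homogeneous"))
    }
    sizes <- if (k - 1L >= 2L) seq(k - 1L, 2L, by = -1L) else integer(0)
    for (size in sizes) {
        subsets <- utils::combn(labs, size, simplify = FALSE)
        results <- lapply(subsets, test)
        pass <- which(!vapply(results, function(r) r$reject, TRUE))
        if (length(pass)) {
            hs <- vapply(results[pass], function(r) r$statistic, 0)
            best <- pass[which.min(hs)]
            members <- subsets[[best]]
            return(list(members = members,
                        excluded = setdiff(labs, members),
                        values = unlist(datasets[members], use.names = FALSE),
                        H = results[[best]],
                        reason = sprintf("smallest-H passing subset of size %d (choice among %d passing subsets)",
                                         size, length(pass))))
        }
    }
    list(members = character(), excluded = labs, values = numeric(),
         H = NULL, reason = "irreconcilable data-sets")
}

#' Identify t_max outliers in a pooled macro-sample
#'
#' Residues whose pooled t_max strictly exceeds the macro-sample's
#' Tukey fence, sorted by decreasing t_max.  A value exactly at the
#' fence is not an outlier.
#'
#' @param values Numeric t_max vector (contacting residues).
#' @param ids Optional parallel identifiers (e.g. data-set/residue
#'   keys); defaults to indices.
#' @param quantileType Quartile convention, see [summarizeTmax()].
#' @return A list with `threshold_ns` and `outliers` (data.frame `id`,
#'   `tmax_ns`, descending).
#' @export
findOutliers <- function(values, ids = seq_along(values), quantileType = 7) {
    stopifnot(length(values) == length(ids))
    if (!length(values))
        stop("macro-sample is empty")
    q <- stats::quantile(values, c(0.25, 0.75), type = quantileType,
                         names = FALSE)
    thr <- tukeyFence(q[1], q[2])
    sel <- which(values > thr)
    o <- sel[order(values[sel], decreasing = TRUE)]
    list(threshold_ns = thr,
         outliers = data.frame(id = ids[o], tmax_ns = values[o],
                               stringsAsFactors = FALSE))
}
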