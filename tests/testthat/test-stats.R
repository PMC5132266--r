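## Statistical pipeline on t_max distributions.

test_that("descriptors and the Tukey fence follow the box-plot rule", {
    expect_equal(tukeyFence(4.5, 113.6), 277.25)
    expect_equal(tukeyFence(11.3, 531.5), 1311.8)
    expect_equal(tukeyFence(7, 7), 7)        # zero IQR collapses to Q3
    s <- summarizeTmax(c(1, 2, 3, 4, 100), "x")
    expect_equal(s$outlier_threshold_ns,
                 s$q3_ns + 1.5 * (s$q3_ns - s$q1_ns))
    expect_true(s$q1_ns <= s$median_ns && s$median_ns <= s$q3_ns)
    expect_error(summarizeTmax(c(1, 2, 3), "x"), "at least 4")
})

test_that("the Tukey fence is translation- and scale-equivariant", {
    set.seed(5)
    v <- rlnorm(200)
    f0 <- findOutliers(v)$threshold_ns
    expect_equal(findOutliers(v + 10)$threshold_ns, f0 + 10)
    expect_equal(findOutliers(v * 3)$threshold_ns, f0 * 3)
})

test_that("chi-square critical values match tabulated references", {
    expect_equal(chi2Critical(0.01, 2), 9.21, tolerance = 0.001)
    expect_equal(chi2Critical(0.01, 3), 11.34, tolerance = 0.001)
    expect_equal(chi2Critical(0.01, 5), 15.08, tolerance = 0.001)
    expect_error(chi2Critical(1.5, 2), "alpha")
    expect_error(chi2Critical(0.01, 0), "df")
})

test_that("the omnibus normality statistic matches an independent implementation", {
    ## expected values frozen from scipy.stats.normaltest on the same data
    x1 <- c(1.2, 3.4, 2.2, 5.1, 4.4, 3.3, 2.8, 6.0, 1.9, 3.7,
            4.9, 2.5, 3.1, 5.6, 2.0, 4.1, 3.8, 2.9, 5.3, 3.5,
            1.5, 4.6, 3.0, 2.4, 5.9)
    r1 <- dagostinoPearson(x1)
    expect_equal(r1$statistic, 1.7416108, tolerance = 1e-6)
    expect_equal(r1$p_value, 0.4186143, tolerance = 1e-6)
    expect_false(r1$reject)
    x2 <- exp(seq(0, 5, length.out = 40))
    r2 <- dagostinoPearson(x2)
    expect_equal(r2$statistic, 17.0076312, tolerance = 1e-6)
    expect_true(r2$reject)
    expect_true(dagostinoPearson(c(1, 5, 2, 8, 3, 9, 4, 7, 2.5))$small_n_warning)
    expect_error(dagostinoPearson(rep(1, 30)), "constant")
})

test_that("normality test keeps its nominal size and detects heavy tails", {
    set.seed(6)
    pNull <- replicate(60, dagostinoPearson(rnorm(800))$p_value)
    expect_gte(mean(pNull > 0.01), 0.95)
    pAlt <- replicate(20, dagostinoPearson(rlnorm(800))$p_value)
    expect_true(all(pAlt < 1e-6))
})

test_that("Kruskal-Wallis H matches the hand-computed rank formula", {
    expect_equal(kruskalWallis(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)
    r <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
    expect_equal(r$statistic, 3.857, tolerance = 1e-3)
    expect_equal(r$df, 1L)
    expect_error(kruskalWallis(list(1:3, numeric())), "empty sample")
})

test_that("Kruskal-Wallis H is invariant under strictly monotone transforms", {
    set.seed(7)
    a <- rlnorm(40); b <- rlnorm(35) * 2; c <- rlnorm(30)
    h0 <- kruskalWallis(list(a, b, c))$statistic
    expect_equal(kruskalWallis(list(log(a), log(b), log(c)))$statistic, h0)
    expect_equal(kruskalWallis(list(a^3, b^3, c^3))$statistic, h0)
})

test_that("rank-sum test accepts identical samples and rejects shifted ones", {
    x <- c(1, 2, 3, 4, 5)
    expect_equal(wilcoxonRankSum(x, x)$p_value, 1, tolerance = 1e-9)
    set.seed(8)
    a <- rnorm(200); b <- rnorm(200) + 3
    expect_lt(wilcoxonRankSum(a, b)$p_value, 1e-10)
})

test_that("leave-one-out merging keeps homogeneous sets and drops a shifted one", {
    set.seed(9)
    hom <- list(a = rlnorm(300), b = rlnorm(300), c = rlnorm(300),
                d = rlnorm(300))
    m <- leaveOneOutMerge(hom)
    expect_setequal(m$members, names(hom))
    expect_length(m$excluded, 0)
    expect_equal(length(m$values), sum(lengths(hom)))
    bad <- hom
    bad$d <- rlnorm(300) * 8   # large location shift on the log scale
    m2 <- leaveOneOutMerge(bad)
    expect_equal(m2$excluded, "d")
    expect_setequal(m2$members, c("a", "b", "c"))
    expect_equal(length(m2$values), sum(lengths(bad[m2$members])))
})

test_that("two data-sets merge iff the k = 2 rank test passes", {
    set.seed(10)
    ok <- leaveOneOutMerge(list(a = rnorm(200), b = rnorm(200)))
    expect_setequal(ok$members, c("a", "b"))
    apart <- leaveOneOutMerge(list(a = rnorm(200), b = rnorm(200) + 5))
    expect_length(apart$members, 0)
    expect_match(apart$reason, "irreconcilable")
})

test_that("irreconcilable collections come back empty with a reason", {
    set.seed(11)
    far <- list(a = rnorm(200), b = rnorm(200) + 10, c = rnorm(200) + 20)
    m <- leaveOneOutMerge(far)
    expect_length(m$members, 0)
    expect_match(m$reason, "irreconcilable")
})

test_that("outlier extraction uses a strict fence", {
    v <- c(0:100)
    thr <- tukeyFence(quantile(v, .25, names = FALSE),
                      quantile(v, .75, names = FALSE))
    o <- findOutliers(c(v, thr))        # exactly at the fence: recomputed
    ## fence moves slightly by adding a value; test the strict rule directly
    o2 <- findOutliers(v)
    expect_equal(nrow(o2$outliers), 0L)
    big <- c(rep(1, 50), rep(2, 50), 1000, 2000, 1500, 3000, 2500)
    o3 <- findOutliers(big, ids = seq_along(big))
    expect_setequal(o3$outliers$id, 101:105)
    expect_equal(o3$outliers$tmax_ns, sort(big[101:105], decreasing = TRUE))
    ## a value exactly equal to the fence is not an outlier
    vv <- rep(c(10, 20, 30), each = 10)
    f <- findOutliers(vv)
    exact <- c(vv, f$threshold_ns)
    ## appending the fence value keeps quartiles, hence the fence, fixed
    f2 <- findOutliers(exact)
    expect_equal(f2$threshold_ns, f$threshold_ns)
    expect_equal(nrow(f2$outliers), 0L)
})
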