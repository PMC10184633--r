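test_that("effect estimation matches pooled-variance hand computations", {
    v <- rbind(
        A = c(1, 1, 1, 3, 3, 3),     # exact contrast: lfc 2, s2 0, df 4
        B = c(1, 3, NA, 2, 4, NA),   # 2 vs 2: lfc 1, pooled s2 2, df 2
        C = c(NA, NA, NA, 1, 2, 3))  # control arm absent -> untestable
    colnames(v) <- c(vapply(1:3, function(r) formatSampleKey("CTRL", 24, r), ""),
                     vapply(1:3, function(r) formatSampleKey("TNF", 24, r), ""))
    m <- OmicsMatrix(v, "protein", "LOG2_LFQ")
    est <- estimateEffects(m, "TNF", 24)
    expect_equal(est$log2fc[1], 2)
    expect_equal(est$s2[1], 0)
    expect_equal(est$df[1], 4)
    expect_equal(est$log2fc[2], 1)
    expect_equal(est$s2[2], 2)
    expect_equal(est$df[2], 2)
    expect_false(est$testable[3])
    expect_true(is.na(est$log2fc[3]))
})

test_that("moderation fit recovers the variance prior and matches limma", {
    set.seed(31)
    n <- 5000; d0 <- 4; s0 <- 0.05; df <- 4
    s2 <- s0 * d0 / rchisq(n, d0) * rchisq(n, df) / df
    fit <- fitModeration(s2, df)
    expect_lt(abs(fit$d0 - d0) / d0, 0.25)
    expect_lt(abs(fit$s0Sq - s0) / s0, 0.10)
    # independent route: limma's F-distribution fit
    sq <- limma::squeezeVar(s2, df)
    expect_equal(fit$d0, sq$df.prior, tolerance = 1e-4)
    expect_equal(fit$s0Sq, sq$var.prior, tolerance = 1e-4)

    # zero excess spread: complete shrinkage, posteriors all equal the prior
    flat <- fitModeration(rep(2, 50), df)
    expect_true(is.infinite(flat$d0))
    mt <- moderatedT(rep(1, 50), rep(2, 50), df, flat, 3, 3)
    expect_equal(mt$s2_post, rep(flat$s0Sq, 50))
    sqf <- limma::squeezeVar(rep(2, 50), df)
    expect_equal(flat$s0Sq, sqf$var.prior, tolerance = 1e-8)

    # heavy contamination still yields a finite, sane fit
    s2c <- s2; s2c[1:500] <- s2c[1:500] * 100
    fitc <- fitModeration(s2c, df)
    expect_true(is.finite(fitc$d0))
    expect_lt(fitc$s0Sq / median(s2c), 2)
    expect_gt(fitc$s0Sq / median(s2c), 0.5)

    expect_error(fitModeration(rep(1, 5), 4), "ordinary t")
})

test_that("moderated t reduces to the ordinary t at d0 = 0", {
    set.seed(12)
    x <- rnorm(3, 1); y <- rnorm(3)
    lfc <- mean(x) - mean(y)
    s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 4
    mt <- moderatedT(lfc, s2, 4, list(d0 = 0, s0Sq = 1), 3, 3)
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(mt$t_mod, unname(tt$statistic))
    expect_equal(mt$p, tt$p.value)
    expect_equal(mt$df_total, 4)
})

test_that("null moderated p-values are uniform with nominal type-I error", {
    set.seed(77)
    n <- 5000
    stim <- matrix(rnorm(n * 3), n); ctrl <- matrix(rnorm(n * 3), n)
    lfc <- rowMeans(stim) - rowMeans(ctrl)
    s2 <- (apply(stim, 1, var) * 2 + apply(ctrl, 1, var) * 2) / 4
    mt <- moderatedT(lfc, s2, 4, fitModeration(s2, 4), 3, 3)
    expect_gte(mean(mt$p < 0.05), 0.04)
    expect_lte(mean(mt$p < 0.05), 0.06)
    expect_gt(stats::ks.test(mt$p, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches hand values and the step-up oracle", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0,1\\]")

    set.seed(40)
    for (i in 1:200) {
        p <- runif(sample(1:8, 1))^sample(1:3, 1)
        adj <- bhAdjust(p)
        expect_true(all(adj >= p))
        expect_true(all(adj <= 1))
        # monotone non-decreasing in rank order
        expect_true(all(diff(adj[order(p)]) >= 0))
        o <- sample(length(p))
        expect_equal(bhAdjust(p[o]), adj[o])             # permutation-equivariant
        for (alpha in c(0.01, 0.05, 0.2))
            expect_equal(adj <= alpha, bhOracleReject(p, alpha))
    }
})

test_that("event calls respect layer-specific alpha and the LFC gate", {
    res <- data.frame(feature = c("A", "B", "C"), condition = "TNF_IFN",
                      time_h = 24, log2fc = c(1.5, 0.5, 1.5),
                      p = c(0.0005, 0.0005, 0.04))
    out <- callEvents(res, thresholdConfig(), layer = "protein")
    # p_adj 0.0015 & lfc 1.5 -> significant; lfc 0.5 fails the gate
    expect_true(out$significant[1])
    expect_false(out$significant[2])
    expect_true(out$p_adj[1] >= out$p[1])

    # same p_adj under secretome alpha = 0.01 is no longer significant
    res2 <- data.frame(feature = "A", condition = "TNF", time_h = 24,
                       log2fc = 1.5, p = 0.04)
    expect_true(callEvents(res2, thresholdConfig(), "protein")$significant)
    expect_false(callEvents(res2, thresholdConfig(), "secretome")$significant)
})

test_that("event counts shrink as alpha or the LFC threshold tightens", {
    plan <- makeTruthPlan(c(TNF = 10, "NULL" = 10), layer = "transcript",
                          seed = 6)
    ds <- generateDataset(simConfig(noiseSd = 0.3, seed = 6), plan)
    m <- ds$matrices$transcript
    n <- vapply(list(thresholdConfig(),
                     thresholdConfig(alpha = 0.01),
                     thresholdConfig(lfcMin = 2)),
                function(cfg) sum(runDifferential(m, cfg)$significant), 0)
    expect_lte(n[2], n[1])
    expect_lte(n[3], n[1])
    expect_gt(n[1], 0)
})

test_that("no-intercept SILAC model recovers per-condition ratio means", {
    r <- matrix(c(1.0, 1.2, 0.8), 3, 1, dimnames = list(NULL, "TNF"))
    fit <- fitSilacNoIntercept(r)
    expect_equal(fit$effect, 1.0)
    expect_equal(fit$df, 2)

    # two balanced conditions: effects are column means, residual df = n - k
    r2 <- cbind(TNF = c(1, 2, 3), IFN = c(-1, 0, 1))
    fit2 <- fitSilacNoIntercept(r2)
    expect_equal(fit2$effect, c(2, 0))
    expect_equal(fit2$df, c(4, 4))
    # cross-check against lm() without intercept
    d <- data.frame(y = c(r2), cond = rep(c("TNF", "IFN"), each = 3))
    lmfit <- lm(y ~ 0 + cond, data = d)
    expect_equal(unname(fit2$effect),
                 unname(coef(lmfit)[c("condTNF", "condIFN")]))
    expect_equal(unname(fit2$t),
                 unname(summary(lmfit)$coefficients[c("condTNF", "condIFN"),
                                                    "t value"]))

    # all-zero ratios: effect 0, t 0
    z <- fitSilacNoIntercept(matrix(0, 3, 1, dimnames = list(NULL, "TNF")))
    expect_equal(z$effect, 0)
    expect_equal(z$t, 0)

    # a condition with < 2 observed ratios is untestable
    r3 <- cbind(TNF = c(1, 2, 3), IFN = c(0.5, NA, NA))
    fit3 <- fitSilacNoIntercept(r3)
    expect_false(fit3$testable[2])
    expect_true(is.na(fit3$t[2]))
})
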