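mkTc <- function(times, y) TimeCourse("G", "TNF_IFN", times,
                                      matrix(y, nrow = 1))

test_that("trapezoidal AUC matches closed forms and a fine-grid oracle", {
    expect_equal(timecourseAUC(mkTc(c(0, 24), c(1, 1)), "t0",
                               ctrl = NULL) + 0, 0)  # t0 baseline removes offset
    # rectangle: constant deflection 1 over [0, 24] relative to a zero control
    zero <- mkTc(c(0, 24), c(0, 0))
    expect_equal(timecourseAUC(mkTc(c(0, 24), c(1, 1)), "ctrl_course", zero),
                 24, tolerance = 1e-12)
    # triangle: linear 0 -> 2 over [0, 24]
    expect_equal(timecourseAUC(mkTc(c(0, 24), c(0, 2)), "t0"), 24,
                 tolerance = 1e-12)
    # piecewise (0,0), (4,2), (24,2): 0.5*4*2 + 20*2 = 44
    expect_equal(timecourseAUC(mkTc(c(0, 4, 24), c(0, 2, 2)), "t0"), 44,
                 tolerance = 1e-12)
    expect_error(timecourseAUC(mkTc(24, 1), "t0"), "2 timepoints")

    # random piecewise-linear courses vs dense numeric integration
    set.seed(21)
    for (i in 1:20) {
        times <- sort(c(0, runif(5, 0, 24), 24))
        y <- rnorm(7, 0, 3); y <- y - y[1]
        a <- timecourseAUC(mkTc(times, y), "t0")
        fine <- sort(unique(c(seq(0, 24, length.out = 1e5), times)))
        yf <- approx(times, y, xout = fine)$y
        n <- length(fine)
        oracle <- sum((yf[-1] + yf[-n]) / 2 * diff(fine))
        expect_equal(a, oracle, tolerance = 1e-9)
    }
})

test_that("time-course correlation is Pearson on medians with NA fallthrough", {
    t4 <- c(0, 2, 4, 8)
    expect_equal(timecourseCorrelation(mkTc(t4, 0:3), mkTc(t4, 0:3)), 1)
    expect_equal(timecourseCorrelation(mkTc(t4, 0:3), mkTc(t4, -(0:3))), -1)
    expect_equal(timecourseCorrelation(mkTc(t4, c(0, 1, 2, 3)),
                                       mkTc(t4, c(0, 2, 1, 3))), 0.8)
    expect_true(is.na(timecourseCorrelation(mkTc(t4, 0:3),
                                            mkTc(t4, rep(1, 4)))))
    expect_error(timecourseCorrelation(mkTc(t4, 0:3), mkTc(t4 + 1, 0:3)),
                 "grid mismatch")
    expect_error(timecourseCorrelation(mkTc(c(0, 4), 0:1), mkTc(c(0, 4), 0:1)),
                 "3 timepoints")
})

test_that("shape classes follow the strict correlation rules", {
    cfg <- thresholdConfig()
    expect_equal(classifyShape(0.9, 0.2, cfg), "S1")
    expect_equal(classifyShape(0.2, 0.9, cfg), "S2")
    expect_equal(classifyShape(0.9, 0.9, cfg), "S3")
    expect_equal(classifyShape(0.1, 0.2, cfg), "S4")
    expect_equal(classifyShape(0.5, 0.5, cfg), "NONE")   # the (0.3, 0.7) gap
    expect_equal(classifyShape(0.7, 0.9, cfg), "NONE")   # boundary excluded
    expect_equal(classifyShape(0.3, 0.3, cfg), "NONE")
    expect_equal(classifyShape(NA, 0.9, cfg), "NONE")
    # vectorized
    expect_equal(classifyShape(c(0.9, 0.2), c(0.2, 0.9), cfg), c("S1", "S2"))
})

test_that("effect classes follow the strict AUC-ratio rules", {
    cfg <- thresholdConfig()
    expect_equal(classifyEffect(10, 8, 1, cfg), "E1")    # ratios 1.25 / 10
    expect_equal(classifyEffect(10, 1, 8, cfg), "E2")
    expect_equal(classifyEffect(10, 2, 2, cfg), "E3")    # both ratios 5
    expect_equal(classifyEffect(10, 8, 8, cfg), "NONE")  # both 1.25
    expect_equal(classifyEffect(10, 5, 1, cfg), "NONE")  # ratio exactly 2
    expect_equal(classifyEffect(0, 2, 2, cfg), "NONE")   # zero combined AUC
    # sign disagreement forces that single's ratio to +Inf
    expect_equal(classifyEffect(10, 8, -3, cfg), "E1")
    expect_equal(classifyEffect(-10, -8, 3, cfg), "E1")
    expect_equal(classifyEffect(10, -8, -8, cfg), "E3")
})

test_that("the rule table maps shape/effect to final classes", {
    expect_equal(assignResponseClass("S1", "NONE"), "TNF")
    expect_equal(assignResponseClass("S2", "NONE"), "IFN")
    expect_equal(assignResponseClass("S3", "NONE"), "COMMON")
    expect_equal(assignResponseClass("S3", "E1"), "TNF")
    expect_equal(assignResponseClass("S3", "E2"), "IFN")
    expect_equal(assignResponseClass("S3", "E3"), "SYNERGY")
    expect_equal(assignResponseClass("S4", "NONE"), "SYNERGY")
    expect_equal(assignResponseClass("NONE", "E3"), "SYNERGY")
    expect_equal(assignResponseClass("S1", "E3"), "SYNERGY")  # E3 precedence
    expect_equal(assignResponseClass("NONE", "E1"), "NOT_CLASSIFIED")
    expect_equal(assignResponseClass("NONE", "NONE"), "NOT_CLASSIFIED")
    # literal S3-or-E3 reading: S3 alone becomes synergy
    expect_equal(assignResponseClass("S3", "NONE", rule = "s3-or-e3"),
                 "COMMON")
    expect_equal(assignResponseClass("S3", "E3", rule = "s3-or-e3"), "SYNERGY")
    expect_equal(assignResponseClass("S4", "NONE", rule = "s3-or-e3"),
                 "NOT_CLASSIFIED")
})

test_that("additive expectation sums deflections and is commutative", {
    t3 <- c(0, 4, 24)
    a <- mkTc(t3, c(0, 1, 2)); b <- mkTc(t3, c(0, 0, 0))
    expect_equal(tcMedians(additiveExpectation(a, b)), c(0, 1, 2))
    expect_equal(tcMedians(additiveExpectation(a, a)), c(0, 2, 4))
    expect_equal(tcMedians(additiveExpectation(a, mkTc(t3, c(0, 2, 1)))),
                 tcMedians(additiveExpectation(mkTc(t3, c(0, 2, 1)), a)))
    expect_error(additiveExpectation(a, mkTc(c(0, 5, 24), c(0, 1, 2))),
                 "grid mismatch")
})

test_that("synergy decomposition is exact AUC arithmetic summing to one", {
    expect_equal(unlist(synergyDecomposition(4, 6, 10)),
                 c(frac_tnf = 0.4, frac_ifn = 0.6, frac_excess = 0))
    expect_equal(unlist(synergyDecomposition(2, 2, 8)),
                 c(frac_tnf = 0.25, frac_ifn = 0.25, frac_excess = 0.5))
    expect_equal(unlist(synergyDecomposition(6, 6, 10)),
                 c(frac_tnf = 0.6, frac_ifn = 0.6, frac_excess = -0.2))
    set.seed(3)
    for (i in 1:20) {
        x <- rnorm(3); x[3] <- x[3] + sign(x[3]) + 1e-3
        d <- synergyDecomposition(x[1], x[2], x[3])
        expect_equal(d$frac_tnf + d$frac_ifn + d$frac_excess, 1,
                     tolerance = 1e-9)
    }
    expect_error(synergyDecomposition(1, 1, 0), "zero")
})

test_that("classification is invariant to time-unit rescaling", {
    # only correlations and AUC ratios enter the rules, so hours vs minutes
    # must not change any class
    set.seed(17)
    t_h <- c(0, 0.0333, 0.5, 4, 8, 12, 24)
    for (i in 1:10) {
        comb <- rnorm(7, 0, 2); tnf <- rnorm(7, 0, 2); ifn <- rnorm(7, 0, 2)
        cls_h <- assignResponseClass(
            classifyShape(timecourseCorrelation(comb, tnf),
                          timecourseCorrelation(comb, ifn)),
            classifyEffect(pracma::trapz(t_h, comb), pracma::trapz(t_h, tnf),
                           pracma::trapz(t_h, ifn)))
        t_m <- t_h * 60
        cls_m <- assignResponseClass(
            classifyShape(timecourseCorrelation(comb, tnf),
                          timecourseCorrelation(comb, ifn)),
            classifyEffect(pracma::trapz(t_m, comb), pracma::trapz(t_m, tnf),
                           pracma::trapz(t_m, ifn)))
        expect_identical(cls_h, cls_m)
    }
})

test_that("ground-truth classes are recovered on noisy synthetic data", {
    plan <- makeTruthPlan(c(TNF = 20, IFN = 20, COMMON = 20, SYNERGY = 20,
                            "NULL" = 20), layer = "transcript", seed = 14)
    ds <- generateDataset(simConfig(noiseSd = 0.2, seed = 14), plan)
    m <- ds$matrices$transcript
    diff <- runDifferential(m)
    cl <- classifyResponses(m, diff)
    mg <- merge(cl, ds$truth[, c("feature", "true_class")], by = "feature")
    nonnull <- mg[mg$true_class != "NULL", , drop = FALSE]
    expect_gte(nrow(nonnull), 70)
    expect_gte(mean(nonnull$final == nonnull$true_class), 0.9)
    # NULL features almost never pass the upstream significance gate
    expect_gte(mean(!(ds$truth$feature[ds$truth$true_class == "NULL"] %in%
                      mg$feature[mg$true_class == "NULL" &
                                 mg$final != "NOT_CLASSIFIED"])), 0.95)
    # stored intermediates are consistent with the stored classes
    rec <- assignResponseClass(classifyShape(mg$r_tnf, mg$r_ifn),
                               classifyEffect(mg$auc_comb, mg$auc_tnf,
                                              mg$auc_ifn))
    expect_identical(rec, mg$final)
})
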