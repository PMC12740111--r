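threeGroupManifest <- function() {
    data.frame(sample_id = sprintf("s%02d", 1:15),
               age_days = rep(c(7, 21, 35), each = 5),
               group = rep(c("W1", "W3", "W5"), each = 5),
               treatment = "none", stringsAsFactors = FALSE)
}

test_that("train/test split is stratified, deterministic, and guarded", {
    man <- threeGroupManifest()
    sp <- splitTrainTest(man, 10, seed = 4)
    expect_length(sp$train, 10)
    expect_length(sp$test, 5)
    per_group <- table(man$group[match(sp$train, man$sample_id)])
    expect_true(all(per_group %in% 3:4))
    expect_identical(sp, splitTrainTest(man, 10, seed = 4))
    expect_false(identical(sp$train, splitTrainTest(man, 10, seed = 5)$train))
    expect_error(splitTrainTest(man, 15, seed = 1), "non-empty test")
})

test_that("feature assembly matches clock type and composes with entropy", {
    fr <- cbind(s1 = c(0.5, 0.2, 0.9), s2 = c(0.5, 0.3, 0.8))
    mat <- tinyMatrix(fr)
    dms <- data.frame(site = siteKeys(mat)[2:3])

    lv <- assembleFeatures(mat, clockSpec("elasticnet_levels"))
    expect_equal(dim(lv), c(2L, 3L))
    expect_equal(unname(lv["s1", ]), unname(fr[, "s1"]))

    rd <- assembleFeatures(mat, clockSpec("ridge_dms"), dms)
    expect_equal(colnames(rd), dms$site)

    en <- assembleFeatures(mat, clockSpec("elasticnet_entropy"), dms)
    expect_equal(unname(en), unname(siteEntropy(rd)))
    all_half <- assembleFeatures(tinyMatrix(matrix(0.5, 3, 2,
        dimnames = list(NULL, c("s1", "s2")))), clockSpec("elasticnet_entropy"),
        data.frame(site = siteKeys(mat)))
    expect_true(all(all_half == 1))
    expect_error(assembleFeatures(mat, clockSpec("ridge_dms")), "requires")
})

test_that("a perfect single predictor is found and fit almost exactly", {
    set.seed(6)
    ages <- rep(c(7, 21, 35), each = 4)
    X <- cbind(clock_site = ages / 100,
               noise1 = runif(12), noise2 = runif(12))
    rownames(X) <- paste0("s", 1:12)
    m <- trainClock(X, ages, clockSpec("elasticnet_levels"))
    expect_s4_class(m, "ClockModel")
    expect_true("clock_site" %in% selectedSites(m))
    expect_gte(trainingMetrics(m)$pearson_r, 0.999)
    expect_lt(trainingMetrics(m)$mae_days, 1)
})

test_that("prediction is linear, reproduces the refit, and rejects missing sites", {
    set.seed(16)
    ages <- rep(c(7, 21, 35), each = 4)
    X <- matrix(rbeta(12 * 30, 2, 5), 12, 30,
                dimnames = list(paste0("s", 1:12), paste0("f", 1:30)))
    X[, 1] <- ages / 100 + rnorm(12, 0, 0.002)
    m <- suppressWarnings(trainClock(X, ages, clockSpec("elasticnet_levels")))

    # linearity on feature mixtures
    f1 <- X[1, , drop = FALSE]; f2 <- X[5, , drop = FALSE]
    for (al in c(0.25, 0.5, 0.8)) {
        mix <- al * f1 + (1 - al) * f2
        expect_equal(unname(predictAge(m, mix)),
                     al * unname(predictAge(m, f1)) +
                     (1 - al) * unname(predictAge(m, f2)),
                     tolerance = 1e-10)
    }

    # internal consistency: coefficients reproduce the glmnet refit's fitted
    # values at the chosen penalty
    lam <- methylAging:::.lambdaGrid(X, ages, 0.5, 100, 1e-4)
    refit <- glmnet::glmnet(X, ages, alpha = 0.5, lambda = lam,
                            standardize = TRUE)
    fitted <- as.numeric(predict(refit, X, s = m@lambda))
    expect_equal(unname(predictAge(m, X)), fitted, tolerance = 1e-8)

    # all-zero coefficient edge: prediction is the intercept
    flat <- methods::new("ClockModel", clockType = "elasticnet_levels",
                         mixing = 0.5, sites = character(0),
                         coefficients = numeric(0), intercept = 21,
                         lambda = 1, foldFeatureCounts = integer(0),
                         foldLambdas = numeric(0), cvPredictions = numeric(0),
                         trainingMetrics = list(), featureNames = colnames(X))
    expect_true(all(predictAge(flat, X) == 21))

    m2 <- m
    m2@sites <- c(m2@sites, "ghost:1:+:a")
    m2@coefficients <- c(m2@coefficients, 1)
    expect_error(predictAge(m2, X), "ghost")
})

test_that("prediction metrics match hand arithmetic", {
    perfect <- evaluatePredictions(c(7, 21, 35), c(7, 21, 35))
    expect_equal(perfect$mae_days, 0)
    expect_equal(perfect$mre_percent, 0)
    expect_equal(perfect$pearson_r, 1)

    off <- evaluatePredictions(c(8, 22, 36), c(7, 21, 35))
    expect_equal(off$mae_days, 1)
    expect_equal(off$mre_percent, 100 * (1 / 7 + 1 / 21 + 1 / 35) / 3,
                 tolerance = 1e-10)
    expect_equal(off$pearson_r, 1)

    anti <- evaluatePredictions(c(35, 21, 7), c(7, 21, 35))
    expect_equal(anti$pearson_r, -1)
    expect_error(evaluatePredictions(1:3, 1:4), "length mismatch")
    expect_error(evaluatePredictions(1:3, c(-1, 2, 3)), "positive")
})

test_that("feature stability reports both CV conventions and the ridge flag", {
    m <- methods::new("ClockModel", clockType = "elasticnet_levels",
                      mixing = 0.5, sites = "x", coefficients = c(x = 1),
                      intercept = 0, lambda = 1,
                      foldFeatureCounts = c(40L, 50L, 60L),
                      foldLambdas = c(1, 1, 1),
                      cvPredictions = c(1, 2, 3), trainingMetrics = list(),
                      featureNames = "x")
    fs <- featureStability(m)
    expect_equal(fs$mean_features, 50)
    expect_equal(fs$cv_percent, 20, tolerance = 1e-10)
    expect_equal(fs$cv_percent_population, 100 * sqrt(200 / 3) / 50,
                 tolerance = 1e-10)

    m@foldFeatureCounts <- c(7L, 7L, 7L)
    expect_equal(featureStability(m)$cv_percent, 0)
    m@foldFeatureCounts <- 5L
    expect_error(featureStability(m), "single fold")

    m@clockType <- "ridge_dms"
    m@foldFeatureCounts <- c(1L, 2L)
    rf <- featureStability(m)
    expect_equal(rf$cv_percent, 0)
    expect_match(rf$note, "ridge")
})

test_that("clock models serialize to JSON and back without loss", {
    set.seed(26)
    ages <- rep(c(7, 21, 35), each = 4)
    X <- matrix(rbeta(12 * 20, 2, 5), 12, 20,
                dimnames = list(paste0("s", 1:12), paste0("f", 1:20)))
    X[, 3] <- ages / 50 + rnorm(12, 0, 0.01)
    m <- suppressWarnings(trainClock(X, ages, clockSpec("elasticnet_levels")))
    p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
    writeClockModel(m, p1); writeClockModel(m, p2)
    expect_identical(readLines(p1), readLines(p2))   # deterministic bytes
    back <- readClockModel(p1)
    expect_equal(back@coefficients, m@coefficients)
    expect_equal(back@intercept, m@intercept)
    expect_equal(unname(predictAge(back, X)), unname(predictAge(m, X)),
                 tolerance = 1e-12)
})

test_that("permutation test hits the add-one floor on strong signal and errors on n_perm 0", {
    set.seed(36)
    ages <- rep(c(7, 21, 35), c(4, 3, 3))
    X <- cbind(strong = ages / 100 + rnorm(10, 0, 0.001),
               matrix(runif(10 * 10), 10,
                      dimnames = list(NULL, paste0("n", 1:10))))
    rownames(X) <- paste0("s", 1:10)
    pt <- permutationTest(X, ages, clockSpec("elasticnet_levels"),
                          n_perm = 30, seed = 2)
    expect_equal(pt$p_value, 1 / 31, tolerance = 1e-12)
    expect_identical(pt$permuted,
                     permutationTest(X, ages, clockSpec("elasticnet_levels"),
                                     n_perm = 30, seed = 2)$permuted)
    expect_error(permutationTest(X, ages, n_perm = 0), "n_perm")
})

test_that("training guards degenerate inputs", {
    X <- matrix(runif(12), 4, 3, dimnames = list(paste0("s", 1:4), NULL))
    expect_error(trainClock(X, rep(7, 4)), "constant-age")
    expect_error(trainClock(X[1:2, ], c(7, 21)), "at least 3")
    Xz <- X; Xz[, 2] <- 0.3
    expect_warning(trainClock(Xz, c(7, 14, 21, 35)), "zero-variance")
})

test_that("LOOCV training metrics are invariant to sample ordering", {
    set.seed(46)
    ages <- rep(c(7, 21, 35), c(4, 3, 3))
    X <- matrix(rbeta(10 * 25, 2, 8), 10, 25,
                dimnames = list(paste0("s", 1:10), paste0("f", 1:25)))
    X[, 1] <- ages / 100 + rnorm(10, 0, 0.01)
    m1 <- suppressWarnings(trainClock(X, ages, clockSpec("elasticnet_levels")))
    o <- c(4, 9, 1, 7, 2, 10, 3, 6, 5, 8)
    m2 <- suppressWarnings(trainClock(X[o, ], ages[o],
                                      clockSpec("elasticnet_levels")))
    expect_equal(m1@cvPredictions[rownames(X)[o]], m2@cvPredictions,
                 tolerance = 1e-10)
    expect_equal(trainingMetrics(m1)$mae_days, trainingMetrics(m2)$mae_days,
                 tolerance = 1e-10)
})
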