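test_that("count pooling sums across samples at one site", {
    mat <- tinyMatrix(cbind(s1 = c(0.1, 0.5), s2 = c(0.1, 0.1)),
                      coverage = 30L)
    key <- siteKeys(mat)[1]
    expect_equal(poolCounts(mat, c("s1", "s2"), key),
                 c(n_mod = 6, n_valid = 60))
    expect_equal(poolCounts(mat, "s1", key), c(n_mod = 3, n_valid = 30))
    zero <- tinyMatrix(cbind(a = c(0, 0), b = c(0, 0), c = c(0, 0),
                             d = c(0, 0), e = c(0, 0)), coverage = 10L)
    expect_equal(poolCounts(zero, letters[1:5], siteKeys(zero)[1]),
                 c(n_mod = 0, n_valid = 50))
    expect_error(poolCounts(mat, "s1", "nope:1:+:a"), "not present")
})

test_that("site test matches hypergeometric enumeration and the MAP closed form", {
    same <- siteTest(c(10, 100), c(10, 100))
    expect_equal(same$p_value, 1)
    expect_equal(same$effect_size, 0)

    st <- siteTest(c(10, 100), c(30, 100))
    expect_equal(st$p_value, enumFisherP(10, 100, 30, 100), tolerance = 1e-12)
    expect_equal(st$effect_size, 0.2)

    # MAP of Beta(1 + n_mod, 1 + n_canon) is the observed fraction, so the
    # extreme table gives the maximal score
    ext <- siteTest(c(0, 50), c(50, 50))
    expect_equal(ext$map_score, 1)
    expect_equal(siteTest(c(25, 50), c(25, 50))$map_score, 0)

    # symmetry: swapping conditions keeps p, flips the effect sign
    a <- siteTest(c(3, 40), c(17, 45))
    b <- siteTest(c(17, 45), c(3, 40))
    expect_equal(a$p_value, b$p_value)
    expect_equal(a$effect_size, -b$effect_size)

    expect_error(siteTest(c(0, 0), c(5, 10)), "zero valid")
})

test_that("vectorized Fisher p agrees with enumeration on random tables", {
    set.seed(7)
    va <- sample(5:200, 40, TRUE); vb <- sample(5:200, 40, TRUE)
    ma <- vapply(va, function(v) sample(0:v, 1), 1L)
    mb <- vapply(vb, function(v) sample(0:v, 1), 1L)
    fast <- methylAging:::.fisherPVec(ma, va, mb, vb)
    slow <- mapply(enumFisherP, ma, va, mb, vb)
    expect_equal(fast, slow, tolerance = 1e-12)
    # and both match fisher.test on a few
    for (i in 1:5)
        expect_equal(fast[i],
                     fisher.test(matrix(c(ma[i], va[i] - ma[i],
                                          mb[i], vb[i] - mb[i]), 2))$p.value,
                     tolerance = 1e-9)
})

test_that("BH adjustment matches the brute-force step-up on random vectors", {
    known <- c(0.001, 0.01, 0.02, 0.8)
    expect_equal(p.adjust(known, "BH"), bruteBH(known))
    expect_equal(bruteBH(known), c(0.004, 0.02, 0.8 / 30, 0.8),
                 tolerance = 1e-12)
    set.seed(99)
    for (m in c(10, 1000, 10000)) {
        p <- runif(m)^2
        expect_equal(p.adjust(p, "BH"), bruteBH(p), tolerance = 1e-12)
        # permutation invariance
        o <- sample(m)
        expect_equal(p.adjust(p[o], "BH"), bruteBH(p)[o], tolerance = 1e-12)
    }
})

test_that("DMS calling classifies direction and respects the FDR gate", {
    # 6 informative sites: 2 strongly hyper, 1 strongly hypo, 3 flat
    young <- cbind(y1 = c(0.05, 0.05, 0.90, 0.3, 0.3, 0.3),
                   y2 = c(0.06, 0.04, 0.92, 0.3, 0.3, 0.3))
    old <- cbind(o1 = c(0.60, 0.70, 0.20, 0.3, 0.3, 0.3),
                 o2 = c(0.62, 0.72, 0.22, 0.3, 0.3, 0.3))
    mat <- tinyMatrix(cbind(young, old), ages = c(7, 7, 35, 35),
                      coverage = 200L)
    dms <- callDMS(mat, c("y1", "y2"), c("o1", "o2"))
    expect_equal(nrow(dms), 3L)
    expect_equal(sort(unique(dms$direction)), c("hyper", "hypo"))
    expect_equal(unname(directionProportions(dms)), c(1L, 2L))
    expect_true(all(dms$q_value < 0.05))

    all_rows <- callDMS(mat, c("y1", "y2"), c("o1", "o2"), all_sites = TRUE)
    expect_equal(nrow(all_rows), 6L)
    expect_equal(all_rows$q_value,
                 bruteBH(all_rows$p_value), tolerance = 1e-12)

    flat <- tinyMatrix(matrix(0.3, 4, 4,
                              dimnames = list(NULL, c("y1", "y2", "o1", "o2"))),
                       ages = c(7, 7, 35, 35))
    expect_equal(nrow(callDMS(flat, c("y1", "y2"), c("o1", "o2"))), 0L)
    expect_error(callDMS(mat, character(0), c("o1", "o2")), "non-empty")
    expect_error(callDMS(mat, c("y1", "y2"), c("o1", "o2"), fdr = 1.5), "fdr")
})

test_that("direction summaries count signs and reject empty input", {
    df <- data.frame(direction = c("hyper", "hypo", "hyper"))
    expect_equal(directionProportions(df), c(n_hypo = 1L, n_hyper = 2L))
    expect_equal(directionProportions(data.frame(direction = rep("hyper", 4))),
                 c(n_hypo = 0L, n_hyper = 4L))
    expect_error(directionProportions(df[0, , drop = FALSE]), "no differential")
})

test_that("context annotation uses overlap with rDNA > ncRNA > coding priority", {
    feats <- GenomicRanges::GRanges(
        "ctg1", IRanges::IRanges(start = c(1, 1, 201), end = c(100, 50, 300)))
    S4Vectors::mcols(feats)$feature_class <- c("coding", "rDNA", "ncRNA")
    dms <- data.frame(site = paste0("k", 1:3), contig = "ctg1",
                      start = c(10L, 250L, 999L), end = c(11L, 251L, 1000L),
                      strand = "+", mod_code = "a", effect_size = 0.1,
                      p_value = 0.01, q_value = 0.01, direction = "hyper",
                      context = "unannotated", stringsAsFactors = FALSE)
    ann <- annotateContext(dms, feats)
    expect_equal(ann$context, c("rDNA", "ncRNA", "intergenic"))
})

test_that("direction chi-squared matches the four-term formula, Yates never larger", {
    # direct formula oracle
    chisqOracle <- function(tab, yates) {
        E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        adj <- if (yates) pmin(abs(tab - E), 0.5) else 0
        sum((abs(tab - E) - adj)^2 / E)
    }
    set.seed(5)
    for (i in 1:10) {
        tab <- matrix(sample(5:80, 4, TRUE), 2)
        raw <- compareProportionsChisq(tab[1, ], tab[2, ], yates = FALSE)
        cor <- compareProportionsChisq(tab[1, ], tab[2, ], yates = TRUE)
        expect_equal(raw$statistic, chisqOracle(tab, FALSE), tolerance = 1e-10)
        expect_equal(cor$statistic, chisqOracle(tab, TRUE), tolerance = 1e-10)
        expect_lte(cor$statistic, raw$statistic + 1e-12)
    }
    eq <- compareProportionsChisq(c(50, 50), c(50, 50))
    expect_equal(eq$statistic, 0)
    expect_equal(eq$df, 1)
    expect_error(compareProportionsChisq(c(0, 0), c(5, 5)), "degenerate")
})

test_that("null cohorts keep the raw Fisher false-positive rate at or below nominal", {
    co <- suppressWarnings(simulateCohort(
        simulationConfig(n_sites = 1500L, mod_codes = "a",
                         frac_clock_sites = 0, frac_entropy_sites = 0),
        seed = 77))
    recs <- lapply(co$records, filterCoverage, 10)
    mat <- buildMethylMatrix(recs, co$manifest)
    byAge <- split(co$manifest$sample_id, co$manifest$age_days)
    res <- callDMS(mat, byAge[[1]], byAge[[3]], all_sites = TRUE)
    frac_sig <- mean(res$p_value < 0.05)
    # Fisher on discrete counts is conservative: stay at or below the upper
    # 99% binomial envelope of the nominal 0.05
    upper <- 0.05 + 2.576 * sqrt(0.05 * 0.95 / nrow(res))
    expect_lte(frac_sig, upper)
    expect_equal(nrow(callDMS(mat, byAge[[1]], byAge[[3]])), 0L)
})
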