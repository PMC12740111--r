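test_that("bedMethyl rows are parsed with counts as the source of truth", {
    path <- writeBedmethylLines(bedmethylLine(start = 100L, n_valid = 30L,
                                              n_mod = 3L))
    rec <- readBedMethyl(path)
    expect_equal(nrow(rec), 1L)
    expect_equal(rec$contig, "ctg1")
    expect_equal(rec$start, 100L)
    expect_equal(rec$strand, "+")
    expect_equal(rec$mod_code, "a")
    expect_equal(rec$n_valid, 30L)
    expect_equal(rec$n_mod, 3L)
    expect_equal(rec$fraction, 0.10)

    # the percent column is ignored: corrupt it and nothing changes
    bad_pct <- sub("10.00", "99.99", bedmethylLine(), fixed = TRUE)
    rec2 <- readBedMethyl(writeBedmethylLines(bad_pct))
    expect_equal(rec2$fraction, 0.10)
})

test_that("reader filters mod codes, drops zero coverage, rejects malformed rows", {
    expect_equal(nrow(readBedMethyl(writeBedmethylLines(character(0)))), 0L)

    only_m <- writeBedmethylLines(bedmethylLine(mod = "m"))
    expect_equal(nrow(readBedMethyl(only_m, mod_codes = "a")), 0L)
    expect_equal(nrow(readBedMethyl(only_m, mod_codes = "m")), 1L)

    mixed <- writeBedmethylLines(c(
        bedmethylLine(start = 1L),
        bedmethylLine(start = 2L, n_valid = 0L, n_mod = 0L),
        bedmethylLine(start = 3L, n_valid = 10L, n_mod = 12L)))
    expect_warning(rec <- readBedMethyl(mixed), "N_mod > N_valid_cov")
    expect_equal(rec$start, 1L)
    expect_equal(attr(rec, "n_dropped_zero_cov"), 1L)
    expect_equal(attr(rec, "n_rejected_malformed"), 1L)

    expect_error(readBedMethyl(tempfile()), "not found")
})

test_that("write/read round-trip preserves all retained fields exactly", {
    set.seed(11)
    nv <- sample(1:200, 40, replace = TRUE)
    rec <- recordDF("ctg1", sample.int(1e6, 40), sample(c("+", "-"), 40, TRUE),
                    sample(c("a", "m"), 40, TRUE), nv,
                    vapply(nv, function(v) sample(0:v, 1), 1L))
    path <- tempfile()
    writeBedMethyl(rec, path)
    back <- readBedMethyl(path)
    expect_identical(back[, names(rec)], rec)
})

test_that("coverage filter keeps exactly the >= threshold records, in order", {
    rec <- recordDF("c", c(1, 2, 3), "+", "a", c(9, 10, 11), c(0, 1, 2))
    kept <- filterCoverage(rec, 10)
    expect_equal(kept$n_valid, c(10L, 11L))
    expect_identical(filterCoverage(kept, 10), kept)     # idempotent
    expect_identical(filterCoverage(rec, 1), rec)        # no-op case
    expect_equal(nrow(filterCoverage(rec[0, ], 10)), 0L) # empty in, empty out
    expect_error(filterCoverage(rec, 0), "min_cov")
})

test_that("global methylation is read-weighted by default", {
    rec <- recordDF("c", c(1, 2), "+", "a", c(30, 10), c(3, 1))
    expect_equal(globalMethylation(rec), 100 * 4 / 40)
    expect_equal(globalMethylation(rec, weighting = "site"),
                 100 * mean(c(3 / 30, 1 / 10)))
    expect_equal(globalMethylation(recordDF("c", 1:3, "+", "a", 30, 0)), 0)
    expect_equal(globalMethylation(recordDF("c", 1, "+", "a", 30, 30)), 100)
    expect_error(globalMethylation(rec[0, ]), "empty")
})

test_that("matrix assembly intersects per-sample site sets deterministically", {
    manifest <- data.frame(sample_id = c("s1", "s2"), age_days = c(7, 35),
                           group = c("W1", "W5"), treatment = "none")
    s1 <- recordDF("ctg1", c(10, 20, 30), "+", "a", 30, c(1, 2, 3))
    s2 <- recordDF("ctg1", c(10, 30), "+", "a", 20, c(1, 2))
    mat <- buildMethylMatrix(list(s1 = s1, s2 = s2), manifest)
    expect_s4_class(mat, "MethylExperiment")
    expect_equal(dim(mat), c(2L, 2L))                 # unshared site dropped
    expect_equal(siteKeys(mat), c("ctg1:10:+:a", "ctg1:30:+:a"))
    expect_equal(unname(fractions(mat)["ctg1:30:+:a", ]), c(3 / 30, 2 / 20))
    expect_equal(unname(coverages(mat)["ctg1:10:+:a", ]), c(30, 20))

    # identical site sets: everything preserved, one sample trivially works
    mat3 <- buildMethylMatrix(list(s1 = s1, s2 = s1, s3 = s1),
                              data.frame(sample_id = c("s1", "s2", "s3"),
                                         age_days = 7, group = "W1",
                                         treatment = "none"))
    expect_equal(nrow(mat3), 3L)
    expect_error(buildMethylMatrix(list(s1 = s1), manifest), "no records")
    s3 <- recordDF("ctg2", 99, "+", "a", 30, 1)
    expect_error(buildMethylMatrix(list(s1 = s1, s2 = s3), manifest),
                 "no site")
})

test_that("matrix site set equals a brute-force intersection on random fixtures", {
    set.seed(42)
    for (rep in 1:5) {
        pools <- paste0("ctg", 1:2, ":", rep(seq(0, 90, 10), each = 2))
        per <- lapply(1:3, function(i) {
            picks <- sample(pools, sample(8:16, 1), replace = FALSE)
            parts <- do.call(rbind, strsplit(picks, ":"))
            recordDF(parts[, 1], as.integer(parts[, 2]), "+", "a", 30,
                     sample(0:30, length(picks), TRUE))
        })
        names(per) <- c("x", "y", "z")
        manifest <- data.frame(sample_id = c("x", "y", "z"), age_days = 7,
                               group = "W1", treatment = "none")
        expected <- Reduce(intersect, lapply(per, function(d)
            paste(d$contig, d$start, d$strand, d$mod_code, sep = ":")))
        if (length(expected) == 0) {
            expect_error(buildMethylMatrix(per, manifest), "no site")
        } else {
            mat <- buildMethylMatrix(per, manifest)
            expect_setequal(siteKeys(mat), expected)
        }
    }
})

test_that("feature BED parsing enforces the class vocabulary", {
    p <- writeBedmethylLines("ctg1\t0\t500\tncRNA")
    gr <- readFeatureBed(p)
    expect_equal(length(gr), 1L)
    expect_equal(GenomicRanges::start(gr), 1L)   # 0-based half-open input
    expect_equal(GenomicRanges::end(gr), 500L)
    expect_equal(S4Vectors::mcols(gr)$feature_class, "ncRNA")

    expect_equal(length(readFeatureBed(writeBedmethylLines(character(0)))), 0L)
    expect_error(readFeatureBed(writeBedmethylLines("ctg1")), "4 columns")
    expect_error(readFeatureBed(writeBedmethylLines("ctg1\t0\t5\tpromoter")),
                 "unknown feature class")
})

test_that("MethylExperiment validity rejects inconsistent objects", {
    mat <- tinyMatrix(matrix(c(0.1, 0.2, 0.3, 0.4), 2,
                             dimnames = list(NULL, c("s1", "s2"))))
    bad <- mat
    SummarizedExperiment::assay(bad, "fraction")[1, 1] <- 1.5
    expect_error(methods::validObject(bad), "\\[0, 1\\]")
})
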