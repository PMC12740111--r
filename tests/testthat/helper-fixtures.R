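# Fixtures are generated in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# One well-formed 18-column bedMethyl line.
bedmethylLine <- function(contig = "ctg1", start = 100L, mod = "a",
                          strand = "+", n_valid = 30L, n_mod = 3L) {
    paste(contig, start, start + 1L, mod, n_valid, strand, start, start + 1L,
          "255,0,0", n_valid, sprintf("%.2f", 100 * n_mod / max(1, n_valid)),
          n_mod, n_valid - n_mod, 0L, 0L, 0L, 0L, 0L, sep = "\t")
}

writeBedmethylLines <- function(lines, path = tempfile(fileext = ".tsv")) {
    writeLines(lines, path)
    path
}

# Hand-built record data.frame (readBedMethyl layout).
recordDF <- function(contig, start, strand, mod_code, n_valid, n_mod) {
    data.frame(contig = contig, start = as.integer(start), strand = strand,
               mod_code = mod_code, n_valid = as.integer(n_valid),
               n_mod = as.integer(n_mod), fraction = n_mod / n_valid,
               stringsAsFactors = FALSE)
}

# Small deterministic MethylExperiment: `fractions` is sites x samples;
# coverage fixed at 100 so counts are exact.
tinyMatrix <- function(fractions, ages = NULL, coverage = 100L) {
    n_site <- nrow(fractions); n_samp <- ncol(fractions)
    ids <- colnames(fractions) %||% paste0("s", seq_len(n_samp))
    if (is.null(ages)) ages <- rep(c(7, 21, 35), length.out = n_samp)
    manifest <- data.frame(sample_id = ids, age_days = ages,
                           group = paste0("g", ages), treatment = "none",
                           stringsAsFactors = FALSE)
    per_sample <- lapply(seq_len(n_samp), function(j)
        recordDF(contig = "ctg1", start = seq_len(n_site) * 10L,
                 strand = "+", mod_code = "a",
                 n_valid = coverage,
                 n_mod = round(fractions[, j] * coverage)))
    names(per_sample) <- ids
    buildMethylMatrix(per_sample, manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force Benjamini-Hochberg: q_i = min_{k: p(k) >= p(i)} of
# p(k) * m / k over the sorted vector, capped at 1.
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- p[o] * m / seq_len(m)
    q_sorted <- rev(cummin(rev(q_sorted)))
    q <- numeric(m)
    q[o] <- pmin(1, q_sorted)
    q
}

# Independent two-sided Fisher p by full hypergeometric enumeration.
enumFisherP <- function(n_mod_a, n_valid_a, n_mod_b, n_valid_b) {
    m <- n_mod_a + n_mod_b
    n <- (n_valid_a - n_mod_a) + (n_valid_b - n_mod_b)
    k <- n_valid_a
    lo <- max(0, k - n); hi <- min(k, m)
    d <- dhyper(lo:hi, m, n, k)
    sum(d[d <= d[n_mod_a - lo + 1] * (1 + 1e-7)])
}

# Shared replicate-cohort results for the heavier simulation checks: computed
# once per test run, reused across test files.
.cohortCache <- new.env(parent = emptyenv())

defaultCohortReplicates <- function(n_rep = 20L) {
    key <- paste0("default_", n_rep)
    if (!is.null(.cohortCache[[key]])) return(.cohortCache[[key]])
    out <- lapply(seq_len(n_rep), function(r) {
        co <- suppressWarnings(simulateCohort(simulationConfig(), seed = 1000 + r))
        recs <- lapply(co$records, function(d)
            filterCoverage(d[d$mod_code == "a", , drop = FALSE], 10))
        mat <- buildMethylMatrix(recs, co$manifest)
        ages <- setNames(co$manifest$age_days, co$manifest$sample_id)
        split_ids <- splitTrainTest(co$manifest, 10, seed = 1000 + r)
        spec <- clockSpec("elasticnet_levels")
        model <- suppressWarnings(trainClock(
            assembleFeatures(mat, spec, samples = split_ids$train),
            ages[split_ids$train], spec))
        test_metrics <- evaluatePredictions(
            predictAge(model, assembleFeatures(mat, spec,
                                               samples = split_ids$test)),
            ages[split_ids$test])
        truth <- c(co$truth$clock_sites, co$truth$entropy_sites)
        truth <- truth[grepl(":a$", names(truth))]
        list(mat = mat, ages = ages, model = model,
             test_metrics = test_metrics, truth_slopes = truth)
    })
    .cohortCache[[key]] <- out
    out
}
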