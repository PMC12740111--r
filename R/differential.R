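#' Pool read counts across a sample group at one site
#'
#' Component-wise sums of modified and valid read counts over the group's
#' samples, the replicate-pooling step behind the site-level test.
#'
#' @param mat a \linkS4class{MethylExperiment}.
#' @param sample_ids samples to pool.
#' @param site_key canonical site key \code{"contig:start:strand:mod"}.
#' @return named numeric \code{c(n_mod, n_valid)}.
#' @export
poolCounts <- function(mat, sample_ids, site_key) {
    keys <- siteKeys(mat)
    i <- match(site_key, keys)
    if (is.na(i)) stop("site not present in matrix: ", site_key)
    if (!all(sample_ids %in% colnames(mat)))
        stop("sample(s) missing from matrix: ",
             paste(setdiff(sample_ids, colnames(mat)), collapse = ", "))
    cv <- coverages(mat)[i, sample_ids]
    fr <- fractions(mat)[i, sample_ids]
    c(n_mod = sum(round(fr * cv)), n_valid = sum(cv))
}

#' Site-level differential methylation test on pooled counts
#'
#' Two-sided Fisher's exact test on the 2x2 table of modified versus
#' canonical read counts under the two conditions — the primary inferential
#' test. The effect size is the pooled-fraction difference (condition b minus
#' condition a). A descriptive beta-MAP score is also reported: the absolute
#' difference of the posterior modes of \eqn{Beta(1 + n_{mod}, 1 + n_{canon})}
#' under a uniform prior (the mode of \eqn{Beta(a,b)} is
#' \eqn{(a-1)/(a+b-2)}, i.e. the observed fraction here), an
#' effect-confidence summary, not a p-value.
#'
#' @param counts_a,counts_b numeric \code{c(n_mod, n_valid)} per condition;
#'   both \code{n_valid} must be positive.
#' @return list with \code{p_value}, \code{effect_size}, \code{map_score}.
#' @export
siteTest <- function(counts_a, counts_b) {
    ma <- counts_a[[1]]; va <- counts_a[[2]]
    mb <- counts_b[[1]]; vb <- counts_b[[2]]
    if (va <= 0 || vb <= 0)
        stop("site not testable: zero valid coverage in a condition")
    if (ma > va || mb > vb) stop("n_mod exceeds n_valid")
    tab <- matrix(c(ma, va - ma, mb, vb - mb), nrow = 2)
    p <- stats::fisher.test(tab)$p.value
    list(p_value = min(1, p),
         effect_size = mb / vb - ma / va,
         map_score = abs(mb / vb - ma / va))
}

## Vectorized two-sided Fisher p on many 2x2 tables (same definition as
## fisher.test: sum of hypergeometric probabilities <= P(observed), with the
## standard 1+1e-7 relative tolerance).
.fisherPVec <- function(ma, va, mb, vb) {
    vapply(seq_along(ma), function(i) {
        m <- ma[i] + mb[i]            # total modified (white balls)
        nn <- (va[i] - ma[i]) + (vb[i] - mb[i])
        k <- va[i]                    # draws = condition-a valid reads
        lo <- max(0, k - nn); hi <- min(k, m)
        d <- stats::dhyper(lo:hi, m, nn, k)
        sum(d[d <= d[ma[i] - lo + 1] * (1 + 1e-7)])
    }, numeric(1))
}

#' Call differentially methylated sites between two groups
#'
#' For every site of each modification channel, pools replicate counts within
#' the young and old groups, applies the site test, adjusts p-values with
#' Benjamini-Hochberg across all tested sites of that channel, and returns
#' the sites with \code{q < fdr}. Direction is classified from the sign of
#' the effect size (old minus young): positive = hypermethylated with age.
#' Context is \code{"unannotated"} until \code{\link{annotateContext}} is
#' applied. A per-replicate Welch t-test on fractions is available as a
#' sensitivity option via \code{method = "ttest"}.
#'
#' @param mat a \linkS4class{MethylExperiment}.
#' @param group_young,group_old sample id vectors (non-empty, disjoint).
#' @param fdr FDR threshold in (0, 1); default 0.05.
#' @param method \code{"fisher"} (pooled counts, default) or \code{"ttest"}
#'   (per-replicate fractions).
#' @param all_sites return every tested site (with q-values) instead of only
#'   the significant ones.
#' @return data.frame with columns \code{site}, \code{contig}, \code{start},
#'   \code{end}, \code{strand}, \code{mod_code}, \code{effect_size},
#'   \code{p_value}, \code{q_value}, \code{direction}, \code{context}.
#' @export
callDMS <- function(mat, group_young, group_old, fdr = 0.05,
                    method = c("fisher", "ttest"), all_sites = FALSE) {
    method <- match.arg(method)
    if (length(group_young) == 0 || length(group_old) == 0)
        stop("both groups must be non-empty")
    if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
    ids <- colnames(mat)
    if (!all(c(group_young, group_old) %in% ids))
        stop("group sample ids missing from matrix")
    if (nrow(mat) < 2) stop("fewer than 2 sites: BH adjustment undefined")

    fr <- fractions(mat); cv <- coverages(mat)
    nm <- round(fr * cv)
    keys <- siteKeys(mat)
    mod <- S4Vectors::mcols(SummarizedExperiment::rowRanges(mat))$mod_code
    rr <- SummarizedExperiment::rowRanges(mat)

    ma <- rowSums(nm[, group_young, drop = FALSE])
    va <- rowSums(cv[, group_young, drop = FALSE])
    mb <- rowSums(nm[, group_old, drop = FALSE])
    vb <- rowSums(cv[, group_old, drop = FALSE])
    eff <- mb / vb - ma / va

    if (method == "fisher") {
        p <- .fisherPVec(ma, va, mb, vb)
    } else {
        p <- vapply(seq_len(nrow(fr)), function(i) {
            y <- fr[i, group_young]; o <- fr[i, group_old]
            if (stats::sd(y) == 0 && stats::sd(o) == 0)
                return(if (mean(y) == mean(o)) 1 else 0)
            tryCatch(stats::t.test(o, y)$p.value, error = function(e) 1)
        }, numeric(1))
    }

    q <- rep(NA_real_, length(p))
    for (ch in unique(mod))
        q[mod == ch] <- stats::p.adjust(p[mod == ch], method = "BH")

    out <- data.frame(site = keys,
                      contig = as.character(GenomicRanges::seqnames(rr)),
                      start = GenomicRanges::start(rr) - 1L,
                      end = GenomicRanges::start(rr),
                      strand = as.character(GenomicRanges::strand(rr)),
                      mod_code = mod,
                      effect_size = eff,
                      p_value = p,
                      q_value = q,
                      stringsAsFactors = FALSE)
    out$direction <- ifelse(out$effect_size > 0, "hyper",
                            ifelse(out$effect_size < 0, "hypo", "none"))
    out$context <- "unannotated"
    if (!all_sites)
        out <- out[out$q_value < fdr & out$direction != "none", , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Annotate differential sites with genomic context
#'
#' Assigns each site the class of an overlapping feature interval; when a
#' site overlaps several classes the priority is rDNA > ncRNA > coding, and
#' sites overlapping nothing are \code{"intergenic"}. Strand is ignored for
#' the overlap (feature annotation is strand-agnostic).
#'
#' @param dms data.frame from \code{\link{callDMS}}.
#' @param features \code{GRanges} from \code{\link{readFeatureBed}}.
#' @return \code{dms} with the \code{context} column filled in.
#' @export
annotateContext <- function(dms, features) {
    if (nrow(dms) == 0) return(dms)
    gr <- GenomicRanges::GRanges(dms$contig,
                                 IRanges::IRanges(start = dms$start + 1L,
                                                  width = 1L))
    dms$context <- "intergenic"
    if (length(features) == 0) return(dms)
    hits <- GenomicRanges::findOverlaps(gr, features, ignore.strand = TRUE)
    if (length(hits)) {
        pri <- c(rDNA = 3L, ncRNA = 2L, coding = 1L)
        cls <- S4Vectors::mcols(features)$feature_class[S4Vectors::subjectHits(hits)]
        best <- tapply(pri[cls], S4Vectors::queryHits(hits), max)
        dms$context[as.integer(names(best))] <-
            names(pri)[match(as.integer(best), pri)]
    }
    dms
}

#' Hypo/hyper direction counts
#'
#' @param dms non-empty data.frame from \code{\link{callDMS}}.
#' @return named integer \code{c(n_hypo, n_hyper)} (zero-effect records are
#'   excluded).
#' @export
directionProportions <- function(dms) {
    if (nrow(dms) == 0) stop("no differential sites to summarize")
    c(n_hypo = sum(dms$direction == "hypo"),
      n_hyper = sum(dms$direction == "hyper"))
}

#' Chi-squared comparison of two direction splits
#'
#' Pearson chi-squared test (df = 1) on the 2x2 table formed by two
#' (hypo, hyper) count pairs, e.g. comparing the hypomethylation proportion
#' between the 6mA and 5mC channels. Yates continuity correction is applied
#' by default.
#'
#' @param counts_a,counts_b numeric pairs of direction counts.
#' @param yates apply the continuity correction (default TRUE).
#' @return list with \code{table}, \code{statistic}, \code{df},
#'   \code{p_value}, \code{continuity_corrected}.
#' @export
compareProportionsChisq <- function(counts_a, counts_b, yates = TRUE) {
    tab <- rbind(a = as.numeric(counts_a), b = as.numeric(counts_b))
    if (any(tab < 0)) stop("counts must be non-negative")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("degenerate table: a row or column margin is zero")
    ht <- stats::chisq.test(tab, correct = yates)
    list(table = tab, statistic = unname(ht$statistic),
         df = unname(ht$parameter), p_value = ht$p.value,
         continuity_corrected = yates)
}

#' Write a differential-site table as BED-compatible TSV
#'
#' @param dms data.frame from \code{\link{callDMS}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDMSTable <- function(dms, path) {
    cols <- c("contig", "start", "end", "strand", "mod_code", "effect_size",
              "p_value", "q_value", "direction", "context")
    utils::write.table(dms[, cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
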