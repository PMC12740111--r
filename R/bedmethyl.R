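#' Read a Modkit-style bedMethyl pileup table
#'
#' Parses the 18-column tab-separated per-site modified-base table produced
#' by ONT Modkit's \code{pileup} command (chrom, start, end, mod code, score,
#' strand, thickStart, thickEnd, color, N_valid_cov, percent_modified, N_mod,
#' N_canonical, N_other_mod, N_delete, N_fail, N_diff, N_nocall). One row is
#' one site x modification x strand observation. Coordinates are 0-based
#' half-open and kept that way. The printed percent column is never trusted:
#' the methylation fraction is recomputed as \code{N_mod / N_valid_cov} so
#' downstream statistics do not inherit its rounding.
#'
#' Rows are dropped (with a message, and counted in the
#' \code{"n_dropped_zero_cov"} / \code{"n_rejected_malformed"} attributes)
#' when the modification code is outside \code{mod_codes}, when
#' \code{N_valid_cov} is zero (fraction undefined), or when
#' \code{N_mod > N_valid_cov} (malformed; warned).
#'
#' @param path path to a bedMethyl file (may be empty).
#' @param mod_codes modification codes to keep; default both supported
#'   channels \code{c("a", "m")} (6mA, 5mC).
#' @param verbose emit per-file parse messages.
#' @return a \code{data.frame} with columns \code{contig}, \code{start}
#'   (0-based), \code{strand}, \code{mod_code}, \code{n_valid}, \code{n_mod},
#'   \code{fraction}, one row per retained record.
#' @export
readBedMethyl <- function(path, mod_codes = c("a", "m"), verbose = FALSE) {
    if (!file.exists(path)) stop("bedMethyl file not found: ", path)
    empty <- data.frame(contig = character(), start = integer(),
                        strand = character(), mod_code = character(),
                        n_valid = integer(), n_mod = integer(),
                        fraction = numeric(), stringsAsFactors = FALSE)
    if (file.size(path) == 0) return(empty)
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "",
                             comment.char = "")
    if (ncol(raw) < 18)
        stop("bedMethyl file must have 18 columns, found ", ncol(raw), ": ", path)
    df <- data.frame(contig = raw[[1]],
                     start = as.integer(raw[[2]]),
                     strand = raw[[6]],
                     mod_code = raw[[4]],
                     n_valid = as.integer(raw[[10]]),
                     n_mod = as.integer(raw[[12]]),
                     stringsAsFactors = FALSE)
    if (anyNA(df$start) || anyNA(df$n_valid) || anyNA(df$n_mod))
        stop("non-numeric coordinate or count field in ", path)
    keep_mod <- df$mod_code %in% mod_codes
    df <- df[keep_mod, , drop = FALSE]
    bad <- df$n_mod > df$n_valid
    if (any(bad)) {
        warning(sum(bad), " row(s) with N_mod > N_valid_cov rejected in ", path)
        df <- df[!bad, , drop = FALSE]
    }
    zero <- df$n_valid == 0L
    if (any(zero)) {
        msgf("%d zero-coverage row(s) dropped in %s", sum(zero), path,
             verbose = verbose)
        df <- df[!zero, , drop = FALSE]
    }
    df$fraction <- df$n_mod / df$n_valid
    rownames(df) <- NULL
    attr(df, "n_dropped_zero_cov") <- sum(zero)
    attr(df, "n_rejected_malformed") <- sum(bad)
    df
}

#' Write site records as an 18-column bedMethyl table
#'
#' Inverse of \code{\link{readBedMethyl}} for the fields that reader retains:
#' counts are written exactly, the percent column is recomputed from counts,
#' \code{N_canonical = n_valid - n_mod} and the remaining diagnostic count
#' columns are zero.
#'
#' @param records data.frame as returned by \code{\link{readBedMethyl}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBedMethyl <- function(records, path) {
    out <- data.frame(records$contig,
                      records$start,
                      records$start + 1L,
                      records$mod_code,
                      records$n_valid,
                      records$strand,
                      records$start,
                      records$start + 1L,
                      "255,0,0",
                      records$n_valid,
                      sprintf("%.2f", 100 * records$n_mod / records$n_valid),
                      records$n_mod,
                      records$n_valid - records$n_mod,
                      0L, 0L, 0L, 0L, 0L)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Filter site records by minimum valid coverage
#'
#' Retains exactly the records with \code{n_valid >= min_cov}, preserving
#' input order. The conventional threshold for downstream analyses is 10X.
#'
#' @param records data.frame of site records.
#' @param min_cov minimum valid read coverage, an integer >= 1.
#' @return the retained subset, same columns and order.
#' @export
filterCoverage <- function(records, min_cov = 10L) {
    if (!is.numeric(min_cov) || length(min_cov) != 1 || min_cov < 1)
        stop("min_cov must be a single integer >= 1")
    out <- records[records$n_valid >= min_cov, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Global methylation level of a sample
#'
#' Read-weighted by default: \code{100 * sum(n_mod) / sum(n_valid)}, i.e. the
#' percentage of valid base calls that were modified, which matches a
#' count-based pileup summary. The site-averaged alternative (mean of per-site
#' fractions x 100) is available via \code{weighting = "site"}; the two differ
#' whenever coverage correlates with methylation.
#'
#' @param records data.frame of site records (non-empty).
#' @param weighting \code{"read"} (default) or \code{"site"}.
#' @return global methylation level in percent.
#' @export
globalMethylation <- function(records, weighting = c("read", "site")) {
    weighting <- match.arg(weighting)
    if (nrow(records) == 0)
        stop("global methylation is undefined for an empty record set")
    if (weighting == "read")
        100 * sum(as.numeric(records$n_mod)) / sum(as.numeric(records$n_valid))
    else
        100 * mean(records$fraction)
}

#' Assemble a multi-sample methylation matrix
#'
#' Builds a \linkS4class{MethylExperiment} from per-sample record sets,
#' restricted to the sites observed (after any coverage filtering) in
#' \emph{every} sample — missing sites are dropped rather than imputed, so
#' the matrix is complete-case by construction. Sites are ordered
#' lexicographically by (contig, start, strand, mod_code); samples follow
#' manifest order.
#'
#' @param per_sample named list of record data.frames, one per sample id.
#' @param manifest data.frame with columns \code{sample_id}, \code{age_days},
#'   \code{group}, \code{treatment}; every sample must have a record set.
#' @param verbose log the intersection size.
#' @return a \code{MethylExperiment}.
#' @export
buildMethylMatrix <- function(per_sample, manifest, verbose = FALSE) {
    need <- c("sample_id", "age_days", "group", "treatment")
    if (!all(need %in% colnames(manifest)))
        stop("manifest must have columns ", paste(need, collapse = ", "))
    ids <- as.character(manifest$sample_id)
    if (anyDuplicated(ids)) stop("manifest sample_id values must be unique")
    if (!all(ids %in% names(per_sample)))
        stop("no records for sample(s): ",
             paste(setdiff(ids, names(per_sample)), collapse = ", "))
    keyOf <- function(df) paste(df$contig, df$start, df$strand, df$mod_code, sep = ":")
    keys <- lapply(per_sample[ids], keyOf)
    shared <- Reduce(intersect, keys)
    if (length(shared) == 0)
        stop("no site is observed in every sample; ",
             "per-sample site counts: ",
             paste(vapply(keys, length, 1L), collapse = ", "))
    ## lexicographic site order on the parsed key parts
    parts <- do.call(rbind, strsplit(shared, ":", fixed = TRUE))
    ord <- order(parts[, 1], as.integer(parts[, 2]), parts[, 3], parts[, 4],
                 method = "radix")
    shared <- shared[ord]
    parts <- parts[ord, , drop = FALSE]
    fr <- matrix(NA_real_, length(shared), length(ids),
                 dimnames = list(shared, ids))
    cv <- matrix(NA_real_, length(shared), length(ids),
                 dimnames = list(shared, ids))
    for (s in ids) {
        df <- per_sample[[s]]
        idx <- match(shared, keyOf(df))
        fr[, s] <- df$fraction[idx]
        cv[, s] <- df$n_valid[idx]
    }
    msgf("matrix: %d shared sites x %d samples", length(shared), length(ids),
         verbose = verbose)
    rr <- GenomicRanges::GRanges(
        seqnames = parts[, 1],
        ranges = IRanges::IRanges(start = as.integer(parts[, 2]) + 1L, width = 1L),
        strand = ifelse(parts[, 3] %in% c("+", "-"), parts[, 3], "*"))
    S4Vectors::mcols(rr)$mod_code <- parts[, 4]
    names(rr) <- shared
    cd <- S4Vectors::DataFrame(sample_id = ids,
                               age_days = as.numeric(manifest$age_days),
                               group = as.character(manifest$group),
                               treatment = as.character(manifest$treatment),
                               row.names = ids)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(fraction = fr, coverage = cv),
        rowRanges = rr, colData = cd)
    methods::new("MethylExperiment", se)
}

#' Read a 4-column feature BED file
#'
#' Intervals are 0-based half-open; column 4 must be one of \code{coding},
#' \code{ncRNA}, \code{rDNA}. Overlapping intervals are permitted.
#'
#' @param path BED path.
#' @return a \code{GRanges} with a \code{feature_class} metadata column
#'   (empty \code{GRanges} for an empty file).
#' @export
readFeatureBed <- function(path) {
    if (!file.exists(path)) stop("feature BED not found: ", path)
    empty <- GenomicRanges::GRanges()
    S4Vectors::mcols(empty)$feature_class <- character(0)
    if (file.size(path) == 0) return(empty)
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "",
                             comment.char = "#")
    if (ncol(raw) < 4)
        stop("feature BED must have >= 4 columns, found ", ncol(raw))
    cls <- raw[[4]]
    bad <- setdiff(unique(cls), c("coding", "ncRNA", "rDNA"))
    if (length(bad))
        stop("unknown feature class label(s): ", paste(bad, collapse = ", "))
    gr <- GenomicRanges::GRanges(
        seqnames = raw[[1]],
        ranges = IRanges::IRanges(start = as.integer(raw[[2]]) + 1L,
                                  end = as.integer(raw[[3]])))
    S4Vectors::mcols(gr)$feature_class <- cls
    gr
}
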