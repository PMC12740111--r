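#' Binary Shannon entropy of a methylation fraction
#'
#' \eqn{H(p) = -[p \log_2 p + (1-p)\log_2(1-p)]} with \eqn{0 \log 0 = 0}.
#' Base-2 normalizes to [0,1] (0 at fully un/methylated, 1 at 50%); the
#' genome-normalized entropy of a site set is then simply the mean of the
#' per-site values, which is how sample-level entropy is formed here. Natural
#' log available via \code{base = exp(1)} (rescales by \eqn{\ln 2}).
#'
#' @param p methylation fraction(s) in [0, 1] (vectorized).
#' @param base logarithm base (default 2).
#' @return entropy value(s) in [0, 1] for base 2.
#' @export
siteEntropy <- function(p, base = 2) {
    if (any(p < 0 | p > 1)) stop("fractions must lie in [0, 1]")
    term <- function(x) ifelse(x == 0, 0, x * log(x, base = base))
    -(term(p) + term(1 - p))
}

#' Sample-level mean methylation entropy
#'
#' Mean of per-site binary entropies over a site set for one sample — the
#' individual-level "methylomic entropy" statistic, computable genome-wide or
#' restricted to differential sites.
#'
#' @param mat a \linkS4class{MethylExperiment}.
#' @param sample_id one sample id.
#' @param site_set site keys to average over (default all sites).
#' @param base logarithm base passed to \code{\link{siteEntropy}}.
#' @return a single entropy value.
#' @export
sampleMeanEntropy <- function(mat, sample_id, site_set = NULL, base = 2) {
    if (!sample_id %in% colnames(mat)) stop("unknown sample: ", sample_id)
    keys <- siteKeys(mat)
    if (is.null(site_set)) site_set <- keys
    if (length(site_set) == 0) stop("empty site set")
    idx <- match(site_set, keys)
    if (anyNA(idx))
        stop("site(s) not in matrix: ",
             paste(utils::head(site_set[is.na(idx)], 3), collapse = ", "))
    mean(siteEntropy(fractions(mat)[idx, sample_id], base = base))
}

#' Per-sample entropy profile over a site set
#'
#' @param mat a \linkS4class{MethylExperiment}.
#' @param site_set site keys (default all: genome-wide).
#' @param base logarithm base.
#' @return list with \code{per_site} (site x sample entropy matrix),
#'   \code{per_sample_mean} (named vector), and \code{site_set_label}
#'   (\code{"genome_wide"} or \code{"restricted"}).
#' @export
entropyProfile <- function(mat, site_set = NULL, base = 2) {
    keys <- siteKeys(mat)
    label <- if (is.null(site_set)) "genome_wide" else "restricted"
    if (is.null(site_set)) site_set <- keys
    idx <- match(site_set, keys)
    if (anyNA(idx)) stop("site(s) not in matrix")
    per_site <- siteEntropy(fractions(mat)[idx, , drop = FALSE], base = base)
    rownames(per_site) <- site_set
    list(per_site = per_site,
         per_sample_mean = colMeans(per_site),
         site_set_label = label)
}

#' Gated multi-group comparison (ANOVA or Kruskal-Wallis)
#'
#' Tests a per-sample statistic across groups using the parametric branch —
#' one-way ANOVA with Tukey HSD post hoc — when every group passes the
#' Shapiro normality test and Levene's test (mean-centered) finds
#' homoscedasticity, both at alpha = 0.05; otherwise the nonparametric
#' branch — Kruskal-Wallis with pairwise two-sided Wilcoxon-Mann-Whitney post
#' hoc, BH-adjusted. The branch taken is always reported.
#'
#' @param values named list mapping group label to a numeric vector
#'   (>= 2 groups, >= 3 values each).
#' @param alpha gate level for the Shapiro/Levene checks.
#' @return list with \code{test_name} (\code{"anova"} or
#'   \code{"kruskal"}), \code{statistic}, \code{df}, \code{p_value},
#'   \code{gate} (shapiro p per group, levene p), and \code{pairwise}
#'   (data.frame: group1, group2, p_value, adjusted for the nonparametric
#'   branch by BH; Tukey-adjusted p in the parametric branch).
#' @export
compareGroups <- function(values, alpha = 0.05) {
    if (length(values) < 2) stop("need at least two groups")
    if (any(vapply(values, length, 1L) < 3))
        stop("every group needs at least 3 values")
    g <- factor(rep(names(values), vapply(values, length, 1L)),
                levels = names(values))
    x <- unname(unlist(values))
    shap <- vapply(values, function(v) {
        if (stats::sd(v) == 0) 0 else stats::shapiro.test(v)$p.value
    }, numeric(1))
    lev <- tryCatch(
        car::leveneTest(x ~ g, center = mean)[1, "Pr(>F)"],
        error = function(e) 0)
    parametric <- all(shap > alpha) && !is.na(lev) && lev > alpha
    gate <- list(shapiro_p = shap, levene_p = lev, parametric = parametric)
    if (parametric) {
        fit <- stats::aov(x ~ g)
        an <- summary(fit)[[1]]
        tk <- stats::TukeyHSD(fit)$g
        pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
        pairwise <- data.frame(group1 = pairs[, 2], group2 = pairs[, 1],
                               p_value = tk[, "p adj"],
                               stringsAsFactors = FALSE)
        res <- list(test_name = "anova",
                    statistic = an["g", "F value"],
                    df = an["g", "Df"],
                    p_value = an["g", "Pr(>F)"])
    } else {
        kw <- stats::kruskal.test(x, g)
        cmb <- utils::combn(levels(g), 2)
        praw <- apply(cmb, 2, function(pr)
            stats::wilcox.test(values[[pr[1]]], values[[pr[2]]],
                               exact = NULL)$p.value)
        pairwise <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                               p_value = stats::p.adjust(praw, "BH"),
                               stringsAsFactors = FALSE)
        res <- list(test_name = "kruskal",
                    statistic = unname(kw$statistic),
                    df = unname(kw$parameter),
                    p_value = kw$p.value)
    }
    rownames(pairwise) <- NULL
    c(res, list(gate = gate, pairwise = pairwise))
}

#' Write an entropy profile as TSV
#'
#' @param profile result of \code{\link{entropyProfile}}.
#' @param path output path; a companion \code{<path>.samples.tsv} carries the
#'   per-sample means.
#' @return \code{path}, invisibly.
#' @export
writeEntropyTable <- function(profile, path) {
    per_site <- data.frame(site = rownames(profile$per_site),
                           profile$per_site, check.names = FALSE)
    utils::write.table(per_site, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
        data.frame(sample_id = names(profile$per_sample_mean),
                   mean_entropy = profile$per_sample_mean,
                   site_set = profile$site_set_label),
        paste0(path, ".samples.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}
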