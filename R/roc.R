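#' Per-site linear regression of methylation on age
#'
#' Ordinary least squares of methylation level (percent, i.e. 100 x
#' fraction) on age in weeks for one site: the fitted slope is the site's
#' rate of change (ROC) in percent methylation per week, with the two-sided
#' slope p-value and R-squared used as retention filters.
#'
#' @param ages_weeks ages in weeks (>= 3 points, >= 2 distinct).
#' @param fractions methylation fractions in [0, 1], same length.
#' @return list with \code{slope} (%/week), \code{intercept} (%),
#'   \code{p_value}, \code{r_squared}.
#' @export
siteRegression <- function(ages_weeks, fractions) {
    n <- length(ages_weeks)
    if (n < 3) stop("need at least 3 points")
    if (length(fractions) != n) stop("length mismatch")
    if (length(unique(ages_weeks)) < 2) stop("all ages identical")
    fit <- siteRegressionAll(ages_weeks,
                             matrix(fractions, nrow = 1,
                                    dimnames = list("site", NULL)))
    list(slope = fit$slope[[1]], intercept = fit$intercept[[1]],
         p_value = fit$p_value[[1]], r_squared = fit$r_squared[[1]])
}

#' Vectorized per-site ROC regressions
#'
#' Closed-form OLS (normal equations) applied to every row of a site x
#' sample fraction matrix against a shared age vector. Constant sites get
#' slope 0, R-squared 0 and p-value NA (never retained).
#'
#' @param ages_weeks per-sample ages in weeks.
#' @param fraction_matrix sites x samples matrix of fractions.
#' @param p_threshold,r2_threshold retention filters: a site is retained
#'   when \code{p_value < p_threshold} and \code{r_squared > r2_threshold}.
#' @return data.frame with columns \code{site}, \code{slope},
#'   \code{intercept}, \code{p_value}, \code{r_squared}, \code{retained}.
#' @export
siteRegressionAll <- function(ages_weeks, fraction_matrix,
                              p_threshold = 0.05, r2_threshold = 0.65) {
    x <- as.numeric(ages_weeks)
    n <- length(x)
    if (ncol(fraction_matrix) != n) stop("age/sample length mismatch")
    if (n < 3) stop("need at least 3 samples")
    if (length(unique(x)) < 2) stop("all ages identical")
    y <- 100 * fraction_matrix
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    ybar <- rowMeans(y)
    sxy <- as.numeric(y %*% xc)
    slope <- sxy / sxx
    intercept <- ybar - slope * mean(x)
    syy <- rowSums((y - ybar)^2)
    sse <- pmax(0, syy - slope^2 * sxx)
    r2 <- ifelse(syy > 0, 1 - sse / syy, 0)
    se <- sqrt(sse / (n - 2) / sxx)
    tstat <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p[syy == 0] <- NA_real_
    out <- data.frame(site = rownames(fraction_matrix) %||%
                          as.character(seq_len(nrow(y))),
                      slope = slope, intercept = intercept,
                      p_value = p, r_squared = r2,
                      stringsAsFactors = FALSE)
    out$retained <- !is.na(out$p_value) & out$p_value < p_threshold &
        out$r_squared > r2_threshold
    rownames(out) <- NULL
    out
}

#' Mean rate of change over retained sites
#'
#' Averages per-site slopes over the sites passing the significance and fit
#' filters. An empty retained set is flagged (defined = FALSE) rather than
#' silently reported as zero.
#'
#' @param site_rocs data.frame from \code{\link{siteRegressionAll}} (the
#'   \code{retained} column is recomputed from the thresholds given here).
#' @param p_threshold slope p-value cutoff (default 0.05).
#' @param r2_threshold R-squared cutoff; 0.65 by default, with 0.5 the other
#'   conventional choice — both are supported, neither is canonical.
#' @return list with \code{mean_slope}, \code{sd_slope}, \code{n_retained},
#'   \code{defined}, \code{retained_sites}.
#' @export
meanROC <- function(site_rocs, p_threshold = 0.05, r2_threshold = 0.65) {
    if (p_threshold <= 0 || p_threshold >= 1 ||
        r2_threshold < 0 || r2_threshold >= 1)
        stop("thresholds out of range")
    keep <- !is.na(site_rocs$p_value) & site_rocs$p_value < p_threshold &
        site_rocs$r_squared > r2_threshold
    if (!any(keep))
        return(list(mean_slope = NA_real_, sd_slope = NA_real_,
                    n_retained = 0L, defined = FALSE,
                    retained_sites = character(0)))
    s <- site_rocs$slope[keep]
    list(mean_slope = mean(s),
         sd_slope = if (length(s) > 1) stats::sd(s) else NA_real_,
         n_retained = sum(keep), defined = TRUE,
         retained_sites = site_rocs$site[keep])
}

#' Compare two slope collections
#'
#' Two-sided Wilcoxon rank-sum test for a location difference and Levene's
#' test (mean-centered) for a variance difference between two sets of
#' per-site slopes.
#'
#' @param slopes_a,slopes_b numeric vectors (>= 3 values each).
#' @return list with \code{wilcoxon_p}, \code{levene_p},
#'   \code{levene_statistic}.
#' @export
compareROC <- function(slopes_a, slopes_b) {
    if (length(slopes_a) < 3 || length(slopes_b) < 3)
        stop("each slope collection needs at least 3 values")
    w <- stats::wilcox.test(slopes_a, slopes_b, exact = NULL)
    g <- factor(rep(c("a", "b"), c(length(slopes_a), length(slopes_b))))
    lv <- car::leveneTest(c(slopes_a, slopes_b) ~ g, center = mean)
    list(wilcoxon_p = w$p.value,
         levene_p = lv[1, "Pr(>F)"],
         levene_statistic = lv[1, "F value"])
}
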