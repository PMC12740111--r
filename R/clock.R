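#' Specification of an epigenetic clock
#'
#' Fixes the penalized-regression family of each clock type: elastic net
#' (alpha = 0.5) on genome-wide methylation levels, ridge (alpha = 0) on
#' differential-site methylation levels, or elastic net (alpha = 0.5) on
#' differential-site entropies. The penalty path has \code{nlambda} values
#' log-spaced from the smallest penalty giving the all-zero elastic-net
#' solution down to \code{lambda_min_ratio} times it; features are
#' standardized inside each fit (zero mean, unit variance) and coefficients
#' reported back on the original scale.
#'
#' @param clock_type one of \code{"elasticnet_levels"}, \code{"ridge_dms"},
#'   \code{"elasticnet_entropy"}.
#' @param nlambda penalty path length (default 100).
#' @param lambda_min_ratio smallest/largest penalty ratio (default 1e-4).
#' @param standardize standardize features within each fit (default TRUE).
#' @return a \code{ClockSpec} list with the \code{mixing} (alpha) implied by
#'   the clock type.
#' @export
clockSpec <- function(clock_type = c("elasticnet_levels", "ridge_dms",
                                     "elasticnet_entropy"),
                      nlambda = 100L, lambda_min_ratio = 1e-4,
                      standardize = TRUE) {
    clock_type <- match.arg(clock_type)
    spec <- list(clock_type = clock_type,
                 mixing = if (clock_type == "ridge_dms") 0 else 0.5,
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 standardize = isTRUE(standardize))
    class(spec) <- "ClockSpec"
    spec
}

#' Stratified train/test split of a sample manifest
#'
#' Randomly splits samples into training and testing sets, stratified by age
#' group with proportional (largest-remainder) allocation, so a 15-sample
#' cohort with three groups of five and \code{n_train = 10} yields 3-4
#' training samples per group. Deterministic given the seed; the same split
#' should be reused across clock types so their metrics are comparable.
#'
#' @param manifest data.frame with \code{sample_id} and \code{group}.
#' @param n_train number of training samples (< total).
#' @param seed integer seed.
#' @return list with \code{train} and \code{test} sample-id vectors.
#' @export
splitTrainTest <- function(manifest, n_train, seed) {
    n <- nrow(manifest)
    if (n_train >= n) stop("n_train must leave a non-empty test set")
    if (n_train < 1) stop("n_train must be positive")
    groups <- split(as.character(manifest$sample_id), manifest$group)
    sizes <- vapply(groups, length, 1L)
    exact <- n_train * sizes / n
    alloc <- floor(exact)
    rem <- n_train - sum(alloc)
    if (rem > 0) {
        extra <- order(exact - alloc, decreasing = TRUE)[seq_len(rem)]
        alloc[extra] <- alloc[extra] + 1L
    }
    if (any(alloc > sizes))
        stop("stratified allocation infeasible: group sizes ",
             paste(sizes, collapse = ","), " cannot supply ",
             paste(alloc, collapse = ","))
    withSeed(seed, {
        train <- unlist(lapply(names(groups), function(g)
            sample(groups[[g]], alloc[[g]])), use.names = FALSE)
        list(train = sort(train),
             test = sort(setdiff(manifest$sample_id, train)))
    })
}

#' Assemble a clock feature matrix
#'
#' Builds the samples x features matrix a clock type consumes:
#' genome-wide methylation fractions (\code{elasticnet_levels}), fractions at
#' differential sites only (\code{ridge_dms}), or per-site binary entropies
#' at differential sites (\code{elasticnet_entropy}). Columns are named by
#' site key, in matrix (lexicographic) order.
#'
#' @param mat a \linkS4class{MethylExperiment}.
#' @param spec a \code{\link{clockSpec}}.
#' @param dms differential-site table (required for the two DMS-based
#'   types); its \code{site} column selects features.
#' @param samples sample ids (default all).
#' @return numeric matrix, samples in rows.
#' @export
assembleFeatures <- function(mat, spec, dms = NULL, samples = colnames(mat)) {
    fr <- t(fractions(mat)[, samples, drop = FALSE])
    if (spec$clock_type == "elasticnet_levels") return(fr)
    if (is.null(dms) || nrow(dms) == 0)
        stop(spec$clock_type, " requires a non-empty differential site set")
    keep <- intersect(colnames(fr), dms$site)
    if (length(keep) == 0) stop("no differential site present in the matrix")
    X <- fr[, keep, drop = FALSE]
    if (spec$clock_type == "elasticnet_entropy") X[] <- siteEntropy(X)
    X
}

## glmnet wants >= 2 columns; pad single-feature matrices with a zero dummy.
.padX <- function(X) {
    if (ncol(X) >= 2) return(X)
    cbind(X, ".dummy_zero" = 0)
}

## Penalty path: nlambda values log-spaced from lambda_max (smallest penalty
## zeroing the elastic-net solution on the standardized problem) down to
## lambda_min_ratio * lambda_max. Ridge shares the grid shape via the usual
## alpha floor of 0.001.
.lambdaGrid <- function(X, y, alpha, nlambda, lambda_min_ratio) {
    n <- nrow(X)
    sdn <- function(v) sqrt(mean((v - mean(v))^2))
    Xs <- scale(X, center = TRUE, scale = apply(X, 2, function(v) {
        s <- sdn(v); if (s > 0) s else 1
    }))
    yc <- y - mean(y)
    lmax <- max(abs(crossprod(Xs, yc))) / (n * max(alpha, 0.001))
    if (!is.finite(lmax) || lmax <= 0) lmax <- 1
    exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

.fitPath <- function(X, y, alpha, lambda, standardize) {
    glmnet::glmnet(.padX(X), y, family = "gaussian", alpha = alpha,
                   lambda = lambda, standardize = standardize)
}

## Predictions along the fitted path at the grid itself: glmnet fits the
## supplied lambdas exactly, so a0/beta can be read off without the lambda
## interpolation that predict.glmnet performs.
.pathPredict <- function(fit, xrow)
    as.numeric(fit$a0 + xrow %*% fit$beta)

## Inner LOOCV: pick the penalty minimizing leave-one-out MSE; ties (within
## 1e-10 relative) break toward the larger penalty (sparser model), which is
## the first index since the grid is decreasing.
.innerSelectLambda <- function(X, y, alpha, lambda, standardize) {
    n <- nrow(X)
    Xp <- .padX(X)
    sse <- 0
    for (j in seq_len(n)) {
        fit <- .fitPath(X[-j, , drop = FALSE], y[-j], alpha, lambda, standardize)
        pred <- .pathPredict(fit, Xp[j, , drop = FALSE])
        if (length(pred) < length(lambda))   # defensive: truncated path
            pred <- c(pred, rep(pred[length(pred)],
                                length(lambda) - length(pred)))
        sse <- sse + (pred - y[j])^2
    }
    mse <- sse / n
    best <- which(mse <= min(mse) * (1 + 1e-10))[1]
    lambda[best]
}

## Outer LOOCV with nested inner penalty selection. Returns cross-validated
## predictions and per-fold metadata; no final refit (trainClock adds that).
.nestedCV <- function(X, y, alpha, lambda, standardize) {
    n <- nrow(X)
    Xp <- .padX(X)
    cv_pred <- numeric(n)
    fold_lambda <- numeric(n)
    fold_nonzero <- integer(n)
    dummy <- ncol(Xp) > ncol(X)
    for (i in seq_len(n)) {
        Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
        li <- .innerSelectLambda(Xi, yi, alpha, lambda, standardize)
        fit <- .fitPath(Xi, yi, alpha, lambda, standardize)
        k <- which.min(abs(fit$lambda - li))
        cv_pred[i] <- fit$a0[k] +
            as.numeric(Xp[i, , drop = FALSE] %*% fit$beta[, k])
        nz <- fit$beta[, k] != 0
        if (dummy) nz <- nz[-length(nz)]
        fold_nonzero[i] <- sum(nz)
        fold_lambda[i] <- li
    }
    list(cv_pred = setNames(cv_pred, rownames(X)),
         fold_lambda = fold_lambda, fold_nonzero = fold_nonzero)
}

#' Train an epigenetic clock with nested leave-one-out cross-validation
#'
#' The outer loop leaves each training sample out once; within each outer
#' fold an inner leave-one-out loop over the remaining samples selects the
#' penalty minimizing inner mean-squared error. The held-out predictions
#' give unbiased (cross-validated) training metrics and the per-fold
#' nonzero-feature counts used for stability assessment. The final model is
#' refit on all training samples at the penalty chosen by a full-training
#' leave-one-out selection.
#'
#' Zero-variance feature columns are dropped with a warning before fitting
#' (they carry no age information and break standardization).
#'
#' @param features samples x features matrix (>= 3 samples).
#' @param ages_days per-sample chronological ages (days), not all equal.
#' @param spec a \code{\link{clockSpec}}.
#' @param seed kept for interface symmetry; the gaussian penalized fit is
#'   deterministic, so it is unused.
#' @return a \linkS4class{ClockModel}.
#' @export
trainClock <- function(features, ages_days, spec = clockSpec(), seed = NULL) {
    X <- as.matrix(features)
    y <- as.numeric(ages_days)
    if (nrow(X) < 3) stop("need at least 3 training samples")
    if (nrow(X) != length(y)) stop("feature/age length mismatch")
    if (length(unique(y)) < 2) stop("constant-age training set")
    if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
    keep <- apply(X, 2, function(v) stats::sd(v) > 0)
    if (!all(keep)) {
        warning(sum(!keep), " zero-variance feature(s) dropped: ",
                paste(utils::head(colnames(X)[!keep], 5), collapse = ", "))
        X <- X[, keep, drop = FALSE]
    }
    if (ncol(X) == 0) stop("no informative features left")
    lambda <- .lambdaGrid(X, y, spec$mixing, spec$nlambda, spec$lambda_min_ratio)
    cv <- .nestedCV(X, y, spec$mixing, lambda, spec$standardize)
    lam_final <- .innerSelectLambda(X, y, spec$mixing, lambda, spec$standardize)
    fit <- .fitPath(X, y, spec$mixing, lambda, spec$standardize)
    cf <- as.matrix(coef(fit, s = lam_final))
    intercept <- cf[1, 1]
    beta <- cf[-1, 1]
    beta <- beta[names(beta) != ".dummy_zero"]
    nz <- beta[beta != 0]
    metrics <- evaluatePredictions(cv$cv_pred, y)
    methods::new("ClockModel",
                 clockType = spec$clock_type,
                 mixing = spec$mixing,
                 sites = names(nz),
                 coefficients = nz,
                 intercept = unname(intercept),
                 lambda = lam_final,
                 foldFeatureCounts = as.integer(cv$fold_nonzero),
                 foldLambdas = cv$fold_lambda,
                 cvPredictions = cv$cv_pred,
                 trainingMetrics = metrics,
                 featureNames = colnames(X))
}

#' Predict epigenetic age for new samples
#'
#' Linear prediction: intercept plus the coefficient-weighted sum of the
#' model's features. Predictions are not clamped; a negative epigenetic age
#' is reported as-is.
#'
#' @param model a \linkS4class{ClockModel}.
#' @param features samples x features matrix containing every model feature
#'   column (extra columns are ignored).
#' @return named numeric vector of predicted ages in days.
#' @export
predictAge <- function(model, features) {
    X <- as.matrix(features)
    missing <- setdiff(model@sites, colnames(X))
    if (length(missing))
        stop("feature matrix lacks model site(s): ",
             paste(utils::head(missing, 5), collapse = ", "),
             if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
    pred <- model@intercept +
        as.numeric(X[, model@sites, drop = FALSE] %*% model@coefficients)
    setNames(pred, rownames(X))
}

#' Age-prediction accuracy metrics
#'
#' MAE = mean absolute error in days; MRE = mean of per-sample relative
#' absolute errors as a percent of chronological age; Pearson correlation of
#' predicted versus true age.
#'
#' @param predicted,true_ages equal-length numeric vectors (>= 2 samples,
#'   positive true ages).
#' @return list with \code{mae_days}, \code{mre_percent}, \code{pearson_r}.
#' @export
evaluatePredictions <- function(predicted, true_ages) {
    if (length(predicted) != length(true_ages)) stop("length mismatch")
    if (length(predicted) < 2) stop("need at least 2 samples")
    if (any(true_ages <= 0)) stop("true ages must be positive")
    err <- abs(predicted - true_ages)
    r <- if (stats::sd(predicted) == 0 || stats::sd(true_ages) == 0)
        NA_real_ else stats::cor(predicted, true_ages)
    list(mae_days = mean(err),
         mre_percent = 100 * mean(err / true_ages),
         pearson_r = r)
}

#' Permutation test of clock accuracy
#'
#' The observed statistic is the cross-validated accuracy of the nested
#' LOOCV (MAE by default); each permutation shuffles the ages and reruns the
#' full nested procedure. The add-one estimator
#' \code{p = (1 + #(perm at least as good)) / (n_perm + 1)} never returns
#' zero at finite \code{n_perm}.
#'
#' @param features samples x features matrix.
#' @param ages_days per-sample ages.
#' @param spec a \code{\link{clockSpec}}.
#' @param n_perm number of permutations (>= 1; 100 conventional).
#' @param seed integer seed for the permutations.
#' @param statistic \code{"mae"} (default), \code{"mre"} or \code{"cor"}.
#' @return list with \code{p_value}, \code{observed}, \code{permuted}
#'   (vector), \code{statistic}.
#' @export
permutationTest <- function(features, ages_days, spec = clockSpec(),
                            n_perm = 100L, seed = 1L,
                            statistic = c("mae", "mre", "cor")) {
    statistic <- match.arg(statistic)
    if (n_perm < 1) stop("n_perm must be >= 1")
    X <- as.matrix(features)
    y <- as.numeric(ages_days)
    keep <- apply(X, 2, function(v) stats::sd(v) > 0)
    X <- X[, keep, drop = FALSE]
    statOf <- function(pred, truth) {
        m <- evaluatePredictions(pred, truth)
        switch(statistic, mae = m$mae_days, mre = m$mre_percent,
               cor = m$pearson_r)
    }
    better <- function(perm, obs)   # "at least as good as observed"
        if (statistic == "cor") perm >= obs else perm <= obs
    runCV <- function(yy) {
        lambda <- .lambdaGrid(X, yy, spec$mixing, spec$nlambda,
                              spec$lambda_min_ratio)
        cv <- .nestedCV(X, yy, spec$mixing, lambda, spec$standardize)
        statOf(cv$cv_pred, yy)
    }
    obs <- runCV(y)
    perm_stats <- withSeed(seed, vapply(seq_len(n_perm), function(i)
        runCV(sample(y)), numeric(1)))
    list(p_value = (1 + sum(better(perm_stats, obs))) / (n_perm + 1),
         observed = obs, permuted = perm_stats, statistic = statistic)
}

#' Feature-selection stability across outer CV folds
#'
#' Mean and coefficient of variation (100 x SD / mean) of the nonzero-feature
#' counts across outer LOOCV folds. Sample-SD is the default convention; the
#' population-SD variant is also reported. Ridge clocks do not perform
#' feature selection, so they return CV = 0 with an explanatory flag.
#'
#' @param model a \linkS4class{ClockModel}.
#' @return list with \code{mean_features}, \code{cv_percent},
#'   \code{cv_percent_population}, \code{convention}, and \code{note} for
#'   ridge models.
#' @export
featureStability <- function(model) {
    counts <- model@foldFeatureCounts
    if (length(counts) == 0) stop("model has no fold metadata")
    if (model@clockType == "ridge_dms")
        return(list(mean_features = length(model@featureNames),
                    cv_percent = 0, cv_percent_population = 0,
                    convention = "sample_sd",
                    note = "ridge models do not perform feature selection"))
    if (length(counts) < 2) stop("CV undefined for a single fold")
    m <- mean(counts)
    sd_s <- stats::sd(counts)
    sd_p <- sqrt(mean((counts - m)^2))
    list(mean_features = m,
         cv_percent = 100 * sd_s / m,
         cv_percent_population = 100 * sd_p / m,
         convention = "sample_sd", note = NULL)
}

#' Treatment-arm age-deceleration test
#'
#' Applies a trained clock to control and treated samples sharing one
#' chronological age and tests whether any treated arm's predicted
#' epigenetic age is shifted relative to control, using the gated
#' ANOVA/Kruskal-Wallis comparison (\code{\link{compareGroups}}). An arm is
#' decelerated when its mean predicted age is below control and the post hoc
#' control contrast is significant.
#'
#' @param model a \linkS4class{ClockModel}.
#' @param control_features samples x features matrix of the control arm
#'   (>= 3 samples).
#' @param treated_features_by_arm named list of feature matrices, one per
#'   treated arm (>= 3 samples each).
#' @param chronological_age shared chronological age in days.
#' @param alpha significance level for the post hoc contrast.
#' @return list with \code{predicted} (per-arm prediction vectors),
#'   \code{arm_means}, \code{omnibus} (the \code{compareGroups} result), and
#'   \code{arms}: data.frame with \code{arm}, \code{mean_predicted_age},
#'   \code{delta_vs_control} (arm minus control), \code{posthoc_p},
#'   \code{decelerated}.
#' @export
ageDecelerationTest <- function(model, control_features,
                                treated_features_by_arm, chronological_age,
                                alpha = 0.05) {
    arms <- c(list(control = control_features), treated_features_by_arm)
    if (any(vapply(arms, nrow, 1L) < 3))
        stop("every arm needs at least 3 samples")
    preds <- lapply(arms, function(f) predictAge(model, f))
    cg <- compareGroups(preds, alpha = alpha)
    means <- vapply(preds, mean, numeric(1))
    treated <- setdiff(names(arms), "control")
    ph <- cg$pairwise
    getP <- function(arm) {
        hit <- (ph$group1 == "control" & ph$group2 == arm) |
               (ph$group2 == "control" & ph$group1 == arm)
        if (any(hit)) ph$p_value[hit][1] else NA_real_
    }
    arm_tab <- data.frame(
        arm = treated,
        mean_predicted_age = means[treated],
        delta_vs_control = means[treated] - means[["control"]],
        posthoc_p = vapply(treated, getP, numeric(1)),
        stringsAsFactors = FALSE)
    arm_tab$decelerated <- !is.na(arm_tab$posthoc_p) &
        arm_tab$posthoc_p < alpha & arm_tab$delta_vs_control < 0
    rownames(arm_tab) <- NULL
    list(predicted = preds, arm_means = means, omnibus = cg, arms = arm_tab,
         chronological_age = chronological_age)
}

#' Serialize / restore a ClockModel as JSON
#'
#' @param model a \linkS4class{ClockModel}.
#' @param path output path.
#' @return \code{path} (write) or a \code{ClockModel} (read).
#' @export
writeClockModel <- function(model, path) {
    jsonlite::write_json(list(
        clock_type = model@clockType, mixing = model@mixing,
        intercept = model@intercept, lambda = model@lambda,
        sites = as.list(setNames(model@coefficients, model@sites)),
        feature_names = model@featureNames,
        fold_feature_counts = model@foldFeatureCounts,
        fold_lambdas = model@foldLambdas,
        cv_predictions = as.list(model@cvPredictions),
        training_metrics = model@trainingMetrics),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeClockModel
#' @export
readClockModel <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    methods::new("ClockModel",
                 clockType = j$clock_type, mixing = j$mixing,
                 sites = names(j$sites) %||% character(0),
                 coefficients = setNames(as.numeric(unlist(j$sites)),
                                         names(j$sites)),
                 intercept = j$intercept, lambda = j$lambda,
                 foldFeatureCounts = as.integer(j$fold_feature_counts),
                 foldLambdas = as.numeric(j$fold_lambdas),
                 cvPredictions = setNames(as.numeric(unlist(j$cv_predictions)),
                                          names(j$cv_predictions)),
                 trainingMetrics = as.list(j$training_metrics),
                 featureNames = as.character(j$feature_names))
}
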