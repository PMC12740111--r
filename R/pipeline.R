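#' Pipeline configuration
#'
#' Single configuration object for the end-to-end analysis: ingest (or
#' simulate) per-sample bedMethyl tables, filter by coverage, call
#' differential sites between the extreme age groups, compute entropy and
#' rate-of-change summaries, train the three clock types, and test
#' treatment arms for age deceleration. Can be loaded from YAML with
#' \code{pipelineConfigFromYAML}.
#'
#' @param input_mode \code{"simulate"} (generate a synthetic cohort) or
#'   \code{"bedmethyl_dir"} (read \code{<sample_id>.bedmethyl.tsv} files and
#'   a \code{manifest.tsv} from \code{input_dir}).
#' @param input_dir directory for \code{bedmethyl_dir} mode.
#' @param features_bed optional feature BED for context annotation.
#' @param sim_config \code{\link{simulationConfig}} for simulate mode.
#' @param min_cov minimum site coverage (default 10, must be >= 1).
#' @param fdr differential-site FDR threshold (default 0.05).
#' @param roc_p,roc_r2 rate-of-change retention thresholds (defaults 0.05
#'   and 0.65; 0.5 is the other conventional R-squared choice).
#' @param clock_types clock types to train.
#' @param n_train training-set size for the split (default 10 of 15).
#' @param n_perm permutations for clock significance (0 skips the test).
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir output directory (NULL: nothing written).
#' @return a validated \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(input_mode = c("simulate", "bedmethyl_dir"),
                           input_dir = NULL, features_bed = NULL,
                           sim_config = simulationConfig(),
                           min_cov = 10L, fdr = 0.05,
                           roc_p = 0.05, roc_r2 = 0.65,
                           clock_types = c("elasticnet_levels", "ridge_dms",
                                           "elasticnet_entropy"),
                           n_train = 10L, n_perm = 0L, seed = 1L,
                           out_dir = NULL) {
    input_mode <- match.arg(input_mode)
    if (input_mode == "bedmethyl_dir" && is.null(input_dir))
        stop("bedmethyl_dir mode requires input_dir")
    if (min_cov < 1) stop("min_cov must be >= 1")
    if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
    if (roc_p <= 0 || roc_p >= 1 || roc_r2 < 0 || roc_r2 >= 1)
        stop("ROC thresholds out of range")
    cfg <- list(input_mode = input_mode, input_dir = input_dir,
                features_bed = features_bed, sim_config = sim_config,
                min_cov = as.integer(min_cov), fdr = fdr, roc_p = roc_p,
                roc_r2 = roc_r2, clock_types = clock_types,
                n_train = as.integer(n_train), n_perm = as.integer(n_perm),
                seed = as.integer(seed), out_dir = out_dir)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' @rdname pipelineConfig
#' @param path YAML file whose top-level keys are \code{pipelineConfig}
#'   arguments (a \code{sim_config} mapping is passed to
#'   \code{simulationConfig}).
#' @export
pipelineConfigFromYAML <- function(path) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$sim_config))
        y$sim_config <- do.call(simulationConfig, y$sim_config)
    do.call(pipelineConfig, y)
}

.loadCohort <- function(config) {
    if (config$input_mode == "simulate") {
        cohort <- simulateCohort(config$sim_config,
                                 seed = childSeed(config$seed, "sim"))
        list(records = cohort$records, manifest = cohort$manifest,
             truth = cohort$truth)
    } else {
        man_path <- file.path(config$input_dir, "manifest.tsv")
        if (!file.exists(man_path)) stop("manifest.tsv not found in ", config$input_dir)
        manifest <- utils::read.table(man_path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE)
        records <- lapply(manifest$sample_id, function(s)
            readBedMethyl(file.path(config$input_dir,
                                    paste0(s, ".bedmethyl.tsv"))))
        names(records) <- manifest$sample_id
        list(records = records, manifest = manifest, truth = NULL)
    }
}

.summaryBy <- function(vals, labels) {
    lapply(split(vals, labels), function(v)
        list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
             n = length(v)))
}

#' Run the full epigenetic-aging analysis pipeline
#'
#' Executes every stage separately for each modification channel present
#' (6mA \code{"a"} and 5mC \code{"m"} are never mixed in one model):
#' coverage filtering with logged input/output counts, global methylation
#' levels with age-group comparison, differential methylation between the
#' extreme age groups, direction proportions with the cross-channel 2x2
#' chi-squared, genome-wide and DMS-restricted entropy with gated group
#' comparisons, DMS rate-of-change, the configured clocks (train/test
#' metrics, optional permutation p, feature stability), and — when
#' treatment arms exist — the age-deceleration test. Identical config and
#' seed give an identical report.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param verbose log stage progress.
#' @return report list (see \code{\link{writeReport}}); when
#'   \code{config$out_dir} is set, stage tables and the report are written
#'   there.
#' @export
runPipeline <- function(config, verbose = FALSE) {
    stopifnot(inherits(config, "PipelineConfig"))
    stage <- "ingest"
    report <- list(config = list(min_cov = config$min_cov, fdr = config$fdr,
                                 roc_p = config$roc_p, roc_r2 = config$roc_r2,
                                 n_train = config$n_train,
                                 n_perm = config$n_perm, seed = config$seed,
                                 input_mode = config$input_mode),
                   channels = list())
    tryCatch({
        cohort <- .loadCohort(config)
        manifest <- cohort$manifest
        features <- if (!is.null(config$features_bed))
            readFeatureBed(config$features_bed) else NULL

        stage <- "coverage_filter"
        filtered <- lapply(cohort$records, function(df) {
            out <- filterCoverage(df, config$min_cov)
            attr(out, "n_in") <- nrow(df)
            out
        })
        report$filter_log <- lapply(filtered, function(df)
            list(rows_in = attr(df, "n_in"), rows_out = nrow(df)))

        base_ids <- manifest$sample_id[manifest$treatment %in% "none"]
        base_man <- manifest[manifest$treatment %in% "none", , drop = FALSE]
        arm_man <- manifest[!manifest$treatment %in% "none", , drop = FALSE]
        channels <- sort(unique(unlist(lapply(filtered, function(d)
            unique(d$mod_code)))))
        dir_counts <- list()

        for (ch in channels) {
            msgf("channel %s", ch, verbose = verbose)
            stage <- paste0("matrix_", ch)
            ch_records <- lapply(filtered, function(d)
                d[d$mod_code == ch, , drop = FALSE])
            mat <- buildMethylMatrix(ch_records, manifest)
            chrep <- list(n_sites = nrow(mat), n_samples = ncol(mat))

            stage <- paste0("global_", ch)
            glob <- vapply(ch_records[base_ids], globalMethylation, numeric(1))
            glob_site <- vapply(ch_records[base_ids], globalMethylation,
                                numeric(1), weighting = "site")
            chrep$global_methylation <- list(
                read_weighted_pct = as.list(glob),
                site_weighted_pct = as.list(glob_site),
                by_group = .summaryBy(glob, base_man$group),
                group_test = compareGroups(split(glob, base_man$group)))

            stage <- paste0("dms_", ch)
            groups <- split(base_ids, base_man$age_days)
            young <- groups[[1]]; old <- groups[[length(groups)]]
            dms <- callDMS(mat, young, old, fdr = config$fdr)
            if (!is.null(features)) dms <- annotateContext(dms, features)
            chrep$dms <- list(n = nrow(dms))
            if (nrow(dms) > 0) {
                dp <- directionProportions(dms)
                dir_counts[[ch]] <- dp
                chrep$dms$direction <- as.list(dp)
                chrep$dms$context <- as.list(table(dms$context))
            }

            stage <- paste0("entropy_", ch)
            ent_gw <- entropyProfile(mat[, base_ids])
            chrep$entropy <- list(
                genome_wide = list(
                    per_sample = as.list(ent_gw$per_sample_mean),
                    by_group = .summaryBy(ent_gw$per_sample_mean, base_man$group),
                    group_test = compareGroups(
                        split(ent_gw$per_sample_mean, base_man$group))))
            if (nrow(dms) >= 1) {
                keep <- intersect(dms$site, siteKeys(mat))
                if (length(keep)) {
                    ent_dms <- entropyProfile(mat[, base_ids], site_set = keep)
                    chrep$entropy$dms_only <- list(
                        per_sample = as.list(ent_dms$per_sample_mean),
                        by_group = .summaryBy(ent_dms$per_sample_mean,
                                              base_man$group),
                        group_test = compareGroups(
                            split(ent_dms$per_sample_mean, base_man$group)))
                }
            }

            stage <- paste0("roc_", ch)
            if (nrow(dms) >= 1) {
                keep <- intersect(dms$site, siteKeys(mat))
                fr <- fractions(mat)[keep, base_ids, drop = FALSE]
                rocs <- siteRegressionAll(base_man$age_days / 7, fr,
                                          config$roc_p, config$roc_r2)
                mr <- meanROC(rocs, config$roc_p, config$roc_r2)
                chrep$roc <- list(mean_slope_pct_per_week = mr$mean_slope,
                                  sd_slope = mr$sd_slope,
                                  n_retained = mr$n_retained,
                                  defined = mr$defined)
            } else chrep$roc <- list(defined = FALSE, n_retained = 0L)

            stage <- paste0("clocks_", ch)
            split_ids <- splitTrainTest(base_man, config$n_train,
                                        seed = childSeed(config$seed, "split"))
            ages <- setNames(base_man$age_days, base_man$sample_id)
            chrep$clocks <- list()
            for (ct in config$clock_types) {
                spec <- clockSpec(ct)
                needs_dms <- ct != "elasticnet_levels"
                if (needs_dms && nrow(dms) == 0) {
                    chrep$clocks[[ct]] <- list(skipped = "no differential sites")
                    next
                }
                Xtr <- assembleFeatures(mat, spec, dms, samples = split_ids$train)
                Xte <- assembleFeatures(mat, spec, dms, samples = split_ids$test)
                model <- trainClock(Xtr, ages[split_ids$train], spec)
                test_pred <- predictAge(model, Xte)
                entry <- list(
                    train_cv = model@trainingMetrics,
                    test = evaluatePredictions(test_pred, ages[split_ids$test]),
                    n_features_in = length(model@featureNames),
                    n_selected = length(model@sites),
                    stability = featureStability(model))
                if (config$n_perm > 0)
                    entry$permutation <- permutationTest(
                        Xtr, ages[split_ids$train], spec,
                        n_perm = config$n_perm,
                        seed = childSeed(config$seed, paste0("perm_", ct, ch)))[
                            c("p_value", "observed", "statistic")]
                chrep$clocks[[ct]] <- entry
                if (nrow(arm_man) > 0 && "control" %in% arm_man$treatment) {
                    stage <- paste0("deceleration_", ch)
                    arms <- split(arm_man$sample_id, arm_man$treatment)
                    armX <- lapply(arms, function(ids)
                        assembleFeatures(mat, spec, dms, samples = ids))
                    dec <- ageDecelerationTest(
                        model, armX$control,
                        armX[setdiff(names(armX), "control")],
                        chronological_age = unique(arm_man$age_days)[1])
                    chrep$clocks[[ct]]$deceleration <- list(
                        arm_means = as.list(dec$arm_means),
                        arms = dec$arms,
                        omnibus_p = dec$omnibus$p_value,
                        omnibus_test = dec$omnibus$test_name)
                }
            }
            report$channels[[ch]] <- chrep
        }

        stage <- "direction_chisq"
        if (length(dir_counts) == 2) {
            cc <- compareProportionsChisq(dir_counts[[1]], dir_counts[[2]])
            report$direction_chisq <- list(
                channels = names(dir_counts),
                statistic = cc$statistic, df = cc$df, p_value = cc$p_value,
                continuity_corrected = cc$continuity_corrected)
        }
        if (!is.null(cohort$truth))
            report$truth_summary <- list(
                n_clock_sites = length(cohort$truth$clock_sites),
                n_entropy_sites = length(cohort$truth$entropy_sites))
    }, error = function(e)
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
    if (!is.null(config$out_dir)) writeReport(report, config$out_dir)
    report
}

#' Write the pipeline report
#'
#' Serializes the report as schema-stable JSON (full numeric precision) plus
#' a human-readable text summary in mean +/- SD / test-statistic style.
#'
#' @param report list from \code{\link{runPipeline}}.
#' @param out_dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
writeReport <- function(report, out_dir) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", out_dir)
    jpath <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, jpath, auto_unbox = TRUE, digits = NA,
                         force = TRUE, null = "null")
    tpath <- file.path(out_dir, "report.txt")
    con <- file(tpath, "w"); on.exit(close(con))
    w <- function(fmt, ...) writeLines(sprintf(fmt, ...), con)
    w("Epigenetic aging pipeline report (seed %d)", report$config$seed)
    for (ch in names(report$channels)) {
        cr <- report$channels[[ch]]
        w("\n== channel %s: %d sites x %d samples ==", ch, cr$n_sites,
          cr$n_samples)
        for (g in names(cr$global_methylation$by_group)) {
            s <- cr$global_methylation$by_group[[g]]
            w("  global %s: %.2f%% +/- %.2f%%", g, s$mean, s$sd)
        }
        if (!is.null(cr$dms$n)) {
            w("  DMS (q < %.2g): %d", report$config$fdr, cr$dms$n)
            if (!is.null(cr$dms$direction))
                w("    hypo = %d, hyper = %d", cr$dms$direction$n_hypo,
                  cr$dms$direction$n_hyper)
        }
        if (isTRUE(cr$roc$defined))
            w("  mean ROC: %.3f +/- %.3f %%/week (n = %d retained)",
              cr$roc$mean_slope_pct_per_week, cr$roc$sd_slope,
              cr$roc$n_retained)
        for (ct in names(cr$clocks)) {
            cl <- cr$clocks[[ct]]
            if (!is.null(cl$skipped)) { w("  clock %s: skipped (%s)", ct, cl$skipped); next }
            w("  clock %s: train CV MAE = %.2f d, r = %.3f | test MAE = %.2f d, r = %.3f",
              ct, cl$train_cv$mae_days, cl$train_cv$pearson_r,
              cl$test$mae_days, cl$test$pearson_r)
            if (!is.null(cl$permutation))
                w("    permutation p = %.4g (%s)", cl$permutation$p_value,
                  cl$permutation$statistic)
            if (!is.null(cl$deceleration))
                for (i in seq_len(nrow(cl$deceleration$arms))) {
                    a <- cl$deceleration$arms[i, ]
                    w("    arm %s: mean predicted %.1f d (delta %.1f), post hoc p = %.3g",
                      a$arm, a$mean_predicted_age, a$delta_vs_control,
                      a$posthoc_p)
                }
        }
    }
    if (!is.null(report$direction_chisq))
        w("\ndirection 2x2 chi-squared (%s vs %s): X2 = %.3f, df = %d, p = %.4g",
          report$direction_chisq$channels[1], report$direction_chisq$channels[2],
          report$direction_chisq$statistic, report$direction_chisq$df,
          report$direction_chisq$p_value)
    invisible(c(jpath, tpath))
}
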