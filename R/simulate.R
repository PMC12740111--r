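#' Configuration for the synthetic aging-methylome generator
#'
#' Bundles every tunable of \code{\link{simulateCohort}} with defaults chosen
#' to emulate a small aging cohort profiled by long-read modified-base
#' calling: three age groups (7, 21, 35 days, n = 5 each), two modification
#' channels (6mA-like \code{"a"}, 5mC-like \code{"m"}) with a low global
#' methylation background, a minority of "clock" sites whose methylation
#' drifts linearly with age (6mA slope prior mean 1.32 %/week, SD 2.04), a
#' minority of "entropy" sites whose across-sample dispersion grows and whose
#' mean moves toward intermediate methylation with age, negative-binomial
#' read depth (mean 30X, SD ~ 11X), and optional treatment arms modelled as
#' an effective-age offset (rejuvenation).
#'
#' @param n_per_group samples per age group (and per treatment arm).
#' @param ages_days age-group ages in days.
#' @param n_sites sites per modification channel.
#' @param mod_codes channels to simulate (\code{"a"}, \code{"m"}).
#' @param frac_clock_sites proportion of sites with linear age drift.
#' @param frac_entropy_sites proportion of sites with age-increasing
#'   dispersion; \code{frac_clock_sites + frac_entropy_sites <= 1}.
#' @param slope_mean_pct_per_week,slope_sd named per-channel normal prior for
#'   clock-site slopes, in percent methylation per week on the fraction scale
#'   at the cohort midpoint age.
#' @param baseline_beta_params Beta shape pair for the unmethylated
#'   background component.
#' @param bg_methylated_weight,bg_methylated_beta mixture weight and Beta
#'   shapes of the minority methylated background component (keeps the
#'   read-weighted global level near 2-3 percent).
#' @param clock_beta_params Beta shapes for clock-site baselines (low, like
#'   the sparse methylation background, and floored at 0.005 so the drift
#'   has read-level headroom; with the mostly positive slope prior this
#'   yields predominantly hypermethylation with age).
#' @param entropy_beta_params Beta shapes for entropy-site baselines
#'   (truncated at 0.45 so drift toward 0.5 has headroom).
#' @param entropy_drift fraction of the distance from baseline to 0.5 that an
#'   entropy site's mean traverses across the age range.
#' @param dispersion_phi0,dispersion_phi_per_day,dispersion_phi_min Beta
#'   precision schedule for entropy sites:
#'   \code{phi(age) = max(phi_min, phi0 - phi_per_day * age)} (precision
#'   falls, across-sample noise rises with age).
#' @param coverage_mean,coverage_dispersion negative-binomial read-depth
#'   model (\code{mu}, \code{size}).
#' @param treatment_arms named numeric vector of effective-age offsets in
#'   days (e.g. \code{c(control = 0, rapamycin = 10, resveratrol = 10)});
#'   empty for no arms. Arm samples are simulated at \code{treatment_age}.
#' @param treatment_age chronological age (days) of treatment-arm samples.
#' @return a \code{SimulationConfig} (validated list).
#' @export
simulationConfig <- function(n_per_group = 5L,
                             ages_days = c(7, 21, 35),
                             n_sites = 2000L,
                             mod_codes = c("a", "m"),
                             frac_clock_sites = 0.1,
                             frac_entropy_sites = 0.1,
                             slope_mean_pct_per_week = c(a = 1.32, m = 0.61),
                             slope_sd = c(a = 2.04, m = 3.0),
                             baseline_beta_params = c(0.5, 30),
                             bg_methylated_weight = 0.03,
                             bg_methylated_beta = c(5, 5),
                             clock_beta_params = c(1.5, 73.5),
                             entropy_beta_params = c(2, 8),
                             entropy_drift = 0.35,
                             dispersion_phi0 = 60,
                             dispersion_phi_per_day = 1.25,
                             dispersion_phi_min = 8,
                             coverage_mean = 30,
                             coverage_dispersion = 10,
                             treatment_arms = numeric(0),
                             treatment_age = NULL) {
    cfg <- list(n_per_group = as.integer(n_per_group), ages_days = ages_days,
                n_sites = as.integer(n_sites), mod_codes = mod_codes,
                frac_clock_sites = frac_clock_sites,
                frac_entropy_sites = frac_entropy_sites,
                slope_mean_pct_per_week = slope_mean_pct_per_week,
                slope_sd = slope_sd,
                baseline_beta_params = baseline_beta_params,
                bg_methylated_weight = bg_methylated_weight,
                bg_methylated_beta = bg_methylated_beta,
                clock_beta_params = clock_beta_params,
                entropy_beta_params = entropy_beta_params,
                entropy_drift = entropy_drift,
                dispersion_phi0 = dispersion_phi0,
                dispersion_phi_per_day = dispersion_phi_per_day,
                dispersion_phi_min = dispersion_phi_min,
                coverage_mean = coverage_mean,
                coverage_dispersion = coverage_dispersion,
                treatment_arms = treatment_arms,
                treatment_age = treatment_age %||% max(ages_days))
    if (cfg$n_per_group < 1) stop("n_per_group must be >= 1")
    if (length(cfg$ages_days) < 2 || any(cfg$ages_days <= 0))
        stop("ages_days must be >= 2 positive ages")
    if (cfg$frac_clock_sites < 0 || cfg$frac_entropy_sites < 0 ||
        cfg$frac_clock_sites + cfg$frac_entropy_sites > 1)
        stop("site fractions must be in [0,1] with clock + entropy <= 1")
    if (cfg$coverage_mean < 1) stop("coverage_mean must be >= 1")
    if (!all(cfg$mod_codes %in% c("a", "m")))
        stop("mod_codes must be a subset of c('a', 'm')")
    for (ch in cfg$mod_codes)
        if (is.na(cfg$slope_mean_pct_per_week[ch]) || is.na(cfg$slope_sd[ch]))
            stop("slope prior missing for channel ", ch)
    class(cfg) <- "SimulationConfig"
    cfg
}

## Beta precision at a given (effective) age under the dispersion schedule.
precisionAt <- function(config, age_days)
    pmax(config$dispersion_phi_min,
         config$dispersion_phi0 - config$dispersion_phi_per_day * age_days)

## Entropy-site mean at a given (effective) age: linear interpolation from
## the baseline toward 0.5 across the chronological age range.
entropyMeanAt <- function(config, p0, age_days) {
    a0 <- min(config$ages_days); a1 <- max(config$ages_days)
    s <- (age_days - a0) / (a1 - a0)
    pmin(0.99, pmax(0.01, p0 + (0.5 - p0) * config$entropy_drift * s))
}

#' Expected binary entropy of a Beta-distributed methylation fraction
#'
#' Closed form via digamma identities: for \eqn{p ~ Beta(\mu\phi,(1-\mu)\phi)},
#' \eqn{E[p\,\ln p] = \mu\,(\psi(\mu\phi+1) - \psi(\phi+1))} and symmetrically
#' for \eqn{(1-p)\ln(1-p)}, giving \eqn{E[H_2(p)]} exactly. Used to reason
#' about the generator's entropy-site schedule without simulation.
#'
#' @param mu mean in (0,1).
#' @param phi precision (sum of Beta shapes), > 0.
#' @return expected binary (base-2) entropy in [0,1].
#' @export
expectedSiteEntropy <- function(mu, phi) {
    a <- mu * phi; b <- (1 - mu) * phi
    (mu * (digamma(phi + 1) - digamma(a + 1)) +
     (1 - mu) * (digamma(phi + 1) - digamma(b + 1))) / log(2)
}

#' Expected entropy-site schedule across ages
#'
#' Tabulates, for a grid of entropy-site baselines (quantiles of the
#' configured baseline Beta), the generating mean, precision, and expected
#' binary entropy at each cohort age, plus the baseline-averaged expectation.
#' This is the generating-parameter view of the "stochastic aging" component:
#' the cohort-average expected entropy should be non-decreasing in age.
#'
#' @param config a \code{SimulationConfig}.
#' @param ages_days ages to evaluate (default the config's age groups).
#' @param n_quantiles baseline quantile grid size.
#' @return data.frame with columns \code{age_days}, \code{p0}, \code{mu},
#'   \code{phi}, \code{expected_entropy}.
#' @export
entropySchedule <- function(config, ages_days = config$ages_days,
                            n_quantiles = 25L) {
    q <- (seq_len(n_quantiles) - 0.5) / n_quantiles
    p0 <- pmin(0.45, stats::qbeta(q, config$entropy_beta_params[1],
                                  config$entropy_beta_params[2]))
    out <- expand.grid(age_days = ages_days, p0 = p0)
    out$mu <- entropyMeanAt(config, out$p0, out$age_days)
    out$phi <- precisionAt(config, out$age_days)
    out$expected_entropy <- expectedSiteEntropy(out$mu, out$phi)
    out
}

#' Simulate a synthetic aging-methylome cohort
#'
#' Draws per-site baselines, assigns clock/entropy/stable site classes, and
#' generates per-sample read counts for every configured sample, returning
#' bedMethyl-style record tables plus the generating ground truth.
#'
#' Clock sites drift on the logit scale; a site's nominal slope (drawn from
#' the channel's normal prior, % methylation per week) is the fraction-scale
#' derivative at the cohort midpoint age, evaluated at each sample's
#' \emph{effective} age (chronological age minus the treatment offset,
#' floored at 1 day). Entropy sites draw each sample's latent fraction from a
#' Beta whose mean moves toward 0.5 and whose precision falls with effective
#' age. Stable sites keep their baseline. Observed counts are
#' \code{n_valid ~ NegBin(coverage_mean, coverage_dispersion)} and
#' \code{n_mod ~ Binomial(n_valid, fraction)}. A fixed seed reproduces the
#' cohort exactly.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed (required for reproducibility).
#' @return a list with elements \code{records} (named list of per-sample
#'   record data.frames in \code{\link{readBedMethyl}} layout),
#'   \code{manifest} (sample_id, age_days, group, treatment), and
#'   \code{truth}: \code{clock_sites} / \code{entropy_sites} (named numeric
#'   vectors of true fraction-scale slopes, % per week, named by site key),
#'   \code{effective_age_days} (per sample), \code{n_clipped} (latent
#'   fractions clipped to (0,1) tolerance), and \code{seed}.
#' @export
simulateCohort <- function(config = simulationConfig(), seed) {
    if (missing(seed)) stop("simulateCohort requires an explicit seed")
    stopifnot(inherits(config, "SimulationConfig"))
    withSeed(seed, {
        groupOf <- function(age)
            if (age %% 7 == 0) paste0("W", age %/% 7) else paste0("d", age)
        manifest <- do.call(rbind, lapply(config$ages_days, function(age) {
            data.frame(sample_id = sprintf("%s_s%d", groupOf(age),
                                           seq_len(config$n_per_group)),
                       age_days = age, group = groupOf(age),
                       treatment = "none", stringsAsFactors = FALSE)
        }))
        if (length(config$treatment_arms)) {
            arms <- do.call(rbind, lapply(names(config$treatment_arms), function(arm) {
                data.frame(sample_id = sprintf("%s_s%d", arm,
                                               seq_len(config$n_per_group)),
                           age_days = config$treatment_age,
                           group = groupOf(config$treatment_age),
                           treatment = arm, stringsAsFactors = FALSE)
            }))
            manifest <- rbind(manifest, arms)
        }
        offsets <- rep(0, nrow(manifest))
        if (length(config$treatment_arms)) {
            m <- match(manifest$treatment, names(config$treatment_arms))
            offsets[!is.na(m)] <- config$treatment_arms[m[!is.na(m)]]
        }
        eff_age <- pmax(1, manifest$age_days - offsets)
        names(eff_age) <- manifest$sample_id

        mid_wk <- mean(range(config$ages_days)) / 7
        n <- config$n_sites
        truth_clock <- truth_entropy <- list()
        per_sample <- replicate(nrow(manifest), vector("list", 0), simplify = FALSE)
        names(per_sample) <- manifest$sample_id
        n_clipped <- 0L

        for (ch in config$mod_codes) {
            start <- seq.int(0L, by = 11L, length.out = n) +
                ifelse(ch == "a", 0L, 3L)
            strand <- rep(c("+", "-"), length.out = n)
            key <- paste("ctg1", start, strand, ch, sep = ":")

            n_clock <- round(n * config$frac_clock_sites)
            n_ent <- round(n * config$frac_entropy_sites)
            cls <- rep("stable", n)
            special <- sample.int(n, n_clock + n_ent)
            cls[special[seq_len(n_clock)]] <- "clock"
            if (n_ent > 0) cls[special[n_clock + seq_len(n_ent)]] <- "entropy"

            p0 <- numeric(n)
            is_st <- cls == "stable"
            if (any(is_st)) {
                comp <- stats::rbinom(sum(is_st), 1, config$bg_methylated_weight)
                p0[is_st] <- ifelse(comp == 1,
                    stats::rbeta(sum(is_st), config$bg_methylated_beta[1],
                                 config$bg_methylated_beta[2]),
                    stats::rbeta(sum(is_st), config$baseline_beta_params[1],
                                 config$baseline_beta_params[2]))
            }
            is_ck <- cls == "clock"
            ## floored so every drifting site has read-level headroom at 30X
            p0[is_ck] <- pmax(0.005,
                stats::rbeta(sum(is_ck), config$clock_beta_params[1],
                             config$clock_beta_params[2]))
            is_en <- cls == "entropy"
            p0[is_en] <- pmin(0.45,
                stats::rbeta(sum(is_en), config$entropy_beta_params[1],
                             config$entropy_beta_params[2]))
            ## Stable baselines may sit arbitrarily close to 0/1 (no drift to
            ## destabilize them); drifting sites need headroom, so only their
            ## clipping is counted as an infeasibility signal.
            clip <- (is_ck | is_en) & (p0 < 1e-3 | p0 > 1 - 1e-3)
            n_clipped <- n_clipped + sum(clip)
            p0[is_ck | is_en] <- pmin(1 - 1e-3, pmax(1e-3, p0[is_ck | is_en]))
            p0[is_st] <- pmin(1 - 1e-9, pmax(1e-9, p0[is_st]))

            slope <- numeric(n)
            slope[is_ck] <- stats::rnorm(sum(is_ck),
                                         config$slope_mean_pct_per_week[ch],
                                         config$slope_sd[ch])
            ## logit-scale rate giving that fraction-scale slope at midpoint
            d <- ifelse(is_ck, (slope / 100) / (p0 * (1 - p0)), 0)

            if (any(is_ck)) {
                ## truth slope = linear (secant) rate of the latent mean
                ## trajectory across the age range — the quantity a per-site
                ## OLS estimates; the drawn slope parameterizes the logit
                ## drift as the fraction-scale derivative at the midpoint
                a0 <- min(config$ages_days); a1 <- max(config$ages_days)
                fAt <- function(t) stats::plogis(stats::qlogis(p0[is_ck]) +
                                                 d[is_ck] * (t / 7 - mid_wk))
                secant <- 100 * (fAt(a1) - fAt(a0)) / ((a1 - a0) / 7)
                truth_clock[[ch]] <- setNames(secant, key[is_ck])
            }
            if (any(is_en)) {
                a0 <- min(config$ages_days); a1 <- max(config$ages_days)
                ent_slope <- 100 * (entropyMeanAt(config, p0[is_en], a1) -
                                    entropyMeanAt(config, p0[is_en], a0)) /
                             ((a1 - a0) / 7)
                truth_entropy[[ch]] <- setNames(ent_slope, key[is_en])
            }

            for (s in manifest$sample_id) {
                t <- eff_age[[s]]
                frac <- p0
                if (any(is_ck))
                    frac[is_ck] <- stats::plogis(stats::qlogis(p0[is_ck]) +
                                                 d[is_ck] * (t / 7 - mid_wk))
                if (any(is_en)) {
                    mu <- entropyMeanAt(config, p0[is_en], t)
                    phi <- precisionAt(config, t)
                    frac[is_en] <- stats::rbeta(sum(is_en), mu * phi,
                                                (1 - mu) * phi)
                }
                n_valid <- as.integer(
                    stats::rnbinom(n, size = config$coverage_dispersion,
                                   mu = config$coverage_mean))
                n_mod <- as.integer(stats::rbinom(n, n_valid, frac))
                per_sample[[s]][[ch]] <- data.frame(
                    contig = "ctg1", start = start, strand = strand,
                    mod_code = ch, n_valid = n_valid, n_mod = n_mod,
                    fraction = ifelse(n_valid > 0, n_mod / n_valid, NA_real_),
                    stringsAsFactors = FALSE)
            }
        }
        if (n_clipped > 0)
            warning(n_clipped, " baseline fraction(s) clipped into (0, 1)")
        records <- lapply(per_sample, function(chunks) {
            df <- do.call(rbind, chunks)
            df <- df[!is.na(df$fraction), , drop = FALSE]
            rownames(df) <- NULL
            df
        })
        list(records = records, manifest = manifest,
             truth = list(clock_sites = unlist(unname(truth_clock)),
                          entropy_sites = unlist(unname(truth_entropy)),
                          effective_age_days = eff_age,
                          n_clipped = n_clipped, seed = as.integer(seed)))
    })
}

#' Write a simulated cohort as an on-disk fixture set
#'
#' Writes one 18-column bedMethyl file per sample, a tab-separated sample
#' manifest, and the ground truth as JSON, in exactly the dialects the
#' package's readers consume.
#'
#' @param cohort result of \code{\link{simulateCohort}}.
#' @param out_dir output directory (created if needed).
#' @return named list of written paths (\code{bedmethyl} vector,
#'   \code{manifest}, \code{truth}), invisibly.
#' @export
writeFixtureSet <- function(cohort, out_dir) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", out_dir)
    bm <- vapply(names(cohort$records), function(s) {
        p <- file.path(out_dir, paste0(s, ".bedmethyl.tsv"))
        writeBedMethyl(cohort$records[[s]], p)
        p
    }, character(1))
    man_path <- file.path(out_dir, "manifest.tsv")
    utils::write.table(cohort$manifest, man_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth_path <- file.path(out_dir, "truth.json")
    jsonlite::write_json(
        list(clock_sites = as.list(cohort$truth$clock_sites),
             entropy_sites = as.list(cohort$truth$entropy_sites),
             effective_age_days = as.list(cohort$truth$effective_age_days),
             n_clipped = cohort$truth$n_clipped,
             seed = cohort$truth$seed),
        truth_path, auto_unbox = TRUE, digits = NA)
    invisible(list(bedmethyl = bm, manifest = man_path, truth = truth_path))
}
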