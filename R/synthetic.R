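# Seeded synthetic-data generator: food libraries with realistic
# within-site replicate noise, and consumer cohorts constructed as known
# mixtures of the food signatures distorted by a known calibration vector.

default_site_diets <- function() {
  # per-site mean diets of the study system (grass/roots/feces, %),
  # normalized to the simplex; cohort sizes 8/7/5 animals
  list(
    low = c(grass = 55.3, roots = 32.0, feces = 12.8) / 100.1,
    medium = c(grass = 61.9, roots = 17.7, feces = 20.4) / 100,
    high = c(grass = 73.6, roots = 0.2, feces = 26.2) / 100
  )
}

#' Scenario configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator: site names, per-site mean food
#' signatures (default: the bundled reference food table), number of field
#' replicates per source (default 8), the range of per-fatty-acid
#' coefficients of variation of the food replicates (default 2-5%, the
#' consistency observed for real food sources within a site), the true
#' calibration vector the consumers apply when storing fat, the consumers'
#' true diets, the consumer measurement/physiology noise cv, and the seed.
#'
#' Consumer diets default to the study design: 20 animals in site blocks of
#' 8/7/5, each site block sharing its site's mean diet. Consumer fat is
#' generated on the `fa_subset` used for fitting (default: the ten
#' high-abundance acids shared by the bundled pika and mouse fat means),
#' mixing food signatures that have been restricted to that subset and
#' rescaled to a common total, so generated cohorts are exact grid mixtures
#' when noise is zero.
#'
#' @param seed integer seed (required; all generation is reproducible).
#' @param sites character vector of site names.
#' @param source_means named list (per site) of FA-by-source matrices;
#'   default from [example_source_means()].
#' @param replicates_per_source field replicates per source and site.
#' @param food_cv length-2 range for replicate cv, drawn uniformly per
#'   fatty acid; `c(0, 0)` gives noise-free replicates.
#' @param true_cc named calibration vector applied by consumers (default:
#'   all 1, no discrimination).
#' @param consumer_diets data.frame with columns `animal_id`, `site` and one
#'   column per source (proportions summing to 1 per row).
#' @param consumer_noise_cv multiplicative noise cv on consumer fat
#'   (default 0.02; the within-animal adipose variance of real animals is
#'   unknown, so 0-5% is an assumption).
#' @param fa_subset fatty acids the generated consumer fat covers.
#' @param total common subset total (ug/mg) for generated fat signatures.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(seed,
                            sites = c("low", "medium", "high"),
                            source_means = NULL,
                            replicates_per_source = 8,
                            food_cv = c(0.02, 0.05),
                            true_cc = NULL,
                            consumer_diets = NULL,
                            consumer_noise_cv = 0.02,
                            fa_subset = NULL,
                            total = 1000) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (is.null(source_means)) {
    source_means <- stats::setNames(lapply(sites, example_source_means), sites)
  }
  stopifnot(all(sites %in% names(source_means)))
  stopifnot(replicates_per_source >= 1)
  stopifnot(length(food_cv) == 2L, all(food_cv >= 0), all(food_cv < 1),
            food_cv[1] <= food_cv[2])
  stopifnot(consumer_noise_cv >= 0, consumer_noise_cv < 1)
  sources <- colnames(source_means[[1L]])
  if (is.null(fa_subset)) {
    fa_subset <- select_shared_fas(example_fat_means(), threshold = 5)
  }
  if (is.null(consumer_diets)) {
    site_diets <- default_site_diets()
    n_per_site <- c(low = 8, medium = 7, high = 5)
    stopifnot(all(sites %in% names(site_diets)))
    consumer_diets <- do.call(rbind, lapply(sites, function(s) {
      n <- n_per_site[[s]]
      d <- site_diets[[s]][sources]
      out <- data.frame(animal_id = sprintf("%s_%d", s, seq_len(n)),
                        site = s, stringsAsFactors = FALSE)
      for (src in sources) out[[src]] <- d[[src]]
      out
    }))
  }
  stopifnot(all(c("animal_id", "site", sources) %in% names(consumer_diets)))
  P <- as.matrix(consumer_diets[sources])
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9)) {
    stop("consumer diets must be non-negative and sum to 1", call. = FALSE)
  }
  if (is.null(true_cc)) {
    true_cc <- stats::setNames(rep(1, length(fa_subset)), fa_subset)
  }
  structure(list(seed = as.integer(seed), sites = sites,
                 source_means = source_means, sources = sources,
                 replicates_per_source = as.integer(replicates_per_source),
                 food_cv = food_cv, true_cc = check_cc(true_cc, fa_subset),
                 consumer_diets = consumer_diets,
                 consumer_noise_cv = consumer_noise_cv,
                 fa_subset = sort_fa(fa_subset), total = total),
            class = "scenario_config")
}

#' Generate a synthetic food-source library
#'
#' For every site and source, draws the configured number of replicate
#' signatures: each fatty acid with positive mean gets a cv drawn uniformly
#' from `food_cv`, and replicates are drawn from a normal with that mean
#' and sd = mean * cv, truncated at zero. Structural zeros (fatty acids a
#' source does not contain) stay exactly zero in every replicate.
#'
#' @param config a [scenario_config()].
#' @return A [source_library()].
#' @export
gen_source_library <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  nrep <- config$replicates_per_source
  sets <- list()
  for (site in config$sites) {
    M <- config$source_means[[site]]
    for (src in colnames(M)) {
      mu <- M[, src]
      reps <- matrix(0, nrow = length(mu), ncol = nrep,
                     dimnames = list(rownames(M), NULL))
      for (i in seq_along(mu)) {
        if (mu[i] > 0) {
          cv <- stats::runif(1L, config$food_cv[1], config$food_cv[2])
          reps[i, ] <- pmax(0, stats::rnorm(nrep, mu[i], mu[i] * cv))
        }
      }
      sets[[length(sets) + 1L]] <- source_sample_set(
        src, site, lapply(seq_len(nrep), function(j) reps[, j]))
    }
  }
  source_library(sets)
}

#' Generate one synthetic consumer
#'
#' Builds a consumer whose stored fat is, on the fitting fatty-acid subset,
#' the calibration-distorted mixture of the site's food signatures:
#' each food mean is restricted to `fa_subset` and rescaled to `total`,
#' the diet-weighted mixture is taken, multiplied per fatty acid by the
#' true calibration vector, rescaled back to `total`, and finally perturbed
#' by multiplicative Gaussian noise with cv `noise_cv` (truncated at zero).
#'
#' @param diet named diet proportions over the sources (sums to 1).
#' @param site_means FA-by-source matrix of mean food signatures.
#' @param true_cc calibration vector on `fa_subset` (default all 1).
#' @param noise_cv multiplicative noise cv (0 = deterministic).
#' @param fa_subset fatty acids of the generated fat signature.
#' @param total subset total (ug/mg) of the generated fat.
#' @param animal_id,species,site identifiers for the returned sample.
#' @return A [consumer_sample()].
#' @export
gen_consumer <- function(diet, site_means, true_cc = NULL, noise_cv = 0,
                         fa_subset = rownames(site_means), total = 1000,
                         animal_id = "sim", species = "synthetic",
                         site = "sim") {
  fa_subset <- sort_fa(fa_subset)
  Msub <- vapply(colnames(site_means), function(src) {
    restrict_and_rescale(site_means[, src], fa_subset, target_total = total)
  }, numeric(length(fa_subset)))
  Msub <- matrix(Msub, nrow = length(fa_subset),
                 dimnames = list(fa_subset, colnames(site_means)))
  fat <- predict_fat_signature(diet, Msub, cc = true_cc, total = total)
  if (noise_cv > 0) {
    fat <- pmax(fat * (1 + stats::rnorm(length(fat), 0, noise_cv)), 0)
  }
  consumer_sample(animal_id, species, site, fat)
}

#' Generate a synthetic consumer cohort
#'
#' One [gen_consumer()] per row of the configured diet table, mixing the
#' empirical site means of `library` (or the configured true means if no
#' library is given).
#'
#' @param config a [scenario_config()].
#' @param library optional [source_library()] whose empirical site means
#'   the consumers should mix (pass the library you will fit against to
#'   make zero-noise cohorts exactly recoverable).
#' @return List with `consumers` (list of [consumer_sample()]) and
#'   `true_diets` (the configured diet data.frame).
#' @export
gen_cohort <- function(config, library = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)
  diets <- config$consumer_diets
  consumers <- lapply(seq_len(nrow(diets)), function(i) {
    site <- diets$site[i]
    M <- if (is.null(library)) config$source_means[[site]] else {
      library_means(library, site = site)
    }
    p <- stats::setNames(as.numeric(diets[i, config$sources]), config$sources)
    gen_consumer(p, M, true_cc = config$true_cc,
                 noise_cv = config$consumer_noise_cv,
                 fa_subset = config$fa_subset, total = config$total,
                 animal_id = diets$animal_id[i], species = "synthetic_pika",
                 site = site)
  })
  list(consumers = consumers, true_diets = diets)
}

#' Generate negative-control consumers from an unrelated signature
#'
#' Control animals never ate the candidate foods; their fat is generated
#' from an arbitrary reference signature (default: the bundled laboratory
#' mouse adipose mean, which is rich in 18:1 and nearly lacks 18:3n3) plus
#' multiplicative noise, on the same fatty-acid subset and total as the
#' target cohort.
#'
#' @param config a [scenario_config()].
#' @param n number of control animals.
#' @param signature reference fat signature (default: bundled mouse mean).
#' @return List of [consumer_sample()] objects (sites recycled from the
#'   configured sites).
#' @export
gen_control_cohort <- function(config, n = 5, signature = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(signature)) signature <- example_fat_means()$mouse
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 2L)
  base <- restrict_and_rescale(signature, config$fa_subset,
                               target_total = config$total)
  sites <- rep(config$sites, length.out = n)
  lapply(seq_len(n), function(i) {
    fat <- base
    if (config$consumer_noise_cv > 0) {
      fat <- pmax(fat * (1 + stats::rnorm(length(fat), 0,
                                          config$consumer_noise_cv)), 0)
    }
    consumer_sample(sprintf("control_%d", i), "control_mouse", sites[i], fat)
  })
}

#' Diet-recovery experiment on a synthetic cohort
#'
#' End-to-end validation harness: generates a food library and a consumer
#' cohort with known diets (and known calibration vector), runs the fitting
#' pipeline, and tabulates true vs estimated proportions. Optionally runs
#' the calibration stage (index animals, perfect-fit coefficients,
#' averaging, refit) and reports how well the true calibration vector is
#' recovered.
#'
#' @param config a [scenario_config()].
#' @param step simplex grid resolution for fitting.
#' @param calibrate run the calibration stage and refit with the derived
#'   average coefficients.
#' @param index_seed seed for index-animal selection (default: the
#'   scenario seed).
#' @return List with `per_consumer` (data.frame: animal, site, true and
#'   estimated % per source, absolute error, bmd), `summary` (mean/max
#'   absolute error and RMSE of proportions), `report` (the
#'   [fit_cohort()] result used), and when `calibrate = TRUE`: `cc_true`,
#'   `cc_est` (both normalized to geometric mean 1) and `cc_max_abs_log_err`.
#' @export
recovery_experiment <- function(config, step = 0.01, calibrate = FALSE,
                                index_seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  lib <- gen_source_library(config)
  coh <- gen_cohort(config, lib)
  cc_used <- NULL
  cal <- NULL
  if (calibrate) {
    cal <- derive_calibration(coh$consumers, lib, seed = index_seed,
                              step = step, fa_subset = config$fa_subset)
    cc_used <- cal$cc
  }
  report <- fit_cohort(coh$consumers, lib, cc = cc_used, step = step,
                       fa_subset = config$fa_subset)
  est <- report$per_animal
  truth <- coh$true_diets
  per <- data.frame(animal_id = est$animal_id, site = est$site,
                    stringsAsFactors = FALSE)
  errs <- NULL
  for (src in config$sources) {
    per[[paste0(src, "_true")]] <- 100 * truth[[src]]
    per[[paste0(src, "_est")]] <- est[[src]]
    e <- abs(est[[src]] - 100 * truth[[src]])
    per[[paste0(src, "_abs_err")]] <- e
    errs <- cbind(errs, e)
  }
  per$bmd <- est$bmd
  out <- list(
    per_consumer = per,
    summary = data.frame(mean_abs_err = mean(errs), max_abs_err = max(errs),
                         rmse = sqrt(mean(errs^2))),
    report = report
  )
  if (calibrate) {
    norm_gm <- function(x) x / exp(mean(log(x)))
    cc_true <- norm_gm(config$true_cc[report$fa_subset])
    cc_est <- norm_gm(cc_used[report$fa_subset])
    out$cc_true <- cc_true
    out$cc_est <- cc_est
    out$cc_max_abs_log_err <- max(abs(log(cc_est) - log(cc_true)))
    out$calibration <- cal
  }
  out
}
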