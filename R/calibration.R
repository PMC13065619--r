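# Calibration coefficients derived as outputs from index animals.
#
# Without feeding trials, per-fatty-acid calibration coefficients are
# derived from the data themselves: fit each index animal with all
# coefficients set to 1, then compute the coefficient vector that would
# make that fit perfect, and average across index animals.

#' Derive the perfect-fit calibration coefficients for one animal
#'
#' Given an animal's observed fat signature and its best fit obtained with
#' all calibration coefficients equal to 1, returns the coefficient vector
#' `cc_i = observed_i / predicted_i` that makes the fitted diet reproduce
#' the observed signature exactly. Fatty acids absent from both vectors get
#' coefficient 1.
#'
#' @param observed the animal's observed signature (fitting subset).
#' @param unity_fit the [fit_diet()] result for this animal at cc = 1.
#' @return Named calibration-coefficient vector (dimensionless, > 0).
#' @export
derive_perfect_fit_cc <- function(observed, unity_fit) {
  stopifnot(inherits(unity_fit, "qfasa_fit"))
  if (any(unity_fit$cc != 1)) {
    stop("unity_fit must be computed with all calibration coefficients = 1",
         call. = FALSE)
  }
  observed <- as_signature(observed)
  pred <- unity_fit$predicted
  if (!identical(names(observed), names(pred))) {
    stop("observed signature and unity fit cover different fatty acids",
         call. = FALSE)
  }
  undef <- pred == 0 & observed > 0
  if (any(undef)) {
    stop("coefficient undefined (predicted 0, observed > 0) for: ",
         paste(names(pred)[undef], collapse = ", "), call. = FALSE)
  }
  cc <- ifelse(pred == 0 & observed == 0, 1, observed / pred)
  stats::setNames(cc, names(pred))
}

#' Average calibration coefficients across index animals
#'
#' Arithmetic mean per fatty acid of the unlogged coefficients (the
#' default). A geometric mean is available as an alternative for users who
#' prefer averaging on the log scale.
#'
#' @param ccs list of calibration vectors on a shared fatty-acid subset.
#' @param method `"arithmetic"` (default) or `"geometric"`.
#' @return Averaged calibration vector.
#' @export
average_cc <- function(ccs, method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  stopifnot(length(ccs) >= 1L)
  fas <- names(ccs[[1L]])
  same <- vapply(ccs, function(cc) identical(sort(names(cc)), sort(fas)), TRUE)
  if (!all(same)) stop("calibration vectors cover different fatty-acid subsets",
                       call. = FALSE)
  mat <- vapply(ccs, function(cc) cc[fas], numeric(length(fas)))
  mat <- matrix(mat, nrow = length(fas), dimnames = list(fas, NULL))
  out <- if (method == "arithmetic") rowMeans(mat) else exp(rowMeans(log(mat)))
  stats::setNames(out, fas)
}

#' Natural-log calibration coefficients
#'
#' Reports `log_e` of each coefficient. A positive logged value means the
#' animal discriminates against storing that fatty acid (it is less
#' abundant in fat than the diet mixture predicts); a negative value means
#' storage is favored; 0 means no discrimination.
#'
#' @param cc calibration vector (all coefficients > 0).
#' @return Named numeric vector of `log_e` coefficients.
#' @export
log_cc_report <- function(cc) {
  if (any(!is.finite(cc)) || any(cc <= 0)) {
    stop("calibration coefficients must be strictly positive", call. = FALSE)
  }
  log(cc)
}

#' Randomly select one index animal per site
#'
#' @param consumers list of [consumer_sample()] objects.
#' @param seed integer seed (required: index-animal selection must be
#'   reproducible).
#' @return Character vector of selected animal ids, one per site, in site
#'   order of first appearance.
#' @export
select_index_animals <- function(consumers, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  sites <- vapply(consumers, `[[`, "", "site")
  ids <- vapply(consumers, `[[`, "", "animal_id")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  vapply(unique(sites), function(s) {
    cand <- ids[sites == s]
    cand[sample.int(length(cand), 1L)]
  }, "")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Derive averaged calibration coefficients from a cohort
#'
#' The full calibration stage: select one index animal per site, fit each
#' at cc = 1, derive the perfect-fit coefficients for each, and average
#' them (unlogged). The averaged vector is then used to re-fit the whole
#' cohort (see [fit_cohort()]).
#'
#' @inheritParams fit_cohort
#' @param seed integer seed for index-animal selection.
#' @param method averaging method, see [average_cc()].
#' @return List with `index_ids`, `per_animal_cc` (list of calibration
#'   vectors), `cc` (the average), `log_cc`, and `unity_fits`.
#' @export
derive_calibration <- function(consumers, library, seed, step = 0.01,
                               fa_subset = NULL, threshold = 5,
                               site_matched = TRUE, rescale = TRUE,
                               method = "arithmetic") {
  idx <- select_index_animals(consumers, seed)
  sel <- consumers[vapply(consumers, `[[`, "", "animal_id") %in% idx]
  prep <- prepare_cohort(sel, library, fa_subset = fa_subset,
                         threshold = threshold, site_matched = site_matched)
  unity_fits <- lapply(prep, function(p) {
    fit_diet(p$fat, p$means, cc = NULL, step = step, rescale = rescale,
             profile = FALSE)
  })
  ccs <- Map(function(p, f) derive_perfect_fit_cc(p$fat, f), prep, unity_fits)
  cc <- average_cc(ccs, method = method)
  list(index_ids = unname(idx), per_animal_cc = ccs, cc = cc,
       log_cc = log_cc_report(cc), unity_fits = unity_fits)
}
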