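# Core QFASA fit: exhaustive least-absolute-deviation search over the
# diet-proportion simplex.

# Coerce source means (matrix or list of signatures) to an FA x source
# matrix aligned with `observed`; checks the FA sets match exactly.
align_sources <- function(observed, source_means) {
  if (!is.matrix(source_means)) {
    source_means <- zero_fill(lapply(source_means, as_signature))
  }
  if (is.null(colnames(source_means)) || is.null(rownames(source_means))) {
    stop("source means must have source column names and fatty-acid row names",
         call. = FALSE)
  }
  observed <- as_signature(observed)
  fas <- sort_fa(rownames(source_means))
  if (!setequal(names(observed), fas)) {
    stop("observed signature and source means must cover the same fatty acids; ",
         "restrict both to a common subset first (see restrict_and_rescale)",
         call. = FALSE)
  }
  list(observed = observed[fas], M = source_means[fas, , drop = FALSE])
}

check_cc <- function(cc, fas) {
  if (is.null(cc)) return(stats::setNames(rep(1, length(fas)), fas))
  if (is.null(names(cc))) stop("calibration coefficients must be named by fatty acid",
                               call. = FALSE)
  miss <- setdiff(fas, names(cc))
  if (length(miss)) {
    stop("calibration coefficient missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cc <- cc[fas]
  if (any(!is.finite(cc)) || any(cc <= 0)) {
    stop("calibration coefficients must be strictly positive and finite",
         call. = FALSE)
  }
  cc
}

check_step <- function(step) {
  stopifnot(is.numeric(step), length(step) == 1L)
  if (step <= 0 || step > 1) stop("step must be in (0, 1]", call. = FALSE)
  n <- round(1 / step)
  if (abs(n * step - 1) > 1e-8) {
    stop("step must divide 1 exactly (e.g. 0.01)", call. = FALSE)
  }
  as.integer(n)
}

#' Predict a stored-fat signature from a diet
#'
#' Under the QFASA model the stored fat of a consumer eating diet
#' proportions \eqn{p} is, fatty acid by fatty acid,
#' \eqn{\hat{y}_i = c_i \sum_k p_k \mu_{ki}}, where \eqn{\mu_{ki}} is the
#' mean signature of food \eqn{k} and \eqn{c_i} a calibration coefficient
#' absorbing digestion/deposition selectivity. If `total` is given the
#' prediction is rescaled to that subset total so it is comparable with an
#' observed signature in ug/mg.
#'
#' @param diet named numeric vector of diet proportions (sums to 1).
#' @param source_means FA-by-source matrix of mean signatures, or a named
#'   list of signatures.
#' @param cc named calibration-coefficient vector (default: all 1, i.e. no
#'   discrimination).
#' @param total optional target subset total (ug/mg) for rescaling.
#' @return Predicted signature (named numeric vector).
#' @examples
#' M <- cbind(food1 = c(a = 100, b = 0), food2 = c(a = 0, b = 100))
#' rownames(M) <- c("16:0", "18:1")
#' predict_fat_signature(c(food1 = 0.38, food2 = 0.62), M)
#' @export
predict_fat_signature <- function(diet, source_means, cc = NULL, total = NULL) {
  if (!is.matrix(source_means)) {
    source_means <- zero_fill(lapply(source_means, as_signature))
  }
  if (is.null(names(diet))) stop("diet proportions must be named by source",
                                 call. = FALSE)
  unknown <- setdiff(names(diet), colnames(source_means))
  if (length(unknown)) {
    stop("diet references unknown source(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  diet <- diet[colnames(source_means)]
  diet[is.na(diet)] <- 0
  if (any(diet < 0) || abs(sum(diet) - 1) > 1e-9) {
    stop("diet proportions must be non-negative and sum to 1", call. = FALSE)
  }
  fas <- rownames(source_means)
  cc <- check_cc(cc, fas)
  pred <- as.numeric(source_means %*% diet) * cc
  names(pred) <- fas
  if (!is.null(total)) {
    s <- sum(pred)
    if (s <= 0) stop("predicted signature has zero total", call. = FALSE)
    pred <- pred * (total / s)
  }
  pred
}

#' Summed absolute deviation between two signatures
#'
#' \eqn{\sum_i |\hat{y}_i - y_i|} over the shared fatty-acid subset, in
#' ug/mg. Evaluated at the best-fitting diet this is the best model
#' deviation (BMD).
#'
#' @param predicted,observed signatures over identical fatty-acid subsets.
#' @return Non-negative deviation (ug/mg).
#' @export
summed_abs_deviation <- function(predicted, observed) {
  predicted <- as_signature(predicted)
  observed <- as_signature(observed)
  if (!identical(names(predicted), names(observed))) {
    stop("signatures cover different fatty-acid subsets", call. = FALSE)
  }
  sum(abs(predicted - observed))
}

#' Squared Pearson correlation between predicted and observed signatures
#'
#' @param predicted,observed signatures over identical fatty-acid subsets
#'   (at least 3 fatty acids, neither vector constant).
#' @return r-squared in `[0, 1]`.
#' @export
pearson_r_squared <- function(predicted, observed) {
  predicted <- as_signature(predicted)
  observed <- as_signature(observed)
  if (!identical(names(predicted), names(observed))) {
    stop("signatures cover different fatty-acid subsets", call. = FALSE)
  }
  if (length(predicted) < 3L) {
    stop("need at least 3 shared fatty acids", call. = FALSE)
  }
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(predicted, observed)^2
}

#' Fit a diet by exhaustive simplex-grid search
#'
#' Enumerates every diet-proportion vector whose components are multiples
#' of `step` and sum to 1, and returns the one minimizing the summed
#' absolute deviation between the predicted and observed stored-fat
#' signatures. The default `step = 0.01` searches at 1% resolution (5151
#' grid diets for three foods). Ties are broken toward the
#' lexicographically smallest proportion vector in canonical source order.
#'
#' With `rescale = TRUE` (default) the mixture prediction is rescaled to
#' the observed subset total before the deviation is computed, so foods and
#' fat are compared as compositions on a common ug/mg total and calibration
#' coefficients are identifiable up to a common factor. `rescale = FALSE`
#' compares raw mixture totals instead.
#'
#' @inheritParams predict_fat_signature
#' @param observed the consumer's stored-fat signature, restricted to the
#'   fitting fatty-acid subset (see [select_shared_fas()] and
#'   [restrict_and_rescale()]).
#' @param step grid resolution; must divide 1 exactly.
#' @param rescale rescale predictions to the observed subset total.
#' @param profile also compute per-source uniqueness profiles (see
#'   [uniqueness_profile()]).
#' @return An object of class `qfasa_fit` with elements `diet` (named
#'   proportions), `bmd`, `r_squared` (`NA` with fewer than 3 fatty acids),
#'   `predicted`, `observed`, `step`, `n_ties`, and (if requested)
#'   `profiles` and `non_unique` flags.
#' @examples
#' M <- cbind(food1 = c("16:0" = 100, "18:1" = 0),
#'            food2 = c("16:0" = 0, "18:1" = 100))
#' fit <- fit_diet(c("16:0" = 38, "18:1" = 62), M)
#' fit$diet   # 0.38 / 0.62, exact fit
#' @export
fit_diet <- function(observed, source_means, cc = NULL, step = 0.01,
                     rescale = TRUE, profile = TRUE) {
  al <- align_sources(observed, source_means)
  nsteps <- check_step(step)
  if (ncol(al$M) < 2L) stop("need at least 2 sources", call. = FALSE)
  cc <- check_cc(cc, rownames(al$M))
  Mcc <- al$M * cc  # fold cc into the rows: cc_i * sum_k p_k mu_ki
  res <- grid_scan(Mcc, al$observed, nsteps, rescale, sum(al$observed),
                   profile = profile)
  diet <- stats::setNames(res$best / nsteps, colnames(al$M))
  predicted <- predict_fat_signature(
    diet, al$M, cc = cc,
    total = if (rescale) sum(al$observed) else NULL)
  r2 <- if (length(al$observed) >= 3L &&
            stats::sd(predicted) > 0 && stats::sd(al$observed) > 0) {
    stats::cor(predicted, al$observed)^2
  } else NA_real_
  out <- structure(
    list(diet = diet, bmd = res$bmd, r_squared = r2,
         predicted = predicted, observed = al$observed,
         cc = cc, step = step, rescale = rescale, n_ties = res$n_ties),
    class = "qfasa_fit")
  if (profile) {
    prof <- res$profile
    dimnames(prof) <- list(colnames(al$M), NULL)
    out$profiles <- profile_frame(prof, nsteps)
    out$non_unique <- flag_non_unique(prof, res$bmd, nsteps)
  }
  out
}

profile_frame <- function(prof, nsteps) {
  data.frame(
    source = rep(rownames(prof), each = nsteps + 1L),
    proportion = rep(0:nsteps / nsteps, times = nrow(prof)),
    min_dev = as.vector(t(prof)),
    stringsAsFactors = FALSE
  )
}

# Multiple-solution diagnostic. For each source the profile curve gives the
# minimal deviation attainable at each fixed proportion. With a unique
# solution the near-optimal proportions (within `tol` relative of the
# global minimum, with a small absolute floor for exact fits) cluster
# around the best proportion; a near-optimal proportion farther than
# `flat_width` away marks a distant, almost-as-good solution (e.g. two
# interchangeable sources give a fully flat curve).
flag_non_unique <- function(prof, bmd, nsteps, tol = 0.01, flat_width = 0.10) {
  apply(prof, 1L, function(curve) {
    cut <- max(bmd * (1 + tol), bmd + 1e-9)
    near <- (which(curve <= cut) - 1L) / nsteps
    best <- (which.min(curve) - 1L) / nsteps
    any(abs(near - best) > flat_width)
  })
}

#' Uniqueness profile of a diet fit
#'
#' For each food source and each grid proportion `v`, the minimum summed
#' absolute deviation over all grid diets that assign that source exactly
#' `v`. Plotting these curves shows whether the best fit sits in a single
#' sharp valley (unique solution) or whether distant diets fit almost as
#' well.
#'
#' @inheritParams fit_diet
#' @param tol relative tolerance (default 1%) within which a deviation
#'   counts as near-optimal.
#' @param flat_width maximum distance (fraction of the proportion axis) a
#'   near-optimal proportion may lie from the best one before the solution
#'   is flagged non-unique.
#' @return List with `profiles` (data.frame `source`, `proportion`,
#'   `min_dev`), `non_unique` (named logical per source) and `bmd`.
#' @export
uniqueness_profile <- function(observed, source_means, cc = NULL, step = 0.01,
                               rescale = TRUE, tol = 0.01, flat_width = 0.10) {
  al <- align_sources(observed, source_means)
  nsteps <- check_step(step)
  cc <- check_cc(cc, rownames(al$M))
  res <- grid_scan(al$M * cc, al$observed, nsteps, rescale, sum(al$observed),
                   profile = TRUE)
  prof <- res$profile
  dimnames(prof) <- list(colnames(al$M), NULL)
  list(profiles = profile_frame(prof, nsteps),
       non_unique = flag_non_unique(prof, res$bmd, nsteps,
                                    tol = tol, flat_width = flat_width),
       bmd = res$bmd)
}

#' @export
print.qfasa_fit <- function(x, ...) {
  cat("<qfasa_fit>\n")
  cat("  diet:", paste(sprintf("%s = %.1f%%", names(x$diet), 100 * x$diet),
                       collapse = ", "), "\n")
  cat(sprintf("  bmd: %.2f ug/mg   r^2: %s   grid step: %g\n",
              x$bmd, ifelse(is.na(x$r_squared), "NA",
                            sprintf("%.3f", x$r_squared)), x$step))
  if (!is.null(x$non_unique) && any(x$non_unique)) {
    cat("  WARNING: near-optimal solutions not unique for:",
        paste(names(x$non_unique)[x$non_unique], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot a diet fit
#'
#' `which = "fit"` draws predicted vs observed concentrations, one point
#' per fatty acid, with the identity line; `which = "profile"` draws the
#' per-source uniqueness curves.
#'
#' @param x a `qfasa_fit`.
#' @param which `"fit"` or `"profile"`.
#' @param ... passed on to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.qfasa_fit <- function(x, which = c("fit", "profile"), ...) {
  which <- match.arg(which)
  if (which == "fit") {
    plot(x$observed, x$predicted,
         xlab = "observed (ug/mg)", ylab = "predicted (ug/mg)", ...)
    graphics::abline(0, 1, lty = 2)
    graphics::text(x$observed, x$predicted, names(x$observed),
                   pos = 3, cex = 0.7)
  } else {
    if (is.null(x$profiles)) stop("fit computed without profiles", call. = FALSE)
    sources <- unique(x$profiles$source)
    graphics::matplot(
      matrix(x$profiles$proportion, ncol = length(sources)),
      matrix(x$profiles$min_dev, ncol = length(sources)),
      type = "l", lty = 1, xlab = "proportion of source",
      ylab = "minimum deviation (ug/mg)", ...)
    graphics::legend("topright", legend = sources, lty = 1,
                     col = seq_along(sources), bty = "n")
  }
  invisible(x)
}
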