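# Cohort-level orchestration: per-animal fits, site and pooled summaries,
# negative-control comparison, consumer classification.

# Restrict every signature to the fitting subset and put foods and fat on
# a common subset total (the animal's own observed subset total). Returns
# one prepared record per consumer: the restricted fat signature and the
# aligned FA-by-source mean matrix.
prepare_cohort <- function(consumers, library, fa_subset = NULL,
                           threshold = 5, site_matched = TRUE) {
  stopifnot(length(consumers) >= 1L,
            all(vapply(consumers, inherits, TRUE, what = "consumer_sample")))
  stopifnot(inherits(library, "source_library"))
  if (is.null(fa_subset)) {
    species <- vapply(consumers, `[[`, "", "species")
    sp_means <- lapply(split(consumers, species), function(group) {
      rowMeans(zero_fill(lapply(group, `[[`, "fat")))
    })
    fa_subset <- select_shared_fas(sp_means, threshold = threshold)
  }
  sites <- library_sites(library)
  lapply(consumers, function(cs) {
    if (site_matched && !(cs$site %in% sites)) {
      stop("no food sources in library for site ", sQuote(cs$site),
           " (animal ", cs$animal_id, "); use site_matched = FALSE to pool",
           call. = FALSE)
    }
    M <- library_means(library, site = if (site_matched) cs$site else NULL)
    fat <- restrict_and_rescale(cs$fat, fa_subset,
                                target_total = sum(cs$fat[intersect(fa_subset, names(cs$fat))]))
    total <- sum(fat)
    Msub <- vapply(colnames(M), function(src) {
      restrict_and_rescale(M[, src], fa_subset, target_total = total)
    }, numeric(length(fa_subset)))
    Msub <- matrix(Msub, nrow = length(fa_subset),
                   dimnames = list(sort_fa(fa_subset), colnames(M)))
    list(consumer = cs, fat = fat, means = Msub)
  })
}

#' Fit a whole consumer cohort and summarize by site
#'
#' Runs [fit_diet()] for every animal against its own site's food means
#' (or pooled means), then aggregates: per-animal diet percentages, BMD and
#' r-squared; per-site mean and sd of each source percentage and mean BMD;
#' and a pooled across-site summary weighted by the number of animals per
#' site.
#'
#' @param consumers list of [consumer_sample()] objects.
#' @param library a [source_library()].
#' @param cc calibration vector (default all 1).
#' @param step simplex grid resolution.
#' @param fa_subset fatty-acid subset to fit on; default: derived from the
#'   cohort's species mean signatures via [select_shared_fas()].
#' @param threshold abundance threshold (ug/mg) for the default subset rule.
#' @param site_matched fit each animal against its own site's food means
#'   (default) or pooled across-site means.
#' @param rescale see [fit_diet()].
#' @return An object of class `cohort_report`: list with data.frames
#'   `per_animal`, `per_site`, `pooled`, plus `sources`, `fa_subset`,
#'   `fits` (the individual `qfasa_fit` objects, named by animal id).
#' @export
fit_cohort <- function(consumers, library, cc = NULL, step = 0.01,
                       fa_subset = NULL, threshold = 5,
                       site_matched = TRUE, rescale = TRUE) {
  prep <- prepare_cohort(consumers, library, fa_subset = fa_subset,
                         threshold = threshold, site_matched = site_matched)
  fits <- lapply(prep, function(p) {
    fit_diet(p$fat, p$means, cc = cc, step = step, rescale = rescale)
  })
  names(fits) <- vapply(prep, function(p) p$consumer$animal_id, "")
  sources <- names(fits[[1L]]$diet)
  per_animal <- do.call(rbind, Map(function(p, f) {
    row <- data.frame(animal_id = p$consumer$animal_id,
                      species = p$consumer$species,
                      site = p$consumer$site,
                      stringsAsFactors = FALSE)
    for (s in sources) row[[s]] <- 100 * f$diet[[s]]
    row$bmd <- f$bmd
    row$r_squared <- f$r_squared
    row
  }, prep, fits))
  rownames(per_animal) <- NULL

  per_site <- do.call(rbind, lapply(split(per_animal, per_animal$site), function(d) {
    row <- data.frame(site = d$site[1L], n = nrow(d), stringsAsFactors = FALSE)
    for (s in sources) {
      row[[paste0(s, "_mean")]] <- mean(d[[s]])
      row[[paste0(s, "_sd")]] <- if (nrow(d) > 1L) stats::sd(d[[s]]) else 0
    }
    row$bmd_mean <- mean(d$bmd)
    row
  }))
  per_site <- per_site[order(match(per_site$site, unique(per_animal$site))), ]
  rownames(per_site) <- NULL

  pooled <- data.frame(source = sources, stringsAsFactors = FALSE)
  pooled$pct <- vapply(sources, function(s) {
    pooled_weighted_mean(per_site[[paste0(s, "_mean")]], per_site$n)
  }, 1)
  structure(list(per_animal = per_animal, per_site = per_site,
                 pooled = pooled, sources = sources,
                 fa_subset = sort_fa(rownames(prep[[1L]]$means)),
                 step = step, site_matched = site_matched, fits = fits),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, digits = 1, ...) {
  cat(sprintf("<cohort_report> %d animals, %d sites, sources: %s\n",
              nrow(x$per_animal), nrow(x$per_site),
              paste(x$sources, collapse = ", ")))
  cat("per-site means (% of fatty acids from each source):\n")
  print(format(x$per_site, digits = digits + 2), ...)
  cat("pooled (weighted by site n):\n")
  print(transform(x$pooled, pct = round(pct, digits)), ...)
  invisible(x)
}

#' Sample-size-weighted mean of site means
#'
#' Recovers the across-animal mean from per-site means and sample sizes:
#' \eqn{\sum_s n_s m_s / \sum_s n_s}.
#'
#' @param site_means numeric vector of site means (e.g. percentages).
#' @param n number of animals per site.
#' @return The weighted mean.
#' @examples
#' pooled_weighted_mean(c(12.8, 20.4, 26.2), c(8, 7, 5))  # 18.8
#' @export
pooled_weighted_mean <- function(site_means, n) {
  if (length(site_means) == 0L) stop("no site means supplied", call. = FALSE)
  stopifnot(length(site_means) == length(n), all(n >= 1))
  sum(n * site_means) / sum(n)
}

#' Compare target and negative-control model deviations
#'
#' Two-sample t-test of best-model deviations between the target consumers
#' (animals presumed to eat the candidate foods) and negative controls
#' (animals known not to). A credible diet reconstruction requires control
#' deviations to be much larger. Welch's unequal-variance test is the
#' default; Student's pooled-variance test is available.
#'
#' @param bmd_target,bmd_control numeric vectors of per-animal BMDs (>= 2
#'   values each).
#' @param flavor `"welch"` (default) or `"student"`.
#' @return List with `t`, `p`, `mean_target`, `mean_control`, `df` and the
#'   underlying `htest` object.
#' @export
negative_control_compare <- function(bmd_target, bmd_control,
                                     flavor = c("welch", "student")) {
  flavor <- match.arg(flavor)
  if (length(bmd_target) < 2L || length(bmd_control) < 2L) {
    stop("need at least 2 deviations per group", call. = FALSE)
  }
  ht <- stats::t.test(bmd_target, bmd_control,
                      var.equal = (flavor == "student"))
  list(t = unname(ht$statistic), p = ht$p.value,
       mean_target = mean(bmd_target), mean_control = mean(bmd_control),
       df = unname(ht$parameter), htest = ht)
}

#' Classify consumers by fitted contribution of one source
#'
#' Counts the animals whose fitted percentage for `source` strictly exceeds
#' `threshold` (default 10%), and bins the full distribution to expose
#' bimodality (default bins: 0-5, 5-10, 10-50, 50-100%).
#'
#' @param report a [fit_cohort()] result.
#' @param source food-source name.
#' @param threshold classification threshold in percent (strict `>`).
#' @param bins bin breaks in percent for the distribution summary.
#' @return List with `count`, `total`, `fraction` and `bins` (a table of
#'   counts per bin).
#' @export
classify_consumers <- function(report, source, threshold = 10,
                               bins = c(0, 5, 10, 50, 100)) {
  stopifnot(inherits(report, "cohort_report"))
  if (!source %in% report$sources) {
    stop("unknown source ", sQuote(source), call. = FALSE)
  }
  pct <- report$per_animal[[source]]
  count <- sum(pct > threshold)
  binned <- table(cut(pct, breaks = bins, right = FALSE, include.lowest = TRUE))
  list(count = count, total = length(pct), fraction = count / length(pct),
       bins = binned)
}
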