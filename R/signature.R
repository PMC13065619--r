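#' Validate a fatty-acid signature
#'
#' A signature is a named numeric vector mapping fatty-acid labels to
#' concentrations in micrograms of fatty acid per milligram of sample
#' (ug/mg). All concentrations must be finite and non-negative and at least
#' one must be positive. The returned vector is in canonical label order
#' (see [fa_order()]).
#'
#' @param x named numeric vector (names are fatty-acid labels).
#' @return The validated signature, canonically ordered.
#' @examples
#' as_signature(c("16:0" = 285, "12:0" = 61.7))
#' @export
as_signature <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("signature values must be named by fatty-acid label", call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop("duplicate fatty-acid labels in signature: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  }
  x <- stats::setNames(as.numeric(x), parse_fa_label(names(x))$label)
  if (any(!is.finite(x)) || any(x < 0)) {
    bad <- names(x)[!is.finite(x) | x < 0]
    stop("negative or non-finite concentration for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (all(x == 0)) stop("signature has no positive concentration", call. = FALSE)
  x[fa_order(names(x))]
}

# Zero-fill a list of signatures onto the union of their labels,
# returning a matrix with FAs as rows (canonical order) and one column
# per signature.
zero_fill <- function(sigs) {
  labels <- sort_fa(unique(unlist(lapply(sigs, names))))
  m <- vapply(sigs, function(s) {
    out <- stats::setNames(numeric(length(labels)), labels)
    out[names(s)] <- s
    out
  }, numeric(length(labels)))
  matrix(m, nrow = length(labels), dimnames = list(labels, names(sigs)))
}

#' Replicate sample set for one food source at one site
#'
#' Groups replicate fatty-acid signatures of a single food source (e.g.
#' grass, roots, yak feces) collected at one site. Replicates are
#' zero-filled onto the union of their fatty-acid labels: an acid measured
#' in some replicates but absent from others is a true zero there.
#'
#' @param source food-source name.
#' @param site site name.
#' @param replicates list of signatures (see [as_signature()]), or a matrix
#'   with fatty-acid labels as row names and one column per replicate.
#' @return An object of class `source_sample_set` with elements `source`,
#'   `site` and `replicates` (FA-by-replicate matrix).
#' @export
source_sample_set <- function(source, site, replicates) {
  if (is.matrix(replicates)) {
    replicates <- lapply(seq_len(ncol(replicates)),
                         function(j) replicates[, j])
  }
  if (length(replicates) < 1L) stop("no samples", call. = FALSE)
  replicates <- lapply(replicates, as_signature)
  mat <- zero_fill(replicates)
  colnames(mat) <- sprintf("%s_%s_%d", source, site, seq_len(ncol(mat)))
  structure(list(source = as.character(source), site = as.character(site),
                 replicates = mat),
            class = "source_sample_set")
}

#' @export
print.source_sample_set <- function(x, ...) {
  cat(sprintf("<source_sample_set> %s @ %s: %d replicates, %d fatty acids\n",
              x$source, x$site, ncol(x$replicates), nrow(x$replicates)))
  invisible(x)
}

#' Mean signature of a replicate set
#'
#' Per-fatty-acid arithmetic mean across the replicates of a
#' [source_sample_set()].
#'
#' @param samples a `source_sample_set`.
#' @return A signature (named numeric vector, ug/mg).
#' @export
mean_signature <- function(samples) {
  stopifnot(inherits(samples, "source_sample_set"))
  if (ncol(samples$replicates) < 1L) stop("no samples", call. = FALSE)
  rowMeans(samples$replicates)
}

#' Coefficient-of-variation profile of a replicate set
#'
#' Per-fatty-acid sd/mean across replicates (sample sd, n - 1 denominator).
#' Food-source replicates in this system are typically very consistent
#' within a site (cv around 2-5%). Fatty acids with zero mean have an
#' undefined cv and are reported as `NA`.
#'
#' @param samples a `source_sample_set` with at least 2 replicates.
#' @return Named numeric vector of cv values (dimensionless), `NA` where the
#'   mean is zero.
#' @export
cv_profile <- function(samples) {
  stopifnot(inherits(samples, "source_sample_set"))
  if (ncol(samples$replicates) < 2L) {
    stop("cv undefined: need at least 2 replicates", call. = FALSE)
  }
  mu <- rowMeans(samples$replicates)
  s <- apply(samples$replicates, 1L, stats::sd)
  cv <- ifelse(mu > 0, s / mu, NA_real_)
  stats::setNames(cv, rownames(samples$replicates))
}

#' Select fatty acids shared at high abundance across consumer species
#'
#' Diet fitting is restricted to fatty acids that are well represented in
#' stored fat. This applies the abundance rule: keep every fatty acid whose
#' unweighted arithmetic mean across the supplied species mean-signatures
#' strictly exceeds `threshold` (default 5.0 ug/mg). On the bundled pika and
#' mouse fat means this selects the ten acids 12:0, 14:0, 15:0, 16:0, 16:1,
#' 17:0, 18:0, 18:1, 18:2 and 18:3n3.
#'
#' @param consumer_means list of mean signatures (one per consumer species).
#' @param threshold abundance threshold in ug/mg (strict inequality).
#' @return Character vector of selected labels in canonical order.
#' @export
select_shared_fas <- function(consumer_means, threshold = 5) {
  if (length(consumer_means) < 1L) stop("no consumer means supplied", call. = FALSE)
  stopifnot(threshold >= 0)
  mat <- zero_fill(lapply(consumer_means, as_signature))
  keep <- rowMeans(mat) > threshold
  if (!any(keep)) stop("no FAs pass threshold", call. = FALSE)
  rownames(mat)[keep]
}

#' Restrict a signature to a fatty-acid subset and rescale its total
#'
#' Keeps only the fatty acids in `subset` (absent ones count as zero) and
#' linearly rescales so the restricted signature sums to `target_total`.
#' Relative composition is preserved. Food and fat signatures are put on a
#' common subset total before fitting so that deviations are comparable in
#' ug/mg.
#'
#' @param sig a signature.
#' @param subset character vector of fatty-acid labels (non-empty).
#' @param target_total positive total (ug/mg) for the restricted signature.
#' @return A signature over `subset` (canonical order) summing to
#'   `target_total`.
#' @export
restrict_and_rescale <- function(sig, subset, target_total) {
  sig <- as_signature(sig)
  subset <- parse_fa_label(subset)$label
  if (length(subset) < 1L) stop("empty fatty-acid subset", call. = FALSE)
  stopifnot(is.numeric(target_total), target_total > 0)
  out <- stats::setNames(numeric(length(subset)), subset)
  hit <- intersect(subset, names(sig))
  out[hit] <- sig[hit]
  tot <- sum(out)
  if (tot <= 0) stop("signature has zero total over the requested subset",
                     call. = FALSE)
  out <- out * (target_total / tot)
  out[fa_order(names(out))]
}

#' Library of food-source replicate sets
#'
#' A collection of [source_sample_set()] objects covering each food source
#' at each site.
#'
#' @param sets list of `source_sample_set` objects.
#' @return An object of class `source_library`.
#' @export
source_library <- function(sets) {
  if (length(sets) < 1L) stop("no samples", call. = FALSE)
  ok <- vapply(sets, inherits, TRUE, what = "source_sample_set")
  stopifnot(all(ok))
  key <- vapply(sets, function(s) paste(s$source, s$site, sep = "@"), "")
  if (anyDuplicated(key)) {
    stop("duplicate source/site combination: ",
         paste(key[duplicated(key)], collapse = ", "), call. = FALSE)
  }
  structure(list(sets = stats::setNames(sets, key)), class = "source_library")
}

#' @export
print.source_library <- function(x, ...) {
  cat(sprintf("<source_library> %d source/site sets: %s\n",
              length(x$sets), paste(names(x$sets), collapse = ", ")))
  invisible(x)
}

#' @rdname source_library
#' @param library a `source_library`.
#' @export
library_sites <- function(library) {
  unique(vapply(library$sets, `[[`, "", "site"))
}

#' @rdname source_library
#' @export
library_sources <- function(library) {
  unique(vapply(library$sets, `[[`, "", "source"))
}

#' Per-site (or pooled) mean food signatures
#'
#' @param library a [source_library()].
#' @param site site name, or `NULL` to pool replicates across all sites.
#' @return Matrix with fatty acids as rows (canonical order, zero-filled)
#'   and one column per food source, entries in ug/mg.
#' @export
library_means <- function(library, site = NULL) {
  stopifnot(inherits(library, "source_library"))
  sets <- library$sets
  if (!is.null(site)) {
    sets <- Filter(function(s) s$site == site, sets)
    if (length(sets) == 0L) {
      stop("no food sources in library for site ", sQuote(site), call. = FALSE)
    }
  }
  srcs <- unique(vapply(sets, `[[`, "", "source"))
  means <- lapply(srcs, function(sn) {
    reps <- unlist(lapply(Filter(function(s) s$source == sn, sets),
                          function(s) lapply(seq_len(ncol(s$replicates)),
                                             function(j) s$replicates[, j])),
                   recursive = FALSE)
    rowMeans(zero_fill(reps))
  })
  names(means) <- srcs
  zero_fill(means)
}

#' Consumer adipose sample
#'
#' One animal's stored-fat fatty-acid signature with its identifiers.
#'
#' @param animal_id animal identifier.
#' @param species species name.
#' @param site site name.
#' @param fat a signature (see [as_signature()]).
#' @return An object of class `consumer_sample`.
#' @export
consumer_sample <- function(animal_id, species, site, fat) {
  structure(list(animal_id = as.character(animal_id),
                 species = as.character(species),
                 site = as.character(site),
                 fat = as_signature(fat)),
            class = "consumer_sample")
}

#' @export
print.consumer_sample <- function(x, ...) {
  cat(sprintf("<consumer_sample> %s (%s @ %s): %d fatty acids, total %.1f ug/mg\n",
              x$animal_id, x$species, x$site, length(x$fat), sum(x$fat)))
  invisible(x)
}
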