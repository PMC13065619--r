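#' Bundled reference tables for the plateau-pika study system
#'
#' The package ships two small plain-text reference tables for the
#' Qinghai-Tibetan plateau study system in which QFASA was applied to
#' winter coprophagy by plateau pika:
#'
#' * `example_food_means()` - mean and sd (8 field replicates) of the
#'   fatty-acid signatures of three candidate winter foods (grass, roots,
#'   yak feces) at three elevation sites (low, medium, high), in ug
#'   fatty acid per mg sample.
#' * `example_fat_means()` - species-average adipose fatty-acid signatures
#'   of the plateau pika (n = 20) and of laboratory mice (n = 5) that never
#'   ate any of the candidate foods; the mouse column is the negative
#'   control.
#'
#' These tables seed the synthetic-data generator defaults and the worked
#' examples; they are species/site means, not per-animal raw data.
#'
#' @return `example_food_means()`: data.frame with columns `source`, `site`,
#'   `fa`, `mean_ug_mg`, `sd_ug_mg`. `example_fat_means()`: named list of
#'   signatures, one per species.
#' @examples
#' head(example_food_means())
#' names(example_fat_means())
#' @export
example_food_means <- function() {
  path <- system.file("extdata", "food_source_means.csv",
                      package = "qfasadiet", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname example_food_means
#' @export
example_fat_means <- function() {
  path <- system.file("extdata", "consumer_fat_means.csv",
                      package = "qfasadiet", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$species), function(d) {
    as_signature(stats::setNames(d$mean_ug_mg, d$fa))
  })
}

#' Mean food signatures by site from the bundled reference table
#'
#' Convenience wrapper turning [example_food_means()] into the
#' fatty-acid-by-source matrix expected by [fit_diet()].
#'
#' @param site `"low"`, `"medium"` or `"high"`, or `NULL` to average the
#'   three site means per source.
#' @return Matrix of mean concentrations (ug/mg), fatty acids as rows in
#'   canonical order, one column per food source.
#' @export
example_source_means <- function(site = NULL) {
  df <- example_food_means()
  if (!is.null(site)) {
    stopifnot(site %in% unique(df$site))
    df <- df[df$site == site, ]
    agg <- df
  } else {
    agg <- stats::aggregate(mean_ug_mg ~ source + fa, data = df, FUN = mean)
  }
  sigs <- lapply(split(agg, agg$source), function(d) {
    as_signature(stats::setNames(d$mean_ug_mg, d$fa))
  })
  zero_fill(sigs)
}
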