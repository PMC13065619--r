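#' Parse fatty-acid labels
#'
#' Fatty acids are named in carbon:double-bond nomenclature, e.g. `"16:0"`,
#' `"18:1"`, `"18:3n3"`. An optional `n<k>` (or `n-<k>`) suffix gives the
#' omega series of the first double bond.
#'
#' @param labels character vector of fatty-acid labels.
#' @return A data.frame with columns `label`, `carbon`, `double_bonds` and
#'   `series` (`NA` when no omega-series suffix is present). Labels are
#'   normalized so `"18:3n-3"` and `"18:3n3"` are the same acid.
#' @examples
#' parse_fa_label(c("16:0", "18:3n3"))
#' @export
parse_fa_label <- function(labels) {
  labels <- as.character(labels)
  m <- regmatches(labels, regexec("^([0-9]+):([0-9]+)(?:n-?([0-9]+))?$", labels))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("unparseable fatty-acid label(s): ",
         paste(sQuote(labels[bad]), collapse = ", "), call. = FALSE)
  }
  carbon <- vapply(m, function(x) as.integer(x[2]), 1L)
  dbl <- vapply(m, function(x) as.integer(x[3]), 1L)
  series <- vapply(m, function(x) if (x[4] == "") NA_integer_ else as.integer(x[4]), 1L)
  norm <- ifelse(is.na(series),
                 paste0(carbon, ":", dbl),
                 paste0(carbon, ":", dbl, "n", series))
  data.frame(label = norm, carbon = carbon, double_bonds = dbl,
             series = series, stringsAsFactors = FALSE)
}

#' Canonical fatty-acid ordering
#'
#' Orders labels by ascending carbon chain length, then ascending number of
#' double bonds, then omega series (unsuffixed labels first). All tabular
#' outputs of the package use this ordering so results are deterministic.
#'
#' @param labels character vector of fatty-acid labels.
#' @return `fa_order()` returns an integer permutation (as [order()]);
#'   `sort_fa()` returns the sorted labels.
#' @examples
#' sort_fa(c("18:1", "12:0", "18:3n3", "16:0"))
#' @export
fa_order <- function(labels) {
  p <- parse_fa_label(labels)
  order(p$carbon, p$double_bonds, !is.na(p$series), p$series)
}

#' @rdname fa_order
#' @export
sort_fa <- function(labels) {
  as.character(labels)[fa_order(labels)]
}

is_fa_label <- function(labels) {
  grepl("^[0-9]+:[0-9]+(n-?[0-9]+)?$", as.character(labels))
}
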