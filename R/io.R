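#' Read a fatty-acid signature table from CSV
#'
#' Accepts two plain-CSV dialects (UTF-8, `.` decimal separator):
#'
#' * long: columns `sample_id, group, site, fa_label, ug_per_mg`, one row
#'   per (sample, fatty acid);
#' * wide: columns `sample_id, group, site` followed by one column per
#'   fatty-acid label.
#'
#' `group` is the food-source name when `kind = "source"` and the species
#' when `kind = "consumer"`. Fatty acids absent from a sample are filled in
#' as concentration 0 (a true structural zero for acids a source does not
#' contain).
#'
#' @param path CSV file path.
#' @param kind `"source"` for food replicates, `"consumer"` for adipose
#'   samples.
#' @param format `"auto"` (default), `"long"` or `"wide"`.
#' @return For `kind = "source"`, a [source_library()]; for
#'   `kind = "consumer"`, a list of [consumer_sample()] objects.
#' @export
read_signature_table <- function(path, kind = c("source", "consumer"),
                                 format = c("auto", "long", "wide")) {
  kind <- match.arg(kind)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no samples in ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (all(c("fa_label", "ug_per_mg") %in% names(df))) "long" else "wide"
  }
  long <- if (format == "long") {
    need <- c("sample_id", "group", "site", "fa_label", "ug_per_mg")
    if (!all(need %in% names(df))) {
      stop("long-format CSV must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    df[need]
  } else {
    meta <- c("sample_id", "group", "site")
    if (!all(meta %in% names(df))) {
      stop("wide-format CSV must have columns ", paste(meta, collapse = ", "),
           " followed by fatty-acid columns", call. = FALSE)
    }
    fa_cols <- setdiff(names(df), meta)
    if (length(fa_cols) == 0L) stop("no fatty-acid columns in ", path, call. = FALSE)
    data.frame(
      sample_id = rep(df$sample_id, times = length(fa_cols)),
      group = rep(df$group, times = length(fa_cols)),
      site = rep(df$site, times = length(fa_cols)),
      fa_label = rep(fa_cols, each = nrow(df)),
      ug_per_mg = unlist(df[fa_cols], use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  bad_label <- !is_fa_label(long$fa_label)
  if (any(bad_label)) {
    stop("unparseable fatty-acid label(s) in ", path, ": ",
         paste(sQuote(unique(long$fa_label[bad_label])), collapse = ", "),
         call. = FALSE)
  }
  long$fa_label <- parse_fa_label(long$fa_label)$label
  neg <- !is.finite(long$ug_per_mg) | long$ug_per_mg < 0
  if (any(neg)) {
    i <- which(neg)[1L]
    stop(sprintf(
      "negative or non-numeric concentration in %s (sample %s, fatty acid %s)",
      path, long$sample_id[i], long$fa_label[i]), call. = FALSE)
  }
  dup <- duplicated(long[c("sample_id", "fa_label")])
  if (any(dup)) {
    i <- which(dup)[1L]
    stop(sprintf("duplicate fatty-acid label %s for sample %s in %s",
                 long$fa_label[i], long$sample_id[i], path), call. = FALSE)
  }

  sig_of <- function(rows) stats::setNames(rows$ug_per_mg, rows$fa_label)
  if (kind == "source") {
    keys <- unique(long[c("group", "site")])
    sets <- lapply(seq_len(nrow(keys)), function(i) {
      rows <- long[long$group == keys$group[i] & long$site == keys$site[i], ]
      reps <- lapply(split(rows, rows$sample_id), sig_of)
      source_sample_set(keys$group[i], keys$site[i], reps)
    })
    source_library(sets)
  } else {
    ids <- unique(long$sample_id)
    lapply(ids, function(id) {
      rows <- long[long$sample_id == id, ]
      consumer_sample(id, rows$group[1L], rows$site[1L], sig_of(rows))
    })
  }
}

#' Write signatures to a tidy long-format CSV
#'
#' Inverse of [read_signature_table()]'s long dialect.
#'
#' @param x a [source_library()] or a list of [consumer_sample()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_signature_table <- function(x, path) {
  rows <- if (inherits(x, "source_library")) {
    do.call(rbind, lapply(x$sets, function(s) {
      do.call(rbind, lapply(seq_len(ncol(s$replicates)), function(j) {
        data.frame(sample_id = colnames(s$replicates)[j],
                   group = s$source, site = s$site,
                   fa_label = rownames(s$replicates),
                   ug_per_mg = s$replicates[, j],
                   stringsAsFactors = FALSE)
      }))
    }))
  } else {
    stopifnot(all(vapply(x, inherits, TRUE, what = "consumer_sample")))
    do.call(rbind, lapply(x, function(cs) {
      data.frame(sample_id = cs$animal_id, group = cs$species, site = cs$site,
                 fa_label = names(cs$fat), ug_per_mg = unname(cs$fat),
                 stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
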