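# Native on-disk container: one directory per recording holding
# manifest.json (format version, metadata, channel manifest) plus one
# single-column CSV per channel. Text-based by design so recordings can be
# inspected and diffed; sample values round-trip to <= 1e-12 relative.

FORMAT_VERSION <- "1.0"

#' Write a recording to its native directory container
#'
#' @param rec a [wbp_recording()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "wbp_recording"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory '", path, "'")
  }
  manifest <- list(
    format_version = FORMAT_VERSION,
    meta = rec$meta,
    channels = lapply(unname(rec$channels), function(ch) {
      list(name = ch$name, role = ch$role, unit = ch$unit,
           sample_rate = ch$sample_rate, n_samples = length(ch$samples),
           file = paste0(ch$role, ".csv"))
    })
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (ch in rec$channels) {
    data.table::fwrite(data.table::data.table(value = ch$samples),
                       file.path(path, paste0(ch$role, ".csv")))
  }
  invisible(path)
}

#' Read a recording from its native directory container
#'
#' Channels with roles this package does not know are preserved with role
#' `"other"`. A manifest/sample-count mismatch raises an integrity error; a
#' missing required manifest field raises a schema error naming the field.
#'
#' @param path directory written by [write_recording()].
#' @return a [wbp_recording()].
#' @export
read_recording <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under '", path, "'")
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  ver <- manifest$format_version
  if (is.null(ver)) stop("schema error: manifest missing field 'format_version'")
  ver_parts <- as.integer(strsplit(ver, ".", fixed = TRUE)[[1]])
  cur_parts <- as.integer(strsplit(FORMAT_VERSION, ".", fixed = TRUE)[[1]])
  if (ver_parts[1] != cur_parts[1] || ver_parts[2] > cur_parts[2]) {
    stop("unsupported container format version '", ver, "'")
  }
  if (is.null(manifest$channels)) stop("schema error: manifest missing field 'channels'")
  channels <- lapply(manifest$channels, function(cm) {
    for (f in c("role", "unit", "sample_rate", "n_samples", "file")) {
      if (is.null(cm[[f]])) stop("schema error: channel entry missing field '", f, "'")
    }
    fp <- file.path(path, cm$file)
    if (!file.exists(fp)) stop("integrity error: channel file '", cm$file, "' missing")
    x <- data.table::fread(fp)$value
    if (length(x) != cm$n_samples) {
      stop("integrity error: channel '", cm$role, "' has ", length(x),
           " samples, manifest says ", cm$n_samples)
    }
    suppressWarnings(ts_channel(x, cm$role, cm$unit, cm$sample_rate,
                                name = cm$name %||% cm$role))
  })
  names(channels) <- vapply(manifest$channels, function(cm) cm$role, "")
  meta <- lapply(manifest$meta, function(x) if (is.list(x)) unlist(x) else x)
  if (!is.null(manifest$meta$co2_protocol)) {
    meta$co2_protocol <- lapply(manifest$meta$co2_protocol, unlist)
  }
  wbp_recording(channels, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write derived tables
#'
#' Delimited-table writers for the derived products of the pipeline. An
#' empty table writes a header-only file.
#'
#' @param breaths,events data frames as produced by the pipeline.
#' @param path output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_breath_table <- function(breaths, path) {
  data.table::fwrite(breaths, path)
  invisible(path)
}

#' @rdname write_breath_table
#' @export
write_events <- function(events, path) {
  if (nrow(events) == 0 && ncol(events) == 0) {
    events <- data.frame(kind = character(), t_start = numeric(),
                         duration = numeric(), stage = character(),
                         magnitude = numeric())
  }
  data.table::fwrite(events, path)
  invisible(path)
}

#' Write / read a hypnogram as a two-column table
#'
#' Exchange format: `epoch_start_s, stage`, one row per 5-s epoch.
#'
#' @param hyp a [hypnogram()].
#' @param path CSV path.
#' @return `path` (write) or a [hypnogram()] (read).
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "wbp_hypnogram"))
  tab <- data.frame(
    epoch_start_s = (seq_along(hyp$stages) - 1) * hyp$epoch_len,
    stage = hyp$stages
  )
  data.table::fwrite(tab, path)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  tab <- data.table::fread(path)
  if (nrow(tab) < 2) stop("hypnogram table needs >= 2 epochs")
  epoch_len <- tab$epoch_start_s[2] - tab$epoch_start_s[1]
  hypnogram(as.character(tab$stage), epoch_len = epoch_len, source = "external")
}
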