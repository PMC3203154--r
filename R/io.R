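# Delimited-text recordings and JSON result records.
#
# A recording is a rectangular table (one column per channel, header row
# of channel labels, CSV or TSV by extension) with the sampling rate in a
# JSON sidecar `<path>.json` or in a commented first line
# `# sampling_rate: <Hz>`.  Results round-trip through JSON at full double
# precision.

sidecar_path <- function(path) paste0(path, ".json")

#' Read a multichannel recording from delimited text
#'
#' @param path CSV (`,`) or TSV (tab; any non-`.csv` extension) file whose
#'   header row carries the channel labels.  The sampling rate is read
#'   from `<path>.json` (keys `sampling_rate`, optionally `units`) or from
#'   a leading comment line `# sampling_rate: <Hz>`.
#' @return A [multichannel_series()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) {
    mdfa_stop(sprintf("recording file not found: %s", path), "mdfa_io_error")
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L)
  sampling_rate <- NULL
  skip <- 0L
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("sampling_rate[:= ]+([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2L) sampling_rate <- as.numeric(m[2])
    skip <- 1L
  }
  sc <- sidecar_path(path)
  if (is.null(sampling_rate) && file.exists(sc)) {
    meta <- jsonlite::fromJSON(sc)
    if (!is.null(meta$sampling_rate)) sampling_rate <- as.numeric(meta$sampling_rate)
  }
  if (is.null(sampling_rate) || !is.finite(sampling_rate) || sampling_rate <= 0) {
    mdfa_stop(sprintf(
      "no sampling rate for %s: provide %s or a '# sampling_rate: <Hz>' header line",
      path, sc), "mdfa_io_error")
  }
  dt <- data.table::fread(path, sep = sep, header = TRUE, skip = skip,
                          colClasses = "character", data.table = FALSE)
  if (ncol(dt) < 1L || nrow(dt) < 1L) {
    mdfa_stop(sprintf("empty recording table in %s", path), "mdfa_io_error")
  }
  labels <- colnames(dt)
  vals <- matrix(NA_real_, nrow(dt), ncol(dt))
  for (j in seq_len(ncol(dt))) {
    v <- suppressWarnings(as.numeric(dt[[j]]))
    bad <- which(is.na(v) & !(dt[[j]] %in% c("NA", "")))
    na_in <- which(dt[[j]] %in% c("NA", ""))
    if (length(bad) > 0L) {
      mdfa_stop(sprintf("non-numeric cell in %s at data row %d, column '%s' (value '%s')",
                        path, bad[1], labels[j], dt[[j]][bad[1]]),
                "mdfa_io_error")
    }
    if (length(na_in) > 0L) {
      mdfa_stop(sprintf("missing value in %s at data row %d, column '%s'",
                        path, na_in[1], labels[j]), "mdfa_io_error")
    }
    vals[, j] <- v
  }
  multichannel_series(vals, sampling_rate, labels)
}

#' Write a multichannel recording as delimited text
#'
#' Full-precision values; a JSON sidecar `<path>.json` stores the sampling
#' rate, labels, and units so [read_recording()] round-trips exactly.
#'
#' @param mc A [multichannel_series()].
#' @param path Output file (`.csv` for commas, anything else tab).
#' @param units Unit string recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_recording <- function(mc, path, units = "uV") {
  stopifnot(inherits(mc, "mdfa_mc"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # 17 significant digits guarantee a value-exact read-back of doubles
  df <- as.data.frame(lapply(seq_len(ncol(mc$values)), function(j) {
    sprintf("%.17g", mc$values[, j])
  }))
  colnames(df) <- mc$labels
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
  jsonlite::write_json(list(sampling_rate = mc$sampling_rate,
                            labels = mc$labels, units = units,
                            n_samples = nrow(mc$values)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assemble a result record
#'
#' The uniform reporting container: what analysis ran, on which channels,
#' with which configuration, and the resulting fluctuation curve and
#' scaling fit.  Every reported exponent must carry its R^2 and fit range.
#'
#' @param kind One of `"dfa"`, `"mdfa"`, `"coherence"`, `"compare"`.
#' @param channels Channel labels used.
#' @param config Named list echoing the run configuration (order, schedule,
#'   n_range, seeds, ...).
#' @param curve Optional [fluctuation_curve()].
#' @param fit Optional [fit_scaling()] result; required for `"dfa"`/`"mdfa"`.
#' @param extra Optional named list of additional payload (e.g. a coherence
#'   spectrum or comparison).
#' @return An object of class `result_record`.
#' @export
result_record <- function(kind, channels, config = list(), curve = NULL,
                          fit = NULL, extra = NULL) {
  kind <- match.arg(kind, c("dfa", "mdfa", "coherence", "compare"))
  if (kind %in% c("dfa", "mdfa")) {
    if (is.null(fit) || is.null(fit$r_squared) || is.null(fit$n_range)) {
      mdfa_stop("dfa/mdfa result records require a fit with r_squared and n_range",
                "mdfa_schema_error")
    }
  }
  structure(list(kind = kind, channels = as.character(channels),
                 config = config,
                 curve = if (!is.null(curve)) unclass(curve),
                 fit = if (!is.null(fit)) unclass(fit),
                 extra = extra,
                 version = as.character(utils::packageVersion("mdfa")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "result_record")
}

#' Write a result record to JSON
#'
#' Numbers are serialized at full double precision so a read-back is
#' value-exact.
#'
#' @param record A [result_record()].
#' @param path Output JSON path.
#' @param curve_tsv Optional path for the curve as two-column
#'   (box size, fluctuation) tab-separated text.
#' @return `path`, invisibly.
#' @export
write_result <- function(record, path, curve_tsv = NULL) {
  stopifnot(inherits(record, "result_record"))
  if (record$kind %in% c("dfa", "mdfa") && is.null(record$fit$r_squared)) {
    mdfa_stop("result record is missing r_squared", "mdfa_schema_error")
  }
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(curve_tsv) && !is.null(record$curve)) {
    data.table::fwrite(data.frame(box_size = record$curve$box_sizes,
                                  fluctuation = record$curve$fluctuations),
                       curve_tsv, sep = "\t")
  }
  invisible(path)
}

#' Read a result record back from JSON
#'
#' @param path JSON file written by [write_result()].
#' @return A `result_record`.
#' @export
read_result <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(rec$kind) ||
      (rec$kind %in% c("dfa", "mdfa") && is.null(rec$fit$r_squared))) {
    mdfa_stop(sprintf("invalid result record in %s", path), "mdfa_schema_error")
  }
  structure(rec, class = "result_record")
}
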