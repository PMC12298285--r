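# File formats: photon-trace CSV (one trace per file, header
# `time_ms,counts[,temperature_C]`, metadata in a JSON sidecar) and JSON
# result/calibration records.

.sidecar_path <- function(path) paste0(path, ".json")

#' Read a photon-count trace from CSV
#'
#' Expects a header row \code{time_ms,counts} with an optional
#' \code{temperature_C} column; one trace per file. If a JSON sidecar
#' \code{<path>.json} exists, its metadata (sample id/type, lamp voltage,
#' dilution factor, dark-subtraction flag) is applied; explicit arguments
#' override the sidecar.
#'
#' @param path CSV file path.
#' @param ... Metadata overrides passed to \code{\link{photon_trace}}.
#' @return A \code{\link{photon_trace}}.
#' @export
read_trace <- function(path, ...) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_ms", "counts")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L)
    stop("parse error in ", path, ": no data rows")
  for (col in required) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad) > 0L)
      stop(sprintf("parse error in %s: non-numeric '%s' at data line %d",
                   path, col, bad[1L]))
    df[[col]] <- as.numeric(df[[col]])
  }
  nonmono <- which(diff(df$time_ms) <= 0)
  if (length(nonmono) > 0L)
    stop(sprintf(
      "parse error in %s: time_ms not strictly increasing at data line %d",
      path, nonmono[1L] + 1L))
  meta <- list()
  sc <- .sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  overrides <- list(...)
  meta[names(overrides)] <- overrides
  args <- c(list(times_ms = df$time_ms, counts = df$counts),
            meta[intersect(names(meta),
                           c("sample_type", "sample_id", "lamp_voltage_V",
                             "temperature_C", "dilution_factor",
                             "dark_subtracted"))])
  if (!is.null(df$temperature_C) && is.null(args$temperature_C))
    args$temperature_C <- df$temperature_C[1L]
  do.call(photon_trace, args)
}

#' Write a photon-count trace to CSV with a JSON metadata sidecar
#'
#' Emits the \code{time_ms,counts[,temperature_C]} dialect at full numeric
#' precision, plus a \code{<path>.json} sidecar holding the acquisition
#' metadata so that \code{\link{read_trace}} round-trips the trace exactly.
#'
#' @param trace A \code{\link{photon_trace}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "photon_trace"))
  df <- data.frame(time_ms = trace$times_ms, counts = trace$counts)
  if (!is.na(trace$temperature_C))
    df$temperature_C <- trace$temperature_C
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- trace[c("sample_type", "sample_id", "lamp_voltage_V",
                  "temperature_C", "dilution_factor", "dark_subtracted")]
  jsonlite::write_json(meta, .sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read (activity, rate) calibration pairs from CSV
#'
#' Header \code{activity,rate}: activity as a fraction (1.0 = 100\%), rate
#' in AU/min.
#'
#' @param path CSV file path.
#' @return A data.frame with columns \code{activity}, \code{rate}.
#' @export
read_calibration_pairs <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("activity", "rate") %in% names(df)))
    stop("parse error in ", path, ": need columns activity,rate")
  df$activity <- as.numeric(df$activity)
  df$rate <- as.numeric(df$rate)
  if (any(!is.finite(df$activity)) || any(!is.finite(df$rate)))
    stop("parse error in ", path, ": non-numeric calibration values")
  df
}

#' Serialize a calibration curve to JSON
#' @param curve A \code{calibration_curve}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a calibration curve from JSON
#' @param path JSON path written by \code{\link{write_calibration}}.
#' @return A \code{calibration_curve}.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "calibration_curve")
}

#' Assemble a result record for one sample
#'
#' The per-sample output of the pipeline: identity, dilution, measured
#' dA/min, estimated activity, and the QC flags that were applied.
#' Serializes losslessly via \code{\link{write_results}} /
#' \code{\link{read_results}}.
#'
#' @param trace The processed \code{\link{photon_trace}}.
#' @param rate A \code{rate_result} from \code{\link{compute_rate}}.
#' @param activity An \code{activity_result}, or NULL if no calibration
#'   was applied.
#' @param saturated Saturation QC flag.
#' @param negative_counts Were nonpositive corrected counts observed?
#' @param calibration_id Identifier of the calibration used.
#' @return An object of class \code{result_record}.
#' @export
result_record <- function(trace, rate, activity = NULL,
                          saturated = FALSE, negative_counts = FALSE,
                          calibration_id = NA_character_) {
  stopifnot(inherits(trace, "photon_trace"))
  structure(
    list(sample_id = trace$sample_id,
         sample_type = trace$sample_type,
         dilution_factor = trace$dilution_factor,
         rate_per_min = if (is.null(rate)) NA_real_ else rate$rate_per_min,
         activity_percent = if (is.null(activity)) NA_real_
                            else activity$activity_percent,
         qc_saturated = saturated,
         qc_negative_counts = negative_counts,
         calibration_id = calibration_id,
         software_version = as.character(utils::packageVersion("atquant"))),
    class = "result_record")
}

#' Write result records to JSON
#' @param records A list of \code{result_record}s (or a single one).
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(records, path) {
  if (inherits(records, "result_record")) records <- list(records)
  jsonlite::write_json(lapply(records, unclass), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read result records from JSON
#' @param path JSON path written by \code{\link{write_results}}.
#' @return A list of \code{result_record}s.
#' @export
read_results <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(lst, function(x) structure(x, class = "result_record"))
}
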