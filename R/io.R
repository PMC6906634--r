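# File formats: spike-time CSV, cohort metadata CSV, and the trace container
# (flat float32 binary + JSON header with sampling rate, filter band and
# ground-truth spike times).

#' Write spike times to CSV
#'
#' Dialect: UTF-8, comma separated, header `cell_id,unit_type,time_s`, one
#' event per row, times in seconds to 6 decimals.
#'
#' @param cohort a `cohort`, or a named list `cell_id -> list(ss=, cs=, cn=)`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(cohort, path) {
  trains_by_cell <- if (inherits(cohort, "cohort")) {
    stats::setNames(lapply(cohort, `[[`, "trains"),
                    vapply(cohort, `[[`, character(1), "cell_id"))
  } else cohort
  rows <- list()
  for (cid in names(trains_by_cell)) {
    for (ut in names(trains_by_cell[[cid]])) {
      t <- as.numeric(trains_by_cell[[cid]][[ut]])
      if (length(t))
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = cid, unit_type = ut, time_s = sprintf("%.6f", t))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(cell_id = character(0), unit_type = character(0),
                        time_s = character(0))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spike times from CSV
#'
#' Returns trains grouped by cell and unit type. Times are sorted (with a
#' warning if the file was unsorted) and de-duplicated (warning counts the
#' duplicates); malformed rows are rejected with their line numbers; negative
#' times are an error.
#'
#' @param path CSV path (dialect of [write_spike_csv()]).
#' @param durations optional named vector of recording durations (s) per cell;
#'   when supplied, trains are returned as [spike_train()]s, otherwise as bare
#'   numeric vectors.
#' @return named list `cell_id -> unit_type -> times`.
#' @export
read_spike_csv <- function(path, durations = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    warning("empty spike file: ", path)
    return(list())
  }
  if (!all(c("cell_id", "unit_type", "time_s") %in% names(df)))
    stop_invalid("spike CSV must have columns cell_id, unit_type, time_s")
  t <- suppressWarnings(as.numeric(df$time_s))
  bad <- which(is.na(t) | df$cell_id == "" | df$unit_type == "")
  if (length(bad))
    stop_invalid("malformed spike rows at lines: ",
                 paste(bad + 1L, collapse = ", "))
  if (any(t < 0)) stop_invalid("negative spike times")
  df$time_s <- t
  out <- list()
  for (cid in unique(df$cell_id)) {
    sub <- df[df$cell_id == cid, ]
    out[[cid]] <- list()
    for (ut in unique(sub$unit_type)) {
      tt <- sub$time_s[sub$unit_type == ut]
      if (is.unsorted(tt)) {
        warning("unsorted times for ", cid, "/", ut, "; sorting")
        tt <- sort(tt)
      }
      ndup <- sum(duplicated(tt))
      if (ndup) {
        warning(ndup, " duplicated event(s) removed for ", cid, "/", ut)
        tt <- unique(tt)
      }
      out[[cid]][[ut]] <- if (!is.null(durations) && cid %in% names(durations))
        spike_train(tt, durations[[cid]]) else tt
    }
  }
  out
}

#' Write cohort metadata to CSV
#' @param cohort a `cohort` (or its `as.data.frame`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata_csv <- function(cohort, path) {
  df <- if (inherits(cohort, "cohort")) as.data.frame(cohort) else cohort
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cohort metadata from CSV
#' @param path CSV path.
#' @return data frame.
#' @export
read_metadata_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write a voltage trace container
#'
#' Stores the samples as little-endian float32 binary next to a JSON header
#' (`<path>.json`) with the sampling rate, filter band, sample count and the
#' ground-truth spike times when present.
#'
#' @param trace a [voltage_trace()].
#' @param path output path for the binary samples.
#' @return `path`, invisibly.
#' @export
write_trace_bin <- function(trace, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(trace), con, size = 4, endian = "little")
  gt <- attr(trace, "ground_truth")
  hdr <- list(fs_hz = sampling_rate(trace),
              filter_band_hz = attr(trace, "band_hz"),
              n_samples = length(trace), dtype = "float32_le",
              units = "uV")
  if (!is.null(gt))
    hdr$ground_truth <- lapply(gt, function(tr)
      list(duration_s = duration(tr), times_s = as.numeric(tr)))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a voltage trace container
#' @param path binary path written by [write_trace_bin()].
#' @return a [voltage_trace()] with ground truth reattached when stored.
#' @export
read_trace_bin <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = hdr$n_samples, size = 4, endian = "little")
  gt <- NULL
  if (!is.null(hdr$ground_truth))
    gt <- lapply(hdr$ground_truth, function(e)
      spike_train(e$times_s, e$duration_s))
  voltage_trace(v, hdr$fs_hz, hdr$filter_band_hz, gt)
}
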