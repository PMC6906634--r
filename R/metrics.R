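#' Mean firing rate
#'
#' Rate in Hz = spikes/s over the analysed window (the stated recording
#' duration, not last spike minus first spike).
#'
#' @param train a [spike_train()] or numeric vector of times.
#' @param duration_s analysis window, s; defaults to the train's duration.
#' @return rate in Hz.
#' @examples
#' firing_rate(spike_train(seq(0.5, 50, 0.5), 50))  # 2 Hz
#' @export
firing_rate <- function(train, duration_s = duration(train)) {
  if (is.null(duration_s) || !is.numeric(duration_s) || duration_s <= 0)
    stop_invalid("duration_s must be positive")
  length(train) / duration_s
}

#' ISI coefficient of variation
#'
#' Sample standard deviation of the interspike intervals (n-1 denominator)
#' divided by their mean: global firing irregularity. Undefined (NA) below 3
#' spikes (2 ISIs).
#'
#' @param train a [spike_train()] or sorted numeric time vector.
#' @return CV (dimensionless), or `NA_real_` when undefined.
#' @examples
#' isi_cv(spike_train(c(0.01, 0.02, 0.05), 0.1))  # ISIs 10, 30 ms -> 0.7071
#' @export
isi_cv <- function(train) {
  d <- isis(train)
  if (length(d) < 2) return(NA_real_)
  sd(d) / mean(d)
}

#' ISI CV2, local firing irregularity
#'
#' Mean over adjacent ISI pairs of `2|ISI[n+1] - ISI[n]| / (ISI[n+1] + ISI[n])`,
#' bounded in `[0, 2)`: the variability in timing between one spike and the
#' next. Undefined (NA) below 3 spikes.
#'
#' @param train a [spike_train()] or sorted numeric time vector.
#' @return mean CV2, or `NA_real_` when undefined.
#' @examples
#' isi_cv2(spike_train(c(0.01, 0.02, 0.05), 0.1))  # single pair: 2*20/40 = 1
#' @export
isi_cv2 <- function(train) {
  d <- isis(train)
  if (length(d) < 2) return(NA_real_)
  mean(2 * abs(diff(d)) / (d[-1] + d[-length(d)]))
}

#' Per-cell metrics for each spike type
#'
#' Computes rate, CV and CV2 per spike type from sorted (or ground-truth)
#' trains. For the simple-spike train of a Purkinje cell, ISIs spanning a
#' complex spike are included by default (the stated CV/CV2 formulas applied
#' literally); set `exclude_cs_spanning = TRUE` to drop ISI pairs that bracket
#' a complex spike.
#'
#' @param trains named list of [spike_train()]s (`ss`, `cs`, `cn`), a
#'   `sorted_train` from [sort_spikes()], or a cell record from
#'   [gen_cohort()].
#' @param metadata optional named list/row of metadata carried into the result.
#' @param exclude_cs_spanning logical; see above.
#' @return data frame with one row per spike type: `unit_type, n_spikes,
#'   duration_s, rate_hz, cv, cv2` plus any metadata columns.
#' @export
summarize_cell <- function(trains, metadata = NULL,
                           exclude_cs_spanning = FALSE) {
  if (inherits(trains, "cell_record")) {
    metadata <- metadata %||% trains[c("cell_id", "genotype", "state",
                                       "cell_type", "depth_mm",
                                       "days_post_surgery")]
    trains <- trains$trains
  }
  if (inherits(trains, "sorted_train")) trains <- trains[c("ss", "cs")]
  trains <- Filter(Negate(is.null), trains)
  rows <- lapply(names(trains), function(nm) {
    tr <- trains[[nm]]
    cv <- isi_cv(tr); cv2 <- isi_cv2(tr)
    if (nm == "ss" && exclude_cs_spanning && !is.null(trains$cs) &&
        length(trains$cs) && length(tr) >= 3) {
      d <- isis(tr)
      # ISI i spans a complex spike if some cs time falls between spikes i, i+1
      spans <- vapply(seq_along(d), function(i)
        any(trains$cs > tr[i] & trains$cs < tr[i + 1]), logical(1))
      dk <- d[!spans]
      cv <- if (length(dk) >= 2) sd(dk) / mean(dk) else NA_real_
      pair_ok <- !spans[-length(spans)] & !spans[-1]
      r <- 2 * abs(diff(d)) / (d[-1] + d[-length(d)])
      cv2 <- if (any(pair_ok)) mean(r[pair_ok]) else NA_real_
    }
    data.frame(unit_type = nm, n_spikes = length(tr),
               duration_s = duration(tr), rate_hz = firing_rate(tr),
               cv = cv, cv2 = cv2)
  })
  out <- do.call(rbind, rows)
  if (!is.null(metadata)) out <- cbind(as.data.frame(metadata), out)
  out
}

#' Percent difference relative to a reference value
#'
#' `100 * (reference - other) / reference`: e.g. the percent by which the mdx
#' group mean falls below the control mean.
#'
#' @param reference reference (control) value, nonzero.
#' @param other comparison value.
#' @param digits rounding; use `digits = 0` to mirror reported integer
#'   percentages, `NULL` for the exact value.
#' @return percent difference.
#' @examples
#' percent_difference(85.3, 69.1, digits = 0)  # 19
#' @export
percent_difference <- function(reference, other, digits = NULL) {
  if (any(reference == 0)) stop_invalid("reference must be nonzero")
  out <- 100 * (reference - other) / reference
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Per-cell metrics table for a whole cohort
#'
#' @param cohort a `cohort` from [gen_cohort()].
#' @param exclude_cs_spanning see [summarize_cell()].
#' @return data frame of per-cell, per-unit-type metrics with metadata.
#' @export
cohort_metrics <- function(cohort, exclude_cs_spanning = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort, summarize_cell,
                        exclude_cs_spanning = exclude_cs_spanning))
}

#' Group summaries (mean, SEM, n) of cohort metrics
#'
#' @param metrics per-cell metrics data frame ([cohort_metrics()] output or
#'   equivalent with `rate_hz, cv, cv2` columns).
#' @param grouping name(s) of grouping column(s), default `"genotype"`.
#' @return data frame with one row per group x unit_type: mean, sem (sample
#'   sd / sqrt(n); NA for n < 2) and n per metric, plus the count of cells with
#'   undefined (missing) values excluded per metric.
#' @export
cohort_summary <- function(metrics, grouping = "genotype") {
  stopifnot(all(c(grouping, "unit_type") %in% names(metrics)))
  key <- interaction(metrics[c(grouping, "unit_type")], drop = TRUE)
  rows <- lapply(split(metrics, key), function(df) {
    out <- df[1, c(grouping, "unit_type"), drop = FALSE]
    for (m in c("rate_hz", "cv", "cv2")) {
      x <- df[[m]]; xin <- x[!is.na(x)]
      out[[paste0(m, "_mean")]] <- if (length(xin)) mean(xin) else NA_real_
      out[[paste0(m, "_sem")]] <- if (length(xin) >= 2) sd(xin) / sqrt(length(xin)) else NA_real_
      out[[paste0(m, "_n")]] <- length(xin)
      out[[paste0(m, "_missing")]] <- sum(is.na(x))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
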