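#' Specification of a simulated cohort
#'
#' A cohort is a set of simulated cells in named groups (e.g. genotypes). Each
#' group's cells are generated from the `base` specification scaled by that
#' group's effect multipliers; cells within a group are i.i.d. realizations of
#' the same point process unless a between-cell `dispersion` is requested.
#'
#' @param base a [purkinje_spec()] (simple + complex spikes) or a
#'   [process_spec()] (single spike type, e.g. a cerebellar nuclear neuron).
#' @param multipliers named list, one entry per group, each a named numeric
#'   vector of effect multipliers. For a `purkinje_spec` base use names among
#'   `ss_rate, ss_cv, ss_cv2, cs_rate, cs_cv, cs_cv2`; for a `process_spec`
#'   base use `rate, cv, cv2`. Missing names default to 1.
#' @param n_per_group named integer vector of cells per group (names must match
#'   `multipliers`).
#' @param state recording state label, `"awake"` or `"anesthetized"`.
#' @param cell_type `"purkinje"` or `"nuclear"`.
#' @param master_seed integer; per-cell seeds are derived deterministically
#'   from it, so regeneration is bit-identical.
#' @param dispersion named numeric vector `c(rate=, cv=, cv2=)` of lognormal
#'   between-cell standard deviations (log scale) applied to each cell's
#'   targets; default all zero (homogeneous groups).
#' @param depth_range_mm,days_range recording depth (mm) and days-post-surgery
#'   ranges from which per-cell covariates are drawn uniformly.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(base, multipliers, n_per_group,
                        state = "awake",
                        cell_type = if (inherits(base, "purkinje_spec")) "purkinje" else "nuclear",
                        master_seed = 1L,
                        dispersion = c(rate = 0, cv = 0, cv2 = 0),
                        depth_range_mm = c(0.3, 2.9),
                        days_range = c(3, 14)) {
  if (!inherits(base, "purkinje_spec") && !inherits(base, "process_spec"))
    stop_invalid("base must be a purkinje_spec or process_spec")
  if (is.null(names(multipliers)) || any(names(multipliers) == ""))
    stop_invalid("multipliers must be a named list of groups")
  if (!identical(sort(names(multipliers)), sort(names(n_per_group))))
    stop_invalid("n_per_group names must match multipliers names")
  if (any(n_per_group < 1)) stop_invalid("n_per_group must be >= 1")
  if (any(unlist(multipliers) <= 0)) stop_invalid("multipliers must be positive")
  disp <- c(rate = 0, cv = 0, cv2 = 0)
  disp[names(dispersion)] <- dispersion
  structure(list(base = base, multipliers = multipliers,
                 n_per_group = n_per_group, state = state,
                 cell_type = cell_type, master_seed = as.integer(master_seed),
                 dispersion = disp, depth_range_mm = depth_range_mm,
                 days_range = days_range),
            class = "cohort_spec")
}

scale_process <- function(spec, rate_m = 1, cv_m = 1, cv2_m = 1) {
  process_spec(spec$mean_rate * rate_m, spec$target_cv * cv_m,
               if (!is.null(spec$target_cv2)) spec$target_cv2 * cv2_m,
               spec$duration_s, spec$seed)
}

mult_get <- function(m, name) if (name %in% names(m)) m[[name]] else 1

# simulate one cell from its (already group-scaled) spec
simulate_cell <- function(base, seed, dispersion) {
  jitter3 <- function(spec) {
    if (all(dispersion == 0)) return(spec)
    # mean-one lognormal multipliers on the cell's target statistics
    mm <- exp(rnorm(3, -dispersion^2 / 2, dispersion))
    scale_process(spec, mm[1], mm[2], mm[3])
  }
  gen1 <- function(spec) {
    if (!is.null(spec$target_cv2)) gen_cv2_train(spec, seed = NULL)
    else gen_renewal_train(spec, seed = NULL)
  }
  with_seed(seed, {
    if (inherits(base, "purkinje_spec")) {
      ss_spec <- jitter3(base$ss); cs_spec <- jitter3(base$cs)
      cs <- gen1(cs_spec)
      # pre-compensate the simple-spike rate for the pause deletion so the
      # delivered rate matches the spec target
      del <- cs_spec$mean_rate * base$pause_ms / 1000
      ss_raw <- gen1(scale_process(ss_spec, rate_m = 1 / max(1e-6, 1 - del)))
      ss <- apply_cs_pause(ss_raw, cs, base$pause_ms)
      list(ss = ss, cs = cs)
    } else {
      list(cn = gen1(jitter3(base)))
    }
  })
}

#' Generate a simulated cohort
#'
#' Produces one cell record per cell: metadata (group/genotype, state, cell
#' type, recording depth, days post-surgery, duration, seed) plus the
#' ground-truth spike trains. Regeneration with the same `master_seed` is
#' bit-identical.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `cohort`: a list of cell records with the spec
#'   attached.
#' @examples
#' co <- gen_cohort(study_cohort_spec("awake_purkinje", n_per_group = c(control = 2, mdx = 2),
#'                                    master_seed = 1))
#' as.data.frame(co)
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- names(spec$multipliers)
  n_total <- sum(spec$n_per_group[groups])
  seeds <- derive_seeds(spec$master_seed, 2L * n_total)
  cells <- vector("list", n_total)
  idx <- 0L
  for (g in groups) {
    m <- spec$multipliers[[g]]
    base_g <- if (inherits(spec$base, "purkinje_spec")) {
      purkinje_spec(
        scale_process(spec$base$ss, mult_get(m, "ss_rate"),
                      mult_get(m, "ss_cv"), mult_get(m, "ss_cv2")),
        scale_process(spec$base$cs, mult_get(m, "cs_rate"),
                      mult_get(m, "cs_cv"), mult_get(m, "cs_cv2")),
        spec$base$pause_ms)
    } else {
      scale_process(spec$base, mult_get(m, "rate"),
                    mult_get(m, "cv"), mult_get(m, "cv2"))
    }
    for (i in seq_len(spec$n_per_group[[g]])) {
      idx <- idx + 1L
      seed_i <- seeds[idx]
      cov_seed <- seeds[n_total + idx]
      covs <- with_seed(cov_seed, c(runif(1, spec$depth_range_mm[1], spec$depth_range_mm[2]),
                                    runif(1, spec$days_range[1], spec$days_range[2])))
      trains <- simulate_cell(base_g, seed_i, spec$dispersion)
      dur <- if (inherits(spec$base, "purkinje_spec")) spec$base$ss$duration_s
             else spec$base$duration_s
      cells[[idx]] <- structure(list(
        cell_id = sprintf("%s_%03d", g, i),
        genotype = g, state = spec$state, cell_type = spec$cell_type,
        depth_mm = round(covs[1], 3),
        days_post_surgery = round(covs[2]),
        duration_s = dur, seed = seed_i,
        trains = trains, spec = base_g), class = "cell_record")
    }
  }
  structure(cells, spec = spec, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("<cohort> %d %s cells (%s): %s\n", length(x), sp$cell_type,
              sp$state,
              paste(sprintf("%s n=%d", names(sp$n_per_group), sp$n_per_group),
                    collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  do.call(rbind, lapply(x, function(cl) {
    data.frame(cell_id = cl$cell_id, genotype = cl$genotype, state = cl$state,
               cell_type = cl$cell_type, depth_mm = cl$depth_mm,
               days_post_surgery = cl$days_post_surgery,
               duration_s = cl$duration_s, seed = cl$seed)
  }))
}

#' Cohort specifications matching the mdx study conditions
#'
#' Pre-parameterised [cohort_spec()]s for the three recorded populations, with
#' group-level targets taken from the reported control means and genotype
#' effect ratios:
#' \describe{
#'   \item{`awake_purkinje`}{simple spikes 85.3 Hz control, mdx rate x0.81;
#'     complex spikes 1.2 Hz, mdx CV x0.83; 71 s per cell; n = 24 per group.}
#'   \item{`anesthetized_purkinje`}{simple spikes 30.8 Hz control, mdx rate
#'     x0.87; complex spikes 0.6 Hz; 200 s; n = 48 control, 46 mdx.}
#'   \item{`nuclear`}{single spike type, 60 Hz, CV 0.5, CV2 0.39 control, mdx
#'     CV2 x1.19; 71 s; n = 28 control, 23 mdx.}
#' }
#' Complex-spike rates are not reported in the source data; the defaults (1.2
#' Hz awake, 0.6 Hz anesthetized) follow the observation that complex spikes
#' are more frequent in awake recordings. Simple-spike CV defaults (0.5 awake,
#' 0.7 anesthetized) sit inside the typical 0.4-1.0 envelope.
#'
#' @param condition one of `"awake_purkinje"`, `"anesthetized_purkinje"`,
#'   `"nuclear"`.
#' @param n_per_group optional named integer vector overriding the study sizes.
#' @param master_seed integer master seed.
#' @param dispersion between-cell lognormal dispersion, see [cohort_spec()].
#' @return a [cohort_spec()].
#' @export
study_cohort_spec <- function(condition = c("awake_purkinje",
                                            "anesthetized_purkinje", "nuclear"),
                              n_per_group = NULL, master_seed = 1L,
                              dispersion = c(rate = 0, cv = 0, cv2 = 0)) {
  condition <- match.arg(condition)
  if (condition == "awake_purkinje") {
    base <- purkinje_spec(
      ss = process_spec(85.3, 0.5, duration_s = 71),
      cs = process_spec(1.2, 0.92, duration_s = 71),
      pause_ms = 20)
    cohort_spec(base,
                multipliers = list(control = c(ss_rate = 1),
                                   mdx = c(ss_rate = 0.81, cs_cv = 0.83)),
                n_per_group = n_per_group %||% c(control = 24, mdx = 24),
                state = "awake", master_seed = master_seed,
                dispersion = dispersion)
  } else if (condition == "anesthetized_purkinje") {
    base <- purkinje_spec(
      ss = process_spec(30.8, 0.7, duration_s = 200),
      cs = process_spec(0.6, 1.0, duration_s = 200),
      pause_ms = 20)
    cohort_spec(base,
                multipliers = list(control = c(ss_rate = 1),
                                   mdx = c(ss_rate = 0.87)),
                n_per_group = n_per_group %||% c(control = 48, mdx = 46),
                state = "anesthetized", master_seed = master_seed,
                dispersion = dispersion,
                depth_range_mm = c(0.2, 2.4), days_range = c(0, 0))
  } else {
    base <- process_spec(60, 0.5, target_cv2 = 0.39, duration_s = 71)
    cohort_spec(base,
                multipliers = list(control = c(rate = 1),
                                   mdx = c(cv2 = 1.19)),
                n_per_group = n_per_group %||% c(control = 28, mdx = 23),
                state = "awake", master_seed = master_seed,
                dispersion = dispersion,
                depth_range_mm = c(1.8, 4.0))
  }
}
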