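#' Specification of a simulated point process
#'
#' Bundles the target statistics of one simulated unit: mean firing rate, ISI
#' coefficient of variation (CV), optionally the local variability (CV2), the
#' recording duration and a seed. Rate and duration must be positive; a set
#' `target_cv2` must lie in (0, 2) (use `target_cv2 = 0` together with
#' `target_cv = 0` for a perfectly regular train).
#'
#' @param mean_rate target mean rate, events/s.
#' @param target_cv target ISI CV (dimensionless, >= 0).
#' @param target_cv2 optional target mean CV2 in [0, 2).
#' @param duration_s recording duration, seconds.
#' @param seed optional integer seed.
#' @return a `process_spec` list.
#' @export
process_spec <- function(mean_rate, target_cv, target_cv2 = NULL,
                         duration_s = 60, seed = NULL) {
  if (!is.numeric(mean_rate) || mean_rate <= 0)
    stop_invalid("mean_rate must be positive")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop_invalid("duration_s must be positive")
  if (!is.numeric(target_cv) || target_cv < 0)
    stop_invalid("target_cv must be >= 0")
  if (!is.null(target_cv2)) {
    if (target_cv2 < 0 || target_cv2 >= 2)
      stop_invalid("target_cv2 must lie in [0, 2)")
    if (target_cv2 > 0 && target_cv == 0)
      stop_infeasible("a regular train (cv = 0) forces cv2 = 0")
  }
  structure(list(mean_rate = mean_rate, target_cv = target_cv,
                 target_cv2 = target_cv2, duration_s = duration_s,
                 seed = seed),
            class = "process_spec")
}

#' Specification of a simulated Purkinje cell
#'
#' A Purkinje cell fires simple spikes (tens of Hz) and complex spikes (~1 Hz);
#' each complex spike silences simple-spike firing for roughly `pause_ms`
#' milliseconds.
#'
#' @param ss `process_spec` for the simple-spike train.
#' @param cs `process_spec` for the complex-spike train (rate must be lower
#'   than the simple-spike rate).
#' @param pause_ms post-complex-spike simple-spike pause, milliseconds.
#' @return a `purkinje_spec` list.
#' @export
purkinje_spec <- function(ss, cs, pause_ms = 20) {
  stopifnot(inherits(ss, "process_spec"), inherits(cs, "process_spec"))
  if (cs$mean_rate >= ss$mean_rate)
    stop_invalid("complex-spike rate must be below the simple-spike rate")
  if (pause_ms < 0) stop_invalid("pause_ms must be >= 0")
  structure(list(ss = ss, cs = cs, pause_ms = pause_ms),
            class = "purkinje_spec")
}

# ---- CV2 theory for gamma / Markov-modulated gamma ISIs ---------------------
#
# For X, Y iid gamma(k): U = X/(X+Y) ~ Beta(k, k) and
#   E[2|X-Y|/(X+Y)] = 2 E|2U-1| = 2 (2 (1 - pbeta(1/2, k+1, k)) - 1).
# For scales a = rho*b: V = rho*U / (rho*U + 1 - U) replaces U.

cv2_gamma_same <- function(k) 2 * (2 * (1 - pbeta(0.5, k + 1, k)) - 1)

cv2_gamma_cross <- function(k, rho) {
  integrate(function(u) {
    v <- rho * u / (rho * u + 1 - u)
    2 * abs(2 * v - 1) * dbeta(u, k, k)
  }, 0, 1, rel.tol = 1e-9)$value
}

# Second moment of the (mean-one) two-state scale multiplier at ratio rho.
scale_m2 <- function(rho) 2 * (1 + rho^2) / (1 + rho)^2

# Gamma shape that yields overall ISI CV `cv` once the two-state scale
# modulation at ratio rho is applied: CV^2 = (1+k)/k * E[m^2] - 1.
shape_for_cv <- function(rho, cv) {
  m2 <- scale_m2(rho)
  if (m2 >= 1 + cv^2) return(NA_real_)
  m2 / (1 + cv^2 - m2)
}

# Solve (rho, q, k) of the two-state Markov-modulated gamma renewal process so
# that the overall ISI CV equals `cv` and the expected CV2 equals `cv2`.
# Adjacent ISIs share a state with probability 1-q, so
#   E[CV2] = (1-q) cv2_gamma_same(k) + q cv2_gamma_cross(k, rho).
# Persistence (small q) lowers CV2 below the plain-renewal value at fixed CV;
# alternation (large q) raises it.
calibrate_cv2 <- function(mean_rate, cv, cv2) {
  if (cv <= 0) {
    if (cv2 > 1e-12)
      stop_infeasible("cv = 0 admits only cv2 = 0")
    return(list(rho = 1, q = 0.5, k = Inf))
  }
  renewal <- cv2_gamma_same(1 / cv^2)
  if (abs(cv2 - renewal) < 1e-3)
    return(list(rho = 1, q = 0.5, k = 1 / cv^2))
  q <- if (cv2 < renewal) 0.05 else 0.95
  rho_max <- if (cv < 1) {
    uniroot(function(r) scale_m2(r) - (1 + cv^2) * 0.999, c(1, 1e5))$root
  } else 200
  f <- function(rho) {
    k <- shape_for_cv(rho, cv)
    (1 - q) * cv2_gamma_same(k) + q * cv2_gamma_cross(k, rho) - cv2
  }
  lo <- 1 + 1e-6; hi <- rho_max * 0.999
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    lo_cv2 <- min(flo, fhi, na.rm = TRUE) + cv2
    hi_cv2 <- max(flo, fhi, na.rm = TRUE) + cv2
    rng <- sort(c(renewal, lo_cv2, hi_cv2))
    stop_infeasible(sprintf(
      "target cv2 = %.3f unreachable at cv = %.3f; achievable approximately [%.3f, %.3f]",
      cv2, cv, rng[1], rng[length(rng)]))
  }
  r <- uniroot(f, c(lo, hi), tol = 1e-9)$root
  list(rho = r, q = q, k = shape_for_cv(r, cv))
}

regular_times <- function(rate, duration_s) {
  if (1 / rate > duration_s) return(numeric(0))
  seq(1 / rate, duration_s, by = 1 / rate)
}

# draw ISIs for a (possibly modulated) gamma renewal process until `duration`
# is covered, vectorised with top-up
draw_train_times <- function(mean_rate, duration_s, draw_isi) {
  n <- ceiling(mean_rate * duration_s * 1.25) + 50
  t <- cumsum(draw_isi(n))
  while (length(t) && t[length(t)] < duration_s) {
    t <- c(t, t[length(t)] + cumsum(draw_isi(n)))
  }
  t[t <= duration_s]
}

#' Generate a gamma-renewal spike train
#'
#' ISIs are drawn i.i.d. from a gamma distribution with shape `k = 1/cv^2` and
#' scale `1/(rate*k)`, so the mean ISI is `1/rate` and the ISI CV is `cv`.
#' `target_cv = 0` produces a perfectly regular train; `target_cv = 1` gives a
#' Poisson process. Empirical rate and CV converge to the spec targets as the
#' duration grows.
#'
#' @param spec a [process_spec()]. Any `target_cv2` field is ignored here; use
#'   [gen_cv2_train()] to control CV2.
#' @param seed optional seed overriding `spec$seed`.
#' @return a [spike_train()].
#' @examples
#' st <- gen_renewal_train(process_spec(30, 1, duration_s = 100, seed = 1))
#' sd(isis(st)) / mean(isis(st))  # near 1
#' @export
gen_renewal_train <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "process_spec"))
  seed <- seed %||% spec$seed
  with_seed(seed, {
    rate <- spec$mean_rate; cv <- spec$target_cv
    if (cv < 1e-3) {
      times <- regular_times(rate, spec$duration_s)
    } else {
      k <- 1 / cv^2
      times <- draw_train_times(rate, spec$duration_s,
                                function(n) rgamma(n, shape = k, scale = 1 / (rate * k)))
    }
    spike_train(times, spec$duration_s)
  })
}

#' Generate a spike train with calibrated CV and CV2
#'
#' Simulates a two-state Markov-modulated gamma renewal process: the ISI scale
#' alternates between two values (ratio `rho`) under a symmetric two-state
#' Markov chain with per-interval switch probability `q`, while the gamma shape
#' sets within-state regularity. The three parameters are solved
#' semi-analytically so the long-run ISI CV matches `spec$target_cv` and the
#' expected CV2 matches `spec$target_cv2`; this decouples local (CV2) from
#' global (CV) variability, e.g. raising CV2 while the rate and CV are held
#' fixed, as observed in cerebellar nuclear neurons.
#'
#' @param spec a [process_spec()] with `target_cv2` set.
#' @param seed optional seed overriding `spec$seed`.
#' @return a [spike_train()] with a `calibration` attribute (rho, q, k).
#' @examples
#' st <- gen_cv2_train(process_spec(40, 0.5, target_cv2 = 0.39,
#'                                  duration_s = 200, seed = 1))
#' isi_cv2(st)  # near 0.39
#' @export
gen_cv2_train <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "process_spec"))
  if (is.null(spec$target_cv2))
    stop_invalid("spec$target_cv2 must be set for gen_cv2_train")
  seed <- seed %||% spec$seed
  cal <- calibrate_cv2(spec$mean_rate, spec$target_cv, spec$target_cv2)
  with_seed(seed, {
    rate <- spec$mean_rate
    if (!is.finite(cal$k)) {  # regular limit
      times <- regular_times(rate, spec$duration_s)
    } else {
      a <- 2 * cal$rho / (1 + cal$rho); b <- 2 / (1 + cal$rho)
      state0 <- rbinom(1, 1, 0.5)
      draw <- function(n) {
        st <- (state0 + cumsum(rbinom(n, 1, cal$q))) %% 2
        state0 <<- st[n]
        m <- ifelse(st == 1, a, b)
        rgamma(n, shape = cal$k, scale = m / (rate * cal$k))
      }
      times <- draw_train_times(rate, spec$duration_s, draw)
    }
    out <- spike_train(times, spec$duration_s)
    attr(out, "calibration") <- cal
    out
  })
}

#' Apply the post-complex-spike pause to a simple-spike train
#'
#' Removes every simple spike falling in the half-open window
#' `(t_cs, t_cs + pause_ms/1000]` after any complex spike, emulating the ~20 ms
#' silencing of simple-spike firing that follows each complex spike. A
#' simple spike exactly coincident with a complex spike is treated as the
#' complex-spike event and kept out of the deletion window.
#'
#' @param ss simple-spike [spike_train()].
#' @param cs complex-spike [spike_train()] on the same time base.
#' @param pause_ms pause length in milliseconds.
#' @return the censored simple-spike `spike_train`.
#' @examples
#' ss <- spike_train(c(0.010, 0.025, 0.050), 0.1)
#' cs <- spike_train(0.020, 0.1)
#' apply_cs_pause(ss, cs, 20)  # 0.025 removed
#' @export
apply_cs_pause <- function(ss, cs, pause_ms = 20) {
  if (length(cs) == 0 || length(ss) == 0 || pause_ms == 0) return(ss)
  pause <- pause_ms / 1000
  cs_t <- as.numeric(cs)
  # index of latest cs at or after which each ss might fall in a pause window
  j <- findInterval(as.numeric(ss), cs_t)  # cs_t[j] <= ss < cs_t[j+1]; 0 if before all
  ss_t <- as.numeric(ss)
  inside <- j > 0 & ss_t > cs_t[pmax(j, 1)] & ss_t <= cs_t[pmax(j, 1)] + pause
  spike_train(ss_t[!inside], duration(ss))
}
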