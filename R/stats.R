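#' Two-group Wilks' lambda MANOVA
#'
#' One-way MANOVA on a multivariate response (here typically the per-cell
#' firing rate, CV and CV2). Wilks' lambda is `det(E) / det(E + H)` where `E`
#' and `H` are the within- and between-group SSCP matrices. For two groups the
#' conversion to F is exact:
#' `F = ((1 - lambda)/lambda) * ((N - p - 1)/p)` on `(p, N - p - 1)` degrees of
#' freedom. The displayed hypothesis/error df follow the `(g - 1, N - g)`
#' convention used in reports.
#'
#' @param X numeric matrix or data frame, rows = cells, columns = responses.
#' @param groups factor/vector of group labels (exactly 2 levels).
#' @return a `manova_result` list: `wilks_lambda, f_stat, df1, df2,
#'   df_hypothesis, df_error, p, n_total, n_responses`.
#' @export
wilks_manova <- function(X, groups) {
  X <- as.matrix(X)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_invalid("need at least 2 groups")
  if (nlevels(groups) != 2)
    stop_invalid("exact F conversion implemented for 2 groups only")
  if (any(!is.finite(X))) stop_invalid("response matrix contains missing values")
  p <- ncol(X); N <- nrow(X)
  if (any(table(groups) <= p))
    stop_invalid("each group needs more observations than responses")
  grand <- colMeans(X)
  E <- matrix(0, p, p); H <- matrix(0, p, p)
  for (g in levels(groups)) {
    Xg <- X[groups == g, , drop = FALSE]
    mg <- colMeans(Xg)
    C <- sweep(Xg, 2, mg)
    E <- E + crossprod(C)
    H <- H + nrow(Xg) * tcrossprod(mg - grand)
  }
  dE <- det(E); dEH <- det(E + H)
  if (dEH <= 0 || dE < 0)
    stop(errorCondition("singular within-group covariance",
                        class = c("purkinje_singular", "error")))
  lambda <- dE / dEH
  f_stat <- ((1 - lambda) / lambda) * ((N - p - 1) / p)
  pval <- pf(f_stat, p, N - p - 1, lower.tail = FALSE)
  structure(list(wilks_lambda = lambda, f_stat = f_stat,
                 df1 = p, df2 = N - p - 1,
                 df_hypothesis = nlevels(groups) - 1,
                 df_error = N - nlevels(groups),
                 p = pval, n_total = N, n_responses = p),
            class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("Wilks' lambda(%d,%d) = %.4f, F(%d,%d) = %.3f, P = %.4g\n",
              x$df_hypothesis, x$df_error, x$wilks_lambda,
              x$df1, x$df2, x$f_stat, x$p))
  invisible(x)
}

#' P-value from a reported Wilks' lambda
#'
#' Converts a two-group Wilks' lambda and design size to the exact F statistic
#' and p-value, e.g. to check reported omnibus results.
#'
#' @param lambda Wilks' lambda in (0, 1].
#' @param n_total total number of observations N.
#' @param n_responses number of response variables p.
#' @return list with `f_stat, df1, df2, p`.
#' @examples
#' manova_p_from_lambda(0.9028, 94, 3)$p  # ~0.026
#' @export
manova_p_from_lambda <- function(lambda, n_total, n_responses) {
  if (lambda <= 0 || lambda > 1) stop_invalid("lambda must be in (0, 1]")
  p <- n_responses; N <- n_total
  f_stat <- ((1 - lambda) / lambda) * ((N - p - 1) / p)
  list(f_stat = f_stat, df1 = p, df2 = N - p - 1,
       p = pf(f_stat, p, N - p - 1, lower.tail = FALSE))
}

#' Wilcoxon rank-sum test (normal approximation)
#'
#' Rank-sum statistic with midrank tie handling and tie-corrected variance;
#' two-sided p from the normal approximation, by default without continuity
#' correction. The sign convention is positive `z` when the first sample
#' (conventionally the control group) tends larger.
#'
#' @param x,y numeric samples (first sample = reference/control).
#' @param continuity apply the 0.5 continuity correction.
#' @return list with `w` (rank sum of `x`), `z`, `p`.
#' @examples
#' wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))  # W = 6, z = -1.964
#' @export
wilcoxon_ranksum <- function(x, y, continuity = FALSE) {
  if (!length(x) || !length(y)) stop_invalid("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))  # midranks
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v <= 0) return(list(w = w, z = 0, p = 1))  # all values identical
  dev <- w - mu
  if (continuity) dev <- sign(dev) * max(0, abs(dev) - 0.5)
  z <- dev / sqrt(v)
  list(w = w, z = z, p = 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up procedure
#'
#' Sorts the p-values ascending, computes critical values
#' `(i/m) * fdr`, finds the largest rank `i` with `p_(i) <= (i/m) * fdr`, and
#' rejects all hypotheses of rank up to `i`.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param fdr false discovery rate (default 0.2, the rate used throughout the
#'   firing-property comparisons this package mirrors).
#' @return list with `rejected` (logical, input order) and `critical`
#'   (per-hypothesis critical value `(rank/m) * fdr`, input order).
#' @examples
#' benjamini_hochberg(c(0.01, 0.03, 0.04), fdr = 0.2)
#' @export
benjamini_hochberg <- function(pvals, fdr = 0.2) {
  m <- length(pvals)
  if (m == 0) return(list(rejected = logical(0), critical = numeric(0)))
  if (any(pvals < 0 | pvals > 1)) stop_invalid("p-values must be in [0, 1]")
  o <- order(pvals)
  crit_sorted <- (seq_len(m) / m) * fdr
  ok <- which(pvals[o] <= crit_sorted)
  rejected <- rep(FALSE, m)
  if (length(ok)) rejected[o[seq_len(max(ok))]] <- TRUE
  critical <- numeric(m)
  critical[o] <- crit_sorted
  list(rejected = rejected, critical = critical)
}

#' Median split of a continuous covariate
#'
#' Binarizes values into `low` (<= median) and `high` (> median); the median is
#' the midpoint of the central order statistics. If all values are equal the
#' split is degenerate and flagged.
#'
#' @param values numeric vector (length >= 2).
#' @return factor with levels `low`/`high` and attribute `degenerate`.
#' @examples
#' median_split(c(1, 2, 3, 4))  # low low high high
#' @export
median_split <- function(values) {
  if (length(values) < 2) stop_invalid("need at least 2 values")
  med <- median(values)
  lab <- factor(ifelse(values <= med, "low", "high"), levels = c("low", "high"))
  structure(lab, degenerate = length(unique(values)) == 1 ||
              nlevels(droplevels(lab)) < 2)
}

#' Two-sample t test from summary statistics
#'
#' Student's t from reported means, SEMs and group sizes. For equal group
#' sizes `t = (mean1 - mean2) / sqrt(sem1^2 + sem2^2)` (identical to the
#' pooled-variance t); unequal sizes use the pooled-variance formula. Two-sided
#' p on `n1 + n2 - 2` df.
#'
#' @param mean1,sem1,n1 first group summary.
#' @param mean2,sem2,n2 second group summary.
#' @return a `t_test_result` list: `t, df, p` (and `infinite` flag when the
#'   pooled SEM is zero).
#' @examples
#' t_from_summary(152.3, 3.7, 3, 155.7, 4.0, 3)  # t(4) ~ -0.624
#' @export
t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  df <- n1 + n2 - 2
  if (n1 == n2) {
    denom <- sqrt(sem1^2 + sem2^2)
  } else {
    s1sq <- sem1^2 * n1; s2sq <- sem2^2 * n2
    sp2 <- ((n1 - 1) * s1sq + (n2 - 1) * s2sq) / df
    denom <- sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  if (denom == 0) {
    return(structure(list(t = ifelse(mean1 == mean2, 0, Inf * sign(mean1 - mean2)),
                          df = df, p = ifelse(mean1 == mean2, 1, 0),
                          infinite = mean1 != mean2),
                     class = "t_test_result"))
  }
  tt <- (mean1 - mean2) / denom
  structure(list(t = tt, df = df, p = 2 * pt(-abs(tt), df), infinite = FALSE),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, P = %.3g\n", x$df, x$t, x$p))
  invisible(x)
}

#' Hierarchical group analysis of a cohort
#'
#' Mirrors the study's decision tree for one spike type: for each predictor
#' (genotype, plus median-split continuous covariates such as days
#' post-surgery and recording depth) run an omnibus two-group MANOVA on the
#' per-cell response matrix (rate, CV, CV2). Only when the omnibus p is below
#' `alpha` are the three per-response Wilcoxon rank-sum tests run, followed by
#' Benjamini-Hochberg correction at `fdr` across that family. Cells with
#' undefined metrics are dropped listwise and counted; predictors with a
#' degenerate split are skipped with a warning.
#'
#' @param metrics per-cell metrics data frame ([cohort_metrics()] output), or a
#'   `cohort` (metrics are computed).
#' @param unit_type which spike type to analyse (`"ss"`, `"cs"` or `"cn"`).
#' @param predictors character vector of metadata columns; continuous ones are
#'   median-split. The first level/reference group is the first sorted level
#'   for factors (`control` before `mdx`) or `low` for splits.
#' @param alpha omnibus gate level.
#' @param fdr Benjamini-Hochberg false discovery rate for the pairwise family.
#' @return a `stat_report` list with one entry per predictor: the
#'   `manova_result`, gate decision, and (when gated through) per-response
#'   `z`, `p`, BH critical value and rejection flag; plus dropped-cell counts.
#' @export
analysis_workflow <- function(metrics, unit_type = "ss",
                              predictors = c("genotype", "days_post_surgery",
                                             "depth_mm"),
                              alpha = 0.05, fdr = 0.2) {
  if (inherits(metrics, "cohort")) metrics <- cohort_metrics(metrics)
  df <- metrics[metrics$unit_type == unit_type, , drop = FALSE]
  if (!nrow(df)) stop_invalid("no cells with unit_type ", unit_type)
  responses <- c("rate_hz", "cv", "cv2")
  ok <- complete.cases(df[responses])
  n_dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  out <- list()
  for (pred in predictors) {
    if (!pred %in% names(df)) next
    v <- df[[pred]]
    if (is.numeric(v)) {
      g <- median_split(v)
      if (attr(g, "degenerate")) {
        warning("predictor ", pred, " has a degenerate split; skipped")
        out[[pred]] <- list(skipped = TRUE, reason = "degenerate split")
        next
      }
    } else {
      g <- factor(v)
      if (nlevels(droplevels(g)) < 2) {
        warning("predictor ", pred, " has a single level; skipped")
        out[[pred]] <- list(skipped = TRUE, reason = "single level")
        next
      }
    }
    mv <- tryCatch(wilks_manova(df[responses], g), error = function(e) e)
    if (inherits(mv, "error")) {
      warning("predictor ", pred, " skipped: ", conditionMessage(mv))
      out[[pred]] <- list(skipped = TRUE, reason = conditionMessage(mv))
      next
    }
    entry <- list(skipped = FALSE, manova = mv, gate_passed = mv$p < alpha,
                  groups = levels(droplevels(g)),
                  n_per_group = as.integer(table(droplevels(g))))
    if (entry$gate_passed) {
      ref <- levels(droplevels(g))[1]
      pw <- lapply(responses, function(rn)
        wilcoxon_ranksum(df[[rn]][g == ref], df[[rn]][g != ref]))
      pvals <- vapply(pw, `[[`, numeric(1), "p")
      bh <- benjamini_hochberg(pvals, fdr)
      entry$pairwise <- data.frame(
        response = responses,
        z = vapply(pw, `[[`, numeric(1), "z"),
        p = pvals, bh_critical = bh$critical, rejected = bh$rejected)
    }
    out[[pred]] <- entry
  }
  structure(list(unit_type = unit_type, alpha = alpha, fdr = fdr,
                 n_cells = nrow(df), n_dropped = n_dropped,
                 predictors = out), class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("Hierarchical analysis (%s): %d cells (%d dropped), gate alpha = %.2f, BH FDR = %.2f\n",
              x$unit_type, x$n_cells, x$n_dropped, x$alpha, x$fdr))
  for (pred in names(x$predictors)) {
    e <- x$predictors[[pred]]
    if (isTRUE(e$skipped)) {
      cat(sprintf("  %s: skipped (%s)\n", pred, e$reason)); next
    }
    cat(sprintf("  %s: Wilks' lambda(%d,%d) = %.4f, P = %.4g -> %s\n",
                pred, e$manova$df_hypothesis, e$manova$df_error,
                e$manova$wilks_lambda, e$manova$p,
                if (e$gate_passed) "pairwise tests" else "stop (omnibus ns)"))
    if (e$gate_passed) {
      for (i in seq_len(nrow(e$pairwise))) {
        r <- e$pairwise[i, ]
        cat(sprintf("    %-8s |z| = %.2f, P = %.4g, BH crit %.3f: %s\n",
                    r$response, abs(r$z), r$p, r$bh_critical,
                    if (r$rejected) "rejected (significant)" else "not rejected"))
      }
    }
  }
  invisible(x)
}
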