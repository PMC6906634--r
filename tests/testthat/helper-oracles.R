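# Independent oracles, deliberately written as plain loops so they share no
# code with the package implementations they check.

brute_cv <- function(times) {
  isi <- c()
  for (i in 2:length(times)) isi <- c(isi, times[i] - times[i - 1])
  if (length(isi) < 2) return(NA_real_)
  m <- sum(isi) / length(isi)
  v <- sum((isi - m)^2) / (length(isi) - 1)
  sqrt(v) / m
}

brute_cv2 <- function(times) {
  isi <- c()
  for (i in 2:length(times)) isi <- c(isi, times[i] - times[i - 1])
  if (length(isi) < 2) return(NA_real_)
  vals <- c()
  for (i in 2:length(isi))
    vals <- c(vals, 2 * abs(isi[i] - isi[i - 1]) / (isi[i] + isi[i - 1]))
  sum(vals) / length(vals)
}

# step-up BH by direct rule evaluation
brute_bh <- function(p, fdr) {
  m <- length(p)
  o <- order(p)
  kmax <- 0
  for (i in 1:m) if (p[o[i]] <= fdr * i / m) kmax <- i
  rej <- rep(FALSE, m)
  if (kmax > 0) for (i in 1:kmax) rej[o[i]] <- TRUE
  rej
}

# 8-connected component count by label propagation to a fixpoint
fixpoint_count <- function(m, min_size = 1) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  lab[m] <- seq_len(sum(m))
  repeat {
    changed <- FALSE
    for (r in 1:nr) for (cc in 1:nc) {
      if (!m[r, cc]) next
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- cc + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && m[r2, c2] &&
            lab[r2, c2] < lab[r, cc]) {
          lab[r, cc] <- lab[r2, c2]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  sizes <- table(lab[lab > 0])
  sum(sizes >= min_size)
}

# match detected event times to ground truth within a tolerance (s)
match_events <- function(detected, truth, tol = 5e-4) {
  used <- rep(FALSE, length(detected))
  hits <- 0L
  for (t in truth) {
    d <- abs(detected - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) { hits <- hits + 1L; used[j] <- TRUE }
  }
  list(recall = if (length(truth)) hits / length(truth) else NA_real_,
       precision = if (length(detected)) hits / length(detected) else NA_real_)
}
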