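# Independent brute-force oracles used to back the implementation tests.

# sort, slice the central five order statistics, average
oracle_central_five <- function(x) {
  n <- length(x)
  if (n %% 2 == 0) {
    d <- abs(x - median(x))
    cand <- which(d == max(d))
    if (length(cand) > 1) cand <- cand[which.max(x[cand])]
    x <- x[-cand]
    n <- n - 1
  }
  k <- (n - 5) / 2
  xs <- sort(x)
  mean(xs[(k + 1):(k + 5)])
}

# all-pairs AUC: P(pos > neg) + 0.5 P(pos == neg)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Mann-Whitney U by direct pair counting
oracle_u <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# beat table with n_cycles respiratory cycles, beats at fixed phases;
# each cycle gets one end-expiratory beat (phase 0.02) and inspiratory
# beats; vti_end may be a vector (one value per cycle)
make_beats <- function(n_cycles, vti_end = 18, vti_insp = 15, pv_end = 95,
                       insp_phases = c(0.3, 0.5, 0.7)) {
  vti_end <- rep(vti_end, length.out = n_cycles)
  rows <- lapply(seq_len(n_cycles), function(cy) {
    phases <- c(0.02, insp_phases)
    data.frame(
      t_s = (cy - 1) * 4 + phases * 4,
      vti_cm = c(vti_end[cy], rep(vti_insp, length(insp_phases))),
      pv_cm_s = pv_end,
      resp_phase = phases
    )
  })
  do.call(rbind, rows)
}
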