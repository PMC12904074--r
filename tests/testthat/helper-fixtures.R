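# Shared fixtures: tiny signals and recordings built in code at test time.

fsDefault <- 1000

toneSignal <- function(freq_hz, duration_s, fs = fsDefault, amp = 1,
                       phase = 0) {
  amp * cos(2 * pi * freq_hz * (0:(duration_s * fs - 1)) / fs + phase)
}

tinyRecording <- function(duration_s = 2, fs = fsDefault,
                          regions = c("OB", "aPC", "LEC"), seed = 1) {
  set.seed(seed)
  Recording(lfp = matrix(rnorm(length(regions) * duration_s * fs),
                         nrow = length(regions)),
            fs_hz = fs, regions = regions, subject_id = "tiny",
            group = "control")
}

tinyEvents <- function() {
  EventTable(data.frame(
    epoch_id = c("e1", "e2", "e3", "e4"),
    label = c("obj_a", "obj_a", "obj_b", "obj_b"),
    start_s = c(0.1, 0.6, 0.2, 0.9),
    end_s = c(0.4, 0.9, 0.5, 1.4),
    condition = c("familiar", "familiar", "novel", "novel"),
    stringsAsFactors = FALSE))
}

# greedy-free exact assignment for small K: maximize total |cosine| between
# rows of A (estimates) and rows of B (truth); returns per-truth best match
# under a one-to-one assignment (exhaustive over permutations via clue)
matchedCosines <- function(W_est, W_true) {
  C <- abs(W_est %*% t(W_true)) /
    (sqrt(rowSums(W_est^2)) %o% sqrt(rowSums(W_true^2)))
  # pad to square for the assignment solver
  k <- ncol(C)
  if (nrow(C) < k) stop("need at least as many estimates as truths")
  sol <- clue::solve_LSAP(t(C), maximum = TRUE)  # truth -> estimate
  vapply(seq_len(k), function(j) C[sol[j], j], numeric(1))
}

# ground-truth co-participation signature of a planted pattern: the unit
# contrast between the mean standardized feature vector inside the pattern's
# activation windows and outside all activation windows. Built only from the
# planted epochs (ground truth) and the feature matrix, independently of the
# ICA fit it is compared against.
contrastSignature <- function(F_std, on, off = !on) {
  s <- colMeans(F_std$F[on, , drop = FALSE]) -
    colMeans(F_std$F[off, , drop = FALSE])
  s / sqrt(sum(s^2))
}

# window mask for a set of epochs
windowsIn <- function(times_s, epochs) {
  hit <- rep(FALSE, length(times_s))
  for (r in seq_len(nrow(epochs)))
    hit <- hit | (times_s >= epochs$start_s[r] & times_s < epochs$end_s[r])
  hit
}
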