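# shared fixtures and independent oracles, built in code at test time

# filled disc mask (0-based center coordinates)
disc_mask <- function(w, h, cx, cy, r) {
  xs <- matrix(rep(0:(w - 1), each = h), h)
  ys <- matrix(rep(0:(h - 1), times = w), h)
  ((xs - cx)^2 + (ys - cy)^2 <= r^2) * 1
}

# brute-force overlap metrics by explicit pixel loops (independent oracle)
brute_overlap <- function(test, ref) {
  tp <- 0L; fn <- 0L; fp <- 0L; nr <- 0L; nt <- 0L
  for (i in seq_len(nrow(ref))) for (j in seq_len(ncol(ref))) {
    r <- ref[i, j] == 1; t <- test[i, j] == 1
    if (r) nr <- nr + 1L
    if (t) nt <- nt + 1L
    if (r && t) tp <- tp + 1L
    if (r && !t) fn <- fn + 1L
    if (!r && t) fp <- fp + 1L
  }
  list(dice = 2 * tp / (2 * tp + fn + fp),
       jaccard = tp / (tp + fn + fp),
       volume_similarity = 2 * (nt - nr) / (nt + nr),
       fn_fraction = fn / nr, fp_fraction = fp / nr)
}

# exhaustive O(n m) synchronization oracle with the documented tie-breaks
brute_sync <- function(a, b) {
  best <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- abs(a$timestamp_s[i] - b$timestamp_s[j])
    cand <- c(d, a$timestamp_s[i], b$timestamp_s[j], a$frame_id[i], b$frame_id[j])
    if (is.null(best) ||
        d < best[1] ||
        (d == best[1] && (cand[2] < best[2] ||
                          (cand[2] == best[2] && cand[3] < best[3]))))
      best <- cand
  }
  list(delta_t_s = best[1], t_a = best[2], t_b = best[3],
       frame_id_a = best[4], frame_id_b = best[5])
}

# random binary mask with at least one foreground and one background pixel
random_mask <- function(w, h, p = 0.4) {
  m <- matrix(as.numeric(stats::runif(w * h) < p), h, w)
  if (sum(m) == 0) m[1, 1] <- 1
  if (sum(m) == length(m)) m[1, 1] <- 0
  m
}

test_rig <- function() default_rig()
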