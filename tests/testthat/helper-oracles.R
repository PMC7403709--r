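# Independent oracles and small fixture builders shared across test files.

# Naive double-loop symmetrized co-occurrence counts.
naive_glcm_counts <- function(q, dr, dc, G) {
  H <- nrow(q); W <- ncol(q)
  cnt <- matrix(0L, G, G)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W) {
        i <- q[r, c] + 1L; j <- q[r2, c2] + 1L
        cnt[i, j] <- cnt[i, j] + 1L
        cnt[j, i] <- cnt[j, i] + 1L
      }
    }
  }
  cnt
}

# Brute-force pairwise AUC (ties count 1/2).
brute_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# 0/255 checkerboard luminance matrix.
checkerboard <- function(n) {
  255 * outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2)
}

# Gray matrix -> RGB array with identical channels.
gray_to_rgb <- function(m) array(rep(m, 3), dim = c(dim(m), 3))

# Small, fast pipeline configuration for wiring tests.
tiny_pipeline_config <- function(seed = 1, effect_size = 1) {
  pipeline_config(
    cohort = cohort_config(n_patients = 14, tiles_per_patient_min = 3,
                           tiles_per_patient_max = 4, tile_size = 96,
                           effect_size = effect_size),
    bootstrap_B = 200, seed = seed)
}

offset_table <- function() {
  data.frame(angle = c(0, 45, 90, 135), dr = c(0, -1, -1, -1), dc = c(1, 1, 0, -1))
}
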