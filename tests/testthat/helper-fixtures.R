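# Shared fixture builders (all data is generated in code).

# constant-orientation recording: gravity g0 (unit or not), optional extras
const_recording <- function(g0 = c(0, 0, -1), duration = 20, rate = 50,
                            limb_id = "ULL") {
  t <- seq(0, duration, by = 1 / rate)
  limb_recording(t, rep(g0[1], length(t)), rep(g0[2], length(t)),
                 rep(g0[3], length(t)), limb_id = limb_id,
                 sample_rate_hz = rate)
}

# drift series directly from values (bypasses the kinematics pipeline)
toy_series <- function(t, theta, limb_id = "ULL") {
  structure(data.frame(t = t, theta_drift = theta), limb_id = limb_id,
            class = c("drift_series", "data.frame"))
}

# two well-separated Gaussian blobs (linearly separable for gap >= 6)
blob_data <- function(n_per_class = 50, gap = 8, p = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * p), ncol = p),
             matrix(stats::rnorm(n_per_class * p, mean = gap), ncol = p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = factor(rep(c("a", "b"), each = n_per_class)))
}

# brute-force pairwise-concordance AUC (U-statistic with half credit for ties)
auc_ustat <- function(scores, truth, positive) {
  pos <- which(truth == positive)
  neg <- which(truth != positive)
  s <- 0
  for (i in pos) for (j in neg)
    s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  s / (length(pos) * length(neg))
}
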