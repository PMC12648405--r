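# Small geometries and signal builders shared across tests.

line_array <- function(n, pitch = 4, type = "depth", bad = FALSE,
                       prefix = "L") {
  electrode_array(sprintf("%s%02d", prefix, seq_len(n)),
                  cbind((seq_len(n) - 1) * pitch, 0, 0),
                  component_id = paste0(prefix, "comp"),
                  component_type = type, pitch_mm = pitch, bad = bad)
}

grid_row_array <- function(n = 16, pitch = 4) {
  electrode_array(sprintf("G%02d", seq_len(n)),
                  cbind((seq_len(n) - 1) * pitch, 0, 0),
                  component_id = "grid1", component_type = "grid",
                  pitch_mm = pitch, row_id = "R01")
}

noise_recording <- function(n_ch, n_s, fs, sd = 1, seed = 1) {
  set.seed(seed)
  ieeg_recording(matrix(rnorm(n_ch * n_s * fs, 0, sd), n_ch),
                 fs, paste0("ch", seq_len(n_ch)))
}

noise_windows <- function(n_ch, n_win, fs, sd = 1, seed = 1,
                          label = "baseline") {
  set.seed(seed)
  ieeg_windows(array(rnorm(n_ch * fs * n_win, 0, sd), c(n_ch, fs, n_win)),
               fs, paste0("ch", seq_len(n_ch)),
               data.frame(start_sample = NA_integer_,
                          label = rep(label, n_win)))
}

tone_recording <- function(freq, fs, dur_s, amp = 1, n_ch = 1) {
  tt <- (0:(round(dur_s * fs) - 1)) / fs
  x <- amp * sin(2 * pi * freq * tt)
  ieeg_recording(matrix(rep(x, each = n_ch), n_ch), fs,
                 paste0("ch", seq_len(n_ch)))
}

# exact two-sided signed-rank p-value by enumerating all sign assignments
brute_force_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  min(1, mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9) )
}

# exhaustive BH step-up: scan all thresholds p_(k) and apply the step-up rule
brute_force_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= q * seq_len(m) / m)
  rej <- rep(FALSE, m)
  if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}
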