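# Shared fixtures and independent oracles. Heavy simulations are memoised
# so several test files can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small 3-channel, 2-class session for fast pipeline tests
small_session <- function(seed = 11, n_per = 10, depth = 0.5,
                          noise = list(one_over_f_exponent = 1, pink_sd = 1,
                                       white_sd = 0.3, common_sd = 0.3)) {
  simulate_session(sim_config(
    n_trials_per_class = n_per, n_classes = 2, montage = montage_iv2b(),
    depth = depth, seed = seed, noise = noise))
}

# exact null distribution of the Wilcoxon signed-rank statistic W+ for n
# untied pairs, by dynamic programming over the 2^n sign assignments
# (generating-function enumeration); independent of stats::wilcox.test
signed_rank_null_cdf <- function(n) {
  maxw <- n * (n + 1) / 2
  counts <- numeric(maxw + 1)
  counts[1] <- 1                 # W = 0
  for (r in seq_len(n)) {
    shifted <- c(rep(0, r), counts[seq_len(maxw + 1 - r)])
    counts <- counts + shifted
  }
  counts / 2^n                   # P(W = w), w = 0..maxw
}

# two-sided exact p-value by enumeration for paired data without ties
wilcoxon_exact_oracle <- function(a, b) {
  d <- (a - b)[a != b]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  pmf <- signed_rank_null_cdf(n)
  w_all <- 0:(n * (n + 1) / 2)
  p_lo <- sum(pmf[w_all <= W])
  p_hi <- sum(pmf[w_all >= W])
  min(1, 2 * min(p_lo, p_hi))
}

# brute-force Pareto dominance filter: keep points for which no other
# point has <= parameters and >= accuracy (with at least one strict)
pareto_oracle <- function(points) {
  keep <- vapply(seq_len(nrow(points)), function(i) {
    pi <- points$n_parameters[i]; ai <- points$accuracy[i]
    dominated <- any(points$n_parameters <= pi & points$accuracy >= ai &
                       (points$n_parameters < pi | points$accuracy > ai))
    !dominated
  }, TRUE)
  out <- points[keep, ]
  out[order(out$n_parameters), ]
}

# closed-form parameter totals used as an independent check of the graphs
params_proposed_closed_form <- function(C1, C2, K_l, K_s, F1, D, T, N) {
  F2 <- F1 * D
  (C1 * C2 * K_l * D * F1 + D * F1) + 2 * D * F1 +
    D * F1 * (C1 * C2 * K_s) + (D * F1 * F2 + F2) + 2 * F2 +
    (F2 * (T %/% 64) * N + N)
}

params_eegnet_closed_form <- function(C, K_l, F1, D, K_l2, T, N) {
  F2 <- F1 * D
  F1 * K_l + 2 * F1 + D * F1 * C + 2 * F2 + F2 * K_l2 + F2 * F2 + 2 * F2 +
    (F2 * (T %/% 32) * N + N)
}

# minimal EDF writer (int16 records) for adapter round-trip fixtures
write_edf_fixture <- function(path, labels, signal, fs, record_s = 1) {
  ns <- length(labels)
  spr <- as.integer(fs * record_s)
  n_rec <- ncol(signal) %/% spr
  pad <- function(x, n) {
    s <- substr(as.character(x), 1, n)
    paste0(s, strrep(" ", n - nchar(s)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(pad("0", 8), con, eos = NULL)
  writeChar(pad("test patient", 80), con, eos = NULL)
  writeChar(pad("test recording", 80), con, eos = NULL)
  writeChar(pad("01.01.26", 8), con, eos = NULL)
  writeChar(pad("00.00.00", 8), con, eos = NULL)
  writeChar(pad(256 + 256 * ns, 8), con, eos = NULL)
  writeChar(pad("", 44), con, eos = NULL)
  writeChar(pad(n_rec, 8), con, eos = NULL)
  writeChar(pad(record_s, 8), con, eos = NULL)
  writeChar(pad(ns, 4), con, eos = NULL)
  for (l in labels) writeChar(pad(l, 16), con, eos = NULL)
  for (l in labels) writeChar(pad("", 80), con, eos = NULL)
  for (l in labels) writeChar(pad("uV", 8), con, eos = NULL)
  for (l in labels) writeChar(pad("-32768", 8), con, eos = NULL)   # phys min
  for (l in labels) writeChar(pad("32767", 8), con, eos = NULL)    # phys max
  for (l in labels) writeChar(pad("-32768", 8), con, eos = NULL)   # dig min
  for (l in labels) writeChar(pad("32767", 8), con, eos = NULL)    # dig max
  for (l in labels) writeChar(pad("", 80), con, eos = NULL)
  for (l in labels) writeChar(pad(spr, 8), con, eos = NULL)
  for (l in labels) writeChar(pad("", 32), con, eos = NULL)
  for (r in seq_len(n_rec)) for (i in seq_len(ns))
    writeBin(as.integer(round(signal[i, ((r - 1) * spr + 1):(r * spr)])), con,
             size = 2L, endian = "little")
  invisible(path)
}

# minimal GDF v2 writer (int16 channels + mode-1 event table)
write_gdf_fixture <- function(path, labels, signal, fs, events, record_s = 1) {
  ns <- length(labels)
  spr <- as.integer(fs * record_s)
  n_rec <- ncol(signal) %/% spr
  padc <- function(x, n) {
    s <- substr(x, 1, n)
    charToRaw(paste0(s, strrep(" ", n - nchar(s))))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(padc("GDF 2.20", 8), con)
  writeBin(padc("patient", 216), con)                        # patient+recording block
  writeBin(as.integer(n_rec), con, size = 8L, endian = "little")
  writeBin(as.integer(c(record_s, 1)), con, size = 4L, endian = "little")
  writeBin(as.integer(ns), con, size = 2L, endian = "little")
  writeBin(raw(14L), con)
  for (l in labels) writeBin(padc(l, 16), con)
  writeBin(raw(80L * ns), con)
  writeBin(raw(6L * ns), con)
  writeBin(raw(2L * ns), con)
  writeBin(rep(-32768, ns), con, size = 8L, endian = "little")  # phys min
  writeBin(rep(32767, ns), con, size = 8L, endian = "little")   # phys max
  writeBin(rep(-32768, ns), con, size = 8L, endian = "little")  # dig min
  writeBin(rep(32767, ns), con, size = 8L, endian = "little")   # dig max
  writeBin(raw(68L * ns), con)
  writeBin(raw(12L * ns), con)
  writeBin(rep(spr, ns), con, size = 4L, endian = "little")
  writeBin(rep(3L, ns), con, size = 4L, endian = "little")      # int16 type
  writeBin(raw(32L * ns), con)
  for (r in seq_len(n_rec)) for (i in seq_len(ns))
    writeBin(as.integer(round(signal[i, ((r - 1) * spr + 1):(r * spr)])), con,
             size = 2L, endian = "little")
  nev <- nrow(events)
  writeBin(as.raw(1L), con)                                   # mode 1
  writeBin(as.raw(c(nev %% 256, (nev %/% 256) %% 256, nev %/% 65536)), con)
  writeBin(as.numeric(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(events$sample + 1L), con, size = 4L, endian = "little")
  writeBin(as.integer(events$code), con, size = 2L, endian = "little")
  invisible(path)
}
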