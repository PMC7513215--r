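# Minimal EDF writer, test-only: builds a toy continuous EDF recording so
# the package's reader can be exercised round-trip without shipping binary
# fixtures. Single data-record duration, equal rate across signals.
write_toy_edf <- function(path, signals, rate, record_dur = 1) {
  signals <- as.matrix(signals)
  ns <- ncol(signals)
  spr <- as.integer(rate * record_dur)
  stopifnot(nrow(signals) %% spr == 0)
  n_records <- nrow(signals) %/% spr
  labels <- colnames(signals)
  if (is.null(labels)) labels <- sprintf("EEG %03d", seq_len(ns))

  # digital range and per-signal physical calibration
  dmin <- -32768; dmax <- 32767
  # outward-rounded to 2 decimals so the 8-char header fields are exact
  pmin <- floor(apply(signals, 2, min) * 100) / 100
  pmax <- ceiling(apply(signals, 2, max) * 100) / 100
  flat <- pmax - pmin <= 0
  pmax[flat] <- pmin[flat] + 1
  digital <- round(sweep(sweep(signals, 2, pmin), 2,
                         (pmax - pmin) / (dmax - dmin), "/") + dmin)

  pad <- function(x, w) {
    s <- formatC(as.character(x), width = -w)
    substr(paste0(s, strrep(" ", w)), 1, w)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(pad("0", 8))                       # version
  wr(pad("toy patient", 80))
  wr(pad("toy recording", 80))
  wr(pad("01.01.20", 8)); wr(pad("00.00.00", 8))
  wr(pad(256 + ns * 256, 8))            # header bytes
  wr(pad("", 44))
  wr(pad(n_records, 8))
  wr(pad(format(record_dur), 8))
  wr(pad(ns, 4))
  wrv <- function(vals, w) for (v in vals) wr(pad(v, w))
  wrv(labels, 16)
  wrv(rep("", ns), 80)                  # transducer
  wrv(rep("uV", ns), 8)
  wrv(sprintf("%.2f", pmin), 8)
  wrv(sprintf("%.2f", pmax), 8)
  wrv(rep(dmin, ns), 8)
  wrv(rep(dmax, ns), 8)
  wrv(rep("", ns), 80)                  # prefiltering
  wrv(rep(spr, ns), 8)
  wrv(rep("", ns), 32)
  for (rec in seq_len(n_records)) {
    rows <- ((rec - 1L) * spr + 1L):(rec * spr)
    for (s in seq_len(ns))
      writeBin(as.integer(digital[rows, s]), con, size = 2L,
               endian = "little")
  }
  invisible(path)
}
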