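# Preprocessing: resampling to the model rate, zero-padding to the fixed
# input length, the RR-interval measurement oracle, and dataset splits.

#' Resample a record to a target sampling rate
#'
#' Zero-phase band-limited resampling of each lead: when downsampling, a
#' forward-backward Butterworth low-pass ([signal::filtfilt()]) removes
#' content above the new Nyquist frequency without introducing group delay,
#' then the signal is evaluated on the new sample grid by Hann-windowed sinc
#' interpolation. Output length is exactly `round(n * target_fs / fs)` and
#' the time origin is preserved (sample j sits at time j / target_fs).
#'
#' @param rec an [ECGRecord-class].
#' @param target_fs target sampling rate in Hz (default 400).
#' @param order half-width of the interpolation kernel in input samples.
#' @return resampled ECGRecord.
#' @export
resampleRecord <- function(rec, target_fs = 400, order = 16L) {
  stopifnot(methods::is(rec, "ECGRecord"))
  if (target_fs <= 0) stop("target_fs must be positive")
  if (rec@fs == target_fs) return(rec)
  x <- rec@signal
  n <- nrow(x)
  r <- target_fs / rec@fs
  if (r < 1) {  # anti-alias before decimation (zero-phase)
    bf <- signal::butter(8, 0.9 * r)
    x <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  }
  nOut <- round(n * r)
  t <- (seq_len(nOut) - 1) / r             # positions in input samples (0-based)
  idx <- floor(t)
  frac <- t - idx
  pad <- matrix(0, order + 1, 12)
  xp <- rbind(pad, x, pad)
  sig <- matrix(0, nOut, 12)
  for (i in (-order):order) {
    u <- frac - i
    w <- ifelse(u == 0, 1, sin(pi * u) / (pi * u)) *
      (0.5 + 0.5 * cos(pi * u / (order + 0.5)))
    sig <- sig + xp[idx + i + order + 2, , drop = FALSE] * w
  }
  methods::initialize(rec, signal = sig, fs = target_fs)
}

#' Zero-pad a record to a fixed length
#'
#' @param rec an [ECGRecord-class].
#' @param target_len target samples per lead (default 4096).
#' @param placement where the zeros go: at the "end" (default) or
#'   "symmetric" (split between both sides, extra zero at the end).
#' @param long_policy what to do with records longer than `target_len`:
#'   "error" (default) or "crop" (centre crop).
#' @return padded ECGRecord (sampling rate unchanged).
#' @export
zeroPadRecord <- function(rec, target_len = 4096,
                          placement = c("end", "symmetric"),
                          long_policy = c("error", "crop")) {
  stopifnot(methods::is(rec, "ECGRecord"))
  placement <- match.arg(placement)
  long_policy <- match.arg(long_policy)
  n <- nrow(rec@signal)
  if (n == target_len) return(rec)
  if (n > target_len) {
    if (long_policy == "error")
      stop(sprintf("record has %d samples, longer than target_len %d",
                   n, target_len))
    from <- (n - target_len) %/% 2 + 1L
    return(methods::initialize(rec,
      signal = rec@signal[from:(from + target_len - 1L), , drop = FALSE]))
  }
  pad <- target_len - n
  before <- if (placement == "end") 0L else pad %/% 2L
  sig <- rbind(matrix(0, before, 12), rec@signal,
               matrix(0, pad - before, 12))
  methods::initialize(rec, signal = sig)
}

#' Preprocess a record into the fixed model-input shape
#'
#' Resamples to `target_fs` then zero-pads to `target_len`, the canonical
#' 4096 x 12 network input.
#'
#' @inheritParams resampleRecord
#' @inheritParams zeroPadRecord
#' @return ECGRecord with exactly `target_len` samples at `target_fs` Hz.
#' @export
preprocessRecord <- function(rec, target_fs = 400, target_len = 4096,
                             placement = "end", long_policy = "error") {
  zeroPadRecord(resampleRecord(rec, target_fs), target_len,
                placement, long_policy)
}

#' Preprocess a dataset into a model-input tensor
#'
#' @param ds an [ECGDataset-class].
#' @inheritParams preprocessRecord
#' @return list with `x` (n x target_len x 12 array) and `y`
#'   (n x 6 logical label matrix).
#' @export
preprocessDataset <- function(ds, target_fs = 400, target_len = 4096) {
  n <- recordCount(ds)
  x <- array(0, c(n, target_len, 12))
  for (i in seq_len(n))
    x[i, , ] <- ecgSignal(preprocessRecord(records(ds)[[i]],
                                           target_fs, target_len))
  list(x = x, y = labelMatrix(ds))
}

#' Detect R peaks
#'
#' Band-passes one lead (5-25 Hz Butterworth, zero-phase), finds local maxima
#' of the absolute filtered signal above an adaptive amplitude threshold, and
#' enforces a 200 ms refractory period (strongest peak wins). Peak positions
#' are refined to the extremum of the detrended raw signal. A flat or
#' too-quiet signal yields an empty result.
#'
#' @param rec an [ECGRecord-class] of at least 2 s.
#' @param lead lead index to analyse (default 2, lead II).
#' @param min_amplitude minimum filtered amplitude (mV) for any detection.
#' @return integer vector of strictly increasing sample indices.
#' @export
detectRPeaks <- function(rec, lead = 2L, min_amplitude = 0.05) {
  stopifnot(methods::is(rec, "ECGRecord"))
  fs <- rec@fs
  if (nrow(rec@signal) < 2 * fs) stop("record must be at least 2 s long")
  x <- rec@signal[, lead]
  bf <- signal::butter(2, c(5, 25) / (fs / 2), type = "pass")
  z <- abs(signal::filtfilt(bf, x - mean(x)))
  if (max(z) < min_amplitude) return(integer(0))
  thr <- 0.4 * stats::quantile(z, 0.995, names = FALSE)
  n <- length(z)
  cand <- which(z > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[z[cand] >= z[cand - 1] & z[cand] >= z[cand + 1]]
  if (!length(cand)) return(integer(0))
  refr <- round(0.2 * fs)
  keep <- integer(0)
  for (i in cand[order(z[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= refr)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  # refine on the detrended raw lead
  xd <- x - stats::median(x)
  half <- round(0.04 * fs)
  peaks <- vapply(keep, function(i) {
    w <- max(1, i - half):min(n, i + half)
    w[which.max(abs(xd[w]))]
  }, integer(1))
  sort(unique(peaks))
}

#' Measure heart rate, SDNN and PR/QRS intervals
#'
#' A minimal automatic-measurement stand-in: R peaks give the RR series
#' (heart rate = 60 / mean RR; SDNN = sample sd of the NN intervals, reported
#' in ms by default); PR and QRS are estimated on a median beat via an
#' amplitude-floor support rule (QRS) and P-wave local-maximum detection with
#' onset walking (PR). With fewer than 2 beats, rate and SDNN are missing.
#'
#' @param rec an [ECGRecord-class].
#' @param lead lead used for detection and fiducials (default lead II).
#' @param sdnn_scale multiplier applied to the SDNN in seconds before
#'   reporting; the default 1000 reports milliseconds.
#' @param amp_floor amplitude floor (mV) delimiting QRS/P-wave support.
#' @return a [measurementSet()].
#' @export
measureRecord <- function(rec, lead = 2L, sdnn_scale = 1000,
                          amp_floor = 0.02) {
  peaks <- detectRPeaks(rec, lead)
  fs <- rec@fs
  if (length(peaks) < 2L)
    return(measurementSet(n_beats = length(peaks), p_present = NA))
  rr <- diff(peaks) / fs
  hr <- 60 / mean(rr)
  sdnn <- if (length(rr) >= 2L) stats::sd(rr) * sdnn_scale else NA_real_
  fid <- .medianBeatFiducials(rec@signal[, lead], peaks, fs, mean(rr),
                              amp_floor)
  measurementSet(heart_rate = hr, pr_interval = fid$pr,
                 qrs_duration = fid$qrs, sdnn = sdnn,
                 n_beats = length(peaks), p_present = fid$p_present)
}

# Median-beat PR/QRS estimation. Window -380..+450 ms around each R peak;
# QRS support = contiguous region around R where |median beat| exceeds the
# amplitude floor (gaps up to 12 ms bridged, search limited to +/-160 ms);
# P wave = largest interior local maximum in a pre-QRS window, its onset found
# by walking left until the signal drops below the floor or turns back up.
.medianBeatFiducials <- function(x, peaks, fs, mean_rr, amp_floor) {
  pre <- round(min(0.380, 0.5 * mean_rr) * fs)
  post <- round(min(0.450, 0.5 * mean_rr) * fs)
  ok <- peaks - pre >= 1 & peaks + post <= length(x)
  if (!any(ok)) return(list(pr = NA_real_, qrs = NA_real_, p_present = NA))
  mb <- vapply(peaks[ok], function(p) x[(p - pre):(p + post)],
               numeric(pre + post + 1))
  m <- apply(mb, 1, stats::median)
  # baseline = mode of the beat values (flat segments dominate the window)
  dens <- stats::density(m, bw = 0.01, n = 512)
  m <- m - dens$x[which.max(dens$y)]
  r0 <- pre + 1L
  lim <- round(0.160 * fs); gapMax <- round(0.012 * fs)
  walk <- function(dir) {
    i <- r0; last <- r0; gap <- 0L
    repeat {
      j <- i + dir
      if (j < 1L || j > length(m) || abs(j - r0) > lim) break
      if (abs(m[j]) >= amp_floor) { last <- j; gap <- 0L }
      else { gap <- gap + 1L; if (gap > gapMax) break }
      i <- j
    }
    last
  }
  on <- walk(-1L); off <- walk(1L)
  qrs <- (off - on) / fs * 1000
  # P search window before QRS onset
  wlo <- max(2L, on - round(min(0.280, 0.42 * mean_rr) * fs))
  whi <- on - round(0.015 * fs)
  p_present <- FALSE; pr <- NA_real_
  if (whi > wlo + 2) {
    w <- (wlo + 1):(whi - 1)
    locmax <- w[m[w] > m[w - 1] & m[w] >= m[w + 1] & m[w] >= 0.08]
    # a genuine P wave is a narrow prominent bump that repeats beat after
    # beat; broad or beat-inconsistent bumps (neighbouring-beat averaging in
    # irregular rhythm) are rejected
    span <- round(0.10 * fs)
    for (pk in locmax[order(m[locmax], decreasing = TRUE)]) {
      lt <- min(m[max(1L, pk - span):pk])
      rt <- min(m[pk:min(length(m), pk + span)])
      half <- which(m < m[pk] / 2)
      lh <- suppressWarnings(max(half[half < pk]))
      rh <- suppressWarnings(min(half[half > pk]))
      fwhm <- if (is.finite(lh) && is.finite(rh)) (rh - lh) / fs else Inf
      beatSpread <- stats::IQR(mb[pk, ])
      if (m[pk] - max(lt, rt) >= 0.06 && fwhm <= 0.12 &&
          beatSpread <= 0.06) {
        p_present <- TRUE
        i <- pk
        while (i > 1 && m[i] >= amp_floor && m[i - 1] <= m[i]) i <- i - 1L
        # width-based onset bound (2 sd ~ 1.7 x the half-width at half max)
        # guards against slow-tail contamination from the preceding T wave
        if (is.finite(lh)) i <- max(i, pk - round(1.7 * (pk - lh)))
        pr <- (on - i) / fs * 1000
        break
      }
    }
  }
  list(pr = pr, qrs = qrs, p_present = p_present)
}

#' Split a dataset into train/validation/test parts
#'
#' @param x an [ECGDataset-class] or a label/metadata data.frame with columns
#'   `patient_id` and/or `date` as required by the strategy.
#' @param strategy "random", "by_patient" (no patient in two parts) or
#'   "chronological" (order-preserving by acquisition date).
#' @param fractions length-3 fractions summing to 1 (default 0.90/0.05/0.05).
#' @param seed integer seed (random and by_patient strategies).
#' @return list of integer index vectors `train`, `validation`, `test`;
#'   disjoint and exhaustive.
#' @export
splitDataset <- function(x, strategy = c("random", "by_patient",
                                         "chronological"),
                         fractions = c(0.90, 0.05, 0.05), seed = 1) {
  strategy <- match.arg(strategy)
  meta <- if (methods::is(x, "ECGDataset")) labelSidecar(x) else x
  n <- nrow(meta)
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L)
    stop("fractions must be three values summing to 1")
  n1 <- round(n * fractions[1]); n2 <- round(n * fractions[2])
  n3 <- n - n1 - n2
  if (n3 < 0) stop("fractions produce a negative part size")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- switch(strategy,
    random = sample.int(n),
    by_patient = {
      if (is.null(meta$patient_id) || anyNA(meta$patient_id))
        stop("by_patient split requires complete 'patient_id'")
      pats <- sample(unique(meta$patient_id))
      unlist(lapply(pats, function(p) which(meta$patient_id == p)),
             use.names = FALSE)
    },
    chronological = {
      if (is.null(meta$date) || anyNA(meta$date))
        stop("chronological split requires complete 'date'")
      order(meta$date)
    })
  parts <- list(train = integer(0), validation = integer(0),
                test = integer(0))
  if (strategy == "by_patient") {
    # keep whole patients together: fill part 1, then 2, then 3
    bounds <- c(n1, n1 + n2, n)
    part <- 1L; counts <- 0L
    assigned <- integer(n)
    for (p in unique(meta$patient_id[idx])) {
      rows <- which(meta$patient_id == p)
      assigned[rows] <- part
      counts <- counts + length(rows)
      while (part < 3L && counts >= bounds[part]) part <- part + 1L
    }
    parts$train <- which(assigned == 1L)
    parts$validation <- which(assigned == 2L)
    parts$test <- which(assigned == 3L)
  } else {
    parts$train <- sort(idx[seq_len(n1)])
    parts$validation <- sort(idx[n1 + seq_len(n2)])
    parts$test <- sort(idx[n1 + n2 + seq_len(n3)])
    if (strategy == "chronological") {
      parts$train <- idx[seq_len(n1)]
      parts$validation <- idx[n1 + seq_len(n2)]
      parts$test <- idx[n1 + n2 + seq_len(n3)]
    }
  }
  parts
}
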