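# Synthetic 12-lead ECG generator.
#
# Beats are sums of five Gaussian bumps (P, Q, R, S, T) projected onto the 12
# leads through a fixed weight matrix; rhythm is a sampled RR-interval
# sequence (regular sinus with Gaussian jitter, or irregular log-normal RR
# with absent P waves for atrial fibrillation). Every record carries its
# generating parameters back as ground truth, so downstream measurement and
# classification stages can be tested without real data.

WAVES <- c("P", "Q", "R", "S", "T")

#' Default per-lead projection weights for the five beat waves
#'
#' Rows are the 12 leads, columns the P, Q, R, S, T waves. The pattern gives a
#' plausible normal axis: dominant R in II/V5-V6, rS in V1, P upright in II,
#' negative deflections in aVR. Bundle-branch-block morphologies are obtained
#' by overriding the V1/V6 rows (see [synthesizeRecord()]).
#'
#' @return 12 x 5 numeric matrix with lead and wave dimnames.
#' @export
defaultLeadWeights <- function() {
  w <- rbind(
    #        P     Q     R     S     T
    I    = c(0.5,  0.8,  0.7,  0.30, 0.6),
    II   = c(1.0,  1.0,  1.0,  0.40, 1.0),
    III  = c(0.5,  0.6,  0.5,  0.30, 0.4),
    aVR  = c(-0.8, -0.9, -0.9, -0.30, -0.8),
    aVL  = c(0.2,  0.4,  0.3,  0.20, 0.2),
    aVF  = c(0.7,  0.8,  0.8,  0.30, 0.7),
    V1   = c(0.3,  0.2, -0.3,  1.20, 0.2),
    V2   = c(0.3,  0.2,  0.1,  1.00, 0.4),
    V3   = c(0.3,  0.4,  0.5,  0.70, 0.6),
    V4   = c(0.3,  0.7,  0.9,  0.40, 0.8),
    V5   = c(0.3,  0.9,  1.0,  0.25, 0.8),
    V6   = c(0.3,  0.9,  0.9,  0.20, 0.7))
  colnames(w) <- WAVES
  w
}

#' Beat morphology for the Gaussian-bump beat model
#'
#' Parametrises one heartbeat as five Gaussian bumps. Timing convention
#' (milliseconds relative to the R-wave centre): the QRS complex occupies
#' `[-qrs_duration/2, +qrs_duration/2]`; the Q and S bump centres sit at
#' -/+ 0.3 x `qrs_duration` with sd `qrs_duration`/10, so their 2-sd support
#' edges land exactly on the QRS onset/offset; the P-wave onset (centre minus
#' two P sds) precedes the QRS onset by exactly `pr_interval`.
#'
#' @param pr_interval PR interval in ms (P onset to QRS onset).
#' @param qrs_duration QRS duration in ms.
#' @param p_present logical; FALSE removes the P wave (e.g. AF).
#' @param amplitudes named numeric, wave amplitudes in mV for a unit-weight
#'   lead; defaults P 0.15, Q -0.15, R 1.0, S -0.25, T 0.30.
#' @param t_center T-wave centre in ms after the R centre (rate-dependent
#'   in generated records; default 300).
#' @param p_sigma,t_sigma Gaussian sds (ms) of the P and T bumps.
#' @param lead_weights 12 x 5 projection matrix, see [defaultLeadWeights()].
#' @return object of class "BeatMorphology".
#' @export
beatMorphology <- function(pr_interval = 160, qrs_duration = 90,
                           p_present = TRUE,
                           amplitudes = c(P = 0.15, Q = -0.15, R = 1.0,
                                          S = -0.25, T = 0.30),
                           t_center = 300, p_sigma = 25, t_sigma = 40,
                           lead_weights = defaultLeadWeights()) {
  if (qrs_duration <= 0) stop("qrs_duration must be positive")
  if (p_present && pr_interval <= 0)
    stop("pr_interval must be positive when p_present")
  if (p_sigma <= 0 || t_sigma <= 0) stop("wave widths must be positive")
  if (nrow(lead_weights) != 12L)
    stop("lead_weights must have 12 rows (one per lead)")
  amplitudes <- amplitudes[WAVES]
  d <- qrs_duration
  centers <- c(P = -d / 2 - pr_interval + 2 * p_sigma,
               Q = -0.3 * d, R = 0, S = 0.3 * d, T = t_center)
  sigmas <- c(P = p_sigma, Q = d / 10, R = d / 7, S = d / 10, T = t_sigma)
  structure(list(pr_interval = pr_interval, qrs_duration = d,
                 p_present = p_present, amplitudes = amplitudes,
                 centers = centers, sigmas = sigmas,
                 lead_weights = lead_weights),
            class = "BeatMorphology")
}

#' Rhythm specification
#'
#' @param mean_hr mean heart rate in bpm, in (20, 300).
#' @param rr_model "regular_sinus" or "irregular_af".
#' @param rr_jitter_sd sd of the sinus RR jitter, in ms.
#' @param af_sdlog log-scale sd of the log-normal AF RR distribution.
#'   The distribution is parametrised so its mean equals 60/`mean_hr`;
#'   its analytic sd is `mean * sqrt(exp(sdlog^2) - 1)`.
#' @return object of class "RhythmSpec".
#' @export
rhythmSpec <- function(mean_hr = 75, rr_model = c("regular_sinus",
                                                  "irregular_af"),
                       rr_jitter_sd = 30, af_sdlog = 0.25) {
  rr_model <- match.arg(rr_model)
  if (mean_hr <= 20 || mean_hr >= 300)
    stop("mean_hr must lie in (20, 300)")
  if (rr_jitter_sd < 0 || af_sdlog <= 0)
    stop("invalid rhythm variability parameters")
  structure(list(mean_hr = mean_hr, rr_model = rr_model,
                 rr_jitter_sd = rr_jitter_sd, af_sdlog = af_sdlog),
            class = "RhythmSpec")
}

#' Analytic sd (seconds) of the RR distribution of a RhythmSpec
#' @param rhythm a [rhythmSpec()].
#' @return sd of one RR draw, in seconds.
#' @export
rrAnalyticSd <- function(rhythm) {
  m <- 60 / rhythm$mean_hr
  switch(rhythm$rr_model,
         regular_sinus = rhythm$rr_jitter_sd / 1000,
         irregular_af = m * sqrt(exp(rhythm$af_sdlog^2) - 1))
}

#' Synthesize a single beat waveform
#'
#' Evaluates the five Gaussian bumps of a [beatMorphology()] on a sample grid
#' and projects them onto the 12 leads. The returned matrix covers
#' `[min(center - 4 sd), max(center + 4 sd)]` around the R centre.
#'
#' @param morph a BeatMorphology.
#' @param fs sampling rate in Hz.
#' @return samples x 12 matrix (mV) with attributes `r_index` (sample of the
#'   R-wave centre) and `t0_ms` (time of the first sample, ms before R).
#' @export
synthesizeBeat <- function(morph, fs) {
  stopifnot(inherits(morph, "BeatMorphology"))
  if (fs <= 0) stop("fs must be positive")
  if (any(morph$sigmas <= 0)) stop("wave widths must be positive")
  use <- if (morph$p_present) WAVES else setdiff(WAVES, "P")
  t0 <- min(morph$centers[use] - 4 * morph$sigmas[use])
  t1 <- max(morph$centers[use] + 4 * morph$sigmas[use])
  step <- 1000 / fs
  # grid snapped to sample multiples of the R centre, so beats with
  # different wave extents share sample phases
  t <- seq(floor(t0 / step), ceiling(t1 / step)) * step
  bumps <- vapply(WAVES, function(w) {
    if (w == "P" && !morph$p_present) return(numeric(length(t)))
    morph$amplitudes[w] *
      exp(-(t - morph$centers[w])^2 / (2 * morph$sigmas[w]^2))
  }, numeric(length(t)))
  sig <- bumps %*% t(morph$lead_weights)
  colnames(sig) <- ecgLeads()
  attr(sig, "r_index") <- which.min(abs(t))
  attr(sig, "t0_ms") <- t0
  sig
}

#' Sample an RR-interval sequence
#'
#' Draws RR intervals until their cumulative sum reaches at least `duration`.
#' Regular sinus rhythm draws Gaussian RR around 60/`mean_hr`; atrial
#' fibrillation draws log-normal RR (mean 60/`mean_hr`). Draws are truncated
#' to [0.25, 2.5] s.
#'
#' @param rhythm a [rhythmSpec()].
#' @param duration time to cover, in seconds.
#' @return numeric vector of RR intervals in seconds.
#' @export
sampleRRSequence <- function(rhythm, duration) {
  stopifnot(inherits(rhythm, "RhythmSpec"))
  if (duration <= 0) stop("duration must be positive")
  m <- 60 / rhythm$mean_hr
  draw <- function(k) {
    rr <- switch(rhythm$rr_model,
      regular_sinus = stats::rnorm(k, m, rhythm$rr_jitter_sd / 1000),
      irregular_af = stats::rlnorm(
        k, meanlog = log(m) - rhythm$af_sdlog^2 / 2, sdlog = rhythm$af_sdlog))
    pmin(pmax(rr, 0.25), 2.5)
  }
  rr <- draw(ceiling(duration / m) + 4L)
  while (sum(rr) < duration) rr <- c(rr, draw(4L))
  rr[seq_len(which(cumsum(rr) >= duration)[1])]
}

#' Specification of one synthetic record
#'
#' @param ... abnormality class names to set positive (subset of
#'   [ecgClasses()]); the rhythm classes SB, AF and ST are mutually exclusive.
#' @param flags alternatively, a named logical vector as from [labelVector()].
#' @param duration record duration in seconds, in \[7, 10\].
#' @param fs sampling rate in Hz, in \[300, 600\].
#' @param seed optional integer seed for reproducible parameter draws.
#' @param avb_pr_cutoff prolonged-PR cutoff (ms) above which generated
#'   first-degree AV block PR intervals are drawn; default 200.
#' @param noise list with `gaussian_sd` (mV), `baseline_amp` (mV) and
#'   `baseline_freq` (Hz) for additive noise; use [noiseFree()] to disable.
#' @return object of class "SyntheticRecordSpec".
#' @export
syntheticRecordSpec <- function(..., flags = labelVector(...),
                                duration = 10, fs = 400, seed = NULL,
                                avb_pr_cutoff = 200,
                                noise = defaultNoise()) {
  flags <- labelVector(flags)
  if (sum(flags[c("SB", "AF", "ST")]) > 1L)
    stop("rhythm classes SB, AF and ST are mutually exclusive")
  if (flags[["AF"]] && flags[["1dAVb"]])
    stop("1dAVb requires P waves and cannot be combined with AF")
  if (duration < 7 || duration > 10) stop("duration must be in [7, 10] s")
  if (fs < 300 || fs > 600) stop("fs must be in [300, 600] Hz")
  structure(list(flags = flags, duration = duration, fs = fs, seed = seed,
                 avb_pr_cutoff = avb_pr_cutoff, noise = noise),
            class = "SyntheticRecordSpec")
}

#' Default additive-noise parameters (mild Gaussian noise + baseline wander)
#' @export
defaultNoise <- function() list(gaussian_sd = 0.02, baseline_amp = 0.05,
                                baseline_freq = 0.33)

#' Noise-free generation settings
#' @export
noiseFree <- function() list(gaussian_sd = 0, baseline_amp = 0,
                             baseline_freq = 0.33)

# Heart-rate ranges (bpm) used when drawing record parameters. SB < 50 and
# ST > 100 by the class definitions; other ranges keep waves separable at the
# chosen rates (see the methods vignette).
.hrRange <- function(flags) {
  if (flags[["SB"]]) c(35, 48)
  else if (flags[["ST"]]) c(103, 123)
  else if (flags[["AF"]]) c(70, 110)
  else if (flags[["1dAVb"]]) c(55, 80)
  else c(55, 95)
}

#' Synthesize one 12-lead record with ground truth
#'
#' Maps abnormality flags to generating parameters: SB draws mean HR below 50
#' bpm, ST above 100 bpm; first-degree AV block draws a PR interval above the
#' prolonged-PR cutoff; RBBB/LBBB draw QRS duration of at least 120 ms with
#' opposite-polarity V1/V6 QRS projections; AF uses irregular log-normal RR
#' intervals with absent P waves. The returned measurements are the
#' generator's ground truth, not re-estimated from the signal.
#'
#' @param spec a [syntheticRecordSpec()].
#' @param examId,patientId identifiers for the record.
#' @return list with elements `record` ([ECGRecord-class]), `labels` (named
#'   logical vector) and `measurements` ([measurementSet()]).
#' @export
synthesizeRecord <- function(spec, examId = "exam1", patientId = examId) {
  stopifnot(inherits(spec, "SyntheticRecordSpec"))
  if (!is.null(spec$seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
  }
  fl <- spec$flags
  hr <- stats::runif(1, .hrRange(fl)[1], .hrRange(fl)[2])
  pr <- if (fl[["1dAVb"]])
          stats::runif(1, spec$avb_pr_cutoff + 15, spec$avb_pr_cutoff + 85)
        else if (fl[["ST"]]) stats::runif(1, 125, 160)
        else stats::runif(1, 130, 180)
  qrs <- if (fl[["RBBB"]] || fl[["LBBB"]]) stats::runif(1, 125, 150)
         else stats::runif(1, 75, 105)
  w <- defaultLeadWeights()
  if (fl[["RBBB"]]) {           # tall R' in V1, deep wide S in V6
    w["V1", c("R", "S")] <- c(1.2, 0.3)
    w["V6", c("R", "S")] <- c(0.4, 2.8)
  } else if (fl[["LBBB"]]) {    # deep QS in V1, broad monophasic R in V6
    w["V1", c("R", "S")] <- c(0.1, 2.8)
    w["V6", c("R", "S")] <- c(1.2, 0.1)
  }
  rhythm <- rhythmSpec(mean_hr = hr,
                       rr_model = if (fl[["AF"]]) "irregular_af"
                                  else "regular_sinus")
  rr <- sampleRRSequence(rhythm, spec$duration)
  mean_rr <- 60 / hr
  morph <- beatMorphology(
    pr_interval = pr, qrs_duration = qrs, p_present = !fl[["AF"]],
    t_center = max(200, min(330, 420 * mean_rr)), lead_weights = w)

  fs <- spec$fs
  n <- round(spec$duration * fs)
  sig <- matrix(0, n, 12)
  beat <- synthesizeBeat(morph, fs)
  rIdx <- attr(beat, "r_index")
  rTimes <- 0.5 * rr[1] + cumsum(c(0, rr))
  rTimes <- rTimes[rTimes < spec$duration + 0.3]
  for (rt in rTimes) {
    at <- round(rt * fs) + 1L
    lo <- at - rIdx + 1L
    hi <- lo + nrow(beat) - 1L
    if (lo > n || hi < 1L) next
    bi <- seq(max(1L, lo), min(n, hi))
    sig[bi, ] <- sig[bi, ] + beat[bi - lo + 1L, ]
  }
  nz <- spec$noise
  if (nz$gaussian_sd > 0)
    sig <- sig + matrix(stats::rnorm(n * 12, 0, nz$gaussian_sd), n, 12)
  if (nz$baseline_amp > 0) {
    tt <- (seq_len(n) - 1) / fs
    for (l in 1:12)
      sig[, l] <- sig[, l] + nz$baseline_amp *
        sin(2 * pi * nz$baseline_freq * tt + stats::runif(1, 0, 2 * pi))
  }
  inside <- rTimes >= 0 & rTimes <= spec$duration
  rrIn <- diff(rTimes[inside])
  meas <- measurementSet(
    heart_rate = 60 / mean(rrIn),
    pr_interval = if (fl[["AF"]]) NA_real_ else pr,
    qrs_duration = qrs,
    sdnn = if (length(rrIn) >= 2) stats::sd(rrIn) * 1000 else NA_real_,
    n_beats = sum(inside), p_present = !fl[["AF"]])
  list(record = ECGRecord(sig, fs, examId = examId, patientId = patientId),
       labels = fl, measurements = meas)
}

#' Default per-class prevalences
#'
#' Prevalences of the six classes in the study population used as generator
#' defaults: 1dAVb 1.5%, RBBB 2.7%, LBBB 1.7%, SB 1.6%, AF 1.8%, ST 2.1%.
#' @return named numeric vector of length 6.
#' @export
defaultPrevalences <- function() {
  stats::setNames(c(0.015, 0.027, 0.017, 0.016, 0.018, 0.021), ecgClasses())
}

# Draw an n x 6 logical label matrix honouring mutual exclusivity of the
# rhythm classes (SB/AF/ST drawn from one multinomial) and of RBBB/LBBB;
# 1dAVb is suppressed on AF records (no P waves, PR undefined).
.drawLabels <- function(n, prevalences) {
  if (is.null(names(prevalences))) names(prevalences) <- ecgClasses()
  p <- prevalences[ecgClasses()]
  if (any(is.na(p))) stop("prevalences must be named by the canonical classes")
  if (any(p < 0 | p > 1)) stop("prevalences must lie in [0, 1]")
  if (sum(p[c("SB", "AF", "ST")]) > 1)
    stop("rhythm-class prevalences must sum to at most 1")
  if (sum(p[c("RBBB", "LBBB")]) > 1)
    stop("RBBB + LBBB prevalences must sum to at most 1")
  rhythm <- sample(c("none", "SB", "AF", "ST"), n, replace = TRUE,
                   prob = c(1 - sum(p[c("SB", "AF", "ST")]),
                            p["SB"], p["AF"], p["ST"]))
  bbb <- sample(c("none", "RBBB", "LBBB"), n, replace = TRUE,
                prob = c(1 - sum(p[c("RBBB", "LBBB")]),
                         p["RBBB"], p["LBBB"]))
  avb <- stats::runif(n) < p["1dAVb"]
  m <- matrix(FALSE, n, 6, dimnames = list(NULL, ecgClasses()))
  m[cbind(which(rhythm != "none"), match(rhythm[rhythm != "none"],
                                         ecgClasses()))] <- TRUE
  m[cbind(which(bbb != "none"), match(bbb[bbb != "none"], ecgClasses()))] <- TRUE
  m[, "1dAVb"] <- avb & !m[, "AF"]
  m
}

#' Generate a labelled synthetic dataset
#'
#' Draws per-record abnormality flags at the requested prevalences (rhythm
#' classes mutually exclusive), synthesizes each record, and optionally
#' writes the HDF5 tensor + CSV sidecar container (see [writeDataset()]).
#' Fully reproducible under a fixed seed.
#'
#' @param n number of records.
#' @param prevalences named per-class rates in \[0, 1\]; defaults to the
#'   study prevalences ([defaultPrevalences()]).
#' @param duration length-2 range of record durations (s).
#' @param fsChoices sampling rates (Hz) sampled uniformly per record.
#' @param seed integer seed.
#' @param noise additive-noise settings, see [syntheticRecordSpec()].
#' @param avb_pr_cutoff generator PR cutoff for 1dAVb records (ms).
#' @param out optional path of an HDF5 container to write (records are
#'   preprocessed to 400 Hz / 4096 samples for the fixed-shape tensor).
#' @param labelsOut optional CSV sidecar path (defaults next to `out`).
#' @return an [ECGDataset-class] with ground-truth measurements attached.
#' @export
generateDataset <- function(n, prevalences = defaultPrevalences(),
                            duration = c(7, 10),
                            fsChoices = c(300, 400, 500, 600),
                            seed = 1, noise = defaultNoise(),
                            avb_pr_cutoff = 200,
                            out = NULL, labelsOut = NULL) {
  stopifnot(n > 0)
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lab <- .drawLabels(n, prevalences)
  recs <- vector("list", n)
  meas <- vector("list", n)
  ids <- sprintf("exam_%06d", seq_len(n))
  age <- round(stats::runif(n, 16, 90))
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.4, 0.6))
  date <- as.character(as.Date("2017-01-01") + seq_len(n) - 1L)
  for (i in seq_len(n)) {
    spec <- syntheticRecordSpec(
      flags = lab[i, ], duration = stats::runif(1, duration[1], duration[2]),
      fs = sample(fsChoices, 1L), noise = noise,
      avb_pr_cutoff = avb_pr_cutoff)
    r <- synthesizeRecord(spec, examId = ids[i], patientId = ids[i])
    r$record@age <- age[i]; r$record@sex <- sex[i]; r$record@date <- date[i]
    recs[[i]] <- r$record
    meas[[i]] <- as.data.frame(unclass(r$measurements))
  }
  labels <- data.frame(exam_id = ids, as.data.frame(lab, check.names = FALSE),
                       age = age, sex = sex, patient_id = ids, date = date,
                       check.names = FALSE)
  ds <- ECGDataset(recs, labels, do.call(rbind, meas))
  if (!is.null(out)) writeDataset(ds, out, labelsOut)
  ds
}

#' Generate a synthetic dataset directly as a model-input tensor
#'
#' Streaming variant of [generateDataset()] for large training runs: each
#' record is synthesized, preprocessed to 400 Hz / 4096 samples and written
#' into a preallocated tensor, so no per-record objects are retained.
#'
#' @inheritParams generateDataset
#' @return list with `x` (n x 4096 x 12 array), `y` (n x 6 logical label
#'   matrix) and `measurements` (ground-truth data.frame).
#' @export
generateTensor <- function(n, prevalences = defaultPrevalences(),
                           duration = c(7, 10),
                           fsChoices = c(300, 400, 500, 600),
                           seed = 1, noise = defaultNoise(),
                           avb_pr_cutoff = 200) {
  stopifnot(n > 0)
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lab <- .drawLabels(n, prevalences)
  x <- array(0, c(n, 4096L, 12L))
  meas <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- syntheticRecordSpec(
      flags = lab[i, ], duration = stats::runif(1, duration[1], duration[2]),
      fs = sample(fsChoices, 1L), noise = noise,
      avb_pr_cutoff = avb_pr_cutoff)
    r <- synthesizeRecord(spec, examId = sprintf("exam_%06d", i))
    x[i, , ] <- ecgSignal(preprocessRecord(r$record))
    meas[[i]] <- as.data.frame(unclass(r$measurements))
  }
  list(x = x, y = lab, measurements = do.call(rbind, meas))
}
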