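#' Specify planted phase coupling for one frequency band
#'
#' Describes which channel pairs of a simulated recording carry a narrowband
#' carrier with a planted phase-lag relation. Each pair oscillates at
#' `carrier_freq` with a phase difference of `+lag_angle` with probability
#' q = (1 + target_pli) / 2 and `-lag_angle` otherwise, redrawn once per
#' realization block, so the expected PLI over many blocks is exactly
#' |2q - 1| = `target_pli` in the noise-free limit.
#'
#' @param band A [band_definition].
#' @param pairs Data frame with columns `i`, `j` (distinct channel indices),
#'   `target_pli` in \[0, 1\] and `lag_angle` strictly inside (0, pi); an
#'   optional `carrier_freq` column assigns each pair its own carrier
#'   (pairs left at one shared carrier would show spurious cross-pair
#'   synchronization, since two tones at the same frequency hold a constant
#'   phase offset).
#' @param carrier_freq Default carrier frequency in Hz, inside the band,
#'   for pairs without their own.
#' @param background_noise_sd Amplitude SD of channel noise (muV).
#' @return A `coupling_spec` object.
#' @export
#' @examples
#' coupling_spec(band_definition("theta", 4, 8),
#'               data.frame(i = 1, j = 2, target_pli = 0.5, lag_angle = pi / 2),
#'               carrier_freq = 6)
coupling_spec <- function(band, pairs, carrier_freq, background_noise_sd = 10) {
  stop_if_not(inherits(band, "band_definition"), "`band` must be a band_definition")
  stop_if_not(is.data.frame(pairs) &&
                all(c("i", "j", "target_pli", "lag_angle") %in% names(pairs)),
              "`pairs` needs columns i, j, target_pli, lag_angle")
  stop_if_not(all(pairs$i != pairs$j), "pair indices must be distinct")
  stop_if_not(all(pairs$target_pli >= 0 & pairs$target_pli <= 1),
              "target_pli must lie in [0, 1]")
  stop_if_not(all(pairs$lag_angle > 0 & pairs$lag_angle < pi),
              "lag_angle must lie strictly inside (0, pi)")
  stop_if_not(carrier_freq >= band$low && carrier_freq <= band$high,
              "carrier_freq must lie inside the band")
  if (!is.null(pairs$carrier_freq))
    stop_if_not(all(pairs$carrier_freq >= band$low & pairs$carrier_freq <= band$high),
                "per-pair carrier_freq must lie inside the band")
  stop_if_not(background_noise_sd >= 0, "noise SD must be nonnegative")
  structure(list(band = band, pairs = pairs, carrier_freq = carrier_freq,
                 background_noise_sd = background_noise_sd),
            class = "coupling_spec")
}

#' Generate an n-back trial schedule
#'
#' Builds `n_sequences` stimulus sequences of `trials_per_sequence` trials
#' with exactly `n_match_total` matches overall, distributed across
#' sequences as evenly as feasibility allows. For the 2-back task a match
#' means the stimulus equals the one two positions earlier (within its
#' sequence); for the 0-back control a "match" trial shows a character
#' (response target) and non-match trials show an asterisk. Stimulus onsets
#' are spaced 5.0 s apart (0.5 s fixation + 0.5 s stimulus + 4.0 s blank),
#' the first at 0.5 s.
#'
#' @param task `"0-back"` or `"2-back"`.
#' @param n_sequences Number of sequences (default 3).
#' @param trials_per_sequence Trials per sequence (default 40).
#' @param n_match_total Total number of match trials (default 39).
#' @param seed Integer seed.
#' @param n_stimuli Size of the stimulus alphabet (default 25 identities).
#' @return A `trial_schedule`: data frame with `sequence`, `trial`,
#'   `stimulus_id`, `is_match`, `onset_s`, plus `task` and counts as
#'   attributes.
#' @export
#' @examples
#' s <- generate_trial_schedule("2-back", 3, 40, 39, seed = 1)
#' nrow(s); sum(s$is_match)
generate_trial_schedule <- function(task = c("2-back", "0-back"),
                                    n_sequences = 3, trials_per_sequence = 40,
                                    n_match_total = 39, seed = NULL,
                                    n_stimuli = 25) {
  task <- match.arg(task)
  stop_if_not(n_sequences >= 1 && trials_per_sequence >= 1, "counts must be >= 1")
  stop_if_not(n_stimuli >= 25, "stimulus alphabet must offer at least 25 identities")
  max_per_seq <- if (task == "2-back") max(trials_per_sequence - 2, 0) else trials_per_sequence
  stop_if_not(n_match_total >= 0 && n_match_total <= n_sequences * max_per_seq,
              sprintf("infeasible match count: %d matches cannot be placed in %d sequence(s) of %d trials under the %s rule",
                      n_match_total, n_sequences, trials_per_sequence, task))
  # even split, remainder to the earliest sequences, capped by feasibility
  m <- rep(floor(n_match_total / n_sequences), n_sequences)
  extra <- n_match_total - sum(m)
  if (extra > 0) m[seq_len(extra)] <- m[seq_len(extra)] + 1
  while (any(m > max_per_seq)) {
    over <- which(m > max_per_seq)[1]
    room <- which(m < max_per_seq)[1]
    m[room] <- m[room] + (m[over] - max_per_seq)
    m[over] <- max_per_seq
  }
  alphabet <- sprintf("S%02d", seq_len(n_stimuli))
  build <- function() {
    rows <- lapply(seq_len(n_sequences), function(s) {
      L <- trials_per_sequence
      if (task == "2-back") {
        match_pos <- if (m[s] > 0) sort(sample(seq(3, L), m[s])) else integer(0)
        stim <- character(L)
        for (i in seq_len(L)) {
          if (i %in% match_pos) {
            stim[i] <- stim[i - 2]
          } else if (i >= 3) {
            stim[i] <- sample(setdiff(alphabet, stim[i - 2]), 1)
          } else {
            stim[i] <- sample(alphabet, 1)
          }
        }
        is_match <- seq_len(L) %in% match_pos
      } else {
        match_pos <- if (m[s] > 0) sort(sample(seq_len(L), m[s])) else integer(0)
        stim <- rep("*", L)
        stim[match_pos] <- sample(alphabet, m[s], replace = TRUE)
        is_match <- stim != "*"
      }
      data.frame(sequence = s, trial = seq_len(L), stimulus_id = stim,
                 is_match = is_match)
    })
    do.call(rbind, rows)
  }
  df <- if (is.null(seed)) build() else with_seed(seed, build())
  df$onset_s <- 0.5 + 5.0 * (seq_len(nrow(df)) - 1)
  # internal consistency: re-derive the flags from the identities
  rederived <- rederive_matches(df, task)
  stop_if_not(identical(rederived, df$is_match),
              "internal consistency error: n-back rule violated in constructed sequence")
  stop_if_not(sum(df$is_match) == n_match_total,
              "internal consistency error: match count mismatch")
  structure(df, task = task, n_sequences = n_sequences,
            class = c("trial_schedule", "data.frame"))
}

#' Re-derive match flags from stimulus identities
#'
#' Scans a schedule's stimulus identities and applies the task rule
#' (lag-2 equality within sequence for 2-back; character-vs-asterisk for
#' 0-back), independently of any stored flags.
#'
#' @param schedule A `trial_schedule` (or compatible data frame).
#' @param task Task rule to apply; defaults to the schedule's own task.
#' @return Logical vector of derived match flags.
#' @export
rederive_matches <- function(schedule, task = attr(schedule, "task")) {
  if (task == "0-back") return(schedule$stimulus_id != "*")
  unlist(lapply(split(schedule$stimulus_id, schedule$sequence), function(stim) {
    L <- length(stim)
    flags <- logical(L)
    if (L >= 3)
      flags[3:L] <- stim[3:L] == stim[1:(L - 2)]
    flags
  }), use.names = FALSE)
}

#' Generate one phase-coupled channel pair
#'
#' Two narrowband carriers plus independent Gaussian noise. The coupled
#' component of channel b lags channel a by `+lag_angle` with probability
#' q = (1 + target_pli) / 2 and by `-lag_angle` otherwise; the sign is
#' drawn once per realization block (default: one block for the whole
#' duration), giving expected PLI = |2q - 1| = `target_pli` over many
#' blocks in the noise-free limit.
#'
#' @param duration Signal duration in seconds (> 0).
#' @param fs Sampling rate in Hz.
#' @param carrier_freq Carrier frequency in Hz.
#' @param target_pli Target PLI in \[0, 1\].
#' @param lag_angle Coupling lag in radians, strictly inside (0, pi)
#'   (default pi / 2).
#' @param noise_sd Independent noise SD per channel (default 0).
#' @param amplitude Carrier amplitude (default 10 muV).
#' @param flip_interval Seconds between sign redraws (default: `duration`,
#'   i.e. a single realization per call).
#' @param seed Integer seed.
#' @return List with channels `a`, `b`, the per-block `signs`, the block
#'   sample index `block` and `fs`.
#' @export
generate_coupled_pair <- function(duration, fs, carrier_freq, target_pli,
                                  lag_angle = pi / 2, noise_sd = 0,
                                  amplitude = 10, flip_interval = NULL,
                                  seed = NULL) {
  nsamp <- round(duration * fs)
  stop_if_not(nsamp >= 2, "duration x fs must give at least 2 samples")
  stop_if_not(target_pli >= 0 && target_pli <= 1, "target_pli must lie in [0, 1]")
  stop_if_not(lag_angle > 0 && lag_angle < pi, "lag_angle must lie strictly inside (0, pi)")
  if (is.null(flip_interval)) flip_interval <- duration
  q <- (1 + target_pli) / 2
  t <- (seq_len(nsamp) - 1) / fs
  block <- pmin(floor(t / flip_interval) + 1, ceiling(duration / flip_interval))
  nblocks <- max(block)
  gen <- function() {
    phi0 <- runif(1, 0, 2 * pi)
    signs <- ifelse(rbinom(nblocks, 1, q) == 1, 1, -1)
    a <- amplitude * cos(2 * pi * carrier_freq * t + phi0)
    b <- amplitude * cos(2 * pi * carrier_freq * t + phi0 - signs[block] * lag_angle)
    if (noise_sd > 0) {
      a <- a + rnorm(nsamp, 0, noise_sd)
      b <- b + rnorm(nsamp, 0, noise_sd)
    }
    list(a = a, b = b, signs = signs, block = block, fs = fs)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate a multichannel EEG-like recording with planted coupling
#'
#' Every channel starts as independent Gaussian broadband noise; for each
#' pair listed in the coupling specs a phase-coupled carrier pair (see
#' [generate_coupled_pair()]) is added onto the two channels. Uncoupled
#' channel pairs therefore contain independent noise only (expected PLI
#' near 0); output is deterministic given the seed.
#'
#' @param n_channels Number of channels.
#' @param duration Duration in seconds.
#' @param fs Sampling rate in Hz (default 500).
#' @param specs List of [coupling_spec] objects (may be empty).
#' @param seed Integer seed.
#' @param labels Channel labels; defaults to the leading `n_channels`
#'   entries of [default_montage()] (or `chNN` beyond 59).
#' @param noise_sd Background noise SD in muV (default 10).
#' @param amplitude Carrier amplitude in muV (default 10).
#' @param flip_interval Sign-redraw interval in seconds passed to the
#'   coupled-pair generator (default: whole duration).
#' @param condition Optional condition tag.
#' @return An [eeg_recording].
#' @export
generate_recording <- function(n_channels, duration, fs = 500, specs = list(),
                               seed = NULL, labels = NULL, noise_sd = 10,
                               amplitude = 10, flip_interval = NULL,
                               condition = NA_character_) {
  nsamp <- round(duration * fs)
  stop_if_not(nsamp >= 2, "duration x fs must give at least 2 samples")
  if (is.null(labels)) {
    mon <- default_montage()
    labels <- if (n_channels <= length(mon)) mon[seq_len(n_channels)]
              else c(mon, sprintf("ch%02d", seq(length(mon) + 1, n_channels)))[seq_len(n_channels)]
  }
  if (inherits(specs, "coupling_spec")) specs <- list(specs)
  for (sp in specs)
    stop_if_not(all(c(sp$pairs$i, sp$pairs$j) >= 1) &&
                  all(c(sp$pairs$i, sp$pairs$j) <= n_channels),
                "coupling spec references a missing channel")
  gen <- function() {
    data <- matrix(rnorm(n_channels * nsamp, 0, noise_sd), nrow = n_channels)
    for (sp in specs) {
      for (r in seq_len(nrow(sp$pairs))) {
        p <- sp$pairs[r, ]
        cf <- if (!is.null(p$carrier_freq)) p$carrier_freq else sp$carrier_freq
        cp <- generate_coupled_pair(duration, fs, cf,
                                    p$target_pli, p$lag_angle,
                                    noise_sd = 0, amplitude = amplitude,
                                    flip_interval = flip_interval)
        data[p$i, ] <- data[p$i, ] + cp$a
        data[p$j, ] <- data[p$j, ] + cp$b
      }
    }
    data
  }
  data <- if (is.null(seed)) gen() else with_seed(seed, gen())
  eeg_recording(data, fs, labels, condition)
}

# moment-matched log-normal parameters
lnorm_params <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  for (it in 1:1000) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

#' Specify a synthetic two-group cohort
#'
#' Defaults emulate the demographics, behavior and connectivity calibration
#' of a young (n = 15) vs senior (n = 10) working-memory EEG study:
#' education 16.1 +/- 1.9 vs 9.3 +/- 3.0 years, age 23.1 +/- 2.0 vs
#' 64.0 +/- 3.3 years, 0-back/2-back accuracy and reaction-time moments per
#' group, and theta-band mean target PLI of 0.205 (young) vs 0.223 (senior)
#' in the 2-back condition with between-subject SDs 0.019 / 0.038 obtained
#' from the reported standard errors times sqrt(n). Recording-scale
#' parameters default to a demo scale (8 channels, 12-trial task blocks,
#' 35 s rest) so that a full cohort is desk-computable; they are not part
#' of the scientific calibration and can be raised to the full 59-channel,
#' 120-trial scale.
#'
#' @param n_young,n_senior Group sizes (default 15 / 10).
#' @param n_channels Channels per recording (default 8).
#' @param fs Sampling rate (default 500 Hz).
#' @param rest_duration Rest recording length in seconds (default 35).
#' @param n_sequences,trials_per_sequence,n_match_total Task schedule shape
#'   (defaults 1 sequence of 12 trials with 4 matches at demo scale).
#' @param pli_mean Named list: band -> condition -> c(young, senior) mean
#'   target PLI.
#' @param pli_sd Same structure, between-subject SD of the target PLI.
#' @param lag_angle Coupling lag (default pi / 2).
#' @param carrier_freq Named list band -> carrier Hz (default: band centre).
#' @param flip_interval Sign-redraw interval in seconds (default 0.25).
#' @param noise_sd,amplitude Signal scale in muV (defaults 10 / 10).
#' @param education,age Named lists `young`/`senior` of c(mean, sd).
#' @param accuracy,reaction_time Named lists task -> group -> c(mean, sd)
#'   (accuracy on \[0, 1\], RT in ms).
#' @param coupled_pairs Two-column matrix of channel index pairs carrying
#'   the planted coupling (default: consecutive disjoint pairs).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_young = 15, n_senior = 10,
                        n_channels = 8, fs = 500, rest_duration = 35,
                        n_sequences = 1, trials_per_sequence = 12, n_match_total = 4,
                        pli_mean = list(theta = list(
                          "rest" = c(young = 0.205, senior = 0.205),
                          "0-back" = c(young = 0.205, senior = 0.205),
                          "2-back" = c(young = 0.205, senior = 0.223))),
                        pli_sd = list(theta = list(
                          "rest" = c(young = 0.019, senior = 0.038),
                          "0-back" = c(young = 0.019, senior = 0.038),
                          "2-back" = c(young = 0.019, senior = 0.038))),
                        lag_angle = pi / 2, carrier_freq = NULL,
                        flip_interval = 0.25, noise_sd = 10, amplitude = 10,
                        education = list(young = c(16.1, 1.9), senior = c(9.3, 3.0)),
                        age = list(young = c(23.1, 2.0), senior = c(64.0, 3.3)),
                        accuracy = list(
                          "0-back" = list(young = c(0.95, 0.03), senior = c(0.88, 0.10)),
                          "2-back" = list(young = c(0.96, 0.03), senior = c(0.73, 0.20))),
                        reaction_time = list(
                          "0-back" = list(young = c(497, 109), senior = c(660, 127)),
                          "2-back" = list(young = c(743, 244), senior = c(1092, 527))),
                        coupled_pairs = NULL) {
  stop_if_not(n_young >= 1 && n_senior >= 1, "group counts must be >= 1")
  for (b in names(pli_mean)) for (cn in names(pli_mean[[b]])) {
    stop_if_not(all(pli_mean[[b]][[cn]] >= 0 & pli_mean[[b]][[cn]] <= 1),
                "mean target PLI must lie in [0, 1]")
    stop_if_not(all(pli_sd[[b]][[cn]] >= 0), "PLI SDs must be nonnegative")
  }
  for (tk in names(accuracy)) for (g in names(accuracy[[tk]])) {
    stop_if_not(accuracy[[tk]][[g]][1] >= 0 && accuracy[[tk]][[g]][1] <= 1,
                "accuracy means must lie in [0, 1]")
    stop_if_not(accuracy[[tk]][[g]][2] >= 0, "accuracy SDs must be nonnegative")
  }
  if (is.null(coupled_pairs)) {
    k <- floor(n_channels / 2)
    coupled_pairs <- cbind(2 * seq_len(k) - 1, 2 * seq_len(k))
  }
  structure(list(n_young = n_young, n_senior = n_senior,
                 n_channels = n_channels, fs = fs, rest_duration = rest_duration,
                 n_sequences = n_sequences, trials_per_sequence = trials_per_sequence,
                 n_match_total = n_match_total,
                 pli_mean = pli_mean, pli_sd = pli_sd, lag_angle = lag_angle,
                 carrier_freq = carrier_freq, flip_interval = flip_interval,
                 noise_sd = noise_sd, amplitude = amplitude,
                 education = education, age = age,
                 accuracy = accuracy, reaction_time = reaction_time,
                 coupled_pairs = coupled_pairs),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with recordings, schedules and behavior
#'
#' Draws per-subject covariates, behavioral outcomes (truncated-normal
#' accuracy in \[0, 1\], log-normal reaction times) and per-subject target
#' PLIs from the group distributions, then simulates one recording per
#' condition (rest, 0-back, 2-back) with the planted coupling.
#'
#' @param spec A [cohort_spec].
#' @param seed Integer seed.
#' @param conditions Conditions to simulate recordings for (default all
#'   three); covariates and behavior are always generated.
#' @return A `cohort` list: `table` (one row per subject: id, group coded
#'   young = 0 / senior = 1, age, education, accuracy and RT per task,
#'   per-band per-condition subject target PLI), `recordings` (per subject,
#'   named by condition), `schedules` (per task), the spec and the seed.
#' @export
generate_cohort <- function(spec, seed = NULL,
                            conditions = c("rest", "0-back", "2-back")) {
  stop_if_not(inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec")
  n <- spec$n_young + spec$n_senior
  group <- c(rep(0L, spec$n_young), rep(1L, spec$n_senior))
  gname <- ifelse(group == 0, "young", "senior")
  bands <- default_bands()
  task_dur <- 0.5 + 5.0 * spec$n_sequences * spec$trials_per_sequence + 3.5
  run <- function() {
    tab <- data.frame(id = sprintf("sub%02d", seq_len(n)), group = group,
                      age = NA_real_, education = NA_real_)
    for (g in c("young", "senior")) {
      idx <- gname == g
      tab$age[idx] <- rtrunc_norm(sum(idx), spec$age[[g]][1], spec$age[[g]][2], lo = 0)
      tab$education[idx] <- rtrunc_norm(sum(idx), spec$education[[g]][1],
                                        spec$education[[g]][2], lo = 0)
    }
    for (tk in names(spec$accuracy)) {
      acc <- rt <- numeric(n)
      for (g in c("young", "senior")) {
        idx <- gname == g
        a <- spec$accuracy[[tk]][[g]]
        r <- spec$reaction_time[[tk]][[g]]
        acc[idx] <- rtrunc_norm(sum(idx), a[1], a[2], lo = 0, hi = 1)
        lp <- lnorm_params(r[1], r[2])
        rt[idx] <- exp(rnorm(sum(idx), lp$meanlog, lp$sdlog))
      }
      tab[[paste0("accuracy_", sub("-back", "back", tk))]] <- acc
      tab[[paste0("rt_", sub("-back", "back", tk))]] <- rt
    }
    # per-subject, per-band, per-condition target PLI
    targets <- list()
    for (b in names(spec$pli_mean)) for (cn in names(spec$pli_mean[[b]])) {
      v <- numeric(n)
      for (g in c("young", "senior")) {
        idx <- gname == g
        v[idx] <- rtrunc_norm(sum(idx), spec$pli_mean[[b]][[cn]][[g]],
                              spec$pli_sd[[b]][[cn]][[g]], lo = 0, hi = 1)
      }
      targets[[paste(b, cn, sep = ".")]] <- v
      tab[[paste0("target_pli_", b, "_", sub("-back", "back", cn))]] <- v
    }
    schedules <- list(
      "0-back" = generate_trial_schedule("0-back", spec$n_sequences,
                                         spec$trials_per_sequence,
                                         spec$n_match_total),
      "2-back" = generate_trial_schedule("2-back", spec$n_sequences,
                                         spec$trials_per_sequence,
                                         spec$n_match_total))
    recordings <- vector("list", n)
    for (s in seq_len(n)) {
      recs <- list()
      for (cn in conditions) {
        dur <- if (cn == "rest") spec$rest_duration else task_dur
        specs <- list()
        for (b in names(spec$pli_mean)) {
          if (is.null(spec$pli_mean[[b]][[cn]])) next
          np <- nrow(spec$coupled_pairs)
          # pairs get evenly spread carriers so cross-pair tones drift apart
          # instead of holding a constant (spuriously synchronized) offset
          cfs <- if (!is.null(spec$carrier_freq[[b]])) rep_len(spec$carrier_freq[[b]], np)
                 else bands[[b]]$low + (seq_len(np) - 0.5) * (bands[[b]]$high - bands[[b]]$low) / np
          pairs <- data.frame(i = spec$coupled_pairs[, 1],
                              j = spec$coupled_pairs[, 2],
                              target_pli = targets[[paste(b, cn, sep = ".")]][s],
                              lag_angle = spec$lag_angle,
                              carrier_freq = cfs)
          specs <- c(specs, list(coupling_spec(bands[[b]], pairs, cfs[1],
                                               spec$noise_sd)))
        }
        recs[[cn]] <- generate_recording(spec$n_channels, dur, spec$fs, specs,
                                         noise_sd = spec$noise_sd,
                                         amplitude = spec$amplitude,
                                         flip_interval = spec$flip_interval,
                                         condition = cn)
      }
      recordings[[s]] <- recs
    }
    names(recordings) <- tab$id
    list(table = tab, recordings = recordings, schedules = schedules)
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(c(out, list(spec = spec, seed = seed)), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d young, %d senior), conditions: %s\n",
              nrow(x$table), sum(x$table$group == 0), sum(x$table$group == 1),
              paste(names(x$recordings[[1]]), collapse = ", ")))
  invisible(x)
}
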