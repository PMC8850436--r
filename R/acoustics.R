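#' The f0 x VTL stimulus grid
#'
#' Voice targets vary along two axes in 2-semitone steps: a congruent axis
#' (f0 and formant spacing shifted in the same direction, biologically likely
#' covariation) and an incongruent axis (opposite directions).  Per carrier
#' word the full grid holds 1 baseline + 8 modified conditions; the rtMRI
#' session used only the baseline and the four +/- 4 semitone endpoints.
#'
#' Sign convention: \code{vtl_shift_st > 0} means formant frequencies are
#' raised (a shorter apparent tract, the "small" voice condition);
#' \code{vtl_shift_st < 0} is the "large" condition.
#'
#' @param session \code{"full"} (audio session, 9 conditions) or
#'   \code{"rtmri"} (5 conditions).
#' @return data.frame of condition labels: \code{f0_shift_st},
#'   \code{vtl_shift_st}, \code{axis} (\code{baseline}, \code{congruent},
#'   \code{incongruent}), \code{vt_condition} (\code{baseline}, \code{small},
#'   \code{large}), \code{condition} (compact label).
#' @export
build_stimulus_grid <- function(session = c("full", "rtmri")) {
  session <- match.arg(session)
  steps <- c(-4, -2, 2, 4)
  grid <- rbind(
    data.frame(f0_shift_st = 0, vtl_shift_st = 0, axis = "baseline"),
    data.frame(f0_shift_st = steps, vtl_shift_st = steps, axis = "congruent"),
    data.frame(f0_shift_st = steps, vtl_shift_st = -steps,
               axis = "incongruent")
  )
  if (session == "rtmri")
    grid <- grid[abs(grid$f0_shift_st) %in% c(0, 4), , drop = FALSE]
  grid$vt_condition <- ifelse(grid$vtl_shift_st > 0, "small",
                              ifelse(grid$vtl_shift_st < 0, "large",
                                     "baseline"))
  grid$condition <- sprintf("f0%+d_vtl%+d", grid$f0_shift_st,
                            grid$vtl_shift_st)
  grid$condition[grid$axis == "baseline"] <- "baseline"
  rownames(grid) <- NULL
  grid
}

#' Enumerate the trials of an imitation session
#'
#' The audio session presents each of the 18 word-condition combinations
#' (9 grid conditions x 2 words) in 2 blocks of 5 trials (180 trials); the
#' rtMRI session presents each of the 10 combinations (5 conditions x 2
#' words) in 10 blocks of 4 trials (400 trials).
#'
#' @param session \code{"audio"} or \code{"rtmri"}.
#' @param words carrier words.
#' @param blocks,trials_per_block block structure; defaults follow the
#'   session type.
#' @return data.frame with one row per trial: \code{trial}, \code{block},
#'   \code{word} and the grid condition columns.
#' @export
enumerate_trials <- function(session = c("audio", "rtmri"),
                             words = c("bead", "bard"),
                             blocks = NULL, trials_per_block = NULL) {
  session <- match.arg(session)
  grid <- build_stimulus_grid(if (session == "audio") "full" else "rtmri")
  if (is.null(blocks)) blocks <- if (session == "audio") 2L else 10L
  if (is.null(trials_per_block))
    trials_per_block <- if (session == "audio") 5L else 4L
  cells <- merge(data.frame(word = words), grid)
  out <- cells[rep(seq_len(nrow(cells)), each = blocks * trials_per_block), ]
  out$block <- rep(rep(seq_len(blocks), each = trials_per_block),
                   times = nrow(cells))
  rownames(out) <- NULL
  out$trial <- seq_len(nrow(out))
  out
}

#' Apply a grid condition to a baseline recording's measurements
#'
#' Target construction first shifts the baseline f0 two semitones upward
#' (headroom for the lower-pitched targets), then applies the condition's
#' shifts as frequency ratios: f0 by \code{2^((2 + f0_shift)/12)} and every
#' formant by \code{2^(vtl_shift/12)}.
#'
#' @param baseline one-row data.frame (or list) with \code{f0_hz},
#'   \code{F1_hz} .. \code{F4_hz} of the unmodified recording.
#' @param condition one row of \code{\link{build_stimulus_grid}}.
#' @return the take with shifted frequencies; condition columns attached.
#' @export
apply_grid_to_baseline <- function(baseline, condition) {
  take <- as.data.frame(as.list(baseline))
  take$f0_hz <- take$f0_hz * 2^((2 + condition$f0_shift_st) / 12)
  for (f in c("F1_hz", "F2_hz", "F3_hz", "F4_hz"))
    take[[f]] <- take[[f]] * 2^(condition$vtl_shift_st / 12)
  take$f0_shift_st <- condition$f0_shift_st
  take$vtl_shift_st <- condition$vtl_shift_st
  take$condition <- condition$condition
  take$vt_condition <- condition$vt_condition
  take
}

#' Frequency modulation in semitones
#'
#' \code{12 * log2(observed / baseline)}: the log-ratio of an observed
#' frequency to its baseline, expressed in semitones (12 per octave).
#'
#' @param observed_hz,baseline_hz frequencies in Hz (> 0); vectorized.
#' @return modulation in semitones.
#' @export
semitone_modulation <- function(observed_hz, baseline_hz) {
  if (any(!is.finite(observed_hz)) || any(observed_hz <= 0) ||
      any(!is.finite(baseline_hz)) || any(baseline_hz <= 0))
    stop("frequencies must be positive and finite", call. = FALSE)
  12 * log2(observed_hz / baseline_hz)
}

#' Apparent vocal tract length from formant frequencies
#'
#' Pools F1..F4 through the quarter-wavelength resonator model: formant i of
#' a uniform closed-open tube of length L lies at \code{(2i - 1) c / (4 L)},
#' so each formant yields a length estimate \code{(2i - 1) c / (4 F_i)}; the
#' apparent vocal tract length is their mean.
#'
#' @param take one-row data.frame (or list) with \code{F1_hz} .. \code{F4_hz};
#'   alternatively a numeric vector of the four formant frequencies in Hz.
#' @param c_cm_s speed of sound in cm/s.
#' @return apparent vocal tract length in cm.
#' @export
compute_avtl <- function(take, c_cm_s = 35000) {
  f <- if (is.numeric(take)) take
       else unlist(take[c("F1_hz", "F2_hz", "F3_hz", "F4_hz")],
                   use.names = FALSE)
  if (length(f) != 4L || any(!is.finite(f)) || any(f <= 0))
    stop("need four positive formant frequencies", call. = FALSE)
  mean((2 * (1:4) - 1) * c_cm_s / (4 * f))
}

#' Select the representative token of a condition cell
#'
#' Picks the take with the smallest total deviation from the within-cell
#' medians of f0, F1 and F2, deviation measured in semitones so pitch and
#' formants are commensurable.  Ties break toward the lowest
#' \code{take_index}.
#'
#' @param takes data.frame of takes of one speaker/word/condition cell, with
#'   columns \code{take_index}, \code{f0_hz}, \code{F1_hz}, \code{F2_hz}.
#' @return the selected row.
#' @export
select_representative_token <- function(takes) {
  if (is.null(takes) || nrow(takes) == 0L)
    stop("no takes to select from", call. = FALSE)
  dev <- abs(semitone_modulation(takes$f0_hz, stats::median(takes$f0_hz))) +
    abs(semitone_modulation(takes$F1_hz, stats::median(takes$F1_hz))) +
    abs(semitone_modulation(takes$F2_hz, stats::median(takes$F2_hz)))
  ord <- order(dev, takes$take_index)
  takes[ord[1L], , drop = FALSE]
}

#' Per-take modulation records relative to the speaker-word baseline
#'
#' For every take of one speaker and carrier word, computes the semitone
#' modulation of f0, F1..F4 and aVTL relative to the median of the
#' baseline-condition takes of that speaker and word.
#'
#' @param takes data.frame of all takes for one speaker and word: columns
#'   \code{speaker_id}, \code{word}, \code{condition}, \code{vt_condition},
#'   \code{take_index}, \code{f0_hz}, \code{F1_hz} .. \code{F4_hz}.
#' @param c_cm_s speed of sound for the aVTL composite.
#' @return long data.frame of modulation records: one row per take x measure
#'   with columns \code{speaker_id}, \code{word}, \code{condition},
#'   \code{vt_condition}, \code{take_index}, \code{measure},
#'   \code{modulation_st}.  aVTL modulation is the semitone log-ratio of the
#'   take's aVTL to the baseline median aVTL.
#' @export
modulation_table <- function(takes, c_cm_s = 35000) {
  base <- takes[takes$vt_condition == "baseline", , drop = FALSE]
  if (nrow(base) == 0L)
    stop("no baseline-condition takes for speaker '",
         takes$speaker_id[1L], "', word '", takes$word[1L], "'",
         call. = FALSE)
  avtl <- apply(takes[, c("F1_hz", "F2_hz", "F3_hz", "F4_hz")], 1L,
                compute_avtl, c_cm_s = c_cm_s)
  ref <- c(f0 = stats::median(base$f0_hz),
           F1 = stats::median(base$F1_hz), F2 = stats::median(base$F2_hz),
           F3 = stats::median(base$F3_hz), F4 = stats::median(base$F4_hz),
           aVTL = stats::median(avtl[takes$vt_condition == "baseline"]))
  obs <- cbind(f0 = takes$f0_hz, F1 = takes$F1_hz, F2 = takes$F2_hz,
               F3 = takes$F3_hz, F4 = takes$F4_hz, aVTL = avtl)
  recs <- lapply(colnames(obs), function(m) {
    out <- data.frame(speaker_id = takes$speaker_id, word = takes$word,
                      condition = takes$condition,
                      vt_condition = takes$vt_condition,
                      take_index = takes$take_index, measure = m,
                      modulation_st = semitone_modulation(obs[, m], ref[[m]]))
    for (extra in c("f0_shift_st", "vtl_shift_st"))
      if (extra %in% names(takes)) out[[extra]] <- takes[[extra]]
    out
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
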