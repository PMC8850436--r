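#' Construct a synthetic speaker profile
#'
#' Houses the between-speaker variation the pipeline measures: baseline
#' vocal-tract shape, the larynx-height excursion used when imitating small
#' or large voice targets (modulation skill), baseline voice measures, and
#' imaging noise.
#'
#' @param speaker_id character label.
#' @param sex \code{"male"} or \code{"female"}.
#' @param singer logical; prior vocal training.
#' @param baseline_params \code{\link{shape_params}} at rest.
#' @param modulation_amplitude larynx-height excursion (dimensionless,
#'   >= 0) applied with positive sign in small-voice and negative sign in
#'   large-voice conditions; must keep \code{larynx_height} within [-1, 1].
#' @param baseline_f0_hz baseline fundamental frequency, Hz.
#' @param baseline_vtl_cm baseline vocal tract length, cm (> 0).
#' @param frame_noise_sd imaging noise SD in intensity units.
#' @return \code{"speaker_profile"} object.
#' @export
speaker_profile <- function(speaker_id, sex = c("female", "male"),
                            singer = FALSE,
                            baseline_params = shape_params(),
                            modulation_amplitude = 0.5,
                            baseline_f0_hz = if (sex[1L] == "male") 120 else 210,
                            baseline_vtl_cm = if (sex[1L] == "male") 16.5 else 14.5,
                            frame_noise_sd = 0) {
  sex <- match.arg(sex)
  validate_shape_params(baseline_params)
  if (modulation_amplitude < 0)
    stop("modulation_amplitude must be >= 0", call. = FALSE)
  if (abs(baseline_params$larynx_height) + modulation_amplitude > 1)
    stop("modulation_amplitude would push larynx_height outside [-1, 1]",
         call. = FALSE)
  if (baseline_vtl_cm <= 0) stop("baseline_vtl_cm must be > 0", call. = FALSE)
  structure(list(speaker_id = as.character(speaker_id), sex = sex,
                 singer = singer, baseline_params = baseline_params,
                 modulation_amplitude = modulation_amplitude,
                 baseline_f0_hz = baseline_f0_hz,
                 baseline_vtl_cm = baseline_vtl_cm,
                 frame_noise_sd = frame_noise_sd),
            class = "speaker_profile")
}

#' Simulate an rtMRI imitation session for one speaker
#'
#' For each trial of the design, draws frames of the posed phantom: the
#' trial's carrier word sets the tongue position, the vocal-tract condition
#' sets the larynx height (\code{baseline + amplitude} when imitating small
#' targets, \code{baseline - amplitude} for large), small random rigid head
#' motion perturbs each frame, and articulatory jitter perturbs the shape
#' parameters trial to trial.  Every frame's exact generating parameters,
#' head-motion transform and pre-noise outline are recorded as ground truth.
#'
#' @param profile a \code{\link{speaker_profile}}.
#' @param design trial data.frame (see \code{\link{enumerate_trials}}); only
#'   \code{word} and the grid condition columns are used.
#' @param seed integer seed; the session is a pure function of
#'   (profile, design, seed).
#' @param frames_per_trial frames drawn per trial.
#' @param word_tongue tongue-position targets per carrier word.
#' @param jitter_sd trial-to-trial articulatory variability (SD of the
#'   perturbation added to tongue position/shape, curvature and larynx
#'   height); within-speaker variability is exposed rather than fixed.
#' @param motion_sd_mm,motion_sd_deg per-frame head-motion SDs.
#' @param cfg render configuration.
#' @return list with \code{series} (an \code{\link{image_series}}) and
#'   \code{truth}: \code{frames} (per-frame table of true parameters, rigid
#'   registration transform parameters and true centerline length),
#'   \code{outlines} (list of true \code{vt_contour}s in reference space)
#'   and \code{takes} (per-take true tract lengths in cm).
#' @export
simulate_speaker_session <- function(profile, design, seed = 1L,
                                     frames_per_trial = 2L,
                                     word_tongue = c(bead = 0.8, bard = -0.8),
                                     jitter_sd = 0.05,
                                     motion_sd_mm = 1, motion_sd_deg = 0.5,
                                     cfg = render_config()) {
  stopifnot(inherits(profile, "speaker_profile"))
  if (!all(design$word %in% names(word_tongue)))
    stop("design contains words without a tongue-position target",
         call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))

  n_fr <- nrow(design) * frames_per_trial
  frames <- array(0, c(cfg$ny, cfg$nx, n_fr))
  outlines <- vector("list", n_fr)
  rows <- vector("list", n_fr)
  bp <- profile$baseline_params
  clamp <- function(v) pmin(pmax(v, -1), 1)
  k <- 0L
  for (tr in seq_len(nrow(design))) {
    cond <- design$vt_condition[tr]
    amp <- switch(cond, small = profile$modulation_amplitude,
                  large = -profile$modulation_amplitude, 0)
    for (fr in seq_len(frames_per_trial)) {
      k <- k + 1L
      par <- shape_params(
        tongue_position = clamp(word_tongue[[design$word[tr]]] +
                                  stats::rnorm(1, 0, jitter_sd)),
        larynx_height = clamp(bp$larynx_height + amp +
                                stats::rnorm(1, 0, jitter_sd)),
        body_scale = bp$body_scale,
        tongue_shape = clamp(bp$tongue_shape + stats::rnorm(1, 0, jitter_sd)),
        curvature = clamp(bp$curvature + stats::rnorm(1, 0, jitter_sd)))
      motion <- rigid_transform(stats::rnorm(1, 0, motion_sd_deg),
                                stats::rnorm(1, 0, motion_sd_mm),
                                stats::rnorm(1, 0, motion_sd_mm))
      outl <- make_vocal_tract_contour(par)
      f <- render_frame(outl, motion, profile$frame_noise_sd,
                        seed = sample.int(.Machine$integer.max, 1L), cfg = cfg,
                        frame_index = k)
      frames[, , k] <- f$intensities
      outlines[[k]] <- vt_contour(unclass(outl), closed = TRUE,
                                  frame_index = k)
      reg <- rigid_invert(motion)      # transform registering frame -> ref
      rows[[k]] <- data.frame(
        frame_index = k, speaker_id = profile$speaker_id,
        word = design$word[tr], vt_condition = cond,
        f0_shift_st = design$f0_shift_st[tr],
        vtl_shift_st = design$vtl_shift_st[tr], trial = tr,
        tongue_position = par$tongue_position,
        larynx_height = par$larynx_height, body_scale = par$body_scale,
        tongue_shape = par$tongue_shape, curvature = par$curvature,
        reg_rotation_deg = reg$rotation_deg, reg_tx_mm = reg$tx_mm,
        reg_ty_mm = reg$ty_mm,
        true_length_mm = measure_centerline_length(par))
    }
  }
  truth_frames <- do.call(rbind, rows)
  labels <- truth_frames[, c("frame_index", "speaker_id", "word",
                             "vt_condition", "f0_shift_st", "vtl_shift_st")]
  takes <- stats::aggregate(true_length_mm ~ trial + word + vt_condition,
                            truth_frames, mean)
  takes$true_vtl_cm <- takes$true_length_mm / 10
  takes$speaker_id <- profile$speaker_id
  list(series = image_series(frames, cfg$pixel_size_mm, labels),
       truth = list(frames = truth_frames, outlines = outlines,
                    takes = takes))
}

#' Simulate formant measurements of a tube resonator
#'
#' Formants follow the quarter-wavelength model \code{F_i = (2i-1) c / (4 L)}
#' multiplied by a word-specific perturbation vector (vowel coloring) and
#' lognormal measurement noise with a given coefficient of variation.
#'
#' @param true_vtl_cm tract length in cm (> 0).
#' @param word \code{"bead"} or \code{"bard"}; selects the perturbation
#'   vector.  Defaults: bard scales F1 by 1.4 and F2 by 0.75; bead scales
#'   F1 by 0.55 and F2 by 1.45; F3 and F4 are unscaled.
#' @param f0_hz fundamental frequency to record on the take.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise (0 disables noise).
#' @param seed integer seed.
#' @param word_perturbation named list of length-4 multipliers per word, or
#'   \code{NULL} to disable vowel coloring.
#' @param c_cm_s speed of sound in cm/s.
#' @return one-row data.frame with \code{f0_hz}, \code{F1_hz} .. \code{F4_hz}.
#' @export
simulate_formants <- function(true_vtl_cm, word = c("bead", "bard"),
                              f0_hz = 150, noise_cv = 0, seed = 1L,
                              word_perturbation = list(
                                bard = c(1.4, 0.75, 1, 1),
                                bead = c(0.55, 1.45, 1, 1)),
                              c_cm_s = 35000) {
  if (!is.numeric(true_vtl_cm) || true_vtl_cm <= 0)
    stop("true_vtl_cm must be > 0", call. = FALSE)
  word <- match.arg(word)
  seed <- as.integer(seed)   # force before any RNG state handling
  f <- (2 * (1:4) - 1) * c_cm_s / (4 * true_vtl_cm)
  if (!is.null(word_perturbation)) f <- f * word_perturbation[[word]]
  if (noise_cv > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    sdlog <- sqrt(log(1 + noise_cv^2))
    f <- f * stats::rlnorm(4, -sdlog^2 / 2, sdlog)
    f0_hz <- f0_hz * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
  }
  data.frame(f0_hz = f0_hz, F1_hz = f[1], F2_hz = f[2], F3_hz = f[3],
             F4_hz = f[4], word = word, true_vtl_cm = true_vtl_cm)
}

#' Simulate an audio imitation session (acoustic measurement table)
#'
#' Generates per-take f0/F1..F4 measurements for one speaker over the
#' stimulus grid.  The speaker reproduces a fraction of each nominal shift
#' (\code{fidelity} for vocal-tract length, \code{f0_fidelity} for pitch):
#' the take's true tract length is
#' \code{baseline_vtl * 2^(-vtl_shift * fidelity / 12)}.
#'
#' @param profile a \code{\link{speaker_profile}}.
#' @param session grid to imitate (\code{"full"} or \code{"rtmri"}).
#' @param takes_per_condition takes per word x condition cell.
#' @param fidelity fraction of the nominal formant shift achieved (1 =
#'   perfect imitator, 0 = non-modulator).
#' @param f0_fidelity fraction of the nominal f0 shift achieved.
#' @param noise_cv measurement noise CV passed to
#'   \code{\link{simulate_formants}}.
#' @param seed integer seed.
#' @param word_perturbation vowel-coloring multipliers, see
#'   \code{\link{simulate_formants}}.
#' @return data.frame of takes with speaker/word/condition labels, true
#'   tract lengths, and measured frequencies.
#' @export
simulate_acoustic_session <- function(profile, session = c("full", "rtmri"),
                                      takes_per_condition = 5L,
                                      fidelity = 1, f0_fidelity = 1,
                                      noise_cv = 0.02, seed = 1L,
                                      word_perturbation = list(
                                        bard = c(1.4, 0.75, 1, 1),
                                        bead = c(0.55, 1.45, 1, 1))) {
  stopifnot(inherits(profile, "speaker_profile"))
  grid <- build_stimulus_grid(match.arg(session))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  out <- list()
  for (w in c("bead", "bard")) {
    for (i in seq_len(nrow(grid))) {
      vtl <- profile$baseline_vtl_cm *
        2^(-grid$vtl_shift_st[i] * fidelity / 12)
      f0 <- profile$baseline_f0_hz *
        2^(grid$f0_shift_st[i] * f0_fidelity / 12)
      for (tk in seq_len(takes_per_condition)) {
        take <- simulate_formants(vtl, w, f0, noise_cv,
                                  seed = sample.int(.Machine$integer.max, 1L),
                                  word_perturbation = word_perturbation)
        take$speaker_id <- profile$speaker_id
        take$sex <- profile$sex
        take$condition <- grid$condition[i]
        take$vt_condition <- grid$vt_condition[i]
        take$f0_shift_st <- grid$f0_shift_st[i]
        take$vtl_shift_st <- grid$vtl_shift_st[i]
        take$take_index <- tk
        out[[length(out) + 1L]] <- take
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default generative effect structure for perception ratings
#'
#' @param grand_mean_cm grand means of perceived height per voice sex.
#' @param vt_effect_cm fixed effect of vocal-tract condition on perceived
#'   height (cm added for \code{large}, subtracted for \code{small});
#'   speakers lengthening their tract sound taller.
#' @param f0_slope_cm_per_st fixed effect of f0 modulation (cm per semitone;
#'   negative: higher pitch sounds shorter).
#' @param interaction_cm vt x f0 interaction (cm), applied as
#'   \code{interaction * sign(vt) * f0/4}.
#' @param skill_gain multiplier on the vt effect for the good skill group.
#' @param listener_sd,speaker_sd random intercept SDs (cm).
#' @param speaker_slope_sd random vt- and f0-slope SD within speaker.
#' @param residual_sd residual rating noise (cm).
#' @return list of effect parameters.
#' @export
rating_effects <- function(grand_mean_cm = c(female = 162.5, male = 172.5),
                           vt_effect_cm = 3, f0_slope_cm_per_st = -0.8,
                           interaction_cm = 0, skill_gain = 2,
                           listener_sd = 2, speaker_sd = 2,
                           speaker_slope_sd = 0.5, residual_sd = 4) {
  as.list(environment())
}

#' Sex-specific slider range of the height scale
#' @param sex \code{"female"} or \code{"male"} (vectorized).
#' @return 2-column matrix of lower/upper bounds in cm (females 145-180,
#'   males 155-190).
#' @export
slider_range_cm <- function(sex) {
  lo <- ifelse(sex == "male", 155, 145)
  cbind(lower = lo, upper = lo + 35)
}

#' Simulate listener height ratings for a stimulus set
#'
#' Generates one rating per listener x stimulus following the perceived-
#' height model: grand mean + fixed effects of vocal-tract condition, f0
#' modulation, their interaction and skill group + a normal listener
#' intercept + normal speaker intercept and slopes + residual noise, clipped
#' to the sex-specific slider range.  Each listener rates a single voice
#' sex.
#'
#' @param stimuli data.frame with one row per stimulus: \code{speaker_id},
#'   \code{voice_sex}, \code{skill_group} (\code{good}/\code{poor}),
#'   \code{word}, \code{vt_condition} (\code{small}/\code{baseline}/
#'   \code{large}), \code{f0_shift_st}.
#' @param effects a \code{\link{rating_effects}} list.
#' @param n_listeners listeners per voice sex (>= 1).
#' @param seed integer seed.
#' @return data.frame of perception trials with \code{listener_id},
#'   stimulus labels and \code{rating_cm}.
#' @export
simulate_perception_ratings <- function(stimuli, effects = rating_effects(),
                                        n_listeners = 20L, seed = 1L) {
  if (n_listeners < 1L) stop("n_listeners must be >= 1", call. = FALSE)
  need <- c("speaker_id", "voice_sex", "skill_group", "vt_condition",
            "f0_shift_st")
  miss <- setdiff(need, names(stimuli))
  if (length(miss))
    stop("stimulus table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  req <- c("grand_mean_cm", "vt_effect_cm", "f0_slope_cm_per_st",
           "interaction_cm", "skill_gain", "listener_sd", "speaker_sd",
           "speaker_slope_sd", "residual_sd")
  miss <- setdiff(req, names(effects))
  if (length(miss))
    stop("effect table lacks terms: ", paste(miss, collapse = ", "),
         call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))

  spk <- unique(stimuli$speaker_id)
  spk_int <- stats::setNames(stats::rnorm(length(spk), 0, effects$speaker_sd),
                             spk)
  spk_vt <- stats::setNames(stats::rnorm(length(spk), 0,
                                         effects$speaker_slope_sd), spk)
  spk_f0 <- stats::setNames(stats::rnorm(length(spk), 0,
                                         effects$speaker_slope_sd), spk)
  out <- list()
  for (sx in unique(stimuli$voice_sex)) {
    st <- stimuli[stimuli$voice_sex == sx, , drop = FALSE]
    rng <- slider_range_cm(sx)[1L, ]
    vt_sign <- ifelse(st$vt_condition == "large", 1,
                      ifelse(st$vt_condition == "small", -1, 0))
    gain <- ifelse(st$skill_group == "good", effects$skill_gain, 1)
    fixed <- effects$grand_mean_cm[[sx]] +
      gain * effects$vt_effect_cm * vt_sign +
      effects$f0_slope_cm_per_st * st$f0_shift_st +
      effects$interaction_cm * vt_sign * st$f0_shift_st / 4 +
      spk_int[st$speaker_id] +
      spk_vt[st$speaker_id] * vt_sign + spk_f0[st$speaker_id] *
      st$f0_shift_st
    for (li in seq_len(n_listeners)) {
      l_int <- stats::rnorm(1, 0, effects$listener_sd)
      r <- fixed + l_int + stats::rnorm(nrow(st), 0, effects$residual_sd)
      r <- pmin(pmax(r, rng["lower"]), rng["upper"])
      out[[length(out) + 1L]] <- data.frame(
        listener_id = sprintf("L_%s_%03d", substr(sx, 1, 1), li),
        voice_sex = sx, speaker_id = st$speaker_id,
        skill_group = st$skill_group, word = st$word,
        vt_condition = st$vt_condition, f0_shift_st = st$f0_shift_st,
        rating_cm = r)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate contours spanning the five planted shape modes
#'
#' Draws independent normal shape parameters whose standard deviations are
#' calibrated (by finite-difference sensitivities of the resampled contour)
#' so that the five deformation modes contribute prescribed shares of total
#' contour variance.  Used to validate that functional PCA recovers the
#' planted decomposition.
#'
#' @param n number of contours.
#' @param shares length-5 variance shares for (tongue position, vocal-tract
#'   length, body size, tongue shape, curvature); normalized internally.
#'   Defaults emulate the decomposition observed on the study data.
#' @param rms_mm overall root-mean-square contour perturbation in mm.  The
#'   default keeps all five modes well inside their linear range (the
#'   constriction-tilt mode changes wall arc length quadratically, and at
#'   larger amplitudes that quadratic term masquerades as a spurious sixth
#'   mode).
#' @param n_points resampling resolution used for calibration and output.
#' @param seed integer seed.
#' @return list with \code{params} (n x 5 matrix of drawn parameters),
#'   \code{curves} (n x 2\code{n_points} matrix of resampled contours),
#'   \code{sd} (calibrated parameter SDs) and \code{shares} (normalized
#'   planted shares).
#' @export
plant_shape_modes <- function(n = 500L,
                              shares = c(0.407, 0.340, 0.093, 0.082, 0.034),
                              rms_mm = 0.12, n_points = 100L, seed = 1L) {
  stopifnot(length(shares) == 5L, all(shares > 0))
  shares <- shares / sum(shares)
  fields <- c("tongue_position", "larynx_height", "body_scale",
              "tongue_shape", "curvature")
  base <- c(0, 0, 1, 0, 0)
  flat <- function(p) {
    pp <- shape_params(p[1], p[2], p[3], p[4], p[5])
    as.vector(unclass(resample_contour(make_vocal_tract_contour(pp),
                                       n_points)))
  }
  f0 <- flat(base)
  eps <- 0.02
  g <- vapply(1:5, function(k) {
    d <- base; d[k] <- d[k] + eps
    sqrt(sum((flat(d) - f0)^2)) / eps
  }, numeric(1))
  total_var <- (rms_mm^2) * 2 * n_points     # variance in concatenated space
  sd <- sqrt(shares * total_var) / g

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  ## draw normal scores, then whiten the sample so the realized parameter
  ## covariance is exactly diagonal with the calibrated variances — the
  ## planted shares are a design property of the generator, not an estimate
  Z <- matrix(stats::rnorm(n * 5L), n, 5L)
  Z <- sweep(Z, 2L, colMeans(Z))
  Z <- Z %*% solve(chol(stats::cov(Z)))
  params <- sweep(Z, 2L, sd, `*`)
  colnames(params) <- fields
  ## keep parameters inside their domains (draws beyond +-1 would be
  ## rejected by the generator); with default scales this never triggers.
  params[, -3] <- pmin(pmax(params[, -3], -0.99), 0.99)
  params[, 3] <- pmax(params[, 3] + 1, 0.05)
  curves <- t(apply(params, 1L, function(p)
    flat(c(p[1], p[2], p[3], p[4], p[5]))))
  list(params = params, curves = curves, sd = sd, shares = shares)
}
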