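#' Compact session design (one row per trial)
#'
#' @param session \code{"rtmri"} or \code{"audio"} grid.
#' @param words carrier words.
#' @param trials_per_condition trials per word x condition cell.
#' @return trial design data.frame for
#'   \code{\link{simulate_speaker_session}}.
#' @export
session_design <- function(session = c("rtmri", "audio"),
                           words = c("bead", "bard"),
                           trials_per_condition = 1L) {
  session <- match.arg(session)
  grid <- build_stimulus_grid(if (session == "rtmri") "rtmri" else "full")
  cells <- merge(data.frame(word = words), grid)
  out <- cells[rep(seq_len(nrow(cells)), each = trials_per_condition), ]
  rownames(out) <- NULL
  out$trial <- seq_len(nrow(out))
  out
}

#' Generate a synthetic speaker cohort
#'
#' Speakers receive graded vocal-tract modulation amplitudes; acoustic
#' imitation fidelity is coupled to the same latent modulation skill (plus
#' independent noise), emulating the study's finding that tract and
#' acoustic modulation covary.
#'
#' @param n_per_sex speakers per sex.
#' @param amp_range range of \code{modulation_amplitude} spanned evenly
#'   within each sex.
#' @param fidelity_noise_sd SD of the noise decoupling acoustic fidelity
#'   from tract amplitude (0 = perfectly coupled).
#' @param singer_fraction fraction of speakers marked as trained singers
#'   (assigned to the highest amplitudes).
#' @param frame_noise_sd imaging noise of each speaker's session.
#' @param seed integer seed.
#' @return list with \code{profiles} (list of
#'   \code{\link{speaker_profile}}s) and \code{table} (cohort summary
#'   data.frame with the planted amplitudes and fidelities).
#' @export
make_speaker_cohort <- function(n_per_sex = 10L, amp_range = c(0.05, 0.85),
                                fidelity_noise_sd = 0.1,
                                singer_fraction = 0.5,
                                frame_noise_sd = 0, seed = 1L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  profiles <- list()
  rows <- list()
  for (sx in c("female", "male")) {
    amps <- seq(amp_range[1], amp_range[2], length.out = n_per_sex)
    singer <- rank(amps, ties.method = "first") >
      n_per_sex * (1 - singer_fraction)
    for (i in seq_len(n_per_sex)) {
      id <- sprintf("S_%s_%02d", substr(sx, 1, 1), i)
      fid <- min(max(amps[i] / max(amp_range) +
                       stats::rnorm(1, 0, fidelity_noise_sd), 0.02), 1)
      f0_fid <- stats::runif(1, 0.6, 1)   # pitch matching mostly unrelated
                                          # to tract modulation skill
      pr <- speaker_profile(
        id, sx, singer = singer[i],
        baseline_params = shape_params(
          tongue_position = stats::runif(1, -0.1, 0.1),
          larynx_height = stats::runif(1, -0.1, 0.1),
          body_scale = if (sx == "male") stats::runif(1, 1.02, 1.08)
                       else stats::runif(1, 0.94, 1.0),
          tongue_shape = stats::runif(1, -0.2, 0.2),
          curvature = stats::runif(1, -0.2, 0.2)),
        modulation_amplitude = amps[i],
        frame_noise_sd = frame_noise_sd)
      profiles[[id]] <- pr
      rows[[id]] <- data.frame(speaker_id = id, sex = sx,
                               singer = singer[i],
                               modulation_amplitude = amps[i],
                               fidelity = fid, f0_fidelity = f0_fid,
                               baseline_vtl_cm = pr$baseline_vtl_cm,
                               baseline_f0_hz = pr$baseline_f0_hz)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(profiles = profiles, table = tab)
}

#' Pipeline configuration
#'
#' Validates paths and stage parameters for \code{\link{run_pipeline}}.
#' Either a simulation block is given (the pipeline generates its own
#' cohort) or paths to an existing image series and take table.
#'
#' @param out_dir output directory (created if absent).
#' @param simulate list of cohort options (\code{n_per_sex},
#'   \code{frames_per_trial}, \code{trials_per_condition},
#'   \code{takes_per_condition}, \code{frame_noise_sd},
#'   \code{n_listeners}) or \code{NULL} to run on supplied inputs.
#' @param series_path,takes_path inputs when \code{simulate} is NULL.
#' @param variance_quantile,closing_px,dilate_px candidate-mask stage
#'   parameters.
#' @param n_points,n_components fPCA stage parameters.
#' @param n_per_group speakers per skill group and sex.
#' @param avtl_c speed of sound (cm/s) for the aVTL composite.
#' @param seed master seed; all stage seeds derive from it.
#' @return validated \code{"pipeline_config"} list.
#' @export
pipeline_config <- function(out_dir,
                            simulate = list(n_per_sex = 3L,
                                            frames_per_trial = 1L,
                                            trials_per_condition = 1L,
                                            takes_per_condition = 3L,
                                            frame_noise_sd = 0,
                                            n_listeners = 2L),
                            series_path = NULL, takes_path = NULL,
                            variance_quantile = 0.85, closing_px = 6L,
                            dilate_px = 4L, n_points = 100L,
                            n_components = 5L, n_per_group = 1L,
                            avtl_c = 35000, seed = 1L) {
  if (is.null(simulate)) {
    for (p in c(series_path, takes_path))
      if (is.null(p) || !file.exists(p))
        stop("input path missing or nonexistent: ",
             if (is.null(p)) "(NULL)" else p, call. = FALSE)
  }
  if (variance_quantile <= 0 || variance_quantile >= 1)
    stop("variance_quantile must be in (0, 1)", call. = FALSE)
  cfg <- list(out_dir = out_dir, simulate = simulate,
              series_path = series_path, takes_path = takes_path,
              variance_quantile = variance_quantile,
              closing_px = closing_px, dilate_px = dilate_px,
              n_points = n_points, n_components = n_components,
              n_per_group = n_per_group, avtl_c = avtl_c,
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages simulate (optional), segment, fpca, acoustics,
#' scores and perception in order, writing each stage's outputs as
#' delimited text (and NIfTI for images) into the configured output
#' directory before the next stage starts.  A run manifest with per-stage
#' wall-clock, output checksums and the configuration is written at the
#' end (also on failure, recording the failure point).
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return the manifest, invisibly (list; also written as
#'   \code{manifest.json}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = paste("vtmod",
                                as.character(utils::packageVersion("vtmod"))),
                   seed = config$seed, stages = list())
  t_all <- proc.time()[3]
  paths <- character(0)
  stage <- function(name, fun) {
    t0 <- proc.time()[3]
    res <- fun()
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[3] - t0, 2),
      outputs = lapply(res$outputs, function(p)
        list(path = basename(p), md5 = unname(tools::md5sum(p)))))
    paths <<- c(paths, res$outputs)
    res$value
  }
  finish <- function(error = NULL) {
    manifest$error <- error
    manifest$total_seconds <- round(proc.time()[3] - t_all, 2)
    tmp <- file.path(config$out_dir, ".manifest.json.tmp")
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    file.rename(tmp, file.path(config$out_dir, "manifest.json"))
    manifest
  }
  out <- function(...) file.path(config$out_dir, ...)

  res <- tryCatch({
    ## -- simulate ---------------------------------------------------------
    sims <- NULL; takes <- NULL; cohort <- NULL
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      cohort <- make_speaker_cohort(sim$n_per_sex,
                                    frame_noise_sd = sim$frame_noise_sd,
                                    seed = config$seed)
      design <- session_design("rtmri",
                               trials_per_condition =
                                 sim$trials_per_condition)
      sims <- stage("simulate", function() {
        s <- list(); tk <- list(); outs <- character(0)
        for (i in seq_along(cohort$profiles)) {
          pr <- cohort$profiles[[i]]
          ses <- simulate_speaker_session(
            pr, design, seed = config$seed + 7L * i,
            frames_per_trial = sim$frames_per_trial)
          s[[pr$speaker_id]] <- ses
          ac <- simulate_acoustic_session(
            pr, "rtmri", takes_per_condition = sim$takes_per_condition,
            fidelity = cohort$table$fidelity[i],
            f0_fidelity = cohort$table$f0_fidelity[i],
            seed = config$seed + 7L * i + 1L)
          tk[[pr$speaker_id]] <- ac
          outs <- c(outs, write_image_series(
            ses$series, out(sprintf("series_%s.nii.gz", pr$speaker_id))))
        }
        takes <<- do.call(rbind, tk)
        outs <- c(outs, write_table_tsv(takes, out("acoustic_takes.tsv")),
                  write_table_tsv(cohort$table, out("cohort.tsv")))
        list(value = s, outputs = outs)
      })
    } else {
      series_in <- read_image_series(config$series_path)
      takes <- read_table_tsv(config$takes_path)
      sims <- list(input = list(series = series_in, truth = NULL))
    }

    ## -- segment ----------------------------------------------------------
    static_mask <- static_structure_mask()
    reference <- get_frame(sims[[1L]]$series, 1L)
    seg <- stage("segment", function() {
      all_out <- list(); lab <- list()
      for (nm in names(sims)) {
        reg <- register_series(sims[[nm]]$series, reference, static_mask)
        sr <- segment_series(reg$series, config$variance_quantile,
                             config$closing_px, TRUE, config$dilate_px,
                             static_mask = static_mask)
        all_out[[nm]] <- sr$outlines
        lab[[nm]] <- sims[[nm]]$series$labels
      }
      outlines <- do.call(c, unname(all_out))
      labels <- do.call(rbind, unname(lab))
      p <- out("outlines.tsv")
      write_contours(outlines, p)
      list(value = list(outlines = outlines, labels = labels),
           outputs = p)
    })

    ## -- fpca -------------------------------------------------------------
    fp <- stage("fpca", function() {
      model <- vt_fpca(seg$outlines, n_components = config$n_components,
                       n_points = config$n_points)
      defs <- canonical_deformations(config$n_points)
      len_k <- match_component(model, defs[, "larynx_height"])
      ref <- matrix(NA_real_, nrow(defs), ncol(model$efuns))
      ref[, len_k] <- defs[, "larynx_height"]
      model <- orient_components(model, ref)
      scores <- predict(model, labels = seg$labels)
      p <- out("fpc_scores.tsv")
      write_table_tsv(scores, p)
      list(value = list(model = model, scores = scores,
                        length_component = len_k), outputs = p)
    })

    ## -- acoustics --------------------------------------------------------
    mods <- stage("acoustics", function() {
      m <- do.call(rbind, lapply(
        split(takes, list(takes$speaker_id, takes$word), drop = TRUE),
        modulation_table, c_cm_s = config$avtl_c))
      rownames(m) <- NULL
      p <- out("modulations.tsv")
      write_table_tsv(m, p)
      list(value = m, outputs = p)
    })

    ## -- scores -----------------------------------------------------------
    sk <- stage("scores", function() {
      vt <- vt_skill_score(fp$scores, fp$length_component)
      sex_map <- unique(takes[, c("speaker_id", "sex")])
      vt <- merge(vt, sex_map, by = "speaker_id")
      grouped <- rank_and_group(vt, config$n_per_group)
      assoc <- do.call(rbind, lapply(
        c("f0", "F1", "F2", "F3", "F4", "aVTL"), function(m)
          skill_acoustic_association(grouped, acoustic_skill_score(mods, m),
                                     measure = m)))
      p1 <- out("skill_records.tsv"); p2 <- out("associations.tsv")
      write_table_tsv(grouped, p1)
      write_table_tsv(assoc, p2)
      list(value = list(skills = grouped, associations = assoc),
           outputs = c(p1, p2))
    })

    ## -- perception -------------------------------------------------------
    stage("perception", function() {
      stim <- assemble_stimulus_set(sk$skills, takes)
      trials <- simulate_perception_ratings(
        stim, n_listeners = if (!is.null(config$simulate))
          config$simulate$n_listeners else 2L,
        seed = config$seed + 1000L)
      rnd <- if (length(unique(trials$speaker_id)) >= 8L) "slopes"
             else "intercepts"
      fit <- fit_height_model(build_height_design(trials, random = rnd),
                              contrasts = FALSE)
      p1 <- out("perception_trials.tsv"); p2 <- out("height_coefficients.tsv")
      write_table_tsv(trials, p1)
      write_table_tsv(fit$coefficients, p2)
      list(value = fit, outputs = c(p1, p2))
    })
    finish()
  }, error = function(e) {
    finish(error = conditionMessage(e))
    stop(e)
  })
  invisible(res)
}
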