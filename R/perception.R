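#' Map a height-slider percentile to centimetres
#'
#' The rating slider spans the 1st to the 99th percentile of adult height:
#' 145-180 cm for female voices, 155-190 cm for male voices, linear in
#' slider position.
#'
#' @param percentile slider position in [1, 99] (vectorized).
#' @param sex \code{"female"} or \code{"male"}.
#' @return height in cm.
#' @export
percentile_to_cm <- function(percentile, sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (any(percentile < 1 | percentile > 99))
    stop("percentile must lie in [1, 99]", call. = FALSE)
  rng <- slider_range_cm(sex)[1L, ]
  rng[["lower"]] + (percentile - 1) / 98 * (rng[["upper"]] - rng[["lower"]])
}

#' Assemble the perception-experiment stimulus set
#'
#' For each voice sex, takes the good and poor modulator groups (from
#' \code{\link{rank_and_group}}) and selects one representative token per
#' speaker x word x condition cell over the five rtMRI-endpoint conditions,
#' yielding (5 good + 5 poor) x 2 words x 5 conditions = 100 stimuli per
#' sex on a complete cohort.
#'
#' @param skills grouped skill table with \code{speaker_id}, \code{sex},
#'   \code{group}.
#' @param takes acoustic take table covering all five conditions x 2 words
#'   for every grouped speaker (columns as in
#'   \code{\link{simulate_acoustic_session}}).
#' @param words carrier words expected in every cell.
#' @return stimulus data.frame: one selected take per cell with
#'   \code{skill_group} and \code{voice_sex} columns.
#' @export
assemble_stimulus_set <- function(skills, takes, words = c("bead", "bard")) {
  grouped <- skills[skills$group %in% c("good", "poor"), , drop = FALSE]
  conds <- build_stimulus_grid("rtmri")$condition
  missing_cells <- character(0)
  out <- list()
  for (i in seq_len(nrow(grouped))) {
    sp <- grouped$speaker_id[i]
    for (w in words) for (cn in conds) {
      cell <- takes[takes$speaker_id == sp & takes$word == w &
                      takes$condition == cn, , drop = FALSE]
      if (nrow(cell) == 0L) {
        missing_cells <- c(missing_cells,
                           sprintf("(%s, %s, %s)", sp, w, cn))
        next
      }
      tok <- select_representative_token(cell)
      tok$skill_group <- grouped$group[i]
      tok$voice_sex <- grouped$sex[i]
      out[[length(out) + 1L]] <- tok
    }
  }
  if (length(missing_cells))
    stop("missing take cells: ", paste(missing_cells, collapse = ", "),
         call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the perceived-height model design
#'
#' Constructs the fixed- and random-effect design of the perceived-height
#' mixed model: all interactions of skill group, vocal-tract condition, f0
#' modulation and voice sex as fixed effects (treatment coding with
#' baseline condition, poor group and female voices as references), a
#' random listener intercept, and random intercept plus f0- and
#' vt-condition slopes within speaker.
#'
#' @param trials perception-trial data.frame with \code{listener_id},
#'   \code{speaker_id}, \code{skill_group}, \code{vt_condition},
#'   \code{f0_shift_st}, \code{voice_sex}, \code{rating_cm}.
#' @param f0_as_factor treat f0 modulation as a factor instead of
#'   continuous semitones.
#' @param random \code{"slopes"} for the full structure (listener
#'   intercept; speaker intercept + f0 and vt-condition slopes) or
#'   \code{"intercepts"} for intercepts only, which small cohorts cannot
#'   identify the slope covariances from.
#' @return list with \code{formula} (lme4 model formula), \code{data}
#'   (recoded trials), \code{fixed} (fixed-effect model matrix) and
#'   \code{spec} (coding description).
#' @export
build_height_design <- function(trials, f0_as_factor = FALSE,
                                random = c("slopes", "intercepts")) {
  random <- match.arg(random)
  need <- c("listener_id", "speaker_id", "skill_group", "vt_condition",
            "f0_shift_st", "voice_sex", "rating_cm")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(unique(trials$listener_id)) < 2L ||
      length(unique(trials$speaker_id)) < 2L)
    stop("need at least 2 listeners and 2 speakers", call. = FALSE)
  d <- trials
  refs <- c(skill_group = "poor", vt_condition = "baseline",
            voice_sex = "female")
  for (f in names(refs)) {
    d[[f]] <- factor(d[[f]])
    if (nlevels(d[[f]]) < 2L)
      stop("factor '", f, "' has a single level", call. = FALSE)
    if (refs[[f]] %in% levels(d[[f]]))
      d[[f]] <- stats::relevel(d[[f]], ref = refs[[f]])
  }
  d$f0_modulation <- if (f0_as_factor) factor(d$f0_shift_st)
                     else as.numeric(d$f0_shift_st)
  fixed_terms <- "skill_group * vt_condition * f0_modulation * voice_sex"
  rand_terms <- if (random == "slopes")
    "(1 | listener_id) + (1 + f0_modulation + vt_condition | speaker_id)"
  else "(1 | listener_id) + (1 | speaker_id)"
  formula <- stats::as.formula(paste("rating_cm ~", fixed_terms, "+",
                                     rand_terms))
  fixed <- stats::model.matrix(stats::as.formula(paste("~", fixed_terms)), d)
  list(formula = formula, data = d, fixed = fixed,
       spec = list(coding = "treatment",
                   references = c(skill_group = "poor",
                                  vt_condition = "baseline",
                                  voice_sex = "female"),
                   f0_as_factor = f0_as_factor, random = random))
}

#' Fit the perceived-height mixed model
#'
#' Delegates the restricted-maximum-likelihood fit to lme4/lmerTest and
#' extracts the coefficient table plus the study's contrast set (small vs
#' baseline and large vs baseline, per skill group and voice sex) via
#' estimated marginal means.
#'
#' @param design a design list from \code{\link{build_height_design}} (or a
#'   raw trial data.frame, which is passed through it).
#' @param contrasts compute the emmeans contrast set (set FALSE to skip).
#' @return object of class \code{"vt_height_fit"}: list with \code{model}
#'   (the lmer fit), \code{coefficients} (fixed-effect table),
#'   \code{contrasts}, \code{converged}, \code{design}.
#' @export
fit_height_model <- function(design, contrasts = TRUE) {
  if (is.data.frame(design)) design <- build_height_design(design)
  fixed_formula <- stats::as.formula(
    paste("rating_cm ~",
          "skill_group * vt_condition * f0_modulation * voice_sex"))
  ## degenerate case: ratings are an exact function of the fixed effects;
  ## all variance components are zero and REML coincides with least squares
  ols <- stats::lm(fixed_formula, data = design$data)
  if (stats::sigma(ols) < 1e-8) {
    co <- as.data.frame(suppressWarnings(
      summary(ols))$coefficients[, 1:2, drop = FALSE])
    names(co) <- c("estimate", "std_error")
    co$term <- rownames(co)
    rownames(co) <- NULL
    ctr <- NULL
    if (contrasts) {
      em <- suppressWarnings(suppressMessages(
        emmeans::emmeans(ols, ~ vt_condition | skill_group + voice_sex)))
      ctr <- suppressWarnings(
        as.data.frame(emmeans::contrast(em, method = "trt.vs.ctrl",
                                        ref = "baseline")))
    }
    return(structure(list(model = ols, coefficients = co, contrasts = ctr,
                          converged = TRUE,
                          note = paste("zero residual variance:",
                                       "exact least-squares interpolation,",
                                       "random-effect variances are zero"),
                          design = design$spec),
                     class = "vt_height_fit"))
  }
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(design$formula, data = design$data,
                                    REML = TRUE,
                                    control = lme4::lmerControl(
                                      check.conv.singular = "ignore"))),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("mixed-model fit failed: ", conditionMessage(fit), call. = FALSE)
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  grad <- suppressWarnings(
    max(c(0, as.numeric(sub(".*max\\|grad\\| = ([0-9.eE+-]+).*", "\\1",
                            grep("max\\|grad\\|", msgs, value = TRUE))))))
  converged <- !any(grepl("failed to converge", msgs)) || grad <= 0.05
  if (!converged)
    stop("mixed-model fit did not converge: ",
         paste(msgs, collapse = "; "), call. = FALSE)
  co <- as.data.frame(summary(fit)$coefficients)
  co$term <- rownames(co)
  rownames(co) <- NULL
  names(co)[1:2] <- c("estimate", "std_error")
  ctr <- NULL
  if (contrasts) {
    em <- suppressMessages(
      emmeans::emmeans(fit, ~ vt_condition | skill_group + voice_sex,
                       lmer.df = "satterthwaite"))
    ctr <- as.data.frame(emmeans::contrast(em, method = "trt.vs.ctrl",
                                           ref = "baseline"))
  }
  structure(list(model = fit, coefficients = co, contrasts = ctr,
                 converged = converged, design = design$spec),
            class = "vt_height_fit")
}

#' @export
print.vt_height_fit <- function(x, ...) {
  cat("Perceived-height mixed model (REML via lmer)\n")
  cat(sprintf("  %d fixed effects, converged: %s\n",
              nrow(x$coefficients), x$converged))
  print(utils::head(x$coefficients[, c("term", "estimate", "std_error")],
                    12L), row.names = FALSE, digits = 3)
  if (!is.null(x$contrasts)) {
    cat("  vocal-tract condition contrasts vs baseline:\n")
    print(x$contrasts[, c("contrast", "skill_group", "voice_sex",
                          "estimate", "SE")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
coef.vt_height_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}
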