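#' Vocal-tract modulation skill score
#'
#' Per speaker, the median length-component score over frames imitating
#' small voice targets minus the median over frames imitating large targets
#' (words and f0 directions pooled within vocal-tract condition).  Positive
#' scores mean the speaker raised the larynx when aiming small and lowered
#' it when aiming large.
#'
#' @param scores score table (see \code{\link{project_scores}}) with columns
#'   \code{speaker_id}, \code{vt_condition} and the component scores.
#' @param component component index (or column name such as "fPC2") holding
#'   the vocal-tract length mode.
#' @return data.frame with \code{speaker_id}, \code{vt_skill},
#'   \code{n_small}, \code{n_large}; speakers missing a condition get
#'   \code{NA} skill and a \code{flag}.
#' @export
vt_skill_score <- function(scores, component = 2L) {
  col <- if (is.character(component)) component else paste0("fPC", component)
  if (!col %in% names(scores))
    stop("score table has no column '", col, "'", call. = FALSE)
  out <- lapply(split(scores, scores$speaker_id), function(d) {
    sm <- d[[col]][d$vt_condition == "small"]
    lg <- d[[col]][d$vt_condition == "large"]
    data.frame(speaker_id = d$speaker_id[1L],
               vt_skill = if (length(sm) && length(lg))
                 stats::median(sm) - stats::median(lg) else NA_real_,
               n_small = length(sm), n_large = length(lg),
               flag = if (length(sm) && length(lg)) ""
                      else "missing condition")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Acoustic modulation skill score
#'
#' Eq.-style analogue of the vocal-tract score on acoustic measurements:
#' median semitone modulation in the small (+4 st) conditions minus the
#' median in the large (-4 st) conditions, pooled across carrier words.
#' For the pitch measure (f0) the imitation target direction is the f0
#' shift, not the formant shift, so takes are grouped by the sign of the
#' f0 target: the score is then pitch-matching range (high-pitch targets
#' minus low-pitch targets).
#'
#' @param modulations modulation record table from
#'   \code{\link{modulation_table}} (rows for the measure of interest are
#'   selected internally).
#' @param measure one of \code{"f0"}, \code{"F1"} .. \code{"F4"},
#'   \code{"aVTL"}.
#' @return data.frame with \code{speaker_id}, \code{measure},
#'   \code{acoustic_skill} (semitones) and a \code{flag} for speakers
#'   missing a condition.
#' @export
acoustic_skill_score <- function(modulations, measure = "F1") {
  if (!measure %in% unique(modulations$measure))
    stop("no modulation records for measure '", measure, "'", call. = FALSE)
  d <- modulations[modulations$measure == measure, , drop = FALSE]
  if (measure == "f0") {
    if (!"f0_shift_st" %in% names(d))
      stop("f0 skill needs the f0_shift_st column in the modulation table",
           call. = FALSE)
    d$vt_condition <- ifelse(d$f0_shift_st > 0, "small",
                             ifelse(d$f0_shift_st < 0, "large", "baseline"))
  }
  out <- lapply(split(d, d$speaker_id), function(s) {
    sm <- s$modulation_st[s$vt_condition == "small"]
    lg <- s$modulation_st[s$vt_condition == "large"]
    data.frame(speaker_id = s$speaker_id[1L], measure = measure,
               acoustic_skill = if (length(sm) && length(lg))
                 stats::median(sm) - stats::median(lg) else NA_real_,
               flag = if (length(sm) && length(lg)) ""
                      else "missing condition")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank speakers and assign good/poor modulator groups
#'
#' Within each sex, speakers are ranked by descending vocal-tract skill;
#' the top \code{n_per_group} form the good-modulator group and the bottom
#' \code{n_per_group} the poor group.  Ties break by speaker id; speakers
#' flagged as excluded are removed before ranking.
#'
#' @param skills data.frame with \code{speaker_id}, \code{sex},
#'   \code{vt_skill} and optionally a logical \code{excluded} column.
#' @param n_per_group speakers per group and sex.
#' @param by_training also split rankings by a logical \code{singer} column
#'   (optional variant; the primary grouping is by sex only).
#' @return the input with \code{rank_within_sex} and \code{group}
#'   (\code{good}/\code{poor}/\code{unassigned}) columns.
#' @export
rank_and_group <- function(skills, n_per_group = 5L, by_training = FALSE) {
  skills$excluded <- if ("excluded" %in% names(skills)) skills$excluded
                     else FALSE
  keep <- skills[!skills$excluded & !is.na(skills$vt_skill), , drop = FALSE]
  strata <- if (by_training) interaction(keep$sex, keep$singer, drop = TRUE)
            else keep$sex
  res <- lapply(split(keep, strata), function(d) {
    if (nrow(d) < 2L * n_per_group)
      stop("fewer than ", 2L * n_per_group, " rankable speakers for sex '",
           d$sex[1L], "'", call. = FALSE)
    ord <- order(-d$vt_skill, d$speaker_id)
    d <- d[ord, , drop = FALSE]
    d$rank_within_sex <- seq_len(nrow(d))
    d$group <- "unassigned"
    d$group[seq_len(n_per_group)] <- "good"
    d$group[(nrow(d) - n_per_group + 1L):nrow(d)] <- "poor"
    d
  })
  res <- do.call(rbind, res)
  dropped <- skills[skills$excluded | is.na(skills$vt_skill), , drop = FALSE]
  if (nrow(dropped)) {
    dropped$rank_within_sex <- NA_integer_
    dropped$group <- "unassigned"
    res <- rbind(res, dropped)
  }
  rownames(res) <- NULL
  res[order(res$speaker_id), , drop = FALSE]
}

#' Pearson association between vocal-tract and acoustic skill
#'
#' Pearson correlation of per-speaker scores, with \code{t = r
#' sqrt(df / (1 - r^2))}, \code{df = n - 2}, and a p-value from the t
#' distribution (one-sided for a positive association by default).
#'
#' @param vt_skill,acoustic_skill paired numeric vectors (or data.frames
#'   with \code{speaker_id} plus \code{vt_skill} / \code{acoustic_skill}
#'   columns, merged on speaker).
#' @param measure label carried into the result.
#' @param alternative \code{"greater"} (one-sided, default) or
#'   \code{"two.sided"}.
#' @return one-row data.frame: \code{measure}, \code{n}, \code{r},
#'   \code{r_squared}, \code{t_statistic}, \code{df}, \code{p_value}.
#' @export
skill_acoustic_association <- function(vt_skill, acoustic_skill,
                                       measure = NA_character_,
                                       alternative = c("greater",
                                                       "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.data.frame(vt_skill)) {
    m <- merge(vt_skill[, c("speaker_id", "vt_skill")],
               acoustic_skill[, c("speaker_id", "acoustic_skill")],
               by = "speaker_id")
    x <- m$vt_skill; y <- m$acoustic_skill
  } else {
    x <- vt_skill; y <- acoustic_skill
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in one variable",
         call. = FALSE)
  r <- stats::cor(x, y)
  df <- n - 2L
  t <- if (abs(r) < 1) r * sqrt(df / (1 - r^2)) else sign(r) * Inf
  p <- if (alternative == "greater") stats::pt(t, df, lower.tail = FALSE)
       else 2 * stats::pt(-abs(t), df)
  data.frame(measure = measure, n = n, r = r, r_squared = r^2,
             t_statistic = t, df = df, p_value = p)
}
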