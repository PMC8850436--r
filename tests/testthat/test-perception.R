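test_that("slider percentiles map linearly onto the printed height ranges", {
  expect_equal(percentile_to_cm(1, "female"), 145)
  expect_equal(percentile_to_cm(99, "female"), 180)
  expect_equal(percentile_to_cm(50, "female"), 162.5)
  expect_equal(percentile_to_cm(1, "male"), 155)
  expect_equal(percentile_to_cm(99, "male"), 190)
  expect_error(percentile_to_cm(0, "female"), "percentile")
  expect_error(percentile_to_cm(100, "male"), "percentile")
  ## strictly increasing, 35 cm span for both sexes
  p <- seq(1, 99, 0.5)
  for (sx in c("female", "male")) {
    h <- percentile_to_cm(p, sx)
    expect_true(all(diff(h) > 0))
    expect_equal(diff(range(h)), 35)
  }
})

test_that("the stimulus assembler returns 100 tokens per sex", {
  fx <- fix_acoustic_cohort()
  stim <- assemble_stimulus_set(fx$skills, fx$takes)
  expect_equal(sum(stim$voice_sex == "female"), 100L)
  expect_equal(sum(stim$voice_sex == "male"), 100L)
  ## every token is a member of its cell
  key <- function(d) paste(d$speaker_id, d$word, d$condition, d$f0_hz,
                           d$F1_hz)
  expect_true(all(key(stim) %in% key(fx$takes)))
  ## a removed cell is named in the error
  broken <- fx$takes[!(fx$takes$speaker_id == fx$skills$speaker_id[1] &
                         fx$takes$word == "bead" &
                         fx$takes$condition == "baseline"), ]
  expect_error(assemble_stimulus_set(fx$skills, broken),
               paste0("\\(", fx$skills$speaker_id[1], ", bead, baseline\\)"))
})

test_that("the height design uses treatment coding with stated references", {
  fx <- fix_acoustic_cohort()
  stim <- assemble_stimulus_set(fx$skills, fx$takes)
  tr <- simulate_perception_ratings(stim, n_listeners = 2L, seed = 3L)
  des <- build_height_design(tr)
  expect_equal(nrow(des$fixed), nrow(tr))
  ## full column rank on a complete vt x f0 factorial (the experiment's
  ## five-condition subset ties f0 = 0 to the baseline, aliasing the f0
  ## main effect with its vt interactions; fitters drop those columns)
  fact <- expand.grid(listener_id = c("L1", "L2"),
                      speaker_id = c("A", "B"),
                      skill_group = c("good", "poor"),
                      voice_sex = c("female", "male"),
                      vt_condition = c("baseline", "small", "large"),
                      f0_shift_st = c(-4, 0, 4), stringsAsFactors = FALSE)
  fact$rating_cm <- 160
  desf <- build_height_design(fact)
  expect_equal(qr(desf$fixed)$rank, ncol(desf$fixed))
  ## baseline rows have zero vt-condition dummies
  vt_cols <- grep("^vt_condition", colnames(des$fixed))
  expect_true(all(des$fixed[tr$vt_condition == "baseline", vt_cols] == 0))
  expect_error(build_height_design(tr[1:3, ]), "at least 2")
  one <- tr; one$skill_group <- "good"
  expect_error(build_height_design(one), "single level")
})

test_that("zero-noise ratings are interpolated exactly", {
  fx <- fix_acoustic_cohort()
  stim <- assemble_stimulus_set(fx$skills, fx$takes)
  eff <- rating_effects(vt_effect_cm = 3, f0_slope_cm_per_st = -0.8,
                        skill_gain = 2, listener_sd = 0, speaker_sd = 0,
                        speaker_slope_sd = 0, residual_sd = 0)
  tr <- simulate_perception_ratings(stim, eff, n_listeners = 2L, seed = 5L)
  fit <- fit_height_model(tr)
  ctr <- fit$contrasts
  pick <- function(con, grp, sex)
    ctr$estimate[grepl(con, ctr$contrast) & ctr$skill_group == grp &
                   ctr$voice_sex == sex]
  for (sex in c("female", "male")) {
    expect_equal(pick("large", "poor", sex), 3, tolerance = 1e-6)
    expect_equal(pick("large", "good", sex), 6, tolerance = 1e-6)
    expect_equal(pick("small", "poor", sex), -3, tolerance = 1e-6)
    expect_equal(pick("small", "good", sex), -6, tolerance = 1e-6)
  }
  co <- coef(fit)
  expect_equal(unname(co["f0_modulation"]), -0.8, tolerance = 1e-6)
})

test_that("planted effects are recovered from noisy ratings", {
  fx <- fix_acoustic_cohort()
  stim <- assemble_stimulus_set(fx$skills, fx$takes)
  eff <- rating_effects(vt_effect_cm = 3, skill_gain = 2,
                        speaker_slope_sd = 0.3)
  tr <- simulate_perception_ratings(stim, eff, n_listeners = 30L, seed = 6L)
  fit <- fit_height_model(build_height_design(tr))
  ctr <- fit$contrasts
  lp <- ctr$estimate[grepl("large", ctr$contrast) &
                       ctr$skill_group == "poor"]
  lg <- ctr$estimate[grepl("large", ctr$contrast) &
                       ctr$skill_group == "good"]
  expect_equal(mean(lp), 3, tolerance = 0.8)
  expect_equal(mean(lg), 6, tolerance = 0.8)
})

test_that("a listener-permuted refit shows no vocal-tract effect", {
  fx <- fix_acoustic_cohort()
  stim <- assemble_stimulus_set(fx$skills, fx$takes)
  eff <- rating_effects(vt_effect_cm = 0, f0_slope_cm_per_st = 0,
                        skill_gain = 1, listener_sd = 1, speaker_sd = 0.3,
                        speaker_slope_sd = 0, residual_sd = 2)
  tr <- simulate_perception_ratings(stim, eff, n_listeners = 80L, seed = 7L)
  set.seed(8)
  for (sx in unique(tr$voice_sex)) {
    i <- tr$voice_sex == sx
    tr$rating_cm[i] <- sample(tr$rating_cm[i])
  }
  fit <- fit_height_model(build_height_design(tr, random = "intercepts"),
                          contrasts = TRUE)
  expect_lt(max(abs(fit$contrasts$estimate)), 0.5)
})
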