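make_scores <- function(small, large, id = "S") {
  data.frame(speaker_id = id,
             vt_condition = rep(c("small", "large"),
                                c(length(small), length(large))),
             fPC2 = c(small, large))
}

test_that("vocal-tract skill is the difference of condition medians", {
  sc <- make_scores(c(2, 3, 4), c(-1, -2, -3))
  expect_equal(vt_skill_score(sc, 2)$vt_skill, 3 - (-2))
  ## identical distributions give zero
  sc0 <- make_scores(c(1, 2, 3), c(1, 2, 3))
  expect_equal(vt_skill_score(sc0, 2)$vt_skill, 0)
  ## translation invariance
  sc1 <- sc; sc1$fPC2 <- sc1$fPC2 + 57.3
  expect_equal(vt_skill_score(sc1, 2)$vt_skill,
               vt_skill_score(sc, 2)$vt_skill, tolerance = 1e-12)
  ## label swap negates the score
  sw <- sc; sw$vt_condition <- ifelse(sw$vt_condition == "small",
                                      "large", "small")
  expect_equal(vt_skill_score(sw, 2)$vt_skill,
               -vt_skill_score(sc, 2)$vt_skill)
  ## missing condition flags the speaker instead of scoring it
  mis <- sc[sc$vt_condition == "small", ]
  out <- vt_skill_score(mis, 2)
  expect_true(is.na(out$vt_skill))
  expect_match(out$flag, "missing")
})

test_that("acoustic skill recovers full, null and partial imitators", {
  pr <- speaker_profile("P", "female")
  perfect <- simulate_acoustic_session(pr, "rtmri", 2L, fidelity = 1,
                                       noise_cv = 0, seed = 1L)
  mods <- do.call(rbind, lapply(split(perfect, perfect$word),
                                modulation_table))
  expect_equal(acoustic_skill_score(mods, "F1")$acoustic_skill, 8,
               tolerance = 1e-9)
  expect_equal(acoustic_skill_score(mods, "f0")$acoustic_skill, 8,
               tolerance = 1e-9)
  none <- simulate_acoustic_session(pr, "rtmri", 2L, fidelity = 0,
                                    f0_fidelity = 0, noise_cv = 0,
                                    seed = 1L)
  mods0 <- do.call(rbind, lapply(split(none, none$word), modulation_table))
  expect_equal(acoustic_skill_score(mods0, "F1")$acoustic_skill, 0,
               tolerance = 1e-9)
  half <- simulate_acoustic_session(pr, "rtmri", 2L, fidelity = 0.5,
                                    noise_cv = 0.01, seed = 2L)
  modsh <- do.call(rbind, lapply(split(half, half$word), modulation_table))
  expect_equal(acoustic_skill_score(modsh, "F1")$acoustic_skill, 4,
               tolerance = 0.2)
})

test_that("ranking partitions each sex into good and poor groups", {
  set.seed(4)
  sk <- data.frame(speaker_id = sprintf("S%02d", 1:20),
                   sex = rep(c("female", "male"), each = 10),
                   vt_skill = rnorm(20))
  g <- rank_and_group(sk, 5L)
  for (sx in c("female", "male")) {
    gs <- g[g$sex == sx, ]
    expect_equal(sort(gs$rank_within_sex), 1:10)
    expect_equal(sum(gs$group == "good"), 5L)
    expect_equal(sum(gs$group == "poor"), 5L)
    top <- gs$speaker_id[order(-gs$vt_skill)][1:5]
    expect_setequal(gs$speaker_id[gs$group == "good"], top)
  }
  ## adding a constant does not change the grouping
  sk2 <- sk; sk2$vt_skill <- sk2$vt_skill + 100
  g2 <- rank_and_group(sk2, 5L)
  expect_identical(g2$group, g$group)
  ## an excluded speaker is removed before ranking
  sk3 <- sk; sk3$excluded <- sk3$speaker_id == "S03"
  g3 <- rank_and_group(sk3, 4L)
  expect_equal(g3$group[g3$speaker_id == "S03"], "unassigned")
  expect_true(is.na(g3$rank_within_sex[g3$speaker_id == "S03"]))
  expect_equal(sort(g3$rank_within_sex[g3$sex == "female" & !g3$excluded]),
               1:9)
  expect_error(rank_and_group(sk[1:6, ], 5L), "fewer than")
})

test_that("associations match the closed-form t and an independent test", {
  set.seed(8)
  x <- rnorm(30); y <- 2 * x + rnorm(30)
  a <- skill_acoustic_association(x, y, "F1")
  ct <- cor.test(x, y, alternative = "greater")
  expect_equal(a$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(a$t_statistic, unname(ct$statistic), tolerance = 1e-9)
  expect_equal(a$p_value, ct$p.value, tolerance = 1e-12)
  expect_equal(a$df, 28L)
  expect_equal(a$r_squared, a$r^2, tolerance = 1e-15)
  ## exact linear relation
  lin <- skill_acoustic_association(x, 3 * x + 1, "F1",
                                    alternative = "two.sided")
  expect_equal(lin$r_squared, 1, tolerance = 1e-12)
  expect_error(skill_acoustic_association(x, rep(1, 30)), "zero variance")
  expect_error(skill_acoustic_association(1:2, 2:3), "at least 3")
})

test_that("a planted correlation strength is recovered on average", {
  set.seed(12)
  r2 <- replicate(150, {
    x <- rnorm(52); y <- x + rnorm(52, 0, sqrt(1 / 0.6 - 1))
    skill_acoustic_association(x, y)$r_squared
  })
  expect_equal(mean(r2), 0.6, tolerance = 0.05)
})

test_that("tract and acoustic skill share a common latent factor end to end", {
  fx <- fix_acoustic_cohort()
  mods <- do.call(rbind, lapply(
    split(fx$takes, list(fx$takes$speaker_id, fx$takes$word), drop = TRUE),
    modulation_table))
  f1 <- acoustic_skill_score(mods, "F1")
  a <- skill_acoustic_association(fx$skills, f1, "F1")
  expect_gt(a$r, 0)
  expect_lt(a$p_value, 0.05)
})
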