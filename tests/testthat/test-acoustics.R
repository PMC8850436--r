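test_that("the stimulus grid enumerates the published condition counts", {
  full <- build_stimulus_grid("full")
  expect_equal(nrow(full), 9L)
  expect_equal(sum(full$axis != "baseline"), 8L)
  rt <- build_stimulus_grid("rtmri")
  expect_equal(nrow(rt), 5L)
  mod <- full[full$axis != "baseline", ]
  expect_true(all(abs(mod$f0_shift_st) == abs(mod$vtl_shift_st)))
  expect_true(all(abs(mod$vtl_shift_st) %in% c(2, 4)))
  expect_true(all(rt$vtl_shift_st %in% c(-4, 0, 4)))
  ## trial enumeration: 2 blocks x 5 trials x 18 conditions
  expect_equal(nrow(enumerate_trials("audio")), 180L)
  expect_equal(nrow(enumerate_trials("rtmri")), 400L)
})

test_that("grid application shifts f0 and formants as frequency ratios", {
  base <- data.frame(f0_hz = 200, F1_hz = 500, F2_hz = 1500, F3_hz = 2500,
                     F4_hz = 3500)
  grid <- build_stimulus_grid("full")
  bl <- apply_grid_to_baseline(base, grid[grid$axis == "baseline", ])
  expect_equal(bl$F1_hz, 500)                       # formants unchanged
  expect_equal(bl$f0_hz, 200 * 2^(2 / 12))          # +2 st headroom shift
  up4 <- apply_grid_to_baseline(base, grid[grid$f0_shift_st == 4 &
                                             grid$vtl_shift_st == 4, ])
  expect_equal(up4$F1_hz, 500 * 2^(4 / 12), tolerance = 1e-9)
  dn <- apply_grid_to_baseline(up4, grid[grid$f0_shift_st == -4 &
                                           grid$vtl_shift_st == -4, ])
  expect_equal(dn$F1_hz, 500, tolerance = 1e-9)     # inverse ratios cancel
})

test_that("semitone modulation is the 12 log2 frequency ratio", {
  expect_equal(semitone_modulation(440, 440), 0)
  expect_equal(semitone_modulation(880, 440), 12)
  expect_equal(semitone_modulation(440, 415.305), 1, tolerance = 1e-3)
  expect_error(semitone_modulation(-1, 100), "positive")
  ## antisymmetry and additivity over random frequency triples
  set.seed(2)
  for (i in 1:25) {
    f <- runif(3, 80, 4000)
    expect_equal(semitone_modulation(f[1], f[2]),
                 -semitone_modulation(f[2], f[1]), tolerance = 1e-12)
    expect_equal(semitone_modulation(f[1], f[3]),
                 semitone_modulation(f[1], f[2]) +
                   semitone_modulation(f[2], f[3]), tolerance = 1e-12)
  }
})

test_that("grid closure: applied shifts are recovered exactly by Eq-style modulation", {
  base <- data.frame(f0_hz = 180, F1_hz = 520, F2_hz = 1480, F3_hz = 2600,
                     F4_hz = 3450)
  grid <- build_stimulus_grid("full")
  bl <- apply_grid_to_baseline(base, grid[grid$axis == "baseline", ])
  for (i in which(grid$axis != "baseline")) {
    tk <- apply_grid_to_baseline(base, grid[i, ])
    expect_equal(semitone_modulation(tk$F2_hz, bl$F2_hz),
                 grid$vtl_shift_st[i], tolerance = 1e-9)
    expect_equal(semitone_modulation(tk$f0_hz, bl$f0_hz),
                 grid$f0_shift_st[i], tolerance = 1e-9)
  }
})

test_that("aVTL inverts tube formants and scales homogeneously", {
  f15 <- c(583.3333333, 1750, 2916.6666667, 4083.3333333)
  expect_equal(compute_avtl(f15), 15, tolerance = 1e-6)
  expect_equal(compute_avtl(2 * f15), 7.5, tolerance = 1e-9)
  expect_error(compute_avtl(c(-500, 1500, 2500, 3500)), "positive")
  ## vowel coloring biases the estimate by less than 15%
  tk <- simulate_formants(17.5, "bard")
  expect_lt(abs(compute_avtl(tk) - 17.5) / 17.5, 0.15)
  ## strict monotonicity: raising any single formant shrinks aVTL
  for (i in 1:4) {
    f2 <- f15; f2[i] <- f2[i] * 1.2
    expect_lt(compute_avtl(f2), compute_avtl(f15))
  }
})

test_that("representative-token selection minimizes summed semitone deviation", {
  takes <- data.frame(take_index = 1:3, f0_hz = 200,
                      F1_hz = c(480, 500, 560), F2_hz = 1500)
  expect_equal(select_representative_token(takes)$F1_hz, 500)
  ## single take returns itself
  expect_equal(select_representative_token(takes[2, ])$take_index, 2L)
  ## duplicated winner: tie broken by lowest take index
  dup <- rbind(takes, transform(takes[2, ], take_index = 4L))
  expect_equal(select_representative_token(dup)$take_index, 2L)
  expect_error(select_representative_token(takes[0, ]), "no takes")
})

test_that("modulation tables reference the speaker-word baseline median", {
  base <- data.frame(f0_hz = 200, F1_hz = 500, F2_hz = 1500, F3_hz = 2500,
                     F4_hz = 3500)
  grid <- build_stimulus_grid("rtmri")
  takes <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    apply_grid_to_baseline(base, grid[i, ])))
  takes$speaker_id <- "S"; takes$word <- "bead"; takes$take_index <- 1L
  m <- modulation_table(takes)
  ## baseline rows modulate by zero for every measure
  expect_true(all(abs(m$modulation_st[m$vt_condition == "baseline"]) < 1e-9))
  ## a -4 st condition moves every formant by exactly -4 st
  f_rows <- m$measure %in% c("F1", "F2", "F3", "F4") &
    m$condition == "f0-4_vtl-4"
  expect_equal(m$modulation_st[f_rows], rep(-4, 4), tolerance = 1e-9)
  ## aVTL modulation mirrors the common formant shift with opposite sign
  av <- m$modulation_st[m$measure == "aVTL" & m$condition == "f0-4_vtl-4"]
  expect_equal(av, 4, tolerance = 0.2)
  expect_error(modulation_table(takes[takes$vt_condition != "baseline", ]),
               "baseline")
})
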