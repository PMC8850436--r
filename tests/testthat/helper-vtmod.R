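## Shared fixtures, built once per test run and memoized.

.vtmod_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .vtmod_cache))
    assign(name, expr, envir = .vtmod_cache)
  get(name, envir = .vtmod_cache)
}

fix_reference <- function() cached("reference", {
  render_frame(make_vocal_tract_contour(shape_params()))
})

fix_static_mask <- function() cached("static_mask", static_structure_mask())

## One registered + segmented noiseless session (20 frames) with ground
## truth, reused by segmentation, fpca and skill tests.
fix_session <- function() cached("session", {
  pr <- speaker_profile("S_fix", "female", modulation_amplitude = 0.6)
  ses <- simulate_speaker_session(pr, session_design("rtmri"), seed = 3L,
                                  frames_per_trial = 2L)
  reg <- register_series(ses$series, fix_reference(), fix_static_mask())
  seg <- segment_series(reg$series, static_mask = fix_static_mask())
  list(profile = pr, raw = ses, registered = reg, seg = seg)
})

## Acoustic takes for a small two-sex cohort (no imaging), for stimulus
## assembly and perception tests.
fix_acoustic_cohort <- function() cached("acoustic_cohort", {
  coh <- make_speaker_cohort(10L, seed = 11L)
  takes <- do.call(rbind, lapply(seq_along(coh$profiles), function(i)
    simulate_acoustic_session(coh$profiles[[i]], "rtmri",
                              takes_per_condition = 3L,
                              fidelity = coh$table$fidelity[i],
                              seed = 100L + i)))
  skills <- coh$table
  ## synthetic tract skill proportional to planted amplitude (imaging-free)
  skills$vt_skill <- skills$modulation_amplitude * 100
  grouped <- rank_and_group(skills, n_per_group = 5L)
  list(cohort = coh, takes = takes, skills = grouped)
})
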