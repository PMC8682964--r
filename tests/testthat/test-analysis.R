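test_that("burst detection recovers a constructed square wave", {
  sq <- make_square_v(period = 3, duty = 0.5, t_end = 30)
  b <- detect_bursts(sq$t, sq$v)
  expect_true(b$oscillating)
  expect_equal(b$period, 3, tolerance = 0.02)
  expect_equal(b$duty, 0.5, tolerance = 0.05)
  ## constant trace: no bursts
  b0 <- detect_bursts(sq$t, rep(-65, length(sq$t)))
  expect_false(b0$oscillating)
  expect_equal(nrow(b0$active), 0)
  ## spikes riding the plateau are counted
  sp <- make_square_v(period = 3, duty = 0.4, t_end = 30, spike_amp = 15,
                      spike_period = 0.02)
  bs <- detect_bursts(sp$t, sp$v)
  ## interior bursts (edge bursts may be truncated by the window)
  expect_true(all(head(tail(bs$spikes, -1), -1) > 5))
})

test_that("period and amplitude measurement matches constructed signals", {
  s <- make_sine(period = 5, amp = 2, t_end = 40)
  m <- measure_period_amplitude(s$t, s$x)
  expect_true(m$oscillating)
  expect_equal(m$period, 5, tolerance = 0.01)
  expect_equal(m$amplitude, 4, tolerance = 0.05)
  ## constant: non-oscillating
  m0 <- measure_period_amplitude(s$t, rep(3.2, length(s$t)))
  expect_false(m0$oscillating)
  ## sawtooth fixture amplitude within 2%
  tri <- make_triangle(period = 4, lo = 5, hi = 9, t_end = 40)
  mt <- measure_period_amplitude(tri$t, tri$x)
  expect_equal(mt$amplitude, 4, tolerance = 0.02)
  expect_equal(mt$period, 4, tolerance = 0.02)
})

test_that("waveform classification separates triangle from pulse train", {
  tri <- make_triangle(period = 4, lo = 5, hi = 9)
  expect_equal(classify_fbp_waveform(tri$t, tri$x), "sawtooth")
  pu <- make_pulses(period = 5, peak = 8)
  expect_equal(classify_fbp_waveform(pu$t, pu$x), "pulsatile")
  expect_equal(classify_fbp_waveform(tri$t, rep(1, length(tri$t))), "none")
})

test_that("classifier verdicts are invariant to resampling and rescaling", {
  for (mk in list(make_triangle, make_pulses)) {
    a <- mk(); cls <- classify_fbp_waveform(a$t, a$x)
    fine <- mk(dt = 1 / 1200)
    expect_equal(classify_fbp_waveform(fine$t, fine$x), cls)
    expect_equal(classify_fbp_waveform(a$t, 7.3 * a$x), cls)
  }
  sq <- make_square_v()
  b1 <- detect_bursts(sq$t, sq$v)
  sq2 <- make_square_v(dt = 1 / 1200)
  b2 <- detect_bursts(sq2$t, sq2$v)
  expect_equal(b1$period, b2$period, tolerance = 0.02)
})

test_that("episode grouping splits on large gaps only", {
  ## bursts in triplets separated by 3-min gaps: episodes of 3
  g <- make_gapped_bursts(rep(c(0.2, 0.2, 3), 5)[-15])
  b <- detect_bursts(g$t, g$v)
  ep <- detect_episodes(b)
  expect_true(ep$compound)
  expect_true(all(ep$episodes$n_bursts == 3))
  expect_equal(ep$episode_period, 3.7, tolerance = 0.1)
  ## regular bursting: a single episode, no compound pattern
  r <- make_gapped_bursts(rep(0.5, 11))
  er <- detect_episodes(detect_bursts(r$t, r$v))
  expect_false(er$compound)
  ## too few bursts
  few <- make_gapped_bursts(c(0.5, 0.5))
  expect_false(detect_episodes(detect_bursts(few$t, few$v))$compound)
})

test_that("psi phase relation compares active and silent means", {
  sq <- make_square_v(period = 4, duty = 0.5, t_end = 40)
  b <- detect_bursts(sq$t, sq$v)
  ## psi elevated during active phases -> hyperpolarizing
  psi_hi <- ifelse(sq$v > -45, 162, 158)
  expect_equal(psi_phase_relation(sq$t, psi_hi, b), "hyperpolarizing")
  expect_equal(psi_phase_relation(sq$t, 320 - psi_hi, b), "depolarizing")
  expect_equal(psi_phase_relation(sq$t, rep(160, length(sq$t)), b), "flat")
})

test_that("subthreshold detector requires quiet V with oscillating FBP", {
  t <- seq(0, 30, by = 1 / 600)
  quiet <- data.frame(t = t, v = -64 + 0.4 * sin(2 * pi * t / 5),
                      cac = 0.1 + 0.01 * sin(2 * pi * t / 5),
                      fbp = 2 + 1.5 * sin(2 * pi * t / 5))
  st <- detect_subthreshold(quiet, ca_ref = 0.2)
  expect_false(st$spiking)
  expect_true(st$fbp_oscillating)
  expect_true(st$verdict)
  ## spiking disqualifies
  spiky <- quiet
  spiky$v <- spiky$v + ifelse(sin(2 * pi * t / 0.02) > 0.99, 40, 0)
  expect_false(detect_subthreshold(spiky, ca_ref = 0.2)$verdict)
  ## constant state disqualifies
  flat <- quiet; flat$fbp <- rep(2, length(t)); flat$cac <- rep(0.1, length(t))
  expect_false(detect_subthreshold(flat, ca_ref = 0.2)$verdict)
})
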