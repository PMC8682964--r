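## Synthetic waveform fixtures used by the analysis tests.  All are built
## in code; dt in minutes.

## square-wave "bursting" V trace with optional spikes riding the plateau
make_square_v <- function(period = 3, duty = 0.5, t_end = 30, dt = 1 / 600,
                          v_lo = -65, v_hi = -25, spike_amp = 0,
                          spike_period = 0.01) {
  t <- seq(0, t_end, by = dt)
  phase <- (t %% period) / period
  v <- ifelse(phase < duty, v_hi, v_lo)
  if (spike_amp > 0)
    v <- v + ifelse(phase < duty,
                    spike_amp * sin(2 * pi * t / spike_period)^2, 0)
  list(t = t, v = v)
}

make_sine <- function(period = 5, amp = 1, t_end = 40, dt = 1 / 600,
                      offset = 10) {
  t <- seq(0, t_end, by = dt)
  list(t = t, x = offset + amp * sin(2 * pi * t / period))
}

## triangle wave bounded away from zero (sawtooth-class fixture)
make_triangle <- function(period = 4, lo = 5, hi = 9, t_end = 40,
                          dt = 1 / 600) {
  t <- seq(0, t_end, by = dt)
  phase <- (t %% period) / period
  x <- ifelse(phase < 0.5, lo + (hi - lo) * 2 * phase,
              hi - (hi - lo) * 2 * (phase - 0.5))
  list(t = t, x = x)
}

## pulse train that decays to near zero between pulses (pulsatile-class)
make_pulses <- function(period = 5, peak = 8, t_end = 40, dt = 1 / 600,
                        width = 0.15) {
  t <- seq(0, t_end, by = dt)
  phase <- (t %% period) / period
  x <- peak * exp(-(phase / width)^2)
  list(t = t, x = x)
}

## V trace with bursts at prescribed onset gaps (for episode grouping)
make_gapped_bursts <- function(gaps_min, burst_len = 0.15, dt = 1 / 600,
                               v_lo = -65, v_hi = -25) {
  onsets <- cumsum(c(1, gaps_min + burst_len))
  t_end <- max(onsets) + 2
  t <- seq(0, t_end, by = dt)
  v <- rep(v_lo, length(t))
  for (on in onsets) v[t >= on & t < on + burst_len] <- v_hi
  list(t = t, v = v, onsets = onsets)
}

## short deterministic simulation used by several tests
sim_short <- function(params = iom_parameters(), t_span = 5, ...) {
  simulate_iom(params, t_span = t_span, init = iom_initial_state(),
               out_dt = 1000, ...)
}
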