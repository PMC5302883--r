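# Shared fixtures kept small so the default run stays fast.

# A short template at coarse sampling for tests that only need a waveform.
fast_spr <- function(fs = 1000) make_spr_template(sampling_rate = fs)

# Noise-free trace with events placed at known times.
trace_with_events <- function(times, duration = 120, spr = fast_spr(),
                              amplitudes = 1, noise_sd = 0,
                              fs = 1000, seed = 1) {
  set.seed(seed)
  n <- duration * fs
  x <- if (noise_sd > 0) rnorm(n, sd = noise_sd) else numeric(n)
  amplitudes <- rep_len(amplitudes, length(times))
  for (i in seq_along(times)) {
    i0 <- round(times[i] * fs) + 1L
    i1 <- min(n, i0 + length(spr$waveform) - 1L)
    x[i0:i1] <- x[i0:i1] + amplitudes[i] * spr$waveform[seq_len(i1 - i0 + 1L)]
  }
  current_trace(x, fs)
}

# LWS-like isomer template pair on the long-wavelength fit range.
lws_template_pair <- function(wl = seq(300, 750, 2)) {
  t11 <- pigment_template_spectrum(558, wl)
  t9 <- pigment_template_spectrum(530, wl)
  list(pair = template_pair(fit_template(t11, range = c(510, 750)),
                            fit_template(t9, range = c(510, 750))),
       t11 = t11, t9 = t9, wl = wl)
}
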