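# shared fixtures: small calibrations and random sequences built in code

# parameter set rescaled so the kernels fit a small image (2 deg across
# `size` px); the Gaussian sigma is widened to stay above one pixel at
# these coarse calibrations
small_params <- function(size = 32, m_sigma_deg = 0.1) {
  msinrf_params(deg_per_px = 2 / size, m_sigma_deg = m_sigma_deg)
}

random_seq <- function(size = 32, n_frames = 12, seed = 1, fps = 120) {
  set.seed(seed)
  stimulus_sequence(array(runif(size * size * n_frames),
                          dim = c(size, size, n_frames)),
                    fps = fps, deg_per_px = 2 / size)
}

max_rel_err <- function(a, b, floor = 1e-12) {
  max(abs(a - b) / pmax(abs(b), floor), na.rm = TRUE)
}

# x profile (width x time) of a y-constant stimulus
xt_profile <- function(seq) {
  d <- dim(seq$frames)
  matrix(seq$frames[1L, , ], d[2], d[3])
}
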