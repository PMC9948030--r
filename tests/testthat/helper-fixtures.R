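# Shared fixtures, generated in code at test time.

# A small, fast phantom for structural tests (18 x 18 x 4 grid, 3 cycles).
small_phantom <- function(tsnr = Inf, seed = 1L, ...) {
  generate_phantom(phantom_spec(dim = c(20, 20, 5), n_frames = 120,
                                tsnr = tsnr, seed = seed, ...))
}

# Wrap a single voxel time course into a minimal echo_series (2x1x1 grid so
# array dims survive; voxel [1,1,1] carries the series, voxel [2,1,1] is a
# flat baseline).
one_voxel_series <- function(x, te = 0.035, tr = 1.5, baseline = 100) {
  arr <- array(baseline, dim = c(2, 1, 1, length(x)))
  arr[1, 1, 1, ] <- x
  echo_series(arr, te = te, tr = tr)
}

# Render a mono-exponential decay signal S = s0 * exp(-te * dr2s(t))
render_echo <- function(dr2s, te, s0 = 100, tr = 1.5) {
  arr <- array(s0, dim = c(2, 1, 1, length(dr2s)))
  arr[1, 1, 1, ] <- s0 * exp(-te * dr2s)
  echo_series(arr, te = te, tr = tr)
}
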