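# internal helpers shared across modules

# log-log linear interpolation on tabulated cross sections.
loglog_interp <- function(x, y, xout) {
  if (any(xout < x[1] - 1e-9) || any(xout > x[length(x)] + 1e-9)) {
    stop("energy outside tabulated range [", x[1], ", ", x[length(x)], "] keV")
  }
  xout <- pmin(pmax(xout, x[1]), x[length(x)])
  exp(stats::approx(log(x), log(pmax(y, .Machine$double.xmin)),
                    xout = log(xout), rule = 2)$y)
}

# linear index into a 3d array from integer voxel subscripts (matrices ok)
vox_index <- function(i, j, k, dims) {
  (k - 1L) * dims[1L] * dims[2L] + (j - 1L) * dims[1L] + i
}
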