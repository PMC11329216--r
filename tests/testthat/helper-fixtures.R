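# shared fixtures: direction sets, tensor signals, quadrature oracles

fib60 <- sphere_fibonacci(60)
scheme60 <- gradient_scheme(1000, fib60, tau = 0.0387)
cfg_exact <- fit_config(6, 0)

# noise-free single-tensor attenuation on a direction set
tensor_signal <- function(evals, axis, dirs, bval = 1000) {
  D <- tensor_from_axis(evals, axis)
  exp(-bval * rowSums((dirs %*% D) * dirs))
}

# dense-quadrature (no SH) implementations of the three restriction
# indices, used as independent oracles; r0 for rtap/rtpp is the argmax
# of the ADC over the dense grid itself
quad_oracle <- function(evals, axis, tau, n_grid = 10000L,
                        n_equator = 2048L) {
  D <- tensor_from_axis(evals, axis)
  g <- sphere_fibonacci(n_grid)
  adc <- rowSums((g %*% D) * g)
  r0 <- g[which.max(adc), ]
  # orthonormal tangent pair for the equator normal to r0
  ref <- diag(3)[, which.min(abs(r0))]
  b1 <- ref - sum(ref * r0) * r0; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(r0[2] * b1[3] - r0[3] * b1[2],
          r0[3] * b1[1] - r0[1] * b1[3],
          r0[1] * b1[2] - r0[2] * b1[1])
  ang <- (seq_len(n_equator) - 1) * 2 * pi / n_equator
  eq <- outer(cos(ang), b1) + outer(sin(ang), b2)
  adc_eq <- rowSums((eq %*% D) * eq)
  list(
    rtop = mean(adc^-1.5) * sqrt(4 * pi) / ((4 * pi)^2 * tau^1.5),
    rtap = mean(1 / adc_eq) * 2 * pi / (8 * pi^2 * tau),
    rtpp = 1 / sqrt(4 * pi * tau * max(adc)),
    r0 = r0)
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

angle_deg <- function(a, b) {
  acos(pmin(1, abs(sum(a * b)))) * 180 / pi
}
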