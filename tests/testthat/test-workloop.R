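# shoelace signed area of a polygon, the independent oracle for loop work
shoelace <- function(x, y) {
  n <- length(x)
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

test_that("an analytic ellipse integrates to pi a h", {
  g <- fiber_geometry(1e-3, 1e-8)
  a <- 0.005; h <- 10  # strain semi-axis, stress semi-axis (kN/m^2)
  t <- seq(0, 2 / 100, length.out = 4001)
  tr <- length_force_trace(t, a * sin(2 * pi * 100 * t),
                           -h * cos(2 * pi * 100 * t),
                           drive_frequency = 100, amplitude = a)
  w <- integrate_loop(tr, 1, g)
  expect_equal(w$net_work, pi * a * h * 1000, tolerance = 1e-4)  # 157.1 J/m^3
  expect_equal(w$direction, "counter_clockwise")
  expect_equal(w$net_work, w$work_generated - w$work_absorbed,
               tolerance = 1e-9)
})

test_that("net work splits as generated minus absorbed (bench arithmetic)", {
  expect_equal(36.16 - 33.98, 2.18, tolerance = 1e-9)
  expect_equal(21.92 - 20.99, 0.93, tolerance = 1e-9)
  r <- structure(list(net_work = 0.65, frequency = 130),
                 class = "workloop_result")
  expect_equal(loop_power(r), 84.5)
  # reported at the table's precision (half away from zero)
  expect_equal(floor(loop_power(r) + 0.5), 85)
  r0 <- structure(list(net_work = 0, frequency = 130),
                  class = "workloop_result")
  expect_equal(loop_power(r0), 0)
  r2 <- structure(list(net_work = 2, frequency = 100),
                  class = "workloop_result")
  expect_equal(loop_power(r2), 200)
})

test_that("closed polygonal paths match the shoelace oracle", {
  # clockwise unit square in (length m, force N): net work = -area
  Lsq <- c(0, 0, 1, 1, 0); Fsq <- c(0, 1, 1, 0, 0)
  w <- loop_work_path(Lsq, Fsq)
  expect_equal(w$net, shoelace(Lsq[-5], Fsq[-5]))
  expect_equal(w$net, -1)
  # random smooth loops against the shoelace formula
  set.seed(7)
  for (i in 1:10) {
    th <- seq(0, 2 * pi, length.out = 400)
    r <- 1 + 0.3 * sin(sample(2:5, 1) * th + runif(1, 0, 2 * pi))
    L <- r * cos(th); Fn <- r * sin(th)
    L[400] <- L[1]; Fn[400] <- Fn[1]
    w <- loop_work_path(L, Fn)
    expect_equal(w$net, shoelace(L[-400], Fn[-400]), tolerance = 1e-9)
  }
})

test_that("reversing traversal negates net work and swaps the split", {
  set.seed(21)
  for (i in 1:8) {
    th <- seq(0, 2 * pi, length.out = 300)
    L <- cos(th) + 0.2 * cos(2 * th + runif(1, 0, 6))
    Fn <- sin(th) + 0.2 * sin(3 * th + runif(1, 0, 6))
    L[300] <- L[1]; Fn[300] <- Fn[1]
    fwd <- loop_work_path(L, Fn)
    rev_ <- loop_work_path(rev(L), rev(Fn))
    expect_equal(rev_$net, -fwd$net, tolerance = 1e-9)
    expect_equal(rev_$generated, fwd$absorbed, tolerance = 1e-9)
    expect_equal(rev_$absorbed, fwd$generated, tolerance = 1e-9)
  }
})

test_that("open cycles are rejected", {
  g <- fiber_geometry(1e-3, 1e-8)
  # stress that ramps through the cycle does not return to its starting
  # value: the (length, force) path is open and the loop area ill-defined
  t <- seq(0, 2 / 100, by = 1 / 10000)
  strain <- 0.005 * sin(2 * pi * 100 * t)
  stress <- sin(2 * pi * 100 * t) + 300 * t
  tr <- length_force_trace(t, strain, stress,
                           drive_frequency = 100, amplitude = 0.005)
  expect_error(integrate_loop(tr, 1, g), "open")
})

test_that("loop integral converges to the sinusoidal-analysis work", {
  # ties the large-amplitude integrator to W = -pi eps0^2 E'' for a linear
  # fiber, within 1% at 200 samples per cycle
  model <- control_nyquist()
  f <- 150; eps0 <- 0.00125
  pr <- synthetic_protocol("sinusoid", frequency = f, amplitude = eps0,
                           n_cycles = 3, sample_rate = 200 * f)
  tr <- gen_linear_trace(model, pr)
  g <- fiber_geometry(1e-3, 1e-8)
  w <- integrate_loop(tr, 1, g)
  w_expected <- -pi * eps0^2 * Im(eval_nyquist(model, f)) * 1000
  expect_equal(w$net_work, w_expected, tolerance = 0.01)
})

test_that("grid optimization picks the largest amplitude for a linear fiber", {
  # power scales with eps0^2 when the moduli are amplitude-independent and
  # E'' < 0, so the optimum sits at the largest amplitude on the grid
  model <- nyquist_params(A = 300, k = 0.1, B = 900, b = 120, C = 400,
                          c = 900)
  stopifnot(Im(eval_nyquist(model, c(50, 100, 150, 200))) < 0)
  fiber <- function(amp_pct, freq) {
    pr <- synthetic_protocol("workloop", frequency = freq,
                             amplitude = amp_pct / 100, n_cycles = 10,
                             sample_rate = 200 * freq)
    pr$kind <- "sinusoid"
    gen_linear_trace(model, pr)
  }
  g <- fiber_geometry(1e-3, 1e-8)
  opt <- optimize_workloop(fiber, amplitudes = c(0.25, 0.5, 0.75, 1.0, 1.25),
                           frequencies = c(50, 100, 150, 200), geometry = g)
  expect_equal(opt$amplitude_pct_ml, 1.25)
  expect_false(opt$all_negative)
  # invariant to grid ordering
  opt2 <- optimize_workloop(fiber, amplitudes = c(1.25, 0.25, 0.75, 1.0, 0.5),
                            frequencies = c(200, 50, 150, 100), geometry = g)
  expect_equal(opt2$amplitude_pct_ml, opt$amplitude_pct_ml)
  expect_equal(opt2$frequency, opt$frequency)
  # single-cell grid returns that cell
  one <- optimize_workloop(fiber, amplitudes = 0.5, frequencies = 100,
                           geometry = g)
  expect_equal(one$amplitude_pct_ml, 0.5)
  expect_equal(one$frequency, 100)
})

test_that("all-absorbing fiber flags the all-negative grid", {
  model <- nyquist_params(A = 300, k = 0.1, B = 0, b = 120, C = 800, c = 300)
  fiber <- function(amp_pct, freq) {
    pr <- synthetic_protocol("sinusoid", frequency = freq,
                             amplitude = amp_pct / 100, n_cycles = 10,
                             sample_rate = 200 * freq)
    gen_linear_trace(model, pr)
  }
  g <- fiber_geometry(1e-3, 1e-8)
  opt <- optimize_workloop(fiber, amplitudes = c(0.25, 0.5),
                           frequencies = c(50, 100), geometry = g)
  expect_true(opt$all_negative)
  expect_equal(opt$best$power, max(opt$grid$power))
})

test_that("length optimization follows the 2%-step / 3%-gain rule", {
  # non-increasing power: stops after the first comparison at 2%
  flat <- function(off) 100 - off
  r1 <- optimize_muscle_length(flat)
  expect_equal(r1$offset_pct, 2)

  # concave power peaking at +6%: the stop lands at 6 or 8%
  peak <- function(off) 100 - (off - 6)^2
  r2 <- optimize_muscle_length(peak)
  expect_true(r2$offset_pct %in% c(6, 8))

  # gain of exactly 3% stops (boundary inclusive)
  seqpow <- c(100, 103, 200, 300)
  stepper <- function(off) seqpow[off / 2 + 1]
  r3 <- optimize_muscle_length(stepper)
  expect_equal(r3$offset_pct, 2)

  expect_error(optimize_muscle_length(function(off) 2^off, max_steps = 5),
               "max_steps")
})
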