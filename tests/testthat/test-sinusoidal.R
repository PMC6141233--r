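make_trace <- function(eprime, eloss, f = 100, eps0 = 0.00125,
                       sample_rate = 20000, n_cycles = 10, offset = 0,
                       noise_sd = 0, seed = NULL) {
  n <- ceiling(n_cycles / f * sample_rate)
  t <- seq(0, by = 1 / sample_rate, length.out = n)
  strain <- eps0 * sin(2 * pi * f * t)
  stress <- eps0 * (eprime * sin(2 * pi * f * t) + eloss * cos(2 * pi * f * t)) +
    offset
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    stress <- stress + rnorm(n, 0, noise_sd * eps0 * sqrt(eprime^2 + eloss^2))
  }
  length_force_trace(t, strain, stress, drive_frequency = f, amplitude = eps0)
}

test_that("pure spring and pure damper give the textbook moduli", {
  # stress 1.25 kN/m^2 in phase with strain eps0 = 0.00125 -> E' = 1000
  spring <- make_trace(1000, 0)
  m <- extract_complex_modulus(spring)
  expect_equal(m$elastic, 1000, tolerance = 1e-9)
  expect_equal(m$viscous, 0, tolerance = 1e-6)

  damper <- make_trace(0, 1000)
  m2 <- extract_complex_modulus(damper)
  expect_equal(m2$elastic, 0, tolerance = 1e-6)
  expect_equal(m2$viscous, 1000, tolerance = 1e-9)
})

test_that("moduli survive 1% noise within 2% across 20 seeds", {
  for (s in 1:20) {
    tr <- make_trace(800, -300, noise_sd = 0.01, seed = s)
    m <- extract_complex_modulus(tr)
    expect_equal(m$elastic, 800, tolerance = 0.02)
    expect_equal(m$viscous, -300, tolerance = 0.02 * 800 / 300)
  }
})

test_that("projection equals the DFT-bin estimate on integer-cycle windows", {
  set.seed(99)
  for (i in 1:20) {
    ep <- runif(1, -500, 1500); ev <- runif(1, -600, 600)
    f <- sample(c(50, 100, 250), 1)
    tr <- make_trace(ep, ev, f = f, sample_rate = 200 * f, n_cycles = 8,
                     noise_sd = 0.02, seed = 1000 + i)
    m <- extract_complex_modulus(tr, drop_cycles = 2)
    # DFT oracle over the same integer-cycle window the extractor uses
    n_cyc <- floor(tr$time[length(tr$time)] * f + 1e-9)
    idx <- which(tr$time >= 2 / f - 1e-12 & tr$time < n_cyc / f - 1e-12)
    x <- tr$stress[idx]; n <- length(x)
    k <- n_cyc - 2  # remaining cycles in the window
    phasor <- sum(x * exp(-2i * pi * k * (seq_len(n) - 1) / n)) * 2 / n
    # strain = eps0 sin -> reference phasor of sin at the same bin
    sref <- sum(tr$strain[idx] * exp(-2i * pi * k * (seq_len(n) - 1) / n)) * 2 / n
    y_dft <- phasor / sref
    expect_equal(m$elastic, Re(y_dft), tolerance = 1e-6)
    expect_equal(m$viscous, Im(y_dft), tolerance = 1e-6)
  }
})

test_that("extraction is amplitude-invariant for a linear fiber", {
  model <- control_nyquist()
  for (eps0 in c(0.00125, 0.000625)) {
    pr <- synthetic_protocol("sinusoid", frequency = 150, amplitude = eps0,
                             n_cycles = 10, sample_rate = 20000)
    tr <- gen_linear_trace(model, pr)
    m <- extract_complex_modulus(tr)
    y <- eval_nyquist(model, 150)
    expect_equal(m$elastic, Re(y), tolerance = 0.005)
    expect_equal(m$viscous, Im(y), tolerance = 0.005)
  }
})

test_that("harmonic distortion in strain raises the warning flag", {
  tr <- make_trace(1000, 0)
  tr$strain <- tr$strain + 0.3 * tr$amplitude *
    sin(2 * pi * 2 * tr$drive_frequency * tr$time)
  expect_warning(m <- extract_complex_modulus(tr), "distortion")
  expect_true(m$distorted)
})

test_that("sweep assembles a sorted spectrum and validates its inputs", {
  model <- control_nyquist()
  freqs <- c(150, 20, 500)  # deliberately unsorted
  traces <- lapply(freqs, function(f) {
    pr <- synthetic_protocol("sinusoid", frequency = f, amplitude = 0.00125,
                             n_cycles = 6, sample_rate = 100 * f)
    gen_linear_trace(model, pr)
  })
  spec <- sweep_spectrum(traces)
  expect_equal(spec$frequency, sort(freqs))
  expect_s3_class(spec, "modulus_spectrum")

  one <- sweep_spectrum(traces[1])
  expect_equal(nrow(one), 1L)

  expect_error(sweep_spectrum(c(traces, traces[1])), "duplicate")
  tr_big <- traces[[1]]; tr_big$amplitude <- 0.01
  tr_big$strain <- tr_big$strain * 8
  expect_error(sweep_spectrum(list(traces[[2]], tr_big)), "amplitude")
})

test_that("sweep of 50 generated traces matches the forward model closely", {
  model <- control_nyquist()
  freqs <- protocol_frequencies(50)
  traces <- lapply(freqs, function(f) {
    pr <- synthetic_protocol("sinusoid", frequency = f, amplitude = 0.00125,
                             n_cycles = 6, sample_rate = 40 * f)
    gen_linear_trace(model, pr)
  })
  spec <- sweep_spectrum(traces)
  y <- eval_nyquist(model, spec$frequency)
  expect_true(all(Mod(complex(real = spec$elastic, imaginary = spec$viscous) - y) <=
                  0.005 * Mod(y)))
})

test_that("work and power follow W = -pi eps0^2 E'' and P = W f", {
  spec <- modulus_spectrum(150, 800, -300, amplitude = 0.00125)
  wp <- work_and_power(spec)
  expect_equal(wp$work, pi * 0.00125^2 * 3e5, tolerance = 1e-9)  # 1.473 J/m^3
  expect_equal(wp$power, wp$work * 150)

  zero <- modulus_spectrum(c(10, 100), c(5, 5), c(0, 0), amplitude = 0.00125)
  expect_true(all(work_and_power(zero)$work == 0))

  # quadratic amplitude scaling
  wp2 <- work_and_power(spec, amplitude = 0.0025)
  expect_equal(wp2$work, 4 * wp$work)

  # sign coherence: P and W always share sign, P = W f identically
  spec3 <- control_spectrum()
  wp3 <- work_and_power(spec3)
  expect_true(all(sign(wp3$work) == sign(wp3$power) | wp3$work == 0))
  expect_identical(wp3$power, wp3$work * spec3$frequency)
})

test_that("spectrum summary matches a dense-grid argmax oracle", {
  spec <- control_spectrum()
  s <- summarize_spectrum(spec)
  # brute-force oracle: dense 1 Hz grid of -f * Im Y(f)
  f_dense <- seq(1, 650, by = 1)
  p_dense <- -f_dense * Im(eval_nyquist(control_nyquist(), f_dense))
  f_opt <- f_dense[which.max(p_dense)]
  # agreement within one measured grid step
  grid <- spec$frequency
  i_near <- which.min(abs(grid - f_opt))
  expect_true(abs(which(grid == s$f_max) - i_near) <= 1)
  expect_false(s$boundary_flag)
  # stiffness is read at the measured frequency nearest 500 Hz
  i500 <- which.min(abs(grid - 500))
  expect_equal(s$stiffness_500hz, spec$elastic[i500])
})

test_that("monotone power flags a boundary maximum", {
  f <- c(10, 50, 100)
  spec <- modulus_spectrum(f, c(100, 100, 100), c(-30, -20, -10),
                           amplitude = 0.00125)
  expect_warning(s <- summarize_spectrum(spec), "boundary")
  expect_true(s$boundary_flag)
  expect_equal(s$f_wmax, 10)
})

test_that("tension measurement subtracts passive from active plateau", {
  mk_iso <- function(level) {
    t <- seq(0, 1, by = 1e-3)
    length_force_trace(t, rep(0, length(t)) + 1e-9 * sin(2 * pi * t),
                       rep(level, length(t)), drive_frequency = 1,
                       amplitude = 0)
  }
  tm <- measure_tension(mk_iso(1.94), mk_iso(3.07))
  expect_equal(tm$net_f0, 1.13, tolerance = 1e-9)
  tm2 <- measure_tension(mk_iso(2.73), mk_iso(4.59))
  expect_equal(tm2$net_f0, 1.86, tolerance = 1e-9)
  tm3 <- measure_tension(mk_iso(2.5), mk_iso(2.5))
  expect_equal(tm3$net_f0, 0)
  # steep ramp has no plateau
  t <- seq(0, 1, by = 1e-3)
  ramp <- length_force_trace(t, rep(0, length(t)), 1 + 5 * t,
                             drive_frequency = 1, amplitude = 0)
  expect_error(measure_tension(ramp, mk_iso(3)), "plateau")
})
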