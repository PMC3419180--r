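test_that("waveform passes through the known anchor stages exactly", {
  wf <- build_waveform()
  ev <- waveform_eval(wf, c(0.26, 0.36, 0.80))
  expect_equal(ev$v_in, c(0.51, 0.42, 0.318), tolerance = 1e-12)
  expect_equal(ev$p_out, c(17850, 20206, 10869), tolerance = 1e-12)
})

test_that("waveform is periodic and the inlet velocity stays non-negative", {
  wf <- build_waveform()
  set.seed(42)
  t <- runif(100, -3, 3)
  e1 <- waveform_eval(wf, t)
  e2 <- waveform_eval(wf, t + wf$period)
  expect_equal(e1$v_in, e2$v_in, tolerance = 1e-12)
  expect_equal(e1$p_out, e2$p_out, tolerance = 1e-12)
  expect_true(all(waveform_eval(wf, seq(0, 1, by = 1e-3))$v_in >= 0))
})

test_that("the default cycle decelerates through late systole", {
  wf <- build_waveform()
  eps <- 1e-4
  dvdt <- (wf$v_in(0.8 + eps) - wf$v_in(0.8 - eps)) / (2 * eps)
  expect_lt(dvdt, 0)
})

test_that("a single anchor yields a constant waveform", {
  wf <- build_waveform(data.frame(t = 0, v_in = 0.156, p_out = 0), period = 1)
  ev <- waveform_eval(wf, c(0, 0.123, 0.9, 5.5))
  expect_true(all(ev$v_in == 0.156))
  expect_true(all(ev$p_out == 0))
})

test_that("waveform construction rejects bad anchors", {
  a <- data.frame(t = c(0.2, 0.2), v_in = c(1, 2), p_out = c(0, 0))
  expect_error(build_waveform(a), "duplicate")
  b <- data.frame(t = c(0.5, 0.2), v_in = c(1, 2), p_out = c(0, 0))
  expect_error(build_waveform(b), "sorted")
  # a deep negative excursion between anchors is rejected with advice
  cc <- data.frame(t = c(0.1, 0.2, 0.3), v_in = c(0.01, 2, 0.01),
                   p_out = c(0, 0, 0))
  expect_error(build_waveform(cc), "negative")
})

test_that("plane-Poiseuille closed form evaluates and scales linearly", {
  expect_equal(poiseuille_drop(0.0035, 0.156, 0.130, 0.003), 94.64,
               tolerance = 1e-4)
  expect_equal(poiseuille_drop(0.0035, 0.156, 0.260, 0.003),
               2 * poiseuille_drop(0.0035, 0.156, 0.130, 0.003))
  expect_equal(poiseuille_drop(0.0035, 0, 0.130, 0.003), 0)
})

test_that("coarse-mesh channel oracle matches the hand-solved 3-cell system", {
  # fully developed 3-cell system: wall cells -3u1 + u2 = -beta,
  # centre 2u1 - 2u2 = -beta => u = beta*(3/4, 5/4, 3/4), mean = 11/12 beta,
  # so the discrete gradient is 9/11 of the continuum one
  expect_equal(coarse_channel_drop(0.0035, 0.156, 0.130, 0.003, 3),
               (9 / 11) * poiseuille_drop(0.0035, 0.156, 0.130, 0.003),
               tolerance = 1e-12)
  # brute-force check of the n = 2 system: -3u1 + u2 = -beta (symmetric)
  # => u1 = u2 = beta/2, mean = beta/2 => ratio (1/2)/(3/2)... solve directly
  Tm <- matrix(c(-3, 1, 1, -3), 2, 2)
  z <- solve(Tm, c(-1, -1))
  dp2 <- 0.0035 * (0.156 / mean(z)) / (0.003 / 2)^2 * 0.130
  expect_equal(coarse_channel_drop(0.0035, 0.156, 0.130, 0.003, 2), dp2,
               tolerance = 1e-12)
  expect_lt(dp2, poiseuille_drop(0.0035, 0.156, 0.130, 0.003))
})

test_that("coarse oracle increases monotonically to the continuum limit", {
  drops <- vapply(2:40, function(n)
    coarse_channel_drop(0.0035, 0.156, 0.130, 0.003, n), numeric(1))
  expect_true(all(diff(drops) > 0))
  expect_equal(coarse_channel_drop(0.0035, 0.156, 0.130, 0.003, 100),
               94.64, tolerance = 1e-3)
})

test_that("waveform CSV export round-trips", {
  wf <- build_waveform()
  f <- tempfile(fileext = ".csv")
  write_waveform_csv(wf, f)
  x <- read.csv(f)
  expect_equal(names(x), c("t", "v_in", "p_out"))
  expect_equal(x$v_in[x$t == 0.26], 0.51, tolerance = 1e-9)
})
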