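# Filtering, resampling, baseline correction, segmentation, labels.

sinus_rec <- function(freq, fs, seconds, channels = 1) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  recording(matrix(rep(sin(2 * pi * freq * t), channels), nrow = channels,
                   byrow = TRUE), fs = fs)
}

test_that("bandpass attenuates stopband and preserves passband", {
  # 50 Hz tone at fs=128 through the 1-45 Hz broadband filter; the
  # zero-phase (forward-backward) pass has amplitude response |H(w)|^2
  rec <- sinus_rec(50, 128, 10)
  out <- bandpass(rec, 1, 45, order = 3)
  mid <- 129:1152                       # discard 1-s edges
  ratio <- sd(out$data[1, mid]) / sd(rec$data[1, mid])
  # oracle: evaluate the designed filter's transfer function analytically
  bf <- signal::butter(3, c(1, 45) / 64, type = "pass")
  z <- exp(-1i * 2 * pi * 50 / 128)
  Hmag <- Mod(sum(bf$b * z^(0:(length(bf$b) - 1))) /
                sum(bf$a * z^(0:(length(bf$a) - 1))))
  expect_equal(ratio, Hmag^2, tolerance = 0.02)
  expect_lt(ratio, 0.2)                 # strong attenuation 5 Hz past edge
  # 10 Hz tone through the alpha band keeps its amplitude
  rec10 <- sinus_rec(10, 128, 10)
  alpha <- bandpass(rec10, 8, 13, order = 3)
  expect_equal(sd(alpha$data[1, mid]), sd(rec10$data[1, mid]),
               tolerance = 0.05)
  # zero in, zero out; invalid band errors
  z <- recording(matrix(0, 1, 256), 128)
  expect_equal(bandpass(z, 1, 45)$data, z$data)
  expect_error(bandpass(rec, 1, 70), "invalid band")
})

test_that("passband filtering is nearly idempotent", {
  rec <- sinus_rec(10, 128, 10)
  once <- bandpass(rec, 8, 13)
  twice <- bandpass(once, 8, 13)
  mid <- 129:1152
  expect_lt(abs(sd(twice$data[1, mid]) / sd(once$data[1, mid]) - 1), 0.10)
})

test_that("resampling: sample counts, waveform fidelity, identity, errors", {
  rec <- sinus_rec(5, 1024, 20)
  expect_equal(ncol(rec$data), 20480)
  down <- resample_recording(rec, 128)
  expect_equal(ncol(down$data), 2560)
  expect_equal(down$fs, 128)
  ideal <- sin(2 * pi * 5 * seq(0, 20 - 1 / 128, by = 1 / 128))
  expect_gt(cor(down$data[1, ], ideal), 0.999)
  same <- resample_recording(rec, 1024)
  expect_identical(same$data, rec$data)
  expect_error(resample_recording(rec, 2048), "upsampling")
})

test_that("baseline correction subtracts the early mean and drops it", {
  const <- recording(matrix(7, 2, 128 * 20), 128)
  out <- baseline_correct(const, 2)
  expect_equal(ncol(out$data), 18 * 128)
  expect_true(all(abs(out$data) < 1e-12))
  set.seed(3)
  rec <- recording(matrix(rnorm(2 * 128 * 20, mean = 5), 2), 128)
  out2 <- baseline_correct(rec, 2)
  # definition: the baseline window has mean zero after the shift
  mu <- rowMeans(rec$data[, 1:256])
  expect_lt(max(abs(rowMeans(rec$data[, 1:256] - mu))), 1e-9)
  expect_error(baseline_correct(recording(matrix(0, 1, 100), 128), 2),
               "shorter")
})

test_that("segmentation: counts, shapes, taper power, reconstruction", {
  set.seed(8)
  rec <- recording(matrix(rnorm(128 * 18 * 128), nrow = 128), 128,
                   meta = list(trial_id = "t1", class_name = "calm"))
  segs <- segment_recording(rec, 2, taper = "none")
  expect_length(segs, 9)
  expect_equal(dim(segs[[1]]$data), c(128, 256))
  # concatenating untapered windows reconstructs the trimmed recording
  expect_equal(do.call(cbind, lapply(segs, `[[`, "data")),
               rec$data[, 1:(9 * 256)])
  # hann taper with power renormalization keeps white-noise power
  set.seed(21)
  long <- recording(matrix(rnorm(1 * 1000 * 256), nrow = 1), 128)
  vh <- mean(sapply(segment_recording(long, 2, taper = "hann"),
                    function(s) mean(s$data^2)))
  vn <- mean(sapply(segment_recording(long, 2, taper = "none"),
                    function(s) mean(s$data^2)))
  expect_equal(vh / vn, 1, tolerance = 0.05)
  # too-short recording warns and returns nothing
  expect_warning(out <- segment_recording(recording(matrix(0, 1, 100), 128), 2),
                 "shorter")
  expect_length(out, 0)
})

test_that("band decomposition separates tones and conserves broadband power", {
  rec <- sinus_rec(10, 128, 4)
  bd <- band_decompose(rec)
  expect_named(bd, c("theta", "alpha", "beta", "gamma"))
  v <- sapply(bd, function(m) var(m[1, ]))
  expect_true(all(v["alpha"] > 10 * v[c("theta", "beta", "gamma")]))
  expect_true(all(sapply(bd, dim)[1, ] == 1 & sapply(bd, dim)[2, ] == 512))
  # Parseval-style bound on 1-45 Hz noise: band powers cannot exceed total
  set.seed(5)
  noise <- bandpass(recording(matrix(rnorm(4 * 128 * 8), 4), 128), 1, 45)
  bd2 <- band_decompose(noise)
  tot <- apply(noise$data, 1, var)
  bsum <- rowSums(sapply(bd2, function(m) apply(m, 1, var)))
  expect_true(all(bsum <= tot * 1.1))
})

test_that("rating binarization threshold and monotonicity", {
  expect_identical(as.integer(binarize_ratings(3)), 0L)
  expect_identical(as.integer(binarize_ratings(7)), 1L)
  expect_identical(as.integer(binarize_ratings(5)), 1L)   # boundary -> high
  r <- seq(1, 9, by = 0.5)
  expect_true(all(diff(as.integer(binarize_ratings(r))) >= 0))
  expect_error(binarize_ratings(0.5), "\\[1, 9\\]")
  expect_error(binarize_ratings(10), "\\[1, 9\\]")
})

test_that("end-to-end preprocessing yields the expected segment count", {
  ds <- fixture_dataset()
  segs <- preprocess_dataset(ds$recordings, ds$ratings)
  # 10-s trials, 2-s baseline dropped -> 8 usable seconds -> 4 windows each
  expect_length(segs, length(ds$recordings) * 4)
  s <- segs[[1]]
  expect_equal(dim(s$data), c(8, 256))
  expect_true(all(vapply(segs, function(x) x$valence_label, integer(1))
                  %in% c(0L, 1L)))
  # labels follow the class rating structure: fear = low valence, high arousal
  fear <- Filter(function(x) x$class_name == "fear", segs)
  expect_true(all(vapply(fear, function(x) x$valence_label, integer(1)) == 0L))
  expect_true(all(vapply(fear, function(x) x$arousal_label, integer(1)) == 1L))
})
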