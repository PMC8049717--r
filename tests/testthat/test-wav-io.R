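test_that("WAV roundtrip preserves samples in both encodings", {
  x <- sin(2 * pi * 440 * seq_len(2000) / 8000) * 0.7
  f16 <- tempfile(fileext = ".wav")
  write_wav(x, 8000, f16, format = "pcm16")
  r16 <- read_wav(f16)
  expect_equal(r16$rate_hz, 8000)
  expect_equal(r16$samples, x, tolerance = 1e-4)
  f32 <- tempfile(fileext = ".wav")
  write_wav(x, 8000, f32, format = "float32")
  r32 <- read_wav(f32)
  expect_equal(r32$samples, x, tolerance = 1e-7)
})

test_that("pcm16 clips out-of-range samples", {
  f <- tempfile(fileext = ".wav")
  write_wav(c(-2, 0, 2), 1000, f, format = "pcm16")
  r <- read_wav(f)
  expect_equal(r$samples, c(-1, 0, 1), tolerance = 1e-4)
})

test_that("read_wav rejects non-WAV data", {
  f <- tempfile(fileext = ".wav")
  writeLines("definitely not audio", f)
  expect_error(read_wav(f), "RIFF")
})
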