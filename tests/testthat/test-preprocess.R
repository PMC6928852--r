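test_that("denoising annihilates zero and constant inputs", {
  rec0 <- ecg_record("z", rep(0, 1000))
  expect_equal(denoise(rec0)$samples, rep(0, 1000))

  rec_c <- ecg_record("c", rep(5, 1000))
  out <- denoise(rec_c)$samples
  expect_lt(max(abs(out)), 1e-6)
  expect_lt(abs(mean(out)), 1e-6)
})

test_that("denoising is linear and length/annotation preserving", {
  set.seed(4)
  x <- cumsum(rnorm(2000)) / 10
  rec <- ecg_record("r", x, ann_indices = c(500L, 1000L),
                    ann_symbols = c("N", "V"))
  out1 <- denoise(rec)
  rec3 <- rec; rec3$samples <- 3 * x
  out3 <- denoise(rec3)
  expect_equal(out3$samples, 3 * out1$samples, tolerance = 1e-9)
  expect_length(out1$samples, length(x))
  expect_identical(out1$ann_indices, rec$ann_indices)
})

test_that("60 Hz interference is attenuated at least as much as the analytic low-pass bound", {
  fs <- 360
  n <- 7200
  rec <- ecg_record("pl", make_tone(60, n = n, fs = fs))
  out <- denoise(rec)$samples
  # 4th-order Butterworth at 45 Hz, applied forward-backward, has squared
  # magnitude 1/(1 + (60/45)^8) at 60 Hz; the full chain can only attenuate
  # further (moving average and high-pass both have gain <= 1 there).
  bound <- 1 / (1 + (60 / 45)^8)
  core <- (n / 4):(3 * n / 4)  # avoid filter edge transients
  rms_ratio <- sqrt(mean(out[core]^2)) / sqrt(mean(rec$samples[core]^2))
  expect_lt(rms_ratio, bound)
})

test_that("denoise rejects bad inputs", {
  expect_error(denoise(ecg_record("e", numeric())), "empty")
  rec <- ecg_record("s", rnorm(100), fs = 80)
  expect_error(denoise(rec), "sampling rate")
})

test_that("annotation symbols map onto the AAMI groups", {
  expect_equal(map_aami_label(c("N", "L", "R", "e", "j")), rep("N", 5))
  expect_equal(map_aami_label(c("A", "a", "J", "S")), rep("S", 4))
  expect_equal(map_aami_label(c("V", "E", "!")), rep("V", 3))
  expect_equal(map_aami_label("F"), "F")
  expect_equal(map_aami_label(c("/", "f", "Q")), rep("Q", 3))
  expect_true(is.na(map_aami_label("+")))     # rhythm annotation
  expect_true(is.na(map_aami_label("~")))     # artifact
  expect_warning(res <- map_aami_label("?"), "unknown")
  expect_true(is.na(res))
})

test_that("segmentation emits 300-sample windows and drops edge beats", {
  rec <- generate_record(20, class_mix = c(N = 1, S = 0, V = 0, F = 0, Q = 0),
                         noise = noise_params(white_sd = 0), seed = 2)
  segs <- segment_beats(denoise(rec))
  expect_length(segs, 20)    # all interior by construction (padded record)
  expect_true(all(vapply(segs, function(s) length(s$samples), integer(1)) == 300))
  expect_true(all(vapply(segs, `[[`, character(1), "aami_class") == "N"))

  # window leaving the record start drops the beat
  short <- ecg_record("s", rnorm(500), ann_indices = c(10L, 250L),
                      ann_symbols = c("N", "N"))
  segs2 <- segment_beats(short, pre_samples = 100, post_samples = 200)
  expect_length(segs2, 1)
  expect_identical(segs2[[1]]$r_index, 250L)

  expect_error(segment_beats(short, pre_samples = 100, post_samples = 100),
               "300")
})

test_that("segments are cut at the annotated position", {
  rec <- generate_record(10, class_mix = c(N = 1, S = 0, V = 0, F = 0, Q = 0),
                         noise = noise_params(0, 0.3, 0, 60, 0), seed = 5)
  segs <- segment_beats(rec, pre_samples = 100, post_samples = 200)
  # sample 101 of each window (0-based offset 100) is the annotated R sample
  for (s in segs[1:3]) {
    expect_equal(s$samples[101],
                 rec$samples[s$r_index + 1])
    expect_equal(which.max(s$samples[80:120]) + 79, 101, tolerance = 2)
  }
})

test_that("DS1/DS2 split matches the canonical inter-patient partition", {
  sp <- split_ds1_ds2()
  expect_length(sp$ds1_records, 22)
  expect_length(sp$ds2_records, 22)
  expect_length(intersect(sp$ds1_records, sp$ds2_records), 0)
  expect_true("101" %in% sp$ds1_records)
  expect_true("100" %in% sp$ds2_records)
  expect_true(all(c("102", "104", "107", "217") %in% sp$excluded_records))
  expect_false(any(c("102", "104", "107", "217") %in%
                     c(sp$ds1_records, sp$ds2_records)))

  sub <- split_ds1_ds2(c("101", "100", "104", "999"))
  expect_equal(sub$ds1_records, "101")
  expect_equal(sub$ds2_records, "100")
  expect_true(all(c("104", "999") %in% sub$excluded_records))
})

test_that("plain-text record IO round-trips", {
  dir <- withr::local_tempdir()
  rec <- generate_record(5, seed = 9, record_id = "io1")
  write_ecg_csv(rec, dir)
  back <- read_ecg_csv(file.path(dir, "io1.csv"),
                       file.path(dir, "io1_ann.json"))
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_identical(back$ann_indices, rec$ann_indices)
  expect_identical(back$ann_symbols, rec$ann_symbols)
})
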