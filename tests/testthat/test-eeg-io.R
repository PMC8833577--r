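test_that("raw+json container round-trips losslessly", {
  rec <- withr::with_seed(1, hfo_recording(matrix(stats::rnorm(3 * 4000), 3),
                                           2000, c("a", "b", "c"), "pt1"))
  d <- withr::local_tempdir()
  write_recording(rec, file.path(d, "pt1.json"))
  r2 <- read_recording(file.path(d, "pt1.json"))
  expect_identical(r2$signal, rec$signal)
  expect_identical(r2$sampling_rate, rec$sampling_rate)
  expect_identical(r2$channel_names, rec$channel_names)
})

test_that("EDF round-trip stays within one 16-bit quantization step", {
  rec <- withr::with_seed(2, hfo_recording(matrix(stats::rnorm(2 * 4000, sd = 50), 2),
                                           2000, c("ch1", "ch2"), "pt2"))
  d <- withr::local_tempdir()
  write_recording(rec, file.path(d, "pt2.edf"))
  r2 <- read_recording(file.path(d, "pt2.edf"))
  step <- apply(rec$signal, 1, function(z) diff(range(z))) / 65535
  for (ch in 1:2)
    expect_lt(max(abs(r2$signal[ch, ] - rec$signal[ch, ])), step[ch])
  expect_equal(r2$sampling_rate, 2000)
})

test_that("corrupt containers raise corrupt-input errors", {
  d <- withr::local_tempdir()
  writeLines('{"sampling_rate": 2000, "channel_names": ["a"]}',
             file.path(d, "bad.json"))
  expect_error(read_recording(file.path(d, "bad.json")),
               class = "epihfo_corrupt_input")
  writeBin(raw(100), file.path(d, "bad.edf"))
  expect_error(read_recording(file.path(d, "bad.edf")),
               class = "epihfo_corrupt_input")
  expect_error(read_recording(file.path(d, "absent.json")), "not found")
})

test_that("average reference matches closed forms and direct computation", {
  # identical channels cancel
  sig <- matrix(rep(sin(1:100), each = 3), 3, byrow = FALSE)
  rec <- hfo_recording(matrix(rep(sin(1:100), 3), 3, byrow = TRUE), 100)
  expect_equal(max(abs(apply_average_reference(rec)$signal)), 0)
  # two channels a, b -> (a-b)/2, (b-a)/2
  a <- stats::rnorm(50); b <- stats::rnorm(50)
  rec2 <- hfo_recording(rbind(a, b), 100, c("a", "b"))
  ar2 <- apply_average_reference(rec2)
  expect_equal(ar2$signal[1, ], (a - b) / 2, ignore_attr = TRUE)
  expect_equal(ar2$signal[2, ], (b - a) / 2, ignore_attr = TRUE)
  # 4 channels, one excluded: direct mean oracle
  x <- matrix(stats::rnorm(4 * 200), 4)
  rec4 <- hfo_recording(x, 100, paste0("c", 1:4))
  meta <- data.frame(channel = paste0("c", 1:4), excluded = c(0, 0, 0, 1))
  ar4 <- apply_average_reference(rec4, meta)
  ref <- colMeans(x[1:3, ])
  expect_equal(max(abs(colSums(ar4$signal[1:3, ]))), 0, tolerance = 1e-9)
  expect_equal(ar4$signal[4, ], x[4, ] - ref, ignore_attr = TRUE)
  # idempotent on included channels
  ar4b <- apply_average_reference(ar4, meta)
  expect_equal(ar4b$signal, ar4$signal, tolerance = 1e-9)
  # all-excluded montage rejected
  meta_all <- data.frame(channel = paste0("c", 1:4), excluded = 1)
  expect_error(apply_average_reference(rec4, meta_all),
               class = "epihfo_invalid_montage")
})

test_that("event tables round-trip and enforce their schema", {
  d <- withr::local_tempdir()
  ev <- data.frame(patient = "p1", channel = "c1", start_sample = 10L,
                   end_sample = 20L, n_peaks = 7L, probability = 0.25)
  f <- file.path(d, "events.csv")
  write_event_table(ev, f)
  expect_equal(read_event_table(f), ev)
  bad <- ev[, setdiff(names(ev), "end_sample")]
  expect_error(write_event_table(bad, f), class = "epihfo_schema_error")
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_event_table(f), class = "epihfo_schema_error")
})
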