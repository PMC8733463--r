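# EDF and annotation round trips.

test_that("EDF write/read round-trips a multirate recording within quantization", {
  set.seed(7)
  rec <- make_test_recording(
    duration_s = 60,
    eeg_fun = function(t) 300 * sin(2 * pi * 5 * t) + rnorm(length(t), sd = 20))
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path)
  back <- read_recording(path)

  expect_identical(back$person_id, rec$person_id)
  for (lab in required_channel_labels()) {
    orig <- get_channel(rec, lab)
    got <- get_channel(back, lab)
    expect_identical(got$fs, orig$fs)
    expect_identical(got$units, orig$units)
    pr <- default_physical_range()[[orig$role]]
    q <- diff(pr) / 2^15  # spec quantization bound, one LSB is half this
    expect_lt(max(abs(got$samples - orig$samples)), q)
  }
})

test_that("an independent EDF reader parses a written file", {
  # mne (Python) as an independent oracle for the hand-rolled EDF writer
  rec <- make_test_recording(duration_s = 10)
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path)
  script <- paste0(
    "import mne\n",
    "raw = mne.io.read_raw_edf(r'", path, "', verbose='ERROR')\n",
    "print(','.join(raw.ch_names))\n",
    "x = raw.get_data(picks=['EEG_prox'])[0]\n",
    "print(abs(x).max())\n")
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- system2("python", sf, stdout = TRUE, stderr = FALSE)
  expect_true(all(required_channel_labels() %in% strsplit(out[1], ",")[[1]]))
  # mne reports EEG in volts; the 50 uV sine peak must survive the round trip
  expect_equal(as.numeric(out[2]) * 1e6, 50, tolerance = 0.01)
})

test_that("channel aliases map onto the naming convention; missing labels error", {
  rec <- make_test_recording(duration_s = 10)
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path)
  # aliasing ACC_z away makes a required label missing
  expect_ip_error(read_recording(path, channel_map = c(ACC_z = "ACC_w")),
                  "ip_format_error")
  # a full alias map round-trips
  back <- read_recording(path, channel_map = c(EEG_prox = "EEG_prox"))
  expect_s3_class(back, "recording")
})

test_that("samples beyond the physical range raise a range error, no clipping", {
  rec <- make_test_recording(duration_s = 10,
                             eeg_fun = function(t) 1500 * sin(2 * pi * 2 * t))
  path <- withr::local_tempfile(fileext = ".edf")
  expect_ip_error(write_recording(rec, path), "ip_range_error")
  expect_false(file.exists(path) && file.size(path) > 0)
})

test_that("recordings must span whole seconds and carry the full channel set", {
  rec <- make_test_recording(duration_s = 10)
  rec$channels[[1]]$samples <- rec$channels[[1]]$samples[-(1:10)]
  path <- withr::local_tempfile(fileext = ".edf")
  expect_error(write_recording(rec, path))
  expect_ip_error(
    recording("x", list(channel_signal("EEG_prox", "eeg", 207, numeric(207)))),
    "ip_format_error")
})

test_that("annotation CSV round-trip is bit-identical and validated", {
  annos <- seizure_annotations(
    person_id = c("B", "A", "A"), seizure_id = c("s1", "s1", "s2"),
    onset_s = c(100, 300, 50), duration_s = c(20, 30, 25),
    label = c("FBTCS", "electrographic", "electrographic"))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_annotations(annos, p1)
  back <- read_annotations(p1)
  # deterministic (person_id, onset_s) ordering
  expect_identical(back$person_id, c("A", "A", "B"))
  expect_identical(back$onset_s, c(50, 300, 100))
  write_annotations(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("annotation validation rejects bad labels and times", {
  expect_ip_error(
    seizure_annotations("A", "s1", 10, 20, label = "GTCS"),
    "ip_validation_error")
  expect_ip_error(seizure_annotations("A", "s1", -1, 20), "ip_validation_error")
  expect_ip_error(seizure_annotations("A", "s1", 10, 0), "ip_validation_error")
  expect_ip_error(
    seizure_annotations(c("A", "A"), c("s1", "s1"), c(1, 2), c(5, 5)),
    "ip_validation_error")
})

test_that("an empty annotation list writes a header-only CSV", {
  empty <- seizure_annotations(character(), character(), numeric(), numeric(),
                               character())
  p <- withr::local_tempfile(fileext = ".csv")
  write_annotations(empty, p)
  lines <- readLines(p)
  expect_length(lines, 1L)
  expect_match(lines, "person_id,seizure_id,onset_s,duration_s,label")
  expect_identical(nrow(read_annotations(p)), 0L)
})
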