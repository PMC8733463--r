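# Cohort filter and period arithmetic.

test_that("the rebuilt study cohort retains 74 electrographic seizures", {
  annos <- table1_annotations()
  expect_identical(nrow(annos), 78L)
  flt <- filter_cohort(annos, min_seizures = 10)
  expect_identical(nrow(flt$kept), 74L)
  expect_true(all(flt$kept$label == "electrographic"))
  expect_identical(nrow(flt$log), 4L)
  expect_true(all(flt$log$reason == "FBTCS excluded"))
})

test_that("persons below the seizure minimum are removed entirely", {
  nine <- seizure_annotations("low", sprintf("s%d", 1:9),
                              onset_s = 400 + (0:8) * 500, duration_s = 30)
  flt <- filter_cohort(nine)
  expect_identical(nrow(flt$kept), 0L)
  expect_identical(nrow(flt$log), 9L)
  expect_true(all(flt$log$reason == "below minimum"))
})

test_that("FBTCS removal happens before the count threshold", {
  # 10 electrographic + 3 FBTCS: the FBTCS go first, the 10 stay
  annos <- seizure_annotations(
    "p", sprintf("s%d", 1:13), onset_s = 400 + (0:12) * 500, duration_s = 30,
    label = c(rep("electrographic", 10), rep("FBTCS", 3)))
  flt <- filter_cohort(annos)
  expect_identical(nrow(flt$kept), 10L)
  # and 9 electrographic + 3 FBTCS loses everything
  annos9 <- annos[annos$seizure_id != "s10", ]
  flt9 <- filter_cohort(annos9)
  expect_identical(nrow(flt9$kept), 0L)
  expect_identical(sort(unique(flt9$log$reason)),
                   c("FBTCS excluded", "below minimum"))
})

test_that("filter_cohort is idempotent and warns on empty input", {
  flt <- filter_cohort(table1_annotations())
  again <- filter_cohort(flt$kept)
  expect_identical(again$kept, flt$kept)
  expect_identical(nrow(again$log), 0L)
  empty <- flt$kept[0, ]
  expect_warning(res <- filter_cohort(empty), "empty")
  expect_identical(nrow(res$kept), 0L)
})

test_that("period bounds follow the closed forms for random onsets/durations", {
  set.seed(42)
  for (i in 1:200) {
    o <- runif(1, 360, 5000)
    d <- runif(1, 6.01, 180)
    pb <- period_bounds(o, d)
    expect_equal(pb$start_s[pb$kind == "ictal"], o + 2)
    expect_equal(pb$end_s[pb$kind == "ictal"], o + d - 2)
    expect_equal(unlist(pb[pb$kind == "preictal", c("start_s", "end_s")],
                        use.names = FALSE), c(o - 60, o - 2))
    expect_equal(unlist(pb[pb$kind == "baseline", c("start_s", "end_s")],
                        use.names = FALSE), c(o - 360, o - 300))
  }
})

test_that("extract_periods emits the closed-form windows on a recording", {
  rec <- make_test_recording(duration_s = 1200)
  annos <- seizure_annotations("T", "s1", onset_s = 1000, duration_s = 30)
  per <- extract_periods(rec, annos)
  expect_identical(nrow(per), 3L)
  ict <- per[per$kind == "ictal", ]
  expect_equal(c(ict$start_s, ict$end_s), c(1002, 1028))
  expect_equal(unlist(per[per$kind == "preictal", c("start_s", "end_s")],
                      use.names = FALSE), c(940, 998))
  expect_equal(unlist(per[per$kind == "baseline", c("start_s", "end_s")],
                      use.names = FALSE), c(640, 700))
})

test_that("short seizures and out-of-range windows are skipped with reasons", {
  rec <- make_test_recording(duration_s = 600)
  short <- seizure_annotations("T", "s1", onset_s = 400, duration_s = 5)
  per <- extract_periods(rec, short)
  expect_false("ictal" %in% per$kind)
  log <- attr(per, "skip_log")
  expect_true(any(log$kind == "ictal" & grepl("minimum", log$reason)))

  early <- seizure_annotations("T", "s2", onset_s = 200, duration_s = 30)
  per2 <- extract_periods(rec, early)
  expect_setequal(per2$kind, c("ictal", "preictal"))
  log2 <- attr(per2, "skip_log")
  expect_true(any(log2$kind == "baseline" & grepl("before recording", log2$reason)))
})

test_that("pre-ictal/baseline windows colliding with another seizure are dropped", {
  rec <- make_test_recording(duration_s = 2000)
  # s2 starts 20 s after s1 ends: its pre-ictal window overlaps s1's ictal
  # interval; s3 starts 350 s after s1's onset: its baseline window does
  annos <- seizure_annotations("T", c("s1", "s2", "s3"),
                               onset_s = c(1000, 1050, 1350),
                               duration_s = c(30, 30, 30))
  per <- extract_periods(rec, annos)
  expect_identical(per$kind[per$seizure_id == "s2"], c("ictal", "baseline"))
  expect_identical(per$kind[per$seizure_id == "s3"], c("ictal", "preictal"))
  log <- attr(per, "skip_log")
  expect_identical(log$kind[log$seizure_id == "s2"], "preictal")
  expect_identical(log$kind[log$seizure_id == "s3"], "baseline")
  expect_true(all(grepl("overlaps", log$reason)))
})

test_that("no emitted period overlaps another seizure's ictal interval", {
  set.seed(5)
  onsets <- c(500, 1200, 1290, 2500)
  annos <- seizure_annotations("T", sprintf("s%d", 1:4), onset_s = onsets,
                               duration_s = c(30, 40, 35, 25))
  rec <- make_test_recording(duration_s = 3000)
  per <- extract_periods(rec, annos)
  for (i in seq_len(nrow(per))) {
    others <- annos[annos$seizure_id != per$seizure_id[i], ]
    expect_false(any(per$start_s[i] < others$onset_s + others$duration_s &
                       per$end_s[i] > others$onset_s))
  }
})
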