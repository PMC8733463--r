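# Synthetic cohort generator: determinism, planted signatures, manifests.

test_that("the same profile and seed reproduce bit-identical data", {
  co <- small_cohort(3)
  a <- simulate_recording(co$profiles[[1]], co)
  b <- simulate_recording(co$profiles[[1]], co)
  for (k in 1:5)
    expect_identical(a$recording$channels[[k]]$samples,
                     b$recording$channels[[k]]$samples)
  expect_identical(a$annotations, b$annotations)
})

test_that("a null profile leaves ictal features at baseline level", {
  # background drift is disabled so ictal and baseline windows (which differ
  # in length) are exchangeable: any remaining ictal/baseline difference
  # would have to come from the planting path, which must be inert here
  co <- cohort_spec(
    list(person_profile("N", n_seizures = 20,
                        seizure_duration_s = c(20, 40), seed = 11)),
    background_eeg = list(alpha = 1, sd = 20, alpha_spread = 0,
                          amp_mod_sd = 0, dist_gain = 0.02),
    background_acc = list(gravity = c(0, 0, 1), noise_sd = 0.02,
                          posture_sd = 0))
  sim <- simulate_recording(co$profiles[[1]], co)
  per <- extract_periods(sim$recording, sim$annotations)
  tab <- compute_feature_table(sim$recording, per)
  feats <- setdiff(names(tab), feature_meta_cols())
  pvals <- vapply(feats, function(f) {
    p <- suppressWarnings(stats::wilcox.test(
      tab[[f]][tab$kind == "ictal"],
      tab[[f]][tab$kind == "baseline"]))$p.value
    if (is.nan(p)) 1 else p  # fully tied feature: indistinguishable
  }, numeric(1))
  # at the 1 % level no more than a chance-consistent handful of the 65
  # (correlated) features may differ between ictal and baseline
  expect_lte(sum(pvals < 0.01), 3)
})

test_that("a planted low-theta gain raises ictal relative low-theta power", {
  co <- cohort_spec(list(
    person_profile("T", eeg_band_gain = c(low_theta = 4), n_seizures = 15,
                   seizure_duration_s = c(20, 40), seed = 1)))
  sim <- simulate_recording(co$profiles[[1]], co)
  per <- extract_periods(sim$recording, sim$annotations)
  tab <- compute_feature_table(sim$recording, per,
                               feature_catalog("paper5"))
  expect_gt(mean(tab$eeg_relpow_low_theta[tab$kind == "ictal"]),
            mean(tab$eeg_relpow_low_theta[tab$kind == "baseline"]))
})

test_that("FBTCS extras are injected, labelled and countable", {
  co <- archetype_cohort(seed = 2, n_seizures = c(B = 10, E = 10, G = 10, I = 10))
  annos <- NULL
  for (p in co$profiles)
    annos <- rbind(annos, simulate_recording(p, co)$annotations)
  expect_identical(sum(annos$label == "FBTCS"), 4L)
  expect_identical(sort(unique(annos$person_id[annos$label == "FBTCS"])),
                   c("B", "E"))
  counts <- table(annos$person_id[annos$label == "electrographic"])
  expect_true(all(counts == 10))
})

test_that("simulate_cohort writes per-person EDFs, one CSV and a manifest", {
  dir <- withr::local_tempdir()
  co <- small_cohort(5)
  man <- simulate_cohort(co, dir)
  expect_length(man$edf_paths, 2L)
  expect_true(all(file.exists(unlist(man$edf_paths))))
  expect_true(file.exists(man$annotation_path))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  annos <- read_annotations(man$annotation_path)
  expect_identical(nrow(annos), 20L)

  # byte-identical CSV and sample-identical EDF on rerun
  dir2 <- withr::local_tempdir()
  man2 <- simulate_cohort(co, dir2)
  expect_identical(readLines(man$annotation_path),
                   readLines(man2$annotation_path))
  expect_identical(readBin(man$edf_paths[[1]], "raw", 5e6),
                   readBin(man2$edf_paths[[1]], "raw", 5e6))
})

test_that("a single-profile cohort simulates to one EDF", {
  dir <- withr::local_tempdir()
  co <- cohort_spec(list(person_profile("solo", n_seizures = 10, seed = 9)))
  man <- simulate_cohort(co, dir)
  expect_length(man$edf_paths, 1L)
})

test_that("a capped timeline that cannot host the seizures is a config error", {
  co <- cohort_spec(list(person_profile("X", n_seizures = 10, seed = 1)),
                    max_duration_s = 600)
  expect_ip_error(simulate_recording(co$profiles[[1]], co), "ip_config_error")
})

test_that("profile invariants are enforced", {
  expect_ip_error(person_profile("A", n_seizures = 9), "ip_config_error")
  expect_ip_error(person_profile("A", seizure_duration_s = c(5, 10)),
                  "ip_config_error")
  expect_ip_error(person_profile("A", eeg_band_gain = c(theta = 2)),
                  "ip_config_error")
  expect_ip_error(
    cohort_spec(list(person_profile("A"), person_profile("A"))),
    "ip_config_error")
})
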