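# Abundance-mass confusion scoring and study-level evaluation.

test_that("a perfectly reproduced profile yields zero disagreement mass", {
  set.seed(3)
  for (i in 1:10) {
    prof <- random_profile(8)
    mock <- names(prof)[1:4]
    for (scheme in c("excess-deficit", "split-mass")) {
      cm <- confusion_mass(prof, prof, mock, scheme)
      expect_equal(cm$TP, sum(prof[mock]))
      expect_equal(cm$TN, sum(prof[!names(prof) %in% mock]))
      expect_equal(cm$FP, 0)
      expect_equal(cm$FN, 0)
      pm <- performance_metrics(cm)
      expect_equal(pm$accuracy, 1)
      expect_equal(pm$f_score, 1)
    }
  }
})

test_that("the worked example evaluates to the exact fractions under both
           schemes", {
  toy <- toy_profiles()
  cm <- confusion_mass(toy$observed, toy$expected, toy$mock, "excess-deficit")
  expect_equal(c(cm$TP, cm$FP, cm$FN, cm$TN), c(0.8, 0.1, 0.2, 0))
  pm <- performance_metrics(cm)
  expect_equal(pm$accuracy, 8 / 11)
  expect_equal(pm$precision, 8 / 9)
  expect_equal(pm$sensitivity, 4 / 5)
  expect_equal(pm$f_score, 16 / 19)

  cm2 <- confusion_mass(toy$observed, toy$expected, toy$mock, "split-mass")
  expect_equal(c(cm2$TP, cm2$FP, cm2$FN, cm2$TN), c(0.8, 0.3, 0.1, 0))
  pm2 <- performance_metrics(cm2)
  expect_equal(pm2$accuracy, 2 / 3)
  expect_equal(pm2$precision, 8 / 11)
  expect_equal(pm2$sensitivity, 8 / 9)
  expect_equal(pm2$f_score, 4 / 5)
})

test_that("zero denominators are total and flagged degenerate", {
  pm <- performance_metrics(list(TP = 0, FP = 0, TN = 0, FN = 1))
  expect_equal(c(pm$accuracy, pm$precision, pm$sensitivity, pm$f_score),
               c(0, 0, 0, 0))
  expect_true(pm$degenerate[["precision"]])
  expect_true(pm$degenerate[["f_score"]])
  expect_false(pm$degenerate[["accuracy"]])
  expect_error(confusion_mass(c(a = 1), c(a = 1), character(0)), "non-empty")
  expect_error(confusion_mass(c(a = 0.5), c(a = 1), "a"), "sum to 1")
})

test_that("confusion-mass identities and metric bounds hold on random
           profiles", {
  set.seed(11)
  for (i in 1:200) {
    k <- sample(3:10, 1)
    taxa <- paste0("t", 1:k)
    obs <- random_profile(k, taxa)
    exp_ <- random_profile(k, taxa)
    mock <- sample(taxa, sample(seq_len(k - 1), 1))
    ed <- confusion_mass(obs, exp_, mock, "excess-deficit")
    # mass bookkeeping: TP + FP = observed mock mass; TP + FN = expected
    expect_equal(ed$TP + ed$FP, sum(obs[mock]), tolerance = 1e-12)
    expect_equal(ed$TP + ed$FN, sum(exp_[mock]), tolerance = 1e-12)
    for (scheme in c("excess-deficit", "split-mass")) {
      pm <- performance_metrics(confusion_mass(obs, exp_, mock, scheme))
      v <- c(pm$accuracy, pm$precision, pm$sensitivity, pm$f_score)
      expect_true(all(v >= 0 & v <= 1))
      if (pm$precision > 0 && pm$sensitivity > 0) {
        expect_lte(pm$f_score, max(pm$precision, pm$sensitivity) + 1e-12)
        expect_gte(pm$f_score, min(pm$precision, pm$sensitivity) - 1e-12)
      }
      # invariance under taxon permutation
      perm <- sample(k)
      pm_p <- performance_metrics(confusion_mass(obs[perm], exp_[perm], mock,
                                                 scheme))
      expect_equal(pm_p$accuracy, pm$accuracy, tolerance = 1e-12)
      expect_equal(pm_p$f_score, pm$f_score, tolerance = 1e-12)
    }
  }
})

test_that("profiles over different genus sets are aligned on their union", {
  obs <- c(Bacillus = 0.6, Acinetobacter = 0.4)
  exp_ <- c(Bacillus = 0.5, Lactococcus = 0.5)
  cm <- confusion_mass(obs, exp_, c("Bacillus", "Lactococcus"))
  expect_equal(cm$TP, 0.5)  # Bacillus overlap
  expect_equal(cm$FP, 0.1)  # Bacillus excess
  expect_equal(cm$FN, 0.5)  # Lactococcus missed entirely
  expect_equal(cm$TN, 0)    # Acinetobacter absent from reference
})

make_identity_study <- function() {
  # two methods whose spiked samples reproduce the matched control exactly
  taxa <- c("Bacillus", "Escherichia", "Lactococcus", "Pseudomonas",
            "Staphylococcus", "Acinetobacter")
  base <- c(200, 200, 200, 200, 150, 50)
  mk <- function(ids) {
    m <- matrix(rep(base, length(ids)), nrow = length(taxa),
                dimnames = list(taxa, ids))
    count_table(m, rank = "genus")
  }
  tables <- list(
    illumina_shotgun = mk(c("i-shotgun-live-1", "i-shotgun-dead-1",
                            "i-shotgun-control_live-1",
                            "i-shotgun-control_dead-1")),
    ont_s16 = mk(c("o-16s-live-1", "o-16s-dead-1", "o-16s-control_live-1",
                   "o-16s-control_dead-1")))
  metadata <- sample_metadata(
    sample_id = c(colnames(tables[[1]]$counts), colnames(tables[[2]]$counts)),
    method = rep(c("shotgun", "s16"), each = 4),
    platform = rep(c("illumina", "ont"), each = 4),
    condition = rep(c("live", "dead", "control_live", "control_dead"), 2),
    replicate = 1L, qpcr_total = 1e6)
  list(tables = tables, metadata = metadata)
}

test_that("evaluate_study propagates identity to perfect metrics", {
  st <- make_identity_study()
  res <- evaluate_study(st$tables, st$metadata, mock_community_spec())
  expect_identical(nrow(res$per_sample), 4L) # 2 spiked samples x 2 tables
  expect_true(all(res$per_sample$accuracy == 1))
  expect_true(all(res$per_sample$f_score == 1))
  agg <- res$per_method[res$per_method$subset == "all", ]
  expect_true(all(agg$f_score_median == 1))
  expect_true(all(agg$accuracy_mad == 0))
})

test_that("single-sample aggregates are the sample itself with zero spread", {
  st <- make_identity_study()
  keep <- st$metadata$condition != "dead"
  res <- evaluate_study(st$tables, st$metadata[keep, ], mock_community_spec())
  live <- res$per_method[res$per_method$subset == "live", ]
  expect_equal(live$accuracy_median, res$per_sample$accuracy[match(
    paste(live$method, live$platform),
    paste(res$per_sample$method, res$per_sample$platform))])
  expect_true(all(live$accuracy_mad == 0))
  expect_true(all(live$accuracy_sd == 0))
})

test_that("missing controls are reported by name", {
  st <- make_identity_study()
  keep <- st$metadata$sample_id != "i-shotgun-control_dead-1"
  expect_error(
    evaluate_study(st$tables, st$metadata[keep, ], mock_community_spec()),
    "control_dead control for method 'shotgun' on platform 'illumina'")
})

test_that("theoretical reference scores against intended proportions", {
  st <- make_identity_study()
  res <- evaluate_study(st$tables, st$metadata, mock_community_spec(),
                        reference = "theoretical")
  # observed mock mass 0.95 vs theoretical 1.0: sensitivity below 1
  expect_true(all(res$per_sample$sensitivity < 1))
  expect_true(all(res$per_sample$precision == 1))
})

test_that("schemes disagree exactly when background taxa are present", {
  toy <- toy_profiles()
  ed <- performance_metrics(confusion_mass(toy$observed, toy$expected,
                                           toy$mock, "excess-deficit"))
  sm <- performance_metrics(confusion_mass(toy$observed, toy$expected,
                                           toy$mock, "split-mass"))
  expect_false(isTRUE(all.equal(ed$accuracy, sm$accuracy)))
  expect_false(isTRUE(all.equal(ed$precision, sm$precision)))
})

test_that("expect_absent scores dead spikes against the unspiked control", {
  cfg <- small_study_config(seed = 41L)
  study <- generate_study(cfg)
  res <- evaluate_study(study$tables, study$metadata, cfg$community,
                        expect_absent = TRUE)
  dead <- res$per_sample[res$per_sample$condition == "dead", ]
  # every method detects dead mock mass it should not -> large FP, tiny TP
  expect_true(all(dead$FP > 0.9))
  expect_true(all(dead$precision < 0.01))
  live <- res$per_sample[res$per_sample$condition == "live", ]
  expect_true(all(live$accuracy > 0.5)) # live scoring unchanged
})
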