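# Deterministic feature profiles: each category gets a distinct amplitude
# on its own marker; PN300 sign encodes modality.
profile_amp <- function(subject, category, marker) {
  cats <- stimulus_categories()
  if (marker == "PN300") {
    return(if (category %in% cats$visual) -4 else 4)
  }
  idx <- match(category, cats$all)
  mk <- match(marker, marker_registry()$marker)
  if ((idx + mk) %% 3 == 0) 5 else if ((idx * mk) %% 4 == 1) -3 else 0.5
}

test_that("the decoder is exact on separable noiseless cohorts", {
  ft <- make_feature_table(4, profile_amp)
  model <- fit_centroid_classifier(ft)
  expect_s3_class(model, "erp_classifier")
  preds <- predict(model, ft)
  expect_true(all(preds$predicted == preds$category))
  ev <- evaluate_loso(ft)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$modality_accuracy, 1)
  expect_equal(sum(ev$confusion), 40)
  expect_true(all(diag(ev$confusion) == 4))
})

test_that("the PN300 gate routes predictions by modality", {
  ft <- make_feature_table(4, profile_amp)
  model <- fit_centroid_classifier(ft)
  probe <- ft[ft$subject == "S01", ]
  # flip the PN300 sign of a visual evoked: prediction must go auditory
  probe$amplitude_uv[probe$marker == "PN300" &
                       probe$category == "body"] <- 3
  pred <- predict(model, probe)
  expect_equal(pred$modality_predicted[pred$category == "body"], "auditory")
  expect_true(pred$predicted[pred$category == "body"] %in%
                stimulus_categories()$auditory)
})

test_that("fitting is order-invariant and leakage-free", {
  ft <- make_feature_table(5, function(s, c, m) {
    profile_amp(s, c, m) + 0.1 * match(s, sprintf("S%02d", 1:5))
  })
  m1 <- fit_centroid_classifier(ft)
  perm <- ft[order(rev(seq_len(nrow(ft)))), ]
  m2 <- fit_centroid_classifier(perm)
  expect_equal(m1$centroids_visual, m2$centroids_visual)
  expect_equal(m1$center, m2$center)
  # standardization uses training statistics only
  wide <- erpmarkers:::.feature_matrix(ft)
  X <- as.matrix(wide[, m1$features])
  expect_equal(m1$center, colMeans(X))
  expect_equal(m1$scale, apply(X, 2, sd))
  # predicting extreme test data does not alter the model
  probe <- ft[ft$subject == "S01", ]
  probe$amplitude_uv <- probe$amplitude_uv * 100
  invisible(predict(m1, probe))
  expect_equal(m1, fit_centroid_classifier(ft))
})

test_that("exact centroid ties resolve lexicographically and are flagged", {
  # two visual categories with identical profiles -> identical centroids
  amp <- function(s, c, m) {
    cc <- if (c == "object") "checkerboard" else c
    profile_amp(s, cc, m)
  }
  ft <- make_feature_table(3, amp)
  model <- fit_centroid_classifier(ft)
  expect_equal(model$centroids_visual["checkerboard", ],
               model$centroids_visual["object", ])
  pred <- predict(model, ft[ft$subject == "S01", ])
  hit <- pred[pred$category == "checkerboard", ]
  expect_true(hit$tie)
  expect_equal(hit$predicted, "checkerboard")  # first in sorted order
})

test_that("uninformative features decode at the 10% chance level", {
  set.seed(12)
  ft <- make_feature_table(20, function(s, c, m) rnorm(1))
  ev <- evaluate_loso(ft)
  # binomial 99% CI around 0.1 with n = 200
  expect_gt(ev$accuracy, 0.1 - 2.58 * sqrt(0.1 * 0.9 / 200))
  expect_lt(ev$accuracy, 0.1 + 2.58 * sqrt(0.1 * 0.9 / 200))
})

test_that("decoder errors are explicit", {
  ft <- make_feature_table(4, profile_amp)
  expect_error(fit_centroid_classifier(ft[ft$subject == "S01", ]),
               "2 training subjects")
  expect_error(fit_centroid_classifier(ft[ft$category != "music", ]),
               "missing categories")
  model <- fit_centroid_classifier(ft)
  expect_error(predict(model, ft[ft$marker != "PN300", ]), "incomplete|lacks")
  expect_error(evaluate_loso(ft[ft$subject %in% c("S01", "S02"), ]),
               "3 subjects")
})

test_that("accuracy degrades monotonically with noise (with MC slack)", {
  accs <- vapply(c(2, 6, 14), function(ns) {
    cfg <- sim_config(n_subjects = 5, trials_per_category = 6,
                      noise_sd = ns, seed = 123)
    # rejection disabled: this property is about noise, and at 6
    # trials/category mass rejection could empty a cell
    co <- simulate_cohort(cfg, threshold_uv = 1e6)
    evaluate_loso(co$features_full)$accuracy
  }, numeric(1))
  expect_gte(accs[1], accs[2] - 0.08)
  expect_gte(accs[2], accs[3] - 0.08)
  expect_gte(accs[1], accs[3] - 0.08)
})

test_that("modality-level accuracy is never below 10-class accuracy", {
  co <- cached_cohort(1)
  ev <- evaluate_loso(co$features_full)
  expect_gte(ev$modality_accuracy, ev$accuracy)
  # confusion rows sum to the per-class trial counts
  expect_true(all(rowSums(ev$confusion) == 20))
})
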