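# Marker-based category decoder: a two-stage, parameter-free rule.
# Stage 1 gates sensory modality on the sign of the pooled PN300 amplitude
# (negative -> visual, non-negative -> auditory); stage 2 picks the nearest
# category centroid (Euclidean distance in z-scored marker-feature space)
# within the gated modality. Operates on per-subject averaged evoked
# features, not single trials.

# wide matrix of pooled marker amplitudes: rows subject x category
.feature_matrix <- function(features) {
  pooled <- features[features$electrode == "pooled", ]
  wide <- tidyr::pivot_wider(pooled[, c("subject", "category", "marker",
                                        "amplitude_uv")],
                             names_from = "marker",
                             values_from = "amplitude_uv")
  if (anyNA(wide)) {
    abort(paste0("incomplete feature set: the classifier needs every marker ",
                 "measured on every category (use extract_feature_table(..., ",
                 "restrict = FALSE))"))
  }
  wide
}

#' Fit the two-stage nearest-centroid category decoder
#'
#' @param features unrestricted feature table ([extract_feature_table()] with
#'   `restrict = FALSE`): every marker measured on every subject x category
#'   evoked.
#' @return An `erp_classifier`: feature list, training standardization
#'   parameters (training statistics only - no test leakage), per-category
#'   centroids split by modality, and the PN300 gate column.
#' @export
fit_centroid_classifier <- function(features) {
  wide <- .feature_matrix(features)
  if (length(unique(wide$subject)) < 2) abort("need >= 2 training subjects")
  cats <- stimulus_categories()
  missing <- setdiff(cats$all, unique(wide$category))
  if (length(missing) > 0) {
    abort(paste0("training data missing categories: ",
                 paste(missing, collapse = ", ")))
  }
  feat_cols <- sort(setdiff(names(wide), c("subject", "category")))
  X <- as.matrix(wide[, feat_cols])
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale, `/`)
  centroid <- function(cat_set) {
    t(vapply(cat_set, function(cc) {
      colMeans(Z[wide$category == cc, , drop = FALSE])
    }, numeric(ncol(Z))))
  }
  structure(
    list(features = feat_cols, center = center, scale = scale,
         centroids_visual = centroid(sort(cats$visual)),
         centroids_auditory = centroid(sort(cats$auditory)),
         gate_feature = "PN300"),
    class = "erp_classifier"
  )
}

#' @export
print.erp_classifier <- function(x, ...) {
  cat("<erp_classifier> two-stage nearest-centroid decoder, ",
      length(x$features), " marker features, PN300 modality gate\n", sep = "")
  invisible(x)
}

#' Predict stimulus categories from marker features
#'
#' Stage 1: pooled PN300 amplitude < 0 routes to the visual branch, >= 0 to
#' the auditory branch. Stage 2: nearest centroid within the branch; exact
#' ties resolve to the lexicographically first category (flagged in `tie`).
#'
#' @param object an `erp_classifier`.
#' @param features unrestricted feature table of the evokeds to classify.
#' @param ... unused.
#' @return tibble: `subject`, `category` (true label), `predicted`,
#'   `modality_predicted`, `distance`, `tie`.
#' @export
predict.erp_classifier <- function(object, features, ...) {
  wide <- .feature_matrix(features)
  miss <- setdiff(object$features, names(wide))
  if (length(miss) > 0) {
    abort(paste0("feature table lacks marker(s): ", paste(miss, collapse = ", ")))
  }
  X <- as.matrix(wide[, object$features])
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  gate <- X[, object$gate_feature]
  out <- lapply(seq_len(nrow(Z)), function(i) {
    branch <- if (gate[i] < 0) object$centroids_visual else
      object$centroids_auditory
    dd <- sqrt(rowSums(sweep(branch, 2, Z[i, ])^2))
    best <- which(dd == min(dd))
    tibble::tibble(
      predicted = rownames(branch)[best[1]],
      modality_predicted = if (gate[i] < 0) "visual" else "auditory",
      distance = dd[best[1]],
      tie = length(best) > 1
    )
  })
  dplyr::bind_cols(wide[, c("subject", "category")], dplyr::bind_rows(out))
}

#' Leave-one-subject-out evaluation of the marker decoder
#'
#' For each subject: fit the decoder on all other subjects' per-category
#' evoked features and classify the held-out subject's ten evokeds.
#' Aggregates a 10 x 10 confusion matrix, overall accuracy, per-class
#' recall, and the coarser visual-vs-auditory (modality) accuracy.
#'
#' @param features unrestricted feature table of the full cohort (>= 3
#'   subjects).
#' @return An `erp_evaluation`: `confusion` (true x predicted counts),
#'   `accuracy`, `modality_accuracy`, `per_class` tibble, `predictions`.
#' @export
evaluate_loso <- function(features) {
  subjects <- unique(features$subject)
  if (length(subjects) < 3) abort("leave-one-subject-out needs >= 3 subjects")
  preds <- lapply(subjects, function(s) {
    model <- fit_centroid_classifier(features[features$subject != s, ])
    predict(model, features[features$subject == s, ])
  })
  preds <- dplyr::bind_rows(preds)
  cats <- sort(stimulus_categories()$all)
  confusion <- table(factor(preds$category, levels = cats),
                     factor(preds$predicted, levels = cats))
  acc <- mean(preds$category == preds$predicted)
  modality_of <- function(x) {
    ifelse(x %in% stimulus_categories()$visual, "visual", "auditory")
  }
  mod_acc <- mean(modality_of(preds$category) == preds$modality_predicted)
  per_class <- tibble::tibble(
    category = cats,
    n = as.integer(rowSums(confusion)),
    recall = diag(confusion) / pmax(1, rowSums(confusion))
  )
  structure(
    list(confusion = confusion, accuracy = acc,
         modality_accuracy = mod_acc, per_class = per_class,
         predictions = preds),
    class = "erp_evaluation"
  )
}

#' @export
print.erp_evaluation <- function(x, ...) {
  cat("<erp_evaluation> leave-one-subject-out: accuracy ",
      sprintf("%.1f%%", 100 * x$accuracy), " (modality ",
      sprintf("%.1f%%", 100 * x$modality_accuracy), ") over ",
      sum(x$confusion), " evoked responses\n", sep = "")
  invisible(x)
}

#' @export
glance.erp_evaluation <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 modality_accuracy = x$modality_accuracy,
                 n = sum(x$confusion))
}

#' Write a confusion matrix as CSV
#' @param evaluation an `erp_evaluation`.
#' @param path file path.
#' @export
write_confusion_csv <- function(evaluation, path) {
  m <- as.data.frame.matrix(evaluation$confusion)
  utils::write.csv(cbind(true_category = rownames(m), m), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
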