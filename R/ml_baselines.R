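# Feature-score machine-learning baselines. A trained network scores four
# single-lesion planes per patient (tumor + three largest node groups,
# blank-plane padding when fewer exist); the resulting 4-vector — and never
# the raw plane — is the input to SVM / logistic regression / KNN. The
# information bottleneck is the point of the comparison.

#' Score one lesion plane with a trained network
#'
#' The score is the class-1 probability of the extractor on a centered
#' single-ROI plane (see [singleRoiPlane()]); inference is deterministic, so
#' identical planes receive identical scores and the blank plane has one
#' constant score shared by all patients.
#'
#' @param model a trained [resnetCbam()] model.
#' @param plane a [PlaneImage-class].
#' @return numeric score in [0, 1].
#' @export
roiScore <- function(model, plane) {
  unname(predictProb(model, list(plane))[1, 2])
}

#' Build 4-entry feature vectors for a cohort
#'
#' Entries are (tumor, node group 1, node group 2, node group 3) scores with
#' groups in descending-size order; patients with fewer than three groups are
#' padded with the blank-plane score.
#'
#' @param patients list; each element a list with `volume` ([CTVolume-class]),
#'   `mask` (windowed [ROIMask-class]) and `groups` (sorted
#'   [LymphGroup-class] list).
#' @param model trained extractor network.
#' @param tileSide lesion tile side for the score planes.
#' @return matrix n x 4 (columns tumor, g1, g2, g3).
#' @export
buildFeatureVectors <- function(patients, model, tileSide = 112L) {
  blank <- singleRoiPlane(NULL, 1L, NULL)
  blank_score <- roiScore(model, blank)
  out <- matrix(NA_real_, length(patients), 4,
                dimnames = list(NULL, c("tumor", "g1", "g2", "g3")))
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    s0 <- selectDatumPlane(p$mask)
    tpx <- which(maskLabels(p$mask)[s0, , , drop = TRUE] == 1L, arr.ind = TRUE)
    out[i, 1] <- roiScore(model, singleRoiPlane(p$volume, s0, tpx,
                                                tileSide = tileSide))
    gs <- head(p$groups, 3L)
    for (k in seq_len(3)) {
      out[i, k + 1] <- if (k <= length(gs))
        roiScore(model, singleRoiPlane(p$volume, maxSlice(gs[[k]]),
                                       maxRoiPixels(gs[[k]]),
                                       tileSide = tileSide))
      else blank_score
    }
  }
  out
}

#' Fit and evaluate a feature-vector baseline
#'
#' @param kind "svm" (radial kernel), "lr" (binomial GLM) or "knn" (k = 5).
#' @param train,test numeric feature matrices (rows = patients).
#' @param trainLabels,testLabels integer vectors in {0, 1}.
#' @param k neighbours for KNN.
#' @return list with `metrics` ([confusionMetrics()]), `roc` ([rocAuc()]),
#'   `pred` and `scores` on the test set.
#' @export
fitBaseline <- function(kind = c("svm", "lr", "knn"), train, trainLabels,
                        test, testLabels, k = 5L) {
  kind <- match.arg(kind)
  if (length(unique(trainLabels)) < 2L)
    stop("both classes must be present in the training labels")
  if (length(unique(testLabels)) < 2L)
    stop("degenerate single-class test set")
  train <- as.matrix(train); test <- as.matrix(test)
  if (kind == "svm") {
    fit <- e1071::svm(train, factor(trainLabels, levels = 0:1),
                      kernel = "radial", probability = TRUE)
    pr <- predict(fit, test, probability = TRUE)
    scores <- attr(pr, "probabilities")[, "1"]
  } else if (kind == "lr") {
    df_tr <- data.frame(y = trainLabels, train)
    fit <- glm(y ~ ., data = df_tr, family = binomial())
    scores <- predict(fit, data.frame(test), type = "response")
  } else {
    pr <- class::knn(train, test, factor(trainLabels, levels = 0:1),
                     k = k, prob = TRUE)
    pwin <- attr(pr, "prob")
    scores <- ifelse(pr == "1", pwin, 1 - pwin)
  }
  pred <- as.integer(scores > 0.5)
  list(metrics = confusionMetrics(pred, testLabels),
       roc = rocAuc(scores, testLabels),
       pred = pred, scores = unname(scores))
}
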