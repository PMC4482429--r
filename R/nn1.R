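#' Distance between two simulation sequences
#'
#' Treats each simulation as a multivariate time series: the Euclidean
#' distance between the two feature vectors is computed at each tick of
#' the prefix, and the Euclidean norm of those per-tick distances is the
#' distance between the simulations. With a single feature this collapses
#' to the plain Euclidean distance between the two univariate series.
#' Optional per-feature scale constants (see [nn1_train()]) equalise the
#' contributions of features with different ranges.
#'
#' @param a,b trajectories (data frames containing the feature columns).
#' @param features character vector of feature columns to use.
#' @param prefix_len number of leading ticks to compare.
#' @param scale named per-feature divisors (default 1 for each feature).
#' @return a non-negative number, zero iff the prefixes are identical on
#'   the chosen features.
#' @export
sequence_distance <- function(a, b, features = feature_names(),
                              prefix_len = min(nrow(a), nrow(b)),
                              scale = NULL) {
  miss <- setdiff(features, intersect(colnames(a), colnames(b)))
  if (length(miss))
    stop("feature(s) absent from both sequences: ",
         paste(miss, collapse = ", "))
  if (nrow(a) < prefix_len || nrow(b) < prefix_len)
    stop("sequences shorter than the requested prefix")
  ma <- as.matrix(a[seq_len(prefix_len), features, drop = FALSE])
  mb <- as.matrix(b[seq_len(prefix_len), features, drop = FALSE])
  if (!is.null(scale)) {
    s <- scale[features]
    s[!is.finite(s) | s == 0] <- 1
    ma <- sweep(ma, 2, s, "/")
    mb <- sweep(mb, 2, s, "/")
  }
  sqrt(sum((ma - mb)^2))
}

#' Train a 1-nearest-neighbour trajectory classifier
#'
#' Stores the labelled training prefixes and the per-feature
#' normalisation constants (each feature's maximum absolute value over the
#' training prefixes, so all features fall into similar ranges before
#' distances are taken). Labels must come from outcome models or
#' ulceration events, never set by hand.
#'
#' @param trajectories list of training trajectories.
#' @param labels vector of class labels, one per trajectory.
#' @param features feature columns used by the classifier.
#' @param prefix_len ticks of history available to the classifier.
#' @return an `nn1_classifier`.
#' @export
nn1_train <- function(trajectories, labels, features, prefix_len) {
  stopifnot(length(trajectories) >= 1,
            length(labels) == length(trajectories))
  prefixes <- lapply(trajectories, function(tr) {
    if (nrow(tr) < prefix_len) stop("training sequence shorter than prefix")
    as.matrix(tr[seq_len(prefix_len), features, drop = FALSE])
  })
  scale <- apply(do.call(rbind, prefixes), 2, function(v) max(abs(v)))
  scale[!is.finite(scale) | scale == 0] <- 1
  scaled <- lapply(prefixes, function(m) sweep(m, 2, scale, "/"))
  structure(list(prefixes = scaled, labels = labels, features = features,
                 prefix_len = prefix_len, scale = scale),
            class = "nn1_classifier")
}

#' Classify a trajectory by its nearest labelled neighbour
#'
#' Assigns the label of the training sequence at minimum sequence distance
#' over the classifier's prefix; exact distance ties are broken by the
#' lowest training index.
#'
#' @param classifier an [nn1_train()] result.
#' @param trajectory the unlabelled test trajectory.
#' @return the predicted label.
#' @export
nn1_classify <- function(classifier, trajectory) {
  stopifnot(inherits(classifier, "nn1_classifier"))
  m <- as.matrix(trajectory[seq_len(classifier$prefix_len),
                            classifier$features, drop = FALSE])
  m <- sweep(m, 2, classifier$scale, "/")
  d <- vapply(classifier$prefixes,
              function(p) sqrt(sum((p - m)^2)), numeric(1))
  classifier$labels[which.min(d)]
}

#' Misclassification over feature sets and prefix lengths
#'
#' For every combination of feature subset and prefix length, trains a
#' 1NN classifier on the training set and reports the misclassification
#' fraction on the (disjoint) test set.
#'
#' @param train_traj,test_traj lists of trajectories.
#' @param train_labels,test_labels their class labels.
#' @param feature_sets named list of feature-name vectors.
#' @param prefix_lens integer vector of prefix lengths.
#' @return data frame with columns `feature_set`, `n_features`,
#'   `prefix_len`, `error`.
#' @export
error_curve <- function(train_traj, train_labels, test_traj, test_labels,
                        feature_sets, prefix_lens) {
  stopifnot(length(test_traj) == length(test_labels))
  if (is.null(names(feature_sets)))
    names(feature_sets) <- vapply(feature_sets, paste, "", collapse = "+")
  out <- list()
  for (fs in names(feature_sets)) {
    for (pl in prefix_lens) {
      cls <- nn1_train(train_traj, train_labels, feature_sets[[fs]], pl)
      pred <- vapply(test_traj, function(tr)
        as.character(nn1_classify(cls, tr)), character(1))
      err <- mean(pred != as.character(test_labels))
      out[[length(out) + 1]] <- data.frame(
        feature_set = fs, n_features = length(feature_sets[[fs]]),
        prefix_len = pl, error = err, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
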