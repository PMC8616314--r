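# Level-2 fusion: the screened top models act like the specialists of a
# multi-disciplinary team; each contributes its class-1 probability and the
# consensus is the accuracy-weighted linear sum of those probabilities.

#' Accuracy-proportional consensus weights
#'
#' `w_i = acc_i / sum_k acc_k`, with the accuracies averaged over the
#' cross-validation folds.
#'
#' @param accuracies Numeric vector of mean CV accuracies in `[0, 1]`.
#' @return Weights summing to 1.
#' @export
#' @examples
#' compute_weights(c(0.9, 0.8, 0.7))  # 0.375, 1/3, 7/24
compute_weights <- function(accuracies) {
  if (length(accuracies) == 0) rf_stop("no accuracies supplied")
  if (any(accuracies < 0)) rf_stop("negative accuracy")
  if (sum(accuracies) == 0) rf_stop("all accuracies are zero; weights undefined")
  accuracies / sum(accuracies)
}

#' Build an accuracy-weighted consensus model
#'
#' @param members List of `trained_model` objects (the screened top models).
#' @param accuracies Mean CV accuracies, one per member; defaults to the
#'   `acc_i` carried by each member's attached `cv_report`.
#' @param threshold Decision threshold on the consensus score (default 0.5;
#'   class 1 on `>=`).
#' @return An object of class `consensus_model`.
#' @export
build_consensus <- function(members, accuracies = NULL, threshold = 0.5) {
  stopifnot(is.list(members), length(members) >= 1)
  if (!all(vapply(members, inherits, logical(1), "trained_model"))) {
    rf_stop("members must be trained_model objects")
  }
  if (is.null(accuracies)) {
    accuracies <- vapply(members, function(m) {
      if (is.null(m$cv_report)) rf_stop("member without cv_report; pass accuracies")
      m$cv_report$acc_i
    }, numeric(1))
  }
  stopifnot(length(accuracies) == length(members))
  structure(
    list(members = members, weights = compute_weights(accuracies),
         accuracies = accuracies, threshold = threshold),
    class = "consensus_model"
  )
}

#' @export
print.consensus_model <- function(x, ...) {
  ids <- vapply(x$members, function(m) spec_id(m$spec), character(1))
  cat(sprintf("<consensus_model> %d members: %s; weights %s\n",
              length(ids), paste(ids, collapse = ", "),
              paste(sprintf("%.3f", x$weights), collapse = ", ")))
  invisible(x)
}

#' Weighted consensus score from member probabilities
#'
#' The low-level soft vote: `score = sum_i w_i c_i(x)` where `c_i` is
#' member i's class-1 probability. The consensus is convex, so it always
#' lies between the smallest and largest member score.
#'
#' @param member_scores Numeric matrix, samples x members, entries in
#'   `[0, 1]`.
#' @param weights Member weights summing to 1.
#' @return Numeric vector of consensus scores.
#' @export
consensus_score <- function(member_scores, weights) {
  member_scores <- as.matrix(member_scores)
  stopifnot(ncol(member_scores) == length(weights))
  if (abs(sum(weights) - 1) > 1e-8) rf_stop("weights must sum to 1")
  drop(member_scores %*% weights)
}

#' Predict with a consensus model
#'
#' Scores every member on the sample(s), combines by the weighted linear
#' sum, and thresholds (class 1 on `score >= threshold`). A failing member
#' is reported by name.
#'
#' @param model A `consensus_model`.
#' @param table A `feature_table` (or matrix with named columns).
#' @return A data frame with `sample_id`, per-member scores, `score`,
#'   `class`.
#' @export
weighted_consensus_predict <- function(model, table) {
  stopifnot(inherits(model, "consensus_model"))
  scores <- vapply(model$members, function(m) {
    tryCatch(predict_model(m, table), error = function(e) {
      rf_stop(sprintf("member '%s' failed to score: %s",
                      spec_id(m$spec), conditionMessage(e)))
    })
  }, numeric(if (inherits(table, "feature_table")) length(table$sample_ids)
             else nrow(table)))
  scores <- matrix(scores, ncol = length(model$members))
  colnames(scores) <- vapply(model$members, function(m) spec_id(m$spec), character(1))
  sc <- consensus_score(scores, model$weights)
  data.frame(
    sample_id = if (inherits(table, "feature_table")) table$sample_ids
    else rownames(table) %||% seq_len(nrow(scores)),
    scores,
    score = sc,
    class = as.integer(sc >= model$threshold),
    check.names = FALSE
  )
}

#' @export
predict.consensus_model <- function(object, newdata, ...) {
  weighted_consensus_predict(object, newdata)
}

#' Majority (plurality) vote over member class decisions
#'
#' Each member votes its thresholded class; the class with the most votes
#' wins. Ties are broken toward the positive class with a warning, so an
#' odd number of members is recommended.
#'
#' @param votes Integer matrix, samples x members, entries in `{0, 1}`;
#'   or a list of `trained_model` plus `table` to score first.
#' @param table Optional `feature_table` when `votes` is a member list.
#' @param threshold Threshold applied to member probabilities (default 0.5).
#' @return Integer vector of voted classes.
#' @export
majority_vote_predict <- function(votes, table = NULL, threshold = 0.5) {
  if (is.list(votes) && !is.matrix(votes) && !is.data.frame(votes)) {
    if (length(votes) == 0) rf_stop("no members to vote")
    stopifnot(!is.null(table))
    n <- if (inherits(table, "feature_table")) length(table$sample_ids) else nrow(table)
    member_votes <- lapply(votes, function(m) {
      as.integer(predict_model(m, table) >= threshold)
    })
    votes <- matrix(unlist(member_votes), nrow = n)
  }
  votes <- as.matrix(votes)
  if (ncol(votes) == 0) rf_stop("no members to vote")
  pos <- rowSums(votes == 1)
  neg <- ncol(votes) - pos
  if (any(pos == neg)) {
    warning("tie(s) in majority vote broken toward the positive class",
            call. = FALSE)
  }
  as.integer(pos >= neg)
}
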