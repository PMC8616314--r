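#' Fit the full two-level pipeline on a training bundle
#'
#' Convenience wrapper chaining the stages: fuse the training bundle
#' (fitting the cross-modality whitening transform), cross-validate the
#' model grid on the fused features, rank, screen the top-k models, refit
#' them on the full training cohort, and build the accuracy-weighted
#' consensus.
#'
#' @param bundle Training [modality_bundle()] (>= 2 modalities).
#' @param labels Binary labels (default: the bundle's).
#' @param specs Model grid (default: the full fifteen-model grid).
#' @param top_k Number of models merged into the consensus (default 3).
#' @param folds CV folds (default 5).
#' @param seed Seed.
#' @param tol Fusion eigenvalue tolerance.
#' @return A list of class `fusion_pipeline`: `transform`, `fused`,
#'   `reports` (ranked), `consensus`.
#' @export
fit_pipeline <- function(bundle, labels = NULL, specs = build_model_zoo(),
                         top_k = 3, folds = 5, seed = 1, tol = 1e-10) {
  labels <- labels %||% bundle_labels(bundle)
  fit <- fit_feature_fusion(bundle, labels = labels, tol = tol)
  reports <- run_model_zoo(specs, fit$fused, labels, folds = folds, seed = seed)
  ranked <- rank_models(reports)
  members <- select_top_k(ranked, k = top_k, table = fit$fused,
                          labels = labels, seed = seed)
  consensus <- build_consensus(members)
  structure(
    list(transform = fit$transform, fused = fit$fused, reports = ranked,
         consensus = consensus, seed = seed),
    class = "fusion_pipeline"
  )
}

#' Score held-out data with a fitted pipeline
#'
#' Applies the stored fusion transform (training statistics, no refitting)
#' and the consensus model.
#'
#' @param pipeline A `fusion_pipeline` from [fit_pipeline()].
#' @param bundle Held-out [modality_bundle()] with matching modalities.
#' @return The consensus prediction data frame (see
#'   [weighted_consensus_predict()]).
#' @export
predict_pipeline <- function(pipeline, bundle) {
  stopifnot(inherits(pipeline, "fusion_pipeline"))
  fused <- apply_feature_fusion(pipeline$transform, bundle)
  weighted_consensus_predict(pipeline$consensus, fused)
}

#' @export
print.fusion_pipeline <- function(x, ...) {
  cat("<fusion_pipeline>\n")
  print(x$transform)
  print(x$consensus)
  invisible(x)
}
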