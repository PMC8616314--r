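# Classifier registry. Every classifier exposes fit(x, y, hyper, seed) and
# a class-1 probability in [0, 1] via predict_prob(model, x); margin-only
# outputs are calibrated internally by the backing implementations.

.classifier_registry <- list(
  logistic = list(
    fit = function(x, y, hyper, seed) {
      df <- as.data.frame(x)
      df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    predict_prob = function(model, x) {
      p <- suppressWarnings(
        stats::predict(model, newdata = as.data.frame(x), type = "response")
      )
      pmin(pmax(as.numeric(p), 0), 1)
    }
  ),
  svm_rbf = list(
    fit = function(x, y, hyper, seed) {
      set.seed(seed)
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                 probability = TRUE,
                 cost = hyper$cost %||% 1,
                 gamma = hyper$gamma %||% (1 / ncol(x)),
                 scale = FALSE)
    },
    predict_prob = function(model, x) {
      pr <- stats::predict(model, x, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    }
  ),
  random_forest = list(
    fit = function(x, y, hyper, seed) {
      ranger::ranger(
        x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
        probability = TRUE,
        num.trees = hyper$num_trees %||% 300,
        seed = seed,
        num.threads = 1
      )
    },
    predict_prob = function(model, x) {
      as.numeric(stats::predict(model, data = as.data.frame(x),
                                num.threads = 1)$predictions[, "1"])
    }
  )
)

#' @rdname registered_selectors
#' @export
registered_classifiers <- function() names(.classifier_registry)

get_classifier <- function(classifier_id) {
  clf <- .classifier_registry[[classifier_id]]
  if (is.null(clf)) {
    rf_stop(sprintf("unknown classifier '%s'; registered: %s", classifier_id,
                    paste(registered_classifiers(), collapse = ", ")))
  }
  clf
}
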