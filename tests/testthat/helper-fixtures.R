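# Small programmatic fixtures shared across tests.

make_table <- function(values, modality = "A", labels = NULL,
                       sample_ids = NULL, feature_names = NULL) {
  values <- as.matrix(values)
  sample_ids <- sample_ids %||% sprintf("s%02d", seq_len(nrow(values)))
  feature_names <- feature_names %||% sprintf("f%02d", seq_len(ncol(values)))
  feature_table(values, sample_ids, feature_names, modality, labels = labels)
}

`%||%` <- radfusion:::`%||%`

# two-modality bundle around the worked single-feature example:
# modality A = (1, 1, 3, 3), modality B = (0, 2, 2, 4), labels (0, 0, 1, 1)
worked_example_bundle <- function() {
  labels <- c(0, 0, 1, 1)
  modality_bundle(list(
    make_table(matrix(c(1, 1, 3, 3), 4, 1), "A", labels),
    make_table(matrix(c(0, 2, 2, 4), 4, 1), "B", labels)
  ))
}

# random PSD between-class-style fixture for whitening property tests
random_scatter_fixture <- function(p, n = 24) {
  labels <- rep(c(0, 1), length.out = n)
  x <- matrix(rnorm(p * n), p, n) + outer(runif(p, -2, 2), labels)
  between_class_scatter(x, labels)
}

# closed-form rank-1 oracle for the two-class scatter: S = c * d d' with
# d = xbar1 - xbar(grand), c = n1 + n1^2/n2; eigenpair (lambda, q) in
# closed form, no eigensolver involved
oracle_fused_row <- function(x, labels) {
  g1 <- labels == 1
  n1 <- sum(g1)
  n0 <- sum(!g1)
  d <- rowMeans(x[, g1, drop = FALSE]) - rowMeans(x)
  lambda <- (n1 + n1^2 / n0) * sum(d^2)
  q <- d / sqrt(sum(d^2))
  drop(crossprod(q, x)) / sqrt(lambda)
}

# align a fused row with its oracle up to the documented sign convention
align_sign <- function(a, b) if (sum(a * b) < 0) -a else a

tiny_zoo <- function(selector = "anova", classifier = "logistic", k = 3) {
  build_model_zoo(list(selectors = selector, classifiers = classifier,
                       selector_k = k))
}
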