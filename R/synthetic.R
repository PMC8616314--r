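# Synthetic two-class multi-modality feature generator. The generative
# model is Gaussian with unit within-class variance: for sample i with
# class y_i, feature j, modality k,
#   value = delta[k, j] * y_i + eps,  eps ~ N(0, Sigma_rho) across modalities,
# where Sigma_rho is the p x p equicorrelation matrix. A single feature
# with effect delta then has closed-form discrimination AUC = Phi(delta /
# sqrt(2)), which the calibration tests lean on.

#' Configuration for the multi-modality feature simulator
#'
#' @param n_per_class Samples per class.
#' @param p Number of modalities (1-4).
#' @param m Number of features per modality.
#' @param delta Effect size in within-class SD units: a scalar (applied to
#'   every informative (modality, feature) entry), a length-p vector (per
#'   modality), or a full p x m matrix.
#' @param rho Cross-modality noise correlation (equicorrelation); must keep
#'   the noise covariance positive semi-definite (`rho > -1/(p-1)`).
#' @param informative_fraction Fraction of features per modality that carry
#'   the effect (default 1).
#' @param mode `"shared"` (every modality informative on the same feature
#'   subset) or `"disjoint"` (the informative subset is partitioned across
#'   modalities — complementary information at table level).
#' @param modality_ids Optional modality names (default `mod1`, ...).
#' @param feature_names Optional feature names (default `f001`, ...).
#' @param seed Integer seed (mandatory).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_per_class = 60, p = 2, m = 10, delta = 1,
                              rho = 0, informative_fraction = 1,
                              mode = c("shared", "disjoint"),
                              modality_ids = NULL, feature_names = NULL,
                              seed) {
  if (missing(seed)) rf_stop("seed is mandatory")
  mode <- match.arg(mode)
  stopifnot(n_per_class >= 1, p >= 1, p <= 4, m >= 1,
            informative_fraction >= 0, informative_fraction <= 1)
  if (!all(is.finite(delta))) rf_stop("effect sizes must be finite")
  if (p > 1 && (rho <= -1 / (p - 1) || rho > 1)) {
    rf_stop(sprintf("rho = %g gives a non-positive-semidefinite noise covariance for p = %d",
                    rho, p))
  }
  modality_ids <- modality_ids %||% paste0("mod", seq_len(p))
  feature_names <- feature_names %||% sprintf("f%03d", seq_len(m))
  stopifnot(length(modality_ids) == p, length(feature_names) == m)

  n_info <- round(informative_fraction * m)
  mask <- matrix(0, p, m)
  if (n_info > 0) {
    if (mode == "shared") {
      mask[, seq_len(n_info)] <- 1
    } else {
      # partition the informative block across modalities
      blocks <- split(seq_len(n_info), rep_len(seq_len(p), n_info))
      for (k in seq_len(p)) mask[k, blocks[[k]]] <- 1
    }
  }
  delta_mat <- if (is.matrix(delta)) {
    stopifnot(nrow(delta) == p, ncol(delta) == m)
    delta
  } else if (length(delta) == p) {
    matrix(delta, p, m) * mask
  } else if (length(delta) == 1) {
    matrix(delta, p, m) * mask
  } else {
    rf_stop("delta must be a scalar, a length-p vector, or a p x m matrix")
  }
  structure(
    list(n_per_class = n_per_class, p = p, m = m, delta = delta_mat,
         rho = rho, informative_fraction = informative_fraction, mode = mode,
         modality_ids = modality_ids, feature_names = feature_names,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a two-class multi-modality feature bundle
#'
#' @param config A [simulation_config()].
#' @param sample_prefix Prefix for generated sample ids.
#' @return A list with `bundle` (a [modality_bundle()], labels attached to
#'   every member table) and `labels`. Deterministic under the config seed.
#' @export
#' @examples
#' sim <- simulate_multimodal_features(simulation_config(n_per_class = 20, seed = 1))
#' sim$bundle
simulate_multimodal_features <- function(config, sample_prefix = "s") {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$p
  m <- config$m
  n <- 2 * config$n_per_class
  y <- rep(c(1L, 0L), each = config$n_per_class)
  Sigma <- matrix(config$rho, p, p)
  diag(Sigma) <- 1
  L <- chol(Sigma)
  set.seed(derive_seed(config$seed, "simulate_features"))
  sample_ids <- sprintf("%s%04d", sample_prefix, seq_len(n))
  values <- array(NA_real_, dim = c(n, m, p))
  for (j in seq_len(m)) {
    eps <- matrix(stats::rnorm(n * p), n, p) %*% L
    for (k in seq_len(p)) {
      values[, j, k] <- config$delta[k, j] * y + eps[, k]
    }
  }
  tables <- lapply(seq_len(p), function(k) {
    feature_table(values[, , k, drop = TRUE], sample_ids,
                  config$feature_names, config$modality_ids[k], labels = y)
  })
  list(bundle = modality_bundle(tables), labels = y)
}

#' Default study-shaped synthetic scenario
#'
#' A fixed-seed scenario mirroring the study cohort geometry: a training
#' cohort of 121 samples (61 positive / 60 negative), an independent test
#' cohort of 62 (33 / 29), four modalities named after the conventional MRI
#' sequences, and the full 109-feature registry panel. Two modalities carry
#' the bulk of the signal on disjoint informative feature subsets
#' (complementary at table level: T1WI on one block, T2_FLAIR on another)
#' while CE_T1WI and T2WI are weakly informative; modality noise is mildly
#' correlated.
#'
#' @param seed Integer seed (default fixed so the scenario is reproducible).
#' @param n_train,n_test Cohort sizes; defaults 121 and 62 with 61/60 and
#'   33/29 class patterns.
#' @return A list: `train` (bundle), `test` (bundle), `train_labels`,
#'   `test_labels`, `informative` (named list of informative feature sets).
#' @export
default_study_scenario <- function(seed = 20211118, n_train = 121, n_test = 62) {
  registry <- default_feature_registry()
  feats <- registry_feature_names(registry)
  m <- length(feats)
  mods <- c("T1WI", "CE_T1WI", "T2WI", "T2_FLAIR")
  p <- length(mods)
  # disjoint informative blocks: first-order block for T1WI, texture block
  # for T2_FLAIR; the other two sequences echo those blocks weakly
  block_a <- feats[1:12]
  block_b <- feats[13:24]
  delta <- matrix(0, p, m, dimnames = list(mods, feats))
  delta["T1WI", block_a] <- 1.0
  delta["T2_FLAIR", block_b] <- 1.0
  delta["CE_T1WI", block_a] <- 0.3
  delta["T2WI", block_b] <- 0.3
  rho <- 0.2

  # generate train and test as independent draws from the same model
  make_cohort <- function(n_pos, n_neg, tag, prefix) {
    n_per <- max(n_pos, n_neg)
    cfg <- simulation_config(n_per_class = n_per, p = p, m = m, delta = delta,
                             rho = rho, mode = "disjoint",
                             modality_ids = mods, feature_names = feats,
                             seed = derive_seed(seed, tag))
    sim <- simulate_multimodal_features(cfg, sample_prefix = prefix)
    keep <- c(which(sim$labels == 1)[seq_len(n_pos)],
              which(sim$labels == 0)[seq_len(n_neg)])
    ids <- sim$bundle[[1]]$sample_ids[keep]
    list(bundle = subset_bundle(sim$bundle, sample_ids = ids),
         labels = sim$labels[keep])
  }
  n_train_pos <- ceiling(n_train / 2)          # 61 at the default size
  n_train_neg <- n_train - n_train_pos         # 60
  n_test_pos <- round(n_test * 33 / 62)        # 33
  n_test_neg <- n_test - n_test_pos            # 29
  train <- make_cohort(n_train_pos, n_train_neg, "train_cohort", "tr")
  test <- make_cohort(n_test_pos, n_test_neg, "test_cohort", "te")
  list(
    train = train$bundle, test = test$bundle,
    train_labels = train$labels, test_labels = test$labels,
    informative = list(T1WI = block_a, T2_FLAIR = block_b),
    delta = delta, rho = rho
  )
}

#' Simulate three nested toy VOI masks
#'
#' Builds a core (nET), a surrounding shell (ET), and an outer ring (pTE)
#' as pairwise disjoint binary regions with the core/rim/ring topology of a
#' necrotic enhancing tumor with peritumoral edema. The center is jittered
#' deterministically under the seed.
#'
#' @param shape Length-3 integer grid extents (each >= 8).
#' @param seed Integer seed.
#' @return A named list of three `voxel_mask` objects: `nET`, `ET`, `pTE`.
#' @export
simulate_toy_masks <- function(shape = c(24, 24, 24), seed = 1) {
  stopifnot(length(shape) == 3)
  if (any(shape < 8)) rf_stop("each grid extent must be at least 8")
  set.seed(derive_seed(seed, "toy_masks"))
  center <- shape / 2 + stats::runif(3, -1, 1)
  r_max <- min(shape) / 2 - 1
  r1 <- r_max * 0.35   # core
  r2 <- r_max * 0.6    # enhancing shell
  r3 <- r_max * 0.9    # edema ring
  grid <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                      z = seq_len(shape[3]))
  d <- sqrt((grid$x - center[1])^2 + (grid$y - center[2])^2 +
              (grid$z - center[3])^2)
  as_mask <- function(cond, label) {
    voxel_mask(array(as.integer(cond), dim = shape), label = label)
  }
  list(
    nET = as_mask(d <= r1, "nET"),
    ET = as_mask(d > r1 & d <= r2, "ET"),
    pTE = as_mask(d > r2 & d <= r3, "pTE")
  )
}
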