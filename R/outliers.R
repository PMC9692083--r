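# Unsupervised outlier ensemble behind the Similarity Component: local
# outlier factor (density-based, run on the precomputed dissimilarities),
# one-class SVM (domain-based) and isolation forest (isolation-based), both
# run on the dissimilarity-matrix rows as coordinate vectors. An extract
# flagged by at least one detector gets SC = 1.

#' Local outlier factor from a precomputed dissimilarity matrix
#'
#' Classic LOF: the average ratio between each point's local reachability
#' density and that of its k nearest neighbours. Values near 1 mean the point
#' sits in a neighbourhood of comparable density; values well above 1 mean it
#' is locally isolated. Neighbourhoods include distance ties.
#'
#' @param dist symmetric dissimilarity matrix with zero diagonal.
#' @param k neighbourhood size.
#' @return numeric vector of LOF scores, one per row of `dist`.
#' @export
lof_scores <- function(dist, k) {
  n <- nrow(dist)
  if (k < 1 || k > n - 1) parameter_error("k must be in [1, n - 1]")
  eps <- 1e-10
  kdist <- numeric(n)
  neighbors <- vector("list", n)
  for (i in seq_len(n)) {
    d <- dist[i, -i]
    kdist[i] <- sort(d, partial = k)[k]
    nb <- setdiff(which(dist[i, ] <= kdist[i]), i)
    neighbors[[i]] <- nb
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    reach <- pmax(kdist[neighbors[[i]]], dist[i, neighbors[[i]]])
    lrd[i] <- 1 / max(mean(reach), eps)
  }
  vapply(seq_len(n), function(i) mean(lrd[neighbors[[i]]]) / lrd[i], numeric(1))
}

# One-class SVM used as a leave-one-out novelty detector: the domain is
# learned from the other n-1 extracts (in their reduced coordinate space)
# and the held-out extract is flagged when it falls outside. A one-class
# SVM is a novelty detector by construction; scoring the very points it was
# fitted on marks ~nu*n boundary points as outliers regardless of the data,
# which at library sizes of tens of extracts is pure noise. The RBF width
# follows the variance scaling gamma = 1/(dim * var(X)).
ocsvm_loo_flags <- function(x, nu = 0.1) {
  n <- nrow(x)
  vapply(seq_len(n), function(i) {
    test <- x[i, -i, drop = FALSE]
    train <- x[-i, -i, drop = FALSE]
    # a point coinciding with a training point cannot be novel (and sits on
    # the decision boundary, where the sign is numerically unstable)
    if (any(apply(train, 1, function(r) all(r == drop(test))))) return(FALSE)
    v <- stats::var(as.vector(train))
    gamma <- if (v > 0) 1 / (ncol(train) * v) else 1 / ncol(train)
    fit <- e1071::svm(train, type = "one-classification", nu = nu,
                      kernel = "radial", scale = FALSE, gamma = gamma)
    !as.logical(stats::predict(fit, test))
  }, logical(1))
}

# Isolation forest on a plain numeric matrix; anomaly score in (0, 1).
# Standard construction: 100 trees on subsamples of size <= 256, random
# axis-aligned splits, expected-path-length normalisation.
iforest_scores <- function(x, n_trees = 100, subsample = 256) {
  n <- nrow(x)
  psi <- min(subsample, n)
  depth_limit <- ceiling(log2(max(psi, 2)))
  harmonic <- function(m) log(m) + 0.5772156649015329
  c_factor <- function(m) {
    ifelse(m > 2, 2 * harmonic(m - 1) - 2 * (m - 1) / m, ifelse(m == 2, 1, 0))
  }
  grow <- function(idx, depth) {
    if (length(idx) <= 1 || depth >= depth_limit) {
      return(list(size = length(idx)))
    }
    spreads <- apply(x[idx, , drop = FALSE], 2, function(v) diff(range(v)))
    usable <- which(spreads > 0)
    if (length(usable) == 0) return(list(size = length(idx)))
    f <- if (length(usable) == 1) usable else sample(usable, 1)
    rng <- range(x[idx, f])
    cut <- stats::runif(1, rng[1], rng[2])
    left <- idx[x[idx, f] < cut]
    right <- idx[x[idx, f] >= cut]
    if (length(left) == 0 || length(right) == 0) return(list(size = length(idx)))
    list(feature = f, cut = cut,
         left = grow(left, depth + 1), right = grow(right, depth + 1))
  }
  path_length <- function(tree, p, depth) {
    if (is.null(tree$feature)) return(depth + c_factor(tree$size))
    if (p[tree$feature] < tree$cut) path_length(tree$left, p, depth + 1)
    else path_length(tree$right, p, depth + 1)
  }
  depths <- matrix(0, n, n_trees)
  for (t in seq_len(n_trees)) {
    idx <- if (psi < n) sample.int(n, psi) else seq_len(n)
    tree <- grow(idx, 0)
    depths[, t] <- apply(x, 1, function(p) path_length(tree, p, 0))
  }
  2^(-rowMeans(depths) / c_factor(psi))
}

#' Run the outlier-detector ensemble on a dissimilarity matrix
#'
#' Three unsupervised detectors vote: LOF on the precomputed dissimilarities
#' (flagged above `lof_threshold`), a one-class SVM with radial kernel on the
#' dissimilarity-matrix rows (leave-one-out novelty detection: each extract
#' is flagged when it falls outside the domain learned from the others), and
#' an isolation forest on the same rows (flagged above anomaly score 0.5).
#' The Similarity Component is the OR of the three flags.
#'
#' @param dist symmetric dissimilarity matrix with extract filenames as
#'   dimnames.
#' @param lof_k LOF neighbourhood size; default `min(5, n - 1)`, shrunk with
#'   a warning when fewer extracts are available.
#' @param lof_threshold LOF value above which an extract is flagged.
#' @param nu one-class SVM nu (upper bound on the training outlier fraction).
#' @param n_trees number of isolation trees.
#' @param seed integer seed fixing the isolation forest's randomness.
#' @return a tibble with one row per extract: `filename`, logical `lof`,
#'   `ocsvm`, `iforest`, integer `SC`, plus the parameters used recorded as
#'   attribute `"params"`.
#' @export
detect_outliers <- function(dist, lof_k = NULL, lof_threshold = 1.5,
                            nu = 0.1, n_trees = 100, seed = 42) {
  n <- nrow(dist)
  if (n < 2 || n != ncol(dist)) validation_error("dist must be square with >= 2 extracts")
  filenames <- rownames(dist) %||% as.character(seq_len(n))
  requested_k <- lof_k %||% min(5, n - 1)
  k <- min(requested_k, n - 1)
  if (k < requested_k) {
    warn(paste0("LOF neighbourhood shrunk to ", k, " (only ", n, " extracts)"))
  }
  lof <- lof_scores(dist, k)
  lof_flag <- lof > lof_threshold
  coords <- unname(dist)
  ocsvm_flag <- ocsvm_loo_flags(coords, nu = nu)
  if_scores <- withr::with_seed(seed, iforest_scores(coords, n_trees = n_trees))
  iforest_flag <- if_scores > 0.5
  out <- tibble(
    filename = filenames,
    lof = unname(lof_flag),
    ocsvm = unname(ocsvm_flag),
    iforest = unname(iforest_flag)
  ) |>
    mutate(SC = as.integer(.data$lof | .data$ocsvm | .data$iforest))
  attr(out, "params") <- list(lof_k = k, lof_threshold = lof_threshold,
                              nu = nu, n_trees = n_trees, seed = seed)
  attr(out, "scores") <- list(lof = unname(lof), iforest = unname(if_scores))
  out
}
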