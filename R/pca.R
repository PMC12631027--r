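#' Fit a principal-component basis on waves
#'
#' Centered PCA of the wave matrix (one row per wave). Components follow a
#' fixed sign convention — each component's largest-magnitude coefficient is
#' positive — so fitted models are reproducible. Fit the basis on training
#' waves only and project held-out waves with [project_waves()].
#'
#' @param waves Wave tibble (typically normalized and filtered).
#' @return An object of class `eag_pca`: list with `mean_wave`, `components`
#'   (columns, orthonormal), `explained_variance_ratio` (non-increasing),
#'   `scores` (training scores), `n_fit_waves`.
#' @export
fit_wave_pca <- function(waves) {
  X <- wave_matrix(waves)
  if (nrow(X) < 2) stop("PCA needs >= 2 waves", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (sum(Xc^2) == 0) {
    stop("degenerate data: zero total variance (all waves identical)",
         call. = FALSE)
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  # sign convention: largest-magnitude loading positive
  flip <- apply(pr$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pr$rotation, 2, flip, `*`)
  scores <- sweep(pr$x, 2, flip, `*`)
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  structure(
    list(mean_wave = ctr, components = rot,
         explained_variance_ratio = evr, scores = scores,
         n_fit_waves = nrow(X)),
    class = "eag_pca")
}

# stack the samples list-column into a waves x samples matrix
wave_matrix <- function(waves) {
  if (is.matrix(waves)) return(waves)
  lens <- lengths(waves$samples)
  if (length(unique(lens)) > 1) {
    stop("waves have inconsistent lengths", call. = FALSE)
  }
  do.call(rbind, waves$samples)
}

#' Project waves onto a fitted principal-component basis
#'
#' Scores are inner products of the centered wave with the leading
#' components of the training basis.
#'
#' @param model An `eag_pca` from [fit_wave_pca()].
#' @param waves Wave tibble (or matrix) to project.
#' @param n_pcs Number of leading components (default: all).
#' @return Numeric score matrix, one row per wave.
#' @export
project_waves <- function(model, waves, n_pcs = NULL) {
  stopifnot(inherits(model, "eag_pca"))
  X <- wave_matrix(waves)
  if (ncol(X) != length(model$mean_wave)) {
    stop("wave length ", ncol(X), " does not match the fitted basis (",
         length(model$mean_wave), ")", call. = FALSE)
  }
  if (is.null(n_pcs)) n_pcs <- ncol(model$components)
  if (n_pcs > ncol(model$components)) {
    stop("requested ", n_pcs, " components; model has ",
         ncol(model$components), call. = FALSE)
  }
  sweep(X, 2, model$mean_wave) %*%
    model$components[, seq_len(n_pcs), drop = FALSE]
}

#' Check the explained-variance floor of the retained components
#'
#' The random-forest features are the first few principal components; this
#' verifies they retain at least the required fraction of the dataset's
#' variance (the conventional floor is 90%). Failure warns rather than
#' aborts.
#'
#' @param model An `eag_pca`.
#' @param n_pcs Number of leading components retained.
#' @param floor Required cumulative explained-variance fraction.
#' @return A list with `pass` and `cumulative_fraction`.
#' @export
check_variance_floor <- function(model, n_pcs = 5, floor = 0.9) {
  evr <- model$explained_variance_ratio
  n_pcs <- min(n_pcs, length(evr))
  cum <- sum(evr[seq_len(n_pcs)])
  pass <- cum >= floor
  if (!pass) {
    warning(sprintf(
      "first %d components explain %.1f%% of variance, below the %.0f%% floor",
      n_pcs, 100 * cum, 100 * floor), call. = FALSE)
  }
  list(pass = pass, cumulative_fraction = cum)
}

#' Confidence ellipse of a class mean in PC1-PC2 space
#'
#' The ellipse bounds the location of the class mean (not the data cloud):
#' eigen-decomposition of `sample covariance / n`, semi-axes
#' `sqrt(eigenvalue * qchisq(level, 2))`.
#'
#' @param scores_2d Two-column matrix of a class's PC1-PC2 scores (>= 3
#'   rows, nonsingular covariance).
#' @param level Confidence level in (0, 1).
#' @param label Optional class label carried on the result.
#' @return A list with `label`, `center`, `axes` (semi-axis lengths,
#'   decreasing), `orientation_rad`, `level`, `n`.
#' @export
class_ellipse <- function(scores_2d, level = 0.95, label = NULL) {
  s <- as.matrix(scores_2d)
  if (ncol(s) != 2) stop("scores_2d must have 2 columns", call. = FALSE)
  n <- nrow(s)
  if (n < 3) {
    stop("class ", if (!is.null(label)) paste0("'", label, "' "),
         "has fewer than 3 points; cannot form an ellipse", call. = FALSE)
  }
  S <- stats::cov(s)
  if (!all(is.finite(S)) || det(S) <= 0) {
    stop("singular covariance for class ",
         if (!is.null(label)) paste0("'", label, "'"), call. = FALSE)
  }
  ed <- eigen(S / n, symmetric = TRUE)
  q <- stats::qchisq(level, df = 2)
  list(label = label, center = colMeans(s),
       axes = sqrt(ed$values * q),
       orientation_rad = atan2(ed$vectors[2, 1], ed$vectors[1, 1]),
       level = level, n = n)
}

#' Per-class mean confidence ellipses for a score table
#'
#' @param scores Matrix of scores (at least two columns; PC1 and PC2 used).
#' @param labels Class label per row.
#' @param level Confidence level.
#' @return A tibble with one row per class: label, center, semi-axes,
#'   orientation, n.
#' @export
class_ellipses <- function(scores, labels, level = 0.95) {
  labels <- as.character(labels)
  purrr::map_dfr(unique(labels), function(cl) {
    e <- class_ellipse(scores[labels == cl, 1:2, drop = FALSE],
                       level = level, label = cl)
    tibble::tibble(label = cl, center_x = e$center[[1]],
                   center_y = e$center[[2]], semi_major = e$axes[[1]],
                   semi_minor = e$axes[[2]],
                   orientation_rad = e$orientation_rad, level = level,
                   n = e$n)
  })
}

#' @export
print.eag_pca <- function(x, ...) {
  cum5 <- sum(x$explained_variance_ratio[seq_len(
    min(5, length(x$explained_variance_ratio)))])
  cat(sprintf(
    "<eag_pca> %d components fit on %d waves; first 5 explain %.1f%% of variance\n",
    ncol(x$components), x$n_fit_waves, 100 * cum5))
  invisible(x)
}

#' @method tidy eag_pca
#' @export
tidy.eag_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$explained_variance_ratio),
    explained_variance_ratio = x$explained_variance_ratio,
    cumulative = cumsum(x$explained_variance_ratio))
}

#' @method glance eag_pca
#' @export
glance.eag_pca <- function(x, ...) {
  evr <- x$explained_variance_ratio
  tibble::tibble(
    n_fit_waves = x$n_fit_waves,
    n_components = ncol(x$components),
    evr_pc1 = evr[[1]],
    cum_evr_5 = sum(evr[seq_len(min(5, length(evr)))]))
}
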