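rank2_waves <- function(n = 30, len = 120, noise = 1e-6, seed = 3) {
  set.seed(seed)
  t <- seq(0, 1, length.out = len)
  b1 <- sin(2 * pi * t)
  b2 <- exp(-3 * t)
  tibble::tibble(
    wave_id = sprintf("w%02d", seq_len(n)),
    samples = lapply(seq_len(n), function(i) {
      rnorm(1) * b1 + rnorm(1) * b2 + rnorm(len, 0, noise)
    }))
}

test_that("a rank-2 construction concentrates variance in two components", {
  w <- rank2_waves()
  m <- fit_wave_pca(w)
  expect_gte(sum(m$explained_variance_ratio[1:2]), 0.999)
  expect_true(all(diff(m$explained_variance_ratio) <= 1e-12))
  expect_true(all(m$explained_variance_ratio >= 0 &
                    m$explained_variance_ratio <= 1))
  expect_lte(sum(m$explained_variance_ratio), 1 + 1e-9)
})

test_that("components are orthonormal and reconstruction is complete", {
  w <- rank2_waves(n = 12, len = 40, noise = 0.05)
  m <- fit_wave_pca(w)
  G <- crossprod(m$components)
  expect_equal(G, diag(ncol(m$components)), tolerance = 1e-8,
               ignore_attr = TRUE)
  X <- do.call(rbind, w$samples)
  recon <- m$scores %*% t(m$components) +
    matrix(m$mean_wave, nrow(X), ncol(X), byrow = TRUE)
  expect_equal(recon, X, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("identical waves are rejected as degenerate", {
  w <- tibble::tibble(wave_id = c("a", "b", "c"),
                      samples = replicate(3, rep(1.5, 20), simplify = FALSE))
  expect_error(fit_wave_pca(w), "degenerate|zero total variance")
})

test_that("projection is centered, consistent with training scores, and energy-preserving", {
  w <- rank2_waves(n = 15, len = 50, noise = 0.1)
  m <- fit_wave_pca(w)
  # the mean wave projects to the origin
  mean_scores <- project_waves(m, matrix(m$mean_wave, 1))
  expect_equal(as.numeric(mean_scores), rep(0, ncol(m$components)),
               tolerance = 1e-10)
  # re-projecting the training waves reproduces the training scores
  expect_equal(project_waves(m, w), m$scores, tolerance = 1e-8,
               ignore_attr = TRUE)
  # Parseval on the orthonormal basis: full score energy = centered norm
  X <- do.call(rbind, w$samples)
  Xc <- sweep(X, 2, m$mean_wave)
  expect_equal(rowSums(project_waves(m, w)^2), rowSums(Xc^2),
               tolerance = 1e-8)
  # shape mismatch
  expect_error(project_waves(m, matrix(0, 1, 49)), "length")
  expect_error(project_waves(m, w, n_pcs = 99), "components")
})

test_that("explained variance agrees with a brute-force eigen-decomposition", {
  w <- rank2_waves(n = 40, len = 30, noise = 0.3, seed = 8)
  m <- fit_wave_pca(w)
  X <- do.call(rbind, w$samples)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  ev <- ev / sum(ev)
  k <- min(length(m$explained_variance_ratio), sum(ev > 1e-12))
  expect_equal(m$explained_variance_ratio[seq_len(k)], ev[seq_len(k)],
               tolerance = 1e-8)
})

test_that("PCA is unsupervised: labels play no role", {
  w <- rank2_waves(n = 20, len = 40, noise = 0.2)
  m1 <- fit_wave_pca(w)
  w$odor <- sample(c("x", "y"), 20, replace = TRUE)
  m2 <- fit_wave_pca(w)
  expect_identical(m1$components, m2$components)
})

test_that("variance floor checks are arithmetic on the ratio vector", {
  fake <- structure(list(explained_variance_ratio = c(0.6, 0.2, 0.1, 0.05, 0.03, 0.02)),
                    class = "eag_pca")
  r <- check_variance_floor(fake, n_pcs = 5, floor = 0.9)
  expect_true(r$pass)
  expect_equal(r$cumulative_fraction, 0.98)
  fake2 <- structure(list(explained_variance_ratio = c(0.3, 0.2, 0.1, 0.1, 0.1, 0.2)),
                     class = "eag_pca")
  expect_warning(r2 <- check_variance_floor(fake2, n_pcs = 5, floor = 0.9),
                 "below")
  expect_false(r2$pass)
  expect_equal(r2$cumulative_fraction, 0.8)
})

test_that("the default synthetic session clears the 90% variance floor", {
  cum <- vapply(1:5, function(s) {
    w <- simulate_session(session_config(n_antennae = 4, seed = s))
    f <- filter_waves(qc_waves(normalize_waves(w)))
    sum(fit_wave_pca(f)$explained_variance_ratio[1:5])
  }, numeric(1))
  expect_true(all(cum >= 0.9))
})

test_that("mean-confidence ellipses follow the chi-square closed form", {
  # construct a cloud whose sample covariance is exactly the identity
  set.seed(4)
  n <- 100
  raw <- matrix(rnorm(2 * n), n, 2)
  raw <- sweep(raw, 2, colMeans(raw))
  W <- chol(solve(stats::cov(raw)))
  pts <- raw %*% t(W)
  expect_equal(stats::cov(pts), diag(2), tolerance = 1e-10, ignore_attr = TRUE)

  e <- class_ellipse(pts, level = 0.95)
  expect_equal(e$axes, rep(sqrt(stats::qchisq(0.95, 2) / n), 2),
               tolerance = 1e-6)
  # quadrupling n with the same covariance halves the axes
  pts4 <- rbind(pts, pts, pts, pts)
  scale_fix <- sqrt((4 * n - 0) / (4 * n)) # cov of stacked copies shrinks by (n-1) factors
  e4 <- class_ellipse(pts4, level = 0.95)
  expect_equal(mean(e4$axes / e$axes), 0.5, tolerance = 0.01)

  expect_error(class_ellipse(pts[1:2, ]), "fewer than 3")
  expect_error(class_ellipse(cbind(1:5, 1:5)), "singular")
})

test_that("per-class ellipse table covers every class", {
  set.seed(6)
  sc <- rbind(matrix(rnorm(40), 20, 2),
              matrix(rnorm(40, mean = 3), 20, 2))
  lab <- rep(c("a", "b"), each = 20)
  tab <- class_ellipses(sc, lab)
  expect_equal(sort(tab$label), c("a", "b"))
  expect_true(all(tab$semi_major >= tab$semi_minor))
  expect_true(all(tab$semi_minor > 0))
})
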