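#' Configure the filter-tuning genetic algorithm
#'
#' Each individual carries three genes — Butterworth low cut, high cut, and
#' order — drawn within the ranges of [filter_params()]. Fitness is the
#' Fisher class-separability of the filtered waves' principal-component
#' scores, evaluated on a tuning subset (half the antennae by default).
#' Selection is by tournament, crossover blends the continuous genes,
#' mutation is Gaussian clipped to the gene ranges, and elitism carries the
#' best individual forward unchanged.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param n_generations Generations to evolve.
#' @param crossover_rate,mutation_rate Per-pair / per-gene operator
#'   probabilities in `[0, 1]`.
#' @param mutation_sd_frac Mutation standard deviation as a fraction of each
#'   gene's range.
#' @param blend_alpha Blend-crossover expansion factor.
#' @param tournament_size Tournament size for parent selection.
#' @param elitism Number of top individuals copied unchanged.
#' @param tuning_fraction Fraction of antennae used for fitness evaluation,
#'   in (0, 1); selection is by antenna to avoid leakage into later
#'   model evaluation.
#' @param n_pcs_fitness Principal components entering the fitness.
#' @param fitness Either `"difference"` (between-class minus within-class
#'   variance) or `"ratio"` (between / within).
#' @param seed Integer seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100, n_generations = 30,
                      crossover_rate = 0.9, mutation_rate = 0.2,
                      mutation_sd_frac = 0.1, blend_alpha = 0.5,
                      tournament_size = 3, elitism = 1,
                      tuning_fraction = 0.5, n_pcs_fitness = 5,
                      fitness = c("difference", "ratio"), seed = 1L) {
  if (population_size < 2) stop("`population_size` must be >= 2", call. = FALSE)
  if (!(tuning_fraction > 0 && tuning_fraction < 1)) {
    stop("`tuning_fraction` must lie in (0, 1)", call. = FALSE)
  }
  for (r in c(crossover_rate, mutation_rate)) {
    if (r < 0 || r > 1) stop("operator rates must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(population_size = as.integer(population_size),
         n_generations = as.integer(n_generations),
         crossover_rate = crossover_rate, mutation_rate = mutation_rate,
         mutation_sd_frac = mutation_sd_frac, blend_alpha = blend_alpha,
         tournament_size = as.integer(tournament_size),
         elitism = as.integer(elitism), tuning_fraction = tuning_fraction,
         n_pcs_fitness = as.integer(n_pcs_fitness),
         fitness = match.arg(fitness), seed = as.integer(seed)),
    class = "ga_config")
}

# gene ranges of the chromosome (shared with filter_params validation)
ga_gene_ranges <- function() {
  list(low_cut_hz = c(1e-3, 1), high_cut_hz = c(1.001, 5), order = c(1, 4))
}

#' Initialize a random GA population
#'
#' Each gene is drawn uniformly within its range (order rounded to an
#' integer); the low- and high-cut ranges are disjoint by construction, so
#' every individual is a valid band-pass.
#'
#' @param config A [ga_config()].
#' @return List of [filter_params()] of length `population_size`.
#' @export
init_population <- function(config) {
  rngs <- ga_gene_ranges()
  lapply(seq_len(config$population_size), function(i) {
    filter_params(
      low_cut_hz = stats::runif(1, rngs$low_cut_hz[1], rngs$low_cut_hz[2]),
      high_cut_hz = stats::runif(1, rngs$high_cut_hz[1], rngs$high_cut_hz[2]),
      order = round(stats::runif(1, rngs$order[1] - 0.499,
                                 rngs$order[2] + 0.499)))
  })
}

#' Fisher class separability of score vectors
#'
#' With classes weighted equally: `between_class` is the mean squared
#' Euclidean distance of the class means to the grand mean of class means;
#' `within_class` is the mean over classes of the mean squared distance of
#' members to their class mean; `fisher_score` is their difference (or
#' ratio). Invariant to class relabeling and row order.
#'
#' @param scores Numeric matrix, one row per observation.
#' @param labels Class labels, one per row.
#' @param type `"difference"` or `"ratio"`.
#' @return A list with `between_class`, `within_class`, `fisher_score`.
#' @export
#' @examples
#' s <- rbind(c(0, 0), c(0, 2), c(4, 0), c(4, 2))
#' fisher_score(s, c("a", "a", "b", "b")) # between 4, within 1, fisher 3
fisher_score <- function(scores, labels, type = "difference") {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  stopifnot(nrow(scores) == length(labels))
  classes <- unique(labels)
  if (length(classes) < 2) stop("need >= 2 classes", call. = FALSE)
  small <- names(which(table(labels) < 2))
  if (length(small)) {
    stop("class '", small[1], "' has fewer than 2 members", call. = FALSE)
  }
  means <- t(vapply(classes, function(cl) {
    colMeans(scores[labels == cl, , drop = FALSE])
  }, numeric(ncol(scores))))
  grand <- colMeans(means)
  between <- mean(rowSums((means - matrix(grand, nrow(means), ncol(means),
                                          byrow = TRUE))^2))
  within <- mean(vapply(classes, function(cl) {
    x <- scores[labels == cl, , drop = FALSE]
    mu <- colMeans(x)
    mean(rowSums((x - matrix(mu, nrow(x), ncol(x), byrow = TRUE))^2))
  }, numeric(1)))
  fs <- if (type == "ratio") {
    if (within == 0) Inf else between / within
  } else {
    between - within
  }
  list(between_class = between, within_class = within, fisher_score = fs)
}

#' Fitness of one filter chromosome
#'
#' Filters the tuning waves with `params`, fits a PCA on the filtered set,
#' projects to the first `n_pcs` scores and evaluates [fisher_score()] on
#' the class labels.
#'
#' @param params A [filter_params()].
#' @param waves Labeled (normalized) wave tibble; class labels taken from
#'   `labels` or the `odor` column.
#' @param n_pcs Number of principal components entering the fitness.
#' @param labels Optional label vector overriding `waves$odor`.
#' @param sample_rate_hz Sampling rate; from table metadata when omitted.
#' @param type Fitness type, `"difference"` or `"ratio"`.
#' @return A list with `between_class`, `within_class`, `fisher_score`.
#' @export
fisher_fitness <- function(params, waves, n_pcs = 5, labels = NULL,
                           sample_rate_hz = NULL, type = "difference") {
  if (is.null(labels)) labels <- waves$odor
  filt <- filter_waves(waves, params, sample_rate_hz = sample_rate_hz)
  pca <- fit_wave_pca(filt)
  n_pcs <- min(n_pcs, ncol(pca$components))
  scores <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  fisher_score(scores, labels, type = type)
}

clip <- function(x, rng) pmin(pmax(x, rng[1]), rng[2])

#' Evolve Butterworth filter parameters by class separability
#'
#' Generational genetic algorithm over [filter_params()] chromosomes:
#' tournament selection, blend crossover on the continuous genes, Gaussian
#' mutation clipped to the gene ranges (order re-rounded to an integer),
#' and elitism. Fitness is evaluated on a tuning subset of antennae
#' (`tuning_fraction`); the best-ever individual is returned and the
#' best-so-far fitness is non-decreasing across generations.
#'
#' @param waves Labeled normalized wave tibble.
#' @param config A [ga_config()].
#' @param labels Optional label vector overriding `waves$odor`.
#' @param sample_rate_hz Sampling rate; from table metadata when omitted.
#' @return An object of class `eag_ga`: list with `best_params`,
#'   `best_fitness`, `trajectory` (tibble: generation, best, mean,
#'   best_so_far), `tuning_antennae`, `config`.
#' @export
evolve_filter <- function(waves, config = ga_config(), labels = NULL,
                          sample_rate_hz = NULL) {
  stopifnot(inherits(config, "ga_config"))
  if (is.null(labels)) labels <- waves$odor
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  antennae <- sort(unique(waves$antenna_id))
  if (length(antennae) >= 2) {
    n_tune <- max(1L, as.integer(floor(
      config$tuning_fraction * length(antennae) + 0.5)))
    n_tune <- min(n_tune, length(antennae) - 0L)
    tune_ant <- sample(antennae)[seq_len(n_tune)]
  } else {
    tune_ant <- antennae
  }
  keep <- waves$antenna_id %in% tune_ant
  tune_waves <- waves[keep, , drop = FALSE]
  attr(tune_waves, "config") <- attr(waves, "config")
  attr(tune_waves, "sample_rate_hz") <- attr(waves, "sample_rate_hz")
  tune_labels <- labels[keep]

  eval_fit <- function(ind) {
    fisher_fitness(ind, tune_waves, n_pcs = config$n_pcs_fitness,
                   labels = tune_labels, sample_rate_hz = sample_rate_hz,
                   type = config$fitness)$fisher_score
  }

  rngs <- ga_gene_ranges()
  genes <- c("low_cut_hz", "high_cut_hz", "order")

  pop <- init_population(config)
  fit <- vapply(pop, eval_fit, numeric(1))
  best_idx <- which.max(fit)
  best_ind <- pop[[best_idx]]
  best_fit <- fit[[best_idx]]
  traj <- list(tibble::tibble(generation = 0L, best = max(fit),
                              mean = mean(fit), best_so_far = best_fit))

  tournament <- function() {
    idx <- sample.int(length(pop), min(config$tournament_size, length(pop)))
    pop[[idx[which.max(fit[idx])]]]
  }
  make_valid <- function(ind) {
    ind$low_cut_hz <- clip(ind$low_cut_hz, rngs$low_cut_hz)
    ind$high_cut_hz <- clip(ind$high_cut_hz, rngs$high_cut_hz)
    ind$order <- as.integer(clip(round(ind$order), rngs$order))
    filter_params(ind$low_cut_hz, ind$high_cut_hz, ind$order)
  }

  for (gen in seq_len(config$n_generations)) {
    elite_idx <- utils::head(order(fit, decreasing = TRUE), config$elitism)
    offspring <- pop[elite_idx]
    while (length(offspring) < config$population_size) {
      p1 <- tournament(); p2 <- tournament()
      c1 <- p1; c2 <- p2
      if (stats::runif(1) < config$crossover_rate) {
        for (g in genes) {
          lo <- min(p1[[g]], p2[[g]]); hi <- max(p1[[g]], p2[[g]])
          d <- hi - lo
          a <- config$blend_alpha
          c1[[g]] <- stats::runif(1, lo - a * d, hi + a * d)
          c2[[g]] <- stats::runif(1, lo - a * d, hi + a * d)
        }
      }
      for (ch in list(quote(c1), quote(c2))) {
        ind <- eval(ch)
        for (g in genes) {
          if (stats::runif(1) < config$mutation_rate) {
            sd_g <- config$mutation_sd_frac * diff(rngs[[g]])
            ind[[g]] <- ind[[g]] + stats::rnorm(1, 0, sd_g)
          }
        }
        assign(as.character(ch), ind)
      }
      offspring <- c(offspring, list(make_valid(c1)))
      if (length(offspring) < config$population_size) {
        offspring <- c(offspring, list(make_valid(c2)))
      }
    }
    pop <- offspring
    fit <- vapply(pop, eval_fit, numeric(1))
    gi <- which.max(fit)
    if (fit[[gi]] > best_fit) { best_fit <- fit[[gi]]; best_ind <- pop[[gi]] }
    traj[[gen + 1L]] <- tibble::tibble(
      generation = gen, best = max(fit), mean = mean(fit),
      best_so_far = best_fit)
  }

  structure(list(best_params = best_ind, best_fitness = best_fit,
                 trajectory = dplyr::bind_rows(traj),
                 tuning_antennae = tune_ant, config = config),
            class = "eag_ga")
}

#' @export
print.eag_ga <- function(x, ...) {
  cat(sprintf(
    "<eag_ga> best fitness %.4g after %d generations\n  best: %.4g-%.4g Hz, order %d (tuned on %d antennae)\n",
    x$best_fitness, max(x$trajectory$generation), x$best_params$low_cut_hz,
    x$best_params$high_cut_hz, x$best_params$order, length(x$tuning_antennae)))
  invisible(x)
}

#' @method tidy eag_ga
#' @export
tidy.eag_ga <- function(x, ...) x$trajectory

#' @method glance eag_ga
#' @export
glance.eag_ga <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best_fitness,
    low_cut_hz = x$best_params$low_cut_hz,
    high_cut_hz = x$best_params$high_cut_hz,
    order = x$best_params$order,
    n_generations = max(x$trajectory$generation),
    population_size = x$config$population_size)
}
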