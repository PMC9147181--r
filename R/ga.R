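# Genetic algorithm over individuals encoding K feature subsets of Sfs
# integer indices each. Crossover exchanges whole subsets at a single point
# drawn uniformly from {0..K}; mutation resamples each position
# independently with probability P_M; selection keeps the best M of the 2M
# parents + children by validation F1 (elitism, stable tie-break). All
# randomness is drawn from named streams derived from the master seed.

#' GA configuration
#'
#' Defaults follow the published study settings: 50 generations, population
#' 50, mutation probability 0.1, K = 10 subsets of size 300, random forest
#' with 50 trees as base learner. `M` must be even (parents are paired for
#' crossover).
#'
#' @param generations number of generations T.
#' @param pop_size population size M (even).
#' @param p_mutation per-position mutation probability.
#' @param k subsets per individual.
#' @param subset_size indices per subset (Sfs).
#' @param n_features feature count Sf of the fused matrix.
#' @param base_learner base-learner spec; default [base_learner_rf()].
#' @param retries per-slot retry cap in boosting.
#' @param seed master seed; every random stream derives from it.
#' @return a `ga_config` list.
#' @export
ga_config <- function(generations = 50L, pop_size = 50L, p_mutation = 0.1,
                      k = 10L, subset_size = 300L, n_features,
                      base_learner = base_learner_rf(), retries = 5L,
                      seed = 1L) {
  stopifnot(generations >= 0, pop_size >= 2, pop_size %% 2 == 0,
            p_mutation >= 0, p_mutation <= 1, k >= 1, subset_size >= 1,
            n_features >= 1, retries >= 0)
  structure(list(generations = as.integer(generations),
                 pop_size = as.integer(pop_size),
                 p_mutation = p_mutation, k = as.integer(k),
                 subset_size = as.integer(subset_size),
                 n_features = as.integer(n_features),
                 base_learner = base_learner, retries = as.integer(retries),
                 seed = as.integer(seed)),
            class = "ga_config")
}

new_individual <- function(k, subset_size, n_features) {
  matrix(sample.int(n_features, k * subset_size, replace = TRUE),
         nrow = k, ncol = subset_size)
}

#' Initialize a random population
#'
#' @param config a [ga_config()].
#' @return list of `pop_size` individuals, each a `k x subset_size` integer
#'   matrix of 1-based feature indices (duplicates permitted).
#' @export
init_population <- function(config) {
  with_seed(derive_seed(config$seed, "init"), {
    lapply(seq_len(config$pop_size), function(i) {
      new_individual(config$k, config$subset_size, config$n_features)
    })
  })
}

#' Single-point crossover at subset granularity
#'
#' Draws a crossover point CP uniformly from `{0..K}` and exchanges whole
#' subsets: child a = a's subsets `[0, CP)` + b's `[CP, K)`, and vice versa.
#' CP = 0 swaps the parents entirely; CP = K returns them unchanged.
#'
#' @param a,b parent individuals with equal dimensions.
#' @param cp optional fixed crossover point (otherwise drawn from the
#'   ambient RNG).
#' @return list of two children.
#' @export
crossover_pair <- function(a, b, cp = NULL) {
  stopifnot(identical(dim(a), dim(b)))
  k <- nrow(a)
  if (is.null(cp)) cp <- sample.int(k + 1L, 1L) - 1L
  stopifnot(cp >= 0, cp <= k)
  left <- seq_len(cp)
  child_a <- rbind(a[left, , drop = FALSE],
                   b[setdiff(seq_len(k), left), , drop = FALSE])
  child_b <- rbind(b[left, , drop = FALSE],
                   a[setdiff(seq_len(k), left), , drop = FALSE])
  list(child_a, child_b)
}

#' Per-position mutation
#'
#' Each of the `K x Sfs` positions is independently replaced with
#' probability `p_mutation` by a uniform-random feature index.
#'
#' @param individual a `k x subset_size` integer matrix.
#' @param p_mutation per-position mutation probability.
#' @param n_features feature count Sf.
#' @return the mutated individual.
#' @export
mutate <- function(individual, p_mutation, n_features) {
  hit <- stats::runif(length(individual)) < p_mutation
  if (any(hit)) {
    individual[hit] <- sample.int(n_features, sum(hit), replace = TRUE)
  }
  individual
}

#' Fitness: validation F1 of the individual's ensemble
#'
#' Trains the individual's rotation-boosting ensemble on the training rows
#' and returns the F1 of the positive class on the validation rows (0 when
#' precision + recall is 0). A degenerate individual (no usable subset)
#' scores 0 with a warning rather than aborting the run.
#'
#' @param individual a `k x subset_size` index matrix.
#' @param train_x,train_y,val_x,val_y data splits over the full feature
#'   space (already normalized).
#' @param config a [ga_config()].
#' @param column_kinds per-column kinds of the feature space.
#' @param seed RNG stream for the boosting bootstraps.
#' @return list with `fitness` (F1) and the trained `ensemble`.
#' @export
evaluate_fitness <- function(individual, train_x, train_y, val_x, val_y,
                             config, column_kinds, seed = config$seed) {
  ens <- try(train_ensemble(individual, train_x, train_y,
                            column_kinds = column_kinds,
                            base_learner = config$base_learner,
                            retries = config$retries, seed = seed),
             silent = TRUE)
  if (inherits(ens, "try-error")) {
    rega_warn("individual evaluation failed, fitness 0: ",
              attr(ens, "condition")$message)
    return(list(fitness = 0, ensemble = NULL))
  }
  pred <- predict_labels(ens, val_x)
  m <- compute_metrics(val_y, pred)
  list(fitness = m$f1, ensemble = ens)
}

#' Elitist survivor selection
#'
#' Keeps the `m` fittest of the evaluated individuals; exact fitness ties
#' are broken by stable original order (parents come before children).
#'
#' @param individuals list of individuals (parents followed by children).
#' @param fitness numeric fitness per individual.
#' @param m number of survivors.
#' @return list with `individuals` and `fitness` of the survivors.
#' @export
select_survivors <- function(individuals, fitness, m) {
  stopifnot(length(individuals) == length(fitness), m <= length(individuals))
  keep <- order_stable_desc(fitness)[seq_len(m)]
  keep <- sort(keep)  # stable order among survivors
  list(individuals = individuals[keep], fitness = fitness[keep])
}

#' Evolve a population against validation F1
#'
#' Runs the full GA loop: random parent pairing, unconditional single-point
#' crossover of every pair, mutation of the children, child evaluation, and
#' elitist top-M selection from the 2M parents + children. Parents keep
#' their cached fitness across generations. The per-generation best
#' validation F1 is recorded (non-decreasing by elitism); when `test_x` is
#' supplied the best individual's test F1 is tracked for the evolution
#' curve only and never influences selection.
#'
#' @param config a [ga_config()].
#' @param train_x,train_y,val_x,val_y training and validation splits.
#' @param column_kinds per-column kinds of the feature space.
#' @param test_x,test_y optional held-out split tracked in the curve.
#' @param verbose print per-generation progress.
#' @return list with `population`, `fitness`, `best_individual`,
#'   `best_fitness`, `best_ensemble`, and `curve` (data frame with columns
#'   `generation`, `best_val_f1`, `test_f1`).
#' @export
evolve <- function(config, train_x, train_y, val_x, val_y, column_kinds,
                   test_x = NULL, test_y = NULL, verbose = FALSE) {
  eval_seed <- function(gen, idx) derive_seed(config$seed, "eval", gen, idx)
  pop <- init_population(config)
  fit <- numeric(config$pop_size)
  best_ens <- NULL
  best_fit_seen <- -Inf
  evaluate_at <- function(ind, gen, idx) {
    evaluate_fitness(ind, train_x, train_y, val_x, val_y, config,
                     column_kinds, seed = eval_seed(gen, idx))
  }
  for (i in seq_along(pop)) {
    r <- evaluate_at(pop[[i]], 0L, i)
    fit[i] <- r$fitness
    if (r$fitness > best_fit_seen && !is.null(r$ensemble)) {
      best_fit_seen <- r$fitness
      best_ens <- r$ensemble
    }
  }
  curve <- data.frame(generation = integer(0), best_val_f1 = numeric(0),
                      test_f1 = numeric(0))
  record <- function(gen) {
    b <- which.max(fit)
    test_f1 <- NA_real_
    if (!is.null(test_x) && !is.null(best_ens)) {
      test_f1 <- compute_metrics(test_y,
                                 predict_labels(best_ens, test_x))$f1
    }
    curve[nrow(curve) + 1L, ] <<- list(gen, fit[b], test_f1)
    if (verbose) {
      rega_msg(sprintf("generation %d: best validation F1 = %.4f", gen,
                       fit[b]))
    }
  }
  record(0L)
  if (config$generations > 0) {
    for (gen in seq_len(config$generations)) {
      pairing <- with_seed(derive_seed(config$seed, "pair", gen),
                           sample.int(config$pop_size))
      children <- with_seed(derive_seed(config$seed, "ops", gen), {
        out <- vector("list", config$pop_size)
        for (p in seq_len(config$pop_size / 2L)) {
          i <- pairing[2L * p - 1L]
          j <- pairing[2L * p]
          ch <- crossover_pair(pop[[i]], pop[[j]])
          out[[2L * p - 1L]] <- mutate(ch[[1]], config$p_mutation,
                                       config$n_features)
          out[[2L * p]] <- mutate(ch[[2]], config$p_mutation,
                                  config$n_features)
        }
        out
      })
      child_fit <- numeric(config$pop_size)
      for (i in seq_along(children)) {
        r <- evaluate_at(children[[i]], gen, i)
        child_fit[i] <- r$fitness
        if (r$fitness > best_fit_seen && !is.null(r$ensemble)) {
          best_fit_seen <- r$fitness
          best_ens <- r$ensemble
        }
      }
      sel <- select_survivors(c(pop, children), c(fit, child_fit),
                              config$pop_size)
      pop <- sel$individuals
      fit <- sel$fitness
      record(gen)
    }
  }
  b <- which.max(fit)
  list(population = pop, fitness = fit, best_individual = pop[[b]],
       best_fitness = fit[b], best_ensemble = best_ens, curve = curve)
}
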