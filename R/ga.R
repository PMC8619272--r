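#' Genetic algorithm configuration
#'
#' Defaults follow the published optimization run: population 200, 1000
#' generations, per-gene uniform mutation at rate 0.05, roulette-wheel
#' selection and two-point crossover with a crossover fraction of 0.6.
#' The search box defaults to the experimental envelope - sodium
#' hypochlorite 0-15 %, hydrogen peroxide 0-30 %, immersion 0-20 min - and
#' 2 elites guarantee a monotone best-objective trace.
#'
#' @param population_size Number of chromosomes per generation.
#' @param generations Number of generations (no early stopping).
#' @param mutation_rate Per-gene probability of uniform resampling.
#' @param crossover_fraction Proportion of non-elite offspring produced by
#'   crossover rather than cloning.
#' @param elite_count Chromosomes copied unchanged into the next
#'   generation.
#' @param lower,upper Per-gene bounds (equal length, `lower < upper`).
#' @param seed Integer seed; the whole run is deterministic given it.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 200L, generations = 1000L,
                      mutation_rate = 0.05, crossover_fraction = 0.6,
                      elite_count = 2L,
                      lower = c(naocl = 0, h2o2 = 0, time = 0),
                      upper = c(naocl = 15, h2o2 = 30, time = 20),
                      seed = 1L) {
  stopifnot(population_size >= 2L, generations >= 1L,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_fraction >= 0, crossover_fraction <= 1,
            elite_count >= 0L, population_size > elite_count,
            length(lower) == length(upper), length(lower) >= 2L,
            all(is.finite(lower)), all(is.finite(upper)))
  if (any(lower >= upper)) stop("each gene needs lower < upper bounds")
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         mutation_rate = mutation_rate,
         crossover_fraction = crossover_fraction,
         elite_count = as.integer(elite_count),
         lower = lower, upper = upper, seed = as.integer(seed)),
    class = "ga_config")
}

#' Roulette-wheel selection
#'
#' Samples `count` indices with replacement, each index selected with
#' probability proportional to its (nonnegative) fitness. Uses the current
#' RNG stream.
#'
#' @param fitness Nonnegative fitness values, at least one positive.
#' @param count Number of draws.
#' @return Integer vector of selected indices.
#' @export
roulette_select <- function(fitness, count) {
  if (any(!is.finite(fitness)) || any(fitness < 0)) {
    stop("fitness values must be finite and nonnegative")
  }
  if (all(fitness == 0)) {
    stop("all fitness values are zero: selection probabilities undefined")
  }
  sample.int(length(fitness), count, replace = TRUE, prob = fitness)
}

#' Two-point crossover
#'
#' Draws two cut points `i < j` uniformly from `{0, ..., L}` and swaps the
#' gene segment in positions `(i, j]` between the parents. Cuts are drawn
#' from the inclusive range so that on a 3-gene chromosome single-gene and
#' two-gene swaps are both reachable. Equal cuts leave the parents
#' unchanged.
#'
#' @param a,b Parent chromosomes (equal length >= 2).
#' @param cuts Optional fixed cut points (length-2 integer vector),
#'   otherwise drawn from the current RNG stream.
#' @return A list with children `a` and `b`.
#' @export
crossover_two_point <- function(a, b, cuts = NULL) {
  L <- length(a)
  if (length(b) != L) stop("parents must have equal gene counts")
  if (L < 2L) stop("two-point crossover needs at least 2 genes")
  if (is.null(cuts)) cuts <- sort(sample(0:L, 2L, replace = TRUE))
  cuts <- sort(as.integer(cuts))
  if (cuts[1L] < 0L || cuts[2L] > L) stop("cuts must lie in {0, ..., L}")
  if (cuts[1L] < cuts[2L]) {
    seg <- (cuts[1L] + 1L):cuts[2L]
    tmp <- a[seg]
    a[seg] <- b[seg]
    b[seg] <- tmp
  }
  list(a = a, b = b)
}

#' Uniform mutation
#'
#' Each gene is independently replaced, with probability `rate`, by a
#' uniform draw within its bounds; otherwise it is left unchanged.
#'
#' @param genes Chromosome (numeric vector).
#' @param rate Per-gene mutation probability in \[0, 1\].
#' @param lower,upper Per-gene bounds (recycled if scalar).
#' @return The mutated chromosome.
#' @export
mutate_uniform <- function(genes, rate, lower, upper) {
  stopifnot(rate >= 0, rate <= 1)
  L <- length(genes)
  lower <- rep_len(lower, L)
  upper <- rep_len(upper, L)
  hit <- stats::runif(L) < rate
  if (any(hit)) {
    genes[hit] <- stats::runif(sum(hit), lower[hit], upper[hit])
  }
  genes
}

#' Minimize an objective over a box with a real-coded genetic algorithm
#'
#' Per generation: evaluate the population, copy the `elite_count` best
#' unchanged, produce `crossover_fraction` of the remaining offspring by
#' two-point crossover of roulette-selected parents and the rest by
#' cloning roulette-selected parents, then apply uniform mutation to every
#' non-elite offspring. Selection fitness is windowed per generation as
#' `max(objective) - objective` (uniform when the population is flat), the
#' standard tuning-free way to run roulette selection on a minimization
#' problem. On the 0-100 % contamination surface this is within a constant
#' of the "100 minus contamination" fitness the optimization was designed
#' around, but it also behaves on objectives of any scale.
#'
#' @param objective Vectorized objective: a function taking an `n x L`
#'   matrix of chromosomes (columns named after the genes) and returning
#'   `n` finite values to minimize.
#' @param config A [ga_config()].
#' @return An object of class `ga_result`: `best` (named gene vector),
#'   `best_objective`, `history` (data frame with per-generation `best`
#'   and `mean` objective), and the `seed`/`config` used.
#' @examples
#' sphere <- function(m) rowSums((m - 0.5)^2)
#' cfg <- ga_config(population_size = 50, generations = 100,
#'                  lower = c(x = 0, y = 0, z = 0),
#'                  upper = c(x = 1, y = 1, z = 1), seed = 7)
#' run_ga(sphere, cfg)$best
#' @export
run_ga <- function(objective, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"), is.function(objective))
  L <- length(config$lower)
  pop <- config$population_size
  gene_names <- names(config$lower)
  evaluate <- function(P) {
    y <- objective(P)
    if (length(y) != nrow(P) || any(!is.finite(y))) {
      bad <- if (length(y) == nrow(P)) which(!is.finite(y))[1L] else 1L
      stop("objective returned a non-finite value at chromosome (",
           paste(signif(P[bad, ], 6), collapse = ", "), ")")
    }
    y
  }
  with_seed(config$seed, {
    P <- matrix(stats::runif(pop * L, rep(config$lower, each = pop),
                             rep(config$upper, each = pop)),
                nrow = pop, ncol = L, dimnames = list(NULL, gene_names))
    best_genes <- NULL
    best_obj <- Inf
    hist_best <- hist_mean <- numeric(config$generations)
    for (g in seq_len(config$generations)) {
      y <- evaluate(P)
      gen_best <- which.min(y)
      if (y[gen_best] < best_obj) {
        best_obj <- y[gen_best]
        best_genes <- P[gen_best, ]
      }
      hist_best[g] <- y[gen_best]
      hist_mean[g] <- mean(y)
      if (g == config$generations) break
      fitness <- max(y) - y
      pick <- function(k) {
        if (all(fitness == 0)) sample.int(pop, k, replace = TRUE)
        else roulette_select(fitness, k)
      }
      elites <- P[order(y)[seq_len(config$elite_count)], , drop = FALSE]
      n_off <- pop - config$elite_count
      n_cross <- round(config$crossover_fraction * n_off)
      offspring <- matrix(NA_real_, n_off, L,
                          dimnames = list(NULL, gene_names))
      if (n_cross > 0L) {
        n_pairs <- ceiling(n_cross / 2)
        pa <- pick(n_pairs)
        pb <- pick(n_pairs)
        row <- 1L
        for (j in seq_len(n_pairs)) {
          ch <- crossover_two_point(P[pa[j], ], P[pb[j], ])
          offspring[row, ] <- ch$a
          if (row + 1L <= n_cross) offspring[row + 1L, ] <- ch$b
          row <- row + 2L
        }
      }
      if (n_off > n_cross) {
        offspring[(n_cross + 1L):n_off, ] <- P[pick(n_off - n_cross), ,
                                               drop = FALSE]
      }
      for (j in seq_len(n_off)) {
        offspring[j, ] <- mutate_uniform(offspring[j, ], config$mutation_rate,
                                         config$lower, config$upper)
      }
      P <- rbind(elites, offspring)
    }
    structure(
      list(best = best_genes, best_objective = best_obj,
           history = data.frame(generation = seq_len(config$generations),
                                best = hist_best, mean = hist_mean),
           seed = config$seed, config = config),
      class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat("Genetic algorithm result\n")
  cat(sprintf("  generations: %d  population: %d  seed: %d\n",
              x$config$generations, x$config$population_size, x$seed))
  cat("  best chromosome:",
      paste(sprintf("%s = %.4g", names(x$best), x$best), collapse = ", "),
      "\n")
  cat(sprintf("  best objective: %.6g\n", x$best_objective))
  invisible(x)
}
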