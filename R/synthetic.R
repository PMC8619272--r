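#' Parameters of the synthetic contamination surface
#'
#' A first-order kill-kinetics model for the probability that a seed
#' remains contaminated after immersion:
#' \deqn{p(x) = p_0 \exp\{-(\alpha \cdot \mathrm{naocl} +
#'       \beta \cdot \mathrm{h2o2}) \cdot \mathrm{time}^\gamma\}.}
#' Defaults are calibrated to the qualitative pattern of the packaged
#' trial: an untreated control at 100 % contamination (`baseline = 1`),
#' sodium hypochlorite roughly 25 times as potent as hydrogen peroxide
#' (`potency_naocl = 0.025` vs `potency_h2o2 = 0.001` per percent-minute),
#' and first-order time dependence (`time_exponent = 1`). With these
#' values 5 % hypochlorite for 10 min leaves p ~ 0.29 and 10-30 % hydrogen
#' peroxide alone stays above 0.74, mirroring the observed contrast
#' between the two disinfectants.
#'
#' @param baseline Baseline contamination probability `p0` in \[0, 1\].
#' @param potency_naocl Kill rate of sodium hypochlorite per %-min (>= 0).
#' @param potency_h2o2 Kill rate of hydrogen peroxide per %-min (>= 0).
#' @param time_exponent Exponent on immersion time (>= 0).
#' @return An object of class `surface_params`.
#' @export
surface_params <- function(baseline = 1.0, potency_naocl = 0.025,
                           potency_h2o2 = 0.001, time_exponent = 1.0) {
  stopifnot(baseline >= 0, baseline <= 1, potency_naocl >= 0,
            potency_h2o2 >= 0, time_exponent >= 0)
  structure(
    list(baseline = baseline, potency_naocl = potency_naocl,
         potency_h2o2 = potency_h2o2, time_exponent = time_exponent),
    class = "surface_params")
}

#' True contamination probability of the synthetic surface
#'
#' @param treatments A treatment data frame/matrix (columns `naocl`,
#'   `h2o2`, `time`) or a single length-3 vector.
#' @param params A [surface_params()] object.
#' @return Probabilities in \[0, 1\], non-increasing in each coordinate.
#' @examples
#' contamination_probability(c(5, 0, 10), surface_params(potency_naocl = 0.1))
#' # exp(-5) ~ 0.0067
#' @export
contamination_probability <- function(treatments, params = surface_params()) {
  stopifnot(inherits(params, "surface_params"))
  m <- as_treatment_matrix(treatments)
  dose <- params$potency_naocl * m[, "naocl"] + params$potency_h2o2 * m[, "h2o2"]
  # 0^0 = 1 by convention: with time_exponent 0 the exposure is dose-only
  p <- params$baseline * exp(-dose * m[, "time"]^params$time_exponent)
  unname(pmin(pmax(p, 0), 1))
}

#' Factorial design of the packaged trial
#'
#' The 19 (naocl, h2o2, time) combinations of the disinfection experiment,
#' for drop-in simulated counterparts of the real data.
#'
#' @return A data frame with columns `naocl`, `h2o2`, `time`.
#' @export
default_design <- function() {
  disinfection_trial()[, c("naocl", "h2o2", "time")]
}

#' Simulate a disinfection experiment from the synthetic surface
#'
#' Each replicate cultures `seeds_per_rep` seeds; the number contaminated
#' is binomial with the surface probability, so replicate contamination
#' percentages are multiples of `100 / seeds_per_rep` - the same
#' discretization the real assay exhibits. Summaries use the package's
#' mean/SE conventions (mean to 1 decimal, SE = sample SD / sqrt(n_reps)
#' to 2 decimals), so simulated tables round-trip through
#' [reconstruct_replicates()].
#'
#' @param design Data frame of treatments (default: the packaged trial's
#'   factorial design).
#' @param params A [surface_params()] object.
#' @param n_reps Replicates per treatment (default 3).
#' @param seeds_per_rep Seeds per replicate (default 5).
#' @param seed Integer seed.
#' @return A list with `summary` (an experiment table with `mean`, `se`)
#'   and `replicates` (long data frame with `rep` and `contamination`).
#' @export
simulate_experiment <- function(design = default_design(),
                                params = surface_params(),
                                n_reps = 3L, seeds_per_rep = 5L, seed = 1L) {
  stopifnot(n_reps >= 1L, seeds_per_rep >= 1L)
  m <- as_treatment_matrix(design)
  p <- contamination_probability(m, params)
  n_trt <- nrow(m)
  counts <- with_seed(seed, {
    stats::rbinom(n_trt * n_reps, size = seeds_per_rep,
                  prob = rep(p, each = n_reps))
  })
  contamination <- 100 * counts / seeds_per_rep
  replicates <- data.frame(
    naocl = rep(m[, "naocl"], each = n_reps),
    h2o2 = rep(m[, "h2o2"], each = n_reps),
    time = rep(m[, "time"], each = n_reps),
    rep = rep(seq_len(n_reps), times = n_trt),
    contamination = contamination)
  by_trt <- matrix(contamination, nrow = n_reps)
  summary <- data.frame(
    naocl = m[, "naocl"], h2o2 = m[, "h2o2"], time = m[, "time"],
    mean = round(colMeans(by_trt), 1),
    se = round(apply(by_trt, 2L, stats::sd) / sqrt(n_reps), 2))
  attr(summary, "n_reps") <- as.integer(n_reps)
  attr(summary, "seeds_per_rep") <- as.integer(seeds_per_rep)
  list(summary = summary, replicates = replicates, seed = seed,
       params = params)
}

#' End-to-end optimum recovery check on a synthetic surface
#'
#' Simulates a factorial experiment from a known monotone surface, fits a
#' GRNN to the replicate-level data, minimizes its predictions with the
#' genetic algorithm, and checks that the *true* contamination probability
#' at the GA's protocol is within `tolerance` of the minimum achievable
#' over the search box. This is the harness that validates the whole
#' pipeline against ground truth.
#'
#' @param params A [surface_params()] with positive potencies.
#' @param ga A [ga_config()]; defaults to a 100 x 300 run, ample for the
#'   smooth three-gene surface.
#' @param design Treatments to simulate (default: the packaged factorial).
#' @param n_reps,seeds_per_rep Replication structure.
#' @param tolerance Allowed excess of true probability over the box
#'   minimum (default 0.02).
#' @param seed Master seed; simulation and GA seeds are derived from it.
#' @return A list: `pass`, `best` (the GA protocol), `true_probability`,
#'   `envelope_min`, `predicted_contamination`, and the fitted `sigma`.
#' @export
recover_optimum_check <- function(params = surface_params(),
                                  ga = NULL,
                                  design = default_design(),
                                  n_reps = 3L, seeds_per_rep = 5L,
                                  tolerance = 0.02, seed = 1L) {
  if (is.null(ga)) {
    ga <- ga_config(population_size = 100L, generations = 300L,
                    seed = derive_seed(seed, 2L))
  }
  sim <- simulate_experiment(design, params, n_reps = n_reps,
                             seeds_per_rep = seeds_per_rep,
                             seed = derive_seed(seed, 1L))
  obs <- sim$replicates
  model <- fit_grnn(obs[, c("naocl", "h2o2", "time")], obs$contamination)
  result <- run_ga(function(m) predict(model, m), ga)
  # the surface is monotone non-increasing in every coordinate, but scan a
  # grid anyway so the envelope minimum is honest for any parameterization
  grid <- as.matrix(expand.grid(
    naocl = seq(ga$lower[1L], ga$upper[1L], length.out = 16L),
    h2o2 = seq(ga$lower[2L], ga$upper[2L], length.out = 16L),
    time = seq(ga$lower[3L], ga$upper[3L], length.out = 16L)))
  envelope_min <- min(contamination_probability(grid, params))
  true_p <- contamination_probability(result$best, params)
  list(pass = true_p <= envelope_min + tolerance,
       best = result$best,
       true_probability = true_p,
       envelope_min = envelope_min,
       predicted_contamination = result$best_objective,
       sigma = model$sigma,
       seed = seed)
}
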