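#' The cannabis seed disinfection trial
#'
#' The complete published disinfection experiment: 19 treatments over
#' sodium hypochlorite concentration (% v/v), hydrogen peroxide
#' concentration (%) and immersion time (min), each summarised as mean
#' contamination percentage (1 decimal) with its standard error
#' (2 decimals) over 3 replicates of 5 seeds. The untreated control
#' (0, 0, 0) shows 100 % contamination; sodium hypochlorite at 5-15 %
#' eliminates contamination by 10-15 min while hydrogen peroxide alone
#' never drops below ~73 %.
#'
#' @param path Optional path to an alternative experiment CSV; defaults to
#'   the packaged trial.
#' @return A data frame with columns `naocl`, `h2o2`, `time`, `mean`, `se`
#'   and attributes `n_reps` (3) and `seeds_per_rep` (5).
#' @examples
#' trial <- disinfection_trial()
#' nrow(trial) # 19 treatments
#' @export
disinfection_trial <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cannabis_disinfection.csv",
                        package = "disinfectr", mustWork = TRUE)
  }
  tab <- read_experiment_csv(path)
  attr(tab, "n_reps") <- 3L
  attr(tab, "seeds_per_rep") <- 5L
  tab
}

# all multisets of `k` values drawn from `levels`, one per row, ascending
# within each row; 56 rows for k = 3 over 6 contamination levels
replicate_multisets <- function(levels, k) {
  g <- do.call(expand.grid, rep(list(levels), k))
  g <- as.matrix(g[do.call(order, as.data.frame(g)), , drop = FALSE])
  keep <- rowSums(g[, -1, drop = FALSE] >= g[, -k, drop = FALSE]) == k - 1L
  m <- unique(g[keep, , drop = FALSE])
  dimnames(m) <- NULL
  m
}

#' Reconstruct replicate observations from a printed mean and SE
#'
#' Individual replicates of a contamination assay with `seeds_per_rep`
#' seeds can only take values that are multiples of `100 / seeds_per_rep`.
#' This makes the published per-treatment mean (1 decimal) and standard
#' error (2 decimals) invertible in practice: the function enumerates every
#' multiset of `n_reps` admissible values and returns the one whose mean
#' and SE (sample SD with the n-1 divisor, divided by sqrt(n_reps)) match
#' the printed pair to within half a unit of the printed precision.
#'
#' @param mean Printed mean contamination percentage (1 decimal).
#' @param se Printed standard error (2 decimals).
#' @param n_reps Number of replicates behind the summary (default 3).
#' @param seeds_per_rep Seeds per replicate (default 5).
#' @param tol_mean Matching half-width for the mean (default 0.05, half a
#'   unit in the last printed digit).
#' @param tol_se Matching half-width for the SE (default 0.005).
#' @return A numeric vector of `n_reps` contamination percentages
#'   (ascending).
#' @section Errors: Throws a condition of class `disinfectr_no_solution`
#'   when no multiset matches, and `disinfectr_ambiguous` (with all
#'   candidate multisets attached as the `candidates` field) when more
#'   than one does.
#' @examples
#' reconstruct_replicates(53.3, 17.64) # 20 60 80
#' reconstruct_replicates(80.0, 11.55) # 60 80 100
#' @export
reconstruct_replicates <- function(mean, se, n_reps = 3L, seeds_per_rep = 5L,
                                   tol_mean = 0.05, tol_se = 0.005) {
  stopifnot(length(mean) == 1L, length(se) == 1L, is.finite(mean),
            is.finite(se), se >= 0, mean >= 0, mean <= 100,
            n_reps >= 2L, seeds_per_rep >= 1L)
  levels <- seq(0, 100, by = 100 / seeds_per_rep)
  cand <- replicate_multisets(levels, n_reps)
  means <- rowMeans(cand)
  ses <- apply(cand, 1L, stats::sd) / sqrt(n_reps)
  hit <- abs(means - mean) <= tol_mean & abs(ses - se) <= tol_se
  found <- cand[hit, , drop = FALSE]
  if (nrow(found) == 0L) {
    stop(structure(
      class = c("disinfectr_no_solution", "error", "condition"),
      list(message = sprintf(
        "no replicate multiset reproduces mean %.1f with SE %.2f", mean, se),
        call = sys.call())))
  }
  if (nrow(found) > 1L) {
    stop(structure(
      class = c("disinfectr_ambiguous", "error", "condition"),
      list(message = sprintf(
        "%d replicate multisets reproduce mean %.1f with SE %.2f: %s",
        nrow(found), mean, se,
        paste(apply(found, 1L, paste, collapse = "/"), collapse = "; ")),
        call = sys.call(), candidates = found)))
  }
  as.numeric(found[1L, ])
}

#' Expand a summary table into replicate-level observations
#'
#' Applies [reconstruct_replicates()] to every row of an experiment table,
#' yielding the long replicate-level data the kernel regression is fitted
#' on (19 x 3 = 57 rows for the packaged trial).
#'
#' @param table An experiment table as returned by [disinfection_trial()]
#'   or [read_experiment_csv()].
#' @param n_reps,seeds_per_rep Replication structure (defaults taken from
#'   the table's attributes, falling back to 3 and 5).
#' @return A data frame with columns `naocl`, `h2o2`, `time`, `rep`,
#'   `contamination`.
#' @export
expand_replicates <- function(table,
                              n_reps = attr(table, "n_reps"),
                              seeds_per_rep = attr(table, "seeds_per_rep")) {
  if (is.null(n_reps)) n_reps <- 3L
  if (is.null(seeds_per_rep)) seeds_per_rep <- 5L
  validate_experiment_table(table)
  out <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    reps <- tryCatch(
      reconstruct_replicates(table$mean[i], table$se[i],
                             n_reps = n_reps, seeds_per_rep = seeds_per_rep),
      error = function(e) {
        stop(sprintf(
          "reconstruction failed for treatment (naocl=%g, h2o2=%g, time=%g): %s",
          table$naocl[i], table$h2o2[i], table$time[i], conditionMessage(e)),
          call. = FALSE)
      })
    out[[i]] <- data.frame(
      naocl = table$naocl[i], h2o2 = table$h2o2[i], time = table$time[i],
      rep = seq_len(n_reps), contamination = reps)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stratified train/test split of replicate observations
#'
#' Standard proportional stratified holdout: `round(n * test_fraction)`
#' observations go to the test set, allocated across treatments in
#' proportion to their replicate counts, with the constraint that every
#' treatment keeps at least one replicate in training (so the kernel
#' regression never extrapolates to a treatment it has never seen).
#' Deterministic for a fixed seed. When every treatment has a single
#' observation (mean-level modeling) stratification is vacuous and the
#' split degrades to simple random sampling.
#'
#' @param observations Replicate-level data frame from
#'   [expand_replicates()] (columns `naocl`, `h2o2`, `time`,
#'   `contamination`).
#' @param test_fraction Proportion held out, strictly between 0 and 1
#'   (default 0.2).
#' @param seed Integer seed.
#' @return A list with data frames `train` and `test` (disjoint, union =
#'   input) and the `seed` used.
#' @export
split_replicates <- function(observations, test_fraction = 0.2, seed = 1L) {
  if (!is.numeric(test_fraction) || length(test_fraction) != 1L ||
      !is.finite(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  n <- nrow(observations)
  if (n < 2L) stop("need at least 2 observations to split")
  trt <- interaction(observations$naocl, observations$h2o2,
                     observations$time, drop = TRUE)
  strata <- split(seq_len(n), trt)
  k <- round(n * test_fraction)
  capacity <- vapply(strata, length, 1L) - 1L
  if (all(capacity == 0L)) {
    # singleton strata: stratification is vacuous, fall back to SRS
    if (k >= n) {
      stop(sprintf("test_fraction %.2f would hold out every observation",
                   test_fraction))
    }
    test_idx <- sort(with_seed(seed, sample.int(n, k)))
    return(list(
      train = observations[setdiff(seq_len(n), test_idx), , drop = FALSE],
      test = observations[test_idx, , drop = FALSE],
      seed = seed))
  }
  if (k > sum(capacity)) {
    stop(sprintf(
      "test_fraction %.2f would empty some treatments from training (max holdout %d of %d)",
      test_fraction, sum(capacity), n))
  }
  test_idx <- with_seed(seed, {
    alloc <- pmin(vapply(strata, function(s) floor(test_fraction * length(s)),
                         1), capacity)
    room <- capacity - alloc
    while (sum(alloc) < k) {
      open <- which(room > 0)
      take <- if (length(open) <= k - sum(alloc)) open else
        sample(open, k - sum(alloc))
      alloc[take] <- alloc[take] + 1
      room[take] <- room[take] - 1
    }
    unlist(mapply(function(s, a) {
      if (a > 0) sample(s, a) else integer(0)
    }, strata, alloc, SIMPLIFY = FALSE), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  list(train = observations[setdiff(seq_len(n), test_idx), , drop = FALSE],
       test = observations[test_idx, , drop = FALSE],
       seed = seed)
}

validate_experiment_table <- function(table) {
  required <- c("naocl", "h2o2", "time", "mean", "se")
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    stop("experiment table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in required) {
    if (!is.numeric(table[[col]])) {
      stop(sprintf("column '%s' must be numeric", col))
    }
    bad <- which(!is.finite(table[[col]]))
    if (length(bad)) {
      stop(sprintf("column '%s' has non-numeric or missing cells at row(s) %s",
                   col, paste(bad, collapse = ", ")))
    }
  }
  neg <- which(table$naocl < 0 | table$h2o2 < 0 | table$time < 0)
  if (length(neg)) {
    stop("negative concentration or time at row(s) ",
         paste(neg, collapse = ", "))
  }
  bad_mean <- which(table$mean < 0 | table$mean > 100)
  if (length(bad_mean)) {
    stop("mean contamination outside [0, 100] at row(s) ",
         paste(bad_mean, collapse = ", "))
  }
  bad_se <- which(table$se < 0)
  if (length(bad_se)) {
    stop("negative SE at row(s) ", paste(bad_se, collapse = ", "))
  }
  key <- paste(table$naocl, table$h2o2, table$time)
  if (anyDuplicated(key)) {
    stop("duplicate treatment(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  invisible(table)
}

#' Read / write an experiment summary CSV
#'
#' Plain UTF-8 comma-separated files with header columns `naocl`, `h2o2`,
#' `time`, `mean`, `se`. Reading validates the schema (missing columns,
#' non-numeric cells, negative values and duplicate treatments are each
#' reported by name/row); writing then reading reproduces the table.
#'
#' @param path File path.
#' @return `read_experiment_csv()` returns a validated experiment data
#'   frame; `write_experiment_csv()` returns `path` invisibly.
#' @export
read_experiment_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_experiment_table(tab)
  tab[, c("naocl", "h2o2", "time", "mean", "se")]
}

#' @rdname read_experiment_csv
#' @param table An experiment table (validated before writing).
#' @export
write_experiment_csv <- function(table, path) {
  validate_experiment_table(table)
  utils::write.csv(table[, c("naocl", "h2o2", "time", "mean", "se")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
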