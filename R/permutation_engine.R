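#' Data-stream randomisation of group membership
#'
#' Permutes individual identities uniformly at random across the group
#' slots of each sampling period, leaving the number of groups, group
#' sizes, and the set of individuals observed in every period unchanged:
#' the null retains the original sampling pattern of the data and only
#' breaks who-was-with-whom within periods.
#'
#' @param groups long group-membership table from [assign_groups_all()].
#' @return table of the same shape with identities (and their attached
#'   sex labels) shuffled within periods.
#' @export
datastream_randomise <- function(groups) {
  out <- groups
  idx <- split(seq_len(nrow(groups)), groups$period_id)
  has_sex <- "sex" %in% names(groups)
  for (i in idx) {
    if (length(i) > 1L) {
      perm <- sample.int(length(i))
      out$individual_id[i] <- groups$individual_id[i][perm]
      if (has_sex) out$sex[i] <- groups$sex[i][perm]
    }
  }
  out
}

#' Habitat-constrained randomisation of mate identities
#'
#' Permutes female identities among breeding pairs within each stratum
#' (breeding season, or breeding season crossed with nesting habitat),
#' keeping male identities, strata and the number of pairs per stratum
#' fixed. Which sex is permuted is arbitrary; results are invariant to the
#' choice.
#'
#' @param pairs data.frame with `male_id`, `female_id` and the stratum
#'   columns.
#' @param stratum character vector of stratum column names
#'   (default `"year"`; use `c("year", "habitat")` for habitat-constrained
#'   randomisation).
#' @return pairs table with `female_id` permuted within strata.
#' @export
mate_randomise <- function(pairs, stratum = "year") {
  out <- pairs
  key <- interaction(pairs[, stratum, drop = FALSE], drop = TRUE)
  for (i in split(seq_len(nrow(pairs)), key)) {
    if (length(i) > 1L) {
      out$female_id[i] <- pairs$female_id[i][sample.int(length(i))]
    }
  }
  out
}

#' Habitat-constrained randomisation of nest location and timing
#'
#' Jointly permutes the tuples (x, y, laid date, incubation end) among the
#' nests of each stratum (breeding season crossed with habitat by
#' default), keeping pair identities, success and strata attached to their
#' original rows. Conserves the within-stratum multisets of locations and
#' incubation intervals, hence all within-stratum pairwise distances.
#'
#' @param nests nests table.
#' @param stratum character vector of stratum column names
#'   (default `c("year", "habitat")`).
#' @return nests table with location/timing tuples permuted within strata.
#' @export
nest_randomise <- function(nests, stratum = c("year", "habitat")) {
  out <- nests
  cols <- c("x", "y", "laid_date", "incubation_end")
  key <- interaction(nests[, stratum, drop = FALSE], drop = TRUE)
  for (i in split(seq_len(nrow(nests)), key)) {
    if (length(i) > 1L) {
      perm <- i[sample.int(length(i))]
      out[i, cols] <- nests[perm, cols]
    }
  }
  out
}

#' Two-tailed permutation p-value
#'
#' One-tailed fractions include the observed value in both numerator and
#' denominator: p_up = (1 + #\{null >= obs\}) / (n + 1) and p_down likewise
#' with <=. The default two-tailed rule doubles the smaller tail and caps
#' at 1; the alternative `"deviation"` rule measures extremity as absolute
#' deviation from the null mean. Permutation p-values are never 0.
#'
#' @param observed finite scalar statistic.
#' @param null_values numeric vector of null statistics (non-empty).
#' @param method `"doubled"` (default) or `"deviation"`.
#' @return p-value in (0, 1\].
#' @export
pvalue_two_tailed <- function(observed, null_values,
                              method = c("doubled", "deviation")) {
  method <- match.arg(method)
  if (!is.finite(observed)) stop("observed statistic is not finite")
  null_values <- null_values[is.finite(null_values)]
  n <- length(null_values)
  if (n == 0L) stop("empty null distribution")
  if (method == "doubled") {
    p_up <- (1 + sum(null_values >= observed)) / (n + 1)
    p_down <- (1 + sum(null_values <= observed)) / (n + 1)
    min(1, 2 * min(p_up, p_down))
  } else {
    centre <- mean(null_values)
    (1 + sum(abs(null_values - centre) >= abs(observed - centre))) / (n + 1)
  }
}

#' Run a permutation test around an arbitrary statistic
#'
#' Recomputes `statistic_fn` on `n_perm` independently randomised copies of
#' `data` produced by `randomiser`, and compares the observed statistic to
#' the null distribution with [pvalue_two_tailed()]. Each replicate runs
#' under its own RNG substream derived from `seed`, so results are
#' reproducible and independent of execution order. Replicates on which
#' the statistic fails (e.g. a model fit error) are dropped and counted;
#' more than `max_fail_frac` failures aborts the test.
#'
#' @param statistic_fn function(data) -> finite scalar.
#' @param randomiser function(data) -> randomised data.
#' @param data input data object.
#' @param n_perm number of randomisations (default 10000).
#' @param seed integer seed.
#' @param method two-tailed rule, see [pvalue_two_tailed()].
#' @param max_fail_frac maximum tolerated fraction of failed replicates.
#' @param statistic_name label stored in the result.
#' @return object of class `permutation_result`: `statistic_name`,
#'   `observed`, `null_values`, `n_perm`, `n_failed`, `p_two_tailed`,
#'   `seed`, `method`.
#' @export
run_permutation_test <- function(statistic_fn, randomiser, data,
                                 n_perm = 10000, seed = 1,
                                 method = c("doubled", "deviation"),
                                 max_fail_frac = 0.1,
                                 statistic_name = "statistic") {
  method <- match.arg(method)
  observed <- statistic_fn(data)
  if (!is.finite(observed)) stop("observed statistic is not finite")
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, n_perm)
  nulls <- vapply(seq_len(n_perm), function(i) {
    set.seed(rep_seeds[i])
    tryCatch(statistic_fn(randomiser(data)),
             error = function(e) NA_real_)
  }, numeric(1))
  n_failed <- sum(!is.finite(nulls))
  if (n_failed > max_fail_frac * n_perm) {
    stop(sprintf("%d of %d permutation replicates failed; null unreliable",
                 n_failed, n_perm))
  }
  if (n_failed > 0L) {
    message(n_failed, " of ", n_perm,
            " permutation replicates failed and were dropped")
  }
  nulls <- nulls[is.finite(nulls)]
  structure(list(
    statistic_name = statistic_name,
    observed = observed,
    null_values = nulls,
    n_perm = n_perm,
    n_failed = n_failed,
    p_two_tailed = pvalue_two_tailed(observed, nulls, method),
    seed = seed,
    method = method
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: %s = %.4g, %d randomisations (%d failed), p = %.4g\n",
    x$statistic_name, x$observed, x$n_perm, x$n_failed, x$p_two_tailed))
  invisible(x)
}
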