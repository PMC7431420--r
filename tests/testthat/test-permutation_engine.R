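test_that("data-stream randomisation preserves the sampling pattern", {
  per <- function(p, ids, grp) data.frame(
    period_id = p, individual_id = ids,
    sex = c("M", "F", "M")[seq_along(ids)],
    group = paste0(p, ":", grp), stringsAsFactors = FALSE)
  g <- rbind(per("p1", c("A", "B", "C"), c(1, 1, 2)),
             per("p2", c("A", "B"), c(1, 1)),
             per("p3", "C", 1))
  set.seed(1)
  for (i in 1:50) {
    r <- datastream_randomise(g)
    # same individuals per period
    expect_setequal(r$individual_id[r$period_id == "p1"], c("A", "B", "C"))
    # group sizes per period unchanged
    expect_identical(table(r$group), table(g$group))
    # per-period sighting counts per individual unchanged
    expect_identical(table(r$period_id), table(g$period_id))
    # singleton period unchanged
    expect_identical(r[r$period_id == "p3", "individual_id"], "C")
    # sex labels move with identities
    expect_identical(r$sex[match("A", r$individual_id)], "M")
  }
})

test_that("who-is-alone is uniform under data-stream randomisation", {
  # one period, groups of sizes {2,1}: each bird is the singleton 1/3 of
  # the time (exact enumeration of labellings)
  g <- data.frame(period_id = "p1", individual_id = c("A", "B", "C"),
                  sex = "M", group = c("p1:1", "p1:1", "p1:2"),
                  stringsAsFactors = FALSE)
  set.seed(42)
  alone <- replicate(6000, {
    r <- datastream_randomise(g)
    r$individual_id[r$group == "p1:2"]
  })
  freq <- table(alone) / 6000
  expect_true(all(abs(freq - 1 / 3) < 0.025))
})

test_that("mate randomisation permutes females within strata only", {
  pairs <- data.frame(
    male_id = paste0("M", 1:6), female_id = paste0("F", 1:6),
    year = c(2015L, 2015L, 2015L, 2016L, 2016L, 2016L),
    habitat = c("s", "s", "g", "s", "g", "g"), stringsAsFactors = FALSE)
  set.seed(2)
  for (i in 1:30) {
    r <- mate_randomise(pairs, stratum = "year")
    expect_identical(r$male_id, pairs$male_id)
    expect_identical(r$year, pairs$year)
    # multiset of (female, stratum) preserved
    expect_setequal(r$female_id[r$year == 2015L], c("F1", "F2", "F3"))
    expect_setequal(r$female_id[r$year == 2016L], c("F4", "F5", "F6"))
  }
  # habitat-constrained: females never cross habitat strata
  for (i in 1:30) {
    r <- mate_randomise(pairs, stratum = c("year", "habitat"))
    expect_setequal(r$female_id[r$year == 2015L & r$habitat == "s"],
                    c("F1", "F2"))
    expect_identical(r$female_id[r$year == 2015L & r$habitat == "g"], "F3")
  }
  # single-pair stratum is an identity permutation
  one <- pairs[3, ]
  expect_identical(mate_randomise(one, "year"), one)
  # two pairs in one stratum swap about half the time (binomial oracle)
  two <- pairs[1:2, ]
  set.seed(3)
  swaps <- sum(replicate(1000, mate_randomise(two, "year")$female_id[1]) ==
                 "F2")
  expect_gt(swaps, 500 - 4 * sqrt(250))
  expect_lt(swaps, 500 + 4 * sqrt(250))
})

test_that("nest randomisation permutes location-timing tuples within strata", {
  nests <- demo_nests()
  set.seed(4)
  for (i in 1:50) {
    r <- nest_randomise(nests)
    # pair identities and success stay on their rows
    expect_identical(r$male_id, nests$male_id)
    expect_identical(r$success, nests$success)
    # tuples never cross year x habitat strata
    key <- paste(nests$year, nests$habitat)
    for (k in unique(key)) {
      got <- sort(paste(r$x[key == k], r$laid_date[key == k]))
      want <- sort(paste(nests$x[key == k], nests$laid_date[key == k]))
      expect_identical(got, want)
    }
    # within-stratum pairwise distance multiset is conserved
    for (k in unique(key)) {
      i_k <- which(key == k)
      if (length(i_k) >= 2) {
        d0 <- sort(as.numeric(dist(cbind(nests$x[i_k], nests$y[i_k]))))
        d1 <- sort(as.numeric(dist(cbind(r$x[i_k], r$y[i_k]))))
        expect_equal(d0, d1)
      }
    }
  }
  # stratum of size one is unchanged
  single <- nests[3, ]
  expect_identical(nest_randomise(single), single)
})

test_that("two-tailed permutation p-values follow the inclusion formula", {
  # observed above all 9,999 nulls
  expect_equal(pvalue_two_tailed(1e5, seq_len(9999)), 2e-04)
  # observed equal to every null: capped at 1
  expect_equal(pvalue_two_tailed(5, rep(5, 100)), 1)
  # hand count, nulls {-2,-1,0,1,2}, observed 2:
  # p_up = (1 + #{null >= 2})/6 = 2/6, p_down = 1, doubled = 2/3
  expect_equal(pvalue_two_tailed(2, c(-2, -1, 0, 1, 2)), 2 / 3)
  # and observed 3 beyond all nulls: p_up = 1/6, doubled = 1/3
  expect_equal(pvalue_two_tailed(3, c(-2, -1, 0, 1, 2)), 1 / 3)
  # deviation-from-centre alternative
  expect_equal(pvalue_two_tailed(3, c(-2, -1, 0, 1, 2),
                                 method = "deviation"), 1 / 6)
  expect_error(pvalue_two_tailed(NaN, 1:5), "finite")
  # p is never zero
  expect_gt(pvalue_two_tailed(1e6, rnorm(1000)), 0)
})

test_that("p-values are super-uniform when the observed value is null", {
  set.seed(5)
  p <- replicate(400, {
    null <- rnorm(99)
    pvalue_two_tailed(rnorm(1), null)
  })
  expect_lt(mean(p <= 0.05), 0.09)
  expect_lt(mean(p <= 0.2), 0.26)
})

test_that("run_permutation_test is reproducible and handles failures", {
  g <- data.frame(period_id = rep(c("p1", "p2"), each = 3),
                  individual_id = c("A", "B", "C", "A", "B", "D"),
                  sex = "M",
                  group = c("p1:1", "p1:1", "p1:2", "p2:1", "p2:2", "p2:2"),
                  stringsAsFactors = FALSE)
  stat <- function(d) compute_sri(d, "A", "B")
  r1 <- run_permutation_test(stat, datastream_randomise, g,
                             n_perm = 200, seed = 9)
  r2 <- run_permutation_test(stat, datastream_randomise, g,
                             n_perm = 200, seed = 9)
  expect_identical(r1$null_values, r2$null_values)
  expect_identical(r1$p_two_tailed, r2$p_two_tailed)
  expect_equal(length(r1$null_values), 200L)

  # constant statistic: p = 1
  rconst <- run_permutation_test(function(d) 1, datastream_randomise, g,
                                 n_perm = 50, seed = 1)
  expect_equal(rconst$p_two_tailed, 1)

  # too many failing replicates aborts
  flaky <- local({
    k <- 0
    function(d) {
      k <<- k + 1
      if (k > 1) stop("boom") else 0.5
    }
  })
  expect_error(
    run_permutation_test(flaky, datastream_randomise, g,
                         n_perm = 20, seed = 1),
    "unreliable")
})
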