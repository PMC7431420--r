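test_that("duplicate within-period sightings collapse to the mean position", {
  s <- make_sightings(c("A", "A", "B"), c("p1", "p1", "p1"),
                      x = c(0, 10, 5), y = c(0, 0, 5))
  d <- deduplicate_sightings(s)
  expect_equal(nrow(d), 2L)
  expect_equal(d$x[d$individual_id == "A"], 5)
  expect_equal(d$y[d$individual_id == "A"], 0)

  # no duplicates: identity
  s2 <- make_sightings(c("A", "B"), c("p1", "p1"), x = c(0, 1), y = c(0, 1))
  expect_identical(deduplicate_sightings(s2), s2)

  # conflicting sexes are a hard error naming the bird
  s3 <- make_sightings(c("A", "A"), c("p1", "p2"), x = c(0, 0), y = c(0, 0),
                       sex = c("M", "F"))
  expect_error(deduplicate_sightings(s3), "A")
})

test_that("pre-breeding filter honours the exclusion window and variants", {
  season <- data.frame(year = 2015L,
                       season_start = as.Date("2015-08-01"))
  dates <- as.Date("2015-08-01") - c(13, 14, 15, 40)
  s <- make_sightings(paste0("B", 1:4), paste0("p", 1:4),
                      x = 1:4, y = 1:4, date = dates)
  kept <- filter_prebreeding(s, season, exclusion_days = 14)
  expect_setequal(kept$individual_id, c("B3", "B4"))  # 15 and 40 days out

  kept30 <- filter_prebreeding(s, season, exclusion_days = 30)
  expect_setequal(kept30$individual_id, "B4")

  # drop-May removes exactly the May rows (set-difference oracle)
  dates2 <- as.Date(c("2015-03-10", "2015-05-02", "2015-05-30", "2015-06-15"))
  s2 <- make_sightings(paste0("C", 1:4), paste0("q", 1:4),
                       x = 1:4, y = 1:4, date = dates2)
  base <- filter_prebreeding(s2, season, exclusion_days = 14)
  nomay <- filter_prebreeding(s2, season, exclusion_days = 14,
                              drop_may = TRUE)
  oracle <- base[format(base$date, "%m") != "05", ]
  expect_equal(nomay$individual_id, oracle$individual_id)

  expect_error(filter_prebreeding(s, data.frame(year = 2016L,
                                                season_start = dates[1])),
               "2015")
})

test_that("chain-rule grouping joins chains and splits distant birds", {
  # two birds 25 m apart form two groups
  s <- make_sightings(c("A", "B"), "p1", x = c(0, 25), y = c(0, 0))
  expect_equal(length(unique(assign_groups(s)$group)), 2L)

  # 0,15,30: chained through the middle bird despite 30 m ends
  s2 <- make_sightings(c("A", "B", "C"), "p1", x = c(0, 15, 30), y = 0)
  expect_equal(length(unique(assign_groups(s2)$group)), 1L)

  # single bird: singleton group
  s3 <- make_sightings("A", "p1", x = 0, y = 0)
  expect_equal(assign_groups(s3)$group, 1L)

  # boundary is inclusive at exactly 20 m
  s4 <- make_sightings(c("A", "B"), "p1", x = c(0, 20), y = 0)
  expect_equal(length(unique(assign_groups(s4)$group)), 1L)
})

test_that("grouping equals the brute-force chain oracle on random instances", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(2:50, 1)
    x <- runif(n, 0, 120); y <- runif(n, 0, 120)
    s <- make_sightings(sprintf("B%02d", seq_len(n)), "p1", x = x, y = y)
    got <- assign_groups(s)$group
    want <- bruteforce_chain_groups(x, y, 20)
    # same partition: equal label co-membership matrices
    expect_identical(outer(got, got, "=="), outer(want, want, "=="))
  }
})

test_that("SRI follows the simple ratio formula", {
  # together in all 5 periods -> 1
  g1 <- data.frame(period_id = rep(paste0("p", 1:5), each = 2),
                   individual_id = rep(c("A", "B"), 5),
                   sex = rep(c("M", "F"), 5),
                   group = rep(paste0("p", 1:5, ":1"), each = 2),
                   stringsAsFactors = FALSE)
  expect_equal(compute_sri(g1, "A", "B"), 1)

  # x=2, y_AB=1, y_A=3, y_B=2 -> 2/8
  per <- function(p, ids, grp) data.frame(period_id = p,
                                          individual_id = ids,
                                          sex = "M", group = paste0(p, ":", grp),
                                          stringsAsFactors = FALSE)
  g2 <- rbind(per("p1", c("A", "B"), c(1, 1)), per("p2", c("A", "B"), c(1, 1)),
              per("p3", c("A", "B"), c(1, 2)),
              per("p4", "A", 1), per("p5", "A", 1), per("p6", "A", 1),
              per("p7", "B", 1), per("p8", "B", 1))
  expect_equal(compute_sri(g2, "A", "B"), 0.25)
  # symmetric
  expect_equal(compute_sri(g2, "B", "A"), 0.25)
  # never together with sightings of A only -> 0
  g3 <- rbind(per("p1", "A", 1), per("p2", "A", 1), per("p3", "A", 1),
              per("p4", "A", 1), per("p5", "B", 1))
  expect_equal(compute_sri(g3, "A", "B"), 0)
  # dyad never observed -> 0 (zero denominator)
  expect_equal(compute_sri(g3[0, ], "A", "B"), 0)

  # matrix route agrees with the per-dyad count route
  S <- sri_matrix(g2)
  expect_equal(S["A", "B"], 0.25)
  expect_equal(S, t(S))

  # adding a period where neither bird is seen leaves the dyad unchanged
  g4 <- rbind(g2, per("p9", "C", 1))
  expect_equal(compute_sri(g4, "A", "B"), 0.25)
})

test_that("SRI matrix agrees with per-dyad counting on random streams", {
  set.seed(7)
  ids <- sprintf("B%02d", 1:8)
  per <- lapply(1:30, function(p) {
    k <- sample(0:5, 1)
    if (k == 0) return(NULL)
    who <- sample(ids, k)
    data.frame(period_id = paste0("p", p), individual_id = who, sex = "M",
               group = paste0("p", p, ":", sample(1:2, k, replace = TRUE)),
               stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, per)
  S <- sri_matrix(g, ids)
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(S[ids[i], ids[j]], compute_sri(g, ids[i], ids[j]))
  }
  expect_true(all(S >= 0 & S <= 1))
})

test_that("network density and node metrics follow their definitions", {
  # 4 birds always co-grouped -> density 1
  s <- make_sightings(rep(c("A", "B", "C", "D"), 3),
                      rep(paste0("p", 1:3), each = 4),
                      x = rep(c(0, 5, 10, 15), 3), y = 0)
  nw <- build_network(s, 2015L)
  expect_equal(network_density(nw), 1)

  # hand-built network: edges 0.5 (to male) and 0.25 (to female)
  per <- function(p, ids, grp, sex) data.frame(
    period_id = p, individual_id = ids, sex = sex,
    group = paste0(p, ":", grp), stringsAsFactors = FALSE)
  # X seen in all 8 periods: with M1 co-grouped in 4 of 8 (SRI 0.5) and
  # with F1 co-grouped in 2 of 8 (SRI 0.25)
  g <- rbind(
    per("p1", c("X", "M1"), c(1, 1), c("F", "M")),
    per("p2", c("X", "M1"), c(1, 1), c("F", "M")),
    per("p3", c("X", "M1"), c(1, 1), c("F", "M")),
    per("p4", c("X", "M1"), c(1, 1), c("F", "M")),
    per("p5", c("X", "F1"), c(1, 1), c("F", "F")),
    per("p6", c("X", "F1"), c(1, 1), c("F", "F")),
    per("p7", c("X", "F1"), c(1, 2), c("F", "F")),
    per("p8", c("X", "F1"), c(1, 2), c("F", "F"))
  )
  nw2 <- network_from_groups(g, 2015L)
  expect_equal(nw2$sri["X", "M1"], 0.5)
  expect_equal(nw2$sri["X", "F1"], 0.25)
  m <- node_metrics(nw2)
  xrow <- m[m$individual_id == "X", ]
  expect_equal(xrow$degree, 2L)
  expect_equal(xrow$strength, 0.75)
  expect_equal(xrow$prop_male_associates, 0.5)

  # isolated node: degree 0, strength 0, prop_male undefined
  g_iso <- rbind(g, per("p9", "LONER", 1, "M"))
  m2 <- node_metrics(network_from_groups(g_iso, 2015L))
  lrow <- m2[m2$individual_id == "LONER", ]
  expect_equal(lrow$degree, 0L)
  expect_equal(lrow$strength, 0)
  expect_true(is.na(lrow$prop_male_associates))

  # sum of degrees = 2 x edge count; density matches the formula
  e <- network_edges(nw2)
  expect_equal(sum(m$degree), 2L * nrow(e))
  expect_equal(network_density(nw2),
               2 * nrow(e) / (nrow(nw2$nodes) * (nrow(nw2$nodes) - 1)))
})
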