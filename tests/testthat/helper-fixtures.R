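# Constructed fixtures and independent oracles shared across test files.

# minimal sightings table; positions and periods fully specified by caller
make_sightings <- function(ids, periods, x, y,
                           sex = NULL, date = as.Date("2015-03-01"),
                           habitat = "saltmarsh", year = 2015L) {
  if (is.null(sex)) {
    sex <- ifelse(as.integer(factor(ids)) %% 2L == 1L, "M", "F")
  }
  data.frame(individual_id = ids, sex = sex, date = date,
             period_id = periods, x = x, y = y, habitat = habitat,
             year = year, stringsAsFactors = FALSE)
}

make_nest <- function(nest_id, male_id, female_id, x, y, habitat,
                      laid, end, success, year) {
  data.frame(nest_id = nest_id, male_id = male_id, female_id = female_id,
             x = x, y = y, habitat = habitat,
             laid_date = as.Date(laid), incubation_end = as.Date(end),
             success = success, year = year, stringsAsFactors = FALSE)
}

# brute-force chain-rule oracle: repeatedly merge any two clusters that
# contain a pair of points within the threshold
bruteforce_chain_groups <- function(x, y, chain = 20) {
  n <- length(x)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (grp[i] != grp[j] &&
          sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= chain) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

# day-set oracle for interval overlap
dayset_overlap <- function(s1, e1, s2, e2) {
  length(intersect(seq(as.Date(s1), as.Date(e1), by = "day"),
                   seq(as.Date(s2), as.Date(e2), by = "day"))) > 0
}

# a small deterministic multi-year nests table used in several files
demo_nests <- function() {
  rbind(
    make_nest("N1", "M1", "F1", 0, 0, "saltmarsh",
              "2015-09-01", "2015-09-27", TRUE, 2015L),
    make_nest("N2", "M2", "F2", 50, 0, "saltmarsh",
              "2015-09-10", "2015-10-06", FALSE, 2015L),
    make_nest("N3", "M3", "F3", 150, 0, "grassland",
              "2015-09-20", "2015-10-16", TRUE, 2015L),
    make_nest("N4", "M1", "F1", 30, 40, "saltmarsh",
              "2016-09-05", "2016-10-01", TRUE, 2016L),
    make_nest("N5", "M2", "F2", 500, 0, "grassland",
              "2016-09-05", "2016-10-01", TRUE, 2016L),
    make_nest("N6", "M3", "F3", 160, 10, "grassland",
              "2016-10-20", "2016-11-15", FALSE, 2016L)
  )
}
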