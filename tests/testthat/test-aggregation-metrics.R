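test_that("population profiles are normalised percentages", {
  p <- population_profile(make_series(rep(1, 40), 11))
  expect_equal(as.numeric(p[1]), 100)
  expect_equal(sum(p), 100)
  p2 <- population_profile(make_series(c(3, 7), 11))
  expect_equal(as.numeric(p2[c(3, 7)]), c(50, 50))
  expect_equal(sum(p2), 100)
  set.seed(5)
  for (i in 1:100) {
    nmol <- sample(5:23, 1)
    s <- make_series(sample(nmol, sample(10:500, 1), TRUE), nmol)
    expect_equal(sum(population_profile(s)), 100, tolerance = 1e-9)
  }
  expect_error(population_profile(make_series(integer(0), 11)), "empty")
})

test_that("fC_5 limits and strictness match the definition", {
  expect_equal(fraction_below(make_series(rep(1, 100), 11)), 100)   # one blob
  expect_equal(fraction_below(make_series(rep(11, 100), 11)), 0)    # dispersed
  # 1650 of 5000 frames below five clusters -> 33.0%
  s <- make_series(c(rep(4, 1650), rep(8, 3350)), 11)
  expect_equal(fraction_below(s), 33.0)
  # frames at exactly N_c = 5 are excluded (strict <)
  expect_equal(fraction_below(make_series(rep(5, 50), 11)), 0)
  expect_equal(fraction_below(make_series(c(rep(5, 30), rep(4, 10)), 11)), 25)
})

test_that("fraction_below is monotone in k with 0/100 endpoints", {
  set.seed(6)
  for (i in 1:20) {
    nmol <- sample(5:23, 1)
    s <- make_series(sample(nmol, 200, TRUE), nmol)
    fb <- sapply(1:(nmol + 1), function(k) fraction_below(s, k))
    expect_true(all(diff(fb) >= 0))
    expect_equal(fb[1], 0)
    expect_equal(fb[nmol + 1], 100)
    # permutation invariance over frames
    s2 <- make_series(sample(s$n_clusters), nmol)
    expect_equal(fraction_below(s2), fraction_below(s))
    expect_equal(as.numeric(population_profile(s2)),
                 as.numeric(population_profile(s)))
  }
})

test_that("classification separates observed aggregators from non-aggregators", {
  expect_equal(classify_aggregator(16), "non-aggregator")
  expect_equal(classify_aggregator(36), "aggregator")
  expect_equal(classify_aggregator(0), "non-aggregator")
  expect_equal(classify_aggregator(20), "aggregator")  # >= threshold
  # monotone in the threshold: raising it never creates an aggregator call
  fc5 <- seq(0, 100, by = 5)
  prev <- classify_aggregator(fc5, 0)
  for (th in seq(5, 100, by = 5)) {
    cur <- classify_aggregator(fc5, th)
    expect_true(all(!(prev == "non-aggregator" & cur == "aggregator")))
    prev <- cur
  }
})

test_that("profile shapes follow the band rule with exclusive bounds", {
  conc <- function(k, n) {
    p <- rep(0, n); p[k] <- 80; p[-k] <- 20 / (n - 1)
    structure(setNames(p, seq_len(n)), class = "population_profile")
  }
  expect_equal(profile_shape(conc(1, 12)), "aggregated-exponential")
  expect_equal(profile_shape(conc(12, 12)), "dispersed-exponential")
  expect_equal(profile_shape(conc(8, 12)), "bell")  # 8 of 12 is interior
  expect_equal(profile_shape(conc(3, 11)), "bell")  # peak ~3 of 11: bell
  expect_equal(profile_shape(conc(2, 11)), "aggregated-exponential")
  expect_equal(profile_shape(conc(10, 11)), "dispersed-exponential")
})

test_that("reports bundle metric, class and parameters", {
  s <- make_series(c(rep(1, 70), rep(9, 30)), 11)
  r <- aggregation_report(s, compound_id = "cmpd", cutoff = 3)
  expect_equal(r$fc5_percent, 70)
  expect_equal(r$class, "aggregator")
  expect_equal(r$n_frames, 100)
  expect_equal(r$shape, "aggregated-exponential")
  j <- file.path(tempdir(), "rep.json")
  write_report_json(r, j)
  back <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(back$fc5_percent, 70)
  expect_equal(back$class, "aggregator")
})

test_that("replicate summaries average fC_5 with sample standard deviation", {
  s1 <- make_series(c(rep(1, 92), rep(9, 8)), 11)
  s2 <- make_series(c(rep(1, 89), rep(9, 11)), 11)
  reps <- list(aggregation_report(s1, cutoff = 3),
               aggregation_report(s2, cutoff = 3))
  m <- replicate_summary(reps)
  expect_equal(m$fc5_percent, 90.5)     # replicas at 92% and 89%
  expect_equal(m$replicas, c(92, 89))
  expect_equal(m$fc5_sd, sd(c(92, 89)))
  expect_equal(m$class, "aggregator")
  # single replica: mean = value, sd absent
  one <- replicate_summary(reps[1])
  expect_equal(one$fc5_percent, 92)
  expect_true(is.na(one$fc5_sd))
  # degenerate all-zero replicas
  z <- make_series(rep(11, 10), 11)
  zr <- replicate_summary(replicate(3, aggregation_report(z, cutoff = 3),
                                    simplify = FALSE))
  expect_equal(zr$fc5_percent, 0)
  expect_equal(zr$fc5_sd, 0)
  # mixed parameters refuse to average
  bad <- aggregation_report(s2, cutoff = 5)
  expect_error(replicate_summary(list(reps[[1]], bad)), "parameters")
})
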