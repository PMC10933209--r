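fixture_table <- function() {
  read_compound_table(system.file("extdata", "compounds_synthetic.csv",
                                  package = "scamscreen"))
}

test_that("the compound table loads with validated columns", {
  tab <- fixture_table()
  expect_equal(nrow(tab), 32)
  expect_true(all(c("id", "logp", "logd", "vsurf_a", "tpsa", "label") %in%
                  names(tab)))
  expect_setequal(unique(tab$label), c("aggregator", "non-aggregator"))
  bad <- file.path(tempdir(), "bad.csv")
  writeLines("id,logp,label\n1,2.0,aggregator", bad)
  expect_error(read_compound_table(bad), "missing column")
  expect_error(read_compound_table(file.path(tempdir(), "absent.csv")),
               "does not exist")
})

test_that("the logD > 3 rule is strict and matches the known outcomes", {
  tab <- fixture_table()
  res <- threshold_classify(tab, "logd", 3)
  pred <- setNames(res$predictions$predicted, res$predictions$id)
  # ionisation-corrected hydrophobicity: logD 2.8 and 1.3 stay non-aggregators
  expect_equal(unname(pred["31"]), "non-aggregator")  # logD 2.8
  expect_equal(unname(pred["32"]), "non-aggregator")  # logD 1.3
  # a value exactly at the threshold is NOT called an aggregator
  tab3 <- data.frame(id = "x", logp = 3, logd = 3.0, vsurf_a = 1,
                     label = "aggregator")
  expect_equal(threshold_classify(tab3, "logd", 3)$predictions$predicted,
               "non-aggregator")
  expect_equal(threshold_classify(tab3, "logd", 3,
                                  inclusive = TRUE)$predictions$predicted,
               "aggregator")
  # on the shipped table the rule misses exactly three compounds
  expect_setequal(res$misclassified, c("11", "21", "23"))
  expect_equal(res$success_rate_percent, round(100 * 29 / 32, 1))
  expect_equal(sum(res$confusion), 32)
})

test_that("degenerate thresholds label everything one way", {
  tab <- fixture_table()
  all_agg <- threshold_classify(tab, "logd", min(tab$logd) - 1)
  expect_true(all(all_agg$predictions$predicted == "aggregator"))
  none <- threshold_classify(tab, "logd", max(tab$logd) + 1)
  expect_true(all(none$predictions$predicted == "non-aggregator"))
  expect_error(threshold_classify(tab, "melting_point", 3),
               "unknown descriptor")
  # records missing the descriptor are excluded and reported
  tab$logd[3] <- NA
  res <- threshold_classify(tab, "logd", 3)
  expect_equal(res$excluded, "3")
  expect_equal(nrow(res$predictions), 31)
})

test_that("success_rate reports one-decimal percentages and offender ids", {
  truth <- rep(c("aggregator", "non-aggregator"), each = 16)
  pred <- truth
  pred[5] <- "non-aggregator"
  sr <- success_rate(pred, truth, ids = as.character(1:32))
  expect_equal(sr$percent, 96.9)  # 31 of 32
  expect_equal(sr$misclassified, "5")
  expect_equal(success_rate(truth, truth)$percent, 100)
  expect_length(success_rate(truth, truth)$misclassified, 0)
  expect_equal(success_rate(pred[1:32 %% 4 != 0], truth[1:32 %% 4 != 0])$n, 24)
  sr75 <- success_rate(c(rep("a", 24), rep("b", 8)), rep("a", 32))
  expect_equal(sr75$percent, 75.0)
  expect_error(success_rate(pred[1:3], truth), "equal length")
  # symmetric under consistent relabelling of the classes
  flip <- function(x) ifelse(x == "aggregator", "non-aggregator", "aggregator")
  expect_equal(success_rate(flip(pred), flip(truth))$percent, sr$percent)
})

test_that("compare_methods builds an agreement table across methods", {
  tab <- fixture_table()
  truth <- setNames(tab$label, tab$id)
  screen <- threshold_classify(tab, "logd", 3)
  md_calls <- lapply(tab$id, function(id) {
    s <- make_series(if (truth[id] == "aggregator") rep(1, 10) else
                     rep(11, 10), 11)
    aggregation_report(s, compound_id = id, cutoff = 3)
  })
  names(md_calls) <- tab$id
  # flip one MD call so the methods disagree somewhere
  md_calls[["21"]]$class <- "aggregator"
  cmp <- compare_methods(md_calls, list(logd = screen), truth)
  expect_equal(unname(cmp$success["md"]), 96.9)
  expect_equal(unname(cmp$success["logd"]), 90.6)
  expect_equal(nrow(cmp$table), 32)
  # a compound absent from one method is marked not-scored
  cmp2 <- compare_methods(md_calls[1:31], list(logd = screen), truth)
  expect_equal(cmp2$table$md[cmp2$table$id == "32"], "not-scored")
  expect_error(compare_methods(md_calls, NULL,
                               setNames(rep("aggregator", 2),
                                        c("zz1", "zz2"))),
               "no shared compound ids")
  csv <- file.path(tempdir(), "cmp.csv")
  write_comparison_csv(cmp, csv)
  expect_equal(nrow(read.csv(csv)), 32)
})
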