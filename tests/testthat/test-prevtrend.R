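test_that("fixed-width epochs bin backwards from the anchor date", {
  sp <- epoch_spec("fixed_width", width_months = 6,
                   anchor_date = "2016-10-04")
  ep <- assign_epoch(as.Date(c("2016-09-01", "2016-03-01", "2016-10-04",
                               "2016-04-04", "2016-04-05")), sp)
  expect_equal(ep$epoch, c(0L, 1L, 0L, 1L, 0L))
  # epoch boundaries are half-open: (anchor - (e+1)w, anchor - e*w]
  expect_equal(assign_epoch(as.Date("2016-04-04"), sp)$epoch, 1L)
  expect_error(assign_epoch(as.Date("2016-11-01"), sp), "after the anchor")
})

test_that("month arithmetic clamps day-of-month", {
  sp <- epoch_spec("fixed_width", width_months = 6,
                   anchor_date = "2016-10-31")
  # Oct-31 minus 6 months is Apr-30: Apr-30 is the last day of epoch 1
  expect_equal(assign_epoch(as.Date("2016-04-30"), sp)$epoch, 1L)
  expect_equal(assign_epoch(as.Date("2016-05-01"), sp)$epoch, 0L)
})

test_that("quantile epochs split evenly and keep tied dates together", {
  sp <- epoch_spec("quantile", n_bins = 4)
  ep <- assign_epoch(as.Date("2016-01-01") + c(0, 10, 20, 30, 40, 50, 60, 70),
                     sp)
  expect_equal(as.integer(table(ep$epoch)), c(2L, 2L, 2L, 2L))
  expect_equal(ep$epoch, ep$epoch_index)  # oldest bin is index 0
  # ties crossing a boundary stay in one bin
  dates <- as.Date("2016-01-01") + c(0, 1, 2, 3, 3, 3, 4, 5)
  ep2 <- assign_epoch(dates, sp)
  per_date <- tapply(ep2$epoch, as.character(dates), function(x)
    length(unique(x)))
  expect_true(all(per_date == 1))
  expect_true(length(unique(table(ep2$epoch))) > 1)  # sizes now differ
})

test_that("epoch assignment partitions any corpus", {
  set.seed(101)
  for (rep in 1:20) {
    dates <- as.Date("2014-10-04") +
      sample(0:730, sample(5:60, 1), replace = TRUE)
    for (sp in list(epoch_spec("fixed_width", width_months = sample(1:9, 1),
                               anchor_date = "2016-10-04"),
                    epoch_spec("quantile", n_bins = sample(2:5, 1)))) {
      ep <- assign_epoch(dates, sp)
      expect_equal(nrow(ep), length(dates))
      expect_false(anyNA(ep$epoch))
      # dates in the same epoch share its label
      expect_true(all(tapply(ep$label, ep$epoch, function(x)
        length(unique(x))) == 1))
    }
  }
})

test_that("journal ranking filters small groups into a pooled 'other' row", {
  ids <- sprintf("d%02d", 1:13)
  journal <- c(rep("journal a", 10), rep("journal b", 3))
  corpus <- data.frame(doc_id = ids, text = "", journal = journal)
  calls <- data.frame(doc_id = ids, item = "blinding",
                      call = c(rep(TRUE, 6), rep(FALSE, 4), TRUE, FALSE,
                               FALSE),
                      n_matches = 0L, first_snippet = "")
  prev <- group_prevalence(calls, corpus, "journal", items = "blinding")
  expect_equal(prev$group_label, c("journal a", "other"))
  expect_equal(prev$k, c(6L, 1L))
  expect_equal(prev$n, c(10L, 3L))
  # conservation: ranked + pooled counts equal the corpus totals
  expect_equal(sum(prev$k), sum(calls$call))
  expect_equal(sum(prev$n), length(ids))
})

test_that("all-positive boundary group has a degenerate upper CI bound", {
  ids <- sprintf("d%d", 1:7)
  calls <- data.frame(doc_id = ids, item = "randomization", call = TRUE,
                      n_matches = 1L, first_snippet = "")
  prev <- group_prevalence(calls, items = "randomization")
  expect_equal(prev$proportion, 1)
  expect_equal(prev$ci_high, 1)
  expect_gt(prev$ci_low, 0)
})

test_that("journal prevalence equals a brute-force per-group tally", {
  set.seed(111)
  for (rep in 1:15) {
    n <- sample(20:80, 1)
    ids <- sprintf("d%03d", 1:n)
    journal <- sample(paste("journal", letters[1:6]), n, replace = TRUE)
    corpus <- data.frame(doc_id = ids, text = "", journal = journal)
    pos <- runif(n) < 0.5
    calls <- data.frame(doc_id = ids, item = "randomization", call = pos,
                        n_matches = 0L, first_snippet = "")
    mgs <- sample(1:6, 1)
    prev <- group_prevalence(calls, corpus, "journal", min_group_size = mgs,
                             items = "randomization")
    for (j in unique(journal)) {
      k_want <- sum(pos[journal == j])
      n_want <- sum(journal == j)
      if (n_want >= mgs) {
        row <- prev[prev$group_label == j, ]
        expect_equal(row$k, k_want)
        expect_equal(row$n, n_want)
      }
    }
    expect_equal(sum(prev$k), sum(pos))
    expect_equal(sum(prev$n), n)
    # ranked rows (everything before any 'other') are ordered correctly
    ranked <- prev[prev$group_label != "other", ]
    expect_true(all(diff(ranked$proportion) <= 1e-12))
  }
})

test_that("trend fitting handles constant and perfectly linear input", {
  est <- data.frame(item = "blinding", proportion = rep(0.5, 4),
                    epoch_index = 0:3, n = 10)
  fit <- fit_trend(est)
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)
  est2 <- data.frame(item = "blinding", proportion = c(0.1, 0.2, 0.3, 0.4),
                     epoch_index = 0:3, n = 10)
  fit2 <- fit_trend(est2)
  expect_equal(fit2$slope, 0.1)
  expect_equal(fit2$intercept, 0.1)
  expect_equal(fit2$r_squared, 1)
  expect_error(fit_trend(est2[1:2, ]), "at least 3 epochs")
})

test_that("trend fitting matches the closed-form normal equations", {
  set.seed(121)
  for (rep in 1:20) {
    x <- 0:5
    y <- runif(6)
    est <- data.frame(item = "samplesize", proportion = y, epoch_index = x,
                      n = 20)
    fit <- fit_trend(est)
    # longhand least squares
    sxx <- sum((x - mean(x))^2)
    beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
    alpha <- mean(y) - beta * mean(x)
    res <- y - alpha - beta * x
    se <- sqrt(sum(res^2) / 4 / sxx)
    expect_equal(fit$slope, beta, tolerance = 1e-12)
    expect_equal(fit$intercept, alpha, tolerance = 1e-12)
    expect_equal(fit$slope_se, se, tolerance = 1e-12)
    expect_equal(fit$r_squared, 1 - sum(res^2) / sum((y - mean(y))^2),
                 tolerance = 1e-12)
    expect_equal(fit$p_value,
                 2 * pt(abs(beta / se), df = 4, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("a known slope is recovered within two standard errors", {
  # |slope - beta| <= 2*SE is itself a stochastic event (roughly a 2-sigma
  # t interval), so assert its frequency over replicates rather than one draw
  set.seed(131)
  beta <- 0.02
  epochs <- 0:7
  covered <- vapply(1:40, function(r) {
    k <- rbinom(length(epochs), 100, 0.3 + beta * epochs)
    est <- data.frame(item = "randomization", proportion = k / 100,
                      epoch_index = epochs, n = 100)
    fit <- fit_trend(est)
    abs(fit$slope - beta) <= 2 * fit$slope_se
  }, logical(1))
  expect_gte(sum(covered), 30)  # expected ~36/40 under the t(6) reference
  # weighted fit agrees when every epoch has equal n
  est <- data.frame(item = "randomization", proportion = (1:8) / 10,
                    epoch_index = epochs, n = 100)
  expect_equal(fit_trend(est, weighted = TRUE)$slope, fit_trend(est)$slope)
})

test_that("epoch prevalence plus trend runs end to end on synthetic data", {
  gen <- generate_corpus(synth_config(n_docs = 60, seed = 9))
  calls <- classify_corpus(gen$corpus)
  sp <- epoch_spec("quantile", n_bins = 4)
  est <- group_prevalence(calls, gen$corpus, "epoch", spec = sp)
  expect_equal(sum(est$n), 3 * 60)  # every doc in exactly one epoch per item
  fit <- fit_trend(est)
  expect_equal(sort(fit$item), sort(ITEMS))
  expect_true(all(is.finite(fit$slope)))
})
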