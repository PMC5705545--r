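ranked_from <- function(scores, labels) {
  o <- order(-scores)
  data.frame(rank = seq_along(scores), mol_id = paste0("m", o),
             score = scores[o], label = labels[o],
             stringsAsFactors = FALSE)
}

test_that("ROC AUC matches hand-counted concordance", {
  expect_equal(roc_auc(ranked_from(c(0.9, 0.8, 0.7),
                                   c("active", "active", "inactive"))), 1)
  # 3 of 4 active/inactive pairs concordant
  expect_equal(roc_auc(ranked_from(c(0.9, 0.8, 0.7, 0.6),
                                   c("active", "inactive", "active",
                                     "inactive"))), 0.75)
  expect_equal(roc_auc(ranked_from(rep(0.4, 6),
                                   rep(c("active", "inactive"), 3))), 0.5)
  expect_error(roc_auc(ranked_from(1:3, rep("active", 3))), "inactive")
})

test_that("ROC AUC equals the all-pairs oracle on random lists", {
  set.seed(301)
  for (i in 1:200) {
    r <- rand_ranked(n = sample(5:200, 1L))
    expect_equal(roc_auc(r), auc_bruteforce(r))
  }
})

test_that("ROC AUC agrees with an independent ROC package", {
  skip_if_not_installed("pROC")
  set.seed(11)
  r <- rand_ranked(n = 150)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = r$label, predictor = r$score, levels = c("inactive", "active"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(r), ref)
})

test_that("power metric evaluates TPR/(TPR+FPR) at the top-x% prefix", {
  # 10 molecules, 2 actives, top-10% prefix is 1 molecule which is active
  r <- ranked_from(seq(1, 0.1, length.out = 10),
                   c("active", rep("inactive", 8), "active"))
  expect_equal(power_metric(r, 10), 1.0)
  # prefix with equal TPR and FPR
  r2 <- ranked_from(seq(1, 0.1, length.out = 4),
                    c("active", "inactive", "active", "inactive"))
  expect_equal(power_metric(r2, 50), 0.5)
  # no active in prefix
  r3 <- ranked_from(seq(1, 0.1, length.out = 10),
                    c(rep("inactive", 9), "active"))
  expect_equal(power_metric(r3, 10), 0)
  expect_error(power_metric(r, 0), "x_percent")
  set.seed(21)
  for (i in 1:50) {
    pm <- power_metric(rand_ranked(40), sample(c(1, 5, 10, 25, 100), 1L))
    expect_gte(pm, 0); expect_lte(pm, 1)
  }
})

test_that("accumulated-actives curve is the running count of actives", {
  r <- ranked_from(c(0.9, 0.8, 0.7), c("active", "inactive", "active"))
  expect_equal(accumulated_actives(r)$y, c(1, 1, 2))
  r2 <- ranked_from(1:4 / 4, rep("inactive", 4))
  expect_equal(accumulated_actives(r2)$y, rep(0, 4))
  # the endpoint is invariant under any reranking
  set.seed(9)
  rr <- rand_ranked(30)
  shuffled <- rr[sample.int(nrow(rr)), ]
  expect_equal(utils::tail(accumulated_actives(rr)$y, 1),
               utils::tail(accumulated_actives(shuffled)$y, 1))
})

test_that("median and raw MAD use the even-length mean convention", {
  expect_equal(median_and_mad(c(1, 2, 3)), c(median = 2, mad = 1))
  expect_equal(median_and_mad(c(1, 3)), c(median = 2, mad = 1))
  expect_equal(median_and_mad(rep(4.2, 5)), c(median = 4.2, mad = 0))
  expect_error(median_and_mad(numeric(0)), "empty")
})

test_that("median curve is the pointwise median on a shared grid", {
  cv <- function(y) data.frame(x = seq_along(y), y = y)
  expect_equal(median_curve(list(cv(c(0, 0)), cv(c(2, 2)), cv(c(1, 1))))$y,
               c(1, 1))
  expect_equal(median_curve(list(cv(c(0, 4)), cv(c(2, 2))))$y, c(1, 3))
  expect_equal(median_curve(list(cv(1:3)))$y, 1:3)
  expect_error(median_curve(list(cv(1:3), data.frame(x = 2:4, y = 1:3))),
               "grid")
})

test_that("empirical CDF curves step through the sorted sample", {
  expect_equal(cdf_curve(0.5), data.frame(x = 0.5, y = 1))
  c4 <- cdf_curve(c(0.2, 0.4, 0.6, 0.8))
  expect_equal(c4$y, c(0.25, 0.5, 0.75, 1))
  dup <- cdf_curve(c(1, 1, 2))
  expect_equal(dup$y, c(2 / 3, 1)) # duplicates collapse into taller steps
})

test_that("two-sample KS comparison matches the ECDF sup-difference", {
  same <- ks_two_sample(1:5, 1:5)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$not_significantly_different)
  expect_equal(ks_two_sample(1:5, 101:105)$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 4))$statistic, 1 / 3)
  set.seed(13)
  for (i in 1:25) {
    a <- stats::rnorm(sample(5:40, 1L))
    b <- stats::rnorm(sample(5:40, 1L), mean = stats::runif(1, 0, 2))
    expect_equal(ks_two_sample(a, b)$statistic, ks_bruteforce(a, b))
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})
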