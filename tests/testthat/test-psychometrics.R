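test_that("Mann-Whitney U follows the smaller-side convention", {
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$u, 0)
  expect_equal(sep$u_cases_lower, 9) # every control outscores every case
  x <- c(2, 5, 5, 7, 9, 1)
  perm <- mann_whitney(x, sample(x))
  expect_equal(perm$u, length(x)^2 / 2)
  expect_equal(perm$z, 0)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney agrees with wilcox.test on tied integer data", {
  set.seed(101)
  for (i in 1:25) {
    x <- sample(0:8, sample(5:40, 1), replace = TRUE)
    y <- sample(0:8, sample(5:40, 1), replace = TRUE)
    ours <- mann_whitney(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))
    expect_equal(ours$u_cases_higher, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    expect_true(ours$u >= 0 && ours$u <= length(x) * length(y))
    expect_gte(ours$r, 0)
  }
})

test_that("rank effect size follows r = |z|/sqrt(N)", {
  expect_equal(round(effect_size_r(-8.6, 146), 2), 0.71)
  expect_equal(effect_size_r(-8.6, 146), 8.6 / sqrt(146))
  expect_equal(effect_size_r(0, 999), 0)
  expect_equal(round(effect_size_r(-11.6, 648), 3), 0.456)
  expect_error(effect_size_r(1, 0), "N")
})

test_that("empirical ROC handles separation, identity and monotonicity", {
  perfect <- empirical_roc(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1.0)
  same <- empirical_roc(c(1, 2, 3, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(same$auc, 0.5)
  expect_true(all(diff(perfect$sensitivity) <= 0))
  expect_true(all(diff(perfect$specificity) >= 0))
  expect_error(empirical_roc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("trapezoidal AUC equals the U-based AUC and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(102)
  for (i in 1:10) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    scores <- c(sample(0:6, n1, TRUE), sample(0:6, n2, TRUE))
    labels <- rep(c(TRUE, FALSE), c(n1, n2))
    ours <- empirical_roc(scores, labels)$auc
    mw <- mann_whitney(scores[labels], scores[!labels])
    expect_equal(ours, auc_from_u(mw$u_cases_lower, n1, n2), tolerance = 1e-9)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(103)
  scores <- c(rnorm(30, 1), rnorm(40))
  labels <- rep(c(TRUE, FALSE), c(30, 40))
  a0 <- empirical_roc(scores, labels)$auc
  expect_equal(empirical_roc(exp(scores), labels)$auc, a0)
  expect_equal(empirical_roc(scores^3 + 5 * scores, labels)$auc, a0)
})

test_that("auc_from_u reproduces known operating values", {
  expect_equal(round(auc_from_u(467.5, 77, 69), 2), 0.91)
  expect_equal(round(auc_from_u(2824, 77, 301), 2), 0.88)
  expect_equal(auc_from_u(10 * 20 / 2, 10, 20), 0.5)
  expect_error(auc_from_u(201, 10, 20), "U must lie")
})

test_that("operating points count >= threshold as positive", {
  expect_equal(operating_point(c(14, 15, 20, 0, 13),
                               c(TRUE, TRUE, TRUE, FALSE, FALSE), 14),
               c(sensitivity = 1, specificity = 1))
  expect_equal(operating_point(c(13, 14), c(TRUE, FALSE), 14),
               c(sensitivity = 0, specificity = 0))
  cases_only <- operating_point(c(10, 20), c(TRUE, TRUE), 14)
  expect_equal(cases_only[["sensitivity"]], 0.5)
  expect_true(is.na(cases_only[["specificity"]]))
})

test_that("cut-off selection matches the exhaustive-search oracle", {
  expect_equal(select_cutoff(c(14, 15, 20, 29), rep(TRUE, 4)), 14L)
  expect_equal(select_cutoff(rep(5, 10), rep(TRUE, 10)), 5L)
  set.seed(104)
  for (i in 1:30) {
    n1 <- sample(10:60, 1); n2 <- sample(10:60, 1)
    scores <- c(rbinom(n1, 42, 0.6), rbinom(n2, 42, 0.3))
    is_case <- rep(c(TRUE, FALSE), c(n1, n2))
    for (rule in c("highest", "lowest")) {
      got <- select_cutoff(scores, is_case, 0.93, rule = rule)
      expect_equal(got, brute_force_cutoff(scores, is_case, 0.93, rule))
    }
    # achieved sensitivity really meets the constraint
    expect_gte(mean(scores[is_case] >= select_cutoff(scores, is_case, 0.93)),
               0.93)
  }
  expect_error(select_cutoff(1:5, rep(FALSE, 5)), "case group")
})

test_that("alpha matches the standardized two-item closed form exactly", {
  set.seed(105)
  for (i in 1:5) {
    a <- scale(rnorm(60))
    b <- scale(0.6 * a + rnorm(60))
    r <- stats::cor(a, b)[1, 1]
    got <- cronbach_alpha(cbind(a, b))$alpha
    expect_equal(got, 2 * r / (1 + r), tolerance = 1e-12)
  }
  same <- matrix(rep(rnorm(30), 4), ncol = 4)
  expect_equal(cronbach_alpha(same)$alpha, 1)
  expect_warning(cronbach_alpha(matrix(1, 10, 3)), "zero variance")
  expect_error(cronbach_alpha(matrix(rnorm(10), ncol = 1)), "2 items")
})

test_that("alpha on one-factor data matches the Spearman-Brown value", {
  set.seed(106)
  n <- 2000; k <- 14; lambda <- 0.7
  f <- rnorm(n)
  x <- outer(f, rep(lambda, k)) + matrix(rnorm(n * k), n, k) * sqrt(1 - lambda^2)
  rel <- cronbach_alpha(x)
  rbar <- lambda^2
  expect_equal(rel$alpha, k * rbar / (1 + (k - 1) * rbar), tolerance = 0.02)
  expect_true(all(rel$item_total > 0.4))
})

test_that("corrected item-total correlations exclude the item itself", {
  set.seed(107)
  x <- matrix(rnorm(300), 100, 3)
  rel <- cronbach_alpha(x)
  manual <- stats::cor(x[, 1], x[, 2] + x[, 3])
  expect_equal(unname(rel$item_total[1]), manual)
})

test_that("the discrimination index is the product of its two factors", {
  set.seed(108)
  grp <- rep(c(TRUE, FALSE), each = 50)
  dm <- matrix(sample(0:3, 300, TRUE), 100, 3)
  dm[grp, 1] <- pmin(dm[grp, 1] + 2L, 3L) # plant a group effect on item 1
  ds <- discrimination_index(dm[, 1], grp, dm, 1)
  expect_equal(ds$index, ds$r_pb * ds$r_it)
  expect_lte(abs(ds$index), 1)

  # an item distributed identically in both groups has exactly zero r_pb
  item <- c(rep(0:3, 10), rep(0:3, 10))
  g <- rep(c(TRUE, FALSE), each = 40)
  dmx <- cbind(item, stats::rnorm(80), stats::rnorm(80))
  expect_equal(discrimination_index(item, g, dmx, 1)$r_pb, 0)

  flat <- rep(2, 80)
  dzero <- discrimination_index(flat, g, cbind(flat, dmx[, 2:3]), 1)
  expect_true(dzero$degenerate)
  expect_true(is.na(dzero$index))
})

test_that("items with stronger planted separation rank higher by index", {
  set.seed(109)
  n <- 2000
  grp <- rep(c(TRUE, FALSE), each = n / 2)
  sep <- seq(0, 1.5, length.out = 8) # planted group separations
  latent <- rnorm(n)
  m <- sapply(sep, function(d) {
    pmax(pmin(round(latent + d * grp + rnorm(n, sd = 0.8) + 1.5), 3), 0)
  })
  idx <- vapply(seq_along(sep), function(j) {
    discrimination_index(m[, j], grp, m, j)$index
  }, numeric(1))
  expect_gte(stats::cor(rank(idx), rank(sep), method = "spearman"), 0.9)
})
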