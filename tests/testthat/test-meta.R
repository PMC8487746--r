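test_that("sign test reproduces exact binomial tails", {
  expect_equal(sign_test(7, 8)$p.value, 9 / 256)
  expect_equal(sign_test(6, 8)$p.value, 37 / 256)
  expect_equal(sign_test(12, 15)$p.value, 576 / 32768)
  expect_equal(sign_test(10, 23, "two.sided")$p.value,
               2 * pbinom(10, 23, 0.5))
  expect_equal(sign_test(0, 1)$p.value, 1)          # full upper tail
  expect_equal(sign_test(5, 10, "two.sided")$p.value, 1)  # capped at 1
  expect_error(sign_test(5, 4), "k <= n")
  expect_error(sign_test(-1, 4), "k <= n")
})

test_that("sign test tails are complementary and symmetric", {
  for (n in c(1, 8, 23)) for (k in 0:n) {
    if (k >= 1)
      expect_lt(abs(sign_test(k, n)$p.value +
                    sign_test(k - 1, n, "less")$p.value - 1), 1e-12)
    expect_equal(sign_test(k, n, "two.sided")$p.value,
                 sign_test(n - k, n, "two.sided")$p.value,
                 tolerance = 1e-12)
  }
})

test_that("sign test agrees with the base binomial-test oracle", {
  for (case in list(c(7, 8), c(10, 23), c(6, 8), c(12, 15), c(2, 9))) {
    expect_equal(sign_test(case[1], case[2], "two.sided")$p.value,
                 binom.test(case[1], case[2], 0.5,
                            alternative = "two.sided")$p.value,
                 tolerance = 1e-12)
    expect_equal(sign_test(case[1], case[2], "greater")$p.value,
                 binom.test(case[1], case[2], 0.5,
                            alternative = "greater")$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U counts exceedances with half-weight ties", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(unname(mw$statistic), 0)
  expect_equal(mw$p.value, 1 / 20)
  tied <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3), "two.sided")
  expect_equal(unname(tied$statistic), 4.5)
  expect_equal(tied$p.value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("U statistics of the two orderings sum to n*m", {
  set.seed(16)
  for (k in 1:20) {
    x <- sample(1:6, sample(2:7, 1), replace = TRUE)
    y <- sample(1:6, sample(2:7, 1), replace = TRUE)
    expect_equal(unname(mann_whitney_u(x, y)$statistic +
                        mann_whitney_u(y, x)$statistic),
                 length(x) * length(y))
  }
})

test_that("exact p-values equal the permutation oracle, with and without ties", {
  set.seed(17)
  for (k in 1:12) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- round(runif(n, 0, 4), if (k %% 2) 1 else 0)  # even k forces ties
    y <- round(runif(m, 0, 4), if (k %% 2) 1 else 0)
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(mann_whitney_u(x, y, alt)$p.value,
                   mw_exact_oracle(x, y, alt),
                   tolerance = 1e-12,
                   label = sprintf("alt=%s k=%d", alt, k))
    }
  }
})

test_that("tie-free exact p-values match the base wilcox.test oracle", {
  set.seed(18)
  for (k in 1:8) {
    x <- runif(sample(3:7, 1))
    y <- runif(sample(3:7, 1))
    expect_equal(mann_whitney_u(x, y, "two.sided")$p.value,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
    expect_equal(unname(mann_whitney_u(x, y)$statistic),
                 unname(wilcox.test(x, y)$statistic))
  }
})

test_that("large samples fall back to the corrected normal approximation", {
  set.seed(19)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  mw <- mann_whitney_u(x, y, "two.sided")
  expect_match(mw$method, "normal approximation")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mw$p.value, ref$p.value, tolerance = 1e-10)
  exact_small <- mann_whitney_u(runif(5), runif(5))
  expect_match(exact_small$method, "exact")
})

test_that("the exact test holds its size under the null", {
  set.seed(20)
  reps <- 5000
  rej <- logical(reps)
  for (i in 1:reps) {
    x <- runif(5); y <- runif(5)
    rej[i] <- mann_whitney_u(x, y, "two.sided")$p.value <= 0.05
  }
  # discrete exact test: attained size <= nominal, plus Monte Carlo error
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("outcome tables are validated on construction and round-trip", {
  tab <- data.frame(experiment = "E1", condition = c("control", "t1"),
                    network = 1L, gini = c(0.2, 0.3), pearson = c(0.1, NA))
  ot <- as_outcome_table(tab)
  expect_s3_class(ot, "outcome_table")
  f <- tempfile(fileext = ".csv")
  write_outcome_table(ot, f)
  back <- read_outcome_table(f)
  expect_equal(as.data.frame(back), as.data.frame(ot))
  unlink(f)
  expect_error(as_outcome_table(tab[, -4]), "columns")
  bad <- tab; bad$gini[1] <- 1.2
  expect_error(as_outcome_table(bad), "gini")
  dup <- rbind(tab, tab)
  expect_error(as_outcome_table(dup), "once")
})

test_that("compare_conditions pairs treatments with controls per experiment", {
  # two experiments, clean separation: every treatment median above control
  set.seed(22)
  mk <- function(exp_id, shift) {
    rbind(data.frame(experiment = exp_id, condition = "control",
                     network = 1:6, gini = 0.30 + runif(6, 0, 0.01),
                     pearson = 0.1),
          data.frame(experiment = exp_id, condition = "rep",
                     network = 1:6, gini = 0.30 + shift + runif(6, 0, 0.01),
                     pearson = 0.1))
  }
  tab <- as_outcome_table(rbind(mk("E1", 0.2), mk("E2", 0.2)))
  meta <- compare_conditions(tab, "gini", alternative = "greater")
  expect_equal(meta$n_positive, 2)
  expect_equal(meta$n_negative, 0)
  # both pairs fully separated: exact one-sided MW p = 1 / C(12, 6)
  expect_equal(meta$pairs$p_mw,
               rep(min(1, 2 / choose(12, 6)), 2))
  expect_equal(meta$sign_test$p.value, 0.25)   # (1/2)^2
  expect_error(compare_conditions(tab, "gini", control = "absent"),
               "no control")
})

test_that("a single identical pair gives a degenerate sign test", {
  tab <- as_outcome_table(
    data.frame(experiment = "E", condition = rep(c("control", "t"), each = 4),
               network = rep(1:4, 2), gini = rep(c(0.2, 0.25, 0.3, 0.35), 2),
               pearson = 0))
  meta <- compare_conditions(tab, "gini")
  expect_equal(meta$n_ties_dropped, 1)
  expect_null(meta$sign_test)
  meta2 <- compare_conditions(tab, "gini", summary_fun = "mean")
  expect_equal(meta2$pairs$direction, 0)
})
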