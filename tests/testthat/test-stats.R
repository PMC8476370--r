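test_that("Mann-Kendall S and tau match exhaustive pair counting", {
  brute <- function(x) {
    n <- length(x)
    S <- 0
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) S <- S + sign(x[j] - x[i])
    }
    S
  }
  set.seed(51)
  series <- c(list(c(3, 1, 2, 4)),
              lapply(1:10, function(i) round(stats::rnorm(sample(3:8, 1)), 1)))
  for (x in series) {
    mk <- mann_kendall(x)
    expect_equal(unname(mk$statistic["S"]), brute(x))
    if (length(unique(x)) > 1) {
      ct <- suppressWarnings(stats::cor.test(x, seq_along(x),
                                             method = "kendall",
                                             exact = FALSE,
                                             continuity = TRUE))
      expect_equal(unname(mk$statistic["tau"]), unname(ct$estimate),
                   tolerance = 1e-10)
      expect_equal(mk$p_value, ct$p.value, tolerance = 1e-10)
    }
  }
})

test_that("Mann-Kendall endpoints: monotone series, ties, transform invariance", {
  expect_equal(unname(mann_kendall(1:10)$statistic["tau"]), 1)
  expect_equal(unname(mann_kendall(10:1)$statistic["tau"]), -1)
  flat <- mann_kendall(rep(2, 6))
  expect_equal(unname(flat$statistic["tau"]), 0)
  expect_equal(flat$p_value, 1)
  x <- c(5, 3, 4, 1, 2, 6, 0.5)
  expect_equal(mann_kendall(x)$statistic, mann_kendall(exp(x))$statistic)
  expect_error(mann_kendall(c(1, 2)), "at least 3")
})

test_that("t tests: symmetric samples, zero-variance guard, effect sizes", {
  sym <- c(-2, -1, 0, 1, 2)
  tt <- one_sample_t(sym, mu0 = 0)
  expect_equal(unname(tt$statistic["t"]), 0)
  expect_equal(tt$p_value, 1)
  expect_error(one_sample_t(rep(3, 5)), "zero variance")
  expect_error(independent_t(rep(1, 4), rep(1, 4)), "zero pooled variance")
  a <- c(1, 2, 3, 4)
  b <- c(3, 4, 5, 6)
  it <- independent_t(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(unname(it$statistic["t"]), unname(ref$statistic))
  expect_equal(it$p_value, ref$p.value)
  sp <- sqrt((3 * stats::var(a) + 3 * stats::var(b)) / 6)
  expect_equal(unname(it$effect["cohens_d"]), (mean(a) - mean(b)) / sp)
})

test_that("Mann-Whitney U equals exhaustive cross-pair counting", {
  brute_u <- function(a, b) {
    u <- 0
    for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
    u
  }
  set.seed(52)
  cases <- list(list(a = c(1.2, 3.4, 2.2, 5.1, 0.3), b = c(2.0, 2.2, 4.4, 1.1, 0.9)),
                list(a = stats::rnorm(6), b = stats::rnorm(5)),
                list(a = c(1, 1, 2, 3), b = c(1, 2, 2, 4)))
  for (cs in cases) {
    mw <- mann_whitney_u(cs$a, cs$b)
    expect_equal(unname(mw$statistic["U"]), brute_u(cs$a, cs$b))
  }
  ident <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(unname(ident$statistic["U"]), 8)  # null mean n1*n2/2
  expect_gt(ident$p_value, 0.95)
})

test_that("balanced 2x2 designs give identical Type I and Type III sums of squares", {
  set.seed(53)
  d <- expand.grid(f1 = c("a", "b"), f2 = c("x", "y"),
                   rep = 1:6, stringsAsFactors = FALSE)
  d$y <- stats::rnorm(nrow(d)) + (d$f1 == "a") * 0.8 + (d$f2 == "x") * 0.3
  a3 <- factorial_anova(d, "y", c("f1", "f2"), type = 3)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  seq_ss <- stats::anova(stats::lm(y ~ f1 * f2, d))
  options(old)
  for (term in c("f1", "f2", "f1:f2")) {
    expect_equal(a3$table$sum_sq[a3$table$term == term],
                 seq_ss[term, "Sum Sq"], tolerance = 1e-10)
  }
})

test_that("one-way F values match textbook arithmetic (simple effects oracle)", {
  d <- data.frame(g = rep(c("a", "b"), each = 4),
                  w = "only",
                  y = c(1, 2, 3, 4, 6, 7, 8, 9))
  se <- simple_effects(d, "y", "g", "w")
  means <- tapply(d$y, d$g, mean)
  ssb <- 4 * sum((means - mean(d$y))^2)
  ssw <- sum((d$y - means[d$g])^2)
  f_hand <- (ssb / 1) / (ssw / 6)
  expect_equal(se$F, f_hand)
  expect_equal(se$df1, 1)
  expect_equal(se$df2, 6)
  expect_equal(se$p_value, stats::pf(f_hand, 1, 6, lower.tail = FALSE))
})

test_that("ANCOVA Type III SS match hand-solved normal equations on a 12-row fixture", {
  d <- data.frame(
    f1 = rep(c("a", "a", "b", "b"), each = 3),
    f2 = rep(c("x", "y"), times = 6),
    cov = c(1.2, 0.4, -0.8, 2.1, 0.9, -1.3, 0.2, 1.8, -0.5, 1.1, -2.0, 0.6),
    y = c(2.5, 1.9, 0.7, 3.6, 2.2, 0.1, 1.4, 3.0, 0.9, 2.8, -1.1, 1.6))
  got <- ancova(d, "y", c("f1", "f2"), covariate = "cov")
  # oracle: explicit sum-coded design matrix, Type III SS by normal-equation
  # model comparison (drop each term's columns from the full model)
  x1 <- ifelse(d$f1 == "a", 1, -1)
  x2 <- ifelse(d$f2 == "x", 1, -1)
  X <- cbind(intercept = 1, cov = d$cov, f1 = x1, f2 = x2, f1f2 = x1 * x2)
  rss <- function(Xm) {
    beta <- solve(crossprod(Xm), crossprod(Xm, d$y))
    sum((d$y - Xm %*% beta)^2)
  }
  rss_full <- rss(X)
  ss_term <- function(drop_col) rss(X[, setdiff(colnames(X), drop_col)]) - rss_full
  expected <- c(cov = ss_term("cov"), f1 = ss_term("f1"), f2 = ss_term("f2"),
                `f1:f2` = ss_term("f1f2"))
  for (term in names(expected)) {
    expect_equal(got$table$sum_sq[got$table$term == term],
                 unname(expected[term]), tolerance = 1e-8,
                 label = paste("SS for", term))
  }
  expect_equal(got$table$sum_sq[got$table$term == "Residuals"], rss_full,
               tolerance = 1e-8)
  df_res <- 12 - ncol(X)
  for (term in names(expected)) {
    f_hand <- (expected[term] / 1) / (rss_full / df_res)
    expect_equal(got$table$F[got$table$term == term], unname(f_hand),
                 tolerance = 1e-8)
  }
})

test_that("ANOVA guards and effect sizes behave", {
  d <- data.frame(f1 = c("a", "a", "b", "b", "a", "a"),
                  f2 = c("x", "x", "x", "x", "y", "y"),
                  y = stats::rnorm(6))
  expect_error(factorial_anova(d, "y", c("f1", "f2")), "empty design cell")
  set.seed(54)
  d2 <- expand.grid(f1 = c("a", "b"), f2 = c("x", "y"), rep = 1:5,
                    stringsAsFactors = FALSE)
  d2$y <- stats::rnorm(nrow(d2)) + 2 * (d2$f1 == "a")
  a <- factorial_anova(d2, "y", c("f1", "f2"))
  eff <- a$table[a$table$term != "Residuals", ]
  expect_true(all(eff$eta_sq >= 0 & eff$eta_sq <= 1))
  expect_true(all(eff$partial_eta_sq >= 0 & eff$partial_eta_sq <= 1))
  # classical eta^2 sums (with residual share) to 1
  ss_res <- a$table$sum_sq[a$table$term == "Residuals"]
  expect_equal(sum(eff$sum_sq) + ss_res,
               sum(eff$sum_sq[eff$term == "f1"]) / eff$eta_sq[eff$term == "f1"],
               tolerance = 1e-8)
})

test_that("Tukey-Kramer post hoc compares all cell pairs under unequal n", {
  set.seed(55)
  d <- data.frame(f1 = rep(c("B", "I"), times = c(9, 12)),
                  f2 = rep(c("B", "I", "B", "I"), times = c(5, 4, 6, 6)))
  d$y <- stats::rnorm(nrow(d)) + ifelse(d$f1 == "B" & d$f2 == "I", 3, 0)
  tk <- tukey_posthoc(d, "y", c("f1", "f2"))
  expect_equal(nrow(tk), choose(4, 2))
  expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))
  big <- tk[grepl("BI", tk$comparison), ]
  expect_true(any(big$p_adj < 0.01))
})

test_that("tests are invariant to observation order within groups", {
  set.seed(56)
  a <- stats::rnorm(10)
  b <- stats::rnorm(12)
  p1 <- mann_whitney_u(a, b)$p_value
  p2 <- mann_whitney_u(sample(a), sample(b))$p_value
  expect_equal(p1, p2)
  expect_equal(one_sample_t(a)$p_value, one_sample_t(rev(a))$p_value)
})
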