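# The test-selection decision engine.

test_that("normality gate follows the by-n test rule", {
  set.seed(1)
  g8 <- list(a = rnorm(8), b = rnorm(8))
  out8 <- gate_normality(g8)
  expect_identical(unique(out8$test), "shapiro_wilk")
  g25 <- list(a = rnorm(25), b = rnorm(25))
  out25 <- gate_normality(g25)
  expect_identical(unique(out25$test), "dagostino_omnibus")
  mixed <- gate_normality(list(a = rnorm(8), b = rnorm(25)))
  expect_identical(mixed$test, c("shapiro_wilk", "dagostino_omnibus"))
  expect_error(gate_normality(list(a = rnorm(2))), "n >= 3")
})

test_that("D'Agostino omnibus matches the reference implementation", {
  # frozen oracle values computed once with an independent implementation
  x <- c(1.37, -0.56, 0.36, 0.63, 0.40, -0.11, 1.51, -0.09, 2.02,
         -0.06, 1.30, 2.29, -1.39, -0.28, -0.13, 0.64, -0.28, -2.66,
         -2.44, 1.32, -0.31, -1.78, -0.17, 1.21, 1.90)
  r <- dagostino_test(x)
  expect_equal(r$statistic, 1.3359651139, tolerance = 1e-8)
  expect_equal(r$p.value, 0.5127419627, tolerance = 1e-8)
  expect_equal(r$z_skewness, -1.1404088524, tolerance = 1e-8)
  expect_equal(r$z_kurtosis, 0.1882359247, tolerance = 1e-8)

  y <- exp(c(0.5, 1.1, -0.2, 0.8, 2.5, 0.1, 1.9, 0.3, 0.9, 1.4,
             -0.5, 2.2, 0.6, 1.7, 0.2, -0.1, 1.2, 3.1, 0.4, 0.7,
             1.0, 2.8, -0.3, 1.6, 0.05))
  ry <- dagostino_test(y)
  expect_equal(ry$statistic, 23.5355000087, tolerance = 1e-8)
  expect_equal(ry$p.value, 7.750524772e-06, tolerance = 1e-6)
  expect_error(dagostino_test(rnorm(10)), "n >= 20")
})

test_that("variance gate picks the F test for two groups and median Levene beyond", {
  set.seed(2)
  x <- rnorm(15)
  same <- gate_variance(list(a = x, b = x))
  expect_identical(same$test, "f_test")
  expect_equal(same$p, 1)
  expect_true(same$pass)

  three <- gate_variance(list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))
  expect_identical(three$test, "levene_median")

  # grossly unequal spread must fail the gate
  fails <- 0
  for (i in 1:20) {
    set.seed(100 + i)
    g <- list(a = rnorm(20, sd = 1), b = rnorm(20, sd = 4))
    if (!gate_variance(g)$pass) fails <- fails + 1
  }
  expect_gte(fails, 19)

  expect_error(gate_variance(list(a = rep(1, 5), b = rnorm(5))),
               "zero-variance")
  expect_error(gate_variance(list(a = rnorm(5))), "two groups")
})

test_that("median-centred Levene agrees with the reference implementation", {
  set.seed(3)
  d <- data.frame(group = rep(c("a", "b", "c"), each = 12),
                  value = c(rnorm(12, sd = 1), rnorm(12, sd = 2),
                            rnorm(12, sd = 1)))
  mine <- gate_variance(d)
  ref <- car::leveneTest(value ~ factor(group), data = d,
                         center = median)[["Pr(>F)"]][1]
  expect_equal(mine$p, ref)
})

test_that("the decision tree selects Student, Welch, Mann-Whitney and log2 paths", {
  # normal, equal variance -> Student's t on raw data
  set.seed(11)
  d1 <- data.frame(group = rep(c("a", "b"), each = 12),
                   value = rnorm(24))
  t1 <- select_and_run(d1, "two_group")
  expect_identical(t1$test_name, "student_t")
  expect_identical(t1$transform_applied, "none")
  expect_identical(t1$family, "parametric")

  # normal but unequally variable (negatives block the log2 rescue) -> Welch
  set.seed(12)
  d2 <- data.frame(group = rep(c("a", "b"), each = 25),
                   value = c(rnorm(25, 0, 1), rnorm(25, 0, 6)))
  t2 <- select_and_run(d2, "two_group")
  expect_identical(t2$test_name, "welch_t")
  expect_identical(t2$family, "parametric")

  # heavy-tailed with negatives: both gates unrescued -> Mann-Whitney
  set.seed(13)
  d3 <- data.frame(group = rep(c("a", "b"), each = 30),
                   value = rcauchy(60))
  t3 <- select_and_run(d3, "two_group")
  expect_identical(t3$test_name, "mann_whitney")
  expect_identical(t3$family, "nonparametric")

  # lognormal positive data: log2 rescues both gates -> Student on log2
  d4 <- simulate_grouped_phenotypes(
    pheno_sim_config(n_groups = 2, n_per_group = 25,
                     distribution = "lognormal", group_means = c(2, 2),
                     group_sds = c(1, 1), seed = 14))
  t4 <- select_and_run(d4, "two_group")
  expect_identical(t4$transform_applied, "log2")
  expect_identical(t4$test_name, "student_t")

  # already_transformed disables the fallback
  t4b <- select_and_run(d4, "two_group", already_transformed = TRUE)
  expect_identical(t4b$transform_applied, "none")
  expect_identical(t4b$family, "nonparametric")
})

test_that("one-way and two-way designs run the matching ANOVA", {
  set.seed(15)
  d <- data.frame(group = rep(c("a", "b", "c"), each = 10),
                  value = rnorm(30))
  t1 <- select_and_run(d, "one_way")
  expect_identical(t1$test_name, "one_way_anova")
  ref <- summary(aov(value ~ group, data = d))[[1]]
  expect_equal(t1$raw_p, ref$`Pr(>F)`[1])

  d$factor2 <- rep(rep(c("m", "f"), each = 5), 3)
  t2 <- select_and_run(d, "two_way")
  expect_identical(t2$test_name, "two_way_anova")

  # non-normal positive-skew breaks both scales -> Kruskal-Wallis
  set.seed(16)
  d3 <- data.frame(group = rep(c("a", "b", "c"), each = 15),
                   value = rcauchy(45))
  t3 <- select_and_run(d3, "one_way")
  expect_identical(t3$test_name, "kruskal_wallis")
})

test_that("nested t equals Student's t on subject means when replicates are constant", {
  means_a <- c(1.2, 0.7, 1.9)
  means_b <- c(2.4, 3.0, 2.1)
  d <- data.frame(
    group = rep(c("a", "b"), each = 9),
    subject = rep(paste0("s", 1:6), each = 3),
    value = rep(c(means_a, means_b), each = 3))
  nt <- nested_t(d)
  ref <- t.test(means_a, means_b, var.equal = TRUE)
  expect_equal(abs(nt$statistic), abs(unname(ref$statistic)),
               tolerance = 1e-10)
  expect_equal(nt$raw_p, ref$p.value, tolerance = 1e-10)
  expect_identical(nt$df, 4L)

  expect_error(nested_t(data.frame(group = c("a", "a", "b", "b"),
                                   subject = c("s1", "s1", "s2", "s2"),
                                   value = rnorm(4))),
               "2 subjects")
})

test_that("nested t agrees with the nested ANOVA fit and calibrates under the null", {
  d <- simulate_grouped_phenotypes(pheno_sim_config(
    n_groups = 2, group_means = c(0, 0),
    nested = list(subjects_per_group = 4, replicates_per_subject = 3,
                  subject_sd = 1), seed = 10))
  nt <- nested_t(d)
  fit <- summary(aov(value ~ group + Error(factor(subject)), data = d))
  f_ref <- fit[["Error: factor(subject)"]][[1]]$`F value`[1]
  expect_equal(nt$statistic^2, f_ref, tolerance = 1e-8)

  rej <- 0; N <- 1000
  for (i in 1:N) {
    di <- simulate_grouped_phenotypes(pheno_sim_config(
      n_groups = 2, group_means = c(0, 0),
      nested = list(subjects_per_group = 3, replicates_per_subject = 4,
                    subject_sd = 0.8), seed = 20000 + i))
    if (nested_t(di)$raw_p < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / N - 0.05), 3 * sqrt(0.05 * 0.95 / N))
})

test_that("Sidak and Holm-Sidak match closed-form hand computation", {
  expect_equal(adjust_p(0.03, "sidak"), 0.03)        # m = 1: unchanged
  expect_equal(adjust_p(0.03, "holm_sidak"), 0.03)

  p <- c(0.01, 0.04)
  expect_equal(adjust_p(p, "sidak"), 1 - (1 - p)^2)
  hs <- adjust_p(p, "holm_sidak")
  expect_equal(hs[1], 1 - 0.99^2)
  expect_equal(hs[2], max(1 - 0.99^2, 1 - 0.96^1))

  # order independence and monotonicity
  p2 <- c(0.04, 0.01)
  expect_equal(adjust_p(p2, "holm_sidak"), rev(hs))
  expect_error(adjust_p(numeric(0)), "empty")
  expect_error(adjust_p(c(0.1, 1.2)), "0, 1")
})

test_that("adjusted p-values are monotone and never below raw", {
  set.seed(77)
  for (i in 1:25) {
    p <- sort(runif(sample(2:8, 1)))
    for (m in c("sidak", "holm_sidak")) {
      adj <- adjust_p(p, m)
      expect_true(all(adj >= p))
      expect_true(all(diff(adj) >= -1e-12))
      expect_true(all(adj <= 1))
    }
  }
})

test_that("Dunnett Monte-Carlo reproduces reference critical values and calibrates", {
  # two-sided 5% critical value for k = 3 treatments, df = 16: 2.59
  ad <- dunnett_adjust(rep(2, 3), df = 16, n_control = 5, n_treat = 5,
                       nsim = 2e5, seed = 42)
  expect_equal(ad$critical_value, 2.59, tolerance = 0.01)
  # k = 1 collapses to the ordinary two-sided t p-value
  one <- dunnett_adjust(2.2, df = 10, n_control = 6, n_treat = 6,
                        nsim = 2e5, seed = 1)
  # within 4 Monte-Carlo standard errors of the exact t tail
  p_exact <- 2 * pt(-2.2, 10)
  expect_lt(abs(one$adjusted_p - p_exact),
            4 * sqrt(p_exact * (1 - p_exact) / 2e5))
  # deterministic given the seed
  again <- dunnett_adjust(rep(2, 3), df = 16, n_control = 5, n_treat = 5,
                          nsim = 2e5, seed = 42)
  expect_identical(ad$adjusted_p, again$adjusted_p)

  # family-wise error with 3 treatments vs control under the null
  crit <- ad$critical_value
  set.seed(7)
  N <- 2000; fw <- 0
  for (i in 1:N) {
    x <- matrix(rnorm(20), ncol = 4)
    m <- colMeans(x)
    s2 <- sum((x - rep(m, each = 5))^2) / 16
    t <- (m[2:4] - m[1]) / sqrt(s2 * (2 / 5))
    if (any(abs(t) > crit)) fw <- fw + 1
  }
  expect_lt(abs(fw / N - 0.05), 3 * sqrt(0.05 * 0.95 / N))
})

test_that("dunnett_test wraps the ANOVA layout correctly", {
  set.seed(9)
  d <- data.frame(group = rep(c("ctrl", "t1", "t2", "t3"), each = 6),
                  value = c(rnorm(6), rnorm(6, 2), rnorm(6), rnorm(6)))
  out <- dunnett_test(d, control = "ctrl", nsim = 5e4, seed = 3)
  expect_identical(nrow(out), 3L)
  expect_true(all(out$adjusted_p >= out$raw_p - 0.01))
  expect_lt(out$adjusted_p[out$comparison == "t1 - ctrl"], 0.05)
  expect_error(dunnett_test(d, control = "zz"), "control level")
})

test_that("every reported p-value is two-sided: negation leaves it unchanged", {
  set.seed(21)
  d <- data.frame(group = rep(c("a", "b"), each = 12), value = rnorm(24))
  for (des in c("two_group", "one_way")) {
    p1 <- select_and_run(d, des)$raw_p
    dneg <- d; dneg$value <- -dneg$value
    p2 <- select_and_run(dneg, des)$raw_p
    expect_equal(p1, p2)
  }
  dn <- simulate_grouped_phenotypes(pheno_sim_config(
    n_groups = 2, group_means = c(0, 0.5),
    nested = list(subjects_per_group = 3, replicates_per_subject = 3,
                  subject_sd = 1), seed = 22))
  dn_neg <- dn; dn_neg$value <- -dn_neg$value
  expect_equal(nested_t(dn)$raw_p, nested_t(dn_neg)$raw_p)
})

test_that("the decision trace is a pure function of data and design", {
  d <- simulate_grouped_phenotypes(pheno_sim_config(seed = 30))
  t1 <- select_and_run(d, "two_group")
  t2 <- select_and_run(d, "two_group")
  expect_identical(t1, t2)
  expect_true(t1$two_sided)
  expect_gte(t1$adjusted_p, t1$raw_p)
})
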