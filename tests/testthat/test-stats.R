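test_that("field z-scores centre and scale within each field", {
  tab <- data.frame(field_id = rep(c("A", "B"), each = 3),
                    soc = c(1, 2, 3, 10, 20, 60))
  out <- field_zscore(tab, "soc")
  expect_equal(out$soc_z[1:3], c(-1, 0, 1))
  for (f in c("A", "B")) {
    z <- out$soc_z[out$field_id == f]
    expect_lt(abs(mean(z)), 1e-9)
    expect_equal(sd(z), 1, tolerance = 1e-9)
  }
  const <- data.frame(field_id = "A", v = c(2, 2, 2))
  expect_warning(outc <- field_zscore(const, "v"), "zero within-field SD")
  expect_true(all(is.na(outc$v_z)))
  expect_error(field_zscore(tab, "nope"), "missing")
})

test_that("correlation matrix: identities and perfect relations", {
  set.seed(141)
  tab <- data.frame(a = 1:5, b = c(2, 4, 6, 8, 10), c = rnorm(5),
                    k = rep(1, 5))
  expect_warning(cm <- correlation_matrix(tab, c("a", "b", "c", "k")),
                 "constant")
  expect_equal(cm$r["a", "a"], 1)
  expect_equal(cm$r["a", "b"], 1, tolerance = 1e-12)
  expect_equal(cm$r2["a", "b"], 1, tolerance = 1e-12)
  expect_true(is.na(cm$r["a", "k"]))
  tab$d <- -tab$a
  cm2 <- correlation_matrix(tab, c("a", "d"))
  expect_equal(cm2$r["a", "d"], -1, tolerance = 1e-12)
  expect_equal(cm2$stars["a", "d"], "***")
})

test_that("stepwise MLR finds an exact signal and drops pure noise", {
  set.seed(151)
  n <- 100
  x1 <- rnorm(n); x2 <- rnorm(n)
  tab <- data.frame(y = 2 * x1 + rnorm(n, sd = 1e-8), x1 = x1, x2 = x2)
  # the essentially-noise-free fit triggers R's perfect-fit warnings
  m <- suppressWarnings(stepwise_mlr(tab, "y", c("x1", "x2")))
  expect_identical(m$selected, "x1")
  expect_equal(unname(m$coefficients["x1"]), 2, tolerance = 1e-6)
})

test_that("stepwise MLR mostly rejects pure-noise candidates", {
  # closed-form oracle: AIC keeps a junk predictor when its chi-square(1)
  # deviance gain exceeds 2, i.e. with probability P(X2_1 > 2) = 0.157, so
  # the intercept-only model is selected in about 0.843^3 = 0.60 of
  # replicates with three independent noise candidates
  set.seed(161)
  picks <- replicate(50, {
    tab <- data.frame(y = rnorm(200), a = rnorm(200), b = rnorm(200),
                      c = rnorm(200))
    length(stepwise_mlr(tab, "y", c("a", "b", "c"))$selected)
  })
  expect_gt(mean(picks == 0), 0.45)
  expect_lt(mean(picks == 0), 0.78)
  # and the expected number of retained noise terms matches 3 * 0.157
  expect_lt(abs(mean(picks) - 3 * pchisq(2, 1, lower.tail = FALSE)), 0.25)
})

test_that("collinear candidates are dropped with a warning", {
  set.seed(171)
  x <- rnorm(50)
  tab <- data.frame(y = x + rnorm(50, sd = 0.1), x1 = x, x2 = 2 * x)
  expect_warning(m <- stepwise_mlr(tab, "y", c("x1", "x2")), "collinear")
  expect_identical(m$selected, "x1")
})

test_that("ANOVA decomposition matches hand arithmetic", {
  tab <- data.frame(y = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  a <- anova_tukey(tab, "y", "g")
  expect_equal(a$F, 13.5)
  expect_equal(a$eta_squared, 13.5 / 17.5, tolerance = 1e-12)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 4)
  # null data: identical groups -> F = 0, eta^2 = 0
  null <- data.frame(y = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  a0 <- anova_tukey(null, "y", "g")
  expect_equal(a0$F, 0)
  expect_equal(a0$eta_squared, 0)
  expect_error(anova_tukey(data.frame(y = 1:3, g = c("a", "a", "b")),
                           "y", "g"), "b")
})

test_that("two-group Tukey CI equals the studentized-range closed form", {
  set.seed(181)
  tab <- data.frame(y = c(rnorm(8), rnorm(8, 1.5)),
                    g = rep(c("a", "b"), each = 8))
  a <- anova_tukey(tab, "y", "g")
  s2 <- sum(tapply(tab$y, tab$g, function(v) sum((v - mean(v))^2))) / 14
  dmean <- mean(tab$y[tab$g == "b"]) - mean(tab$y[tab$g == "a"])
  half <- qtukey(0.95, 2, 14) / sqrt(2) * sqrt(s2 * 2 / 8)
  expect_equal(a$tukey$diff, dmean, tolerance = 1e-10)
  expect_equal(a$tukey$upr - a$tukey$diff, half, tolerance = 1e-8)
  # eta^2 for two groups equals r^2 of the indicator regression
  r2 <- summary(lm(y ~ g, tab))$r.squared
  expect_equal(a$eta_squared, r2, tolerance = 1e-12)
})

test_that("Tukey-adjusted p-values never undercut the pairwise t-test", {
  set.seed(191)
  for (trial in 1:10) {
    tab <- data.frame(y = rnorm(40), g = rep(letters[1:4], each = 10))
    a <- anova_tukey(tab, "y", "g")
    for (i in seq_len(nrow(a$tukey))) {
      gs <- strsplit(a$tukey$pair[i], "-")[[1]]
      pt <- t.test(tab$y[tab$g == gs[1]], tab$y[tab$g == gs[2]],
                   var.equal = TRUE)$p.value
      expect_gte(a$tukey$p_adj[i] + 1e-10, pt)
    }
  }
})

test_that("bootstrap power: determinism, overwhelming effects, Levene", {
  set.seed(201)
  tab <- data.frame(y = c(rnorm(12), rnorm(12, 1)),
                    g = rep(c("a", "b"), each = 12))
  p1 <- bootstrap_power(tab, "y", "g", n_iter = 500, seed = 9)
  p2 <- bootstrap_power(tab, "y", "g", n_iter = 500, seed = 9)
  expect_identical(p1$power, p2$power)
  expect_true(p1$ci[1] <= p1$power && p1$power <= p1$ci[2])

  big <- data.frame(y = c(rnorm(10), rnorm(10, 10)),
                    g = rep(c("a", "b"), each = 10))
  pb <- bootstrap_power(big, "y", "g", n_iter = 500, seed = 9)
  expect_gte(pb$power, 0.999)
})

test_that("effect-size bias correction tames the naive null inflation", {
  set.seed(221)
  both <- replicate(10, {
    tab <- data.frame(y = rnorm(60), g = rep(letters[1:4], each = 15))
    sd <- sample.int(1e6, 1)
    c(corr = bootstrap_power(tab, "y", "g", n_iter = 200, seed = sd)$power,
      naive = bootstrap_power(tab, "y", "g", n_iter = 200, seed = sd,
                              bias_correct = FALSE)$power)
  })
  expect_lt(mean(both["corr", ]), 0.25)
  expect_lt(mean(both["corr", ]), mean(both["naive", ]))
})

test_that("power grows with the configured effect size", {
  set.seed(211)
  powers <- sapply(c(0, 0.6, 1.5), function(eff) {
    mean(replicate(10, {
      tab <- data.frame(y = c(rnorm(15), rnorm(15, eff)),
                        g = rep(c("a", "b"), each = 15))
      bootstrap_power(tab, "y", "g", n_iter = 200,
                      seed = sample.int(1e6, 1))$power
    }))
  })
  expect_true(all(diff(powers) > 0))
})

test_that("management contrasts: nulls, recovery direction, lone level", {
  tab <- expand.grid(field_id = c("f1", "f2"), zone = c("HS", "LS"),
                     depth_top_cm = c(0, 15), rep = 1:3)
  tab$till <- ifelse(tab$field_id == "f1", "till", "no-till")
  tab$v <- 1  # identical everywhere -> zero contrasts
  mc <- management_contrast(tab, "v", "till")
  expect_true(all(mc$mean_hs_ls_diff == 0))
  expect_equal(sort(unique(mc$flag_level)), c("no-till", "till"))

  tab$v2 <- ifelse(tab$zone == "HS" & tab$till == "no-till", 2, 1)
  mc2 <- management_contrast(tab, "v2", "till")
  expect_equal(mc2$mean_hs_ls_diff[mc2$flag_level == "no-till"], c(1, 1))
  expect_equal(mc2$mean_hs_ls_diff[mc2$flag_level == "till"], c(0, 0))

  solo <- tab[tab$till == "till", ]
  mc3 <- management_contrast(solo, "v", "till")
  expect_equal(unique(mc3$flag_level), "till")

  noLS <- tab[!(tab$field_id == "f1" & tab$zone == "LS"), ]
  expect_warning(management_contrast(noLS, "v", "till"), "f1")
})
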