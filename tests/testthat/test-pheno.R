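# counts as printed for the two lines (maximum per-category record counts)
line_counts <- function() {
  data.frame(
    WS = rep(c("NORM", "MOD", "SEV", "NORM", "MOD", "SEV"),
             times = c(234, 289, 162, 431, 206, 27)),
    line = rep(c("pHu+", "pHu-"), times = c(685, 664)),
    stringsAsFactors = FALSE)
}

test_that("incidence table reproduces known fractions and handles margins", {
  tab <- line_counts()
  it <- incidence_table(tab, by = "line")
  ov <- it[it$group == "overall", ]
  expect_equal(ov$N, 1349L)
  expect_equal(ov$pct_MOD, 100 * 495 / 1349)
  expect_equal(ov$pct_SEV, 100 * 189 / 1349)
  expect_equal(ov$pct_affected, 100 * 684 / 1349)
  plus <- it[it$group == "pHu+", ]
  expect_equal(plus$pct_MOD, 100 * 289 / 685)

  allnorm <- incidence_table(data.frame(WS = rep("NORM", 10)))
  expect_equal(allnorm$pct_NORM, 100)
  expect_equal(allnorm$pct_affected, 0)

  # row order and unrelated columns do not change percentages
  tab2 <- tab[sample.int(nrow(tab)), ]
  tab2$BW <- rnorm(nrow(tab2))
  it2 <- incidence_table(tab2, by = "line")
  expect_equal(it2[order(it2$group), -1], it[order(it$group), -1])

  # group with no scored birds is flagged, not an error
  tab3 <- rbind(tab, data.frame(WS = NA, line = "base"))
  it3 <- incidence_table(tab3, by = "line")
  expect_equal(it3$N[it3$group == "base"], 0L)
  expect_true(is.na(it3$pct_NORM[it3$group == "base"]))
})

test_that("chi-squared statistics match the closed form", {
  # 2x2 table (10,90; 20,80): n(ad - bc)^2 / row/col products = 3.9216
  tab <- data.frame(WS = rep(c("MOD", "NORM", "MOD", "NORM"),
                             c(10, 90, 20, 80)),
                    line = rep(c("a", "b"), c(100, 100)))
  res <- chi_square_by_category(tab, groups = "line")
  hand <- 200 * (10 * 80 - 90 * 20)^2 / (100 * 100 * 30 * 170)
  mod <- res$overall[res$overall$category == "MOD", ]
  expect_equal(mod$statistic, hand, tolerance = 1e-12)
  expect_equal(mod$df, 1)

  # identical proportions in every group -> statistic 0
  t0 <- data.frame(WS = rep(c("MOD", "NORM"), times = c(20, 80)),
                   line = rep(c("a", "b"), 50))
  r0 <- chi_square_by_category(t0, groups = "line")
  expect_equal(r0$overall$statistic[r0$overall$category == "MOD"], 0)

  # 4 groups -> df 3, and pairwise table has choose(4,2) rows per category
  t4 <- data.frame(WS = rep(rep(c("MOD", "NORM"), 4), c(rbind(10:13, 40))),
                   g = rep(letters[1:4], times = 10:13 + 40))
  r4 <- chi_square_by_category(t4, groups = "g")
  expect_equal(unique(r4$overall$df), 3)
  expect_equal(sum(r4$pairwise$category == "MOD"), 6)
})

test_that("fixed-effects fit is exact least squares and guards its inputs", {
  set.seed(7)
  n <- 400
  d <- data.frame(id = 1:n, hatch = sample(1:3, n, TRUE),
                  sex = sample(c("male", "female"), n, TRUE),
                  line = sample(c("pHu+", "pHu-"), n, TRUE),
                  WS = sample(c("NORM", "MOD", "SEV"), n, TRUE))
  d$BW <- 2500 + 20 * d$hatch + 40 * (d$sex == "male") + rnorm(n, 0, 60)
  fit <- fit_ws_fixed_model(d, "BW")
  expect_equal(fitted(fit$lm) + resid(fit$lm), fit$data$y,
               ignore_attr = TRUE)

  # single hatch, sex, line: collapses to a one-way layout on WS
  d1 <- d; d1$hatch <- 1; d1$sex <- "male"; d1$line <- "pHu+"
  fit1 <- fit_ws_fixed_model(d1, "BW")
  means <- tapply(fit1$data$y, fit1$data$WS, mean)
  ls1 <- lsmeans_tukey(fit1)
  expect_equal(ls1$lsmean, as.numeric(means[as.character(ls1$WS)]))

  expect_error(fit_ws_fixed_model(d, "nope"), "missing column")
  dneg <- d; dneg$DL <- d$BW - 2600
  expect_error(fit_ws_fixed_model(dneg, "DL"), "positive")
})

test_that("null simulation keeps intra-line WS contrasts near zero", {
  set.seed(11)
  n <- 2000
  d <- data.frame(id = 1:n, hatch = sample(1:4, n, TRUE),
                  sex = sample(c("male", "female"), n, TRUE),
                  line = sample(c("pHu+", "pHu-"), n, TRUE),
                  WS = sample(c("NORM", "MOD", "SEV"), n, TRUE,
                              prob = c(0.5, 0.35, 0.15)))
  d$BW <- 2500 + 25 * d$hatch + 60 * (d$sex == "male") +
    30 * (d$line == "pHu+") + rnorm(n, 0, 80)
  fit <- fit_ws_fixed_model(d, "BW")
  cmp <- attr(lsmeans_tukey(fit), "comparisons")
  expect_true(all(abs(cmp$t.ratio) < 3.5))
})

test_that("LSMeans agree with a brute-force prediction-grid average and emmeans", {
  set.seed(13)
  n <- 500
  d <- data.frame(id = 1:n, hatch = sample(1:4, n, TRUE),
                  sex = sample(c("male", "female"), n, TRUE,
                               prob = c(0.7, 0.3)), # unbalanced on purpose
                  line = sample(c("pHu+", "pHu-"), n, TRUE),
                  WS = sample(c("NORM", "MOD", "SEV"), n, TRUE,
                              prob = c(0.6, 0.3, 0.1)))
  d$BW <- 2500 + 25 * d$hatch + 60 * (d$sex == "male") +
    50 * (d$WS == "SEV") + rnorm(n, 0, 70)
  fit <- fit_ws_fixed_model(d, "BW")
  ls <- lsmeans_tukey(fit)

  # oracle 1: predict() over the full hatch x sex grid, averaged uniformly
  for (r in seq_len(nrow(ls))) {
    grid <- expand.grid(hatch = levels(fit$data$hatch),
                        sex = levels(fit$data$sex),
                        line = as.character(ls$line[r]),
                        WS = as.character(ls$WS[r]),
                        stringsAsFactors = FALSE)
    pred <- predict(fit$lm, newdata = grid)
    expect_lt(abs(mean(pred) - ls$lsmean[r]), 1e-8)
  }

  # oracle 2: emmeans point estimates and standard errors
  skip_if_not_installed("emmeans")
  em <- suppressMessages(
    as.data.frame(emmeans::emmeans(fit$lm, ~ WS | line)))
  key_ls <- paste(ls$line, ls$WS)
  key_em <- paste(em$line, em$WS)
  m <- match(key_ls, key_em)
  expect_equal(ls$lsmean, em$emmean[m], tolerance = 1e-10)
  expect_equal(ls$se, em$SE[m], tolerance = 1e-10)
})

test_that("two-group Tukey collapses to the plain t-test", {
  set.seed(17)
  n <- 120
  d <- data.frame(id = 1:n, hatch = 1, sex = "male", line = "pHu+",
                  WS = sample(c("NORM", "MOD"), n, TRUE))
  d$BW <- 2500 + 40 * (d$WS == "MOD") + rnorm(n, 0, 70)
  fit <- fit_ws_fixed_model(d, "BW")
  cmp <- attr(lsmeans_tukey(fit), "comparisons")
  tt <- t.test(y ~ WS, data = fit$data, var.equal = TRUE)
  expect_equal(cmp$p.value, tt$p.value, tolerance = 1e-10)
})

test_that("adding a constant shifts every LSMean but no comparison", {
  set.seed(19)
  n <- 300
  d <- data.frame(id = 1:n, hatch = sample(1:3, n, TRUE),
                  sex = sample(c("male", "female"), n, TRUE),
                  line = sample(c("pHu+", "pHu-"), n, TRUE),
                  WS = sample(c("NORM", "MOD", "SEV"), n, TRUE))
  d$BW <- 2500 + rnorm(n, 0, 50)
  ls1 <- lsmeans_tukey(fit_ws_fixed_model(d, "BW"))
  d2 <- d; d2$BW <- d$BW + 123.4
  ls2 <- lsmeans_tukey(fit_ws_fixed_model(d2, "BW"))
  expect_equal(ls2$lsmean, ls1$lsmean + 123.4)
  expect_equal(attr(ls2, "comparisons")$p.value,
               attr(ls1, "comparisons")$p.value, tolerance = 1e-10)
  expect_equal(ls2$letters, ls1$letters)
})

test_that("the optional outlier filter flags by median +- k MAD and logs", {
  tab <- data.frame(id = as.character(1:21),
                    BW = c(rnorm(20, 100, 1), 500))
  out <- remove_outliers(tab, "BW", k = 5)
  expect_true(is.na(out$BW[21]))
  expect_equal(attr(out, "removed")$id, "21")
  expect_equal(sum(is.na(out$BW)), 1L)
})
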