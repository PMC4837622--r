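test_that("MCMC schedule bookkeeping is exact", {
  cfg <- mcmc_config()
  expect_equal(cfg$n_iter, 100000L)
  expect_equal(cfg$burnin, 20000L)
  expect_equal(cfg$thin, 20L)
  expect_equal(cfg$n_retained, 4000L)
  expect_equal(mcmc_config(20000, 4000, 10)$n_retained, 1600L)
  expect_error(mcmc_config(100, 100, 1), "burnin")
  expect_error(mcmc_config(100, 10, 0), "thin")
})

test_that("missing-record plan classifies contributions", {
  ped <- pedigree(c("s", "d", "o1", "o2", "o3"),
                  c(NA, NA, "s", "s", "s"), c(NA, NA, "d", "d", "d"))
  tab <- data.frame(id = c("o1", "o2", "o3"),
                    WS = c("MOD", NA, "SEV"),
                    Q = c(1.2, 3.4, NA))
  plan <- handle_missing(ped, tab, model_spec("WS", "Q"))
  expect_equal(plan$contributes[match(c("s", "o1", "o2", "o3"), plan$id)],
               c("pedigree-only", "both", "trait2", "trait1"))
})

test_that("truncated-normal draws respect bounds and the moment identity", {
  set.seed(1)
  # mean 0, sd 1, interval (0, Inf): E = dnorm(0)/(1 - pnorm(0))
  x <- pedliab:::.rtruncnorm_vec(100000L, 0, 1, 0, Inf)
  expect_true(all(x > 0))
  m <- sqrt(2 / pi)
  v <- 1 - m^2
  expect_lt(abs(mean(x) - m), 3 * sqrt(v / length(x)))
  # two-sided interval
  y <- pedliab:::.rtruncnorm_vec(2000L, 1, 2, -0.5, 0.25)
  expect_true(all(y >= -0.5 & y <= 0.25))
  # degenerate near-equal bounds: no numeric failure
  z <- pedliab:::.rtruncnorm_vec(10L, 0, 1, 0.999999, 1.000001)
  expect_true(all(is.finite(z) & z >= 0.999 & z <= 1.001))
})

test_that("a reduced-schedule run has exact bookkeeping and is reproducible", {
  ds <- small_sim(seed = 71)
  spec <- model_spec("WS", "Q")
  cfg <- mcmc_config(600, 200, 10, seed = 5)
  ch1 <- gibbs_run(ds$pedigree, ds$phenotypes, spec, cfg)
  expect_s3_class(ch1, "chain_store")
  expect_equal(nrow(ch1), 40L)
  ch2 <- gibbs_run(ds$pedigree, ds$phenotypes, spec, cfg)
  expect_identical(as.data.frame(ch1), as.data.frame(ch2))

  # every retained draw: liability residual variance exactly 1, G and R
  # positive definite, derived parameters in range
  expect_true(all(ch1$sigma2_e1 == 1))
  expect_true(all(ch1$sigma2_g1 * ch1$sigma2_g2 - ch1$sigma_g12^2 > 0))
  expect_true(all(ch1$sigma2_e1 * ch1$sigma2_e2 - ch1$sigma_e12^2 > 0))
  expect_true(all(ch1$h2_1 >= 0 & ch1$h2_1 <= 1))
  expect_true(all(ch1$h2_2 >= 0 & ch1$h2_2 <= 1))
  expect_true(all(abs(ch1$rg) <= 1))
  expect_true(all(ch1$t2 > 0))
})

test_that("an empty ordinal category is a hard error", {
  ds <- small_sim(seed = 73, thresholds = c(0, 50)) # no SEV birds
  expect_error(
    gibbs_run(ds$pedigree, ds$phenotypes, model_spec("WS", "Q"),
              mcmc_config(200, 100, 10)),
    "zero observations")
})

test_that("chain files round-trip through delimited text", {
  ds <- small_sim(seed = 75)
  ch <- gibbs_run(ds$pedigree, ds$phenotypes, model_spec("WS", "Q"),
                  mcmc_config(400, 200, 10, seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_chain(ch, f)
  back <- read_chain(f)
  expect_equal(back$rg, ch$rg, tolerance = 1e-10)
  expect_equal(names(back), names(as.data.frame(ch)))
})

test_that("with variances fixed, posterior location means solve the MME", {
  ds <- small_sim(seed = 5)
  ped <- ds$pedigree
  tab <- ds$phenotypes
  spec <- model_spec(trait1 = "Q", trait2 = NULL)
  G <- matrix(0.5, 1, 1); R <- matrix(0.5, 1, 1)
  ch <- gibbs_run(ped, tab, spec, mcmc_config(21000, 1000, 5, seed = 11),
                  fix_G = G, fix_R = R)
  loc <- attr(ch, "location_means")
  expect_true(all(ch$sigma2_g1 == 0.5))

  y <- tab$Q
  X <- model.matrix(~ factor(tab$hatch) + factor(tab$sex))
  Z <- matrix(0, nrow(tab), nrow(ped))
  Z[cbind(seq_len(nrow(tab)), match(tab$id, ped$id))] <- 1
  Ai <- as.matrix(a_inverse(ped))
  lam <- drop(R) / drop(G)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lam * Ai))
  sol <- solve(C, c(crossprod(X, y), crossprod(Z, y)))
  p <- ncol(X)
  # agreement within Monte-Carlo error of the chain averages
  expect_lt(max(abs(loc$beta1 - sol[1:p])), 0.02)
  expect_lt(max(abs(loc$breeding_values[, 1] - sol[-(1:p)])), 0.02)
  expect_gt(cor(loc$breeding_values[, 1], sol[-(1:p)]), 0.999)
})

test_that("as the variance ratio degenerates the fit approaches OLS", {
  ds <- small_sim(seed = 77)
  tab <- ds$phenotypes
  spec <- model_spec(trait1 = "Q", trait2 = NULL)
  ch <- gibbs_run(ds$pedigree, tab, spec,
                  mcmc_config(11000, 1000, 5, seed = 13),
                  fix_G = matrix(1e-8, 1, 1), fix_R = matrix(0.5, 1, 1))
  loc <- attr(ch, "location_means")
  ols <- coef(lm(tab$Q ~ factor(tab$hatch) + factor(tab$sex)))
  expect_lt(max(abs(loc$beta1 - ols)), 0.02)
})

test_that("a single-animal model reproduces the shrinkage closed form", {
  ped1 <- pedigree("x", NA, NA)
  tab1 <- data.frame(id = "x", Q = 1.0)
  sp <- model_spec("Q", NULL, fixed = character(0), intercept = FALSE)
  ch <- gibbs_run(ped1, tab1, sp, mcmc_config(42000, 2000, 5, seed = 3),
                  fix_G = matrix(2, 1, 1), fix_R = matrix(1, 1, 1))
  bv <- attr(ch, "location_means")$breeding_values
  # E(a | y) = (sigma2_g / (sigma2_g + sigma2_e)) y = 2/3
  expect_lt(abs(bv[1, 1] - 2 / 3), 0.05)
})

test_that("under a joint null the covariance posteriors are calibrated", {
  # sigma_g12 = sigma_e12 = 0 in truth; over replicate datasets the
  # posterior means of sigma_e12 average to 0 and the 95% interval of rg
  # covers 0 in >= 90% of chains
  nrep <- 20
  e12_mean <- e12_sd <- numeric(nrep)
  rg_covers <- logical(nrep)
  for (r in seq_len(nrep)) {
    ds <- medium_sim(seed = 300 + r, G = matrix(c(1, 0, 0, 0.5), 2),
                     R = matrix(c(1, 0, 0, 0.5), 2))
    ch <- gibbs_run(ds$pedigree, ds$phenotypes, model_spec("WS", "Q"),
                    mcmc_config(4000, 1000, 5, seed = 7))
    s <- summarize_chain(ch, c("sigma_e12", "rg"))
    e12_mean[r] <- s$mean[1]; e12_sd[r] <- s$sd[1]
    rg_covers[r] <- s$lower[2] <= 0 && s$upper[2] >= 0
  }
  expect_lt(abs(mean(e12_mean)), 3 * mean(e12_sd) / sqrt(nrep))
  expect_gte(mean(rg_covers), 0.90)
})

test_that("line restriction keeps the pedigree but drops other-line records", {
  ds <- small_sim(seed = 81)
  spec <- model_spec("WS", "Q", lines = "pHu+")
  ch <- gibbs_run(ds$pedigree, ds$phenotypes, spec,
                  mcmc_config(300, 100, 10, seed = 1))
  n_plus <- sum(ds$phenotypes$line == "pHu+" &
                (!is.na(ds$phenotypes$WS) | !is.na(ds$phenotypes$Q)))
  expect_equal(attr(ch, "n_records"), n_plus)
  expect_equal(nrow(attr(ch, "location_means")$breeding_values),
               nrow(ds$pedigree))
})

test_that("direct observation of the liability agrees with the threshold fit", {
  # replace the ordinal score by the simulated continuous liability and
  # compare the genetic-parameter posteriors on the same data
  ds <- small_sim(seed = 83, ngen = 3)
  tab_obs <- ds$phenotypes
  tab_obs$L <- ds$truth$liability
  cfg <- mcmc_config(6000, 2000, 5, seed = 9)
  ch_thr <- gibbs_run(ds$pedigree, ds$phenotypes, model_spec("WS", "Q"), cfg)
  ch_obs <- gibbs_run(ds$pedigree, tab_obs, model_spec("L", "Q"), cfg)
  s_thr <- summarize_chain(ch_thr, c("h2_1", "rg"))
  s_obs <- summarize_chain(ch_obs, c("h2_1", "rg"))
  for (k in 1:2) {
    tol <- 3 * sqrt(s_thr$sd[k]^2 + s_obs$sd[k]^2)
    expect_lt(abs(s_thr$mean[k] - s_obs$mean[k]), tol)
  }
})

test_that("partially missing co-trait records are integrated out correctly", {
  ds <- medium_sim(seed = 85, G = matrix(c(1, 0.5, 0.5, 0.5), 2),
                   R = matrix(c(1, 0, 0, 0.5), 2))
  tab <- ds$phenotypes
  set.seed(99)
  drop <- sample(which(!is.na(tab$Q)), floor(0.4 * sum(!is.na(tab$Q))))
  tab$Q[drop] <- NA
  ch <- gibbs_run(ds$pedigree, tab, model_spec("WS", "Q"),
                  mcmc_config(6000, 2000, 5, seed = 15))
  s <- summarize_chain(ch, "rg")
  rg_true <- 0.5 / sqrt(1 * 0.5)
  expect_lt(abs(s$mean - rg_true), 3 * s$sd)
})
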