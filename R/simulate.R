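#' Configuration of the synthetic divergent-selection breeding scheme
#'
#' Builds a validated simulation configuration emulating a two-line divergent
#' truncation-selection design: a common base generation, then
#' `n_generations` of within-line selection on the phenotype of a
#' quantitative trait (high direction in one line, low in the other), with a
#' 3-category ordinal trait generated by thresholding a latent liability
#' that is genetically and residually correlated with the quantitative
#' trait.
#'
#' Defaults emulate the study population the package targets: about 10,600
#' birds over a base plus six generations, divergent selection on breast
#' ultimate pH (`pHu`), liability-scale heritability 0.65 for the ordinal
#' white-striping trait, and thresholds placed so that roughly 37% of birds
#' fall in the middle (MOD) and 14% in the top (SEV) category.
#'
#' @param n_generations generations of selection after the base (default 6).
#' @param base_males,base_females size of the unselected base generation.
#' @param sires_per_line,dams_per_line parents selected per line per
#'   generation.
#' @param offspring_per_dam full-sib family size.
#' @param trait2_name name of the quantitative trait (default `"pHu"`; it is
#'   also the selection criterion).
#' @param true_G 2x2 additive genetic covariance matrix
#'   (liability, trait2).
#' @param true_R 2x2 residual covariance matrix; the liability residual
#'   variance `true_R[1,1]` must be 1.
#' @param mu length-2 vector of overall means (liability, trait2).
#' @param thresholds increasing liability thresholds; the first must be 0
#'   (identifiability anchor). Length 2 for 3 categories NORM/MOD/SEV.
#' @param sex_effects length-2 vector: additive offset for females relative
#'   to males on each trait.
#' @param hatch_sd length-2 vector: SD of per-hatch offsets (one hatch per
#'   generation), drawn once at simulation time from the seed.
#' @param c2 common maternal-environment variance as a fraction of the
#'   phenotypic variance of trait2; used only when `maternal = TRUE`
#'   (intended for body weight).
#' @param maternal logical; attach a common maternal environment effect to
#'   trait2?
#' @param selection_fraction maximal fraction of available candidates that
#'   may be selected as parents (validation cap on truncation selection),
#'   in (0, 1].
#' @param ws_generations generations in which the ordinal score is recorded
#'   (`NULL` = all; default generations 5 and 6, mirroring a trait scored
#'   only late in the scheme).
#' @param trait2_generations generations in which trait2 is recorded
#'   (`NULL` = all).
#' @param seed integer RNG seed used by [simulate_population].
#' @return object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_generations = 6,
                       base_males = 820, base_females = 820,
                       sires_per_line = 30, dams_per_line = 85,
                       offspring_per_dam = 9,
                       trait2_name = "pHu",
                       true_G = matrix(c(1.857, 0.0467, 0.0467, 0.0266), 2),
                       true_R = matrix(c(1, 0, 0, 0.0218), 2),
                       mu = c(0.03, 5.90),
                       thresholds = c(0, 1.86),
                       sex_effects = c(0.2, -0.03),
                       hatch_sd = c(0.1, 0.02),
                       c2 = 0,
                       maternal = FALSE,
                       selection_fraction = 0.5,
                       ws_generations = c(5, 6),
                       trait2_generations = NULL,
                       seed = 1L) {
  cfg <- list(n_generations = as.integer(n_generations),
              base_males = as.integer(base_males),
              base_females = as.integer(base_females),
              sires_per_line = as.integer(sires_per_line),
              dams_per_line = as.integer(dams_per_line),
              offspring_per_dam = as.integer(offspring_per_dam),
              trait2_name = trait2_name,
              true_G = true_G, true_R = true_R,
              mu = mu, thresholds = thresholds,
              sex_effects = sex_effects, hatch_sd = hatch_sd,
              c2 = c2, maternal = isTRUE(maternal),
              selection_fraction = selection_fraction,
              ws_generations = ws_generations,
              trait2_generations = trait2_generations,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg a `sim_config`.
#' @export
validate_sim_config <- function(cfg) {
  .check_psd <- function(M, nm) {
    if (!isTRUE(all.equal(M, t(M), tolerance = 1e-10)))
      stop(nm, " must be symmetric")
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop(nm, " is not positive semi-definite")
  }
  .check_psd(cfg$true_G, "true_G")
  .check_psd(cfg$true_R, "true_R")
  if (abs(cfg$true_R[1, 1] - 1) > 1e-12)
    stop("liability residual variance true_R[1,1] must equal 1")
  if (is.unsorted(cfg$thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  if (abs(cfg$thresholds[1]) > 1e-12)
    stop("first threshold must be 0 (identifiability anchor)")
  if (cfg$selection_fraction <= 0 || cfg$selection_fraction > 1)
    stop("selection_fraction must be in (0, 1]")
  if (cfg$c2 < 0 || cfg$c2 >= 1) stop("c2 must be in [0, 1)")
  if (any(c(cfg$n_generations, cfg$base_males, cfg$base_females,
            cfg$sires_per_line, cfg$dams_per_line,
            cfg$offspring_per_dam) < 1))
    stop("population size parameters must be positive integers")
  invisible(cfg)
}

#' Write or read a simulation configuration as YAML
#'
#' Flat key-value text: covariance matrices are stored row-wise as numeric
#' vectors (`true_G`, `true_R` of length 4).
#'
#' @param cfg a [sim_config].
#' @param path file path.
#' @return `write_sim_config`: `path`, invisibly. `read_sim_config`: a
#'   validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$true_G <- as.numeric(cfg$true_G)
  out$true_R <- as.numeric(cfg$true_R)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$true_G <- matrix(as.numeric(raw$true_G), 2)
  raw$true_R <- matrix(as.numeric(raw$true_R), 2)
  do.call(sim_config, raw)
}

## pairwise kinship (coancestry) on an index-based pedigree, memoized;
## f(i, i) = 0.5 (1 + F_i); offspring inbreeding F = f(sire, dam).
## Parent vectors si/di are read live from `env` (the pedigree grows
## append-only, so memoized values stay valid).
.kinship_fun <- function(env) {
  memo <- new.env(hash = TRUE, parent = emptyenv())
  phi <- function(i, j) {
    if (is.na(i) || is.na(j) || i == 0L || j == 0L) return(0)
    if (i < j) { k <- i; i <- j; j <- k } # i is the later-born
    key <- paste0(i, "_", j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == j) {
      0.5 * (1 + phi(env$si[i], env$di[i]))
    } else {
      0.5 * (phi(env$si[i], j) + phi(env$di[i], j))
    }
    memo[[key]] <- v
    v
  }
  phi
}

.rmvn2 <- function(n, Sigma) {
  L <- chol(Sigma + diag(1e-12, nrow(Sigma)))
  matrix(stats::rnorm(n * nrow(Sigma)), n) %*% L
}

.ws_cut <- function(liability, thresholds) {
  cut(liability, breaks = c(-Inf, thresholds, Inf),
      labels = c("NORM", "MOD", "SEV"), right = FALSE)
}

#' Simulate a two-line divergent-selection population
#'
#' Runs the breeding scheme described in [sim_config]: base individuals are
#' unrelated founders with breeding values drawn from `true_G`; offspring
#' breeding values are the parent average plus a Mendelian-sampling
#' deviation with covariance `0.5 (1 - (F_s + F_d)/2) true_G`; phenotypes
#' add hatch and sex offsets, a common maternal-environment draw per dam
#' (trait2 only, when configured), and a residual from `true_R`; the ordinal
#' category is the deterministic image of the liability under the
#' thresholds. Parents of each next generation are chosen by truncation on
#' the trait2 phenotype (high in line `pHu+`, low in line `pHu-`).
#'
#' @param cfg a [sim_config].
#' @param seed optional override of `cfg$seed`.
#' @return object of class `sim_dataset`: list with elements
#'   `pedigree` ([pedigree]), `phenotypes` (data.frame with columns `id`,
#'   `line`, `sex`, `hatch`, `generation`, `WS`, and the quantitative
#'   trait), and `truth` (true breeding values, liabilities, variance
#'   components, maternal-effect values, realized selection differentials,
#'   seed and config).
#' @export
simulate_population <- function(cfg, seed = NULL) {
  validate_sim_config(cfg)
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  set.seed(seed)

  G <- cfg$true_G; R <- cfg$true_R
  ngen <- cfg$n_generations
  n_hatch <- ngen + 1L
  hatch_eff <- cbind(stats::rnorm(n_hatch, 0, cfg$hatch_sd[1]),
                     stats::rnorm(n_hatch, 0, cfg$hatch_sd[2]))
  sigma2_c <- if (cfg$maternal)
    cfg$c2 / (1 - cfg$c2) * (G[2, 2] + R[2, 2]) else 0

  # growing pedigree stored index-based for speed
  cap <- cfg$base_males + cfg$base_females +
    2L * ngen * cfg$dams_per_line * cfg$offspring_per_dam
  si <- di <- rep(NA_integer_, cap)
  sex <- character(cap); line <- character(cap)
  gen <- integer(cap); hatch <- integer(cap)
  bv <- matrix(0, cap, 2); ee <- matrix(0, cap, 2)
  cvals <- numeric(cap) # maternal-environment contribution per individual
  fcoef <- numeric(cap)
  n <- 0L

  add_birds <- function(k, s_idx, d_idx, sx, ln, g) {
    idx <- n + seq_len(k)
    si[idx] <<- s_idx; di[idx] <<- d_idx
    sex[idx] <<- sx; line[idx] <<- ln
    gen[idx] <<- g; hatch[idx] <<- g + 1L
    n <<- n + k
    idx
  }

  # base generation: unrelated founders, no maternal effect
  n0 <- cfg$base_males + cfg$base_females
  idx0 <- add_birds(n0, NA_integer_, NA_integer_,
                    c(rep("male", cfg$base_males),
                      rep("female", cfg$base_females)),
                    "base", 0L)
  bv[idx0, ] <- .rmvn2(n0, G)
  ee[idx0, ] <- .rmvn2(n0, R)

  phi <- .kinship_fun(environment())

  seldiff <- list()
  lines <- c("pHu+", "pHu-")
  prev <- list("pHu+" = idx0, "pHu-" = idx0) # candidate pools for gen 1

  pheno2 <- function(idx) {
    cfg$mu[2] + hatch_eff[hatch[idx], 2] +
      cfg$sex_effects[2] * (sex[idx] == "female") +
      cvals[idx] + bv[idx, 2] + ee[idx, 2]
  }

  for (g in seq_len(ngen)) {
    for (ln in lines) {
      cands <- prev[[ln]]
      males <- cands[sex[cands] == "male"]
      females <- cands[sex[cands] == "female"]
      y2m <- pheno2(males); y2f <- pheno2(females)
      dir <- if (ln == "pHu+") -1 else 1 # order() ascending; -1 = take high
      need_s <- cfg$sires_per_line; need_d <- cfg$dams_per_line
      if (need_s > floor(cfg$selection_fraction * length(males)) ||
          need_d > floor(cfg$selection_fraction * length(females)))
        stop("not enough candidates in line ", ln, " generation ", g,
             " under selection_fraction = ", cfg$selection_fraction)
      sires <- males[order(dir * y2m)][seq_len(need_s)]
      dams <- females[order(dir * y2f)][seq_len(need_d)]
      seldiff[[length(seldiff) + 1L]] <- data.frame(
        line = ln, generation = g,
        diff_sires = mean(pheno2(sires)) - mean(y2m),
        diff_dams = mean(pheno2(dams)) - mean(y2f))

      # each dam mated to one sire, sires used across dams
      sire_of_dam <- rep_len(sample(sires), length(dams))
      # maternal-environment draw: one per dam (per hatch)
      c_dam <- if (cfg$maternal)
        stats::rnorm(length(dams), 0, sqrt(sigma2_c)) else numeric(length(dams))
      for (k in seq_along(dams)) {
        dm <- dams[k]; sr <- sire_of_dam[k]
        noff <- cfg$offspring_per_dam
        sx <- ifelse(stats::runif(noff) < 0.5, "male", "female")
        idx <- add_birds(noff, sr, dm, sx, ln, g)
        foff <- phi(sr, dm)
        fcoef[idx] <- foff
        msv <- 0.5 * (1 - (fcoef[sr] + fcoef[dm]) / 2)
        bv[idx, ] <- rep(0.5 * (bv[sr, ] + bv[dm, ]), each = noff) +
          .rmvn2(noff, msv * G)
        ee[idx, ] <- .rmvn2(noff, R)
        cvals[idx] <- c_dam[k]
      }
    }
    for (ln in lines)
      prev[[ln]] <- which(gen == g & line == ln & seq_len(cap) <= n)
  }

  idx <- seq_len(n)
  ids <- sprintf("B%05d", idx)
  ped <- pedigree(id = ids,
                  sire = ifelse(is.na(si[idx]), NA, ids[si[idx]]),
                  dam = ifelse(is.na(di[idx]), NA, ids[di[idx]]),
                  line = line[idx], sex = sex[idx], hatch = hatch[idx],
                  generation = gen[idx])

  liab <- cfg$mu[1] + hatch_eff[hatch[idx], 1] +
    cfg$sex_effects[1] * (sex[idx] == "female") + bv[idx, 1] + ee[idx, 1]
  y2 <- pheno2(idx)
  ws <- .ws_cut(liab, cfg$thresholds)

  ws_rec <- if (is.null(cfg$ws_generations)) rep(TRUE, n) else
    gen[idx] %in% cfg$ws_generations
  t2_rec <- if (is.null(cfg$trait2_generations)) rep(TRUE, n) else
    gen[idx] %in% cfg$trait2_generations

  phen <- data.frame(id = ids, line = line[idx], sex = sex[idx],
                     hatch = hatch[idx], generation = gen[idx],
                     WS = ifelse(ws_rec, as.character(ws), NA),
                     stringsAsFactors = FALSE)
  phen[[cfg$trait2_name]] <- ifelse(t2_rec, y2, NA)

  truth <- list(config = cfg, seed = seed,
                true_G = G, true_R = R, sigma2_c = sigma2_c,
                thresholds = cfg$thresholds,
                hatch_effects = hatch_eff,
                breeding_values = stats::setNames(
                  as.data.frame(bv[idx, , drop = FALSE]),
                  c("liability", cfg$trait2_name)),
                liability = liab,
                inbreeding = fcoef[idx],
                maternal_values = cvals[idx],
                selection_differentials = do.call(rbind, seldiff))
  structure(list(pedigree = ped, phenotypes = phen, truth = truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated divergent-selection dataset:",
      nrow(x$pedigree), "individuals;",
      sum(!is.na(x$phenotypes$WS)), "with ordinal records\n")
  invisible(x)
}

#' Write or read a simulated dataset as plain-text files
#'
#' `write_dataset` emits `pedigree.csv`, `phenotypes.csv` and `truth.yaml`
#' (true variance components, thresholds, seed, realized selection
#' differentials) into `dir`; `read_dataset` reads them back.
#'
#' @param ds a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_dataset`: `dir`, invisibly. `read_dataset`: a list with
#'   `pedigree`, `phenotypes` and `truth`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  write_pedigree(ds$pedigree, file.path(dir, "pedigree.csv"))
  utils::write.table(ds$phenotypes, file.path(dir, "phenotypes.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  tr <- ds$truth
  yaml::write_yaml(list(
    seed = tr$seed,
    trait2_name = tr$config$trait2_name,
    true_G = as.numeric(tr$true_G),
    true_R = as.numeric(tr$true_R),
    sigma2_c = tr$sigma2_c,
    thresholds = tr$thresholds,
    mu = tr$config$mu,
    n_individuals = nrow(ds$pedigree)),
    file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  list(pedigree = load_pedigree(file.path(dir, "pedigree.csv")),
       phenotypes = load_phenotypes(file.path(dir, "phenotypes.csv")),
       truth = yaml::read_yaml(file.path(dir, "truth.yaml")))
}
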