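# shared fixture builders (all data generated in code)

# random valid pedigree: nf founders, then offspring of random earlier
# male/female pairs; returns a pedigree object
random_pedigree <- function(n, nf = max(4, n %/% 5), seed = 1) {
  set.seed(seed)
  id <- sprintf("i%03d", seq_len(n))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  sex[1:2] <- c("male", "female") # guarantee both sexes among founders
  sire <- dam <- rep(NA_character_, n)
  for (i in (nf + 1):n) {
    males <- which(sex[1:(i - 1)] == "male")
    females <- which(sex[1:(i - 1)] == "female")
    sire[i] <- id[males[sample.int(length(males), 1)]]
    dam[i] <- id[females[sample.int(length(females), 1)]]
  }
  pedigree(id, sire, dam, sex = sex)
}

# medium dataset (~840 birds) where the genetic/residual covariance split
# is reasonably identified
medium_sim <- function(seed, G, R, thresholds = c(0, 1.2)) {
  cfg <- sim_config(n_generations = 3, base_males = 60, base_females = 60,
                    sires_per_line = 8, dams_per_line = 20,
                    offspring_per_dam = 6, trait2_name = "Q",
                    true_G = G, true_R = R, mu = c(0, 10),
                    thresholds = thresholds, sex_effects = c(0.2, 0.3),
                    hatch_sd = c(0.1, 0.1), ws_generations = NULL,
                    selection_fraction = 1, seed = seed)
  simulate_population(cfg)
}

# small divergent-selection dataset used across sampler tests
small_sim <- function(seed = 5, ngen = 2, thresholds = c(0, 1.2),
                      G = matrix(c(1, 0.3, 0.3, 0.5), 2),
                      R = matrix(c(1, 0, 0, 0.5), 2), ...) {
  cfg <- sim_config(n_generations = ngen, base_males = 20, base_females = 20,
                    sires_per_line = 3, dams_per_line = 8,
                    offspring_per_dam = 5, trait2_name = "Q",
                    true_G = G, true_R = R, mu = c(0, 10),
                    thresholds = thresholds, sex_effects = c(0.2, 0.3),
                    hatch_sd = c(0.1, 0.1), ws_generations = NULL,
                    selection_fraction = 1, seed = seed, ...)
  simulate_population(cfg)
}
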