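# Shared fixture builders. Everything is generated in code; no data files.

# Random overlapping-generation pedigree with inbreeding: each non-founder
# draws parents from the animals already created (sex-consistent).
random_pedigree <- function(n, n_founders = max(4L, n %/% 5L), seed = 1L) {
  set.seed(seed)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")
  sire <- dam <- rep(0L, n)
  for (i in (n_founders + 1L):n) {
    prev <- seq_len(i - 1L)
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (!length(males) || !length(females)) next
    sire[i] <- if (length(males) == 1L) males else sample(males, 1L)
    dam[i] <- if (length(females) == 1L) females else sample(females, 1L)
  }
  coat <- sample(c("chestnut", "bay", "black", "gray"), n, replace = TRUE)
  raw <- data.frame(animal = seq_len(n), sire = sire, dam = dam,
                    sex = sex, coat = coat)
  validate_and_renumber(raw)
}

# Small simulated phenotype dataset for model tests.
small_dataset <- function(n_founders = 80L, n_per_generation = 80L,
                          n_generations = 2L, n_phenotyped = 150L,
                          sigma_u2 = 0.186, sigma_e2 = 0.736, seed = 42L,
                          ...) {
  cfg <- sim_config(n_founders = n_founders, n_generations = n_generations,
                    n_per_generation = n_per_generation,
                    n_phenotyped = n_phenotyped, sigma_u2 = sigma_u2,
                    sigma_e2 = sigma_e2, seed = seed, ...)
  ped <- simulate_pedigree(cfg)
  rec <- simulate_phenotypes(ped, cfg)
  list(config = cfg, pedigree = ped, records = rec)
}

# One-way records data.frame from a list of group value vectors.
grouped_records <- function(groups) {
  data.frame(
    etr = unlist(groups, use.names = FALSE),
    g = rep(names(groups), lengths(groups)),
    coat = "bay",
    stringsAsFactors = FALSE
  )
}
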