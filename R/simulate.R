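#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic-data generator:
#' pedigree shape, coat-color frequencies, fixed-effect level means and
#' shares, variance components for the two residual regimes, the target
#' rank correlation and the master seed.
#'
#' Defaults emulate the study population the pipeline is designed for:
#' 471 phenotyped sport horses inside a ~2,000-animal pedigree, coat shares
#' 16.6\% gray / 11.3\% chestnut / 51.6\% bay / 20.5\% black, additive
#' variance 0.186 and residual variance 0.736 (homogeneous regime) or
#' per-coat residuals 0.82/0.88/0.98/0.72 with additive variance 0.201
#' (heterogeneous regime), and a target Spearman correlation of 0.11 between
#' eye temperature at rest (ETR, degrees C) and competition rank.
#'
#' @param n_founders founder count (generation 0).
#' @param n_generations number of descendant generations.
#' @param n_per_generation offspring per descendant generation.
#' @param n_phenotyped number of measured animals, drawn from the latest
#'   generations.
#' @param coat_frequencies named probabilities over coat colors; must sum
#'   to 1.
#' @param base_mean baseline ETR in degrees C.
#' @param fixed_effect_levels named list: for each effect, a named numeric
#'   vector of true level means (deviations, degrees C).
#' @param fixed_effect_shares named list of level sampling probabilities,
#'   same shape as \code{fixed_effect_levels}.
#' @param interaction_sex_coat crossover interaction size (degrees C): added
#'   to female chestnut/bay records and male black records, subtracted from
#'   their sex-mirrored cells; 0 disables it.
#' @param sigma_u2 additive genetic variance (degrees C squared).
#' @param sigma_e2 residual variance: scalar (homogeneous / MGG regime) or
#'   named per-coat vector (heterogeneous / MHRV regime).
#' @param rank_correlation target Spearman correlation between ETR and rank.
#' @param event_size maximum entrants per competition event (<= 72).
#' @param coat_transmission optional square matrix of parent-to-offspring
#'   coat transition probabilities (rows = a parent's coat); \code{NULL}
#'   means offspring coats are independent draws from
#'   \code{coat_frequencies}.
#' @param n_sires_per_generation size of the active stallion pool per
#'   generation: each cohort's sires are drawn from a random subset of this
#'   many males, mirroring the strong polygyny of horse studbooks (a few
#'   stallions sire most foals, producing the large paternal half-sib
#'   families that carry most of the heritability information).
#'   \code{NULL} makes every male a candidate sire.
#' @param seed master integer seed.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(n_founders = 500L,
                       n_generations = 3L,
                       n_per_generation = n_founders,
                       n_phenotyped = 471L,
                       coat_frequencies = c(chestnut = 0.113, bay = 0.516,
                                            black = 0.205, gray = 0.166),
                       base_mean = 36.0,
                       fixed_effect_levels = list(
                         age_class = c(le4 = 0.30, a5to10 = 0.15, ge11 = 0.00),
                         sex = c(M = 0.00, F = 0.20),
                         coat = c(chestnut = 0.10, bay = 0.00,
                                  black = 0.15, gray = -0.50),
                         location = c(central = 0.15, east = 0.15, south = 0.00),
                         breed_group = c(BG1 = 0.15, BG2 = 0.15, BG3 = 0.15,
                                         BG4 = -0.10, BG5 = 0.15)
                       ),
                       fixed_effect_shares = list(
                         age_class = c(le4 = 0.106, a5to10 = 0.132, ge11 = 0.762),
                         sex = c(M = 0.66, F = 0.34),
                         location = c(central = 0.272, east = 0.469, south = 0.259),
                         breed_group = c(BG1 = 0.096, BG2 = 0.059, BG3 = 0.299,
                                         BG4 = 0.433, BG5 = 0.113)
                       ),
                       interaction_sex_coat = 0,
                       sigma_u2 = 0.186,
                       sigma_e2 = 0.736,
                       rank_correlation = 0.11,
                       event_size = 40L,
                       coat_transmission = NULL,
                       n_sires_per_generation = 60L,
                       seed = 1L) {
  if (n_founders < 1L) stop("n_founders must be positive")
  if (n_generations > 0L && n_founders < 2L)
    stop("n_founders must be >= 2 when matings are requested")
  if (n_generations < 0L) stop("n_generations must be >= 0")
  if (abs(sum(coat_frequencies) - 1) > 1e-12)
    stop("coat_frequencies must sum to 1")
  for (nm in names(fixed_effect_shares)) {
    if (abs(sum(fixed_effect_shares[[nm]]) - 1) > 1e-12)
      stop("fixed_effect_shares$", nm, " must sum to 1")
  }
  if (sigma_u2 < 0) stop("sigma_u2 must be >= 0")
  if (any(sigma_e2 < 0)) stop("sigma_e2 must be >= 0")
  if (length(sigma_e2) > 1L && is.null(names(sigma_e2)))
    stop("per-class sigma_e2 must be a named (coat) vector")
  if (abs(rank_correlation) > 1) stop("rank_correlation must lie in [-1, 1]")
  if (event_size < 1L || event_size > 72L) stop("event_size must be in 1..72")
  n_ped <- n_founders + n_generations * n_per_generation
  if (n_phenotyped > n_ped)
    stop("n_phenotyped (", n_phenotyped, ") exceeds pedigree size (", n_ped, ")")
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              n_per_generation = as.integer(n_per_generation),
              n_phenotyped = as.integer(n_phenotyped),
              coat_frequencies = coat_frequencies,
              base_mean = base_mean,
              fixed_effect_levels = fixed_effect_levels,
              fixed_effect_shares = fixed_effect_shares,
              interaction_sex_coat = interaction_sex_coat,
              sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
              rank_correlation = rank_correlation,
              event_size = as.integer(event_size),
              coat_transmission = coat_transmission,
              n_sires_per_generation =
                if (is.null(n_sires_per_generation)) NULL
                else as.integer(n_sires_per_generation),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a pedigree with coat colors
#'
#' Builds a discrete-generation pedigree: \code{n_founders} unrelated
#' founders, then \code{n_generations} cohorts of \code{n_per_generation}
#' offspring, each from a sire drawn from the generation's active stallion
#' pool and a dam drawn from all previous-generation females (no
#' self-mating; random mating otherwise). Coats are independent draws from
#' \code{coat_frequencies} unless a transmission table is supplied, in which
#' case an offspring's coat is drawn from the row of a randomly chosen
#' parent's coat. The final generation's sex ratio follows the configured
#' phenotype sex shares (the animals later measured come from it); earlier
#' generations are balanced.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A \code{pedigree_table}.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  coats <- names(config$coat_frequencies)
  nf <- config$n_founders
  draw_sex <- function(n, p_male) {
    s <- sample(c("M", "F"), n, replace = TRUE, prob = c(p_male, 1 - p_male))
    if (n >= 2L) { # both sexes must exist for mating
      if (!any(s == "M")) s[1L] <- "M"
      if (!any(s == "F")) s[2L] <- "F"
    }
    s
  }
  p_male_last <- if (!is.null(config$fixed_effect_shares$sex))
    unname(config$fixed_effect_shares$sex["M"]) else 0.5
  id <- seq_len(nf)
  sire <- dam <- rep(0L, nf)
  sex <- draw_sex(nf, 0.5)
  coat <- sample(coats, nf, replace = TRUE, prob = config$coat_frequencies)
  gen <- rep(0L, nf)
  prev <- seq_len(nf)
  for (g in seq_len(config$n_generations)) {
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (!length(males) || !length(females))
      stop("generation ", g - 1L, " lacks one sex; cannot mate")
    ns <- config$n_sires_per_generation
    if (!is.null(ns) && length(males) > ns)
      males <- sample(males, ns)
    m <- config$n_per_generation
    new_id <- max(id) + seq_len(m)
    s <- sample(males, m, replace = TRUE)
    d <- sample(females, m, replace = TRUE)
    if (is.null(config$coat_transmission)) {
      cc <- sample(coats, m, replace = TRUE, prob = config$coat_frequencies)
    } else {
      tt <- config$coat_transmission
      parent_coat <- ifelse(stats::runif(m) < 0.5, coat[s], coat[d])
      cc <- vapply(parent_coat, function(pc)
        sample(coats, 1L, prob = tt[pc, ]), character(1))
    }
    p_male <- if (g == config$n_generations) p_male_last else 0.5
    id <- c(id, new_id)
    sire <- c(sire, s)
    dam <- c(dam, d)
    sex <- c(sex, draw_sex(m, p_male))
    coat <- c(coat, cc)
    gen <- c(gen, rep(g, m))
    prev <- new_id
  }
  out <- data.frame(id = id, sire = sire, dam = dam, sex = sex, coat = coat,
                    gen = gen, label = as.character(id),
                    stringsAsFactors = FALSE)
  class(out) <- c("pedigree_table", "data.frame")
  out
}

# Recursive (mendelian-sampling) draw of breeding values over a renumbered
# pedigree: u_i = (u_s + u_d)/2 + m_i, Var(m_i) = sigma_u2 * d_i with d_i the
# inbreeding-adjusted within-family variance. Gives Var(u) = A * sigma_u2.
draw_breeding_values <- function(ped, sigma_u2) {
  n <- nrow(ped)
  if (sigma_u2 == 0) return(numeric(n))
  F <- inbreeding_ml(ped)
  dvar <- 1 / mendelian_alpha(ped, F)
  u <- numeric(n)
  z <- stats::rnorm(n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    pa <- 0
    if (s > 0L) pa <- pa + u[s] / 2
    if (d > 0L) pa <- pa + u[d] / 2
    u[i] <- pa + z[i] * sqrt(sigma_u2 * dvar[i])
  }
  u
}

#' Simulate ETR phenotypes over a pedigree
#'
#' Draws breeding values jointly with covariance \eqn{A \sigma_u^2} by
#' recursive mendelian sampling, attaches fixed-effect levels (age class,
#' sex, location, breed group; coat and sex come from the pedigree), adds a
#' residual with the variance of the record's coat class (or the common
#' variance), and assembles ETR = base mean + fixed-level means +
#' interaction + u + e. Phenotyped animals are taken from the latest
#' generations. Event ids group records of a location into competitions of
#' at most \code{event_size} entrants.
#'
#' @param ped a \code{pedigree_table} from \code{\link{simulate_pedigree}}.
#' @param config a \code{\link{sim_config}}.
#' @return data.frame of phenotype records: \code{animal}, \code{etr},
#'   \code{coat}, \code{sex}, \code{age_class}, \code{location},
#'   \code{breed_group}, \code{event}, \code{rank} (NA until
#'   \code{\link{simulate_ranks}}), \code{true_u}.
#' @export
simulate_phenotypes <- function(ped, config) {
  stopifnot(is_pedigree_table(ped), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(ped)
  if (config$n_phenotyped > n) stop("n_phenotyped exceeds pedigree size")
  u <- draw_breeding_values(ped, config$sigma_u2)
  # phenotype the most recent animals (latest generations first)
  ord <- order(-ped$gen, ped$id)
  pheno_ids <- sort(ped$id[ord[seq_len(config$n_phenotyped)]])
  m <- length(pheno_ids)
  coat <- ped$coat[pheno_ids]
  if (anyNA(coat)) stop("phenotyped animal with unrecorded coat")
  sex <- ped$sex[pheno_ids]
  draw_level <- function(effect) {
    sh <- config$fixed_effect_shares[[effect]]
    sample(names(sh), m, replace = TRUE, prob = sh)
  }
  age_class <- draw_level("age_class")
  location <- draw_level("location")
  breed_group <- draw_level("breed_group")
  lv <- config$fixed_effect_levels
  pick <- function(effect, value) {
    v <- lv[[effect]]
    if (is.null(v)) return(numeric(length(value)))
    if (!all(value %in% names(v)))
      stop("level(s) of ", effect, " missing from fixed_effect_levels")
    unname(v[value])
  }
  mu <- config$base_mean + pick("age_class", age_class) + pick("sex", sex) +
    pick("coat", coat) + pick("location", location) +
    pick("breed_group", breed_group)
  if (config$interaction_sex_coat != 0) {
    delta <- config$interaction_sex_coat
    flip <- ifelse(coat == "black", ifelse(sex == "M", 1, -1),
                   ifelse(sex == "F", 1, -1))
    mu <- mu + delta * flip
  }
  se2 <- config$sigma_e2
  if (is.null(names(se2))) {
    evar <- rep(unname(se2), m)
  } else {
    if (!all(coat %in% names(se2)))
      stop("coat class(es) missing from sigma_e2 map: ",
           paste(setdiff(unique(coat), names(se2)), collapse = ", "))
    evar <- unname(se2[coat])
  }
  e <- stats::rnorm(m, 0, sqrt(evar))
  etr <- mu + u[pheno_ids] + e
  # competitions: records of one location split into events of <= event_size
  event <- character(m)
  for (loc in unique(location)) {
    idx <- which(location == loc)
    ev <- ceiling(seq_along(idx) / config$event_size)
    event[idx] <- paste0(loc, "_", ev)
  }
  data.frame(animal = pheno_ids, etr = etr, coat = coat, sex = sex,
             age_class = age_class, location = location,
             breed_group = breed_group, event = event, rank = NA_integer_,
             true_u = u[pheno_ids], stringsAsFactors = FALSE)
}

#' Simulate competition ranks with a target Spearman correlation
#'
#' Gaussian-copula construction: each record gets a latent score
#' \eqn{z = r \cdot s + \sqrt{1 - r^2}\,\epsilon}, where \eqn{s} is the
#' record's overall normal score of ETR and \eqn{r = 2\sin(\pi\rho_s/6)}
#' converts the target Spearman correlation to the latent Pearson
#' correlation. Within each event the integer ranks \code{1..n_event} are the
#' ordering of the latent scores (rank 1 = best = lowest latent reactivity
#' score is assigned to the smallest latent value's complement; concretely,
#' higher latent score means worse rank, matching a positive ETR-rank
#' correlation).
#'
#' @param records phenotype records from \code{\link{simulate_phenotypes}}.
#' @param config a \code{\link{sim_config}}.
#' @return The records with the \code{rank} column filled.
#' @export
simulate_ranks <- function(records, config) {
  stopifnot(is.data.frame(records), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  rho <- config$rank_correlation
  r <- 2 * sin(pi * rho / 6)
  n <- nrow(records)
  s <- stats::qnorm((rank(records$etr, ties.method = "average") - 0.5) / n)
  noise <- if (abs(r) < 1) stats::rnorm(n) else numeric(n)
  z <- r * s + sqrt(max(0, 1 - r^2)) * noise
  records$rank <- NA_integer_
  for (ev in unique(records$event)) {
    idx <- which(records$event == ev)
    if (!length(idx)) {
      warning("event ", ev, " has no records; skipped")
      next
    }
    if (length(idx) > 72L) stop("event ", ev, " has more than 72 entrants")
    records$rank[idx] <- rank(z[idx], ties.method = "first")
  }
  records
}
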