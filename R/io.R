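coat_vocabulary <- c("chestnut", "bay", "black", "gray")

#' Read a phenotype CSV
#'
#' Expected header: \code{animal,etr,coat,sex,age_class,location,
#' breed_group,event,rank}. Coat labels are validated against the coat
#' vocabulary (chestnut, bay, black, gray); \code{rank} may be blank.
#'
#' @param path CSV file path.
#' @return data.frame of typed phenotype records.
#' @export
load_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal", "etr", "coat", "sex", "age_class", "location",
           "breed_group", "event", "rank")
  missing <- setdiff(req, names(d))
  if (length(missing)) stop("phenotype file misses column(s): ",
                            paste(missing, collapse = ", "))
  if (!is.numeric(d$etr)) {
    bad <- which(is.na(suppressWarnings(as.numeric(d$etr))))
    stop("non-numeric ETR in row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  bad_coat <- which(!(d$coat %in% coat_vocabulary))
  if (length(bad_coat))
    stop("unknown coat label \"", d$coat[bad_coat[1L]], "\" in row ", bad_coat[1L])
  if (!is.numeric(d$rank)) d$rank <- suppressWarnings(as.integer(d$rank))
  if (all(is.na(d$rank)))
    warning("all ranks missing; the rank-correlation stage will be skipped")
  d$animal <- as.integer(d$animal)
  d
}

#' Write a phenotype CSV
#' @param records phenotype records.
#' @param path output path.
#' @export
write_phenotypes <- function(records, path) {
  utils::write.csv(records[, c("animal", "etr", "coat", "sex", "age_class",
                               "location", "breed_group", "event", "rank")],
                   path, row.names = FALSE)
}

#' Read a pedigree CSV
#'
#' Columns \code{animal,sire,dam} and optionally \code{sex,coat}; 0 or blank
#' marks an unknown parent. The table is validated and renumbered.
#'
#' @param path CSV file path.
#' @param strict reject (instead of founder-inserting) unlisted parents.
#' @return A \code{pedigree_table}.
#' @export
load_pedigree <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_and_renumber(d, strict = strict)
}

#' Write a pedigree CSV
#' @param ped a \code{pedigree_table}.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  lab0 <- c("0", ped$label)
  out <- data.frame(animal = ped$label,
                    sire = lab0[ped$sire + 1L],
                    dam = lab0[ped$dam + 1L],
                    sex = ped$sex, coat = ped$coat)
  utils::write.csv(out, path, row.names = FALSE)
}

#' Write a sparse matrix as coordinate-format text
#' @param m a sparse Matrix.
#' @param path output path (CSV with columns row, col, value).
#' @export
write_sparse_coords <- function(m, path) {
  tm <- Matrix::summary(as(m, "TsparseMatrix"))
  utils::write.csv(data.frame(row = tm$i, col = tm$j, value = tm$x),
                   path, row.names = FALSE)
}

#' Default pipeline configuration
#'
#' Demo-scale settings: a ~2,000-animal pedigree with 471 phenotyped
#' animals, both model variants at 20,000-iteration chains (4,000 burn-in,
#' thinning 10), 5\% tests, 20\% selection. The full-scale chain settings of
#' the study design (100,000 / 10,000 / 10) can be requested with
#' \code{full_chains = TRUE}.
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param out_dir output directory for the run's tables.
#' @param full_chains use the full 100,000-iteration chain settings.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = tempfile("etr_run_"),
                                    full_chains = FALSE) {
  ni <- if (full_chains) 100000L else 20000L
  bi <- if (full_chains) 10000L else 4000L
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulation = sim_config(seed = seed),
    mgg = model_spec("MGG", n_iter = ni, burn_in = bi, thin = 10L,
                     seed = seed + 100L),
    mhrv = model_spec("MHRV", n_iter = ni, burn_in = bi, thin = 10L,
                      seed = seed + 200L),
    stats = list(alpha = 0.05,
                 effects = c("age_class", "sex", "location", "breed_group")),
    report = list(fraction = 0.20, standardization = "zscore")
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> describe -> GLM/post-hoc/correlation -> MGG fit
#' -> MHRV fit -> EBV report, writing per-stage CSV tables and a plain-text
#' run log under \code{config$out_dir}. Identical config and seed give
#' byte-identical outputs.
#'
#' @param config a configuration list from
#'   \code{\link{default_pipeline_config}} (possibly edited).
#' @return Invisibly, a list bundle with every stage's in-memory result.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run_log.txt")
  log_line <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                                "\n", file = logf, append = TRUE)
  cat("", file = logf)
  cfg_txt <- utils::capture.output(utils::str(config, digits.d = 12))
  cfg_hash <- sprintf("%08x", sum(utf8ToInt(paste(cfg_txt, collapse = "\n")) *
                                    (seq_along(utf8ToInt(paste(cfg_txt, collapse = "\n"))) %% 977)) %% 4294967296)
  writeLines(c(paste("# config hash:", cfg_hash), cfg_txt),
             file.path(config$out_dir, "config_used.txt"))
  log_line("pipeline start; master seed", config$seed, "; config hash", cfg_hash)
  log_line("R", as.character(getRversion()), "; etrgen",
           as.character(utils::packageVersion("etrgen")))

  stage <- "simulate"
  bundle <- tryCatch({
    ped <- simulate_pedigree(config$simulation)
    records <- simulate_phenotypes(ped, config$simulation)
    records <- simulate_ranks(records, config$simulation)
    write_pedigree(ped, file.path(config$out_dir, "pedigree.csv"))
    write_phenotypes(records, file.path(config$out_dir, "phenotypes.csv"))
    log_line("simulated", nrow(ped), "pedigree animals,",
             nrow(records), "phenotyped")

    stage <- "describe"
    gate <- shapiro_wilk_gate(records$etr)
    log_line(sprintf("Shapiro-Wilk W = %.4f, p = %.3g, pass = %s",
                     gate$statistic, gate$p_value, gate$pass))

    stage <- "glm"
    grid <- significance_grid(records, config$stats$effects)
    utils::write.csv(cbind(subset = rownames(grid), grid),
                     file.path(config$out_dir, "glm_significance.csv"),
                     row.names = FALSE)
    duncan <- lapply(c("coat", config$stats$effects), function(ef)
      duncan_mrt(ls_means(records, ef), alpha = config$stats$alpha))
    names(duncan) <- c("coat", config$stats$effects)
    duncan_tab <- do.call(rbind, lapply(names(duncan), function(ef)
      cbind(effect = ef, duncan[[ef]])))
    utils::write.csv(duncan_tab,
                     file.path(config$out_dir, "duncan_letters.csv"),
                     row.names = FALSE)
    cors <- if (all(is.na(records$rank))) {
      warning("ranks missing; skipping rank correlations")
      NULL
    } else {
      cs <- c(list(spearman_rank(records$etr, records$rank)),
              lapply(sort(unique(records$coat)), function(cc) {
                sub <- records[records$coat == cc, , drop = FALSE]
                spearman_rank(sub$etr, sub$rank, subset = cc)
              }))
      df <- do.call(rbind, lapply(cs, function(x)
        data.frame(subset = x$subset, rho = x$rho, p_value = x$p_value,
                   n = x$n)))
      utils::write.csv(df, file.path(config$out_dir, "rank_correlations.csv"),
                       row.names = FALSE)
      df
    }

    stage <- "fit-mgg"
    ainv_g <- a_inverse_with_groups(ped)
    fit_mgg <- gibbs_run(records, ainv_g, config$mgg)
    utils::write.csv(fit_mgg$samples,
                     file.path(config$out_dir, "chain_mgg.csv"),
                     row.names = FALSE)
    utils::write.csv(posterior_summary(fit_mgg),
                     file.path(config$out_dir, "posterior_mgg.csv"),
                     row.names = FALSE)
    log_line("MGG fitted:", nrow(fit_mgg$samples), "saved samples")

    stage <- "fit-mhrv"
    ainv_p <- a_inverse(ped)
    fit_mhrv <- gibbs_run(records, ainv_p, config$mhrv)
    utils::write.csv(fit_mhrv$samples,
                     file.path(config$out_dir, "chain_mhrv.csv"),
                     row.names = FALSE)
    utils::write.csv(posterior_summary(fit_mhrv),
                     file.path(config$out_dir, "posterior_mhrv.csv"),
                     row.names = FALSE)
    log_line("MHRV fitted:", nrow(fit_mhrv$samples), "saved samples")

    stage <- "report"
    tab_mgg <- select_top_fraction(
      ebv_table(fit_mgg$ebv, ped$coat, "MGG", config$report$standardization),
      config$report$fraction)
    tab_mhrv <- select_top_fraction(
      ebv_table(fit_mhrv$ebv, ped$coat, "MHRV", config$report$standardization),
      config$report$fraction)
    summary_fig <- ebv_selection_summary(tab_mgg, tab_mhrv,
                                         config$report$fraction)
    utils::write.csv(rbind(tab_mgg, tab_mhrv),
                     file.path(config$out_dir, "ebv_tables.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_fig$coincidence,
                     file.path(config$out_dir, "ebv_coincidence.csv"),
                     row.names = FALSE)
    log_line("report written; elapsed",
             round(as.numeric(difftime(Sys.time(), t0, units = "secs"))), "s")
    list(pedigree = ped, records = records, gate = gate,
         significance = grid, duncan = duncan, correlations = cors,
         fit_mgg = fit_mgg, fit_mhrv = fit_mhrv,
         ebv_mgg = tab_mgg, ebv_mhrv = tab_mhrv, selection = summary_fig)
  }, error = function(e) {
    log_line("FAILED at stage", stage, ":", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(bundle)
}
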