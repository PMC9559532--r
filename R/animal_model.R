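#' Animal-model specification
#'
#' Declarative description of one single-trait animal model: which variant,
#' which fixed effects, the residual-class structure, scaled-inverse
#' chi-square priors for the variance components, and the chain settings.
#'
#' The two variants mirror the two genetic models of the pipeline:
#' \describe{
#'   \item{MGG}{genetic groups by ancestor coat color, homogeneous residual
#'     variance; fixed effects age class, sex-within-coat, location, breed
#'     group.}
#'   \item{MHRV}{no groups, one residual variance per coat class of the
#'     measured animal; fixed effects age class, sex, coat, location, breed
#'     group.}
#' }
#'
#' Default priors are the flat limit of the scaled-inverse chi-square
#' (\code{nu = -2}, \code{s2 = 0}); proper weakly informative settings can be
#' supplied instead. Default chain settings are the study settings: 100,000
#' iterations, 10,000 burn-in, thinning 10 (9,000 saved samples).
#'
#' @param variant \code{"MGG"} or \code{"MHRV"}.
#' @param fixed_effects character vector of effect column names; \code{NULL}
#'   picks the variant default. The name \code{"sex_coat"} is built on the
#'   fly from \code{sex} and \code{coat} if absent from the records.
#' @param nu_u,s2_u prior degrees of freedom and scale for the additive
#'   variance.
#' @param nu_e,s2_e prior degrees of freedom and scale for the residual
#'   variance(s).
#' @param n_iter,burn_in,thin,seed chain settings.
#' @return A \code{model_spec} list.
#' @export
model_spec <- function(variant = c("MGG", "MHRV"), fixed_effects = NULL,
                       nu_u = -2, s2_u = 0, nu_e = -2, s2_e = 0,
                       n_iter = 100000L, burn_in = 10000L, thin = 10L,
                       seed = 1L) {
  variant <- match.arg(variant)
  if (is.null(fixed_effects)) {
    fixed_effects <- if (variant == "MGG")
      c("age_class", "sex_coat", "location", "breed_group")
    else
      c("age_class", "sex", "coat", "location", "breed_group")
  }
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(variant = variant, fixed_effects = fixed_effects,
                 nu_u = nu_u, s2_u = s2_u, nu_e = nu_e, s2_e = s2_e,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "model_spec")
}

#' Number of saved Gibbs samples implied by a model spec
#' @param spec a \code{model_spec}.
#' @return integer \code{(n_iter - burn_in) \%/\% thin}.
#' @export
n_saved_samples <- function(spec) {
  (spec$n_iter - spec$burn_in) %/% spec$thin
}

#' Heritability from variance components
#'
#' \eqn{h^2 = \sigma_u^2 / (\sigma_u^2 + \sigma_e^2)}; under heterogeneous
#' residual variances the shared additive variance is combined with each
#' class residual in turn, giving one class-specific heritability.
#'
#' @param sigma_u2 additive genetic variance (scalar or vector).
#' @param sigma_e2 residual variance (scalar or vector, recycled).
#' @return numeric heritability value(s).
#' @export
heritability <- function(sigma_u2, sigma_e2) {
  sigma_u2 / (sigma_u2 + sigma_e2)
}

# Residual class of each record: the measured animal's own coat under MHRV,
# a single pooled class otherwise.
residual_classes <- function(records, spec) {
  if (spec$variant == "MHRV") {
    cls <- as.character(records$coat)
    if (anyNA(cls)) stop("record(s) with missing coat under MHRV")
    factor(cls)
  } else {
    factor(rep("all", nrow(records)))
  }
}

#' Build Henderson's mixed-model equations
#'
#' Assembles the system for \code{y = Xb + Zu + e}: fixed-effect incidence
#' \code{X} (first effect fully coded, later effects drop their first level),
#' animal incidence \code{Z} against the (optionally group-augmented)
#' A-inverse, records weighted by the inverse residual variance of their
#' class. With genetic groups and fixed effects present the system has a
#' one-dimensional null space (a constant shift of all group and animal
#' equations against the fixed effects), so the last non-empty group equation
#' is absorbed (its solution fixed at zero); empty group equations are
#' dropped.
#'
#' @param records phenotype records with \code{animal} (renumbered pedigree
#'   id), \code{etr} and the effect columns.
#' @param ainv result of \code{\link{a_inverse}} or
#'   \code{\link{a_inverse_with_groups}}.
#' @param spec a \code{\link{model_spec}}.
#' @return An \code{mme_system} list; \code{mme_coefficients()} evaluates the
#'   coefficient matrix and right-hand side at given variances.
#' @export
build_mme <- function(records, ainv, spec) {
  stopifnot(is.data.frame(records), inherits(spec, "model_spec"))
  Ainv <- ainv$a_inverse
  n_u_eq <- nrow(Ainv)
  n_animals <- if (!is.null(ainv$n_animals)) ainv$n_animals else n_u_eq
  n_groups <- n_u_eq - n_animals
  if (!all(records$animal %in% seq_len(n_animals)))
    stop("phenotyped animal(s) missing from pedigree: ",
         paste(utils::head(setdiff(records$animal, seq_len(n_animals)), 5L),
               collapse = ", "))
  if ("sex_coat" %in% spec$fixed_effects && !("sex_coat" %in% names(records)))
    records$sex_coat <- interaction(records$sex, records$coat,
                                    drop = TRUE, sep = "_")
  missing_fx <- setdiff(spec$fixed_effects, names(records))
  if (length(missing_fx)) stop("fixed effect column(s) missing: ",
                               paste(missing_fx, collapse = ", "))
  dd <- records[spec$fixed_effects]
  dd[] <- lapply(dd, function(x) droplevels(factor(x)))
  single <- vapply(dd, nlevels, integer(1)) < 2L
  if (any(single)) stop("fixed effect(s) with a single level after coding: ",
                        paste(names(dd)[single], collapse = ", "))
  form <- stats::as.formula(paste("~ 0 +", paste(spec$fixed_effects, collapse = " + ")))
  X <- Matrix::sparse.model.matrix(form, data = dd)
  m <- nrow(records)
  Z <- Matrix::sparseMatrix(i = seq_len(m), j = records$animal, x = 1,
                            dims = c(m, n_u_eq))
  p <- ncol(X)

  # group bookkeeping: drop empty group equations, absorb one for rank
  keep_u <- seq_len(n_animals)
  absorbed <- integer(0)
  if (n_groups > 0L) {
    gdiag <- Matrix::diag(Ainv)[n_animals + seq_len(n_groups)]
    nonempty <- which(gdiag > 0)
    if (length(nonempty) && p > 0L) {
      absorbed <- nonempty[length(nonempty)]
      nonempty <- nonempty[-length(nonempty)]
    }
    keep_u <- c(keep_u, n_animals + nonempty)
  }
  Ainv_sub <- Ainv[keep_u, keep_u, drop = FALSE]
  W <- cbind(X, Z[, keep_u, drop = FALSE])
  cls <- residual_classes(records, spec)
  y <- records$etr
  M_list <- list(); v_list <- list(); n_k <- integer(0)
  for (k in levels(cls)) {
    rows <- which(cls == k)
    Wk <- W[rows, , drop = FALSE]
    M_list[[k]] <- Matrix::forceSymmetric(Matrix::crossprod(Wk))
    v_list[[k]] <- Matrix::crossprod(Wk, y[rows])
    n_k[k] <- length(rows)
  }
  Pmat <- Matrix::bdiag(Matrix::Diagonal(p, 0), Ainv_sub)
  structure(list(y = y, X = X, W = W, class_of_record = cls,
                 class_labels = levels(cls), M_list = M_list,
                 v_list = v_list, n_k = n_k, p = p,
                 fixed_names = colnames(X), n_animals = n_animals,
                 n_groups = n_groups, keep_u = keep_u, absorbed = absorbed,
                 group_labels = ainv$labels, Ainv_sub = Ainv_sub,
                 Pmat = Matrix::forceSymmetric(Pmat)),
            class = "mme_system")
}

#' Coefficient matrix and right-hand side at given variances
#'
#' @param mme an \code{mme_system}.
#' @param sigma_u2 additive variance.
#' @param sigma_e2 residual variance(s), named by class when heterogeneous.
#' @return list with sparse symmetric \code{C} and \code{rhs}.
#' @export
mme_coefficients <- function(mme, sigma_u2, sigma_e2) {
  if (length(sigma_e2) == 1L && is.null(names(sigma_e2)))
    sigma_e2 <- stats::setNames(rep(sigma_e2, length(mme$class_labels)),
                                mme$class_labels)
  if (!all(mme$class_labels %in% names(sigma_e2)))
    stop("sigma_e2 missing class(es): ",
         paste(setdiff(mme$class_labels, names(sigma_e2)), collapse = ", "))
  C <- mme$Pmat * (1 / sigma_u2)
  rhs <- numeric(ncol(mme$W))
  for (k in mme$class_labels) {
    w <- 1 / sigma_e2[[k]]
    C <- C + mme$M_list[[k]] * w
    rhs <- rhs + as.numeric(mme$v_list[[k]]) * w
  }
  list(C = Matrix::forceSymmetric(C), rhs = rhs)
}

#' Solve the mixed-model equations (BLUP at fixed variances)
#'
#' Direct sparse solve of Henderson's equations. Serves as the deterministic
#' fixed-variance reference for the Gibbs sampler.
#'
#' @inheritParams mme_coefficients
#' @return list with \code{b_hat} (named), \code{u_hat} (per pedigree
#'   animal; under MGG these are total breeding values, group effect
#'   included), \code{g_hat} (group solutions, absorbed group 0),
#'   \code{theta}, and the relative residual norm of the solved system.
#' @export
blup_solve <- function(mme, sigma_u2, sigma_e2) {
  stopifnot(inherits(mme, "mme_system"), sigma_u2 > 0, all(sigma_e2 > 0))
  cs <- mme_coefficients(mme, sigma_u2, sigma_e2)
  theta <- tryCatch(as.numeric(Matrix::solve(cs$C, cs$rhs)),
                    error = function(e) stop("singular mixed-model system: ",
                                             conditionMessage(e)))
  resid <- sqrt(sum((as.numeric(cs$C %*% theta) - cs$rhs)^2)) /
    max(sqrt(sum(cs$rhs^2)), .Machine$double.eps)
  b_hat <- stats::setNames(theta[seq_len(mme$p)], mme$fixed_names)
  u_all <- theta[-seq_len(mme$p)]
  u_hat <- u_all[seq_len(mme$n_animals)]
  g_hat <- NULL
  if (mme$n_groups > 0L) {
    g_hat <- stats::setNames(numeric(mme$n_groups), mme$group_labels)
    kept_groups <- mme$keep_u[mme$keep_u > mme$n_animals] - mme$n_animals
    g_hat[kept_groups] <- u_all[-seq_len(mme$n_animals)]
  }
  list(b_hat = b_hat, u_hat = u_hat, g_hat = g_hat, theta = theta,
       relative_residual = resid)
}

# Draw from N(C^-1 rhs, C^-1) given a Cholesky factorization ch of C
# (supernodal/simplicial CHMfactor with permutation): C = P' L L' P, so
# mu + P'(L')^{-1} z has the required covariance.
sample_location <- function(ch, rhs, z) {
  mu <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  w <- Matrix::solve(ch, z, system = "Lt")
  mu + as.numeric(Matrix::solve(ch, w, system = "Pt"))
}

# Precompute a pattern-aligned template so the coefficient matrix can be
# refreshed each Gibbs iteration by filling its x-slot, avoiding repeated
# sparse additions. Returns the union-pattern matrix plus, per component,
# the positions of its nonzeros inside the template's x vector.
coef_template <- function(mme) {
  comps <- c(list(P = mme$Pmat), mme$M_list)
  n <- nrow(comps[[1L]])
  key <- function(m) {
    tm <- as(as(m, "generalMatrix"), "TsparseMatrix")
    keep <- tm@i <= tm@j  # upper triangle determines the symmetric matrix
    list(k = tm@i[keep] + as.numeric(tm@j[keep]) * n, x = tm@x[keep])
  }
  keys <- lapply(comps, key)
  allk <- sort(unique(unlist(lapply(keys, `[[`, "k"))))
  # a dsCMatrix (uplo = "U") stores x column-major over the upper triangle,
  # i.e. by ascending key i + j*n: positions in sorted allk index Cpat@x
  Cpat <- Matrix::sparseMatrix(i = as.integer(allk %% n) + 1L,
                               j = as.integer(allk %/% n) + 1L,
                               x = 0, dims = c(n, n), symmetric = TRUE)
  stopifnot(Cpat@uplo == "U", length(Cpat@x) == length(allk))
  maps <- lapply(keys, function(kk)
    list(pos = match(kk$k, allk), x = kk$x))
  list(C = Cpat, maps = maps, nnz = length(allk))
}

# Fill the template at given precisions: weights named like comps
# (P = 1/sigma_u2, then one weight per residual class).
coef_fill <- function(tpl, weights) {
  x <- numeric(tpl$nnz)
  for (i in seq_along(tpl$maps)) {
    mp <- tpl$maps[[i]]
    x[mp$pos] <- x[mp$pos] + mp$x * weights[[i]]
  }
  C <- tpl$C
  C@x <- x
  C
}

#' Gibbs sampler for the single-trait animal model
#'
#' Systematic-scan Gibbs sampling of the Bayesian animal model. Location
#' parameters (fixed effects, breeding values, group effects) are drawn as
#' one Gaussian block from their joint full conditional via a sparse
#' Cholesky factorization; the additive variance is drawn from its scaled
#' inverse chi-square full conditional with degrees of freedom
#' \eqn{\nu_u + q} (q = number of pedigree animals) and scale
#' \eqn{u'A^{-1}u + \nu_u S^2_u} (group-augmented quadratic under MGG); each
#' class residual variance from degrees of freedom \eqn{\nu_e + n_k} and
#' scale \eqn{SSE_k + \nu_e S^2_e}. Samples after burn-in are saved every
#' \code{thin} iterations, together with the per-class heritability
#' \eqn{h^2_k = \sigma_u^2 / (\sigma_u^2 + \sigma^2_{e,k})}.
#'
#' @param records phenotype records.
#' @param ainv result of \code{\link{a_inverse}} (MHRV) or
#'   \code{\link{a_inverse_with_groups}} (MGG).
#' @param spec a \code{\link{model_spec}}.
#' @param start_sigma_u2,start_sigma_e2 optional starting values (defaults:
#'   half the phenotypic variance each).
#' @param fix_variances if \code{TRUE}, variances stay at their starting
#'   values and only location parameters are sampled (used to check the
#'   sampler against the BLUP solution).
#' @param keep_theta if \code{TRUE}, save the location-parameter samples as
#'   well (memory permitting).
#' @return A \code{gibbs_chain}: \code{samples} (data.frame of saved
#'   variance, heritability and derived draws), \code{theta_mean} (posterior
#'   mean of all location parameters), \code{ebv} (posterior-mean breeding
#'   values per pedigree animal), \code{b_mean}, \code{g_mean}, plus
#'   bookkeeping fields.
#' @export
gibbs_run <- function(records, ainv, spec, start_sigma_u2 = NULL,
                      start_sigma_e2 = NULL, fix_variances = FALSE,
                      keep_theta = FALSE) {
  mme <- build_mme(records, ainv, spec)
  set.seed(spec$seed)
  y <- mme$y
  vy <- stats::var(y)
  sigma_u2 <- if (is.null(start_sigma_u2)) vy / 2 else start_sigma_u2
  cls_lab <- mme$class_labels
  sigma_e2 <- if (is.null(start_sigma_e2))
    stats::setNames(rep(vy / 2, length(cls_lab)), cls_lab)
  else if (length(start_sigma_e2) == 1L && is.null(names(start_sigma_e2)))
    stats::setNames(rep(start_sigma_e2, length(cls_lab)), cls_lab)
  else start_sigma_e2[cls_lab]
  q <- mme$n_animals
  df_u <- spec$nu_u + q
  if (df_u <= 0) stop("additive-variance degrees of freedom not positive")
  n_eq <- ncol(mme$W)
  n_save <- n_saved_samples(spec)
  samp <- matrix(NA_real_, n_save,
                 1L + 2L * length(cls_lab),
                 dimnames = list(NULL, c("sigma_u2",
                                         paste0("sigma_e2_", cls_lab),
                                         paste0("h2_", cls_lab))))
  theta_keep <- if (keep_theta) matrix(NA_real_, n_save, n_eq) else NULL
  theta_sum <- numeric(n_eq)
  n_acc <- 0L
  ch <- NULL
  isave <- 0L
  u_idx <- mme$p + seq_len(length(mme$keep_u))
  tpl <- coef_template(mme)
  v_mat <- vapply(mme$v_list[cls_lab], as.numeric, numeric(n_eq))
  cls_rows <- lapply(stats::setNames(cls_lab, cls_lab),
                     function(k) which(mme$class_of_record == k))
  for (it in seq_len(spec$n_iter)) {
    w_e <- 1 / unname(sigma_e2[cls_lab])
    C <- coef_fill(tpl, c(1 / sigma_u2, w_e))
    rhs <- as.numeric(v_mat %*% w_e)
    if (is.null(ch)) {
      ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
    } else {
      ch <- Matrix::update(ch, C)
    }
    theta <- sample_location(ch, rhs, stats::rnorm(n_eq))
    if (!fix_variances) {
      u_part <- theta[u_idx]
      quad_u <- as.numeric(t(u_part) %*% (mme$Ainv_sub %*% u_part))
      sigma_u2 <- (quad_u + spec$nu_u * spec$s2_u) / stats::rchisq(1L, df_u)
      e <- y - as.numeric(mme$W %*% theta)
      for (k in cls_lab) {
        sse <- sum(e[cls_rows[[k]]]^2)
        sigma_e2[[k]] <- (sse + spec$nu_e * spec$s2_e) /
          stats::rchisq(1L, spec$nu_e + mme$n_k[[k]])
      }
      if (!all(is.finite(c(sigma_u2, sigma_e2))))
        stop("non-finite variance draw at iteration ", it,
             " (sigma_u2 = ", sigma_u2, ")")
    }
    if (it > spec$burn_in) {
      theta_sum <- theta_sum + theta
      n_acc <- n_acc + 1L
      if ((it - spec$burn_in) %% spec$thin == 0L) {
        isave <- isave + 1L
        samp[isave, ] <- c(sigma_u2, unname(sigma_e2[cls_lab]),
                           heritability(sigma_u2, unname(sigma_e2[cls_lab])))
        if (keep_theta) theta_keep[isave, ] <- theta
      }
    }
  }
  theta_mean <- theta_sum / n_acc
  b_mean <- stats::setNames(theta_mean[seq_len(mme$p)], mme$fixed_names)
  u_all <- theta_mean[-seq_len(mme$p)]
  ebv <- u_all[seq_len(mme$n_animals)]
  g_mean <- NULL
  if (mme$n_groups > 0L) {
    g_mean <- stats::setNames(numeric(mme$n_groups), mme$group_labels)
    kept_groups <- mme$keep_u[mme$keep_u > mme$n_animals] - mme$n_animals
    g_mean[kept_groups] <- u_all[-seq_len(mme$n_animals)]
  }
  structure(list(samples = as.data.frame(samp[seq_len(isave), , drop = FALSE]),
                 theta_mean = theta_mean, b_mean = b_mean, ebv = ebv,
                 g_mean = g_mean, theta_samples = theta_keep,
                 spec = spec, class_labels = cls_lab,
                 n_animals = mme$n_animals),
            class = "gibbs_chain")
}

#' Posterior summary of a chain
#'
#' Mean, standard deviation (n - 1 denominator), median and the highest
#' posterior density interval (the shortest interval containing at least
#' \code{prob} of the saved samples, found by a scan over the sorted
#' samples).
#'
#' @param x numeric vector of saved samples (>= 2), or a \code{gibbs_chain}.
#' @param prob HPD mass.
#' @param ... passed on between methods.
#' @return For a vector: list with \code{mean}, \code{sd}, \code{median},
#'   \code{hpd} (length-2). For a chain: data.frame with one row per
#'   monitored parameter.
#' @export
posterior_summary <- function(x, prob = 0.95, ...) UseMethod("posterior_summary")

#' @rdname posterior_summary
#' @export
posterior_summary.numeric <- function(x, prob = 0.95, ...) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) stop("empty chain")
  xs <- sort(x)
  k <- ceiling(prob * n)
  if (k >= n) {
    hpd <- c(xs[1L], xs[n])
  } else {
    widths <- xs[k:n] - xs[1:(n - k + 1L)]
    i <- which.min(widths)
    hpd <- c(xs[i], xs[i + k - 1L])
  }
  list(mean = mean(x), sd = stats::sd(x), median = stats::median(x),
       hpd = hpd)
}

#' @rdname posterior_summary
#' @export
posterior_summary.gibbs_chain <- function(x, prob = 0.95, ...) {
  cols <- names(x$samples)
  out <- do.call(rbind, lapply(cols, function(cn) {
    s <- posterior_summary(x$samples[[cn]], prob = prob)
    data.frame(parameter = cn, mean = s$mean, sd = s$sd, median = s$median,
               hpd_lower = s$hpd[1L], hpd_upper = s$hpd[2L])
  }))
  rownames(out) <- NULL
  out
}

# Integrated autocorrelation time by Geyer's initial positive sequence.
integrated_act <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(1)
  ac <- stats::acf(x, lag.max = min(n - 1L, 2000L), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  # ac[1] is lag 0 (= 1); pair sums Gamma_m = rho_{2m} + rho_{2m+1}
  tau <- -1
  m <- 1L
  while (m + 1L <= length(ac)) {
    gam <- ac[m] + ac[m + 1L]
    if (gam < 0) break
    tau <- tau + 2 * gam
    m <- m + 2L
  }
  max(tau, 1)
}

#' Convergence diagnostics for a chain
#'
#' Effective sample size (integrated autocorrelation time by the initial
#' positive sequence estimator) and a split-chain stationarity statistic
#' (potential scale reduction factor computed on the two halves of the
#' chain). Advisory only: values of the split statistic near 1 and an ESS
#' that is an appreciable fraction of the saved draws indicate a
#' well-behaved chain. Optionally writes the traces to a CSV for plotting.
#'
#' @param chain a \code{gibbs_chain}, or a numeric vector.
#' @param trace_file optional path for a tidy (iteration, parameter, value)
#'   CSV of the saved traces.
#' @return data.frame with \code{parameter}, \code{n_saved}, \code{ess},
#'   \code{split_rhat}.
#' @export
convergence_report <- function(chain, trace_file = NULL) {
  samples <- if (inherits(chain, "gibbs_chain")) chain$samples
             else data.frame(value = as.numeric(chain))
  diag1 <- function(x) {
    n <- length(x)
    tau <- integrated_act(x)
    h <- n %/% 2L
    a <- x[seq_len(h)]; b <- x[h + seq_len(h)]
    W <- (stats::var(a) + stats::var(b)) / 2
    B <- h * (mean(a) - mean(b))^2 / 2  # between-half variance, 2 chains
    rhat <- if (W > 0) sqrt(((h - 1) / h * W + B / h) / W) else 1
    c(n_saved = n, ess = n / tau, split_rhat = rhat)
  }
  out <- do.call(rbind, lapply(names(samples), function(cn) {
    d <- diag1(samples[[cn]])
    data.frame(parameter = cn, n_saved = d[["n_saved"]], ess = d[["ess"]],
               split_rhat = d[["split_rhat"]])
  }))
  if (!is.null(trace_file)) {
    long <- do.call(rbind, lapply(names(samples), function(cn)
      data.frame(iteration = seq_len(nrow(samples)), parameter = cn,
                 value = samples[[cn]])))
    utils::write.csv(long, trace_file, row.names = FALSE)
  }
  rownames(out) <- NULL
  out
}
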