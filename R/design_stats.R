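#' Shapiro-Wilk normality gate
#'
#' Runs the Shapiro-Wilk test and converts it into a gate: the pipeline's
#' parametric stages assume an approximately normal trait, so a failing test
#' is logged as a warning but does not stop the analysis.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @param alpha gate level.
#' @return list with \code{statistic}, \code{p_value}, \code{pass}.
#' @export
shapiro_wilk_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3L || length(values) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("constant input: W undefined")
  sw <- stats::shapiro.test(values)
  pass <- sw$p.value > alpha
  if (!pass) warning("normality gate failed (Shapiro-Wilk p = ",
                     signif(sw$p.value, 3), "); proceeding with parametric analyses")
  list(statistic = unname(sw$statistic), p_value = sw$p.value, pass = pass)
}

significance_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s.")))
}

#' One-way GLM (ANOVA) F-test for a single effect
#'
#' Classical one-way analysis of variance of ETR on one categorical effect,
#' optionally within a coat-color subset: F = MS_between / MS_within with
#' degrees of freedom (k - 1, n - k). Significance codes use the
#' 0.05 / 0.01 / 0.001 thresholds.
#'
#' @param records phenotype records (needs \code{etr} and the effect column,
#'   plus \code{coat} when subsetting).
#' @param effect name of the categorical effect column.
#' @param subset a coat label to restrict to, or \code{"all"}.
#' @return list of class \code{anova_result}: \code{effect}, \code{subset},
#'   \code{df_effect}, \code{df_error}, \code{f_value}, \code{p_value},
#'   \code{significance_code}.
#' @export
one_way_glm <- function(records, effect, subset = "all") {
  stopifnot(effect %in% names(records))
  if (!identical(subset, "all")) records <- records[records$coat == subset, , drop = FALSE]
  g <- as.character(records[[effect]])
  y <- records$etr
  keep <- !is.na(g) & !is.na(y)
  g <- g[keep]; y <- y[keep]
  tab <- table(g)
  if (any(tab == 0L)) {
    warning("dropping empty level(s) of ", effect)
    tab <- tab[tab > 0L]
  }
  k <- length(tab)
  if (k < 2L) stop("effect ", effect, " has fewer than 2 non-empty levels in subset ", subset)
  n <- length(y)
  sums <- tapply(y, g, sum)
  ns <- tapply(y, g, length)
  ss_between <- sum(sums^2 / ns) - sum(y)^2 / n
  ss_total <- sum(y^2) - sum(y)^2 / n
  ss_within <- ss_total - ss_between
  df1 <- k - 1L
  df2 <- n - k
  if (df2 < 1L) stop("no error degrees of freedom")
  f <- (ss_between / df1) / (ss_within / df2)
  if (ss_within == 0 && ss_between == 0) f <- 0
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  structure(list(effect = effect, subset = subset, df_effect = df1,
                 df_error = df2, f_value = f, p_value = p,
                 significance_code = significance_code(p),
                 ms_within = ss_within / df2,
                 level_n = as.vector(ns), level_names = names(ns)),
            class = "anova_result")
}

#' Coat-by-effect interaction test
#'
#' Fits the additive two-factor linear model \code{etr ~ coat + effect} and
#' the full model with the \code{coat:effect} interaction, and F-tests the
#' interaction term from the residual-sum-of-squares difference. Empty cells
#' reduce the interaction degrees of freedom naturally through the rank of
#' the design.
#'
#' @inheritParams one_way_glm
#' @return An \code{anova_result} for the interaction term.
#' @export
interaction_glm <- function(records, effect) {
  stopifnot(effect %in% names(records), "coat" %in% names(records))
  d <- data.frame(y = records$etr,
                  coat = factor(records$coat),
                  eff = factor(records[[effect]]))
  d <- stats::na.omit(d)
  d <- droplevels(d)
  if (nlevels(d$coat) < 2L || nlevels(d$eff) < 2L)
    stop("both coat and ", effect, " need >= 2 levels for an interaction test")
  fit_add <- stats::lm(y ~ coat + eff, data = d)
  fit_full <- stats::lm(y ~ coat * eff, data = d)
  an <- stats::anova(fit_add, fit_full)
  df1 <- an$Df[2L]
  if (is.na(df1) || df1 < 1L) stop("interaction has no degrees of freedom (empty cells)")
  f <- an$F[2L]
  p <- an$`Pr(>F)`[2L]
  structure(list(effect = paste0("coat:", effect), subset = "all",
                 df_effect = df1, df_error = fit_full$df.residual,
                 f_value = f, p_value = p,
                 significance_code = significance_code(p)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("%s (%s): F(%d, %d) = %.3f, p = %.4g %s\n", x$effect, x$subset,
              x$df_effect, x$df_error, x$f_value, x$p_value,
              x$significance_code))
  invisible(x)
}

#' Least-squares means per level
#'
#' For the one-way layout the least-squares means equal the arithmetic level
#' means; standard errors are \eqn{\sqrt{MS_{within} / n_{level}}} from the
#' fitted one-way model.
#'
#' @inheritParams one_way_glm
#' @return data.frame with \code{level}, \code{ls_mean}, \code{standard_error},
#'   \code{n}, and an empty \code{letters} column (filled by
#'   \code{\link{duncan_mrt}}); \code{ms_within} and \code{df_error} attached
#'   as attributes.
#' @export
ls_means <- function(records, effect, subset = "all") {
  an <- one_way_glm(records, effect, subset)
  if (!identical(subset, "all")) records <- records[records$coat == subset, , drop = FALSE]
  g <- as.character(records[[effect]])
  y <- records$etr
  keep <- !is.na(g) & !is.na(y)
  g <- g[keep]; y <- y[keep]
  mns <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  out <- data.frame(level = names(mns), ls_mean = as.vector(mns),
                    standard_error = sqrt(an$ms_within / as.vector(ns)),
                    n = as.vector(ns), letters = "",
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ls_mean), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ms_within") <- an$ms_within
  attr(out, "df_error") <- an$df_error
  out
}

#' Duncan's multiple range test
#'
#' Assigns letter groups to sorted level means. The critical range for a
#' span of \eqn{p} consecutive ordered means is
#' \eqn{R_p = q_{\alpha_p}(p, df)\sqrt{MS_{within}/n_h}} with the
#' Duncan protection level \eqn{\alpha_p = 1 - (1-\alpha)^{p-1}},
#' studentized-range quantiles from \code{\link[stats]{qtukey}}, and
#' \eqn{n_h} the harmonic mean of the level counts (classical unbalanced
#' extension). Levels sharing a letter are not significantly different.
#'
#' @param groupings output of \code{\link{ls_means}} (or a data.frame with
#'   \code{level}, \code{ls_mean}, \code{n}).
#' @param ms_within within-group mean square (defaults to the attribute left
#'   by \code{ls_means}).
#' @param df_error error degrees of freedom (same default).
#' @param alpha test level.
#' @return The groupings data.frame, sorted by descending mean, with the
#'   \code{letters} column filled.
#' @export
duncan_mrt <- function(groupings, ms_within = attr(groupings, "ms_within"),
                       df_error = attr(groupings, "df_error"), alpha = 0.05) {
  if (is.null(ms_within) || is.null(df_error))
    stop("ms_within and df_error are required")
  if (df_error <= 0) stop("df_error must be positive")
  if (ms_within <= 0) stop("ms_within must be positive")
  g <- groupings[order(-groupings$ls_mean), , drop = FALSE]
  k <- nrow(g)
  if (k < 2L) stop("Duncan test needs >= 2 levels")
  n_h <- k / sum(1 / g$n)
  crit <- vapply(2:k, function(p) {
    alpha_p <- 1 - (1 - alpha)^(p - 1)
    stats::qtukey(1 - alpha_p, p, df_error) * sqrt(ms_within / n_h)
  }, numeric(1))
  differ <- function(i, j) { # TRUE if means ranked i..j (i<j) are declared different
    span <- j - i + 1L
    abs(g$ls_mean[i] - g$ls_mean[j]) > crit[span - 1L]
  }
  # standard letter sweep: for each i, extend the non-significant run, emit a
  # letter for every maximal run
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !differ(i, j + 1L)) j <- j + 1L
    runs[[i]] <- c(i, j)
  }
  # keep maximal runs only
  keep <- vapply(seq_along(runs), function(r) {
    !any(vapply(seq_along(runs), function(s) {
      s != r && runs[[s]][1] <= runs[[r]][1] && runs[[s]][2] >= runs[[r]][2]
    }, logical(1)))
  }, logical(1))
  runs <- unique(runs[keep])
  letters_out <- rep("", k)
  for (r in seq_along(runs)) {
    idx <- runs[[r]][1]:runs[[r]][2]
    letters_out[idx] <- paste0(letters_out[idx], letters[r])
  }
  g$letters <- letters_out
  rownames(g) <- NULL
  g
}

#' Spearman rank correlation with competition rank
#'
#' Tie-safe Spearman correlation: Pearson correlation of mid-ranks, with the
#' p-value from the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom
#' (two-sided).
#'
#' @param x,y paired numeric vectors (NA pairs dropped), n >= 3.
#' @param subset label carried into the result (e.g., a coat class).
#' @return list of class \code{rank_correlation}: \code{rho}, \code{p_value},
#'   \code{n}, \code{subset}.
#' @export
spearman_rank <- function(x, y, subset = "all") {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("Spearman correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: Spearman correlation undefined")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  structure(list(rho = rho, p_value = p, n = n, subset = subset),
            class = "rank_correlation")
}

#' @export
print.rank_correlation <- function(x, ...) {
  cat(sprintf("Spearman rho (%s): %.3f (n = %d, p = %.4g)\n",
              x$subset, x$rho, x$n, x$p_value))
  invisible(x)
}

#' Table of per-effect significance codes
#'
#' Reproduces the effect-by-subset grid of one-way F-test significance
#' codes: one row for the total population, one per coat class, plus the
#' coat-by-effect interaction row.
#'
#' @param records phenotype records.
#' @param effects effect columns to test.
#' @return data.frame grid of significance codes.
#' @export
significance_grid <- function(records,
                              effects = c("age_class", "sex", "location",
                                          "breed_group")) {
  coats <- sort(unique(records$coat))
  rows <- c("total", "interaction", coats)
  out <- matrix("", nrow = length(rows), ncol = length(effects),
                dimnames = list(rows, effects))
  for (ef in effects) {
    out["total", ef] <- one_way_glm(records, ef)$significance_code
    out["interaction", ef] <- tryCatch(
      interaction_glm(records, ef)$significance_code,
      error = function(e) NA_character_)
    for (cc in coats) {
      out[cc, ef] <- tryCatch(one_way_glm(records, ef, subset = cc)$significance_code,
                              error = function(e) NA_character_)
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
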