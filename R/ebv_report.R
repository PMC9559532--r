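#' Standardize estimated breeding values to the 80-120 scale
#'
#' Linear map \eqn{s = 100 + 5 (e - \bar e)/sd(e)}, then clipped to
#' [80, 120]: one genetic standard deviation is 5 points, so plus or minus
#' four standard deviations span the interval, and the population average is
#' exactly 100 before clipping. A min-max variant mapping the observed range
#' onto [80, 120] is available.
#'
#' @param ebv_raw numeric vector of raw EBVs (posterior means of u).
#' @param method \code{"zscore"} (default) or \code{"minmax"}.
#' @return numeric vector of standardized EBVs in [80, 120].
#' @export
standardize_ebv <- function(ebv_raw, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  if (length(ebv_raw) < 2L) stop("need at least 2 animals to standardize")
  s <- stats::sd(ebv_raw)
  if (s == 0) return(rep(100, length(ebv_raw)))
  out <- if (method == "zscore") {
    100 + 5 * (ebv_raw - mean(ebv_raw)) / s
  } else {
    80 + 40 * (ebv_raw - min(ebv_raw)) / (max(ebv_raw) - min(ebv_raw))
  }
  pmin(pmax(out, 80), 120)
}

#' Build an EBV table for one fitted model
#'
#' @param ebv_raw named or plain numeric vector of raw EBVs, one per
#'   evaluated animal (pedigree order).
#' @param coat coat label per animal.
#' @param model_tag \code{"MGG"} or \code{"MHRV"}.
#' @param method standardization variant, see \code{\link{standardize_ebv}}.
#' @return data.frame with \code{animal_id}, \code{coat}, \code{model_tag},
#'   \code{ebv_raw}, \code{ebv_std}, \code{selected} (filled by
#'   \code{\link{select_top_fraction}}).
#' @export
ebv_table <- function(ebv_raw, coat, model_tag, method = "zscore") {
  stopifnot(length(ebv_raw) == length(coat))
  data.frame(animal_id = seq_along(ebv_raw), coat = as.character(coat),
             model_tag = model_tag, ebv_raw = as.numeric(ebv_raw),
             ebv_std = standardize_ebv(ebv_raw, method), selected = FALSE,
             stringsAsFactors = FALSE)
}

#' Select the top fraction of animals by EBV
#'
#' Marks the \code{floor(fraction * n)} animals with the highest
#' standardized EBVs as selected. Ties at the cutoff are broken by animal id
#' (lower id wins), making the selection deterministic.
#'
#' @param tab an EBV table from \code{\link{ebv_table}}.
#' @param fraction selected fraction in (0, 1].
#' @return The table with the \code{selected} column set.
#' @export
select_top_fraction <- function(tab, fraction = 0.20) {
  stopifnot(fraction > 0, fraction <= 1)
  n_sel <- floor(fraction * nrow(tab))
  ord <- order(-tab$ebv_std, tab$animal_id)
  tab$selected <- FALSE
  tab$selected[ord[seq_len(n_sel)]] <- TRUE
  tab
}

#' Cross-model coincidence of selected animals by coat group
#'
#' Compares the top-fraction selections of two genetic evaluations over the
#' same animals and counts, per coat class, the animals selected by both.
#' The coincidence percentage uses the first selection's (MGG) group size as
#' denominator; the symmetric Jaccard index is reported alongside.
#'
#' @param tab_mgg,tab_mhrv EBV tables (with \code{selected} filled) from the
#'   two models, over the same animal universe.
#' @return data.frame per coat class (plus a \code{total} row): group sizes
#'   of each selection, intersection count, \code{coincidence_pct},
#'   \code{jaccard}.
#' @export
model_coincidence <- function(tab_mgg, tab_mhrv) {
  if (nrow(tab_mgg) != nrow(tab_mhrv) ||
      !all(tab_mgg$animal_id == tab_mhrv$animal_id) ||
      !all(tab_mgg$coat == tab_mhrv$coat))
    stop("selections come from different animal universes")
  sel1 <- tab_mgg$animal_id[tab_mgg$selected]
  sel2 <- tab_mhrv$animal_id[tab_mhrv$selected]
  coat_of <- stats::setNames(tab_mgg$coat, tab_mgg$animal_id)
  coats <- sort(unique(tab_mgg$coat))
  one <- function(ids1, ids2, label) {
    both <- intersect(ids1, ids2)
    data.frame(coat = label, n_mgg = length(ids1), n_mhrv = length(ids2),
               n_coincident = length(both),
               coincidence_pct = if (length(ids1)) 100 * length(both) / length(ids1) else NA_real_,
               jaccard = if (length(union(ids1, ids2)))
                 length(both) / length(union(ids1, ids2)) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(coats, function(cc)
    one(sel1[coat_of[as.character(sel1)] == cc],
        sel2[coat_of[as.character(sel2)] == cc], cc)))
  rbind(out, one(sel1, sel2, "total"))
}

#' Figure-style EBV summary by coat and model
#'
#' Mean standardized EBV and group size of the selected animals per coat
#' class and model, with the coincident counts attached: the tabular
#' equivalent of the cross-model selection comparison plot.
#'
#' @inheritParams model_coincidence
#' @param fraction selection fraction used (for the header only).
#' @return list with \code{by_group} (coat x model means among selected) and
#'   \code{coincidence} (from \code{\link{model_coincidence}}).
#' @export
ebv_selection_summary <- function(tab_mgg, tab_mhrv, fraction = 0.20) {
  by_group <- do.call(rbind, lapply(list(tab_mgg, tab_mhrv), function(tb) {
    sel <- tb[tb$selected, , drop = FALSE]
    agg <- stats::aggregate(ebv_std ~ coat, data = sel, FUN = mean)
    agg$n <- stats::aggregate(ebv_std ~ coat, data = sel, FUN = length)$ebv_std
    agg$model_tag <- tb$model_tag[1L]
    agg
  }))
  names(by_group)[names(by_group) == "ebv_std"] <- "mean_ebv_std"
  list(fraction = fraction, by_group = by_group,
       coincidence = model_coincidence(tab_mgg, tab_mhrv))
}
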