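# aim_selection: rank candidate markers by intercontinental allele-frequency
# differentials, then pick the panel with lowest Native American expected
# heterozygosity among the top-ranked candidates (reducing sensitivity to
# allele-frequency variation between Native American groups).

#' Select ancestry-informative markers
#'
#' Candidates are ranked by the differential statistic (default: the larger
#' of |f_EUR - f_NAM| and |f_EUR - f_AFR|). Within the top `top_fraction`
#' of that ranking, the `n_select` markers with lowest Native American
#' expected heterozygosity 2f(1-f) are returned; ties are broken
#' lexicographically by marker id, so output is deterministic.
#'
#' @param candidates data.frame with columns `marker_id`, `AFR`, `EUR`,
#'   `NAM` (allele frequencies), or a [parental_panel()]
#' @param n_select panel size to return
#' @param top_fraction fraction of the differential ranking considered
#'   (default 0.2)
#' @param combine how the two EUR-involving pairwise differentials are
#'   combined: `"max"` (default) or `"sum"`
#' @return character vector of `n_select` marker ids; the full diagnostics
#'   table is attached as attribute `"table"` (per-pair deltas, NAM
#'   heterozygosity, rank, selected flag)
#' @export
select_aims <- function(candidates, n_select, top_fraction = 0.2,
                        combine = c("max", "sum")) {
  combine <- match.arg(combine)
  if (inherits(candidates, "parental_panel"))
    candidates <- data.frame(marker_id = candidates$marker_ids,
                             candidates$freqs, check.names = FALSE)
  need <- c("marker_id", "AFR", "EUR", "NAM")
  if (!all(need %in% names(candidates)))
    stop_config("candidate table must have columns %s", paste(need, collapse = ", "))
  if (top_fraction <= 0 || top_fraction > 1)
    stop_config("top_fraction must lie in (0, 1]")
  d_en <- abs(candidates$EUR - candidates$NAM)
  d_ea <- abs(candidates$EUR - candidates$AFR)
  diff_stat <- if (combine == "max") pmax(d_en, d_ea) else d_en + d_ea
  het_nam <- 2 * candidates$NAM * (1 - candidates$NAM)
  ord <- order(-diff_stat, candidates$marker_id)
  n_top <- max(1L, ceiling(top_fraction * nrow(candidates)))
  if (n_select > n_top)
    stop_config("n_select = %d exceeds the %d candidates in the top fraction",
                n_select, n_top)
  top_ids <- candidates$marker_id[ord[seq_len(n_top)]]
  top <- candidates$marker_id %in% top_ids
  pick_ord <- order(het_nam, candidates$marker_id)
  pick_ord <- pick_ord[top[pick_ord]]
  sel <- sort(candidates$marker_id[pick_ord[seq_len(n_select)]])
  tab <- data.frame(marker_id = candidates$marker_id,
                    delta_EUR_NAM = d_en, delta_EUR_AFR = d_ea,
                    diff_stat = diff_stat, het_NAM = het_nam,
                    diff_rank = match(candidates$marker_id,
                                      candidates$marker_id[ord]),
                    in_top_fraction = top,
                    selected = candidates$marker_id %in% sel)
  admix_log("selected %d of %d candidates (top fraction %.2f = %d markers)",
            n_select, nrow(candidates), top_fraction, n_top)
  structure(sel, table = tab)
}

#' Estimation accuracy as a function of panel size
#'
#' For each requested size, selects that many markers from the cohort's
#' parental panel with [select_aims()], re-estimates ancestry from the
#' cohort genotypes restricted to the selected markers, and reports the
#' Pearson correlation of the estimates with the cohort's true ancestry,
#' per component. Quantifies the diminishing return in accuracy as the
#' panel grows.
#'
#' @param panel_sizes integer vector of panel sizes
#' @param cohort a [simulate_cohort()] result (or any list with
#'   `genotypes`, `parental_freqs`, `true_q`)
#' @param top_fraction passed to [select_aims()]
#' @return data.frame: size, one correlation column per ancestry component,
#'   and their mean
#' @export
panel_accuracy_curve <- function(panel_sizes, cohort, top_fraction = 0.2) {
  if (length(panel_sizes) == 0) stop_config("panel_sizes is empty")
  panel <- cohort$parental_freqs
  if (any(panel_sizes > nrow(panel$freqs)))
    stop_config("panel size exceeds the %d available markers", nrow(panel$freqs))
  rows <- lapply(panel_sizes, function(sz) {
    ids <- select_aims(panel, sz, top_fraction = top_fraction)
    al <- align_panel(cohort$genotypes[, ids, drop = FALSE],
                      panel)
    est <- estimate_ancestry(al$genotypes, al$panel)
    cors <- vapply(colnames(cohort$true_q), function(k)
      stats::cor(est$q[, k], cohort$true_q[, k]), numeric(1))
    c(size = sz, cors, mean_cor = mean(cors))
  })
  as.data.frame(do.call(rbind, rows))
}
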