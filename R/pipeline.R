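# Whole-run orchestration: preprocess -> search -> validate, per-spectrum
# summaries, and the neutral-loss threshold sweep.

#' Identify phosphopeptides in a set of spectra
#'
#' Runs the full per-spectrum chain: charge filter, normalization, bin
#' denoising, neutral-loss prescreen, composite-database search and
#' decoy-based significance filtering. Spectra failing the prescreen are
#' reported as not selected, with empty hit lists.
#'
#' @param spectra list of `ms2_spectrum`.
#' @param db a `composite_db`.
#' @param params a [search_params()].
#' @param nl_threshold neutral-loss intensity threshold in `[0, 100]`.
#' @param sig a [significance_config()] (default: alpha_whole 0.05 over the
#'   database's K, gumbel tail).
#' @param max_z maximum precursor charge (default 4).
#' @param nl_tolerance neutral-loss tolerance numerator in Da (default 3).
#' @param max_losses maximum H3PO4 losses considered (default 4).
#' @return list with `summary` (data.frame: `spectrum_id`, `passed_nl`,
#'   `n_hits`, `n_significant`, `top_hit_phospho`, `best_modseq`,
#'   `best_score`, `best_p`) and `hits` (named list per spectrum with
#'   `target`, `decoy`, `significant`).
#' @export
identify_spectra <- function(spectra, db, params = search_params(),
                             nl_threshold = 30,
                             sig = significance_config(0.05, db_K(db)),
                             max_z = 4L, nl_tolerance = 3.0,
                             max_losses = 4L) {
  processed <- preprocess_spectra(spectra, nl_threshold, max_z,
                                  nl_tolerance, max_losses)
  n <- length(processed)
  summ <- data.frame(
    spectrum_id = vapply(processed, `[[`, character(1), "spectrum_id"),
    passed_nl = vapply(processed, nl_passed, logical(1)),
    n_hits = 0L, n_significant = 0L, top_hit_phospho = FALSE,
    best_modseq = NA_character_, best_score = NA_real_, best_p = NA_real_,
    stringsAsFactors = FALSE)
  hits <- vector("list", n)
  names(hits) <- summ$spectrum_id
  for (i in seq_len(n)) {
    if (!summ$passed_nl[i]) next
    res <- search_spectrum(processed[[i]], db, params)
    fs <- filter_significant(res$target, res$decoy$score, sig)
    hits[[i]] <- list(target = fs$annotated, decoy = res$decoy,
                      significant = fs$significant)
    summ$n_hits[i] <- nrow(res$target)
    summ$n_significant[i] <- nrow(fs$significant)
    if (nrow(fs$annotated) > 0L) {
      summ$top_hit_phospho[i] <- fs$annotated$n_phospho[1L] > 0L
      summ$best_modseq[i] <- fs$annotated$modseq[1L]
      summ$best_score[i] <- fs$annotated$score[1L]
      summ$best_p[i] <- fs$annotated$p_value[1L]
    }
  }
  list(summary = summ, hits = hits)
}

#' Neutral-loss threshold sweep
#'
#' Re-applies the neutral-loss prescreen over a grid of intensity
#' thresholds. The search is run once (at the most permissive threshold);
#' because the set of selected spectra can only shrink as the threshold
#' grows, per-threshold results are obtained by masking. Returns the
#' per-threshold selection counts and detection metrics — the shape of a
#' threshold tuning table.
#'
#' @param spectra list of `ms2_spectrum`.
#' @param db a `composite_db`.
#' @param truth truth data.frame (`spectrum_id`, `modseq`).
#' @param thresholds numeric vector (default `seq(0, 100, by = 10)`).
#' @param params a [search_params()].
#' @param sig a [significance_config()].
#' @param mode `"all_hits"` or `"significant"` for the metric columns.
#' @return data.frame: one row per threshold with `n_selected`,
#'   `n_selected_phospho`, `n_selected_nonphospho`, `TP`, `FP`, `FN`,
#'   `TN` and the six indexes.
#' @export
nl_threshold_sweep <- function(spectra, db, truth,
                               thresholds = seq(0, 100, by = 10),
                               params = search_params(),
                               sig = significance_config(0.05, db_K(db)),
                               mode = "all_hits") {
  base <- identify_spectra(spectra, db, params, nl_threshold = min(thresholds),
                           sig = sig)
  processed <- preprocess_spectra(spectra, min(thresholds))
  truth$is_phospho <- nzchar(truth$modseq)
  rows <- lapply(thresholds, function(th) {
    passed <- vapply(processed, function(s)
      nl_passed(neutral_loss_check(s, th)), logical(1))
    pred <- base$summary
    pred$passed_nl <- passed[match(pred$spectrum_id,
                                   vapply(processed, `[[`, character(1),
                                          "spectrum_id"))]
    cc <- confusion(pred, truth[, c("spectrum_id", "is_phospho")],
                    mode = mode)
    met <- suppressWarnings(metrics(cc, digits = NA))
    is_phos <- truth$is_phospho[match(pred$spectrum_id, truth$spectrum_id)]
    data.frame(threshold = th,
               n_selected = sum(pred$passed_nl),
               n_selected_phospho = sum(pred$passed_nl & is_phos),
               n_selected_nonphospho = sum(pred$passed_nl & !is_phos),
               TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN,
               t(met))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
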