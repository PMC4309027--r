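# Detection/localization performance evaluation: confusion counts, the six
# standard indexes, and sequence/site correctness checks.

#' Confusion counts for phospho-spectrum detection
#'
#' A spectrum is called positive when it passed the neutral-loss prescreen
#' and has at least one (or, in `"significant"` mode, at least one
#' significant) target hit. With `tp_rule = "top_hit_phospho"` the call
#' additionally requires the top-ranked hit to carry a phospho group — the
#' convention used when benchmarking rank-1-reporting engines.
#'
#' @param predictions data.frame with one row per spectrum: `spectrum_id`,
#'   `passed_nl` (logical), `n_hits`, `n_significant` (integers), and, for
#'   the `top_hit_phospho` rule, `top_hit_phospho` (logical).
#' @param truth data.frame: `spectrum_id`, `is_phospho` (logical).
#' @param mode `"all_hits"` (default) or `"significant"`.
#' @param tp_rule `"any_hit"` (default) or `"top_hit_phospho"`.
#' @return a `confusion_counts` list with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(predictions, truth,
                      mode = c("all_hits", "significant"),
                      tp_rule = c("any_hit", "top_hit_phospho")) {
  mode <- match.arg(mode)
  tp_rule <- match.arg(tp_rule)
  if (!setequal(predictions$spectrum_id, truth$spectrum_id) ||
      nrow(predictions) != nrow(truth))
    stop("prediction and truth spectrum IDs do not match 1:1")
  m <- match(truth$spectrum_id, predictions$spectrum_id)
  pred <- predictions[m, , drop = FALSE]
  nh <- if (mode == "all_hits") pred$n_hits else pred$n_significant
  called <- pred$passed_nl & nh >= 1L
  if (tp_rule == "top_hit_phospho") called <- called & pred$top_hit_phospho
  phos <- truth$is_phospho
  structure(list(TP = sum(called & phos), FP = sum(called & !phos),
                 FN = sum(!called & phos), TN = sum(!called & !phos)),
            class = "confusion_counts")
}

#' Construct confusion counts directly
#' @param TP,FP,FN,TN non-negative integer counts.
#' @return a `confusion_counts` list.
#' @export
confusion_counts <- function(TP, FP, FN, TN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN),
            class = "confusion_counts")
}

# half-away-from-zero rounding, the convention of the printed tables
round_half_up <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' The six performance indexes from confusion counts
#'
#' sensitivity (recall) TP/(TP+FN); specificity TN/(TN+FP); accuracy
#' (TP+TN)/all; FDR FP/(TP+FP); precision TP/(TP+FP); F-measure
#' 2*precision*recall/(precision+recall). Ratios with a zero denominator
#' are reported as `NA` with a warning, never silently as 0.
#'
#' @param counts a `confusion_counts`.
#' @param digits rounding digits (default 3, half away from zero, matching
#'   conventional table formatting); `NA` for unrounded values.
#' @return named numeric vector: `sensitivity`, `specificity`, `accuracy`,
#'   `fdr`, `precision`, `f_measure`.
#' @export
metrics <- function(counts, digits = 3L) {
  TP <- unname(counts$TP); FP <- unname(counts$FP)
  FN <- unname(counts$FN); TN <- unname(counts$TN)
  total <- TP + FP + FN + TN
  rat <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NA_real_)
    }
    num / den
  }
  sens <- rat(TP, TP + FN, "sensitivity")
  spec <- rat(TN, TN + FP, "specificity")
  acc <- rat(TP + TN, total, "accuracy")
  fdr <- rat(FP, TP + FP, "FDR")
  prec <- rat(TP, TP + FP, "precision")
  f <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) {
    warning("F-measure undefined")
    NA_real_
  } else 2 * prec * sens / (prec + sens)
  out <- c(sensitivity = sens, specificity = spec, accuracy = acc,
           fdr = fdr, precision = prec, f_measure = f)
  if (!is.na(digits)) out <- round_half_up(out, digits)
  out
}

#' Sequence and phosphosite correctness of a hit list
#'
#' @param hit_modseqs character vector of hit modified sequences (the
#'   target list or its significant sublist), phospho residues lower-case.
#' @param truth_modseq the true modified sequence.
#' @return list with logicals `sequence_found` (some hit has the right
#'   plain sequence) and `site_correct` (some hit equals the truth exactly,
#'   i.e. right sequence and right sites).
#' @export
sequence_site_check <- function(hit_modseqs, truth_modseq) {
  if (length(hit_modseqs) == 0L)
    return(list(sequence_found = FALSE, site_correct = FALSE))
  list(sequence_found = any(unmodified_sequence(hit_modseqs) ==
                              unmodified_sequence(truth_modseq)),
       site_correct = any(hit_modseqs == truth_modseq))
}

#' Read / write the spectrum truth table
#'
#' Tab-separated: `spectrum_id`, `modseq` (empty string for non-phospho
#' spectra), `charge`.
#'
#' @param truth data.frame (writer) / path (reader).
#' @param path output path.
#' @return `path` invisibly (writer); data.frame (reader).
#' @export
write_truth <- function(truth, path) {
  data.table::fwrite(truth, path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t",
                                  colClasses = list(character = "modseq"),
                                  na.strings = NULL))
}
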