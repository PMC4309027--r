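# Candidate generation and scoring: precursor mass matching, phosphosite
# isomer enumeration, b/y (+neutral loss) theoretical spectra and the
# sigmoid intensity-weighted match score.

#' Search parameters
#'
#' @param precursor_tol precursor mass tolerance value (default 7).
#' @param precursor_unit `"ppm"` (default) or `"Da"`.
#' @param fragment_tol fragment tolerance in Da (default 0.8).
#' @param max_fragment_charge highest fragment charge generated; fragments
#'   are produced at charges `1..min(max_fragment_charge, precursor z)`
#'   (default 1: the dominant species for CID of tryptic 2+/3+ precursors).
#' @return a `search_params` list.
#' @export
search_params <- function(precursor_tol = 7, precursor_unit = c("ppm", "Da"),
                          fragment_tol = 0.8, max_fragment_charge = 1L) {
  precursor_unit <- match.arg(precursor_unit)
  stopifnot(precursor_tol > 0, fragment_tol > 0, max_fragment_charge >= 1L)
  structure(list(precursor_tol = precursor_tol,
                 precursor_unit = precursor_unit,
                 fragment_tol = fragment_tol,
                 max_fragment_charge = as.integer(max_fragment_charge)),
            class = "search_params")
}

precursor_delta <- function(params, precursor_mass) {
  if (params$precursor_unit == "ppm")
    params$precursor_tol * precursor_mass / 1e6
  else params$precursor_tol
}

#' Candidate peptides for a spectrum by precursor mass
#'
#' Matches database entries (target and decoy) whose neutral mass lies
#' within the tolerance window of the spectrum's neutral precursor mass;
#' the comparison is inclusive.
#'
#' @param db a `composite_db`.
#' @param spectrum an `ms2_spectrum`.
#' @param params a [search_params()].
#' @return subset of `db` (possibly empty).
#' @export
precursor_candidates <- function(db, spectrum, params = search_params()) {
  x <- precursor_neutral_mass(spectrum)
  db_mass_query(db, x, precursor_delta(params, x))
}

#' Enumerate phosphosite placements
#'
#' All C(#S/T sites, n_phospho) placements, ordered lexicographically by
#' position tuple.
#'
#' @param sequence peptide sequence.
#' @param n_phospho number of phospho groups to place.
#' @return list of integer vectors of 1-based phosphorylated positions
#'   (a single empty vector when `n_phospho = 0`).
#' @export
enumerate_site_configs <- function(sequence, n_phospho) {
  sites <- which(strsplit(sequence, "")[[1]] %in% c("S", "T"))
  if (n_phospho > length(sites))
    stop("n_phospho (", n_phospho, ") exceeds available S/T sites (",
         length(sites), ") in ", sequence)
  if (n_phospho == 0L) return(list(integer(0)))
  if (n_phospho == length(sites)) return(list(sites))
  combs <- utils::combn(sites, n_phospho, simplify = FALSE)
  combs  # combn emits lexicographic order over positions
}

#' Render a modified sequence with lower-case phospho residues
#'
#' @param sequence peptide sequence.
#' @param positions 1-based phosphorylated positions.
#' @return modified-sequence string, e.g. `"sCPEDCK"`.
#' @export
modified_sequence <- function(sequence, positions) {
  chars <- strsplit(sequence, "")[[1]]
  chars[positions] <- tolower(chars[positions])
  paste(chars, collapse = "")
}

#' Strip phospho markers from a modified sequence
#' @param modseq modified-sequence string.
#' @return uppercase plain sequence.
#' @export
unmodified_sequence <- function(modseq) toupper(modseq)

#' Phosphosite positions encoded in a modified sequence
#' @param modseq modified-sequence string.
#' @return integer vector of 1-based positions.
#' @export
phospho_positions <- function(modseq) {
  which(strsplit(modseq, "")[[1]] %in% c("s", "t"))
}

#' Theoretical CID fragment spectrum of a phosphosite configuration
#'
#' Emits the full b- and y-ion series with, per fragment, neutral-loss
#' variants gated on residue content: -H2O for fragments containing
#' S/T/E/D, -NH3 for R/K/N/Q, and -H3PO4 for fragments carrying a
#' phosphorylated residue. Fixed Cys carbamidomethylation is applied;
#' phosphorylated positions add the HPO3 delta. Fragment charges
#' `1..min(max_fragment_charge, z)` are generated.
#'
#' @param sequence peptide sequence.
#' @param positions 1-based phosphorylated positions (S/T).
#' @param params a [search_params()].
#' @param z precursor charge (caps fragment charge), default 2.
#' @return data.frame with columns `series` ("b"/"y"), `index`, `loss`
#'   ("none"/"H2O"/"NH3"/"H3PO4"), `charge`, `mz`.
#' @export
generate_theoretical <- function(sequence, positions = integer(0),
                                 params = search_params(), z = 2L) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  stopifnot(L >= 2L, all(chars[positions] %in% c("S", "T")))
  res <- MASS$residues[chars]
  res <- res + (chars == "C") * MASS$carbamidomethyl
  res[positions] <- res[positions] + MASS$phospho
  csum <- cumsum(res)
  total <- csum[L]

  idx <- seq_len(L - 1L)
  b_neutral <- csum[idx]                           # b_i: residues 1..i
  y_neutral <- total - csum[L - idx] + MASS$water  # y_i: residues L-i+1..L
  has_phospho_b <- vapply(idx, function(i) any(positions <= i), logical(1))
  has_water_b <- vapply(idx, function(i) any(chars[1:i] %in%
                                               c("S", "T", "E", "D")),
                        logical(1))
  has_amm_b <- vapply(idx, function(i) any(chars[1:i] %in%
                                             c("R", "K", "N", "Q")),
                      logical(1))
  # y_i covers residues (L-i+1)..L
  has_phospho_y <- vapply(idx, function(i) any(positions > L - i), logical(1))
  has_water_y <- vapply(idx, function(i) any(chars[(L - i + 1L):L] %in%
                                               c("S", "T", "E", "D")),
                        logical(1))
  has_amm_y <- vapply(idx, function(i) any(chars[(L - i + 1L):L] %in%
                                             c("R", "K", "N", "Q")),
                      logical(1))

  rows <- list()
  add <- function(series, index, loss, neutral) {
    rows[[length(rows) + 1L]] <<- data.frame(
      series = series, index = index, loss = loss, neutral = neutral,
      stringsAsFactors = FALSE)
  }
  add("b", idx, "none", b_neutral)
  add("y", idx, "none", y_neutral)
  if (any(has_water_b)) add("b", idx[has_water_b], "H2O",
                            b_neutral[has_water_b] - MASS$water)
  if (any(has_water_y)) add("y", idx[has_water_y], "H2O",
                            y_neutral[has_water_y] - MASS$water)
  if (any(has_amm_b)) add("b", idx[has_amm_b], "NH3",
                          b_neutral[has_amm_b] - MASS$ammonia)
  if (any(has_amm_y)) add("y", idx[has_amm_y], "NH3",
                          y_neutral[has_amm_y] - MASS$ammonia)
  if (any(has_phospho_b)) add("b", idx[has_phospho_b], "H3PO4",
                              b_neutral[has_phospho_b] - MASS$h3po4)
  if (any(has_phospho_y)) add("y", idx[has_phospho_y], "H3PO4",
                              y_neutral[has_phospho_y] - MASS$h3po4)
  frag <- do.call(rbind, rows)

  zs <- seq_len(min(params$max_fragment_charge, z))
  out <- do.call(rbind, lapply(zs, function(fz) {
    d <- frag
    d$charge <- fz
    d$mz <- (d$neutral + fz * MASS$proton) / fz
    d
  }))
  out$neutral <- NULL
  rownames(out) <- NULL
  out
}

#' Sigmoid peak weight
#'
#' `2 / (1 + exp(-I)) - 1` for a normalized intensity I: low-intensity
#' (noise-prone) peaks contribute less to the match score than confident,
#' intense ones.
#'
#' @param intensity normalized intensity in `[0, 100]`.
#' @return value in `[0, 1)` (vectorized).
#' @export
peak_score <- function(intensity) {
  if (any(intensity < 0)) stop("negative intensity")
  2 / (1 + exp(-intensity)) - 1
}

#' Score an experimental spectrum against a theoretical one
#'
#' An experimental peak matches if it lies within the fragment tolerance of
#' any theoretical fragment m/z; each experimental peak is counted at most
#' once. The score sums the sigmoid weights of the M matched peaks, so
#' `0 <= score <= M`.
#'
#' @param spectrum a processed `ms2_spectrum`.
#' @param theoretical data.frame from [generate_theoretical()].
#' @param params a [search_params()].
#' @return list with `score`, `M` (matched experimental peak count) and
#'   `matched` (logical vector over experimental peaks).
#' @export
score_match <- function(spectrum, theoretical, params = search_params()) {
  exp_mz <- spectrum$peaks$mz
  th <- sort(theoretical$mz)
  tol <- params$fragment_tol
  # nearest theoretical fragment for each experimental peak
  pos <- findInterval(exp_mz, th)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(th))
  d <- pmin(abs(exp_mz - th[lo]), abs(exp_mz - th[hi]))
  matched <- d <= tol
  list(score = sum(peak_score(spectrum$peaks$intensity[matched])),
       M = sum(matched), matched = matched)
}

#' Search one spectrum against a composite database
#'
#' For every precursor-matching entry, all phosphosite isomers are scored;
#' configurations matching at least one experimental peak are recorded as
#' hits. Target and decoy hits are returned as two lists sorted by
#' descending score, then descending matched-peak count, then
#' modified-sequence string — a fully deterministic order.
#'
#' @param spectrum a processed `ms2_spectrum` (should have passed the
#'   neutral-loss prescreen).
#' @param db a `composite_db`.
#' @param params a [search_params()].
#' @return list with data.frames `target` and `decoy`; columns
#'   `spectrum_id`, `modseq`, `sequence`, `n_phospho`, `score`, `M`,
#'   `is_decoy`, `p_value` (NA until [filter_significant()]).
#' @export
search_spectrum <- function(spectrum, db, params = search_params()) {
  empty <- data.frame(spectrum_id = character(0), modseq = character(0),
                      sequence = character(0), n_phospho = integer(0),
                      score = numeric(0), M = integer(0),
                      is_decoy = logical(0), p_value = numeric(0))
  cand <- precursor_candidates(db, spectrum, params)
  if (nrow(cand) == 0L) return(list(target = empty, decoy = empty))
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    seqc <- cand$sequence[i]
    np <- cand$n_phospho[i]
    for (posv in enumerate_site_configs(seqc, np)) {
      theo <- generate_theoretical(seqc, posv, params, spectrum$charge)
      sm <- score_match(spectrum, theo, params)
      if (sm$M >= 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          spectrum_id = spectrum$spectrum_id,
          modseq = modified_sequence(seqc, posv),
          sequence = seqc, n_phospho = np, score = sm$score, M = sm$M,
          is_decoy = cand$is_decoy[i], p_value = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(list(target = empty, decoy = empty))
  hits <- do.call(rbind, rows)
  hits <- hits[order(-hits$score, -hits$M, hits$modseq), , drop = FALSE]
  rownames(hits) <- NULL
  list(target = hits[!hits$is_decoy, , drop = FALSE],
       decoy = hits[hits$is_decoy, , drop = FALSE])
}

#' Write a hit list as tab-separated text
#'
#' @param hits data.frame of hits (target or decoy, or both bound together).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  out <- hits
  out$score <- sprintf("%.6f", out$score)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
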