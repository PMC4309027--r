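# dta spectrum IO and the three-stage preprocessing: charge filter,
# base-peak normalization + per-bin denoising, and H3PO4 neutral-loss
# prescreening.

new_spectrum <- function(spectrum_id, precursor_mh, charge, peaks) {
  structure(list(spectrum_id = spectrum_id,
                 precursor_mh = precursor_mh,
                 charge = as.integer(charge),
                 peaks = peaks,          # data.frame(mz, intensity)
                 normalized = FALSE,
                 nl_peaks = NULL),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> %s  (M+H)+ %.4f  z=%d  %d peaks%s\n",
              x$spectrum_id, x$precursor_mh, x$charge, nrow(x$peaks),
              if (x$normalized) "  [normalized]" else ""))
  invisible(x)
}

#' Neutral precursor mass of a spectrum
#' @param spectrum an `ms2_spectrum`.
#' @return neutral monoisotopic mass in Da ((M+H)+ minus one proton).
#' @export
precursor_neutral_mass <- function(spectrum) spectrum$precursor_mh - MASS$proton

#' Precursor m/z of a spectrum
#' @param spectrum an `ms2_spectrum`.
#' @return the m/z at the spectrum's charge state.
#' @export
precursor_mz <- function(spectrum) {
  (precursor_neutral_mass(spectrum) + spectrum$charge * MASS$proton) /
    spectrum$charge
}

parse_dta_lines <- function(lines, spectrum_id, precursor_convention = "mh") {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty dta record: ", spectrum_id)
  fields <- strsplit(lines, "[ \t]+")
  nums <- suppressWarnings(lapply(fields, as.numeric))
  bad <- which(vapply(nums, anyNA, logical(1)) |
                 lengths(nums) != 2L)
  if (length(bad)) stop("malformed dta line ", bad[1L], " in ", spectrum_id,
                        ": '", lines[bad[1L]], "'")
  head <- nums[[1L]]
  z <- head[2L]
  if (z != round(z) || z < 1) stop("non-integer or invalid charge in ",
                                   spectrum_id, ": ", z)
  mh <- if (precursor_convention == "mz") {
    # convert measured precursor m/z at charge z to (M+H)+
    head[1L] * z - (z - 1) * MASS$proton
  } else head[1L]
  if (length(nums) < 2L) {
    warning("dta record with no fragment peaks skipped: ", spectrum_id)
    return(NULL)
  }
  pk <- do.call(rbind, nums[-1L])
  peaks <- data.frame(mz = pk[, 1L], intensity = pk[, 2L])
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  new_spectrum(spectrum_id, mh, z, peaks)
}

#' Read a single dta spectrum file
#'
#' Sequest-style dta: first line is the singly protonated precursor mass
#' (M+H)+ and the charge; each following line is an m/z intensity pair.
#' Instruments exporting precursor m/z instead of (M+H)+ are supported via
#' `precursor_convention = "mz"`.
#'
#' @param path path to a `.dta` file.
#' @param precursor_convention `"mh"` (default) or `"mz"`.
#' @return an `ms2_spectrum`, or `NULL` (with a warning) if the record has
#'   no fragment peaks.
#' @export
read_dta <- function(path, precursor_convention = c("mh", "mz")) {
  precursor_convention <- match.arg(precursor_convention)
  parse_dta_lines(readLines(path, warn = FALSE), basename(path),
                  precursor_convention)
}

#' Merge a directory of dta files into one ASCII file
#'
#' Records are concatenated in lexicographic filename order, each preceded
#' by a `# <filename>` comment line and separated by blank lines — a
#' deterministic, greppable container for whole-run processing.
#'
#' @param directory directory containing `*.dta` files.
#' @param out_path output file path.
#' @return `out_path`, invisibly.
#' @export
merge_dta <- function(directory, out_path) {
  files <- sort(list.files(directory, pattern = "\\.dta$", full.names = TRUE))
  if (length(files) == 0L) stop("no .dta files in ", directory)
  con <- file(out_path, "w")
  on.exit(close(con))
  for (f in files) {
    writeLines(paste0("# ", basename(f)), con)
    writeLines(trimws(readLines(f, warn = FALSE)), con)
    writeLines("", con)
  }
  invisible(out_path)
}

#' Parse a merged multi-spectrum file
#'
#' @param path file written by [merge_dta()].
#' @param precursor_convention `"mh"` (default) or `"mz"`.
#' @return list of `ms2_spectrum` objects (records with no peaks dropped
#'   with a warning).
#' @export
read_merged <- function(path, precursor_convention = c("mh", "mz")) {
  precursor_convention <- match.arg(precursor_convention)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^# ", lines)
  if (length(starts) == 0L) stop("no '# <filename>' record headers in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    id <- sub("^# ", "", lines[starts[i]])
    body <- lines[(starts[i] + 1L):ends[i]]
    out[[i]] <- parse_dta_lines(body, id, precursor_convention)
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Remove spectra with precursor charge above a cutoff
#'
#' High-charge precursors fragment poorly under CID and are discarded.
#'
#' @param spectra list of `ms2_spectrum`.
#' @param max_z maximum retained charge (default 4).
#' @return the retained sublist; the number removed is reported via message.
#' @export
filter_by_charge <- function(spectra, max_z = 4L) {
  keep <- vapply(spectra, function(s) s$charge <= max_z, logical(1))
  if (any(!keep)) message(sum(!keep), " spectra removed (charge > ", max_z, ")")
  spectra[keep]
}

#' Normalize a spectrum to its base peak
#'
#' All intensities are scaled so the most intense peak is exactly 100.
#'
#' @param spectrum an `ms2_spectrum`.
#' @return the normalized spectrum, or `NULL` (with warning) if all
#'   intensities are zero.
#' @export
normalize_spectrum <- function(spectrum) {
  mx <- max(spectrum$peaks$intensity)
  if (mx <= 0) {
    warning("all-zero intensities, spectrum rejected: ", spectrum$spectrum_id)
    return(NULL)
  }
  spectrum$peaks$intensity <- spectrum$peaks$intensity * (100 / mx)
  spectrum$peaks$intensity[which.max(spectrum$peaks$intensity)] <- 100
  spectrum$normalized <- TRUE
  spectrum
}

#' Remove the least intense half of each 100-peak bin
#'
#' Peaks are split, in m/z order, into consecutive bins of 100; within each
#' bin the 50 least intense peaks are removed. A final partial bin of n
#' peaks loses its floor(n/2) least intense. Intensity ties at the cut rank
#' are resolved by keeping the higher-m/z peak.
#'
#' @param spectrum a normalized `ms2_spectrum`.
#' @param bin_size peaks per bin (default 100).
#' @return the denoised spectrum.
#' @export
bin_denoise <- function(spectrum, bin_size = 100L) {
  pk <- spectrum$peaks
  n <- nrow(pk)
  if (n == 0L) return(spectrum)
  bin <- (seq_len(n) - 1L) %/% bin_size
  keep <- logical(n)
  for (b in unique(bin)) {
    idx <- which(bin == b)
    nb <- length(idx)
    drop_n <- nb %/% 2L
    # rank by ascending intensity, ties broken toward lower mz being dropped
    ord <- idx[order(pk$intensity[idx], pk$mz[idx])]
    keep[ord[seq.int(drop_n + 1L, nb)]] <- TRUE
  }
  spectrum$peaks <- pk[keep, , drop = FALSE]
  rownames(spectrum$peaks) <- NULL
  spectrum
}

#' Prescreen a spectrum for H3PO4 neutral-loss peaks
#'
#' Candidate positions are `precursor_mz - k * 97.976896 / z` for
#' k = 1..`max_losses` (multiply phosphorylated precursors can lose several
#' phosphate groups). The spectrum passes if any candidate position carries
#' a peak within `tol_base / z` Da whose normalized intensity is at least
#' `intensity_threshold`; even at threshold 0 an actual matched peak is
#' required.
#'
#' @param spectrum a normalized (and denoised) `ms2_spectrum`.
#' @param intensity_threshold value in `[0, 100]`.
#' @param tol_base tolerance numerator in Da (default 3.0; divided by the
#'   precursor charge).
#' @param max_losses maximum number of H3PO4 losses considered (default 4,
#'   matching the default phospho cap per peptide).
#' @return the spectrum with `nl_peaks` set (data.frame of matched peaks,
#'   possibly empty) and logical attribute accessible via [nl_passed()].
#' @export
neutral_loss_check <- function(spectrum, intensity_threshold,
                               tol_base = 3.0, max_losses = 4L) {
  stopifnot(intensity_threshold >= 0, intensity_threshold <= 100)
  z <- spectrum$charge
  tol <- tol_base / z
  cand <- precursor_mz(spectrum) - seq_len(max_losses) * MASS$h3po4 / z
  pk <- spectrum$peaks
  hit <- rep(FALSE, nrow(pk))
  for (pos in cand) {
    hit <- hit | (abs(pk$mz - pos) <= tol &
                    pk$intensity >= intensity_threshold)
  }
  spectrum$nl_peaks <- pk[hit, , drop = FALSE]
  rownames(spectrum$nl_peaks) <- NULL
  spectrum
}

#' Did a spectrum pass the neutral-loss prescreen?
#' @param spectrum an `ms2_spectrum` after [neutral_loss_check()].
#' @return logical.
#' @export
nl_passed <- function(spectrum) {
  !is.null(spectrum$nl_peaks) && nrow(spectrum$nl_peaks) > 0L
}

#' Standard spectrum preprocessing chain
#'
#' charge filter -> normalize -> bin denoise -> neutral-loss check, in that
#' fixed order.
#'
#' @param spectra list of `ms2_spectrum`.
#' @param nl_threshold neutral-loss intensity threshold in `[0, 100]`.
#' @param max_z maximum precursor charge (default 4).
#' @param nl_tolerance tolerance numerator in Da (default 3.0).
#' @param max_losses maximum H3PO4 losses considered (default 4).
#' @return list of processed spectra (all retained charges, each annotated
#'   with `nl_peaks`; use [nl_passed()] to split selected/unselected).
#' @export
preprocess_spectra <- function(spectra, nl_threshold, max_z = 4L,
                               nl_tolerance = 3.0, max_losses = 4L) {
  spectra <- filter_by_charge(spectra, max_z)
  out <- lapply(spectra, function(s) {
    s <- normalize_spectrum(s)
    if (is.null(s)) return(NULL)
    s <- bin_denoise(s)
    neutral_loss_check(s, nl_threshold, nl_tolerance, max_losses)
  })
  out[!vapply(out, is.null, logical(1))]
}
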