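# Ground-truthed synthetic CID spectrum generator. Emulates the structure
# the pipeline's filters assume: b/y fragment peaks at sampled coverage, a
# dominant precursor H3PO4 neutral-loss peak for phosphopeptides, and
# uniform noise peaks; intensities are drawn so normalization lands the
# base peak on a planted (not noise) peak.

#' Simulation configuration
#'
#' Defaults describe a CID run on tryptic phosphopeptides: charge mix
#' 2+/3+/4+ at 0.76/0.22/0.02 (the composition of typical enriched test
#' sets), 80% fragment coverage, fragment m/z jitter of 0.1 Da, precursor
#' accuracy of 2 ppm, a dominant neutral-loss peak (raw intensity 100
#' against fragments in [40, 90]) and 30 uniform noise peaks below
#' intensity 20.
#'
#' @param charge_probs named numeric, sampling weights over charges.
#' @param coverage fraction of theoretical b/y fragments emitted, in (0,1].
#' @param frag_int_range raw fragment intensity range (uniform).
#' @param nl_intensity raw intensity of the planted neutral-loss peak.
#' @param noise_n number of uniform noise peaks.
#' @param noise_int_range raw noise intensity range (uniform).
#' @param mz_jitter_sd fragment m/z jitter standard deviation (Da).
#' @param precursor_jitter_ppm precursor mass jitter s.d. (ppm).
#' @param min_mz lower m/z bound for noise peaks.
#' @param seed integer random seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(charge_probs = c("2" = 0.76, "3" = 0.22, "4" = 0.02),
                       coverage = 0.8,
                       frag_int_range = c(40, 90),
                       nl_intensity = 100,
                       noise_n = 30L,
                       noise_int_range = c(0, 20),
                       mz_jitter_sd = 0.1,
                       precursor_jitter_ppm = 2,
                       min_mz = 100,
                       seed = 1L) {
  stopifnot(coverage > 0, coverage <= 1, noise_n >= 0L,
            all(charge_probs >= 0), sum(charge_probs) > 0)
  structure(list(charge_probs = charge_probs, coverage = coverage,
                 frag_int_range = frag_int_range,
                 nl_intensity = nl_intensity, noise_n = as.integer(noise_n),
                 noise_int_range = noise_int_range,
                 mz_jitter_sd = mz_jitter_sd,
                 precursor_jitter_ppm = precursor_jitter_ppm,
                 min_mz = min_mz, seed = as.integer(seed)),
            class = "sim_config")
}

#' Path of the bundled synthetic protein FASTA
#'
#' Twenty invented protein sequences (generated once from a fixed random
#' draw over typical amino-acid frequencies; no relation to any real
#' proteome) used as the default peptide source for simulation and tests.
#'
#' @return file path.
#' @export
synthetic_fasta <- function() {
  system.file("extdata", "synthetic_proteins.fasta", package = "phosphoscan",
              mustWork = TRUE)
}

#' Tryptic peptide pool for simulation
#'
#' @param fasta FASTA path (default the bundled synthetic proteins).
#' @param config a [digest_config()].
#' @param min_st minimum number of S/T residues required (default 0).
#' @return character vector of unique peptides, length 7-18, sorted.
#' @export
simulation_peptides <- function(fasta = synthetic_fasta(),
                                config = digest_config(), min_st = 0L) {
  prot <- parse_fasta(fasta)
  peps <- unlist(lapply(prot$sequence, function(s) digest(s, config)$peptide))
  peps <- sort(unique(peps))
  len <- nchar(peps)
  peps <- peps[len >= 7L & len <= 18L]
  if (min_st > 0L) {
    nst <- vapply(strsplit(peps, ""), function(ch)
      sum(ch %in% c("S", "T")), integer(1))
    peps <- peps[nst >= min_st]
  }
  peps
}

#' Simulate one CID MS/MS spectrum
#'
#' Emits a sampled subset (`coverage`) of the singly charged b/y fragments
#' of `modseq` with Gaussian m/z jitter and uniform intensities; for
#' phosphopeptides, a precursor neutral-loss peak at
#' `precursor_mz - k * 97.976896 / z` (k = 1) at the configured dominant
#' intensity; plus uniform noise peaks. Randomness is taken from the
#' current RNG state — seed at the dataset level.
#'
#' @param modseq modified sequence (phospho residues lower-case); an
#'   all-uppercase string yields a non-phospho spectrum with no planted
#'   neutral-loss peak.
#' @param z precursor charge.
#' @param config a [sim_config()].
#' @param spectrum_id identifier (defaults to the modseq).
#' @return list with `spectrum` (`ms2_spectrum`), `dta_lines` (character)
#'   and `truth` (one-row data.frame: `spectrum_id`, `modseq`, `charge`).
#' @export
simulate_spectrum <- function(modseq, z, config = sim_config(),
                              spectrum_id = modseq) {
  sequence <- unmodified_sequence(modseq)
  positions <- phospho_positions(modseq)
  n_phospho <- length(positions)
  neutral <- compute_mass(sequence, n_phospho)
  mh_true <- neutral + MASS$proton
  mh <- mh_true * (1 + stats::rnorm(1, 0, config$precursor_jitter_ppm) / 1e6)

  theo <- generate_theoretical(sequence, positions,
                               search_params(max_fragment_charge = 1L), z)
  theo <- theo[theo$loss == "none", , drop = FALSE]
  n_keep <- max(1L, round(config$coverage * nrow(theo)))
  keep <- sort(sample.int(nrow(theo), n_keep))
  mz <- theo$mz[keep] + stats::rnorm(n_keep, 0, config$mz_jitter_sd)
  int <- stats::runif(n_keep, config$frag_int_range[1],
                      config$frag_int_range[2])

  if (n_phospho > 0L) {
    pmz <- (neutral + z * MASS$proton) / z
    mz <- c(mz, pmz - MASS$h3po4 / z)
    int <- c(int, config$nl_intensity)
  }
  if (config$noise_n > 0L) {
    mz <- c(mz, stats::runif(config$noise_n, config$min_mz, mh))
    int <- c(int, stats::runif(config$noise_n, config$noise_int_range[1],
                               config$noise_int_range[2]))
  }
  ord <- order(mz)
  peaks <- data.frame(mz = mz[ord], intensity = int[ord])
  spectrum <- new_spectrum(spectrum_id, mh, z, peaks)
  dta_lines <- c(sprintf("%.5f %d", mh, z),
                 sprintf("%.5f %.4f", peaks$mz, peaks$intensity))
  truth <- data.frame(spectrum_id = spectrum_id, modseq = if (n_phospho > 0L)
    modseq else "", charge = z, stringsAsFactors = FALSE)
  list(spectrum = spectrum, dta_lines = dta_lines, truth = truth)
}

#' Simulate a ground-truthed dataset of dta files
#'
#' Draws phospho peptides (1-2 phospho groups placed uniformly at random
#' on S/T sites, weights 0.7/0.3) and non-phospho peptides from the
#' bundled pool, simulates each spectrum, and writes one `.dta` file per
#' spectrum plus a tab-separated truth table. Fully deterministic for a
#' fixed `config$seed`.
#'
#' @param n_phospho,n_nonphospho spectrum counts (>= 0).
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()].
#' @param fasta peptide source FASTA (default bundled).
#' @param digest_cfg a [digest_config()].
#' @return list with `truth` (data.frame), `spectra` (list of
#'   `ms2_spectrum`) and `dir`.
#' @export
simulate_dataset <- function(n_phospho, n_nonphospho, out_dir,
                             config = sim_config(),
                             fasta = synthetic_fasta(),
                             digest_cfg = digest_config()) {
  stopifnot(n_phospho >= 0, n_nonphospho >= 0)
  set.seed(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pool_phos <- simulation_peptides(fasta, digest_cfg, min_st = 1L)
  pool_any <- simulation_peptides(fasta, digest_cfg)
  n <- n_phospho + n_nonphospho
  zs <- as.integer(sample(names(config$charge_probs), n, replace = TRUE,
                          prob = config$charge_probs))
  truth <- vector("list", n)
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("sim_%04d.dta", i)
    if (i <= n_phospho) {
      pep <- pool_phos[sample.int(length(pool_phos), 1L)]
      sites <- which(strsplit(pep, "")[[1]] %in% c("S", "T"))
      np <- if (length(sites) >= 2L)
        sample(1:2, 1L, prob = c(0.7, 0.3)) else 1L
      pos <- sort(sites[sample.int(length(sites), np)])
      modseq <- modified_sequence(pep, pos)
    } else {
      modseq <- pool_any[sample.int(length(pool_any), 1L)]
    }
    sim <- simulate_spectrum(modseq, zs[i], config, spectrum_id = id)
    writeLines(sim$dta_lines, file.path(out_dir, id))
    truth[[i]] <- sim$truth
    spectra[[i]] <- sim$spectrum
  }
  truth <- do.call(rbind, truth)
  write_truth(truth, file.path(out_dir, "truth.tsv"))
  list(truth = truth, spectra = spectra, dir = out_dir)
}
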