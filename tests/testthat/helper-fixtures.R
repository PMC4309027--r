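# Shared fixtures and independent oracles used across test files.

# build an ms2_spectrum directly from vectors
make_spectrum <- function(mz, intensity, precursor_mh = 1000, z = 2L,
                          id = "test") {
  ord <- order(mz)
  phosphoscan:::new_spectrum(id, precursor_mh, z,
                             data.frame(mz = mz[ord],
                                        intensity = intensity[ord]))
}

# a spectrum with a chosen precursor m/z (converts to the (M+H)+ bookkeeping)
make_spectrum_mz <- function(mz, intensity, prec_mz, z = 2L, id = "test") {
  neutral <- prec_mz * z - z * MASS$proton
  make_spectrum(mz, intensity, precursor_mh = neutral + MASS$proton, z, id)
}

random_protein <- function(len) {
  paste(sample(names(MASS$residues), len, replace = TRUE), collapse = "")
}

# brute-force digestion oracle: tests every substring against the
# cleavage-boundary definition (independent of digest()'s boundary walk)
oracle_digest <- function(sequence, protease = "trypsin", mc_max = 2L) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  cut_after <- if (protease == "trypsin") c("K", "R") else
    c("F", "Y", "W", "L", "M")
  is_boundary <- function(p) {
    p == 0L || p == n ||
      (chars[p] %in% cut_after && chars[p + 1L] != "P")
  }
  out_pep <- character(0); out_mc <- integer(0)
  for (i in 0:(n - 1L)) for (j in (i + 1L):n) {
    if (!is_boundary(i) || !is_boundary(j)) next
    internal <- if (j - i >= 2L)
      sum(vapply((i + 1L):(j - 1L), is_boundary, logical(1))) else 0L
    if (internal <= mc_max) {
      out_pep <- c(out_pep, substr(sequence, i + 1L, j))
      out_mc <- c(out_mc, internal)
    }
  }
  data.frame(peptide = out_pep, missed_cleavages = out_mc,
             stringsAsFactors = FALSE)
}

# brute-force scoring oracle: explicit double loop over
# (experimental peak x theoretical fragment)
oracle_score <- function(spectrum, theoretical, tol = 0.8) {
  M <- 0L; score <- 0
  for (j in seq_len(nrow(spectrum$peaks))) {
    matched <- FALSE
    for (k in seq_len(nrow(theoretical))) {
      if (abs(spectrum$peaks$mz[j] - theoretical$mz[k]) <= tol) {
        matched <- TRUE
        break
      }
    }
    if (matched) {
      M <- M + 1L
      score <- score + (2 / (1 + exp(-spectrum$peaks$intensity[j])) - 1)
    }
  }
  list(score = score, M = M)
}

# composite DB over the bundled synthetic FASTA, built once per run
shared_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- build_composite(parse_fasta(synthetic_fasta()))
    db
  }
})

# published detection-performance benchmark rows used as fixtures:
# counts TP/FP/FN/TN and the six indexes at 3 decimals (22 threshold rows
# for the with/without-validation sweeps plus 2 comparison-tool rows)
detection_rows <- function() {
  m <- rbind(
    c(750, 488,   0, 262, 1.000, 0.349, 0.675, 0.394, 0.606, 0.755),
    c(727, 239,  23, 511, 0.969, 0.681, 0.825, 0.247, 0.753, 0.847),
    c(703, 147,  47, 603, 0.937, 0.804, 0.871, 0.173, 0.827, 0.879),
    c(664,  98,  86, 652, 0.885, 0.869, 0.877, 0.129, 0.871, 0.878),
    c(634,  70, 116, 680, 0.845, 0.907, 0.876, 0.099, 0.901, 0.872),
    c(603,  49, 147, 701, 0.804, 0.935, 0.869, 0.075, 0.925, 0.860),
    c(579,  34, 171, 716, 0.772, 0.955, 0.863, 0.055, 0.945, 0.850),
    c(548,  24, 202, 726, 0.731, 0.968, 0.849, 0.042, 0.958, 0.829),
    c(520,  19, 230, 731, 0.693, 0.975, 0.834, 0.035, 0.965, 0.807),
    c(493,  14, 257, 736, 0.657, 0.981, 0.819, 0.028, 0.972, 0.784),
    c(464,  11, 286, 739, 0.619, 0.985, 0.802, 0.023, 0.977, 0.758),
    c(743, 240,   7, 510, 0.991, 0.680, 0.835, 0.244, 0.756, 0.857),
    c(721, 129,  29, 621, 0.961, 0.828, 0.895, 0.152, 0.848, 0.901),
    c(697,  77,  53, 673, 0.929, 0.897, 0.913, 0.099, 0.901, 0.915),
    c(659,  50,  91, 700, 0.879, 0.933, 0.906, 0.071, 0.929, 0.903),
    c(630,  35, 120, 715, 0.840, 0.953, 0.897, 0.053, 0.947, 0.890),
    c(599,  23, 151, 727, 0.799, 0.969, 0.884, 0.037, 0.963, 0.873),
    c(575,  18, 175, 732, 0.767, 0.976, 0.871, 0.030, 0.970, 0.856),
    c(544,  12, 206, 738, 0.725, 0.984, 0.855, 0.022, 0.978, 0.833),
    c(516,   9, 234, 741, 0.688, 0.988, 0.838, 0.017, 0.983, 0.809),
    c(489,   6, 261, 744, 0.652, 0.992, 0.822, 0.012, 0.988, 0.786),
    c(460,   3, 290, 747, 0.613, 0.996, 0.805, 0.006, 0.994, 0.758),
    c(552,   0, 198, 750, 0.736, 1.000, 0.868, 0.000, 1.000, 0.848),
    c(650,  15, 100, 735, 0.867, 0.980, 0.923, 0.023, 0.977, 0.919))
  colnames(m) <- c("TP", "FP", "FN", "TN", "sensitivity", "specificity",
                   "accuracy", "fdr", "precision", "f_measure")
  m
}

write_fasta_fixture <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
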