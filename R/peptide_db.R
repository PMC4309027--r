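# Target/decoy/composite peptide database construction: FASTA parsing,
# in silico digestion, modification-state enumeration and mass computation.

#' Read and validate a protein FASTA file
#'
#' Reads a multi-record FASTA file and returns one row per valid protein.
#' The accession is the header token before the first whitespace; sequences
#' are uppercased and joined across lines. Records whose sequence contains a
#' character outside the 20 standard amino-acid letters (e.g. the ambiguity
#' codes B, X, Z) are rejected with a warning, mirroring the usual curation
#' rule for phosphoproteomic search databases.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `accession`, `sequence`, `is_decoy`
#'   (always `FALSE` here).
#' @export
parse_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  acc <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) stop("FASTA record with empty sequence: ",
                               paste(acc[!nzchar(seqs)], collapse = ", "))
  ok <- !grepl(sprintf("[^%s]", paste(STANDARD_AA, collapse = "")), seqs)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) rejected (non-standard amino acids): ",
            paste(utils::head(acc[!ok], 5L), collapse = ", "))
  }
  if (!any(ok)) stop("no valid protein records in ", path)
  data.frame(accession = acc[ok], sequence = unname(seqs[ok]),
             is_decoy = FALSE, stringsAsFactors = FALSE)
}

#' Digestion configuration
#'
#' @param protease `"trypsin"` (cleave C-terminal to K/R, not before P) or
#'   `"chymotrypsin"` (low specificity: C-terminal to F/Y/W/L/M, not before P).
#' @param max_missed_cleavages maximum internal uncleaved sites (default 2).
#' @param min_length,max_length peptide length guards (defaults 5 and 60;
#'   shorter peptides are unidentifiable by CID and only inflate the
#'   multiple-testing burden).
#' @return a `digest_config` list.
#' @export
digest_config <- function(protease = "trypsin", max_missed_cleavages = 2L,
                          min_length = 5L, max_length = 60L) {
  protease <- match.arg(protease, c("trypsin", "chymotrypsin"))
  stopifnot(max_missed_cleavages >= 0L, min_length >= 1L,
            max_length >= min_length)
  structure(list(protease = protease,
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "digest_config")
}

# cleavage boundary positions: i means "cut after residue i"
cleavage_sites <- function(sequence, protease = "trypsin") {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  cut_after <- switch(protease,
    trypsin = c("K", "R"),
    chymotrypsin = c("F", "Y", "W", "L", "M"))
  idx <- which(chars[-n] %in% cut_after & chars[-1L] != "P")
  idx
}

#' In silico proteolytic digestion
#'
#' Returns all fully specific peptides with up to `max_missed_cleavages`
#' internal uncleaved sites. Length guards are applied unless
#' `apply_length_guards = FALSE` (useful for oracle testing).
#'
#' @param sequence protein sequence (validated, standard letters).
#' @param config a [digest_config()].
#' @param apply_length_guards apply the min/max length filter? Default TRUE.
#' @return data.frame with columns `peptide`, `missed_cleavages`.
#' @export
digest <- function(sequence, config = digest_config(),
                   apply_length_guards = TRUE) {
  n <- nchar(sequence)
  bounds <- c(0L, cleavage_sites(sequence, config$protease), n)
  nb <- length(bounds)
  out_pep <- character(0)
  out_mc <- integer(0)
  mc_max <- config$max_missed_cleavages
  for (i in seq_len(nb - 1L)) {
    for (mc in 0:mc_max) {
      j <- i + 1L + mc
      if (j > nb) break
      out_pep <- c(out_pep, substr(sequence, bounds[i] + 1L, bounds[j]))
      out_mc <- c(out_mc, mc)
    }
  }
  res <- data.frame(peptide = out_pep, missed_cleavages = out_mc,
                    stringsAsFactors = FALSE)
  if (apply_length_guards) {
    len <- nchar(res$peptide)
    res <- res[len >= config$min_length & len <= config$max_length, ,
               drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus one water (peptide termini), plus fixed
#' carbamidomethylation of every cysteine and `n_phospho` times the HPO3
#' delta.
#'
#' @param sequence peptide sequence (standard letters only).
#' @param n_phospho number of phospho groups carried.
#' @param cys_cam apply the fixed Cys carbamidomethyl modification?
#'   Default TRUE.
#' @return neutral monoisotopic mass in Da.
#' @export
compute_mass <- function(sequence, n_phospho = 0L, cys_cam = TRUE) {
  if (!nzchar(sequence)) stop("empty peptide sequence")
  chars <- strsplit(sequence, "")[[1]]
  m <- MASS$residues[chars]
  if (anyNA(m)) stop("unknown residue(s): ",
                     paste(unique(chars[is.na(m)]), collapse = ", "))
  mass <- sum(m) + MASS$water + n_phospho * MASS$phospho
  if (cys_cam) mass <- mass + sum(chars == "C") * MASS$carbamidomethyl
  mass
}

#' Enumerate phosphorylation states of a peptide
#'
#' One entry per phospho count n in 0..min(#S + #T, `max_phospho`). Fixed
#' Cys carbamidomethylation is always applied. Site placement is deferred to
#' search time; the database stores mass-level entries only.
#'
#' @param peptide peptide string.
#' @param max_phospho cap on variable phospho groups per peptide (default 4).
#' @return data.frame with columns `sequence`, `n_phospho`, `neutral_mass`.
#' @export
enumerate_mod_states <- function(peptide, max_phospho = 4L) {
  chars <- strsplit(peptide, "")[[1]]
  n_sites <- sum(chars %in% c("S", "T"))
  ns <- 0:min(n_sites, max_phospho)
  base <- compute_mass(peptide, 0L)
  data.frame(sequence = peptide, n_phospho = ns,
             neutral_mass = base + ns * MASS$phospho,
             stringsAsFactors = FALSE)
}

#' Build the decoy protein set by sequence reversal
#'
#' @param proteins data.frame as returned by [parse_fasta()].
#' @param prefix accession prefix marking decoys (default `"REV_"`).
#' @return data.frame of the same shape, `is_decoy = TRUE`, one decoy per
#'   target.
#' @export
build_decoy <- function(proteins, prefix = "REV_") {
  rev_seq <- vapply(proteins$sequence, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
  data.frame(accession = paste0(prefix, proteins$accession),
             sequence = rev_seq, is_decoy = TRUE, stringsAsFactors = FALSE)
}

#' Build the composite (target + decoy) peptide database
#'
#' Digests every protein, enumerates phospho states, computes neutral
#' monoisotopic masses and returns a single mass-sorted table. Duplicate
#' (sequence, n_phospho) pairs arising from different proteins or missed-
#' cleavage paths are collapsed to one entry per origin class
#' (target/decoy), keeping the smallest missed-cleavage count; `K`, the
#' number of distinct TARGET peptide entries, drives the Bonferroni
#' correction downstream.
#'
#' @param targets target protein data.frame ([parse_fasta()]).
#' @param decoys decoy protein data.frame ([build_decoy()]); pass `NULL` to
#'   generate reversals automatically.
#' @param config a [digest_config()].
#' @param max_phospho cap on phospho groups per peptide (default 4).
#' @return a `composite_db`: data.table with columns `accession`, `sequence`,
#'   `n_phospho`, `neutral_mass`, `missed_cleavages`, `is_decoy`, keyed by
#'   `neutral_mass`, with attributes `K` (target entry count) and `config`.
#' @export
build_composite <- function(targets, decoys = NULL, config = digest_config(),
                            max_phospho = 4L) {
  if (is.null(decoys)) decoys <- build_decoy(targets)
  proteins <- rbind(targets, decoys)
  pieces <- vector("list", nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    peps <- digest(proteins$sequence[i], config)
    if (nrow(peps) == 0L) next
    states <- lapply(seq_len(nrow(peps)), function(j) {
      st <- enumerate_mod_states(peps$peptide[j], max_phospho)
      st$missed_cleavages <- peps$missed_cleavages[j]
      st
    })
    piece <- data.table::rbindlist(states)
    piece[, `:=`(accession = proteins$accession[i],
                 is_decoy = proteins$is_decoy[i])]
    pieces[[i]] <- piece
  }
  db <- data.table::rbindlist(pieces)
  if (nrow(db) == 0L) stop("digestion produced no peptides")
  # one entry per (sequence, n_phospho, origin class)
  data.table::setorder(db, sequence, n_phospho, is_decoy, missed_cleavages)
  db <- unique(db, by = c("sequence", "n_phospho", "is_decoy"))
  data.table::setcolorder(db, c("accession", "sequence", "n_phospho",
                                "neutral_mass", "missed_cleavages",
                                "is_decoy"))
  data.table::setkey(db, neutral_mass)
  data.table::setattr(db, "K", sum(!db$is_decoy))
  data.table::setattr(db, "config",
                      c(unclass(config), list(max_phospho = max_phospho)))
  data.table::setattr(db, "class", c("composite_db", class(db)))
  db
}

#' Number of target peptide entries in a composite database
#' @param db a `composite_db`.
#' @return integer K used for the Bonferroni correction.
#' @export
db_K <- function(db) attr(db, "K")

#' Query a composite database by neutral mass window
#'
#' @param db a `composite_db`.
#' @param mass neutral precursor mass (Da).
#' @param delta absolute half-window (Da); matches are `|mass - m| <= delta`
#'   (inclusive).
#' @return the matching subset, both target and decoy entries.
#' @export
db_mass_query <- function(db, mass, delta) {
  db[db$neutral_mass >= mass - delta & db$neutral_mass <= mass + delta, ]
}

#' Write / read a composite database as tab-separated text
#'
#' The TSV holds one peptide entry per row; a JSON sidecar (`<path>.meta`)
#' records `K` and the digestion configuration.
#'
#' @param db a `composite_db`.
#' @param path output TSV path.
#' @return `path`, invisibly (writer); a `composite_db` (reader).
#' @export
write_composite_db <- function(db, path) {
  out <- data.table::copy(db)
  out[, neutral_mass := sprintf("%.6f", neutral_mass)]
  data.table::fwrite(out, path, sep = "\t")
  jsonlite::write_json(list(K = db_K(db), config = attr(db, "config")),
                       paste0(path, ".meta"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_composite_db
#' @export
read_composite_db <- function(path) {
  db <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = "sequence"))
  meta <- jsonlite::read_json(paste0(path, ".meta"), simplifyVector = TRUE)
  data.table::setkey(db, neutral_mass)
  data.table::setattr(db, "K", as.integer(meta$K))
  data.table::setattr(db, "config", meta$config)
  data.table::setattr(db, "class", c("composite_db", class(db)))
  db
}
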