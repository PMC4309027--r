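test_that("precursor_candidates applies inclusive Da and ppm windows", {
  prot <- data.frame(accession = "P", sequence = "AAAAKSSSSKCCCCK",
                     is_decoy = FALSE)
  db <- build_composite(prot, config = digest_config(min_length = 3))
  # pick an entry and query at its exact mass
  m <- db$neutral_mass[5]
  sp <- make_spectrum(c(100), c(10), precursor_mh = m + MASS$proton)
  got <- precursor_candidates(db, sp, search_params(7, "ppm"))
  expect_true(m %in% got$neutral_mass)
  expect_true(all(abs(got$neutral_mass - m) <= 7e-6 * m))
  # Da mode, boundary inclusive
  sp2 <- make_spectrum(c(100), c(10), precursor_mh = m + 0.5 + MASS$proton)
  got2 <- precursor_candidates(db, sp2, search_params(0.5, "Da"))
  expect_true(m %in% got2$neutral_mass)
  # empty DB window
  sp3 <- make_spectrum(c(100), c(10), precursor_mh = 9999)
  expect_equal(nrow(precursor_candidates(db, sp3, search_params())), 0L)
})

test_that("site-isomer enumeration matches the worked examples and counts", {
  six <- enumerate_site_configs("FSAASSASK", 2)
  expect_equal(vapply(six, function(p) modified_sequence("FSAASSASK", p),
                      character(1)),
               c("FsAAsSASK", "FsAASsASK", "FsAASSAsK",
                 "FSAAssASK", "FSAAsSAsK", "FSAASsAsK"))
  expect_equal(vapply(enumerate_site_configs("SCPEDCK", 1), function(p)
    modified_sequence("SCPEDCK", p), character(1)), "sCPEDCK")
  expect_equal(enumerate_site_configs("ANYSEQ", 0), list(integer(0)))
  expect_error(enumerate_site_configs("SCPEDCK", 2), "exceeds")
})

test_that("site-config count equals C(#ST, n) via bitmask enumeration", {
  set.seed(201)
  for (rep in 1:20) {
    s <- random_protein(sample(4:12, 1))
    sites <- which(strsplit(s, "")[[1]] %in% c("S", "T"))
    ns <- length(sites)
    if (ns == 0 || ns > 8) next
    for (n in 0:ns) {
      got <- enumerate_site_configs(s, n)
      # independent oracle: all bitmasks over the site set
      masks <- 0:(2^ns - 1)
      want <- sum(vapply(masks, function(m)
        sum(bitwAnd(m, 2^(0:(ns - 1))) > 0) == n, logical(1)))
      expect_length(got, want)
      expect_false(any(duplicated(vapply(got, paste, character(1),
                                         collapse = ","))))
    }
  }
})

test_that("theoretical b/y masses match closed-form values", {
  th <- generate_theoretical("AK", integer(0))
  b1 <- th$mz[th$series == "b" & th$index == 1 & th$loss == "none"]
  y1 <- th$mz[th$series == "y" & th$index == 1 & th$loss == "none"]
  expect_equal(b1, 72.044386, tolerance = 1e-5)
  expect_equal(y1, 147.112802, tolerance = 1e-5)
})

test_that("b/y complementarity holds at every index", {
  set.seed(202)
  for (rep in 1:10) {
    s <- random_protein(sample(5:15, 1))
    sites <- which(strsplit(s, "")[[1]] %in% c("S", "T"))
    pos <- if (length(sites)) sites[sample.int(length(sites), 1)] else
      integer(0)
    th <- generate_theoretical(s, pos)
    L <- nchar(s)
    mh <- compute_mass(s, length(pos)) + MASS$proton
    plain <- th[th$loss == "none" & th$charge == 1, ]
    for (i in 1:(L - 1)) {
      b <- plain$mz[plain$series == "b" & plain$index == i]
      y <- plain$mz[plain$series == "y" & plain$index == L - i]
      expect_equal(b + y, mh + MASS$proton, tolerance = 1e-6)
    }
  }
})

test_that("phospho placement shifts covering fragments by the HPO3 delta", {
  un <- generate_theoretical("SCPEDCK", integer(0))
  ph <- generate_theoretical("SCPEDCK", 1L)
  for (i in 1:6) {
    bu <- un$mz[un$series == "b" & un$index == i & un$loss == "none"]
    bp <- ph$mz[ph$series == "b" & ph$index == i & ph$loss == "none"]
    expect_equal(bp - bu, MASS$phospho, tolerance = 1e-9)
  }
  # -H3PO4 variants exist only when a phospho residue is in the fragment
  expect_false(any(un$loss == "H3PO4"))
  expect_true(any(ph$loss == "H3PO4"))
})

test_that("loss variants are gated on residue content", {
  th <- generate_theoretical("GGKGG", integer(0))  # K only at position 3
  # b1, b2 contain no R/K/N/Q -> no NH3 loss; b3+ do
  expect_false(any(th$series == "b" & th$index <= 2 & th$loss == "NH3"))
  expect_true(any(th$series == "b" & th$index == 3 & th$loss == "NH3"))
  # no S/T/E/D anywhere -> no water losses
  expect_false(any(th$loss == "H2O"))
})

test_that("peak_score is the sigmoid weight", {
  expect_equal(peak_score(0), 0)
  expect_equal(peak_score(1), 0.4621172, tolerance = 1e-6)
  expect_equal(peak_score(100), 1, tolerance = 1e-40)
  expect_error(peak_score(-1), "negative")
  # monotone (strictly until double-precision saturation at 1)
  expect_true(all(diff(peak_score(seq(0, 100, by = 5))) >= 0))
  expect_true(all(diff(peak_score(seq(0, 20, by = 1))) > 0))
})

test_that("score_match counts each experimental peak once and is bounded by M", {
  th <- generate_theoretical("FSAASSASK", c(2L, 5L))
  sp <- make_spectrum(c(th$mz[1], th$mz[1] + 0.3, 5000),
                      c(100, 100, 100))
  sm <- score_match(sp, th, search_params())
  expect_equal(sm$M, 2L)  # both near peaks match, far one does not
  expect_equal(sm$score, 2 * peak_score(100), tolerance = 1e-9)
  expect_lte(sm$score, sm$M)
  # no peaks in tolerance
  sp0 <- make_spectrum(c(5000), c(100))
  expect_equal(score_match(sp0, th, search_params())$M, 0L)
})

test_that("score_match equals the brute-force double-loop oracle", {
  set.seed(203)
  for (rep in 1:30) {
    s <- random_protein(sample(6:12, 1))
    sites <- which(strsplit(s, "")[[1]] %in% c("S", "T"))
    pos <- if (length(sites)) sites[1] else integer(0)
    th <- generate_theoretical(s, pos)
    sp <- make_spectrum(runif(40, 100, 1500), runif(40, 0, 100))
    got <- score_match(sp, th, search_params())
    want <- oracle_score(sp, th, 0.8)
    expect_equal(got$M, want$M)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("search_spectrum ranks the planted peptide first and partitions origins", {
  db <- shared_db()
  set.seed(204)
  pool <- simulation_peptides(min_st = 1)
  pep <- pool[5]
  sites <- which(strsplit(pep, "")[[1]] %in% c("S", "T"))
  modseq <- modified_sequence(pep, sites[1])
  sim <- simulate_spectrum(modseq, 2L,
                           sim_config(noise_n = 10L, mz_jitter_sd = 0.05))
  sp <- bin_denoise(normalize_spectrum(sim$spectrum))
  res <- search_spectrum(sp, db)
  expect_gt(nrow(res$target), 0)
  expect_equal(res$target$modseq[1], modseq)
  expect_false(any(res$target$is_decoy))
  expect_true(all(res$decoy$is_decoy))
  expect_true(all(diff(res$target$score) <= 1e-12))
  expect_true(all(res$target$M >= 1))

  # spectrum with no precursor candidates -> two empty lists
  far <- make_spectrum(c(100), c(10), precursor_mh = 20000)
  res0 <- search_spectrum(far, db)
  expect_equal(nrow(res0$target), 0L)
  expect_equal(nrow(res0$decoy), 0L)
})

test_that("true site config outscores isomers on noise-free spectra", {
  set.seed(205)
  pool <- simulation_peptides(min_st = 2)
  cfg <- sim_config(coverage = 1, mz_jitter_sd = 0, noise_n = 0L,
                    precursor_jitter_ppm = 0)
  for (pep in pool[c(2, 9, 17)]) {
    sites <- which(strsplit(pep, "")[[1]] %in% c("S", "T"))
    true_pos <- sites[sample.int(length(sites), 1)]
    modseq <- modified_sequence(pep, true_pos)
    sim <- simulate_spectrum(modseq, 2L, cfg)
    sp <- normalize_spectrum(sim$spectrum)
    true_score <- NULL
    for (pos in enumerate_site_configs(pep, 1L)) {
      th <- generate_theoretical(pep, pos, z = 2L)
      sc <- score_match(sp, th, search_params())$score
      if (identical(pos, true_pos)) true_score <- sc
    }
    for (pos in enumerate_site_configs(pep, 1L)) {
      th <- generate_theoretical(pep, pos, z = 2L)
      expect_lte(score_match(sp, th, search_params())$score,
                 true_score + 1e-9)
    }
  }
})
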