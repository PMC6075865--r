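test_that("self-similarity is 100% and gapless similarity is symmetric", {
  seg <- snareSegments()
  expect_equal(percentSimilarity(seg$snap25_sn1,
                                 seg$snap25_sn1)@percentSimilarity, 100)
  for (pair in list(c("cpx2_ctd_box", "snap25_sn1"),
                    c("snap25_sn2", "syx1a"))) {
    ab <- percentSimilarity(seg[[pair[1]]], seg[[pair[2]]])
    ba <- percentSimilarity(seg[[pair[2]]], seg[[pair[1]]])
    expect_equal(ab@percentSimilarity, ba@percentSimilarity)
    expect_identical(ab@mode, "gapless")
  }
})

test_that("gapless and global-affine similarity agree on the SNARE pairs", {
  seg <- snareSegments()
  for (tn in c("snap25_sn1", "snap25_sn2", "syb2", "syx1a")) {
    g0 <- percentSimilarity(seg$cpx2_ctd_box, seg[[tn]], mode = "gapless")
    g1 <- percentSimilarity(seg$cpx2_ctd_box, seg[[tn]], mode = "global")
    expect_equal(g1@percentSimilarity, g0@percentSimilarity,
                 info = tn)
  }
})

test_that("unequal-length comparisons fall back to global alignment", {
  seg <- snareSegments()
  r <- percentSimilarity(seg$cpx2_ctd, seg$snap25_sn1)
  expect_identical(r@mode, "global-affine")
  expect_true(r@percentSimilarity >= 0 && r@percentSimilarity <= 100)
})

test_that("non-standard residues are rejected with their position", {
  expect_error(percentSimilarity("ACDX", "ACDE"), "position 4")
  expect_error(hydrophobicMoment("ABC"), "position 2")
})

test_that("the hydrophobic moment obeys its structural invariants", {
  scale <- hydrophobicityScale("eisenberg")
  ## single residue: muH equals |H|
  expect_equal(hydrophobicMoment("I")@muH, abs(scale[["I"]]))
  expect_equal(hydrophobicMoment("K")@muH, abs(scale[["K"]]))
  ## bounded by max |H|, non-negative, over random peptides
  set.seed(7)
  for (i in 1:20) {
    s <- paste(sample(names(scale), sample(3:25, 1), replace = TRUE),
               collapse = "")
    hw <- hydrophobicMoment(s)
    expect_gte(hw@muH, 0)
    expect_lte(hw@muH, max(abs(hw@H)) + 1e-12)
    ## rotation invariance: any phase origin gives the same magnitude
    for (phase in c(37, 120, 251))
      expect_equal(muHWithPhase(hw@H, 100, phase), hw@muH,
                   tolerance = 1e-12)
  }
})

test_that("helical wheel angles follow the 100-degree helix period", {
  hw <- helicalWheel(strrep("A", 19))
  expect_equal(hw$angle_deg[1], 0)
  expect_equal(hw$angle_deg[2], 100)
  expect_equal(hw$angle_deg[19], 0)   # (18 * 100) mod 360
  expect_true(all(hw$angle_deg >= 0 & hw$angle_deg < 360))
})

test_that("the CTD hydrophobic face is angularly coherent on the wheel", {
  hw <- helicalWheel(snareSegments()$cpx2_ctd_box)
  hydro <- hw$residue %in% c("L", "V", "M", "F", "I")
  span <- angularSpan(unique(hw$angle_deg[hydro]))
  ## an amphipathic helix keeps its hydrophobic residues on one face:
  ## brute-force enumeration puts them within a half-circle plus one step
  expect_lte(span, 180)
})

test_that("mimicry scans locate embedded motifs and average per target", {
  seg <- snareSegments()
  ## exact embedding: a window scores 100%
  sc0 <- scanMimicry(seg$snap25_sn1@sequence, list(seg$snap25_sn1))
  expect_true(any(sc0$windows$percent_similarity == 100))
  ## embedding with 2 substitutions: best window at the embedding site
  q <- paste0("MKDAAAGSTP", "VEEGMNHINQDAKEAEKQ", "GGSDDEL")
  sc <- scanMimicry(c(sp1 = q), list(seg$snap25_sn1), window = 18)
  best <- sc$windows[which.max(sc$windows$percent_similarity), ]
  expect_equal(best$start, 11)
  ## summary over species = arithmetic mean of per-species best scores
  q2 <- paste0("MTTT", seg$snap25_sn1@sequence, "KKE")
  sc2 <- scanMimicry(c(sp1 = q, sp2 = q2), list(seg$snap25_sn1),
                     window = 18)
  best1 <- max(sc2$windows$percent_similarity[sc2$windows$query == "sp1"])
  best2 <- max(sc2$windows$percent_similarity[sc2$windows$query == "sp2"])
  expect_equal(sc2$summary$mean_best_percent, mean(c(best1, best2)))
  expect_error(scanMimicry(q, list()), "no target")
  expect_error(scanMimicry("ACDE", list(seg$snap25_sn1), window = 18),
               "window exceeds")
})

test_that("peptide segments validate coordinates and alphabet", {
  s <- peptideSegment("x", "LDTVLKYLPGPLQDMFKK", 117, 134)
  expect_equal(s@endRes - s@startRes + 1L, nchar(segmentSequence(s)))
  expect_error(peptideSegment("bad", "ACDE", 1, 10), "length")
  expect_error(peptideSegment("bad", "ACDB"), "non-standard")
})
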