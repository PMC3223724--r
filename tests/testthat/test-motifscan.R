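test_that("twin-arginine scanner finds the leftmost ZXRRX-phi-phi motif", {
  m <- scan_tat_motif("MSDRRGFLKAAA")
  expect_equal(c(m$start, m$end), c(2L, 8L))
  expect_null(scan_tat_motif("MKKLLALAQQQQ"))       # no RR pair
  expect_null(scan_tat_motif("MSDRR"))              # shorter than the motif
  # motif outside the search window is ignored
  far <- paste0(strrep("Q", 40), "SNRRQFL")
  expect_null(scan_tat_motif(far))
  expect_false(is.null(scan_tat_motif(far, window = 80)))
})

test_that("lipobox scanner reports cleavage before the invariant Cys", {
  m <- scan_lipobox("MKKLLLAGCSSQQ")
  expect_equal(m$end, 9L)
  expect_equal(m$cleavage_pos, 8L)
  expect_null(scan_lipobox("MKKLLLAGDQQQ"))         # no Cys
  # Cys beyond the window is ignored
  late <- paste0(strrep("Q", 39), "LAGC")
  expect_null(scan_lipobox(late))
  expect_false(is.null(scan_lipobox(late, window = 60)))
})

test_that("Tat-lipoprotein detection composes both rules with a gap limit", {
  tl <- paste0("MSNRRQFL", strrep("Q", 9), "LAGC", strrep("Q", 40))
  m <- detect_tat_lipoprotein(tl)
  expect_equal(m$kind, "TAT_LIPO")
  expect_equal(m$cleavage_pos, 20L)
  tat_only <- paste0("MSNRRQFL", strrep("Q", 60))
  expect_null(detect_tat_lipoprotein(tat_only))
  lipo_only <- paste0("MKK", strrep("Q", 14), "LAGC", strrep("Q", 40))
  expect_null(detect_tat_lipoprotein(lipo_only))
  # Cys too far downstream of the RR pair
  far <- paste0("MSNRRQFL", strrep("Q", 35), "LAGC", strrep("Q", 40))
  expect_null(detect_tat_lipoprotein(far))
})

test_that("Sec heuristic reproduces the classic three-part leader", {
  m <- scan_sec_signal("MKKTAIAIAVALAGFATVAQAAPQQNDEKQ")
  expect_equal(m$cleavage_pos, 21L)
  # no positive n-region
  expect_null(scan_sec_signal(paste0("DDDDD", strrep("L", 20), "AQAQQ")))
  # hydrophobic 60-mer without an Ala/Ser cleavage site
  expect_null(scan_sec_signal(paste0("MK", strrep("L", 58))))
})

test_that("twin-glycine leader requires a small ORF and a GG pair in window", {
  s <- paste0("M", strrep("Q", 15), "GG", strrep("N", 30))
  m <- scan_gg_leader(s)
  expect_equal(m$cleavage_pos, 18L)
  expect_null(scan_gg_leader(paste0("M", strrep("Q", 40))))      # no GG
  expect_null(scan_gg_leader(paste0("M", strrep("Q", 15), "GG",
                                    strrep("N", 400))))          # too long
  expect_null(scan_gg_leader(paste0("MGG", strrep("Q", 40))))    # GG too early
})

test_that("beta-signal rule checks the terminus and alternating positions", {
  expect_true(scan_beta_csig_rule("QQQQQQIAVALAAAF"))
  expect_false(scan_beta_csig_rule("QQQQQQIAVALAAAK"))  # no terminal F/Y
  expect_false(scan_beta_csig_rule("QQQQQQIAVADAAAF"))  # D at 5 from C
  expect_false(scan_beta_csig_rule("IAVALAAF"))         # shorter than 9
})

test_that("scanners agree with brute-force oracles on a random corpus", {
  seqs <- random_seqs(2000, seed = 1)
  for (s in seqs) {
    tat <- scan_tat_motif(s)
    expect_identical(if (is.null(tat)) integer() else tat$start,
                     utils::head(oracle_tat_starts(s), 1L), label = s)
    lip <- scan_lipobox(s)
    expect_identical(if (is.null(lip)) integer() else lip$end,
                     utils::head(oracle_lipobox_cys(s), 1L), label = s)
    gg <- scan_gg_leader(s)
    expect_identical(if (is.null(gg)) integer() else gg$end,
                     utils::head(oracle_gg_ends(s), 1L), label = s)
    expect_identical(scan_beta_csig_rule(s), oracle_beta(s), label = s)
    sec <- scan_sec_signal(s)
    expect_identical(if (is.null(sec)) NA_integer_ else sec$cleavage_pos,
                     oracle_sec(s), label = s)
  }
})

test_that("X residues never satisfy any residue class", {
  expect_null(scan_tat_motif("MSDRRGXLKAAA"))   # X at a phi position
  expect_null(scan_lipobox("MKKLLLAGXSS"))      # X at the Cys position
  expect_false(scan_beta_csig_rule("QQQQQQIAVALAAAX"))
  # X in a hydropathy window counts as maximally hydrophilic: a marginal
  # 19-residue Ala window passes, but not with one X in it
  pure <- paste0(strrep("D", 30), strrep("A", 19), strrep("D", 30))
  with_x <- paste0(strrep("D", 30), strrep("A", 9), "X", strrep("A", 9),
                   strrep("D", 30))
  expect_length(scan_tm_hydropathy(pure), 1L)
  expect_length(scan_tm_hydropathy(with_x), 0L)
})

test_that("hydropathy spans match a sliding-window oracle", {
  # one insert, two inserts, and random sequences
  one <- paste0(strrep("D", 30), strrep("L", 25), strrep("D", 30))
  two <- paste0(strrep("D", 20), strrep("L", 25), strrep("D", 30),
                strrep("I", 25), strrep("D", 20))
  polyd <- strrep("D", 80)
  seqs <- c(one, two, polyd, random_seqs(300, min_len = 19, max_len = 120,
                                         seed = 4))
  for (s in seqs) {
    got <- lapply(scan_tm_hydropathy(s), function(m) c(m$start, m$end))
    expect_identical(got, unname(oracle_tm_spans(s)), label = substr(s, 1, 30))
  }
  expect_length(scan_tm_hydropathy(two), 2L)
  expect_length(scan_tm_hydropathy(polyd), 0L)
})

test_that("planted motifs are recovered exactly and decoys never fire", {
  b <- get_bundle7()
  tr <- b$truth
  seqs <- stats::setNames(b$proteins$sequence, b$proteins$locus_tag)
  for (i in seq_len(nrow(tr))) {
    s <- seqs[[tr$locus_tag[i]]]
    cls <- tr$class[i]
    if (cls %in% c("lipo", "tat_lipo")) {
      expect_equal(scan_lipobox(s)$end, 21L, label = tr$locus_tag[i])
    }
    if (cls %in% c("tat", "tat_lipo", "tat_decoy")) {
      hit <- scan_tat_motif(s)
      if (cls == "tat_decoy") expect_null(hit, label = tr$locus_tag[i])
      else expect_equal(hit$start, 2L, label = tr$locus_tag[i])
    }
    if (cls %in% c("gg", "gg_decoy")) {
      hit <- scan_gg_leader(s)
      if (cls == "gg_decoy") expect_null(hit, label = tr$locus_tag[i])
      else expect_equal(hit$end, 16L, label = tr$locus_tag[i])
    }
    if (cls %in% c("beta", "t5dss", "beta_decoy")) {
      expect_identical(scan_beta_csig_rule(s), cls != "beta_decoy",
                       label = tr$locus_tag[i])
    }
    if (cls == "lipo_decoy") expect_null(scan_lipobox(s),
                                         label = tr$locus_tag[i])
  }
})

test_that("+2 sorting rule and composition scores behave as specified", {
  expect_equal(check_plus2("CDAAAA"), "IM_retained")
  expect_equal(check_plus2("CSAAAA"), "OM_sorted")
  expect_warning(res <- check_plus2("C"), "no \\+2")
  expect_equal(res, "OM_sorted")
  expect_error(check_plus2("DAAA"), "Cys")

  expect_equal(glyser_enrichment("GSGSGS", 0.12), 1 - 0.12)
  expect_equal(glyser_enrichment("AAAA", 0.12), -0.12)
  b <- get_bundle7()
  bg <- proteome_background(b$proteins$sequence)
  ch <- unlist(strsplit(b$proteins$sequence, ""))
  ch <- ch[ch != "X"]
  expect_equal(bg, mean(ch %in% c("G", "S")))

  expect_equal(basic_cterm_enrichment(paste0(strrep("A", 10), "KRKRKRKRKR"),
                                      n = 10), 1.0)
  expect_equal(basic_cterm_enrichment(strrep("A", 30)), 0.0)
  tail_mixed <- paste0(strrep("Q", 30), "KARHQQNDET")  # 3 basic in last 10
  expect_equal(basic_cterm_enrichment(tail_mixed, n = 10), 0.3)
})

test_that("scanners are pure and leftmost under multiple candidate sites", {
  s <- "MSNRRQFLQQSNRRQFLQQQ"   # two Tat motifs; leftmost wins
  m1 <- scan_tat_motif(s)
  expect_equal(m1$start, 2L)
  expect_identical(scan_tat_motif(s), m1)
  s2 <- paste0("MKK", strrep("Q", 14), "LAGC", "LAGC", strrep("Q", 30))
  expect_equal(scan_lipobox(s2)$end, 21L)
})
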