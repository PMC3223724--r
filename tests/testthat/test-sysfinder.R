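make_genes <- function(slots, genome = "G1", annotation = NULL) {
  data.frame(locus_tag = sprintf("g%02d", slots), genome_id = genome,
             replicon_id = "chr", start = slots * 1000L + 1L,
             end = slots * 1000L + 900L, strand = "+",
             annotation = if (is.null(annotation)) "" else annotation,
             stringsAsFactors = FALSE)
}

dhit <- function(tags, accs) {
  data.frame(locus_tag = tags, accession = accs, evalue = 1e-20,
             ali_from = 1L, ali_to = 50L, stringsAsFactors = FALSE)
}

test_that("cluster_context forms maximal runs bounded by the gene gap", {
  # gene_index comes from the full genome, then the seed genes are a subset
  all_genes <- index_genes(make_genes(1:11))
  genes <- all_genes[all_genes$locus_tag %in%
                       sprintf("g%02d", c(1, 2, 3, 10, 11)), ]
  loci <- cluster_context(genes, max_gap_genes = 3)
  expect_length(loci, 2L)
  expect_equal(loci[[1]]$locus_tag, c("g01", "g02", "g03"))
  expect_equal(loci[[2]]$locus_tag, c("g10", "g11"))
  expect_length(cluster_context(genes[1, , drop = FALSE]), 1L)
  close_genes <- all_genes[all_genes$locus_tag %in%
                             sprintf("g%02d", c(1, 3, 5, 7)), ]
  expect_length(cluster_context(close_genes, max_gap_genes = 3), 1L)
  # loci never span replicons
  g2 <- make_genes(1:4)
  g2$replicon_id <- c("chr", "chr", "p1", "p1")
  expect_length(cluster_context(index_genes(g2), max_gap_genes = 3), 2L)
})

test_that("secretin hits seed loci with registry system classes", {
  genes <- make_genes(1:20)
  loci <- find_secretion_loci(dhit("g05", "pfam00577"), genes)
  expect_equal(loci$system_class, "T7SS")
  expect_equal(loci$anchor, "g05")
})

test_that("a lone TolC hit is efflux, promoted to T1SS by partner domains", {
  genes <- make_genes(1:20)
  lone <- find_secretion_loci(dhit("g05", "TIGR01844"), genes)
  expect_equal(lone$system_class, "efflux/unassigned")
  partnered <- find_secretion_loci(
    dhit(c("g05", "g06"), c("TIGR01844", "TIGR01843")), genes)
  expect_equal(partnered$system_class, "T1SS")
  expect_equal(partnered$members, "g05,g06")
})

test_that("hits to unregistered accessions are ignored with a warning", {
  genes <- make_genes(1:5)
  expect_warning(
    loci <- find_secretion_loci(dhit(c("g01", "g03"),
                                     c("pfam00577", "pfam99999")), genes),
    "pfam99999")
  expect_equal(nrow(loci), 1L)
})

test_that("five planted systems are recovered with their classes", {
  genes <- make_genes(1:40)
  hits <- dhit(c("g02", "g10", "g18", "g26", "g34"),
               c("pfam00577", "pfam03783", "TIGR02519", "pfam02107",
                 "TIGR02516"))
  set.seed(5)
  hits <- hits[sample(nrow(hits)), ]  # input permutation must not matter
  loci <- find_secretion_loci(hits, genes)
  expect_equal(nrow(loci), 5L)
  expect_setequal(loci$system_class, c("T7SS", "T8SS", "T2bSS", "T3bSS",
                                       "T3aSS"))
})

test_that("T1SS substrate candidates require size, no signal and composition", {
  b <- get_bundle7()
  res <- get_result7()
  cands <- res$candidates
  t1 <- cands[cands$candidate_kind == "T1SS_substrate", ]
  expect_setequal(unique(b$truth$slot[match(t1$locus_tag, b$truth$locus_tag)]),
                  12L)
  expect_equal(sort(unique(table(t1$locus_tag))), 2L)  # beside both T1SS loci
  # a signal-bearing or short protein is never a candidate
  expect_false(any(b$truth$class[match(t1$locus_tag, b$truth$locus_tag)] %in%
                     c("sec", "lipo")))
})

test_that("bacteriocin candidates sit in C39 loci with a GG leader", {
  b <- get_bundle7()
  res <- get_result7()
  bact <- res$candidates[res$candidates$candidate_kind == "bacteriocin", ]
  expect_equal(nrow(bact), 19L)  # one per genome
  expect_true(all(b$truth$slot[match(bact$locus_tag, b$truth$locus_tag)] == 16L))
  # the same ORF far from any C39 locus is not flagged
  genes <- make_genes(1:30)
  prot <- data.frame(locus_tag = "g25", genome_id = "G1",
                     sequence = b$proteins$sequence[b$truth$slot == 16][1],
                     stringsAsFactors = FALSE)
  loci <- find_secretion_loci(dhit("g02", "pfam0341"), genes)
  cands <- find_bacteriocin_candidates(loci, prot, genes,
                                       dhit("g02", "pfam0341"))
  expect_equal(nrow(cands), 0L)
})

test_that("holin candidates are small basic single-span phage proteins", {
  b <- get_bundle7()
  res <- get_result7()
  hol <- res$candidates[res$candidates$candidate_kind == "holin", ]
  expect_equal(nrow(hol), 19L)
  expect_true(all(b$truth$slot[match(hol$locus_tag, b$truth$locus_tag)] == 21L))
  # a large protein or an acidic C-terminus disqualifies
  big <- data.frame(locus_tag = "h1", sequence = strrep("L", 300),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(find_holin_candidates(big, "h1")), 0L)
  acidic <- data.frame(
    locus_tag = "h2",
    sequence = paste0("M", strrep("D", 24), strrep("L", 21), strrep("D", 40)),
    stringsAsFactors = FALSE)
  expect_equal(nrow(find_holin_candidates(acidic, "h2")), 0L)
})

test_that("microcompartment cargo must be shell-exclusive and adjacent", {
  genes <- rbind(make_genes(1:20, "G1"), make_genes(1:20, "G2"),
                 make_genes(1:20, "G3"))
  genes$locus_tag <- paste0(genes$genome_id, "_", genes$locus_tag)
  shell <- dhit(c("G1_g05", "G2_g05"), "pfam00936")
  og <- data.frame(
    locus_tag = c("G1_g06", "G2_g06",            # exclusive + adjacent
                  "G1_g18", "G2_g18",            # exclusive but distant
                  "G1_g07", "G2_g07", "G3_g07"), # present in a shell-free genome
    group_id = c("OGA", "OGA", "OGB", "OGB", "OGC", "OGC", "OGC"),
    genome_id = c("G1", "G2", "G1", "G2", "G1", "G2", "G3"),
    stringsAsFactors = FALSE)
  cands <- find_microcompartment_candidates(og, shell, genes)
  expect_setequal(cands$locus_tag, c("G1_g06", "G2_g06"))
})

test_that("mixed OM/extracellular evidence flags type-V-like proteins", {
  rec_flag <- make_record(
    tools = rbind(tool_row("P1", "signalp", "signal_lepb", 21),
                  tool_row("P1", "bomp", "beta_barrel", "TRUE"),
                  tool_row("P1", "psortb", "global_location", "EXTRA"),
                  tool_row("P1", "cello", "global_location", "OM")))
  expect_equal(nrow(flag_t5dss_like(list(rec_flag))), 1L)
  rec_cyt <- make_record(
    tools = rbind(tool_row("P1", "psortb", "global_location", "CYT"),
                  tool_row("P1", "cello", "global_location", "CYT")))
  expect_equal(nrow(flag_t5dss_like(list(rec_cyt))), 0L)
  rec_om <- make_record(
    tools = rbind(tool_row("P1", "signalp", "signal_lepb", 21),
                  tool_row("P1", "bomp", "beta_barrel", "TRUE"),
                  tool_row("P1", "psortb", "global_location", "OM"),
                  tool_row("P1", "cello", "global_location", "OM")))
  expect_equal(nrow(flag_t5dss_like(list(rec_om))), 0L)
})

test_that("long Sec-like leaders that defeat the standard window are flagged", {
  long_leader <- paste0("MKK", strrep("Q", 37), strrep("L", 10), "QNAQA",
                        strrep("Q", 60))
  prot <- data.frame(locus_tag = c("L1", "L2"),
                     sequence = c(long_leader, strrep("Q", 100)),
                     stringsAsFactors = FALSE)
  fl <- flag_long_leader(prot)
  expect_equal(fl$locus_tag, "L1")
})
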