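test_that("majority_vote computes weighted plurality with margin", {
  v <- majority_vote(c("CYT", "CYT", "EXTRA"))
  expect_equal(v$label, "CYT")
  expect_equal(v$margin, 1 / 3)
  tie <- majority_vote(c("OM", "EXTRA"))
  expect_equal(tie$label, "UNKNOWN")
  expect_equal(tie$margin, 0)
  expect_equal(majority_vote(c("OM", "EXTRA"), tie_policy = "alpha")$label,
               "EXTRA")
  # weights by voter name
  v2 <- majority_vote(stats::setNames(c("OM", "EXTRA"), c("a", "b")),
                      weights = c(a = 3, b = 1))
  expect_equal(v2$label, "OM")
  expect_equal(v2$margin, 0.5)
  expect_error(majority_vote("Golgi"), "vocabulary")
})

test_that("majority_vote agrees with an exhaustive counting oracle", {
  set.seed(42)
  labs <- c("CYT", "IM", "PERI", "OM", "EXTRA")
  for (i in 1:500) {
    v <- sample(labs, sample(1:8, 1L), replace = TRUE)
    got <- majority_vote(v)
    want <- oracle_vote(v)
    expect_equal(got$label, want$label)
    expect_equal(got$margin, want$margin)
  }
})

test_that("the decision tree follows its precedence on hand-built records", {
  cfg <- locweaver_config()
  # phage beats everything
  ph <- decide(make_record(phage = TRUE,
                           tools = tool_row("P", "psortb", "global_location",
                                            "CYT")))
  expect_equal(ph$label, "PHAGE")

  # secretion component takes the registry location
  sc <- decide(make_record(secretion_component = "LIPO_OM"))
  expect_equal(sc$label, "LIPO_OM")
  expect_equal(sc$trail$rule[nrow(sc$trail)], "secretion_component")
  # "mixed" components fall through
  mx <- decide(make_record(secretion_component = "mixed"))
  expect_equal(mx$label, "CYT")

  # lipoprotein with D+2 under the enterobacterial rule
  lipo_seq <- paste0("MKK", strrep("Q", 14), "LAGCD", strrep("Q", 40))
  ent <- locweaver_config(decide = list(plus2_mode = "enterobacterial"))
  cl <- decide(make_record(sequence = lipo_seq,
                           motifs = scan_all_motifs(lipo_seq)), config = ent)
  expect_equal(cl$label, "LIPO_IM")
  expect_equal(cl$trail$rule[nrow(cl$trail)], "lipoprotein")
  # same record without D+2 sorts to the outer membrane
  lipo_sd <- sub("LAGCD", "LAGCS", lipo_seq)
  cl2 <- decide(make_record(sequence = lipo_sd,
                            motifs = scan_all_motifs(lipo_sd)), config = ent)
  expect_equal(cl2$label, "LIPO_OM")
  # genus mode: IM anchor domain, then Gly/Ser enrichment, then LIPO_OM
  expect_equal(decide(make_record(sequence = lipo_seq,
                                  motifs = scan_all_motifs(lipo_seq),
                                  domains = "pfam00529"))$label, "LIPO_IM")
  expect_equal(decide(make_record(sequence = lipo_seq,
                                  motifs = scan_all_motifs(lipo_seq),
                                  glyser = 0.2))$label, "LIPO_SURFACE")
  expect_equal(decide(make_record(sequence = lipo_seq,
                                  motifs = scan_all_motifs(lipo_seq),
                                  glyser = -0.01))$label, "LIPO_OM")

  # many TM spans give the inner membrane
  spans <- paste(sprintf("%d-%d", seq(10, 290, 40), seq(30, 310, 40)),
                 collapse = ";")
  tm <- decide(make_record(tools = tool_row("P", "tmhmm", "tm_spans", spans)))
  expect_equal(tm$label, "IM")

  # beta-barrel evidence wins the exported branch over the vote
  om <- decide(make_record(
    tools = rbind(tool_row("P", "signalp", "signal_lepb", 21),
                  tool_row("P", "bomp", "beta_barrel", "TRUE"),
                  tool_row("P", "psortb", "global_location", "EXTRA"),
                  tool_row("P", "cello", "global_location", "OM"),
                  tool_row("P", "sosuigramn", "global_location", "OM"))))
  expect_equal(om$label, "OM")
  expect_equal(om$trail$outcome[nrow(om$trail)], "OM_beta")

  # exported without barrel evidence follows the restricted vote
  peri <- decide(make_record(
    tools = rbind(tool_row("P", "signalp", "signal_lepb", 21),
                  tool_row("P", "psortb", "global_location", "PERI"),
                  tool_row("P", "cello", "global_location", "PERI"),
                  tool_row("P", "subloc", "global_location", "CYT"))))
  expect_equal(peri$label, "PERI")  # the CYT vote is outside the exported set

  # no evidence at all: cytoplasmic default, low confidence
  none <- decide(make_record())
  expect_equal(none$label, "CYT")
  expect_equal(none$confidence, "low")
  expect_true(none$defaulted)
})

test_that("a single N-terminal span with SP support is treated as a signal", {
  rec <- make_record(
    tools = rbind(tool_row("P", "tmhmm", "tm_spans", "3-23"),
                  tool_row("P", "phobius", "signal_lepb", 21),
                  tool_row("P", "psortb", "global_location", "PERI"),
                  tool_row("P", "cello", "global_location", "PERI")))
  expect_equal(decide(rec)$label, "PERI")
  # without SP-aware support the span anchors the protein in the membrane
  rec2 <- make_record(tools = rbind(
    tool_row("P", "tmhmm", "tm_spans", "3-23"),
    tool_row("P", "psortb", "global_location", "PERI")))
  expect_equal(decide(rec2)$label, "IM")
})

test_that("decide is total, deterministic and order-insensitive", {
  set.seed(99)
  n_checked <- 0L
  for (i in 1:2000) {
    rec <- random_record(i)
    cl <- decide(rec)
    expect_s3_class(cl, "localization_call")
    expect_true(cl$label %in% LOC_VOCAB)
    expect_gte(nrow(cl$trail), 1L)
    # identical input, identical output
    expect_identical(decide(rec)$trail, cl$trail)
    # permuting the evidence rows never changes the call
    if (nrow(rec$tools) > 1L) {
      rec2 <- rec
      rec2$tools <- rec2$tools[sample(nrow(rec2$tools)), , drop = FALSE]
      expect_equal(decide(rec2)$label, cl$label)
      n_checked <- n_checked + 1L
    }
    # the stored trail replays to the stored label
    expect_true(isTRUE(replay_trail(cl, rec)))
  }
  expect_gte(n_checked, 100L)
})

test_that("lower-priority evidence never overturns a higher-priority call", {
  set.seed(7)
  extra_votes <- function(rec) {
    rec$tools <- rbind(rec$tools,
                       tool_row(rec$locus_tag, "cello", "global_location",
                                sample(c("CYT", "IM", "OM"), 1L)),
                       tool_row(rec$locus_tag, "psortb", "global_location",
                                sample(c("PERI", "EXTRA"), 1L)))
    rec
  }
  rules <- c("phage", "secretion_component", "lipoprotein", "tat", "tm", "sec")
  for (i in 1:800) {
    rec <- random_record(i)
    cl <- decide(rec)
    deciding <- cl$trail$rule[nrow(cl$trail)]
    if (deciding %in% rules) {
      expect_equal(decide(extra_votes(rec))$label, cl$label, label = i)
    }
  }
})

test_that("location-informative domains need carriers and purity", {
  calls <- data.frame(
    locus_tag = sprintf("p%02d", 1:12),
    label = c(rep("PERI", 6), rep("CYT", 5), "OM"),
    confidence = "high", defaulted = FALSE, stringsAsFactors = FALSE)
  hits <- data.frame(
    locus_tag = sprintf("p%02d", 1:12),
    accession = c(rep("pfamPURE", 6), rep("pfamMIX", 6)),
    evalue = 1e-10, ali_from = 1L, ali_to = 10L, stringsAsFactors = FALSE)
  map <- infer_domain_locations(calls, hits)
  expect_equal(map$accession, "pfamPURE")
  expect_equal(map$location, "PERI")
  expect_equal(map$n_proteins, 6L)
  expect_equal(map$purity, 1.0)
  # 5 CYT + 1 OM fails purity 1.0 but passes 0.8
  relaxed <- infer_domain_locations(calls, hits, purity_min = 0.8)
  expect_setequal(relaxed$accession, c("pfamPURE", "pfamMIX"))
  # defaulted calls never contribute
  calls$defaulted[1:6] <- TRUE
  expect_equal(nrow(infer_domain_locations(calls, hits)), 0L)
})

test_that("purity matches a brute-force tally on random assignments", {
  set.seed(13)
  for (rep_i in 1:20) {
    n <- 40L
    calls <- data.frame(locus_tag = sprintf("q%02d", 1:n),
                        label = sample(c("CYT", "IM", "PERI"), n, TRUE),
                        confidence = "high", defaulted = FALSE,
                        stringsAsFactors = FALSE)
    hits <- data.frame(locus_tag = calls$locus_tag,
                       accession = sample(c("d1", "d2", "d3"), n, TRUE),
                       evalue = 1, ali_from = 1L, ali_to = 5L,
                       stringsAsFactors = FALSE)
    map <- infer_domain_locations(calls, hits, min_n = 5, purity_min = 0.6)
    for (acc in c("d1", "d2", "d3")) {
      labs <- calls$label[calls$locus_tag %in%
                            hits$locus_tag[hits$accession == acc]]
      tab <- sort(table(labs), decreasing = TRUE)
      included <- length(labs) >= 5 && tab[1] / length(labs) >= 0.6
      expect_equal(acc %in% map$accession, included)
      if (included) {
        expect_equal(map$location[map$accession == acc], names(tab)[1])
      }
    }
  }
})

test_that("domain-map refinement promotes evidence-only proteins and fixes", {
  # six confident PERI carriers plus one evidence-free carrier
  recs <- c(
    lapply(1:6, function(i) make_record(
      locus_tag = paste0("c", i), domains = "pfamLOC",
      tools = rbind(tool_row(paste0("c", i), "signalp", "signal_lepb", 21),
                    tool_row(paste0("c", i), "psortb", "global_location",
                             "PERI"),
                    tool_row(paste0("c", i), "cello", "global_location",
                             "PERI")))),
    list(make_record(locus_tag = "bare", domains = "pfamLOC")))
  names(recs) <- vapply(recs, `[[`, character(1), "locus_tag")
  hits <- data.frame(locus_tag = names(recs), accession = "pfamLOC",
                     evalue = 1, ali_from = 1L, ali_to = 5L,
                     stringsAsFactors = FALSE)
  pass1 <- decide_all(recs)
  expect_equal(pass1$label[pass1$locus_tag == "bare"], "CYT")
  expect_true(pass1$defaulted[pass1$locus_tag == "bare"])
  map <- infer_domain_locations(pass1, hits)
  pass2 <- rerun_with_domain_map(recs, map)
  expect_equal(pass2$label[pass2$locus_tag == "bare"], "PERI")
  # proteins without mapped domains are unchanged
  expect_equal(pass2$label[pass2$locus_tag != "bare"],
               pass1$label[pass1$locus_tag != "bare"])
  # third pass is a fixed point
  map2 <- infer_domain_locations(pass2, hits)
  pass3 <- rerun_with_domain_map(recs, map2)
  expect_identical(pass3, pass2)
})

test_that("Tat hitchhiker candidates are reported, never called", {
  b <- get_bundle7()
  res <- get_result7()
  hh <- tat_hitchhiker_report(res$records, res$calls, b$genes)
  # neighbors of the planted Tat substrate (slot 38) lacking signals: the
  # IM-span slot 40 neighbor has no signal prediction of its own
  expect_true(all(hh$tat_substrate %in%
                    b$truth$locus_tag[b$truth$class %in% c("tat", "tat_lipo")]))
  # the report must not have changed any call
  expect_false(any(res$calls$label[match(hh$locus_tag,
                                         res$calls$locus_tag)] == "UNKNOWN"))
})
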