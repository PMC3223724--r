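panel_og <- function(n_genomes = 19, groups = list()) {
  do.call(rbind, lapply(names(groups), function(gid) {
    g <- groups[[gid]]
    data.frame(locus_tag = g$tags, group_id = gid, genome_id = g$genomes,
               pseudogene = g$pseudo %||% rep(FALSE, length(g$tags)),
               stringsAsFactors = FALSE)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("group consistency is a trichotomy over evaluable members", {
  all_cyt <- data.frame(locus_tag = sprintf("m%02d", 1:19),
                        label = "CYT", stringsAsFactors = FALSE)
  expect_equal(classify_group(all_cyt)$status, "consistent")
  one_off <- all_cyt
  one_off$label[19] <- "OM"
  v <- classify_group(one_off)
  expect_equal(v$status, "mixed")
  expect_equal(v$majority_label, "CYT")
  empty <- data.frame(locus_tag = "m1", label = NA_character_,
                      stringsAsFactors = FALSE)
  expect_equal(classify_group(empty)$status, "no_evidence")
})

test_that("pseudogene members are excluded from evaluation by default", {
  m <- data.frame(locus_tag = c("a", "b", "c"),
                  label = c("CYT", "CYT", "OM"),
                  pseudogene = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  expect_equal(classify_group(m)$status, "consistent")
  expect_equal(classify_group(m, exclude_pseudogenes = FALSE)$status, "mixed")
})

test_that("verdict counts always partition the group set", {
  set.seed(31)
  for (rep_i in 1:10) {
    n_groups <- sample(3:12, 1)
    og <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
      k <- sample(1:6, 1)
      data.frame(locus_tag = sprintf("g%d_%d", g, 1:k),
                 group_id = sprintf("OG%02d", g),
                 genome_id = sprintf("G%d", 1:k), stringsAsFactors = FALSE)
    }))
    calls <- data.frame(locus_tag = og$locus_tag,
                        label = sample(c("CYT", "OM", NA), nrow(og), TRUE),
                        stringsAsFactors = FALSE)
    calls <- calls[!is.na(calls$label), , drop = FALSE]
    v <- classify_groups(og, calls)
    expect_equal(sum(table(v$status)), n_groups)
  }
})

test_that("anomaly flags catch length outliers and missing signals", {
  lens <- c(rep(300, 18), 150)
  memb <- data.frame(locus_tag = sprintf("m%02d", 1:19),
                     sequence = strrep("Q", 1) , stringsAsFactors = FALSE)
  memb$sequence <- vapply(lens, function(l) paste0(
    "MKKT", strrep("L", 8), "QNQQNQAQA", strrep("Q", l - 21)), character(1))
  # drop the leader from the short outlier so it also lacks the signal
  memb$sequence[19] <- strrep("Q", 150)
  fl <- flag_anomalies(memb)
  expect_match(fl$flags[19], "LENGTH_OUTLIER")
  expect_match(fl$flags[19], "SP_MISSING:SEC_SP")
  expect_true(all(fl$flags[1:18] == ""))
  # the converse: one member with a rare extra signal
  memb2 <- data.frame(locus_tag = c("a", "b", "c", "d"),
                      sequence = strrep("Q", 200), stringsAsFactors = FALSE)
  memb2$sequence[1] <- paste0("MSNRRQFL", strrep("Q", 192))
  fl2 <- flag_anomalies(memb2)
  expect_match(fl2$flags[1], "SP_EXTRA:TAT_RR")
})

test_that("core-group detection equals the brute-force definition", {
  set.seed(8)
  for (rep_i in 1:15) {
    n_gen <- sample(3:6, 1)
    og <- do.call(rbind, lapply(1:8, function(g) {
      gens <- sample(sprintf("G%d", 1:n_gen), sample(1:(n_gen + 1), 1),
                     replace = TRUE)
      data.frame(locus_tag = sprintf("t%d_%d", g, seq_along(gens)),
                 group_id = sprintf("OG%d", g), genome_id = gens,
                 stringsAsFactors = FALSE)
    }))
    cg <- core_groups(og, n_genomes = n_gen)
    for (gid in cg$group_id) {
      gens <- og$genome_id[og$group_id == gid]
      brute <- length(gens) == n_gen && !any(duplicated(gens)) &&
        length(unique(gens)) == n_gen
      expect_equal(cg$is_core[cg$group_id == gid], brute, label = gid)
    }
  }
})

test_that("feature trichotomy over core groups matches a brute-force tally", {
  og <- panel_og(groups = list(
    OGP = list(tags = sprintf("p%d", 1:3), genomes = c("G1", "G2", "G3")),
    OGN = list(tags = sprintf("n%d", 1:3), genomes = c("G1", "G2", "G3")),
    OGM = list(tags = sprintf("x%d", 1:3), genomes = c("G1", "G2", "G3"))))
  feat <- stats::setNames(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                            TRUE, FALSE, TRUE),
                          c(sprintf("p%d", 1:3), sprintf("n%d", 1:3),
                            sprintf("x%d", 1:3)))
  counts <- summarize_feature(og, feat, n_genomes = 3)
  expect_equal(unname(counts), c(1L, 1L, 1L))
  # empty panel gives zeros
  empty <- og[0, , drop = FALSE]
  expect_equal(unname(summarize_feature(empty, feat, n_genomes = 3)),
               c(0L, 0L, 0L))
  # random panels against a direct tally
  set.seed(17)
  for (rep_i in 1:10) {
    og2 <- do.call(rbind, lapply(1:6, function(g) data.frame(
      locus_tag = sprintf("r%d_%d", g, 1:4), group_id = sprintf("OG%d", g),
      genome_id = sprintf("G%d", 1:4), stringsAsFactors = FALSE)))
    f <- stats::setNames(sample(c(TRUE, FALSE), nrow(og2), TRUE),
                         og2$locus_tag)
    got <- summarize_feature(og2, f, n_genomes = 4)
    brute <- c(0L, 0L, 0L)
    for (g in 1:6) {
      fg <- f[og2$locus_tag[og2$group_id == sprintf("OG%d", g)]]
      brute[if (all(fg)) 2L else if (!any(fg)) 1L else 3L] <-
        brute[if (all(fg)) 2L else if (!any(fg)) 1L else 3L] + 1L
    }
    expect_equal(unname(got), brute)
  }
})

test_that("the localization contingency table reproduces cell semantics", {
  og <- panel_og(groups = list(
    OG1 = list(tags = c("a1", "a2"), genomes = c("G1", "G2")),
    OG2 = list(tags = c("b1", "b2"), genomes = c("G1", "G2"))))
  og$location <- "PERI"
  tool <- list(toolA = c(a1 = "PERI", a2 = "PERI",    # consistent + agrees
                         b1 = "PERI", b2 = "CYT"))    # inconsistent
  tab <- summarize_localization(og, tool, n_genomes = 2)
  peri_row <- tab[tab$reference == "PERI", ]
  expect_equal(peri_row$n_groups, 2L)
  expect_equal(peri_row$toolA_consistent, 1L)
  expect_equal(peri_row$toolA_agree, 1L)
  expect_equal(tab$n_groups[tab$reference == "Total"], 2L)
  # member order never matters
  og_rev <- og[rev(seq_len(nrow(og))), ]
  expect_equal(summarize_localization(og_rev, tool, n_genomes = 2), tab)
})

test_that("bundle verdicts are all consistent at zero inconsistency", {
  b <- get_bundle7()
  res <- get_result7()
  expect_true(all(res$verdicts$status == "consistent"))
  cg <- core_groups(b$orthologs)
  expect_equal(sum(cg$is_core), 49L)  # the cargo slot is split, all else core
  # planting inconsistency produces mixed verdicts
  og_bad <- make_ortholog_panel(b$truth, inconsistency_rate = 0.3, seed = 5)
  v_bad <- classify_groups(og_bad, res$calls)
  expect_gt(sum(v_bad$status == "mixed"), 0L)
})
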