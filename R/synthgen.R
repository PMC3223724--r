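# Deterministic generator of multi-genome synthetic fixtures with planted
# ground truth: every sorting-signal class, secretion-system locus type,
# decision-tree branch, ortholog-panel structure and tryptic digest the
# pipeline handles is represented by a fixed per-genome slot layout, with
# sequences drawn per seed. Planted motifs strictly satisfy the configured
# scanner rules; decoys violate exactly one condition; backgrounds are
# resampled until they trigger no scanner accidentally.

#' Synthetic-bundle configuration
#'
#' @param n_genomes genomes in the panel (default 19).
#' @param proteins_per_genome proteins per genome (default 50; the planted
#'   slot layout is designed for 50 and repeats/truncates beyond it).
#' @param seed master seed; fixes all randomness (must be < 2^31).
#' @param evidence_dropout probability that a correct tool row is not emitted.
#' @param tool_noise probability that an emitted global label is wrong.
#' @param noise_tool restrict noise to one named tool (`NULL` = all).
#' @param inconsistency_rate fraction of ortholog groups given one
#'   wrong-group member (creates `mixed` verdicts).
#' @param spurious_rate probability of emitting a nonspecific decoy peptide
#'   per protein in the digest.
#' @param background `"uniform"` (default) or `"shewanella"` (an
#'   approximately realistic gammaproteobacterial composition).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_genomes = 19L, proteins_per_genome = 50L,
                         seed = 1L, evidence_dropout = 0, tool_noise = 0,
                         noise_tool = NULL, inconsistency_rate = 0,
                         spurious_rate = 0, background = "uniform") {
  stopifnot(evidence_dropout >= 0, evidence_dropout <= 1,
            tool_noise >= 0, tool_noise <= 1,
            inconsistency_rate >= 0, inconsistency_rate <= 1)
  structure(list(n_genomes = as.integer(n_genomes),
                 proteins_per_genome = as.integer(proteins_per_genome),
                 seed = as.integer(seed),
                 evidence_dropout = evidence_dropout,
                 tool_noise = tool_noise, noise_tool = noise_tool,
                 inconsistency_rate = inconsistency_rate,
                 spurious_rate = spurious_rate, background = background),
            class = "synth_config")
}

.synth_comp <- function(background) {
  if (background == "shewanella") {
    w <- c(A = .09, C = .01, D = .05, E = .06, F = .04, G = .07, H = .02,
           I = .06, K = .05, L = .11, M = .025, N = .04, P = .04, Q = .04,
           R = .05, S = .06, T = .05, V = .07, W = .012, Y = .033)
    return(w / sum(w))
  }
  stats::setNames(rep(1 / 20, 20), .aa20)
}

.rseq <- function(n, comp) {
  paste(sample(names(comp), n, replace = TRUE, prob = comp), collapse = "")
}

.rseq_from <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# hydrophilic filler that cannot seed Sec n-regions, lipoboxes, GG pairs or
# TM spans
.linker_alpha <- c("D", "E", "N", "Q", "S", "T", "P")

# --- per-class sequence builders --------------------------------------------
# Each returns the sequence; positions of planted motifs are fixed by
# construction (Tat motif at 2-8, lipobox Cys at 21, Sec cleavage at 21,
# GG leader end at 16).

.sec_leader <- function() {
  h <- .rseq_from(8L, c("L", "I", "V", "A", "F"))
  c_fill <- .rseq_from(6L, c("Q", "N", "E", "D", "G", "T"))
  paste0("MKKT", h, c_fill, "AQA")  # cleavage after position 21
}

.tm_segment <- function() .rseq_from(21L, c("L", "I", "V", "F", "A"))

.expected_kinds <- function(class) {
  switch(class,
    sec = , met_sec = "SEC_SP",
    beta = , t5dss = c("SEC_SP", "BETA_CSIG"),
    lipo = "LIPOBOX",
    tat = c("TAT_RR", "SEC_SP"),          # Tat leaders satisfy the Sec rule too
    tat_lipo = c("TAT_RR", "LIPOBOX", "TAT_LIPO"),
    gg = "GG_LEADER",
    character())  # im/holin plants are checked via the span count
}

# build one sequence of `class`, resampling until the scanners report exactly
# the planted motif set (TM count checked separately)
.build_seq <- function(class, len, comp, config, opts = list()) {
  for (attempt in 1:400) {
    seq_try <- switch(class,
      cyt = .rseq(len, comp),
      met_exc = paste0("MA", .rseq_from(10L, c("Q", "N", "E", "D", "G", "T",
                                               "S", "V", "I", "L")),
                       "K", .rseq(len - 13L, comp)),
      gs_rich = {
        boosted <- comp
        boosted[c("G", "S")] <- boosted[c("G", "S")] + 0.08
        .rseq(len, boosted / sum(boosted))
      },
      sec = paste0(.sec_leader(), .rseq(len - 21L, comp)),
      met_sec = paste0(.sec_leader(), "AP",
                       .rseq_from(8L, c("Q", "N", "E", "D", "G", "T")), "K",
                       .rseq(len - 32L, comp)),
      beta = , t5dss = paste0(.sec_leader(), .rseq(len - 30L, comp),
                              "IQVQLQQQF"),
      beta_decoy = paste0(.rseq(len - 9L, comp), "IQVQLQQQK"),
      lipo = paste0("MKK", .rseq_from(14L, .linker_alpha), "LAGC",
                    if (isTRUE(opts$surface)) {
                      paste0(.rseq_from(len - 21L, c("G", "S", "A", "Q", "N",
                                                     "E", "D", "T", "G", "S")))
                    } else {
                      .rseq(len - 21L, comp)
                    }),
      lipo_decoy = paste0("MKK", .rseq_from(14L, .linker_alpha), "LAGS",
                          .rseq(len - 21L, comp)),
      tat = paste0("MSNRRQFL", .rseq_from(6L, c("L", "I", "V", "A")),
                   .rseq_from(4L, c("Q", "N", "E", "D")), "AQA",
                   .rseq(len - 21L, comp)),
      tat_decoy = paste0("MSNRKQFL", .rseq(len - 8L, comp)),
      tat_lipo = paste0("MSNRRQFL", .rseq_from(9L, .linker_alpha), "LAGC",
                        .rseq(len - 21L, comp)),
      gg = paste0("M", .rseq_from(13L, c("Q", "N", "E", "D", "S", "T", "A",
                                         "I", "V")), "GG",
                  .rseq_from(len - 16L, c("Q", "N", "E", "D", "S", "T", "A",
                                          "K", "W", "H", "Y", "I", "V"))),
      gg_decoy = paste0("M", .rseq_from(13L, c("Q", "N", "E", "D", "S", "T",
                                               "A", "I", "V")), "GA",
                        .rseq_from(len - 16L, c("Q", "N", "E", "D", "S", "T",
                                                "A", "K", "W", "H", "Y"))),
      im = {
        k <- opts$tm %||% 2L
        body <- paste(vapply(seq_len(k), function(i)
          paste0(.tm_segment(), .rseq_from(30L, .linker_alpha)), character(1)),
          collapse = "")
        paste0("M", .rseq_from(34L, .linker_alpha), body,
               .rseq_from(max(0L, len - 35L - k * 51L), .linker_alpha))
      },
      holin = paste0("M", .rseq_from(24L, .linker_alpha), .tm_segment(),
                     .rseq_from(24L, .linker_alpha),
                     paste(sample(c(rep("K", 5L), rep("R", 3L),
                                    sample(.linker_alpha, 12L, TRUE))),
                           collapse = "")),
      stop("unknown sequence class: ", class)
    )
    if (.seq_ok(seq_try, class, config, opts)) return(seq_try)
  }
  stop("failed to build a clean '", class, "' sequence in 400 attempts")
}

.seq_ok <- function(seq, class, config, opts) {
  m <- scan_all_motifs(seq, config = config)
  kinds <- setdiff(names(m), "TM_SPAN")
  class_key <- switch(class, met_exc = "cyt", gs_rich = "cyt",
                      met_sec = "sec", beta_decoy = "cyt",
                      lipo_decoy = "cyt", tat_decoy = "cyt",
                      gg_decoy = "cyt", class)
  want <- .expected_kinds(class_key)
  # Tat leaders may or may not satisfy the Sec fallback rule; accept either
  optional <- if (class_key %in% c("tat", "tat_lipo", "lipo")) "SEC_SP"
              else character()
  if (!setequal(setdiff(kinds, optional), setdiff(want, optional))) {
    return(FALSE)
  }
  tm_want <- switch(class_key, im = opts$tm %||% 2L, holin = 1L, 0L)
  tm_got <- length(m$TM_SPAN %||% list())
  if (tm_got != tm_want) return(FALSE)
  # planted positions must be exact
  if ("SEC_SP" %in% want && (is.null(m$SEC_SP) || m$SEC_SP$cleavage_pos != 21L)) {
    return(FALSE)
  }
  if ("LIPOBOX" %in% want && (is.null(m$LIPOBOX) || m$LIPOBOX$end != 21L)) {
    return(FALSE)
  }
  if ("TAT_RR" %in% want && (is.null(m$TAT_RR) || m$TAT_RR$start != 2L)) {
    return(FALSE)
  }
  if ("GG_LEADER" %in% want && (is.null(m$GG_LEADER) || m$GG_LEADER$end != 16L)) {
    return(FALSE)
  }
  # composition constraints for lipoprotein sorting and T1SS substrates
  gs <- glyser_enrichment(seq, 0.10)
  if (isTRUE(opts$surface) && gs < 0.15) return(FALSE)
  if (isTRUE(opts$low_gs) && gs > 0.02) return(FALSE)
  if (isTRUE(opts$high_gs) && gs < 0.06) return(FALSE)
  if (class == "holin" &&
      basic_cterm_enrichment(seq, config = config) < 0.3) return(FALSE)
  TRUE
}

# --- slot layout -------------------------------------------------------------
# One row per slot: what is planted at that gene position in every genome.
.slot_plan <- function() {
  p <- function(slot, class, label, len, domains = "", phage = FALSE,
                opts = "") {
    data.frame(slot = slot, class = class, label = label, len = len,
               domains = domains, phage = phage, opts = opts,
               stringsAsFactors = FALSE)
  }
  rbind(
    p(1L, "im", "IM", 300L),
    p(2L, "beta", "OM", 280L, domains = "pfam00577"),
    p(3L, "im", "IM", 310L),
    p(4L, "im", "IM", 290L),
    p(5L, "lipo_decoy", "CYT", 260L),
    p(6L, "tat_decoy", "CYT", 270L),
    p(7L, "cyt", "CYT", 250L),
    p(8L, "cyt", "OM", 440L, domains = "TIGR01844"),
    p(9L, "im", "IM", 320L, domains = "TIGR01843"),
    p(10L, "im", "IM", 330L, domains = "TIGR01846"),
    p(11L, "cyt", "CYT", 240L),
    p(12L, "gs_rich", "EXTRA", 720L, opts = "high_gs"),
    p(13L, "cyt", "CYT", 260L),
    p(14L, "cyt", "CYT", 280L),
    p(15L, "im", "IM", 350L, domains = "pfam0341,TIGR01847"),
    p(16L, "gg", "EXTRA", 80L),
    p(17L, "gg_decoy", "CYT", 80L),
    p(18L, "beta_decoy", "CYT", 300L),
    p(19L, "cyt", "CYT", 270L),
    p(20L, "cyt", "PHAGE", 250L, phage = TRUE),
    p(21L, "holin", "PHAGE", 90L, phage = TRUE),
    p(22L, "cyt", "PHAGE", 260L, phage = TRUE),
    p(23L, "cyt", "PHAGE", 240L, phage = TRUE),
    p(24L, "cyt", "CYT", 250L),
    p(25L, "cyt", "CYT", 300L),
    p(26L, "lipo", "LIPO_OM", 270L, domains = "pfam03783", opts = "low_gs"),
    p(27L, "cyt", "CYT", 260L),
    p(28L, "cyt", "CYT", 240L),
    p(29L, "cyt", "CYT", 280L),
    p(30L, "cyt", "CYT", 260L, domains = "pfam00936"),  # shell: genomes 1-3
    p(31L, "cyt", "CYT", 250L),                         # MCP cargo split group
    p(32L, "sec", "PERI", 300L),
    p(33L, "sec", "EXTRA", 310L),
    p(34L, "beta", "OM", 320L),
    p(35L, "lipo", "LIPO_OM", 280L, opts = "low_gs"),
    p(36L, "lipo", "LIPO_SURFACE", 280L, opts = "surface"),
    p(37L, "lipo", "LIPO_IM", 290L, domains = "pfam00529", opts = "low_gs"),
    p(38L, "tat", "PERI", 300L),
    p(39L, "tat_lipo", "LIPO_OM", 290L, opts = "low_gs"),
    p(40L, "im", "IM", 420L, opts = "tm3"),
    p(41L, "im", "IM", 300L),
    p(42L, "sec", "PERI", 310L, domains = "pfam21170"),
    p(43L, "cyt", "PERI", 280L, domains = "pfam21170"),  # refinement target
    p(44L, "met_exc", "CYT", 280L),
    p(45L, "cyt", "CYT", 260L),                          # pseudogene in last genome
    p(46L, "cyt", "CYT", 270L),
    p(47L, "cyt", "CYT", 250L),
    p(48L, "met_sec", "PERI", 320L),
    p(49L, "t5dss", "OM", 330L),
    p(50L, "cyt", "CYT", 260L)
  )
}

.slot_opts <- function(opts_str) {
  o <- list()
  if (grepl("surface", opts_str)) o$surface <- TRUE
  if (grepl("low_gs", opts_str)) o$low_gs <- TRUE
  if (grepl("high_gs", opts_str)) o$high_gs <- TRUE
  if (grepl("tm3", opts_str)) o$tm <- 3L
  o
}

.genome_id <- function(g) sprintf("SYN%02d", g)
.locus_tag <- function(g, slot) sprintf("S%02d_%04d", g, slot)

#' Generate the synthetic proteomes, gene tables and ground truth
#'
#' Emits `n_genomes` proteomes, each with the same planted slot layout:
#' secretion-system loci (a fimbrial usher, a TolC-dependent T1SS with
#' membrane-fusion/permease partners and a large Gly/Ser-rich signal-less
#' substrate, a C39-peptidase bacteriocin T1SS with a small twin-glycine ORF,
#' a curli-type usher), an annotated prophage containing a holin, a
#' microcompartment shell/cargo pair present in the first three genomes only,
#' and one representative of every sorting-signal class plus matched
#' near-miss decoys (lipobox Cys to Ser, RR to RK, GG to GA, terminal Phe to
#' Lys). Sequences are resampled until the scanners report exactly the
#' planted motifs, so recovery failures downstream indicate pipeline defects,
#' not generator noise.
#'
#' @param config `synth_config`.
#' @param outdir optional directory: writes one FASTA per genome plus
#'   `genes.tsv` and `truth.tsv`.
#' @param locw_config scanner configuration used to verify plants.
#' @return list with `proteins`, `genes` and `truth` data.frames.
#' @export
make_proteomes <- function(config = synth_config(), outdir = NULL,
                           locw_config = locweaver_config()) {
  set.seed(config$seed)
  comp <- .synth_comp(config$background)
  plan <- .slot_plan()
  n_slots <- config$proteins_per_genome
  prot <- list()
  genes <- list()
  truth <- list()
  for (g in seq_len(config$n_genomes)) {
    gid <- .genome_id(g)
    for (s in seq_len(n_slots)) {
      row <- plan[(s - 1L) %% nrow(plan) + 1L, ]
      opts <- .slot_opts(row$opts)
      seq_s <- .build_seq(row$class, row$len, comp, locw_config, opts)
      tag <- .locus_tag(g, s)
      pseudo <- row$slot == 45L && g == config$n_genomes
      if (pseudo) {  # internal stops translated as X
        mid <- nchar(seq_s) %/% 2L
        substr(seq_s, mid, mid) <- "X"
        substr(seq_s, mid + 40L, mid + 40L) <- "X"
      }
      doms <- row$domains
      if (row$slot == 30L && g > 3L) doms <- ""  # shell only in genomes 1-3
      cleav <- switch(row$class, sec = , met_sec = , beta = , t5dss = 21L,
                      lipo = , tat_lipo = 20L, 0L)
      mstart <- if (row$class %in% c("sec", "met_sec", "beta", "t5dss")) 22L
                else if (row$class == "met_exc") 2L else 1L
      prot[[length(prot) + 1L]] <- data.frame(
        locus_tag = tag, genome_id = gid, pseudogene = pseudo,
        sequence = seq_s, stringsAsFactors = FALSE)
      genes[[length(genes) + 1L]] <- data.frame(
        locus_tag = tag, genome_id = gid, replicon_id = "chr",
        start = (s - 1L) * 1000L + 1L, end = (s - 1L) * 1000L + 990L,
        strand = "+", annotation = if (row$phage) "phage" else "",
        pseudogene = pseudo, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        locus_tag = tag, genome_id = gid, slot = row$slot, class = row$class,
        label = row$label, cleavage_pos = cleav, mature_start = mstart,
        tm_count = if (row$class == "im") (opts$tm %||% 2L)
                   else if (row$class == "holin") 1L else 0L,
        domains = doms, phage = row$phage, pseudogene = pseudo,
        stringsAsFactors = FALSE)
    }
  }
  proteins <- do.call(rbind, prot)
  genes <- do.call(rbind, genes)
  truth <- do.call(rbind, truth)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (g in seq_len(config$n_genomes)) {
      gid <- .genome_id(g)
      write_proteome(proteins[proteins$genome_id == gid, , drop = FALSE],
                     file.path(outdir, paste0(gid, ".faa")))
    }
    gw <- genes
    gw$locus_tag <- paste0(gw$locus_tag, ifelse(gw$pseudogene, "*", ""))
    write_table(gw[setdiff(names(gw), "pseudogene")],
                file.path(outdir, "genes.tsv"))
    write_table(truth, file.path(outdir, "truth.tsv"))
  }
  list(proteins = proteins, genes = genes, truth = truth)
}

#' Emit the planted domain-hit table
#'
#' @param truth ground-truth data.frame from [make_proteomes()].
#' @return data.frame in the `domain_hits` schema.
#' @export
make_domain_hits <- function(truth) {
  rows <- truth[nzchar(truth$domains), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rows))) {
    accs <- strsplit(rows$domains[i], ",", fixed = TRUE)[[1L]]
    for (j in seq_along(accs)) {
      out[[length(out) + 1L]] <- data.frame(
        locus_tag = rows$locus_tag[i], accession = accs[j],
        evalue = 1e-30 * j, ali_from = 10L, ali_to = 100L,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.five_cat_one <- function(label) .five_cat(label)

#' Emit synthetic external-tool prediction tables
#'
#' Models a panel of batch predictors: a SignalP-like and a Phobius-like
#' LepB-signal caller, a LipoP-like lipoprotein caller (which, like the real
#' tools, misses Tat lipoproteins), a TatP-like caller, TMHMM/Phobius-like
#' span predictors (which report the signal peptide of exported proteins as a
#' spurious N-terminal 1-21 span), a BOMP-like barrel caller and four global
#' predictors (`psortb`, `cello`, `sosuigramn` on five compartments; `subloc`
#' on soluble compartments only). The mixed-evidence type-V slot gets the
#' characteristic OM/EXTRA split. Correct rows are emitted with probability
#' 1 - dropout; with probability `noise` a global label is replaced by a
#' wrong one.
#'
#' @param truth ground-truth data.frame.
#' @param dropout,noise overrides of the config rates.
#' @param noise_tool restrict noise to this tool name (`NULL` = all).
#' @param seed RNG seed (derive from the master seed).
#' @return data.frame in the `tool_predictions` schema.
#' @export
make_tool_tables <- function(truth, dropout = 0, noise = 0,
                             noise_tool = NULL, seed = 1L) {
  set.seed(seed)
  out <- list()
  emit <- function(tag, tool, type, value) {
    if (dropout > 0 && stats::runif(1) < dropout) return()
    if (type == "global_location" && noise > 0 &&
        (is.null(noise_tool) || tool == noise_tool) &&
        stats::runif(1) < noise) {
      value <- sample(setdiff(c("CYT", "IM", "PERI", "OM", "EXTRA"), value), 1L)
    }
    out[[length(out) + 1L]] <<- data.frame(
      locus_tag = tag, tool_name = tool, prediction_type = type,
      value = as.character(value), score = 1, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    tag <- tr$locus_tag
    cls <- tr$class
    if (tr$phage) next                      # viral proteins: no usable rows
    if (tr$slot == 43L) next                # evidence-free refinement target
    fivecat <- .five_cat_one(tr$label)
    if (cls %in% c("sec", "met_sec", "beta", "t5dss")) {
      emit(tag, "signalp", "signal_lepb", tr$cleavage_pos)
      emit(tag, "phobius", "signal_lepb", tr$cleavage_pos)
      emit(tag, "tmhmm", "tm_spans", "1-21")
    }
    if (cls == "lipo") emit(tag, "lipop", "signal_lspa", tr$cleavage_pos)
    if (cls == "tat") emit(tag, "tatp", "signal_tat", 0L)
    if (cls == "im") {
      spans <- paste(vapply(seq_len(tr$tm_count), function(k) {
        a <- 36L + (k - 1L) * 51L
        sprintf("%d-%d", a, a + 20L)
      }, character(1)), collapse = ";")
      emit(tag, "tmhmm", "tm_spans", spans)
      emit(tag, "phobius", "tm_spans", spans)
    }
    if (cls %in% c("beta", "t5dss") || tr$label == "OM") {
      emit(tag, "bomp", "beta_barrel", "TRUE")
    }
    if (cls == "t5dss") {                   # the tell-tale OM/EXTRA split
      emit(tag, "psortb", "global_location", "EXTRA")
      emit(tag, "cello", "global_location", "OM")
      emit(tag, "sosuigramn", "global_location", "OM")
    } else {
      for (tool in c("psortb", "cello", "sosuigramn")) {
        emit(tag, tool, "global_location", fivecat)
      }
      if (fivecat %in% c("CYT", "PERI", "EXTRA")) {
        emit(tag, "subloc", "global_location", fivecat)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Emit the synthetic ortholog panel
#'
#' One group per slot across all genomes (core by construction), except the
#' microcompartment-cargo slot, which is split into a 3-genome shell-adjacent
#' group and a remainder group (both non-core). With
#' `inconsistency_rate > 0`, that fraction of groups swaps one member with
#' the next group, producing `mixed` verdicts.
#'
#' @param truth ground-truth data.frame.
#' @param inconsistency_rate see [synth_config()].
#' @param seed RNG seed.
#' @return data.frame in the `ortholog_groups` schema, with `genome_id`,
#'   `pseudogene` and a curated `location` column.
#' @export
make_ortholog_panel <- function(truth, inconsistency_rate = 0, seed = 1L) {
  set.seed(seed)
  og <- data.frame(locus_tag = truth$locus_tag,
                   group_id = sprintf("OG_%04d", truth$slot),
                   genome_id = truth$genome_id,
                   pseudogene = truth$pseudogene,
                   location = truth$label, stringsAsFactors = FALSE)
  mcp <- truth$slot == 31L
  first3 <- truth$genome_id %in% vapply(1:3, .genome_id, character(1))
  og$group_id[mcp & first3] <- "OG_MCPC"
  og$group_id[mcp & !first3] <- "OG_31XX"
  if (inconsistency_rate > 0) {
    gids <- sort(unique(og$group_id))
    for (k in seq_along(gids)) {
      if (stats::runif(1) < inconsistency_rate && k < length(gids)) {
        a <- which(og$group_id == gids[k])[1L]
        og$group_id[a] <- gids[k + 1L]
      }
    }
  }
  og
}

# cut a sequence after every K/R; returns data.frame of fragments with
# start/end relative to the *parent* coordinate offset supplied
.tryptic_fragments <- function(seq, offset = 0L) {
  s <- .chars(seq)
  cuts <- which(s %in% c("K", "R"))
  bounds <- unique(c(0L, cuts, length(s)))
  starts <- utils::head(bounds, -1L) + 1L
  ends <- bounds[-1L]
  data.frame(peptide = substring(seq, starts, ends),
             start = starts + offset, end = ends + offset,
             stringsAsFactors = FALSE)
}

#' Emit the synthetic tryptic-digest peptide table
#'
#' In-silico trypsin digest of the *mature* sequence of every protein (after
#' planted signal cleavage or N-terminal Met excision): the first mature
#' fragment of a processed protein is partially tryptic and maps to
#' cleavage + 1, validating the prediction; unprocessed proteins yield only
#' fully tryptic peptides. At most three detectable fragments (length >= 6)
#' are reported per protein. With `spurious_rate > 0`, decoy nonspecific
#' peptides are added.
#'
#' @param proteins proteome data.frame.
#' @param truth ground-truth data.frame.
#' @param seed RNG seed.
#' @param spurious_rate probability of one spurious internal peptide per
#'   protein.
#' @return data.frame in the `peptides` schema (with `start`/`end`).
#' @export
make_digest <- function(proteins, truth, seed = 1L, spurious_rate = 0) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(proteins))) {
    tr <- truth[truth$locus_tag == proteins$locus_tag[i], ]
    seq_i <- proteins$sequence[i]
    mstart <- tr$mature_start
    frags <- .tryptic_fragments(substring(seq_i, mstart), offset = mstart - 1L)
    frags <- frags[nchar(frags$peptide) >= 6L, , drop = FALSE]
    frags <- utils::head(frags, 3L)
    for (j in seq_len(nrow(frags))) {
      out[[length(out) + 1L]] <- data.frame(
        peptide = frags$peptide[j], locus_tag = proteins$locus_tag[i],
        start = frags$start[j], end = frags$end[j],
        n_observations = if (j == 1L) 3L else 1L, stringsAsFactors = FALSE)
    }
    if (spurious_rate > 0 && stats::runif(1) < spurious_rate) {
      a <- sample(seq(mstart + 30L, nchar(seq_i) - 12L), 1L)
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(seq_i, a, a + 9L), locus_tag = proteins$locus_tag[i],
        start = a, end = a + 9L, n_observations = 1L,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate the full synthetic input bundle
#'
#' Convenience wrapper producing everything the pipeline consumes, with
#' derived per-table seeds so each table is independently reproducible.
#'
#' @param config `synth_config`.
#' @param outdir optional directory to write all tables and FASTAs.
#' @param locw_config scanner configuration.
#' @return list with `proteins`, `genes`, `truth`, `domain_hits`, `tools`,
#'   `orthologs`, `peptides` and the `config` used.
#' @export
synth_bundle <- function(config = synth_config(), outdir = NULL,
                         locw_config = locweaver_config()) {
  pg <- make_proteomes(config, outdir = outdir, locw_config = locw_config)
  domain_hits <- make_domain_hits(pg$truth)
  tools <- make_tool_tables(pg$truth, dropout = config$evidence_dropout,
                            noise = config$tool_noise,
                            noise_tool = config$noise_tool,
                            seed = config$seed + 101L)
  orthologs <- make_ortholog_panel(pg$truth,
                                   inconsistency_rate = config$inconsistency_rate,
                                   seed = config$seed + 202L)
  peptides <- make_digest(pg$proteins, pg$truth, seed = config$seed + 303L,
                          spurious_rate = config$spurious_rate)
  if (!is.null(outdir)) {
    write_table(domain_hits, file.path(outdir, "domain_hits.tsv"))
    write_table(tools, file.path(outdir, "tool_predictions.tsv"))
    write_table(orthologs, file.path(outdir, "orthologs.tsv"))
    write_table(peptides, file.path(outdir, "peptides.tsv"))
  }
  list(proteins = pg$proteins, genes = pg$genes, truth = pg$truth,
       domain_hits = domain_hits, tools = tools, orthologs = orthologs,
       peptides = peptides, config = config)
}

#' Construct a synthetic genus-scale curation panel
#'
#' Stand-in for a curated multi-genome ortholog/localization table (the kind
#' distributed as genome-project supplementary data): `n_core` core groups
#' with one member in each of `n_genomes` genomes and curated locations drawn
#' from `core_counts`, padded with non-core groups (variable membership,
#' occasional in-genome duplicates and pseudogenes) up to `n_proteins` rows.
#' Entirely synthetic: the marginals are inputs, so parsing the table back
#' must reproduce them exactly.
#'
#' @param n_genomes genomes in the panel (default 19).
#' @param n_core number of core groups (default 1990).
#' @param core_counts named integer vector: curated core-group counts per
#'   label (default `c(EXTRA = 40, OM = 32, PERI = 176, IM = 403,
#'   CYT = 1339)`).
#' @param n_proteins total rows to emit (default 81169).
#' @param seed RNG seed.
#' @return data.frame in the `ortholog_groups` schema with `genome_id`,
#'   curated `location` and starred pseudogene locus tags.
#' @export
synth_curation_panel <- function(n_genomes = 19L, n_core = 1990L,
                                 core_counts = c(EXTRA = 40L, OM = 32L,
                                                 PERI = 176L, IM = 403L,
                                                 CYT = 1339L),
                                 n_proteins = 81169L, seed = 1L) {
  stopifnot(sum(core_counts) == n_core)
  set.seed(seed)
  genomes <- sprintf("CUR%02d", seq_len(n_genomes))
  core_labels <- rep(names(core_counts), core_counts)
  core <- data.frame(
    group_id = rep(sprintf("COG_%05d", seq_len(n_core)), each = n_genomes),
    genome_id = rep(genomes, times = n_core),
    location = rep(core_labels, each = n_genomes),
    stringsAsFactors = FALSE)
  n_extra <- n_proteins - nrow(core)
  stopifnot(n_extra >= 0)
  extra <- list()
  gi <- 0L
  remaining <- n_extra
  while (remaining > 0L) {
    gi <- gi + 1L
    size <- min(remaining, sample(seq_len(n_genomes - 1L), 1L))
    dup <- size > 1L && stats::runif(1) < 0.05
    gens <- if (dup) {
      c(sample(genomes, size - 1L), sample(genomes, 1L))
    } else {
      sample(genomes, size)
    }
    extra[[gi]] <- data.frame(
      group_id = sprintf("NOG_%05d", gi), genome_id = gens,
      location = sample(names(core_counts), 1L), stringsAsFactors = FALSE)
    remaining <- remaining - size
  }
  panel <- rbind(core, do.call(rbind, extra))
  panel$locus_tag <- sprintf("%s_%05d", panel$genome_id,
                             stats::ave(seq_len(nrow(panel)), panel$genome_id,
                                        FUN = seq_along))
  pseudo <- stats::runif(nrow(panel)) < 0.02
  panel$locus_tag <- paste0(panel$locus_tag, ifelse(pseudo, "*", ""))
  panel[, c("locus_tag", "group_id", "genome_id", "location")]
}
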