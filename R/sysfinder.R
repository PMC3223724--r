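# Genome-context detection of secretion-system loci. Secretion-system genes
# are typically co-localized, so a secretin/usher domain hit seeds a locus
# that is grown over neighboring genes carrying machinery evidence.

#' Order genes along each replicon
#'
#' Adds a `gene_index` column: 1-based rank of each gene by start coordinate
#' within its (genome, replicon). Locus clustering measures gaps in gene-index
#' units (number of intervening genes), not base pairs.
#'
#' @param genes gene-coordinate data.frame (schema `gene_coords`).
#' @return the data.frame sorted by genome, replicon and start, with
#'   `gene_index` added.
#' @export
index_genes <- function(genes) {
  o <- order(genes$genome_id, genes$replicon_id, genes$start)
  genes <- genes[o, , drop = FALSE]
  key <- paste(genes$genome_id, genes$replicon_id, sep = "\r")
  genes$gene_index <- stats::ave(seq_along(key), key, FUN = seq_along)
  rownames(genes) <- NULL
  genes
}

#' Cluster genes into genomic loci
#'
#' Groups a set of seed genes into maximal runs where consecutive members are
#' separated by at most `max_gap_genes` intervening genes on the same
#' replicon. Deterministic: input order is normalized by coordinate first.
#'
#' @param genes indexed gene table ([index_genes()]) restricted to the genes
#'   to cluster.
#' @param max_gap_genes maximum intervening genes between consecutive locus
#'   members (default `config$sysfinder$max_gap_genes`, 3).
#' @param config configuration list.
#' @return list of data.frames, one per locus, each a slice of `genes`.
#' @export
cluster_context <- function(genes, max_gap_genes = NULL,
                            config = locweaver_config()) {
  if (is.null(max_gap_genes)) max_gap_genes <- config$sysfinder$max_gap_genes
  if (nrow(genes) == 0L) return(list())
  if (is.null(genes$gene_index)) stop("genes must be indexed; see index_genes()")
  o <- order(genes$genome_id, genes$replicon_id, genes$gene_index)
  genes <- genes[o, , drop = FALSE]
  key <- paste(genes$genome_id, genes$replicon_id, sep = "\r")
  new_locus <- c(TRUE, key[-1L] != key[-nrow(genes)] |
                   diff(genes$gene_index) - 1L > max_gap_genes)
  grp <- cumsum(new_locus)
  lapply(split(seq_len(nrow(genes)), grp),
         function(i) { g <- genes[i, , drop = FALSE]; rownames(g) <- NULL; g })
}

#' Find secretion-system loci from secretin/usher hits
#'
#' Every protein hitting one of the 18 secretin/usher registry domains seeds a
#' locus; neighboring genes carrying machinery evidence (hits to the secretin
#' or core-machinery registries) are absorbed by [cluster_context()]. The
#' locus system class comes from the anchoring secretin's registry row, with
#' one exception: a TolC-family hit alone classifies as `"efflux/unassigned"`
#' because TolC also serves drug/metal efflux; it is promoted to `T1SS` only
#' when membrane-fusion or permease domains (HlyD/PrtD/HlyB/LssB families or
#' the bacteriocin-exporter accession) co-occur in the same locus. Clusters of
#' T1SS membrane-fusion/permease evidence without any secretin (their TolC is
#' encoded elsewhere) are classed `T1SS` with an empty anchor.
#'
#' @param domain_hits domain-hit data.frame (schema `domain_hits`).
#' @param genes gene-coordinate data.frame.
#' @param registry secretin registry ([load_registry]`("secretins")`).
#' @param machinery core-machinery registry used for locus growth and the
#'   TolC rule; defaults to [load_registry]`("core_machinery")`.
#' @param config configuration list.
#' @return data.frame of class `secretion_loci`: one row per locus with
#'   `locus_id`, `genome_id`, `replicon_id`, `system_class`, `anchor` (locus
#'   tag of the secretin, or `""`) and `members` (comma-joined locus tags in
#'   coordinate order).
#' @export
find_secretion_loci <- function(domain_hits, genes, registry = NULL,
                                machinery = NULL,
                                config = locweaver_config()) {
  if (is.null(registry)) registry <- load_registry("secretins")
  if (is.null(machinery)) machinery <- load_registry("core_machinery")
  genes <- index_genes(genes)
  t1ss_parts <- machinery$accession[machinery$system == "T1SS"]
  known <- c(registry$accession, machinery$accession)
  unknown <- setdiff(unique(domain_hits$accession), known)
  sec_hits <- domain_hits[domain_hits$accession %in% registry$accession, ,
                          drop = FALSE]
  part_hits <- domain_hits[domain_hits$accession %in% machinery$accession, ,
                           drop = FALSE]
  evidence_tags <- unique(c(sec_hits$locus_tag, part_hits$locus_tag))
  seed <- genes[genes$locus_tag %in% evidence_tags, , drop = FALSE]
  clusters <- cluster_context(seed, config = config)
  out <- lapply(clusters, function(cl) {
    anchors <- sec_hits[sec_hits$locus_tag %in% cl$locus_tag, , drop = FALSE]
    part_acc <- part_hits$accession[part_hits$locus_tag %in% cl$locus_tag]
    has_t1ss_parts <- any(part_acc %in% t1ss_parts)
    if (nrow(anchors)) {
      reg <- registry_lookup(registry, anchors$accession[1L])
      anchor_tag <- anchors$locus_tag[1L]
      cls <- reg$system[1L]
      if (grepl("TolC", reg$descriptor[1L], ignore.case = TRUE) ||
          reg$accession[1L] == "TIGR01844") {
        cls <- if (has_t1ss_parts) "T1SS" else "efflux/unassigned"
      }
    } else if (has_t1ss_parts) {
      anchor_tag <- ""
      cls <- "T1SS"
    } else {
      return(NULL)  # machinery-only cluster of a non-secretion system
    }
    data.frame(genome_id = cl$genome_id[1L], replicon_id = cl$replicon_id[1L],
               system_class = cls, anchor = anchor_tag,
               members = paste(cl$locus_tag, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(genome_id = character(), replicon_id = character(),
                      system_class = character(), anchor = character(),
                      members = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out <- cbind(locus_id = sprintf("SL%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  if (length(unknown)) {
    warning("ignoring hits to accession(s) absent from registries: ",
            paste(unknown, collapse = ", "))
  }
  class(out) <- c("secretion_loci", class(out))
  out
}

.locus_members <- function(loci) strsplit(loci$members, ",", fixed = TRUE)

# genes within `window` gene indices of any member of a locus
.near_locus <- function(genes, locus_tags, window) {
  idx <- genes$gene_index[genes$locus_tag %in% locus_tags]
  rep_id <- genes$replicon_id[genes$locus_tag %in% locus_tags][1L]
  gen_id <- genes$genome_id[genes$locus_tag %in% locus_tags][1L]
  same <- genes$replicon_id == rep_id & genes$genome_id == gen_id
  near <- same & vapply(genes$gene_index,
                        function(i) any(abs(i - idx) <= window), logical(1))
  genes$locus_tag[near]
}

#' Find candidate T1SS substrates
#'
#' T1SS substrates are typically large proteins that lack any N-terminal
#' signal peptide and have the Gly/Ser-enriched composition typical of
#' extracellular proteins, encoded in or adjacent to the T1SS locus itself.
#'
#' @param loci `secretion_loci` data.frame.
#' @param proteins proteome data.frame (with `sequence`).
#' @param genes gene-coordinate data.frame.
#' @param glyser_bg background Gly+Ser fraction (default computed from
#'   `proteins`).
#' @param config configuration list (`adjacency_genes` 5, `t1ss_min_len` 700).
#' @return data.frame with `locus_tag`, `candidate_kind = "T1SS_substrate"`,
#'   `locus_id` and `evidence`.
#' @export
find_t1ss_substrates <- function(loci, proteins, genes, glyser_bg = NULL,
                                 config = locweaver_config()) {
  sf <- config$sysfinder
  if (is.null(glyser_bg)) glyser_bg <- proteome_background(proteins$sequence)
  genes <- index_genes(genes)
  t1 <- loci[loci$system_class == "T1SS", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(t1))) {
    memb <- .locus_members(t1[i, , drop = FALSE])[[1L]]
    near <- setdiff(.near_locus(genes, memb, sf$adjacency_genes), memb)
    cand <- proteins[proteins$locus_tag %in% c(memb, near), , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      seq_j <- cand$sequence[j]
      if (nchar(seq_j) < sf$t1ss_min_len) next
      if (!is.null(scan_sec_signal(seq_j, config = config))) next
      if (!is.null(scan_lipobox(seq_j, config = config))) next
      if (!is.null(scan_tat_motif(seq_j, config = config))) next
      gs <- glyser_enrichment(seq_j, glyser_bg)
      if (gs <= 0) next
      out[[length(out) + 1L]] <- data.frame(
        locus_tag = cand$locus_tag[j], candidate_kind = "T1SS_substrate",
        locus_id = t1$locus_id[i],
        evidence = sprintf("len=%d;no_signal;glyser=%+.3f;near=%s",
                           nchar(seq_j), gs, t1$locus_id[i]),
        stringsAsFactors = FALSE)
    }
  }
  .bind_candidates(out)
}

#' Find candidate class I/II bacteriocins
#'
#' Small ORFs (<= 150 aa) carrying a twin-glycine leader and encoded within a
#' T1SS locus whose permease carries the C39 peptidase (bacteriocin-exporter
#' accessions).
#'
#' @param loci `secretion_loci` data.frame.
#' @param proteins proteome data.frame.
#' @param genes gene-coordinate data.frame.
#' @param domain_hits domain-hit data.frame (to identify C39-type loci).
#' @param config configuration list.
#' @return candidate data.frame (`candidate_kind = "bacteriocin"`).
#' @export
find_bacteriocin_candidates <- function(loci, proteins, genes, domain_hits,
                                        config = locweaver_config()) {
  sf <- config$sysfinder
  c39_acc <- c("pfam0341", "TIGR01847")
  genes <- index_genes(genes)
  t1 <- loci[loci$system_class == "T1SS", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(t1))) {
    memb <- .locus_members(t1[i, , drop = FALSE])[[1L]]
    has_c39 <- any(domain_hits$locus_tag %in% memb &
                     domain_hits$accession %in% c39_acc)
    if (!has_c39) next
    near <- .near_locus(genes, memb, sf$adjacency_genes)
    cand <- proteins[proteins$locus_tag %in% near, , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      gg <- scan_gg_leader(cand$sequence[j], config = config)
      if (is.null(gg)) next
      out[[length(out) + 1L]] <- data.frame(
        locus_tag = cand$locus_tag[j], candidate_kind = "bacteriocin",
        locus_id = t1$locus_id[i],
        evidence = sprintf("gg_leader@%d;len=%d;C39_locus=%s", gg$end,
                           nchar(cand$sequence[j]), t1$locus_id[i]),
        stringsAsFactors = FALSE)
    }
  }
  .bind_candidates(out)
}

#' Find candidate holins within phage loci
#'
#' A holin is the phage-encoded endolysin translocase: a small inner-membrane
#' protein (single or few transmembrane spans) with a C-terminus enriched in
#' basic residues. Phage loci are taken from input annotation labels, not
#' computed.
#'
#' @param proteins proteome data.frame.
#' @param phage_loci list of gene-table slices (e.g. [phage_loci()] output)
#'   or a character vector of phage locus tags.
#' @param config configuration list (`holin_max_len` 150,
#'   `holin_basic_threshold` 0.25).
#' @return candidate data.frame (`candidate_kind = "holin"`).
#' @export
find_holin_candidates <- function(proteins, phage_loci,
                                  config = locweaver_config()) {
  sf <- config$sysfinder
  tags <- if (is.character(phage_loci)) phage_loci
          else unlist(lapply(phage_loci, function(x) x$locus_tag))
  cand <- proteins[proteins$locus_tag %in% tags, , drop = FALSE]
  out <- list()
  for (j in seq_len(nrow(cand))) {
    seq_j <- cand$sequence[j]
    if (nchar(seq_j) > sf$holin_max_len) next
    tm <- scan_tm_hydropathy(seq_j, config = config)
    if (length(tm) < 1L) next
    bc <- basic_cterm_enrichment(seq_j, config = config)
    if (bc < sf$holin_basic_threshold) next
    out[[length(out) + 1L]] <- data.frame(
      locus_tag = cand$locus_tag[j], candidate_kind = "holin", locus_id = "",
      evidence = sprintf("len=%d;tm_spans=%d;basic_cterm=%.2f",
                         nchar(seq_j), length(tm), bc),
      stringsAsFactors = FALSE)
  }
  .bind_candidates(out)
}

#' Extract phage loci from annotated genes
#'
#' @param genes gene-coordinate data.frame with an `annotation` column;
#'   genes annotated `"phage"` (case-insensitive substring) are clustered.
#' @param config configuration list.
#' @return list of gene-table slices, one per phage locus.
#' @export
phage_loci <- function(genes, config = locweaver_config()) {
  if (is.null(genes$annotation)) return(list())
  ph <- index_genes(genes)
  ph <- ph[grepl("phage", ph$annotation, ignore.case = TRUE), , drop = FALSE]
  cluster_context(ph, config = config)
}

#' Find candidate microcompartment-encapsulated proteins
#'
#' Bacterial microcompartment shells are built from pfam00936-domain proteins.
#' Cargo candidates are ortholog groups whose members occur *only* in genomes
#' that encode shell proteins and that are frequently encoded in the shell
#' genes' neighborhood.
#'
#' @param ortholog_groups ortholog table (schema `ortholog_groups`, with
#'   `genome_id`).
#' @param domain_hits domain-hit data.frame.
#' @param genes gene-coordinate data.frame.
#' @param all_genomes character vector of every genome in the panel (defaults
#'   to the genomes present in `genes`).
#' @param config configuration list (`mcp_frac` 0.5, `mcp_ctx_genes` 10).
#' @return candidate data.frame (`candidate_kind = "microcompartment_cargo"`),
#'   one row per member of each flagged group.
#' @export
find_microcompartment_candidates <- function(ortholog_groups, domain_hits,
                                             genes, all_genomes = NULL,
                                             config = locweaver_config()) {
  sf <- config$sysfinder
  genes <- index_genes(genes)
  if (is.null(all_genomes)) all_genomes <- unique(genes$genome_id)
  shell_tags <- domain_hits$locus_tag[domain_hits$accession == "pfam00936"]
  shell_genes <- genes[genes$locus_tag %in% shell_tags, , drop = FALSE]
  mcp_genomes <- unique(shell_genes$genome_id)
  if (!length(mcp_genomes)) return(.bind_candidates(list()))
  og <- ortholog_groups
  if (is.null(og$genome_id)) {
    og$genome_id <- genes$genome_id[match(og$locus_tag, genes$locus_tag)]
  }
  out <- list()
  for (gid in unique(og$group_id)) {
    members <- og[og$group_id == gid, , drop = FALSE]
    if (any(!members$genome_id %in% mcp_genomes)) next  # not MCP-exclusive
    mg <- genes[match(members$locus_tag, genes$locus_tag), , drop = FALSE]
    near <- vapply(seq_len(nrow(mg)), function(k) {
      sh <- shell_genes[shell_genes$genome_id == mg$genome_id[k] &
                          shell_genes$replicon_id == mg$replicon_id[k], ,
                        drop = FALSE]
      nrow(sh) > 0 &&
        any(abs(sh$gene_index - mg$gene_index[k]) <= sf$mcp_ctx_genes)
    }, logical(1))
    if (mean(near) < sf$mcp_frac) next
    for (k in seq_len(nrow(members))) {
      out[[length(out) + 1L]] <- data.frame(
        locus_tag = members$locus_tag[k],
        candidate_kind = "microcompartment_cargo", locus_id = "",
        evidence = sprintf("group=%s;mcp_only;near_frac=%.2f", gid, mean(near)),
        stringsAsFactors = FALSE)
    }
  }
  .bind_candidates(out)
}

#' Flag proteins with the T5dSS mixed-evidence signature
#'
#' Novel single-protein (type V) secretion systems can hide behind
#' contradictory predictions: a Sec signal peptide, beta-barrel support, and
#' global predictors split between outer-membrane and extracellular calls.
#' Such proteins are flagged for manual review, not auto-called.
#'
#' @param records list of evidence records ([build_evidence_records()]).
#' @param config configuration list.
#' @return candidate data.frame (`candidate_kind = "T5dSS_like"`).
#' @export
flag_t5dss_like <- function(records, config = locweaver_config()) {
  out <- list()
  for (rec in records) {
    has_sec <- !is.null(rec$motifs$SEC_SP) ||
      any(rec$tools$prediction_type == "signal_lepb")
    has_barrel <- !is.null(rec$motifs$BETA_CSIG) ||
      any(rec$tools$prediction_type == "beta_barrel" &
            toupper(rec$tools$value) %in% c("TRUE", "YES", "1", "OM"))
    glob <- rec$tools$value[rec$tools$prediction_type == "global_location"]
    split_om_extra <- any(glob == "OM") && any(glob == "EXTRA")
    if (has_sec && has_barrel && split_om_extra) {
      out[[length(out) + 1L]] <- data.frame(
        locus_tag = rec$locus_tag, candidate_kind = "T5dSS_like",
        locus_id = "",
        evidence = sprintf("sec_signal;beta_barrel;votes=%s",
                           paste(sort(glob), collapse = "/")),
        stringsAsFactors = FALSE)
    }
  }
  .bind_candidates(out)
}

#' Flag possible long-leader type V translocases
#'
#' Some autotransporter and two-partner-secretion leaders carry an extra
#' charged/hydrophobic extension and escape standard signal-peptide windows.
#' Proteins whose first 80 residues contain a Sec-like hydrophobic run but
#' that fail the standard Sec scanner are flagged for manual inspection.
#'
#' @param proteins proteome data.frame.
#' @param config configuration list.
#' @return candidate data.frame (`candidate_kind = "long_leader"`).
#' @export
flag_long_leader <- function(proteins, config = locweaver_config()) {
  long_cfg <- config
  long_cfg$motifs$long_leader <- TRUE
  long_cfg$motifs$sec_h_last_start <- long_cfg$motifs$long_leader_window
  out <- list()
  for (j in seq_len(nrow(proteins))) {
    seq_j <- proteins$sequence[j]
    if (!is.null(scan_sec_signal(seq_j, config = config))) next
    long_hit <- scan_sec_signal(seq_j, config = long_cfg)
    if (is.null(long_hit)) next
    out[[length(out) + 1L]] <- data.frame(
      locus_tag = proteins$locus_tag[j], candidate_kind = "long_leader",
      locus_id = "",
      evidence = sprintf("sec_like_h_region;cleave=%d", long_hit$cleavage_pos),
      stringsAsFactors = FALSE)
  }
  .bind_candidates(out)
}

.bind_candidates <- function(out) {
  if (!length(out)) {
    return(data.frame(locus_tag = character(), candidate_kind = character(),
                      locus_id = character(), evidence = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
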