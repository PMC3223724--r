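# Per-protein evidence assembly: scanner results, external predictor rows,
# domain hits and genome-context flags, fused into one record per protein.

.empty_tools <- function() {
  data.frame(locus_tag = character(), tool_name = character(),
             prediction_type = character(), value = character(),
             score = numeric(), stringsAsFactors = FALSE)
}

#' Build one evidence record per protein
#'
#' Runs every sorting-signal scanner, attaches external-tool prediction rows,
#' domain hits and genome-context flags (bacteriophage locus membership,
#' secretion-system component via the packaged registries, microcompartment
#' candidacy), computes Gly/Ser enrichment against the proteome background and
#' optionally scores the C-terminus against a beta-signal PSSM.
#'
#' @param proteins proteome data.frame ([read_proteome()]).
#' @param genes gene-coordinate data.frame, or `NULL` (no context flags).
#' @param domain_hits domain-hit data.frame, or `NULL`.
#' @param tool_predictions tool-prediction data.frame, or `NULL` (scanners
#'   then provide all signal evidence).
#' @param loci `secretion_loci` from [find_secretion_loci()], or `NULL`.
#' @param pssm optional `cterm_pssm` for the beta-signal score.
#' @param config configuration list.
#' @return named list (by locus tag) of evidence records; each record is a
#'   list with `locus_tag`, `sequence`, `motifs` (at most one match per kind;
#'   `TM_SPAN` holds a list), `tools` (data.frame), `domains` (accession
#'   vector), `context` (`phage`, `secretion_component`, `microcompartment`),
#'   `glyser` and `beta_score`/`beta_threshold`.
#' @export
build_evidence_records <- function(proteins, genes = NULL, domain_hits = NULL,
                                   tool_predictions = NULL, loci = NULL,
                                   pssm = NULL, config = locweaver_config()) {
  secreg <- load_registry("secretins")
  machreg <- load_registry("core_machinery")
  reg <- rbind(
    data.frame(accession = secreg$accession, system = secreg$system,
               component_location = secreg$component_location,
               stringsAsFactors = FALSE),
    data.frame(accession = machreg$accession, system = machreg$system,
               component_location = machreg$component_location,
               stringsAsFactors = FALSE))
  bg <- proteome_background(proteins$sequence)
  phage_tags <- character()
  if (!is.null(genes)) {
    phage_tags <- unlist(lapply(phage_loci(genes, config = config),
                                function(x) x$locus_tag))
  }
  records <- vector("list", nrow(proteins))
  names(records) <- proteins$locus_tag
  for (i in seq_len(nrow(proteins))) {
    tag <- proteins$locus_tag[i]
    seq_i <- proteins$sequence[i]
    tools_i <- .empty_tools()
    if (!is.null(tool_predictions)) {
      tools_i <- tool_predictions[tool_predictions$locus_tag == tag, ,
                                  drop = FALSE]
      tools_i <- tools_i[order(tools_i$tool_name, tools_i$prediction_type), ,
                         drop = FALSE]
    }
    doms_i <- character()
    if (!is.null(domain_hits)) {
      dh <- domain_hits[domain_hits$locus_tag == tag, , drop = FALSE]
      doms_i <- dh$accession[order(dh$evalue, dh$accession)]
    }
    sec_comp <- NA_character_
    hit_reg <- reg[match(tolower(doms_i), tolower(reg$accession)), ,
                   drop = FALSE]
    hit_reg <- hit_reg[!is.na(hit_reg$accession), , drop = FALSE]
    if (nrow(hit_reg)) sec_comp <- hit_reg$component_location[1L]
    records[[i]] <- list(
      locus_tag = tag,
      sequence = seq_i,
      motifs = scan_all_motifs(seq_i, config = config),
      tools = tools_i,
      domains = doms_i,
      context = list(
        phage = tag %in% phage_tags,
        secretion_component = sec_comp,
        microcompartment = FALSE),
      glyser = glyser_enrichment(seq_i, bg),
      beta_score = if (is.null(pssm)) NA_real_ else score_cterm(seq_i, pssm),
      beta_threshold = if (is.null(pssm)) NA_real_ else pssm$threshold)
  }
  records
}
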