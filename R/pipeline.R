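#' Run the full localization-prediction pipeline
#'
#' End-to-end driver: finds secretion-system loci, assembles per-protein
#' evidence (scanners, external tool tables, domain hits, context flags),
#' makes a first pass of decision-tree calls, infers location-informative
#' domains from the confident calls, and re-runs the tree with the inferred
#' domain map active (the second pass is a fixed point of further passes).
#' Substrate-candidate searches (T1SS substrates, bacteriocins, holins,
#' microcompartment cargo, mixed-evidence type-V flags) run on the side and
#' never override a call.
#'
#' @param proteins proteome data.frame ([read_proteome()]).
#' @param genes gene-coordinate data.frame, or `NULL`.
#' @param domain_hits domain-hit data.frame, or `NULL`.
#' @param tool_predictions tool-prediction data.frame, or `NULL`.
#' @param orthologs ortholog table, or `NULL` (skips group verdicts).
#' @param config configuration list.
#' @param two_pass run the domain-map refinement pass (default `TRUE`).
#' @return list of class `locweaver_result`: `calls` (final), `first_pass`,
#'   `domain_map`, `loci`, `candidates`, `verdicts` (or `NULL`), `records`.
#' @export
predict_localization <- function(proteins, genes = NULL, domain_hits = NULL,
                                 tool_predictions = NULL, orthologs = NULL,
                                 config = locweaver_config(),
                                 two_pass = TRUE) {
  loci <- NULL
  if (!is.null(domain_hits) && !is.null(genes)) {
    loci <- suppressWarnings(
      find_secretion_loci(domain_hits, genes, config = config))
  }
  records <- build_evidence_records(proteins, genes = genes,
                                    domain_hits = domain_hits,
                                    tool_predictions = tool_predictions,
                                    loci = loci, config = config)
  first <- decide_all(records, config = config)
  map <- NULL
  calls <- first
  if (two_pass && !is.null(domain_hits)) {
    map <- infer_domain_locations(first, domain_hits, config = config)
    if (nrow(map)) calls <- rerun_with_domain_map(records, map, config = config)
  }
  cands <- list()
  if (!is.null(loci) && !is.null(genes)) {
    cands$t1ss <- find_t1ss_substrates(loci, proteins, genes, config = config)
    cands$bacteriocin <- find_bacteriocin_candidates(loci, proteins, genes,
                                                     domain_hits,
                                                     config = config)
    cands$holin <- find_holin_candidates(proteins,
                                         phage_loci(genes, config = config),
                                         config = config)
    if (!is.null(orthologs)) {
      cands$microcompartment <- find_microcompartment_candidates(
        orthologs, domain_hits, genes, config = config)
    }
  }
  cands$t5dss <- flag_t5dss_like(records, config = config)
  candidates <- do.call(rbind, cands)
  if (!is.null(candidates)) rownames(candidates) <- NULL
  verdicts <- NULL
  if (!is.null(orthologs)) {
    verdicts <- classify_groups(orthologs, calls, config = config)
  }
  structure(list(calls = calls, first_pass = first, domain_map = map,
                 loci = loci, candidates = candidates, verdicts = verdicts,
                 records = records),
            class = "locweaver_result")
}

#' @export
print.locweaver_result <- function(x, ...) {
  cat("locweaver result:", nrow(x$calls), "proteins\n")
  print(table(x$calls$label))
  if (!is.null(x$loci)) cat(nrow(x$loci), "secretion loci;",
                            if (is.null(x$candidates)) 0
                            else nrow(x$candidates), "substrate candidates\n")
  if (!is.null(x$verdicts)) print(table(x$verdicts$status))
  invisible(x)
}
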