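# The decision tree: one localization call per protein, with an ordered,
# replayable evidence trail. Rules fire in a fixed precedence; each later
# rule is evaluated only if no earlier rule fixed the label.

#' Weighted majority vote over location labels
#'
#' Weighted plurality with an explicit margin. Tools restricted to soluble
#' compartments (Subloc-type) simply never contribute membrane labels. Ties
#' abstain by default.
#'
#' @param labels character vector of controlled-vocabulary labels.
#' @param weights numeric vector parallel to `labels`, or a named vector
#'   keyed by voter name (then `names(labels)` are the voters); default all 1.
#' @param tie_policy `"abstain"` (tie returns `UNKNOWN`, margin 0) or
#'   `"alpha"` (alphabetically first top label wins).
#' @return list with `label` and `margin` = (top - runner-up) / total weight.
#' @export
majority_vote <- function(labels, weights = NULL, tie_policy = "abstain") {
  if (!length(labels)) return(list(label = "UNKNOWN", margin = 0))
  bad <- setdiff(labels, LOC_VOCAB)
  if (length(bad)) stop("labels outside controlled vocabulary: ",
                        paste(unique(bad), collapse = ", "))
  if (is.null(weights)) {
    w <- rep(1, length(labels))
  } else if (!is.null(names(weights)) && !is.null(names(labels))) {
    w <- ifelse(names(labels) %in% names(weights),
                weights[names(labels)], 1)
  } else {
    stopifnot(length(weights) == length(labels))
    w <- weights
  }
  tot <- tapply(w, factor(labels, levels = sort(unique(labels))), sum)
  tot <- sort(tot, decreasing = TRUE)
  top <- tot[1L]
  runner <- if (length(tot) > 1L) tot[2L] else 0
  tied <- names(tot)[tot == top]
  if (length(tied) > 1L) {
    if (tie_policy == "alpha") {
      return(list(label = sort(tied)[1L], margin = 0))
    }
    return(list(label = "UNKNOWN", margin = 0))
  }
  list(label = names(tot)[1L], margin = unname((top - runner) / sum(w)))
}

# --- internal rule steps -----------------------------------------------------

.tool_rows <- function(rec, type) {
  rec$tools[rec$tools$prediction_type == type, , drop = FALSE]
}

.global_votes <- function(rec) {
  g <- .tool_rows(rec, "global_location")
  stats::setNames(as.character(g$value), g$tool_name)
}

.parse_spans <- function(value) {
  # "12-30;45-70" -> list of c(from,to); bare integer k -> k spans of NA pos
  value <- as.character(value)
  if (grepl("-", value, fixed = TRUE)) {
    parts <- strsplit(value, ";", fixed = TRUE)[[1L]]
    lapply(parts, function(p) as.integer(strsplit(p, "-", fixed = TRUE)[[1L]]))
  } else {
    k <- suppressWarnings(as.integer(value))
    if (is.na(k) || k <= 0L) list() else rep(list(c(NA_integer_, NA_integer_)), k)
  }
}

.get_spans <- function(rec, config) {
  tm <- .tool_rows(rec, "tm_spans")
  if (nrow(tm)) {
    pref <- intersect(config$decide$sp_aware_tools, tm$tool_name)
    pick <- if (length(pref)) pref[1L] else sort(tm$tool_name)[1L]
    return(.parse_spans(tm$value[tm$tool_name == pick][1L]))
  }
  if (!is.null(rec$motifs$TM_SPAN)) {
    return(lapply(rec$motifs$TM_SPAN, function(m) c(m$start, m$end)))
  }
  list()
}

.has_signal_prediction <- function(rec) {
  any(rec$tools$prediction_type %in%
        c("signal_lepb", "signal_lspa", "signal_tat")) ||
    any(c("SEC_SP", "LIPOBOX", "TAT_RR", "TAT_LIPO") %in% names(rec$motifs))
}

.beta_evidence <- function(rec, config, domain_map) {
  bb <- .tool_rows(rec, "beta_barrel")
  if (nrow(bb) && any(toupper(bb$value) %in% c("TRUE", "YES", "1", "OM"))) {
    return(TRUE)
  }
  if (!is.null(rec$motifs$BETA_CSIG)) return(TRUE)
  if (!is.na(rec$beta_score) && !is.na(rec$beta_threshold) &&
      rec$beta_score >= rec$beta_threshold) {
    return(TRUE)
  }
  if (!is.null(domain_map) && nrow(domain_map)) {
    hit <- domain_map[domain_map$accession %in% rec$domains &
                        domain_map$location == "OM", , drop = FALSE]
    if (nrow(hit)) return(TRUE)
  }
  FALSE
}

# Evaluate the tree. Returns trail (data.frame rule/outcome), label,
# defaulted flag. Pure in (record, config, domain_map).
.decide_steps <- function(rec, config, domain_map = NULL) {
  d <- config$decide
  trail <- list()
  note <- function(rule, outcome) trail[[length(trail) + 1L]] <<-
    data.frame(rule = rule, outcome = outcome, stringsAsFactors = FALSE)
  finish <- function(label, defaulted = FALSE) {
    list(trail = do.call(rbind, trail), label = label, defaulted = defaulted)
  }

  # 1. phage structural proteins are not cell components
  if (isTRUE(rec$context$phage)) {
    note("phage", "PHAGE")
    return(finish("PHAGE"))
  }
  note("phage", "no")

  # 2. curated secretion-system component: registry localization wins
  sc <- rec$context$secretion_component
  if (!is.na(sc) && sc != "mixed") {
    note("secretion_component", sc)
    return(finish(sc))
  }
  note("secretion_component", if (is.na(sc)) "no" else "mixed")

  # 3. lipoprotein signal, then the sorting sub-rule
  lipo_tool <- .tool_rows(rec, "signal_lspa")
  lipo_motif <- rec$motifs$TAT_LIPO %||% rec$motifs$LIPOBOX
  if (nrow(lipo_tool) || !is.null(lipo_motif)) {
    cleave <- if (!is.null(lipo_motif)) {
      lipo_motif$cleavage_pos
    } else {
      suppressWarnings(as.integer(lipo_tool$value[1L]))
    }
    mature <- if (!is.na(cleave) && !is.null(rec$sequence) &&
                  cleave < nchar(rec$sequence)) {
      substr(rec$sequence, cleave + 1L, nchar(rec$sequence))
    } else NA_character_
    if (identical(d$plus2_mode, "enterobacterial")) {
      lab <- if (!is.na(mature) && startsWith(mature, "C") &&
                 check_plus2(mature) == "IM_retained") "LIPO_IM" else "LIPO_OM"
    } else {  # genus mode: D+2 not trusted in this genus
      lab <- if (any(rec$domains %in% d$im_anchor_domains)) {
        "LIPO_IM"
      } else if (!is.na(rec$glyser) && rec$glyser >= d$surface_threshold) {
        "LIPO_SURFACE"
      } else {
        "LIPO_OM"
      }
    }
    note("lipoprotein", lab)
    return(finish(lab))
  }
  note("lipoprotein", "no")

  exported <- FALSE
  exported_via <- ""

  # 4. twin-arginine (non-lipoprotein) substrates are exported
  if (!is.null(rec$motifs$TAT_RR) ||
      nrow(.tool_rows(rec, "signal_tat")) > 0L) {
    note("tat", "exported")
    exported <- TRUE
    exported_via <- "tat"
  } else {
    note("tat", "no")
  }

  # 5. transmembrane spans (signal peptides are often miscounted as spans)
  if (!exported) {
    spans <- .get_spans(rec, config)
    if (length(spans)) {
      sig <- .has_signal_prediction(rec)
      nterm <- vapply(spans, function(s)
        is.na(s[1L]) || s[1L] <= d$nterm_tm_window, logical(1))
      kept <- spans
      if (sig && any(nterm)) kept <- spans[-which(nterm)[1L]]
      if (length(kept) >= 2L) {
        note("tm", "IM")
        return(finish("IM"))
      }
      if (length(kept) == 1L) {
        k1 <- kept[[1L]]
        k1_nterm <- is.na(k1[1L]) || k1[1L] <= d$nterm_tm_window
        sp_aware <- any(rec$tools$prediction_type == "signal_lepb" &
                          rec$tools$tool_name %in% d$sp_aware_tools)
        if (k1_nterm && sp_aware) {
          note("tm", "signal_like")
        } else {
          note("tm", "IM")
          return(finish("IM"))
        }
      } else {
        note("tm", "discounted")
      }
    } else {
      note("tm", "no")
    }
  } else {
    note("tm", "skipped")
  }

  # 6. Sec signal peptide
  if (!exported) {
    if (!is.null(rec$motifs$SEC_SP) ||
        nrow(.tool_rows(rec, "signal_lepb")) > 0L) {
      note("sec", "exported")
      exported <- TRUE
      exported_via <- "sec"
    } else {
      note("sec", "no")
    }
  } else {
    note("sec", "skipped")
  }

  # 7. exported branch: beta-barrel evidence beats the vote
  if (exported) {
    if (.beta_evidence(rec, config, domain_map)) {
      note("exported", "OM_beta")
      return(finish("OM"))
    }
    votes <- .global_votes(rec)
    votes <- votes[votes %in% c("PERI", "EXTRA", "OM")]
    mv <- majority_vote(votes, weights = d$weights, tie_policy = d$tie_policy)
    if (mv$label == "UNKNOWN") {
      note("exported", paste0("abstain_", d$exported_abstain))
      return(finish(d$exported_abstain, defaulted = TRUE))
    }
    note("exported", mv$label)
    return(finish(mv$label))
  }

  # 8. no signal, no membrane anchor
  if (!is.null(domain_map) && nrow(domain_map)) {
    hits <- sort(intersect(rec$domains, domain_map$accession))
    if (length(hits)) {
      lab <- domain_map$location[match(hits[1L], domain_map$accession)]
      note("no_signal", paste0("domain_", lab))
      return(finish(lab))
    }
  }
  votes <- .global_votes(rec)
  votes <- votes[votes %in% setdiff(LOC_VOCAB, c("UNKNOWN", "PHAGE"))]
  mv <- majority_vote(votes, weights = d$weights, tie_policy = d$tie_policy)
  if (mv$label == "UNKNOWN") {
    note("no_signal", paste0("abstain_", d$no_signal_abstain))
    return(finish(d$no_signal_abstain, defaulted = TRUE))
  }
  note("no_signal", mv$label)
  finish(mv$label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Count independent evidence sources concordant with the final label.
.support_count <- function(rec, label, config, domain_map = NULL) {
  n <- 0L
  exported_labels <- c("PERI", "OM", "EXTRA")
  lipo_labels <- c("LIPO_IM", "LIPO_OM", "LIPO_SURFACE")
  supports <- function(vote, lab) {
    vote == lab ||
      (vote == "OM" && lab %in% c("LIPO_OM", "LIPO_SURFACE")) ||
      (vote == "IM" && lab == "LIPO_IM")
  }
  for (v in seq_len(nrow(rec$tools))) {
    ty <- rec$tools$prediction_type[v]
    val <- rec$tools$value[v]
    ok <- switch(ty,
      global_location = supports(val, label),
      signal_lepb = label %in% exported_labels,
      signal_lspa = label %in% lipo_labels,
      signal_tat = label %in% c(exported_labels, lipo_labels),
      beta_barrel = toupper(val) %in% c("TRUE", "YES", "1", "OM") &&
        label == "OM",
      tm_spans = length(.parse_spans(val)) >= 2L && label == "IM",
      FALSE)
    if (isTRUE(ok)) n <- n + 1L
  }
  for (kind in names(rec$motifs)) {
    ok <- switch(kind,
      SEC_SP = label %in% exported_labels,
      TAT_RR = label %in% exported_labels,
      LIPOBOX = label %in% lipo_labels,
      TAT_LIPO = label %in% lipo_labels,
      BETA_CSIG = label == "OM",
      GG_LEADER = label == "EXTRA",
      TM_SPAN = length(rec$motifs$TM_SPAN) >= 2L && label == "IM",
      FALSE)
    if (isTRUE(ok)) n <- n + 1L
  }
  sc <- rec$context$secretion_component
  if (!is.na(sc) && sc == label) n <- n + 1L
  if (isTRUE(rec$context$phage) && label == "PHAGE") n <- n + 1L
  if (!is.null(domain_map) && nrow(domain_map)) {
    hit <- domain_map[domain_map$accession %in% rec$domains, , drop = FALSE]
    if (any(hit$location == label)) n <- n + 1L
  }
  n
}

#' Decide the localization of one protein
#'
#' Applies the decision tree to an evidence record. Precedence (each step
#' fires only if no earlier step fixed the label): (1) phage structural
#' protein; (2) secretion-system component (registry localization); (3)
#' lipoprotein signal, sorted by the configured +2-rule mode; (4)
#' twin-arginine signal (exported); (5) transmembrane spans, discounting a
#' single N-terminal span that coincides with a predicted signal peptide; (6)
#' Sec signal (exported); (7) exported branch: beta-barrel evidence gives OM,
#' otherwise a majority vote restricted to PERI/EXTRA/OM, abstaining to PERI;
#' (8) otherwise a location-informative domain if one is mapped, else a
#' majority vote over all global predictors, abstaining to CYT.
#'
#' Confidence counts concordant independent evidence sources: `high` >= 3,
#' `medium` = 2, `low` otherwise. Calls produced by an abstain default carry
#' `defaulted = TRUE` and are ignored when inferring location-informative
#' domains.
#'
#' @param record evidence record ([build_evidence_records()]).
#' @param config configuration list.
#' @param domain_map optional location-informative domain map
#'   ([infer_domain_locations()]).
#' @return list of class `localization_call`: `locus_tag`, `label`,
#'   `confidence`, `defaulted`, `trail` (data.frame of rule/outcome pairs; the
#'   last rule determines the label).
#' @export
decide <- function(record, config = locweaver_config(), domain_map = NULL) {
  res <- .decide_steps(record, config, domain_map)
  support <- .support_count(record, res$label, config, domain_map)
  confidence <- if (res$defaulted) "low"
                else if (support >= 3L) "high"
                else if (support == 2L) "medium"
                else "low"
  structure(list(locus_tag = record$locus_tag, label = res$label,
                 confidence = confidence, defaulted = res$defaulted,
                 trail = res$trail),
            class = "localization_call")
}

#' @export
print.localization_call <- function(x, ...) {
  cat(sprintf("<%s -> %s (%s)%s trail: %s>\n", x$locus_tag, x$label,
              x$confidence, if (x$defaulted) " [default]" else "",
              paste(x$trail$rule, x$trail$outcome, sep = "=",
                    collapse = "; ")))
  invisible(x)
}

# Map a trail's terminal outcome back to the label it implies; used to audit
# trail soundness independently of decide()'s return value.
.outcome_label <- function(rule, outcome, config) {
  d <- config$decide
  if (outcome %in% LOC_VOCAB) return(outcome)
  if (startsWith(outcome, "abstain_")) return(sub("abstain_", "", outcome))
  if (startsWith(outcome, "domain_")) return(sub("domain_", "", outcome))
  if (outcome == "OM_beta") return("OM")
  NA_character_
}

#' Audit a localization call against its evidence record
#'
#' Replays the decision tree on the record and checks that (a) every
#' (rule, outcome) pair in the stored trail is reproduced in order and (b)
#' the trail's terminal outcome implies the stored label.
#'
#' @param call `localization_call`.
#' @param record the evidence record it was derived from.
#' @param config configuration list.
#' @param domain_map optional domain map active when the call was made.
#' @return `TRUE`, or a character message describing the first discrepancy.
#' @export
replay_trail <- function(call, record, config = locweaver_config(),
                         domain_map = NULL) {
  res <- .decide_steps(record, config, domain_map)
  if (!identical(res$trail$rule, call$trail$rule) ||
      !identical(res$trail$outcome, call$trail$outcome)) {
    return("trail mismatch on replay")
  }
  last <- nrow(call$trail)
  implied <- .outcome_label(call$trail$rule[last], call$trail$outcome[last],
                            config)
  if (is.na(implied) || implied != call$label) {
    return(sprintf("terminal outcome '%s' does not imply label '%s'",
                   call$trail$outcome[last], call$label))
  }
  TRUE
}

#' Decide every protein and tabulate the calls
#'
#' @param records list of evidence records.
#' @param config configuration list.
#' @param domain_map optional domain map.
#' @return data.frame with `locus_tag`, `label`, `confidence`, `defaulted`
#'   and `trail` (semicolon-joined `rule=outcome` pairs).
#' @export
decide_all <- function(records, config = locweaver_config(),
                       domain_map = NULL) {
  calls <- lapply(records, decide, config = config, domain_map = domain_map)
  data.frame(
    locus_tag = vapply(calls, `[[`, character(1), "locus_tag"),
    label = vapply(calls, `[[`, character(1), "label"),
    confidence = vapply(calls, `[[`, character(1), "confidence"),
    defaulted = vapply(calls, `[[`, logical(1), "defaulted"),
    trail = vapply(calls, function(cl)
      paste(cl$trail$rule, cl$trail$outcome, sep = "=", collapse = ";"),
      character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Infer location-informative domains from a call set
#'
#' A domain is location-informative when it occurs in at least `min_n`
#' called proteins and the dominant location among its carriers reaches
#' `purity_min`. Calls labeled `UNKNOWN` or `PHAGE`, and calls produced by an
#' abstain default, are excluded: a default is not a prediction and would
#' otherwise dilute every domain carried by evidence-poor proteins.
#'
#' @param calls data.frame from [decide_all()].
#' @param domain_hits domain-hit data.frame.
#' @param min_n minimum carrier count (default `config$domains$min_n`, 5).
#' @param purity_min minimum dominant-location fraction (default
#'   `config$domains$purity_min`, 1.0).
#' @param config configuration list.
#' @return data.frame with `accession`, `location`, `n_proteins`, `purity`.
#' @export
infer_domain_locations <- function(calls, domain_hits, min_n = NULL,
                                   purity_min = NULL,
                                   config = locweaver_config()) {
  if (is.null(min_n)) min_n <- config$domains$min_n
  if (is.null(purity_min)) purity_min <- config$domains$purity_min
  use <- calls[!calls$label %in% c("UNKNOWN", "PHAGE") & !calls$defaulted, ,
               drop = FALSE]
  dh <- unique(domain_hits[, c("locus_tag", "accession")])
  dh$label <- use$label[match(dh$locus_tag, use$locus_tag)]
  dh <- dh[!is.na(dh$label), , drop = FALSE]
  out <- list()
  for (acc in sort(unique(dh$accession))) {
    labs <- dh$label[dh$accession == acc]
    if (length(labs) < min_n) next
    tab <- sort(table(labs), decreasing = TRUE)
    purity <- as.numeric(tab[1L]) / length(labs)
    if (purity < purity_min) next
    out[[length(out) + 1L]] <- data.frame(
      accession = acc, location = names(tab)[1L],
      n_proteins = length(labs), purity = purity, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(accession = character(), location = character(),
                      n_proteins = integer(), purity = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Re-run the decision tree with an inferred domain map
#'
#' Second pass of [decide_all()] with the location-informative domain map
#' active, refining calls that previously fell through to a default. A third
#' pass with a map re-inferred from the second pass reaches a fixed point.
#'
#' @param records list of evidence records.
#' @param map domain map from [infer_domain_locations()].
#' @param config configuration list.
#' @return calls data.frame (see [decide_all()]).
#' @export
rerun_with_domain_map <- function(records, map,
                                  config = locweaver_config()) {
  decide_all(records, config = config, domain_map = map)
}

#' List candidate Tat hitchhikers
#'
#' Proteins exported in complex with a Tat substrate carry no signal of their
#' own; they are reported (never auto-called) when encoded within `window`
#' genes of a Tat-substrate call and lacking any signal evidence.
#'
#' @param records list of evidence records.
#' @param calls calls data.frame.
#' @param genes gene-coordinate data.frame.
#' @param window gene-index distance (default 2).
#' @return data.frame of candidate locus tags and their nearby Tat substrate.
#' @export
tat_hitchhiker_report <- function(records, calls, genes, window = 2L) {
  genes <- index_genes(genes)
  tat_tags <- calls$locus_tag[grepl("tat=exported", calls$trail, fixed = TRUE)]
  out <- list()
  for (tag in tat_tags) {
    g <- genes[genes$locus_tag == tag, , drop = FALSE]
    if (!nrow(g)) next
    near <- genes[genes$genome_id == g$genome_id &
                    genes$replicon_id == g$replicon_id &
                    abs(genes$gene_index - g$gene_index) <= window &
                    genes$locus_tag != tag, , drop = FALSE]
    for (nt in near$locus_tag) {
      rec <- records[[nt]]
      if (is.null(rec) || .has_signal_prediction(rec)) next
      out[[length(out) + 1L]] <- data.frame(
        locus_tag = nt, tat_substrate = tag, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(locus_tag = character(), tat_substrate = character(),
                      stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}
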