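# Cross-genome reconciliation: inconsistencies in localization calls or
# signal detection among orthologs usually flag gene-model errors (displaced
# start codons, long leaders) or wrong group membership.

#' Identify core ortholog groups
#'
#' A group is core when it has exactly one member in every genome of the
#' panel.
#'
#' @param ortholog_groups ortholog table (schema `ortholog_groups`, with
#'   `genome_id`).
#' @param n_genomes panel size; defaults to the number of distinct genomes in
#'   the table.
#' @return data.frame with `group_id`, `n_members`, `is_core`.
#' @export
core_groups <- function(ortholog_groups, n_genomes = NULL) {
  og <- ortholog_groups
  if (is.null(og$genome_id)) stop("ortholog table needs a genome_id column")
  if (is.null(n_genomes)) n_genomes <- length(unique(og$genome_id))
  tab <- table(og$group_id, og$genome_id)
  per_group <- rowSums(tab)
  is_core <- rowSums(tab == 1L) == n_genomes & per_group == n_genomes
  data.frame(group_id = rownames(tab), n_members = as.integer(per_group),
             is_core = as.logical(is_core), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify a group's localization consistency
#'
#' `consistent` when all evaluable members share one label, `mixed` when more
#' than one distinct label occurs, `no_evidence` when no member is evaluable.
#' Pseudogene members are excluded from evaluation by default.
#'
#' @param member_calls data.frame with `locus_tag`, `label` and optionally
#'   `pseudogene` for the group's members; members without a call (label `NA`)
#'   are not evaluable.
#' @param exclude_pseudogenes drop pseudogene members first (default from
#'   config).
#' @param config configuration list.
#' @return list with `status`, `majority_label` (`NA` if no evidence) and
#'   `n_evaluable`.
#' @export
classify_group <- function(member_calls, exclude_pseudogenes = NULL,
                           config = locweaver_config()) {
  if (is.null(exclude_pseudogenes)) {
    exclude_pseudogenes <- config$orthocheck$exclude_pseudogenes
  }
  m <- member_calls
  if (exclude_pseudogenes && !is.null(m$pseudogene)) {
    m <- m[!m$pseudogene | is.na(m$pseudogene), , drop = FALSE]
  }
  labs <- m$label[!is.na(m$label)]
  if (!length(labs)) {
    return(list(status = "no_evidence", majority_label = NA_character_,
                n_evaluable = 0L))
  }
  tab <- sort(table(labs), decreasing = TRUE)
  status <- if (length(tab) == 1L) "consistent" else "mixed"
  list(status = status, majority_label = names(tab)[1L],
       n_evaluable = length(labs))
}

#' Classify every group against a call set
#'
#' @param ortholog_groups ortholog table.
#' @param calls calls data.frame ([decide_all()]).
#' @param config configuration list.
#' @return data.frame with `group_id`, `status`, `majority_label`,
#'   `n_evaluable`.
#' @export
classify_groups <- function(ortholog_groups, calls,
                            config = locweaver_config()) {
  og <- ortholog_groups
  og$label <- calls$label[match(og$locus_tag, calls$locus_tag)]
  out <- lapply(split(og, og$group_id), function(g) {
    v <- classify_group(g, config = config)
    data.frame(group_id = g$group_id[1L], status = v$status,
               majority_label = v$majority_label,
               n_evaluable = v$n_evaluable, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$group_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Flag gene-model anomalies within an ortholog group
#'
#' Member flags: `LENGTH_OUTLIER` when a member's length deviates from the
#' group median by more than `len_frac`; `SP_MISSING` when at least `sp_frac`
#' of members carry a given signal kind and this member lacks it (suggesting
#' a displaced start codon or a leader too long for the scanner);
#' `SP_EXTRA` for the converse (a rare signal present only in this member).
#'
#' @param group_members proteome rows for one group's members (need
#'   `locus_tag`, `sequence`).
#' @param motif_lists named list (by locus tag) of [scan_all_motifs()] output;
#'   computed from the sequences if `NULL`.
#' @param config configuration list.
#' @return data.frame with `locus_tag` and `flags` (comma-joined, possibly
#'   empty).
#' @export
flag_anomalies <- function(group_members, motif_lists = NULL,
                           config = locweaver_config()) {
  oc <- config$orthocheck
  if (is.null(motif_lists)) {
    motif_lists <- lapply(stats::setNames(group_members$sequence,
                                          group_members$locus_tag),
                          scan_all_motifs, config = config)
  }
  lens <- nchar(group_members$sequence)
  med <- stats::median(lens)
  sig_kinds <- c("SEC_SP", "LIPOBOX", "TAT_RR", "TAT_LIPO", "GG_LEADER")
  has <- sapply(sig_kinds, function(k)
    vapply(group_members$locus_tag,
           function(t) k %in% names(motif_lists[[t]]), logical(1)))
  has <- matrix(has, nrow = nrow(group_members), dimnames = list(NULL, sig_kinds))
  frac <- colMeans(has)
  flags <- vapply(seq_len(nrow(group_members)), function(i) {
    f <- character()
    if (med > 0 && abs(lens[i] - med) / med > oc$len_frac) {
      f <- c(f, "LENGTH_OUTLIER")
    }
    for (k in sig_kinds) {
      if (frac[k] >= oc$sp_frac && !has[i, k]) f <- c(f, paste0("SP_MISSING:", k))
      if (frac[k] <= 1 - oc$sp_frac && frac[k] > 0 && has[i, k]) {
        f <- c(f, paste0("SP_EXTRA:", k))
      }
    }
    paste(f, collapse = ",")
  }, character(1))
  data.frame(locus_tag = group_members$locus_tag, flags = flags,
             stringsAsFactors = FALSE)
}

#' Tally a per-member boolean feature over core groups
#'
#' Mirrors the signal-peptide tool-performance summaries: for each core
#' ortholog group, is the feature absent in every member (`all_negative`),
#' present in every member (`all_positive`), or `mixed`?
#'
#' @param ortholog_groups ortholog table (with `genome_id`).
#' @param feature named logical vector keyed by locus tag.
#' @param n_genomes panel size for the core test.
#' @return named integer vector `c(all_negative, all_positive, mixed)`.
#' @export
summarize_feature <- function(ortholog_groups, feature, n_genomes = NULL) {
  cg <- core_groups(ortholog_groups, n_genomes)
  core_ids <- cg$group_id[cg$is_core]
  og <- ortholog_groups[ortholog_groups$group_id %in% core_ids, , drop = FALSE]
  counts <- c(all_negative = 0L, all_positive = 0L, mixed = 0L)
  for (gid in unique(og$group_id)) {
    f <- feature[og$locus_tag[og$group_id == gid]]
    f <- f[!is.na(f)]
    if (!length(f)) next
    key <- if (all(f)) "all_positive" else if (!any(f)) "all_negative" else "mixed"
    counts[key] <- counts[key] + 1L
  }
  counts
}

# Map lipoprotein labels onto membranes for five-category comparisons.
.five_cat <- function(labels) {
  out <- labels
  out[labels %in% c("LIPO_OM", "LIPO_SURFACE")] <- "OM"
  out[labels == "LIPO_IM"] <- "IM"
  out
}

#' Per-location tool-consistency contingency table
#'
#' For each reference (curated) label, counts the number of core groups so
#' curated, and for each tool the number of groups on which the tool is
#' internally consistent (all members one label) and, of those, how many agree
#' with the reference. Lipoprotein labels are mapped onto their membranes for
#' the five-category comparison.
#'
#' @param ortholog_groups ortholog table with a curated `location` column (the
#'   reference), or supply `reference_calls`.
#' @param tool_calls named list of call vectors (one per tool), each a named
#'   character vector keyed by locus tag.
#' @param reference_calls optional named reference label vector keyed by group
#'   id; defaults to the per-group curated `location` (which must be uniform
#'   within each group).
#' @param n_genomes panel size for the core test.
#' @return data.frame: one row per reference label plus a `Total` row;
#'   columns `n_groups`, then per tool `<tool>_consistent` and
#'   `<tool>_agree`.
#' @export
summarize_localization <- function(ortholog_groups, tool_calls,
                                   reference_calls = NULL, n_genomes = NULL) {
  cg <- core_groups(ortholog_groups, n_genomes)
  core_ids <- cg$group_id[cg$is_core]
  og <- ortholog_groups[ortholog_groups$group_id %in% core_ids, , drop = FALSE]
  if (is.null(reference_calls)) {
    if (is.null(og$location)) stop("need a curated location column or reference_calls")
    ref <- tapply(.five_cat(og$location), og$group_id,
                  function(x) if (length(unique(x)) == 1L) x[1L] else NA_character_)
  } else {
    ref <- reference_calls[core_ids]
    names(ref) <- core_ids
  }
  ref_labels <- sort(unique(stats::na.omit(as.character(ref))))
  rows <- lapply(ref_labels, function(lab) {
    gids <- names(ref)[!is.na(ref) & ref == lab]
    row <- list(reference = lab, n_groups = length(gids))
    for (tool in names(tool_calls)) {
      tc <- tool_calls[[tool]]
      cons <- agree <- 0L
      for (gid in gids) {
        labs <- .five_cat(tc[og$locus_tag[og$group_id == gid]])
        labs <- labs[!is.na(labs)]
        if (length(labs) && length(unique(labs)) == 1L) {
          cons <- cons + 1L
          if (labs[1L] == lab) agree <- agree + 1L
        }
      }
      row[[paste0(tool, "_consistent")]] <- cons
      row[[paste0(tool, "_agree")]] <- agree
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  total <- res[1L, , drop = FALSE]
  total$reference <- "Total"
  for (cn in names(res)[-1L]) total[[cn]] <- sum(res[[cn]])
  res <- rbind(res, total)
  rownames(res) <- NULL
  res
}

#' Group verdicts table
#'
#' Convenience wrapper combining [classify_groups()] with per-member anomaly
#' flags.
#'
#' @param ortholog_groups ortholog table.
#' @param calls calls data.frame.
#' @param proteins proteome data.frame (for anomaly flags; skipped if `NULL`).
#' @param config configuration list.
#' @return list with `verdicts` (per group) and `anomalies` (per member,
#'   non-empty flags only).
#' @export
orthocheck_run <- function(ortholog_groups, calls, proteins = NULL,
                           config = locweaver_config()) {
  verdicts <- classify_groups(ortholog_groups, calls, config = config)
  anomalies <- NULL
  if (!is.null(proteins)) {
    an <- lapply(split(ortholog_groups, ortholog_groups$group_id),
                 function(g) {
      memb <- proteins[proteins$locus_tag %in% g$locus_tag, , drop = FALSE]
      if (nrow(memb) < 2L) return(NULL)
      fl <- flag_anomalies(memb, config = config)
      fl$group_id <- g$group_id[1L]
      fl[nzchar(fl$flags), , drop = FALSE]
    })
    an <- do.call(rbind, an[!vapply(an, is.null, logical(1))])
    anomalies <- if (is.null(an)) {
      data.frame(locus_tag = character(), flags = character(),
                 group_id = character(), stringsAsFactors = FALSE)
    } else {
      rownames(an) <- NULL
      an
    }
  }
  list(verdicts = verdicts, anomalies = anomalies)
}
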