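# Validation of protein N-termini from observed tryptic peptides. Trypsin
# cleaves C-terminal to Lys/Arg, so a peptide terminus that does not match
# that rule is evidence of in-vivo processing (signal cleavage, N-terminal
# Met excision) or of a wrong gene model.

#' Classify a peptide's tryptic specificity
#'
#' The N-side is specific when the peptide starts at the protein N-terminus
#' or immediately after a Lys/Arg; the C-side is specific when the peptide
#' ends at the protein C-terminus or on a Lys/Arg. With the optional
#' `trypsin_kr_before_p` refinement (off by default), a Lys/Arg followed by
#' Pro does not count as a cleavage site.
#'
#' @param start,end 1-based peptide position in the parent protein.
#' @param parent parent protein sequence (must contain the peptide at
#'   `[start, end]`).
#' @param config configuration list.
#' @return one of `"fully"`, `"partial_N"` (N-side nonspecific), `"partial_C"`
#'   (C-side nonspecific), `"nonspecific"`.
#' @export
classify_tryptic <- function(start, end, parent,
                             config = locweaver_config()) {
  n <- nchar(parent)
  stopifnot(start >= 1L, end >= start, end <= n)
  kr_site <- function(pos) {
    # is a trypsin cleavage after residue `pos` allowed?
    res <- substr(parent, pos, pos)
    if (!res %in% c("K", "R")) return(FALSE)
    if (config$proteoval$trypsin_kr_before_p && pos < n &&
        substr(parent, pos + 1L, pos + 1L) == "P") {
      return(FALSE)
    }
    TRUE
  }
  n_spec <- start == 1L || kr_site(start - 1L)
  c_spec <- end == n || kr_site(end)
  if (n_spec && c_spec) "fully"
  else if (!n_spec && c_spec) "partial_N"
  else if (n_spec && !c_spec) "partial_C"
  else "nonspecific"
}

#' Map observed peptides onto their parent proteins
#'
#' When a peptide table has no position columns, each peptide is mapped to
#' every exact occurrence in the parent; peptides matching at more than one
#' site are flagged ambiguous and excluded from maturation calls.
#'
#' @param observations peptide table (schema `peptides`).
#' @param proteins proteome data.frame.
#' @param config configuration list.
#' @return data.frame with `peptide`, `locus_tag`, `start`, `end`,
#'   `n_observations`, `ambiguous` and `tryptic` class.
#' @export
map_peptides <- function(observations, proteins,
                         config = locweaver_config()) {
  out <- list()
  for (i in seq_len(nrow(observations))) {
    ob <- observations[i, , drop = FALSE]
    parent <- proteins$sequence[match(ob$locus_tag, proteins$locus_tag)]
    if (is.na(parent)) stop("unknown parent protein: ", ob$locus_tag)
    if (!is.null(ob$start) && !is.na(ob$start)) {
      starts <- ob$start
      if (substr(parent, starts, starts + nchar(ob$peptide) - 1L) !=
          ob$peptide) {
        stop("peptide/position mismatch for ", ob$locus_tag, " at ", starts)
      }
    } else {
      starts <- integer()
      p <- 1L
      repeat {
        hit <- regexpr(ob$peptide, substr(parent, p, nchar(parent)),
                       fixed = TRUE)
        if (hit == -1L) break
        starts <- c(starts, p + hit - 1L)
        p <- p + hit
      }
      if (!length(starts)) stop("peptide not found in parent ", ob$locus_tag)
    }
    for (s in starts) {
      e <- s + nchar(ob$peptide) - 1L
      out[[length(out) + 1L]] <- data.frame(
        peptide = ob$peptide, locus_tag = ob$locus_tag, start = s, end = e,
        n_observations = ob$n_observations, ambiguous = length(starts) > 1L,
        tryptic = classify_tryptic(s, e, parent, config = config),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(peptide = character(), locus_tag = character(),
                      start = integer(), end = integer(),
                      n_observations = integer(), ambiguous = logical(),
                      tryptic = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select the maturation-candidate peptide for one protein
#'
#' Partially tryptic peptides can also arise from sample processing or
#' misidentification, so only the partial-N peptide mapping most closely to
#' the parent's N-terminus is considered evidence of maturation. Ties are
#' broken by higher observation count, then longer peptide. Ambiguous
#' multi-site peptides never qualify.
#'
#' @param mapped mapped-peptide rows for one protein ([map_peptides()]).
#' @return one row of `mapped`, or `NULL` when no partial-N peptide exists.
#' @export
select_maturation_candidate <- function(mapped) {
  pn <- mapped[mapped$tryptic == "partial_N" & !mapped$ambiguous, ,
               drop = FALSE]
  if (!nrow(pn)) return(NULL)
  o <- order(pn$start, -pn$n_observations, -(pn$end - pn$start))
  pn[o[1L], , drop = FALSE]
}

.map_small <- c("A", "S", "G", "C", "T", "P", "V")

#' Explain an observed mature N-terminus
#'
#' Categories, mutually exclusive and exhaustive given a start position:
#' * `FULLY_TRYPTIC` — start 1 (no processing to explain);
#' * `MET_EXCISION_AMPP` — start 2 with Met1 followed by Pro (aminopeptidase
#'   P removes Met before Pro);
#' * `MET_EXCISION_MAP` — start 2 with Met1 followed by a small residue
#'   (methionine aminopeptidase: Ala, Ser, Gly, Cys, Thr, Pro or Val);
#' * `SIGNAL_CLEAVAGE` — the residue before the start matches a predicted
#'   signal-peptidase cleavage position exactly (tolerance configurable);
#' * `INTERNAL_UNEXPLAINED` — anything else.
#'
#' @param start observed mature-N-terminus position (first observed residue).
#' @param parent parent protein sequence.
#' @param cleavage_positions integer vector of predicted cleavage positions
#'   (last residue of each predicted signal peptide), from the scanners or
#'   external tool tables.
#' @param config configuration list (`proteoval$cleavage_tol`, default 0).
#' @return list with `category` and `matched_cleavage` (position or `NA`).
#' @export
explain_nterm <- function(start, parent, cleavage_positions = integer(),
                          config = locweaver_config()) {
  n <- nchar(parent)
  if (start <= 0L || start > n) stop("start position out of range: ", start)
  if (start == 1L) {
    return(list(category = "FULLY_TRYPTIC", matched_cleavage = NA_integer_))
  }
  if (start == 2L && substr(parent, 1L, 1L) == "M") {
    after <- substr(parent, 2L, 2L)
    if (after == "P") {
      return(list(category = "MET_EXCISION_AMPP", matched_cleavage = 1L))
    }
    if (after %in% .map_small) {
      return(list(category = "MET_EXCISION_MAP", matched_cleavage = 1L))
    }
  }
  tol <- config$proteoval$cleavage_tol
  cp <- cleavage_positions[abs(cleavage_positions - (start - 1L)) <= tol]
  if (length(cp)) {
    return(list(category = "SIGNAL_CLEAVAGE", matched_cleavage = cp[1L]))
  }
  list(category = "INTERNAL_UNEXPLAINED", matched_cleavage = NA_integer_)
}

#' Validate predicted signal cleavage against observed peptides
#'
#' One row per protein with at least one observed peptide: the maturation
#' candidate (most-N-terminal partial-N peptide), its explanation, and an
#' agreement flag with respect to the predicted signal cleavage —
#' `supports` (candidate maps exactly to cleavage + 1), `contradicts`
#' (candidate maps elsewhere and is not Met excision), or `silent` (no
#' partial-N peptide, or no predicted cleavage and nothing to contradict).
#'
#' @param observations peptide table (schema `peptides`).
#' @param proteins proteome data.frame.
#' @param predictions named list (by locus tag) of integer cleavage-position
#'   vectors; computed from the scanners if `NULL`.
#' @param config configuration list.
#' @return data.frame with `locus_tag`, `candidate_start`, `category`,
#'   `matched_cleavage`, `agreement`.
#' @export
validate_proteome <- function(observations, proteins, predictions = NULL,
                              config = locweaver_config()) {
  if (is.null(predictions)) {
    predictions <- lapply(stats::setNames(proteins$sequence,
                                          proteins$locus_tag), function(s) {
      m <- scan_all_motifs(s, config = config)
      cp <- vapply(m[setdiff(names(m), "TM_SPAN")], `[[`, integer(1),
                   "cleavage_pos")
      sort(unique(cp[cp > 0L]))
    })
  }
  mapped <- map_peptides(observations, proteins, config = config)
  out <- list()
  for (tag in unique(mapped$locus_tag)) {
    mp <- mapped[mapped$locus_tag == tag, , drop = FALSE]
    cand <- select_maturation_candidate(mp)
    preds <- predictions[[tag]] %||% integer()
    if (is.null(cand)) {
      out[[length(out) + 1L]] <- data.frame(
        locus_tag = tag, candidate_start = NA_integer_,
        category = NA_character_, matched_cleavage = NA_integer_,
        agreement = "silent", stringsAsFactors = FALSE)
      next
    }
    parent <- proteins$sequence[match(tag, proteins$locus_tag)]
    ex <- explain_nterm(cand$start, parent, preds, config = config)
    agreement <- if (ex$category == "SIGNAL_CLEAVAGE") {
      "supports"
    } else if (ex$category %in% c("MET_EXCISION_MAP", "MET_EXCISION_AMPP") ||
               !length(preds)) {
      "silent"
    } else {
      "contradicts"
    }
    out[[length(out) + 1L]] <- data.frame(
      locus_tag = tag, candidate_start = cand$start, category = ex$category,
      matched_cleavage = ex$matched_cleavage, agreement = agreement,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(locus_tag = character(), candidate_start = integer(),
                      category = character(), matched_cleavage = integer(),
                      agreement = character(), stringsAsFactors = FALSE))
  }
  rownames(res) <- NULL
  res
}
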