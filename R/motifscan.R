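# Rule-based sorting-signal scanners. All scanners are pure functions of the
# sequence and configuration, return the leftmost qualifying match (closest to
# the C-terminus for the beta-signal, which is read from that end), and treat
# the unknown residue X as belonging to no residue class.

.motif_kinds <- c("TAT_RR", "LIPOBOX", "TAT_LIPO", "SEC_SP", "GG_LEADER",
                  "BETA_CSIG", "TM_SPAN")

#' Construct a motif match
#'
#' @param kind one of `TAT_RR`, `LIPOBOX`, `TAT_LIPO`, `SEC_SP`, `GG_LEADER`,
#'   `BETA_CSIG`, `TM_SPAN`.
#' @param start,end 1-based residue positions of the matched region.
#' @param cleavage_pos position of the last residue of the removed peptide
#'   (0 if the signal is not cleaved).
#' @param score scanner-specific score.
#' @return list of class `motif_match`.
#' @export
motif_match <- function(kind, start, end, cleavage_pos = 0L, score = NA_real_) {
  kind <- match.arg(kind, .motif_kinds)
  stopifnot(start >= 1L, start <= end)
  structure(list(kind = kind, start = as.integer(start), end = as.integer(end),
                 cleavage_pos = as.integer(cleavage_pos), score = score),
            class = "motif_match")
}

#' @export
print.motif_match <- function(x, ...) {
  cat(sprintf("<%s %d-%d cleave@%d score=%s>\n", x$kind, x$start, x$end,
              x$cleavage_pos, format(x$score, digits = 3)))
  invisible(x)
}

.chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Scan for the twin-arginine (Tat) motif
#'
#' Finds the leftmost occurrence of the twin-arginine consensus
#' Z-X-R-R-X-phi-phi (Z hydrophilic, phi hydrophobic, X any residue) whose
#' first residue lies within the N-terminal search window.
#'
#' @param seq amino-acid sequence (single string).
#' @param window motif must start within the first `window` residues; default
#'   from `config$motifs$tat_window` (35), or the long-leader window (80) when
#'   `config$motifs$long_leader` is set.
#' @param config configuration list.
#' @return `motif_match` of kind `TAT_RR` (positions of the 7-residue motif,
#'   no cleavage assigned) or `NULL`.
#' @export
scan_tat_motif <- function(seq, window = NULL, config = locweaver_config()) {
  m <- config$motifs
  if (is.null(window)) {
    window <- if (isTRUE(m$long_leader)) m$long_leader_window else m$tat_window
  }
  stopifnot(window >= 7L)
  n <- nchar(seq)
  if (n < 7L) return(NULL)
  s <- .chars(seq)
  last_start <- min(window, n - 6L)
  for (i in seq_len(last_start)) {
    if (s[i] %in% m$z && s[i + 2L] == "R" && s[i + 3L] == "R" &&
        s[i + 5L] %in% m$phi && s[i + 6L] %in% m$phi) {
      return(motif_match("TAT_RR", i, i + 6L, 0L, 1))
    }
  }
  NULL
}

#' Scan for a lipobox (signal peptidase II site)
#'
#' Finds the leftmost lipobox `[LVIFMST][ASTVIG][GAS]C`. The invariant Cys is
#' lipidated and becomes residue +1 of the mature lipoprotein, so the reported
#' cleavage position is the residue immediately preceding it.
#'
#' @param seq amino-acid sequence.
#' @param window the Cys must lie within the first `window` residues (default
#'   `config$motifs$lipobox_window`, 40).
#' @param config configuration list.
#' @return `motif_match` of kind `LIPOBOX` (start = first lipobox residue,
#'   end = Cys position, cleavage before the Cys) or `NULL`.
#' @export
scan_lipobox <- function(seq, window = NULL, config = locweaver_config()) {
  if (is.null(window)) window <- config$motifs$lipobox_window
  stopifnot(window >= 4L)
  n <- nchar(seq)
  if (n < 4L) return(NULL)
  s <- .chars(seq)
  set1 <- c("L", "V", "I", "F", "M", "S", "T")
  set2 <- c("A", "S", "T", "V", "I", "G")
  set3 <- c("G", "A", "S")
  last_cys <- min(window, n)
  for (cys in 4:last_cys) {
    if (s[cys] == "C" && s[cys - 3L] %in% set1 && s[cys - 2L] %in% set2 &&
        s[cys - 1L] %in% set3) {
      return(motif_match("LIPOBOX", cys - 3L, cys, cys - 1L, 1))
    }
  }
  NULL
}

#' Detect a Tat lipoprotein signal
#'
#' Composite rule for lipoprotein substrates of the twin-arginine pathway
#' (missed by LipoP-style and TatP-style tools alike): a twin-arginine motif
#' followed by a lipobox whose Cys lies downstream of the RR pair within
#' `max_h_gap` residues.
#'
#' @param seq amino-acid sequence.
#' @param max_h_gap maximum residues between the second R and the lipobox Cys
#'   (default `config$motifs$tat_lipo_max_gap`, 30).
#' @param config configuration list.
#' @return `motif_match` of kind `TAT_LIPO` spanning the Tat motif start to
#'   the Cys, cleavage before the Cys, or `NULL`.
#' @export
detect_tat_lipoprotein <- function(seq, max_h_gap = NULL,
                                   config = locweaver_config()) {
  if (is.null(max_h_gap)) max_h_gap <- config$motifs$tat_lipo_max_gap
  tat <- scan_tat_motif(seq, config = config)
  if (is.null(tat)) return(NULL)
  # search for a lipobox Cys downstream of the RR pair (second R at tat$start+3)
  rr2 <- tat$start + 3L
  lip <- scan_lipobox(seq, window = min(nchar(seq), rr2 + max_h_gap),
                      config = config)
  if (is.null(lip)) return(NULL)
  cys <- lip$end
  if (cys <= rr2 || cys - rr2 > max_h_gap) return(NULL)
  motif_match("TAT_LIPO", tat$start, cys, cys - 1L, 1)
}

#' Scan for a Sec (signal peptidase I) signal peptide
#'
#' Deliberately simple three-part fallback heuristic for when external
#' SignalP-style predictions are unavailable (external tables take precedence
#' during evidence integration): (1) n-region: at least one Lys/Arg within the
#' first `sec_n_len` residues; (2) h-region: a run of at least `sec_h_min`
#' consecutive hydrophobic residues starting between positions `sec_h_start`
#' and `sec_h_last_start`; (3) c-region: an Ala-X-Ala-style site (residues
#' from `cleav_set` at -3 and -1) whose -3 position falls within
#' `sec_c_window` residues after the h-region; cleavage occurs after the -1
#' residue. Returns `NULL` if any element is missing.
#'
#' @param seq amino-acid sequence.
#' @param config configuration list.
#' @return `motif_match` of kind `SEC_SP` spanning residues 1..cleavage, or
#'   `NULL`.
#' @export
scan_sec_signal <- function(seq, config = locweaver_config()) {
  m <- config$motifs
  n <- nchar(seq)
  if (n < m$sec_h_start + m$sec_h_min) return(NULL)
  s <- .chars(seq)
  # n-region
  if (!any(s[seq_len(min(m$sec_n_len, n))] %in% c("K", "R"))) return(NULL)
  # h-region: first run of >= h_min consecutive phi starting in the window
  is_phi <- s %in% m$phi
  h_end <- 0L
  for (i in m$sec_h_start:min(m$sec_h_last_start, n - m$sec_h_min + 1L)) {
    if (all(is_phi[i:(i + m$sec_h_min - 1L)])) {
      j <- i + m$sec_h_min - 1L
      while (j < n && is_phi[j + 1L]) j <- j + 1L
      h_end <- j
      break
    }
  }
  if (h_end == 0L) return(NULL)
  # c-region: leftmost A-X-A-style motif starting within h_end..h_end+c_window
  hi <- min(h_end + m$sec_c_window, n - 3L)  # cleavage must leave a mature part
  if (hi >= h_end) {
    for (p in h_end:hi) {
      if (s[p] %in% m$cleav_set && s[p + 2L] %in% m$cleav_set) {
        cleave <- p + 2L
        return(motif_match("SEC_SP", 1L, cleave, cleave,
                           h_end - m$sec_h_start + 1))
      }
    }
  }
  NULL
}

#' Scan for a twin-glycine bacteriocin leader
#'
#' Class I/II bacteriocins and microcins carry a short leader ending in a
#' Gly-Gly pair, cleaved by the C39 peptidase domain of their T1SS permease.
#' Only small ORFs qualify.
#'
#' @param seq amino-acid sequence.
#' @param config configuration list; uses `gg_min_pos`/`gg_max_pos` (first Gly
#'   of the pair at positions 10..30) and `gg_max_len` (150).
#' @return `motif_match` of kind `GG_LEADER` (cleavage after the second Gly)
#'   or `NULL`.
#' @export
scan_gg_leader <- function(seq, config = locweaver_config()) {
  m <- config$motifs
  n <- nchar(seq)
  if (n > m$gg_max_len || n < m$gg_min_pos + 1L) return(NULL)
  s <- .chars(seq)
  for (i in m$gg_min_pos:min(m$gg_max_pos, n - 1L)) {
    if (s[i] == "G" && s[i + 1L] == "G") {
      return(motif_match("GG_LEADER", 1L, i + 1L, i + 1L, 1))
    }
  }
  NULL
}

#' Test the C-terminal beta-barrel signature
#'
#' Outer-membrane beta-barrel proteins end with a sorting signature read by
#' the Bam machinery: a Phe or Tyr at the very C-terminus and hydrophobic
#' residues at alternating positions 5, 7 and 9 from the C-terminus. Proteins
#' with large periplasmic C-terminal domains (e.g. TolC family) are expected
#' to lack the terminal signature.
#'
#' @param seq amino-acid sequence (length >= 9 required; shorter returns
#'   `FALSE`).
#' @param config configuration list (hydrophobic set).
#' @return logical.
#' @export
scan_beta_csig_rule <- function(seq, config = locweaver_config()) {
  n <- nchar(seq)
  if (n < 9L) return(FALSE)
  s <- .chars(seq)
  phi <- config$motifs$phi
  s[n] %in% c("F", "Y") && s[n - 4L] %in% phi && s[n - 6L] %in% phi &&
    s[n - 8L] %in% phi
}

#' Lipoprotein +2 sorting rule (enterobacterial convention)
#'
#' Applies the classical rule that an Asp at position +2 of the mature
#' lipoprotein (the residue after the lipidated Cys) retains it in the inner
#' membrane, while all others are carried to the outer membrane by Lol. This
#' rule is advisory: it holds in enterobacteria but demonstrably not in all
#' genera, so the decision tree only uses it when
#' `decide$plus2_mode = "enterobacterial"`.
#'
#' @param mature_seq mature-protein sequence beginning with the lipidated Cys.
#' @return `"IM_retained"` or `"OM_sorted"`; a length-1 mature sequence has no
#'   +2 residue and returns `"OM_sorted"` with a warning.
#' @export
check_plus2 <- function(mature_seq) {
  if (substr(mature_seq, 1L, 1L) != "C") {
    stop("mature lipoprotein sequence must begin with the lipidated Cys")
  }
  if (nchar(mature_seq) < 2L) {
    warning("mature sequence has no +2 residue; returning OM_sorted")
    return("OM_sorted")
  }
  if (substr(mature_seq, 2L, 2L) == "D") "IM_retained" else "OM_sorted"
}

#' Glycine/serine enrichment
#'
#' Enrichment of Gly and Ser coincides with predicted surface localization of
#' lipoproteins and with extracellular proteins generally; used both for
#' surface-lipoprotein sorting (genus mode) and T1SS substrate composition.
#'
#' @param seq amino-acid sequence.
#' @param background background Gly+Ser fraction (e.g. computed over the whole
#'   proteome with [proteome_background()]).
#' @return observed Gly+Ser fraction minus `background`; positive = enriched.
#' @export
glyser_enrichment <- function(seq, background) {
  s <- .chars(seq)
  sum(s %in% c("G", "S")) / length(s) - background
}

#' Proteome-wide residue background frequencies
#'
#' @param sequences character vector of amino-acid sequences.
#' @param residues residues whose aggregate fraction is returned; with
#'   `NULL` (default) the full 20-residue frequency table is returned.
#' @return named numeric frequency vector, or a single aggregate fraction.
#' @export
proteome_background <- function(sequences, residues = c("G", "S")) {
  tab <- table(factor(unlist(strsplit(sequences, "", fixed = TRUE)),
                      levels = c(.aa20, "X")))
  tab <- tab[.aa20]  # X never contributes to a residue class
  freq <- as.numeric(tab) / sum(tab)
  names(freq) <- .aa20
  if (is.null(residues)) freq else sum(freq[residues])
}

.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Basic-residue enrichment of the C-terminus
#'
#' Fraction of Lys/Arg/His in the last `n` residues; a basic C-terminus on a
#' small single-span inner-membrane protein supports a holin call.
#'
#' @param seq amino-acid sequence.
#' @param n tail length (default `config$motifs$basic_cterm_n`, 20).
#' @param config configuration list.
#' @return fraction in `[0, 1]`.
#' @export
basic_cterm_enrichment <- function(seq, n = NULL, config = locweaver_config()) {
  if (is.null(n)) n <- config$motifs$basic_cterm_n
  s <- .chars(seq)
  tail_s <- s[max(1L, length(s) - n + 1L):length(s)]
  sum(tail_s %in% config$motifs$basic) / length(tail_s)
}

# Kyte-Doolittle hydropathy; X treated as maximally hydrophilic so it can
# never support a transmembrane span.
.kd_scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2, X = -4.5)

#' Predict transmembrane spans by sliding-window hydropathy
#'
#' Fallback used when no external TMHMM/Phobius-style table is supplied
#' (external tables take precedence; note that such tools often count signal
#' peptides as spans, which the decision tree corrects for). Windows of mean
#' Kyte-Doolittle hydropathy above the threshold are merged into spans.
#'
#' @param seq amino-acid sequence.
#' @param config configuration list (`tm_window` 19, `tm_threshold` 1.6).
#' @return list of `motif_match` of kind `TM_SPAN` (possibly empty).
#' @export
scan_tm_hydropathy <- function(seq, config = locweaver_config()) {
  m <- config$motifs
  w <- m$tm_window
  n <- nchar(seq)
  if (n < w) return(list())
  h <- .kd_scale[.chars(seq)]
  h[is.na(h)] <- -4.5
  cs <- cumsum(c(0, h))
  means <- (cs[(w + 1L):(n + 1L)] - cs[seq_len(n - w + 1L)]) / w
  hit <- which(means > m$tm_threshold)
  if (!length(hit)) return(list())
  # merge overlapping qualifying windows [i, i+w-1]
  spans <- list()
  cur_s <- hit[1L]
  cur_e <- hit[1L] + w - 1L
  for (i in hit[-1L]) {
    if (i <= cur_e + 1L) {
      cur_e <- i + w - 1L
    } else {
      spans[[length(spans) + 1L]] <- c(cur_s, cur_e)
      cur_s <- i
      cur_e <- i + w - 1L
    }
  }
  spans[[length(spans) + 1L]] <- c(cur_s, cur_e)
  lapply(spans, function(sp) motif_match("TM_SPAN", sp[1L], sp[2L], 0L,
                                         max(means[hit[hit >= sp[1L] &
                                                         hit + w - 1L <= sp[2L]]])))
}

#' Run every sorting-signal scanner on one sequence
#'
#' Convenience wrapper returning at most one (leftmost) match per motif kind,
#' as required by the evidence-record invariant.
#'
#' @param seq amino-acid sequence.
#' @param config configuration list.
#' @return named list of `motif_match` objects keyed by kind; `TM_SPAN` holds
#'   a list of spans; `BETA_CSIG` is present only when the C-terminal rule
#'   fires.
#' @export
scan_all_motifs <- function(seq, config = locweaver_config()) {
  out <- list()
  tat <- scan_tat_motif(seq, config = config)
  if (!is.null(tat)) out$TAT_RR <- tat
  lip <- scan_lipobox(seq, config = config)
  if (!is.null(lip)) out$LIPOBOX <- lip
  tl <- detect_tat_lipoprotein(seq, config = config)
  if (!is.null(tl)) out$TAT_LIPO <- tl
  sec <- scan_sec_signal(seq, config = config)
  if (!is.null(sec)) out$SEC_SP <- sec
  gg <- scan_gg_leader(seq, config = config)
  if (!is.null(gg)) out$GG_LEADER <- gg
  n <- nchar(seq)
  if (scan_beta_csig_rule(seq, config = config)) {
    out$BETA_CSIG <- motif_match("BETA_CSIG", max(1L, n - 8L), n, 0L, 1)
  }
  tm <- scan_tm_hydropathy(seq, config = config)
  if (length(tm)) out$TM_SPAN <- tm
  out
}
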