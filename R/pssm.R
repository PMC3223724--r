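# C-terminal position-specific scoring matrix for the outer-membrane
# beta-signal. Motivated by the observation that a genus has enough TonB-
# dependent receptors (hundreds across a strain panel) to train a genus-
# specific C-terminal signature and sweep the proteome for further substrates.

#' Derive a C-terminal PSSM from known outer-membrane beta-barrel proteins
#'
#' Builds a log-odds matrix over the last `L` residues of the training
#' sequences with additive pseudocount `alpha`, against background residue
#' frequencies taken from a supplied proteome (uniform if none). The score
#' threshold is set to the `percentile`-th percentile of the training
#' sequences' own scores, so roughly that fraction of true substrates would be
#' missed at the threshold.
#'
#' @param training_seqs character vector of at least 20 sequences, each of
#'   length >= `L` (e.g. curated TonB-dependent receptor C-termini).
#' @param L window length (default `config$motifs$pssm_L`, 10).
#' @param background named 20-residue frequency vector (see
#'   [proteome_background()] with `residues = NULL`); uniform if `NULL`.
#' @param config configuration list (`pssm_alpha`, `pssm_percentile`).
#' @return list of class `cterm_pssm` with elements `L`, `logodds`
#'   (`L` x 20 matrix, rows = positions from the C-terminus outward in
#'   N-to-C order), `background` and `threshold`.
#' @export
derive_cterm_pssm <- function(training_seqs, L = NULL, background = NULL,
                              config = locweaver_config()) {
  m <- config$motifs
  if (is.null(L)) L <- m$pssm_L
  if (length(training_seqs) < 20L) {
    stop("need at least 20 training sequences, got ", length(training_seqs))
  }
  if (any(nchar(training_seqs) < L)) {
    stop("all training sequences must have length >= ", L)
  }
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), .aa20)
  }
  background <- background[.aa20]
  stopifnot(abs(sum(background) - 1) < 1e-9, all(is.finite(background)))
  tails <- substr(training_seqs, nchar(training_seqs) - L + 1L,
                  nchar(training_seqs))
  tmat <- do.call(rbind, strsplit(tails, "", fixed = TRUE))
  counts <- apply(tmat, 2L, function(col) {
    table(factor(col, levels = .aa20))
  })
  counts <- t(counts) + m$pssm_alpha  # L x 20, pseudocount
  freqs <- counts / rowSums(counts)
  logodds <- log2(sweep(freqs, 2L, background, "/"))
  pssm <- structure(list(L = L, logodds = logodds, background = background,
                         threshold = NA_real_),
                    class = "cterm_pssm")
  self <- vapply(training_seqs, score_cterm, numeric(1), pssm = pssm)
  pssm$threshold <- unname(stats::quantile(self, m$pssm_percentile / 100,
                                           type = 1))
  pssm
}

#' Score a sequence's C-terminus against a PSSM
#'
#' Sum of per-position log-odds over the last `L` residues; residues outside
#' that window never affect the score. `X` residues score the minimum column
#' value at their position.
#'
#' @param seq amino-acid sequence (length >= `pssm$L`; shorter scores `-Inf`).
#' @param pssm a `cterm_pssm` from [derive_cterm_pssm()].
#' @return numeric score; compare against `pssm$threshold`.
#' @export
score_cterm <- function(seq, pssm) {
  L <- pssm$L
  n <- nchar(seq)
  if (n < L) return(-Inf)
  tail_ch <- .chars(substr(seq, n - L + 1L, n))
  sum(vapply(seq_len(L), function(i) {
    if (tail_ch[i] %in% colnames(pssm$logodds)) {
      pssm$logodds[i, tail_ch[i]]
    } else {
      min(pssm$logodds[i, ])  # X and other non-standard residues
    }
  }, numeric(1)))
}

#' @export
print.cterm_pssm <- function(x, ...) {
  cat(sprintf("<cterm_pssm L=%d threshold=%.3f>\n", x$L, x$threshold))
  invisible(x)
}
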