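# Independent brute-force oracles for the sorting-signal scanners and the
# counting operations. Deliberately implemented with different mechanics than
# the package (regex lookahead / rle / exhaustive enumeration) so agreement is
# meaningful.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seqs <- function(n, min_len = 7, max_len = 60, seed = 1,
                        with_x = TRUE) {
  set.seed(seed)
  alphabet <- if (with_x) c(AA20, "X") else AA20
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1L)
    paste(sample(alphabet, len, replace = TRUE,
                 prob = c(rep(1, length(alphabet) - if (with_x) 1 else 0),
                          if (with_x) 0.5)), collapse = "")
  }, character(1))
}

.re_starts <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1L]]
  as.integer(m[m > 0L])
}

oracle_tat_starts <- function(seq, window = 35) {
  starts <- .re_starts(seq, "[DEHKNQRST].RR.[AILFMVW][AILFMVW]")
  starts[starts <= window]
}

oracle_lipobox_cys <- function(seq, window = 40) {
  starts <- .re_starts(seq, "[LVIFMST][ASTVIG][GAS]C")
  cys <- starts + 3L
  cys[cys <= window]
}

oracle_gg_ends <- function(seq, min_pos = 10, max_pos = 30, max_len = 150) {
  if (nchar(seq) > max_len) return(integer())
  starts <- .re_starts(seq, "GG")
  starts <- starts[starts >= min_pos & starts <= max_pos]
  starts + 1L
}

oracle_beta <- function(seq) {
  if (nchar(seq) < 9L) return(FALSE)
  r <- rev(strsplit(seq, "")[[1L]])
  r[1L] %in% c("F", "Y") && all(r[c(5L, 7L, 9L)] %in%
                                  c("A", "I", "L", "F", "M", "V", "W"))
}

oracle_sec <- function(seq) {
  # independent re-derivation of the three-part heuristic using rle
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  if (n < 10L) return(NA_integer_)
  if (!any(ch[1:min(5L, n)] %in% c("K", "R"))) return(NA_integer_)
  phi <- c("A", "I", "L", "F", "M", "V", "W")
  r <- rle(ch %in% phi)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  h_end <- NA_integer_
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    qualifies <- if (starts[k] >= 3L) {
      r$lengths[k] >= 7L && starts[k] <= 25L
    } else {
      # a run starting before 3 counts via its sub-run starting at 3
      ends[k] >= 9L
    }
    if (qualifies) { h_end <- ends[k]; break }
  }
  if (is.na(h_end)) return(NA_integer_)
  hi <- min(h_end + 12L, n - 3L)
  if (hi >= h_end) {
    for (p in h_end:hi) {
      if (ch[p] %in% c("A", "S") && ch[p + 2L] %in% c("A", "S")) {
        return(p + 2L)
      }
    }
  }
  NA_integer_
}

KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
        G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
        P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = -4.5)

oracle_tm_spans <- function(seq, w = 19, thr = 1.6) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  if (n < w) return(list())
  h <- unname(KD[ch])
  hits <- which(vapply(seq_len(n - w + 1L),
                       function(i) mean(h[i:(i + w - 1L)]) > thr, logical(1)))
  if (!length(hits)) return(list())
  w <- as.integer(w)
  spans <- list()
  cur <- c(hits[1L], hits[1L] + w - 1L)
  for (i in hits[-1L]) {
    if (i <= cur[2L] + 1L) cur[2L] <- i + w - 1L
    else { spans[[length(spans) + 1L]] <- cur; cur <- c(i, i + w - 1L) }
  }
  spans[[length(spans) + 1L]] <- cur
  spans
}

oracle_vote <- function(labels, weights = NULL) {
  if (!length(labels)) return(list(label = "UNKNOWN", margin = 0))
  if (is.null(weights)) weights <- rep(1, length(labels))
  ul <- unique(labels)
  tot <- vapply(ul, function(l) sum(weights[labels == l]), numeric(1))
  top <- max(tot)
  winners <- ul[tot == top]
  if (length(winners) > 1L) return(list(label = "UNKNOWN", margin = 0))
  second <- if (length(tot) > 1L) max(tot[ul != winners]) else 0
  list(label = winners, margin = unname((top - second) / sum(weights)))
}

oracle_tryptic <- function(start, end, parent) {
  ch <- strsplit(parent, "")[[1L]]
  n <- length(ch)
  n_spec <- start == 1L || ch[start - 1L] %in% c("K", "R")
  c_spec <- end == n || ch[end] %in% c("K", "R")
  if (n_spec && c_spec) "fully"
  else if (c_spec) "partial_N"
  else if (n_spec) "partial_C"
  else "nonspecific"
}

# cached synthetic bundle shared across test files (generation is ~4 s)
get_bundle7 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synth_bundle(synth_config(seed = 7L))
    cache
  }
})

get_result7 <- local({
  cache <- NULL
  function() {
    b <- get_bundle7()
    if (is.null(cache)) {
      cache <<- predict_localization(b$proteins, b$genes, b$domain_hits,
                                     b$tools, b$orthologs)
    }
    cache
  }
})

# a minimal hand-built evidence record for decision-tree tests
make_record <- function(locus_tag = "P1", sequence = strrep("Q", 120),
                        motifs = list(), tools = NULL, domains = character(),
                        phage = FALSE, secretion_component = NA_character_,
                        glyser = 0, beta_score = NA_real_,
                        beta_threshold = NA_real_) {
  if (is.null(tools)) {
    tools <- data.frame(locus_tag = character(), tool_name = character(),
                        prediction_type = character(), value = character(),
                        score = numeric(), stringsAsFactors = FALSE)
  }
  list(locus_tag = locus_tag, sequence = sequence, motifs = motifs,
       tools = tools, domains = domains,
       context = list(phage = phage,
                      secretion_component = secretion_component,
                      microcompartment = FALSE),
       glyser = glyser, beta_score = beta_score,
       beta_threshold = beta_threshold)
}

tool_row <- function(tag, tool, type, value) {
  data.frame(locus_tag = tag, tool_name = tool, prediction_type = type,
             value = as.character(value), score = 1, stringsAsFactors = FALSE)
}

# random evidence record driven by an RNG already seeded by the caller
random_record <- function(i) {
  seq_i <- paste(sample(AA20, sample(60:200, 1L), replace = TRUE),
                 collapse = "")
  tools <- list()
  tag <- paste0("R", i)
  for (tool in c("psortb", "cello", "sosuigramn")) {
    if (runif(1) < 0.7) {
      tools[[length(tools) + 1L]] <-
        tool_row(tag, tool, "global_location",
                 sample(c("CYT", "IM", "PERI", "OM", "EXTRA"), 1L))
    }
  }
  if (runif(1) < 0.3) {
    tools[[length(tools) + 1L]] <- tool_row(tag, "subloc", "global_location",
                                            sample(c("CYT", "PERI", "EXTRA"), 1L))
  }
  if (runif(1) < 0.2) {
    tools[[length(tools) + 1L]] <- tool_row(tag, "signalp", "signal_lepb", 21L)
  }
  if (runif(1) < 0.15) {
    tools[[length(tools) + 1L]] <- tool_row(tag, "lipop", "signal_lspa", 20L)
  }
  if (runif(1) < 0.1) {
    tools[[length(tools) + 1L]] <- tool_row(tag, "tatp", "signal_tat", 0L)
  }
  if (runif(1) < 0.25) {
    k <- sample(1:4, 1L)
    spans <- paste(vapply(seq_len(k), function(j) {
      a <- 10L + (j - 1L) * 40L
      sprintf("%d-%d", a, a + 20L)
    }, character(1)), collapse = ";")
    tools[[length(tools) + 1L]] <- tool_row(tag, "tmhmm", "tm_spans", spans)
  }
  if (runif(1) < 0.1) {
    tools[[length(tools) + 1L]] <- tool_row(tag, "bomp", "beta_barrel", "TRUE")
  }
  tools_df <- if (length(tools)) do.call(rbind, tools) else NULL
  make_record(
    locus_tag = tag, sequence = seq_i, tools = tools_df,
    domains = if (runif(1) < 0.2) sample(c("pfamA", "pfamB"), 1L) else character(),
    phage = runif(1) < 0.05,
    secretion_component = if (runif(1) < 0.1) {
      sample(c("OM", "IM", "LIPO_OM", "mixed"), 1L)
    } else NA_character_,
    glyser = runif(1, -0.1, 0.2))
}
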