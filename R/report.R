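# Human-readable run report. Every number in the report is recomputable
# from the emitted tables: the report holds no state of its own.

#' Render a run summary
#'
#' Tallies the final calls (label histogram, confidence distribution),
#' the ortholog-group consistency trichotomy, the anomaly and candidate
#' lists, and the fraction of proteins on which at least three global
#' predictors agree.
#'
#' @param calls calls data.frame ([decide_all()]).
#' @param verdicts group-verdict data.frame ([classify_groups()]), or `NULL`.
#' @param candidates candidate data.frame, or `NULL`.
#' @param tools tool-prediction data.frame (for the agreement fraction), or
#'   `NULL`.
#' @param anomalies anomaly data.frame ([orthocheck_run()]), or `NULL`.
#' @param config configuration list (echoed into the header).
#' @return list of class `locweaver_report` with `label_counts`,
#'   `confidence_counts`, `verdict_counts`, `candidate_counts`,
#'   `frac_3tool_agreement` and `text` (printable lines).
#' @export
render_summary <- function(calls, verdicts = NULL, candidates = NULL,
                           tools = NULL, anomalies = NULL,
                           config = locweaver_config()) {
  lab <- table(factor(calls$label, levels = LOC_VOCAB))
  conf <- table(factor(calls$confidence, levels = c("high", "medium", "low")))
  vc <- if (is.null(verdicts)) {
    c(consistent = 0L, mixed = 0L, no_evidence = 0L)
  } else {
    tab <- table(factor(verdicts$status,
                        levels = c("consistent", "mixed", "no_evidence")))
    stats::setNames(as.integer(tab), names(tab))
  }
  cc <- if (is.null(candidates) || !nrow(candidates)) {
    integer(0)
  } else {
    tab <- table(candidates$candidate_kind)
    stats::setNames(as.integer(tab), names(tab))
  }
  frac3 <- NA_real_
  if (!is.null(tools) && nrow(tools)) {
    g <- tools[tools$prediction_type == "global_location", , drop = FALSE]
    if (nrow(g)) {
      agree <- tapply(g$value, g$locus_tag, function(v) {
        max(table(v)) >= 3L
      })
      frac3 <- mean(agree[names(agree) %in% calls$locus_tag])
    }
  }
  text <- c(
    sprintf("# locweaver run summary (config version %s)", config$version),
    sprintf("proteins called: %d", nrow(calls)),
    "## localization calls",
    sprintf("  %-13s %6d", names(lab), as.integer(lab)),
    "## confidence",
    sprintf("  %-7s %6d", names(conf), as.integer(conf)),
    "## ortholog-group consistency",
    sprintf("  %-12s %6d", names(vc), as.integer(vc)),
    "## substrate candidates",
    if (length(cc)) sprintf("  %-22s %6d", names(cc), cc) else "  none",
    sprintf("## >=3 global predictors agree: %s",
            if (is.na(frac3)) "n/a" else sprintf("%.1f%%", 100 * frac3)),
    if (!is.null(anomalies) && nrow(anomalies)) {
      c("## gene-model anomalies",
        sprintf("  %s (%s): %s", anomalies$locus_tag, anomalies$group_id,
                anomalies$flags))
    } else "## gene-model anomalies: none"
  )
  structure(list(label_counts = lab, confidence_counts = conf,
                 verdict_counts = vc, candidate_counts = cc,
                 frac_3tool_agreement = frac3, text = text),
            class = "locweaver_report")
}

#' @export
print.locweaver_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' Write a report to disk
#'
#' @param report `locweaver_report`.
#' @param path output text path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  writeLines(report$text, path)
  invisible(path)
}
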