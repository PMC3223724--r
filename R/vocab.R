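#' Controlled subcellular-location vocabulary
#'
#' All localization labels used throughout the package are drawn from this
#' fixed vocabulary. External predictor labels are normalized onto it with
#' [normalize_location()].
#'
#' @format Character vector of the ten recognized labels:
#' `CYT` (cytoplasm), `IM` (inner membrane), `PERI` (periplasm),
#' `OM` (outer membrane), `EXTRA` (extracellular), `LIPO_IM`, `LIPO_OM`,
#' `LIPO_SURFACE` (lipoproteins anchored to the inner membrane, to the
#' periplasmic face of the outer membrane, or exposed on the cell surface),
#' `PHAGE` (bacteriophage structural protein) and `UNKNOWN`.
#' @export
LOC_VOCAB <- c("CYT", "IM", "PERI", "OM", "EXTRA",
               "LIPO_IM", "LIPO_OM", "LIPO_SURFACE", "PHAGE", "UNKNOWN")

# Synonym table for labels emitted by external tools and by the packaged
# registries. Keys are matched case-insensitively after stripping spaces,
# hyphens and underscores.
.loc_synonyms <- c(
  "cyt" = "CYT", "cytoplasm" = "CYT", "cytoplasmic" = "CYT",
  "cytimassoc" = "CYT",
  "im" = "IM", "innermembrane" = "IM", "cytoplasmicmembrane" = "IM",
  "membrane" = "IM", "plasmamembrane" = "IM",
  "peri" = "PERI", "periplasm" = "PERI", "periplasmic" = "PERI",
  "om" = "OM", "outermembrane" = "OM",
  "extra" = "EXTRA", "extracellular" = "EXTRA", "secreted" = "EXTRA",
  "lipoim" = "LIPO_IM", "imlipoprotein" = "LIPO_IM",
  "lipoom" = "LIPO_OM", "omlipoprotein" = "LIPO_OM", "lpom" = "LIPO_OM",
  "liposurface" = "LIPO_SURFACE", "surfacelipoprotein" = "LIPO_SURFACE",
  "phage" = "PHAGE",
  "unknown" = "UNKNOWN", "na" = "UNKNOWN",
  "mixed" = "mixed", "omextra" = "mixed"
)

#' Normalize a location label onto the controlled vocabulary
#'
#' Maps free-form labels from external predictors (e.g. `"Cytoplasmic"`,
#' `"OuterMembrane"`) or registry tables (e.g. `"LP-OM"`, `"OM lipoprotein"`)
#' onto [LOC_VOCAB]. The special value `"mixed"` (a component observed in more
#' than one compartment) is passed through unchanged.
#'
#' @param x character vector of labels.
#' @param strict error on unmappable labels (default) instead of `UNKNOWN`.
#' @return character vector of vocabulary labels (or `"mixed"`).
#' @export
normalize_location <- function(x, strict = TRUE) {
  key <- tolower(gsub("[ _|-]", "", as.character(x)))
  out <- .loc_synonyms[key]
  direct <- x %in% c(LOC_VOCAB, "mixed")
  out[direct] <- x[direct]
  bad <- is.na(out)
  if (any(bad)) {
    if (strict) {
      stop("unknown location label(s): ", paste(unique(x[bad]), collapse = ", "))
    }
    out[bad] <- "UNKNOWN"
  }
  unname(out)
}

#' Amino-acid residue classes used by the sorting-signal scanners
#'
#' The scanners classify residues into hydrophobic (phi), hydrophilic (Z),
#' small (the seven residues accepted next to an excised N-terminal Met) and
#' basic sets. The unknown residue `X` (internal stop codon in a pseudogene
#' translation) belongs to no class and therefore never satisfies a motif.
#'
#' @param config optional configuration list (see [locweaver_config()]); the
#'   sets are read from its `motifs` block so they can be overridden.
#' @return named list with character vectors `phi`, `z`, `small`, `basic` and
#'   the signal-peptidase cleavage-site set `cleav`.
#' @export
residue_classes <- function(config = locweaver_config()) {
  m <- config$motifs
  stopifnot(length(intersect(m$phi, m$z)) == 0)
  list(phi = m$phi, z = m$z, small = m$small, basic = m$basic,
       cleav = m$cleav_set)
}

#' Default configuration
#'
#' Central registry of every tunable threshold and residue set in the
#' pipeline, overridable via `...` (named nested lists merged over the
#' defaults) or from a YAML file via [read_config()].
#'
#' Defaults of note (all positions 1-based, inclusive):
#' * `motifs$phi` / `motifs$z`: hydrophobic and hydrophilic residue sets used
#'   by the twin-arginine (ZXRRX-phi-phi), Sec h-region and beta-signal rules.
#' * `motifs$tat_window` (35): twin-arginine motif must begin within this many
#'   residues of the N-terminus; `motifs$long_leader_window` (80) is used
#'   instead when `motifs$long_leader = TRUE` (some Tat leaders run to ~68 aa).
#' * `motifs$lipobox_window` (40): the invariant lipobox Cys must occur within
#'   this window.
#' * `motifs$cleav_set` (`A`,`S`): residues accepted at -3/-1 of a signal
#'   peptidase I cleavage site (Ala-X-Ala style).
#' * `decide$plus2_mode`: `"genus"` (default; Asp+2 not trusted, surface
#'   lipoproteins called from Gly/Ser enrichment and inner-membrane anchors
#'   from a domain list) or `"enterobacterial"` (classical D+2 rule).
#' * `domains$min_n` (5) / `domains$purity_min` (1.0): carrier count and
#'   location purity required before a domain is considered
#'   location-informative.
#'
#' @param ... named overrides, e.g. `motifs = list(tat_window = 80)`.
#' @return nested configuration list of class `locweaver_config`.
#' @export
locweaver_config <- function(...) {
  cfg <- list(
    version = 1L,
    motifs = list(
      phi = c("A", "I", "L", "F", "M", "V", "W"),
      z = c("D", "E", "H", "K", "N", "Q", "R", "S", "T"),
      small = c("A", "S", "G", "C", "T", "P", "V"),
      basic = c("K", "R", "H"),
      cleav_set = c("A", "S"),
      tat_window = 35L,
      long_leader = FALSE,
      long_leader_window = 80L,
      lipobox_window = 40L,
      tat_lipo_max_gap = 30L,
      sec_n_len = 5L,
      sec_h_min = 7L,
      sec_h_start = 3L,
      sec_h_last_start = 25L,
      sec_c_window = 12L,
      gg_min_pos = 10L,
      gg_max_pos = 30L,
      gg_max_len = 150L,
      tm_window = 19L,
      tm_threshold = 1.6,
      pssm_L = 10L,
      pssm_alpha = 1,
      pssm_percentile = 5,
      basic_cterm_n = 20L
    ),
    decide = list(
      plus2_mode = "genus",
      surface_threshold = 0.05,
      glyser_background = 0.13,
      weights = NULL,
      tie_policy = "abstain",
      exported_abstain = "PERI",
      no_signal_abstain = "CYT",
      im_anchor_domains = c("pfam00529"),
      sp_aware_tools = c("phobius"),
      nterm_tm_window = 35L,
      beta_pssm_active = FALSE
    ),
    sysfinder = list(
      max_gap_genes = 3L,
      adjacency_genes = 5L,
      t1ss_min_len = 700L,
      holin_max_len = 150L,
      holin_basic_threshold = 0.25,
      mcp_frac = 0.5,
      mcp_ctx_genes = 10L
    ),
    orthocheck = list(
      len_frac = 0.2,
      sp_frac = 0.75,
      exclude_pseudogenes = TRUE
    ),
    proteoval = list(
      cleavage_tol = 0L,
      trypsin_kr_before_p = FALSE
    ),
    domains = list(
      min_n = 5L,
      purity_min = 1.0
    )
  )
  cfg <- .merge_config(cfg, list(...))
  class(cfg) <- "locweaver_config"
  cfg
}

.merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read a configuration file
#'
#' Loads a YAML configuration and merges it over [locweaver_config()]
#' defaults. Keys not present in the default tree are rejected so typos fail
#' loudly.
#'
#' @param path YAML file.
#' @return `locweaver_config` list.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  def <- locweaver_config()
  .check_keys(y, def, "")
  do.call(locweaver_config, y[setdiff(names(y), "version")])
}

.check_keys <- function(x, ref, prefix) {
  bad <- setdiff(names(x), names(ref))
  if (length(bad)) stop("unknown config key(s): ",
                        paste0(prefix, bad, collapse = ", "))
  for (nm in names(x)) {
    if (is.list(x[[nm]]) && is.list(ref[[nm]])) {
      .check_keys(x[[nm]], ref[[nm]], paste0(prefix, nm, "$"))
    }
  }
  invisible(TRUE)
}

#' Write a configuration file
#'
#' @param config `locweaver_config` list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
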