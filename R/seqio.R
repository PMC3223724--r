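#' Read a proteome FASTA file
#'
#' Reads translated gene products. The locus tag is the first
#' whitespace-delimited token of each header; a trailing `*` marks a
#' pseudogene translation (which may contain `X` residues at internal stop
#' codons). Coordinates are not carried in FASTA; join against a gene
#' coordinate table where needed.
#'
#' @param path FASTA file of amino-acid sequences.
#' @param genome_id genome identifier recorded on every record.
#' @return data.frame with columns `locus_tag`, `genome_id`, `pseudogene`
#'   (logical) and `sequence`.
#' @export
read_proteome <- function(path, genome_id) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("empty FASTA file: ", path)
  tags <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  pseudo <- grepl("\\*$", tags)
  tags <- sub("\\*$", "", tags)
  dup <- tags[duplicated(tags)]
  if (length(dup)) stop("duplicate locus_tag in ", path, ": ",
                        paste(unique(dup), collapse = ", "))
  seqs <- as.character(aa)
  if (any(!nzchar(seqs))) stop("empty sequence for locus_tag ",
                               paste(tags[!nzchar(seqs)], collapse = ", "))
  data.frame(locus_tag = tags, genome_id = genome_id, pseudogene = pseudo,
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a proteome FASTA file
#'
#' Inverse of [read_proteome()]: pseudogenes regain their trailing `*`.
#'
#' @param proteins data.frame as returned by [read_proteome()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- paste0(proteins$locus_tag, ifelse(proteins$pseudogene, "*", ""))
  Biostrings::writeXStringSet(aa, path, width = 70L)
  invisible(path)
}

# Required and typed columns per table schema. Coordinates are 1-based
# inclusive everywhere.
.table_schemas <- list(
  gene_coords = list(
    required = c("locus_tag", "genome_id", "replicon_id", "start", "end",
                 "strand"),
    integer = c("start", "end"),
    optional = c("annotation", "pseudogene")
  ),
  domain_hits = list(
    required = c("locus_tag", "accession", "evalue", "ali_from", "ali_to"),
    integer = c("ali_from", "ali_to"),
    numeric = "evalue"
  ),
  tool_predictions = list(
    required = c("locus_tag", "tool_name", "prediction_type", "value"),
    optional = "score"
  ),
  ortholog_groups = list(
    required = c("locus_tag", "group_id"),
    optional = c("genome_id", "pseudogene", "location")
  ),
  peptides = list(
    required = c("peptide", "locus_tag", "n_observations"),
    integer = "n_observations",
    optional = c("start", "end")
  )
)

.tool_prediction_types <- c("signal_lepb", "signal_lspa", "signal_tat",
                            "tm_spans", "beta_barrel", "global_location")

#' Read a typed TSV table
#'
#' Reads one of the pipeline's tabular inputs. Lines starting with `#` are
#' ignored; unknown columns are kept but not validated. Locus tags carrying a
#' trailing `*` (pseudogene convention) are stripped and recorded in a logical
#' `pseudogene` column.
#'
#' Schemas: `gene_coords` (locus_tag, genome_id, replicon_id, start, end,
#' strand, optional annotation), `domain_hits` (locus_tag, accession, evalue,
#' ali_from, ali_to), `tool_predictions` (locus_tag, tool_name,
#' prediction_type, value, optional score; `global_location` values are
#' normalized onto the controlled vocabulary), `ortholog_groups` (locus_tag,
#' group_id, optional genome_id/pseudogene/location) and `peptides` (peptide,
#' locus_tag, n_observations, optional start/end).
#'
#' @param path TSV file with a header row.
#' @param schema one of the schema names above.
#' @return data.frame of typed records.
#' @export
read_table <- function(path, schema = names(.table_schemas)) {
  schema <- match.arg(schema)
  sc <- .table_schemas[[schema]]
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  miss <- setdiff(sc$required, names(df))
  if (length(miss)) stop("table ", path, " (schema ", schema,
                         ") is missing required column(s): ",
                         paste(miss, collapse = ", "))
  for (col in sc$integer) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) | v <= 0L)
    if (length(bad)) stop("column '", col, "' of ", path,
                          " must be a positive integer; first bad data row: ",
                          bad[1])
    df[[col]] <- v
  }
  for (col in sc$numeric) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) stop("column '", col, "' of ", path,
                          " must be numeric; first bad data row: ", bad[1])
    df[[col]] <- v
  }
  if ("locus_tag" %in% names(df)) {
    starred <- grepl("\\*$", df$locus_tag)
    df$locus_tag <- sub("\\*$", "", df$locus_tag)
    if ("pseudogene" %in% names(df)) {
      df$pseudogene <- as.logical(df$pseudogene) | starred
    } else if (any(starred) || schema %in% c("ortholog_groups", "gene_coords")) {
      df$pseudogene <- starred
    }
  }
  if (schema == "domain_hits" && any(df$evalue < 0)) {
    stop("negative e-value in ", path)
  }
  if (schema == "gene_coords" && any(df$start > df$end)) {
    stop("start > end in ", path)
  }
  if (schema == "tool_predictions") {
    bad <- setdiff(unique(df$prediction_type), .tool_prediction_types)
    if (length(bad)) stop("unknown prediction_type in ", path, ": ",
                          paste(bad, collapse = ", "))
    gl <- df$prediction_type == "global_location"
    df$value[gl] <- normalize_location(df$value[gl])
  }
  if (schema == "ortholog_groups" && "location" %in% names(df)) {
    df$location <- normalize_location(df$location)
  }
  df
}

#' Write a typed TSV table
#'
#' Writer counterpart of [read_table()]. All coordinates are written 1-based
#' inclusive. Round-trips: `read_table(write_table(x, p), schema)` reproduces
#' `x`'s typed columns exactly.
#'
#' @param df data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a packaged domain registry
#'
#' The package ships three registries transcribed from the curated
#' *Shewanella* export-machinery tables: `secretins` (the 18 secretin/usher
#' domains that anchor secretion-system loci, with per-domain system class and
#' predicted component localization), `core_machinery` (Sec, Tat, Lol and Bam
#' core components plus the membrane-fusion/permease domains that identify
#' TolC-dependent T1SS) and `peptidases` (signal peptidases and their
#' substrates' signature domains).
#'
#' @param name registry name.
#' @return data.frame of class `domain_registry` with columns `accession`,
#'   `system`, `component_location` (controlled vocabulary or `"mixed"`),
#'   `role` and `ambiguous`; one row per accession.
#' @export
load_registry <- function(name = c("secretins", "core_machinery",
                                   "peptidases")) {
  name <- match.arg(name)
  path <- system.file("extdata", "registry", paste0(name, ".tsv"),
                      package = "locweaver", mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("accession", "system", "component_location", "role", "ambiguous")
  if (!all(need %in% names(df)) || anyNA(df$accession) ||
      any(duplicated(df$accession))) {
    stop("corrupted registry file: ", path)
  }
  ok <- df$component_location %in% c(LOC_VOCAB, "mixed")
  if (!all(ok)) stop("corrupted registry file (bad location): ", path)
  class(df) <- c("domain_registry", class(df))
  df
}

#' Look up registry entries by accession
#'
#' @param registry a `domain_registry` from [load_registry()].
#' @param accession character vector of accessions (case-insensitive match).
#' @return data.frame of matching rows (zero rows where absent).
#' @export
registry_lookup <- function(registry, accession) {
  registry[match(tolower(accession), tolower(registry$accession)), ,
           drop = FALSE]
}
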