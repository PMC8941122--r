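#' @importFrom stats setNames runif aggregate
#' @importFrom utils read.table write.table head packageVersion
NULL

# Canonical domain labels used throughout the pipeline.  Everything a
# scanner emits is normalized onto this vocabulary; labels outside it
# collapse to "Other" so no hit is ever dropped silently.
CANONICAL_DOMAINS <- c(
  "Stress-antifungal", "Pkinase-tyr", "Pkinase", "Pkinase_fungal",
  "DUF3403", "FYVE", "ALMT", "FUSC_2", "FUSC", "Cript", "TauE",
  "PRIMA1", "SugarTransporter", "SignalPeptide", "Transmembrane", "Other"
)

#' Default alias table mapping scanner labels to canonical domain names
#'
#' Domain scanners spell the same domain several ways: the DUF26
#' extracellular domain alone appears as \code{PF01657},
#' \code{Stress-antifungal}, \code{Gnk2}, \code{DUF26} or \code{DUF 26}
#' depending on the database release.  The alias table is a named
#' character vector mapping every raw label or accession (names) to one
#' canonical label (values).  Matching is case-insensitive and Pfam
#' accession versions (\code{PF01657.17}) are stripped before lookup.
#'
#' @param extra optional named character vector of additional raw ->
#'   canonical pairs; entries override the defaults on name collision.
#' @return named character vector (raw label -> canonical label).
#' @export
#' @examples
#' tab <- default_alias_table()
#' normalize_domain(c("Gnk2", "PF01657.17", "Pkinase_Tyr"), tab)
default_alias_table <- function(extra = NULL) {
  tab <- c(
    "stress-antifungal" = "Stress-antifungal",
    "stress_antifungal" = "Stress-antifungal",
    "gnk2"              = "Stress-antifungal",
    "gnk2-homologous"   = "Stress-antifungal",
    "duf26"             = "Stress-antifungal",
    "duf 26"            = "Stress-antifungal",
    "duf_26"            = "Stress-antifungal",
    "pf01657"           = "Stress-antifungal",
    "ipr002902"         = "Stress-antifungal",
    "ipr038408"         = "Stress-antifungal",
    "pkinase-tyr"       = "Pkinase-tyr",
    "pkinase_tyr"       = "Pkinase-tyr",
    "pk_tyr_ser-thr"    = "Pkinase-tyr",
    "pf07714"           = "Pkinase-tyr",
    "pkinase"           = "Pkinase",
    "pf00069"           = "Pkinase",
    "pkinase_fungal"    = "Pkinase_fungal",
    "pkinase-fungal"    = "Pkinase_fungal",
    "duf3403"           = "DUF3403",
    "pf11883"           = "DUF3403",
    "fyve"              = "FYVE",
    "fyve_2"            = "FYVE",
    "pf01363"           = "FYVE",
    "almt"              = "ALMT",
    "fusc_2"            = "FUSC_2",
    "fusc"              = "FUSC",
    "cript"             = "Cript",
    "taue"              = "TauE",
    "prima1"            = "PRIMA1",
    "sugartransporter"  = "SugarTransporter",
    "sugar_tr"          = "SugarTransporter",
    "pf00083"           = "SugarTransporter",
    "signalpeptide"     = "SignalPeptide",
    "signal_peptide"    = "SignalPeptide",
    "sigp"              = "SignalPeptide",
    "transmembrane"     = "Transmembrane",
    "tmhelix"           = "Transmembrane",
    "other"             = "Other"
  )
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra))))
      stop("`extra` alias entries must all be named")
    names(extra) <- tolower(names(extra))
    tab[names(extra)] <- unname(extra)
  }
  tab
}

#' Normalize raw domain labels through an alias table
#'
#' Unknown labels map to \code{"Other"} with one warning listing them;
#' they are never dropped, so downstream class signatures can still be
#' computed and flagged.
#'
#' @param labels character vector of raw scanner labels or accessions.
#' @param aliases alias table from [default_alias_table()].
#' @return character vector of canonical labels, same length as input.
#' @export
normalize_domain <- function(labels, aliases = default_alias_table()) {
  key <- tolower(sub("\\.\\d+$", "", labels))
  out <- unname(aliases[key])
  unknown <- is.na(out)
  if (any(unknown)) {
    warning("unrecognized domain label(s) mapped to 'Other': ",
            paste(unique(labels[unknown]), collapse = ", "))
    out[unknown] <- "Other"
  }
  out
}

#' Construct a table of domain hits
#'
#' The canonical in-memory representation of domain-scan evidence: one
#' row per match of one domain on one protein.  Coordinates are
#' amino-acid positions, 1-based and inclusive at both ends, the same
#' convention as GFF3 and Pfam-Scan output.
#'
#' @param protein_id character.
#' @param domain_name canonical domain label.
#' @param start,end 1-based inclusive amino-acid coordinates.
#' @param e_value non-negative numeric.
#' @param bit_score numeric.
#' @param domain_accession optional accession (PF or IPR style); NA if
#'   unknown.
#' @param significant logical flag as reported by the scanner; NA when
#'   the scanner provides none.
#' @return data.frame of class \code{crk_hits}.
#' @export
domain_hits <- function(protein_id, domain_name, start, end,
                        e_value = 0, bit_score = 0,
                        domain_accession = NA_character_,
                        significant = NA) {
  if (length(protein_id) == 0) {
    df <- data.frame(protein_id = character(0), domain_name = character(0),
                     domain_accession = character(0), start = integer(0),
                     end = integer(0), e_value = numeric(0),
                     bit_score = numeric(0), significant = logical(0),
                     stringsAsFactors = FALSE)
    return(validate_hits(df))
  }
  df <- data.frame(
    protein_id = as.character(protein_id),
    domain_name = as.character(domain_name),
    domain_accession = as.character(domain_accession),
    start = as.integer(start),
    end = as.integer(end),
    e_value = as.numeric(e_value),
    bit_score = as.numeric(bit_score),
    significant = as.logical(significant),
    stringsAsFactors = FALSE
  )
  validate_hits(df)
}

validate_hits <- function(df) {
  req <- c("protein_id", "domain_name", "domain_accession",
           "start", "end", "e_value", "bit_score", "significant")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("hit table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(!nzchar(df$protein_id) | is.na(df$protein_id)))
      stop("hit table contains empty protein_id")
    bad <- which(df$start < 1L | df$end < df$start)
    if (length(bad))
      stop("invalid coordinates (need 1 <= start <= end) in hit row(s): ",
           paste(head(bad, 5), collapse = ", "))
    if (any(df$e_value < 0, na.rm = TRUE))
      stop("negative e_value in hit table")
  }
  class(df) <- unique(c("crk_hits", class(df)))
  df
}

#' Read a protein FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of uppercased amino-acid sequences,
#'   names are the identifiers up to the first whitespace; the remainder
#'   of each header is kept in the \code{"descriptions"} attribute.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file does not exist: ", path)
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0) {
    warning("FASTA file contains no records: ", path)
    out <- character(0)
    attr(out, "descriptions") <- character(0)
    return(out)
  }
  full <- names(aa)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA identifier(s): ", paste(unique(dup), collapse = ", "))
  out <- toupper(as.character(aa))
  names(out) <- ids
  attr(out, "descriptions") <- setNames(desc, ids)
  out
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector as returned by [read_fasta()].
#' @param path output file.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  desc <- attr(sequences, "descriptions")
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    hdr <- id
    if (!is.null(desc) && !is.na(desc[id]) && nzchar(desc[id]))
      hdr <- paste(id, desc[id])
    writeLines(paste0(">", hdr), con)
    s <- sequences[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read Pfam-Scan tabular output
#'
#' Parses the whitespace-separated table written by the \code{pfam_scan.pl}
#' wrapper around hmmscan: one row per domain match with alignment and
#' envelope coordinates, HMM accession and name, bit score, E-value and
#' the curated significance flag.  Alignment coordinates (not envelope)
#' become the hit interval.
#'
#' @param path Pfam-Scan output file; lines starting with '#' are skipped.
#' @param aliases alias table for label normalization.
#' @return \code{crk_hits} data.frame.
#' @export
read_pfamscan <- function(path, aliases = default_alias_table()) {
  if (!file.exists(path)) stop("Pfam-Scan file does not exist: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) {
    warning("Pfam-Scan file contains no data rows: ", path)
    return(domain_hits(character(0), character(0), integer(0), integer(0)))
  }
  lineno <- which(keep)
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  ncols <- lengths(rows)
  if (any(ncols < 14))
    stop("line ", lineno[which(ncols < 14)[1]],
         ": expected >= 14 whitespace-separated columns of the Pfam-Scan ",
         "dialect (seq id, aln start/end, env start/end, hmm acc, hmm name, ",
         "type, hmm start/end/length, bit score, E-value, significance)")
  get <- function(i) vapply(rows, `[[`, "", i)
  aln_start <- suppressWarnings(as.integer(get(2)))
  aln_end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(aln_start) | is.na(aln_end))
  if (length(bad))
    stop("line ", lineno[bad[1]], ": non-numeric alignment coordinate")
  domain_hits(
    protein_id = get(1),
    domain_name = normalize_domain(get(7), aliases),
    domain_accession = sub("\\.\\d+$", "", get(6)),
    start = aln_start,
    end = aln_end,
    bit_score = as.numeric(get(12)),
    e_value = as.numeric(get(13)),
    significant = get(14) == "1"
  )
}

#' Read InterProScan TSV output
#'
#' Parses the tab-separated InterProScan table (protein accession, MD5,
#' length, analysis, signature accession/description, start, end, score,
#' status, date, InterPro accession, ...).  The hit's accession field
#' carries the InterPro accession when one is present (else the member
#' database signature accession) so candidate filtering can
#' cross-validate against accepted InterPro entries.
#'
#' @param path InterProScan TSV file.
#' @param aliases alias table for label normalization.
#' @return \code{crk_hits} data.frame.
#' @export
read_interproscan <- function(path, aliases = default_alias_table()) {
  if (!file.exists(path)) stop("InterProScan file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("InterProScan file contains no data rows: ", path)
    return(domain_hits(character(0), character(0), integer(0), integer(0)))
  }
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(rows)
  if (any(ncols < 11))
    stop("line ", which(ncols < 11)[1],
         ": expected >= 11 tab-separated InterProScan columns")
  get <- function(i, default = NA_character_) {
    vapply(rows, function(r) if (length(r) >= i) r[[i]] else default, "")
  }
  start <- suppressWarnings(as.integer(get(7)))
  end <- suppressWarnings(as.integer(get(8)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("line ", bad[1], ": non-numeric coordinate")
  bad <- which(start > end)
  if (length(bad)) stop("line ", bad[1], ": start > end")
  score <- suppressWarnings(as.numeric(get(9)))
  ipr <- get(12)
  sig_acc <- get(5)
  acc <- ifelse(!is.na(ipr) & nzchar(ipr) & ipr != "-", ipr, sig_acc)
  label <- get(6)
  nolabel <- is.na(label) | !nzchar(label) | label == "-"
  label[nolabel] <- sig_acc[nolabel]
  domain_hits(
    protein_id = get(1),
    domain_name = normalize_domain(label, aliases),
    domain_accession = acc,
    start = start,
    end = end,
    e_value = ifelse(is.na(score), 0, score),
    bit_score = 0,
    significant = get(10) %in% c("T", "TRUE", "true")
  )
}

#' Read gene loci from a GFF3 file
#'
#' @param path GFF3 file.
#' @param feature_type feature rows to keep (default \code{"gene"}).
#' @param species species tag stored with every locus.
#' @return data.frame with columns gene_id, chromosome, start, end,
#'   strand (\code{"+"}, \code{"-"} or \code{"unknown"}), species;
#'   coordinates 1-based inclusive as in GFF3, rows in file order.
#' @export
read_gff <- function(path, feature_type = "gene", species = "unknown") {
  if (!file.exists(path)) stop("GFF3 file does not exist: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0)
    return(data.frame(gene_id = character(0), chromosome = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), species = character(0)))
  ids <- as.character(gr$ID)
  bad <- which(is.na(ids) | !nzchar(ids))
  if (length(bad))
    stop("missing ID attribute on '", feature_type, "' feature number ",
         bad[1], " of ", path)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[!strand %in% c("+", "-")] <- "unknown"
  data.frame(
    gene_id = ids,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand,
    species = species,
    stringsAsFactors = FALSE
  )
}

#' Read a two-column chromosome-length table
#'
#' @param path TSV with columns chromosome, length_bp (header optional).
#' @return named numeric vector of chromosome lengths in bp.
#' @export
read_chrom_lengths <- function(path) {
  if (!file.exists(path)) stop("chromosome-length file does not exist: ", path)
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected two tab-separated columns: chromosome, length_bp")
  if (is.character(df[[2]][1]) && is.na(suppressWarnings(as.numeric(df[[2]][1]))))
    df <- df[-1, , drop = FALSE]
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Write and re-read the canonical hit table
#'
#' The internal exchange format is a TSV with header columns protein_id,
#' domain_name, domain_accession, start, end, e_value, bit_score,
#' significant.  Writing and re-reading reproduces the table
#' field-for-field.
#'
#' @param hits \code{crk_hits} data.frame.
#' @param path output TSV.
#' @export
write_hits <- function(hits, path) {
  validate_hits(hits)
  df <- as.data.frame(hits)[, c("protein_id", "domain_name",
                                "domain_accession", "start", "end",
                                "e_value", "bit_score", "significant")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_hits
#' @param check_names if TRUE (default), warn when a domain_name falls
#'   outside the canonical vocabulary.
#' @export
read_hits <- function(path, check_names = TRUE) {
  if (!file.exists(path)) stop("hit table does not exist: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = "NA", colClasses = c(
                     protein_id = "character", domain_name = "character",
                     domain_accession = "character", start = "integer",
                     end = "integer", e_value = "numeric",
                     bit_score = "numeric", significant = "logical"))
  if (check_names && nrow(df)) {
    out <- setdiff(unique(df$domain_name), CANONICAL_DOMAINS)
    if (length(out))
      warning("non-canonical domain name(s) in ", path, ": ",
              paste(out, collapse = ", "))
  }
  validate_hits(df)
}
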