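# Three-way classification of DUF26 architectures:
#   scheme 1 — major class: run-collapsed domain-type signature
#   scheme 2 — subclass: full ordered domain signature (repeats kept)
#   scheme 3 — nomenclature: sd/dd/td/qd CRRSP / CRK / CRdK grammar name

KINASE_SET <- c("Pkinase-tyr", "Pkinase")
FUNGAL_KINASE <- "Pkinase_fungal"
# Signal peptides and transmembrane segments define the literature
# CRK/CRRSP/PDLP split but play no part in any of the three schemes.
TOPOLOGY_LABELS <- c("SignalPeptide", "Transmembrane")

#' Nomenclature grammar for scheme-3 class names
#'
#' Names are built as \code{prefix + core + suffixes}: the prefix
#' encodes the DUF26 repeat count (sd/dd/td/qd for 1-4, a numeric
#' \code{"<n>d"} beyond), the core is \code{CRRSP} (no kinase),
#' \code{CRK} (canonical kinase present) or \code{CRdK} (canonical plus
#' fungal-type kinase), and each decoy domain contributes one suffix
#' letter in N-to-C order of first occurrence; a doubled sugar
#' transporter contributes \code{dS}.
#'
#' @param prefixes named character vector, repeat count -> prefix.
#' @param kinase_set canonical kinase labels.
#' @param fungal_kinase fungal-type kinase label.
#' @param decoy_suffixes named character vector, decoy label -> suffix
#'   letter.
#' @return list of class \code{crk_grammar}.
#' @export
#' @examples
#' g <- nomenclature_grammar()
#' classify_nomenclature(toy_architecture(
#'   c("Stress-antifungal", "Stress-antifungal", "Pkinase-tyr")), g)
nomenclature_grammar <- function(prefixes = c("1" = "sd", "2" = "dd",
                                              "3" = "td", "4" = "qd"),
                                 kinase_set = KINASE_SET,
                                 fungal_kinase = FUNGAL_KINASE,
                                 decoy_suffixes = c(DUF3403 = "D",
                                                    FYVE = "F",
                                                    PRIMA1 = "P",
                                                    SugarTransporter = "S")) {
  if (anyDuplicated(prefixes) || anyDuplicated(decoy_suffixes))
    stop("prefix and suffix maps must be injective")
  structure(list(prefixes = prefixes, kinase_set = kinase_set,
                 fungal_kinase = fungal_kinase,
                 decoy_suffixes = decoy_suffixes),
            class = "crk_grammar")
}

# Labels entering the three schemes: topology labels are dropped.
scheme_labels <- function(arch) {
  lab <- architecture_labels(arch)
  lab <- lab[!lab %in% TOPOLOGY_LABELS]
  if (!"Stress-antifungal" %in% lab)
    stop("protein ", arch$protein_id,
         " has no Stress-antifungal domain and is not a CRK candidate")
  lab
}

#' Scheme 1: major-class signature
#'
#' Collapses each run of consecutive identical labels to a single
#' occurrence and joins with an en dash.  Non-consecutive repeats are
#' retained, so alternating patterns such as
#' \code{Stress-antifungal–Pkinase-tyr–Stress-antifungal–Pkinase-tyr}
#' stay distinct from \code{Stress-antifungal–Pkinase-tyr}.
#'
#' @param arch \code{crk_architecture} with >= 1 Stress-antifungal
#'   element.
#' @return major-class signature string.
#' @export
classify_major <- function(arch) {
  lab <- scheme_labels(arch)
  paste(rle(lab)$values, collapse = "\u2013")
}

#' Scheme 2: subclass signature
#'
#' The full ordered label sequence with all repeats retained, joined
#' with \code{"__"}.  Scheme 2 refines scheme 1: equal subclass
#' signatures imply equal major signatures.
#'
#' @inheritParams classify_major
#' @return subclass signature string.
#' @export
classify_subclass <- function(arch) {
  paste(scheme_labels(arch), collapse = "__")
}

# Decoy labels of an architecture in N->C order of first occurrence,
# with per-decoy counts.
decoy_summary <- function(lab, grammar) {
  decoy <- lab[!lab %in% c("Stress-antifungal", grammar$kinase_set,
                           grammar$fungal_kinase)]
  first <- unique(decoy)
  counts <- vapply(first, function(d) sum(decoy == d), integer(1))
  list(order = first, counts = counts)
}

#' Scheme 3: nomenclature grammar name
#'
#' @inheritParams classify_major
#' @param grammar [nomenclature_grammar()].
#' @return class name, e.g. \code{"ddCRKF"}.  DUF26 repeat counts
#'   beyond the named prefixes yield an explicit numeric prefix
#'   (\code{"5d"}, \code{"6d"}, ...) with attribute
#'   \code{extended_prefix = TRUE} rather than an error.
#' @export
classify_nomenclature <- function(arch, grammar = nomenclature_grammar()) {
  lab <- scheme_labels(arch)
  n_duf <- sum(lab == "Stress-antifungal")
  extended <- !as.character(n_duf) %in% names(grammar$prefixes)
  prefix <- if (extended) paste0(n_duf, "d")
            else grammar$prefixes[[as.character(n_duf)]]
  has_kinase <- any(lab %in% grammar$kinase_set)
  has_fungal <- any(lab == grammar$fungal_kinase)
  core <- if (has_kinase && has_fungal) "CRdK"
          else if (has_kinase) "CRK"
          else "CRRSP"
  dec <- decoy_summary(lab, grammar)
  suffix <- ""
  for (d in dec$order) {
    if (!d %in% names(grammar$decoy_suffixes)) next  # unmapped decoy: no letter
    letter <- grammar$decoy_suffixes[[d]]
    suffix <- paste0(suffix,
                     if (d == "SugarTransporter" && dec$counts[[d]] >= 2)
                       paste0("d", letter) else letter)
  }
  out <- paste0(prefix, core, suffix)
  if (extended) attr(out, "extended_prefix") <- TRUE
  out
}

#' Parse a nomenclature name back into its parts
#'
#' Inverse of [classify_nomenclature()] on its image:
#' \code{parse_nomenclature(classify_nomenclature(a))} recovers the
#' DUF26 repeat count, the core kind and the suffix tokens of \code{a}.
#'
#' @param name class name string.
#' @param grammar [nomenclature_grammar()].
#' @return list with \code{duf26_count}, \code{core} (one of CRRSP,
#'   CRK, CRdK) and \code{suffixes} (character vector of suffix tokens,
#'   \code{"dS"} kept as one token).
#' @export
parse_nomenclature <- function(name, grammar = nomenclature_grammar()) {
  stopifnot(is.character(name), length(name) == 1L)
  rest <- name
  # prefix: named (sd/dd/td/qd) or numeric <n>d
  pre_names <- grammar$prefixes
  hit <- which(vapply(pre_names, function(p) startsWith(rest, p), TRUE))
  if (length(hit)) {
    count <- as.integer(names(pre_names)[hit[1]])
    rest <- substring(rest, nchar(pre_names[hit[1]]) + 1L)
  } else if (grepl("^\\d+d", rest)) {
    count <- as.integer(sub("^(\\d+)d.*$", "\\1", rest))
    rest <- sub("^\\d+d", "", rest)
  } else {
    stop("cannot parse nomenclature name '", name,
         "': no valid prefix (longest valid prefix: '')")
  }
  core <- NULL
  for (c0 in c("CRRSP", "CRdK", "CRK")) {   # longest/most specific first
    if (startsWith(rest, c0)) { core <- c0; rest <- substring(rest, nchar(c0) + 1L); break }
  }
  if (is.null(core))
    stop("cannot parse nomenclature name '", name,
         "': no core after prefix (longest valid prefix: '",
         substring(name, 1, nchar(name) - nchar(rest)), "')")
  suffixes <- character(0)
  while (nzchar(rest)) {
    if (startsWith(rest, "d")) {
      tok <- substring(rest, 1, 2)
      if (nchar(rest) < 2 || !substring(rest, 2, 2) %in% grammar$decoy_suffixes)
        stop("cannot parse nomenclature name '", name,
             "': bad suffix (longest valid prefix: '",
             substring(name, 1, nchar(name) - nchar(rest)), "')")
    } else {
      tok <- substring(rest, 1, 1)
      if (!tok %in% grammar$decoy_suffixes)
        stop("cannot parse nomenclature name '", name,
             "': bad suffix (longest valid prefix: '",
             substring(name, 1, nchar(name) - nchar(rest)), "')")
    }
    suffixes <- c(suffixes, tok)
    rest <- substring(rest, nchar(tok) + 1L)
  }
  list(duf26_count = count, core = core, suffixes = suffixes)
}

#' Assign all three class labels to a set of architectures
#'
#' @param architectures list of \code{crk_architecture}.
#' @param grammar [nomenclature_grammar()].
#' @param species optional character vector (recycled) tagging each
#'   architecture's species.
#' @return data.frame of class \code{crk_assignments} with one row per
#'   architecture: protein_id, species, major_class_id (integers in
#'   first-appearance order of distinct major signatures, stable for a
#'   fixed input order), major_signature, subclass_signature,
#'   nomenclature, duf26_count, has_kinase, decoys (semicolon-joined,
#'   N-to-C first occurrence, each as \code{label@Nterm} or
#'   \code{label@Cterm} relative to the first DUF26).
#' @export
assign_all <- function(architectures, grammar = nomenclature_grammar(),
                       species = "unknown") {
  if (!length(architectures))
    return(structure(data.frame(protein_id = character(0),
                                species = character(0),
                                major_class_id = integer(0),
                                major_signature = character(0),
                                subclass_signature = character(0),
                                nomenclature = character(0),
                                duf26_count = integer(0),
                                has_kinase = logical(0),
                                decoys = character(0),
                                stringsAsFactors = FALSE),
                     class = c("crk_assignments", "data.frame")))
  species <- rep_len(species, length(architectures))
  rows <- mapply(function(a, sp) {
    lab <- tryCatch(scheme_labels(a), error = function(e)
      stop("protein ", a$protein_id, ": ", conditionMessage(e), call. = FALSE))
    dec <- decoy_summary(lab, grammar)
    first_duf <- match("Stress-antifungal", lab)
    side <- vapply(dec$order, function(d)
      if (match(d, lab) < first_duf) "Nterm" else "Cterm", "")
    data.frame(
      protein_id = a$protein_id,
      species = sp,
      major_signature = classify_major(a),
      subclass_signature = classify_subclass(a),
      nomenclature = as.character(classify_nomenclature(a, grammar)),
      duf26_count = sum(lab == "Stress-antifungal"),
      has_kinase = any(lab %in% grammar$kinase_set),
      decoys = paste(sprintf("%s@%s", dec$order, side), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }, architectures, species, SIMPLIFY = FALSE)
  df <- do.call(rbind, rows)
  df$major_class_id <- match(df$major_signature, unique(df$major_signature))
  df <- df[, c("protein_id", "species", "major_class_id", "major_signature",
               "subclass_signature", "nomenclature", "duf26_count",
               "has_kinase", "decoys")]
  rownames(df) <- NULL
  class(df) <- c("crk_assignments", "data.frame")
  df
}

#' Write an assignment table
#' @param assignments \code{crk_assignments}.
#' @param path output TSV.
#' @export
write_assignments <- function(assignments, path) {
  write.table(as.data.frame(assignments), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Build a toy architecture from a label vector
#'
#' Lays the given domains left to right with plausible domain lengths
#' (DUF26 ~100 aa, kinases ~270 aa, others ~80 aa) and 20-residue
#' linkers, producing valid non-overlapping coordinates.  Used by the
#' worked examples, the class-catalog constructors and the tests.
#'
#' @param labels character vector of canonical domain labels, N to C.
#' @param protein_id identifier for the toy protein.
#' @return \code{crk_architecture}.
#' @export
toy_architecture <- function(labels, protein_id = "toy") {
  len <- ifelse(labels == "Stress-antifungal", 100L,
         ifelse(labels %in% c(KINASE_SET, FUNGAL_KINASE), 270L, 80L))
  start <- integer(length(labels))
  pos <- 21L
  for (i in seq_along(labels)) {
    start[i] <- pos
    pos <- pos + len[i] + 20L
  }
  hits <- domain_hits(protein_id, labels, start, start + len - 1L,
                      e_value = 1e-20, bit_score = 100)
  build_architecture(hits)
}

#' Catalog of major-class architecture definitions
#'
#' The eleven distinct domain architectures that define the major
#' classes of the cotton CRK family, as label vectors.  Feeding one
#' toy protein per entry through scheme 1 yields eleven distinct major
#' signatures.
#'
#' @return named list of label vectors (names Class_I ... Class_XI).
#' @export
major_class_catalog <- function() {
  S <- "Stress-antifungal"; K <- "Pkinase-tyr"
  list(
    Class_I    = c("ALMT", "FUSC_2", "FUSC", S),
    Class_II   = c("Cript", S, K),
    Class_III  = c(K, S, K),
    Class_IV   = S,
    Class_V    = c(S, "DUF3403"),
    Class_VI   = c(S, K),
    Class_VII  = c(S, K, "DUF3403"),
    Class_VIII = c(S, K, "FYVE"),
    Class_IX   = c(S, K, "Pkinase_fungal"),
    Class_X    = c(S, K, S, K),
    Class_XI   = c(S, K, "TauE")
  )
}

#' Catalog of land-plant nomenclature class definitions
#'
#' The nineteen land-plant CRK/CRRSP classes of the sd/dd/td/qd
#' nomenclature, each instantiated as a representative label vector.
#' The list is named by the class name the grammar must generate for
#' it.
#'
#' @return named list of label vectors.
#' @export
nomenclature_class_catalog <- function() {
  S <- "Stress-antifungal"; K <- "Pkinase-tyr"; Fk <- "Pkinase_fungal"
  list(
    sdCRRSP   = S,
    sdCRRSPD  = c("DUF3403", S),
    sdCRRSPdS = c("SugarTransporter", "SugarTransporter", S),
    ddCRRSP   = c(S, S),
    ddCRRSPD  = c("DUF3403", S, S),
    ddCRRSPP  = c("PRIMA1", S, S),
    tdCRRSP   = c(S, S, S),
    sdCRK     = c(S, K),
    sdCRKD    = c("DUF3403", S, K),
    ddCRK     = c(S, S, K),
    ddCRKD    = c(S, S, K, "DUF3403"),
    ddCRKF    = c("FYVE", S, S, K),
    ddCRKP    = c("PRIMA1", S, S, K),
    ddCRKS    = c("SugarTransporter", S, S, K),
    ddCRdK    = c(S, S, K, Fk),
    tdCRK     = c(S, S, S, K),
    tdCRdK    = c(S, S, S, K, Fk),
    qdCRK     = c(S, S, S, S, K),
    qdCRKD    = c(S, S, S, S, K, "DUF3403")
  )
}
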