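# Candidate filtering and overlap resolution: raw scan hits in, one
# clean ordered architecture per protein out.

#' Candidate filter policy
#'
#' Controls which proteins are admitted as CRK candidates.  A protein
#' qualifies when it carries at least one Stress-antifungal (DUF26) hit
#' passing the evidence rule: the scanner's curated significance flag
#' when present and required, otherwise an E-value ceiling.  When
#' InterPro evidence is supplied, candidates can additionally be
#' required to carry an accepted InterPro accession (the DUF26 entries
#' IPR002902 and its superfamily IPR038408 by default).
#'
#' @param e_value_max E-value ceiling for hits lacking a significance
#'   flag (default 1e-3).
#' @param require_significant use the scanner flag when present
#'   (default TRUE).
#' @param interpro_accessions accepted InterPro accessions.
#' @param interpro_mode \code{"off"} (ignore InterPro evidence),
#'   \code{"either"} (any accepted accession suffices, the default) or
#'   \code{"both"} (every accepted accession must be seen on the
#'   protein).
#' @return list of class \code{crk_filter_policy}.
#' @export
filter_policy <- function(e_value_max = 1e-3,
                          require_significant = TRUE,
                          interpro_accessions = c("IPR038408", "IPR002902"),
                          interpro_mode = c("either", "off", "both")) {
  interpro_mode <- match.arg(interpro_mode)
  stopifnot(is.numeric(e_value_max), e_value_max > 0)
  structure(list(e_value_max = e_value_max,
                 require_significant = isTRUE(require_significant),
                 interpro_accessions = interpro_accessions,
                 interpro_mode = interpro_mode),
            class = "crk_filter_policy")
}

hit_passes <- function(hits, policy) {
  if (!nrow(hits)) return(logical(0))
  by_flag <- policy$require_significant & !is.na(hits$significant)
  pass <- logical(nrow(hits))
  pass[by_flag] <- hits$significant[by_flag]
  pass[!by_flag] <- hits$e_value[!by_flag] <= policy$e_value_max
  pass
}

#' Identify CRK candidate proteins
#'
#' A protein is a candidate iff it carries at least one
#' Stress-antifungal hit passing the policy.  When
#' \code{interpro_mode != "off"} and any hit in the table carries an
#' InterPro-style accession, candidates must additionally match the
#' accepted accessions (either/both per mode).
#'
#' @param hits \code{crk_hits} table, labels already normalized.
#' @param policy [filter_policy()].
#' @return sorted character vector of candidate protein ids.
#' @export
filter_crk_candidates <- function(hits, policy = filter_policy()) {
  validate_hits(hits)
  if (!nrow(hits)) return(character(0))
  pass <- hit_passes(hits, policy)
  duf <- hits$domain_name == "Stress-antifungal" & pass
  cand <- unique(hits$protein_id[duf])
  if (policy$interpro_mode != "off") {
    is_ipr <- grepl("^IPR\\d+$", hits$domain_accession)
    if (any(is_ipr)) {
      ipr <- hits[is_ipr & hits$domain_accession %in% policy$interpro_accessions, ]
      keep <- if (policy$interpro_mode == "either") {
        unique(ipr$protein_id)
      } else {
        tab <- unique(ipr[, c("protein_id", "domain_accession")])
        n_acc <- table(tab$protein_id)
        names(n_acc)[n_acc == length(policy$interpro_accessions)]
      }
      cand <- intersect(cand, keep)
    }
  }
  sort(cand)
}

# Total priority order used everywhere a conflict must be broken:
# higher bit score, then lower E-value, then leftmost start, then
# lexicographic domain name.  Returns a permutation of row indices.
hit_priority_order <- function(hits) {
  order(-hits$bit_score, hits$e_value, hits$start,
        hits$domain_name, method = "radix")
}

#' Resolve overlapping domain hits on one protein
#'
#' Scanner output routinely contains the same region matched twice
#' (overlapping database entries, repeated models).  Among any group of
#' hits in conflict — reciprocal overlap exceeding
#' \code{overlap_fraction} of the longer hit — exactly the best hit
#' survives (highest bit score, ties by lowest E-value, then leftmost
#' start, then domain name).  Residual boundary overlaps at or below
#' the fraction are trimmed from the lower-priority hit so the output
#' is strictly non-overlapping and sorted by start; the operation is
#' idempotent.
#'
#' @param hits \code{crk_hits} rows for a single protein.
#' @param overlap_fraction reciprocal-overlap fraction above which two
#'   hits conflict (default 0.3).
#' @return non-overlapping \code{crk_hits}, sorted by start.
#' @export
resolve_overlaps <- function(hits, overlap_fraction = 0.3) {
  validate_hits(hits)
  if (nrow(hits) <= 1) return(hits[order(hits$start), , drop = FALSE])
  if (length(unique(hits$protein_id)) != 1L)
    stop("resolve_overlaps expects hits of a single protein; got: ",
         paste(unique(hits$protein_id), collapse = ", "))
  ord <- hit_priority_order(hits)
  w <- hits$end - hits$start + 1L
  kept <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (j in kept) {
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]) + 1L
      if (ov > overlap_fraction * max(w[i], w[j])) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) kept <- c(kept, i)
  }
  out <- hits[kept, , drop = FALSE]
  out$.prio <- seq_along(kept)                # kept is in best-first order
  # trim residual sub-threshold boundary overlaps: of an overlapping
  # adjacent pair the lower-priority hit yields; a hit fully eaten by
  # the trim is dropped
  repeat {
    out <- out[order(out$start, out$end), , drop = FALSE]
    changed <- FALSE
    k <- 1L
    while (k < nrow(out)) {
      if (out$end[k] >= out$start[k + 1]) {
        changed <- TRUE
        if (out$.prio[k] < out$.prio[k + 1]) {      # right hit yields
          out$start[k + 1] <- out$end[k] + 1L
          if (out$start[k + 1] > out$end[k + 1]) out <- out[-(k + 1), , drop = FALSE]
        } else {                                    # left hit yields
          out$end[k] <- out$start[k + 1] - 1L
          if (out$start[k] > out$end[k]) out <- out[-k, , drop = FALSE]
        }
      } else k <- k + 1L
    }
    if (!changed) break
  }
  out$.prio <- NULL
  rownames(out) <- NULL
  validate_hits(out)
}

#' Merge fragmented hits of one domain
#'
#' HMM scanners sometimes split a single long domain into two adjacent
#' partial matches.  Consecutive non-overlapping hits of the same
#' domain separated by at most \code{max_gap} residues are merged into
#' one hit spanning both, keeping the better bit score and the smaller
#' E-value.  \code{max_gap = 0} disables merging.
#'
#' @param hits non-overlapping, start-sorted \code{crk_hits} for one
#'   protein.
#' @param max_gap maximum residue gap to bridge (default 30).
#' @return \code{crk_hits} with fragments merged.
#' @export
merge_fragmented <- function(hits, max_gap = 30L) {
  validate_hits(hits)
  if (nrow(hits) <= 1 || max_gap <= 0) return(hits)
  hits <- hits[order(hits$start), , drop = FALSE]
  out <- hits[1, , drop = FALSE]
  for (i in 2:nrow(hits)) {
    last <- nrow(out)
    gap <- hits$start[i] - out$end[last] - 1L
    if (hits$domain_name[i] == out$domain_name[last] && gap <= max_gap) {
      out$end[last] <- max(out$end[last], hits$end[i])
      out$bit_score[last] <- max(out$bit_score[last], hits$bit_score[i])
      out$e_value[last] <- min(out$e_value[last], hits$e_value[i])
      out$significant[last] <- out$significant[last] | hits$significant[i]
    } else {
      out <- rbind(out, hits[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  validate_hits(out)
}

#' Build the ordered domain architecture of one protein
#'
#' @param hits overlap-resolved \code{crk_hits} for one protein.
#' @param protein_length optional residue count from the FASTA; when
#'   given, a hit extending beyond it is an error.
#' @return object of class \code{crk_architecture}: list with
#'   \code{protein_id}, \code{elements} (data.frame domain_name, start,
#'   end sorted by start) and \code{protein_length}.
#' @export
build_architecture <- function(hits, protein_length = NA_integer_) {
  validate_hits(hits)
  if (!nrow(hits)) stop("cannot build an architecture from zero hits")
  pid <- unique(hits$protein_id)
  if (length(pid) != 1L)
    stop("build_architecture expects hits of a single protein; got: ",
         paste(pid, collapse = ", "))
  if (!is.na(protein_length) && any(hits$end > protein_length))
    stop("hit extends beyond declared length of protein ", pid)
  el <- hits[order(hits$start), c("domain_name", "start", "end")]
  if (any(el$end[-nrow(el)] >= el$start[-1]))
    stop("hits of protein ", pid, " overlap; run resolve_overlaps() first")
  rownames(el) <- NULL
  structure(list(protein_id = pid, elements = el,
                 protein_length = as.integer(protein_length)),
            class = "crk_architecture")
}

#' @export
print.crk_architecture <- function(x, ...) {
  cat("<crk_architecture> ", x$protein_id, ": ",
      paste(x$elements$domain_name, collapse = "__"), "\n", sep = "")
  invisible(x)
}

#' Architecture labels, N-terminal to C-terminal
#' @param arch \code{crk_architecture}.
#' @return character vector of domain labels.
#' @export
architecture_labels <- function(arch) {
  stopifnot(inherits(arch, "crk_architecture"))
  arch$elements$domain_name
}

#' Full hits-to-architectures pass over a hit table
#'
#' Convenience wrapper: splits the table by protein, resolves overlaps,
#' optionally merges fragments, and builds one architecture per
#' candidate protein.
#'
#' @param hits \code{crk_hits} for any number of proteins.
#' @param proteins protein ids to process (default: all in the table).
#' @param lengths optional named vector of protein lengths.
#' @param overlap_fraction passed to [resolve_overlaps()].
#' @param max_gap passed to [merge_fragmented()].  Disabled (0) by
#'   default: with alignment coordinates alone a split HMM fragment is
#'   indistinguishable from a genuine tandem repeat, and DUF26 repeat
#'   counts are exactly what the subclass and nomenclature schemes
#'   measure, so bridging gaps is an explicit opt-in.
#' @param policy optional [filter_policy()]; when given, hits failing
#'   the evidence rule are removed before architecture building.
#' @return named list of \code{crk_architecture}, ordered by protein id.
#' @export
build_architectures <- function(hits, proteins = NULL, lengths = NULL,
                                overlap_fraction = 0.3, max_gap = 0L,
                                policy = NULL) {
  validate_hits(hits)
  if (!is.null(policy)) hits <- hits[hit_passes(hits, policy), , drop = FALSE]
  if (is.null(proteins)) proteins <- sort(unique(hits$protein_id))
  out <- lapply(proteins, function(p) {
    h <- hits[hits$protein_id == p, , drop = FALSE]
    if (!nrow(h)) return(NULL)
    h <- resolve_overlaps(h, overlap_fraction)
    h <- merge_fragmented(h, max_gap)
    len <- if (!is.null(lengths) && p %in% names(lengths))
      lengths[[p]] else NA_integer_
    build_architecture(h, len)
  })
  names(out) <- proteins
  out[!vapply(out, is.null, TRUE)]
}

#' Write an architecture table
#'
#' @param archs list of \code{crk_architecture}.
#' @param path output TSV with columns protein_id, architecture
#'   (labels joined with \code{"__"}) and elements
#'   (\code{name:start-end} joined with \code{";"}).
#' @export
write_architectures <- function(archs, path) {
  df <- data.frame(
    protein_id = vapply(archs, `[[`, "", "protein_id"),
    architecture = vapply(archs, function(a)
      paste(a$elements$domain_name, collapse = "__"), ""),
    elements = vapply(archs, function(a)
      paste(sprintf("%s:%d-%d", a$elements$domain_name,
                    a$elements$start, a$elements$end), collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
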