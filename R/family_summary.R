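# Cross-species aggregation: class-by-species count matrix, shared and
# species-specific classes, and the derived percentage arithmetic.

#' Class-by-species family summary
#'
#' Builds the count matrix of one classification scheme against
#' species, plus per-class totals, per-species totals, the grand total,
#' and the presence patterns: classes found in every species (shared)
#' and classes found in exactly one (species-specific).  Classes are
#' ordered by descending grand total, ties broken lexicographically, so
#' "largest class" reporting is deterministic.
#'
#' @param assignments \code{crk_assignments} with species tags.
#' @param scheme \code{"major"}, \code{"subclass"} or
#'   \code{"nomenclature"}.
#' @return list of class \code{crk_family_summary}: \code{counts}
#'   (matrix class x species), \code{class_totals},
#'   \code{species_totals}, \code{grand_total}, \code{shared_classes},
#'   \code{species_specific} (named by species), \code{scheme}.
#' @export
summarize_family <- function(assignments,
                             scheme = c("major", "subclass", "nomenclature")) {
  scheme <- match.arg(scheme)
  col <- switch(scheme, major = "major_signature",
                subclass = "subclass_signature",
                nomenclature = "nomenclature")
  if (!nrow(assignments)) {
    out <- list(counts = matrix(integer(0), 0, 0), class_totals = integer(0),
                species_totals = integer(0), grand_total = 0L,
                shared_classes = character(0), species_specific = character(0),
                scheme = scheme)
    class(out) <- "crk_family_summary"
    return(out)
  }
  if (any(is.na(assignments$species) | !nzchar(assignments$species)))
    stop("missing species tag for protein(s): ",
         paste(assignments$protein_id[is.na(assignments$species) |
                                        !nzchar(assignments$species)],
               collapse = ", "))
  counts <- table(class = assignments[[col]], species = assignments$species)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  totals <- rowSums(counts)
  ord <- order(-totals, rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  totals <- totals[ord]
  present <- counts > 0
  shared <- rownames(counts)[rowSums(present) == ncol(counts)]
  specific_idx <- which(rowSums(present) == 1)
  species_specific <- setNames(
    vapply(specific_idx, function(i) colnames(counts)[which(present[i, ])], ""),
    rownames(counts)[specific_idx])
  out <- list(counts = counts,
              class_totals = totals,
              species_totals = colSums(counts),
              grand_total = sum(counts),
              shared_classes = shared,
              species_specific = species_specific,
              scheme = scheme)
  class(out) <- "crk_family_summary"
  out
}

#' @export
print.crk_family_summary <- function(x, ...) {
  cat("<crk_family_summary> scheme:", x$scheme,
      "|", nrow(x$counts), "classes x", ncol(x$counts), "species |",
      "grand total", x$grand_total, "\n")
  invisible(x)
}

#' Largest class of a family summary
#'
#' @param summary \code{crk_family_summary}.
#' @return list with \code{class}, \code{total} and \code{tie} (TRUE
#'   when another class reaches the same total; the lexicographically
#'   first is returned).
#' @export
largest_class_total <- function(summary) {
  stopifnot(inherits(summary, "crk_family_summary"))
  if (!length(summary$class_totals)) stop("summary is empty")
  top <- max(summary$class_totals)
  at_top <- sort(names(summary$class_totals)[summary$class_totals == top])
  list(class = at_top[1], total = unname(top), tie = length(at_top) > 1)
}

# round-half-up at one decimal (base round() is round-half-even)
round_half_up1 <- function(x) floor(x * 10 + 0.5) / 10

#' Percentage of genes assigned to orthogroups
#'
#' \code{100 * (total - unassigned) / total}, rounded half-up to one
#' decimal — the convention of gene-family survey reporting.
#'
#' @param total_genes total gene count (> 0).
#' @param unassigned genes left out of any orthogroup.
#' @return percentage with one decimal.
#' @export
#' @examples
#' assignment_percentage(437, 21)  # 95.2
assignment_percentage <- function(total_genes, unassigned) {
  stopifnot(length(total_genes) == 1, length(unassigned) == 1)
  if (total_genes <= 0) stop("total_genes must be positive")
  if (unassigned < 0 || unassigned > total_genes)
    stop("unassigned must lie in [0, total_genes]")
  round_half_up1(100 * (total_genes - unassigned) / total_genes)
}

#' Write a family summary
#'
#' @param summary \code{crk_family_summary}.
#' @param path wide-format TSV (class, one column per species, total);
#'   a long format (class, species, count) goes to
#'   \code{<path>.long.tsv}.
#' @export
write_family_summary <- function(summary, path) {
  wide <- data.frame(class = rownames(summary$counts),
                     summary$counts,
                     total = summary$class_totals,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  long <- as.data.frame(as.table(summary$counts), stringsAsFactors = FALSE)
  names(long) <- c("class", "species", "count")
  write.table(long, paste0(path, ".long.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
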