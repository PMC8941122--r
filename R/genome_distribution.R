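# Chromosome-level organisation of the family: per-chromosome counts,
# tandem clusters, terminal-arm localisation.

#' Tandem-cluster and terminal-arm policy
#'
#' Two consecutive family members on one chromosome join a cluster when
#' the gap between their nearest boundaries is at most \code{max_gap_bp}
#' and (when the full gene set is supplied) at most
#' \code{max_intervening} non-family genes lie between them; clusters
#' are the transitive closure of that relation.  A gene is "terminal"
#' when its midpoint falls within \code{arm_fraction} of the chromosome
#' length from either end.
#'
#' @param max_gap_bp maximum boundary-to-boundary gap in bp
#'   (default 250 kb, the conventional tandem-array criterion in plant
#'   gene-family surveys).
#' @param max_intervening maximum number of intervening non-family
#'   genes; -1 disables the criterion (default 8).
#' @param arm_fraction fraction of the chromosome length defining each
#'   terminal arm (default 0.25); must lie in (0, 0.5).
#' @return list of class \code{crk_cluster_policy}.
#' @export
cluster_policy <- function(max_gap_bp = 250000, max_intervening = 8L,
                           arm_fraction = 0.25) {
  stopifnot(max_gap_bp > 0, arm_fraction > 0, arm_fraction < 0.5)
  structure(list(max_gap_bp = max_gap_bp,
                 max_intervening = as.integer(max_intervening),
                 arm_fraction = arm_fraction),
            class = "crk_cluster_policy")
}

#' Per-chromosome gene counts
#'
#' @param loci GeneLocus data.frame (gene_id, chromosome, start, end,
#'   strand, species).
#' @param unplaced_patterns regular expressions identifying unplaced
#'   scaffolds, grouped under \code{"unplaced"}.
#' @return data.frame (species, chromosome, count), sorted by species
#'   then descending count.
#' @export
chromosome_counts <- function(loci,
                              unplaced_patterns = c("^scaffold", "^contig",
                                                    "^tig", "^utg", "^Un")) {
  if (!nrow(loci))
    return(data.frame(species = character(0), chromosome = character(0),
                      count = integer(0)))
  chrom <- loci$chromosome
  unplaced <- Reduce(`|`, lapply(unplaced_patterns, grepl, x = chrom,
                                 ignore.case = TRUE))
  chrom[unplaced] <- "unplaced"
  tab <- as.data.frame(table(species = loci$species, chromosome = chrom),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab <- tab[tab$count > 0, ]
  tab <- tab[order(tab$species, -tab$count, tab$chromosome), ]
  rownames(tab) <- NULL
  tab$count <- as.integer(tab$count)
  tab
}

#' Detect tandem clusters of family genes
#'
#' @param family_loci GeneLocus rows of the family members.
#' @param all_loci optional GeneLocus rows of every gene (same species),
#'   enabling the intervening-gene criterion; must contain all family
#'   genes.
#' @param policy [cluster_policy()].
#' @return data.frame of class \code{crk_clusters}: chromosome,
#'   span_start, span_end, member_count, members (semicolon-joined,
#'   sorted by start).  Singletons are not reported.
#' @export
detect_tandem_clusters <- function(family_loci, all_loci = NULL,
                                   policy = cluster_policy()) {
  empty <- data.frame(chromosome = character(0), span_start = numeric(0),
                      span_end = numeric(0), member_count = integer(0),
                      members = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("crk_clusters", "data.frame")
  if (!nrow(family_loci)) return(empty)
  if (!is.null(all_loci)) {
    absent <- setdiff(family_loci$gene_id, all_loci$gene_id)
    if (length(absent))
      stop("all_loci is missing family gene(s): ",
           paste(absent, collapse = ", "))
  }
  out <- list()
  for (chr in unique(family_loci$chromosome)) {
    fam <- family_loci[family_loci$chromosome == chr, , drop = FALSE]
    fam <- fam[order(fam$start, fam$end), , drop = FALSE]
    if (nrow(fam) < 2) next
    linked <- logical(nrow(fam) - 1)
    for (i in seq_len(nrow(fam) - 1)) {
      gap <- fam$start[i + 1] - fam$end[i] - 1
      ok <- gap <= policy$max_gap_bp
      if (ok && !is.null(all_loci) && policy$max_intervening >= 0) {
        between <- all_loci$chromosome == chr &
          all_loci$start > fam$end[i] &
          all_loci$end < fam$start[i + 1] &
          !all_loci$gene_id %in% fam$gene_id
        ok <- sum(between) <= policy$max_intervening
      }
      linked[i] <- ok
    }
    grp <- cumsum(c(TRUE, !linked))
    for (g in unique(grp)) {
      memb <- fam[grp == g, , drop = FALSE]
      if (nrow(memb) < 2) next
      out[[length(out) + 1]] <- data.frame(
        chromosome = chr,
        span_start = min(memb$start),
        span_end = max(memb$end),
        member_count = nrow(memb),
        members = paste(memb$gene_id, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chromosome, res$span_start), ]
  rownames(res) <- NULL
  class(res) <- c("crk_clusters", "data.frame")
  res
}

#' Fraction of family genes on the terminal chromosome arms
#'
#' @param family_loci GeneLocus rows of the family members.
#' @param chromosome_lengths named vector of chromosome lengths in bp;
#'   every chromosome carrying a locus must be present.
#' @param policy [cluster_policy()]; only \code{arm_fraction} is used.
#' @return list with \code{fraction} (terminal genes / all genes),
#'   \code{terminal_count}, \code{total_count} and
#'   \code{per_chromosome} breakdown.
#' @export
terminal_arm_fraction <- function(family_loci, chromosome_lengths,
                                  policy = cluster_policy()) {
  if (!nrow(family_loci))
    return(list(fraction = NA_real_, terminal_count = 0L, total_count = 0L,
                per_chromosome = data.frame()))
  missing_chr <- setdiff(unique(family_loci$chromosome),
                         names(chromosome_lengths))
  if (length(missing_chr))
    stop("no length known for chromosome(s): ",
         paste(missing_chr, collapse = ", "))
  len <- chromosome_lengths[family_loci$chromosome]
  mid <- (family_loci$start + family_loci$end) / 2
  arm <- policy$arm_fraction * len
  terminal <- mid <= arm | mid >= len - arm
  per <- aggregate(list(terminal = terminal),
                   by = list(chromosome = family_loci$chromosome),
                   FUN = sum)
  per$total <- as.vector(table(family_loci$chromosome)[per$chromosome])
  list(fraction = mean(terminal),
       terminal_count = sum(terminal),
       total_count = length(terminal),
       per_chromosome = per)
}

#' Write cluster and density tables
#' @param clusters \code{crk_clusters}.
#' @param counts result of [chromosome_counts()].
#' @param dir output directory.
#' @export
write_distribution <- function(clusters, counts, dir) {
  write.table(as.data.frame(clusters), file.path(dir, "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(counts, file.path(dir, "chromosome_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
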