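# Per-protein physicochemical statistics: length, average molecular
# weight, net charge at a given pH, isoelectric point, GRAVY.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
WATER_MASS <- 18.02  # Da, average

read_constant_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  setNames(df[[2]], df[[1]])
}

#' Physicochemical constant tables
#'
#' Loads the residue constants the statistics are computed from: free
#' amino-acid average masses (Da; the peptide-bond water loss is
#' applied at summation time), the Kyte-Doolittle hydropathy scale, and
#' an EMBOSS-style pKa set (terminal groups plus the side chains of C,
#' D, E, H, K, R, Y).  All three ship as editable two-column TSV files
#' under \code{inst/extdata}, so a different scale or pKa convention
#' can be swapped in without touching code.
#'
#' @param masses,hydropathy,pka optional paths to replacement TSV files
#'   (columns: residue/group, value).
#' @return list of class \code{crk_physchem} with elements
#'   \code{masses}, \code{hydropathy}, \code{pka}.
#' @export
physchem_tables <- function(masses = NULL, hydropathy = NULL, pka = NULL) {
  pkgfile <- function(f) system.file("extdata", f, package = "crkscan",
                                     mustWork = TRUE)
  m <- read_constant_table(masses %||% pkgfile("residue_mass_average.tsv"))
  h <- read_constant_table(hydropathy %||% pkgfile("hydropathy_kyte_doolittle.tsv"))
  p <- read_constant_table(pka %||% pkgfile("pka_emboss.tsv"))
  miss <- setdiff(AA_ALPHABET, names(m))
  if (length(miss)) stop("mass table lacks residue(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(AA_ALPHABET, names(h))
  if (length(miss)) stop("hydropathy table lacks residue(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(c("Nterm", "Cterm", "C", "D", "E", "H", "K", "R", "Y"), names(p))
  if (length(miss)) stop("pKa table lacks group(s): ", paste(miss, collapse = ", "))
  structure(list(masses = m, hydropathy = h, pka = p),
            class = "crk_physchem")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum: the N-terminus and the side chains of H,
#' K, R contribute \eqn{+1/(1+10^{pH-pKa})} each; the C-terminus and
#' the side chains of D, E, C, Y contribute \eqn{-1/(1+10^{pKa-pH})}.
#' Each term is strictly decreasing in pH, so the total is too — the
#' property the pI bisection relies on.
#'
#' @param sequence amino-acid string (X allowed, contributes nothing).
#' @param ph pH value.
#' @param tables [physchem_tables()].
#' @return net charge in elementary charges.
#' @export
net_charge <- function(sequence, ph, tables = physchem_tables()) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  pka <- tables$pka
  pos_counts <- c(Nterm = 1, H = sum(aa == "H"), K = sum(aa == "K"),
                  R = sum(aa == "R"))
  neg_counts <- c(Cterm = 1, D = sum(aa == "D"), E = sum(aa == "E"),
                  C = sum(aa == "C"), Y = sum(aa == "Y"))
  pos_pka <- c(pka[["Nterm"]], pka[["H"]], pka[["K"]], pka[["R"]])
  neg_pka <- c(pka[["Cterm"]], pka[["D"]], pka[["E"]], pka[["C"]], pka[["Y"]])
  sum(pos_counts / (1 + 10^(ph - pos_pka))) -
    sum(neg_counts / (1 + 10^(neg_pka - ph)))
}

#' Physicochemical statistics of one protein sequence
#'
#' Molecular weight is the sum of free amino-acid average masses minus
#' one water per peptide bond, reported in kDa.  GRAVY is the
#' arithmetic mean of per-residue Kyte-Doolittle hydropathy.  Charge is
#' the Henderson-Hasselbalch sum at \code{ph}.  The isoelectric point
#' is found by bisection of the monotone charge curve on pH 0-14 to a
#' tolerance of 0.002 pH units.  Ambiguity code X is excluded from the
#' mass and GRAVY averages with a warning; any other letter outside
#' the 20-residue alphabet is an error naming its position.
#'
#' @param sequence amino-acid string.
#' @param tables [physchem_tables()].
#' @param ph pH at which the reported charge is evaluated (default 7).
#' @param protein_id identifier carried into the result.
#' @return one-row data.frame: protein_id, length, molecular_weight
#'   (kDa), charge, isoelectric_point, gravy.
#' @export
#' @examples
#' compute_stats("AAAAA")$gravy         # 1.8
#' compute_stats("GG")$molecular_weight # 0.13212
compute_stats <- function(sequence, tables = physchem_tables(), ph = 7.0,
                          protein_id = NA_character_) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% c(AA_ALPHABET, "X"))
  if (length(bad))
    stop("invalid residue '", aa[bad[1]], "' at position ", bad[1],
         if (!is.na(protein_id)) paste0(" of protein ", protein_id))
  n_x <- sum(aa == "X")
  if (n_x > 0)
    warning(n_x, " X residue(s) excluded from mass and GRAVY averages",
            if (!is.na(protein_id)) paste0(" (protein ", protein_id, ")"))
  known <- aa[aa != "X"]
  if (!length(known)) stop("sequence contains only X residues")
  mw_da <- sum(tables$masses[known]) - (length(known) - 1L) * WATER_MASS
  gravy <- mean(tables$hydropathy[known])
  charge <- net_charge(sequence, ph, tables)
  # bisection: net charge is strictly decreasing in pH
  lo <- 0; hi <- 14
  while (hi - lo > 0.002) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, tables) > 0) lo <- mid else hi <- mid
  }
  data.frame(protein_id = protein_id, length = length(aa),
             molecular_weight = mw_da / 1000, charge = charge,
             isoelectric_point = (lo + hi) / 2, gravy = gravy,
             stringsAsFactors = FALSE)
}

#' Statistics table and range summary for a whole proteome
#'
#' @param sequences named character vector as from [read_fasta()].
#' @param tables [physchem_tables()].
#' @param ph reported-charge pH.
#' @return list with \code{stats} (one row per protein) and
#'   \code{summary} (min and max of every numeric field, mirroring the
#'   range-style reporting of family surveys); proteins whose sequence
#'   fails validation are excluded from the summary and counted in
#'   \code{n_failed}.
#' @export
stats_table <- function(sequences, tables = physchem_tables(), ph = 7.0) {
  if (!length(sequences)) stop("no sequences supplied")
  rows <- list()
  failed <- character(0)
  for (id in names(sequences)) {
    r <- tryCatch(compute_stats(sequences[[id]], tables, ph, protein_id = id),
                  error = function(e) {
                    warning("protein ", id, " skipped: ", conditionMessage(e))
                    NULL
                  })
    if (is.null(r)) failed <- c(failed, id) else rows[[id]] <- r
  }
  if (!length(rows)) stop("all sequences failed validation")
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  num <- c("length", "molecular_weight", "charge", "isoelectric_point", "gravy")
  summary <- data.frame(
    field = num,
    min = vapply(stats[num], min, numeric(1)),
    max = vapply(stats[num], max, numeric(1)),
    min_protein = vapply(num, function(f) stats$protein_id[which.min(stats[[f]])], ""),
    max_protein = vapply(num, function(f) stats$protein_id[which.max(stats[[f]])], ""),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  list(stats = stats, summary = summary, n_failed = length(failed))
}

#' Write the statistics table
#' @param st result of [stats_table()].
#' @param path output TSV; the range summary goes to
#'   \code{<path>.summary.tsv}.
#' @export
write_stats <- function(st, path) {
  write.table(st$stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(st$summary, paste0(path, ".summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
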