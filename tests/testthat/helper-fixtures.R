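# Programmatic fixtures shared across test files.

S_DOM <- "Stress-antifungal"
K_DOM <- "Pkinase-tyr"

# write text lines to a temp file, return path
tmpfile_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a small Pfam-Scan-dialect table: seq id, aln start/end, env start/end,
# hmm acc, hmm name, type, hmm start/end/length, bit score, E-value,
# significance (+ clan)
pfamscan_fixture <- function() {
  c("# pfam_scan.pl output",
    "#",
    paste("protA  30 130  25 135 PF01657.17 Stress-antifungal Domain 1 95 98 150.2 1.2e-40 1 CL0630"),
    paste("protA 300 560 295 565 PF07714.17 Pkinase_Tyr       Domain 1 250 260 210.5 3.1e-60 1 CL0016"),
    paste("protB  40 140  35 145 PF01657.17 Stress-antifungal Domain 1 95 98 120.9 5.0e-33 1 CL0630"))
}

# InterProScan 14-column TSV rows
interproscan_fixture <- function() {
  c(paste("protA", "d41d8cd9", "600", "Pfam", "PF01657", "Stress-antifungal",
          "30", "130", "1.2E-40", "T", "2020-01-01", "IPR002902",
          "Gnk2-homologous domain", "-", sep = "\t"),
    paste("protA", "d41d8cd9", "600", "Pfam", "PF07714", "Pkinase_Tyr",
          "300", "560", "3.1E-60", "T", "2020-01-01", "IPR001245",
          "Ser-Thr/Tyr kinase", "-", sep = "\t"))
}

gff_fixture <- function() {
  c("##gff-version 3",
    "Chr01\tsrc\tgene\t100\t900\t.\t+\t.\tID=g1;Name=g1",
    "Chr01\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=g1.t1;Parent=g1",
    "Chr01\tsrc\tgene\t5000\t9000\t.\t.\t.\tID=g2",
    "Chr02\tsrc\tmRNA\t10\t90\t.\t-\t.\tID=g3.t1;Parent=g3")
}

# random valid hit table for one protein (hits may overlap)
random_protein_hits <- function(n, protein_id = "p1") {
  starts <- sample(1:800, n, replace = TRUE)
  len <- sample(50:150, n, replace = TRUE)
  domain_hits(protein_id,
              sample(c(S_DOM, K_DOM, "DUF3403", "FYVE"), n, replace = TRUE),
              starts, starts + len - 1L,
              e_value = 10^-runif(n, 3, 40),
              bit_score = round(runif(n, 10, 300), 1))
}

# loci data.frame helper
make_loci <- function(gene_id, chromosome, start, end,
                      species = "spX", strand = "+") {
  data.frame(gene_id = gene_id, chromosome = chromosome,
             start = start, end = end,
             strand = strand, species = species, stringsAsFactors = FALSE)
}

# brute-force transitive-closure clustering oracle (gap criterion only)
brute_force_clusters <- function(loci, max_gap_bp) {
  out <- list()
  for (chr in unique(loci$chromosome)) {
    fam <- loci[loci$chromosome == chr, , drop = FALSE]
    fam <- fam[order(fam$start), , drop = FALSE]
    n <- nrow(fam)
    if (n < 2) next
    # adjacency by pairwise boundary distance, then connected components
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
      gap <- max(fam$start[j] - fam$end[i] - 1, fam$start[i] - fam$end[j] - 1)
      # consecutive-only linking, as tandem arrays are defined
      if (abs(i - j) == 1 && gap <= max_gap_bp) adj[i, j] <- TRUE
    }
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) if (adj[i, j] &&
          comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
      if (!changed) break
    }
    for (g in unique(comp)) {
      memb <- fam$gene_id[comp == g]
      if (length(memb) >= 2) out[[length(out) + 1]] <-
          list(chromosome = chr, members = sort(memb))
    }
  }
  out
}
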