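# Synthetic proteome generator with planted ground truth.  Emulates the
# structure of a multi-species gene-family survey — several species,
# multi-chromosome gene sets, proteins carrying ordered planted domain
# architectures at configurable class frequencies, tandem clusters, and
# scanner noise — so the whole pipeline is testable without a download.

#' Simulation configuration
#'
#' Defaults mirror the study conditions of a five-species cotton CRK
#' survey: per-species family sizes of 60/74/65/120/118 genes,
#' architecture templates drawn from the major-class catalog at the
#' frequencies of the published class totals, 13 chromosomes per
#' species with a gene-density peak on Chr06, and one planted 3-gene
#' tandem cluster per species at 10 kb spacing.
#'
#' @param seed integer random seed; a fixed seed makes every output
#'   byte-identical across runs.
#' @param species named integer vector: family gene count per species.
#' @param templates named list of architecture label vectors.
#' @param class_freq named numeric vector over \code{names(templates)};
#'   must sum to 1 (tolerance 1e-9).
#' @param n_chromosomes chromosomes per species.
#' @param chrom_length_range range (bp) that per-chromosome lengths are
#'   evenly spaced over.
#' @param density_weight named numeric: relative sampling weight of a
#'   chromosome (by its \code{Chr<nn>} suffix) when placing genes;
#'   defaults upweight Chr06 threefold, planting the density peak.
#' @param clusters data.frame of planted tandem clusters (columns
#'   species, chromosome_index, size, spacing_bp); one 3-gene, 10 kb
#'   cluster per species by default.
#' @param dup_noise_rate fraction of family proteins given an
#'   overlapping duplicate hit with a strictly lower bit score.
#' @param subthreshold_rate fraction of decoy proteins given a
#'   sub-threshold Stress-antifungal hit (high E-value, flagged
#'   non-significant).
#' @param decoy_rate decoy (non-DUF26) proteins as a fraction of the
#'   family size.
#' @param domain_length_ranges list of c(min, max) residue spans per
#'   domain kind (\code{duf26}, \code{kinase}, \code{decoy}).
#' @param linker_range c(min, max) residue span of inter-domain
#'   linkers.
#' @return list of class \code{crk_sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       species = c(Gar = 60L, Gra = 74L, Gher = 65L,
                                   Gbar = 120L, Ghir = 118L),
                       templates = major_class_catalog(),
                       class_freq = NULL,
                       n_chromosomes = 13L,
                       chrom_length_range = c(60e6, 120e6),
                       density_weight = c(Chr06 = 3),
                       clusters = NULL,
                       dup_noise_rate = 0.1,
                       subthreshold_rate = 0.05,
                       decoy_rate = 0.1,
                       domain_length_ranges = list(duf26 = c(90L, 110L),
                                                   kinase = c(250L, 290L),
                                                   decoy = c(60L, 120L)),
                       linker_range = c(10L, 40L)) {
  if (is.null(class_freq)) {
    # published major-class totals: 2,1,1,169,1,2,243,13,2,2,1 of 437
    tot <- c(Class_I = 2, Class_II = 1, Class_III = 1, Class_IV = 169,
             Class_V = 1, Class_VI = 2, Class_VII = 243, Class_VIII = 13,
             Class_IX = 2, Class_X = 2, Class_XI = 1)
    class_freq <- tot[names(templates)[names(templates) %in% names(tot)]]
    if (!length(class_freq)) class_freq <- setNames(
      rep(1, length(templates)), names(templates))
    class_freq <- class_freq / sum(class_freq)
  }
  if (is.null(clusters))
    clusters <- data.frame(species = names(species), chromosome_index = 6L,
                           size = 3L, spacing_bp = 10000,
                           stringsAsFactors = FALSE)
  stopifnot(!is.null(names(species)), all(species >= 0),
            abs(sum(class_freq) - 1) < 1e-9,
            all(names(class_freq) %in% names(templates)),
            dup_noise_rate >= 0, subthreshold_rate >= 0, decoy_rate >= 0)
  structure(list(seed = as.integer(seed), species = species,
                 templates = templates, class_freq = class_freq,
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_range = chrom_length_range,
                 density_weight = density_weight, clusters = clusters,
                 dup_noise_rate = dup_noise_rate,
                 subthreshold_rate = subthreshold_rate,
                 decoy_rate = decoy_rate,
                 domain_length_ranges = domain_length_ranges,
                 linker_range = linker_range),
            class = "crk_sim_config")
}

# --- independent truth-label rules ----------------------------------------
# Deliberately separate, simpler implementations of the three schemes,
# so generator truth never self-validates classifier bugs.

truth_major <- function(labels) {
  out <- labels[1]
  for (i in seq_along(labels)[-1])
    if (labels[i] != labels[i - 1]) out <- c(out, labels[i])
  paste(out, collapse = "\u2013")
}

truth_subclass <- function(labels) paste(labels, collapse = "__")

truth_nomenclature <- function(labels) {
  n <- 0
  for (l in labels) if (l == "Stress-antifungal") n <- n + 1
  prefix <- if (n >= 1 && n <= 4) c("sd", "dd", "td", "qd")[n] else paste0(n, "d")
  kin <- FALSE; fun <- FALSE
  for (l in labels) {
    if (l == "Pkinase-tyr" || l == "Pkinase") kin <- TRUE
    if (l == "Pkinase_fungal") fun <- TRUE
  }
  core <- if (kin && fun) "CRdK" else if (kin) "CRK" else "CRRSP"
  suffix <- ""
  seen <- character(0)
  for (l in labels) {
    if (l %in% seen) next
    seen <- c(seen, l)
    letter <- switch(l, DUF3403 = "D", FYVE = "F", PRIMA1 = "P",
                     SugarTransporter = "S", NULL)
    if (is.null(letter)) next
    if (l == "SugarTransporter" && sum(labels == l) >= 2)
      letter <- paste0("d", letter)
    suffix <- paste0(suffix, letter)
  }
  paste0(prefix, core, suffix)
}

domain_kind <- function(label) {
  if (label == "Stress-antifungal") "duf26"
  else if (label %in% c(KINASE_SET, FUNGAL_KINASE)) "kinase"
  else "decoy"
}

random_sequence <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                                     collapse = "")

#' Generate a complete synthetic dataset
#'
#' Produces, for the configured species, a proteome (named sequence
#' vector), gene loci, a clean domain-hit table whose coordinates match
#' the planted domain intervals, chromosome lengths, and a truth table
#' recording each protein's planted architecture and the class labels
#' every scheme is expected to recover (computed by an independent
#' in-module rule copy, not by the classification functions).
#' Decoy (non-DUF26) proteins carry kinase/TauE hits only.  Noise is
#' NOT added here; see [inject_noise()].
#'
#' @param config [sim_config()].
#' @return list of class \code{crk_dataset}: \code{sequences},
#'   \code{loci}, \code{hits}, \code{chrom_lengths}, \code{truth},
#'   \code{config}.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "crk_sim_config"))
  set.seed(config$seed)
  chrom_names <- function(sp) sprintf("%s_Chr%02d", sp,
                                      seq_len(config$n_chromosomes))
  # chromosome lengths: evenly spaced, longest first (deterministic)
  base_len <- round(seq(config$chrom_length_range[2],
                        config$chrom_length_range[1],
                        length.out = config$n_chromosomes))
  chrom_lengths <- numeric(0)
  for (sp in names(config$species))
    chrom_lengths[chrom_names(sp)] <- base_len
  weights <- rep(1, config$n_chromosomes)
  names(weights) <- sprintf("Chr%02d", seq_len(config$n_chromosomes))
  weights[names(config$density_weight)] <- config$density_weight

  sequences <- character(0)
  seq_desc <- character(0)
  hit_rows <- list()
  truth_rows <- list()
  loci_rows <- list()

  rng_int <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1L)

  for (sp in names(config$species)) {
    n_fam <- config$species[[sp]]
    n_decoy <- round(config$decoy_rate * n_fam)
    chrs <- chrom_names(sp)
    # planted clusters for this species
    cl <- config$clusters[config$clusters$species == sp, , drop = FALSE]
    cluster_assign <- rep(NA_character_, n_fam)
    idx <- 1L
    if (nrow(cl)) for (k in seq_len(nrow(cl))) {
      size <- cl$size[k]
      if (idx + size - 1L > n_fam) break
      cluster_assign[idx:(idx + size - 1L)] <- sprintf("%s_cluster%d", sp, k)
      idx <- idx + size
    }
    # exclusion zones around planted clusters (span + default max gap)
    zones <- list()
    cluster_next <- list()   # running next-start position per cluster

    tmpl_draw <- sample(names(config$class_freq), n_fam, replace = TRUE,
                        prob = config$class_freq)
    n_total <- n_fam + n_decoy
    gene_pos <- data.frame(chromosome = character(n_total),
                           start = numeric(n_total), end = numeric(n_total),
                           stringsAsFactors = FALSE)

    for (i in seq_len(n_total)) {
      is_fam <- i <= n_fam
      pid <- sprintf("%s_g%04d", sp, i)
      labels <- if (is_fam) config$templates[[tmpl_draw[i]]]
                else list(c("Pkinase-tyr"), c("TauE"),
                          c("Pkinase-tyr", "TauE"))[[rng_int(1L, 3L)]]
      pos <- rng_int(config$linker_range[1], config$linker_range[2]) + 1L
      starts <- integer(length(labels)); ends <- integer(length(labels))
      for (j in seq_along(labels)) {
        r <- config$domain_length_ranges[[domain_kind(labels[j])]]
        len <- rng_int(r[1], r[2])
        starts[j] <- pos
        ends[j] <- pos + len - 1L
        pos <- ends[j] + rng_int(config$linker_range[1],
                                 config$linker_range[2]) + 1L
      }
      plen <- pos + rng_int(0L, 50L)
      sequences[pid] <- random_sequence(plen)
      seq_desc[pid] <- sprintf("%s synthetic %s", sp,
                               if (is_fam) tmpl_draw[i] else "decoy")
      hit_rows[[pid]] <- data.frame(
        protein_id = pid, domain_name = labels,
        domain_accession = ifelse(labels == "Stress-antifungal",
                                  "IPR002902", NA_character_),
        start = starts, end = ends,
        e_value = signif(10^-runif(length(labels), 10, 50), 3),
        bit_score = round(runif(length(labels), 80, 300), 1),
        significant = TRUE, stringsAsFactors = FALSE)
      truth_rows[[pid]] <- data.frame(
        protein_id = pid, species = sp,
        template = if (is_fam) tmpl_draw[i] else "decoy",
        architecture = paste(labels, collapse = "__"),
        is_crk = is_fam,
        major_truth = if (is_fam) truth_major(labels) else NA_character_,
        subclass_truth = if (is_fam) truth_subclass(labels) else NA_character_,
        nomenclature_truth = if (is_fam) truth_nomenclature(labels)
                             else NA_character_,
        cluster_id = if (is_fam) cluster_assign[i] else NA_character_,
        protein_length = plen,
        noise = "", stringsAsFactors = FALSE)
      # gene placement: gene span ~ 3x protein length plus introns
      glen <- plen * 3 + rng_int(200L, 2000L)
      if (is_fam && !is.na(cluster_assign[i])) {
        cid <- cluster_assign[i]
        k <- as.integer(sub(".*cluster", "", cid))
        chr <- chrs[cl$chromosome_index[k]]
        anchor <- 5e6 + (k - 1) * 2e6
        gstart <- cluster_next[[cid]] %||% anchor
        cluster_next[[cid]] <- gstart + glen + cl$spacing_bp[k]
        zones[[cid]] <- list(chr = chr, lo = anchor - 5e5,
                             hi = anchor + cl$size[k] * (glen + cl$spacing_bp[k]) + 5e5)
      } else {
        repeat {
          chr_idx <- sample(seq_len(config$n_chromosomes), 1L, prob = weights)
          chr <- chrs[chr_idx]
          gstart <- rng_int(1L, as.integer(chrom_lengths[chr] - glen))
          clash <- FALSE
          for (z in zones)
            if (z$chr == chr && gstart < z$hi && gstart + glen > z$lo) {
              clash <- TRUE
              break
            }
          if (!clash) break
        }
      }
      gene_pos$chromosome[i] <- chr
      gene_pos$start[i] <- gstart
      gene_pos$end[i] <- gstart + glen - 1
    }
    loci_rows[[sp]] <- data.frame(
      gene_id = sprintf("%s_g%04d", sp, seq_len(n_total)),
      chromosome = gene_pos$chromosome,
      start = gene_pos$start, end = gene_pos$end,
      strand = sample(c("+", "-"), n_total, replace = TRUE),
      species = sp, stringsAsFactors = FALSE)
  }

  hits <- validate_hits(do.call(rbind, hit_rows))
  rownames(hits) <- NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  loci <- do.call(rbind, loci_rows)
  rownames(loci) <- NULL
  attr(sequences, "descriptions") <- seq_desc
  structure(list(sequences = sequences, loci = loci, hits = hits,
                 chrom_lengths = chrom_lengths, truth = truth,
                 config = config),
            class = "crk_dataset")
}

#' Inject scanner noise into a clean dataset
#'
#' Adds (a) overlapping duplicate hits with a strictly lower bit score
#' on a sampled fraction of family proteins — overlap resolution must
#' remove them — and (b) sub-threshold Stress-antifungal hits (high
#' E-value, flagged non-significant) on a sampled fraction of decoy
#' proteins — candidate filtering must reject them.  Every injected
#' row is recorded in the truth table's \code{noise} field.
#'
#' @param dataset \code{crk_dataset} from [generate_dataset()].
#' @param seed seed for the noise draws (default: config seed + 1).
#' @return \code{crk_dataset} with noisy \code{hits} and annotated
#'   \code{truth}.
#' @export
inject_noise <- function(dataset, seed = NULL) {
  stopifnot(inherits(dataset, "crk_dataset"))
  config <- dataset$config
  set.seed(seed %||% (config$seed + 1L))
  hits <- dataset$hits
  truth <- dataset$truth
  noise_rows <- list()

  fam_ids <- truth$protein_id[truth$is_crk]
  n_dup <- round(config$dup_noise_rate * length(fam_ids))
  if (n_dup > 0) {
    for (pid in sample(fam_ids, n_dup)) {
      h <- hits[hits$protein_id == pid, , drop = FALSE]
      src <- h[sample(nrow(h), 1L), , drop = FALSE]
      shift <- sample(-10:10, 1L)
      dup <- src
      dup$start <- max(1L, src$start + shift)
      dup$end <- src$end + shift
      dup$bit_score <- round(src$bit_score * runif(1, 0.5, 0.9), 1)
      dup$e_value <- signif(src$e_value * 10^runif(1, 1, 5), 3)
      noise_rows[[length(noise_rows) + 1]] <- dup
      truth$noise[truth$protein_id == pid] <-
        paste0(truth$noise[truth$protein_id == pid], "dup;")
    }
  }
  decoy_ids <- truth$protein_id[!truth$is_crk]
  n_sub <- round(config$subthreshold_rate * length(decoy_ids))
  if (n_sub > 0 && length(decoy_ids)) {
    n_sub <- min(n_sub, length(decoy_ids))
    for (pid in sample(decoy_ids, n_sub)) {
      plen <- truth$protein_length[truth$protein_id == pid]
      st <- sample(seq_len(max(1L, plen - 100L)), 1L)
      noise_rows[[length(noise_rows) + 1]] <- data.frame(
        protein_id = pid, domain_name = "Stress-antifungal",
        domain_accession = NA_character_,
        start = st, end = min(plen, st + 95L),
        e_value = signif(runif(1, 0.01, 5), 3), bit_score = round(runif(1, 5, 15), 1),
        significant = FALSE, stringsAsFactors = FALSE)
      truth$noise[truth$protein_id == pid] <-
        paste0(truth$noise[truth$protein_id == pid], "subthreshold;")
    }
  }
  if (length(noise_rows)) {
    hits <- rbind(hits, do.call(rbind, noise_rows))
    hits <- hits[order(hits$protein_id, hits$start), , drop = FALSE]
    rownames(hits) <- NULL
  }
  dataset$hits <- validate_hits(hits)
  dataset$truth <- truth
  dataset
}

#' Write a dataset to disk in standard formats
#'
#' @param dataset \code{crk_dataset}.
#' @param dir output directory (created if absent).  Writes
#'   \code{proteins.faa}, \code{genes.gff3}, \code{hits.tsv},
#'   \code{chrom_lengths.tsv}, \code{truth.tsv}.
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$sequences, file.path(dir, "proteins.faa"))
  con <- file(file.path(dir, "genes.gff3"), "w")
  writeLines("##gff-version 3", con)
  l <- dataset$loci
  writeLines(sprintf("%s\tcrkscan_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     l$chromosome, as.integer(l$start), as.integer(l$end),
                     l$strand, l$gene_id), con)
  close(con)
  write_hits(dataset$hits, file.path(dir, "hits.tsv"))
  write.table(data.frame(chromosome = names(dataset$chrom_lengths),
                         length_bp = as.integer(dataset$chrom_lengths)),
              file.path(dir, "chrom_lengths.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}

#' End-to-end recovery report
#'
#' Runs the full pipeline on a generated dataset — candidate filtering,
#' overlap resolution, architecture building, three-scheme
#' classification, cluster detection — and compares every stage with
#' the generator's planted truth.
#'
#' @param config [sim_config()].
#' @param noise add scanner noise via [inject_noise()] before running.
#' @param policy [filter_policy()].
#' @param clusters_policy [cluster_policy()].
#' @return list: \code{candidate_precision}, \code{candidate_recall},
#'   per-scheme agreement fractions (\code{major_agreement},
#'   \code{subclass_agreement}, \code{nomenclature_agreement}),
#'   \code{clusters_recovered} (fraction of planted clusters detected
#'   with identical membership), \code{n_proteins}, \code{assignments},
#'   \code{dataset}.
#' @export
end_to_end_recovery <- function(config = sim_config(), noise = FALSE,
                                policy = filter_policy(),
                                clusters_policy = cluster_policy()) {
  ds <- generate_dataset(config)
  if (noise) ds <- inject_noise(ds)
  cand <- filter_crk_candidates(ds$hits, policy)
  truth <- ds$truth
  true_fam <- truth$protein_id[truth$is_crk]
  precision <- if (length(cand)) mean(cand %in% true_fam) else NA_real_
  recall <- if (length(true_fam)) mean(true_fam %in% cand) else NA_real_

  lengths <- setNames(truth$protein_length, truth$protein_id)
  archs <- build_architectures(ds$hits[ds$hits$protein_id %in% cand, ,
                                       drop = FALSE],
                               lengths = lengths, policy = policy)
  sp <- setNames(truth$species, truth$protein_id)
  asg <- assign_all(archs, species = unname(sp[names(archs)]))
  m <- merge(asg, truth, by = "protein_id")
  report <- list(
    candidate_precision = precision,
    candidate_recall = recall,
    major_agreement = mean(m$major_signature == m$major_truth),
    subclass_agreement = mean(m$subclass_signature == m$subclass_truth),
    nomenclature_agreement = mean(m$nomenclature == m$nomenclature_truth),
    n_proteins = nrow(truth)
  )
  # planted-cluster recovery, per species
  planted <- unique(truth$cluster_id[!is.na(truth$cluster_id)])
  if (length(planted)) {
    fam_loci <- ds$loci[ds$loci$gene_id %in% true_fam, , drop = FALSE]
    found <- 0L
    det <- detect_tandem_clusters(fam_loci, all_loci = ds$loci,
                                  policy = clusters_policy)
    det_sets <- strsplit(det$members, ";", fixed = TRUE)
    for (cid in planted) {
      memb <- sort(truth$protein_id[!is.na(truth$cluster_id) &
                                      truth$cluster_id == cid])
      if (any(vapply(det_sets, function(s) identical(sort(s), memb), TRUE)))
        found <- found + 1L
    }
    report$clusters_recovered <- found / length(planted)
  } else report$clusters_recovered <- NA_real_
  report$assignments <- asg
  report$dataset <- ds
  report
}
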