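# Orchestration: one entry point running the pipeline stages with a
# config, writing TSV outputs and a machine-readable run manifest.

#' Assemble a run configuration
#'
#' @param fasta,gff,hits,chrom_lengths input paths (any may be NA when
#'   the chosen stages do not need them).
#' @param out_dir output directory.
#' @param species species tag for the inputs.
#' @param e_value_max,interpro_mode see [filter_policy()].
#' @param max_gap_bp,max_intervening,arm_fraction see
#'   [cluster_policy()].
#' @param overlap_fraction,merge_max_gap see [resolve_overlaps()] and
#'   [merge_fragmented()].
#' @param ph reported-charge pH for [compute_stats()].
#' @param seed simulation seed (for the \code{simulate} stage).
#' @return list of class \code{crk_run_config}.
#' @export
run_config <- function(fasta = NA, gff = NA, hits = NA, chrom_lengths = NA,
                       out_dir = "crkscan_out", species = "unknown",
                       e_value_max = 1e-3, interpro_mode = "either",
                       max_gap_bp = 250000, max_intervening = 8L,
                       arm_fraction = 0.25, overlap_fraction = 0.3,
                       merge_max_gap = 0L, ph = 7.0, seed = 1L) {
  structure(list(fasta = fasta, gff = gff, hits = hits,
                 chrom_lengths = chrom_lengths, out_dir = out_dir,
                 species = species, e_value_max = e_value_max,
                 interpro_mode = interpro_mode, max_gap_bp = max_gap_bp,
                 max_intervening = as.integer(max_intervening),
                 arm_fraction = arm_fraction,
                 overlap_fraction = overlap_fraction,
                 merge_max_gap = as.integer(merge_max_gap), ph = ph,
                 seed = as.integer(seed)),
            class = "crk_run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys are the arguments of [run_config()]; unknown keys are an
#' error, so typos never silently fall back to defaults.
#'
#' @param path YAML file.
#' @param ... command-line style overrides applied after the file.
#' @return \code{crk_run_config}.
#' @export
load_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

need_input <- function(path, what) {
  if (is.na(path) || !file.exists(path))
    stop("required input for ", what, " is missing: ",
         if (is.na(path)) "(not configured)" else path)
  path
}

#' Run the pipeline
#'
#' Stages: \code{simulate} writes a synthetic dataset into the output
#' directory; \code{identify} filters CRK candidates from the hit
#' table; \code{classify} builds architectures and assigns the three
#' class labels; \code{stats} computes physicochemical statistics;
#' \code{clusters} detects tandem clusters and terminal-arm
#' localization; \code{summarize} writes the class-by-species summary;
#' \code{all} chains every stage (running \code{simulate} first only if
#' no hit table is configured).  Every run writes
#' \code{manifest.json} recording inputs, parameters, package version
#' and per-stage in/out counts.
#'
#' @param stage one of \code{"identify"}, \code{"classify"},
#'   \code{"stats"}, \code{"clusters"}, \code{"summarize"},
#'   \code{"simulate"}, \code{"all"}.
#' @param config [run_config()].
#' @return the manifest list, invisibly.
#' @export
run_crkscan <- function(stage = c("all", "identify", "classify", "stats",
                                  "clusters", "summarize", "simulate"),
                        config = run_config()) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "crkscan",
    version = as.character(utils::packageVersion("crkscan")),
    stage = stage,
    parameters = unclass(config),
    counts = list(),
    warnings = character(0)
  )
  wcount <- function(expr) {
    ws <- character(0)
    val <- withCallingHandlers(expr, warning = function(w) {
      ws <<- c(ws, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    manifest$warnings <<- c(manifest$warnings, ws)
    val
  }
  out <- function(f) file.path(config$out_dir, f)
  policy <- filter_policy(e_value_max = config$e_value_max,
                          interpro_mode = config$interpro_mode)
  cpolicy <- cluster_policy(max_gap_bp = config$max_gap_bp,
                            max_intervening = config$max_intervening,
                            arm_fraction = config$arm_fraction)

  if (stage == "simulate" || (stage == "all" && is.na(config$hits))) {
    ds <- generate_dataset(sim_config(seed = config$seed))
    write_dataset(ds, config$out_dir)
    config$fasta <- out("proteins.faa")
    config$gff <- out("genes.gff3")
    config$hits <- out("hits.tsv")
    config$chrom_lengths <- out("chrom_lengths.tsv")
    manifest$counts$simulate <- list(proteins = length(ds$sequences),
                                     genes = nrow(ds$loci),
                                     hits = nrow(ds$hits))
    if (stage == "simulate") {
      write_manifest(manifest, out("manifest.json"))
      return(invisible(manifest))
    }
  }

  hits <- wcount(read_hits(need_input(config$hits, "identify")))
  candidates <- filter_crk_candidates(hits, policy)
  writeLines(candidates, out("candidates.txt"))
  manifest$counts$identify <- list(proteins_in = length(unique(hits$protein_id)),
                                   hits_in = nrow(hits),
                                   candidates_out = length(candidates))
  if (!length(candidates))
    manifest$warnings <- c(manifest$warnings, "no CRK candidates found")
  if (stage == "identify") {
    write_manifest(manifest, out("manifest.json"))
    return(invisible(manifest))
  }

  sequences <- NULL
  lengths <- NULL
  if (!is.na(config$fasta) && file.exists(config$fasta)) {
    sequences <- wcount(read_fasta(config$fasta))
    lengths <- setNames(nchar(sequences), names(sequences))
  }

  if (stage %in% c("classify", "summarize", "all")) {
    archs <- build_architectures(hits[hits$protein_id %in% candidates, ,
                                      drop = FALSE],
                                 lengths = lengths,
                                 overlap_fraction = config$overlap_fraction,
                                 max_gap = config$merge_max_gap,
                                 policy = policy)
    write_architectures(archs, out("architectures.tsv"))
    asg <- assign_all(archs, species = config$species)
    write_assignments(asg, out("assignments.tsv"))
    manifest$counts$classify <- list(candidates_in = length(candidates),
                                     assignments_out = nrow(asg))
    if (stage %in% c("summarize", "all")) {
      for (sch in c("major", "subclass", "nomenclature")) {
        fs <- summarize_family(asg, scheme = sch)
        write_family_summary(fs, out(sprintf("summary_%s.tsv", sch)))
      }
      manifest$counts$summarize <- list(
        classes_major = length(unique(asg$major_signature)),
        classes_subclass = length(unique(asg$subclass_signature)),
        classes_nomenclature = length(unique(asg$nomenclature)))
    }
    if (stage != "all") {
      write_manifest(manifest, out("manifest.json"))
      return(invisible(manifest))
    }
  }

  if (stage %in% c("stats", "all")) {
    seqs <- if (!is.null(sequences)) sequences else
      wcount(read_fasta(need_input(config$fasta, "stats")))
    keep <- intersect(names(seqs), candidates)
    if (length(keep)) {
      st <- wcount(stats_table(seqs[keep], ph = config$ph))
      write_stats(st, out("protein_stats.tsv"))
      manifest$counts$stats <- list(proteins_in = length(keep),
                                    rows_out = nrow(st$stats),
                                    failed = st$n_failed)
    }
    if (stage != "all") {
      write_manifest(manifest, out("manifest.json"))
      return(invisible(manifest))
    }
  }

  if (stage %in% c("clusters", "all")) {
    loci <- wcount(read_gff(need_input(config$gff, "clusters"),
                            species = config$species))
    fam <- loci[loci$gene_id %in% candidates, , drop = FALSE]
    cl <- detect_tandem_clusters(fam, all_loci = loci, policy = cpolicy)
    counts <- chromosome_counts(fam)
    write_distribution(cl, counts, config$out_dir)
    manifest$counts$clusters <- list(family_genes = nrow(fam),
                                     clusters = nrow(cl),
                                     clustered_genes = sum(cl$member_count))
    if (!is.na(config$chrom_lengths) && file.exists(config$chrom_lengths)) {
      lens <- read_chrom_lengths(config$chrom_lengths)
      ta <- terminal_arm_fraction(fam, lens, cpolicy)
      manifest$counts$clusters$terminal_arm_fraction <- ta$fraction
    }
  }

  write_manifest(manifest, out("manifest.json"))
  invisible(manifest)
}

write_manifest <- function(manifest, path) {
  manifest$n_warnings <- length(manifest$warnings)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
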