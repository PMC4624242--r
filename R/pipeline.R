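#' Default pipeline configuration
#'
#' Study conditions for the simulated-panel pipeline: 8 strains against a
#' 60-gene reference, per-strain variant counts drawn once per strain from
#' the given ranges, ortholog sets at 95% identity with 20% of genes
#' dropped, and 7 MLST loci of 450 bp evolved with transition bias
#' `kappa = 4`; bootstrap uses 1500 replicates. Any entry can be overridden
#' by the corresponding element of the list passed to [run_pipeline()].
#'
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    outdir = NULL,
    simulate = list(
      n_strains = 8,
      n_genes = 60,
      gene_len = c(300, 600),
      intergap_len = c(50, 150),
      gc = 0.45,
      variants = list(n_high = c(1, 5), n_mod = c(3, 10), n_low = c(5, 15),
                      n_modifier = c(2, 8)),
      ortholog = list(target_identity = 0.95, drop_fraction = 0.2),
      mlst = list(loci = default_mlst_loci(), kappa = 4,
                  edge_range = c(0.005, 0.03), identical_group = NULL)),
    inputs = NULL,
    thresholds = list(dp_min = 10, qual_min = 100, qd_min = 5,
                      min_identity = 80, min_coverage = 0.8),
    options = list(center = TRUE, bootstrap = 1500))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

log_stage <- function(quiet, ...) if (!quiet) message("[strainprofiler] ", ...)

#' Run the full strain-profiling pipeline
#'
#' Orchestrates every stage end to end: reference and strain inputs
#' (simulated with planted ground truth, or read from files), variant
#' filtering and impact annotation, gene variant score matrix, PCA and
#' complete-linkage clustering, reciprocal-best-hit orthology, and MLST
#' profiling with a neighbor-joining tree and bootstrap supports. The run
#' report records seeds, thresholds and per-stage record counts, and the
#' stage-count conservation `records in = filtered out + retained` is
#' asserted. Identical config and seed give identical outputs.
#'
#' In simulation mode (the default, `inputs = NULL`) every per-stage seed
#' is derived deterministically from `config$seed`. In file mode, set
#' `config$inputs` to a list with any of: `reference_fasta` + `gene_table`,
#' `vcfs` (named character vector strain -> VCF path), `set_a` / `set_b`
#' (gene FASTA paths) or `hits_ab` / `hits_ba` (tabular hit files), and
#' `loci_dir` (per-locus FASTA directory); stages without inputs are
#' skipped.
#'
#' @param config nested list (see [default_pipeline_config()]) or a path to
#'   a YAML/JSON file with the same structure; partial configs are merged
#'   over the defaults.
#' @param quiet suppress per-stage log messages.
#' @return invisibly, a list with the stage results (`reference`,
#'   `annotated`, `truth`, `score_matrix`, `pca`, `dendrogram`, `orthologs`,
#'   `mlst`) and `report` (also written to `<outdir>/report.json` when
#'   `outdir` is set).
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- merge_config(default_pipeline_config(), config)
  check_count(cfg$seed, "seed")
  th <- cfg$thresholds
  simulate <- is.null(cfg$inputs)
  outdir <- cfg$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  out_path <- function(...) file.path(outdir, ...)
  report <- list(package_version = as.character(utils::packageVersion(
    "strainprofiler")), seed = cfg$seed, thresholds = th,
    mode = if (simulate) "simulate" else "files", counts = list(),
    warnings = character(0))
  add_warning <- function(w) report$warnings <<- c(report$warnings, w)
  res <- list()

  # --- reference ---
  if (simulate) {
    sim <- cfg$simulate
    log_stage(quiet, "simulating reference genome (", sim$n_genes,
              " genes)")
    ref <- generate_reference(sim$n_genes, gene_len = sim$gene_len,
                              intergap_len = sim$intergap_len, gc = sim$gc,
                              seed = cfg$seed)
  } else {
    ref <- NULL
    if (!is.null(cfg$inputs$reference_fasta)) {
      log_stage(quiet, "reading reference genome")
      ref <- read_reference(cfg$inputs$reference_fasta,
                            cfg$inputs$gene_table)
    }
  }
  res$reference <- ref
  if (!is.null(ref) && !is.null(outdir))
    write_reference(ref, out_path("reference.fasta"),
                    out_path("genes.tsv"))

  # --- variants: simulate or read, filter, annotate ---
  records <- NULL
  truth <- NULL
  if (simulate) {
    sim <- cfg$simulate
    strains <- sprintf("strain%02d", seq_len(sim$n_strains))
    vr <- sim$variants
    pick <- function(rng, k) if (length(rng) == 2)
      floor(runif(k, rng[1], rng[2] + 1)) else rep(rng, k)
    set.seed(cfg$seed + 1000L)
    n_high <- pick(vr$n_high, sim$n_strains)
    n_mod <- pick(vr$n_mod, sim$n_strains)
    n_low <- pick(vr$n_low, sim$n_strains)
    n_modifier <- pick(vr$n_modifier, sim$n_strains)
    log_stage(quiet, "planting variants for ", sim$n_strains, " strains")
    sets <- lapply(seq_along(strains), function(i)
      generate_strain_variants(ref, n_high[i], n_mod[i], n_low[i],
                               n_modifier[i], seed = cfg$seed + 2000L + i,
                               strain = strains[i]))
    records <- do.call(rbind, lapply(sets, `[[`, "records"))
    truth <- do.call(rbind, lapply(sets, `[[`, "truth"))
    if (!is.null(outdir))
      for (s in sets) write_vcf(s, out_path(paste0(s$strain, ".vcf")),
                                chrom = ref$name)
  } else if (!is.null(cfg$inputs$vcfs)) {
    vcfs <- cfg$inputs$vcfs
    log_stage(quiet, "reading ", length(vcfs), " VCF file(s)")
    records <- do.call(rbind, lapply(names(vcfs), function(s)
      read_vcf(vcfs[[s]], strain = s)))
  }

  sim_strains <- if (simulate)
    sprintf("strain%02d", seq_len(cfg$simulate$n_strains)) else NULL
  if (!is.null(records)) {
    if (is.null(ref))
      stop("stage 'annotate': variant records present but no reference")
    n_in <- nrow(records)
    filtered <- withCallingHandlers(
      filter_variants(records, th$dp_min, th$qual_min, th$qd_min),
      warning = function(w) { add_warning(conditionMessage(w))
        invokeRestart("muffleWarning") })
    n_kept <- nrow(filtered)
    n_out <- n_in - n_kept
    stopifnot(n_kept + n_out == n_in, n_kept >= 0, n_out >= 0)
    report$counts$variants_in <- n_in
    report$counts$variants_filtered_out <- n_out
    report$counts$variants_retained <- n_kept
    log_stage(quiet, "filter: ", n_in, " in, ", n_kept, " retained")
    annotated <- annotate_variants(filtered, ref)
    res$annotated <- annotated
    res$truth <- truth
    if (!is.null(truth) && nrow(truth) > 0) {
      key <- function(d) paste(d$strain, d$pos, d$ref, d$alt)
      m <- match(key(annotated), key(truth))
      acc <- mean(annotated$impact == truth$impact[m]) * 100
      report$counts$planted_variants <- nrow(truth)
      report$truth_recovery_pct <- acc
      log_stage(quiet, "impact round trip: ", sprintf("%.1f", acc),
                "% of planted labels recovered")
    }
    if (!is.null(outdir)) write_annotated(annotated, out_path(
      "annotated_variants.tsv"))

    # --- scoring + profiling ---
    strains <- sim_strains %||% unique(records$strain)
    sm <- withCallingHandlers(
      score_strains(annotated, strains = strains),
      warning = function(w) { add_warning(conditionMessage(w))
        invokeRestart("muffleWarning") })
    res$score_matrix <- sm
    report$counts$scored_genes <- ncol(sm)
    log_stage(quiet, "score matrix: ", nrow(sm), " strains x ", ncol(sm),
              " genes")
    if (ncol(sm) > 0 && nrow(sm) >= 2) {
      res$pca <- strain_pca(sm, center = cfg$options$center)
      if (res$pca$degenerate)
        add_warning("PCA degenerate: score matrix has no variance")
      res$dendrogram <- cluster_strains(sm)
      if (!is.null(outdir)) {
        write_score_matrix(sm, out_path("score_matrix.tsv"),
                           out_path("score_constants.json"))
        write_pca(res$pca, out_path("pca"))
        writeLines(write_newick(ape::as.phylo(res$dendrogram)),
                   out_path("dendrogram.nwk"))
      }
    } else {
      add_warning("score matrix empty or single strain; PCA/clustering skipped")
    }
  }

  # --- orthologs ---
  orth <- NULL
  if (simulate) {
    oc <- cfg$simulate$ortholog
    log_stage(quiet, "simulating ortholog sets (identity ",
              oc$target_identity, ", drop ", oc$drop_fraction, ")")
    sets <- generate_ortholog_sets(ref, oc$target_identity,
                                   oc$drop_fraction,
                                   seed = cfg$seed + 3000L)
    pairs <- reciprocal_best_hits(sets$set_a, sets$set_b,
                                  min_identity = th$min_identity,
                                  min_coverage = th$min_coverage)
    orth <- list(pairs = pairs, truth = sets$truth,
                 fraction = ortholog_fraction(pairs, length(sets$set_a)))
  } else if (!is.null(cfg$inputs$set_a) || !is.null(cfg$inputs$hits_ab)) {
    log_stage(quiet, "computing reciprocal best hits")
    if (!is.null(cfg$inputs$hits_ab)) {
      pairs <- reciprocal_best_hits(
        hits_ab = read_hit_table(cfg$inputs$hits_ab),
        hits_ba = read_hit_table(cfg$inputs$hits_ba),
        min_identity = th$min_identity, min_coverage = th$min_coverage)
      n_ref <- length(unique(read_hit_table(cfg$inputs$hits_ab)$qseqid))
    } else {
      set_a <- read_gene_set(cfg$inputs$set_a)
      set_b <- read_gene_set(cfg$inputs$set_b)
      pairs <- reciprocal_best_hits(set_a, set_b,
                                    min_identity = th$min_identity,
                                    min_coverage = th$min_coverage)
      n_ref <- length(set_a)
    }
    orth <- list(pairs = pairs,
                 fraction = ortholog_fraction(pairs, n_ref))
  }
  if (!is.null(orth)) {
    res$orthologs <- orth
    report$counts$ortholog_pairs <- nrow(orth$pairs)
    report$ortholog_fraction_pct <- orth$fraction
    log_stage(quiet, "orthologs: ", nrow(orth$pairs), " pairs (",
              sprintf("%.2f", orth$fraction), "% of reference genes)")
    if (!is.null(outdir)) {
      write.table(orth$pairs, out_path("ortholog_pairs.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(n_pairs = nrow(orth$pairs),
                                ortholog_fraction_pct = orth$fraction),
                           out_path("ortholog_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  # --- MLST ---
  loci_seqs <- NULL
  true_tree <- NULL
  if (simulate) {
    mc <- cfg$simulate$mlst
    strains <- sprintf("strain%02d", seq_len(cfg$simulate$n_strains))
    ig <- mc$identical_group
    if (is.numeric(ig) && length(ig) == 1) ig <- strains[seq_len(ig)]
    log_stage(quiet, "simulating MLST loci on a random strain tree")
    true_tree <- simulate_strain_tree(strains, edge_range = mc$edge_range,
                                      identical_group = ig,
                                      seed = cfg$seed + 4000L)
    loci <- mc$loci
    if (is.list(loci)) loci <- unlist(loci)
    loci_seqs <- simulate_mlst_loci(true_tree, loci = loci,
                                    kappa = mc$kappa,
                                    seed = cfg$seed + 5000L)
    if (!is.null(outdir)) write_mlst_loci(loci_seqs, out_path("mlst_loci"))
  } else if (!is.null(cfg$inputs$loci_dir)) {
    log_stage(quiet, "reading MLST loci from ", cfg$inputs$loci_dir)
    loci_seqs <- read_mlst_loci(cfg$inputs$loci_dir)
  }
  if (!is.null(loci_seqs)) {
    profiles <- assign_alleles(loci_seqs)
    concat <- concatenate_loci(loci_seqs)
    dm <- k2p_matrix(concat)
    tree <- if (length(concat) >= 4)
      bootstrap_support(concat, n_replicates = cfg$options$bootstrap,
                        seed = cfg$seed + 6000L)
    else nj_tree(dm)
    res$mlst <- list(profiles = profiles, distances = dm, tree = tree,
                     true_tree = true_tree)
    report$counts$mlst_strains <- nrow(profiles)
    report$counts$sequence_types <- max(profiles$sequence_type)
    log_stage(quiet, "MLST: ", nrow(profiles), " strains, ",
              max(profiles$sequence_type), " sequence types")
    if (!is.null(outdir)) {
      write.table(profiles, out_path("mlst_profiles.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write_phylip(dm, out_path("mlst_distances.phy"))
      writeLines(write_newick(tree), out_path("mlst_tree.nwk"))
    }
  }

  res$report <- report
  if (!is.null(outdir))
    jsonlite::write_json(report, out_path("report.json"),
                         auto_unbox = TRUE, digits = NA)
  log_stage(quiet, "pipeline complete")
  invisible(res)
}
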