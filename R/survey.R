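# End-to-end survey: composes every stage into a report bundle.
#
# With no input paths configured, the survey runs on a fully synthetic
# bundle generated from the configured seed, so two runs with equal
# configuration are byte-identical. Outputs are staged in a temporary
# directory and moved into place only on success, so a failing stage never
# leaves partial outputs behind.

#' Survey configuration
#'
#' All thresholds of the pipeline in one place. Paths left `NULL` are
#' simulated by the synthetic-data generators.
#'
#' @param proteome_path,gff3_path,genome_path,ct_path Optional input files
#'   (protein FASTA, GFF3 gene models, genome FASTA, long-format CT CSV).
#' @param seed Master seed; every stage derives its stream from it.
#' @param scan A [scan_config()].
#' @param rule A [cluster_rule()].
#' @param promoter_length Promoter length in bp (default 1500).
#' @param fold_change_threshold Regulation-call threshold (default 2).
#' @param dating A [dating_config()].
#' @param bootstrap_reps NJ bootstrap replicates (default 1000).
#' @param sim Sizes for the synthetic bundle: a list with `n_per_class`,
#'   `n_chroms`, `n_genes`, `n_family`, `cluster_spec`, `n_pairs`,
#'   `n_codons`, `target_ks`, `target_ka`, `qpcr_noise_sd`.
#' @return List of class `survey_config`.
#' @export
survey_config <- function(proteome_path = NULL, gff3_path = NULL,
                          genome_path = NULL, ct_path = NULL,
                          seed = 1L,
                          scan = scan_config(),
                          rule = cluster_rule(),
                          promoter_length = 1500L,
                          fold_change_threshold = 2,
                          dating = dating_config(),
                          bootstrap_reps = 1000L,
                          sim = list()) {
  sim_defaults <- list(
    n_per_class = c(group1 = 3L, sub2a = 3L, sub2b = 3L, sub2c = 3L,
                    sub2d = 3L, sub2e = 3L, group3 = 3L, ungrouped = 1L,
                    incomplete = 1L, duplicate = 1L),
    n_chroms = 3L, n_genes = 60L, n_family = 12L, cluster_spec = c(2L, 3L),
    n_pairs = 10L, n_codons = 300L, target_ks = 0.25, target_ka = 0.05,
    qpcr_noise_sd = 0.15)
  sim_defaults[names(sim)] <- sim
  structure(list(proteome_path = proteome_path, gff3_path = gff3_path,
                 genome_path = genome_path, ct_path = ct_path,
                 seed = as.integer(seed), scan = scan, rule = rule,
                 promoter_length = as.integer(promoter_length),
                 fold_change_threshold = fold_change_threshold,
                 dating = dating, bootstrap_reps = as.integer(bootstrap_reps),
                 sim = sim_defaults),
            class = "survey_config")
}

#' Run the full family survey and write a report bundle
#'
#' Stages, in order: domain scan + classification + family table;
#' gene models, exon/intron structure, chromosome distribution and cluster
#' detection; promoter extraction + CARE scan + category summary; ortholog
#' Ka/Ks + divergence dating; NJ tree with bootstrap supports + subgroup
#' assignment; qPCR regulation calls + summary; tissue-atlas summary.
#' A `run_metadata.json` records versions, seeds, thresholds and the
#' estimator conventions in force (pattern scan for domain identification,
#' NG86 counting for Ka/Ks).
#'
#' Any stage error aborts the run with the stage name; partial outputs are
#' removed (the staging directory is discarded).
#'
#' @param out_dir Output directory (created; must not be an existing
#'   non-empty bundle unless `overwrite = TRUE`).
#' @param cfg A [survey_config()].
#' @param overwrite Replace an existing bundle.
#' @return Invisibly, a list of the main in-memory results.
#' @export
run_survey <- function(out_dir, cfg = survey_config(), overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("output directory exists and is not empty: ", out_dir)
  stage_dir <- tempfile("survey_stage_")
  dir.create(stage_dir, recursive = TRUE)
  on.exit(unlink(stage_dir, recursive = TRUE), add = TRUE)
  seed <- cfg$seed
  results <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("survey stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  p <- function(...) file.path(stage_dir, ...)

  # -- family scan ----------------------------------------------------------
  results$proteome <- stage("family_scan", {
    if (is.null(cfg$proteome_path)) {
      gen <- make_proteome(cfg$sim$n_per_class, seed = seed)
      proteins <- gen$proteins
      truth <- gen$truth
    } else {
      proteins <- read_proteome(cfg$proteome_path)
      truth <- NULL
    }
    scan <- scan_proteome(proteins, cfg$scan)
    fam <- dedupe_and_filter(proteins, scan$classification, cfg$scan)
    write_family_table(proteins, scan, p("family_table.tsv"))
    write_hits_json(scan, p("domain_hits.json"))
    utils::write.table(fam[, setdiff(names(fam), "sequence")],
                       p("family_members.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(proteins = proteins, truth = truth, scan = scan, family = fam)
  })

  # -- genome context -------------------------------------------------------
  results$genome <- stage("genome_context", {
    if (is.null(cfg$gff3_path)) {
      fasta <- p("synthetic_genome.fa")
      gen <- make_genome(cfg$sim$n_chroms, cfg$sim$n_genes,
                         cfg$sim$n_family, cfg$sim$cluster_spec,
                         seed = seed + 1L, rule = cfg$rule,
                         fasta_path = fasta, gff3_path = p("synthetic_genome.gff3"))
      genes <- gen$genes
      truth <- gen$truth
      genome_path <- fasta
    } else {
      genes <- read_gene_models(cfg$gff3_path)
      truth <- NULL
      genome_path <- cfg$genome_path
    }
    clusters <- detect_clusters(genes, cfg$rule)
    write_clusters(clusters, genes, bed_path = p("clusters.bed"),
                   tsv_path = p("clusters.tsv"))
    stats <- structure_stats(genes)
    utils::write.table(stats$per_gene, p("structure_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dist <- chromosome_distribution(genes)
    utils::write.table(dist, p("chromosome_distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(genes = genes, truth = truth, clusters = clusters,
         structure = stats, distribution = dist, genome_path = genome_path)
  })

  # -- promoter CAREs -------------------------------------------------------
  results$promoters <- stage("promoter_cares", {
    genes <- results$genome$genes
    fam <- genes[genes$is_family_member, ]
    if (is.null(results$genome$genome_path))
      stop("promoter scan requested but no genome FASTA is configured")
    genome <- Biostrings::readDNAStringSet(results$genome$genome_path)
    names(genome) <- sub("\\s.*$", "", names(genome))
    proms <- stats::setNames(
      vapply(seq_len(nrow(fam)), function(i)
        extract_promoter(fam[i, ], genome, cfg$promoter_length), ""),
      fam$gene_id)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(proms),
                                p("promoters.fa"))
    motifs <- care_motifs()
    hits <- scan_promoters(proms, motifs)
    write_care_hits(hits, tsv_path = p("care_hits.tsv"),
                    gff3_path = p("care_hits.gff3"))
    summ <- care_summary(hits, motifs, gene_ids = fam$gene_id)
    utils::write.table(summ, p("care_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(promoters = proms, hits = hits, summary = summ)
  })

  # -- evolution ------------------------------------------------------------
  results$evolution <- stage("evolution", {
    gen <- make_ortholog_pairs(cfg$sim$n_pairs, cfg$sim$n_codons,
                               cfg$sim$target_ks, cfg$sim$target_ka,
                               seed = seed + 2L)
    tab <- kaks_table(gen$pairs, cfg$dating)
    out <- tab
    out$t_mya <- out$t_years / 1e6
    utils::write.table(format(out, digits = 6), p("kaks_dating.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(pairs = gen$pairs, truth = gen$truth, table = tab)
  })

  # -- phylogeny ------------------------------------------------------------
  results$phylo <- stage("phylo", {
    truth <- results$proteome$truth
    if (is.null(truth)) {
      list(tree = NULL, assignments = NULL)
    } else {
      g2 <- truth[grepl("^sub2", truth$class) & is.na(truth$duplicate_of), ]
      aln <- stats::setNames(g2$domain_seq, g2$id)
      tree <- bootstrap_support(aln, reps = cfg$bootstrap_reps,
                                seed = seed + 3L)
      write_newick(tree, p("nj_tree.nwk"))
      tags <- stats::setNames(g2$subgroup, g2$id)
      assignments <- do.call(rbind, lapply(g2$id, function(q) {
        res <- assign_subgroup(stats::setNames(aln[q], q),
                               aln[setdiff(g2$id, q)],
                               tags[setdiff(g2$id, q)])
        data.frame(id = q, true_subgroup = tags[[q]],
                   assigned = res$subgroup, method = res$method)
      }))
      utils::write.table(assignments, p("subgroup_assignments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(tree = tree, assignments = assignments)
    }
  })

  # -- expression -----------------------------------------------------------
  results$expression <- stage("expression", {
    if (is.null(cfg$ct_path)) {
      design <- load_fold_change_table()[, c("gene", "fc_LOI_LTD",
                                             "fc_NOI_NTD", "fc_LOI_NOI")]
      gen <- make_qpcr(design, noise_sd = cfg$sim$qpcr_noise_sd,
                       seed = seed + 4L)
      tab <- gen$table
      truth <- gen$truth
    } else {
      tab <- read_qpcr(cfg$ct_path)
      truth <- NULL
    }
    calls <- regulation_calls(tab, cfg$fold_change_threshold)
    utils::write.csv(format(calls, digits = 6), p("regulation_calls.csv"),
                     row.names = FALSE, quote = FALSE)
    summ <- summarize_calls(calls)
    atlas_gen <- make_atlas(rep(c("constitutive", "tissue-specific",
                                  "intermediate", "silent"),
                                c(20, 3, 6, 1)), seed = seed + 5L)
    asum <- atlas_summary(atlas_gen$atlas)
    utils::write.table(asum$per_gene, p("atlas_breadth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(asum$per_tissue, p("atlas_tissue_pct.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summ, p("regulation_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(table = tab, truth = truth, calls = calls, summary = summ,
         atlas = atlas_gen, atlas_summary = asum)
  })

  # -- metadata -------------------------------------------------------------
  meta <- list(
    package = "wrkysurvey",
    version = as.character(utils::packageVersion("wrkysurvey")),
    seed = seed,
    thresholds = list(
      heptapeptides = cfg$scan$allowed_heptapeptides,
      finger_search_window = cfg$scan$finger_search_window,
      cluster_max_gap_bp = cfg$rule$max_gap_bp,
      cluster_max_intervening_genes = cfg$rule$max_intervening_genes,
      cluster_distance_convention = "end-to-start intergenic gap",
      promoter_length = cfg$promoter_length,
      fold_change_threshold = cfg$fold_change_threshold,
      lambda = cfg$dating$lambda,
      bootstrap_reps = cfg$bootstrap_reps),
    estimators = list(
      domain_identification = "deterministic heptapeptide + zinc-finger pattern scan (no profile-HMM search)",
      kaks = "Nei-Gojobori 1986 counting with Jukes-Cantor correction (no ML codon model)",
      significance = "two-sided Welch t on replicate dCT values"))
  jsonlite::write_json(meta, p("run_metadata.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  # -- commit the bundle ----------------------------------------------------
  if (dir.exists(out_dir) && overwrite) unlink(out_dir, recursive = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in dir(stage_dir)) {
    file.copy(file.path(stage_dir, f), file.path(out_dir, f),
              overwrite = TRUE)
  }
  invisible(results)
}
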