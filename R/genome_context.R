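# Gene models, exon/intron structure and chromosomal WRKY clusters.
#
# Cluster rule: two neighbouring family genes are linked when the intergenic
# gap is under max_gap_bp AND at most max_intervening_genes non-family genes
# lie fully between them; clusters are maximal linked runs of >= 2 genes.
# Internal coordinates follow the GFF3 dialect (1-based inclusive) at the
# interface; BED export converts to 0-based half-open.

#' Cluster rule parameters
#'
#' @param max_gap_bp Strict upper bound on the intergenic gap between
#'   neighbouring family genes (default 200 kb).
#' @param max_intervening_genes Inclusive upper bound on the number of
#'   non-family genes lying fully between neighbouring family genes
#'   (default 8).
#' @return A list of class `cluster_rule`.
#' @export
cluster_rule <- function(max_gap_bp = 200000L, max_intervening_genes = 8L) {
  stopifnot(max_gap_bp > 0, max_intervening_genes > 0)
  structure(list(max_gap_bp = as.integer(max_gap_bp),
                 max_intervening_genes = as.integer(max_intervening_genes)),
            class = "cluster_rule")
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS features; for multi-isoform genes the mRNA with
#' the most exonic bases is retained (longest-isoform rule). Output rows are
#' stably sorted by (chrom, start).
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `exons` (list column of 2-column start/end matrices, sorted),
#'   `cds_start`, `cds_end` (NA when the gene has no CDS feature),
#'   `is_family_member` (initialised `FALSE`).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  first_parent <- function(p) vapply(p, function(x)
    if (length(x)) x[[1]] else NA_character_, "")
  df$parent <- first_parent(df$Parent)
  if (any(!df$strand %in% c("+", "-") & df$type == "gene"))
    stop("unknown strand in gene feature")
  genes <- df[df$type == "gene", ]
  mrnas <- df[df$type == "mRNA", ]
  exons <- df[df$type == "exon", ]
  cdss  <- df[df$type == "CDS", ]

  build_one <- function(i) {
    gid <- genes$ID[i]
    gm <- mrnas[which(mrnas$parent == gid), ]
    if (nrow(gm) > 0) {
      ex_bases <- vapply(gm$ID, function(mid) {
        e <- exons[which(exons$parent == mid), ]
        sum(e$end - e$start + 1L)
      }, 0)
      best <- gm$ID[which.max(ex_bases)]
      ex <- exons[which(exons$parent == best), ]
      cd <- cdss[which(cdss$parent == best), ]
    } else {
      ex <- exons[which(exons$parent == gid), ]
      cd <- cdss[which(cdss$parent == gid), ]
    }
    if (nrow(ex) == 0)
      ex <- genes[i, , drop = FALSE]  # exonless annotation: whole span
    if (any(ex$start < genes$start[i] | ex$end > genes$end[i]))
      stop(sprintf("exon outside gene span for gene '%s'", gid))
    exm <- as.matrix(ex[order(ex$start), c("start", "end")])
    dimnames(exm) <- list(NULL, c("start", "end"))
    list(gene_id = gid, chrom = as.character(genes$seqnames[i]),
         start = genes$start[i], end = genes$end[i],
         strand = as.character(genes$strand[i]), exons = exm,
         cds_start = if (nrow(cd)) min(cd$start) else NA_integer_,
         cds_end = if (nrow(cd)) max(cd$end) else NA_integer_)
  }
  rows <- lapply(seq_len(nrow(genes)), build_one)
  out <- data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, function(r) as.integer(r$start), 0L),
    end = vapply(rows, function(r) as.integer(r$end), 0L),
    strand = vapply(rows, `[[`, "", "strand"),
    cds_start = vapply(rows, function(r) as.integer(r$cds_start), 0L),
    cds_end = vapply(rows, function(r) as.integer(r$cds_end), 0L),
    is_family_member = FALSE,
    row.names = NULL)
  out$exons <- lapply(rows, `[[`, "exons")
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Exon/intron structure statistics
#'
#' @param genes Gene-model data.frame from [read_gene_models()].
#' @return List with `per_gene` (gene_id, n_exons, n_introns) and
#'   `family_mean_exons` (mean exon count over family members, 2 dp;
#'   over all genes when no family flags are set).
#' @export
structure_stats <- function(genes) {
  stopifnot(nrow(genes) >= 1)
  n_ex <- vapply(genes$exons, nrow, 0L)
  per_gene <- data.frame(gene_id = genes$gene_id, n_exons = n_ex,
                         n_introns = n_ex - 1L)
  fam <- if (any(genes$is_family_member)) genes$is_family_member
         else rep(TRUE, nrow(genes))
  list(per_gene = per_gene,
       family_mean_exons = round(mean(n_ex[fam]), 2))
}

#' Detect chromosomal family-gene clusters
#'
#' Neighbouring family genes are linked when `next$start - prev$end - 1 <
#' max_gap_bp` and the number of non-family genes lying strictly between
#' their spans is `<= max_intervening_genes`. Clusters are maximal linked
#' runs with at least two members, labelled `CLU1..N` in genome order.
#'
#' @param genes Gene models sorted by (chrom, start) with
#'   `is_family_member` set; unsorted input is an error (no silent sort).
#' @param rule A [cluster_rule()].
#' @return Data.frame: `cluster_id`, `chrom`, `members` (comma-separated
#'   gene ids in genomic order), `n_members`, `span_bp`.
#' @export
detect_clusters <- function(genes, rule = cluster_rule()) {
  ord <- order(genes$chrom, genes$start)
  if (!identical(ord, seq_len(nrow(genes))))
    stop("genes must be sorted by (chrom, start); refusing to sort silently")
  fam_idx <- which(genes$is_family_member)
  clusters <- list()
  current <- integer()
  flush <- function() {
    if (length(current) >= 2L) clusters[[length(clusters) + 1L]] <<- current
    current <<- integer()
  }
  for (k in seq_along(fam_idx)) {
    i <- fam_idx[k]
    if (length(current) == 0L) { current <- i; next }
    j <- current[length(current)]
    linked <- FALSE
    if (genes$chrom[i] == genes$chrom[j]) {
      gap <- genes$start[i] - genes$end[j] - 1L
      between <- sum(!genes$is_family_member &
                       genes$chrom == genes$chrom[j] &
                       genes$start > genes$end[j] &
                       genes$end < genes$start[i])
      linked <- gap < rule$max_gap_bp && between <= rule$max_intervening_genes
    }
    if (linked) current <- c(current, i) else { flush(); current <- i }
  }
  flush()
  if (length(clusters) == 0L)
    return(data.frame(cluster_id = character(), chrom = character(),
                      members = character(), n_members = integer(),
                      span_bp = integer()))
  data.frame(
    cluster_id = paste0("CLU", seq_along(clusters)),
    chrom = vapply(clusters, function(ix) genes$chrom[ix[1]], ""),
    members = vapply(clusters, function(ix)
      paste(genes$gene_id[ix], collapse = ","), ""),
    n_members = lengths(clusters),
    span_bp = vapply(clusters, function(ix)
      genes$end[ix[length(ix)]] - genes$start[ix[1]] + 1L, 0L))
}

#' Per-chromosome family-gene distribution
#'
#' @param genes Gene models with family flags set.
#' @return Data.frame: `chrom`, `n_family`, `pct` (1 dp); counts sum to the
#'   family size.
#' @export
chromosome_distribution <- function(genes) {
  fam <- genes[genes$is_family_member, ]
  tab <- table(fam$chrom)
  data.frame(chrom = names(tab), n_family = as.integer(tab),
             pct = round(100 * as.integer(tab) / nrow(fam), 1),
             row.names = NULL)
}

#' Write clusters as BED (0-based half-open) and TSV
#'
#' @param clusters Result of [detect_clusters()].
#' @param genes The gene models the clusters were computed from.
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @export
write_clusters <- function(clusters, genes, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(clusters, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(bed_path)) {
    first_ids <- vapply(strsplit(clusters$members, ","), `[`, "", 1L)
    starts <- genes$start[match(first_ids, genes$gene_id)]
    bed <- data.frame(chrom = clusters$chrom,
                      start = starts - 1L,
                      end = starts - 1L + clusters$span_bp,
                      name = clusters$cluster_id,
                      score = clusters$n_members,
                      strand = ".")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(clusters)
}
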