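# Promoter extraction and cis-acting regulatory element (CARE) scanning.
#
# Promoters are the 1,500 bp upstream of the translational start (the first
# CDS base), reverse-complemented for minus-strand genes. Scanning is exact
# degenerate matching of IUPAC consensus strings on both strands, via
# Biostrings fixed=FALSE matching; correctness is defined against the
# shipped dictionary, which users can edit freely.

#' Load a CARE motif dictionary
#'
#' The packaged default (`inst/extdata/care_motifs.tsv`) carries
#' PlantCARE-style element names, IUPAC consensus strings and one of seven
#' categories: essential, enhancer, light, tissue, abiotic, hormone, other.
#' Variable-length elements are represented by their canonical core.
#'
#' @param path TSV with columns `name`, `consensus`, `category`; default the
#'   packaged dictionary.
#' @return Data.frame of motifs; consensus validated as IUPAC.
#' @export
care_motifs <- function(path = system.file("extdata", "care_motifs.tsv",
                                           package = "wrkysurvey")) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "consensus", "category") %in% names(m)))
  m$consensus <- toupper(m$consensus)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", m$consensus)
  if (any(bad))
    stop("invalid IUPAC code in motif(s): ",
         paste(m$name[bad], collapse = ", "))
  if (any(nchar(m$consensus) < 4))
    stop("motif consensus shorter than 4 nt: ",
         paste(m$name[nchar(m$consensus) < 4], collapse = ", "))
  m
}

#' Extract the promoter upstream of a gene's translational start
#'
#' Plus strand: the `length` bases ending immediately before the first CDS
#' base. Minus strand: the reverse complement of the `length` bases
#' immediately after the CDS's rightmost base. Truncated with a warning at
#' contig edges.
#'
#' @param gene One row of a gene-model data.frame (needs `chrom`, `strand`,
#'   `cds_start`, `cds_end`).
#' @param genome A `Biostrings::DNAStringSet` (or named character vector)
#'   keyed by chromosome.
#' @param length Promoter length in bp (default 1500).
#' @return Upstream sequence as a character scalar (promoter 5'->3' on the
#'   coding strand).
#' @export
extract_promoter <- function(gene, genome, length = 1500L) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (!gene$chrom %in% names(genome))
    stop("chromosome '", gene$chrom, "' not present in genome")
  if (is.na(gene$cds_start) || is.na(gene$cds_end))
    stop("gene '", gene$gene_id, "' has no CDS; cannot anchor promoter")
  chrom <- genome[[gene$chrom]]
  clen <- Biostrings::nchar(chrom)
  if (gene$strand == "+") {
    to <- gene$cds_start - 1L
    from <- max(1L, to - length + 1L)
    if (to < 1L) stop("no upstream sequence before CDS start")
    if (to - from + 1L < length)
      warning("promoter truncated to ", to - from + 1L, " bp at contig edge")
    as.character(Biostrings::subseq(chrom, from, to))
  } else if (gene$strand == "-") {
    from <- gene$cds_end + 1L
    to <- min(clen, from + length - 1L)
    if (from > clen) stop("no upstream sequence after CDS end")
    if (to - from + 1L < length)
      warning("promoter truncated to ", to - from + 1L, " bp at contig edge")
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(chrom, from, to)))
  } else stop("unknown strand '", gene$strand, "'")
}

#' Scan a promoter for CARE motifs
#'
#' Every window matching the IUPAC-expanded consensus is reported on each
#' scanned strand. Minus-strand hits are occurrences of the reverse
#' complement of the consensus; `offset` is always the 1-based position of
#' the window's leftmost base within the promoter.
#'
#' @param promoter Nucleotide string (A/C/G/T).
#' @param motifs Motif data.frame from [care_motifs()].
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return Data.frame: `motif`, `category`, `strand`, `offset`, `match`
#'   (promoter-strand sequence of the window), sorted by offset then motif
#'   name then strand.
#' @export
scan_cares <- function(promoter, motifs = care_motifs(), both_strands = TRUE) {
  bad <- grepl("[^ACGTRYSWKMBDHVN]", motifs$consensus)
  if (any(bad))
    stop("invalid IUPAC code in motif(s): ",
         paste(motifs$name[bad], collapse = ", "))
  subject <- Biostrings::DNAString(promoter)
  one <- function(name, category, pattern, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                  fixed = FALSE)
    if (length(m) == 0) return(NULL)
    data.frame(motif = name, category = category, strand = strand,
               offset = BiocGenerics::start(m),
               match = as.character(m))
  }
  res <- list()
  for (k in seq_len(nrow(motifs))) {
    res[[length(res) + 1L]] <-
      one(motifs$name[k], motifs$category[k], motifs$consensus[k], "+")
    if (both_strands) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motifs$consensus[k])))
      res[[length(res) + 1L]] <-
        one(motifs$name[k], motifs$category[k], rc, "-")
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(motif = character(), category = character(),
                      strand = character(), offset = integer(),
                      match = character()))
  out <- out[order(out$offset, out$motif, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Scan many promoters
#'
#' @param promoters Named character vector of promoter sequences (names are
#'   gene ids).
#' @inheritParams scan_cares
#' @return Data.frame as [scan_cares()] with a leading `gene_id` column.
#' @export
scan_promoters <- function(promoters, motifs = care_motifs(),
                           both_strands = TRUE) {
  out <- lapply(names(promoters), function(g) {
    h <- scan_cares(promoters[[g]], motifs, both_strands)
    if (nrow(h)) cbind(gene_id = g, h) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), motif = character(),
                      category = character(), strand = character(),
                      offset = integer(), match = character())
  rownames(out) <- NULL
  out
}

#' Per-gene CARE category summary
#'
#' Counts distinct motif names per category per gene: multiple hits of one
#' motif count once, matching how surveys list which elements a promoter
#' "contains". Instance counts are exposed alongside.
#'
#' @param hits Data.frame from [scan_promoters()] (needs `gene_id`, `motif`,
#'   `category`).
#' @param motifs Motif dictionary, used to enumerate categories so genes
#'   with no hits get explicit zeros.
#' @param gene_ids Optional vector of all gene ids to report (zeros for
#'   genes with no hits).
#' @return Data.frame: `gene_id`, `category`, `n_distinct_motifs`,
#'   `n_instances`.
#' @export
care_summary <- function(hits, motifs = care_motifs(), gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- unique(hits$gene_id)
  cats <- sort(unique(motifs$category))
  grid <- expand.grid(gene_id = gene_ids, category = cats,
                      stringsAsFactors = FALSE)
  grid$n_distinct_motifs <- 0L
  grid$n_instances <- 0L
  if (nrow(hits)) {
    key <- paste(hits$gene_id, hits$category)
    dist <- tapply(hits$motif, key, function(m) length(unique(m)))
    inst <- tapply(hits$motif, key, length)
    gkey <- paste(grid$gene_id, grid$category)
    hit <- gkey %in% names(dist)
    grid$n_distinct_motifs[hit] <- as.integer(dist[gkey[hit]])
    grid$n_instances[hit] <- as.integer(inst[gkey[hit]])
  }
  grid[order(grid$gene_id, grid$category), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Write promoter hits as TSV and promoter-relative GFF3
#'
#' @param hits Data.frame from [scan_promoters()].
#' @param tsv_path,gff3_path Output paths (`NULL` to skip either).
#' @export
write_care_hits <- function(hits, tsv_path = NULL, gff3_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(hits, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(gff3_path)) {
    con <- file(gff3_path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    if (nrow(hits)) {
      lines <- sprintf("%s\twrkysurvey\tregulatory_region\t%d\t%d\t.\t%s\t.\tName=%s;category=%s",
                       hits$gene_id, hits$offset,
                       hits$offset + nchar(hits$match) - 1L,
                       hits$strand, hits$motif, hits$category)
      writeLines(lines, con)
    }
  }
  invisible(hits)
}
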