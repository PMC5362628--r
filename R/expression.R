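# qRT-PCR 2^-ddCT analysis and tissue-atlas breadth summaries.
#
# Four-sample drought design: LOI/LTD (tolerant genotype, optimal
# irrigation / terminal drought) and NOI/NTD (sensitive genotype). Fold
# changes follow the signed convention: ratio r reported as +r when r >= 1
# and -1/r when r < 1, so a halving prints as -2.00. Regulation calls use
# |FC| >= threshold (default 2).

QPCR_SAMPLES <- c("LOI", "LTD", "NOI", "NTD")
QPCR_COMPARISONS <- c("LOI_LTD", "NOI_NTD", "LOI_NOI")

#' Read a long-format qRT-PCR CT table
#'
#' @param path CSV with columns `sample`, `gene`, `replicate`, `ct`.
#' @param reference_gene Internal control gene id (default "Skip16").
#' @return Data.frame of class `qpcr_table` (attribute `reference_gene`).
#' @export
read_qpcr <- function(path, reference_gene = "Skip16") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_qpcr(tab, reference_gene)
}

#' Validate a qRT-PCR CT table
#'
#' Checks CT values lie in (0, 45), every (sample, gene) has >= 3
#' replicates, and the reference gene is present in every sample.
#'
#' @param tab Data.frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @inheritParams read_qpcr
#' @return The table, classed `qpcr_table`.
#' @export
validate_qpcr <- function(tab, reference_gene = "Skip16") {
  stopifnot(all(c("sample", "gene", "replicate", "ct") %in% names(tab)))
  if (any(tab$ct <= 0 | tab$ct >= 45))
    stop("CT values must lie in (0, 45)")
  nrep <- table(paste(tab$sample, tab$gene))
  if (any(nrep < 3))
    stop("every (sample, gene) needs >= 3 replicates")
  for (s in unique(tab$sample))
    if (!reference_gene %in% tab$gene[tab$sample == s])
      stop("reference gene '", reference_gene, "' missing from sample ", s)
  attr(tab, "reference_gene") <- reference_gene
  class(tab) <- c("qpcr_table", class(tab))
  tab
}

#' Signed 2^-ddCT fold change for one gene and comparison
#'
#' Per sample, `dCT = CT(gene) - CT(reference)` per replicate (paired by
#' replicate index); `ddCT = mean dCT(treatment) - mean dCT(control)`;
#' ratio `r = 2^-ddCT`; signed fold change is `+r` when `r >= 1`, else
#' `-1/r`. The p-value is a two-sided Welch t test on the replicate dCT
#' values of the two samples.
#'
#' @param tab A validated `qpcr_table`.
#' @param gene Target gene id.
#' @param treatment,control Sample names.
#' @return List: `ratio`, `signed_fold_change`, `p_value`, `significance`
#'   (`ns`, `*` p < 0.05, `**` p < 0.01).
#' @export
ddct_fold_change <- function(tab, gene, treatment, control) {
  ref <- attr(tab, "reference_gene")
  dct <- function(s) {
    g <- tab[tab$sample == s & tab$gene == gene, ]
    r <- tab[tab$sample == s & tab$gene == ref, ]
    if (nrow(r) == 0) stop("reference gene missing in sample ", s)
    if (nrow(g) < 2) stop("fewer than 2 replicates for ", gene, " in ", s)
    g <- g[order(g$replicate), ]; r <- r[order(r$replicate), ]
    if (nrow(g) == nrow(r)) g$ct - r$ct else g$ct - mean(r$ct)
  }
  dt <- dct(treatment); dc <- dct(control)
  ddct <- mean(dt) - mean(dc)
  ratio <- 2^(-ddct)
  sfc <- if (ratio >= 1) ratio else -1 / ratio
  p <- tryCatch(stats::t.test(dt, dc)$p.value, error = function(e) NA_real_)
  sig <- if (is.na(p)) "ns" else if (p < 0.01) "**" else if (p < 0.05) "*"
         else "ns"
  list(ratio = ratio, signed_fold_change = sfc, p_value = p,
       significance = sig)
}

#' Classify a signed fold change as up/down/unchanged
#'
#' @param signed_fold_change Signed fold change (+r or -1/r convention).
#' @param threshold Magnitude threshold (default 2): `>= +threshold` is up,
#'   `<= -threshold` is down, anything else unchanged.
#' @return "up", "down" or "unchanged" (vectorised).
#' @export
classify_regulation <- function(signed_fold_change, threshold = 2) {
  ifelse(signed_fold_change >= threshold, "up",
         ifelse(signed_fold_change <= -threshold, "down", "unchanged"))
}

#' All regulation calls for a qRT-PCR table
#'
#' Runs [ddct_fold_change()] for every target gene over the three design
#' comparisons LOI->LTD, NOI->NTD and LOI->NOI, then classifies each call.
#'
#' @param tab A validated `qpcr_table`.
#' @param threshold Fold-change threshold (default 2).
#' @param comparisons Character vector drawn from
#'   `c("LOI_LTD", "NOI_NTD", "LOI_NOI")`.
#' @return Data.frame: `gene`, `comparison`, `ratio`, `signed_fold_change`,
#'   `direction`, `p_value`, `significance`.
#' @export
regulation_calls <- function(tab, threshold = 2,
                             comparisons = QPCR_COMPARISONS) {
  ref <- attr(tab, "reference_gene")
  genes <- setdiff(unique(tab$gene), ref)
  rows <- list()
  for (g in genes) {
    for (cmp in comparisons) {
      parts <- strsplit(cmp, "_")[[1]]
      fc <- ddct_fold_change(tab, g, treatment = parts[2],
                             control = parts[1])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, comparison = cmp, ratio = fc$ratio,
        signed_fold_change = fc$signed_fold_change,
        direction = classify_regulation(fc$signed_fold_change, threshold),
        p_value = fc$p_value, significance = fc$significance)
    }
  }
  do.call(rbind, rows)
}

#' Summarise regulation calls across the four-sample design
#'
#' A gene is responsive when any comparison is up/down. Up/down gene counts
#' follow the primary-direction grouping: a gene counts once, by the
#' direction of its drought-comparison (LOI->LTD / NOI->NTD) calls; genes
#' with only a genotype (LOI->NOI) call count under that direction.
#' Genotype-differential genes are those with any LOI->NOI up/down call;
#' same-pattern genes have equal, non-unchanged LOI->LTD and NOI->NTD
#' directions.
#'
#' @param calls Data.frame with columns `gene`, `comparison`, `direction`
#'   (missing comparisons may simply be absent rows or "unchanged").
#' @return List of counts: `n_responsive_genes`, `n_up`, `n_down`,
#'   `n_genotype_differential`, `n_same_pattern_both_genotypes`.
#' @export
summarize_calls <- function(calls) {
  if (nrow(calls) == 0)
    return(list(n_responsive_genes = 0L, n_up = 0L, n_down = 0L,
                n_genotype_differential = 0L,
                n_same_pattern_both_genotypes = 0L))
  key <- paste(calls$gene, calls$comparison)
  if (anyDuplicated(key)) {
    dirs <- tapply(calls$direction, key, function(d) length(unique(d)))
    if (any(dirs > 1))
      stop("conflicting duplicate calls for: ",
           paste(names(dirs)[dirs > 1], collapse = ", "))
    calls <- calls[!duplicated(key), ]
  }
  get_dir <- function(g, cmp) {
    d <- calls$direction[calls$gene == g & calls$comparison == cmp]
    if (length(d) == 0) "unchanged" else d
  }
  genes <- unique(calls$gene)
  primary <- character(0)
  responsive <- character(0)
  genotype_diff <- character(0)
  same_pattern <- character(0)
  for (g in genes) {
    d_lt <- get_dir(g, "LOI_LTD"); d_nt <- get_dir(g, "NOI_NTD")
    d_ln <- get_dir(g, "LOI_NOI")
    drought <- setdiff(c(d_lt, d_nt), "unchanged")
    all_dirs <- setdiff(c(d_lt, d_nt, d_ln), "unchanged")
    if (length(all_dirs)) responsive <- c(responsive, g)
    if (length(drought)) primary[g] <- drought[1]
    else if (d_ln != "unchanged") primary[g] <- d_ln
    if (d_ln != "unchanged") genotype_diff <- c(genotype_diff, g)
    if (d_lt != "unchanged" && d_lt == d_nt)
      same_pattern <- c(same_pattern, g)
  }
  list(n_responsive_genes = length(responsive),
       n_up = sum(primary[responsive] == "up"),
       n_down = sum(primary[responsive] == "down"),
       n_genotype_differential = length(genotype_diff),
       n_same_pattern_both_genotypes = length(same_pattern))
}

#' Load the packaged drought-response fold-change table
#'
#' The published signed fold changes for the 19 drought-responsive WRKY
#' genes across the LOI->LTD, NOI->NTD and LOI->NOI comparisons, transcribed
#' verbatim; empty cells are comparisons the source table left blank.
#'
#' @param path CSV path; default the packaged fixture.
#' @return Data.frame: `pattern`, `gene`, `fc_LOI_LTD`, `fc_NOI_NTD`,
#'   `fc_LOI_NOI`.
#' @export
load_fold_change_table <- function(path = system.file(
  "extdata", "table1_fold_changes.csv", package = "wrkysurvey")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Convert a wide fold-change table into regulation calls
#'
#' @param fc_table Data.frame as returned by [load_fold_change_table()].
#' @param threshold Fold-change threshold (default 2).
#' @return Calls data.frame suitable for [summarize_calls()]; rows only for
#'   non-missing fold changes.
#' @export
fold_change_calls <- function(fc_table, threshold = 2) {
  rows <- list()
  for (cmp in QPCR_COMPARISONS) {
    col <- paste0("fc_", cmp)
    keep <- !is.na(fc_table[[col]])
    if (!any(keep)) next
    rows[[cmp]] <- data.frame(
      gene = fc_table$gene[keep], comparison = cmp,
      signed_fold_change = fc_table[[col]][keep],
      direction = classify_regulation(fc_table[[col]][keep], threshold))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tissue-atlas breadth summary
#'
#' @param atlas Numeric matrix, genes x tissues (unique tissue names);
#'   nonnegative expression values.
#' @param threshold A gene is expressed in a tissue when value > threshold
#'   (default 0).
#' @return List: `per_tissue` (tissue, pct_expressed to 1 dp) and
#'   `per_gene` (gene, n_tissues, class: constitutive /
#'   `tissue-specific(<tissue>)` / intermediate / silent).
#' @export
atlas_summary <- function(atlas, threshold = 0) {
  stopifnot(ncol(atlas) >= 1)
  if (anyDuplicated(colnames(atlas))) stop("tissue names must be unique")
  expressed <- atlas > threshold
  per_tissue <- data.frame(
    tissue = colnames(atlas),
    pct_expressed = round(100 * colMeans(expressed), 1),
    row.names = NULL)
  n_t <- rowSums(expressed)
  cls <- character(nrow(atlas))
  for (i in seq_len(nrow(atlas))) {
    cls[i] <- if (n_t[i] == ncol(atlas)) "constitutive"
    else if (n_t[i] == 1L)
      sprintf("tissue-specific(%s)", colnames(atlas)[which(expressed[i, ])])
    else if (n_t[i] == 0L) "silent"
    else "intermediate"
  }
  per_gene <- data.frame(gene = rownames(atlas), n_tissues = n_t,
                         class = cls, row.names = NULL)
  list(per_tissue = per_tissue, per_gene = per_gene)
}
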