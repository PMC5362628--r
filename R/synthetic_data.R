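# Seeded synthetic-data generators with machine-readable ground truth.
#
# Every generator is a deterministic function of (parameters, seed), and
# each pipeline stage applied to its generator's output reproduces the
# truth table exactly at zero noise. Protein backgrounds are sampled from
# an alphabet without C, H or W, so planted heptapeptides and zinc fingers
# are provably the only matches; promoter backgrounds are rejection-sampled
# against the active motif dictionary with an independent regex matcher.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  force(code)
}

PROTEIN_BG_ALPHABET <- setdiff(AA_ALPHABET20, c("C", "H", "W"))

bg_protein <- function(n) {
  paste(sample(PROTEIN_BG_ALPHABET, n, replace = TRUE), collapse = "")
}

# one planted zinc finger with fixed spacings, background filler inside
plant_finger <- function(type = "C2H2", gap1 = 4L, gap2 = 22L) {
  last <- if (type == "C2H2") "H" else "C"
  paste0("C", bg_protein(gap1), "C", bg_protein(gap2), "H",
         bg_protein(1L), last)
}

#' Generate a synthetic proteome with planted WRKY architectures
#'
#' Each class plants its group's heptapeptide/zinc-finger architecture in a
#' random background that cannot produce spurious matches. Subgroup classes
#' (`sub2a`..`sub2e`) are built around distinct flanking-sequence centroids
#' (few point mutations per member) so phylogenetic subgroup assignment is
#' learnable from the domain windows.
#'
#' @param n_per_class Named integer vector over classes `group1`, `sub2a`,
#'   `sub2b`, `sub2c`, `sub2d`, `sub2e`, `group3`, `ungrouped`,
#'   `incomplete`, `duplicate`; missing classes default to 0.
#' @param seed RNG seed.
#' @param domain_flank Residues of centroid flank kept on each side of the
#'   planted domain in the reported `domain_seq` window (default 10).
#' @return List: `proteins` (named character vector) and `truth`
#'   (data.frame: id, class, group, subgroup, heptapeptide, hepta_start,
#'   finger_type, finger_start, domain_seq, duplicate_of, seed).
#' @export
make_proteome <- function(n_per_class, seed = 1L, domain_flank = 10L) {
  classes <- c("group1", "sub2a", "sub2b", "sub2c", "sub2d", "sub2e",
               "group3", "ungrouped", "incomplete", "duplicate")
  counts <- stats::setNames(integer(length(classes)), classes)
  counts[names(n_per_class)] <- as.integer(n_per_class)
  stopifnot(all(counts >= 0))
  with_seed(seed, {
    proteins <- character(0)
    rows <- list()
    # per-subgroup centroids: flanks around a fixed-spacing C2H2 domain
    sub_cfg <- list(
      sub2a = list(variant = "WRKYGQK", gap1 = 5L, gap2 = 23L),
      sub2b = list(variant = "WRKYGQK", gap1 = 5L, gap2 = 23L),
      sub2c = list(variant = "WRKYGKK", gap1 = 5L, gap2 = 23L),
      sub2d = list(variant = "WRKYGQK", gap1 = 5L, gap2 = 23L),
      sub2e = list(variant = "WRKYGQK", gap1 = 5L, gap2 = 23L))
    centroids <- lapply(sub_cfg, function(cfg) {
      list(pre = bg_protein(domain_flank + 15L),
           mid = bg_protein(8L),
           finger = plant_finger("C2H2", cfg$gap1, cfg$gap2),
           post = bg_protein(domain_flank + 15L))
    })
    mutate_bg <- function(s, k = 3L) {
      ch <- strsplit(s, "")[[1]]
      idx <- sample(seq_along(ch), min(k, length(ch)))
      for (i in idx) ch[i] <- sample(PROTEIN_BG_ALPHABET, 1L)
      paste(ch, collapse = "")
    }
    add <- function(id, class, seqparts, group, subgroup, variant,
                    finger_type, dup_of = NA_character_) {
      # seqparts: list(prefix, hepta, mid, finger, suffix [, hepta2 ...])
      seqn <- paste(unlist(seqparts$parts), collapse = "")
      proteins[[id]] <<- seqn
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, class = class, group = group, subgroup = subgroup,
        heptapeptide = variant, hepta_start = seqparts$hepta_start,
        finger_type = finger_type, finger_start = seqparts$finger_start,
        domain_seq = seqparts$domain_seq, duplicate_of = dup_of)
    }
    idn <- 0L
    next_id <- function(class) {
      idn <<- idn + 1L
      sprintf("SYN%03d_%s", idn, class)
    }
    build_single <- function(variant, finger, prefix, mid, suffix,
                             flank = domain_flank) {
      hepta_start <- nchar(prefix) + 1L
      finger_start <- hepta_start + nchar(variant) + nchar(mid)
      domain <- paste0(variant, mid, finger)
      dstart <- max(1L, hepta_start - flank)
      full <- paste0(prefix, domain, suffix)
      dend <- min(nchar(full), hepta_start + nchar(domain) - 1L + flank)
      list(parts = list(prefix, domain, suffix),
           hepta_start = hepta_start, finger_start = finger_start,
           domain_seq = substr(full, dstart, dend))
    }
    for (cl in classes) {
      for (k in seq_len(counts[[cl]])) {
        if (cl == "group1") {
          prefix <- bg_protein(sample(10:40, 1))
          mid1 <- bg_protein(8L); mid2 <- bg_protein(8L)
          f1 <- plant_finger("C2H2", 4L, 22L)
          f2 <- plant_finger("C2H2", 4L, 23L)
          linker <- bg_protein(sample(20:35, 1))
          suffix <- bg_protein(sample(10:40, 1))
          h1 <- nchar(prefix) + 1L
          d1 <- paste0("WRKYGQK", mid1, f1)
          h2 <- nchar(prefix) + nchar(d1) + nchar(linker) + 1L
          d2 <- paste0("WRKYGQK", mid2, f2)
          full <- paste0(prefix, d1, linker, d2, suffix)
          id <- next_id(cl)
          proteins[[id]] <- full
          rows[[length(rows) + 1L]] <- data.frame(
            id = id, class = cl, group = "1", subgroup = "none",
            heptapeptide = "WRKYGQK;WRKYGQK",
            hepta_start = h1, finger_type = "C2H2;C2H2",
            finger_start = h1 + 7L + nchar(mid1),
            domain_seq = substr(full, max(1L, h1 - domain_flank),
                                h2 + nchar(d2) - 1L + domain_flank),
            duplicate_of = NA_character_)
        } else if (cl %in% names(sub_cfg)) {
          cfg <- sub_cfg[[cl]]
          cen <- centroids[[cl]]
          sp <- build_single(cfg$variant,
                             plant_finger("C2H2", cfg$gap1, cfg$gap2),
                             paste0(bg_protein(sample(5:20, 1)),
                                    mutate_bg(cen$pre)),
                             cen$mid,
                             paste0(mutate_bg(cen$post),
                                    bg_protein(sample(5:20, 1))))
          # subgroup members share the centroid finger too, so domain
          # windows differ only in the mutated flanks
          add(next_id(cl), cl, sp, "2", sub("sub", "", cl), cfg$variant,
              "C2H2")
        } else if (cl == "group3") {
          sp <- build_single("WRKYGQK", plant_finger("C2HC", 7L, 23L),
                             bg_protein(sample(10:40, 1)), bg_protein(8L),
                             bg_protein(sample(10:40, 1)))
          add(next_id(cl), cl, sp, "3", "none", "WRKYGQK", "C2HC")
        } else if (cl %in% c("ungrouped", "incomplete")) {
          variant <- if (cl == "ungrouped") "WKKYCEDK" else "WRKYGQK"
          prefix <- bg_protein(sample(10:40, 1))
          suffix <- bg_protein(sample(70:90, 1))
          full <- paste0(prefix, variant, suffix)
          id <- next_id(cl)
          proteins[[id]] <- full
          rows[[length(rows) + 1L]] <- data.frame(
            id = id, class = cl, group = "ungrouped", subgroup = "none",
            heptapeptide = variant, hepta_start = nchar(prefix) + 1L,
            finger_type = NA_character_, finger_start = NA_integer_,
            domain_seq = NA_character_, duplicate_of = NA_character_)
        } else if (cl == "duplicate") {
          if (length(proteins) == 0L)
            stop("duplicate class requires at least one other protein")
          src <- names(proteins)[1]
          tr <- do.call(rbind, rows)
          srcrow <- tr[tr$id == src, ]
          id <- next_id(cl)
          proteins[[id]] <- proteins[[src]]
          srcrow$id <- id; srcrow$class <- cl; srcrow$duplicate_of <- src
          rows[[length(rows) + 1L]] <- srcrow
        }
      }
    }
    truth <- do.call(rbind, rows)
    if (!is.null(truth)) { truth$seed <- seed; rownames(truth) <- NULL }
    else truth <- data.frame()
    list(proteins = unlist(proteins), truth = truth)
  })
}

#' Generate a synthetic genome: FASTA + GFF3 + cluster truth
#'
#' Plants family-gene clusters that satisfy the cluster rule strictly
#' (member gaps sampled below `rule$max_gap_bp`, at most 3 intervening
#' non-family genes) and isolated family genes that violate it by
#' construction (every non-cluster family neighbour is at least
#' `2 * max_gap_bp` away). Remaining genes are non-family filler.
#'
#' @param n_chroms Number of chromosomes.
#' @param n_genes Total genes.
#' @param n_family Family genes (>= sum of `cluster_spec`).
#' @param cluster_spec Integer vector of planted cluster sizes (each >= 2).
#' @param seed RNG seed.
#' @param rule A [cluster_rule()]; planted distances are drawn against it.
#' @param fasta_path,gff3_path Output paths; `NULL` skips writing FASTA
#'   (coordinates and GFF3 are always produced).
#' @return List: `genes` (gene-model data.frame as [read_gene_models()]),
#'   `truth` (gene_id, chrom, start, end, strand, is_family, cluster_id,
#'   n_exons, seed), `gff3_path`, `fasta_path`, `chrom_lengths`.
#' @export
make_genome <- function(n_chroms = 3L, n_genes = 60L, n_family = 12L,
                        cluster_spec = c(2L, 3L), seed = 1L,
                        rule = cluster_rule(),
                        fasta_path = NULL, gff3_path = tempfile(fileext = ".gff3")) {
  stopifnot(n_family <= n_genes, all(cluster_spec >= 2))
  if (sum(cluster_spec) > n_family)
    stop("cluster_spec needs more family genes than n_family provides")
  with_seed(seed, {
    n_iso <- n_family - sum(cluster_spec)
    # family units: clusters (with sizes) and isolated singletons
    units <- c(lapply(cluster_spec, function(s) list(type = "cluster", size = s)),
               replicate(n_iso, list(type = "isolated", size = 1L),
                         simplify = FALSE))
    unit_chrom <- rep_len(seq_len(n_chroms), length(units))
    n_filler <- n_genes - n_family
    gene_rows <- list()
    gid <- 0L
    fam_i <- 0L
    clu_i <- 0L
    filler_left <- n_filler
    new_gene <- function(chrom, start, is_family, cluster_id) {
      gid <<- gid + 1L
      n_ex <- sample(1:5, 1L)
      glen <- sample(900:4000, 1L)
      # exon grid: split span into 2*n_ex-1 chunks, odd chunks are exons
      bounds <- sort(sample(seq.int(start + 30L, start + glen - 30L),
                            2L * n_ex - 2L))
      edges <- c(start, bounds, start + glen)
      ex <- cbind(start = edges[seq(1, 2 * n_ex - 1, by = 2)],
                  end = edges[seq(2, 2 * n_ex, by = 2)] -
                    c(rep(1L, n_ex - 1L), 0L))
      id <- if (is_family) { fam_i <<- fam_i + 1L; sprintf("FAM%03d", fam_i) }
            else sprintf("GENE%04d", gid)
      list(gene_id = id, chrom = chrom, start = start,
           end = start + glen, strand = sample(c("+", "-"), 1L),
           exons = ex, is_family = is_family, cluster_id = cluster_id,
           n_exons = n_ex)
    }
    cursor <- stats::setNames(rep(2000L, n_chroms),
                              sprintf("CHR%d", seq_len(n_chroms)))
    place <- function(chrom, is_family, cluster_id = NA_character_) {
      g <- new_gene(chrom, cursor[[chrom]], is_family, cluster_id)
      gene_rows[[length(gene_rows) + 1L]] <<- g
      cursor[[chrom]] <<- g$end + 1L
      g
    }
    advance <- function(chrom, gap) cursor[[chrom]] <<- cursor[[chrom]] + gap
    big_gap <- 2L * rule$max_gap_bp
    for (u in seq_along(units)) {
      chrom <- sprintf("CHR%d", unit_chrom[u])
      advance(chrom, big_gap + sample(1000:20000, 1L))
      if (units[[u]]$type == "isolated") {
        place(chrom, TRUE)
      } else {
        clu_i <- clu_i + 1L
        cid <- paste0("TRUECLU", clu_i)
        place(chrom, TRUE, cid)
        for (m in seq_len(units[[u]]$size - 1L)) {
          n_int <- min(sample(0:3, 1L), filler_left,
                       rule$max_intervening_genes)
          # place intervening filler genes inside the inter-member gap;
          # total gap stays far below max_gap_bp by construction
          for (f in seq_len(n_int)) {
            advance(chrom, sample(2000:10000, 1L))
            place(chrom, FALSE)
            filler_left <- filler_left - 1L
          }
          advance(chrom, sample(2000:30000, 1L))
          place(chrom, TRUE, cid)
        }
      }
    }
    # remaining filler genes: far from any family unit
    while (filler_left > 0L) {
      chrom <- sprintf("CHR%d", sample(n_chroms, 1L))
      advance(chrom, big_gap + sample(1000:5000, 1L))
      place(chrom, FALSE)
      filler_left <- filler_left - 1L
    }
    # enforce the planted cluster invariant: no planted neighbour pair may
    # exceed the rule (cheap audit; construction keeps gaps far below it)
    truth <- data.frame(
      gene_id = vapply(gene_rows, `[[`, "", "gene_id"),
      chrom = vapply(gene_rows, `[[`, "", "chrom"),
      start = vapply(gene_rows, function(g) as.integer(g$start), 0L),
      end = vapply(gene_rows, function(g) as.integer(g$end), 0L),
      strand = vapply(gene_rows, `[[`, "", "strand"),
      is_family = vapply(gene_rows, `[[`, TRUE, "is_family"),
      cluster_id = vapply(gene_rows, `[[`, "", "cluster_id"),
      n_exons = vapply(gene_rows, function(g) as.integer(g$n_exons), 0L),
      seed = seed)
    chrom_lengths <- vapply(sprintf("CHR%d", seq_len(n_chroms)),
                            function(ch) {
                              ends <- truth$end[truth$chrom == ch]
                              as.integer(if (length(ends)) max(ends) + 2000L
                                         else 10000L)
                            }, 0L)
    write_gff3(gene_rows, gff3_path, chrom_lengths)
    if (!is.null(fasta_path)) {
      seqs <- Biostrings::DNAStringSet(vapply(chrom_lengths, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), ""))
      names(seqs) <- names(chrom_lengths)
      Biostrings::writeXStringSet(seqs, fasta_path)
    }
    genes <- read_gene_models(gff3_path)
    genes$is_family_member <- truth$is_family[match(genes$gene_id,
                                                    truth$gene_id)]
    list(genes = genes, truth = truth, gff3_path = gff3_path,
         fasta_path = fasta_path, chrom_lengths = chrom_lengths)
  })
}

# deterministic GFF3 writer for generated annotations (gene/mRNA/exon/CDS)
write_gff3 <- function(gene_rows, path, chrom_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ch in names(chrom_lengths))
    writeLines(sprintf("##sequence-region %s 1 %d", ch, chrom_lengths[[ch]]),
               con)
  ord <- order(vapply(gene_rows, `[[`, "", "chrom"),
               vapply(gene_rows, function(g) as.integer(g$start), 0L))
  for (g in gene_rows[ord]) {
    l <- function(type, s, e, attrs)
      sprintf("%s\twrkysurvey\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, type, s, e, g$strand, attrs)
    lines <- c(l("gene", g$start, g$end, paste0("ID=", g$gene_id)),
               l("mRNA", g$start, g$end,
                 paste0("ID=", g$gene_id, ".1;Parent=", g$gene_id)))
    for (i in seq_len(nrow(g$exons))) {
      lines <- c(lines,
                 l("exon", g$exons[i, "start"], g$exons[i, "end"],
                   paste0("ID=", g$gene_id, ".1.exon", i, ";Parent=",
                          g$gene_id, ".1")),
                 l("CDS", g$exons[i, "start"], g$exons[i, "end"],
                   paste0("ID=", g$gene_id, ".1.cds", i, ";Parent=",
                          g$gene_id, ".1")))
    }
    writeLines(lines, con)
  }
  invisible(path)
}

NON_STOP_CODONS <- local({
  nts <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(nts, nts, paste0), nts, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

codon_variants <- function(codon, gc) {
  nts <- c("A", "C", "G", "T")
  syn <- character(0); nonsyn <- character(0)
  for (p in 1:3) for (b in setdiff(nts, substr(codon, p, p))) {
    alt <- codon; substr(alt, p, p) <- b
    if (gc[[alt]] == "*") next
    if (gc[[alt]] == gc[[codon]]) syn <- c(syn, alt) else nonsyn <- c(nonsyn, alt)
  }
  list(syn = syn, nonsyn = nonsyn)
}

#' Generate ortholog CDS pairs with controlled Ka and Ks
#'
#' Sequence A is random non-stop codons; sequence B plants synonymous and
#' nonsynonymous single-nucleotide substitutions on disjoint codons at
#' densities matching the targets in expectation: the substitution
#' proportions are the Jukes-Cantor inverses `p = 3/4 (1 - exp(-4 d / 3))`
#' of the target rates, scaled by the NG86 site counts of sequence A.
#'
#' @param n_pairs Number of pairs.
#' @param n_codons Codons per sequence (>= 50).
#' @param target_ks,target_ka Target synonymous/nonsynonymous rates (>= 0).
#' @param seed RNG seed.
#' @return List: `pairs` (data.frame id_a, id_b, cds_a, cds_b) and `truth`
#'   (per pair: planted substitution counts, targets, seed).
#' @export
make_ortholog_pairs <- function(n_pairs = 20L, n_codons = 500L,
                                target_ks = 0.25, target_ka = 0.05,
                                seed = 1L) {
  stopifnot(n_codons >= 50L, target_ks >= 0, target_ka >= 0)
  gc <- genetic_code()
  inv_jc <- function(d) 0.75 * (1 - exp(-4 * d / 3))
  with_seed(seed, {
    pairs <- list(); rows <- list()
    for (k in seq_len(n_pairs)) {
      codons <- sample(NON_STOP_CODONS, n_codons, replace = TRUE)
      vars <- lapply(codons, codon_variants, gc = gc)
      S_A <- sum(vapply(codons, codon_syn_sites, 0, gc = gc))
      N_A <- 3 * n_codons - S_A
      n_s <- round(inv_jc(target_ks) * S_A)
      n_n <- round(inv_jc(target_ka) * N_A)
      can_syn <- which(lengths(lapply(vars, `[[`, "syn")) > 0)
      syn_idx <- sample(can_syn, min(n_s, length(can_syn)))
      can_non <- setdiff(which(lengths(lapply(vars, `[[`, "nonsyn")) > 0),
                         syn_idx)
      non_idx <- sample(can_non, min(n_n, length(can_non)))
      codons_b <- codons
      for (i in syn_idx)
        codons_b[i] <- sample(vars[[i]]$syn, 1L)
      for (i in non_idx)
        codons_b[i] <- sample(vars[[i]]$nonsyn, 1L)
      pairs[[k]] <- data.frame(
        id_a = sprintf("ORTHA%03d", k), id_b = sprintf("ORTHB%03d", k),
        cds_a = paste(codons, collapse = ""),
        cds_b = paste(codons_b, collapse = ""))
      rows[[k]] <- data.frame(
        id_a = pairs[[k]]$id_a, id_b = pairs[[k]]$id_b,
        n_codons = n_codons, planted_syn = length(syn_idx),
        planted_nonsyn = length(non_idx), target_ks = target_ks,
        target_ka = target_ka, S_A = S_A, N_A = N_A, seed = seed)
    }
    list(pairs = do.call(rbind, pairs), truth = do.call(rbind, rows))
  })
}

#' Generate a qRT-PCR CT table with planted signed fold changes
#'
#' The reference gene's CT is constant (20) across samples up to noise;
#' each target's dCT in a sample is offset by `-log2(r)` relative to its
#' control, following the LOI -> LTD, LOI -> NOI, NOI -> NTD design paths.
#'
#' @param design Data.frame: `gene`, `fc_LOI_LTD`, `fc_NOI_NTD`,
#'   `fc_LOI_NOI` (signed fold changes; `NA` means +1, i.e. no change).
#' @param noise_sd CT noise standard deviation (0 = exact recovery).
#' @param n_reps Replicates per (sample, gene), >= 3.
#' @param seed RNG seed.
#' @param reference_gene Reference gene id (default "Skip16").
#' @return List: `table` (validated `qpcr_table`) and `truth` (the design
#'   with NA replaced by +1, plus noise_sd, n_reps, seed).
#' @export
make_qpcr <- function(design, noise_sd = 0.15, n_reps = 3L, seed = 1L,
                      reference_gene = "Skip16") {
  stopifnot(n_reps >= 3L)
  to_ratio <- function(fc) {
    fc[is.na(fc)] <- 1
    ifelse(fc >= 1, fc, -1 / fc)
  }
  with_seed(seed, {
    r_lt <- to_ratio(design$fc_LOI_LTD)
    r_nt <- to_ratio(design$fc_NOI_NTD)
    r_ln <- to_ratio(design$fc_LOI_NOI)
    base <- 5  # target dCT in the LOI reference condition
    dct <- cbind(LOI = rep(base, nrow(design)),
                 LTD = base - log2(r_lt),
                 NOI = base - log2(r_ln),
                 NTD = base - log2(r_ln) - log2(r_nt))
    rows <- list()
    for (s in QPCR_SAMPLES) {
      for (rep in seq_len(n_reps)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, gene = reference_gene, replicate = rep,
          ct = 20 + stats::rnorm(1, 0, noise_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, gene = design$gene, replicate = rep,
          ct = 20 + dct[, s] + stats::rnorm(nrow(design), 0, noise_sd))
      }
    }
    tab <- do.call(rbind, rows)
    truth <- data.frame(gene = design$gene,
                        fc_LOI_LTD = ifelse(r_lt >= 1, r_lt, -1 / r_lt),
                        fc_NOI_NTD = ifelse(r_nt >= 1, r_nt, -1 / r_nt),
                        fc_LOI_NOI = ifelse(r_ln >= 1, r_ln, -1 / r_ln),
                        noise_sd = noise_sd, n_reps = n_reps, seed = seed)
    list(table = validate_qpcr(tab, reference_gene), truth = truth)
  })
}

iupac_regex <- function(consensus) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[strsplit(consensus, "")[[1]]], collapse = "")
}

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  vapply(x, function(s)
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = ""), "")
}

# regex-based motif finder, independent of the Biostrings scan path
regex_motif_hits <- function(seqn, motifs) {
  hits <- list()
  for (k in seq_len(nrow(motifs))) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") motifs$consensus[k]
             else revcomp_chr(motifs$consensus[k])
      rx <- paste0("(?=", iupac_regex(pat), ")")
      m <- gregexpr(rx, seqn, perl = TRUE)[[1]]
      if (m[1] != -1L)
        hits[[length(hits) + 1L]] <- data.frame(
          motif = motifs$name[k], strand = strand, offset = as.integer(m),
          len = nchar(motifs$consensus[k]))
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) data.frame(motif = character(), strand = character(),
                               offset = integer(), len = integer())
  else out
}

#' Generate motif-free promoters with planted CARE instances
#'
#' Backgrounds are rejection-sampled until an independent regex matcher
#' finds no dictionary motif on either strand; planted motifs are concrete
#' instantiations of their IUPAC consensus inserted at the requested
#' offsets (reverse-complemented for minus-strand plantings). Guarantees:
#' every planting is recovered at its offset, and no scan hit falls outside
#' a planted window (complementary motif pairs, e.g. TGACG/CGTCA, produce
#' the expected paired hits inside planted windows).
#'
#' @param n Number of promoters.
#' @param length Promoter length in bp (default 1500).
#' @param plantings Data.frame: `promoter` (1..n), `motif`, `offset`
#'   (1-based), `strand` ("+"/"-"). Overlapping plantings are an error.
#' @param seed RNG seed.
#' @param motifs Motif dictionary (see [care_motifs()]).
#' @return List: `promoters` (named character vector PROM1..n) and `truth`
#'   (plantings with instantiated sequences and seed).
#' @export
make_promoters <- function(n, length = 1500L, plantings = NULL, seed = 1L,
                           motifs = care_motifs()) {
  if (is.null(plantings))
    plantings <- data.frame(promoter = integer(), motif = character(),
                            offset = integer(), strand = character())
  stopifnot(all(plantings$promoter %in% seq_len(n)),
            all(plantings$motif %in% motifs$name),
            all(plantings$strand %in% c("+", "-")))
  lens <- nchar(motifs$consensus[match(plantings$motif, motifs$name)])
  if (any(plantings$offset < 1 | plantings$offset + lens - 1L > length))
    stop("planted motifs must fit within the promoter")
  for (p in unique(plantings$promoter)) {
    pl <- plantings[plantings$promoter == p, ]
    L <- nchar(motifs$consensus[match(pl$motif, motifs$name)])
    iv <- cbind(pl$offset, pl$offset + L - 1L)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      stop("overlapping plantings in promoter ", p)
  }
  with_seed(seed, {
    nts <- c("A", "C", "G", "T")
    clean_background <- function() {
      s <- paste(sample(nts, length, replace = TRUE), collapse = "")
      for (iter in 1:100) {
        h <- regex_motif_hits(s, motifs)
        if (nrow(h) == 0L) return(s)
        ch <- strsplit(s, "")[[1]]
        for (i in seq_len(nrow(h))) {
          w <- seq.int(h$offset[i], h$offset[i] + h$len[i] - 1L)
          ch[w] <- sample(nts, base::length(w), replace = TRUE)
        }
        s <- paste(ch, collapse = "")
      }
      stop("could not construct a motif-free background")
    }
    instantiate <- function(consensus) {
      opts <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                   Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                   K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                   D = c("A", "G", "T"), H = c("A", "C", "T"),
                   V = c("A", "C", "G"), N = nts)
      paste(vapply(strsplit(consensus, "")[[1]],
                   function(x) {
                     o <- opts[[x]]
                     if (base::length(o) == 1L) o else sample(o, 1L)
                   }, ""),
            collapse = "")
    }
    proms <- character(n)
    truth_rows <- list()
    for (p in seq_len(n)) {
      pl <- plantings[plantings$promoter == p, , drop = FALSE]
      ok <- FALSE
      for (attempt in 1:50) {
        s <- clean_background()
        ch <- strsplit(s, "")[[1]]
        inst <- character(nrow(pl))
        win <- integer(0)
        for (i in seq_len(nrow(pl))) {
          cons <- motifs$consensus[motifs$name == pl$motif[i]]
          inst[i] <- instantiate(cons)
          insert <- if (pl$strand[i] == "+") inst[i]
                    else revcomp_chr(inst[i])
          w <- seq.int(pl$offset[i], pl$offset[i] + nchar(cons) - 1L)
          ch[w] <- strsplit(insert, "")[[1]]
          win <- c(win, w)
        }
        s <- paste(ch, collapse = "")
        h <- regex_motif_hits(s, motifs)
        covered <- rep(FALSE, nrow(h))
        if (nrow(h))
          covered <- vapply(seq_len(nrow(h)), function(i)
            all(seq.int(h$offset[i], h$offset[i] + h$len[i] - 1L) %in% win),
            TRUE)
        planted_found <- all(vapply(seq_len(nrow(pl)), function(i)
          any(h$motif == pl$motif[i] & h$strand == pl$strand[i] &
                h$offset == pl$offset[i]), TRUE))
        if (all(covered) && planted_found) { ok <- TRUE; break }
      }
      if (!ok) stop("could not realise plantings for promoter ", p)
      proms[p] <- s
      if (nrow(pl))
        truth_rows[[base::length(truth_rows) + 1L]] <-
          cbind(pl, instance = inst)
    }
    names(proms) <- sprintf("PROM%d", seq_len(n))
    truth <- do.call(rbind, truth_rows)
    if (is.null(truth))
      truth <- data.frame(promoter = integer(), motif = character(),
                          offset = integer(), strand = character(),
                          instance = character())
    truth$seed <- if (nrow(truth)) seed else integer(0)
    list(promoters = proms, truth = truth)
  })
}

#' Generate a tissue atlas with planted breadth classes
#'
#' @param breadth Character vector over genes: "constitutive",
#'   "tissue-specific", "intermediate" or "silent".
#' @param tissues Tissue names (default the nine-organ legume atlas set).
#' @param seed RNG seed.
#' @return List: `atlas` (genes x tissues matrix) and `truth` (gene, class,
#'   specific_tissue, seed).
#' @export
make_atlas <- function(breadth, tissues = c(
  "young trifoliates", "leaves", "flower buds", "flowers",
  "green mature pods", "young pods", "roots", "stems", "nodules"),
  seed = 1L) {
  with_seed(seed, {
    n <- base::length(breadth)
    atlas <- matrix(0, n, base::length(tissues),
                    dimnames = list(sprintf("GENE%03d", seq_len(n)), tissues))
    spec <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      if (breadth[i] == "constitutive") {
        atlas[i, ] <- stats::runif(base::length(tissues), 1, 100)
      } else if (breadth[i] == "tissue-specific") {
        t <- sample(base::length(tissues), 1L)
        atlas[i, t] <- stats::runif(1, 1, 100)
        spec[i] <- tissues[t]
      } else if (breadth[i] == "intermediate") {
        k <- sample(2:(base::length(tissues) - 1L), 1L)
        atlas[i, sample(base::length(tissues), k)] <-
          stats::runif(k, 1, 100)
      } else if (breadth[i] != "silent") {
        stop("unknown breadth class: ", breadth[i])
      }
    }
    list(atlas = atlas,
         truth = data.frame(gene = rownames(atlas), class = breadth,
                            specific_tissue = spec, seed = seed))
  })
}
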