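# WRKY domain identification and family classification.
#
# A WRKY protein is recognised by (i) a near-invariant heptapeptide
# (canonically WRKYGQK, with rarer variants) and (ii) a downstream
# zinc-finger motif whose Cys/His spacing separates groups 1-2 (C2H2,
# Cx4-5 Cx22-23 HxH) from group 3 (C2HC, Cx7 Cx23 HxC). Identification here
# is deterministic pattern matching, so every call is reproducible and
# testable against exhaustive oracles.

#' Default heptapeptide variant set
#'
#' The canonical WRKYGQK heptapeptide plus the variant forms observed in
#' legume WRKY families. WKKYCEDK is treated literally as an eight-residue
#' variant.
#'
#' @return Character vector of exact-match peptide motifs.
#' @export
default_heptapeptides <- function() {
  c("WRKYGQK", "WRKYGKK", "WRKYGEK", "WKKYEDK", "WKKYCEDK")
}

#' Scan configuration for WRKY domain identification
#'
#' @param allowed_heptapeptides Exact-match peptide motifs marking the start
#'   of a WRKY domain. Users may extend the set (e.g. WSKY/WVKY forms)
#'   without code changes.
#' @param finger_search_window Maximum number of residues between the end of
#'   a heptapeptide and the first Cys of its zinc finger. The default (60)
#'   mirrors the canonical ~60-residue span of the WRKY domain.
#' @param evalue_threshold Placeholder threshold for an optional external
#'   profile-HMM pre-screen (default 1e-5). The in-package scan is
#'   deterministic pattern matching and does not use it.
#' @param require_complete_domain If `TRUE`, [dedupe_and_filter()] drops
#'   proteins without at least one complete (heptapeptide + finger) domain.
#' @return A list of class `wrky_scan_config`.
#' @export
scan_config <- function(allowed_heptapeptides = default_heptapeptides(),
                        finger_search_window = 60L,
                        evalue_threshold = 1e-5,
                        require_complete_domain = TRUE) {
  stopifnot(length(allowed_heptapeptides) >= 1,
            finger_search_window >= 1)
  structure(list(allowed_heptapeptides = toupper(allowed_heptapeptides),
                 finger_search_window = as.integer(finger_search_window),
                 evalue_threshold = evalue_threshold,
                 require_complete_domain = isTRUE(require_complete_domain)),
            class = "wrky_scan_config")
}

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_protein_sequence <- function(sequence, allow_x = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("protein sequence must be a non-empty character scalar")
  allowed <- c(AA_ALPHABET20, if (allow_x) "X")
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), allowed)
  if (length(bad))
    stop("non-alphabet character(s) in protein sequence: ",
         paste(bad, collapse = ", "))
  invisible(sequence)
}

#' Locate heptapeptide variants in a protein
#'
#' Reports every exact occurrence of each allowed heptapeptide variant,
#' including overlapping occurrences of different variants.
#'
#' @param sequence Uppercase amino-acid string (20 canonical letters + X).
#' @param cfg A [scan_config()].
#' @return A data.frame with columns `variant`, `start` (1-based),
#'   `end` (1-based, inclusive), ordered by `start` then `variant`.
#' @export
find_heptapeptides <- function(sequence, cfg = scan_config()) {
  check_protein_sequence(sequence)
  hits <- lapply(cfg$allowed_heptapeptides, function(v) {
    m <- gregexpr(v, sequence, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(variant = v, start = as.integer(m),
               end = as.integer(m) + nchar(v) - 1L)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    return(data.frame(variant = character(), start = integer(),
                      end = integer()))
  out <- out[order(out$start, out$variant), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Candidate (gap1, gap2, gap3, type) spacings, in preference order for a
# fixed first-Cys position: smaller gap1 first, C2H2 before C2HC on a tie.
zf_spacings <- function() {
  data.frame(
    type = c("C2H2", "C2H2", "C2H2", "C2H2", "C2HC"),
    gap1 = c(4L, 4L, 5L, 5L, 7L),
    gap2 = c(22L, 23L, 22L, 23L, 23L),
    gap3 = c(1L, 1L, 1L, 1L, 1L),
    last = c("H", "H", "H", "H", "C"))
}

#' Find the first zinc-finger motif at or after a position
#'
#' Searches for C2H2 (Cx4-5 Cx22-23 HxH) or C2HC (Cx7 Cx23 HxC) spacings
#' whose first Cys lies in `[from_index, from_index + window - 1]`. The
#' leftmost first-Cys match wins; at the same Cys, smaller spacings are
#' preferred and C2H2 beats C2HC on an exact tie.
#'
#' @param sequence Protein sequence.
#' @param from_index 1-based position at which the search window opens.
#' @param cfg A [scan_config()]; `finger_search_window` bounds the first Cys.
#' @return `NULL` if absent, else a list with `type`, `start` (first Cys,
#'   1-based), `end` (last coordinating residue), and `spacings = c(gap1,
#'   gap2, gap3)`.
#' @export
find_zinc_finger <- function(sequence, from_index = 1L, cfg = scan_config()) {
  check_protein_sequence(sequence)
  n <- nchar(sequence)
  if (from_index < 1L || from_index > n)
    stop("from_index outside sequence")
  chars <- strsplit(sequence, "")[[1]]
  sp <- zf_spacings()
  last_c1 <- min(n, from_index + cfg$finger_search_window - 1L)
  for (c1 in seq.int(from_index, last_c1)) {
    if (chars[c1] != "C") next
    for (k in seq_len(nrow(sp))) {
      c2 <- c1 + sp$gap1[k] + 1L
      h1 <- c2 + sp$gap2[k] + 1L
      x2 <- h1 + sp$gap3[k] + 1L
      if (x2 > n) next
      if (chars[c2] == "C" && chars[h1] == "H" && chars[x2] == sp$last[k]) {
        return(list(type = sp$type[k], start = c1, end = x2,
                    spacings = c(gap1 = sp$gap1[k], gap2 = sp$gap2[k],
                                 gap3 = sp$gap3[k])))
      }
    }
  }
  NULL
}

#' Scan one protein for WRKY domains
#'
#' Composes [find_heptapeptides()] and [find_zinc_finger()]: each
#' heptapeptide hit is paired with the first zinc finger found downstream of
#' its end (within the configured window). Hits with no finger are reported
#' with `complete = FALSE`.
#'
#' @inheritParams find_heptapeptides
#' @return A data.frame with one row per heptapeptide occurrence: columns
#'   `heptapeptide`, `hepta_start`, `hepta_end`, `finger_type`,
#'   `finger_start`, `finger_end`, `gap1`, `gap2`, `gap3`, `complete`.
#' @export
scan_protein <- function(sequence, cfg = scan_config()) {
  hp <- find_heptapeptides(sequence, cfg)
  n <- nrow(hp)
  out <- data.frame(
    heptapeptide = character(n), hepta_start = integer(n),
    hepta_end = integer(n), finger_type = rep(NA_character_, n),
    finger_start = rep(NA_integer_, n), finger_end = rep(NA_integer_, n),
    gap1 = rep(NA_integer_, n), gap2 = rep(NA_integer_, n),
    gap3 = rep(NA_integer_, n), complete = logical(n))
  if (n == 0L) return(out)
  for (i in seq_len(n)) {
    out$heptapeptide[i] <- hp$variant[i]
    out$hepta_start[i] <- hp$start[i]
    out$hepta_end[i] <- hp$end[i]
    from <- hp$end[i] + 1L
    zf <- if (from <= nchar(sequence))
      find_zinc_finger(sequence, from, cfg) else NULL
    if (!is.null(zf)) {
      out$finger_type[i] <- zf$type
      out$finger_start[i] <- zf$start
      out$finger_end[i] <- zf$end
      out$gap1[i] <- zf$spacings[["gap1"]]
      out$gap2[i] <- zf$spacings[["gap2"]]
      out$gap3[i] <- zf$spacings[["gap3"]]
      out$complete[i] <- TRUE
    }
  }
  out
}

#' Classify a protein into WRKY groups from its domain hits
#'
#' Two complete C2H2 domains give group 1; one complete C2H2 gives group 2
#' (subgroup assignment needs a phylogenetic reference panel, see
#' [assign_subgroup()]); one complete C2HC gives group 3. Proteins whose
#' heptapeptide lacks a classifiable finger, or with no hits, or with an
#' architecture outside those rules, are left ungrouped with an explanatory
#' note.
#'
#' @param hits Data.frame from [scan_protein()], position-sorted.
#' @return A list with `group` ("1", "2", "3" or "ungrouped"), `subgroup`
#'   ("none" at this stage), `n_domains` (complete domains), `notes`.
#' @export
classify_protein <- function(hits) {
  comp <- hits[hits$complete, , drop = FALSE]
  nC <- nrow(comp)
  note <- ""
  if (nrow(hits) > 0 && nC > 0) {
    # N- vs C-terminal finger sub-spacings recorded, not used for grouping
    note <- paste0("fingers: ", paste(sprintf("%s(Cx%dCx%d)", comp$finger_type,
                                              comp$gap1, comp$gap2),
                                      collapse = ","))
  }
  if (nC == 2L && all(comp$finger_type == "C2H2")) {
    return(list(group = "1", subgroup = "none", n_domains = 2L, notes = note))
  }
  if (nC == 1L && comp$finger_type == "C2H2") {
    return(list(group = "2", subgroup = "none", n_domains = 1L, notes = note))
  }
  if (nC == 1L && comp$finger_type == "C2HC") {
    return(list(group = "3", subgroup = "none", n_domains = 1L, notes = note))
  }
  reason <- if (nrow(hits) == 0L) {
    "no heptapeptide found"
  } else if (nC == 0L) {
    "heptapeptide(s) without classifiable zinc finger"
  } else {
    sprintf("unusual architecture: %d complete domains (%s)", nC,
            paste(comp$finger_type, collapse = ","))
  }
  list(group = "ungrouped", subgroup = "none", n_domains = nrow(hits),
       notes = paste(c(reason, if (nzchar(note)) note), collapse = "; "))
}

#' Scan a whole proteome
#'
#' @param proteins Named character vector of sequences, or a
#'   `Biostrings::AAStringSet`.
#' @param cfg A [scan_config()].
#' @return A list with `hits` (named list of per-protein hit tables) and
#'   `classification` (data.frame: id, group, subgroup, n_domains, notes).
#' @export
scan_proteome <- function(proteins, cfg = scan_config()) {
  proteins <- as_protein_vector(proteins)
  hits <- lapply(proteins, scan_protein, cfg = cfg)
  cls <- lapply(hits, classify_protein)
  classification <- data.frame(
    id = names(proteins),
    group = vapply(cls, `[[`, "", "group"),
    subgroup = vapply(cls, `[[`, "", "subgroup"),
    n_domains = vapply(cls, `[[`, 0L, "n_domains"),
    notes = vapply(cls, `[[`, "", "notes"),
    row.names = NULL)
  list(hits = hits, classification = classification)
}

as_protein_vector <- function(proteins) {
  if (methods::is(proteins, "XStringSet")) {
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  }
  if (is.null(names(proteins)) || anyDuplicated(names(proteins)))
    stop("proteins must have unique names (ids)")
  proteins
}

#' Collapse duplicates and drop incomplete family members
#'
#' Exact-duplicate sequences are collapsed to one record (the
#' lexicographically smallest id is kept). When the configuration requires a
#' complete domain, proteins without one are removed. Survivors are renamed
#' `<prefix>1..N`, ordered by chromosome then coordinate when gene models
#' are supplied, else by input order.
#'
#' @param proteins Named character vector (or `AAStringSet`) of sequences.
#' @param classification Classification data.frame from [scan_proteome()],
#'   aligned to `proteins` by id.
#' @param cfg A [scan_config()].
#' @param gene_models Optional gene-model data.frame (see
#'   [read_gene_models()]) used to order survivors genomically; matched to
#'   proteins by id.
#' @param prefix Name stem for renamed survivors.
#' @return Data.frame: `new_id`, `id` (original), `sequence`, `group`,
#'   `subgroup`, `n_domains`, `dropped_duplicates` (comma-separated ids).
#' @export
dedupe_and_filter <- function(proteins, classification, cfg = scan_config(),
                              gene_models = NULL, prefix = "WRKY") {
  proteins <- as_protein_vector(proteins)
  stopifnot(setequal(names(proteins), classification$id))
  classification <- classification[match(names(proteins), classification$id), ]

  # collapse exact duplicates, keeping the lexicographically smallest id
  keep <- logical(length(proteins))
  dropped <- stats::setNames(vector("list", length(proteins)), names(proteins))
  by_seq <- split(names(proteins), unname(proteins))
  for (ids in by_seq) {
    ids <- sort(ids)
    keep[match(ids[1], names(proteins))] <- TRUE
    if (length(ids) > 1L) dropped[[ids[1]]] <- ids[-1]
  }
  surv <- names(proteins)[keep]

  if (cfg$require_complete_domain) {
    complete <- classification$group != "ungrouped" |
      grepl("unusual architecture", classification$notes)
    names(complete) <- classification$id
    surv <- surv[complete[surv]]
  }

  if (!is.null(gene_models)) {
    gm <- gene_models[match(surv, gene_models$gene_id), ]
    ord <- order(gm$chrom, gm$start, surv)
  } else {
    ord <- order(match(surv, names(proteins)))
  }
  surv <- surv[ord]
  out <- data.frame(
    new_id = paste0(prefix, seq_along(surv)),
    id = surv,
    sequence = unname(proteins[surv]),
    group = classification$group[match(surv, classification$id)],
    subgroup = classification$subgroup[match(surv, classification$id)],
    n_domains = classification$n_domains[match(surv, classification$id)],
    dropped_duplicates = vapply(dropped[surv], function(d)
      paste(d, collapse = ","), ""),
    row.names = NULL)
  out
}

# -- protein features (MW, pI, ORF) -----------------------------------------

#' Average residue masses (Da) for the 20 canonical amino acids
#' @return Named numeric vector of monomer (residue) masses.
#' @export
residue_masses <- function() {
  c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
}

#' Bjellqvist-style pKa table used for isoelectric-point calculation
#'
#' The set used by common pI web calculators; editable by passing a modified
#' copy to [protein_features()]. `nterm`/`cterm` are the free termini.
#'
#' @return Named numeric vector of pKa values.
#' @export
default_pka <- function() {
  c(nterm = 7.50, cterm = 3.55,
    C = 9.00, D = 4.05, E = 4.45, H = 5.98, K = 10.00, R = 12.00, Y = 10.00)
}

net_charge <- function(counts, pH, pka) {
  pos <- c("nterm", "H", "K", "R")
  neg <- c("cterm", "C", "D", "E", "Y")
  q <- 0
  for (g in pos) if (counts[[g]] > 0)
    q <- q + counts[[g]] / (1 + 10^(pH - pka[[g]]))
  for (g in neg) if (counts[[g]] > 0)
    q <- q - counts[[g]] / (1 + 10^(pka[[g]] - pH))
  q
}

#' Compute basic protein features: length, MW, pI, ORF length
#'
#' Molecular weight is the sum of average residue masses plus one water
#' (18.0153 Da), reported in kDa. The isoelectric point is solved by
#' bisection on the Henderson-Hasselbalch net charge (termini plus
#' D, E, C, Y, H, K, R side chains) until |charge| < 1e-4. ORF length is
#' 3*(length + 1) nt (coding triplets plus stop).
#'
#' @param sequence Protein sequence; the 20 canonical residues only
#'   (`X` is rejected with an error naming the residue).
#' @param pka Named pKa table, see [default_pka()].
#' @return List: `length`, `molecular_weight_kda`, `isoelectric_point`,
#'   `orf_length_nt`.
#' @export
protein_features <- function(sequence, pka = default_pka()) {
  check_protein_sequence(sequence, allow_x = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  masses <- residue_masses()
  mw_da <- sum(masses[chars]) + 18.0153
  counts <- as.list(table(factor(chars, levels = AA_ALPHABET20)))
  counts$nterm <- 1L
  counts$cterm <- 1L
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(counts, mid, pka)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-12) break
    if (q > 0) lo <- mid else hi <- mid
  }
  list(length = length(chars),
       molecular_weight_kda = mw_da / 1000,
       isoelectric_point = mid,
       orf_length_nt = 3L * (length(chars) + 1L))
}

# -- I/O ---------------------------------------------------------------------

#' Read a protein FASTA into a named character vector
#'
#' Trailing/internal `*` stop characters are stripped with a warning.
#'
#' @param path FASTA file (wrapped or single-line).
#' @return Named character vector of uppercase sequences.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- sub("\\s.*$", "", names(aa))
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("'*' stop characters stripped from input sequences")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  seqs
}

#' Write the per-protein family table
#'
#' One row per protein: id, domain count, heptapeptide variants, finger
#' types and spacings, group, MW (kDa, 2 dp), pI (2 dp).
#'
#' @param proteins Named character vector of sequences.
#' @param scan Result of [scan_proteome()] on the same proteins.
#' @param path Output TSV path.
#' @return Invisibly, the data.frame written.
#' @export
write_family_table <- function(proteins, scan, path) {
  proteins <- as_protein_vector(proteins)
  cls <- scan$classification
  feats <- lapply(proteins, function(s) {
    if (grepl("X", s, fixed = TRUE))
      list(molecular_weight_kda = NA_real_, isoelectric_point = NA_real_)
    else protein_features(s)
  })
  rowfor <- function(id) {
    h <- scan$hits[[id]]
    c(id = id,
      n_domains = as.character(cls$n_domains[cls$id == id]),
      variants = paste(h$heptapeptide, collapse = ","),
      fingers = paste(stats::na.omit(sprintf("%s(%d,%d,%d)", h$finger_type,
                                             h$gap1, h$gap2, h$gap3)),
                      collapse = ","),
      group = cls$group[cls$id == id],
      mw_kda = sprintf("%.2f", feats[[id]]$molecular_weight_kda),
      pi = sprintf("%.2f", feats[[id]]$isoelectric_point))
  }
  tab <- as.data.frame(do.call(rbind, lapply(names(proteins), rowfor)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Export full hit coordinates as JSON
#'
#' 1-based inclusive coordinates for every heptapeptide and finger hit.
#'
#' @param scan Result of [scan_proteome()].
#' @param path Output JSON path.
#' @export
write_hits_json <- function(scan, path) {
  jsonlite::write_json(scan$hits, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
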