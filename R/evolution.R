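# Ortholog divergence: protein-guided codon alignment, Nei-Gojobori (1986)
# Ka/Ks with Jukes-Cantor correction, and synonymous-rate molecular dating.
#
# Throughout, Ka = nonsynonymous substitutions per nonsynonymous site and
# Ks = synonymous substitutions per synonymous site (the standard letter
# assignment; a well-known erratum in parts of the survey literature swaps
# the letters in prose).

#' Default protein alignment scoring scheme
#'
#' BLOSUM62 with affine gaps: a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`.
#'
#' @param gap_open Cost of a gap of length 1 (default 10).
#' @param gap_extend Cost of each additional gapped position (default 0.5).
#' @return List with `matrix`, `gap_open`, `gap_extend`.
#' @export
alignment_scoring <- function(gap_open = 10, gap_extend = 0.5) {
  blosum62 <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  list(matrix = blosum62, gap_open = gap_open, gap_extend = gap_extend)
}

#' Needleman-Wunsch global protein alignment with affine gaps
#'
#' Gotoh three-state dynamic programming with a deterministic traceback
#' preferring diagonal over up (gap in the second sequence) over left.
#'
#' @param seq_a,seq_b Protein sequences (non-empty, but either may be empty
#'   relative to the other; both empty is an error).
#' @param scoring Scheme from [alignment_scoring()].
#' @return List: `aligned_a`, `aligned_b` (equal-length strings with `-`
#'   gaps), `score`.
#' @export
align_proteins_global <- function(seq_a, seq_b,
                                  scoring = alignment_scoring()) {
  a <- strsplit(seq_a, "")[[1]]; b <- strsplit(seq_b, "")[[1]]
  n <- length(a); m <- length(b)
  if (n == 0L && m == 0L) stop("both sequences empty")
  go <- scoring$gap_open; ge <- scoring$gap_extend
  S <- scoring$matrix
  NEG <- -1e18
  gapcost <- function(L) if (L == 0L) 0 else go + (L - 1L) * ge
  # M: a[i] aligned to b[j]; X: gap in b (consume a, "up"); Y: gap in a
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -gapcost(i)
  for (j in seq_len(m)) Y[1L, j + 1L] <- -gapcost(j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- S[a[i], b[j]]
      M[i + 1L, j + 1L] <- sub +
        max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <-
        max(M[i, j + 1L] - go, X[i, j + 1L] - ge, Y[i, j + 1L] - go)
      Y[i + 1L, j + 1L] <-
        max(M[i + 1L, j] - go, Y[i + 1L, j] - ge, X[i + 1L, j] - go)
    }
  }
  # traceback from best final state (preference M > X > Y on ties)
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  finals <- c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  state <- c("M", "X", "Y")[which.max(finals)]
  score <- max(finals)
  while (i > 0L || j > 0L) {
    if (state == "M") {
      sub <- S[a[i], b[j]]
      ra <- c(a[i], ra); rb <- c(b[j], rb)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- c("M", "X", "Y")[which.max(prev)]
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      ra <- c(a[i], ra); rb <- c("-", rb)
      cand <- c(M[i, j + 1L] - go, X[i, j + 1L] - ge, Y[i, j + 1L] - go)
      state <- if (i == 1L && j == 0L) "M" else c("M", "X", "Y")[which.max(cand)]
      i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(b[j], rb)
      cand <- c(M[i + 1L, j] - go, Y[i + 1L, j] - ge, X[i + 1L, j] - go)
      state <- if (j == 1L && i == 0L) "M" else c("M", "X", "Y")[which.max(cand)]
      j <- j - 1L
    }
    if (i == 0L && j > 0L) state <- "Y"
    if (j == 0L && i > 0L) state <- "X"
  }
  list(aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""),
       score = score)
}

strip_stop <- function(cds, protein_len) {
  if (nchar(cds) == 3L * protein_len + 3L) {
    last <- toupper(substr(cds, nchar(cds) - 2L, nchar(cds)))
    if (last %in% c("TAA", "TAG", "TGA"))
      cds <- substr(cds, 1L, nchar(cds) - 3L)
  }
  cds
}

translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}

#' Thread CDS codons through a protein alignment
#'
#' Each aligned residue column becomes its source codon; residue gaps become
#' `---`. A trailing stop codon on either CDS is stripped.
#'
#' @param aln Protein alignment from [align_proteins_global()].
#' @param cds_a,cds_b Coding sequences whose translations equal the
#'   ungapped aligned proteins.
#' @return List of class `codon_pair_alignment`: `codons_a`, `codons_b`
#'   (character vectors of triplets or `---`), `n_ungapped_codon_columns`.
#' @export
thread_codons <- function(aln, cds_a, cds_b) {
  pa <- gsub("-", "", aln$aligned_a, fixed = TRUE)
  pb <- gsub("-", "", aln$aligned_b, fixed = TRUE)
  cds_a <- strip_stop(toupper(cds_a), nchar(pa))
  cds_b <- strip_stop(toupper(cds_b), nchar(pb))
  for (side in list(list(p = pa, c = cds_a, n = "a"),
                    list(p = pb, c = cds_b, n = "b"))) {
    if (nchar(side$c) != 3L * nchar(side$p))
      stop("cds_", side$n, " length is not 3x the protein length")
    tr <- translate_cds(side$c)
    if (tr != side$p) {
      k <- which(strsplit(tr, "")[[1]] != strsplit(side$p, "")[[1]])[1]
      stop(sprintf("translation of cds_%s disagrees with protein at residue %d (%s vs %s)",
                   side$n, k, substr(tr, k, k), substr(side$p, k, k)))
    }
  }
  split_codons <- function(cds) substring(cds, seq(1, nchar(cds), 3),
                                          seq(3, nchar(cds), 3))
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  cols_a <- strsplit(aln$aligned_a, "")[[1]]
  cols_b <- strsplit(aln$aligned_b, "")[[1]]
  ia <- 0L; ib <- 0L
  out_a <- character(length(cols_a)); out_b <- character(length(cols_b))
  for (k in seq_along(cols_a)) {
    if (cols_a[k] == "-") out_a[k] <- "---"
    else { ia <- ia + 1L; out_a[k] <- ca[ia] }
    if (cols_b[k] == "-") out_b[k] <- "---"
    else { ib <- ib + 1L; out_b[k] <- cb[ib] }
  }
  structure(list(codons_a = out_a, codons_b = out_b,
                 n_ungapped_codon_columns =
                   sum(out_a != "---" & out_b != "---")),
            class = "codon_pair_alignment")
}

GENETIC_CODE_TAB <- NULL
genetic_code <- function() {
  Biostrings::GENETIC_CODE
}

# Fraction of the 3 possible changes at each codon position that are
# synonymous; changes creating stop codons count as nonsynonymous, so every
# codon contributes exactly 3 sites and S + N = 3 x columns.
codon_syn_sites <- function(codon, gc = genetic_code()) {
  aa <- gc[[codon]]
  nts <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(nts, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      if (gc[[alt]] != "*" && gc[[alt]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# Average synonymous/nonsynonymous difference counts between two codons over
# all minimal substitution pathways, excluding pathways through stop codons.
codon_diffs <- function(ca, cb, gc = genetic_code()) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(pos) else {
    if (k == 2L) list(pos, rev(pos)) else {
      # all 6 orderings of 3 positions
      idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      lapply(idx, function(o) pos[o])
    }
  }
  step_class <- function(from, to) {
    if (gc[[from]] == gc[[to]]) "s" else "n"
  }
  sds <- numeric(0); nds <- numeric(0)
  for (ord in perms) {
    cur <- ca; sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (gc[[nxt]] == "*") { ok <- FALSE; break }
      if (step_class(cur, nxt) == "s") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { sds <- c(sds, sd); nds <- c(nds, nd) }
  }
  if (length(sds) == 0L) {
    # every pathway passes a stop; classify each position change in isolation
    sd <- 0; nd <- 0
    for (p in pos) {
      alt <- ca
      substr(alt, p, p) <- substr(cb, p, p)
      if (gc[[alt]] != "*" && gc[[alt]] == gc[[ca]]) sd <- sd + 1
      else nd <- nd + 1
    }
    return(c(sd = sd, nd = nd))
  }
  c(sd = mean(sds), nd = mean(nds))
}

jukes_cantor <- function(p) -0.75 * log(1 - 4 * p / 3)

#' Nei-Gojobori (1986) Ka/Ks estimation on a codon pair alignment
#'
#' Synonymous site fractions are averaged over the two sequences; codons
#' differing at several positions average their synonymous/nonsynonymous
#' difference counts over all minimal substitution pathways (pathways through
#' stop codons excluded). Proportions are Jukes-Cantor corrected,
#' `d = -(3/4) ln(1 - 4p/3)`; `p >= 3/4` raises a saturation flag instead of
#' an estimate.
#'
#' @param aln A `codon_pair_alignment` from [thread_codons()].
#' @return List of class `kaks_result`: `S`, `N` (site counts), `sd`, `nd`
#'   (difference counts), `ps`, `pn`, `ks`, `ka`, `ratio` (Ka/Ks; `NA` with
#'   `ratio_undefined = TRUE` when Ks = 0), `saturated`.
#' @export
ng86_kaks <- function(aln) {
  gc <- genetic_code()
  keep <- aln$codons_a != "---" & aln$codons_b != "---"
  ca <- aln$codons_a[keep]; cb <- aln$codons_b[keep]
  if (length(ca) == 0L) stop("no ungapped codon columns")
  if (any(vapply(ca, function(x) gc[[x]], "") == "*") ||
      any(vapply(cb, function(x) gc[[x]], "") == "*"))
    stop("internal stop codon in alignment")
  Sa <- sum(vapply(ca, codon_syn_sites, 0, gc = gc))
  Sb <- sum(vapply(cb, codon_syn_sites, 0, gc = gc))
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  d <- mapply(function(x, y) codon_diffs(x, y, gc), ca, cb)
  sd <- sum(d["sd", ]); nd <- sum(d["nd", ])
  ps <- if (S > 0) sd / S else 0
  pn <- if (N > 0) nd / N else 0
  saturated <- ps >= 0.75 || pn >= 0.75
  ks <- if (ps >= 0.75) NA_real_ else jukes_cantor(ps)
  ka <- if (pn >= 0.75) NA_real_ else jukes_cantor(pn)
  ratio_undefined <- is.na(ks) || ks == 0
  ratio <- if (!ratio_undefined && !is.na(ka)) ka / ks else NA_real_
  structure(list(S = S, N = N, sd = sd, nd = nd, ps = ps, pn = pn,
                 ks = ks, ka = ka, ratio = ratio,
                 ratio_undefined = ratio_undefined, saturated = saturated),
            class = "kaks_result")
}

#' Molecular dating configuration
#' @param lambda Substitutions per synonymous site per year (default
#'   6.1e-9, the legume synonymous substitution rate).
#' @return List of class `dating_config`.
#' @export
dating_config <- function(lambda = 6.1e-9) {
  stopifnot(lambda > 0)
  structure(list(lambda = lambda), class = "dating_config")
}

#' Divergence time from synonymous divergence: T = Ks / (2 lambda)
#'
#' @param ks Synonymous substitutions per synonymous site (>= 0).
#' @param cfg A [dating_config()].
#' @return Time in years.
#' @export
divergence_time <- function(ks, cfg = dating_config()) {
  if (any(ks < 0, na.rm = TRUE)) stop("ks must be nonnegative")
  ks / (2 * cfg$lambda)
}

#' Full ortholog-pair Ka/Ks + dating table
#'
#' Aligns translated proteins, threads codons, runs NG86 and dates each
#' pair. The estimator behind this table is NG86 counting (recorded in the
#' table's attributes as `estimator`).
#'
#' @param cds_pairs Data.frame with columns `id_a`, `id_b`, `cds_a`,
#'   `cds_b`.
#' @param cfg A [dating_config()].
#' @param scoring An [alignment_scoring()].
#' @return Data.frame: ids, S, N, sd, nd, ka, ks, ratio, t_years.
#' @export
kaks_table <- function(cds_pairs, cfg = dating_config(),
                       scoring = alignment_scoring()) {
  rows <- lapply(seq_len(nrow(cds_pairs)), function(i) {
    a_cds <- drop_trailing_stop(toupper(cds_pairs$cds_a[i]))
    b_cds <- drop_trailing_stop(toupper(cds_pairs$cds_b[i]))
    pa <- translate_cds(a_cds); pb <- translate_cds(b_cds)
    aln <- align_proteins_global(pa, pb, scoring)
    cpa <- thread_codons(aln, a_cds, b_cds)
    r <- ng86_kaks(cpa)
    data.frame(id_a = cds_pairs$id_a[i], id_b = cds_pairs$id_b[i],
               S = r$S, N = r$N, sd = r$sd, nd = r$nd,
               ka = r$ka, ks = r$ks, ratio = r$ratio,
               t_years = if (is.na(r$ks)) NA_real_
                         else divergence_time(r$ks, cfg))
  })
  out <- do.call(rbind, rows)
  attr(out, "estimator") <- "NG86 + Jukes-Cantor"
  attr(out, "lambda") <- cfg$lambda
  out
}

drop_trailing_stop <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("CDS length not a multiple of 3")
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (last %in% c("TAA", "TAG", "TGA")) substr(cds, 1L, nchar(cds) - 3L)
  else cds
}
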