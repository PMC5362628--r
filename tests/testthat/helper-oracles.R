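# Independent brute-force oracles used by the property tests. Each one
# recomputes the quantity from first principles, by a different mechanism
# than the implementation under test.

# every 7-mer/8-mer window compared against the variant set directly
oracle_heptapeptides <- function(sequence, variants) {
  n <- nchar(sequence)
  out <- list()
  for (v in variants) {
    L <- nchar(v)
    if (L > n) next
    for (i in seq_len(n - L + 1L)) {
      if (substr(sequence, i, i + L - 1L) == v)
        out[[length(out) + 1L]] <- data.frame(variant = v, start = i)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(data.frame(variant = character(), start = integer()))
  res <- res[order(res$start, res$variant), ]
  rownames(res) <- NULL
  res
}

# enumerate all (c1, c2, h1, x2) quadruples satisfying either spacing rule,
# honoring the search window and the preference order
oracle_zinc_finger <- function(sequence, from_index, window = 60L) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  specs <- list(list(type = "C2H2", g1 = 4L, g2 = 22L, last = "H"),
                list(type = "C2H2", g1 = 4L, g2 = 23L, last = "H"),
                list(type = "C2H2", g1 = 5L, g2 = 22L, last = "H"),
                list(type = "C2H2", g1 = 5L, g2 = 23L, last = "H"),
                list(type = "C2HC", g1 = 7L, g2 = 23L, last = "C"))
  cands <- list()
  for (c1 in seq.int(from_index, min(n, from_index + window - 1L))) {
    for (k in seq_along(specs)) {
      s <- specs[[k]]
      c2 <- c1 + s$g1 + 1L; h1 <- c2 + s$g2 + 1L; x2 <- h1 + 2L
      if (x2 > n) next
      if (ch[c1] == "C" && ch[c2] == "C" && ch[h1] == "H" &&
          ch[x2] == s$last)
        cands[[length(cands) + 1L]] <-
          list(start = c1, rank = k, type = s$type, g1 = s$g1, g2 = s$g2)
    }
  }
  if (length(cands) == 0L) return(NULL)
  ord <- order(vapply(cands, `[[`, 0L, "start"),
               vapply(cands, `[[`, 0L, "rank"))
  cands[[ord[1]]]
}

# pairwise-link + connected-components oracle for family clusters
oracle_clusters <- function(genes, rule) {
  fam <- which(genes$is_family_member)
  if (length(fam) < 2) return(list())
  linked <- matrix(FALSE, length(fam), length(fam))
  for (a in seq_along(fam)) for (b in seq_along(fam)) {
    if (a >= b) next
    i <- fam[a]; j <- fam[b]
    if (genes$chrom[i] != genes$chrom[j]) next
    # only *neighbouring* family genes can be linked
    between_fam <- sum(genes$is_family_member &
                         genes$chrom == genes$chrom[i] &
                         genes$start > genes$end[i] &
                         genes$end < genes$start[j])
    if (between_fam > 0) next
    gap <- genes$start[j] - genes$end[i] - 1L
    n_int <- sum(!genes$is_family_member &
                   genes$chrom == genes$chrom[i] &
                   genes$start > genes$end[i] &
                   genes$end < genes$start[j])
    if (gap < rule$max_gap_bp && n_int <= rule$max_intervening_genes)
      linked[a, b] <- linked[b, a] <- TRUE
  }
  # connected components by repeated expansion
  comp <- rep(0L, length(fam)); cid <- 0L
  for (a in seq_along(fam)) {
    if (comp[a] != 0L) next
    cid <- cid + 1L
    frontier <- a
    comp[a] <- cid
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        nb <- which(linked[f, ] & comp == 0L)
        comp[nb] <- cid
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
  }
  comps <- split(genes$gene_id[fam], comp)
  Filter(function(x) length(x) >= 2, unname(comps))
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

revcomp_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# naive per-window IUPAC membership check, vectorised over window starts
oracle_iupac_hits <- function(promoter, pattern) {
  ch <- strsplit(promoter, "")[[1]]
  n <- length(ch); L <- nchar(pattern)
  if (L > n) return(integer(0))
  starts <- seq_len(n - L + 1L)
  ok <- rep(TRUE, length(starts))
  pat <- strsplit(pattern, "")[[1]]
  for (j in seq_len(L))
    ok <- ok & ch[starts + j - 1L] %in% IUPAC_SETS[[pat[j]]]
  starts[ok]
}

oracle_care_scan <- function(promoter, motifs) {
  rows <- list()
  for (k in seq_len(nrow(motifs))) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") motifs$consensus[k]
             else revcomp_oracle(motifs$consensus[k])
      off <- oracle_iupac_hits(promoter, pat)
      if (length(off))
        rows[[length(rows) + 1L]] <- data.frame(
          motif = motifs$name[k], strand = strand, offset = off)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame(motif = character(),
                                      strand = character(),
                                      offset = integer()))
  res[order(res$offset, res$motif, res$strand), , drop = FALSE]
}

# exhaustive global-alignment enumeration: best score over every alignment
oracle_alignment_score <- function(a, b, scoring) {
  S <- scoring$matrix; go <- scoring$gap_open; ge <- scoring$gap_extend
  # state: positions consumed + whether we are inside a gap in a or b
  best <- -Inf
  rec <- function(i, j, score, gapstate) {
    if (i > nchar(a) && j > nchar(b)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= nchar(a) && j <= nchar(b))
      rec(i + 1L, j + 1L,
          score + S[substr(a, i, i), substr(b, j, j)], "none")
    if (i <= nchar(a))  # gap in b
      rec(i + 1L, j, score - if (gapstate == "b") ge else go, "b")
    if (j <= nchar(b))  # gap in a
      rec(i, j + 1L, score - if (gapstate == "a") ge else go, "a")
  }
  rec(1L, 1L, 0, "none")
  best
}

# least-squares fit of a 4-taxon distance matrix to each unrooted topology
oracle_best_quartet <- function(dm) {
  labs <- rownames(dm)
  quartets <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  d <- function(i, j) dm[min(i, j), max(i, j)]
  rss <- vapply(quartets, function(q) {
    # topology ((q1,q2),(q3,q4)) has 5 edges: 4 pendant + 1 internal
    X <- matrix(0, 6, 5)
    y <- numeric(6)
    pairs <- utils::combn(4, 2)
    for (c in seq_len(ncol(pairs))) {
      i <- pairs[1, c]; j <- pairs[2, c]
      y[c] <- d(q[i], q[j])
      X[c, i] <- 1; X[c, j] <- 1
      same_side <- (i <= 2 && j <= 2) || (i >= 3 && j >= 3)
      if (!same_side) X[c, 5] <- 1
    }
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }, 0)
  sides <- list(c(labs[1], labs[2]), c(labs[1], labs[3]), c(labs[1], labs[4]))
  sides[[which.min(rss)]]
}

# the 4-taxon split side containing the alphabetically first taxon
quartet_split <- function(tree) {
  tips <- tree$tip.label
  anchor <- sort(tips)[1]
  sets <- lapply((length(tips) + 1):(length(tips) + tree$Nnode), function(nd) {
    sort(tips[phangorn_descendants(tree, nd)])
  })
  cherries <- sets[lengths(sets) == 2]
  for (ch in cherries) if (anchor %in% ch) return(ch)
  sort(setdiff(tips, cherries[[1]]))
}

phangorn_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  out
}

random_protein <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

translate_seq <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}
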