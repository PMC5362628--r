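# Distance-based phylogeny over WRKY domain sequences: p-distance with
# pairwise deletion, Saitou-Nei neighbor joining with deterministic
# tie-breaking, bootstrap split support, and reference-guided subgroup
# assignment. Trees are ape "phylo" objects; Newick I/O goes through ape.

#' Pairwise p-distance matrix with pairwise deletion
#'
#' `d = mismatches / compared columns`; columns where either row has a gap
#' (`-`) are skipped for that pair.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = labels.
#' @export
p_distance <- function(alignment) {
  if (length(unique(nchar(alignment))) != 1L)
    stop("aligned sequences must have equal length")
  labs <- names(alignment)
  chars <- do.call(rbind, strsplit(alignment, ""))
  n <- length(alignment)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(ok))
        stop(sprintf("zero comparable columns for pair (%s, %s)",
                     labs[i], labs[j]))
      d[i, j] <- d[j, i] <- sum(chars[i, ok] != chars[j, ok]) / sum(ok)
    }
  }
  d
}

clamp_pair <- function(vi, vj) {
  # negative branch clamped to 0, deficit moved to the sibling edge
  if (vi < 0) { vj <- vj + vi; vi <- 0 }
  if (vj < 0) { vi <- max(0, vi + vj); vj <- 0 }
  c(vi, vj)
}

fmt_bl <- function(x) sprintf("%.15g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei Q-criterion agglomeration. Ties on Q are broken by the
#' lexicographically smallest (representative label) pair, so the topology
#' is deterministic. Negative branch lengths are clamped to zero with the
#' deficit moved to the sibling edge. Additive input distances are exactly
#' realised on the output tree.
#'
#' @param dm Symmetric distance matrix with labelled dimnames (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  labs <- rownames(dm)
  n <- length(labs)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  # active nodes carry a Newick fragment and a representative (min) label
  frags <- as.list(labs)
  reps <- labs
  D <- dm
  while (length(frags) > 3L) {
    m <- length(frags)
    r <- rowSums(D)
    best <- NULL; bestQ <- Inf; bestKey <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        key <- paste(sort(c(reps[i], reps[j])), collapse = "\r")
        if (q < bestQ - 1e-12 ||
            (abs(q - bestQ) <= 1e-12 && !is.null(bestKey) && key < bestKey)) {
          bestQ <- q; best <- c(i, j); bestKey <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    v <- clamp_pair(vi, vj)
    newfrag <- sprintf("(%s:%s,%s:%s)", frags[[i]], fmt_bl(v[1]),
                       frags[[j]], fmt_bl(v[2]))
    newrep <- min(reps[i], reps[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- matrix(0, m - 1L, m - 1L)
    if (length(keep)) {
      D2[seq_along(keep), seq_along(keep)] <- D[keep, keep]
      D2[m - 1L, seq_along(keep)] <- dnew[keep]
      D2[seq_along(keep), m - 1L] <- dnew[keep]
    }
    D <- D2
    frags <- c(frags[keep], newfrag)
    reps <- c(reps[keep], newrep)
  }
  # final 3-way join: closed-form branch lengths
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v1 <- max(0, v1); v2 <- max(0, v2); v3 <- max(0, v3)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frags[[1]], fmt_bl(v1),
                 frags[[2]], fmt_bl(v2), frags[[3]], fmt_bl(v3))
  ape::read.tree(text = nwk)
}

#' Neighbor-joining tree with bootstrap split support
#'
#' Alignment columns are resampled with replacement per replicate; each
#' replicate tree is rebuilt with [p_distance()] + [nj_tree()]. Support for
#' each internal split of the full-data tree is the percentage of replicate
#' trees containing that bipartition, attached as internal node labels.
#' Seeded and fully reproducible.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences.
#' @param reps Bootstrap replicates (default 1000; 0 = no supports).
#' @param seed RNG seed (default 1, recorded as attribute `seed`).
#' @return `ape::phylo` with `node.label` holding supports in \[0, 100\].
#' @export
bootstrap_support <- function(alignment, reps = 1000L, seed = 1L) {
  stopifnot(reps >= 0)
  full <- nj_tree(p_distance(alignment))
  if (reps == 0L) {
    attr(full, "seed") <- seed
    return(full)
  }
  ncols <- nchar(alignment[[1]])
  chars <- do.call(rbind, strsplit(alignment, ""))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  btrees <- vector("list", reps)
  ok <- logical(reps)
  for (b in seq_len(reps)) {
    cols <- sample.int(ncols, ncols, replace = TRUE)
    rep_aln <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
    names(rep_aln) <- names(alignment)
    t <- tryCatch(nj_tree(p_distance(rep_aln)), error = function(e) NULL)
    if (!is.null(t)) { btrees[[b]] <- t; ok[b] <- TRUE }
  }
  btrees <- btrees[ok]
  counts <- ape::prop.clades(full, btrees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / length(btrees))
  full$node.label <- as.character(support)
  attr(full, "seed") <- seed
  attr(full, "reps") <- reps
  full
}

# tip labels descending from each node of a phylo object
node_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  sets <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  # postorder guarantees children before parents
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    par <- eo[k, 1]; child <- eo[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[child]])
  }
  sets
}

#' Assign a group-2 query domain to a subgroup using a reference panel
#'
#' Builds an NJ tree over the query plus the labelled reference panel and
#' returns the tag of the smallest clade (split side) containing the query
#' whose other members all share one subgroup tag. When no pure clade
#' exists, falls back to the nearest reference by p-distance (ties broken
#' by label), flagged `nearest-neighbor fallback`.
#'
#' @param query Named length-1 character vector: the aligned query domain.
#' @param panel Named character vector of aligned reference domains,
#'   aligned to the query's coordinate system.
#' @param panel_tags Named character vector: subgroup tag per panel id
#'   (>= 2 references per tag).
#' @param group Classification of the query; anything but "2" is an error
#'   (subgroups exist only within group 2).
#' @return List: `subgroup`, `method` ("clade" or
#'   "nearest-neighbor fallback").
#' @export
assign_subgroup <- function(query, panel, panel_tags, group = "2") {
  if (!identical(as.character(group), "2"))
    stop("subgroup assignment applies only to group-2 queries")
  stopifnot(length(query) == 1L, !is.null(names(query)))
  tagtab <- table(panel_tags[names(panel)])
  if (any(tagtab < 2))
    stop("reference panel needs >= 2 references per subgroup tag")
  qid <- names(query)
  aln <- c(query, panel)
  dm <- p_distance(aln)
  tree <- nj_tree(dm)
  sets <- node_tip_sets(tree)
  all_tips <- tree$tip.label
  # both sides of every split are candidate clades
  cands <- c(sets, lapply(sets, function(s) setdiff(all_tips, s)))
  with_q <- Filter(function(s) qid %in% s && length(s) >= 2, cands)
  pure <- Filter(function(s) {
    tags <- unique(panel_tags[setdiff(s, qid)])
    length(tags) == 1L && !any(is.na(tags))
  }, with_q)
  if (length(pure)) {
    sizes <- lengths(pure)
    best <- pure[sizes == min(sizes)]
    tags <- sort(vapply(best, function(s)
      unique(panel_tags[setdiff(s, qid)]), ""))
    return(list(subgroup = tags[[1]], method = "clade"))
  }
  dq <- dm[qid, names(panel)]
  nearest <- sort(names(dq)[dq == min(dq)])[1]
  list(subgroup = unname(panel_tags[nearest]),
       method = "nearest-neighbor fallback")
}

#' Write a tree as Newick (bootstrap supports as internal node labels)
#' @param tree `ape::phylo`.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
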