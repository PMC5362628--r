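test_that("p-distance follows the pairwise-deletion definition", {
  aln <- c(a = "AAAA", b = "AATT")
  expect_equal(p_distance(aln)["a", "b"], 0.5)
  aln2 <- c(a = "A-AA", b = "AGAT")
  expect_equal(p_distance(aln2)["a", "b"], 1 / 3)
  expect_equal(p_distance(c(x = "AAAA", y = "AAAA"))["x", "y"], 0)
  expect_error(p_distance(c(x = "--AA", y = "GG--")), "zero comparable")
})

test_that("NJ recovers the 3-taxon closed form and degenerate input", {
  dm <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  cd <- cophenetic(tr)
  expect_equal(cd[rownames(dm), colnames(dm)], dm, tolerance = 1e-12)
  zero <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tz <- nj_tree(zero)
  expect_true(all(tz$edge.length == 0))
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("NJ exactly reconstructs random additive matrices (5-8 taxa)", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
    dm <- cophenetic(tr)
    dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
    rec <- nj_tree(dm)
    drec <- cophenetic(rec)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(drec - dm)), 1e-9)
    # agreement with the reference NJ implementation on path lengths
    dape <- cophenetic(ape::nj(dm))[rownames(dm), colnames(dm)]
    expect_lt(max(abs(dape - dm)), 1e-6)
  }
})

test_that("4-taxon topology matches the least-squares quartet oracle", {
  set.seed(101)
  for (rep in 1:25) {
    tr <- ape::rtree(4)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
    dm <- cophenetic(tr)
    dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
    got <- quartet_split(nj_tree(dm))
    want <- oracle_best_quartet(dm)
    # the split containing taxon 1 must agree (possibly as complement)
    labs <- rownames(dm)
    want_side <- if (labs[1] %in% want) sort(want)
                 else sort(setdiff(labs, want))
    expect_equal(got, want_side)
  }
})

test_that("label permutation yields an isomorphic tree", {
  set.seed(5)
  aln <- vapply(1:6, function(i) random_protein(60), "")
  names(aln) <- paste0("t", 1:6)
  t1 <- nj_tree(p_distance(aln))
  perm <- sample(6)
  t2 <- nj_tree(p_distance(aln[perm]))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(t1),
                                         ape::unroot(t2))[1]), 0)
})

test_that("bootstrap supports are reproducible, bounded and signal-forced", {
  gen <- make_proteome(c(sub2a = 3, sub2b = 3, sub2c = 3), seed = 9)
  aln <- stats::setNames(gen$truth$domain_seq, gen$truth$id)
  t0 <- bootstrap_support(aln, reps = 0, seed = 1)
  expect_null(t0$node.label)
  t1 <- bootstrap_support(aln, reps = 100, seed = 1)
  sup <- as.numeric(t1$node.label)
  expect_true(all(sup >= 0 & sup <= 100))
  nwk1 <- ape::write.tree(t1)
  nwk2 <- ape::write.tree(bootstrap_support(aln, reps = 100, seed = 1))
  expect_identical(nwk1, nwk2)
  # an alignment whose every column supports one split gives 100%
  aln4 <- c(a = strrep("A", 40), b = strrep("A", 40),
            c = strrep("C", 40), d = strrep("C", 40))
  t4 <- bootstrap_support(aln4, reps = 50, seed = 2)
  expect_true("100" %in% t4$node.label)
})

test_that("subgroup assignment recovers planted tags and rejects non-group-2", {
  gen <- make_proteome(c(sub2a = 4, sub2b = 4, sub2c = 4, sub2d = 4,
                         sub2e = 4), seed = 71)
  aln <- stats::setNames(gen$truth$domain_seq, gen$truth$id)
  tags <- stats::setNames(gen$truth$subgroup, gen$truth$id)
  for (q in names(aln)) {
    res <- assign_subgroup(stats::setNames(aln[q], q),
                           aln[setdiff(names(aln), q)],
                           tags[setdiff(names(aln), q)])
    expect_equal(res$subgroup, unname(tags[q]), info = q)
  }
  expect_error(assign_subgroup(stats::setNames(aln[1], names(aln)[1]),
                               aln[-1], tags[-1], group = "3"),
               "group-2")
  # identical-to-reference query is assigned that reference's tag
  q <- names(aln)[1]
  res <- assign_subgroup(stats::setNames(aln[[q]], "query"), aln, tags)
  expect_equal(res$subgroup, unname(tags[q]))
})

test_that("pathological equidistant query falls back deterministically", {
  mk <- function(blocks) paste(blocks, collapse = "")
  A <- strrep("A", 10); C <- strrep("C", 10); G <- strrep("G", 10)
  panel <- c(r2a_1 = mk(c(C, A, A)), r2b_1 = mk(c(C, A, G)),
             r2a_2 = mk(c(A, C, A)), r2b_2 = mk(c(A, C, G)))
  tags <- c(r2a_1 = "2a", r2b_1 = "2b", r2a_2 = "2a", r2b_2 = "2b")
  query <- c(q = mk(c(A, A, A)))
  r1 <- assign_subgroup(query, panel, tags)
  r2 <- assign_subgroup(query, panel[c(3, 1, 4, 2)], tags)
  expect_identical(r1, r2)
  if (r1$method == "nearest-neighbor fallback") {
    dq <- p_distance(c(query, panel))["q", names(panel)]
    nearest <- sort(names(dq)[dq == min(dq)])[1]
    expect_equal(r1$subgroup, unname(tags[nearest]))
  }
})
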