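make_gene_df <- function(chrom, start, end, fam, exon_counts = NULL) {
  n <- length(start)
  df <- data.frame(gene_id = sprintf("G%02d", seq_len(n)), chrom = chrom,
                   start = as.integer(start), end = as.integer(end),
                   strand = "+", cds_start = as.integer(start),
                   cds_end = as.integer(end), is_family_member = fam)
  df$exons <- lapply(seq_len(n), function(i)
    cbind(start = start[i], end = end[i]))
  df
}

test_that("GFF3 gene models round-trip through the reader", {
  gen <- make_genome(n_chroms = 3, n_genes = 50, n_family = 10,
                     cluster_spec = c(2, 3), seed = 21,
                     gff3_path = tempfile(fileext = ".gff3"))
  genes <- read_gene_models(gen$gff3_path)
  expect_equal(nrow(genes), 50L)
  tr <- gen$truth[order(gen$truth$chrom, gen$truth$start), ]
  expect_equal(genes$gene_id, tr$gene_id)
  expect_equal(genes$start, tr$start)
  expect_equal(genes$end, tr$end)
  expect_equal(genes$strand, tr$strand)
  expect_equal(vapply(genes$exons, nrow, 0L), tr$n_exons)
  # exons sorted, non-overlapping, within gene span
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    expect_true(all(diff(ex[, "start"]) > 0))
    expect_true(all(ex[, "start"] <= ex[, "end"]))
    expect_true(all(ex[, "start"] >= genes$start[i] &
                      ex[, "end"] <= genes$end[i]))
  }
})

test_that("longest-isoform rule keeps the mRNA with the most exonic bases", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t1000\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t1000\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tID=e1;Parent=m1",
    "chr1\tsrc\texon\t300\t400\t.\t+\t.\tID=e2;Parent=m1",
    "chr1\tsrc\tmRNA\t100\t1000\t.\t+\t.\tID=m2;Parent=g1",
    "chr1\tsrc\texon\t100\t250\t.\t+\t.\tID=e3;Parent=m2",
    "chr1\tsrc\texon\t300\t450\t.\t+\t.\tID=e4;Parent=m2",
    "chr1\tsrc\texon\t500\t600\t.\t+\t.\tID=e5;Parent=m2",
    "chr1\tsrc\texon\t700\t1000\t.\t+\t.\tID=e6;Parent=m2"), gff)
  g <- read_gene_models(gff)
  expect_equal(nrow(g$exons[[1]]), 4L)
})

test_that("structure stats follow the exon arithmetic", {
  df <- make_gene_df("c1", c(1, 100, 300, 500) * 100,
                     c(50, 150, 350, 560) * 100, rep(TRUE, 4))
  ex_counts <- c(1, 3, 7, 4)
  df$exons <- lapply(seq_len(4), function(i) {
    k <- ex_counts[i]
    s <- df$start[i] + (0:(k - 1)) * 100L
    cbind(start = s, end = s + 50L)
  })
  st <- structure_stats(df)
  expect_equal(st$per_gene$n_exons, ex_counts)
  expect_equal(st$per_gene$n_introns, ex_counts - 1L)
  expect_equal(st$family_mean_exons, 3.75)
})

test_that("cluster rule boundary cases are honoured", {
  rule <- cluster_rule()
  # 150 kb apart, 3 intervening -> one cluster
  g <- make_gene_df("c1",
                    start = c(1000, 60000, 70000, 80000, 160000),
                    end = c(9999, 61000, 71000, 81000, 170000),
                    fam = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(nrow(detect_clusters(g, rule)), 1L)
  expect_equal(detect_clusters(g, rule)$n_members, 2L)
  # 250 kb apart -> no cluster
  g2 <- make_gene_df("c1", start = c(1000, 260000),
                     end = c(9999, 270000), fam = c(TRUE, TRUE))
  expect_equal(nrow(detect_clusters(g2, rule)), 0L)
  # exactly at the gap bound: gap == max_gap_bp is not "< 200 kb"
  g3 <- make_gene_df("c1", start = c(1000, 10000 + 200000 + 1),
                     end = c(9999, 215000), fam = c(TRUE, TRUE))
  expect_equal(nrow(detect_clusters(g3, rule)), 0L)
  # 100 kb apart but 9 intervening genes -> no cluster
  starts <- c(1000, seq(15000, 95000, by = 10000), 110000)
  ends <- c(9999, seq(15000, 95000, by = 10000) + 500, 120000)
  g4 <- make_gene_df("c1", starts, ends,
                     c(TRUE, rep(FALSE, 9), TRUE))
  expect_equal(nrow(detect_clusters(g4, rule)), 0L)
  # same layout with 8 intervening -> cluster
  g5 <- make_gene_df("c1", starts[-2], ends[-2],
                     c(TRUE, rep(FALSE, 8), TRUE))
  expect_equal(nrow(detect_clusters(g5, rule)), 1L)
  # unsorted input is refused
  expect_error(detect_clusters(g[c(2, 1, 3, 4, 5), ], rule), "sorted")
})

test_that("cluster detection equals the brute-force oracle on random layouts", {
  rule <- cluster_rule()
  set.seed(77)
  for (rep in 1:30) {
    n <- 100
    chrom <- sort(sample(paste0("c", 1:3), n, replace = TRUE))
    start <- unlist(tapply(seq_len(n), chrom, function(ix)
      cumsum(sample(c(500:2000, 150000, 250000), length(ix), replace = TRUE))))
    df <- make_gene_df(chrom, start, start + sample(200:1500, n, TRUE),
                       fam = seq_len(n) %in% sample(n, 20))
    df <- df[order(df$chrom, df$start), ]
    rownames(df) <- NULL
    got <- detect_clusters(df, rule)
    want <- oracle_clusters(df, rule)
    got_sets <- lapply(strsplit(got$members, ","), sort)
    want_sets <- lapply(want, sort)
    expect_setequal(got_sets, want_sets)
    # every member in exactly one cluster
    all_members <- unlist(strsplit(got$members, ","))
    expect_false(anyDuplicated(all_members) > 0)
  }
})

test_that("tightening the cluster rule never adds clustered genes", {
  set.seed(13)
  gen <- make_genome(2, 60, 14, c(2, 2, 3), seed = 31,
                     gff3_path = tempfile(fileext = ".gff3"))
  base <- detect_clusters(gen$genes, cluster_rule())
  n_base <- sum(base$n_members)
  for (gap in c(150000, 80000, 20000)) {
    tighter <- detect_clusters(gen$genes, cluster_rule(max_gap_bp = gap))
    expect_lte(sum(tighter$n_members), n_base)
  }
  for (iv in c(4, 2, 1)) {
    tighter <- detect_clusters(gen$genes,
                               cluster_rule(max_intervening_genes = iv))
    expect_lte(sum(tighter$n_members), n_base)
  }
})

test_that("chromosome distribution percentages sum and round correctly", {
  df <- make_gene_df(rep(c("c1", "c2"), each = 5),
                     seq(1000, by = 10000, length.out = 10),
                     seq(2000, by = 10000, length.out = 10),
                     rep(TRUE, 10))
  df <- df[order(df$chrom, df$start), ]
  d <- chromosome_distribution(df)
  expect_equal(d$pct, c(50.0, 50.0))
  expect_equal(sum(d$n_family), 10L)
  one <- chromosome_distribution(make_gene_df("c9", 1000, 2000, TRUE))
  expect_equal(one$pct, 100.0)
})

test_that("planted genome clusters are recovered exactly (closed loop)", {
  gen <- make_genome(3, 80, 16, c(2, 3, 2), seed = 55,
                     gff3_path = tempfile(fileext = ".gff3"))
  got <- detect_clusters(gen$genes, cluster_rule())
  truth_sets <- lapply(split(gen$truth$gene_id[gen$truth$cluster_id != ""],
                             gen$truth$cluster_id[gen$truth$cluster_id != ""]),
                       sort)
  got_sets <- lapply(strsplit(got$members, ","), sort)
  expect_setequal(got_sets, unname(truth_sets))
  # no-family genome has no clusters
  gen0 <- make_genome(2, 20, 0, integer(0), seed = 2,
                      gff3_path = tempfile(fileext = ".gff3"))
  expect_equal(nrow(detect_clusters(gen0$genes, cluster_rule())), 0L)
})
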