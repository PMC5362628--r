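test_that("global alignment handles identity and pure-gap cases", {
  sc <- alignment_scoring()
  a <- align_proteins_global("MKVL", "MKVL", sc)
  expect_equal(a$aligned_a, "MKVL")
  expect_equal(a$aligned_b, "MKVL")
  expect_equal(a$score, sum(diag(sc$matrix[c("M", "K", "V", "L"),
                                           c("M", "K", "V", "L")])))
  g <- align_proteins_global("A", "", sc)
  expect_equal(g$aligned_b, "-")
  expect_equal(g$score, -sc$gap_open)
})

test_that("alignment scores equal the exhaustive enumeration oracle", {
  sc <- alignment_scoring()
  alphabet <- c("A", "C", "D")
  strings <- unlist(lapply(1:3, function(L)
    apply(expand.grid(rep(list(alphabet), L)), 1, paste, collapse = "")))
  set.seed(11)
  pairs <- cbind(sample(strings, 60, replace = TRUE),
                 sample(strings, 60, replace = TRUE))
  for (k in seq_len(nrow(pairs))) {
    got <- align_proteins_global(pairs[k, 1], pairs[k, 2], sc)$score
    want <- oracle_alignment_score(pairs[k, 1], pairs[k, 2], sc)
    expect_equal(got, want, info = paste(pairs[k, ], collapse = " vs "))
  }
  # a few length-4 pairs too
  s4 <- apply(expand.grid(rep(list(alphabet), 4)), 1, paste, collapse = "")
  set.seed(12)
  for (k in 1:15) {
    a <- sample(s4, 1); b <- sample(s4, 1)
    expect_equal(align_proteins_global(a, b, sc)$score,
                 oracle_alignment_score(a, b, sc))
  }
})

test_that("codon threading back-translates the protein alignment", {
  aln <- list(aligned_a = "MK", aligned_b = "MK")
  cp <- thread_codons(aln, "ATGAAA", "ATGAAG")
  expect_equal(cp$codons_a, c("ATG", "AAA"))
  expect_equal(cp$codons_b, c("ATG", "AAG"))
  expect_equal(cp$n_ungapped_codon_columns, 2L)
  # insertion becomes a gap triplet
  aln2 <- list(aligned_a = "MAK", aligned_b = "M-K")
  cp2 <- thread_codons(aln2, "ATGGCTAAA", "ATGAAA")
  expect_equal(cp2$codons_b[2], "---")
  expect_equal(cp2$n_ungapped_codon_columns, 2L)
  # trailing stop codons are stripped
  cp3 <- thread_codons(aln, "ATGAAATAA", "ATGAAGTGA")
  expect_equal(cp3$n_ungapped_codon_columns, 2L)
  # translation mismatch errors with the discordant residue
  expect_error(thread_codons(aln, "ATGGGG", "ATGAAA"), "residue 2")
})

test_that("NG86 reproduces the hand-counted glycine example", {
  ca <- rep("GGG", 10)
  cb <- c(rep("GGG", 9), "GGA")
  aln <- structure(list(codons_a = ca, codons_b = cb,
                        n_ungapped_codon_columns = 10L),
                   class = "codon_pair_alignment")
  r <- ng86_kaks(aln)
  expect_equal(r$S, 10)
  expect_equal(r$N, 20)
  expect_equal(r$sd, 1)
  expect_equal(r$nd, 0)
  expect_equal(r$ks, -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  expect_equal(r$ka, 0)
  # S + N = 3 x columns, exactly
  expect_equal(r$S + r$N, 3 * 10)
})

test_that("NG86 is symmetric and identity gives zero rates", {
  gen <- make_ortholog_pairs(3, 120, 0.2, 0.1, seed = 4)
  for (k in 1:3) {
    pa <- gen$pairs[k, ]
    aln_ab <- thread_codons(
      align_proteins_global(translate_seq(pa$cds_a), translate_seq(pa$cds_b)),
      pa$cds_a, pa$cds_b)
    aln_ba <- thread_codons(
      align_proteins_global(translate_seq(pa$cds_b), translate_seq(pa$cds_a)),
      pa$cds_b, pa$cds_a)
    r1 <- ng86_kaks(aln_ab); r2 <- ng86_kaks(aln_ba)
    expect_equal(r1$ka, r2$ka, tolerance = 1e-12)
    expect_equal(r1$ks, r2$ks, tolerance = 1e-12)
    expect_equal(r1$S, r2$S, tolerance = 1e-12)
    expect_equal(r1$S + r1$N, 3 * aln_ab$n_ungapped_codon_columns)
  }
  ident <- structure(list(codons_a = c("ATG", "AAA"),
                          codons_b = c("ATG", "AAA"),
                          n_ungapped_codon_columns = 2L),
                     class = "codon_pair_alignment")
  r0 <- ng86_kaks(ident)
  expect_equal(r0$ka, 0)
  expect_equal(r0$ks, 0)
  expect_true(r0$ratio_undefined)
  expect_error(ng86_kaks(structure(list(codons_a = "TAA", codons_b = "TAA",
                                        n_ungapped_codon_columns = 1L),
                                   class = "codon_pair_alignment")),
               "stop")
})

test_that("generator targets are recovered and ka = 0 is exact without
           nonsynonymous plantings", {
  gen <- make_ortholog_pairs(5, 500, 0.25, 0, seed = 6)
  tab <- kaks_table(gen$pairs)
  expect_true(all(tab$ka == 0))
  expect_true(all(abs(tab$ks - 0.25) / 0.25 < 0.1))
  # equal syn and nonsyn pressure pushes ka/ks toward 1
  gen2 <- make_ortholog_pairs(5, 500, 0.1, 0.1, seed = 7)
  tab2 <- kaks_table(gen2$pairs)
  expect_true(all(abs(tab2$ratio - 1) < 0.25))
})

test_that("divergence dating is the Ks/2-lambda line", {
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.122), 1.0e7)
  expect_equal(divergence_time(0.244), 2.0e7)
  # linear in ks, inverse-linear in lambda
  expect_equal(divergence_time(0.3) / divergence_time(0.1), 3)
  expect_equal(divergence_time(0.2, dating_config(lambda = 1.22e-8)),
               divergence_time(0.2) / 2)
  expect_error(divergence_time(-0.1), "nonnegative")
})
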