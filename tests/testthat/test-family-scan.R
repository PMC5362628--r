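test_that("heptapeptide finder reports planted and degenerate cases", {
  expect_equal(find_heptapeptides("MAAWRKYGQKLVK"),
               data.frame(variant = "WRKYGQK", start = 4L, end = 10L))
  expect_equal(nrow(find_heptapeptides("MAAAAA")), 0L)
  expect_error(find_heptapeptides(""), "non-empty")
  expect_error(find_heptapeptides("MAB*"), "non-alphabet")
})

test_that("heptapeptide scanner equals the exhaustive window oracle", {
  cfg <- scan_config()
  set.seed(42)
  for (i in 1:50) {
    s <- random_protein(200)
    # plant one WRKYGKK at a random position
    pos <- sample(1:(200 - 7), 1)
    substr(s, pos, pos + 6) <- "WRKYGKK"
    got <- find_heptapeptides(s, cfg)[, c("variant", "start")]
    want <- oracle_heptapeptides(s, cfg$allowed_heptapeptides)
    expect_equal(got, want)
    expect_true(any(got$variant == "WRKYGKK" & got$start == pos))
  }
})

test_that("zinc finger matching is pattern-forced for both types", {
  junk <- function(n) strrep("A", n)
  s1 <- paste0("C", junk(4), "C", junk(22), "H", junk(1), "H")
  z1 <- find_zinc_finger(s1, 1)
  expect_equal(z1$type, "C2H2")
  expect_equal(unname(z1$spacings), c(4L, 22L, 1L))
  s2 <- paste0("C", junk(7), "C", junk(23), "H", junk(1), "C")
  z2 <- find_zinc_finger(s2, 1)
  expect_equal(z2$type, "C2HC")
  expect_equal(unname(z2$spacings), c(7L, 23L, 1L))
})

test_that("zinc finger finder equals the enumeration oracle on random input", {
  set.seed(7)
  for (i in 1:100) {
    s <- random_protein(120)
    got <- find_zinc_finger(s, 1)
    want <- oracle_zinc_finger(s, 1)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$type, want$type)
      expect_equal(unname(got$spacings[1:2]), c(want$g1, want$g2))
    }
  }
})

test_that("scan_protein pairs heptapeptides with downstream fingers", {
  s <- paste0("MAA", "WRKYGQK", strrep("A", 10),
              "C", strrep("A", 4), "C", strrep("A", 22), "HAH", "QQ")
  hits <- scan_protein(s)
  expect_equal(nrow(hits), 1L)
  expect_true(hits$complete)
  expect_equal(hits$finger_type, "C2H2")
  expect_gt(hits$finger_start, hits$hepta_end)

  hits2 <- scan_protein(paste0("MAA", "WRKYGQK", strrep("A", 20)))
  expect_equal(nrow(hits2), 1L)
  expect_false(hits2$complete)
})

test_that("classification follows the group architecture rules", {
  mk <- function(type, complete = TRUE, start = 1L)
    data.frame(heptapeptide = "WRKYGQK", hepta_start = start,
               hepta_end = start + 6L, finger_type = if (complete) type else NA,
               finger_start = if (complete) start + 20L else NA,
               finger_end = if (complete) start + 50L else NA,
               gap1 = 4L, gap2 = 22L, gap3 = 1L, complete = complete)
  expect_equal(classify_protein(rbind(mk("C2H2"), mk("C2H2", start = 80L)))$group, "1")
  expect_equal(classify_protein(mk("C2H2"))$group, "2")
  expect_equal(classify_protein(mk("C2HC"))$group, "3")
  empty <- scan_protein("MAAAAA")
  expect_equal(classify_protein(empty)$group, "ungrouped")
  expect_equal(classify_protein(mk("C2H2", complete = FALSE))$group, "ungrouped")
})

test_that("synthetic proteome scan recovers every planted label at zero noise", {
  gen <- make_proteome(c(group1 = 4, sub2a = 3, sub2b = 3, sub2c = 3,
                         sub2d = 3, sub2e = 3, group3 = 4, ungrouped = 2,
                         incomplete = 2, duplicate = 2), seed = 101)
  scan <- scan_proteome(gen$proteins)
  got <- scan$classification$group[match(gen$truth$id,
                                         scan$classification$id)]
  expect_equal(got, gen$truth$group)
  # permuting protein order never changes any call
  perm <- sample(length(gen$proteins))
  scan2 <- scan_proteome(gen$proteins[perm])
  got2 <- scan2$classification$group[match(gen$truth$id,
                                           scan2$classification$id)]
  expect_equal(got2, gen$truth$group)
})

test_that("dedupe collapses duplicates and drops incomplete records", {
  p <- c(b_prot = "MAAWRKYGQKL", a_prot = "MAAWRKYGQKL")
  cls <- data.frame(id = names(p), group = c("2", "2"),
                    subgroup = "none", n_domains = 1L, notes = "")
  out <- dedupe_and_filter(p, cls, scan_config(require_complete_domain = FALSE))
  expect_equal(nrow(out), 1L)
  expect_equal(out$id, "a_prot")  # lexicographically smallest id kept
  expect_equal(out$dropped_duplicates, "b_prot")

  gen <- make_proteome(c(sub2a = 5, incomplete = 1, duplicate = 2,
                         ungrouped = 1), seed = 5)
  scan <- scan_proteome(gen$proteins)
  out2 <- dedupe_and_filter(gen$proteins, scan$classification)
  # 9 records - 2 duplicates - 1 incomplete - 1 ungrouped = 5 survivors
  expect_equal(nrow(out2), 5L)
  expect_equal(out2$new_id, paste0("WRKY", 1:5))
})

test_that("molecular weight matches a hand-summed oracle and is monotone", {
  masses <- residue_masses()
  s <- "ACDEFGHIKLMNPQRSTVWY"
  f <- protein_features(s)
  expect_equal(f$molecular_weight_kda * 1000,
               sum(masses[strsplit(s, "")[[1]]]) + 18.0153,
               tolerance = 1e-10)
  expect_equal(f$orf_length_nt, 3L * (nchar(s) + 1L))
  set.seed(3)
  for (i in 1:20) {
    base <- random_protein(sample(5:50, 1))
    bigger <- paste0(base, sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 1))
    expect_gt(protein_features(bigger)$molecular_weight_kda,
              protein_features(base)$molecular_weight_kda)
  }
  expect_error(protein_features("AXA"), "X")
  expect_error(protein_features(""))
})

test_that("pI matches a brute-force grid oracle and orders by charge", {
  grid_pi <- function(seq) {
    counts <- as.list(table(factor(strsplit(seq, "")[[1]],
                                   levels = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])))
    counts$nterm <- 1L; counts$cterm <- 1L
    pka <- default_pka()
    charge <- function(pH) {
      pos <- c("nterm", "H", "K", "R"); neg <- c("cterm", "C", "D", "E", "Y")
      q <- 0
      for (g in pos) if (counts[[g]] > 0)
        q <- q + counts[[g]] / (1 + 10^(pH - pka[[g]]))
      for (g in neg) if (counts[[g]] > 0)
        q <- q - counts[[g]] / (1 + 10^(pka[[g]] - pH))
      q
    }
    grid <- seq(0, 14, by = 0.001)
    grid[which.min(abs(vapply(grid, charge, 0)))]
  }
  for (s in c("GG", "KKRKG", "DDEEG", "ACDKRHY")) {
    expect_equal(protein_features(s)$isoelectric_point, grid_pi(s),
                 tolerance = 2e-3)
  }
  expect_gt(protein_features("KKRRKGG")$isoelectric_point,
            protein_features("DDEEDGG")$isoelectric_point)
})

test_that("proteome FASTA round-trips through Biostrings with stop stripping", {
  gen <- make_proteome(c(sub2a = 2, group3 = 1), seed = 8)
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(gen$proteins), function(id)
    c(paste0(">", id), paste0(gen$proteins[[id]], "*")))), fa)
  expect_warning(p2 <- read_proteome(fa), "stop characters")
  expect_equal(p2, gen$proteins)
})
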