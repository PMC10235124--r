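# Pairwise identity, codon back-alignment, NG86 dN/dS and the
# neighbor-joining utility.

test_that("pairwise identity handles trivial and mutant pairs", {
  a <- strrep("ACGT", 25)
  expect_equal(pairwise_identity(a, a), 100)
  b <- paste0("T", substr(a, 2, 100))  # single substitution, length 100
  expect_equal(pairwise_identity(a, b), 99)
  expect_error(pairwise_identity("", a), "non-empty")
})

test_that("identity matches an independent affine-gap DP implementation", {
  withr::with_seed(31, {
    for (i in 1:10) {
      a <- rnd_dna(120)
      bb <- strsplit(a, "")[[1]]
      k <- sample(3:20, 1)
      pos <- sample(120, k)
      bb[pos] <- vapply(bb[pos], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
      b <- paste(bb, collapse = "")
      ref <- oracle_global_identity(a, b)
      expect_equal(pairwise_identity(a, b), ref$identity)
    }
  })
})

test_that("codon back-alignment preserves codons and round-trips", {
  # gapless alignment is the concatenation of original codons
  aln <- c(x = "MKP", y = "MKP")
  cds <- c(x = "ATGAAACCC", y = "ATGAAGCCG")
  ca <- codon_backalign(aln, cds)
  expect_identical(unname(ca["x"]), "ATGAAACCC")
  # a protein gap becomes --- at the same codon column
  aln2 <- c(x = "MK-P", y = "MKQP")
  ca2 <- codon_backalign(aln2, c(x = "ATGAAACCC", y = "ATGAAGCAACCG"))
  expect_identical(unname(ca2["x"]), "ATGAAA---CCC")
  expect_identical(unname(ca2["y"]), "ATGAAGCAACCG")
  # random fixtures: stripping gaps and re-translating recovers the rows
  withr::with_seed(32, {
    for (i in 1:5) {
      prot <- rnd_protein(40)
      cds1 <- dinoeve:::back_translate(prot, 0.4)
      gaps <- sort(sample(40, 4))
      row <- strsplit(prot, "")[[1]]
      for (g in gaps) row[g] <- "-"
      aln3 <- c(a = prot, b = paste(row, collapse = ""))
      cds_b <- dinoeve:::back_translate(
        paste(row[row != "-"], collapse = ""), 0.6)
      ca3 <- codon_backalign(aln3, c(a = cds1, b = cds_b))
      expect_equal(nchar(ca3[["a"]]), 120L)
      degapped <- gsub("-", "", ca3[["b"]])
      expect_identical(degapped, cds_b)
      expect_identical(
        as.character(Biostrings::translate(
          Biostrings::DNAString(degapped))),
        paste(row[row != "-"], collapse = ""))
    }
  })
  # translation mismatch errors name the offending row
  expect_error(codon_backalign(aln, c(x = "ATGAAACCC", y = "ATGTTTCCG")),
               "'y'")
})

test_that("NG86 reproduces forced and degenerate cases", {
  # identical rows: no differences, omega undefined
  r0 <- ng86_dnds(c("TTTAAAGGG", "TTTAAAGGG"))
  expect_equal(r0$Nd + r0$Sd, 0)
  expect_true(is.na(r0$omega))
  # TTT -> TTC is synonymous by code degeneracy
  r1 <- ng86_dnds(c("TTT", "TTC"))
  expect_equal(r1$Sd, 1)
  expect_equal(r1$Nd, 0)
  expect_equal(r1$dN, 0)
  # N + S = 3 x compared codons
  expect_equal(r1$N + r1$S, 3)
  # gap codons are skipped
  r2 <- ng86_dnds(c("TTT---AAA", "TTCGGGAAA"))
  expect_equal(r2$codons, 2L)
})

test_that("pathway counts equal exhaustive enumeration", {
  # classic two-substitution codon: TTT (Phe) -> GTA (Val)
  ref <- oracle_codon_diffs("TTT", "GTA")
  expect_equal(unname(ref), c(0.5, 1.5))  # frozen from the enumeration
  r <- ng86_dnds(c("TTT", "GTA"))
  expect_equal(r$Sd, ref[["Sd"]])
  expect_equal(r$Nd, ref[["Nd"]])
  # a 5-codon toy pair containing that codon
  x <- "ATGTTTAAAGGGCCC"; y <- "ATGGTAAAAGGACCC"
  rt <- ng86_dnds(c(x, y))
  cods_x <- substring(x, seq(1, 13, 3), seq(3, 15, 3))
  cods_y <- substring(y, seq(1, 13, 3), seq(3, 15, 3))
  ref_tot <- rowSums(vapply(seq_len(5), function(i)
    oracle_codon_diffs(cods_x[i], cods_y[i]), numeric(2)))
  expect_equal(rt$Sd, ref_tot[["Sd"]])
  expect_equal(rt$Nd, ref_tot[["Nd"]])
  # random multi-substitution codon pairs against the oracle
  withr::with_seed(33, {
    for (k in 1:25) {
      repeat {
        c1 <- rnd_dna(3); c2 <- rnd_dna(3)
        if (!ORACLE_CODE[c1] == "*" && !ORACLE_CODE[c2] == "*") break
      }
      ref <- oracle_codon_diffs(c1, c2)
      r <- ng86_dnds(c(c1, c2))
      expect_equal(r$Sd, ref[["Sd"]])
      expect_equal(r$Nd, ref[["Nd"]])
    }
  })
})

test_that("NG86 is symmetric and invariant to codon-column permutation", {
  withr::with_seed(34, {
    prot <- rnd_protein(60)
    a <- dinoeve:::back_translate(prot, 0.5)
    b <- degrade_cds(a, 0.08, "neutral")
    r_ab <- ng86_dnds(c(a, b)); r_ba <- ng86_dnds(c(b, a))
    expect_equal(r_ab$omega, r_ba$omega)
    expect_equal(r_ab$Nd, r_ba$Nd)
    perm <- sample(60)
    shuffle <- function(s) paste(substring(s, 3 * perm - 2, 3 * perm),
                                 collapse = "")
    r_perm <- ng86_dnds(c(shuffle(a), shuffle(b)))
    expect_equal(r_ab$Nd, r_perm$Nd)
    expect_equal(r_ab$Sd, r_perm$Sd)
    expect_equal(r_ab$omega, r_perm$omega)
  })
})

test_that("purely synonymous divergence gives dN = 0", {
  withr::with_seed(35, {
    a <- dinoeve:::back_translate(rnd_protein(150), 0.5)
    b <- degrade_cds(a, 0.3, "synonymous_only")
    r <- ng86_dnds(c(a, b))
    expect_gt(r$Sd, 0)
    expect_equal(r$dN, 0)
  })
})

test_that("neighbor joining recovers exact and additive trees", {
  # three taxa: closed-form branch lengths
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(unname(ape::cophenetic.phylo(tr)[c("A", "B", "C"),
                                                c("A", "B", "C")]),
               unname(d))
  # an additive 5-taxon metric is recovered exactly
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):2,E:4);")
  dm <- ape::cophenetic.phylo(ref)
  tr5 <- nj_tree(dm)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref),
                                         ape::unroot(tr5))), 0)
  expect_equal(ape::cophenetic.phylo(tr5)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-8)
  # taxon-order permutation leaves the unrooted topology unchanged
  perm <- c("D", "A", "E", "C", "B")
  tr5p <- nj_tree(dm[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr5),
                                         ape::unroot(tr5p))), 0)
  # invalid inputs are refused
  bad <- d; bad[1, 2] <- 5
  expect_error(nj_tree(bad), "symmetric")
  bad2 <- d; diag(bad2) <- c(0, 1, 0)
  expect_error(nj_tree(bad2), "diagonal")
})
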