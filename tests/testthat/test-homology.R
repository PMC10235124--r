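# Six-frame translation, coordinate maps, the translated search engine
# and the exclusion filters.

test_that("six-frame translation handles the trivial and symmetric cases", {
  expect_identical(six_frame_translate("ATG")$F1$aa, "M")
  expect_identical(six_frame_translate("")$F1$aa, "")
  expect_identical(six_frame_translate("ATNGGG")$F1$aa, "XG")
  withr::with_seed(1, {
    dna <- rnd_dna(300)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(dna)))
    expect_identical(six_frame_translate(rc)$F1$aa,
                     six_frame_translate(dna)$`F-1`$aa)
  })
})

test_that("aa/nt coordinate maps round-trip in all frames", {
  withr::with_seed(2, {
    dna <- rnd_dna(999)
    L <- nchar(dna)
    fr <- six_frame_translate(dna)
    for (f in fr) {
      n_aa <- nchar(f$aa)
      for (i in sample(n_aa, 100, replace = TRUE)) {
        nt <- aa_to_nt(f$frame, i, i, L)
        expect_equal(nt[2] - nt[1], 3L)
        # every position of the codon maps back to residue i
        for (p in nt[1]:(nt[2] - 1))
          expect_equal(nt_to_aa(f$frame, p, L), i)
        # and the codon really translates to that residue
        cod <- substr(if (f$frame > 0) dna else
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(dna))),
          abs(f$frame) + 3 * (i - 1), abs(f$frame) + 3 * i - 1)
        expect_identical(
          as.character(Biostrings::translate(Biostrings::DNAString(cod),
                                             no.init.codon = TRUE)),
          substr(f$aa, i, i))
      }
    }
  })
})

test_that("an exact back-translation yields one full-length perfect hit", {
  withr::with_seed(3, {
    panel <- synthetic_viral_panel()[1, , drop = FALSE]
    prot <- substr(panel$aa, 1, 120)
    panel$aa <- prot
    dna <- dinoeve:::back_translate(prot, 0.5)
    h <- translated_search(dna, panel)
    expect_equal(nrow(h), 1L)
    expect_equal(h$frame, 1L)
    expect_equal(h$pident, 100)
    expect_equal(h$length, 120L)
    expect_equal(c(h$q_start, h$q_end), c(0L, 360L))
    expect_equal(c(h$s_start, h$s_end), c(0L, 120L))
  })
})

test_that("hit sets are strand-symmetric up to frame sign and mirroring", {
  withr::with_seed(4, {
    panel <- synthetic_viral_panel()
    frag <- dinoeve:::back_translate(substr(panel$aa[3], 50, 250), 0.5)
    dna <- splice(rnd_dna(1200), frag, 300)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(dna)))
    L <- nchar(dna)
    hf <- translated_search(dna, panel)
    hr <- translated_search(rc, panel)
    expect_equal(nrow(hf), nrow(hr))
    key <- function(h, mirror) {
      q0 <- if (mirror) L - h$q_end else h$q_start
      q1 <- if (mirror) L - h$q_start else h$q_end
      fr <- if (mirror) -h$frame else h$frame
      o <- order(h$subject, q0)
      paste(h$subject[o], fr[o], q0[o], q1[o], h$raw[o])
    }
    expect_identical(key(hf, FALSE), key(hr, TRUE))
  })
})

test_that("best raw scores equal independent per-frame Smith-Waterman", {
  withr::with_seed(5, {
    for (i in 1:20) {
      dna <- rnd_dna(300)
      prot <- rnd_protein(100)
      if (i %% 2 == 0) {  # half the instances carry real homology
        frag <- dinoeve:::back_translate(substr(prot, 10, 60), 0.5)
        dna <- splice(dna, frag, sample(0:(300 - nchar(frag)), 1))
      }
      panel <- protein_panel("P", prot, "MCP")
      h <- translated_search(dna, panel,
                             search_params(min_raw = 1L,
                                           max_hits_per_pair = 1L))
      mine <- if (nrow(h)) max(h$raw) else 0
      expect_equal(mine, oracle_best_local_score(dna, prot))
    }
  })
})

test_that("E-values decrease strictly in raw score at fixed search space", {
  p <- search_params()
  raw <- seq(50, 300, by = 10)
  ev <- dinoeve:::evalue_from_bit(
    dinoeve:::bit_score(raw, p$lambda, p$K), 1e4, 1600)
  expect_true(all(diff(ev) < 0))
})

test_that("exclusion filters match the published operating point exactly", {
  mk <- function(bit, pident, evalue, length)
    data.frame(scaffold = "s", frame = 1L, q_start = 0L, q_end = 3L,
               subject = "x", gene_class = "MCP", s_start = 0L,
               s_end = 1L, raw = 100L, bit = bit, evalue = evalue,
               pident = pident, length = length, n_ident = length)
  base <- mk(80, 45, 1e-10, 120L)
  # each sub-threshold variant is excluded ...
  expect_equal(nrow(filter_hits(mk(49.9, 95, 1e-20, 120L), "genome")), 0L)
  expect_equal(nrow(filter_hits(mk(80, 29, 1e-10, 120L), "genome")), 0L)
  expect_equal(nrow(filter_hits(mk(80, 45, 1.1e-5, 120L), "genome")), 0L)
  expect_equal(nrow(filter_hits(mk(80, 45, 1e-10, 99L), "genome")), 0L)
  # ... the same hits exactly at the thresholds are retained
  expect_equal(nrow(filter_hits(mk(50, 45, 1e-10, 120L), "genome")), 1L)
  expect_equal(nrow(filter_hits(mk(80, 30, 1e-10, 120L), "genome")), 1L)
  expect_equal(nrow(filter_hits(mk(80, 45, 1e-5, 120L), "genome")), 1L)
  expect_equal(nrow(filter_hits(mk(80, 45, 1e-10, 100L), "genome")), 1L)
  # metagenome mode imposes no length penalty
  short <- mk(80, 45, 1e-10, 60L)
  expect_equal(nrow(filter_hits(short, "metagenome")), 1L)
  expect_equal(nrow(filter_hits(short, "genome")), 0L)
  expect_equal(nrow(filter_hits(base, "genome")), 1L)
})

test_that("raising any threshold never enlarges the retained set", {
  withr::with_seed(6, {
    panel <- synthetic_viral_panel()
    frag <- dinoeve:::back_translate(
      dinoeve:::mutate_protein(substr(panel$aa[1], 1, 200), 0.3), 0.5)
    dna <- splice(rnd_dna(1500), frag, 400)
    h <- translated_search(dna, panel, search_params(min_raw = 30L))
    base <- filter_hits(h, "metagenome", max_evalue = 1e-3, min_bit = 30,
                        min_identity = 20)
    for (tw in list(list(max_evalue = 1e-6), list(min_bit = 60),
                    list(min_identity = 50))) {
      args <- utils::modifyList(
        list(hits = h, mode = "metagenome", max_evalue = 1e-3,
             min_bit = 30, min_identity = 20), tw)
      tightened <- do.call(filter_hits, args)
      expect_true(nrow(tightened) <= nrow(base))
      expect_true(all(rownames(tightened) %in% rownames(base)))
    }
  })
})

test_that("EVE-free scaffolds yield no retained hits", {
  b <- make_benchmark(sim_config(seed = 8, n_scaffolds = 1L,
                                 n_single_eves = 1L, n_genomic_eves = 0L,
                                 negatives = 4L, chimeras = 0L))
  negs <- b$assembly[grepl("_n", names(b$assembly))]
  h <- search_assembly(negs, b$viral_panel)
  expect_equal(nrow(filter_hits(h, "genome")), 0L)
  expect_equal(nrow(filter_hits(h, "metagenome")), 0L)
})
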