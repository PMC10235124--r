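# Synthetic benchmark generator: planted features, degradation model,
# determinism, manifest consistency.

noise_free_cfg <- function(seed = 5) {
  sim_config(seed = seed, n_scaffolds = 1L, n_single_eves = 0L,
             n_genomic_eves = 1L, divergence = 0, genomic_divergence = 0,
             stop_rate = 0, indel_rate = 0, genomic_gap = 400L,
             negatives = 0L, chimeras = 0L, sl_offset = 100L,
             line_offset = 0L, n_cellular_per_scaffold = 0L)
}

test_that("a noise-free genomic plant reproduces its panel sources exactly", {
  b <- make_benchmark(noise_free_cfg())
  man <- b$manifest
  mcp <- man[man$feature == "MCP", ]
  rdrp <- man[man$feature == "RdRp", ]
  expect_equal(nrow(mcp), 1L)
  expect_equal(nrow(rdrp), 1L)
  # separated by exactly the configured noncoding gap
  expect_equal(rdrp$start - mcp$end, 400L)
  expect_equal(man$gap[man$feature == "genomic_pair"], 400L)
  # planted ORFs translate with 100% identity to their panel sources
  seqc <- as.character(b$assembly[[mcp$scaffold]])
  for (rec in list(mcp, rdrp)) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(
      substr(seqc, rec$start + 1, rec$end))))
    src <- b$viral_panel$aa[b$viral_panel$id == rec$source_id]
    expect_identical(aa, src)
  }
  # spliced leader ends exactly sl_offset nt before the RdRp start
  sl <- man[man$feature == "dinoSL", ]
  expect_equal(sl$end, rdrp$start - 100L)
  expect_identical(substr(seqc, sl$start + 1, sl$end), sl_query()$seq)
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 42, n_scaffolds = 3L, n_single_eves = 2L,
                    n_genomic_eves = 1L, negatives = 1L, chimeras = 1L,
                    genomic_gap = 500L)
  b1 <- make_benchmark(cfg)
  b2 <- make_benchmark(cfg)
  expect_identical(as.character(b1$assembly), as.character(b2$assembly))
  expect_identical(b1$manifest, b2$manifest)
  expect_identical(as.character(b1$reads), as.character(b2$reads))
  expect_identical(b1$depth, b2$depth)
  # a different seed gives different sequence
  b3 <- make_benchmark(sim_config(seed = 43, n_scaffolds = 3L,
                                  n_single_eves = 2L, n_genomic_eves = 1L,
                                  negatives = 1L, chimeras = 1L,
                                  genomic_gap = 500L))
  expect_false(identical(as.character(b1$assembly),
                         as.character(b3$assembly)))
})

test_that("realized divergence of 50 plants matches the binomial target", {
  cfg <- sim_config(seed = 17, n_scaffolds = 50L, n_single_eves = 50L,
                    n_genomic_eves = 0L, divergence = 0.2, stop_rate = 0,
                    indel_rate = 0, negatives = 0L, chimeras = 0L,
                    sl_offset = 0L, line_offset = 0L,
                    n_cellular_per_scaffold = 0L)
  b <- make_benchmark(cfg)
  man <- b$manifest[b$manifest$feature %in% c("MCP", "RdRp"), ]
  expect_equal(nrow(man), 50L)
  # measure divergence independently by comparing residues of each plant
  # against its source (substitution-only, so positions align)
  divs <- vapply(seq_len(nrow(man)), function(i) {
    rec <- man[i, ]
    seqc <- as.character(b$assembly[[rec$scaffold]])
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(
      substr(seqc, rec$start + 1, rec$end))))
    src <- b$viral_panel$aa[b$viral_panel$id == rec$source_id]
    mean(strsplit(aa, "")[[1]] != strsplit(src, "")[[1]])
  }, numeric(1))
  total_sites <- sum(nchar(
    b$viral_panel$aa[match(man$source_id, b$viral_panel$id)]))
  se <- sqrt(0.2 * 0.8 / total_sites)
  expect_lt(abs(mean(divs) - 0.2), 3 * se)
  # manifest records the same realized divergence
  expect_equal(mean(man$divergence), mean(divs), tolerance = 1e-12)
})

test_that("manifest intervals translate to the recorded internal stops", {
  cfg <- sim_config(seed = 9, n_scaffolds = 6L, n_single_eves = 5L,
                    n_genomic_eves = 1L, stop_rate = 0.6,
                    indel_rate = 0.002, genomic_gap = 400L,
                    negatives = 0L, chimeras = 0L)
  b <- make_benchmark(cfg)
  man <- b$manifest[b$manifest$feature %in% c("MCP", "RdRp"), ]
  for (i in seq_len(nrow(man))) {
    rec <- man[i, ]
    seqc <- as.character(b$assembly[[rec$scaffold]])
    nt <- substr(seqc, rec$start + 1, rec$end)
    nt <- substr(nt, 1, nchar(nt) - nchar(nt) %% 3)
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(nt), if.fuzzy.codon = "X")), "")[[1]]
    n_stops <- sum(aa[-length(aa)] == "*")
    expect_equal(n_stops, rec$stops)
  }
})

test_that("stop_rate = 1 forces an in-frame internal stop", {
  withr::with_seed(3, {
    panel <- synthetic_viral_panel()
    res <- plant_eve(rnd_dna(7000), list(type = "single",
                                         source_id = "synMCP_A",
                                         divergence = 0, stop_rate = 1,
                                         indel_rate = 0),
                     panel, scaffold_id = "s")
    rec <- res$records[res$records$feature == "MCP", ]
    expect_gte(rec$stops, 1L)
  })
})

test_that("infeasible placements raise configuration errors", {
  expect_error(sim_config(gc = 1.2), "fraction")
  expect_error(sim_config(n_scaffolds = 10L, n_single_eves = 3L,
                          n_genomic_eves = 3L), "n_scaffolds")
  expect_error(sim_config(genomic_gap = -5L), "genomic_gap")
  withr::with_seed(1, {
    panel <- synthetic_viral_panel()
    expect_error(
      plant_eve(rnd_dna(1200), list(type = "single",
                                    source_id = "synRdRp_A",
                                    divergence = 0),
                panel, scaffold_id = "s"),
      "scaffold_len|does not fit")
  })
})

test_that("synonymous-only degradation changes no amino acid", {
  withr::with_seed(21, {
    src <- synthetic_viral_panel()$aa[1]
    cds <- dinoeve:::back_translate(src, 0.5)
    mut <- degrade_cds(cds, 0.3, mode = "synonymous_only")
    expect_false(identical(cds, mut))
    expect_identical(
      as.character(Biostrings::translate(Biostrings::DNAString(mut))),
      src)
  })
})
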