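# EVE classification: MCP/RdRp pairing under the 1.5-kbp rule, the
# spliced-leader scanner, neighborhood annotation and the coverage screen.

mk_loci <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(scaffold = r$sc %||% "s1", start = r$start, end = r$end,
               gene_class = r$class, subject = r$subject %||% "x",
               bit = r$bit %||% 100, status = "confirmed_orf",
               stringsAsFactors = FALSE)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pairing respects the 1.5-kbp boundary", {
  # gap 1200: one genomic EVE
  e <- call_eves(mk_loci(list(start = 1000, end = 2000, class = "MCP"),
                         list(start = 3200, end = 4000, class = "RdRp")))
  expect_equal(e$type, "genomic")
  expect_equal(e$gap, 1200)
  # gap exactly 1500 still pairs; 1501 does not
  e2 <- call_eves(mk_loci(list(start = 0, end = 500, class = "MCP"),
                          list(start = 2000, end = 2500, class = "RdRp")))
  expect_equal(e2$type, "genomic")
  e3 <- call_eves(mk_loci(list(start = 0, end = 500, class = "MCP"),
                          list(start = 2001, end = 2500, class = "RdRp")))
  expect_setequal(e3$type, c("single_MCP", "single_RdRp"))
})

test_that("two adjacent genomic pairs do not cross-pair", {
  loci <- mk_loci(list(start = 0, end = 1000, class = "MCP"),
                  list(start = 1400, end = 2400, class = "RdRp"),
                  list(start = 4901, end = 5901, class = "MCP"),
                  list(start = 6301, end = 7301, class = "RdRp"))
  e <- call_eves(loci)
  expect_equal(sum(e$type == "genomic"), 2L)
  expect_equal(e$gap[e$type == "genomic"], c(400, 400))
  expect_true(all(e$mcp_end < e$rdrp_start))
  # genomic count never exceeds min(#MCP, #RdRp)
  expect_lte(sum(e$type == "genomic"), 2L)
})

test_that("pairing is invariant under input row order", {
  loci <- mk_loci(list(start = 0, end = 1000, class = "MCP"),
                  list(start = 1400, end = 2400, class = "RdRp"),
                  list(start = 2800, end = 3800, class = "MCP"),
                  list(start = 5000, end = 6000, class = "RdRp"))
  e1 <- call_eves(loci)
  withr::with_seed(1, {
    for (k in 1:5) {
      e2 <- call_eves(loci[sample(nrow(loci)), ])
      expect_identical(e1, e2)
    }
  })
})

test_that("spliced-leader scan finds planted relicts inside the window", {
  withr::with_seed(20, {
    q <- sl_query()
    dna <- rnd_dna(3000)
    # exact copy ending 100 nt before the EVE start
    dna <- splice(dna, q$seq, 1000 - 100 - 22)
    h <- scan_dinosl(dna, 1000, 2000, q)
    expect_equal(nrow(h), 1L)
    expect_equal(h$offset, -100)
    expect_equal(h$identity, 100)
    expect_equal(h$strand, "+")
    # a copy 600 nt upstream is outside the 500-nt window
    dna2 <- splice(rnd_dna(3000), q$seq, 1000 - 600 - 22)
    expect_equal(nrow(scan_dinosl(dna2, 1000, 2000, q)), 0L)
    # mutated so no shared non-ambiguous 9-mer survives: no hit
    sl <- strsplit(q$seq, "")[[1]]
    for (p in c(6, 15)) sl[p] <- setdiff(c("A", "C", "G", "T"), sl[p])[1]
    dna3 <- splice(rnd_dna(3000), paste(sl, collapse = ""), 878)
    h3 <- scan_dinosl(dna3, 1000, 2000, q)
    ref <- oracle_sl(dna3, 1000, 2000, q)
    expect_equal(nrow(h3), nrow(ref))
  })
})

test_that("scanner agrees exactly with brute force on random cases", {
  withr::with_seed(21, {
    q <- sl_query()
    for (i in 1:150) {
      dna <- rnd_dna(400)
      if (i %% 2 == 0) {
        sl <- strsplit(q$seq, "")[[1]]
        k <- sample(0:6, 1)
        if (k > 0) {
          pos <- sample(22, k)
          sl[pos] <- vapply(sl[pos], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        }
        dna <- splice(dna, paste(sl, collapse = ""), sample(0:378, 1))
      }
      mine <- scan_dinosl(dna, 200, 250, q)
      ref <- oracle_sl(dna, 200, 250, q)
      expect_equal(mine$position, ref$position)
      expect_equal(mine$strand, ref$strand)
    }
  })
})

test_that("neighborhood annotation reports classes and signed distances", {
  orfs <- data.frame(orf_id = c("o1", "o2", "o3"), scaffold = "s1",
                     start = c(2095, 100, 30000), end = c(2695, 700, 30600),
                     strand = "+", frame = 1L, n_aa = 200L, aa = "M",
                     has_start = TRUE, has_stop = TRUE,
                     ann_subject = c("synLINE_RT", "synCollagen",
                                     "synRBP"),
                     ann_class = c("retroelement", "cellular", "cellular"),
                     ann_bit = 100, ann_evalue = 1e-10, ann_pident = 99,
                     stringsAsFactors = FALSE)
  eve <- data.frame(eve_id = "EVE_001", scaffold = "s1", start = 1000,
                    end = 2000)
  nb <- annotate_neighbors(eve, orfs, window_nt = 20000)
  expect_equal(nrow(nb), 2L)  # the 28-kb-away ORF is outside the window
  line <- nb[nb$gene_class == "retroelement", ]
  expect_equal(line$distance, 95)
  expect_identical(line$side, "downstream")
  up <- nb[nb$gene_class == "cellular", ]
  expect_equal(up$distance, -300)
  # no annotated ORFs -> empty
  expect_equal(nrow(annotate_neighbors(eve, orfs[0, ])), 0L)
})

test_that("coverage screen passes uniform depth and fails discontinuities", {
  L <- 4000
  uni <- data.frame(scaffold = "s1", pos = 0:(L - 1), depth = 30L)
  r <- coverage_uniformity(uni, "s1", 1500, 2500)
  expect_identical(r$status, "pass")
  expect_equal(r$stat_diff, 0)
  expect_equal(r$cv, 0)
  # chimeric profile: covered left half, bare right half
  chi <- data.frame(scaffold = "s1", pos = 0:(L - 1),
                    depth = rep(c(30L, 0L), each = L / 2))
  r2 <- coverage_uniformity(chi, "s1", 1700, 2300)
  expect_identical(r2$status, "fail")
  # all-zero depth fails with an explicit reason
  z <- data.frame(scaffold = "s1", pos = 0:(L - 1), depth = 0L)
  r3 <- coverage_uniformity(z, "s1", 1500, 2500)
  expect_identical(r3$status, "fail")
  expect_match(r3$reason, "zero coverage")
  # no depth -> untested
  expect_identical(coverage_uniformity(NULL, "s1", 0, 10)$status,
                   "untested")
})
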