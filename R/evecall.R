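# Assembly of validated hits into EVE calls: locus merging, single-ORF
# versus whole-genome (paired MCP + RdRp) classification, spliced-leader
# relict scanning, neighborhood annotation, and the read-coverage
# uniformity screen against chimeric assembly artifacts.

#' Merge validated hits into candidate loci
#'
#' Overlapping confirmed hits on a scaffold (often the same region matched
#' by several panel entries) are merged into one locus spanning their
#' union; the locus takes the gene class of its best hit (highest bit
#' score, ties broken by higher identity then lexicographic subject id).
#'
#' @param hits validated hits from [verify_candidates()] (only
#'   `confirmed_*` rows are used).
#' @return data.frame of loci: `scaffold`, `start`, `end`, `gene_class`,
#'   `subject`, `bit`, `status`.
#' @export
merge_loci <- function(hits) {
  hits <- hits[hits$status %in% c("confirmed_orf", "confirmed_flank"), ,
               drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), gene_class = character(),
                      subject = character(), bit = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  out <- lapply(split(hits, hits$scaffold), function(h) {
    ir <- IRanges::IRanges(start = h$q_start + 1L, end = h$q_end)
    red <- IRanges::reduce(ir)
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    do.call(rbind, lapply(seq_along(red), function(g) {
      hh <- h[grp == g, , drop = FALSE]
      best <- hh[order(-hh$bit, -hh$pident, hh$subject), ][1L, ]
      data.frame(scaffold = best$scaffold,
                 start = IRanges::start(red)[g] - 1L,
                 end = IRanges::end(red)[g],
                 gene_class = best$gene_class, subject = best$subject,
                 bit = best$bit,
                 status = if (any(hh$status == "confirmed_orf"))
                   "confirmed_orf" else "confirmed_flank",
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$scaffold, out$start), , drop = FALSE]
}

#' Call EVEs from validated MCP/RdRp loci
#'
#' MCP and RdRp loci on the same scaffold are matched greedily by the
#' noncoding gap between their facing ends, ascending (ties broken by the
#' leftmost MCP); a pair with gap <= `pairing_nt` becomes one `genomic`
#' EVE — the signature of a whole viral genome integration — and each
#' remaining locus becomes a `single_MCP` or `single_RdRp` EVE.  Pairing
#' is stable under input order (loci are sorted internally).
#'
#' @param loci data.frame from [merge_loci()].
#' @param pairing_nt maximum noncoding gap for a genomic pair
#'   (default 1500, i.e. the 1.5-kbp rule).
#' @return data.frame of EVE calls: span, type, member intervals and the
#'   realized gap (`NA` for single-ORF calls).
#' @export
call_eves <- function(loci, pairing_nt = 1500L) {
  empty <- data.frame(eve_id = character(), scaffold = character(),
                      type = character(), start = integer(),
                      end = integer(), mcp_start = integer(),
                      mcp_end = integer(), rdrp_start = integer(),
                      rdrp_end = integer(), gap = integer(),
                      mcp_subject = character(), rdrp_subject = character(),
                      stringsAsFactors = FALSE)
  if (nrow(loci) == 0L) return(empty)
  loci <- loci[order(loci$scaffold, loci$start, loci$end), , drop = FALSE]
  out <- list()
  for (sc in unique(loci$scaffold)) {
    l <- loci[loci$scaffold == sc, , drop = FALSE]
    mcp <- l[l$gene_class == "MCP", , drop = FALSE]
    rdrp <- l[l$gene_class == "RdRp", , drop = FALSE]
    pairs <- NULL
    if (nrow(mcp) && nrow(rdrp)) {
      pairs <- expand.grid(i = seq_len(nrow(mcp)), j = seq_len(nrow(rdrp)))
      pairs$gap <- mapply(function(i, j)
        interval_gap(mcp$start[i], mcp$end[i], rdrp$start[j], rdrp$end[j]),
        pairs$i, pairs$j)
      pairs <- pairs[pairs$gap <= pairing_nt, , drop = FALSE]
      pairs <- pairs[order(pairs$gap, mcp$start[pairs$i],
                           rdrp$start[pairs$j]), , drop = FALSE]
    }
    used_m <- logical(nrow(mcp)); used_r <- logical(nrow(rdrp))
    if (!is.null(pairs)) for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (used_m[i] || used_r[j]) next
      used_m[i] <- TRUE; used_r[j] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, type = "genomic",
        start = min(mcp$start[i], rdrp$start[j]),
        end = max(mcp$end[i], rdrp$end[j]),
        mcp_start = mcp$start[i], mcp_end = mcp$end[i],
        rdrp_start = rdrp$start[j], rdrp_end = rdrp$end[j],
        gap = pairs$gap[k], mcp_subject = mcp$subject[i],
        rdrp_subject = rdrp$subject[j], stringsAsFactors = FALSE)
    }
    for (i in which(!used_m)) out[[length(out) + 1L]] <- data.frame(
      scaffold = sc, type = "single_MCP",
      start = mcp$start[i], end = mcp$end[i],
      mcp_start = mcp$start[i], mcp_end = mcp$end[i],
      rdrp_start = NA_integer_, rdrp_end = NA_integer_, gap = NA_integer_,
      mcp_subject = mcp$subject[i], rdrp_subject = NA_character_,
      stringsAsFactors = FALSE)
    for (j in which(!used_r)) out[[length(out) + 1L]] <- data.frame(
      scaffold = sc, type = "single_RdRp",
      start = rdrp$start[j], end = rdrp$end[j],
      mcp_start = NA_integer_, mcp_end = NA_integer_,
      rdrp_start = rdrp$start[j], rdrp_end = rdrp$end[j],
      gap = NA_integer_, mcp_subject = NA_character_,
      rdrp_subject = rdrp$subject[j], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  cbind(eve_id = sprintf("EVE_%03d", seq_len(nrow(out))), out,
        stringsAsFactors = FALSE)
}

#' Spliced-leader query
#'
#' The dinoflagellate spliced leader (dinoSL) is a 22-nt sequence
#' trans-spliced onto the 5' end of dinoflagellate mRNAs; a relict copy
#' near an EVE is evidence that an mRNA intermediate was retroposed into
#' the genome.  The bundled default is the canonical conserved dinoSL
#' (with the degenerate first base fixed to T); which positions are exempt
#' from mismatch counting is configuration — the default exempts the
#' degenerate position 1 and the splice-junction position 22.
#'
#' @param seq 22-nt query sequence.
#' @param ambiguous integer positions (1-based) exempt from mismatch
#'   counting.
#' @return list of class `sl_query`.
#' @export
sl_query <- function(seq = "TCCGTAGCCATTTTGGCTCAAG",
                     ambiguous = c(1L, 22L)) {
  seq <- toupper(seq)
  if (nchar(seq) != 22L) stop("spliced-leader query must be 22 nt")
  if (any(ambiguous < 1L | ambiguous > 22L))
    stop("ambiguous positions must lie in 1..22")
  structure(list(seq = seq, ambiguous = as.integer(sort(unique(ambiguous)))),
            class = "sl_query")
}

#' Scan for spliced-leader relicts near an EVE
#'
#' Both strands of the region within `window_nt` of the EVE boundaries are
#' scanned with exact seed words of length `word` (drawn from the
#' non-ambiguous positions of the query) followed by ungapped comparison
#' of the full 22-nt query; mismatches at the ambiguous positions are not
#' counted.  A placement is a hit when it shares an exact `word`-mer with
#' the query outside the ambiguous positions and matches at least
#' `min_matches` of the non-ambiguous positions.
#'
#' @param scaffold nucleotide sequence.
#' @param eve_start,eve_end 0-based half-open interval of the EVE (use the
#'   RdRp member for genomic calls; the spliced leader marks the 5' end of
#'   the retroposed mRNA).
#' @param query an [sl_query()].
#' @param window_nt scan window on each side of the EVE (default 500).
#' @param word exact seed length (default 9).
#' @param min_matches minimum matching non-ambiguous positions
#'   (default 18 of 20, i.e. >= 90% identity).
#' @return data.frame of hits: `position` (0-based start of the 22-nt
#'   placement, forward strand), `strand`, `offset` (signed distance to
#'   the EVE: negative upstream — `position + 22 - eve_start` — positive
#'   downstream), `matches`, `identity` (% of non-ambiguous positions).
#' @export
scan_dinosl <- function(scaffold, eve_start, eve_end, query = sl_query(),
                        window_nt = 500L, word = 9L, min_matches = 18L) {
  stopifnot(window_nt > 0L, word > 0L)
  seqc <- as_dna_character(scaffold)
  eve_start <- as.integer(eve_start)
  eve_end <- as.integer(eve_end)
  window_nt <- as.integer(window_nt)
  L <- nchar(seqc)
  qlen <- 22L
  regions <- list(c(max(0L, eve_start - window_nt), eve_start),
                  c(eve_end, min(L, eve_end + window_nt)))
  qf <- strsplit(query$seq, "")[[1]]
  qr <- strsplit(revcomp(query$seq), "")[[1]]
  amb_f <- query$ambiguous
  amb_r <- sort(qlen + 1L - query$ambiguous)
  hits <- list()
  for (reg in regions) {
    if (reg[2] - reg[1] < qlen) next
    sub <- strsplit(substr(seqc, reg[1] + 1L, reg[2]), "")[[1]]
    for (strand in c("+", "-")) {
      qq <- if (strand == "+") qf else qr
      amb <- if (strand == "+") amb_f else amb_r
      nonamb <- setdiff(seq_len(qlen), amb)
      for (p in 0:(length(sub) - qlen)) {
        win <- sub[(p + 1L):(p + qlen)]
        eq <- win == qq
        m <- sum(eq[nonamb])
        if (m < min_matches) next
        # exact seed word avoiding ambiguous positions
        seeded <- FALSE
        for (w0 in 1:(qlen - word + 1L)) {
          idx <- w0:(w0 + word - 1L)
          if (any(idx %in% amb)) next
          if (all(eq[idx])) { seeded <- TRUE; break }
        }
        if (!seeded) next
        pos <- as.integer(reg[1] + p)
        offset <- if (pos + qlen <= eve_start) pos + qlen - eve_start
                  else pos - eve_end
        hits[[length(hits) + 1L]] <- data.frame(
          position = pos, strand = strand, offset = offset,
          matches = m, identity = 100 * m / length(nonamb),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(position = integer(), strand = character(),
                      offset = integer(), matches = integer(),
                      identity = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Annotate the genomic neighborhood of an EVE
#'
#' Lists every annotated ORF within `window_nt` of the EVE span, with its
#' gene class and signed distance (positive downstream of the EVE end,
#' negative upstream of the EVE start); ORFs overlapping the EVE span
#' itself (its own members) are excluded.  Retroelement proximity — a
#' candidate integration mechanism for a non-retroviral virus — is
#' flagged.
#'
#' @param eve one row of the [call_eves()] data.frame.
#' @param orfs annotated ORFs for the scaffold (see [annotate_orfs()]).
#' @param window_nt neighborhood radius (default 20000).
#' @return data.frame: `orf_id`, `gene_class`, `distance`, `side`, and
#'   attribute-style column `retroelement` (logical).
#' @export
annotate_neighbors <- function(eve, orfs, window_nt = 20000L) {
  ann <- orfs[!is.na(orfs$ann_class), , drop = FALSE]
  empty <- data.frame(orf_id = character(), gene_class = character(),
                      distance = integer(), side = character(),
                      retroelement = logical(), stringsAsFactors = FALSE)
  if (nrow(ann) == 0L) return(empty)
  res <- list()
  for (i in seq_len(nrow(ann))) {
    if (intervals_overlap(ann$start[i], ann$end[i], eve$start, eve$end))
      next
    if (ann$start[i] >= eve$end) {
      d <- ann$start[i] - eve$end; side <- "downstream"
    } else {
      d <- -(eve$start - ann$end[i]); side <- "upstream"
    }
    if (abs(d) > window_nt) next
    res[[length(res) + 1L]] <- data.frame(
      orf_id = ann$orf_id[i], gene_class = ann$ann_class[i],
      distance = d, side = side,
      retroelement = ann$ann_class[i] == "retroelement",
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  out[order(abs(out$distance)), , drop = FALSE]
}

# --- coverage ---------------------------------------------------------------

#' Read a per-base depth table
#'
#' Three tab-separated columns: scaffold, position (0-based), depth.
#'
#' @param path TSV path.
#' @return data.frame with columns `scaffold`, `pos`, `depth`.
#' @export
read_depth_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("scaffold", "pos", "depth") %in% names(d)))
  d
}

#' Per-base depth from a BAM file
#'
#' Pileup-based depth extraction; requires the Rsamtools package.
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @return data.frame with columns `scaffold`, `pos` (0-based), `depth`.
#' @export
depth_from_bam <- function(bam) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("depth_from_bam() requires the Rsamtools package")
  p <- Rsamtools::pileup(bam, pileupParam = Rsamtools::PileupParam(
    distinguish_strands = FALSE, distinguish_nucleotides = FALSE,
    min_base_quality = 0L, min_mapq = 0L))
  data.frame(scaffold = as.character(p$seqnames), pos = p$pos - 1L,
             depth = p$count, stringsAsFactors = FALSE)
}

#' Coverage-uniformity screen for chimeric assembly
#'
#' A real integration should sit in a scaffold with uniform read depth; a
#' depth discontinuity at the candidate suggests the scaffold is a
#' chimeric assembly artifact.  The screen computes (i) the relative
#' difference between mean depth inside the EVE interval and in its
#' flanks, `|mean_in - mean_flank| / mean_union`, and (ii) the coefficient
#' of variation of depth across the union of interval and flanks; it
#' fails when either exceeds its threshold, and reports zero coverage
#' explicitly.
#'
#' @param depth depth data.frame (`scaffold`, `pos`, `depth`), 0-based.
#' @param scaffold_id scaffold to test.
#' @param start,end 0-based half-open EVE interval.
#' @param flank_nt flank width (default 500).
#' @param diff_threshold,cv_threshold failure thresholds (defaults 0.25
#'   and 0.5).
#' @return list: `status` (`"pass"`, `"fail"`, `"untested"`), `stat_diff`,
#'   `cv`, `reason`.
#' @export
coverage_uniformity <- function(depth, scaffold_id, start, end,
                                flank_nt = 500L, diff_threshold = 0.25,
                                cv_threshold = 0.5) {
  if (is.null(depth))
    return(list(status = "untested", stat_diff = NA_real_, cv = NA_real_,
                reason = "no depth provided"))
  d <- depth[depth$scaffold == scaffold_id, , drop = FALSE]
  if (nrow(d) == 0L)
    return(list(status = "untested", stat_diff = NA_real_, cv = NA_real_,
                reason = "scaffold absent from depth profile"))
  inside <- d$depth[d$pos >= start & d$pos < end]
  flank <- d$depth[(d$pos >= start - flank_nt & d$pos < start) |
                     (d$pos >= end & d$pos < end + flank_nt)]
  union <- c(inside, flank)
  if (length(union) == 0L || mean(union) == 0)
    return(list(status = "fail", stat_diff = NA_real_, cv = NA_real_,
                reason = "zero coverage"))
  mu <- mean(union)
  stat_diff <- if (length(flank))
    abs(mean(inside) - mean(flank)) / mu else 0
  cv <- sd(union) / mu
  fail <- stat_diff > diff_threshold || cv > cv_threshold
  list(status = if (fail) "fail" else "pass",
       stat_diff = stat_diff, cv = cv,
       reason = if (fail) "depth discontinuity" else NA_character_)
}
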