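# ORF calling, panel-based annotation, and flank-based verification of
# fragmented candidate integrations.
#
# The caller is deterministic stop-to-stop: every maximal stop-free run of
# codons across the six frames, at or above a minimum residue length, is an
# ORF.  Endogenized viral genes are routinely fragmented, so a start codon
# is not required; has_start records whether one is present (or the run
# abuts the scaffold edge), and has_stop whether the run is terminated by
# an in-frame stop (rather than the scaffold edge).  A "complete" ORF is
# one with has_stop and length >= min_len_aa.

#' @noRd
empty_orfs <- function() {
  data.frame(orf_id = character(), scaffold = character(),
             start = integer(), end = integer(), strand = character(),
             frame = integer(), n_aa = integer(), aa = character(),
             has_start = logical(), has_stop = logical(),
             stringsAsFactors = FALSE)
}

#' Call open reading frames on a scaffold
#'
#' @param scaffold nucleotide sequence (character / `DNAString`).
#' @param min_len_aa minimum ORF length in residues (default 60).
#' @param scaffold_id id recorded in the output.
#' @return a data.frame of ORFs; `start`/`end` are 0-based half-open
#'   forward-strand nucleotide coordinates of the stop-free codon run
#'   (the terminating stop codon is not included), `frame` is the reading
#'   frame, `aa` the translation (no internal stops).
#' @examples
#' find_orfs("TAAATGAAACCCTAAGG", min_len_aa = 2)
#' @export
find_orfs <- function(scaffold, min_len_aa = 60L, scaffold_id = NULL) {
  if (is.null(scaffold_id))
    scaffold_id <- names(scaffold) %||% "scaffold"
  seqc <- as_dna_character(scaffold)
  frames <- six_frame_translate(seqc)
  L <- nchar(seqc)
  res <- list()
  for (fr in frames) {
    aa <- fr$aa
    n <- nchar(aa)
    if (n == 0L) next
    chars <- strsplit(aa, "")[[1]]
    stops <- which(chars == "*")
    seg_start <- c(1L, stops + 1L)           # first residue of each run
    seg_end <- c(stops - 1L, n)              # last residue of each run
    keep <- seg_end - seg_start + 1L >= min_len_aa
    for (k in which(keep)) {
      a0 <- seg_start[k]; a1 <- seg_end[k]
      nt <- aa_to_nt(fr$frame, a0, a1, L)
      seg_aa <- substr(aa, a0, a1)
      res[[length(res) + 1L]] <- data.frame(
        scaffold = scaffold_id,
        start = nt[1L], end = nt[2L],
        strand = if (fr$frame > 0L) "+" else "-",
        frame = fr$frame, n_aa = a1 - a0 + 1L, aa = seg_aa,
        has_start = substr(seg_aa, 1L, 1L) == "M" || a0 == 1L,
        has_stop = a1 < n,
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) return(empty_orfs())
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$end, out$frame), , drop = FALSE]
  out <- cbind(orf_id = sprintf("%s_orf%03d", scaffold_id,
                                seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Annotate ORFs against viral and cellular protein panels
#'
#' Each ORF translation is aligned (Smith-Waterman, BLOSUM62) against the
#' combined panels; the best alignment passing the annotation thresholds
#' (default E < 1e-3 and bit score >= 50) is recorded with its panel id
#' and gene class.  ORFs with no qualifying alignment are marked
#' unannotated (`NA` columns).
#'
#' @param orfs data.frame from [find_orfs()].
#' @param viral_panel,cellular_panel [protein_panel()]s; `cellular_panel`
#'   may be `NULL`.
#' @param max_evalue,min_bit annotation thresholds.
#' @param params [search_params()] used for scoring.
#' @return `orfs` with columns `ann_subject`, `ann_class`, `ann_bit`,
#'   `ann_evalue`, `ann_pident` appended.
#' @export
annotate_orfs <- function(orfs, viral_panel, cellular_panel = NULL,
                          max_evalue = 1e-3, min_bit = 50,
                          params = search_params()) {
  panel <- rbind(viral_panel, cellular_panel)
  orfs$ann_subject <- rep(NA_character_, nrow(orfs))
  orfs$ann_class <- rep(NA_character_, nrow(orfs))
  orfs$ann_bit <- rep(NA_real_, nrow(orfs))
  orfs$ann_evalue <- rep(NA_real_, nrow(orfs))
  orfs$ann_pident <- rep(NA_real_, nrow(orfs))
  if (is.null(panel) || nrow(panel) == 0L) {
    warning("empty annotation panels: all ORFs left unannotated")
    return(orfs)
  }
  if (nrow(orfs) == 0L) return(orfs)
  mat <- blosum62()
  n <- sum(nchar(panel$aa))
  for (i in seq_len(nrow(orfs))) {
    q <- encode_aa(orfs$aa[i])
    best <- NULL
    for (k in seq_len(nrow(panel))) {
      al <- sw_all_hits_cpp(q, encode_aa(panel$aa[k]), mat,
                            params$gap_open, params$gap_ext, 1L, 1L)
      if (nrow(al) == 0L) next
      bit <- bit_score(al$score[1L], params$lambda, params$K)
      ev <- evalue_from_bit(bit, orfs$n_aa[i], n)
      cand <- list(subject = panel$id[k], class = panel$gene_class[k],
                   bit = bit, evalue = ev,
                   pident = 100 * al$n_ident[1L] / al$cols[1L])
      if (is.null(best) || cand$bit > best$bit ||
          (cand$bit == best$bit && cand$pident > best$pident))
        best <- cand
    }
    if (!is.null(best) && best$evalue <= max_evalue && best$bit >= min_bit) {
      orfs$ann_subject[i] <- best$subject
      orfs$ann_class[i] <- best$class
      orfs$ann_bit[i] <- best$bit
      orfs$ann_evalue[i] <- best$evalue
      orfs$ann_pident[i] <- best$pident
    }
  }
  orfs
}

#' Extract flanking sequence around an interval
#'
#' Returns up to `flank_nt` nucleotides on each side of a 0-based
#' half-open interval, truncated at the scaffold ends (truncation is
#' flagged).
#'
#' @param scaffold nucleotide sequence.
#' @param start,end 0-based half-open interval within the scaffold.
#' @param flank_nt flank width (default 300).
#' @return list with `upstream`, `downstream` (character sequences),
#'   `upstream_truncated`, `downstream_truncated` (logical), and the
#'   flank intervals.
#' @export
extract_flanks <- function(scaffold, start, end, flank_nt = 300L) {
  seqc <- as_dna_character(scaffold)
  L <- nchar(seqc)
  if (start < 0L || end > L || start > end)
    stop("interval [", start, ",", end, ") outside scaffold of length ", L)
  u0 <- max(0L, start - flank_nt)
  d1 <- min(L, end + flank_nt)
  list(upstream = substr(seqc, u0 + 1L, start),
       downstream = substr(seqc, end + 1L, d1),
       upstream_interval = c(u0, start),
       downstream_interval = c(end, d1),
       upstream_truncated = start - u0 < flank_nt,
       downstream_truncated = d1 - end < flank_nt)
}

#' Verify filtered homology hits against ORFs and flanking sequence
#'
#' Endogenized viral genes can be fragmented or degraded, so a candidate
#' hit is vetted in two tiers: it is `confirmed_orf` when a complete ORF
#' (terminated by a stop, length >= `min_len_aa`) overlapping the hit
#' annotates to the same gene class; otherwise the hit region plus
#' `flank_nt` of context on each side is re-searched against the viral
#' panel and the hit is `confirmed_flank` when the viral annotation is
#' reproduced at E <= `flank_evalue`, else `rejected`.
#'
#' @param scaffold nucleotide sequence of the scaffold the hits lie on.
#' @param hits filtered hit data.frame (one scaffold).
#' @param orfs annotated ORFs for the same scaffold
#'   (see [annotate_orfs()]).
#' @param viral_panel viral [protein_panel()].
#' @param flank_nt flank width for the rescue re-search (default 300).
#' @param flank_evalue re-search E-value ceiling (default 1e-3).
#' @param min_len_aa completeness length threshold for ORFs (default 60).
#' @param params [search_params()].
#' @return `hits` with columns `status` (`confirmed_orf`,
#'   `confirmed_flank`, `rejected`) and `support` (supporting ORF or
#'   flank-hit id) appended.
#' @export
verify_candidates <- function(scaffold, hits, orfs, viral_panel,
                              flank_nt = 300L, flank_evalue = 1e-3,
                              min_len_aa = 60L,
                              params = search_params()) {
  hits$status <- rep("rejected", nrow(hits))
  hits$support <- rep(NA_character_, nrow(hits))
  if (nrow(hits) == 0L) return(hits)
  seqc <- as_dna_character(scaffold)
  L <- nchar(seqc)
  complete <- orfs[!is.na(orfs$ann_class) & orfs$has_stop &
                     orfs$n_aa >= min_len_aa, , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    ov <- complete[complete$ann_class == hits$gene_class[i] &
                     complete$start < hits$q_end[i] &
                     hits$q_start[i] < complete$end, , drop = FALSE]
    if (nrow(ov) > 0L) {
      hits$status[i] <- "confirmed_orf"
      hits$support[i] <- ov$orf_id[which.max(ov$ann_bit)]
      next
    }
    r0 <- max(0L, hits$q_start[i] - flank_nt)
    r1 <- min(L, hits$q_end[i] + flank_nt)
    region <- substr(seqc, r0 + 1L, r1)
    re <- translated_search(region, viral_panel, params,
                            scaffold_id = "flank")
    re <- re[re$gene_class == hits$gene_class[i] &
               re$evalue <= flank_evalue, , drop = FALSE]
    if (nrow(re) > 0L) {
      hits$status[i] <- "confirmed_flank"
      hits$support[i] <- re$subject[1L]
    }
  }
  hits
}
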