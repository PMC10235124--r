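# Six-frame translated homology search of scaffolds against a protein
# panel, with BLAST-compatible score statistics and the exclusion filters
# used to screen candidate integrations.

FRAMES <- c(1L, 2L, 3L, -1L, -2L, -3L)

#' Translate a nucleotide sequence in all six reading frames
#'
#' @param dna a nucleotide sequence (character, `DNAString`, or length-1
#'   `DNAStringSet`); alphabet `ACGTN` (fuzzy codons translate to `X`,
#'   stops to `*`).
#' @return a list with one element per frame (`F1`, `F2`, `F3`, `F-1`,
#'   `F-2`, `F-3`), each a list with `frame`, `aa` (the translation),
#'   `offset` and `seqlen`.  Use [aa_to_nt()] / [nt_to_aa()] to convert
#'   between residue positions and forward-strand nucleotide intervals.
#' @examples
#' six_frame_translate("ATG")$F1$aa  # "M"
#' @export
six_frame_translate <- function(dna) {
  dna <- as_dna_character(dna)
  L <- nchar(dna)
  rc <- if (L > 0L) revcomp(dna) else ""
  out <- lapply(FRAMES, function(f) {
    off <- abs(f) - 1L
    src <- if (f > 0L) dna else rc
    n_aa <- max(0L, (L - off) %/% 3L)
    aa <- if (n_aa > 0L)
      translate_str(substr(src, off + 1L, off + 3L * n_aa)) else ""
    list(frame = f, aa = aa, offset = off, seqlen = L)
  })
  names(out) <- paste0("F", FRAMES)
  out
}

#' Map residue positions in a reading frame to a forward-strand interval
#'
#' @param frame reading frame in `{1, 2, 3, -1, -2, -3}`.
#' @param aa_start,aa_end 1-based inclusive residue positions within the
#'   frame translation.
#' @param seqlen nucleotide length of the source sequence.
#' @return integer `c(start, end)`: 0-based half-open forward-strand
#'   nucleotide interval covering those residues.
#' @export
aa_to_nt <- function(frame, aa_start, aa_end, seqlen) {
  off <- abs(frame) - 1L
  if (frame > 0L) {
    c(off + 3L * (aa_start - 1L), off + 3L * aa_end)
  } else {
    c(seqlen - off - 3L * aa_end, seqlen - off - 3L * (aa_start - 1L))
  }
}

#' Map a forward-strand nucleotide position to its residue position
#'
#' Inverse of [aa_to_nt()]: returns the 1-based residue index of the codon
#' covering forward-strand position `pos` (0-based) in `frame`, or `NA`
#' when the position falls outside the frame's codons.
#'
#' @inheritParams aa_to_nt
#' @param pos 0-based forward-strand nucleotide position.
#' @export
nt_to_aa <- function(frame, pos, seqlen) {
  off <- abs(frame) - 1L
  p <- if (frame > 0L) pos else seqlen - 1L - pos
  if (p < off) return(NA_integer_)
  i <- (p - off) %/% 3L + 1L
  n_aa <- (seqlen - off) %/% 3L
  if (i > n_aa) NA_integer_ else i
}

# --- scoring ----------------------------------------------------------------

aln_env <- new.env(parent = emptyenv())

# BLOSUM62 as an integer matrix plus a char -> row-index lookup
#' @noRd
blosum62 <- function() {
  if (is.null(aln_env$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    storage.mode(m) <- "integer"
    aln_env$mat <- m
    aln_env$alphabet <- rownames(m)
  }
  aln_env$mat
}

# encode an aa string as 0-based indices into the BLOSUM62 alphabet;
# unknown characters map to X
#' @noRd
encode_aa <- function(aa) {
  alpha <- { blosum62(); aln_env$alphabet }
  idx <- match(strsplit(aa, "")[[1]], alpha)
  idx[is.na(idx)] <- match("X", alpha)
  idx - 1L
}

#' Search parameters for the translated homology scan
#'
#' Karlin-Altschul constants are the standard gapped BLOSUM62 values for
#' gap open 11 / extend 1 (lambda = 0.267, K = 0.041); the E-value is
#' `E = K * m * n * exp(-lambda * S)` with search space `m` = translated
#' query residues and `n` = total panel residues.
#'
#' @param gap_open,gap_ext affine gap penalties (BLAST convention: a gap
#'   of length L costs `gap_open + L * gap_ext`).
#' @param lambda,K Karlin-Altschul parameters for the raw-score scale.
#' @param min_raw minimum raw alignment score reported by the engine.
#' @param max_hits_per_pair cap on locally optimal alignments reported
#'   per (frame, panel entry) pair.
#' @return a named list of parameters.
#' @export
search_params <- function(gap_open = 11L, gap_ext = 1L,
                          lambda = 0.267, K = 0.041,
                          min_raw = 55L, max_hits_per_pair = 16L) {
  list(gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext),
       lambda = lambda, K = K, min_raw = as.integer(min_raw),
       max_hits_per_pair = as.integer(max_hits_per_pair))
}

#' @noRd
bit_score <- function(raw, lambda, K) (lambda * raw - log(K)) / log(2)

#' @noRd
evalue_from_bit <- function(bit, m, n) m * n * 2^(-bit)

#' @noRd
empty_hits <- function() {
  data.frame(scaffold = character(), frame = integer(),
             q_start = integer(), q_end = integer(),
             subject = character(), gene_class = character(),
             s_start = integer(), s_end = integer(),
             raw = integer(), bit = numeric(), evalue = numeric(),
             pident = numeric(), length = integer(), n_ident = integer(),
             stringsAsFactors = FALSE)
}

#' Six-frame translated search of one scaffold against a protein panel
#'
#' BLASTx-style screen: each frame translation is aligned locally
#' (Smith-Waterman, BLOSUM62, affine gaps) against every panel protein;
#' alignments at or above the reporting score are returned with raw score,
#' bit score, database-size-aware E-value and percent identity (identity
#' denominator = alignment columns including gaps, the BLAST convention).
#'
#' @param scaffold nucleotide sequence (character / `DNAString`); may be
#'   named, the name is carried as `scaffold` in the output.
#' @param panel a [protein_panel()].
#' @param params a [search_params()] list.
#' @param scaffold_id id recorded in the output (defaults to the name of
#'   `scaffold` or `"scaffold"`).
#' @param m_residues search-space residue count for the query side;
#'   defaults to the total translated residues of this scaffold.  Pass the
#'   assembly-wide total for statistics consistent across a multi-scaffold
#'   run.
#' @return a data.frame of hits; query intervals (`q_start`, `q_end`) are
#'   0-based half-open forward-strand nucleotide coordinates, subject
#'   intervals (`s_start`, `s_end`) 0-based half-open residue coordinates.
#' @export
translated_search <- function(scaffold, panel, params = search_params(),
                              scaffold_id = NULL, m_residues = NULL) {
  if (is.null(scaffold_id))
    scaffold_id <- names(scaffold) %||% "scaffold"
  seqc <- as_dna_character(scaffold)
  frames <- six_frame_translate(seqc)
  m <- m_residues %||% sum(vapply(frames, function(f) nchar(f$aa),
                                  numeric(1)))
  n <- sum(nchar(panel$aa))
  mat <- blosum62()
  L <- nchar(seqc)
  res <- list()
  for (fr in frames) {
    if (nchar(fr$aa) == 0L) next
    q <- encode_aa(fr$aa)
    for (k in seq_len(nrow(panel))) {
      s <- encode_aa(panel$aa[k])
      al <- sw_all_hits_cpp(q, s, mat, params$gap_open, params$gap_ext,
                            params$min_raw, params$max_hits_per_pair)
      if (nrow(al) == 0L) next
      nt <- t(vapply(seq_len(nrow(al)), function(i)
        aa_to_nt(fr$frame, al$q_start[i], al$q_end[i], L), integer(2)))
      bit <- bit_score(al$score, params$lambda, params$K)
      res[[length(res) + 1L]] <- data.frame(
        scaffold = scaffold_id, frame = fr$frame,
        q_start = nt[, 1L], q_end = nt[, 2L],
        subject = panel$id[k], gene_class = panel$gene_class[k],
        s_start = al$s_start - 1L, s_end = al$s_end,
        raw = al$score, bit = bit,
        evalue = evalue_from_bit(bit, m, n),
        pident = 100 * al$n_ident / al$cols,
        length = al$cols, n_ident = al$n_ident,
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) return(empty_hits())
  out <- do.call(rbind, res)
  out[order(-out$bit, -out$pident, out$subject), , drop = FALSE]
}

#' Translated search over a whole assembly
#'
#' Runs [translated_search()] per scaffold with a shared search space
#' (total translated residues of the assembly times panel residues).
#'
#' @param assembly a named `DNAStringSet` (see [read_assembly()]).
#' @inheritParams translated_search
#' @return a combined hit data.frame.
#' @export
search_assembly <- function(assembly, panel, params = search_params()) {
  stopifnot(is(assembly, "DNAStringSet"))
  if (is.null(names(assembly)))
    names(assembly) <- paste0("scaffold_", seq_along(assembly))
  # total translated residues: ~2 * nt length summed over scaffolds
  m <- sum(vapply(seq_along(assembly), function(i) {
    L <- Biostrings::width(assembly)[i]
    sum(pmax(0L, (L - 0:2) %/% 3L)) * 2L
  }, numeric(1)))
  out <- lapply(seq_along(assembly), function(i)
    translated_search(as.character(assembly[[i]]), panel, params,
                      scaffold_id = names(assembly)[i], m_residues = m))
  out <- do.call(rbind, out)
  if (is.null(out)) empty_hits() else out
}

#' Apply the candidate-integration exclusion filters
#'
#' Retains hits with E-value at most `max_evalue`, bit score at least
#' `min_bit` and percent amino-acid identity at least `min_identity`.
#' In `"genome"` mode alignments shorter than `min_len_aa` residues are
#' additionally omitted; `"metagenome"` mode imposes no length penalty
#' (assembled metagenome scaffolds are short).  Threshold comparisons
#' follow BLAST cutoff semantics: a hit exactly at a threshold is kept.
#'
#' @param hits data.frame from [translated_search()].
#' @param mode `"genome"` or `"metagenome"`.
#' @param max_evalue,min_bit,min_identity,min_len_aa filter thresholds.
#' @return the retained subset of `hits`.
#' @export
filter_hits <- function(hits, mode = c("genome", "metagenome"),
                        max_evalue = 1e-5, min_bit = 50,
                        min_identity = 30, min_len_aa = 100L) {
  mode <- match.arg(mode)
  keep <- hits$evalue <= max_evalue & hits$bit >= min_bit &
    hits$pident >= min_identity
  if (mode == "genome") keep <- keep & hits$length >= min_len_aa
  hits[keep, , drop = FALSE]
}

#' Write hits as a BLAST outfmt-6-compatible table
#'
#' Standard 12 columns plus `frame` and `gene_class`; output coordinates
#' are 1-based inclusive as in BLAST tabular output.
#'
#' @param hits hit data.frame.
#' @param path output TSV path.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(
    qseqid = hits$scaffold, sseqid = hits$subject,
    pident = round(hits$pident, 3), length = hits$length,
    mismatch = hits$length - hits$n_ident,
    gapopen = NA_integer_,
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = hits$s_start + 1L, send = hits$s_end,
    evalue = signif(hits$evalue, 3), bitscore = round(hits$bit, 1),
    frame = hits$frame, gene_class = hits$gene_class)
  write_tsv(out, path)
}
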