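# Shared low-level helpers.  Coordinate convention: every interval in this
# package is 0-based half-open on the forward strand unless a writer says
# otherwise (GFF3 output converts to 1-based inclusive).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
as_dna_string <- function(x) {
  if (is(x, "DNAString")) return(x)
  if (is(x, "DNAStringSet")) {
    stopifnot(length(x) == 1L)
    return(x[[1L]])
  }
  Biostrings::DNAString(x)
}

#' @noRd
as_dna_character <- function(x) {
  if (is.character(x)) return(toupper(x))
  as.character(as_dna_string(x))
}

#' Reverse complement of a nucleotide string
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# translate a nucleotide string; trailing partial codon dropped; fuzzy
# codons (N) become X; stops are '*'
#' @noRd
translate_str <- function(nt) {
  n <- nchar(nt)
  if (n < 3L) return("")
  n3 <- n - n %% 3L
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n3)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

# count in-frame stop codons, excluding a stop in the final codon position
#' @noRd
count_internal_stops <- function(nt) {
  aa <- translate_str(nt)
  if (nchar(aa) <= 1L) return(0L)
  internal <- substr(aa, 1L, nchar(aa) - 1L)
  sum(strsplit(internal, "")[[1]] == "*")
}

# distance between the facing ends of two 0-based half-open intervals
# (0 when they overlap or abut)
#' @noRd
interval_gap <- function(a_start, a_end, b_start, b_end) {
  if (b_start >= a_end) return(b_start - a_end)
  if (a_start >= b_end) return(a_start - b_end)
  0L
}

#' @noRd
intervals_overlap <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end && b_start < a_end
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# rough background amino-acid frequencies (Robinson & Robinson style),
# used for the synthetic panels
AA20_FREQ <- c(A = 0.078, C = 0.019, D = 0.054, E = 0.063, F = 0.039,
               G = 0.074, H = 0.022, I = 0.051, K = 0.057, L = 0.090,
               M = 0.022, N = 0.045, P = 0.052, Q = 0.043, R = 0.051,
               S = 0.071, T = 0.058, V = 0.064, W = 0.013, Y = 0.032)

#' @noRd
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' @noRd
random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE, prob = AA20_FREQ), collapse = "")
}

# synonymous codon tables ----------------------------------------------------

codon_env <- new.env(parent = emptyenv())

#' @noRd
genetic_code <- function() {
  if (is.null(codon_env$code)) {
    codon_env$code <- Biostrings::GENETIC_CODE
    codon_env$by_aa <- split(names(codon_env$code), unname(codon_env$code))
    codon_env$gc_frac <- vapply(names(codon_env$code), function(cd) {
      b <- strsplit(cd, "")[[1]]
      sum(b %in% c("G", "C")) / 3
    }, numeric(1))
  }
  codon_env
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Back-translate an amino-acid string choosing synonymous codons with
# probability weighted toward a target GC fraction, so planted coding
# sequence matches the compositional background of its host scaffold.
#' @noRd
back_translate <- function(aa, gc = 0.5) {
  ce <- genetic_code()
  res <- strsplit(aa, "")[[1]]
  codons <- vapply(res, function(a) {
    cands <- ce$by_aa[[a]]
    if (is.null(cands)) stop("cannot back-translate residue '", a, "'")
    if (length(cands) == 1L) return(cands)
    g <- ce$gc_frac[cands]
    # weight each codon by Bernoulli base probabilities at the target GC
    w <- (gc / 2)^(3 * g) * ((1 - gc) / 2)^(3 * (1 - g))
    sample(cands, 1L, prob = w / sum(w))
  }, character(1))
  paste(codons, collapse = "")
}

# seeded evaluation that restores the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

#' Read an assembly FASTA into a DNAStringSet
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that trims FASTA
#' descriptions to the first whitespace token so scaffold ids are stable.
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_assembly <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L)
    stop("no sequence records in '", path, "'")
  names(x) <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  x
}

#' @noRd
write_fasta <- function(x, path, width = 70L) {
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
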