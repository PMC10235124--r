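# Sequence-comparison layer: global pairwise identity, codon-aware
# back-alignment of CDS onto a protein alignment, Nei-Gojobori (1986)
# counting dN/dS with Jukes-Cantor correction, and a neighbor-joining
# tree utility.

#' Global pairwise identity
#'
#' Needleman-Wunsch global alignment identity: matches divided by
#' alignment columns (gaps included), as a percentage.  Nucleotide input
#' is scored match +1 / mismatch -1 with gap open 2 / extend 1; protein
#' input uses BLOSUM62 with gap open 11 / extend 1.
#'
#' @param a,b two sequences over the same alphabet (nucleotide or amino
#'   acid, auto-detected).
#' @return identity in percent (0-100).
#' @export
pairwise_identity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("pairwise_identity() requires non-empty sequences")
  is_nt <- !grepl("[^ACGTUN]", paste0(a, b))
  if (is_nt) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                    mismatch = -1)
    p <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  } else {
    p <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 11, gapExtension = 1)
  }
  pa <- strsplit(as.character(Biostrings::alignedPattern(p)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(p)), "")[[1]]
  100 * sum(pa == sa & pa != "-") / length(pa)
}

#' Back-align coding sequences onto a protein alignment
#'
#' Every residue of the protein alignment is replaced by the codon of the
#' corresponding CDS and every gap by `---`, so codons are preserved
#' verbatim (pal2nal-style).  Each CDS must translate exactly to its
#' ungapped protein row (a terminal stop codon on the CDS is tolerated
#' and dropped).
#'
#' @param protein_aln named character vector of gapped amino-acid rows
#'   (equal widths).
#' @param cds named character vector of in-frame coding sequences, names
#'   matching `protein_aln`.
#' @return a `codon_alignment`: named character vector of gapped CDS rows
#'   whose width is 3x the protein alignment width.
#' @export
codon_backalign <- function(protein_aln, cds) {
  stopifnot(length(protein_aln) >= 2L,
            !is.null(names(protein_aln)), !is.null(names(cds)))
  if (length(unique(nchar(protein_aln))) != 1L)
    stop("protein alignment rows must have equal width")
  missing <- setdiff(names(protein_aln), names(cds))
  if (length(missing))
    stop("no CDS for row(s): ", paste(missing, collapse = ", "))
  out <- vapply(names(protein_aln), function(nm) {
    row <- strsplit(toupper(protein_aln[[nm]]), "")[[1]]
    nt <- toupper(cds[[nm]])
    if (nchar(nt) %% 3L != 0L)
      stop("CDS length of '", nm, "' is not a multiple of 3")
    aa <- translate_str(nt)
    if (endsWith(aa, "*")) {  # drop a terminal stop codon
      aa <- substr(aa, 1L, nchar(aa) - 1L)
      nt <- substr(nt, 1L, nchar(nt) - 3L)
    }
    ungapped <- paste(row[row != "-"], collapse = "")
    if (aa != ungapped) {
      pos <- which(strsplit(aa, "")[[1]] !=
                     strsplit(ungapped, "")[[1]])[1]
      stop("CDS of '", nm, "' does not translate to its protein row ",
           "(first mismatch at residue ", pos %||% NA, ")")
    }
    codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
    k <- 0L
    paste(vapply(row, function(ch) {
      if (ch == "-") "---" else { k <<- k + 1L; codons[k] }
    }, character(1)), collapse = "")
  }, character(1))
  structure(out, class = "codon_alignment")
}

# --- NG86 -------------------------------------------------------------------

NT4 <- c("A", "C", "G", "T")

# expected synonymous/nonsynonymous site fractions of one codon;
# substitutions producing a stop codon count as nonsynonymous
#' @noRd
ng86_sites <- function(codon) {
  ce <- genetic_code()
  aa <- unname(ce$code[codon])
  s <- 0
  b <- strsplit(codon, "")[[1]]
  for (p in 1:3) for (alt in setdiff(NT4, b[p])) {
    nb <- b; nb[p] <- alt
    naa <- unname(ce$code[paste(nb, collapse = "")])
    if (naa != "*" && naa == aa) s <- s + 1 / 3
  }
  c(S = s, N = 3 - s)
}

# observed synonymous/nonsynonymous differences between two codons,
# averaged over all mutational pathways (orderings of the differing
# positions); pathways passing through a stop codon are excluded unless
# every pathway does
#' @noRd
ng86_diffs <- function(c1, c2) {
  ce <- genetic_code()
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  diff <- which(b1 != b2)
  k <- length(diff)
  if (k == 0L) return(c(Sd = 0, Nd = 0))
  paths <- if (k == 1L) list(diff) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      unlist(lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
    }
    perms(diff)
  }
  tally <- function(order) {
    cur <- b1; sd <- 0; nd <- 0; ok <- TRUE
    for (p in order) {
      nxt <- cur; nxt[p] <- b2[p]
      a1 <- unname(ce$code[paste(cur, collapse = "")])
      a2 <- unname(ce$code[paste(nxt, collapse = "")])
      if (a2 == "*" && !identical(nxt, b2)) ok <- FALSE
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, ok)
  }
  res <- t(vapply(paths, tally, numeric(3)))
  use <- res[, 3] == 1
  if (!any(use)) use <- rep(TRUE, nrow(res))
  c(Sd = mean(res[use, 1]), Nd = mean(res[use, 2]))
}

#' Nei-Gojobori (1986) dN/dS on a codon alignment
#'
#' Counting estimator: per-codon synonymous/nonsynonymous site fractions
#' averaged over both sequences, observed differences averaged over all
#' equally weighted mutational pathways (pathways through intermediate
#' stop codons excluded when avoidable), proportions corrected with
#' Jukes-Cantor, `d = -3/4 log(1 - 4p/3)`.  Codon columns containing a
#' gap or an in-frame stop in either sequence are skipped.  The first two
#' rows of the alignment are compared.
#'
#' @param ca a `codon_alignment` (see [codon_backalign()]) or character
#'   vector of two equal-width gapped in-frame CDS.
#' @return object of class `dnds_result`: list with `codons` (compared),
#'   `N`, `S` (site counts), `Nd`, `Sd`, `pN`, `pS`, `dN`, `dS`, `omega`
#'   (`NA` when `dS` is 0 or a proportion exceeds the Jukes-Cantor domain,
#'   flagged in `notes`).
#' @export
ng86_dnds <- function(ca) {
  stopifnot(length(ca) >= 2L)
  x <- toupper(ca[[1]]); y <- toupper(ca[[2]])
  if (nchar(x) != nchar(y) || nchar(x) %% 3L != 0L)
    stop("rows must be equal-width and a multiple of 3")
  cods_x <- substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  cods_y <- substring(y, seq(1, nchar(y), 3), seq(3, nchar(y), 3))
  ce <- genetic_code()
  N <- 0; S <- 0; Nd <- 0; Sd <- 0; used <- 0L; notes <- character()
  for (i in seq_along(cods_x)) {
    cx <- cods_x[i]; cy <- cods_y[i]
    if (grepl("[^ACGT]", cx) || grepl("[^ACGT]", cy)) next
    if (ce$code[cx] == "*" || ce$code[cy] == "*") {
      notes <- c(notes, sprintf("in-frame stop at codon %d skipped", i))
      next
    }
    used <- used + 1L
    sx <- ng86_sites(cx); sy <- ng86_sites(cy)
    S <- S + (sx["S"] + sy["S"]) / 2
    N <- N + (sx["N"] + sy["N"]) / 2
    d <- ng86_diffs(cx, cy)
    Sd <- Sd + d["Sd"]; Nd <- Nd + d["Nd"]
  }
  pN <- if (N > 0) unname(Nd / N) else NA_real_
  pS <- if (S > 0) unname(Sd / S) else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  dN <- jc(pN); dS <- jc(pS)
  if (!is.na(pN) && pN >= 3 / 4)
    notes <- c(notes, "pN >= 3/4: Jukes-Cantor correction undefined")
  if (!is.na(pS) && pS >= 3 / 4)
    notes <- c(notes, "pS >= 3/4: Jukes-Cantor correction undefined")
  omega <- if (is.na(dN) || is.na(dS) || dS == 0) NA_real_ else dN / dS
  structure(list(codons = used, N = unname(N), S = unname(S),
                 Nd = unname(Nd), Sd = unname(Sd),
                 pN = unname(pN), pS = unname(pS),
                 dN = dN, dS = dS, omega = omega, notes = notes),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf(
    "NG86 dN/dS over %d codons: N=%.1f S=%.1f Nd=%.2f Sd=%.2f\n",
    x$codons, x$N, x$S, x$Nd, x$Sd))
  cat(sprintf("  pN=%.4f pS=%.4f dN=%.4f dS=%.4f omega=%s\n",
              x$pN, x$pS, x$dN, x$dS,
              if (is.na(x$omega)) "undefined" else sprintf("%.3f",
                                                           x$omega)))
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

#' All-pairs NG86 dN/dS summary
#'
#' @param ca a `codon_alignment` with two or more rows.
#' @return list with matrices `omega`, `dN`, `dS` and `mean_omega` (mean
#'   of defined pairwise omegas).
#' @export
dnds_matrix <- function(ca) {
  n <- length(ca)
  nm <- names(ca) %||% paste0("seq", seq_len(n))
  om <- dn <- ds <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- ng86_dnds(c(ca[[i]], ca[[j]]))
    om[i, j] <- om[j, i] <- r$omega
    dn[i, j] <- dn[j, i] <- r$dN
    ds[i, j] <- ds[j, i] <- r$dS
  }
  list(omega = om, dN = dn, dS = ds,
       mean_omega = mean(om[upper.tri(om)], na.rm = TRUE))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via the ape package), with input checks;
#' returns an `ape::phylo` tree that can be written with
#' [ape::write.tree()].
#'
#' @param d symmetric numeric matrix with zero diagonal (taxa in
#'   dimnames) or a `dist` object.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (any(abs(d - t(d)) > 1e-8))
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0))
    stop("distance matrix must have a zero diagonal")
  ape::nj(d)
}
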