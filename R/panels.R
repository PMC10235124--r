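# Protein reference panels.  A panel is a plain data.frame with one row per
# reference protein: id, aa (sequence), gene_class, panel_name.  Recognized
# gene classes: MCP, RdRp, other_viral, retroelement, cellular.

PANEL_CLASSES <- c("MCP", "RdRp", "other_viral", "retroelement", "cellular")

#' Construct a protein panel
#'
#' @param id character vector of unique protein ids.
#' @param aa character vector of amino-acid sequences (no gaps, no stops).
#' @param gene_class one of `"MCP"`, `"RdRp"`, `"other_viral"`,
#'   `"retroelement"`, `"cellular"`, recycled along `id`.
#' @param panel_name label recorded with every entry.
#' @return a `data.frame` of class `protein_panel`.
#' @export
protein_panel <- function(id, aa, gene_class, panel_name = "user_panel") {
  stopifnot(length(id) == length(aa), !anyDuplicated(id))
  gene_class <- rep_len(gene_class, length(id))
  bad <- setdiff(unique(gene_class), PANEL_CLASSES)
  if (length(bad))
    stop("unknown gene_class: ", paste(bad, collapse = ", "))
  aa <- toupper(aa)
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX]", aa)))
    stop("panel sequences must use the amino-acid alphabet")
  out <- data.frame(id = as.character(id), aa = aa,
                    gene_class = gene_class,
                    panel_name = panel_name,
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_panel", "data.frame")
  out
}

#' Read a protein panel from FASTA
#'
#' Headers carry annotation tokens, e.g.
#' `>vMCP_A gene_class=MCP panel=synthetic_dinoRNAV`.
#' Entries without a `gene_class=` token default to `other_viral`.
#'
#' @param path FASTA file of protein sequences.
#' @param default_class gene class assumed when the header has no token.
#' @return a `protein_panel` data.frame.
#' @export
read_panel <- function(path, default_class = "other_viral") {
  x <- Biostrings::readAAStringSet(path)
  if (length(x) == 0L) stop("no records in panel '", path, "'")
  hdr <- names(x)
  id <- vapply(strsplit(hdr, "\\s+"), `[[`, character(1), 1L)
  token <- function(h, key, default) {
    m <- regmatches(h, regexpr(paste0(key, "=\\S+"), h))
    if (length(m)) sub(paste0(key, "="), "", m) else default
  }
  gene_class <- vapply(hdr, token, character(1), key = "gene_class",
                       default = default_class, USE.NAMES = FALSE)
  panel <- vapply(hdr, token, character(1), key = "panel",
                  default = "user_panel", USE.NAMES = FALSE)
  out <- protein_panel(id, as.character(x), gene_class, panel[1L])
  out$panel_name <- panel
  out
}

#' Write a protein panel to FASTA with annotation tokens
#'
#' @param panel a `protein_panel`.
#' @param path output FASTA path.
#' @export
write_panel <- function(panel, path) {
  aa <- Biostrings::AAStringSet(panel$aa)
  names(aa) <- sprintf("%s gene_class=%s panel=%s",
                       panel$id, panel$gene_class, panel$panel_name)
  write_fasta(aa, path)
}

# --- bundled synthetic panels ----------------------------------------------
#
# The panels below are synthetic stand-ins generated from a fixed internal
# seed: deterministic pseudo-random proteins with the lengths and class
# structure of a curated dinoRNAV reference set (MCP ~358 aa, RdRp ~460 aa,
# two strains per class ~70% identical), plus a cellular decoy panel
# (collagen-like, RNA-binding, histone-like, LINE reverse transcriptase,
# integrase-like).  They are NOT real viral or dinoflagellate sequences;
# they exist so the detector and the synthetic benchmark share a closed,
# self-consistent reference set.

#' @noRd
mutate_protein <- function(aa, p) {
  res <- strsplit(aa, "")[[1]]
  hit <- runif(length(res)) < p
  res[hit] <- vapply(res[hit], function(a)
    sample(setdiff(AA20, a), 1L), character(1))
  paste(res, collapse = "")
}

#' Bundled synthetic viral protein panel
#'
#' Two MCP and two RdRp pseudo-proteins ("strain" A/B variants ~70%
#' identical within a class).  Deterministic; labelled synthetic.
#'
#' @return a `protein_panel` with gene classes `MCP` and `RdRp`.
#' @export
synthetic_viral_panel <- function() {
  with_seed(780923L, {
    mcp_a <- random_protein(358L)
    mcp_b <- mutate_protein(mcp_a, 0.30)
    rdrp_a <- random_protein(460L)
    rdrp_b <- mutate_protein(rdrp_a, 0.30)
    protein_panel(
      id = c("synMCP_A", "synMCP_B", "synRdRp_A", "synRdRp_B"),
      aa = c(mcp_a, mcp_b, rdrp_a, rdrp_b),
      gene_class = c("MCP", "MCP", "RdRp", "RdRp"),
      panel_name = "synthetic_dinoRNAV")
  })
}

#' Bundled synthetic cellular decoy panel
#'
#' Pseudo-proteins standing in for the host (cellular) protein space used
#' to annotate ORFs adjacent to candidate integrations: collagen-like,
#' RNA-binding-like, histone-like, integrase-like, and a LINE reverse
#' transcriptase surrogate carried as gene class `retroelement`.
#' Deterministic; labelled synthetic.
#'
#' @return a `protein_panel`.
#' @export
synthetic_cellular_panel <- function() {
  with_seed(411217L, {
    protein_panel(
      id = c("synCollagen", "synRBP", "synHistone", "synIntegrase",
             "synLINE_RT"),
      aa = c(random_protein(300L), random_protein(240L),
             random_protein(140L), random_protein(280L),
             random_protein(220L)),
      gene_class = c("cellular", "cellular", "cellular", "cellular",
                     "retroelement"),
      panel_name = "synthetic_decoy")
  })
}
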