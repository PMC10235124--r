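# Independent oracles used to check the package implementations, plus a
# lazily built shared benchmark.  Each oracle is deliberately written as a
# plain, slow, loop-based reference, separate from the package code paths.

# random sequence helpers (driven by the calling test's RNG state)
rnd_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rnd_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

splice <- function(seqc, insert, at) {
  paste0(substr(seqc, 1, at), insert,
         substr(seqc, at + nchar(insert) + 1, nchar(seqc)))
}

# --- Smith-Waterman oracle: best local score per frame, via Biostrings ----
oracle_best_local_score <- function(dna, protein) {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  best <- 0
  for (f in six_frame_translate(dna)) {
    if (nchar(f$aa) == 0) next
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(f$aa), Biostrings::AAString(protein),
      type = "local", substitutionMatrix = e$BLOSUM62,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    best <- max(best, sc)
  }
  best
}

# --- ORF oracle: per-codon stop mask from a local codon table ------------
ORACLE_CODE <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  cods <- as.vector(sapply(bases, function(b1)
    sapply(bases, function(b2) paste0(b1, b2, bases))))
  stats::setNames(aas, cods)
})

oracle_orfs <- function(dna, min_len_aa) {
  L <- nchar(dna)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- paste(rev(comp[strsplit(dna, "")[[1]]]), collapse = "")
  out <- list()
  for (fr in c(1, 2, 3, -1, -2, -3)) {
    src <- if (fr > 0) dna else rc
    off <- abs(fr) - 1
    n_aa <- (L - off) %/% 3
    if (n_aa == 0) next
    aa <- vapply(seq_len(n_aa), function(i) {
      cod <- substr(src, off + 3 * (i - 1) + 1, off + 3 * i)
      if (grepl("[^ACGT]", cod)) "X" else unname(ORACLE_CODE[cod])
    }, character(1))
    is_stop <- aa == "*"
    r <- rle(is_stop)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(!r$values & r$lengths >= min_len_aa)) {
      a0 <- starts[k]; a1 <- ends[k]
      nt <- if (fr > 0) c(off + 3 * (a0 - 1), off + 3 * a1)
            else c(L - off - 3 * a1, L - off - 3 * (a0 - 1))
      out[[length(out) + 1]] <- data.frame(
        start = nt[1], end = nt[2], frame = fr,
        aa = paste(aa[a0:a1], collapse = ""), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                      frame = integer(), aa = character()))
  out <- do.call(rbind, out)
  out[order(out$start, out$end, out$frame), , drop = FALSE]
}

# --- spliced-leader oracle: all placements, both strands, plain loops ----
oracle_sl <- function(seqc, eve_start, eve_end, q, window = 500,
                      word = 9, min_matches = 18) {
  L <- nchar(seqc)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rcq <- paste(rev(comp[strsplit(q$seq, "")[[1]]]), collapse = "")
  res <- list()
  regions <- list(c(max(0, eve_start - window), eve_start),
                  c(eve_end, min(L, eve_end + window)))
  for (reg in regions) {
    if (reg[2] - reg[1] < 22) next
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") q$seq else rcq
      amb <- if (strand == "+") q$ambiguous else sort(23 - q$ambiguous)
      for (pos in reg[1]:(reg[2] - 22)) {
        win <- substr(seqc, pos + 1, pos + 22)
        eq <- strsplit(win, "")[[1]] == strsplit(qs, "")[[1]]
        m <- sum(eq[setdiff(1:22, amb)])
        seeded <- FALSE
        for (w0 in 1:(22 - word + 1)) {
          idx <- w0:(w0 + word - 1)
          if (any(idx %in% amb)) next
          if (all(eq[idx])) { seeded <- TRUE; break }
        }
        if (m >= min_matches && seeded)
          res[[length(res) + 1]] <- data.frame(
            position = pos, strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(data.frame(position = integer(),
                                      strand = character()))
  out <- do.call(rbind, res)
  out[order(out$position, out$strand), , drop = FALSE]
}

# --- NG86 pathway oracle: exhaustive enumeration for one codon pair ------
oracle_codon_diffs <- function(c1, c2) {
  code <- ORACLE_CODE
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  d <- which(b1 != b2)
  if (!length(d)) return(c(Sd = 0, Nd = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  walk <- function(ord) {
    cur <- b1; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- b2[p]
      a1 <- unname(code[paste(cur, collapse = "")])
      a2 <- unname(code[paste(nxt, collapse = "")])
      if (a2 == "*" && !all(nxt == b2)) blocked <- TRUE
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, blocked)
  }
  res <- t(vapply(perms(d), walk, numeric(3)))
  use <- res[, 3] == 0
  if (!any(use)) use <- rep(TRUE, nrow(res))
  c(Sd = mean(res[use, 1]), Nd = mean(res[use, 2]))
}

# --- global affine-gap alignment oracle (Gotoh, plain R) -----------------
# returns list(score, identity) for nucleotide scoring match 1 /
# mismatch -1, gap of length L costs open + L * ext
oracle_global_identity <- function(a, b, match = 1, mismatch = -1,
                                   open = 2, ext = 1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1); E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  H[1, 1] <- 0
  for (j in 2:(m + 1)) { E[1, j] <- -(open + (j - 1) * ext); H[1, j] <- E[1, j] }
  for (i in 2:(n + 1)) { F[i, 1] <- -(open + (i - 1) * ext); H[i, 1] <- F[i, 1] }
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
    sub <- if (x[i - 1] == y[j - 1]) match else mismatch
    H[i, j] <- max(H[i - 1, j - 1] + sub, E[i, j], F[i, j])
  }
  # traceback for identity
  i <- n + 1; j <- m + 1; ident <- 0; cols <- 0
  while (i > 1 || j > 1) {
    if (i > 1 && j > 1 &&
        H[i, j] == H[i - 1, j - 1] +
          (if (x[i - 1] == y[j - 1]) match else mismatch)) {
      ident <- ident + (x[i - 1] == y[j - 1]); cols <- cols + 1
      i <- i - 1; j <- j - 1
    } else if (j > 1 && H[i, j] == E[i, j]) {
      while (j > 1 && E[i, j] == E[i, j - 1] - ext) { cols <- cols + 1; j <- j - 1 }
      cols <- cols + 1; j <- j - 1
    } else {
      while (i > 1 && F[i, j] == F[i - 1, j] - ext) { cols <- cols + 1; i <- i - 1 }
      cols <- cols + 1; i <- i - 1
    }
  }
  list(score = H[n + 1, m + 1], identity = 100 * ident / cols)
}

# --- shared default benchmark (built once per test run) ------------------
bench_env <- new.env()

default_benchmark_scan <- function() {
  if (is.null(bench_env$res))
    bench_env$res <- scan_benchmark(sim_config(seed = 1))
  bench_env$res
}
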