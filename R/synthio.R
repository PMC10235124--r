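# Seeded synthetic benchmark generator.  Builds host-like assemblies with
# planted, ground-truthed features: degraded viral ORFs (single MCP/RdRp
# or whole-genome MCP+RdRp pairs separated by a noncoding gap), relict
# spliced leaders at known offsets, LINE-like retroelement neighbors,
# planted cellular genes, EVE-free negative scaffolds, and chimeric
# scaffolds whose read set covers only one half.  Everything is emitted
# together with a manifest that records exactly what was planted where,
# so every stage of the detector is verifiable.

#' Simulation configuration
#'
#' Defines the conditions of the default benchmark.  Viral plants are
#' degraded back-translations of the bundled synthetic panel proteins:
#' amino-acid substitutions at rate `divergence`, then nucleotide indels
#' at per-site rate `indel_rate` (indel length a multiple of 3 with
#' probability 1/2, otherwise frameshifting), then with probability
#' `stop_rate` an in-frame internal stop codon — the degradation spectrum
#' seen in real fragmented integrations.  `divergence` is recycled across
#' the single-ORF plants (the default grid 0-0.5 spans intact to heavily
#' degraded copies); `genomic_divergence` across the genomic pairs;
#' `genomic_gap` (noncoding nt between the paired MCP and RdRp) is
#' recycled across pairs and by default spans the observed ~200-800 nt
#' range plus probes at 1200 and 1501 nt around the 1.5-kbp pairing rule.
#'
#' @param seed integer seed; a fixed seed makes every output
#'   byte-identical.
#' @param n_scaffolds number of EVE-bearing scaffolds
#'   (`n_single_eves + n_genomic_eves`).
#' @param scaffold_len scaffold length in nt.
#' @param gc GC fraction of host background (0-1).
#' @param n_single_eves,n_genomic_eves single-ORF and paired plants.
#' @param divergence expected amino-acid divergence of single plants
#'   (fraction 0-1, recycled).
#' @param genomic_divergence divergence of genomic-pair plants (recycled).
#' @param stop_rate probability a planted ORF receives an internal stop.
#' @param indel_rate per-nucleotide indel probability.
#' @param sl_offset dinoSL placement this many nt 5' of the RdRp start
#'   (0 disables).
#' @param line_offset LINE-like neighbor placement this many nt
#'   downstream of the EVE (0 disables; applied to every other plant).
#' @param genomic_gap noncoding gap(s) between paired MCP and RdRp, nt.
#' @param negatives number of EVE-free scaffolds.
#' @param chimeras number of chimeric scaffolds (EVE adjacent to a
#'   coverage discontinuity).
#' @param n_cellular_per_scaffold cellular decoy genes planted per
#'   EVE-bearing scaffold.
#' @param read_len,depth read length and target uniform depth for the
#'   simulated read set.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_scaffolds = 30L, scaffold_len = 7000L,
                       gc = 0.5, n_single_eves = 24L, n_genomic_eves = 6L,
                       divergence = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                       genomic_divergence = c(0, 0.1, 0.2),
                       stop_rate = 0.3, indel_rate = 0.001,
                       sl_offset = 100L, line_offset = 95L,
                       genomic_gap = c(319L, 400L, 656L, 800L, 1200L,
                                       1501L),
                       negatives = 10L, chimeras = 5L,
                       n_cellular_per_scaffold = 1L,
                       read_len = 100L, depth = 30L) {
  cfg <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
              scaffold_len = as.integer(scaffold_len), gc = gc,
              n_single_eves = as.integer(n_single_eves),
              n_genomic_eves = as.integer(n_genomic_eves),
              divergence = divergence,
              genomic_divergence = genomic_divergence,
              stop_rate = stop_rate, indel_rate = indel_rate,
              sl_offset = as.integer(sl_offset),
              line_offset = as.integer(line_offset),
              genomic_gap = as.integer(genomic_gap),
              negatives = as.integer(negatives),
              chimeras = as.integer(chimeras),
              n_cellular_per_scaffold = as.integer(n_cellular_per_scaffold),
              read_len = as.integer(read_len), depth = as.integer(depth))
  fracs <- c(cfg$gc, cfg$divergence, cfg$genomic_divergence, cfg$stop_rate,
             cfg$indel_rate)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions (gc, divergence, stop_rate, indel_rate) must lie in ",
         "[0, 1]")
  if (any(cfg$genomic_gap < 0L)) stop("genomic_gap must be >= 0")
  if (cfg$n_single_eves + cfg$n_genomic_eves != cfg$n_scaffolds)
    stop("n_scaffolds must equal n_single_eves + n_genomic_eves")
  if (cfg$scaffold_len < 1000L) stop("scaffold_len too small")
  class(cfg) <- "sim_config"
  cfg
}

# degrade a panel protein and back-translate it; returns the cassette
# (coding nt + terminal stop) plus realized statistics
#' @noRd
degrade_and_encode <- function(aa, divergence, stop_rate, indel_rate, gc) {
  res <- strsplit(aa, "")[[1]]
  hit <- runif(length(res)) < divergence
  res[hit] <- vapply(res[hit], function(a)
    sample(setdiff(AA20, a), 1L), character(1))
  realized_div <- mean(hit)
  nt <- back_translate(paste(res, collapse = ""), gc)
  # indels: per-site events; length 3 (in-frame) with probability 1/2,
  # else 1 or 2 (frameshift); insertion or deletion equally likely
  sites <- which(runif(nchar(nt)) < indel_rate)
  for (p in rev(sites)) {   # right-to-left so positions stay valid
    len <- if (runif(1) < 0.5) 3L else sample(1:2, 1L)
    if (runif(1) < 0.5) {   # insertion after p
      nt <- paste0(substr(nt, 1L, p), random_dna(len, gc),
                   substr(nt, p + 1L, nchar(nt)))
    } else {                # deletion starting at p
      if (p + len - 1L >= nchar(nt)) next
      nt <- paste0(substr(nt, 1L, p - 1L),
                   substr(nt, p + len, nchar(nt)))
    }
  }
  # stop injection: replace an internal in-frame codon with a stop
  if (runif(1) < stop_rate && nchar(nt) >= 9L) {
    ncod <- nchar(nt) %/% 3L
    k <- sample(2:(ncod - 1L), 1L)
    nt <- paste0(substr(nt, 1L, 3L * (k - 1L)), sample(STOP_CODONS, 1L),
                 substr(nt, 3L * k + 1L, nchar(nt)))
  }
  list(nt = nt, realized_div = realized_div,
       realized_stops = count_internal_stops(nt))
}

#' Degrade a coding sequence under a simple substitution model
#'
#' Applies per-site nucleotide substitutions to an in-frame CDS.  In
#' `"neutral"` mode every site mutates with probability `rate` to a
#' uniformly chosen alternative base (substitutions creating an in-frame
#' stop codon are suppressed, mirroring the absence of segregating
#' nonsense alleles); in `"synonymous_only"` mode a substitution is kept
#' only when it leaves the encoded amino acid unchanged, giving sequence
#' pairs whose differences are synonymous by construction.
#'
#' @param cds in-frame coding sequence (length a multiple of 3, no
#'   internal stops).
#' @param rate per-site substitution probability.
#' @param mode `"neutral"` or `"synonymous_only"`.
#' @return the degraded CDS (same length).
#' @export
degrade_cds <- function(cds, rate, mode = c("neutral", "synonymous_only")) {
  mode <- match.arg(mode)
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3L != 0L) stop("CDS length must be a multiple of 3")
  ce <- genetic_code()
  b <- strsplit(cds, "")[[1]]
  sites <- which(runif(length(b)) < rate)
  for (p in sites) {
    alt <- sample(setdiff(NT4, b[p]), 1L)
    cod_i <- (p - 1L) %/% 3L
    idx <- (cod_i * 3L + 1L):(cod_i * 3L + 3L)
    new <- b[idx]; new[p - cod_i * 3L] <- alt
    old_aa <- unname(ce$code[paste(b[idx], collapse = "")])
    new_aa <- unname(ce$code[paste(new, collapse = "")])
    if (new_aa == "*") next
    if (mode == "synonymous_only" && new_aa != old_aa) next
    b[p] <- alt
  }
  paste(b, collapse = "")
}

#' @noRd
manifest_record <- function(scaffold_id, feature, start, end, strand = "+",
                            source_id = NA_character_,
                            divergence = NA_real_, stops = NA_integer_,
                            gap = NA_integer_, pair_id = NA_character_) {
  data.frame(scaffold = scaffold_id, feature = feature,
             start = as.integer(start), end = as.integer(end),
             strand = strand, source_id = source_id,
             divergence = divergence, stops = as.integer(stops),
             gap = as.integer(gap), pair_id = pair_id,
             stringsAsFactors = FALSE)
}

# overwrite scaffold background with a cassette at 0-based position p
#' @noRd
splice_in <- function(seqc, cassette, p) {
  stopifnot(p >= 0L, p + nchar(cassette) <= nchar(seqc))
  paste0(substr(seqc, 1L, p), cassette,
         substr(seqc, p + nchar(cassette) + 1L, nchar(seqc)))
}

# pick a placement start that keeps [p - need_before, p + len + need_after)
# inside the scaffold and clear of occupied intervals; bounded retries
#' @noRd
place_feature <- function(L, len, occupied, need_before = 0L,
                          need_after = 0L, tries = 25L) {
  lo <- need_before
  hi <- L - len - need_after
  if (hi < lo)
    stop("configuration error: planted feature of ", len,
         " nt (+", need_before, "/+", need_after,
         " nt of clearance) does not fit a scaffold of length ", L,
         " — reduce feature sizes or increase scaffold_len")
  for (t in seq_len(tries)) {
    p <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    w0 <- p - need_before; w1 <- p + len + need_after
    clash <- any(vapply(occupied, function(iv)
      intervals_overlap(w0, w1, iv[1], iv[2]), logical(1)))
    if (!clash) return(p)
  }
  stop("could not place a ", len,
       "-nt feature without overlap after ", tries, " attempts")
}

#' Plant one EVE (and its accessories) into a scaffold
#'
#' Plants a degraded viral ORF cassette — or a whole-genome MCP + RdRp
#' pair separated by `gap` noncoding nt — by overwriting background
#' sequence, together with an optional relict spliced leader placed
#' `sl_offset` nt 5' of the RdRp start and an optional LINE-like
#' retroelement gene `line_offset` nt downstream of the EVE.
#'
#' @param scaffold background nucleotide sequence (character).
#' @param spec list of per-EVE parameters: `type` (`"single"` or
#'   `"genomic"`), `source_id` (panel id; for genomic, the MCP — its
#'   RdRp partner is the same strain), `divergence`, `stop_rate`,
#'   `indel_rate`, `gap`, `sl_offset`, `line_offset`, `at` (optional
#'   fixed 0-based start).
#' @param viral_panel,cellular_panel bundled or user panels.
#' @param scaffold_id id used in the truth records.
#' @param gc GC fraction used for codon choice in back-translation.
#' @param occupied list of intervals already in use on this scaffold.
#' @return list: `seq` (modified scaffold), `records` (truth
#'   data.frame), `occupied` (updated).
#' @export
plant_eve <- function(scaffold, spec, viral_panel,
                      cellular_panel = synthetic_cellular_panel(),
                      scaffold_id = "scaffold", gc = 0.5,
                      occupied = list()) {
  seqc <- as_dna_character(scaffold)
  L <- nchar(seqc)
  spec$sl_offset <- spec$sl_offset %||% 0L
  spec$line_offset <- spec$line_offset %||% 0L
  spec$stop_rate <- spec$stop_rate %||% 0
  spec$indel_rate <- spec$indel_rate %||% 0
  genomic <- identical(spec$type, "genomic")
  src <- viral_panel[viral_panel$id == spec$source_id, , drop = FALSE]
  if (nrow(src) != 1L)
    stop("unknown panel source '", spec$source_id, "'")
  if (genomic && src$gene_class != "MCP")
    stop("genomic plants start from an MCP panel entry")
  pair_src <- NULL
  if (genomic) {
    strain <- sub("^[^_]*_", "", spec$source_id)
    pair_src <- viral_panel[viral_panel$gene_class == "RdRp" &
                              endsWith(viral_panel$id, strain), ,
                            drop = FALSE][1L, ]
  }
  mcp_cas <- degrade_and_encode(src$aa, spec$divergence, spec$stop_rate,
                                spec$indel_rate, gc)
  cassette <- paste0(mcp_cas$nt, "TAA")
  lens <- c(mcp = nchar(mcp_cas$nt))
  rdrp_cas <- NULL
  if (genomic) {
    if ((spec$gap %||% 0L) < 3L)
      stop("configuration error: genomic_gap must be >= 3 nt ",
           "(it contains the MCP stop codon)")
    rdrp_cas <- degrade_and_encode(pair_src$aa, spec$divergence,
                                   spec$stop_rate, spec$indel_rate, gc)
    gapseq <- random_dna(spec$gap - 3L, gc)  # gap includes the MCP stop
    cassette <- paste0(mcp_cas$nt, "TAA", gapseq, rdrp_cas$nt, "TAA")
    lens["rdrp"] <- nchar(rdrp_cas$nt)
  }
  sl_need <- if (spec$sl_offset > 0L) spec$sl_offset + 22L else 0L
  line_len <- 3L * nchar(
    cellular_panel$aa[cellular_panel$gene_class == "retroelement"][1L]) + 3L
  line_need <- if (spec$line_offset > 0L) spec$line_offset + line_len else 0L
  margin <- 320L  # keep flanks extractable and clear of scaffold edges
  p <- spec$at %||% place_feature(L, nchar(cassette), occupied,
                                  need_before = margin + sl_need,
                                  need_after = margin + line_need)
  seqc <- splice_in(seqc, cassette, p)
  recs <- list()
  pair_id <- if (genomic) sprintf("%s_pair", scaffold_id) else NA_character_
  mcp_cls <- src$gene_class   # MCP for genomic, MCP or RdRp for single
  m0 <- p; m1 <- p + lens[["mcp"]]
  recs[[1]] <- manifest_record(scaffold_id, mcp_cls, m0, m1,
                               source_id = src$id,
                               divergence = mcp_cas$realized_div,
                               stops = mcp_cas$realized_stops,
                               pair_id = pair_id)
  eve_start <- m0; eve_end <- m1
  rdrp_start <- if (mcp_cls == "RdRp") m0 else NA_integer_
  if (genomic) {
    r0 <- m1 + spec$gap; r1 <- r0 + lens[["rdrp"]]
    recs[[2]] <- manifest_record(scaffold_id, "RdRp", r0, r1,
                                 source_id = pair_src$id,
                                 divergence = rdrp_cas$realized_div,
                                 stops = rdrp_cas$realized_stops,
                                 pair_id = pair_id)
    recs[[3]] <- manifest_record(scaffold_id, "genomic_pair", m0, r1,
                                 gap = spec$gap, pair_id = pair_id)
    eve_end <- r1
    rdrp_start <- r0
  }
  occupied <- c(occupied, list(c(eve_start, eve_end)))
  # relict spliced leader, sl_offset nt 5' of the RdRp start
  if (spec$sl_offset > 0L && !is.na(rdrp_start)) {
    sl <- sl_query()$seq
    s0 <- rdrp_start - spec$sl_offset - 22L
    if (s0 < 0L)
      stop("configuration error: sl_offset places the spliced leader ",
           "before the scaffold start")
    seqc <- splice_in(seqc, sl, s0)
    recs[[length(recs) + 1L]] <-
      manifest_record(scaffold_id, "dinoSL", s0, s0 + 22L)
    occupied <- c(occupied, list(c(s0, s0 + 22L)))
  }
  # LINE-like retroelement neighbor downstream of the EVE
  if (spec$line_offset > 0L) {
    rt <- cellular_panel[cellular_panel$gene_class == "retroelement", ,
                         drop = FALSE][1L, ]
    rt_nt <- paste0(back_translate(rt$aa, gc), "TAA")
    l0 <- eve_end + spec$line_offset
    seqc <- splice_in(seqc, rt_nt, l0)
    recs[[length(recs) + 1L]] <-
      manifest_record(scaffold_id, "LINE", l0, l0 + nchar(rt_nt) - 3L,
                      source_id = rt$id)
    occupied <- c(occupied, list(c(l0, l0 + nchar(rt_nt))))
  }
  list(seq = seqc, records = do.call(rbind, recs), occupied = occupied)
}

#' @noRd
plant_cellular <- function(seqc, scaffold_id, cellular_panel, gc,
                           occupied) {
  cand <- cellular_panel[cellular_panel$gene_class == "cellular", ,
                         drop = FALSE]
  g <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
  nt <- paste0(back_translate(g$aa, gc), "TAA")
  p <- place_feature(nchar(seqc), nchar(nt), occupied,
                     need_before = 50L, need_after = 50L)
  seqc <- splice_in(seqc, nt, p)
  rec <- manifest_record(scaffold_id, "cellular_gene", p,
                         p + nchar(nt) - 3L, source_id = g$id)
  list(seq = seqc, records = rec,
       occupied = c(occupied, list(c(p, p + nchar(nt)))))
}

# error-free fixed-length reads tiling [from, to) at uniform depth
#' @noRd
tile_reads <- function(seqc, scaffold_id, from, to, read_len, depth) {
  span <- to - from
  if (span < read_len || depth < 1L) return(Biostrings::DNAStringSet())
  reads <- character()
  for (d in seq_len(depth)) {
    phase <- ((d - 1L) * read_len) %/% depth
    starts <- seq(from + phase, to - read_len, by = read_len)
    reads <- c(reads, substring(seqc, starts + 1L, starts + read_len))
  }
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- sprintf("%s_read%05d", scaffold_id, seq_along(out))
  out
}

#' @noRd
depth_profile <- function(scaffold_id, L, reads_start, reads_end,
                          read_len, depth) {
  d <- integer(L)
  if (reads_end - reads_start >= read_len) {
    for (k in seq_len(depth)) {
      phase <- ((k - 1L) * read_len) %/% depth
      starts <- seq(reads_start + phase, reads_end - read_len,
                    by = read_len)
      for (s in starts) d[(s + 1L):(s + read_len)] <-
          d[(s + 1L):(s + read_len)] + 1L
    }
  }
  data.frame(scaffold = scaffold_id, pos = 0:(L - 1L), depth = d,
             stringsAsFactors = FALSE)
}

#' Build the synthetic benchmark
#'
#' Generates `n_single_eves + n_genomic_eves` EVE-bearing scaffolds,
#' `negatives` EVE-free scaffolds, and `chimeras` chimeric scaffolds
#' (two unrelated halves; an intact EVE ends just before the junction and
#' the read set covers only the first half, so the depth profile is
#' discontinuous across the candidate).  All randomness is driven by
#' `config$seed`; identical configs give byte-identical output.
#'
#' @param config a [sim_config()].
#' @return list of class `eve_benchmark`: `assembly` (`DNAStringSet`),
#'   `reads` (`DNAStringSet`), `depth` (data.frame), `manifest`
#'   (truth data.frame), `viral_panel`, `cellular_panel`, `config`.
#' @export
make_benchmark <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  viral <- synthetic_viral_panel()
  cellular <- synthetic_cellular_panel()
  mcp_ids <- viral$id[viral$gene_class == "MCP"]
  rdrp_ids <- viral$id[viral$gene_class == "RdRp"]
  with_seed(config$seed, {
    seqs <- list(); manifest <- list(); reads <- list(); depth <- list()
    div_s <- rep_len(config$divergence, config$n_single_eves)
    div_g <- rep_len(config$genomic_divergence, config$n_genomic_eves)
    gaps <- rep_len(config$genomic_gap, config$n_genomic_eves)
    add_scaffold <- function(id, seqc, reads_to = NULL) {
      seqs[[id]] <<- seqc
      L <- nchar(seqc)
      to <- reads_to %||% L
      reads[[id]] <<- tile_reads(seqc, id, 0L, to, config$read_len,
                                 config$depth)
      depth[[id]] <<- depth_profile(id, L, 0L, to, config$read_len,
                                    config$depth)
    }
    # single-ORF plants: alternate RdRp / MCP sources across the grid
    for (i in seq_len(config$n_single_eves)) {
      id <- sprintf("scaffold_s%02d", i)
      src <- if (i %% 2L == 1L) rdrp_ids[(i %/% 2L) %% 2L + 1L]
             else mcp_ids[(i %/% 2L) %% 2L + 1L]
      res <- plant_eve(random_dna(config$scaffold_len, config$gc),
                       list(type = "single", source_id = src,
                            divergence = div_s[i],
                            stop_rate = config$stop_rate,
                            indel_rate = config$indel_rate,
                            sl_offset = if (i %% 2L == 1L)
                              config$sl_offset else 0L,
                            line_offset = if (i %% 2L == 0L)
                              config$line_offset else 0L),
                       viral, cellular, scaffold_id = id, gc = config$gc)
      cel <- res
      for (k in seq_len(config$n_cellular_per_scaffold)) {
        cel2 <- plant_cellular(cel$seq, id, cellular, config$gc,
                               cel$occupied)
        cel <- list(seq = cel2$seq,
                    records = rbind(cel$records, cel2$records),
                    occupied = cel2$occupied)
      }
      add_scaffold(id, cel$seq)
      manifest[[id]] <- cel$records
    }
    # genomic pairs
    for (i in seq_len(config$n_genomic_eves)) {
      id <- sprintf("scaffold_g%02d", i)
      res <- plant_eve(random_dna(config$scaffold_len, config$gc),
                       list(type = "genomic",
                            source_id = mcp_ids[i %% 2L + 1L],
                            divergence = div_g[i],
                            stop_rate = config$stop_rate,
                            indel_rate = config$indel_rate,
                            gap = gaps[i],
                            sl_offset = config$sl_offset,
                            line_offset = if (i %% 2L == 0L)
                              config$line_offset else 0L),
                       viral, cellular, scaffold_id = id, gc = config$gc)
      add_scaffold(id, res$seq)
      manifest[[id]] <- res$records
    }
    # negatives: background only
    for (i in seq_len(config$negatives)) {
      id <- sprintf("scaffold_n%02d", i)
      add_scaffold(id, random_dna(config$scaffold_len, config$gc))
    }
    # chimeras: covered half carries an intact EVE ending just before the
    # junction; the other half gets no reads
    for (i in seq_len(config$chimeras)) {
      id <- sprintf("scaffold_c%02d", i)
      half <- config$scaffold_len %/% 2L
      left <- random_dna(half, config$gc)
      src <- rdrp_ids[i %% 2L + 1L]
      eve <- degrade_and_encode(
        viral$aa[viral$id == src], 0, 0, 0, config$gc)
      cassette <- paste0(eve$nt, "TAA")
      p <- half - nchar(cassette) - 100L
      if (p < 350L)
        stop("configuration error: scaffold_len too small for a ",
             "chimeric plant")
      left <- splice_in(left, cassette, p)
      seqc <- paste0(left, random_dna(config$scaffold_len - half,
                                      config$gc))
      add_scaffold(id, seqc, reads_to = half)
      manifest[[id]] <- rbind(
        manifest_record(id, viral$gene_class[viral$id == src], p,
                        p + nchar(eve$nt), source_id = src,
                        divergence = 0, stops = eve$realized_stops),
        manifest_record(id, "chimera_junction", half, half))
    }
    assembly <- Biostrings::DNAStringSet(unlist(seqs))
    manifest <- do.call(rbind, manifest)
    rownames(manifest) <- NULL
    structure(list(assembly = assembly,
                   reads = do.call(c, unname(reads)),
                   depth = do.call(rbind, c(depth,
                                            make.row.names = FALSE)),
                   manifest = manifest,
                   viral_panel = viral, cellular_panel = cellular,
                   config = config),
              class = "eve_benchmark")
  })
}

#' Write a benchmark to disk
#'
#' Emits `assembly.fasta`, `reads.fasta`, `depth.tsv`, `manifest.json`,
#' `viral_panel.fasta`, `cellular_panel.fasta` and a `config.txt` echo.
#'
#' @param bench an `eve_benchmark` from [make_benchmark()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(bench$assembly, file.path(dir, "assembly.fasta"))
  write_fasta(bench$reads, file.path(dir, "reads.fasta"))
  write_tsv(bench$depth, file.path(dir, "depth.tsv"))
  jsonlite::write_json(bench$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", na = "null", digits = NA)
  write_panel(bench$viral_panel, file.path(dir, "viral_panel.fasta"))
  write_panel(bench$cellular_panel, file.path(dir, "cellular_panel.fasta"))
  cfg <- bench$config
  writeLines(vapply(names(cfg), function(k)
    paste0(k, ": ", paste(cfg[[k]], collapse = ",")), character(1)),
    file.path(dir, "config.txt"))
  invisible(dir)
}

#' Read a benchmark manifest back from JSON
#'
#' @param path `manifest.json` written by [write_benchmark()].
#' @return the manifest data.frame.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::fromJSON(path)
  m$start <- as.integer(m$start); m$end <- as.integer(m$end)
  m
}
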