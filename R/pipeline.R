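# Pipeline drivers: configuration, the end-to-end scan
# (homology -> ORFs -> validation -> EVE calls -> context -> coverage),
# simulation and evaluation wrappers, and the GFF3/TSV/JSON writers.

#' Pipeline configuration
#'
#' All stage thresholds in one place.  Defaults equal the screen's
#' published operating point where one exists: homology inclusion at
#' E <= 1e-5, bit >= 50, identity >= 30%, alignments >= 100 aa in genome
#' mode (no length penalty in metagenome mode), ORF annotation at
#' E <= 1e-3 with bit >= 50, 300-nt verification flanks, the 1.5-kbp
#' MCP/RdRp pairing rule, and a 500-nt spliced-leader window with seed
#' word 9.
#'
#' @param mode `"genome"` (length filter imposed) or `"metagenome"`.
#' @param max_evalue,min_bit,min_identity,min_len_aa homology filters.
#' @param orf_min_len_aa minimum ORF length (residues).
#' @param annot_evalue,annot_min_bit ORF annotation thresholds.
#' @param flank_nt verification flank width.
#' @param pairing_nt genomic-pair gap ceiling.
#' @param sl_window,sl_word,sl_min_matches spliced-leader scan settings.
#' @param sl the [sl_query()] to scan for.
#' @param neighbor_window neighborhood annotation radius.
#' @param cov_flank,cov_diff,cov_cv coverage-screen settings.
#' @param search [search_params()] for the alignment engine.
#' @return named list of class `run_config`.
#' @export
run_config <- function(mode = c("genome", "metagenome"),
                       max_evalue = 1e-5, min_bit = 50,
                       min_identity = 30, min_len_aa = 100L,
                       orf_min_len_aa = 60L, annot_evalue = 1e-3,
                       annot_min_bit = 50, flank_nt = 300L,
                       pairing_nt = 1500L, sl_window = 500L,
                       sl_word = 9L, sl_min_matches = 18L,
                       sl = sl_query(), neighbor_window = 20000L,
                       cov_flank = 500L, cov_diff = 0.25, cov_cv = 0.5,
                       search = search_params()) {
  mode <- match.arg(mode)
  structure(list(mode = mode, max_evalue = max_evalue, min_bit = min_bit,
                 min_identity = min_identity,
                 min_len_aa = as.integer(min_len_aa),
                 orf_min_len_aa = as.integer(orf_min_len_aa),
                 annot_evalue = annot_evalue,
                 annot_min_bit = annot_min_bit,
                 flank_nt = as.integer(flank_nt),
                 pairing_nt = as.integer(pairing_nt),
                 sl_window = as.integer(sl_window),
                 sl_word = as.integer(sl_word),
                 sl_min_matches = as.integer(sl_min_matches),
                 sl = sl, neighbor_window = as.integer(neighbor_window),
                 cov_flank = as.integer(cov_flank), cov_diff = cov_diff,
                 cov_cv = cov_cv, search = search),
            class = "run_config")
}

#' End-to-end EVE scan of an assembly
#'
#' Runs the full screen: six-frame translated search of every scaffold
#' against the viral panel; exclusion filters; ORF calling, annotation
#' and flank-based verification on candidate scaffolds; locus merging and
#' EVE calling under the pairing rule; spliced-leader scan, neighborhood
#' annotation and (when depth is supplied) the coverage-uniformity
#' screen.  Optionally writes GFF3/TSV outputs plus a machine-readable
#' run manifest.
#'
#' @param assembly path to a FASTA file or a named `DNAStringSet`.
#' @param viral_panel viral [protein_panel()] (or FASTA path).
#' @param cellular_panel cellular/decoy panel (or FASTA path), optional
#'   but needed for neighborhood annotation.
#' @param depth per-base depth data.frame, TSV path, or `NULL`
#'   (coverage untested).
#' @param config a [run_config()].
#' @param outdir output directory; `NULL` suppresses file output.
#' @param assembly_id label recorded on the calls.
#' @return list of class `eve_scan`: `hits`, `filtered`, `orfs`,
#'   `validated`, `loci`, `eves` (with `sl_hits`, `neighbors`,
#'   `coverage`, `validation` columns), `sl`, `neighbors`, `config`.
#' @export
run_scan <- function(assembly, viral_panel,
                     cellular_panel = synthetic_cellular_panel(),
                     depth = NULL, config = run_config(),
                     outdir = NULL, assembly_id = "assembly") {
  if (is.character(assembly)) assembly <- read_assembly(assembly)
  stopifnot(is(assembly, "DNAStringSet"))
  if (length(assembly) == 0L) stop("empty assembly")
  if (is.character(viral_panel)) viral_panel <- read_panel(viral_panel)
  if (is.character(cellular_panel))
    cellular_panel <- read_panel(cellular_panel,
                                 default_class = "cellular")
  if (is.character(depth)) depth <- read_depth_tsv(depth)
  if (is.null(depth))
    message("no depth input: coverage screen untested")

  hits <- search_assembly(assembly, viral_panel, config$search)
  filtered <- filter_hits(hits, config$mode,
                          max_evalue = config$max_evalue,
                          min_bit = config$min_bit,
                          min_identity = config$min_identity,
                          min_len_aa = config$min_len_aa)
  cand <- unique(filtered$scaffold)
  all_orfs <- list(); validated <- list()
  for (sc in cand) {
    seqc <- as.character(assembly[[sc]])
    orfs <- find_orfs(seqc, min_len_aa = config$orf_min_len_aa,
                      scaffold_id = sc)
    orfs <- annotate_orfs(orfs, viral_panel, cellular_panel,
                          max_evalue = config$annot_evalue,
                          min_bit = config$annot_min_bit,
                          params = config$search)
    all_orfs[[sc]] <- orfs
    validated[[sc]] <- verify_candidates(
      seqc, filtered[filtered$scaffold == sc, , drop = FALSE], orfs,
      viral_panel, flank_nt = config$flank_nt,
      flank_evalue = config$annot_evalue,
      min_len_aa = config$orf_min_len_aa, params = config$search)
  }
  all_orfs <- if (length(all_orfs)) do.call(rbind, c(all_orfs,
                                                     make.row.names = FALSE))
              else empty_orfs()
  validated <- if (length(validated))
    do.call(rbind, c(validated, make.row.names = FALSE)) else
      cbind(empty_hits(), status = character(), support = character())
  loci <- merge_loci(validated)
  eves <- call_eves(loci, pairing_nt = config$pairing_nt)
  eves$assembly <- rep(assembly_id, nrow(eves))
  # per-EVE context: spliced leaders, neighbors, coverage
  sl_all <- list(); nb_all <- list()
  eves$n_sl <- integer(nrow(eves))
  eves$sl_offsets <- character(nrow(eves))
  eves$n_neighbors <- integer(nrow(eves))
  eves$retro_neighbor <- logical(nrow(eves))
  eves$coverage <- character(nrow(eves))
  eves$validation <- character(nrow(eves))
  for (i in seq_len(nrow(eves))) {
    e <- eves[i, ]
    seqc <- as.character(assembly[[e$scaffold]])
    # the spliced leader marks the 5' end of the retroposed mRNA: anchor
    # the scan on the RdRp member when present
    a0 <- if (!is.na(e$rdrp_start)) e$rdrp_start else e$start
    a1 <- if (!is.na(e$rdrp_start)) e$rdrp_end else e$end
    sl <- scan_dinosl(seqc, a0, a1, query = config$sl,
                      window_nt = config$sl_window,
                      word = config$sl_word,
                      min_matches = config$sl_min_matches)
    if (nrow(sl)) {
      sl$eve_id <- e$eve_id; sl$scaffold <- e$scaffold
      sl_all[[length(sl_all) + 1L]] <- sl
    }
    eves$n_sl[i] <- nrow(sl)
    eves$sl_offsets[i] <- paste(sl$offset, collapse = ",")
    nb <- annotate_neighbors(e, all_orfs[all_orfs$scaffold == e$scaffold, ,
                                         drop = FALSE],
                             window_nt = config$neighbor_window)
    if (nrow(nb)) {
      nb$eve_id <- e$eve_id; nb$scaffold <- e$scaffold
      nb_all[[length(nb_all) + 1L]] <- nb
    }
    eves$n_neighbors[i] <- nrow(nb)
    eves$retro_neighbor[i] <- any(nb$retroelement)
    cov <- coverage_uniformity(depth, e$scaffold, e$start, e$end,
                               flank_nt = config$cov_flank,
                               diff_threshold = config$cov_diff,
                               cv_threshold = config$cov_cv)
    eves$coverage[i] <- cov$status
    mem_status <- loci$status[loci$scaffold == e$scaffold &
                                loci$start >= e$start &
                                loci$end <= e$end]
    eves$validation[i] <- if (any(mem_status == "confirmed_flank"))
      "confirmed_flank" else "confirmed_orf"
  }
  sl_all <- if (length(sl_all)) do.call(rbind, sl_all) else NULL
  nb_all <- if (length(nb_all)) do.call(rbind, nb_all) else NULL
  out <- structure(list(hits = hits, filtered = filtered, orfs = all_orfs,
                        validated = validated, loci = loci, eves = eves,
                        sl = sl_all, neighbors = nb_all, config = config,
                        assembly_id = assembly_id),
                   class = "eve_scan")
  if (!is.null(outdir)) write_scan(out, assembly, outdir)
  out
}

#' @export
print.eve_scan <- function(x, ...) {
  cat(sprintf(
    "EVE scan of '%s': %d hits, %d retained, %d loci, %d EVE calls\n",
    x$assembly_id, nrow(x$hits), nrow(x$filtered), nrow(x$loci),
    nrow(x$eves)))
  if (nrow(x$eves)) print(table(x$eves$type))
  invisible(x)
}

#' @noRd
gff3_escape <- function(x) gsub("[;=,\t]", "_", x)

# minimal GFF3 emission for ORF and EVE features (1-based inclusive)
#' @noRd
write_gff3 <- function(df, path, source, type, attrs) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(df))) {
    at <- paste(vapply(names(attrs), function(k) {
      v <- df[[attrs[[k]]]][i]
      paste0(k, "=", gff3_escape(as.character(v)))
    }, character(1)), collapse = ";")
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       df$scaffold[i], source, type,
                       df$start[i] + 1L, df$end[i],
                       df$strand[i] %||% "+", at), con)
  }
  invisible(path)
}

#' Write scan outputs
#'
#' Emits `hits.tsv` (BLAST-style 12+2 columns), `orfs.gff3`, `eves.gff3`
#' (type `EVE` with class, gap, spliced-leader offsets, neighbor count
#' and coverage attributes), `eves.tsv`, and `run_manifest.json` (package
#' version, configuration echo, input checksums).
#'
#' @param scan an `eve_scan` from [run_scan()].
#' @param assembly the scanned `DNAStringSet` (for checksums).
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_scan <- function(scan, assembly, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_hits_tsv(scan$filtered, file.path(outdir, "hits.tsv"))
  orfs <- scan$orfs
  if (nrow(orfs)) {
    orfs$strand_out <- orfs$strand
    write_gff3(orfs, file.path(outdir, "orfs.gff3"), "dinoeve", "ORF",
               list(ID = "orf_id", annotation = "ann_subject",
                    gene_class = "ann_class"))
  }
  eves <- scan$eves
  eves$strand <- "+"
  write_gff3(eves, file.path(outdir, "eves.gff3"), "dinoeve", "EVE",
             list(ID = "eve_id", class = "type", gap = "gap",
                  sl_offsets = "sl_offsets", n_neighbors = "n_neighbors",
                  coverage = "coverage", validation = "validation"))
  write_tsv(eves, file.path(outdir, "eves.tsv"))
  manifest <- list(
    package = "dinoeve",
    version = as.character(utils::packageVersion("dinoeve")),
    assembly_id = scan$assembly_id,
    n_scaffolds = length(assembly),
    assembly_md5 = unname(vapply(seq_along(assembly), function(i)
      digest_string(as.character(assembly[[i]])), character(1))),
    config = scan$config[setdiff(names(scan$config),
                                 c("sl", "search"))],
    sl = scan$config$sl,
    search = scan$config$search)
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, na = "null", digits = NA,
                       force = TRUE)
  invisible(outdir)
}

#' @noRd
digest_string <- function(x) {
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

#' Simulate a benchmark (wrapper)
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory for [write_benchmark()].
#' @return the `eve_benchmark`.
#' @export
run_simulate <- function(config = sim_config(), outdir = NULL) {
  bench <- make_benchmark(config)
  if (!is.null(outdir)) write_benchmark(bench, outdir)
  bench
}

#' Evaluate calls against ground truth (wrapper)
#'
#' @param eves [call_eves()] data.frame (or `eves.tsv` path).
#' @param manifest truth data.frame (or `manifest.json` path).
#' @param outdir optional directory for a `benchmark_metrics.tsv`.
#' @return a `benchmark_metrics` object.
#' @export
run_evaluate <- function(eves, manifest, outdir = NULL) {
  if (is.character(eves))
    eves <- utils::read.table(eves, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  m <- benchmark_eval(eves, manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(m$overall, file.path(outdir, "benchmark_metrics.tsv"))
    write_tsv(m$per_bin, file.path(outdir, "benchmark_per_bin.tsv"))
  }
  m
}

#' Scan a simulated benchmark end to end
#'
#' Convenience composition of [make_benchmark()], [run_scan()] (with the
#' benchmark's own panels and depth profile) and [benchmark_eval()].
#'
#' @param config a [sim_config()].
#' @param run_cfg a [run_config()].
#' @return list with `bench`, `scan`, `metrics`.
#' @export
scan_benchmark <- function(config = sim_config(),
                           run_cfg = run_config()) {
  bench <- make_benchmark(config)
  scan <- run_scan(bench$assembly, bench$viral_panel,
                   bench$cellular_panel, depth = bench$depth,
                   config = run_cfg, assembly_id = "benchmark")
  metrics <- benchmark_eval(scan$eves, bench$manifest)
  list(bench = bench, scan = scan, metrics = metrics)
}
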