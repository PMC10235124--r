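# Aggregation and statistics: per-assembly scaffold-count summaries in the
# RdRp-only / MCP-only / both layout, the EVE-count linear model with
# pairwise genus contrasts, and benchmark scoring against ground truth.

#' Construct per-assembly summary rows directly
#'
#' Scaffold counts by category: a scaffold carrying both ORF classes is
#' counted once, under `both` (this resolves the ambiguity of summing
#' per-ORF versus per-scaffold tallies explicitly).
#'
#' @param assembly,genus,family identifiers (vectors recycled to the
#'   longest).
#' @param rdrp_only,mcp_only,both scaffold counts per category.
#' @param total_length,n50,completeness assembly metrics (optional).
#' @return data.frame of class `genome_summary`.
#' @export
genome_summary <- function(assembly, genus, family, rdrp_only, mcp_only,
                           both, total_length = NA_real_, n50 = NA_real_,
                           completeness = NA_real_) {
  out <- data.frame(assembly = assembly, genus = genus, family = family,
                    rdrp_only = as.integer(rdrp_only),
                    mcp_only = as.integer(mcp_only),
                    both = as.integer(both),
                    total_length = total_length, n50 = n50,
                    completeness = completeness,
                    stringsAsFactors = FALSE)
  if (any(out$rdrp_only < 0 | out$mcp_only < 0 | out$both < 0))
    stop("scaffold counts must be non-negative")
  out$total <- out$rdrp_only + out$mcp_only + out$both
  class(out) <- c("genome_summary", "data.frame")
  out
}

#' Summarize EVE calls per assembly
#'
#' Tallies EVE-containing scaffolds per assembly into RdRp-only,
#' MCP-only and both-on-scaffold categories (a scaffold is counted
#' exactly once: under `both` when it carries both ORF classes, whether
#' paired or not).
#'
#' @param eves [call_eves()] data.frame carrying an `assembly` column.
#' @param metadata data.frame with one row per assembly: `assembly`,
#'   `genus`, `family` and optional metrics (`total_length`, `n50`,
#'   `completeness`).  Every `eves$assembly` value must appear here.
#' @return a `genome_summary` data.frame (one row per metadata assembly,
#'   zero counts for assemblies without calls).
#' @export
summarize_eves <- function(eves, metadata) {
  stopifnot(all(c("assembly", "genus", "family") %in% names(metadata)))
  if (nrow(eves) > 0L) {
    unknown <- setdiff(unique(eves$assembly), metadata$assembly)
    if (length(unknown))
      stop("calls reference unknown assembly id(s): ",
           paste(unknown, collapse = ", "))
  }
  counts <- lapply(metadata$assembly, function(a) {
    e <- eves[nrow(eves) > 0 & eves$assembly == a, , drop = FALSE]
    if (nrow(e) == 0L) return(c(rdrp = 0L, mcp = 0L, both = 0L))
    per_scaffold <- vapply(split(e, e$scaffold), function(sc) {
      has_m <- any(sc$type %in% c("single_MCP", "genomic"))
      has_r <- any(sc$type %in% c("single_RdRp", "genomic"))
      if (has_m && has_r) "both" else if (has_m) "mcp" else "rdrp"
    }, character(1))
    c(rdrp = sum(per_scaffold == "rdrp"),
      mcp = sum(per_scaffold == "mcp"),
      both = sum(per_scaffold == "both"))
  })
  counts <- do.call(rbind, counts)
  genome_summary(metadata$assembly, metadata$genus, metadata$family,
                 rdrp_only = counts[, "rdrp"], mcp_only = counts[, "mcp"],
                 both = counts[, "both"],
                 total_length = metadata$total_length %||% NA_real_,
                 n50 = metadata$n50 %||% NA_real_,
                 completeness = metadata$completeness %||% NA_real_)
}

#' Roll summaries up by family (and genus)
#'
#' @param summaries a `genome_summary` data.frame.
#' @param by `"family"` or `"genus"`.
#' @return data.frame of category totals and the total count of
#'   EVE-containing scaffolds per group.
#' @export
rollup_summaries <- function(summaries, by = c("family", "genus")) {
  by <- match.arg(by)
  agg <- lapply(split(summaries, summaries[[by]]), function(s)
    data.frame(group = s[[by]][1L],
               rdrp_only = sum(s$rdrp_only), mcp_only = sum(s$mcp_only),
               both = sum(s$both), total = sum(s$total),
               n_assemblies = nrow(s), stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  names(out)[1L] <- by
  rownames(out) <- NULL
  out
}

#' Linear model for EVE-containing scaffold counts
#'
#' Ordinary least squares of the per-assembly count of EVE-containing
#' scaffolds on host genus and assembly-quality metrics (query length,
#' N50, completeness), with type-II F-tests per term and all pairwise
#' genus contrasts (Tukey adjustment by default, Holm available).
#'
#' @param summaries a `genome_summary` data.frame (metrics columns must
#'   be complete).
#' @param metrics character vector of metric columns to include.
#' @param adjust multiplicity adjustment for the genus contrasts.
#' @return list of class `count_model_fit`: `model` (the `lm`), `anova`
#'   (type-II table), `coefficients`, `contrasts` (estimate, SE, df,
#'   t, adjusted p per genus pair), `genus_F`, `genus_p`.
#' @export
fit_count_model <- function(summaries,
                            metrics = c("total_length", "n50",
                                        "completeness"),
                            adjust = c("tukey", "holm")) {
  adjust <- match.arg(adjust)
  if (length(unique(summaries$genus)) < 2L)
    stop("need at least two genera")
  metrics <- intersect(metrics, names(summaries))
  if (any(!stats::complete.cases(summaries[, c("total", metrics)])))
    stop("metrics must be complete for every assembly")
  dat <- summaries
  dat$genus <- factor(dat$genus)
  fml <- stats::reformulate(c("genus", metrics), response = "total")
  fit <- stats::lm(fml, data = dat)
  if (fit$df.residual <= 0L)
    stop("no residual degrees of freedom")
  ali <- stats::alias(fit)$Complete
  if (!is.null(ali))
    stop("rank-deficient model; collinear terms: ",
         paste(rownames(ali), collapse = ", "))
  resid_var <- sum(stats::residuals(fit)^2)
  if (resid_var < 1e-12) {
    warning("response has zero residual variance; F statistics undefined")
    an <- NULL
  } else {
    an <- car::Anova(fit, type = 2)
  }
  em <- emmeans::emmeans(fit, "genus")
  ct <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = adjust))
  structure(list(model = fit,
                 anova = an,
                 coefficients = stats::coef(fit),
                 contrasts = ct,
                 genus_F = if (!is.null(an)) an["genus", "F value"]
                           else NA_real_,
                 genus_p = if (!is.null(an)) an["genus", "Pr(>F)"]
                           else NA_real_,
                 adjust = adjust),
            class = "count_model_fit")
}

#' @export
print.count_model_fit <- function(x, ...) {
  cat("EVE-count linear model\n")
  print(x$coefficients)
  if (!is.null(x$anova)) {
    cat("\nType-II F tests:\n"); print(x$anova)
  }
  cat("\nPairwise genus contrasts (", x$adjust, "):\n", sep = "")
  print(x$contrasts)
  invisible(x)
}

#' Score EVE calls against a benchmark manifest
#'
#' Sensitivity = recovered planted viral ORFs / planted viral ORFs
#' (a plant is recovered when an EVE member interval of the same gene
#' class overlaps it on its scaffold); precision = call members
#' overlapping a planted viral ORF / all call members; plus F1, per
#' divergence-bin sensitivity, genomic-pair recovery (counted only when
#' both members are correct and the pair was called `genomic`), and
#' false calls on negative (unplanted) scaffolds.
#'
#' @param eves [call_eves()] data.frame.
#' @param manifest truth data.frame from [make_benchmark()].
#' @param bins divergence bin edges (default 0, 0.1, ..., 0.5 plus 1).
#' @return list of class `benchmark_metrics`: `overall` (sensitivity,
#'   precision, f1, counts), `per_bin`, `pairs` (per planted pair),
#'   `negatives` (false member calls on scaffolds without plants).
#' @export
benchmark_eval <- function(eves, manifest,
                           bins = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 1)) {
  truth <- manifest[manifest$feature %in% c("MCP", "RdRp"), , drop = FALSE]
  if (nrow(eves) > 0L && nrow(truth) > 0L &&
      !any(eves$scaffold %in% manifest$scaffold))
    stop("mismatched benchmark: no call scaffold id appears in the ",
         "manifest")
  # flatten calls into members (one row per MCP/RdRp interval)
  members <- list()
  for (i in seq_len(nrow(eves))) {
    e <- eves[i, ]
    if (!is.na(e$mcp_start)) members[[length(members) + 1L]] <-
        data.frame(scaffold = e$scaffold, gene_class = "MCP",
                   start = e$mcp_start, end = e$mcp_end,
                   eve_id = e$eve_id, type = e$type,
                   stringsAsFactors = FALSE)
    if (!is.na(e$rdrp_start)) members[[length(members) + 1L]] <-
        data.frame(scaffold = e$scaffold, gene_class = "RdRp",
                   start = e$rdrp_start, end = e$rdrp_end,
                   eve_id = e$eve_id, type = e$type,
                   stringsAsFactors = FALSE)
  }
  members <- if (length(members)) do.call(rbind, members) else
    data.frame(scaffold = character(), gene_class = character(),
               start = integer(), end = integer(), eve_id = character(),
               type = character(), stringsAsFactors = FALSE)
  overlaps_truth <- function(m) {
    any(truth$scaffold == m$scaffold & truth$feature == m$gene_class &
          truth$start < m$end & m$start < truth$end)
  }
  recovered <- vapply(seq_len(nrow(truth)), function(k) {
    t <- truth[k, ]
    any(members$scaffold == t$scaffold &
          members$gene_class == t$feature &
          members$start < t$end & t$start < members$end)
  }, logical(1))
  member_true <- vapply(seq_len(nrow(members)), function(k)
    overlaps_truth(members[k, ]), logical(1))
  sens <- if (nrow(truth)) mean(recovered) else NA_real_
  prec <- if (nrow(members)) mean(member_true) else NA_real_
  f1 <- if (!is.na(sens) && !is.na(prec) && sens + prec > 0)
    2 * sens * prec / (sens + prec) else NA_real_
  # per divergence bin
  bin_of <- cut(truth$divergence, breaks = bins, include.lowest = TRUE,
                right = TRUE)
  per_bin <- do.call(rbind, lapply(levels(bin_of), function(b) {
    idx <- which(bin_of == b)
    data.frame(bin = b, n = length(idx),
               sensitivity = if (length(idx)) mean(recovered[idx])
                             else NA_real_,
               stringsAsFactors = FALSE)
  }))
  # genomic pairs
  pt <- manifest[manifest$feature == "genomic_pair", , drop = FALSE]
  pairs <- do.call(rbind, lapply(seq_len(nrow(pt)), function(k) {
    p <- pt[k, ]
    mem <- truth[!is.na(truth$pair_id) & truth$pair_id == p$pair_id, ,
                 drop = FALSE]
    g <- eves[eves$scaffold == p$scaffold & eves$type == "genomic", ,
              drop = FALSE]
    ok <- FALSE
    for (j in seq_len(nrow(g))) {
      mt <- mem[mem$feature == "MCP", ]; rt <- mem[mem$feature == "RdRp", ]
      if (nrow(mt) && nrow(rt) &&
          intervals_overlap(g$mcp_start[j], g$mcp_end[j],
                            mt$start, mt$end) &&
          intervals_overlap(g$rdrp_start[j], g$rdrp_end[j],
                            rt$start, rt$end)) ok <- TRUE
    }
    data.frame(pair_id = p$pair_id, scaffold = p$scaffold, gap = p$gap,
               recovered_genomic = ok, stringsAsFactors = FALSE)
  }))
  planted_scaffolds <- unique(manifest$scaffold)
  neg_calls <- members[!(members$scaffold %in% planted_scaffolds), ,
                       drop = FALSE]
  structure(list(
    overall = data.frame(sensitivity = sens, precision = prec, f1 = f1,
                         n_truth = nrow(truth), n_called = nrow(members),
                         false_on_negatives = nrow(neg_calls)),
    per_bin = per_bin, pairs = pairs, negatives = neg_calls,
    members = cbind(members,
                    true_positive = if (nrow(members)) member_true
                                    else logical(0))),
    class = "benchmark_metrics")
}

#' @export
print.benchmark_metrics <- function(x, ...) {
  cat("Benchmark recovery\n"); print(x$overall)
  cat("\nPer divergence bin:\n"); print(x$per_bin)
  if (!is.null(x$pairs) && nrow(x$pairs)) {
    cat("\nGenomic pairs:\n"); print(x$pairs)
  }
  invisible(x)
}
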