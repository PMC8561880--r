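#' Pipeline configuration
#'
#' Bundles every numeric threshold of the scan in one place. Defaults are
#' the field-standard values for a small-cohort resequencing scan: 1 kb
#' depth bins, retention of windows with -log10(P) > 2, 5 kb variant
#' density tiles requiring more than 10 fully sex-associated variants,
#' exclusion of contigs shorter than 3 kb.
#'
#' @param bin_width Depth bin width, bp.
#' @param density_window Variant density tile width, bp.
#' @param density_min_count Density tiles with count strictly greater than
#'   this are significant.
#' @param neglogp_threshold Retention threshold on -log10(P) for depth
#'   windows.
#' @param min_contig_len Contigs strictly shorter than this are excluded, bp.
#' @param neglogp_cap Cap on reported -log10(P).
#' @param merge_gap Candidate intervals closer than this merge, bp.
#' @param zero_depth_max Maximum per-base depth still counted as "absent"
#'   in zero-depth tracts.
#' @param min_tract_len Minimum zero-depth tract length, bp.
#' @param colocalization_slop Overlap slop used to judge co-location of
#'   depth and genotype evidence, bp.
#' @param depth_deficit_ratio Fold-change qualification for depth-deficit
#'   support in region classification (see [classify_region()]).
#' @param seed Integer seed echoed into run logs (randomness only enters
#'   via the simulator).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(bin_width = 1000,
                            density_window = 5000,
                            density_min_count = 10,
                            neglogp_threshold = 2,
                            min_contig_len = 3000,
                            neglogp_cap = 300,
                            merge_gap = 1000,
                            zero_depth_max = 0,
                            min_tract_len = 1000,
                            colocalization_slop = 5000,
                            depth_deficit_ratio = 0.5,
                            seed = 1L) {
  cfg <- list(bin_width = bin_width, density_window = density_window,
              density_min_count = density_min_count,
              neglogp_threshold = neglogp_threshold,
              min_contig_len = min_contig_len, neglogp_cap = neglogp_cap,
              merge_gap = merge_gap, zero_depth_max = zero_depth_max,
              min_tract_len = min_tract_len,
              colocalization_slop = colocalization_slop,
              depth_deficit_ratio = depth_deficit_ratio,
              seed = as.integer(seed))
  sizes <- c("bin_width", "density_window", "min_contig_len", "min_tract_len")
  if (any(unlist(cfg[sizes]) <= 0)) stop("window/length sizes must be positive")
  thr <- c("density_min_count", "neglogp_threshold", "neglogp_cap",
           "merge_gap", "zero_depth_max", "colocalization_slop")
  if (any(unlist(cfg[thr]) < 0)) stop("thresholds must be non-negative")
  if (depth_deficit_ratio < 0 || depth_deficit_ratio >= 1) {
    stop("depth_deficit_ratio must be in [0, 1)")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a flat key=value config file into a pipeline configuration
#'
#' Unknown keys are an error; missing keys take their defaults.
#'
#' @param path Path to a text file with one `key = value` pair per line;
#'   `#` comments and blank lines are ignored.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, "", 2L)))
  known <- names(formals(pipeline_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, as.list(stats::setNames(vals, keys)))
}

#' Scan a sexed cohort for sex-determining regions
#'
#' The central fit of the package. Runs, in order: exclusion of short
#' contigs; the windowed read-depth contrast (1 kb bin means, Welch
#' two-sample t-tests male vs female, -log10(P) retention); zero-depth
#' tract detection in each sex; the per-variant Fisher exact genotype-sex
#' association with retention of fully sex-associated variants and their
#' 5 kb density windows; candidate-region merging, per-region
#' classification (XY-linked / ZW-linked / spurious / ambiguous) and the
#' cohort-level heterogamety verdict.
#'
#' @param cohort Sample sheet as from [read_sample_sheet()].
#' @param depth Depth set as from [read_depth_dir()].
#' @param genotypes Genotype table as from [read_genotypes()].
#' @param contigs Contig table as from [read_contig_table()].
#' @param config A [pipeline_config()].
#' @return Object of class `sex_scan`: list with elements `verdict`
#'   (a `sex_system_verdict`), `region_calls`, `window_stats`,
#'   `retained_windows`, `tracts`, `associations`, `flagged`,
#'   `density`, `contigs`, `cohort` and `config`.
#' @seealso [run_pipeline()] for the file-based front end.
#' @export
sex_scan <- function(cohort, depth, genotypes, contigs,
                     config = pipeline_config()) {
  validate_cohort(cohort)
  filt <- exclude_short_contigs(contigs, depth = depth, genotypes = genotypes,
                                min_len = config$min_contig_len)

  binned <- bin_depths(filt$depth, cohort, bin_width = config$bin_width)
  window_stats <- welch_window_tests(binned, cohort,
                                     neglogp_cap = config$neglogp_cap)
  retained <- filter_depth_windows(window_stats,
                                   threshold = config$neglogp_threshold)
  tracts <- rbind(
    zero_depth_tracts(filt$depth, cohort, "FEMALE",
                      max_allowed_depth = config$zero_depth_max,
                      min_tract_len = config$min_tract_len),
    zero_depth_tracts(filt$depth, cohort, "MALE",
                      max_allowed_depth = config$zero_depth_max,
                      min_tract_len = config$min_tract_len))

  associations <- variant_associations(filt$genotypes, cohort)
  flagged <- flag_fully_associated(associations)
  density <- density_windows(flagged, filt$contigs,
                             window = config$density_window,
                             min_count = config$density_min_count)

  regions <- merge_candidate_regions(density, retained,
                                     merge_gap = config$merge_gap)
  calls <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    classify_region(regions[i, , drop = FALSE], tracts, associations,
                    retained,
                    colocalization_slop = config$colocalization_slop,
                    depth_deficit_ratio = config$depth_deficit_ratio)
  }))
  if (is.null(calls)) {
    calls <- data.frame(contig = character(), start = numeric(),
                        end = numeric(), variant_direction = character(),
                        has_density_signal = logical(),
                        female_zero_tract_overlap = logical(),
                        male_zero_tract_overlap = logical(),
                        depth_window_overlap = logical(),
                        max_neg_log10_p = numeric(),
                        classification = character(), stringsAsFactors = FALSE)
  }
  verdict <- infer_sex_system(calls)

  structure(list(verdict = verdict, region_calls = calls,
                 window_stats = window_stats, retained_windows = retained,
                 tracts = tracts, associations = associations,
                 flagged = flagged, density = density,
                 contigs = filt$contigs, cohort = cohort, config = config),
            class = "sex_scan")
}

#' Run the full pipeline from files on disk
#'
#' Reads the sample sheet, per-sample depth tables, VCF and contig table,
#' runs [sex_scan()], and (optionally) writes all tabular and BED outputs
#' plus a run log to `out_dir`. Partial outputs are removed on failure.
#'
#' @param sample_sheet Path to the two-column sample sheet.
#' @param depth_dir Directory with `<sample_id>.depth.tsv[.gz]` files.
#' @param vcf Path to the multi-sample VCF.
#' @param contig_table Path to the .fai-style contig table.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @return The `sex_scan` object, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(sample_sheet, depth_dir, vcf, contig_table,
                         config = pipeline_config(), out_dir = NULL) {
  cohort <- read_sample_sheet(sample_sheet)
  contigs <- read_contig_table(contig_table)
  depth <- read_depth_dir(depth_dir, cohort, contigs)
  genotypes <- read_genotypes(vcf, cohort)
  fit <- sex_scan(cohort, depth, genotypes, contigs, config)
  if (!is.null(out_dir)) {
    ok <- FALSE
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    on.exit(if (!ok) unlink(file.path(out_dir, scan_output_files()),
                            force = TRUE))
    write_scan_outputs(fit, out_dir)
    ok <- TRUE
    return(invisible(fit))
  }
  fit
}

scan_output_files <- function() {
  c("window_stats.tsv", "retained_windows.bed", "zero_depth_tracts.bed",
    "variant_associations.tsv", "density_windows.bed", "region_calls.bed",
    "region_calls.tsv", "verdict.txt", "run_log.txt")
}

# BED6 writer; score capped at 1000 per the BED convention
write_bed6 <- function(df, path, name, score) {
  bed <- data.frame(df$contig, format_num(df$start), format_num(df$end),
                    name, format_num(pmin(score, 1000)), ".")
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
}

format_num <- function(x) {
  ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
         format(round(x, 6), scientific = FALSE, trim = TRUE))
}

write_scan_outputs <- function(fit, out_dir) {
  tsv <- function(df, f) data.table::fwrite(df, file.path(out_dir, f),
                                            sep = "\t", quote = FALSE)
  tsv(fit$window_stats, "window_stats.tsv")
  tsv(fit$associations, "variant_associations.tsv")
  tsv(fit$region_calls, "region_calls.tsv")
  write_bed6(fit$retained_windows, file.path(out_dir, "retained_windows.bed"),
             name = "depth_window", score = fit$retained_windows$neg_log10_p)
  write_bed6(fit$tracts, file.path(out_dir, "zero_depth_tracts.bed"),
             name = paste0("zero_depth_", fit$tracts$sex),
             score = rep(0, nrow(fit$tracts)))
  write_bed6(fit$density, file.path(out_dir, "density_windows.bed"),
             name = paste0("density_", fit$density$direction),
             score = fit$density$count)
  write_bed6(fit$region_calls, file.path(out_dir, "region_calls.bed"),
             name = fit$region_calls$classification,
             score = fit$region_calls$max_neg_log10_p)
  writeLines(c(paste("system:", fit$verdict$system),
               paste("rationale:", fit$verdict$rationale)),
             file.path(out_dir, "verdict.txt"))
  cfg <- fit$config
  writeLines(c("sdscan run log",
               paste0(names(cfg), " = ", unlist(cfg)),
               paste("n_samples =", nrow(fit$cohort)),
               paste("n_contigs =", nrow(fit$contigs)),
               paste("verdict =", fit$verdict$system)),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.sex_scan <- function(x, ...) {
  cat("Sex-determining region scan\n")
  cat(sprintf("  cohort: %d males, %d females\n",
              sum(x$cohort$sex == "MALE"), sum(x$cohort$sex == "FEMALE")))
  cat(sprintf("  contigs analysed: %d (%.1f Mb)\n", nrow(x$contigs),
              sum(x$contigs$length) / 1e6))
  cat(sprintf("  retained depth windows (-log10P > %g): %d\n",
              x$config$neglogp_threshold, nrow(x$retained_windows)))
  cat(sprintf("  fully sex-associated variants: %d of %d\n",
              nrow(x$flagged), nrow(x$associations)))
  cat(sprintf("  candidate regions: %d\n", nrow(x$region_calls)))
  print(x$verdict)
  invisible(x)
}

#' @export
summary.sex_scan <- function(object, ...) {
  cls <- table(factor(object$region_calls$classification,
                      levels = c("XY_LINKED", "ZW_LINKED", "SPURIOUS",
                                 "AMBIGUOUS")))
  out <- list(
    system = object$verdict$system,
    rationale = object$verdict$rationale,
    n_regions = nrow(object$region_calls),
    classifications = cls,
    n_fully_associated = nrow(object$flagged),
    n_variants = nrow(object$associations),
    n_retained_windows = nrow(object$retained_windows),
    n_windows = nrow(object$window_stats),
    tracts = object$tracts,
    region_calls = object$region_calls)
  class(out) <- "summary.sex_scan"
  out
}

#' @export
print.summary.sex_scan <- function(x, ...) {
  cat("Sex-determination scan summary\n")
  cat(sprintf("  verdict: %s\n", x$system))
  cat(sprintf("  %s\n", x$rationale))
  cat(sprintf("  depth windows: %d tested, %d retained\n",
              x$n_windows, x$n_retained_windows))
  cat(sprintf("  variants: %d tested, %d fully sex-associated\n",
              x$n_variants, x$n_fully_associated))
  cat("  region classifications:\n")
  for (nm in names(x$classifications)) {
    cat(sprintf("    %-10s %d\n", nm, x$classifications[[nm]]))
  }
  if (nrow(x$region_calls)) {
    cat("  regions:\n")
    print(x$region_calls[, c("contig", "start", "end", "variant_direction",
                             "classification", "max_neg_log10_p")])
  }
  invisible(x)
}

#' Plot a sex-determination scan
#'
#' Per-contig scatter of window -log10(P) from the depth contrast, with
#' fully sex-associated variant positions marked as a rug and candidate
#' regions shaded.
#'
#' @param x A `sex_scan` object.
#' @param contig Contig to plot; defaults to the contig with the strongest
#'   signal.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.sex_scan <- function(x, contig = NULL, ...) {
  if (is.null(contig)) {
    contig <- if (nrow(x$region_calls)) {
      x$region_calls$contig[which.max(x$region_calls$max_neg_log10_p)]
    } else {
      x$window_stats$contig[which.max(x$window_stats$neg_log10_p)]
    }
  }
  ws <- x$window_stats[x$window_stats$contig == contig, , drop = FALSE]
  if (nrow(ws) == 0L) stop("no windows on contig '", contig, "'")
  mid <- (ws$start + ws$end) / 2
  plot(mid, ws$neg_log10_p, pch = 16, cex = 0.5,
       xlab = paste0("position on ", contig, " (bp)"),
       ylab = expression(-log[10] * italic(P)),
       main = paste("Depth contrast:", contig), ...)
  abline(h = x$config$neglogp_threshold, lty = 2, col = "grey40")
  rc <- x$region_calls[x$region_calls$contig == contig, , drop = FALSE]
  if (nrow(rc)) {
    usr <- par("usr")
    rect(rc$start, usr[3], rc$end, usr[4],
         col = grDevices::adjustcolor("red", 0.15), border = NA)
  }
  fl <- x$flagged[x$flagged$contig == contig, , drop = FALSE]
  if (nrow(fl)) rug(fl$pos, col = "blue")
  invisible(x)
}
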