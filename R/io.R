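#' Read a sample sheet of sexed individuals
#'
#' Parses a two-column delimited text file mapping sample identifiers to sex
#' labels. Sex tokens `M`, `MALE`, `F`, `FEMALE` are accepted
#' case-insensitively.
#'
#' @param path Path to a two-column (sample_id, sex) whitespace- or
#'   tab-delimited file. Lines starting with `#` are ignored.
#' @return A `data.frame` with columns `sample_id` (character) and `sex`
#'   (character, `"MALE"` or `"FEMALE"`).
#' @examples
#' sheet <- tempfile()
#' writeLines(c("m1\tM", "m2\tM", "f1\tF", "f2\tF"), sheet)
#' read_sample_sheet(sheet)
#' @export
read_sample_sheet <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("no samples in sample sheet '", path, "'")
  parts <- strsplit(trimws(lines), "[\t ]+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) stop("malformed sample sheet line ", bad[1L], ": ", lines[bad[1L]])
  ids <- vapply(parts, `[[`, "", 1L)
  tok <- toupper(vapply(parts, `[[`, "", 2L))
  sex <- c(M = "MALE", MALE = "MALE", F = "FEMALE", FEMALE = "FEMALE")[tok]
  if (anyNA(sex)) {
    i <- which(is.na(sex))[1L]
    stop("unknown sex token '", tok[i], "' on sample sheet line ", i)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s) in sample sheet: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cohort <- data.frame(sample_id = ids, sex = unname(sex),
                       stringsAsFactors = FALSE)
  validate_cohort(cohort)
  cohort
}

validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort), all(c("sample_id", "sex") %in% names(cohort)))
  if (anyDuplicated(cohort$sample_id)) stop("duplicate sample ids in cohort")
  if (!all(cohort$sex %in% c("MALE", "FEMALE"))) stop("sex must be MALE or FEMALE")
  n <- table(factor(cohort$sex, levels = c("MALE", "FEMALE")))
  if (any(n < 2L)) {
    stop("cohort needs at least 2 samples of each sex (got ",
         n[["MALE"]], " MALE, ", n[["FEMALE"]], " FEMALE)")
  }
  invisible(cohort)
}

#' Read a contig-length table
#'
#' Reads a FASTA-index style (.fai) table; only the first two columns
#' (contig name, length) are used, further columns are ignored.
#'
#' @param path Path to the tab-delimited table.
#' @return A `data.frame` with columns `contig` (character) and
#'   `length` (integer-valued numeric, bp).
#' @export
read_contig_table <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          select = 1:2, col.names = c("contig", "length"))
  contigs <- data.frame(contig = as.character(dt$contig),
                        length = as.numeric(dt$length),
                        stringsAsFactors = FALSE)
  if (nrow(contigs) == 0L) stop("empty contig table '", path, "'")
  if (anyDuplicated(contigs$contig)) stop("duplicate contig names in '", path, "'")
  if (any(!is.finite(contigs$length) | contigs$length <= 0 |
          contigs$length != round(contigs$length))) {
    stop("contig lengths must be positive integers")
  }
  contigs
}

#' Read a per-base depth table for one sample
#'
#' Reads a samtools-depth style three-column TSV (contig, 1-based position,
#' depth) and densifies it against a contig table: positions absent from the
#' file become explicit zeros, so every contig yields a full-length track.
#' Zero-depth tracts are the signal of interest downstream, which is why the
#' reader is insensitive to whether the producing tool emitted zero rows.
#'
#' @param path Path to the TSV (optionally gzip-compressed).
#' @param contigs Contig table as from [read_contig_table()].
#' @return A named list (one element per contig, in `contigs` order) of
#'   integer vectors of per-base depths, each of the full contig length.
#' @export
read_depth_table <- function(path, contigs) {
  if (file.size(path) == 0) {
    dt <- data.frame(contig = character(), pos = integer(), depth = integer())
  } else {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            col.names = c("contig", "pos", "depth"),
                            colClasses = list(character = 1, integer = 2:3))
  }
  if (nrow(dt) > 0L) {
    unknown <- setdiff(unique(dt$contig), contigs$contig)
    if (length(unknown)) {
      stop("depth table '", path, "' references unknown contig(s): ",
           paste(unknown, collapse = ", "))
    }
    if (any(dt$depth < 0L)) stop("negative depth in '", path, "'")
    if (any(dt$pos < 1L)) stop("non-positive position in '", path, "'")
  }
  tracks <- vector("list", nrow(contigs))
  names(tracks) <- contigs$contig
  for (i in seq_len(nrow(contigs))) {
    ctg <- contigs$contig[i]
    len <- contigs$length[i]
    v <- integer(len)
    rows <- dt[dt$contig == ctg, ]
    if (nrow(rows) > 0L) {
      if (max(rows$pos) > len) {
        stop("position ", max(rows$pos), " exceeds length of contig '",
             ctg, "' (", len, ") in '", path, "'")
      }
      v[rows$pos] <- rows$depth
    }
    tracks[[i]] <- v
  }
  tracks
}

#' Read per-base depth tables for a whole cohort
#'
#' Looks for one depth TSV per sample in `dir`, named
#' `<sample_id>.depth.tsv` (optionally `.gz`), and assembles per-contig
#' depth matrices.
#'
#' @param dir Directory containing one depth file per cohort sample.
#' @param cohort Sample sheet as from [read_sample_sheet()].
#' @param contigs Contig table as from [read_contig_table()].
#' @return A named list (per contig) of integer matrices, rows = bases
#'   (0-based offset + 1), columns = samples (named by `sample_id`).
#' @export
read_depth_dir <- function(dir, cohort, contigs) {
  paths <- file.path(dir, paste0(cohort$sample_id, ".depth.tsv"))
  gz <- paste0(paths, ".gz")
  paths[!file.exists(paths) & file.exists(gz)] <- gz[!file.exists(paths) & file.exists(gz)]
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing depth file(s) for sample(s): ",
         paste(cohort$sample_id[missing], collapse = ", "))
  }
  per_sample <- lapply(paths, read_depth_table, contigs = contigs)
  depth <- lapply(seq_len(nrow(contigs)), function(i) {
    m <- vapply(per_sample, `[[`, integer(contigs$length[i]), i)
    colnames(m) <- cohort$sample_id
    m
  })
  names(depth) <- contigs$contig
  depth
}

#' Read genotype states from a multi-sample VCF
#'
#' Maps diploid GT fields to three states: both alleles equal -> `HOM`,
#' alleles differ (including multi-allelic heterozygotes such as `1/2`) ->
#' `HET`, any missing allele (`./.`, `./1`) -> `MISSING`. Phased separators
#' (`|`) are treated as unphased.
#'
#' @param path Path to a VCF (v4.x) file with GT in FORMAT.
#' @param cohort Sample sheet; every VCF sample must appear in it.
#' @return A list with `variants` (`data.frame`: contig, pos (1-based), ref,
#'   alt) and `states` (character matrix, variants x samples, values
#'   `"HOM"`, `"HET"`, `"MISSING"`).
#' @export
read_genotypes <- function(path, cohort) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  extra <- setdiff(colnames(gt), cohort$sample_id)
  if (length(extra)) {
    stop("VCF sample(s) absent from sample sheet: ", paste(extra, collapse = ", "))
  }
  absent <- setdiff(cohort$sample_id, colnames(gt))
  if (length(absent)) {
    stop("cohort sample(s) absent from VCF: ", paste(absent, collapse = ", "))
  }
  gt <- gt[, cohort$sample_id, drop = FALSE]
  states <- gt_to_state(gt)
  variants <- data.frame(contig = as.character(fix[, "CHROM"]),
                         pos = as.integer(fix[, "POS"]),
                         ref = as.character(fix[, "REF"]),
                         alt = as.character(fix[, "ALT"]),
                         stringsAsFactors = FALSE)
  list(variants = variants, states = states)
}

# GT string matrix -> HOM/HET/MISSING state matrix; errors on non-diploid GT.
gt_to_state <- function(gt) {
  u <- unique(as.vector(gt))
  u[is.na(u)] <- "./."
  norm <- gsub("|", "/", u, fixed = TRUE)
  alleles <- strsplit(norm, "/", fixed = TRUE)
  bad <- vapply(alleles, length, 1L) != 2L
  if (any(bad)) stop("non-diploid GT encountered: ", paste(u[bad], collapse = ", "))
  state_of <- vapply(alleles, function(a) {
    if (any(a == "." | a == "")) "MISSING"
    else if (a[1] == a[2]) "HOM"
    else "HET"
  }, "")
  names(state_of) <- u
  g <- as.vector(gt)
  g[is.na(g)] <- "./."
  matrix(state_of[g], nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Drop short contigs from a dataset
#'
#' Removes all records on contigs strictly shorter than `min_len` (contigs of
#' exactly `min_len` bp are retained) from a contig table and, optionally,
#' from an accompanying depth set and/or genotype table.
#'
#' @param contigs Contig table.
#' @param depth Optional depth set as from [read_depth_dir()].
#' @param genotypes Optional genotype table as from [read_genotypes()].
#' @param min_len Minimum contig length to keep, bp (default 3000).
#' @return A list with the filtered `contigs`, `depth` and `genotypes`
#'   (the latter two `NULL` if not supplied).
#' @export
exclude_short_contigs <- function(contigs, depth = NULL, genotypes = NULL,
                                  min_len = 3000) {
  stopifnot(min_len >= 1)
  keep <- contigs$length >= min_len
  if (!any(keep)) warning("all contigs shorter than ", min_len, " bp; empty result")
  kept <- contigs[keep, , drop = FALSE]
  rownames(kept) <- NULL
  out <- list(contigs = kept, depth = NULL, genotypes = NULL)
  if (!is.null(depth)) out$depth <- depth[kept$contig]
  if (!is.null(genotypes)) {
    sel <- genotypes$variants$contig %in% kept$contig
    out$genotypes <- list(
      variants = genotypes$variants[sel, , drop = FALSE],
      states = genotypes$states[sel, , drop = FALSE])
    rownames(out$genotypes$variants) <- NULL
  }
  out
}

#' Assembly span arithmetic
#'
#' Sums anchored contig lengths and adds the unanchored remainder, as
#' reported for chromosome-scale assemblies.
#'
#' @param contigs Contig table of anchored scaffolds.
#' @param extra_unanchored Total length (bp) of unanchored scaffolds.
#' @return Named numeric vector `c(anchored_total=, grand_total=)` in bp.
#' @export
assembly_span <- function(contigs, extra_unanchored = 0) {
  stopifnot(nrow(contigs) > 0, extra_unanchored >= 0)
  anchored <- sum(as.numeric(contigs$length))
  c(anchored_total = anchored, grand_total = anchored + extra_unanchored)
}

#' Sequencing coverage arithmetic
#'
#' Computes pre-assembly fold coverage of input data over the estimated
#' genome size, and the rounded mean per-sample read depth over the
#' assembly.
#'
#' @param total_input_bases Total sequenced bases (bp).
#' @param genome_size Estimated genome size (bp).
#' @param mean_read_count Mean number of aligned reads per sample.
#' @param read_length Read length (bp).
#' @param assembly_length Assembly length (bp).
#' @return Named numeric vector `c(fold_coverage=, mean_depth_rounded=)`;
#'   `fold_coverage` is rounded to one decimal place.
#' @export
coverage_stats <- function(total_input_bases, genome_size, mean_read_count,
                           read_length, assembly_length) {
  if (genome_size <= 0 || assembly_length <= 0) {
    stop("genome_size and assembly_length must be positive")
  }
  stopifnot(total_input_bases > 0, mean_read_count > 0, read_length > 0)
  c(fold_coverage = round(total_input_bases / genome_size, 1),
    mean_depth_rounded = round(mean_read_count * read_length / assembly_length))
}
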