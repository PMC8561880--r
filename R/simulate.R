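#' Describe a planted sex-determination feature
#'
#' A feature is an interval of a simulated contig with kind-specific depth
#' and genotype behaviour:
#' \describe{
#'   \item{`XY_SDR`}{male-specific sequence: males carry heterozygous
#'     variants and drop to `het_depth_factor` (hemizygous, default 0.5x)
#'     mean depth; females drop to `hom_depth_factor` (default 0x).}
#'   \item{`ZW_SDR`}{the mirror image (female-heterozygous, male depth
#'     absent).}
#'   \item{`SPURIOUS_HET`}{a heterozygosity-state bias (all samples of
#'     `het_sex` heterozygous, the others homozygous) with normal depth in
#'     both sexes — the signature of a false-discovery region.}
#'   \item{`REPEAT_CONFOUND`}{a repeat-like short-scaffold confounder:
#'     male-heterozygous variants, zero female depth, and a random subset
#'     of males (probability `confound_prob` each) also at zero depth while
#'     the rest pile up reads at `confound_factor` times the mean.}
#' }
#'
#' @param kind One of `"XY_SDR"`, `"ZW_SDR"`, `"SPURIOUS_HET"`,
#'   `"REPEAT_CONFOUND"`.
#' @param contig,start,end Interval (0-based half-open, bp).
#' @param variant_density Sex-linked variants per kb inside the feature
#'   (default 4, the density seen in a ~6 kb region carrying ~25 fully
#'   sex-associated variants).
#' @param het_depth_factor Depth multiplier for the heterogametic sex
#'   (default 0.5).
#' @param hom_depth_factor Depth multiplier for the homogametic sex
#'   (default 0).
#' @param het_sex For `SPURIOUS_HET`: which sex is heterozygous
#'   (default `"FEMALE"`).
#' @param confound_prob,confound_factor `REPEAT_CONFOUND` parameters.
#' @return A list of class `planted_feature`.
#' @export
planted_feature <- function(kind, contig, start, end,
                            variant_density = 4,
                            het_depth_factor = 0.5,
                            hom_depth_factor = 0,
                            het_sex = "FEMALE",
                            confound_prob = 0.5,
                            confound_factor = 2) {
  kind <- match.arg(kind, c("XY_SDR", "ZW_SDR", "SPURIOUS_HET",
                            "REPEAT_CONFOUND"))
  het_sex <- match.arg(het_sex, c("FEMALE", "MALE"))
  stopifnot(start >= 0, end > start, variant_density >= 0,
            het_depth_factor >= 0, hom_depth_factor >= 0,
            confound_prob >= 0, confound_prob <= 1)
  structure(list(kind = kind, contig = contig, start = start, end = end,
                 variant_density = variant_density,
                 het_depth_factor = het_depth_factor,
                 hom_depth_factor = hom_depth_factor,
                 het_sex = het_sex, confound_prob = confound_prob,
                 confound_factor = confound_factor),
            class = "planted_feature")
}

#' Configure a synthetic sexed cohort
#'
#' Defaults emulate the study conditions of a small-cohort sexing scan:
#' 7 males + 6 females at ~13x mean per-base depth, Poisson-sampled depth,
#' background variants at Hardy-Weinberg equilibrium, a small genotype
#' state-flip error and missing-genotype rate.
#'
#' @param contigs Contig table (`data.frame`: contig, length).
#' @param n_males,n_females Cohort composition (defaults 7 and 6).
#' @param mean_depth Expected per-base depth outside planted features
#'   (default 13).
#' @param depth_model `"POISSON"` or `"NEGBIN"`.
#' @param overdispersion For `NEGBIN`: variance = mu + overdispersion *
#'   mu^2 (ignored for `POISSON`).
#' @param background_rate Sex-independent variants per kb (default 5; a
#'   desk-scale density, far below genome-wide resequencing reality but
#'   enough to exercise every filter).
#' @param features List of [planted_feature()] objects (must not overlap).
#' @param genotype_error Probability of a symmetric HET<->HOM state flip
#'   applied after truth assignment (default 0.005).
#' @param missing_rate Probability a genotype call is missing
#'   (default 0.01).
#' @param seed Integer RNG seed; identical configs give byte-identical
#'   output files.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(contigs,
                              n_males = 7, n_females = 6,
                              mean_depth = 13,
                              depth_model = c("POISSON", "NEGBIN"),
                              overdispersion = 0.1,
                              background_rate = 5,
                              features = list(),
                              genotype_error = 0.005,
                              missing_rate = 0.01,
                              seed = 1L) {
  depth_model <- match.arg(depth_model)
  stopifnot(n_males >= 2, n_females >= 2, mean_depth > 0,
            background_rate >= 0, genotype_error >= 0, genotype_error <= 1,
            missing_rate >= 0, missing_rate <= 1, overdispersion >= 0)
  for (f in features) {
    stopifnot(inherits(f, "planted_feature"))
    if (!f$contig %in% contigs$contig) {
      stop("feature contig '", f$contig, "' not in contig table")
    }
    if (f$end > contigs$length[contigs$contig == f$contig]) {
      stop("feature on '", f$contig, "' exceeds contig length")
    }
  }
  # overlapping planted features are a configuration error
  if (length(features) > 1L) {
    fdf <- data.frame(contig = vapply(features, `[[`, "", "contig"),
                      start = vapply(features, `[[`, 0, "start"),
                      end = vapply(features, `[[`, 0, "end"))
    for (ctg in unique(fdf$contig)) {
      iv <- fdf[fdf$contig == ctg, , drop = FALSE]
      iv <- iv[order(iv$start), , drop = FALSE]
      if (nrow(iv) > 1L && any(iv$start[-1] < iv$end[-nrow(iv)])) {
        stop("overlapping planted features on contig '", ctg, "'")
      }
    }
  }
  structure(list(contigs = contigs, n_males = n_males, n_females = n_females,
                 mean_depth = mean_depth, depth_model = depth_model,
                 overdispersion = overdispersion,
                 background_rate = background_rate, features = features,
                 genotype_error = genotype_error, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

rdepth <- function(n, mu, config) {
  out <- integer(n)
  pos <- mu > 0
  if (config$depth_model == "POISSON" || config$overdispersion == 0) {
    out[pos] <- stats::rpois(sum(pos), mu[pos])
  } else {
    out[pos] <- stats::rnbinom(sum(pos), mu = mu[pos],
                               size = 1 / config$overdispersion)
  }
  out
}

heterogametic_sex <- function(kind, het_sex) {
  switch(kind,
         XY_SDR = "MALE", ZW_SDR = "FEMALE",
         REPEAT_CONFOUND = "MALE", SPURIOUS_HET = het_sex)
}

#' Generate a synthetic sexed cohort
#'
#' Draws per-base depths i.i.d. from the configured depth model (with
#' per-feature scaled means), genotypes from Hardy-Weinberg equilibrium at
#' background sites and from the kind-specific rules at planted sites, then
#' perturbs genotypes by the state-flip error and missingness. When
#' `out_dir` is given, writes the exact dialects the readers consume:
#' `sample_sheet.tsv`, `contigs.fai`, `depth/<sample>.depth.tsv`
#' (zero-depth positions omitted, as depth tools do by default),
#' `variants.vcf` (v4.2, GT-only FORMAT) and `truth.bed` recording every
#' planted interval and kind.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory, or `NULL` for in-memory results only.
#' @return A list with `cohort`, `contigs`, `depth` (per-contig
#'   bases x samples integer matrices), `genotypes` (as from
#'   [read_genotypes()]), `truth` (`data.frame`: contig, start, end, kind)
#'   and, when written, `paths`.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  data <- with_seed(config$seed, simulate_cohort_impl(config))
  if (!is.null(out_dir)) {
    data$paths <- write_cohort_files(data, out_dir)
  }
  data
}

simulate_cohort_impl <- function(config) {
  cohort <- data.frame(
    sample_id = c(sprintf("M%02d", seq_len(config$n_males)),
                  sprintf("F%02d", seq_len(config$n_females))),
    sex = c(rep("MALE", config$n_males), rep("FEMALE", config$n_females)),
    stringsAsFactors = FALSE)
  n <- nrow(cohort)
  male <- cohort$sex == "MALE"

  # --- depth -----------------------------------------------------------
  depth <- vector("list", nrow(config$contigs))
  names(depth) <- config$contigs$contig
  for (i in seq_len(nrow(config$contigs))) {
    ctg <- config$contigs$contig[i]
    len <- config$contigs$length[i]
    # per-sample depth factor profile along the contig
    factors <- matrix(1, nrow = len, ncol = n)
    for (f in config$features) {
      if (f$contig != ctg) next
      rows <- (f$start + 1):f$end
      if (f$kind == "SPURIOUS_HET") next       # depth untouched
      if (f$kind == "REPEAT_CONFOUND") {
        factors[rows, !male] <- 0
        dropped <- stats::runif(sum(male)) < f$confound_prob
        factors[rows, which(male)[dropped]] <- 0
        factors[rows, which(male)[!dropped]] <- f$confound_factor
      } else {
        het <- heterogametic_sex(f$kind, f$het_sex) == "MALE"
        factors[rows, if (het) male else !male] <- f$het_depth_factor
        factors[rows, if (het) !male else male] <- f$hom_depth_factor
      }
    }
    m <- matrix(0L, nrow = len, ncol = n, dimnames = list(NULL, cohort$sample_id))
    for (j in seq_len(n)) {
      m[, j] <- rdepth(len, config$mean_depth * factors[, j], config)
    }
    depth[[i]] <- m
  }

  # --- genotypes -------------------------------------------------------
  var_rows <- list()
  for (i in seq_len(nrow(config$contigs))) {
    ctg <- config$contigs$contig[i]
    len <- config$contigs$length[i]
    # planted sex-linked sites
    planted_pos <- integer(0); planted_gt <- NULL
    for (f in config$features) {
      if (f$contig != ctg || f$variant_density == 0) next
      k <- stats::rpois(1, f$variant_density * (f$end - f$start) / 1000)
      if (k == 0) next
      pos <- sort(sample.int(f$end - f$start, min(k, f$end - f$start))) + f$start
      het <- heterogametic_sex(f$kind, f$het_sex)
      gt <- matrix(ifelse(rep(cohort$sex == het, each = length(pos)),
                          "0/1", "0/0"),
                   nrow = length(pos))
      planted_pos <- c(planted_pos, pos)
      planted_gt <- rbind(planted_gt, gt)
    }
    # background HWE sites
    k_bg <- stats::rpois(1, config$background_rate * len / 1000)
    bg_pos <- if (k_bg > 0) sort(sample.int(len, min(k_bg, len))) else integer(0)
    bg_pos <- setdiff(bg_pos, planted_pos)
    bg_gt <- NULL
    if (length(bg_pos)) {
      p_alt <- stats::runif(length(bg_pos), 0.1, 0.9)
      u <- matrix(stats::runif(length(bg_pos) * n), ncol = n)
      hom_ref <- (1 - p_alt)^2
      het_p <- 2 * p_alt * (1 - p_alt)
      bg_gt <- matrix("1/1", nrow = length(bg_pos), ncol = n)
      bg_gt[u < hom_ref + het_p] <- "0/1"
      bg_gt[u < hom_ref] <- "0/0"
    }
    pos <- c(planted_pos, bg_pos)
    if (!length(pos)) next
    gt <- rbind(planted_gt, bg_gt)
    o <- order(pos)
    var_rows[[ctg]] <- list(
      variants = data.frame(contig = ctg, pos = pos[o] ,
                            ref = "A", alt = "C", stringsAsFactors = FALSE),
      gt = gt[o, , drop = FALSE])
  }
  variants <- do.call(rbind, lapply(var_rows, `[[`, "variants"))
  gt <- do.call(rbind, lapply(var_rows, `[[`, "gt"))
  if (is.null(variants)) {
    variants <- data.frame(contig = character(), pos = integer(),
                           ref = character(), alt = character(),
                           stringsAsFactors = FALSE)
    gt <- matrix(character(0), nrow = 0, ncol = n)
  }
  rownames(variants) <- NULL
  colnames(gt) <- cohort$sample_id

  # symmetric HET<->HOM state flips, then missingness
  if (length(gt)) {
    flip <- matrix(stats::runif(length(gt)) < config$genotype_error,
                   nrow = nrow(gt))
    gt[flip & gt == "0/1"] <- "0/0"
    gt[flip & gt == "0/0"] <- "0/1"
    gt[flip & gt == "1/1"] <- "0/1"
    miss <- matrix(stats::runif(length(gt)) < config$missing_rate,
                   nrow = nrow(gt))
    gt[miss] <- "./."
  }

  truth <- data.frame(
    contig = vapply(config$features, `[[`, "", "contig"),
    start = vapply(config$features, `[[`, 0, "start"),
    end = vapply(config$features, `[[`, 0, "end"),
    kind = vapply(config$features, `[[`, "", "kind"),
    stringsAsFactors = FALSE)

  list(cohort = cohort, contigs = config$contigs, depth = depth,
       genotypes = list(variants = variants, states = gt_to_state(gt)),
       gt = gt, truth = truth, config = config)
}

write_cohort_files <- function(data, out_dir) {
  dir.create(file.path(out_dir, "depth"), showWarnings = FALSE,
             recursive = TRUE)
  paths <- list(
    sample_sheet = file.path(out_dir, "sample_sheet.tsv"),
    contigs = file.path(out_dir, "contigs.fai"),
    depth_dir = file.path(out_dir, "depth"),
    vcf = file.path(out_dir, "variants.vcf"),
    truth = file.path(out_dir, "truth.bed"))

  writeLines(paste(data$cohort$sample_id,
                   ifelse(data$cohort$sex == "MALE", "M", "F"), sep = "\t"),
             paths$sample_sheet)
  writeLines(paste(data$contigs$contig,
                   format(data$contigs$length, scientific = FALSE, trim = TRUE),
                   sep = "\t"),
             paths$contigs)
  for (s in data$cohort$sample_id) {
    rows <- lapply(names(data$depth), function(ctg) {
      d <- data$depth[[ctg]][, s]
      nz <- which(d > 0L)             # zero-depth positions omitted
      if (!length(nz)) return(NULL)
      data.frame(ctg, nz, d[nz])
    })
    rows <- do.call(rbind, rows)
    f <- file.path(paths$depth_dir, paste0(s, ".depth.tsv"))
    if (is.null(rows)) {
      file.create(f)
    } else {
      data.table::fwrite(rows, f, sep = "\t", col.names = FALSE, quote = FALSE)
    }
  }

  header <- c("##fileformat=VCFv4.2",
              "##source=sdscan-simulator",
              paste0("##contig=<ID=", data$contigs$contig, ",length=",
                     format(data$contigs$length, scientific = FALSE,
                            trim = TRUE), ">"),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", data$cohort$sample_id),
                    collapse = "\t"))
  body <- if (nrow(data$genotypes$variants)) {
    v <- data$genotypes$variants
    paste(v$contig, v$pos, ".", v$ref, v$alt, ".", ".", ".", "GT",
          apply(data$gt, 1, paste, collapse = "\t"), sep = "\t")
  } else character(0)
  writeLines(c(header, body), paths$vcf)

  if (nrow(data$truth)) {
    writeLines(paste(data$truth$contig,
                     format(data$truth$start, scientific = FALSE, trim = TRUE),
                     format(data$truth$end, scientific = FALSE, trim = TRUE),
                     data$truth$kind, sep = "\t"),
               paths$truth)
  } else {
    file.create(paths$truth)
  }
  paths
}

#' Pinned simulation fixtures
#'
#' Named cohort configurations used throughout the test suite:
#' \describe{
#'   \item{`xy_small`}{three 30 kb contigs plus one 2.5 kb scaffold (to
#'     exercise short-contig exclusion); a 6 kb `XY_SDR` at the proximal
#'     end of the first contig and a 5 kb female-heterozygous
#'     `SPURIOUS_HET` on the second.}
#'   \item{`zw_small`}{the mirror image (a `ZW_SDR`, male-heterozygous
#'     spurious region).}
#'   \item{`null_small`}{the same contigs with no planted features.}
#'   \item{`confounded`}{`xy_small` plus a 4 kb `REPEAT_CONFOUND` short
#'     scaffold.}
#' }
#'
#' @param name One of `"xy_small"`, `"zw_small"`, `"null_small"`,
#'   `"confounded"`.
#' @param seed RNG seed stored in the config.
#' @return A [simulation_config()].
#' @export
make_fixture <- function(name = c("xy_small", "zw_small", "null_small",
                                  "confounded"),
                         seed = 1L) {
  name <- match.arg(name)
  contigs <- data.frame(
    contig = c("contig_01", "contig_02", "contig_03", "scaffold_tiny"),
    length = c(30000, 30000, 30000, 2500),
    stringsAsFactors = FALSE)
  if (name == "confounded") {
    contigs <- rbind(contigs,
                     data.frame(contig = "scaffold_rep", length = 4000))
  }
  features <- switch(
    name,
    xy_small = list(
      planted_feature("XY_SDR", "contig_01", 0, 6000),
      planted_feature("SPURIOUS_HET", "contig_02", 15000, 20000,
                      het_sex = "FEMALE")),
    zw_small = list(
      planted_feature("ZW_SDR", "contig_01", 0, 6000),
      planted_feature("SPURIOUS_HET", "contig_02", 15000, 20000,
                      het_sex = "MALE")),
    null_small = list(),
    confounded = list(
      planted_feature("XY_SDR", "contig_01", 0, 6000),
      planted_feature("SPURIOUS_HET", "contig_02", 15000, 20000,
                      het_sex = "FEMALE"),
      planted_feature("REPEAT_CONFOUND", "scaffold_rep", 0, 4000)))
  simulation_config(contigs, features = features, seed = seed)
}
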