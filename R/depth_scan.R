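#' Bin per-base depths into fixed-width windows
#'
#' Tiles every contig with non-overlapping windows `[0,b), [b,2b), ...`
#' (0-based half-open) and records the mean depth per sample in each window.
#' A shorter final window is emitted and averaged over its true length.
#'
#' @param depth Depth set: named list (per contig) of integer matrices,
#'   bases x samples, as from [read_depth_dir()].
#' @param cohort Sample sheet; a track must be present for every sample.
#' @param bin_width Window width in bp (default 1000).
#' @return Object of class `binned_depth`: list with `windows`
#'   (`data.frame`: contig, start, end) and `means` (numeric matrix,
#'   windows x samples).
#' @export
bin_depths <- function(depth, cohort, bin_width = 1000) {
  stopifnot(bin_width >= 1)
  missing <- vapply(depth, function(m) !all(cohort$sample_id %in% colnames(m)), TRUE)
  if (any(missing)) {
    stop("missing sample track(s) on contig(s): ",
         paste(names(depth)[missing], collapse = ", "))
  }
  per_contig <- lapply(names(depth), function(ctg) {
    m <- depth[[ctg]][, cohort$sample_id, drop = FALSE]
    len <- nrow(m)
    idx <- rep(seq_len(ceiling(len / bin_width)), each = bin_width,
               length.out = len)
    sums <- rowsum(m, idx, reorder = TRUE)
    nper <- tabulate(idx)
    start <- (seq_along(nper) - 1) * bin_width
    list(windows = data.frame(contig = ctg, start = start,
                              end = start + nper,
                              stringsAsFactors = FALSE),
         means = sums / nper)
  })
  out <- list(
    windows = do.call(rbind, lapply(per_contig, `[[`, "windows")),
    means = do.call(rbind, lapply(per_contig, `[[`, "means")),
    bin_width = bin_width)
  rownames(out$windows) <- NULL
  rownames(out$means) <- NULL
  class(out) <- "binned_depth"
  out
}

# Vectorised two-sided Welch t-test over rows of two matrices.
# Degenerate-variance policy: both groups zero variance and equal means
# -> t = 0, p = 1; both zero variance, unequal means -> p = p_floor;
# a single zero variance proceeds through the Welch formula (finite df).
welch_rows <- function(x, y, p_floor = 1e-300) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  same <- degen & (mx == my)
  t[same] <- 0; p[same] <- 1
  diff <- degen & (mx != my)
  t[diff] <- sign(mx[diff] - my[diff]) * Inf
  p[diff] <- p_floor
  p <- pmax(p, p_floor)
  list(t = t, p = p, male_mean = mx, female_mean = my)
}

#' Welch t-tests of windowed depth between sexes
#'
#' For each depth window, tests the difference between male and female
#' per-sample mean depths with a two-sided Welch two-sample t-test
#' (Welch-Satterthwaite degrees of freedom). P-values are converted to
#' -log10(P) and capped.
#'
#' @param binned A `binned_depth` object from [bin_depths()].
#' @param cohort Sample sheet with at least 2 samples of each sex.
#' @param p_floor Smallest reportable p-value; windows where both sexes
#'   have zero variance but different means get this floor (default 1e-300).
#' @param neglogp_cap Cap on -log10(P) (default 300, consistent with
#'   `p_floor`).
#' @return `data.frame` with columns contig, start, end, male_mean,
#'   female_mean, t, p, neg_log10_p.
#' @export
welch_window_tests <- function(binned, cohort, p_floor = 1e-300,
                               neglogp_cap = 300) {
  validate_cohort(cohort)
  males <- cohort$sample_id[cohort$sex == "MALE"]
  females <- cohort$sample_id[cohort$sex == "FEMALE"]
  w <- welch_rows(binned$means[, males, drop = FALSE],
                  binned$means[, females, drop = FALSE],
                  p_floor = p_floor)
  data.frame(binned$windows,
             male_mean = w$male_mean, female_mean = w$female_mean,
             t = w$t, p = w$p,
             neg_log10_p = pmin(-log10(w$p), neglogp_cap),
             stringsAsFactors = FALSE)
}

#' Retain depth windows above a significance threshold
#'
#' Keeps windows with -log10(P) strictly greater than the threshold,
#' sorted by contig then start.
#'
#' @param stats Window statistics from [welch_window_tests()].
#' @param threshold Retention threshold on -log10(P) (default 2).
#' @return The retained subset, sorted.
#' @export
filter_depth_windows <- function(stats, threshold = 2) {
  stopifnot(threshold >= 0)
  keep <- stats[stats$neg_log10_p > threshold, , drop = FALSE]
  keep <- keep[order(keep$contig, keep$start), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Find sex-specific (near-)zero depth tracts
#'
#' Reports maximal intervals in which every sample of the chosen sex has
#' per-base depth at most `max_allowed_depth` at every base, and which are
#' at least `min_tract_len` long. Such tracts are evidence that the
#' reference sequence is absent from that sex (e.g. Y-derived sequence in
#' females of an XY system).
#'
#' @param depth Depth set (densified; zeros explicit).
#' @param cohort Sample sheet.
#' @param sex `"MALE"` or `"FEMALE"`: the sex required to lack coverage.
#' @param max_allowed_depth Maximum per-base depth still counted as absent
#'   (default 0).
#' @param min_tract_len Minimum tract length in bp (default 1000).
#' @return `data.frame` with columns contig, start, end (0-based half-open),
#'   sex, max_allowed_depth.
#' @export
zero_depth_tracts <- function(depth, cohort, sex,
                              max_allowed_depth = 0, min_tract_len = 1000) {
  sex <- match.arg(sex, c("MALE", "FEMALE"))
  ids <- cohort$sample_id[cohort$sex == sex]
  res <- lapply(names(depth), function(ctg) {
    m <- depth[[ctg]][, ids, drop = FALSE]
    ok <- rowSums(m > max_allowed_depth) == 0L
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    sel <- r$values & r$lengths >= min_tract_len
    if (!any(sel)) return(NULL)
    data.frame(contig = ctg, start = starts[sel], end = ends[sel],
               sex = sex, max_allowed_depth = max_allowed_depth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(contig = character(), start = numeric(),
                      end = numeric(), sex = character(),
                      max_allowed_depth = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
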