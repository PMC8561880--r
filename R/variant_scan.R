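#' Fisher exact test of genotype state against sex
#'
#' Tests the 2x2 table sex x state (HET vs HOM) for a single variant by
#' direct hypergeometric enumeration over all tables with the observed
#' margins. The two-sided p-value is the sum of probabilities of tables
#' whose point probability does not exceed that of the observed table
#' (within a relative tolerance of 1e-7, matching the conventional exact
#' test). `MISSING` samples are dropped before tabulation.
#'
#' @param states Named character vector of per-sample states (`"HOM"`,
#'   `"HET"`, `"MISSING"`), names = sample ids.
#' @param cohort Sample sheet.
#' @return List with `p_value`, `neg_log10_p`, `direction` (`"MALE_HET"`,
#'   `"FEMALE_HET"` or `"NONE"`: the sex with the higher HET fraction,
#'   `NONE` on a tie), the `counts` (het/hom per sex plus `n_missing`) and
#'   `skipped` (`TRUE`, with p-value `NA`, when one sex is entirely
#'   missing).
#' @export
fisher_sex_state_test <- function(states, cohort) {
  states <- states[cohort$sample_id]
  male <- cohort$sex == "MALE"
  het_m <- sum(states[male] == "HET"); hom_m <- sum(states[male] == "HOM")
  het_f <- sum(states[!male] == "HET"); hom_f <- sum(states[!male] == "HOM")
  n_missing <- sum(states == "MISSING")
  counts <- c(het_males = het_m, hom_males = hom_m,
              het_females = het_f, hom_females = hom_f,
              n_missing = n_missing)
  if (het_m + hom_m == 0L || het_f + hom_f == 0L) {
    return(list(p_value = NA_real_, neg_log10_p = NA_real_,
                direction = "NONE", counts = counts, skipped = TRUE))
  }
  p <- fisher_2x2_p(het_m, hom_m, het_f, hom_f)
  fm <- het_m / (het_m + hom_m)
  ff <- het_f / (het_f + hom_f)
  direction <- if (fm > ff) "MALE_HET" else if (ff > fm) "FEMALE_HET" else "NONE"
  list(p_value = p, neg_log10_p = -log10(p), direction = direction,
       counts = counts, skipped = FALSE)
}

# Two-sided exact p for the table [[a, b], [c, d]] (rows: males, females;
# cols: HET, HOM) by enumeration of the hypergeometric support.
fisher_2x2_p <- function(a, b, c, d) {
  nm <- a + b        # non-missing males
  nf <- c + d        # non-missing females
  k <- a + c         # total HET
  support <- max(0L, k - nf):min(k, nm)
  probs <- stats::dhyper(support, nm, nf, k)
  p_obs <- stats::dhyper(a, nm, nf, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Score sex association for every variant in a genotype table
#'
#' Applies [fisher_sex_state_test()] to each variant and flags variants
#' whose state is entirely associated with sex: every genotyped sample of
#' one sex HET, every genotyped sample of the other HOM, with no missing
#' genotypes in the cohort (cohort-complete rule). Variants with one sex
#' entirely missing are skipped with a message.
#'
#' @param genotypes Genotype table as from [read_genotypes()].
#' @param cohort Sample sheet.
#' @return `data.frame` with columns contig, pos, het_males, hom_males,
#'   het_females, hom_females, n_missing, p, neg_log10_p, fully_associated,
#'   direction.
#' @export
variant_associations <- function(genotypes, cohort) {
  st <- genotypes$states[, cohort$sample_id, drop = FALSE]
  male <- cohort$sex == "MALE"
  n_m <- sum(male); n_f <- sum(!male)
  het_m <- rowSums(st[, male, drop = FALSE] == "HET")
  hom_m <- rowSums(st[, male, drop = FALSE] == "HOM")
  het_f <- rowSums(st[, !male, drop = FALSE] == "HET")
  hom_f <- rowSums(st[, !male, drop = FALSE] == "HOM")
  n_missing <- nrow(cohort) - (het_m + hom_m + het_f + hom_f)

  skipped <- (het_m + hom_m == 0L) | (het_f + hom_f == 0L)
  if (any(skipped)) {
    message(sum(skipped), " variant(s) skipped: one sex entirely missing")
  }
  # memoise the exact test over distinct count configurations
  key <- paste(het_m, hom_m, het_f, hom_f)
  uk <- !duplicated(key) & !skipped
  pu <- vapply(which(uk), function(i) {
    fisher_2x2_p(het_m[i], hom_m[i], het_f[i], hom_f[i])
  }, 0)
  p <- unname(pu[match(key, key[uk])])
  p[skipped] <- NA_real_

  fm <- het_m / (het_m + hom_m)
  ff <- het_f / (het_f + hom_f)
  direction <- ifelse(is.na(p) | fm == ff, "NONE",
                      ifelse(fm > ff, "MALE_HET", "FEMALE_HET"))
  fully <- !skipped & n_missing == 0L &
    ((het_m == n_m & hom_f == n_f) | (hom_m == n_m & het_f == n_f))
  out <- data.frame(genotypes$variants[, c("contig", "pos")],
                    het_males = het_m, hom_males = hom_m,
                    het_females = het_f, hom_females = hom_f,
                    n_missing = n_missing,
                    p = p, neg_log10_p = -log10(p),
                    fully_associated = fully, direction = direction,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Subset fully sex-associated variants
#'
#' @param associations `data.frame` from [variant_associations()].
#' @return The subset with `fully_associated == TRUE`.
#' @export
flag_fully_associated <- function(associations) {
  out <- associations[associations$fully_associated, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dense windows of fully sex-associated variants
#'
#' Tiles each contig with non-overlapping windows anchored at coordinate 0
#' and reports windows containing strictly more than `min_count` fully
#' sex-associated variants. A window's direction is the common direction of
#' all counted variants, or `"MIXED"`.
#'
#' @param flagged Fully associated variants, as from
#'   [flag_fully_associated()].
#' @param contigs Contig table (defines tiling extents).
#' @param window Tile width in bp (default 5000).
#' @param min_count Count threshold; windows with count > `min_count` are
#'   reported (default 10).
#' @return `data.frame` with columns contig, start, end, count, direction.
#' @export
density_windows <- function(flagged, contigs, window = 5000, min_count = 10) {
  empty <- data.frame(contig = character(), start = numeric(),
                      end = numeric(), count = integer(),
                      direction = character(), stringsAsFactors = FALSE)
  if (nrow(flagged) == 0L) return(empty)
  res <- lapply(seq_len(nrow(contigs)), function(i) {
    ctg <- contigs$contig[i]
    v <- flagged[flagged$contig == ctg, , drop = FALSE]
    if (nrow(v) == 0L) return(NULL)
    bin <- (v$pos - 1) %/% window          # 0-based tile index
    counts <- table(bin)
    keep <- counts > min_count
    if (!any(keep)) return(NULL)
    idx <- as.integer(names(counts)[keep])
    dir <- vapply(idx, function(b) {
      d <- unique(v$direction[bin == b])
      if (length(d) == 1L) d else "MIXED"
    }, "")
    data.frame(contig = ctg, start = idx * window,
               end = pmin((idx + 1) * window, contigs$length[i]),
               count = as.integer(counts[keep]), direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
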