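# 0-based half-open data.frame intervals -> IRanges (1-based closed)
as_iranges0 <- function(df) {
  IRanges::IRanges(start = df$start + 1, end = df$end)
}

# any overlap between 0-based half-open query rows and subject rows,
# with subject expanded by `slop` bp on both sides
overlaps_any0 <- function(query, subject, slop = 0) {
  if (nrow(subject) == 0L || nrow(query) == 0L) return(logical(nrow(query)))
  hit <- logical(nrow(query))
  for (ctg in unique(query$contig)) {
    qi <- which(query$contig == ctg)
    s <- subject[subject$contig == ctg, , drop = FALSE]
    if (nrow(s) == 0L) next
    sr <- IRanges::IRanges(start = pmax(s$start - slop, 0) + 1,
                           end = s$end + slop)
    hit[qi] <- IRanges::overlapsAny(as_iranges0(query[qi, , drop = FALSE]), sr)
  }
  hit
}

#' Merge candidate regions from density and depth evidence
#'
#' Takes the significant variant-density windows and the retained
#' depth-contrast windows, forms their per-contig interval union, and merges
#' intervals separated by less than `merge_gap` bp (adjacent intervals are
#' always merged). Each merged region records which evidence types
#' contributed.
#'
#' @param density Density windows from [density_windows()].
#' @param depth_windows Retained depth windows from
#'   [filter_depth_windows()].
#' @param merge_gap Gap below which neighbouring intervals merge, bp
#'   (default 1000).
#' @return `data.frame` with columns contig, start, end,
#'   from_density, from_depth (logicals).
#' @export
merge_candidate_regions <- function(density, depth_windows, merge_gap = 1000) {
  cols <- c("contig", "start", "end")
  all_iv <- rbind(density[, cols, drop = FALSE],
                  depth_windows[, cols, drop = FALSE])
  if (nrow(all_iv) == 0L) {
    return(data.frame(contig = character(), start = numeric(), end = numeric(),
                      from_density = logical(), from_depth = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- lapply(unique(all_iv$contig), function(ctg) {
    iv <- all_iv[all_iv$contig == ctg, , drop = FALSE]
    red <- IRanges::reduce(as_iranges0(iv), min.gapwidth = max(merge_gap, 1))
    data.frame(contig = ctg, start = IRanges::start(red) - 1,
               end = IRanges::end(red), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$from_density <- overlaps_any0(out, density)
  out$from_depth <- overlaps_any0(out, depth_windows)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a candidate region as XY-linked, ZW-linked, spurious or ambiguous
#'
#' Applies the evidence rule table to one merged candidate region:
#' \itemize{
#'   \item male-heterozygous variants plus co-located female depth absence
#'     (a female zero-depth tract, or a retained depth window whose female
#'     mean is at most `depth_deficit_ratio` times the male mean)
#'     -> `XY_LINKED`;
#'   \item female-heterozygous variants plus co-located male depth absence
#'     (mirror rule) -> `ZW_LINKED`;
#'   \item a heterozygosity association with no co-located sex-specific
#'     depth deficit -> `SPURIOUS` (the parsimonious reading of
#'     depth-unsupported genotype signal);
#'   \item depth evidence without a variant direction, conflicting variant
#'     directions, or a direction whose depth support points the wrong way
#'     -> `AMBIGUOUS`.
#' }
#' Co-location means overlap within `colocalization_slop` bp. The
#' fold-change qualification on deficit windows keeps chance-significant
#' windows with near-equal means (expected at a few percent of windows
#' under the null) from counting as depth support; a genuine hemizygous or
#' absent region shows a halved or zero mean in the deficit sex.
#'
#' @param region One-row `data.frame` (contig, start, end).
#' @param tracts Zero-depth tracts of both sexes (rbind of
#'   [zero_depth_tracts()] calls), may be empty.
#' @param associations Variant associations from [variant_associations()].
#' @param depth_windows Retained depth windows from
#'   [filter_depth_windows()].
#' @param colocalization_slop Co-location slop in bp (default 5000).
#' @param depth_deficit_ratio A retained window supports a deficit in one
#'   sex when that sex's mean is at most this fraction of the other sex's
#'   mean (default 0.5, the hemizygous scale).
#' @param direction_dominance The region's variant direction is assigned
#'   when one direction accounts for at least this fraction of the
#'   co-located fully associated variants (default 0.8); a genuine
#'   sex-determining region is expected to be unanimous, and a lone chance
#'   variant of the opposite direction should not veto it. Below the
#'   threshold the direction is `MIXED`.
#' @return One-row `data.frame`: region coords, evidence columns
#'   (variant_direction, has_density_signal, female_zero_tract_overlap,
#'   male_zero_tract_overlap, depth_window_overlap, max_neg_log10_p) and
#'   `classification`.
#' @export
classify_region <- function(region, tracts, associations, depth_windows,
                            colocalization_slop = 5000,
                            depth_deficit_ratio = 0.5,
                            direction_dominance = 0.8) {
  stopifnot(nrow(region) == 1L, region$start < region$end)
  slop <- colocalization_slop
  flagged <- associations[associations$fully_associated, , drop = FALSE]
  inside <- flagged$contig == region$contig &
    flagged$pos - 1 >= region$start - slop &
    flagged$pos - 1 < region$end + slop
  dir_counts <- table(factor(flagged$direction[inside],
                             levels = c("MALE_HET", "FEMALE_HET")))
  variant_direction <- if (sum(dir_counts) == 0L) {
    "NONE"
  } else if (max(dir_counts) / sum(dir_counts) >= direction_dominance) {
    names(dir_counts)[which.max(dir_counts)]
  } else {
    "MIXED"
  }

  f_tracts <- tracts[tracts$sex == "FEMALE", , drop = FALSE]
  m_tracts <- tracts[tracts$sex == "MALE", , drop = FALSE]
  female_tract <- any(overlaps_any0(region, f_tracts, slop))
  male_tract <- any(overlaps_any0(region, m_tracts, slop))

  dw_hit <- overlaps_any0(depth_windows, region, slop)
  dw <- depth_windows[dw_hit, , drop = FALSE]
  depth_overlap <- nrow(dw) > 0L
  female_deficit <- depth_overlap &&
    any(dw$female_mean <= depth_deficit_ratio * dw$male_mean)
  male_deficit <- depth_overlap &&
    any(dw$male_mean <= depth_deficit_ratio * dw$female_mean)

  max_p <- suppressWarnings(max(c(dw$neg_log10_p,
                                  flagged$neg_log10_p[inside], 0)))

  female_absence <- female_tract || female_deficit
  male_absence <- male_tract || male_deficit
  classification <-
    if (variant_direction == "MALE_HET" && female_absence) {
      "XY_LINKED"
    } else if (variant_direction == "FEMALE_HET" && male_absence) {
      "ZW_LINKED"
    } else if (variant_direction %in% c("MALE_HET", "FEMALE_HET") &&
               !female_absence && !male_absence) {
      "SPURIOUS"
    } else {
      "AMBIGUOUS"
    }

  data.frame(contig = region$contig, start = region$start, end = region$end,
             variant_direction = variant_direction,
             has_density_signal = isTRUE(region$from_density),
             female_zero_tract_overlap = female_tract,
             male_zero_tract_overlap = male_tract,
             depth_window_overlap = depth_overlap,
             max_neg_log10_p = max_p,
             classification = classification,
             stringsAsFactors = FALSE)
}

#' Infer the cohort sex-determination system from region calls
#'
#' Returns `XY` when at least one region is `XY_LINKED` and none is
#' `ZW_LINKED`; `ZW` symmetrically; otherwise `UNDETERMINED` (including the
#' conflicting case — no majority vote is taken).
#'
#' @param region_calls `data.frame` of classified regions (rbind of
#'   [classify_region()] rows).
#' @return Object of class `sex_system_verdict`: list with `system`
#'   (`"XY"`, `"ZW"` or `"UNDETERMINED"`), `supporting_regions` and a
#'   human-readable `rationale`.
#' @export
infer_sex_system <- function(region_calls) {
  n_xy <- sum(region_calls$classification == "XY_LINKED")
  n_zw <- sum(region_calls$classification == "ZW_LINKED")
  pick <- function(cls) {
    region_calls[region_calls$classification == cls, , drop = FALSE]
  }
  if (n_xy >= 1L && n_zw == 0L) {
    sup <- pick("XY_LINKED")
    system <- "XY"
    rationale <- paste0(
      "Male-heterozygous variants co-located with female depth deficits on: ",
      paste(unique(sup$contig), collapse = ", "),
      "; no ZW-linked region detected.")
  } else if (n_zw >= 1L && n_xy == 0L) {
    sup <- pick("ZW_LINKED")
    system <- "ZW"
    rationale <- paste0(
      "Female-heterozygous variants co-located with male depth deficits on: ",
      paste(unique(sup$contig), collapse = ", "),
      "; no XY-linked region detected.")
  } else {
    sup <- region_calls[region_calls$classification %in%
                          c("XY_LINKED", "ZW_LINKED"), , drop = FALSE]
    system <- "UNDETERMINED"
    rationale <- if (n_xy > 0L && n_zw > 0L) {
      "Conflicting XY-linked and ZW-linked regions; no verdict taken."
    } else {
      "No region shows co-located genotype and depth evidence."
    }
  }
  structure(list(system = system, supporting_regions = sup,
                 rationale = rationale),
            class = "sex_system_verdict")
}

#' @export
print.sex_system_verdict <- function(x, ...) {
  cat("Sex-determination system:", x$system, "\n")
  cat(x$rationale, "\n")
  if (nrow(x$supporting_regions) > 0) {
    cat("Supporting regions:\n")
    print(x$supporting_regions[, c("contig", "start", "end",
                                   "classification", "max_neg_log10_p")])
  }
  invisible(x)
}
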