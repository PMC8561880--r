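iv <- function(contig, start, end, ...) {
  data.frame(contig = contig, start = start, end = end, ...,
             stringsAsFactors = FALSE)
}

dw <- function(contig, start, end, male = 13, female = 13, nlp = 3) {
  data.frame(contig = contig, start = start, end = end,
             male_mean = male, female_mean = female, t = 1, p = 10^-nlp,
             neg_log10_p = nlp, stringsAsFactors = FALSE)
}

no_assoc <- data.frame(contig = character(), pos = integer(),
                       neg_log10_p = numeric(), fully_associated = logical(),
                       direction = character(), stringsAsFactors = FALSE)

assoc <- function(contig, pos, direction) {
  data.frame(contig = contig, pos = pos, neg_log10_p = 3.234517,
             fully_associated = TRUE, direction = direction,
             stringsAsFactors = FALSE)
}

no_tracts <- data.frame(contig = character(), start = numeric(),
                        end = numeric(), sex = character(),
                        max_allowed_depth = numeric(), stringsAsFactors = FALSE)

tract <- function(contig, start, end, sex) {
  data.frame(contig = contig, start = start, end = end, sex = sex,
             max_allowed_depth = 0, stringsAsFactors = FALSE)
}

test_that("candidate regions merge adjacency and respect the gap", {
  dens <- iv("c1", 0, 5000, count = 11L, direction = "MALE_HET")
  dens2 <- iv("c1", 5000, 10000, count = 12L, direction = "MALE_HET")
  m <- merge_candidate_regions(rbind(dens, dens2), dw("c1", 0, 0)[0, ],
                               merge_gap = 0)
  expect_equal(m[, c("start", "end")], data.frame(start = 0, end = 10000))
  expect_true(m$from_density)
  expect_false(m$from_depth)

  far <- rbind(iv("c1", 0, 5000, count = 11L, direction = "MALE_HET"),
               iv("c1", 55000, 60000, count = 11L, direction = "MALE_HET"))
  m <- merge_candidate_regions(far, dw("c1", 0, 0)[0, ], merge_gap = 10000)
  expect_equal(nrow(m), 2)

  # both evidence types recorded
  m <- merge_candidate_regions(dens, dw("c1", 4000, 6000), merge_gap = 1000)
  expect_equal(nrow(m), 1)
  expect_true(m$from_density && m$from_depth)
  expect_equal(nrow(merge_candidate_regions(dens[0, ], dw("c1", 0, 0)[0, ])), 0)
})

test_that("merged regions equal an interval-union sweep oracle", {
  set.seed(41)
  for (rep in 1:5) {
    starts <- sample(seq(0, 95000, 1000), 12)
    ivs <- iv("c1", starts, starts + sample(c(1000, 5000), 12, TRUE))
    gap <- sample(c(0, 1000, 3000), 1)
    m <- merge_candidate_regions(ivs, dw("c1", 0, 0)[0, ], merge_gap = gap)
    # oracle: base-wise paint, then bridge gaps < gap
    painted <- logical(110000)
    for (i in seq_len(nrow(ivs))) painted[(ivs$start[i] + 1):ivs$end[i]] <- TRUE
    r <- rle(painted)
    off <- cumsum(r$lengths) - r$lengths
    bridge <- !r$values & r$lengths < max(gap, 1) &
      seq_along(r$values) != 1 & seq_along(r$values) != length(r$values)
    r$values[bridge] <- TRUE
    painted2 <- inverse.rle(r)
    r2 <- rle(painted2)
    ends <- cumsum(r2$lengths); starts2 <- ends - r2$lengths
    oracle <- data.frame(start = starts2[r2$values], end = ends[r2$values])
    expect_equal(m[, c("start", "end")], oracle)
  }
})

test_that("region classification follows the evidence rule table", {
  region <- iv("c1", 0, 6000, from_density = TRUE, from_depth = TRUE)

  # male-het variants + all-female zero tract -> XY-linked
  call <- classify_region(region, tract("c1", 0, 6000, "FEMALE"),
                          assoc("c1", c(100, 2000), "MALE_HET"),
                          dw("c1", 0, 6000, male = 6.5, female = 0.02))
  expect_equal(call$classification, "XY_LINKED")
  expect_true(call$female_zero_tract_overlap)
  expect_equal(call$max_neg_log10_p, 3.234517, tolerance = 1e-6)

  # mirror evidence -> ZW-linked
  call <- classify_region(region, tract("c1", 0, 6000, "MALE"),
                          assoc("c1", c(100, 2000), "FEMALE_HET"),
                          dw("c1", 0, 6000, male = 0.02, female = 6.5))
  expect_equal(call$classification, "ZW_LINKED")

  # female-het variants with no depth evidence at all -> spurious
  call <- classify_region(iv("c2", 15000, 20000), no_tracts,
                          assoc("c2", c(15100, 16000), "FEMALE_HET"),
                          dw("c1", 0, 0)[0, ])
  expect_equal(call$classification, "SPURIOUS")

  # a chance-significant window with near-equal means is not depth support
  call <- classify_region(iv("c2", 15000, 20000), no_tracts,
                          assoc("c2", c(15100, 16000), "FEMALE_HET"),
                          dw("c2", 17000, 18000, male = 13.4, female = 12.6))
  expect_equal(call$classification, "SPURIOUS")
  expect_true(call$depth_window_overlap)

  # a hemizygous-scale deficit without any zero tract still supports XY
  call <- classify_region(region, no_tracts,
                          assoc("c1", 100, "MALE_HET"),
                          dw("c1", 0, 6000, male = 13, female = 6.2))
  expect_equal(call$classification, "XY_LINKED")

  # depth evidence with no variant direction -> ambiguous
  call <- classify_region(region, tract("c1", 0, 6000, "FEMALE"),
                          no_assoc, dw("c1", 0, 6000, male = 13, female = 0))
  expect_equal(call$classification, "AMBIGUOUS")

  # conflicting directions -> ambiguous
  call <- classify_region(region, tract("c1", 0, 6000, "FEMALE"),
                          rbind(assoc("c1", 100, "MALE_HET"),
                                assoc("c1", 300, "FEMALE_HET")),
                          dw("c1", 0, 6000, male = 13, female = 0))
  expect_equal(call$classification, "AMBIGUOUS")

  # co-location honours the slop
  call <- classify_region(iv("c1", 0, 2000), tract("c1", 6500, 9000, "FEMALE"),
                          assoc("c1", 100, "MALE_HET"), dw("c1", 0, 0)[0, ],
                          colocalization_slop = 5000)
  expect_equal(call$classification, "XY_LINKED")
  call <- classify_region(iv("c1", 0, 2000), tract("c1", 6500, 9000, "FEMALE"),
                          assoc("c1", 100, "MALE_HET"), dw("c1", 0, 0)[0, ],
                          colocalization_slop = 1000)
  expect_equal(call$classification, "SPURIOUS")
})

test_that("classification is antisymmetric under a global sex-label swap", {
  region <- iv("c1", 0, 6000)
  swap_dir <- function(d) switch(d, MALE_HET = "FEMALE_HET",
                                 FEMALE_HET = "MALE_HET", d)
  cases <- list(
    list(tr = tract("c1", 0, 6000, "FEMALE"),
         as = assoc("c1", 100, "MALE_HET"),
         wd = dw("c1", 0, 6000, male = 6.5, female = 0)),
    list(tr = no_tracts, as = assoc("c1", 100, "FEMALE_HET"),
         wd = dw("c1", 0, 0)[0, ]),
    list(tr = no_tracts, as = no_assoc,
         wd = dw("c1", 0, 6000, male = 13, female = 0)))
  for (cs in cases) {
    a <- classify_region(region, cs$tr, cs$as, cs$wd)
    tr2 <- cs$tr
    tr2$sex <- ifelse(tr2$sex == "MALE", "FEMALE", "MALE")
    as2 <- cs$as
    if (nrow(as2)) as2$direction <- vapply(as2$direction, swap_dir, "")
    wd2 <- cs$wd
    tmp <- wd2$male_mean; wd2$male_mean <- wd2$female_mean
    wd2$female_mean <- tmp
    b <- classify_region(region, tr2, as2, wd2)
    expected <- switch(a$classification, XY_LINKED = "ZW_LINKED",
                       ZW_LINKED = "XY_LINKED", a$classification)
    expect_equal(b$classification, expected)
  }
})

test_that("the verdict requires unopposed linked regions", {
  xy <- classify_region(iv("c1", 0, 6000), tract("c1", 0, 6000, "FEMALE"),
                        assoc("c1", 100, "MALE_HET"),
                        dw("c1", 0, 6000, male = 6.5, female = 0))
  sp <- classify_region(iv("c2", 0, 5000), no_tracts,
                        assoc("c2", 100, "FEMALE_HET"), dw("c1", 0, 0)[0, ])
  zw <- classify_region(iv("c3", 0, 6000), tract("c3", 0, 6000, "MALE"),
                        assoc("c3", 100, "FEMALE_HET"),
                        dw("c3", 0, 6000, male = 0, female = 6.5))

  v <- infer_sex_system(rbind(xy, sp, sp, sp))
  expect_equal(v$system, "XY")
  expect_equal(nrow(v$supporting_regions), 1)
  expect_match(v$rationale, "c1")

  expect_equal(infer_sex_system(rbind(zw, sp))$system, "ZW")
  expect_equal(infer_sex_system(xy[0, ])$system, "UNDETERMINED")
  v <- infer_sex_system(rbind(xy, zw))
  expect_equal(v$system, "UNDETERMINED")
  expect_match(v$rationale, "Conflicting")
  expect_output(print(v), "UNDETERMINED")
})
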