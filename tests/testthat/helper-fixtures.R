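# Shared fixture builders; all data generated in code at test time.

make_cohort <- function(n_males = 7, n_females = 6) {
  data.frame(
    sample_id = c(sprintf("M%02d", seq_len(n_males)),
                  sprintf("F%02d", seq_len(n_females))),
    sex = c(rep("MALE", n_males), rep("FEMALE", n_females)),
    stringsAsFactors = FALSE)
}

# write a minimal VCF v4.2 with GT-only FORMAT for a matrix of GT strings
write_tiny_vcf <- function(gt, contig = "c1", pos = seq_len(nrow(gt)),
                           path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", contig, ",length=",
                     max(pos) + 10, ">"),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  body <- paste(contig, pos, ".", "A", "C", ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  path
}

# states vector helper: named per-sample HOM/HET/MISSING
states_for <- function(cohort, male_state, female_state) {
  stats::setNames(ifelse(cohort$sex == "MALE", male_state, female_state),
                  cohort$sample_id)
}

# independent two-sided Fisher p oracle: full enumeration with choose(),
# no hypergeometric distribution functions
fisher_oracle <- function(a, b, c, d) {
  nm <- a + b; nf <- c + d; k <- a + c; ntot <- nm + nf
  support <- max(0, k - nf):min(k, nm)
  prob <- function(x) choose(nm, x) * choose(nf, k - x) / choose(ntot, k)
  probs <- vapply(support, prob, 0)
  p_obs <- prob(a)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# simulate a named fixture to disk and run the full file-based pipeline
run_fixture <- function(name, seed, out_dir = NULL) {
  d <- file.path(tempdir(), paste0("fx_", name, "_", seed))
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  sim <- simulate_cohort(make_fixture(name, seed = seed), out_dir = d)
  fit <- run_pipeline(file.path(d, "sample_sheet.tsv"),
                      file.path(d, "depth"),
                      file.path(d, "variants.vcf"),
                      file.path(d, "contigs.fai"),
                      config = pipeline_config(seed = seed),
                      out_dir = out_dir)
  list(fit = fit, truth = sim$truth)
}

# reciprocal overlap fraction of two 0-based half-open intervals
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}
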