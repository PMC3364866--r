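# Fixtures are built in code at test time.

write_toy_table <- function(path = tempfile(fileext = ".tsv"),
                            genotypes = NULL) {
  if (is.null(genotypes))
    genotypes <- rbind(
      I1 = c(0L, 1L),
      I2 = c(1L, 2L),
      I3 = c(0L, NA))
  colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  m <- genotype_matrix(genotypes,
                       species = rep("mallard", nrow(genotypes)),
                       locality = rep("pondA", nrow(genotypes)))
  write_genotype_table(m, path)
  path
}

# minimal biallelic VCF with one multi-allelic record to be skipped
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "0|1", "./.", "1/0", sep = "\t"),
    paste("1", "300", "rs3", "G", "A,T", ".", "PASS", ".", "GT",
          "0/1", "0/2", "1/1", sep = "\t"))
  writeLines(lines, path)
  path
}

toy_species_map <- function() {
  data.frame(sample = c("S1", "S2", "S3"),
             species = c("mallard", "mallard", "pintail"),
             stringsAsFactors = FALSE)
}

# Independent brute-force HWE oracle: enumerate every genotype configuration
# (n0, n1, n2) compatible with the sample size and allele counts, with
# P(config) = choose(n, n0) choose(n - n0, n1) 2^n1 / choose(2n, n_alt).
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  n_alt <- 2 * n2 + n1
  configs <- expand.grid(a0 = 0:n, a1 = 0:n)
  configs$a2 <- n - configs$a0 - configs$a1
  configs <- configs[configs$a2 >= 0 &
                       2 * configs$a2 + configs$a1 == n_alt, ]
  prob <- with(configs,
               choose(n, a0) * choose(n - a0, a1) * 2^a1) / choose(2 * n, n_alt)
  stopifnot(abs(sum(prob) - 1) < 1e-9)
  obs <- prob[configs$a0 == n0 & configs$a1 == n1]
  sum(prob[prob <= obs + 1e-12])
}

# small fast panel for end-to-end tests
small_panel_config <- function(seed = 1L, ...) {
  sp <- data.frame(
    species = c("focal", "near", "far"),
    diploid_size = c(60L, 30L, 30L),
    divergence_generations = c(0L, 60L, 120L),
    hybridisation_rate = c(0, 0.01, 0.001),
    sample_size = c(40L, 10L, 10L),
    missingness = c(0.04, 0.15, 0.2),
    stringsAsFactors = FALSE)
  panel_config(n_candidate_loci = 600L, n_panel_loci = 80L,
               focal_species = "focal", ascertainment_sample_size = 12L,
               species_params = sp,
               hybrids = data.frame(parent1 = "focal", parent2 = "near",
                                    stringsAsFactors = FALSE),
               seed = seed, ...)
}
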