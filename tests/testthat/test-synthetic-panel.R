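test_that("panel evolution respects neutrality and degenerate histories", {
  # zero divergence everywhere: terminal frequencies equal ancestral
  sp <- small_panel_config()$species_params
  sp$divergence_generations <- 0L
  cfg <- panel_config(n_candidate_loci = 300L, n_panel_loci = 50L,
                      focal_species = "focal", species_params = sp,
                      hybrids = NULL, seed = 3)
  tr <- evolve_panel(cfg)
  for (s in sp$species)
    expect_equal(unname(tr$terminal[s, ]), tr$ancestral)
  # huge duration without gene flow: nearly everything absorbed
  sp2 <- small_panel_config()$species_params
  sp2$divergence_generations <- c(0L, 3000L, 3000L)
  sp2$hybridisation_rate <- 0
  tr2 <- evolve_panel(panel_config(n_candidate_loci = 400L, n_panel_loci = 10L,
                                   focal_species = "focal",
                                   species_params = sp2, hybrids = NULL,
                                   seed = 4))
  expect_lt(mean(tr2$polymorphic["far", ]), 0.05)
  # martingale: mean terminal frequency tracks the ancestral mean
  cfg3 <- small_panel_config(seed = 5)
  cfg3$n_candidate_loci <- 4000L
  tr3 <- evolve_panel(cfg3)
  expect_lt(abs(mean(tr3$terminal["near", ]) - mean(tr3$ancestral)), 0.02)
})

test_that("ascertainment keeps only focal-polymorphic loci and biases MAF up", {
  cfg <- small_panel_config(seed = 8)
  tr <- evolve_panel(cfg)
  panel <- ascertain_loci(tr, cfg)
  expect_length(panel, cfg$n_panel_loci)
  idx <- match(panel, sprintf("L%04d", seq_len(cfg$n_candidate_loci)))
  f <- tr$terminal[cfg$focal_species, idx]
  # a locus fixed in the focal species can never be in the panel
  expect_true(all(f > 0 & f < 1))
  # ascertainment bias: panel loci have higher mean focal MAF than candidates
  maf <- function(x) pmin(x, 1 - x)
  cand <- tr$terminal[cfg$focal_species, ]
  expect_gt(mean(maf(f)), mean(maf(cand)))
  # unreachable panel size is reported, not truncated
  cfg_big <- small_panel_config(seed = 8)
  cfg_big$n_panel_loci <- 600L
  expect_error(ascertain_loci(tr, cfg_big), "cannot reach")
})

test_that("genotype sampling honours frequencies, missingness and hybrids", {
  cfg <- small_panel_config(seed = 12)
  tr <- evolve_panel(cfg)
  # force extreme frequencies at two loci to pin down genotypes
  tr$terminal["focal", 1] <- 0
  tr$terminal["near", 1] <- 1
  panel <- c("L0001", ascertain_loci(tr, cfg)[1:39])
  m <- sample_genotypes(tr, panel, cfg)
  focal_rows <- m$species == "focal"
  g1 <- m$genotypes[focal_rows, "L0001"]
  expect_true(all(g1[!is.na(g1)] == 0L))
  # F1 hybrid between frequency-0 and frequency-1 parents is heterozygous
  hyb <- m$genotypes[m$species == "focal_x_near", "L0001"]
  expect_true(is.na(hyb) || hyb == 1L)
  # realised missingness within the 99% binomial envelope per species
  for (s in cfg$species_params$species) {
    rate <- cfg$species_params$missingness[cfg$species_params$species == s]
    gm <- m$genotypes[m$species == s, , drop = FALSE]
    n <- length(gm)
    ci <- qbinom(c(0.005, 0.995), n, rate)
    expect_gte(sum(is.na(gm)), ci[1])
    expect_lte(sum(is.na(gm)), ci[2])
  }
})

test_that("sample-level sharing recovers truth and rises with hybridisation", {
  # sharing between focal and 'near' increases with m (averaged over seeds)
  share_at_m <- function(m_rate, seeds) {
    vapply(seeds, function(sd) {
      sp <- small_panel_config()$species_params
      sp$hybridisation_rate[2] <- m_rate
      sp$sample_size <- c(40L, 20L, 10L)
      cfg <- panel_config(n_candidate_loci = 600L, n_panel_loci = 60L,
                          focal_species = "focal", species_params = sp,
                          hybrids = NULL, seed = sd)
      study <- simulate_panel(cfg)
      length(suppressMessages(polymorphic_loci(study$matrix, "near"))) / 60
    }, numeric(1))
  }
  seeds <- 1:20
  means <- vapply(c(0, 0.01, 0.1), function(m) mean(share_at_m(m, seeds)),
                  numeric(1))
  expect_true(all(diff(means) > 0))

  # with zero missingness, sample frequencies are unbiased for the truth
  sp <- small_panel_config()$species_params
  sp$missingness <- 0
  sp$sample_size <- c(60L, 30L, 30L)
  cfg <- panel_config(n_candidate_loci = 800L, n_panel_loci = 100L,
                      focal_species = "focal", species_params = sp,
                      hybrids = NULL, seed = 17)
  study <- simulate_panel(cfg)
  idx <- match(study$panel, sprintf("L%04d", seq_len(cfg$n_candidate_loci)))
  truth_f <- study$truth$terminal["near", idx]
  gm <- study$matrix$genotypes[study$matrix$species == "near", ]
  sample_f <- colMeans(gm) / 2
  expect_lt(abs(mean(sample_f - truth_f)), 0.01)
})
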