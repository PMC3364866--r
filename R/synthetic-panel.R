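# Synthetic genotype panels: a SNP set ascertained in one focal species and
# typed across several diverged, hybridising species.
#
# Everything here is synthetic — the generator emulates the statistical
# structure of a focal-species SNP panel (ascertainment bias, small
# cross-species samples, species-specific missingness, optional F1 hybrids)
# so the whole analysis pipeline is testable without any external data.

#' Synthetic panel configuration
#'
#' Describes a synthetic study: candidate loci with ancestral minor-allele
#' frequencies, a star-shaped species history (each non-focal species
#' diverges from the focal lineage and keeps receiving migrants from it at
#' a species-specific hybridisation rate), a finite focal discovery sample
#' that ascertains the SNP panel, and per-species genotyping sample sizes
#' and missingness.
#'
#' The default configuration mirrors the duck study shape: a 364-locus
#' panel ascertained in the focal species, six species sampled at
#' 197/7/9/14/10/17 individuals, missingness 4\% in the focal species and
#' 14-24\% in the others, and one F1 hybrid between the focal species and
#' its closest relative. Drift is simulated at desk-scale diploid sizes
#' (hundreds, not millions); the closed-form calculus, linear in Ne,
#' carries results to realistic population sizes.
#'
#' @param n_candidate_loci candidate loci drawn before ascertainment.
#' @param n_panel_loci panel size after ascertainment.
#' @param focal_species label of the ascertainment species.
#' @param ascertainment_sample_size focal individuals in the discovery
#'   sample.
#' @param maf_range range of the uniform ancestral minor-allele-frequency
#'   distribution.
#' @param species_params data.frame with one row per species: columns
#'   \code{species}, \code{diploid_size}, \code{divergence_generations}
#'   (0 for the focal species), \code{hybridisation_rate} (gene flow from
#'   the focal lineage, 0 for the focal species), \code{sample_size},
#'   \code{missingness}.
#' @param hybrids data.frame of F1 individuals with columns \code{parent1},
#'   \code{parent2} (distinct species in \code{species_params}); NULL for
#'   none.
#' @param seed integer seed.
#' @return an object of class \code{panel_config}.
#' @export
panel_config <- function(n_candidate_loci = 8000L,
                         n_panel_loci = 364L,
                         focal_species = "platyrhynchos",
                         ascertainment_sample_size = 24L,
                         maf_range = c(0.05, 0.5),
                         species_params = NULL,
                         hybrids = data.frame(parent1 = "platyrhynchos",
                                              parent2 = "acuta",
                                              stringsAsFactors = FALSE),
                         seed = 1L) {
  if (is.null(species_params))
    # Desk-scale mirror of the duck system: effective sizes and divergence
    # times both scaled down by 1e4 (Ne 1.9e6 -> N 190, 6.4 My -> 640
    # generations), which preserves each species' drift intensity
    # (divergence measured in units of N). Hybridisation rates reflect the
    # qualitative gradient mallard > acuta/crecca > penelope/strepera >
    # fuligula; the study quantifies no rate.
    species_params <- data.frame(
      species = c("platyrhynchos", "acuta", "crecca", "penelope",
                  "strepera", "fuligula"),
      diploid_size = c(190L, 54L, 69L, 33L, 38L, 29L),
      divergence_generations = c(0L, 640L, 640L, 800L, 800L, 800L),
      hybridisation_rate = c(0, 0.002, 0.002, 0.0005, 0.0005, 0.0001),
      sample_size = c(197L, 7L, 9L, 14L, 10L, 17L),
      missingness = c(0.04, 0.14, 0.16, 0.20, 0.18, 0.24),
      stringsAsFactors = FALSE
    )
  stopifnot(is.data.frame(species_params),
            all(c("species", "diploid_size", "divergence_generations",
                  "hybridisation_rate", "sample_size", "missingness") %in%
                  names(species_params)),
            !anyDuplicated(species_params$species),
            focal_species %in% species_params$species,
            n_candidate_loci >= n_panel_loci,
            ascertainment_sample_size >= 1,
            all(species_params$sample_size >= 1),
            all(species_params$missingness >= 0),
            all(species_params$missingness < 1),
            all(species_params$hybridisation_rate >= 0),
            all(species_params$hybridisation_rate <= 0.5),
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (!is.null(hybrids)) {
    stopifnot(is.data.frame(hybrids),
              all(c("parent1", "parent2") %in% names(hybrids)),
              all(unlist(hybrids[c("parent1", "parent2")]) %in%
                    species_params$species),
              all(hybrids$parent1 != hybrids$parent2))
  }
  structure(list(n_candidate_loci = as.integer(n_candidate_loci),
                 n_panel_loci = as.integer(n_panel_loci),
                 focal_species = focal_species,
                 ascertainment_sample_size = as.integer(ascertainment_sample_size),
                 maf_range = maf_range,
                 species_params = species_params,
                 hybrids = hybrids,
                 seed = as.integer(seed)),
            class = "panel_config")
}

#' Evolve candidate-locus frequencies along the species history
#'
#' Draws ancestral minor-allele frequencies uniformly from
#' \code{maf_range} (the minor allele is assigned to the alternate allele
#' with probability 1/2), then evolves each species' alternate-allele
#' frequency by Wright-Fisher resampling for its divergence duration. The
#' focal lineage drifts on its own; each other species' gamete pool mixes
#' in a fraction m of the focal lineage's contemporary frequency each
#' generation (star topology with one-way gene flow from the abundant
#' focal species).
#'
#' @param config a \code{\link{panel_config}}.
#' @return an object of class \code{synthetic_truth}: a list with
#'   \code{ancestral} (alternate-allele frequencies), \code{terminal}
#'   (species x loci frequency matrix), \code{polymorphic} (species x loci
#'   logical: 0 < frequency < 1 at the population level) and the config.
#' @export
evolve_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  sp <- config$species_params
  n_loci <- config$n_candidate_loci
  maf <- runif(n_loci, config$maf_range[1], config$maf_range[2])
  flip <- runif(n_loci) < 0.5
  ancestral <- ifelse(flip, 1 - maf, maf)
  max_dur <- max(sp$divergence_generations)
  # Focal lineage drifts from the root (max divergence ago) to the present;
  # its per-generation path is kept so branching species can (a) start from
  # the focal state at their split time and (b) draw migrants from the
  # contemporary focal frequency. Row g+1 is the state g generations after
  # the root, so row max_dur+1 is the present.
  focal_n <- sp$diploid_size[sp$species == config$focal_species]
  two_nf <- 2L * focal_n
  focal_path <- matrix(NA_real_, nrow = max_dur + 1L, ncol = n_loci)
  focal_path[1L, ] <- ancestral
  f <- ancestral
  if (max_dur > 0) for (g in seq_len(max_dur)) {
    f <- rbinom(n_loci, two_nf, f) / two_nf
    focal_path[g + 1L, ] <- f
  }
  terminal <- matrix(NA_real_, nrow = nrow(sp), ncol = n_loci,
                     dimnames = list(sp$species, NULL))
  terminal[config$focal_species, ] <- focal_path[max_dur + 1L, ]
  for (i in seq_len(nrow(sp))) {
    if (sp$species[i] == config$focal_species) next
    dur <- sp$divergence_generations[i]
    split_row <- max_dur - dur + 1L          # focal state at the split
    two_n <- 2L * sp$diploid_size[i]
    m <- sp$hybridisation_rate[i]
    f <- focal_path[split_row, ]
    if (dur > 0) for (g in seq_len(dur)) {
      pool <- (1 - m) * f + m * focal_path[split_row + g, ]
      f <- rbinom(n_loci, two_n, pool) / two_n
    }
    terminal[i, ] <- f
  }
  structure(list(ancestral = ancestral,
                 terminal = terminal,
                 polymorphic = terminal > 0 & terminal < 1,
                 config = config),
            class = "synthetic_truth")
}

#' Ascertain a SNP panel in the focal species
#'
#' Draws Hardy-Weinberg genotypes for a finite focal discovery sample and
#' retains only candidate loci at which both alleles were observed — the
#' mechanism that gives real SNP panels their ascertainment bias towards
#' high minor-allele frequencies in the focal species. The requested panel
#' size is then sampled from the retained loci.
#'
#' @param truth a \code{\link{evolve_panel}} result.
#' @param config the same \code{\link{panel_config}}.
#' @return character vector of retained locus ids (length
#'   \code{n_panel_loci}), with the discovery-sample polymorphic loci as
#'   attribute \code{"discovered"}.
#' @export
ascertain_loci <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(config$seed + 1L)
  f <- truth$terminal[config$focal_species, ]
  n <- config$ascertainment_sample_size
  alt_copies <- rbinom(length(f), 2L * n, f)
  discovered <- which(alt_copies > 0L & alt_copies < 2L * n)
  if (length(discovered) < config$n_panel_loci)
    stop(sprintf(paste0("cannot reach the requested panel size: %d loci ",
                        "requested but only %d of %d candidates are ",
                        "polymorphic in the discovery sample"),
                 config$n_panel_loci, length(discovered),
                 config$n_candidate_loci))
  panel <- sort(sample(discovered, config$n_panel_loci))
  ids <- locus_id(panel)
  attr(ids, "discovered") <- locus_id(discovered)
  ids
}

locus_id <- function(i) sprintf("L%04d", i)

#' Sample genotypes for the ascertained panel
#'
#' Draws each individual's genotype at each panel locus binomially from its
#' species' terminal frequency under Hardy-Weinberg proportions, then
#' injects missing calls independently at the species' missingness rate.
#' F1 hybrids receive one allele from each parent species' frequency and
#' the smaller of the parents' missingness rates.
#'
#' @param truth a \code{\link{evolve_panel}} result.
#' @param panel locus ids from \code{\link{ascertain_loci}}.
#' @param config the same \code{\link{panel_config}}.
#' @return a \code{\link{genotype_matrix}}; hybrid individuals carry the
#'   species label \code{"<parent1>_x_<parent2>"} and locality
#'   \code{"synthetic"}.
#' @export
sample_genotypes <- function(truth, panel, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(config$seed + 2L)
  sp <- config$species_params
  idx <- match(panel, locus_id(seq_len(config$n_candidate_loci)))
  stopifnot(!anyNA(idx))
  n_loci <- length(idx)
  blocks <- list(); species_lab <- character(0)
  for (i in seq_len(nrow(sp))) {
    f <- truth$terminal[sp$species[i], idx]
    ns <- sp$sample_size[i]
    g <- matrix(rbinom(ns * n_loci, 2L, rep(f, each = ns)),
                nrow = ns, ncol = n_loci)
    miss <- matrix(runif(ns * n_loci) < sp$missingness[i], nrow = ns)
    g[miss] <- NA_integer_
    rownames(g) <- sprintf("%s_%03d", toupper(substr(sp$species[i], 1, 4)),
                           seq_len(ns))
    blocks[[length(blocks) + 1L]] <- g
    species_lab <- c(species_lab, rep(sp$species[i], ns))
  }
  if (!is.null(config$hybrids) && nrow(config$hybrids) > 0) {
    for (j in seq_len(nrow(config$hybrids))) {
      p1 <- config$hybrids$parent1[j]; p2 <- config$hybrids$parent2[j]
      a1 <- rbinom(n_loci, 1L, truth$terminal[p1, idx])
      a2 <- rbinom(n_loci, 1L, truth$terminal[p2, idx])
      g <- matrix(a1 + a2, nrow = 1L)
      mrate <- min(sp$missingness[sp$species %in% c(p1, p2)])
      g[runif(n_loci) < mrate] <- NA_integer_
      rownames(g) <- sprintf("HYB%s%s_%02d", toupper(substr(p1, 1, 2)),
                             toupper(substr(p2, 1, 2)), j)
      blocks[[length(blocks) + 1L]] <- g
      species_lab <- c(species_lab, paste0(p1, "_x_", p2))
    }
  }
  geno <- do.call(rbind, blocks)
  colnames(geno) <- panel
  genotype_matrix(geno, species = species_lab,
                  locality = rep("synthetic", nrow(geno)))
}

#' Generate a full synthetic study panel
#'
#' Convenience wrapper: \code{\link{evolve_panel}} then
#' \code{\link{ascertain_loci}} then \code{\link{sample_genotypes}}.
#'
#' @param config a \code{\link{panel_config}}.
#' @return a list with \code{matrix} (the \code{\link{genotype_matrix}}),
#'   \code{truth}, \code{panel} (locus ids) and \code{config}.
#' @examples
#' \donttest{
#' study <- simulate_panel(panel_config(seed = 7))
#' print(study$matrix)
#' }
#' @export
simulate_panel <- function(config = panel_config()) {
  truth <- evolve_panel(config)
  panel <- ascertain_loci(truth, config)
  mat <- sample_genotypes(truth, panel, config)
  list(matrix = mat, truth = truth, panel = panel, config = config)
}

#' Write synthetic truth tables
#'
#' Writes the terminal frequencies and population-level polymorphic flags
#' as TSV for parameter-recovery tests.
#'
#' @param truth a \code{\link{evolve_panel}} result.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_truth_table <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  df <- data.frame(locus_id = locus_id(seq_along(truth$ancestral)),
                   ancestral = truth$ancestral,
                   t(truth$terminal), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
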