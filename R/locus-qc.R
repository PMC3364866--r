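# Per-locus, per-group QC: allele frequencies, heterozygosity, missingness,
# exact Hardy-Weinberg testing.

#' Exact Hardy-Weinberg test for a biallelic locus
#'
#' Exact conditional test of Hardy-Weinberg proportions from genotype counts
#' at a biallelic locus. Conditional on the observed allele counts, the
#' heterozygote count h under HWE follows
#' \deqn{P(h) = \frac{n!\, 2^h}{n_{AA}!\, h!\, n_{aa}!} \bigg/ \binom{2n}{n_A},}
#' and the two-sided p-value sums P(h') over all attainable h' with
#' P(h') <= P(h_obs) (probability-ordering convention, the analogue of
#' Fisher's exact test). All compatible heterozygote counts are enumerated,
#' so the p-value is deterministic — no Markov-chain noise.
#'
#' @param n_hom_ref count of homozygous-reference individuals.
#' @param n_het count of heterozygous individuals.
#' @param n_hom_alt count of homozygous-alternate individuals.
#' @return p-value in (0, 1]. A monomorphic sample (one allele absent) has a
#'   single attainable configuration and returns 1.
#' @examples
#' hwe_exact_test(3, 5, 2)
#' hwe_exact_test(10, 0, 0) # monomorphic: 1
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0L) stop("all genotype counts are zero")
  n_a <- 2 * n_hom_alt + n_het          # minor-or-major alt allele copies
  n_rare <- min(n_a, 2 * n - n_a)
  if (n_rare == 0) return(1.0)           # monomorphic: single configuration
  # attainable heterozygote counts share the parity of the rare-allele count
  h <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- lfactorial(n) + h * log(2) -
    lfactorial((n_rare - h) / 2) - lfactorial(h) -
    lfactorial(n - (n_rare + h) / 2) -
    (lfactorial(2 * n) - lfactorial(n_rare) - lfactorial(2 * n - n_rare))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, h)]
  if (is.na(obs)) stop("internal error: observed configuration not attainable")
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

allele_counts <- function(geno_col) {
  g <- geno_col[!is.na(geno_col)]
  n_ref <- 2 * sum(g == 0L) + sum(g == 1L)
  n_alt <- 2 * sum(g == 2L) + sum(g == 1L)
  c(ref = n_ref, alt = n_alt)
}

#' Per-locus QC summary for one group
#'
#' For every locus, computes over the group's non-missing genotypes: the
#' number of called individuals, the minor-allele frequency, the observed
#' heterozygote fraction, the missing fraction, the exact Hardy-Weinberg
#' p-value (\code{\link{hwe_exact_test}}) and a polymorphic flag (both
#' alleles observed). Loci with no called individuals get NA statistics.
#'
#' @param x a \code{\link{genotype_matrix}}.
#' @param group a species label present in \code{x} (or, with
#'   \code{by = "locality"}, a locality label).
#' @param by grouping field, \code{"species"} (default) or \code{"locality"}.
#' @return data.frame with one row per locus: \code{locus_id},
#'   \code{group}, \code{n_called}, \code{maf}, \code{h_obs},
#'   \code{missing_fraction}, \code{hwe_p}, \code{polymorphic}.
#' @export
summarize_locus <- function(x, group, by = c("species", "locality")) {
  stopifnot(inherits(x, "genotype_matrix"))
  by <- match.arg(by)
  labels <- x[[by]]
  if (!group %in% labels) stop("unknown ", by, " label: ", group)
  g <- x$genotypes[labels == group, , drop = FALSE]
  n_ind <- nrow(g)
  res <- lapply(colnames(g), function(loc) {
    col <- g[, loc]
    n_called <- sum(!is.na(col))
    if (n_called == 0L)
      return(data.frame(locus_id = loc, group = group, n_called = 0L,
                        maf = NA_real_, h_obs = NA_real_,
                        missing_fraction = 1, hwe_p = NA_real_,
                        polymorphic = NA, stringsAsFactors = FALSE))
    ac <- allele_counts(col)
    n0 <- sum(col == 0L, na.rm = TRUE)
    n1 <- sum(col == 1L, na.rm = TRUE)
    n2 <- sum(col == 2L, na.rm = TRUE)
    data.frame(locus_id = loc, group = group, n_called = n_called,
               maf = min(ac) / (2 * n_called),
               h_obs = n1 / n_called,
               missing_fraction = 1 - n_called / n_ind,
               hwe_p = hwe_exact_test(n0, n1, n2),
               polymorphic = all(ac > 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Loci polymorphic in a species' sample
#'
#' A locus counts as polymorphic in a species when both alleles are observed
#' among that species' non-missing genotypes (sample minor-allele frequency
#' > 0); no frequency floor is applied. Loci with all genotypes missing in
#' the species are excluded with a message.
#'
#' @param x a \code{\link{genotype_matrix}}.
#' @param species a species label present in \code{x}.
#' @return character vector of locus ids.
#' @export
polymorphic_loci <- function(x, species) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (!species %in% x$species) stop("unknown species: ", species)
  g <- x$genotypes[x$species == species, , drop = FALSE]
  all_missing <- colSums(!is.na(g)) == 0L
  if (any(all_missing))
    message(sum(all_missing), " locus/loci with no called genotypes in '",
            species, "' excluded")
  poly <- vapply(colnames(g), function(loc) {
    ac <- allele_counts(g[, loc])
    all(ac > 0)
  }, logical(1))
  colnames(g)[poly & !all_missing]
}
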