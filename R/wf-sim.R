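# Forward-time Wright-Fisher simulation and exact Markov-chain validation.
#
# Time unit: one Wright-Fisher generation. The diploid size N here plays the
# role of the effective size Ne in the closed-form persistence calculus;
# linearity of t(p) in Ne bridges desk-scale simulations (N <= a few hundred)
# to the million-scale populations of the closed form.

#' Wright-Fisher run configuration
#'
#' @param diploid_size diploid population size N (>= 1); each generation
#'   resamples 2N allele copies binomially.
#' @param initial_frequency starting allele frequency in [0, 1]; realised as
#'   the nearest whole allele count.
#' @param max_generations generations to simulate before giving up on a
#'   replicate; default 40 N (far beyond the mean absorption time 4 N ln 2
#'   for p = 0.5, so unabsorbed replicates are rare).
#' @param replicates number of independent replicate loci.
#' @param seed integer seed; every run is deterministic given the seed.
#' @return an object of class \code{wf_config}.
#' @export
wf_config <- function(diploid_size, initial_frequency = 0.5,
                      max_generations = 40 * diploid_size,
                      replicates = 1000L, seed = 1L) {
  stopifnot(diploid_size >= 1, diploid_size == round(diploid_size),
            replicates >= 1, max_generations >= 1)
  if (initial_frequency < 0 || initial_frequency > 1)
    stop("initial_frequency must lie in [0, 1]")
  structure(list(diploid_size = as.integer(diploid_size),
                 initial_frequency = initial_frequency,
                 max_generations = as.integer(max_generations),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "wf_config")
}

# Core engine: evolve a vector of allele counts one generation.
wf_step <- function(counts, two_n) {
  active <- counts > 0L & counts < two_n
  if (any(active))
    counts[active] <- rbinom(sum(active), two_n, counts[active] / two_n)
  counts
}

#' Simulate neutral absorption times
#'
#' Runs \code{replicates} independent Wright-Fisher loci from the same
#' initial frequency until loss, fixation, or \code{max_generations}.
#' Replicates are advanced in a single vectorised stream, so results do not
#' depend on replicate order. Unabsorbed replicates are reported separately
#' and never counted into the mean absorption time.
#'
#' @param config a \code{\link{wf_config}}.
#' @param checkpoints optional generation numbers at which to record the
#'   fraction of replicates still segregating.
#' @return an object of class \code{absorption_stats}: a list with
#'   \code{mean_absorption_time} (generations, over absorbed replicates),
#'   \code{standard_error}, \code{fixation_fraction}, \code{loss_fraction},
#'   \code{unabsorbed_fraction}, \code{final_mean_frequency} and, if
#'   checkpoints were given, \code{segregating_fraction_at}.
#' @examples
#' simulate_absorption(wf_config(10, 0.5, replicates = 500, seed = 42))
#' @export
simulate_absorption <- function(config, checkpoints = NULL) {
  stopifnot(inherits(config, "wf_config"))
  if (!is.null(checkpoints))
    stopifnot(all(checkpoints >= 0), all(checkpoints <= config$max_generations))
  set.seed(config$seed)
  two_n <- 2L * config$diploid_size
  reps <- config$replicates
  counts <- rep(as.integer(round(config$initial_frequency * two_n)), reps)
  absorbed_at <- ifelse(counts == 0L | counts == two_n, 0L, NA_integer_)
  seg_at <- if (is.null(checkpoints)) NULL else
    setNames(numeric(length(checkpoints)), checkpoints)
  if (!is.null(seg_at) && any(checkpoints == 0))
    seg_at[checkpoints == 0] <- mean(counts > 0L & counts < two_n)
  for (g in seq_len(config$max_generations)) {
    if (all(!is.na(absorbed_at))) {
      if (!is.null(seg_at)) seg_at[checkpoints >= g] <- 0
      break
    }
    counts <- wf_step(counts, two_n)
    newly <- is.na(absorbed_at) & (counts == 0L | counts == two_n)
    absorbed_at[newly] <- g
    if (!is.null(seg_at) && g %in% checkpoints)
      seg_at[match(g, checkpoints)] <- mean(counts > 0L & counts < two_n)
  }
  times <- absorbed_at[!is.na(absorbed_at)]
  fixed <- counts == two_n
  lost <- counts == 0L
  structure(list(
    config = config,
    mean_absorption_time = if (length(times)) mean(times) else NA_real_,
    standard_error = if (length(times) > 1)
      stats::sd(times) / sqrt(length(times)) else NA_real_,
    fixation_fraction = mean(fixed),
    loss_fraction = mean(lost),
    unabsorbed_fraction = mean(!fixed & !lost),
    final_mean_frequency = mean(counts) / two_n,
    segregating_fraction_at = seg_at
  ), class = "absorption_stats")
}

#' @export
print.absorption_stats <- function(x, ...) {
  cat(sprintf(paste0("absorption_stats: N = %d, p0 = %.3f, %d replicates\n",
                     "  mean absorption time %.2f generations (SE %.3f)\n",
                     "  fixed %.3f, lost %.3f, unabsorbed at %d generations: %.4f\n"),
              x$config$diploid_size, x$config$initial_frequency,
              x$config$replicates, x$mean_absorption_time, x$standard_error,
              x$fixation_fraction, x$loss_fraction,
              x$config$max_generations, x$unabsorbed_fraction))
  invisible(x)
}

#' Exact Markov-chain absorption oracle
#'
#' Builds the full (2N+1)-state binomial transition matrix of the neutral
#' Wright-Fisher chain and solves the linear system (I - Q) t = 1 for the
#' exact expected absorption time from every transient state, and
#' (I - Q) b = R_fix for the exact fixation probabilities. Feasible for
#' 2N up to a few hundred (dense linear algebra).
#'
#' @param diploid_size diploid size N with 2N <= 400.
#' @param initial_count optional allele-copy count (0..2N); if supplied, the
#'   scalar expectations for that start are returned alongside the vectors.
#' @return a list with \code{expected_time} (named vector over transient
#'   states 1..2N-1), \code{fixation_prob}, and if \code{initial_count} is
#'   given, \code{time_from_start} and \code{fix_from_start} (both 0 for an
#'   absorbing start).
#' @examples
#' markov_absorption_oracle(1, initial_count = 1)$time_from_start # exactly 2
#' @export
markov_absorption_oracle <- function(diploid_size, initial_count = NULL) {
  stopifnot(diploid_size >= 1, diploid_size == round(diploid_size))
  two_n <- 2L * diploid_size
  if (two_n > 400) stop("state space too large: 2N must be <= 400")
  states <- 0:two_n
  P <- outer(states, states,
             function(i, j) dbinom(j, two_n, i / two_n))
  trans <- 2:two_n                       # transient states 1..2N-1 (1-based idx)
  Q <- P[trans, trans, drop = FALSE]
  iq <- diag(length(trans)) - Q
  t_exp <- solve(iq, rep(1, length(trans)))
  b_fix <- solve(iq, P[trans, two_n + 1L])
  names(t_exp) <- names(b_fix) <- states[trans]
  out <- list(diploid_size = diploid_size,
              expected_time = t_exp, fixation_prob = b_fix)
  if (!is.null(initial_count)) {
    stopifnot(initial_count >= 0, initial_count <= two_n)
    if (initial_count == 0L || initial_count == two_n) {
      out$time_from_start <- 0
      out$fix_from_start <- as.numeric(initial_count == two_n)
    } else {
      out$time_from_start <- unname(t_exp[as.character(initial_count)])
      out$fix_from_start <- unname(b_fix[as.character(initial_count)])
    }
  }
  out
}

#' Exact probability of still segregating after g generations
#'
#' Computes P(0 < X_g < 2N | X_0 = initial_count) for the neutral
#' Wright-Fisher chain by repeated multiplication with the transient-state
#' transition matrix (exact, no simulation).
#'
#' @param diploid_size diploid size N with 2N <= 400.
#' @param initial_count starting allele-copy count (0..2N).
#' @param generations vector of non-negative generation numbers.
#' @return named numeric vector of exact segregation probabilities.
#' @examples
#' # retention of a balanced polymorphism at the 3.8 N threshold:
#' oracle_segregating_prob(50, 50, round(3.8 * 50))
#' @export
oracle_segregating_prob <- function(diploid_size, initial_count, generations) {
  stopifnot(diploid_size >= 1, all(generations >= 0),
            all(generations == round(generations)))
  two_n <- 2L * diploid_size
  if (two_n > 400) stop("state space too large: 2N must be <= 400")
  stopifnot(initial_count >= 0, initial_count <= two_n)
  gen_sorted <- sort(unique(as.integer(generations)))
  out <- setNames(numeric(length(gen_sorted)), gen_sorted)
  if (initial_count == 0L || initial_count == two_n) {
    return(setNames(out[as.character(generations)], generations))  # all zero
  }
  states <- 0:two_n
  P <- outer(states, states, function(i, j) dbinom(j, two_n, i / two_n))
  Q <- P[2:two_n, 2:two_n, drop = FALSE]
  v <- numeric(two_n - 1L)
  v[initial_count] <- 1
  g_cur <- 0L
  for (g in gen_sorted) {
    while (g_cur < g) {
      v <- as.numeric(v %*% Q)
      g_cur <- g_cur + 1L
    }
    out[as.character(g)] <- sum(v)
  }
  setNames(out[as.character(generations)], generations)
}

#' Segregating fraction at checkpoint generations
#'
#' Simulated fraction of replicate loci still segregating (0 < frequency
#' < 1) at each checkpoint, with exact binomial 95\% confidence intervals.
#'
#' @param config a \code{\link{wf_config}}.
#' @param checkpoints generation numbers, each <= \code{max_generations}.
#' @return data.frame with columns \code{generation}, \code{fraction},
#'   \code{lower}, \code{upper}.
#' @export
segregating_fraction <- function(config, checkpoints) {
  stopifnot(inherits(config, "wf_config"),
            all(checkpoints <= config$max_generations))
  res <- simulate_absorption(config, checkpoints = checkpoints)
  frac <- res$segregating_fraction_at
  ci <- t(vapply(frac, function(f) {
    k <- round(f * config$replicates)
    as.numeric(stats::binom.test(k, config$replicates)$conf.int)
  }, numeric(2)))
  data.frame(generation = as.integer(names(frac)),
             fraction = as.numeric(frac),
             lower = ci[, 1], upper = ci[, 2])
}

#' Two-population gene-flow configuration
#'
#' @param pop_sizes diploid sizes of the two populations.
#' @param hybridisation_rate per-generation fraction m (0 <= m <= 0.5) of
#'   each population's gamete pool drawn from the other population;
#'   m = 0.5 makes the two gamete pools identical (complete mixing).
#' @param duration generations to simulate.
#' @param n_loci number of independent loci.
#' @param initial_frequency common ancestral frequency per locus: a scalar
#'   or a vector of length \code{n_loci}.
#' @param seed integer seed.
#' @return an object of class \code{gene_flow_config}.
#' @export
gene_flow_config <- function(pop_sizes, hybridisation_rate = 0,
                             duration, n_loci = 1000L,
                             initial_frequency = 0.5, seed = 1L) {
  stopifnot(length(pop_sizes) == 2L, all(pop_sizes >= 1),
            all(pop_sizes == round(pop_sizes)),
            hybridisation_rate >= 0, hybridisation_rate <= 0.5,
            duration >= 1, n_loci >= 1,
            all(initial_frequency >= 0), all(initial_frequency <= 1),
            length(initial_frequency) %in% c(1L, n_loci))
  structure(list(pop_sizes = as.integer(pop_sizes),
                 hybridisation_rate = hybridisation_rate,
                 duration = as.integer(duration),
                 n_loci = as.integer(n_loci),
                 initial_frequency = initial_frequency,
                 seed = as.integer(seed)),
            class = "gene_flow_config")
}

#' Simulate divergence of two populations with gene flow
#'
#' Two Wright-Fisher populations start from a common ancestral frequency at
#' every locus. Each generation, each population's gamete pool is the
#' mixture (1-m) x own frequency + m x other population's frequency
#' (symmetric gametic migration — the demographic footprint of ongoing
#' interspecific hybridisation with backcrossing), followed by binomial
#' resampling. Tracks the fraction of loci segregating in each population
#' and jointly in both: the joint fraction operationalises "shared
#' polymorphism".
#'
#' @param config a \code{\link{gene_flow_config}}.
#' @param checkpoints generation numbers at which to record fractions;
#'   default: ~25 evenly spaced points plus the final generation.
#' @return an object of class \code{shared_poly_stats}: a data.frame with
#'   columns \code{generation}, \code{seg_pop1}, \code{seg_pop2},
#'   \code{seg_joint}, carrying the config as an attribute.
#' @export
simulate_divergence_with_geneflow <- function(config, checkpoints = NULL) {
  stopifnot(inherits(config, "gene_flow_config"))
  if (is.null(checkpoints)) {
    step <- max(1L, config$duration %/% 25L)
    checkpoints <- unique(c(0L, seq(step, config$duration, by = step),
                            config$duration))
  }
  stopifnot(all(checkpoints >= 0), all(checkpoints <= config$duration))
  set.seed(config$seed)
  two_n1 <- 2L * config$pop_sizes[1]
  two_n2 <- 2L * config$pop_sizes[2]
  m <- config$hybridisation_rate
  f1 <- f2 <- rep_len(config$initial_frequency, config$n_loci)
  rec <- matrix(NA_real_, nrow = length(checkpoints), ncol = 3L,
                dimnames = list(NULL, c("seg_pop1", "seg_pop2", "seg_joint")))
  record <- function(row, f1, f2) {
    s1 <- f1 > 0 & f1 < 1
    s2 <- f2 > 0 & f2 < 1
    rec[row, ] <<- c(mean(s1), mean(s2), mean(s1 & s2))
  }
  cps <- sort(unique(as.integer(checkpoints)))
  if (0L %in% cps) record(match(0L, cps), f1, f2)
  for (g in seq_len(config$duration)) {
    g1 <- (1 - m) * f1 + m * f2
    g2 <- (1 - m) * f2 + m * f1
    f1 <- rbinom(config$n_loci, two_n1, g1) / two_n1
    f2 <- rbinom(config$n_loci, two_n2, g2) / two_n2
    if (g %in% cps) record(match(g, cps), f1, f2)
  }
  out <- data.frame(generation = cps, rec)
  attr(out, "config") <- config
  class(out) <- c("shared_poly_stats", "data.frame")
  out
}
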