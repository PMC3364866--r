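# Cross-species polymorphism-sharing summaries (Venn structure) and
# multiple-testing bookkeeping for pairwise LD tests.

#' Venn-style polymorphism-sharing report
#'
#' Given 2-6 named sets of locus ids (typically the per-species polymorphic
#' loci from \code{\link{polymorphic_loci}}), computes per-set totals and
#' fractions of the panel, every exclusive Venn region count (one per
#' non-empty subset of set names), and the core count of loci present in
#' all sets. Region counts sum to the size of the union; they are invariant
#' to the order the sets are supplied in.
#'
#' @param sets named list of 2-6 character vectors of locus ids.
#' @param panel_size number of loci in the full panel, used for the
#'   per-set fractions; defaults to the size of the union of the sets.
#' @return an object of class \code{sharing_report}: a list with
#'   \code{set_counts}, \code{set_fractions}, \code{regions} (named integer
#'   vector keyed like \code{"A&B"}), \code{core_count}, \code{union_size},
#'   \code{panel_size}.
#' @examples
#' sharing_venn(list(A = c("l1", "l2"), B = c("l2", "l3")), panel_size = 10)
#' @export
sharing_venn <- function(sets, panel_size = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be a named list")
  k <- length(sets)
  if (k < 2L || k > 6L) stop("between 2 and 6 sets required, got ", k)
  if (anyDuplicated(names(sets))) stop("set names must be unique")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  all_loci <- unique(unlist(sets, use.names = FALSE))
  if (is.null(panel_size)) panel_size <- length(all_loci)
  # membership matrix: loci x sets
  member <- vapply(sets, function(s) all_loci %in% s,
                   logical(length(all_loci)))
  if (length(all_loci) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  # region keys use alphabetical name order so they are input-order invariant
  sorted_names <- sort(names(sets))
  pattern <- apply(member, 1L, function(row)
    paste(sort(names(sets)[row]), collapse = "&"))
  keys <- unlist(lapply(seq_len(k), function(m)
    combn(sorted_names, m, paste, collapse = "&", simplify = FALSE)))
  regions <- setNames(integer(length(keys)), keys)
  tab <- table(pattern)
  regions[names(tab)] <- as.integer(tab)
  core_key <- paste(sorted_names, collapse = "&")
  structure(list(
    sets = sets,
    set_counts = vapply(sets, length, integer(1)),
    set_fractions = vapply(sets, length, integer(1)) / panel_size,
    regions = regions,
    core_count = unname(regions[core_key]),
    union_size = length(all_loci),
    panel_size = panel_size
  ), class = "sharing_report")
}

#' @export
print.sharing_report <- function(x, ...) {
  cat(sprintf("sharing_report: %d sets over a %d-locus panel (union %d)\n",
              length(x$sets), x$panel_size, x$union_size))
  for (nm in names(x$set_counts))
    cat(sprintf("  %-24s %4d loci (%.1f%% of panel)\n", nm,
                x$set_counts[[nm]], 100 * x$set_fractions[[nm]]))
  cat(sprintf("  core (all %d sets): %d loci\n", length(x$sets), x$core_count))
  invisible(x)
}

#' Write a sharing report to JSON and TSV
#'
#' @param report a \code{\link{sharing_venn}} result.
#' @param json_path,tsv_path output paths; either may be NULL to skip.
#' @return invisibly, the report.
#' @export
write_sharing_report <- function(report, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(report, "sharing_report"))
  if (!is.null(json_path))
    jsonlite::write_json(
      list(panel_size = report$panel_size, union_size = report$union_size,
           core_count = report$core_count,
           set_counts = as.list(report$set_counts),
           set_fractions = as.list(report$set_fractions),
           regions = as.list(report$regions)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(tsv_path))
    write.table(data.frame(region = names(report$regions),
                           count = as.integer(report$regions)),
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Number of pairwise LD tests for a panel
#'
#' Every unordered pair of loci in a panel is one pairwise
#' linkage-disequilibrium test, so n loci generate n(n-1)/2 tests. This is
#' the count over which the LD significance level is Bonferroni corrected.
#'
#' @param n_loci number of loci, >= 2.
#' @return the number of unordered pairs.
#' @examples
#' pairwise_test_count(364) # 66066
#' @export
pairwise_test_count <- function(n_loci) {
  if (!is.numeric(n_loci) || n_loci != round(n_loci) || n_loci < 2)
    stop("n_loci must be an integer >= 2")
  n_loci * (n_loci - 1) / 2
}

#' Bonferroni-corrected significance level
#'
#' @param alpha nominal significance level.
#' @param n_tests number of tests.
#' @return \code{alpha / n_tests}.
#' @examples
#' bonferroni_alpha(0.05, pairwise_test_count(364))
#' @export
bonferroni_alpha <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha <= 1, n_tests >= 1)
  alpha / n_tests
}
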