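# Genotype-matrix container and file I/O.
#
# Genotype codes: 0 = homozygous reference, 1 = heterozygous,
# 2 = homozygous alternate, NA = missing.

#' Construct a validated genotype matrix
#'
#' The central data container: an individuals-by-loci integer matrix of
#' biallelic genotype codes (0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, NA = missing call) with a species and an
#' optional locality label per individual.
#'
#' @param genotypes integer matrix, individuals in rows (rownames are
#'   individual ids), loci in columns (colnames are locus ids); entries in
#'   \{0, 1, 2, NA\}.
#' @param species character vector of species labels, one per individual.
#' @param locality optional character vector of locality labels.
#' @return an object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(genotypes, species, locality = NULL) {
  if (!is.matrix(genotypes)) stop("genotypes must be a matrix")
  storage.mode(genotypes) <- "integer"
  ids <- rownames(genotypes); loci <- colnames(genotypes)
  if (is.null(ids) || is.null(loci))
    stop("genotypes must carry individual ids (rownames) and locus ids (colnames)")
  if (anyDuplicated(ids)) stop("duplicate individual ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(loci)) stop("duplicate locus ids: ",
                                paste(unique(loci[duplicated(loci)]), collapse = ", "))
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("illegal genotype code %s for individual '%s' at locus '%s' (allowed: 0, 1, 2, NA)",
                 genotypes[w[1], w[2]], ids[w[1]], loci[w[2]]))
  }
  if (length(species) != nrow(genotypes))
    stop("species labels must match the number of individuals")
  if (is.null(locality)) locality <- rep(NA_character_, nrow(genotypes))
  if (length(locality) != nrow(genotypes))
    stop("locality labels must match the number of individuals")
  structure(list(genotypes = genotypes,
                 species = as.character(species),
                 locality = as.character(locality)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci, %d species, %.1f%% missing\n",
              nrow(x$genotypes), ncol(x$genotypes), length(unique(x$species)),
              100 * mean(is.na(x$genotypes))))
  tbl <- table(x$species)
  cat("  ", paste(sprintf("%s (n=%d)", names(tbl), as.integer(tbl)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Read a genotype table
#'
#' Reads the package's genotype TSV dialect: one row per individual; the
#' first three columns are \code{individual_id}, \code{species},
#' \code{locality}; every remaining column is a locus with genotype codes
#' 0/1/2 and missing token \code{NA}. Malformed genotype tokens raise an
#' error naming the offending individual and locus.
#'
#' @param path path to a tab-separated file.
#' @param missing_token token denoting a missing call; default \code{"NA"}.
#' @return a \code{\link{genotype_matrix}}.
#' @seealso \code{\link{write_genotype_table}} for the inverse.
#' @export
read_genotype_table <- function(path, missing_token = "NA") {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stop("ragged rows in ", path, ": lines have ", paste(unique(nf), collapse = ", "),
         " fields")
  df <- read.delim(path, sep = "\t", colClasses = "character",
                   check.names = FALSE, na.strings = NULL, quote = "")
  need <- c("individual_id", "species", "locality")
  if (!all(need %in% names(df)[1:3]))
    stop("first three columns must be: ", paste(need, collapse = ", "))
  loci <- setdiff(names(df), need)
  if (length(loci) == 0L) stop("no locus columns found")
  geno <- as.matrix(df[, loci, drop = FALSE])
  is_missing <- geno == missing_token
  ok <- is_missing | geno %in% c("0", "1", "2")
  if (!all(ok)) {
    w <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable genotype token '%s' for individual '%s' at locus '%s'",
                 geno[w[1], w[2]], df$individual_id[w[1]], loci[w[2]]))
  }
  geno[is_missing] <- NA
  mode(geno) <- "integer"
  rownames(geno) <- df$individual_id
  loc <- df$locality
  loc[loc == missing_token] <- NA
  genotype_matrix(geno, species = df$species, locality = loc)
}

#' Write a genotype table
#'
#' Writes the TSV dialect read by \code{\link{read_genotype_table}};
#' write-then-read reproduces the matrix exactly.
#'
#' @param x a \code{\link{genotype_matrix}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_genotype_table <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  df <- data.frame(individual_id = rownames(x$genotypes),
                   species = x$species, locality = x$locality,
                   x$genotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a biallelic-SNP VCF into a genotype matrix
#'
#' Extracts GT fields from a VCF: \code{0/0} becomes 0, \code{0/1} or
#' \code{1/0} becomes 1, \code{1/1} becomes 2, \code{./.} becomes NA;
#' phased separators (\code{|}) are treated like unphased. Multi-allelic
#' records are skipped with a warning. Species labels come from a sidecar
#' two- or three-column TSV mapping sample to species (and optional
#' locality).
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param species_map path to a TSV with columns \code{sample},
#'   \code{species}, optionally \code{locality}; or a data.frame of the
#'   same shape.
#' @return a \code{\link{genotype_matrix}}.
#' @export
read_vcf <- function(path, species_map) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@gt) == 0L || !"FORMAT" %in% colnames(v@gt))
    stop("VCF has no genotype (GT) data")
  if (!any(grepl("GT", v@gt[, "FORMAT"])))
    stop("VCF FORMAT lacks a GT field")
  bi <- vcfR::is.biallelic(v)
  if (sum(bi) == 0L) stop("no biallelic SNP records in ", path)
  if (any(!bi))
    warning(sum(!bi), " multi-allelic record(s) skipped")
  v <- v[bi, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- v@fix[, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(v@fix[blank, "CHROM"], ":", v@fix[blank, "POS"])
  rownames(gt) <- ids
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  norm <- gsub("|", "/", gt, fixed = TRUE)
  code[norm %in% "0/0"] <- 0L
  code[norm %in% c("0/1", "1/0")] <- 1L
  code[norm %in% "1/1"] <- 2L
  unknown <- !is.na(norm) & !norm %in% c("0/0", "0/1", "1/0", "1/1", "./.")
  if (any(unknown))
    warning(sum(unknown), " unrecognised GT value(s) treated as missing")
  if (is.data.frame(species_map)) {
    sm <- species_map
  } else {
    if (!file.exists(species_map)) stop("species map not found: ", species_map)
    sm <- read.delim(species_map, sep = "\t", colClasses = "character",
                     check.names = FALSE, quote = "")
  }
  if (!all(c("sample", "species") %in% names(sm)))
    stop("species map needs columns 'sample' and 'species'")
  samples <- colnames(code)
  idx <- match(samples, sm$sample)
  if (anyNA(idx))
    stop("samples missing from species map: ",
         paste(samples[is.na(idx)], collapse = ", "))
  loc <- if ("locality" %in% names(sm)) sm$locality[idx] else NULL
  genotype_matrix(t(code), species = sm$species[idx], locality = loc)
}
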