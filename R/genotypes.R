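#' Genotype dosage tables
#'
#' A `genotype_table` holds a clone x marker matrix of alternate-allele
#' dosages (0, 1, 2 or `NA` for a missing call) plus optional marker
#' metadata (chromosome label, 1-based position). It is the substrate for
#' QC, relationship matrices and whole-genome regression.
#'
#' @param dosage numeric matrix, clones in rows (rownames = clone ids),
#'   markers in columns (colnames = marker ids); entries in {0,1,2,NA}.
#' @param marker_meta optional data.frame with columns `marker_id`, `chrom`,
#'   `pos` (integer, 1-based), one row per marker in column order.
#' @return An object of class `genotype_table`: a list with elements
#'   `dosage`, `clone_ids`, `marker_ids`, `marker_meta`.
#' @examples
#' m <- matrix(c(0, 1, 2, 1, 0, 2), nrow = 3,
#'             dimnames = list(c("c1", "c2", "c3"), c("m1", "m2")))
#' gt <- genotype_table(m)
#' dim(gt$dosage)
#' @export
genotype_table <- function(dosage, marker_meta = NULL) {
  if (!is.matrix(dosage) || !is.numeric(dosage))
    hcn_stop("dosage must be a numeric matrix")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    hcn_stop("dosage must have clone ids as rownames and marker ids as colnames")
  clone_ids <- rownames(dosage)
  marker_ids <- colnames(dosage)
  if (anyDuplicated(clone_ids))
    hcn_stop("duplicate clone ids: ",
             paste(unique(clone_ids[duplicated(clone_ids)]), collapse = ", "))
  if (anyDuplicated(marker_ids))
    hcn_stop("duplicate marker ids: ",
             paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  bad <- !is.na(dosage) & !(dosage %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    hcn_stop("invalid dosage value ", dosage[bad][1], " at clone '",
             clone_ids[idx[1]], "', marker '", marker_ids[idx[2]],
             "' (must be 0, 1, 2 or missing)")
  }
  if (!is.null(marker_meta)) {
    stopifnot(is.data.frame(marker_meta))
    if (nrow(marker_meta) != ncol(dosage) ||
        !identical(as.character(marker_meta$marker_id), marker_ids))
      hcn_stop("marker_meta must have one row per marker, in column order")
  }
  structure(list(dosage = dosage, clone_ids = clone_ids,
                 marker_ids = marker_ids, marker_meta = marker_meta),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$clone_ids), "clones x",
      length(x$marker_ids), "markers;",
      sum(is.na(x$dosage)), "missing calls\n")
  if (!is.null(x$marker_meta))
    cat("  chromosomes:", length(unique(x$marker_meta$chrom)), "\n")
  invisible(x)
}

#' Read genotypes from a dosage CSV or a VCF
#'
#' The dosage CSV layout is: first column clone id, header row marker ids,
#' cells in {0,1,2} or empty for a missing call. VCF import (requires the
#' vcfR package) converts biallelic SNP genotypes to alternate-allele
#' dosage; multi-allelic sites are dropped with a logged count.
#'
#' @param path file path.
#' @param format `"dosage_csv"` or `"vcf"`.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("dosage_csv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) hcn_stop("file not found: ", path)
  if (format == "dosage_csv") read_dosage_csv(path) else read_vcf_dosage(path)
}

read_dosage_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character",
                 stringsAsFactors = FALSE)
  if (ncol(df) < 2) hcn_stop("dosage CSV needs a clone id column plus markers")
  clone_ids <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  ok <- matrix(cells %in% c("0", "1", "2", "", "NA"), nrow = nrow(cells))
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    hcn_stop("malformed dosage cell '", cells[!ok][1], "' at row ", idx[1],
             " (clone '", clone_ids[idx[1]], "'), column '",
             colnames(cells)[idx[2]], "'")
  }
  cells[cells %in% c("", "NA")] <- NA
  dosage <- matrix(as.numeric(cells), nrow = nrow(cells),
                   dimnames = list(clone_ids, colnames(cells)))
  genotype_table(dosage)
}

read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    hcn_stop("VCF import requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "." &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  n_drop <- sum(!biallelic)
  if (n_drop > 0)
    hcn_log("dropping ", n_drop, " non-biallelic site(s)", verbose = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  alt_count <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
  }
  dosage <- t(apply(gt, c(1, 2), alt_count))
  marker_ids <- fix[biallelic, "ID"]
  marker_ids[is.na(marker_ids) | marker_ids == "."] <-
    paste0(fix[biallelic, "CHROM"], "_", fix[biallelic, "POS"])[
      is.na(marker_ids) | marker_ids == "."]
  colnames(dosage) <- marker_ids
  meta <- data.frame(marker_id = marker_ids,
                     chrom = fix[biallelic, "CHROM"],
                     pos = as.integer(fix[biallelic, "POS"]),
                     stringsAsFactors = FALSE)
  genotype_table(dosage, marker_meta = meta)
}

#' Write a genotype table as a dosage CSV
#'
#' Round-trips bit-exactly with [read_genotypes()] (format `"dosage_csv"`):
#' missing calls become empty cells.
#'
#' @param geno a [genotype_table()].
#' @param path output file path.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_table"))
  d <- geno$dosage
  out <- data.frame(clone_id = geno$clone_ids,
                    format(d, trim = TRUE), check.names = FALSE,
                    stringsAsFactors = FALSE)
  out[-1][is.na(d)] <- ""
  colnames(out) <- c("clone_id", geno$marker_ids)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## restrict a genotype table to given clones/markers, preserving order given
subset_geno <- function(geno, clones = NULL, markers = NULL) {
  d <- geno$dosage
  if (!is.null(clones)) d <- d[clones, , drop = FALSE]
  if (!is.null(markers)) d <- d[, markers, drop = FALSE]
  meta <- geno$marker_meta
  if (!is.null(meta) && !is.null(markers))
    meta <- meta[match(colnames(d), meta$marker_id), , drop = FALSE]
  genotype_table(d, marker_meta = meta)
}
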