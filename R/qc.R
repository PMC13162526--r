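#' Per-marker allele frequency and call rate
#'
#' Call rate is the non-missing fraction per marker; the allele frequency
#' `p` is the mean dosage over non-missing calls divided by 2, and MAF is
#' `min(p, 1 - p)`. A marker with zero calls gets call rate 0 and `NA` MAF
#' (it fails both filters). Both statistics are invariant to flipping the
#' dosage polarity of a marker.
#'
#' @param geno a [genotype_table()].
#' @return data.frame: `marker_id`, `p`, `maf`, `call_rate`.
#' @export
compute_marker_stats <- function(geno) {
  stopifnot(inherits(geno, "genotype_table"))
  d <- geno$dosage
  if (nrow(d) < 1) hcn_stop("genotype table has no clones")
  n_called <- colSums(!is.na(d))
  call_rate <- n_called / nrow(d)
  p <- ifelse(n_called > 0, colMeans(d, na.rm = TRUE) / 2, NA_real_)
  maf <- pmin(p, 1 - p)
  data.frame(marker_id = geno$marker_ids, p = p, maf = maf,
             call_rate = call_rate, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Filter markers on MAF and call rate
#'
#' Removes markers with minor allele frequency below `maf_min` or call rate
#' below `call_rate_min`; retention therefore uses `>=` on both statistics.
#' Markers failing both are counted under the MAF reason. Errors if no
#' marker survives.
#'
#' @param geno a [genotype_table()].
#' @param maf_min minimum MAF to keep a marker.
#' @param call_rate_min minimum call rate to keep a marker.
#' @return list: `geno` (filtered table), `report` (a `qc_report`).
#' @export
filter_markers <- function(geno, maf_min = 0.05, call_rate_min = 0.80) {
  st <- compute_marker_stats(geno)
  fail_maf <- is.na(st$maf) | st$maf < maf_min
  fail_cr <- st$call_rate < call_rate_min
  keep <- !fail_maf & !fail_cr
  if (!any(keep))
    hcn_stop("no markers survive the MAF/call-rate filters")
  removed_maf <- sum(fail_maf)
  removed_cr <- sum(fail_cr & !fail_maf)      # MAF counted first when both fail
  out <- subset_geno(geno, markers = geno$marker_ids[keep])
  report <- qc_report(stage = "markers",
                      input = ncol(geno$dosage), retained = sum(keep),
                      removed = list(maf = removed_maf, call_rate = removed_cr),
                      thresholds = list(maf_min = maf_min,
                                        call_rate_min = call_rate_min),
                      stats = st)
  hcn_log("markers: ", ncol(geno$dosage), " -> ", sum(keep),
          " (", removed_maf, " by MAF, ", removed_cr, " by call rate)")
  list(geno = out, report = report)
}

#' Filter clones on missing-call fraction
#'
#' Drops clones whose missing fraction strictly exceeds `missing_max`
#' (a clone at exactly the threshold is retained). Errors if no clone
#' survives.
#'
#' @param geno a [genotype_table()].
#' @param missing_max maximum tolerated missing fraction.
#' @return list: `geno` (filtered table), `report` (a `qc_report`).
#' @export
filter_clones <- function(geno, missing_max = 0.20) {
  stopifnot(inherits(geno, "genotype_table"))
  d <- geno$dosage
  miss <- rowMeans(is.na(d))
  keep <- miss <= missing_max
  if (!any(keep)) hcn_stop("no clones survive the missingness filter")
  out <- subset_geno(geno, clones = geno$clone_ids[keep])
  report <- qc_report(stage = "clones",
                      input = nrow(d), retained = sum(keep),
                      removed = list(missing = sum(!keep)),
                      thresholds = list(clone_missing_max = missing_max),
                      stats = data.frame(clone_id = geno$clone_ids,
                                         missing_fraction = miss,
                                         row.names = NULL,
                                         stringsAsFactors = FALSE))
  hcn_log("clones: ", nrow(d), " -> ", sum(keep))
  list(geno = out, report = report)
}

qc_report <- function(stage, input, retained, removed, thresholds, stats) {
  stopifnot(retained + sum(unlist(removed)) == input)
  structure(list(stage = stage, input = input, retained = retained,
                 removed = removed, thresholds = thresholds, stats = stats),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC [", x$stage, "]: ", x$input, " -> ", x$retained, " retained; removed: ",
      paste(names(x$removed), unlist(x$removed), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a QC report as JSON
#' @param report a `qc_report` (from [filter_markers()] or [filter_clones()]).
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(report[c("stage", "input", "retained", "removed",
                                "thresholds")],
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the full marker-then-clone QC pass
#'
#' Single pass, mirroring the reported pipeline: marker filters (MAF, then
#' call rate) followed by the clone missingness filter; no re-iteration.
#'
#' @param geno a [genotype_table()].
#' @param qc list with `maf_min`, `call_rate_min`, `clone_missing_max`
#'   (e.g. the `qc` block of a [run_config()]).
#' @return list: `geno`, `marker_report`, `clone_report`.
#' @export
run_qc <- function(geno, qc = run_config()$qc) {
  mk <- filter_markers(geno, maf_min = qc$maf_min,
                       call_rate_min = qc$call_rate_min)
  cl <- filter_clones(mk$geno, missing_max = qc$clone_missing_max)
  list(geno = cl$geno, marker_report = mk$report, clone_report = cl$report)
}

#' Mean-impute residual missing calls and center dosages
#'
#' Remaining missing calls are replaced by the marker mean dosage `2p`;
#' the centered matrix `Z = dosage - 2p` is the input for the VanRaden
#' relationship matrix and for whole-genome regression. Column means of
#' `Z` are exactly zero.
#'
#' @param geno a [genotype_table()] (post-filter).
#' @param p optional allele frequencies to center with (defaults to
#'   frequencies estimated from the table, e.g. training frequencies when
#'   centering a validation set).
#' @return list: `Z` (centered matrix), `M` (imputed dosages), `p` (allele
#'   frequencies used).
#' @export
impute_and_center <- function(geno, p = NULL) {
  stopifnot(inherits(geno, "genotype_table"))
  M <- geno$dosage
  p_est <- colMeans(M, na.rm = TRUE) / 2
  if (is.null(p)) p <- p_est
  if (length(p) != ncol(M)) hcn_stop("allele frequency vector length mismatch")
  if (anyNA(M)) {
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- (2 * p)[idx[, 2]]
  }
  Z <- sweep(M, 2, 2 * p, `-`)
  list(Z = Z, M = M, p = p)
}

#' Intersect genotype and phenotype clone sets
#'
#' Both outputs are returned in the genotype table's clone order; counts
#' dropped from each side are logged. Errors on an empty intersection.
#'
#' @param geno a [genotype_table()].
#' @param blues a `blue_set` (see [fit_mixed_model()]) or any data.frame
#'   with a `clone_id` column.
#' @return list: `geno`, `blues`, both restricted to the common clones.
#' @export
match_geno_pheno <- function(geno, blues) {
  stopifnot(inherits(geno, "genotype_table"))
  btab <- if (inherits(blues, "blue_set")) blues$blues else blues
  common <- geno$clone_ids[geno$clone_ids %in% btab$clone_id]
  if (!length(common)) hcn_stop("no clones shared between genotypes and phenotypes")
  hcn_log("matched ", length(common), " clones (dropped ",
          length(geno$clone_ids) - length(common), " genotyped, ",
          nrow(btab) - length(common), " phenotyped)")
  btab <- btab[match(common, btab$clone_id), , drop = FALSE]
  rownames(btab) <- NULL
  out_blues <- if (inherits(blues, "blue_set")) {
    blues$blues <- btab
    blues
  } else btab
  list(geno = subset_geno(geno, clones = common), blues = out_blues)
}
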