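#' Plot-level phenotype records
#'
#' A `phenotype_set` is a data.frame of plot-level trial observations with
#' columns `clone_id`, `location`, `year`, `block_id`, `is_check` and up to
#' six ordinal subsample scores `score_1`..`score_6` (picrate readings on a
#' 1-9 scale), plus `plot_mean`, the arithmetic mean of the scores present.
#' The plot mean is the response used for all downstream modelling.
#'
#' @param records data.frame with the columns above (`score_*` columns with
#'   trailing scores optional; `plot_mean` recomputed here).
#' @return data.frame of class `phenotype_set`.
#' @export
phenotype_set <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("clone_id", "location", "year", "block_id", "is_check")
  miss <- setdiff(needed, names(records))
  if (length(miss)) hcn_stop("missing phenotype columns: ", paste(miss, collapse = ", "))
  score_cols <- grep("^score_[1-6]$", names(records), value = TRUE)
  if (!length(score_cols)) hcn_stop("no score_1..score_6 columns present")
  scores <- as.matrix(records[score_cols])
  storage.mode(scores) <- "numeric"
  out_of_range <- !is.na(scores) & (scores < 1 | scores > 9)
  if (any(out_of_range)) {
    idx <- which(out_of_range, arr.ind = TRUE)[1, ]
    hcn_stop("score ", scores[out_of_range][1], " outside [1, 9] at row ",
             idx[1], ", column ", score_cols[idx[2]])
  }
  n_scores <- rowSums(!is.na(scores))
  if (any(n_scores == 0))
    hcn_stop("row(s) without any subsample score: ",
             paste(head(which(n_scores == 0)), collapse = ", "))
  records$plot_mean <- rowMeans(scores, na.rm = TRUE)
  records$is_check <- as.logical(records$is_check)
  class(records) <- c("phenotype_set", "data.frame")
  records
}

#' Read plot-level phenotypes from CSV
#'
#' Expects columns `clone_id`, `location`, `year`, `block_id`, `is_check`,
#' `score_1`..`score_6` (trailing score columns optional). Scores outside
#' \[1, 9\] or rows with no score at all are rejected.
#'
#' @param path file path to the CSV.
#' @return A [phenotype_set()].
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) hcn_stop("file not found: ", path)
  phenotype_set(read.csv(path, stringsAsFactors = FALSE))
}

#' Write plot-level phenotypes to CSV
#' @param pheno a [phenotype_set()].
#' @param path output file path.
#' @export
write_phenotypes <- function(pheno, path) {
  write.csv(as.data.frame(pheno), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat("phenotype_set:", nrow(x), "plots,", length(unique(x$clone_id)),
      "clones,", length(unique(paste(x$location, x$year))), "trial(s)\n")
  invisible(x)
}
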