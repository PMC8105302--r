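#' Gene-by-sample count matrix with paired sample metadata
#'
#' Container for raw integer RNA-seq counts from sorted cell populations,
#' together with the per-sample factors the paired design needs: which mouse
#' each library came from and which population it is
#' (`background`, `young_tuft` or `mature_tuft`).
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All entries must be
#'   non-negative integers.
#' @param sample_meta data.frame with one row per sample and columns
#'   `sample`, `mouse`, `population`; row order must match `colnames(counts)`.
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (integer matrix) and `sample_meta` (data.frame with factor
#'   columns `mouse` and `population`).
#' @export
count_matrix <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in counts")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  req <- c("sample", "mouse", "population")
  if (!all(req %in% names(sample_meta))) {
    stop("sample_meta needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(sample_meta) != ncol(counts)) {
    stop("sample_meta rows must match count columns")
  }
  if (!is.null(colnames(counts)) &&
      !identical(as.character(sample_meta$sample), colnames(counts))) {
    stop("sample_meta$sample must match colnames(counts) in order")
  }
  if (anyNA(sample_meta$mouse) || anyNA(sample_meta$population)) {
    stop("every sample needs a mouse and a population")
  }
  sample_meta$mouse <- factor(sample_meta$mouse)
  sample_meta$population <- factor(sample_meta$population,
                                   levels = tuft_populations())
  if (anyNA(sample_meta$population)) {
    stop("population labels must be among: ",
         paste(tuft_populations(), collapse = ", "))
  }
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "count_matrix")
}

#' The three sorted populations, in maturation order
#'
#' @return character vector `c("background", "young_tuft", "mature_tuft")`.
#' @export
tuft_populations <- function() c("background", "young_tuft", "mature_tuft")

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("populations:", paste(table(x$sample_meta$population), collapse = "/"),
      " mice:", nlevels(x$sample_meta$mouse), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)
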