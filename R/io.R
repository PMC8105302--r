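#' Read a count matrix from TSV files
#'
#' Counts: genes as rows, first column `gene_id`, samples as columns.
#' Metadata: columns `sample`, `mouse`, `population`.
#'
#' @param counts_path,meta_path file paths.
#' @return a [count_matrix()].
#' @export
read_counts_tsv <- function(counts_path, meta_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

#' Write a count matrix to TSV files
#'
#' @param cm a [count_matrix()].
#' @param counts_path,meta_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_counts_tsv <- function(cm, counts_path, meta_path) {
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(tab, counts_path)
  write_tsv(cm$sample_meta, meta_path)
  invisible(c(counts_path, meta_path))
}

#' Read a GMT geneset collection
#'
#' Standard GMT: one set per line — name, description, then tab-separated
#' member ids.
#'
#' @param path GMT file path.
#' @return named list of character vectors of member ids.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write a geneset collection as GMT
#'
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @param descriptions optional per-set description column (defaults to
#'   the set name).
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# deterministic table writers (fixed quoting/precision conventions)
write_tsv <- function(x, path) {
  utils::write.table(format_num_cols(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_csv <- function(x, path) {
  utils::write.table(format_num_cols(x), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# fixed 15-significant-digit rendering so reruns are byte-identical
# regardless of options(scipen/digits)
format_num_cols <- function(x) {
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) {
      x[[j]] <- formatC(x[[j]], digits = 15, format = "g")
    }
  }
  x
}

#' Read a time-lapse track table from CSV
#'
#' Columns: cell_id, organoid_id, time_h, gfp (0/1), mcherry (0/1).
#'
#' @param path CSV path.
#' @return data.frame in long frame-per-row format.
#' @export
read_tracks_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a qPCR Ct table from CSV
#'
#' @param path CSV path.
#' @return data.frame suitable for [ddct_relative_expression()].
#' @export
read_ct_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
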