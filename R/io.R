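#' Read a region x gene expression TSV
#'
#' Expects the layout written by [write_dataset()]: first column region
#' identifiers, remaining columns genes.
#'
#' @param path File path.
#' @return Numeric region x gene matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a subject x connection connectivity TSV
#' @param path File path.
#' @return Numeric subject x connection matrix.
#' @export
read_connectivity_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a network atlas TSV
#'
#' Columns: region_id, region_name, network, hemisphere, homolog_id.
#'
#' @param path File path.
#' @return A `"network_atlas"` data.frame.
#' @export
read_atlas_tsv <- function(path) {
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "region_name", "network", "hemisphere", "homolog_id")
  missing <- setdiff(need, names(atlas))
  if (length(missing)) {
    stop("atlas file lacks column(s): ", paste(missing, collapse = ", "))
  }
  class(atlas) <- c("network_atlas", "data.frame")
  atlas
}

write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a gene list, one identifier per line
#'
#' Plain format suitable as input to external enrichment tools.
#'
#' @param genes Character vector of gene identifiers.
#' @param path File path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
}
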