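#' Read / write expression matrices as TSV
#'
#' Expression TSVs have rows = genes, columns = samples, and a first
#' column `gene_id`.
#'
#' @param path File path.
#' @return `read_expression_tsv`: a named list of [expression_profile()]s.
#' @param profiles List of profiles on a shared gene universe.
#' @export
read_expression_tsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id")
    stop_invalid("expression TSV must start with a gene_id column")
  genes <- tab$gene_id
  out <- lapply(names(tab)[-1], function(s)
    expression_profile(s, setNames(as.numeric(tab[[s]]), genes)))
  names(out) <- names(tab)[-1]
  out
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(profiles, path) {
  genes <- Reduce(intersect, lapply(profiles, function(p) names(p$values)))
  tab <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (p in profiles) tab[[p$sample_id]] <- unname(p$values[genes])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a normal reference as TSV (`gene_id location scale`)
#' @param path File path.
#' @param reference A [normal_reference()].
#' @export
read_reference_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  normal_reference(setNames(tab$location, tab$gene_id),
                   setNames(tab$scale, tab$gene_id),
                   n_tissues = attr(tab, "n_tissues") %||% 2L)
}

#' @rdname read_reference_tsv
#' @export
write_reference_tsv <- function(reference, path) {
  write.table(
    data.frame(gene_id = names(reference$location),
               location = unname(reference$location),
               scale = unname(reference$scale)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then gene ids, tab-separated.
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in lines[nzchar(lines)]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    out[[f[1]]] <- f[-(1:2)]
  }
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a directed network as SIF-style TSV
#'
#' Three tab-separated columns: `source interaction target`.
#'
#' @param path File path.
#' @param network A [ppi_network()].
#' @export
read_sif <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("source", "interaction", "target"))
  ppi_network(tab)
}

#' @rdname read_sif
#' @export
write_sif <- function(network, path) {
  write.table(network$edges[, c("source", "interaction", "target")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write a drug knowledge base as JSON
#' @param path File path.
#' @param kb A `drug_kb`.
#' @export
read_kb_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  drug_kb(as.data.frame(obj$drugs), as.data.frame(obj$targets))
}

#' @rdname read_kb_json
#' @export
write_kb_json <- function(kb, path) {
  jsonlite::write_json(list(drugs = kb$drugs, targets = kb$targets), path,
                       dataframe = "columns", auto_unbox = FALSE)
  invisible(path)
}

#' Write a method-score table as TSV
#' @param scores Method-score data frame.
#' @param path File path.
#' @export
write_method_scores_tsv <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a drug-prediction report (and optional plan) as JSON
#' @param report A `drug_report`.
#' @param path File path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(drugs = report$table, method_scores = report$scores),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
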