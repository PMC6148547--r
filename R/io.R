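# Plain-text readers/writers for the pipeline's exchange formats:
# expression TSV + two-column group file, STRING-style edge TSV, GMT,
# FASTA, clinical TSV, ground-truth JSON.

#' Write / read an expression study as TSV plus a group file
#'
#' @param study an `expression_study`.
#' @param prefix file prefix; writes `<prefix>.tsv` (genes x samples) and
#'   `<prefix>.groups.tsv` (columns `sample`, `group`).
#' @return invisibly, the paths written.
#' @export
write_expression_study <- function(study, prefix) {
  expr_path <- paste0(prefix, ".tsv")
  grp_path <- paste0(prefix, ".groups.tsv")
  utils::write.table(data.frame(gene = rownames(study$values), study$values,
                                check.names = FALSE),
                     expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(study$values),
                                group = as.character(study$group)),
                     grp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expr_path, grp_path))
}

#' @rdname write_expression_study
#' @param log2 whether the stored values are log2 scale.
#' @param study_id,subgroup labels for the reconstructed study.
#' @export
read_expression_study <- function(prefix, log2 = FALSE, study_id = basename(prefix),
                                  subgroup = NA_character_) {
  tab <- utils::read.delim(paste0(prefix, ".tsv"), check.names = FALSE)
  grp <- utils::read.delim(paste0(prefix, ".groups.tsv"))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab[[1]]
  .expression_study(vals, grp$group[match(colnames(vals), grp$sample)],
                    log2 = log2, study_id = study_id, subgroup = subgroup)
}

#' Write / read a STRING-style edge list
#'
#' Tab-separated `node_a`, `node_b`, `score`; on read, scores above 1 are
#' interpreted as the STRING 0-1000 dialect and divided by 1000.
#'
#' @param edges data.frame `node_a`, `node_b`, `score`.
#' @param path file path.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  ed <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(ed)[1:3] <- c("node_a", "node_b", "score")
  if (any(ed$score > 1)) ed$score <- ed$score / 1000
  ed
}

#' Write gene sets as GMT
#'
#' @param sets named list of gene sets.
#' @param path file path; the description field stores the category when a
#'   `categories` attribute is present.
#' @export
write_gmt <- function(sets, path) {
  categories <- attr(sets, "categories")
  lines <- vapply(names(sets), function(id) {
    desc <- if (!is.null(categories) && !is.na(categories[id])) categories[[id]] else "pathway"
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from GMT
#'
#' Parsing goes through `fgsea::gmtPathways`; the description column is
#' recovered separately as the `categories` attribute.
#'
#' @param path GMT file path.
#' @return named list of gene sets with a `categories` attribute.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  categories <- stats::setNames(vapply(fields, `[`, "", 2),
                                vapply(fields, `[`, "", 1))
  attr(sets, "categories") <- categories[names(sets)]
  sets
}

#' Write / read RNA FASTA
#'
#' @param seqs named character vector of RNA sequences.
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- chartr("Tt", "Uu", toupper(as.character(set)))
  stats::setNames(out, names(set))
}
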