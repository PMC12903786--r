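# Readers and writers for the formats the pipeline touches. All
# coordinates are stored 0-based half-open internally; writers restore
# each format's native convention (GFF3 is 1-based inclusive).

#' Read coding sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences (ids from the
#'   first whitespace-delimited token of each header). Errors on an empty
#'   file or duplicated ids.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("format error: empty FASTA file")
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("format error: duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene features from GFF3-lite
#'
#' Parses a tab-separated GFF3 subset: only rows with type \code{gene}
#' are kept (mRNA, exon etc. are skipped), each must carry an \code{ID}
#' attribute and may carry a \code{source_label} attribute tagging the
#' progenitor/scaffold group. GFF3's 1-based inclusive coordinates are
#' converted to 0-based half-open on input.
#'
#' @param path GFF3 file path.
#' @return Data frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{strand},
#'   \code{source_label} (NA when absent).
#' @export
read_gene_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), source_label = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) != 9L
  if (any(bad)) stop("format error: expected 9 tab-separated columns")
  m <- do.call(rbind, fields)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), source_label = character(0)))
  start1 <- as.integer(m[, 4])
  end1 <- as.integer(m[, 5])
  if (any(is.na(start1) | is.na(end1)))
    stop("format error: non-integer coordinates")
  if (any(end1 < start1)) stop("format error: end < start")
  attr_field <- m[, 9]
  get_attr <- function(attrs, key) {
    re <- paste0("(^|;)", key, "=[^;]*")
    pos <- regexpr(re, attrs)
    out <- rep(NA_character_, length(attrs))
    idx <- which(pos > 0)
    if (length(idx))
      out[idx] <- sub(paste0("^;?", key, "="), "",
                      regmatches(attrs, pos))
    out
  }
  ids <- get_attr(attr_field, "ID")
  if (any(is.na(ids))) stop("format error: gene row missing ID attribute")
  src <- get_attr(attr_field, "source_label")
  data.frame(gene_id = ids, chrom = m[, 1],
             start = start1 - 1L, end = end1,
             strand = m[, 7], source_label = src)
}

#' Write gene features to GFF3-lite
#'
#' Restores GFF3's native 1-based inclusive coordinates on output.
#'
#' @param features Data frame as returned by
#'   \code{\link{read_gene_features}}.
#' @param path Output path.
#' @export
write_gene_features <- function(features, path) {
  stopifnot(is.data.frame(features))
  attrs <- paste0("ID=", features$gene_id)
  has_src <- !is.na(features$source_label)
  attrs[has_src] <- paste0(attrs[has_src], ";source_label=",
                           features$source_label[has_src])
  lines <- paste(features$chrom, "allodater", "gene",
                 features$start + 1L, features$end, ".",
                 features$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a collinearity table
#'
#' Minimal TSV dialect for collinear blocks: a header row then one gene
#' pair per row with columns \code{block_id}, \code{gene_a},
#' \code{gene_b}; rows are grouped by block in input order.
#'
#' @param path TSV path.
#' @param features Optional gene feature data frame; when given, every
#'   gene id in the table is validated against it.
#' @return Data frame \code{block_id}, \code{gene_a}, \code{gene_b}.
#' @export
read_collinearity <- function(path, features = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, colClasses = "character")
  if (!all(c("block_id", "gene_a", "gene_b") %in% names(tab)))
    stop("format error: need columns block_id, gene_a, gene_b")
  tab <- tab[, c("block_id", "gene_a", "gene_b")]
  if (nrow(tab) == 0L) warning("collinearity file has no data rows")
  if (!is.null(features)) {
    missing <- setdiff(unique(c(tab$gene_a, tab$gene_b)),
                       features$gene_id)
    if (length(missing) > 0)
      stop("validation error: unknown gene id(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  tab
}

#' Write a collinearity table
#' @param blocks Data frame \code{block_id}, \code{gene_a}, \code{gene_b}.
#' @param path Output path.
#' @export
write_collinearity <- function(blocks, path) {
  utils::write.table(blocks[, c("block_id", "gene_a", "gene_b")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an orthogroup-by-species count matrix
#'
#' TSV with the orthogroup id in the first column and one column per
#' species. All cells must be non-negative integers and the species set
#' must equal the tree's tip labels (order-insensitive).
#'
#' @param path TSV path.
#' @param tree \code{ape::phylo} whose tips define the species set.
#' @return Integer matrix, orthogroups x species.
#' @export
read_count_matrix <- function(path, tree) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE)
  if (ncol(tab) < 2) stop("format error: need id column plus species")
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!setequal(colnames(vals), tree$tip.label))
    stop("validation error: species columns do not match tree tips")
  if (any(is.na(vals)) || any(vals < 0) || any(vals != round(vals)))
    stop("format error: counts must be non-negative integers")
  storage.mode(vals) <- "integer"
  rownames(vals) <- ids
  vals
}

#' Write an orthogroup-by-species count matrix
#' @param counts Integer matrix with orthogroup row names.
#' @param path Output path.
#' @param id_column Name of the first (id) column.
#' @export
write_count_matrix <- function(counts, path, id_column = "orthogroup") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   row.names = NULL)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a divergence-value table
#'
#' TSV with one Kimura percent value per row and a subgenome label
#' column: columns \code{subgenome}, \code{divergence}.
#'
#' @param path TSV path.
#' @return List of \code{"divergence_profile"} objects, one per label.
#' @export
read_divergence_table <- function(path) {
  tab <- utils::read.delim(path)
  if (!all(c("subgenome", "divergence") %in% names(tab)))
    stop("format error: need columns subgenome, divergence")
  sp <- split(tab$divergence, tab$subgenome)
  lapply(stats::setNames(names(sp), names(sp)), function(nm) {
    structure(list(label = nm, values = sp[[nm]]),
              class = "divergence_profile")
  })
}

#' Write divergence profiles to a TSV
#' @param profiles List of \code{"divergence_profile"} objects.
#' @param path Output path.
#' @export
write_divergence_table <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(subgenome = p$label, divergence = p$values)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
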