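#' Construct a homology matrix
#'
#' A homology matrix holds, for each query enzyme (row) and target genome
#' (column), the number of homologues of that enzyme detected in the
#' genome. Virtual pangenome columns created by [aggregate_pangenome()]
#' with the mean rule may carry non-integer values, so cells are stored as
#' non-negative reals.
#'
#' @param counts Numeric matrix with enzyme row names and genome column
#'   names; all cells must be `>= 0`.
#' @param blocks Optional named character vector mapping genome (column)
#'   names to pangenome block labels. When supplied, columns are reordered
#'   by block then genome ID so blocks form contiguous runs.
#' @return An object of class `homology_matrix` (a numeric matrix with a
#'   `blocks` attribute).
#' @export
homology_matrix <- function(counts, blocks = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry enzyme row names and genome column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("row and column labels must be unique", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("homology counts must be non-negative", call. = FALSE)
  }
  if (!is.null(blocks)) {
    bl <- unname(blocks[colnames(counts)]) # NA for unblocked columns
    ord <- order(factor(bl, levels = unique(unname(blocks))),
                 colnames(counts), na.last = TRUE)
    counts <- counts[, ord, drop = FALSE]
    blocks <- blocks[intersect(colnames(counts), names(blocks))]
  }
  structure(counts, blocks = blocks, class = c("homology_matrix", "matrix"))
}

#' @export
print.homology_matrix <- function(x, ...) {
  blocks <- attr(x, "blocks")
  cat(sprintf("homology matrix: %d enzymes x %d genomes (%d cells)\n",
              nrow(x), ncol(x), length(x)))
  if (!is.null(blocks)) {
    cat("blocks:", paste(unique(unname(blocks)), collapse = ", "), "\n")
  }
  print(unclass(structure(x, blocks = NULL)), ...)
  invisible(x)
}

#' Read similarity-search hits in BLAST tabular format
#'
#' Consumes outfmt-6 style tab-separated rows (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore); only the
#' query ID, subject ID and e-value columns are used.
#'
#' @param path Path to the tabular hits file.
#' @return Data frame with columns `query`, `subject`, `evalue`.
#' @export
read_blast_hits <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 11L) {
    stop("expected >= 11 tab-separated columns (BLAST outfmt 6), found ",
         ncol(raw), call. = FALSE)
  }
  data.frame(query = as.character(raw[[1L]]),
             subject = as.character(raw[[2L]]),
             evalue = as.numeric(raw[[11L]]),
             stringsAsFactors = FALSE)
}

#' Count homologues per enzyme and genome
#'
#' Builds the homology matrix from similarity-search hits: cell `[i, j]` is
#' the number of *distinct* subject genes of genome `j` hit by enzyme `i`
#' with e-value at or below the cutoff. Duplicate (query, subject) rows —
#' e.g. multiple HSPs for one gene pair — are collapsed to the best
#' e-value, so genes rather than alignments are counted. Self-hits of a
#' query against its own source genome are counted like any other hit;
#' source genomes thereby act as positive controls.
#'
#' @param hits Data frame with columns `query`, `subject`, `evalue` (see
#'   [read_blast_hits()]).
#' @param gene_to_genome Named character vector mapping subject gene IDs to
#'   genome IDs.
#' @param enzymes Character vector of query enzyme IDs (matrix rows).
#' @param genomes Character vector of target genome IDs (matrix columns).
#' @param evalue_cutoff Positive e-value cutoff; hits with
#'   `evalue <= evalue_cutoff` are counted. Default `1e-6`.
#' @param blocks Optional genome-to-block map, stored on the result.
#' @return A [homology_matrix()] of dimension
#'   `length(enzymes) x length(genomes)`.
#' @export
count_homologues <- function(hits, gene_to_genome, enzymes, genomes,
                             evalue_cutoff = 1e-6, blocks = NULL) {
  stopifnot(is.data.frame(hits),
            all(c("query", "subject", "evalue") %in% names(hits)))
  if (!is.numeric(evalue_cutoff) || length(evalue_cutoff) != 1L ||
      evalue_cutoff <= 0) {
    stop("evalue_cutoff must be a single positive number", call. = FALSE)
  }
  hits <- hits[hits$query %in% enzymes, , drop = FALSE]
  unmapped <- setdiff(unique(hits$subject), names(gene_to_genome))
  if (length(unmapped)) {
    stop("subject gene(s) with no genome mapping: ",
         paste(sort(unmapped), collapse = ", "), call. = FALSE)
  }
  m <- matrix(0, nrow = length(enzymes), ncol = length(genomes),
              dimnames = list(enzymes, genomes))
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(hits)) {
    # best-e-value deduplication of (query, subject) pairs; since every
    # kept pair passes the cutoff, dedup reduces to distinct pairs
    key <- paste(hits$query, hits$subject, sep = "\r")
    hits <- hits[!duplicated(key), , drop = FALSE]
    genome <- gene_to_genome[hits$subject]
    keep <- genome %in% genomes
    tab <- table(factor(hits$query[keep], levels = enzymes),
                 factor(genome[keep], levels = genomes))
    m[] <- as.numeric(tab)
  }
  homology_matrix(m, blocks = blocks)
}

#' Append pangenome "virtual genome" columns
#'
#' For each block of strains, adds one virtual column aggregating the
#' member columns cell-wise. The default `max` approximates a search
#' against the non-redundant union of the strain proteomes without
#' double-counting orthologues shared between strains; `sum` and `mean`
#' are alternative aggregation rules.
#'
#' @param matrix A [homology_matrix()].
#' @param blocks Named character vector mapping (a subset of) column names
#'   to block labels; defaults to the matrix's own `blocks` attribute.
#' @param mode One of `"max"`, `"mean"`, `"sum"`.
#' @param png_names Named character vector block -> virtual column name;
#'   defaults to `"<block>-png"`.
#' @return A `homology_matrix` with one extra column per block.
#' @export
aggregate_pangenome <- function(matrix, blocks = attr(matrix, "blocks"),
                                mode = c("max", "mean", "sum"),
                                png_names = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "homology_matrix"))
  if (is.null(blocks) || !length(blocks)) {
    stop("empty block map", call. = FALSE)
  }
  absent <- setdiff(names(blocks), colnames(matrix))
  if (length(absent)) {
    stop("block members are not matrix columns: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  block_ids <- unique(unname(blocks))
  if (is.null(png_names)) {
    png_names <- stats::setNames(paste0(block_ids, "-png"), block_ids)
  }
  fun <- switch(mode, max = function(x) apply(x, 1L, max),
                mean = rowMeans, sum = rowSums)
  extra <- vapply(block_ids, function(b) {
    members <- names(blocks)[blocks == b]
    if (!length(members)) stop("empty block '", b, "'", call. = FALSE)
    fun(unclass(matrix)[, members, drop = FALSE])
  }, numeric(nrow(matrix)))
  extra <- base::matrix(extra, nrow = nrow(matrix),
                        dimnames = list(rownames(matrix),
                                        unname(png_names[block_ids])))
  out <- cbind(unclass(structure(matrix, blocks = NULL)), extra)
  structure(out, blocks = attr(matrix, "blocks"),
            class = c("homology_matrix", "matrix"))
}

#' Read and write homology matrices as TSV
#'
#' The on-disk format is a tab-separated grid with a header row of genome
#' IDs and the enzyme IDs in the first column; the round trip is lossless.
#'
#' @param path File path.
#' @param blocks Optional genome-to-block map attached on read.
#' @return `read_homology_matrix()` returns a [homology_matrix()];
#'   `write_homology_matrix()` returns the path invisibly.
#' @export
read_homology_matrix <- function(path, blocks = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty matrix file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(fields[[1L]])
  bad <- which(lengths(fields) != ncols)
  if (length(bad)) {
    stop("ragged row at line ", bad[1L], ": expected ", ncols, " fields, ",
         "found ", length(fields[[bad[1L]]]), call. = FALSE)
  }
  genomes <- fields[[1L]][-1L]
  body <- fields[-1L]
  enzymes <- vapply(body, `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(ncols - 1L))
  )
  vals <- base::matrix(vals, ncol = ncols - 1L, byrow = TRUE,
                       dimnames = list(enzymes, genomes))
  if (anyNA(vals)) {
    bad_row <- which(apply(is.na(vals), 1L, any))[1L]
    stop("non-numeric cell at line ", bad_row + 1L, call. = FALSE)
  }
  if (any(vals < 0)) {
    bad_row <- which(apply(vals < 0, 1L, any))[1L]
    stop("negative cell at line ", bad_row + 1L, call. = FALSE)
  }
  homology_matrix(vals, blocks = blocks)
}

#' @rdname read_homology_matrix
#' @param matrix A [homology_matrix()].
#' @export
write_homology_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "homology_matrix"))
  m <- unclass(structure(matrix, blocks = NULL))
  header <- paste(c("enzyme", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a two-column TSV map
#'
#' Used for both gene-to-genome and genome-to-block maps: two tab-separated
#' columns, key then value, no header.
#'
#' @param path File path.
#' @return Named character vector (values named by keys).
#' @export
read_id_map <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expected two tab-separated columns", call. = FALSE)
  stats::setNames(as.character(raw[[2L]]), as.character(raw[[1L]]))
}
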