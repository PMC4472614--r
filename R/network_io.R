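#' Normalize gene symbols
#'
#' Gene symbols are whitespace-trimmed and upper-cased on ingest so that case
#' variants of the same HUGO symbol do not create duplicate network nodes.
#'
#' @param x Character vector of gene symbols.
#' @return Normalized character vector.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Construct an undirected gene network
#'
#' Builds a simple undirected graph from a two-column edge table. Self-loops
#' are dropped (the enrichment statistic counts links *between* genes, and the
#' degree bookkeeping assumes a simple graph) and reversed duplicates are
#' collapsed, so an edge present several times, in either orientation, counts
#' once.
#'
#' @param edges Two-column character matrix or data frame (gene A, gene B).
#' @param quiet Suppress messages about dropped self-loops.
#' @return An object of class `gene_network` with elements `nodes` (character),
#'   `edges` (two-column character matrix, each row ordered
#'   lexicographically), `degree` (named integer vector) and `n_total`
#'   (number of edges).
#' @export
gene_network <- function(edges, quiet = FALSE) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(edges) <- "character"
  a <- normalize_symbols(edges[, 1])
  b <- normalize_symbols(edges[, 2])
  keep <- !is.na(a) & !is.na(b) & nzchar(a) & nzchar(b)
  a <- a[keep]; b <- b[keep]
  loops <- a == b
  if (any(loops) && !quiet) {
    message("gene_network: dropped ", sum(loops), " self-loop(s)")
  }
  a2 <- pmin(a[!loops], b[!loops])
  b2 <- pmax(a[!loops], b[!loops])
  key <- paste(a2, b2, sep = "\r")
  dup <- duplicated(key)
  em <- cbind(from = a2[!dup], to = b2[!dup])
  if (nrow(em) == 0L) stop("gene_network: no edges left after cleaning")
  deg <- table(c(em[, 1], em[, 2]))
  degree <- as.integer(deg)
  names(degree) <- names(deg)
  structure(
    list(nodes = sort(names(degree)), edges = em, degree = degree,
         n_total = nrow(em)),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$nodes), "nodes,", x$n_total, "edges\n")
  invisible(x)
}

open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

read_table_lines <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Load a gene network from an edge-list file
#'
#' Reads a 2-3 column tab-separated edge list (gene A, gene B, optional
#' confidence score). Lines starting with `#` are ignored; gzip-compressed
#' files are accepted. When a confidence threshold is given, only rows with a
#' score strictly greater than the threshold are kept (merged functional-
#' coupling networks are conventionally cut at confidence above 0.5; edges
#' from curated databases typically carry no score and a missing third column
#' passes all rows).
#'
#' @param path Path to the edge list.
#' @param min_confidence Optional numeric; rows whose confidence is not
#'   strictly greater than this value are dropped. Ignored when the file has
#'   no third column.
#' @return A [gene_network].
#' @export
load_network <- function(path, min_confidence = NULL) {
  tl <- read_table_lines(path)
  if (length(tl$lines) == 0L) stop("load_network: no data rows in ", path)
  fields <- strsplit(tl$lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("load_network: malformed row (fewer than 2 columns) at line ",
         tl$lineno[which(nf < 2L)[1]], " of ", path)
  }
  a <- vapply(fields, `[`, "", 1L)
  b <- vapply(fields, `[`, "", 2L)
  if (!is.null(min_confidence) && any(nf >= 3L)) {
    conf_chr <- vapply(fields, function(f) if (length(f) >= 3L) f[3L] else NA_character_, "")
    conf <- suppressWarnings(as.numeric(conf_chr))
    bad <- !is.na(conf_chr) & is.na(conf)
    if (any(bad)) {
      stop("load_network: non-numeric confidence at line ",
           tl$lineno[which(bad)[1]], " of ", path)
    }
    keep <- is.na(conf) | conf > min_confidence
    a <- a[keep]; b <- b[keep]
  }
  if (length(a) == 0L) stop("load_network: no edges pass the confidence filter")
  gene_network(cbind(a, b))
}

#' Merge gene networks into a union network
#'
#' Node and edge sets are unioned; an edge present in several source networks
#' (multiple lines of evidence) is treated as a single edge.
#'
#' @param networks List of [gene_network] objects.
#' @return A [gene_network].
#' @export
merge_networks <- function(networks) {
  if (inherits(networks, "gene_network")) networks <- list(networks)
  stopifnot(length(networks) >= 1L)
  for (n in networks) stopifnot(inherits(n, "gene_network"))
  gene_network(do.call(rbind, lapply(networks, `[[`, "edges")), quiet = TRUE)
}

#' Write a gene network to an edge-list TSV
#'
#' @param network A [gene_network].
#' @param path Output path.
#' @export
write_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Direct network neighbors of a set of genes
#'
#' @param network A [gene_network].
#' @param genes Character vector of gene symbols.
#' @return Character vector of neighbors, excluding the query genes
#'   themselves.
#' @export
network_neighbors <- function(network, genes) {
  genes <- normalize_symbols(genes)
  e <- network$edges
  ia <- e[, 1] %in% genes
  ib <- e[, 2] %in% genes
  setdiff(unique(c(e[ib, 1], e[ia, 2])), genes)
}

#' Construct a gene set
#'
#' @param id Non-empty identifier.
#' @param members Character vector of gene symbols; duplicates are collapsed.
#' @return An object of class `gene_set` with elements `id` and `members`.
#' @export
gene_set <- function(id, members) {
  id <- as.character(id)
  if (length(id) != 1L || !nzchar(id)) stop("gene_set: id must be a non-empty string")
  members <- unique(normalize_symbols(members))
  members <- members[nzchar(members) & !is.na(members)]
  if (length(members) == 0L) stop("gene_set: empty member list for '", id, "'")
  structure(list(id = id, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$id, "': ", length(x$members), " genes\n", sep = "")
  invisible(x)
}

as_gene_set <- function(x, id = "set") {
  if (inherits(x, "gene_set")) x else gene_set(id, x)
}

#' Load gene sets from a GMT file
#'
#' Standard GMT dialect: `id TAB description TAB member1 TAB member2 ...`.
#' Duplicate members within a set are collapsed; sets outside
#' `[min_size, max_size]` (after deduplication) are dropped with a message.
#'
#' @param path Path to the GMT file (gzip accepted).
#' @param min_size,max_size Inclusive size bounds for retained sets.
#' @return Named list of [gene_set] objects.
#' @export
load_gene_sets <- function(path, min_size = 1L, max_size = Inf) {
  tl <- read_table_lines(path)
  if (length(tl$lines) == 0L) stop("load_gene_sets: no data rows in ", path)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("load_gene_sets: unreadable GMT line (fewer than 3 fields) at line ",
         tl$lineno[which(nf < 3L)[1]], " of ", path)
  }
  sets <- lapply(fields, function(f) gene_set(f[1L], f[-(1:2)]))
  sizes <- vapply(sets, function(s) length(s$members), 0L)
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep)) {
    message("load_gene_sets: dropped ", sum(!keep),
            " set(s) outside size range [", min_size, ", ", max_size, "]")
  }
  sets <- sets[keep]
  if (length(sets) == 0L) stop("load_gene_sets: no sets pass the size filter")
  names(sets) <- vapply(sets, `[[`, "", "id")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets List of [gene_set] objects.
#' @param path Output path.
#' @param description Description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$id, description, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a TF-to-target map
#'
#' @param tf,target Character vectors of equal length (ordered pairs).
#' @param allow_autoregulation Keep pairs with `tf == target`; by default they
#'   are dropped with a message.
#' @return An object of class `tf_target_map`: a data frame with columns `tf`
#'   and `target`, duplicate ordered pairs removed.
#' @export
tf_target_map <- function(tf, target, allow_autoregulation = FALSE) {
  tf <- normalize_symbols(tf)
  target <- normalize_symbols(target)
  stopifnot(length(tf) == length(target))
  auto <- tf == target
  if (any(auto) && !allow_autoregulation) {
    message("tf_target_map: dropped ", sum(auto), " autoregulatory pair(s)")
    tf <- tf[!auto]; target <- target[!auto]
  }
  key <- paste(tf, target, sep = "\r")
  dup <- duplicated(key)
  out <- data.frame(tf = tf[!dup], target = target[!dup],
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) stop("tf_target_map: empty map")
  class(out) <- c("tf_target_map", "data.frame")
  out
}

#' Load a TF-target edge list
#'
#' Two-column TSV: `tf TAB target`; `#` comment lines ignored, gzip accepted.
#'
#' @inheritParams load_network
#' @inheritParams tf_target_map
#' @return A [tf_target_map].
#' @export
load_tf_map <- function(path, allow_autoregulation = FALSE) {
  tl <- read_table_lines(path)
  if (length(tl$lines) == 0L) stop("load_tf_map: no data rows in ", path)
  fields <- strsplit(tl$lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("load_tf_map: malformed row at line ", tl$lineno[which(nf < 2L)[1]],
         " of ", path)
  }
  tf_target_map(vapply(fields, `[`, "", 1L), vapply(fields, `[`, "", 2L),
                allow_autoregulation = allow_autoregulation)
}

#' Construct an expression study
#'
#' Bundles a log2 expression matrix (genes x samples) with its sample sheet.
#' The sample sheet must contain columns `sample_id`, `line_id`, `condition`
#' (`pre`/`post`), `inhibition` (`high`/`low`) and `origin`
#' (`in_vitro`/`ex_vivo`). Missing expression values are an error: the
#' upstream normalization is expected to deliver a complete matrix.
#'
#' @param matrix Numeric matrix of log2 intensities, rownames = gene symbols,
#'   colnames = sample ids.
#' @param samples Data frame of per-sample annotations.
#' @return An object of class `expression_study` with elements `matrix` and
#'   `samples`.
#' @export
expression_study <- function(matrix, samples) {
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix)) stop("expression_study: matrix must be numeric")
  if (anyNA(matrix)) stop("expression_study: missing values in expression matrix")
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix))) {
    stop("expression_study: gene ids must be present and unique")
  }
  req <- c("sample_id", "line_id", "condition", "inhibition", "origin")
  miss <- setdiff(req, colnames(samples))
  if (length(miss)) stop("expression_study: sample sheet lacks column(s): ",
                         paste(miss, collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!setequal(colnames(matrix), samples$sample_id)) {
    stop("expression_study: matrix columns and sample sheet disagree")
  }
  samples <- samples[match(colnames(matrix), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!all(samples$condition %in% c("pre", "post"))) {
    stop("expression_study: condition must be 'pre' or 'post'")
  }
  rownames(matrix) <- normalize_symbols(rownames(matrix))
  structure(list(matrix = matrix, samples = samples),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples (", length(unique(x$samples$line_id)), "lines )\n")
  invisible(x)
}

#' Load an expression study from TSV files
#'
#' The matrix file has a header row of sample ids and gene symbols in the
#' first column; the sample sheet is a TSV with columns `sample_id`,
#' `line_id`, `condition`, `inhibition`, `origin`.
#'
#' @param matrix_path,samples_path File paths (gzip accepted).
#' @return An [expression_study].
#' @export
load_expression <- function(matrix_path, samples_path) {
  mat <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  genes <- as.character(mat[[1]])
  m <- as.matrix(mat[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  expression_study(m, samples)
}

#' Keep a subset of samples of an expression study
#'
#' @param study An [expression_study].
#' @param keep Logical vector over samples, or character vector of sample ids.
#' @return An [expression_study] restricted to the selected samples.
#' @export
subset_samples <- function(study, keep) {
  if (is.character(keep)) keep <- study$samples$sample_id %in% keep
  expression_study(study$matrix[, keep, drop = FALSE],
                   study$samples[keep, , drop = FALSE])
}
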