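#' Read a log2 expression matrix and its sample metadata
#'
#' Reads a tab-separated gene-by-sample expression table (first column gene
#' symbol, header row sample identifiers, log2-scale values) together with a
#' sample metadata table (columns `sample_id`, `group`, `day`, `batch`), and
#' validates the pair. The returned matrix and metadata are aligned: the
#' metadata rows appear in the column order of the matrix.
#'
#' Gene identifiers are treated as case-sensitive symbols; duplicated gene
#' rows are an error rather than being merged silently (probe-level merging
#' is [collapse_probes()]'s job).
#'
#' @param path Path to the expression TSV.
#' @param metadata_path Path to the metadata TSV.
#' @return A list with elements `expr` (numeric matrix, genes as rownames,
#'   samples as colnames) and `meta` (data.frame with columns `sample_id`,
#'   `group` (factor control/induced), `day` (integer), `batch` (character)).
#' @export
read_expression <- function(path, metadata_path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) {
    stop("expression file must have a gene column plus at least one sample")
  }
  genes <- as.character(tab[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L) {
    stop("duplicate gene identifier(s) in expression file: ",
         paste(unique(dup), collapse = ", "))
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                 genes[bad[1L]], colnames(vals)[bad[2L]]))
  }
  rownames(vals) <- genes
  meta <- read_metadata(metadata_path)
  missing <- setdiff(colnames(vals), meta$sample_id)
  if (length(missing) > 0L) {
    stop("sample(s) in expression matrix absent from metadata: ",
         paste(missing, collapse = ", "))
  }
  meta <- meta[match(colnames(vals), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  validate_expression(vals, meta)
  list(expr = vals, meta = meta)
}

#' Read a sample metadata table
#'
#' @param path Path to a TSV with columns `sample_id`, `group`, `day`,
#'   `batch`.
#' @return A validated data.frame; `group` is a factor with levels
#'   `control`, `induced` and `day` is integer.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "day", "batch")
  miss <- setdiff(need, colnames(meta))
  if (length(miss) > 0L) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata")
  }
  bad_grp <- setdiff(unique(meta$group), c("control", "induced"))
  if (length(bad_grp) > 0L) {
    stop("metadata group values must be control/induced; found: ",
         paste(bad_grp, collapse = ", "))
  }
  meta$group <- factor(meta$group, levels = c("control", "induced"))
  meta$day <- as.integer(meta$day)
  if (anyNA(meta$day) || any(meta$day < 0L)) {
    stop("metadata day must be a non-negative integer stage label")
  }
  if (any(meta$day[meta$group == "control"] != 0L)) {
    stop("control samples must have day = 0")
  }
  meta$batch <- as.character(meta$batch)
  meta[, need]
}

validate_expression <- function(expr, meta = NULL) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample identifiers")
  if (anyNA(expr)) stop("expression matrix contains missing values")
  if (!is.null(meta)) {
    if (!identical(colnames(expr), meta$sample_id)) {
      stop("expression columns and metadata rows are not aligned")
    }
  }
  invisible(expr)
}

#' Write an expression matrix as TSV
#'
#' UTF-8, Unix newlines, full float precision (values survive a read/write
#' round trip bit-faithfully).
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(expr)), collapse = "\t"),
             con, sep = "\n", useBytes = TRUE)
  body <- vapply(seq_len(nrow(expr)), function(i) {
    paste(c(rownames(expr)[i],
            format(expr[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1L))
  writeLines(body, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a sample metadata table as TSV
#'
#' @param meta Metadata data.frame (see [read_metadata()]).
#' @param path Output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta[, c("sample_id", "group", "day", "batch")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Standard MSigDB dialect: one set per line, `name TAB description TAB
#' member...`. Member symbols are deduplicated. Category tags for the five
#' osteoblast pathway classes are not encoded in MSigDB names, so they come
#' from an optional sidecar TSV with columns `set_name` and `category`;
#' sets without a sidecar entry default to category `"other"`.
#'
#' @param path Path to the GMT file.
#' @param category_path Optional path to the category sidecar TSV.
#' @return An object of class `gene_set_collection`: a list with `sets`
#'   (named list of character vectors) and `categories` (named character
#'   vector over the same names, values among transcription_factor,
#'   differentiation, development, proliferation, signaling, other).
#' @export
read_gmt <- function(path, category_path = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) stop("malformed GMT line: ", substr(ln, 1, 40))
    name <- parts[1L]
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      warning("GMT set '", name, "' has no members; skipped")
      next
    }
    if (name %in% names(sets)) {
      stop("duplicate gene-set name in GMT: ", name)
    }
    sets[[name]] <- members
  }
  categories <- rep("other", length(sets))
  names(categories) <- names(sets)
  if (!is.null(category_path)) {
    sc <- utils::read.delim(category_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!all(c("set_name", "category") %in% colnames(sc))) {
      stop("category sidecar needs columns set_name, category")
    }
    hit <- sc$set_name %in% names(sets)
    categories[sc$set_name[hit]] <- sc$category[hit]
  }
  bad <- setdiff(unique(categories), gene_set_categories())
  if (length(bad) > 0L) {
    stop("unknown gene-set category: ", paste(bad, collapse = ", "))
  }
  gene_set_collection(sets, categories)
}

gene_set_categories <- function() {
  c("transcription_factor", "differentiation", "development",
    "proliferation", "signaling", "other")
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (unique, non-empty).
#' @param categories Optional named character vector of category tags over
#'   the same names; defaults to `"other"`.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, categories = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) == 0L) stop("empty gene-set collection")
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene sets must have unique names")
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0L)) stop("gene sets must be non-empty")
  if (is.null(categories)) {
    categories <- stats::setNames(rep("other", length(sets)), names(sets))
  }
  categories <- categories[names(sets)]
  names(categories) <- names(sets)
  categories[is.na(categories)] <- "other"
  structure(list(sets = sets, categories = categories),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets\n")
  tab <- table(x$categories)
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Write a gene-set collection in GMT format (plus category sidecar)
#'
#' @param gs A `gene_set_collection`.
#' @param path Output GMT path.
#' @param category_path Optional sidecar TSV path for the category tags.
#' @export
write_gmt <- function(gs, path, category_path = NULL) {
  stopifnot(inherits(gs, "gene_set_collection"))
  lines <- vapply(names(gs$sets), function(nm) {
    paste(c(nm, "na", gs$sets[[nm]]), collapse = "\t")
  }, character(1L))
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  if (!is.null(category_path)) {
    utils::write.table(
      data.frame(set_name = names(gs$sets), category = unname(gs$categories)),
      category_path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  }
  invisible(path)
}

#' Read an undirected edge list (e.g. a PPI network)
#'
#' Two- or three-column TSV (`gene_a`, `gene_b`[, `weight`]). Edges are
#' canonicalized to lexicographic pair order; duplicate undirected edges are
#' collapsed keeping the maximum weight; self-loops are dropped with a
#' warning; weights must lie in [0, 1].
#'
#' @param path Path to the edge-list TSV (with header).
#' @return A data.frame with columns `gene_a`, `gene_b`, `weight`, one row
#'   per undirected edge, `gene_a < gene_b`.
#' @export
read_edge_list <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("edge list needs at least two columns")
  edges <- data.frame(gene_a = as.character(tab[[1L]]),
                      gene_b = as.character(tab[[2L]]),
                      weight = if (ncol(tab) >= 3L) as.numeric(tab[[3L]]) else 1,
                      stringsAsFactors = FALSE)
  canonicalize_edges(edges)
}

#' Canonicalize an undirected edge list
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` and optionally
#'   `weight` (defaults to 1).
#' @return Canonical edge data.frame (see [read_edge_list()]).
#' @export
canonicalize_edges <- function(edges) {
  if (is.null(edges$weight)) edges$weight <- 1
  if (anyNA(edges$weight) || any(edges$weight < 0 | edges$weight > 1)) {
    stop("edge weights must lie in [0, 1]")
  }
  loop <- edges$gene_a == edges$gene_b
  if (any(loop)) {
    warning(sum(loop), " self-loop(s) dropped from edge list")
    edges <- edges[!loop, , drop = FALSE]
  }
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  edges <- data.frame(gene_a = a, gene_b = b, weight = edges$weight,
                      stringsAsFactors = FALSE)
  key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
  if (anyDuplicated(key)) {
    w <- tapply(edges$weight, key, max)
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
    edges$weight <- as.numeric(w[paste(edges$gene_a, edges$gene_b,
                                       sep = "\r")])
  }
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Write an undirected edge list as TSV
#'
#' @param edges Canonical edge data.frame.
#' @param path Output path.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges[, c("gene_a", "gene_b", "weight")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}
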