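#' Validate an expression matrix
#'
#' An expression matrix is a numeric genes x samples matrix with unique,
#' non-empty gene identifiers as row names and unique sample identifiers as
#' column names. Values are taken to be abundances on a log-like scale and are
#' consumed as given: no transformation is applied anywhere downstream unless
#' requested explicitly.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   dimnames set.
#' @return the validated matrix, invisibly unchanged.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("expression matrix needs at least 1 gene and 1 sample", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must carry gene and sample identifiers", call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values", call. = FALSE)
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicated gene identifiers: ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicated sample identifiers: ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  values
}

#' Read a gene expression table
#'
#' Reads a delimited table whose first column holds gene identifiers and whose
#' header row holds sample identifiers; the body must be numeric.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return a validated expression matrix (see [expression_matrix()]).
#' @export
read_expression <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty expression file: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   colClasses = "character", quote = "\"", comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("expression file has no data body: ", path, call. = FALSE)
  genes <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  num <- vapply(body, function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(body)))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(body))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                 genes[bad[1L, 1L]], colnames(body)[bad[1L, 2L]]),
         call. = FALSE)
  rownames(num) <- genes
  colnames(num) <- colnames(body)
  expression_matrix(num)
}

#' Write a gene expression table
#'
#' @param x expression matrix.
#' @param path output path.
#' @inheritParams read_expression
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  x <- expression_matrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' A gene-set collection maps unique set names to non-empty lists of unique
#' gene identifiers, with an optional per-set description (as carried by GMT
#' files) and a free-text source description.
#'
#' @param sets named list of character vectors.
#' @param descriptions named character vector of per-set descriptions
#'   (defaults to empty strings).
#' @param source_description free text recording provenance.
#' @return an object of class `gene_sets`.
#' @export
gene_sets <- function(sets, descriptions = NULL, source_description = "") {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("'sets' must be a named list of gene identifier vectors", call. = FALSE)
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup))
    stop("duplicate gene-set names: ", paste(dup, collapse = ", "), call. = FALSE)
  if (any(lengths(sets) == 0L))
    stop("empty gene sets: ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "), call. = FALSE)
  for (nm in names(sets)) {
    if (anyDuplicated(sets[[nm]]))
      stop("duplicate genes within set ", nm, call. = FALSE)
  }
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 source_description = source_description),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat("gene_sets collection:", length(x$sets), "sets")
  if (nzchar(x$source_description)) cat(" [", x$source_description, "]", sep = "")
  cat("\n")
  if (length(x$sets)) {
    sz <- lengths(x$sets)
    cat("  set sizes: min", min(sz), "median", stats::median(sz), "max", max(sz), "\n")
  }
  invisible(x)
}

#' @export
length.gene_sets <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Genes repeated
#' within a line are deduplicated with a warning; duplicated set names or
#' lines with fewer than three fields are hard errors.
#'
#' @param path path to the GMT file.
#' @return a [gene_sets()] collection, one set per line, in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields", call. = FALSE)
  nms <- vapply(fields, `[[`, character(1L), 1L)
  dup <- unique(nms[duplicated(nms)])
  if (length(dup))
    stop("duplicate gene-set names in GMT: ", paste(dup, collapse = ", "),
         call. = FALSE)
  descr <- setNames(vapply(fields, `[[`, character(1L), 2L), nms)
  sets <- lapply(fields, function(f) f[-(1:2)])
  deduped <- vapply(sets, anyDuplicated, integer(1L)) > 0L
  if (any(deduped)) {
    warning("duplicate genes deduplicated within sets: ",
            paste(nms[deduped], collapse = ", "), call. = FALSE)
    sets <- lapply(sets, unique)
  }
  names(sets) <- nms
  gene_sets(sets, descr, source_description = basename(path))
}

#' Write a gene-set collection as GMT
#'
#' @param gs a [gene_sets()] collection.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gs, path) {
  stopifnot(inherits(gs, "gene_sets"))
  lines <- vapply(names(gs$sets), function(nm) {
    paste(c(nm, gs$descriptions[[nm]], gs$sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a clinical response table
#'
#' Per-sample binary response (1 = responder, pathological complete response;
#' 0 = non-responder), treatment arm and estrogen-receptor stratum. Any sample
#' without a recorded complete response is a non-responder, so `response` is
#' required for every sample.
#'
#' @param sample_id unique character sample identifiers.
#' @param response integer/logical vector of 0/1 labels.
#' @param arm character treatment arm per sample.
#' @param er_status character ER stratum per sample (e.g. `"ER+"`, `"ER-"`).
#' @return a `data.frame` of class `response_table`.
#' @export
response_table <- function(sample_id, response, arm, er_status) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicated sample identifiers in response table", call. = FALSE)
  response <- as.integer(response)
  if (anyNA(response) || !all(response %in% c(0L, 1L)))
    stop("response labels must be binary 0/1", call. = FALSE)
  n <- length(sample_id)
  if (length(response) != n || length(arm) != n || length(er_status) != n)
    stop("all response-table fields must have one value per sample", call. = FALSE)
  structure(data.frame(sample_id = sample_id, response = response,
                       arm = as.character(arm),
                       er_status = as.character(er_status),
                       stringsAsFactors = FALSE),
            class = c("response_table", "data.frame"))
}

#' Read a clinical response table
#'
#' Expects columns `sample_id`, `response`, `arm`, `er_status`.
#'
#' @inheritParams read_expression
#' @return a [response_table()].
#' @export
read_response_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "response", "arm", "er_status")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("response table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  response_table(df$sample_id, df$response, df$arm, df$er_status)
}

#' Write a clinical response table
#'
#' @param labels a [response_table()].
#' @param path output path.
#' @inheritParams read_expression
#' @return `path`, invisibly.
#' @export
write_response_table <- function(labels, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  write.table(labels, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter gene sets by measured size
#'
#' Restricts each set to the genes actually present in the expression matrix,
#' then keeps sets whose intersected size lies in `[min_size, max_size]`
#' (inclusive). Counting after intersection is deliberate: the similarity
#' coefficient can only use measured genes, so the effective pathway size is
#' what matters. Genes absent from the matrix are dropped silently per set,
#' with one summary message.
#'
#' @param collection a [gene_sets()] collection.
#' @param min_size smallest retained intersected size (>= 2).
#' @param max_size largest retained intersected size.
#' @param expr expression matrix providing the measured gene universe.
#' @return a filtered [gene_sets()] collection; empty collections are allowed
#'   (with a warning) so pipelines can continue.
#' @export
filter_sets_by_size <- function(collection, min_size, max_size, expr) {
  stopifnot(inherits(collection, "gene_sets"))
  if (min_size < 2L) stop("min_size must be >= 2", call. = FALSE)
  if (max_size < min_size) stop("max_size must be >= min_size", call. = FALSE)
  universe <- rownames(expr)
  inter <- lapply(collection$sets, function(g) g[g %in% universe])
  n_dropped <- sum(lengths(collection$sets)) - sum(lengths(inter))
  if (n_dropped > 0L)
    message(n_dropped, " gene memberships outside the measured universe dropped")
  keep <- lengths(inter) >= min_size & lengths(inter) <= max_size
  if (!any(keep)) {
    warning("no gene sets within size bounds [", min_size, ", ", max_size, "]",
            call. = FALSE)
    return(structure(list(sets = setNames(list(), character(0L)),
                          descriptions = setNames(character(0L), character(0L)),
                          source_description = collection$source_description),
                     class = "gene_sets"))
  }
  gene_sets(inter[keep], collection$descriptions[keep],
            collection$source_description)
}
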