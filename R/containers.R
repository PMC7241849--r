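#' Construct an abundance table
#'
#' An abundance table is a numeric samples x features matrix tagged with the
#' kind of feature it carries (\code{gene}, \code{cag}, \code{taxon},
#' \code{pathway} or \code{demographic}). Rows are samples (rownames are
#' sample ids), columns are features. For compositional kinds each row sums
#' to one; demographic tables are ordinary design matrices.
#'
#' @param x numeric matrix, samples in rows (rownames = sample ids).
#' @param kind feature kind label.
#' @param closed logical; if TRUE, rows are checked to sum to 1 (within 1e-6).
#' @return the matrix with class \code{abund_table} and a \code{kind} attribute.
#' @export
abundance_table <- function(x, kind = c("gene", "cag", "taxon", "pathway", "demographic"),
                            closed = kind[1] %in% c("gene", "cag", "taxon")) {
  kind <- match.arg(kind)
  if (!is.matrix(x) || !is.numeric(x)) stop("abundance table must be a numeric matrix")
  if (is.null(rownames(x)) || (ncol(x) > 0 && is.null(colnames(x)))) {
    stop("abundance table needs sample ids as rownames and feature ids as colnames")
  }
  if (ncol(x) == 0) closed <- FALSE
  if (closed) {
    rs <- rowSums(x)
    if (any(abs(rs - 1) > 1e-6)) {
      stop("rows of a '", kind, "' abundance table must sum to 1 (max deviation ",
           format(max(abs(rs - 1))), ")")
    }
  }
  structure(x, class = c("abund_table", "matrix", "array"), kind = kind)
}

#' @export
`[.abund_table` <- function(x, i, j, ..., drop = FALSE) {
  kind <- attr(x, "kind")
  out <- NextMethod("[", drop = drop)
  if (is.matrix(out)) {
    attr(out, "kind") <- kind
    class(out) <- c("abund_table", "matrix", "array")
  }
  out
}

#' @export
print.abund_table <- function(x, ...) {
  cat(sprintf("<abund_table> %d samples x %d %s features\n",
              nrow(x), ncol(x), attr(x, "kind")))
  invisible(x)
}

table_kind <- function(x) attr(x, "kind") %||% "unknown"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write abundance tables as TSV
#'
#' Samples as rows, header row, sample id in the first column (\code{sample_id}).
#'
#' @param x an \code{abund_table}.
#' @param path file path.
#' @param kind feature kind to tag on read.
#' @export
write_abundance_tsv <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path, kind = "gene") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  abundance_table(m, kind = kind, closed = FALSE)
}

#' Write a sample-metadata table as TSV
#' @param metadata a sample-metadata data.frame.
#' @param path file path.
#' @export
write_metadata_tsv <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# deterministic 32-bit-safe integer hash of a character label, used to derive
# per-cell seeds from a master seed
hash_seed <- function(seed, label) {
  codes <- utf8ToInt(paste(label, collapse = "|"))
  h <- as.double(seed %% 2147483647L)
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}
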