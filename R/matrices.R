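#' The BLOSUM62 substitution matrix
#'
#' Returns the standard BLOSUM62 amino-acid substitution matrix (integer
#' log-odds scores) as shipped with Biostrings, restricted here only in that
#' the local-matching score uses its diagonal. `M["X","X"]` is -1.
#'
#' @return Integer matrix with residue one-letter codes as dimnames.
#' @export
#' @examples
#' m <- blosum62()
#' m["A", "A"]  # 4
blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix format used by NCBI BLAST (`#` comment lines,
#' a header row of residue letters, one row per residue). The matrix must be
#' symmetric and define a diagonal entry for all 20 standard residues plus X.
#'
#' @param path Path to the matrix file.
#' @return Integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a score matrix file: ", path, call. = FALSE)
  cols <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(ln) strsplit(trimws(ln), "\\s+")[[1L]])
  m <- matrix(NA_integer_, length(rows), length(cols),
              dimnames = list(vapply(rows, `[`, character(1), 1L), cols))
  for (i in seq_along(rows)) {
    vals <- suppressWarnings(as.integer(rows[[i]][-1L]))
    if (length(vals) != length(cols) || anyNA(vals)) {
      stop("malformed matrix row for residue '", rownames(m)[i], "'",
           call. = FALSE)
    }
    m[i, ] <- vals
  }
  validate_score_matrix(m)
  m
}

# A usable scoring matrix is symmetric and has a diagonal for the 20+X
# alphabet; checked once at the distance-matrix entry points.
validate_score_matrix <- function(m) {
  if (!is.matrix(m) || is.null(rownames(m)) ||
      !identical(rownames(m), colnames(m))) {
    stop("score matrix must be square with identical row/column names",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
    stop("score matrix must be symmetric", call. = FALSE)
  }
  missing <- setdiff(AA_ALPHABET20X, rownames(m))
  if (length(missing) > 0L) {
    stop("score matrix lacks diagonal entries for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(m)
}
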