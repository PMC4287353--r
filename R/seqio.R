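#' Read a protein FASTA file
#'
#' Reads amino-acid sequences, normalizes them to the 20-letter alphabet plus
#' `X`, and validates them. The identifier of each record is the FASTA header
#' up to the first whitespace, so that it can be matched against the keys of a
#' domain-architecture table. Lowercase residues are uppercased, `*` stop
#' characters and internal whitespace are stripped, and the nonstandard codes
#' B, Z, U, O and J are mapped to `X` with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::AAStringSet]; names are the record
#'   identifiers, in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 kinase", "ACDEFGH", ">p2", "acdefgh"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("cannot read FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(raw) == 0L) {
    stop("no sequences found in '", path, "'", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids))) {
    stop("FASTA record ", which(!nzchar(ids))[1L], " has an empty identifier",
         call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence identifier(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(raw))
  seqs <- gsub("[*[:space:]]", "", seqs)
  if (any(!nzchar(seqs))) {
    stop("record '", ids[!nzchar(seqs)][1L], "' has an empty sequence",
         call. = FALSE)
  }
  n_nonstd <- 0L
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    nonstd <- chars %in% AA_NONSTANDARD
    if (any(nonstd)) {
      n_nonstd <- n_nonstd + sum(nonstd)
      chars[nonstd] <- "X"
      seqs[i] <- paste(chars, collapse = "")
    }
    bad <- setdiff(unique(chars), AA_ALPHABET20X)
    if (length(bad) > 0L) {
      stop("record '", ids[i], "' contains invalid character(s): ",
           paste(sprintf("'%s'", bad), collapse = ", "), call. = FALSE)
    }
  }
  if (n_nonstd > 0L) {
    warning(n_nonstd, " nonstandard residue(s) (B/Z/U/O/J) mapped to 'X'",
            call. = FALSE)
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write protein sequences as FASTA
#'
#' @param records Named character vector or [Biostrings::AAStringSet].
#' @param path Output file path.
#' @param width Line-wrap width in residues.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  records <- as_aa_set(records)
  Biostrings::writeXStringSet(records, filepath = path, width = width)
  invisible(path)
}

# Coerce a named character vector (or AAStringSet) to a named AAStringSet.
as_aa_set <- function(records) {
  if (methods::is(records, "XStringSet")) {
    return(Biostrings::AAStringSet(records))
  }
  if (is.character(records)) {
    if (is.null(names(records)) || any(!nzchar(names(records)))) {
      stop("sequence records must be named", call. = FALSE)
    }
    out <- Biostrings::AAStringSet(records)
    names(out) <- names(records)
    return(out)
  }
  stop("records must be an AAStringSet or a named character vector",
       call. = FALSE)
}

#' Read a tab-delimited domain-architecture file
#'
#' Each non-empty line is `protein_id TAB domain1 TAB domain2 ...`, domains
#' listed N-terminal to C-terminal. Repeated domain identifiers are preserved
#' (duplication is one of the things the similarity indices measure). A line
#' with only an identifier yields an empty architecture.
#'
#' @param path Path to the TSV file.
#' @return A named list mapping protein identifier to a character vector of
#'   domain identifiers (possibly empty), in N-to-C order.
#' @export
read_architectures <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  archs <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    id <- trimws(fields[1L])
    if (!nzchar(id)) {
      stop("architecture line with empty protein identifier: '", ln, "'",
           call. = FALSE)
    }
    if (!is.null(archs[[id]])) {
      stop("duplicate architecture entry for protein '", id, "'",
           call. = FALSE)
    }
    domains <- if (length(fields) > 1L) fields[-1L] else character(0)
    domains <- domains[nzchar(trimws(domains))]
    archs[[id]] <- as.character(domains)
  }
  archs
}

#' Write a domain-architecture table
#'
#' @param archs Named list of character vectors (see [read_architectures()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_architectures <- function(archs, path) {
  stopifnot(is.list(archs), !is.null(names(archs)))
  lines <- vapply(names(archs), function(id) {
    paste(c(id, archs[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write cluster assignments to a two-column TSV
#'
#' One line per protein, `protein_id TAB cluster_index`, sorted by cluster
#' index and then by identifier.
#'
#' @param assignments A named integer vector of 1-based cluster indices, or a
#'   `cluster_assignment` object from [cut_tree()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cluster_assignments <- function(assignments, path) {
  if (inherits(assignments, "cluster_assignment")) {
    assignments <- assignments$labels
  }
  labels <- assignments
  if (length(labels) > 0L) {
    if (is.null(names(labels)) || any(!nzchar(names(labels)))) {
      stop("assignments must be named by protein identifier", call. = FALSE)
    }
    if (any(labels != as.integer(labels)) || any(labels < 1L)) {
      stop("cluster indices must be positive integers (1-based)",
           call. = FALSE)
    }
    ord <- order(labels, names(labels), method = "radix")
    labels <- labels[ord]
  }
  lines <- paste(names(labels), as.integer(labels), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a distance matrix in the tool's tabular format
#'
#' First line: tab-joined identifiers. Each following line: identifier, then
#' the distances of that row to 6 decimal places, tab-separated.
#'
#' @param d Symmetric numeric matrix with identical row/column names.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(d, path) {
  stopifnot(is.matrix(d), !is.null(rownames(d)),
            identical(rownames(d), colnames(d)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rownames(d), collapse = "\t"), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(rownames(d)[i], sprintf("%.6f", d[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' @param path Input file path.
#' @return Symmetric numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  n <- length(ids)
  if (length(lines) != n + 1L) {
    stop("malformed distance matrix file: expected ", n + 1L, " lines",
         call. = FALSE)
  }
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    fields <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (fields[1L] != ids[i]) {
      stop("row identifier '", fields[1L], "' does not match header",
           call. = FALSE)
    }
    m[i, ] <- as.numeric(fields[-1L])
  }
  m
}
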