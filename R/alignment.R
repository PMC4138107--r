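# Pairwise global alignment, percent identity and distance matrices.
#
# Distances feed the neighbor-joining stage: d = 1 - identity/100 on
# pairwise global alignments (Needleman-Wunsch, BLOSUM62, affine gaps,
# identity denominator = full alignment length including gapped columns).

.matrix_cache <- new.env(parent = emptyenv())

#' Read a substitution matrix in NCBI text format
#'
#' Lines starting with `#` are comments; the first non-comment row names the
#' column alphabet, subsequent rows carry the row letter and scores.
#'
#' @param path matrix file.
#' @return integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  alphabet <- fields[[1L]]
  rows <- fields[-1L]
  m <- t(vapply(rows, function(f) as.integer(f[-1L]),
                integer(length(alphabet))))
  rownames(m) <- vapply(rows, `[[`, character(1), 1L)
  colnames(m) <- alphabet
  if (!identical(rownames(m), colnames(m)) || !isSymmetric(unname(m))) {
    stop("malformed substitution matrix: ", path, call. = FALSE)
  }
  m
}

#' The packaged BLOSUM62 matrix
#'
#' @return BLOSUM62 as an integer matrix (half-bit scores).
#' @export
blosum62 <- function() {
  if (is.null(.matrix_cache$blosum62)) {
    .matrix_cache$blosum62 <- read_score_matrix(
      system.file("extdata", "BLOSUM62.txt", package = "ptpscan"))
  }
  .matrix_cache$blosum62
}

#' Optimal pairwise alignment with affine gap penalties
#'
#' Global (Needleman-Wunsch) by default; end gaps are penalized.  A gap of
#' length k costs `gap_open + k * gap_extend`.  A BLAST-style local mode
#' (Smith-Waterman) is available with `type = "local"`, useful when
#' comparing identity values whose alignment protocol is unknown.
#'
#' @param a,b residue strings (non-empty).
#' @param matrix substitution matrix, see [blosum62()].
#' @param gap_open,gap_extend positive gap penalties.
#' @param type `"global"` or `"local"`.
#' @param query_id,subject_id optional sequence labels.
#' @return a `ptp_alignment`: list with `query_id`, `subject_id`,
#'   `aligned_query`, `aligned_subject` (gapped strings of equal length),
#'   `score` and `percent_identity` (identical columns / alignment length,
#'   gapped columns counted in the denominator).
#' @examples
#' global_align("HEAGAWGHEE", "PAWHEAE")$score
#' @export
global_align <- function(a, b, matrix = blosum62(), gap_open = 10,
                         gap_extend = 1, type = c("global", "local"),
                         query_id = "query", subject_id = "subject") {
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  a <- validate_residues(a, context = query_id)
  b <- validate_residues(b, context = subject_id)
  aln <- Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = type)
  qa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  structure(list(query_id = query_id, subject_id = subject_id,
                 aligned_query = qa, aligned_subject = sa,
                 score = Biostrings::score(aln),
                 percent_identity = alignment_identity(qa, sa)),
            class = "ptp_alignment")
}

# identical columns / alignment length * 100 (gapped columns in denominator)
alignment_identity <- function(qa, sa) {
  qc <- strsplit(qa, "", fixed = TRUE)[[1L]]
  sc <- strsplit(sa, "", fixed = TRUE)[[1L]]
  stopifnot(length(qc) == length(sc))
  100 * sum(qc == sc & qc != "-") / length(qc)
}

#' @export
print.ptp_alignment <- function(x, ...) {
  cat(sprintf("%s vs %s: score %.1f, identity %.1f%%\n", x$query_id,
              x$subject_id, x$score, x$percent_identity))
  cat(" ", x$aligned_query, "\n ", x$aligned_subject, "\n")
  invisible(x)
}

#' Percent identity between two sequences
#'
#' @inheritParams global_align
#' @return identity on the 0-100 scale.
#' @export
percent_identity <- function(a, b, matrix = blosum62(), gap_open = 10,
                             gap_extend = 1, type = c("global", "local")) {
  global_align(a, b, matrix, gap_open, gap_extend, type)$percent_identity
}

#' Pairwise identity distance matrix
#'
#' `d[i, j] = 1 - identity(i, j) / 100` on global alignments; symmetric with
#' a zero diagonal.
#'
#' @param seqs named character vector of sequences (unique names, >= 2).
#' @param ... passed to [percent_identity()].
#' @return symmetric numeric matrix with taxon dimnames.
#' @export
build_distance_matrix <- function(seqs, matrix = blosum62(), gap_open = 10,
                                  gap_extend = 1,
                                  type = c("global", "local")) {
  type <- match.arg(type)
  if (length(seqs) < 2L) stop("need >= 2 sequences", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids)) {
    stop("sequences must carry unique non-empty ids", call. = FALSE)
  }
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    # one batched alignment call per row keeps large families fast
    aln <- Biostrings::pairwiseAlignment(
      unname(seqs[(i + 1L):n]), seqs[[i]], substitutionMatrix = matrix,
      gapOpening = gap_open, gapExtension = gap_extend, type = type)
    # identical columns over all alignment columns, gaps included
    pid <- 100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
    d[i, (i + 1L):n] <- 1 - pid / 100
    d[(i + 1L):n, i] <- d[i, (i + 1L):n]
  }
  d
}

#' Write / read a distance matrix in PHYLIP square format
#'
#' First line: number of taxa; then one row per taxon (name, values).
#' Names longer than the classic 10 characters are written as-is and
#' separated from the values by whitespace.
#'
#' @param d symmetric matrix with dimnames.
#' @param path output file.
#' @return `read_phylip_dist()` returns the matrix.
#' @export
write_phylip_dist <- function(d, path) {
  n <- nrow(d)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste(formatC(rownames(d)[i], width = -12),
                     paste(sprintf("%.6f", d[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  fields <- strsplit(trimws(lines[1L + seq_len(n)]), "\\s+")
  ids <- vapply(fields, `[[`, character(1), 1L)
  d <- t(vapply(fields, function(f) as.numeric(f[-1L]), numeric(n)))
  dimnames(d) <- list(ids, ids)
  d
}
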