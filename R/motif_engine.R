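# Motif grammar: the ten classical-PTP motifs and the catalytic-competence
# calls for the four active-site motifs (1 = KNRY loop, 8 = WPD loop,
# 9 = P-loop/HCX5R, 10 = Q loop).
#
# The competence patterns are data, not code: they ship in
# inst/extdata/ptp_motifs.tsv and were chosen to separate exactly the ACTIVE
# from the INACTIVE motif strings of the published A. aegypti catalytic-motif
# table, which is the regression surface for the grammar.

#' Load the PTP motif registry
#'
#' Reads a tab-separated motif-definition file with columns `motif_id`,
#' `name`, `role`, `active_pattern`, `relaxed_pattern`, `offset`, `tolerance`
#' and `template_seq`.  Patterns are POSIX/PCRE character-class expressions
#' over the amino-acid alphabet.  `offset` is the expected start of the motif
#' relative to the catalytic P-loop cysteine (signed residues) and
#' `tolerance` the half-width of the search window used by the domain
#' scanner.  The packaged default defines the classical-PTP grammar: motifs
#' 1, 8, 9, 10 are active-site motifs; motifs 2-7 are core motifs used only
#' for domain anchoring.
#'
#' @param path motif-definition TSV; defaults to the packaged registry.
#' @return a `ptp_motif_registry` data frame with exactly ten rows.
#' @examples
#' reg <- load_motif_registry()
#' reg[reg$role == "active_site", c("motif_id", "name")]
#' @export
load_motif_registry <- function(path = system.file("extdata", "ptp_motifs.tsv",
                                                   package = "ptpscan")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("motif-definition file not found: ", path, call. = FALSE)
  }
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("motif_id", "name", "role", "active_pattern",
                "relaxed_pattern", "offset", "tolerance", "template_seq")
  missing <- setdiff(required, names(reg))
  if (length(missing)) {
    stop("motif registry lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(reg) != 10L || anyDuplicated(reg$motif_id) ||
      !setequal(reg$motif_id, 1:10)) {
    stop("motif registry must define exactly the ten motifs 1..10",
         call. = FALSE)
  }
  active_ids <- sort(reg$motif_id[reg$role == "active_site"])
  if (!identical(active_ids, c(1L, 8L, 9L, 10L)) ||
      !all(reg$role[reg$motif_id %in% 2:7] == "core")) {
    stop("motifs 1, 8, 9, 10 must have role 'active_site' and 2..7 'core'",
         call. = FALSE)
  }
  reg <- reg[order(reg$motif_id), , drop = FALSE]
  rownames(reg) <- NULL
  class(reg) <- c("ptp_motif_registry", "data.frame")
  reg
}

motif_row <- function(registry, motif_id) {
  registry[registry$motif_id == motif_id, , drop = FALSE]
}

new_motif_call <- function(motif_id, observed_sequence, start, status) {
  structure(list(motif_id = as.integer(motif_id),
                 observed_sequence = observed_sequence,
                 start = start,
                 status = status),
            class = "ptp_motif_call")
}

#' @export
print.ptp_motif_call <- function(x, ...) {
  cat(sprintf("motif %d: %s  [%s]\n", x$motif_id,
              if (nzchar(x$observed_sequence)) x$observed_sequence else "<absent>",
              x$status))
  invisible(x)
}

#' Call catalytic competence of an isolated motif region
#'
#' Decides whether a motif-region sequence is catalytically competent
#' (`ACTIVE`), present but degenerate (`INACTIVE`) or missing (`ABSENT`,
#' returned only for the empty string).  Calls are case-insensitive and
#' deterministic.  A region shorter than the pattern's minimal span is
#' `INACTIVE`, not an error, because published tables print truncated
#' degenerate motifs.  Ambiguity codes B/Z/X are accepted but can never
#' satisfy an anchor position; any other non-amino-acid character raises an
#' invalid-residue error naming the character.
#'
#' Competence rules of the packaged grammar:
#' \describe{
#'   \item{motif 1 (KNRY loop)}{a basic residue \code{[KR]}, up to two
#'     arbitrary residues, \code{R}, up to one arbitrary residue, then an
#'     aromatic \code{[YF]}.}
#'   \item{motif 8 (WPD loop)}{the contiguous \code{WPD} triad (general-acid
#'     aspartate in place).}
#'   \item{motif 9 (P-loop/HCX5R)}{\code{HCSAG[IVLM]GR}: the nucleophilic
#'     cysteine inside a C-x5-R frame with the PTP-specific SAG context.}
#'   \item{motif 10 (Q loop)}{a nine-residue window carrying glutamine at
#'     relative positions 2 and 6.}
#' }
#'
#' @param region residue string (possibly empty).
#' @param motif_id integer in 1..10.
#' @param registry a motif registry, see [load_motif_registry()].
#' @return a `ptp_motif_call`: list with `motif_id`, `observed_sequence`,
#'   `start` (0-based match offset within `region`, `NA` when absent) and
#'   `status`.
#' @examples
#' call_motif1("NLNKNRY")$status    # "ACTIVE"
#' call_motif8("LWPKQSA")$status    # "INACTIVE" (WP present, no D)
#' call_motif9("PIIHCSAGIGRSGT")$status
#' call_motif10("")$status          # "ABSENT"
#' @export
call_motif <- function(region, motif_id, registry = load_motif_registry()) {
  stopifnot(motif_id %in% registry$motif_id)
  if (is.na(region)) region <- ""
  if (!nzchar(region)) {
    return(new_motif_call(motif_id, "", NA_integer_, "ABSENT"))
  }
  region <- validate_residues(region, allow_ambiguous = TRUE,
                              context = sprintf("motif %d region", motif_id))
  def <- motif_row(registry, motif_id)
  m <- regexpr(def$active_pattern, region, perl = TRUE)
  if (m[1L] != -1L) {
    new_motif_call(motif_id, region, as.integer(m) - 1L, "ACTIVE")
  } else {
    new_motif_call(motif_id, region, 0L, "INACTIVE")
  }
}

#' @rdname call_motif
#' @export
call_motif1 <- function(region, registry = load_motif_registry()) {
  call_motif(region, 1L, registry)
}

#' @rdname call_motif
#' @export
call_motif8 <- function(region, registry = load_motif_registry()) {
  call_motif(region, 8L, registry)
}

#' @rdname call_motif
#' @export
call_motif9 <- function(region, registry = load_motif_registry()) {
  call_motif(region, 9L, registry)
}

#' @rdname call_motif
#' @export
call_motif10 <- function(region, registry = load_motif_registry()) {
  call_motif(region, 10L, registry)
}

#' Published catalytic-motif table for the A. aegypti classical PTPs
#'
#' Returns the packaged table of active-site motif strings and their printed
#' per-motif and per-domain verdicts for the ten A. aegypti classical-PTP
#' proteins.  This table is the regression surface for the motif grammar:
#' applied to every printed motif string, [call_motif()] reproduces every
#' printed status.
#'
#' @return data frame, one row per PTP domain.
#' @export
table1_motifs <- function() {
  path <- system.file("extdata", "table1_motifs.tsv", package = "ptpscan")
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = character(0))
}
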