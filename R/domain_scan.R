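# Motif-constellation domain scanner.
#
# Candidate P-loop anchors are (i) every occurrence of the relaxed C-x5-R
# frame and (ii) anchors predicted from clusters of core-motif matches (which
# rescues domains whose catalytic cysteine has been lost).  For each anchor
# the ten motifs are searched in offset windows taken from the registry; a
# candidate locating >= `min_located` of the ten motifs, including a located
# P-loop region, is a WELL_FORMED domain.  Core-motif clusters that fail the
# constellation test and contain no C-x5-R frame are reported as DEGENERATE
# ("absent") domains, the pseudophosphatase signature.

#' Construct a protein record
#'
#' @param accession protein accession (e.g. `AAEL001919-PA`); the gene id is
#'   the accession with a trailing splice suffix (`-PA`, `-PB`, ...) removed.
#' @param sequence residue string, alphabet = 20 amino acids + X.
#' @param description free-text description.
#' @return a `ptp_protein` list with fields `accession`, `gene_id`,
#'   `sequence`, `description`.
#' @export
protein_record <- function(accession, sequence, description = "") {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession))
  sequence <- validate_residues(sequence, allow_ambiguous = TRUE,
                                context = accession)
  if (!nzchar(sequence)) stop("empty sequence for ", accession, call. = FALSE)
  structure(list(accession = accession,
                 gene_id = strip_splice_suffix(accession),
                 sequence = sequence,
                 description = description),
            class = "ptp_protein")
}

#' Strip the splice-variant suffix from a protein accession
#'
#' `AAEL001919-PA` and `AAEL001919-PB` are alternative products of the same
#' gene locus; both map to gene id `AAEL001919`.
#'
#' @param accession character vector of accessions.
#' @return character vector of gene ids (always a prefix of the accession).
#' @export
strip_splice_suffix <- function(accession) {
  sub("-P[A-Z]$", "", accession)
}

#' Read a proteome from FASTA
#'
#' Wrapped or unwrapped FASTA with `>accession description` headers.
#'
#' @param path FASTA file.
#' @return list of [protein_record()] objects, in file order.
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA: ", path, call. = FALSE)
  headers <- names(set)
  acc <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  lapply(seq_along(set), function(i) {
    protein_record(acc[i], as.character(set[[i]]), desc[i])
  })
}

#' Domain-scanner tuning parameters
#'
#' @param min_located minimum number of located motifs (of ten) for a
#'   WELL_FORMED call.
#' @param pad_upstream,pad_downstream boundary padding (residues) applied
#'   before the most upstream / after the most downstream located motif.
#' @param cluster_gap maximum spacing (residues) between consecutive
#'   core-motif matches grouped into one constellation cluster.
#' @param core_min minimum number of distinct core motifs for a DEGENERATE
#'   call or a predicted anchor.
#' @param anchor_dedupe predicted anchors closer than this to a C-x5-R
#'   anchor are dropped as duplicates.
#' @return list of scanner settings.
#' @export
scan_params <- function(min_located = 5L, pad_upstream = 30L,
                        pad_downstream = 20L, cluster_gap = 80L,
                        core_min = 2L, anchor_dedupe = 15L) {
  list(min_located = min_located, pad_upstream = pad_upstream,
       pad_downstream = pad_downstream, cluster_gap = cluster_gap,
       core_min = core_min, anchor_dedupe = anchor_dedupe)
}

PLOOP_FRAME <- "C.{5}R"

# All core-motif matches over the full sequence.
core_motif_hits <- function(seq, registry) {
  cores <- registry[registry$role == "core", , drop = FALSE]
  hits <- lapply(seq_len(nrow(cores)), function(i) {
    m <- regex_matches(cores$active_pattern[i], seq)
    if (nrow(m) == 0L) return(NULL)
    data.frame(motif_id = cores$motif_id[i], start = m$start,
               end = m$start + m$length - 1L)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- data.frame(motif_id = integer(0), start = integer(0),
                       end = integer(0))
  }
  hits[order(hits$start, hits$motif_id), , drop = FALSE]
}

# Group core hits into clusters by consecutive spacing.
cluster_core_hits <- function(hits, gap) {
  if (nrow(hits) == 0L) return(list())
  brk <- c(0L, which(diff(hits$start) > gap), nrow(hits))
  lapply(seq_len(length(brk) - 1L), function(i) {
    hits[(brk[i] + 1L):brk[i + 1L], , drop = FALSE]
  })
}

# Predicted anchor position of a cluster: mean of (match start - offset).
predict_anchor <- function(cluster, registry) {
  off <- registry$offset[match(cluster$motif_id, registry$motif_id)]
  as.integer(round(mean(cluster$start - off)))
}

# Search one motif in its offset window around anchor `a`.  Among multiple
# matches the one closest to the expected position is kept (ties: leftmost).
locate_motif <- function(seq, n, a, def, frame_anchors) {
  w_start <- max(1L, a + def$offset - def$tolerance)
  w_end <- min(n, a + def$offset + def$tolerance + 20L)
  if (w_start > w_end) {
    return(list(located = FALSE, status = "ABSENT", seq = "",
                start = NA_integer_, end = NA_integer_))
  }
  window <- substr(seq, w_start, w_end)
  expected <- a + def$offset
  pick <- function(m) {
    abs_start <- w_start + m$start - 1L
    i <- order(abs(abs_start - expected), abs_start)[1L]
    list(start = abs_start[i], end = abs_start[i] + m$length[i] - 1L,
         seq = substr(seq, abs_start[i], abs_start[i] + m$length[i] - 1L))
  }
  m <- regex_matches(def$active_pattern, window)
  if (nrow(m)) {
    hit <- pick(m)
    return(list(located = TRUE, status = "ACTIVE", seq = hit$seq,
                start = hit$start, end = hit$end))
  }
  m <- regex_matches(def$relaxed_pattern, window)
  if (nrow(m)) {
    hit <- pick(m)
    return(list(located = TRUE, status = "INACTIVE", seq = hit$seq,
                start = hit$start, end = hit$end))
  }
  if (def$motif_id == 9L) {
    near <- frame_anchors[frame_anchors >= a - 16L & frame_anchors <= a + 10L]
    if (length(near)) {
      fs <- near[1L]
      return(list(located = TRUE, status = "INACTIVE",
                  seq = substr(seq, fs, min(n, fs + 6L)),
                  start = fs, end = min(n, fs + 6L)))
    }
  }
  list(located = FALSE, status = "ABSENT", seq = "", start = NA_integer_,
       end = NA_integer_)
}

empty_annotation <- function() {
  cols <- c("accession", "gene_id", "start", "end", "presence", "anchor",
            "n_motifs_located",
            paste0("m", 1:10, "_status"),
            paste0("m", c(1, 8, 9, 10), "_seq"),
            paste0("m", c(1, 8, 9, 10), "_start"),
            "verdict")
  out <- as.data.frame(matrix(nrow = 0L, ncol = length(cols)),
                       stringsAsFactors = FALSE)
  names(out) <- cols
  out$start <- integer(0); out$end <- integer(0)
  out$anchor <- integer(0); out$n_motifs_located <- integer(0)
  out
}

#' Scan one protein for classical-PTP domains
#'
#' Locates candidate PTP domains (including degenerate "absent" domains) by
#' motif-constellation search and emits one annotation per domain with
#' 1-based inclusive boundaries, presence class (`WELL_FORMED` or
#' `DEGENERATE`), the per-motif statuses and the observed active-site motif
#' sequences.  The `verdict` column is left `NA`; fill it with
#' [classify_annotations()].
#'
#' @param record a [protein_record()].
#' @param registry motif registry, see [load_motif_registry()].
#' @param params scanner settings, see [scan_params()].
#' @return data frame of domain annotations ordered by start (zero rows when
#'   no domain is found).
#' @export
scan_protein <- function(record, registry = load_motif_registry(),
                         params = scan_params()) {
  if (!inherits(record, "ptp_protein")) {
    record <- protein_record(record$accession, record$sequence,
                             record$description %||% "")
  }
  if (nrow(registry) == 0L) stop("empty motif registry", call. = FALSE)
  seq <- record$sequence
  n <- nchar(seq)

  frame_anchors <- regex_matches(PLOOP_FRAME, seq, overlapping = TRUE)$start
  cores <- core_motif_hits(seq, registry)
  clusters <- cluster_core_hits(cores, params$cluster_gap)
  clusters <- Filter(function(cl) length(unique(cl$motif_id)) >= params$core_min,
                     clusters)
  predicted <- vapply(clusters, predict_anchor, integer(1), registry = registry)
  predicted <- predicted[predicted >= 1L & predicted <= n]
  keep <- vapply(predicted, function(p) {
    !length(frame_anchors) || min(abs(frame_anchors - p)) > params$anchor_dedupe
  }, logical(1))
  anchors <- sort(unique(c(frame_anchors, predicted[keep])))

  candidates <- lapply(anchors, function(a) {
    locs <- lapply(seq_len(nrow(registry)), function(i) {
      locate_motif(seq, n, a, registry[i, , drop = FALSE], frame_anchors)
    })
    names(locs) <- as.character(registry$motif_id)
    located <- vapply(locs, `[[`, logical(1), "located")
    n_loc <- sum(located)
    if (n_loc < params$min_located || !located[["9"]]) return(NULL)
    s_ref <- if (located[["1"]]) locs[["1"]]$start
             else if (located[["8"]]) locs[["8"]]$start else a - 60L
    e_ref <- if (located[["10"]]) locs[["10"]]$end else a + 20L
    list(anchor = a, n_loc = n_loc, locs = locs,
         start = max(1L, s_ref - params$pad_upstream),
         end = min(n, e_ref + params$pad_downstream))
  })
  candidates <- Filter(Negate(is.null), candidates)

  # Overlap resolution: most located motifs wins, ties to the leftmost start.
  ord <- order(-vapply(candidates, `[[`, integer(1), "n_loc"),
               vapply(candidates, `[[`, integer(1), "start"),
               vapply(candidates, `[[`, integer(1), "anchor"))
  accepted <- list()
  spans <- matrix(integer(0), ncol = 2L)
  for (cand in candidates[ord]) {
    if (nrow(spans) == 0L ||
        all(cand$end < spans[, 1L] | cand$start > spans[, 2L])) {
      accepted[[length(accepted) + 1L]] <- cand
      spans <- rbind(spans, c(cand$start, cand$end))
    }
  }

  rows <- lapply(accepted, function(cand) {
    locs <- cand$locs
    st <- vapply(as.character(1:10), function(id) locs[[id]]$status,
                 character(1))
    names(st) <- paste0("m", 1:10, "_status")
    # core motifs carry presence, not competence
    st[paste0("m", 2:7, "_status")] <-
      ifelse(st[paste0("m", 2:7, "_status")] == "ABSENT", "ABSENT", "PRESENT")
    data.frame(accession = record$accession, gene_id = record$gene_id,
               start = cand$start, end = cand$end, presence = "WELL_FORMED",
               anchor = cand$anchor, n_motifs_located = cand$n_loc,
               as.list(st),
               m1_seq = locs[["1"]]$seq, m8_seq = locs[["8"]]$seq,
               m9_seq = locs[["9"]]$seq, m10_seq = locs[["10"]]$seq,
               m1_start = locs[["1"]]$start, m8_start = locs[["8"]]$start,
               m9_start = locs[["9"]]$start, m10_start = locs[["10"]]$start,
               verdict = NA_character_, stringsAsFactors = FALSE)
  })

  # Degenerate pass: unclaimed core clusters without any P-loop frame.
  inside_accepted <- function(pos) {
    nrow(spans) > 0L && any(pos >= spans[, 1L] & pos <= spans[, 2L])
  }
  free <- cores[!vapply(cores$start, inside_accepted, logical(1)), ,
                drop = FALSE]
  for (cl in cluster_core_hits(free, params$cluster_gap)) {
    if (length(unique(cl$motif_id)) < params$core_min) next
    cs <- min(cl$start); ce <- max(cl$end)
    if (any(frame_anchors >= cs & frame_anchors <= ce)) next
    d_start <- max(1L, cs - params$pad_upstream)
    d_end <- min(n, ce + params$pad_downstream)
    if (nrow(spans) > 0L &&
        any(!(d_end < spans[, 1L] | d_start > spans[, 2L]))) next
    st <- stats::setNames(rep("ABSENT", 10L), paste0("m", 1:10, "_status"))
    st[paste0("m", cl$motif_id, "_status")] <- "PRESENT"
    rows[[length(rows) + 1L]] <-
      data.frame(accession = record$accession, gene_id = record$gene_id,
                 start = d_start, end = d_end, presence = "DEGENERATE",
                 anchor = NA_integer_,
                 n_motifs_located = length(unique(cl$motif_id)),
                 as.list(st),
                 m1_seq = "", m8_seq = "", m9_seq = "", m10_seq = "",
                 m1_start = NA_integer_, m8_start = NA_integer_,
                 m9_start = NA_integer_, m10_start = NA_integer_,
                 verdict = NA_character_, stringsAsFactors = FALSE)
    spans <- rbind(spans, c(d_start, d_end))
  }

  if (!length(rows)) return(empty_annotation())
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of proteins
#'
#' Concatenation of [scan_protein()] outputs in stable input order.
#'
#' @param records list of [protein_record()]s (duplicate accessions are a
#'   validation error).
#' @param registry,params see [scan_protein()].
#' @param verbose log per-protein domain counts.
#' @return combined annotation data frame.
#' @export
scan_proteome <- function(records, registry = load_motif_registry(),
                          params = scan_params(), verbose = FALSE) {
  if (length(records) == 0L) return(empty_annotation())
  acc <- vapply(records, function(r) r$accession, character(1))
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  anns <- lapply(records, function(r) {
    ann <- scan_protein(r, registry, params)
    if (verbose) {
      message(sprintf("%s: %d domain(s)", r$accession, nrow(ann)))
    }
    ann
  })
  out <- do.call(rbind, anns)
  rownames(out) <- NULL
  out
}

#' Write / read a domain-annotation report
#'
#' Tab-separated, one row per domain, 1-based inclusive coordinates.
#'
#' @param annotations annotation data frame from [scan_proteome()].
#' @param path output TSV.
#' @return `read_annotations()` returns the annotation data frame.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA")
  for (col in grep("_seq$", names(ann), value = TRUE)) {
    ann[[col]][is.na(ann[[col]])] <- ""
  }
  ann
}
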