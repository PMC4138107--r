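# End-to-end drivers: configuration, the annotate/tree/expression/simulate
# commands, and provenance logging (config hash, seed, input digests).

#' Pipeline configuration
#'
#' Every field has a packaged default that reproduces the fixture results.
#' The configuration serializes to a single human-readable YAML file with
#' [save_config()] / [load_config()].
#'
#' @param motif_file motif-definition TSV (see [load_motif_registry()]).
#' @param scan scanner settings, see [scan_params()].
#' @param gap_open,gap_extend affine gap penalties for pairwise alignment.
#' @param alignment_type `"global"` or `"local"`.
#' @param nj_clamp clamp negative neighbor-joining branch estimates.
#' @param ddct_mode `"pfaffl"` (efficiency-corrected) or `"classic"`
#'   (`2^(-ddCt)`).
#' @param exclusions_file gene exclusion TSV, `NULL` for none.
#' @param seed integer seed for seeded commands.
#' @return a `ptp_config` list.
#' @export
ptp_config <- function(motif_file = system.file("extdata", "ptp_motifs.tsv",
                                                package = "ptpscan"),
                       scan = scan_params(),
                       gap_open = 10, gap_extend = 1,
                       alignment_type = "global",
                       nj_clamp = TRUE,
                       ddct_mode = "pfaffl",
                       exclusions_file = system.file(
                         "extdata", "exclusions_default.tsv",
                         package = "ptpscan"),
                       seed = 1L) {
  structure(list(motif_file = motif_file, scan = scan, gap_open = gap_open,
                 gap_extend = gap_extend, alignment_type = alignment_type,
                 nj_clamp = nj_clamp, ddct_mode = ddct_mode,
                 exclusions_file = exclusions_file, seed = seed),
            class = "ptp_config")
}

#' @rdname ptp_config
#' @param config a `ptp_config`.
#' @param path YAML file.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname ptp_config
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- ptp_config()
  for (k in names(y)) cfg[[k]] <- y[[k]]
  cfg
}

log_provenance <- function(cmd, config, inputs, log_level = "info") {
  if (identical(log_level, "quiet")) return(invisible(NULL))
  message(sprintf("[%s] config %s seed %s", cmd, digest_object(unclass(config)),
                  config$seed))
  for (f in inputs) {
    if (file.exists(f)) message(sprintf("[%s] input %s %s", cmd, f,
                                        digest_file(f)))
  }
  invisible(NULL)
}

#' Annotate a proteome FASTA
#'
#' Drives the full in-silico stage: FASTA in, domain scan, motif grammar,
#' domain verdicts, gene-level repertoire.  Writes `annotations.tsv`,
#' `repertoire.tsv` and `summary.txt` under `out_dir` and prints the summary.
#'
#' @param fasta proteome FASTA path.
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @param config a [ptp_config()].
#' @param log_level `"info"` or `"quiet"`.
#' @return (invisibly) list with `annotations`, `repertoire`.
#' @export
cmd_annotate <- function(fasta, out_dir = NULL, config = ptp_config(),
                         log_level = "info") {
  log_provenance("annotate", config, fasta, log_level)
  records <- read_proteome(fasta)
  registry <- load_motif_registry(config$motif_file)
  ann <- scan_proteome(records, registry, config$scan,
                       verbose = !identical(log_level, "quiet"))
  ann <- classify_annotations(ann)
  exclusions <- if (!is.null(config$exclusions_file) &&
                    nzchar(config$exclusions_file)) {
    read_exclusions(config$exclusions_file)
  }
  rep <- summarize_repertoire(ann, exclusions,
                              proteins = vapply(records, `[[`, character(1),
                                                "accession"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_annotations(ann, file.path(out_dir, "annotations.tsv"))
    write_repertoire(rep, file.path(out_dir, "repertoire.tsv"))
    writeLines(repertoire_summary_lines(rep),
               file.path(out_dir, "summary.txt"))
  }
  cat(paste(repertoire_summary_lines(rep), collapse = "\n"), "\n")
  invisible(list(annotations = ann, repertoire = rep))
}

#' Distance matrix and neighbor-joining tree from a FASTA
#'
#' Pairwise global-alignment identity distances, then neighbor joining.
#' Two sequences serialize as the trivial single-edge tree.  Writes
#' `tree.nwk` (Newick, branch lengths, no internal labels) and `dist.phy`
#' (PHYLIP square) under `out_dir`.
#'
#' @param fasta FASTA of >= 2 sequences with unique ids.
#' @param out_dir output directory; `NULL` to skip writing.
#' @param config a [ptp_config()].
#' @param log_level `"info"` or `"quiet"`.
#' @return (invisibly) list with `tree` (`ape::phylo`, or `NULL` for the
#'   two-taxon case where only Newick text is produced), `newick`, `dist`.
#' @export
cmd_tree <- function(fasta, out_dir = NULL, config = ptp_config(),
                     log_level = "info") {
  log_provenance("tree", config, fasta, log_level)
  records <- read_proteome(fasta)
  ids <- vapply(records, `[[`, character(1), "accession")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (length(ids) < 2L) stop("need >= 2 sequences", call. = FALSE)
  seqs <- stats::setNames(vapply(records, `[[`, character(1), "sequence"),
                          ids)
  d <- build_distance_matrix(seqs, gap_open = config$gap_open,
                             gap_extend = config$gap_extend,
                             type = config$alignment_type)
  if (length(ids) == 2L) {
    tree <- NULL
    newick <- sprintf("(%s:%.10g,%s:%.10g);", ids[1L], d[1L, 2L] / 2,
                      ids[2L], d[1L, 2L] / 2)
  } else {
    tree <- neighbor_joining(d, clamp_negative = config$nj_clamp)
    newick <- ape::write.tree(tree)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(newick, file.path(out_dir, "tree.nwk"))
    write_phylip_dist(d, file.path(out_dir, "dist.phy"))
  }
  invisible(list(tree = tree, newick = newick, dist = d))
}

#' Relative-expression analysis of a Ct table
#'
#' Efficiency-corrected comparative-Ct ratios for every non-reference gene,
#' plus a one-way ANOVA on replicate dCt values across conditions per gene
#' (dCt = target Ct - reference Ct within the same sample/replicate).
#' Writes `ratios.csv` and `stats.tsv` under `out_dir`.
#'
#' @param ct_csv Ct table CSV (see [read_ct_table()]).
#' @param calibrator calibrator condition (always explicit: baselines
#'   differ between experimental designs).
#' @param reference reference gene (default the rp49 housekeeping gene).
#' @param out_dir output directory; `NULL` to skip writing.
#' @param config a [ptp_config()].
#' @param log_level `"info"` or `"quiet"`.
#' @return (invisibly) list with `ratios` and `stats` data frames.
#' @export
cmd_expression <- function(ct_csv, calibrator, reference = "rp49",
                           out_dir = NULL, config = ptp_config(),
                           log_level = "info") {
  log_provenance("expression", config, ct_csv, log_level)
  ct <- read_ct_table(ct_csv)
  validate_ct(ct)
  targets <- setdiff(unique(ct$gene), reference)
  if (!length(targets)) stop("no target genes in table", call. = FALSE)
  ratios <- do.call(rbind, lapply(targets, function(g) {
    relative_expression(ct, g, reference, calibrator,
                        mode = config$ddct_mode)
  }))
  stats_rows <- lapply(targets, function(g) {
    dct <- lapply(unique(ct$condition), function(cond) {
      t_ct <- ct[ct$gene == g & ct$condition == cond, ]
      r_ct <- ct[ct$gene == reference & ct$condition == cond, ]
      t_ct$ct - r_ct$ct[match(t_ct$replicate, r_ct$replicate)]
    })
    dct <- Filter(function(x) length(x) >= 2L, dct)
    if (length(dct) < 2L) return(NULL)
    a <- one_way_anova(dct)
    data.frame(gene = g, test = "one_way_anova_dCt",
               statistic = a$statistic, df1 = a$df[["df1"]],
               df2 = a$df[["df2"]], p_value = a$p.value,
               stringsAsFactors = FALSE)
  })
  stats_df <- do.call(rbind, stats_rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(ratios, file.path(out_dir, "ratios.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(stats_df)) {
      utils::write.table(stats_df, file.path(out_dir, "stats.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(list(ratios = ratios, stats = stats_df))
}

#' Emit a synthetic dataset with its truth sidecar
#'
#' @param preset one of `"proteome"`, `"table1"`, `"family"`, `"ct"`,
#'   `"eggs"`.
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param ... forwarded to the corresponding generator.
#' @return (invisibly) the generator output.
#' @export
cmd_simulate <- function(preset, out_dir, seed = 1L, ...) {
  presets <- c("proteome", "table1", "family", "ct", "eggs")
  if (!preset %in% presets) {
    stop("unknown preset '", preset, "'; choose one of ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(preset,
    proteome = ,
    table1 = {
      x <- make_proteome(seed = seed,
                         preset = if (preset == "table1") "table1"
                                  else "random", ...)
      write_fasta(x$sequences, file.path(out_dir, "proteome.fasta"))
      write_truth(x$truth, file.path(out_dir, "proteome_truth.yaml"))
      x
    },
    family = {
      x <- make_family(seed = seed, ...)
      write_fasta(x$sequences, file.path(out_dir, "family.fasta"))
      writeLines(ape::write.tree(x$tree), file.path(out_dir,
                                                    "family_truth.nwk"))
      x
    },
    ct = {
      x <- make_ct_table(seed = seed, ...)
      utils::write.csv(x$table, file.path(out_dir, "ct_table.csv"),
                       row.names = FALSE, quote = FALSE)
      write_truth(x$truth, file.path(out_dir, "ct_truth.yaml"))
      x
    },
    eggs = {
      x <- make_egg_table(seed = seed, ...)
      utils::write.csv(x$table, file.path(out_dir, "egg_table.csv"),
                       row.names = FALSE, quote = FALSE)
      write_truth(x$truth, file.path(out_dir, "egg_truth.yaml"))
      x
    })
  invisible(out)
}
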