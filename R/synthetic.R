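# Seeded synthetic data with known ground truth: proteomes with planted PTP
# domain cassettes, sequence families evolved on known trees, qPCR Ct tables
# and egg-count tables.  All randomness flows from the single `seed`
# argument; the same seed reproduces byte-identical output.
#
# Well-formed cassettes embed the ten motif template strings at their
# canonical offsets from the catalytic cysteine (KNRY loop ~170 residues
# upstream, WPD loop ~40 upstream, Q loop ~50 downstream), separated by
# random linkers; lesions (anchor-residue mutation, whole-motif omission)
# realize intended per-motif statuses.  Degenerate ("absent domain")
# cassettes carry core motifs only and are cysteine-free so that they can
# never present a P-loop frame.  Background residue composition is uniform
# over the 20 residues, which keeps false motif-hit rates analytically
# estimable.

random_aa <- function(n, exclude = NULL) {
  pool <- setdiff(AA20, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# Replace the anchor residue of an active-site motif with a neutral one.
mutate_anchor <- function(motif_id, s) {
  switch(as.character(motif_id),
         "1" = {          # last aromatic -> S
           pos <- max(gregexpr("[YF]", s)[[1L]])
           substr(s, pos, pos) <- "S"; s
         },
         "8" = sub("WPD", "WPG", s, fixed = TRUE),
         "9" = sub("HC", "HS", s, fixed = TRUE),
         "10" = sub("Q", "L", s, fixed = TRUE),
         stop("no lesion defined for motif ", motif_id, call. = FALSE))
}

CASSETTE_UPSTREAM <- 180L    # residues before the anchor cysteine
CASSETTE_DOWNSTREAM <- 64L   # residues after it

# Build one well-formed domain cassette.
#   motif_seqs: named list "1".."10"; NULL entries fall back to the registry
#     template, NA entries omit the motif entirely.
#   lesions: active-site motif ids whose anchor residue is mutated.
# Returns list(seq, truth = named statuses for motifs 1, 8, 9, 10).
build_cassette <- function(registry, motif_seqs = list(), lesions = integer(0),
                           cys_free_linkers = FALSE) {
  len <- CASSETTE_UPSTREAM + CASSETTE_DOWNSTREAM + 1L
  anchor_idx <- CASSETTE_UPSTREAM + 1L
  chars <- strsplit(random_aa(len, exclude = if (cys_free_linkers) "C"),
                    "")[[1L]]
  truth <- stats::setNames(rep("ABSENT", 4L), c("1", "8", "9", "10"))
  for (i in seq_len(nrow(registry))) {
    id <- registry$motif_id[i]
    key <- as.character(id)
    s <- if (!is.null(motif_seqs[[key]])) motif_seqs[[key]]
         else registry$template_seq[i]
    if (length(s) == 1L && is.na(s)) next
    if (id %in% lesions) s <- mutate_anchor(id, s)
    at <- anchor_idx + registry$offset[i]
    stopifnot(at >= 1L, at + nchar(s) - 1L <= len)
    chars[at:(at + nchar(s) - 1L)] <- strsplit(s, "")[[1L]]
    if (key %in% names(truth)) {
      truth[key] <- if (grepl(registry$active_pattern[i], s, perl = TRUE))
        "ACTIVE" else "INACTIVE"
    }
  }
  list(seq = paste(chars, collapse = ""), truth = truth)
}

# Degenerate cassette: core motifs 3, 4, 5 at template-consistent spacing,
# cysteine-free background, no active-site motifs at all.
build_degenerate_cassette <- function(registry, len = 90L) {
  stopifnot(len >= 60L)
  chars <- strsplit(random_aa(len, exclude = "C"), "")[[1L]]
  at <- c(`3` = 8L, `4` = 33L, `5` = 53L)
  for (key in names(at)) {
    s <- registry$template_seq[registry$motif_id == as.integer(key)]
    chars[at[[key]]:(at[[key]] + nchar(s) - 1L)] <- strsplit(s, "")[[1L]]
  }
  list(seq = paste(chars, collapse = ""),
       truth = stats::setNames(rep("ABSENT", 4L), c("1", "8", "9", "10")))
}

#' Generator settings for synthetic proteomes
#'
#' @param flank_len min/max random flank length around cassettes.
#' @param domain_probs probabilities of 0, 1 and 2 planted domains per
#'   protein.
#' @param type_probs probabilities of cassette types: `active` (all motifs
#'   intact), `lesioned` (anchor-residue mutations, by default 1-2 random
#'   active-site motifs with at least one of the catalytic motifs 8/9/10),
#'   `degenerate` (core motifs only, the pseudophosphatase/"absent domain"
#'   signature).
#' @param lesion_motifs `NULL` for the random default, or a fixed vector of
#'   active-site motif ids (from 1, 8, 9, 10) mutated in every lesioned
#'   cassette.
#' @return list of settings.
#' @export
proteome_config <- function(flank_len = c(60L, 150L),
                            domain_probs = c(0.15, 0.65, 0.20),
                            type_probs = c(active = 0.5, lesioned = 0.3,
                                           degenerate = 0.2),
                            lesion_motifs = NULL) {
  stopifnot(length(domain_probs) == 3L, abs(sum(domain_probs) - 1) < 1e-9,
            abs(sum(type_probs) - 1) < 1e-9)
  if (!is.null(lesion_motifs) &&
      !all(lesion_motifs %in% c(1L, 8L, 9L, 10L))) {
    stop("lesion_motifs must name active-site motifs (1, 8, 9, 10)",
         call. = FALSE)
  }
  list(flank_len = flank_len, domain_probs = domain_probs,
       type_probs = type_probs, lesion_motifs = lesion_motifs)
}

#' Generate a synthetic proteome with planted PTP domains
#'
#' Each protein is random flanks plus 0-2 planted domain cassettes; the
#' returned truth records every planted domain's coordinates, presence class
#' and intended per-motif statuses.  `preset = "table1"` emits the packaged
#' ten-protein fixture whose domain counts and active-site motif content
#' mirror the published A. aegypti catalytic-motif table: 10 proteins over 8
#' gene loci, 13 domains, the printed motif strings planted verbatim.
#'
#' @param n_proteins number of proteins (`preset = "random"`).
#' @param config see [proteome_config()].
#' @param seed integer seed; same seed, same bytes.
#' @param preset `"random"` or `"table1"`.
#' @param registry motif registry.
#' @return a `ptp_synthetic_proteome`: list with `sequences` (named
#'   character), `truth` (list: `seed`, `domains` data frame with columns
#'   `accession`, `domain_index`, `start`, `end`, `presence`, `m1_truth`,
#'   `m8_truth`, `m9_truth`, `m10_truth`).
#' @export
make_proteome <- function(n_proteins = 25L, config = proteome_config(),
                          seed = 1L, preset = c("random", "table1"),
                          registry = load_motif_registry()) {
  preset <- match.arg(preset)
  if (preset == "table1") {
    return(withr::with_seed(derive_seed(seed, 11L),
                            table1_proteome(registry, seed)))
  }
  stopifnot(n_proteins >= 1L)
  withr::with_seed(derive_seed(seed, 7L), {
    sequences <- character(0)
    rows <- list()
    for (p in seq_len(n_proteins)) {
      acc <- sprintf("SYN%06d-PA", p)
      n_dom <- sample(0:2, 1L, prob = config$domain_probs)
      parts <- random_aa(sample(config$flank_len[1L]:config$flank_len[2L], 1L))
      for (k in seq_len(n_dom)) {
        type <- sample(names(config$type_probs), 1L,
                       prob = config$type_probs)
        cass <- switch(type,
          active = build_cassette(registry),
          lesioned = {
            lesions <- if (!is.null(config$lesion_motifs)) {
              as.integer(config$lesion_motifs)
            } else {
              catalytic <- sample(c(8L, 9L, 10L), 1L)
              extra <- sample(c(1L, 8L, 9L, 10L), sample(0:1, 1L))
              unique(c(catalytic, extra))
            }
            build_cassette(registry, lesions = lesions)
          },
          degenerate = build_degenerate_cassette(registry))
        start <- nchar(parts) + 1L
        parts <- paste0(parts, cass$seq)
        rows[[length(rows) + 1L]] <- data.frame(
          accession = acc, domain_index = k, start = start,
          end = start + nchar(cass$seq) - 1L,
          presence = if (type == "degenerate") "DEGENERATE" else "WELL_FORMED",
          m1_truth = cass$truth[["1"]], m8_truth = cass$truth[["8"]],
          m9_truth = cass$truth[["9"]], m10_truth = cass$truth[["10"]],
          stringsAsFactors = FALSE)
        parts <- paste0(parts, random_aa(
          sample(config$flank_len[1L]:config$flank_len[2L], 1L)))
      }
      sequences[[acc]] <- parts
    }
    domains <- if (length(rows)) do.call(rbind, rows) else
      data.frame(accession = character(0), domain_index = integer(0),
                 start = integer(0), end = integer(0),
                 presence = character(0), m1_truth = character(0),
                 m8_truth = character(0), m9_truth = character(0),
                 m10_truth = character(0), stringsAsFactors = FALSE)
    structure(list(sequences = sequences,
                   truth = list(seed = seed, preset = "random",
                                domains = domains)),
              class = "ptp_synthetic_proteome")
  })
}

# The Table-1-mirroring fixture.  Flanks and linkers are cysteine-free so
# the planted P-loop frames are the only anchors and the fixture scan is
# unambiguous; active-site motif strings are planted verbatim.
table1_proteome <- function(registry, seed) {
  wf <- function(m1, m8, m9, m10) {
    build_cassette(registry,
                   motif_seqs = list(`1` = if (is.null(m1)) NA else m1,
                                     `8` = m8, `9` = m9, `10` = m10),
                   cys_free_linkers = TRUE)
  }
  flank <- function(n) random_aa(n, exclude = "C")

  cass_1919 <- wf(NULL, "YTTWPDFGIP", "PIIHCSAGIGRSGT", "IQTVDQLYF")
  cass_8528 <- wf("NESKHKR", "FQVWPDHGVP", "PICVHCSAGIGRT", "VQTEAQYKF")
  deg_8528 <- build_degenerate_cassette(registry, 65L)

  spec <- list(
    list(acc = "AAEL001046",
         parts = list(flank(5L), build_degenerate_cassette(registry, 172L),
                      flank(8L), build_degenerate_cassette(registry, 90L),
                      flank(20L))),
    list(acc = "AAEL001919-PA",
         parts = list(flank(2L), cass_1919, flank(15L))),
    list(acc = "AAEL001919-PB",
         parts = list(flank(2L), cass_1919, flank(40L))),
    list(acc = "AAEL003108",
         parts = list(flank(590L),
                      wf("NLNKNRY", "YLAWPDHGVP", "PIIHCSAGIGRTG",
                         "VQNVSQYRF"), flank(80L))),
    list(acc = "AAEL005492",
         parts = list(flank(400L),
                      wf("NLAKNRY", "FTSWPDYGVP", "PMVVHCSAGIGRT",
                         "IQMPDQYVF"), flank(40L))),
    list(acc = "AAEL008528-PA",
         parts = list(flank(100L), deg_8528, flank(35L), cass_8528,
                      flank(30L))),
    list(acc = "AAEL008528-PB",
         parts = list(flank(100L), deg_8528, flank(35L), cass_8528,
                      flank(55L))),
    list(acc = "AAEL010234",
         parts = list(flank(975L),
                      wf("NKARNF", "YNEWGDQNCP", "PPVLIHCNEGGGRT",
                         "TPSLAQYKF"), flank(40L))),
    list(acc = "AAEL010914",
         parts = list(flank(290L),
                      wf("KNRSID", "LWPKQSA", "NCLNGSDRSC", "DPNHMQL"),
                      flank(60L))),
    list(acc = "AAEL011434",
         parts = list(flank(770L),
                      wf("QSKNRY", "FPDWPDHRSP", "PIIHCSAGIGRTG",
                         "VQNSEQYEL"), flank(150L))))

  sequences <- character(0)
  rows <- list()
  for (pr in spec) {
    seq <- ""
    idx <- 0L
    for (part in pr$parts) {
      if (is.character(part)) {
        seq <- paste0(seq, part)
      } else {
        idx <- idx + 1L
        start <- nchar(seq) + 1L
        seq <- paste0(seq, part$seq)
        degenerate <- all(part$truth == "ABSENT")
        rows[[length(rows) + 1L]] <- data.frame(
          accession = pr$acc, domain_index = idx, start = start,
          end = start + nchar(part$seq) - 1L,
          presence = if (degenerate) "DEGENERATE" else "WELL_FORMED",
          m1_truth = part$truth[["1"]], m8_truth = part$truth[["8"]],
          m9_truth = part$truth[["9"]], m10_truth = part$truth[["10"]],
          stringsAsFactors = FALSE)
      }
    }
    sequences[[pr$acc]] <- seq
  }
  structure(list(sequences = sequences,
                 truth = list(seed = seed, preset = "table1",
                              domains = do.call(rbind, rows))),
            class = "ptp_synthetic_proteome")
}

#' Evolve a sequence family on a known tree
#'
#' A random root sequence is evolved down a random (or supplied) rooted
#' binary topology by per-branch, per-site point mutation; the probability a
#' site changes on a branch is the branch length times `rate`.  Records the
#' true (unrooted) topology for downstream tree-reconstruction checks.
#'
#' @param taxa number of leaves (>= 3); ignored when `tree` is supplied.
#' @param seq_length root sequence length in residues.
#' @param branch_range min/max branch length (expected substitutions per
#'   site) for randomly drawn branches.
#' @param rate multiplier on branch lengths, in `[0, 1)`; 0 leaves all
#'   leaves identical.
#' @param tree optional `ape::phylo` rooted tree with branch lengths.
#' @param seed integer seed.
#' @return list with `sequences` (named character, one per leaf), `tree`
#'   (unrooted truth topology with branch lengths) and `seed`.
#' @export
make_family <- function(taxa = 8L, seq_length = 300L,
                        branch_range = c(0.05, 0.15), rate = 1,
                        tree = NULL, seed = 1L) {
  if (is.null(tree)) stopifnot(taxa >= 3L)
  if (rate < 0) stop("rate must be nonnegative", call. = FALSE)
  withr::with_seed(derive_seed(seed, 3L), {
    if (is.null(tree)) {
      tree <- ape::rtree(taxa)
      tree$edge.length <- stats::runif(nrow(tree$edge), branch_range[1L],
                                       branch_range[2L])
    }
    ntip <- length(tree$tip.label)
    root_seq <- strsplit(random_aa(seq_length), "")[[1L]]
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[ntip + 1L]] <- root_seq
    edges <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(edges$edge))) {
      p <- edges$edge[k, 1L]; ch <- edges$edge[k, 2L]
      s <- seqs[[p]]
      pmut <- edges$edge.length[k] * rate
      if (pmut >= 1) {
        stop("per-site per-branch mutation probability must lie in [0, 1)",
             call. = FALSE)
      }
      hit <- which(stats::runif(length(s)) < pmut)
      for (i in hit) s[i] <- sample(setdiff(AA20, s[i]), 1L)
      seqs[[ch]] <- s
    }
    leaves <- vapply(seq_len(ntip), function(i) paste(seqs[[i]],
                                                      collapse = ""),
                     character(1))
    names(leaves) <- tree$tip.label
    list(sequences = leaves, tree = ape::unroot(tree), seed = seed)
  })
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Draws threshold cycles as `baseline - log_E(fold) + N(0, noise_sd)` for
#' one target gene and a reference gene whose fold change is fixed at 1, in
#' a calibrator condition plus one condition per entry of `fold_changes`.
#'
#' @param fold_changes named positive numeric: true fold change of each
#'   non-calibrator condition relative to the calibrator.
#' @param target_gene,reference_gene gene names.
#' @param calibrator calibrator condition name.
#' @param efficiencies named amplification efficiencies in `[1, 2]`, one
#'   per gene (the mosquito assays used primers at >= 95% efficiency, i.e.
#'   >= 1.95 fold per cycle).
#' @param noise_sd replicate Gaussian Ct noise (cycles).
#' @param n_replicates technical replicates per gene x condition (>= 2;
#'   qPCR is typically run in triplicate).
#' @param baseline named baseline Ct per gene.
#' @param seed integer seed.
#' @return list with `table` (data frame: `sample_id`, `condition`, `gene`,
#'   `replicate`, `ct`, `efficiency`) and `truth` (fold changes).
#' @export
make_ct_table <- function(fold_changes = c(fed = 4),
                          target_gene = "target", reference_gene = "rp49",
                          calibrator = "control",
                          efficiencies = c(target = 2, rp49 = 2),
                          noise_sd = 0.2, n_replicates = 3L,
                          baseline = c(target = 24, rp49 = 18),
                          seed = 1L) {
  if (any(fold_changes <= 0)) stop("fold changes must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  if (any(efficiencies < 1 | efficiencies > 2)) {
    stop("efficiencies must lie in [1, 2]", call. = FALSE)
  }
  conditions <- c(stats::setNames(1, calibrator), fold_changes)
  genes <- c(target_gene, reference_gene)
  withr::with_seed(derive_seed(seed, 5L), {
    rows <- list()
    for (cond in names(conditions)) {
      for (g in genes) {
        fold <- if (g == reference_gene) 1 else conditions[[cond]]
        e <- efficiencies[[g]]
        mu <- baseline[[g]] - log(fold) / log(e)
        for (r in seq_len(n_replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s_r%d", cond, r), condition = cond,
            gene = g, replicate = r,
            ct = mu + stats::rnorm(1L, 0, noise_sd), efficiency = e,
            stringsAsFactors = FALSE)
        }
      }
    }
    list(table = do.call(rbind, rows),
         truth = list(seed = seed, fold_changes = as.list(fold_changes),
                      calibrator = calibrator))
  })
}

#' Simulate an egg-count table with known per-female means
#'
#' Egg counts per cage are Poisson with mean `females x mean_eggs`; female
#' counts are drawn uniformly from `females_range` (cages of 10-15 females
#' are typical for oviposition assays).
#'
#' @param mean_eggs named per-treatment true mean eggs per female.
#' @param n_units cages per treatment.
#' @param females_range min/max females per cage.
#' @param seed integer seed.
#' @return list with `table` (`unit_id`, `treatment`, `eggs`, `females`)
#'   and `truth` (the per-treatment means).
#' @export
make_egg_table <- function(mean_eggs = c(control = 60, treated = 40),
                           n_units = 5L, females_range = c(10L, 15L),
                           seed = 1L) {
  withr::with_seed(derive_seed(seed, 9L), {
    rows <- list()
    for (tr in names(mean_eggs)) {
      for (u in seq_len(n_units)) {
        females <- sample(females_range[1L]:females_range[2L], 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = sprintf("%s_cage%d", tr, u), treatment = tr,
          eggs = stats::rpois(1L, females * mean_eggs[[tr]]),
          females = females, stringsAsFactors = FALSE)
      }
    }
    list(table = do.call(rbind, rows),
         truth = list(seed = seed, mean_eggs = as.list(mean_eggs)))
  })
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write / read a ground-truth sidecar
#'
#' Plain-text YAML key-value format; data frames are stored as lists of
#' records and reconstructed on read.
#'
#' @param truth truth list (as found in generator outputs).
#' @param path sidecar file.
#' @return `read_truth()` returns the truth list.
#' @export
write_truth <- function(truth, path) {
  serialize_df <- function(x) {
    if (is.data.frame(x)) {
      lapply(seq_len(nrow(x)), function(i) as.list(x[i, , drop = FALSE]))
    } else if (is.list(x)) lapply(x, serialize_df) else x
  }
  yaml::write_yaml(serialize_df(truth), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$domains)) {
    y$domains <- do.call(rbind, lapply(y$domains, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
    rownames(y$domains) <- NULL
  }
  y
}
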