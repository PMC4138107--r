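# Efficiency-corrected relative expression (comparative Ct), egg-count
# normalization and the classical significance tests.
#
# The quantification unifies the comparative ddCt method with per-primer
# efficiency correction as the Pfaffl ratio
#   ratio = E_target^(-dCt_target) / E_ref^(-dCt_ref),
# dCt = mean Ct(condition) - mean Ct(calibrator) per gene, which reduces to
# 2^(-ddCt) exactly when both efficiencies are 2 (perfect doubling).
# Standard errors are propagated from the replicate dCt spread by the delta
# method.  Replicates aggregate by arithmetic mean of Ct (the geometric-mean
# equivalent on the expression scale); no outlier handling is applied.

#' Read a Ct table
#'
#' CSV with columns `sample_id`, `condition`, `gene`, `replicate`, `ct`,
#' `efficiency` (amplification efficiency as fold change per cycle, in
#' `[1, 2]`; e.g. 1.95 for a primer pair at 95% efficiency).
#'
#' @param path CSV file.
#' @return data frame.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("condition", "gene", "replicate", "ct", "efficiency")
  missing <- setdiff(required, names(ct))
  if (length(missing)) {
    stop("Ct table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ct
}

validate_ct <- function(ct) {
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  if (any(ct$efficiency < 1 | ct$efficiency > 2)) {
    stop("amplification efficiency must lie in [1, 2]", call. = FALSE)
  }
  invisible(ct)
}

gene_efficiency <- function(ct, gene) {
  e <- unique(ct$efficiency[ct$gene == gene])
  if (length(e) != 1L) {
    stop("efficiency must be constant per gene (", gene, ")", call. = FALSE)
  }
  e
}

#' Efficiency-corrected relative expression (comparative Ct)
#'
#' For each condition of the target gene, computes the expression ratio
#' relative to a calibrator condition, normalized to a reference gene, with
#' per-primer efficiency correction (Pfaffl form).  `mode = "classic"`
#' forces both efficiencies to 2, giving the textbook `2^(-ddCt)`.
#'
#' @param ct Ct table (see [read_ct_table()]); target and reference must be
#'   measured in the same conditions.
#' @param target,reference gene names (reference is typically the rp49
#'   housekeeping transcript).
#' @param calibrator calibrator condition (the baseline the ratios are
#'   expressed against); must be present in the table.
#' @param mode `"pfaffl"` (efficiency-corrected, default) or `"classic"`.
#' @return data frame, one row per condition: `gene`, `condition`,
#'   `calibrator`, `ratio`, `se`, `n_replicates`.  The calibrator row has
#'   ratio 1 by construction.
#' @examples
#' tab <- make_ct_table(fold_changes = c(fed = 4), seed = 1)$table
#' relative_expression(tab, "target", "rp49", calibrator = "control")
#' @export
relative_expression <- function(ct, target, reference, calibrator,
                                mode = c("pfaffl", "classic")) {
  mode <- match.arg(mode)
  validate_ct(ct)
  for (g in c(target, reference)) {
    if (!any(ct$gene == g)) stop("gene not in table: ", g, call. = FALSE)
  }
  conditions <- unique(ct$condition[ct$gene == target])
  if (!calibrator %in% conditions ||
      !calibrator %in% ct$condition[ct$gene == reference]) {
    stop("calibrator condition '", calibrator,
         "' missing from the Ct table", call. = FALSE)
  }
  e_t <- if (mode == "classic") 2 else gene_efficiency(ct, target)
  e_r <- if (mode == "classic") 2 else gene_efficiency(ct, reference)

  stats_for <- function(gene, cond) {
    x <- ct$ct[ct$gene == gene & ct$condition == cond]
    list(mean = mean(x), varm = if (length(x) > 1L)
      stats::var(x) / length(x) else 0, n = length(x))
  }

  rows <- lapply(conditions, function(cond) {
    t_c <- stats_for(target, cond); t_0 <- stats_for(target, calibrator)
    r_c <- stats_for(reference, cond); r_0 <- stats_for(reference, calibrator)
    dct_t <- t_c$mean - t_0$mean
    dct_r <- r_c$mean - r_0$mean
    ratio <- e_t^(-dct_t) / e_r^(-dct_r)
    var_dct_t <- t_c$varm + t_0$varm
    var_dct_r <- r_c$varm + r_0$varm
    var_log <- log(e_t)^2 * var_dct_t + log(e_r)^2 * var_dct_r
    data.frame(gene = target, condition = cond, calibrator = calibrator,
               ratio = ratio, se = ratio * sqrt(var_log),
               n_replicates = t_c$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Eggs laid per female
#'
#' Each experimental unit (cage or tube) contributes the egg count divided
#' by the number of females housed in it.
#'
#' @param eggs nonnegative egg counts.
#' @param females female counts, each >= 1.
#' @return eggs-per-female values.
#' @examples
#' normalize_egg_counts(120, 12)   # 10
#' @export
normalize_egg_counts <- function(eggs, females) {
  if (any(eggs < 0)) stop("negative egg count", call. = FALSE)
  if (any(females < 1)) {
    stop("each unit must house at least one female", call. = FALSE)
  }
  eggs / females
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F with `(k - 1, N - k)` degrees of
#' freedom, computed from explicit sums of squares; p-value from the F
#' distribution.  Identical constant groups give F = 0 (no between-group
#' signal), p = 1.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return list with `statistic` (F), `df` (length 2), `p.value` and the
#'   sums of squares `ss_between`, `ss_within`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need >= 2 groups", call. = FALSE)
  }
  n <- lengths(groups)
  if (any(n < 2L)) stop("each group needs n >= 2", call. = FALSE)
  all_x <- unlist(groups)
  grand <- mean(all_x)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1L
  df2 <- length(all_x) - length(groups)
  if (ssb <= 0) {
    f <- 0; p <- 1
  } else if (ssw <= 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  list(statistic = f, df = c(df1 = df1, df2 = df2), p.value = p,
       ss_between = ssb, ss_within = ssw)
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance and a two-sided p-value.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list with `statistic` (t), `df`, `p.value`.
#' @export
two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each sample needs n >= 2", call. = FALSE)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  if (sp2 <= 0) {
    t <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    t <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  }
  p <- 2 * stats::pt(-abs(t), df)
  list(statistic = t, df = df, p.value = p)
}
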