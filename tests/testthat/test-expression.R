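# Comparative-Ct quantification, egg normalization and significance tests.

make_flat_ct <- function(e_t = 2, e_r = 2, shift_fed_target = 0,
                         shift_fed_ref = 0) {
  rows <- expand.grid(condition = c("control", "fed"),
                      gene = c("tg", "rp49"), replicate = 1:3,
                      stringsAsFactors = FALSE)
  rows$sample_id <- paste0(rows$condition, "_r", rows$replicate)
  rows$ct <- 24
  sel_t <- rows$condition == "fed" & rows$gene == "tg"
  sel_r <- rows$condition == "fed" & rows$gene == "rp49"
  rows$ct[sel_t] <- rows$ct[sel_t] + shift_fed_target
  rows$ct[sel_r] <- rows$ct[sel_r] + shift_fed_ref
  rows$efficiency <- ifelse(rows$gene == "tg", e_t, e_r)
  rows
}

test_that("equal Ct everywhere gives ratio 1, one cycle of drop gives 2", {
  ct <- make_flat_ct()
  r <- relative_expression(ct, "tg", "rp49", "control")
  expect_equal(r$ratio, c(1, 1))
  ct2 <- make_flat_ct(shift_fed_target = -1)
  r2 <- relative_expression(ct2, "tg", "rp49", "control")
  expect_equal(r2$ratio[r2$condition == "fed"], 2)
})

test_that("the efficiency-corrected ratio matches direct arithmetic", {
  # E_t = 1.95, E_r = 2.0, dCt_t = -2.0, dCt_r = 0.5
  ct <- make_flat_ct(e_t = 1.95, e_r = 2, shift_fed_target = -2,
                     shift_fed_ref = 0.5)
  r <- relative_expression(ct, "tg", "rp49", "control")
  oracle <- 1.95^2 / 2^(-0.5)
  expect_equal(r$ratio[r$condition == "fed"], oracle, tolerance = 1e-12)
})

test_that("at perfect efficiency the ratio equals 2^(-ddCt) exactly", {
  withr::with_seed(21, {
    for (k in 1:20) {
      dt <- stats::runif(1, -3, 3)
      dr <- stats::runif(1, -1, 1)
      ct <- make_flat_ct(shift_fed_target = dt, shift_fed_ref = dr)
      r <- relative_expression(ct, "tg", "rp49", "control")
      expect_equal(r$ratio[r$condition == "fed"], 2^(-(dt - dr)),
                   tolerance = 1e-12)
    }
  })
})

test_that("ratios are invariant to Ct offsets shared by all conditions", {
  tab <- make_ct_table(fold_changes = c(fed = 4), noise_sd = 0.1,
                       seed = 3)$table
  r1 <- relative_expression(tab, "target", "rp49", "control")
  tab$ct[tab$gene == "target"] <- tab$ct[tab$gene == "target"] + 5
  r2 <- relative_expression(tab, "target", "rp49", "control")
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
})

test_that("standard errors come from the replicate dCt spread", {
  tab <- make_ct_table(fold_changes = c(fed = 2), noise_sd = 0.2,
                       seed = 4)$table
  r <- relative_expression(tab, "target", "rp49", "control")
  expect_true(all(is.finite(r$se)) && all(r$se >= 0))
  expect_equal(r$ratio[r$condition == "control"], 1)
  # noise-free replicates give zero spread
  tab0 <- make_ct_table(fold_changes = c(fed = 2), noise_sd = 0,
                        seed = 4)$table
  r0 <- relative_expression(tab0, "target", "rp49", "control")
  expect_equal(r0$se, c(0, 0))
})

test_that("validation: efficiency range and calibrator presence", {
  ct <- make_flat_ct()
  ct$efficiency[1] <- 2.3
  expect_error(relative_expression(ct, "tg", "rp49", "control"),
               "efficiency")
  ct2 <- make_flat_ct()
  expect_error(relative_expression(ct2, "tg", "rp49", "sucrose_0h"),
               "calibrator")
})

test_that("fold-change recovery is unbiased across the design grid", {
  grid <- expand.grid(fold = c(0.5, 1, 2, 4), sd = c(0.1, 0.2, 0.3))
  for (g in seq_len(nrow(grid))) {
    est <- vapply(1:60, function(s) {
      tab <- make_ct_table(fold_changes = c(fed = grid$fold[g]),
                           noise_sd = grid$sd[g], n_replicates = 3,
                           seed = s)$table
      r <- relative_expression(tab, "target", "rp49", "control")
      r$ratio[r$condition == "fed"]
    }, numeric(1))
    bias <- stats::median((est - grid$fold[g]) / grid$fold[g])
    expect_lt(abs(bias), 0.15,
              label = sprintf("median bias at fold %.1f sd %.1f",
                              grid$fold[g], grid$sd[g]))
  }
})

test_that("egg counts normalize per female with guarded input", {
  expect_equal(normalize_egg_counts(120, 12), 10)
  expect_equal(normalize_egg_counts(0, 5), 0)
  expect_error(normalize_egg_counts(10, 0), "at least one female")
  eg <- make_egg_table(mean_eggs = c(control = 60), n_units = 30, seed = 2)
  per_female <- normalize_egg_counts(eg$table$eggs, eg$table$females)
  se <- stats::sd(per_female) / sqrt(length(per_female))
  expect_lte(abs(mean(per_female) - 60), 2 * se + 1e-9)
})

test_that("one-way ANOVA matches the sums-of-squares oracle to 1e-10", {
  groups <- list(c(4.1, 5.2, 3.9, 4.8, 5.0),
                 c(6.3, 5.9, 6.8, 7.1, 6.0),
                 c(5.1, 4.7, 5.5, 5.0, 4.9))
  a <- one_way_anova(groups)
  o <- anova_oracle(groups)
  expect_equal(a$statistic, o$statistic, tolerance = 1e-10)
  expect_equal(a$p.value, o$p.value, tolerance = 1e-10)
  # and the stock implementation agrees
  ot <- stats::oneway.test(values ~ g,
                           data = data.frame(values = unlist(groups),
                                             g = rep(1:3, each = 5)),
                           var.equal = TRUE)
  expect_equal(a$statistic, unname(ot$statistic), tolerance = 1e-10)
  expect_equal(a$p.value, unname(ot$p.value), tolerance = 1e-10)
})

test_that("identical constant groups give F = 0, p = 1", {
  a <- one_way_anova(list(c(2, 2, 2), c(2, 2, 2), c(2, 2, 2)))
  expect_identical(a$statistic, 0)
  expect_identical(a$p.value, 1)
})

test_that("with two groups F equals the squared pooled t statistic", {
  withr::with_seed(77, {
    for (k in 1:10) {
      a <- stats::rnorm(6, 10, 2)
      b <- stats::rnorm(5, 12, 2)
      f <- one_way_anova(list(a, b))
      t <- two_sample_t(a, b)
      expect_equal(f$statistic, t$statistic^2, tolerance = 1e-10)
      expect_equal(f$p.value, t$p.value, tolerance = 1e-10)
    }
  })
})

test_that("the pooled t test matches the textbook formula and stats::t.test", {
  a <- c(10.2, 11.5, 9.8, 10.9, 11.1, 10.4)
  b <- c(12.0, 12.8, 11.6, 13.1, 12.2, 12.5)
  t <- two_sample_t(a, b)
  o <- t_oracle(a, b)
  expect_equal(t$statistic, o$statistic, tolerance = 1e-10)
  expect_equal(t$p.value, o$p.value, tolerance = 1e-10)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(t$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(t$p.value, tt$p.value, tolerance = 1e-10)
})

test_that("t statistic negates under swap; identical samples give t=0, p=1", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 6)
  t1 <- two_sample_t(a, b); t2 <- two_sample_t(b, a)
  expect_equal(t1$statistic, -t2$statistic)
  expect_equal(t1$p.value, t2$p.value)
  t0 <- two_sample_t(a, a)
  expect_identical(t0$statistic, 0)
  expect_equal(t0$p.value, 1)
})

test_that("sample-size contracts are enforced", {
  expect_error(one_way_anova(list(c(1, 2))), ">= 2 groups")
  expect_error(one_way_anova(list(c(1, 2), 3)), "n >= 2")
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})
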