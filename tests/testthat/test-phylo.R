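# Alignment, identity distances, neighbor joining and clade queries.

test_that("identity is 100 on self and 0 on disjoint sequences", {
  expect_equal(percent_identity("HCSAGIGR", "HCSAGIGR"), 100)
  expect_equal(percent_identity("AAAA", "GGGG"), 0)
  for (s in c("PIIHCSAGIGRSGT", "YTTWPDFGIP", "NLNKNRYAQWERTY")) {
    expect_equal(percent_identity(s, s), 100)
  }
})

test_that("aligned strings ungap back to the inputs", {
  al <- global_align("HEAGAWGHEE", "PAWHEAE")
  expect_identical(gsub("-", "", al$aligned_query), "HEAGAWGHEE")
  expect_identical(gsub("-", "", al$aligned_subject), "PAWHEAE")
  expect_identical(nchar(al$aligned_query), nchar(al$aligned_subject))
})

test_that("alignment scores match the brute-force affine DP oracle", {
  mat <- blosum62()
  expect_equal(global_align("HEAGAWGHEE", "PAWHEAE")$score,
               gotoh_score("HEAGAWGHEE", "PAWHEAE", mat))
  withr::with_seed(99, {
    for (k in 1:50) {
      a <- random_seq(sample(5:12, 1))
      b <- random_seq(sample(5:12, 1))
      expect_equal(global_align(a, b)$score, gotoh_score(a, b, mat),
                   label = sprintf("score(%s, %s)", a, b))
    }
  })
})

test_that("alignment score is symmetric in its arguments", {
  withr::with_seed(17, {
    for (k in 1:10) {
      a <- random_seq(sample(8:20, 1))
      b <- random_seq(sample(8:20, 1))
      expect_equal(global_align(a, b)$score, global_align(b, a)$score)
    }
  })
})

test_that("empty sequences are a contract error; local mode is available", {
  expect_error(global_align("", "AAA"), "non-empty")
  expect_gte(percent_identity("MKVLHCSAGIGR", "HCSAGIGR", type = "local"),
             percent_identity("MKVLHCSAGIGR", "HCSAGIGR", type = "global"))
})

test_that("distance matrices are symmetric recomputations of pair identity", {
  seqs <- c(a = "HCSAGIGRSGT", b = "HCSAGIGRSGT", c = "YTTWPDFGIPAA")
  d <- build_distance_matrix(seqs)
  expect_equal(d["a", "b"], 0)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
  fam <- make_family(taxa = 6, seed = 5)
  d2 <- build_distance_matrix(fam$sequences)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(d2[i, j],
                   1 - percent_identity(fam$sequences[[i]],
                                        fam$sequences[[j]]) / 100)
    }
  }
  disjoint <- c(x = "AAAA", y = "GGGG", z = "PPPP")
  d3 <- build_distance_matrix(disjoint)
  expect_true(all(d3[upper.tri(d3)] == 1))
})

test_that("duplicate ids are rejected when building distances", {
  expect_error(build_distance_matrix(c(a = "AAA", a = "GGG")), "unique")
})

test_that("the three-taxon closed form gives the classic branch lengths", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
})

test_that("fewer than three taxa is a contract error", {
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(d), ">= 3 taxa")
})

test_that("NJ reconstructs additive matrices exactly (branch lengths too)", {
  for (s in 1:10) {
    ntaxa <- sample(4:8, 1)
    ra <- random_additive(ntaxa, s)
    tr <- neighbor_joining(ra$d)
    expect_identical(robinson_foulds(tr, ra$tree), 0L)
    pd <- stats::cophenetic(tr)[rownames(ra$d), colnames(ra$d)]
    expect_equal(pd, ra$d, tolerance = 1e-8)
  }
})

test_that("on a 4-taxon additive matrix NJ picks the zero-residual quartet", {
  ra <- random_additive(4, 77)
  d <- ra$d
  taxa <- rownames(d)
  pairs <- list(taxa[c(1, 2)], taxa[c(1, 3)], taxa[c(1, 4)])
  rss <- vapply(pairs, function(p) quartet_ls_rss(d, p), numeric(1))
  best <- pairs[[which.min(rss)]]
  expect_lt(min(rss), 1e-16)
  tr <- neighbor_joining(d)
  # NJ must place the least-squares-perfect pair as a cherry
  expect_true(clade_check(tr, best[1], best[2],
                          setdiff(taxa, best)))
})

test_that("NJ topology agrees with the reference implementation", {
  withr::with_seed(31, {
    for (k in 1:5) {
      n <- sample(5:8, 1)
      d <- as.matrix(stats::dist(matrix(stats::runif(n * 4), n)))
      dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
      t_pkg <- neighbor_joining(d)
      t_ape <- ape::nj(d)
      expect_equal(as.numeric(phangorn::RF.dist(t_pkg, t_ape)), 0)
      # and the package RF agrees with phangorn on random tree pairs
      x <- ape::rtree(n); y <- ape::rtree(n)
      expect_equal(robinson_foulds(x, y),
                   as.integer(phangorn::RF.dist(ape::unroot(x),
                                                ape::unroot(y))))
    }
  })
})

test_that("negative branch estimates are clamped to zero by default", {
  d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 2, 9, 10, 2, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("trees round-trip through Newick", {
  fam <- make_family(taxa = 6, seed = 9)
  d <- build_distance_matrix(fam$sequences)
  tr <- neighbor_joining(d)
  txt <- ape::write.tree(tr)
  back <- ape::read.tree(text = txt)
  expect_identical(robinson_foulds(tr, back), 0L)
  expect_setequal(back$tip.label, names(fam$sequences))
})

test_that("clade_check finds separating edges and rejects unknown taxa", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,E:2);")
  expect_true(clade_check(tr, "A", "B", c("C", "D")))
  expect_false(clade_check(tr, "A", "C", c("B", "D")))
  expect_error(clade_check(tr, "A", "Z", "C"), "unknown taxa")
  # generator families built with a known clade keep it
  for (s in 1:10) {
    fam <- make_family(taxa = 6, seed = s)
    d <- build_distance_matrix(fam$sequences)
    tr2 <- neighbor_joining(d)
    splits <- ptpscan:::tree_splits(fam$tree)
    if (length(splits) == 0) next
    side <- strsplit(splits[1], "")[[1]] == "1"
    tips <- sort(fam$tree$tip.label)
    S <- tips[side]
    if (robinson_foulds(tr2, fam$tree) == 0L && length(S) >= 2) {
      expect_true(clade_check(tr2, S[1], S[-1], tips[!side]))
    }
  }
})

test_that("distance matrices round-trip through PHYLIP square format", {
  fam <- make_family(taxa = 5, seed = 12)
  d <- build_distance_matrix(fam$sequences)
  tf <- tempfile(fileext = ".phy")
  write_phylip_dist(d, tf)
  back <- read_phylip_dist(tf)
  expect_equal(back, d, tolerance = 1e-6)
})
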