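# Independent oracles used to cross-check package computations.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(n, pool = AAS) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# Brute-force affine-gap global alignment score (Gotoh three-state DP,
# end gaps penalized; a gap of length k costs open + k * ext).
gotoh_score <- function(a, b, mat, open = 10, ext = 1) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[ac[i - 1], bc[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext,
                      Iy[i - 1, j] - open - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Ix[i, j - 1] - open - ext,
                      Iy[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Hand-computed one-way ANOVA from raw sums of squares.
anova_oracle <- function(groups) {
  x <- unlist(groups)
  k <- length(groups)
  N <- length(x)
  grand <- sum(x) / N
  ssb <- 0; ssw <- 0
  for (g in groups) {
    gm <- sum(g) / length(g)
    ssb <- ssb + length(g) * (gm - grand)^2
    ssw <- ssw + sum((g - gm)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(statistic = f,
       p.value = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

# Textbook pooled-variance Student t.
t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t,
       p.value = 2 * stats::pt(-abs(t), na + nb - 2))
}

# Least-squares branch fit of a 4-taxon quartet topology; returns the
# residual sum of squares.  Topology given as the pair grouped together.
quartet_ls_rss <- function(d, pair) {
  taxa <- rownames(d)
  others <- setdiff(taxa, pair)
  a <- pair[1]; b <- pair[2]; c <- others[1]; e <- others[2]
  # branches: la, lb, lc, le, internal m
  X <- rbind(c(1, 1, 0, 0, 0),   # d(a,b)
             c(0, 0, 1, 1, 0),   # d(c,e)
             c(1, 0, 1, 0, 1),   # d(a,c)
             c(1, 0, 0, 1, 1),   # d(a,e)
             c(0, 1, 1, 0, 1),   # d(b,c)
             c(0, 1, 0, 1, 1))   # d(b,e)
  y <- c(d[a, b], d[c, e], d[a, c], d[a, e], d[b, c], d[b, e])
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# Random additive distance matrix from a random topology.
random_additive <- function(ntaxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(ntaxa)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
    list(tree = ape::unroot(tr), d = stats::cophenetic(tr))
  })
}

# independent simulation streams per grid cell
derive_seed_for_test <- function(cell, rep) 100000L * cell + rep

table1_fixture_records <- function(seed = 1) {
  px <- make_proteome(preset = "table1", seed = seed)
  list(records = lapply(names(px$sequences), function(a) {
         protein_record(a, px$sequences[[a]])
       }),
       proteome = px)
}
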