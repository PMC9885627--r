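# Independent oracles and fixture builders shared across tests.

# Floyd-Warshall all-pairs hop distances from an adjacency matrix.
fwDistances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Exhaustive Hardy-Weinberg exact test: enumerate every genotype triple
# compatible with the observed allele counts; conditional probability of a
# triple is proportional to the multinomial coefficient times 2^het.
hweEnumOracle <- function(counts) {
  N <- sum(counts)
  nMinor <- counts[2] + 2 * counts[3]
  grid <- expand.grid(n1 = 0:N, n2 = 0:N)
  grid$n0 <- N - grid$n1 - grid$n2
  grid <- grid[grid$n0 >= 0 & grid$n1 + 2 * grid$n2 == nMinor, ]
  w <- apply(grid, 1, function(g)
    exp(lfactorial(N) - lfactorial(g["n0"]) - lfactorial(g["n1"]) -
          lfactorial(g["n2"]) + g["n1"] * log(2)))
  w <- w / sum(w)
  wObs <- w[grid$n1 == counts[2]]
  sum(w[w <= wObs * (1 + 1e-9)])
}

# Exact permutation distribution of the trend statistic: enumerate every
# case-count split (r0, r1, r2) of the genotype margins.
caPermutationOracle <- function(caseCounts, controlCounts) {
  n <- caseCounts + controlCounts
  R <- sum(caseCounts)
  obs <- cochranArmitageTrend(caseCounts, controlCounts)$chisq
  p <- 0
  for (r0 in 0:min(n[1], R)) for (r1 in 0:min(n[2], R - r0)) {
    r2 <- R - r0 - r1
    if (r2 < 0 || r2 > n[3]) next
    prob <- exp(lchoose(n[1], r0) + lchoose(n[2], r1) + lchoose(n[3], r2) -
                  lchoose(sum(n), R))
    stat <- cochranArmitageTrend(c(r0, r1, r2), n - c(r0, r1, r2))$chisq
    if (stat >= obs - 1e-9) p <- p + prob
  }
  p
}

# AANetwork straight from an explicit edge list (graph-theory fixtures).
netFromEdges <- function(n, edges, resNames = rep("ALA", n)) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  if (length(edges))
    g <- igraph::add_edges(g, t(matrix(as.character(edges), ncol = 2)))
  new("AANetwork", graph = g, mode = "ca_distance", cutoff = 7,
      positions = seq_len(n), residueNames = resNames)
}

pathNet <- function(n) netFromEdges(n, cbind(1:(n - 1), 2:n))
starNet <- function(n) netFromEdges(n, cbind(1, 2:n))
cycleNet <- function(n) netFromEdges(n, rbind(cbind(1:(n - 1), 2:n), c(n, 1)))

# Minor-allele dosage matrix with iid binomial genotypes, seeded.
randomDosage <- function(nVariants, nSamples, maf = 0.3, seed = 1) {
  set.seed(seed)
  matrix(rbinom(nVariants * nSamples, 2L, maf), nVariants, nSamples,
         dimnames = list(paste0("v", seq_len(nVariants)),
                         paste0("s", seq_len(nSamples))))
}

# Empirical type-I error of the trend test over null multinomial tables.
trendTypeIError <- function(nSim = 10000, nPerGroup = 200, maf = 0.3,
                            alpha = 0.05, seed = 42) {
  set.seed(seed)
  g <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  rej <- logical(nSim)
  for (i in seq_len(nSim)) {
    r <- rmultinom(1, nPerGroup, g)[, 1]
    s <- rmultinom(1, nPerGroup, g)[, 1]
    rej[i] <- cochranArmitageTrend(r, s)$p < alpha
  }
  mean(rej)
}

# Mann-Whitney concordance through the rank-sum statistic (ties: midranks).
wilcoxAUC <- function(scores, y) {
  w <- suppressWarnings(
    stats::wilcox.test(scores[y], scores[!y], exact = FALSE))
  unname(w$statistic) / (sum(y) * sum(!y))
}

# QC fixture where every filter has exactly one planted failure.
plantedQCFixture <- function() {
  set.seed(31)
  n <- 60
  base <- randomDosage(6, n, maf = 0.4, seed = 31)
  mono <- rep(0L, n)                                   # step 1
  chrx <- rbinom(n, 2L, 0.4)                           # step 3
  lowcall <- rbinom(n, 2L, 0.4); lowcall[1:8] <- NA    # step 4 (cr 0.867)
  lowmaf <- c(rep(1L, 2), rep(0L, n - 2))              # step 5 (maf 0.017)
  hwebad <- rep(1L, n)                                 # step 8 (all het)
  d <- rbind(base, mono = mono, chrx = chrx, lowcall = lowcall,
             lowmaf = lowmaf, hwebad = hwebad)
  rownames(d) <- c(rownames(base), "mono", "chrx", "lowcall", "lowmaf",
                   "hwebad")
  colnames(d) <- sprintf("s%03d", 1:n)
  meta <- data.frame(status = rep(c("case", "control"), n / 2),
                     sex = rep("F", n), inferred_sex = rep("F", n),
                     row.names = colnames(d))
  meta$inferred_sex[5] <- "M"                          # step 2
  vmeta <- data.frame(chrom = c(rep("1", 6), "2", "X", "3", "4", "5"),
                      pos = seq_len(11) * 100L,
                      row.names = rownames(d))
  GenotypeData(d, meta, vmeta)
}

# Planted multi-variant fixture: nStrong variants with a real per-allele
# effect, the rest null, split into train/valid groups.
plantedSplitFixture <- function(nStrong = 3, nNull = 7, orStrong = 4,
                                nCases = 400, nControls = 400, seed = 11) {
  v <- data.frame(
    variant = sprintf("v%02d", seq_len(nStrong + nNull)),
    chrom = "1", pos = seq_len(nStrong + nNull) * 1000L,
    maf = 0.3, beta = c(rep(log(orStrong), nStrong), rep(0, nNull)))
  simulateGenotypes(nCases, nControls, v, mode = "sampled", seed = seed,
                    trainCases = round(nCases * 0.75),
                    trainControls = round(nControls * 0.75))
}
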