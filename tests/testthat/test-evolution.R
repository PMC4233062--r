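test_that("p-distance excludes gap columns per pair", {
  expect_equal(p_distance_pairwise_deletion("AAAA", "AAAA")$p, 0)
  expect_equal(p_distance_pairwise_deletion("AAAA", "AAAT")$p, 0.25)
  pd <- p_distance_pairwise_deletion("AA-A", "AATA")
  expect_equal(pd$sites, 3L)
  expect_equal(pd$p, 0)
})

test_that("Poisson correction is exact, monotone and domain-aware", {
  expect_equal(poisson_correct(0)$d, 0)
  expect_equal(poisson_correct(0.1)$d, 0.105361, tolerance = 1e-5)
  expect_true(poisson_correct(1)$undefined)
  p <- seq(0.01, 0.95, by = 0.01)
  d <- vapply(p, function(x) poisson_correct(x)$d, numeric(1))
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("NJ solves the three-taxon system exactly and additive cases generally", {
  D <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  res <- build_nj(D)
  ed <- tidy(res)
  lens <- setNames(ed$length[ed$tip], ed$label[ed$tip])
  expect_equal(unname(lens[c("a", "b", "c")]), c(1, 2, 4))

  # additive matrices from random topologies are recovered exactly (n <= 8)
  for (s in 1:20) {
    set.seed(400 + s)
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    D2 <- ape::cophenetic.phylo(tr)
    nj <- build_nj(D2)
    expect_equal(phangorn::RF.dist(nj$tree, tr), 0, info = paste("seed", s))
    # path-length metric of the NJ tree reproduces the input distances
    co <- ape::cophenetic.phylo(nj$tree)
    expect_equal(co[rownames(D2), colnames(D2)], D2, tolerance = 1e-8)
  }
})

test_that("NJ matches an exhaustive least-squares topology search on 5 taxa", {
  skip_if_not_installed("phangorn")
  for (s in 1:5) {
    set.seed(600 + s)
    tr <- ape::rtree(5, br = function(k) runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(tr)
    nj <- build_nj(D)
    all_tr <- phangorn::allTrees(5, rooted = FALSE, tip.label = rownames(D))
    rss <- vapply(all_tr, function(t) {
      fit <- phangorn::nnls.tree(D, t, method = "unrooted")
      sum((ape::cophenetic.phylo(fit)[rownames(D), colnames(D)] - D)^2)
    }, numeric(1))
    best <- all_tr[[which.min(rss)]]
    expect_equal(phangorn::RF.dist(nj$tree, best), 0, info = paste("seed", s))
  }
})

test_that("NJ output is deterministic on tie-heavy matrices", {
  D <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  t1 <- build_nj(D)
  t2 <- build_nj(D[c(3, 1, 4, 2), c(3, 1, 4, 2)])
  expect_equal(ape::write.tree(t1$tree), ape::write.tree(t2$tree))
})

test_that("bootstrap support separates planted clades and is seed-stable", {
  set.seed(31)
  alpha <- c("A", "R", "N", "D", "E", "Q", "G", "H", "K", "S")
  base <- paste(sample(alpha, 500, replace = TRUE), collapse = "")
  mutate_at <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), n)
    ch[pos] <- sample(c("L", "I", "V", "F", "T", "W"), n, replace = TRUE)
    paste(ch, collapse = "")
  }
  clade2 <- mutate_at(base, 150) # divergence ~0.3 between clades
  aln <- tibble::tibble(
    id = c("a1", "a2", "b1", "b2"),
    seq = c(mutate_at(base, 5), mutate_at(base, 5),
            mutate_at(clade2, 5), mutate_at(clade2, 5)))
  bs <- bootstrap_support(aln, n_reps = 200, seed = 7)
  internal <- bs$support[-1] # drop the root bipartition slot
  expect_true(all(internal >= 0.95))
  bs2 <- bootstrap_support(aln, n_reps = 200, seed = 7)
  expect_identical(bs$support, bs2$support)
  # row order of the alignment does not change the supports
  bs3 <- bootstrap_support(aln[c(3, 1, 4, 2), ], n_reps = 200, seed = 7)
  expect_equal(sort(bs3$support), sort(bs$support))
  expect_error(bootstrap_support(aln, n_reps = 0), "n_reps")
})

test_that("Nei-Gojobori counting matches hand enumeration and planted truth", {
  g <- fix_genome()
  cds <- g$cds$seq[[4]]
  ident <- count_substitutions_ng(cds, cds)
  expect_equal(ident$Sd, 0)
  expect_equal(ident$Nd, 0)

  # TTT vs TTC: third-position change F->F is synonymous; S(TTT) = 1/3
  one <- count_substitutions_ng("TTT", "TTC")
  expect_equal(one$Sd, 1)
  expect_equal(one$Nd, 0)
  expect_equal(one$S, 1 / 3) # mean of S(TTT), S(TTC), both 1/3
  expect_equal(one$S + one$N, 3)

  op <- generate_ortholog_pair(cds, n_syn = 2, n_nonsyn = 5, seed = 17)
  ng <- count_substitutions_ng(op$cds_a, op$cds_b)
  expect_equal(ng$Sd, 2)
  expect_equal(ng$Nd, 5)
})

test_that("aggregated mutation frequencies share one denominator", {
  g <- fix_genome()
  # genes 5..10 are non-duplicates with intact reading frames
  pairs <- purrr::map_dfr(1:6, function(i) {
    op <- generate_ortholog_pair(g$cds$seq[[i + 4]], n_syn = i, n_nonsyn = 2 * i,
                                 seed = 40 + i)
    tibble::tibble(cds_a = op$cds_a, cds_b = op$cds_b,
                   n_syn = i, n_nonsyn = 2 * i)
  })
  mf <- mutation_frequency(pairs)
  sites <- sum(nchar(pairs$cds_a))
  expect_equal(mf$stats$sites_compared, sites)
  expect_equal(mf$stats$syn_freq, sum(pairs$n_syn) / sites)
  expect_equal(mf$stats$nonsyn_freq, sum(pairs$n_nonsyn) / sites)
  # identity: syn + nonsyn = total under the shared denominator
  expect_equal(mf$stats$syn_freq + mf$stats$nonsyn_freq, mf$stats$total_freq,
               tolerance = 1e-9)
  # arithmetic spot check on one pair with 4 + 6 planted changes
  one <- generate_ortholog_pair(g$cds$seq[[8]], 4, 6, seed = 3)
  m1 <- mutation_frequency(tibble::tibble(cds_a = one$cds_a, cds_b = one$cds_b))
  L <- nchar(one$cds_a)
  expect_equal(m1$stats$total_freq, 10 / L)
  expect_equal(m1$stats$syn_freq, 4 / L)
  expect_equal(m1$stats$nonsyn_freq, 6 / L)
})
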