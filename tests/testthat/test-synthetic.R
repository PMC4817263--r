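test_that("simulateTree produces deterministic ultrametric Yule trees", {
  expect_error(simulateTree(1), ">= 2")
  tr2 <- simulateTree(2, 1, seed = 4)
  expect_equal(length(tr2$tip.label), 2)
  d <- ape::node.depth.edgelength(tr2)
  expect_equal(d[1], d[2]) # cherry: equal root-to-tip distances

  a <- ape::write.tree(simulateTree(64, 1, seed = 99))
  b <- ape::write.tree(simulateTree(64, 1, seed = 99))
  expect_identical(a, b)
  expect_true(ape::is.ultrametric(simulateTree(32, 2, seed = 5)))
})

test_that("simulateTree internode intervals match the Yule expectation", {
  ## while k lineages exist the waiting time is Exp(birth_rate * k); checked
  ## by Monte-Carlo for the early intervals (k = 2..5), where conditioning
  ## on the final tip count distorts least
  set.seed(202)
  b <- 1
  ints <- replicate(200, {
    tr <- simulateTree(16, b)
    bt <- sort(ape::branching.times(tr), decreasing = TRUE)
    -diff(bt)[1:4] # intervals with k = 2..5 lineages
  })
  for (k in 2:5) {
    obs <- ints[k - 1, ]
    se <- stats::sd(obs) / sqrt(length(obs))
    expect_lt(abs(mean(obs) - 1 / (b * k)), 3 * se + 0.01)
  }
})

test_that("evolveSequences follows Jukes-Cantor expectations", {
  tr <- ape::read.tree(text = "(A:0.5,B:0.5);")
  same <- evolveSequences(tr, 100, substitution_rate = 0, seed = 1)
  expect_equal(as.character(same[["A"]]), as.character(same[["B"]]))

  ## two tips at patristic distance d = 1 * rate: proportion of differing
  ## sites ~ (3/4)(1 - exp(-4d/3)) within 3 SE over 100 replicates
  rate <- 0.1
  p_exp <- 0.75 * (1 - exp(-4 * rate / 3))
  set.seed(303)
  props <- replicate(100, {
    s <- evolveSequences(tr, 377, substitution_rate = rate)
    a <- strsplit(as.character(s[["A"]]), "")[[1]]
    b <- strsplit(as.character(s[["B"]]), "")[[1]]
    mean(a != b)
  })
  se <- sqrt(p_exp * (1 - p_exp) / (377 * 100))
  expect_lt(abs(mean(props) - p_exp), 3 * se)
})

test_that("evolveSequences is byte-deterministic under a fixed seed", {
  tr <- simulateTree(8, 1, seed = 11)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeFasta(evolveSequences(tr, 60, 0.01, seed = 7), f1)
  writeFasta(evolveSequences(tr, 60, 0.01, seed = 7), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("panmictic site assignment is independent of site", {
  cfg <- scenarioConfig(n_haplotypes = 10, n_sites = 2,
                        latitudes = c(30, 50), strains_per_site = 1000,
                        scenario = "panmixia", seed = 21)
  tr <- simulateTree(10, 1, seed = 1)
  asg <- assignSites(tr, cfg)
  m <- communityCounts(asg$community)
  ## each count ~ Bin(1000, 1/10); difference between sites has
  ## SD sqrt(2 * 1000 * p(1-p))
  sd_diff <- sqrt(2 * 1000 * 0.1 * 0.9)
  expect_lt(max(abs(m[1, ] - m[2, ])), 5 * sd_diff)
})

test_that("expansion with founder_fraction 1 reduces to panmixia over pools", {
  cfg <- scenarioConfig(n_haplotypes = 12, n_sites = 4,
                        latitudes = c(30, 40, 50, 60), strains_per_site = 5,
                        scenario = "expansion", founder_fraction = 1,
                        seed = 3)
  tr <- simulateTree(12, 1, seed = 2)
  asg <- assignSites(tr, cfg)
  for (p in asg$pools) expect_setequal(p, tr$tip.label)
})

test_that("expansion nests founder pools and ranks sites by latitude", {
  cfg <- scenarioConfig(n_haplotypes = 32, n_sites = 5,
                        latitudes = c(55, 30, 45, 60, 38),
                        strains_per_site = 10, scenario = "expansion",
                        founder_fraction = 0.3, seed = 9)
  tr <- simulateTree(32, 1, seed = 9)
  asg <- assignSites(tr, cfg)
  ord <- order(cfg@latitudes)
  D <- ape::cophenetic.phylo(tr)
  for (k in 2:5) {
    src <- asg$pools[[ord[k - 1]]]
    pool <- asg$pools[[ord[k]]]
    expect_true(all(pool %in% src)) # nested founder pools
    expect_equal(length(pool),
                 min(length(src), max(2, ceiling(0.3 * length(src)))))
    ## kin-structured: the pool is a patristic neighbourhood of one of
    ## its members (the seed), i.e. for some member, no outside member
    ## of the source is closer than the farthest pool member
    is_neighbourhood <- any(vapply(pool, function(s) {
      r <- max(D[s, pool])
      closer <- src[D[s, src] < r - 1e-12]
      all(closer %in% pool)
    }, NA))
    expect_true(is_neighbourhood)
  }
  expect_equal(siteData(asg$sites)$time_rank[ord], 1:5)
  expect_equal(siteData(asg$sites)$glaciated, cfg@latitudes > 40)
})

test_that("expansion generates a declining latitudinal PD gradient", {
  ## generator contract: with founder_fraction 0.2 over 6 sites, Faith PD
  ## declines with latitude (negative Spearman) in >= 90% of replicates
  lat <- seq(30, 60, length.out = 6)
  hits <- vapply(1:100, function(r) {
    cfg <- scenarioConfig(n_haplotypes = 32, n_sites = 6, latitudes = lat,
                          strains_per_site = 20, scenario = "expansion",
                          founder_fraction = 0.2, seed = 5000 + r)
    tr <- simulateTree(32, 1, seed = 5000 + r)
    m <- communityCounts(assignSites(tr, cfg)$community)
    pd <- vapply(rownames(m), function(s)
      faithPD(tr, colnames(m)[m[s, ] > 0]), 0)
    stats::cor(pd, lat, method = "spearman") < 0
  }, NA)
  expect_gte(mean(hits), 0.90)
})

test_that("generateDataset emits cross-consistent, reproducible files", {
  cfg <- scenarioConfig(n_haplotypes = 16, n_sites = 3,
                        latitudes = c(32, 44, 58), strains_per_site = 12,
                        seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  out <- generateDataset(cfg, d1)
  aln <- readFasta(out$paths$fasta)
  tr <- readNewick(out$paths$tree)
  st <- readSiteTable(out$paths$sites)
  sm <- readStrainMap(out$paths$strains, sites = st, alignment = aln)
  expect_length(aln, 16)
  expect_setequal(tr$tip.label, names(aln))
  expect_equal(nrow(sm), 36)

  generateDataset(cfg, d2)
  expect_identical(readLines(out$paths$truth),
                   readLines(file.path(d2, "ground_truth.json")))
})

test_that("the default configuration has the shape of a continental survey", {
  cfg <- scenarioConfig(seed = 1)
  expect_equal(cfg@n_haplotypes, 208)
  expect_equal(cfg@n_sites, 12)
  expect_equal(cfg@strains_per_site, 77)
  expect_equal(cfg@seq_length, 377)
  d <- withr::local_tempdir()
  out <- generateDataset(cfg, d)
  expect_length(out$alignment, 208)
  expect_equal(nrow(out$strains), 12 * 77)
  expect_equal(nrow(siteData(out$sites)), 12)
})
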