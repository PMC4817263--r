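test_that("parsimonyLimit behaves like a connection-limit criterion", {
  expect_error(parsimonyLimit(0), "positive")
  expect_error(parsimonyLimit(100, 1), "confidence")
  ## only single steps are trusted as confidence approaches 1
  expect_equal(parsimonyLimit(377, 1 - 1e-12), 1)
  ## non-decreasing in sequence length
  lims <- vapply(c(50, 100, 200, 377, 800, 1600), parsimonyLimit, 0)
  expect_true(all(diff(lims) >= 0))
  ## independently coded closed form of the same criterion: largest j with
  ## exp(-(m * dJC(j/m) - j)) >= confidence
  m <- 377
  j <- 2:floor(0.7 * m)
  p <- exp(-(m * (-0.75 * log(1 - 4 * (j / m) / 3)) - j))
  oracle <- max(1, j[p >= 0.95])
  expect_equal(parsimonyLimit(377, 0.95), oracle)
})

test_that("buildNetwork joins close haplotypes and respects the limit", {
  seqs <- c(A = "AAAA", B = "AAAT", C = "AATT")
  net <- buildNetwork(haploTab(seqs), limit = 5)
  g <- haploGraph(net)
  expect_equal(igraph::vcount(g), 3) # path A-B-C, no inferred intermediates
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::components(g)$no, 1)
  expect_equal(unname(igraph::degree(g)["B"]), 2)

  ## pair beyond the limit stays in two components
  far <- c(A = "AAAAAA", B = "TTTAAA") # 3 steps apart
  net2 <- buildNetwork(haploTab(far), limit = 2)
  expect_equal(igraph::components(haploGraph(net2))$no, 2)
  ## within the limit, intermediates make every edge one step
  net3 <- buildNetwork(haploTab(far), limit = 3)
  g3 <- haploGraph(net3)
  expect_equal(igraph::components(g3)$no, 1)
  expect_equal(igraph::vcount(g3), 4) # two inferred intermediates
  expect_false(all(igraph::V(g3)$observed))
  expect_equal(unname(igraph::distances(g3, "A", "B")[1, 1]), 3)
})

test_that("simulated networks are consistent with Hamming distances", {
  set.seed(91)
  tr <- simulateTree(20, 1, seed = 92)
  aln <- evolveSequences(tr, 120, 0.01, seed = 93)
  tab <- haplotypeTable(aln)
  net <- buildNetwork(tab, limit = 6)
  g <- haploGraph(net)
  seqs <- stats::setNames(tab$sequence, tab$haplotype_id)
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  ## every edge between observed haplotypes spans exactly one step
  el <- igraph::as_edgelist(g)
  obs <- igraph::V(g)$name[igraph::V(g)$observed]
  for (e in seq_len(nrow(el))) {
    if (all(el[e, ] %in% obs))
      expect_equal(ham(seqs[el[e, 1]], seqs[el[e, 2]]), 1)
  }
  ## graph distance between observed haplotypes in one component is at
  ## least their Hamming distance (each edge is one mutation), and pairs
  ## within the connection limit share a component
  dg <- igraph::distances(g, v = obs, to = obs)
  comp <- igraph::components(g)$membership
  for (i in seq_along(obs)) for (j in seq_along(obs)) {
    if (i >= j) next
    h <- ham(seqs[obs[i]], seqs[obs[j]])
    if (h <= net@limit) {
      expect_equal(unname(comp[obs[i]]), unname(comp[obs[j]]))
      expect_gte(dg[i, j], h)
    }
  }
  ## node identity is stable under input order permutation
  set.seed(94)
  tab_shuffled <- tab[sample(nrow(tab)), ]
  attr(tab_shuffled, "siteCounts") <- attr(tab, "siteCounts")
  net_b <- buildNetwork(tab_shuffled, limit = 6)
  expect_equal(sort(igraph::degree(haploGraph(net_b))[obs]),
               sort(igraph::degree(g)[obs]))
})

test_that("resolveLoops removes the edge between low-frequency haplotypes", {
  ## 4-cycle H-a-b-c-H with H at high frequency: the edge removed must be
  ## the one joining the two lowest-frequency nodes (a-b)
  seqs <- c(H = "AAAA", a = "TAAA", b = "TTAA", c = "ATAA")
  ## distances: H-a 1, a-b 1, b-c 2... use an explicit square instead
  seqs <- c(H = "AAAA", a = "ATAA", b = "ATTA", c = "AATA")
  ## H-a 1, a-b 1, b-c 1, c-H 1, H-b 2, a-c 2 -> 4-cycle
  tab <- haploTab(seqs, counts = c(H = 10, a = 1, b = 2, c = 3))
  net <- buildNetwork(tab, limit = 5)
  g <- haploGraph(net)
  expect_equal(igraph::ecount(g), 4)
  resolved <- resolveLoops(net)
  gr <- haploGraph(resolved)
  expect_equal(igraph::ecount(gr), 3)
  expect_equal(igraph::components(gr)$no, 1)
  ## a-b (counts 1+2) is gone, all other edges remain
  expect_equal(unname(igraph::get_edge_ids(gr, c("a", "b"))), 0)
  for (pr in list(c("H", "a"), c("H", "c"), c("b", "c")))
    expect_gt(igraph::get_edge_ids(gr, pr), 0)
})

test_that("resolveLoops leaves forests untouched and preserves components", {
  seqs <- c(A = "AAAA", B = "AAAT", C = "AATT")
  net <- buildNetwork(haploTab(seqs), limit = 5)
  resolved <- resolveLoops(net)
  expect_identical(igraph::as_edgelist(haploGraph(net)),
                   igraph::as_edgelist(haploGraph(resolved)))

  set.seed(95)
  for (rep in 1:5) {
    tr <- simulateTree(12, 1, seed = 950 + rep)
    aln <- evolveSequences(tr, 60, 0.02, seed = 960 + rep)
    net <- buildNetwork(haplotypeTable(aln), limit = 8)
    resolved <- resolveLoops(net)
    gr <- haploGraph(resolved)
    expect_false(is.finite(igraph::girth(gr)$girth) &&
                   igraph::girth(gr)$girth > 0)
    expect_equal(igraph::components(gr)$no,
                 igraph::components(haploGraph(net))$no)
  }
})

test_that("nestClades follows the tip-first pairing on a path", {
  seqs <- c(A = "AAAA", B = "AAAT", C = "AATT")
  net <- buildNetwork(haploTab(seqs), limit = 5)
  design <- nestClades(net)
  m <- designMembership(design)
  ## level 1: {A,B} together, C stranded as a singleton
  expect_equal(m$level_1[m$node == "A"], m$level_1[m$node == "B"])
  expect_false(m$level_1[m$node == "C"] == m$level_1[m$node == "A"])
  ## level 2 unites everything
  expect_equal(length(unique(m$level_2)), 1)
  expect_equal(design@n_levels, 2)
})

test_that("nesting partitions every level and terminates", {
  ## single haplotype: trivial design
  single <- buildNetwork(haploTab(c(A = "AAAA")), limit = 3)
  d0 <- nestClades(single)
  expect_equal(d0@n_levels, 0)
  expect_equal(nrow(designMembership(d0)), 1)

  set.seed(96)
  tr <- simulateTree(15, 1, seed = 97)
  aln <- evolveSequences(tr, 80, 0.015, seed = 98)
  net <- resolveLoops(buildNetwork(haplotypeTable(aln), limit = 6))
  design <- nestClades(net)
  m <- designMembership(design)
  n_nodes <- nrow(m)
  expect_lte(design@n_levels, n_nodes)
  for (lv in 0:design@n_levels) {
    col <- paste0("level_", lv)
    expect_false(anyNA(m[[col]])) # every node in exactly one clade
    ## nesting strictly coarsens
    if (lv > 0) {
      prev <- paste0("level_", lv - 1)
      expect_true(all(tapply(m[[col]], m[[prev]],
                             function(x) length(unique(x))) == 1))
    }
  }
  ## top level: one clade per component
  top <- paste0("level_", design@n_levels)
  expect_equal(length(unique(m[[top]])),
               length(unique(m$component)))
  expect_error(nestClades(buildNetwork(haploTab(
    c(H = "AAAA", a = "ATAA", b = "ATTA", c = "AATA")), 5)), "loops")
})

test_that("clade distances match direct great-circle averaging", {
  ## all members at one site: Dc = 0
  seqs <- c(A = "AAAA", B = "AAAT")
  net <- buildNetwork(haploTab(seqs), limit = 3)
  design <- nestClades(net)
  st <- toySites(c(40, 50), lon = c(-100, -90))
  strains <- data.frame(strain_id = c("s1", "s2"),
                        site_id = c("S01", "S01"),
                        haplotype_id = c("A", "B"))
  cd <- cladeDistances(design, strains, st)
  expect_lt(max(cd$dc[cd$n_strains > 0]), 1e-9) # all at one point: Dc = 0

  ## two strains at symmetric longitudes around the centroid: Dc equals
  ## the common distance to the centre
  st2 <- toySites(c(0, 0), lon = c(-10, 10), ids = c("S01", "S02"))
  strains2 <- data.frame(strain_id = c("s1", "s2"),
                         site_id = c("S01", "S02"),
                         haplotype_id = c("A", "B"))
  cd2 <- cladeDistances(design, strains2, st2)
  top <- cd2[cd2$level == cd2$level[which.max(cd2$level)] &
               cd2$n_strains == 2, ]
  d_half <- geosphere::distHaversine(c(-10, 0), c(0, 0), r = 6371008.8) / 1000
  expect_equal(top$dc[1], d_half, tolerance = 1e-9)

  ## random configuration: brute-force recomputation
  set.seed(99)
  tr <- simulateTree(10, 1, seed = 100)
  aln <- evolveSequences(tr, 60, 0.02, seed = 101)
  st3 <- toySites(runif(4, 25, 60), lon = runif(4, -120, -70))
  tab <- haplotypeTable(aln)
  strains3 <- data.frame(
    strain_id = sprintf("st%02d", 1:30),
    site_id = sample(siteNames(st3), 30, TRUE),
    haplotype_id = sample(tab$haplotype_id, 30, TRUE))
  net3 <- resolveLoops(buildNetwork(haplotypeTable(aln, strains3), limit = 6))
  design3 <- nestClades(net3)
  cd3 <- cladeDistances(design3, strains3, st3,
                        mapping = attr(tab, "mapping"))
  m <- designMembership(design3)
  sd_ <- siteData(st3)
  lv <- 1
  for (i in which(cd3$level == lv & cd3$n_strains > 0)) {
    members <- m$node[m[[paste0("level_", lv)]] == cd3$clade[i]]
    rows <- strains3[strains3$haplotype_id %in% members, ]
    lon <- sd_$longitude[match(rows$site_id, sd_$site_id)]
    lat <- sd_$latitude[match(rows$site_id, sd_$site_id)]
    rad <- pi / 180
    v <- c(sum(cos(lat * rad) * cos(lon * rad)),
           sum(cos(lat * rad) * sin(lon * rad)), sum(sin(lat * rad)))
    v <- v / sqrt(sum(v^2))
    ctr <- c(atan2(v[2], v[1]) / rad, asin(v[3]) / rad) # lon, lat
    dc_oracle <- mean(geosphere::distHaversine(cbind(lon, lat), ctr,
                                               r = 6371008.8) / 1000)
    expect_equal(cd3$dc[i], dc_oracle, tolerance = 1e-9)
  }
})

test_that("NCA permutation flags a geographically confined clade", {
  ## parent clade with two daughters: one confined to a single site inside
  ## a widespread parent -> its Dc must be flagged significantly small
  seqs <- c(A = "AAAA", B = "AAAT", C = "AATT")
  tab0 <- haploTab(seqs)
  st <- toySites(c(25, 35, 45, 55, 65),
                 lon = c(-120, -105, -90, -80, -70))
  strains <- rbind(
    data.frame(strain_id = sprintf("a%02d", 1:20), site_id = "S03",
               haplotype_id = "A"),
    data.frame(strain_id = sprintf("b%02d", 1:10), site_id = "S01",
               haplotype_id = "B"),
    data.frame(strain_id = sprintf("b2%02d", 1:10), site_id = "S05",
               haplotype_id = "B"),
    data.frame(strain_id = sprintf("c%02d", 1:10), site_id = "S02",
               haplotype_id = "C"),
    data.frame(strain_id = sprintf("c2%02d", 1:10), site_id = "S04",
               haplotype_id = "C"))
  net <- buildNetwork(haplotypeTable(
    Biostrings::DNAStringSet(seqs), strains), limit = 5)
  design <- nestClades(net)
  res <- ncaPermutation(design, strains, st, n_perm = 499, seed = 7)
  cl <- res$clades
  a_rows <- cl[vapply(strsplit(cl$clade, "_"), function(x) x[1] != "C",
                      NA) & cl$clade == "A", ]
  expect_true(nrow(a_rows) >= 1)
  expect_true(any(a_rows$dc_flag == "small"))
})

test_that("single-daughter nesting groups produce no flags", {
  seqs <- c(A = "AAAA", B = "AAAT")
  strains <- data.frame(strain_id = c("s1", "s2"),
                        site_id = c("S01", "S02"),
                        haplotype_id = c("A", "B"))
  st <- toySites(c(30, 50))
  net <- buildNetwork(haplotypeTable(
    Biostrings::DNAStringSet(seqs), strains), limit = 3)
  design <- nestClades(net)
  ## the level-1 clade {A,B} has two daughters; restrict to a degenerate
  ## single-site observation set so permutations cannot vary
  res <- ncaPermutation(design, strains[1, ], st, n_perm = 99, seed = 1)
  if (nrow(res$clades)) {
    expect_true(all(res$clades$dc_flag == "" | res$clades$p_dc_small > 0.05))
  } else {
    expect_equal(nrow(res$clades), 0)
  }
})

test_that("interpretNca walks the decision table deterministically", {
  mk <- function(dc_flags, dn_flags, tips) {
    list(clades = data.frame(
      parent = "C2_001", clade = sprintf("C1_%03d", seq_along(dc_flags)),
      level = 1, is_tip = tips, n_strains = 10,
      dc = 100, dn = 100,
      p_dc_large = ifelse(dc_flags == "large", 0.01, 0.5),
      p_dc_small = ifelse(dc_flags == "small", 0.01, 0.5),
      p_dn_large = ifelse(dn_flags == "large", 0.01, 0.5),
      p_dn_small = ifelse(dn_flags == "small", 0.01, 0.5),
      dc_flag = dc_flags, dn_flag = dn_flags,
      stringsAsFactors = FALSE),
      contrasts = data.frame(parent = character(), level = numeric(),
                             it_dc = numeric(), it_dn = numeric(),
                             p_it_dc_large = numeric(),
                             p_it_dc_small = numeric(),
                             p_it_dn_large = numeric(),
                             p_it_dn_small = numeric()),
      alpha = 0.05, n_perm = 999, seed = 1)
  }
  ## no flags anywhere
  quiet <- mk(c("", ""), c("", ""), c(TRUE, FALSE))
  expect_equal(interpretNca(quiet)$inference, "no significant association")
  ## tip Dc small + interior Dc large: isolation by distance chain
  ibd <- mk(c("small", "large"), c("", ""), c(TRUE, FALSE))
  expect_equal(interpretNca(ibd)$inference,
               "restricted gene flow with isolation by distance")
  ## tip Dc large: range expansion chain
  cre <- mk(c("large", ""), c("", ""), c(TRUE, FALSE))
  expect_equal(interpretNca(cre)$inference, "contiguous range expansion")
  ## flags that match no shipped chain
  odd <- mk(c("", ""), c("large", ""), c(TRUE, FALSE))
  expect_equal(interpretNca(odd)$inference, "inconclusive")
  ## malformed tables are rejected
  expect_error(interpretNca(quiet, table = list()), "malformed")
  expect_error(interpretNca(quiet, table = list(rules = list(list(x = 1)))),
               "malformed")
  ## table round-trips through JSON
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(defaultInferenceTable(), f, auto_unbox = TRUE)
  expect_equal(interpretNca(ibd, table = f)$inference,
               "restricted gene flow with isolation by distance")
})
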