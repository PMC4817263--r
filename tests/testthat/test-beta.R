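test_that("unweighted UniFrac matches worked examples and the edge oracle", {
  bal <- balancedTree()
  m <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), bal$tip.label))
  d <- as.matrix(unifracMatrix(bal, communityMatrix(m)))
  expect_equal(d["s1", "s2"], 1) # no shared branches below the root

  m2 <- rbind(m, s3 = c(1, 1, 0, 0))
  d2 <- as.matrix(unifracMatrix(bal, communityMatrix(m2)))
  expect_equal(d2["s1", "s3"], 0) # identical communities

  tr <- simulateTree(15, 1, seed = 81)
  set.seed(82)
  comm <- randomCommunity(tr, 4, p = 0.35)
  got <- as.matrix(unifracMatrix(tr, comm))
  mm <- communityCounts(comm)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(got[i, j],
                 unifracOracle(tr, colnames(mm)[mm[i, ] > 0],
                               colnames(mm)[mm[j, ] > 0]))
  }
  ## and against picante's implementation
  expect_equal(got, as.matrix(picante::unifrac(mm, tr))[rownames(got),
                                                        rownames(got)],
               tolerance = 1e-10)
  expect_error(unifracMatrix(bal, communityMatrix(
    matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 2, byrow = TRUE,
           dimnames = list(c("e", "f"), bal$tip.label)))), "empty site")
})

test_that("abundance-weighted UniFrac stays within [0, 1] and detects identity", {
  tr <- simulateTree(12, 1, seed = 83)
  set.seed(84)
  m <- matrix(rpois(36, 3), 3, 12,
              dimnames = list(c("s1", "s2", "s3"), tr$tip.label))
  m[rowSums(m) == 0, 1] <- 1
  m <- rbind(m, s4 = m[1, ]) # duplicate site
  d <- as.matrix(unifracMatrix(tr, communityMatrix(m), "abundance_weighted"))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d["s1", "s4"], 0)
})

test_that("UniFrac label permutation gives minimal p for disjoint clades", {
  ## two sites on disjoint clades of a balanced tree separate maximally
  bal <- balancedTree()
  m <- matrix(c(5, 5, 0, 0, 0, 0, 5, 5), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), bal$tip.label))
  res <- unifracSignificance(bal, communityMatrix(m), n_perm = 49, seed = 9)
  expect_equal(as.matrix(res$observed)["s1", "s2"], 1)
  ## permuted assemblages can tie the observed maximum only rarely; the
  ## p-value must be far below any plausible null expectation
  expect_lte(res$p["s1", "s2"], 0.1)
  expect_gte(res$p["s1", "s2"], 1 / 50)
})

test_that("Bray-Curtis follows the direct formula and vegan", {
  m <- matrix(c(1, 1, 2, 0, 0, 2, 6, 2, 2, 2),
              nrow = 5, byrow = TRUE,
              dimnames = list(paste0("s", 1:5), c("t1", "t2")))
  d <- as.matrix(brayCurtisMatrix(communityMatrix(m)))
  expect_equal(d["s1", "s1"], 0)
  expect_equal(d["s2", "s3"], 1)            # disjoint (2,0) vs (0,2)
  expect_equal(d["s4", "s5"], 4 / 12)       # (6,2) vs (2,2)
  expect_equal(d, as.matrix(vegan::vegdist(m, "bray")), tolerance = 1e-12)
  ## unweighted view collapses to presence
  du <- as.matrix(brayCurtisMatrix(communityMatrix(m), "unweighted"))
  expect_equal(du["s4", "s5"], 0)
  expect_error(brayCurtisMatrix(communityMatrix(
    matrix(c(1, 0, 0, 0), 2, dimnames = list(c("a", "b"), c("x", "y"))))),
    "empty site")
})

test_that("haversine distances: analytic values, symmetry, triangle", {
  st <- toySites(c(0, 0), lon = c(0, 180), ids = c("p1", "p2"))
  d <- as.matrix(haversineMatrix(st))
  expect_equal(d["p1", "p2"], 20015.1, tolerance = 1e-4) # half circumference
  st2 <- toySites(c(10, 10), lon = c(20, 20), ids = c("a", "b"))
  expect_equal(as.matrix(haversineMatrix(st2))["a", "b"], 0)

  set.seed(85)
  st3 <- toySites(runif(20, -60, 60), lon = runif(20, -180, 180))
  d3 <- as.matrix(haversineMatrix(st3))
  expect_equal(d3, t(d3))
  for (k in 1:30) {
    ijk <- sample(20, 3)
    expect_lte(d3[ijk[1], ijk[2]],
               d3[ijk[1], ijk[3]] + d3[ijk[3], ijk[2]] + 1e-8)
  }
})

test_that("environmental distance is Euclidean on z-scores", {
  d <- siteData(toySites(c(30, 50)))
  d$pH <- c(5, 7); d$som <- c(5, 5); d$temp <- c(10, 10); d$ppt <- c(800, 800)
  st <- siteTable(d)
  expect_warning(ed <- envDistance(st), "zero-variance")
  expect_equal(as.matrix(ed)["S01", "S02"], 2) # one variable, z = -1 and +1

  set.seed(86)
  d2 <- siteData(toySites(seq(30, 55, length.out = 6)))
  d2$pH <- rnorm(6); d2$som <- rnorm(6); d2$temp <- rnorm(6)
  d2$ppt <- rnorm(6)
  ed2 <- as.matrix(envDistance(siteTable(d2)))
  x <- as.matrix(d2[c("pH", "som", "temp", "ppt")])
  z <- scale(x, scale = apply(x, 2, sd) * sqrt(5 / 6)) # population SD
  expect_equal(ed2["S02", "S05"], sqrt(sum((z[2, ] - z[5, ])^2)))
  ## duplicate site rows are at distance zero
  d3 <- rbind(d2, d2[1, ]); d3$site_id[7] <- "S07"; d3$time_rank[7] <- 7
  expect_equal(as.matrix(envDistance(siteTable(d3)))["S01", "S07"], 0)
})

test_that("mantelTest: identity gives r = 1 with minimal p", {
  set.seed(87)
  x <- matrix(rnorm(16), 8)
  d1 <- as.matrix(dist(x)); dimnames(d1) <- list(letters[1:8], letters[1:8])
  mt <- mantelTest(d1, d1, n_perm = 199, seed = 3)
  expect_equal(mt@value, 1)
  expect_equal(mt@r_squared, 1)
  expect_equal(mt@p_value, 1 / 200)
  expect_error(mantelTest(d1[1:3, 1:3], d1[1:3, 1:3]), "n >= 4")
  cm <- matrix(1, 8, 8, dimnames = dimnames(d1)); diag(cm) <- 0
  expect_error(mantelTest(d1, cm), "constant")
})

test_that("mantelTest p equals full enumeration at n = 5", {
  set.seed(88)
  m1 <- as.matrix(dist(matrix(rnorm(10), 5)))
  m2 <- as.matrix(dist(matrix(rnorm(10), 5)))
  dimnames(m1) <- dimnames(m2) <- list(letters[1:5], letters[1:5])
  mt <- mantelTest(m1, m2, n_perm = 999, seed = 4) # complete enumeration
  P <- permsOf(5)
  rs <- apply(P, 1, function(p)
    stats::cor(m1[upper.tri(m1)], (m2[p, p])[upper.tri(m2)]))
  expect_equal(mt@p_value, mean(rs >= mt@value - 1e-9))
})

test_that("permanovaTest matches adonis2 and exhaustive enumeration", {
  set.seed(89)
  x <- matrix(rnorm(12), 6)
  dd <- dist(x)
  g <- c("a", "a", "a", "b", "b", "b")
  got <- permanovaTest(as.matrix(dd), g, exhaustive = TRUE)
  ref <- vegan::adonis2(dd ~ g, permutations = 99)
  expect_equal(got@value, ref$F[1])
  expect_equal(got@r_squared, ref$R2[1])

  ## independent oracle: classical group-sum-of-squares identity plus
  ## explicit enumeration of all 720 relabelings
  D2 <- as.matrix(dd)^2
  n <- 6
  ssFromGroups <- function(grp) {
    ss_t <- sum(D2[upper.tri(D2)]) / n
    ss_w <- sum(vapply(unique(grp), function(l) {
      ix <- which(grp == l)
      sum(D2[ix, ix][upper.tri(D2[ix, ix])]) / length(ix)
    }, 0))
    c(model = ss_t - ss_w, total = ss_t)
  }
  ss <- ssFromGroups(g)
  expect_equal(got@r_squared, unname(ss["model"] / ss["total"]))
  f_of <- function(grp) {
    s <- ssFromGroups(grp)
    (s["model"] / 1) / ((s["total"] - s["model"]) / 4)
  }
  fs <- apply(permsOf(6), 1, function(p) f_of(g[p]))
  expect_equal(got@p_value, mean(fs >= got@value - 1e-12))

  ## scale invariance of R2
  got2 <- permanovaTest(as.matrix(dd) * 3.7, g, exhaustive = TRUE)
  expect_equal(got2@r_squared, got@r_squared)
  expect_error(permanovaTest(as.matrix(dd), rep("a", 6)), "singular")
})

test_that("equidistant sites give a flat PERMANOVA (F = 1, p = 1)", {
  n <- 6
  D <- matrix(1, n, n); diag(D) <- 0
  dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
  got <- permanovaTest(D, rep(c("a", "b"), each = 3), exhaustive = TRUE)
  expect_equal(got@value, 1)
  expect_equal(got@p_value, 1)
})

test_that("correlationTable matches cor.test and flags significance", {
  set.seed(90)
  df <- data.frame(a = rnorm(12), b = rnorm(12))
  df$c <- -df$a
  df$d <- df$a + rnorm(12, sd = 0.1)
  ct <- correlationTable(df)
  expect_equal(diag(ct$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(ct$r["a", "c"], -1)
  ref <- stats::cor.test(df$a, df$b)
  expect_equal(ct$p["a", "b"], ref$p.value)
  expect_equal(ct$r["a", "b"], unname(ref$estimate))
  expect_true(ct$stars["a", "d"] %in% c("*", "**", "***"))
  ## constant column reported as missing
  df$e <- 1
  ct2 <- correlationTable(df)
  expect_true(all(is.na(ct2$r["e", ])))
})
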