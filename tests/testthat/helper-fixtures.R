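## shared fixtures and independent oracle implementations

balancedTree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

caterpillarTree <- function()
  ape::read.tree(text = "((((A:1,B:1):1,C:1):1,D:1):1,E:1);")

## minimal valid site table around given latitudes
toySites <- function(lat, lon = NULL, glaciated = lat > 40,
                     ids = sprintf("S%02d", seq_along(lat))) {
  n <- length(lat)
  if (is.null(lon)) lon <- seq(-120, -70, length.out = n)
  siteTable(data.frame(
    site_id = ids, latitude = lat, longitude = lon,
    pH = rep(6, n), som = rep(5, n), temp = rep(10, n), ppt = rep(800, n),
    glaciated = glaciated, time_rank = seq_len(n)))
}

## independent patristic oracle: shortest paths on the weighted tree graph
patristicOracle <- function(tree) {
  n_tip <- length(tree$tip.label)
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  d <- igraph::distances(g, v = as.character(seq_len(n_tip)),
                         to = as.character(seq_len(n_tip)))
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

## independent Faith PD oracle: per-edge membership of descendant tips
pdOracle <- function(tree, taxa) {
  tips <- match(taxa, tree$tip.label)
  sum(vapply(seq_len(nrow(tree$edge)), function(e) {
    below <- phangorn::Descendants(tree, tree$edge[e, 2], "tips")[[1]]
    if (any(tips %in% below)) tree$edge.length[e] else 0
  }, 0))
}

## independent MRD oracle: count nodes on the ape::nodepath to the root
mrdOracle <- function(tree, taxa) {
  root <- length(tree$tip.label) + 1L
  mean(vapply(match(taxa, tree$tip.label), function(t) {
    length(ape::nodepath(tree, t, root)) - 1L
  }, 0L))
}

## independent unweighted-UniFrac oracle: classify every edge as shared or
## unique from descendant tip sets
unifracOracle <- function(tree, taxa1, taxa2) {
  t1 <- match(taxa1, tree$tip.label); t2 <- match(taxa2, tree$tip.label)
  uniq <- tot <- 0
  for (e in seq_len(nrow(tree$edge))) {
    below <- phangorn::Descendants(tree, tree$edge[e, 2], "tips")[[1]]
    in1 <- any(t1 %in% below); in2 <- any(t2 %in% below)
    if (in1 || in2) tot <- tot + tree$edge.length[e]
    if (xor(in1, in2)) uniq <- uniq + tree$edge.length[e]
  }
  uniq / tot
}

## all permutations of 1..n as a matrix (test-local copy)
permsOf <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permsOf(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

## random community over a tree's tips, every site with >= min_rich taxa
randomCommunity <- function(tree, n_sites, p = 0.4, min_rich = 2) {
  n <- length(tree$tip.label)
  m <- matrix(rbinom(n_sites * n, 1, p), n_sites, n,
              dimnames = list(sprintf("s%d", seq_len(n_sites)),
                              tree$tip.label))
  for (i in seq_len(n_sites)) {
    while (sum(m[i, ]) < min_rich) m[i, sample(n, 1)] <- 1
  }
  communityMatrix(m)
}

## tiny haplotype table from explicit sequences
haploTab <- function(seqs, counts = rep(1, length(seqs)),
                     site_counts = NULL) {
  tab <- data.frame(haplotype_id = names(seqs), count = counts,
                    sequence = unname(seqs), stringsAsFactors = FALSE)
  attr(tab, "siteCounts") <-
    if (is.null(site_counts))
      matrix(0, length(seqs), 0, dimnames = list(names(seqs), NULL))
    else site_counts
  tab
}
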