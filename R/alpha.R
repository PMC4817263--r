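#' Faith's phylogenetic diversity
#'
#' Total branch length of the union of root-to-tip paths over the taxa
#' present at a site (root-inclusive convention: the branches connecting
#' the taxa to the tree root are all counted, so even a single-taxon site
#' has positive PD).
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param taxa_present Character vector of tip labels present.
#' @return Summed branch length.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' faithPD(tr, c("A", "B")) # 3
#' @export
faithPD <- function(tree, taxa_present) {
  if (length(taxa_present) == 0) stop("no taxa present", call. = FALSE)
  idx <- match(taxa_present, tree$tip.label)
  if (anyNA(idx))
    stop("unknown taxon: ", taxa_present[is.na(idx)][1], call. = FALSE)
  paths <- tipEdgePaths(tree)
  edges <- unique(unlist(paths[idx]))
  sum(tree$edge.length[edges])
}

#' Mean root distance
#'
#' Average, over the taxa present, of the number of nodes separating each
#' tip from the tree root (the root counts, the tip does not; equivalently
#' the number of edges on the tip-to-root path). Higher values indicate
#' assemblages dominated by more derived lineages.
#'
#' @inheritParams faithPD
#' @return Mean node count.
#' @export
meanRootDistance <- function(tree, taxa_present) {
  if (length(taxa_present) == 0) stop("no taxa present", call. = FALSE)
  idx <- match(taxa_present, tree$tip.label)
  if (anyNA(idx))
    stop("unknown taxon: ", taxa_present[is.na(idx)][1], call. = FALSE)
  paths <- tipEdgePaths(tree)
  mean(vapply(paths[idx], length, 1L))
}

.mpd <- function(D, idx) {
  sub <- D[idx, idx]
  mean(sub[upper.tri(sub)])
}

.mntd <- function(D, idx) {
  sub <- D[idx, idx]
  diag(sub) <- Inf
  mean(apply(sub, 1, min))
}

#' Standardized effect size of MPD / MNTD (NRI / NTI)
#'
#' Observed mean pairwise (MPD) or mean nearest-taxon (MNTD) patristic
#' distance among the taxa present at each site, compared to a null model
#' in which the same number of taxa is drawn without replacement from the
#' pool of all taxa in the community matrix. The reported index negates
#' the z-score (NRI for MPD, NTI for MNTD) so that positive values
#' indicate phylogenetic clustering. The permutation p-value is two-sided:
#' `(1 + #{null draws as or more extreme than observed}) / (n_perm + 1)`.
#' A degenerate null (zero spread, e.g. a site containing the whole pool)
#' reports index 0, p 1 and `degenerate = TRUE`.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param community [CommunityMatrix-class]; statistics are presence-based
#'   (pass the unweighted [communityView()] explicitly if in doubt —
#'   abundances are ignored either way).
#' @param metric `"MPD"` or `"MNTD"`.
#' @param n_perm Null draws (ignored for `null = "exhaustive"`).
#' @param seed Integer seed.
#' @param null `"sample"` (Monte-Carlo) or `"exhaustive"` (enumerate all
#'   subsets of the pool; only for small pools).
#' @return data.frame with one row per site with >= 2 taxa: `site_id`,
#'   `richness`, `obs`, `null_mean`, `null_sd`, `z`, `index`, `p`,
#'   `degenerate`.
#' @export
sesMetric <- function(tree, community, metric = c("MPD", "MNTD"),
                      n_perm = 999, seed = NULL,
                      null = c("sample", "exhaustive")) {
  metric <- match.arg(metric)
  null <- match.arg(null)
  m <- communityCounts(community)
  pool <- colnames(m)
  bad <- setdiff(pool, tree$tip.label)
  if (length(bad)) stop("unknown taxon: ", bad[1], call. = FALSE)
  D <- as.matrix(patristicMatrix(tree))[pool, pool]
  stat <- if (metric == "MPD") .mpd else .mntd
  rows <- withSeed(seed, lapply(rownames(m), function(s) {
    present <- which(m[s, ] > 0)
    k <- length(present)
    if (k < 2) {
      return(data.frame(site_id = s, richness = k, obs = NA_real_,
                        null_mean = NA_real_, null_sd = NA_real_,
                        z = NA_real_, index = NA_real_, p = NA_real_,
                        degenerate = NA))
    }
    obs <- stat(D, present)
    nulls <- if (null == "exhaustive") {
      combos <- utils::combn(length(pool), k)
      if (ncol(combos) > 2e5)
        stop("exhaustive null too large; use null = 'sample'", call. = FALSE)
      apply(combos, 2, function(idx) stat(D, idx))
    } else {
      vapply(seq_len(n_perm), function(i) {
        stat(D, sample(length(pool), k))
      }, 0)
    }
    mu <- mean(nulls)
    sdev <- stats::sd(nulls)
    if (!is.finite(sdev) || sdev < 1e-12) {
      data.frame(site_id = s, richness = k, obs = obs, null_mean = mu,
                 null_sd = 0, z = 0, index = 0, p = 1, degenerate = TRUE)
    } else {
      z <- (obs - mu) / sdev
      extreme <- sum(abs(nulls - mu) >= abs(obs - mu) - 1e-12)
      data.frame(site_id = s, richness = k, obs = obs, null_mean = mu,
                 null_sd = sdev, z = z, index = -z,
                 p = permPvalue(extreme, length(nulls)), degenerate = FALSE)
    }
  }))
  out <- do.call(rbind, rows)
  attr(out, "metric") <- metric
  attr(out, "index_name") <- if (metric == "MPD") "NRI" else "NTI"
  out
}

#' Per-site alpha phylodiversity table
#'
#' Convenience wrapper computing Faith's PD, NRI, NTI (with permutation
#' p-values) and mean root distance for every site of a community matrix.
#'
#' @inheritParams sesMetric
#' @return data.frame with `site_id`, `richness`, `pd`, `nri`, `p_nri`,
#'   `nti`, `p_nti`, `mrd`.
#' @export
siteDiversity <- function(tree, community, n_perm = 999, seed = NULL) {
  m <- communityCounts(community)
  nri <- sesMetric(tree, community, "MPD", n_perm = n_perm,
                   seed = childSeed(seed, "nri"))
  nti <- sesMetric(tree, community, "MNTD", n_perm = n_perm,
                   seed = childSeed(seed, "nti"))
  pd <- vapply(rownames(m), function(s) {
    present <- colnames(m)[m[s, ] > 0]
    if (length(present) == 0) NA_real_ else faithPD(tree, present)
  }, 0)
  mrd <- vapply(rownames(m), function(s) {
    present <- colnames(m)[m[s, ] > 0]
    if (length(present) == 0) NA_real_ else meanRootDistance(tree, present)
  }, 0)
  data.frame(site_id = rownames(m), richness = nri$richness, pd = pd,
             nri = nri$index, p_nri = nri$p, nti = nti$index,
             p_nti = nti$p, mrd = mrd, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Two-group contrast of a per-site statistic
#'
#' Compares a statistic between two groups of sites (typically glaciated
#' vs nonglaciated), reporting group means and SDs (n-1 denominator) and
#' two-sided p-values from both Welch's t and the Mann-Whitney test. When
#' either group has a single member, Welch's test is unavailable and the
#' Mann-Whitney p is used, with a warning.
#'
#' @param values Numeric per-site statistic.
#' @param groups Logical (or two-level) group indicator, same length.
#' @param test Preferred test, `"welch"` or `"mannwhitney"`.
#' @return List with `mean`, `sd`, `n` (per group), `p_welch`, `p_mannwhitney`,
#'   `p` (from the selected test) and `test`.
#' @export
groupContrast <- function(values, groups, test = c("welch", "mannwhitney")) {
  test <- match.arg(test)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("need exactly two groups", call. = FALSE)
  ok <- !is.na(values)
  sp <- split(values[ok], groups[ok])
  if (any(vapply(sp, length, 1L) == 0))
    stop("both groups must be non-empty", call. = FALSE)
  means <- vapply(sp, mean, 0)
  sds <- vapply(sp, stats::sd, 0)
  p_mw <- stats::wilcox.test(sp[[1]], sp[[2]], exact = FALSE,
                             correct = FALSE)$p.value
  if (any(vapply(sp, length, 1L) < 2)) {
    if (test == "welch") {
      warning("a group has size 1; Welch unavailable, using Mann-Whitney",
              call. = FALSE)
      test <- "mannwhitney"
    }
    p_welch <- NA_real_
  } else {
    p_welch <- stats::t.test(sp[[1]], sp[[2]], var.equal = FALSE)$p.value
  }
  list(mean = means, sd = sds, n = vapply(sp, length, 1L),
       p_welch = p_welch, p_mannwhitney = p_mw,
       p = if (test == "welch") p_welch else p_mw, test = test)
}

#' Spearman rank correlation with a per-site covariate
#'
#' Spearman's rho with mid-rank ties; the p-value is exact for n <= 10
#' in the absence of ties and uses the t approximation otherwise.
#'
#' @param values Numeric vector (e.g. per-site PD).
#' @param ranks Numeric vector (e.g. colonization-time rank).
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
rankCorrelation <- function(values, ranks) {
  if (length(values) != length(ranks))
    stop("'values' and 'ranks' must have equal length", call. = FALSE)
  ok <- !is.na(values) & !is.na(ranks)
  values <- values[ok]; ranks <- ranks[ok]
  if (length(values) < 3)
    stop("need >= 3 paired observations", call. = FALSE)
  if (stats::sd(values) == 0 || stats::sd(ranks) == 0)
    stop("constant vector: rank correlation undefined", call. = FALSE)
  n <- length(values)
  ties <- anyDuplicated(values) || anyDuplicated(ranks)
  exact <- n <= 10 && !ties
  ct <- suppressWarnings(
    stats::cor.test(values, ranks, method = "spearman", exact = exact))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n,
       method = if (exact) "exact" else "t-approximation")
}
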