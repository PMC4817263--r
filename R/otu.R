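#' Patristic distance matrix
#'
#' Tip-to-tip distances: the sum of branch lengths along the path joining
#' each pair of tips.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @return A [DistanceMatrix-class] of kind `"patristic"`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):1,C:3);")
#' as.matrix(patristicMatrix(tr))
#' @export
patristicMatrix <- function(tree) {
  assertBranchLengths(tree)
  distanceMatrix(ape::cophenetic.phylo(tree), kind = "patristic")
}

## children list indexed by node id
.childrenList <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  ch
}

#' Cluster tips into OTUs at a patristic-distance threshold
#'
#' Two clustering rules are provided. `"node_depth"` (default) takes the
#' maximal clades in which every tip lies within `threshold/2` (patristic)
#' of the clade root, so the deepest tip-to-root radius bounds within-OTU
#' divergence; tips absorbed by no qualifying clade become singletons.
#' `"max_pairwise"` is complete-linkage agglomeration on the patristic
#' matrix cut at `threshold`, bounding the maximum within-OTU tip-pair
#' distance directly.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param threshold Patristic-distance cutoff (substitutions/site);
#'   default 0.01.
#' @param method `"node_depth"` or `"max_pairwise"`.
#' @return data.frame with `haplotype_id` and `otu_id`, one row per tip;
#'   attributes `threshold` and `method` record the rule.
#' @export
clusterOtus <- function(tree, threshold = 0.01,
                        method = c("node_depth", "max_pairwise")) {
  assertBranchLengths(tree)
  method <- match.arg(method)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  tips <- tree$tip.label
  n_tip <- length(tips)
  if (method == "node_depth") {
    ch <- .childrenList(tree)
    edge_len <- numeric(n_tip + tree$Nnode)
    edge_len[tree$edge[, 2]] <- tree$edge.length
    ## max distance from each node down to its deepest descendant tip
    maxdepth <- rep(NA_real_, n_tip + tree$Nnode)
    nodeDepth <- function(nd) {
      if (nd <= n_tip) return(0)
      d <- vapply(ch[[nd]], function(c) nodeDepth(c) + edge_len[c], 0)
      maxdepth[nd] <<- max(d)
      maxdepth[nd]
    }
    root <- n_tip + 1L
    nodeDepth(root)
    groups <- list()
    collect <- function(nd) {
      ok <- if (nd <= n_tip) TRUE else maxdepth[nd] <= threshold / 2
      if (ok) {
        members <- if (nd <= n_tip) tips[nd]
                   else tips[phangorn::Descendants(tree, nd, "tips")[[1]]]
        groups[[length(groups) + 1L]] <<- members
      } else {
        for (c in ch[[nd]]) collect(c)
      }
    }
    collect(root)
  } else {
    d <- as.matrix(patristicMatrix(tree))
    ord <- order(tips)
    d <- d[ord, ord] # lexicographic label order fixes agglomeration ties
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    cl <- stats::cutree(hc, h = threshold)
    groups <- split(names(cl), cl)
  }
  ## deterministic OTU ids, ordered by smallest member label
  groups <- groups[order(vapply(groups, min, ""))]
  otu <- rep(sprintf("OTU%03d", seq_along(groups)),
             vapply(groups, length, 1L))
  out <- data.frame(haplotype_id = unlist(groups, use.names = FALSE),
                    otu_id = otu, stringsAsFactors = FALSE)
  out <- out[match(tips, out$haplotype_id), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "method") <- method
  out
}

#' Representative tip per OTU
#'
#' @param assignment Output of [clusterOtus()].
#' @return Named character vector: OTU id -> lexicographically smallest
#'   member tip.
#' @export
otuRepresentatives <- function(assignment) {
  vapply(split(assignment$haplotype_id, assignment$otu_id), min, "")
}

#' Prune a tree to one representative tip per OTU
#'
#' Keeps the lexicographically smallest member of each OTU and renames the
#' kept tips to their OTU ids, giving a tree usable for OTU-level
#' phylogenetic statistics.
#'
#' @param tree [ape::phylo].
#' @param assignment Output of [clusterOtus()].
#' @return An [ape::phylo] with one tip per OTU, labelled by OTU id.
#' @export
otuRepresentativeTree <- function(tree, assignment) {
  reps <- otuRepresentatives(assignment)
  pruned <- ape::keep.tip(tree, unname(reps))
  pruned$tip.label <- names(reps)[match(pruned$tip.label, reps)]
  pruned
}

#' Collapse identical sequences into haplotypes
#'
#' Exact string-identity grouping; each group's representative is its
#' lexicographically smallest member id.
#'
#' @param alignment `DNAStringSet` (or named character) of equal-length
#'   sequences.
#' @return data.frame with `haplotype_id` (representative), `count` and
#'   `sequence`; attribute `"mapping"` maps every input id to its
#'   representative.
#' @export
dedupHaplotypes <- function(alignment) {
  seqs <- if (is.character(alignment)) alignment else as.character(alignment)
  if (is.null(names(seqs))) stop("sequences must be named", call. = FALSE)
  if (length(unique(nchar(seqs))) > 1)
    stop("sequences must share one length", call. = FALSE)
  groups <- split(names(seqs), seqs)
  reps <- vapply(groups, min, "")
  ord <- order(reps)
  out <- data.frame(haplotype_id = unname(reps[ord]),
                    count = vapply(groups, length, 1L)[ord],
                    sequence = names(groups)[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  mapping <- stats::setNames(rep(reps, vapply(groups, length, 1L)),
                             unlist(groups, use.names = FALSE))
  attr(out, "mapping") <- mapping
  out
}

#' Good's coverage estimator
#'
#' `C = 1 - f1/N`, the estimated fraction of individuals belonging to
#' classes already observed more than once.
#'
#' @param counts Non-negative integer abundance vector.
#' @return Coverage in `[0, 1]`.
#' @examples
#' goodsCoverage(c(5, 3, 1, 1)) # 0.8
#' @export
goodsCoverage <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) stop("total count must be positive", call. = FALSE)
  1 - sum(counts == 1) / n
}

#' Rarefaction curve
#'
#' Expected number of distinct classes in subsamples drawn without
#' replacement, by Monte-Carlo (mean and SD over `n_reps` draws) and by
#' the exact hypergeometric formula
#' `E[S_d] = sum_i (1 - C(N - n_i, d)/C(N, d))`.
#'
#' @param counts Non-negative integer abundance vector.
#' @param depths Subsample sizes (each <= `sum(counts)`).
#' @param n_reps Monte-Carlo replicates per depth.
#' @param seed Integer seed.
#' @return data.frame with `depth`, `mean_richness`, `sd_richness`,
#'   `expected_richness`.
#' @export
rarefactionCurve <- function(counts, depths, n_reps = 100, seed = NULL) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (any(depths < 1) || any(depths > n))
    stop("depths must lie in [1, total count]", call. = FALSE)
  pool <- rep(seq_along(counts), counts)
  exact <- vapply(depths, function(d) {
    sum(1 - exp(lchoose(n - counts, d) - lchoose(n, d)))
  }, 0)
  mc <- withSeed(seed, {
    vapply(depths, function(d) {
      reps <- vapply(seq_len(n_reps), function(i) {
        length(unique(sample(pool, d)))
      }, 0L)
      c(mean(reps), stats::sd(reps))
    }, c(0, 0))
  })
  data.frame(depth = depths, mean_richness = mc[1, ],
             sd_richness = mc[2, ], expected_richness = exact)
}
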