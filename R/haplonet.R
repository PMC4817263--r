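#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps `j` between two haplotypes such that
#' the probability that the `j` observed differences arose without any
#' superimposed (homoplastic) change still exceeds `confidence`. The
#' probability model: the Jukes-Cantor-corrected divergence for `j`
#' observed differences over `seq_length` sites implies an expected excess
#' of `seq_length * d_JC - j` unobserved superimposed substitutions;
#' treating that excess as a Poisson mean, the probability of strict
#' parsimony is `exp(-(seq_length * d_JC - j))`. A single step is always
#' trusted, so the limit is at least 1, is non-decreasing in `seq_length`,
#' and tends to 1 as `confidence` tends to 1.
#'
#' @param seq_length Alignment length in bp.
#' @param confidence Required parsimony probability (default 0.95).
#' @return Integer connection limit (mutational steps).
#' @examples
#' parsimonyLimit(377) # the limit for a 377-bp locus at 95%
#' @export
parsimonyLimit <- function(seq_length, confidence = 0.95) {
  if (seq_length <= 0) stop("seq_length must be positive", call. = FALSE)
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must lie in (0, 1)", call. = FALSE)
  j <- 1L
  repeat {
    jn <- j + 1L
    if (jn >= 0.74 * seq_length) break # JC correction undefined beyond this
    p_obs <- jn / seq_length
    d_jc <- -0.75 * log(1 - 4 * p_obs / 3)
    p_pars <- exp(-(seq_length * d_jc - jn))
    if (p_pars < confidence) break
    j <- jn
  }
  j
}

## Hamming distance matrix over equal-length sequence strings
.hammingMatrix <- function(seqs) {
  X <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(X)
  D <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- sum(X[i, ] != X[j, ])
    }
  }
  D
}

#' Haplotype table from an alignment and strain map
#'
#' Collapses the alignment to unique haplotypes ([dedupHaplotypes()]) and
#' attaches strain counts, overall and per site.
#'
#' @param alignment `DNAStringSet` (or named character vector).
#' @param strains Optional strain map (`strain_id`, `site_id`,
#'   `haplotype_id`); without it every sequence counts once.
#' @return data.frame (`haplotype_id`, `count`, `sequence`) with a
#'   `"siteCounts"` attribute (haplotype x site matrix).
#' @export
haplotypeTable <- function(alignment, strains = NULL) {
  tab <- dedupHaplotypes(alignment)
  mapping <- attr(tab, "mapping")
  if (is.null(strains)) {
    sc <- matrix(0, nrow(tab), 0, dimnames = list(tab$haplotype_id, NULL))
  } else {
    rep_of <- mapping[strains$haplotype_id]
    if (anyNA(rep_of))
      stop("strain map references unknown haplotype: ",
           strains$haplotype_id[is.na(rep_of)][1], call. = FALSE)
    sc <- unclass(table(factor(rep_of, levels = tab$haplotype_id),
                        strains$site_id))
    tab$count <- rowSums(sc)
    tab <- tab[tab$count > 0, , drop = FALSE]
    sc <- sc[tab$haplotype_id, , drop = FALSE]
    rownames(tab) <- NULL
  }
  attr(tab, "siteCounts") <- sc
  attr(tab, "mapping") <- mapping
  tab
}

#' Build a statistical-parsimony haplotype network
#'
#' Haplotype pairs are connected in order of increasing Hamming distance.
#' A pair at distance `d` is joined (inserting `d - 1` inferred,
#' unsampled intermediate nodes so every edge spans exactly one mutational
#' step) when its endpoints lie in different components at the moment the
#' distance class is processed; equally parsimonious alternative
#' connections within one distance class are all added, so ambiguities
#' remain as loops. Components are never joined across more than `limit`
#' steps.
#'
#' @param haplotypes data.frame from [haplotypeTable()] (needs
#'   `haplotype_id`, `sequence`, `count`).
#' @param limit Connection limit, e.g. from [parsimonyLimit()].
#' @return A [HaploNetwork-class].
#' @export
buildNetwork <- function(haplotypes, limit) {
  seqs <- stats::setNames(haplotypes$sequence, haplotypes$haplotype_id)
  if (length(unique(nchar(seqs))) > 1)
    stop("sequences must share one length", call. = FALSE)
  D <- .hammingMatrix(seqs)
  n <- length(seqs)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(names(seqs), observed = TRUE,
                     count = haplotypes$count)
  n_int <- 0L
  ## pair list sorted by (distance, label pair) for deterministic joining
  ut <- which(upper.tri(D), arr.ind = TRUE)
  pd <- D[ut]
  keep <- pd > 0 & pd <= limit
  ut <- ut[keep, , drop = FALSE]; pd <- pd[keep]
  u_lab <- pmin(names(seqs)[ut[, 1]], names(seqs)[ut[, 2]])
  v_lab <- pmax(names(seqs)[ut[, 1]], names(seqs)[ut[, 2]])
  o <- order(pd, u_lab, v_lab)
  pd <- pd[o]; u_lab <- u_lab[o]; v_lab <- v_lab[o]
  for (d in unique(pd)) {
    comp <- igraph::components(g)$membership
    for (e in which(pd == d)) {
      u <- u_lab[e]; v <- v_lab[e]
      if (comp[u] == comp[v]) next
      if (d == 1) {
        g <- igraph::add_edges(g, c(u, v))
      } else {
        mids <- sprintf("int%03d", n_int + seq_len(d - 1))
        n_int <- n_int + d - 1L
        g <- g + igraph::vertices(mids, observed = FALSE, count = 0)
        path <- c(u, mids, v)
        for (s in seq_len(d)) g <- igraph::add_edges(g, path[c(s, s + 1)])
      }
    }
  }
  new("HaploNetwork", graph = g,
      haplotypes = haplotypes[c("haplotype_id", "count")],
      siteCounts = attr(haplotypes, "siteCounts") %||%
        matrix(0, n, 0, dimnames = list(names(seqs), NULL)),
      limit = limit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## weighted spherical centroid (lon/lat degrees) of points with weights
.sphericalCentroid <- function(lon, lat, w) {
  rad <- pi / 180
  x <- sum(w * cos(lat * rad) * cos(lon * rad))
  y <- sum(w * cos(lat * rad) * sin(lon * rad))
  z <- sum(w * sin(lat * rad))
  nrm <- sqrt(x^2 + y^2 + z^2)
  if (nrm < 1e-12) return(c(lon = lon[1], lat = lat[1]))
  c(lon = atan2(y, x) / rad, lat = asin(z / nrm) / rad)
}

.gcKm <- function(lon, lat, centre) {
  geosphere::distHaversine(cbind(lon, lat), centre, r = 6371008.8) / 1000
}

## per-haplotype geographic centroids for loop resolution
.hapCentroids <- function(net, sites) {
  sc <- net@siteCounts
  if (is.null(sites) || ncol(sc) == 0) return(NULL)
  sd_ <- siteData(sites)
  idx <- match(colnames(sc), sd_$site_id)
  if (anyNA(idx)) stop("site counts reference unknown site", call. = FALSE)
  t(apply(sc, 1, function(w) {
    if (sum(w) == 0) return(c(lon = NA_real_, lat = NA_real_))
    .sphericalCentroid(sd_$longitude[idx], sd_$latitude[idx], w)
  }))
}

#' Resolve loops in a haplotype network
#'
#' Breaks every cycle by deleting one edge at a time, preferring to keep
#' connections (1) to higher-frequency haplotypes, then (2) to more
#' interior (higher-degree) nodes, then (3) to geographically closer
#' haplotypes; remaining ties break lexicographically by edge label, so
#' resolution is deterministic. Connected components are unchanged.
#'
#' @param net A [HaploNetwork-class].
#' @param sites Optional [SiteTable-class]; enables the geographic
#'   criterion when the network carries per-site counts.
#' @return A loop-free [HaploNetwork-class].
#' @export
resolveLoops <- function(net, sites = NULL) {
  g <- net@graph
  cents <- .hapCentroids(net, sites)
  repeat {
    gi <- igraph::girth(g)
    if (!is.finite(gi$girth) || gi$girth == 0) break
    cyc <- names(gi$circle)
    k <- length(cyc)
    pairs <- cbind(cyc, cyc[c(2:k, 1)])
    cnt <- igraph::V(g)$count[match(c(pairs), igraph::V(g)$name)]
    cnt <- matrix(cnt, ncol = 2)
    deg <- igraph::degree(g)[match(c(pairs), igraph::V(g)$name)]
    deg <- matrix(deg, ncol = 2)
    geo <- rep(0, k)
    if (!is.null(cents)) {
      for (e in seq_len(k)) {
        a <- pairs[e, 1]; b <- pairs[e, 2]
        if (a %in% rownames(cents) && b %in% rownames(cents) &&
            !is.na(cents[a, "lat"]) && !is.na(cents[b, "lat"])) {
          geo[e] <- .gcKm(cents[b, "lon"], cents[b, "lat"], cents[a, ])
        }
      }
    }
    lab <- apply(pairs, 1, function(p) paste(sort(p), collapse = "|"))
    ## remove the edge between the lowest-frequency pair; then the least
    ## interior; then the geographically farthest; then smallest label
    o <- order(cnt[, 1] + cnt[, 2], deg[, 1] + deg[, 2], -geo, lab)[1]
    g <- igraph::delete_edges(
      g, igraph::get_edge_ids(g, pairs[o, ]))
  }
  methods::initialize(net, graph = g)
}
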