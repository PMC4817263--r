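#' Build the bipartite site-OTU sharing network
#'
#' One vertex per site and per OTU, with an edge (weight = strain count)
#' wherever an OTU occurs at a site. OTUs present in fewer than
#' `min_sites` sites are excluded.
#'
#' @param community [CommunityMatrix-class] of OTU strain counts per site.
#' @param sites [SiteTable-class] (supplies the glaciation flag).
#' @param min_sites Minimum number of occupied sites for an OTU to enter
#'   the network (default 2).
#' @return A [SharingGraph-class] (unclassified; see [classifyOtus()]).
#' @export
buildBipartite <- function(community, sites, min_sites = 2) {
  m <- communityCounts(community)
  sd_ <- siteData(sites)
  idx <- match(rownames(m), sd_$site_id)
  if (anyNA(idx))
    stop("community references unknown site: ",
         rownames(m)[is.na(idx)][1], call. = FALSE)
  keep <- colSums(m > 0) >= min_sites
  m <- m[, keep, drop = FALSE]
  glac <- sd_$glaciated[idx]
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(rownames(m), type = FALSE, glaciated = glac,
                     class = NA_character_, color = NA_character_) +
    igraph::vertices(colnames(m), type = TRUE, glaciated = NA,
                     class = "unclassified", color = "grey")
  nz <- which(m > 0, arr.ind = TRUE)
  if (nrow(nz)) {
    ends <- rbind(rownames(m)[nz[, 1]], colnames(m)[nz[, 2]])
    g <- igraph::add_edges(g, as.vector(ends), weight = m[nz])
  }
  frac <- if (any(glac)) colSums(m[glac, , drop = FALSE]) / colSums(m)
          else rep(0, ncol(m))
  tab <- data.frame(otu = colnames(m), n_strains = colSums(m),
                    n_sites = colSums(m > 0), frac_glacial = frac,
                    class = "unclassified", p_fisher = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  new("SharingGraph", graph = g, otuTable = tab, min_sites = min_sites)
}

#' Classify OTUs by glaciation history
#'
#' For every OTU in the sharing network, builds the 2x2 table of strain
#' counts (this OTU vs all other retained OTUs) x (glaciated vs
#' nonglaciated sites) and labels the OTU `"glacial"` (or
#' `"nonglacial"`) when more than `threshold` of its strains come from
#' that site class AND the two-sided Fisher exact test rejects random
#' assortment at `alpha`; otherwise `"unclassified"`.
#'
#' @param sharing A [SharingGraph-class] from [buildBipartite()].
#' @param community [CommunityMatrix-class] used to build it.
#' @param sites [SiteTable-class].
#' @param threshold Strain-fraction rule (default 0.90).
#' @param alpha Fisher significance level (default 0.05).
#' @return The [SharingGraph-class] with class labels and colors set
#'   (blue = glacial, red = nonglacial, grey = unclassified).
#' @export
classifyOtus <- function(sharing, community, sites, threshold = 0.90,
                         alpha = 0.05) {
  tab <- sharing@otuTable
  m <- communityCounts(community)[, tab$otu, drop = FALSE]
  sd_ <- siteData(sites)
  glac <- sd_$glaciated[match(rownames(m), sd_$site_id)]
  if (all(glac) || !any(glac))
    stop("both glaciated and nonglaciated sites are required", call. = FALSE)
  g_tot <- sum(m[glac, , drop = FALSE])
  n_tot <- sum(m[!glac, , drop = FALSE])
  for (i in seq_len(nrow(tab))) {
    gi <- sum(m[glac, tab$otu[i]])
    ni <- sum(m[!glac, tab$otu[i]])
    ft <- stats::fisher.test(matrix(c(gi, ni, g_tot - gi, n_tot - ni), 2))
    tab$p_fisher[i] <- ft$p.value
    frac_g <- gi / (gi + ni)
    tab$class[i] <-
      if (frac_g > threshold && ft$p.value < alpha) "glacial"
      else if ((1 - frac_g) > threshold && ft$p.value < alpha) "nonglacial"
      else "unclassified"
  }
  g <- sharing@graph
  cols <- c(glacial = "blue", nonglacial = "red", unclassified = "grey")
  g <- igraph::set_vertex_attr(g, "class", index = tab$otu,
                               value = tab$class)
  g <- igraph::set_vertex_attr(g, "color", index = tab$otu,
                               value = unname(cols[tab$class]))
  site_ids <- igraph::V(g)$name[!igraph::V(g)$type]
  site_glac <- igraph::vertex_attr(g, "glaciated", site_ids)
  g <- igraph::set_vertex_attr(g, "color", index = site_ids,
                               value = ifelse(site_glac, "blue", "red"))
  methods::initialize(sharing, graph = g, otuTable = tab)
}

#' Sharing-network summary statistics
#'
#' Counts of OTU sharing with respect to glaciation history: how many
#' retained (shared) OTUs touch glaciated sites, how many of those also
#' occur in at least one nonglaciated site, how many are common to a
#' designated focal site, and the per-site OTU degree ranking.
#'
#' @param sharing A [SharingGraph-class].
#' @param community [CommunityMatrix-class] used to build it.
#' @param sites [SiteTable-class].
#' @param focal_site Optional site id to count shared OTUs against.
#' @return List with `n_shared_otus`, `n_glacial_shared`,
#'   `n_glacial_shared_also_nonglacial`, `frac_glacial_shared_also_nonglacial`
#'   (NA when no glacial-shared OTUs), `n_common_to_focal`, and
#'   `site_degree` (named, decreasing).
#' @export
sharingSummary <- function(sharing, community, sites, focal_site = NULL) {
  tab <- sharing@otuTable
  m <- communityCounts(community)[, tab$otu, drop = FALSE] > 0
  sd_ <- siteData(sites)
  glac <- sd_$glaciated[match(rownames(m), sd_$site_id)]
  in_glac <- colSums(m[glac, , drop = FALSE]) > 0
  in_non <- colSums(m[!glac, , drop = FALSE]) > 0
  n_gs <- sum(in_glac)
  deg <- sort(colSums(t(m)), decreasing = TRUE) # OTUs per site
  list(
    n_shared_otus = nrow(tab),
    n_glacial_shared = n_gs,
    n_glacial_shared_also_nonglacial = sum(in_glac & in_non),
    frac_glacial_shared_also_nonglacial =
      if (n_gs == 0) NA_real_ else sum(in_glac & in_non) / n_gs,
    n_common_to_focal = if (is.null(focal_site)) NA_integer_
      else sum(m[focal_site, ] & colSums(m[rownames(m) != focal_site, ,
                                           drop = FALSE]) > 0),
    site_degree = deg)
}
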