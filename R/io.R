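#' Read an aligned FASTA file
#'
#' Reads a FASTA file of aligned DNA sequences and validates that all
#' records share one length and carry unique ids. Sequences are
#' upper-cased; record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] of uniform width.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">h1", "ACGT", ">h2", "ACGA"), f)
#' readFasta(f)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("no FASTA records in ", path, call. = FALSE)
  ids <- names(seqs)
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1], call. = FALSE)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) > 1) {
    bad <- ids[w != w[1]][1]
    stop(sprintf("alignment length mismatch: '%s' has length %d, expected %d",
                 bad, w[ids == bad], w[1]), call. = FALSE)
  }
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

#' Write sequences to FASTA
#'
#' @param seqs A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 20000L)
  invisible(path)
}

#' Read a rooted Newick tree
#'
#' Reads a single Newick tree, requiring branch lengths on every edge and
#' unique tip labels. The tree is treated as rooted as written; a
#' basal polytomy (root of degree > 2) is accepted with a warning.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
readNewick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1) stop("expected a single tree in ", path, call. = FALSE)
    tree <- tree[[1]]
  }
  if (is.null(tree)) stop("could not parse Newick in ", path, call. = FALSE)
  validateTree(tree)
}

#' @rdname readNewick
#' @param tree An [ape::phylo] object.
#' @export
validateTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label: ",
         tree$tip.label[duplicated(tree$tip.label)][1], call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge))
    stop("tree must have a branch length on every edge", call. = FALSE)
  root_children <- sum(tree$edge[, 1] == length(tree$tip.label) + 1L)
  if (root_children > 2)
    warning("root has degree ", root_children,
            "; tree accepted as rooted as written", call. = FALSE)
  tree
}

#' Drop an outgroup tip from a tree
#'
#' @param tree An [ape::phylo] tree.
#' @param outgroup Tip label to remove.
#' @return The pruned tree.
#' @export
pruneOutgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a tip of the tree", call. = FALSE)
  ape::drop.tip(tree, outgroup)
}

.readTsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  d
}

#' Read a site metadata table
#'
#' Tab-delimited with header; columns `site_id`, `latitude`, `longitude`,
#' `pH`, `som`, `temp`, `ppt`, `glaciated`, `time_rank`.
#'
#' @param path Path to a TSV file.
#' @return A [SiteTable-class] object.
#' @export
readSiteTable <- function(path) {
  d <- .readTsv(path, .SITE_COLS)
  for (v in c("latitude", "longitude", "pH", "som", "temp", "ppt")) {
    x <- suppressWarnings(as.numeric(d[[v]]))
    if (anyNA(x))
      stop(sprintf("non-numeric value in column '%s', row %d of %s",
                   v, which(is.na(x))[1], basename(path)), call. = FALSE)
    d[[v]] <- x
  }
  d$glaciated <- as.logical(d$glaciated)
  if (anyNA(d$glaciated))
    stop("column 'glaciated' must be TRUE/FALSE", call. = FALSE)
  siteTable(d)
}

#' Write a site table as TSV
#'
#' @param sites A [SiteTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSiteTable <- function(sites, path) {
  utils::write.table(siteData(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a strain-to-site mapping
#'
#' Tab-delimited with header; columns `strain_id`, `site_id`,
#' `haplotype_id`. When `sites` and/or `alignment` are supplied, every
#' `site_id` must exist in the site table and every `haplotype_id` in the
#' alignment.
#'
#' @param path Path to a TSV file.
#' @param sites Optional [SiteTable-class] for referential validation.
#' @param alignment Optional `DNAStringSet` for referential validation.
#' @return data.frame with columns `strain_id`, `site_id`, `haplotype_id`.
#' @export
readStrainMap <- function(path, sites = NULL, alignment = NULL) {
  d <- .readTsv(path, c("strain_id", "site_id", "haplotype_id"))
  d[] <- lapply(d, as.character)
  if (anyDuplicated(d$strain_id))
    stop("duplicate strain_id: ", d$strain_id[duplicated(d$strain_id)][1],
         call. = FALSE)
  if (!is.null(sites)) {
    bad <- setdiff(d$site_id, siteNames(sites))
    if (length(bad))
      stop("strain map references unknown site: ", bad[1], call. = FALSE)
  }
  if (!is.null(alignment)) {
    bad <- setdiff(d$haplotype_id, names(alignment))
    if (length(bad))
      stop("strain map references unknown haplotype: ", bad[1], call. = FALSE)
  }
  d
}

#' Write a strain map as TSV
#'
#' @param strains Strain map data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeStrainMap <- function(strains, path) {
  utils::write.table(strains, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a community matrix
#'
#' TSV with header: first column `site_id`, remaining columns one taxon
#' each, cells non-negative integer counts.
#'
#' @param path Path to a TSV file.
#' @return [readCommunity()] returns a [CommunityMatrix-class].
#' @export
readCommunity <- function(path) {
  d <- .readTsv(path, "site_id")
  ids <- as.character(d$site_id)
  m <- as.matrix(d[setdiff(names(d), "site_id")])
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != round(m)))
    stop("community counts must be non-negative integers", call. = FALSE)
  rownames(m) <- ids
  communityMatrix(m)
}

#' @rdname readCommunity
#' @param community A [CommunityMatrix-class].
#' @export
writeCommunity <- function(community, path) {
  m <- communityCounts(community)
  d <- data.frame(site_id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a graph to GraphML
#'
#' Writes an igraph object (or the graph inside a [HaploNetwork-class] /
#' [SharingGraph-class]) as GraphML readable by standard graph tools.
#' Vertex/edge attributes must be scalar (atomic); others raise an error.
#'
#' @param graph igraph, [HaploNetwork-class] or [SharingGraph-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
exportGraphML <- function(graph, path) {
  if (is(graph, "HaploNetwork") || is(graph, "SharingGraph"))
    graph <- haploGraph(graph)
  if (!igraph::is_igraph(graph)) stop("not a graph", call. = FALSE)
  for (a in igraph::vertex_attr_names(graph)) {
    v <- igraph::vertex_attr(graph, a)
    if (!is.atomic(v))
      stop("non-scalar vertex attribute: ", a, call. = FALSE)
    if (is.logical(v))
      graph <- igraph::set_vertex_attr(graph, a, value = as.character(v))
  }
  for (a in igraph::edge_attr_names(graph)) {
    v <- igraph::edge_attr(graph, a)
    if (!is.atomic(v))
      stop("non-scalar edge attribute: ", a, call. = FALSE)
    if (is.logical(v))
      graph <- igraph::set_edge_attr(graph, a, value = as.character(v))
  }
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file
#'
#' @param path Path to a GraphML file.
#' @return An igraph object.
#' @export
readGraphML <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  igraph::read_graph(path, format = "graphml")
}
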