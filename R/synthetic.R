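#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree with `n_tips` tips, branch lengths in time units.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Per-lineage birth rate.
#' @param seed Integer seed (or `NULL` to use the current RNG stream).
#' @return A rooted, binary, ultrametric [ape::phylo] tree with tip labels
#'   `h001`, `h002`, ...
#' @examples
#' tr <- simulateTree(8, 1, seed = 42)
#' @export
simulateTree <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot_scalar(n_tips, "n_tips")
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  tree <- withSeed(seed, ape::rphylo(as.integer(n_tips), birth = birth_rate,
                                     death = 0))
  tree$tip.label <- sprintf("h%03d", seq_len(n_tips))
  tree
}

#' Evolve aligned sequences along a tree
#'
#' Jukes-Cantor sequence evolution: one DNA sequence per tip, with the
#' expected number of substitutions per site on a branch equal to
#' `substitution_rate` times its length. Identical tip sequences are
#' possible (and, for short branches, likely) — this is what makes
#' multiple strains share a haplotype.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param seq_length Alignment length (bp).
#' @param substitution_rate Expected substitutions/site per unit branch
#'   length.
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet], one record per tip, uniform width.
#' @export
evolveSequences <- function(tree, seq_length = 377, substitution_rate = 0.004,
                            seed = NULL) {
  assertBranchLengths(tree)
  stopifnot_scalar(seq_length, "seq_length")
  if (substitution_rate == 0) {
    root <- withSeed(seed, paste(sample(c("A", "C", "G", "T"),
                                        seq_length, replace = TRUE),
                                 collapse = ""))
    seqs <- rep(root, length(tree$tip.label))
    names(seqs) <- tree$tip.label
    return(Biostrings::DNAStringSet(seqs))
  }
  sim <- withSeed(seed, phangorn::simSeq(tree, l = as.integer(seq_length),
                                         rate = substitution_rate))
  chars <- toupper(apply(as.character(sim), 1, paste, collapse = ""))
  Biostrings::DNAStringSet(chars[tree$tip.label])
}

## Draw per-site haplotype pools according to the scenario.
.sitePools <- function(tree, config, order_idx) {
  tips <- tree$tip.label
  n <- config@n_sites
  pools <- vector("list", n)
  if (config@scenario == "panmixia") {
    for (k in seq_len(n)) pools[[k]] <- tips
  } else if (config@scenario == "expansion") {
    ## order_idx walks sites from lowest to highest latitude; each derived
    ## site keeps a founder subset of its nearest lower-latitude
    ## neighbour. The founding propagule is kin-structured — a random seed
    ## haplotype plus its closest relatives in the source pool — so
    ## derived assemblages are phylogenetically clustered, not just
    ## poorer; the subset size is floored at two lineages so diversity
    ## statistics stay defined along deep founder chains.
    D <- ape::cophenetic.phylo(tree)
    pools[[order_idx[1]]] <- tips
    for (k in seq_len(n)[-1]) {
      src <- pools[[order_idx[k - 1]]]
      if (length(src) == 0)
        stop("founder subset empty at site rank ", k, call. = FALSE)
      size <- min(length(src),
                  max(2, ceiling(config@founder_fraction * length(src))))
      if (length(src) == 1) {
        pools[[order_idx[k]]] <- src
      } else {
        seed_hap <- sample(src, 1)
        ord <- order(D[seed_hap, src], src) # patristic, label tie-break
        pools[[order_idx[k]]] <- src[ord][seq_len(size)]
      }
    }
  } else { # clustered: each site draws from one random subtree
    n_tip <- length(tips)
    internal <- n_tip + seq_len(tree$Nnode)
    desc <- lapply(internal, function(nd) {
      tips[phangorn::Descendants(tree, nd, "tips")[[1]]]
    })
    keep <- which(vapply(desc, length, 1L) >= 2)
    for (k in seq_len(n)) pools[[k]] <- desc[[sample(keep, 1)]]
  }
  pools
}

#' Assign strains to sites under a scenario
#'
#' Generates a site table, a strain-to-site mapping and the per-site
#' haplotype pools for one of three scenarios. Under `"panmixia"` every
#' strain is drawn from the full haplotype pool regardless of site; under
#' `"expansion"` sites are ordered by latitude, the lowest-latitude site
#' draws from the full pool and each higher-latitude site from a founder
#' subset (`founder_fraction` of its source's pool, floored at two
#' lineages) of the nearest lower-latitude site, recursively; founder
#' subsets are kin-structured (a random seed haplotype and its nearest
#' patristic relatives), emulating colonization by related lineages, so
#' derived sites show lower phylogenetic diversity and positive
#' clustering. Under `"clustered"` each site draws from the tips of one
#' randomly chosen subtree. Environmental columns are
#' uncorrelated noise, so latitude is the only simulated driver.
#'
#' @param tree Haplotype tree from [simulateTree()].
#' @param config A [ScenarioConfig-class].
#' @return List with `sites` ([SiteTable-class]), `strains` (data.frame),
#'   `community` (haplotype-level [CommunityMatrix-class]) and `pools`
#'   (per-site haplotype pools).
#' @export
assignSites <- function(tree, config) {
  validObject(config)
  withSeed(childSeed(config@seed, "assign"), {
    n <- config@n_sites
    lat <- config@latitudes
    site_id <- sprintf("S%02d", seq_len(n))
    order_idx <- order(lat) # ascending latitude = colonization order
    pools <- .sitePools(tree, config, order_idx)
    strain_site <- rep(site_id, each = config@strains_per_site)
    hap <- unlist(lapply(seq_len(n), function(k) {
      sample(pools[[k]], config@strains_per_site, replace = TRUE)
    }))
    strains <- data.frame(
      strain_id = sprintf("%s_str%03d", strain_site,
                          rep(seq_len(config@strains_per_site), times = n)),
      site_id = strain_site, haplotype_id = hap,
      stringsAsFactors = FALSE)
    time_rank <- integer(n)
    if (config@scenario == "expansion") {
      time_rank[order_idx] <- seq_len(n)
    } else {
      time_rank <- sample(n)
    }
    sites <- siteTable(data.frame(
      site_id = site_id, latitude = lat,
      longitude = runif(n, -123, -68),
      pH = rnorm(n, 6, 0.5),
      som = pmax(0.5, rnorm(n, 5, 2)),
      temp = rnorm(n, 10, 4),
      ppt = pmax(100, rnorm(n, 800, 200)),
      glaciated = lat > config@glaciation_cutoff_latitude,
      time_rank = time_rank, stringsAsFactors = FALSE))
    community <- communityFromStrains(strains, taxa = tree$tip.label)
    list(sites = sites, strains = strains, community = community,
         pools = pools)
  })
}

#' Build a community matrix from a strain map
#'
#' @param strains Strain map data.frame (`strain_id`, `site_id`, and a
#'   taxon column).
#' @param taxa Optional full taxon set for the columns (defaults to taxa
#'   observed in the map).
#' @param taxon_col Column holding the taxon of each strain.
#' @return A [CommunityMatrix-class] of strain counts.
#' @export
communityFromStrains <- function(strains, taxa = NULL,
                                 taxon_col = "haplotype_id") {
  if (!taxon_col %in% names(strains))
    stop("strain map lacks column '", taxon_col, "'", call. = FALSE)
  sites <- sort(unique(strains$site_id))
  if (is.null(taxa)) taxa <- sort(unique(strains[[taxon_col]]))
  m <- table(factor(strains$site_id, levels = sites),
             factor(strains[[taxon_col]], levels = taxa))
  communityMatrix(unclass(as.matrix(m)))
}

#' Generate a complete synthetic dataset on disk
#'
#' Simulates tree, alignment, site table and strain map under a
#' [ScenarioConfig-class], writes them in the package's external formats
#' (FASTA, Newick, TSV) plus a ground-truth JSON, and returns the in-memory
#' objects. Identical configs produce identical files.
#'
#' @param config A [ScenarioConfig-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file `paths`.
#' @examples
#' cfg <- scenarioConfig(n_haplotypes = 16, n_sites = 3,
#'                       strains_per_site = 10, seed = 7)
#' out <- generateDataset(cfg, tempfile())
#' @export
generateDataset <- function(config, dir) {
  validObject(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tree <- simulateTree(config@n_haplotypes, config@birth_rate,
                       seed = childSeed(config@seed, "tree"))
  ## emit the tree in substitutions/site (the units of an estimated gene
  ## tree, and of the patristic OTU threshold); the Yule clock makes the
  ## scaled tree ultrametric too
  tree$edge.length <- tree$edge.length * config@substitution_rate
  alignment <- evolveSequences(tree, config@seq_length, 1,
                               seed = childSeed(config@seed, "seq"))
  asg <- assignSites(tree, config)
  paths <- list(fasta = file.path(dir, "haplotypes.fasta"),
                tree = file.path(dir, "tree.nwk"),
                sites = file.path(dir, "sites.tsv"),
                strains = file.path(dir, "strains.tsv"),
                truth = file.path(dir, "ground_truth.json"))
  writeFasta(alignment, paths$fasta)
  ape::write.tree(tree, paths$tree)
  writeSiteTable(asg$sites, paths$sites)
  writeStrainMap(asg$strains, paths$strains)
  truth <- list(
    scenario = config@scenario, seed = config@seed,
    n_haplotypes = config@n_haplotypes, seq_length = config@seq_length,
    birth_rate = config@birth_rate,
    substitution_rate = config@substitution_rate,
    founder_fraction = config@founder_fraction,
    glaciation_cutoff_latitude = config@glaciation_cutoff_latitude,
    site_order_by_latitude = siteNames(asg$sites)[order(config@latitudes)],
    founder_pools = lapply(stats::setNames(asg$pools, siteNames(asg$sites)),
                           sort))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(tree = tree, alignment = alignment, sites = asg$sites,
                 strains = asg$strains, community = asg$community,
                 pools = asg$pools, paths = paths))
}
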