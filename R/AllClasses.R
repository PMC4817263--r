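#' @import methods
NULL

setOldClass("phylo")
setOldClass("igraph")

## ---------------------------------------------------------------------------
## CommunityMatrix: sites x taxa non-negative integer counts
## ---------------------------------------------------------------------------

#' Site-by-taxon count matrix
#'
#' Holds strain counts per site (rows) and taxon (columns, haplotypes or
#' OTUs). Counts are non-negative integers; "weighted" vs "unweighted"
#' analyses are derived views ([communityView()]), never stored separately.
#'
#' @slot counts Integer matrix, sites in rows, taxa in columns, with unique
#'   dimnames.
#' @export
setClass("CommunityMatrix", representation(counts = "matrix"))

setValidity("CommunityMatrix", function(object) {
  m <- object@counts
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("counts must have site rownames and taxon colnames")
  if (anyDuplicated(rownames(m))) return("duplicate site ids")
  if (anyDuplicated(colnames(m))) return("duplicate taxon ids")
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    return("counts must be non-negative integers")
  TRUE
})

#' Construct a CommunityMatrix
#'
#' @param counts Numeric matrix of non-negative integer counts with site
#'   rownames and taxon colnames.
#' @return A [CommunityMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 0, 2, 0, 4, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
#' communityMatrix(m)
#' @export
communityMatrix <- function(counts) {
  storage.mode(counts) <- "double"
  new("CommunityMatrix", counts = counts)
}

setMethod("show", "CommunityMatrix", function(object) {
  cat(sprintf("CommunityMatrix: %d sites x %d taxa, %d individuals\n",
              nrow(object@counts), ncol(object@counts), sum(object@counts)))
})

## ---------------------------------------------------------------------------
## SiteTable: per-site coordinates, environment, history
## ---------------------------------------------------------------------------

#' Per-site metadata table
#'
#' Coordinates, environmental measurements, glaciation history and
#' colonization-time rank for every sampling site. `time_rank` 1 marks the
#' site with the longest time available for colonization.
#'
#' @slot data data.frame with columns `site_id`, `latitude`, `longitude`,
#'   `pH`, `som`, `temp`, `ppt`, `glaciated`, `time_rank`.
#' @export
setClass("SiteTable", representation(data = "data.frame"))

.SITE_COLS <- c("site_id", "latitude", "longitude", "pH", "som", "temp",
                "ppt", "glaciated", "time_rank")

setValidity("SiteTable", function(object) {
  d <- object@data
  missing <- setdiff(.SITE_COLS, names(d))
  if (length(missing))
    return(paste("missing column(s):", paste(missing, collapse = ", ")))
  if (anyDuplicated(d$site_id))
    return(paste("duplicate site_id:", d$site_id[duplicated(d$site_id)][1]))
  num <- c("latitude", "longitude", "pH", "som", "temp", "ppt")
  for (v in num) {
    if (!is.numeric(d[[v]]) || anyNA(d[[v]]))
      return(sprintf("column '%s' must be numeric and complete", v))
  }
  if (any(d$latitude < -90 | d$latitude > 90))
    return(sprintf("latitude out of [-90, 90] for site %s",
                   d$site_id[which(d$latitude < -90 | d$latitude > 90)[1]]))
  if (any(d$longitude < -180 | d$longitude > 180))
    return(sprintf("longitude out of [-180, 180] for site %s",
                   d$site_id[which(d$longitude < -180 | d$longitude > 180)[1]]))
  if (!is.logical(d$glaciated)) return("'glaciated' must be logical")
  if (anyNA(d$time_rank) || any(d$time_rank < 1) ||
      any(d$time_rank != round(d$time_rank)))
    return("'time_rank' must be positive integers")
  if (anyDuplicated(d$time_rank)) return("'time_rank' values must be unique")
  TRUE
})

#' Construct a SiteTable
#'
#' @param data data.frame with the required site columns (see
#'   [SiteTable-class]).
#' @return A [SiteTable-class] object.
#' @export
siteTable <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$site_id <- as.character(data$site_id)
  if (!is.null(data$glaciated) && !is.logical(data$glaciated))
    data$glaciated <- as.logical(data$glaciated)
  rownames(data) <- NULL
  new("SiteTable", data = data)
}

setMethod("show", "SiteTable", function(object) {
  d <- object@data
  cat(sprintf("SiteTable: %d sites (%d glaciated), latitude %.1f..%.1f\n",
              nrow(d), sum(d$glaciated), min(d$latitude), max(d$latitude)))
})

## ---------------------------------------------------------------------------
## DistanceMatrix: labelled symmetric distances with a kind tag
## ---------------------------------------------------------------------------

#' Labelled symmetric distance matrix
#'
#' @slot values Symmetric non-negative numeric matrix with zero diagonal and
#'   identical row/column labels.
#' @slot kind One of `"geographic_km"`, `"environmental"`, `"unifrac"`,
#'   `"braycurtis"`, `"patristic"`, `"other"`.
#' @export
setClass("DistanceMatrix",
         representation(values = "matrix", kind = "character"))

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("values must carry identical row and column labels")
  if (any(is.na(v))) return("distances must be complete")
  if (max(abs(v - t(v))) > 1e-8) return("matrix must be symmetric")
  if (any(diag(v) != 0)) return("diagonal must be zero")
  if (any(v < 0)) return("distances must be non-negative")
  if (length(object@kind) != 1L) return("kind must be a single string")
  TRUE
})

#' Construct a DistanceMatrix
#'
#' @param values Symmetric matrix with labels.
#' @param kind Distance kind tag.
#' @return A [DistanceMatrix-class] object.
#' @export
distanceMatrix <- function(values, kind = "other") {
  values <- as.matrix(values)
  values <- (values + t(values)) / 2 # remove floating-point asymmetry
  diag(values) <- 0
  new("DistanceMatrix", values = values, kind = kind)
}

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix (%s): %d labels, range %.4g..%.4g\n",
              object@kind, nrow(object@values),
              min(object@values[upper.tri(object@values)]),
              max(object@values[upper.tri(object@values)])))
})

#' @export
as.matrix.DistanceMatrix <- function(x, ...) x@values

#' @export
as.dist.DistanceMatrix <- function(m, diag = FALSE, upper = FALSE)
  stats::as.dist(m@values, diag = diag, upper = upper)

## ---------------------------------------------------------------------------
## TestResult: permutation test output
## ---------------------------------------------------------------------------

#' Permutation test result
#'
#' @slot statistic Name of the statistic (e.g. `"mantel_r"`, `"pseudo_F"`).
#' @slot value Observed statistic.
#' @slot r_squared Proportion of variation explained (squared Mantel r, or
#'   PERMANOVA `SS_model/SS_total`). Lies in `[0, 1]` for metric
#'   distances; semimetric dissimilarities (Bray-Curtis, UniFrac) can
#'   produce negative partial sums of squares and push it slightly
#'   outside that range.
#' @slot p_value Smoothed permutation p-value, `(1 + b)/(1 + n_perm)`.
#' @slot n_perm Number of permutations.
#' @slot seed Seed used (NA if none).
#' @export
setClass("TestResult",
         representation(statistic = "character", value = "numeric",
                        r_squared = "numeric", p_value = "numeric",
                        n_perm = "numeric", seed = "numeric"))

setValidity("TestResult", function(object) {
  if (!is.na(object@p_value) &&
      (object@p_value <= 0 || object@p_value > 1))
    return("p_value must lie in (0, 1]")
  if (!is.na(object@r_squared) && !is.finite(object@r_squared))
    return("r_squared must be finite")
  TRUE
})

testResult <- function(statistic, value, r_squared, p_value, n_perm, seed) {
  new("TestResult", statistic = statistic, value = value,
      r_squared = r_squared, p_value = p_value, n_perm = n_perm,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s = %.4f, R2 = %.3f, p = %.4g (%d permutations)\n",
              object@statistic, object@value, object@r_squared,
              object@p_value, as.integer(object@n_perm)))
})

## ---------------------------------------------------------------------------
## ScenarioConfig: synthetic-data generator configuration
## ---------------------------------------------------------------------------

#' Synthetic-scenario configuration
#'
#' Defines the conditions under which [generateDataset()] simulates a
#' haplotype collection. Defaults emulate the shape of a continental strain
#' survey: 208 haplotypes of a 377-bp locus, 12 sites spanning 28-65 degrees
#' latitude, 77 strains per site, glaciation above 40 degrees N, and a
#' founder-style range expansion from the lowest-latitude site.
#'
#' @slot n_haplotypes Number of haplotypes (tree tips).
#' @slot seq_length Alignment length in bp.
#' @slot birth_rate Per-lineage birth rate of the Yule tree.
#' @slot substitution_rate Expected substitutions per site per unit branch
#'   length (Jukes-Cantor).
#' @slot n_sites Number of sampling sites.
#' @slot latitudes Site latitudes (decimal degrees), length `n_sites`.
#' @slot scenario `"panmixia"`, `"expansion"` or `"clustered"`.
#' @slot founder_fraction Fraction of the source pool colonizing each
#'   derived site under `"expansion"` (in (0, 1]).
#' @slot strains_per_site Strains sampled per site.
#' @slot glaciation_cutoff_latitude Sites above this latitude are flagged
#'   glaciated.
#' @slot seed Integer seed; identical configs yield identical outputs.
#' @export
setClass("ScenarioConfig",
         representation(n_haplotypes = "numeric", seq_length = "numeric",
                        birth_rate = "numeric", substitution_rate = "numeric",
                        n_sites = "numeric", latitudes = "numeric",
                        scenario = "character", founder_fraction = "numeric",
                        strains_per_site = "numeric",
                        glaciation_cutoff_latitude = "numeric",
                        seed = "numeric"))

setValidity("ScenarioConfig", function(object) {
  if (object@n_haplotypes < 2) return("n_haplotypes must be >= 2")
  if (object@seq_length < 1) return("seq_length must be positive")
  if (object@birth_rate <= 0) return("birth_rate must be positive")
  if (object@substitution_rate < 0) return("substitution_rate must be >= 0")
  if (object@n_sites < 2) return("n_sites must be >= 2")
  if (length(object@latitudes) != object@n_sites)
    return("latitudes must have length n_sites")
  if (any(object@latitudes < -90 | object@latitudes > 90))
    return("latitudes must lie in [-90, 90]")
  if (!object@scenario %in% c("panmixia", "expansion", "clustered"))
    return("scenario must be panmixia, expansion or clustered")
  if (object@founder_fraction <= 0 || object@founder_fraction > 1)
    return("founder_fraction must lie in (0, 1]")
  if (object@strains_per_site < 1) return("strains_per_site must be >= 1")
  TRUE
})

#' Construct a ScenarioConfig
#'
#' @param n_haplotypes,seq_length,birth_rate,substitution_rate,n_sites
#'   See [ScenarioConfig-class].
#' @param latitudes,scenario,founder_fraction,strains_per_site See
#'   [ScenarioConfig-class].
#' @param glaciation_cutoff_latitude,seed See [ScenarioConfig-class].
#' @return A [ScenarioConfig-class] object.
#' @examples
#' cfg <- scenarioConfig(n_haplotypes = 32, n_sites = 4,
#'                       strains_per_site = 20, seed = 1)
#' @export
scenarioConfig <- function(n_haplotypes = 208, seq_length = 377,
                           birth_rate = 1, substitution_rate = 0.008,
                           n_sites = 12,
                           latitudes = seq(28, 65, length.out = n_sites),
                           scenario = c("expansion", "panmixia", "clustered"),
                           founder_fraction = 0.75, strains_per_site = 77,
                           glaciation_cutoff_latitude = 40, seed = 1) {
  new("ScenarioConfig", n_haplotypes = n_haplotypes, seq_length = seq_length,
      birth_rate = birth_rate, substitution_rate = substitution_rate,
      n_sites = n_sites, latitudes = latitudes,
      scenario = match.arg(scenario), founder_fraction = founder_fraction,
      strains_per_site = strains_per_site,
      glaciation_cutoff_latitude = glaciation_cutoff_latitude,
      seed = seed)
}

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf(
    "ScenarioConfig: %s, %d haplotypes x %d bp, %d sites, %d strains/site, seed %d\n",
    object@scenario, object@n_haplotypes, object@seq_length, object@n_sites,
    object@strains_per_site, as.integer(object@seed)))
})

## ---------------------------------------------------------------------------
## HaploNetwork: statistical parsimony graph
## ---------------------------------------------------------------------------

#' Statistical-parsimony haplotype network
#'
#' Undirected graph whose vertices are observed haplotypes plus inferred
#' unsampled intermediates, and whose edges each span exactly one mutational
#' step. Components are joined only when the mutational path between them is
#' within the parsimony connection limit.
#'
#' @slot graph igraph object; vertex attributes `name`, `observed`, `count`.
#' @slot haplotypes data.frame with `haplotype_id`, `count` for observed
#'   haplotypes.
#' @slot siteCounts Matrix of per-site strain counts (haplotypes x sites),
#'   possibly 0-column when no mapping was supplied.
#' @slot limit Connection limit (mutational steps).
#' @export
setClass("HaploNetwork",
         representation(graph = "igraph", haplotypes = "data.frame",
                        siteCounts = "matrix", limit = "numeric"))

setValidity("HaploNetwork", function(object) {
  g <- object@graph
  if (igraph::vcount(g) > 0 &&
      is.null(igraph::vertex_attr(g, "observed")))
    return("graph vertices must carry an 'observed' attribute")
  TRUE
})

setMethod("show", "HaploNetwork", function(object) {
  g <- object@graph
  obs <- sum(igraph::V(g)$observed)
  cat(sprintf(
    "HaploNetwork: %d haplotypes + %d inferred intermediates, %d edges, %d component(s), limit %d\n",
    obs, igraph::vcount(g) - obs, igraph::ecount(g),
    igraph::components(g)$no, as.integer(object@limit)))
})

## ---------------------------------------------------------------------------
## NestedDesign: hierarchical clade nesting of a haplotype network
## ---------------------------------------------------------------------------

#' Nested clade design
#'
#' Hierarchical nesting of a loop-free haplotype network: level 0 is the
#' haplotypes (and inferred intermediates), level k clades union level-(k-1)
#' clades lying one mutational step apart, until each network component is a
#' single clade.
#'
#' @slot membership data.frame with `node`, `component`, and one
#'   `level_<k>` column of clade ids per nesting level.
#' @slot clades data.frame with `level`, `clade`, `parent`, `component`,
#'   `is_tip` (degree <= 1 in the clade graph of its level), `n_nodes`.
#' @slot n_levels Number of nesting levels.
#' @export
setClass("NestedDesign",
         representation(membership = "data.frame", clades = "data.frame",
                        n_levels = "numeric"))

setValidity("NestedDesign", function(object) {
  m <- object@membership
  if (!all(c("node", "component") %in% names(m)))
    return("membership needs 'node' and 'component' columns")
  lv <- grep("^level_", names(m)) # includes level_0
  if (length(lv) != object@n_levels + 1)
    return("level columns must match n_levels")
  for (k in lv) if (anyNA(m[[k]])) return("every node needs a clade per level")
  TRUE
})

setMethod("show", "NestedDesign", function(object) {
  cat(sprintf("NestedDesign: %d nodes, %d levels, %d clades\n",
              nrow(object@membership), as.integer(object@n_levels),
              nrow(object@clades)))
})

## ---------------------------------------------------------------------------
## SharingGraph: bipartite site-OTU network
## ---------------------------------------------------------------------------

#' Bipartite site-OTU sharing network
#'
#' Sites and OTUs as the two vertex classes; an edge (weight = strain
#' count) joins a site to every OTU observed there. OTUs found in fewer
#' than `min_sites` sites are excluded at construction.
#'
#' @slot graph Bipartite igraph; vertex attributes `name`, `type` (TRUE for
#'   OTU vertices), `glaciated` (sites), `class`/`color` (OTUs).
#' @slot otuTable data.frame with per-OTU totals, glacial strain fraction
#'   and classification.
#' @slot min_sites Minimum number of sites for an OTU to be retained.
#' @export
setClass("SharingGraph",
         representation(graph = "igraph", otuTable = "data.frame",
                        min_sites = "numeric"))

setMethod("show", "SharingGraph", function(object) {
  tab <- table(factor(object@otuTable$class,
                      levels = c("glacial", "nonglacial", "unclassified")))
  cat(sprintf(
    "SharingGraph: %d sites, %d OTUs (%d glacial, %d nonglacial, %d unclassified)\n",
    sum(!igraph::V(object@graph)$type), nrow(object@otuTable),
    tab["glacial"], tab["nonglacial"], tab["unclassified"]))
})
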