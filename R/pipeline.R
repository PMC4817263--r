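#' Assemble a run configuration
#'
#' Collects every knob of an end-to-end run, materializing all defaults so
#' the manifest records exactly what was used. Supply either `input`
#' (paths to FASTA alignment, Newick tree, site TSV, strain-map TSV) or
#' `scenario` (a [ScenarioConfig-class]) to generate synthetic inputs.
#'
#' @param input List with `fasta`, `tree`, `sites`, `strains` paths, or
#'   `NULL` when `scenario` is given.
#' @param scenario Optional [ScenarioConfig-class].
#' @param otu_threshold,otu_method OTU definition (patristic threshold and
#'   clustering rule, see [clusterOtus()]).
#' @param n_perm Named list of permutation counts: `alpha` (NRI/NTI),
#'   `mantel`, `permanova`, `unifrac`, `nca`.
#' @param seed Master seed; all stage seeds derive from it.
#' @param confidence Parsimony connection-limit confidence.
#' @param exclude_sites Sites to drop before analysis (e.g. re-runs
#'   without the highest-latitude sites).
#' @param aggregate Optional named character vector mapping sub-site ids
#'   in the strain map to aggregated site ids present in the site table.
#' @param focal_site Optional site id for the sharing summary.
#' @param outgroup Optional outgroup tip to prune from the tree.
#' @return A list of class `phylogeodivConfig`.
#' @export
runConfig <- function(input = NULL, scenario = NULL, otu_threshold = 0.01,
                      otu_method = "node_depth",
                      n_perm = list(), seed = 1, confidence = 0.95,
                      exclude_sites = character(), aggregate = NULL,
                      focal_site = NULL, outgroup = NULL) {
  if (is.null(input) && is.null(scenario))
    stop("supply 'input' paths or a 'scenario'", call. = FALSE)
  np <- utils::modifyList(list(alpha = 999, mantel = 1000, permanova = 999,
                               unifrac = 99, nca = 1000), n_perm)
  structure(list(input = input, scenario = scenario,
                 otu_threshold = otu_threshold, otu_method = otu_method,
                 n_perm = np, seed = seed, confidence = confidence,
                 exclude_sites = exclude_sites, aggregate = aggregate,
                 focal_site = focal_site, outgroup = outgroup),
            class = "phylogeodivConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [runConfig()]
#'   (a `scenario` block is passed to [scenarioConfig()]).
#' @return A `phylogeodivConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scenario)) y$scenario <- do.call(scenarioConfig, y$scenario)
  do.call(runConfig, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

.loadInputs <- function(config, out_dir) {
  if (!is.null(config$scenario)) {
    syn <- generateDataset(config$scenario, file.path(out_dir, "synthetic"))
    return(list(alignment = syn$alignment, tree = syn$tree,
                sites = syn$sites, strains = syn$strains))
  }
  alignment <- readFasta(config$input$fasta)
  tree <- readNewick(config$input$tree)
  if (!is.null(config$outgroup)) tree <- pruneOutgroup(tree, config$outgroup)
  sites <- readSiteTable(config$input$sites)
  strains <- readStrainMap(config$input$strains, sites = sites,
                           alignment = alignment)
  list(alignment = alignment, tree = tree, sites = sites, strains = strains)
}

## distinct-haplotype counts per OTU per site (the "unweighted"
## sequence-inclusion view: duplicate sequences within an OTU collapse)
.otuUniqueHaploCommunity <- function(strains, assignment, mapping) {
  rep_of <- mapping[strains$haplotype_id]
  otu_of <- stats::setNames(assignment$otu_id, assignment$haplotype_id)
  d <- unique(data.frame(site_id = strains$site_id, hap = unname(rep_of),
                         stringsAsFactors = FALSE))
  d$otu <- unname(otu_of[d$hap])
  communityMatrix(unclass(table(d$site_id, d$otu)))
}

#' Run the full phylogeographic-diversity pipeline
#'
#' Executes every stage on the configured inputs and writes all
#' table-shaped outputs plus a manifest into `out_dir`: OTU assignment,
#' per-site alpha diversity, distance matrices, Mantel/PERMANOVA results,
#' the diversity-environment correlation matrix, the classified sharing
#' network with summary, haplotype networks with nested-clade statistics
#' and inferences, rarefaction and coverage. All randomness derives from
#' `config$seed`; re-running with a different seed changes permutation
#' p-values but no observed statistic.
#'
#' @param config A `phylogeodivConfig` from [runConfig()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every intermediate and result object.
#' @export
runAll <- function(config, out_dir) {
  stopifnot(inherits(config, "phylogeodivConfig"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed
  inp <- .stage("load", .loadInputs(config, out_dir))
  alignment <- inp$alignment; tree <- inp$tree
  sites <- inp$sites; strains <- inp$strains

  if (!is.null(config$aggregate)) {
    hit <- strains$site_id %in% names(config$aggregate)
    strains$site_id[hit] <- unname(config$aggregate[strains$site_id[hit]])
  }
  if (length(config$exclude_sites)) {
    unknown <- setdiff(config$exclude_sites, siteNames(sites))
    if (length(unknown))
      warning("exclusion of never-sampled site(s) is a no-op: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    keep <- !siteNames(sites) %in% config$exclude_sites
    sites <- siteTable(siteData(sites)[keep, , drop = FALSE])
    strains <- strains[strains$site_id %in% siteNames(sites), , drop = FALSE]
  }
  message(sprintf("stage load: %d sequences, %d strains, %d sites",
                  length(alignment), nrow(strains), nrow(siteData(sites))))

  ## --- haplotypes and OTUs -------------------------------------------------
  haplo <- .stage("haplotypes", haplotypeTable(alignment, strains))
  mapping <- attr(haplo, "mapping")
  assignment <- .stage("otu_cluster",
                       clusterOtus(tree, config$otu_threshold,
                                   config$otu_method))
  writeCommunity(communityFromStrains(strains), file.path(out_dir,
                                                          "community_haplotype.tsv"))
  utils::write.table(assignment, file.path(out_dir, "otu_assignment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  otu_of <- stats::setNames(assignment$otu_id, assignment$haplotype_id)
  strains$otu_id <- unname(otu_of[unname(mapping[strains$haplotype_id])])
  otu_comm <- communityFromStrains(strains, taxon_col = "otu_id")
  otu_comm_uniq <- .otuUniqueHaploCommunity(strains, assignment, mapping)
  hap_comm <- communityFromStrains(strains,
                                   taxa = sort(unique(unname(
                                     mapping[strains$haplotype_id]))))
  writeCommunity(otu_comm, file.path(out_dir, "community_otu.tsv"))
  message(sprintf("stage otu_cluster: %d haplotypes -> %d OTUs",
                  nrow(haplo), length(unique(assignment$otu_id))))

  ## --- alpha diversity -----------------------------------------------------
  otu_tree <- otuRepresentativeTree(tree, assignment)
  alpha <- .stage("alpha", siteDiversity(otu_tree, otu_comm,
                                         n_perm = config$n_perm$alpha,
                                         seed = childSeed(seed, "alpha")))
  sd_ <- siteData(sites)
  alpha <- cbind(alpha, sd_[match(alpha$site_id, sd_$site_id),
                            c("latitude", "longitude", "temp", "som",
                              "ppt", "pH", "glaciated", "time_rank")])
  utils::write.table(alpha, file.path(out_dir, "site_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  contrasts <- lapply(c(pd = "pd", nri = "nri", mrd = "mrd"), function(v) {
    gc_ <- groupContrast(alpha[[v]], alpha$glaciated)
    list(mean_nonglaciated = unname(gc_$mean["FALSE"]),
         sd_nonglaciated = unname(gc_$sd["FALSE"]),
         mean_glaciated = unname(gc_$mean["TRUE"]),
         sd_glaciated = unname(gc_$sd["TRUE"]),
         p_welch = gc_$p_welch, p_mannwhitney = gc_$p_mannwhitney)
  })
  time_cor <- lapply(c(pd = "pd", nri = "nri", mrd = "mrd"), function(v) {
    rc <- rankCorrelation(alpha[[v]], alpha$time_rank)
    list(rho = rc$rho, p = rc$p)
  })
  jsonlite::write_json(list(glaciation_contrasts = contrasts,
                            time_rank_spearman = time_cor),
                       file.path(out_dir, "alpha_contrasts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## --- beta diversity and distance decay ----------------------------------
  beta <- .stage("beta", {
    geo <- haversineMatrix(sites)
    env <- envDistance(sites)
    uf_u <- unifracMatrix(tree, communityView(hap_comm, "unweighted"))
    uf_w <- unifracMatrix(tree, hap_comm, "abundance_weighted")
    bc_w <- brayCurtisMatrix(otu_comm)
    bc_u <- brayCurtisMatrix(otu_comm_uniq)
    list(geo = geo, env = env, unifrac_unweighted = uf_u,
         unifrac_weighted = uf_w, bray_weighted = bc_w,
         bray_unweighted = bc_u)
  })
  for (nm in names(beta)) {
    utils::write.table(as.matrix(beta[[nm]]),
                       file.path(out_dir, paste0("distance_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  tests <- .stage("distance_decay", {
    out <- list()
    for (nm in c("unifrac_unweighted", "unifrac_weighted",
                 "bray_weighted", "bray_unweighted")) {
      mt <- mantelTest(beta[[nm]], beta$geo, n_perm = config$n_perm$mantel,
                       seed = childSeed(seed, paste0("mantel_", nm)))
      out[[paste0("mantel_", nm, "_vs_geo")]] <-
        list(statistic = mt@statistic, r = mt@value, r_squared = mt@r_squared,
             p = mt@p_value, n_perm = mt@n_perm, seed = mt@seed)
    }
    mt <- mantelTest(beta$bray_weighted, beta$env,
                     n_perm = config$n_perm$mantel,
                     seed = childSeed(seed, "mantel_env"))
    out$mantel_bray_weighted_vs_env <-
      list(statistic = mt@statistic, r = mt@value, r_squared = mt@r_squared,
           p = mt@p_value, n_perm = mt@n_perm, seed = mt@seed)
    vars <- c("latitude", "pH", "temp", "som", "ppt")
    for (dm in c("unifrac_weighted", "unifrac_unweighted",
                 "bray_weighted", "bray_unweighted")) {
      for (v in vars) {
        pt <- permanovaTest(beta[[dm]],
                            sd_[[v]][match(rownames(as.matrix(beta[[dm]])),
                                           sd_$site_id)],
                            n_perm = config$n_perm$permanova,
                            seed = childSeed(seed, paste0("adonis_", dm, v)))
        out[[paste0("permanova_", dm, "_", v)]] <-
          list(statistic = pt@statistic, F = pt@value,
               r_squared = pt@r_squared, p = pt@p_value,
               n_perm = pt@n_perm, seed = pt@seed)
      }
    }
    out
  })
  jsonlite::write_json(tests, file.path(out_dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## --- correlation matrix (diversity x environment) ------------------------
  ct <- correlationTable(alpha[c("pd", "nri", "mrd", "latitude", "longitude",
                                 "temp", "som", "ppt", "pH")])
  utils::write.table(round(ct$r, 3),
                     file.path(out_dir, "correlation_r.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(signif(ct$p, 3),
                     file.path(out_dir, "correlation_p.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)

  ## --- OTU sharing network -------------------------------------------------
  share <- .stage("sharing_network", {
    sg <- buildBipartite(otu_comm, sites)
    sg <- classifyOtus(sg, otu_comm, sites)
    focal <- config$focal_site
    if (is.null(focal)) {
      dg <- sharingSummary(sg, otu_comm, sites)$site_degree
      focal <- names(dg)[1]
    }
    list(graph = sg, summary = sharingSummary(sg, otu_comm, sites, focal),
         focal = focal)
  })
  exportGraphML(share$graph, file.path(out_dir, "sharing_network.graphml"))
  jsonlite::write_json(share$summary,
                       file.path(out_dir, "sharing_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## --- haplotype networks and nested clade analysis ------------------------
  nca <- .stage("nca", {
    limit <- parsimonyLimit(unique(Biostrings::width(alignment)),
                            config$confidence)
    net <- buildNetwork(haplo, limit)
    net <- resolveLoops(net, sites)
    design <- nestClades(net)
    perm <- ncaPermutation(design, strains, sites, mapping = mapping,
                           n_perm = config$n_perm$nca,
                           seed = childSeed(seed, "nca"))
    list(limit = limit, network = net, design = design, perm = perm,
         inference = interpretNca(perm))
  })
  exportGraphML(nca$network, file.path(out_dir, "haplotype_network.graphml"))
  utils::write.table(nca$perm$clades, file.path(out_dir, "nca_clades.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(nca$perm$contrasts,
                     file.path(out_dir, "nca_contrasts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(nca$inference, file.path(out_dir, "nca_inference.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- coverage and rarefaction -------------------------------------------
  cov <- .stage("coverage", {
    hap_ab <- haplo$count
    otu_ab <- as.vector(table(strains$otu_id))
    n <- sum(hap_ab)
    depths <- unique(round(seq(1, n, length.out = 20)))
    list(goods_haplotype = goodsCoverage(hap_ab),
         goods_otu = goodsCoverage(otu_ab),
         rarefaction = rarefactionCurve(otu_ab, depths, n_reps = 50,
                                        seed = childSeed(seed, "rare")))
  })
  utils::write.table(cov$rarefaction, file.path(out_dir, "rarefaction.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cov[c("goods_haplotype", "goods_otu")],
                       file.path(out_dir, "coverage.json"),
                       auto_unbox = TRUE, digits = NA)

  ## --- manifest ------------------------------------------------------------
  cfg_plain <- unclass(config)
  if (!is.null(cfg_plain$scenario))
    cfg_plain$scenario <- lapply(slotNames(cfg_plain$scenario), function(s)
      methods::slot(config$scenario, s)) |>
      stats::setNames(slotNames(config$scenario))
  cfg_path <- file.path(out_dir, "config_materialized.json")
  jsonlite::write_json(cfg_plain, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  manifest <- list(
    package_version = as.character(utils::packageVersion("phylogeodiv")),
    r_version = R.version.string,
    seed = seed, n_perm = config$n_perm,
    config_hash = unname(tools::md5sum(cfg_path)),
    n_sequences = length(alignment), n_strains = nrow(strains),
    n_sites = nrow(sd_), n_haplotypes = nrow(haplo),
    n_otus = length(unique(assignment$otu_id)),
    parsimony_limit = nca$limit)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(config = config, alignment = alignment, tree = tree,
                 sites = sites, strains = strains, haplotypes = haplo,
                 assignment = assignment, otu_tree = otu_tree,
                 communities = list(otu = otu_comm,
                                    otu_unique = otu_comm_uniq,
                                    haplotype = hap_comm),
                 alpha = alpha, contrasts = contrasts,
                 time_rank_spearman = time_cor, beta = beta, tests = tests,
                 correlation = ct, sharing = share, nca = nca,
                 coverage = cov, manifest = manifest))
}

#' Paired runs with and without an exclusion set
#'
#' Runs the pipeline twice — once on all sites, once with `exclusion`
#' dropped — and tabulates the headline distance-decay statistics side by
#' side, flagging results whose significance at 0.05 changes.
#'
#' @param config A `phylogeodivConfig`.
#' @param exclusion Character vector of site ids to exclude in the second
#'   run (must leave at least 4 sites).
#' @param out_dir Output directory; sub-directories `all/` and
#'   `excluded/` receive the two runs.
#' @return List with `full`, `excluded` (both [runAll()] results) and
#'   `comparison` (data.frame).
#' @export
withAndWithout <- function(config, exclusion, out_dir) {
  full <- runAll(config, file.path(out_dir, "all"))
  n_left <- nrow(siteData(full$sites)) -
    length(intersect(exclusion, siteNames(full$sites)))
  if (n_left < 4)
    stop("exclusion leaves fewer than 4 sites", call. = FALSE)
  cfg2 <- config
  cfg2$exclude_sites <- union(config$exclude_sites, exclusion)
  excl <- runAll(cfg2, file.path(out_dir, "excluded"))
  keys <- intersect(names(full$tests), names(excl$tests))
  comparison <- do.call(rbind, lapply(keys, function(k) {
    a <- full$tests[[k]]; b <- excl$tests[[k]]
    data.frame(test = k, r_squared_all = a$r_squared, p_all = a$p,
               r_squared_excluded = b$r_squared, p_excluded = b$p,
               changed = (a$p <= 0.05) != (b$p <= 0.05),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(comparison,
                     file.path(out_dir, "comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(full = full, excluded = excl, comparison = comparison)
}
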