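## edge x taxon incidence: is taxon a descendant of the edge's child node
.edgeIncidence <- function(tree, taxa) {
  idx <- match(taxa, tree$tip.label)
  if (anyNA(idx)) stop("unknown taxon: ", taxa[is.na(idx)][1], call. = FALSE)
  paths <- tipEdgePaths(tree)
  M <- matrix(FALSE, nrow(tree$edge), length(taxa),
              dimnames = list(NULL, taxa))
  for (j in seq_along(idx)) M[paths[[idx[j]]], j] <- TRUE
  M
}

#' UniFrac distance matrix
#'
#' Unweighted UniFrac between every pair of sites: the branch length
#' unique to either site's taxa divided by the total branch length spanned
#' by their union (root-inclusive spanning, matching [faithPD()]). The
#' `"abundance_weighted"` variant weights each branch by the absolute
#' difference of the abundance fractions beneath it, normalized by the
#' branch lengths times the summed fractions, so it also lies in `[0, 1]`.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param community [CommunityMatrix-class]; all taxa must be tree tips and
#'   no site may be empty.
#' @param variant `"unweighted"` or `"abundance_weighted"`.
#' @return A [DistanceMatrix-class] of kind `"unifrac"`.
#' @export
unifracMatrix <- function(tree, community,
                          variant = c("unweighted", "abundance_weighted")) {
  variant <- match.arg(variant)
  m <- communityCounts(community)
  if (any(rowSums(m) == 0))
    stop("empty site: ", rownames(m)[rowSums(m) == 0][1], call. = FALSE)
  M <- .edgeIncidence(tree, colnames(m))
  bl <- tree$edge.length
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (variant == "unweighted") {
    pres <- M %*% t(m > 0) > 0 # edge x site: any member tip below edge
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- pres[, i]; b <- pres[, j]
      union <- sum(bl[a | b])
      out[i, j] <- out[j, i] <- sum(bl[xor(a, b)]) / union
    }
  } else {
    frac <- t(m / rowSums(m)) # taxon x site abundance fractions
    P <- M %*% frac           # edge x site: fraction beneath each edge
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      num <- sum(bl * abs(P[, i] - P[, j]))
      den <- sum(bl * (P[, i] + P[, j]))
      out[i, j] <- out[j, i] <- num / den
    }
  }
  distanceMatrix(out, kind = "unifrac")
}

#' Permutation significance of pairwise UniFrac
#'
#' Permutes the site labels of individual strain records (holding site
#' sample sizes fixed), recomputes unweighted UniFrac, and reports for
#' each site pair the one-sided smoothed p-value
#' `(1 + #{permuted >= observed}) / (1 + n_perm)`.
#'
#' @inheritParams unifracMatrix
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `observed` ([DistanceMatrix-class]) and `p` (matrix of
#'   per-pair p-values).
#' @export
unifracSignificance <- function(tree, community, n_perm = 999, seed = NULL) {
  m <- communityCounts(community)
  if (nrow(m) < 2) stop("need >= 2 sites", call. = FALSE)
  obs <- as.matrix(unifracMatrix(tree, community, "unweighted"))
  ## strain-level records: one site label and one taxon per strain
  strain_site <- rep(rownames(m), times = rowSums(m))
  strain_taxon <- unlist(lapply(rownames(m), function(s)
    rep(colnames(m), times = m[s, ])))
  count_ge <- matrix(0, nrow(m), nrow(m), dimnames = dimnames(obs))
  withSeed(seed, for (b in seq_len(n_perm)) {
    perm_site <- sample(strain_site)
    mp <- unclass(table(factor(perm_site, levels = rownames(m)),
                        factor(strain_taxon, levels = colnames(m))))
    dp <- as.matrix(unifracMatrix(tree, communityMatrix(mp), "unweighted"))
    count_ge <- count_ge + (dp >= obs - 1e-12)
  })
  p <- permPvalue(count_ge, n_perm)
  diag(p) <- NA
  list(observed = distanceMatrix(obs, "unifrac"), p = p,
       n_perm = n_perm, seed = if (is.null(seed)) NA else seed)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` on the chosen community
#' view (`"weighted"` = stored counts, `"unweighted"` = presence).
#'
#' @param community [CommunityMatrix-class] with no empty sites.
#' @param view Passed to [communityView()].
#' @return A [DistanceMatrix-class] of kind `"braycurtis"`.
#' @export
brayCurtisMatrix <- function(community, view = c("weighted", "unweighted")) {
  view <- match.arg(view)
  m <- communityCounts(communityView(community, view))
  if (any(rowSums(m) == 0))
    stop("empty site: ", rownames(m)[rowSums(m) == 0][1], call. = FALSE)
  distanceMatrix(as.matrix(vegan::vegdist(m, method = "bray")),
                 kind = "braycurtis")
}

#' Great-circle distance matrix
#'
#' Haversine distances between site coordinates, Earth radius
#' 6371.0088 km.
#'
#' @param sites [SiteTable-class] (or data.frame with `site_id`,
#'   `latitude`, `longitude`).
#' @return A [DistanceMatrix-class] of kind `"geographic_km"`.
#' @export
haversineMatrix <- function(sites) {
  d <- if (is(sites, "SiteTable")) siteData(sites) else sites
  n <- nrow(d)
  coords <- cbind(d$longitude, d$latitude)
  out <- matrix(0, n, n, dimnames = list(d$site_id, d$site_id))
  for (i in seq_len(n - 1)) {
    km <- geosphere::distHaversine(coords[i, , drop = FALSE],
                                   coords[(i + 1):n, , drop = FALSE],
                                   r = 6371008.8) / 1000
    out[i, (i + 1):n] <- km
    out[(i + 1):n, i] <- km
  }
  distanceMatrix(out, kind = "geographic_km")
}

#' Environmental distance matrix
#'
#' Euclidean distance on z-scored environmental variables (each variable
#' centred and scaled to unit SD across sites). Zero-variance variables
#' are dropped with a warning.
#'
#' @param sites [SiteTable-class].
#' @param variables Environmental columns to use.
#' @param standardize Scale variables before computing distances.
#' @return A [DistanceMatrix-class] of kind `"environmental"`.
#' @export
envDistance <- function(sites, variables = c("pH", "som", "temp", "ppt"),
                        standardize = TRUE) {
  d <- siteData(sites)
  missing <- setdiff(variables, names(d))
  if (length(missing))
    stop("unknown variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(d[variables])
  keep <- apply(x, 2, stats::sd) > 0
  if (!all(keep)) {
    warning("dropping zero-variance variable(s): ",
            paste(variables[!keep], collapse = ", "), call. = FALSE)
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0) stop("no usable variables", call. = FALSE)
  if (standardize) {
    ## population-SD z-scores: the standardized sites have mean 0 and
    ## root-mean-square 1, so two sites map exactly to -1 and +1
    n <- nrow(x)
    x <- scale(x, center = TRUE,
               scale = apply(x, 2, stats::sd) * sqrt((n - 1) / n))
  }
  rownames(x) <- d$site_id
  distanceMatrix(as.matrix(stats::dist(x)), kind = "environmental")
}

.asDistMatrix <- function(x) {
  if (is(x, "DistanceMatrix")) return(x@values)
  if (inherits(x, "dist")) return(as.matrix(x))
  as.matrix(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries, with a one-sided
#' permutation p-value (`>=` observed, +1 smoothing) obtained by jointly
#' permuting rows and columns of the second matrix. `r_squared` is the
#' squared Mantel r; the sign of r is retained in `value`.
#'
#' @param d1,d2 [DistanceMatrix-class], `dist` or matrix with identical
#'   labels, n >= 4.
#' @param n_perm Permutations (default 1000).
#' @param seed Integer seed.
#' @return A [TestResult-class].
#' @export
mantelTest <- function(d1, d2, n_perm = 1000, seed = NULL) {
  m1 <- .asDistMatrix(d1); m2 <- .asDistMatrix(d2)
  if (!identical(dim(m1), dim(m2)))
    stop("matrices must have the same size", call. = FALSE)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("matrix labels disagree", call. = FALSE)
  if (nrow(m1) < 4) stop("need n >= 4 sites", call. = FALSE)
  if (stats::sd(m1[upper.tri(m1)]) == 0 || stats::sd(m2[upper.tri(m2)]) == 0)
    stop("constant distance matrix", call. = FALSE)
  mt <- withSeed(seed, vegan::mantel(stats::as.dist(m1), stats::as.dist(m2),
                                     method = "pearson",
                                     permutations = n_perm))
  r <- unname(mt$statistic)
  n_used <- if (length(mt$perm)) length(mt$perm) else n_perm
  testResult("mantel_r", r, r^2, mt$signif, n_used, seed)
}

#' Single-variable PERMANOVA on a distance matrix
#'
#' Partitions the total sum of squares of a distance matrix by one
#' explanatory variable (factor or numeric covariate) using the
#' Gower-centred inner-product formulation: `G = J(-D^2/2)J` with
#' `J = I - 11'/n`, `SS_model = tr(HG)` for the hat matrix `H` of the
#' design, `R^2 = SS_model / tr(G)`, and pseudo-F with the usual degrees
#' of freedom. Significance is by permutation of the variable, one-sided
#' on F with +1 smoothing.
#'
#' @param d [DistanceMatrix-class], `dist` or matrix.
#' @param variable Explanatory variable, one value per site (in label
#'   order of `d`).
#' @param n_perm Permutations (default 999; ignored when `exhaustive`).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all `n!` permutations instead of sampling
#'   (only for n <= 8); the p-value is then exact.
#' @return A [TestResult-class] (value = pseudo-F).
#' @export
permanovaTest <- function(d, variable, n_perm = 999, seed = NULL,
                          exhaustive = FALSE) {
  D <- .asDistMatrix(d)
  n <- nrow(D)
  if (length(variable) != n)
    stop("variable must have one value per site", call. = FALSE)
  if (length(unique(variable)) < 2)
    stop("singular design: variable is constant", call. = FALSE)
  X <- stats::model.matrix(~v, data.frame(v = variable))
  rank <- qr(X)$rank
  if (rank < 2) stop("singular design: variable is constant", call. = FALSE)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% (-D^2 / 2) %*% J
  ss_total <- sum(diag(G))
  df_model <- rank - 1
  df_res <- n - rank
  if (df_res < 1) stop("no residual degrees of freedom", call. = FALSE)
  fstat <- function(perm) {
    Xp <- X[perm, , drop = FALSE]
    H <- Xp %*% solve(crossprod(Xp), t(Xp))
    ss_m <- sum(H * G) # tr(HG): H symmetric
    (ss_m / df_model) / ((ss_total - ss_m) / df_res)
  }
  f_obs <- fstat(seq_len(n))
  H0 <- X %*% solve(crossprod(X), t(X))
  ss_model <- sum(H0 * G)
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration only for n <= 8", call. = FALSE)
    perms <- allPerms(n)
    fs <- apply(perms, 1, fstat) # includes the identity
    count <- sum(fs >= f_obs - 1e-12)
    return(testResult("pseudo_F", f_obs, ss_model / ss_total,
                      count / nrow(perms), nrow(perms) - 1, seed))
  }
  count <- withSeed(seed, sum(vapply(seq_len(n_perm), function(b) {
    fstat(sample(n)) >= f_obs - 1e-12
  }, NA)))
  testResult("pseudo_F", f_obs, ss_model / ss_total,
             permPvalue(count, n_perm), n_perm, seed)
}

#' Pairwise Pearson correlation table
#'
#' All pairwise Pearson correlations among the numeric columns of a
#' per-site statistics table, with two-sided t-based p-values and
#' significance flags at 0.05 / 0.01 / 0.001. Constant columns yield NA
#' correlations.
#'
#' @param stats_table data.frame of per-site statistics and environmental
#'   characteristics (numeric columns are used).
#' @return List with matrices `r`, `p`, `stars` and the sample size `n`.
#' @export
correlationTable <- function(stats_table) {
  x <- as.matrix(stats_table[vapply(stats_table, is.numeric, NA)])
  n <- nrow(x)
  if (n < 3) stop("need >= 3 sites", call. = FALSE)
  k <- ncol(x)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(x[, i], x[, j]) # pairwise complete
    nn <- sum(ok)
    if (nn < 3 || stats::sd(x[ok, i]) == 0 || stats::sd(x[ok, j]) == 0) next
    rr <- stats::cor(x[ok, i], x[ok, j])
    r[i, j] <- rr
    if (i == j) { p[i, j] <- NA; next }
    tt <- rr * sqrt((nn - 2) / (1 - rr^2))
    p[i, j] <- 2 * stats::pt(abs(tt), nn - 2, lower.tail = FALSE)
  }
  stars <- matrix("", k, k, dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  list(r = r, p = p, stars = stars, n = n)
}
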