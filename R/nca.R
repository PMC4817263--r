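## one nesting pass: given unit labels and an edge list between units,
## union units one mutational step apart, tips first, label order.
.nestOnce <- function(units, edges) {
  deg <- stats::setNames(integer(length(units)), units)
  if (nrow(edges)) {
    t1 <- table(factor(edges[, 1], levels = units))
    t2 <- table(factor(edges[, 2], levels = units))
    deg <- as.integer(t1 + t2)
    names(deg) <- units
  }
  nbrs <- function(u) {
    sort(unique(c(edges[edges[, 1] == u, 2], edges[edges[, 2] == u, 1])))
  }
  assigned <- stats::setNames(rep(NA_integer_, length(units)), units)
  k <- 0L
  for (pass in 1:2) {
    cand <- if (pass == 1) sort(units[deg <= 1]) else sort(units)
    for (u in cand) {
      if (!is.na(assigned[u])) next
      nb <- nbrs(u)
      nb <- nb[is.na(assigned[nb])]
      k <- k + 1L
      assigned[u] <- k
      if (length(nb)) assigned[nb[1]] <- k # union with one neighbour only
    }
  }
  assigned
}

#' Nest a loop-free haplotype network into clades
#'
#' Hierarchical nesting: starting from the tips of each network component,
#' nodes one mutational step apart are unioned into 1-step clades
#' (tips first, in label order; each node unions with at most one
#' neighbour, stranded nodes become singleton clades), then the procedure
#' iterates on the clade graph until every component is a single clade.
#' Level 0 is the nodes themselves. Interior/tip status is recorded per
#' level from the clade-graph degree.
#'
#' @param net A loop-free [HaploNetwork-class] (see [resolveLoops()]).
#' @return A [NestedDesign-class].
#' @export
nestClades <- function(net) {
  g <- net@graph
  gi <- igraph::girth(g)
  if (is.finite(gi$girth) && gi$girth > 0)
    stop("network contains loops; run resolveLoops() first", call. = FALSE)
  nodes <- igraph::V(g)$name
  comp <- igraph::components(g)$membership
  el <- igraph::as_edgelist(g)
  membership <- data.frame(node = nodes, component = unname(comp[nodes]),
                           level_0 = nodes, stringsAsFactors = FALSE)
  clades <- data.frame()
  ## current clade of each node, and edges between clades
  cur <- stats::setNames(nodes, nodes)
  cur_edges <- el
  level <- 0L
  degOf <- function(units, edges) {
    d <- stats::setNames(integer(length(units)), units)
    if (nrow(edges)) {
      tt <- table(factor(c(edges[, 1], edges[, 2]), levels = units))
      d[] <- as.integer(tt)
    }
    d
  }
  ## record level-0 tip status
  d0 <- degOf(unique(cur), cur_edges)
  clades <- data.frame(level = 0L, clade = names(d0),
                       component = unname(comp[names(d0)]),
                       is_tip = unname(d0) <= 1L,
                       n_nodes = 1L, parent = NA_character_,
                       stringsAsFactors = FALSE)
  repeat {
    units <- sort(unique(cur))
    comp_of_unit <- vapply(units, function(u) {
      unname(comp[names(cur)[cur == u][1]])
    }, 0)
    if (!anyDuplicated(comp_of_unit)) break # one clade per component
    level <- level + 1L
    asg <- .nestOnce(units, cur_edges)
    ids <- sprintf("C%d_%03d", level, asg)
    names(ids) <- names(asg)
    new_cur <- stats::setNames(ids[cur], names(cur))
    membership[[paste0("level_", level)]] <- unname(new_cur[membership$node])
    ## edges between new clades (dedup, drop self)
    if (nrow(cur_edges)) {
      ne <- cbind(ids[cur_edges[, 1]], ids[cur_edges[, 2]])
      ne <- ne[ne[, 1] != ne[, 2], , drop = FALSE]
      if (nrow(ne)) {
        key <- paste(pmin(ne[, 1], ne[, 2]), pmax(ne[, 1], ne[, 2]))
        ne <- ne[!duplicated(key), , drop = FALSE]
      }
    } else ne <- cur_edges
    dl <- degOf(sort(unique(ids)), ne)
    comp_of_clade <- vapply(names(dl), function(cl) {
      unname(comp[names(new_cur)[new_cur == cl][1]])
    }, 0)
    n_nodes <- vapply(names(dl), function(cl) sum(new_cur == cl), 0L)
    clades <- rbind(clades, data.frame(
      level = level, clade = names(dl), component = comp_of_clade,
      is_tip = unname(dl) <= 1L, n_nodes = unname(n_nodes),
      parent = NA_character_, stringsAsFactors = FALSE))
    cur <- new_cur
    cur_edges <- ne
    if (level > length(nodes)) stop("nesting failed to terminate")
  }
  n_levels <- level
  ## fill parent pointers from membership columns
  for (lv in 0:n_levels) {
    if (lv == n_levels) break
    this <- paste0("level_", lv)
    up <- paste0("level_", lv + 1)
    map <- unique(membership[c(this, up)])
    idx <- clades$level == lv
    clades$parent[idx] <- map[[up]][match(clades$clade[idx], map[[this]])]
  }
  new("NestedDesign", membership = membership, clades = clades,
      n_levels = n_levels)
}

## strain-level geographic observations per node
.nodeObservations <- function(strains, sites, mapping = NULL) {
  sd_ <- siteData(sites)
  idx <- match(strains$site_id, sd_$site_id)
  if (anyNA(idx))
    stop("strain map references unknown site: ",
         strains$site_id[is.na(idx)][1], call. = FALSE)
  hap <- strains$haplotype_id
  if (!is.null(mapping)) hap <- unname(mapping[hap])
  data.frame(node = hap, lon = sd_$longitude[idx], lat = sd_$latitude[idx],
             stringsAsFactors = FALSE)
}

#' Clade and nested-clade geographic distances
#'
#' For every clade of a nested design: the clade centre is the
#' strain-weighted spherical centroid of its members' site coordinates
#' (mean of unit vectors, renormalized); `Dc` is the weighted mean
#' great-circle distance (km) of members to their own clade centre, and
#' `Dn` the weighted mean distance to the centre of the nesting (parent)
#' clade — for outermost clades, the centre of the whole network
#' component. Clades containing no sampled strains (inferred
#' intermediates only) report NA.
#'
#' @param design A [NestedDesign-class].
#' @param strains Strain map (`strain_id`, `site_id`, `haplotype_id`).
#' @param sites [SiteTable-class] with coordinates.
#' @param mapping Optional named vector mapping strain haplotype ids to
#'   network node ids (from [haplotypeTable()]).
#' @return data.frame with `level`, `clade`, `parent`, `component`,
#'   `is_tip`, `n_strains`, `dc`, `dn`.
#' @export
cladeDistances <- function(design, strains, sites, mapping = NULL) {
  obs <- .nodeObservations(strains, sites, mapping)
  m <- designMembership(design)
  obs <- obs[obs$node %in% m$node, , drop = FALSE]
  lvl_of <- function(lv) {
    col <- if (lv == 0) "level_0" else paste0("level_", lv)
    stats::setNames(m[[col]], m$node)
  }
  ## centroids per clade per level (and per component for the top)
  cl <- designClades(design)
  out <- cl
  out$n_strains <- 0L
  out$dc <- NA_real_
  out$dn <- NA_real_
  centre_of <- list()
  for (lv in 0:design@n_levels) {
    lab <- lvl_of(lv)[obs$node]
    for (cid in unique(cl$clade[cl$level == lv])) {
      sel <- which(lab == cid)
      if (!length(sel)) next
      centre_of[[cid]] <- .sphericalCentroid(obs$lon[sel], obs$lat[sel],
                                             rep(1, length(sel)))
    }
  }
  comp_centre <- list()
  comp_of_node <- stats::setNames(m$component, m$node)
  for (cp in unique(m$component)) {
    sel <- which(comp_of_node[obs$node] == cp)
    if (length(sel))
      comp_centre[[as.character(cp)]] <-
        .sphericalCentroid(obs$lon[sel], obs$lat[sel], rep(1, length(sel)))
  }
  for (i in seq_len(nrow(out))) {
    lv <- out$level[i]; cid <- out$clade[i]
    lab <- lvl_of(lv)[obs$node]
    sel <- which(lab == cid)
    out$n_strains[i] <- length(sel)
    if (!length(sel)) next
    out$dc[i] <- mean(.gcKm(obs$lon[sel], obs$lat[sel], centre_of[[cid]]))
    pc <- if (!is.na(out$parent[i])) centre_of[[out$parent[i]]]
          else comp_centre[[as.character(out$component[i])]]
    if (!is.null(pc))
      out$dn[i] <- mean(.gcKm(obs$lon[sel], obs$lat[sel], pc))
  }
  out
}

#' Nested-clade permutation test (Dc/Dn significance)
#'
#' Within every nesting clade with at least two strain-bearing daughter
#' clades, permutes the daughter-clade membership of individual strain
#' observations against their geography and flags each daughter's Dc and
#' Dn as significantly large (`>=` observed in at most `alpha` of
#' permutations) or small (`<=` likewise), with +1 smoothing. The
#' interior-minus-tip Dc and Dn contrasts are tested with the same
#' permutations whenever a nesting clade has both interior and tip
#' daughters.
#'
#' @inheritParams cladeDistances
#' @param n_perm Permutations (default 1000).
#' @param seed Integer seed.
#' @param alpha Significance level for flags.
#' @return List with `clades` (per-daughter Dc/Dn, p-values, flags),
#'   `contrasts` (per nesting clade interior-tip tests), `alpha`,
#'   `n_perm`, `seed`.
#' @export
ncaPermutation <- function(design, strains, sites, mapping = NULL,
                           n_perm = 1000, seed = NULL, alpha = 0.05) {
  obs_tab <- cladeDistances(design, strains, sites, mapping)
  obs <- .nodeObservations(strains, sites, mapping)
  m <- designMembership(design)
  obs <- obs[obs$node %in% m$node, , drop = FALSE]
  rad <- pi / 180
  U <- cbind(cos(obs$lat * rad) * cos(obs$lon * rad),
             cos(obs$lat * rad) * sin(obs$lon * rad),
             sin(obs$lat * rad))
  res <- list(); ctr <- list()
  withSeed(seed, {
    for (lv in seq_len(design@n_levels)) {
      parents <- unique(obs_tab$clade[obs_tab$level == lv])
      child_col <- if (lv == 1) "level_0" else paste0("level_", lv - 1)
      par_col <- paste0("level_", lv)
      child_of <- stats::setNames(m[[child_col]], m$node)
      par_of <- stats::setNames(m[[par_col]], m$node)
      for (p in parents) {
        sel <- which(par_of[obs$node] == p)
        if (!length(sel)) next
        labs <- child_of[obs$node[sel]]
        daughters <- sort(unique(labs))
        if (length(daughters) < 2) next
        Up <- U[sel, , drop = FALSE]
        tipness <- stats::setNames(
          obs_tab$is_tip[match(daughters, obs_tab$clade)], daughters)
        pc <- .sphericalCentroid(obs$lon[sel], obs$lat[sel],
                                 rep(1, length(sel)))
        pcv <- c(cos(pc["lat"] * rad) * cos(pc["lon"] * rad),
                 cos(pc["lat"] * rad) * sin(pc["lon"] * rad),
                 sin(pc["lat"] * rad))
        dn_pt <- 6371.0088 * acos(pmin(1, pmax(-1, Up %*% pcv)))
        statFun <- function(lab_vec) {
          dc <- dn <- stats::setNames(rep(NA_real_, length(daughters)),
                                      daughters)
          for (dgt in daughters) {
            k <- which(lab_vec == dgt)
            if (!length(k)) next
            ctd <- colSums(Up[k, , drop = FALSE])
            nrm <- sqrt(sum(ctd^2))
            if (nrm < 1e-12) ctd <- Up[k[1], ] else ctd <- ctd / nrm
            dc[dgt] <- mean(6371.0088 *
                              acos(pmin(1, pmax(-1, Up[k, , drop = FALSE] %*% ctd))))
            dn[dgt] <- mean(dn_pt[k])
          }
          it_dc <- it_dn <- NA_real_
          if (any(tipness[daughters]) && any(!tipness[daughters])) {
            wgt <- table(factor(lab_vec, levels = daughters))
            iw <- wgt[!tipness[daughters]]; tw <- wgt[tipness[daughters]]
            di <- dc[!tipness[daughters]]; dt <- dc[tipness[daughters]]
            ni <- dn[!tipness[daughters]]; nt <- dn[tipness[daughters]]
            ok_i <- !is.na(di) & iw > 0; ok_t <- !is.na(dt) & tw > 0
            if (any(ok_i) && any(ok_t)) {
              it_dc <- sum(di[ok_i] * iw[ok_i]) / sum(iw[ok_i]) -
                sum(dt[ok_t] * tw[ok_t]) / sum(tw[ok_t])
              it_dn <- sum(ni[ok_i] * iw[ok_i]) / sum(iw[ok_i]) -
                sum(nt[ok_t] * tw[ok_t]) / sum(tw[ok_t])
            }
          }
          list(dc = dc, dn = dn, it_dc = it_dc, it_dn = it_dn)
        }
        o <- statFun(labs)
        ge_dc <- le_dc <- ge_dn <- le_dn <-
          stats::setNames(rep(0, length(daughters)), daughters)
        ge_it_dc <- le_it_dc <- ge_it_dn <- le_it_dn <- 0
        for (b in seq_len(n_perm)) {
          pp <- statFun(sample(labs))
          ge_dc <- ge_dc + (!is.na(pp$dc) & !is.na(o$dc) &
                              pp$dc >= o$dc - 1e-9)
          le_dc <- le_dc + (!is.na(pp$dc) & !is.na(o$dc) &
                              pp$dc <= o$dc + 1e-9)
          ge_dn <- ge_dn + (!is.na(pp$dn) & !is.na(o$dn) &
                              pp$dn >= o$dn - 1e-9)
          le_dn <- le_dn + (!is.na(pp$dn) & !is.na(o$dn) &
                              pp$dn <= o$dn + 1e-9)
          if (!is.na(o$it_dc) && !is.na(pp$it_dc)) {
            ge_it_dc <- ge_it_dc + (pp$it_dc >= o$it_dc - 1e-9)
            le_it_dc <- le_it_dc + (pp$it_dc <= o$it_dc + 1e-9)
          }
          if (!is.na(o$it_dn) && !is.na(pp$it_dn)) {
            ge_it_dn <- ge_it_dn + (pp$it_dn >= o$it_dn - 1e-9)
            le_it_dn <- le_it_dn + (pp$it_dn <= o$it_dn + 1e-9)
          }
        }
        for (dgt in daughters) {
          if (is.na(o$dc[dgt])) next
          p_dc_l <- permPvalue(ge_dc[dgt], n_perm)
          p_dc_s <- permPvalue(le_dc[dgt], n_perm)
          p_dn_l <- permPvalue(ge_dn[dgt], n_perm)
          p_dn_s <- permPvalue(le_dn[dgt], n_perm)
          res[[length(res) + 1L]] <- data.frame(
            parent = p, clade = dgt, level = lv - 1,
            is_tip = unname(tipness[dgt]),
            n_strains = sum(labs == dgt),
            dc = unname(o$dc[dgt]), dn = unname(o$dn[dgt]),
            p_dc_large = p_dc_l, p_dc_small = p_dc_s,
            p_dn_large = p_dn_l, p_dn_small = p_dn_s,
            dc_flag = if (p_dc_l <= alpha) "large"
                      else if (p_dc_s <= alpha) "small" else "",
            dn_flag = if (p_dn_l <= alpha) "large"
                      else if (p_dn_s <= alpha) "small" else "",
            stringsAsFactors = FALSE)
        }
        if (!is.na(o$it_dc)) {
          ctr[[length(ctr) + 1L]] <- data.frame(
            parent = p, level = lv, it_dc = o$it_dc, it_dn = o$it_dn,
            p_it_dc_large = permPvalue(ge_it_dc, n_perm),
            p_it_dc_small = permPvalue(le_it_dc, n_perm),
            p_it_dn_large = permPvalue(ge_it_dn, n_perm),
            p_it_dn_small = permPvalue(le_it_dn, n_perm),
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  list(clades = if (length(res)) do.call(rbind, res) else
         data.frame(parent = character(), clade = character()),
       contrasts = if (length(ctr)) do.call(rbind, ctr) else
         data.frame(parent = character()),
       alpha = alpha, n_perm = n_perm,
       seed = if (is.null(seed)) NA else seed)
}

#' Default nested-clade inference table
#'
#' A machine-readable decision table distinguishing the inference classes
#' this pipeline reports: restricted gene flow with isolation by
#' distance, and contiguous range expansion. Each rule carries a label
#' and `requires`, a list of predicate groups; a rule matches a nesting
#' clade when every group contains at least one predicate that is true
#' there. Rules are evaluated in order; no significant flags at all gives
#' "no significant association", and flags matching no rule give
#' "inconclusive". The table is plain-list/JSON editable, so additional
#' chains of a published inference key can be supplied without code
#' changes.
#'
#' @return List with a `rules` element.
#' @export
defaultInferenceTable <- function() {
  list(rules = list(
    list(label = "restricted gene flow with isolation by distance",
         requires = list(list("tip_dc_small"),
                         list("interior_dc_large", "it_dc_large"))),
    list(label = "contiguous range expansion",
         requires = list(list("tip_dc_large", "interior_dc_small",
                              "it_dc_small")))
  ))
}

.ncaPredicates <- function(group, contrasts, alpha) {
  tips <- group[group$is_tip, , drop = FALSE]
  ints <- group[!group$is_tip, , drop = FALSE]
  ct <- contrasts
  list(
    tip_dc_small = any(tips$dc_flag == "small"),
    tip_dc_large = any(tips$dc_flag == "large"),
    tip_dn_small = any(tips$dn_flag == "small"),
    tip_dn_large = any(tips$dn_flag == "large"),
    interior_dc_small = any(ints$dc_flag == "small"),
    interior_dc_large = any(ints$dc_flag == "large"),
    interior_dn_small = any(ints$dn_flag == "small"),
    interior_dn_large = any(ints$dn_flag == "large"),
    it_dc_large = nrow(ct) > 0 && any(ct$p_it_dc_large <= alpha),
    it_dc_small = nrow(ct) > 0 && any(ct$p_it_dc_small <= alpha),
    it_dn_large = nrow(ct) > 0 && any(ct$p_it_dn_large <= alpha),
    it_dn_small = nrow(ct) > 0 && any(ct$p_it_dn_small <= alpha))
}

#' Interpret nested-clade significance flags
#'
#' Deterministic lookup of each nesting clade's flag pattern through a
#' pluggable decision table (see [defaultInferenceTable()]).
#'
#' @param nca Result of [ncaPermutation()].
#' @param table Decision table (list or path to a JSON file).
#' @return data.frame with `parent`, `level`, `n_strains`, `inference`.
#' @export
interpretNca <- function(nca, table = defaultInferenceTable()) {
  if (is.character(table))
    table <- jsonlite::read_json(table, simplifyVector = FALSE)
  if (!is.list(table) || is.null(table$rules))
    stop("malformed inference table: needs a 'rules' element", call. = FALSE)
  for (r in table$rules) {
    if (is.null(r$label) || is.null(r$requires))
      stop("malformed inference rule: needs 'label' and 'requires'",
           call. = FALSE)
  }
  cl <- nca$clades
  if (!nrow(cl)) {
    return(data.frame(parent = character(), level = numeric(),
                      n_strains = numeric(), inference = character()))
  }
  out <- lapply(split(cl, cl$parent), function(group) {
    p <- group$parent[1]
    ct <- nca$contrasts[nca$contrasts$parent == p, , drop = FALSE]
    any_flag <- any(group$dc_flag != "") || any(group$dn_flag != "") ||
      (nrow(ct) > 0 && any(c(ct$p_it_dc_large, ct$p_it_dc_small,
                             ct$p_it_dn_large, ct$p_it_dn_small) <=
                             nca$alpha))
    label <- if (!any_flag) "no significant association" else {
      preds <- .ncaPredicates(group, ct, nca$alpha)
      hit <- NULL
      for (r in table$rules) {
        ok <- all(vapply(r$requires, function(grp) {
          any(unlist(preds[unlist(grp)]))
        }, NA))
        if (isTRUE(ok)) { hit <- r$label; break }
      }
      if (is.null(hit)) "inconclusive" else hit
    }
    data.frame(parent = p, level = group$level[1] + 1,
               n_strains = sum(group$n_strains), inference = label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
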