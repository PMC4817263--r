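#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded package functions never perturb the
#' global random stream. A `NULL` seed evaluates `expr` under the current
#' stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a reproducible child seed from a parent seed and a stage label.
## Keeps every stage independently seeded while the whole run is a pure
## function of one integer. Result stays below 2^31.
childSeed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 2017L + (h %% 99991L)
}

## all permutations of 1..n (n <= 8), in lexicographic order
allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

stopifnot_scalar <- function(x, name, numeric = TRUE) {
  if (length(x) != 1L || is.na(x) || (numeric && !is.numeric(x))) {
    stop(sprintf("'%s' must be a single non-missing %s value", name,
                 if (numeric) "numeric" else ""), call. = FALSE)
  }
  invisible(x)
}

## Smoothed permutation p-value: (1 + b) / (1 + n).
permPvalue <- function(n_extreme, n_perm) {
  (1 + n_extreme) / (1 + n_perm)
}

## Check that a phylo object has a full set of branch lengths.
assertBranchLengths <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree must have branch lengths on every edge", call. = FALSE)
  }
  invisible(tree)
}

## Tip -> root edge paths for every tip, as lists of edge indices.
## Used by Faith's PD, MRD and UniFrac; computed once per tree.
tipEdgePaths <- function(tree) {
  assertBranchLengths(tree)
  n_tip <- length(tree$tip.label)
  parent <- integer(n_tip + tree$Nnode)
  edge_of <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- n_tip + 1L
  lapply(seq_len(n_tip), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      path <- c(path, edge_of[node])
      node <- parent[node]
    }
    path
  })
}
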