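#' Accessors
#'
#' Accessor generics for the package's S4 containers; user code should use
#' these instead of reaching into slots.
#'
#' @param x An object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("communityCounts", function(x) standardGeneric("communityCounts"))

#' @rdname accessors
#' @export
setMethod("communityCounts", "CommunityMatrix", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("siteNames", function(x) standardGeneric("siteNames"))

#' @rdname accessors
#' @export
setMethod("siteNames", "CommunityMatrix", function(x) rownames(x@counts))

#' @rdname accessors
#' @export
setMethod("siteNames", "SiteTable", function(x) x@data$site_id)

#' @rdname accessors
#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))

#' @rdname accessors
#' @export
setMethod("taxonNames", "CommunityMatrix", function(x) colnames(x@counts))

#' @rdname accessors
#' @export
setGeneric("siteData", function(x) standardGeneric("siteData"))

#' @rdname accessors
#' @export
setMethod("siteData", "SiteTable", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("haploGraph", function(x) standardGeneric("haploGraph"))

#' @rdname accessors
#' @export
setMethod("haploGraph", "HaploNetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setMethod("haploGraph", "SharingGraph", function(x) x@graph)

#' @rdname accessors
#' @export
setGeneric("designClades", function(x) standardGeneric("designClades"))

#' @rdname accessors
#' @export
setMethod("designClades", "NestedDesign", function(x) x@clades)

#' @rdname accessors
#' @export
setGeneric("designMembership", function(x) standardGeneric("designMembership"))

#' @rdname accessors
#' @export
setMethod("designMembership", "NestedDesign", function(x) x@membership)

#' @rdname accessors
#' @export
setGeneric("otuTable", function(x) standardGeneric("otuTable"))

#' @rdname accessors
#' @export
setMethod("otuTable", "SharingGraph", function(x) x@otuTable)

#' Weighted and unweighted community views
#'
#' The weighted view is the stored strain-count matrix; the unweighted view
#' collapses every non-zero count to presence (1). Both are derived on
#' demand from one stored matrix.
#'
#' @param x A [CommunityMatrix-class].
#' @param view `"weighted"` or `"unweighted"`.
#' @return A [CommunityMatrix-class].
#' @export
setGeneric("communityView",
           function(x, view = c("weighted", "unweighted"))
             standardGeneric("communityView"))

#' @rdname communityView
#' @export
setMethod("communityView", "CommunityMatrix", function(x, view) {
  view <- match.arg(view, c("weighted", "unweighted"))
  if (view == "weighted") return(x)
  m <- x@counts
  m[m > 0] <- 1
  communityMatrix(m)
})
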