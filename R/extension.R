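#' Construct an ontology extension (annotated dataset)
#'
#' The extension holds the data instances (e.g. gene products): each
#' instance carries one or more direct class annotations, an optional set
#' of directed links to other instances, and a weight in `[0, 1]` (e.g. a
#' rescaled test statistic; defaults to 1).
#'
#' @param instances character vector of instance identifiers (unique).
#' @param types named list mapping each instance to a non-empty character
#'   vector of directly annotated classes.
#' @param rels named list mapping instances to character vectors of related
#'   instances (directed, source -> target). Defaults to none.
#' @param weights named numeric vector of instance weights in `[0, 1]`;
#'   instances absent from it get weight 1.
#' @param graph optional `mcoa_ontology`; when given, every annotated class
#'   must belong to it.
#' @return An object of class `"mcoa_extension"` with elements `instances`,
#'   `types`, `rels`, `weights` (all covering every instance).
#' @export
ontology_extension <- function(instances, types, rels = list(),
                               weights = NULL, graph = NULL) {
  instances <- as.character(instances)
  if (anyDuplicated(instances)) stop("duplicate instance identifiers")
  instances <- sort(instances)
  tps <- stats::setNames(vector("list", length(instances)), instances)
  rl <- tps
  w <- stats::setNames(rep(1, length(instances)), instances)
  for (i in instances) {
    ti <- unique(as.character(types[[i]]))
    if (length(ti) == 0L) {
      stop("instance '", i, "' has no direct class annotation")
    }
    if (!is.null(graph)) {
      unknown <- setdiff(ti, graph$classes)
      if (length(unknown) > 0L) {
        stop("instance '", i, "' annotated to unknown class(es): ",
             paste(unknown, collapse = ", "))
      }
    }
    tps[[i]] <- sort(ti)
    ri <- unique(as.character(rels[[i]]))
    bad <- setdiff(ri, instances)
    if (length(bad) > 0L) {
      stop("instance '", i, "' linked to unknown instance(s): ",
           paste(bad, collapse = ", "))
    }
    rl[[i]] <- sort(ri)
    if (!is.null(weights) && i %in% names(weights)) {
      wi <- as.numeric(weights[[i]])
      if (is.na(wi) || wi < 0 || wi > 1) {
        stop("weight for instance '", i, "' must lie in [0, 1]")
      }
      w[i] <- wi
    }
  }
  extra <- setdiff(names(types), instances)
  if (length(extra) > 0L) {
    stop("type map refers to unknown instance(s): ",
         paste(extra, collapse = ", "))
  }
  structure(list(instances = instances, types = tps, rels = rl, weights = w),
            class = "mcoa_extension")
}

#' @export
print.mcoa_extension <- function(x, ...) {
  cat("Ontology extension:", length(x$instances), "instances,",
      sum(lengths(x$types)), "direct annotations,",
      sum(lengths(x$rels)), "inter-instance links\n")
  invisible(x)
}

#' Restrict an extension to a subset of instances
#'
#' Keeps the given instances with their annotations and weights; links to
#' dropped instances are removed.
#'
#' @param ext an `mcoa_extension`.
#' @param instances instance identifiers to keep.
#' @return A new `mcoa_extension`.
#' @export
subset_extension <- function(ext, instances) {
  keep <- intersect(ext$instances, instances)
  if (length(keep) == 0L) stop("no instances left after subsetting")
  ontology_extension(
    keep,
    types = ext$types[keep],
    rels = lapply(ext$rels[keep], intersect, x = keep),
    weights = ext$weights[keep])
}
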