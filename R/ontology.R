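#' Construct an ontology graph
#'
#' An ontology is modelled as a rooted directed acyclic graph of class
#' identifiers with a direct-parent relation (is-a / part-of style
#' hierarchy). Every class has a (possibly empty) set of direct parents;
#' classes with no parents are roots and at least one root must exist.
#'
#' @param classes character vector of class identifiers (non-empty, unique).
#' @param parents named list mapping each class to a character vector of its
#'   direct parents. Classes absent from the list get no parents.
#' @param labels optional named character vector of human-readable names.
#' @param namespaces optional named character vector (e.g. GO aspect).
#' @return An object of class `"mcoa_ontology"` with elements `classes`,
#'   `parents` (named list covering every class), `labels`, `namespaces`.
#' @examples
#' g <- ontology_graph(c("C1", "C2", "C3"),
#'                     parents = list(C2 = "C1", C3 = "C2"))
#' ancestors(g, "C3")
#' @export
ontology_graph <- function(classes, parents = list(), labels = NULL,
                           namespaces = NULL) {
  classes <- as.character(classes)
  if (length(classes) == 0L) stop("ontology must contain at least one class")
  if (anyDuplicated(classes)) stop("duplicate class identifiers")
  full <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    p <- unique(as.character(parents[[cl]]))
    p <- p[!is.na(p) & nzchar(p)]
    unknown <- setdiff(p, classes)
    if (length(unknown) > 0L) {
      stop("class '", cl, "' has unknown parent(s): ",
           paste(unknown, collapse = ", "))
    }
    if (cl %in% p) stop("class '", cl, "' is its own parent")
    full[[cl]] <- sort(p)
  }
  extra <- setdiff(names(parents), classes)
  if (length(extra) > 0L) {
    stop("parent map refers to unknown class(es): ",
         paste(extra, collapse = ", "))
  }
  g <- structure(
    list(classes = sort(classes), parents = full[sort(classes)],
         labels = labels, namespaces = namespaces),
    class = "mcoa_ontology")
  validate_acyclic(g)
  if (length(roots(g)) == 0L) stop("ontology has no root class")
  g
}

#' @export
print.mcoa_ontology <- function(x, ...) {
  cat("Ontology graph:", length(x$classes), "classes,",
      length(roots(x)), "root(s),",
      sum(lengths(x$parents)), "parent edges\n")
  invisible(x)
}

# Kahn-style check via igraph; names one cycle on failure.
validate_acyclic <- function(graph) {
  el <- parent_edge_list(graph)
  if (nrow(el) == 0L) return(invisible(TRUE))
  ig <- igraph::graph_from_data_frame(el, directed = TRUE,
                                      vertices = graph$classes)
  if (!igraph::is_dag(ig)) {
    comp <- igraph::components(ig, mode = "strong")
    bad <- names(comp$membership)[comp$membership ==
                                    which(comp$csize > 1)[1]]
    stop("ontology hierarchy contains a cycle involving: ",
         paste(sort(bad), collapse = " -> "))
  }
  invisible(TRUE)
}

# two-column matrix (child, parent)
parent_edge_list <- function(graph) {
  np <- lengths(graph$parents)
  cbind(child = rep(names(graph$parents), np),
        parent = unlist(graph$parents, use.names = FALSE))
}

#' Root and leaf classes of an ontology
#'
#' @param graph an `mcoa_ontology`.
#' @return Character vector of class identifiers.
#' @export
roots <- function(graph) {
  graph$classes[lengths(graph$parents) == 0L]
}

#' @rdname roots
#' @export
leaves <- function(graph) {
  setdiff(graph$classes, unlist(graph$parents, use.names = FALSE))
}

#' Proper ancestors of a class
#'
#' Returns every class reachable from `class_id` by following parent edges,
#' excluding `class_id` itself; empty for a root.
#'
#' @param graph an `mcoa_ontology`.
#' @param class_id a class identifier present in the graph.
#' @return Character vector of ancestor identifiers (sorted).
#' @export
ancestors <- function(graph, class_id) {
  if (!class_id %in% graph$classes) {
    stop("unknown class: ", class_id)
  }
  seen <- character(0)
  frontier <- graph$parents[[class_id]]
  while (length(frontier) > 0L) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      unique(unlist(graph$parents[frontier], use.names = FALSE)), seen)
  }
  sort(seen)
}

# ancestors for every class at once (named list), memoized in topological
# order so each class is resolved after its parents
ancestor_table <- function(graph) {
  order <- topo_order(graph)
  anc <- stats::setNames(vector("list", length(graph$classes)),
                         graph$classes)
  for (cl in order) {
    ps <- graph$parents[[cl]]
    anc[[cl]] <- if (length(ps) == 0L) character(0) else
      sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
  }
  anc
}

# classes ordered so parents precede children
topo_order <- function(graph) {
  el <- parent_edge_list(graph)
  if (nrow(el) == 0L) return(graph$classes)
  ig <- igraph::graph_from_data_frame(
    el[, c("parent", "child"), drop = FALSE], directed = TRUE,
    vertices = graph$classes)
  names(igraph::topo_sort(ig, mode = "out"))
}

#' Longest-path depth of each class
#'
#' Depth (level) of a class is the length of the longest parent path from
#' the class up to a root; roots have level 0.
#'
#' @param graph an `mcoa_ontology`.
#' @return Named integer vector over all classes.
#' @export
class_levels <- function(graph) {
  lev <- stats::setNames(integer(length(graph$classes)), graph$classes)
  for (cl in topo_order(graph)) {
    ps <- graph$parents[[cl]]
    lev[cl] <- if (length(ps) == 0L) 0L else max(lev[ps]) + 1L
  }
  lev
}

#' Restrict an ontology to one namespace
#'
#' Keeps only classes whose recorded namespace matches, along with parent
#' edges between kept classes. Useful for single-aspect GO analyses.
#'
#' @param graph an `mcoa_ontology` with a `namespaces` map.
#' @param namespace namespace value to keep (e.g. `"biological_process"`).
#' @return A new `mcoa_ontology`.
#' @export
filter_namespace <- function(graph, namespace) {
  if (is.null(graph$namespaces)) stop("ontology has no namespace map")
  keep <- graph$classes[graph$namespaces[graph$classes] %in% namespace]
  if (length(keep) == 0L) stop("no classes in namespace '", namespace, "'")
  ontology_graph(
    keep,
    parents = lapply(graph$parents[keep], intersect, x = keep),
    labels = graph$labels[intersect(names(graph$labels), keep)],
    namespaces = graph$namespaces[keep])
}

#' Build the direct and materialized annotation index
#'
#' Materialization propagates every direct instance annotation to all
#' ancestor classes, so `materialized(c)` holds every instance annotated to
#' `c` or to any descendant of `c` (as a set: an instance reachable through
#' several descendants is counted once).
#'
#' @param graph an `mcoa_ontology`.
#' @param ext an `mcoa_extension` whose types are classes of `graph`.
#' @return An object of class `"mcoa_annotation_index"`: named lists
#'   `direct` and `materialized` (class -> character vector of instances),
#'   covering every class of the graph.
#' @export
build_annotation_index <- function(graph, ext) {
  stopifnot(inherits(graph, "mcoa_ontology"), inherits(ext, "mcoa_extension"))
  anc <- ancestor_table(graph)
  direct <- lapply(stats::setNames(graph$classes, graph$classes),
                   function(cl) character(0))
  mat <- direct
  for (i in ext$instances) {
    tps <- ext$types[[i]]
    for (cl in tps) direct[[cl]] <- c(direct[[cl]], i)
    closure <- unique(c(tps, unlist(anc[tps], use.names = FALSE)))
    for (cl in closure) mat[[cl]] <- c(mat[[cl]], i)
  }
  structure(list(direct = lapply(direct, unique),
                 materialized = lapply(mat, unique),
                 classes = graph$classes,
                 instances = ext$instances),
            class = "mcoa_annotation_index")
}

#' @export
print.mcoa_annotation_index <- function(x, ...) {
  cat("Annotation index:", length(x$classes), "classes,",
      length(x$instances), "instances;",
      sum(lengths(x$direct)), "direct /",
      sum(lengths(x$materialized)), "materialized annotations\n")
  invisible(x)
}
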