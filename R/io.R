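#' Read an OBO ontology file
#'
#' Parses OBO 1.2/1.4 `[Term]` stanzas into an ontology graph. Parent edges
#' are taken from `is_a` lines and from `relationship` lines whose relation
#' is listed in `hierarchy_relations` (default is-a and part-of, the GO
#' hierarchy convention). Obsolete terms are dropped; `alt_id`s are mapped
#' to their primary identifier and kept in the returned object's `alt_ids`
#' element so annotation readers can resolve them.
#'
#' @param path path to an OBO file.
#' @param hierarchy_relations relation names treated as parent edges.
#' @return An `mcoa_ontology` (with `labels`, `namespaces` and `alt_ids`).
#' @export
read_obo <- function(path, hierarchy_relations = c("is_a", "part_of")) {
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (length(starts) == 0L) stop("no stanzas found in OBO file: ", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0)
  labels <- character(0)
  nspaces <- character(0)
  parents <- list()
  alt_ids <- character(0)
  for (k in seq_along(starts)) {
    if (lines[starts[k]] != "[Term]") next
    body <- lines[(starts[k] + 1L):(bounds[k + 1L] - 1L)]
    body <- sub("!.*$", "", body)          # strip trailing comments
    body <- trimws(body)
    body <- body[nzchar(body)]
    get <- function(tag) {
      v <- body[startsWith(body, paste0(tag, ":"))]
      trimws(sub(paste0("^", tag, ":"), "", v))
    }
    id <- get("id")[1]
    if (is.na(id)) next
    if (any(tolower(get("is_obsolete")) == "true")) next
    ps <- get("is_a")
    for (rl in get("relationship")) {
      parts <- strsplit(rl, "[[:space:]]+")[[1]]
      if (length(parts) >= 2L && parts[1] %in% hierarchy_relations) {
        ps <- c(ps, parts[2])
      }
    }
    ids <- c(ids, id)
    parents[[id]] <- unique(ps)
    nm <- get("name")[1]
    if (!is.na(nm)) labels[id] <- nm
    ns <- get("namespace")[1]
    if (!is.na(ns)) nspaces[id] <- ns
    for (a in get("alt_id")) alt_ids[a] <- id
  }
  if (length(ids) == 0L) stop("no non-obsolete [Term] stanzas in: ", path)
  unknown <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(unknown) > 0L) {
    stop("parent edge references unknown term(s): ",
         paste(sort(unique(unknown)), collapse = ", "))
  }
  g <- ontology_graph(ids, parents, labels = labels, namespaces = nspaces)
  g$alt_ids <- alt_ids
  g
}

#' Read a GAF annotation file
#'
#' Reads GAF 2.0/2.1/2.2 (17 tab-separated columns, `!` comment lines).
#' Instances are keyed by the DB_Object_ID column; an instance's direct
#' annotations are the union of its annotated term identifiers. Rows whose
#' qualifier contains `NOT` are skipped; rows annotated to a term absent
#' from the ontology (after alt_id resolution) are skipped and counted in
#' a message. All weights default to 1 and no inter-instance links are
#' created.
#'
#' @param path path to a GAF file.
#' @param ontology an `mcoa_ontology` used to validate and filter terms.
#' @param evidence_codes optional character vector; when given, only rows
#'   with these evidence codes (column 7) are kept.
#' @return An `mcoa_extension`.
#' @export
read_gaf <- function(path, ontology, evidence_codes = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0L) stop("no annotation rows in GAF file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- fields[lengths(fields) >= 5L]
  if (length(fields) == 0L) stop("no parseable annotation rows in: ", path)
  obj <- vapply(fields, `[`, "", 2L)
  qual <- vapply(fields, `[`, "", 4L)
  term <- vapply(fields, `[`, "", 5L)
  keep <- !vapply(strsplit(qual, "|", fixed = TRUE),
                  function(q) "NOT" %in% q, TRUE)
  if (!is.null(evidence_codes)) {
    ev <- vapply(fields, function(f) if (length(f) >= 7L) f[7] else "", "")
    keep <- keep & ev %in% evidence_codes
  }
  obj <- obj[keep]; term <- term[keep]
  # resolve alt_ids to primary identifiers
  if (length(ontology$alt_ids) > 0L) {
    hit <- term %in% names(ontology$alt_ids)
    term[hit] <- ontology$alt_ids[term[hit]]
  }
  known <- term %in% ontology$classes
  n_skip <- sum(!known)
  if (n_skip > 0L) {
    message(n_skip, " annotation row(s) to terms absent from the ontology ",
            "were skipped")
  }
  obj <- obj[known]; term <- term[known]
  if (length(obj) == 0L) stop("no usable annotation rows in: ", path)
  types <- split(term, obj)
  ontology_extension(names(types), types = lapply(types, unique),
                     graph = ontology)
}

#' Read and write the self-contained toy JSON format
#'
#' A compact JSON representation of an ontology plus extension, used for
#' small diagnostic fixtures:
#' `{"classes": [{"id", "parents": [...]}],
#'   "instances": [{"id", "types": [...], "rels": [...], "weight"}]}`.
#' `read_toy_json(write_toy_json(...))` is lossless.
#'
#' @param path file path.
#' @return `read_toy_json` returns `list(graph, ext)`.
#' @export
read_toy_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$classes)) stop("toy JSON lacks a 'classes' array")
  ids <- vapply(x$classes, function(cl) as.character(cl$id), "")
  parents <- stats::setNames(
    lapply(x$classes, function(cl) unlist(cl$parents, use.names = FALSE)),
    ids)
  lab <- unlist(lapply(x$classes, function(cl)
    if (!is.null(cl$label)) stats::setNames(cl$label, cl$id)))
  graph <- ontology_graph(ids, parents, labels = lab)
  inst <- vapply(x$instances, function(i) as.character(i$id), "")
  ext <- ontology_extension(
    inst,
    types = stats::setNames(lapply(x$instances, function(i)
      unlist(i$types, use.names = FALSE)), inst),
    rels = stats::setNames(lapply(x$instances, function(i)
      unlist(i$rels, use.names = FALSE)), inst),
    weights = stats::setNames(vapply(x$instances, function(i)
      if (is.null(i$weight)) 1 else as.numeric(i$weight), 1), inst),
    graph = graph)
  list(graph = graph, ext = ext)
}

#' @rdname read_toy_json
#' @param graph an `mcoa_ontology`.
#' @param ext an `mcoa_extension`.
#' @export
write_toy_json <- function(graph, ext, path) {
  classes <- lapply(graph$classes, function(cl) {
    out <- list(id = jsonlite::unbox(cl), parents = graph$parents[[cl]])
    if (!is.null(graph$labels) && cl %in% names(graph$labels)) {
      out$label <- jsonlite::unbox(unname(graph$labels[cl]))
    }
    out
  })
  instances <- lapply(ext$instances, function(i) {
    list(id = jsonlite::unbox(i), types = ext$types[[i]],
         rels = ext$rels[[i]],
         weight = jsonlite::unbox(unname(ext$weights[i])))
  })
  jsonlite::write_json(list(classes = classes, instances = instances),
                       path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a gene-list TSV
#'
#' One instance identifier per line, with an optional second tab-separated
#' column giving a continuous weight in `[0, 1]`.
#'
#' @param path file path.
#' @return Named numeric vector of weights (1 where absent), named by
#'   instance identifier.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty gene list: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  w <- vapply(parts, function(p)
    if (length(p) >= 2L) as.numeric(p[2]) else 1, 1)
  if (anyNA(w)) stop("non-numeric weight in gene list: ", path)
  stats::setNames(w, ids)
}
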