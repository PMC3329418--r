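#' Diagnostic challenge scenarios
#'
#' Small hand-shaped ontologies plus datasets, each isolating one
#' structural feature that annotation-frequency information content
#' cannot see but the Markov chain steady-state probabilities resolve:
#'
#' * `multiple_annotation` — one instance annotated to both `C2` and
#'   `C3`; `C4` unshared with equal nominal counts. Expect
#'   `ssp(C2) == ssp(C3) < ssp(C4)`.
#' * `multiple_parents` — `C2` receives an exclusive child, `C3` a child
#'   shared with `C6`; equal materialized counts. Expect
#'   `ssp(C3) < ssp(C2)`.
#' * `continuous_weights` — per-class instance weight totals ordered
#'   `C3 > C2 > C4`. Expect `ssp(C3) > ssp(C2) > ssp(C4)`.
#' * `instance_links` — `C4` instances are net link receivers, `C3`
#'   instances net senders, `C2` balanced. Expect
#'   `ssp(C4) > ssp(C2) > ssp(C3)`.
#' * `semantic_distance` — `C2` is the only child of root `C1` with
#'   identical materialized instances. Expect `ssp(C2) > ssp(C1)`.
#' * `sparse_class` — `C4` has no instances at all. Expect
#'   `ssp(C4) > 0` whenever `omega > 0`.
#'
#' @param name one of the six scenario names above.
#' @param n_per_class nominal instances per contrasted class (default 3).
#' @return List with `name`, `graph`, `ext`, and `expected` (a short
#'   machine-readable description of the ordinal claim: list of
#'   `greater`/`equal` identifier pairs on ssp values).
#' @examples
#' sc <- challenge_scenario("semantic_distance")
#' fit <- mcoa(sc$graph, sc$ext)
#' fit$info_rank["C2"] < fit$info_rank["C1"]
#' @export
challenge_scenario <- function(name = c("multiple_annotation",
                                        "multiple_parents",
                                        "continuous_weights",
                                        "instance_links",
                                        "semantic_distance",
                                        "sparse_class"),
                               n_per_class = 3L) {
  name <- match.arg(name)
  n <- as.integer(n_per_class)
  if (n < 2L) stop("n_per_class must be at least 2")
  inst_ids <- function(cl, k) sprintf("i_%s_%d", cl, seq_len(k))
  siblings <- ontology_graph(
    c("C1", "C2", "C3", "C4"),
    parents = list(C2 = "C1", C3 = "C1", C4 = "C1"))
  sc <- switch(
    name,
    multiple_annotation = {
      # shared instance splits its mass between C2 and C3
      shared <- "i_shared_1"
      ids <- c(shared, inst_ids("C2", n - 1L), inst_ids("C3", n - 1L),
               inst_ids("C4", n))
      types <- c(list(c("C2", "C3")),
                 rep(list("C2"), n - 1L), rep(list("C3"), n - 1L),
                 rep(list("C4"), n))
      list(graph = siblings,
           ext = ontology_extension(ids, stats::setNames(types, ids),
                                    graph = siblings),
           expected = list(equal = list(c("C2", "C3")),
                           greater = list(c("C4", "C2"), c("C4", "C3"))))
    },
    multiple_parents = {
      # C4 is an exclusive child of C2; C5 is shared by C3 and C6
      g <- ontology_graph(
        c("C1", "C2", "C3", "C4", "C5", "C6"),
        parents = list(C2 = "C1", C3 = "C1", C6 = "C1",
                       C4 = "C2", C5 = c("C3", "C6")))
      ids <- c(inst_ids("C4", n), inst_ids("C5", n))
      types <- c(rep(list("C4"), n), rep(list("C5"), n))
      list(graph = g,
           ext = ontology_extension(ids, stats::setNames(types, ids),
                                    graph = g),
           expected = list(equal = list(c("C3", "C6")),
                           greater = list(c("C2", "C3"))))
    },
    continuous_weights = {
      ids <- c(inst_ids("C2", n), inst_ids("C3", n), inst_ids("C4", n))
      types <- c(rep(list("C2"), n), rep(list("C3"), n),
                 rep(list("C4"), n))
      w <- stats::setNames(rep(c(0.5, 0.9, 0.1), each = n), ids)
      list(graph = siblings,
           ext = ontology_extension(ids, stats::setNames(types, ids),
                                    weights = w, graph = siblings),
           expected = list(greater = list(c("C3", "C2"), c("C2", "C4"))))
    },
    instance_links = {
      ids <- c(inst_ids("C2", n), inst_ids("C3", n), inst_ids("C4", n))
      types <- c(rep(list("C2"), n), rep(list("C3"), n),
                 rep(list("C4"), n))
      rels <- stats::setNames(vector("list", length(ids)), ids)
      for (j in seq_len(n)) {
        # C3 -> C4 one-way links; C2 instances linked in a balanced cycle
        rels[[sprintf("i_C3_%d", j)]] <- sprintf("i_C4_%d", j)
        rels[[sprintf("i_C2_%d", j)]] <-
          sprintf("i_C2_%d", j %% n + 1L)
      }
      list(graph = siblings,
           ext = ontology_extension(ids, stats::setNames(types, ids),
                                    rels = rels, graph = siblings),
           expected = list(greater = list(c("C4", "C2"), c("C2", "C3"))))
    },
    semantic_distance = {
      g <- ontology_graph(c("C1", "C2"), parents = list(C2 = "C1"))
      ids <- inst_ids("C2", n)
      list(graph = g,
           ext = ontology_extension(
             ids, stats::setNames(rep(list("C2"), n), ids), graph = g),
           expected = list(greater = list(c("C2", "C1"))))
    },
    sparse_class = {
      ids <- c(inst_ids("C2", n), inst_ids("C3", n))
      types <- c(rep(list("C2"), n), rep(list("C3"), n))
      list(graph = siblings,
           ext = ontology_extension(ids, stats::setNames(types, ids),
                                    graph = siblings),
           expected = list(positive = "C4"))
    })
  c(list(name = name), sc)
}

#' Random ontology-plus-extension fixture
#'
#' Generates a connected rooted DAG by topological parent sampling (class
#' `k` draws 1 to `max_parents` parents among classes `1..k-1`, so the
#' first class is the unique root), annotates each instance to one to
#' three uniformly chosen classes, and assigns weights. Uses the current
#' R random number generator state; seed before calling for
#' reproducibility.
#'
#' @param n_classes number of classes (>= 1).
#' @param n_instances number of instances (>= 0).
#' @param max_parents maximum direct parents per class.
#' @param weights `"uniform"` for weights drawn uniformly from `[0, 1]`,
#'   `"one"` for unit weights.
#' @return List with `graph` and `ext`.
#' @export
random_fixture <- function(n_classes, n_instances, max_parents = 2L,
                           weights = c("uniform", "one")) {
  weights <- match.arg(weights)
  if (n_classes < 1L) stop("need at least one class")
  cls <- sprintf("C%04d", seq_len(n_classes))
  parents <- list()
  if (n_classes > 1L) {
    for (k in 2:n_classes) {
      np <- sample.int(min(max_parents, k - 1L), 1L)
      parents[[cls[k]]] <- cls[sample.int(k - 1L, np)]
    }
  }
  graph <- ontology_graph(cls, parents)
  if (n_instances == 0L) {
    return(list(graph = graph,
                ext = ontology_extension(character(0), types = list())))
  }
  ids <- sprintf("g%05d", seq_len(n_instances))
  types <- stats::setNames(lapply(ids, function(i) {
    nt <- sample.int(min(3L, n_classes), 1L)
    cls[sample.int(n_classes, nt)]
  }), ids)
  w <- stats::setNames(
    if (weights == "uniform") stats::runif(n_instances) else
      rep(1, n_instances), ids)
  list(graph = graph,
       ext = ontology_extension(ids, types, weights = w, graph = graph))
}
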