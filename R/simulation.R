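#' Categories eligible to be planted as active
#'
#' Filters classes by their number of *direct* annotations (not
#' materialized ones): filtering on direct annotations preserves the
#' share of leaf categories and yields planted sets that better reflect a
#' generative model of activation.
#'
#' @param graph an `mcoa_ontology`.
#' @param ext an `mcoa_extension`.
#' @param min_direct minimum number of direct annotations (default 5).
#' @param index optional precomputed `mcoa_annotation_index`.
#' @return Character vector of eligible class identifiers.
#' @export
eligible_categories <- function(graph, ext, min_direct = 5L, index = NULL) {
  if (is.null(index)) index <- build_annotation_index(graph, ext)
  out <- index$classes[lengths(index$direct) >= min_direct]
  if (length(out) == 0L) {
    stop("no category has at least ", min_direct, " direct annotations")
  }
  out
}

#' Sample an antichain of active categories
#'
#' Draws `k` eligible categories uniformly, sequentially and without
#' replacement, rejecting any draw that is an ancestor or descendant of a
#' category already chosen (active sets must be hierarchically
#' unrelated). Uses the current R random number generator state.
#'
#' @param eligible eligible class identifiers.
#' @param k number of categories to plant.
#' @param graph an `mcoa_ontology`.
#' @param max_restarts restart budget before giving up.
#' @return Character vector of `k` class identifiers.
#' @export
sample_active_categories <- function(eligible, k, graph,
                                     max_restarts = 100L) {
  anc <- ancestor_table(graph)
  related <- function(a, b) a %in% anc[[b]] || b %in% anc[[a]]
  for (attempt in seq_len(max_restarts)) {
    chosen <- character(0)
    pool <- eligible
    ok <- TRUE
    for (j in seq_len(k)) {
      pool <- pool[!vapply(pool, function(x)
        any(vapply(chosen, related, TRUE, b = x)), TRUE)]
      if (length(pool) == 0L) { ok <- FALSE; break }
      pick <- pool[sample.int(length(pool), 1L)]
      chosen <- c(chosen, pick)
      pool <- setdiff(pool, pick)
    }
    if (ok) return(chosen)
  }
  stop("could not sample ", k, " hierarchically unrelated categories ",
       "from the eligible set")
}

#' Generate a noisy activated gene list from planted categories
#'
#' Every instance associated with a planted category (by materialized
#' annotation) is activated with probability `p`; every other instance is
#' activated with probability `q`. Draws are independent and use the
#' current R random number generator state.
#'
#' @param graph an `mcoa_ontology`.
#' @param ext an `mcoa_extension` (the reference population).
#' @param truth planted active class identifiers.
#' @param p true-positive activation rate (`1 - p` is the false-negative
#'   rate).
#' @param q false-positive activation rate.
#' @param index optional precomputed `mcoa_annotation_index`.
#' @return List with `truth`, `gene_list` (activated instance
#'   identifiers) and `associated` (instances covered by the truth set).
#' @export
generate_gene_list <- function(graph, ext, truth, p, q, index = NULL) {
  if (p < 0 || p > 1 || q < 0 || q > 1) stop("rates must lie in [0, 1]")
  if (is.null(index)) index <- build_annotation_index(graph, ext)
  associated <- unique(unlist(index$materialized[truth], use.names = FALSE))
  is_assoc <- ext$instances %in% associated
  prob <- ifelse(is_assoc, p, q)
  on <- stats::runif(length(prob)) < prob
  list(truth = truth, gene_list = ext$instances[on],
       associated = ext$instances[is_assoc])
}

#' Precision/recall and average precision of a category ranking
#'
#' Scores a best-first category ranking against the planted truth set.
#' In `"significant_only"` mode the ranking is first reduced to the
#' entries flagged significant (corrected p-value below the threshold),
#' mirroring how a user would read the results. Average precision is the
#' un-interpolated sum of precision times recall increment over the ranks
#' where recall increases; an empty prediction set scores 0.
#'
#' @param ranked character vector of class identifiers, best first.
#' @param truth character vector of planted classes (non-empty).
#' @param mode `"rank_only"` or `"significant_only"`.
#' @param significant logical vector parallel to `ranked` (required in
#'   `"significant_only"` mode).
#' @return List with `points` (data frame of recall, precision at each
#'   hit), `average_precision` and `mode`.
#' @export
precision_recall <- function(ranked, truth,
                             mode = c("rank_only", "significant_only"),
                             significant = NULL) {
  mode <- match.arg(mode)
  if (length(truth) == 0L) stop("truth set must be non-empty")
  if (mode == "significant_only") {
    if (is.null(significant) || length(significant) != length(ranked)) {
      stop("significant_only mode requires a significance flag per rank")
    }
    ranked <- ranked[significant]
  }
  if (length(ranked) == 0L) {
    return(list(points = data.frame(recall = numeric(0),
                                    precision = numeric(0)),
                average_precision = 0, mode = mode))
  }
  hit <- ranked %in% truth
  cum_hits <- cumsum(hit)
  prec <- cum_hits / seq_along(ranked)
  rec <- cum_hits / length(truth)
  ap <- sum(prec[hit]) / length(truth)
  list(points = data.frame(recall = rec[hit], precision = prec[hit]),
       average_precision = ap, mode = mode)
}

# best-first ranking + significance flags from an mcoa_enrich object;
# ranking is by raw p-value with identifier tie-break
ranking_of <- function(fit, sigma) {
  tab <- fit$table
  if (nrow(tab) == 0L) {
    return(list(ranked = character(0), significant = logical(0)))
  }
  ord <- order(tab$pvalue, tab$class_id)
  list(ranked = tab$class_id[ord],
       significant = tab$pvalue_bonferroni[ord] < sigma)
}

#' Simulation benchmark of enrichment methods
#'
#' For each replicate, plants a random antichain of active categories,
#' generates a noisy activated gene list (rates `q` and `fn_rate`), runs
#' each requested enrichment method against the full reference
#' population, and scores the resulting category ranking by average
#' precision — over the whole ranking and, separately, over only the
#' significantly enriched categories. Each replicate derives its own RNG
#' stream from `(seed, replicate)` so runs are reproducible and
#' replicates independently repeatable.
#'
#' @param graph an `mcoa_ontology`.
#' @param ext the reference `mcoa_extension` (all annotated genes).
#' @param methods subset of `c("mcoa", "gengo", "hyper")`.
#' @param n_replicates number of simulated gene lists.
#' @param seed integer master seed.
#' @param n_active maximum number of planted categories; per replicate the
#'   count is drawn uniformly from `1:n_active` (or fixed when
#'   `fixed_size` is `TRUE`).
#' @param q false-positive activation rate.
#' @param fn_rate false-negative rate (`1 - p`).
#' @param min_direct eligibility threshold on direct annotations.
#' @param sigma corrected p-value threshold for the significant-only
#'   scoring mode.
#' @param beta regularization weight for the `"mcoa"` method.
#' @param alpha,omega Markov chain parameters.
#' @param fixed_size plant exactly `n_active` categories per replicate.
#' @param sigma_modes scoring modes to report.
#' @return Data frame with columns `replicate`, `method`, `mode`,
#'   `truth_ids` (comma-separated), `ap`.
#' @export
run_benchmark <- function(graph, ext, methods = c("mcoa", "hyper"),
                          n_replicates = 50L, seed = 1L, n_active = 5L,
                          q = 0.1, fn_rate = 0.25, min_direct = 5L,
                          sigma = 0.01, beta = 0.5, alpha = 0.15,
                          omega = 0.01, fixed_size = FALSE,
                          sigma_modes = c("rank_only",
                                          "significant_only")) {
  methods <- match.arg(methods, c("mcoa", "gengo", "hyper"),
                       several.ok = TRUE)
  index <- build_annotation_index(graph, ext)
  eligible <- eligible_categories(graph, ext, min_direct, index = index)
  ssp_ref <- mcoa(graph, ext, alpha = alpha, omega = omega)$ssp
  p <- 1 - fn_rate
  rows <- list()
  for (r in seq_len(n_replicates)) {
    set.seed((as.integer(seed) + r * 10007L) %% .Machine$integer.max)
    k <- if (fixed_size) n_active else sample.int(n_active, 1L)
    truth <- sample_active_categories(eligible, k, graph)
    sim <- generate_gene_list(graph, ext, truth, p = p, q = q,
                              index = index)
    fits <- list()
    if (length(sim$gene_list) > 0L) {
      target <- subset_extension(ext, sim$gene_list)
      for (m in methods) {
        fits[[m]] <- if (m == "hyper") {
          hyper_enrich(graph, ext, target)
        } else {
          mcoa_enrich(graph, ext, target, alpha = alpha, omega = omega,
                      p = p, q = q, beta = beta,
                      mode = if (m == "gengo") "gengo" else "mcoa",
                      ssp_ref = ssp_ref, index = index)
        }
      }
    }
    for (m in methods) {
      rk <- if (is.null(fits[[m]])) {
        list(ranked = character(0), significant = logical(0))
      } else ranking_of(fits[[m]], sigma)
      for (mode in sigma_modes) {
        pr <- precision_recall(rk$ranked, truth, mode = mode,
                               significant = rk$significant)
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, method = m, mode = mode,
          truth_ids = paste(sort(truth), collapse = ","),
          ap = pr$average_precision, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Annotation-filter statistics
#'
#' Summarizes how filtering the annotated categories (no filter, at least
#' 5 materialized annotations, at least 5 direct annotations) changes the
#' number of categories kept, the share of leaf categories among them,
#' and their distribution over hierarchy levels (longest path to a root).
#' Filtering on total annotations disproportionately removes leaves;
#' filtering on direct annotations keeps the leaf share nearly constant.
#'
#' @param graph an `mcoa_ontology`.
#' @param ext an `mcoa_extension`.
#' @param min_annotations filter threshold (default 5).
#' @return List with `summary` (data frame: regime, n_classes, n_leaves,
#'   leaf_proportion) and `levels` (data frame of per-level class counts
#'   per regime).
#' @export
annotation_filter_stats <- function(graph, ext, min_annotations = 5L) {
  index <- build_annotation_index(graph, ext)
  lv <- class_levels(graph)
  lf <- leaves(graph)
  regimes <- list(
    no_filter = index$classes[lengths(index$materialized) >= 1L],
    min_total = index$classes[lengths(index$materialized) >=
                                min_annotations],
    min_direct = index$classes[lengths(index$direct) >= min_annotations])
  summary <- do.call(rbind, lapply(names(regimes), function(r) {
    cls <- regimes[[r]]
    nl <- length(intersect(cls, lf))
    data.frame(regime = r, n_classes = length(cls), n_leaves = nl,
               leaf_proportion = if (length(cls) > 0L)
                 nl / length(cls) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  levels <- do.call(rbind, lapply(names(regimes), function(r) {
    cls <- regimes[[r]]
    if (length(cls) == 0L) return(NULL)
    tab <- table(lv[cls])
    data.frame(regime = r, level = as.integer(names(tab)),
               n_classes = as.integer(tab), stringsAsFactors = FALSE)
  }))
  list(summary = summary, levels = levels)
}
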