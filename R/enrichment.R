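#' Generative-model objective counts
#'
#' Counts the four quantities entering the gene-activation log-likelihood
#' for an active class set `C`: `A_g`, the active instances with at least
#' one materialized annotation to a class in `C`; `A_n`, the remaining
#' active instances; and the annotations of inactive instances split into
#' those to classes in `C` (`S_g`) and those outside `C` (`S_n`).
#'
#' With `count_mode = "pairs"` (the default) `S_g`/`S_n` count materialized
#' (instance, class) annotation pairs; with `"genes"` they count inactive
#' instances covered / not covered by `C` (the per-gene convention of the
#' original greedy maximum-likelihood formulation).
#'
#' @param C character vector of active classes.
#' @param active character vector of active instance identifiers.
#' @param index an `mcoa_annotation_index` built on the reference dataset.
#' @param count_mode `"pairs"` or `"genes"`.
#' @return List with integer elements `A_g`, `A_n`, `S_g`, `S_n`.
#' @export
objective_counts <- function(C, active, index,
                             count_mode = c("pairs", "genes")) {
  count_mode <- match.arg(count_mode)
  stopifnot(inherits(index, "mcoa_annotation_index"))
  C <- unique(as.character(C))
  unknown <- setdiff(C, index$classes)
  if (length(unknown) > 0L) {
    stop("unknown class(es) in active set: ", paste(unknown, collapse = ", "))
  }
  active <- intersect(index$instances, active)
  inactive <- setdiff(index$instances, active)
  covered <- unique(unlist(index$materialized[C], use.names = FALSE))
  A_g <- length(intersect(active, covered))
  A_n <- length(active) - A_g
  if (count_mode == "pairs") {
    S_g <- sum(vapply(index$materialized[C], function(m)
      length(setdiff(m, active)), 0L))
    total <- sum(vapply(index$materialized, function(m)
      length(setdiff(m, active)), 0L))
    S_n <- total - S_g
  } else {
    S_g <- length(intersect(inactive, covered))
    S_n <- length(inactive) - S_g
  }
  list(A_g = A_g, A_n = A_n, S_g = S_g, S_n = S_n)
}

# count * log(prob) with the 0 * log(0) = 0 convention; a positive count
# against a zero probability yields -Inf (sentinel, not an error)
ll_term <- function(count, prob) {
  if (count == 0L) 0 else count * log(prob)
}

# clamped variant used inside the greedy search so that degenerate rates
# (p = 1 or q = 0) still rank candidate improvements instead of
# collapsing every value to -Inf
ll_term_safe <- function(count, prob) {
  if (count == 0L) 0 else count * log(max(prob, 1e-300))
}

#' Modified generative-model objective function
#'
#' The log-likelihood of the observed active instance set under the gene
#' activation model (true-positive rate `p`, false-positive rate `q`) for
#' a candidate active class set `C`, plus a regularization term. In
#' `"mcoa"` mode the regularizer is
#' `beta * sum_{c in C} log(ssp_tar(c)^2 / ssp_ref(c))`, which penalizes
#' large and semantically general sets while preferring classes whose
#' steady-state probability rises in the target data; in `"gengo"` mode it
#' is the plain size penalty `-gamma * |C|`. Natural logarithms
#' throughout. Degenerate rate/count combinations return `-Inf`.
#'
#' @param C active class set.
#' @param active active instance identifiers.
#' @param index reference `mcoa_annotation_index`.
#' @param p true-positive rate in `(0, 1]`.
#' @param q false-positive rate in `[0, 1)`.
#' @param beta weight of the steady-state regularizer (mcoa mode).
#' @param mode `"mcoa"` or `"gengo"`.
#' @param gamma size-penalty constant (gengo mode).
#' @param ssp_tar,ssp_ref named steady-state class probability vectors
#'   (required in mcoa mode when `beta > 0` and `C` is non-empty).
#' @param count_mode see [objective_counts()].
#' @return The objective value (a single number, possibly `-Inf`).
#' @export
objective <- function(C, active, index, p, q, beta = 0.5,
                      mode = c("mcoa", "gengo"), gamma = 1,
                      ssp_tar = NULL, ssp_ref = NULL,
                      count_mode = c("pairs", "genes")) {
  mode <- match.arg(mode)
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
  if (q < 0 || q >= 1) stop("q must lie in [0, 1)")
  cnt <- objective_counts(C, active, index, count_mode = count_mode)
  L <- ll_term(cnt$A_g, p) + ll_term(cnt$A_n, q) +
    ll_term(cnt$S_g, 1 - p) + ll_term(cnt$S_n, 1 - q)
  C <- unique(as.character(C))
  if (length(C) > 0L) {
    if (mode == "mcoa") {
      if (beta > 0) {
        if (is.null(ssp_tar) || is.null(ssp_ref)) {
          stop("mcoa mode with beta > 0 requires ssp_tar and ssp_ref")
        }
        L <- L + beta * sum(log(ssp_tar[C]^2 / ssp_ref[C]))
      }
    } else {
      if (gamma <= 0) stop("gengo mode requires gamma > 0")
      L <- L - gamma * length(C)
    }
  }
  unname(L)
}

#' One-sided hypergeometric over-representation p-value
#'
#' Probability of drawing `k` or more annotated members in a sample of
#' size `n` from a population of `N` containing `K` annotated members.
#'
#' @param N population size.
#' @param K annotated members in the population.
#' @param n study-set size.
#' @param k annotated members in the study set.
#' @return P(X >= k), in `(0, 1]`.
#' @export
hypergeometric_pvalue <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(n, K)) {
    stop("inconsistent hypergeometric counts (N=", N, ", K=", K,
         ", n=", n, ", k=", k, ")")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' @param pvalues numeric vector of raw p-values.
#' @param m number of hypotheses (for the generative methods the size of
#'   the selected active set; for the baseline the number of classes
#'   tested).
#' @return `pmin(1, m * pvalues)`.
#' @export
bonferroni <- function(pvalues, m) {
  if (m < 1) stop("m must be at least 1")
  pmin(1, m * pvalues)
}

# per-candidate precomputation shared by greedy_search
candidate_stats <- function(candidates, active, index) {
  lapply(stats::setNames(candidates, candidates), function(cl) {
    m <- index$materialized[[cl]]
    act <- intersect(m, active)
    list(mat_active = act,
         mat_inactive = setdiff(m, active),
         n_inactive = length(m) - length(act),
         n_mat = length(m))
  })
}

#' Greedy maximum-likelihood search for the active class set
#'
#' Starting from the empty set, each iteration adds the candidate class
#' giving the largest objective improvement, stopping when no candidate
#' improves the objective by more than `epsilon` (or `max_set_size` is
#' reached). Ties are broken toward the candidate with fewer materialized
#' annotations, then lexicographically. When `estimate_pq` is set, `p` and
#' `q` are re-chosen each iteration from a grid to maximize the
#' likelihood of the current counts.
#'
#' @param candidates candidate classes.
#' @param active active instance identifiers.
#' @param index reference `mcoa_annotation_index`.
#' @inheritParams objective
#' @param max_set_size optional cap on the selected set size.
#' @param estimate_pq estimate `p`, `q` from the data on a grid.
#' @param p_grid,q_grid grids used when `estimate_pq` is `TRUE`.
#' @param epsilon minimal improvement counted as progress.
#' @return List with `active_set` (in order of addition), `trace`
#'   (data frame of step, class, objective value), and the fitted `p`,
#'   `q`.
#' @export
greedy_search <- function(candidates, active, index, p = 0.95, q = 0.05,
                          beta = 0.5, mode = c("mcoa", "gengo"), gamma = 1,
                          ssp_tar = NULL, ssp_ref = NULL,
                          count_mode = c("pairs", "genes"),
                          max_set_size = Inf, estimate_pq = FALSE,
                          p_grid = seq(0.5, 0.99, length.out = 10),
                          q_grid = seq(0.01, 0.5, length.out = 10),
                          epsilon = 1e-9) {
  mode <- match.arg(mode)
  count_mode <- match.arg(count_mode)
  active <- intersect(index$instances, active)
  candidates <- unique(as.character(candidates))
  stats_by_cand <- candidate_stats(candidates, active, index)
  # deterministic tie-break order: materialized count, then identifier
  ord <- order(vapply(stats_by_cand, `[[`, 0L, "n_mat"), candidates)
  candidates <- candidates[ord]
  stats_by_cand <- stats_by_cand[candidates]

  n_active <- length(active)
  n_inactive <- length(index$instances) - n_active
  total_inactive_pairs <- sum(vapply(index$materialized, function(m)
    length(setdiff(m, active)), 0L))
  cover_act <- stats::setNames(integer(n_active), active)
  cover_inact_ids <- character(0)   # inactive instances covered (genes mode)
  A_g <- 0L; S_g <- 0L
  reg_term <- function(cl) {
    if (mode == "gengo") return(-gamma)
    if (beta <= 0) return(0)
    if (is.null(ssp_tar) || is.null(ssp_ref)) {
      stop("mcoa mode with beta > 0 requires ssp_tar and ssp_ref")
    }
    beta * log(ssp_tar[[cl]]^2 / ssp_ref[[cl]])
  }
  counts_L <- function(A_g, S_g, p, q) {
    A_n <- n_active - A_g
    S_n <- if (count_mode == "pairs") total_inactive_pairs - S_g else
      n_inactive - S_g
    ll_term_safe(A_g, p) + ll_term_safe(A_n, q) + ll_term_safe(S_g, 1 - p) +
      ll_term_safe(S_n, 1 - q)
  }
  best_pq <- function(A_g, S_g) {
    # p and q enter disjoint terms, so optimize each on its grid
    A_n <- n_active - A_g
    S_n <- if (count_mode == "pairs") total_inactive_pairs - S_g else
      n_inactive - S_g
    p_best <- p_grid[which.max(vapply(p_grid, function(pp)
      ll_term_safe(A_g, pp) + ll_term_safe(S_g, 1 - pp), 0))]
    q_best <- q_grid[which.max(vapply(q_grid, function(qq)
      ll_term_safe(A_n, qq) + ll_term_safe(S_n, 1 - qq), 0))]
    c(p = p_best, q = q_best)
  }

  selected <- character(0)
  reg_total <- 0
  trace <- list()
  repeat {
    if (length(selected) >= max_set_size) break
    pool <- setdiff(candidates, selected)
    if (length(pool) == 0L) break
    L_cur <- counts_L(A_g, S_g, p, q) + reg_total
    best <- NULL
    for (cl in pool) {
      st <- stats_by_cand[[cl]]
      dA <- sum(cover_act[st$mat_active] == 0L)
      dS <- if (count_mode == "pairs") st$n_inactive else
        length(setdiff(st$mat_inactive, cover_inact_ids))
      A_g2 <- A_g + dA; S_g2 <- S_g + dS
      if (estimate_pq) {
        pq <- best_pq(A_g2, S_g2)
        L_new <- counts_L(A_g2, S_g2, pq["p"], pq["q"]) + reg_total +
          reg_term(cl)
      } else {
        pq <- c(p = p, q = q)
        L_new <- counts_L(A_g2, S_g2, p, q) + reg_total + reg_term(cl)
      }
      if (is.null(best) || L_new > best$L) {
        best <- list(cl = cl, L = L_new, A_g = A_g2, S_g = S_g2,
                     pq = pq)
      }
    }
    if (!is.finite(best$L) || best$L - L_cur <= epsilon) break
    selected <- c(selected, best$cl)
    reg_total <- reg_total + reg_term(best$cl)
    A_g <- best$A_g; S_g <- best$S_g
    st <- stats_by_cand[[best$cl]]
    cover_act[st$mat_active] <- cover_act[st$mat_active] + 1L
    cover_inact_ids <- union(cover_inact_ids, st$mat_inactive)
    if (estimate_pq) {
      p <- unname(best$pq["p"]); q <- unname(best$pq["q"])
    }
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(selected), class_id = best$cl, objective = best$L,
      stringsAsFactors = FALSE)
  }
  list(active_set = selected,
       trace = if (length(trace) > 0L) do.call(rbind, trace) else
         data.frame(step = integer(0), class_id = character(0),
                    objective = numeric(0)),
       p = p, q = q)
}

# shared post-processing: per-class contingency table and p-values
enrich_table <- function(classes, index, target_ids, m, graph,
                         ssp_ref = NULL, ssp_tar = NULL) {
  if (length(classes) == 0L) {
    return(data.frame(class_id = character(0), label = character(0),
                      n_ref = integer(0), n_target = integer(0),
                      ssp_ref = numeric(0), ssp_tar = numeric(0),
                      pvalue = numeric(0),
                      pvalue_bonferroni = numeric(0),
                      stringsAsFactors = FALSE))
  }
  N <- length(index$instances)
  n <- length(target_ids)
  K <- vapply(index$materialized[classes], length, 0L)
  k <- vapply(index$materialized[classes], function(mm)
    length(intersect(mm, target_ids)), 0L)
  pv <- mapply(hypergeometric_pvalue, N, K, n, k)
  lab <- if (!is.null(graph$labels)) {
    unname(ifelse(classes %in% names(graph$labels),
                  graph$labels[classes], NA_character_))
  } else NA_character_
  data.frame(class_id = classes, label = lab,
             n_ref = as.integer(K), n_target = as.integer(k),
             ssp_ref = if (is.null(ssp_ref)) NA_real_ else
               as.numeric(ssp_ref[classes]),
             ssp_tar = if (is.null(ssp_tar)) NA_real_ else
               as.numeric(ssp_tar[classes]),
             pvalue = as.numeric(pv),
             pvalue_bonferroni = as.numeric(bonferroni(pv, m)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Steady-state-regularized generative enrichment analysis
#'
#' The full enrichment pipeline: (1) fit the Markov chain model on the
#' reference dataset and on the target dataset to obtain steady-state
#' class probabilities for both; (2) greedily maximize the generative
#' objective over classes with at least one materialized target
#' annotation; (3) compute hypergeometric p-values for the selected set,
#' Bonferroni-corrected over the size of that set only.
#'
#' @param graph an `mcoa_ontology`.
#' @param reference_ext reference (background) `mcoa_extension`.
#' @param target_ext target `mcoa_extension` (e.g. the differentially
#'   expressed genes); its instances should be a subset of the reference
#'   instances, and may carry continuous weights.
#' @param alpha,omega Markov chain parameters, see [mcoa()].
#' @param ssp_ref optional precomputed reference steady-state class
#'   probabilities (reused across many targets sharing one reference).
#' @param index optional precomputed reference `mcoa_annotation_index`.
#' @inheritParams greedy_search
#' @return An object of class `"mcoa_enrich"`: `method`, `active_set`,
#'   `trace`, fitted `p`, `q`, and a `table` data frame (one row per
#'   selected class, in order of addition, with `selected_rank`).
#' @examples
#' g <- ontology_graph(c("C1", "C2", "C3"),
#'                     parents = list(C2 = "C1", C3 = "C1"))
#' ref <- ontology_extension(paste0("g", 1:6),
#'   types = stats::setNames(as.list(rep(c("C2", "C3"), each = 3)),
#'                           paste0("g", 1:6)))
#' tar <- subset_extension(ref, c("g1", "g2", "g3"))
#' fit <- mcoa_enrich(g, ref, tar, p = 0.95, q = 0.05)
#' fit$active_set
#' @export
mcoa_enrich <- function(graph, reference_ext, target_ext,
                        alpha = 0.15, omega = 0.01, p = 0.95, q = 0.05,
                        beta = 0.5, mode = c("mcoa", "gengo"), gamma = 1,
                        count_mode = c("pairs", "genes"),
                        max_set_size = Inf, estimate_pq = FALSE,
                        ssp_ref = NULL, index = NULL, ...) {
  mode <- match.arg(mode)
  count_mode <- match.arg(count_mode)
  if (length(target_ext$instances) == 0L) stop("empty target dataset")
  stray <- setdiff(target_ext$instances, reference_ext$instances)
  if (length(stray) > 0L) {
    warning(length(stray),
            " target instance(s) absent from the reference dataset")
  }
  if (is.null(ssp_ref)) {
    ssp_ref <- mcoa(graph, reference_ext, alpha = alpha, omega = omega)$ssp
  }
  ssp_tar <- mcoa(graph, target_ext, alpha = alpha, omega = omega)$ssp
  if (is.null(index)) {
    index <- build_annotation_index(graph, reference_ext)
  }
  target_ids <- target_ext$instances
  candidates <- index$classes[vapply(index$materialized, function(m)
    length(intersect(m, target_ids)) > 0L, TRUE)]
  fit <- greedy_search(candidates, target_ids, index, p = p, q = q,
                       beta = beta, mode = mode, gamma = gamma,
                       ssp_tar = ssp_tar, ssp_ref = ssp_ref,
                       count_mode = count_mode,
                       max_set_size = max_set_size,
                       estimate_pq = estimate_pq, ...)
  m <- max(length(fit$active_set), 1L)
  tab <- enrich_table(fit$active_set, index, target_ids, m, graph,
                      ssp_ref = ssp_ref, ssp_tar = ssp_tar)
  if (nrow(tab) > 0L) tab$selected_rank <- seq_len(nrow(tab))
  else tab$selected_rank <- integer(0)
  structure(list(method = mode, active_set = fit$active_set,
                 trace = fit$trace, p = fit$p, q = fit$q, beta = beta,
                 table = tab, n_reference = length(index$instances),
                 n_target = length(target_ids)),
            class = "mcoa_enrich")
}

#' Baseline per-class hypergeometric enrichment
#'
#' The standard one-class-at-a-time over-representation test: every class
#' with at least one materialized target annotation is tested, with
#' Bonferroni correction over all tested classes, ranked by raw p-value.
#'
#' @inheritParams mcoa_enrich
#' @return An `"mcoa_enrich"` object with `method = "hyper"`.
#' @export
hyper_enrich <- function(graph, reference_ext, target_ext) {
  if (length(target_ext$instances) == 0L) stop("empty target dataset")
  index <- build_annotation_index(graph, reference_ext)
  target_ids <- target_ext$instances
  tested <- index$classes[vapply(index$materialized, function(m)
    length(intersect(m, target_ids)) > 0L, TRUE)]
  tab <- enrich_table(tested, index, target_ids, length(tested), graph)
  tab <- tab[order(tab$pvalue, tab$class_id), , drop = FALSE]
  tab$selected_rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(method = "hyper", active_set = character(0),
                 trace = NULL, p = NA_real_, q = NA_real_, beta = NA_real_,
                 table = tab, n_reference = length(index$instances),
                 n_target = length(target_ids)),
            class = "mcoa_enrich")
}

#' @export
print.mcoa_enrich <- function(x, ...) {
  cat("Enrichment analysis (", x$method, " method): ",
      x$n_target, " target / ", x$n_reference, " reference instances\n",
      sep = "")
  if (x$method == "hyper") {
    cat(nrow(x$table), "classes tested; top of ranking:\n")
    print(utils::head(x$table[, c("class_id", "n_ref", "n_target",
                                  "pvalue", "pvalue_bonferroni")], 5L),
          row.names = FALSE, digits = 4)
  } else {
    cat(length(x$active_set), "classes selected (p =", x$p, ", q =", x$q,
        ")\n")
    if (nrow(x$table) > 0L) {
      print(x$table[, c("class_id", "n_ref", "n_target", "pvalue",
                        "pvalue_bonferroni", "selected_rank")],
            row.names = FALSE, digits = 4)
    }
  }
  invisible(x)
}

#' @export
as.data.frame.mcoa_enrich <- function(x, ...) x$table

#' @export
summary.mcoa_enrich <- function(object, ...) {
  print(object)
  invisible(object)
}
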