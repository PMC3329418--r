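# Independent oracles, written as direct transcriptions of the model
# definitions with plain loops; deliberately naive and kept separate from
# the package's sparse/incremental code paths.

# dense transition matrix, elementwise from the definition of the
# adjusted chain (class rows -> parents, instance rows -> types + links,
# jump mass alpha with class share omega; dangling root rows = jump)
naive_dense_matrix <- function(graph, ext, alpha, omega) {
  classes <- sort(graph$classes)
  insts <- sort(ext$instances)
  states <- c(classes, insts)
  n <- length(states)
  wsum <- if (length(insts) == 0) 0 else sum(ext$weights[insts])
  omega_eff <- if (wsum <= 0) 1 else omega
  J <- numeric(n)
  for (j in seq_len(n)) {
    s <- states[j]
    J[j] <- if (s %in% classes) omega_eff / length(classes) else
      (1 - omega_eff) * ext$weights[[s]] / wsum
  }
  P <- matrix(0, n, n, dimnames = list(states, states))
  for (i in seq_len(n)) {
    si <- states[i]
    if (si %in% classes) {
      ps <- graph$parents[[si]]
      if (length(ps) == 0) {
        P[i, ] <- J
        next
      }
      for (j in seq_len(n)) {
        sj <- states[j]
        P[i, j] <- alpha * J[j] +
          if (sj %in% ps) (1 - alpha) / length(ps) else 0
      }
    } else {
      out <- c(ext$types[[si]], ext$rels[[si]])
      for (j in seq_len(n)) {
        sj <- states[j]
        P[i, j] <- alpha * J[j] +
          if (sj %in% out) (1 - alpha) / length(out) else 0
      }
    }
  }
  P
}

# hypergeometric upper tail by explicit summation of combination counts
enum_hyper_tail <- function(N, K, n, k) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# objective recomputed from scratch with set operations only
naive_objective <- function(C, active, index, p, q, beta = 0, gamma = NULL,
                            ssp_tar = NULL, ssp_ref = NULL) {
  inactive <- setdiff(index$instances, active)
  covered <- unique(unlist(index$materialized[C], use.names = FALSE))
  A_g <- sum(active %in% covered)
  A_n <- length(active) - A_g
  S_g <- 0L
  S_n <- 0L
  for (cl in index$classes) {
    pairs <- length(intersect(index$materialized[[cl]], inactive))
    if (cl %in% C) S_g <- S_g + pairs else S_n <- S_n + pairs
  }
  term <- function(cnt, pr) if (cnt == 0) 0 else cnt * log(pr)
  L <- term(A_g, p) + term(A_n, q) + term(S_g, 1 - p) + term(S_n, 1 - q)
  if (!is.null(gamma)) L <- L - gamma * length(C)
  if (beta > 0 && length(C) > 0) {
    L <- L + beta * sum(log(ssp_tar[C]^2 / ssp_ref[C]))
  }
  L
}

# exhaustive maximum over all candidate subsets up to a size cap
exhaustive_best_set <- function(candidates, active, index, p, q,
                                max_size = 3, beta = 0, gamma = NULL,
                                ssp_tar = NULL, ssp_ref = NULL) {
  best <- list(set = character(0),
               L = naive_objective(character(0), active, index, p, q,
                                   beta, gamma, ssp_tar, ssp_ref))
  for (sz in seq_len(min(max_size, length(candidates)))) {
    combos <- utils::combn(sort(candidates), sz, simplify = FALSE)
    for (C in combos) {
      L <- naive_objective(C, active, index, p, q, beta, gamma,
                           ssp_tar, ssp_ref)
      if (L > best$L + 1e-12) best <- list(set = C, L = L)
    }
  }
  best
}

# small shared fixtures -------------------------------------------------

chain_graph <- function() {
  ontology_graph(c("C1", "C2", "C3"),
                 parents = list(C2 = "C1", C3 = "C2"))
}

# root with three annotated children and disjoint gene blocks
two_branch_data <- function(n_per = 4) {
  g <- ontology_graph(c("R", "X", "Y", "Z"),
                      parents = list(X = "R", Y = "R", Z = "R"))
  ids <- c(sprintf("gx%d", seq_len(n_per)), sprintf("gy%d", seq_len(n_per)),
           sprintf("gz%d", seq_len(n_per)))
  types <- stats::setNames(
    c(rep(list("X"), n_per), rep(list("Y"), n_per), rep(list("Z"), n_per)),
    ids)
  list(graph = g, ext = ontology_extension(ids, types, graph = g))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
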