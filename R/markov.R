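#' Markov chain state space for an ontology and its extension
#'
#' Every ontology class and every data instance becomes one state. The
#' ordering is deterministic (classes sorted lexicographically, then
#' instances sorted lexicographically) so repeated runs index states
#' identically.
#'
#' @param graph an `mcoa_ontology`.
#' @param ext an `mcoa_extension`.
#' @return List with `class_states`, `instance_states`, `states` (their
#'   concatenation), `n_class`, `n` — class `"mcoa_state_space"`.
#' @export
build_state_space <- function(graph, ext) {
  cs <- sort(graph$classes)
  is <- sort(ext$instances)
  clash <- intersect(cs, is)
  if (length(clash) > 0L) {
    stop("identifier(s) used for both a class and an instance: ",
         paste(clash, collapse = ", "))
  }
  structure(list(class_states = cs, instance_states = is,
                 states = c(cs, is), n_class = length(cs),
                 n = length(cs) + length(is)),
            class = "mcoa_state_space")
}

# validate the two chain parameters
mcoa_params <- function(alpha, omega) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must be a single number in (0, 1]")
  }
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0 || omega > 1) {
    stop("omega must be a single number in [0, 1]")
  }
  list(alpha = alpha, omega = omega)
}

#' Random-jump distribution over states
#'
#' The jump vector J spreads the random-jump mass: a share `omega` is
#' divided uniformly over class states, and the remaining `1 - omega` is
#' divided over instance states in proportion to their weights. When there
#' are no instance states (or total instance weight is zero) the whole
#' jump mass goes to the classes, so J always remains a probability
#' vector.
#'
#' @param space an `mcoa_state_space`.
#' @param ext the companion `mcoa_extension`.
#' @param omega share of jump mass sent to class states, in `[0, 1]`.
#' @return Named numeric probability vector over all states.
#' @export
jump_distribution <- function(space, ext, omega) {
  wsum <- if (length(space$instance_states) == 0L) 0 else
    sum(ext$weights[space$instance_states])
  omega_eff <- if (wsum <= 0) 1 else omega
  j_class <- rep(omega_eff / space$n_class, space$n_class)
  j_inst <- if (length(space$instance_states) == 0L) numeric(0) else
    if (wsum <= 0) rep(0, length(space$instance_states)) else
      (1 - omega_eff) * ext$weights[space$instance_states] / wsum
  stats::setNames(c(j_class, j_inst), space$states)
}

#' Adjusted transition probability matrix
#'
#' Builds the row-stochastic transition matrix of the combined
#' class/instance chain. A class state moves to each of its direct parents
#' with probability `(1 - alpha) / #parents` and jumps with probability
#' `alpha` according to the jump distribution; an instance state spreads
#' `1 - alpha` uniformly over its direct class annotations and outgoing
#' instance links. A root class has no structural out-edges, so its whole
#' row is the jump distribution (the dangling-node convention), which
#' together with `alpha > 0` makes the chain ergodic.
#'
#' The matrix is stored as a sparse structural part plus the rank-one jump
#' component; `as.matrix()` realizes the dense values.
#'
#' @param graph an `mcoa_ontology`.
#' @param ext an `mcoa_extension`.
#' @param alpha random-jump probability in `(0, 1)` (PageRank damping
#'   `d = 1 - alpha`).
#' @param omega share of jump mass sent to class states.
#' @return An object of class `"mcoa_transition"` with elements `space`,
#'   `structural` (sparse row-stochastic part; zero rows for roots),
#'   `jump` (the vector J), `dangling` (logical per state), `alpha`,
#'   `omega`.
#' @export
build_transition_matrix <- function(graph, ext, alpha = 0.15, omega = 0.01) {
  params <- mcoa_params(alpha, omega)
  space <- build_state_space(graph, ext)
  jump <- jump_distribution(space, ext, params$omega)
  idx <- stats::setNames(seq_len(space$n), space$states)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (cl in space$class_states) {
    ps <- graph$parents[[cl]]
    if (length(ps) > 0L) {
      ii <- c(ii, rep(idx[cl], length(ps)))
      jj <- c(jj, idx[ps])
      xx <- c(xx, rep(1 / length(ps), length(ps)))
    }
  }
  for (i in space$instance_states) {
    targets <- c(ext$types[[i]], ext$rels[[i]])
    if (length(targets) == 0L) {
      stop("instance '", i, "' has no outgoing transitions")
    }
    ii <- c(ii, rep(idx[i], length(targets)))
    jj <- c(jj, idx[targets])
    xx <- c(xx, rep(1 / length(targets), length(targets)))
  }
  structural <- Matrix::sparseMatrix(
    i = ii, j = jj, x = xx, dims = c(space$n, space$n),
    dimnames = list(space$states, space$states))
  dangling <- stats::setNames(
    Matrix::rowSums(structural) == 0, space$states)
  structure(list(space = space, structural = structural, jump = jump,
                 dangling = dangling, alpha = params$alpha,
                 omega = params$omega),
            class = "mcoa_transition")
}

#' @export
print.mcoa_transition <- function(x, ...) {
  cat("Adjusted transition matrix:", x$space$n, "states (",
      x$space$n_class, "classes,",
      x$space$n - x$space$n_class, "instances ), alpha =", x$alpha,
      ", omega =", x$omega, "\n")
  invisible(x)
}

#' @export
as.matrix.mcoa_transition <- function(x, ...) {
  P <- (1 - x$alpha) * as.matrix(x$structural)
  jump_share <- ifelse(x$dangling, 1, x$alpha)
  P + outer(jump_share, x$jump)
}

#' Stationary distribution of the chain
#'
#' Computes the principal left eigenvector of the adjusted transition
#' matrix: the unique probability vector with `pi P = pi`. The default
#' solver is power iteration on the sparse-plus-rank-one form (each step
#' costs one sparse matrix-vector product); a dense eigen-decomposition
#' path is provided for small chains as a verification oracle.
#'
#' @param model an `mcoa_transition`.
#' @param method `"power"` (default) or `"dense"`.
#' @param tol L1 convergence tolerance on `pi P - pi`.
#' @param max_iter iteration cap for the power method.
#' @return Named probability vector over states, with attributes
#'   `iterations` and `residual` for the power method.
#' @export
stationary_distribution <- function(model, method = c("power", "dense"),
                                    tol = 1e-12, max_iter = 100000L) {
  method <- match.arg(method)
  if (method == "dense") {
    P <- as.matrix(model)
    e <- eigen(t(P))
    k <- which.min(abs(e$values - 1))
    v <- Re(e$vectors[, k])
    v <- v / sum(v)
    if (any(v < -1e-10)) stop("dense eigenvector has negative components")
    v[v < 0] <- 0
    return(stats::setNames(v / sum(v), model$space$states))
  }
  A <- model$structural
  jump <- model$jump
  d <- model$dangling
  alpha <- model$alpha
  pi_cur <- jump
  for (it in seq_len(max_iter)) {
    structural <- (1 - alpha) * as.numeric(Matrix::crossprod(A, pi_cur))
    jump_mass <- alpha * sum(pi_cur[!d]) + sum(pi_cur[d])
    pi_new <- structural + jump_mass * jump
    resid <- sum(abs(pi_new - pi_cur))
    pi_cur <- pi_new / sum(pi_new)
    if (resid < tol) {
      return(structure(stats::setNames(pi_cur, model$space$states),
                       iterations = it, residual = resid))
    }
  }
  stop("power iteration did not converge in ", max_iter,
       " iterations (final L1 residual ", format(resid), ")")
}

#' Adjusted steady-state class probability
#'
#' Restricts the stationary distribution to the class states and
#' renormalizes so the class probabilities sum to one.
#'
#' @param stationary stationary vector over all states.
#' @param space the `mcoa_state_space` used to build it.
#' @return Named numeric vector over classes summing to 1.
#' @export
class_ssp <- function(stationary, space) {
  v <- stationary[space$class_states]
  tot <- sum(v)
  if (tot <= 0) stop("class states carry no stationary mass")
  v / tot
}

#' Information rank
#'
#' The negative base-2 logarithm of the adjusted steady-state class
#' probability, in bits: lower values mean more important classes.
#'
#' @param ssp named numeric vector of steady-state class probabilities
#'   (all strictly positive).
#' @return Named numeric vector of information ranks.
#' @export
information_rank <- function(ssp) {
  if (any(ssp <= 0)) {
    stop("information rank undefined for non-positive steady-state ",
         "probability")
  }
  -log2(ssp)
}

#' Fit the Markov chain ontology model
#'
#' The main fitting function: maps the ontology and its annotated dataset
#' to a finite ergodic Markov chain, solves for its stationary
#' distribution, and derives per-class steady-state probabilities and
#' information ranks.
#'
#' @param graph an `mcoa_ontology`.
#' @param ext an `mcoa_extension` annotated with classes of `graph`.
#' @param alpha random-jump probability in `(0, 1)`; default 0.15.
#' @param omega share of jump mass sent (uniformly) to class states;
#'   default 0.01. The remaining mass goes to instances in proportion to
#'   their weights.
#' @param method stationary solver, `"power"` or `"dense"`.
#' @param tol,max_iter solver controls, see
#'   [stationary_distribution()].
#' @return An object of class `"mcoa"`: `stationary` (all states), `ssp`
#'   and `info_rank` (per class), the `model` (transition matrix), solver
#'   diagnostics, and the matched `call`.
#' @examples
#' g <- ontology_graph(c("C1", "C2"), parents = list(C2 = "C1"))
#' e <- ontology_extension(c("i1", "i2"),
#'                         types = list(i1 = "C2", i2 = "C2"))
#' fit <- mcoa(g, e)
#' coef(fit)
#' summary(fit)
#' @export
mcoa <- function(graph, ext, alpha = 0.15, omega = 0.01,
                 method = c("power", "dense"), tol = 1e-12,
                 max_iter = 100000L) {
  stopifnot(inherits(graph, "mcoa_ontology"), inherits(ext, "mcoa_extension"))
  model <- build_transition_matrix(graph, ext, alpha = alpha, omega = omega)
  stat <- stationary_distribution(model, method = match.arg(method),
                                  tol = tol, max_iter = max_iter)
  ssp <- class_ssp(stat, model$space)
  structure(list(stationary = stat, ssp = ssp,
                 info_rank = information_rank(ssp),
                 model = model, alpha = alpha, omega = omega,
                 iterations = attr(stat, "iterations"),
                 residual = attr(stat, "residual"),
                 call = match.call()),
            class = "mcoa")
}

#' @export
print.mcoa <- function(x, ...) {
  cat("Markov chain ontology analysis fit\n")
  cat("  states:", x$model$space$n, "(", x$model$space$n_class, "classes )",
      " alpha =", x$alpha, " omega =", x$omega, "\n")
  if (!is.null(x$iterations)) {
    cat("  power iteration:", x$iterations, "steps, L1 residual",
        format(x$residual, digits = 3), "\n")
  }
  top <- utils::head(sort(x$info_rank), 5L)
  cat("  lowest information ranks (bits):\n")
  print(round(top, 4))
  invisible(x)
}

#' @export
coef.mcoa <- function(object, type = c("info_rank", "ssp", "stationary"),
                      ...) {
  switch(match.arg(type),
         info_rank = object$info_rank,
         ssp = object$ssp,
         stationary = object$stationary)
}

#' @export
as.data.frame.mcoa <- function(x, ...) {
  cls <- names(x$ssp)
  data.frame(class_id = cls,
             stationary = as.numeric(x$stationary[cls]),
             ssp = as.numeric(x$ssp),
             info_rank = as.numeric(x$info_rank),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
summary.mcoa <- function(object, n = 10L, ...) {
  df <- as.data.frame(object)
  df <- df[order(df$info_rank), , drop = FALSE]
  out <- list(top = utils::head(df, n), n_class = nrow(df),
              alpha = object$alpha, omega = object$omega)
  class(out) <- "summary.mcoa"
  out
}

#' @export
print.summary.mcoa <- function(x, ...) {
  cat("MCOA fit over", x$n_class, "classes (alpha =", x$alpha,
      ", omega =", x$omega, ")\n")
  cat("Classes by increasing information rank:\n")
  print(x$top, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
plot.mcoa <- function(x, n = 20L, ...) {
  ir <- sort(x$info_rank)
  ir <- utils::head(ir, n)
  graphics::barplot(rev(ir), horiz = TRUE, las = 1,
                    xlab = "information rank (bits)",
                    main = "Lowest information ranks", ...)
  invisible(x)
}
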