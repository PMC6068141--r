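# Independent oracles used against the package's own code paths.

# Exhaustive vertex enumeration for  max obj'v  s.t.  S v = 0,
# lb <= v <= ub.  A vertex of the polytope has n - rank(S) variables at
# a bound; every such choice is enumerated, the remaining variables are
# solved from the steady-state system, and feasible candidates are
# scored.  Exponential, usable only on toy systems -- which is the point:
# it shares no code with the package's simplex.
oracle_fba <- function(model, state = NULL, tol = 1e-8) {
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  if (!is.null(state)) {
    idx <- match(state$reaction_id, model$reactions$id)
    lb[idx] <- state$LB
    ub[idx] <- state$UB
  }
  S <- model$S
  obj <- as.numeric(model$reactions$id == model$biomass_id)
  n <- ncol(S)
  r <- qr(S)$rank
  nfree <- n - r
  best <- -Inf
  feasible <- FALSE
  free_sets <- utils::combn(n, nfree, simplify = FALSE)
  for (J in free_sets) {
    K <- setdiff(seq_len(n), J)
    SK <- S[, K, drop = FALSE]
    if (qr(SK)$rank < r) next
    for (mask in 0:(2^nfree - 1)) {
      vJ <- ifelse(bitwAnd(mask, 2^(seq_len(nfree) - 1)) > 0,
                   ub[J], lb[J])
      rhs <- -S[, J, drop = FALSE] %*% vJ
      vK <- tryCatch(qr.solve(SK, rhs, tol = 1e-10),
                     error = function(e) NULL)
      if (is.null(vK)) next
      if (max(abs(SK %*% vK - rhs)) > tol) next
      v <- numeric(n)
      v[J] <- vJ
      v[K] <- vK
      if (any(v < lb - tol) || any(v > ub + tol)) next
      feasible <- TRUE
      best <- max(best, sum(obj * v))
    }
  }
  if (!feasible) return(list(status = "infeasible", objective = 0))
  list(status = "optimal", objective = best)
}

# Brute-force GPR evaluation, written as an explicit stack walk so it
# shares no structure with reaction_weight()'s recursion.
oracle_gpr <- function(tree, weights) {
  if (is.null(tree)) return(1)
  stack <- list(tree)
  post <- list()
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    post[[length(post) + 1L]] <- node
    if (node$kind != "gene")
      for (ch in node$children) stack[[length(stack) + 1L]] <- ch
  }
  values <- list()
  for (node in rev(post)) {
    key <- length(values) + 1L
    if (node$kind == "gene") {
      values[[key]] <- unname(weights[[node$gene]])
    } else {
      k <- length(node$children)
      args <- unlist(values[(key - k):(key - 1L)])
      values <- values[seq_len(key - 1L - k)]
      values[[length(values) + 1L]] <-
        if (node$kind == "and") min(args) else max(args)
    }
  }
  values[[1L]]
}

# Random GPR tree over the given gene pool.
random_gpr_tree <- function(genes, max_leaves = 15L) {
  n_leaves <- sample(seq_len(max_leaves), 1L)
  grow <- function(budget) {
    if (budget == 1L) return(list(kind = "gene",
                                  gene = sample(genes, 1L)))
    k <- sample(2:min(4L, budget), 1L)
    splits <- sort(sample(seq_len(budget - 1L), k - 1L))
    sizes <- diff(c(0L, splits, budget))
    kids <- lapply(sizes, grow)
    kind <- sample(c("and", "or"), 1L)
    # collapse same-kind children as the parser does
    flat <- list()
    for (ch in kids)
      if (identical(ch$kind, kind)) flat <- c(flat, ch$children)
      else flat <- c(flat, list(ch))
    if (length(flat) == 1L) flat[[1L]] else list(kind = kind,
                                                 children = flat)
  }
  grow(n_leaves)
}
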