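# Independent brute-force oracles: plain recursive Boolean evaluation and
# 2^n truth-table enumeration, kept free of the package's MOCUS/factoring
# code paths so they can stand as a cross-check.

# all 2^n assignments over the given event ids, as a logical matrix
enumerate_assignments <- function(ids) {
  M <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(ids)),
                             KEEP.OUT.ATTRS = FALSE))
  colnames(M) <- ids
  M
}

# direct recursive evaluation of the gate logic, vectorized over rows of M
oracle_eval <- function(tree, M) {
  rec <- function(id) {
    if (id %in% names(tree$events)) return(M[, id])
    g <- tree$gates[[id]]
    kids <- lapply(g$inputs, rec)
    if (g$kind == "AND") Reduce(`&`, kids) else Reduce(`|`, kids)
  }
  rec(tree$top)
}

# exact top probability by weighted truth-table enumeration
oracle_top_probability <- function(tree, selector = "average") {
  ids <- names(tree$events)
  p <- leaf_probabilities(tree, selector)[ids]
  M <- enumerate_assignments(ids)
  hit <- oracle_eval(tree, M)
  if (!any(hit)) return(0)
  w <- apply(M[hit, , drop = FALSE], 1, function(x)
    prod(ifelse(x, p, 1 - p)))
  sum(w)
}

# naive quadratic superset removal, independent of minimize_cut_sets
oracle_minimize <- function(sets) {
  sets <- unique(lapply(sets, function(s) sort(unique(s))))
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i != j && keep[i] && keep[j] &&
        length(sets[[j]]) < length(sets[[i]]) &&
        all(sets[[j]] %in% sets[[i]])) keep[i] <- FALSE
  }
  sets[keep]
}

# minimal cut sets by enumeration: minimal true points of the truth table
oracle_cut_sets <- function(tree) {
  ids <- names(tree$events)
  M <- enumerate_assignments(ids)
  hit <- oracle_eval(tree, M)
  sets <- lapply(which(hit), function(i) ids[M[i, ]])
  oracle_minimize(sets)
}

# canonical string form for set-of-sets comparison
canon_sets <- function(sets) sort(vapply(sets, function(s)
  paste(sort(s), collapse = "+"), character(1)))

collection_sets <- function(coll) lapply(coll$cut_sets, `[[`, "events")

# small-tree generator config used across property suites
small_config <- function(seed, n_events = NULL, repeat_rate = 0.3) {
  set.seed(seed * 7 + 1)
  if (is.null(n_events)) n_events <- sample(3:12, 1)
  n_gates <- sample.int(max(1, n_events %/% 3), 1)
  generator_config(n_events = n_events, n_gates = n_gates,
                   and_fraction = stats::runif(1, 0, 0.6),
                   max_fanin = 12, repeat_rate = repeat_rate,
                   sources_per_event = c(1, 3), seed = seed)
}
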