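# Internal helpers shared across modules.

# Union-find with path halving; ids are 1-based integers.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# Union by assignment; returns updated parent vector. Callers keep the vector.
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[ri] <- rj
  parent
}

# Resolve every element to its component root and relabel 1..k in first-seen order.
uf_components <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}

# Connected components of an interval set where touching closed intervals join.
# Returns an integer component label per interval. O(n log n) sweep.
interval_components <- function(start, end) {
  n <- length(start)
  if (n == 0L) return(integer(0))
  ord <- order(start, end)
  comp <- integer(n)
  cur <- 0L
  max_end <- -Inf
  for (k in seq_len(n)) {
    i <- ord[k]
    if (start[i] > max_end) cur <- cur + 1L
    comp[i] <- cur
    if (end[i] > max_end) max_end <- end[i]
  }
  comp
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopifnot_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required columns: %s", what,
                  paste(miss, collapse = ", ")))
  }
  invisible(df)
}
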