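# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)

check_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) stop_bad("%s must be TRUE or FALSE", what)
  x
}

check_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_bad("%s must be a single integer >= %d", what, min)
  as.integer(x)
}

check_number <- function(x, what, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop_bad("%s must be a single finite number in [%s, %s]", what, min, max)
  as.numeric(x)
}

# derive a reproducible sub-seed from a root seed; kept below 2^31 - 1
derive_seed <- function(seed, stage) {
  seed <- as.numeric(seed)
  (seed * 7919 + stage * 104729) %% 2147483647
}

# union-find with path compression; n elements, returns component labels 1..k
union_find <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}
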