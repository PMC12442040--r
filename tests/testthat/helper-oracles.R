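# Independent brute-force oracles used to cross-check the implementation.

# all-pairs step chaining: O(n^2) edge test + breadth-first components;
# returns component id per point (NA for singletons), labelled by the
# lowest member m/z so partitions can be compared across algorithms
oracle_chain_components <- function(mz, step_mass, tol_ppm, k_max) {
  n <- length(mz)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- abs(mz[i] - mz[j])
      heavier <- max(mz[i], mz[j])
      for (k in seq_len(k_max)) {
        if (abs(d - k * step_mass) / heavier * 1e6 <= tol_ppm) {
          adj[[i]] <- c(adj[[i]], j)
          break
        }
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    queue <- s; members <- integer(0)
    visited <- rep(FALSE, n); visited[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      members <- c(members, v)
      for (w in adj[[v]]) {
        if (!visited[w]) { visited[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    if (length(members) >= 2) {
      cid <- cid + 1L
      comp[members] <- cid
    } else {
      comp[members] <- NA_integer_
    }
  }
  comp
}

# normalize a component labelling to a canonical partition representation
partition_of <- function(ids) {
  split(seq_along(ids), ifelse(is.na(ids), paste0("s", seq_along(ids)),
                               paste0("c", ids))) |>
    lapply(sort) |>
    (\(x) x[order(vapply(x, `[`, integer(1), 1))])() |>
    unname()
}

# hand-rolled mass summation over the atomic mass table, independent of
# monoisotopic_mass()'s parsing path
oracle_mass_sum <- function(counts) {
  m <- atomic_masses()
  s <- 0
  for (el in names(counts)) s <- s + m[[el]] * counts[[el]]
  s
}
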