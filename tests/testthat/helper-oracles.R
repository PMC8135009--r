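# Independent oracles used across the suite. Each recomputes a quantity by
# a route different from the package implementation (explicit summation,
# exhaustive enumeration, brute-force graph search, position-wise scans).

# binomial upper tail P(X >= k) by explicit log-space term summation
oracle_binom_tail <- function(k, N, p) {
  if (k == 0) return(1)
  i <- k:N
  sum(exp(lchoose(N, i) + i * log(p) + (N - i) * log1p(-p)))
}

# two-tailed Fisher p by enumeration with factorial table probabilities
oracle_fisher_2tail <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  n <- a + b + c + d
  if (n == 0) return(1)
  tab_p <- function(x) {
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
          lfactorial(n) - lfactorial(x) - lfactorial(r1 - x) -
          lfactorial(c1 - x) - lfactorial(r2 - c1 + x))
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  ps <- vapply(xs, tab_p, numeric(1))
  p_obs <- tab_p(a)
  min(1, sum(ps[ps <= p_obs * (1 + 1e-7)]))
}

# upper-tail hypergeometric by direct summation of choose() products
oracle_hyper_upper <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# exhaustive QGRS candidate enumeration by substring comparison
oracle_qgrs_candidates <- function(s, max_length = 30, min_g_group = 2,
                                   loop_min = 0, loop_max = 36) {
  n <- nchar(s)
  res <- list()
  for (g in min_g_group:(max_length %/% 4)) {
    gb <- strrep("G", g)
    budget <- max_length - 4 * g
    if (budget < 3 * loop_min) next
    for (l1 in loop_min:min(loop_max, budget)) {
      for (l2 in loop_min:min(loop_max, budget - l1)) {
        for (l3 in loop_min:min(loop_max, budget - l1 - l2)) {
          len <- 4 * g + l1 + l2 + l3
          if (len > n) next
          for (i in seq_len(n - len + 1)) {
            p2 <- i + g + l1; p3 <- p2 + g + l2; p4 <- p3 + g + l3
            if (substr(s, i, i + g - 1) == gb &&
                substr(s, p2, p2 + g - 1) == gb &&
                substr(s, p3, p3 + g - 1) == gb &&
                substr(s, p4, p4 + g - 1) == gb) {
              res[[length(res) + 1]] <- c(i, i + len - 1L, g, l1, l2, l3)
            }
          }
        }
      }
    }
  }
  if (!length(res)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          g_group_size = integer(), loop1 = integer(),
                          loop2 = integer(), loop3 = integer()))
  }
  m <- do.call(rbind, res)
  out <- tibble::tibble(start = m[, 1], end = m[, 2], g_group_size = m[, 3],
                        loop1 = m[, 4], loop2 = m[, 5], loop3 = m[, 6])
  dplyr::arrange(out, start, end, g_group_size, loop1, loop2)
}

# adjacency-list BFS connected components (independent of igraph)
oracle_components <- function(ids, edges) {
  adj <- setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(edges))) {
    a <- edges$protein_a[i]; b <- edges$protein_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  cid <- 0L
  for (v in ids) {
    if (!is.na(comp[[v]])) next
    cid <- cid + 1L
    queue <- v
    comp[[v]] <- cid
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in adj[[u]]) {
        if (is.na(comp[[w]])) {
          comp[[w]] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# brute-force hub-connector labels: remove each low-degree node and test
# whether two central hubs formerly in one component get separated
oracle_connectors <- function(ids, edges) {
  deg <- table(factor(c(edges$protein_a, edges$protein_b), levels = ids))
  hubs <- ids[deg > 4]
  comp <- oracle_components(ids, edges)
  out <- setNames(rep(FALSE, length(ids)), ids)
  for (v in ids) {
    if (deg[[v]] > 4 || deg[[v]] == 0) next
    mates <- hubs[hubs != v & comp[hubs] == comp[[v]]]
    if (length(mates) < 2) next
    ids2 <- setdiff(ids, v)
    e2 <- edges[edges$protein_a != v & edges$protein_b != v, , drop = FALSE]
    comp2 <- oracle_components(ids2, e2)
    out[[v]] <- length(unique(comp2[mates])) > 1
  }
  out
}

# position-wise coverage scan
oracle_coverage <- function(starts, ends, genome_length) {
  depth <- integer(genome_length)
  for (i in seq_along(starts)) {
    depth[starts[i]:ends[i]] <- depth[starts[i]:ends[i]] + 1L
  }
  covered <- depth > 0
  runs <- rle(covered)
  list(
    mean_depth = if (any(covered)) sum(depth) / sum(covered) else 0,
    longest_run = if (any(covered)) max(runs$lengths[runs$values]) else 0
  )
}

# small random edge table over n nodes (used for connector property tests)
random_edge_table <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  ids <- sprintf("p%03d", seq_len(n_nodes))
  a <- sample(ids, n_edges, replace = TRUE)
  b <- sample(ids, n_edges, replace = TRUE)
  keep <- a != b
  edges <- tibble::tibble(protein_a = pmin(a[keep], b[keep]),
                          protein_b = pmax(a[keep], b[keep]))
  list(ids = ids, edges = dplyr::distinct(edges))
}
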