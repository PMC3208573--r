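# Independent brute-force oracles used to check the package's exact
# computations. These deliberately share no code with the implementation.

# Exhaustive null distribution of the correctness score: enumerate every
# placement of G_up up-labels and G_down down-labels onto distinct nodes
# 1..N, with predicted-up set 1..d_up and predicted-down set
# (d_up+1)..(d_up+d_down).
enum_null_oracle <- function(N, G_up, G_down, d_up, d_down) {
  U <- seq_len(d_up)
  D <- d_up + seq_len(d_down)
  ups <- if (G_up > 0) combn(N, G_up, simplify = FALSE) else list(integer())
  tally <- new.env(parent = emptyenv())
  total <- 0
  for (up in ups) {
    rest <- setdiff(seq_len(N), up)
    dns <- if (G_down > 0) combn(rest, G_down, simplify = FALSE) else
      list(integer())
    for (dn in dns) {
      s <- as.character(sum(up %in% U) + sum(dn %in% D) -
                          sum(up %in% D) - sum(dn %in% U))
      tally[[s]] <- (tally[[s]] %||% 0) + 1
      total <- total + 1
    }
  }
  sup <- sort(as.integer(ls(tally)))
  list(support = sup,
       pmf = vapply(as.character(sup), function(s) tally[[s]] / total,
                    numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Total variation distance between two pmfs given as (support, pmf).
tv_distance <- function(a, b) {
  sup <- union(a$support, b$support)
  pa <- setNames(rep(0, length(sup)), sup)
  pb <- pa
  pa[as.character(a$support)] <- a$pmf
  pb[as.character(b$support)] <- b$pmf
  sum(abs(pa - pb)) / 2
}

# Upper-tail hypergeometric probability by direct summation with choose().
hyper_tail_oracle <- function(k, K, n, N) {
  j <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Two-sided Fisher exact p for the 2x2 table (a = hits, b = term-only,
# cc = significant-only, d = rest) by exhaustive tail enumeration.
fisher2_oracle <- function(a, b, cc, d) {
  K <- a + cc            # significant genes
  m <- a + b             # term size
  N <- a + b + cc + d
  x <- max(0, m - (N - K)):min(m, K)
  px <- choose(K, x) * choose(N - K, m - x) / choose(N, m)
  pobs <- choose(K, a) * choose(N - K, m - a) / choose(N, m)
  sum(px[px <= pobs * (1 + 1e-7)])
}

# Exhaustive simple-path sign propagation: iteratively extend all simple
# paths up to `depth` edges and collect the chain-sign products seen per
# transcript (relative to an assumed increase of `entity`).
paths_oracle <- function(kg, entity, depth) {
  st <- kg$statements
  is_tx <- setNames(kg$entities$kind == "transcript", kg$entities$id)
  acc <- list()
  frontier <- list(list(nodes = entity, sign = 1L))
  for (d in seq_len(depth)) {
    nxt <- list()
    for (p in frontier) {
      last <- p$nodes[length(p$nodes)]
      rows <- which(st$source == last)
      for (i in rows) {
        tgt <- st$target[i]
        if (tgt %in% p$nodes) next
        s <- p$sign * st$sign[i]
        if (is_tx[[tgt]]) acc[[tgt]] <- union(acc[[tgt]], s)
        nxt[[length(nxt) + 1]] <- list(nodes = c(p$nodes, tgt), sign = s)
      }
    }
    frontier <- nxt
    if (length(frontier) == 0) break
  }
  if (length(acc) == 0) return(setNames(integer(0), character(0)))
  out <- vapply(acc, function(s) if (length(s) > 1) 0L else s, integer(1))
  out[order(names(out))]
}

# Naive threshold-stopped average-linkage agglomeration on cosine
# similarity of feature sets; recomputes every pairwise average from the
# raw sets at each step. Same tie-break contract as the implementation
# (merge the lexicographically smallest qualifying pair); empty sets never
# merge. Returns the partition as a sorted list of sorted label vectors.
avg_linkage_oracle <- function(feats, threshold) {
  labs <- names(feats)
  cos <- function(x, y) {
    x <- unique(x); y <- unique(y)
    if (!length(x) || !length(y)) return(0)
    length(intersect(x, y)) / sqrt(length(x) * length(y))
  }
  pool <- lapply(labs[lengths(feats) > 0], identity)
  fixed <- lapply(labs[lengths(feats) == 0], identity)
  repeat {
    if (length(pool) < 2) break
    best <- -Inf; bi <- bj <- NA
    for (i in seq_along(pool)) for (j in seq_along(pool)) {
      if (j <= i) next
      sims <- outer(pool[[i]], pool[[j]],
                    Vectorize(function(x, y) cos(feats[[x]], feats[[y]])))
      lk <- mean(sims)
      key <- sort(c(min(pool[[i]]), min(pool[[j]])))
      if (lk > best + 1e-9 ||
          (lk > best - 1e-9 && !is.na(bi) &&
           paste(key, collapse = "\r") <
           paste(sort(c(min(pool[[bi]]), min(pool[[bj]]))), collapse = "\r"))) {
        best <- lk; bi <- i; bj <- j
      }
    }
    if (best < threshold - 1e-9) break
    pool[[bi]] <- c(pool[[bi]], pool[[bj]])
    pool[[bj]] <- NULL
  }
  part <- lapply(c(pool, fixed), sort)
  part[order(vapply(part, `[`, character(1), 1))]
}

# Canonical form of a clustering partition for comparison.
partition_of <- function(clustered) {
  part <- attr(clustered, "clusters")
  part <- lapply(part, sort)
  part[order(vapply(part, `[`, character(1), 1))]
}
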