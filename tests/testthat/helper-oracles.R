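# Independent brute-force oracles used to validate the package's fast paths.
# These deliberately share no code with the implementation.

# Dense full-matrix circuit solve: explicit 8-neighbour scan, base solve().
dense_pair_current <- function(vals, src, dst) {
  nr <- nrow(vals); nc <- ncol(vals); n <- nr * nc
  idx <- function(r, c) (c - 1L) * nr + r
  G <- matrix(0, n, n)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (d in list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        g <- (vals[r, c] + vals[r2, c2]) / 2
        if (abs(d[1]) + abs(d[2]) == 2) g <- g / sqrt(2)
        G[idx(r, c), idx(r2, c2)] <- g
        G[idx(r2, c2), idx(r, c)] <- g
      }
    }
  }
  L <- diag(rowSums(G)) - G
  b <- numeric(n); b[src] <- 1; b[dst] <- -1
  v <- numeric(n)
  v[-dst] <- solve(L[-dst, -dst], b[-dst])
  cur <- numeric(n)
  for (i in seq_len(n)) {
    cur[i] <- sum(abs(G[i, ] * (v[i] - v))) / 2
  }
  cur[c(src, dst)] <- cur[c(src, dst)] * 2
  list(potentials = v, current = cur, reff = v[src] - v[dst])
}

# Exhaustive simple-path enumeration: minimal path cost from src to every
# other node, then closeness = sum of reciprocals.
enum_closeness_node <- function(costm, src) {
  n <- nrow(costm)
  best <- rep(Inf, n)
  visited <- rep(FALSE, n)
  dfs <- function(i, acc) {
    if (acc < best[i]) best[i] <<- acc
    visited[i] <<- TRUE
    for (j in seq_len(n)) {
      if (!visited[j] && is.finite(costm[i, j])) dfs(j, acc + costm[i, j])
    }
    visited[i] <<- FALSE
  }
  dfs(src, 0)
  inv <- 1 / best[-src]
  sum(inv[is.finite(inv)])
}

enum_closeness <- function(costm) {
  vapply(seq_len(nrow(costm)), function(s) enum_closeness_node(costm, s),
         numeric(1))
}

# Optimal one-to-one timestamp assignment: maximise pair count, then
# minimise total |dt|; exhaustive recursion (small instances only).
optimal_assignment <- function(ti, tj, max_dt) {
  nj <- length(tj)
  rec <- function(a, used) {
    if (a > length(ti)) return(c(0, 0))
    best <- rec(a + 1L, used)
    for (b in seq_len(nj)) {
      if (!used[b] && abs(ti[a] - tj[b]) <= max_dt) {
        used[b] <- TRUE
        r <- rec(a + 1L, used)
        used[b] <- FALSE
        cand <- c(r[1] + 1, r[2] + abs(ti[a] - tj[b]))
        if (cand[1] > best[1] ||
            (cand[1] == best[1] && cand[2] < best[2])) best <- cand
      }
    }
    best
  }
  rec(1L, rep(FALSE, nj))
}

# Small fix-table builders.
make_fixes <- function(id, times, x, y) {
  data.frame(animal_id = id, timestamp = times, x = x, y = y,
             stringsAsFactors = FALSE)
}

utc <- function(s) as.POSIXct(s, tz = "UTC")

# Random positive-weight network on n nodes with edge probability p.
random_network <- function(n, p = 0.5) {
  pr <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pr)) < p
  e <- data.frame(node_i = as.character(pr[1, keep]),
                  node_j = as.character(pr[2, keep]),
                  weight = stats::runif(sum(keep), 0.1, 2))
  social_network(e, nodes = as.character(seq_len(n)))
}
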