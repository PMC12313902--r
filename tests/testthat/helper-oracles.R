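# Independent oracles the implementation is checked against. These stay
# deliberately naive: direct per-edge iteration for indices, explicit
# normal equations for least squares, central differences for gradients,
# permutation sampling for Shapley values.

# per-edge evaluation of a degree-based index, bypassing edge partitions
index_by_edge_iteration <- function(g, term) {
  deg <- igraph::degree(g)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  sum(mapply(function(u, v) term(deg[u], deg[v]), ends[, 1], ends[, 2]))
}

edge_terms <- list(
  M1 = function(du, dv) du + dv,
  M2 = function(du, dv) du * dv,
  H = function(du, dv) 2 / (du + dv),
  F = function(du, dv) du^2 + dv^2,
  SS = function(du, dv) sqrt(du * dv / (du + dv)),
  ABC = function(du, dv) sqrt((du + dv - 2) / (du * dv)),
  RI = function(du, dv) sqrt(1 / (du * dv)),
  SC = function(du, dv) sqrt(1 / (du + dv)),
  GA = function(du, dv) 2 * sqrt(du * dv) / (du + dv),
  HZ = function(du, dv) (du + dv)^2
)

# ordinary least squares by explicit normal equations on raw monomials
ols_normal_equations <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# random edge partition with degrees in 1..4
random_partition <- function() {
  pairs <- expand.grid(d1 = 1:4, d2 = 1:4)
  pairs <- pairs[pairs$d1 <= pairs$d2, ]
  keep <- sample(nrow(pairs), sample(2:6, 1))
  as_edge_partition(data.frame(d1 = pairs$d1[keep], d2 = pairs$d2[keep],
                               count = sample(1:12, length(keep), replace = TRUE)))
}

# central-difference gradient of the network loss in one weight entry
fd_loss <- function(W, b, X, y) mean((topoqspr:::.ann_forward_raw(W, b, X)$out - y)^2)

# Monte-Carlo Shapley estimate by permutation sampling: the average
# marginal contribution of feature i over random feature orderings
shapley_by_permutation <- function(predict_fn, background, x, n_perm, seed) {
  set.seed(seed)
  d <- length(x)
  bg <- colMeans(as.matrix(background))
  phi <- numeric(d)
  for (r in seq_len(n_perm)) {
    ord <- sample.int(d)
    # d+1 cumulative coalitions along the ordering, evaluated in one batch
    M <- matrix(bg, d + 1L, d, byrow = TRUE)
    for (k in seq_len(d)) M[(k + 1L):(d + 1L), ord[k]] <- x[ord[k]]
    v <- predict_fn(M)
    phi[ord] <- phi[ord] + diff(v)
  }
  phi / n_perm
}

# small deterministic feedforward net (weights only, no training) usable
# as a generic nonlinear predictor in shapley tests
make_toy_net <- function(d, hidden = 8L, seed = 1) {
  set.seed(seed)
  W1 <- matrix(rnorm(d * hidden, sd = 0.7), d, hidden)
  b1 <- rnorm(hidden, sd = 0.3)
  w2 <- rnorm(hidden, sd = 0.7)
  function(M) {
    M <- as.matrix(M)
    drop(pmax(sweep(M %*% W1, 2, b1, "+"), 0) %*% w2)
  }
}
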