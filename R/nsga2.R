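## Compact NSGA-II: fast non-dominated sorting, crowding distance,
## binary tournament, SBX crossover and polynomial mutation.

nd_sort <- function(F) {
  n <- nrow(F)
  rank <- integer(n)
  dominates <- function(i, j) all(F[i, ] <= F[j, ]) && any(F[i, ] < F[j, ])
  S <- vector("list", n); ncount <- integer(n)
  front <- list(integer(0))
  for (i in seq_len(n)) {
    S[[i]] <- integer(0)
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(i, j)) S[[i]] <- c(S[[i]], j)
      else if (dominates(j, i)) ncount[i] <- ncount[i] + 1
    }
    if (ncount[i] == 0) { rank[i] <- 1L; front[[1]] <- c(front[[1]], i) }
  }
  k <- 1L
  while (length(front[[k]]) > 0) {
    nxt <- integer(0)
    for (i in front[[k]]) for (j in S[[i]]) {
      ncount[j] <- ncount[j] - 1
      if (ncount[j] == 0) { rank[j] <- k + 1L; nxt <- c(nxt, j) }
    }
    k <- k + 1L
    front[[k]] <- nxt
  }
  rank
}

crowding <- function(F) {
  n <- nrow(F); cd <- numeric(n)
  for (m in seq_len(ncol(F))) {
    o <- order(F[, m])
    rng <- F[o[n], m] - F[o[1], m]
    cd[o[c(1, n)]] <- Inf
    if (rng > 0 && n > 2)
      cd[o[2:(n - 1)]] <- cd[o[2:(n - 1)]] +
        (F[o[3:n], m] - F[o[1:(n - 2)], m]) / rng
  }
  cd
}

sbx_cross <- function(p1, p2, lower, upper, eta = 15) {
  u <- stats::runif(length(p1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

poly_mutate <- function(x, lower, upper, eta = 20, p = NULL) {
  d <- length(x)
  if (is.null(p)) p <- 1 / d
  for (k in seq_len(d)) {
    if (stats::runif(1) >= p || upper[k] <= lower[k]) next
    u <- stats::runif(1)
    delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1
             else 1 - (2 * (1 - u))^(1 / (eta + 1))
    x[k] <- min(max(x[k] + delta * (upper[k] - lower[k]), lower[k]), upper[k])
  }
  x
}

#' Non-dominated Sorting Genetic Algorithm II
#'
#' Minimises a vector-valued objective over a box, returning the final
#' population and its objective values.  Standard operators: binary
#' tournament on (rank, crowding), simulated binary crossover and
#' polynomial mutation, with elitist environmental selection.
#'
#' @param fn Function mapping a parameter vector to a numeric objective
#'   vector (all objectives minimised).
#' @param lower,upper Box bounds.
#' @param pop_size Population size.
#' @param generations Number of generations (0 returns the evaluated
#'   initial population unchanged).
#' @param seed Integer seed.
#' @param init Optional matrix of initial individuals (rows; recycled or
#'   truncated to `pop_size`).
#' @return List with `X` (population matrix), `F` (objectives), `rank`.
#' @export
nsga2 <- function(fn, lower, upper, pop_size = 40, generations = 20,
                  seed = 1L, init = NULL) {
  d <- length(lower)
  set.seed(seed)
  X <- matrix(stats::runif(pop_size * d, rep(lower, each = pop_size),
                           rep(upper, each = pop_size)), nrow = pop_size)
  if (!is.null(init)) {
    init <- as.matrix(init)
    m <- min(nrow(init), pop_size)
    X[seq_len(m), ] <- init[seq_len(m), , drop = FALSE]
  }
  evalF <- function(X) t(apply(X, 1, fn))
  F <- evalF(X)
  if (generations == 0)
    return(list(X = X, F = F, rank = nd_sort(F)))
  for (g in seq_len(generations)) {
    rank <- nd_sort(F); cd <- crowding(F)
    tourn <- function() {
      i <- sample(pop_size, 2)
      if (rank[i[1]] < rank[i[2]] ||
          (rank[i[1]] == rank[i[2]] && cd[i[1]] > cd[i[2]])) i[1] else i[2]
    }
    off <- matrix(0, pop_size, d)
    for (i in seq(1, pop_size, by = 2)) {
      ch <- sbx_cross(X[tourn(), ], X[tourn(), ], lower, upper)
      off[i, ] <- poly_mutate(ch[[1]], lower, upper)
      off[min(i + 1, pop_size), ] <- poly_mutate(ch[[2]], lower, upper)
    }
    Xall <- rbind(X, off); Fall <- rbind(F, evalF(off))
    r <- nd_sort(Fall); cdall <- crowding(Fall)
    keep <- order(r, -cdall)[seq_len(pop_size)]
    X <- Xall[keep, , drop = FALSE]; F <- Fall[keep, , drop = FALSE]
  }
  list(X = X, F = F, rank = nd_sort(F))
}
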