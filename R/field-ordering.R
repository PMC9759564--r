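#' Covariance-derived closeness ranks between fields
#'
#' Computes the sample covariance matrix of the features and converts each
#' row to ordinal ranks: within row `i`, the off-diagonal entry with the
#' largest covariance magnitude gets rank 1 (most closely related), the
#' next largest rank 2, and so on up to `d - 1`.  Ties are broken towards
#' the lower column index, so the result is deterministic; a constant
#' feature has all-zero covariances and its partners rank purely by the
#' tie rule.  Magnitude is used because strong negative covariance is
#' relatedness too.
#'
#' @param ds a `tabular_dataset` with at least 2 records and 2 features,
#'   or a plain numeric matrix.
#' @return an object of class `"rank_matrix"`: integer `d x d` matrix
#'   (diagonal `NA`) plus the covariance it derives from.
#' @export
covariance_rank_matrix <- function(ds) {
  feats <- if (inherits(ds, "tabular_dataset")) ds$features else as.matrix(ds)
  if (nrow(feats) < 2L || ncol(feats) < 2L)
    stop("need at least 2 records and 2 features")
  if (anyNA(feats)) stop("resolve missing cells before ranking")
  rank_matrix_from_scores(abs(stats::cov(feats)), derivation = stats::cov(feats))
}

# Rank each row of a d x d closeness-score matrix: largest score -> rank 1,
# ties to the lower column index; diagonal excluded (NA).
rank_matrix_from_scores <- function(scores, derivation = scores) {
  d <- nrow(scores)
  ranks <- matrix(NA_integer_, d, d)
  for (i in seq_len(d)) {
    j <- setdiff(seq_len(d), i)
    ord <- j[order(-scores[i, j], j)]
    ranks[i, ord] <- seq_len(d - 1L)
  }
  dimnames(ranks) <- dimnames(scores)
  structure(list(ranks = ranks, derivation = derivation, d = d),
            class = "rank_matrix")
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("<rank_matrix> %d fields\n", x$d))
  print(x$ranks)
  invisible(x)
}

# Symmetrized edge weights: (ranks[i,j] + ranks[j,i]) / 2.
sym_rank <- function(rm) {
  s <- (rm$ranks + t(rm$ranks)) / 2
  diag(s) <- 0
  s
}

#' A field ordering and its path cost
#'
#' @param order permutation of `1..d` (1-based field indices).
#' @param cost total adjacent symmetrized rank along the open path.
#' @export
field_ordering <- function(order, cost = NA_real_) {
  order <- as.integer(order)
  if (!setequal(order, seq_along(order)))
    stop("order must be a permutation of 1..d")
  structure(list(order = order, cost = cost), class = "field_ordering")
}

#' @export
print.field_ordering <- function(x, ...) {
  cat(sprintf("<field_ordering> [%s]  cost %.1f\n",
              paste(x$order, collapse = ", "), x$cost))
  invisible(x)
}

#' Total adjacent-rank cost of a field ordering
#'
#' Sums the symmetrized rank `(ranks[i,j] + ranks[j,i]) / 2` over
#' consecutive pairs of the ordering — an open path, no wrap-around.
#' Reversing an ordering leaves the cost unchanged.
#'
#' @param order a [field_ordering()] or an integer permutation.
#' @param rm a [covariance_rank_matrix()] result.
#' @export
path_cost <- function(order, rm) {
  if (inherits(order, "field_ordering")) order <- order$order
  order <- as.integer(order)
  stopifnot(inherits(rm, "rank_matrix"), length(order) == rm$d,
            setequal(order, seq_len(rm$d)))
  s <- sym_rank(rm)
  sum(s[cbind(order[-length(order)], order[-1L])])
}

#' Exhaustive minimum-cost field ordering
#'
#' Depth-first lexicographic enumeration of permutations with
#' branch-and-bound pruning, exploiting the reversal symmetry of the open
#' path (only orderings whose first field index is below the last are
#' expanded).  The first strict improvement is kept, so ties resolve to
#' the lexicographically smallest optimum.  Refuses `d > 10`.
#'
#' @param rm a [covariance_rank_matrix()] result.
#' @return a [field_ordering()] with the global minimum cost.
#' @export
brute_force_order <- function(rm) {
  stopifnot(inherits(rm, "rank_matrix"))
  d <- rm$d
  if (d > 10L) stop("exhaustive search refused for d > 10")
  if (d == 2L) return(field_ordering(1:2, path_cost(1:2, rm)))
  s <- sym_rank(rm)
  best_cost <- Inf
  best_order <- NULL
  perm <- integer(d)
  used <- logical(d)
  recurse <- function(pos, cost) {
    if (cost >= best_cost) return()
    if (pos > d) {
      if (perm[1L] < perm[d]) {   # canonical orientation of the pair
        best_cost <<- cost
        best_order <<- perm
      }
      return()
    }
    for (v in seq_len(d)) {
      if (used[v]) next
      step <- if (pos == 1L) 0 else s[perm[pos - 1L], v]
      if (cost + step >= best_cost) next
      perm[pos] <<- v
      used[v] <<- TRUE
      recurse(pos + 1L, cost + step)
      used[v] <<- FALSE
    }
  }
  recurse(1L, 0)
  field_ordering(best_order, best_cost)
}

#' Genetic-algorithm settings for the ordering search
#'
#' Defaults (population 100, 100 generations, order crossover at rate
#' 0.9, per-position swap mutation at rate 0.1, tournament selection of
#' size 3, elitism 1, five random immigrants per generation, and a
#' 2-swap hill-climb polish of each generation's best individual)
#' comfortably cover problems of a few dozen fields; the best cost
#' typically stops moving within the first ten generations.
#'
#' @param population_size individuals per generation.
#' @param generations number of generations.
#' @param crossover_rate probability a pair is recombined.
#' @param mutation_rate per-position probability of a swap mutation in
#'   each offspring (each selected position is exchanged with a uniformly
#'   chosen partner).
#' @param tournament_size individuals competing per parent selection.
#' @param immigrants random permutations injected each generation to
#'   keep the population diverse.
#' @param local_search polish the generation's best individual to a
#'   2-swap local optimum.
#' @param seed integer seed; the run is fully deterministic given it.
#' @export
ga_config <- function(population_size = 100L, generations = 100L,
                      crossover_rate = 0.9, mutation_rate = 0.1,
                      tournament_size = 3L, immigrants = 5L,
                      local_search = TRUE, seed = 1L) {
  stopifnot(population_size >= 2L, generations >= 1L,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            tournament_size >= 1L, immigrants >= 0L,
            immigrants < population_size)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 immigrants = as.integer(immigrants),
                 local_search = isTRUE(local_search),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Exhaustive 2-swap hill climb used to polish the elite individual.
two_swap_polish <- function(p, cost_of) {
  d <- length(p)
  c0 <- cost_of(p)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(d - 1L)) for (j in (i + 1L):d) {
      q <- p
      q[c(i, j)] <- q[c(j, i)]
      cq <- cost_of(q)
      if (cq < c0) {
        p <- q; c0 <- cq; improved <- TRUE
      }
    }
  }
  list(order = p, cost = c0)
}

# Order crossover (OX): copy a random slice from parent 1, fill the rest
# in parent 2's circular order.
ox_crossover <- function(p1, p2) {
  d <- length(p1)
  cut <- sort(sample.int(d, 2L))
  child <- integer(d)
  seg <- cut[1L]:cut[2L]
  child[seg] <- p1[seg]
  rest <- p2[!p2 %in% child[seg]]
  child[-seg] <- rest
  child
}

#' Genetic-algorithm search for a low-cost field ordering
#'
#' Permutation-encoded GA: tournament selection, order crossover, swap
#' mutation, elitism of one, random immigrants, and an optional 2-swap
#' polish of each generation's best individual.  The identity ordering
#' is seeded into the initial population, so the returned cost never
#' exceeds the identity's.  Deterministic for a fixed seed; returns the
#' best ordering ever seen.
#'
#' @param rm a [covariance_rank_matrix()] result.
#' @param cfg a [ga_config()].
#' @return a [field_ordering()].
#' @export
ga_order <- function(rm, cfg = ga_config()) {
  stopifnot(inherits(rm, "rank_matrix"), inherits(cfg, "ga_config"))
  d <- rm$d
  if (d < 2L) stop("need at least 2 fields")
  s <- sym_rank(rm)
  cost_of <- function(p) sum(s[cbind(p[-d], p[-1L])])
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(cfg$seed)
  np <- cfg$population_size
  pop <- c(list(seq_len(d)),
           replicate(np - 1L, sample.int(d), simplify = FALSE))
  costs <- vapply(pop, cost_of, numeric(1L))
  best_i <- which.min(costs)
  best <- pop[[best_i]]; best_cost <- costs[best_i]
  history <- numeric(cfg$generations)
  for (g in seq_len(cfg$generations)) {
    tournament <- function() {
      cand <- sample.int(np, cfg$tournament_size)
      pop[[cand[which.min(costs[cand])]]]
    }
    nxt <- vector("list", np)
    nxt[[1L]] <- best                      # elitism
    for (k in 2:np) {
      p1 <- tournament(); p2 <- tournament()
      child <- if (stats::runif(1L) < cfg$crossover_rate)
        ox_crossover(p1, p2) else p1
      for (pos in which(stats::runif(d) < cfg$mutation_rate)) {
        partner <- sample.int(d, 1L)
        tmp <- child[pos]; child[pos] <- child[partner]
        child[partner] <- tmp
      }
      nxt[[k]] <- child
    }
    if (cfg$immigrants > 0L)
      for (m in seq_len(cfg$immigrants))
        nxt[[np - m + 1L]] <- sample.int(d)
    pop <- nxt
    costs <- vapply(pop, cost_of, numeric(1L))
    gen_best <- which.min(costs)
    if (cfg$local_search) {
      pol <- two_swap_polish(pop[[gen_best]], cost_of)
      pop[[gen_best]] <- pol$order
      costs[gen_best] <- pol$cost
    }
    if (costs[gen_best] < best_cost) {
      best_cost <- costs[gen_best]
      best <- pop[[gen_best]]
    }
    history[g] <- best_cost
  }
  out <- field_ordering(best, best_cost)
  attr(out, "history") <- history
  out
}
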