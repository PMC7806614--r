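#' Construct a bipartite agent-source network
#'
#' A static affiliation structure between `M` agents and `N` common-pool
#' resource sources. An edge means the agent has access to that source. The
#' structure is validated: every edge joins one agent (`1..M`) and one source
#' (`1..N`), there are no duplicate edges, and no node is isolated.
#'
#' @param edges two-column integer matrix or data frame; first column agent
#'   ids, second column source ids, both 1-based.
#' @param M,N numbers of agents and sources. Defaults to the largest id seen.
#' @return An object of class `bipartite_network` with fields `M`, `N`,
#'   `edges` (integer matrix sorted by agent then source), `agent_deg`
#'   (length `M`), `source_deg` (length `N`) and edge count `E`.
#' @export
bipartite_network <- function(edges, M = max(edges[, 1]), N = max(edges[, 2])) {
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  if (ncol(edges) != 2L) stop("`edges` must have two columns (agent, source)")
  if (anyNA(edges) || any(edges < 1L)) stop("edge ids must be positive integers")
  if (any(edges[, 1] > M) || any(edges[, 2] > N)) stop("edge ids exceed M or N")
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) stop("duplicate edges are not allowed")
  agent_deg <- tabulate(edges[, 1], nbins = M)
  source_deg <- tabulate(edges[, 2], nbins = N)
  if (any(agent_deg == 0L) || any(source_deg == 0L)) stop("isolated nodes are not allowed")
  dimnames(edges) <- list(NULL, c("agent", "source"))
  structure(list(M = as.integer(M), N = as.integer(N), edges = edges,
                 agent_deg = agent_deg, source_deg = source_deg,
                 E = nrow(edges)),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d agents, %d sources, %d edges (<m>=%.2f, <n>=%.2f)\n",
              x$M, x$N, x$E, mean(x$agent_deg), mean(x$source_deg)))
  invisible(x)
}

# Discrete power law p(d) ~ d^(-tau) on 1..dmax with tau chosen so the
# truncated mean equals `mean`.
power_law_pmf <- function(mean, dmax) {
  d <- seq_len(dmax)
  mean_of <- function(tau) {
    w <- d^(-tau)
    sum(d * w) / sum(w)
  }
  lo <- 0.01; hi <- 20
  if (mean >= mean_of(lo) || mean <= mean_of(hi))
    stop("power-law target mean ", mean, " not attainable on support 1..", dmax)
  tau <- uniroot(function(t) mean_of(t) - mean, c(lo, hi), tol = 1e-12)$root
  w <- d^(-tau)
  list(d = d, p = w / sum(w), tau = tau)
}

#' Sample a degree sequence of a given heterogeneity kind
#'
#' The six kinds match the ensemble labels used throughout the package:
#' source-side `"D"` (delta function), `"N"` (normal), `"PL"` (power law) and
#' agent-side `"U"` (uniform), `"R"` (random), `"SF"` (scale-free-type).
#' `D`/`U` return the constant `round(mean)`. `N` rounds draws from
#' Normal(`mean`, `sigma`) and truncates at 1. `R` throws
#' `round(size * mean)` edge stubs uniformly into `size` bins (binomial-like
#' margins), bumping empty bins to degree 1. `PL`/`SF` draw from a discrete
#' power law on `1..(size-1)` whose exponent is solved numerically so the
#' truncated mean equals `mean`.
#'
#' Sampling uses the current RNG state; seed via [set.seed()].
#'
#' @param kind one of `"D"`, `"N"`, `"PL"`, `"U"`, `"R"`, `"SF"`.
#' @param size number of nodes (>= 1).
#' @param mean target mean degree (>= 1).
#' @param sigma standard deviation of the `"N"` kind (default 1.5).
#' @return integer vector of `size` degrees, all >= 1.
#' @export
sample_degree_sequence <- function(kind, size, mean, sigma = 1.5) {
  kind <- match.arg(kind, c("D", "N", "PL", "U", "R", "SF"))
  if (size < 1L) stop("`size` must be >= 1")
  if (mean < 1) stop("`mean` must be >= 1")
  deg <- switch(kind,
    D = ,
    U = rep.int(as.integer(round(mean)), size),
    N = pmax(1L, as.integer(round(rnorm(size, mean, sigma)))),
    R = {
      E <- as.integer(round(size * mean))
      d <- tabulate(sample.int(size, E, replace = TRUE), nbins = size)
      d[d == 0L] <- 1L
      as.integer(d)
    },
    PL = ,
    SF = {
      pmf <- power_law_pmf(mean, max(2L, size - 1L))
      as.integer(sample(pmf$d, size, replace = TRUE, prob = pmf$p))
    })
  deg
}

# Gale-Ryser feasibility of a bipartite degree pair (simple graph).
gale_ryser_feasible <- function(agent_deg, source_deg) {
  if (sum(agent_deg) != sum(source_deg)) return(FALSE)
  a <- sort(agent_deg, decreasing = TRUE)
  s <- source_deg
  cums <- cumsum(a)
  for (k in seq_along(a)) {
    if (cums[k] > sum(pmin(s, k))) return(FALSE)
  }
  TRUE
}

#' Reconcile two degree sequences to a common total
#'
#' Adds or subtracts 1 at uniformly random nodes of the deficient side
#' (respecting degree >= 1 and degree <= opposite-side size) until the two
#' sides carry equally many edge stubs.
#'
#' @param agent_deg,source_deg integer degree vectors.
#' @return list with reconciled `agent_deg` and `source_deg`.
#' @export
reconcile_degree_sequences <- function(agent_deg, source_deg) {
  M <- length(agent_deg); N <- length(source_deg)
  agent_deg <- as.integer(agent_deg)
  source_deg <- as.integer(source_deg)
  if (any(agent_deg > N) || any(source_deg > M))
    stop("a degree exceeds the opposite-side size (simple graph impossible)")
  if (any(agent_deg < 1L) || any(source_deg < 1L)) stop("degrees must be >= 1")
  # raise the deficient side or lower the excess side with equal probability,
  # so the expected total is preserved rather than dragged toward the larger draw
  bump_up <- function(d, cap) {
    cand <- which(d < cap)
    if (!length(cand)) return(NULL)
    i <- cand[sample.int(length(cand), 1L)]
    d[i] <- d[i] + 1L
    d
  }
  bump_down <- function(d) {
    cand <- which(d > 1L)
    if (!length(cand)) return(NULL)
    i <- cand[sample.int(length(cand), 1L)]
    d[i] <- d[i] - 1L
    d
  }
  guard <- 0L
  while (sum(agent_deg) != sum(source_deg)) {
    guard <- guard + 1L
    if (guard > 1000000L) stop("degree sequences could not be reconciled")
    agents_low <- sum(agent_deg) < sum(source_deg)
    raise <- sample(c(TRUE, FALSE), 1L)
    new <- if (agents_low) {
      if (raise) bump_up(agent_deg, N) else bump_down(source_deg)
    } else {
      if (raise) bump_up(source_deg, M) else bump_down(agent_deg)
    }
    if (is.null(new)) {  # chosen move impossible; try the complementary one
      new <- if (agents_low) {
        if (raise) bump_down(source_deg) else bump_up(agent_deg, N)
      } else {
        if (raise) bump_down(agent_deg) else bump_up(source_deg, M)
      }
      raise <- !raise
    }
    if (is.null(new)) stop("degree sequences impossible to reconcile")
    if (agents_low == raise) agent_deg <- new else source_deg <- new
  }
  list(agent_deg = agent_deg, source_deg = source_deg)
}

#' Build a simple bipartite network realizing two degree sequences
#'
#' A maximal-first greedy realization (each agent, taken in decreasing degree
#' order, is wired to the sources with the most remaining stubs, ties broken
#' at random) — guaranteed to succeed for any Gale-Ryser-feasible pair — is
#' randomized by `max_swaps` attempted double-edge swaps, which hold every
#' degree fixed and never create duplicate edges. Sequences with unequal
#' totals are first reconciled by [reconcile_degree_sequences()]; a degree
#' exceeding the opposite-side size is rejected, and joint-tail
#' infeasibility is repaired minimally (see Details).
#'
#' @param agent_degrees,source_degrees integer degree vectors.
#' @param max_swaps double-edge-swap attempts used to randomize the greedy
#'   realization; default `20 * E`.
#' @return a [bipartite_network()].
#' @export
build_bipartite <- function(agent_degrees, source_degrees, max_swaps = NULL) {
  rec <- reconcile_degree_sequences(agent_degrees, source_degrees)
  a_deg <- rec$agent_deg; s_deg <- rec$source_deg
  M <- length(a_deg); N <- length(s_deg)
  # Gale-Ryser repair: joint heavy tails can be unrealizable as a simple
  # graph even with matching totals. Shave the largest hub by one and add one
  # to a random lower-degree node of the same side (totals and means are
  # preserved; only the extreme joint tail is trimmed).
  guard <- 0L
  while (!gale_ryser_feasible(a_deg, s_deg)) {
    guard <- guard + 1L
    if (guard > 10000L)
      stop("degree sequences are not realizable as a simple bipartite graph")
    if (guard %% 2L == 1L) {
      i <- which(a_deg == max(a_deg))
      i <- i[sample.int(length(i), 1L)]
      j <- which(a_deg < pmin(N, max(a_deg) - 1L) & seq_along(a_deg) != i)
      if (!length(j)) j <- which(a_deg < N & seq_along(a_deg) != i)
      if (!length(j)) next
      j <- j[sample.int(length(j), 1L)]
      a_deg[i] <- a_deg[i] - 1L; a_deg[j] <- a_deg[j] + 1L
    } else {
      i <- which(s_deg == max(s_deg))
      i <- i[sample.int(length(i), 1L)]
      j <- which(s_deg < pmin(M, max(s_deg) - 1L) & seq_along(s_deg) != i)
      if (!length(j)) j <- which(s_deg < M & seq_along(s_deg) != i)
      if (!length(j)) next
      j <- j[sample.int(length(j), 1L)]
      s_deg[i] <- s_deg[i] - 1L; s_deg[j] <- s_deg[j] + 1L
    }
  }
  E <- sum(a_deg)
  if (is.null(max_swaps)) max_swaps <- 20L * E
  # greedy maximal-first realization
  ag <- integer(E); src <- integer(E)
  rs <- s_deg
  pos <- 0L
  for (a in order(a_deg, decreasing = TRUE)) {
    d <- a_deg[a]
    pick <- order(-rs, sample.int(N))[seq_len(d)]
    if (rs[pick[d]] < 1L) stop("internal error: greedy realization failed")
    rs[pick] <- rs[pick] - 1L
    ag[pos + seq_len(d)] <- a
    src[pos + seq_len(d)] <- pick
    pos <- pos + d
  }
  # randomize by double-edge swaps (degree-preserving, duplicate-free)
  key <- (as.numeric(ag) - 1) * N + as.numeric(src)
  for (t in seq_len(max_swaps)) {
    e <- sample.int(E, 2L)
    a1 <- ag[e[1L]]; s1 <- src[e[1L]]; a2 <- ag[e[2L]]; s2 <- src[e[2L]]
    if (a1 == a2 || s1 == s2) next
    k1 <- (as.numeric(a1) - 1) * N + s2
    k2 <- (as.numeric(a2) - 1) * N + s1
    if (any(key == k1) || any(key == k2)) next
    src[e] <- c(s2, s1)
    key[e] <- c(k1, k2)
  }
  bipartite_network(cbind(ag, src), M = M, N = N)
}

#' Generate one random network from distribution kinds
#'
#' Samples an agent and a source degree sequence, reconciles their totals and
#' assembles a simple bipartite graph.
#'
#' @param source_dist one of `"D"`, `"N"`, `"PL"`.
#' @param agent_dist one of `"U"`, `"R"`, `"SF"`.
#' @param M,N node counts.
#' @param mean_m,mean_n target mean degrees (must satisfy
#'   `M * mean_m == N * mean_n`).
#' @param sigma normal-kind standard deviation, passed through.
#' @return a [bipartite_network()].
#' @export
generate_network <- function(source_dist, agent_dist, M = 50L, N = 50L,
                             mean_m = 5, mean_n = 5, sigma = 1.5,
                             max_attempts = 100L) {
  if (abs(M * mean_m - N * mean_n) > 1e-9)
    stop("edge-count consistency requires M * mean_m == N * mean_n")
  last <- NULL
  for (attempt in seq_len(max_attempts)) {
    a_deg <- sample_degree_sequence(agent_dist, M, mean_m, sigma = sigma)
    s_deg <- sample_degree_sequence(source_dist, N, mean_n, sigma = sigma)
    net <- tryCatch(build_bipartite(a_deg, s_deg), error = function(e) e)
    if (!inherits(net, "error")) return(net)
    last <- net  # infeasible degree pair (heavy tails); redraw
  }
  stop("could not realize a network after ", max_attempts, " attempts: ",
       conditionMessage(last))
}

#' Specify a network ensemble
#'
#' An ensemble is a family of independent network realizations sharing one
#' source-degree kind, one agent-degree kind, sizes and mean degrees. The
#' study design uses the nine combinations of D/N/PL sources with U/R/SF
#' agents at `M = N = 50`, mean degrees 5.
#'
#' @inheritParams generate_network
#' @param n_realizations number of networks in the ensemble.
#' @param seed master seed; realization `i` uses the child seed
#'   `(seed + 1000003 * i) mod 2147483629`.
#' @return an object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(source_dist, agent_dist, M = 50L, N = 50L,
                          mean_m = 5, mean_n = 5, n_realizations = 100L,
                          seed = 1L, sigma = 1.5) {
  source_dist <- match.arg(source_dist, c("D", "N", "PL"))
  agent_dist <- match.arg(agent_dist, c("U", "R", "SF"))
  if (n_realizations < 1L) stop("`n_realizations` must be >= 1")
  if (abs(M * mean_m - N * mean_n) > 1e-9)
    stop("edge-count consistency requires M * mean_m == N * mean_n")
  structure(list(source_dist = source_dist, agent_dist = agent_dist,
                 M = as.integer(M), N = as.integer(N),
                 mean_m = mean_m, mean_n = mean_n,
                 n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed), sigma = sigma,
                 label = paste0(source_dist, "-", agent_dist)),
            class = "ensemble_spec")
}

#' Generate all realizations of an ensemble
#'
#' @param spec an [ensemble_spec()].
#' @param seed optional master-seed override.
#' @return list of [bipartite_network()] objects.
#' @export
generate_ensemble <- function(spec, seed = spec$seed) {
  lapply(seq_len(spec$n_realizations), function(i) {
    with_seed(child_seed(seed, i),
              generate_network(spec$source_dist, spec$agent_dist,
                               M = spec$M, N = spec$N,
                               mean_m = spec$mean_m, mean_n = spec$mean_n,
                               sigma = spec$sigma))
  })
}

#' Degree distributions of a network population
#'
#' Container for the agent-degree mass function `P_A(m)` and source-degree
#' mass function `P_S(n)` together with the node counts they describe. Both
#' mass functions must sum to one (tolerance 1e-12).
#'
#' @param P_A,P_S numeric probability vectors named by degree (or unnamed,
#'   implying degrees `1..length`).
#' @param M,N agent and source counts the distributions refer to.
#' @return object of class `degree_distributions` with fields `m`, `P_A`,
#'   `n`, `P_S`, `mean_m`, `mean_n`, `m_max`, `n_max`, `M`, `N`.
#' @export
degree_distributions <- function(P_A, P_S, M = 50L, N = 50L) {
  norm_side <- function(p) {
    d <- if (is.null(names(p))) seq_along(p) else as.integer(names(p))
    keep <- p > 0
    p <- as.numeric(p[keep]); d <- d[keep]
    if (!length(p) || any(p < 0)) stop("degree masses must be nonnegative with positive total")
    if (abs(sum(p) - 1) > 1e-12) stop("degree mass function must sum to 1 (tolerance 1e-12)")
    o <- order(d)
    list(d = d[o], p = p[o])
  }
  A <- norm_side(P_A); S <- norm_side(P_S)
  structure(list(m = A$d, P_A = A$p, n = S$d, P_S = S$p,
                 mean_m = sum(A$d * A$p), mean_n = sum(S$d * S$p),
                 m_max = max(A$d), n_max = max(S$d),
                 M = as.integer(M), N = as.integer(N)),
            class = "degree_distributions")
}

#' Pooled empirical degree distributions of a set of networks
#'
#' @param networks non-empty list of [bipartite_network()] objects.
#' @return a [degree_distributions()] built from pooled degree histograms.
#' @export
empirical_distributions <- function(networks) {
  if (!length(networks)) stop("`networks` must be a non-empty list")
  a <- unlist(lapply(networks, `[[`, "agent_deg"))
  s <- unlist(lapply(networks, `[[`, "source_deg"))
  P_A <- tabulate(a, nbins = max(a)) / length(a)
  P_S <- tabulate(s, nbins = max(s)) / length(s)
  degree_distributions(P_A, P_S, M = networks[[1]]$M, N = networks[[1]]$N)
}

#' Read / write a network as a tab-separated edge list
#'
#' The file carries a header line `agent_id<TAB>source_id` and 0-based ids.
#'
#' @param net a [bipartite_network()].
#' @param path file path.
#' @param M,N optional node counts for files whose largest ids undersell the
#'   network size.
#' @return `write_edgelist()` returns `path` invisibly; `read_edgelist()`
#'   returns a [bipartite_network()].
#' @export
write_edgelist <- function(net, path) {
  df <- data.frame(agent_id = net$edges[, 1] - 1L, source_id = net$edges[, 2] - 1L)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path, M = NULL, N = NULL) {
  df <- read.delim(path)
  if (!all(c("agent_id", "source_id") %in% names(df)))
    stop("edge list must have columns `agent_id` and `source_id`")
  bipartite_network(cbind(df$agent_id + 1L, df$source_id + 1L),
                    M = if (is.null(M)) max(df$agent_id) + 1L else M,
                    N = if (is.null(N)) max(df$source_id) + 1L else N)
}
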