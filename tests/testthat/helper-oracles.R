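# Independent oracles used across test files. Each deliberately takes a
# different route than the package implementation.

# Identifiability verdict by explicit rank computations (Matrix::rankMatrix)
# on random fillings of the support pattern.
oracle_identifiability <- function(support, n_conditions, seed = 99L) {
  set.seed(seed)
  grank <- function(pat) {
    if (length(pat) == 0 || sum(pat) == 0) return(0L)
    best <- 0L
    for (f in 1:3) {
      m <- matrix(0, nrow(pat), ncol(pat))
      m[pat] <- stats::rnorm(sum(pat)) + sign(stats::rnorm(sum(pat))) * 0.5
      best <- max(best, as.integer(Matrix::rankMatrix(m)))
    }
    best
  }
  L <- ncol(support)
  c1 <- grank(support) == L
  c2 <- all(vapply(seq_len(L), function(j) {
    sub <- support[!support[, j], -j, drop = FALSE]
    need <- L - 1L
    need == 0L || grank(sub) == need
  }, logical(1)))
  c3 <- L <= n_conditions
  list(pass = c1 && c2 && c3, c1 = c1, c2 = c2, c3 = c3)
}

# Random support pattern with no empty row or column (not necessarily
# identifiable), as a correlation-valued prior.
random_prior <- function(n_genes, n_tfs, density = 0.35, seed = 1L) {
  set.seed(seed)
  repeat {
    pat <- matrix(stats::runif(n_genes * n_tfs) < density, n_genes, n_tfs)
    if (all(rowSums(pat) > 0) && all(colSums(pat) > 0)) break
  }
  s <- matrix(0, n_genes, n_tfs,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("t%02d", seq_len(n_tfs))))
  s[pat] <- stats::runif(sum(pat), 0.3, 0.95) * sample(c(-1, 1), sum(pat), TRUE)
  connectivity_prior(s)
}

# Brute-force census of connected induced size-k subgraphs: enumerate every
# node subset, test weak connectivity with a hand-rolled BFS, and classify
# with igraph's canonical permutation (BLISS), fully independent of the
# package's ESU + brute-force-permutation canonicalizer.
brute_force_census <- function(edges, k) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n)
  adj[cbind(match(edges$from, nodes), match(edges$to, nodes))] <- TRUE
  und <- adj | t(adj)
  classes <- character(0)
  for (s in utils::combn(n, k, simplify = FALSE)) {
    u <- und[s, s, drop = FALSE]
    seen <- c(1L, integer(0))
    frontier <- 1L
    while (length(frontier)) {
      nxt <- setdiff(which(rowSums(u[, frontier, drop = FALSE] + 0) > 0), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (length(seen) < k) next
    sg <- igraph::graph_from_adjacency_matrix(adj[s, s, drop = FALSE] + 0,
                                              mode = "directed")
    pg <- igraph::permute(sg, igraph::canonical_permutation(sg)$labeling)
    classes <- c(classes,
                 paste(as.vector(igraph::as_adjacency_matrix(pg, sparse = FALSE)),
                       collapse = ""))
  }
  tab <- table(classes)
  list(total = length(classes),
       class_counts = sort(as.integer(tab), decreasing = TRUE))
}

# Minimal "nca"-classed object for exercising gauge / network code on
# hand-built strength and activity matrices.
fake_fit <- function(S, A, E, control_stage, prior = NULL) {
  if (is.null(prior)) prior <- connectivity_prior(S, correlation_valued = FALSE)
  structure(list(strengths = S, activities = A,
                 objective = sqrt(sum((E - S %*% A)^2)),
                 objective_trajectory = numeric(0), converged = TRUE,
                 n_iterations = 0L, best_restart = 1L, normalization = "none",
                 prior = prior, E = E, control_stage = control_stage,
                 norm_E = sqrt(sum(E^2)), call = NULL),
            class = "nca")
}

# Canonical gauge for a ground truth (same convention the estimator reports),
# so estimates and truth are compared in one gauge.
truth_canonical <- function(truth, convention = "control-zero") {
  f <- fake_fit(truth$prior$strengths, truth$activities,
                unclass(truth$expression)[truth$prior$gene_ids, , drop = FALSE],
                attr(truth$activities, "control_stage"), prior = truth$prior)
  normalize_nca(f, convention)
}

# Seeded random digraph edge list without self-loops or duplicates.
random_digraph <- function(n, m, seed = 1L) {
  set.seed(seed)
  pairs <- which(matrix(TRUE, n, n) & !diag(n) > 0, arr.ind = TRUE)
  pick <- pairs[sample.int(nrow(pairs), min(m, nrow(pairs))), , drop = FALSE]
  data.frame(from = sprintf("n%02d", pick[, 1]), to = sprintf("n%02d", pick[, 2]),
             stringsAsFactors = FALSE)
}

# Feed-forward background (edges only from lower to higher node index, so no
# reciprocal pairs) with FFLs planted on random ordered triples. Mirrors a
# TF hierarchy; keeps the planted FFL the only exotic 3-node structure.
planted_ffl_graph <- function(n, m_background, n_ffl, seed = 1L) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  pick <- pairs[sample.int(nrow(pairs), min(m_background, nrow(pairs))), ,
                drop = FALSE]
  edges <- pick
  for (i in seq_len(n_ffl)) {
    tri <- sort(sample.int(n, 3))
    edges <- rbind(edges,
                   cbind(tri[c(1, 1, 2)], tri[c(2, 3, 3)]))
  }
  edges <- unique(edges)
  data.frame(from = sprintf("n%02d", edges[, 1]), to = sprintf("n%02d", edges[, 2]),
             stringsAsFactors = FALSE)
}
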