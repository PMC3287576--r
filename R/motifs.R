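# --- internal graph representation -----------------------------------------
# Directed simple graph as an integer edge matrix plus node names. Self-loops
# are stripped (they are node attributes, not part of subgraph connectivity);
# duplicate edges are an error.
as_motif_graph <- function(graph) {
  if (inherits(graph, "motif_graph")) return(graph)
  if (inherits(graph, "regulatory_network")) {
    nodes <- graph$nodes$id
    from <- graph$edges$tf; to <- graph$edges$gene
    sign <- graph$edges$sign
  } else if (inherits(graph, "igraph")) {
    nodes <- igraph::V(graph)$name
    if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(graph)))
    el <- igraph::as_edgelist(graph, names = FALSE)
    from <- nodes[el[, 1]]; to <- nodes[el[, 2]]
    sign <- if ("sign" %in% igraph::edge_attr_names(graph))
      igraph::E(graph)$sign else rep(1L, length(from))
  } else if (is.data.frame(graph) || is.matrix(graph)) {
    graph <- as.data.frame(graph, stringsAsFactors = FALSE)
    if (ncol(graph) < 2) stop("edge table needs at least 2 columns (from, to)")
    from <- as.character(graph[[1]]); to <- as.character(graph[[2]])
    sign <- if (ncol(graph) >= 3 && is.numeric(graph[[3]]))
      as.integer(sign(graph[[3]])) else rep(1L, length(from))
    nodes <- sort(unique(c(from, to)))
  } else stop("unsupported graph input; use a regulatory_network, igraph, or edge table")
  sign[is.na(sign) | sign == 0] <- 1L
  fi <- match(from, nodes); ti <- match(to, nodes)
  loops <- fi == ti
  n_loops <- sum(loops)
  fi <- fi[!loops]; ti <- ti[!loops]; sign <- sign[!loops]
  key <- (fi - 1) * length(nodes) + ti
  if (anyDuplicated(key))
    stop("multigraph input: duplicate directed edge(s), e.g. ",
         nodes[fi[duplicated(key)][1]], " -> ", nodes[ti[duplicated(key)][1]])
  structure(list(nodes = nodes, from = fi, to = ti, sign = as.integer(sign),
                 n_self_loops = n_loops),
            class = "motif_graph")
}

motif_adjacency <- function(g) {
  n <- length(g$nodes)
  adj <- matrix(0L, n, n)
  adj[cbind(g$from, g$to)] <- g$sign
  adj
}

# undirected neighbor lists (union of both directions), sorted
neighbor_lists <- function(g) {
  n <- length(g$nodes)
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  pairs <- unique(rbind(cbind(g$from, g$to), cbind(g$to, g$from)))
  sp <- split(pairs[, 2], pairs[, 1])
  for (nm in names(sp)) nb[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
  nb
}

# --- canonical labelling -----------------------------------------------------
permutations_of <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    gen <- function(n) {
      if (n == 1L) return(matrix(1L))
      sub <- gen(n - 1L)
      do.call(rbind, lapply(seq_len(n), function(i) {
        rest <- setdiff(seq_len(n), i)
        cbind(i, matrix(rest[sub], nrow(sub)))
      }))
    }
    out <- gen(n)
    cache[[key]] <<- out
    out
  }
})

#' Canonical class label of a small directed (sub)graph
#'
#' The canonical label is the lexicographically minimal row-major adjacency
#' string over all `k!` node permutations (brute force; `k <= 5` so at most
#' 120 permutations). Isomorphic subgraphs always receive the same label.
#' With `signed = TRUE` edge signs enter the label (`1` positive, `2`
#' negative); otherwise any nonzero entry counts as `1`.
#'
#' @param adj k x k adjacency matrix (nonzero = edge; sign used when
#'   `signed = TRUE`); diagonal ignored.
#' @param signed include edge signs in the class label.
#' @return a character class label of length k*k over digits 0/1/2.
#' @export
motif_class <- function(adj, signed = FALSE) {
  k <- nrow(adj)
  if (k != ncol(adj) || k < 1 || k > 5) stop("adjacency must be k x k with k <= 5")
  m <- matrix(as.integer(adj != 0), k, k)
  if (signed) m[adj < 0] <- 2L
  diag(m) <- 0L
  perms <- permutations_of(k)
  best <- NULL
  for (p in seq_len(nrow(perms))) {
    q <- perms[p, ]
    s <- paste(t(m[q, q, drop = FALSE]), collapse = "")
    if (is.null(best) || s < best) best <- s
  }
  best
}

# cached canonicalization keyed on the raw pattern string
canonicalizer <- function(signed) {
  cache <- new.env(parent = emptyenv())
  function(m) {
    raw <- paste(m, collapse = "")
    hit <- cache[[raw]]
    if (!is.null(hit)) return(hit)
    lab <- motif_class(m, signed = signed)
    cache[[raw]] <- lab
    lab
  }
}

# --- ESU enumeration ---------------------------------------------------------

#' Enumerate connected induced subgraphs of size k
#'
#' Exhaustive, non-redundant enumeration (ESU): every connected induced
#' size-`k` subgraph is visited exactly once, classified by its canonical
#' label, and counted. Connectivity is taken on the underlying undirected
#' graph; self-loops are excluded.
#'
#' @param graph a `regulatory_network`, igraph, or edge table
#'   (from/to columns, optional numeric sign column).
#' @param k subgraph size, 3 to 5.
#' @param signed classify with edge signs (default `FALSE`: structural
#'   classes).
#' @return named integer vector of counts per canonical class, with
#'   attributes `k`, `total` (total connected size-k subgraphs) and `signed`.
#' @export
enumerate_subgraphs <- function(graph, k, signed = FALSE) {
  if (k < 3 || k > 5) stop("k must be 3, 4 or 5")
  g <- as_motif_graph(graph)
  n <- length(g$nodes)
  adj <- motif_adjacency(g)
  nb <- neighbor_lists(g)
  canon <- canonicalizer(signed)
  counts <- new.env(parent = emptyenv())
  record <- function(sub) {
    lab <- canon(adj[sub, sub, drop = FALSE])
    counts[[lab]] <- (if (is.null(counts[[lab]])) 0L else counts[[lab]]) + 1L
  }
  extend <- function(sub, ext, v, seen) {
    if (length(sub) == k - 1L) {
      for (w in ext) record(c(sub, w))
      return(invisible())
    }
    while (length(ext) > 0) {
      w <- ext[1]
      ext <- ext[-1]
      nw <- nb[[w]]
      excl <- nw[!seen[nw] & nw > v]
      seen2 <- seen
      seen2[nw] <- TRUE
      seen2[w] <- TRUE
      extend(c(sub, w), c(ext, excl), v, seen2)
    }
  }
  for (v in seq_len(n)) {
    nv <- nb[[v]]
    ext0 <- nv[nv > v]
    if (length(ext0) == 0 && k > 1) next
    seen <- logical(n)
    seen[nv] <- TRUE
    seen[v] <- TRUE
    extend(v, ext0, v, seen)
  }
  labs <- sort(ls(counts))
  out <- vapply(labs, function(l) counts[[l]], integer(1))
  structure(out, k = k, total = sum(out), signed = signed)
}

# --- degree-preserving randomization ----------------------------------------

#' Degree-preserving network randomization
#'
#' Randomizes a simple directed graph by repeated double-edge switches
#' (a->b, c->d becomes a->d, c->b), each applied only when it creates no
#' self-loop and no duplicate edge, so every draw preserves the in- and
#' out-degree sequences exactly. Edge signs travel with their source edge.
#' A graph admitting no legal switch (e.g. a single edge) is returned
#' unchanged.
#'
#' @param graph a `regulatory_network`, igraph, or edge table.
#' @param n_switch_attempts number of attempted switches; default
#'   `100 * n_edges`.
#' @param seed integer RNG seed.
#' @return data.frame with columns `from`, `to`, `sign` — the randomized edge
#'   list (accepted everywhere a graph input is).
#' @export
randomize_network <- function(graph, n_switch_attempts = NULL, seed = 1L) {
  g <- as_motif_graph(graph)
  m <- length(g$from)
  if (m < 2)
    return(data.frame(from = g$nodes[g$from], to = g$nodes[g$to],
                      sign = g$sign, stringsAsFactors = FALSE))
  if (is.null(n_switch_attempts)) n_switch_attempts <- 100L * m
  n <- length(g$nodes)
  from <- g$from; to <- g$to; sgn <- g$sign
  present <- logical(n * n)
  present[(from - 1L) * n + to] <- TRUE
  with_seed(seed, {
    e1s <- sample.int(m, n_switch_attempts, replace = TRUE)
    e2s <- sample.int(m, n_switch_attempts, replace = TRUE)
    for (a in seq_len(n_switch_attempts)) {
      i <- e1s[a]; j <- e2s[a]
      if (i == j) next
      f1 <- from[i]; t1 <- to[i]; f2 <- from[j]; t2 <- to[j]
      if (f1 == t2 || f2 == t1) next              # would create self-loop
      if (t1 == t2 || f1 == f2) next              # no-op swap
      k1 <- (f1 - 1L) * n + t2; k2 <- (f2 - 1L) * n + t1
      if (present[k1] || present[k2]) next        # would duplicate
      present[(f1 - 1L) * n + t1] <- FALSE
      present[(f2 - 1L) * n + t2] <- FALSE
      present[k1] <- TRUE
      present[k2] <- TRUE
      to[i] <- t2; to[j] <- t1
    }
  })
  data.frame(from = g$nodes[from], to = g$nodes[to], sign = sgn,
             stringsAsFactors = FALSE)
}

# --- significance ------------------------------------------------------------

#' Motif over-representation against a degree-preserving null
#'
#' Enumerates size-`k` connected subgraph classes in the observed network and
#' in `n_random` degree-preserving randomizations, and scores each class with
#' `z = (observed - null mean) / null sd` and the add-one empirical p-value
#' `p = (1 + #{null >= observed}) / (1 + n_random)` (so the smallest
#' attainable p is `1/(n_random + 1)` and p = 0 never occurs). Classes whose
#' null count never varies (`sd = 0`) get `z = NA`, reported as such.
#'
#' @inheritParams enumerate_subgraphs
#' @param n_random number of randomized networks (>= 2).
#' @param n_switch_attempts per-draw switch attempts (default `100 * edges`).
#' @param seed integer RNG seed.
#' @return an object of class `"motif_census"`: data.frame with columns
#'   `class`, `count`, `frequency` (percent of all size-k subgraphs, summing
#'   to 100), `null_mean`, `null_sd`, `z`, `p`; attributes `k`, `n_random`,
#'   `n_switch_attempts`, `seed`, `total`, `n_classes`.
#' @export
motif_significance <- function(graph, k, n_random = 1000L, seed = 1L,
                               n_switch_attempts = NULL, signed = FALSE) {
  if (n_random < 2) stop("`n_random` must be at least 2")
  g <- as_motif_graph(graph)
  obs <- enumerate_subgraphs(g, k, signed = signed)
  null_counts <- vector("list", n_random)
  for (b in seq_len(n_random)) {
    rb <- randomize_network(g, n_switch_attempts, seed = derive_seed(seed, b))
    null_counts[[b]] <- enumerate_subgraphs(rb, k, signed = signed)
  }
  classes <- sort(unique(c(names(obs), unlist(lapply(null_counts, names)))))
  obs_v <- stats::setNames(rep(0L, length(classes)), classes)
  obs_v[names(obs)] <- obs
  nulls <- matrix(0L, n_random, length(classes), dimnames = list(NULL, classes))
  for (b in seq_len(n_random)) nulls[b, names(null_counts[[b]])] <- null_counts[[b]]
  mu <- colMeans(nulls)
  sdv <- apply(nulls, 2, stats::sd)
  z <- ifelse(sdv == 0, NA_real_, (obs_v - mu) / sdv)
  p <- (1 + colSums(nulls >= matrix(obs_v, n_random, length(classes), byrow = TRUE))) /
    (1 + n_random)
  total <- sum(obs_v)
  out <- data.frame(class = classes, count = as.integer(obs_v),
                    frequency = if (total > 0) 100 * obs_v / total else 0 * obs_v,
                    null_mean = mu, null_sd = sdv, z = z, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$z, na.last = TRUE), , drop = FALSE]
  structure(out, k = k, n_random = n_random,
            n_switch_attempts = if (is.null(n_switch_attempts))
              100L * length(g$from) else n_switch_attempts,
            seed = seed, total = total, n_classes = length(classes),
            signed = signed, class = c("motif_census", "data.frame"))
}

#' @export
print.motif_census <- function(x, ...) {
  cat(sprintf("Motif census: size k=%d, %d subgraphs in %d classes, %d randomizations\n",
              attr(x, "k"), attr(x, "total"), attr(x, "n_classes"),
              attr(x, "n_random")))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4, row.names = FALSE)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more classes\n")
  invisible(x)
}

#' Write a motif census as TSV
#' @param census a `"motif_census"`.
#' @param path output file.
#' @export
write_motif_census <- function(census, path) {
  utils::write.table(as.data.frame(census), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
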