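#' Prior connectivity matrix (the NCA constraint set Z0)
#'
#' A sparse signed pattern linking transcription factors (columns) to target
#' genes (rows). The support pattern is the zero/nonzero constraint imposed on
#' the strength matrix during decomposition; the initial strengths are the
#' signed Pearson correlations used both as the starting point of the solver
#' and, by sign, as the regulatory mode of each edge.
#'
#' @param strengths numeric genes x TFs matrix, zero exactly off-support, with
#'   rownames (gene ids) and colnames (TF ids); `|strengths| <= 1` when
#'   `correlation_valued`.
#' @param correlation_valued if `TRUE` (default) the initial strengths are
#'   signed Pearson correlations and must satisfy `|strength| <= 1`; set
#'   `FALSE` for a ground-truth prior whose control strengths are free
#'   log-linear exponents.
#' @return an object of class `"connectivity_prior"` with fields `gene_ids`,
#'   `tf_ids`, `support` (logical matrix) and `strengths`.
#' @export
connectivity_prior <- function(strengths, correlation_valued = TRUE) {
  if (!is.matrix(strengths) || !is.numeric(strengths))
    stop("`strengths` must be a numeric matrix")
  if (is.null(rownames(strengths)) || is.null(colnames(strengths)))
    stop("`strengths` needs gene rownames and TF colnames")
  if (anyDuplicated(rownames(strengths)) || anyDuplicated(colnames(strengths)))
    stop("gene and TF identifiers must be unique")
  if (correlation_valued && max(abs(strengths)) > 1 + 1e-12)
    stop("initial strengths are correlation-valued; |strength| must not exceed 1 ",
         "(use correlation_valued = FALSE for free control strengths)")
  support <- strengths != 0
  if (any(colSums(support) == 0))
    stop("TF(s) with no targets: ", paste(colnames(strengths)[colSums(support) == 0], collapse = ", "))
  if (any(rowSums(support) == 0))
    stop("gene(s) with no regulator: ", paste(rownames(strengths)[rowSums(support) == 0], collapse = ", "))
  structure(list(gene_ids = rownames(strengths), tf_ids = colnames(strengths),
                 support = support, strengths = strengths),
            class = "connectivity_prior")
}

#' @export
print.connectivity_prior <- function(x, ...) {
  cat(sprintf("Connectivity prior: %d genes x %d TFs, %d edges (%.1f%% dense)\n",
              length(x$gene_ids), length(x$tf_ids), sum(x$support),
              100 * mean(x$support)))
  neg <- sum(x$strengths < 0)
  cat(sprintf("Signs: %d positive, %d negative edges\n", sum(x$support) - neg, neg))
  invisible(x)
}

#' @export
dim.connectivity_prior <- function(x) dim(x$support)

#' Read / write a prior as an edge-list TSV
#'
#' Columns `tf_id`, `gene_id`, `strength`; one row per nonzero entry.
#'
#' @param prior a `connectivity_prior`.
#' @param path file path.
#' @rdname prior_io
#' @export
write_prior <- function(prior, path) {
  idx <- which(prior$support, arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  df <- data.frame(tf_id = prior$tf_ids[idx[, 2]],
                   gene_id = prior$gene_ids[idx[, 1]],
                   strength = format(prior$strengths[idx], digits = 15, trim = TRUE,
                                     scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @details `read_prior()` orders genes and TFs lexicographically, so a
#'   written prior round-trips to identical matrices whenever its
#'   identifiers were sorted to begin with.
#' @rdname prior_io
#' @export
read_prior <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("tf_id", "gene_id", "strength") %in% names(df)))
    stop("prior edge list needs columns tf_id, gene_id, strength")
  tfs <- sort(unique(df$tf_id)); genes <- sort(unique(df$gene_id))
  m <- matrix(0, length(genes), length(tfs), dimnames = list(genes, tfs))
  m[cbind(match(df$gene_id, genes), match(df$tf_id, tfs))] <- df$strength
  connectivity_prior(m)
}

#' Pairwise Pearson correlation of gene expression profiles
#'
#' Correlation across stages for each pair of genes. Pairs involving a
#' constant profile have undefined correlation; these are reported and set to
#' zero so they can never seed an edge.
#'
#' @param E an `expression_matrix`.
#' @param genes gene identifiers to include (default: all).
#' @return symmetric correlation matrix with unit diagonal and a
#'   `constant_genes` attribute naming flat profiles.
#' @export
expression_correlation <- function(E, genes = rownames(E)) {
  if (length(genes) < 2) stop("need at least 2 genes to correlate")
  missing <- setdiff(genes, rownames(E))
  if (length(missing)) stop("genes absent from expression matrix: ",
                            paste(missing, collapse = ", "))
  if (ncol(E) < 3)
    stop("need at least 3 stages for a meaningful Pearson correlation")
  m <- unclass(E)[genes, , drop = FALSE]
  const <- genes[apply(m, 1, function(r) stats::sd(r) == 0)]
  r <- suppressWarnings(stats::cor(t(m)))
  r[is.na(r)] <- 0
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  attr(r, "constant_genes") <- const
  r
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of gene fold-change profiles on a correlation
#' distance. The default distance `1 - |r|` places strongly anti-correlated
#' genes together, which is what the sub-tree membership rule of the prior
#' builder needs (negative regulation is admitted); linkage defaults to
#' complete.
#'
#' @param E an `expression_matrix`.
#' @param genes gene identifiers to cluster (default: all).
#' @param linkage linkage method passed to [stats::hclust()].
#' @param distance `"abs_correlation"` (1 - |r|) or `"correlation"` (1 - r).
#' @return an object of class `"hclust"`.
#' @export
cluster_genes <- function(E, genes = rownames(E), linkage = "complete",
                          distance = c("abs_correlation", "correlation")) {
  distance <- match.arg(distance)
  if (length(genes) < 2) stop("need at least 2 genes to cluster")
  r <- expression_correlation(E, genes)
  if (length(attr(r, "constant_genes")) == length(genes))
    warning("all profiles are constant; distances are degenerate")
  d <- if (distance == "abs_correlation") 1 - abs(r) else 1 - r
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Build the coexpression prior
#'
#' A TF--gene edge enters the prior iff the absolute Pearson correlation of
#' their fold-change profiles exceeds `r_threshold` AND the two genes fall in
#' the same cluster when the dendrogram is cut at `cut_height` (the sub-tree
#' membership rule). The edge carries the signed correlation as its initial
#' control strength; anticorrelated pairs yield negative strengths. TFs may
#' appear as targets of other TFs, and a TF is trivially in its own sub-tree,
#' so self-edges (autoregulation candidates) are representable.
#'
#' @param E an `expression_matrix` (typically already DEG-filtered).
#' @param tf_ids transcription-factor identifiers; must be rows of `E`.
#' @param r_threshold absolute-correlation cutoff in (0, 1); default 0.9.
#' @param cut_height dendrogram cut height on the 1 - |r| scale; default 0.1,
#'   consistent with the 0.9 correlation cutoff.
#' @param include_self keep TF self-edges (default `TRUE`).
#' @return a `connectivity_prior`.
#' @export
build_prior <- function(E, tf_ids, r_threshold = 0.9, cut_height = 0.1,
                        include_self = TRUE) {
  if (r_threshold <= 0 || r_threshold >= 1) stop("`r_threshold` must be in (0, 1)")
  missing <- setdiff(tf_ids, rownames(E))
  if (length(missing)) stop("TF(s) absent from expression matrix: ",
                            paste(missing, collapse = ", "))
  genes <- rownames(E)
  r <- expression_correlation(E)
  cl <- stats::cutree(cluster_genes(E), h = cut_height)
  strengths <- matrix(0, length(genes), length(tf_ids),
                      dimnames = list(genes, tf_ids))
  for (tf in tf_ids) {
    keep <- abs(r[, tf]) > r_threshold & cl == cl[tf]
    if (!include_self) keep[tf] <- FALSE
    strengths[keep, tf] <- r[keep, tf]
  }
  strengths <- strengths[rowSums(strengths != 0) > 0, colSums(strengths != 0) > 0,
                         drop = FALSE]
  if (length(strengths) == 0 || nrow(strengths) == 0 || ncol(strengths) == 0)
    stop("empty prior support: no TF-gene pair satisfies the correlation and sub-tree rules")
  connectivity_prior(strengths)
}

# Generic (structural) rank of a 0/1 pattern: maximum rank over random
# fillings of the support with values bounded away from zero. The maximum over
# fillings equals the generic rank almost surely.
generic_rank <- function(support, n_fillings = 3L, rng) {
  if (length(support) == 0) return(0L)
  nz <- sum(support)
  if (nz == 0) return(0L)
  best <- 0L
  for (f in seq_len(n_fillings)) {
    vals <- (0.5 + rng(nz)) * ifelse(rng(nz) < 0.5, -1, 1)
    m <- matrix(0, nrow(support), ncol(support))
    m[support] <- vals
    best <- max(best, qr(m)$rank)
  }
  best
}

#' Check the NCA identifiability criteria
#'
#' The constrained decomposition `[E] = [S][A]` is unique (up to a diagonal
#' scaling gauge) only when the support topology satisfies three criteria:
#' (i) the connectivity pattern has full column rank L; (ii) removing any one
#' TF together with all genes it regulates leaves a pattern of full column
#' rank L - 1; (iii) the activity matrix can have full row rank, i.e.
#' L <= number of conditions. Ranks are assessed generically: the pattern is
#' filled with random nonzero values several times and the maximal numeric
#' rank is taken as the structural rank.
#'
#' @param prior a `connectivity_prior`.
#' @param n_conditions number of expression conditions (stages or profiles)
#'   available to the activity matrix.
#' @param n_fillings random fillings per rank assessment (>= 3 recommended).
#' @param seed seed for the random fillings (local; the global RNG state is
#'   untouched).
#' @return an object of class `"nca_identifiability"`: a list with `pass` and
#'   per-criterion detail, naming every violating TF for criterion (ii).
#' @export
check_identifiability <- function(prior, n_conditions, n_fillings = 3L, seed = 1L) {
  S <- prior$support
  L <- ncol(S)
  rng <- local_runif(seed)
  r1 <- generic_rank(S, n_fillings, rng)
  crit1 <- list(pass = r1 == L, rank = r1, required = L)
  failing <- character(0)
  ranks2 <- integer(0)
  for (j in seq_len(L)) {
    keep_rows <- !S[, j]
    sub <- S[keep_rows, -j, drop = FALSE]
    need <- L - 1L
    rk <- if (need == 0L) 0L else generic_rank(sub, n_fillings, rng)
    ranks2[prior$tf_ids[j]] <- rk
    if (rk < need) failing <- c(failing, prior$tf_ids[j])
  }
  crit2 <- list(pass = length(failing) == 0, failing_tfs = failing, ranks = ranks2)
  crit3 <- list(pass = L <= n_conditions, n_tfs = L, n_conditions = n_conditions)
  structure(list(pass = crit1$pass && crit2$pass && crit3$pass,
                 criterion_i = crit1, criterion_ii = crit2, criterion_iii = crit3),
            class = "nca_identifiability")
}

#' @export
print.nca_identifiability <- function(x, ...) {
  cat("NCA identifiability:", if (x$pass) "PASS" else "FAIL", "\n")
  cat(sprintf("  (i)  connectivity full column rank: %s (rank %d / %d)\n",
              x$criterion_i$pass, x$criterion_i$rank, x$criterion_i$required))
  cat(sprintf("  (ii) rank preserved under TF removal: %s%s\n", x$criterion_ii$pass,
              if (length(x$criterion_ii$failing_tfs))
                paste0(" (violated by ", paste(x$criterion_ii$failing_tfs, collapse = ", "), ")")
              else ""))
  cat(sprintf("  (iii) L <= conditions: %s (%d TFs, %d conditions)\n",
              x$criterion_iii$pass, x$criterion_iii$n_tfs, x$criterion_iii$n_conditions))
  invisible(x)
}

#' Reduce a prior to an identifiable subnetwork
#'
#' Greedy repair of a non-identifiable prior: while any criterion fails,
#' remove the TF whose deletion best reduces the remaining violations
#' (ties broken by fewest targets, then lexicographic TF id), drop genes left
#' with no regulator, and re-check. Mirrors the shrinkage from a large
#' coexpression prior to the identifiable subnetwork the solver can use.
#'
#' @inheritParams check_identifiability
#' @return the reduced `connectivity_prior` with attribute `removal_log`, a
#'   data.frame of removed TFs in order. Errors if nothing identifiable
#'   remains.
#' @export
reduce_to_identifiable <- function(prior, n_conditions, n_fillings = 3L, seed = 1L) {
  violation_score <- function(p) {
    rep_ <- check_identifiability(p, n_conditions, n_fillings, seed)
    (rep_$criterion_i$required - rep_$criterion_i$rank) +
      length(rep_$criterion_ii$failing_tfs) +
      max(0L, rep_$criterion_iii$n_tfs - n_conditions)
  }
  drop_tf <- function(p, tf) {
    s <- p$strengths[, setdiff(p$tf_ids, tf), drop = FALSE]
    s <- s[rowSums(s != 0) > 0, , drop = FALSE]
    if (nrow(s) == 0 || ncol(s) == 0) return(NULL)
    connectivity_prior(s)
  }
  log <- data.frame(tf_id = character(0), n_targets = integer(0), score_after = integer(0))
  current <- prior
  repeat {
    if (check_identifiability(current, n_conditions, n_fillings, seed)$pass) {
      attr(current, "removal_log") <- log
      return(current)
    }
    cand <- current$tf_ids
    scores <- vapply(cand, function(tf) {
      p2 <- drop_tf(current, tf)
      if (is.null(p2)) Inf else violation_score(p2)
    }, numeric(1))
    ntarg <- colSums(current$support)
    ord <- order(scores, ntarg, cand)
    pick <- cand[ord[1]]
    if (!is.finite(scores[ord[1]]))
      stop("no identifiable subnetwork remains after TF removal")
    log <- rbind(log, data.frame(tf_id = pick, n_targets = ntarg[[pick]],
                                 score_after = scores[[ord[1]]]))
    current <- drop_tf(current, pick)
    if (is.null(current))
      stop("no identifiable subnetwork remains after TF removal")
  }
}

# Seeded uniform generator that does not disturb the caller's RNG stream.
local_runif <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
}
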