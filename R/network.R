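#' Assign regulatory signs to fitted edges
#'
#' NCA itself does not decide the mode of regulation, so each supported edge
#' is signed by the Pearson correlation between the TF's own gene-expression
#' profile and the target's: positive correlation means activation, negative
#' means repression. An exactly-zero (or undefined) correlation falls back to
#' the sign of the fitted strength; such ties are flagged in the result.
#'
#' @param fit an `"nca"` object.
#' @param E an `expression_matrix` containing a row for every TF (TFs are
#'   themselves genes).
#' @return data.frame with columns `tf`, `gene`, `sign`, `correlation`,
#'   `strength`, `tie_break`.
#' @export
assign_edge_signs <- function(fit, E) {
  idx <- which(fit$prior$support, arr.ind = TRUE)
  tfs <- fit$prior$tf_ids[idx[, 2]]
  genes <- fit$prior$gene_ids[idx[, 1]]
  missing <- setdiff(unique(tfs), rownames(E))
  if (length(missing))
    stop("TF expression row(s) missing: ", paste(missing, collapse = ", "))
  m <- unclass(E)
  r <- vapply(seq_along(tfs), function(k) {
    x <- m[tfs[k], ]; y <- m[genes[k], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  strength <- fit$strengths[cbind(idx[, 1], idx[, 2])]
  sgn <- sign(r)
  tie <- is.na(sgn) | sgn == 0
  sgn[tie] <- sign(strength[tie])
  sgn[sgn == 0] <- 1
  out <- data.frame(tf = tfs, gene = genes, sign = as.integer(sgn),
                    correlation = r, strength = strength, tie_break = tie,
                    stringsAsFactors = FALSE)
  out[order(out$tf, out$gene), , drop = FALSE]
}

#' Cluster genes by their regulatory influence profiles
#'
#' Hierarchically clusters the gene rows of the adjusted (fitted) strength
#' matrix on a correlation distance with complete linkage, so that genes
#' sharing a regulator profile co-cluster even when their raw expression
#' patterns differ. This is the regulatory-context alternative to clustering
#' expression alone.
#'
#' @param strengths genes x TFs adjusted strength matrix (e.g.
#'   `coef(fit, "strengths")`).
#' @param k number of clusters, or `NULL` to cut by height.
#' @param h cut height on the 1 - r distance scale (used when `k` is `NULL`).
#' @return named integer vector of cluster labels (deterministic: labels
#'   follow [stats::cutree()] order), with the `"hclust"` tree as attribute
#'   `tree`.
#' @export
cluster_by_strength <- function(strengths, k = NULL, h = NULL) {
  if (nrow(strengths) < 2) stop("need at least 2 genes to cluster")
  if (!is.null(k) && k > nrow(strengths)) stop("more clusters than genes")
  r <- suppressWarnings(stats::cor(t(strengths)))
  r[is.na(r)] <- 0
  diag(r) <- 1
  tree <- stats::hclust(stats::as.dist(1 - r), method = "complete")
  cl <- if (!is.null(k)) stats::cutree(tree, k = k)
        else stats::cutree(tree, h = if (is.null(h)) 0.5 else h)
  attr(cl, "tree") <- tree
  cl
}

#' Agreement between TF activity and TF gene expression
#'
#' Pearson correlation between each TF's inferred activity trajectory and its
#' own gene-expression trajectory (both control-normalized), classified per
#' the conventional buckets: strong positive (r > 0.5), strong negative
#' (r < -0.5), otherwise weak; exactly 0.5 is weak. Constant trajectories
#' yield an undefined correlation, reported as such.
#'
#' @param fit an `"nca"` object.
#' @param E an `expression_matrix` containing the TF gene rows.
#' @return data.frame with columns `tf`, `r`, `class` (one of
#'   `"strong_positive"`, `"strong_negative"`, `"weak"`, `"undefined"`).
#' @export
tfa_expression_agreement <- function(fit, E) {
  tfs <- fit$prior$tf_ids
  missing <- setdiff(tfs, rownames(E))
  if (length(missing))
    stop("TF expression row(s) missing: ", paste(missing, collapse = ", "))
  m <- unclass(E)[tfs, colnames(fit$activities), drop = FALSE]
  r <- vapply(tfs, function(tf) {
    a <- fit$activities[tf, ]; e <- m[tf, ]
    if (stats::sd(a) == 0 || stats::sd(e) == 0) return(NA_real_)
    stats::cor(a, e)
  }, numeric(1))
  cls <- ifelse(is.na(r), "undefined",
         ifelse(r > 0.5, "strong_positive",
         ifelse(r < -0.5, "strong_negative", "weak")))
  data.frame(tf = tfs, r = r, class = cls, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Combinatorial TF pairs from activity correlation
#'
#' Unordered TF pairs whose activity trajectories correlate with
#' `|r| > threshold`; positively correlated pairs suggest cooperation,
#' negative ones antagonism. These are coactivity relations, not physical
#' interactions.
#'
#' @param activities L x M activity matrix (`coef(fit, "activities")`).
#' @param threshold absolute-correlation cutoff (default 0.5).
#' @return data.frame with columns `tf1`, `tf2`, `r`, sorted by decreasing
#'   `|r|`.
#' @export
combinatorial_pairs <- function(activities, threshold = 0.5) {
  L <- nrow(activities)
  if (L < 2) stop("need at least 2 TFs")
  r <- suppressWarnings(stats::cor(t(activities)))
  r[is.na(r)] <- 0
  idx <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  out <- data.frame(tf1 = rownames(activities)[idx[, 1]],
                    tf2 = rownames(activities)[idx[, 2]],
                    r = r[idx], stringsAsFactors = FALSE)
  out[order(-abs(out$r), out$tf1, out$tf2), , drop = FALSE]
}

#' Assemble the signed, stage-annotated regulatory network
#'
#' Merges the NCA-fitted signed edges with optional curated edges (e.g.
#' literature TF--TF relations), attaches per-stage expressed flags and
#' regulator-profile cluster labels, and computes node roles (`TF`, `target`,
#' or `both` for autoregulators / TF targets). A curated edge duplicating a
#' fitted edge collapses into one edge with provenance `"both"`; a curated
#' edge naming an unknown node adds that node with provenance `"curated"` and
#' a warning.
#'
#' @param fit an `"nca"` object.
#' @param E an `expression_matrix` with TF rows.
#' @param curated_edges optional data.frame (or TSV path) with columns `tf`,
#'   `gene` and optionally `sign`.
#' @param expressed_threshold optional absolute log2-ratio cutoff for the
#'   per-stage expressed flag; by default every observed value counts as
#'   expressed (detection calls are upstream of this package).
#' @param expressed_flags optional logical genes x stages matrix overriding
#'   the threshold rule.
#' @param cluster_k,cluster_h forwarded to [cluster_by_strength()].
#' @return an object of class `"regulatory_network"`: list with `nodes`,
#'   `edges`, `stage_expressed`, `clusters`.
#' @export
assemble_network <- function(fit, E, curated_edges = NULL,
                             expressed_threshold = NULL, expressed_flags = NULL,
                             cluster_k = NULL, cluster_h = NULL) {
  edges <- assign_edge_signs(fit, E)
  edges$provenance <- "NCA"
  if (!is.null(curated_edges)) {
    if (is.character(curated_edges))
      curated_edges <- utils::read.table(curated_edges, header = TRUE, sep = "\t",
                                         stringsAsFactors = FALSE)
    if (!all(c("tf", "gene") %in% names(curated_edges)))
      stop("curated edges need columns `tf` and `gene`")
    known <- c(edges$tf, edges$gene, rownames(E))
    unknown <- setdiff(c(curated_edges$tf, curated_edges$gene), known)
    if (length(unknown))
      warning("curated edge(s) name node(s) unknown to the fit/expression: ",
              paste(unknown, collapse = ", "), "; added with provenance 'curated'")
    for (i in seq_len(nrow(curated_edges))) {
      hit <- edges$tf == curated_edges$tf[i] & edges$gene == curated_edges$gene[i]
      if (any(hit)) {
        edges$provenance[hit] <- "both"
      } else {
        edges <- rbind(edges, data.frame(
          tf = curated_edges$tf[i], gene = curated_edges$gene[i],
          sign = if ("sign" %in% names(curated_edges))
            as.integer(curated_edges$sign[i]) else NA_integer_,
          correlation = NA_real_, strength = NA_real_, tie_break = FALSE,
          provenance = "curated", stringsAsFactors = FALSE))
      }
    }
  }
  tf_nodes <- unique(edges$tf)
  target_nodes <- unique(edges$gene)
  ids <- union(tf_nodes, target_nodes)
  role <- ifelse(ids %in% tf_nodes & ids %in% target_nodes, "both",
          ifelse(ids %in% tf_nodes, "TF", "target"))
  node_prov <- ifelse(ids %in% c(fit$prior$tf_ids, fit$prior$gene_ids), "NCA", "curated")
  nodes <- data.frame(id = ids, role = role, provenance = node_prov,
                      stringsAsFactors = FALSE)
  present <- intersect(ids, rownames(E))
  flags <- matrix(NA, length(ids), ncol(E), dimnames = list(ids, colnames(E)))
  if (!is.null(expressed_flags)) {
    flags[rownames(expressed_flags), colnames(expressed_flags)] <- expressed_flags
  } else if (!is.null(expressed_threshold)) {
    flags[present, ] <- abs(unclass(E)[present, , drop = FALSE]) > expressed_threshold
  } else {
    flags[present, ] <- TRUE
  }
  clusters <- cluster_by_strength(fit$strengths, k = cluster_k, h = cluster_h)
  structure(list(nodes = nodes, edges = edges, stage_expressed = flags,
                 clusters = clusters, control_stage = fit$control_stage),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("Regulatory network: %d nodes (%d TFs, %d pure targets, %d both), %d edges\n",
              nrow(x$nodes), sum(x$nodes$role == "TF"), sum(x$nodes$role == "target"),
              sum(x$nodes$role == "both"), nrow(x$edges)))
  prov <- table(x$edges$provenance)
  cat("Edge provenance:", paste(sprintf("%s=%d", names(prov), prov), collapse = ", "), "\n")
  sgn <- table(factor(x$edges$sign, levels = c(-1, 1)))
  cat(sprintf("Signs: %s positive, %s negative; %d clusters\n",
              sgn["1"], sgn["-1"], length(unique(x$clusters))))
  invisible(x)
}

#' Convert a regulatory network to an igraph object
#' @param net a `"regulatory_network"`.
#' @return a directed [igraph::igraph] with node/edge attributes (role,
#'   provenance, sign, strength, cluster, per-stage expressed flags).
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = net$nodes)
  cl <- net$clusters[igraph::V(g)$name]
  igraph::V(g)$cluster <- ifelse(is.na(cl), -1L, cl)
  for (stg in colnames(net$stage_expressed)) {
    v <- net$stage_expressed[igraph::V(g)$name, stg]
    igraph::vertex_attr(g, paste0("expressed_", stg)) <- ifelse(is.na(v), FALSE, v)
  }
  g
}

#' Write a network as SIF / GraphML / cluster TSV
#'
#' SIF rows are `tf <sign> gene` with the sign (`1` / `-1`, `NA` for unsigned
#' curated edges) as the relation; GraphML carries all node and edge
#' attributes via igraph.
#'
#' @param net a `"regulatory_network"`.
#' @param path output file.
#' @rdname network_io
#' @export
write_network_sif <- function(net, path) {
  lines <- sprintf("%s\t%s\t%s", net$edges$tf,
                   ifelse(is.na(net$edges$sign), "NA", net$edges$sign),
                   net$edges$gene)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname network_io
#' @export
write_network_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::E(g)$sign[is.na(igraph::E(g)$sign)] <- 0L
  igraph::E(g)$strength[is.na(igraph::E(g)$strength)] <- 0
  igraph::E(g)$correlation[is.na(igraph::E(g)$correlation)] <- 0
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname network_io
#' @export
write_clusters_tsv <- function(net, path) {
  df <- data.frame(gene_id = names(net$clusters),
                   cluster = as.integer(net$clusters))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
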