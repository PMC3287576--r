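#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end reconstruction with the conventional
#' defaults: fold-change filter 1.6 (linear scale), coexpression prior cutoff
#' |r| > 0.9 with sub-tree cut height 0.1, TF-pair coactivity cutoff 0.5, and
#' the solver/motif settings. All thresholds are overridable.
#'
#' @param expression path to an expression TSV, or an `expression_matrix`.
#' @param tf_ids character vector of TF gene identifiers, or path to a
#'   one-column text file.
#' @param control_stage control stage label.
#' @param out_dir output directory for artifacts.
#' @param curated_edges optional curated edge TSV path or data.frame.
#' @param fc_threshold,r_threshold,tf_corr_threshold,cut_height thresholds.
#' @param tol,max_iter,n_restarts solver settings (see [nca()]).
#' @param n_boot bootstrap draws (0 disables the stability step).
#' @param motif_sizes motif sizes to census (subset of 3:5).
#' @param n_random randomizations per motif size.
#' @param cluster_h strength-clustering cut height.
#' @param seed master seed; all stage seeds derive from it.
#' @return a validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expression, tf_ids, control_stage, out_dir,
                            curated_edges = NULL,
                            fc_threshold = 1.6, r_threshold = 0.9,
                            tf_corr_threshold = 0.5, cut_height = 0.1,
                            tol = 1e-8, max_iter = 1000L, n_restarts = 10L,
                            n_boot = 0L, motif_sizes = 3L, n_random = 200L,
                            cluster_h = 0.5, seed = 1L) {
  stopifnot(fc_threshold > 1, r_threshold > 0, r_threshold < 1,
            tf_corr_threshold >= 0, tf_corr_threshold <= 1,
            cut_height > 0, cut_height < 1, tol > 0, max_iter >= 1,
            n_restarts >= 1, n_boot >= 0, all(motif_sizes %in% 3:5),
            n_random >= 2)
  if (is.character(tf_ids) && length(tf_ids) == 1 && file.exists(tf_ids))
    tf_ids <- readLines(tf_ids)
  structure(list(expression = expression, tf_ids = tf_ids,
                 control_stage = control_stage, out_dir = out_dir,
                 curated_edges = curated_edges, fc_threshold = fc_threshold,
                 r_threshold = r_threshold, tf_corr_threshold = tf_corr_threshold,
                 cut_height = cut_height, tol = tol, max_iter = max_iter,
                 n_restarts = n_restarts, n_boot = n_boot,
                 motif_sizes = motif_sizes, n_random = n_random,
                 cluster_h = cluster_h, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end reconstruction
#'
#' Executes the full workflow: differential-expression filter, coexpression
#' prior (correlation + sub-tree rule), identifiability reduction, the
#' constrained ALS decomposition with gauge normalization, edge signing,
#' regulator-profile clustering, combinatorial-pair inference, network
#' assembly with exports (SIF, GraphML, clusters TSV) and the motif census.
#' Every artifact is written under `config$out_dir` and listed with an MD5
#' content hash in `manifest.json`, together with the configuration, the
#' derived stage seeds and per-stage funnel counts (genes/TFs/edges in and
#' out), so the reduction from the raw coexpression prior to the identifiable
#' subnetwork is auditable. A rerun with the same config and seed produces
#' byte-identical numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    artifacts <<- c(artifacts, path)
    path
  }
  stage <- "load_expression"
  manifest <- list(config = config[setdiff(names(config), c("expression", "curated_edges"))],
                   counts = list())
  result <- tryCatch({
    E <- if (inherits(config$expression, "expression_matrix")) config$expression
         else read_expression(config$expression, config$control_stage)
    manifest$counts$genes_in <- nrow(E)
    say("loaded %d genes x %d stages", nrow(E), ncol(E))

    stage <- "filter_degs"
    degs <- filter_degs(E, config$fc_threshold)
    tfs <- intersect(config$tf_ids, degs)
    if (length(tfs) == 0) stop("no TF passes the differential-expression filter")
    Ed <- expression_matrix(unclass(E)[degs, , drop = FALSE], config$control_stage)
    manifest$counts$degs <- length(degs)
    manifest$counts$tfs_deg <- length(tfs)
    emit("degs.txt", function(p) writeLines(degs, p))
    say("DEG filter |FC|>%g: %d genes (%d TFs) retained", config$fc_threshold,
        length(degs), length(tfs))

    stage <- "build_prior"
    prior <- build_prior(Ed, tfs, r_threshold = config$r_threshold,
                         cut_height = config$cut_height)
    manifest$counts$prior_tfs <- length(prior$tf_ids)
    manifest$counts$prior_genes <- length(prior$gene_ids)
    manifest$counts$prior_edges <- sum(prior$support)
    emit("prior.tsv", function(p) write_prior(prior, p))
    say("coexpression prior: %d TFs, %d genes, %d edges", length(prior$tf_ids),
        length(prior$gene_ids), sum(prior$support))

    stage <- "reduce_to_identifiable"
    prior_id <- reduce_to_identifiable(prior, n_conditions = ncol(Ed))
    removal <- attr(prior_id, "removal_log")
    manifest$counts$identifiable_tfs <- length(prior_id$tf_ids)
    manifest$counts$identifiable_genes <- length(prior_id$gene_ids)
    manifest$counts$identifiable_edges <- sum(prior_id$support)
    manifest$counts$removed_tfs <- nrow(removal)
    emit("prior_identifiable.tsv", function(p) write_prior(prior_id, p))
    emit("removed_tfs.tsv", function(p)
      utils::write.table(removal, p, sep = "\t", quote = FALSE, row.names = FALSE))
    say("identifiable subnetwork: %d TFs, %d genes (%d TFs removed)",
        length(prior_id$tf_ids), length(prior_id$gene_ids), nrow(removal))

    stage <- "decompose"
    fit <- nca(Ed, prior_id, max_iter = config$max_iter, tol = config$tol,
               n_restarts = config$n_restarts,
               seed = derive_seed(config$seed, 10L))
    manifest$counts$objective <- fit$objective
    manifest$counts$converged <- fit$converged
    emit("strengths.tsv", function(p) {
      df <- data.frame(gene_id = rownames(fit$strengths),
                       apply(fit$strengths, 2, function(col)
                         format(col, digits = 15, trim = TRUE, scientific = FALSE)),
                       check.names = FALSE)
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
    emit("activities.tsv", function(p) {
      df <- data.frame(tf_id = rownames(fit$activities),
                       apply(fit$activities, 2, function(col)
                         format(col, digits = 15, trim = TRUE, scientific = FALSE)),
                       check.names = FALSE)
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
    say("NCA objective %.4g (converged: %s)", fit$objective, fit$converged)

    stage <- "bootstrap"
    if (config$n_boot > 0) {
      bs <- nca_bootstrap(Ed, prior_id, n_boot = config$n_boot,
                          seed = derive_seed(config$seed, 20L), fit = fit)
      emit("bootstrap_activity_intervals.tsv", function(p) {
        df <- data.frame(tf_id = rep(rownames(bs$activity_lower),
                                     ncol(bs$activity_lower)),
                         stage = rep(colnames(bs$activity_lower),
                                     each = nrow(bs$activity_lower)),
                         lower = as.vector(bs$activity_lower),
                         upper = as.vector(bs$activity_upper))
        utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      })
    }

    stage <- "network_assembly"
    pairs <- combinatorial_pairs(fit$activities, config$tf_corr_threshold)
    agreement <- tfa_expression_agreement(fit, Ed)
    net <- assemble_network(fit, Ed, curated_edges = config$curated_edges,
                            cluster_h = config$cluster_h)
    manifest$counts$network_nodes <- nrow(net$nodes)
    manifest$counts$network_edges <- nrow(net$edges)
    manifest$counts$clusters <- length(unique(net$clusters))
    manifest$counts$combinatorial_pairs <- nrow(pairs)
    emit("network.sif", function(p) write_network_sif(net, p))
    emit("network.graphml", function(p) write_network_graphml(net, p))
    emit("clusters.tsv", function(p) write_clusters_tsv(net, p))
    emit("tf_pairs.tsv", function(p)
      utils::write.table(pairs, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("tfa_agreement.tsv", function(p)
      utils::write.table(agreement, p, sep = "\t", quote = FALSE, row.names = FALSE))
    say("network: %d nodes, %d edges, %d clusters, %d TF pairs",
        nrow(net$nodes), nrow(net$edges), length(unique(net$clusters)),
        nrow(pairs))

    stage <- "motif_census"
    for (k in config$motif_sizes) {
      census <- motif_significance(net, k = k, n_random = config$n_random,
                                   seed = derive_seed(config$seed, 30L + k))
      manifest$counts[[sprintf("motif_k%d_total", k)]] <- attr(census, "total")
      manifest$counts[[sprintf("motif_k%d_classes", k)]] <- attr(census, "n_classes")
      emit(sprintf("motifs_k%d.tsv", k), function(p) write_motif_census(census, p))
      say("motif census k=%d: %d subgraphs in %d classes", k,
          attr(census, "total"), attr(census, "n_classes"))
    }
    list(fit = fit, network = net, prior = prior, prior_identifiable = prior_id)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest$seed <- config$seed
  manifest$stage_seeds <- list(nca = derive_seed(config$seed, 10L),
                               bootstrap = derive_seed(config$seed, 20L),
                               motifs = lapply(stats::setNames(
                                 as.list(config$motif_sizes),
                                 paste0("k", config$motif_sizes)),
                                 function(k) derive_seed(config$seed, 30L + k)))
  manifest$files <- as.list(tools::md5sum(artifacts))
  names(manifest$files) <- basename(artifacts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(c(manifest, result))
}

#' Simulate a truth bundle to disk
#'
#' Thin wrapper over [simulate_truth()] + [write_truth_bundle()]: generates a
#' seeded ground-truth bundle (identifiable prior, stage-peaked activities,
#' noisy log-linear expression) and writes it with its manifest.
#'
#' @param dir output directory.
#' @param ... passed to [simulate_truth()].
#' @return the `synthetic_truth`, invisibly.
#' @export
simulate_to_dir <- function(dir, ...) {
  truth <- simulate_truth(...)
  write_truth_bundle(truth, dir)
  invisible(truth)
}
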