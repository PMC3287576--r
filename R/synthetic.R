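#' Generate a random identifiable prior topology
#'
#' Rejection-samples a sparse signed genes x TFs connectivity pattern until it
#' passes the topological identifiability criteria (i) and (ii) of
#' [check_identifiability()] (criterion (iii) involves the stage count, which
#' the topology alone does not know; [simulate_truth()] checks it with the
#' real stage count). Each gene receives `edges_per_gene` distinct regulators,
#' every TF is guaranteed at least one target, and nonzero strengths are drawn
#' uniformly from `strength_range` in magnitude with a `sign_fraction` share
#' negative.
#'
#' @param n_genes,n_tfs numbers of genes and TFs; `n_genes >= n_tfs >= 1`.
#' @param edges_per_gene regulators per gene; `1 <= edges_per_gene <= n_tfs`.
#'   Note `edges_per_gene = n_tfs` with `n_tfs >= 2` is infeasible: deleting
#'   any TF then deletes every gene and criterion (ii) can never hold.
#' @param strength_range magnitude interval for nonzero strengths, within (0, 1].
#' @param sign_fraction expected fraction of negative edges.
#' @param seed integer RNG seed.
#' @param max_attempts rejection-sampling cap (default 1000).
#' @return a `connectivity_prior` that passes criteria (i) and (ii).
#' @export
generate_prior_topology <- function(n_genes, n_tfs, edges_per_gene,
                                    strength_range = c(0.5, 0.95),
                                    sign_fraction = 0.3, seed = 1L,
                                    max_attempts = 1000L) {
  if (n_genes < n_tfs || n_tfs < 1) stop("need n_genes >= n_tfs >= 1")
  if (edges_per_gene < 1 || edges_per_gene > n_tfs)
    stop("need 1 <= edges_per_gene <= n_tfs")
  if (min(strength_range) <= 0 || max(strength_range) > 1)
    stop("`strength_range` magnitudes must lie in (0, 1]")
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      support <- matrix(FALSE, n_genes, n_tfs, dimnames = list(gene_ids, tf_ids))
      for (i in seq_len(n_genes))
        support[i, sample.int(n_tfs, edges_per_gene)] <- TRUE
      # guarantee TF coverage: move one edge of a multi-regulator gene
      for (j in which(colSums(support) == 0)) {
        donor <- which(rowSums(support) > 1)[1]
        if (is.na(donor)) donor <- sample.int(n_genes, 1)
        drop_from <- which(support[donor, ])[1]
        if (rowSums(support)[donor] > 1) support[donor, drop_from] <- FALSE
        support[donor, j] <- TRUE
      }
      nz <- sum(support)
      mags <- stats::runif(nz, min(strength_range), max(strength_range))
      signs <- ifelse(stats::runif(nz) < sign_fraction, -1, 1)
      strengths <- matrix(0, n_genes, n_tfs, dimnames = list(gene_ids, tf_ids))
      strengths[support] <- mags * signs
      prior <- connectivity_prior(strengths)
      if (check_identifiability(prior, n_conditions = n_tfs)$pass)
        return(prior)
    }
    stop("no identifiable topology found in ", max_attempts,
         " attempts; parameters are likely infeasible (e.g. edges_per_gene = n_tfs)")
  })
}

#' Generate stage-resolved TF activity trajectories
#'
#' Emits an L x M matrix of log2 TF-activity ratios over ordered developmental
#' stages, normalized so the control-stage column is exactly zero. Three
#' pattern families are available: `"single-peak"` (a smooth bump with one
#' interior maximum at a random non-control stage, emulating stage-specific
#' activation), `"monotone"` (steady up- or down-regulation across the
#' course), and `"flat"` (all zeros). These are statistical stand-ins for
#' developmental activation patterns, not biophysical simulations.
#'
#' @param n_tfs number of TFs (rows).
#' @param stage_labels ordered stage labels (columns).
#' @param control_stage label of the control stage; must occur in
#'   `stage_labels`.
#' @param peak_model one of `"single-peak"`, `"monotone"`, `"flat"`.
#' @param amplitude bound on `max(abs(value))` per row (log2 units).
#' @param seed integer RNG seed.
#' @param tf_ids optional row identifiers (default `TF01`, `TF02`, ...).
#' @return numeric matrix with a `control_stage` attribute.
#' @export
generate_tf_activities <- function(n_tfs, stage_labels, control_stage,
                                   peak_model = c("single-peak", "monotone", "flat"),
                                   amplitude = 2, seed = 1L, tf_ids = NULL) {
  peak_model <- match.arg(peak_model)
  if (!control_stage %in% stage_labels)
    stop("control stage '", control_stage, "' not among stage labels")
  M <- length(stage_labels)
  if (is.null(tf_ids)) tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  ctrl <- match(control_stage, stage_labels)
  A <- matrix(0, n_tfs, M, dimnames = list(tf_ids, stage_labels))
  if (peak_model == "flat") {
    attr(A, "control_stage") <- control_stage
    return(A)
  }
  with_seed(seed, {
    t <- seq_len(M)
    for (j in seq_len(n_tfs)) {
      if (peak_model == "single-peak") {
        candidates <- setdiff(2:(M - 1), ctrl)
        if (M < 3 || length(candidates) == 0)
          stop("single-peak model needs an interior non-control stage (M >= 4, or M = 3 with control at an end)")
        p <- candidates[sample.int(length(candidates), 1)]
        w <- stats::runif(1, 0.8, 1.6)
        amp <- stats::runif(1, 0.5, 1) * amplitude
        row <- amp * exp(-(t - p)^2 / (2 * w^2))
      } else {
        amp <- stats::runif(1, 0.5, 1) * amplitude * sample(c(-1, 1), 1)
        row <- amp * (t - 1) / (M - 1)
      }
      A[j, ] <- row - row[ctrl]
    }
  })
  # control-normalized rows stay within the amplitude bound by construction
  attr(A, "control_stage") <- control_stage
  A
}

#' Generate expression from the log-linear regulation model
#'
#' Under the log-linear (Hill-cooperation) model, each gene's linear-scale
#' expression ratio is a product of TF activity ratios raised to their control
#' strengths; on the log2 scale this is the matrix product
#' `strengths %*% activities`. Measurement noise is additive Gaussian on the
#' log2 scale (multiplicative log-normal on the linear scale) in every
#' non-control stage; the control column is exactly zero because the control
#' ratio is 1 by definition.
#'
#' @param prior a `connectivity_prior` holding the true strengths.
#' @param activities L x M activity matrix with a `control_stage` attribute
#'   (rows must match `prior$tf_ids`).
#' @param noise_sd standard deviation of the additive log2 noise (>= 0).
#' @param seed integer RNG seed.
#' @return an `expression_matrix`.
#' @export
generate_expression <- function(prior, activities, noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  if (ncol(prior$strengths) != nrow(activities) ||
      !identical(prior$tf_ids, rownames(activities)))
    stop("TF dimension mismatch between prior and activities")
  ctrl <- attr(activities, "control_stage")
  if (is.null(ctrl)) stop("`activities` lacks a control_stage attribute")
  E <- prior$strengths %*% activities
  if (noise_sd > 0) {
    noisy <- setdiff(colnames(E), ctrl)
    with_seed(seed, {
      E[, noisy] <- E[, noisy] + stats::rnorm(length(E[, noisy]), sd = noise_sd)
    })
  }
  expression_matrix(E, ctrl)
}

#' Simulate a complete ground-truth bundle
#'
#' Convenience wrapper tying the three generators together: an identifiable
#' prior, stage-peaked activities and noisy log-linear expression, all derived
#' deterministically from one master seed.
#'
#' @inheritParams generate_prior_topology
#' @inheritParams generate_tf_activities
#' @inheritParams generate_expression
#' @param check_conditions if `TRUE` (default) also require criterion (iii),
#'   `n_tfs <= length(stage_labels)`.
#' @param tf_as_genes if `TRUE` (default), each TF's own transcript is part
#'   of the expression matrix as an autoregulated gene row (self-edge of
#'   strength 1, so its log2 expression ratio equals the TF's log2 activity
#'   ratio plus noise). TFs are genes, and the coexpression prior builder and
#'   the edge-sign rule both need their transcript profiles; the resulting
#'   identity block also makes the topological criteria (i)-(ii) hold by
#'   construction.
#' @return an object of class `"synthetic_truth"`: list with `prior` (the
#'   true support and strengths, including TF self-rows when
#'   `tf_as_genes = TRUE`), `activities`, `expression`, `noise_sd`, `seed`,
#'   `params`. With `noise_sd = 0` the expression equals
#'   `prior$strengths %*% activities` exactly.
#' @export
simulate_truth <- function(n_genes = 100, n_tfs = 10,
                           stage_labels = c("UNM", "BCP", "TCP", "MP", "HP", "PT05", "PT4"),
                           control_stage = "MP", edges_per_gene = 3,
                           peak_model = "single-peak", amplitude = 2,
                           strength_range = c(0.5, 0.95), sign_fraction = 0.3,
                           noise_sd = 0, seed = 1L, check_conditions = TRUE,
                           tf_as_genes = TRUE) {
  if (check_conditions && n_tfs > length(stage_labels))
    stop("criterion (iii): n_tfs must not exceed the number of stages (",
         length(stage_labels), ")")
  prior <- generate_prior_topology(n_genes, n_tfs, edges_per_gene,
                                   strength_range, sign_fraction,
                                   seed = derive_seed(seed, 1L))
  if (tf_as_genes) {
    self_block <- diag(1, n_tfs)
    dimnames(self_block) <- list(prior$tf_ids, prior$tf_ids)
    prior <- connectivity_prior(rbind(prior$strengths, self_block))
  }
  activities <- generate_tf_activities(n_tfs, stage_labels, control_stage,
                                       peak_model, amplitude,
                                       seed = derive_seed(seed, 2L),
                                       tf_ids = prior$tf_ids)
  expr <- generate_expression(prior, activities, noise_sd,
                              seed = derive_seed(seed, 3L))
  structure(list(prior = prior, activities = activities, expression = expr,
                 noise_sd = noise_sd, seed = seed,
                 params = list(n_genes = n_genes, n_tfs = n_tfs,
                               stage_labels = stage_labels,
                               control_stage = control_stage,
                               edges_per_gene = edges_per_gene,
                               peak_model = peak_model, amplitude = amplitude,
                               strength_range = strength_range,
                               sign_fraction = sign_fraction,
                               tf_as_genes = tf_as_genes)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth bundle: %d genes, %d TFs, %d stages (control '%s')\n",
              nrow(x$expression), nrow(x$activities), ncol(x$expression),
              control_stage(x$expression)))
  cat(sprintf("Edges: %d; noise sd (log2): %g; seed: %d\n",
              sum(x$prior$support), x$noise_sd, x$seed))
  invisible(x)
}

#' Write / read a truth bundle directory
#'
#' The bundle directory holds `expression.tsv` (the dialect
#' [read_expression()] consumes), `prior.tsv` (edge-list TSV),
#' `activities.tsv`, and `manifest.json` recording the seed, parameters and
#' per-file MD5 hashes.
#'
#' @param truth a `synthetic_truth`.
#' @param dir output directory (created if absent).
#' @rdname truth_bundle
#' @export
write_truth_bundle <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(truth$expression, file.path(dir, "expression.tsv"))
  write_prior(truth$prior, file.path(dir, "prior.tsv"))
  act <- truth$activities
  df <- data.frame(tf_id = rownames(act),
                   apply(act, 2, function(col) format(col, digits = 15, trim = TRUE,
                                                      scientific = FALSE)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, "activities.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c("expression.tsv", "prior.tsv", "activities.tsv")
  manifest <- list(seed = truth$seed, noise_sd = truth$noise_sd,
                   params = truth$params,
                   files = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @param dir bundle directory written by [write_truth_bundle()].
#' @rdname truth_bundle
#' @export
read_truth_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  ctrl <- manifest$params$control_stage
  expr <- read_expression(file.path(dir, "expression.tsv"), ctrl)
  prior <- read_prior(file.path(dir, "prior.tsv"))
  adf <- utils::read.table(file.path(dir, "activities.tsv"), header = TRUE,
                           sep = "\t", check.names = FALSE)
  act <- as.matrix(adf[, -1, drop = FALSE])
  rownames(act) <- adf[[1]]
  attr(act, "control_stage") <- ctrl
  structure(list(prior = prior, activities = act, expression = expr,
                 noise_sd = manifest$noise_sd, seed = manifest$seed,
                 params = manifest$params),
            class = "synthetic_truth")
}
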