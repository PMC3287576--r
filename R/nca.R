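#' Network component analysis by constrained alternating least squares
#'
#' Decomposes a genes x stages log2-ratio expression matrix `[E]` into a
#' control-strength matrix `[S]` (genes x TFs, constrained to the prior
#' support `Z0`) and a hidden TF-activity matrix `[A]` (TFs x stages) by
#' minimizing the Frobenius objective `||E - S A||_F` subject to `S` being
#' zero off-support. The solution of this constrained factorization is unique
#' up to a diagonal scaling gauge provided the prior passes the
#' identifiability criteria, which are verified before any fitting starts.
#'
#' The solver alternates exact least-squares steps: with `A` fixed, each
#' gene's supported strengths are the LS solution of its own small system;
#' with `S` fixed, `A` is the unrestricted LS solution. Each half-step can
#' only decrease the objective, so the recorded trajectory is nonincreasing.
#' Restart 1 starts from the prior's correlation-valued strengths (the
#' coexpression starting point); the remaining restarts draw standard-normal
#' activity matrices, and the best final objective wins.
#'
#' @param E an [expression_matrix()] whose rows include every prior gene.
#' @param prior a [connectivity_prior()]; must be identifiable for `ncol(E)`
#'   conditions.
#' @param max_iter maximum full (S-step, A-step) iterations per restart.
#' @param tol relative objective-change convergence tolerance.
#' @param n_restarts number of initializations (>= 1).
#' @param seed integer seed for the random restarts.
#' @param normalization gauge convention applied to the winner:
#'   `"control-zero"` (default; see [normalize_nca()]),
#'   `"unit-activity-norm"`, or `"none"`.
#' @return an object of class `"nca"`: list with `strengths` (N x L),
#'   `activities` (L x M), `objective` (final Frobenius residual),
#'   `objective_trajectory`, `converged`, `n_iterations`, `best_restart`,
#'   `normalization`, `prior`, `E`, `control_stage`, `call`.
#' @seealso [normalize_nca()], [nca_bootstrap()], [reconstruction_error()]
#' @examples
#' truth <- simulate_truth(n_genes = 30, n_tfs = 4, noise_sd = 0, seed = 7)
#' fit <- nca(truth$expression, truth$prior, n_restarts = 2, seed = 7)
#' fit
#' range(residuals(fit))
#' @export
nca <- function(E, prior, max_iter = 1000L, tol = 1e-8, n_restarts = 10L,
                seed = 1L,
                normalization = c("control-zero", "unit-activity-norm", "none")) {
  normalization <- match.arg(normalization)
  if (!inherits(E, "expression_matrix")) stop("`E` must be an expression_matrix")
  missing <- setdiff(prior$gene_ids, rownames(E))
  if (length(missing))
    stop("expression matrix lacks prior gene(s): ", paste(missing, collapse = ", "))
  Emat <- unclass(E)[prior$gene_ids, , drop = FALSE]
  M <- ncol(Emat)
  report <- check_identifiability(prior, n_conditions = M)
  if (!report$pass)
    stop("prior is not identifiable for ", M, " conditions; run ",
         "reduce_to_identifiable() first.\n",
         paste(utils::capture.output(print(report)), collapse = "\n"))
  support <- prior$support
  L <- ncol(support)

  runs <- vector("list", n_restarts)
  runs[[1]] <- nca_core(Emat, prior, A0 = NULL, max_iter = max_iter, tol = tol)
  if (n_restarts > 1) {
    inits <- with_seed(seed, lapply(seq_len(n_restarts - 1L), function(r)
      matrix(stats::rnorm(L * M), L, M,
             dimnames = list(colnames(support), colnames(Emat)))))
    for (r in seq_len(n_restarts - 1L))
      runs[[r + 1L]] <- nca_core(Emat, prior, inits[[r]], max_iter, tol)
  }
  norm_E <- sqrt(sum(Emat^2))
  finals <- vapply(runs, function(r) r$traj[length(r$traj)], numeric(1))
  best <- which.min(finals)
  win <- runs[[best]]

  fit <- structure(list(strengths = win$S, activities = win$A,
                        objective = finals[best],
                        objective_trajectory = win$traj,
                        converged = win$converged, n_iterations = win$it,
                        best_restart = best, normalization = "none",
                        prior = prior, E = Emat,
                        control_stage = control_stage(E),
                        norm_E = norm_E, call = match.call()),
                   class = "nca")
  if (normalization != "none") fit <- normalize_nca(fit, convention = normalization)
  fit
}

#' Fix the scaling gauge of an NCA solution
#'
#' The factorization `[E] = [S][A] = [S][X][X^-1][A]` is invariant under any
#' nonsingular diagonal `[X]` (only diagonal matrices preserve the support
#' constraint), so a convention is needed to report one canonical solution.
#'
#' `"control-zero"` fixes the gauge completely: each activity row is shifted
#' so its control-stage entry is 0 on the log2 scale (the shift is numerically
#' zero after a least-squares activity step, because the control column of
#' `[E]` is zero), the sign of each TF is flipped so its strength column
#' correlates nonnegatively with the prior's initial strengths, and the
#' magnitude is fixed by scaling each strength column to unit Euclidean norm.
#' `"unit-activity-norm"` instead puts unit Euclidean norm on each activity
#' row (magnitudes live in the strengths), with the same sign rule. Both
#' conventions are idempotent and leave the product `S %*% A` unchanged to
#' numerical precision.
#'
#' @param fit an `"nca"` object.
#' @param convention `"control-zero"` or `"unit-activity-norm"`.
#' @return the `"nca"` object in canonical gauge.
#' @export
normalize_nca <- function(fit, convention = c("control-zero", "unit-activity-norm")) {
  convention <- match.arg(convention)
  S <- fit$strengths
  A <- fit$activities
  if (convention == "control-zero") {
    ctrl <- fit$control_stage
    if (!ctrl %in% colnames(A)) stop("control stage '", ctrl, "' absent from activities")
    A <- A - A[, ctrl]          # numerically ~0 shift; exact-zeroes the column
  }
  for (j in seq_len(ncol(S))) {
    sgn <- sign(sum(S[, j] * fit$prior$strengths[, j]))
    if (sgn == 0) sgn <- 1
    scale <- if (convention == "control-zero") sqrt(sum(S[, j]^2))
             else sqrt(sum(A[j, ]^2))
    if (scale == 0)
      stop("cannot normalize: TF '", colnames(S)[j],
           if (convention == "control-zero") "' has an all-zero strength column"
           else "' has an all-zero activity row")
    if (convention == "control-zero") {
      S[, j] <- S[, j] * sgn / scale
      A[j, ] <- A[j, ] * sgn * scale
    } else {
      A[j, ] <- A[j, ] * sgn / scale
      S[, j] <- S[, j] * sgn * scale
    }
  }
  fit$strengths <- S
  fit$activities <- A
  fit$normalization <- convention
  fit
}

#' Frobenius reconstruction error of an NCA fit
#'
#' @param fit an `"nca"` object.
#' @param E optional `expression_matrix` to evaluate against (defaults to the
#'   fitted data).
#' @return list with `frobenius` (the Eq.-style objective `||E - S A||_F`)
#'   and `per_gene` row-wise residual norms.
#' @export
reconstruction_error <- function(fit, E = NULL) {
  Emat <- if (is.null(E)) fit$E else unclass(E)[rownames(fit$strengths), , drop = FALSE]
  if (!identical(dim(Emat), dim(fit$E))) stop("dimension mismatch")
  R <- Emat - fit$strengths %*% fit$activities
  list(frobenius = sqrt(sum(R^2)),
       per_gene = sqrt(rowSums(R^2)))
}

#' @export
print.nca <- function(x, ...) {
  cat(sprintf("NCA fit: %d genes x %d TFs x %d stages (control '%s')\n",
              nrow(x$strengths), ncol(x$strengths), ncol(x$activities),
              x$control_stage))
  cat(sprintf("Objective ||E - SA||_F = %.4g (%.3g relative to ||E||_F)\n",
              x$objective, x$objective / max(x$norm_E, .Machine$double.eps)))
  cat(sprintf("Converged: %s after %d iterations (winning restart %d); gauge: %s\n",
              x$converged, x$n_iterations, x$best_restart, x$normalization))
  invisible(x)
}

#' @export
summary.nca <- function(object, ...) {
  err <- reconstruction_error(object)
  act_range <- t(apply(object$activities, 1, range))
  colnames(act_range) <- c("min", "max")
  out <- list(dims = c(genes = nrow(object$strengths), tfs = ncol(object$strengths),
                       stages = ncol(object$activities)),
              objective = object$objective, relative_objective =
                object$objective / max(object$norm_E, .Machine$double.eps),
              converged = object$converged, n_iterations = object$n_iterations,
              normalization = object$normalization,
              activity_range = act_range,
              per_gene_residual = summary(err$per_gene),
              edges = sum(object$prior$support))
  class(out) <- "summary.nca"
  out
}

#' @export
print.summary.nca <- function(x, ...) {
  cat(sprintf("NCA decomposition of %d genes x %d stages onto %d TFs (%d supported edges)\n",
              x$dims["genes"], x$dims["stages"], x$dims["tfs"], x$edges))
  cat(sprintf("Objective %.4g (relative %.3g); converged: %s (%d iterations); gauge: %s\n",
              x$objective, x$relative_objective, x$converged, x$n_iterations,
              x$normalization))
  cat("Activity ranges (log2):\n")
  print(round(x$activity_range, 3))
  cat("Per-gene residual norms:\n")
  print(x$per_gene_residual)
  invisible(x)
}

#' @param object,x an `"nca"` fit.
#' @param which `"strengths"` for the genes x TFs control-strength matrix,
#'   `"activities"` for the TFs x stages activity matrix.
#' @rdname nca
#' @export
coef.nca <- function(object, which = c("strengths", "activities"), ...) {
  which <- match.arg(which)
  object[[which]]
}

#' @export
fitted.nca <- function(object, ...) object$strengths %*% object$activities

#' @export
residuals.nca <- function(object, ...) object$E - fitted(object)

#' @param activities optional replacement activity matrix (L x stages) for
#'   which to predict log2 expression; defaults to the fitted activities.
#' @rdname nca
#' @export
predict.nca <- function(object, activities = NULL, ...) {
  if (is.null(activities)) return(fitted(object))
  if (nrow(activities) != ncol(object$strengths))
    stop("`activities` must have one row per TF")
  object$strengths %*% activities
}

#' @param nsim,seed see [stats::simulate()].
#' @param noise_sd log2-scale noise standard deviation for the replicates.
#' @rdname nca
#' @export
simulate.nca <- function(object, nsim = 1, seed = NULL, noise_sd = 0.1, ...) {
  if (is.null(seed)) seed <- 1L
  mu <- fitted(object)
  ctrl <- object$control_stage
  noisy <- setdiff(colnames(mu), ctrl)
  with_seed(seed, lapply(seq_len(nsim), function(s) {
    E <- mu
    E[, noisy] <- E[, noisy] + stats::rnorm(length(E[, noisy]), sd = noise_sd)
    expression_matrix(E, ctrl, require_control = FALSE)
  }))
}

#' @param ... passed to [graphics::matplot()].
#' @rdname nca
#' @export
plot.nca <- function(x, ...) {
  A <- x$activities
  graphics::matplot(t(A), type = "b", lty = 1, pch = 16, xaxt = "n",
                    xlab = "developmental stage", ylab = "log2 TF activity ratio",
                    main = "Inferred TF activities", ...)
  graphics::axis(1, at = seq_len(ncol(A)), labels = colnames(A))
  graphics::abline(h = 0, lty = 3, col = "grey50")
  graphics::legend("topleft", legend = rownames(A), col = seq_len(nrow(A)),
                   lty = 1, pch = 16, cex = 0.7, bty = "n")
  invisible(x)
}

#' Bootstrap stability of an NCA fit
#'
#' Resamples genes with replacement, refits the constrained decomposition on
#' each resample (initialized from the reference activities, so every refit
#' lands in the reference basin), re-fixes the gauge with the reference
#' convention, and returns percentile intervals for every supported strength
#' and every activity value. Draws whose resampled support fails the
#' identifiability check are rejected and redrawn (bounded retries); if fewer
#' than half of `n_boot` draws succeed the procedure aborts.
#'
#' @param E an `expression_matrix`.
#' @param prior an identifiable `connectivity_prior`.
#' @param n_boot number of bootstrap draws.
#' @param seed integer RNG seed.
#' @param level central interval coverage (default 0.95).
#' @param fit optional reference `"nca"` fit (computed if omitted).
#' @param ... passed to [nca()] for the reference fit.
#' @return list with `strength_lower`/`strength_upper` (N x L, `NA` where a
#'   gene never entered a successful draw), `activity_lower`/`activity_upper`
#'   (L x M), `level`, `n_boot`, `n_failed`, and the reference `fit`.
#' @export
nca_bootstrap <- function(E, prior, n_boot = 100L, seed = 1L, level = 0.95,
                          fit = NULL, ...) {
  if (is.null(fit)) fit <- nca(E, prior, seed = seed, ...)
  Emat <- fit$E
  N <- nrow(Emat); M <- ncol(Emat)
  genes <- rownames(Emat)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  draws_S <- vector("list", n_boot)
  draws_A <- vector("list", n_boot)
  n_failed <- 0L
  idx_list <- with_seed(seed, {
    out <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      ok <- FALSE
      for (try in 1:20) {
        idx <- sort(sample.int(N, N, replace = TRUE))
        sub <- prior$strengths[idx, , drop = FALSE]
        keep_tf <- colSums(sub != 0) > 0
        if (!all(keep_tf)) { n_failed <- n_failed + 1L; next }
        rownames(sub) <- sprintf("%s.%d", genes[idx], seq_along(idx))
        p <- connectivity_prior(sub)
        if (check_identifiability(p, n_conditions = M)$pass) { ok <- TRUE; break }
        n_failed <- n_failed + 1L
      }
      out[[b]] <- if (ok) idx else NULL
    }
    out
  })
  ok_draws <- !vapply(idx_list, is.null, logical(1))
  if (sum(ok_draws) < n_boot / 2)
    stop("fewer than half of the bootstrap draws produced an identifiable support")
  for (b in which(ok_draws)) {
    idx <- idx_list[[b]]
    Eb <- Emat[idx, , drop = FALSE]
    rownames(Eb) <- sprintf("%s.%d", genes[idx], seq_along(idx))
    pb <- connectivity_prior(structure(prior$strengths[idx, , drop = FALSE],
                                       dimnames = list(rownames(Eb), prior$tf_ids)))
    Eb_x <- expression_matrix(Eb, fit$control_stage, require_control = FALSE)
    attr(Eb_x, "control_stage") <- fit$control_stage
    fb <- nca_refit(Eb_x, pb, fit$activities, align_to = fit$activities)
    # map resampled rows back: first occurrence of each gene
    first <- !duplicated(idx)
    Sb <- matrix(NA_real_, N, ncol(fb$strengths), dimnames = dimnames(prior$strengths))
    Sb[idx[first], ] <- fb$strengths[first, , drop = FALSE]
    draws_S[[b]] <- Sb
    draws_A[[b]] <- fb$activities
  }
  arr_S <- simplify2array(draws_S[ok_draws])
  arr_A <- simplify2array(draws_A[ok_draws])
  qfun <- function(v) if (all(is.na(v))) c(NA_real_, NA_real_) else
    stats::quantile(v, probs, na.rm = TRUE, names = FALSE)
  qS <- apply(arr_S, c(1, 2), qfun)
  qA <- apply(arr_A, c(1, 2), qfun)
  dn_S <- dimnames(prior$strengths)
  dn_A <- dimnames(fit$activities)
  slice <- function(q, i, dn) structure(q[i, , ], dimnames = dn)
  list(strength_lower = slice(qS, 1, dn_S), strength_upper = slice(qS, 2, dn_S),
       activity_lower = slice(qA, 1, dn_A), activity_upper = slice(qA, 2, dn_A),
       level = level, n_boot = n_boot, n_successful = sum(ok_draws),
       n_failed_draws = n_failed, fit = fit)
}

# Single-start ALS refit used by the bootstrap: warm-started at the reference
# activities so the resampled solution stays in the reference gauge basin, then
# aligned to the reference by the per-TF diagonal gauge (least-squares scalar
# per activity row). A convention-based normalization would not do here: its
# unit-column-norm scale depends on which genes a resample drew, so draws
# would sit in incomparable gauges.
nca_refit <- function(E, prior, A0, align_to = NULL, max_iter = 500L, tol = 1e-8) {
  fit <- nca_core(unclass(E), prior, A0, max_iter, tol)
  S <- fit$S; A <- fit$A
  if (!is.null(align_to)) {
    for (j in seq_len(nrow(A))) {
      denom <- sum(A[j, ]^2)
      cj <- if (denom == 0) 1 else sum(A[j, ] * align_to[j, ]) / denom
      if (cj == 0) cj <- 1
      A[j, ] <- A[j, ] * cj
      S[, j] <- S[, j] / cj
    }
  }
  structure(list(strengths = S, activities = A,
                 objective = fit$traj[length(fit$traj)],
                 objective_trajectory = fit$traj, converged = fit$converged,
                 n_iterations = fit$it, best_restart = 1L,
                 normalization = "reference-aligned", prior = prior,
                 E = unclass(E), control_stage = attr(E, "control_stage"),
                 norm_E = sqrt(sum(unclass(E)^2)), call = NULL),
            class = "nca")
}

# The ALS loop. Genes sharing a support pattern are solved as one
# least-squares system with a matrix right-hand side (normal equations on the
# at-most-LxL Gram matrix, QR fallback for the rank-deficient case), which is
# what keeps the per-iteration cost linear in the number of distinct patterns
# rather than the number of genes. `A0 = NULL` starts from the prior's
# correlation-valued strengths (the coexpression initialization).
nca_core <- function(Emat, prior, A0, max_iter, tol) {
  support <- prior$support
  N <- nrow(support); L <- ncol(support)
  norm_E <- sqrt(sum(Emat^2))
  key <- apply(support, 1, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(N), key)
  group_J <- lapply(groups, function(rows) which(support[rows[1], ]))

  tEmat <- t(Emat)
  s_step <- function(A) {
    S <- matrix(0, N, L, dimnames = dimnames(support))
    G <- tcrossprod(A)                # L x L Gram of activity rows
    H <- A %*% tEmat                  # L x N cross products, shared by groups
    for (g in seq_along(groups)) {
      rows <- groups[[g]]; J <- group_J[[g]]
      cf <- tryCatch(solve(G[J, J, drop = FALSE], H[J, rows, drop = FALSE]),
                     error = function(e) {
        out <- qr.coef(qr(t(A[J, , drop = FALSE])),
                       t(Emat[rows, , drop = FALSE]))
        out[is.na(out)] <- 0
        out
      })
      S[rows, J] <- t(cf)
    }
    S
  }
  a_step <- function(S) {
    A <- tryCatch(solve(crossprod(S), crossprod(S, Emat)), error = function(e) {
      out <- qr.coef(qr(S), Emat)
      out[is.na(out)] <- 0
      out
    })
    rownames(A) <- colnames(support)
    A
  }

  if (is.null(A0)) {
    S <- prior$strengths
    A <- a_step(S)
  } else {
    A <- A0
    S <- s_step(A)
  }
  traj <- sqrt(sum((Emat - S %*% A)^2))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    S <- s_step(A)
    A <- a_step(S)
    obj <- sqrt(sum((Emat - S %*% A)^2))
    traj <- c(traj, obj)
    prev <- traj[length(traj) - 1L]
    # converged when the relative improvement stalls, or at an (essentially
    # exact) fit where relative change is no longer meaningful
    if (abs(prev - obj) <= tol * max(prev, .Machine$double.eps) ||
        obj <= 1e-13 * max(norm_E, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  list(S = S, A = A, traj = traj, converged = converged, it = it)
}
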