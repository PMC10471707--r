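#' @title Block-wise PCA and Gaussian-mixture clustering of light responses
#' @name clustermod
#' @description
#' Reduces per-cell response vectors block by block (each step segment,
#' the chirp, and each spectral kernel is its own block), retaining per
#' block the minimal number of principal components explaining at least
#' half the variance, then clusters the concatenated scores with a
#' Gaussian mixture model. Four covariance structures are explored
#' (shared/unshared x diagonal/full), each with replicate random
#' initialisations; the final model minimises BIC. Clusters are merged by
#' similarity of their mean response traces and small clusters discarded.
NULL

#' Block-wise PCA feature reduction
#'
#' Applies PCA separately to each named response block and retains, per
#' block, the minimal number of leading components whose cumulative
#' explained variance reaches `min_var`; the per-block scores are
#' concatenated into one feature matrix.
#'
#' @param blocks Named list of numeric matrices (cells x variables), one
#'   per stimulus block; all with the same row count.
#' @param min_var Cumulative explained-variance threshold (default 0.5).
#' @return List with `scores` (cells x total components), `n_components`
#'   (named per block), `bases` (per-block rotation matrices).
#' @export
block_pca <- function(blocks, min_var = 0.5) {
  stopifnot(length(blocks) >= 1)
  n_cells <- unique(vapply(blocks, nrow, integer(1)))
  stopifnot(length(n_cells) == 1)
  scores <- list()
  n_comp <- integer(length(blocks))
  names(n_comp) <- names(blocks)
  bases <- vector("list", length(blocks))
  names(bases) <- names(blocks)
  for (b in seq_along(blocks)) {
    m <- as.matrix(blocks[[b]])
    vars <- apply(m, 2, stats::var)
    if (all(vars == 0)) {
      n_comp[b] <- 0L
      next
    }
    pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    ve <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    k <- which(ve >= min_var)[1]
    n_comp[b] <- k
    scores[[length(scores) + 1]] <- pc$x[, seq_len(k), drop = FALSE]
    bases[[b]] <- pc$rotation[, seq_len(k), drop = FALSE]
  }
  list(scores = do.call(cbind, scores), n_components = n_comp, bases = bases)
}

# mclust model names for the four covariance structures
.gmm_structures <- c(shared_diagonal = "EEI", unshared_diagonal = "VVI",
                     shared_full = "EEE", unshared_full = "VVV")

#' Fit a Gaussian mixture model over covariance structures
#'
#' For each of the four covariance structures (shared-diagonal,
#' unshared-diagonal, shared-full, unshared-full), runs EM from
#' `n_replicates` random initialisations (random hard assignments), keeps
#' the replicate with the largest log-likelihood, and finally selects the
#' structure minimising BIC.
#'
#' @param scores Cells x features matrix (from [block_pca()]).
#' @param k Number of mixture components (default 100).
#' @param structures Covariance structures to explore (default all four).
#' @param n_replicates Random initialisations per structure (default 20).
#' @param max_iter EM iteration cap (default 1e4).
#' @param seed Integer seed.
#' @return A `cluster_model`: list with `assignments`, `structure`,
#'   `k`, `bic` (named, all structures), `loglik`, `parameters`,
#'   `posterior`.
#' @export
fit_gmm <- function(scores, k = 100, structures = names(.gmm_structures),
                    n_replicates = 20, max_iter = 1e4, seed = 1) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stopifnot(n > k)
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  ctrl <- mclust::emControl(itmax = max_iter)
  best <- NULL
  bics <- stats::setNames(rep(NA_real_, length(structures)), structures)
  for (s in structures) {
    mname <- .gmm_structures[[s]]
    best_ll <- -Inf
    best_fit <- NULL
    for (rep_i in seq_len(n_replicates)) {
      # random hard initial assignment with every component non-empty
      cl <- sample(rep_len(seq_len(k), n))
      z <- mclust::unmap(cl, groups = seq_len(k))
      me_fun <- get(paste0("me", mname), envir = asNamespace("mclust"))
      fit <- tryCatch(
        suppressWarnings(me_fun(data = scores, z = z, control = ctrl)),
        error = function(e) NULL
      )
      if (is.null(fit) || is.null(fit$loglik) || !is.finite(fit$loglik)) next
      if (fit$loglik > best_ll) {
        best_ll <- fit$loglik
        best_fit <- fit
      }
    }
    if (is.null(best_fit)) next
    bic_s <- as.numeric(mclust::bic(mname, best_ll, n, ncol(scores), k))
    bics[s] <- -bic_s  # mclust BIC is "larger is better"; store standard sign
    if (is.null(best) || bics[s] < best$bic_value) {
      best <- list(fit = best_fit, structure = s, bic_value = bics[s])
    }
  }
  if (is.null(best)) stop("no GMM replicate converged", call. = FALSE)
  post <- best$fit$z
  structure(
    list(assignments = apply(post, 1, which.max),
         structure = best$structure, k = k, bic = bics,
         loglik = best$fit$loglik, parameters = best$fit$parameters,
         posterior = post),
    class = "cluster_model"
  )
}

#' Merge mixture components by mean-response similarity
#'
#' An automated surrogate for curation by eye: components are merged by
#' complete-linkage agglomerative clustering on the correlation distance
#' (1 - r) between their concatenated mean response traces, cut at
#' `1 - min_cor`.
#'
#' @param assignments Integer component per cell.
#' @param responses Cells x variables matrix of concatenated response
#'   traces (the traces the curation would inspect).
#' @param min_cor Correlation threshold for merging (default 0.9);
#'   `min_cor = 1` performs no merging.
#' @return Integer vector of merged labels (consecutive from 1), same
#'   order as `sort(unique(assignments))` groups.
#' @export
merge_clusters <- function(assignments, responses, min_cor = 0.9) {
  responses <- as.matrix(responses)
  comp <- sort(unique(assignments))
  means <- t(vapply(comp, function(cc) {
    colMeans(responses[assignments == cc, , drop = FALSE])
  }, numeric(ncol(responses))))
  if (length(comp) == 1 || min_cor >= 1) {
    merged_of <- stats::setNames(seq_along(comp), comp)
  } else {
    cors <- suppressWarnings(stats::cor(t(means)))
    cors[!is.finite(cors)] <- 0
    d <- stats::as.dist(1 - cors)
    hc <- stats::hclust(d, method = "complete")
    merged_of <- stats::setNames(stats::cutree(hc, h = 1 - min_cor), comp)
  }
  unname(merged_of[as.character(assignments)])
}

#' Retention filter on merged clusters
#'
#' Clusters with fewer than `min_members` cells are discarded; their cells
#' are marked unassigned (NA).
#'
#' @param labels Integer cluster label per cell.
#' @param min_members Minimum cluster size (default 20; a cluster of
#'   exactly 20 is retained).
#' @return List with `labels` (NA for discarded cells), `retained`
#'   (retained cluster ids), `dropped`.
#' @export
retention_filter <- function(labels, min_members = 20) {
  tab <- table(labels)
  retained <- as.integer(names(tab)[tab >= min_members])
  dropped <- as.integer(names(tab)[tab < min_members])
  out <- ifelse(labels %in% retained, labels, NA_integer_)
  list(labels = out, retained = retained, dropped = dropped)
}
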