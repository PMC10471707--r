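#' @title End-to-end analysis pipeline
#' @name pipeline
#' @description
#' Orchestrates the full analysis on a dataset of spike responses to the
#' four stimuli: quality filtering, rate traces, response indices, spectral
#' kernels, chirp analysis, block-PCA + GMM clustering, response-group
#' assignment, and a run report of per-stage counts and group percentages.
NULL

#' Default pipeline configuration
#'
#' All thresholds applied by [run_pipeline()], with their defaults: the
#' signal-to-noise quality threshold (0.4) for step and chirp responses,
#' the kernel clustering-quality threshold (2.5), the GMM size and merge
#' correlation, the minimum cluster size (20), and the group-assignment
#' polarity cut (1/3).
#'
#' @param k Number of GMM components.
#' @param seed Random seed for the run.
#' @param ... Overrides for individual entries.
#' @return A named list of configuration values.
#' @export
pipeline_config <- function(k = 8, seed = 1, ...) {
  cfg <- list(
    qi_threshold = 0.4,
    kernel_quality_threshold = 2.5,
    k = k,
    gmm_replicates = 5,
    merge_min_cor = 0.9,
    min_members = 20,
    polarity_cut = 1 / 3,
    kernel_step_s = 0.02,
    opponency_step_s = 0.005,
    opponency_amp_threshold = 3,
    seed = seed
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

# Per-repeat KDE response matrix (time x repeats) for the SNR quality index.
repeat_kde_matrix <- function(spike_times, duration_s, n_repeats,
                              n_points = 200, bandwidth = 0.05) {
  rep_idx <- pmin(n_repeats, floor(spike_times / duration_s) + 1L)
  within <- spike_times - (rep_idx - 1) * duration_s
  vapply(seq_len(n_repeats), function(r) {
    sp <- within[rep_idx == r]
    if (length(sp) < 2) return(numeric(n_points))
    stats::density(sp, bw = bandwidth, from = 0, to = duration_s,
                   n = n_points)$y
  }, numeric(n_points))
}

#' Assign a cell to a response group
#'
#' Automated surrogate for per-cluster assignment by inspection: Off when
#' `PI <= -cut`, On when `PI >= +cut` (split into transient and sustained
#' by the sign of the colour-step transience index), OnOff otherwise.
#'
#' @param pi Polarity index.
#' @param ti_cs Colour-step transience index (splits the On group).
#' @param cut Polarity cut (default 1/3).
#' @return One of "Off", "OnOff", "On_transient", "On_sustained", or NA.
#' @export
assign_response_group <- function(pi, ti_cs, cut = 1 / 3) {
  if (is.na(pi) || is.nan(pi)) return(NA_character_)
  if (pi <= -cut) return("Off")
  if (pi >= cut) {
    if (!is.na(ti_cs) && ti_cs < 0) return("On_sustained")
    return("On_transient")
  }
  "OnOff"
}

#' Group percentages from counts
#'
#' `100 * count / denominator`, rounded to one decimal.
#'
#' @param counts Named integer vector of group sizes.
#' @param denominator Total cell count (> 0).
#' @return Named numeric vector of percentages.
#' @export
group_percentages <- function(counts, denominator) {
  if (denominator <= 0) stop("denominator must be positive", call. = FALSE)
  round(100 * counts / denominator, 1)
}

#' Conduction-velocity comparison between response groups
#'
#' One-tailed Wilcoxon rank-sum tests for the stated pairings (Off vs
#' OnOff, Off vs On, OnOff vs On), with the transient and sustained On
#' groups pooled.
#'
#' @param velocities Numeric conduction velocities, m/s.
#' @param groups Response-group label per velocity.
#' @return data.frame per pairing: `comparison`, `n1`, `n2`, `p_value`
#'   (alternative: first group faster).
#' @export
velocity_group_comparison <- function(velocities, groups) {
  pool <- ifelse(groups %in% c("On_transient", "On_sustained"), "On", groups)
  pairings <- list(c("Off", "OnOff"), c("Off", "On"), c("OnOff", "On"))
  rows <- lapply(pairings, function(pr) {
    v1 <- velocities[pool == pr[1]]
    v2 <- velocities[pool == pr[2]]
    if (length(v1) < 2 || length(v2) < 2) return(NULL)
    p <- suppressWarnings(
      stats::wilcox.test(v1, v2, alternative = "greater")$p.value
    )
    data.frame(comparison = paste(pr, collapse = " vs "),
               n1 = length(v1), n2 = length(v2), p_value = p)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Run the full analysis pipeline on a fixture-style dataset
#'
#' Stages: per-stimulus quality indices and the retain-if-any-passes
#' filter; KDE rate traces; step amplitudes and polarity/transience
#' indices; spectral kernels with amplitude and opponency; chirp
#' high-frequency index; block-PCA + GMM clustering with merge and
#' retention; response-group assignment; run report.
#'
#' @param dataset A dataset as returned by [generate_fixture_dataset()]:
#'   list with `timelines` (ws, cs, chirp, noise) and `spikes` (spike
#'   tables per stimulus).
#' @param config From [pipeline_config()].
#' @return A `pipeline_run`: list with `features` (per-cell data.frame),
#'   `cluster_model`, `merged_labels`, `retention`, `report`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  tl <- dataset$timelines
  sp <- dataset$spikes
  cell_ids <- sort(unique(unlist(lapply(sp, function(s) unique(s$cell_id)))))
  n_raw <- length(cell_ids)
  spikes_of <- function(tabl, id) tabl$time_s[tabl$cell_id == id]
  n_rep <- list(ws = attr(sp$ws, "n_repeats"), cs = attr(sp$cs, "n_repeats"),
                chirp = attr(sp$chirp, "n_repeats"))

  feats <- list()
  traces <- list()
  kern_list <- list()
  for (id in cell_ids) {
    ws_sp <- spikes_of(sp$ws, id)
    cs_sp <- spikes_of(sp$cs, id)
    ch_sp <- spikes_of(sp$chirp, id)
    nz_sp <- spikes_of(sp$noise, id)

    qi_ws <- snr_quality_index(repeat_kde_matrix(ws_sp, tl$ws$duration_s, n_rep$ws))
    qi_cs <- snr_quality_index(repeat_kde_matrix(cs_sp, tl$cs$duration_s, n_rep$cs))
    qi_ch <- snr_quality_index(repeat_kde_matrix(ch_sp, tl$chirp$duration_s,
                                                 n_rep$chirp))
    kern <- compute_kernel(nz_sp, tl$noise, step_s = config$kernel_step_s)
    kq <- if (kern$n_spikes > 0) kernel_clustering_quality(kern$z) else 0

    amp_ws <- response_amplitudes(ws_sp, tl$ws, n_rep$ws)
    amp_cs <- response_amplitudes(cs_sp, tl$cs, n_rep$cs)
    ws100_on <- amp_ws[amp_ws$kind == "WS_on" & amp_ws$parameter == 1, ]
    ws100_off <- amp_ws[amp_ws$kind == "WS_off" & amp_ws$parameter == 1, ]
    pi_v <- suppressWarnings(polarity_index(ws100_on$a_mean, ws100_off$a_mean))
    ti_on <- suppressWarnings(transience_index(ws100_on$a_tr, ws100_on$a_sus))
    ti_off <- suppressWarnings(transience_index(ws100_off$a_tr, ws100_off$a_sus))
    ti_comp <- compound_ti(ti_on, ti_off, pi_v)
    # spectral dominance and CS transience from the dominant polarity:
    # Off-dominated cells respond at light offset
    dom_on <- is.nan(pi_v) || pi_v >= 0
    cs_dom <- amp_cs[amp_cs$kind == (if (dom_on) "CS_on" else "CS_off"), ]
    ws_dom <- if (dom_on) ws100_on else ws100_off
    best_cs <- cs_dom[which.max(cs_dom$a_tr), ]
    sd_v <- suppressWarnings(spectral_dominance(best_cs$a_tr, ws_dom$a_tr))
    ti_cs <- suppressWarnings(transience_index(best_cs$a_tr, best_cs$a_sus))

    kamp <- kernel_amplitude(kern)
    fine <- compute_kernel(nz_sp, tl$noise, step_s = config$opponency_step_s)
    prof <- classify_opponency(fine, config$opponency_amp_threshold)
    kqi <- kernel_quality(fine$z)$score
    # the 20-of-1000-bins rule, rescaled to the configured opponency grid
    min_op <- max(2, round(20 * length(prof$labels) / 1000))
    coi <- colour_opponency_index(prof, kernel_qi = kqi,
                                  min_opponent_bins = min_op)

    ch_kde <- kde_rate(ch_sp, tl$chirp$duration_s, n_points = 2000)
    spec <- suppressWarnings(
      chirp_spectrum(ch_kde$rate, sampling_rate_hz = 2000 / tl$chirp$duration_s)
    )
    hfi <- high_frequency_index(spec)

    feats[[id]] <- data.frame(
      cell_id = id, qi_ws = qi_ws, qi_cs = qi_cs, qi_chirp = qi_ch,
      kernel_cluster_quality = kq, pi = pi_v, ti_on = ti_on,
      ti_off = ti_off, ti_compound = ti_comp, ti_cs = ti_cs, sd = sd_v,
      kernel_amplitude = kamp$max_amplitude, kernel_qi = kqi,
      coi = ifelse(is.na(coi), 0, coi), opponent = !is.na(coi),
      hfi = hfi, best_frequency = spec$best_frequency,
      stringsAsFactors = FALSE
    )
    ws_kde <- kde_rate(ws_sp, tl$ws$duration_s)
    cs_kde <- kde_rate(cs_sp, tl$cs$duration_s)
    chirp_ds <- kde_rate(ch_sp, tl$chirp$duration_s, n_points = 500)
    traces[[id]] <- list(ws = ws_kde$rate, cs = cs_kde$rate,
                         chirp = chirp_ds$rate)
    kern_list[[id]] <- kern$z
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL

  pass <- with(features, qi_ws >= config$qi_threshold |
                 qi_cs >= config$qi_threshold |
                 qi_chirp >= config$qi_threshold |
                 kernel_cluster_quality >= config$kernel_quality_threshold)
  pass[is.na(pass)] <- FALSE
  features$qc_pass <- pass
  kept <- features$cell_id[pass]
  n_qc <- length(kept)

  # feature blocks over QC-passing cells: 10 WS segments, 6 CS segments,
  # chirp, 4 kernels (23 blocks)
  seg_block <- function(get_trace, n_seg) {
    full <- t(vapply(kept, get_trace, numeric(length(get_trace(kept[1])))))
    len <- ncol(full) %/% n_seg
    lapply(seq_len(n_seg), function(s) {
      full[, ((s - 1) * len + 1):(s * len), drop = FALSE]
    })
  }
  blocks <- c(
    stats::setNames(seg_block(function(id) traces[[id]]$ws, 10),
                    paste0("ws", 1:10)),
    stats::setNames(seg_block(function(id) traces[[id]]$cs, 6),
                    paste0("cs", 1:6)),
    list(chirp = t(vapply(kept, function(id) traces[[id]]$chirp,
                          numeric(length(traces[[kept[1]]]$chirp))))),
    stats::setNames(lapply(1:4, function(l) {
      t(vapply(kept, function(id) {
        z <- kern_list[[id]][l, ]
        z[is.na(z)] <- 0
        z
      }, numeric(ncol(kern_list[[kept[1]]]))))
    }), paste0("sk_", c("R", "G", "C", "B")))
  )
  pca <- block_pca(blocks)
  k_eff <- min(config$k, n_qc - 1)
  model <- fit_gmm(pca$scores, k = k_eff,
                   n_replicates = config$gmm_replicates, seed = config$seed)
  resp_mat <- t(vapply(kept, function(id) {
    c(traces[[id]]$ws, traces[[id]]$cs)
  }, numeric(length(traces[[kept[1]]]$ws) + length(traces[[kept[1]]]$cs))))
  merged <- merge_clusters(model$assignments, resp_mat,
                           min_cor = config$merge_min_cor)
  ret <- retention_filter(merged, min_members = config$min_members)

  features$raw_cluster <- NA_integer_
  features$merged_cluster <- NA_integer_
  features$raw_cluster[match(kept, features$cell_id)] <- model$assignments
  features$merged_cluster[match(kept, features$cell_id)] <- ret$labels
  # groups are assigned per cluster from the cluster-mean indices and
  # inherited by member cells; unclustered cells fall back to their own
  features$group <- mapply(assign_response_group, features$pi, features$ti_cs,
                           MoreArgs = list(cut = config$polarity_cut))
  for (cl in unique(stats::na.omit(features$merged_cluster))) {
    mem <- which(features$merged_cluster == cl)
    grp <- assign_response_group(mean(features$pi[mem], na.rm = TRUE),
                                 mean(features$ti_cs[mem], na.rm = TRUE),
                                 cut = config$polarity_cut)
    features$group[mem] <- grp
  }

  grp_counts <- table(features$group[features$qc_pass])
  report <- list(
    n_raw = n_raw, n_qc = n_qc,
    n_clustered = sum(!is.na(features$merged_cluster)),
    n_retained_clusters = length(ret$retained),
    group_counts = as.list(grp_counts),
    group_percentages = as.list(group_percentages(unclass(grp_counts), n_qc)),
    pca_components = pca$n_components,
    pca_total = sum(pca$n_components),
    gmm_structure = model$structure,
    config = config
  )
  structure(list(features = features, cluster_model = model,
                 merged_labels = merged, retention = ret,
                 block_pca = pca, report = report),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<pipeline_run> %d cells -> %d post-QC -> %d clustered (%d clusters)\n",
    r$n_raw, r$n_qc, r$n_clustered, r$n_retained_clusters
  ))
  gp <- unlist(r$group_percentages)
  cat("groups:", paste(sprintf("%s %.1f%%", names(gp), gp), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a pipeline run report to JSON
#'
#' Serialises the run report (per-stage counts, group sizes and
#' percentages, PCA component counts, configuration) for audit and reuse.
#'
#' @param run A `pipeline_run`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path) {
  stopifnot(inherits(run, "pipeline_run"))
  jsonlite::write_json(run$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
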