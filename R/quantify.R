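# Absolute quantification: anchor relative abundances to the sample's
# total-bacteria qPCR estimate, and summarize the depletion induced by PMA
# treatment in paired shotgun / PMA-shotgun samples.

#' Estimate per-genus absolute cell counts
#'
#' Distributes a sample's total-bacteria qPCR estimate over genera in
#' proportion to their relative abundance: `cells_i = qpcr_total * abundance_i`.
#' Genera at zero abundance are flagged below detection and carry no log value.
#'
#' @param profile Named relative-abundance vector (sums to 1 within 1e-6).
#' @param qpcr_total Total bacterial load, cells/mL (>= 0; `NA` is an error —
#'   skip absolute quantification for samples without a qPCR value).
#' @param sample_id Sample identifier carried into the output.
#' @return `data.frame` with columns `sample_id`, `genus`, `cells_per_ml`,
#'   `log10_cells_per_ml` (`NA` when below detection), `below_detection`.
#' @examples
#' estimate_cell_counts(c(Bacillus = 0.25, Escherichia = 0.75), 1e6, "s1")
#' @export
estimate_cell_counts <- function(profile, qpcr_total, sample_id = "sample") {
  if (is.na(qpcr_total)) {
    stop(paste("estimate_cell_counts: qpcr_total is missing; skip absolute",
               "quantification for this sample"), call. = FALSE)
  }
  if (qpcr_total < 0) stop("estimate_cell_counts: qpcr_total must be >= 0",
                           call. = FALSE)
  if (is.null(names(profile))) {
    stop("estimate_cell_counts: profile must be named by genus", call. = FALSE)
  }
  if (abs(sum(profile) - 1) > 1e-6) {
    stop("estimate_cell_counts: profile must sum to 1", call. = FALSE)
  }
  cells <- qpcr_total * as.numeric(profile)
  below <- cells <= 0
  data.frame(sample_id = sample_id, genus = names(profile),
             cells_per_ml = cells,
             log10_cells_per_ml = ifelse(below, NA_real_, log10(cells)),
             below_detection = below, stringsAsFactors = FALSE)
}

#' Cell-count estimates for every sample of a study
#'
#' Convenience wrapper: collapses each table to genus level, normalizes and
#' anchors each sample to its qPCR total. Samples without a qPCR value are
#' skipped with a message.
#'
#' @param tables Named list of [count_table]s.
#' @param metadata Sample metadata (see [sample_metadata]).
#' @param map Harmonization map.
#' @return Combined `data.frame` of [estimate_cell_counts] outputs.
#' @export
estimate_study_cell_counts <- function(tables, metadata,
                                       map = default_harmonization_map()) {
  out <- list()
  for (tab in tables) {
    genus_tab <- collapse_to_genus(drop_unclassified(tab), map)
    prof <- profile_matrix(genus_tab)
    for (sid in genus_tab$samples) {
      q <- metadata$qpcr_total[match(sid, metadata$sample_id)]
      if (length(q) != 1L || is.na(q)) {
        message(sprintf("estimate_study_cell_counts: no qPCR total for '%s'; skipped", sid))
        next
      }
      out[[sid]] <- estimate_cell_counts(prof[, sid], q, sid)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize PMA-induced depletion in paired samples
#'
#' Pairs shotgun with PMA-shotgun samples by (platform, condition, replicate)
#' and reports, per pair, total estimated cells under each method and the
#' log10 difference (shotgun minus PMA), plus per-genus log10 differences.
#' Genera below detection in either member are excluded from log-scale
#' differences (flagged, not imputed). Unpaired samples are listed, never
#' silently dropped.
#'
#' @param estimates Cell-count estimates (see [estimate_study_cell_counts]).
#' @param metadata Sample metadata.
#' @return List with `pairs` (per-pair totals and log10 difference),
#'   `per_genus` (per-pair, per-genus differences) and `unpaired` (samples of
#'   either method lacking a partner).
#' @export
pma_depletion_summary <- function(estimates, metadata) {
  meta <- metadata[metadata$method %in% c("shotgun", "pma_shotgun"), ]
  meta <- meta[meta$sample_id %in% unique(estimates$sample_id), ]
  key <- paste(meta$platform, meta$condition, meta$replicate, sep = "|")
  pairs <- list()
  per_genus <- list()
  unpaired <- list()
  for (k in unique(key)) {
    rows <- meta[key == k, ]
    sg <- rows$sample_id[rows$method == "shotgun"]
    pm <- rows$sample_id[rows$method == "pma_shotgun"]
    if (length(sg) != 1L || length(pm) != 1L) {
      unpaired[[k]] <- data.frame(pair = k, sample_id = rows$sample_id,
                                  method = rows$method,
                                  stringsAsFactors = FALSE)
      next
    }
    e_sg <- estimates[estimates$sample_id == sg, ]
    e_pm <- estimates[estimates$sample_id == pm, ]
    tot_sg <- sum(e_sg$cells_per_ml)
    tot_pm <- sum(e_pm$cells_per_ml)
    pairs[[k]] <- data.frame(
      platform = rows$platform[1L], condition = rows$condition[1L],
      replicate = rows$replicate[1L], shotgun_sample = sg, pma_sample = pm,
      total_shotgun = tot_sg, total_pma = tot_pm,
      log10_difference = if (tot_sg > 0 && tot_pm > 0) {
        log10(tot_sg) - log10(tot_pm)
      } else NA_real_,
      stringsAsFactors = FALSE)
    genera <- union(e_sg$genus, e_pm$genus)
    c_sg <- e_sg$cells_per_ml[match(genera, e_sg$genus)]
    c_pm <- e_pm$cells_per_ml[match(genera, e_pm$genus)]
    c_sg[is.na(c_sg)] <- 0
    c_pm[is.na(c_pm)] <- 0
    detectable <- c_sg > 0 & c_pm > 0
    per_genus[[k]] <- data.frame(
      platform = rows$platform[1L], condition = rows$condition[1L],
      replicate = rows$replicate[1L], genus = genera,
      cells_shotgun = c_sg, cells_pma = c_pm,
      log10_difference = ifelse(detectable, log10(c_sg) - log10(c_pm),
                                NA_real_),
      below_detection = !detectable, stringsAsFactors = FALSE)
  }
  bind <- function(x) {
    if (!length(x)) return(NULL)
    out <- do.call(rbind, x)
    rownames(out) <- NULL
    out
  }
  list(pairs = bind(pairs), per_genus = bind(per_genus),
       unpaired = bind(unpaired))
}

#' Recover the PMA dead-DNA residual from paired dead samples
#'
#' Ratio estimator: mean absolute mock-community mass (cells/mL, qPCR-anchored)
#' across dead-spiked PMA-shotgun samples divided by the mean across paired
#' shotgun samples. Under the generative model this estimates the dead-DNA
#' residual weight epsilon of the PMA method.
#'
#' @param estimates Cell-count estimates (see [estimate_study_cell_counts]).
#' @param metadata Sample metadata.
#' @param mock_genera Character vector of mock-community genera.
#' @return Scalar estimate of epsilon.
#' @export
pma_epsilon_estimate <- function(estimates, metadata, mock_genera) {
  dead <- metadata[metadata$condition == "dead" &
                     metadata$method %in% c("shotgun", "pma_shotgun"), ]
  if (!nrow(dead)) stop("pma_epsilon_estimate: no dead-spiked shotgun/PMA samples",
                        call. = FALSE)
  mock_mass <- function(sids) {
    m <- vapply(sids, function(sid) {
      e <- estimates[estimates$sample_id == sid & estimates$genus %in% mock_genera, ]
      sum(e$cells_per_ml)
    }, numeric(1L))
    mean(m)
  }
  num <- mock_mass(dead$sample_id[dead$method == "pma_shotgun"])
  den <- mock_mass(dead$sample_id[dead$method == "shotgun"])
  if (den <= 0) stop("pma_epsilon_estimate: zero mock mass in shotgun samples",
                     call. = FALSE)
  num / den
}
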