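# Abundance-mass confusion scoring.
#
# A method's observed genus profile is compared with a reference profile
# (a sequenced control community, or the theoretical community composition).
# Agreement and disagreement are measured as relative-abundance *mass*, split
# between mock-community genera and all other taxa, and summarized by
# accuracy, precision, sensitivity and F-score.
#
# Two bookkeeping schemes are supported because verbal definitions of the
# quantities admit both:
#  * "excess-deficit" (default): FP is observed mock mass in excess of the
#    reference, FN is the mock deficit; this matches precision = TP over
#    observed mock mass and sensitivity = TP over reference mock mass
#    (standard precision/recall semantics).
#  * "split-mass": FP is total absolute mock disagreement and FN total
#    absolute non-mock disagreement; under this scheme accuracy is a
#    monotone transform of Bray-Curtis dissimilarity,
#    A = (1 - BC) / (1 + BC).

#' Abundance-mass confusion quantities
#'
#' @param observed Named relative-abundance vector (sums to 1 within 1e-6).
#' @param expected Named reference relative-abundance vector (sums to 1 within
#'   1e-6). Genera absent from either vector count as zero.
#' @param mock_genera Non-empty character vector of mock-community genera.
#' @param scheme `"excess-deficit"` or `"split-mass"` (see file header).
#' @return Object of class `confusion_mass`: list with `TP`, `FP`, `TN`, `FN`
#'   and the scheme used.
#' @examples
#' obs <- c(Bacillus = 0.1, Escherichia = 0.3, Lactococcus = 0.2,
#'          Pseudomonas = 0.2, Staphylococcus = 0.1, Acinetobacter = 0.1)
#' exp <- c(Bacillus = 0.2, Escherichia = 0.2, Lactococcus = 0.2,
#'          Pseudomonas = 0.2, Staphylococcus = 0.2)
#' confusion_mass(obs, exp, names(exp))
#' @export
confusion_mass <- function(observed, expected, mock_genera,
                           scheme = c("excess-deficit", "split-mass")) {
  scheme <- match.arg(scheme)
  if (!length(mock_genera)) {
    stop("confusion_mass: mock_genera must be non-empty", call. = FALSE)
  }
  if (is.null(names(observed)) || is.null(names(expected))) {
    stop("confusion_mass: profiles must be named by genus", call. = FALSE)
  }
  if (abs(sum(observed) - 1) > 1e-6 || abs(sum(expected) - 1) > 1e-6) {
    stop("confusion_mass: profiles must each sum to 1 (within 1e-6)",
         call. = FALSE)
  }
  taxa <- union(names(observed), names(expected))
  obs <- stats::setNames(numeric(length(taxa)), taxa)
  exp_ <- obs
  obs[names(observed)] <- observed
  exp_[names(expected)] <- expected
  mock <- taxa %in% mock_genera

  tp <- sum(pmin(obs[mock], exp_[mock]))
  tn <- sum(pmin(obs[!mock], exp_[!mock]))
  if (scheme == "excess-deficit") {
    fp <- sum(pmax(obs[mock] - exp_[mock], 0))
    fn <- sum(pmax(exp_[mock] - obs[mock], 0))
  } else {
    fp <- sum(abs(obs[mock] - exp_[mock]))
    fn <- sum(abs(obs[!mock] - exp_[!mock]))
  }
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn, scheme = scheme),
            class = "confusion_mass")
}

#' @export
print.confusion_mass <- function(x, ...) {
  cat(sprintf("<confusion_mass> scheme %s: TP=%.4g FP=%.4g TN=%.4g FN=%.4g\n",
              x$scheme, x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Performance metrics from confusion masses
#'
#' * accuracy `A = (TP + TN) / (TP + TN + FP + FN)`
#' * precision `P = TP / (TP + FP)`
#' * sensitivity `S = TP / (TP + FN)`
#' * F-score `F = 2 P S / (P + S)`
#'
#' Any ratio with a zero denominator returns 0 and raises the corresponding
#' degenerate flag.
#'
#' @param x A [confusion_mass] (or list with elements TP, FP, TN, FN).
#' @return Object of class `performance_metrics`: `accuracy`, `precision`,
#'   `sensitivity`, `f_score` (each in `[0, 1]`) and logical `degenerate`
#'   flags per metric.
#' @export
performance_metrics <- function(x) {
  v <- c(x$TP, x$FP, x$TN, x$FN)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("performance_metrics: confusion masses must be finite and non-negative",
         call. = FALSE)
  }
  ratio <- function(num, den) {
    if (den > 0) list(value = num / den, degenerate = FALSE)
    else list(value = 0, degenerate = TRUE)
  }
  a <- ratio(x$TP + x$TN, x$TP + x$TN + x$FP + x$FN)
  p <- ratio(x$TP, x$TP + x$FP)
  s <- ratio(x$TP, x$TP + x$FN)
  f <- ratio(2 * p$value * s$value, p$value + s$value)
  structure(list(accuracy = a$value, precision = p$value,
                 sensitivity = s$value, f_score = f$value,
                 degenerate = c(accuracy = a$degenerate,
                                precision = p$degenerate,
                                sensitivity = s$degenerate,
                                f_score = f$degenerate)),
            class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf("<performance_metrics> A=%.4f P=%.4f S=%.4f F=%.4f\n",
              x$accuracy, x$precision, x$sensitivity, x$f_score))
  invisible(x)
}

# Resolve the reference profile for one sample.
# matched_control: live samples are scored against the same method x
#   platform's sequenced live community control; dead samples against its dead
#   control, or (expect_absent = TRUE) against the unspiked matrix control so
#   any detected mock signal in a dead spike counts as false-positive mass.
# theoretical: the community's intended proportions (mock genera only).
reference_profile <- function(sample_row, profiles, metadata, community,
                              reference, expect_absent) {
  if (reference == "theoretical") {
    if (expect_absent && sample_row$condition == "dead") {
      stop(paste("evaluate_study: expect_absent requires matched_control",
                 "(an unspiked control supplies the viable background profile)"),
           call. = FALSE)
    }
    return(community$proportions)
  }
  want_condition <- switch(sample_row$condition,
                           live = "control_live",
                           dead = if (expect_absent) "unspiked" else "control_dead",
                           stop("reference_profile: only spiked samples are scored",
                                call. = FALSE))
  ctrl <- metadata$sample_id[metadata$method == sample_row$method &
                               metadata$platform == sample_row$platform &
                               metadata$condition == want_condition]
  if (length(ctrl) != 1L || !ctrl %in% colnames(profiles)) {
    stop(sprintf(
      "evaluate_study: missing %s control for method '%s' on platform '%s'",
      want_condition, sample_row$method, sample_row$platform), call. = FALSE)
  }
  profiles[, ctrl]
}

#' Score every spiked sample of a study
#'
#' Collapses each count table to genus level (dropping unclassified rows),
#' normalizes, resolves each live/dead spiked sample's reference profile,
#' computes confusion masses and the four performance metrics, and aggregates
#' per method x platform (median, MAD and SD of each metric, overall and split
#' by live/dead; methods ranked by median F-score). Control samples serve as
#' references and are excluded from the aggregates.
#'
#' @param tables Named list of [count_table]s (one per method x platform).
#' @param metadata Sample metadata (see [sample_metadata]).
#' @param community A [mock_community_spec] defining the mock genera.
#' @param reference `"matched_control"` (default) or `"theoretical"`.
#' @param scheme Confusion scheme, see [confusion_mass].
#' @param expect_absent If `TRUE`, dead-spiked samples are scored against the
#'   matched unspiked control (viable-truth expectation: no mock genera), so
#'   dead signal that a method fails to suppress is counted as false-positive
#'   mass. Default `FALSE`: dead samples are scored against the sequenced dead
#'   community control.
#' @param map Harmonization map for genus collapse.
#' @return List with `per_sample` (one row per spiked sample: metadata,
#'   confusion masses, metrics) and `per_method` (aggregates; `subset` column
#'   takes values "all", "live", "dead").
#' @export
evaluate_study <- function(tables, metadata, community,
                           reference = c("matched_control", "theoretical"),
                           scheme = c("excess-deficit", "split-mass"),
                           expect_absent = FALSE,
                           map = default_harmonization_map()) {
  reference <- match.arg(reference)
  scheme <- match.arg(scheme)
  stopifnot(inherits(community, "mock_community_spec"))
  rows <- list()
  for (tab in tables) {
    genus_tab <- collapse_to_genus(suppressMessages(drop_unclassified(tab)), map)
    profiles <- profile_matrix(genus_tab)
    spiked <- metadata[metadata$sample_id %in% genus_tab$samples &
                         metadata$condition %in% c("live", "dead"), ]
    for (k in seq_len(nrow(spiked))) {
      srow <- spiked[k, ]
      expected <- reference_profile(srow, profiles, metadata, community,
                                    reference, expect_absent)
      cm <- confusion_mass(profiles[, srow$sample_id], expected,
                           community$genera, scheme)
      pm <- performance_metrics(cm)
      rows[[srow$sample_id]] <- data.frame(
        srow, TP = cm$TP, FP = cm$FP, TN = cm$TN, FN = cm$FN,
        accuracy = pm$accuracy, precision = pm$precision,
        sensitivity = pm$sensitivity, f_score = pm$f_score,
        degenerate = any(pm$degenerate), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("evaluate_study: no spiked samples to score",
                          call. = FALSE)
  per_sample <- do.call(rbind, rows)
  rownames(per_sample) <- NULL
  per_sample$scheme <- scheme
  per_sample$reference <- reference

  metrics <- c("accuracy", "precision", "sensitivity", "f_score")
  agg <- list()
  groups <- unique(per_sample[, c("method", "platform")])
  for (g in seq_len(nrow(groups))) {
    sel <- per_sample$method == groups$method[g] &
      per_sample$platform == groups$platform[g]
    for (subset in c("all", "live", "dead")) {
      keep <- sel & (subset == "all" | per_sample$condition == subset)
      if (!any(keep)) next
      row <- data.frame(method = groups$method[g],
                        platform = groups$platform[g],
                        subset = subset, n = sum(keep),
                        stringsAsFactors = FALSE)
      for (m in metrics) {
        v <- per_sample[[m]][keep]
        row[[paste0(m, "_median")]] <- stats::median(v)
        row[[paste0(m, "_mad")]] <- stats::mad(v)
        row[[paste0(m, "_sd")]] <- if (length(v) > 1L) stats::sd(v) else 0
      }
      agg[[length(agg) + 1L]] <- row
    }
  }
  per_method <- do.call(rbind, agg)
  rownames(per_method) <- NULL
  overall <- per_method$subset == "all"
  rank_f <- rank(-per_method$f_score_median[overall], ties.method = "min")
  per_method$rank_f <- NA_integer_
  per_method$rank_f[overall] <- as.integer(rank_f)
  list(per_sample = per_sample, per_method = per_method)
}
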