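# Generative model of a live/dead spike-in study.
#
# Latent layer: per-strain live (L) and dead (D) cell loads after spiking and
# overnight incubation, plus a low background flora from the milk matrix.
# Observation layer: each library type sees a weighted combination of live and
# dead signal (PMA suppresses dead DNA; RNA targets decay in dead cells and
# scale live signal by metabolic activity), and each platform draws multinomial
# read counts at its own depth and misclassification rate.

# ---- RNG plumbing -----------------------------------------------------------

#' Derive a reproducible sub-stream seed
#'
#' Hashes a master seed together with a string key (e.g. "method|platform|
#' condition|replicate|purpose") into a 31-bit seed, so each sample draws from
#' its own stream and adding a method or platform never perturbs the draws of
#' the others.
#'
#' @param master_seed Integer master seed.
#' @param ... Character/atomic components of the stream key.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stream_seed <- function(master_seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1L)), collapse = "|")
  m <- 2147483647 # 2^31 - 1 (prime); doubles stay exact below 2^53
  h <- as.numeric(master_seed) %% m
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% m
  as.integer(h)
}

# Evaluate expr under a local, seeded RNG; the caller's RNG state is restored.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# ---- observation models -----------------------------------------------------

#' Define a library-type observation model
#'
#' Each method weighs live and dead cell signal separately. DNA shotgun sees
#' both in full; PMA treatment suppresses dead DNA to a residual `w_dead`
#' (epsilon); RNA methods scale live signal by per-strain metabolic activity
#' and see dead cells only through residual RNA (rRNA persists more than mRNA).
#'
#' @param w_live Weight on live-cell signal, in `[0, 1]`.
#' @param w_dead Weight on dead-cell signal, in `[0, 1]`.
#' @param uses_activity If `TRUE`, live signal is multiplied by the strain's
#'   activity factor (RNA-based methods).
#' @param suppresses_dead_dna If `TRUE` the method's wet-lab treatment (PMA)
#'   also suppresses dead DNA in the qPCR assay of the same aliquot.
#' @return Object of class `method_model`.
#' @export
method_model <- function(w_live = 1, w_dead = 1, uses_activity = FALSE,
                         suppresses_dead_dna = FALSE) {
  if (w_live < 0 || w_live > 1 || w_dead < 0 || w_dead > 1) {
    stop("method_model: weights must lie in [0, 1]", call. = FALSE)
  }
  structure(list(w_live = w_live, w_dead = w_dead,
                 uses_activity = isTRUE(uses_activity),
                 suppresses_dead_dna = isTRUE(suppresses_dead_dna)),
            class = "method_model")
}

#' Default observation models for the four library types
#'
#' shotgun: sees live and dead DNA alike. pma_shotgun: dead DNA reduced to
#' epsilon = 0.05. s16 (RNA-based 16S rRNA): activity-scaled live signal, dead
#' rRNA residual 0.10. metat (metatranscriptomics): activity-scaled live
#' signal, dead mRNA residual 0.01.
#'
#' @param epsilon_pma Residual dead-DNA weight after PMA treatment.
#' @param rho_rrna Residual dead-cell rRNA weight.
#' @param rho_mrna Residual dead-cell mRNA weight.
#' @return Named list of [method_model]s.
#' @export
default_method_models <- function(epsilon_pma = 0.05, rho_rrna = 0.10,
                                  rho_mrna = 0.01) {
  list(
    shotgun     = method_model(1, 1),
    pma_shotgun = method_model(1, epsilon_pma, suppresses_dead_dna = TRUE),
    metat       = method_model(1, rho_mrna, uses_activity = TRUE),
    s16         = method_model(1, rho_rrna, uses_activity = TRUE)
  )
}

#' Define a sequencing-platform observation model
#'
#' @param depth Expected total counts per sample (>= 1).
#' @param misclass_rate Fraction of counts reassigned uniformly across
#'   background genera, in `[0, 0.5)`; a coarse stand-in for platform error
#'   rate plus pipeline misassignment.
#' @return Object of class `platform_model`.
#' @export
platform_model <- function(depth, misclass_rate) {
  if (depth < 1) stop("platform_model: depth must be >= 1", call. = FALSE)
  if (misclass_rate < 0 || misclass_rate >= 0.5) {
    stop("platform_model: misclass_rate must lie in [0, 0.5)", call. = FALSE)
  }
  structure(list(depth = depth, misclass_rate = misclass_rate),
            class = "platform_model")
}

#' Default platform models
#'
#' illumina: high depth (1e6), low misclassification (0.002). ont: lower depth
#' (1e5), higher misclassification (0.02).
#'
#' @return Named list of [platform_model]s.
#' @export
default_platform_models <- function() {
  list(illumina = platform_model(1e6, 0.002),
       ont      = platform_model(1e5, 0.02))
}

# ---- study configuration ----------------------------------------------------

#' Build a synthetic-study configuration
#'
#' Bundles the mock community, observation models, replication, background
#' flora, noise scales and the master seed. Two runs with an identical config
#' produce identical output.
#'
#' @param community A [mock_community_spec].
#' @param methods Named list of [method_model]s.
#' @param platforms Named list of [platform_model]s.
#' @param n_replicates Spiked replicates per condition (default 3).
#' @param background Named numeric vector: background genus -> cells/mL in the
#'   milk matrix (default three genera at 1e3, a low-background UHT matrix).
#' @param growth_mean Mean overnight growth factor for live spiked cells
#'   (lognormal mean; dead cells never grow).
#' @param sigma_growth Lognormal sdlog of the per-strain growth factor.
#' @param activity Named numeric vector of per-strain metabolic activity
#'   factors; genera not named take `activity_default`. Defaults make
#'   Pseudomonas the most active strain (factor 5), illustrative only.
#' @param activity_default Activity for unnamed genera.
#' @param sigma_q Lognormal sdlog of multiplicative qPCR noise.
#' @param seed Integer master seed.
#' @return Object of class `study_config`.
#' @export
study_config <- function(community = mock_community_spec(),
                         methods = default_method_models(),
                         platforms = default_platform_models(),
                         n_replicates = 3L,
                         background = c(Acinetobacter = 1e3,
                                        Corynebacterium = 1e3,
                                        Streptococcus = 1e3),
                         growth_mean = 10,
                         sigma_growth = 0.5,
                         activity = c(Pseudomonas = 5),
                         activity_default = 1,
                         sigma_q = 0.1,
                         seed = 1L) {
  stopifnot(inherits(community, "mock_community_spec"))
  if (!length(methods) || is.null(names(methods)) ||
      !all(names(methods) %in% .methods)) {
    stop("study_config: methods must be a named list keyed by ",
         paste(.methods, collapse = "/"), call. = FALSE)
  }
  if (!length(platforms) || is.null(names(platforms)) ||
      !all(names(platforms) %in% .platforms)) {
    stop("study_config: platforms must be keyed by illumina/ont", call. = FALSE)
  }
  for (m in methods) stopifnot(inherits(m, "method_model"))
  for (p in platforms) stopifnot(inherits(p, "platform_model"))
  if (n_replicates < 1L) stop("study_config: n_replicates must be >= 1",
                              call. = FALSE)
  if (length(background) && (is.null(names(background)) || any(background < 0))) {
    stop("study_config: background must be a named non-negative vector",
         call. = FALSE)
  }
  if (growth_mean < 1) stop("study_config: growth_mean must be >= 1 (growth factors g >= 1 in expectation)",
                            call. = FALSE)
  if (sigma_growth < 0 || sigma_q < 0) {
    stop("study_config: noise scales must be >= 0", call. = FALSE)
  }
  if (any(activity < 0) || activity_default < 0) {
    stop("study_config: activity factors must be >= 0", call. = FALSE)
  }
  structure(list(community = community, methods = methods,
                 platforms = platforms, n_replicates = as.integer(n_replicates),
                 background = background, growth_mean = growth_mean,
                 sigma_growth = sigma_growth, activity = activity,
                 activity_default = activity_default, sigma_q = sigma_q,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(paste0("<study_config> %d-strain community, %d method(s) x %d ",
                     "platform(s), %d replicates, seed %d\n"),
              length(x$community$genera), length(x$methods),
              length(x$platforms), x$n_replicates, x$seed))
  invisible(x)
}

#' Serialize / deserialize a study configuration (JSON)
#' @param config A [study_config].
#' @param path JSON path.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- list(
    community = list(
      members = data.frame(genus = config$community$genera,
                           strain = config$community$strains,
                           proportion = unname(config$community$proportions)),
      spike_density = config$community$spike_density),
    methods = lapply(config$methods, unclass),
    platforms = lapply(config$platforms, unclass),
    n_replicates = config$n_replicates,
    background = as.list(config$background),
    growth_mean = config$growth_mean,
    sigma_growth = config$sigma_growth,
    activity = as.list(config$activity),
    activity_default = config$activity_default,
    sigma_q = config$sigma_q,
    seed = config$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("community", "methods", "platforms", "n_replicates", "background",
            "growth_mean", "sigma_growth", "activity", "activity_default",
            "sigma_q", "seed")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop(sprintf("read_study_config: missing key(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  methods <- lapply(x$methods, function(m) {
    method_model(m$w_live, m$w_dead, isTRUE(m$uses_activity),
                 isTRUE(m$suppresses_dead_dna))
  })
  platforms <- lapply(x$platforms, function(p) {
    platform_model(p$depth, p$misclass_rate)
  })
  study_config(
    community = mock_community_spec(genera = x$community$members$genus,
                                    strains = x$community$members$strain,
                                    proportions = x$community$members$proportion,
                                    spike_density = x$community$spike_density),
    methods = methods, platforms = platforms,
    n_replicates = x$n_replicates, background = unlist(x$background),
    growth_mean = x$growth_mean, sigma_growth = x$sigma_growth,
    activity = unlist(x$activity), activity_default = x$activity_default,
    sigma_q = x$sigma_q, seed = x$seed)
}

# ---- latent layer -----------------------------------------------------------

#' Simulate latent cell loads for one sample
#'
#' Live spiked samples carry live cells grown overnight in the matrix
#' (per-strain lognormal growth factors); dead (heat-killed) spikes carry the
#' spiked load with no subsequent growth. Untreated community controls skip
#' the matrix incubation (growth factor 1, no background); unspiked samples
#' contain only the background flora.
#'
#' @param config A [study_config].
#' @param condition One of `"live"`, `"dead"`, `"control_live"`,
#'   `"control_dead"`, `"unspiked"`.
#' @param seed Integer stream seed (see [stream_seed]).
#' @return Object of class `latent_loads`: named vectors `live`, `dead`
#'   (cells/mL per mock strain), `background` (cells/mL per background genus),
#'   `growth` and `activity` factors.
#' @export
simulate_latent_loads <- function(config, condition, seed) {
  stopifnot(inherits(config, "study_config"))
  if (!condition %in% .conditions) {
    stop(sprintf("simulate_latent_loads: unknown condition '%s'", condition),
         call. = FALSE)
  }
  com <- config$community
  n <- length(com$genera)
  base <- com$spike_density * unname(com$proportions)
  activity <- ifelse(com$genera %in% names(config$activity),
                     config$activity[com$genera], config$activity_default)
  activity <- stats::setNames(as.numeric(activity), com$genera)
  zero <- stats::setNames(numeric(n), com$genera)

  growth <- stats::setNames(rep(1, n), com$genera)
  if (condition == "live") {
    g <- with_seed(seed, stats::rlnorm(n, meanlog = log(config$growth_mean),
                                       sdlog = config$sigma_growth))
    growth <- stats::setNames(pmax(g, 1), com$genera)
  }

  live <- dead <- zero
  background <- stats::setNames(numeric(0L), character(0L))
  if (condition %in% c("live", "dead", "unspiked")) background <- config$background

  if (condition %in% c("live", "control_live")) {
    live <- stats::setNames(base * growth, com$genera)
  } else if (condition %in% c("dead", "control_dead")) {
    dead <- stats::setNames(base, com$genera)
  }
  structure(list(live = live, dead = dead, background = background,
                 growth = growth, activity = activity, condition = condition),
            class = "latent_loads")
}

#' Expected signal intensity per taxon under a method model
#'
#' `signal_i = L_i * a_i^[uses_activity] * w_live + D_i * w_dead` for mock
#' strains; background genera are viable matrix flora and contribute
#' `B_j * w_live`.
#'
#' @param loads A `latent_loads` object.
#' @param method A [method_model].
#' @return Named non-negative vector over mock genera then background genera.
#' @export
compute_method_signal <- function(loads, method) {
  stopifnot(inherits(loads, "latent_loads"), inherits(method, "method_model"))
  act <- if (method$uses_activity) loads$activity else 1
  mock <- loads$live * act * method$w_live + loads$dead * method$w_dead
  bg <- loads$background * method$w_live
  c(mock, bg)
}

#' Draw observed read counts from a signal vector
#'
#' The sample total is Poisson around the platform depth; counts are
#' multinomial with probabilities proportional to signal; a binomial fraction
#' `misclass_rate` of every taxon's counts is then reassigned uniformly across
#' the background genera. The total is conserved by the reassignment.
#'
#' @param signal Named non-negative vector with at least one positive entry.
#' @param platform A [platform_model].
#' @param seed Integer stream seed.
#' @param background Character vector naming the entries of `signal` that are
#'   misclassification targets (required when `misclass_rate > 0`).
#' @return Named integer-valued count vector aligned with `signal`.
#' @export
sample_read_counts <- function(signal, platform, seed, background = character()) {
  stopifnot(inherits(platform, "platform_model"))
  if (any(signal < 0)) stop("sample_read_counts: negative signal", call. = FALSE)
  if (sum(signal) <= 0) {
    stop("sample_read_counts: nothing to sequence (all-zero signal)",
         call. = FALSE)
  }
  if (platform$misclass_rate > 0 && !length(background)) {
    stop("sample_read_counts: misclass_rate > 0 needs background genera",
         call. = FALSE)
  }
  bg_idx <- match(background, names(signal))
  if (anyNA(bg_idx)) {
    stop("sample_read_counts: background names absent from signal", call. = FALSE)
  }
  with_seed(seed, {
    total <- stats::rpois(1L, platform$depth)
    counts <- as.numeric(stats::rmultinom(1L, total, prob = signal))
    names(counts) <- names(signal)
    if (platform$misclass_rate > 0 && total > 0) {
      moved <- stats::rbinom(length(counts), size = counts,
                             prob = platform$misclass_rate)
      counts <- counts - moved
      if (sum(moved) > 0) {
        redistributed <- as.numeric(
          stats::rmultinom(1L, sum(moved), prob = rep(1, length(bg_idx))))
        counts[bg_idx] <- counts[bg_idx] + redistributed
      }
    }
    counts
  })
}

#' Simulate a total-bacteria qPCR measurement
#'
#' qPCR targets DNA, so dead cells contribute fully unless the aliquot was
#' PMA-treated, in which case dead DNA is suppressed to the method's residual
#' weight. Multiplicative lognormal noise models assay variability.
#'
#' @param loads A `latent_loads` object.
#' @param method A [method_model] (its `suppresses_dead_dna` flag selects the
#'   dead-DNA weight).
#' @param sigma_q Lognormal sdlog (>= 0); 0 gives the noiseless expectation.
#' @param seed Integer stream seed.
#' @return Estimated total cells/mL.
#' @export
simulate_qpcr_total <- function(loads, method, sigma_q, seed) {
  stopifnot(inherits(loads, "latent_loads"), inherits(method, "method_model"))
  if (sigma_q < 0) stop("simulate_qpcr_total: sigma_q must be >= 0", call. = FALSE)
  w_dead_dna <- if (method$suppresses_dead_dna) method$w_dead else 1
  expected <- sum(loads$live) + w_dead_dna * sum(loads$dead) +
    sum(loads$background)
  noise <- if (sigma_q > 0) {
    with_seed(seed, stats::rlnorm(1L, meanlog = 0, sdlog = sigma_q))
  } else 1
  expected * noise
}

# ---- raw classifier labels --------------------------------------------------

# Mimic how each method/platform reports the mock strains: shotgun and
# metatranscriptomic pipelines emit GTDB-flavoured species names (with the
# staphylococcal strain resolving to a sibling species on short reads); the
# RNA 16S pipeline reports Silva genus labels ("Escherichia-Shigella").
raw_mock_labels <- function(genera, strains, method, platform) {
  if (method == "s16") {
    labels <- genera
    labels[genera == "Escherichia"] <- "Escherichia-Shigella"
    return(labels)
  }
  labels <- strains
  labels[genera == "Pseudomonas"] <- "Pseudomonas_E proteolytica"
  labels[genera == "Staphylococcus"] <-
    if (platform == "illumina") "Staphylococcus hominis" else "Staphylococcus haemolyticus"
  labels
}

# ---- study generation -------------------------------------------------------

#' Generate a complete synthetic spike-in study
#'
#' Emits one count table per method x platform with, per table: `n_replicates`
#' live and dead spiked samples, an untreated live and dead community control,
#' and an unspiked matrix sample; plus a metadata table (with per-sample qPCR
#' totals) and a ground-truth bundle (latent loads and noise-free expected
#' signal profiles). All randomness flows from `config$seed` through
#' per-sample hashed streams ([stream_seed]), so subsets are reproducible and
#' adding a method does not perturb the draws of the others.
#'
#' @param config A [study_config].
#' @return List with elements `tables` (named list of [count_table]s keyed
#'   `"<platform>_<method>"`), `metadata` (data.frame), `truth` (per-sample
#'   list of latent loads and expected genus-level signal profiles) and
#'   `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  com <- config$community
  bg_genera <- names(config$background)
  tables <- list()
  meta <- list()
  truth <- list()

  prefix <- c(illumina = "i", ont = "o")
  short <- c(shotgun = "shotgun", pma_shotgun = "pma", metat = "metat",
             s16 = "16s")

  for (pname in names(config$platforms)) {
    platform <- config$platforms[[pname]]
    for (mname in names(config$methods)) {
      method <- config$methods[[mname]]
      labels <- raw_mock_labels(com$genera, com$strains, mname, pname)
      taxa <- c(labels, bg_genera)
      design <- rbind(
        expand.grid(condition = c("live", "dead"),
                    replicate = seq_len(config$n_replicates),
                    stringsAsFactors = FALSE),
        data.frame(condition = c("control_live", "control_dead", "unspiked"),
                   replicate = 1L))
      design <- design[order(match(design$condition, .conditions),
                             design$replicate), ]
      cols <- list()
      for (k in seq_len(nrow(design))) {
        cond <- design$condition[k]
        rep_k <- design$replicate[k]
        sid <- paste(prefix[[pname]], short[[mname]], cond, rep_k, sep = "-")
        # the physical spiked sample is shared by every method x platform
        # (split aliquots of one milk sample), so its latent loads are keyed
        # by (condition, replicate) only; observation draws below are keyed
        # per method x platform
        loads <- simulate_latent_loads(
          config, cond, stream_seed(config$seed, cond, rep_k, "loads"))
        signal0 <- compute_method_signal(loads, method)
        # controls carry no matrix flora; pad zero background entries so every
        # column of a table shares the same taxa (misclassification targets
        # included)
        signal <- stats::setNames(numeric(length(com$genera) + length(bg_genera)),
                                  c(com$genera, bg_genera))
        signal[names(signal0)] <- signal0
        counts <- sample_read_counts(
          signal, platform,
          stream_seed(config$seed, mname, pname, cond, rep_k, "counts"),
          background = bg_genera)
        qpcr <- simulate_qpcr_total(
          loads, method, config$sigma_q,
          stream_seed(config$seed, mname, pname, cond, rep_k, "qpcr"))
        names(counts) <- taxa
        cols[[sid]] <- counts
        meta[[sid]] <- data.frame(sample_id = sid, method = mname,
                                  platform = pname, condition = cond,
                                  replicate = rep_k, qpcr_total = qpcr,
                                  stringsAsFactors = FALSE)
        expected <- stats::setNames(signal, c(com$genera, bg_genera))
        truth[[sid]] <- list(
          loads = loads,
          expected_profile = expected / sum(expected))
      }
      m <- do.call(cbind, cols)
      rownames(m) <- taxa
      tables[[paste(pname, mname, sep = "_")]] <- count_table(m, rank = "species")
    }
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  metadata <- sample_metadata(metadata$sample_id, metadata$method,
                              metadata$platform, metadata$condition,
                              metadata$replicate, metadata$qpcr_total)
  list(tables = tables, metadata = metadata, truth = truth, config = config)
}
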