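# ---- count tables -----------------------------------------------------------

#' Construct a taxon-by-sample count table
#'
#' The in-memory twin of a taxonomic classifier's abundance output: a numeric
#' matrix of non-negative counts with taxa as rows and samples as columns.
#'
#' @param counts Numeric matrix (taxa x samples) with row names (taxon labels,
#'   species- or genus-level as emitted by the classifier) and column names
#'   (sample ids).
#' @param rank Rank of the taxon labels, `"species"` or `"genus"`.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (the matrix), `taxa` (row labels), `samples` (column labels) and `rank`.
#' @examples
#' m <- matrix(c(10, 30, 60, 5, 15, 80), nrow = 3,
#'             dimnames = list(c("Bacillus", "Escherichia", "Lactococcus"),
#'                             c("s1", "s2")))
#' count_table(m, rank = "genus")
#' @export
count_table <- function(counts, rank = c("species", "genus")) {
  rank <- match.arg(rank)
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("count_table: 'counts' must be numeric", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count_table: 'counts' needs taxon row names and sample column names",
         call. = FALSE)
  }
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("count_table: missing value at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]),
         call. = FALSE)
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("count_table: negative count at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1L]
    stop(sprintf("count_table: duplicate sample id '%s'", dup), call. = FALSE)
  }
  structure(list(counts = counts, taxa = rownames(counts),
                 samples = colnames(counts), rank = rank),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d taxa x %d samples (rank: %s)\n",
              length(x$taxa), length(x$samples), x$rank))
  utils::str(x$counts, give.attr = FALSE)
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read a count table from TSV
#'
#' Expects classifier-style layout: first column taxon names, header row of
#' sample ids, numeric body. Blank cells are treated as errors, not zeros.
#'
#' @param path Path to a TSV file.
#' @param rank Rank of the taxon labels (`"species"` or `"genus"`).
#' @param transpose If `TRUE`, the file stores samples as rows and taxa as
#'   columns and is transposed on read.
#' @return A [count_table].
#' @export
read_count_table <- function(path, rank = c("species", "genus"),
                             transpose = FALSE) {
  rank <- match.arg(rank)
  if (!file.exists(path)) {
    stop(sprintf("read_count_table: file not found: '%s'", path), call. = FALSE)
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]][-1L]
  if (!transpose && anyDuplicated(header)) {
    stop(sprintf("read_count_table: duplicate sample id '%s' in header of '%s'",
                 header[duplicated(header)][1L], path), call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L) {
    stop(sprintf("read_count_table: '%s' is not a taxa x samples TSV", path),
         call. = FALSE)
  }
  labels <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  for (j in seq_len(ncol(body))) {
    cell <- trimws(body[[j]])
    if (any(cell == "")) {
      i <- which(cell == "")[1L]
      stop(sprintf(
        "read_count_table: blank cell at row '%s', column '%s' (blank is not zero)",
        labels[i], colnames(body)[j]), call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(cell))
    if (anyNA(val)) {
      i <- which(is.na(val))[1L]
      stop(sprintf("read_count_table: non-numeric value '%s' at row '%s', column '%s'",
                   cell[i], labels[i], colnames(body)[j]), call. = FALSE)
    }
    body[[j]] <- val
  }
  m <- as.matrix(body)
  rownames(m) <- labels
  if (transpose) m <- t(m)
  count_table(m, rank = rank)
}

#' Write a count table to TSV
#'
#' @param table A [count_table].
#' @param path Output path.
#' @param taxon_column Name of the first (taxon-label) column.
#' @return The path, invisibly.
#' @export
write_count_table <- function(table, path, taxon_column = "taxon") {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(table$taxa, table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(taxon_column, table$samples)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# ---- sample metadata --------------------------------------------------------

.methods <- c("shotgun", "pma_shotgun", "metat", "s16")
.platforms <- c("illumina", "ont")
.conditions <- c("live", "dead", "control_live", "control_dead", "unspiked")

#' Assemble and validate sample metadata
#'
#' One row per sample: sequencing method, platform, spike condition, replicate
#' and the sample's total-bacteria qPCR estimate (cells/mL; `NA` if the assay
#' was not run).
#'
#' @param sample_id,method,platform,condition,replicate,qpcr_total Vectors of
#'   equal length (replicate integer >= 1; qpcr_total >= 0 or `NA`).
#' @return A `data.frame` with validated columns.
#' @export
sample_metadata <- function(sample_id, method, platform, condition, replicate,
                            qpcr_total = NA_real_) {
  df <- data.frame(sample_id = as.character(sample_id),
                   method = as.character(method),
                   platform = as.character(platform),
                   condition = as.character(condition),
                   replicate = as.integer(replicate),
                   qpcr_total = as.numeric(qpcr_total),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$method), .methods)
  if (length(bad)) stop(sprintf("sample_metadata: unknown method '%s'", bad[1L]),
                        call. = FALSE)
  bad <- setdiff(unique(df$platform), .platforms)
  if (length(bad)) stop(sprintf("sample_metadata: unknown platform '%s'", bad[1L]),
                        call. = FALSE)
  bad <- setdiff(unique(df$condition), .conditions)
  if (length(bad)) stop(sprintf("sample_metadata: unknown condition '%s'", bad[1L]),
                        call. = FALSE)
  if (any(df$replicate < 1L)) stop("sample_metadata: replicate must be >= 1",
                                   call. = FALSE)
  if (any(!is.na(df$qpcr_total) & df$qpcr_total < 0)) {
    stop("sample_metadata: qpcr_total must be >= 0", call. = FALSE)
  }
  key <- paste(df$method, df$platform, df$condition, df$replicate)
  if (anyDuplicated(key)) {
    stop(sprintf("sample_metadata: duplicate (method, platform, condition, replicate): %s",
                 key[duplicated(key)][1L]), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop(sprintf("sample_metadata: duplicate sample id '%s'",
                 df$sample_id[duplicated(df$sample_id)][1L]), call. = FALSE)
  }
  df
}

#' Read sample metadata from TSV
#' @param path TSV with columns sample_id, method, platform, condition,
#'   replicate, qpcr_total.
#' @return A validated metadata `data.frame`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "method", "platform", "condition", "replicate",
            "qpcr_total")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop(sprintf("read_sample_metadata: missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sample_metadata(df$sample_id, df$method, df$platform, df$condition,
                  df$replicate, df$qpcr_total)
}

#' Write sample metadata to TSV
#' @param metadata A metadata `data.frame` (see [sample_metadata]).
#' @param path Output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# ---- taxonomy harmonization -------------------------------------------------

#' Default raw-name to canonical-genus harmonization map
#'
#' Reference taxonomies name the same organism differently: GTDB splits genera
#' with suffixed placeholders ("Pseudomonas_E"), Silva merges
#' "Escherichia-Shigella", and short reads can resolve a staphylococcal strain
#' to a sibling species within the same species group. The default map covers
#' the names the bundled mock community is emitted under.
#'
#' @return Named character vector: `raw_name -> canonical_genus`.
#' @export
default_harmonization_map <- function() {
  c("Pseudomonas_E proteolytica" = "Pseudomonas",
    "Pseudomonas_E"              = "Pseudomonas",
    "Escherichia-Shigella"       = "Escherichia",
    "Escherichia coli"           = "Escherichia",
    "Staphylococcus hominis"     = "Staphylococcus",
    "Staphylococcus haemolyticus" = "Staphylococcus",
    "Bacillus velezensis"        = "Bacillus",
    "Lactococcus lactis"         = "Lactococcus")
}

#' Read a harmonization map from JSON
#' @param path JSON file of `{"raw name": "CanonicalGenus", ...}` pairs.
#' @return Named character vector.
#' @export
read_harmonization_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  map <- unlist(x)
  if (any(!nzchar(map))) {
    stop("read_harmonization_map: empty canonical genus in map", call. = FALSE)
  }
  map
}

#' Harmonize raw taxon names to canonical genera
#'
#' Names present in the map take the mapped genus. Unmapped names fall back to
#' their first whitespace-delimited token, with a trailing GTDB-style
#' placeholder suffix (`"_<capital letter>"`) stripped, so
#' `"Pseudomonas_E proteolytica"` resolves to `"Pseudomonas"` even without a
#' map entry.
#'
#' @param raw_names Character vector of classifier-emitted names.
#' @param map Named character vector (see [default_harmonization_map]).
#' @return Character vector of canonical genus names.
#' @export
harmonize_taxa <- function(raw_names, map = default_harmonization_map()) {
  out <- unname(map[raw_names])
  fallback <- is.na(out)
  if (any(fallback)) {
    token <- sub("\\s.*$", "", raw_names[fallback])
    token <- sub("_[A-Z]$", "", token)
    out[fallback] <- token
  }
  if (any(!nzchar(out))) {
    stop("harmonize_taxa: harmonization produced an empty genus", call. = FALSE)
  }
  out
}

.unclassified_pattern <- "^(unclassified|unassigned)$"

#' Drop unclassified rows from a count table
#'
#' Rows labelled "unclassified" or "unassigned" (case-insensitive) are removed
#' before normalization; the dropped mass is reported via a message and
#' attached as attribute `"dropped_mass"` (per-sample counts).
#'
#' @param table A [count_table].
#' @return The filtered [count_table].
#' @export
drop_unclassified <- function(table) {
  stopifnot(inherits(table, "count_table"))
  drop <- grepl(.unclassified_pattern, table$taxa, ignore.case = TRUE)
  if (!any(drop)) return(table)
  dropped <- colSums(table$counts[drop, , drop = FALSE])
  out <- count_table(table$counts[!drop, , drop = FALSE], rank = table$rank)
  message(sprintf("drop_unclassified: removed %d row(s); total mass dropped: %g",
                  sum(drop), sum(dropped)))
  attr(out, "dropped_mass") <- dropped
  out
}

#' Collapse a count table to canonical genus level
#'
#' Taxa are relabelled via the harmonization map (fallback: first token of the
#' raw name, GTDB suffix stripped) and rows sharing a canonical genus are
#' summed. Per-sample totals are conserved exactly and the operation is
#' idempotent.
#'
#' @param table A [count_table] (may mix species- and genus-level labels).
#' @param map Harmonization map (named character vector).
#' @return A genus-rank [count_table] with unique taxon labels.
#' @export
collapse_to_genus <- function(table, map = default_harmonization_map()) {
  stopifnot(inherits(table, "count_table"))
  genus <- harmonize_taxa(table$taxa, map)
  groups <- factor(genus, levels = unique(genus))
  m <- rowsum(table$counts, group = groups, reorder = FALSE)
  rownames(m) <- levels(groups)
  count_table(m, rank = "genus")
}

# ---- normalization ----------------------------------------------------------

#' Normalize a count vector to relative abundances
#'
#' @param x Non-negative numeric vector with at least one positive entry.
#' @return Vector proportional to `x` summing to 1 (names preserved).
#' @examples
#' normalize_profile(c(10, 30, 60))
#' @export
normalize_profile <- function(x) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop("normalize_profile: need a non-empty numeric vector", call. = FALSE)
  }
  if (any(x < 0)) stop("normalize_profile: negative abundance", call. = FALSE)
  s <- sum(x)
  if (s <= 0) stop("normalize_profile: empty sample (all-zero column)",
                   call. = FALSE)
  x / s
}

#' Relative-abundance matrix of a count table
#'
#' Applies [normalize_profile] column-wise.
#'
#' @param table A [count_table].
#' @return Numeric matrix (taxa x samples) with unit column sums.
#' @export
profile_matrix <- function(table) {
  stopifnot(inherits(table, "count_table"))
  apply(table$counts, 2L, normalize_profile)
}

# ---- mock community ---------------------------------------------------------

#' Define a mock (model) community
#'
#' The ground truth against which profiling methods are scored: member strains,
#' their intended proportions, and the spike density. The default is the
#' 5-strain milk community (Bacillus, Escherichia, Lactococcus, Pseudomonas,
#' Staphylococcus) at equal proportions, spiked at 1e7 cells/mL per strain.
#'
#' @param genera Character vector of canonical genus names.
#' @param strains Character vector of strain names (same length).
#' @param proportions Intended relative proportions (must sum to 1).
#' @param spike_density Spike density in cells/mL (per-strain suspension
#'   density before equal-volume mixing).
#' @return An object of class `mock_community_spec`.
#' @export
mock_community_spec <- function(
    genera = c("Bacillus", "Escherichia", "Lactococcus", "Pseudomonas",
               "Staphylococcus"),
    strains = c("Bacillus velezensis", "Escherichia coli",
                "Lactococcus lactis", "Pseudomonas proteolytica",
                "Staphylococcus haemolyticus"),
    proportions = rep(1 / length(genera), length(genera)),
    spike_density = 1e7) {
  if (length(genera) != length(strains) ||
      length(genera) != length(proportions)) {
    stop("mock_community_spec: genera, strains and proportions lengths differ",
         call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("mock_community_spec: proportions must sum to 1", call. = FALSE)
  }
  if (any(proportions < 0) || spike_density <= 0) {
    stop("mock_community_spec: negative proportion or non-positive density",
         call. = FALSE)
  }
  structure(list(genera = genera, strains = strains,
                 proportions = stats::setNames(proportions, genera),
                 spike_density = spike_density),
            class = "mock_community_spec")
}

#' @export
print.mock_community_spec <- function(x, ...) {
  cat(sprintf("<mock_community_spec> %d members, spike density %g cells/mL\n",
              length(x$genera), x$spike_density))
  print(data.frame(genus = x$genera, strain = x$strains,
                   proportion = unname(x$proportions)))
  invisible(x)
}

#' Read / write a mock community specification (JSON)
#' @param path JSON path.
#' @return [mock_community_spec] (reader) or the path invisibly (writer).
#' @export
read_mock_community_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mock_community_spec(genera = x$members$genus, strains = x$members$strain,
                      proportions = x$members$proportion,
                      spike_density = x$spike_density)
}

#' @rdname read_mock_community_spec
#' @param spec A [mock_community_spec].
#' @export
write_mock_community_spec <- function(spec, path) {
  stopifnot(inherits(spec, "mock_community_spec"))
  jsonlite::write_json(
    list(members = data.frame(genus = spec$genera, strain = spec$strains,
                              proportion = unname(spec$proportions)),
         spike_density = spec$spike_density),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
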