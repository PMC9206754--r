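#' Validate a taxa-by-samples count matrix
#'
#' A count table is an integer matrix with taxa as rows and samples as
#' columns, unique row and column names, non-negative integer cells and
#' (after preparation) a positive total per sample.
#'
#' @param counts integer matrix, taxa x samples, with dimnames.
#' @param require_positive_samples error on all-zero sample columns.
#' @return the validated matrix, invisibly.
#' @export
validate_count_table <- function(counts, require_positive_samples = TRUE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("count table must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table must carry taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts))) stop("non-numeric or missing cells in count table")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (require_positive_samples && any(colSums(counts) == 0))
    stop("samples with zero total reads: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  invisible(counts)
}

#' Read a count table from tab-separated text
#'
#' First column holds row identifiers, header holds column identifiers.
#' The result is always oriented taxa x samples.
#'
#' @param path TSV file.
#' @param orientation `"taxa_rows"` (default) if file rows are taxa,
#'   `"samples_rows"` if file rows are samples (transposed on load).
#' @return integer matrix taxa x samples.
#' @export
load_count_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]][-1]
  if (anyDuplicated(hdr))
    stop("duplicate sample ids in header: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in count table")
  rownames(m) <- ids
  if (orientation == "samples_rows") m <- t(m)
  storage.mode(m) <- "integer"
  validate_count_table(m, require_positive_samples = FALSE)
  m
}

#' Write a count table as tab-separated text
#' @param counts taxa x samples matrix.
#' @param path output file.
#' @param id_column name for the leading identifier column.
#' @export
write_count_table <- function(counts, path, id_column = "taxon_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Categorize adult age in years
#'
#' Young adult spans 6--10 inclusive, mid-aged is strictly between 10 and
#' 18, old is 18 and above. Ages below 6 denote non-adult samples and are
#' rejected.
#'
#' @param age numeric vector of ages in years.
#' @return factor with levels `young`, `mid`, `old`.
#' @export
derive_age_category <- function(age) {
  if (any(!is.finite(age)) || any(age < 0)) stop("ages must be non-negative numbers")
  if (any(age < 6))
    stop("non-adult age(s) below 6 y must not enter the pipeline: ",
         paste(age[age < 6], collapse = ", "))
  out <- ifelse(age <= 10, "young", ifelse(age < 18, "mid", "old"))
  factor(out, levels = c("young", "mid", "old"))
}

.meta_required <- c("sample_id", "individual_id", "age", "group", "season",
                    "gestation", "collection_date", "rainfall_30d")

#' Read per-sample metadata from CSV
#'
#' Requires columns `sample_id, individual_id, age, group, season,
#' gestation, collection_date, rainfall_30d`; `read_count` and
#' `age_category` are optional (`age_category` is derived from `age` when
#' absent). Dates must be ISO-8601 (`YYYY-MM-DD`).
#'
#' @param path CSV file.
#' @return data.frame, one row per sample, `collection_date` as `Date`.
#' @export
load_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.meta_required, colnames(df))
  if (length(miss)) stop("missing required metadata column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  dates <- as.Date(as.character(df$collection_date), format = "%Y-%m-%d")
  if (any(is.na(dates)))
    stop("unparseable collection_date at row(s): ",
         paste(which(is.na(dates)), collapse = ", "))
  df$collection_date <- dates
  if (!all(df$gestation %in% c(0, 1))) stop("gestation must be 0/1")
  if (is.null(df$age_category)) {
    df$age_category <- derive_age_category(df$age)
  } else {
    df$age_category <- factor(df$age_category, levels = c("young", "mid", "old"))
  }
  df$group <- factor(df$group)
  df$season <- factor(df$season)
  df
}

#' Remove spurious low-abundance signal from a count table
#'
#' Two filters, iterated jointly to a fixed point so the operation is
#' idempotent: (i) taxa present in at most `min_samples - 1` samples are
#' dropped; (ii) with `mode = "per_sample"` (default) every cell whose
#' within-sample relative abundance falls below `min_relab` is zeroed,
#' with `mode = "per_taxon"` whole taxa whose relative abundance never
#' reaches `min_relab` in any sample are dropped. Taxa left all-zero are
#' dropped.
#'
#' @param counts taxa x samples matrix.
#' @param min_relab relative-abundance threshold (default 0.25%).
#' @param min_samples minimum number of samples a taxon must occur in.
#' @param mode apply the threshold within samples (zeroing cells) or to
#'   whole taxa.
#' @return filtered matrix with attribute `removal_report`, a list with
#'   `taxa_dropped` (ids) and `cells_zeroed` (count).
#' @export
filter_spurious <- function(counts, min_relab = 0.0025, min_samples = 2,
                            mode = c("per_sample", "per_taxon")) {
  mode <- match.arg(mode)
  validate_count_table(counts, require_positive_samples = FALSE)
  dropped <- character(0)
  zeroed <- 0L
  repeat {
    changed <- FALSE
    pres <- rowSums(counts > 0)
    kill <- pres < min_samples
    if (any(kill)) {
      dropped <- c(dropped, rownames(counts)[kill])
      counts <- counts[!kill, , drop = FALSE]
      changed <- TRUE
    }
    if (nrow(counts) == 0) stop("count table empty after filtering")
    relab <- sweep(counts, 2, pmax(colSums(counts), 1), "/")
    if (mode == "per_sample") {
      low <- counts > 0 & relab < min_relab
      if (any(low)) {
        zeroed <- zeroed + sum(low)
        counts[low] <- 0L
        changed <- TRUE
      }
    } else {
      kill <- apply(relab, 1, max) < min_relab
      if (any(kill)) {
        dropped <- c(dropped, rownames(counts)[kill])
        counts <- counts[!kill, , drop = FALSE]
        changed <- TRUE
      }
    }
    gone <- rowSums(counts) == 0
    if (any(gone)) {
      dropped <- c(dropped, rownames(counts)[gone])
      counts <- counts[!gone, , drop = FALSE]
      changed <- TRUE
    }
    if (nrow(counts) == 0) stop("count table empty after filtering")
    if (!changed) break
  }
  validate_count_table(counts)
  attr(counts, "removal_report") <- list(taxa_dropped = dropped, cells_zeroed = zeroed)
  counts
}

#' Rarefy every sample to a common read depth
#'
#' Each sample's counts are replaced by a without-replacement subsample of
#' exactly `depth` reads (a single seeded draw; the analysis rarefies once
#' at the minimum sample depth).
#'
#' @param counts taxa x samples matrix.
#' @param depth target depth; default is the minimum sample total.
#' @param seed integer seed making the draw reproducible.
#' @return rarefied integer matrix with identical dimnames.
#' @export
rarefy <- function(counts, depth = NULL, seed = 1L) {
  validate_count_table(counts)
  totals <- colSums(counts)
  depth <- depth %||% min(totals)
  if (depth < 1) stop("rarefaction depth must be at least 1")
  if (any(totals < depth))
    stop("depth ", depth, " exceeds total reads of sample(s): ",
         paste(colnames(counts)[totals < depth], collapse = ", "))
  out <- withr::with_seed(seed, suppressWarnings(t(vegan::rrarefy(t(counts), depth))))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(counts)
  out
}

#' Write / read a labeled square dissimilarity matrix (TSV)
#'
#' Values are serialized with 17 significant digits so a round trip is
#' exact to double precision. Loading validates symmetry and a zero
#' diagonal; an optional `labels` argument returns the matrix reordered.
#'
#' @param m symmetric numeric matrix with matching dimnames.
#' @param path file path.
#' @export
write_distance_matrix <- function(m, path) {
  .validate_distance_matrix(m)
  txt <- matrix(sprintf("%.17g", m), nrow(m))
  df <- data.frame(rownames(m), txt, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @param labels optional label order for the returned matrix.
#' @export
load_distance_matrix <- function(path, labels = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  .validate_distance_matrix(m)
  if (!is.null(labels)) {
    if (!setequal(labels, rownames(m))) stop("requested labels do not match matrix labels")
    m <- m[labels, labels]
  }
  m
}

.validate_distance_matrix <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop("distance matrix must carry identical row and column labels")
  if (any(abs(m - t(m)) > tol)) stop("distance matrix is asymmetric")
  if (any(abs(diag(m)) > tol)) stop("distance matrix has a non-zero diagonal")
  invisible(m)
}
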