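# Plain-text interchange: cohorts and matrices as deterministic TSV.
# 12 significant digits keeps round-trips lossless beyond 1e-9 relative.

.fmt_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- "NA"
  out
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")  # binary: fixed \n line endings
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  cols <- lapply(df, function(col) if (is.numeric(col)) .fmt_num(col) else as.character(col))
  writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

.numeric_table <- function(df, path) {
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    conv <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
    bad <- which(is.na(conv) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("non-numeric cell in ", basename(path), " at row ", bad[1, 1],
           ", column '", colnames(m)[bad[1, 2]], "'")
    dimnames(conv) <- dimnames(m)
    m <- conv
  }
  rownames(m) <- ids
  m
}

#' Save a cohort as a directory of TSV tables
#'
#' Writes `metadata.tsv`, one wide table per structural measure
#' (`area.tsv`, `thickness.tsv`, `myelin.tsv`, `subcortical.tsv`),
#' `scalars.tsv` (eTIV, global surface area) and, when present, one
#' `timeseries/<subject>.tsv` per subject (parcels x timepoints).
#' All writers emit deterministic byte streams.
#'
#' @param cohort A `syn_cohort` (or compatible list).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(cohort$meta, file.path(dir, "metadata.tsv"))
  for (m in c("area", "thickness", "myelin", "subcortical")) {
    df <- data.frame(subject_id = rownames(cohort[[m]]), cohort[[m]],
                     check.names = FALSE, stringsAsFactors = FALSE)
    .write_tsv(df, file.path(dir, paste0(m, ".tsv")))
  }
  sc <- data.frame(subject_id = cohort$meta$subject_id,
                   etiv = unname(cohort$etiv[cohort$meta$subject_id]),
                   global_area = unname(cohort$global_area[cohort$meta$subject_id]),
                   stringsAsFactors = FALSE)
  .write_tsv(sc, file.path(dir, "scalars.tsv"))
  if (!is.null(cohort$timeseries)) {
    tdir <- file.path(dir, "timeseries")
    dir.create(tdir, showWarnings = FALSE)
    for (id in names(cohort$timeseries)) {
      ts <- cohort$timeseries[[id]]
      df <- data.frame(parcel = rownames(ts), ts, check.names = FALSE,
                       stringsAsFactors = FALSE)
      colnames(df) <- c("parcel", sprintf("t%04d", seq_len(ncol(ts))))
      .write_tsv(df, file.path(tdir, paste0(id, ".tsv")))
    }
  }
  invisible(dir)
}

#' Load a cohort saved by [save_cohort()]
#'
#' Validates that every measure table covers exactly the metadata's subject
#' set (errors name the offending subject), that subject ids are unique, and
#' canonicalizes row order to the metadata order and column order by parcel
#' label.
#'
#' @param dir Directory written by [save_cohort()].
#' @param load_timeseries Read per-subject time series if present (default
#'   TRUE).
#' @return A `syn_cohort` list (without the generating config).
#' @export
load_cohort <- function(dir, load_timeseries = TRUE) {
  meta <- .read_tsv(file.path(dir, "metadata.tsv"))
  if (anyDuplicated(meta$subject_id))
    stop("duplicate subject_id in metadata: ",
         meta$subject_id[duplicated(meta$subject_id)][1])
  ids <- meta$subject_id
  read_measure <- function(name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    m <- .numeric_table(.read_tsv(path), path)
    missing <- setdiff(ids, rownames(m))
    if (length(missing))
      stop("subject '", missing[1], "' missing from ", name, ".tsv")
    extra <- setdiff(rownames(m), ids)
    if (length(extra))
      stop("subject '", extra[1], "' in ", name, ".tsv absent from metadata")
    m <- m[ids, sort(colnames(m)), drop = FALSE]
    m
  }
  out <- list(meta = meta)
  for (m in c("area", "thickness", "myelin", "subcortical"))
    out[[m]] <- read_measure(m)
  sc <- read_measure("scalars")
  out$etiv <- sc[, "etiv"]
  out$global_area <- sc[, "global_area"]
  tdir <- file.path(dir, "timeseries")
  out$timeseries <- NULL
  if (load_timeseries && dir.exists(tdir)) {
    ts <- lapply(ids, function(id) {
      path <- file.path(tdir, paste0(id, ".tsv"))
      if (!file.exists(path)) stop("time series missing for subject '", id, "'")
      m <- .numeric_table(.read_tsv(path), path)
      m
    })
    names(ts) <- ids
    out$timeseries <- ts
  }
  structure(out, class = "syn_cohort")
}

#' Save a labeled numeric matrix as TSV
#'
#' Header row and first column carry the labels. Square matrices must be
#' symmetric within 1e-8 and are stored in full.
#'
#' @param m Numeric matrix.
#' @param path Output file.
#' @param labels Row labels (default `rownames(m)`); column labels are taken
#'   from `colnames(m)` (or `labels` when square).
#' @return `path`, invisibly.
#' @export
save_matrix <- function(m, path, labels = rownames(m)) {
  if (is.null(labels)) labels <- sprintf("r%04d", seq_len(nrow(m)))
  collabs <- colnames(m)
  if (nrow(m) == ncol(m)) {
    if (max(abs(m - t(m))) > 1e-8)
      stop("square matrix is not symmetric within 1e-8")
    if (is.null(collabs)) collabs <- labels
  } else if (is.null(collabs)) {
    collabs <- sprintf("c%04d", seq_len(ncol(m)))
  }
  df <- data.frame(label = labels, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("label", collabs)
  .write_tsv(df, path)
}

#' Load a matrix saved by [save_matrix()]
#'
#' @param path TSV file.
#' @return Numeric matrix with dimnames restored.
#' @export
load_matrix <- function(path) {
  .numeric_table(.read_tsv(path), path)
}
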