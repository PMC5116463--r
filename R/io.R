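# Trial matrix readers/writers. Dialect chosen by extension:
#   .csv  comma-separated text, one row per sample, one column per channel
#   .tsv  tab-separated text, same layout
#   .rds  R binary matrix container
.readTrialMatrix <- function(path) {
  if (!file.exists(path))
    stop(sprintf("trial file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    csv = as.matrix(utils::read.table(path, sep = ",", header = FALSE)),
    tsv = ,
    txt = as.matrix(utils::read.table(path, sep = "\t", header = FALSE)),
    rds = readRDS(path),
    stop(sprintf("unsupported trial file extension '.%s' (%s)", ext, path))
  )
  if (!is.numeric(m))
    stop(sprintf("non-numeric content in trial file: %s", path))
  m <- unname(as.matrix(m))
  storage.mode(m) <- "double"
  m
}

.writeTrialMatrix <- function(m, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = utils::write.table(m, path, sep = ",", row.names = FALSE,
                             col.names = FALSE),
    tsv = ,
    txt = utils::write.table(m, path, sep = "\t", row.names = FALSE,
                             col.names = FALSE),
    rds = saveRDS(m, path),
    stop(sprintf("unsupported trial file extension '.%s'", ext))
  )
  invisible(path)
}

#' Load an EMG dataset from a manifest
#'
#' The manifest is a YAML document holding \code{sampling_rate},
#' \code{channel_names} and a \code{trials} table; each trial entry names a
#' matrix file (path relative to the manifest), its class label, its
#' repetition index, and optionally pre-segmented \code{active_intervals}
#' (0-based half-open \code{[onset, offset)} pairs) that bypass activity
#' detection downstream.
#'
#' @param manifestPath path to the manifest file.
#' @return A validated \code{\linkS4class{EMGDataset}}; trial order follows
#'   the manifest.
#' @seealso \code{\link{writeDataset}} for the inverse operation.
#' @export
loadDataset <- function(manifestPath) {
  if (!file.exists(manifestPath))
    stop(sprintf("manifest not found: %s", manifestPath))
  man <- yaml::read_yaml(manifestPath)
  for (f in c("sampling_rate", "channel_names", "trials"))
    if (is.null(man[[f]]))
      stop(sprintf("manifest is missing the '%s' field", f))
  base <- dirname(manifestPath)
  channelNames <- as.character(man$channel_names)
  trials <- vector("list", length(man$trials))
  labels <- character(length(man$trials))
  reps <- integer(length(man$trials))
  intervals <- vector("list", length(man$trials))
  for (i in seq_along(man$trials)) {
    tr <- man$trials[[i]]
    path <- file.path(base, tr$file)
    m <- .readTrialMatrix(path)
    if (ncol(m) != length(channelNames))
      stop(sprintf(
        "trial '%s' has %d columns but %d channel names are declared",
        tr$file, ncol(m), length(channelNames)))
    trials[[i]] <- m
    labels[i] <- as.character(tr$class)
    reps[i] <- as.integer(tr$repetition)
    if (!is.null(tr$active_intervals)) {
      iv <- do.call(rbind, lapply(tr$active_intervals, as.integer))
      colnames(iv) <- c("onset", "offset")
      intervals[[i]] <- iv
    }
  }
  EMGDataset(trials, labels, reps, as.numeric(man$sampling_rate),
             channelNames, intervals)
}

#' Write an EMG dataset as trial files plus a manifest
#'
#' @param dataset an \code{\linkS4class{EMGDataset}}.
#' @param dir output directory (created if needed).
#' @param format trial matrix dialect: \code{"csv"}, \code{"tsv"} or
#'   \code{"rds"}.
#' @return The manifest path, invisibly.
#' @export
writeDataset <- function(dataset, dir, format = c("csv", "tsv", "rds")) {
  stopifnot(is(dataset, "EMGDataset"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nTrials(dataset)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    fn <- sprintf("trial_%03d.%s", i, format)
    .writeTrialMatrix(dataset@trials[[i]], file.path(dir, fn))
    e <- list(file = fn, class = dataset@classLabels[i],
              repetition = dataset@repetitions[i])
    iv <- dataset@activeIntervals[[i]]
    if (!is.null(iv) && nrow(iv) > 0L)
      e$active_intervals <- lapply(seq_len(nrow(iv)),
                                   function(r) as.integer(iv[r, ]))
    entries[[i]] <- e
  }
  man <- list(sampling_rate = dataset@samplingRate,
              channel_names = as.list(dataset@channelNames),
              trials = entries)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, path, precision = 17L)
  invisible(path)
}

#' Write a FeatureMatrix as a table plus a column-map sidecar
#'
#' The values go to \code{<stem>.csv} (with \code{label} and
#' \code{repetition} columns first) and the per-column provenance to
#' \code{<stem>_columns.csv}.
#'
#' @param x a \code{\linkS4class{FeatureMatrix}}.
#' @param stem output path stem (no extension).
#' @return The values path, invisibly.
#' @export
writeFeatureMatrix <- function(x, stem) {
  stopifnot(is(x, "FeatureMatrix"))
  df <- data.frame(label = x@labels, repetition = x@repetitions,
                   x@values, check.names = FALSE)
  names(df) <- c("label", "repetition",
                 paste0("f", seq_len(ncol(x@values))))
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  utils::write.csv(x@columnMap, paste0(stem, "_columns.csv"),
                   row.names = FALSE)
  invisible(paste0(stem, ".csv"))
}

#' Read a FeatureMatrix written by \code{writeFeatureMatrix}
#'
#' @param stem the path stem used when writing.
#' @return A \code{\linkS4class{FeatureMatrix}}.
#' @export
readFeatureMatrix <- function(stem) {
  df <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE)
  cm <- utils::read.csv(paste0(stem, "_columns.csv"),
                        stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(vals) <- NULL
  FeatureMatrix(vals, df$label, df$repetition, cm)
}
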