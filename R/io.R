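#' Write / read EEG segments as delimited text
#'
#' Segments are stored one file per segment in a directory: `#`-prefixed
#' key-value header lines carry the metadata (label, sample rate), then
#' a tab-separated table with one row per time sample and one `chN`
#' column per channel. Values are written at full precision so a
#' round-trip reproduces the numbers exactly.
#'
#' @param segments list of [eeg_segment()] objects.
#' @param path directory to write into (created if missing).
#' @return `write_segments()` invisibly returns the file paths;
#'   `read_segments()` returns a list of [eeg_segment()]s.
#' @export
write_segments <- function(segments, path) {
  if (inherits(segments, "eeg_segment")) segments <- list(segments)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(path, sprintf("segment_%04d.tsv", seq_along(segments)))
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    con <- file(files[i], "w")
    writeLines(c(sprintf("# label: %s",
                         if (is.null(s$label)) "NA" else s$label),
                 sprintf("# sample_rate: %.17g", s$sample_rate),
                 paste(rownames(s$samples), collapse = "\t")), con)
    utils::write.table(format(t(s$samples), digits = 17, trim = TRUE,
                              scientific = FALSE),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  invisible(files)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
  Filter(Negate(is.null), lapply(files, read_one_segment))
}

read_one_segment <- function(file) {
  lines <- readLines(file)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (!length(m)) return(NULL)
    trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  label <- get_meta("label")
  if (is.null(label)) {
    warning("missing label metadata; defaulting to unlabeled")
    label <- "NA"
  }
  rate <- get_meta("sample_rate")
  if (is.null(rate)) {
    warning("missing sample_rate metadata; defaulting to 125 Hz")
    rate <- "125"
  }
  if (!length(body)) return(NULL)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  n_ch <- length(header)
  rows <- body[-1]
  if (!length(rows)) {
    warning(sprintf("'%s' has a header but no data rows; skipping",
                    basename(file)))
    return(NULL)
  }
  parts <- strsplit(rows, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_ch)
  if (length(bad))
    stopf("parse error at line %d of '%s': expected %d columns, found %d",
          length(meta) + 1 + bad[1], basename(file), n_ch,
          lengths(parts)[bad[1]])
  m <- matrix(as.numeric(unlist(parts)), ncol = n_ch, byrow = TRUE)
  if (anyNA(m)) stopf("parse error in '%s': non-numeric value", basename(file))
  eeg_segment(t(m), sample_rate = as.numeric(rate),
              label = if (label == "NA") NULL else label)
}

MODEL_FORMAT_VERSION <- 1L

# full-precision double <-> string (round-trips bit-exactly)
num_to_chr <- function(x) sprintf("%.17g", x)

#' Save / load a fitted SOM-Hebb classifier
#'
#' The model — weights, neuron labels, enabled flags, win counts, class
#' set, bands and schedule — is serialized to a single JSON file with
#' weights written as 17-significant-digit strings, so a round-trip is
#' bit-exact and loaded models predict identically.
#'
#' @param model a fitted `"som_hebb"`.
#' @param path file path (`.json`).
#' @return `read_som_hebb()` returns the restored `"som_hebb"` object.
#' @export
write_som_hebb <- function(model, path) {
  stopifnot(inherits(model, "som_hebb"))
  sched <- model$schedule
  payload <- list(
    format = "som_hebb", version = MODEL_FORMAT_VERSION,
    M = model$map$M, D = model$map$D,
    classes = model$classes,
    bands = model$bands,
    schedule = list(epochs = sched$epochs, alpha0 = sched$alpha0,
                    alpha_final = sched$alpha_final,
                    sigma0 = sched$sigma0, sigma_final = sched$sigma_final,
                    decay = sched$decay, seed = sched$seed),
    weights = num_to_chr(model$map$weights),
    feature_names = colnames(model$map$weights),
    label = model$neuron_labels$label,
    enabled = model$neuron_labels$enabled,
    counts = model$neuron_labels$counts$counts,
    train_qe = num_to_chr(model$train_qe),
    n_train = model$n_train)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_som_hebb
#' @export
read_som_hebb <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e)
                        stop("incompatible model file: ", conditionMessage(e),
                             call. = FALSE))
  if (!identical(payload$format, "som_hebb") ||
      !identical(as.integer(payload$version), MODEL_FORMAT_VERSION))
    stop("incompatible model file: unknown format or version")
  M <- as.integer(payload$M); D <- as.integer(payload$D)
  n <- M^2
  W <- matrix(as.numeric(payload$weights), n, D)
  colnames(W) <- payload$feature_names
  k <- seq_len(n) - 1L
  map <- structure(list(weights = W,
                        grid = cbind(row = k %/% M + 1L, col = k %% M + 1L),
                        M = M, D = D), class = "som_map")
  counts <- matrix(as.integer(payload$counts), n, length(payload$classes),
                   dimnames = list(NULL, payload$classes))
  wins <- structure(list(counts = counts, classes = payload$classes),
                    class = "win_counts")
  lab <- as.character(payload$label)
  sched <- payload$schedule
  schedule <- som_schedule(epochs = sched$epochs, alpha0 = sched$alpha0,
                           alpha_final = sched$alpha_final,
                           sigma0 = if (is.null(sched$sigma0)) NULL else
                             sched$sigma0,
                           sigma_final = sched$sigma_final,
                           decay = sched$decay, seed = sched$seed)
  structure(list(map = map,
                 neuron_labels = structure(
                   list(label = lab,
                        enabled = as.logical(payload$enabled),
                        counts = wins),
                   class = "som_labels"),
                 classes = payload$classes,
                 bands = as.data.frame(payload$bands),
                 schedule = schedule,
                 grid_size = M,
                 train_qe = as.numeric(payload$train_qe),
                 n_train = as.integer(payload$n_train),
                 call = NULL),
            class = "som_hebb")
}
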