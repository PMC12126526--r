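# Format plumbing: trajectory readers (DeepLabCut dialect and a plain
# time,x,y table), dF/F trace matrices with a YAML metadata sidecar, and the
# session manifest.

#' Read a DeepLabCut tracking table
#'
#' Parses the standard DeepLabCut CSV layout: three header rows (scorer /
#' bodyparts / coords) over an index column plus x, y, likelihood triplets
#' per body part. Returns the selected body part as a pixel-space
#' [trajectory()] with `time = frame_index / fps`.
#'
#' @param path File path.
#' @param fps Camera frame rate used to convert frame index to seconds.
#' @param bodypart Body part name; default the first one in the file.
#' @param sep Field separator, default ",".
#' @return A [trajectory()] in pixel coordinates with DLC likelihoods as
#'   confidence.
#' @export
read_dlc <- function(path, fps, bodypart = NULL, sep = ",") {
  lines <- readLines(path, n = 3)
  if (length(lines) < 3) stop("not a DeepLabCut table: ", path, call. = FALSE)
  hdr <- lapply(lines, function(l) strsplit(l, sep, fixed = TRUE)[[1]])
  bodyparts <- hdr[[2]][-1]
  coords <- hdr[[3]][-1]
  if (!identical(tolower(hdr[[3]][1]), "coords")) {
    stop("missing 'coords' header row; not a DeepLabCut table", call. = FALSE)
  }
  if (is.null(bodypart)) bodypart <- bodyparts[1]
  sel <- which(bodyparts == bodypart)
  if (length(sel) == 0) {
    stop("body part not found: ", bodypart, " (available: ",
         paste(unique(bodyparts), collapse = ", "), ")", call. = FALSE)
  }
  dat <- utils::read.table(path, sep = sep, skip = 3, header = FALSE)
  col <- function(what) {
    j <- sel[coords[sel] == what]
    if (length(j) != 1) stop("missing ", what, " column for ", bodypart,
                             call. = FALSE)
    as.numeric(dat[[j + 1]])
  }
  idx <- as.numeric(dat[[1]])
  trajectory(idx / fps, col("x"), col("y"), col("likelihood"))
}

#' Read a plain trajectory table
#'
#' Delimited text with header `time,x,y` and an optional `confidence`
#' column.
#'
#' @param path File path.
#' @param arena_size Arena side (cm) recorded on the result.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, arena_size = ARENA_SIDE_CM) {
  dat <- utils::read.csv(path)
  need <- c("time", "x", "y")
  if (!all(need %in% names(dat))) {
    stop("expected columns time,x,y in ", path, call. = FALSE)
  }
  conf <- if ("confidence" %in% names(dat)) dat$confidence else NULL
  trajectory(dat$time, dat$x, dat$y, conf, arena_size = arena_size)
}

#' Write a trajectory as a plain table
#'
#' @param traj A [trajectory()].
#' @param path Output file.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
}

#' Write a trace set
#'
#' The dF/F matrix as delimited text (one row per neuron, `neuron_id`
#' column plus one column per frame) and a YAML metadata sidecar
#' (`<path>.meta.yaml`: frame rate, condition, animal, experiment).
#'
#' @param ts A [trace_set()].
#' @param path Output file for the matrix.
#' @export
write_traces <- function(ts, path) {
  stopifnot(inherits(ts, "trace_set"))
  df <- data.frame(neuron_id = ts$neuron_ids, ts$dff,
                   check.names = FALSE)
  names(df) <- c("neuron_id", paste0("f", seq_len(ncol(ts$dff))))
  utils::write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(frame_rate = ts$frame_rate,
                        animal_id = ts$animal_id,
                        condition = ts$condition,
                        experiment = ts$experiment),
                   paste0(path, ".meta.yaml"))
}

#' Read a trace set
#'
#' Reads the matrix written by [write_traces()]. Metadata comes from the
#' YAML sidecar when present; explicit arguments override it. A two-file
#' layout (`ids_path` holding one neuron id per line, matrix without an id
#' column) is also accepted.
#'
#' @param path Matrix file.
#' @param frame_rate,animal_id,condition,experiment Metadata overrides.
#' @param ids_path Optional separate neuron-id file.
#' @return A [trace_set()].
#' @export
read_traces <- function(path, frame_rate = NULL, animal_id = NULL,
                        condition = NULL, experiment = NULL,
                        ids_path = NULL) {
  meta <- list()
  sidecar <- paste0(path, ".meta.yaml")
  if (file.exists(sidecar)) meta <- yaml::read_yaml(sidecar)
  pick <- function(arg, key, default) {
    if (!is.null(arg)) arg else if (!is.null(meta[[key]])) meta[[key]]
    else default
  }
  dat <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(ids_path)) {
    ids <- readLines(ids_path)
    dff <- as.matrix(dat)
  } else {
    if (!"neuron_id" %in% names(dat)) {
      stop("expected a neuron_id column (or supply ids_path) in ", path,
           call. = FALSE)
    }
    ids <- as.character(dat$neuron_id)
    dff <- as.matrix(dat[, setdiff(names(dat), "neuron_id"), drop = FALSE])
  }
  storage.mode(dff) <- "double"
  trace_set(dff,
            frame_rate = pick(frame_rate, "frame_rate", 3),
            neuron_ids = ids,
            animal_id = pick(animal_id, "animal_id", NA_character_),
            condition = pick(condition, "condition", NA_character_),
            experiment = pick(experiment, "experiment", NA_integer_))
}

#' Read a session manifest
#'
#' Validates the manifest written by [make_cohort()] (or hand-written in the
#' same layout): one row per session with metadata and relative file paths.
#'
#' @param path Manifest CSV; referenced files are resolved relative to its
#'   directory.
#' @return A tibble with an extra `dir` attribute.
#' @export
read_manifest <- function(path) {
  man <- tibble::as_tibble(utils::read.csv(path))
  need <- c("animal_id", "condition", "experiment", "session_id",
            "trajectory_file", "fps")
  miss <- setdiff(need, names(man))
  if (length(miss) > 0) {
    stop("manifest missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(man) == 0) stop("manifest is empty", call. = FALSE)
  bad <- setdiff(unique(man$condition), CONDITIONS)
  if (length(bad) > 0) {
    stop("manifest has unknown condition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dir <- dirname(path)
  for (f in man$trajectory_file) {
    if (!file.exists(file.path(dir, f))) {
      stop("missing trajectory file: ", f, call. = FALSE)
    }
  }
  attr(man, "dir") <- dir
  man
}
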