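#' Construct a single BOLD run
#'
#' A run is one subject x condition x session acquisition: a T x G BOLD
#' matrix in arbitrary BOLD units, the six rigid-body motion parameters
#' (translations in mm, rotations in radians), and precomputed ventricle and
#' white-matter nuisance time series.
#'
#' @param subject subject identifier (coerced to character).
#' @param condition one of `"Pla"`, `"LSD"`, `"KetLSD"`.
#' @param session session number, 1 or 2.
#' @param bold T x G numeric matrix.
#' @param tr repetition time in seconds.
#' @param motion T x 6 numeric matrix.
#' @param ventricle_ts,wm_ts length-T numeric nuisance channels.
#' @return an object of class `bold_run`.
#' @export
bold_run <- function(subject, condition, session, bold, tr, motion,
                     ventricle_ts, wm_ts) {
  run <- structure(list(subject = as.character(subject),
                        condition = match.arg(condition, CONDITIONS),
                        session = as.integer(session),
                        bold = bold, tr = as.numeric(tr),
                        motion = motion,
                        ventricle_ts = as.numeric(ventricle_ts),
                        wm_ts = as.numeric(wm_ts)),
                   class = "bold_run")
  validate_run(run)
  run
}

run_id <- function(run) {
  sprintf("%s_%s_s%d", run$subject, run$condition, run$session)
}

#' Validate a BOLD run
#'
#' @param run a `bold_run`.
#' @return the run, invisibly; errors name the offending run and field.
#' @export
validate_run <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  id <- run_id(run)
  t_len <- nrow(run$bold)
  if (is.null(t_len) || t_len < 8L)
    stop(sprintf("run %s: bold must have T >= 8 frames", id))
  if (!all(is.finite(run$bold)))
    stop(sprintf("run %s: bold contains non-finite values", id))
  if (!is.matrix(run$motion) || ncol(run$motion) != 6L)
    stop(sprintf("run %s: motion must be a T x 6 matrix", id))
  if (nrow(run$motion) != t_len)
    stop(sprintf("run %s: motion length %d does not match T = %d",
                 id, nrow(run$motion), t_len))
  if (length(run$ventricle_ts) != t_len)
    stop(sprintf("run %s: ventricle_ts length does not match T", id))
  if (length(run$wm_ts) != t_len)
    stop(sprintf("run %s: wm_ts length does not match T", id))
  if (!all(is.finite(run$motion)) || !all(is.finite(run$ventricle_ts)) ||
      !all(is.finite(run$wm_ts)))
    stop(sprintf("run %s: non-finite motion or nuisance values", id))
  if (!is.finite(run$tr) || run$tr <= 0)
    stop(sprintf("run %s: tr must be positive", id))
  if (!(run$session %in% c(1L, 2L)))
    stop(sprintf("run %s: session must be 1 or 2", id))
  invisible(run)
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %s: T=%d, G=%d, tr=%.3g s\n", run_id(x),
              nrow(x$bold), ncol(x$bold), x$tr))
  invisible(x)
}

#' Build a cohort design table from a run list
#'
#' @param runs named list of `bold_run` objects (names are run ids).
#' @param excluded optional data.frame (subject, reason) of excluded subjects.
#' @return a `cohort_design`: data.frame with subject, condition, session,
#'   run_id, plus an `excluded` attribute.
#' @export
cohort_design <- function(runs, excluded = NULL) {
  stopifnot(length(runs) >= 1L)
  tab <- do.call(rbind, lapply(runs, function(r)
    data.frame(subject = r$subject, condition = r$condition,
               session = r$session, run_id = run_id(r),
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  if (is.null(excluded))
    excluded <- data.frame(subject = character(), reason = character(),
                           stringsAsFactors = FALSE)
  # full-crossing invariant: 3 conditions x 2 sessions per included subject
  for (s in unique(tab$subject)) {
    cell <- tab[tab$subject == s, ]
    if (nrow(cell) != 6L ||
        !all(table(cell$condition, cell$session) == 1L))
      stop(sprintf(
        "subject %s: design requires the full 3 condition x 2 session crossing",
        s))
  }
  structure(tab, excluded = excluded, class = c("cohort_design",
                                                "data.frame"))
}

#' Assemble a cohort container
#'
#' @param space a `gray_space`.
#' @param runs named list of `bold_run` objects.
#' @param design a `cohort_design` (built from `runs` when omitted).
#' @param truth optional ground-truth list (from the synthetic generator).
#' @return an object of class `cohort`.
#' @export
cohort <- function(space, runs, design = NULL, truth = NULL) {
  validate_space(space)
  if (is.null(names(runs)) || any(names(runs) == ""))
    names(runs) <- vapply(runs, run_id, character(1))
  if (is.null(design)) design <- cohort_design(runs)
  obj <- structure(list(space = space, design = design, runs = runs,
                        truth = truth), class = "cohort")
  validate_cohort(obj)
  obj
}

#' Validate a cohort container
#'
#' Checks each run against the space (grayordinate count, frame counts) and
#' the design against the run list.  Failures name the run and field.
#'
#' @param x a `cohort`.
#' @return the cohort, invisibly.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  validate_space(x$space)
  for (nm in names(x$runs)) {
    r <- x$runs[[nm]]
    validate_run(r)
    if (ncol(r$bold) != x$space$n_gray)
      stop(sprintf("run %s: bold has %d grayordinates, space has %d",
                   nm, ncol(r$bold), x$space$n_gray))
  }
  if (!all(x$design$run_id %in% names(x$runs)))
    stop("design references runs missing from the container")
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d runs, %d subjects, G=%d\n", length(x$runs),
              length(unique(x$design$subject)), x$space$n_gray))
  invisible(x)
}

#' Save / load the native cohort container
#'
#' The native container is a single serialized file holding the logical
#' groups space, design, runs and (optionally) ground truth.  Round trips
#' are bit-identical.
#'
#' @param x a `cohort`.
#' @param path file path.
#' @return `save_cohort` returns `path` invisibly; `load_cohort` returns a
#'   validated `cohort`.
#' @export
save_cohort <- function(x, path) {
  validate_cohort(x)
  saveRDS(unclass_cohort(x), path)
  invisible(path)
}

unclass_cohort <- function(x) {
  list(format = "pharmaconn-cohort", version = 1L,
       space = x$space, design = x$design, runs = x$runs, truth = x$truth)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("container file not found: ", path)
  raw <- readRDS(path)
  if (!identical(raw$format, "pharmaconn-cohort") || is.null(raw$space))
    stop("format error: not a cohort container (missing space block)")
  if (length(raw$runs) < 1L) stop("format error: container holds no runs")
  obj <- structure(list(space = raw$space, design = raw$design,
                        runs = raw$runs, truth = raw$truth),
                   class = "cohort")
  validate_cohort(obj)
  obj
}

#' Save a scalar map
#'
#' A scalar map is one value per grayordinate (GBC-Fz, GS-beta, variance, Z,
#' ...).  TSV files carry a 0-based grayordinate index column and preserve
#' full double precision; masked entries are written as `NaN`.
#'
#' @param values numeric vector (length G, or P for parcel-level maps).
#' @param path output path.
#' @param format `"tsv"`, `"container"` (serialized), or `"nifti-like"`
#'   (NIfTI-1 via the RNifti adapter; values stored along the first axis).
#' @return `path`, invisibly.
#' @export
save_map <- function(values, path, format = c("tsv", "container",
                                              "nifti-like")) {
  format <- match.arg(format)
  values <- as.numeric(values)
  if (format == "tsv") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines("index\tvalue", con)
    writeLines(sprintf("%d\t%s", seq_along(values) - 1L,
                       format_full(values)), con)
  } else if (format == "container") {
    saveRDS(list(format = "pharmaconn-map", values = values), path)
  } else {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("the nifti-like format requires the RNifti package")
    img <- array(values, dim = c(length(values), 1L, 1L))
    RNifti::writeNifti(RNifti::asNifti(img, datatype = "double"), path)
  }
  invisible(path)
}

# full-precision text rendering that survives a strtod round trip
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.nan(x)] <- "NaN"
  out
}

#' @rdname save_map
#' @param reorder_check error if the TSV index column is not 0..G-1 in order
#'   (loading never silently reorders grayordinates).
#' @export
load_map <- function(path, format = c("tsv", "container", "nifti-like"),
                     reorder_check = TRUE) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- read.delim(path, colClasses = c("integer", "numeric"))
    if (reorder_check && !identical(tab$index, seq_len(nrow(tab)) - 1L))
      stop("map index column must be 0..G-1 in order")
    tab$value
  } else if (format == "container") {
    raw <- readRDS(path)
    if (!identical(raw$format, "pharmaconn-map"))
      stop("format error: not a map container")
    raw$values
  } else {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("the nifti-like format requires the RNifti package")
    as.numeric(RNifti::readNifti(path))
  }
}

#' Export a space definition as TSV
#'
#' Writes two files: `<stem>_labels.tsv` (index, structure, network, parcel)
#' and `<stem>_edges.tsv` (0-based endpoint pairs).
#'
#' @param space a `gray_space`.
#' @param stem output path stem.
#' @return character vector of the two paths, invisibly.
#' @export
save_space_tsv <- function(space, stem) {
  lab_path <- paste0(stem, "_labels.tsv")
  edge_path <- paste0(stem, "_edges.tsv")
  lab <- data.frame(index = seq_len(space$n_gray) - 1L,
                    structure = as.character(space$structure),
                    network = as.character(space$network),
                    parcel = ifelse(is.na(space$parcel), -1L, space$parcel))
  write.table(lab, lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  edg <- data.frame(a = space$edges[, 1] - 1L, b = space$edges[, 2] - 1L)
  write.table(edg, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(lab_path, edge_path))
}
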