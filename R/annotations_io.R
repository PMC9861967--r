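#' Write fiducial annotations to CSV or JSON
#'
#' Long format: columns `beat`, `point` (one of `b`, `c`, `x`) and
#' `sample_index` (1-based, matching R indexing throughout the
#' package); absent points are simply omitted. The JSON form carries
#' the same records plus the sampling rate.
#'
#' @param fiducials An [icg_fiducials()] set.
#' @param path Output path; a `.json` extension selects JSON, anything
#'   else CSV.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(fiducials, path) {
  stopifnot(inherits(fiducials, "icg_fiducials"))
  long <- do.call(rbind, lapply(c("b", "c", "x"), function(p) {
    keep <- !is.na(fiducials[[p]])
    if (!any(keep)) return(NULL)
    data.frame(beat = fiducials$beat[keep], point = p,
               sample_index = fiducials[[p]][keep])
  }))
  long <- long[order(long$beat, match(long$point, c("b", "c", "x"))), ]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(fs = attr(fiducials, "fs"),
                              annotations = long),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(long, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read fiducial annotations from CSV or JSON
#'
#' @param path File written by [write_annotations()] (or any file with
#'   `beat`, `point`, `sample_index` columns).
#' @param fs Sampling rate in Hz; required for CSV, taken from the file
#'   for JSON when present.
#' @return An [icg_fiducials()] set.
#' @export
read_annotations <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    long <- as.data.frame(j$annotations)
    if (is.null(fs)) fs <- j$fs
  } else {
    long <- utils::read.csv(path)
  }
  if (is.null(fs)) stop("fs must be supplied for CSV annotations")
  need <- c("beat", "point", "sample_index")
  if (!all(need %in% names(long)))
    stop("annotation file must have columns ", paste(need, collapse = ", "))
  beats <- sort(unique(long$beat))
  pick <- function(p) {
    v <- rep(NA_integer_, length(beats))
    sel <- long$point == p
    v[match(long$beat[sel], beats)] <- as.integer(long$sample_index[sel])
    v
  }
  icg_fiducials(pick("b"), pick("c"), pick("x"), fs)
}
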