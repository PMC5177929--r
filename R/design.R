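#' Treatments and sampling times of the stress time-course design
#'
#' Four treatments (control, heat, continuous light, UV), three biological
#' replicates and six sampling time points in days after treatment (DAT).
#' @name design-constants
NULL

#' @rdname design-constants
#' @export
TREATMENTS <- c("control", "heat", "light", "uv")

#' @rdname design-constants
#' @export
TIME_POINTS <- c(0L, 1L, 2L, 3L, 7L, 10L)

#' Build the full 72-library design sheet
#'
#' One library per (treatment, replicate, time point) combination:
#' 4 treatments x 3 replicates x 6 time points = 72 libraries.
#'
#' @param treatments character vector of treatment levels.
#' @param replicates integer vector of replicate ids.
#' @param time_dat integer vector of sampling times (days after treatment).
#' @return data.frame with columns `library_id`, `treatment`, `replicate`,
#'   `time_dat`; `library_id` is unique and encodes the condition.
#' @examples
#' d <- full_design()
#' nrow(d)  # 72
#' @export
full_design <- function(treatments = TREATMENTS, replicates = 1:3,
                        time_dat = TIME_POINTS) {
  d <- expand.grid(replicate = as.integer(replicates),
                   time_dat = as.integer(time_dat),
                   treatment = treatments,
                   stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  d <- d[, c("treatment", "replicate", "time_dat")]
  d <- d[order(match(d$treatment, treatments), d$time_dat, d$replicate), ]
  d$library_id <- sprintf("%s_t%02d_r%d", d$treatment, d$time_dat, d$replicate)
  rownames(d) <- NULL
  stopifnot(!anyDuplicated(d$library_id))
  d[, c("library_id", "treatment", "replicate", "time_dat")]
}

#' Write / read a design sheet TSV
#'
#' The sheet has the header `library_id treatment replicate time_dat`.
#'
#' @param design data.frame as returned by [full_design()].
#' @param path TSV file path.
#' @return `read_design` returns the design data.frame; `write_design`
#'   returns `path` invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("library_id", "treatment", "replicate", "time_dat")
  if (!all(need %in% names(d))) {
    stop("design sheet must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(d$library_id)) stop("duplicate library_id in design", call. = FALSE)
  d$replicate <- as.integer(d$replicate)
  d$time_dat <- as.integer(d$time_dat)
  d[, need]
}
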