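## End-to-end convenience wrappers: run the preprocessing + annotation
## chain on a simulated experiment directory and score recovery of the
## planted truth.

#' Preprocess and annotate a simulated experiment directory
#'
#' Runs [preprocess_fastq()] and [classify_mirna()] on the files
#' written by [simulate_experiment()].
#'
#' @param simdir directory written by [simulate_experiment()], or the
#'   list it returns.
#' @param min_rpm expression filter (RPM).
#' @param ... passed to [classify_mirna()].
#' @return list with `preprocess` (preprocess_result) and `annotation`
#'   (mirna_annotation).
#' @export
run_pipeline <- function(simdir, min_rpm = 10, ...) {
  if (is.list(simdir)) {
    paths <- simdir$paths
    fastq <- simdir$fastq
    design <- simdir$design
  } else {
    design <- read_design(file.path(simdir, "design.tsv"))
    fastq <- stats::setNames(file.path(simdir, "fastq",
                                       paste0(design$library_id, ".fastq")),
                             design$library_id)
    paths <- list(precursors = file.path(simdir, "ref", "precursors.fa"),
                  decoys = file.path(simdir, "ref", "decoys.fa"),
                  matures = file.path(simdir, "ref", "known_matures.fa"))
  }
  pp <- preprocess_fastq(fastq, design, decoys = paths$decoys,
                         min_rpm = min_rpm)
  ann <- classify_mirna(pp$tags, paths$precursors, catalog = paths$matures, ...)
  list(preprocess = pp, annotation = ann)
}

#' Score recovery of the planted truth by the annotation chain
#'
#' @param annotation a `mirna_annotation` object.
#' @param truth a `sim_truth` object.
#' @param tags the distinct_tags object that entered classification.
#' @return list with counts: `n_planted`, `n_accepted`,
#'   `planted_accepted` (planted matures accepted),
#'   `planted_star_supported`, `false_accepts` (accepted tags that are
#'   not planted matures), and the rejection reason table of decoy and
#'   siRNA tags.
#' @export
evaluate_recovery <- function(annotation, truth, tags) {
  acc <- annotation$annotations
  planted <- truth$matures$sequence
  planted_seen <- planted[planted %in% tags$sequence]
  accepted_seqs <- acc$sequence
  list(n_planted = length(planted),
       n_planted_seen = length(planted_seen),
       n_accepted = nrow(acc),
       planted_accepted = sum(planted_seen %in% accepted_seqs),
       planted_star_supported = sum(acc$star_supported &
                                    acc$sequence %in% planted_seen),
       false_accepts = sum(!(accepted_seqs %in% planted)),
       rejection_reasons = table(annotation$rejections$reason))
}
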