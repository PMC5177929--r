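## Synthetic experiment generator: plants hairpin-borne miRNAs,
## ncRNA/chloroplast contaminants and 24-nt siRNA-like background into a
## 72-library treatment x replicate x time design, with recorded truth.

#' The 3' sequencing adapter used for read layout
#'
#' Adenylated 3' adapter ligated to the small RNA insert; reads are
#' insert + adapter, padded to the sequencer cycle count.
#' @export
ADAPTER3 <- "ATCTCGTATGCCGTCTTCTGCTTGT"

## plant miRNA family names used to label planted matures
SIM_FAMILIES <- c("miR156", "miR159", "miR160", "miR164", "miR166", "miR167",
                  "miR169", "miR171", "miR172", "miR393", "miR396", "miR398",
                  "miR399", "miR408", "miR528", "miR827", "miR1122", "miR1130",
                  "miR1439", "miR5205")

## mature length distribution: conserved plant miRNAs are dominated by
## 21-mers, with a 24-nt shoulder
SIM_LEN_PROBS <- c(`18` = 0.02, `19` = 0.03, `20` = 0.13, `21` = 0.55,
                   `22` = 0.12, `23` = 0.05, `24` = 0.10)

#' Default planted stress-effect table
#'
#' Emulates a heat-dominated response: a fraction of planted miRNAs is
#' perturbed by heat at the early recovery time points (mostly down at
#' 0-1 days after treatment), while light and UV each perturb a single
#' miRNA.
#'
#' @param mature_seqs character vector of planted mature sequences (DNA).
#' @param frac_heat fraction of matures affected by heat.
#' @param frac_down fraction of the heat-affected set that is
#'   downregulated (the rest is upregulated).
#' @param log2fc effect magnitude (log2 fold change) at 0 and 1 DAT.
#' @return data.frame with columns `sequence`, `treatment`, `time_dat`,
#'   `log2fc`.
#' @export
default_effect_table <- function(mature_seqs, frac_heat = 0.34,
                                 frac_down = 0.55, log2fc = 2) {
  n <- length(mature_seqs)
  n_heat <- max(0L, round(frac_heat * n))
  eff <- list()
  if (n_heat > 0) {
    affected <- mature_seqs[seq_len(n_heat)]
    n_down <- round(frac_down * n_heat)
    sign <- rep(c(-1, 1), c(n_down, n_heat - n_down))
    for (t in c(0L, 1L)) {
      eff[[length(eff) + 1L]] <- data.frame(sequence = affected, treatment = "heat",
                                            time_dat = t, log2fc = sign * log2fc)
    }
  }
  if (n >= n_heat + 1L) {
    eff[[length(eff) + 1L]] <- data.frame(sequence = mature_seqs[n_heat + 1L],
                                          treatment = "light", time_dat = 0L,
                                          log2fc = -log2fc)
  }
  if (n >= n_heat + 2L) {
    eff[[length(eff) + 1L]] <- data.frame(sequence = mature_seqs[n_heat + 2L],
                                          treatment = "uv", time_dat = 0L,
                                          log2fc = -log2fc)
  }
  if (length(eff) == 0L) {
    return(data.frame(sequence = character(0), treatment = character(0),
                      time_dat = integer(0), log2fc = numeric(0)))
  }
  do.call(rbind, eff)
}

#' Generate the planted ground truth for a synthetic experiment
#'
#' Draws mature miRNA sequences, builds hairpin precursors around them,
#' assigns family names, baseline expression and planted stress effects.
#'
#' @param n_mirnas number of planted miRNA precursors.
#' @param seed RNG seed recorded in the truth object.
#' @param dispersion negative-binomial dispersion of the count model.
#' @param effects effect table (see [default_effect_table()]) or `NULL`
#'   for the default heat-dominated pattern.
#' @param n_bulges bulges per hairpin star arm (0 = perfect duplexes).
#' @param star_fraction star baseline expression as a fraction of the
#'   mature baseline.
#' @return list of class `sim_truth`: `precursors` (data.frame
#'   locus_id, sequence, mature/star intervals), `matures` (data.frame
#'   sequence, family, locus_id, baseline), `stars`, `effects`,
#'   `dispersion`, `seed`.
#' @export
sim_truth <- function(n_mirnas = 50, seed = 1, dispersion = 0.1,
                      effects = NULL, n_bulges = 0L, star_fraction = 0.06) {
  stopifnot(dispersion > 0)
  with_seed(seed, {
    lens <- as.integer(sample(names(SIM_LEN_PROBS), n_mirnas, replace = TRUE,
                              prob = SIM_LEN_PROBS))
    matures <- character(0)
    while (length(matures) < n_mirnas) {
      need <- n_mirnas - length(matures)
      matures <- unique(c(matures, random_seq(need, lens[seq_len(need)], DNA_BASES)))
    }
    matures <- matures[seq_len(n_mirnas)]
    loop_lens <- sample(8:24, n_mirnas, replace = TRUE)
    hp <- lapply(seq_len(n_mirnas), function(i) {
      build_hairpin(matures[i], loop_len = loop_lens[i], n_bulges = n_bulges)
    })
    locus_ids <- sprintf("locus_%03d", seq_len(n_mirnas))
    precursors <- data.frame(
      locus_id = locus_ids,
      sequence = vapply(hp, `[[`, character(1), "precursor"),
      mature_start = vapply(hp, function(h) h$mature_interval[1], integer(1)),
      mature_end = vapply(hp, function(h) h$mature_interval[2], integer(1)),
      star_start = vapply(hp, function(h) h$star_interval[1], integer(1)),
      star_end = vapply(hp, function(h) h$star_interval[2], integer(1)),
      n_bulges = vapply(hp, `[[`, integer(1), "n_bulges"))
    fam <- rep_len(SIM_FAMILIES, n_mirnas)
    base_mature <- pmax(20, pmin(5000, round(stats::rlnorm(n_mirnas, log(80), 1))))
    matures_df <- data.frame(sequence = matures, family = fam,
                             locus_id = locus_ids, baseline = base_mature)
    stars_df <- data.frame(sequence = vapply(hp, `[[`, character(1), "star_seq"),
                           locus_id = locus_ids,
                           baseline = pmax(2, round(base_mature * star_fraction)))
    if (is.null(effects)) effects <- default_effect_table(matures)
    structure(list(precursors = precursors, matures = matures_df,
                   stars = stars_df, effects = effects,
                   dispersion = dispersion, seed = as.integer(seed)),
              class = "sim_truth")
  })
}

## expand an effect table into a per-tag x per-library log2 fold matrix
effect_matrix <- function(sequences, design, effects) {
  e <- matrix(0, length(sequences), nrow(design),
              dimnames = list(sequences, design$library_id))
  if (nrow(effects) == 0) return(e)
  for (k in seq_len(nrow(effects))) {
    libs <- design$library_id[design$treatment == effects$treatment[k] &
                              design$time_dat == effects$time_dat[k]]
    if (effects$sequence[k] %in% sequences && length(libs)) {
      e[effects$sequence[k], libs] <- e[effects$sequence[k], libs] + effects$log2fc[k]
    }
  }
  e
}

#' Simulate negative-binomial counts for a planted experiment
#'
#' Counts are drawn NB(mean = baseline x 2^effect x size factor,
#' dispersion) per tag and library; identical seeds give identical
#' matrices.
#'
#' @param design design sheet (see [full_design()]).
#' @param baselines named numeric vector: per-tag baseline mean counts
#'   (names are tag sequences); all must be > 0.
#' @param effects effect table with columns `sequence`, `treatment`,
#'   `time_dat`, `log2fc`.
#' @param dispersion NB dispersion (> 0); small values approach Poisson.
#' @param size_factors per-library relative depth multipliers (default
#'   1: libraries pooled at the same target depth).
#' @param seed RNG seed.
#' @return integer matrix, tags (rows, named by sequence) x libraries.
#' @export
simulate_counts <- function(design, baselines, effects = NULL, dispersion = 0.1,
                            size_factors = NULL, seed = 1) {
  if (any(baselines <= 0)) stop("baseline means must be > 0", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (is.null(size_factors)) size_factors <- rep(1, nrow(design))
  if (any(size_factors <= 0)) stop("size factors must be > 0", call. = FALSE)
  if (is.null(effects)) {
    effects <- data.frame(sequence = character(0), treatment = character(0),
                          time_dat = integer(0), log2fc = numeric(0))
  }
  seqs <- names(baselines)
  e <- effect_matrix(seqs, design, effects)
  mu <- (baselines %o% size_factors) * 2^e
  dimnames(mu) <- list(seqs, design$library_id)
  with_seed(seed, {
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    storage.mode(counts) <- "integer"
    counts
  })
}

#' @rdname simulate_counts
#' @param truth a `sim_truth` object; convenience wrapper drawing counts
#'   for all planted matures and stars with the truth's effects,
#'   dispersion and seed.
#' @export
simulate_truth_counts <- function(design, truth, size_factors = NULL) {
  baselines <- c(stats::setNames(truth$matures$baseline, truth$matures$sequence),
                 stats::setNames(truth$stars$baseline, truth$stars$sequence))
  ## a star identical to some mature (possible in principle) collapses
  baselines <- baselines[!duplicated(names(baselines))]
  simulate_counts(design, baselines, truth$effects, truth$dispersion,
                  size_factors, seed = truth$seed)
}

#' Emit per-library FASTQ files from a count matrix
#'
#' Each read is insert + 3' adapter, padded with `pad_base` (run-off
#' cycles) or truncated to `cycles` (default 50) bases; base qualities
#' are constant Phred `qual` with an optional uniform substitution error
#' rate.  Read counts per tag per library equal the count matrix; read
#' order within a library is a seeded permutation, so output is
#' byte-identical given (counts, seed).
#'
#' @param counts integer matrix, tag sequences (rows) x library ids
#'   (columns).
#' @param outdir output directory (created if needed).
#' @param adapter3 3' adapter (DNA).
#' @param cycles read length in sequencing cycles.
#' @param qual constant Phred quality score.
#' @param error_rate per-base uniform substitution probability.
#' @param pad_base base used for cycles beyond the adapter.
#' @param seed RNG seed for read shuffling (and errors, if any).
#' @return named character vector of FASTQ paths, one per library.
#' @export
emit_fastq <- function(counts, outdir, adapter3 = ADAPTER3, cycles = 50L,
                       qual = 40L, error_rate = 0, pad_base = "A", seed = 1) {
  stopifnot_seq(rownames(counts), DNA_BASES, "tag inserts")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  adapter3 <- as_dna(adapter3)
  qchar <- rawToChar(as.raw(qual + 33L))
  paths <- character(0)
  tags <- rownames(counts)
  full <- substr(paste0(tags, adapter3, strrep(pad_base, cycles)), 1L, cycles)
  for (li in seq_len(ncol(counts))) {
    lib <- colnames(counts)[li]
    cnt <- counts[, li]
    reads <- rep(full, cnt)
    with_seed(seed + 7L * li, {
      if (length(reads) > 1L) reads <- sample(reads)
      if (error_rate > 0 && length(reads)) {
        n_err <- stats::rbinom(1, length(reads) * cycles, error_rate)
        if (n_err > 0) {
          pos <- sample(length(reads) * cycles, n_err)
          ri <- (pos - 1L) %/% cycles + 1L
          ci <- (pos - 1L) %% cycles + 1L
          for (k in seq_len(n_err)) {
            old <- substr(reads[ri[k]], ci[k], ci[k])
            substr(reads[ri[k]], ci[k], ci[k]) <- sample(setdiff(DNA_BASES, old), 1)
          }
        }
      }
    })
    x <- Biostrings::DNAStringSet(reads)
    if (length(x)) names(x) <- sprintf("%s:%06d", lib, seq_along(x))
    path <- file.path(outdir, paste0(lib, ".fastq"))
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(
                                  rep(strrep(qchar, cycles), length(x))))
    paths[lib] <- path
  }
  paths
}

#' Emit decoy references and contaminant / background tag sequences
#'
#' Generates ncRNA-like (rRNA/tRNA/snRNA/snoRNA) and chloroplast decoy
#' reference sequences, contaminant tags that are exact substrings of
#' those references, and precursor-less 24-nt siRNA-like tags.  All
#' decoy and siRNA tags are checked not to occur in `avoid` sequences
#' (e.g. planted precursors) or collide with each other.
#'
#' @param n_rfam number of ncRNA decoy references.
#' @param n_chloro number of chloroplast decoy references.
#' @param n_decoy_tags number of contaminant tags drawn from the decoy
#'   references (18-24 nt substrings).
#' @param n_sirna24 number of siRNA-like 24-mers with no precursor.
#' @param avoid character vector of sequences decoy tags must not occur in.
#' @param seed RNG seed.
#' @return list with `refs` (named DNA vector: decoy references),
#'   `decoy_tags`, `sirna_tags` (character vectors).
#' @export
emit_decoys <- function(n_rfam = 10, n_chloro = 3, n_decoy_tags = 200,
                        n_sirna24 = 300, avoid = character(0), seed = 1) {
  stopifnot(n_rfam >= 0, n_chloro >= 0, n_decoy_tags >= 0, n_sirna24 >= 0)
  with_seed(seed, {
    classes <- rep_len(c("rRNA", "tRNA", "snRNA", "snoRNA", "lncRNA"),
                       max(n_rfam, 1L))[seq_len(n_rfam)]
    refs <- character(0)
    if (n_rfam > 0) {
      r <- random_seq(n_rfam, sample(200:1200, n_rfam, replace = TRUE))
      names(r) <- sprintf("rfam_%s_%03d", classes, seq_len(n_rfam))
      refs <- c(refs, r)
    }
    if (n_chloro > 0) {
      r <- random_seq(n_chloro, sample(500:2000, n_chloro, replace = TRUE))
      names(r) <- sprintf("chloroplast_%03d", seq_len(n_chloro))
      refs <- c(refs, r)
    }
    avoid_all <- paste(c(avoid, "#"), collapse = "#")
    draw_decoy_tag <- function() {
      ref <- refs[[sample(length(refs), 1)]]
      len <- sample(18:24, 1)
      start <- sample(nchar(ref) - len + 1L, 1)
      substr(ref, start, start + len - 1L)
    }
    decoy_tags <- character(0)
    if (n_decoy_tags > 0) {
      if (length(refs) == 0) stop("decoy tags requested but no decoy references")
      while (length(decoy_tags) < n_decoy_tags) {
        cand <- unique(replicate(n_decoy_tags - length(decoy_tags), draw_decoy_tag()))
        cand <- cand[!stringi::stri_detect_fixed(avoid_all, cand)]
        decoy_tags <- unique(c(decoy_tags, cand))
      }
      decoy_tags <- decoy_tags[seq_len(n_decoy_tags)]
    }
    refs_both <- paste(c(refs, revcomp(refs), avoid, "#"), collapse = "#")
    sirna_tags <- character(0)
    while (length(sirna_tags) < n_sirna24) {
      cand <- unique(random_seq(n_sirna24 - length(sirna_tags), 24L))
      cand <- cand[!stringi::stri_detect_fixed(refs_both, cand)]
      sirna_tags <- unique(c(sirna_tags, cand))
    }
    list(refs = refs, decoy_tags = decoy_tags, sirna_tags = sirna_tags)
  })
}

#' Simulate a complete synthetic small RNA experiment on disk
#'
#' Orchestrates [sim_truth()], [emit_decoys()], [simulate_counts()] and
#' [emit_fastq()]: writes per-library FASTQ files, reference FASTAs
#' (precursors, decoys, known matures), the design sheet and
#' ground-truth TSV sidecars.
#'
#' @param outdir output directory.
#' @param n_mirnas,n_decoy_tags,n_sirna24 planted feature counts.
#' @param design design sheet (defaults to the full 72-library design).
#' @param dispersion NB dispersion of the count model.
#' @param effects planted effect table or `NULL` for the default.
#' @param size_factors per-library depth multipliers (default equal).
#' @param decoy_baseline mean baseline count of contaminant/siRNA tags.
#' @param n_bulges bulges per star arm.
#' @param seed master seed.
#' @return list (invisible): `truth`, `design`, `counts` (full planted
#'   count matrix incl. contaminants), `fastq` (paths), `paths` (named
#'   list of reference/sheet paths), `decoys`.
#' @export
simulate_experiment <- function(outdir, n_mirnas = 50, n_decoy_tags = 200,
                                n_sirna24 = 300, design = full_design(),
                                dispersion = 0.1, effects = NULL,
                                size_factors = NULL, decoy_baseline = 25,
                                n_bulges = 0L, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- sim_truth(n_mirnas = n_mirnas, seed = seed, dispersion = dispersion,
                     effects = effects, n_bulges = n_bulges)
  decoys <- emit_decoys(n_decoy_tags = n_decoy_tags, n_sirna24 = n_sirna24,
                        avoid = c(truth$precursors$sequence), seed = seed + 1L)

  base_planted <- c(stats::setNames(truth$matures$baseline, truth$matures$sequence),
                    stats::setNames(truth$stars$baseline, truth$stars$sequence))
  bg <- c(decoys$decoy_tags, decoys$sirna_tags)
  base_bg <- with_seed(seed + 2L, {
    stats::setNames(pmax(5, round(stats::rlnorm(length(bg), log(decoy_baseline), 0.8))), bg)
  })
  baselines <- c(base_planted, base_bg)
  baselines <- baselines[!duplicated(names(baselines))]
  counts <- simulate_counts(design, baselines, truth$effects, dispersion,
                            size_factors, seed = truth$seed)

  fastq <- emit_fastq(counts, file.path(outdir, "fastq"), seed = seed + 3L)

  paths <- list(
    precursors = file.path(outdir, "ref", "precursors.fa"),
    decoys = file.path(outdir, "ref", "decoys.fa"),
    matures = file.path(outdir, "ref", "known_matures.fa"),
    design = file.path(outdir, "design.tsv"),
    truth_precursors = file.path(outdir, "truth", "precursors.tsv"),
    truth_tags = file.path(outdir, "truth", "tags.tsv"),
    truth_effects = file.path(outdir, "truth", "effects.tsv"))
  dir.create(file.path(outdir, "ref"), showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  write_fasta_seqs(stats::setNames(truth$precursors$sequence,
                                   truth$precursors$locus_id), paths$precursors)
  write_fasta_seqs(decoys$refs, paths$decoys)
  mature_names <- sprintf("tae-%s%s", truth$matures$family,
                          letters[stats::ave(seq_len(n_mirnas),
                                             truth$matures$family,
                                             FUN = seq_along)])
  write_fasta_seqs(stats::setNames(truth$matures$sequence, mature_names),
                   paths$matures)
  write_design(design, paths$design)
  utils::write.table(truth$precursors, paths$truth_precursors, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tag_truth <- rbind(
    data.frame(sequence = truth$matures$sequence, kind = "mature",
               locus_id = truth$matures$locus_id, baseline = truth$matures$baseline),
    data.frame(sequence = truth$stars$sequence, kind = "star",
               locus_id = truth$stars$locus_id, baseline = truth$stars$baseline),
    data.frame(sequence = decoys$decoy_tags, kind = "decoy", locus_id = NA,
               baseline = unname(base_bg[decoys$decoy_tags])),
    data.frame(sequence = decoys$sirna_tags, kind = "sirna24", locus_id = NA,
               baseline = unname(base_bg[decoys$sirna_tags])))
  utils::write.table(tag_truth, paths$truth_tags, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$effects, paths$truth_effects, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(truth = truth, design = design, counts = counts,
                 fastq = fastq, paths = paths, decoys = decoys,
                 tag_truth = tag_truth))
}
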