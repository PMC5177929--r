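## Preprocessing: FASTQ -> cross-library table of consistently named
## distinct 18-24 nt tags with counts and RPM.

#' Trim the 3' adapter from reads
#'
#' Returns, for each read, the prefix before the leftmost exact match of
#' an adapter prefix of length >= `min_overlap` that extends to the end
#' of the read (or covers the whole adapter).  Reads with no such match
#' are returned whole and flagged untrimmed.
#'
#' @param reads character vector of reads (DNA).
#' @param adapter3 3' adapter sequence.
#' @param min_overlap minimum adapter prefix length to accept (>= 5).
#' @return list with `insert` (character) and `trimmed` (logical).
#' @export
trim_adapter <- function(reads, adapter3 = ADAPTER3, min_overlap = 5L) {
  if (min_overlap < 5L) stop("min_overlap must be >= 5", call. = FALSE)
  adapter3 <- as_dna(adapter3)
  la <- nchar(adapter3)
  if (min_overlap > la) stop("min_overlap exceeds adapter length", call. = FALSE)
  reads <- as_dna(reads)
  n <- length(reads)
  rl <- stringi::stri_length(reads)
  seedp <- substr(adapter3, 1L, min_overlap)

  valid_at <- function(idx, pos) {
    ## adapter prefix starting at pos must run to the read end (or cover
    ## the full adapter)
    len <- pmin(rl[idx] - pos + 1L, la)
    stringi::stri_sub(reads[idx], pos, pos + len - 1L) == substr(adapter3, 1L, len)
  }

  insert <- reads
  trimmed <- rep(FALSE, n)
  first <- stringi::stri_locate_first_fixed(reads, seedp)[, 1]
  cand <- which(!is.na(first))
  if (length(cand)) {
    ok <- valid_at(cand, first[cand])
    hit <- cand[ok]
    insert[hit] <- stringi::stri_sub(reads[hit], 1L, first[hit] - 1L)
    trimmed[hit] <- TRUE
    ## rare: seed occurs but continuation mismatches; scan later occurrences
    retry <- cand[!ok]
    if (length(retry)) {
      locs <- stringi::stri_locate_all_fixed(reads[retry], seedp, overlap = TRUE)
      for (k in seq_along(retry)) {
        i <- retry[k]
        for (p in locs[[k]][, 1]) {
          if (isTRUE(valid_at(i, p))) {
            insert[i] <- substr(reads[i], 1L, p - 1L)
            trimmed[i] <- TRUE
            break
          }
        }
      }
    }
  }
  list(insert = insert, trimmed = trimmed)
}

#' Select inserts in the small RNA size range
#'
#' @param inserts character vector.
#' @param min_len,max_len inclusive length bounds (18-24 nt).
#' @return the inserts with `min_len <= length <= max_len`, order preserved.
#' @export
size_select <- function(inserts, min_len = 18L, max_len = 24L) {
  len <- stringi::stri_length(inserts)
  inserts[len >= min_len & len <= max_len]
}

#' Collapse size-selected inserts into consistently named distinct tags
#'
#' One tag per unique sequence across all libraries; `tag_id`s are
#' assigned after sorting the pooled sequence set, so they depend only
#' on the set of sequences, not on read order or library order.
#'
#' @param inserts_by_library named list (library_id -> character vector
#'   of size-selected inserts).
#' @param design design sheet; defines the library column order.
#' @return object of class `distinct_tags`: list with `tag_id`,
#'   `sequence`, `counts` (integer matrix tags x libraries), and `rpm`
#'   (NULL until [compute_rpm()]).
#' @export
collapse_and_name <- function(inserts_by_library, design) {
  libs <- design$library_id
  missing <- setdiff(libs, names(inserts_by_library))
  if (length(missing)) {
    inserts_by_library[missing] <- list(character(0))
  }
  seqs <- sort(unique(unlist(inserts_by_library[libs], use.names = FALSE)))
  counts <- matrix(0L, length(seqs), length(libs),
                   dimnames = list(NULL, libs))
  for (lib in libs) {
    x <- inserts_by_library[[lib]]
    if (length(x)) {
      t <- table(factor(x, levels = seqs))
      counts[, lib] <- as.integer(t)
    }
  }
  structure(list(tag_id = sprintf("tag_%06d", seq_along(seqs)),
                 sequence = seqs,
                 counts = counts,
                 rpm = NULL,
                 retained_reads = NULL),
            class = "distinct_tags")
}

#' @export
print.distinct_tags <- function(x, ...) {
  cat(sprintf("distinct_tags: %d tags x %d libraries (%s RPM)\n",
              length(x$sequence), ncol(x$counts),
              if (is.null(x$rpm)) "no" else "with"))
  invisible(x)
}

#' Subset a distinct_tags object by row
#' @param x distinct_tags object.
#' @param i row index (logical, integer or character tag_id).
#' @param ... ignored.
#' @export
`[.distinct_tags` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$tag_id)
  structure(list(tag_id = x$tag_id[i],
                 sequence = x$sequence[i],
                 counts = x$counts[i, , drop = FALSE],
                 rpm = if (is.null(x$rpm)) NULL else x$rpm[i, , drop = FALSE],
                 retained_reads = x$retained_reads),
            class = "distinct_tags")
}

#' Reads-per-million normalization
#'
#' `rpm[t, i] = counts[t, i] / retained_reads[i] * 1e6`.  The
#' denominator is the per-library total of retained (size-selected)
#' reads at collapse time, before contaminant removal.
#'
#' @param tags distinct_tags object.
#' @param retained_reads named integer vector of per-library retained
#'   read totals; defaults to the column sums of the count matrix.
#' @return the tags object with `rpm` filled.
#' @export
compute_rpm <- function(tags, retained_reads = colSums(tags$counts)) {
  retained_reads <- retained_reads[colnames(tags$counts)]
  bad <- retained_reads == 0 & colSums(tags$counts) > 0
  if (any(bad)) {
    stop("zero retained-read denominator with nonzero counts in: ",
         paste(colnames(tags$counts)[bad], collapse = ", "), call. = FALSE)
  }
  denom <- ifelse(retained_reads == 0, 1, retained_reads)
  tags$rpm <- sweep(tags$counts, 2, denom, "/") * 1e6
  tags$retained_reads <- retained_reads
  tags
}

#' Remove tags matching known ncRNA / chloroplast decoy references
#'
#' A tag is removed iff its sequence or its reverse complement is an
#' exact substring of any decoy reference (matching after U->T
#' canonicalization).
#'
#' @param tags distinct_tags object.
#' @param decoys either a named character vector of reference sequences
#'   or a character vector of FASTA file paths.
#' @return list with `retained` and `removed` distinct_tags objects.
#' @export
filter_known_ncRNA <- function(tags, decoys) {
  if (length(decoys) && all(file.exists(decoys))) {
    decoys <- unlist(lapply(decoys, read_fasta_seqs))
  }
  decoys <- as_dna(decoys)
  if (length(decoys) == 0) {
    keep <- rep(TRUE, length(tags$sequence))
  } else {
    haystack <- paste(c(decoys, revcomp(decoys)), collapse = "#")
    keep <- !stringi::stri_detect_fixed(haystack, tags$sequence)
  }
  list(retained = tags[keep], removed = tags[!keep])
}

#' Keep tags reaching a minimum RPM in at least one library
#'
#' @param tags distinct_tags with RPM computed.
#' @param threshold minimum reads-per-million (inclusive: a tag at
#'   exactly the threshold in one library is retained).
#' @return the retained distinct_tags.
#' @export
filter_min_rpm <- function(tags, threshold = 10) {
  if (is.null(tags$rpm)) stop("call compute_rpm() first", call. = FALSE)
  keep <- apply(tags$rpm, 1, max) >= threshold
  tags[keep]
}

#' Size distribution of reads and distinct tags
#'
#' Per treatment, counts of reads (weighted by multiplicity) and of
#' distinct tags (unweighted, present with count > 0) per size class.
#'
#' @param tags distinct_tags object.
#' @param design design sheet mapping libraries to treatments.
#' @param stage label recorded in the output (e.g. "collapsed",
#'   "post_decoy").
#' @param sizes size classes to tabulate.
#' @return data.frame with columns `stage`, `treatment`, `size`,
#'   `reads`, `tags`.
#' @export
size_distribution <- function(tags, design, stage = "collapsed", sizes = 18:24) {
  len <- nchar(tags$sequence)
  out <- list()
  for (trt in unique(design$treatment)) {
    libs <- design$library_id[design$treatment == trt]
    cnt <- tags$counts[, libs, drop = FALSE]
    tot <- rowSums(cnt)
    reads <- vapply(sizes, function(s) sum(tot[len == s]), numeric(1))
    ntags <- vapply(sizes, function(s) sum(len == s & tot > 0), numeric(1))
    out[[trt]] <- data.frame(stage = stage, treatment = trt, size = sizes,
                             reads = reads, tags = ntags)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## mean Phred+33 score per read; computed on unique quality strings
## (libraries with uniform qualities reduce to one evaluation)
mean_phred <- function(quality_strings) {
  uq <- unique(quality_strings)
  ms <- vapply(uq, function(s) mean(utf8ToInt(s)) - 33, numeric(1), USE.NAMES = FALSE)
  ms[match(quality_strings, uq)]
}

#' Run the full preprocessing pipeline on per-library FASTQ files
#'
#' Stages: adapter trimming, mean-quality gate, 18-24 nt size selection,
#' cross-library collapsing into named distinct tags, RPM normalization
#' (denominator: retained size-selected reads), decoy removal, and the
#' minimum-RPM expression filter.
#'
#' @param fastq_files named character vector (library_id -> FASTQ path).
#' @param design design sheet.
#' @param adapter3 3' adapter.
#' @param decoys decoy references (FASTA paths or named sequence vector).
#' @param min_rpm expression filter threshold (RPM).
#' @param min_overlap minimum adapter overlap for trimming.
#' @param min_mean_phred mean base-quality gate (set to 0 to disable).
#' @return list of class `preprocess_result`: `tags` (final filtered
#'   tags), `tags_collapsed` (all distinct tags with RPM, before decoy
#'   removal), `tags_post_decoy`, `removed_decoy`, `stats` (per-library
#'   data.frame raw/trimmed/quality_pass/retained/after_decoy reads),
#'   `size_dist` (size-distribution tables), `design`.
#' @export
preprocess_fastq <- function(fastq_files, design, adapter3 = ADAPTER3,
                             decoys = character(0), min_rpm = 10,
                             min_overlap = 5L, min_mean_phred = 20) {
  libs <- design$library_id
  if (!all(libs %in% names(fastq_files))) {
    stop("fastq_files must be named by library_id and cover the design",
         call. = FALSE)
  }
  inserts <- list()
  stats_rows <- list()
  for (lib in libs) {
    ## the reader warns about dropping per-read metadata columns; the
    ## pipeline only needs sequences and qualities
    fq <- suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(fastq_files[[lib]]))
    reads <- as.character(fq)
    raw_n <- length(reads)
    if (min_mean_phred > 0 && raw_n > 0) {
      mq <- mean_phred(as.character(Biostrings::quality(fq)))
      reads <- reads[mq >= min_mean_phred]
    }
    qual_n <- length(reads)
    tr <- trim_adapter(reads, adapter3, min_overlap)
    ins <- tr$insert[tr$trimmed]          # untrimmed reads carry no insert
    sel <- size_select(ins)
    inserts[[lib]] <- sel
    stats_rows[[lib]] <- data.frame(library_id = lib, raw_reads = raw_n,
                                    quality_pass = qual_n,
                                    trimmed_reads = sum(tr$trimmed),
                                    retained_reads = length(sel))
  }
  tags_all <- collapse_and_name(inserts, design)
  retained <- vapply(inserts, length, integer(1))[libs]
  tags_all <- compute_rpm(tags_all, retained)

  flt <- filter_known_ncRNA(tags_all, decoys)
  tags_final <- filter_min_rpm(flt$retained, min_rpm)

  stats <- do.call(rbind, stats_rows)
  stats$after_decoy <- colSums(flt$retained$counts)[stats$library_id]
  rownames(stats) <- NULL
  size_dist <- rbind(size_distribution(tags_all, design, "collapsed"),
                     size_distribution(flt$retained, design, "post_decoy"))
  structure(list(tags = tags_final,
                 tags_collapsed = tags_all,
                 tags_post_decoy = flt$retained,
                 removed_decoy = flt$removed,
                 stats = stats,
                 size_dist = size_dist,
                 design = design),
            class = "preprocess_result")
}

#' Write / read a distinct-tags table as TSV
#'
#' Columns: `tag_id`, `sequence`, `count_<library>`..., `rpm_<library>`...
#'
#' @param tags distinct_tags object.
#' @param path TSV path.
#' @return `read_tags` returns a distinct_tags object.
#' @export
write_tags <- function(tags, path) {
  df <- data.frame(tag_id = tags$tag_id, sequence = tags$sequence)
  cnt <- as.data.frame(tags$counts)
  names(cnt) <- paste0("count_", colnames(tags$counts))
  df <- cbind(df, cnt)
  if (!is.null(tags$rpm)) {
    rp <- as.data.frame(tags$rpm)
    names(rp) <- paste0("rpm_", colnames(tags$rpm))
    df <- cbind(df, rp)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tags
#' @export
read_tags <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  ccols <- grep("^count_", names(df), value = TRUE)
  rcols <- grep("^rpm_", names(df), value = TRUE)
  counts <- as.matrix(df[, ccols, drop = FALSE])
  colnames(counts) <- sub("^count_", "", ccols)
  storage.mode(counts) <- "integer"
  rpm <- NULL
  if (length(rcols)) {
    rpm <- as.matrix(df[, rcols, drop = FALSE])
    colnames(rpm) <- sub("^rpm_", "", rcols)
  }
  structure(list(tag_id = df$tag_id, sequence = df$sequence,
                 counts = counts, rpm = rpm, retained_reads = NULL),
            class = "distinct_tags")
}
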