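## Annotation of distinct tags as genuine conserved miRNAs: perfect
## precursor match + stable hairpin + star sequence with 2-nt 3'
## overhang geometry, plus family assignment and summaries.

#' Map tags to precursor loci by perfect match
#'
#' Reports every exact occurrence of every tag in every precursor (a
#' tag may hit multiple loci and multiple positions per locus).
#'
#' @param tags distinct_tags object (normally already RPM-filtered).
#' @param precursors named character vector of precursor sequences, or
#'   a FASTA path.
#' @return data.frame with `tag_id`, `sequence`, `locus_id`, `start`,
#'   `end` (1-based closed coordinates on the precursor), `exact`.
#' @export
map_to_precursors <- function(tags, precursors) {
  if (length(precursors) == 1 && file.exists(precursors)) {
    precursors <- read_fasta_seqs(precursors)
  }
  precursors <- as_dna(precursors)
  empty <- data.frame(tag_id = character(0), sequence = character(0),
                      locus_id = character(0), start = integer(0),
                      end = integer(0), exact = logical(0))
  if (length(precursors) == 0) {
    warning("empty precursor set: no hits possible")
    return(empty)
  }
  if (length(tags$sequence) == 0) return(empty)
  out <- list()
  for (li in seq_along(precursors)) {
    locs <- stringi::stri_locate_all_fixed(precursors[[li]], tags$sequence,
                                           overlap = TRUE)
    hit <- which(!is.na(vapply(locs, function(m) m[1, 1], integer(1))))
    for (ti in hit) {
      m <- locs[[ti]]
      out[[length(out) + 1L]] <- data.frame(
        tag_id = tags$tag_id[ti], sequence = tags$sequence[ti],
        locus_id = names(precursors)[li],
        start = as.integer(m[, 1]), end = as.integer(m[, 2]), exact = TRUE)
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(res$tag_id, res$locus_id, res$start), , drop = FALSE]
}

## walk a stem inward from pair (x, y) to its innermost pair; returns
## c(x*, y*) such that no pair lies strictly between them on this branch
innermost_pair <- function(pt, x, y) {
  repeat {
    inner <- which(!is.na(pt))
    inner <- inner[inner > x & inner < y & pt[inner] > inner & pt[inner] <= y - 1L]
    if (length(inner) == 0L) return(c(x, y))
    x <- min(inner)
    y <- pt[x]
  }
}

#' Predict the star sequence interval for a mature hit on a folded precursor
#'
#' The star is the interval pairing the mature under the canonical
#' processing geometry: both strands of the duplex carry `overhang`-nt
#' (2-nt) 3' overhangs.  With the 1-based pair table `pt`, the star
#' interval is `[pt[i2] - shift2, pt[i1] + overhang + shift1]`, where
#' `i1`/`i2` are the paired positions nearest the mature 5' end and
#' nearest position `mature_end - overhang`, and the shifts extrapolate
#' across unpaired (bulged) edge bases.
#'
#' @param s a [secondary_structure()] of the precursor.
#' @param mature_start,mature_end 1-based closed mature interval.
#' @param overhang 3' overhang length (2 = canonical).
#' @param min_paired_frac minimum fraction of mature bases that must be
#'   paired.
#' @return list with `ok` (logical), `reason` (`"ok"`, `"spans_loop"`,
#'   `"low_pairing"`, `"out_of_bounds"`, `"overlaps_mature"`,
#'   `"crosses_loop"`), `star_start`, `star_end` (1-based closed),
#'   `star_seq` (DNA), `exact` (TRUE iff the duplex is bulge-free over
#'   the anchored region and both anchors are paired).
#' @export
predict_star <- function(s, mature_start, mature_end, overhang = 2L,
                         min_paired_frac = 0.6) {
  pt <- s$pair_table
  n <- length(pt)
  no_star <- function(reason) list(ok = FALSE, reason = reason,
                                   star_start = NA_integer_,
                                   star_end = NA_integer_,
                                   star_seq = NA_character_, exact = FALSE)
  if (mature_start < 1L || mature_end > n || mature_start >= mature_end) {
    return(no_star("out_of_bounds"))
  }
  idx <- mature_start:mature_end
  paired <- idx[!is.na(pt[idx])]
  ## mature folding back on itself, or sitting inside a hairpin loop
  if (length(paired) && any(pt[paired] %in% idx)) return(no_star("spans_loop"))
  if (length(paired) == 0L) {
    enclosing <- which(!is.na(pt) & seq_len(n) < mature_start & pt > mature_end)
    if (length(enclosing)) {
      x <- max(enclosing)
      if (all(is.na(pt[(x + 1L):(pt[x] - 1L)]))) return(no_star("spans_loop"))
    }
    return(no_star("low_pairing"))
  }
  if (length(paired) / length(idx) < min_paired_frac) return(no_star("low_pairing"))

  i1 <- min(paired)
  shift1 <- i1 - mature_start
  target3 <- mature_end - overhang
  p3 <- paired[paired <= target3]
  if (length(p3) == 0L) return(no_star("low_pairing"))
  i2 <- max(p3)
  shift2 <- target3 - i2

  star_end <- pt[i1] + overhang + shift1
  star_start <- pt[i2] - shift2
  if (star_start < 1L || star_end > n || star_start >= star_end) {
    return(no_star("out_of_bounds"))
  }
  if (star_start <= mature_end && star_end >= mature_start) {
    return(no_star("overlaps_mature"))
  }
  ## the star must stay on its own arm, outside the hairpin loop
  apex <- innermost_pair(pt, min(i2, pt[i2]), max(i2, pt[i2]))
  if (apex[2] - apex[1] > 1L) {
    loop_pos <- (apex[1] + 1L):(apex[2] - 1L)
    loop_pos <- setdiff(loop_pos, idx)    # the mature 3' overhang may sit here
    if (any(star_start:star_end %in% loop_pos)) return(no_star("crosses_loop"))
  }
  between <- paired[paired >= i1 & paired <= i2]
  exact <- shift1 == 0L && shift2 == 0L &&
    all(pt[between] == pt[i1] - (between - i1))
  list(ok = TRUE, reason = "ok",
       star_start = as.integer(star_start), star_end = as.integer(star_end),
       star_seq = as_dna(substr(s$sequence, star_start, star_end)),
       exact = exact)
}

#' Is a predicted star sequence expressed among the distinct tags?
#'
#' @param star_seq star sequence (DNA or RNA).
#' @param tags distinct_tags object.
#' @return TRUE iff the star sequence occurs as a distinct tag with
#'   count >= 1 in any library.
#' @export
check_star_expression <- function(star_seq, tags) {
  i <- match(as_dna(star_seq), tags$sequence)
  !is.na(i) && sum(tags$counts[i, ]) >= 1
}

#' Assign tags to mature miRNA families from a known catalog
#'
#' A tag matches a catalog entry if the sequences are identical, or
#' (optionally) of equal length with at most `max_mismatch` mismatches
#' and an identical seed (positions 2-8).  Tags matching entries from
#' more than one family are labelled `AMBIGUOUS`; tags matching none
#' (or an empty catalog) are `UNASSIGNED`.
#'
#' @param sequences character vector of tag sequences.
#' @param catalog named character vector of known matures (names carry
#'   the family, e.g. `tae-miR398a`), or a FASTA path.
#' @param max_mismatch maximum mismatches outside the exact rule (0
#'   disables the relaxed rule).
#' @return character vector of family labels.
#' @export
assign_family <- function(sequences, catalog, max_mismatch = 2L) {
  if (length(catalog) == 1 && file.exists(catalog)) catalog <- read_fasta_seqs(catalog)
  if (length(catalog) == 0) return(rep("UNASSIGNED", length(sequences)))
  catalog <- as_dna(catalog)
  fam <- regmatches(names(catalog),
                    regexpr("miR[0-9]+", names(catalog), ignore.case = TRUE))
  if (length(fam) != length(catalog)) {
    ## entries without a parseable family name get their full name
    fam <- vapply(names(catalog), function(nm) {
      m <- regmatches(nm, regexpr("miR[0-9]+", nm, ignore.case = TRUE))
      if (length(m)) m else nm
    }, character(1), USE.NAMES = FALSE)
  }
  seqs <- as_dna(sequences)
  cat_len <- nchar(catalog)
  cat_seed <- substr(catalog, 2L, 8L)
  vapply(seqs, function(s) {
    hit <- catalog == s
    if (max_mismatch > 0L) {
      same_len <- cat_len == nchar(s)
      if (any(same_len)) {
        cand <- which(same_len & !hit)
        if (length(cand)) {
          seed_ok <- cat_seed[cand] == substr(s, 2L, 8L)
          cand <- cand[seed_ok]
          if (length(cand)) {
            mm <- vapply(cand, function(ci) {
              sum(utf8ToInt(catalog[[ci]]) != utf8ToInt(s))
            }, integer(1))
            hit[cand[mm <= max_mismatch]] <- TRUE
          }
        }
      }
    }
    fams <- unique(fam[hit])
    if (length(fams) == 0L) "UNASSIGNED"
    else if (length(fams) > 1L) "AMBIGUOUS"
    else fams
  }, character(1), USE.NAMES = FALSE)
}

#' Classify distinct tags as genuine conserved miRNAs
#'
#' A tag is accepted iff it has (i) a perfect match to at least one
#' precursor locus, (ii) that precursor folds into a hairpin passing
#' the MFE/nt gate, and (iii) valid star geometry (2-nt 3' overhang
#' duplex) on that precursor.  `star_supported` additionally requires
#' the predicted star sequence to be expressed among the tags; the
#' `accepted_strict` verdict requires star support, the lenient
#' `accepted` verdict does not.
#'
#' @param tags distinct_tags object (RPM-filtered).
#' @param precursor_sets a named character vector of precursors, a FASTA
#'   path, or a list of either (multiple evidence sets combined by OR).
#' @param catalog known mature catalog for family naming (optional).
#' @param mfe_threshold hairpin gate in kcal/mol/nt.
#' @param overhang star overhang (nt).
#' @param min_paired_frac minimum paired fraction of the mature region.
#' @param energy_params folding parameters.
#' @param fold_provider function(sequence) -> secondary_structure; by
#'   default the built-in [fold_mfe()]; supply a wrapper around parsed
#'   external-folder output for interoperability.
#' @return list of class `mirna_annotation`: `annotations` (data.frame
#'   per accepted tag: tag_id, sequence, name, family, loci,
#'   mfe_per_nt, star_supported, size_class, star geometry witness),
#'   `rejections` (data.frame tag_id, sequence, reason), `hits`,
#'   `structures` (per-locus secondary structures).
#' @export
classify_mirna <- function(tags, precursor_sets, catalog = character(0),
                           mfe_threshold = -0.2, overhang = 2L,
                           min_paired_frac = 0.6,
                           energy_params = default_energy_params(),
                           fold_provider = NULL) {
  if (is.null(fold_provider)) {
    fold_provider <- function(seq) fold_mfe(seq, energy_params)
  }
  if (!is.list(precursor_sets)) precursor_sets <- list(precursor_sets)
  precursors <- character(0)
  for (ps in precursor_sets) {
    if (length(ps) == 1 && file.exists(ps)) ps <- read_fasta_seqs(ps)
    precursors <- c(precursors, ps[!(names(ps) %in% names(precursors))])
  }
  hits <- map_to_precursors(tags, precursors)

  loci <- unique(hits$locus_id)
  structures <- lapply(stats::setNames(loci, loci),
                       function(l) fold_provider(precursors[[l]]))
  gate <- vapply(structures, passes_mfe_gate, logical(1), threshold = mfe_threshold)

  ann <- list()
  rej <- list()
  for (ti in seq_along(tags$tag_id)) {
    id <- tags$tag_id[ti]
    h <- hits[hits$tag_id == id, , drop = FALSE]
    if (nrow(h) == 0L) {
      rej[[length(rej) + 1L]] <- data.frame(tag_id = id,
                                            sequence = tags$sequence[ti],
                                            reason = "no_precursor")
      next
    }
    best <- NULL
    reasons <- character(0)
    star_expressed <- FALSE
    ok_loci <- character(0)
    for (k in seq_len(nrow(h))) {
      locus <- h$locus_id[k]
      if (!gate[[locus]]) {
        reasons <- c(reasons, "mfe_gate")
        next
      }
      sp <- predict_star(structures[[locus]], h$start[k], h$end[k],
                         overhang = overhang, min_paired_frac = min_paired_frac)
      if (!sp$ok) {
        reasons <- c(reasons, sp$reason)
        next
      }
      ok_loci <- c(ok_loci, locus)
      expressed <- check_star_expression(sp$star_seq, tags)
      star_expressed <- star_expressed || expressed
      if (is.null(best) || (expressed && !best$expressed)) {
        best <- list(locus = locus, start = h$start[k], end = h$end[k],
                     sp = sp, expressed = expressed,
                     mfe_per_nt = structures[[locus]]$mfe_per_nt)
      }
    }
    if (is.null(best)) {
      reason <- if (all(reasons == "mfe_gate")) "mfe_gate"
                else paste(unique(reasons[reasons != "mfe_gate"]), collapse = ";")
      rej[[length(rej) + 1L]] <- data.frame(tag_id = id,
                                            sequence = tags$sequence[ti],
                                            reason = reason)
      next
    }
    ann[[length(ann) + 1L]] <- data.frame(
      tag_id = id, sequence = tags$sequence[ti],
      locus_id = best$locus, mature_start = best$start, mature_end = best$end,
      star_start = best$sp$star_start, star_end = best$sp$star_end,
      star_seq = best$sp$star_seq, star_exact = best$sp$exact,
      star_supported = star_expressed,
      loci = paste(unique(ok_loci), collapse = ","),
      mfe_per_nt = best$mfe_per_nt,
      size_class = nchar(tags$sequence[ti]))
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(tag_id = character(0), sequence = character(0),
               locus_id = character(0), mature_start = integer(0),
               mature_end = integer(0), star_start = integer(0),
               star_end = integer(0), star_seq = character(0),
               star_exact = logical(0), star_supported = logical(0),
               loci = character(0), mfe_per_nt = numeric(0),
               size_class = integer(0))
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(tag_id = character(0), sequence = character(0),
               reason = character(0))
  if (nrow(annotations)) {
    annotations$family <- assign_family(annotations$sequence, catalog)
    annotations$name <- paste0(annotations$family, "_",
                               tolower(annotations$sequence))
    annotations$accepted <- TRUE
    annotations$accepted_strict <- annotations$star_supported
  } else {
    annotations$family <- character(0)
    annotations$name <- character(0)
    annotations$accepted <- logical(0)
    annotations$accepted_strict <- logical(0)
  }
  rownames(annotations) <- NULL
  rownames(rejections) <- NULL
  structure(list(annotations = annotations, rejections = rejections,
                 hits = hits, structures = structures),
            class = "mirna_annotation")
}

#' @export
print.mirna_annotation <- function(x, ...) {
  cat(sprintf("mirna_annotation: %d accepted (%d star-supported), %d rejected\n",
              nrow(x$annotations), sum(x$annotations$star_supported),
              nrow(x$rejections)))
  invisible(x)
}

#' Family membership and size-class summary
#'
#' @param annotation a `mirna_annotation` object or its `annotations`
#'   data.frame.
#' @param sizes size classes to tabulate.
#' @return data.frame: one row per family with `n_members` and one
#'   `len<k>` column per size class.
#' @export
family_summary <- function(annotation, sizes = 18:24) {
  a <- if (inherits(annotation, "mirna_annotation")) annotation$annotations
       else annotation
  if (nrow(a) == 0L) {
    out <- data.frame(family = character(0), n_members = integer(0))
    for (s in sizes) out[[paste0("len", s)]] <- integer(0)
    return(out)
  }
  fams <- sort(unique(a$family))
  out <- data.frame(family = fams,
                    n_members = vapply(fams, function(f) sum(a$family == f),
                                       integer(1), USE.NAMES = FALSE))
  for (s in sizes) {
    out[[paste0("len", s)]] <- vapply(fams, function(f) {
      sum(a$family == f & a$size_class == s)
    }, integer(1), USE.NAMES = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write the annotation report and rejection log as TSV
#' @param annotation a `mirna_annotation` object.
#' @param path annotation TSV path.
#' @param rejections_path optional rejection-log TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, rejections_path = NULL) {
  cols <- c("tag_id", "name", "family", "loci", "mfe_per_nt",
            "star_supported", "accepted_strict", "size_class", "sequence")
  utils::write.table(annotation$annotations[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(rejections_path)) {
    utils::write.table(annotation$rejections, rejections_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
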