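## Hairpin precursor construction with planted mature/star duplexes.
##
## Geometry (1-based, closed intervals): the precursor is
##   mature (L nt) + loop (loop_len nt) + star arm (L + n_bulges nt)
## where positions i = 1..L-2 of the mature pair with positions
## N-1-i of the star arm.  The last `overhang` (2) nt of the mature and
## the last 2 nt of the star arm are unpaired: both strands of the
## mature/star duplex carry the 2-nt 3' overhangs that genuine
## DCL1 processing leaves.  The star arm is therefore the reverse
## complement of the first L-2 mature bases followed by a 2-nt tail
## chosen not to pair with the mature 5' end (so the planted duplex is
## also the outermost helix of the fold).

## a base that can pair (Watson-Crick or G:U) with neither face
pick_nonpairing <- function(faces) {
  for (cand in c("A", "C", "G", "U")) {
    partners <- switch(cand, A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))
    if (!any(faces %in% partners)) return(cand)
  }
  "C"   # faces {U, G}: no fully safe base exists; C pairs only G
}

#' Build a hairpin precursor around a mature miRNA sequence
#'
#' Constructs a stem-loop precursor whose 5' arm is the mature sequence
#' and whose 3' arm carries the star sequence positioned so that the
#' mature/star duplex has perfect 2-nt 3' overhangs on both strands.
#' Optionally plants bulges (unpaired insertions) in the star arm to
#' emulate the asymmetric bulges of real precursors.
#'
#' @param mature mature miRNA sequence, 18-24 nt, ACGU (or ACGT).
#' @param loop_len hairpin loop length, >= 3.
#' @param overhang length of the 3' overhangs (2 for canonical DCL1
#'   processing; fixed at 2 in the downstream annotation rule).
#' @param n_bulges number of 1-nt bulges (0-2) to insert into the star arm.
#' @param loop_seq optional explicit loop sequence (length `loop_len`).
#' @return list with `precursor` (DNA string), `mature_interval` and
#'   `star_interval` (1-based closed `c(start, end)`), `mature`,
#'   `star_seq`, `loop_len`, `n_bulges`.
#' @examples
#' h <- build_hairpin("UGUGUUCCCAGCUCGACCCCG", loop_len = 8)
#' nchar(h$precursor)  # 21 + 8 + 21 = 50
#' @export
build_hairpin <- function(mature, loop_len, overhang = 2L, n_bulges = 0L,
                          loop_seq = NULL) {
  mature <- as_rna(mature)
  stopifnot_seq(mature, RNA_BASES, "mature")
  L <- nchar(mature)
  if (L < 18L || L > 24L) {
    stop("mature must be 18-24 nt (size-selected small RNA), got ", L, call. = FALSE)
  }
  if (loop_len < 3L) stop("loop_len must be >= 3", call. = FALSE)
  if (n_bulges < 0L || n_bulges > 2L) stop("n_bulges must be 0-2", call. = FALSE)
  mch <- strsplit(mature, "")[[1]]

  if (is.null(loop_seq)) {
    ## loop bases that avoid pairing with the mature 3' overhang keep the
    ## planted helix cleanly separated from the loop
    loop_seq <- paste(rep(pick_nonpairing(mch[c(L - 1L, L)]), loop_len), collapse = "")
  }
  loop_seq <- as_rna(loop_seq)
  if (nchar(loop_seq) != loop_len) stop("loop_seq length != loop_len", call. = FALSE)

  core <- revcomp(substr(mature, 1L, L - overhang))     # pairs mature[1..L-2]
  if (n_bulges > 0L) {
    ## insert unpaired bases at interior positions of the star core
    pos <- round(seq(0.35, 0.65, length.out = n_bulges) * nchar(core))
    ch <- strsplit(core, "")[[1]]
    for (b in seq_len(n_bulges)) {
      p <- pos[b] + (b - 1L)    # account for earlier insertions
      idx <- pmin(pmax(L - overhang - p + c(0L, 1L), 1L), L)
      faces <- mch[idx]
      ch <- append(ch, pick_nonpairing(faces), after = p)
    }
    core <- paste(ch, collapse = "")
  }
  ## 2-nt star 3' tail: the unpaired overhang at the precursor 3' end
  tail2 <- paste(rep(pick_nonpairing(mch[c(1L, 2L)]), overhang), collapse = "")
  star <- paste0(core, tail2)

  precursor <- paste0(mature, loop_seq, star)
  N <- nchar(precursor)
  list(precursor = as_dna(precursor),
       mature_interval = c(1L, L),
       star_interval = c(L + loop_len + 1L, N),
       mature = as_dna(mature),
       star_seq = as_dna(star),
       loop_len = as.integer(loop_len),
       n_bulges = as.integer(n_bulges))
}
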