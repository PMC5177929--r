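## Plant-style miRNA target prediction: penalty-based complementarity
## ("expectation") scoring of the miRNA aligned antisense to a
## transcript site, and a transcript scanner.

#' Default target-scoring parameters
#'
#' Penalty model of the classical plant target predictors: per aligned
#' miRNA position, Watson-Crick match 0, G:U wobble 0.5, mismatch 1,
#' gap 2; penalties are doubled inside the seed region (miRNA positions
#' 2-13, 1-based from the 5' end).  Sites scoring at or below `cutoff`
#' are reported.
#'
#' @return list with `match`, `wobble`, `mismatch`, `gap`,
#'   `seed_start`, `seed_end`, `seed_factor`, `cutoff`, `gap_slack`.
#' @export
target_params <- function() {
  list(match = 0, wobble = 0.5, mismatch = 1, gap = 2,
       seed_start = 2L, seed_end = 13L, seed_factor = 2,
       cutoff = 3.0, gap_slack = 1L)
}

## per-position base-pair penalty lookup (miRNA base vs target base,
## antisense pairing): match if WC pair, wobble if G:U
target_pair_penalty <- function(params) {
  m <- matrix(params$mismatch, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  m["A", "U"] <- params$match
  m["U", "A"] <- params$match
  m["G", "C"] <- params$match
  m["C", "G"] <- params$match
  m["G", "U"] <- params$wobble
  m["U", "G"] <- params$wobble
  m
}

seed_factor_vec <- function(L, params) {
  f <- rep(1, L)
  f[params$seed_start:min(params$seed_end, L)] <- params$seed_factor
  f
}

#' Score a miRNA against a candidate target site
#'
#' Global alignment of the miRNA (5'->3') against the reverse of the
#' site window (i.e. antisense, antiparallel pairing), minimizing the
#' summed penalty ("expectation") under [target_params()].  A gap in
#' the site strand (unaligned miRNA base at position i) costs
#' `gap x seed_factor(i)`; a gap in the miRNA strand (unaligned site
#' base between miRNA positions k and k+1) costs
#' `gap x seed_factor(k+1)`.
#'
#' @param mirna miRNA sequence (5'->3', RNA or DNA).
#' @param site transcript site window (sense strand, 5'->3').
#' @param params scoring parameters.
#' @return list with `expectation` and `alignment` (three strings:
#'   miRNA 5'->3', pairing marks `|` match / `o` wobble / `.` mismatch /
#'   space gap, site 3'->5').
#' @export
score_duplex <- function(mirna, site, params = target_params()) {
  mirna <- as_rna(mirna)
  site <- as_rna(site)
  stopifnot_seq(mirna, RNA_BASES, "mirna")
  stopifnot_seq(site, RNA_BASES, "site")
  m <- strsplit(mirna, "")[[1]]
  t <- rev(strsplit(site, "")[[1]])    # site read 3'->5' against the miRNA
  L <- length(m)
  W <- length(t)
  pen <- target_pair_penalty(params)
  sf <- seed_factor_vec(L, params)
  ## gap factors: deletion of miRNA base i; insertion after miRNA pos k
  del_cost <- params$gap * sf
  ins_cost <- params$gap * c(sf, 1)   # position L+1 (past the 3' end) is unweighted
  ## D[i+1, j+1]: min penalty aligning m[1..i] with t[1..j]
  D <- matrix(Inf, L + 1L, W + 1L)
  D[1, 1] <- 0
  for (j in seq_len(W)) D[1, j + 1L] <- D[1, j] + ins_cost[1]
  for (i in seq_len(L)) {
    D[i + 1L, 1] <- D[i, 1] + del_cost[i]
    for (j in seq_len(W)) {
      D[i + 1L, j + 1L] <- min(D[i, j] + pen[m[i], t[j]] * sf[i],
                               D[i, j + 1L] + del_cost[i],
                               D[i + 1L, j] + ins_cost[i + 1L])
    }
  }
  ## traceback for the alignment strings
  am <- character(0)
  at <- character(0)
  mk <- character(0)
  i <- L
  j <- W
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        abs(D[i + 1L, j + 1L] - (D[i, j] + pen[m[i], t[j]] * sf[i])) < 1e-12) {
      am <- c(m[i], am)
      at <- c(t[j], at)
      p0 <- pen[m[i], t[j]]
      mk <- c(if (p0 == params$match) "|" else if (p0 == params$wobble) "o" else ".",
              mk)
      i <- i - 1L
      j <- j - 1L
    } else if (i > 0 && abs(D[i + 1L, j + 1L] - (D[i, j + 1L] + del_cost[i])) < 1e-12) {
      am <- c(m[i], am)
      at <- c("-", at)
      mk <- c(" ", mk)
      i <- i - 1L
    } else {
      am <- c("-", am)
      at <- c(t[j], at)
      mk <- c(" ", mk)
      j <- j - 1L
    }
  }
  list(expectation = D[L + 1L, W + 1L],
       alignment = c(mirna = paste(am, collapse = ""),
                     marks = paste(mk, collapse = ""),
                     site = paste(at, collapse = "")))
}

## vectorized expectation over all windows of one length, <= 1 gap.
## Exact whenever the optimum uses at most one gap; with gap penalty 2
## (4 in seed) any two-gap alignment scores >= 4, so values <= 4 are
## exact minima and hits at the default cutoff 3 are unaffected.
scan_scores_onegap <- function(m_idx, sf, tr_idx, W, pen_mat, gap, params) {
  L <- length(m_idx)
  n <- length(tr_idx)
  ns <- n - W + 1L
  if (ns < 1L) return(numeric(0))
  starts <- seq_len(ns)
  if (W == L) {
    P <- matrix(0, L, ns)
    for (i in seq_len(L)) {
      P[i, ] <- pen_mat[m_idx[i], tr_idx[starts + W - i]] * sf[i]
    }
    return(colSums(P))
  }
  if (W == L + 1L) {            # one unaligned site base
    A <- matrix(0, L, ns)       # m[i] ~ t'[i]   (gap later)
    B <- matrix(0, L, ns)       # m[i] ~ t'[i+1] (gap earlier)
    for (i in seq_len(L)) {
      A[i, ] <- pen_mat[m_idx[i], tr_idx[starts + W - i]] * sf[i]
      B[i, ] <- pen_mat[m_idx[i], tr_idx[starts + W - i - 1L]] * sf[i]
    }
    cumA <- apply(A, 2, cumsum)
    sB <- colSums(B)
    cumB <- apply(B, 2, cumsum)
    gap_f <- gap * c(sf, 1)
    best <- rep(Inf, ns)
    for (k in 0L:L) {           # gap after miRNA position k
      pre <- if (k == 0L) 0 else cumA[k, ]
      post <- if (k == 0L) sB else sB - cumB[k, ]
      v <- pre + gap_f[k + 1L] + post
      best <- pmin(best, v)
    }
    return(best)
  }
  if (W == L - 1L) {            # one unaligned miRNA base
    A <- matrix(0, L, ns)       # m[i] ~ t'[i]   (deletion later)
    B <- matrix(0, L, ns)       # m[i] ~ t'[i-1] (deletion earlier)
    for (i in seq_len(L)) {
      ja <- starts + W - i
      A[i, ] <- if (i <= W) pen_mat[m_idx[i], tr_idx[ja]] * sf[i] else Inf
      jb <- starts + W - i + 1L
      B[i, ] <- if (i >= 2L) pen_mat[m_idx[i], tr_idx[jb]] * sf[i] else Inf
    }
    cumA <- apply(A, 2, function(x) cumsum(ifelse(is.finite(x), x, 0)))
    cumB <- apply(B, 2, function(x) cumsum(ifelse(is.finite(x), x, 0)))
    sB <- cumB[L, ]
    best <- rep(Inf, ns)
    for (k in seq_len(L)) {     # miRNA position k unaligned
      pre <- if (k == 1L) 0 else cumA[k - 1L, ]
      post <- sB - cumB[k, ]
      v <- pre + gap * sf[k] + post
      best <- pmin(best, v)
    }
    return(best)
  }
  stop("scan window length must be miRNA length - 1 .. + 1")
}

#' Scan transcripts for miRNA target sites
#'
#' Evaluates every window of length `L - gap_slack .. L + gap_slack`
#' (L = miRNA length) on every transcript and reports windows with
#' expectation at or below the cutoff, ordered by (expectation,
#' transcript, position); the best site of each transcript therefore
#' appears before its weaker ones.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param transcripts named character vector of transcript sequences,
#'   or a FASTA path.
#' @param cutoff maximum reported expectation.
#' @param params scoring parameters (see [target_params()]).
#' @param mirna_id identifier recorded in the output.
#' @return data.frame with `mirna_id`, `transcript_id`, `expectation`,
#'   `t_start`, `t_end` (1-based closed transcript coordinates) and the
#'   three alignment strings.
#' @export
scan_transcripts <- function(mirna, transcripts, cutoff = 3.0,
                             params = target_params(), mirna_id = "mirna") {
  if (length(transcripts) == 1 && file.exists(transcripts)) {
    transcripts <- read_fasta_seqs(transcripts)
  }
  empty <- data.frame(mirna_id = character(0), transcript_id = character(0),
                      expectation = numeric(0), t_start = integer(0),
                      t_end = integer(0), aln_mirna = character(0),
                      aln_marks = character(0), aln_site = character(0))
  if (length(transcripts) == 0) {
    warning("empty transcript set")
    return(empty)
  }
  mirna <- as_rna(mirna)
  L <- nchar(mirna)
  m_idx <- match(strsplit(mirna, "")[[1]], RNA_BASES)
  pen_mat <- target_pair_penalty(params)
  sf <- seed_factor_vec(L, params)
  slack <- params$gap_slack
  exact_needed <- cutoff >= 2 * params$gap   # one-gap shortcut insufficient
  out <- list()
  for (tx in names(transcripts)) {
    seq_t <- as_rna(transcripts[[tx]])
    tr_idx <- match(strsplit(seq_t, "")[[1]], RNA_BASES)
    if (anyNA(tr_idx)) stop("non-ACGT symbol in transcript ", tx, call. = FALSE)
    for (W in (L - slack):(L + slack)) {
      if (W < 1L || W > length(tr_idx)) next
      sc <- if (exact_needed || abs(W - L) > 1L) {
        vapply(seq_len(length(tr_idx) - W + 1L), function(s) {
          score_duplex(mirna, substr(seq_t, s, s + W - 1L), params)$expectation
        }, numeric(1))
      } else {
        scan_scores_onegap(m_idx, sf, tr_idx, W, pen_mat, params$gap, params)
      }
      hit <- which(sc <= cutoff + 1e-12)
      for (s in hit) {
        site <- substr(seq_t, s, s + W - 1L)
        d <- score_duplex(mirna, site, params)
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = mirna_id, transcript_id = tx,
          expectation = d$expectation,
          t_start = as.integer(s), t_end = as.integer(s + W - 1L),
          aln_mirna = d$alignment[["mirna"]],
          aln_marks = d$alignment[["marks"]],
          aln_site = d$alignment[["site"]])
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$expectation, res$transcript_id, res$t_start, res$t_end), ]
  rownames(res) <- NULL
  res
}
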