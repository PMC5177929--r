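## Independent oracles used across the suite.  These deliberately avoid
## the package's own code paths: plain loops, recursion and sliding
## scans, written from the model definitions.

rna_bases <- c("A", "C", "G", "U")
dna_bases <- c("A", "C", "G", "T")

rand_seq <- function(len, alphabet = dna_bases) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

can_pair_ch <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

## ---- folding: exhaustive enumeration of nested structures (min loop 3)
enum_structures <- function(ch) {
  n <- length(ch)
  memo <- new.env(parent = emptyenv())
  gen <- function(i, j) {
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    if (i > j) return(list(list()))
    out <- list()
    for (s in gen(i + 1L, j)) out[[length(out) + 1L]] <- s
    if (i + 4L <= j) {
      for (k in (i + 4L):j) {
        if (!can_pair_ch(ch[i], ch[k])) next
        for (a in gen(i + 1L, k - 1L)) for (b in gen(k + 1L, j)) {
          out[[length(out) + 1L]] <- c(list(c(i, k)), a, b)
        }
      }
    }
    memo[[key]] <- out
    out
  }
  gen(1L, n)
}

## independent loop-decomposition energy of a pair list
brute_energy <- function(ch, pairlist, params) {
  if (length(pairlist) == 0) return(0)
  opens <- vapply(pairlist, `[`, integer(1), 1)
  closes <- vapply(pairlist, `[`, integer(1), 2)
  e <- 0
  for (idx in seq_along(pairlist)) {
    i <- opens[idx]
    j <- closes[idx]
    ## children: pairs directly inside (i, j), i.e. inside but not
    ## inside any other pair that is itself inside (i, j)
    inside <- which(opens > i & closes < j)
    direct <- inside[vapply(inside, function(a) {
      !any(opens[inside] < opens[a] & closes[inside] > closes[a])
    }, logical(1))]
    if (length(direct) == 0) {
      e <- e + params$hairpin_a + params$hairpin_b * log((j - i - 1) / 3)
    } else if (length(direct) == 1) {
      k <- opens[direct]
      l <- closes[direct]
      u <- (k - i - 1) + (j - l - 1)
      if (u == 0) {
        e <- e + params$stack[paste0(ch[i], ch[j]), paste0(ch[k], ch[l])]
      } else {
        e <- e + params$interior_a + params$interior_b * log(u)
      }
    } else {
      e <- e + params$multiloop
    }
  }
  e
}

brute_mfe <- function(seq, params) {
  ch <- strsplit(as_rna(seq), "")[[1]]
  best <- 0
  for (st in enum_structures(ch)) {
    e <- brute_energy(ch, st, params)
    if (e < best) best <- e
  }
  best
}

## stack-based dot-bracket matcher, independent of parse_dotbracket
brute_pair_table <- function(db) {
  ch <- strsplit(db, "")[[1]]
  pt <- rep(NA_integer_, length(ch))
  st <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") st <- c(st, i)
    if (ch[i] == ")") {
      j <- st[length(st)]
      st <- st[-length(st)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  pt
}

## ---- star geometry: scan all intervals of mature length for the
## duplex complementarity + 2-nt 3' overhang condition
brute_star_search <- function(precursor, mature_start, mature_end, overhang = 2L) {
  prec <- strsplit(as_rna(precursor), "")[[1]]
  n <- length(prec)
  L <- mature_end - mature_start + 1L
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  found <- list()
  for (s in seq_len(n - L + 1L)) {
    t <- s + L - 1L
    if (s <= mature_end && t >= mature_start) next
    ok <- TRUE
    for (k in 0:(L - 1L - overhang)) {
      mi <- mature_start + k
      pi <- t - overhang - k
      if (prec[pi] != comp[[prec[mi]]]) { ok <- FALSE; break }
    }
    if (ok) found[[length(found) + 1L]] <- c(s, t)
  }
  found
}

## ---- TMM: independent step-by-step reimplementation
naive_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  ns <- colSums(counts)
  uq <- numeric(ncol(counts))
  for (k in seq_len(ncol(counts))) {
    uq[k] <- quantile(counts[, k] / ns[k], 0.75)
  }
  ref <- which.min(abs(uq - mean(uq)))
  fac <- rep(1, ncol(counts))
  for (k in seq_len(ncol(counts))) {
    if (k == ref) next
    keep_rows <- which(counts[, k] > 0 & counts[, ref] > 0)
    if (length(keep_rows) == 0) next
    M <- A <- w <- numeric(length(keep_rows))
    for (z in seq_along(keep_rows)) {
      yk <- counts[keep_rows[z], k]
      yr <- counts[keep_rows[z], ref]
      M[z] <- log2(yk) - log2(yr)
      A[z] <- (log2(yk) + log2(yr)) / 2
      w[z] <- (ns[k] - yk) / (ns[k] * yk) + (ns[ref] - yr) / (ns[ref] * yr)
    }
    nn <- length(M)
    loM <- floor(nn * trim_m) + 1
    hiM <- nn + 1 - loM
    loA <- floor(nn * trim_a) + 1
    hiA <- nn + 1 - loA
    rM <- rank(M)
    rA <- rank(A)
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (any(sel)) fac[k] <- 2^(sum((w[sel] * M[sel])) / sum(w[sel]))
  }
  fac / exp(mean(log(fac)))
}

## ---- target scoring
## suffix-form memoized minimum over all global alignments; independent
## recurrence orientation from the package's prefix DP
oracle_expectation <- function(mirna, site, params = target_params()) {
  m <- strsplit(as_rna(mirna), "")[[1]]
  t <- rev(strsplit(as_rna(site), "")[[1]])
  L <- length(m)
  W <- length(t)
  pen <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("AU", "UA", "GC", "CG")) params$match
    else if (p %in% c("GU", "UG")) params$wobble
    else params$mismatch
  }
  sf <- function(i) {
    if (i >= params$seed_start && i <= min(params$seed_end, L)) params$seed_factor
    else 1
  }
  memo <- new.env(parent = emptyenv())
  best <- function(i, j) {   # min cost aligning m[i..L] with t[j..W]
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    v <- if (i > L && j > W) {
      0
    } else if (i > L) {
      (W - j + 1) * params$gap * 1          # site overhang past the miRNA 3' end
    } else if (j > W) {
      sum(vapply(i:L, function(x) params$gap * sf(x), numeric(1)))
    } else {
      min(pen(m[i], t[j]) * sf(i) + best(i + 1L, j + 1L),
          params$gap * sf(i) + best(i + 1L, j),
          params$gap * (if (i <= L) sf(i) else 1) + best(i, j + 1L))
    }
    memo[[key]] <- v
    v
  }
  best(1L, 1L)
}

## plain exhaustive enumeration of every global alignment (tiny inputs)
enum_alignment_min <- function(mirna, site, params = target_params()) {
  m <- strsplit(as_rna(mirna), "")[[1]]
  t <- rev(strsplit(as_rna(site), "")[[1]])
  L <- length(m)
  W <- length(t)
  pen <- target_pair_penalty(params)
  sf <- seed_factor_vec(L, params)
  sfx <- c(sf, 1)
  rec <- function(i, j, acc) {
    if (i > L && j > W) return(acc)
    out <- Inf
    if (i <= L && j <= W) {
      out <- min(out, rec(i + 1L, j + 1L, acc + pen[m[i], t[j]] * sf[i]))
    }
    if (i <= L) out <- min(out, rec(i + 1L, j, acc + params$gap * sf[i]))
    if (j <= W) out <- min(out, rec(i, j + 1L, acc + params$gap * sfx[i]))
    out
  }
  rec(1L, 1L, 0)
}

## ---- misc
## leftmost adapter-prefix match by sliding scan (trimming oracle)
brute_trim <- function(read, adapter, min_overlap) {
  rl <- nchar(read)
  la <- nchar(adapter)
  for (p in seq_len(max(rl - min_overlap + 1L, 0L))) {
    len <- min(rl - p + 1L, la)
    if (len >= min_overlap &&
        substr(read, p, p + len - 1L) == substr(adapter, 1L, len)) {
      return(list(insert = substr(read, 1L, p - 1L), trimmed = TRUE))
    }
  }
  list(insert = read, trimmed = FALSE)
}

## naive all-pairs substring hit scan (annotation mapping oracle)
naive_hits <- function(tag_seqs, precursors) {
  out <- list()
  for (ti in seq_along(tag_seqs)) {
    s <- tag_seqs[ti]
    for (li in seq_along(precursors)) {
      prec <- precursors[[li]]
      L <- nchar(s)
      if (L > nchar(prec)) next
      for (p in seq_len(nchar(prec) - L + 1L)) {
        if (substr(prec, p, p + L - 1L) == s) {
          out[[length(out) + 1L]] <- data.frame(
            tag = ti, locus = names(precursors)[li], start = p, end = p + L - 1L)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

## naive UPGMA (average linkage) merge heights
naive_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    bi <- bj <- NA
    bd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- mean(d[clusters[[a]], clusters[[b]]])
      if (dd < bd) { bd <- dd; bi <- a; bj <- b }
    }
    heights <- c(heights, bd)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

## tiny simulated experiment shared by pipeline-level tests
make_mini_sim <- function(dir, n_mirnas = 6, n_decoy_tags = 12, n_sirna24 = 15,
                          seed = 5, design = full_design(replicates = 1:2,
                                                         time_dat = c(0L, 1L))) {
  unlink(dir, recursive = TRUE)
  simulate_experiment(dir, n_mirnas = n_mirnas, n_decoy_tags = n_decoy_tags,
                      n_sirna24 = n_sirna24, design = design, seed = seed)
}
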