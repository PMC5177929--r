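## RNA secondary structure: simplified nearest-neighbour energy model,
## minimum-free-energy dynamic program, and dot-bracket interoperability.
##
## The energy model is deliberately compact (downstream it is consumed
## only through the MFE-per-nucleotide hairpin gate): stacking energies
## for the six allowed pair types, logarithmic hairpin- and interior-loop
## penalties, a constant multiloop closing penalty, minimum hairpin loop
## of 3, and no pseudoknots.  Energies are in kcal/mol.

PAIR_TYPES <- c("AU", "CG", "GC", "GU", "UA", "UG")

## 180-degree rotation of a stacked pair: the same stack read from the
## other strand swaps and reverses the two pairs.
rotate_pair <- function(p) {
  paste0(substr(p, 2, 2), substr(p, 1, 1))
}

#' Default parameters of the simplified RNA folding energy model
#'
#' Stacking energies approximate published nearest-neighbour values and
#' are symmetrized so a stack has the same energy read from either
#' strand (`stack[p, q] == stack[rot(q), rot(p)]`).  Loop penalties are
#' `hairpin_a + hairpin_b * log(l / 3)` for a hairpin of `l` unpaired
#' bases (`l >= min_loop = 3`) and `interior_a + interior_b * log(u)`
#' for a bulge or interior loop with `u` unpaired bases
#' (`1 <= u <= max_interior`); closing a multiloop costs the constant
#' `multiloop` and unpaired bases inside multiloops (and in the exterior
#' loop) are free.
#'
#' @return list with elements `stack` (6 x 6 matrix over pair types
#'   AU, CG, GC, GU, UA, UG), `hairpin_a`, `hairpin_b`, `interior_a`,
#'   `interior_b`, `multiloop`, `min_loop`, `max_interior`.
#' @export
default_energy_params <- function() {
  s <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  s["AU", ] <- c(-0.93, -2.24, -2.08, -0.55, -1.10, -1.36)
  s["CG", ] <- c(-2.11, -3.26, -2.36, -1.41, -2.08, -2.11)
  s["GC", ] <- c(-2.35, -3.42, -3.26, -1.53, -2.24, -2.51)
  s["GU", ] <- c(-1.27, -2.51, -2.11, -0.50, -1.36, 0.47)
  s["UA", ] <- c(-1.33, -2.35, -2.11, -1.00, -0.93, -0.55)
  s["UG", ] <- c(-1.00, -1.53, -1.41, 0.30, -0.55, -0.50)
  ## enforce rotational symmetry exactly by averaging with the rotated table
  s2 <- s
  for (p in PAIR_TYPES) for (q in PAIR_TYPES) {
    s2[p, q] <- (s[p, q] + s[rotate_pair(q), rotate_pair(p)]) / 2
  }
  list(stack = s2,
       hairpin_a = 4.5, hairpin_b = 1.6,
       interior_a = 3.2, interior_b = 1.1,
       multiloop = 3.4,
       min_loop = 3L, max_interior = 12L)
}

#' Read / write the folding energy parameter table
#'
#' The configuration is a small two-column TSV (`key`, `value`);
#' stacking entries use keys `stack.<outer>.<inner>` such as
#' `stack.AU.CG`, scalar penalties use their parameter name.  The
#' default table ships as
#' `system.file("extdata", "energy_params.tsv", package = "stressmir")`.
#'
#' @param path TSV file.
#' @param params parameter list as from [default_energy_params()].
#' @return `read_energy_params` returns the parameter list;
#'   `write_energy_params` returns `path` invisibly.
#' @export
read_energy_params <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  params <- default_energy_params()
  for (k in seq_len(nrow(tab))) {
    key <- tab$key[k]
    val <- tab$value[k]
    if (startsWith(key, "stack.")) {
      pq <- strsplit(sub("^stack\\.", "", key), ".", fixed = TRUE)[[1]]
      params$stack[pq[1], pq[2]] <- val
    } else {
      params[[key]] <- if (key %in% c("min_loop", "max_interior")) as.integer(val) else val
    }
  }
  params
}

#' @rdname read_energy_params
#' @export
write_energy_params <- function(params, path) {
  keys <- character(0)
  vals <- numeric(0)
  for (p in PAIR_TYPES) for (q in PAIR_TYPES) {
    keys <- c(keys, sprintf("stack.%s.%s", p, q))
    vals <- c(vals, params$stack[p, q])
  }
  scalars <- c("hairpin_a", "hairpin_b", "interior_a", "interior_b",
               "multiloop", "min_loop", "max_interior")
  keys <- c(keys, scalars)
  vals <- c(vals, vapply(scalars, function(k) as.numeric(params[[k]]), numeric(1)))
  utils::write.table(data.frame(key = keys, value = vals), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pair_type <- function(a, b) paste0(a, b)

CAN_PAIR <- local({
  m <- matrix(FALSE, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  for (p in PAIR_TYPES) m[substr(p, 1, 1), substr(p, 2, 2)] <- TRUE
  m
})

hairpin_penalty <- function(l, params) params$hairpin_a + params$hairpin_b * log(l / 3)
interior_penalty <- function(u, params) params$interior_a + params$interior_b * log(u)

#' Construct a SecondaryStructure object
#'
#' @param sequence RNA string.
#' @param pairs integer vector the length of the sequence; `pairs[i]` is
#'   the 1-based partner of position `i`, or `NA` if unpaired.
#' @param mfe free energy in kcal/mol.
#' @return object of class `secondary_structure` with fields `sequence`,
#'   `dotbracket`, `mfe_kcal_mol`, `pair_table` (1-based, NA = unpaired)
#'   and `mfe_per_nt`.
#' @export
secondary_structure <- function(sequence, pairs, mfe) {
  sequence <- as_rna(sequence)
  n <- nchar(sequence)
  stopifnot(length(pairs) == n)
  idx <- which(!is.na(pairs))
  if (length(idx)) {
    stopifnot(all(pairs[pairs[idx]] == idx))   # involution
    ch <- strsplit(sequence, "")[[1]]
    pt <- pair_type(ch[idx], ch[pairs[idx]])
    if (!all(pt %in% PAIR_TYPES)) {
      stop("invalid base pair(s): ",
           paste(unique(setdiff(pt, PAIR_TYPES)), collapse = ","), call. = FALSE)
    }
  }
  db <- rep(".", n)
  db[idx[pairs[idx] > idx]] <- "("
  db[idx[pairs[idx] < idx]] <- ")"
  structure(list(sequence = sequence,
                 dotbracket = paste(db, collapse = ""),
                 mfe_kcal_mol = mfe,
                 pair_table = as.integer(pairs),
                 mfe_per_nt = mfe / n),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, sprintf(" (%.2f)", x$mfe_kcal_mol), "\n", sep = "")
  invisible(x)
}

#' Energy of a given nested structure under the simplified model
#'
#' Loop-decomposition evaluation: every pair closes either a hairpin
#' loop, a stack, a bulge/interior loop, or a multiloop; unpaired bases
#' in multiloops and in the exterior loop are free.
#'
#' @param sequence RNA string.
#' @param pairs 1-based pair table (NA = unpaired).
#' @param params energy parameters.
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(sequence, pairs, params = default_energy_params()) {
  sequence <- as_rna(sequence)
  ch <- strsplit(sequence, "")[[1]]
  energy <- 0
  opens <- which(!is.na(pairs) & pairs > seq_along(pairs))
  for (i in opens) {
    j <- pairs[i]
    kids <- integer(0)                  # direct children of (i, j)
    k <- i + 1L
    while (k < j) {
      if (!is.na(pairs[k]) && pairs[k] > k && pairs[k] < j) {
        kids <- c(kids, k)
        k <- pairs[k] + 1L
      } else k <- k + 1L
    }
    if (length(kids) == 0L) {
      energy <- energy + hairpin_penalty(j - i - 1L, params)
    } else if (length(kids) == 1L) {
      k <- kids
      l <- pairs[k]
      u <- (k - i - 1L) + (j - l - 1L)
      if (u == 0L) {
        energy <- energy + params$stack[pair_type(ch[i], ch[j]), pair_type(ch[k], ch[l])]
      } else {
        energy <- energy + interior_penalty(u, params)
      }
    } else {
      energy <- energy + params$multiloop
    }
  }
  energy
}

#' Fold an RNA sequence to its minimum free energy structure
#'
#' Zuker-style dynamic program over the simplified energy model of
#' [default_energy_params()]: pseudoknot-free, minimum hairpin loop of 3
#' unpaired bases, bulge/interior loops capped at `max_interior`
#' unpaired bases, multiloops closed at constant cost with free unpaired
#' bases.  The empty structure (energy 0) is always admissible, so the
#' reported MFE is never positive.  Ties are resolved by a fixed
#' traceback preference (pair the earliest exterior position, then
#' hairpin, then stack/interior with the smallest loop, then multiloop
#' with the earliest branch), which makes the reported structure
#' deterministic.
#'
#' @param sequence RNA (or DNA; T is read as U) string, 10-500 nt.
#' @param params energy parameters, see [default_energy_params()].
#' @return a [secondary_structure()] object.
#' @examples
#' s <- fold_mfe("GGGGGAAAAACCCCC")
#' s$mfe_kcal_mol
#' @export
fold_mfe <- function(sequence, params = default_energy_params()) {
  sequence <- as_rna(sequence)
  stopifnot_seq(sequence, RNA_BASES, "fold_mfe() sequence")
  n <- nchar(sequence)
  if (n < 10 || n > 500) stop("fold_mfe() expects 10-500 nt, got ", n, call. = FALSE)
  ch <- strsplit(sequence, "")[[1]]
  minl <- params$min_loop
  maxint <- params$max_interior
  stk <- params$stack
  INF <- 1e9

  can <- CAN_PAIR[ch, ch, drop = FALSE]
  ## V[i,j]: min energy of [i..j] with (i,j) paired.
  ## WM[i,j]: >= 1 helix branch in [i..j], unpaired free (multiloop body).
  ## MB[i,j]: >= 2 branches in [i..j] (first branch + WM of the rest).
  ## WM0 = min(0, WM): >= 0 branches.  Row/col n+1 are empty guards.
  V <- matrix(INF, n, n)
  WM <- matrix(INF, n + 1L, n + 1L)
  MB <- matrix(INF, n + 1L, n + 1L)
  WM0 <- matrix(0, n + 1L, n + 1L)

  for (s in (minl + 1L):(n - 1L)) {
    for (i in seq_len(n - s)) {
      j <- i + s
      if (can[i, j]) {
        best <- hairpin_penalty(s - 1L, params)
        u_max <- min(maxint, s - 3L - minl)   # room left for the inner helix
        if (u_max >= 0L) {
          for (di in 0L:u_max) {
            k <- i + 1L + di
            ls <- (j - 1L - (u_max - di)):(j - 1L)
            ls <- ls[ls - k - 1L >= minl]
            if (length(ls)) {
              u <- di + (j - 1L - ls)
              cost <- interior_penalty(pmax(u, 1L), params)
              iz <- which(u == 0L)     # adjacent inner pair: stack, not loop
              if (length(iz)) {
                l0 <- ls[iz]
                cost[iz] <- if (can[k, l0])
                  stk[pair_type(ch[i], ch[j]), pair_type(ch[k], ch[l0])] else INF
              }
              m <- min(V[k, ls] + cost)
              if (m < best) best <- m
            }
          }
        }
        if (s - 2L >= 2L * (minl + 2L)) {     # room for two branches
          mb <- MB[i + 1L, j - 1L]
          if (mb < INF / 2) {
            v <- params$multiloop + mb
            if (v < best) best <- v
          }
        }
        V[i, j] <- best
      }
      ## WM / MB: first branch opens at i (else recurse on i+1)
      ls <- (i + minl + 1L):j
      vi <- V[i, ls]
      fin <- which(vi < INF / 2)
      if (length(fin)) {
        lf <- ls[fin]
        e1 <- min(vi[fin] + WM0[cbind(lf + 1L, j)])
        w <- WM[cbind(lf + 1L, j)]
        wf <- which(w < INF / 2)
        e2 <- if (length(wf)) min(vi[fin][wf] + w[wf]) else INF
      } else {
        e1 <- INF
        e2 <- INF
      }
      WM[i, j] <- min(WM[i + 1L, j], e1)
      MB[i, j] <- min(MB[i + 1L, j], e2)
      WM0[i, j] <- min(0, WM[i, j])
    }
  }

  ## exterior loop: WE[i] = min energy of the suffix starting at i
  WE <- numeric(n + 2L)
  for (i in n:1) {
    best <- WE[i + 1L]
    if (i + minl + 1L <= n) {
      js <- (i + minl + 1L):n
      vv <- V[i, js]
      fin <- which(vv < INF / 2)
      if (length(fin)) {
        m <- min(vv[fin] + WE[js[fin] + 1L])
        if (m < best) best <- m
      }
    }
    WE[i] <- best
  }
  mfe <- WE[1]

  ## ---- deterministic traceback
  eps <- 1e-9
  pairs <- rep(NA_integer_, n)
  trace_V <- function(i, j) {
    pairs[i] <<- j
    pairs[j] <<- i
    target <- V[i, j]
    s <- j - i
    if (abs(hairpin_penalty(s - 1L, params) - target) < eps) return(invisible())
    u_max <- min(maxint, s - 3L - minl)
    if (u_max >= 0L) {
      for (u in 0L:u_max) {             # stacks first, then growing loops
        for (di in 0L:u) {
          k <- i + 1L + di
          l <- j - 1L - (u - di)
          if (l - k - 1L < minl) next
          if (V[k, l] >= INF / 2) next
          cost <- if (u == 0L) stk[pair_type(ch[i], ch[j]), pair_type(ch[k], ch[l])]
                  else interior_penalty(u, params)
          if (abs(V[k, l] + cost - target) < eps) {
            trace_V(k, l)
            return(invisible())
          }
        }
      }
    }
    if (MB[i + 1L, j - 1L] < INF / 2 &&
        abs(params$multiloop + MB[i + 1L, j - 1L] - target) < eps) {
      trace_MB(i + 1L, j - 1L)
      return(invisible())
    }
    stop("fold_mfe(): traceback failed at V[", i, ",", j, "]")
  }
  trace_MB <- function(i, j) {
    target <- MB[i, j]
    k <- i
    while (k + minl + 1L <= j) {
      for (l in (k + minl + 1L):j) {
        if (V[k, l] < INF / 2 && WM[l + 1L, j] < INF / 2 &&
            abs(V[k, l] + WM[l + 1L, j] - target) < eps) {
          trace_V(k, l)
          trace_WM(l + 1L, j)
          return(invisible())
        }
      }
      k <- k + 1L
    }
    stop("fold_mfe(): traceback failed in multiloop body")
  }
  trace_WM <- function(i, j) {
    target <- WM[i, j]
    k <- i
    while (k + minl + 1L <= j) {
      for (l in (k + minl + 1L):j) {
        if (V[k, l] < INF / 2 &&
            abs(V[k, l] + WM0[l + 1L, j] - target) < eps) {
          trace_V(k, l)
          if (l < j && WM0[l + 1L, j] < -eps) trace_WM(l + 1L, j)
          return(invisible())
        }
      }
      k <- k + 1L
    }
    stop("fold_mfe(): traceback failed in WM")
  }
  i <- 1L
  while (i <= n) {
    advanced <- FALSE
    if (i + minl + 1L <= n) {
      for (j in (i + minl + 1L):n) {
        if (V[i, j] < INF / 2 && abs(V[i, j] + WE[j + 1L] - WE[i]) < eps) {
          trace_V(i, j)
          i <- j + 1L
          advanced <- TRUE
          break
        }
      }
    }
    if (!advanced) i <- i + 1L
  }

  secondary_structure(sequence, pairs, mfe)
}

#' Parse a folder-style sequence / dot-bracket record
#'
#' Accepts the conventional two-line text dialect written by external
#' RNA folding tools: a sequence line followed by a structure line whose
#' trailing parenthesized number is the free energy, e.g.
#' `"GGGAAACCC\n(((...)))  (-1.2)"`.
#'
#' @param record a single string with embedded newlines, or a character
#'   vector of lines (a leading `>`-name line is tolerated).
#' @param require_energy if `FALSE`, a missing trailing energy is
#'   accepted and recorded as 0.
#' @return a [secondary_structure()] object.
#' @export
parse_dotbracket <- function(record, require_energy = TRUE) {
  lines <- if (length(record) == 1L) strsplit(record, "\n", fixed = TRUE)[[1]] else record
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && startsWith(lines[1], ">")) lines <- lines[-1]
  if (length(lines) < 2L) {
    stop("dot-bracket record needs a sequence and a structure line", call. = FALSE)
  }
  seq <- as_rna(trimws(lines[1]))
  stopifnot_seq(seq, RNA_BASES, "dot-bracket sequence")
  sline <- trimws(lines[2])
  m <- regmatches(sline,
                  regexec("^([().]+)(\\s*\\(\\s*(-?[0-9]+\\.?[0-9]*)\\s*\\))?$", sline))[[1]]
  if (length(m) == 0L || !nzchar(m[2])) {
    stop("unparseable structure line: ", sline, call. = FALSE)
  }
  db <- m[2]
  if (!nzchar(m[4])) {
    if (require_energy) stop("missing or unparseable energy in: ", sline, call. = FALSE)
    mfe <- 0
  } else {
    mfe <- as.numeric(m[4])
  }
  if (nchar(db) != nchar(seq)) {
    stop("structure length ", nchar(db), " != sequence length ", nchar(seq), call. = FALSE)
  }
  ch <- strsplit(db, "")[[1]]
  pairs <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) {
        stop("unbalanced brackets: unmatched ')' at position ", i, call. = FALSE)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  if (length(stack)) {
    stop("unbalanced brackets: unmatched '(' at position ", stack[length(stack)],
         call. = FALSE)
  }
  secondary_structure(seq, pairs, mfe)
}

#' Serialize a secondary structure to the two-line folder dialect
#' @param s a [secondary_structure()] object.
#' @return single string `"<sequence>\n<dotbracket> (<energy>)"`.
#' @export
serialize_structure <- function(s) {
  sprintf("%s\n%s (%s)", s$sequence, s$dotbracket,
          format(s$mfe_kcal_mol, digits = 15, scientific = FALSE))
}

#' Hairpin stability gate on MFE per nucleotide
#'
#' A precursor candidate passes if its folding free energy per
#' nucleotide is strictly below the threshold (default -0.2 kcal/mol/nt,
#' i.e. strictly more stable than the threshold).
#'
#' @param s a [secondary_structure()] object.
#' @param threshold gate in kcal/mol per nucleotide.
#' @return logical.
#' @export
passes_mfe_gate <- function(s, threshold = -0.2) {
  (s$mfe_kcal_mol / nchar(s$sequence)) < threshold
}
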