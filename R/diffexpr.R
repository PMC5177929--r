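## Differential expression over the treatment x time design:
## trimmed-mean normalization factors, negative-binomial dispersion
## estimation (Cox-Reid adjusted profile likelihood + moment/shrunk
## tagwise), per-tag NB GLM fits, likelihood-ratio treatment tests with
## BH-FDR, per-time direction calls, Venn region counts and the log2
## heat-map matrix.

#' Trimmed mean of M-values normalization factors
#'
#' The reference library is the one whose upper quartile of count
#' proportions is closest to the mean upper quartile.  For every
#' library, M (log2 count ratio to the reference) and A (average log2
#' abundance) are computed over tags nonzero in both libraries; the
#' extreme `trim_m` fraction of M and `trim_a` fraction of A are
#' discarded and the factor is 2 to the precision-weighted mean of the
#' remaining M values (weights: inverse binomial-approximation
#' variances).  Factors are rescaled to geometric mean 1.
#'
#' @param counts integer matrix, tags x libraries.
#' @param trim_m two-sided trim fraction on M.
#' @param trim_a two-sided trim fraction on A.
#' @return list with `tmm_factor` (named, geometric mean 1),
#'   `effective_size` (library size x factor) and `ref` (reference
#'   library id).
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  if (ncol(counts) < 2) stop("need >= 2 libraries", call. = FALSE)
  lib_size <- colSums(counts)
  if (any(lib_size == 0)) stop("library with all-zero counts", call. = FALSE)
  uq <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  yr <- counts[, ref]
  Nr <- lib_size[ref]
  f <- rep(1, ncol(counts))
  for (k in seq_len(ncol(counts))) {
    if (k == ref) next
    yk <- counts[, k]
    use <- yk > 0 & yr > 0
    if (!any(use)) {
      warning("library ", colnames(counts)[k],
              " shares no nonzero tag with the reference; factor set to 1")
      next
    }
    Nk <- lib_size[k]
    M <- log2(yk[use]) - log2(yr[use])
    A <- (log2(yk[use]) + log2(yr[use])) / 2
    w <- (Nk - yk[use]) / (Nk * yk[use]) + (Nr - yr[use]) / (Nr * yr[use])
    n <- length(M)
    loM <- floor(n * trim_m) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1
    hiA <- n + 1 - loA
    rM <- rank(M)
    rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep) || sum(w[keep]) == 0) {
      warning("no tags left after trimming for ", colnames(counts)[k],
              "; factor set to 1")
      next
    }
    f[k] <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  list(tmm_factor = f, effective_size = lib_size * f,
       ref = colnames(counts)[ref])
}

## negative-binomial deviance (log link), phi > 0
nb_deviance <- function(y, mu, phi) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu))
  2 * sum(t1 - t2)
}

## IRLS for one tag at fixed dispersion; X must be full rank
nb_irls <- function(y, X, offset, phi, mu0 = NULL, maxit = 50L, tol = 1e-8) {
  mu <- if (is.null(mu0)) pmax(y, 1 / 6) else pmax(mu0, 1e-8)
  eta <- log(mu)
  dev <- nb_deviance(y, mu, phi)
  converged <- FALSE
  beta <- rep(NA_real_, ncol(X))
  U <- NULL
  w <- NULL
  for (it in seq_len(maxit)) {
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    sw <- sqrt(w)
    Xw <- X * sw
    A <- crossprod(Xw)
    U <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(U)) break
    beta <- backsolve(U, forwardsolve(t(U), crossprod(Xw, z * sw)))
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    dev_new <- nb_deviance(y, mu, phi)
    if (!is.finite(dev_new)) break
    if (abs(dev_new - dev) < tol * (abs(dev_new) + 0.1)) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  list(beta = drop(beta), mu = mu, deviance = dev, converged = converged,
       chol = U, w = w)
}

#' Fit a negative-binomial log-link GLM for one tag
#'
#' Iteratively reweighted least squares at fixed dispersion, with
#' offsets for (effective) library sizes.
#'
#' @param y integer counts over libraries.
#' @param X design matrix (full rank).
#' @param offset per-library offset, normally `log(effective_size)`.
#' @param phi NB dispersion.
#' @param ... passed to the internal IRLS (`maxit`, `tol`).
#' @return list with `coefficients` (named, natural-log scale), `mu`,
#'   `deviance`, `converged`, `vcov`.
#' @export
fit_nb_glm <- function(y, X, offset, phi, ...) {
  fit <- nb_irls(y, X, offset, phi, ...)
  cf <- fit$beta
  names(cf) <- colnames(X)
  vc <- if (!is.null(fit$chol)) chol2inv(fit$chol) else
    matrix(NA_real_, ncol(X), ncol(X))
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(coefficients = cf, mu = fit$mu, deviance = fit$deviance,
       converged = fit$converged, vcov = vc)
}

#' Model matrix of the treatment x time factorial design
#'
#' Intercept + treatment (control as baseline) + time (first time point
#' as baseline, as a factor) + treatment:time interactions.
#'
#' @param design design sheet.
#' @return design matrix with one row per library.
#' @export
design_matrix <- function(design) {
  trt <- factor(design$treatment,
                levels = c(intersect(TREATMENTS, unique(design$treatment)),
                           setdiff(unique(design$treatment), TREATMENTS)))
  timef <- factor(design$time_dat)
  if (nlevels(timef) > 1L && nlevels(trt) > 1L) {
    X <- stats::model.matrix(~ trt * timef)
  } else if (nlevels(trt) > 1L) {
    X <- stats::model.matrix(~ trt)
  } else {
    X <- stats::model.matrix(~ timef)
  }
  rownames(X) <- design$library_id
  X
}

#' Estimate negative-binomial dispersion for a count matrix
#'
#' The common dispersion maximizes the summed Cox-Reid adjusted profile
#' log-likelihood (likelihood at the IRLS fit minus half the log
#' determinant of the Fisher information) over tags, by 1-D search on
#' a log grid in [1e-6, 10].  Tagwise dispersions are per-tag moment
#' estimates shrunk toward the common value with `prior_df` prior
#' degrees of freedom.
#'
#' @param counts integer matrix, tags x libraries.
#' @param design design sheet.
#' @param offsets per-library offsets (default log library size).
#' @param prior_df prior degrees of freedom of the shrinkage
#'   (`Inf` returns the common value for every tag).
#' @param X optional explicit design matrix.
#' @return list with `common` (scalar) and `tagwise` (named vector).
#' @export
estimate_dispersion <- function(counts, design, offsets = log(colSums(counts)),
                                prior_df = 10, X = design_matrix(design)) {
  use <- rowSums(counts) > 0
  Y <- counts[use, , drop = FALSE]
  p <- ncol(X)
  n <- ncol(Y)
  warm <- vector("list", nrow(Y))
  apl_total <- function(phi) {
    tot <- 0
    for (t in seq_len(nrow(Y))) {
      y <- Y[t, ]
      fit <- nb_irls(y, X, offsets, phi, mu0 = warm[[t]], tol = 1e-6)
      warm[[t]] <<- fit$mu
      ll <- sum(stats::dnbinom(y, size = 1 / phi, mu = fit$mu, log = TRUE))
      cr <- if (!is.null(fit$chol)) sum(log(diag(fit$chol))) else 0
      tot <- tot + ll - cr
    }
    tot
  }
  opt <- stats::optimize(function(lp) -apl_total(exp(lp)),
                         interval = log(c(1e-6, 10)), tol = 1e-3)
  common <- exp(opt$minimum)

  tagwise <- rep(common, nrow(counts))
  names(tagwise) <- rownames(counts)
  if (!is.infinite(prior_df)) {
    df <- n - p
    mom <- rep(common, nrow(Y))
    for (t in seq_len(nrow(Y))) {
      y <- Y[t, ]
      fit <- nb_irls(y, X, offsets, common, mu0 = warm[[t]], tol = 1e-6)
      mu <- fit$mu
      mom[t] <- max(0, (sum((y - mu)^2) * n / df - sum(mu)) / sum(mu^2))
    }
    shrunk <- (prior_df * common + df * mom) / (prior_df + df)
    tagwise[use] <- pmax(shrunk, 1e-6)
  }
  list(common = common, tagwise = tagwise)
}

## columns of the full design matrix involving one treatment level
treatment_columns <- function(X, treatment) {
  grep(paste0("^trt", treatment, "(:|$)"), colnames(X))
}

#' Treatment-level and per-time differential expression tests
#'
#' Per treatment, the treatment-level call is a likelihood-ratio test
#' of all terms involving that treatment (main effect + its time
#' interactions) against the full model.  Per (treatment, time point),
#' the log2 fold change versus control at that time (main effect +
#' interaction) gives the direction, with a Wald test.  BH-FDR is
#' applied within each contrast family (per treatment for the overall
#' tests; per treatment x time for the direction tests).
#'
#' @param counts integer matrix, tags x libraries (column order must
#'   match the design).
#' @param design design sheet.
#' @param dispersion tagwise dispersion vector (or scalar), e.g. from
#'   [estimate_dispersion()].
#' @param offsets per-library offsets, normally log effective sizes
#'   from [tmm_factors()].
#' @param alpha FDR threshold for direction calls.
#' @return data.frame of class `de_results` with columns `tag_id`,
#'   `treatment`, `scope` (`"overall"` or the time point), `log2fc`,
#'   `statistic`, `p`, `fdr`, `direction`, `converged`.
#' @export
test_contrasts <- function(counts, design, dispersion,
                           offsets = log(colSums(counts)), alpha = 0.05) {
  X <- design_matrix(design)
  stopifnot(all(colnames(counts) == design$library_id))
  treatments <- setdiff(intersect(TREATMENTS, unique(design$treatment)), "control")
  times <- sort(unique(design$time_dat))
  t0 <- times[1]
  phi <- rep_len(dispersion, nrow(counts))
  names(phi) <- rownames(counts)

  reduced_X <- lapply(stats::setNames(treatments, treatments), function(tr) {
    X[, -treatment_columns(X, tr), drop = FALSE]
  })

  rows <- list()
  for (ti in seq_len(nrow(counts))) {
    tag <- rownames(counts)[ti]
    y <- counts[ti, ]
    if (sum(y) == 0) next
    full <- fit_nb_glm(y, X, offsets, phi[ti])
    if (!full$converged) {
      rows[[length(rows) + 1L]] <- data.frame(
        tag_id = tag, treatment = rep(treatments, each = 1L + length(times)),
        scope = rep(c("overall", as.character(times)), length(treatments)),
        log2fc = NA_real_, statistic = NA_real_, p = NA_real_,
        converged = FALSE)
      next
    }
    for (tr in treatments) {
      red <- nb_irls(y, reduced_X[[tr]], offsets, phi[ti])
      lrt <- max(0, red$deviance - full$deviance)
      df <- length(treatment_columns(X, tr))
      p_overall <- stats::pchisq(lrt, df = df, lower.tail = FALSE)
      main <- paste0("trt", tr)
      lfc_t <- numeric(length(times))
      z_t <- numeric(length(times))
      p_t <- numeric(length(times))
      for (k in seq_along(times)) {
        tt <- times[k]
        sel <- main
        if (tt != t0) sel <- c(main, paste0("trt", tr, ":timef", tt))
        est <- sum(full$coefficients[sel])
        v <- sum(full$vcov[sel, sel])
        lfc_t[k] <- est / log(2)
        z_t[k] <- est / sqrt(v)
        p_t[k] <- 2 * stats::pnorm(-abs(z_t[k]))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tag_id = tag, treatment = tr,
        scope = c("overall", as.character(times)),
        log2fc = c(mean(lfc_t), lfc_t),
        statistic = c(lrt, z_t),
        p = c(p_overall, p_t),
        converged = TRUE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  ## BH within each contrast family
  res$fdr <- NA_real_
  for (tr in treatments) {
    for (sc in unique(res$scope)) {
      i <- res$treatment == tr & res$scope == sc & !is.na(res$p)
      if (any(i)) res$fdr[i] <- stats::p.adjust(res$p[i], method = "BH")
    }
  }
  res$direction <- ifelse(is.na(res$fdr) | res$fdr >= alpha, "ns",
                          ifelse(res$log2fc > 0, "up", "down"))
  attr(res, "alpha") <- alpha
  class(res) <- c("de_results", class(res))
  res
}

#' Tag sets called differentially expressed per treatment
#' @param de a `de_results` data.frame.
#' @param alpha FDR threshold.
#' @return named list of tag_id vectors (one per treatment).
#' @export
de_sets <- function(de, alpha = attr(de, "alpha")) {
  ov <- de[de$scope == "overall" & !is.na(de$fdr) & de$fdr < alpha, ]
  lapply(split(ov$tag_id, ov$treatment), unique)
}

#' Direction-by-time table among treatment-level DE tags
#'
#' For each treatment and time point, counts how many of the tags
#' called differentially expressed at the treatment level are down- or
#' upregulated at that time (sign of the per-time log2 fold change).
#'
#' @param de a `de_results` data.frame.
#' @param alpha FDR threshold for the treatment-level call.
#' @return data.frame `treatment`, `time_dat`, `n_de`, `down`, `up`.
#' @export
direction_by_time <- function(de, alpha = attr(de, "alpha")) {
  sets <- de_sets(de, alpha)
  out <- list()
  for (tr in names(sets)) {
    sub <- de[de$treatment == tr & de$scope != "overall" &
              de$tag_id %in% sets[[tr]], ]
    for (tt in unique(sub$scope)) {
      s <- sub[sub$scope == tt, ]
      out[[length(out) + 1L]] <- data.frame(
        treatment = tr, time_dat = as.integer(tt), n_de = length(sets[[tr]]),
        down = sum(s$log2fc < 0), up = sum(s$log2fc > 0))
    }
  }
  res <- do.call(rbind, out)
  res[order(res$treatment, res$time_dat), ]
}

#' Seven-region Venn overlap counts of three DE sets
#'
#' @param sets named list of three character vectors (e.g. heat, light,
#'   uv tag sets from [de_sets()]; missing treatments count as empty).
#' @return named integer vector of the 7 exclusive region sizes:
#'   `heat`, `light`, `uv`, `heat_light`, `heat_uv`, `light_uv`,
#'   `heat_light_uv`.
#' @export
venn_counts <- function(sets) {
  h <- unique(sets[["heat"]])
  l <- unique(sets[["light"]])
  u <- unique(sets[["uv"]])
  all3 <- intersect(intersect(h, l), u)
  hl <- setdiff(intersect(h, l), all3)
  hu <- setdiff(intersect(h, u), all3)
  lu <- setdiff(intersect(l, u), all3)
  c(heat = length(setdiff(h, union(l, u))),
    light = length(setdiff(l, union(h, u))),
    uv = length(setdiff(u, union(h, l))),
    heat_light = length(hl),
    heat_uv = length(hu),
    light_uv = length(lu),
    heat_light_uv = length(all3))
}

#' Log2 normalized count matrix with hierarchical clustering orders
#'
#' Entries are `log2(count / effective_size * 1e6 + pseudocount)`;
#' rows (tags) and columns (libraries) are clustered by average-linkage
#' hierarchical clustering on Euclidean distances.
#'
#' @param counts integer matrix, tags x libraries.
#' @param effective_size per-library effective sizes.
#' @param tags optional row subset (e.g. the DE set).
#' @param pseudocount added inside the log.
#' @return list with `matrix`, `row_order`, `col_order`, `row_hclust`,
#'   `col_hclust`.
#' @export
heatmap_matrix <- function(counts, effective_size, tags = NULL, pseudocount = 1) {
  if (!is.null(tags)) counts <- counts[tags, , drop = FALSE]
  if (nrow(counts) == 0) stop("empty tag set for heat map", call. = FALSE)
  mat <- log2(sweep(counts, 2, effective_size, "/") * 1e6 + pseudocount)
  rh <- if (nrow(mat) > 1) stats::hclust(stats::dist(mat), method = "average") else NULL
  chc <- if (ncol(mat) > 1) stats::hclust(stats::dist(t(mat)), method = "average") else NULL
  list(matrix = mat,
       row_order = if (is.null(rh)) 1L else rh$order,
       col_order = if (is.null(chc)) 1L else chc$order,
       row_hclust = rh, col_hclust = chc)
}

#' Run the full differential-expression stage
#'
#' TMM factors, offsets, dispersion estimation, treatment-level and
#' per-time tests, DE sets, Venn counts, direction table and the
#' heat-map matrix of the DE union.
#'
#' @param counts integer matrix, tags x libraries.
#' @param design design sheet.
#' @param alpha FDR threshold.
#' @param prior_df dispersion shrinkage prior degrees of freedom.
#' @return list with `factors`, `dispersion`, `results`, `sets`,
#'   `venn`, `direction`, `heatmap` (NULL if no DE tags).
#' @export
run_de <- function(counts, design, alpha = 0.05, prior_df = 10) {
  counts <- counts[, design$library_id, drop = FALSE]
  fac <- tmm_factors(counts)
  offsets <- log(fac$effective_size)
  disp <- estimate_dispersion(counts, design, offsets = offsets,
                              prior_df = prior_df)
  res <- test_contrasts(counts, design, disp$tagwise, offsets, alpha)
  sets <- de_sets(res, alpha)
  vn <- venn_counts(sets)
  dir <- if (length(sets)) direction_by_time(res, alpha) else NULL
  de_union <- unique(unlist(sets))
  hm <- if (length(de_union)) heatmap_matrix(counts, fac$effective_size, de_union)
        else NULL
  list(factors = fac, dispersion = disp, results = res, sets = sets,
       venn = vn, direction = dir, heatmap = hm)
}
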