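#' Sample genome combinations of a given size
#'
#' When the number of combinations `choose(n_total, k)` does not exceed
#' `cap`, all combinations are returned exactly once; otherwise `cap`
#' distinct combinations are sampled uniformly without replacement
#' (seeded).
#'
#' @param n_total number of genomes.
#' @param k combination size, `1 <= k <= n_total`.
#' @param cap maximum number of combinations, default 100000.
#' @param seed integer seed used only in sampling mode.
#' @return integer matrix with `k` rows, one column per combination
#'   (columns sorted ascending within themselves).
#' @export
sample_combinations <- function(n_total, k, cap = 100000L, seed = 1L) {
  if (k < 1 || k > n_total) stop("k must be in 1..n_total")
  total <- choose(n_total, k)
  if (total <= cap) return(utils::combn(n_total, k))
  set.seed(seed)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- matrix(0L, nrow = k, ncol = cap)
  got <- 0L
  while (got < cap) {
    draw <- sort.int(sample.int(n_total, k))
    key <- paste(draw, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      out[, got] <- draw
    }
  }
  out
}

#' Pangenome / core-genome growth points
#'
#' For every combination size `k = 1..n_accessions` and every sampled
#' combination, counts the pangenome size (genes or families present in at
#' least one member) and the core size (present in all members; for
#' families, at least one member gene present in every accession of the
#' combination). All sampled points are retained for fitting, not per-`k`
#' means.
#'
#' @param matrix binary PAV matrix.
#' @param unit `"genes"` or `"families"`.
#' @param families required when `unit = "families"`: data.frame
#'   `gene_id`, `family_id`.
#' @param cap per-`k` combination cap (see [sample_combinations()]).
#' @param seed integer seed.
#' @return data.frame with columns `n` (combination size), `pan_size`,
#'   `core_size`, one row per sampled combination.
#' @export
growth_curves <- function(matrix, unit = c("genes", "families"),
                          families = NULL, cap = 100000L, seed = 1L) {
  unit <- match.arg(unit)
  stopifnot(nrow(matrix) > 0, ncol(matrix) > 0)
  n_acc <- ncol(matrix)
  if (unit == "families") {
    if (is.null(families)) stop("families required for unit = 'families'")
    fam <- families$family_id[match(rownames(matrix), families$gene_id)]
    if (anyNA(fam)) stop("matrix genes without family assignment")
    fam_f <- factor(fam)
  }
  pts <- vector("list", n_acc)
  for (k in seq_len(n_acc)) {
    combos <- sample_combinations(n_acc, k, cap = cap,
                                  seed = seed + k)
    # gene x combo presence counts via one matrix product
    ind <- matrix(0L, nrow = n_acc, ncol = ncol(combos))
    ind[cbind(as.vector(combos),
              rep(seq_len(ncol(combos)), each = k))] <- 1L
    counts <- matrix %*% ind                       # genes x combos
    if (unit == "genes") {
      pan <- colSums(counts > 0L)
      core <- colSums(counts == k)
    } else {
      any_by_fam <- rowsum((counts > 0L) + 0L, fam_f)   # families x combos
      all_by_fam <- rowsum((counts == k) + 0L, fam_f)
      pan <- colSums(any_by_fam > 0L)
      core <- colSums(all_by_fam > 0L)
    }
    pts[[k]] <- data.frame(n = k, pan_size = as.integer(pan),
                           core_size = as.integer(core))
  }
  do.call(rbind, pts)
}

#' Exhaustive growth points over every non-empty accession subset
#'
#' Brute-force enumeration intended as an oracle for small matrices
#' (`<= 15` accessions).
#'
#' @param matrix binary PAV matrix.
#' @return data.frame `n`, `pan_size`, `core_size`, one row per subset.
#' @export
growth_curves_exhaustive <- function(matrix) {
  n_acc <- ncol(matrix)
  stopifnot(n_acc <= 15)
  rows <- list()
  for (k in seq_len(n_acc)) {
    combos <- utils::combn(n_acc, k)
    for (j in seq_len(ncol(combos))) {
      sub <- matrix[, combos[, j], drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        n = k, pan_size = sum(rowSums(sub) > 0),
        core_size = sum(rowSums(sub) == k))
    }
  }
  do.call(rbind, rows)
}

#' Fit pangenome and core-genome growth models
#'
#' The pangenome curve is fitted as a power law `y = A * x^B + C`, the core
#' curve as an exponential decay `y = A * exp(B * x) + C`, both by
#' Levenberg–Marquardt nonlinear least squares
#' ([minpack.lm::nlsLM()]) over all supplied points. Starting values:
#' pan `C0 = 1.01 * max(pan)`, `A0 = mean(pan at n = 1) - C0`, `B0 = -1`;
#' core `C0 = 0.99 * min(core)`, `A0 = mean(core at n = 1) - C0`,
#' `B0 = -0.5`; up to 5 seeded jittered restarts on failure. The predicted
#' asymptotic size is the fitted `C` when `B < 0` (a closed pangenome);
#' otherwise the asymptote is flagged as open. The quoted `predicted_size
#' +/- se` pairs the asymptote with the standard error of `C` from the
#' coefficient covariance.
#'
#' @param points data.frame from [growth_curves()] (columns `n`,
#'   `pan_size`, `core_size`) spanning >= 4 distinct `n` values.
#' @param restarts maximum jittered restarts per curve.
#' @return list with elements `pan` and `core`, each a `fit_result`: list
#'   with `model`, `A`, `B`, `C`, `se_A`, `se_B`, `se_C`,
#'   `predicted_size`, `predicted_size_se`, `closed`, `converged`,
#'   `n_points`.
#' @export
fit_growth_models <- function(points, restarts = 5L) {
  stopifnot(all(c("n", "pan_size", "core_size") %in% names(points)))
  if (length(unique(points$n)) < 4)
    stop("need points spanning at least 4 distinct n values")
  pan <- fit_one_curve(points$n, points$pan_size, "power-law", restarts)
  core <- fit_one_curve(points$n, points$core_size, "exponential", restarts)
  list(pan = pan, core = core)
}

fit_one_curve <- function(x, y, model = c("power-law", "exponential"),
                          restarts = 5L) {
  model <- match.arg(model)
  if (stats::sd(y) < .Machine$double.eps^0.5) {
    # degenerate flat curve: no growth term
    return(fit_result(model, A = 0, B = if (model == "power-law") -1 else
      -0.5, C = mean(y), se = c(0, 0, 0), converged = TRUE,
      n_points = length(x)))
  }
  if (model == "power-law") {
    form <- y ~ A * x^B + C
    C0 <- max(y) * 1.01
    B0 <- -1
  } else {
    form <- y ~ A * exp(B * x) + C
    C0 <- min(y) * 0.99
    B0 <- -0.5
  }
  A0 <- mean(y[x == min(x)]) - C0
  dat <- data.frame(x = x, y = y)
  fit <- NULL
  start <- list(A = A0, B = B0, C = C0)
  for (r in 0:restarts) {
    st <- start
    if (r > 0) {
      set.seed(1000L + r)
      st <- lapply(start, function(v) v * stats::runif(1, 0.5, 1.5) +
                     stats::rnorm(1, 0, 0.01))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(fit_result(model, A = NA_real_, B = NA_real_, C = NA_real_,
                      se = rep(NA_real_, 3), converged = FALSE,
                      n_points = length(x)))
  }
  co <- summary(fit)$coefficients
  fit_result(model, A = co["A", 1], B = co["B", 1], C = co["C", 1],
             se = co[c("A", "B", "C"), 2], converged = TRUE,
             n_points = length(x))
}

fit_result <- function(model, A, B, C, se, converged, n_points) {
  closed <- isTRUE(!is.na(B) && B < 0)
  structure(list(
    model = model, A = A, B = B, C = C,
    se_A = se[1], se_B = se[2], se_C = se[3],
    predicted_size = if (closed) C else NA_real_,
    predicted_size_se = if (closed) se[3] else NA_real_,
    closed = closed, converged = converged, n_points = n_points
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit (%s): A=%.4g B=%.4g C=%.4g", x$model,
              if (x$converged) "converged" else "NOT converged",
              x$A, x$B, x$C))
  if (x$closed)
    cat(sprintf("; predicted asymptotic size %.1f +/- %.1f",
                x$predicted_size, x$predicted_size_se))
  cat("\n")
  invisible(x)
}
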