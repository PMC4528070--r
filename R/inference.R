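#' Fixel-wise GLM t-statistics
#'
#' Ordinary least squares per fixel with a shared design: for data matrix Y
#' (subjects x fixels), design X (subjects x P) and contrast c,
#' \deqn{t = c^T\hat\beta / \sqrt{\hat\sigma^2\, c^T (X^TX)^{-1} c},}
#' with \eqn{\hat\sigma^2 = RSS/(N - P)}. Fixels with zero residual variance
#' (degenerate, e.g. identically zero data) get t = 0 and are reported in the
#' `degenerate` attribute.
#'
#' @param data numeric matrix, subjects x fixels (rows align with `design`).
#' @param design numeric design matrix, subjects x P, full column rank.
#' @param contrast numeric contrast vector of length P, not all zero.
#' @return numeric t-statistic per fixel, with attribute `degenerate`.
#' @export
glm_tstat <- function(data, design, contrast) {
  data <- as.matrix(data)
  design <- as.matrix(design)
  contrast <- as.numeric(contrast)
  n <- nrow(design); p <- ncol(design)
  if (nrow(data) != n) stop_structural("data rows must align with design rows")
  if (length(contrast) != p) stop_structural("contrast length must equal ncol(design)")
  if (all(contrast == 0)) stop_structural("contrast must not be all zero")
  if (qr(design)$rank < p) stop_structural("design must have full column rank")
  if (n - p < 1) stop_structural("need at least 1 residual degree of freedom")
  xtx_inv <- solve(crossprod(design))
  beta <- xtx_inv %*% crossprod(design, data)
  res <- data - design %*% beta
  rss <- colSums(res^2)
  sigma2 <- rss / (n - p)
  cvar <- drop(t(contrast) %*% xtx_inv %*% contrast)
  num <- drop(contrast %*% beta)
  degenerate <- which(sigma2 <= .Machine$double.eps * pmax(1, colSums(data^2)))
  tt <- num / sqrt(sigma2 * cvar)
  tt[degenerate] <- 0
  attr(tt, "degenerate") <- degenerate
  tt
}

# All-orderings count; Inf-safe for larger n.
n_orderings <- function(n) if (n > 170) Inf else factorial(n)

# Seeded permutation schedule: a matrix with one subject ordering per row,
# row 1 = identity. Near or past the number of distinct orderings the
# schedule is drawn without replacement from (or is exactly) the exhaustive
# enumeration.
permutation_schedule <- function(n_subjects, n_permutations, seed) {
  if (n_permutations < 2) stop_structural("need n_permutations >= 2")
  total <- n_orderings(n_subjects)
  if (n_permutations >= total) {
    if (n_permutations > total) {
      warning(sprintf(paste0("requested %d permutations but only %.0f distinct ",
                             "orderings exist; enumerating exhaustively"),
                      n_permutations, total), call. = FALSE)
    }
    perms <- enumerate_orderings(n_subjects)
    idx <- c(1L, setdiff(seq_len(nrow(perms)), 1L))
    return(perms[idx, , drop = FALSE])
  }
  with_seed(seed, {
    if (n_permutations > total / 2) {
      perms <- enumerate_orderings(n_subjects)
      keep <- sample(2:nrow(perms), n_permutations - 1L)
      rbind(perms[1, ], perms[keep, , drop = FALSE])
    } else {
      seen <- new.env(hash = TRUE)
      assign(paste(seq_len(n_subjects), collapse = ","), TRUE, envir = seen)
      out <- matrix(NA_integer_, n_permutations, n_subjects)
      out[1, ] <- seq_len(n_subjects)
      filled <- 1L
      while (filled < n_permutations) {
        cand <- sample.int(n_subjects)
        key <- paste(cand, collapse = ",")
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          filled <- filled + 1L
          out[filled, ] <- cand
        }
      }
      out
    }
  })
}

enumerate_orderings <- function(n) {
  if (n > 10) stop_structural("exhaustive enumeration limited to <= 10 subjects")
  rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1))
    do.call(rbind, lapply(seq_along(v), function(a) {
      cbind(v[a], rec(v[-a]))
    }))
  }
  m <- rec(seq_len(n))
  # identity first
  idx <- which(apply(m, 1, function(r) all(r == seq_len(n))))
  rbind(m[idx, ], m[-idx, , drop = FALSE])
}

# Freedman-Lane pieces: reduced-model fit under the null c'beta = 0.
freedman_lane_parts <- function(data, design, contrast) {
  p <- ncol(design)
  nullspace <- qr.Q(qr(matrix(contrast, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
  if (ncol(nullspace) == 0) {
    fitted <- matrix(0, nrow(data), ncol(data))
  } else {
    z <- design %*% nullspace
    qz <- qr(z)
    fitted <- qr.fitted(qz, data)
  }
  list(fitted = fitted, resid = data - fitted)
}

#' Max-statistic permutation test with CFE enhancement
#'
#' Family-wise-error-corrected fixel p-values: CFE is applied to the
#' t-statistic image of every permutation (becoming part of the test
#' statistic), the global maximum of each enhanced image forms the null
#' distribution, and each fixel's corrected p-value is the proportion of
#' null maxima as-or-more extreme than its observed enhanced value.
#'
#' Permutations follow the Freedman-Lane scheme: the reduced model under the
#' null hypothesis (`contrast' beta = 0`) is fitted, its residual rows are
#' permuted, and the full-model t-statistic is recomputed on the
#' reconstructed data. The identity permutation is always included first, so
#' no p-value can fall below `1/n_permutations`.
#'
#' @param data subjects x fixels matrix (already smoothed, or pass `weights`).
#' @param design,contrast GLM design matrix and contrast vector.
#' @param conn a [build_connectivity()] result.
#' @param params a [cfe_params()].
#' @param weights optional [compute_smoothing_weights()]; if given, each
#'   subject's map is smoothed once before fitting.
#' @param n_permutations number of permutations including the identity.
#' @param seed RNG seed for the permutation schedule.
#' @param two_sided if `TRUE`, runs a second pass on the negated statistic
#'   and Bonferroni-doubles; default `FALSE` (directional contrast).
#' @return an object of class `cfe_fit` with fields `tstat`, `enhanced`,
#'   `pvalue`, `null_max` (the permutation distribution of maxima, identity
#'   first), plus the call parameters. Has [tidy()] and [glance()] methods.
#' @export
cfe_permutation_test <- function(data, design, contrast, conn,
                                 params = cfe_params(), weights = NULL,
                                 n_permutations = 1000, seed = 1,
                                 two_sided = FALSE) {
  data <- as.matrix(data)
  if (!is.null(weights)) {
    data <- as.matrix(data %*% Matrix::t(weights$matrix))
  }
  perms <- permutation_schedule(nrow(data), n_permutations, seed)
  n_perm <- nrow(perms)
  fl <- freedman_lane_parts(data, as.matrix(design), contrast)

  run_direction <- function(sign) {
    tstat_obs <- sign * as.vector(glm_tstat(data, design, contrast))
    cfe_obs <- cfe_enhance(tstat_obs, conn, params)
    null_max <- numeric(n_perm)
    null_max[1] <- max(cfe_obs)
    for (b in seq_len(n_perm)[-1]) {
      y_star <- fl$fitted + fl$resid[perms[b, ], , drop = FALSE]
      t_star <- sign * as.vector(glm_tstat(y_star, design, contrast))
      null_max[b] <- max(cfe_enhance(t_star, conn, params))
    }
    list(tstat = tstat_obs, enhanced = cfe_obs,
         pvalue = fwe_pvalue(cfe_obs, null_max), null_max = null_max)
  }

  pos <- run_direction(1)
  if (two_sided) {
    neg <- run_direction(-1)
    pvalue <- pmin(1, 2 * pmin(pos$pvalue, neg$pvalue))
  } else {
    neg <- NULL
    pvalue <- pos$pvalue
  }
  structure(
    list(tstat = pos$tstat, enhanced = pos$enhanced, pvalue = pvalue,
         null_max = pos$null_max, negative = neg, params = params,
         n_permutations = n_perm, seed = seed, two_sided = two_sided),
    class = "cfe_fit"
  )
}

#' @export
print.cfe_fit <- function(x, ...) {
  cat(sprintf("<cfe_fit> %d fixels, %d permutations (identity included)\n",
              length(x$tstat), x$n_permutations))
  cat(sprintf("  min FWE p-value: %.4g; fixels with p < 0.05: %d\n",
              min(x$pvalue), sum(x$pvalue < 0.05)))
  invisible(x)
}

#' Family-wise-error corrected p-value from a max-statistic null
#'
#' `p = #(null >= observed) / length(null)`; ties count as as-or-more
#' extreme. With the identity labelling included in `null`, an observed
#' value equal to the identity maximum gets at least `1/length(null)`.
#'
#' @param observed numeric (scalar or vector of enhanced values).
#' @param null numeric vector of null maxima (identity first).
#' @return p-values, same length as `observed`.
#' @export
fwe_pvalue <- function(observed, null) {
  if (!length(null)) stop_structural("null distribution is empty")
  ns <- sort(null)
  # count of null >= v via binary search on the sorted null
  (length(ns) - findInterval(observed, ns, left.open = TRUE)) / length(ns)
}

#' Threshold FWE p-values into a significance mask
#'
#' Strict inequality: `p < alpha`.
#' @param pvalues numeric fixel p-values.
#' @param alpha family-wise error level, default 0.05.
#' @return logical mask.
#' @export
significant_fixels <- function(pvalues, alpha = 0.05) {
  pvalues < alpha
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a CFE permutation fit
#'
#' @param x a `cfe_fit`.
#' @param alpha significance level for the `significant` column.
#' @param ... unused.
#' @return a tibble with one row per fixel: `fixel`, `tstat`, `enhanced`,
#'   `pvalue`, `significant`.
#' @export
tidy.cfe_fit <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    fixel = seq_along(x$tstat),
    tstat = x$tstat,
    enhanced = x$enhanced,
    pvalue = x$pvalue,
    significant = significant_fixels(x$pvalue, alpha)
  )
}

#' One-row summary of a CFE permutation fit
#'
#' @param x a `cfe_fit`.
#' @param alpha significance level.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.cfe_fit <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_fixels = length(x$tstat),
    n_permutations = x$n_permutations,
    min_pvalue = min(x$pvalue),
    n_significant = sum(significant_fixels(x$pvalue, alpha)),
    max_enhanced = max(x$enhanced),
    two_sided = x$two_sided
  )
}
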