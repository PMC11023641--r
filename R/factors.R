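#' Z-score metrics within subject-day
#'
#' Normalizes each metric column against the individual daily mean and
#' standard deviation, removing between-subject and between-day level
#' differences before factor analysis. Columns with zero daily SD come out
#' `NA` for that subject-day.
#'
#' @param table data frame with grouping columns and metric columns.
#' @param vars metric column names to normalize.
#' @param by grouping column names (default subject and day).
#' @return The table with `vars` replaced by their within-group z-scores.
#' @export
zscore_daily <- function(table, vars, by = c("subject", "day")) {
  stopifnot(all(vars %in% names(table)), all(by %in% names(table)))
  key <- interaction(table[by], drop = TRUE)
  for (v in vars) {
    mu <- stats::ave(table[[v]], key, FUN = function(x) mean(x, na.rm = TRUE))
    sd <- stats::ave(table[[v]], key, FUN = function(x) stats::sd(x, na.rm = TRUE))
    z <- (table[[v]] - mu) / sd
    z[!is.finite(z)] <- NA_real_
    table[[v]] <- z
  }
  table
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix of the input differs from identity
#' (i.e. whether the variables are correlated enough to factor):
#' chi-square = -(n - 1 - (2p + 5) / 6) * log det(R), with p(p-1)/2 degrees
#' of freedom.
#'
#' @param x data frame or matrix of observations (rows) by variables
#'   (columns); incomplete rows are dropped.
#' @return list with `statistic`, `df`, `p_value`, `n`.
#' @export
bartlett_sphericity <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("need more observations than variables")
  R <- stats::cor(x)
  detR <- det(R)
  if (detR <= 0) stop("singular correlation matrix")
  stat <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), n = n)
}

#' Eigenvalues of the correlation matrix (scree)
#'
#' @param x observations-by-variables data; incomplete rows dropped.
#' @return Descending eigenvalues; they sum to the number of variables.
#' @export
scree_eigenvalues <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  sort(eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

# Minimum-residual (ULS) factor extraction: minimize the sum of squared
# off-diagonal residuals of R - LL' over the uniquenesses, with L the
# top-k eigenstructure of R with its diagonal replaced by the communalities.
minres_extract <- function(R, n_factors, max_iter = 500) {
  p <- ncol(R)
  loadings_for <- function(psi) {
    Rs <- R
    diag(Rs) <- 1 - psi
    e <- eigen(Rs, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(n_factors)], 0)
    e$vectors[, seq_len(n_factors), drop = FALSE] %*% diag(sqrt(lam), n_factors)
  }
  objective <- function(psi) {
    L <- loadings_for(psi)
    res <- R - tcrossprod(L)
    diag(res) <- 0
    sum(res^2) / 2
  }
  start <- pmin(pmax(1 - 0.5 / diag(solve(R)), 0.05), 0.95)
  fit <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = rep(0.001, p), upper = rep(0.999, p),
                      control = list(maxit = max_iter, factr = 1e7))
  if (fit$convergence != 0) {
    stop(sprintf("minres extraction did not converge (code %d after %d evaluations): %s",
                 fit$convergence, fit$counts[1L], fit$message))
  }
  L <- loadings_for(fit$par)
  list(loadings = L, uniquenesses = fit$par, objective = fit$value)
}

.fa_vars <- c("rmssd", "sdnn", "pnni50", "total_power", "nhf_power", "cvi", "csi")

# Rule-based factor naming from the rotated loading pattern. Factor signs are
# arbitrary, so each rule is also tried on the negated column; `flip` marks
# factors whose orientation should be reversed to match the named pattern.
label_factors <- function(L) {
  labels <- paste("Factor", seq_len(ncol(L)))
  flip <- rep(FALSE, ncol(L))
  vars <- rownames(L)
  parasym <- function(lj) {
    all(c("rmssd", "nhf_power", "csi") %in% vars) &&
      !anyNA(lj[c("rmssd", "nhf_power", "csi")]) &&
      lj["rmssd"] > 0 && lj["nhf_power"] > 0 && lj["csi"] < 0
  }
  for (j in seq_len(ncol(L))) {
    lj <- L[, j]
    top <- vars[order(abs(lj), decreasing = TRUE)[1:4]]
    if (all(c("rmssd", "sdnn", "pnni50", "total_power") %in% top)) {
      labels[j] <- "Overall HRV"
      if (sum(lj[top]) < 0) flip[j] <- TRUE
    } else if (parasym(lj)) {
      labels[j] <- "Parasympathetic Activity"
    } else if (parasym(-lj)) {
      labels[j] <- "Parasympathetic Activity"
      flip[j] <- TRUE
    }
  }
  list(labels = labels, flip = flip)
}

#' Exploratory factor analysis of the autonomic metric set
#'
#' Fits the two-factor model of autonomic function: minimum-residual (ULS)
#' extraction from the correlation matrix, varimax rotation for
#' interpretability, and regression (Thurstone) factor scores. Factors are
#' labeled by their rotated loading pattern, not their position: a factor
#' whose four strongest loadings are RMSSD, SDNN, pNNI_50 and total power is
#' "Overall HRV"; a factor loading positively on RMSSD and normalized HF
#' power and negatively on the cardiac sympathetic index is "Parasympathetic
#' Activity".
#'
#' @param x observations-by-variables data (typically the seven z-scored HRV
#'   metrics); incomplete rows are dropped listwise.
#' @param n_factors number of factors (2 for this analysis, per the scree
#'   rule).
#' @param rotation `"varimax"` or `"none"`.
#' @param check_sphericity warn (not stop) when Bartlett's test does not
#'   reject sphericity.
#' @return Object of class `hrv_fa`: `loadings` (rotated), `uniquenesses`,
#'   `communalities`, `scores`, `labels`, `rotation`, `eigenvalues`, `n_obs`,
#'   `bartlett`.
#' @export
fit_factors <- function(x, n_factors = 2, rotation = c("varimax", "none"),
                        check_sphericity = TRUE) {
  rotation <- match.arg(rotation)
  x <- as.matrix(x)
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  bt <- bartlett_sphericity(x)
  if (check_sphericity && bt$p_value > 0.05) {
    warning("Bartlett's test does not reject sphericity (p = ",
            format(bt$p_value, digits = 3), "); factors may be meaningless")
  }
  R <- stats::cor(x)
  ext <- minres_extract(R, n_factors)
  L <- ext$loadings
  rownames(L) <- colnames(x)
  rot <- diag(n_factors)
  if (rotation == "varimax" && n_factors > 1L) {
    vm <- stats::varimax(L, normalize = TRUE)
    L <- vm$loadings[, , drop = TRUE]
    L <- matrix(L, nrow = ncol(x), dimnames = list(colnames(x), NULL))
    rot <- vm$rotmat
  }
  # deterministic sign convention: dominant loading positive
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  lab <- label_factors(L)
  labels <- lab$labels
  if (any(lab$flip)) L[, lab$flip] <- -L[, lab$flip, drop = FALSE]
  colnames(L) <- paste0("F", seq_len(ncol(L)))
  # regression (Thurstone) scores on standardized data
  z <- scale(x)
  scores <- z %*% solve(R, L)
  colnames(scores) <- colnames(L)
  structure(list(loadings = L, uniquenesses = ext$uniquenesses,
                 communalities = rowSums(L^2), scores = scores,
                 labels = labels, rotation = rotation,
                 eigenvalues = sort(eigen(R, symmetric = TRUE,
                                          only.values = TRUE)$values,
                                    decreasing = TRUE),
                 n_obs = nrow(x), bartlett = bt,
                 objective = ext$objective),
            class = "hrv_fa")
}

#' @export
print.hrv_fa <- function(x, digits = 2, ...) {
  cat(sprintf("Autonomic factor model: %d factors, %d observations, %s rotation\n",
              ncol(x$loadings), x$n_obs, x$rotation))
  cat("Factor labels:", paste(x$labels, collapse = " | "), "\n\nLoadings:\n")
  print(round(x$loadings, digits))
  cat("\nCommunalities:\n")
  print(round(x$communalities, digits))
  invisible(x)
}

#' @export
summary.hrv_fa <- function(object, ...) {
  ss <- colSums(object$loadings^2)
  cat("Sum of squared loadings:", paste(round(ss, 3), collapse = ", "), "\n")
  cat(sprintf("Bartlett sphericity: chi2(%d) = %.1f, p = %.3g\n",
              object$bartlett$df, object$bartlett$statistic,
              object$bartlett$p_value))
  print(object, ...)
}

#' Tucker congruence between two loading matrices
#'
#' Column-wise congruence coefficients after resolving the factor-order and
#' sign indeterminacy: columns of `B` are permuted and sign-flipped to best
#' match `A`.
#'
#' @param A,B loading matrices with the same dimensions.
#' @param align resolve permutation/sign indeterminacy first.
#' @return Numeric vector of per-factor congruence coefficients (in
#'   \[-1, 1\]; 1 is perfect recovery).
#' @export
tucker_congruence <- function(A, B, align = TRUE) {
  stopifnot(all(dim(A) == dim(B)))
  cong <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  k <- ncol(A)
  if (!align) return(vapply(seq_len(k), function(j) cong(A[, j], B[, j]), 1))
  perms <- if (k <= 5) asplit(permutations_of(k), 1L) else list(seq_len(k))
  best <- -Inf; best_val <- NULL
  for (pm in perms) {
    v <- vapply(seq_len(k), function(j) cong(A[, j], B[, pm[j]]), 1)
    v <- abs(v)
    if (sum(v) > best) { best <- sum(v); best_val <- v }
  }
  best_val
}

# all permutations of 1..n as a matrix (n small)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  unname(out)
}
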