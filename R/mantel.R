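#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with significance
#' from joint row-and-column permutations of the second matrix. The
#' p-value carries the add-one correction
#' `p = (1 + #permutations as extreme) / (1 + n_perm)` and is two-sided by
#' default.
#'
#' @param d1,d2 Distance matrices with identical label sets (d2 is aligned
#'   to d1's label order); at least 4 labels.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return Object of class `mantel_result`: list with `r`, `r_squared`,
#'   `p`, `n_perm`, `seed`, `alternative`, `n`.
#' @export
mantel_test <- function(d1, d2, n_perm = 10000, seed = NULL,
                        alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2)))
      stop("label sets differ", call. = FALSE)
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  n <- nrow(d1)
  if (n < 4) stop("need >= 4 labels", call. = FALSE)
  ut <- upper.tri(d1)
  v1 <- d1[ut]; v2 <- d2[ut]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("constant distance matrix; Mantel r undefined", call. = FALSE)
  r_obs <- stats::cor(v1, v2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  count <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    rp <- stats::cor(v1, d2[p, p][ut])
    hit <- if (alternative == "two.sided") abs(rp) >= abs(r_obs) - 1e-12
    else rp >= r_obs - 1e-12
    if (hit) count <- count + 1L
  }
  structure(list(r = r_obs, r_squared = r_obs^2,
                 p = (1 + count) / (1 + n_perm),
                 n_perm = n_perm, seed = seed, alternative = alternative,
                 n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %d permutations): r = %.4f, r^2 = %.4f, p = %.4g\n",
              x$alternative, x$n_perm, x$r, x$r_squared, x$p))
  invisible(x)
}

#' Linearized genetic distance for isolation-by-distance regressions
#'
#' `R_ST / (1 - R_ST)` applied entrywise; values at 1 map to `Inf`.
#' @param m Matrix of pairwise R_ST values.
#' @return Transformed matrix.
#' @export
linearize_rst <- function(m) {
  out <- m / (1 - m)
  diag(out) <- 0
  out
}
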