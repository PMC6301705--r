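# Supporting statistics: correlation/regression across phases and theory
# levels, randomization tests for group differences, and assay batch
# normalization.

#' Pearson correlation and coefficient of determination
#'
#' @param x,y paired numeric vectors (length >= 3, no missing values).
#' @return List with `r` and `r2`.
#' @export
pearson_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            !anyNA(x), !anyNA(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  r <- stats::cor(x, y)
  list(r = r, r2 = r^2)
}

#' Ordinary least-squares line through paired values
#'
#' Thin wrapper around [stats::lm()] used to relate energies computed at
#' two theory levels (or in two phases).
#'
#' @inheritParams pearson_r2
#' @return List with `slope`, `intercept`, `r2`, `se_slope`,
#'   `se_intercept` and the underlying `fit`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3, !anyNA(x), !anyNA(y))
  if (stats::sd(x) == 0)
    stop("regression undefined for constant x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # summary.lm warns on numerically perfect fits; those are legitimate here
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- sm$coefficients
  list(slope = unname(cf["x", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       r2 = sm$r.squared,
       se_slope = unname(cf["x", "Std. Error"]),
       se_intercept = unname(cf["(Intercept)", "Std. Error"]),
       fit = fit)
}

#' Two-sided randomization test for a two-group difference
#'
#' Tests the null of exchangeability between two groups with the absolute
#' group statistic difference (mean difference by default). All
#' `choose(n1+n2, n1)` label assignments are enumerated when there are at
#' most `max_exhaustive` of them; otherwise `n_perm` random relabelings
#' are drawn and the add-one Monte-Carlo correction
#' `p = (1 + #more extreme) / (1 + n_perm)` keeps p away from zero.
#'
#' @param g1,g2 numeric vectors (both nonempty).
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed RNG seed for the Monte-Carlo branch; mandatory there for
#'   reproducible pipelines.
#' @param statistic function of two vectors; default mean difference.
#' @param max_exhaustive threshold on the number of assignments below
#'   which exact enumeration is used.
#' @return List with `p`, `observed`, `method`
#'   (`"exhaustive"`/`"monte-carlo"`), `n_perm`.
#' @export
#' @examples
#' randomization_test(c(1, 2, 3), c(10, 11, 12))$p  # 0.1, the exact minimum
randomization_test <- function(g1, g2, n_perm = 10000, seed = NULL,
                               statistic = function(a, b) mean(a) - mean(b),
                               max_exhaustive = 20000) {
  n1 <- length(g1); n2 <- length(g2)
  if (n1 == 0L || n2 == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  pooled <- c(g1, g2)
  obs <- abs(statistic(g1, g2))
  total <- choose(n1 + n2, n1)
  if (total <= max_exhaustive) {
    idx <- utils::combn(n1 + n2, n1)
    stat <- apply(idx, 2, function(i)
      abs(statistic(pooled[i], pooled[-i])))
    p <- mean(stat >= obs - 1e-12)
    method <- "exhaustive"; n_used <- total
  } else {
    if (is.null(seed))
      stop("seed is required for the Monte-Carlo branch", call. = FALSE)
    set.seed(seed)
    stat <- vapply(seq_len(n_perm), function(k) {
      i <- sample.int(n1 + n2, n1)
      abs(statistic(pooled[i], pooled[-i]))
    }, 0)
    p <- (1 + sum(stat >= obs - 1e-12)) / (1 + n_perm)
    method <- "monte-carlo"; n_used <- n_perm
  }
  list(p = p, observed = obs, method = method, n_perm = n_used)
}

#' Normalize assay batches to their means and merge
#'
#' Each measurement is divided by the mean of its batch (experiment), so
#' that batches measured under different conditions become comparable,
#' then all batches are concatenated. Within-batch ratios are preserved.
#'
#' @param batches named list of nonempty numeric vectors with nonzero
#'   means.
#' @return data.frame with `batch` and `value` (normalized) columns.
#' @export
#' @examples
#' batch_normalize(list(a = c(2, 4)))$value  # 0.667, 1.333
batch_normalize <- function(batches) {
  stopifnot(is.list(batches), length(batches) >= 1)
  out <- lapply(seq_along(batches), function(i) {
    v <- batches[[i]]
    if (!length(v)) stop("empty batch ", i, call. = FALSE)
    m <- mean(v)
    if (m == 0) stop("zero mean in batch ", i, call. = FALSE)
    data.frame(batch = if (!is.null(names(batches))) names(batches)[i]
               else as.character(i),
               value = v / m, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
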