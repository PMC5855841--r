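# The statistical battery applied to grouped measurements, implemented
# from the defining formulas (rank arithmetic, enumeration, hypergeometric
# sums) rather than wrapping existing test functions. Base distribution
# functions (pnorm, pchisq, pt) supply the reference distributions.

new_test_result <- function(method, statistic, p_value, ...) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(c(list(method = method, statistic = statistic,
                   p_value = p_value), list(...)),
            class = "cavgate_test")
}

#' @export
print.cavgate_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method,
              as.numeric(x$statistic)[1], x$p_value))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Group summary (mean +/- SEM)
#'
#' @param x Numeric sample.
#' @param name Group label.
#' @return data.frame with `name`, `n`, `mean`, `sd`, `sem` (= sd / sqrt(n)).
#' @export
group_summary <- function(x, name = deparse(substitute(x))) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 1)
  s <- stats::sd(x)
  data.frame(name = name, n = length(x), mean = mean(x), sd = s,
             sem = s / sqrt(length(x)))
}

# sum of (t^3 - t) over tie groups
tie_term <- function(values) {
  t <- table(values)
  sum(t^3 - t)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. In `exact` mode (or `auto` with
#' `n_x + n_y <= 12` and no ties) the p value is computed by full
#' enumeration of all \eqn{\binom{N}{n_x}} rank assignments:
#' \eqn{p = P(|U - n_x n_y / 2| \ge |U_{obs} - n_x n_y/2|)}. Otherwise the
#' tie-corrected normal approximation is used, with a 0.5 continuity
#' correction by default.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @param continuity Apply the continuity correction in the asymptotic
#'   mode.
#' @return A test result with the U statistic (for `x`), `p_value`, and
#'   `exact` flag.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "asymptotic"),
                           continuity = TRUE) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y); N <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- tie_term(pooled) > 0
  do_exact <- switch(mode,
    exact = TRUE,
    asymptotic = FALSE,
    auto = N <= 12 && !ties)
  if (do_exact && ties)
    stop("exact enumeration requires tie-free data", call. = FALSE)
  mu <- nx * ny / 2
  if (do_exact) {
    # tie-free: the rank multiset is exactly 1..N, so every relabelling is
    # a choice of nx ranks out of N
    combos <- utils::combn(N, nx)
    u_all <- colSums(combos) - nx * (nx + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    return(new_test_result("Mann-Whitney U (exact)", c(U = u_obs), p,
                           exact = TRUE))
  }
  sigma2 <- nx * ny / 12 * ((N + 1) - tie_term(pooled) / (N * (N - 1)))
  if (sigma2 <= 0)
    return(new_test_result("Mann-Whitney U (asymptotic)", c(U = u_obs), 1,
                           exact = FALSE, degenerate = TRUE))
  dev <- abs(u_obs - mu)
  if (continuity) dev <- max(0, dev - 0.5)
  z <- dev / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  new_test_result("Mann-Whitney U (asymptotic)", c(U = u_obs), p,
                  exact = FALSE, z = z)
}

#' Kruskal-Wallis rank test
#'
#' \eqn{H = \frac{12}{N(N+1)} \sum_j R_j^2/n_j - 3(N+1)}, divided by the tie
#' correction \eqn{1 - \sum(t^3 - t)/(N^3 - N)}; p from the chi-square
#' distribution with k - 1 degrees of freedom.
#'
#' @param groups List of >= 2 non-empty numeric samples.
#' @return Test result with statistic `H` (tie-corrected), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2 || any(lengths(groups) == 0))
    stop("need >= 2 non-empty groups", call. = FALSE)
  k <- length(groups)
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_len(k), lengths(groups))
  rj <- tapply(r, idx, sum)
  h <- 12 / (N * (N + 1)) * sum(rj^2 / lengths(groups)) - 3 * (N + 1)
  corr <- 1 - tie_term(pooled) / (N^3 - N)
  if (corr <= 0)   # all observations identical
    return(new_test_result("Kruskal-Wallis", c(H = 0), 1, df = k - 1))
  h <- h / corr
  p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
  new_test_result("Kruskal-Wallis", c(H = h), p, df = k - 1)
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks,
#' \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(\frac{N(N+1)}{12} -
#' \frac{\sum(t^3-t)}{12(N-1)}) (1/n_i + 1/n_j)}}, with two-sided normal p
#' values, Bonferroni-multiplied by the number of pairs when requested.
#'
#' @param groups Named or unnamed list of >= 3 non-empty samples (for two
#'   groups use [mann_whitney_u()]).
#' @param adjustment `"bonferroni"` (default) or `"none"`.
#' @return Test result whose `pairwise` element is a data.frame with
#'   columns `group_i`, `group_j`, `z`, `p`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, adjustment = c("bonferroni", "none")) {
  adjustment <- match.arg(adjustment)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 3)
    stop("need >= 3 groups (use mann_whitney_u for two)", call. = FALSE)
  if (any(lengths(groups) == 0))
    stop("empty group", call. = FALSE)
  k <- length(groups)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("g", seq_len(k))
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_len(k), lengths(groups))
  rbar <- tapply(r, idx, mean)
  n <- lengths(groups)
  var_base <- N * (N + 1) / 12 - tie_term(pooled) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  npairs <- ncol(pairs)
  tab <- do.call(rbind, lapply(seq_len(npairs), function(c0) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    se <- sqrt(var_base * (1 / n[i] + 1 / n[j]))
    z <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    p <- min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    data.frame(group_i = nms[i], group_j = nms[j], z = z, p = p)
  }))
  tab$p_adjusted <- if (adjustment == "bonferroni")
    pmin(1, tab$p * npairs) else tab$p
  new_test_result("Dunn post hoc", c(pairs = npairs), min(tab$p_adjusted),
                  pairwise = tab, adjusted = adjustment == "bonferroni")
}

#' Pooled-variance (Student's) two-sample t test
#'
#' Two-sided, classic pooled variance with \eqn{n_x + n_y - 2} degrees of
#' freedom. Zero pooled variance is degenerate: p = 1 for equal means,
#' p = 0 (limit) for unequal means, flagged via `degenerate = TRUE`.
#'
#' @param x,y Numeric samples with >= 2 observations each.
#' @return Test result with statistic `t`, `df`, `p_value`.
#' @export
students_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("need >= 2 observations per group",
                             call. = FALSE)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  d <- mean(x) - mean(y)
  if (sp2 == 0) {
    p <- if (d == 0) 1 else 0
    return(new_test_result("Student's t (pooled)",
                           c(t = if (d == 0) 0 else sign(d) * Inf), p,
                           df = df, degenerate = TRUE))
  }
  t <- d / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  new_test_result("Student's t (pooled)", c(t = t), min(1, p), df = df)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p value as the sum of hypergeometric probabilities, over all
#' tables with the observed margins, whose point probability does not
#' exceed that of the observed table (with a relative slack of 1e-7).
#' A zero margin is degenerate and yields p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Test result with the sample odds ratio as statistic.
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
      any(tab != round(tab)))
    stop("need a 2x2 table of non-negative integers", call. = FALSE)
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  n <- r1 + r2
  or <- (a * d) / (b * c_)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(new_test_result("Fisher exact", c(odds_ratio = or), 1,
                           degenerate = TRUE))
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  probs <- exp(logp)
  p_obs <- probs[ks == a]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  new_test_result("Fisher exact", c(odds_ratio = or), min(1, p))
}
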