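## ---- Wilcoxon signed-rank ------------------------------------------------

# exact null distribution of W+ over all 2^n sign assignments, with ranks
# doubled so average (tied) ranks become integers; returns P(W+ <= w) and
# P(W+ >= w)
wsr_exact_tails <- function(ranks2, w2) {
  total <- sum(ranks2)
  dist <- numeric(total + 1)       # index k+1 holds count of W2+ == k
  dist[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dist[seq_len(total + 1 - r)])
    dist <- dist + shifted
  }
  dist <- dist / 2^length(ranks2)
  k <- 0:total
  c(lower = sum(dist[k <= w2 + 1e-9]), upper = sum(dist[k >= w2 - 1e-9]))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test on paired values (or directly on their
#' differences). Zero differences are discarded; ties in `|d|` receive
#' average ranks. The statistic is `W = min(W+, W-)`. For up to 25 nonzero
#' differences the p-value is exact, from full enumeration of the `2^n`
#' sign assignments (tie-aware); above that a normal approximation with
#' continuity and tie correction is used.
#'
#' @param x numeric vector: first arm, or the paired differences when `y`
#'   is `NULL`.
#' @param y optional numeric vector: second arm, paired with `x`.
#' @param exact_limit largest `n` for which the exact distribution is
#'   enumerated.
#' @return list with `statistic` (W), `w_plus`, `w_minus`, `p_value`,
#'   `n` (nonzero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 25L) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (length(d) < 2) stop("need at least 2 paired values", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop("degenerate test: all paired differences are zero", call. = FALSE)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  W <- min(w_plus, w_minus)
  if (n <= exact_limit) {
    tails <- wsr_exact_tails(as.integer(round(2 * r)), 2 * w_plus)
    p <- min(1, 2 * min(tails))
    method <- "exact (sign enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- w_plus - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (continuity + tie correction)"
  }
  list(statistic = W, w_plus = w_plus, w_minus = w_minus, p_value = p,
       n = n, method = method)
}

## ---- summaries -----------------------------------------------------------

#' Median/range/mean/SEM summary
#'
#' SEM is `sigma / sqrt(n)` with the sample (n-1) standard deviation, the
#' convention used when reporting mean +/- SEM alongside median (range).
#'
#' @param values numeric vector, `n >= 1`.
#' @return A `summary_stats` list: `median`, `range`, `mean`, `sem`, `n`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty input", call. = FALSE)
  n <- length(values)
  structure(list(median = median(values), range = range(values),
                 mean = mean(values),
                 sem = if (n > 1) sd(values) / sqrt(n) else 0,
                 n = n),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("median ", signif(x$median, 4), " (", signif(x$range[1], 4), "-",
      signif(x$range[2], 4), "); mean ", signif(x$mean, 4), " +/- ",
      signif(x$sem, 3), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

## ---- arm comparison ------------------------------------------------------

# per-case metric vectors from a list of qa_reports
arm_metric_values <- function(reports, metric) {
  switch(metric,
         dsc = vapply(reports, function(r) r$dsc, numeric(1)),
         mda = vapply(reports, function(r) r$mda_mm, numeric(1)),
         pct_neg_jacobian = vapply(reports, function(r) r$jacobian$pct_negative,
                                   numeric(1)),
         tre = {
           out <- lapply(seq_along(reports), function(i) {
             p <- reports[[i]]$tre$pairs
             setNames(p$tre_mm, paste0("case", i, ":", p$name))
           })
           unlist(out)
         },
         stop("unknown metric: ", metric, call. = FALSE))
}

#' Compare registration arms over a cohort
#'
#' Takes per-case QA reports for several registration arms (e.g. rigid,
#' deformable, structure-guided variants) and produces a per-arm summary
#' table — one row per arm with median and range of DSC, MDA, TRE and the
#' negative-Jacobian percentage — plus all pairwise two-sided Wilcoxon
#' signed-rank p-values per metric. DSC, MDA and %J<0 are paired per case;
#' TRE is paired per landmark pooled across cases. Raw p-values are
#' reported (no multiplicity correction by default, a Holm adjustment is
#' available).
#'
#' @param arms named list; each element is a list of [qa_report]s, one per
#'   case, in the same case order across arms.
#' @param alpha significance level used for flagging.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return list with `table` (data.frame, one row per arm), `tests`
#'   (data.frame of pairwise comparisons), `alpha`.
#' @export
compare_arms <- function(arms, alpha = 0.05, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (is.null(names(arms)) || any(names(arms) == ""))
    stop("arms must be a named list", call. = FALSE)
  ncase <- unique(vapply(arms, length, integer(1)))
  if (length(ncase) != 1)
    stop("all arms must carry the same number of cases", call. = FALSE)
  has_tre <- all(vapply(arms, function(a)
    all(vapply(a, function(r) !is.null(r$tre), logical(1))), logical(1)))
  metrics <- c("dsc", "mda", if (has_tre) "tre", "pct_neg_jacobian")

  vals <- lapply(metrics, function(m) lapply(arms, arm_metric_values, metric = m))
  names(vals) <- metrics

  tab <- data.frame(arm = names(arms), stringsAsFactors = FALSE)
  for (m in metrics) {
    s <- lapply(vals[[m]], summarize_values)
    tab[[paste0("median_", m)]] <- vapply(s, `[[`, numeric(1), "median")
    tab[[paste0("min_", m)]] <- vapply(s, function(x) x$range[1], numeric(1))
    tab[[paste0("max_", m)]] <- vapply(s, function(x) x$range[2], numeric(1))
    tab[[paste0("mean_", m)]] <- vapply(s, `[[`, numeric(1), "mean")
    tab[[paste0("sem_", m)]] <- vapply(s, `[[`, numeric(1), "sem")
  }

  tests <- list()
  arm_names <- names(arms)
  for (m in metrics) {
    for (i in seq_along(arm_names)) for (j in seq_along(arm_names)) {
      if (j <= i) next
      va <- vals[[m]][[i]]; vb <- vals[[m]][[j]]
      if (m == "tre") {
        common <- intersect(names(va), names(vb))
        if (!setequal(names(va), names(vb)))
          stop("TRE landmark identifiers differ between arms", call. = FALSE)
        va <- va[common]; vb <- vb[common]
      }
      p <- tryCatch(wilcoxon_signed_rank(va, vb)$p_value,
                    error = function(e) NA_real_)
      tests[[length(tests) + 1]] <- data.frame(
        metric = m, arm_a = arm_names[i], arm_b = arm_names[j],
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  if (adjust == "holm")
    tests$p_value <- stats::p.adjust(tests$p_value, method = "holm")
  tests$significant <- !is.na(tests$p_value) & tests$p_value < alpha
  list(table = tab, tests = tests, alpha = alpha)
}
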