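#' Significance tier label
#'
#' Maps a p-value onto the conventional star tiers: `***` for p < 0.001,
#' `**` for p < 0.01, `*` for p <= 0.05 (boundary inclusive), otherwise
#' `n.s.`.
#'
#' @param p p-value in `[0, 1]`.
#' @return Character scalar tier label.
#' @export
significance_tier <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("validation error: p must be a probability in [0, 1]", call. = FALSE)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p <= 0.05) "*"
  else "n.s."
}

new_stat_result <- function(test_name, statistic, p_value,
                            adjusted_p = NA_real_, group_sizes = integer(0),
                            method = NA_character_, comparison = NA_character_) {
  p_for_tier <- if (is.na(adjusted_p)) p_value else adjusted_p
  structure(
    list(test_name = test_name, statistic = statistic, p_value = p_value,
         adjusted_p = adjusted_p, group_sizes = group_sizes,
         method = method, comparison = comparison,
         tier = significance_tier(min(1, p_for_tier))),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$test_name,
      if (!is.na(x$comparison)) paste0("[", x$comparison, "]"), "\n")
  cat(sprintf("  statistic = %.4f, p = %.4g%s  %s\n", x$statistic, x$p_value,
              if (!is.na(x$adjusted_p))
                sprintf(", adjusted p = %.4g", x$adjusted_p) else "",
              x$tier))
  invisible(x)
}

# U statistic of sample a versus b from the pooled ranks
.u_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test reporting `U = min(U_a, U_b)` (so complete
#' separation gives U = 0). The exact two-sided p-value is the permutation
#' probability of a U at least as extreme as observed. In `auto` mode the
#' exact distribution is used when both samples have at most 12
#' observations: via the closed-form tie-free distribution when there are
#' no ties, and by full enumeration over all rank assignments otherwise
#' (feasible at these sizes); larger samples use the tie-corrected normal
#' approximation.
#'
#' @param a,b numeric samples (nonempty).
#' @param mode `"auto"` (default), `"exact"`, or `"normal_approx"`.
#' @return A `stat_result` with the U statistic and two-sided p-value.
#' @examples
#' mann_whitney_u(1:8 + 10, 1:11)  # complete separation: U = 0
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("validation error: empty sample", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  ua <- .u_stat(a, b)
  ub <- n1 * n2 - ua
  u <- min(ua, ub)
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal_approx = FALSE,
                      auto = n1 <= 12L && n2 <= 12L)
  method <- NA_character_
  if (use_exact && !ties) {
    # tie-free permutation distribution (closed form)
    p <- 2 * stats::pwilcox(u, n1, n2)
    p <- min(1, p)
    method <- "exact"
  } else if (use_exact && choose(n1 + n2, n1) <= 2e5) {
    # enumeration over all assignments of pooled values to group a
    pool <- c(a, b)
    combos <- utils::combn(n1 + n2, n1)
    r <- rank(pool)
    us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    us <- pmin(us, n1 * n2 - us)
    p <- mean(us <= u)
    method <- "exact (enumeration)"
  } else {
    # tie-corrected normal approximation, no continuity correction
    nn <- n1 + n2
    tie_tab <- table(c(a, b))
    tie_term <- sum(tie_tab^3 - tie_tab) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (ua - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "tie-corrected normal approximation"
  }
  new_stat_result("Mann-Whitney U", statistic = u, p_value = min(1, p),
                  group_sizes = c(n1, n2), method = method)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' k - 1 degrees of freedom (delegates to [stats::kruskal.test()]).
#'
#' @param groups list of numeric samples (>= 2 groups, each nonempty).
#' @return A `stat_result` with the H statistic; the chi-square degrees of
#'   freedom are reported in `method`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("validation error: need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0L))
    stop("validation error: empty group", call. = FALSE)
  kt <- stats::kruskal.test(groups)
  new_stat_result("Kruskal-Wallis", statistic = unname(kt$statistic),
                  p_value = unname(kt$p.value),
                  group_sizes = lengths(groups),
                  method = sprintf("chi-square, df = %d",
                                   unname(kt$parameter)))
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z statistics from tie-corrected mean-rank differences on the
#' pooled ranking, with Bonferroni adjustment over the number of pairs
#' actually compared. Pairs involving a singleton group are skipped with
#' a warning.
#'
#' @param groups named (or unnamed) list of numeric samples.
#' @param correction multiplicity correction; only `"bonferroni"` is
#'   offered.
#' @return List of `stat_result`, one per compared pair.
#' @export
dunn_posthoc <- function(groups, correction = "bonferroni") {
  correction <- match.arg(correction, "bonferroni")
  if (!is.list(groups) || length(groups) < 2L)
    stop("validation error: need >= 2 groups", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  sizes <- lengths(groups)
  pool <- unlist(groups, use.names = FALSE)
  Ntot <- length(pool)
  r <- rank(pool)
  grp <- rep(names(groups), sizes)
  mean_ranks <- tapply(r, grp, mean)
  tie_tab <- table(pool)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (Ntot - 1))
  base_var <- Ntot * (Ntot + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  usable <- vapply(pairs, function(p) all(sizes[p] > 1L), logical(1))
  if (any(!usable))
    warning("skipping pair(s) with singleton group(s): ",
            paste(vapply(pairs[!usable], paste, "", collapse = " vs "),
                  collapse = "; "))
  pairs <- pairs[usable]
  m <- length(pairs)
  out <- lapply(pairs, function(p) {
    se <- sqrt(base_var * (1 / sizes[[p[1]]] + 1 / sizes[[p[2]]]))
    z <- if (se > 0) (mean_ranks[[p[1]]] - mean_ranks[[p[2]]]) / se else 0
    praw <- 2 * stats::pnorm(-abs(z))
    new_stat_result("Dunn post hoc", statistic = unname(z),
                    p_value = praw, adjusted_p = min(1, praw * m),
                    group_sizes = sizes[p],
                    method = sprintf("Bonferroni over %d pairs", m),
                    comparison = paste(p, collapse = " vs "))
  })
  names(out) <- vapply(pairs, paste, "", collapse = "_vs_")
  out
}
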