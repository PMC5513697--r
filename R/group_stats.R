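#' Welch's two-tailed t-test
#'
#' Two-sample t-test assuming unequal variances (Welch-Satterthwaite
#' degrees of freedom), the test used for all retina-level group
#' comparisons.
#'
#' @param group_a,group_b Numeric vectors of per-retina values, each of
#'   length >= 2.
#' @return A list `t`, `df`, `p` (two-tailed). All `NA` when either group
#'   is too small or both groups have zero variance (the test is
#'   undefined and reported as missing).
#' @export
welch_t <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2L || length(b) < 2L ||
      (var(a) == 0 && var(b) == 0))
    return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Holm-Bonferroni step-down correction
#'
#' Controls the familywise error rate over `m` comparisons: p-values are
#' sorted ascending and `p_(i)` is rejected while
#' `p_(i) <= alpha / (m - i + 1)`; the first failure stops all further
#' rejections. Adjusted p-values are the running maximum of
#' `(m - i + 1) p_(i)`, capped at 1, so that `rejected <=> adjusted p <=
#' alpha`. Missing p-values are carried through as missing and do not
#' count toward `m`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @param alpha Familywise significance level (default 0.05).
#' @return A list: `rejected` (logical, input order), `p_adjusted`
#'   (numeric, input order), `m` (number of non-missing tests).
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must be in [0, 1]")
  adj <- rep(NA_real_, length(pvals))
  adj[ok] <- p.adjust(pvals[ok], method = "holm")
  rej <- rep(NA, length(pvals))
  rej[ok] <- adj[ok] <= alpha
  list(rejected = rej, p_adjusted = adj, m = sum(ok))
}

#' Compare a family of properties between two groups of retinas
#'
#' One Welch t-test per property with Holm-Bonferroni control over the
#' family.
#'
#' @param values_a,values_b Data frames or matrices, one row per retina,
#'   one column per property (shared column names).
#' @param alpha Familywise significance level.
#' @param family Label recorded in the output.
#' @return Data frame: `family`, `property`, `group_a_mean`,
#'   `group_b_mean`, `t`, `df`, `p`, `p_adjusted`, `rejected`.
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05,
                           family = "spiking_properties") {
  values_a <- as.data.frame(values_a); values_b <- as.data.frame(values_b)
  props <- intersect(names(values_a), names(values_b))
  if (!length(props)) stop("no shared properties to compare")
  tests <- lapply(props, function(p) welch_t(values_a[[p]], values_b[[p]]))
  pv <- vapply(tests, `[[`, numeric(1), "p")
  hb <- holm_bonferroni(pv, alpha)
  data.frame(
    family = family, property = props,
    group_a_mean = vapply(props, function(p) mean(values_a[[p]], na.rm = TRUE), numeric(1)),
    group_b_mean = vapply(props, function(p) mean(values_b[[p]], na.rm = TRUE), numeric(1)),
    t = vapply(tests, `[[`, numeric(1), "t"),
    df = vapply(tests, `[[`, numeric(1), "df"),
    p = pv, p_adjusted = hb$p_adjusted, rejected = hb$rejected,
    row.names = NULL
  )
}

#' Compare STTC-distance curves between two groups of retinas
#'
#' For every interelectrode distance no greater than `max_distance` that
#' both groups provide, the per-retina median STTC values are compared by
#' a Welch t-test, with Holm-Bonferroni control over the distances (10
#' distances on an 8x8 grid with 200 um pitch). Distances present in only
#' one group are skipped with a warning.
#'
#' @param curves_a,curves_b Lists of per-retina curve data frames
#'   (`distance_um`, `median_sttc`), as produced by [sttc_curve()].
#' @param max_distance Largest distance tested, um (default 800).
#' @param alpha Familywise significance level.
#' @return Data frame in the layout of [compare_groups()] with `property`
#'   holding the distance in um.
#' @export
compare_sttc_curves <- function(curves_a, curves_b, max_distance = 800,
                                alpha = 0.05) {
  grab <- function(curves) {
    dl <- lapply(curves, function(cv) cv[cv$distance_um <= max_distance, ])
    all_d <- sort(unique(unlist(lapply(dl, `[[`, "distance_um"))))
    mat <- vapply(dl, function(cv)
      cv$median_sttc[match(all_d, cv$distance_um)], numeric(length(all_d)))
    list(d = all_d, mat = matrix(mat, nrow = length(all_d)))
  }
  ga <- grab(curves_a); gb <- grab(curves_b)
  shared <- intersect(signif(ga$d, 10), signif(gb$d, 10))
  only <- c(setdiff(signif(ga$d, 10), shared), setdiff(signif(gb$d, 10), shared))
  if (length(only))
    warning("distances present in one group only were skipped: ",
            paste(signif(only, 4), collapse = ", "))
  va <- as.data.frame(t(ga$mat[match(shared, signif(ga$d, 10)), , drop = FALSE]))
  vb <- as.data.frame(t(gb$mat[match(shared, signif(gb$d, 10)), , drop = FALSE]))
  names(va) <- names(vb) <- format(shared, trim = TRUE)
  res <- compare_groups(va, vb, alpha, family = "sttc_distance")
  res$property <- as.character(res$property)
  res
}
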