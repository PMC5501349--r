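# Combinatorial analytics on normalized quantification tables: single-mark
# deconvolution, heavy-methyl turnover fractions, hybrid-mark ranking,
# pairwise interplay scores, and replicate statistics.

# Parse a mark key like "K27me3:1", "K27me3" (h = 0) or "K27me3:*"
# (any heavy count).
parse_mark_key <- function(key) {
  tk <- parse_mark_tokens(key, wildcard = TRUE)
  if (nrow(tk) != 1L)
    stop("mark key must contain exactly one modification token: \"",
         key, "\"")
  list(residue = tk$residue, site = tk$site, kind = tk$kind,
       heavy = tk$heavy)   # heavy is "0".."3" or "*"
}

# parsed modification sets for the unique proteoform strings of a table;
# index-based accessor because the unmodified form is the empty string
parsed_forms <- function(forms) {
  u <- unique(forms)
  list(forms = u, tokens = lapply(u, parse_mark_tokens))
}

form_tokens <- function(pf, f) pf$tokens[[match(f, pf$forms)]]

form_has_key <- function(tokens, key) {
  if (!nrow(tokens)) return(FALSE)
  hit <- tokens$site == key$site & tokens$kind == key$kind
  if (key$heavy != "*") hit <- hit & tokens$heavy == key$heavy
  any(hit)
}

single_group_table <- function(table) {
  g <- unique(table[, intersect(c("tail", "channel", "sample"),
                                names(table)), drop = FALSE])
  if (nrow(g) > 1L)
    stop("table spans several (tail, channel, sample) groups; subset first ",
         "or use single_mark_table()")
  invisible(TRUE)
}

#' Abundance of a single mark across combinatorial forms
#'
#' Sums the relative abundance of every combinatorial proteoform containing
#' the given mark.  A key with `:h` matches that exact heavy-methyl count
#' (no suffix means `h = 0`); `":*"` aggregates over all heavy counts.  The
#' remaining share up to 1, summed over a site's states, is the unmodified
#' state of that site.
#'
#' @param table Normalized quantification table for a single
#'   (tail, channel, sample) group.
#' @param key Mark key string, e.g. `"K27me3:1"` or `"K9me2:*"`.
#' @return Summed relative abundance in `[0, 1]`.
#' @export
single_ptm_abundance <- function(table, key) {
  single_group_table(table)
  k <- parse_mark_key(key)
  pf <- parsed_forms(table$proteoform)
  hit <- vapply(table$proteoform, function(f) form_has_key(form_tokens(pf, f), k), TRUE)
  sum(table$relative_abundance[hit])
}

#' Single-mark abundance table
#'
#' @param table Normalized quantification table for one group.
#' @param keys Mark keys; default is every exact (site, kind, heavy) mark
#'   observed in the table.
#' @return Data frame `mark`, `abundance`, sorted by abundance descending.
#' @export
single_mark_table <- function(table, keys = NULL) {
  single_group_table(table)
  pf <- parsed_forms(table$proteoform)
  if (is.null(keys)) {
    all_tk <- do.call(rbind, pf$tokens)
    if (is.null(all_tk) || !nrow(all_tk)) {
      return(data.frame(mark = character(), abundance = numeric(),
                        stringsAsFactors = FALSE))
    }
    all_tk <- unique(all_tk)
    keys <- paste0(all_tk$residue, all_tk$site, all_tk$kind,
                   ifelse(all_tk$heavy != "0", paste0(":", all_tk$heavy), ""))
  }
  ab <- vapply(keys, function(k) single_ptm_abundance(table, k), numeric(1))
  out <- data.frame(mark = keys, abundance = unname(ab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abundance, out$mark), ]
  rownames(out) <- NULL
  out
}

#' Fraction of tails carrying at least one heavy methyl group
#'
#' The methylation-turnover readout: the summed relative abundance of
#' proteoforms whose modifications carry one or more heavy-labeled methyl
#' groups.
#'
#' @param table Normalized quantification table for one group.
#' @return Fraction in `[0, 1]`.
#' @export
heavy_fraction <- function(table) {
  single_group_table(table)
  pf <- parsed_forms(table$proteoform)
  hv <- vapply(table$proteoform, function(f) {
    tk <- form_tokens(pf, f)
    nrow(tk) > 0 && sum(as.integer(tk$heavy)) >= 1L
  }, TRUE)
  sum(table$relative_abundance[hv])
}

#' Ranked hybrid methylation marks
#'
#' Hybrid marks are methylations only partially heavy-labeled
#' (`0 < h < k`: me2:1, me3:1, me3:2); they pinpoint sites that inherited
#' part of their methylation state and acquired the rest after labeling
#' started, distinguishing regulated deposition from bulk turnover.
#'
#' @param table Normalized quantification table for one group.
#' @return Data frame `mark`, `abundance`, sorted by summed abundance
#'   descending; empty when no hybrid mark is present.
#' @export
hybrid_marks <- function(table) {
  single_group_table(table)
  pf <- parsed_forms(table$proteoform)
  all_tk <- unique(do.call(rbind, pf$tokens))
  if (is.null(all_tk) || !nrow(all_tk))
    return(data.frame(mark = character(), abundance = numeric(),
                      stringsAsFactors = FALSE))
  h <- as.integer(all_tk$heavy)
  k <- methyl_degree(all_tk$kind)
  hy <- all_tk[h > 0L & h < k, , drop = FALSE]
  if (!nrow(hy))
    return(data.frame(mark = character(), abundance = numeric(),
                      stringsAsFactors = FALSE))
  keys <- paste0(hy$residue, hy$site, hy$kind, ":", hy$heavy)
  single_mark_table(table, keys)
}

#' Interplay score between two marks
#'
#' The observed coexistence frequency `F_ab` (summed abundance of forms
#' carrying both marks) is compared with the frequency expected under
#' independence, `F_a * F_b`; the score is `log2(F_ab / (F_a * F_b))`.
#' Positive scores mean the marks co-occur on the same tail more often than
#' chance, negative scores that they tend to exclude each other.  Mutually
#' exclusive pairs (`F_ab = 0`) and pairs with an absent mark return a
#' flagged undefined result rather than `-Inf`, keeping ranked outputs
#' sortable.
#'
#' @param table Normalized quantification table for one group.
#' @param a,b Mark keys on different sites.
#' @return A one-row data frame of class `interplay_result`: `mark_a`,
#'   `mark_b`, `F_a`, `F_b`, `F_ab`, `score`, `defined`.
#' @export
interplay <- function(table, a, b) {
  ka <- parse_mark_key(a); kb <- parse_mark_key(b)
  if (ka$site == kb$site)
    stop("interplay requires marks on different sites (both on ",
         ka$site, ")")
  single_group_table(table)
  pf <- parsed_forms(table$proteoform)
  has_a <- vapply(table$proteoform, function(f) form_has_key(form_tokens(pf, f), ka), TRUE)
  has_b <- vapply(table$proteoform, function(f) form_has_key(form_tokens(pf, f), kb), TRUE)
  F_a <- sum(table$relative_abundance[has_a])
  F_b <- sum(table$relative_abundance[has_b])
  F_ab <- sum(table$relative_abundance[has_a & has_b])
  defined <- F_a > 0 && F_b > 0 && F_ab > 0
  out <- data.frame(mark_a = a, mark_b = b, F_a = F_a, F_b = F_b,
                    F_ab = F_ab,
                    score = if (defined) log2(F_ab / (F_a * F_b)) else NA_real_,
                    defined = defined, stringsAsFactors = FALSE)
  class(out) <- c("interplay_result", class(out))
  out
}

#' Interplay scores for every pair of marks
#'
#' @param table Normalized quantification table for one group.
#' @param keys Mark keys to pair; default is every exact mark observed.
#' @return Data frame of [interplay()] rows for all cross-site pairs,
#'   sorted by absolute score (undefined pairs last).
#' @export
interplay_table <- function(table, keys = NULL) {
  if (is.null(keys)) keys <- single_mark_table(table)$mark
  if (length(keys) < 2L)
    return(data.frame(mark_a = character(), mark_b = character(),
                      F_a = numeric(), F_b = numeric(), F_ab = numeric(),
                      score = numeric(), defined = logical(),
                      stringsAsFactors = FALSE))
  sites <- vapply(keys, function(k) parse_mark_key(k)$site, integer(1))
  rows <- list()
  for (i in seq_along(keys)) for (j in seq_along(keys)) {
    if (j <= i || sites[i] == sites[j]) next
    rows[[length(rows) + 1L]] <- interplay(table, keys[i], keys[j])
  }
  out <- do.call(rbind, rows)
  out[order(!out$defined, -abs(out$score)), , drop = FALSE]
}

#' Pearson correlation between paired replicate abundances
#'
#' Pearson's r with a two-tailed t-test on `t = r sqrt((n-2)/(1-r^2))`
#' (`n - 2` degrees of freedom).
#'
#' @param x,y Paired abundance vectors (same proteoforms, length >= 3).
#' @return List `r`, `p`, `n`, `defined`; `defined = FALSE` (with `NA`
#'   statistics) when either vector has zero variance.
#' @export
replicate_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       defined = TRUE)
}

#' Coefficient of variation of single-mark abundances across replicates
#'
#' @param tables List of >= 2 normalized quantification tables (one per
#'   replicate, same group).
#' @param keys Mark keys; default is every exact mark observed in any
#'   replicate.
#' @return Data frame `mark`, `mean`, `sd`, `cv`, `defined`; `cv` is
#'   `sd/mean`, flagged undefined when the mean is 0.
#' @export
cv_by_mark <- function(tables, keys = NULL) {
  if (length(tables) < 2L) stop("need at least 2 replicate tables")
  if (is.null(keys))
    keys <- sort(unique(unlist(lapply(tables,
                                      function(t) single_mark_table(t)$mark))))
  ab <- vapply(tables, function(t)
    vapply(keys, function(k) single_ptm_abundance(t, k), numeric(1)),
    numeric(length(keys)))
  ab <- matrix(ab, nrow = length(keys))
  mu <- rowMeans(ab)
  sdv <- apply(ab, 1L, stats::sd)
  data.frame(mark = keys, mean = mu, sd = sdv,
             cv = ifelse(mu > 0, sdv / mu, NA_real_),
             defined = mu > 0, row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare two single-mark abundance tables
#'
#' Least-squares slope through the origin plus Pearson correlation over the
#' shared marks, e.g. for middle-down versus bottom-up comparisons or
#' between time points.
#'
#' @param t1,t2 Single-mark tables (`mark`, `abundance`) sharing >= 3 keys.
#' @return List `slope`, `r`, `p`, `n`.
#' @export
compare_single_mark_tables <- function(t1, t2) {
  m <- merge(t1, t2, by = "mark", suffixes = c("_1", "_2"))
  if (nrow(m) < 3L) stop("fewer than 3 shared mark keys")
  x <- m$abundance_1; y <- m$abundance_2
  slope <- sum(x * y) / sum(x * x)
  ct <- stats::cor.test(x, y)
  list(slope = slope, r = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}
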