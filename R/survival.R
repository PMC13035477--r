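#' Bundled chemokine gene signatures
#'
#' The homeostatic signature covers the zonation-maintaining chemokines
#' (CXCL12, CXCL13, CCL19, CCL21); the inflammatory signature the
#' interferon-inducible CXCR3 ligands (CXCL9, CXCL10, CXCL11).
#'
#' @return Named list of character vectors.
#' @export
chemokine_signatures <- function() {
  list(homeostatic = c("CXCL12", "CXCL13", "CCL19", "CCL21"),
       inflammatory = c("CXCL9", "CXCL10", "CXCL11"))
}

#' Signature score per sample
#'
#' Arithmetic mean of the (normalized) expression of the signature genes in
#' each column of the matrix. Missing signature genes are dropped with a
#' warning; an error is raised when none are present.
#'
#' @param expr a [gene_expression()] object (columns are samples or cells).
#' @param genes character vector of signature genes.
#' @return Named numeric vector of per-column scores.
#' @export
signature_score <- function(expr, genes) {
  stopifnot(inherits(expr, "gexpr"))
  present <- intersect(genes, expr$gene_ids)
  if (!length(present))
    stop("no signature gene present in the expression matrix")
  if (length(present) < length(genes))
    warning("signature genes absent from matrix: ",
            paste(setdiff(genes, present), collapse = ", "))
  colMeans(expr$values[present, , drop = FALSE])
}

#' Classify clonotypes as expanded
#'
#' A clonotype is clonally expanded when observed in strictly more than
#' `threshold` cells.
#'
#' @param clone_sizes named integer vector of cells per clonotype.
#' @param threshold strict expansion threshold (default 7).
#' @return Named logical vector.
#' @export
classify_clonotypes <- function(clone_sizes, threshold = 7L) {
  if (any(clone_sizes < 1)) stop("clone sizes must be at least 1")
  clone_sizes > threshold
}

#' Regulon target enrichment
#'
#' Fisher's exact test for enrichment of differentially expressed genes
#' among the target genes of a regulon, over a fixed gene universe. The
#' reported odds ratio is the sample cross-product ratio (with a 0.5
#' continuity correction when any table cell is zero); the p-value is the
#' two-sided Fisher exact probability.
#'
#' @param target_genes,deg_set character vectors, subsets of `universe`.
#' @param universe character vector of all considered genes (at least 4).
#' @return A list with `odds_ratio`, `p`, and the 2x2 `table`.
#' @seealso [regulon_enrichment_batch()] for Bonferroni-adjusted batch
#'   testing across regulons.
#' @export
regulon_enrichment <- function(target_genes, deg_set, universe) {
  if (length(universe) < 4) stop("universe must contain at least 4 genes")
  if (length(setdiff(target_genes, universe)))
    stop("target_genes must be a subset of the universe")
  if (length(setdiff(deg_set, universe)))
    stop("deg_set must be a subset of the universe")
  in_t <- universe %in% target_genes
  in_d <- universe %in% deg_set
  a <- sum(in_t & in_d); b <- sum(in_t & !in_d)
  c_ <- sum(!in_t & in_d); d <- sum(!in_t & !in_d)
  tab <- c(a, b, c_, d)
  ctab <- if (any(tab == 0)) tab + 0.5 else tab
  list(odds_ratio = (ctab[1] * ctab[4]) / (ctab[2] * ctab[3]),
       p = fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
       table = matrix(tab, 2, byrow = TRUE,
                      dimnames = list(c("target", "non_target"),
                                      c("deg", "non_deg"))))
}

#' Batch regulon enrichment with Bonferroni adjustment
#'
#' @param target_sets named list of regulon target-gene sets.
#' @param deg_set,universe as in [regulon_enrichment()].
#' @return A data.frame (`regulon`, `odds_ratio`, `p`, `p_bonferroni`).
#' @export
regulon_enrichment_batch <- function(target_sets, deg_set, universe) {
  res <- lapply(names(target_sets), function(nm) {
    r <- regulon_enrichment(target_sets[[nm]], deg_set, universe)
    data.frame(regulon = nm, odds_ratio = r$odds_ratio, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

## log-rank (Nelson-Aalen residual) scores, with ties
logrank_scores <- function(time, event) {
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  n <- length(t_s)
  dt <- unique(t_s[e_s == 1])
  haz <- vapply(dt, function(tt)
    sum(e_s == 1 & t_s == tt) / sum(t_s >= tt), numeric(1))
  cumhaz_at <- function(tt) sum(haz[dt <= tt])
  a <- numeric(n)
  a[ord] <- e_s - vapply(t_s, cumhaz_at, numeric(1))
  a
}

#' Maximally selected rank statistic cutpoint
#'
#' Dichotomizes a continuous score for survival analysis: over candidate
#' cutpoints between the `min_group_fraction` and `1 - min_group_fraction`
#' quantiles of the score, the standardized log-rank statistic of the induced
#' two-group split is computed (log-rank scores are martingale residuals of
#' the pooled Nelson-Aalen estimator; the variance is the exact permutation
#' variance of a group sum). The cutpoint maximizing the absolute
#' standardized statistic is returned, with a selection-aware p-value from a
#' seeded permutation null of the maximal statistic and, separately, the
#' naive log-rank p-value of the selected split.
#'
#' @param tbl data.frame with columns `time`, `event`, `score` (at least 20
#'   subjects, 5 events, non-constant score).
#' @param min_group_fraction smallest allowed group fraction, in (0, 0.5)
#'   (default 0.1).
#' @param n_perm permutations for the selection-aware p (default 1000).
#' @param seed integer seed.
#' @return A list with `cutpoint`, `statistic` (maximal standardized
#'   statistic), `p_permutation`, `p_logrank_naive`, `group` (factor
#'   `high`/`low`, low meaning score at or below the cutpoint) and
#'   `candidates` (data.frame of cutpoints and statistics).
#' @export
maxstat_cutpoint <- function(tbl, min_group_fraction = 0.1,
                             n_perm = 1000L, seed = 1) {
  stopifnot(all(c("time", "event", "score") %in% names(tbl)))
  n <- nrow(tbl)
  if (n < 20) stop("need at least 20 subjects")
  if (sum(tbl$event) < 5) stop("need at least 5 events")
  if (length(unique(tbl$score)) < 2) stop("all scores are identical")
  if (min_group_fraction <= 0 || min_group_fraction >= 0.5)
    stop("min_group_fraction must lie in (0, 0.5)")

  a <- logrank_scores(tbl$time, tbl$event)
  ssq <- sum(a^2)           # sum(a) == 0 by construction
  ord <- order(tbl$score)
  a_ord <- a[ord]
  s_ord <- tbl$score[ord]
  qlo <- quantile(tbl$score, min_group_fraction, names = FALSE)
  qhi <- quantile(tbl$score, 1 - min_group_fraction, names = FALSE)
  ## candidate cutpoints: distinct score values in range, excluding the max
  cand_pos <- which(s_ord >= qlo & s_ord <= qhi &
                      s_ord < s_ord[n])
  cand_pos <- cand_pos[!duplicated(s_ord[cand_pos], fromLast = TRUE)]
  if (!length(cand_pos))
    stop("no candidate cutpoints inside the group-fraction bounds")

  std_stats <- function(a_sorted) {
    cs <- cumsum(a_sorted)[cand_pos]
    m <- cand_pos
    v <- m * (n - m) / (n * (n - 1)) * ssq
    z <- numeric(length(m))
    ok <- v > 0
    z[ok] <- cs[ok] / sqrt(v[ok])
    z
  }
  z <- std_stats(a_ord)
  best <- which.max(abs(z))
  cutpoint <- s_ord[cand_pos[best]]
  statistic <- abs(z[best])

  p_perm <- withr::with_seed(as.integer(seed), {
    if (ssq == 0) 1 else {
      exceed <- vapply(seq_len(n_perm), function(i)
        max(abs(std_stats(sample(a)))) >= statistic, logical(1))
      (1 + sum(exceed)) / (n_perm + 1)
    }
  })

  group <- factor(ifelse(tbl$score <= cutpoint, "low", "high"),
                  levels = c("high", "low"))
  p_naive <- tryCatch({
    sd_ <- survival::survdiff(survival::Surv(tbl$time, tbl$event) ~ group)
    pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  }, error = function(e) NA_real_)

  list(cutpoint = cutpoint, statistic = statistic,
       p_permutation = p_perm, p_logrank_naive = p_naive, group = group,
       candidates = data.frame(cutpoint = s_ord[cand_pos], statistic = z))
}

#' Kaplan-Meier curves and log-rank test for two groups
#'
#' Product-limit survival estimates per group plus the two-group log-rank
#' chi-square and p-value (standard tie handling via the hypergeometric
#' variance). A group without events is processed with a warning.
#'
#' @param tbl data.frame with columns `time`, `event`, `group` (two
#'   non-empty levels).
#' @return A list with `curves` (data.frame `group`, `time`, `n_risk`,
#'   `n_event`, `survival`), `chisq`, `p`, `fit` (the survfit object) and
#'   `median_by_group`.
#' @export
km_logrank <- function(tbl) {
  stopifnot(all(c("time", "event", "group") %in% names(tbl)))
  g <- factor(tbl$group)
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop("exactly two non-empty groups required")
  ev <- tapply(tbl$event, g, sum)
  if (any(ev == 0))
    warning("group(s) without events: ",
            paste(names(ev)[ev == 0], collapse = ", "))
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = tbl)
  sm <- summary(fit)
  strat <- if (is.null(sm$strata)) rep(levels(g)[1], length(sm$time))
           else sub("^g=", "", as.character(sm$strata))
  curves <- data.frame(group = strat, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, survival = sm$surv,
                       stringsAsFactors = FALSE)
  if (sum(ev) == 0) {
    chisq <- 0; p <- 1
  } else {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = tbl)
    chisq <- sd_$chisq
    p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  med <- summary(fit)$table
  med_by_group <- if (is.matrix(med)) setNames(med[, "median"],
                                               sub("^g=", "", rownames(med)))
                  else setNames(med["median"], levels(g)[1])
  list(curves = curves, chisq = chisq, p = p, fit = fit,
       median_by_group = med_by_group)
}
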