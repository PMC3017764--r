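CONTRASTS <- c("PvH", "PvS", "HvS")
contrast_pairs <- list(PvH = c("Polled", "Horned"),
                       PvS = c("Polled", "Scurred"),
                       HvS = c("Horned", "Scurred"))

#' Per-gene standardized phenotype contrasts
#'
#' For each gene, forms the three pairwise differences of phenotype-by-gene
#' BLUPs -- Polled-Horned (PvH), Polled-Scurred (PvS), Horned-Scurred
#' (HvS) -- and standardizes each by the square root of the prediction-error
#' variance of that difference (from the per-gene PEV blocks of the fit),
#' giving a t-like statistic per gene and contrast.
#'
#' @param fit A converged [dyeswap_mm()] fit, or a list with elements `hg`
#'   (genes x 3 matrix of profiles) and `pev_hg` (genes x 6 matrix of PEV
#'   blocks named pev11, pev22, pev33, pev12, pev13, pev23).
#' @return A `data.frame` with `gene_id`, `contrast`, `raw_diff` (log2),
#'   `se`, `statistic`.
#' @export
compute_contrasts <- function(fit) {
  hg <- fit$hg
  pev <- fit$pev_hg
  ph <- colnames(hg)
  idx <- function(a, b) {
    i <- match(a, ph); j <- match(b, ph)
    paste0("pev", min(i, j), max(i, j))
  }
  keep <- rowSums(is.na(hg)) == 0L
  if (any(!keep))
    message(sum(!keep), " gene(s) without a complete phenotype profile skipped")
  hg <- hg[keep, , drop = FALSE]
  pev <- pev[keep, , drop = FALSE]
  out <- lapply(CONTRASTS, function(cn) {
    pr <- contrast_pairs[[cn]]
    if (!all(pr %in% ph))
      stop("fit lacks phenotype(s) needed for contrast ", cn)
    d <- hg[, pr[1]] - hg[, pr[2]]
    v <- pev[, idx(pr[1], pr[1])] + pev[, idx(pr[2], pr[2])] -
      2 * pev[, idx(pr[1], pr[2])]
    se <- sqrt(pmax(v, 0))
    data.frame(gene_id = rownames(hg), contrast = cn,
               raw_diff = d, se = se, statistic = d / se,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  if (any(!is.finite(res$statistic)))
    stop("non-finite contrast statistic (zero prediction-error variance?)")
  res
}

#' Fit a two-component normal mixture by EM
#'
#' Models a vector of per-gene statistics as a mixture of a null and a
#' non-null normal component. After EM convergence, the component whose
#' mean is closest to zero (ties broken by the smaller variance) is
#' labelled the null; posterior probabilities of the non-null component are
#' returned. Initialisation splits the data at the 90th percentile of the
#' absolute statistic; additional random restarts guard against local
#' optima and degenerate (collapsing-variance) solutions.
#'
#' @param x Numeric vector of statistics; at least 50 values (a
#'   two-component mixture is not identifiable at toy sizes).
#' @param tol EM stops when the log-likelihood improves by less than this
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations per start (default 500).
#' @param n_starts Random restarts beyond the quantile-split start
#'   (default 5).
#' @param seed Seed for restart jitter.
#' @return An object of class `mixfit2`: component weights, means,
#'   variances (null first), `posterior_alt` per observation, the
#'   log-likelihood trace of the accepted start, and diagnostics.
#' @export
mixture_fit <- function(x, tol = 1e-8, max_iter = 500L, n_starts = 5L,
                        seed = 1L) {
  x <- x[is.finite(x)]
  if (length(x) < 50L)
    stop("need at least 50 statistics to fit a two-component mixture")
  n <- length(x)

  run_em <- function(par) {
    ll_trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- par$w1 * stats::dnorm(x, par$m1, sqrt(par$v1))
      d2 <- (1 - par$w1) * stats::dnorm(x, par$m2, sqrt(par$v2))
      tot <- d1 + d2
      if (any(tot <= 0) || any(!is.finite(tot))) return(NULL)
      ll <- sum(log(tot))
      ll_trace <- c(ll_trace, ll)
      g1 <- d1 / tot
      s1 <- sum(g1)
      if (s1 < 1e-8 || n - s1 < 1e-8) break
      par$w1 <- s1 / n
      par$m1 <- sum(g1 * x) / s1
      par$m2 <- sum((1 - g1) * x) / (n - s1)
      par$v1 <- sum(g1 * (x - par$m1)^2) / s1
      par$v2 <- sum((1 - g1) * (x - par$m2)^2) / (n - s1)
      if (par$v1 < 1e-8 || par$v2 < 1e-8) return(NULL)  # degenerate
      if (ll - ll_old < tol && it > 1L) break
      ll_old <- ll
    }
    list(par = par, ll = ll_trace[length(ll_trace)], ll_trace = ll_trace,
         iterations = length(ll_trace))
  }

  q90 <- stats::quantile(abs(x), 0.9, names = FALSE)
  lo <- x[abs(x) <= q90]
  hi <- x[abs(x) > q90]
  if (length(hi) < 2L) hi <- x[rank(-abs(x)) <= max(2L, n %/% 20L)]
  starts <- list(list(w1 = length(lo) / n, m1 = mean(lo),
                      v1 = max(stats::var(lo), 1e-4),
                      m2 = mean(hi), v2 = max(stats::var(hi), 1e-4)))
  starts <- c(starts, with_seed(seed, lapply(seq_len(n_starts), function(i) {
    m <- sample(x, 2)
    list(w1 = stats::runif(1, 0.5, 0.95), m1 = m[1],
         v1 = stats::var(x) * stats::runif(1, 0.1, 1),
         m2 = m[2], v2 = stats::var(x) * stats::runif(1, 0.1, 1))
  })))

  fits <- Filter(Negate(is.null), lapply(starts, run_em))
  if (!length(fits))
    stop("mixture EM failed on every start (degenerate components)")
  best <- fits[[which.max(vapply(fits, `[[`, 0, "ll"))]]
  par <- best$par

  # relabel: null = mean closest to zero, ties by smaller variance
  comps <- data.frame(w = c(par$w1, 1 - par$w1), m = c(par$m1, par$m2),
                      v = c(par$v1, par$v2))
  ordn <- order(abs(comps$m), comps$v)
  null_i <- ordn[1]
  alt_i <- ordn[2]
  d_null <- comps$w[null_i] * stats::dnorm(x, comps$m[null_i],
                                           sqrt(comps$v[null_i]))
  d_alt <- comps$w[alt_i] * stats::dnorm(x, comps$m[alt_i],
                                         sqrt(comps$v[alt_i]))
  structure(list(
    weight_null = comps$w[null_i], weight_alt = comps$w[alt_i],
    mean_null = comps$m[null_i], mean_alt = comps$m[alt_i],
    var_null = comps$v[null_i], var_alt = comps$v[alt_i],
    posterior_alt = d_alt / (d_null + d_alt),
    x = x,
    loglik = best$ll, ll_trace = best$ll_trace,
    iterations = best$iterations, n_starts_ok = length(fits)),
    class = "mixfit2")
}

#' @export
print.mixfit2 <- function(x, ...) {
  cat("Two-component normal mixture (EM)\n")
  cat(sprintf("  null: w = %.3f, mean = %.3f, var = %.3f\n",
              x$weight_null, x$mean_null, x$var_null))
  cat(sprintf("  alt : w = %.3f, mean = %.3f, var = %.3f\n",
              x$weight_alt, x$mean_alt, x$var_alt))
  cat(sprintf("  logL %.3f in %d iterations\n", x$loglik, x$iterations))
  invisible(x)
}

#' Signed fold change from a log2 difference
#'
#' Converts a log2 expression difference to a fold change using the
#' negated-reciprocal convention for down-regulation: `2^d` for `d >= 0`,
#' `-2^(-d)` otherwise, so a difference of -3 is reported as -8 rather
#' than 0.125.
#'
#' @param d Numeric vector of log2 differences.
#' @return Signed fold changes.
#' @export
fold_from_log2 <- function(d) {
  stopifnot(all(is.finite(d)))
  ifelse(d >= 0, 2^d, -(2^(-d)))
}

#' Call differentially expressed genes at a posterior-probability FDR
#'
#' Ranks genes by their posterior probability of the non-null component and
#' selects the largest top set whose estimated false discovery rate -- the
#' mean of (1 - posterior) over the selected genes -- stays below
#' `fdr_target`. An empty selection is a valid outcome, not an error.
#'
#' @param mix A [mixture_fit()] object.
#' @param stats The contrast table the mixture was fitted to (one row per
#'   gene, same order as the statistics passed to [mixture_fit()]), with
#'   `gene_id`, `contrast`, `raw_diff`, `statistic`.
#' @param fdr_target Target false discovery rate (default 0.01).
#' @return `stats` with `posterior`, `de_flag`, `log2_diff` and signed
#'   `fold_change` columns appended; attribute `fdr_est` holds the realised
#'   estimate over the selected set.
#' @export
call_de <- function(mix, stats, fdr_target = 0.01) {
  stopifnot(inherits(mix, "mixfit2"), nrow(stats) == length(mix$posterior_alt))
  post <- mix$posterior_alt
  ord <- order(post, decreasing = TRUE)
  cum_fdr <- cumsum(1 - post[ord]) / seq_along(ord)
  k <- which(cum_fdr < fdr_target)
  n_sel <- if (length(k)) max(k) else 0L
  sel <- rep(FALSE, length(post))
  if (n_sel > 0L) sel[ord[seq_len(n_sel)]] <- TRUE
  out <- stats
  out$posterior <- post
  out$de_flag <- sel
  out$log2_diff <- out$raw_diff
  out$fold_change <- fold_from_log2(out$raw_diff)
  attr(out, "fdr_est") <- if (n_sel > 0L) cum_fdr[n_sel] else NA_real_
  out
}

#' Run contrasts, mixture fits and DE calling over all three contrasts
#'
#' Convenience wrapper: computes the standardized contrasts from a fit,
#' fits one mixture per contrast (the three contrasts are processed
#' separately; set `pooled = TRUE` to fit a single mixture to all three)
#' and calls DE genes at the target FDR.
#'
#' @param fit A [dyeswap_mm()] fit.
#' @param fdr_target Target FDR (default 0.01).
#' @param pooled Fit one mixture across the pooled contrasts instead of one
#'   per contrast.
#' @param ... Passed to [mixture_fit()].
#' @return A `data.frame` of per-gene per-contrast results; attribute
#'   `mixtures` holds the fitted `mixfit2` objects.
#' @export
de_analysis <- function(fit, fdr_target = 0.01, pooled = FALSE, ...) {
  cs <- compute_contrasts(fit)
  if (pooled) {
    mix <- mixture_fit(cs$statistic, ...)
    res <- call_de(mix, cs, fdr_target)
    attr(res, "mixtures") <- list(pooled = mix)
    return(res)
  }
  parts <- lapply(CONTRASTS, function(cn) {
    sub <- cs[cs$contrast == cn, , drop = FALSE]
    mix <- mixture_fit(sub$statistic, ...)
    list(res = call_de(mix, sub, fdr_target), mix = mix)
  })
  res <- do.call(rbind, lapply(parts, `[[`, "res"))
  rownames(res) <- NULL
  attr(res, "mixtures") <- stats::setNames(lapply(parts, `[[`, "mix"),
                                           CONTRASTS)
  res
}

#' Summarise DE calls per contrast, pairwise overlap and chromosome
#'
#' @param results A DE results table from [de_analysis()] / [call_de()]
#'   (needs `gene_id`, `contrast`, `de_flag`).
#' @param chrom_map Optional named vector or two-column data.frame
#'   (`gene_id`, `chrom`) mapping genes to chromosomes; genes without an
#'   assignment are tallied as "unplaced".
#' @return A list with `per_contrast` counts, `overlap` (pairwise and
#'   triple intersection counts) and, when a map is supplied,
#'   `per_chromosome` counts per contrast.
#' @export
summarise_de <- function(results, chrom_map = NULL) {
  de_sets <- lapply(CONTRASTS, function(cn)
    unique(results$gene_id[results$contrast == cn & results$de_flag]))
  names(de_sets) <- CONTRASTS
  per_contrast <- vapply(de_sets, length, 1L)
  pairs <- utils::combn(CONTRASTS, 2)
  overlap <- apply(pairs, 2, function(p)
    length(intersect(de_sets[[p[1]]], de_sets[[p[2]]])))
  names(overlap) <- apply(pairs, 2, paste, collapse = "&")
  overlap <- c(overlap,
               "PvH&PvS&HvS" = length(Reduce(intersect, de_sets)))
  out <- list(per_contrast = per_contrast, overlap = overlap,
              total_genes = length(unique(unlist(de_sets))))
  if (!is.null(chrom_map)) {
    if (is.data.frame(chrom_map))
      chrom_map <- stats::setNames(as.character(chrom_map$chrom),
                                   chrom_map$gene_id)
    out$per_chromosome <- lapply(de_sets, function(g) {
      ch <- chrom_map[g]
      ch[is.na(ch)] <- "unplaced"
      table(ch)
    })
  }
  out
}
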