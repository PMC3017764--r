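#' Convert a delta-delta-Ct estimate to a signed fold change
#'
#' Fold change is `2^(-ddct)`; values below 1 (ddct > 0, i.e. lower
#' expression in the first-named phenotype) are reported as the negated
#' reciprocal, so e.g. a ddct of 4.47 cycles becomes about -22.2.
#'
#' @param ddct Numeric vector of delta-delta-Ct estimates (cycles).
#' @return Signed fold changes.
#' @export
ddct_to_fold <- function(ddct) {
  stopifnot(all(is.finite(ddct)))
  fold_from_log2(-ddct)
}

#' Estimate delta-delta-Ct for one contrast and target gene
#'
#' Fits the cell-mean generalised linear model
#' `Ct ~ phenotype + gene + phenotype:gene` by least squares on the
#' records of the two phenotypes of the contrast and the target plus
#' reference genes, and estimates delta-delta-Ct as the combinational-
#' effect contrast `CE1 - CE2 - CE3 + CE4` (first phenotype/target minus
#' second phenotype/target minus first phenotype/reference plus second
#' phenotype/reference of the fitted cell means). The standard error and a
#' two-sided p-value come from the t distribution of the linear-model
#' contrast. Technical replicates enter as observations by default; set
#' `average_replicates = TRUE` to collapse them to per-animal means first.
#'
#' A negative delta-delta-Ct means fewer cycles to threshold relative to the
#' reference in the first-named phenotype, i.e. higher expression there:
#' the fold change in the first-named phenotype is `2^(-ddct)`.
#'
#' @param records qPCR table (`animal_id`, `phenotype`, `gene`,
#'   `replicate`, `Ct`), e.g. from [simulate_qpcr()].
#' @param contrast One of `"PvH"`, `"PvS"`, `"HvS"`.
#' @param target,reference Gene labels of the target and reference gene.
#' @param average_replicates Average technical replicates per animal and
#'   gene before fitting.
#' @return An object of class `ddct_fit` (also a one-row data.frame):
#'   `contrast`, `target`, `ddct`, `se`, `p_value`, `fold`.
#' @export
ddct_fit <- function(records, contrast = c("PvH", "PvS", "HvS"),
                     target, reference = "GAPDH",
                     average_replicates = FALSE) {
  contrast <- match.arg(contrast)
  phens <- contrast_pairs[[contrast]]
  d <- records[records$phenotype %in% phens &
                 records$gene %in% c(target, reference), , drop = FALSE]
  cells <- expand.grid(phenotype = phens, gene = c(target, reference),
                       stringsAsFactors = FALSE)
  missing <- !paste(cells$phenotype, cells$gene) %in%
    paste(d$phenotype, d$gene)
  if (any(missing))
    stop("no Ct observations for cell(s): ",
         paste(sprintf("(%s, %s)", cells$phenotype[missing],
                       cells$gene[missing]), collapse = ", "))
  if (average_replicates) {
    d <- stats::aggregate(Ct ~ animal_id + phenotype + gene, data = d,
                          FUN = mean)
  }
  d$phenotype <- factor(d$phenotype, levels = phens)
  d$gene <- factor(d$gene, levels = c(target, reference))
  fit <- stats::lm(Ct ~ 0 + phenotype:gene, data = d)
  cf_names <- names(stats::coef(fit))
  cell_name <- function(ph, gn)
    cf_names[grepl(paste0("phenotype", ph), cf_names, fixed = TRUE) &
               grepl(paste0("gene", gn), cf_names, fixed = TRUE)]
  L <- stats::setNames(numeric(length(cf_names)), cf_names)
  L[cell_name(phens[1], target)] <- 1     # CE1
  L[cell_name(phens[2], target)] <- -1    # CE2
  L[cell_name(phens[1], reference)] <- -1 # CE3
  L[cell_name(phens[2], reference)] <- 1  # CE4
  est <- drop(L %*% stats::coef(fit))
  se <- drop(sqrt(L %*% stats::vcov(fit) %*% L))
  df <- fit$df.residual
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), df)
  out <- data.frame(contrast = contrast, target = target,
                    ddct = est, se = se, t = tval, df = df, p_value = p,
                    fold = ddct_to_fold(est),
                    stringsAsFactors = FALSE)
  class(out) <- c("ddct_fit", "data.frame")
  out
}

#' @export
print.ddct_fit <- function(x, ...) {
  cat(sprintf("ddCt GLM: %s, target %s\n", x$contrast, x$target))
  cat(sprintf("  ddCt = %.3f (se %.3f), t = %.2f on %d df, p = %.4g\n",
              x$ddct, x$se, x$t, x$df, x$p_value))
  cat(sprintf("  fold change = %.3g\n", x$fold))
  invisible(x)
}

#' Table of delta-delta-Ct estimates over contrasts and targets
#'
#' Runs [ddct_fit()] for every combination of the three phenotype contrasts
#' and the supplied target genes, producing a report shaped like a
#' validation table (contrast, gene, ddCt, s.e., p-value, fold change).
#'
#' @param records qPCR table.
#' @param targets Character vector of target gene names.
#' @param reference Reference gene name.
#' @param ... Passed to [ddct_fit()].
#' @return Data frame with one row per (contrast, target).
#' @export
ddct_table <- function(records, targets, reference = "GAPDH", ...) {
  rows <- lapply(CONTRASTS, function(cn)
    do.call(rbind, lapply(targets, function(tg)
      as.data.frame(ddct_fit(records, cn, tg, reference, ...)))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
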