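#' Build the model specification for the dye-swap mixed model
#'
#' Assembles the incidence structure of the normalization model
#' \deqn{y = \mu + C + G + AG + DG + HG + SG + e}
#' from quality-controlled spot data: a fixed comparison effect `C` with one
#' level per (chip, array, dye) channel, and random gene (`G`),
#' array-by-gene (`AG`), dye-by-gene (`DG`), phenotype-by-gene (`HG`) and
#' sex-by-gene (`SG`) effects, all i.i.d. normal and mutually independent.
#' Spots that failed QC are excluded as missing; genes left with no passing
#' observation are dropped (and listed in the returned object).
#'
#' Because every random term is indexed by gene, the mixed-model equations
#' decompose into one small block per gene coupled only through the fixed
#' channel effects; the specification pre-groups genes by their pattern of
#' observed channels so the fitter can solve all genes of a pattern at once.
#'
#' @param qc Output of [apply_qc()] (or any data frame with `probe_id`,
#'   `channel`, `array_id`, `dye`, `phenotype`, `sex`, `log2_intensity`,
#'   and optionally `passed`).
#' @param design The design table the spots were generated or measured
#'   under; defines the full set of channels, arrays, phenotypes and sexes.
#' @return An object of class `mm_spec`.
#' @export
build_model_spec <- function(qc, design) {
  stopifnot(is.data.frame(qc), is.data.frame(design))
  dat <- qc
  if ("passed" %in% names(dat)) dat <- dat[dat$passed, , drop = FALSE]
  dat <- dat[!is.na(dat$log2_intensity), , drop = FALSE]
  if (nrow(dat) == 0L) stop("no passing observations to model")

  channels <- sort(unique(design$channel))
  arrays <- sort(unique(design$array_id))
  dyes <- c("red", "green")
  phens <- intersect(PHENOTYPES, unique(design$phenotype))
  sexes <- sort(unique(design$sex))

  missing_ph <- setdiff(phens, unique(dat$phenotype))
  if (length(missing_ph))
    stop("phenotype(s) with no passing observations: ",
         paste(missing_ph, collapse = ", "),
         " (contrasts undefined)")

  chan_used <- sort(unique(dat$channel))
  chan_i <- match(dat$channel, chan_used)
  gene_levels <- sort(unique(dat$probe_id))
  gene_i <- match(dat$probe_id, gene_levels)

  n_arr <- length(arrays)
  n_dye <- 2L
  n_ph <- length(phens)
  n_sex <- length(sexes)
  q_per <- 1L + n_arr + n_dye + n_ph + n_sex

  # per-channel incidence into the per-gene random-effect block
  ch_design <- design[match(chan_used, design$channel), ]
  z_of_channel <- cbind(
    1L,
    1L + match(ch_design$array_id, arrays),
    1L + n_arr + match(ch_design$dye, dyes),
    1L + n_arr + n_dye + match(ch_design$phenotype, phens),
    1L + n_arr + n_dye + n_ph + match(ch_design$sex, sexes))

  type_cols <- list(
    g = 1L,
    ag = 1L + seq_len(n_arr),
    dg = 1L + n_arr + seq_len(n_dye),
    hg = 1L + n_arr + n_dye + seq_len(n_ph),
    sg = 1L + n_arr + n_dye + n_ph + seq_len(n_sex))

  ord <- order(gene_i, chan_i)
  gene_i <- gene_i[ord]
  chan_i <- chan_i[ord]
  y <- dat$log2_intensity[ord]

  # group genes by their multiset of observed channels
  chan_by_gene <- split(chan_i, gene_i)
  keys <- vapply(chan_by_gene, function(v) paste(v, collapse = ","), "")
  pat_of_gene <- match(keys, unique(keys))
  y_by_gene <- split(y, gene_i)

  n_ch <- length(chan_used)
  patterns <- lapply(seq_along(unique(keys)), function(p) {
    g_idx <- which(pat_of_gene == p)
    chans <- chan_by_gene[[g_idx[1L]]]
    Zc <- matrix(0, nrow = length(chans), ncol = q_per)
    for (i in seq_along(chans)) Zc[i, z_of_channel[chans[i], ]] <- 1
    Tmat <- matrix(0, nrow = n_ch, ncol = q_per)
    agg <- rowsum(Zc, chans)
    Tmat[as.integer(rownames(agg)), ] <- agg
    Y <- matrix(unlist(y_by_gene[g_idx], use.names = FALSE),
                nrow = length(chans))
    list(genes = g_idx, chans = chans, Zc = Zc, ZtZ = crossprod(Zc),
         Tmat = Tmat, Y = Y)
  })

  dropped <- setdiff(unique(qc$probe_id), gene_levels)
  if (length(dropped))
    message(length(dropped), " gene(s) with no passing observation dropped")

  structure(list(
    patterns = patterns, channels = chan_used, genes = gene_levels,
    arrays = arrays, dyes = dyes, phenotypes = phens, sexes = sexes,
    q_per = q_per, type_cols = type_cols,
    n_obs = length(y), n_ch = n_ch,
    xtx = as.numeric(tabulate(chan_i, nbins = n_ch)),
    xty = as.numeric(rowsum(y, chan_i, reorder = TRUE)),
    yty = sum(y^2), dropped = dropped),
    class = "mm_spec")
}

#' @export
print.mm_spec <- function(x, ...) {
  cat("Dye-swap mixed-model specification\n")
  cat(sprintf("  observations : %d\n", x$n_obs))
  cat(sprintf("  C (channel) levels : %d\n", x$n_ch))
  cat(sprintf("  genes : %d  (random blocks of %d effects each)\n",
              length(x$genes), x$q_per))
  cat(sprintf("  phenotypes : %s\n", paste(x$phenotypes, collapse = ", ")))
  invisible(x)
}

# One pass of the mixed-model equations at variance components `vc`
# (named g, ag, dg, hg, sg, e). Returns solutions, quadratic forms,
# per-component PEV traces and the REML log-likelihood (up to a constant).
mm_engine <- function(spec, vc, want_pev = FALSE) {
  types <- c("g", "ag", "dg", "hg", "sg")
  sig_e <- vc[["e"]]
  lambda <- numeric(spec$q_per)
  for (k in types) lambda[spec$type_cols[[k]]] <- sig_e / vc[[k]]

  n_ch <- spec$n_ch
  S <- diag(spec$xtx, n_ch)
  rhs <- spec$xty
  logdetA <- 0
  pats <- vector("list", length(spec$patterns))
  for (pi in seq_along(spec$patterns)) {
    p <- spec$patterns[[pi]]
    A <- p$ZtZ + diag(lambda, spec$q_per)
    ch <- chol(A)
    Ainv <- chol2inv(ch)
    TAinv <- p$Tmat %*% Ainv
    n_pat <- length(p$genes)
    S <- S - n_pat * tcrossprod(TAinv, p$Tmat)
    R <- crossprod(p$Zc, p$Y)
    rhs <- rhs - TAinv %*% rowSums(R)
    logdetA <- logdetA + n_pat * 2 * sum(log(diag(ch)))
    pats[[pi]] <- list(Ainv = Ainv, TAinv = TAinv, R = R)
  }
  Sch <- chol(S)
  Sinv <- chol2inv(Sch)
  b <- drop(Sinv %*% rhs)
  logdetS <- 2 * sum(log(diag(Sch)))

  usq <- numeric(spec$q_per)
  trpev_col <- numeric(spec$q_per)
  ee <- 0
  ye <- 0
  Ulist <- vector("list", length(spec$patterns))
  Elist <- vector("list", length(spec$patterns))
  pev_hg <- if (want_pev) vector("list", length(spec$patterns)) else NULL
  hg_cols <- spec$type_cols$hg
  for (pi in seq_along(spec$patterns)) {
    p <- spec$patterns[[pi]]
    st <- pats[[pi]]
    n_pat <- length(p$genes)
    tb <- drop(crossprod(p$Tmat, b))
    U <- st$Ainv %*% st$R - drop(st$Ainv %*% tb)
    Fit <- b[p$chans] + p$Zc %*% U
    E <- p$Y - Fit
    usq <- usq + rowSums(U^2)
    ee <- ee + sum(E^2)
    ye <- ye + sum(p$Y * E)
    SW <- Sinv %*% st$TAinv
    corr <- colSums(st$TAinv * SW)
    trpev_col <- trpev_col + n_pat * sig_e * (diag(st$Ainv) + corr)
    if (want_pev) {
      full <- sig_e * (st$Ainv[hg_cols, hg_cols, drop = FALSE] +
                         crossprod(st$TAinv[, hg_cols, drop = FALSE],
                                   SW[, hg_cols, drop = FALSE]))
      pev_hg[[pi]] <- full
    }
    Ulist[[pi]] <- U
    Elist[[pi]] <- E
  }

  n <- spec$n_obs
  p_fix <- n_ch
  n_gene <- length(spec$genes)
  q_k <- vapply(spec$type_cols, length, 1L) * n_gene
  q_tot <- sum(q_k)
  usq_k <- vapply(types, function(k) sum(usq[spec$type_cols[[k]]]), 0)
  trpev_k <- vapply(types, function(k) sum(trpev_col[spec$type_cols[[k]]]), 0)

  sig_k <- unlist(vc[types])
  logLR <- -0.5 * ((n - p_fix - q_tot) * log(sig_e) +
                     sum(q_k[types] * log(sig_k)) +
                     logdetA + logdetS + ye / sig_e)

  list(vc = vc, b = b, Ulist = Ulist, Elist = Elist, pats = pats,
       Sinv = Sinv, usq_k = usq_k, trpev_k = trpev_k, ee = ee, ye = ye,
       q_k = q_k[types], q_tot = q_tot, n = n, p_fix = p_fix,
       logLR = logLR, pev_hg = pev_hg)
}

# Solve the mixed-model equations for an arbitrary response laid out in the
# per-pattern shape of `spec`, reusing the factorisations in `state`.
# Returns the projection P v = (v - X b_v - Z u_v) / sig_e for each column.
mm_apply_P <- function(spec, state, Vlist) {
  sig_e <- state$vc[["e"]]
  rhs <- numeric(spec$n_ch)
  Rs <- vector("list", length(spec$patterns))
  for (pi in seq_along(spec$patterns)) {
    p <- spec$patterns[[pi]]
    st <- state$pats[[pi]]
    V <- Vlist[[pi]]
    agg <- rowsum(V, p$chans)
    add <- numeric(spec$n_ch)
    add[as.integer(rownames(agg))] <- rowSums(agg)
    R <- crossprod(p$Zc, V)
    rhs <- rhs + add - st$TAinv %*% rowSums(R)
    Rs[[pi]] <- R
  }
  b_v <- drop(state$Sinv %*% rhs)
  out <- vector("list", length(spec$patterns))
  for (pi in seq_along(spec$patterns)) {
    p <- spec$patterns[[pi]]
    st <- state$pats[[pi]]
    tb <- drop(crossprod(p$Tmat, b_v))
    U <- st$Ainv %*% Rs[[pi]] - drop(st$Ainv %*% tb)
    out[[pi]] <- (Vlist[[pi]] - b_v[p$chans] - p$Zc %*% U) / sig_e
  }
  out
}

mm_em_update <- function(state) {
  types <- c("g", "ag", "dg", "hg", "sg")
  vc <- state$vc
  for (i in seq_along(types)) {
    k <- types[i]
    vc[[k]] <- max((state$usq_k[[k]] + state$trpev_k[[k]]) / state$q_k[[k]],
                   1e-10)
  }
  vc[["e"]] <- max(state$ye / (state$n - state$p_fix), 1e-10)
  vc
}

mm_gradient <- function(state) {
  types <- c("g", "ag", "dg", "hg", "sg")
  vc <- state$vc
  g <- numeric(6)
  for (i in seq_along(types)) {
    k <- types[i]
    sk <- vc[[k]]
    g[i] <- -0.5 * ((state$q_k[[k]] - state$trpev_k[[k]] / sk) / sk -
                      state$usq_k[[k]] / sk^2)
  }
  se <- vc[["e"]]
  tr_p <- (state$n - state$p_fix - state$q_tot +
             sum(unlist(state$trpev_k) / unlist(vc[types]))) / se
  g[6] <- -0.5 * (tr_p - state$ee / se^2)
  g
}

# Average-information matrix: AI_ij = 0.5 f_i' P f_j with
# f_k = Z_k u_k / sig_k and f_e = e / sig_e.
mm_ai_matrix <- function(spec, state) {
  types <- c("g", "ag", "dg", "hg", "sg")
  vc <- state$vc
  n_f <- 6L
  Fl <- lapply(seq_along(spec$patterns), function(pi) {
    p <- spec$patterns[[pi]]
    U <- state$Ulist[[pi]]
    cols <- lapply(seq_along(types), function(i) {
      k <- types[i]
      sel <- p$Zc[, spec$type_cols[[k]], drop = FALSE] %*%
        U[spec$type_cols[[k]], , drop = FALSE]
      sel / vc[[k]]
    })
    cols[[n_f]] <- state$Elist[[pi]] / vc[["e"]]
    cols
  })
  AI <- matrix(0, n_f, n_f)
  PFl <- vector("list", n_f)
  for (j in seq_len(n_f)) {
    Vj <- lapply(Fl, `[[`, j)
    PFl[[j]] <- mm_apply_P(spec, state, Vj)
  }
  for (i in seq_len(n_f)) {
    for (j in i:n_f) {
      acc <- 0
      for (pi in seq_along(spec$patterns))
        acc <- acc + sum(Fl[[pi]][[i]] * PFl[[j]][[pi]])
      AI[i, j] <- AI[j, i] <- 0.5 * acc
    }
  }
  AI
}

#' Fit the dye-swap normalization mixed model by REML
#'
#' Estimates the six variance components of the model
#' `y = mu + C + G + AG + DG + HG + SG + e` by restricted maximum
#' likelihood and returns BLUP solutions for all random effects at the
#' converged variances. Each iteration computes the expectation-maximisation
#' (EM) update and, from the second iteration on, an average-information
#' (AI) Newton step; the AI candidate is accepted only when its restricted
#' log-likelihood is at least that of the EM candidate, so the criterion is
#' non-decreasing across accepted iterations. Variance updates are bounded
#' below at 1e-10 (a component pinned there is reported as a boundary
#' estimate).
#'
#' The solver exploits the gene-block structure of the model: all random
#' terms are gene-indexed, so the mixed-model equations reduce to one small
#' symmetric block per gene coupled through the fixed channel effects, which
#' are absorbed by a Schur complement. Prediction-error variances of the
#' phenotype-by-gene solutions are exact block inverses under this
#' structure.
#'
#' @param qc QC-ed spot data (see [build_model_spec()]), or an `mm_spec`.
#' @param design Design table (ignored when `qc` is already an `mm_spec`).
#' @param tol Convergence tolerance on the relative change of every
#'   variance component (default 1e-6); iteration also stops when the REML
#'   log-likelihood changes by less than 1e-8.
#' @param max_iter Maximum number of iterations (default 200).
#' @param init Optional named list/vector of starting values
#'   (`g`, `ag`, `dg`, `hg`, `sg`, `e`).
#' @param use_ai Use average-information acceleration (default TRUE);
#'   `FALSE` gives plain EM-REML.
#' @param fix_vc Optional named list of variance components to hold fixed at
#'   supplied values (no iteration for them; useful for solving the
#'   mixed-model equations at known truth).
#' @param verbose Print the iteration trace.
#' @return An object of class `dyeswap_mm`: variance components, fixed
#'   channel solutions, per-gene phenotype (HG) BLUPs with their
#'   prediction-error variance blocks, convergence diagnostics and the
#'   model specification.
#' @export
dyeswap_mm <- function(qc, design = NULL, tol = 1e-6, max_iter = 200L,
                       init = NULL, use_ai = TRUE, fix_vc = NULL,
                       verbose = FALSE) {
  spec <- if (inherits(qc, "mm_spec")) qc else build_model_spec(qc, design)
  types <- c("g", "ag", "dg", "hg", "sg", "e")

  vtot <- (spec$yty - sum(spec$xty^2 / pmax(spec$xtx, 1))) /
    max(spec$n_obs - spec$n_ch, 1)
  vc <- as.list(stats::setNames(c(rep(vtot / 2, 5), vtot / 2), types))
  if (!is.null(init)) vc[names(init)] <- init
  fixed_names <- character(0)
  if (!is.null(fix_vc)) {
    vc[names(fix_vc)] <- fix_vc
    fixed_names <- names(fix_vc)
  }
  free <- setdiff(types, fixed_names)

  state <- mm_engine(spec, vc)
  trace <- data.frame(iter = 0L, logLR = state$logLR, step = "init",
                      stringsAsFactors = FALSE)
  converged <- FALSE
  iter <- 0L
  step_used <- "init"
  while (iter < max_iter && length(free) > 0L) {
    iter <- iter + 1L
    vc_em <- mm_em_update(state)
    vc_em[fixed_names] <- vc[fixed_names]
    st_em <- mm_engine(spec, vc_em)
    cand <- list(vc = vc_em, st = st_em, step = "EM")
    if (use_ai && iter >= 2L) {
      ai_try <- tryCatch({
        grad <- mm_gradient(state)
        AI <- mm_ai_matrix(spec, state)
        idx <- match(free, types)
        delta <- solve(AI[idx, idx, drop = FALSE], grad[idx])
        vc_ai <- vc
        for (i in seq_along(free))
          vc_ai[[free[i]]] <- max(vc[[free[i]]] + delta[i], 1e-10)
        st_ai <- mm_engine(spec, vc_ai)
        if (is.finite(st_ai$logLR) && st_ai$logLR >= st_em$logLR)
          list(vc = vc_ai, st = st_ai, step = "AI") else NULL
      }, error = function(e) NULL)
      if (!is.null(ai_try)) cand <- ai_try
    }
    old_vc <- unlist(vc[free])
    old_ll <- state$logLR
    vc <- cand$vc
    state <- cand$st
    step_used <- cand$step
    trace <- rbind(trace, data.frame(iter = iter, logLR = state$logLR,
                                     step = step_used,
                                     stringsAsFactors = FALSE))
    if (verbose)
      cat(sprintf("iter %3d [%s] logLR %.6f  vc: %s\n", iter, step_used,
                  state$logLR,
                  paste(sprintf("%.4g", unlist(vc)), collapse = " ")))
    rel <- abs(unlist(vc[free]) - old_vc) / pmax(abs(old_vc), 1e-8)
    if (max(rel) < tol || abs(state$logLR - old_ll) < 1e-8) {
      converged <- TRUE
      break
    }
  }
  if (length(free) == 0L) converged <- TRUE

  final <- mm_engine(spec, vc, want_pev = TRUE)

  n_gene <- length(spec$genes)
  hg_cols <- spec$type_cols$hg
  n_ph <- length(spec$phenotypes)
  hg <- matrix(NA_real_, n_gene, n_ph,
               dimnames = list(spec$genes, spec$phenotypes))
  g_blup <- stats::setNames(numeric(n_gene), spec$genes)
  pev_names <- c(outer(seq_len(n_ph), seq_len(n_ph), function(i, j)
    paste0("pev", i, j))[upper.tri(diag(n_ph), diag = TRUE)])
  pev <- matrix(NA_real_, n_gene, length(pev_names),
                dimnames = list(spec$genes, pev_names))
  ut <- upper.tri(diag(n_ph), diag = TRUE)
  for (pi in seq_along(spec$patterns)) {
    p <- spec$patterns[[pi]]
    U <- final$Ulist[[pi]]
    hg[p$genes, ] <- t(U[hg_cols, , drop = FALSE])
    g_blup[p$genes] <- U[1L, ]
    pev[p$genes, ] <- rep(final$pev_hg[[pi]][ut], each = length(p$genes))
  }

  mu <- mean(final$b)
  boundary <- types[unlist(vc[types]) <= 1.5e-10]

  structure(list(
    variances = unlist(vc[types]),
    mu = mu,
    channel_effects = stats::setNames(final$b - mu,
                                      paste0("C", spec$channels)),
    hg = hg, g = g_blup, pev_hg = pev,
    phenotypes = spec$phenotypes,
    logLR = final$logLR,
    converged = converged, iterations = iter,
    last_step = step_used, boundary = boundary,
    trace = trace, spec = spec, state = final),
    class = "dyeswap_mm")
}

#' @export
print.dyeswap_mm <- function(x, ...) {
  cat("Dye-swap mixed model (REML)\n")
  cat(sprintf("  %d observations, %d genes, %d channels\n",
              x$spec$n_obs, length(x$spec$genes), x$spec$n_ch))
  cat("  variance components:\n")
  print(round(x$variances, 5))
  cat(sprintf("  REML logL %.4f after %d iterations (%s)\n", x$logLR,
              x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$boundary))
    cat("  boundary (pinned near zero):",
        paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.dyeswap_mm <- function(object, ...) {
  out <- list(variances = object$variances, mu = object$mu,
              converged = object$converged,
              iterations = object$iterations,
              n_genes = length(object$spec$genes),
              profile_sd = apply(object$hg, 2, stats::sd),
              boundary = object$boundary)
  class(out) <- "summary.dyeswap_mm"
  out
}

#' @export
print.summary.dyeswap_mm <- function(x, ...) {
  cat("Dye-swap mixed model summary\n")
  cat(sprintf("  overall mean (mu): %.4f\n", x$mu))
  cat("  variance components:\n")
  print(round(x$variances, 5))
  cat("  SD of phenotype-by-gene solutions:\n")
  print(round(x$profile_sd, 4))
  cat(sprintf("  %d genes; %s in %d iterations\n", x$n_genes,
              if (x$converged) "converged" else "not converged",
              x$iterations))
  invisible(x)
}

#' @export
coef.dyeswap_mm <- function(object, ...) {
  list(mu = object$mu, channel = object$channel_effects,
       variances = object$variances)
}

#' @export
fitted.dyeswap_mm <- function(object, ...) {
  spec <- object$spec
  b <- object$state$b
  # reconstruct in the (gene, channel) observation order used by the spec
  vals <- lapply(seq_along(spec$patterns), function(pi) {
    p <- spec$patterns[[pi]]
    Fit <- b[p$chans] + p$Zc %*% object$state$Ulist[[pi]]
    list(genes = p$genes, fit = Fit)
  })
  res <- vector("list", length(spec$genes))
  for (v in vals)
    for (j in seq_along(v$genes)) res[[v$genes[j]]] <- v$fit[, j]
  unlist(res)
}

#' @export
residuals.dyeswap_mm <- function(object, ...) {
  spec <- object$spec
  res <- vector("list", length(spec$genes))
  for (pi in seq_along(spec$patterns)) {
    p <- spec$patterns[[pi]]
    E <- object$state$Elist[[pi]]
    for (j in seq_along(p$genes)) res[[p$genes[j]]] <- E[, j]
  }
  unlist(res)
}

#' Per-gene normalized expression profiles by phenotype
#'
#' Returns the phenotype-by-gene BLUP solutions of a converged fit: for each
#' gene, its normalized expression deviation (log2 scale) in each horn
#' phenotype. These are the quantities the downstream contrasts are built
#' from.
#'
#' @param fit A [dyeswap_mm()] fit.
#' @return Numeric matrix, genes x phenotypes.
#' @export
extract_phenotype_profiles <- function(fit) {
  stopifnot(inherits(fit, "dyeswap_mm"))
  fit$hg
}
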