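# Independent brute-force oracles used across the suite. These deliberately
# re-derive results through naive per-element loops and dense linear algebra,
# sharing no code with the package internals they check.

# Per-spot QC decision, one spot at a time.
oracle_qc_one <- function(fg_mean, fg_median, bg_mean, bg_sd,
                          snr = 1, rthr = 0.85) {
  corrected <- fg_mean - bg_mean
  if (bg_sd <= 0) return(FALSE)
  s <- corrected / bg_sd
  if (fg_mean <= 0 || fg_median <= 0) return(FALSE)
  r <- min(fg_mean, fg_median) / max(fg_mean, fg_median)
  s > snr && r >= rthr && corrected > 0
}

# Dense generalized-least-squares solve of the mixed model at known
# variance components. Builds full X, Z and V and solves directly.
oracle_gls <- function(qc, design, vc) {
  d <- qc[qc$passed, ]
  channels <- sort(unique(d$channel))
  genes <- sort(unique(d$probe_id))
  arrays <- sort(unique(design$array_id))
  dyes <- c("red", "green")
  phens <- intersect(c("Polled", "Horned", "Scurred"), design$phenotype)
  sexes <- sort(unique(design$sex))
  n <- nrow(d)
  X <- matrix(0, n, length(channels))
  X[cbind(seq_len(n), match(d$channel, channels))] <- 1

  blocks <- list(g = genes,
                 ag = as.vector(outer(arrays, genes, paste)),
                 dg = as.vector(outer(dyes, genes, paste)),
                 hg = as.vector(outer(phens, genes, paste)),
                 sg = as.vector(outer(sexes, genes, paste)))
  Zs <- list(
    g = outer(d$probe_id, genes, "=="),
    ag = outer(paste(d$array_id, d$probe_id), blocks$ag, "=="),
    dg = outer(paste(d$dye, d$probe_id), blocks$dg, "=="),
    hg = outer(paste(d$phenotype, d$probe_id), blocks$hg, "=="),
    sg = outer(paste(d$sex, d$probe_id), blocks$sg, "=="))
  Z <- do.call(cbind, lapply(Zs, function(m) m * 1))
  gdiag <- c(rep(vc[["g"]], length(blocks$g)),
             rep(vc[["ag"]], length(blocks$ag)),
             rep(vc[["dg"]], length(blocks$dg)),
             rep(vc[["hg"]], length(blocks$hg)),
             rep(vc[["sg"]], length(blocks$sg)))
  V <- Z %*% (gdiag * t(Z)) + diag(vc[["e"]], n)
  Vi <- solve(V)
  y <- d$log2_intensity
  XtVi <- t(X) %*% Vi
  bc <- solve(XtVi %*% X, XtVi %*% y)
  u <- gdiag * drop(t(Z) %*% (Vi %*% (y - X %*% bc)))
  P <- Vi - t(XtVi) %*% solve(XtVi %*% X, XtVi)
  G <- diag(gdiag)
  pev <- G - G %*% t(Z) %*% P %*% Z %*% G
  names(u) <- unlist(blocks)
  list(b = drop(bc), u = u, blocks = blocks, pev = pev,
       genes = genes, phens = phens)
}

# Naive annotation of one probe by literal rule enumeration.
oracle_annotate_one <- function(probe, genes, blast) {
  span_of <- function(g) {
    sp <- lapply(split(g, g$gene_name), function(x)
      c(start = min(x$start), end = max(x$end)))
    sp
  }
  ov_kind <- function(g) {
    # g: exon rows of genes on probe chromosome for one species
    res <- list()
    for (nm in unique(g$gene_name)) {
      ex <- g[g$gene_name == nm, ]
      sp_s <- min(ex$start); sp_e <- max(ex$end)
      if (probe$start < sp_e && probe$end > sp_s) {
        exon_hit <- any(probe$start < ex$end & probe$end > ex$start)
        res[[nm]] <- list(name = nm, acc = ex$accession[1],
                          kind = if (exon_hit) "exon" else "intron")
      }
    }
    res
  }
  acc_num <- function(a) as.numeric(gsub("[^0-9]", "", a))
  lowest <- function(items) {
    accs <- vapply(items, function(i) i$acc, "")
    pref <- gsub("[0-9.]+$", "", accs)
    o <- order(pref, vapply(accs, acc_num, 0))
    items[[o[1]]]
  }
  bov <- ov_kind(genes[genes$species == "bovine" &
                         genes$chrom == probe$chrom, ])
  hum <- ov_kind(genes[genes$species == "human" &
                         genes$chrom == probe$chrom, ])
  bov_ex <- Filter(function(i) i$kind == "exon" &&
                     !grepl("^(LOC|MGC)", i$name), bov)
  name <- NA_character_; step <- "unassigned"
  if (length(bov_ex)) {
    name <- lowest(bov_ex)$name; step <- "1"
  } else if (length(hum)) {
    name <- lowest(hum)$name; step <- "2"
  } else {
    g <- genes[genes$chrom == probe$chrom, ]
    if (nrow(g)) {
      sp <- lapply(split(g, g$gene_name), function(x)
        list(name = x$gene_name[1], acc = x$accession[1],
             s = min(x$start), e = max(x$end)))
      # half-open gap convention: adjacent intervals have distance 0
      dist <- vapply(sp, function(x) {
        if (probe$start < x$e && probe$end > x$s) return(0)
        if (x$e <= probe$start) return(probe$start - x$e)
        x$s - probe$end
      }, 0)
      cand <- sp[dist == min(dist)]
      name <- lowest(cand)$name; step <- "3"
    }
  }
  flagged <- FALSE
  bh <- blast[blast$probe_id == probe$probe_id, ]
  if (nrow(bh) && step %in% c("1", "2")) {
    best <- bh[which.max(bh$bitscore), ]
    if (!is.na(name) && best$gene_name != name) flagged <- TRUE
  }
  list(name = name, step = step, flagged = flagged)
}

# Small clean simulated dataset shared by model tests.
tiny_fit_data <- function(n_probes = 40, seed = 99, ...) {
  cfg <- sim_config(n_probes = n_probes, bad_spot_fraction = 0,
                    de_fraction = 0, seed = seed, ...)
  des <- simulate_design(cfg)
  sim <- simulate_spots(des, cfg)
  list(cfg = cfg, design = des, qc = apply_qc(sim$spots),
       truth = sim$truth)
}
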