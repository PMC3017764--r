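#' Simulation configuration for a dye-swap microarray experiment
#'
#' Builds the configuration object that drives [simulate_design()] and
#' [simulate_spots()]. The defaults emulate a four-chip, four-array-per-chip,
#' two-dye experiment on eleven animals spanning three horn phenotypes
#' (Polled, Horned, Scurred) and two sexes, with spot-level background
#' statistics that exercise both quality filters.
#'
#' The six variance components parameterise the random terms of the
#' normalization model fitted by [dyeswap_mm()]: gene (`var_g`),
#' array-by-gene (`var_ag`), dye-by-gene (`var_dg`), phenotype-by-gene
#' (`var_hg`), sex-by-gene (`var_sg`) and residual (`var_e`), all on the
#' squared log2-intensity scale.
#'
#' @param n_chips Number of chips (slides). Default 4.
#' @param n_arrays_per_chip Number of arrays per chip. Default 4.
#' @param n_probes Number of probes simulated. Default 2000.
#' @param mu Overall mean log2 intensity. Default 7.4.
#' @param var_g,var_ag,var_dg,var_hg,var_sg,var_e Variance components
#'   (log2-intensity squared). Defaults 12, 0.8, 0.4, 0.02, 0.02, 0.4: a
#'   gene-dominated profile whose total SD (about 3.7) sits between the
#'   channel SDs typical of background-corrected two-colour data, with
#'   phenotype- and sex-by-gene background variation kept small so that
#'   planted phenotype effects of `de_effect_size` log2 units are
#'   recoverable at a 1 percent posterior-probability FDR at the default
#'   problem size.
#' @param de_fraction Proportion of probes with a planted phenotype effect.
#'   Default 0.03.
#' @param de_effect_size Planted log2 shift for differentially expressed
#'   probes. Default 1.5.
#' @param background_mean Mean background intensity (linear scale). Default 60.
#' @param background_sd_scale Multiplier on the background pixel SD of clean
#'   spots; at the default 1 all clean spots pass the signal-to-noise filter.
#' @param bad_spot_fraction Proportion of spots engineered to fail quality
#'   control (half by inflated background SD, half by mean/median
#'   disagreement). Default 0.1, i.e. roughly 90 percent of spots usable.
#' @param seed Integer seed used by the generators unless overridden.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chips = 4L, n_arrays_per_chip = 4L, n_probes = 2000L,
                       mu = 7.4,
                       var_g = 12, var_ag = 0.8, var_dg = 0.4,
                       var_hg = 0.02, var_sg = 0.02, var_e = 0.4,
                       de_fraction = 0.03, de_effect_size = 1.5,
                       background_mean = 60, background_sd_scale = 1,
                       bad_spot_fraction = 0.1, seed = 1L) {
  cfg <- list(n_chips = as.integer(n_chips),
              n_arrays_per_chip = as.integer(n_arrays_per_chip),
              n_dyes = 2L, n_probes = as.integer(n_probes),
              n_phenotypes = 3L, n_sexes = 2L,
              mu = mu,
              var_g = var_g, var_ag = var_ag, var_dg = var_dg,
              var_hg = var_hg, var_sg = var_sg, var_e = var_e,
              de_fraction = de_fraction, de_effect_size = de_effect_size,
              background_mean = background_mean,
              background_sd_scale = background_sd_scale,
              bad_spot_fraction = bad_spot_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  vars <- c("var_g", "var_ag", "var_dg", "var_hg", "var_sg", "var_e")
  if (any(unlist(cfg[vars]) < 0))
    stop("all variance components must be >= 0")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("de_fraction must lie in [0, 1]")
  if (cfg$bad_spot_fraction < 0 || cfg$bad_spot_fraction > 1)
    stop("bad_spot_fraction must lie in [0, 1]")
  if (cfg$n_dyes != 2L) stop("the design is two-colour: n_dyes must be 2")
  if (cfg$n_phenotypes != 3L) stop("n_phenotypes is fixed at 3")
  if (cfg$n_chips < 1L || cfg$n_arrays_per_chip < 1L)
    stop("need at least one chip and one array per chip")
  if (cfg$n_probes < 1L) stop("n_probes must be positive")
  if (cfg$background_mean <= 0) stop("background_mean must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Dye-swap simulation configuration\n")
  cat(sprintf("  design : %d chips x %d arrays x 2 dyes (%d channels)\n",
              x$n_chips, x$n_arrays_per_chip,
              x$n_chips * x$n_arrays_per_chip * 2L))
  cat(sprintf("  probes : %d (DE fraction %.3g at %.3g log2)\n",
              x$n_probes, x$de_fraction, x$de_effect_size))
  cat(sprintf("  variances g/ag/dg/hg/sg/e: %s\n",
              paste(format(unlist(x[c("var_g", "var_ag", "var_dg", "var_hg",
                                      "var_sg", "var_e")])), collapse = " ")))
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

PHENOTYPES <- c("Polled", "Horned", "Scurred")

# Animal roster mirroring the study herd when the design is large enough:
# 11 animals, 6 male / 5 female, 4 polled / 3 horned / 4 scurred, with the
# last (scurred) animal hybridised one time fewer than the rest.
animal_roster <- function(n_animals) {
  if (n_animals == 11L) {
    phen <- c("Polled", "Horned", "Scurred", "Polled", "Horned", "Scurred",
              "Polled", "Horned", "Scurred", "Polled", "Scurred")
  } else {
    phen <- rep_len(PHENOTYPES, n_animals)
  }
  data.frame(animal = paste0("A", seq_len(n_animals)),
             phenotype = phen,
             sex = rep_len(c("M", "F"), n_animals),
             stringsAsFactors = FALSE)
}

#' Generate a balanced dye-swap design table
#'
#' Lays animals out over the channel slots of a multi-chip two-colour design
#' in a round-robin so that (i) every array carries one red and one green
#' channel, (ii) any animal hybridised more than once is labelled with both
#' dyes across its hybridisations, and (iii) phenotypes and sexes are spread
#' across chips rather than confounded with them. With the default
#' configuration (4 chips x 4 arrays x 2 dyes = 32 channel slots) the eleven
#' animals of the roster are used, ten of them three times and one scurred
#' animal twice.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with one row per channel (the comparison-effect
#'   level): `channel`, `chip`, `array`, `array_id`, `dye`, `animal`,
#'   `phenotype`, `sex`.
#' @export
simulate_design <- function(config = sim_config()) {
  validate_sim_config(config)
  n_slots <- config$n_chips * config$n_arrays_per_chip * config$n_dyes
  n_animals <- min(11L, n_slots)
  # reuse with an even roster would pin each animal to one dye
  if (n_slots > n_animals && n_animals %% 2L == 0L)
    n_animals <- n_animals - 1L
  if (n_animals < 1L)
    stop("design too small: no channel slots to fill")
  roster <- animal_roster(n_animals)

  slot <- seq_len(n_slots) - 1L
  per_chip <- config$n_arrays_per_chip * 2L
  design <- data.frame(
    channel = slot + 1L,
    chip = slot %/% per_chip + 1L,
    array = (slot %% per_chip) %/% 2L + 1L,
    dye = ifelse(slot %% 2L == 0L, "red", "green"),
    animal = roster$animal[slot %% n_animals + 1L],
    stringsAsFactors = FALSE)
  design$array_id <- (design$chip - 1L) * config$n_arrays_per_chip + design$array
  m <- match(design$animal, roster$animal)
  design$phenotype <- roster$phenotype[m]
  design$sex <- roster$sex[m]
  design <- design[, c("channel", "chip", "array", "array_id", "dye",
                       "animal", "phenotype", "sex")]

  # dye-balance contract: nobody with >1 hybridisation sees only one dye
  dye_tab <- table(design$animal, design$dye)
  multi <- rowSums(dye_tab) > 1L
  if (any(multi & (dye_tab[, 1L] == 0L | dye_tab[, 2L] == 0L)))
    stop("impossible dye balance for this design size")
  design
}

#' Simulate spot-level two-colour intensities with ground truth
#'
#' Draws log2 intensities from the additive model mu + G + AG + DG + HG + SG
#' + error (all random terms i.i.d. normal at the configured variances),
#' plants phenotype-by-gene shifts on a `de_fraction` of probes, and converts
#' to linear-scale foreground/background spot statistics. A
#' `bad_spot_fraction` of spots is engineered to fail quality control: half
#' get their background pixel SD inflated so the signal-to-noise ratio drops
#' below 1, half get a foreground median discrepant from the mean so the
#' mean/median agreement ratio drops below 0.85.
#'
#' @param design A design table from [simulate_design()].
#' @param config The [sim_config()] used to build `design`.
#' @param seed Seed for this draw; defaults to `config$seed`.
#' @return A list with `spots` (one row per probe per channel: design
#'   coordinates plus `fg_mean`, `fg_median`, `bg_mean`, `bg_sd` on the
#'   linear scale) and `truth` (per probe: planted phenotype shifts
#'   `shift_polled`, `shift_horned`, `shift_scurred` in log2 units and DE
#'   flags `de_PvH`, `de_PvS`, `de_HvS`).
#' @export
simulate_spots <- function(design, config = sim_config(), seed = config$seed) {
  validate_sim_config(config)
  stopifnot(is.data.frame(design), nrow(design) >= 1L)
  with_seed(seed, {
    np <- config$n_probes
    nc <- nrow(design)
    probes <- sprintf("P%05d", seq_len(np))

    g  <- rnorm(np, 0, sqrt(config$var_g))
    ag <- matrix(rnorm(np * max(design$array_id), 0, sqrt(config$var_ag)),
                 nrow = max(design$array_id))
    dg <- matrix(rnorm(np * 2L, 0, sqrt(config$var_dg)), nrow = 2L)
    hg <- matrix(rnorm(np * 3L, 0, sqrt(config$var_hg)), nrow = 3L)
    sg <- matrix(rnorm(np * 2L, 0, sqrt(config$var_sg)), nrow = 2L)

    # planted effects sit on top of the random phenotype-by-gene draws
    shift <- matrix(0, nrow = 3L, ncol = np,
                    dimnames = list(PHENOTYPES, NULL))
    n_de <- round(config$de_fraction * np)
    if (n_de > 0L) {
      de_idx <- sample.int(np, n_de)
      de_ph <- sample.int(3L, n_de, replace = TRUE)
      de_sign <- sample(c(-1, 1), n_de, replace = TRUE)
      shift[cbind(de_ph, de_idx)] <- de_sign * config$de_effect_size
    }

    dye_i <- match(design$dye, c("red", "green"))
    ph_i <- match(design$phenotype, PHENOTYPES)
    sex_i <- match(design$sex, c("M", "F"))

    # order: probe fastest within channel
    ch <- rep(seq_len(nc), each = np)
    pr <- rep(seq_len(np), times = nc)
    y <- config$mu + g[pr] +
      ag[cbind(design$array_id[ch], pr)] +
      dg[cbind(dye_i[ch], pr)] +
      hg[cbind(ph_i[ch], pr)] + shift[cbind(ph_i[ch], pr)] +
      sg[cbind(sex_i[ch], pr)] +
      rnorm(np * nc, 0, sqrt(config$var_e))

    n <- np * nc
    bg_mean <- config$background_mean * runif(n, 0.8, 1.2)
    signal <- 2^y
    fg_mean <- bg_mean + signal
    fg_median <- fg_mean * runif(n, 0.95, 1)
    # clean spots: s between ~1.7 and 20 at the default sd scale
    bg_sd <- signal * config$background_sd_scale * runif(n, 0.05, 0.6)

    bad <- runif(n) < config$bad_spot_fraction
    bad_kind <- runif(n) < 0.5
    i_s <- which(bad & bad_kind)     # fail signal-to-noise
    i_r <- which(bad & !bad_kind)    # fail mean/median agreement
    bg_sd[i_s] <- signal[i_s] / runif(length(i_s), 0.2, 0.95)
    fg_median[i_r] <- fg_mean[i_r] * runif(length(i_r), 0.3, 0.8)

    spots <- data.frame(
      probe_id = probes[pr],
      channel = design$channel[ch],
      chip = design$chip[ch],
      array = design$array[ch],
      array_id = design$array_id[ch],
      dye = design$dye[ch],
      animal = design$animal[ch],
      phenotype = design$phenotype[ch],
      sex = design$sex[ch],
      fg_mean = fg_mean,
      fg_median = fg_median,
      bg_mean = bg_mean,
      bg_sd = bg_sd,
      stringsAsFactors = FALSE)

    truth <- data.frame(
      probe_id = probes,
      shift_polled = shift[1L, ],
      shift_horned = shift[2L, ],
      shift_scurred = shift[3L, ],
      stringsAsFactors = FALSE)
    truth$de_PvH <- truth$shift_polled != truth$shift_horned
    truth$de_PvS <- truth$shift_polled != truth$shift_scurred
    truth$de_HvS <- truth$shift_horned != truth$shift_scurred

    list(spots = spots, truth = truth)
  })
}

#' Simulate qPCR Ct tables for a relative-quantification experiment
#'
#' Generates cycle-threshold readings for one target and one reference gene
#' across the three horn phenotypes: Ct = cell mean (phenotype x gene) +
#' animal effect + replicate noise. The per-phenotype target-minus-reference
#' offsets `dct` fix the ground truth: the planted delta-delta-Ct for a
#' contrast A vs B equals `dct[A] - dct[B]`. Animal effects are shared by the
#' two genes within an animal, so they cancel exactly from the
#' delta-delta-Ct contrast in a balanced design.
#'
#' @param n_animals_per_phenotype Biological replicates per phenotype
#'   (default 4).
#' @param dct Named numeric vector of target-minus-reference Ct offsets for
#'   `Polled`, `Horned`, `Scurred` (cycles). Default all zero.
#' @param n_replicates Technical replicates per animal per gene (default 3,
#'   so 12 Ct values per phenotype per gene at the defaults).
#' @param noise_sd Replicate noise SD in cycles (default 0.3).
#' @param animal_sd SD of the animal effect in cycles (default 0.5).
#' @param target,reference Gene labels (defaults `"DSC1"`, `"GAPDH"`).
#' @param ref_mean Mean Ct of the reference gene (default 20 cycles).
#' @param seed RNG seed.
#' @return A `data.frame` with columns `animal_id`, `phenotype`, `gene`,
#'   `replicate`, `Ct`.
#' @export
simulate_qpcr <- function(n_animals_per_phenotype = 4L,
                          dct = c(Polled = 0, Horned = 0, Scurred = 0),
                          n_replicates = 3L, noise_sd = 0.3, animal_sd = 0.5,
                          target = "DSC1", reference = "GAPDH",
                          ref_mean = 20, seed = 1L) {
  stopifnot(n_replicates >= 1L, n_animals_per_phenotype >= 1L)
  full <- c(Polled = 0, Horned = 0, Scurred = 0)
  full[names(dct)] <- dct
  with_seed(seed, {
    rows <- expand.grid(replicate = seq_len(n_replicates),
                        gene = c(target, reference),
                        idx = seq_len(n_animals_per_phenotype),
                        phenotype = PHENOTYPES,
                        stringsAsFactors = FALSE)
    rows$animal_id <- paste0(substr(rows$phenotype, 1, 1), rows$idx)
    a_eff <- rnorm(n_animals_per_phenotype * 3L, 0, animal_sd)
    names(a_eff) <- unique(rows$animal_id)
    cell <- ifelse(rows$gene == reference, ref_mean,
                   ref_mean + full[rows$phenotype])
    rows$Ct <- cell + a_eff[rows$animal_id] +
      rnorm(nrow(rows), 0, noise_sd)
    rows[, c("animal_id", "phenotype", "gene", "replicate", "Ct")]
  })
}

#' Generate annotation fixture tables exercising every assignment rule
#'
#' Emits a probe-alignment table, bovine and human gene-model tables and a
#' BLAST best-hit table (all 0-based half-open coordinates) constructed so
#' that each branch of the probe-to-gene assignment algorithm is exercised:
#' bovine exon overlap with an informative name, provisional (LOC/MGC)
#' bovine names with and without a human overlap, multiple overlapping genes
#' resolved by accession number, intron-only overlap, the nearest-gene
#' fallback, and concordant as well as discordant BLAST hits. Additional
#' probes beyond the scenario set are placed randomly.
#'
#' @param n_probes Total probes to emit (at least the 9 scenario probes).
#' @param seed RNG seed for the extra random probes.
#' @return A list of data.frames: `probes` (`probe_id`, `chrom`, `start`,
#'   `end`, `strand`), `genes` (one row per exon: `gene_name`, `accession`,
#'   `species`, `chrom`, `start`, `end`), `blast` (`probe_id`, `gene_name`,
#'   `bitscore`).
#' @export
generate_annotation_fixtures <- function(n_probes = 12L, seed = 1L) {
  exon <- function(name, acc, species, chrom, start, end)
    data.frame(gene_name = name, accession = acc, species = species,
               chrom = chrom, start = start, end = end,
               stringsAsFactors = FALSE)
  genes <- rbind(
    # informative bovine gene, two exons
    exon("KRT5",      "NM_001008663", "bovine", "chr1", 1000, 1200),
    exon("KRT5",      "NM_001008663", "bovine", "chr1", 1500, 1800),
    # overlapping informative pair with distinct accessions
    exon("DSG1",      "NM_000200",    "bovine", "chr1", 3000, 3400),
    exon("DSG3",      "NM_000300",    "bovine", "chr1", 3200, 3600),
    # provisional bovine names
    exon("LOC511234", "XM_000510",    "bovine", "chr2", 1000, 1400),
    exon("MGC127781", "XM_000900",    "bovine", "chr2", 5000, 5400),
    # bovine gene for the nearest-gene branch
    exon("PKP1",      "NM_000400",    "bovine", "chr3", 100, 190),
    exon("CLDN8",     "NM_000700",    "bovine", "chr3", 9000, 9500),
    # human models
    exon("DSC1",      "NM_024421",    "human",  "chr2", 900, 1500),
    exon("IVL",       "NM_005547",    "human",  "chr2", 1100, 1300))
  scen <- data.frame(
    probe_id = sprintf("AGI%03d", 1:9),
    chrom  = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr3", "chr3",
               "chr4", "chr2"),
    start  = c(1100,  1300,  3300,  1150,  5100,  200,   8900,  500, 1000),
    end    = c(1160,  1360,  3360,  1210,  5160,  260,   8960,  560, 1060),
    stringsAsFactors = FALSE)
  # AGI001 exon overlap KRT5 (step 1, concordant blast)
  # AGI002 intron-only overlap of KRT5 -> falls through, no human -> nearest
  # AGI003 two bovine exons (DSG1/DSG3), lowest accession wins; discordant blast
  # AGI004 LOC bovine + two human overlaps (DSC1/IVL), lowest accession wins
  # AGI005 MGC bovine, no human overlap -> nearest gene
  # AGI006 exon overlap PKP1 (step 1, no blast)
  # AGI007 no overlap -> nearest CLDN8 (closer than PKP1)
  # AGI008 empty chromosome -> unassigned
  # AGI009 LOC bovine region via human-only overlap position (step 2 single)
  blast <- data.frame(
    probe_id = c("AGI001", "AGI003"),
    gene_name = c("KRT5", "DSG3"),
    bitscore = c(120, 110),
    stringsAsFactors = FALSE)
  scen$strand <- "+"
  if (n_probes > nrow(scen)) {
    extra <- with_seed(seed, {
      k <- n_probes - nrow(scen)
      st <- sample.int(10000L, k)
      data.frame(probe_id = sprintf("AGI%03d", nrow(scen) + seq_len(k)),
                 chrom = sample(c("chr1", "chr2", "chr3"), k, replace = TRUE),
                 start = st, end = st + 60L, strand = "+",
                 stringsAsFactors = FALSE)
    })
    scen <- rbind(scen, extra)
  }
  list(probes = scen[, c("probe_id", "chrom", "start", "end", "strand")],
       genes = genes, blast = blast)
}
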